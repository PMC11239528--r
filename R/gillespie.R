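# Photon-level stochastic simulation: Gillespie trajectories of the
# joint model, photon emission/detection, and camera-style framing.

#' Construct a photon stream
#'
#' Timestamped, channel-labelled photons from one or more simulated (or
#' loaded) molecules.  Times must be strictly increasing within each
#' molecule.
#'
#' @param time_s Photon times (s).
#' @param channel Character vector, `"donor"` or `"acceptor"`.
#' @param detected Logical vector: whether the photon was detected.
#' @param molecule_id Integer molecule labels (recycled if scalar).
#' @return An object of class `"photon_stream"` (a data frame).
#' @export
photon_stream <- function(time_s, channel, detected = TRUE,
                          molecule_id = 1L) {
  n <- length(time_s)
  channel <- as.character(channel)
  if (length(channel) == 1L) channel <- rep_len(channel, n)
  detected <- rep_len(as.logical(detected), n)
  molecule_id <- rep_len(as.integer(molecule_id), n)
  if (length(channel) != n || anyNA(channel))
    stop("'channel' must match 'time_s' in length")
  if (!all(channel %in% c("donor", "acceptor")))
    stop("channel labels must be 'donor' or 'acceptor'")
  for (m in unique(molecule_id)) {
    tm <- time_s[molecule_id == m]
    if (is.unsorted(tm, strictly = TRUE))
      stop(sprintf("photon times not strictly increasing for molecule %d", m))
  }
  structure(data.frame(molecule_id = molecule_id, time_s = time_s,
                       channel = channel, detected = detected),
            class = c("photon_stream", "data.frame"))
}

#' Construct a per-frame intensity trace
#'
#' Donor/acceptor photon counts per camera frame.  Frames are half-open
#' intervals `[k dt, (k+1) dt)`.  Raw traces hold non-negative integer
#' counts; corrected traces may hold real values.
#'
#' @param donor,acceptor Per-frame counts (equal length).
#' @param frame_dt Frame exposure (s).
#' @param correction_state One of `"raw"`, `"ct_de_corrected"`,
#'   `"gamma_corrected"`, `"zeta_corrected"`.
#' @param molecule_id Integer label.
#' @return An object of class `"intensity_trace"`.
#' @export
intensity_trace <- function(donor, acceptor, frame_dt,
                            correction_state = "raw", molecule_id = 1L) {
  if (length(donor) != length(acceptor))
    stop("'donor' and 'acceptor' must have equal length")
  if (frame_dt <= 0) stop("'frame_dt' must be positive")
  correction_state <- match.arg(correction_state,
    c("raw", "ct_de_corrected", "gamma_corrected", "zeta_corrected"))
  if (correction_state == "raw" &&
      (any(donor < 0) || any(acceptor < 0) ||
       any(donor != round(donor)) || any(acceptor != round(acceptor))))
    stop("raw traces must hold non-negative integer counts")
  structure(list(donor = as.numeric(donor), acceptor = as.numeric(acceptor),
                 frame_dt = frame_dt, correction_state = correction_state,
                 molecule_id = as.integer(molecule_id)),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("Intensity trace (molecule %d): %d frames of %.4g s [%s]\n",
              x$molecule_id, length(x$donor), x$frame_dt, x$correction_state))
  cat(sprintf("  mean donor %.2f, mean acceptor %.2f per frame\n",
              mean(x$donor), mean(x$acceptor)))
  invisible(x)
}

.run_gillespie <- function(model, duration, record_dwells, detected_only) {
  ch <- model$channels
  fD <- model$pair$donor
  fA <- model$pair$acceptor
  gillespie_run_cpp(as.integer(ch[, "from"]), as.integer(ch[, "to"]),
                    as.numeric(ch[, "rate"]), as.integer(ch[, "photon"]),
                    length(model$states), duration,
                    p_em_d = fD$k_em / (fD$k_em + fD$k_nr),
                    p_em_a = fA$k_em / (fA$k_em + fA$k_nr),
                    eta_d = fD$eta, eta_a = fA$eta,
                    record_dwells = record_dwells,
                    detected_only = detected_only)
}

#' Simulate one Gillespie trajectory of a joint model
#'
#' Standard stochastic simulation: exponential holding times at the
#' total exit rate of the current state and categorical next-state
#' choice proportional to the channel rates.  A donor (acceptor) photon
#' is emitted at each S1 -> S0 transition taken through the combined
#' `k_em + k_nr` channel with probability `k_em/(k_em + k_nr)`, and an
#' emitted photon is marked detected with probability `eta` of its
#' channel.  Fully reproducible given `seed`.
#'
#' @param model A [build_model()] result.
#' @param duration Simulated time (s).
#' @param seed Integer RNG seed.
#' @param record_dwells Keep the full dwell-segment record (state,
#'   entry, exit); disable for long ensembles.
#' @param detected_only Drop undetected photons from the stream (their
#'   counts are still reported).
#' @param molecule_id Label attached to the photon stream.
#' @return A list with elements `trajectory` (class
#'   `"trajectory_record"`: dwell data frame, seed, model) and
#'   `photons` (a [photon_stream()]).  The trajectory carries emission
#'   and detection counts in `counts`.
#' @export
simulate_trajectory <- function(model, duration, seed,
                                record_dwells = TRUE, detected_only = FALSE,
                                molecule_id = 1L) {
  stopifnot(inherits(model, "joint_model"))
  if (duration <= 0) stop("'duration' must be positive")
  set.seed(as.integer(seed))
  res <- .run_gillespie(model, duration, record_dwells, detected_only)
  photons <- photon_stream(
    time_s = res$time,
    channel = c("donor", "acceptor")[res$channel],
    detected = res$detected == 1L,
    molecule_id = molecule_id)
  dwells <- data.frame(state = model$states[res$dwell_state],
                       enter = res$dwell_enter, exit = res$dwell_exit)
  traj <- structure(list(dwells = dwells, seed = as.integer(seed),
                         duration = duration, model = model,
                         counts = c(emitted_donor = res$n_emitted_donor,
                                    emitted_acceptor = res$n_emitted_acceptor,
                                    detected_donor = res$n_detected_donor,
                                    detected_acceptor = res$n_detected_acceptor,
                                    events = res$n_events)),
                    class = "trajectory_record")
  list(trajectory = traj, photons = photons)
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat(sprintf("Gillespie trajectory: %.4g s, %d dwell segments, seed %d\n",
              x$duration, nrow(x$dwells), x$seed))
  print(x$counts)
  invisible(x)
}

#' Per-state time occupancy of a trajectory
#'
#' Fraction of the simulated time spent in each model state; the
#' empirical counterpart of [solve_steady_state()] occupancies.
#'
#' @param traj A `"trajectory_record"`.
#' @return Named numeric vector summing to 1.
#' @export
occupancy_fractions <- function(traj) {
  stopifnot(inherits(traj, "trajectory_record"))
  dt <- traj$dwells$exit - traj$dwells$enter
  occ <- tapply(dt, factor(traj$dwells$state, levels = traj$model$states),
                sum, default = 0)
  occ <- as.numeric(occ) / traj$duration
  names(occ) <- traj$model$states
  occ
}

#' Bin a photon stream into camera frames
#'
#' Only detected photons are counted; a photon at time `t` falls into
#' frame `floor(t / frame_dt)` (half-open, zero-based bins).  The
#' duration is truncated to an integer number of frames and photons
#' beyond it are dropped (their number is reported via a message).
#'
#' @param stream A [photon_stream()] for a single molecule.
#' @param frame_dt Frame exposure (s).
#' @param duration Total time to frame (s).
#' @return An [intensity_trace()] in state `"raw"`.
#' @export
bin_photons <- function(stream, frame_dt, duration) {
  stopifnot(inherits(stream, "photon_stream"))
  if (frame_dt <= 0) stop("'frame_dt' must be positive")
  n_frames <- floor(duration / frame_dt + 1e-9)  # guard binary rounding
  if (n_frames < 1) stop("'duration' shorter than one frame")
  keep <- stream$detected
  t <- stream$time_s[keep]
  ch <- stream$channel[keep]
  inside <- t < n_frames * frame_dt
  if (any(!inside))
    message(sprintf("bin_photons: dropped %d photon(s) beyond the framed window",
                    sum(!inside)))
  t <- t[inside]; ch <- ch[inside]
  frame <- floor(t / frame_dt)
  donor <- tabulate(frame[ch == "donor"] + 1L, nbins = n_frames)
  acceptor <- tabulate(frame[ch == "acceptor"] + 1L, nbins = n_frames)
  mid <- if (nrow(stream)) stream$molecule_id[1] else 1L
  intensity_trace(donor, acceptor, frame_dt, "raw", molecule_id = mid)
}

#' Simulate an ensemble of intensity traces
#'
#' Runs independent Gillespie trajectories for `n_molecules` molecules
#' of the same model and bins each photon stream into frames.
#' Per-molecule seeds are drawn deterministically from `base_seed`, so
#' the ensemble is reproducible and independent of evaluation order.
#'
#' @param model A [build_model()] result.
#' @param n_molecules Number of molecules.
#' @param duration Per-molecule simulated time (s).
#' @param frame_dt Frame exposure (s).
#' @param base_seed Integer seed for the ensemble.
#' @return List of [intensity_trace()] objects, one per molecule.
#' @export
simulate_ensemble <- function(model, n_molecules, duration, frame_dt,
                              base_seed) {
  stopifnot(inherits(model, "joint_model"), n_molecules >= 1)
  set.seed(as.integer(base_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_molecules)
  lapply(seq_len(n_molecules), function(i) {
    sim <- simulate_trajectory(model, duration, seeds[i],
                               record_dwells = FALSE, detected_only = TRUE,
                               molecule_id = i)
    bin_photons(sim$photons, frame_dt, duration)
  })
}
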