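# Experimental-style analysis of intensity traces: crosstalk and
# direct-excitation correction, empirical gamma, per-frame FRET
# efficiencies, zeta application, brightness sweeps and population
# histograms.

#' Correct a raw trace for crosstalk and acceptor direct excitation
#'
#' `I_A' = I_A - alpha I_D - delta (I_D + I_A)`, donor channel
#' unchanged.  `alpha` is the donor-to-acceptor spectral bleed-through
#' fraction; `delta` the acceptor direct-excitation fraction, applied
#' as a fraction of the total emission.  The operation is affine and
#' invertible for `alpha + delta < 1`, and may only be applied once:
#' the trace's correction state is tracked.
#'
#' @param trace A raw [intensity_trace()].
#' @param alpha,delta Correction fractions in `[0, 1)`.
#' @return An [intensity_trace()] in state `"ct_de_corrected"`.
#' @export
correct_crosstalk_direct <- function(trace, alpha, delta) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (trace$correction_state != "raw")
    stop("trace is already corrected (state: ", trace$correction_state, ")")
  if (alpha < 0 || alpha >= 1 || delta < 0 || delta >= 1)
    stop("'alpha' and 'delta' must lie in [0, 1)")
  acc <- trace$acceptor - alpha * trace$donor -
    delta * (trace$donor + trace$acceptor)
  out <- trace
  out$acceptor <- acc
  out$correction_state <- "ct_de_corrected"
  out
}

#' Empirical gamma factor from FRET and no-FRET ensembles
#'
#' `gamma = |<I_A^FRET> - <I_A^NoFRET>| / |<I_D^FRET> - <I_D^NoFRET>|`,
#' where `< >` averages the per-trace mean frame counts across
#' molecules.  The no-FRET ensemble is typically obtained from
#' simulations with the energy transfer switched off (see
#' [without_fret()]) or, for real data, from donor emission after
#' acceptor photobleaching.
#'
#' @param fret_traces,nofret_traces Lists of crosstalk/direct-excitation
#'   corrected [intensity_trace()] objects.
#' @return gamma > 0.
#' @export
empirical_gamma <- function(fret_traces, nofret_traces) {
  for (tr in c(fret_traces, nofret_traces)) {
    stopifnot(inherits(tr, "intensity_trace"))
    if (tr$correction_state != "ct_de_corrected")
      stop("empirical_gamma expects ct/de-corrected traces")
  }
  if (!length(fret_traces) || !length(nofret_traces))
    stop("both trace sets must be non-empty")
  m <- function(traces, chan) mean(vapply(traces, function(tr) mean(tr[[chan]]), 0))
  dA <- abs(m(fret_traces, "acceptor") - m(nofret_traces, "acceptor"))
  dD <- abs(m(fret_traces, "donor") - m(nofret_traces, "donor"))
  if (dD == 0)
    stop("donor brightness identical between FRET and no-FRET sets: ",
         "gamma undefined")
  dA / dD
}

#' Per-frame FRET efficiency of a corrected trace
#'
#' `E = I_A / (I_A + gamma I_D)` per frame.  Frames with
#' `I_A + gamma I_D = 0` are invalid and excluded; the remaining values
#' are clipped to `[-0.2, 1.2]` for histogramming.
#'
#' @param trace A ct/de-corrected [intensity_trace()].
#' @param gamma Gamma correction factor.
#' @return Numeric vector of efficiencies with attribute `"frame"`
#'   giving the originating frame indices (1-based).
#' @export
efficiency_per_frame <- function(trace, gamma) {
  apply_zeta_to_trace(trace, gamma, zeta = 0)
}

#' Zeta-corrected per-frame FRET efficiency
#'
#' `E_true = I_A / (I_A (1 - zeta) + gamma I_D)` per frame, reducing to
#' [efficiency_per_frame()] at `zeta = 0`.  The zeta value should come
#' from [zeta_nine_state()] (or [zeta_four_state()]) evaluated at the
#' trace's excitation rate, and gamma from the lowest-illumination
#' estimate per the correction protocol.
#'
#' @inheritParams efficiency_per_frame
#' @param zeta Zeta correction parameter, `0 <= zeta < 1`.
#' @return Numeric vector of efficiencies with attribute `"frame"`.
#' @export
apply_zeta_to_trace <- function(trace, gamma, zeta) {
  stopifnot(inherits(trace, "intensity_trace"), gamma > 0)
  if (trace$correction_state == "raw")
    stop("correct the trace for crosstalk/direct excitation first")
  if (zeta < 0 || zeta >= 1) stop("'zeta' must lie in [0, 1)")
  den <- trace$acceptor * (1 - zeta) + gamma * trace$donor
  valid <- is.finite(den) & den != 0
  e <- trace$acceptor[valid] / den[valid]
  e <- pmin(pmax(e, -0.2), 1.2)
  attr(e, "frame") <- which(valid)
  e
}

#' Population FRET efficiency histogram
#'
#' Pools the first `frames_per_trace` valid frames of every trace into
#' one efficiency histogram over `[-0.2, 1.2]`.
#'
#' @param traces List of ct/de-corrected [intensity_trace()] objects,
#'   all at the same correction state.
#' @param gamma Gamma correction factor.
#' @param zeta Zeta correction parameter (default 0: plain
#'   gamma-corrected efficiencies).
#' @param bins Number of bins (default 61).
#' @param frames_per_trace Maximum valid frames used per trace
#'   (default all).
#' @return An object of class `"population_histogram"`: `breaks`,
#'   `mids`, `counts`, `n_traces`, `frames_used`.
#' @export
population_histogram <- function(traces, gamma, zeta = 0, bins = 61,
                                 frames_per_trace = Inf) {
  if (!length(traces)) stop("'traces' must be non-empty")
  states <- vapply(traces, function(tr) tr$correction_state, "")
  if (length(unique(states)) != 1L)
    stop("all traces must share one correction state")
  es <- unlist(lapply(traces, function(tr) {
    e <- apply_zeta_to_trace(tr, gamma, zeta)
    utils::head(as.numeric(e), frames_per_trace)
  }))
  breaks <- seq(-0.2, 1.2, length.out = bins + 1L)
  counts <- tabulate(findInterval(es, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  structure(list(breaks = breaks, mids = (breaks[-1] + breaks[-(bins + 1)]) / 2,
                 counts = counts, n_traces = length(traces),
                 frames_used = length(es)),
            class = "population_histogram")
}

#' @export
print.population_histogram <- function(x, ...) {
  cat(sprintf("Population FRET histogram: %d frames from %d traces, %d bins\n",
              x$frames_used, x$n_traces, length(x$counts)))
  invisible(x)
}

#' @export
plot.population_histogram <- function(x, ...) {
  graphics::plot(x$mids, x$counts, type = "h", xlab = "FRET efficiency",
                 ylab = "frames", ...)
  invisible(x)
}

#' Locate modes of a population histogram
#'
#' Smooths the counts with a short running mean and reports bins that
#' are strict local maxima exceeding a minimum fraction of the total.
#' Used to count resolved FRET species in multi-distance mixtures.
#'
#' @param hist A `"population_histogram"`.
#' @param min_frac Minimum smoothed height as a fraction of the total
#'   count for a mode to be reported.
#' @param halfwidth Neighbourhood half-width (bins) over which a mode
#'   must dominate.
#' @return Numeric vector of mode positions (bin midpoints).
#' @export
find_histogram_peaks <- function(hist, min_frac = 0.01, halfwidth = 2L) {
  stopifnot(inherits(hist, "population_histogram"))
  y <- as.numeric(stats::filter(hist$counts, rep(1 / 3, 3), sides = 2))
  y[is.na(y)] <- hist$counts[is.na(y)]
  thr <- min_frac * sum(hist$counts)
  n <- length(y)
  cand <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - halfwidth); hi <- min(n, i + halfwidth)
    y[i] >= thr && y[i] == max(y[lo:hi])
  }, logical(1))
  if (!any(cand)) return(numeric(0))
  # collapse plateaus of tied candidates into a single mode each
  idx <- which(cand)
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  unname(vapply(runs, function(ix) hist$mids[ix[ceiling(length(ix) / 2)]], 0))
}

#' Donor/acceptor brightness versus illumination intensity
#'
#' For each intensity, simulates matched nine-state FRET and no-FRET
#' (`k_ET = 0`) ensembles and summarises the mean per-frame donor and
#' acceptor brightness together with the empirical gamma estimate.
#' Saturation of the brightness-intensity relation is the tell-tale
#' signature of triplet accumulation.
#'
#' @param pair A [fret_pair()].
#' @param intensities Irradiances (W cm^-2), at least two.
#' @param n_molecules Molecules per condition.
#' @param seed Integer base seed.
#' @param duration Per-molecule simulated time (s).
#' @param frame_dt Frame exposure (s).
#' @param wavelength Excitation wavelength (nm).
#' @return Data frame with one row per intensity: `intensity`, `k_ex`,
#'   `I_D_fret`, `I_A_fret`, `I_D_nofret`, `I_A_nofret`, the
#'   corresponding standard deviations across molecules, and `gamma`.
#' @export
brightness_sweep <- function(pair, intensities, n_molecules = 10, seed = 1,
                             duration = 2, frame_dt = 0.1, wavelength = 532) {
  stopifnot(inherits(pair, "fret_pair"), length(intensities) >= 2)
  rows <- lapply(seq_along(intensities), function(j) {
    I <- intensities[j]
    k_ex <- excitation_rate(illumination(I, wavelength), pair$donor$epsilon)
    m_f <- build_model(pair, k_ex, "nine_state")
    m_n <- build_model(without_fret(pair), k_ex, "nine_state")
    tr_f <- lapply(simulate_ensemble(m_f, n_molecules, duration, frame_dt,
                                     base_seed = seed + 2L * j),
                   correct_crosstalk_direct, alpha = 0, delta = 0)
    tr_n <- lapply(simulate_ensemble(m_n, n_molecules, duration, frame_dt,
                                     base_seed = seed + 2L * j + 1L),
                   correct_crosstalk_direct, alpha = 0, delta = 0)
    mns <- function(traces, chan) vapply(traces, function(tr) mean(tr[[chan]]), 0)
    gam <- if (all(pair$acceptor$eta == 0, pair$donor$eta == 0)) NA_real_ else
      tryCatch(empirical_gamma(tr_f, tr_n), error = function(e) NA_real_)
    data.frame(intensity = I, k_ex = k_ex,
               I_D_fret = mean(mns(tr_f, "donor")),
               I_A_fret = mean(mns(tr_f, "acceptor")),
               I_D_nofret = mean(mns(tr_n, "donor")),
               I_A_nofret = mean(mns(tr_n, "acceptor")),
               sd_D_fret = stats::sd(mns(tr_f, "donor")),
               sd_A_fret = stats::sd(mns(tr_f, "acceptor")),
               sd_D_nofret = stats::sd(mns(tr_n, "donor")),
               gamma = gam)
  })
  do.call(rbind, rows)
}
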