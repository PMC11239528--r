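# Confocal-style photon-burst analysis: inter-photon-time burst
# selection, background correction, burst-threshold filtering and
# per-burst FRET efficiencies.

#' Burst selection configuration
#'
#' @param dt_max Maximum inter-photon time within a burst (s).
#' @param BT Burst threshold: bursts whose background-corrected total
#'   photon count `n_D + n_A` does not exceed `BT` are discarded.
#' @param bg_D,bg_A Background photon rates per channel (s^-1).
#' @return An object of class `"burst_config"`.
#' @export
burst_config <- function(dt_max, BT = 0, bg_D = 0, bg_A = 0) {
  stopifnot(dt_max > 0, BT >= 0, bg_D >= 0, bg_A >= 0)
  structure(list(dt_max = dt_max, BT = BT, bg_D = bg_D, bg_A = bg_A),
            class = "burst_config")
}

#' Select photon bursts by inter-photon time
#'
#' A burst is a maximal run of consecutive photons whose inter-photon
#' gaps are all `<= dt_max`; the burst length is the time from its
#' first to its last photon, so an isolated photon forms a degenerate
#' burst of length zero (removable via the burst threshold).  The
#' expected background `bg * T` is subtracted from each channel's raw
#' count (floored at zero) and bursts whose corrected total count is
#' `<= BT` are discarded.
#'
#' @param stream A [photon_stream()] (detected photons of one
#'   molecule/measurement; undetected photons are ignored).
#' @param cfg A [burst_config()].
#' @param bleach_filter Optional predicate `function(times, channels)`
#'   returning `FALSE` for bursts to drop (e.g.
#'   [acceptor_bleach_filter()]); default none.
#' @return Data frame of class `"burst_table"`: `start`, `stop`, `T`,
#'   `n_D_raw`, `n_A_raw`, `n_D`, `n_A` (background-corrected).
#' @export
select_bursts <- function(stream, cfg, bleach_filter = NULL) {
  stopifnot(inherits(stream, "photon_stream"), inherits(cfg, "burst_config"))
  t <- stream$time_s[stream$detected]
  ch <- stream$channel[stream$detected]
  if (is.unsorted(t, strictly = TRUE)) stop("photon times must be sorted")
  n <- length(t)
  empty <- data.frame(start = numeric(0), stop = numeric(0), T = numeric(0),
                      n_D_raw = integer(0), n_A_raw = integer(0),
                      n_D = numeric(0), n_A = numeric(0))
  class(empty) <- c("burst_table", "data.frame")
  if (n == 0) return(empty)
  # runs of photons linked by gaps <= dt_max
  linked <- diff(t) <= cfg$dt_max
  run_id <- cumsum(c(1L, as.integer(!linked)))
  rows <- lapply(split(seq_len(n), run_id), function(ix) {
    tt <- t[ix]; cc <- ch[ix]
    if (!is.null(bleach_filter) && !isTRUE(bleach_filter(tt, cc)))
      return(NULL)
    T_len <- tt[length(tt)] - tt[1]
    nD <- sum(cc == "donor"); nA <- sum(cc == "acceptor")
    data.frame(start = tt[1], stop = tt[length(tt)], T = T_len,
               n_D_raw = nD, n_A_raw = nA,
               n_D = max(nD - cfg$bg_D * T_len, 0),
               n_A = max(nA - cfg$bg_A * T_len, 0))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[out$n_D + out$n_A > cfg$BT, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("burst_table", "data.frame")
  out
}

#' Per-burst FRET efficiency
#'
#' `E = n_A' / (n_A' + n_D)` with the acceptor count first reduced for
#' direct excitation, `n_A' = n_A - delta (n_A + n_D)`, then floored at
#' zero; the result is clipped to `[0, 1]`.
#'
#' @param bursts A `"burst_table"` from [select_bursts()] (uses the
#'   background-corrected counts).
#' @param delta Acceptor direct-excitation fraction in `[0, 1)`.
#' @return Numeric vector of per-burst efficiencies.
#' @export
burst_efficiency <- function(bursts, delta = 0) {
  stopifnot(inherits(bursts, "burst_table"), delta >= 0, delta < 1)
  nA <- pmax(bursts$n_A - delta * (bursts$n_A + bursts$n_D), 0)
  nD <- bursts$n_D
  tot <- nA + nD
  if (any(tot == 0)) stop("burst with zero corrected photons: raise BT")
  pmin(pmax(nA / tot, 0), 1)
}

#' Power-specific dt_max from the inter-photon time distribution
#'
#' Runs an initial burst selection at a common `initial_dt_max`,
#' collects all within-burst inter-photon times, and returns their
#' upper `q` quantile: the smallest gap length encompassing a fraction
#' `q` of the observed distribution.  Deterministic.
#'
#' @param stream A [photon_stream()].
#' @param initial_dt_max Common starting threshold (s), default 150 us.
#' @param q Upper quantile (default 0.999).
#' @return Suggested `dt_max` (s).
#' @export
dtmax_from_distribution <- function(stream, initial_dt_max = 150e-6,
                                    q = 0.999) {
  stopifnot(inherits(stream, "photon_stream"))
  t <- stream$time_s[stream$detected]
  if (length(t) < 2) stop("too few photons to analyse inter-photon times")
  gaps <- diff(t)
  inburst <- gaps[gaps <= initial_dt_max]
  if (!length(inburst)) stop("no inter-photon times below 'initial_dt_max'")
  unname(stats::quantile(inburst, q, type = 1))
}

#' Acceptor-photobleach burst filter (heuristic)
#'
#' Simple built-in predicate for dropping bursts in which the acceptor
#' appears to photobleach mid-transit: the burst is split at its
#' temporal midpoint and rejected when the acceptor-count asymmetry
#' between halves exceeds `z` standard scores.  This heuristic is a
#' pragmatic stand-in for dedicated bleach-detection algorithms and is
#' off by default.
#'
#' @param z Rejection threshold in standard scores (default 3).
#' @return A predicate `function(times, channels)` for
#'   [select_bursts()].
#' @export
acceptor_bleach_filter <- function(z = 3) {
  function(times, channels) {
    acc <- channels == "acceptor"
    n <- sum(acc)
    if (n < 4) return(TRUE)
    mid <- (times[1] + times[length(times)]) / 2
    n1 <- sum(acc & times <= mid)
    n2 <- n - n1
    abs(n1 - n2) / sqrt(n) <= z
  }
}
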