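# Shared generators for randomized photophysical parameter sets and
# small simulation fixtures.

rand_fluorophore <- function(name = "dye") {
  fluorophore(name,
              epsilon = 10^stats::runif(1, 4, 5.5),
              k_em = 10^stats::runif(1, 7.8, 8.8),
              k_nr = 10^stats::runif(1, 8, 9.3),
              k_ISC = 10^stats::runif(1, 5.5, 7.5),
              k_TR = 10^stats::runif(1, 4, 6.5),
              eta = stats::runif(1, 0.1, 0.5))
}

rand_pair <- function() {
  R0 <- stats::runif(1, 40, 70)
  fret_pair(rand_fluorophore("D"), rand_fluorophore("A"),
            R0 = R0, R = R0 * stats::runif(1, 0.7, 1.5))
}

# independent 3x3 null-space solve used as oracle for the closed form
solve_null_3st <- function(k_ex, k_em, k_nr, k_ISC, k_TR) {
  K <- matrix(c(-k_ex,            k_ex,                    0,
                k_em + k_nr,     -(k_em + k_nr + k_ISC),   k_ISC,
                k_TR,             0,                      -k_TR),
              3, 3, byrow = TRUE)
  qr.solve(rbind(t(K), rep(1, 3)), c(0, 0, 0, 1))
}

# brute-force burst scan: grow runs photon by photon, O(n) but written
# independently of the package's vectorised implementation
brute_force_bursts <- function(time_s, channel, dt_max, BT, bg_D = 0, bg_A = 0) {
  n <- length(time_s)
  out <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && (time_s[j + 1] - time_s[j]) <= dt_max) j <- j + 1L
    T_len <- time_s[j] - time_s[i]
    nD <- sum(channel[i:j] == "donor")
    nA <- sum(channel[i:j] == "acceptor")
    cD <- max(nD - bg_D * T_len, 0)
    cA <- max(nA - bg_A * T_len, 0)
    if (cD + cA > BT)
      out[[length(out) + 1L]] <- c(start = time_s[i], stop = time_s[j],
                                   n_D_raw = nD, n_A_raw = nA)
    i <- j + 1L
  }
  do.call(rbind, out)
}

cy3cy5_pair <- function() load_pair("cy3_cy5")
ld_pair <- function() load_pair("ld555_ld655")

raw_trace <- function(donor, acceptor, frame_dt = 0.1)
  intensity_trace(donor, acceptor, frame_dt)

ctde <- function(trace, alpha = 0, delta = 0)
  correct_crosstalk_direct(trace, alpha, delta)
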