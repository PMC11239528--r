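test_that("trajectories are bit-for-bit reproducible and conserve photons", {
  pair <- cy3cy5_pair()
  m <- build_model(pair, 1e5, "nine_state")
  s1 <- simulate_trajectory(m, 0.5, seed = 7)
  s2 <- simulate_trajectory(m, 0.5, seed = 7)
  expect_identical(s1$photons, s2$photons)
  expect_identical(s1$trajectory$dwells, s2$trajectory$dwells)
  s3 <- simulate_trajectory(m, 0.5, seed = 8)
  expect_false(identical(s1$photons$time_s, s3$photons$time_s))

  cnt <- s1$trajectory$counts
  ph <- s1$photons
  expect_equal(sum(ph$channel == "donor"), unname(cnt["emitted_donor"]))
  expect_equal(sum(ph$channel == "acceptor"), unname(cnt["emitted_acceptor"]))
  expect_equal(sum(ph$detected & ph$channel == "donor"),
               unname(cnt["detected_donor"]))
  expect_lte(cnt["detected_donor"], cnt["emitted_donor"])
  expect_lte(cnt["detected_acceptor"], cnt["emitted_acceptor"])
  # dwell segments tile [0, duration) without gaps
  dw <- s1$trajectory$dwells
  expect_equal(dw$enter[1], 0)
  expect_equal(dw$exit[nrow(dw)], 0.5)
  expect_equal(dw$enter[-1], dw$exit[-nrow(dw)])
  expect_true(all(dw$state[-1] != dw$state[-nrow(dw)]))
})

test_that("no triplet states are visited when intersystem crossing is off", {
  noisc <- function(fl) fluorophore(fl$name, fl$epsilon, fl$k_em, fl$k_nr, 0,
                                    fl$k_TR, fl$eta)
  p <- cy3cy5_pair()
  p0 <- fret_pair(noisc(p$donor), noisc(p$acceptor), R0 = p$R0, R = p$R)
  sim <- simulate_trajectory(build_model(p0, 1e5, "nine_state"), 0.5, seed = 1)
  occ <- occupancy_fractions(sim$trajectory)
  expect_equal(unname(sum(occ[grepl("TD|TA", names(occ))])), 0)
})

test_that("long-run occupancy and photon rates match the master equation", {
  pair <- cy3cy5_pair()
  k_ex <- 1e5
  duration <- 2            # 2e5 excitation cycles
  m <- build_model(pair, k_ex, "nine_state")
  ss <- solve_steady_state(m)
  sim <- simulate_trajectory(m, duration, seed = 21)
  occ <- occupancy_fractions(sim$trajectory)
  n_dwell <- nrow(sim$trajectory$dwells)
  for (s in names(occ)) {
    se <- sqrt(ss$probs[[s]] * (1 - ss$probs[[s]]) / n_dwell) +
      5 / n_dwell  # guard for near-zero occupancies
    expect_lt(abs(occ[[s]] - ss$probs[[s]]), 3 * se + 3e-3)
  }
  # detected photon rates within 3 sigma (Poisson)
  nd <- sim$trajectory$counts[["detected_donor"]]
  na <- sim$trajectory$counts[["detected_acceptor"]]
  expect_lt(abs(nd - ss$rho_D * duration), 3 * sqrt(ss$rho_D * duration) + 1)
  expect_lt(abs(na - ss$rho_A * duration), 3 * sqrt(ss$rho_A * duration) + 1)
})

test_that("ground-state dwell times are exponential at the excitation rate", {
  pair <- ld_pair()
  k_ex <- 2e4
  m <- build_model(pair, k_ex, "nine_state")
  sim <- simulate_trajectory(m, 1.2, seed = 31)   # >= 1e4 dwells
  dw <- sim$trajectory$dwells
  d0 <- dw[dw$state == "S0D.S0A", ]
  d0 <- d0[-nrow(d0), ]                            # last dwell is censored
  expect_gt(nrow(d0), 1e4)
  ks <- suppressWarnings(stats::ks.test(d0$exit - d0$enter, "pexp",
                                        rate = k_ex))
  expect_gt(ks$p.value, 0.01)
})

test_that("photon binning uses half-open zero-based frames and conserves counts", {
  st <- photon_stream(c(0.0999, 0.1000, 0.25), c("donor", "donor", "acceptor"),
                      detected = TRUE)
  tr <- bin_photons(st, 0.1, 0.3)
  expect_equal(tr$donor, c(1, 1, 0))
  expect_equal(tr$acceptor, c(0, 0, 1))
  # undetected photons are not counted
  st2 <- photon_stream(c(0.01, 0.02), c("donor", "acceptor"),
                       detected = c(TRUE, FALSE))
  tr2 <- bin_photons(st2, 0.1, 0.2)
  expect_equal(sum(tr2$donor) + sum(tr2$acceptor), 1)
  # photons beyond the framed window are dropped with a message
  expect_message(tr3 <- bin_photons(photon_stream(c(0.05, 0.27), "donor"),
                                    0.1, 0.25), "dropped 1")
  expect_equal(length(tr3$donor), 2L)
  expect_equal(sum(tr3$donor), 1)
  # empty stream
  tr4 <- bin_photons(photon_stream(numeric(0), character(0)), 0.1, 0.5)
  expect_equal(tr4$donor, rep(0, 5))
})

test_that("ensembles have the documented framing and match expected rates", {
  pair <- ld_pair()
  m <- build_model(pair, 1e4, "nine_state")
  traces <- simulate_ensemble(m, 10, 10, 0.1, base_seed = 5)
  expect_length(traces, 10)
  for (tr in traces) expect_length(tr$donor, 100L)
  expect_identical(simulate_ensemble(m, 3, 1, 0.1, base_seed = 9),
                   simulate_ensemble(m, 3, 1, 0.1, base_seed = 9))
  ss <- solve_steady_state(m)
  mean_d <- mean(vapply(traces, function(tr) mean(tr$donor), 0))
  mean_a <- mean(vapply(traces, function(tr) mean(tr$acceptor), 0))
  tot_frames <- 10 * 100
  se_d <- sqrt(ss$rho_D * 0.1 / tot_frames)
  se_a <- sqrt(ss$rho_A * 0.1 / tot_frames)
  expect_lt(abs(mean_d - ss$rho_D * 0.1), 3 * se_d)
  expect_lt(abs(mean_a - ss$rho_A * 0.1), 3 * se_a)
})

test_that("zero detection efficiency yields all-zero traces", {
  p <- cy3cy5_pair()
  dark <- function(fl) fluorophore(fl$name, fl$epsilon, fl$k_em, fl$k_nr,
                                   fl$k_ISC, fl$k_TR, eta = 0)
  p0 <- fret_pair(dark(p$donor), dark(p$acceptor), R0 = p$R0, R = p$R)
  traces <- simulate_ensemble(build_model(p0, 1e5, "nine_state"), 2, 0.5, 0.1,
                              base_seed = 2)
  for (tr in traces) expect_equal(sum(tr$donor) + sum(tr$acceptor), 0)
})

test_that("annihilation extensions deplete the targeted excited states", {
  pair <- cy3cy5_pair()
  m <- build_model(pair, 1e6, "nine_state")
  expect_equal(with_extensions(m, 0, 0, FALSE)$Q, m$Q)
  ss0 <- solve_steady_state(m)
  ss_ssa <- solve_steady_state(with_extensions(m, k_SSA = 1e9))
  expect_lt(ss_ssa$probs[["S1D.S1A"]], ss0$probs[["S1D.S1A"]])
  ss_sta <- solve_steady_state(with_extensions(m, k_STA = 1e9))
  ss_risc <- solve_steady_state(with_extensions(m, k_STA = 1e9, risc = TRUE))
  occ_TA <- function(ss) sum(ss$probs[grepl("\\.TA$", names(ss$probs))])
  expect_lt(occ_TA(ss_risc), occ_TA(ss_sta))
  # RISC wiring: S1D.TA feeds S0D.S1A
  mr <- with_extensions(m, k_STA = 1e9, risc = TRUE)
  expect_equal(mr$Q["S1D.TA", "S0D.S1A"], 1e9)
  mst <- with_extensions(m, k_STA = 1e9)
  expect_equal(mst$Q["S1D.TA", "S0D.TA"],
               pair$donor$k_em + pair$donor$k_nr + 1e9)
})

test_that("ensemble-corrected FRET decreases monotonically with excitation", {
  pair <- cy3cy5_pair()
  gam <- gamma_factor(pair)
  e_at <- function(k_ex, seed) {
    m <- build_model(pair, k_ex, "nine_state")
    traces <- simulate_ensemble(m, 6, 5, 0.1, base_seed = seed)
    IA <- sum(vapply(traces, function(tr) sum(tr$acceptor), 0))
    ID <- sum(vapply(traces, function(tr) sum(tr$donor), 0))
    IA / (IA + gam * ID)
  }
  kexs <- c(1e4, 5e4, 1e5, 3e5, 1e6)
  es <- mapply(e_at, kexs, seed = 41:45)
  expect_true(all(diff(es) < 0))
  expect_lt(es[5], forster_efficiency(pair$R, pair$R0) - 0.03)
})

test_that("simulation halts with an explicit error in absorbing states", {
  pair <- cy3cy5_pair()
  m <- build_model(pair, 0, "nine_state")   # no exit from the ground state
  expect_error(simulate_trajectory(m, 1, seed = 1), "zero exit rate")
})
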