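test_that("generator matrices have zero row sums and the documented structure", {
  set.seed(10)
  for (i in 1:10) {
    pair <- rand_pair()
    k_ex <- 10^runif(1, 3, 6.5)
    for (kind in c("donor_only_3st", "four_state", "nine_state")) {
      m <- build_model(pair, k_ex, kind)
      expect_lt(max(abs(rowSums(m$Q))), 1e-12 * max(abs(m$Q)))
      expect_true(all(m$Q[upper.tri(m$Q) | lower.tri(m$Q)] >= 0))
    }
  }
  # spot-check the nine-state wiring against the printed generator
  pair <- cy3cy5_pair()
  m <- build_model(pair, 1e5, "nine_state")
  fD <- pair$donor; fA <- pair$acceptor
  expect_equal(m$Q["S0D.S0A", "S1D.S0A"], 1e5)
  expect_equal(m$Q["S1D.S0A", "S0D.S0A"], fD$k_em + fD$k_nr)
  expect_equal(m$Q["S1D.S0A", "S0D.S1A"], energy_transfer_rate(pair))
  expect_equal(m$Q["S1D.S0A", "TD.S0A"], fD$k_ISC)
  expect_equal(m$Q["TD.S0A", "S0D.S0A"], fD$k_TR)
  expect_equal(m$Q["S0D.S1A", "S1D.S1A"], 1e5)
  expect_equal(m$Q["S0D.S1A", "S0D.TA"], fA$k_ISC)
  expect_equal(m$Q["S1D.TA", "S1D.S0A"], fA$k_TR)
  expect_equal(m$Q["TD.TA", "TD.S0A"], fA$k_TR)
  # no transfer out of states with an excited or shelved acceptor
  expect_equal(m$Q["S1D.S1A", "S0D.S1A"], fD$k_em + fD$k_nr)
  expect_equal(m$Q["S1D.TA", "S0D.TA"], fD$k_em + fD$k_nr)
})

test_that("four-state generator is the nine-state generator restricted when ISC vanishes", {
  set.seed(11)
  for (i in 1:5) {
    p <- rand_pair()
    noisc <- function(fl) fluorophore(fl$name, fl$epsilon, fl$k_em, fl$k_nr,
                                      0, fl$k_TR, fl$eta)
    p0 <- fret_pair(noisc(p$donor), noisc(p$acceptor), R0 = p$R0, R = p$R)
    k_ex <- 10^runif(1, 3, 6)
    Q9 <- build_model(p0, k_ex, "nine_state")$Q
    Q4 <- build_model(p0, k_ex, "four_state")$Q
    keep <- c("S0D.S0A", "S1D.S0A", "S0D.S1A", "S1D.S1A")
    expect_equal(unname(Q9[keep, keep]), unname(Q4), tolerance = 1e-12)
    # triplet-containing states are unreachable
    ss <- solve_steady_state(build_model(p0, k_ex, "nine_state"))
    trip <- grepl("TD|TA", names(ss$probs))
    expect_equal(unname(ss$probs[trip]), rep(0, sum(trip)), tolerance = 1e-12)
  }
})

test_that("steady-state solver matches its defining property and handles k_ex = 0", {
  set.seed(12)
  for (i in 1:10) {
    m <- build_model(rand_pair(), 10^runif(1, 2, 6.5), "nine_state")
    ss <- solve_steady_state(m)
    expect_true(all(ss$probs >= 0))
    expect_equal(sum(ss$probs), 1, tolerance = 1e-10)
    expect_lt(max(abs(ss$probs %*% m$Q)), 1e-9 * max(abs(m$Q)))
    # detected rates recompute from occupancies
    expect_equal(ss$rho_D,
                 m$pair$donor$eta * m$pair$donor$k_em *
                   sum(ss$probs[grep("S1D", names(ss$probs))]))
  }
  m0 <- build_model(rand_pair(), 0, "nine_state")
  expect_equal(unname(solve_steady_state(m0)$probs),
               c(1, rep(0, 8)))
})

test_that("donor-only closed form agrees with an independent null-space solve", {
  don <- fluorophore("d", 1e5, k_em = 2e8, k_nr = 1e8, k_ISC = 1e6,
                     k_TR = 1 / 31e-6, eta = 0.2)
  cf <- closed_form_donor_only(don, 1e5)
  oracle <- solve_null_3st(1e5, 2e8, 1e8, 1e6, 1 / 31e-6)
  expect_equal(unname(cf), unname(oracle), tolerance = 1e-10)
  expect_equal(cf[["S1"]], 3.287e-4, tolerance = 1e-3)
  expect_equal(cf[["T"]], 1.019e-2, tolerance = 1e-3)
  expect_equal(cf[["S0"]], 0.98948, tolerance = 1e-4)
  expect_equal(sum(cf), 1)

  # no-triplet and fast-relaxation limits
  d0 <- fluorophore("d", 1e5, 2e8, 1e8, 0, 1e4, 0.2)
  cf0 <- closed_form_donor_only(d0, 1e5)
  expect_equal(cf0[["T"]], 0)
  expect_equal(cf0[["S1"]], 1 / (3e8 / 1e5 + 1))
  dfast <- fluorophore("d", 1e5, 2e8, 1e8, 1e6, 1e14, 0.2)
  expect_lt(closed_form_donor_only(dfast, 1e5)[["T"]], 1e-11)
  expect_error(closed_form_donor_only(don, 0), "positive")
})

test_that("donor-only solver equals the closed form across an excitation sweep", {
  don <- load_dye("cy3_like")
  pair <- fret_pair(don, load_dye("cy5_like"), R0 = 56, R = 60.23)
  for (k_ex in 10^seq(2, 7, by = 0.5)) {
    ss <- solve_steady_state(build_model(pair, k_ex, "donor_only_3st"))
    cf <- closed_form_donor_only(don, k_ex)
    expect_equal(unname(ss$probs), unname(cf), tolerance = 1e-10)
  }
})

test_that("steady-state efficiency reaches the Foerster value in the weak limit", {
  pair <- cy3cy5_pair()
  Eth <- forster_efficiency(pair$R, pair$R0)
  E_at <- function(k_ex) efficiency_from_steady_state(
    solve_steady_state(build_model(pair, k_ex, "nine_state")),
    gamma_factor(pair))
  # convergence from below as k_ex -> 0
  expect_lt(abs(E_at(1e2) - Eth), 1e-4)
  expect_lt(abs(E_at(1) - Eth), 1e-6)
  expect_lt(abs(E_at(1) - Eth), abs(E_at(1e2) - Eth))
  expect_equal(efficiency_from_steady_state(
    structure(list(rho_A = 0, rho_D = 5, model = NULL), class = "steady_state"), 1), 0)
  expect_equal(efficiency_from_steady_state(
    structure(list(rho_A = 5, rho_D = 5, model = NULL), class = "steady_state"), 1), 0.5)
  expect_error(efficiency_from_steady_state(
    structure(list(rho_A = 0, rho_D = 0, model = NULL), class = "steady_state"), 1),
    "undefined")
})

test_that("four-state zeta matches arithmetic and the steady-state oracle", {
  # weak-excitation limit: zeta ~ k_ex / (2 k_S1) -> 0
  expect_equal(zeta_four_state(1e3, 1e9, 1e9), 1e3 * 1e9 / (1e9 * (1e3 + 2e9)))
  expect_lt(zeta_four_state(1e3, 1e9, 1e9), 1e-6)
  expect_lt(zeta_four_state(1e-3, 1e9, 1e9), 1e-12)
  expect_equal(zeta_four_state(1e6, 2e8, 2.5e8),
               2e14 / (2.5e8 * (1e6 + 2.5e8 + 2e8)))
  set.seed(13)
  for (i in 1:10) {
    pair <- rand_pair()
    k_ex <- 10^runif(1, 3, 6.5)
    ss <- solve_steady_state(build_model(pair, k_ex, "four_state"))
    E4 <- efficiency_from_steady_state(ss, gamma_factor(pair, "four_state"))
    Eth <- forster_efficiency(pair$R, pair$R0)
    z <- zeta_four_state(k_ex, k_S1(pair$donor, "four_state"),
                         k_S1(pair$acceptor, "four_state"))
    expect_equal(1 / E4 - 1 / Eth, z, tolerance = 1e-9)
    # E_4st equals the displayed rational expression
    kET <- energy_transfer_rate(pair, "four_state")
    expect_equal(E4, 1 / (1 + k_S1(pair$donor, "four_state") / kET + z),
                 tolerance = 1e-9)
  }
})

test_that("nine-state zeta reduces to the four-state form and ignores distance", {
  set.seed(14)
  pair <- rand_pair()
  noisc <- function(fl) fluorophore(fl$name, fl$epsilon, fl$k_em, fl$k_nr, 0,
                                    fl$k_TR, fl$eta)
  d0 <- noisc(pair$donor); a0 <- noisc(pair$acceptor)
  for (k_ex in 10^seq(3, 6, by = 1)) {
    expect_equal(zeta_nine_state(d0, a0, k_ex),
                 zeta_four_state(k_ex, d0$k_em + d0$k_nr, a0$k_em + a0$k_nr),
                 tolerance = 1e-12)
  }
  # fast triplet relaxation limit
  fast <- function(fl) fluorophore(fl$name, fl$epsilon, fl$k_em, fl$k_nr,
                                   fl$k_ISC, 1e14, fl$eta)
  expect_equal(zeta_nine_state(fast(pair$donor), fast(pair$acceptor), 1e5),
               zeta_four_state(1e5, k_S1(pair$donor, "nine_state"),
                               k_S1(pair$acceptor, "nine_state")),
               tolerance = 1e-6)
  # independence of R: numeric zeta from two distances coincides.  The
  # comparison subtracts reciprocal efficiencies, so the achievable
  # agreement scales with their magnitude (double-precision cancellation).
  for (i in 1:5) {
    p1 <- rand_pair()
    p2 <- p1; p2$R <- p1$R * 1.7
    k_ex <- 10^runif(1, 4, 6)
    znum <- function(p) {
      ss <- solve_steady_state(build_model(p, k_ex, "nine_state"))
      1 / efficiency_from_steady_state(ss, gamma_factor(p)) -
        1 / forster_efficiency(p$R, p$R0)
    }
    scale <- 1 / forster_efficiency(p2$R, p2$R0)
    expect_lt(abs(znum(p1) - znum(p2)), 1e-9 * scale)
  }
})

test_that("triplets only lower the nine-state efficiency (no annihilation)", {
  set.seed(15)
  for (i in 1:15) {
    pair <- rand_pair()
    k_ex <- 10^runif(1, 3, 6.5)
    ss <- solve_steady_state(build_model(pair, k_ex, "nine_state"))
    E9 <- efficiency_from_steady_state(ss, gamma_factor(pair))
    expect_lte(E9, forster_efficiency(pair$R, pair$R0) + 1e-12)
  }
})

test_that("four-state gamma_theory matches arithmetic and the k_ET = 0 oracle", {
  d <- fluorophore("d", 1e5, k_em = 1e8, k_nr = 1e8, k_ISC = 0, k_TR = 1e4,
                   eta = 0.2)
  a <- fluorophore("a", 1e4, k_em = 1e8, k_nr = 1e8, k_ISC = 0, k_TR = 1e4,
                   eta = 0.2)
  expect_equal(gamma_theory_four_state(d, a, 1e6), 0.005 + 1)
  expect_equal(gamma_theory_four_state(d, a, 0), 1)
  set.seed(16)
  for (i in 1:8) {
    pair <- rand_pair()
    k_ex <- 10^runif(1, 3.5, 6)
    ss_f <- solve_steady_state(build_model(pair, k_ex, "four_state"))
    ss_n <- solve_steady_state(build_model(without_fret(pair), k_ex, "four_state"))
    oracle <- (ss_f$rho_A - ss_n$rho_A) / (ss_n$rho_D - ss_f$rho_D)
    got <- gamma_theory_four_state(pair$donor, pair$acceptor, k_ex)
    expect_equal(got, oracle, tolerance = 1e-8)
    expect_gte(got, gamma_factor(pair, "four_state"))
  }
})

test_that("zeta correction of counts matches arithmetic and the Eq.-style identity", {
  expect_equal(apply_zeta_correction(10, 10, 1, 0), 0.5)
  expect_equal(apply_zeta_correction(30, 70, 1.2, 0.1), 30 / (27 + 84))
  expect_error(apply_zeta_correction(0, 0, 1, 0), "both")
  expect_error(apply_zeta_correction(10, 0, 1, 2), "denominator|non-positive")
  set.seed(17)
  for (i in 1:8) {
    pair <- rand_pair()
    k_ex <- 10^runif(1, 3, 6)
    ss <- solve_steady_state(build_model(pair, k_ex, "nine_state"))
    z <- zeta_nine_state(pair$donor, pair$acceptor, k_ex)
    gam <- gamma_factor(pair)
    scale <- runif(1, 0.1, 10)          # counts proportional to rates
    E_true <- apply_zeta_correction(scale * ss$rho_A, scale * ss$rho_D, gam, z)
    expect_equal(E_true, forster_efficiency(pair$R, pair$R0), tolerance = 1e-8)
  }
})

test_that("extensions are rejected for models lacking the relevant states", {
  pair <- cy3cy5_pair()
  expect_error(build_model(pair, 1e5, "four_state", k_SSA = 1e7),
               "nine-state")
  m4 <- build_model(pair, 1e5, "four_state")
  expect_error(with_extensions(m4, k_STA = 1e7), "nine-state")
})
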