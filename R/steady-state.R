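# Continuous-time Markov models of the joint donor-acceptor
# photophysical state, their steady states, and the closed-form
# efficiency / zeta / gamma expressions they imply.

.STATES <- list(
  donor_only_3st = c("S0D", "S1D", "TD"),
  four_state     = c("S0D.S0A", "S1D.S0A", "S0D.S1A", "S1D.S1A"),
  nine_state     = c("S0D.S0A", "S1D.S0A", "TD.S0A",
                     "S0D.S1A", "S1D.S1A", "TD.S1A",
                     "S0D.TA",  "S1D.TA",  "TD.TA")
)

# Transition channels for each model kind.  Channels are kept separate
# from the generator matrix because a single matrix entry can merge a
# radiative and a non-radiative pathway (photon emission is resolved
# per channel at simulation time): photon 0 = none, 1 = donor-split
# (Bernoulli k_em/(k_em+k_nr)), 2 = acceptor-split.
.model_channels <- function(kind, k_ex, k_ET, fD, fA,
                            k_SSA = 0, k_STA = 0, risc = FALSE) {
  kfD <- fD$k_em + fD$k_nr
  kiD <- fD$k_ISC
  ktD <- fD$k_TR
  ch <- switch(kind,
    donor_only_3st = rbind(
      c(1, 2, k_ex, 0),
      c(2, 1, kfD, 1), c(2, 3, kiD, 0),
      c(3, 1, ktD, 0)),
    four_state = {
      kfA <- fA$k_em + fA$k_nr
      rbind(
        c(1, 2, k_ex, 0),
        c(2, 1, kfD, 1), c(2, 3, k_ET, 0),
        c(3, 1, kfA, 2), c(3, 4, k_ex, 0),
        c(4, 2, kfA, 2), c(4, 3, kfD, 1))
    },
    nine_state = {
      kfA <- fA$k_em + fA$k_nr
      kiA <- fA$k_ISC
      ktA <- fA$k_TR
      base <- rbind(
        c(1, 2, k_ex, 0),
        c(2, 1, kfD, 1), c(2, 3, kiD, 0), c(2, 4, k_ET, 0),
        c(3, 1, ktD, 0),
        c(4, 1, kfA, 2), c(4, 5, k_ex, 0), c(4, 7, kiA, 0),
        c(5, 2, kfA, 2), c(5, 4, kfD, 1), c(5, 6, kiD, 0), c(5, 8, kiA, 0),
        c(6, 3, kfA, 2), c(6, 4, ktD, 0), c(6, 9, kiA, 0),
        c(7, 1, ktA, 0), c(7, 8, k_ex, 0),
        c(8, 2, ktA, 0), c(8, 7, kfD, 1), c(8, 9, kiD, 0),
        c(9, 3, ktA, 0), c(9, 7, ktD, 0))
      if (k_SSA > 0) base <- rbind(base, c(5, 4, k_SSA, 0))
      if (k_STA > 0)
        base <- rbind(base, c(8, if (risc) 4 else 7, k_STA, 0))
      base
    })
  ch <- ch[ch[, 3] > 0, , drop = FALSE]
  colnames(ch) <- c("from", "to", "rate", "photon")
  ch
}

#' Build a joint photophysical rate model
#'
#' Assembles the generator matrix `Q` of the donor-only three-state,
#' pair four-state or pair nine-state continuous-time Markov model at a
#' given donor excitation rate.  Only the donor is photoexcited; direct
#' acceptor excitation is handled downstream as the delta correction.
#' Off-diagonal entries of `Q` hold the transition rates and each
#' diagonal entry is the negative row sum, so every row sums to zero.
#'
#' Optional excited-state annihilation extensions of the nine-state
#' model: singlet-singlet annihilation (`k_SSA`, channel
#' S1D.S1A -> S0D.S1A), singlet-triplet annihilation (`k_STA`, channel
#' S1D.TA -> S0D.TA) and, with `risc = TRUE`, STA with reverse
#' intersystem crossing, which redirects the same `k_STA` channel into
#' S0D.S1A.  The two STA targets are mutually exclusive by
#' construction.
#'
#' @param pair A [fret_pair()].
#' @param k_ex Donor excitation rate (s^-1).
#' @param kind One of `"nine_state"`, `"four_state"`,
#'   `"donor_only_3st"`.
#' @param k_SSA,k_STA Annihilation rates (s^-1), nine-state only.
#' @param risc Redirect the STA channel to S0D.S1A (nine-state only).
#' @return An object of class `"joint_model"` with elements `states`,
#'   `Q`, `channels`, `k_ex`, `pair`, `kind` and the extension
#'   settings.
#' @export
build_model <- function(pair, k_ex,
                        kind = c("nine_state", "four_state", "donor_only_3st"),
                        k_SSA = 0, k_STA = 0, risc = FALSE) {
  stopifnot(inherits(pair, "fret_pair"))
  kind <- match.arg(kind)
  if (!is.numeric(k_ex) || k_ex < 0 || !is.finite(k_ex))
    stop("'k_ex' must be finite and non-negative")
  if (kind != "nine_state" && (k_SSA > 0 || k_STA > 0 || risc))
    stop("SSA/STA/RISC extensions require the nine-state model")
  model_kind <- if (kind == "four_state") "four_state" else "nine_state"
  k_ET <- if (kind == "donor_only_3st") 0 else
    energy_transfer_rate(pair, model_kind)
  ch <- .model_channels(kind, k_ex, k_ET, pair$donor, pair$acceptor,
                        k_SSA = k_SSA, k_STA = k_STA, risc = risc)
  states <- .STATES[[kind]]
  n <- length(states)
  Q <- matrix(0, n, n, dimnames = list(states, states))
  for (i in seq_len(nrow(ch))) Q[ch[i, 1], ch[i, 2]] <- Q[ch[i, 1], ch[i, 2]] + ch[i, 3]
  diag(Q) <- diag(Q) - rowSums(Q)
  d_idx <- grep("S1D", states)
  a_idx <- grep("S1A", states)
  structure(list(states = states, Q = Q, channels = ch, k_ex = k_ex,
                 k_ET = k_ET, pair = pair, kind = kind,
                 k_SSA = k_SSA, k_STA = k_STA, risc = risc,
                 donor_S1_idx = d_idx, acceptor_S1_idx = a_idx),
            class = "joint_model")
}

#' @export
print.joint_model <- function(x, ...) {
  cat(sprintf("Joint photophysical model (%s), k_ex = %.4g s^-1\n",
              x$kind, x$k_ex))
  if (x$k_SSA > 0 || x$k_STA > 0)
    cat(sprintf("  extensions: k_SSA = %.3g, k_STA = %.3g, risc = %s\n",
                x$k_SSA, x$k_STA, x$risc))
  print(signif(x$Q, 4))
  invisible(x)
}

#' Add annihilation extensions to a nine-state model
#'
#' Convenience wrapper around [build_model()] that returns a copy of
#' `model` whose generator additionally carries the requested
#' singlet-singlet / singlet-triplet annihilation channels.
#'
#' @param model A nine-state `"joint_model"`.
#' @param k_SSA,k_STA,risc See [build_model()].
#' @return A new `"joint_model"`.
#' @export
with_extensions <- function(model, k_SSA = 0, k_STA = 0, risc = FALSE) {
  stopifnot(inherits(model, "joint_model"))
  if (model$kind != "nine_state")
    stop("SSA/STA/RISC extensions require the nine-state model")
  build_model(model$pair, model$k_ex, model$kind,
              k_SSA = k_SSA, k_STA = k_STA, risc = risc)
}

#' Steady state of a joint model
#'
#' Solves `p Q = 0`, `sum(p) = 1` for the stationary distribution via
#' the null space of `t(Q)` (SVD), and reports the mean detected photon
#' rates `rho_D = eta_D k_em^D P(donor in S1)` and
#' `rho_A = eta_A k_em^A P(acceptor in S1)`.  The degenerate case
#' `k_ex = 0` returns all probability mass on the ground state.
#'
#' @param model A `"joint_model"`.
#' @return An object of class `"steady_state"` with elements `probs`
#'   (named occupancies), `rho_D`, `rho_A` (s^-1) and `model`.
#' @export
solve_steady_state <- function(model) {
  stopifnot(inherits(model, "joint_model"))
  n <- length(model$states)
  if (model$k_ex == 0) {
    p <- c(1, rep(0, n - 1))
  } else {
    sv <- svd(t(model$Q))
    if (sv$d[n - 1] < 1e-12 * sv$d[1])
      stop("generator is singular beyond rank-1 deficiency")
    p <- sv$v[, n]
    p <- p / sum(p)
    if (any(p < -1e-9)) stop("negative steady-state probability")
    p <- pmax(p, 0)
    p <- p / sum(p)
    res <- max(abs(p %*% model$Q))
    if (res > 1e-9 * max(abs(model$Q)))
      stop(sprintf("steady-state residual too large: %.3g", res))
  }
  names(p) <- model$states
  rho_D <- model$pair$donor$eta * model$pair$donor$k_em *
    sum(p[model$donor_S1_idx])
  rho_A <- if (length(model$acceptor_S1_idx))
    model$pair$acceptor$eta * model$pair$acceptor$k_em *
      sum(p[model$acceptor_S1_idx]) else 0
  structure(list(probs = p, rho_D = rho_D, rho_A = rho_A, model = model),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("Steady-state occupancies:\n")
  print(signif(x$probs, 5))
  cat(sprintf("rho_D = %.5g s^-1, rho_A = %.5g s^-1\n", x$rho_D, x$rho_A))
  invisible(x)
}

#' Closed-form steady state of a donor-only molecule
#'
#' Ground, singlet-excited and triplet occupancies of a three-state
#' dye under continuous excitation:
#' `S1 = 1 / (k_S1/k_ex + 1 + k_ISC/k_TR)`, `S0 = (k_S1/k_ex) S1`,
#' `T = 1 - S0 - S1`, with `k_S1 = k_em + k_nr + k_ISC`.
#'
#' @param donor A [fluorophore()].
#' @param k_ex Excitation rate (s^-1), strictly positive (the `k_ex =
#'   0` limit is handled by [solve_steady_state()]).
#' @return Named numeric vector `c(S0, S1, T)` summing to 1.
#' @export
closed_form_donor_only <- function(donor, k_ex) {
  stopifnot(inherits(donor, "fluorophore"))
  if (!is.numeric(k_ex) || k_ex <= 0) stop("'k_ex' must be positive")
  if (donor$k_TR <= 0) stop("'k_TR' must be positive")
  kS1 <- donor$k_em + donor$k_nr + donor$k_ISC
  S1 <- 1 / (kS1 / k_ex + 1 + donor$k_ISC / donor$k_TR)
  S0 <- (kS1 / k_ex) * S1
  c(S0 = S0, S1 = S1, T = 1 - S0 - S1)
}

#' FRET efficiency from steady-state photon rates
#'
#' `E = rho_A / (rho_A + gamma rho_D)`.
#'
#' @param ss A `"steady_state"` result.
#' @param gamma Gamma correction factor (see [gamma_factor()]).
#' @return Efficiency in `[0, 1]`.
#' @export
efficiency_from_steady_state <- function(ss, gamma) {
  stopifnot(inherits(ss, "steady_state"), gamma > 0)
  den <- ss$rho_A + gamma * ss$rho_D
  if (den <= 0) stop("total detected photon rate is zero: efficiency undefined")
  ss$rho_A / den
}

#' Four-state zeta correction parameter
#'
#' Closed form of the saturation bias of the triplet-free pair model:
#' `zeta = k_ex k_S1^D / (k_S1^A (k_ex + k_S1^A + k_S1^D))`, where the
#' singlet depopulation rates exclude intersystem crossing.  Satisfies
#' `1/E_4st = 1/E_theory + zeta` exactly, and vanishes in the
#' weak-excitation limit.
#'
#' @param k_ex Donor excitation rate (s^-1).
#' @param k_S1_D,k_S1_A Donor and acceptor singlet depopulation rates
#'   (s^-1), four-state convention (`k_em + k_nr`).
#' @return zeta >= 0.
#' @export
zeta_four_state <- function(k_ex, k_S1_D, k_S1_A) {
  stopifnot(k_ex >= 0, k_S1_D > 0, k_S1_A > 0)
  k_ex * k_S1_D / (k_S1_A * (k_ex + k_S1_A + k_S1_D))
}

# Raw-rate nine-state closed form; kS1 rates include k_ISC.
.zeta9 <- function(kex, kS1D, kS1A, kiD, kiA, ktD, ktA) {
  num <- kex * kS1D * (
    (kS1A * kiA + (kS1D + ktA) * (kiA + ktA)) * (kS1A + ktD) * (ktA + ktD) +
      kex * (kS1A * ktA * (kiA + kiD + ktA) +
               ktD * (kiA + ktA) * (kiD + ktA + kS1A + ktD))
  )
  den <- kS1A * ktA * (
    ((kS1A + kS1D) * (kS1A + ktD) + kex * (kS1A + kiD + ktD)) *
      ((kS1D + ktA) * (ktA + ktD) + kex * (kiD + ktA + ktD))
  )
  num / den
}

#' Nine-state zeta correction parameter
#'
#' Closed form of the combined saturation and triplet-shelving bias of
#' the nine-state pair model.  It is independent of the inter-dye
#' distance and satisfies the identity
#' `E_theory = 1 / (1/E_9st - zeta)` exactly, where `E_9st` is the
#' steady-state efficiency of the nine-state model and `E_theory` the
#' Foerster efficiency.  With vanishing intersystem crossing it reduces
#' to [zeta_four_state()], and for infinitely fast triplet relaxation
#' it approaches the same limit.
#'
#' @param donor,acceptor [fluorophore()] objects.
#' @param k_ex Donor excitation rate (s^-1).
#' @return zeta >= 0.
#' @export
zeta_nine_state <- function(donor, acceptor, k_ex) {
  stopifnot(inherits(donor, "fluorophore"), inherits(acceptor, "fluorophore"),
            k_ex >= 0)
  .zeta9(k_ex,
         kS1D = donor$k_em + donor$k_nr + donor$k_ISC,
         kS1A = acceptor$k_em + acceptor$k_nr + acceptor$k_ISC,
         kiD = donor$k_ISC, kiA = acceptor$k_ISC,
         ktD = donor$k_TR, ktA = acceptor$k_TR)
}

#' Theoretical gamma of the four-state model
#'
#' The gamma factor an empirical FRET / no-FRET brightness comparison
#' would measure on the four-state model,
#' `gamma_theory = (eta_A k_ex / (eta_D k_em^D)) phi_A + gamma`: it
#' approaches the intrinsic `gamma` in the weak-excitation limit and
#' grows linearly in `k_ex`.  Quantum yields use the four-state
#' convention.
#'
#' @param donor,acceptor [fluorophore()] objects.
#' @param k_ex Donor excitation rate (s^-1).
#' @return gamma_theory >= gamma.
#' @export
gamma_theory_four_state <- function(donor, acceptor, k_ex) {
  stopifnot(inherits(donor, "fluorophore"), inherits(acceptor, "fluorophore"),
            k_ex >= 0)
  phi_A <- acceptor$k_em / (acceptor$k_em + acceptor$k_nr)
  phi_D <- donor$k_em / (donor$k_em + donor$k_nr)
  gam <- (acceptor$eta * phi_A) / (donor$eta * phi_D)
  (acceptor$eta * k_ex / (donor$eta * donor$k_em)) * phi_A + gam
}

#' Apply the zeta correction to photon counts
#'
#' `E_true = I_A / (I_A (1 - zeta) + gamma I_D)`.  With `zeta = 0` this
#' reduces to the standard gamma-corrected efficiency.  Inputs must
#' already be crosstalk / direct-excitation corrected.
#'
#' @param I_A,I_D Acceptor and donor photon counts (non-negative, not
#'   both zero).
#' @param gamma Gamma correction factor.
#' @param zeta Zeta correction parameter.
#' @return Corrected efficiency (vectorised over counts).
#' @export
apply_zeta_correction <- function(I_A, I_D, gamma, zeta) {
  stopifnot(all(I_A >= 0), all(I_D >= 0), gamma > 0, zeta >= 0)
  if (any(I_A + I_D == 0)) stop("I_A and I_D must not both be zero")
  den <- I_A * (1 - zeta) + gamma * I_D
  if (any(den <= 0)) stop("non-positive denominator: zeta too large for these counts")
  I_A / den
}
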