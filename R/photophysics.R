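# Elementary photophysical quantities: fluorophore/pair/illumination
# containers and the rate formulas connecting them.

#' Physical constants
#'
#' CODATA 2018 values used throughout the package: Planck constant
#' `h` (J s), speed of light `c` (m s^-1) and the Avogadro number
#' `N_A` (mol^-1).
#'
#' @format A named numeric vector with elements `h`, `c`, `N_A`.
#' @export
physical_constants <- c(
  h   = 6.62607015e-34,
  c   = 2.99792458e8,
  N_A = 6.02214076e23
)

#' Construct a fluorophore parameter set
#'
#' Bundles the rate constants and efficiencies describing one dye.  All
#' rates are in s^-1.  The singlet depopulation rate is model dependent:
#' `k_em + k_nr` when triplet shelving is treated as a separate channel
#' of the four-state pair model, and `k_em + k_nr + k_ISC` in the
#' three- and nine-state models (see [k_S1()]).
#'
#' @param name Text label.
#' @param epsilon Molar extinction coefficient at the excitation
#'   wavelength (M^-1 cm^-1).
#' @param k_em Radiative S1 -> S0 relaxation rate (s^-1).
#' @param k_nr Non-radiative S1 -> S0 relaxation rate (s^-1).
#' @param k_ISC Intersystem-crossing S1 -> T rate (s^-1).
#' @param k_TR Triplet relaxation rate (s^-1); the reciprocal of the
#'   triplet lifetime.
#' @param eta Detection efficiency of the dye's emission channel, in
#'   `[0, 1]`.
#' @return An object of class `"fluorophore"`.
#' @seealso [fluorophore_from_lifetime()] to construct from a
#'   fluorescence lifetime, quantum yield and ISC yield.
#' @export
fluorophore <- function(name, epsilon, k_em, k_nr, k_ISC, k_TR, eta) {
  stopifnot(is.character(name), length(name) == 1L)
  for (nm in c("epsilon", "k_em", "k_nr", "k_ISC", "k_TR", "eta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("'%s' must be a single finite non-negative number", nm))
  }
  if (eta > 1) stop("'eta' must lie in [0, 1]")
  if (k_em + k_nr <= 0) stop("singlet depopulation rate k_em + k_nr must be > 0")
  fl <- list(
    name = name, epsilon = epsilon,
    k_em = k_em, k_nr = k_nr, k_ISC = k_ISC, k_TR = k_TR,
    phi = k_em / (k_em + k_nr + k_ISC),
    eta = eta
  )
  class(fl) <- "fluorophore"
  fl
}

#' Construct a fluorophore from lifetime, quantum yield and ISC yield
#'
#' The rate constants follow from `k_S1 = 1/tau_fl`,
#' `k_em = phi * k_S1`, `k_ISC = Phi_ISC * k_S1` and
#' `k_nr = k_S1 - k_em - k_ISC` (which must be non-negative).
#'
#' @param name Text label.
#' @param tau_fl Fluorescence lifetime (s).
#' @param phi Fluorescence quantum yield.
#' @param Phi_ISC Intersystem-crossing yield.
#' @param tau_T Triplet lifetime (s), so `k_TR = 1/tau_T`.
#' @inheritParams fluorophore
#' @return An object of class `"fluorophore"`.
#' @export
fluorophore_from_lifetime <- function(name, tau_fl, phi, Phi_ISC, tau_T,
                                      epsilon, eta) {
  stopifnot(tau_fl > 0, tau_T > 0, phi >= 0, phi <= 1, Phi_ISC >= 0)
  k_S1 <- 1 / tau_fl
  k_em <- phi * k_S1
  k_ISC <- Phi_ISC * k_S1
  k_nr <- k_S1 - k_em - k_ISC
  if (k_nr < 0) stop("phi + Phi_ISC exceeds 1: negative non-radiative rate")
  fluorophore(name, epsilon = epsilon, k_em = k_em, k_nr = k_nr,
              k_ISC = k_ISC, k_TR = 1 / tau_T, eta = eta)
}

#' @export
print.fluorophore <- function(x, ...) {
  cat(sprintf("Fluorophore '%s'\n", x$name))
  cat(sprintf("  epsilon  %.4g M^-1 cm^-1\n", x$epsilon))
  cat(sprintf("  k_em     %.4g s^-1   k_nr  %.4g s^-1\n", x$k_em, x$k_nr))
  cat(sprintf("  k_ISC    %.4g s^-1   k_TR  %.4g s^-1 (tau_T %.3g us)\n",
              x$k_ISC, x$k_TR, 1e6 / x$k_TR))
  cat(sprintf("  phi      %.3f        eta   %.3f\n", x$phi, x$eta))
  invisible(x)
}

#' Singlet depopulation rate of a fluorophore
#'
#' Returns `k_em + k_nr` for the four-state pair model, where
#' intersystem crossing does not exist as a channel, and
#' `k_em + k_nr + k_ISC` for the three- and nine-state models, where
#' triplet shelving competes with emission.  Every function that
#' depends on this rate takes an explicit `model_kind` because mixing
#' the two conventions silently corrupts the zeta correction.
#'
#' @param fl A [fluorophore()].
#' @param model_kind `"nine_state"` (includes `k_ISC`; also used by the
#'   donor-only three-state model) or `"four_state"`.
#' @return Rate in s^-1.
#' @export
k_S1 <- function(fl, model_kind = c("nine_state", "four_state")) {
  model_kind <- match.arg(model_kind)
  fl$k_em + fl$k_nr + if (model_kind == "nine_state") fl$k_ISC else 0
}

#' Construct an illumination condition
#'
#' @param intensity Incident irradiance in W cm^-2 (note: W, not kW;
#'   the command-line interface accepts kW cm^-2 and converts).
#' @param wavelength Excitation wavelength in nm.
#' @return An object of class `"illumination"`.
#' @export
illumination <- function(intensity, wavelength = 532) {
  if (!is.numeric(intensity) || intensity < 0)
    stop("'intensity' must be non-negative (W cm^-2)")
  if (!is.numeric(wavelength) || wavelength <= 0)
    stop("'wavelength' must be positive (nm)")
  structure(list(intensity = intensity, wavelength = wavelength),
            class = "illumination")
}

#' Excitation rate from irradiance
#'
#' `k_ex = (I / h f) * sigma_abs` with absorption cross-section
#' `sigma_abs = 2303 * epsilon / N_A` (cm^2).  `I` is in W cm^-2 and
#' `f = c / lambda` is the light frequency, so `k_ex` is linear in both
#' the irradiance and the extinction coefficient.
#'
#' @param illum An [illumination()].
#' @param epsilon Molar extinction coefficient at the excitation
#'   wavelength (M^-1 cm^-1).
#' @return Excitation rate in s^-1.
#' @export
excitation_rate <- function(illum, epsilon) {
  if (!inherits(illum, "illumination")) stop("'illum' must be an illumination")
  if (!is.numeric(epsilon) || epsilon < 0) stop("'epsilon' must be non-negative")
  f <- physical_constants[["c"]] / (illum$wavelength * 1e-9)
  sigma_abs <- 2303 * epsilon / physical_constants[["N_A"]]
  illum$intensity / (physical_constants[["h"]] * f) * sigma_abs
}

#' Foerster transfer efficiency at a given distance
#'
#' `E = 1 / (1 + (R/R0)^6)`: strictly decreasing in the inter-dye
#' distance, with `E = 1/2` at `R = R0`.
#'
#' @param R Inter-dye distance (Angstrom).
#' @param R0 Foerster radius (Angstrom).
#' @return Efficiency in `[0, 1]`.
#' @export
forster_efficiency <- function(R, R0) {
  if (any(R <= 0) || any(R0 <= 0)) stop("'R' and 'R0' must be positive")
  1 / (1 + (R / R0)^6)
}

#' Foerster radius from spectral overlap
#'
#' `R0 = 0.0211 * (kappa2 * phi_D * J / n^4)^(1/6)` with the overlap
#' integral `J` in M^-1 cm^-1 nm^4, giving `R0` in nm; the result is
#' returned in Angstrom.  In most workflows `R0` is supplied directly
#' as a pair parameter and this helper is only needed when deriving it
#' from spectra.
#'
#' @param J Spectral overlap integral (M^-1 cm^-1 nm^4).
#' @param phi_D Donor fluorescence quantum yield.
#' @param kappa2 Orientation factor (2/3 for isotropic averaging).
#' @param n_medium Refractive index of the medium.
#' @return Foerster radius in Angstrom.
#' @export
forster_radius <- function(J, phi_D, kappa2 = 2 / 3, n_medium = 1.33) {
  vals <- c(J = J, phi_D = phi_D, kappa2 = kappa2, n_medium = n_medium)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all arguments must be positive")
  10 * 0.0211 * (kappa2 * phi_D * J / n_medium^4)^(1 / 6)
}

#' Construct a donor-acceptor FRET pair
#'
#' @param donor,acceptor [fluorophore()] objects.
#' @param R0 Foerster radius (Angstrom).
#' @param R Inter-dye distance (Angstrom); `Inf` describes a donor-only
#'   / no-transfer configuration.
#' @param kappa2 Optional orientation factor, in `[0, 4]`.
#' @param J Optional spectral overlap integral (M^-1 cm^-1 nm^4).
#' @param n_medium Optional refractive index.
#' @return An object of class `"fret_pair"`.
#' @export
fret_pair <- function(donor, acceptor, R0, R, kappa2 = NULL, J = NULL,
                      n_medium = NULL) {
  stopifnot(inherits(donor, "fluorophore"), inherits(acceptor, "fluorophore"))
  if (!is.numeric(R0) || R0 <= 0) stop("'R0' must be positive")
  if (!is.numeric(R) || R <= 0) stop("'R' must be positive")
  if (!is.null(kappa2) && (kappa2 < 0 || kappa2 > 4))
    stop("'kappa2' must lie in [0, 4]")
  structure(list(donor = donor, acceptor = acceptor, R0 = R0, R = R,
                 kappa2 = kappa2, J = J, n_medium = n_medium),
            class = "fret_pair")
}

#' @export
print.fret_pair <- function(x, ...) {
  cat(sprintf("FRET pair %s -> %s\n", x$donor$name, x$acceptor$name))
  cat(sprintf("  R = %.4g A, R0 = %.4g A, E_theory(9st) = %.4f\n",
              x$R, x$R0, forster_efficiency(x$R, x$R0)))
  invisible(x)
}

#' Remove energy transfer from a pair
#'
#' Returns a copy of the pair with infinite inter-dye distance, so
#' `k_ET = 0`.  Used to emulate the no-FRET (acceptor-dark) condition
#' of gamma-factor calibrations.
#'
#' @param pair A [fret_pair()].
#' @return A `"fret_pair"` with `R = Inf`.
#' @export
without_fret <- function(pair) {
  stopifnot(inherits(pair, "fret_pair"))
  pair$R <- Inf
  pair
}

#' Energy transfer rate of a pair
#'
#' `k_ET = k_S1^D * (R0/R)^6`, so that the Foerster efficiency equals
#' `k_ET / (k_ET + k_S1^D)` exactly.  The donor singlet depopulation
#' rate is the model-dependent [k_S1()].
#'
#' @param pair A [fret_pair()].
#' @param model_kind Passed to [k_S1()].
#' @return Rate in s^-1.
#' @export
energy_transfer_rate <- function(pair, model_kind = c("nine_state", "four_state")) {
  stopifnot(inherits(pair, "fret_pair"))
  model_kind <- match.arg(model_kind)
  k_S1(pair$donor, model_kind) * (pair$R0 / pair$R)^6
}

#' Gamma correction factor of a pair
#'
#' `gamma = eta_A phi_A / (eta_D phi_D)`: the intrinsic brightness
#' ratio correcting for quantum-yield and detection-efficiency
#' differences between the two channels.  The quantum yields follow the
#' same convention as [k_S1()]: in the four-state model intersystem
#' crossing does not exist as a channel, so there
#' `phi = k_em / (k_em + k_nr)`, while the nine-state (and donor-only)
#' yield is `k_em / (k_em + k_nr + k_ISC)`.
#'
#' @param pair A [fret_pair()].
#' @param model_kind Passed to [k_S1()]; selects the quantum-yield
#'   convention.
#' @return Dimensionless factor > 0.
#' @export
gamma_factor <- function(pair, model_kind = c("nine_state", "four_state")) {
  stopifnot(inherits(pair, "fret_pair"))
  model_kind <- match.arg(model_kind)
  phi_of <- function(fl) fl$k_em / k_S1(fl, model_kind)
  (pair$acceptor$eta * phi_of(pair$acceptor)) /
    (pair$donor$eta * phi_of(pair$donor))
}
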