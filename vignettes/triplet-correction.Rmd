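---
title: "Triplet-state photophysics and the zeta correction of smFRET efficiencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triplet-state photophysics and the zeta correction of smFRET efficiencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfret)
```

## The photophysical model

A FRET dye pair is modelled as a continuous-time Markov jump process on
the joint electronic states of donor and acceptor.  Each dye has a
singlet ground state `S0`, a singlet excited state `S1` and a triplet
state `T`, giving nine joint states for the pair.  Only the donor is
photoexcited, at rate

$$k_\mathrm{ex} = \frac{I}{h f}\,\sigma_\mathrm{abs}, \qquad
  \sigma_\mathrm{abs} = \frac{2303\,\varepsilon}{N_A},$$

with irradiance $I$ (W cm$^{-2}$), photon energy $hf$ and molar
extinction coefficient $\varepsilon$ (M$^{-1}$ cm$^{-1}$).  An excited
donor relaxes radiatively ($k_\mathrm{em}$), non-radiatively
($k_\mathrm{nr}$), by intersystem crossing into its triplet
($k_\mathrm{ISC}$), or by energy transfer to a ground-state acceptor at

$$k_\mathrm{ET} = k_{S_1}^D \left(\frac{R_0}{R}\right)^6,$$

so that the transfer probability of a single excitation is exactly the
Foerster efficiency $E = 1/(1 + (R/R_0)^6)$.  Triplets decay back to
the ground state at $k_\mathrm{TR} = 1/\tau_T$.  Energy transfer is
only possible into a ground-state acceptor; an acceptor in `S1` or `T`
cannot accept, which is the microscopic origin of the intensity
dependence of measured FRET.  Optional channels describe
singlet–singlet annihilation (`S1 S1 -> S0 S1`), singlet–triplet
annihilation (`S1 T -> S0 T`) and its reverse-intersystem-crossing
variant (`S1 T -> S0 S1`); these matter at short distances and high
power, and make the bias distance-dependent.

Two deliberate conventions run through the package:

* **Model-dependent singlet depopulation.**  In the four-state model
  (no triplets) $k_{S_1} = k_\mathrm{em} + k_\mathrm{nr}$; in the
  three- and nine-state models $k_{S_1}$ additionally includes
  $k_\mathrm{ISC}$.  Quantum yields follow the same convention, so
  `k_S1()` and `gamma_factor()` both take an explicit `model_kind`.
  Mixing the conventions silently corrupts the closed-form identities
  below, which is why there is no single "default" value.
* **Only photophysics.**  No photobleaching, no radical dark states, no
  photoisomerisation, no detector noise: shot noise of photon emission
  is the only stochastic element besides the state dynamics.  Finite
  simulation time stands in for photobleach-limited observation.

## Steady states and the zeta correction

The stationary distribution of the generator solves $pQ = 0$ subject
to $\sum_i p_i = 1$; `solve_steady_state()` computes it from the null
space of $Q^\top$ via SVD, which is exact up to floating point and
avoids long-time integration.  The degenerate case $k_\mathrm{ex} = 0$
is returned explicitly (all mass in the ground state) rather than
failing in the solver.  Mean detected photon rates follow as
$\rho_D = \eta_D k_\mathrm{em}^D P(\text{donor in } S_1)$ and
likewise for the acceptor, and the apparent efficiency is
$E = \rho_A / (\rho_A + \gamma\rho_D)$ with
$\gamma = \eta_A\varphi_A / (\eta_D\varphi_D)$.

Outside the weak-excitation limit this apparent efficiency falls below
the Foerster value.  The bias is captured by a single distance-naive
parameter $\zeta$:

$$E_\mathrm{theory} = \frac{1}{1/E_\mathrm{9st} - \zeta},$$

where $\zeta$ has a closed form in $k_\mathrm{ex}$ and the rate
constants of both dyes (`zeta_nine_state()`); with vanishing
intersystem crossing it reduces to the four-state saturation form
$\zeta = k_\mathrm{ex} k_{S_1}^D / (k_{S_1}^A (k_\mathrm{ex} +
k_{S_1}^A + k_{S_1}^D))$.  The transcription of the nine-state
expression is verified in the test suite by requiring
$\zeta = 1/E_\mathrm{9st} - 1/E_\mathrm{theory}$ against the numeric
steady state to $10^{-8}$ relative over randomized rate sets — this
identity, not any particular number, is the load-bearing check.  On
count data the correction is applied as
$E_\mathrm{true} = I_A / (I_A(1 - \zeta) + \gamma I_D)$, strictly
after crosstalk/direct-excitation correction; the trace objects track
their correction state and refuse out-of-order application.

A numerical caveat: evaluating $\zeta$ *numerically* as a difference
of reciprocal efficiencies suffers cancellation when $E$ is small, so
the distance-independence property is asserted with a bound scaled by
$1/E_\mathrm{theory}$; the closed form itself is immune.

## The stochastic simulator

`simulate_trajectory()` is a standard Gillespie simulation (exponential
holding times, categorical channel choice) with one refinement: the
generator merges radiative and non-radiative relaxation into a single
$k_\mathrm{em} + k_\mathrm{nr}$ matrix entry, so photon emission is
resolved *per transition* by a Bernoulli split with probability
$k_\mathrm{em}/(k_\mathrm{em} + k_\mathrm{nr})$, and detection by an
independent Bernoulli with probability $\eta$ per channel.  The rate
matrix therefore matches the analytic model exactly while photon
statistics remain correct.  The inner loop is C++; per-molecule seeds
are drawn deterministically from the ensemble seed so results are
bit-for-bit reproducible and independent of evaluation order.  Frames
are half-open, zero-based bins of detected photons; a partial final
frame is dropped.

## Bundled dye parameters — what is reported, what is default

The bundled Cy3-, Cy5-, LD555- and LD655-like parameter sets use the
reported deoxygenated-buffer triplet lifetimes (31, 51, 1.1 and
0.20 us) and a detection efficiency of 0.2 in both channels.  The
singlet rates are literature-typical defaults: fluorescence lifetimes
1.0 ns (donors) and 1.5 ns (acceptors), quantum yields 0.25 and 0.30.
The effective intersystem-crossing yield is 0.03 for all four dyes,
calibrated once so that the nine-state steady state of the Cy3–Cy5-like
pair reproduces the reported magnitude of the illumination-dependent
FRET decrease (from ~0.39 at 0.04 kW cm$^{-2}$ to roughly 0.25–0.29 at
0.64 kW cm$^{-2}$, depending on whether the intrinsic or the empirical
gamma is used).  Users with measured rate constants should supply their
own JSON/YAML configs; every bundled file's `notes` field repeats this
provenance.  The default pair geometry ($R_0 = 56$ A, $R = 60.23$ A)
gives an intermediate Foerster efficiency of 0.392.  The bundled
six-distance DNA table (`dna_distance_table()`) is synthetic: a rigid
B-helix axial rise of 3.4 A per base with a fixed 36.9 A radial linker
offset, anchored so the 14-nt separation reproduces that intermediate
efficiency.

## What the generator emulates — and what it does not

Simulated ensembles reproduce photon shot noise, triplet blinking,
saturation, and their consequences for gamma calibration and
population histograms.  They do **not** contain camera read noise,
background, optical aberrations, labelling heterogeneity, dye–surface
interactions, photobleaching or diffusion through a confocal volume
(burst-analysis fixtures approximate transits by gating photon streams
with transit windows).  Passing tests therefore demonstrate the
internal consistency of model, simulator and corrections — not that
real data are free of the additional broadening these effects cause;
experimental histograms are expected to be wider than the simulated,
shot-noise-limited ones.

## Correction protocol

The pipeline order is fixed and enforced: (1) crosstalk and direct
excitation, $I_A^\mathrm{exp} = I_A' - \alpha I_D' - \delta(I_D' +
I_A')$ with defaults $\delta = 0.05$ of total emission; (2) gamma; (3)
zeta.  The gamma used with zeta corrections defaults to the estimate
obtained at the *lowest* illumination intensity of a series (the
protocol choice; re-deriving gamma per power conflates the saturation
effect into gamma and double-counts part of the correction — it
remains available by simply passing a different `gamma`).  Empirical
gamma is computed from FRET versus no-FRET ensembles as
$|\langle I_A^F\rangle - \langle I_A^{NF}\rangle| /
 |\langle I_D^F\rangle - \langle I_D^{NF}\rangle|$; in simulations the
no-FRET condition is a separate run with $k_\mathrm{ET} = 0$ (there is
no photobleaching in the model to provide it), and a hook accepts
externally supplied no-FRET traces for real data.

## FCS fitting

The autocorrelation model multiplies antibunching, triplet and 3D
diffusion factors.  Parameters keep the field's units: $\tau_D$ and
$\tau_{TR}$ in microseconds, $\tau_{ab}$ in nanoseconds, lags in
seconds; the aspect ratio is fixed at $s = 0.2$ by default.  Fitting
is Levenberg–Marquardt least squares on the log-spaced grid, unweighted
by default, with $1/\sigma^2$ weighting when the curve carries
uncertainties — synthetic curves record their known per-point sigma,
and the weighted fit is the maximum-likelihood estimator for their
multiplicative Gaussian noise.  Starting values come from a documented
heuristic (plateau height for $N$, half-decay lag for $\tau_D$,
geometric mean of the sub-$\tau_D$ shoulder for $\tau_{TR}$),
multi-started over a spread of $\tau_{TR}$ guesses because the triplet
shoulder is the least identifiable feature; the lowest-RSS fit wins.
Non-convergence is flagged on the returned object, never thrown.

One honest limitation, quantified from the Fisher information of the
weighted model: a single 200-point curve at 2% multiplicative noise
carries an intrinsic relative uncertainty of about 7% in $\tau_{TR}$
at a triplet amplitude of 0.3 (worse at smaller amplitudes).  Single-
curve recoveries therefore scatter by that much around the truth no
matter the optimizer; averaging curves or measuring at several powers
and extrapolating to zero power (`extrapolate_zero_power()`) is the
way to better precision, mirroring experimental practice.

The multi-tau photon correlator (`correlate_photons()`) bins detected
timestamps at the requested minimum lag and coarsens by factors of two
with eight lags per octave; it is validated against a brute-force
direct estimator on its first octave and against the analytic
master-equation propagator $P_{S_1S_1}(\tau)/\pi_{S_1} - 1$ for a
blinking dye.  Lags below the initial bin width are out of reach by
construction.

## Burst analysis

Bursts are maximal runs of photons whose inter-photon gaps are at most
$\Delta t_\mathrm{max}$; the burst length is last-minus-first photon
time, so an isolated photon is a degenerate zero-length burst that the
burst threshold removes.  Background is subtracted as the expected
count $bg \cdot T$ per channel, floored at zero — a choice, since only
"corrected for background" is specified, but the only linear
$T$-dependent one.  The power-specific $\Delta t_\mathrm{max}$ is the
0.999 upper quantile of within-burst inter-photon times under an
initial 150 us selection.  Per-burst efficiency is
$n_A/(n_A + n_D)$ after reducing the acceptor count by
$\delta(n_A + n_D)$.  An optional, clearly heuristic
acceptor-photobleach filter (first-half/second-half acceptor count
asymmetry in standard scores) is off by default.

## Problem sizes used in the shipped checks

The package's own test battery runs ensembles of 5–20 molecules at 1–10
seconds per molecule and frame times of 100 ms — for example, the
six-distance mixtures use 10 molecules x 10 s per distance at
0.14 kW cm$^{-2}$, and the end-to-end correction check uses 20
molecules x 5 s at $k_\mathrm{ex} = 10^5$ s$^{-1}$ with gamma
calibrated at $10^4$ s$^{-1}$.  These sizes give shot-noise standard
errors well below the effects being tested while completing in minutes
on one core.

## Known limitations

* Rate constants beyond the triplet lifetimes are defaults, not
  measurements; conclusions about a specific dye require its measured
  rates.
* The zeta correction is exact only within the nine-state model: SSA,
  STA and RISC make the true bias distance-dependent, and real dyes
  add radical states and photobleaching that the model excludes.
* The evanescent-field depth profile of TIRF illumination is not
  modelled; excitation rates assume the nominal irradiance at the
  fluorophore.
* Diffusion is not simulated; burst fixtures emulate transits by
  time-gating.
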