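---
title: "Markov gating models of hERG1 isoforms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov gating models of hERG1 isoforms: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the gating model and its assumptions, the protocol battery, the fitting
machinery, the cell/tissue layer, and the numerical and design choices a
maintainer would want spelled out. Everything quantitative stated here is
computed by the test suite or by `scripts/acceptance.R`; nothing is
asserted that the code does not itself reproduce.

## 1. The gating model

IKr is carried by tetramers of the Kv11.1 (hERG1) channel. Gating is
modeled as a continuous-time Markov chain over five states — three closed
(C3, C2, C1), one open (O), one inactivated (I) — with occupancies
$\vec p(t)$ obeying the master equation $d\vec p/dt = Q(V)\,\vec p$. Two
topologies are shipped:

* **M-model 1** — the linear chain C3 ⇌ C2 ⇌ C1 ⇌ O ⇌ I. The channel
  must open before inactivating. Eight directed transitions.
* **M-model 2** — adds a direct C1 ⇌ I edge, closing the {C1, O, I}
  cycle. Ten directed transitions, one of which (I→C1) is not free: it is
  derived from microscopic reversibility (below).

Every rate has the form $k_i(V) = a_i\,\alpha_i\,e^{b_i \beta_i V}$ with
$\alpha_i$ in ms⁻¹ and $\beta_i$ in mV⁻¹. The dimensionless corrections
$a_i, b_i$ default to 1 and are the free parameters of the fitting module.
The prefactor and voltage coefficient can equivalently be derived from a
thermodynamic parameterization, $\alpha_i = (k_B T/h)\,
e^{\Delta S_i/R - \Delta H_i/RT}$ and $\beta_i = z_i F/RT$; the type
supports this form but no enthalpy/entropy data ship with the package.
Transitions C2 ⇌ C1 (labels `ain`, `bin`) are voltage-independent:
$\beta = 0$ is enforced at construction. Physical constants: $R = 8.315$
J mol⁻¹ K⁻¹, $k_B = 1.381\times10^{-23}$ J K⁻¹, $h = 6.626\times10^{-34}$
J s, and $F = 96485$ C mol⁻¹ (the CODATA value).

**Generator convention.** $Q[j,i]$ is the $i\to j$ rate for $j \ne i$;
diagonals make each column sum to zero, so probability is conserved by
construction (`dp/dt = Q p`). The alternative row convention is equally
common in the literature; the convention here is asserted by tests
(column sums `< 1e-12`).

**Microscopic reversibility.** For every cycle the product of rates
traversed one way must equal the product the other way *at every voltage*.
With exponential-form rates this forces two simultaneous constraints: the
$\alpha$ products must balance and the signed $\beta$ sums must balance.
`constrain_reversibility()` therefore closes the loop on both, deriving
the I→C1 rate's prefactor as a product/quotient of the other five and its
voltage coefficient as their signed sum. Closing on the prefactors alone
would leave the loop unbalanced except at V = 0. The printed C1→I values
are taken as data; the unlisted reverse edge is the derived one. Loop
closure is verified to 1e-10 relative at voltages spanning −120 to +60 mV.

**Current.** $I_{Kr} = g_{Kr}\, p_O\, (V - E_K)$ with
$g_{Kr} = g_{Kr0}\,(aT+b)\,\sqrt{[K^+]_o/5.4\,\mathrm{mM}}$,
$g_{Kr0} = 0.024$ pA/pF/mV, $a = 1/35$ K⁻¹, $b = -55/7$. At $T = 310$ K
the temperature factor is exactly 1. $E_K$ is not an independent datum: it
is computed by Nernst from the pipette (110 mM K-aspartate + 10 mM KCl ⇒
$K_i = 120$ mM) and bath ($K_o = 5.4$ mM) solutions at the working
temperature, giving −79.15 mV at 296.15 K; both concentrations and $E_K$
itself are overridable. "Room temperature" is taken as 296.15 K (23 °C),
configurable.

## 2. Propagation

Voltage-clamp protocols are sequences of constant-voltage segments, so the
master equation is time-homogeneous within a segment and
$\vec p(t) = e^{Qt}\vec p_0$ is exact. `propagate_segment()` computes one
matrix exponential per segment (`Matrix::expm` of $Q\,\Delta t$ for the
sampling interval) and advances by repeated multiplication; sampling
density therefore affects only measurement extraction, never solution
accuracy. Each sweep is initialized at the steady state of the holding
potential (−80 mV), computed from the null space of $Q$ — protocols in
practice begin from a long holding period, and the steady state is its
limit.

Two independent cross-checks guard this path: a closed-form two-state
relaxation (agreement to 1e-10) and a brute-force explicit-Euler
integration at $dt = 10^{-4}$ ms, implemented separately in C++. On
segments with moderate rates the two agree to better than 1e-6 per state.
The agreement floor is set by the *oracle*, not the matrix exponential:
forward Euler is first-order, and on the −120 mV deactivation segments —
where the C2→C3 rate reaches 192 ms⁻¹ and the recovery mode (~0.7 ms⁻¹)
moves most of the probability mass — its discretization error at
$dt = 10^{-4}$ ms is ≈ 1.3e-5 per state. The tests verify this
attribution directly: the expm-vs-Euler deviation halves exactly when the
Euler step is halved.

Rates are evaluated in log space when exponents are extreme, and a
non-finite rate (overflow at unphysical voltage/parameter combinations) is
an error, not an `Inf` that silently propagates.

## 3. The protocol battery and derived measurements

Four protocols ship, mirroring standard hERG characterization; where the
underlying experimental descriptions leave a quantity unstated, the
default chosen here is noted as such and is configurable:

* **Steady-state activation (SSA):** 1-s steps from −100 to +40 mV
  (10-mV increment — a design default; only the range is prescribed),
  then a 1-s tail at −100 mV. Normalized peak tail magnitudes vs. step
  voltage are fitted with a Boltzmann.
* **Envelope of tails:** +40 mV activation for 5–500 ms (grid
  {5, 10, 20, 50, 100, 200, 300, 400, 500} ms — design default spanning
  the stated range), tail at −100 mV for 3 s.
* **Deactivation:** 1-s activation at +40 (duration a design default),
  5-ms repolarization to −120 mV (letting channels recover from
  inactivation), then a 5-s test segment at {−120, −100, −60, −40} mV.
  The tail is fitted with a double exponential starting at the tail peak.
* **Recovery from inactivation:** the experimental protocol behind the
  published recovery time constants is not described; the package uses a
  1-s +40 mV conditioning step and fits a single exponential to the
  rising ("hooked") phase of the test-segment current, onset to peak.
  Recovery values are therefore compared as orderings/ratios only, never
  as absolute numbers.

**Tail polarity.** Tails at −100/−120 mV lie below $E_K$ and are inward;
`peak_tail()` infers the extremum's sign from the driving force.

**Deactivation fitting.** Near −120/−100 mV the hERG1a tail's two genuine
deactivation eigenmodes lie close together while a small opposite-signed
recovery mode survives at the window start. An unconstrained
two-exponential fit can latch onto that contaminating mode, so
`fit_deactivation()` constrains both amplitudes to the decay direction
(standard practice for hooked hERG tails). The components are reported
fast-first; on degenerate single-mode tails the two time constants may
coincide.

**Normalization.** How experimental deactivation traces were normalized
across voltages is unstated; per-trace peak normalization is used. All
normalized outputs are invariant under uniform current scaling (tested).

## 4. Global fitting of correction factors

The fitting module estimates the corrections $a_i$ (optimized in log
space, bounds [0.01, 100]) and $b_i$ (linear space, bounds [0.2, 5]) of
selected transitions against multi-protocol data. The cost is
$\sum_d w_d \sum_i (\mathrm{sim}_i - \mathrm{target}_i)^2$ over derived
observables — not raw traces, matching what the published figures show.
Weights default to equal (the original partial-cost weights are not in the
main text). Simulation failure at proposed parameters contributes a large
finite penalty rather than an exception, so the optimizer can retreat.

`global_fit()` is multi-start: the identity correction plus seeded
log-uniform (for $a_i$) / uniform (for $b_i$) perturbations within bounds;
the best local optimum wins, and reruns with the same seed are
bit-identical (the caller's RNG stream is saved and restored). The local
method is bounded PORT quasi-Newton (`nlminb`) by default. A
Levenberg-Marquardt option on the stacked residuals (`nls.lm`) exists but
cannot be the default: the minpack backend keeps global state and cannot
be nested, and the recovery-τ observable runs its own Levenberg-Marquardt
fit inside the objective.

Because the original raw recordings are not deposited, the module's
primary validation is parameter *recovery*: synthetic four-protocol
datasets generated from known corrections must return those corrections.
Noiseless data are recovered essentially exactly (relative error < 1e-4
in the unit tests). At 2% additive noise the recovery error is of order
10 percent: the late-activation correction direction is only weakly
identified by this protocol battery, and the displacement of the global
cost minimum under a given noise realization can land on either side of
10% (the end-to-end acceptance test asserts the 10% bound at fixed seeds
and documents the margin). `stability_check()` probes each fitted
parameter with ±ε relative
perturbations and flags parameters whose perturbation leaves the cost
unchanged — e.g. a $b_i$ correction on a voltage-independent transition,
which multiplies $\beta = 0$ and can never be identified.

### The synthetic-data generator

`generate_synthetic_dataset()` defines the study conditions for the
recovery tests: the four standard protocols, observables derived exactly
as in fitting, additive Gaussian noise with SD expressed as a fraction of
the per-trace peak (normalized curves have peak 1; each recovery τ is
perturbed relative to its own magnitude, since it derives from its own
trace), and a single seed controlling everything. Deactivation time
courses are sampled on a log-uniform grid (26 points per sweep over
0–4 s): log-uniform sampling is the standard design for multi-exponential
decays — it weights the fast and slow phases evenly — and it keeps the
four partial costs comparable in size under equal weights. (With a dense
uniform grid the deactivation dataset outnumbers the other three ~25:1
and, as a numerical experiment during design showed, 2% noise can then
displace the optimum of the activation-rate correction by ~19%.) What
passing recovery tests show is that the estimator is consistent under the
generator's assumptions — additive Gaussian noise on derived observables,
a correctly specified gating scheme. Real recordings violate both
(capacitive transients, leak, cell-to-cell variability, model
misspecification), so recovery here bounds estimator quality from above.

## 5. Cell, fiber and pseudo-ECG

The point of the cell/tissue layer is to propagate isoform kinetics into
action-potential and QT readouts. IKr is a mixture of two homotetramer
populations — pure-a and pure-b Markov chains with separate state vectors
— mixed linearly by `fraction_b` (maximum single-channel conductance is
taken as identical for the isoforms, so all differences are kinetic). The
cell-context maximal conductance is 0.0422 pA/pF/mV, scaled by
$\sqrt{K_o/5.4}$.

A full reimplementation of the O'Hara-Rudy ventricular model is out of
scope. The shipped membrane model is a **minimal surrogate ventricular
cell** designed so that every tissue-level property of interest is
testable at desk scale: a fast inward current ($g\,m^3h$, Hodgkin-Huxley
gates, τ ≈ 0.3/1.8 ms) for the upstroke and propagation; a slowly
inactivating plateau inward current (τ_w = 500 ms); a small persistent
plateau-range outward K⁺ current; an instantaneous inward-rectifier
background K⁺ current that holds the resting potential at $E_K$ (−86.9 mV
at 310 K with $K_i = 140$, $K_o = 5.4$ mM); and Markov IKr. Parameters
(documented in `?surrogate_cell_model`) were chosen once so that the cell
rests stably (drift < 0.01 mV/s without stimulus), fires a
ventricular-like AP (peak ≈ +48 mV, APD90 ≈ 214 ms for pure hERG1a), and
— crucially — has its late repolarization paced by IKr, so isoform
kinetics move APD. The shipped rate tables are room-temperature fits; the
temperature corrections that physiological simulations would need were
never published alongside the room-temperature tables, so no 37 °C
correction is applied by default and corrected parameter sets can be
supplied explicitly.

**Numerics.** Voltage: forward Euler. Time step: 0.005 ms, switching to
0.00005 ms while the stimulus is active or |dV/dt| exceeds a threshold
(default 1 mV/ms for single cells) — the published scheme gives the two
step sizes but not the switching criterion, so it is exposed as
configuration. Gates: exact exponential (Rush-Larsen) relaxation, exact
for constant τ. Markov states: RK4 at frozen voltage within each step
(operator splitting); at these steps the kernel matches the matrix
exponential to better than 1e-8 per state (tested), and probability drift
is audited during pacing (abort beyond 1e-6). All voltage-dependent rates
and gate targets are tabulated on a 0.005-mV grid with linear
interpolation (relative error ~1e-8, far below the splitting error).

**Fiber.** 165 cells, Δx = 100 μm, D = 0.00092 cm²/ms, monodomain cable
with sealed ends, stimulus 300 μA/cm² × 0.5 ms to cell 1 — conduction
velocity ≈ 39 cm/s with the surrogate. The coarse step is checked against
the diffusion stability bound (Δx²/2D = 0.054 ms) and the run aborts with
a suggested step when violated. The fiber defaults to the coarse step
throughout (`dvdt_switch = 0`): the surrogate is non-stiff at 0.005 ms,
and per-fiber fine-stepping through every cell's upstroke is the regime
the original multi-core C simulations were built for. Endo/M/epi region
labels are carried in the configuration but the surrogate is homogeneous;
they become meaningful only when a regionally varying ionic model is
plugged in. The default run is 20 paced beats (the published protocol
paces 2000 beats to full accommodation; 20 suffices for stable
desk-scale orderings and is a configuration field, not a limit of the
implementation).

**Pseudo-ECG.** $\Phi_e \propto (a^2\sigma_i/4\sigma_e)\int (-\nabla V_m)
\cdot \nabla(1/r)\,dx$ discretized with central differences (one-sided at
the ends), electrode 2.0 cm beyond the distal end on the fiber axis.
Tissue conductivities and the fiber radius are not published alongside
the kinetics; defaults σi/σe = 1, a = 0.0011 cm are used and Φe is reported in
arbitrary units — only shapes and orderings are claims. The QT-like
interval is measured from first departure from baseline beyond a
proportional tolerance (2% of peak deflection) to the last excursion
beyond it; it is invariant under amplitude scaling and used only for
orderings (QT of a pure-b fiber < pure-a).

## 6. Data transcription notes

The shipped fixtures transcribe the published rate tables exactly,
including the M-model 2 table's inactivation/recovery rows whose voltage
coefficients carry signs opposite to the M-model 1 table and to hERG
physiology (recovery accelerating with depolarization). Simulated as
printed, M-model 2 shows no inward rectification and its steady-state
activation does not reproduce the published curves, while its
deactivation orderings and loop closure hold; exchanging the two rows'
values restores rectification. The package does not silently "fix" the
table: fixtures stay verbatim, property tests for M-model 2 cover what
holds under the printed values, and the isoform-ordering and V½ claims
are validated on M-model 1 — the model carried forward into the cell and
tissue simulations. Users who want the physiological variant can swap the
two rows in a copy of the fixture.

Similarly, the methods text accompanying the published tables prints a
Faraday constant of 96785 C/mol; this is treated as a typo and the CODATA
96485 C/mol is used (the Nernst potential shifts by ~0.25 mV otherwise).

## 7. Problem sizes and determinism

Simulations in the examples and tests use: SSA/envelope/deactivation
sweeps sampled at 0.1–1 ms (matrix-exponential propagation makes sampling
a measurement choice); recovery sweeps at 0.1 ms; synthetic-recovery fits
with 2 free corrections, 10 starts; single cells paced 10 beats; fibers
165 cells × 20 beats. All stochastic steps (noise injection, start
generation) flow through explicit integer seeds, and both the generator
and the fitter restore the caller's RNG state.

## 8. Known limitations

* The recovery-from-inactivation protocol is a reconstruction; its τ
  values are comparable across isoforms but not to absolute published
  numbers.
* M-model 2 as printed is physiologically inconsistent (above); only
  M-model 1 carries the full validation surface.
* The surrogate ventricular model is a minimal instrument for IKr
  studies, not a general-purpose AP model: no calcium handling, no
  transmural heterogeneity, no restitution claims.
* Kinetics are room-temperature; cell simulations at 310 K use them
  unchanged unless corrected parameter sets are provided.
* Fitting validation is synthetic-recovery only; fitting real recordings
  will face leak/capacitance artifacts and model misspecification that
  the generator deliberately does not emulate.
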