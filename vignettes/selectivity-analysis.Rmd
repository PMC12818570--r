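---
title: "Quantifying proton/potassium selectivity of pH-gated cation channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying proton/potassium selectivity of pH-gated cation channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghksel)
```

## The measurement problem

Channels that conduct protons pose a special difficulty for selectivity
measurements. The free proton concentration is around a million times lower
than that of K+ at neutral pH, so even modest proton currents deplete or
accumulate protons near the channel faster than buffers can re-equilibrate
them. In whole-cell patch-clamp recordings of a pH-gated cation channel
(such as lysosomal TMEM175 overexpressed at the plasma membrane, where the
luminal face is extracellular), an external acid jump first drives the
reversal potential E_rev toward positive values — the signature of a
dominant H+ conductance — and then back toward 0 mV as the channel's own
proton influx collapses the transmembrane pH gradient. Neither the peak nor
the steady state alone gives the channel's intrinsic H+/K+ selectivity;
both must be interpreted through a quantitative model of the erosion
process. `ghksel` implements that interpretation end to end.

## The selectivity model

For a channel permeable to H+ and K+, the Goldman–Hodgkin–Katz (GHK)
voltage equation links the zero-current (reversal) potential to the
permeability ratio $r = P_{H^+}/P_{K^+}$. Solving for $r$ at a measured
$E_{rev}$:

$$
\frac{P_{H^+}}{P_{K^+}} =
\frac{[K^+]_{ex} - [K^+]_{in}\, e^{F E_{rev}/RT}}
     {10^{-pH_{in}}\, e^{F E_{rev}/RT} - 10^{-pH_{ex}}},
$$

with all concentrations in mol/L so that K+ and $10^{-pH}$ are
commensurate (`ratio_from_erev()`). A second, independent route uses only
the *shift* $\Delta E_{rev}$ caused by changing the external K+
concentration at a fixed external pH:

$$
\frac{P_{H^+}}{P_{K^+}} =
\frac{[K^+]_{ex,2} - [K^+]_{ex,1}\, e^{F \Delta E/RT}}
     {10^{-pH_{ex}}\left(e^{F \Delta E/RT} - 1\right)},
$$

(`ratio_from_delta_erev()`), valid only once the pH gradient — and hence
E_rev — has stabilized before the jump. The closed-form inversion
(`erev_from_ratio()`) and the GHK flux equation (`ghk_current()`) are kept
mutually consistent to below 1e-9 relative error; the zero-current voltage
of the summed fluxes reproduces the ratio equation exactly, which the test
suite verifies as a round-trip property.

Because recording solutions carry a few mM Cs+ whose permeability is close
to that of K+, analyses add the Cs+ concentration to the nominal K+ before
evaluating the equations (`effective_k()`); this correction is an explicit
step so uncorrected analyses remain possible. Ratios are aggregated across
cells as geometric means with a geometric SD factor
(`aggregate_geometric()`), reflecting their lognormal spread. Note that
evaluating the ratio equation at a *mean* reversal potential is not the
same as averaging per-cell ratios (Jensen gap); the package computes
per-record ratios and aggregates afterwards, and the worked benchmark
values agree with this convention to within a few percent.

### Default temperature

All operations take an explicit absolute temperature; the default is
295.15 K (22 °C), the midpoint of typical room-temperature recording
conditions. The benchmark evaluations in the tests use 295 K. Between
293 K and 298 K the benchmark ratios move by less than 8%, so the residual
uncertainty from an unrecorded room temperature is small compared to
biological spread; a dedicated test documents this.

## Ramp analysis

Sweeps follow a symmetric protocol (+120 mV hold, ramp to −120 mV, hold,
ramp back; 20 kHz sampling). Feature extraction per sweep:

* **E_rev**: the current is median-smoothed (width 11 samples — robust
  against Bessel-filtered noise without biasing the crossing), the
  zero-current crossing located by linear interpolation between bracketing
  samples. If several crossings survive smoothing, the one flanked by the
  longest monotone sign runs wins, with remaining ties broken by proximity
  to the previous sweep's value. Forward- and reverse-ramp values are
  averaged, because the ramp-evoked proton influx itself left-shifts the
  reverse ramp by a few mV; the difference is kept as a hysteresis quality
  metric. A sweep without a sign change yields a gap (never an
  interpolated value) flagged `NoReversal`.
* **Chord conductance** at ±120 mV: mean current over a ±1 mV window on
  the ramp divided by the driving force (window-mean voltage minus E_rev),
  the standard chord definition. Dividing by V instead is available as a
  config switch for comparison, since published figures do not always state
  the convention.
* **Current density**: current divided by cell capacitance.

A user-supplied liquid-junction-potential offset per solution is subtracted
from all voltages before analysis; computing LJPs is out of scope. Sweep
files are tidy CSV (sweep_id, t_s, v_mV, i_pA) with a YAML sidecar that
declares units explicitly — unit mismatches are errors, never silently
inferred.

## Erosion kinetics

Three fits summarize the erosion phenomenology across cells
(`fit_erev_decay()`, `fit_invtau_vs_g()`, `fit_peak_vs_tau()`):

1. the falling phase of E_rev after its peak is fitted with a single
   exponential with free offset (the return is toward, not exactly to,
   0 mV), giving the time constant τ;
2. 1/τ regressed on the chord conductance measured 90 s after
   acidification — the erosion model predicts proportionality;
3. peak E_rev against τ with the Hill equation, whose saturation `e_max`
   estimates the undisturbed GHK reversal potential. The Hill coefficient
   is fitted freely and reported, since no published value constrains it.
   Points with τ > 40 s are flagged: they are the quasi-undisturbed
   recordings that selectivity pipelines should feed into the ratio
   equation.

All nonlinear fits use deterministic multi-start Levenberg–Marquardt
(`minpack.lm::nls.lm` under the hood) with starts derived from data
quantiles (plus, for the exponential, the empirical 1/e crossing time) —
no randomness, no seed dependence. The optimizer is called through a thin
wrapper that keeps the best converged start by residual sum of squares.

## The whole-cell simulator

`cell_model()` + `simulate_voltage_clamp()` / `simulate_current_clamp()`
implement the biophysical model implied by the erosion phenomenology: a
single effective sub-membrane cytosolic compartment (volume and buffer
capacity as free parameters) whose local pH is moved by the channel's GHK
proton flux, with the pipette as a first-order reservoir and an optional
finite external layer. State variables are the local internal pH, two gate
activations and an internal weak-acid pool:

$$
\frac{d\,pH_{in}}{dt} = \frac{I_{H}}{F\, v\, \beta}
 + k_{pip}\,(pH_{pip} - pH_{in}) - \frac{J_{HA}\, f_{dep}}{\beta},
$$

where $\beta$ (mol/L per pH unit) is the buffer capacity, an outward proton
current raises the internal pH, and $J_{HA} = P_{wa}([HA]_{ex} - [HA]_{in})$
is the neutral-form weak-acid flux with Henderson–Hasselbalch partitioning
(acetate pK_A 4.76): only the fraction $f_{dep}$ that deprotonates at the
internal pH releases protons. Polyprotic buffer chemistry is deliberately
reduced to a constant β — the erosion dynamics depend on buffering only
through it — plus the weak-acid permeation term, which reproduces the
counterintuitive observation that a *stronger* but membrane-permeant
buffer lowers the E_rev peak and accelerates the backshift.

Integration uses the stiff-capable `lsoda` (deSolve) on the slow state,
sampled densely only inside ramps; the 20 kHz current waveform is then
evaluated from interpolated state, which keeps a full ramp experiment in
seconds of compute. All randomness is confined to additive Gaussian
recording noise under a single integer seed; the dynamics are
deterministic, and identical seeds give byte-identical fixtures
(`make_fixtures()`).

### Gating: two observables, two parameterizations

Two distinct experimental observations constrain pH dependence in opposite
directions, and the package deliberately models them separately:

* Under **symmetric pH** (SSME K+-jump titrations), flux *declines* with
  acidification, with two titration midpoints (≈4.5 and ≈7.0) for the wild
  type and a single conserved midpoint (≈4.2) for the H57Y mutant.
  `gate_open_fraction()` implements exactly this declining single/double
  titration and drives the synthetic SSME titration series.
* Under an **asymmetric acid jump** (whole-cell), total conductance
  *rises*: the K+ branch is enhanced essentially instantly while the H+
  branch activates after a delay, so the conductance increase precedes the
  E_rev shift (temporal uncoupling). The whole-cell gates therefore relax
  toward acid-activated targets: the K branch from a baseline `k_base`
  with midpoint `gate_pka2`, the H branch from a small baseline `h_base`
  with midpoint `h_gate_pka` (default 5.5, below the sensor's single-site
  pK_A, reflecting that proton flux requires essentially complete
  protonation of the luminal sensor cluster) and first-order delay
  `h_gate_delay_tau` (default 10 s). No published rate constants exist for
  these gates; the delays are fixture parameters, not claims, and
  `gate_mode = "fixed"` pins all gates open for clean parameter-recovery
  studies.

Reconciling the two observables in a single microscopic gating scheme is an
open scientific question; the package's split parameterization states the
phenomenology without pretending to resolve it.

### The linearized time constant

With weak acid and pipette exchange off and the membrane held at 0 mV,
linearizing the proton flux around the fully eroded state gives a
closed-form backshift time constant

$$
\tau = \frac{F^2 v \beta}{R T \ln 10\; g_{H}}
     = \frac{v\,\beta}{P_{H}\, a_{H}\, 10^{-pH_{ex}} \ln 10},
$$

implemented as `analytic_tau()` and used as an independent oracle: on
simulated small-gradient jumps the fitted τ agrees within a few percent
once the excursion has decayed into the linear regime. Far from that limit
(a 2.7-unit gradient) the decay is visibly non-exponential — it has a lag
while the internal proton concentration is still negligible against the
ratio-weighted K+ term — which is why cohort-level linearity checks
(1/τ vs G) are run at small gradients where the exponential model is
exact, and why fitting the full large-gradient trajectory yields an
*effective* τ that is still strictly decreasing in conductance.

### What the simulator does and does not emulate

It reproduces: GHK current–voltage shapes, the transient E_rev excursion
and conductance-dependent backshift, buffer-capacity and weak-acid
ordering of peaks, forward/reverse ramp hysteresis of the correct sign,
conditioning-voltage dependence of the steady E_rev (monotone toward the
H+ Nernst potential in acid, shallower at pH 6.1, absent at 7.4),
current-clamp depolarization matching the voltage-clamp E_rev peak, and
additive recording noise. It does not emulate: spatial proton
reaction–diffusion (single compartment only), endogenous background
conductances, series-resistance and capacitive-transient artifacts, or
stochastic single-channel gating. Passing pipeline tests on simulator
output therefore validates the analysis chain and the model's internal
consistency, not the microscopic correctness of the gating scheme.

Geometry defaults (capacitance 20 pF, compartment volume 1 pL) are
arbitrary calibration constants; buffer capacities are quoted in mM per pH
unit. Conductance equivalents (`p_k_max`, `p_h_max`, in nS under stated
reference conditions) are converted internally to lumped GHK
permeabilities, and `h_conductance_for_ratio()` programs an exact
open-channel P_H/P_K.

## SSME analysis

Solid-supported membrane electrophysiology traces are quantified after
in-well background subtraction (the same condition recorded under the
channel blocker 4-AP, interpolated onto the signal time base). K+-jump
series use charge integrals (trapezoidal), pH-jump series peak currents,
and the symmetric-pH titration series a windowed positive peak read after
the oppositely-signed background transient has decayed (window start
0.2 s by default). Dose-interval slopes (`dose_slope()`: 2–8 and 32–80 mM
for K+, ΔpH 0.2–0.8 for H+) provide relative permeabilities; titration
curves are normalized per sensor to the pH 7.0 response before averaging.

`fit_titration()` fits one or two single-site terms with independent
non-negative amplitudes and Hill coefficient fixed at 1. The exact
functional form of published double-titration fits is not reprinted
anywhere accessible, so this form is declared and validated by
self-consistency: noiseless generative recovery is exact to 1e-3, and a
two-site fit applied to single-site data is flagged `unidentifiable`
whenever the midpoints collapse within 0.3 pH units, one site carries
under 10% of the amplitude, or the second site fails to improve the
residual sum of squares at least two-fold over the one-site fit. Under 5%
multiplicative noise with 5-sensor averaging (the study-scale replication),
100-replicate Monte-Carlo recovery stays within ±0.3 / ±0.1 pH units for
the low/high site. The default fit uses all 12 points of the 3.0–8.5
grid; restriction to pH 3–6.5 is available and recovers the low site
identically.

## Salt-bridge contact analysis

Distance series (per-frame minimum over all donor–acceptor atom pairs,
e.g. both imidazole nitrogens against all carboxylate oxygens) are
analyzed after discarding a 50 ns burn-in. Contact fractions use a strict
`<` threshold at the conventional 3.2 Å (conservative) and 4.0 Å cutoffs;
histograms are density-normalized to unit area (bin width 0.1 Å over
1.5–12 Å by default) and replicas are pooled order-invariantly.
`contact_heatmap()` arranges fractions by channel-state group × residue
pair. Trajectory parsing is out of scope: input is a distance table (or
labeled-atom coordinates), with minimum-image unwrapping the exporter's
responsibility. The synthetic generator is a two-state telegraph process
(bound 2.9 ± 0.2 Å, unbound 7 ± 1.5 Å, truncated at 1.5 Å) whose
stationary occupancy and Gaussian tail probabilities provide closed-form
oracles for the counting code.

## Numerical choices and problem sizes

* GHK current uses the analytic limit P z F (c_in − c_out) for
  |zFV/RT| < 1e-8, avoiding 0/0 at the origin.
* Ratio equations treat a numerator within 1e-12 of zero (relative to the
  K+ scale) as exactly zero, so measurements at the K+ Nernst potential
  return a ratio of 0 rather than a sign-noise error; true singularities
  (E_rev at the H+ Nernst potential, ΔE_rev = 0) raise typed errors
  because geometric aggregation requires positive ratios.
* `lsoda` runs at rtol 1e-8 / atol 1e-10; a state leaving the physical pH
  range aborts with the offending parameters named.
* Current clamp solves the zero-current voltage by root bracketing between
  the K+ and H+ Nernst potentials widened by 20 mV.
* Package tests and examples simulate at 2 kHz instead of the full 20 kHz
  and use cohorts of 4–10 synthetic cells with 40–76 sweeps each; these
  sizes were chosen so the complete validation suite runs in well under a
  minute of simulation time while leaving every extracted feature
  rate-independent (the 20 kHz default is exercised explicitly in the
  segment-splitting tests).

## Known limitations

* Whether erosion occurs mainly cytosolically or in an external unstirred
  layer is experimentally unresolved; the cytosolic-compartment mechanism
  is the simplest that reproduces all observed dependencies, and a finite
  external layer is available but not validated against data.
* The split gate parameterization (declining symmetric-pH titration vs
  acid-activated whole-cell gates) is phenomenological.
* NMDG+ is treated as fully impermeant, divalents as impermeant, and no
  surface-potential or activity-coefficient corrections are applied.
* Confidence intervals are not computed for the kinetic fits (point
  estimates with R², matching how such fits are usually reported);
  bootstrap machinery is out of scope.
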