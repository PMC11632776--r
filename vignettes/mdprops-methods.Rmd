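---
title: "Methods: how mdprops turns MD output into material properties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how mdprops turns MD output into material properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdprops)
```

`mdprops` post-processes molecular-dynamics outputs of amorphous polymer
systems. This vignette is the package's own account of the procedures it
implements: the models, the conventions chosen where the field leaves them
open, the numerical safeguards, and what the synthetic-data tests do and do
not demonstrate about real trajectories.

## Data model and units

All tabular data travel as `ts_table` (a data frame whose first column is a
strictly increasing independent variable, with per-column units), coordinate
data as `config_frame` (atom identities, positions, and an orthorhombic
periodic box), and every scalar output as a `property_result` carrying its
unit, an uncertainty when one is defined, and a provenance list recording
every window and threshold that influenced the value. Canonical internal
units are nm, ns, K, g/cm³, GPa and cm²/s; pressures arrive in bar and are
converted on read (1 bar = 10⁻⁴ GPa). Only orthorhombic boxes are supported:
the minimum-image convention then separates per dimension, which keeps the
geometry code simple and independently testable. Triclinic input is refused
with an explicit error rather than silently mis-measured.

## Glass transition by broken-stick regression

The specific volume V(T) = 1/ρ(T) of a glass-forming polymer is nearly
linear in T well below and well above T_g, with a steeper rubbery slope
above. `broken_stick_tg()` fits ordinary least-squares lines independently
to the points inside a low window (default 150–275 K) and a high window
(475–600 K), both endpoints inclusive, and reports the intersection
abscissa. Two free lines are used, not a continuity-constrained hinge: the
procedure is defined by points "clearly above and below" the transition, and
constraining continuity would couple the two slope estimates. Degenerate
cases error rather than mislead: fewer than two points in a window, or a
slope difference below 10⁻¹² cm³/(g·K) ("parallel fits"), which would
otherwise produce an arbitrarily large T_g.

On noiseless hinge data the estimate is exact to machine precision for any
windows that do not straddle the hinge. With Gaussian noise of sd
5·10⁻⁴ cm³/g on a 25 K grid (six points per window), linear error
propagation gives sd(T_g) ≈ 5.8 K; the recovery tests therefore check the
*mean* absolute error over twenty seeded replicates against 10 K rather
than demanding every single draw fall inside — a per-draw bound at 1.7σ
would be violated by one draw in twelve even for a perfect implementation.

## Thermal expansion

`thermal_expansion()` computes α_V = (V(T₂) − V(T₁)) / ((T₂ − T₁) · V(T₁))
from two points of the cooling curve. α_V(T) is strongly temperature
dependent for these materials, so a narrow interval (25 K) is recommended.
The reference volume is V at the lower temperature; a midpoint-volume
convention is available (`normalization = "midpoint"`) and recorded in
provenance. The two conventions differ by O(α·ΔT/2) ≈ 0.2 %, far below the
precision at which expansivities are reported.

## Hydrogen-bond kinetics

A hydrogen bond exists when the donor-oxygen–acceptor-oxygen minimum-image
distance is **strictly** below 0.35 nm and the angle at the donor oxygen
between its hydrogen and the acceptor is **strictly** below 30°. Boundary
values are excluded on both thresholds; the angle vertex is the donor
oxygen. Donors are identified as oxygens with a covalently attached
hydrogen (same molecule, within 0.12 nm), acceptors as all oxygens; both
selections are configurable atom-name regexes, and an explicitly selected
donor without an attached hydrogen is an error naming the atom.

Kinetics use the intermittent existence function with multiple time
origins,

C(t) = Σ_origins Σ_bonds h(t₀) h(t₀+t) / Σ_origins Σ_bonds h(t₀)²,

where h is the 0/1 bond indicator. The intermittent (not continuous)
convention lets a bond that breaks and reforms keep contributing — the form
under which rigid systems whose bonds "never break" legitimately show
near-infinite lifetimes. C(0) = 1 whenever any bond exists, and C ∈ [0, 1]
always. The implementation computes the frame–frame Gram matrix once
(`crossprod`), so cost is O(F²·B) in BLAS rather than R loops.

`fit_decay()` fits C(t) = K₁e^(−t/τ₁) + K₂e^(−t/τ₂) by bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`, K ≥ 0, τ > 0) from a
deterministic 3×3 grid of timescale initializations spanning 2–1000 % of
the observed span; the lowest residual norm wins, and the component with
the smaller τ is reported first. Two safeguards matter in practice:

* **No decay.** If C is constant the fit is refused outright (`converged =
  FALSE`, flag `"no decay: tau unbounded"`): τ is unidentifiable and any
  extrapolated lifetime would be an artifact.
* **Model reduction.** A fitted component with weight below 1 % of C(0)
  *and* τ beyond the observed span is indistinguishable from a constant
  offset in the data, yet would dominate the extrapolated integral
  K₁τ₁ + K₂τ₂ (a 10⁻³ weight at τ = 8000 ns adds 8 ns to a 1 ns lifetime).
  Such fits are deterministically refit as a single exponential and
  flagged `"reduced to single exponential"`. This is what makes the
  single-exponential limit behave: the integral of a fitted pure
  exponential is recovered to 10⁻³ regardless of how the two-term model
  would have split the weight.

`lifetime_halflife()` then reports the lifetime as the full extrapolated
integral ∫₀^∞ C_fit dt = K₁τ₁ + K₂τ₂ and the half-life as the time at
which C_fit crosses 0.5, found by bracketed root-finding (the bracket is
doubled from max(τ₁, τ₂) until it contains the crossing, then solved to
10⁻¹²). An alternative reading of "integrated until it reached 0.5" — the
partial integral up to the crossing time — is implemented behind
`halflife_convention = "integral"`; the crossing time is the default
because it is the convention under which "half-life" has its usual
median-survival meaning, and for completely monotone mixtures it is
provably ≤ the lifetime (median ≤ mean), which the tests assert on every
fit. If C_fit(0) < 0.5 the half-life is 0 with an explicit flag.
Non-converged fits are refused downstream.

## Mechanics

Stress is the negated axial pressure-tensor component, σ(ε) = −P_z(ε),
converted bar → GPa; strain is engineering strain (L_t − L₀)/L₀.

**Smoothing.** Each smoothed value is the unweighted mean of the raw stress
over a ±2.5 % strain window (the kernel is unspecified in common practice;
an unweighted mean is the simplest choice consistent with "smoothed over a
strain range"). To obtain zero stress at zero strain, the data are extended
by odd reflection around ε = 0 — points (−ε′, −σ′) — with one refinement: a
sample exactly at ε = 0 enters the extended set as its odd part (zero).
This makes the extended point set exactly point-symmetric, so the smoothed
curve passes through the origin identically, with noise, not just on
average. At the upper data edge the half-width shrinks symmetrically to
min(h, ε_max − ε): windows never extrapolate, and the shrinkage (rather
than one-sided truncation) preserves linear curves exactly over the whole
grid — σ = a·ε maps to itself to 10⁻¹², which the tests assert. That exact
linearity is also why the modulus fit below can use a zero intercept.

**Constants.** E is the zero-intercept least-squares slope Σσε/Σε² over
0.3–3 % strain (Hooke's law; the reflected smoothing already forces the
curve through the origin, so a free intercept would fight the
construction). Maximum tensile stress is the largest smoothed σ on
3–97 % strain, with the smallest strain reported among exact ties. ν is the
negated OLS slope of transverse vs axial strain over 1–2 %, with the
transverse reference length taken at zero axial strain (not a time
average). K = E/(3(1 − 2ν)); within 10⁻³ of ν = 0.5 the denominator is
effectively zero and the value is withheld with a
`"near-incompressible"` flag instead of reporting a number whose sign and
magnitude are noise. Deformations repeated in x, y and z aggregate to mean
± population SD per constant, the standard error estimate for this
procedure. Energy-term tables are differenced against their first row
(E − E₀ per contribution vs strain).

## Free volume

Free volume is operationalized as the probe-center-accessible fraction: the
fraction of a regular grid of points whose minimum-image distance to every
atom center exceeds that atom's van der Waals radius plus the probe radius
(probes 0.1, 0.05, 0.01 nm). A point exactly on an exclusion surface counts
as excluded. The grid has round(L/spacing) points per dimension so the
spacing tiles the box exactly; the default spacing of 0.02 nm keeps the
discretization error below 1 % against a Monte-Carlo oracle on the test
packings, and the resolution is recorded in provenance. Bundled
Bondi-style vdW radii are config-replaceable. Accessible fractions are
provably nested in probe radius (non-increasing as the probe grows), which
is asserted per frame.

## Diffusion

MSDs are computed with multiple time origins via the standard FFT
autocorrelation algorithm (O(N log N) per particle per dimension; the
tests verify it against a naive O(N²) oracle to 10⁻¹⁰), averaged over
particles and dimensions; a single-origin mode exists for closed-form
worked examples. Unwrapping accumulates minimum-image steps and refuses
data in which any step reaches half a box edge, where the image choice
becomes ambiguous.

D is slope/6 of an OLS line on MSD vs lag over the fractional window
10–90 % of the trace — on a 10 ns run, exactly a 1–9 ns fit. The intercept
is free: the window deliberately excludes the short-time ballistic/cage
regime, and forcing the line through zero would bias D. The error is the
split-half estimate: the window is halved and D fitted on each half
separately, the error being |D₁ − D₂| (exactly 0 on a perfectly linear
MSD). This estimator tracks realized curvature of one MSD curve, not the
full ensemble sampling error, and is known to run tight: in the package's
own 50-replicate calibration the ±2·error interval covers the generating D
in ~80 % of replicates, not 95 %. Per-chain diffusivities fit each chain's
center-of-mass MSD separately (same window) and report mean ± population
SD across chains.

## The synthetic generators: what they emulate, and what they do not

Each generator is a pure function of its seed (bit-identical output,
caller's RNG untouched) and targets the statistical structure one analysis
stage consumes:

| generator | emulates | ground truth |
|---|---|---|
| `gen_vt_curve` | hinged V(T) cooling curve | T_g, branch slopes |
| `gen_bond_events` | two-state Markov bond indicators | 1/k_break lifetime |
| `gen_stress_strain` | elastic–plastic trace, C¹ knee, exactly linear below yield | E, plateau |
| `gen_box_deformation` | coupled transverse box response | ν (linear convention) |
| `gen_random_walk` | unwrapped Brownian ensemble | D (increment variance 2DΔt) |
| `gen_packing` | non-overlapping periodic spheres | analytic excluded volume |
| `gen_hbond_geometry` | one donor–H–acceptor triplet | exact distance and angle |

Noise is additive i.i.d. Gaussian throughout. Real MD observables carry
correlated thermostat/barostat fluctuations, anharmonic baselines and drift
that white noise does not reproduce, so passing recovery tests demonstrates
that the estimators are implemented correctly and are unbiased under clean
conditions — not that their uncertainties are realistic for engine output.
The transverse response defaults to the linear convention ε_t = −ν·ε_a; a
volume-preserving finite-strain variant (L_t = L₀(1+ε)^(−1/2), apparent
ν ≈ 0.489 over the 1–2 % window) is an explicit flag, since the derivative
definition of ν does not fix the finite-strain convention. Bond events
start formed so that C(0) = 1, mirroring how existence is conditioned on an
initial bond.

## Problem sizes and pre-registered test designs

The test suite exercises the study conditions at sizes chosen once,
balancing statistical resolution against a default test run of under a
minute: 10⁴ bonds × 401 frames for kinetics recovery (Gram-matrix cost
~10⁹ BLAS flops), 100 particles × 1001 frames for diffusivity, 100-atom
packings at 0.02 nm spacing against 10⁶-sample Monte Carlo, and 400-point
stress traces. Two designs deserve explicit mention because they were fixed
by error propagation *before* any test data were drawn: the noisy-T_g check
uses the aggregate (mean-over-20-seeds) criterion explained above, and the
noisy-modulus check (noise sd 0.05 GPa, 400 points on [0, 0.06]) averages
the three deformation directions, because the single-direction estimator's
exact SE under that noise is 3.6 % of E — no single 400-point fit can
promise 2 % — while the three-direction mean brings it to 2.1 %.

## Known limitations

* Orthorhombic boxes only; no triclinic support anywhere.
* No binary trajectory formats (XTC/TRR/DCD); GRO, extended XYZ and
  xvg-style/delimited tables are the on-disk contract.
* The existence-function Gram-matrix route scales as O(F²·B); for frame
  counts beyond a few thousand a streaming implementation would be needed.
* The split-half diffusivity error underestimates ensemble error (see
  above); treat it as a linearity diagnostic, not a confidence interval.
* Free volume reports the probe-center-accessible fraction only — no
  cavity connectivity or Voronoi construction.
* Donor/acceptor identification is name-pattern based; exotic naming
  schemes need explicit patterns in the configuration.
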