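---
title: "Mechanistic dissolution-to-exposure modeling for a two-API combination tablet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic dissolution-to-exposure modeling for a two-API combination tablet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbbm)
```

# The problem

A fixed-dose combination (FDC) tablet must demonstrate bioequivalence
(BE) for *every* active ingredient; the product fails when any one
component fails. When the two APIs are biopharmaceutically opposite —
here a freely soluble, poorly permeable base (metformin, BCS III) and a
poorly soluble, highly permeable weak acid (glyburide, BCS II) — a single
release specification has to serve both, and purely in vitro criteria
(f2 similarity) can reject batches that would in fact be bioequivalent
in vivo. `pbbm` implements a physiologically based biopharmaceutics
workflow that links the in vitro release curve to simulated plasma
exposure, so that a *dissolution safe space* — the region of release
behaviors within which BE against the reference is preserved — can be
mapped by simulation.

# The model

## Release: Weibull kinetics in hazard form

Release of dose fraction is the empirical Weibull function

$$F(t) = 1 - \exp\left(-\ln 2\,\left(\frac{t - t_{lag}}{t_{d50}}\right)^{b}\right),$$

parameterized by the time to 50% dissolution $t_{d50}$ (so that release
specifications of the form "50% dissolved by X min" can be used
verbatim; the raw Weibull scale is $a = t_{d50}^{b}/\ln 2$), the shape
$b$, and a lag $t_{lag}$ (0 for both formulations here). For coupling
into the luminal mass balance the same law is used in *hazard* form,
$h(t) = f(t)/(1-F(t)) = \ln 2\, (b/t_{d50}) ((t-t_{lag})/t_{d50})^{b-1}$:
integrating $dS/dt = -h(t)S$ reproduces $F(t)$ exactly when nothing else
limits dissolution, and the hazard multiplies naturally with the
solubility cap below. For $b < 1$ the hazard diverges at $t_{lag}^+$ and
is capped at $10^3\,\mathrm{min}^{-1}$, far above any physically
meaningful rate, purely for stiff-integrator stability.

Empirical Weibull kinetics, rather than mechanistic particle-dissolution
models (Johnson, Wang–Flanagan, Z-factor), is a deliberate choice: in a
combination tablet each API's release is shaped by formulation
interactions for which mechanistic parameters are not available, and the
safe-space axis ("time to 50% dissolution") is itself a Weibull
parameter.

## Gastrointestinal transit and absorption

Six lumped segments in series — stomach, duodenum, jejunum, ileum,
colon, rectum — each carry a solid and a dissolved pool (amounts in
µmol) with first-order transit. Gastric emptying uses separate time
constants for dissolved drug (`get_liquid`) and the undisintegrated
solid fraction (`get_solid`). The small-intestinal transit time is split
10:45:45 over duodenum:jejunum:ileum and the large-intestinal time 80:20
over colon:rectum; these splits are typical human fasted physiology (the
source study does not publish its internal values) and are configurable.

Per segment $i$, with luminal concentration $c_i$ and pH-dependent
solubility $S(\mathrm{pH}_i)$:

* **Dissolution** $= h(t)\,\mathrm{solid}_i\,(1 - c_i/S(\mathrm{pH}_i))$.
  The bracket caps dissolution at saturation and becomes *negative*
  (precipitation back to the solid pool) if a segment is supersaturated,
  e.g. after transit from a high- to a low-pH segment. Precipitate
  remains dissolvable — there is no irreversible luminal loss. This
  makes simulated exposure monotone nonincreasing in $t_{d50}$ (up to
  second-order carrier-saturation effects below 0.1%), a property the
  test suite asserts.
* **Solubility** follows Henderson–Hasselbalch scaling of a single
  reference anchor: for a weak acid
  $S(\mathrm{pH}) = S_0 (1 + 10^{\mathrm{pH}-pK_a})$, mirrored for
  bases, multiple centers multiplying. For glyburide ($pK_a$ 5.3,
  anchor $2.06\times10^{-3}$ g/L at pH 8.31) this gives the steep
  pH dependence that drives everything downstream; metformin's
  solubility is effectively unlimited at GI pH.
* **Passive absorption** $= P_{eff}\,SA_i\,c_i/1000$ (µmol/min), a
  sink-condition linear law on the segment's effective mucosal surface
  area.
* **Carrier-mediated uptake** (metformin's apical PMAT) is Hill-type:
  $V_{max,eff}\,c^n/(K_m^n + c^n)$ with $K_m = 1320$ µmol/L and
  $n = 2.64$, and per-segment relative expression (0 in the stomach,
  0.1/0.45/0.45 across the small intestine, 0.1 in colon, 0 rectum).
  Stomach absorption is disabled by default for both drugs.

## Systemic disposition: a reduced, calibrated bridge

The original study used a whole-body PBPK platform whose tissue
partitioning and population database are not reproducible from the
publication. `pbbm` replaces the systemic side with a two-compartment
disposition (central volume `vc`, peripheral `vp`, flow `q`) while
keeping every mechanism under study — release, transit, pH-dependent
solubility, saturable uptake, saturable renal secretion — intact on the
luminal side. Elimination routes:

* metformin: Michaelis–Menten renal tubular secretion on unbound plasma
  concentration, `secretion_scale * TSmax_spec * Cu/(Km + Cu)` with
  $K_m = 65.6$ µmol/L, plus glomerular filtration $GFR \cdot f_u \cdot C$
  (on by default, $f_u = 1$, GFR 0.12 L/min). Two published optimized
  values of TSmax_spec circulate (85.42 and 68.42 µmol/L/min); both ship
  as named variants, default 85.42.
* glyburide: linear hepatic clearance on unbound drug
  ($f_u = 0.01$).

Two published capacities are printed in simulator-internal units
("1/min", "µmol/L/min") that are not portable; they are bridged by two
calibrated constants, the transporter `capacity_scale` and the renal
`secretion_scale`. These, together with `vc`, `vp`, `q` and the hepatic
clearance, are fitted by seeded Monte-Carlo random search
(`calibrate_disposition()`, log-uniform sampling with a deterministic
box-shrink around the incumbent every quarter of the budget) against the
reference formulation's published geometric means (Cmax 1215.67 ng/mL
and AUC 5770.53 ng·h/mL for metformin; 67.44 and 408.98 for glyburide).
`analysis/02_calibrate.R` performs the calibration; `study_preset()`
freezes its results. The presets reproduce the four anchors within
roughly 5% (see `analysis/03_validate.R`), comfortably inside the
FE ≤ 2 / PE ≤ 20% validation bands.

Integration uses `deSolve::lsoda` with rtol $10^{-8}$ / atol
$10^{-10}$; the dose-fraction ledger (residual solid, luminal dissolved,
systemic, eliminated, fecal) is carried as extra states and closes to
$10^{-6}$ by construction, which the test suite verifies on random
configurations. Plasma concentration is reported in ng/mL
(µmol/L × MW).

# The virtual trial

`sample_population()` draws `n` subjects; each GI parameter (six segment
pHs, two gastric emptying times, small- and large-intestinal transit) is
uniform within configurable ranges (defaults: stomach pH 1.3–2.5,
duodenum 5.8–6.5, jejunum 6.0–7.0, ileum 6.8–7.5, colon 5.5–7.0, rectum
6.5–7.5; liquid GET 10–30 min, solid GET 15–60 min, SITT 2–5 h, LITT
10–40 h). Each subject carries *two* independent GI states — the only
source of within-subject variability; disposition is constant within a
subject, so that the crossover isolates formulation effects from
post-absorption physiology. Uniform sampling and an independent second
state are choices the source text leaves open ("random generation" of GI
parameters); age and BMI are recorded metadata only, a documented
limitation of the reduced disposition (the original whole-body model
scales with demographics).

`assign_crossover()` randomizes a balanced TR/RT 2×2 design; period 1
uses GI state 1, period 2 state 2 (the GI1/GI2 subgroups).
`be_crossover_analysis()` fits the standard fixed-effects crossover
ANOVA on the log metric (`sequence + period + treatment + subject`) and
reports the geometric mean ratio with its 90% CI; BE passes when the CI
lies within 80.00–125.00%. For balanced complete data this coincides
with the paired-t analysis of period differences, which the test suite
uses as an independent oracle. No multiplicity adjustment is applied —
the fixed TOST convention per metric. The FDC verdict requires all four
metric × API tests to pass.

`explore_safe_space()` varies the test formulation's $t_{d50}$ (shape
and lag held fixed) over a grid bracketing the reference, reusing the
same population, design and reference-arm simulations at every point so
that differences are formulation-driven only, then bisects each
pass/fail transition (coarse 5-min grid and 1-min refinement by default;
the analysis scripts use 10-min/1-min).

# Sensitivity screening

`run_sensitivity()` perturbs one parameter at a time (default +10%,
matching the convention of the worked examples in the source
methodology; a central ±step is available) and scores
$S = (\Delta PK/\Delta P)(P/PK)$ per output. Parameters with
$|S| < 0.05$ for every output are flagged excluded — the screening rule
for selecting virtual-population variants. Note that the one-sided
difference of a $1/P$ relationship carries $O(\mathrm{step})$ bias
($-0.909$ at a 10% step); checks against the closed form
$AUC = F\,D/CL$ therefore use a 1% step or the central option.

# Synthetic data

The clinical dataset behind the source study is confidential, so every
input is generated:

* `synth_dissolution()` — three-medium paddle-test profiles (pH 1.2 /
  4.5 / 6.8) on the 6-point (to 60 min) or 10-point (to 240 min)
  schedule, additive Gaussian noise (default SD 2 percentage points),
  clipped to [0, 105].
* `synth_observed_pk()` — the 22-point clinical sampling schedule
  (pre-dose to 48 h) with conventional proportional + additive residual
  error (defaults CV 10%; additive 5 ng/mL metformin, 0.5 ng/mL
  glyburide, roughly scaled to each drug's concentration range).
* `make_demo_study()` — a seeded, checksum-stable bundle of
  configuration + dissolution CSVs + observed dataset.

What the generators deliberately do **not** emulate: assay-specific
error structure (LLOQ censoring, heteroscedastic calibration), food
effects, disintegration variability, inter-occasion variability beyond
the two GI states, and correlation between GI parameters. Passing tests
therefore demonstrate internal consistency of the workflow under its own
stated error model, not agreement with any particular clinical dataset.

# Numerical and design notes

* Tie-breaks: Tmax is the *first* time attaining the maximum; AUC0-t is
  the linear trapezoid on the full simulated grid (a `--clinical-grid`
  style restriction is available by subsampling before NCA).
* Degenerate inputs: all-zero concentration profiles yield zero metrics
  with a warning; all-zero dissolution profiles refuse to fit; a
  saturated crossover fit (all T = R) reports a zero-width CI.
* Weibull fitting is bounded Levenberg–Marquardt with multi-start
  ($t_{d50}$ from the sampling time nearest 50% dissolved and a
  half/double grid around it; shape from {0.7, 1, 1.5}); the lag is held
  at 0 unless explicitly freed. An optional relative weighting
  (1/max(obs,1)²) emphasizes early points.
* f2 uses the standard regulatory formula; after both profiles exceed
  85% dissolved only the first such point is retained.
* Problem sizes: BE properties are exercised at n = 8–24 subjects in the
  test suite and n = 48–100 in the analysis scripts; the study design
  point is n = 100. Simulation output grids are 0.1 h (analysis) or
  0.25 h (fast checks); BE conclusions at these two grids agree to well
  under a CI width.
* Reproducibility: every stochastic routine takes an explicit integer
  seed and restores the caller's RNG state; populations, VBE runs and
  safe-space grids are bit-reproducible for a fixed seed.

# Known limitations

* Exposure is *monotone* in $t_{d50}$ here because precipitated drug
  stays dissolvable. A mechanism in which rapidly released drug
  precipitates in acid and is incompletely redissolved (plausible for a
  weak acid dosed into the stomach) would bend the fast-dissolution end
  of the safe space downward; the platform used in the source study
  includes such behavior, this reduced model does not. Consequently the
  fast-end boundary here is reached through the *upper* 125% limit, and
  Cmax — not AUC — is the boundary-crossing metric at that end. The slow
  end is Cmax-driven through the lower limit, as in the source study.
* Slower release also shifts Tmax slightly *earlier* in this model (the
  systemic peak occurs where the reduced input rate crosses
  elimination), the opposite of intuition for an uncapped
  absorption-rate-limited drug; the effect is ~0.2 h across the studied
  range.
* The two GI states are drawn independently; a `correlated-gi` variant
  (state 2 as a perturbation of state 1) is a natural extension and
  deliberately not implemented.
* Bile-salt micellar solubilization, enterohepatic recycling, metabolite
  kinetics, fed-state physiology and diabetic-population physiology are
  out of scope.
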