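---
title: "Data-driven initial estimates for PopPK models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven initial estimates for PopPK models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkautoinit)
```

## The problem

Every nonlinear mixed-effects PK fit starts from initial estimates. When
no prior values exist — a new compound, a sparse clinical dataset, an
automated model-search loop — the modeler's exploratory work becomes the
bottleneck. `pkautoinit` automates that exploration: from a raw
NONMEM-convention dataset it derives starting values for the structural
parameters of one- to three-compartment models with linear or
Michaelis–Menten elimination, and for the residual-error and
inter-individual-variability (IIV) components.

The package deliberately produces *initial estimates*, not final ones.
Everything downstream (SAEM/FOCEI estimation, covariate modelling,
model selection by information criteria) is out of scope.

## Data preparation

Records are parsed case-insensitively, `ADDL`/`II` shorthand expanded,
and every observation annotated with its time after dose (TAD), dose
amount and ordinal, route, occasion (first vs. multiple dose) and a
steady-state flag. Route detection uses what the dataset itself encodes:
`RATE > 0` (or `DUR`) means infusion, dosing into a compartment other
than the observed one means extravascular, anything else is a bolus; an
explicit route column or the `route` argument overrides this.

Steady state is declared when the regimen behind an observation is
regular — dose amounts *and* intervals within ±25% of their respective
medians, a deliberately two-sided reading since both are regimen
regularity conditions — and covers at least five doses or five
half-lives. The half-life arm can only be evaluated once a half-life
exists, so the flag is re-derived lazily (`update_ss_flags()`) after the
terminal fit.

Pooling treats all subjects' dose-normalized concentrations as one
profile, separately for first-dose, multiple-dose and mixed occasions.
Unique TADs are split into (by default) 10 type-7-quantile bins, ties
assigned to the lower bin, each bin represented by the median TAD and
median normalized concentration. Ten bins leave the 3–4 post-peak and 2
pre-peak points that adequate one-compartment analysis needs; fewer
unique TADs simply produce fewer bins. Zero or missing concentrations
are excluded from log-scale operations but retained for rRMSE scoring,
where they are informative.

## Terminal phase: two estimators, on purpose

Two different needs pull on the terminal slope:

* NCA and the graphic methods *extrapolate from the fitted line*
  (`AUC` tails, intercept volumes), so they use a strict **best-fit
  search**: among all windows of the last *k* post-peak bins
  (*k* ≥ 3, peak excluded for extravascular routes), the window with the
  highest adjusted R² and a negative slope wins; ties go to the larger
  window for stabler extrapolation.
* The adaptive single-point method only needs a **half-life number** for
  its eligibility windows and completion formulas. Sparse designs (two
  or three distinct TADs) cannot satisfy the best-fit preconditions at
  all, so when the strict search fails, `pooled_halflife()` falls back
  to a plain log-linear regression over all pooled bins (two bins
  suffice, negative slope required). This fallback feeds *only* the
  single-point method; NCA stays unavailable without a strict fit.

The half-life is fitted on first-dose data when possible (multiple-dose
data are accumulation-contaminated), otherwise on the mixed pool.

One further sparse-data concession lives in the graphical module: with
exactly two post-peak bins the terminal line is drawn through them
directly (`n = 2` leaves no degrees of freedom for an adjusted R², so
this is a construction, not a fit). Without it, single-dose sparse
designs would be entirely unanalyzable although their two terminal
points determine the one-compartment line exactly.

## Adaptive single-point method

The base phase works per subject on single observations. `V_d = Dose/C_1`
uses the first post-dose IV sample if it falls within 0.2·t½ of dosing —
within that window only `1 − e^{−0.2 ln 2} ≈ 13%` of drug has been
eliminated, so `C_1` still approximates the time-zero concentration. For
infusions the clock starts at the end of the infusion, since a
mid-infusion sample bounds nothing.

Steady-state clearance uses `CL = Dose/(C_{ss,avg} τ)` with
`C_{ss,avg} = (C_{ss,max} + C_{ss,min})/2`. The open design question is
how observed samples map onto the two extremes. Mapping the observed
maximum onto `C_{ss,max}` is correct when sampling brackets the interval
but badly wrong when both samples sit near the trough (the sparse
multiple-dose design samples at 20 and 24 h of a 24 h interval; the
naive mapping put CL off by ~90% in our simulations). We therefore
decay-correct each IV sample back to the interval peak,
`C_{ss,max} = C · e^{k_e (t − t_inf)}`, combine the per-sample values by
geometric mean, and reconstruct the trough with the printed decay
formula — the single-point completion applied per observation. Without a
usable `k_e`, or for extravascular data, the observed extremes are used
directly (two samples minimum when extravascular). The residual ~13%
overestimation of `C_{ss,avg}` by the arithmetic peak–trough mean (vs.
the exponential interval mean) is inherent to the definition and left
as is.

The extended phase fills gaps from the pooled half-life
(`V_d = CL·t½/ln 2`, and its inverse for a missing CL), substitutes the
accumulation-corrected Cmax-based central volume when both are missing,
and solves the analytic absorption equations for Ka at every
absorption-phase observation (TAD at or before the pooled peak) by
Brent root-finding on `(k_e(1+10^{-6}), 1000]` — the lower guard keeps
the bracket away from the `k_a = k_e` singularity; the convergence
tolerance of 1e-8 is far below any data-driven precision. Per-observation
roots combine into per-subject geometric means; all per-subject values
summarize as a 0.05-trimmed geometric mean (2.5% per tail), robust to
the occasional wild individual value.

## NCA and Wagner–Nelson

AUC uses the linear-up log-down trapezoid: exact on exponential decay
segments, linear on rises. Profiles are anchored at TAD 0 before
integration — at the back-extrapolated intercept for a bolus, at zero
for single-dose infusion/oral data, and at the interval-end value for
multiple-dose extravascular data (steady-state continuity). Single-dose
analysis extrapolates `C_last/λz` to infinity (flagging results where
that tail exceeds half the total — the result is retained with a
warning, since a conservative initial estimate is still better than
none); multiple-dose analysis integrates the pooled TAD profile over the
modal dosing interval, extending or truncating by log-down decay at λz.
`CL = 1/AUC` per unit dose and `V_z = CL/λz`.

Wagner–Nelson follows the printed formula set exactly: plain linear
trapezoid cumulative AUC (not lin-up/log-down — the formula row defines
it that way), `F(t) = (C_t + k_e·AUC_{0–t})/(k_e·AUC_{0–∞})`, and Ka as
minus the log-slope of `1 − F(t)` over absorption-phase bins. At least
two usable bins at or before the peak are required, which is exactly
what sparse multiple-dose oral designs lack — there NCA reports CL and V
but no Ka, and cannot form a complete extravascular candidate.

## Graphic methods

For IV first-dose data the terminal intercept gives
`V_extrap = 1/Y_intercept` (per unit dose) and `CL = λz·V_extrap`. For
extravascular data the method of residuals regresses
`ln(C_extrap − C_t)` on the strictly pre-peak bins. When fewer than two
such residuals exist (three-point sparse profiles), we fall back to the
residual line's own intercept identity `ln C_residual = ln C_0 − k_a t`:
anchoring the line at the extrapolated `ln C_0` lets a single positive
residual at or before the peak determine Ka. The volume approximation
`V_d = Dose/C_extrap(0)` is exact only as `k_a ≫ k_e`; at `k_a/k_e = 10`
the bias is 1%, at ratio 2 it reaches tens of percent — acceptable for a
starting value, and the reason flip-flop kinetics (absorption slower
than elimination) are explicitly unsupported.

## Selection

Candidates are the complete per-method sets plus all cross-method
hybrids (Cartesian product of available per-parameter values; any
available volume — Vd, Vz, Vc — may serve as the candidate V, labelled
by source). Each candidate is simulated on every subject's actual dose
and sampling schedule with the closed-form one-compartment engine and
scored by rRMSE against the individual-level observations (not the
pooled bins — pooling is an estimation device, scoring should honor the
data). The pointwise-mean denominator bounds the score at 200% and
treats over- and under-prediction symmetrically; mean-absolute-percentage
error and observed-mean-denominator variants are available via
`metric =` but are not the default, as they penalize bias asymmetrically
and tend to push sweeps toward extreme nonlinear parameters. Ties within
1e-9 resolve by method priority NCA > single-point > graphical >
hybrids, so rich noise-free data — where all methods agree — credit NCA
deterministically.

## Parameter sweeping

Sweeps hold the Part-1 outputs fixed (CL, the selected V, and Ka
unchanged for extravascular data) and grid only the new parameters.
The Km axis spans 4:1 down to 1:20 of the maximum *observed*
concentration; the printed ladder pins only the endpoints, so the
interior {2:1, 1:1, 1:2, 1:4, 1:10} was chosen as a near-log-spaced
ladder and is configurable (`sweep.km_ratios`). Vmax follows from
`CL = V_max/(K_m + C)` at working concentrations of 0.05–0.75·Cmax.
Compartmental grids combine both Part-1 volume candidates (Vd and, when
distinct, the extended-phase Vc) with Vc:Vp ratios 10:1 … 1:10 and Q at
0.25–2-fold CL; three-compartment grids repeat both sets for Vp2/Q2
(2·7·4 = 56 and 56·28 = 1568 nodes).

Every candidate is integrated with `deSolve::lsoda` at rtol 1e-8 /
atol 1e-10 — saturable-elimination corners of the grid are stiff — with
the integration split at every dose time and infusion end so doses enter
as exact state jumps and infusions as piecewise-constant input, and
observations evaluated at their exact times. A failed integration marks
that candidate with an infinite score instead of aborting the sweep.
Exact ties go to the smaller grid index, making sweeps deterministic.
The grid minimum is returned as is; no continuous refinement follows,
since the downstream NLME estimator is the refiner.

## Residual error and IIV

Per subject, the last three positive concentrations (three points
minimize absorption/distribution contamination while still leaving one
residual degree of freedom) are regressed on the log scale; subjects
without a negative slope are skipped. Residuals are formed in the
original concentration scale and give per-subject
`σ_add = √Var(C_obs − C_pred)` and `σ_prop = √Var(C_obs/C_pred − 1)`
with the conventional n−1 variance, summarized by an arithmetic mean
with total trim 0.05. With n = 3 the regression absorbs much of the
noise, so these are order-of-magnitude starting values, not unbiased
estimates — the tests assert exactly that and no more. When no subject
qualifies the fallback sets `σ_add = 0.2 · mean(DV)` and
`σ_prop = 0.2`; fallback and regression never mix. IIV starts at
ω² = 0.1 per structural parameter (≈ 32% CV, a pragmatic default),
overridable per parameter.

## The synthetic-data generator

`pk_design()` emulates the simulated design families used throughout
the tests: rich (0.25–24 h, nine samples), semi-sparse (three
round-robin groups of two samples each at post-dose pairs (2, 8),
(4, 12), (6, 24) h within the final interval of a multiple-dose
regimen), sparse1 (2 h [oral], 20, 24 h after the last of six doses) and
sparse2 (the same times after a single dose). Default truths are
CL = 4 L/h, Vc = 70 L (and for oral Ka = 1 1/h), 100 mg doses at τ = 24 h,
lognormal IIV with ω² = 0.1 and combined error with σ_prop = 0.2 and a
small additive leg σ_add = 0.02 (≈ 1.5% of the bolus Cmax) — chosen once
as representative of a mid-clearance small molecule and matched to the
default IIV/RUV initializations. Six doses in multiple-dose templates
satisfy the five-dose steady-state rule by construction.

The generator draws parameters lognormally, simulates with the same
engines the pipeline uses for *scoring* (closed form for linear 1-cpt,
ODE otherwise), applies `y = f(1 + ε_prop) + ε_add` truncated at zero,
and emits NONMEM-convention records (oral doses into compartment 1,
observations in compartment 2, so route detection is exercised rather
than bypassed). What it does **not** emulate: BLQ censoring, irregular
real-world dosing histories, covariate effects, inter-occasion
variability, absorption lag, and model misspecification beyond the
structural families above. Passing tests therefore demonstrate correct
method behavior under the stated generating models, not robustness to
everything real data can do.

## Numerical choices and degenerate inputs

* `k_a = k_e` in the closed form uses the limiting kernel
  `(D/V)·k_e·t·e^{−k_e t}`.
* Quantile binning, tie handling, window tie-breaks and sweep
  tie-breaks are all deterministic; identical inputs give identical
  reports.
* Empty pooling groups yield empty profiles that downstream methods
  skip; subjects without doses are dropped with a warning; observations
  before any dose are excluded from TAD-based analyses but reported.
* A pipeline run with no complete Part-1 candidate fails with
  per-method diagnostics rather than inventing a structural default.

## Problem sizes used in tests

Noise-free checks run 2–6 subjects (they are deterministic); stochastic
behavior checks use 30 subjects (matching the generator's default) and
the IIV-variance calibration check uses 10⁴ subjects sampled at a
single time point. The acceptance script runs the full pipeline on
30-subject designs and 12-subject sweep recoveries; everything completes
in seconds on one core.

## Known limitations

One-compartment assumptions underlie all Part-1 methods; on
multi-compartment or nonlinear data their outputs are starting points
only. Flip-flop absorption, transit/lag absorption models, BLQ
imputation, inter-occasion variability and covariate models are out of
scope. The Vp grid cannot see peripheral volumes outside the 10:1–1:10
ratio band, and the sweep returns a grid node, not an optimum —
by design, both are left to the downstream estimator.
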