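---
title: "Methods: AUC-weighted integrated pharmacokinetics, validation statistics, and offline network pharmacology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AUC-weighted integrated pharmacokinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbipk)
```

## The problem

Herbal medicines expose the body to many constituents at once; the
pharmacokinetics (PK) of any single marker compound describes only a slice
of the systemic exposure.  A common remedy is *integrated pharmacokinetics*:
estimate each constituent's exposure by non-compartmental analysis (NCA),
weight each constituent by its share of the total area under the
concentration–time curve,

$$ w_j = \frac{AUC_{0\to\infty,j}}{\sum_k AUC_{0\to\infty,k}}, \qquad
   c_T(t) = \sum_j w_j\, c_j(t), $$

and analyze the single integrated profile $c_T(t)$ as if it were one drug.
`herbipk` implements this workflow end to end for long-format plasma data,
together with the bioanalytical method-validation statistics used to qualify
the underlying assay and an offline network-pharmacology stage for relating
the absorbed constituents to disease targets.  The motivating application is
a rat study of *Polygonum multiflorum* extract with five absorbed
constituents (TSG, EG, PG, AE, EM), and the package defaults mirror that
design: 6 subjects, sampling at 5, 15, 30 min and 1, 2, 4, 8, 12, 24 h, an
18 g/kg oral extract dose, and assay LLOQs of 0.125 ng/mL (EG) or
0.500 ng/mL (others).

## Non-compartmental analysis

`run_nca()` computes the standard extravascular parameter set.  Choices that
were genuinely open, and how this package resolves them:

* **AUC method.** Linear trapezoid by default; `"linuplogdown"` switches
  declining positive segments to the logarithmic trapezoid
  $(C_1 - C_2)\,\Delta t / \ln(C_1/C_2)$ (and the matching exponential-interpolation
  first-moment formula), falling back to linear on rising, flat or
  zero-touching segments.
* **Terminal slope ($\lambda_z$).** Log-linear regression over trailing
  windows of at least 3 quantifiable points strictly after Tmax, selecting
  the window with the largest adjusted $R^2$ among fits with a negative
  slope; ties go to the window with more points.  This mirrors the
  "best-fit" convention of mainstream NCA software.  When the peak is the
  first quantifiable sample — a profile already in monotone decline — the
  peak joins the candidate points, as is conventional for such profiles;
  otherwise the peak is excluded.  A profile whose peak is its last
  quantifiable sample has no terminal phase (`terminal-phase-not-estimable`),
  distinct from one with a decline that is simply too short
  (`insufficient-data`).
* **BLQ handling.** Below-LLOQ values before the peak are set to 0 and
  retained; trailing BLQ values are dropped; interior BLQ values are treated
  as missing.  This is the standard bioanalytical convention; censored
  values are never imputed with LLOQ/2.
* **Extrapolation.** $AUC_{0\to\infty} = AUC_{0\to t} + C_{last}/\lambda_z$ with the
  *observed* last quantifiable concentration.  `pct_extrapolated` reports the
  tail share so users can judge reliability.
* **Units.** Times in hours (5/15/30 min enter as 0.083/0.25/0.5 h),
  concentrations in ng/mL, dose in mg/kg.  CLz/F is reported in L/h/kg and
  Vz/F in L/kg; the mg/(ng/mL) mismatch contributes a factor of $10^3$ L.
  The per-constituent dose inside an extract is typically unknown, so `dose`
  defaults to the extract-equivalent dose and clearance/volume values should
  be read as extract-normalized quantities; with `dose = NA` they are
  simply omitted.
* **Dispersion.** All reported SDs are sample (n−1) SDs.

## Integration

`compute_weights()` generalizes the weighting denominator to however many
analytes are supplied.  Two provenance choices exist for the AUCs and the
package exposes both:

* `scope = "pooled-mean"` (default): one weight vector from the mean
  $AUC_{0\to\infty}$ across subjects, applied to every subject.  Published
  integrated-PK studies report a single coefficient set, which this
  reproduces.
* `scope = "per-subject"`: weights recomputed from each subject's own AUCs.

`basis = "auc_0_t"` substitutes the observed-range AUC for studies where the
extrapolated tail is unreliable.

Because the linear trapezoid is linear in concentrations, the integrated
profile's $AUC_{0\to t}$ equals $\sum_j w_j\,AUC_{0\to t,j}$ *exactly* — per subject,
to machine precision — whenever all component profiles share the grid and no
observation is censored.  LLOQ censoring breaks the identity (a censored
tail truncates one component's integration range but contributes zero to the
integrated curve), which is why the exactness property is verified on
uncensored synthetic studies; censored studies are exercised separately in
the recovery analyses.  Two further consequences of convexity are checked as
invariants: integrated Cmax never exceeds $\sum_j w_j\,C_{max,j}$, and the
integrated Tmax lies within the range of component Tmax values for the
simulated unimodal profiles.

Within the integrated profile, a time point is censored only when every
component is censored there; its nominal LLOQ is $\min_j w_j\,LLOQ_j$, the
smallest contribution a single quantifiable component can make.

## Bioanalytical validation statistics

The validation stage reproduces the statistics used to qualify an LC-MS/MS
assay under the FDA bioanalytical guidance:

* **Calibration** by weighted least squares, default weight $1/x^2$; the
  reported correlation is the weighted Pearson $r$ (the guidance does not
  say whether published $r$ values are weighted; the weighted form is
  consistent with the fitting criterion).  Flat-response calibrations are
  flagged invalid rather than fitted.
* **Precision** = 100·SD/mean (RSD), **accuracy** = 100·mean/nominal.
  Accuracy is reported as percent-of-nominal; relative-error conventions
  differ only by 100% and produce identical pass/fail decisions under the
  windows below.
* **Acceptance windows**: accuracy 80–120% and RSD ≤ 20% at the LLOQ,
  85–115% and ≤ 15% elsewhere, treated as closed intervals; the LLOQ
  signal-to-noise criterion is strict (> 10).
* **Recovery** = extracted/post-spiked response; **matrix effect** =
  post-spiked/neat response, both in percent.

## Network pharmacology (offline)

The network stage consumes exported files only — target lists, a
STRING-style PPI edge list, GMT gene sets — and never queries a database:

* `intersect_targets()` is a case-normalized set intersection (compound
  targets ∩ disease targets).
* `topology_metrics()` reports degree and closeness.  Closeness uses the
  Wasserman–Faust component-scaled form
  $\frac{n_c-1}{\sum d}\cdot\frac{n_c-1}{n-1}$ so disconnected subnetworks
  are handled without infinities; harmonic closeness is available by flag.
* `select_key_targets()` keeps nodes whose degree **and** closeness both
  exceed the subnetwork mean, ranked by degree then closeness.  The
  published phrasing ("median value higher than the average value") is not
  interpretable per node; per-node metric > subnetwork mean is the reading
  implemented here.
* `enrich_pathways()` is the exact hypergeometric upper tail
  $P[X \ge k]$ with Benjamini–Hochberg adjustment across pathways.  DAVID's
  EASE variant (one overlapping gene discounted) is available via
  `ease = TRUE` for users comparing against DAVID output.  The default
  universe is the PPI node set, overridable.
* Edge confidence scores are kept by default; `score_cutoff` filters
  STRING-style scores when a threshold is wanted.

## The synthetic study generator

Because the motivating rat dataset is not publicly deposited, the package
ships a generator (`simulate_pk_study()`) whose defaults *are* the study
conditions: 5 analytes × 6 subjects on the 9-point schedule above, with

* one-compartment first-order absorption
  $C(t) = \mathrm{scale}\cdot\frac{k_a}{k_a-k_e}(e^{-k_e t} - e^{-k_a t})$, the
  minimal model consistent with single-peak oral profiles (no
  enterohepatic recirculation);
* per-analyte presets (`default_pk_analytes()`) in which $(k_a, k_e,
  \mathrm{scale})$ reproduce literature-scale mean $AUC_{0\to\infty}$, terminal
  half-life and Tmax for TSG/EG/PG/AE/EM.  A one-compartment curve cannot
  simultaneously match those three quantities *and* the reported Cmax for
  the fastest-eliminated constituents, so exposure, half-life and peak time
  were prioritized — they drive the weights and the recovery statistics;
  simulated Cmax values are therefore lower than the published ones for TSG
  and EM;
* lognormal inter-individual variability (default CV 20%, the usual
  pharmacometric magnitude for rodent PK) on $k_a$, $k_e$ and scale;
* proportional (default 10%) plus additive (default 0) Gaussian assay
  error, truncated at zero;
* LLOQ censoring at the assay limits, reported as zero with a BLQ flag.

What the generator does **not** emulate: multi-peak absorption,
enterohepatic recirculation, metabolite interconversion
(glucoside → aglycone), correlated inter-individual random effects, and
actual-versus-nominal sampling-time deviations.  Passing recovery tests
therefore demonstrate correctness of the estimators under a well-specified
generative model, not robustness to every feature of real rat data.

`simulate_validation_batch()` and `simulate_network_study()` provide the
corresponding ground-truthed fixtures for the validation and network
stages (known bias/CV; a planted intersection and a planted enriched
pathway with Erdős–Rényi decoy edges).

## Numerical and testing choices

* Weight vectors must sum to 1 within $10^{-12}$; the integration linearity
  identity is asserted at $10^{-9}$ relative.
* The terminal-slope selector is verified window-for-window against an
  exhaustive enumeration that refits every candidate window with `lm()`;
  the hypergeometric tail is verified against exhaustive enumeration of all
  $\binom{N}{n}$ draws for universes up to $N = 12$; BH adjustment is
  verified against a hand step-up computation.
* The recovery analysis runs 200 simulated studies at the default design
  (6,000 profile fits) and summarizes the pooled median absolute relative
  error of half-life and $AUC_{0\to\infty}$ against the generative truth; the
  suite also spot-checks that recovery degrades monotonically as the
  proportional error grows (0% → 10% → 30%).  These sizes keep the full
  suite under a minute on a single core.
* All generators are pure functions of `(config, seed)`; pipeline outputs
  embed the configuration hash and seed, and repeated runs are
  byte-identical.

## Known limitations

* No compartmental or population (NLME) modelling, urinary excretion, or
  IV-route parameters.
* No interpolation across mismatched sampling grids: integration requires
  identical nominal grids, matching single-schedule designs.
* Published weighting coefficients for the motivating study are not
  arithmetically recoverable from its published mean AUCs, presumably
  because they were computed per animal on undeposited data; this package
  asserts only the weighting arithmetic itself, never those printed
  coefficients.
* Vz/F and CLz/F magnitudes depend on the per-analyte dose, which is
  unknowable for an extract; they are reported on the extract-equivalent
  dose scale.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_pk_study(sim_pk_config(seed = 7))
study <- integrated_study(sim$profiles)
study$weights
study$summary[, c("parameter", "TSG", "EM", "integrated")]
```
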