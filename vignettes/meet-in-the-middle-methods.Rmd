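---
title: "Methods: BMI milestones, consensus metabolite networks, and the meet-in-the-middle screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BMI milestones, consensus metabolite networks, and the meet-in-the-middle screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Children whose body mass index (BMI) peaks late in infancy or rebounds
early in childhood carry elevated metabolic risk a decade later. `mimnet`
implements a *meet-in-the-middle* analysis that asks which plasma
metabolite profiles mark that relationship: features are screened for
association with the upstream exposure (the BMI milestones) *and* with
the downstream outcome (a composite metabolic syndrome z-score), and only
features associated with both are interpreted. The high-dimensional
metabolome is first reduced to a small number of consensus co-abundance
networks shared between boys and girls, so the screen operates on module
eigengenes rather than ~1000 individual compounds.

Because no individual-level cohort of this kind is publicly released, the
package ships a synthetic-cohort generator with full ground truth. Every
stage is therefore testable: milestone recovery against planted
trajectories, module recovery against planted blocks, coverage of planted
effect coefficients, and false-discovery control under a global null.

## Growth milestones from spline mixed models

Longitudinal BMI is modelled by REML as

\[ \mathrm{BMI}_{ij} = \beta_0 + s\,\beta_s + \sum_k N_k(t_{ij})
   (\beta_k + s\,\gamma_k + b_{ik}) + b_{i0} + \varepsilon_{ij}, \]

where \(N_k\) is a natural cubic spline basis of age in months, \(s\) an
indicator for male sex (so each sex has its own population curve), and
\(b_{i\cdot}\) subject-level random coefficients. The infancy peak and
childhood rebound are the derivative roots of each child's fitted curve:
the derivative of a cubic spline is piecewise quadratic and evaluated
analytically from the basis, roots are bracketed on a 0.1-month grid and
refined by bisection to 0.001 months, and among multiple roots the peak
takes the largest and the rebound the smallest fitted BMI. Children whose
fitted curve has no interior sign change get a flagged (not erroneous)
non-identified milestone and drop out of models that use that exposure.

Choices the data could not dictate, made once and kept:

* **Knots** at 3, 9, 18, 36, 66, 96 months (boundary 0.25 and 130):
  densest where the two milestones live, sparse through late childhood.
* **Random effects**: a subject-level intercept plus independent
  (diagonal-covariance) random coefficients on *every* basis term. With
  random coefficients restricted to the first few (infancy-localised)
  basis terms, subject curves cannot deviate from the population mean
  near the rebound, the per-child rebound magnitude shrinks to the sex
  mean, and its RMSE is several times the measurement noise; the diagonal
  structure keeps the 8-dimensional REML problem fast and stable.
* **Search windows**: infancy peak in [1, 16] months, rebound in
  [24, 110] months. The infancy window is deliberately tight around the
  biologically plausible range (peaks typically occur at 7–9 months):
  the fitted curves are nearly flat after the peak, so a window reaching
  deep into the decline lets noise wiggles win the largest-BMI tie-break
  and systematically inflates the estimated peak age.
* **Eligibility**: at least three measurements from birth through 132
  months.
* **Reporting scale**: each milestone is divided by its within-sex sample
  SD, so all association estimates read "per 1 SD", and the SD table is
  emitted alongside as part of the reporting contract.

### What the synthetic trajectories are — and are not

Each child's latent curve is the quartic whose derivative is
\(b'(t) = k\,(t - t_p)(t - t_r)(t + c)\) with \(c = 12\) months, \(k\)
and the integration constant solved so the curve passes through the drawn
peak magnitude and peak-to-rebound drop. Planted milestones are therefore
*exact* stationary points, which is what makes recovery testing sharp.
The family has one deliberate artificiality: because \(k\) is pinned by
the drop over the long peak-to-rebound span, the infancy rise is tiny
(~0.05 kg/m² from birth to peak, against 0.3 kg/m² measurement noise),
far flatter than real infant BMI curves. Two consequences, verified by
simulation and documented rather than hidden: per-child peak *age*
carries almost no individual information (estimates shrink toward the
per-sex population argmax), and the mean recovered peak age sits
~0.3 months above the mean planted peak age because the argmax of a mean
curve is not the mean of per-child argmaxes in a flat family. Peak
magnitude, rebound age, and rebound magnitude are all recovered well
(bias and RMSE bounds in the acceptance suite). Default study conditions:
150 children per sex, 12 visits from 2 weeks to 114 months on a
well-child-like schedule, milestone distributions matching published
adolescent-cohort descriptives (peak ~8.0/8.7 months at ~18.4/17.8 kg/m²,
rebound ~62/58 months, drop 2.2 ± 0.6 kg/m²), measurement noise 0.3
kg/m².

## Metabolomics preprocessing

Fixed order, refusing re-application: keep endogenous compounds only;
impute below-detection values per metabolite as half its minimum detected
value; log10; Pareto-scale (centre, divide by the square root of the
sample SD, \(n-1\) denominator). Pareto scaling leaves each column with
variance equal to its logged SD, damping high-variance compounds without
flattening them to unit variance. The generator's missingness is
left-censoring at a per-metabolite quantile (default 10%), which is the
data pattern half-minimum imputation presumes.

## Consensus networks

Per sex stratum: Spearman correlation (average ranks on ties — material
here because half-minimum imputation creates ties), signed adjacency
\(a_{ij} = ((1+\rho_{ij})/2)^{10}\), topological overlap
\(\omega_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})\)
computed with matrix products. Stratum TOMs are calibrated so each one's
0.95 quantile matches the across-strata mean of that quantile, combined
by element-wise minimum (so consensus modules are tight in *both* sexes),
and clustered by average linkage on \(1 - \omega\).

**Module detection** is a recursive branch decomposition of the
dendrogram ("tree"-style dynamic cut): starting from the root, a branch
becomes a module when it has at least 20 members and its median internal
dissimilarity is at most 0.99 of the static cut height (the 0.99 quantile
of merge heights); otherwise it splits at its top merge and the children
are examined. Accepted branches are pruned of stragglers — members whose
median dissimilarity to the rest of the branch fails the same rule — and
members of branches that bottom out below the minimum size are left
unassigned (label 0, excluded from eigengenes and all downstream models).
The procedure is deterministic, permutation-equivariant, recovers planted
blocks at loading 0.8 with ARI above 0.9, and leaves pure-noise
metabolomes almost entirely unassigned. The hybrid (PAM-like) variant
with kME reassignment is a documented extension point, not implemented.

**Eigengenes**: per stratum and module, the first singular vector of the
column-standardised sample-by-member submatrix, rescaled to z-scores
across samples and sign-oriented so mean member correlation is positive
(higher score = higher member abundance). Variance explained is the first
squared singular value over the total; kME is each metabolite's
correlation with each eigengene; reporting lists the top 10 per module
plus everything with |kME| > 0.6.

**Outliers**: before construction, samples whose standardized
connectivity in the sample–sample squared-Pearson correlation network
falls below −2.5 are removed. Squared (sign-free) correlation is used
because with factor-structured data the signed similarity between samples
centres at zero, which would make a decoupled sample invisible to
connectivity.

## MetS z-score

HOMA-IR = glucose (mg/dL) × insulin (µIU/mL) / 405; SBP is the mean of
the five readings (fewer tolerated with a logged warning). Each of waist,
SBP, HDL, triglycerides and HOMA-IR is standardized against an external
mean/SD table stratified by sex and closed-open 1-year age bin (height
bins additionally for SBP); the composite is the five-component mean with
HDL negated. The package bundles no population reference values: the
schema accepts any mean/SD table, and the generator emits compatible
tables computed from a 20,000-person null-effect population simulated
under the same marginal model. Triglycerides and HOMA-IR are standardized
on the raw scale, matching direct standardization; a log-first flag is
not provided because the reference interface would then need log-scale
tables.

## The three-step screen

All models are sex-stratified ordinary least squares with complete-case
handling per model and 95% t-intervals.

1. **Milestones → MetS z**: four per-SD exposures, unadjusted and
   adjusted (race/ethnicity + age at the teen visit); milestones with
   adjusted p < 0.05 are carried.
2. **Carried milestones → eigengenes**: each ME as outcome, same
   adjustment; Benjamini–Hochberg at q = 0.05 within the per-sex family
   of all carried-milestone × ME tests (the most conservative family
   consistent with a per-sex 5% FDR); FDR-significant pairs are carried.
3. **Carried eigengenes → MetS z**: four tiers — unadjusted; Model 1
   (race/ethnicity + age); Model 2 (+ ordinal puberty score); Model 3
   (+ maternal education, pre-pregnancy BMI, 3-level pregnancy smoking).
   Model-1-significant eigengenes get five additional Model-1 fits on the
   component z-scores, uncorrected, because the components are correlated
   facets of one construct.

The sensitivity analysis refits step-2 models adding the contemporaneous
milestone of the same period (age adjusted for magnitude and vice versa)
and reports the percent change in the estimate; |correlation| > 0.99
between the pair is treated as collinear and refused. Effects of
*earlier* milestones are read as sign flips at the reporting layer; the
data are never recoded.

## Numerical and testing choices

* Derivative roots: 0.1-month grid bracketing plus bisection to 1e-3
  months; the spline derivative is exact, not finite-differenced.
* BH flags are computed through `stats::p.adjust(·, "BH")` and tested
  against an independently coded exhaustive step-up definition.
* Determinism: every stochastic stage consumes an explicit seed;
  identical configuration + seed reproduces all output files
  byte-identically (hashed in the acceptance suite), and the pipeline
  writes a manifest (seed, config hash, participant-flow counts).
* Problem sizes in the test and acceptance suites are the package's study
  defaults: milestone recovery at n = 300 children × 12 visits; module
  recovery at 5 × 30 metabolites + 50 background, 200 samples per
  stratum; FDR control from 500 global-null screen replicates (26 tests
  per sex); coverage from 200 planted-path replicates at n = 250 per sex.
* Screen-level replicates (`simulate_screen_replicate()`) generate data
  at the screen's interface with the fitted model equal to the generating
  model, so 95% CI coverage of planted coefficients is exactly the
  property being certified. Re-estimating milestones and networks inside
  each replicate would instead measure errors-in-variables attenuation —
  a real phenomenon, but one that makes nominal coverage the wrong target;
  estimation quality of those stages is certified separately.

## Known limitations

* The quartic trajectory family's flat infancy peak (above) makes peak
  *age* bias sit near its identification limit; a generator family with a
  realistic infancy rise would make that recovery much sharper.
* The synthetic metabolome has equal loadings within a module, no
  batch effects, no inter-module correlation, and missingness purely at
  the limit of detection; passing tests say nothing about robustness to
  batch structure or informative missingness.
* Consensus combination is the element-wise minimum after quantile
  calibration; other consensus rules (e.g. component-wise quantiles) are
  not implemented.
* The screen is OLS-only by design; no mediation analysis, no mixed
  models at the association stage, no imputation of missing covariates
  (complete-case per tier, mirroring shrinking per-tier sample sizes).
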