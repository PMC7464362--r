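# mimnet

Meet-in-the-middle screening of early-life BMI milestones, consensus
metabolite networks, and adolescent metabolic risk.

## What this package is for

Two early-life growth milestones — the **infancy BMI peak** (the maximum
of a child's BMI curve, typically at 7–9 months) and the **childhood BMI
rebound** (its subsequent minimum, typically at 3–6 years) — predict
metabolic risk in adolescence. `mimnet` implements, as tested and
reusable R functions plus a numbered analysis workflow, the full pipeline
for asking *which plasma metabolite profiles mark that relationship*:

1. **Milestones** — sex-interacted natural-cubic-spline mixed models fit
   individual BMI curves from longitudinal anthropometry; each child's
   peak and rebound are the roots of the analytic derivative
   (`estimate_milestones()`), reported per within-sex SD.
2. **Metabolomics preprocessing** — endogenous filter, half-minimum
   imputation of below-detection values, log10, Pareto scaling
   (`preprocess_metabolites()`).
3. **Consensus networks** — per-sex signed Spearman adjacency
   \(a_{ij} = ((1+\rho_{ij})/2)^{10}\), topological overlap
   \(\omega_{ij} = (\ell_{ij}+a_{ij})/(\min(k_i,k_j)+1-a_{ij})\),
   quantile-calibrated element-wise-minimum consensus across sexes,
   average-linkage clustering with a dynamic tree cut (minimum module
   size 20), module eigengenes (first singular vector, z-scored) and kME
   membership (`consensus_network()`).
4. **MetS z-score** — five externally standardized components (waist,
   mean of five SBP readings, HDL, triglycerides,
   HOMA-IR = glucose × insulin / 405) averaged with HDL reversed
   (`compute_mets_z()`).
5. **The three-step screen** — per sex: milestones → MetS z (carry
   nominal hits), carried milestones → eigengenes with
   Benjamini–Hochberg FDR at 5%, carried eigengenes → MetS z through
   tiered covariate models, plus component follow-up and a
   mutual-adjustment sensitivity analysis (`run_screen()`).

No individual-level cohort of this kind is public, so the package ships
a **synthetic-cohort generator** (`simulate_cohort()`) with exact ground
truth: quartic BMI trajectories whose derivative roots are the planted
milestones, a block-factor metabolome with limit-of-detection
missingness, components driven linearly by module factors and milestone
ages, and matching reference tables. Every downstream claim is tested
against that truth. See `vignettes/meet-in-the-middle-methods.Rmd` for
the model details and design rationale.

## Worked example

The numbered drivers under `analysis/` run the whole study on the
default synthetic cohort (300 children, 200 metabolites in five planted
modules, seed 1) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_milestones.R
...
Rscript analysis/06_associate.R
```

Stage 2 prints the milestone recovery against the planted truth:

```
identified peaks: 289 of 300
identified rebounds: 296 of 300
recovery vs planted truth: bias(t_p) 0.37 mo, bias(t_r) -0.63 mo,
  RMSE(B_p) 0.19, RMSE(B_r) 0.25 kg/m2
```

i.e. peak and rebound ages are recovered with sub-month mean error and
milestone magnitudes to ~0.2 kg/m² despite 0.3 kg/m² measurement noise.
Stage 4 recovers the planted module structure exactly (five consensus
modules, each mapping one-to-one onto a planted block; all 44 retained
background metabolites left unassigned), and stage 6 prints the screen:

```
step 2 FDR-significant (milestone, network) pairs:
 stratum exposure outcome   beta        p
  female      t_r     ME4 -0.221 6.45e-03
    male      t_r     ME2  0.279 5.34e-04
    male      t_r     ME4 -0.366 9.68e-06
```

These are the planted paths: the generator plants a later rebound
lowering the metabolic-risk module factor in boys (−0.35 per SD;
estimated −0.366 on the eigengene scale), a weaker version in girls
(−0.20; estimated −0.221), and a second boys-only path into the module
found as ME2 (+0.30; estimated +0.279). Step 3 then shows the
metabolic-risk module (found as ME4) strongly associated with the MetS
z-score across all covariate tiers (Model 1 β = 0.48, p ≈ 1e-26) while
ME2 — planted to drive only systolic blood pressure — contributes almost
nothing to the composite, exactly as configured.

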