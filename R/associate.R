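## Sex-stratified three-step meet-in-the-middle screen:
## step 1 milestones -> MetS z (carry nominally significant milestones),
## step 2 carried milestones -> module eigengenes with BH-FDR (carry
## FDR-significant pairs), step 3 carried eigengenes -> MetS z across
## tiered covariate models, with uncorrected component follow-up and a
## mutual-adjustment sensitivity analysis.

#' Fit one linear association model
#'
#' Ordinary least squares of `outcome` on `exposure` plus covariates
#' (categoricals expanded to indicators), on complete cases; 95% CI from
#' the t distribution.
#'
#' @param data data frame holding all variables.
#' @param outcome,exposure column names.
#' @param covariates character vector of covariate column names.
#' @return one-row data frame (outcome, exposure, beta, ci_lo, ci_hi, p, n).
#' @export
fit_linear_association <- function(data, outcome, exposure,
                                   covariates = character()) {
  vars <- c(outcome, exposure, covariates)
  assert_columns(data, vars, "data")
  stop_if(exposure %in% covariates, "exposure cannot also be a covariate")
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars,
            drop = FALSE]
  for (v in vars) if (is.character(d[[v]])) d[[v]] <- factor(d[[v]])
  stop_if(nrow(d) < length(vars) + 2,
          sprintf("too few complete cases (%d) for model %s ~ %s",
                  nrow(d), outcome, exposure))
  stop_if(stats::var(d[[outcome]]) == 0,
          sprintf("constant outcome `%s`", outcome))
  form <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit <- stats::lm(form, data = d)
  co <- stats::coef(fit)
  aliased <- names(co)[is.na(co)]
  stop_if(length(aliased) > 0,
          sprintf("rank-deficient design; aliased term(s): %s",
                  paste(aliased, collapse = ", ")))
  sm <- summary(fit)$coefficients
  est <- sm[exposure, "Estimate"]
  se <- sm[exposure, "Std. Error"]
  tq <- stats::qt(0.975, fit$df.residual)
  data.frame(outcome = outcome, exposure = exposure,
             beta = est, ci_lo = est - tq * se, ci_hi = est + tq * se,
             p = sm[exposure, "Pr(>|t|)"], n = nrow(d),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg rejection flags
#'
#' Step-up FDR control at level `q`; flags are returned in input order.
#'
#' @param p p-values in `[0, 1]`.
#' @param q FDR level.
#' @return logical vector.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0) return(logical(0))
  stop_if(any(p < 0 | p > 1, na.rm = TRUE), "p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH") <= q
}

## accept consensus_network()$eigengenes or a plain list of ME matrices
me_matrix <- function(eig_stratum) {
  if (is.list(eig_stratum) && !is.null(eig_stratum$me)) eig_stratum$me
  else as.matrix(eig_stratum)
}

## per-sex analysis frame: scaled exposures + MEs + MetS z + covariates
build_frame <- function(sex_level, scaled_milestones, eigengenes, mets_z,
                        covariates) {
  d <- scaled_milestones[scaled_milestones$sex == sex_level, , drop = FALSE]
  if (!is.null(eigengenes)) {
    me <- me_matrix(eigengenes[[sex_level]])
    me_df <- data.frame(subject_id = rownames(me), me,
                        check.names = FALSE, stringsAsFactors = FALSE)
    d <- merge(d, me_df, by = "subject_id")
  }
  if (!is.null(mets_z))
    d <- merge(d, mets_z[, c("subject_id", setdiff(names(mets_z), "subject_id")),
                         drop = FALSE], by = "subject_id")
  if (!is.null(covariates))
    d <- merge(d, covariates[, setdiff(names(covariates), "sex"), drop = FALSE],
               by = "subject_id")
  d
}

#' Step 1: milestones vs MetS z-score
#'
#' Per sex, each of the four per-SD milestone exposures is regressed
#' against the composite MetS z-score, unadjusted and adjusted for
#' race/ethnicity and age at the teen visit. Milestones with adjusted
#' p < alpha are marked as carried forward.
#'
#' @param scaled_milestones within-sex per-SD milestone table
#'   ([standardize_exposures()] `$scaled`).
#' @param mets_z output of [compute_mets_z()].
#' @param covariates covariate table (race_ethnicity, age_years, ...).
#' @param alpha nominal significance level for carrying forward.
#' @return data frame (stratum, exposure, outcome, tier, beta, ci_lo,
#'   ci_hi, p, n, carried).
#' @export
run_step1 <- function(scaled_milestones, mets_z, covariates, alpha = 0.05) {
  rows <- list()
  for (s in sort(unique(scaled_milestones$sex))) {
    d <- build_frame(s, scaled_milestones, NULL, mets_z, covariates)
    for (e in c("t_p", "B_p", "t_r", "B_r")) {
      for (tier in c("unadjusted", "adjusted")) {
        cov <- if (tier == "adjusted") c("race_ethnicity", "age_years")
               else character()
        r <- fit_linear_association(d, "mets_z", e, cov)
        rows[[length(rows) + 1L]] <- cbind(stratum = s, r, tier = tier)
      }
    }
  }
  out <- do.call(rbind, rows)
  adj <- out[out$tier == "adjusted", ]
  key <- paste(out$stratum, out$exposure)
  sig <- paste(adj$stratum, adj$exposure)[adj$p < alpha]
  out$carried <- key %in% sig
  rownames(out) <- NULL
  out
}

#' Step 2: carried milestones vs module eigengenes
#'
#' Per sex, each carried milestone is regressed against every module
#' eigengene (ME as outcome), adjusted for race/ethnicity and age;
#' Benjamini-Hochberg flags are computed within the per-sex family of all
#' carried-milestone x ME tests, and FDR-significant pairs are carried
#' forward.
#'
#' @param step1 output of [run_step1()] (or any table with stratum,
#'   exposure, carried columns).
#' @param scaled_milestones per-SD milestone table.
#' @param eigengenes per-stratum eigengene scores (a
#'   [consensus_network()] `$eigengenes` list or plain matrices).
#' @param covariates covariate table.
#' @param q FDR level.
#' @param alpha nominal level.
#' @return data frame (stratum, exposure, outcome, beta, ci_lo, ci_hi, p,
#'   n, nominal_flag, fdr_flag).
#' @export
run_step2 <- function(step1, scaled_milestones, eigengenes, covariates,
                      q = 0.05, alpha = 0.05) {
  rows <- list()
  for (s in sort(unique(step1$stratum))) {
    carried <- unique(step1$exposure[step1$stratum == s & step1$carried])
    if (length(carried) == 0) next
    d <- build_frame(s, scaled_milestones, eigengenes, NULL, covariates)
    mes <- colnames(me_matrix(eigengenes[[s]]))
    sex_rows <- list()
    for (e in carried) {
      for (m in mes) {
        r <- fit_linear_association(d, m, e, c("race_ethnicity", "age_years"))
        sex_rows[[length(sex_rows) + 1L]] <- cbind(stratum = s, r)
      }
    }
    sex_out <- do.call(rbind, sex_rows)
    sex_out$nominal_flag <- sex_out$p < alpha
    sex_out$fdr_flag <- bh_fdr(sex_out$p, q)
    rows[[length(rows) + 1L]] <- sex_out
  }
  if (length(rows) == 0) {
    return(data.frame(stratum = character(), outcome = character(),
                      exposure = character(), beta = numeric(),
                      ci_lo = numeric(), ci_hi = numeric(), p = numeric(),
                      n = integer(), nominal_flag = logical(),
                      fdr_flag = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Step 3: carried eigengenes vs MetS z-score, with component follow-up
#'
#' Per sex, each FDR-carried eigengene is regressed against the composite
#' MetS z-score under four tiers: unadjusted; Model 1 (race/ethnicity +
#' age); Model 2 (Model 1 + puberty score, ordinal); Model 3 (Model 2 +
#' maternal education, pre-pregnancy BMI, smoking category). Eigengenes
#' significant in Model 1 get five additional Model-1 fits on the
#' component z-scores, uncorrected (the components are correlated facets
#' of one construct).
#'
#' @param step2 output of [run_step2()].
#' @param eigengenes per-stratum eigengene scores.
#' @param mets_z output of [compute_mets_z()] (composite + components).
#' @param covariates covariate table.
#' @param scaled_milestones per-SD milestone table (row universe for the
#'   analysis frame).
#' @param alpha nominal level for the component follow-up trigger.
#' @return list with `tiers` and `components` data frames (the latter
#'   empty when nothing is carried).
#' @export
run_step3 <- function(step2, eigengenes, mets_z, covariates,
                      scaled_milestones, alpha = 0.05) {
  tiers <- list(unadjusted = character(),
                M1 = c("race_ethnicity", "age_years"),
                M2 = c("race_ethnicity", "age_years", "puberty_score"),
                M3 = c("race_ethnicity", "age_years", "puberty_score",
                       "maternal_college", "prepreg_bmi", "smoking_preg"))
  empty <- data.frame(stratum = character(), outcome = character(),
                      exposure = character(), tier = character(),
                      beta = numeric(), ci_lo = numeric(), ci_hi = numeric(),
                      p = numeric(), n = integer(), stringsAsFactors = FALSE)
  if (nrow(step2) == 0 || !any(step2$fdr_flag)) {
    log_msg("step 3: no networks carried forward")
    return(list(tiers = empty, components = empty))
  }
  rows <- list(); comp_rows <- list()
  for (s in sort(unique(step2$stratum[step2$fdr_flag]))) {
    mes <- unique(step2$outcome[step2$stratum == s & step2$fdr_flag])
    d <- build_frame(s, scaled_milestones, eigengenes, mets_z, covariates)
    for (m in mes) {
      fits <- lapply(names(tiers), function(tn) {
        r <- fit_linear_association(d, "mets_z", m, tiers[[tn]])
        cbind(stratum = s, r, tier = tn)
      })
      rows <- c(rows, fits)
      m1 <- fits[[2]]
      if (m1$p < alpha) {
        for (cz in c("z_waist", "z_sbp", "z_hdl", "z_tg", "z_homa")) {
          r <- fit_linear_association(d, cz, m, tiers$M1)
          comp_rows[[length(comp_rows) + 1L]] <- cbind(stratum = s, r,
                                                       tier = "M1")
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  comps <- if (length(comp_rows) > 0) do.call(rbind, comp_rows) else empty
  rownames(comps) <- NULL
  list(tiers = out, components = comps)
}

#' Mutual-adjustment sensitivity analysis
#'
#' Refits the step-2 models adding the contemporaneous milestone of the
#' same period as a covariate (age at peak adjusted for BMI at peak and
#' vice versa; likewise at rebound) and reports the adjusted estimate
#' side-by-side with the unadjusted one and the percent change in beta.
#'
#' @param step2 output of [run_step2()].
#' @param scaled_milestones per-SD milestone table.
#' @param eigengenes per-stratum eigengene scores.
#' @param covariates covariate table.
#' @return data frame (stratum, exposure, sibling, outcome, beta,
#'   beta_mutual, ci_lo, ci_hi, p, pct_change).
#' @export
sensitivity_mutual_adjustment <- function(step2, scaled_milestones,
                                          eigengenes, covariates) {
  sibling <- c(t_p = "B_p", B_p = "t_p", t_r = "B_r", B_r = "t_r")
  if (nrow(step2) == 0) return(step2)
  rows <- list()
  for (s in sort(unique(step2$stratum))) {
    d <- build_frame(s, scaled_milestones, eigengenes, NULL, covariates)
    sub <- step2[step2$stratum == s, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      e <- sub$exposure[i]; m <- sub$outcome[i]; sib <- sibling[[e]]
      cc <- stats::complete.cases(d[, c(e, sib)])
      r2 <- stats::cor(d[[e]][cc], d[[sib]][cc])
      stop_if(abs(r2) > 0.99,
              sprintf("`%s` and `%s` are collinear (|cor| = %.3f)", e, sib,
                      abs(r2)))
      r <- fit_linear_association(d, m, e,
                                  c(sib, "race_ethnicity", "age_years"))
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, exposure = e, sibling = sib, outcome = m,
        beta = sub$beta[i], beta_mutual = r$beta,
        ci_lo = r$ci_lo, ci_hi = r$ci_hi, p = r$p,
        pct_change = 100 * (r$beta - sub$beta[i]) / abs(sub$beta[i]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full three-step screen
#'
#' @param scaled_milestones per-SD milestone table.
#' @param eigengenes per-stratum eigengene scores.
#' @param mets_z composite and component z-scores.
#' @param covariates covariate table.
#' @param q FDR level for step 2.
#' @param alpha nominal level.
#' @return list with `step1`, `step2`, `step3` (tiers + components),
#'   `sensitivity`.
#' @export
run_screen <- function(scaled_milestones, eigengenes, mets_z, covariates,
                       q = 0.05, alpha = 0.05) {
  s1 <- run_step1(scaled_milestones, mets_z, covariates, alpha)
  s2 <- run_step2(s1, scaled_milestones, eigengenes, covariates, q, alpha)
  s3 <- run_step3(s2, eigengenes, mets_z, covariates, scaled_milestones,
                  alpha)
  sens <- sensitivity_mutual_adjustment(s2, scaled_milestones, eigengenes,
                                        covariates)
  list(step1 = s1, step2 = s2, step3 = s3, sensitivity = sens)
}
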