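## Growth-milestone estimation.
##
## A sex-interacted natural-cubic-spline mixed model is fit to longitudinal
## BMI by REML; per-subject curves (fixed part for the subject's sex plus
## subject-level random coefficients) are differentiated analytically and
## the infancy BMI peak / childhood BMI rebound are located as derivative
## roots inside configurable search windows.

#' Growth model configuration
#'
#' @param interior_knots interior knot ages (months); the default places
#'   knots densely near the infancy peak and through the rebound range.
#' @param boundary_knots boundary knot pair (months).
#' @param infancy_window,childhood_window search windows (months) for the
#'   BMI peak and rebound. The infancy window is deliberately tight around
#'   the biologically plausible peak range (first 16 months): because the
#'   fitted curves are nearly flat after the infancy peak, a window
#'   extending deep into the decline lets noise wiggles win the
#'   largest-BMI tie-break and biases the peak age late.
#' @param eligibility_max_age upper age bound (months) for the
#'   three-measurement eligibility rule ("birth through mid-childhood").
#' @param min_measurements minimum BMI measurements required per subject.
#' @return list of class `spline_config`.
#' @export
spline_config <- function(interior_knots = c(3, 9, 18, 36, 66, 96),
                          boundary_knots = c(0.25, 130),
                          infancy_window = c(1, 16),
                          childhood_window = c(24, 110),
                          eligibility_max_age = 132,
                          min_measurements = 3L) {
  basis <- ns_basis(interior_knots, boundary_knots)
  structure(list(basis = basis,
                 infancy_window = infancy_window,
                 childhood_window = childhood_window,
                 eligibility_max_age = eligibility_max_age,
                 min_measurements = as.integer(min_measurements)),
            class = "spline_config")
}

#' Eligibility filter
#'
#' Retains subjects with at least `min_measurements` BMI measurements from
#' birth through the mid-childhood bound; logs how many subjects were
#' excluded.
#'
#' @param anthro anthropometry table (subject_id, sex, age_months, bmi).
#' @param config a [spline_config()].
#' @return list with `records` (filtered table), `kept`, `dropped` ids.
#' @export
eligibility_filter <- function(anthro, config = spline_config()) {
  assert_columns(anthro, c("subject_id", "sex", "age_months", "bmi"),
                 "anthro")
  stop_if(nrow(anthro) == 0, "empty anthropometry table")
  in_range <- anthro$age_months >= 0 &
    anthro$age_months <= config$eligibility_max_age
  counts <- table(anthro$subject_id[in_range])
  kept <- names(counts)[counts >= config$min_measurements]
  all_ids <- unique(anthro$subject_id)
  dropped <- setdiff(all_ids, kept)
  log_msg("eligibility: %d of %d subjects retained (>= %d measurements in [0, %g] mo)",
          length(kept), length(all_ids), config$min_measurements,
          config$eligibility_max_age)
  list(records = anthro[anthro$subject_id %in% kept, , drop = FALSE],
       kept = kept, dropped = dropped)
}

#' Fit the sex-interacted spline mixed model
#'
#' REML fit of BMI on the natural-cubic-spline basis of age with a sex main
#' effect, sex-by-basis interactions, and subject-level random coefficients
#' (random intercept plus independent random slopes on every basis term).
#'
#' @param anthro eligible anthropometry table; both sexes must be present.
#' @param config a [spline_config()].
#' @return object of class `growth_fit` holding the lme4 fit, the basis,
#'   per-subject coefficient tables, and a convergence flag.
#' @export
fit_growth_model <- function(anthro, config = spline_config()) {
  assert_columns(anthro, c("subject_id", "sex", "age_months", "bmi"),
                 "anthro")
  stop_if(length(unique(anthro$sex)) < 2,
          "both sexes required for the sex-interacted model")
  stop_if(any(anthro$age_months < config$basis$boundary_knots[1] |
                anthro$age_months > config$basis$boundary_knots[2]),
          "measurement ages outside the spline boundary knots")
  ## canonical row order makes the fit exactly invariant to input order
  anthro <- anthro[order(anthro$subject_id, anthro$age_months), , drop = FALSE]
  B <- ns_eval(config$basis, anthro$age_months)
  df <- data.frame(bmi = anthro$bmi,
                   sex = factor(anthro$sex, levels = c("female", "male")),
                   subject_id = factor(anthro$subject_id))
  df <- cbind(df, as.data.frame(B))
  bn <- colnames(B)
  fixed <- paste0("bmi ~ sex * (", paste(bn, collapse = " + "), ")")
  form <- stats::as.formula(paste0(
    fixed, " + (1 + ", paste(bn, collapse = " + "), " || subject_id)"))
  fit <- lme4::lmer(form, data = df, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs)
  if (!converged)
    log_msg("growth model convergence warnings: %s",
            paste(unlist(msgs), collapse = "; "))

  fe <- lme4::fixef(fit)
  re <- lme4::ranef(fit)$subject_id
  sex_by_id <- tapply(as.character(df$sex), df$subject_id, `[`, 1L)
  structure(list(model = fit, basis = config$basis, config = config,
                 fixef = fe, ranef = re, sex_by_id = sex_by_id,
                 converged = converged,
                 sigma = stats::sigma(fit)),
            class = "growth_fit")
}

## assemble a subject's curve coefficients: (intercept, basis coefs)
subject_coefs <- function(fit, subject_id) {
  stop_if(!(subject_id %in% rownames(fit$ranef)),
          sprintf("unknown subject id `%s`", subject_id))
  sex <- fit$sex_by_id[[subject_id]]
  fe <- fit$fixef
  bn <- paste0("ns", seq_len(fit$basis$df))
  b0 <- fe[["(Intercept)"]]
  bb <- fe[bn]
  if (sex == "male") {
    b0 <- b0 + fe[["sexmale"]]
    bb <- bb + fe[paste0("sexmale:", bn)]
  }
  re <- fit$ranef[subject_id, , drop = TRUE]
  b0 <- b0 + re[["(Intercept)"]]
  bb <- unname(unlist(bb)) + unname(unlist(re[bn]))
  list(intercept = b0, basis = bb)
}

#' Predict a subject's fitted BMI curve and its derivative
#'
#' @param fit a `growth_fit`.
#' @param subject_id subject present in the fit.
#' @param ages ages (months) inside the boundary knots.
#' @return list with `bmi` and `deriv` (kg/m2 per month) vectors; the
#'   derivative is exact (piecewise quadratic) from the spline basis.
#' @export
predict_subject_curve <- function(fit, subject_id, ages) {
  stopifnot(inherits(fit, "growth_fit"))
  co <- subject_coefs(fit, subject_id)
  N <- ns_eval(fit$basis, ages)
  N1 <- ns_eval(fit$basis, ages, deriv = 1L)
  list(bmi = drop(co$intercept + N %*% co$basis),
       deriv = drop(N1 %*% co$basis))
}

## locate derivative sign-change roots on a grid, refine by bisection
derivative_roots <- function(dfun, window, grid_step = 0.1, tol = 1e-3) {
  g <- seq(window[1], window[2], by = grid_step)
  if (g[length(g)] < window[2]) g <- c(g, window[2])
  d <- dfun(g)
  s <- sign(d)
  idx <- which(s[-1] * s[-length(s)] < 0)
  roots <- lapply(idx, function(i) {
    lo <- g[i]; hi <- g[i + 1L]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (sign(dfun(mid)) == sign(dfun(lo))) lo <- mid else hi <- mid
    }
    list(root = (lo + hi) / 2, direction = if (d[i] > 0) "max" else "min")
  })
  exact <- which(d == 0 & g > window[1] & g < window[2])
  for (i in exact) {
    dir <- if (i > 1 && d[i - 1] > 0) "max" else "min"
    roots[[length(roots) + 1L]] <- list(root = g[i], direction = dir)
  }
  roots
}

#' Extract milestone estimates for fitted subjects
#'
#' Within the infancy window the BMI peak is the derivative root where the
#' slope changes from positive to negative (ties broken by the largest
#' fitted BMI); within the childhood window the rebound is the root where
#' the slope turns positive (smallest fitted BMI). Subjects whose fitted
#' curve has no interior sign change get an unidentified flag, not an
#' error.
#'
#' @param fit a `growth_fit`.
#' @param subject_ids subjects to extract; default all in the fit.
#' @return data frame (subject_id, sex, t_p, B_p, t_r, B_r,
#'   peak_identified, rebound_identified); unidentified milestones are NA.
#' @export
extract_milestones <- function(fit, subject_ids = rownames(fit$ranef)) {
  stopifnot(inherits(fit, "growth_fit"))
  cfg <- fit$config
  res <- lapply(subject_ids, function(id) {
    co <- subject_coefs(fit, id)
    dfun <- function(t) drop(ns_eval(fit$basis, t, deriv = 1L) %*% co$basis)
    vfun <- function(t) drop(co$intercept + ns_eval(fit$basis, t) %*% co$basis)

    pk <- Filter(function(r) r$direction == "max",
                 derivative_roots(dfun, cfg$infancy_window))
    rb <- Filter(function(r) r$direction == "min",
                 derivative_roots(dfun, cfg$childhood_window))
    t_p <- B_p <- t_r <- B_r <- NA_real_
    if (length(pk) > 0) {
      vals <- vapply(pk, function(r) vfun(r$root), numeric(1))
      j <- which.max(vals)
      t_p <- pk[[j]]$root; B_p <- vals[j]
    }
    if (length(rb) > 0) {
      vals <- vapply(rb, function(r) vfun(r$root), numeric(1))
      j <- which.min(vals)
      t_r <- rb[[j]]$root; B_r <- vals[j]
    }
    data.frame(subject_id = id, sex = fit$sex_by_id[[id]],
               t_p = t_p, B_p = B_p, t_r = t_r, B_r = B_r,
               peak_identified = length(pk) > 0,
               rebound_identified = length(rb) > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Standardize milestone exposures within sex
#'
#' Divides each milestone exposure by its within-sex sample SD on the
#' analysis sample, so downstream association estimates are per +1 SD; the
#' SDs themselves are reported alongside (the reporting contract for the
#' "per 1 SD" column headers).
#'
#' @param milestones output of [extract_milestones()].
#' @return list with `scaled` (exposures divided by within-sex SD) and
#'   `sds` (sex x exposure SD table).
#' @export
standardize_exposures <- function(milestones) {
  assert_columns(milestones, c("subject_id", "sex", "t_p", "B_p", "t_r", "B_r"),
                 "milestones")
  expo <- c("t_p", "B_p", "t_r", "B_r")
  scaled <- milestones
  sds <- list()
  for (s in unique(milestones$sex)) {
    i <- milestones$sex == s
    row <- list(sex = s)
    for (e in expo) {
      x <- milestones[[e]][i]
      ok <- !is.na(x)
      stop_if(sum(ok) < 2,
              sprintf("fewer than 2 identified `%s` values for sex `%s`", e, s))
      sdev <- stats::sd(x[ok])
      stop_if(!is.finite(sdev) || sdev == 0,
              sprintf("zero SD for `%s` in sex `%s`", e, s))
      scaled[[e]][i] <- x / sdev
      row[[e]] <- sdev
    }
    sds[[s]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  sds <- do.call(rbind, sds)
  rownames(sds) <- NULL
  list(scaled = scaled, sds = sds)
}

#' Estimate milestones from an anthropometry table
#'
#' Convenience wrapper: eligibility filter, model fit, milestone
#' extraction, and within-sex exposure standardization.
#'
#' @param anthro anthropometry table.
#' @param config a [spline_config()].
#' @return list with `fit`, `milestones`, `scaled`, `sds`.
#' @export
estimate_milestones <- function(anthro, config = spline_config()) {
  elig <- eligibility_filter(anthro, config)
  fit <- fit_growth_model(elig$records, config)
  mil <- extract_milestones(fit)
  std <- standardize_exposures(mil)
  list(fit = fit, milestones = mil, scaled = std$scaled, sds = std$sds)
}
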