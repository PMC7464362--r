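## Synthetic cohort generator.
##
## Emulates the structure of a pre-birth cohort followed into early
## adolescence: longitudinal BMI with one infancy maximum and one childhood
## minimum per child, a block-correlated log-normal metabolome with planted
## modules and limit-of-detection missingness, metabolic syndrome components
## linearly driven by planted module factors and milestone ages, matching
## external standardization reference tables, and a covariate table. Ground
## truth (milestones, module labels, effect coefficients) is returned so
## every downstream stage can be tested against known answers.

#' Simulation configuration
#'
#' Builds the configuration object consumed by [simulate_cohort()] and the
#' individual `simulate_*` generators. Defaults encode the study conditions
#' the package is tested under: per-sex milestone distributions matching
#' published descriptives for an adolescent cohort (infancy peak near 8 mo
#' at ~18 kg/m2, rebound near 60 mo with ~21 mo SD), a 5-module metabolome
#' with factor loading 0.8, 10% left-censoring, and metabolic-risk
#' components driven by the childhood rebound through module factors.
#'
#' @param n_per_sex subjects per sex.
#' @param measurement_ages scheduled visit ages in months.
#' @param peak_age_mean,peak_age_sd infancy-peak age distribution (months).
#' @param rebound_age_mean,rebound_age_sd childhood-rebound age distribution
#'   (months).
#' @param peak_magnitude_mean,peak_magnitude_sd BMI at peak (kg/m2).
#' @param drop_mean,drop_sd BMI drop from peak to rebound (kg/m2), must be
#'   positive per subject.
#' @param sex_gaps named list of male-minus-female mean gaps for
#'   `peak_age`, `rebound_age`, `peak_magnitude`.
#' @param peak_age_range,rebound_age_range admissible windows (months);
#'   draws outside are rejected and redrawn.
#' @param bmi_noise_sd measurement noise SD (kg/m2).
#' @param curve_shift_c third (out-of-domain) derivative root at `-c`
#'   months; controls the positive initial slope.
#' @param n_modules,module_sizes planted metabolite modules.
#' @param intra_module_loading factor loading in (0, 1) shared by module
#'   members.
#' @param n_background_metabolites independent-noise metabolites.
#' @param nonendogenous_fraction fraction of metabolites flagged
#'   non-endogenous (dropped by the preprocessing filter).
#' @param lod_censor_fraction per-metabolite left-censoring fraction in
#'   `[0, 0.5]` (limit-of-detection missingness).
#' @param effect_map data frame (exposure, target, beta, stratum) of
#'   planted effects; exposures are milestones (`t_p`, `B_p`, `t_r`,
#'   `B_r`, standardized within sex) or module factors (`module<k>`);
#'   targets are module factors or MetS components
#'   (`waist`, `sbp`, `hdl`, `tg`, `glucose`, `insulin`).
#' @param mets_noise_sd named per-component residual SDs (native units).
#' @param covariate_missing_rate missingness rate for the Model-2/3
#'   covariates (puberty, maternal education, pre-pregnancy BMI, smoking).
#' @param n_reference reference-population size for standardization tables.
#' @param seed integer seed; the full dataset is bit-reproducible given the
#'   same configuration and seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_per_sex = 150,
                       measurement_ages = c(0.5, 2, 4, 6, 9, 12, 18, 30,
                                            48, 66, 90, 114),
                       peak_age_mean = 8.35, peak_age_sd = 2,
                       rebound_age_mean = 60, rebound_age_sd = 21,
                       peak_magnitude_mean = 18.1, peak_magnitude_sd = 1.35,
                       drop_mean = 2.2, drop_sd = 0.6,
                       sex_gaps = list(peak_age = -0.7, rebound_age = 4.8,
                                       peak_magnitude = 0.6),
                       peak_age_range = c(3, 16),
                       rebound_age_range = c(28, 106),
                       bmi_noise_sd = 0.3,
                       curve_shift_c = 12,
                       n_modules = 5,
                       module_sizes = rep(30L, 5),
                       intra_module_loading = 0.8,
                       n_background_metabolites = 50,
                       nonendogenous_fraction = 0.1,
                       lod_censor_fraction = 0.1,
                       effect_map = default_effect_map(),
                       mets_noise_sd = c(waist = 6, sbp = 7, hdl = 10,
                                         tg = 25, glucose = 5, insulin = 3),
                       covariate_missing_rate = 0.005,
                       n_reference = 20000,
                       seed = 1L) {
  assert_scalar_number(peak_age_mean, "peak_age_mean", 0)
  assert_scalar_number(rebound_age_mean, "rebound_age_mean", 0)
  stop_if(peak_age_mean >= rebound_age_mean,
          "peak_age_mean must be below rebound_age_mean")
  for (nm in c("peak_age_sd", "rebound_age_sd", "peak_magnitude_sd",
               "drop_sd", "bmi_noise_sd"))
    assert_scalar_number(get(nm), nm, 0)
  assert_scalar_number(intra_module_loading, "intra_module_loading", 0, 1)
  stop_if(intra_module_loading >= 1, "`intra_module_loading` must be < 1")
  assert_scalar_number(lod_censor_fraction, "lod_censor_fraction", 0, 0.5)
  stop_if(length(module_sizes) != n_modules,
          "`module_sizes` must have `n_modules` entries")
  stop_if(!is.data.frame(effect_map) ||
            !all(c("exposure", "target", "beta", "stratum") %in%
                   names(effect_map)),
          "`effect_map` needs columns exposure, target, beta, stratum")
  cfg <- as.list(environment())
  cfg$module_sizes <- as.integer(module_sizes)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Default planted effect map
#'
#' The default causal structure: in boys, a later childhood rebound lowers
#' the module-2 factor and raises module 4, and a higher rebound BMI raises
#' module 2; module 2 drives waist, insulin, triglycerides and (negatively)
#' HDL in both sexes; module 4 drives systolic blood pressure in boys; the
#' rebound milestones also act directly on waist. Betas are in native
#' component units per 1 SD of the driver (per 1 SD of the milestone within
#' sex, or per unit of the module factor).
#'
#' @return data frame with columns exposure, target, beta, stratum.
#' @export
default_effect_map <- function() {
  data.frame(
    exposure = c("t_r", "t_r", "B_r", "t_r",
                 "module2", "module2", "module2", "module2",
                 "module4", "B_r", "t_r"),
    target   = c("module2", "module4", "module2", "module2",
                 "waist", "insulin", "tg", "hdl",
                 "sbp", "waist", "waist"),
    beta     = c(-0.35, 0.30, 0.25, -0.20,
                 3.0, 2.0, 15, -4.0,
                 3.0, 2.0, -1.2),
    stratum  = c("male", "male", "male", "female",
                 "both", "both", "both", "both",
                 "male", "both", "both"),
    stringsAsFactors = FALSE
  )
}

## Quartic latent BMI curve: b'(t) = k (t - t_p)(t - t_r)(t + c), k > 0,
## integrated analytically; k and the constant solve b(t_p) = B_p and
## b(t_p) - b(t_r) = drop, so the planted milestones are exact.
quartic_curve <- function(t_p, t_r, B_p, drop, c_shift) {
  a2 <- c_shift - (t_p + t_r)
  a1 <- t_p * t_r - c_shift * (t_p + t_r)
  a0 <- c_shift * t_p * t_r
  P <- function(t) t^4 / 4 + a2 * t^3 / 3 + a1 * t^2 / 2 + a0 * t
  k <- drop / (P(t_p) - P(t_r))
  C0 <- B_p - k * P(t_p)
  list(
    value = function(t) k * P(t) + C0,
    deriv = function(t) k * (t - t_p) * (t - t_r) * (t + c_shift)
  )
}

#' Simulate longitudinal BMI trajectories
#'
#' Draws per-subject milestone parameters, builds the latent quartic curve
#' whose derivative has roots exactly at the drawn peak and rebound ages,
#' and observes BMI at the scheduled visit ages with Gaussian noise.
#'
#' @param config a [sim_config()].
#' @return list with `anthropometry` (subject_id, sex, age_months, bmi) and
#'   `truth` (subject_id, sex, t_p, B_p, t_r, B_r).
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- 2L * config$n_per_sex
  sex <- rep(c("male", "female"), each = config$n_per_sex)
  ids <- sprintf("S%04d", seq_len(n))
  half_gap <- function(g) ifelse(sex == "male", g / 2, -g / 2)

  draw_one <- function(mu, sd, range = c(-Inf, Inf), extra_ok = function(x) TRUE,
                       max_try = 200L) {
    for (i in seq_len(max_try)) {
      x <- stats::rnorm(1, mu, sd)
      if (x >= range[1] && x <= range[2] && extra_ok(x)) return(x)
    }
    stop("could not draw an admissible milestone parameter after ",
         max_try, " tries", call. = FALSE)
  }

  t_p <- t_r <- B_p <- drop <- numeric(n)
  for (i in seq_len(n)) {
    t_p[i] <- draw_one(config$peak_age_mean + half_gap(config$sex_gaps$peak_age)[i],
                       config$peak_age_sd, config$peak_age_range)
    t_r[i] <- draw_one(config$rebound_age_mean + half_gap(config$sex_gaps$rebound_age)[i],
                       config$rebound_age_sd, config$rebound_age_range,
                       extra_ok = function(x) x > t_p[i])
    B_p[i] <- draw_one(config$peak_magnitude_mean +
                         half_gap(config$sex_gaps$peak_magnitude)[i],
                       config$peak_magnitude_sd, c(13, 28))
    drop[i] <- draw_one(config$drop_mean, config$drop_sd, c(1e-3, Inf))
  }
  B_r <- B_p - drop

  ages <- config$measurement_ages
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cv <- quartic_curve(t_p[i], t_r[i], B_p[i], drop[i], config$curve_shift_c)
    bmi <- cv$value(ages) + stats::rnorm(length(ages), 0, config$bmi_noise_sd)
    rows[[i]] <- data.frame(subject_id = ids[i], sex = sex[i],
                            age_months = ages, bmi = bmi,
                            stringsAsFactors = FALSE)
  }
  anthro <- do.call(rbind, rows)
  rownames(anthro) <- NULL
  truth <- data.frame(subject_id = ids, sex = sex,
                      t_p = t_p, B_p = B_p, t_r = t_r, B_r = B_r,
                      stringsAsFactors = FALSE)
  list(anthropometry = anthro, truth = truth)
}

## standardize a milestone within sex (generator-side driver scale)
z_within_sex <- function(x, sex) {
  out <- numeric(length(x))
  for (s in unique(sex)) {
    i <- sex == s
    out[i] <- (x[i] - mean(x[i])) / stats::sd(x[i])
  }
  out
}

## per-subject module factors: unit-variance noise plus planted milestone
## effects (within the configured stratum)
build_module_factors <- function(config, truth) {
  n <- nrow(truth)
  fac <- matrix(stats::rnorm(n * config$n_modules), n, config$n_modules,
                dimnames = list(truth$subject_id,
                                paste0("module", seq_len(config$n_modules))))
  em <- config$effect_map
  mile <- c("t_p", "B_p", "t_r", "B_r")
  for (j in seq_len(nrow(em))) {
    if (!(em$exposure[j] %in% mile) || !grepl("^module", em$target[j])) next
    stop_if(!(em$target[j] %in% colnames(fac)),
            sprintf("effect_map references unknown module `%s`", em$target[j]))
    idx <- if (em$stratum[j] == "both") rep(TRUE, n) else truth$sex == em$stratum[j]
    z <- z_within_sex(truth[[em$exposure[j]]], truth$sex)
    fac[idx, em$target[j]] <- fac[idx, em$target[j]] + em$beta[j] * z[idx]
  }
  fac
}

#' Simulate a block-correlated metabolome
#'
#' Module members load on a shared latent factor per subject
#' (log-abundance = loading * factor + sqrt(1 - loading^2) * noise);
#' background metabolites are independent noise. Raw abundances are
#' `10^(log-abundance + location shift)`; per metabolite, values below its
#' `lod_censor_fraction` quantile are set missing (limit of detection), and
#' a configurable fraction of metabolites is flagged non-endogenous.
#'
#' @param config a [sim_config()].
#' @param truth ground-truth table from [simulate_trajectories()].
#' @return list with `abundance` (samples x metabolites, NAs = censored),
#'   `meta` (metabolite_id, name, super_pathway, sub_pathway, endogenous),
#'   `factors` (subject x module latent factors), `module_labels`
#'   (named integer vector; 0 = background).
#' @export
simulate_metabolome <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(truth)
  p_mod <- sum(config$module_sizes)
  p <- p_mod + config$n_background_metabolites
  stop_if(p_mod > p, "module sizes exceed total metabolite count")
  fac <- build_module_factors(config, truth)
  lam <- config$intra_module_loading

  logab <- matrix(NA_real_, n, p)
  labels <- integer(p)
  col <- 1L
  for (m in seq_len(config$n_modules)) {
    for (j in seq_len(config$module_sizes[m])) {
      logab[, col] <- lam * fac[, m] +
        sqrt(1 - lam^2) * stats::rnorm(n)
      labels[col] <- m
      col <- col + 1L
    }
  }
  if (col <= p)
    logab[, col:p] <- matrix(stats::rnorm(n * (p - col + 1L)), n)

  ids <- sprintf("met%04d", seq_len(p))
  shift <- stats::runif(p, 3, 6)
  raw <- 10^(sweep(logab, 2, shift, "+"))
  dimnames(raw) <- list(truth$subject_id, ids)

  if (config$lod_censor_fraction > 0) {
    for (j in seq_len(p)) {
      thr <- stats::quantile(raw[, j], config$lod_censor_fraction,
                             names = FALSE)
      raw[raw[, j] < thr, j] <- NA_real_
    }
  }

  super <- c("Lipid", "Amino Acid", "Carbohydrate", "Nucleotide",
             "Cofactors and Vitamins", "Energy", "Xenobiotics")
  meta <- data.frame(
    metabolite_id = ids,
    name = paste0("compound_", seq_len(p)),
    super_pathway = ifelse(labels > 0, super[(labels - 1L) %% 6L + 1L],
                           sample(super, p, replace = TRUE)),
    sub_pathway = ifelse(labels > 0, paste0("pathway_", labels),
                         "unclassified"),
    endogenous = TRUE,
    stringsAsFactors = FALSE
  )
  n_nonendo <- round(config$nonendogenous_fraction * p)
  if (n_nonendo > 0) {
    nonendo <- sample(p, n_nonendo)
    meta$endogenous[nonendo] <- FALSE
    meta$super_pathway[nonendo] <- "Xenobiotics"
  }
  names(labels) <- ids
  list(abundance = raw, meta = meta, factors = fac, module_labels = labels)
}

## latent mean model for the MetS components in native units; shared by the
## cohort and the (null-effect) reference population
component_means <- function(sex, age, height) {
  male <- as.numeric(sex == "male")
  list(
    waist = 71 + 2.0 * male + 1.5 * (age - 12.9),
    sbp = 106 + 2.0 * male + 1.2 * (age - 12.9) + 0.2 * (height - 157),
    hdl = 55 - 3.0 * male,
    tg = 75 + 2.0 * male,
    glucose = 88 + 1.0 * male,
    insulin = 10
  )
}

draw_height <- function(sex, age) {
  stats::rnorm(length(age), 157 + 4 * (sex == "male") + 5 * (age - 12.9), 7)
}

## planted-effect contributions to each component for the analysis cohort
component_effects <- function(config, truth, factors) {
  n <- nrow(truth)
  comp <- c("waist", "sbp", "hdl", "tg", "glucose", "insulin")
  out <- matrix(0, n, length(comp), dimnames = list(NULL, comp))
  em <- config$effect_map
  mile <- c("t_p", "B_p", "t_r", "B_r")
  for (j in seq_len(nrow(em))) {
    if (!(em$target[j] %in% comp)) next
    idx <- if (em$stratum[j] == "both") rep(TRUE, n) else truth$sex == em$stratum[j]
    if (em$exposure[j] %in% mile) {
      drv <- z_within_sex(truth[[em$exposure[j]]], truth$sex)
    } else if (grepl("^module", em$exposure[j])) {
      stop_if(!(em$exposure[j] %in% colnames(factors)),
              sprintf("effect_map references unknown module `%s`",
                      em$exposure[j]))
      drv <- factors[, em$exposure[j]]
    } else {
      stop(sprintf("unknown effect_map exposure `%s`", em$exposure[j]),
           call. = FALSE)
    }
    out[idx, em$target[j]] <- out[idx, em$target[j]] + em$beta[j] * drv[idx]
  }
  out
}

#' Simulate MetS components, reference tables, and covariates
#'
#' Each component is a linear combination of planted module factors and
#' standardized milestone ages (per the configured effect map), plus sex,
#' age and (for SBP) height terms and Gaussian noise. Reference tables are
#' means/SDs by sex and 1-year age bin (height bins added for SBP) from an
#' independently simulated null-effect population of `config$n_reference`
#' adolescents. Covariates are drawn from fixed categorical distributions
#' and are independent of the planted paths.
#'
#' @param config a [sim_config()].
#' @param truth ground-truth milestones from [simulate_trajectories()].
#' @param factors subject x module factor matrix from [simulate_metabolome()].
#' @return list with `components`, `reference`, `covariates` data frames.
#' @export
simulate_outcomes_and_references <- function(config, truth, factors) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- nrow(truth)
  age <- pmin(pmax(stats::rnorm(n, 12.9, 0.7), 11.2), 15.8)
  height <- draw_height(truth$sex, age)
  mu <- component_means(truth$sex, age, height)
  eff <- component_effects(config, truth, factors)
  nsd <- config$mets_noise_sd

  sbp_lat <- mu$sbp + eff[, "sbp"] + stats::rnorm(n, 0, nsd[["sbp"]])
  sbp_readings <- sapply(1:5, function(k) sbp_lat + stats::rnorm(n, 0, 3))
  colnames(sbp_readings) <- paste0("sbp", 1:5)

  components <- data.frame(
    subject_id = truth$subject_id,
    sex = truth$sex,
    age_years = age,
    height = height,
    waist = mu$waist + eff[, "waist"] + stats::rnorm(n, 0, nsd[["waist"]]),
    sbp_readings,
    hdl = pmax(mu$hdl + eff[, "hdl"] + stats::rnorm(n, 0, nsd[["hdl"]]), 15),
    tg = pmax(mu$tg + eff[, "tg"] + stats::rnorm(n, 0, nsd[["tg"]]), 20),
    glucose = pmax(mu$glucose + eff[, "glucose"] +
                     stats::rnorm(n, 0, nsd[["glucose"]]), 50),
    insulin = pmax(mu$insulin + eff[, "insulin"] +
                     stats::rnorm(n, 0, nsd[["insulin"]]), 1),
    stringsAsFactors = FALSE
  )

  reference <- simulate_reference_tables(config)
  covariates <- simulate_covariates(config, truth, age)
  list(components = components, reference = reference,
       covariates = covariates)
}

#' Simulate external standardization reference tables
#'
#' Simulates a large null-effect adolescent population under the same
#' marginal component model and tabulates mean and SD of each standardized
#' component (waist, averaged SBP, HDL, triglycerides, HOMA-IR) by sex and
#' closed-open 1-year age bin; SBP is additionally stratified by height bin.
#'
#' @param config a [sim_config()]; uses `config$n_reference`.
#' @return data frame (component, sex, age_lo, age_hi, height_lo,
#'   height_hi, mean, sd).
#' @export
simulate_reference_tables <- function(config) {
  set.seed(config$seed + 3L)
  n <- config$n_reference
  sex <- rep(c("male", "female"), length.out = n)
  age <- stats::runif(n, 11, 17)
  height <- draw_height(sex, age)
  mu <- component_means(sex, age, height)
  nsd <- config$mets_noise_sd
  sbp_lat <- mu$sbp + stats::rnorm(n, 0, nsd[["sbp"]])
  sbp_avg <- rowMeans(sapply(1:5, function(k) sbp_lat + stats::rnorm(n, 0, 3)))
  vals <- data.frame(
    waist = mu$waist + stats::rnorm(n, 0, nsd[["waist"]]),
    sbp = sbp_avg,
    hdl = pmax(mu$hdl + stats::rnorm(n, 0, nsd[["hdl"]]), 15),
    tg = pmax(mu$tg + stats::rnorm(n, 0, nsd[["tg"]]), 20),
    homa = homa_ir(pmax(mu$glucose + stats::rnorm(n, 0, nsd[["glucose"]]), 50),
                   pmax(mu$insulin + stats::rnorm(n, 0, nsd[["insulin"]]), 1))
  )
  age_breaks <- 11:17
  height_breaks <- c(-Inf, 150, 160, Inf)
  rows <- list()
  for (comp in names(vals)) {
    for (s in c("male", "female")) {
      for (b in seq_len(length(age_breaks) - 1L)) {
        in_bin <- sex == s & age >= age_breaks[b] & age < age_breaks[b + 1L]
        if (comp == "sbp") {
          for (hb in seq_len(length(height_breaks) - 1L)) {
            i <- in_bin & height >= height_breaks[hb] &
              height < height_breaks[hb + 1L]
            rows[[length(rows) + 1L]] <- data.frame(
              component = comp, sex = s,
              age_lo = age_breaks[b], age_hi = age_breaks[b + 1L],
              height_lo = height_breaks[hb], height_hi = height_breaks[hb + 1L],
              mean = mean(vals[[comp]][i]), sd = stats::sd(vals[[comp]][i]),
              stringsAsFactors = FALSE)
          }
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            component = comp, sex = s,
            age_lo = age_breaks[b], age_hi = age_breaks[b + 1L],
            height_lo = -Inf, height_hi = Inf,
            mean = mean(vals[[comp]][in_bin]),
            sd = stats::sd(vals[[comp]][in_bin]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

simulate_covariates <- function(config, truth, age_years) {
  set.seed(config$seed + 4L)
  n <- nrow(truth)
  race <- sample(c("white", "black", "hispanic", "asian", "other"), n,
                 replace = TRUE, prob = c(0.64, 0.14, 0.09, 0.07, 0.06))
  puberty <- pmin(pmax(round(stats::rnorm(n, 2.6, 0.7) * 5) / 5, 1), 4)
  educ <- stats::rbinom(n, 1, 0.7)
  bmi_pre <- pmin(pmax(stats::rnorm(n, 24.6, 5), 15), 45)
  smoking <- sample(c("never", "former", "during"), n, replace = TRUE,
                    prob = c(0.70, 0.20, 0.10))
  miss <- function(x) {
    if (config$covariate_missing_rate > 0) {
      x[stats::runif(n) < config$covariate_missing_rate] <- NA
    }
    x
  }
  data.frame(subject_id = truth$subject_id, sex = truth$sex,
             age_years = age_years, race_ethnicity = race,
             puberty_score = miss(puberty),
             maternal_college = miss(educ),
             prepreg_bmi = miss(bmi_pre),
             smoking_preg = miss(smoking),
             stringsAsFactors = FALSE)
}

#' Simulate a complete cohort
#'
#' Runs [simulate_trajectories()], [simulate_metabolome()] and
#' [simulate_outcomes_and_references()] and bundles the result with its
#' ground truth.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort` with elements `anthropometry`,
#'   `abundance`, `meta`, `components`, `reference`, `covariates`, and
#'   `truth` (milestones, module labels, factors, effect map, config).
#' @export
simulate_cohort <- function(config = sim_config()) {
  tr <- simulate_trajectories(config)
  met <- simulate_metabolome(config, tr$truth)
  out <- simulate_outcomes_and_references(config, tr$truth, met$factors)
  structure(list(
    anthropometry = tr$anthropometry,
    abundance = met$abundance,
    meta = met$meta,
    components = out$components,
    reference = out$reference,
    covariates = out$covariates,
    truth = list(milestones = tr$truth,
                 module_labels = met$module_labels,
                 factors = met$factors,
                 effect_map = config$effect_map,
                 config = config)
  ), class = "sim_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits the CSV tables (`anthropometry.csv`, `metabolites.csv`,
#' `metabolite_meta.csv`, `mets_components.csv`, `reference_tables.csv`,
#' `covariates.csv`) plus `ground_truth.json`; the tables round-trip
#' losslessly through [read_cohort()].
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @param overwrite allow overwriting existing files.
#' @return invisibly, the file paths written.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("anthropometry.csv", "metabolites.csv",
                            "metabolite_meta.csv", "mets_components.csv",
                            "reference_tables.csv", "covariates.csv",
                            "ground_truth.json"))
  exists <- file.exists(paths)
  stop_if(any(exists) && !overwrite,
          sprintf("refusing to overwrite: %s",
                  paste(basename(paths[exists]), collapse = ", ")))
  wr <- function(df, p) utils::write.csv(df, p, row.names = FALSE)
  wr(cohort$anthropometry, paths[1])
  ab <- data.frame(sample_id = rownames(cohort$abundance),
                   cohort$abundance, check.names = FALSE,
                   stringsAsFactors = FALSE)
  wr(ab, paths[2])
  wr(cohort$meta, paths[3])
  wr(cohort$components, paths[4])
  wr(cohort$reference, paths[5])
  wr(cohort$covariates, paths[6])
  truth <- cohort$truth
  gt <- list(milestones = truth$milestones,
             module_labels = as.list(truth$module_labels),
             effect_map = truth$effect_map,
             seed = truth$config$seed)
  jsonlite::write_json(gt, paths[7], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(paths)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing the cohort CSV files.
#' @return list with the same tabular elements as a `sim_cohort` (ground
#'   truth is reloaded from `ground_truth.json` when present).
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), check.names = FALSE,
                                    stringsAsFactors = FALSE)
  ab <- rd("metabolites.csv")
  m <- as.matrix(ab[, -1, drop = FALSE])
  rownames(m) <- ab$sample_id
  out <- list(anthropometry = rd("anthropometry.csv"),
              abundance = m,
              meta = rd("metabolite_meta.csv"),
              components = rd("mets_components.csv"),
              reference = rd("reference_tables.csv"),
              covariates = rd("covariates.csv"))
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    gt$module_labels <- unlist(gt$module_labels)
    out$truth <- gt
  }
  out
}

#' Simulate one screen-level replicate
#'
#' Generates data at the interface of the three-step screen directly:
#' within-sex standardized milestone exposures, per-stratum module
#' eigengene score matrices, composite and component MetS z-scores, and
#' covariates, with an optional planted exposure -> eigengene ->
#' composite path in one stratum. The fitted screen models coincide with
#' the generating model, so confidence-interval coverage of the planted
#' coefficients is a well-defined property; milestone and eigengene
#' estimation error are assessed separately against the full generator.
#'
#' @param n_per_sex subjects per sex.
#' @param n_me number of module eigengenes.
#' @param exposure planted milestone exposure name.
#' @param me planted eigengene name (e.g. "ME2").
#' @param beta_exposure_me planted step-2 coefficient (ME per SD of
#'   exposure); 0 for a global-null replicate.
#' @param beta_me_mets planted step-3 coefficient (MetS z per ME unit).
#' @param stratum sex stratum carrying the planted path.
#' @param mets_resid_sd residual SD of the composite around the planted
#'   path.
#' @param seed integer seed.
#' @return list with `scaled`, `eigengenes`, `mets_z`, `covariates`.
#' @export
simulate_screen_replicate <- function(n_per_sex = 250, n_me = 13,
                                      exposure = "t_r", me = "ME2",
                                      beta_exposure_me = 0.35,
                                      beta_me_mets = 1.0,
                                      stratum = "male",
                                      mets_resid_sd = 0.6,
                                      seed = 1L) {
  set.seed(as.integer(seed))
  n <- 2L * n_per_sex
  sex <- rep(c("male", "female"), each = n_per_sex)
  ids <- sprintf("S%04d", seq_len(n))
  expo <- c("t_p", "B_p", "t_r", "B_r")
  scaled <- data.frame(subject_id = ids, sex = sex,
                       stringsAsFactors = FALSE)
  for (e in expo) scaled[[e]] <- stats::rnorm(n)
  scaled$peak_identified <- TRUE
  scaled$rebound_identified <- TRUE

  me_names <- paste0("ME", seq_len(n_me))
  eig <- list()
  mets <- stats::rnorm(n)
  for (s in c("male", "female")) {
    i <- sex == s
    m <- matrix(stats::rnorm(sum(i) * n_me), sum(i), n_me,
                dimnames = list(ids[i], me_names))
    if (s == stratum && beta_exposure_me != 0)
      m[, me] <- beta_exposure_me * scaled[[exposure]][i] + m[, me]
    if (s == stratum && beta_me_mets != 0)
      mets[i] <- beta_me_mets * m[, me] +
        stats::rnorm(sum(i), 0, mets_resid_sd)
    eig[[s]] <- m
  }
  mets_z <- data.frame(subject_id = ids,
                       z_waist = stats::rnorm(n), z_sbp = stats::rnorm(n),
                       z_hdl = stats::rnorm(n), z_tg = stats::rnorm(n),
                       z_homa = stats::rnorm(n), mets_z = mets,
                       stringsAsFactors = FALSE)
  covariates <- data.frame(
    subject_id = ids, sex = sex,
    age_years = stats::rnorm(n, 12.9, 0.7),
    race_ethnicity = sample(c("white", "black", "hispanic", "asian",
                              "other"), n, replace = TRUE,
                            prob = c(0.64, 0.14, 0.09, 0.07, 0.06)),
    puberty_score = pmin(pmax(round(stats::rnorm(n, 2.6, 0.7) * 5) / 5, 1), 4),
    maternal_college = stats::rbinom(n, 1, 0.7),
    prepreg_bmi = stats::rnorm(n, 24.6, 5),
    smoking_preg = sample(c("never", "former", "during"), n, replace = TRUE,
                          prob = c(0.7, 0.2, 0.1)),
    stringsAsFactors = FALSE)
  list(scaled = scaled, eigengenes = eig, mets_z = mets_z,
       covariates = covariates)
}
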