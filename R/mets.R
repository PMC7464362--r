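## Metabolic syndrome z-score: component z-scores against external
## sex/age(/height)-stratified reference tables and their five-component
## average (HDL reversed).

#' Homeostatic model assessment of insulin resistance
#'
#' `HOMA-IR = glucose (mg/dL) x insulin (uIU/mL) / 405`.
#'
#' @param glucose fasting glucose, mg/dL (> 0).
#' @param insulin fasting insulin, uIU/mL (> 0).
#' @return numeric vector.
#' @export
homa_ir <- function(glucose, insulin) {
  stop_if(any(glucose <= 0, na.rm = TRUE) || any(insulin <= 0, na.rm = TRUE),
          "glucose and insulin must be positive")
  glucose * insulin / 405
}

#' Average systolic blood pressure readings
#'
#' Arithmetic mean of the available readings; fewer than five readings are
#' allowed with a logged warning, at least one is required.
#'
#' @param readings numeric vector of SBP readings (mmHg), or a matrix with
#'   one row per subject.
#' @return mean SBP per subject.
#' @export
average_sbp <- function(readings) {
  if (is.matrix(readings) || is.data.frame(readings)) {
    readings <- as.matrix(readings)
    n_ok <- rowSums(!is.na(readings))
    stop_if(any(n_ok == 0), "subject with no SBP readings")
    if (any(n_ok < 5))
      log_msg("averaging fewer than 5 SBP readings for %d subject(s)",
              sum(n_ok < 5))
    return(rowMeans(readings, na.rm = TRUE))
  }
  readings <- readings[!is.na(readings)]
  stop_if(length(readings) == 0, "no SBP readings")
  if (length(readings) < 5)
    log_msg("averaging %d SBP readings (expected 5)", length(readings))
  mean(readings)
}

## resolve a reference stratum: sex, closed-open age bin, and height bin
## when the component's table carries one
lookup_reference <- function(reference, component, sex, age, height = NA) {
  r <- reference[reference$component == component & reference$sex == sex, ,
                 drop = FALSE]
  hit <- r$age_lo <= age & age < r$age_hi
  if (any(is.finite(r$height_lo)) || any(is.finite(r$height_hi))) {
    hit <- hit & r$height_lo <= height & height < r$height_hi
  }
  stop_if(sum(hit) == 0,
          sprintf("no reference bin for component `%s` (sex %s, age %.2f, height %.1f)",
                  component, sex, age, height))
  stop_if(sum(hit) > 1,
          sprintf("overlapping reference bins for component `%s`", component))
  r[hit, c("mean", "sd"), drop = FALSE]
}

#' Externally standardize a component value
#'
#' `z = (value - stratum mean) / stratum SD`, the stratum resolved by sex,
#' closed-open age bin, and (when the component's table has one) height
#' bin.
#'
#' @param value component values.
#' @param component component name as used in the reference table.
#' @param sex,age,height per-subject stratification keys (height only used
#'   when the table is height-stratified).
#' @param reference reference table (component, sex, age_lo, age_hi,
#'   height_lo, height_hi, mean, sd).
#' @return z-scores.
#' @export
externally_standardize <- function(value, component, sex, age,
                                   reference, height = rep(NA_real_, length(value))) {
  assert_columns(reference,
                 c("component", "sex", "age_lo", "age_hi", "mean", "sd"),
                 "reference")
  if (!("height_lo" %in% names(reference))) {
    reference$height_lo <- -Inf
    reference$height_hi <- Inf
  }
  stop_if(any(reference$sd <= 0), "reference SDs must be positive")
  vapply(seq_along(value), function(i) {
    ms <- lookup_reference(reference, component, sex[i], age[i], height[i])
    (value[i] - ms$mean) / ms$sd
  }, numeric(1))
}

#' Composite MetS z-score from the five component z-scores
#'
#' Average of the waist, SBP, reversed HDL, triglyceride, and HOMA-IR
#' z-scores: `(z_waist + z_sbp - z_hdl + z_tg + z_homa) / 5`.
#'
#' @param z_waist,z_sbp,z_hdl,z_tg,z_homa component z-scores; all five must
#'   be present (subjects with missing components are excluded upstream).
#' @return composite score vector.
#' @export
composite_mets_z <- function(z_waist, z_sbp, z_hdl, z_tg, z_homa) {
  zs <- cbind(z_waist, z_sbp, z_hdl, z_tg, z_homa)
  stop_if(anyNA(zs), "all five component z-scores are required")
  (z_waist + z_sbp - z_hdl + z_tg + z_homa) / 5
}

#' Compute component and composite MetS z-scores for a cohort
#'
#' Derives HOMA-IR and averaged SBP from the raw component table,
#' standardizes each of the five components against the reference tables,
#' and averages (HDL reversed).
#'
#' @param components table with subject_id, sex, age_years, height, waist,
#'   sbp1..sbp5, hdl, tg, glucose, insulin.
#' @param reference reference table as in [externally_standardize()].
#' @return data frame (subject_id, z_waist, z_sbp, z_hdl, z_tg, z_homa,
#'   mets_z).
#' @export
compute_mets_z <- function(components, reference) {
  assert_columns(components,
                 c("subject_id", "sex", "age_years", "height", "waist",
                   paste0("sbp", 1:5), "hdl", "tg", "glucose", "insulin"),
                 "components")
  sbp <- average_sbp(components[, paste0("sbp", 1:5)])
  homa <- homa_ir(components$glucose, components$insulin)
  std <- function(v, comp, height = rep(NA_real_, nrow(components)))
    externally_standardize(v, comp, components$sex, components$age_years,
                           reference, height)
  z <- data.frame(
    subject_id = components$subject_id,
    z_waist = std(components$waist, "waist"),
    z_sbp = std(sbp, "sbp", components$height),
    z_hdl = std(components$hdl, "hdl"),
    z_tg = std(components$tg, "tg"),
    z_homa = std(homa, "homa"),
    stringsAsFactors = FALSE
  )
  z$mets_z <- composite_mets_z(z$z_waist, z$z_sbp, z$z_hdl, z$z_tg, z$z_homa)
  z
}
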