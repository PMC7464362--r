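## Metabolomics preprocessing: endogenous filter, half-minimum imputation,
## log10 transform, Pareto scaling. The pipeline order is fixed and a
## processed flag refuses re-application.

#' Keep only endogenous metabolites
#'
#' @param abundance samples x metabolites matrix (NA = below detection).
#' @param meta metabolite metadata with `metabolite_id` and logical
#'   `endogenous` covering every column.
#' @return list with filtered `abundance` and `meta`.
#' @export
filter_endogenous <- function(abundance, meta) {
  assert_columns(meta, c("metabolite_id", "endogenous"), "meta")
  missing <- setdiff(colnames(abundance), meta$metabolite_id)
  stop_if(length(missing) > 0,
          sprintf("metadata missing for metabolite(s): %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  flag <- meta$endogenous[match(colnames(abundance), meta$metabolite_id)]
  stop_if(any(is.na(flag)), "endogenous flag missing for some metabolites")
  keep <- colnames(abundance)[flag]
  stop_if(length(keep) == 0, "no endogenous metabolites: empty matrix")
  log_msg("endogenous filter: %d of %d metabolites retained",
          length(keep), ncol(abundance))
  list(abundance = abundance[, keep, drop = FALSE],
       meta = meta[meta$metabolite_id %in% keep, , drop = FALSE])
}

#' Half-minimum imputation
#'
#' Per metabolite, missing entries are replaced by half the minimum
#' detected value of that metabolite across all samples; detected values
#' are unchanged.
#'
#' @param abundance samples x metabolites matrix with NAs.
#' @return imputed matrix (no NAs).
#' @export
impute_half_min <- function(abundance) {
  stop_if(!is.matrix(abundance), "`abundance` must be a matrix")
  all_na <- colSums(!is.na(abundance)) == 0
  stop_if(any(all_na),
          sprintf("metabolite(s) with no detected values: %s",
                  paste(colnames(abundance)[all_na], collapse = ", ")))
  mins <- apply(abundance, 2, min, na.rm = TRUE)
  na_idx <- which(is.na(abundance), arr.ind = TRUE)
  if (nrow(na_idx) > 0)
    abundance[na_idx] <- 0.5 * mins[na_idx[, "col"]]
  abundance
}

#' log10 transform and Pareto scaling
#'
#' Per metabolite: x -> log10(x), then centering and division by the
#' square root of the sample SD (n - 1 denominator) of the logged column.
#' Output columns have mean 0 and variance equal to the logged column's SD,
#' damping the leverage of high-variance compounds.
#'
#' @param abundance strictly positive matrix (post-imputation).
#' @return transformed matrix carrying a `preprocessed` attribute; a second
#'   application is refused.
#' @export
log_pareto_transform <- function(abundance) {
  stop_if(isTRUE(attr(abundance, "preprocessed")),
          "matrix is already log/Pareto transformed; refusing to re-apply")
  stop_if(any(abundance <= 0), "all abundances must be positive before log10")
  lg <- log10(abundance)
  mu <- colMeans(lg)
  sdv <- apply(lg, 2, stats::sd)
  zero_var <- sdv == 0 | !is.finite(sdv)
  stop_if(any(zero_var),
          sprintf("zero-variance metabolite(s) after log: %s",
                  paste(colnames(abundance)[zero_var], collapse = ", ")))
  out <- sweep(sweep(lg, 2, mu, "-"), 2, sqrt(sdv), "/")
  attr(out, "preprocessed") <- TRUE
  out
}

#' Full preprocessing pipeline
#'
#' Fixed order: endogenous filter, half-minimum imputation, log10,
#' Pareto scaling.
#'
#' @param abundance samples x metabolites raw matrix (NA = censored).
#' @param meta metabolite metadata.
#' @return list with `matrix` (processed), `meta` (filtered), and `report`
#'   (counts and imputation tallies).
#' @export
preprocess_metabolites <- function(abundance, meta) {
  filt <- filter_endogenous(abundance, meta)
  n_missing <- sum(is.na(filt$abundance))
  imp <- impute_half_min(filt$abundance)
  proc <- log_pareto_transform(imp)
  report <- list(
    n_input_metabolites = ncol(abundance),
    n_endogenous = ncol(filt$abundance),
    n_samples = nrow(abundance),
    n_imputed_values = n_missing,
    imputed_per_metabolite = colSums(is.na(filt$abundance))
  )
  list(matrix = proc, meta = filt$meta, report = report)
}
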