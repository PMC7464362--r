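## End-to-end orchestration: simulate (or read) a cohort, estimate
## milestones, preprocess the metabolome, build consensus networks, score
## metabolic risk, run the three-step screen, and write the tables plus a
## manifest. Deterministic given the same configuration and seed.

#' Pipeline configuration
#'
#' Exactly one of `input_dir` (a directory of cohort CSV files as written
#' by [write_cohort()]) or `simulate` (a [sim_config()]) must be given.
#'
#' @param input_dir directory of input tables, or NULL.
#' @param simulate a [sim_config()], or NULL.
#' @param spline a [spline_config()].
#' @param network a [network_config()].
#' @param q FDR level for the step-2 screen.
#' @param alpha nominal significance level.
#' @param seed integer seed (overrides the simulate block's seed).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, simulate = sim_config(),
                            spline = spline_config(),
                            network = network_config(),
                            q = 0.05, alpha = 0.05, seed = 1L) {
  stop_if(!xor(is.null(input_dir), is.null(simulate)),
          "exactly one of `input_dir` or `simulate` must be given")
  assert_scalar_number(q, "q", 0, 1)
  stop_if(q == 0, "`q` must be in (0, 1)")
  if (!is.null(simulate)) simulate$seed <- as.integer(seed)
  structure(list(input_dir = input_dir, simulate = simulate,
                 spline = spline, network = network, q = q, alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the full meet-in-the-middle pipeline
#'
#' Stages: simulate or read the cohort; milestone estimation; metabolomics
#' preprocessing; consensus network construction; MetS z-scoring; the
#' three-step association screen; table rendering. All tabular outputs,
#' a JSON manifest (seed, config hash, stage row counts) and the rendered
#' report are written under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param overwrite allow overwriting an existing output directory.
#' @return invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite)
    stop("output directory is non-empty; use overwrite = TRUE", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulate)) {
    log_msg("stage simulate: generating synthetic cohort (seed %d)",
            config$seed)
    cohort <- simulate_cohort(config$simulate)
  } else {
    log_msg("stage read: loading cohort from %s", config$input_dir)
    cohort <- read_cohort(config$input_dir)
  }
  counts <- list(n_subjects = length(unique(cohort$anthropometry$subject_id)),
                 n_metabolites_raw = ncol(cohort$abundance))

  log_msg("stage milestones: %d anthropometry rows", nrow(cohort$anthropometry))
  mil <- estimate_milestones(cohort$anthropometry, config$spline)
  counts$n_eligible <- nrow(mil$milestones)

  log_msg("stage preprocess")
  prep <- preprocess_metabolites(cohort$abundance, cohort$meta)
  counts$n_endogenous <- ncol(prep$matrix)

  log_msg("stage network")
  strata <- stats::setNames(cohort$covariates$sex, cohort$covariates$subject_id)
  net <- consensus_network(prep$matrix, strata, config$network)
  counts$n_outlier_samples <- length(net$outliers)
  counts$n_modules <- net$k

  log_msg("stage mets")
  metsz <- compute_mets_z(cohort$components, cohort$reference)

  log_msg("stage associate")
  screen <- run_screen(mil$scaled, net$eigengenes, metsz, cohort$covariates,
                       q = config$q, alpha = config$alpha)

  ## outputs
  utils::write.csv(mil$milestones, file.path(out_dir, "milestones.csv"),
                   row.names = FALSE)
  utils::write.csv(mil$sds, file.path(out_dir, "milestone_sds.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(metabolite_id = names(net$labels),
                              module = unname(net$labels)),
                   file.path(out_dir, "modules.csv"), row.names = FALSE)
  for (s in names(net$eigengenes)) {
    me <- net$eigengenes[[s]]$me
    utils::write.csv(data.frame(sample_id = rownames(me), me,
                                check.names = FALSE),
                     file.path(out_dir, sprintf("eigengenes_%s.csv", s)),
                     row.names = FALSE)
    km <- net$eigengenes[[s]]$kme
    utils::write.csv(data.frame(metabolite_id = rownames(km), km,
                                check.names = FALSE),
                     file.path(out_dir, sprintf("kme_%s.csv", s)),
                     row.names = FALSE)
  }
  utils::write.csv(metsz, file.path(out_dir, "mets_z.csv"), row.names = FALSE)
  write_tsv(screen$step1, file.path(out_dir, "step1.tsv"))
  write_tsv(screen$step2, file.path(out_dir, "step2.tsv"))
  write_tsv(screen$step3$tiers, file.path(out_dir, "step3.tsv"))
  write_tsv(screen$step3$components, file.path(out_dir, "components.tsv"))
  write_tsv(screen$sensitivity, file.path(out_dir, "sensitivity.tsv"))
  report <- membership_report(net$eigengenes, net$labels, prep$meta,
                              config$network)
  write_tsv(report, file.path(out_dir, "membership_report.tsv"))
  jsonlite::write_json(
    list(outliers = net$outliers,
         variance_explained = lapply(net$eigengenes, `[[`, "var_explained")),
    file.path(out_dir, "network_qc.json"), auto_unbox = TRUE, digits = NA)

  render_tables(screen, report, out_dir)

  ## manifest: seed + config hash + flow counts; identical config + seed
  ## reproduce identical hashes
  cfg_file <- file.path(out_dir, "config_dump.txt")
  dput_out <- utils::capture.output(dput(unclass_config(config)))
  writeLines(dput_out, cfg_file)
  manifest <- list(seed = config$seed,
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   counts = counts,
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, milestones = mil, preprocess = prep,
                 network = net, mets_z = metsz, screen = screen,
                 report = report, manifest = manifest))
}

## strip closures/environments so the config dump is hashable text
unclass_config <- function(config) {
  rapply(unclass(config), function(x) x, how = "replace",
         classes = c("numeric", "integer", "character", "logical",
                     "data.frame"))
}

fmt_ci <- function(b, lo, hi) sprintf("%.3f (%.3f, %.3f)", b, lo, hi)

#' Render human-readable result tables
#'
#' Writes a markdown report mirroring the published table shapes:
#' milestones vs MetS z, milestones vs eigengenes with FDR asterisks,
#' tiered eigengene vs MetS z models, component follow-up, and the top-10
#' kME listing per module.
#'
#' @param screen output of [run_screen()].
#' @param report output of [membership_report()].
#' @param out_dir directory for `report.md`.
#' @return invisibly, the path written.
#' @export
render_tables <- function(screen, report, out_dir) {
  lines <- c("# Meet-in-the-middle screen report", "")
  md_table <- function(df) {
    if (nrow(df) == 0) return("(empty)")
    hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    body <- apply(df, 1, function(r)
      paste0("| ", paste(r, collapse = " | "), " |"))
    c(hdr, sep, body)
  }
  s1 <- screen$step1
  s1_disp <- data.frame(stratum = s1$stratum, exposure = s1$exposure,
                        tier = s1$tier,
                        `beta (95% CI)` = fmt_ci(s1$beta, s1$ci_lo, s1$ci_hi),
                        p = signif(s1$p, 3), n = s1$n,
                        carried = ifelse(s1$carried, "yes", ""),
                        check.names = FALSE)
  lines <- c(lines, "## Step 1: growth milestones vs MetS z-score", "",
             md_table(s1_disp), "")
  s2 <- screen$step2
  if (nrow(s2) > 0) {
    s2_disp <- data.frame(stratum = s2$stratum, exposure = s2$exposure,
                          network = paste0(s2$outcome,
                                           ifelse(s2$fdr_flag, " *", "")),
                          `beta (95% CI)` = fmt_ci(s2$beta, s2$ci_lo, s2$ci_hi),
                          p = signif(s2$p, 3), n = s2$n, check.names = FALSE)
    lines <- c(lines,
               "## Step 2: carried milestones vs network scores (* = FDR-significant)",
               "", md_table(s2_disp), "")
  } else {
    lines <- c(lines, "## Step 2", "", "no milestones carried forward", "")
  }
  s3 <- screen$step3$tiers
  lines <- c(lines, "## Step 3: carried networks vs MetS z-score", "")
  if (nrow(s3) > 0) {
    s3_disp <- data.frame(stratum = s3$stratum, network = s3$exposure,
                          tier = s3$tier,
                          `beta (95% CI)` = fmt_ci(s3$beta, s3$ci_lo, s3$ci_hi),
                          p = signif(s3$p, 3), n = s3$n, check.names = FALSE)
    lines <- c(lines, md_table(s3_disp), "")
  } else {
    lines <- c(lines, "no networks carried forward", "")
  }
  cm <- screen$step3$components
  if (nrow(cm) > 0) {
    cm_disp <- data.frame(stratum = cm$stratum, network = cm$exposure,
                          component = cm$outcome,
                          `beta (95% CI)` = fmt_ci(cm$beta, cm$ci_lo, cm$ci_hi),
                          p = signif(cm$p, 3), check.names = FALSE)
    lines <- c(lines, "## Component follow-up (Model 1, uncorrected)", "",
               md_table(cm_disp), "")
  }
  top <- report[report$top10, , drop = FALSE]
  if (nrow(top) > 0) {
    top_disp <- data.frame(stratum = top$stratum, module = top$module,
                           rank = top$rank, metabolite = top$name,
                           super_pathway = top$super_pathway,
                           kME = round(top$kme, 3))
    lines <- c(lines, "## Top-10 network membership (kME) per module", "",
               md_table(top_disp), "")
  }
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
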