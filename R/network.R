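## Consensus weighted correlation network analysis, implemented from
## scratch: signed soft-threshold adjacency on Spearman correlations,
## topological overlap, quantile-calibrated consensus dissimilarity across
## sex strata, average-linkage clustering with a recursive dynamic tree
## cut, first-singular-vector module eigengenes, kME membership, and
## connectivity-based outlier-sample detection.

#' Network configuration
#'
#' @param power soft-threshold exponent applied to the signed correlation.
#' @param min_module_size smallest admissible module.
#' @param cut_height_quantile static cut height as a quantile of the
#'   dendrogram merge heights.
#' @param tightness a branch is accepted as a module when its median
#'   within-branch dissimilarity is at most `tightness` times the static
#'   cut height; branches that never tighten dissolve into label 0.
#' @param calibration_quantile TOM quantile matched across strata before
#'   the element-wise minimum.
#' @param calibrate logical; disable to take the raw element-wise minimum.
#' @param outlier_z standardized-connectivity threshold below which a
#'   sample is flagged as an outlier.
#' @param kme_threshold absolute kME above which a metabolite is reported
#'   as a member in the membership report.
#' @return list of class `network_config`.
#' @export
network_config <- function(power = 10, min_module_size = 20,
                           cut_height_quantile = 0.99, tightness = 0.99,
                           calibration_quantile = 0.95, calibrate = TRUE,
                           outlier_z = -2.5, kme_threshold = 0.6) {
  assert_scalar_number(power, "power", 1)
  assert_scalar_number(min_module_size, "min_module_size", 2)
  assert_scalar_number(cut_height_quantile, "cut_height_quantile", 0, 1)
  assert_scalar_number(calibration_quantile, "calibration_quantile", 0, 1)
  structure(list(power = power,
                 min_module_size = as.integer(min_module_size),
                 cut_height_quantile = cut_height_quantile,
                 tightness = tightness,
                 calibration_quantile = calibration_quantile,
                 calibrate = isTRUE(calibrate),
                 outlier_z = outlier_z,
                 kme_threshold = kme_threshold),
            class = "network_config")
}

#' Detect outlier samples by standardized connectivity
#'
#' Builds the sample-sample correlation network (squared Pearson
#' correlation, so a sample decoupled from the shared covariance structure
#' has low connectivity regardless of sign), computes each sample's
#' connectivity, and flags samples whose standardized connectivity falls
#' below the threshold. Flagged samples should be removed before network
#' construction.
#'
#' @param x samples x metabolites numeric matrix (preprocessed).
#' @param threshold standardized connectivity cutoff (default -2.5).
#' @return list with `flagged` (sample names), `z` (named vector).
#' @export
detect_outlier_samples <- function(x, threshold = -2.5) {
  stop_if(nrow(x) < 10, "fewer than 10 samples: connectivity Z is unstable")
  a <- stats::cor(t(x))^2
  diag(a) <- 0
  k <- rowSums(a)
  z <- (k - mean(k)) / stats::sd(k)
  flagged <- rownames(x)[z < threshold]
  if (length(flagged) > 0)
    log_msg("outlier samples flagged (Z < %g): %s", threshold,
            paste(flagged, collapse = ", "))
  list(flagged = flagged, z = z)
}

#' Spearman correlation matrix
#'
#' Rank correlation with average ranks for ties.
#'
#' @param x samples x metabolites matrix; no missing values.
#' @return symmetric correlation matrix, unit diagonal.
#' @export
correlation_matrix <- function(x) {
  stop_if(nrow(x) < 3, "need at least 3 samples")
  stop_if(anyNA(x), "missing values present; preprocess first")
  sds <- apply(x, 2, stats::sd)
  stop_if(any(sds == 0),
          sprintf("constant column(s): %s",
                  paste(colnames(x)[sds == 0], collapse = ", ")))
  rho <- stats::cor(x, method = "spearman")
  rho[rho > 1] <- 1; rho[rho < -1] <- -1
  rho
}

#' Signed soft-threshold adjacency
#'
#' `a_ij = ((1 + rho_ij) / 2)^power` off the diagonal; unit diagonal. The
#' signed map keeps strongly negatively correlated pairs unconnected.
#'
#' @param rho correlation matrix.
#' @param power soft-threshold exponent.
#' @return adjacency matrix in `[0, 1]`.
#' @export
signed_adjacency <- function(rho, power = 10) {
  stop_if(!isSymmetric(unname(rho), tol = 1e-10), "`rho` must be symmetric")
  a <- ((1 + rho) / 2)^power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over `u != i, j` and `k_i = sum_u a_iu` over
#' `u != i`; unit diagonal. Computed with matrix products.
#'
#' @param a adjacency matrix (unit diagonal, values in `[0, 1]`).
#' @return TOM, same dimension, values in `[0, 1]`, unit diagonal.
#' @export
topological_overlap <- function(a) {
  a0 <- a
  diag(a0) <- 0
  l <- a0 %*% a0
  k <- rowSums(a0)
  kmin <- outer(k, k, pmin)
  w <- (l + a0) / (kmin + 1 - a0)
  diag(w) <- 1
  dimnames(w) <- dimnames(a)
  w
}

#' Consensus dissimilarity across strata
#'
#' Optionally calibrates each stratum's TOM so its `calibration_quantile`
#' (off-diagonal) matches the across-strata mean of that quantile, takes
#' the element-wise minimum, and returns `1 - consensus TOM`.
#'
#' @param tom_list named list of TOM matrices with identical metabolite
#'   sets (at least 2 strata).
#' @param config a [network_config()].
#' @return consensus dissimilarity matrix (zero diagonal).
#' @export
consensus_dissimilarity <- function(tom_list, config = network_config()) {
  stop_if(length(tom_list) < 2, "need at least 2 strata")
  nm <- colnames(tom_list[[1]])
  for (tm in tom_list)
    stop_if(!identical(colnames(tm), nm),
            "metabolite sets differ across strata")
  if (config$calibrate) {
    q <- vapply(tom_list, function(tm)
      stats::quantile(tm[upper.tri(tm)], config$calibration_quantile,
                      names = FALSE), numeric(1))
    ref <- mean(q)
    tom_list <- Map(function(tm, qs) pmin(tm * (ref / qs), 1), tom_list, q)
  }
  cons <- Reduce(pmin, tom_list)
  d <- 1 - cons
  diag(d) <- 0
  d
}

## Recursive "tree" dynamic cut over an hclust object. A branch becomes a
## module when it is big enough and tight (median internal dissimilarity
## below tightness * static cut height); otherwise it splits at its top
## merge and the children are examined, with members of never-tight small
## branches left unassigned (label 0).
dynamic_tree_cut <- function(hc, d, min_size, cut_quantile, tightness) {
  n <- length(hc$order)
  h_star <- stats::quantile(hc$height, cut_quantile, names = FALSE)
  labels <- integer(n)

  members_of <- function(node) {
    ## node > 0: merge index; node < 0: singleton -node
    if (node < 0) return(-node)
    c(members_of(hc$merge[node, 1]), members_of(hc$merge[node, 2]))
  }
  is_tight <- function(mem) {
    dd <- d[mem, mem]
    stats::median(dd[upper.tri(dd)]) <= tightness * h_star
  }
  ## drop loosely attached members (stragglers merged high into a tight
  ## branch): keep members whose median dissimilarity to the rest of the
  ## branch passes the same tightness rule
  prune_stragglers <- function(mem) {
    med <- vapply(seq_along(mem), function(i)
      stats::median(d[mem[i], mem[-i]]), numeric(1))
    mem[med <= tightness * h_star]
  }
  clusters <- list()
  descend <- function(node) {
    mem <- members_of(node)
    if (length(mem) < min_size) return(invisible(NULL))
    if (length(mem) >= 2 && is_tight(mem)) {
      core <- prune_stragglers(mem)
      if (length(core) >= min_size)
        clusters[[length(clusters) + 1L]] <<- core
      return(invisible(NULL))
    }
    if (node < 0) return(invisible(NULL))
    descend(hc$merge[node, 1])
    descend(hc$merge[node, 2])
    invisible(NULL)
  }
  descend(nrow(hc$merge))
  if (length(clusters) > 0) {
    ord <- order(vapply(clusters, length, integer(1)), decreasing = TRUE)
    for (i in seq_along(ord)) labels[clusters[[ord[i]]]] <- i
  }
  labels
}

#' Detect modules by hierarchical clustering and dynamic tree cut
#'
#' Average-linkage hierarchical clustering on the dissimilarity followed by
#' a recursive branch decomposition of the dendrogram: branches of at least
#' `min_module_size` members whose median internal dissimilarity is below
#' `tightness` times the static cut height become modules; everything else
#' is unassigned (label 0). Labels are contiguous `1..k` in decreasing
#' module size.
#'
#' @param d dissimilarity matrix (zero diagonal).
#' @param config a [network_config()].
#' @return list with `labels` (named integer vector, 0 = unassigned),
#'   `k` module count, `hclust` the dendrogram.
#' @export
detect_modules <- function(d, config = network_config()) {
  stop_if(any(abs(diag(d)) > 1e-12), "`d` must have a zero diagonal")
  n <- ncol(d)
  if (n < config$min_module_size) {
    labels <- stats::setNames(integer(n), colnames(d))
    return(list(labels = labels, k = 0L, hclust = NULL))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  labels <- dynamic_tree_cut(hc, d, config$min_module_size,
                             config$cut_height_quantile, config$tightness)
  names(labels) <- colnames(d)
  list(labels = labels, k = max(labels), hclust = hc)
}

#' Module eigengenes, variance explained, and kME
#'
#' Per stratum and module, the eigengene is the first left-singular vector
#' of the column-standardized sample x member submatrix (equivalently the
#' first right-singular vector of the metabolite x sample profile),
#' rescaled to z-scores across samples and sign-oriented so the mean
#' correlation with member metabolites is positive. Variance explained is
#' the first squared singular value over the total; kME is the correlation
#' of every metabolite with every eigengene.
#'
#' @param x_list named list (one entry per stratum) of preprocessed
#'   sample x metabolite matrices.
#' @param labels module assignment (named integer vector; 0 excluded).
#' @return list per stratum with `me` (sample x module score matrix),
#'   `var_explained`, and `kme` (metabolite x module).
#' @export
eigengene_scores <- function(x_list, labels) {
  mods <- sort(unique(labels[labels > 0]))
  stop_if(length(mods) == 0, "no assigned modules")
  lapply(x_list, function(x) {
    xs <- scale(x)
    me <- matrix(NA_real_, nrow(x), length(mods),
                 dimnames = list(rownames(x), paste0("ME", mods)))
    ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
    for (i in seq_along(mods)) {
      mem <- names(labels)[labels == mods[i]]
      sub <- xs[, mem, drop = FALSE]
      sv <- svd(sub, nu = 1, nv = 0)
      score <- sv$u[, 1]
      score <- (score - mean(score)) / stats::sd(score)
      if (mean(stats::cor(sub, score)) < 0) score <- -score
      me[, i] <- score
      ve[i] <- sv$d[1]^2 / sum(sv$d^2)
    }
    kme <- stats::cor(xs, me)
    list(me = me, var_explained = ve, kme = kme)
  })
}

#' Module membership report
#'
#' Per module and stratum, ranks metabolites by own-module kME and returns
#' the top-`top_n` listing plus every metabolite with
#' `|kME| > kme_threshold`, with pathway metadata attached.
#'
#' @param eig output of [eigengene_scores()].
#' @param labels module assignment.
#' @param meta metabolite metadata.
#' @param config a [network_config()] (threshold).
#' @param top_n listing length per module.
#' @return data frame (stratum, module, metabolite_id, name,
#'   super_pathway, sub_pathway, kme, rank, top10, above_threshold).
#' @export
membership_report <- function(eig, labels, meta,
                              config = network_config(), top_n = 10) {
  rows <- list()
  for (s in names(eig)) {
    kme <- eig[[s]]$kme
    for (m in colnames(kme)) {
      mod <- as.integer(sub("^ME", "", m))
      mem <- names(labels)[labels == mod]
      km <- kme[mem, m]
      ord <- order(km, decreasing = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, module = m,
        metabolite_id = mem[ord],
        kme = km[ord],
        rank = seq_along(ord),
        top10 = seq_along(ord) <= top_n,
        above_threshold = abs(km[ord]) > config$kme_threshold,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  idx <- match(out$metabolite_id, meta$metabolite_id)
  out$name <- meta$name[idx]
  out$super_pathway <- meta$super_pathway[idx]
  out$sub_pathway <- meta$sub_pathway[idx]
  rownames(out) <- NULL
  out[out$top10 | out$above_threshold, , drop = FALSE]
}

#' Full consensus network construction
#'
#' Outlier-sample removal, per-stratum Spearman correlation, signed
#' adjacency, TOM, consensus dissimilarity, module detection, and
#' eigengene/kME scoring.
#'
#' @param x preprocessed sample x metabolite matrix.
#' @param strata named character vector (sample -> stratum), e.g. sex.
#' @param config a [network_config()].
#' @return list with `labels`, `k`, `eigengenes` (per stratum),
#'   `outliers`, `hclust`, `consensus_d`.
#' @export
consensus_network <- function(x, strata, config = network_config()) {
  stop_if(is.null(names(strata)) || !all(rownames(x) %in% names(strata)),
          "`strata` must be a named vector covering all samples")
  out <- detect_outlier_samples(x, config$outlier_z)
  keep <- setdiff(rownames(x), out$flagged)
  x <- x[keep, , drop = FALSE]
  strata <- strata[keep]
  x_list <- lapply(split(names(strata), strata),
                   function(ids) x[ids, , drop = FALSE])
  toms <- lapply(x_list, function(xs)
    topological_overlap(signed_adjacency(correlation_matrix(xs),
                                         config$power)))
  d <- consensus_dissimilarity(toms, config)
  mods <- detect_modules(d, config)
  eig <- if (mods$k > 0) eigengene_scores(x_list, mods$labels) else NULL
  list(labels = mods$labels, k = mods$k, eigengenes = eig,
       outliers = out$flagged, hclust = mods$hclust, consensus_d = d)
}
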