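test_that("signed adjacency matches closed forms", {
  rho <- matrix(c(1, -1, 0, -1, 1, 0.5, 0, 0.5, 1), 3)
  a <- signed_adjacency(rho, power = 10)
  expect_equal(a[1, 2], 0)
  expect_equal(a[1, 3], 2^-10)
  expect_equal(a[2, 3], 0.75^10)
  expect_equal(diag(a), rep(1, 3))
  rho1 <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(signed_adjacency(rho1, 10)[1, 2], 1)
})

test_that("Spearman correlation uses average ranks for ties", {
  x <- cbind(a = c(1, 2, 2, 4), b = c(10, 30, 20, 40))
  rho <- correlation_matrix(x)
  # rank-then-Pearson by hand: ranks a = 1, 2.5, 2.5, 4; b = 1, 3, 2, 4
  expect_equal(rho[1, 2], cor(c(1, 2.5, 2.5, 4), c(1, 3, 2, 4)))
  mono <- cbind(a = 1:5, b = exp(1:5))
  expect_equal(correlation_matrix(mono)[1, 2], 1)
  rev <- cbind(a = 1:5, b = -(1:5)^3)
  expect_equal(correlation_matrix(rev)[1, 2], -1)
  expect_error(correlation_matrix(cbind(a = rep(1, 5), b = 1:5)), "constant")
})

test_that("TOM matches hand computations and the n = 2 closed form", {
  a2 <- matrix(c(1, 0.37, 0.37, 1), 2)
  expect_equal(topological_overlap(a2)[1, 2], 0.37)
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 1
  w <- topological_overlap(a3)
  expect_equal(w[upper.tri(w)], rep(0.5, 3))
  expect_equal(diag(w), rep(1, 3))
})

test_that("matrix-product TOM equals the brute-force triple loop", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    a <- random_adjacency(n)
    expect_lt(max(abs(topological_overlap(a) - tom_brute_force(a))), 1e-10)
  }
})

test_that("adjacency and TOM are symmetric with entries in [0, 1]", {
  set.seed(22)
  x <- matrix(rnorm(300), 30, 10, dimnames = list(NULL, paste0("m", 1:10)))
  a <- signed_adjacency(correlation_matrix(x), 10)
  w <- topological_overlap(a)
  for (m in list(a, w)) {
    expect_true(isSymmetric(unname(m), tol = 1e-12))
    expect_true(all(m >= 0 & m <= 1 + 1e-12))
  }
  d <- 1 - w; diag(d) <- 0
  expect_true(all(diag(d) == 0))
})

test_that("consensus of identical strata equals either input", {
  set.seed(23)
  x <- matrix(rnorm(600), 60, 10, dimnames = list(NULL, paste0("m", 1:10)))
  tom <- topological_overlap(signed_adjacency(correlation_matrix(x), 10))
  cfg_off <- network_config(calibrate = FALSE)
  d <- consensus_dissimilarity(list(a = tom, b = tom), cfg_off)
  expect_equal(unname(d), unname(1 - tom) - diag(0, nrow(tom)),
               tolerance = 1e-15, ignore_attr = TRUE)
  # calibration on with identical strata is still exact
  d2 <- consensus_dissimilarity(list(a = tom, b = tom), network_config())
  expect_equal(d, d2)
})

test_that("consensus without calibration is the element-wise minimum", {
  t1 <- matrix(c(1, 0.3, 0.3, 1), 2, dimnames = list(c("a","b"), c("a","b")))
  t2 <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a","b"), c("a","b")))
  d <- consensus_dissimilarity(list(t1, t2), network_config(calibrate = FALSE))
  expect_equal(d["a", "b"], 1 - 0.3)
  t3 <- t2; dimnames(t3) <- list(c("a","c"), c("a","c"))
  expect_error(consensus_dissimilarity(list(t1, t3), network_config()),
               "differ")
})

test_that("planted blocks are recovered and labels ordered by size", {
  set.seed(24)
  pl <- planted_blocks(200, c(40, 30, 20), 0.8, n_background = 15)
  tom <- topological_overlap(signed_adjacency(correlation_matrix(pl$x), 10))
  d <- 1 - tom; diag(d) <- 0
  mods <- detect_modules(d, network_config())
  expect_gte(ari(mods$labels[pl$labels > 0], pl$labels[pl$labels > 0]), 0.9)
  sizes <- table(mods$labels[mods$labels > 0])
  expect_true(all(diff(as.integer(sizes)) <= 0))
  expect_true(all(sizes >= 20))
})

test_that("a block below the minimum size is left unassigned", {
  set.seed(25)
  pl <- planted_blocks(150, c(30, 10), 0.85, n_background = 40)
  tom <- topological_overlap(signed_adjacency(correlation_matrix(pl$x), 10))
  d <- 1 - tom; diag(d) <- 0
  mods <- detect_modules(d, network_config(min_module_size = 20))
  small_block <- names(pl$labels)[pl$labels == 2]
  expect_true(all(mods$labels[small_block] == 0))
  expect_true(all(mods$labels[names(pl$labels)[pl$labels == 1]] > 0))
})

test_that("pure noise leaves most metabolites unassigned", {
  set.seed(26)
  frac0 <- replicate(5, {
    x <- matrix(rnorm(200 * 120), 200, 120,
                dimnames = list(NULL, sprintf("m%03d", 1:120)))
    tom <- topological_overlap(signed_adjacency(correlation_matrix(x), 10))
    d <- 1 - tom; diag(d) <- 0
    mean(detect_modules(d, network_config())$labels == 0)
  })
  expect_gte(mean(frac0), 0.8)
})

test_that("module labels are permutation-equivariant", {
  set.seed(27)
  pl <- planted_blocks(150, c(30, 25), 0.8, n_background = 10)
  tom <- topological_overlap(signed_adjacency(correlation_matrix(pl$x), 10))
  d <- 1 - tom; diag(d) <- 0
  mods <- detect_modules(d, network_config())
  perm <- sample(ncol(d))
  mods_p <- detect_modules(d[perm, perm], network_config())
  expect_equal(mods_p$labels, mods$labels[perm])
})

test_that("eigengene matches the power-iteration oracle and rank-1 contracts", {
  set.seed(28)
  pl <- planted_blocks(100, c(25), 0.8)
  labels <- pl$labels
  eig <- eigengene_scores(list(all = pl$x), labels)$all
  oracle <- power_iteration_score(pl$x[, labels == 1])
  expect_gt(abs(cor(eig$me[, "ME1"], oracle)), 1 - 1e-8)

  # rank-1 module: two identical columns
  set.seed(29)
  v <- rnorm(50)
  x <- cbind(a = v, b = v)
  rownames(x) <- paste0("s", 1:50)
  eig1 <- eigengene_scores(list(all = x), c(a = 1L, b = 1L))$all
  expect_equal(unname(eig1$var_explained), 1.0)
  expect_equal(unname(eig1$kme[, "ME1"]), c(1, 1), tolerance = 1e-12)
  expect_equal(cor(eig1$me[, 1], v), 1, tolerance = 1e-12)
})

test_that("eigengene recovers a planted factor and kME ranks follow loadings", {
  set.seed(30)
  n <- 500
  f <- rnorm(n)
  loadings <- seq(0.9, 0.5, length.out = 20)
  x <- sapply(loadings, function(l) l * f + sqrt(1 - l^2) * rnorm(n))
  colnames(x) <- sprintf("m%02d", 1:20)
  rownames(x) <- sprintf("s%03d", 1:n)
  labels <- setNames(rep(1L, 20), colnames(x))
  eig <- eigengene_scores(list(all = x), labels)$all
  expect_gte(abs(cor(eig$me[, 1], f)), 0.95)
  # sign orientation: mean own-module kME positive
  expect_gt(mean(eig$kme[, 1]), 0)
  # kME ordering tracks the planted loading ordering
  expect_gt(cor(eig$kme[, 1], loadings, method = "spearman"), 0.9)
})

test_that("membership report applies threshold and top-10 rules", {
  set.seed(31)
  pl <- planted_blocks(300, c(25, 25), 0.75, n_background = 5)
  labels <- pl$labels
  eig <- eigengene_scores(list(all = pl$x), labels)
  meta <- data.frame(metabolite_id = colnames(pl$x), name = colnames(pl$x),
                     super_pathway = "Lipid", sub_pathway = "x")
  rep_tab <- membership_report(eig, labels, meta, network_config())
  expect_true(all(rep_tab$above_threshold == (abs(rep_tab$kme) > 0.6)))
  for (m in unique(rep_tab$module)) {
    km <- rep_tab$kme[rep_tab$module == m & rep_tab$stratum == "all"]
    expect_true(all(diff(km) <= 0))
    expect_lte(sum(rep_tab$top10[rep_tab$module == m]), 10)
  }
})

test_that("outlier samples are flagged by low standardized connectivity", {
  set.seed(32)
  pl <- planted_blocks(60, rep(25, 8), 0.8, n_background = 20)
  x <- pl$x
  # corrupt one sample: independently permute its values
  x[5, ] <- sample(x[5, ])
  out <- detect_outlier_samples(x, threshold = -2.5)
  expect_true(rownames(x)[5] %in% out$flagged)
  expect_error(detect_outlier_samples(x[1:5, ]), "fewer than 10")
  # threshold -Inf flags nothing
  expect_length(detect_outlier_samples(x, threshold = -Inf)$flagged, 0)
})

test_that("null outlier false-flag rate is low", {
  set.seed(33)
  flags <- replicate(40, {
    x <- matrix(rnorm(40 * 60), 40, 60,
                dimnames = list(sprintf("s%02d", 1:40), NULL))
    length(detect_outlier_samples(x, threshold = -2.5)$flagged)
  })
  expect_lt(mean(flags) / 40, 0.02)
})

test_that("consensus on identically-structured strata matches single-stratum recovery", {
  set.seed(34)
  n <- 200
  sizes <- c(30, 30, 30)
  make_stratum <- function() planted_blocks(n, sizes, 0.8, n_background = 20)
  a <- make_stratum(); b <- make_stratum()
  cfg <- network_config()
  tom_a <- topological_overlap(signed_adjacency(correlation_matrix(a$x), 10))
  tom_b <- topological_overlap(signed_adjacency(correlation_matrix(b$x), 10))
  d_cons <- consensus_dissimilarity(list(a = tom_a, b = tom_b), cfg)
  d_single <- 1 - tom_a; diag(d_single) <- 0
  ari_cons <- ari(detect_modules(d_cons, cfg)$labels, a$labels)
  ari_single <- ari(detect_modules(d_single, cfg)$labels, a$labels)
  expect_gte(ari_cons, 0.9)
  expect_lt(abs(ari_cons - ari_single), 0.05)
})
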