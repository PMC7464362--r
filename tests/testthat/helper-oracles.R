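## Independent oracles used across tests. These deliberately use naive
## formulations (triple loops, exhaustive definitions, power iteration) so
## they stay independent of the package implementations they check.

options(mimnet.quiet = TRUE)

## brute-force topological overlap by triple loop
tom_brute_force <- function(a) {
  n <- nrow(a)
  w <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      ki <- sum(a[i, -i])
      kj <- sum(a[j, -j])
      w[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  w
}

## random symmetric adjacency with unit diagonal
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

## exhaustive Benjamini-Hochberg: reject the k smallest p-values where
## k = max { i : p_(i) <= i q / m }
bh_exhaustive <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  flags <- logical(m)
  if (k > 0) flags[o[seq_len(k)]] <- TRUE
  flags
}

## first principal score of a centered matrix by power iteration on the
## member covariance
power_iteration_score <- function(x, iters = 500) {
  xs <- scale(x)
  cc <- crossprod(xs) / (nrow(xs) - 1)
  v <- rep(1, ncol(cc))
  for (i in seq_len(iters)) {
    v <- cc %*% v
    v <- v / sqrt(sum(v^2))
  }
  drop(xs %*% v)
}

## adjusted Rand index between two label vectors (Hubert & Arabie)
ari <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  (nij - expected) / ((ai + bj) / 2 - expected)
}

## planted block-correlated data: samples x (sum(sizes) + background)
planted_blocks <- function(n, sizes, loading, n_background = 0) {
  p <- sum(sizes) + n_background
  x <- matrix(stats::rnorm(n * p), n, p)
  labels <- integer(p)
  col <- 1L
  for (m in seq_along(sizes)) {
    f <- stats::rnorm(n)
    for (j in seq_len(sizes[m])) {
      x[, col] <- loading * f + sqrt(1 - loading^2) * x[, col]
      labels[col] <- m
      col <- col + 1L
    }
  }
  colnames(x) <- sprintf("met%03d", seq_len(p))
  rownames(x) <- sprintf("s%03d", seq_len(n))
  names(labels) <- colnames(x)
  list(x = x, labels = labels)
}
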