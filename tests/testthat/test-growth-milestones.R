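## One shared model fit keeps the expensive REML step out of every block.
make_fit_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 1)
      tr <- simulate_trajectories(cfg)
      est <- estimate_milestones(tr$anthropometry)
      cache <<- list(cfg = cfg, tr = tr, est = est)
    }
    cache
  }
})

test_that("eligibility requires three measurements through mid-childhood", {
  anthro <- data.frame(
    subject_id = c("a", "a", "b", "b", "b", "c", "c", "c", "c"),
    sex = "male",
    age_months = c(1, 12, 1, 12, 60, 1, 12, 60, 150),
    bmi = 16)
  out <- eligibility_filter(anthro)
  expect_setequal(out$kept, c("b", "c"))   # c has 3 in range, the 150-mo
  expect_identical(out$dropped, "a")       # visit does not count
  expect_error(eligibility_filter(anthro[0, ]), "empty")
})

test_that("eligibility counts on a mixed table match a direct oracle", {
  set.seed(11)
  n_per <- c(2, 2, 2, 2, 5, 6, 7, 8, 9, 10)  # 4 subjects below threshold
  anthro <- do.call(rbind, lapply(seq_along(n_per), function(i)
    data.frame(subject_id = sprintf("s%02d", i), sex = "female",
               age_months = sort(runif(n_per[i], 0, 120)), bmi = 16)))
  out <- eligibility_filter(anthro)
  expect_length(out$kept, 6)
  expect_length(out$dropped, 4)
})

test_that("noiseless in-family data are interpolated exactly", {
  # generate curves inside the model family: population spline + per-subject
  # coefficient offsets, both sexes
  basis <- ns_basis()
  set.seed(12)
  ages <- c(0.5, 2, 4, 6, 9, 12, 18, 30, 48, 66, 90, 114)
  subj <- expand.grid(id = sprintf("s%02d", 1:20), age = ages)
  subj$sex <- ifelse(as.integer(sub("s", "", subj$id)) <= 10, "male", "female")
  coefs <- lapply(1:20, function(i) list(b0 = 16 + rnorm(1, 0, 0.5),
                                         bb = rnorm(basis$df, 0, 0.3)))
  pop <- rnorm(basis$df, 0, 1)
  N <- ns_eval(basis, subj$age)
  subj$bmi <- vapply(seq_len(nrow(subj)), function(r) {
    i <- as.integer(sub("s", "", subj$id[r]))
    coefs[[i]]$b0 + sum(N[r, ] * (pop + coefs[[i]]$bb)) +
      0.5 * (subj$sex[r] == "male")
  }, numeric(1))
  anthro <- data.frame(subject_id = as.character(subj$id), sex = subj$sex,
                       age_months = subj$age, bmi = subj$bmi)
  fit <- fit_growth_model(anthro)
  for (id in c("s01", "s15")) {
    rows <- anthro[anthro$subject_id == id, ]
    pred <- predict_subject_curve(fit, id, rows$age_months)
    expect_lt(max(abs(pred$bmi - rows$bmi)), 1e-6)
  }
})

test_that("analytic derivative agrees with finite differences", {
  cache <- make_fit_cache()
  fit <- cache$est$fit
  g <- seq(1, 120, length.out = 200)
  pred <- predict_subject_curve(fit, "S0001", g)
  h <- 1e-4
  fd <- (predict_subject_curve(fit, "S0001", g + h)$bmi -
           predict_subject_curve(fit, "S0001", g - h)$bmi) / (2 * h)
  expect_lt(max(abs(fd - pred$deriv)), 1e-6)
  expect_error(predict_subject_curve(fit, "nobody", g), "unknown subject")
  expect_error(predict_subject_curve(fit, "S0001", 135), "boundary")
})

test_that("single-sex input with interactions requested errors", {
  anthro <- data.frame(subject_id = rep(c("a", "b"), each = 4), sex = "male",
                       age_months = rep(c(1, 6, 12, 24), 2), bmi = 16)
  expect_error(fit_growth_model(anthro), "both sexes")
})

test_that("milestone extraction finds planted analytic stationary points", {
  # fabricate a growth_fit whose subject curve is known analytically by
  # projecting a parabola-like target onto the basis via least squares on a
  # fine grid, then check the extractor's bisection against the projection
  basis <- ns_basis()
  g <- seq(0.3, 129, by = 0.1)
  target <- 17 - 0.01 * (g - 8)^2   # peak at 8 mo, magnitude 17
  X <- cbind(1, ns_eval(basis, g))
  beta <- qr.solve(X, target)
  fitted_fun <- function(t) drop(cbind(1, ns_eval(basis, t)) %*% beta)
  dfun <- function(t) drop(ns_eval(basis, t, deriv = 1) %*% beta[-1])
  roots <- mimnet:::derivative_roots(dfun, c(1, 16))
  expect_length(roots, 1)
  expect_equal(roots[[1]]$direction, "max")
  # the extractor finds the projected curve's own maximum, to grid/bisection
  # tolerance (the projection overshoots the parabola's 17.0 slightly)
  expect_lt(abs(roots[[1]]$root - g[which.max(fitted_fun(g))]), 0.1)
  expect_equal(fitted_fun(roots[[1]]$root), max(fitted_fun(g)),
               tolerance = 1e-6)
  expect_equal(fitted_fun(roots[[1]]$root), 17, tolerance = 0.05)
})

test_that("monotone curves yield unidentified flags, not errors", {
  dfun_up <- function(t) rep(0.01, length(t))
  expect_length(mimnet:::derivative_roots(dfun_up, c(24, 110)), 0)
})

test_that("milestones are recovered on the default synthetic cohort", {
  cache <- make_fit_cache()
  m <- merge(cache$est$milestones, cache$tr$truth,
             by = c("subject_id", "sex"), suffixes = c("_est", "_true"))
  okp <- m$peak_identified; okr <- m$rebound_identified
  expect_gt(mean(okp), 0.9)
  expect_gt(mean(okr), 0.9)
  expect_lt(abs(mean((m$t_p_est - m$t_p_true)[okp])), 0.5)
  expect_lt(abs(mean((m$t_r_est - m$t_r_true)[okr])), 3)
  expect_lt(sqrt(mean(((m$B_p_est - m$B_p_true)[okp])^2)), 0.3)
  expect_lt(sqrt(mean(((m$B_r_est - m$B_r_true)[okr])^2)), 0.3)
  # when both milestones are identified the peak is at least the rebound
  both <- okp & okr
  expect_true(all(m$B_p_est[both] >= m$B_r_est[both]))
})

test_that("row order does not change milestone estimates", {
  cfg <- sim_config(n_per_sex = 25, seed = 13)
  tr <- simulate_trajectories(cfg)
  est1 <- estimate_milestones(tr$anthropometry)
  set.seed(14)
  shuffled <- tr$anthropometry[sample(nrow(tr$anthropometry)), ]
  est2 <- estimate_milestones(shuffled)
  m1 <- est1$milestones[order(est1$milestones$subject_id), ]
  m2 <- est2$milestones[order(est2$milestones$subject_id), ]
  rownames(m1) <- rownames(m2) <- NULL
  expect_equal(m1, m2, tolerance = 1e-8)
})

test_that("exposure standardization divides by within-sex SDs", {
  cache <- make_fit_cache()
  std <- standardize_exposures(cache$est$milestones)
  for (s in c("male", "female")) {
    for (e in c("t_p", "B_p", "t_r", "B_r")) {
      x <- std$scaled[[e]][std$scaled$sex == s]
      expect_equal(sd(x, na.rm = TRUE), 1, tolerance = 1e-12)
      expect_equal(std$sds[[e]][std$sds$sex == s],
                   sd(cache$est$milestones[[e]][cache$est$milestones$sex == s],
                      na.rm = TRUE))
    }
  }
  const <- data.frame(subject_id = c("a", "b", "c"), sex = "male",
                      t_p = 8, B_p = 18, t_r = 60, B_r = 16)
  expect_error(standardize_exposures(const), "zero SD")
})
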