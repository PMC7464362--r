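test_that("OLS recovers a noiseless linear relation exactly", {
  d <- data.frame(y = 2 * (1:20), x = 1:20)
  # a perfect fit makes summary.lm warn; the estimates are still exact
  r <- suppressWarnings(fit_linear_association(d, "y", "x"))
  expect_equal(r$beta, 2.0, tolerance = 1e-12)
  expect_lt(r$ci_hi - r$ci_lo, 1e-8)
  expect_equal(r$n, 20)
  expect_error(fit_linear_association(data.frame(y = rep(1, 20), x = 1:20),
                                      "y", "x"), "constant outcome")
  d$x2 <- d$x
  expect_error(fit_linear_association(d, "y", "x", "x2"), "aliased")
  expect_error(fit_linear_association(d, "y", "x", "x"), "covariate")
})

test_that("confidence intervals attain nominal coverage", {
  set.seed(41)
  hits <- replicate(500, {
    x <- rnorm(250)
    y <- 0.5 * x + rnorm(250)
    r <- fit_linear_association(data.frame(y = y, x = x), "y", "x")
    r$ci_lo <= 0.5 && 0.5 <= r$ci_hi
  })
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("BH flags match the hand-evaluated step-up rule", {
  expect_identical(bh_fdr(c(0.001, 0.004, 0.03, 0.1, 0.9), 0.05),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_identical(bh_fdr(rep(1, 6), 0.05), rep(FALSE, 6))
  expect_identical(bh_fdr(numeric(0), 0.05), logical(0))
})

test_that("BH equals the exhaustive step-up definition", {
  set.seed(42)
  for (i in 1:200) {
    m <- sample(1:8, 1)
    p <- round(runif(m), 3)
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    expect_identical(bh_fdr(p, q), bh_exhaustive(p, q))
  }
  # order invariance on permutations of one fixed vector
  p <- c(0.01, 0.02, 0.04, 0.2, 0.5, 0.9)
  for (i in 1:20) {
    perm <- sample(6)
    expect_identical(bh_fdr(p[perm], 0.05), bh_exhaustive(p, 0.05)[perm])
  }
})

test_that("step 1 has the published table shape and carries planted signals", {
  rep1 <- simulate_screen_replicate(n_per_sex = 250, beta_exposure_me = 0.35,
                                    beta_me_mets = 1.0, seed = 43)
  s1 <- run_step1(rep1$scaled, rep1$mets_z, rep1$covariates)
  expect_equal(nrow(s1), 16)   # 4 exposures x 2 sexes x 2 tiers
  expect_setequal(unique(s1$tier), c("unadjusted", "adjusted"))
  expect_true(all(s1$ci_lo <= s1$beta & s1$beta <= s1$ci_hi))
  expect_true(all(s1$carried[s1$stratum == "male" & s1$exposure == "t_r"]))
})

test_that("the planted path is carried through steps 2 and 3", {
  rep1 <- simulate_screen_replicate(n_per_sex = 250, beta_exposure_me = 0.35,
                                    beta_me_mets = 1.0, seed = 44)
  s1 <- run_step1(rep1$scaled, rep1$mets_z, rep1$covariates)
  s2 <- run_step2(s1, rep1$scaled, rep1$eigengenes, rep1$covariates)
  hit <- s2[s2$stratum == "male" & s2$exposure == "t_r" &
              s2$outcome == "ME2", ]
  expect_true(hit$fdr_flag)
  s3 <- run_step3(s2, rep1$eigengenes, rep1$mets_z, rep1$covariates,
                  rep1$scaled)
  expect_setequal(unique(s3$tiers$tier), c("unadjusted", "M1", "M2", "M3"))
  m1 <- s3$tiers[s3$tiers$tier == "M1" & s3$tiers$exposure == "ME2" &
                   s3$tiers$stratum == "male", ]
  expect_true(m1$ci_lo <= 1.0 && 1.0 <= m1$ci_hi)
  # component follow-up: five components per Model-1-significant network
  expect_equal(sort(unique(s3$components$outcome)),
               sort(c("z_waist", "z_sbp", "z_hdl", "z_tg", "z_homa")))
})

test_that("an empty carried set produces empty step-3 tables, not errors", {
  rep0 <- simulate_screen_replicate(n_per_sex = 60, beta_exposure_me = 0,
                                    beta_me_mets = 0, seed = 45)
  s2_empty <- run_step2(data.frame(stratum = "male", exposure = "t_r",
                                   carried = FALSE),
                        rep0$scaled, rep0$eigengenes, rep0$covariates)
  expect_equal(nrow(s2_empty), 0)
  s3 <- run_step3(s2_empty, rep0$eigengenes, rep0$mets_z, rep0$covariates,
                  rep0$scaled)
  expect_equal(nrow(s3$tiers), 0)
  expect_equal(nrow(s3$components), 0)
})

test_that("null data flag milestones at roughly the nominal rate", {
  set.seed(46)
  flags <- vapply(1:60, function(i) {
    rep0 <- simulate_screen_replicate(n_per_sex = 100, beta_exposure_me = 0,
                                      beta_me_mets = 0, seed = 1000 + i)
    s1 <- run_step1(rep0$scaled, rep0$mets_z, rep0$covariates)
    mean(s1$carried[s1$tier == "adjusted"])
  }, numeric(1))
  expect_lt(abs(mean(flags) - 0.05), 0.03)
})

test_that("complete-case n shrinks monotonically across covariate tiers", {
  rep1 <- simulate_screen_replicate(n_per_sex = 250, beta_exposure_me = 0.5,
                                    beta_me_mets = 1.0, seed = 47)
  # plant covariate missingness that accumulates across tiers
  set.seed(48)
  rep1$covariates$puberty_score[sample(500, 5)] <- NA
  rep1$covariates$prepreg_bmi[sample(500, 5)] <- NA
  s1 <- run_step1(rep1$scaled, rep1$mets_z, rep1$covariates)
  s2 <- run_step2(s1, rep1$scaled, rep1$eigengenes, rep1$covariates)
  s3 <- run_step3(s2, rep1$eigengenes, rep1$mets_z, rep1$covariates,
                  rep1$scaled)
  for (m in unique(s3$tiers$exposure)) {
    ns <- s3$tiers$n[s3$tiers$exposure == m]
    expect_true(all(diff(ns) <= 0))  # unadjusted >= M1 >= M2 >= M3
  }
})

test_that("mutual adjustment leaves independent exposures nearly unchanged", {
  rep1 <- simulate_screen_replicate(n_per_sex = 500, beta_exposure_me = 0.5,
                                    beta_me_mets = 1.0, seed = 49)
  s1 <- run_step1(rep1$scaled, rep1$mets_z, rep1$covariates)
  s2 <- run_step2(s1, rep1$scaled, rep1$eigengenes, rep1$covariates)
  hit <- s2[s2$stratum == "male" & s2$exposure == "t_r" &
              s2$outcome == "ME2", ]
  sens <- sensitivity_mutual_adjustment(hit, rep1$scaled, rep1$eigengenes,
                                        rep1$covariates)
  expect_identical(sens$sibling, "B_r")
  expect_lt(abs(sens$pct_change), 10)
  # collinear sibling errors
  rep1$scaled$B_r <- rep1$scaled$t_r
  expect_error(sensitivity_mutual_adjustment(hit, rep1$scaled,
                                             rep1$eigengenes,
                                             rep1$covariates), "collinear")
})
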