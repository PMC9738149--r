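# Regression battery: design construction, OLS, wild bootstrap, FDR,
# GA adjustment, K-S, moment and t tests.

make_records <- function(n = 40, seed = 1) {
  with(list(), {
    set.seed(seed)
    data.frame(
      ga_weeks = runif(n, 27, 42),
      chd = rbinom(n, 1, 0.4),
      obesity = rbinom(n, 1, 0.5),
      any_mrf = rbinom(n, 1, 0.5)
    )
  })
}

test_that("build_design shapes, interaction column, degeneracy", {
  r <- make_records(10)
  d <- build_design(r, "any_mrf")
  expect_identical(dim(d$X), c(10L, 3L))
  expect_true(all(d$X[, 1] == 1))
  expect_identical(d$target, "any_mrf")

  di <- build_design(r, "any_mrf", include_interaction = TRUE)
  expect_identical(dim(di$X), c(10L, 5L))
  expect_equal(di$X[, 5], di$X[, 3] * di$X[, 4])
  expect_identical(di$target, "any_mrf:chd")

  r0 <- r; r0$chd <- 0
  expect_error(build_design(r0, "any_mrf", include_interaction = TRUE),
               class = "boldvar_degenerate_design")
  r1 <- r; r1$any_mrf <- 1
  expect_error(build_design(r1, "any_mrf"),
               class = "boldvar_degenerate_design")
})

test_that("ols_fit: exact fit, null sampling bound, algebraic oracle", {
  r <- make_records(50, seed = 2)
  d <- build_design(r, "any_mrf")
  y <- 2 + 0.3 * r$ga_weeks  # exactly linear in GA
  fit <- ols_fit(d, y)
  expect_equal(unname(fit$coefficients["ga"]), 0.3, tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-10)

  set.seed(3)
  y2 <- 5 + rnorm(50, 0, 1)
  fit2 <- ols_fit(d, y2)
  se <- 1 / sqrt(50 * var(r$any_mrf))  # crude SE bound for the predictor
  expect_lt(abs(fit2$coefficients["any_mrf"]), 3 * se * 2)

  set.seed(4)
  X <- cbind(1, matrix(rnorm(50 * 3), 50, 3))
  colnames(X) <- c("intercept", "a", "b", "c")
  y3 <- rnorm(50)
  fit3 <- ols_fit(X, y3)
  expect_equal(unname(fit3$coefficients), unname(drop(naive_ols(X, y3))),
               tolerance = 1e-8)
  expect_lt(max(abs(t(X) %*% fit3$residuals)), 1e-8)
})

test_that("wild bootstrap closed form equals explicit per-replicate refits", {
  r <- make_records(30, seed = 5)
  set.seed(6)
  y <- 1 + 0.05 * r$ga_weeks - 0.4 * r$any_mrf + rnorm(30, 0, 0.5)
  d <- build_design(r, "any_mrf")
  B <- 200L
  res <- wild_bootstrap_p(d, y, n_boot = B, seed = 77L)

  # reproduce the Rademacher draws, refit the full model per replicate
  ti <- match("any_mrf", colnames(d$X))
  fit0 <- ols_fit(d$X[, -ti, drop = FALSE], y)
  V <- boldvar:::with_seed(77L, matrix(sample(c(-1, 1), 30 * B,
                                              replace = TRUE), 30, B))
  bstar <- vapply(seq_len(B), function(b) {
    ystar <- fit0$fitted + fit0$residuals * V[, b]
    unname(ols_fit(d$X, ystar)$coefficients[ti])
  }, numeric(1))
  bhat <- unname(ols_fit(d$X, y)$coefficients[ti])
  expect_equal(res$coefficient, bhat, tolerance = 1e-12)
  expect_equal(res$p_one_sided, (1 + sum(bstar <= bhat)) / (B + 1),
               tolerance = 1e-12)
})

test_that("wild bootstrap p is deterministic, scale-invariant, symmetric", {
  r <- make_records(40, seed = 7)
  set.seed(8)
  y <- 3 + rnorm(40, 0, 1 + r$ga_weeks / 40)
  d <- build_design(r, "any_mrf")
  p1 <- wild_bootstrap_p(d, y, n_boot = 500, seed = 9L)
  p2 <- wild_bootstrap_p(d, y, n_boot = 500, seed = 9L)
  expect_identical(p1$p_one_sided, p2$p_one_sided)

  # rescaling y by c > 0 leaves p unchanged under common random numbers
  p3 <- wild_bootstrap_p(d, 100 * y, n_boot = 500, seed = 9L)
  expect_equal(p3$p_one_sided, p1$p_one_sided)
  # rescaling the GA column likewise
  d2 <- d; d2$X[, "ga"] <- d$X[, "ga"] * 12
  p4 <- wild_bootstrap_p(d2, y, n_boot = 500, seed = 9L)
  expect_equal(p4$p_one_sided, p1$p_one_sided)

  # beta-hat forced to exactly 0: p ~ 0.5 under the symmetric bootstrap
  ti <- match("any_mrf", colnames(d$X))
  bhat <- unname(ols_fit(d$X, y)$coefficients[ti])
  y0 <- y - d$X[, ti] * bhat
  stopifnot(abs(ols_fit(d$X, y0)$coefficients[ti]) < 1e-12)
  p5 <- wild_bootstrap_p(d, y0, n_boot = 2000, seed = 10L)
  expect_gt(p5$p_one_sided, 0.4)
  expect_lt(p5$p_one_sided, 0.6)

  expect_error(wild_bootstrap_p(d, y, n_boot = 50), "n_boot")
})

test_that("strong negative effects give small one-sided p-values", {
  hits <- vapply(1:10, function(s) {
    co <- generate_cohort(cohort_spec(n_subjects = 100L, beta_mrf = -1,
                                      hetero_scale = 0, noise_sd = 0.2,
                                      seed = 100 + s))
    d <- build_design(co, "any_mrf")
    wild_bootstrap_p(d, co$tv_placenta, n_boot = 1000, seed = s)$p_one_sided
  }, numeric(1))
  expect_gte(mean(hits < 0.01), 0.95)
})

test_that("fdr_adjust matches the hand BH example and p.adjust", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_adjust(0.3), 0.3)
  set.seed(11)
  for (rep in 1:10) {
    p <- runif(sample(2:12, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p))
    expect_true(all(which(adj <= 0.05) %in% which(p <= 0.05)))
  }
  expect_error(fdr_adjust(c(0.2, 1.4)), "0, 1")
})

test_that("ga_adjust removes the GA trend and nothing else", {
  set.seed(12)
  ga <- runif(60, 27, 42)
  y <- 4 - 0.2 * ga
  expect_lt(max(abs(ga_adjust(y, ga))), 1e-10)

  y2 <- rnorm(60)
  r <- ga_adjust(y2, ga)
  expect_lt(abs(mean(r)), 1e-10)
  expect_lt(abs(cor(r, ga)), 1e-10)

  expect_warning(r3 <- ga_adjust(y2, rep(30, 60)), "constant")
  expect_equal(r3, y2 - mean(y2))
})

test_that("ks_two_sample: identities and ECDF oracle", {
  set.seed(13)
  a <- rnorm(30)
  expect_equal(ks_two_sample(a, a)$D, 0)
  expect_equal(ks_two_sample(a, a + 100)$D, 1)
  b <- rnorm(25, 0.5)
  expect_equal(ks_two_sample(a, b)$D, naive_ks_D(a, b), tolerance = 1e-12)
  expect_error(ks_two_sample(a[1:3], b), ">= 5")
})

test_that("moment_compare: identical groups, variance power, skewness power", {
  set.seed(14)
  a <- rnorm(50)
  mc <- moment_compare(a, a, n_perm = 200, seed = 1)
  expect_equal(mc$variance$statistic, 1)
  expect_gt(mc$variance$p, 0.99)
  expect_gt(mc$skewness$p, 0.9)

  b <- rnorm(200); c4 <- rnorm(200, sd = 2)  # var ratio 4
  expect_lt(moment_compare(b, c4, n_perm = 200, seed = 2)$variance$p, 0.001)

  # normal vs equally-scaled skewed sample: skewness detected in >= 80%
  hits <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    x <- rnorm(500)
    y <- rexp(500) - 1  # mean 0, var 1, skew 2
    moment_compare(x, y, n_perm = 500, seed = s)$skewness$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  expect_error(moment_compare(rep(1, 10), a),
               class = "boldvar_zero_variance")
})

test_that("welch_t: hand formula and raw/summary equivalence", {
  r <- welch_t(list(mean = 0, sd = 1, n = 50), list(mean = 1, sd = 1, n = 50))
  expect_equal(r$t, -5)  # (0 - 1) / sqrt(1/50 + 1/50)
  expect_lt(r$p, 1e-5)

  same <- welch_t(list(mean = 2, sd = 1, n = 20), list(mean = 2, sd = 1, n = 20))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(15)
  x <- rnorm(30, 1); y <- rnorm(40, 1.3)
  raw <- welch_t(x, y)
  summ <- welch_t(list(mean = mean(x), sd = sd(x), n = 30),
                  list(mean = mean(y), sd = sd(y), n = 40))
  expect_equal(raw$t, summ$t, tolerance = 1e-10)
  expect_equal(raw$p, summ$p, tolerance = 1e-10)
  # agreement with the reference implementation
  expect_equal(raw$t, unname(t.test(x, y)$statistic), tolerance = 1e-10)
})

test_that("mrf_battery reports degenerate cells as errors, not numbers", {
  co <- generate_cohort(cohort_spec(n_subjects = 40L, prev_diabetes = 0,
                                    seed = 16L))
  bat <- mrf_battery(co, metrics = "tv_placenta", n_boot = 200, seed = 1)
  expect_equal(nrow(bat), 8L)  # 4 predictors x 2 effect types
  bad <- bat[bat$predictor == "diabetes", ]
  expect_true(all(is.na(bad$coefficient)))
  expect_true(all(grepl("degenerate", bad$note)))
  good <- bat[bat$predictor == "any_mrf" & bat$effect_type == "main", ]
  expect_false(is.na(good$p_fdr))
})

test_that("group_compare assembles K-S, moment and t results", {
  co <- generate_cohort(cohort_spec(n_subjects = 80L, seed = 17L))
  g <- group_compare(co, "tv_placenta", n_perm = 200, seed = 1)
  expect_equal(g$n_chd + g$n_non_chd, 80L)
  expect_true(g$ks$D >= 0 && g$ks$D <= 1)
  expect_true(g$welch$p >= 0 && g$welch$p <= 1)
  expect_named(g$moments, c("variance", "skewness", "kurtosis"))
})
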