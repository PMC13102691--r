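test_that("constant response yields a constant fit with edf near one", {
  set.seed(1)
  age <- runif(40, 1, 80)
  fit <- fit_gamm(rep(2.5, 40), age, k = 6)
  expect_equal(unname(predict_curve(fit, c(5, 40, 75))), rep(2.5, 3),
               tolerance = 1e-8)
  expect_error(fit_gamm(rnorm(40), age, k = 2), "k must be")
  expect_error(fit_gamm(rnorm(5), runif(5, 1, 9), k = 10), "observations")
})

test_that("a noiseless smooth function of sqrt-age is fitted to high accuracy", {
  set.seed(2)
  age <- sort(runif(150, 0.5, 90))
  # exactly representable: linear in the transformed age (penalty null space)
  fit0 <- fit_gamm(3 * sqrt(age) + 1, age, k = 10)
  expect_lte(sqrt(mean((predict_curve(fit0, age) - (3 * sqrt(age) + 1))^2)), 1e-6)
  # y = age is quadratic in sqrt(age): outside the natural-spline boundary
  # conditions, so accuracy is relative to the signal scale
  y <- age
  fit <- fit_gamm(y, age, k = 10)
  rmse <- sqrt(mean((predict_curve(fit, age) - y)^2))
  expect_lte(rmse / sd(y), 0.005)
})

test_that("planted cohort intercepts are recovered from overlapping cohorts", {
  set.seed(3)
  n <- 600
  age <- runif(n, 1, 80)
  cohort <- sample(c("a", "b"), n, replace = TRUE)
  truth <- c(a = 0.5, b = -0.5)
  y <- sqrt(age) + truth[cohort] + rnorm(n, sd = 0.3)
  fit <- fit_gamm(y, age, groups = list(cohort = cohort), k = 8)
  est <- random_intercepts(fit)$cohort
  expect_equal(unname(est["a"] - est["b"]), 1, tolerance = 0.1)
  expect_equal(unname(est[c("a", "b")]), c(0.5, -0.5), tolerance = 0.05 + 0.05)
})

test_that("density weights balance age bins and cohorts", {
  w <- density_weights(rep(c(1, 50), c(10, 10)), n_bins = 2)
  expect_equal(unname(w), rep(1, 20))
  # two bins with counts n and 2n: per-point weights in ratio 2:1
  ages <- rep(c(1, 50), c(10, 20))
  w2 <- density_weights(ages, n_bins = 2)
  expect_equal(w2[1] / w2[30], 2)
  expect_equal(mean(w2), 1)
  set.seed(4)
  w3 <- density_weights(runif(100, 1, 90), sample(c("x", "y"), 100, TRUE))
  expect_equal(mean(w3), 1)
  expect_true(all(w3 > 0))
})

test_that("harmonization is near-identity for one homoscedastic cohort", {
  set.seed(5)
  age <- runif(250, 1, 80)
  y <- sqrt(age) + rnorm(250, sd = 0.4)
  h <- suppressWarnings(
    harmonize(y, age, individual = sprintf("i%d", 1:250),
              cohort = rep("only", 250)))
  expect_equal(h$mean_adjusted, y)   # no second cohort: mean step no-op
  expect_true(all(h$cohort_scale > 0.9 & h$cohort_scale < 1.1))
  expect_true(all(h$weights > 0))
})

test_that("planted cohort offsets are removed by harmonization", {
  set.seed(6)
  n <- 500
  age <- runif(n, 0.5, 90)
  cohort <- sample(c("a", "b", "c"), n, replace = TRUE)
  offs <- c(a = 0.25, b = 0, c = -0.25)   # +/- 0.5 residual s.d.
  sd0 <- 0.5
  y <- 2 * sqrt(age) + offs[cohort] + rnorm(n, sd = sd0)
  h <- suppressWarnings(harmonize(y, age, sprintf("i%d", 1:n), cohort))
  pop <- predict_curve(h$fit, age)
  res_means <- tapply(h$variance_adjusted - pop, cohort, mean) / sd0
  expect_lt(max(abs(res_means)), 0.05)
})

test_that("the variance model detects planted heteroscedasticity", {
  set.seed(7)
  n <- 600
  age <- runif(n, 5, 95)
  sds <- ifelse(age > 40, sqrt(2) * 0.5, 0.5)   # variance doubles after 40
  y <- sqrt(age) + rnorm(n, sd = sds)
  h <- suppressWarnings(harmonize(y, age, sprintf("i%d", 1:n), rep("c1", n)))
  ratio <- mean(h$vhat[age > 60]) / mean(h$vhat[age < 25])
  expect_gte(ratio, 1.6)
  expect_lte(ratio, 2.4)
})

test_that("harmonization preserves within-cohort rank order", {
  set.seed(8)
  n <- 300
  age <- runif(n, 1, 80)
  cohort <- sample(c("a", "b"), n, replace = TRUE)
  y <- sqrt(age) + c(a = 0.3, b = -0.3)[cohort] + rnorm(n, sd = 0.4)
  h <- suppressWarnings(harmonize(y, age, sprintf("i%d", 1:n), cohort))
  for (cc in c("a", "b")) {
    idx <- cohort == cc
    # residual deviations from the common low-k curve keep their order
    expect_equal(order(h$variance_adjusted[idx] - h$mu_low[idx]),
                 order(y[idx] - h$mu_low[idx]))
  }
})

test_that("the nonlinearity F statistic is non-negative and powerful", {
  set.seed(9)
  age <- runif(60, 1, 90)
  for (s in 1:5) {
    y <- rnorm(60)
    expect_gte(nonlinearity_test(y, age)$F, 0)
  }
  age2 <- runif(400, 1, 90)
  y2 <- sin(age2 / 8) + rnorm(400, sd = 0.2)
  expect_lt(nonlinearity_test(y2, age2)$p_nonlinear, 1e-6)
  expect_error(nonlinearity_test(rep(1, 50), runif(50, 1, 9)), "degenerate")
})

test_that("vertex-wise FDR flags follow the BH rule", {
  res <- tibble::tibble(p_nonlinear = c(0.001, 0.01, 0.03, 0.6, 0.9))
  out <- fdr_across_vertices(res)
  expect_equal(out$q_nonlinear, p.adjust(res$p_nonlinear, "BH"))
  expect_equal(out$significant, out$q_nonlinear < 0.05)
})

test_that("posterior peak age finds a noiseless peak and flags monotone fits", {
  set.seed(10)
  age <- runif(300, 1, 60)
  y <- -(sqrt(age) - sqrt(19))^2          # exact interior peak at 19
  fit <- fit_gamm(y, age, k = 10)
  pk <- peak_age(fit, n_draws = 500, seed = 1)
  # the natural-spline boundary conditions shift a quadratic-in-sqrt(age)
  # peak by a few tenths of a year; half a year bounds basis bias plus grid
  expect_lt(abs(pk$estimate - 19), 0.5)
  expect_false(pk$boundary)
  # strictly increasing truth: boundary flag set
  y2 <- sqrt(age) + rnorm(300, sd = 0.01)
  pk2 <- peak_age(fit_gamm(y2, age, k = 6), n_draws = 200, seed = 2)
  expect_true(pk2$boundary)
  expect_true(pk$hdi[1] <= pk$estimate && pk$estimate <= pk$hdi[2])
})

test_that("peak-age draws are reproducible under a fixed seed", {
  set.seed(11)
  age <- runif(200, 1, 80)
  y <- -(sqrt(age) - 4)^2 + rnorm(200, sd = 0.2)
  fit <- fit_gamm(y, age, k = 8)
  p1 <- peak_age(fit, n_draws = 300, seed = 7)
  p2 <- peak_age(fit, n_draws = 300, seed = 7)
  expect_identical(p1$draws, p2$draws)
})

test_that("sex deviation detects a planted female-only bump", {
  set.seed(12)
  n <- 600
  age <- runif(n, 1, 80)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  bump <- ifelse(sex == "F", 0.6 * exp(-(sqrt(age) - 4)^2), 0)
  y <- sqrt(age) / 3 + bump + rnorm(n, sd = 0.25)
  sd_fit <- sex_deviation(y, age, sex)
  expect_lt(sd_fit$p_values[["F"]], 0.01)
  # population curve plus zero residual curve equals the population curve
  expect_warning(sex_deviation(y, age, replace(sex, 1:3, NA)), "missing")
  expect_error(sex_deviation(y, age, rep("M", n)), "both sexes")
})

test_that("vertex-wise fitting streams per-vertex results and survives failures", {
  set.seed(13)
  cohort <- sample_cohort(default_cohort_design(), seed = 5)
  cohort <- cohort[1:120, ]
  n <- nrow(cohort)
  v1 <- -(sqrt(cohort$age_years) - sqrt(10))^2 + rnorm(n, sd = 0.2)
  v2 <- 0.5 * sqrt(cohort$age_years) + rnorm(n, sd = 0.2)
  v3 <- rep(1, n)    # degenerate: handled, never fatal
  vals <- cbind(v1, v2, v3)
  meta <- split_arousal_cohort(cohort)
  out <- suppressWarnings(fit_vertexwise(vals, meta))
  expect_equal(nrow(out), 3)
  expect_lt(out$p_nonlinear[1], 0.01)
  # a vertex whose fit cannot proceed is logged, and the run continues
  tiny <- cohort[1:8, ]
  out_f <- suppressWarnings(
    fit_vertexwise(cbind(rnorm(8)), split_arousal_cohort(tiny)))
  expect_false(is.na(out_f$error[1]))
  # permuting scan order with matched metadata leaves fits unchanged
  perm <- sample(n)
  out2 <- suppressWarnings(fit_vertexwise(vals[perm, , drop = FALSE], meta[perm, ]))
  expect_equal(out$p_nonlinear[1:2], out2$p_nonlinear[1:2], tolerance = 1e-8)
})
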