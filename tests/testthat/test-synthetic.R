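test_that("toy cortex partitions vertices deterministically", {
  cx <- make_toy_cortex(24, n_networks = 7, n_parcels = 12,
                        medial_fraction = 0, seed = 1)
  expect_equal(sum(is.na(cx$network_label)), 0)
  expect_equal(length(unique(cx$network_label)), 7)
  expect_equal(length(unique(cx$parcel_label)), 12)
  cx2 <- make_toy_cortex(24, 7, 12, 0, seed = 1)
  expect_identical(cx, cx2)
  # every unmasked vertex carries exactly one label pair
  cx3 <- fixture_cortex()
  free <- !cx3$medial_mask
  expect_true(all(!is.na(cx3$network_label[free])))
  expect_true(all(is.na(cx3$network_label[!free])))
})

test_that("infeasible cortex parameters are rejected", {
  expect_error(make_toy_cortex(24, 30, 12, 0, 1), "exceed")
  expect_error(make_toy_cortex(24, 5, 40, 0, 1), "exceeds")
  expect_error(make_toy_cortex(10, 2, 4, 0, 1), ">= 24")
})

test_that("cohort sampling honours design, sleep rule and reproducibility", {
  expect_error(sample_cohort(NULL), "empty")
  co <- sample_cohort(default_cohort_design(), seed = 3)
  expect_true(all(co$age_years > 0))
  infant <- co[co$cohort_id == "infant", ]
  expect_true(all(infant$arousal[infant$age_years <= 3] == "sleep"))
  expect_true(all(infant$arousal[infant$age_years > 3] == "wake"))
  # only the longitudinal cohort repeats individuals
  other <- co[co$cohort_id != "infant", ]
  expect_false(any(duplicated(other$individual_id)))
  expect_true(any(duplicated(infant$individual_id)))
  expect_identical(co, sample_cohort(default_cohort_design(), seed = 3))
})

test_that("truth embedding realizes the planted amplitude laws exactly", {
  cx <- fixture_cortex()
  tr <- fixture_truth(cx)
  free <- !cx$medial_mask
  for (age in c(1, 19, 80)) {
    co <- truth_embedding(cx, tr, age)
    for (k in 1:3)
      expect_equal(axis_range(co[free, , drop = FALSE], k),
                   tr$laws[[k]](age), tolerance = 1e-10)
  }
  # planted inverted-U: SA spread larger near the peak than in late life
  sa19 <- axis_range(truth_embedding(cx, tr, 19)[free, ], 1)
  sa80 <- axis_range(truth_embedding(cx, tr, 80)[free, ], 1)
  expect_gt(sa19, sa80)
  expect_error(truth_embedding(cx, tr, -1), "positive")
  expect_identical(truth_embedding(cx, tr, 7), truth_embedding(cx, tr, 7))
})

test_that("planted base maps are orthogonal and laws positive", {
  tr <- fixture_truth()
  expect_lt(max(abs(crossprod(tr$base_maps) - diag(3))), 1e-8)
  ages <- seq(0.1, 100, length.out = 200)
  for (law in tr$laws) expect_true(all(law(ages) > 0))
})

test_that("simulated FC is a clipped monotone kernel with unit diagonal", {
  cx <- fixture_cortex(); tr <- fixture_truth(cx)
  co <- truth_embedding(cx, tr, 19)[!cx$medial_mask, ]
  fc <- simulate_fc(co, noise_sd = 0)
  expect_equal(fc, t(fc))
  expect_equal(unname(diag(fc)), rep(1, nrow(fc)))
  expect_true(all(fc >= -1 & fc <= 1))
  d <- as.matrix(dist(co)); diag(d) <- Inf
  closest <- which(d == min(d), arr.ind = TRUE)[1, ]
  off <- fc; diag(off) <- -Inf
  expect_equal(fc[closest[1], closest[2]], max(off))
  expect_identical(simulate_fc(co, noise_sd = 0.1, seed = 5),
                   simulate_fc(co, noise_sd = 0.1, seed = 5))
  expect_error(simulate_fc(co * NA), "non-finite")
})

test_that("simulated time series converge to the target correlation", {
  cx <- fixture_cortex(48); tr <- fixture_truth(cx)
  co <- truth_embedding(cx, tr, 19)[!cx$medial_mask, ]
  fc <- simulate_fc(co, noise_sd = 0)
  ts <- simulate_timeseries(fc, 2000, seed = 2)
  expect_lte(max(abs(cor(ts) - fc)), 0.1)
  ts0 <- simulate_timeseries(diag(1, 10), 4000, seed = 3)
  emp <- cor(ts0); diag(emp) <- 0
  expect_lt(max(abs(emp)), 0.08)
  expect_error(simulate_timeseries(fc, 2), ">= 3")
  expect_identical(simulate_timeseries(fc, 10, seed = 1),
                   simulate_timeseries(fc, 10, seed = 1))
})

test_that("feature emission respects the coupling weight", {
  cx <- fixture_cortex(); tr <- fixture_truth(cx)
  co <- truth_embedding(cx, tr, 25)[!cx$medial_mask, ]
  f1 <- simulate_features(co, coupling = 1, seed = 1)
  expect_equal(dim(f1), c(nrow(co), 11))
  expect_equal(abs(cor(f1[, 1], co[, 1])), 1, tolerance = 1e-12)
  # coupling 0: correlations bounded by a Monte-Carlo null envelope
  r0 <- vapply(1:20, function(s)
    max(abs(cor(simulate_features(co, coupling = 0, seed = s)[, 1], co))),
    numeric(1))
  expect_lt(max(r0), 4 / sqrt(nrow(co)))
  expect_error(simulate_features(co, coupling = 1.5), "\\[0, 1\\]")
})

test_that("expression emission plants couplings the PLS stage can recover", {
  set.seed(9)
  parcel_truth <- rnorm(40)
  x1 <- simulate_expression(parcel_truth, 30, frac_coupled = 1,
                            noise_sd = 0, seed = 1)
  fit <- pls1_fit(x1, parcel_truth)
  expect_gte(fit$cor_ty, 0.99)
  expect_error(simulate_expression(rnorm(2), 10), ">= 3 parcels")
  expect_identical(simulate_expression(parcel_truth, 12, seed = 4),
                   simulate_expression(parcel_truth, 12, seed = 4))
})

test_that("term-map emission loads classes with the planted signs", {
  set.seed(4)
  parcel_truth <- rnorm(30)
  spec <- tibble::tibble(term = c("tom", "language", "visual", "motor", "pain"),
                         class = c("association", "association", "unimodal",
                                   "unimodal", "intermediate"),
                         loading = 1)
  tm <- simulate_term_maps(parcel_truth, spec, noise_sd = 0, seed = 1)
  expect_gt(cor(tm[, "tom"], parcel_truth), 0.99)
  expect_lt(cor(tm[, "visual"], parcel_truth), -0.99)
  expect_error(simulate_term_maps(parcel_truth, spec[0, ]), "empty")
})

test_that("score emission plants recoverable linear effects", {
  set.seed(11)
  mt <- tibble::tibble(age_years = runif(200, 20, 40),
                       individual_id = sprintf("i%03d", 1:200),
                       dispersion = rnorm(200))
  sc <- simulate_scores(mt, "dispersion", beta_grad = 0.5, noise_sd = 0, seed = 1)
  fit <- ols_assoc(sc$score, sc$age_years, sc$dispersion)
  expect_equal(fit$beta_grad, 0.5, tolerance = 1e-6)
  scn <- simulate_scores(mt, "dispersion", beta_grad = 0.5, norm = TRUE, seed = 1)
  expect_equal(mean(scn$score), 100, tolerance = 1e-8)
  expect_equal(sd(scn$score), 15, tolerance = 1e-8)
  expect_error(simulate_scores(mt, "missing_metric", 0.5), "lacks")
})

test_that("metric series emission is deterministic and offset-faithful", {
  co <- sample_cohort(default_cohort_design(), seed = 2)
  law <- lifespan_law(18.8, 1)
  s1 <- simulate_metric_series(co, law, seed = 5)
  expect_identical(s1, simulate_metric_series(co, law, seed = 5))
  expect_equal(s1$y_true, law(s1$age_years))
  # with zero noise and no individual effects the offsets are exact
  s0 <- simulate_metric_series(co, law, noise_sd_law = function(a) 0 * a,
                               indiv_sd = 0, seed = 1)
  resid <- s0$y - s0$y_true
  expect_equal(as.numeric(tapply(resid, s0$cohort_id, mean)[c("infant", "dev", "adult")]),
               c(0.05, 0, -0.05), tolerance = 1e-12)
})
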