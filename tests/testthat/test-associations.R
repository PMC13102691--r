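test_that("OLS association recovers a planted slope and ignores metric scale", {
  set.seed(1)
  n <- 150
  age <- runif(n, 22, 37)
  g <- rnorm(n)
  y <- 0.2 * zscore_for_test(age) + 0.5 * zscore_for_test(g)
  fit <- ols_assoc(y, age, g)
  expect_equal(fit$beta_grad, 0.5, tolerance = 1e-6)
  fit2 <- ols_assoc(y, age, 100 + 7 * g)   # affine rescaling of the raw metric
  expect_equal(fit2$beta_grad, fit$beta_grad, tolerance = 1e-10)
  expect_error(ols_assoc(y, age, rep(1, n)), "constant")
})

test_that("mixed-model association matches OLS when it must and recovers effects", {
  set.seed(2)
  n <- 200
  age <- runif(n, 1, 5)
  g <- rnorm(n)
  y <- 0.4 * zscore_for_test(g) + rnorm(n, sd = 0.5)
  # one observation per individual: collapses to OLS
  lf <- lmm_assoc(y, age, g, individual = sprintf("i%d", 1:n))
  of <- ols_assoc(y, age, g)
  expect_equal(lf$beta_grad, of$beta_grad, tolerance = 1e-10)
  expect_equal(lf$model_kind, "lmm")
  # zero between-individual variance: estimates agree to high accuracy
  ind2 <- rep(sprintf("j%d", 1:100), each = 2)
  y2 <- 0.4 * zscore_for_test(g) + rnorm(n, sd = 0.5)
  lf2 <- suppressMessages(lmm_assoc(y2, age, g, ind2))
  of2 <- ols_assoc(y2, age, g)
  expect_equal(lf2$beta_grad, of2$beta_grad, tolerance = 1e-3)
  # planted slope with substantial intercept variance
  set.seed(3)
  ind3 <- rep(sprintf("k%d", 1:300), each = 2)
  b <- rnorm(300, sd = 1.5)[rep(1:300, each = 2)]
  g3 <- rnorm(600)
  y3 <- 0.3 * zscore_for_test(g3) + b + rnorm(600, sd = 0.4)
  lf3 <- lmm_assoc(y3, runif(600, 1, 5), g3, ind3)
  expect_lt(abs(lf3$beta_grad - 0.3), 0.05)
})

test_that("BH FDR matches a brute-force step-up oracle", {
  expect_false(any(bh_fdr(rep(1, 10))$reject))
  expect_true(bh_fdr(0.04)$reject)
  expect_false(bh_fdr(0.06)$reject)
  set.seed(4)
  for (s in 1:20) {
    p <- runif(25)^sample(1:3, 1)
    out <- bh_fdr(p, q = 0.05)
    expect_equal(out$reject, oracle_bh(p, 0.05))
    expect_equal(out$q_value, p.adjust(p, "BH"))
  }
  expect_error(bh_fdr(c(0.5, 0)), ">")
})

test_that("gam_contrast returns the planted high-low gradient contrast", {
  set.seed(5)
  n <- 900
  age <- runif(n, 8, 90)
  g <- rnorm(n)
  cohort <- cut(age, c(0, 25, 60, 100), labels = c("d", "y", "a"))
  y <- 0.4 * zscore_for_test(g) + sin(age / 20) + rnorm(n, sd = 0.05)
  gc <- gam_contrast(y, age, g, cohort)
  zg <- zscore_for_test(g)
  expected <- 0.4 * diff(quantile(zg, c(0.1, 0.9))) / sd(y)
  expect_equal(gc$delta_main, unname(expected), tolerance = 0.05)
  expect_lte(abs(gc$delta_age), 0.05)
  # planted positive age x metric interaction
  y2 <- (0.2 + 0.4 * (age - 8) / 82) * zscore_for_test(g) + rnorm(n, sd = 0.3)
  gc2 <- gam_contrast(y2, age, g, cohort)
  expect_gt(gc2$delta_age, 0)
  # single cohort reproduces the two-smooth fit
  gc3 <- gam_contrast(y, age, g, cohort = rep("one", n))
  expect_true(is.finite(gc3$delta_main))
})

test_that("the canonical axis reproduces the four-parcel hand computation", {
  tm <- cbind(assoc1 = c(1, 1, -1, -1), uni1 = c(-1, -1, 1, 1),
              mid = c(0.3, -0.2, 0.1, 0.4))
  ca <- canonical_axis(tm, "assoc1", "uni1", excluded = "mid")
  expect_equal(ca$axis, c(1, 1, -1, -1) / sd(c(1, 1, -1, -1)), tolerance = 1e-12)
  expect_equal(mean(ca$axis), 0, tolerance = 1e-12)
  expect_equal(sd(ca$axis), 1, tolerance = 1e-12)
  # excluded terms change nothing
  ca2 <- canonical_axis(tm[, 1:2], "assoc1", "uni1")
  expect_equal(ca2$axis, ca$axis)
  # swapping classes flips the sign
  ca3 <- canonical_axis(tm, "uni1", "assoc1")
  expect_equal(ca3$axis, -ca$axis)
  expect_error(canonical_axis(tm, character(0), "uni1"), "non-empty")
  expect_error(canonical_axis(tm, "assoc1", "assoc1"), "disjoint")
  expect_error(canonical_axis(tm, "nope", "uni1"), "unknown terms")
})

test_that("term-axis alignment is average-rank Spearman", {
  set.seed(6)
  z <- scale(matrix(rnorm(60), 20))
  colnames(z) <- c("a", "b", "c")
  ax <- z[, "a"]
  out <- term_axis_alignment(ax, z)
  expect_equal(out$rho[out$term == "a"], 1)
  out2 <- term_axis_alignment(-ax, z)
  expect_equal(out2$rho[out2$term == "a"], -1)
  # monotone transform invariance
  out3 <- term_axis_alignment(exp(3 * ax), z)
  expect_equal(out3$rho, out$rho)
  # tie-heavy inputs against a hand-rolled average-rank oracle
  axt <- c(1, 1, 2, 2, 2, 3)
  tmt <- cbind(t1 = c(2, 1, 1, 3, 3, 3))
  r1 <- rank(axt); r2 <- rank(tmt[, 1])
  oracle <- sum((r1 - mean(r1)) * (r2 - mean(r2))) /
    sqrt(sum((r1 - mean(r1))^2) * sum((r2 - mean(r2))^2))
  expect_equal(term_axis_alignment(axt, tmt)$rho, oracle, tolerance = 1e-12)
  expect_error(term_axis_alignment(rep(1, 20), z), "constant")
})

test_that("one-component PLS finds the informative gene and orients itself", {
  set.seed(7)
  n <- 1000
  x <- matrix(rnorm(n * 8), n)
  colnames(x) <- sprintf("g%02d", 1:8)
  y <- scale(x[, 7])[, 1]
  fit <- pls1_fit(x, y)
  expect_equal(names(which.max(abs(fit$coefficients))), "g07")
  expect_gte(fit$cor_ty, 0.99)
  expect_gte(fit$cor_ty, 0.99)
  expect_equal(sum(fit$weights^2), 1, tolerance = 1e-12)
  # single gene: weight +/- 1 and |corr| preserved
  f1 <- pls1_fit(x[, 3, drop = FALSE], y)
  expect_equal(abs(unname(f1$weights)), 1)
  expect_equal(f1$cor_ty, abs(cor(x[, 3], y)), tolerance = 1e-12)
  # orientation survives a sign flip of the phenotype: the weights flip
  # with y and corr(t, y) stays non-negative
  f2 <- pls1_fit(x, -y)
  expect_gte(f2$cor_ty, 0)
  expect_equal(unname(f2$weights), -unname(fit$weights), tolerance = 1e-12)
  # missing handling: all-missing dropped, partial median-imputed
  x2 <- x; x2[, 2] <- NA; x2[3, 5] <- NA
  f3 <- pls1_fit(x2, y)
  expect_false("g02" %in% f3$genes)
  expect_error(pls1_fit(x, rep(1, n)), "constant")
})

test_that("permutation p-values respect their lower bound and detect coupling", {
  set.seed(8)
  n <- 40
  x <- matrix(rnorm(n * 15), n)
  y <- scale(x %*% rnorm(15))[, 1]    # strongly coupled
  out <- pls_permutation(x, y, n_perm = 199, seed = 1)
  expect_equal(out$p, 1 / 200)
  expect_error(pls_permutation(x, y, n_perm = 5), ">= 19")
  # across-age BH wiring
  enr <- pls_enrichment(x, list(`1` = y, `25` = rnorm(n)), n_perm = 99, seed = 2)
  expect_equal(nrow(enr), 2)
  expect_equal(enr$q_value, p.adjust(enr$p, "BH"))
})

test_that("gene-set scores follow the normalized weighted-sum formula", {
  set.seed(9)
  x <- matrix(rnorm(30 * 8), 30)
  colnames(x) <- sprintf("g%d", 1:8)
  w <- setNames(rnorm(8), colnames(x))
  gs <- c("g2", "g5", "g7")
  s <- gene_set_score(x, w, gs)
  z <- scale(x[, gs])
  brute <- as.numeric(z %*% w[gs]) / sqrt(sum(w[gs]^2))
  expect_equal(s, brute, tolerance = 1e-12)
  # singleton set reduces to a signed z-column
  s1 <- gene_set_score(x, w, "g5")
  expect_equal(s1, sign(w["g5"]) * scale(x[, "g5"])[, 1], tolerance = 1e-12,
               ignore_attr = TRUE)
  # duplicated genes counted once
  expect_equal(gene_set_score(x, w, c(gs, "g2")), s)
  expect_equal(gene_set_score(x, w, gs, unweighted = TRUE), rowMeans(z))
  expect_error(gene_set_score(x, w, character(0)), "empty")
})

test_that("theme summaries take medians of significant member terms", {
  tq <- tibble::tibble(
    term = c("synaptic signalling", "SYNAPSE organization", "ion transport",
             "mitochondrial ATP", "unrelated thing"),
    age = 25,
    q = c(0.01, 0.001, 0.2, 0.04, 0.001))
  rules <- list(synapse = c("synap"), ion = c("ion transport"),
                energy = c("mitochond", "ATP"))
  out <- theme_summary(tq, rules)
  expect_equal(out$score[out$theme == "synapse"], 2.5)   # median of 2 and 3
  expect_equal(out$score[out$theme == "ion"], 0)         # member not significant
  expect_equal(out$score[out$theme == "energy"], -log10(0.04))
  expect_equal(attr(out, "unmatched"), "unrelated thing")
  # keyword matching is case-insensitive by construction (SYNAPSE matched)
})
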