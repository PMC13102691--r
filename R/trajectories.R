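#' Penalized-spline lifespan trajectory with random intercepts
#'
#' Fits `y ~ s(age^alpha)` with penalized cubic regression splines, smoothing
#' parameters chosen by REML, and ridge-penalized random intercepts for each
#' supplied grouping factor (individual, cohort), via [mgcv::gam()]. The age
#' transform (default `alpha = 0.5`, i.e. square-root age) increases temporal
#' resolution during the rapid early-life period.
#'
#' @param y numeric response, one value per scan.
#' @param age ages in years (> 0).
#' @param groups optional named list of grouping vectors for random
#'   intercepts (factors with < 2 levels are dropped).
#' @param k spline basis dimension (>= 3).
#' @param weights optional non-negative observation weights.
#' @param covariates optional data frame of additional linear covariates
#'   (e.g. total brain volume).
#' @param alpha age-transform exponent.
#' @param bs spline basis (`"cr"` cubic regression, `"cs"` shrinkage variant).
#' @return a `smooth_fit`: the mgcv model plus transform metadata.
#' @export
fit_gamm <- function(y, age, groups = NULL, k = 10, weights = NULL,
                     covariates = NULL, alpha = 0.5, bs = "cr") {
  if (k < 3) stop_param("k must be >= 3, got %s", k)
  stopifnot(length(y) == length(age), all(age > 0))
  if (length(y) < k + 2) stop_param("need >= k + 2 observations")
  dat <- data.frame(y = y, ta = age^alpha)
  terms <- sprintf("s(ta, bs = \"%s\", k = %d)", bs, k)
  re_names <- character(0)
  for (nm in names(groups)) {
    f <- factor(groups[[nm]])
    if (nlevels(f) >= 2) {
      dat[[nm]] <- f
      re_names <- c(re_names, nm)
      terms <- c(terms, sprintf("s(%s, bs = \"re\")", nm))
    }
  }
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(y))
    dat <- cbind(dat, covariates)
    terms <- c(terms, names(covariates))
  }
  fml <- as.formula(paste("y ~", paste(terms, collapse = " + ")))
  n_coef <- k + sum(vapply(re_names, function(nm) nlevels(dat[[nm]]), integer(1)))
  model <- if (n_coef > 150)
    # large random-intercept factors: bam's fast REML is O(n p) rather than O(p^3)
    mgcv::bam(fml, data = dat, weights = weights, method = "fREML", discrete = TRUE)
  else tryCatch(
    mgcv::gam(fml, data = dat, weights = weights, method = "REML"),
    # REML breaks down for (near-)zero-variance responses; GCV still
    # returns the degenerate constant fit
    error = function(e)
      mgcv::gam(fml, data = dat, weights = weights, method = "GCV.Cp"))
  structure(list(model = model, alpha = alpha, k = k, re_names = re_names,
                 age_range = range(age), data = dat),
            class = "smooth_fit")
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat(sprintf("<smooth_fit> k = %d, edf = %.2f, alpha = %g, n = %d\n",
              x$k, sum(x$model$edf) - length(x$model$coefficients) +
                length(x$model$smooth), x$alpha, nrow(x$data)))
  invisible(x)
}

re_terms <- function(fit) {
  labs <- vapply(fit$model$smooth, function(s) s$label, character(1))
  labs[vapply(fit$model$smooth, function(s) inherits(s, "random.effect"), logical(1))]
}

newdata_grid <- function(fit, age) {
  nd <- data.frame(ta = age^fit$alpha)
  for (nm in fit$re_names) nd[[nm]] <- factor(levels(fit$data[[nm]])[1],
                                              levels = levels(fit$data[[nm]]))
  cov_cols <- setdiff(names(fit$data), c("y", "ta", fit$re_names))
  for (nm in cov_cols) nd[[nm]] <- mean(fit$data[[nm]])
  nd
}

#' Population-level fitted trajectory
#'
#' Evaluates the smooth (plus intercept and mean covariate effects),
#' excluding all random-intercept terms.
#'
#' @param fit a `smooth_fit`.
#' @param age ages at which to evaluate.
#' @param se return standard errors as well.
#' @return fitted values (or list with `fit`, `se`).
#' @export
predict_curve <- function(fit, age, se = FALSE) {
  nd <- newdata_grid(fit, age)
  pr <- predict(fit$model, newdata = nd, exclude = re_terms(fit),
                se.fit = se, newdata.guaranteed = TRUE)
  if (se) list(fit = as.numeric(pr$fit), se = as.numeric(pr$se.fit))
  else as.numeric(pr)
}

#' Random-intercept estimates of a fitted trajectory
#'
#' @param fit a `smooth_fit`.
#' @return named list, one named numeric vector per grouping factor.
#' @export
random_intercepts <- function(fit) {
  out <- list()
  for (s in fit$model$smooth) {
    if (!inherits(s, "random.effect")) next
    nm <- s$term
    idx <- s$first.para:s$last.para
    out[[nm]] <- setNames(coef(fit$model)[idx], levels(fit$data[[nm]]))
  }
  out
}

#' Inverse-density observation weights on the transformed age scale
#'
#' Equal-width bins on the square-root-age scale; each observation's weight
#' is proportional to the reciprocal of its bin count times the reciprocal
#' of its cohort's sample size, normalized to mean 1. Balances sparsely
#' sampled age ranges and small cohorts.
#'
#' @param age ages in years.
#' @param cohort optional cohort id per observation.
#' @param n_bins number of bins (default 20).
#' @param alpha age-transform exponent.
#' @return numeric weights with mean 1.
#' @export
density_weights <- function(age, cohort = NULL, n_bins = 20, alpha = 0.5) {
  stopifnot(all(age > 0), n_bins >= 1)
  ta <- age^alpha
  brk <- seq(min(ta), max(ta), length.out = n_bins + 1)
  bin <- findInterval(ta, brk, rightmost.closed = TRUE, all.inside = TRUE)
  w <- 1 / tabulate(bin, nbins = n_bins)[bin]
  if (!is.null(cohort)) {
    cf <- factor(cohort)
    w <- w / tabulate(cf)[as.integer(cf)]
  }
  w / mean(w)
}

#' Two-step mean and variance harmonization of a lifespan series
#'
#' Implements the four-step harmonization used before final trajectory
#' fitting:
#' 1. a low-complexity GAMM (`k_low`) with individual and cohort random
#'    intercepts is fitted and the cohort intercepts are removed, giving
#'    mean-adjusted data (with `remove_individual = TRUE` the shrunken
#'    individual intercepts are subtracted as well; off by default because
#'    subtracting intercepts shrunk toward the low-k curve pulls the data
#'    toward that curve's bias, which measurably displaces trajectory peaks
#'    at this scale — individual effects are instead retained as random
#'    intercepts in every fit);
#' 2. a second low-complexity GAMM with cohort random intercepts is fitted
#'    to the squared residuals, predicting the variance function `v(age)`
#'    (floored at `var_floor_frac * var(y)`);
#' 3. residuals are rescaled per cohort by a single positive factor so each
#'    cohort's residual variance matches the predicted variance at its ages
#'    (a per-cohort affine adjustment: within-cohort rank order preserved),
#'    giving variance-adjusted data;
#' 4. a final higher-complexity GAMM (`k_high`) is fitted to the
#'    variance-adjusted data with weights equal to the inverse predicted
#'    variance (times optional density weights).
#'
#' @param y numeric response per scan.
#' @param age ages in years.
#' @param individual,cohort grouping vectors.
#' @param k_low basis dimension of the harmonization fits (default 4).
#' @param k_high basis dimension of the final fit (default 10).
#' @param density_w optional [density_weights()] vector folded into step 4.
#' @param alpha age-transform exponent.
#' @param var_floor_frac variance floor as a fraction of `var(y)`.
#' @param remove_individual also subtract the shrunken individual intercepts
#'   from the data (see Details above).
#' @return a `harmonized_series`: mean- and variance-adjusted values, cohort
#'   and individual intercepts, the predicted variance `vhat`, final weights
#'   and the final `smooth_fit`.
#' @export
harmonize <- function(y, age, individual, cohort, k_low = 4, k_high = 10,
                      density_w = NULL, alpha = 0.5, var_floor_frac = 1e-6,
                      remove_individual = FALSE) {
  stopifnot(length(y) == length(age))
  cohort <- as.character(cohort)
  fit0 <- fit_gamm(y, age, groups = list(individual = individual, cohort = cohort),
                   k = k_low, alpha = alpha)
  ri <- random_intercepts(fit0)
  u_coh <- ri$cohort %||% setNames(rep(0, length(unique(cohort))), unique(cohort))
  b_ind <- ri$individual %||% setNames(rep(0, length(unique(individual))), unique(individual))
  mean_adjusted <- y - u_coh[cohort] -
    (if (remove_individual) b_ind[as.character(individual)] else 0)
  mu <- predict_curve(fit0, age)
  r <- as.numeric(mean_adjusted - mu)

  fit_v <- fit_gamm(r^2, age, groups = list(cohort = cohort), k = k_low, alpha = alpha)
  # floor keyed to the typical residual variance: a vanishing floor would let
  # a few floored points monopolize the inverse-variance weights
  floor_eps <- max(var_floor_frac * var(y), 0.05 * mean(r^2), 1e-12)
  vhat_raw <- predict_curve(fit_v, age)
  if (any(vhat_raw < floor_eps))
    warning("predicted variance floored at epsilon for some observations")
  vhat <- pmax(vhat_raw, floor_eps)

  scale_c <- vapply(split(seq_along(y), cohort), function(idx)
    sqrt(mean(vhat[idx]) / max(mean(r[idx]^2), floor_eps)), numeric(1))
  variance_adjusted <- mu + unname(scale_c[cohort]) * r

  w <- 1 / vhat
  if (!is.null(density_w)) w <- w * density_w
  w <- w / mean(w)
  fit <- fit_gamm(variance_adjusted, age,
                  groups = list(individual = individual, cohort = cohort),
                  k = k_high, weights = w, alpha = alpha)
  structure(list(mean_adjusted = as.numeric(mean_adjusted),
                 variance_adjusted = as.numeric(variance_adjusted),
                 mu_low = as.numeric(mu),
                 cohort_intercepts = u_coh, individual_intercepts = b_ind,
                 vhat = vhat, vhat_fit = fit_v, cohort_scale = scale_c,
                 weights = w, fit = fit, age = age, cohort = cohort),
            class = "harmonized_series")
}

#' @export
print.harmonized_series <- function(x, ...) {
  cat(sprintf("<harmonized_series> n = %d, cohorts = %d, final k = %d\n",
              length(x$age), length(x$cohort_intercepts), x$fit$k))
  invisible(x)
}

#' Partial F-test for nonlinearity of an age trajectory
#'
#' Compares the linear model `y ~ sqrt(age)` to the nested smooth model
#' `y ~ s(sqrt(age), k = 6)` by the classical partial F-test. The smooth is
#' fitted as an unpenalized cubic regression spline (fixed degrees of
#' freedom): a valid F distribution requires fixed model dimensions, and a
#' partial F computed from penalized effective degrees of freedom is grossly
#' anticonservative under the null (its df collapse as the smooth shrinks to
#' the linear fit). The linear model spends 2 df, the spline `k` df, so
#' `F ~ F(k - 2, n - k)` under linearity and `F >= 0` by nesting.
#'
#' @param y numeric response (>= 10 observations, non-constant).
#' @param age ages in years.
#' @param k smooth basis dimension (default 6).
#' @param alpha age-transform exponent.
#' @return tibble with `F`, `df1`, `df2`, `p_nonlinear`, `edf`.
#' @export
nonlinearity_test <- function(y, age, k = 6, alpha = 0.5) {
  if (length(y) < 10) stop_param("need >= 10 observations")
  if (length(y) <= k + 1) stop_param("need > k + 1 observations")
  if (sd(y) == 0) stop_param("degenerate (constant) response")
  ta <- age^alpha
  m0 <- lm(y ~ ta)
  m1 <- mgcv::gam(y ~ s(ta, bs = "cr", k = k, fx = TRUE))
  rss0 <- sum(resid(m0)^2)
  rss1 <- sum(resid(m1)^2)
  n <- length(y)
  df1 <- k - 2
  df2 <- n - k
  f <- max(0, rss0 - rss1) / df1 / (rss1 / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  tibble::tibble(F = f, df1 = df1, df2 = df2,
                 p_nonlinear = min(max(p, .Machine$double.xmin), 1),
                 edf = k - 1)
}

#' Benjamini-Hochberg correction across a vertex set
#'
#' @param results tibble with a `p_nonlinear` column (one row per vertex).
#' @param q FDR level (default 0.05).
#' @return the tibble with `q_nonlinear` and `significant` appended.
#' @export
fdr_across_vertices <- function(results, q = 0.05) {
  stopifnot("p_nonlinear" %in% names(results))
  results$q_nonlinear <- p.adjust(results$p_nonlinear, method = "BH")
  results$significant <- results$q_nonlinear < q
  results
}

#' Posterior extremum age of a fitted trajectory
#'
#' Draws spline coefficients from the Gaussian approximation to the
#' coefficient posterior at the REML optimum, evaluates each draw's
#' population curve on an age grid, and takes the per-draw extremum age.
#' Returns the posterior median extremum age and the highest-density
#' interval of the draws. If more than half the draws peak on a grid
#' boundary the trajectory is flagged as monotone over the grid.
#'
#' @param fit a `smooth_fit` (or the `fit` of a `harmonized_series`).
#' @param n_draws number of posterior draws (default 20000).
#' @param level HDI probability (default 0.95).
#' @param age_grid ages searched; defaults to 400 points over the fitted range.
#' @param direction `"max"` (peak) or `"min"` (trough).
#' @param seed seed for the posterior draws.
#' @return a `peak_age` list: `estimate`, `hdi`, `boundary`, `draws`.
#' @export
peak_age <- function(fit, n_draws = 20000, level = 0.95, age_grid = NULL,
                     direction = c("max", "min"), seed = 1) {
  direction <- match.arg(direction)
  if (inherits(fit, "harmonized_series")) fit <- fit$fit
  stopifnot(inherits(fit, "smooth_fit"))
  if (is.null(age_grid))
    age_grid <- seq(fit$age_range[1], fit$age_range[2], length.out = 400)
  nd <- newdata_grid(fit, age_grid)
  xp <- predict(fit$model, newdata = nd, type = "lpmatrix",
                newdata.guaranteed = TRUE)
  # zero out random-effect columns: population-level curves
  for (s in fit$model$smooth) if (inherits(s, "random.effect"))
    xp[, s$first.para:s$last.para] <- 0
  vp <- fit$model$Vp
  set.seed(seed)
  betas <- mgcv::rmvn(n_draws, coef(fit$model), vp)
  curves <- xp %*% t(betas)                       # grid x draws
  pick <- if (direction == "max") max.col(t(curves)) else max.col(-t(curves))
  ages <- age_grid[pick]
  boundary <- mean(pick == 1L | pick == length(age_grid)) > 0.5
  structure(list(estimate = median(ages), hdi = hdi(ages, level),
                 boundary = boundary, draws = ages, level = level),
            class = "peak_age")
}

# shortest interval containing `level` of the draws
hdi <- function(x, level = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, ceiling(level * n))
  if (m >= n) return(c(lo = x[1], hi = x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(lo = x[i], hi = x[i + m])
}

#' @export
print.peak_age <- function(x, ...) {
  cat(sprintf("<peak_age> %.2f y, %d%% HDI [%.2f, %.2f]%s\n", x$estimate,
              round(100 * x$level), x$hdi[1], x$hdi[2],
              if (x$boundary) " (boundary: monotone trajectory)" else ""))
  invisible(x)
}

#' Sex-specific deviations from the population trajectory
#'
#' Two-step procedure: (1) a sex-agnostic shrinkage-spline fit of the metric
#' versus transformed age (`k = 4`, basis `"cs"`); (2) a fit of its residuals
#' with separate smooths per sex (`k = 5`, basis `"cs"`) plus a parametric
#' sex offset. Per-sex smooth p-values test whether either sex departs
#' systematically from the shared curve; sex-specific trajectories are the
#' population curve plus the fitted residual curve.
#'
#' @param metric numeric response per scan.
#' @param age ages in years.
#' @param sex character/factor with levels among `"M"`, `"F"` (other or
#'   missing rows are dropped with a warning).
#' @param k_pop,k_sex basis dimensions of the two steps.
#' @param alpha age-transform exponent.
#' @return a `sex_deviation` list: `population_fit`, `residual_fit`,
#'   `p_values` (per sex; conservative, see Details), `p_difference`
#'   (calibrated male-female difference-smooth p-value), and `curves`
#'   (tibble over an age grid).
#'
#' @details The per-sex smooth p-values of the two-step procedure are
#'   structurally conservative: the pooled step-1 fit absorbs part of each
#'   sex's smooth noise, so each sex's residual smooth is damped under the
#'   null. A calibrated test of sex divergence is therefore also provided as
#'   `p_difference`, from a single joint model with a common smooth, a sex
#'   offset and an ordered-factor difference smooth.
#' @export
sex_deviation <- function(metric, age, sex, k_pop = 4, k_sex = 5, alpha = 0.5) {
  keep <- !is.na(sex) & sex %in% c("M", "F")
  if (!all(keep)) {
    warning(sprintf("dropping %d rows with missing/unknown sex", sum(!keep)))
    metric <- metric[keep]; age <- age[keep]; sex <- sex[keep]
  }
  sexf <- factor(sex, levels = c("M", "F"))
  if (nlevels(droplevels(sexf)) < 2) stop_param("both sexes must be present")
  pop <- fit_gamm(metric, age, k = k_pop, alpha = alpha, bs = "cs")
  r <- metric - predict_curve(pop, age)
  dat <- data.frame(r = r, ta = age^alpha, sexf = sexf)
  m2 <- mgcv::gam(r ~ sexf + s(ta, by = sexf, bs = "cs", k = k_sex),
                  data = dat, method = "REML")
  st <- summary(m2)$s.table
  pv <- setNames(st[, "p-value"], sub(".*sexf", "", rownames(st)))
  # calibrated divergence test: joint model with a difference smooth
  dat$sexo <- factor(sex, levels = c("M", "F"), ordered = TRUE)
  dat$y <- metric
  md <- mgcv::gam(y ~ s(ta, bs = "cs", k = k_pop) + sexo +
                    s(ta, by = sexo, bs = "cr", k = k_sex),
                  data = dat, method = "REML")
  std <- summary(md)$s.table
  p_diff <- unname(std[grep("sexo", rownames(std)), "p-value"])
  grid <- seq(min(age), max(age), length.out = 200)
  curves <- purrr::map_dfr(c("M", "F"), function(s) {
    nd <- data.frame(ta = grid^alpha, sexf = factor(s, levels = c("M", "F")))
    tibble::tibble(age = grid, sex = s,
                   fit = predict_curve(pop, grid) +
                     as.numeric(predict(m2, newdata = nd)))
  })
  structure(list(population_fit = pop, residual_fit = m2,
                 p_values = pv, p_difference = p_diff, curves = curves),
            class = "sex_deviation")
}

#' Harmonized trajectory fits for every vertex
#'
#' Applies [density_weights()], [harmonize()] and the nonlinearity test to
#' each vertex column, streaming a tidy per-vertex result; per-vertex
#' failures are recorded (`error` column) rather than aborting the run.
#'
#' @param values_by_vertex scan x vertex matrix of values (e.g. one aligned
#'   gradient's vertex values across scans).
#' @param meta tibble with `age_years`, `individual_id` and a cohort column.
#' @param cohort_col name of the cohort column (default `cohort_strat` if
#'   present, else `cohort_id`).
#' @param k_low,k_high harmonization basis dimensions.
#' @param n_bins density-weight bin count.
#' @param do_peak also compute posterior peak ages (slower).
#' @param n_draws posterior draws if `do_peak`.
#' @param seed seed for posterior draws.
#' @param q FDR level across vertices.
#' @return tibble with one row per vertex: `vertex`, `edf`, `F`,
#'   `p_nonlinear`, `q_nonlinear`, `significant`, optional peak columns,
#'   `error`.
#' @export
fit_vertexwise <- function(values_by_vertex, meta,
                           cohort_col = NULL, k_low = 4, k_high = 10,
                           n_bins = 20, do_peak = FALSE, n_draws = 2000,
                           seed = 1, q = 0.05) {
  check_matrix(values_by_vertex, "values_by_vertex")
  stopifnot(nrow(values_by_vertex) == nrow(meta))
  cohort_col <- cohort_col %||%
    (if ("cohort_strat" %in% names(meta)) "cohort_strat" else "cohort_id")
  coh <- meta[[cohort_col]]
  dw <- density_weights(meta$age_years, coh, n_bins = n_bins)
  rows <- purrr::map(seq_len(ncol(values_by_vertex)), function(v) {
    tryCatch({
      y <- values_by_vertex[, v]
      h <- harmonize(y, meta$age_years, meta$individual_id, coh,
                     k_low = k_low, k_high = k_high, density_w = dw)
      nl <- nonlinearity_test(h$variance_adjusted, meta$age_years)
      row <- tibble::tibble(vertex = v,
                            edf = sum(h$fit$model$edf),
                            F = nl$F, p_nonlinear = nl$p_nonlinear,
                            error = NA_character_)
      if (do_peak) {
        pk <- peak_age(h$fit, n_draws = n_draws, seed = split_seed(seed, v))
        row$peak_age <- pk$estimate
        row$peak_lo <- pk$hdi[1]; row$peak_hi <- pk$hdi[2]
        row$boundary <- pk$boundary
      }
      row
    }, error = function(e)
      tibble::tibble(vertex = v, edf = NA_real_, F = NA_real_,
                     p_nonlinear = NA_real_, error = conditionMessage(e)))
  })
  out <- dplyr::bind_rows(rows)
  ok <- !is.na(out$p_nonlinear)
  out$q_nonlinear <- NA_real_
  out$significant <- NA
  if (any(ok)) {
    adj <- fdr_across_vertices(out[ok, ], q = q)
    out$q_nonlinear[ok] <- adj$q_nonlinear
    out$significant[ok] <- adj$significant
  }
  out
}
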