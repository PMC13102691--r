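#' OLS association between a behaviour score and a gradient metric
#'
#' `y = b0 + b_age z(age) + b_grad z(G) + e`, predictors z-scored (scores are
#' left on their reported scale, as in normed test batteries). Returns the
#' standardized slope for the metric with its standard error, t and p.
#'
#' @param score numeric outcome, one per individual.
#' @param age ages in years.
#' @param metric gradient metric values.
#' @return a one-row `AssocResult` tibble (`beta_grad`, `se`, `t`, `p`,
#'   `model_kind`).
#' @export
ols_assoc <- function(score, age, metric) {
  stopifnot(length(score) == length(age), length(age) == length(metric))
  if (sd(metric) == 0) stop_param("constant metric")
  m <- lm(score ~ zscore(age) + zscore(metric))
  cf <- summary(m)$coefficients
  tibble::tibble(beta_grad = cf[3, 1], se = cf[3, 2], t = cf[3, 3],
                 p = cf[3, 4], model_kind = "ols")
}

#' Mixed-model association with per-individual random intercepts
#'
#' `y = b0 + b_age z(age) + b_grad z(G) + b_ind + e` with
#' `b_ind ~ N(0, sigma_b^2)`, fitted with lme4 and Satterthwaite p-values
#' via lmerTest — the repeated-measures analogue of [ols_assoc()]. With one
#' observation per individual the mixed model is unidentifiable and the
#' call collapses to OLS.
#'
#' @param score numeric outcome per scan.
#' @param age ages in years.
#' @param metric gradient metric values.
#' @param individual individual id per scan.
#' @return a one-row `AssocResult` tibble.
#' @export
lmm_assoc <- function(score, age, metric, individual) {
  stopifnot(length(score) == length(age), length(age) == length(metric),
            length(metric) == length(individual))
  if (sd(metric) == 0) stop_param("constant metric")
  ind <- factor(individual)
  if (nlevels(ind) < 2) stop_param("need >= 2 individuals")
  if (max(table(ind)) == 1L) {
    out <- ols_assoc(score, age, metric)
    out$model_kind <- "lmm"
    return(out)
  }
  dat <- data.frame(y = score, za = zscore(age), zg = zscore(metric), ind = ind)
  m <- suppressMessages(lmerTest::lmer(y ~ za + zg + (1 | ind), data = dat))
  cf <- coef(summary(m))
  tibble::tibble(beta_grad = cf["zg", "Estimate"], se = cf["zg", "Std. Error"],
                 t = cf["zg", "t value"], p = cf["zg", "Pr(>|t|)"],
                 model_kind = "lmm")
}

#' Benjamini-Hochberg FDR over a family of tests
#'
#' Standard step-up procedure (monotone adjusted values), returning both the
#' adjusted q-values and rejection flags at level `q`.
#'
#' @param p_values numeric p-values in `(0, 1]`.
#' @param q FDR level (default 0.05).
#' @return tibble with `p`, `q_value`, `reject`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  stopifnot(all(p_values > 0 & p_values <= 1))
  adj <- p.adjust(p_values, method = "BH")
  tibble::tibble(p = p_values, q_value = adj, reject = adj <= q)
}

#' Pooled smooth model of cognition with an age x metric interaction
#'
#' Fits `y ~ s(age, k = 8) + s(z(G), k = 5) + ti(age, z(G)) + cohort` (cubic
#' regression splines, fast REML) on a pooled multi-cohort table, then
#' summarizes the age-specific gradient contrast
#' `D(a) = E[y | z(G) = q90, age = a] - E[y | z(G) = q10, age = a]`
#' from cohort-size-weighted predictions. `delta_main` is `D` at the pooled
#' median age; `delta_age` is the change in `D` from the 10th to the 90th
#' age percentile (a change in effect size, not a slope of cognition).
#'
#' @param score numeric outcome per scan (z-scored internally).
#' @param age ages in years.
#' @param metric gradient metric values (z-scored internally).
#' @param cohort cohort id (single-cohort input drops the fixed effect).
#' @param k_age,k_grad smooth basis dimensions (defaults 8, 5).
#' @param n_grid age-grid resolution for `D(a)`.
#' @return a `gam_contrast` list: `delta_main`, `delta_age`, `delta_curve`
#'   tibble, `p_smooth` (gradient main smooth), `p_interaction`, `model`.
#' @export
gam_contrast <- function(score, age, metric, cohort = NULL, k_age = 8,
                         k_grad = 5, n_grid = 101) {
  stopifnot(length(score) == length(age), length(age) == length(metric))
  if (sd(metric) == 0) stop_param("constant metric")
  dat <- data.frame(y = zscore(score), age = age, zg = zscore(metric))
  multi <- !is.null(cohort) && length(unique(cohort)) > 1
  if (multi) dat$cohort <- factor(cohort)
  fml <- as.formula(sprintf(
    "y ~ s(age, bs = \"cr\", k = %d) + s(zg, bs = \"cr\", k = %d) + ti(age, zg)%s",
    k_age, k_grad, if (multi) " + cohort" else ""))
  m <- mgcv::bam(fml, data = dat, method = "fREML")
  qs <- quantile(dat$zg, c(0.10, 0.90), type = 7)
  age_grid <- seq(min(age), max(age), length.out = n_grid)
  pred_at <- function(zg_val) {
    if (multi) {
      lv <- levels(dat$cohort)
      wts <- as.numeric(table(dat$cohort)[lv]); wts <- wts / sum(wts)
      ps <- vapply(lv, function(cc)
        as.numeric(predict(m, newdata = data.frame(
          age = age_grid, zg = zg_val,
          cohort = factor(cc, levels = lv)))), numeric(length(age_grid)))
      as.numeric(ps %*% wts)
    } else {
      as.numeric(predict(m, newdata = data.frame(age = age_grid, zg = zg_val)))
    }
  }
  delta <- pred_at(qs[2]) - pred_at(qs[1])
  med_age <- median(age)
  aq <- quantile(age, c(0.10, 0.90), type = 7)
  d_at <- function(a) stats::approx(age_grid, delta, xout = a)$y
  st <- summary(m)$s.table
  structure(list(
    delta_main = d_at(med_age),
    delta_age = d_at(aq[2]) - d_at(aq[1]),
    delta_curve = tibble::tibble(age = age_grid, delta = delta),
    p_smooth = unname(st[grep("s\\(zg\\)", rownames(st)), "p-value"]),
    p_interaction = unname(st[grep("^ti\\(", rownames(st)), "p-value"]),
    model = m), class = "gam_contrast")
}

#' @export
print.gam_contrast <- function(x, ...) {
  cat(sprintf("<gam_contrast> delta_main = %.3f, delta_age = %.3f\n",
              x$delta_main, x$delta_age))
  invisible(x)
}

#' Canonical association-unimodal axis from meta-analytic term maps
#'
#' Each term map is z-scored across parcels (`Z`); the axis is the z-scored
#' difference between the mean over association-class terms and the mean
#' over unimodal-class terms; excluded (intermediate) terms are ignored.
#' Swapping the two classes flips the axis sign.
#'
#' @param term_matrix parcel x term matrix with column names.
#' @param assoc_terms,unimodal_terms disjoint non-empty character vectors of
#'   term names.
#' @param excluded terms ignored entirely (default none).
#' @return a `canonical_axis` list: `axis` (z-scored parcel scores), `Z`,
#'   the term classes.
#' @export
canonical_axis <- function(term_matrix, assoc_terms, unimodal_terms,
                           excluded = character(0)) {
  check_matrix(term_matrix, "term_matrix")
  if (length(assoc_terms) == 0 || length(unimodal_terms) == 0)
    stop_param("both term classes must be non-empty")
  if (length(intersect(assoc_terms, unimodal_terms)))
    stop_param("term classes must be disjoint")
  miss <- setdiff(c(assoc_terms, unimodal_terms), colnames(term_matrix))
  if (length(miss)) stop_param("unknown terms: %s", paste(miss, collapse = ", "))
  z <- scale(term_matrix)
  contrast <- rowMeans(z[, assoc_terms, drop = FALSE]) -
    rowMeans(z[, unimodal_terms, drop = FALSE])
  if (sd(contrast) == 0) stop_param("zero-variance association-unimodal contrast")
  structure(list(axis = zscore(contrast), Z = z, assoc_terms = assoc_terms,
                 unimodal_terms = unimodal_terms, excluded = excluded),
            class = "canonical_axis")
}

#' Spearman alignment of a parcel axis map with each term map
#'
#' Average-rank Spearman correlation between the (standardized) parcel map
#' of each term and a parcellated gradient axis map; invariant to monotone
#' transforms of the axis map.
#'
#' @param parcel_axis_map numeric parcel vector (an individual's parcellated
#'   axis).
#' @param term_matrix parcel x term matrix.
#' @return tibble with `term` and `rho`, sorted by `rho`.
#' @export
term_axis_alignment <- function(parcel_axis_map, term_matrix) {
  check_matrix(term_matrix, "term_matrix")
  if (length(parcel_axis_map) != nrow(term_matrix)) stop_param("parcel counts differ")
  if (nrow(term_matrix) < 3) stop_param("need >= 3 parcels")
  if (sd(parcel_axis_map) == 0) stop_param("constant axis map")
  z <- scale(term_matrix)
  rho <- unname(apply(z, 2, function(col)
    cor(parcel_axis_map, col, method = "spearman")))
  dplyr::arrange(tibble::tibble(term = colnames(term_matrix), rho = rho),
                 dplyr::desc(.data$rho))
}

#' One-component PLS of a parcel phenotype on gene expression
#'
#' Gene columns and the phenotype are standardized across parcels
#' (all-missing genes dropped; remaining missing values median-imputed per
#' gene). The single latent component is the dominant singular direction of
#' the cross-covariance `X'y` (exact for one component and univariate `y`):
#' unit gene weights `w`, parcel scores `t = Xw`, oriented so
#' `corr(t, y) >= 0`. Signed per-gene coefficients (`w` scaled by the
#' regression of `y` on `t`) rank genes from most positive to most negative.
#'
#' @param X parcel x gene matrix.
#' @param y numeric parcel phenotype (non-constant).
#' @return a `pls_fit`: `weights`, `scores`, `coefficients`, `cor_ty`,
#'   `flipped`, `genes`.
#' @export
pls1_fit <- function(X, y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) < 3) stop_param("need >= 3 parcels")
  if (ncol(X) < 1) stop_param("need >= 1 gene")
  if (length(y) != nrow(X)) stop_param("phenotype length != parcel count")
  if (sd(y) == 0) stop_param("constant phenotype")
  all_na <- colSums(!is.na(X)) == 0
  if (any(all_na)) X <- X[, !all_na, drop = FALSE]
  if (ncol(X) < 1) stop_param("all gene columns missing")
  X <- apply(X, 2, function(col) {
    col[is.na(col)] <- median(col, na.rm = TRUE)
    col
  })
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) X <- X[, sds > 0, drop = FALSE]
  if (ncol(X) < 1) stop_param("no non-constant genes remain")
  zx <- scale(X)
  zy <- zscore(y)
  w <- as.numeric(crossprod(zx, zy))
  w <- w / sqrt(sum(w^2))
  t <- as.numeric(zx %*% w)
  r <- cor(t, zy)
  flipped <- r < 0
  if (flipped) { w <- -w; t <- -t; r <- -r }
  slope <- cov(zy, t) / var(t)
  structure(list(weights = setNames(w, colnames(zx)),
                 scores = t, coefficients = setNames(w * slope, colnames(zx)),
                 cor_ty = r, flipped = flipped, genes = colnames(zx),
                 X = zx, y = zy),
            class = "pls_fit")
}

#' Permutation test (and across-age FDR) for PLS gene-gradient coupling
#'
#' The null distribution shuffles the parcel labels of the phenotype and
#' refits the full one-component model per shuffle; the p-value is
#' `(exceedances + 1) / (n_perm + 1)` for `|corr(t, y)|`, so the minimum
#' attainable p is `1 / (n_perm + 1)`.
#'
#' @param X parcel x gene matrix.
#' @param y parcel phenotype.
#' @param n_perm number of shuffles (>= 19; the study convention is 5000).
#' @param seed integer seed.
#' @return a one-row tibble: `cor_ty`, `p`, `n_perm`.
#' @export
pls_permutation <- function(X, y, n_perm = 5000, seed = 1) {
  if (n_perm < 19) stop_param("n_perm must be >= 19")
  fit <- pls1_fit(X, y)
  set.seed(seed)
  # full refit per shuffle; the weight normalization cancels in the
  # correlation, so the statistic reduces to |cor(X X'y*, y*)|
  zx <- fit$X
  null <- vapply(seq_len(n_perm), function(i) {
    ys <- sample(fit$y)
    abs(cor(as.numeric(zx %*% crossprod(zx, ys)), ys))
  }, numeric(1))
  p <- (sum(null >= abs(fit$cor_ty)) + 1) / (n_perm + 1)
  tibble::tibble(cor_ty = fit$cor_ty, p = p, n_perm = n_perm)
}

#' PLS coupling across target ages with BH correction
#'
#' @param X parcel x gene matrix.
#' @param y_by_age named list of parcel phenotypes, one per target age.
#' @param n_perm permutations per age.
#' @param seed master seed (split per age).
#' @param q FDR level.
#' @return tibble with one row per age: `age`, `cor_ty`, `p`, `q_value`,
#'   `reject`.
#' @export
pls_enrichment <- function(X, y_by_age, n_perm = 5000, seed = 1, q = 0.05) {
  stopifnot(length(y_by_age) >= 1)
  rows <- purrr::imap(y_by_age, function(y, nm) {
    res <- pls_permutation(X, y, n_perm = n_perm,
                           seed = split_seed(seed, match(nm, names(y_by_age))))
    dplyr::mutate(res, age = nm, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  adj <- bh_fdr(out$p, q = q)
  out$q_value <- adj$q_value
  out$reject <- adj$reject
  out
}

#' Project an enriched gene set back onto cortex
#'
#' `s_i = sum_{g in G} w_g z(x_ig) / ||w_G||_2`, with per-gene z-scoring
#' across parcels; duplicate genes are counted once (set semantics). The
#' unweighted variant averages the z-scored member columns.
#'
#' @param X parcel x gene matrix.
#' @param weights named per-gene weights (e.g. `pls_fit$coefficients`).
#' @param gene_set non-empty character vector of member genes.
#' @param unweighted use the unweighted-mean variant.
#' @return numeric parcel score map.
#' @export
gene_set_score <- function(X, weights, gene_set, unweighted = FALSE) {
  if (!is.matrix(X)) X <- as.matrix(X)
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0) stop_param("empty gene set")
  miss <- setdiff(gene_set, colnames(X))
  if (length(miss)) stop_param("genes not in X: %s", paste(miss, collapse = ", "))
  z <- scale(X[, gene_set, drop = FALSE])
  if (unweighted) return(rowMeans(z))
  w <- weights[gene_set]
  if (any(is.na(w))) stop_param("missing weights for some member genes")
  as.numeric(z %*% w) / sqrt(sum(w^2))
}

#' Theme-level summary of term enrichment q-values
#'
#' Matches term names to themes with case-insensitive keyword rules and
#' reports, per theme and age, the median `-log10(q)` over member terms
#' passing the cut-off; 0 when no member term is significant. Unmatched
#' terms are reported in the `unmatched` attribute, not fatal.
#'
#' @param term_q_table tibble with columns `term`, `age`, `q`.
#' @param theme_rules named list mapping theme name to keyword vector.
#' @param cutoff significance cut-off on q (default 0.05).
#' @return theme x age tibble (long format: `theme`, `age`, `score`).
#' @export
theme_summary <- function(term_q_table, theme_rules, cutoff = 0.05) {
  stopifnot(all(c("term", "age", "q") %in% names(term_q_table)),
            length(theme_rules) >= 1)
  match_theme <- function(term) {
    hits <- names(theme_rules)[vapply(theme_rules, function(kw)
      any(vapply(kw, function(k) grepl(k, term, ignore.case = TRUE),
                 logical(1))), logical(1))]
    if (length(hits)) hits[1] else NA_character_
  }
  tq <- dplyr::mutate(term_q_table,
                      theme = vapply(.data$term, match_theme, character(1)))
  unmatched <- unique(tq$term[is.na(tq$theme)])
  grid <- tidyr::expand_grid(theme = names(theme_rules),
                             age = unique(tq$age))
  out <- dplyr::left_join(
    grid,
    tq |>
      dplyr::filter(!is.na(.data$theme), .data$q <= cutoff) |>
      dplyr::group_by(.data$theme, .data$age) |>
      dplyr::summarise(score = median(-log10(.data$q)), .groups = "drop"),
    by = c("theme", "age")) |>
    dplyr::mutate(score = dplyr::coalesce(.data$score, 0))
  attr(out, "unmatched") <- unmatched
  out
}
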