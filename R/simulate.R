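#' Emit a synthetic functional connectivity matrix from planted coordinates
#'
#' Off-diagonal connectivity is a monotone decreasing Gaussian kernel of the
#' Euclidean distance between planted embedding coordinates,
#' `r_max * exp(-d^2 / sigma^2)`, plus an additive cohort offset and
#' symmetric Gaussian noise, clipped to `[-1, 1]`; the diagonal is 1. The
#' kernel scale `sigma` is fixed (not data-adaptive) so that the planted
#' amplitude laws survive into the connectivity scale.
#'
#' @param truth_coords vertex x k coordinate matrix (unmasked vertices).
#' @param cohort_offset additive offset on the connectivity scale.
#' @param noise_sd s.d. of the symmetric entrywise noise (>= 0).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param r_max kernel ceiling keeping entries correlation-like.
#' @param sigma kernel length scale.
#' @return a symmetric vertex x vertex matrix with unit diagonal.
#' @export
simulate_fc <- function(truth_coords, cohort_offset = 0, noise_sd = 0,
                        seed = 1, r_max = 0.8, sigma = 1) {
  check_matrix(truth_coords, "truth_coords")
  if (noise_sd < 0) stop_param("noise_sd must be >= 0")
  d2 <- as.matrix(dist(truth_coords))^2
  fc <- r_max * exp(-d2 / sigma^2) + cohort_offset
  if (noise_sd > 0) {
    set.seed(seed)
    n <- nrow(fc)
    e <- matrix(0, n, n)
    e[upper.tri(e)] <- rnorm(n * (n - 1) / 2, sd = noise_sd)
    fc <- fc + e + t(e)
  }
  fc <- clip(fc, -1, 1)
  diag(fc) <- 1
  fc
}

#' Emit synthetic BOLD-like time series with a target correlation structure
#'
#' Draws i.i.d. Gaussian timepoints and colours them with the matrix square
#' root of the target correlation, after a nearest-positive-semidefinite
#' repair (eigenvalue clipping at 1e-8) and rescaling to unit diagonal. The
#' empirical Pearson correlation of the output converges to the target as
#' `n_timepoints` grows.
#'
#' @param target_fc symmetric target correlation matrix.
#' @param n_timepoints number of timepoints (>= 3).
#' @param seed integer seed.
#' @return an `n_timepoints` x vertex matrix.
#' @export
simulate_timeseries <- function(target_fc, n_timepoints, seed = 1) {
  check_matrix(target_fc, "target_fc")
  if (n_timepoints < 3) stop_param("n_timepoints must be >= 3, got %s", n_timepoints)
  eg <- eigen((target_fc + t(target_fc)) / 2, symmetric = TRUE)
  lam <- pmax(eg$values, 1e-8)
  psd <- eg$vectors %*% (lam * t(eg$vectors))
  s <- sqrt(diag(psd))
  psd <- psd / tcrossprod(s)
  eg <- eigen(psd, symmetric = TRUE)
  rt <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  set.seed(seed)
  matrix(rnorm(n_timepoints * nrow(psd)), n_timepoints) %*% rt
}

#' Emit synthetic microstructural feature maps coupled to planted axes
#'
#' Each feature is a coupling-weighted mix of one planted axis (assigned
#' cyclically over the axes) and independent vertex noise:
#' `coupling * z(axis) + (1 - coupling) * z(noise)`. Default 11 features,
#' mirroring a cortical-microstructure battery (thickness, myelination,
#' diffusion indices, ...).
#'
#' @param truth_coords vertex x 3 planted coordinates.
#' @param n_features number of features.
#' @param coupling mixing weight in `[0, 1]`.
#' @param seed integer seed.
#' @return vertex x `n_features` matrix; attribute `axis` records the axis
#'   each feature is tied to.
#' @export
simulate_features <- function(truth_coords, n_features = 11, coupling = 0.5,
                              seed = 1) {
  check_matrix(truth_coords, "truth_coords")
  if (coupling < 0 || coupling > 1) stop_param("coupling must be in [0, 1]")
  n <- nrow(truth_coords)
  set.seed(seed)
  axis <- rep_len(seq_len(ncol(truth_coords)), n_features)
  out <- vapply(seq_len(n_features), function(f) {
    coupling * zscore(truth_coords[, axis[f]]) +
      (1 - coupling) * zscore(rnorm(n))
  }, numeric(n))
  colnames(out) <- sprintf("feat_%02d", seq_len(n_features))
  attr(out, "axis") <- axis
  out
}

#' Emit a synthetic parcel x gene expression matrix
#'
#' A `frac_coupled` share of genes correlate with the planted parcel axis,
#' with random sign and random strength in `[0.4, 1]`; the remaining genes
#' are pure noise.
#'
#' @param parcel_truth numeric vector of planted parcel-level axis values.
#' @param n_genes number of genes (>= 2).
#' @param frac_coupled share of coupled genes in `[0, 1]`.
#' @param noise_sd s.d. of gene-level noise (0 gives noiseless coupled genes).
#' @param seed integer seed.
#' @return parcel x gene matrix; attribute `coupled` flags coupled genes.
#' @export
simulate_expression <- function(parcel_truth, n_genes, frac_coupled = 0.5,
                                noise_sd = 1, seed = 1) {
  if (length(parcel_truth) < 3) stop_param("need >= 3 parcels, got %d", length(parcel_truth))
  if (n_genes < 2) stop_param("n_genes must be >= 2")
  if (frac_coupled < 0 || frac_coupled > 1) stop_param("frac_coupled must be in [0, 1]")
  p <- length(parcel_truth)
  zt <- zscore(parcel_truth)
  set.seed(seed)
  n_c <- round(frac_coupled * n_genes)
  coupled <- seq_len(n_genes) <= n_c
  out <- vapply(seq_len(n_genes), function(g) {
    base <- if (coupled[g]) sample(c(-1, 1), 1) * runif(1, 0.4, 1) * zt else rep(0, p)
    base + noise_sd * rnorm(p)
  }, numeric(p))
  colnames(out) <- sprintf("gene_%04d", seq_len(n_genes))
  attr(out, "coupled") <- coupled
  out
}

#' Emit a synthetic parcel x term meta-analytic matrix
#'
#' Association-class terms load positively on the planted parcel axis,
#' unimodal-class terms negatively, and intermediate terms near zero.
#'
#' @param parcel_truth numeric vector of planted parcel-level axis values.
#' @param term_spec tibble with columns `term`, `class` (one of
#'   `association`, `unimodal`, `intermediate`) and `loading` (>= 0).
#' @param noise_sd s.d. of term-level parcel noise.
#' @param seed integer seed.
#' @return parcel x term matrix.
#' @export
simulate_term_maps <- function(parcel_truth, term_spec, noise_sd = 0.1, seed = 1) {
  if (is.null(term_spec) || nrow(term_spec) == 0) stop_param("empty term_spec")
  stopifnot(all(c("term", "class", "loading") %in% names(term_spec)),
            all(term_spec$class %in% c("association", "unimodal", "intermediate")))
  p <- length(parcel_truth)
  zt <- zscore(parcel_truth)
  dir <- c(association = 1, unimodal = -1, intermediate = 0)
  set.seed(seed)
  out <- vapply(seq_len(nrow(term_spec)), function(t) {
    dir[[term_spec$class[t]]] * term_spec$loading[t] * zt + noise_sd * rnorm(p)
  }, numeric(p))
  colnames(out) <- term_spec$term
  out
}

#' Emit synthetic behaviour scores from gradient metrics
#'
#' Scores follow a planted linear predictor on z-scored age and metric, an
#' optional age x metric interaction, an optional per-individual random
#' intercept, and Gaussian noise. With `norm = TRUE` the scores are rescaled
#' to the normed convention of standardized test batteries (mean 100,
#' s.d. 15); note that norming rescales the planted slope.
#'
#' @param metric_table tibble with one row per scan, containing `age_years`,
#'   `individual_id` and the metric column.
#' @param metric name of the metric column.
#' @param beta_grad planted metric slope (on the raw score scale).
#' @param beta_age planted age slope.
#' @param interaction planted age x metric interaction coefficient.
#' @param indiv_sd s.d. of the individual random intercept.
#' @param noise_sd residual s.d.
#' @param norm rescale scores to mean 100, s.d. 15.
#' @param score_name name of the emitted score column.
#' @param seed integer seed.
#' @return the input table with the score column appended.
#' @export
simulate_scores <- function(metric_table, metric, beta_grad, beta_age = 0,
                            interaction = 0, indiv_sd = 0, noise_sd = 1,
                            norm = FALSE, score_name = "score", seed = 1) {
  req <- c("age_years", "individual_id", metric)
  miss <- setdiff(req, names(metric_table))
  if (length(miss)) stop_param("metric_table lacks columns: %s", paste(miss, collapse = ", "))
  stopifnot(all(is.finite(c(beta_grad, beta_age, interaction, indiv_sd, noise_sd))))
  set.seed(seed)
  za <- zscore(metric_table$age_years)
  zg <- zscore(metric_table[[metric]])
  ind <- factor(metric_table$individual_id)
  b <- rnorm(nlevels(ind), sd = indiv_sd)
  y <- beta_age * za + beta_grad * zg + interaction * za * zg +
    b[as.integer(ind)] + rnorm(nrow(metric_table), sd = noise_sd)
  if (norm) y <- 100 + 15 * (y - mean(y)) / sd(y)
  metric_table[[score_name]] <- y
  metric_table
}

#' Emit a scan-level metric series directly from a planted lifespan law
#'
#' The scan-level shortcut emission used by trajectory-recovery and
#' harmonization checks: `y = law(age) + cohort offset + individual intercept
#' + heteroscedastic noise`. Cohort offsets default to +/- 0.5 residual s.d.
#' across the three default cohorts, and the noise s.d. grows mildly with
#' age.
#'
#' @param cohort a `CohortTable` tibble.
#' @param law a [lifespan_law()] (or any function of age).
#' @param cohort_offsets named numeric offsets (response units).
#' @param noise_sd_law function of age giving the residual s.d.
#' @param indiv_sd s.d. of per-individual intercepts.
#' @param seed integer seed.
#' @return the cohort table with columns `y_true` and `y` appended.
#' @export
simulate_metric_series <- function(cohort, law,
                                   cohort_offsets = c(infant = 0.05, dev = 0, adult = -0.05),
                                   noise_sd_law = function(age) 0.1 * (1 + age / 100),
                                   indiv_sd = 0.04, seed = 1) {
  stopifnot(all(c("age_years", "cohort_id", "individual_id") %in% names(cohort)))
  missing_coh <- setdiff(unique(cohort$cohort_id), names(cohort_offsets))
  if (length(missing_coh))
    stop_param("no offset for cohort(s): %s", paste(missing_coh, collapse = ", "))
  set.seed(seed)
  ind <- factor(cohort$individual_id)
  b <- rnorm(nlevels(ind), sd = indiv_sd)
  mu <- law(cohort$age_years)
  y <- mu + cohort_offsets[cohort$cohort_id] + b[as.integer(ind)] +
    rnorm(nrow(cohort), sd = noise_sd_law(cohort$age_years))
  cohort$y_true <- mu
  cohort$y <- unname(y)
  cohort
}
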