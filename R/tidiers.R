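#' @importFrom generics tidy glance
NULL

#' Tidy a fitted lifespan trajectory
#'
#' One row per model term (smooth and random-effect terms), with effective
#' degrees of freedom and approximate p-values.
#'
#' @param x a `smooth_fit`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy smooth_fit
#' @export
tidy.smooth_fit <- function(x, ...) {
  st <- summary(x$model)$s.table
  tibble::tibble(term = rownames(st), edf = st[, "edf"],
                 ref_df = st[, "Ref.df"], statistic = st[, 3],
                 p_value = st[, "p-value"])
}

#' One-row summary of a fitted lifespan trajectory
#'
#' @param x a `smooth_fit`.
#' @param ... unused.
#' @return a tibble with sample size, total edf, adjusted R^2, REML score
#'   and residual s.d.
#' @method glance smooth_fit
#' @export
glance.smooth_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(n = nrow(x$data), k = x$k, edf_total = sum(x$model$edf),
                 adj_r_squared = s$r.sq, reml = as.numeric(x$model$gcv.ubre),
                 sigma = sqrt(s$scale))
}

#' Tidy a one-component PLS fit: per-gene weights and coefficients
#'
#' @param x a `pls_fit`.
#' @param ... unused.
#' @return tibble sorted by signed coefficient (most positive first).
#' @method tidy pls_fit
#' @export
tidy.pls_fit <- function(x, ...) {
  out <- tibble::tibble(gene = x$genes, weight = unname(x$weights),
                        coefficient = unname(x$coefficients))
  dplyr::arrange(out, dplyr::desc(.data$coefficient))
}

#' One-row summary of a one-component PLS fit
#'
#' @param x a `pls_fit`.
#' @param ... unused.
#' @return a tibble with parcel count, gene count, in-sample corr(t, y) and
#'   the orientation flag.
#' @method glance pls_fit
#' @export
glance.pls_fit <- function(x, ...) {
  tibble::tibble(n_parcels = length(x$scores), n_genes = length(x$genes),
                 cor_ty = x$cor_ty, flipped = x$flipped)
}

#' @method tidy peak_age
#' @export
tidy.peak_age <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, hdi_lo = x$hdi[1], hdi_hi = x$hdi[2],
                 level = x$level, boundary = x$boundary)
}
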