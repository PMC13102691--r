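#' Age-bin-balanced individual weights for the lifespan template
#'
#' Ages are square-root transformed; the transformed range is split into
#' `n_bins` equal-width bins; each non-empty bin receives equal total weight,
#' split uniformly among the individuals in it; weights are normalized to
#' sum 1. Empty bins (possible at desk scale) have their weight
#' redistributed proportionally across non-empty bins.
#'
#' @param ages numeric vector of ages (> 0), one per individual.
#' @param n_bins number of bins on the transformed scale (default 10).
#' @return numeric weights summing to 1.
#' @export
age_bin_weights <- function(ages, n_bins = 10) {
  stopifnot(all(ages > 0), n_bins >= 1)
  ta <- sqrt(ages)
  brk <- seq(min(ta), max(ta), length.out = n_bins + 1)
  bin <- findInterval(ta, brk, rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- tabulate(bin, nbins = n_bins)
  nonempty <- sum(cnt > 0)
  w <- 1 / (nonempty * cnt[bin])
  w / sum(w)
}

#' Lifespan gradient template by weighted PCA
#'
#' Stacks every individual's gradient set into one
#' `(N_ind x N_grad) x N_vert` matrix, standardizes each vertex column with
#' the row weights (weighted mean 0, weighted variance 1), and extracts the
#' top `n_keep` weighted principal axes. Row weights are the individual's
#' age-bin-balanced weight ([age_bin_weights()]), so sparsely sampled age
#' ranges contribute equally; standardization uses the same weights, which
#' makes the template exactly invariant to duplicating scans versus doubling
#' their weight. The first three axes are named SA, VS and MR.
#'
#' Axis polarity is a convention: each axis is oriented so its mean over the
#' corresponding pole vertex set is positive (`pole_sets`), or, absent pole
#' sets, so its largest-magnitude loading is positive.
#'
#' @param embedding_sets list of `embedding_set`s (or vertex x n_grad
#'   matrices), one per individual.
#' @param ages ages (one per individual) used for bin weighting.
#' @param n_bins number of square-root-age bins (default 10).
#' @param n_keep number of template axes retained (default 10).
#' @param weights optional explicit per-individual weights overriding the
#'   age binning.
#' @param pole_sets optional list of vertex-index vectors fixing axis signs.
#' @return a `gradient_template`: list with `axes` (vertex x n_keep,
#'   orthonormal columns), `weights`, `n_bins`, `pole_sets`.
#' @export
wpca_template <- function(embedding_sets, ages, n_bins = 10, n_keep = 10,
                          weights = NULL, pole_sets = NULL) {
  coords <- lapply(embedding_sets, function(e)
    if (inherits(e, "embedding_set")) e$coords else e)
  n_ind <- length(coords)
  stopifnot(n_ind >= 1, length(ages) == n_ind)
  nv <- nrow(coords[[1]])
  ng <- ncol(coords[[1]])
  ok <- vapply(coords, function(m) nrow(m) == nv && ncol(m) == ng, logical(1))
  if (!all(ok)) stop_param("inconsistent embedding dimensions across individuals")
  if (n_ind * ng < n_keep)
    stop_param("fewer stacked rows (%d) than n_keep (%d)", n_ind * ng, n_keep)
  if (is.null(weights)) {
    if (length(unique(ages)) < n_bins && n_bins > 1)
      message("fewer distinct ages than bins; empty-bin weight redistributed")
    weights <- age_bin_weights(ages, n_bins)
  }
  stopifnot(length(weights) == n_ind, all(weights > 0))
  weights <- weights / sum(weights)

  x <- do.call(rbind, lapply(coords, t))          # (n_ind * ng) x nv
  w <- rep(weights, each = ng)
  w <- w / sum(w)
  wm <- colSums(w * x)
  xc <- sweep(x, 2, wm)
  wv <- colSums(w * xc^2)
  keep_col <- wv > 1e-24
  z <- matrix(0, nrow(x), ncol(x))
  z[, keep_col] <- sweep(xc[, keep_col, drop = FALSE], 2, sqrt(wv[keep_col]), `/`)

  sv <- svd(sqrt(w) * z[, keep_col, drop = FALSE], nu = 0, nv = n_keep)
  axes <- matrix(0, nv, n_keep)
  axes[keep_col, ] <- sv$v
  axes <- vapply(seq_len(n_keep), function(k) {
    a <- axes[, k]
    if (!is.null(pole_sets) && k <= length(pole_sets) && length(pole_sets[[k]])) {
      if (mean(a[pole_sets[[k]]]) < 0) -a else a
    } else fix_sign(a)
  }, numeric(nv))
  colnames(axes) <- axis_labels(n_keep)
  structure(list(axes = axes, weights = weights, n_bins = n_bins,
                 pole_sets = pole_sets, singular_values = sv$d[seq_len(n_keep)]),
            class = "gradient_template")
}

axis_labels <- function(k) {
  base <- c("SA", "VS", "MR")
  if (k <= 3) base[seq_len(k)] else c(base, sprintf("G%d", 4:k))
}

#' @export
print.gradient_template <- function(x, ...) {
  cat(sprintf("<gradient_template> %d vertices x %d axes (%s, ...)\n",
              nrow(x$axes), ncol(x$axes),
              paste(head(colnames(x$axes), 3), collapse = ", ")))
  invisible(x)
}

#' One-shot orthogonal Procrustes alignment
#'
#' Finds the orthogonal rotation `R` minimizing `||source R - target||_F`
#' with no scaling and no mean centring (SVD of the cross-product). The
#' orthogonal group includes reflections, so sign flips are absorbed.
#'
#' @param source,target matrices with the same row count; a target with
#'   fewer columns yields a partial rotation (orthonormal columns) mapping
#'   the full source set onto the target subspace.
#' @param tol relative singular-value tolerance below which the
#'   cross-product is declared rank-deficient (sign ambiguity unresolvable).
#' @return an `alignment_result`: `rotation`, `aligned_coords`, and
#'   `axis_cosine` (per-axis cosine of aligned columns to target columns).
#' @export
procrustes <- function(source, target, tol = 1e-10) {
  check_matrix(source, "source"); check_matrix(target, "target")
  if (nrow(source) != nrow(target) || ncol(target) > ncol(source))
    stop_param("target must have the same rows and no more columns than source")
  if (any(colSums(target^2) == 0)) stop_param("target has an all-zero column")
  sv <- svd(crossprod(source, target))
  if (min(sv$d) < tol * max(sv$d))
    stop_param("rank-deficient cross-product: rotation has unresolvable sign ambiguity")
  rotation <- sv$u %*% t(sv$v)
  aligned <- source %*% rotation
  cosines <- vapply(seq_len(ncol(target)), function(k)
    sum(aligned[, k] * target[, k]) /
      sqrt(sum(aligned[, k]^2) * sum(target[, k]^2)), numeric(1))
  structure(list(rotation = rotation, aligned_coords = aligned,
                 axis_cosine = cosines),
            class = "alignment_result")
}

#' Align an individual embedding to the lifespan template
#'
#' Rotates the individual's gradient set into the template frame by one-shot
#' Procrustes over all retained axes. Axis names are inherited from the
#' template; the pre-alignment eigenvalues are preserved unchanged.
#'
#' @param embedding an unaligned `embedding_set`.
#' @param template a `gradient_template`.
#' @return the aligned `embedding_set` (with `alignment` diagnostics).
#' @export
align_to_template <- function(embedding, template) {
  stopifnot(inherits(embedding, "embedding_set"),
            inherits(template, "gradient_template"))
  if (isTRUE(embedding$aligned)) stop_param("embedding is already aligned")
  if (nrow(embedding$coords) != nrow(template$axes))
    stop_param("vertex counts differ: embedding %d vs template %d",
               nrow(embedding$coords), nrow(template$axes))
  fit <- procrustes(embedding$coords, template$axes)
  out <- embedding
  out$coords <- fit$aligned_coords
  colnames(out$coords) <- colnames(template$axes)
  out$aligned <- TRUE
  out$axis_names <- colnames(template$axes)
  out$alignment <- fit
  out
}

#' Align a structural embedding to an individual's functional embedding
#'
#' Procrustes rotation of the structural gradient set onto the same
#' individual's template-aligned functional gradients; downstream
#' structure-function coupling uses these aligned structural coordinates.
#'
#' @param structural_embedding an `embedding_set` from [structural_affinity()]
#'   input.
#' @param aligned_functional the individual's template-aligned functional
#'   `embedding_set`.
#' @return the aligned structural `embedding_set`.
#' @export
align_structural <- function(structural_embedding, aligned_functional) {
  stopifnot(inherits(structural_embedding, "embedding_set"),
            inherits(aligned_functional, "embedding_set"))
  if (!isTRUE(aligned_functional$aligned))
    stop_param("functional embedding must be template-aligned first")
  k <- min(ncol(structural_embedding$coords), ncol(aligned_functional$coords))
  fit <- procrustes(structural_embedding$coords[, seq_len(k), drop = FALSE],
                    aligned_functional$coords[, seq_len(k), drop = FALSE])
  out <- structural_embedding
  out$coords <- fit$aligned_coords
  colnames(out$coords) <- colnames(aligned_functional$coords)[seq_len(k)]
  out$aligned <- TRUE
  out$axis_names <- colnames(out$coords)
  out$alignment <- fit
  out
}
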