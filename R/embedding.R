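#' Mean functional connectivity from vertex time series
#'
#' Computes the Pearson correlation matrix of each acquisition and averages
#' them entrywise (acquisitions from the same session are treated as
#' replicates of one connectome).
#'
#' @param timeseries_list a list of timepoints x vertex matrices (or a single
#'   matrix), all with the same vertex count and >= 3 timepoints.
#' @return symmetric vertex x vertex correlation matrix with unit diagonal.
#' @export
compute_fc <- function(timeseries_list) {
  if (is.matrix(timeseries_list)) timeseries_list <- list(timeseries_list)
  stopifnot(length(timeseries_list) >= 1)
  nv <- ncol(timeseries_list[[1]])
  mats <- lapply(seq_along(timeseries_list), function(i) {
    ts <- timeseries_list[[i]]
    check_matrix(ts, sprintf("timeseries[[%d]]", i))
    if (nrow(ts) < 3) stop_param("acquisition %d has < 3 timepoints", i)
    if (ncol(ts) != nv) stop_param("acquisition %d has %d vertices, expected %d", i, ncol(ts), nv)
    sds <- apply(ts, 2, sd)
    if (any(sds == 0))
      stop_param("zero-variance time series at vertex %d (acquisition %d)",
                 which(sds == 0)[1], i)
    cor(ts)
  })
  fc <- Reduce(`+`, mats) / length(mats)
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  fc
}

#' Row-wise thresholding of a connectivity matrix
#'
#' Per row, retains the largest `ceiling(density * (n - 1))` off-diagonal
#' entries by signed value (weights kept, not binarized) and zeroes the rest;
#' the diagonal is retained. Ties at the threshold boundary are broken by
#' lowest column index. The output is generally asymmetric; symmetry is
#' restored implicitly by the subsequent cosine-similarity step.
#'
#' @param fc vertex x vertex matrix.
#' @param density fraction of off-diagonal entries retained per row,
#'   in `(0, 1]` (default 0.10).
#' @return the thresholded matrix.
#' @export
threshold_rows <- function(fc, density = 0.10) {
  check_matrix(fc, "fc")
  if (density <= 0 || density > 1) stop_param("density must be in (0, 1], got %s", density)
  n <- nrow(fc)
  keep <- ceiling(density * (n - 1))
  out <- fc
  idx <- seq_len(n)
  for (i in idx) {
    off <- idx[-i]
    v <- fc[i, off]
    # order by decreasing value, ties by lowest column index
    ord <- off[order(-v, off)]
    drop <- ord[-seq_len(keep)]
    out[i, drop] <- 0
  }
  out
}

#' Normalized-angle affinity between connectivity rows
#'
#' `affinity(i, j) = 1 - acos(cosine(row_i, row_j)) / pi`, with the cosine
#' clipped to `[-1, 1]`. Symmetric by construction even for asymmetric
#' (row-thresholded) input, and invariant to uniform positive rescaling of
#' rows. Identical rows map to 1, orthogonal rows to 0.5, opposite rows to 0.
#'
#' @param mat vertex x vertex matrix with no all-zero row.
#' @return an affinity matrix in `[0, 1]` with unit diagonal.
#' @export
normalized_angle <- function(mat) {
  check_matrix(mat, "mat")
  nrm <- sqrt(rowSums(mat^2))
  if (any(nrm == 0)) stop_param("all-zero row at vertex %d", which(nrm == 0)[1])
  cs <- tcrossprod(mat / nrm)
  cs <- clip((cs + t(cs)) / 2, -1, 1)
  aff <- 1 - acos(cs) / pi
  diag(aff) <- 1
  aff
}

#' Mean FC degree of a thresholded connectivity matrix
#'
#' The average across vertices of the sum of retained off-diagonal weights in
#' the row-thresholded matrix.
#'
#' @param thresholded output of [threshold_rows()].
#' @return a scalar.
#' @export
mean_fc_degree <- function(thresholded) {
  check_matrix(thresholded, "thresholded")
  mean(rowSums(thresholded) - diag(thresholded))
}

#' Structural affinity from multivariate microstructural features
#'
#' Features are z-scored per column; affinity is the vertex-pair Pearson
#' correlation across the feature vector, with negative correlations clipped
#' to zero (the morphometric-similarity-network construction).
#'
#' @param features vertex x feature matrix (>= 2 non-constant features).
#' @return an affinity matrix in `[0, 1]` with unit diagonal.
#' @export
structural_affinity <- function(features) {
  check_matrix(features, "features")
  sds <- apply(features, 2, sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance feature column(s)", sum(sds == 0)))
    features <- features[, sds > 0, drop = FALSE]
  }
  if (ncol(features) < 2) stop_param("fewer than 2 non-constant features remain")
  z <- scale(features)
  aff <- cor(t(z))
  aff <- pmax(aff, 0)
  aff <- (aff + t(aff)) / 2
  diag(aff) <- 1
  aff
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Anisotropic diffusion-map embedding: the affinity is degree-normalized
#' with exponent `alpha`, turned into a row-stochastic Markov operator, and
#' eigendecomposed through its symmetric conjugate. The trivial constant
#' eigenvector is dropped; coordinates are the next `n_components`
#' eigenvectors, scaled by `lambda^t` for diffusion time `t > 0` or by the
#' multi-scale weighting `lambda / (1 - lambda)` when `diffusion_time = 0`
#' (the automatic convention). Coordinates are deterministic up to per-axis
#' sign; a fixed sign convention (largest-magnitude loading positive) is
#' applied. Eigenvalues are returned as computed, before any alignment.
#'
#' @param affinity symmetric non-negative matrix, connected as a graph.
#' @param n_components number of embedding axes (default 10).
#' @param alpha anisotropic normalization exponent (default 0.5).
#' @param diffusion_time diffusion time; 0 selects automatic multi-scale
#'   weighting.
#' @return an `embedding_set`: list with `coords` (vertex x n_components),
#'   `eigenvalues`, `aligned = FALSE`, `axis_names = NULL`.
#' @export
diffusion_embedding <- function(affinity, n_components = 10, alpha = 0.5,
                                diffusion_time = 0) {
  check_matrix(affinity, "affinity")
  n <- nrow(affinity)
  if (max(abs(affinity - t(affinity))) > 1e-10)
    stop_param("affinity must be symmetric")
  if (any(affinity < 0)) stop_param("affinity must be non-negative")
  comp <- graph_components(affinity > 0)
  if (max(comp) > 1) {
    sizes <- table(comp)
    stop_param("affinity graph is disconnected (component sizes: %s)",
               paste(sizes, collapse = ", "))
  }
  d <- rowSums(affinity)
  w <- affinity / outer(d^alpha, d^alpha)
  d1 <- rowSums(w)
  inv_sqrt <- 1 / sqrt(d1)
  s <- w * outer(inv_sqrt, inv_sqrt)   # symmetric conjugate of the Markov operator
  eg <- eigen((s + t(s)) / 2, symmetric = TRUE)
  if (n_components > n - 1) stop_param("n_components must be < n_vert")
  lam <- eg$values[seq_len(n_components + 1)]
  psi <- inv_sqrt * eg$vectors[, seq_len(n_components + 1), drop = FALSE]
  # normalize by the trivial eigenvector (constant up to scale)
  psi <- psi / psi[, 1]
  lam <- lam[-1]
  psi <- psi[, -1, drop = FALSE]
  scaling <- if (diffusion_time > 0) lam^diffusion_time else lam / (1 - lam)
  coords <- sweep(psi, 2, scaling, `*`)
  coords <- apply(coords, 2, fix_sign)
  structure(list(coords = coords, eigenvalues = lam, aligned = FALSE,
                 axis_names = NULL),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set> %d vertices x %d axes (%s)\n",
              nrow(x$coords), ncol(x$coords),
              if (isTRUE(x$aligned)) paste("aligned:", paste(head(x$axis_names, 3), collapse = ", "))
              else "unaligned"))
  invisible(x)
}

# connected components of a logical adjacency matrix (BFS)
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    frontier <- start
    comp[start] <- cur
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0)
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}
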