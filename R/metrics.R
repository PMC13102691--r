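#' Gradient dispersion
#'
#' Mean Euclidean distance between each vertex's embedding coordinate and the
#' embedding centroid, over unmasked vertices — the global degree of
#' connectivity differentiation in the (SA, VS, MR) embedding.
#'
#' @param coords vertex x 3 (or more) coordinate matrix; only the first three
#'   axes are used.
#' @param mask optional logical vector; `TRUE` vertices are excluded.
#' @return a non-negative scalar.
#' @export
dispersion <- function(coords, mask = NULL) {
  coords <- metric_coords(coords, mask)
  ctr <- colMeans(coords)
  mean(sqrt(rowSums(sweep(coords, 2, ctr)^2)))
}

metric_coords <- function(coords, mask, n_axes = 3) {
  check_matrix(coords, "coords")
  if (!is.null(mask)) coords <- coords[!mask, , drop = FALSE]
  if (nrow(coords) < 1) stop_param("empty vertex set")
  if (ncol(coords) < n_axes) stop_param("need >= %d axes, got %d", n_axes, ncol(coords))
  coords[, seq_len(n_axes), drop = FALSE]
}

#' Inter-vigintile axis range
#'
#' Spread of one embedding axis between two percentiles (defaults: 5th to
#' 95th), computed with linear interpolation between order statistics.
#'
#' @param coords coordinate matrix (or a numeric vector).
#' @param axis column index of the axis.
#' @param lo,hi percentile bounds in `[0, 100]`, `lo < hi`.
#' @param mask optional logical exclusion vector.
#' @return a non-negative scalar.
#' @export
axis_range <- function(coords, axis = 1, lo = 5, hi = 95, mask = NULL) {
  if (is.numeric(coords) && is.null(dim(coords))) coords <- matrix(coords, ncol = 1)
  check_matrix(coords, "coords")
  if (axis < 1 || axis > ncol(coords)) stop_param("axis %s out of bounds", axis)
  if (!(lo < hi)) stop_param("lo must be < hi")
  x <- coords[, axis]
  if (!is.null(mask)) x <- x[!mask]
  unname(diff(quantile(x, c(lo, hi) / 100, type = 7)))
}

#' Cosine similarity of an individual axis to its template axis
#'
#' Scale-invariant vertex-wise correspondence of one individual gradient map
#' to the group template map, over unmasked vertices.
#'
#' @param coords individual coordinate matrix (or vector).
#' @param template template axis matrix (or vector).
#' @param axis axis index used for both.
#' @param mask optional logical exclusion vector.
#' @return cosine in `[-1, 1]`.
#' @export
cosine_to_template <- function(coords, template, axis = 1, mask = NULL) {
  v <- if (is.null(dim(coords))) coords else coords[, axis]
  t <- if (is.null(dim(template))) template else template[, axis]
  if (length(v) != length(t)) stop_param("vertex counts differ")
  if (!is.null(mask)) { v <- v[!mask]; t <- t[!mask] }
  nv <- sqrt(sum(v^2)); nt <- sqrt(sum(t^2))
  if (nv == 0 || nt == 0) stop_param("zero-norm vector in cosine similarity")
  sum(v * t) / (nv * nt)
}

#' Per-network embedding centroids
#'
#' @param coords vertex x 3 coordinate matrix.
#' @param labels integer network label per vertex (`NA` = masked).
#' @return network x 3 matrix of mean coordinates (rownames = labels).
#' @export
network_centroids <- function(coords, labels) {
  coords <- metric_coords(coords, mask = is.na(labels))
  labels <- labels[!is.na(labels)]
  nets <- sort(unique(labels))
  out <- t(vapply(nets, function(g) {
    idx <- labels == g
    if (!any(idx)) stop_param("empty network %s", g)
    colMeans(coords[idx, , drop = FALSE])
  }, numeric(3)))
  rownames(out) <- nets
  out
}

#' Within-network dispersion
#'
#' Mean Euclidean distance from each vertex to its own network centroid,
#' per network.
#'
#' @inheritParams network_centroids
#' @return named numeric vector, one value per network.
#' @export
within_network_dispersion <- function(coords, labels) {
  coords <- metric_coords(coords, mask = is.na(labels))
  labels <- labels[!is.na(labels)]
  nets <- sort(unique(labels))
  setNames(vapply(nets, function(g) {
    dispersion(coords[labels == g, , drop = FALSE])
  }, numeric(1)), nets)
}

#' Dispersion-normalized between-network embedding distance
#'
#' For each pair of networks, the mean Euclidean distance over all
#' cross-network vertex pairs, divided by the global gradient dispersion;
#' the diagonal is zero.
#'
#' @inheritParams network_centroids
#' @return symmetric network x network matrix.
#' @export
between_network_distance <- function(coords, labels) {
  coords <- metric_coords(coords, mask = is.na(labels))
  labels <- labels[!is.na(labels)]
  disp <- dispersion(coords)
  if (disp == 0) stop_param("global dispersion is zero")
  nets <- sort(unique(labels))
  k <- length(nets)
  dmat <- as.matrix(dist(coords))
  out <- matrix(0, k, k, dimnames = list(nets, nets))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    m <- mean(dmat[labels == nets[i], labels == nets[j], drop = FALSE])
    out[i, j] <- out[j, i] <- m / disp
  }
  out
}

#' Vertex-wise Pearson coupling between an axis and a cortical map
#'
#' Pearson correlation across unmasked cortical vertices, used for
#' axis-microstructure coupling and similar map-to-map comparisons.
#'
#' @param axis_values numeric vertex vector (e.g. one gradient axis).
#' @param vertex_map numeric vertex vector (e.g. a myelination map).
#' @param mask logical; `TRUE` vertices (medial wall) are excluded.
#' @return Pearson r.
#' @export
map_coupling <- function(axis_values, vertex_map, mask = NULL) {
  if (length(axis_values) != length(vertex_map)) stop_param("vertex counts differ")
  if (!is.null(mask)) { axis_values <- axis_values[!mask]; vertex_map <- vertex_map[!mask] }
  if (length(axis_values) < 3) stop_param("mask leaves < 3 vertices")
  if (sd(axis_values) == 0 || sd(vertex_map) == 0)
    stop_param("constant input on the unmasked vertex set")
  cor(axis_values, vertex_map)
}

#' All scalar metrics of one aligned embedding
#'
#' One tidy row per scan: dispersion, inter-vigintile ranges and template
#' cosine similarities per axis, the first three pre-alignment eigenvalues,
#' and mean FC degree if supplied. Column names follow the association-stage
#' convention (`dispersion`, `grange_SA`, ..., `cossim_SA`, ...,
#' `eval1`..`eval3`, `mean_degree`).
#'
#' @param embedding an aligned `embedding_set`.
#' @param template the `gradient_template` used for alignment.
#' @param mask optional logical medial-wall mask.
#' @param mean_degree optional precomputed mean FC degree.
#' @return a one-row tibble.
#' @export
gradient_metrics <- function(embedding, template, mask = NULL, mean_degree = NA_real_) {
  stopifnot(inherits(embedding, "embedding_set"), isTRUE(embedding$aligned))
  co <- embedding$coords
  if (!is.null(mask)) { co <- co[!mask, , drop = FALSE] }
  ax <- template$axes
  if (!is.null(mask)) ax <- ax[!mask, , drop = FALSE]
  nm <- c("SA", "VS", "MR")
  ranges <- setNames(vapply(1:3, function(k) axis_range(co, k), numeric(1)),
                     paste0("grange_", nm))
  cossim <- setNames(vapply(1:3, function(k)
    cosine_to_template(co, ax, axis = k), numeric(1)), paste0("cossim_", nm))
  evals <- setNames(as.numeric(embedding$eigenvalues[1:3]), paste0("eval", 1:3))
  tibble::as_tibble(c(list(dispersion = dispersion(co)),
                      as.list(ranges), as.list(cossim), as.list(evals),
                      list(mean_degree = mean_degree)))
}
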