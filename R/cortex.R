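#' Build a labelled toy cortical sphere
#'
#' Generates a deterministic point set on the unit sphere (Fibonacci lattice)
#' standing in for a registered cortical surface, an optional contiguous
#' "medial wall" cap excluded from analysis, and a two-level spatial
#' parcellation: `n_parcels` contiguous patches grouped into `n_networks`
#' contiguous networks (the Yeo/Schaefer-style 7-network layout at toy scale).
#'
#' @param n_vertices number of surface vertices (>= 24).
#' @param n_networks number of networks (<= `n_parcels`).
#' @param n_parcels number of parcels (<= number of unmasked vertices).
#' @param medial_fraction fraction of vertices masked out as the medial wall.
#' @param seed integer seed (controls parcel/network seed placement).
#' @return an object of class `toy_cortex`: list with `vertex_coords`
#'   (vertex x 3), `network_label`, `parcel_label` (integer, `NA` on the
#'   mask), `medial_mask` (logical), and the generating parameters.
#' @export
#' @examples
#' cx <- make_toy_cortex(60, n_networks = 4, n_parcels = 10, seed = 1)
#' table(cx$network_label)
make_toy_cortex <- function(n_vertices, n_networks = 7, n_parcels = 60,
                            medial_fraction = 0.05, seed = 1) {
  if (n_vertices < 24) stop_param("n_vertices must be >= 24, got %d", n_vertices)
  if (medial_fraction < 0 || medial_fraction >= 0.5)
    stop_param("medial_fraction must be in [0, 0.5)")

  # Fibonacci sphere: deterministic quasi-uniform lattice
  i <- seq_len(n_vertices) - 0.5
  phi <- acos(1 - 2 * i / n_vertices)
  theta <- pi * (1 + sqrt(5)) * i
  coords <- cbind(x = sin(phi) * cos(theta),
                  y = sin(phi) * sin(theta),
                  z = cos(phi))

  n_masked <- floor(medial_fraction * n_vertices)
  medial_mask <- rep(FALSE, n_vertices)
  if (n_masked > 0) {
    # contiguous cap around the "medial" pole (0, 0, -1)
    pole_dist <- coords %*% c(0, 0, -1)
    medial_mask[order(pole_dist, decreasing = TRUE)[seq_len(n_masked)]] <- TRUE
  }
  free <- which(!medial_mask)
  if (n_networks > n_parcels)
    stop_param("n_networks (%d) must not exceed n_parcels (%d)", n_networks, n_parcels)
  if (n_parcels > length(free))
    stop_param("n_parcels (%d) exceeds the %d unmasked vertices", n_parcels, length(free))

  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    expr
  }

  parcel_label <- rep(NA_integer_, n_vertices)
  network_label <- rep(NA_integer_, n_vertices)
  withr_seed({
    # parcel seeds at vertex positions: nearest-seed assignment gives
    # contiguous, non-empty patches
    pseed <- sample(free, n_parcels)
    d <- coords[free, , drop = FALSE] %*% t(coords[pseed, , drop = FALSE])
    parcel_label[free] <- max.col(d, ties.method = "first")
    # group parcels into networks by nearest network seed (itself a parcel seed)
    nseed <- pseed[sample.int(n_parcels, n_networks)]
    dn <- coords[pseed, , drop = FALSE] %*% t(coords[nseed, , drop = FALSE])
    parcel_to_net <- max.col(dn, ties.method = "first")
    network_label[free] <- parcel_to_net[parcel_label[free]]
  })

  stopifnot(length(unique(parcel_label[free])) == n_parcels,
            length(unique(network_label[free])) == n_networks)
  structure(
    list(vertex_coords = coords, network_label = network_label,
         parcel_label = parcel_label, medial_mask = medial_mask,
         n_vertices = n_vertices, n_networks = n_networks,
         n_parcels = n_parcels, seed = seed),
    class = "toy_cortex")
}

#' @export
print.toy_cortex <- function(x, ...) {
  cat(sprintf("<toy_cortex> %d vertices (%d masked), %d networks, %d parcels\n",
              x$n_vertices, sum(x$medial_mask), x$n_networks, x$n_parcels))
  invisible(x)
}
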