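#' A smooth lifespan amplitude law
#'
#' The planted ground truth for each gradient axis's inter-vigintile range as
#' a function of age: a log-normal-in-age bump (single interior peak, rapid
#' early-life change) with a mild linear late-life tilt. The tilt shifts the
#' analytic maximum slightly off the nominal `peak_age`, so recovery tests
#' compare against [law_peak_age()], the numeric argmax of the law.
#'
#' @param peak_age nominal peak age in years.
#' @param peak_amp amplitude of the law at the nominal peak.
#' @param width log-age width of the bump.
#' @param late_slope relative strength of the linear late-life tilt.
#' @param floor strictly positive asymptotic amplitude.
#' @return a function of age (vectorized), with the parameters attached.
#' @export
#' @examples
#' law <- lifespan_law(18.8, 1.0)
#' law(c(1, 18.8, 80))
#' law_peak_age(law)
lifespan_law <- function(peak_age, peak_amp, width = 0.9,
                         late_slope = 0.2, floor = 0.2) {
  stopifnot(peak_age > 0, peak_amp > floor, floor > 0, width > 0)
  amp <- peak_amp - floor
  f <- function(age) {
    stopifnot(all(age > 0))
    bump <- exp(-(log(age / peak_age))^2 / (2 * width^2))
    val <- floor + amp * bump * (1 + late_slope * (peak_age - age) / 100)
    if (any(val <= 0)) stop_param("lifespan law is non-positive; reduce late_slope")
    val
  }
  attr(f, "params") <- list(peak_age = peak_age, peak_amp = peak_amp,
                            width = width, late_slope = late_slope, floor = floor)
  class(f) <- c("lifespan_law", "function")
  f
}

#' Numeric argmax age of a lifespan law
#'
#' @param law a [lifespan_law()] (or any function of age).
#' @param age_grid ages to search over.
#' @return the age at which the law attains its maximum on the grid.
#' @export
law_peak_age <- function(law, age_grid = seq(0.1, 100, by = 0.01)) {
  age_grid[which.max(law(age_grid))]
}

#' Planted ground truth for the synthetic cohort
#'
#' Bundles everything the generator needs to emit age-stamped connectomes with
#' known structure: three mutually orthogonal smooth spatial base maps (the
#' planted SA-, VS- and MR-like axes), one lifespan amplitude law per axis
#' (defaults place the range peaks at 18.8 y, 5.1 y and 19.0 y), additive
#' per-cohort mean offsets on the connectivity scale, and an age-dependent
#' noise s.d. law (mild late-life increase).
#'
#' Base maps are the first three Cartesian coordinate maps of the sphere,
#' orthonormalized by QR over unmasked vertices (masked rows are zero): smooth,
#' deterministic, and orthogonal to machine precision.
#'
#' @param cortex a [make_toy_cortex()] object.
#' @param laws list of three [lifespan_law()]s named SA, VS, MR.
#' @param cohort_offsets named numeric, additive FC offset per cohort.
#' @param noise_sd_law function of age giving the FC noise s.d.
#' @param seed master seed recorded for downstream emission.
#' @return an object of class `planted_truth`.
#' @export
planted_truth <- function(cortex,
                          laws = list(
                            SA = lifespan_law(18.8, 1.00, width = 0.9, late_slope = 0.25, floor = 0.25),
                            VS = lifespan_law(5.1, 0.85, width = 1.0, late_slope = 0.15, floor = 0.20),
                            MR = lifespan_law(19.0, 0.70, width = 0.9, late_slope = 0.20, floor = 0.15)),
                          cohort_offsets = c(infant = 0.02, dev = 0, adult = -0.02),
                          noise_sd_law = function(age) 0.03 * (1 + age / 150),
                          seed = 1) {
  stopifnot(inherits(cortex, "toy_cortex"), length(laws) == 3)
  free <- !cortex$medial_mask
  raw <- cortex$vertex_coords[free, , drop = FALSE]
  q <- qr.Q(qr(scale(raw, scale = FALSE)))[, 1:3, drop = FALSE]
  base_maps <- matrix(0, nrow = cortex$n_vertices, ncol = 3,
                      dimnames = list(NULL, names(laws)))
  base_maps[free, ] <- apply(q, 2, fix_sign)
  ortho <- max(abs(crossprod(base_maps) - diag(3)))
  stopifnot(ortho < 1e-8)
  structure(
    list(base_maps = base_maps, laws = laws, cohort_offsets = cohort_offsets,
         noise_sd_law = noise_sd_law, seed = seed),
    class = "planted_truth")
}

#' Ground-truth gradient coordinates at an age
#'
#' Scales each planted base map so its inter-vigintile (5th-95th percentile)
#' spread over unmasked vertices equals the corresponding amplitude law
#' evaluated at `age`. Deterministic; consumes no randomness.
#'
#' @param cortex a [make_toy_cortex()] object.
#' @param truth a [planted_truth()] object.
#' @param age age in years (> 0).
#' @return vertex x 3 coordinate matrix (zero rows on the medial mask).
#' @export
truth_embedding <- function(cortex, truth, age) {
  if (!is.numeric(age) || length(age) != 1L || age <= 0)
    stop_param("age must be a single positive number")
  free <- !cortex$medial_mask
  out <- truth$base_maps
  for (c in 1:3) {
    spread <- axis_range(truth$base_maps[free, , drop = FALSE], axis = c)
    out[, c] <- out[, c] * (truth$laws[[c]](age) / spread)
  }
  out
}
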