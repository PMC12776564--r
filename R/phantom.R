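#' Sampling configuration for thorax phantoms
#'
#' Describes how random thorax phantoms are drawn: one circular domain of
#' radius 1 (arbitrary units), two lateral "lung" disks and one central
#' "heart" disk. Radii are drawn uniformly from the configured ranges;
#' centers are drawn uniformly from small jitter boxes around nominal
#' anatomical positions. Defaults follow the simulation protocol used
#' throughout the package: lungs 0.5 S/m with radii 0.3-0.6, heart 2 S/m
#' with radii 0.1-0.3, background 1 S/m.
#'
#' @param lung_radius_range numeric length 2, lung disk radius range (a.u.).
#' @param heart_radius_range numeric length 2, heart disk radius range (a.u.).
#' @param lung_centers nominal centers of the two lungs (2x2 matrix, rows =
#'   left/right lung).
#' @param lung_center_jitter half-width of the uniform jitter box applied to
#'   each lung center coordinate.
#' @param heart_center nominal heart center (length 2).
#' @param heart_center_jitter half-width of the uniform jitter box for the
#'   heart center.
#' @param lung_conductivity,heart_conductivity,background_conductivity
#'   conductivities in S/m; all must be positive.
#' @param max_retries bound on rejection-sampling retries before
#'   `sample_phantom()` gives up with an error.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(lung_radius_range = c(0.3, 0.6),
                           heart_radius_range = c(0.1, 0.3),
                           lung_centers = rbind(c(-0.5, 0), c(0.5, 0)),
                           lung_center_jitter = 0.1,
                           heart_center = c(0, 0.15),
                           heart_center_jitter = 0.1,
                           lung_conductivity = 0.5,
                           heart_conductivity = 2,
                           background_conductivity = 1,
                           max_retries = 1000L) {
  stopifnot(
    length(lung_radius_range) == 2L, length(heart_radius_range) == 2L,
    all(lung_radius_range > 0), all(lung_radius_range < 1),
    all(heart_radius_range >= 0), all(heart_radius_range < 1),
    diff(lung_radius_range) >= 0, diff(heart_radius_range) >= 0,
    is.matrix(lung_centers), dim(lung_centers) == c(2L, 2L),
    lung_center_jitter >= 0, heart_center_jitter >= 0,
    lung_conductivity > 0, heart_conductivity > 0,
    background_conductivity > 0, max_retries >= 1
  )
  structure(list(
    lung_radius_range = as.numeric(lung_radius_range),
    heart_radius_range = as.numeric(heart_radius_range),
    lung_centers = lung_centers,
    lung_center_jitter = lung_center_jitter,
    heart_center = as.numeric(heart_center),
    heart_center_jitter = heart_center_jitter,
    lung_conductivity = lung_conductivity,
    heart_conductivity = heart_conductivity,
    background_conductivity = background_conductivity,
    max_retries = as.integer(max_retries)
  ), class = "phantom_config")
}

new_inclusion <- function(label, center, radius, conductivity) {
  list(label = label, center = as.numeric(center),
       radius = as.numeric(radius), conductivity = as.numeric(conductivity))
}

#' Validate a thorax phantom
#'
#' Checks the phantom invariants: exactly two lung and one heart
#' inclusion, every inclusion strictly inside the unit-radius domain
#' (|center| + radius <= 1), pairwise disjoint disks, and positive
#' conductivities.
#'
#' @param phantom a `thorax_phantom`.
#' @return TRUE invisibly, or an error describing the violated invariant.
#' @export
validate_phantom <- function(phantom) {
  stopifnot(inherits(phantom, "thorax_phantom"))
  inc <- phantom$inclusions
  labs <- vapply(inc, `[[`, "", "label")
  if (sum(grepl("^lung", labs)) != 2L || sum(labs == "heart") != 1L)
    stop("phantom must have exactly two lung and one heart inclusion")
  if (phantom$background_conductivity <= 0) stop("background conductivity must be > 0")
  for (a in inc) {
    if (a$conductivity <= 0) stop("inclusion conductivity must be > 0")
    if (a$radius < 0) stop("negative radius")
    if (sqrt(sum(a$center^2)) + a$radius > 1 + 1e-12)
      stop("inclusion ", a$label, " extends outside the unit domain")
  }
  n <- length(inc)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d <- sqrt(sum((inc[[i]]$center - inc[[j]]$center)^2))
    if (d < inc[[i]]$radius + inc[[j]]$radius - 1e-12)
      stop("inclusions ", inc[[i]]$label, " and ", inc[[j]]$label, " overlap")
  }
  invisible(TRUE)
}

#' Sample a random thorax phantom
#'
#' Draws lung and heart radii uniformly from the configured ranges and
#' centers uniformly from the jitter boxes, then rejects and redraws the
#' whole phantom until the inside-domain and disjointness constraints are
#' met (bounded by `config$max_retries`).
#'
#' @param config a [phantom_config()].
#' @param seed optional integer; if given the draw is reproducible.
#' @return an object of class `thorax_phantom` with fields
#'   `background_conductivity` and `inclusions` (list of 3).
#' @export
sample_phantom <- function(config = phantom_config(), seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(seed, {
    for (try in seq_len(config$max_retries)) {
      rl <- stats::runif(2, config$lung_radius_range[1], config$lung_radius_range[2])
      rh <- stats::runif(1, config$heart_radius_range[1], config$heart_radius_range[2])
      cl <- config$lung_centers +
        matrix(stats::runif(4, -config$lung_center_jitter, config$lung_center_jitter), 2, 2)
      ch <- config$heart_center +
        stats::runif(2, -config$heart_center_jitter, config$heart_center_jitter)
      ph <- structure(list(
        background_conductivity = config$background_conductivity,
        inclusions = list(
          new_inclusion("lung_left",  cl[1, ], rl[1], config$lung_conductivity),
          new_inclusion("lung_right", cl[2, ], rl[2], config$lung_conductivity),
          new_inclusion("heart",      ch,      rh,    config$heart_conductivity)
        )), class = "thorax_phantom")
      ok <- tryCatch({ validate_phantom(ph); TRUE }, error = function(e) FALSE)
      if (ok) return(ph)
    }
    stop("sample_phantom: no admissible phantom after ", config$max_retries,
         " retries; the sampling config is over-constrained")
  })
}

#' Homogeneous (inclusion-free) phantom
#'
#' The reference state for difference imaging: the background medium with
#' no inclusions.
#'
#' @param background_conductivity background conductivity in S/m.
#' @return a `thorax_phantom` with zero inclusions (reference use only;
#'   it deliberately does not satisfy the two-lungs-one-heart invariant).
#' @export
homogeneous_phantom <- function(background_conductivity = 1) {
  structure(list(background_conductivity = background_conductivity,
                 inclusions = list()), class = "thorax_phantom")
}

#' Split a phantom into organ-isolated phantoms
#'
#' Returns two phantoms sharing the input's background: one containing
#' only the lung inclusions, one containing only the heart. Used for the
#' optional continuous-target dataset variant, where targets are
#' reconstructions of the isolated organs rather than binary masks.
#'
#' @param phantom a full `thorax_phantom`.
#' @return list with elements `lungs_only` and `heart_only`.
#' @export
isolated_phantoms <- function(phantom) {
  stopifnot(inherits(phantom, "thorax_phantom"))
  labs <- vapply(phantom$inclusions, `[[`, "", "label")
  mk <- function(keep) structure(list(
    background_conductivity = phantom$background_conductivity,
    inclusions = phantom$inclusions[keep]), class = "thorax_phantom")
  list(lungs_only = mk(grepl("^lung", labs)), heart_only = mk(labs == "heart"))
}

#' Pixel grid specification for reconstruction images
#'
#' A square n-by-n grid over \[-1, 1\]^2 with pixel-center coordinates and
#' a circular support mask (pixel centers inside the unit disk). 32x32 is
#' the reconstruction and network grid used throughout.
#'
#' @param n pixels per side (default 32).
#' @return object of class `pixel_grid` with fields `n`, `x`, `y`
#'   (center coordinate vectors), `cx`, `cy` (n-by-n center matrices) and
#'   `support` (n-by-n logical).
#' @export
pixel_grid <- function(n = 32L) {
  stopifnot(n >= 2)
  h <- 2 / n
  x <- -1 + h * (seq_len(n) - 0.5)
  cx <- matrix(x, n, n)        # varies along rows
  cy <- matrix(x, n, n, byrow = TRUE)
  structure(list(n = as.integer(n), x = x, y = x, cx = cx, cy = cy,
                 support = cx^2 + cy^2 <= 1), class = "pixel_grid")
}

#' Rasterize ground-truth organ maps
#'
#' Converts a phantom's geometry into binary 0/1 target maps on the
#' reconstruction grid. A pixel is 1 iff its center lies inside the
#' corresponding disk (pixel-center membership, no area fractions); the
#' lung map is the union of the two lung disks. Pixels outside the
#' circular domain are always 0. Because valid phantoms have disjoint
#' inclusions, the two maps are elementwise disjoint.
#'
#' @param phantom a `thorax_phantom`.
#' @param grid a [pixel_grid()].
#' @return list with `lung` and `heart` n-by-n 0/1 matrices.
#' @export
rasterize_masks <- function(phantom, grid = pixel_grid()) {
  stopifnot(inherits(phantom, "thorax_phantom"), inherits(grid, "pixel_grid"))
  lung <- matrix(0, grid$n, grid$n)
  heart <- matrix(0, grid$n, grid$n)
  for (a in phantom$inclusions) {
    inside <- ((grid$cx - a$center[1])^2 + (grid$cy - a$center[2])^2 <= a$radius^2) &
      grid$support
    if (a$label == "heart") heart[inside] <- 1 else lung[inside] <- 1
  }
  list(lung = lung, heart = heart)
}

#' @export
print.thorax_phantom <- function(x, ...) {
  cat("Thorax phantom: background", x$background_conductivity, "S/m,",
      length(x$inclusions), "inclusion(s)\n")
  for (a in x$inclusions)
    cat(sprintf("  %-10s center (% .3f, % .3f)  radius %.3f  sigma %.2f S/m\n",
                a$label, a$center[1], a$center[2], a$radius, a$conductivity))
  invisible(x)
}
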