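#' Build a structured triangular mesh of the unit disk
#'
#' Constructs a rotationally regular mesh: concentric rings of equally
#' spaced nodes (the same angular positions on every ring) joined by two
#' triangles per quad, plus a central fan. The boundary ring carries a
#' multiple of `electrode_count` nodes, so the electrodes land exactly on
#' mesh nodes, equally spaced counter-clockwise starting at angle 0. The
#' structure is invariant under rotation by one electrode pitch, which
#' the sensitivity-matrix symmetry checks rely on.
#'
#' @param target_element_count requested number of triangles (>= 256);
#'   the realized count is within a factor 2 of the request.
#' @param electrode_count number of boundary electrodes (16 for the
#'   adjacent protocol used here).
#' @return object of class `fe_mesh` with fields:
#'   `nodes` (n x 2 coordinates), `tri` (m x 3 counter-clockwise node
#'   indices), `electrode_nodes` (node index per electrode),
#'   `n_rings`, `ring_size`, plus precomputed per-element quantities
#'   `area` (m), `grad` (m x 3 x 2 P1 shape-function gradients) and
#'   `centroid` (m x 2).
#' @export
build_mesh <- function(target_element_count = 1024L, electrode_count = 16L) {
  stopifnot(target_element_count >= 256, electrode_count >= 4)
  R <- max(2L, as.integer(round(sqrt(target_element_count / (4 * pi)))))
  k <- max(1L, as.integer(round(2 * pi * R / electrode_count)))
  M <- as.integer(electrode_count * k)

  # nodes: center first, then rings j = 1..R at radius j/R, angles 2*pi*i/M
  ang <- 2 * pi * (seq_len(M) - 1L) / M
  nodes <- rbind(c(0, 0),
                 do.call(rbind, lapply(seq_len(R), function(j)
                   cbind(j / R * cos(ang), j / R * sin(ang)))))
  ring_idx <- function(j, i) 1L + (j - 1L) * M + ((i - 1L) %% M) + 1L

  tri <- vector("list", R)
  i <- seq_len(M)
  tri[[1]] <- cbind(1L, ring_idx(1L, i), ring_idx(1L, i + 1L))
  for (j in seq_len(R - 1L)) {
    a  <- ring_idx(j, i);      a1 <- ring_idx(j, i + 1L)
    b  <- ring_idx(j + 1L, i); b1 <- ring_idx(j + 1L, i + 1L)
    tri[[j + 1L]] <- rbind(cbind(a, b, b1), cbind(a, b1, a1))
  }
  tri <- do.call(rbind, tri)

  electrode_nodes <- ring_idx(R, 1L + (seq_len(electrode_count) - 1L) * (M %/% electrode_count))

  mesh <- structure(list(nodes = nodes, tri = tri,
                         electrode_nodes = as.integer(electrode_nodes),
                         n_rings = R, ring_size = M),
                    class = "fe_mesh")
  mesh <- c(mesh, mesh_element_geometry(mesh))
  class(mesh) <- "fe_mesh"
  if (any(mesh$area <= 0)) stop("build_mesh produced a non-CCW element")
  mesh
}

# P1 element geometry: signed areas, constant shape-function gradients,
# centroids. grad[e, i, ] is the gradient of the hat function of local
# vertex i on element e.
mesh_element_geometry <- function(mesh) {
  t1 <- mesh$tri[, 1]; t2 <- mesh$tri[, 2]; t3 <- mesh$tri[, 3]
  x1 <- mesh$nodes[t1, 1]; y1 <- mesh$nodes[t1, 2]
  x2 <- mesh$nodes[t2, 1]; y2 <- mesh$nodes[t2, 2]
  x3 <- mesh$nodes[t3, 1]; y3 <- mesh$nodes[t3, 2]
  area <- 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  m <- length(area)
  grad <- array(0, c(m, 3, 2))
  grad[, 1, 1] <- (y2 - y3) / (2 * area); grad[, 1, 2] <- (x3 - x2) / (2 * area)
  grad[, 2, 1] <- (y3 - y1) / (2 * area); grad[, 2, 2] <- (x1 - x3) / (2 * area)
  grad[, 3, 1] <- (y1 - y2) / (2 * area); grad[, 3, 2] <- (x2 - x1) / (2 * area)
  centroid <- cbind((x1 + x2 + x3) / 3, (y1 + y2 + y3) / 3)
  list(area = area, grad = grad, centroid = centroid)
}

#' Map a phantom onto per-element conductivities
#'
#' Assigns each mesh element the conductivity of the inclusion containing
#' its centroid, or the background conductivity otherwise.
#'
#' @param mesh an `fe_mesh`.
#' @param phantom a `thorax_phantom`.
#' @return numeric vector of length `nrow(mesh$tri)` (S/m).
#' @export
element_conductivities <- function(mesh, phantom) {
  stopifnot(inherits(mesh, "fe_mesh"), inherits(phantom, "thorax_phantom"))
  sigma <- rep(phantom$background_conductivity, nrow(mesh$tri))
  for (a in phantom$inclusions) {
    inside <- (mesh$centroid[, 1] - a$center[1])^2 +
      (mesh$centroid[, 2] - a$center[2])^2 <= a$radius^2
    sigma[inside] <- a$conductivity
  }
  sigma
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat("FE mesh: ", nrow(x$nodes), " nodes, ", nrow(x$tri), " triangles, ",
      length(x$electrode_nodes), " boundary electrodes\n", sep = "")
  invisible(x)
}
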