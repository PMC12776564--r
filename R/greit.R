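#' Fit a linear reconstruction matrix to training pairs
#'
#' Core GREIT-style estimator: given simulated measurement vectors
#' `Y` (n_meas x n_targets) and the corresponding desired images
#' `X` (n_pixels x n_targets), finds the matrix R minimizing
#' sum_k ||R y_k - x_k||^2 + lambda * penalty, i.e.
#' R = X Y' (Y Y' + lambda * tr(Y Y')/n_meas * I)^-1.
#' With `lambda = 0` this is the ordinary least-squares solution
#' (minimum-norm when Y Y' is singular).
#'
#' @param Y measurements, one column per training target.
#' @param X desired images, one column per training target.
#' @param lambda relative Tikhonov weight (>= 0).
#' @return the reconstruction matrix (n_pixels x n_meas).
#' @export
fit_linear_recon <- function(Y, X, lambda = 0) {
  stopifnot(ncol(Y) == ncol(X), lambda >= 0)
  G <- tcrossprod(Y)
  if (lambda > 0) {
    G <- G + diag(lambda * sum(diag(G)) / nrow(Y), nrow(Y))
    t(solve(G, Y %*% t(X)))
  } else {
    # minimum-norm least squares via pseudoinverse for rank-deficient Y Y'
    s <- svd(Y)
    pos <- s$d > max(s$d) * 1e-12
    X %*% s$v[, pos, drop = FALSE] %*%
      (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  }
}

#' Train a GREIT-style reconstruction model
#'
#' Implements the standard GREIT recipe on the package's 2D forward
#' model: simulate many small circular conductivity targets at random
#' positions in the domain, compute their (linearized, reference-
#' normalized) voltage signatures through the sensitivity matrix, define
#' for each a desired image (a disk of `desired_psf_radius` at the
#' target location on the 32x32 grid), and solve the regularized
#' least-squares problem for the matrix mapping voltage differences to
#' images. Rows for pixels outside the circular support are identically
#' zero.
#'
#' @param mesh an `fe_mesh`.
#' @param protocol an [adjacent_protocol()].
#' @param grid a [pixel_grid()] (default 32x32).
#' @param n_targets number of random training targets (>= 200).
#' @param target_radius radius of the simulated conductivity targets
#'   (a.u.).
#' @param desired_psf_radius radius of the desired point-spread disk in
#'   the image (a.u.).
#' @param noise_amplitude relative Tikhonov/noise weight controlling the
#'   resolution/noise trade-off.
#' @param max_target_center targets are placed uniformly in a disk of
#'   this radius so that they stay well inside the electrode ring.
#' @param background_conductivity homogeneous baseline (S/m).
#' @param seed integer seed; the trained matrix is deterministic given
#'   the seed.
#' @return object of class `recon_model` with fields `matrix`
#'   (n_pixels x n_meas, row-major over the grid as `as.vector` of an
#'   n x n matrix), `grid`, `v_ref` (homogeneous reference frame),
#'   `protocol` and `meta`.
#' @export
train_reconstruction_matrix <- function(mesh, protocol = adjacent_protocol(),
                                        grid = pixel_grid(),
                                        n_targets = 1000L,
                                        target_radius = 0.05,
                                        desired_psf_radius = 0.15,
                                        noise_amplitude = 0.02,
                                        max_target_center = 0.85,
                                        background_conductivity = 1,
                                        seed = 1L) {
  stopifnot(n_targets >= 200, target_radius > 0, target_radius < 1,
            desired_psf_radius > 0, desired_psf_radius < 1)
  sigma0 <- rep(background_conductivity, nrow(mesh$tri))
  v_ref <- as.numeric(solve_forward(mesh, sigma0, protocol))
  J <- compute_jacobian(mesh, sigma0, protocol)
  Jn <- J / abs(v_ref)                     # normalized-difference sensitivity

  centers <- with_seed(seed, {
    r <- max_target_center * sqrt(stats::runif(n_targets))
    th <- stats::runif(n_targets, 0, 2 * pi)
    cbind(r * cos(th), r * sin(th))
  })

  np <- grid$n * grid$n
  Y <- matrix(0, protocol$n_meas, n_targets)
  X <- matrix(0, np, n_targets)
  sup <- as.vector(grid$support)
  pcx <- as.vector(grid$cx); pcy <- as.vector(grid$cy)
  for (k in seq_len(n_targets)) {
    in_el <- (mesh$centroid[, 1] - centers[k, 1])^2 +
             (mesh$centroid[, 2] - centers[k, 2])^2 <= target_radius^2
    if (!any(in_el))   # tiny target between centroids: use the nearest element
      in_el <- which.min((mesh$centroid[, 1] - centers[k, 1])^2 +
                         (mesh$centroid[, 2] - centers[k, 2])^2)
    Y[, k] <- rowSums(Jn[, in_el, drop = FALSE])
    X[, k] <- as.numeric(sup & ((pcx - centers[k, 1])^2 +
                                (pcy - centers[k, 2])^2 <= desired_psf_radius^2))
  }
  R <- fit_linear_recon(Y, X, lambda = noise_amplitude)
  R[!sup, ] <- 0
  structure(list(matrix = R, grid = grid, v_ref = v_ref, protocol = protocol,
                 meta = list(n_targets = n_targets, target_radius = target_radius,
                             desired_psf_radius = desired_psf_radius,
                             noise_amplitude = noise_amplitude, seed = seed)),
            class = "recon_model")
}

#' Reconstruct a difference-EIT image
#'
#' Applies the trained linear reconstruction matrix to the elementwise
#' normalized voltage difference (v - v_ref) / |v_ref| between a data
#' frame and a reference frame. Conductivity increases map to positive
#' pixel values; pixels outside the circular support are exactly zero.
#'
#' @param model a `recon_model`.
#' @param frame measured/simulated `voltage_frame` (or numeric vector).
#' @param reference reference frame; defaults to the homogeneous frame
#'   stored in the model.
#' @return n-by-n image matrix of conductivity-change values.
#' @export
reconstruct <- function(model, frame, reference = NULL) {
  stopifnot(inherits(model, "recon_model"))
  v <- as.numeric(frame)
  v_ref <- if (is.null(reference)) model$v_ref else as.numeric(reference)
  if (length(v) != length(v_ref) || length(v) != ncol(model$matrix))
    stop("frame length does not match the reconstruction protocol")
  if (any(v_ref == 0)) stop("reference frame contains zero voltages; protocol mismatch?")
  img <- model$matrix %*% ((v - v_ref) / abs(v_ref))
  matrix(img, model$grid$n, model$grid$n)
}

#' Min-max normalize an image to \[0, 1\] over its support
#'
#' Affinely maps the support pixels so the minimum becomes 0 and the
#' maximum 1; constant images map to all zeros. Out-of-support pixels
#' stay 0. Idempotent on already-normalized non-constant images.
#'
#' @param image n-by-n image matrix.
#' @param support logical matrix of the same shape (default: circular
#'   support of a [pixel_grid()] of matching size).
#' @return normalized image matrix.
#' @export
normalize_image <- function(image, support = NULL) {
  stopifnot(is.matrix(image), nrow(image) == ncol(image))
  if (is.null(support)) support <- pixel_grid(nrow(image))$support
  vals <- image[support]
  lo <- min(vals); hi <- max(vals)
  out <- matrix(0, nrow(image), ncol(image))
  if (hi > lo) out[support] <- (image[support] - lo) / (hi - lo)
  out
}

#' @export
print.recon_model <- function(x, ...) {
  cat("GREIT-style linear reconstruction model: ", x$grid$n, "x", x$grid$n,
      " grid, ", ncol(x$matrix), " measurements, ", x$meta$n_targets,
      " training targets\n", sep = "")
  invisible(x)
}
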