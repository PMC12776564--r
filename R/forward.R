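#' Adjacent-pair stimulation and measurement protocol
#'
#' The standard 16-electrode adjacent protocol: current is driven through
#' each neighbouring electrode pair (d, d+1) in turn at `current` amperes
#' (+I / -I, zero net injection), and for each drive the differential
#' voltage is measured on the 13 adjacent pairs that do not touch either
#' drive electrode, in ascending electrode order. 16 drives x 13
#' measurements = 208 values per frame, drive-major.
#'
#' @param n_electrodes number of electrodes (default 16).
#' @param current drive current in amperes (default 1e-3, i.e. 1 mA).
#' @return object of class `eit_protocol` with fields `n_electrodes`,
#'   `current`, `drive` (n x 2 electrode pairs), `meas` (matrix with one
#'   row per measurement: drive index, measurement pair m, m+1) and
#'   `n_meas` (total measurement count).
#' @export
adjacent_protocol <- function(n_electrodes = 16L, current = 1e-3) {
  stopifnot(n_electrodes >= 8, current > 0)
  L <- as.integer(n_electrodes)
  nxt <- function(e) (e %% L) + 1L
  drive <- cbind(seq_len(L), nxt(seq_len(L)))
  rows <- list()
  for (d in seq_len(L)) {
    excl <- c((d - 2L) %% L + 1L, d, nxt(d))  # pairs touching a drive electrode
    for (m in setdiff(seq_len(L), excl))
      rows[[length(rows) + 1L]] <- c(d, m, nxt(m))
  }
  meas <- do.call(rbind, rows)
  colnames(meas) <- c("drive", "m_pos", "m_neg")
  structure(list(n_electrodes = L, current = current, drive = drive,
                 meas = meas, n_meas = nrow(meas)),
            class = "eit_protocol")
}

# Sparse stiffness-matrix machinery, built once per mesh and reused across
# phantoms: triplet index vectors plus the geometric element matrices
# ke[e, i, j] = area_e * grad_i . grad_j (conductivity enters as a scalar
# factor per element).
stiffness_structure <- function(mesh) {
  m <- nrow(mesh$tri)
  ke <- array(0, c(m, 3, 3))
  for (i in 1:3) for (j in 1:3)
    ke[, i, j] <- mesh$area * (mesh$grad[, i, 1] * mesh$grad[, j, 1] +
                               mesh$grad[, i, 2] * mesh$grad[, j, 2])
  ii <- rep(mesh$tri, times = 3)                       # m*9: local i varies first
  jj <- as.vector(mesh$tri[, rep(1:3, each = 3)])
  list(ii = ii, jj = jj, ke = matrix(ke, m, 9), n_nodes = nrow(mesh$nodes))
}

assemble_stiffness <- function(struct, sigma) {
  vals <- as.vector(struct$ke * sigma)
  Matrix::sparseMatrix(i = struct$ii, j = struct$jj, x = vals,
                       dims = c(struct$n_nodes, struct$n_nodes))
}

# Solve the grounded system for all electrode-pair unit injections at
# once. Returns the node potentials (n_nodes x n_electrodes) for +1 A at
# electrode e, -1 A at electrode e+1, gauge-fixed to zero mean.
solve_pair_fields <- function(mesh, sigma, protocol, struct = NULL) {
  if (is.null(struct)) struct <- stiffness_structure(mesh)
  if (any(sigma <= 0)) stop("conductivities must be strictly positive")
  K <- assemble_stiffness(struct, sigma)
  n <- struct$n_nodes
  B <- matrix(0, n, protocol$n_electrodes)
  en <- mesh$electrode_nodes
  for (d in seq_len(protocol$n_electrodes)) {
    B[en[protocol$drive[d, 1]], d] <- 1
    B[en[protocol$drive[d, 2]], d] <- -1
  }
  # ground node 1 (the mesh center), then re-gauge to zero mean
  Kg <- K[-1, -1]
  U <- matrix(0, n, protocol$n_electrodes)
  U[-1, ] <- as.matrix(Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(Kg)),
                                     B[-1, , drop = FALSE]))
  sweep(U, 2, colMeans(U))
}

#' Solve the EIT forward problem
#'
#' P1 finite-element solution of the 2D conductivity equation
#' div(sigma grad u) = 0 with point-electrode current injection, for all
#' drives of the protocol, returning the 208 differential boundary
#' voltages of one frame. The potential gauge is fixed by a zero-mean
#' constraint; differential measurements are gauge-independent.
#'
#' @param mesh an `fe_mesh`.
#' @param sigma per-element conductivities (S/m), strictly positive.
#' @param protocol an [adjacent_protocol()].
#' @param struct optional precomputed stiffness structure for reuse
#'   across many phantoms on the same mesh (internal).
#' @return object of class `voltage_frame`: numeric vector of
#'   `protocol$n_meas` voltages (V) with the protocol attached as an
#'   attribute.
#' @export
solve_forward <- function(mesh, sigma, protocol = adjacent_protocol(),
                          struct = NULL) {
  stopifnot(inherits(mesh, "fe_mesh"), inherits(protocol, "eit_protocol"),
            length(sigma) == nrow(mesh$tri))
  U <- protocol$current * solve_pair_fields(mesh, sigma, protocol, struct)
  en <- mesh$electrode_nodes
  v <- U[cbind(en[protocol$meas[, "m_pos"]], protocol$meas[, "drive"])] -
       U[cbind(en[protocol$meas[, "m_neg"]], protocol$meas[, "drive"])]
  if (!all(is.finite(v))) stop("forward solve produced non-finite voltages")
  structure(v, class = "voltage_frame", protocol = protocol)
}

#' Sensitivity (Jacobian) matrix of the forward map
#'
#' Computes d V_(d,m) / d sigma_e for every measurement and element by
#' the adjoint-field formula: with u_d the drive field and w_m the field
#' of a unit current on the measurement pair,
#' dV/dsigma_e = -area_e * grad(u_d) . grad(w_m). For P1 elements the
#' gradients are constant per element, so one linear solve per electrode
#' pair suffices for the whole matrix.
#'
#' @param mesh an `fe_mesh`.
#' @param sigma baseline per-element conductivities (typically
#'   homogeneous).
#' @param protocol an [adjacent_protocol()].
#' @return dense matrix (n_meas x n_elements), in V per (S/m).
#' @export
compute_jacobian <- function(mesh, sigma, protocol = adjacent_protocol()) {
  stopifnot(inherits(mesh, "fe_mesh"), length(sigma) == nrow(mesh$tri))
  U <- solve_pair_fields(mesh, sigma, protocol)        # unit-current fields
  m <- nrow(mesh$tri)
  # per-element gradients of each pair field: GX[e, p], GY[e, p]
  GX <- matrix(0, m, protocol$n_electrodes)
  GY <- matrix(0, m, protocol$n_electrodes)
  for (i in 1:3) {
    Ui <- U[mesh$tri[, i], , drop = FALSE]
    GX <- GX + mesh$grad[, i, 1] * Ui
    GY <- GY + mesh$grad[, i, 2] * Ui
  }
  J <- matrix(0, protocol$n_meas, m)
  for (r in seq_len(protocol$n_meas)) {
    d <- protocol$meas[r, "drive"]; p <- protocol$meas[r, "m_pos"]
    J[r, ] <- -protocol$current * mesh$area *
      (GX[, d] * GX[, p] + GY[, d] * GY[, p])
  }
  J
}
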