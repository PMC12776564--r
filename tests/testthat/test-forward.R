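test_that("mesh construction satisfies its geometric invariants", {
  for (target in c(512L, 1024L)) {
    mesh <- build_mesh(target)
    expect_true(all(mesh$area > 0))
    expect_lte(nrow(mesh$tri), 2 * target)
    expect_gte(nrow(mesh$tri), target / 2)
    expect_equal(sum(mesh$area), pi, tolerance = 0.02)
    expect_length(mesh$electrode_nodes, 16)
    r <- sqrt(rowSums(mesh$nodes[mesh$electrode_nodes, ]^2))
    expect_equal(r, rep(1, 16), tolerance = 1e-12)
    ang <- atan2(mesh$nodes[mesh$electrode_nodes, 2],
                 mesh$nodes[mesh$electrode_nodes, 1])
    gaps <- diff(sort(ang %% (2 * pi)))
    expect_equal(gaps, rep(2 * pi / 16, 15), tolerance = 1e-9)
  }
  expect_error(build_mesh(100), "target_element_count")
})

test_that("adjacent protocol has 16 x 13 = 208 measurements avoiding drive electrodes", {
  prot <- adjacent_protocol()
  expect_equal(prot$n_meas, 208)
  for (r in seq_len(prot$n_meas)) {
    d <- prot$meas[r, "drive"]
    drive_el <- c(d, d %% 16 + 1)
    meas_el <- prot$meas[r, c("m_pos", "m_neg")]
    expect_length(intersect(drive_el, meas_el), 0)
  }
  expect_equal(unname(table(prot$meas[, "drive"])), rep(13L, 16L),
               ignore_attr = TRUE)
})

test_that("element conductivities map inclusions by centroid membership", {
  mesh <- test_mesh()
  hom <- homogeneous_phantom(1.5)
  expect_equal(element_conductivities(mesh, hom), rep(1.5, nrow(mesh$tri)))
  ph <- disk_phantom(c(0.1, 0.2), 0.25, conductivity = 2)
  sig <- element_conductivities(mesh, ph)
  inside <- (mesh$centroid[, 1] - 0.1)^2 + (mesh$centroid[, 2] - 0.2)^2 <= 0.25^2
  expect_true(all(sig[inside] == 2) && all(sig[!inside] == 1))
  # covered area fraction approximates the analytic disk area
  frac <- sum(mesh$area[inside]) / sum(mesh$area)
  expect_equal(frac, 0.25^2, tolerance = 0.15)
})

test_that("forward solutions are reciprocal and scale inversely with conductivity", {
  mesh <- test_mesh(); prot <- test_protocol()
  ph <- sample_phantom(seed = 5)
  sig <- element_conductivities(mesh, ph)
  v <- solve_forward(mesh, sig, prot)
  expect_true(all(is.finite(v)))
  # reciprocity on every available drive/measure exchange
  idx <- new.env()
  for (r in seq_len(prot$n_meas))
    assign(paste(prot$meas[r, 1], prot$meas[r, 2]), r, envir = idx)
  checked <- 0L
  for (r in seq_len(prot$n_meas)) {
    key <- paste(prot$meas[r, 2], prot$meas[r, 1])
    r2 <- idx[[key]]
    if (!is.null(r2)) {
      expect_lte(abs(v[r] - v[r2]) / max(abs(v[r]), 1e-300), 1e-8)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 150)
  v2 <- solve_forward(mesh, 2 * sig, prot)
  expect_equal(as.numeric(v2), as.numeric(v) / 2, tolerance = 1e-12)
  expect_error(solve_forward(mesh, sig * 0, prot), "positive")
})

test_that("homogeneous-disk solution matches the analytic two-point-source formula", {
  mesh <- test_mesh(); prot <- test_protocol()
  v <- solve_forward(mesh, rep(1, nrow(mesh$tri)), prot)
  en <- mesh$electrode_nodes
  ex <- mesh$nodes[en, 1]; ey <- mesh$nodes[en, 2]
  I <- prot$current
  rel <- numeric(0)
  for (d in 1:16) {
    A <- c(ex[d], ey[d]); B <- c(ex[d %% 16 + 1], ey[d %% 16 + 1])
    u <- (I / pi) * (log(sqrt((ex - B[1])^2 + (ey - B[2])^2)) -
                     log(sqrt((ex - A[1])^2 + (ey - A[2])^2)))
    rows <- which(prot$meas[, "drive"] == d)
    va <- u[prot$meas[rows, "m_pos"]] - u[prot$meas[rows, "m_neg"]]
    rel <- c(rel, abs(as.numeric(v[rows]) - va) / abs(va))
  }
  expect_lt(max(rel), 0.02)
})

test_that("mesh refinement reduces the analytic-solution error", {
  prot <- test_protocol()
  err_at <- function(target) {
    mesh <- build_mesh(target)
    v <- solve_forward(mesh, rep(1, nrow(mesh$tri)), prot)
    en <- mesh$electrode_nodes
    ex <- mesh$nodes[en, 1]; ey <- mesh$nodes[en, 2]
    rel <- numeric(0)
    for (d in 1:16) {
      A <- c(ex[d], ey[d]); B <- c(ex[d %% 16 + 1], ey[d %% 16 + 1])
      u <- (prot$current / pi) * (log(sqrt((ex - B[1])^2 + (ey - B[2])^2)) -
                                  log(sqrt((ex - A[1])^2 + (ey - A[2])^2)))
      rows <- which(prot$meas[, "drive"] == d)
      va <- u[prot$meas[rows, "m_pos"]] - u[prot$meas[rows, "m_neg"]]
      rel <- c(rel, abs(as.numeric(v[rows]) - va) / abs(va))
    }
    median(rel)
  }
  expect_lt(err_at(2048L), err_at(512L))
})

test_that("adjoint Jacobian matches finite differences and linearity", {
  mesh <- test_mesh(); prot <- test_protocol()
  sig <- rep(1, nrow(mesh$tri))
  J <- compute_jacobian(mesh, sig, prot)
  expect_true(all(is.finite(J)))
  v0 <- as.numeric(solve_forward(mesh, sig, prot))
  h <- 1e-4
  for (e in c(50L, 500L, 900L)) {
    sp <- sig; sp[e] <- sp[e] + h
    fd <- (as.numeric(solve_forward(mesh, sp, prot)) - v0) / h
    expect_lt(sqrt(sum((J[, e] - fd)^2)) / sqrt(sum(fd^2)), 1e-3)
  }
  # zero perturbation predicts zero voltage change
  expect_equal(as.numeric(J %*% rep(0, ncol(J))), rep(0, 208))
})

test_that("Jacobian respects the protocol's rotational symmetry", {
  mesh <- test_mesh(); prot <- test_protocol()
  J <- compute_jacobian(mesh, rep(1, nrow(mesh$tri)), prot)
  M <- mesh$ring_size
  s <- M %/% 16L                       # angular positions per electrode pitch
  # elements are stored in M-sized blocks of constant triangle type, each
  # ordered by angular position; rotation advances the position by s
  n_el <- nrow(mesh$tri)
  rot_block <- function(first) first + ((seq_len(M) - 1L) + s) %% M
  rot_el <- integer(n_el)
  for (first in seq(1L, n_el, by = M))
    rot_el[first:(first + M - 1L)] <- rot_block(first)
  # row rotation: (d, m) -> (d+1, m+1)
  row_of <- matrix(NA_integer_, 16, 16)
  for (r in seq_len(prot$n_meas))
    row_of[prot$meas[r, "drive"], prot$meas[r, "m_pos"]] <- r
  rot_row <- integer(prot$n_meas)
  for (r in seq_len(prot$n_meas)) {
    d <- prot$meas[r, "drive"] %% 16L + 1L
    m <- prot$meas[r, "m_pos"] %% 16L + 1L
    rot_row[r] <- row_of[d, m]
  }
  for (e in c(10L, 300L, 777L))
    expect_equal(J[rot_row, rot_el[e]], J[, e], tolerance = 1e-8,
                 ignore_attr = TRUE)
})
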