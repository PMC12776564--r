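#' Bundle the simulation pipeline components
#'
#' Builds (once) everything needed to turn random phantoms into training
#' samples: the FE mesh, the adjacent protocol, the homogeneous
#' reference frame and the trained GREIT-style reconstruction matrix.
#' Reused across all dataset generation so the expensive pieces are
#' computed a single time.
#'
#' @param phantoms a [phantom_config()].
#' @param mesh_elements target FE element count.
#' @param grid_size reconstruction grid side (default 32).
#' @param recon_seed seed for the reconstruction-matrix training.
#' @param ... further arguments to [train_reconstruction_matrix()].
#' @return object of class `eit_simulator`.
#' @export
eit_simulator <- function(phantoms = phantom_config(), mesh_elements = 1024L,
                          grid_size = 32L, recon_seed = 1L, ...) {
  mesh <- build_mesh(mesh_elements)
  protocol <- adjacent_protocol()
  grid <- pixel_grid(grid_size)
  struct <- stiffness_structure(mesh)
  recon <- train_reconstruction_matrix(mesh, protocol, grid, seed = recon_seed, ...)
  structure(list(phantoms = phantoms, mesh = mesh, protocol = protocol,
                 grid = grid, struct = struct, recon = recon),
            class = "eit_simulator")
}

#' Simulate one training sample from a phantom
#'
#' Full forward pipeline for a single phantom: element conductivities,
#' forward solve, difference reconstruction against the homogeneous
#' reference, min-max normalization, and rasterized binary targets.
#'
#' @param sim an [eit_simulator()].
#' @param phantom a `thorax_phantom`.
#' @param continuous_targets if TRUE, targets are normalized
#'   reconstructions of the organ-isolated phantoms instead of binary
#'   masks (the continuous dataset variant).
#' @return list with `input`, `lung`, `heart` matrices.
#' @export
simulate_sample <- function(sim, phantom, continuous_targets = FALSE) {
  stopifnot(inherits(sim, "eit_simulator"))
  recon_of <- function(ph) {
    sigma <- element_conductivities(sim$mesh, ph)
    v <- solve_forward(sim$mesh, sigma, sim$protocol, sim$struct)
    normalize_image(reconstruct(sim$recon, v), sim$grid$support)
  }
  input <- recon_of(phantom)
  if (continuous_targets) {
    iso <- isolated_phantoms(phantom)
    list(input = input, lung = recon_of(iso$lungs_only),
         heart = recon_of(iso$heart_only))
  } else {
    masks <- rasterize_masks(phantom, sim$grid)
    list(input = input, lung = masks$lung, heart = masks$heart)
  }
}

#' Generate a simulated EIT dataset
#'
#' Draws `n` random phantoms and runs each through
#' [simulate_sample()]. Fully reproducible: sample i uses the seed
#' stream derived from (`seed`, i), so datasets are bit-identical across
#' calls and sample-level provenance records the phantom parameters.
#'
#' @param n number of samples.
#' @param sim an [eit_simulator()].
#' @param seed integer master seed for the phantom stream.
#' @param continuous_targets passed to [simulate_sample()].
#' @return object of class `eit_dataset`: list with arrays `inputs`,
#'   `lung_targets`, `heart_targets` (grid x grid x n), data frame
#'   `provenance` (per-sample phantom geometry and seed) and `meta`.
#' @export
generate_dataset <- function(n, sim = eit_simulator(), seed = 1L,
                             continuous_targets = FALSE) {
  stopifnot(n >= 1, inherits(sim, "eit_simulator"))
  g <- sim$grid$n
  inputs <- array(0, c(g, g, n))
  lung <- array(0, c(g, g, n))
  heart <- array(0, c(g, g, n))
  prov <- vector("list", n)
  for (i in seq_len(n)) {
    si <- derive_seed(seed, i)
    ph <- sample_phantom(sim$phantoms, seed = si)
    smp <- tryCatch(simulate_sample(sim, ph, continuous_targets),
                    error = function(e)
                      stop("sample ", i, ": ", conditionMessage(e)))
    inputs[, , i] <- smp$input
    lung[, , i] <- smp$lung
    heart[, , i] <- smp$heart
    cc <- t(vapply(ph$inclusions, function(a) c(a$center, a$radius), numeric(3)))
    prov[[i]] <- data.frame(sample = i, seed = si,
                            lx = cc[1, 1], ly = cc[1, 2], lr = cc[1, 3],
                            rx = cc[2, 1], ry = cc[2, 2], rr = cc[2, 3],
                            hx = cc[3, 1], hy = cc[3, 2], hr = cc[3, 3])
  }
  structure(list(inputs = inputs, lung_targets = lung, heart_targets = heart,
                 provenance = do.call(rbind, prov),
                 meta = list(n = n, seed = seed, grid = g,
                             continuous_targets = continuous_targets)),
            class = "eit_dataset")
}

#' @export
print.eit_dataset <- function(x, ...) {
  cat("EIT dataset: ", x$meta$n, " samples on a ", x$meta$grid, "x",
      x$meta$grid, " grid (",
      if (isTRUE(x$meta$continuous_targets)) "continuous" else "binary",
      " targets), seed ", x$meta$seed, "\n", sep = "")
  invisible(x)
}

#' Split a dataset into training and validation indices
#'
#' Deterministic shuffled split: floor(n * ratio) training samples, the
#' rest validation; the two index sets partition 1..n exactly.
#'
#' @param n number of samples (or an `eit_dataset`).
#' @param ratio training fraction in (0, 1), default 0.9.
#' @param seed shuffle seed.
#' @return object of class `dataset_split` with integer vectors `train`
#'   and `validation`.
#' @export
split_dataset <- function(n, ratio = 0.9, seed = 1L) {
  if (inherits(n, "eit_dataset")) n <- n$meta$n
  stopifnot(n >= 2, ratio > 0, ratio < 1)
  n_train <- floor(n * ratio)
  if (n_train < 1 || n_train >= n) stop("ratio leaves an empty split")
  perm <- with_seed(seed, sample.int(n))
  structure(list(train = sort(perm[seq_len(n_train)]),
                 validation = sort(perm[(n_train + 1L):n])),
            class = "dataset_split")
}

#' Balanced k-fold cross-validation indices
#'
#' Partitions 1..n into k disjoint folds whose sizes differ by at most
#' one, after a seeded shuffle. Used for training-stability reporting.
#'
#' @param n number of samples.
#' @param k number of folds, 2 <= k <= n.
#' @param seed shuffle seed.
#' @return list of k integer vectors partitioning 1..n.
#' @export
kfold_indices <- function(n, k = 5L, seed = 1L) {
  stopifnot(k >= 2, k <= n)
  perm <- with_seed(seed, sample.int(n))
  fold_of <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(f) sort(perm[fold_of == f]))
}

#' Save / load a dataset container
#'
#' Serializes the dataset (arrays, provenance, metadata) to a single
#' file; loading reproduces every array bit-exactly.
#'
#' @param dataset an `eit_dataset`.
#' @param path file path.
#' @return `save_dataset` returns `path` invisibly; `load_dataset`
#'   returns the `eit_dataset`.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "eit_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "eit_dataset")) stop("file does not contain an eit_dataset")
  x
}

#' Export a sample triptych as a PNG
#'
#' Writes input image, lung target and heart target side by side as a
#' grayscale PNG for visual inspection. Requires the `png` package.
#'
#' @param dataset an `eit_dataset`.
#' @param i sample index.
#' @param path output PNG path.
#' @return `path` invisibly.
#' @export
export_sample_png <- function(dataset, i, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required for PNG export")
  stopifnot(i >= 1, i <= dataset$meta$n)
  upright <- function(img) t(img)[rev(seq_len(ncol(img))), , drop = FALSE]
  trip <- cbind(upright(dataset$inputs[, , i]),
                upright(dataset$lung_targets[, , i]),
                upright(dataset$heart_targets[, , i]))
  png::writePNG(pmin(pmax(trip, 0), 1), path)
  invisible(path)
}
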