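# Optional adapter for the public EIDORS human measurement file
# (MATLAB v5 .mat, user-supplied download). Quantitative acceptance
# never depends on this module: real frames have no ground truth, so
# inference on them is qualitative only.

mat_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L, `5` = 4L,
                   `6` = 4L, `7` = 4L, `9` = 8L, `12` = 8L, `13` = 8L,
                   `16` = 1L)

read_mat_numeric <- function(con, type, nbytes) {
  sz <- mat_type_size[[as.character(type)]]
  n <- nbytes %/% sz
  switch(as.character(type),
         `1` = readBin(con, integer(), n, size = 1, signed = TRUE),
         `2` = readBin(con, integer(), n, size = 1, signed = FALSE),
         `3` = readBin(con, integer(), n, size = 2, signed = TRUE),
         `4` = readBin(con, integer(), n, size = 2, signed = FALSE),
         `5` = readBin(con, integer(), n, size = 4),
         `6` = readBin(con, integer(), n, size = 4),   # uint32 < 2^31 in practice
         `7` = readBin(con, numeric(), n, size = 4),
         `9` = readBin(con, numeric(), n, size = 8),
         `16` = readBin(con, integer(), n, size = 1, signed = FALSE),
         stop("unsupported MAT data type ", type))
}

# one sub/top-level element tag; handles the small-data-element format
read_mat_tag <- function(con) {
  w1 <- readBin(con, integer(), 1, size = 4)
  if (length(w1) == 0) return(NULL)
  small_n <- bitwAnd(bitwShiftR(w1, 16), 0xFFFFL)
  if (small_n > 0) {
    list(type = bitwAnd(w1, 0xFFFFL), nbytes = small_n, small = TRUE)
  } else {
    nb <- readBin(con, integer(), 1, size = 4)
    list(type = w1, nbytes = nb, small = FALSE)
  }
}

skip_mat_padding <- function(con, tag) {
  used <- if (tag$small) 4L else tag$nbytes
  pad <- if (tag$small) (4L - used %% 4L) %% 4L else (8L - used %% 8L) %% 8L
  # small elements occupy exactly 8 bytes total (4 tag + 4 data)
  if (tag$small) pad <- 4L - tag$nbytes
  if (pad > 0) readBin(con, raw(), pad)
  invisible(NULL)
}

read_mat_subelement <- function(con) {
  tag <- read_mat_tag(con)
  if (is.null(tag)) return(NULL)
  dat <- if (tag$nbytes > 0) read_mat_numeric(con, tag$type, tag$nbytes)
         else vector("numeric", 0)
  skip_mat_padding(con, tag)
  list(type = tag$type, data = dat)
}

# parse one miMATRIX payload (already positioned after its tag)
parse_mat_matrix <- function(con) {
  flags <- read_mat_subelement(con)
  cls <- bitwAnd(as.integer(flags$data[1]), 0xFFL)
  dims <- read_mat_subelement(con)$data
  name_el <- read_mat_subelement(con)
  nm <- rawToChar(as.raw(name_el$data[name_el$data != 0]))
  value <-
    if (cls %in% c(6, 7, 8, 9, 10, 11, 12, 13)) {        # numeric classes
      re <- read_mat_subelement(con)$data
      arr <- array(as.numeric(re), dim = dims)
      if (length(dims) == 2) arr <- matrix(arr, dims[1], dims[2])
      arr
    } else if (cls == 4) {                                # char
      ch <- read_mat_subelement(con)$data
      paste(intToUtf8(as.integer(ch), multiple = TRUE), collapse = "")
    } else if (cls == 1) {                                # cell
      n <- prod(dims)
      lapply(seq_len(n), function(i) read_mat_element(con)$value)
    } else if (cls == 2) {                                # struct
      flen <- read_mat_subelement(con)$data[1]
      fn_raw <- read_mat_subelement(con)$data
      nf <- length(fn_raw) %/% flen
      fnames <- vapply(seq_len(nf), function(i) {
        b <- fn_raw[((i - 1) * flen + 1):(i * flen)]
        rawToChar(as.raw(b[b != 0]))
      }, "")
      out <- vector("list", nf * prod(dims))
      for (i in seq_along(out)) out[[i]] <- read_mat_element(con)$value
      if (prod(dims) == 1) names(out) <- fnames
      out
    } else {
      stop("unsupported MATLAB array class ", cls)
    }
  list(name = nm, value = value)
}

# one top-level (or nested miMATRIX) element, following compression
read_mat_element <- function(con) {
  tag <- read_mat_tag(con)
  if (is.null(tag)) return(NULL)
  if (tag$type == 15) {                                  # zlib-compressed
    comp <- readBin(con, raw(), tag$nbytes)
    skip_mat_padding(con, tag)
    raw_dat <- memDecompress(comp, type = "gzip")
    con2 <- rawConnection(raw_dat, "rb")
    on.exit(close(con2))
    return(read_mat_element(con2))
  }
  if (tag$type != 14) {
    # skip non-matrix elements
    if (tag$nbytes > 0) readBin(con, raw(), tag$nbytes)
    skip_mat_padding(con, tag)
    return(list(name = NA_character_, value = NULL))
  }
  parse_mat_matrix(con)
}

#' Read a MATLAB v5 .mat file
#'
#' Minimal little-endian MAT v5 reader covering numeric arrays, char
#' arrays, cell arrays, structs and zlib-compressed elements — enough
#' for the public EIDORS measurement files. Errors on layouts outside
#' this subset.
#'
#' @param path path to the .mat file.
#' @return named list of variables.
#' @export
read_mat <- function(path) {
  if (!file.exists(path)) stop("external data not present: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, raw(), 128)
  if (length(header) < 128) stop("not a MAT v5 file: truncated header")
  endian <- rawToChar(header[127:128])
  if (endian != "IM") stop("unsupported MAT file (not little-endian v5)")
  out <- list()
  repeat {
    el <- tryCatch(read_mat_element(con), error = function(e) {
      if (grepl("unsupported", conditionMessage(e))) stop(e) else NULL
    })
    if (is.null(el)) break
    if (!is.na(el$name) && nzchar(el$name)) out[[el$name]] <- el$value
  }
  out
}

#' Write numeric matrices to a MATLAB v5 .mat file
#'
#' Minimal uncompressed writer for double 2D matrices; used to build
#' test fixtures that round-trip through [read_mat()].
#'
#' @param vars named list of numeric matrices.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_mat <- function(vars, path) {
  stopifnot(length(names(vars)) == length(vars), all(nzchar(names(vars))))
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by eitsep")
  header <- c(charToRaw(desc), rep(as.raw(0x20), 116 - nchar(desc)),
              rep(as.raw(0), 8))
  writeBin(header, con)
  writeBin(c(0x00L, 0x01L), con, size = 1)               # version 0x0100
  writeBin(charToRaw("IM"), con)
  pad8 <- function(n) (8 - n %% 8) %% 8
  for (nm in names(vars)) {
    m <- vars[[nm]]
    stopifnot(is.numeric(m))
    if (is.null(dim(m))) m <- matrix(m, ncol = 1)
    nmr <- charToRaw(nm)
    name_bytes <- length(nmr)
    name_total <- 8L + name_bytes + pad8(name_bytes)
    data_bytes <- 8L * length(m)
    total <- 16L + 16L + name_total + 8L + data_bytes + pad8(data_bytes)
    writeBin(as.integer(c(14L, total)), con, size = 4)               # miMATRIX
    writeBin(c(6L, 8L), con, size = 4)                   # array flags
    writeBin(c(6L, 0L), con, size = 4)                   # mxDOUBLE, no flags
    writeBin(c(5L, 8L), con, size = 4)                   # dims: miINT32 x 2
    writeBin(as.integer(dim(m)), con, size = 4)
    writeBin(as.integer(c(1L, name_bytes)), con, size = 4)           # name: miINT8
    writeBin(nmr, con)
    if (pad8(name_bytes)) writeBin(rep(as.raw(0), pad8(name_bytes)), con)
    writeBin(as.integer(c(9L, data_bytes)), con, size = 4)           # real: miDOUBLE
    writeBin(as.numeric(m), con, size = 8)
    if (pad8(data_bytes)) writeBin(rep(as.raw(0), pad8(data_bytes)), con)
  }
  invisible(path)
}

#' Load the EIDORS human frame sequence
#'
#' Reads a user-supplied copy of the public EIDORS thorax measurement
#' file and extracts the differential-voltage frames of the
#' 16-electrode adjacent protocol. Field mapping: the variable named
#' `zc_resp` is used if present, otherwise the first numeric matrix with
#' a dimension of 208; frames are columns (transposed if needed) and the
#' first `n_frames` are kept.
#'
#' @param path path to the .mat file (e.g. `montreal_data_1995.mat`).
#' @param n_frames number of consecutive frames to keep (default 24,
#'   about 3.3 s at the file's 7 Hz sampling rate).
#' @param sampling_rate sampling rate in Hz recorded in the result.
#' @return object of class `real_frame_sequence`: list with `frames`
#'   (208 x n matrix), `sampling_rate`, `source`.
#' @export
read_eidors_mat <- function(path, n_frames = 24L, sampling_rate = 7) {
  vars <- read_mat(path)
  pick <- NULL
  if (!is.null(vars$zc_resp) && is.numeric(vars$zc_resp)) pick <- vars$zc_resp
  if (is.null(pick)) {
    for (v in vars) {
      if (is.matrix(v) && is.numeric(v) && any(dim(v) == 208)) { pick <- v; break }
      if (is.list(v)) for (f in v)
        if (is.matrix(f) && is.numeric(f) && any(dim(f) == 208)) { pick <- f; break }
    }
  }
  if (is.null(pick))
    stop("unexpected file structure: no 208-measurement frame matrix found")
  if (nrow(pick) != 208) pick <- t(pick)
  if (nrow(pick) != 208) stop("frame matrix is not 208 measurements per frame")
  # complex impedances may arrive as interleaved or absolute values;
  # numeric path keeps real-valued data as-is
  keep <- seq_len(min(n_frames, ncol(pick)))
  structure(list(frames = pick[, keep, drop = FALSE],
                 sampling_rate = sampling_rate, source = path),
            class = "real_frame_sequence")
}

#' Zero-shot inference on a real frame sequence
#'
#' Reconstructs each frame against a reference frame (by default the
#' frame with the smallest overall signal power, an end-expiration
#' proxy) and runs the simulation-trained model on each normalized
#' image. No retraining or fine-tuning is performed.
#'
#' @param model trained `eit_unet` or `eit_fit`.
#' @param sequence a `real_frame_sequence`.
#' @param recon a `recon_model` for the matching protocol.
#' @param reference_index reference frame index; NULL picks the
#'   minimum-power frame.
#' @return list with one element per frame: `image`, `lung`, `heart`
#'   matrices; the chosen reference index is in
#'   `attr(, "reference_index")`.
#' @export
infer_sequence <- function(model, sequence, recon, reference_index = NULL) {
  if (inherits(model, "eit_fit")) model <- model$model
  stopifnot(inherits(sequence, "real_frame_sequence"),
            inherits(recon, "recon_model"))
  fr <- sequence$frames
  if (nrow(fr) != ncol(recon$matrix))
    stop("protocol mismatch: sequence has ", nrow(fr), " measurements, ",
         "reconstruction expects ", ncol(recon$matrix))
  if (is.null(reference_index))
    reference_index <- which.min(colSums(fr^2))
  v_ref <- fr[, reference_index]
  out <- lapply(seq_len(ncol(fr)), function(i) {
    img <- normalize_image(reconstruct(recon, fr[, i], v_ref),
                           recon$grid$support)
    maps <- forward_pass(model, img)
    list(image = img, lung = maps$lung, heart = maps$heart)
  })
  attr(out, "reference_index") <- reference_index
  out
}
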