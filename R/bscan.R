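#' B-scan container
#'
#' A `bscan` holds one grayscale OCT cross-section as a numeric matrix
#' (rows = depth/axial index z, shallowest first; columns = lateral index x)
#' together with its pixel-pitch calibration. Intensities are kept on their
#' source integer scale (e.g. 0..65535 for 16-bit input) or any non-negative
#' floating-point scale for synthetic data.
#'
#' Depth below the top row in micrometres is `(row - 1) * axial_pitch`;
#' lateral position is `(col - 1) * lateral_pitch` (1-based indices).
#'
#' @param pixels numeric matrix of non-negative, finite intensities with at
#'   least 2 rows and 2 columns.
#' @param axial_pitch micrometres per pixel along depth (> 0). The axial pixel
#'   pitch is instrument-specific and must be supplied; the phantom default is
#'   5 µm/px.
#' @param lateral_pitch micrometres per pixel along the lateral axis (> 0).
#'   The default 2.5 µm/px corresponds to a 5 mm scan split into 2000 A-scans.
#' @param bit_depth integer sample depth of the source image (informational).
#' @param id character label.
#' @return An object of class `bscan`.
#' @export
bscan <- function(pixels, axial_pitch = 5, lateral_pitch = 2.5,
                  bit_depth = 16L, id = "") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("`pixels` must have at least 2 rows and 2 columns", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("`pixels` must be finite", call. = FALSE)
  if (any(pixels < 0))
    stop("`pixels` must be non-negative", call. = FALSE)
  if (!is.numeric(axial_pitch) || length(axial_pitch) != 1L || axial_pitch <= 0)
    stop("`axial_pitch` must be a single positive number (µm/px)", call. = FALSE)
  if (!is.numeric(lateral_pitch) || length(lateral_pitch) != 1L || lateral_pitch <= 0)
    stop("`lateral_pitch` must be a single positive number (µm/px)", call. = FALSE)
  structure(
    list(pixels = pixels, axial_pitch = axial_pitch,
         lateral_pitch = lateral_pitch, bit_depth = as.integer(bit_depth),
         id = as.character(id)),
    class = "bscan"
  )
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan %s> %d x %d px (depth x lateral), %g x %g um/px, %d-bit\n",
              if (nzchar(x$id)) x$id else "", nrow(x$pixels), ncol(x$pixels),
              x$axial_pitch, x$lateral_pitch, x$bit_depth))
  invisible(x)
}

#' @export
dim.bscan <- function(x) dim(x$pixels)

#' Test for / coerce to bscan
#' @param x object.
#' @param ... passed to [bscan()] when coercing a matrix.
#' @return `is_bscan()`: logical; `as_bscan()`: a `bscan`.
#' @export
is_bscan <- function(x) inherits(x, "bscan")

#' @rdname is_bscan
#' @export
as_bscan <- function(x, ...) {
  if (is_bscan(x)) return(x)
  if (is.matrix(x)) return(bscan(x, ...))
  stop("cannot coerce to bscan", call. = FALSE)
}

#' Rectangular region of interest
#'
#' 1-based, closed-interval rectangle in B-scan coordinates: columns
#' `x_start..x_end` (lateral), rows `z_start..z_end` (axial). Used to select
#' the region within which depth-profile analyses run.
#'
#' @param x_start,x_end first and last lateral column (inclusive).
#' @param z_start,z_end first and last axial row (inclusive).
#' @return An object of class `roi`.
#' @export
roi <- function(x_start, x_end, z_start, z_end) {
  v <- c(x_start, x_end, z_start, z_end)
  if (any(v != round(v)) || any(v < 1))
    stop("roi indices must be positive integers", call. = FALSE)
  if (x_end < x_start || z_end < z_start)
    stop("roi must satisfy x_start <= x_end and z_start <= z_end", call. = FALSE)
  structure(list(x_start = as.integer(x_start), x_end = as.integer(x_end),
                 z_start = as.integer(z_start), z_end = as.integer(z_end)),
            class = "roi")
}

check_roi <- function(r, pixels) {
  if (!inherits(r, "roi")) stop("`roi` must be created with roi()", call. = FALSE)
  if (r$x_end > ncol(pixels) || r$z_end > nrow(pixels))
    stop(sprintf("roi (%d..%d, %d..%d) exceeds image %d x %d",
                 r$x_start, r$x_end, r$z_start, r$z_end,
                 nrow(pixels), ncol(pixels)), call. = FALSE)
  invisible(r)
}

#' Crop a B-scan to a region of interest
#' @param b a [bscan()].
#' @param r a [roi()].
#' @return A `bscan` restricted to the ROI (calibration preserved).
#' @export
crop_bscan <- function(b, r) {
  b <- as_bscan(b)
  check_roi(r, b$pixels)
  bscan(b$pixels[r$z_start:r$z_end, r$x_start:r$x_end, drop = FALSE],
        axial_pitch = b$axial_pitch, lateral_pitch = b$lateral_pitch,
        bit_depth = b$bit_depth, id = b$id)
}

#' Ordered stack of B-scans (C-scan)
#'
#' @param bscans list of [bscan()] objects with identical shape and pitch.
#' @param slice_pitch micrometres between successive B-scans (default 10,
#'   i.e. 500 slices over 5 mm).
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(bscans, slice_pitch = 10) {
  if (!length(bscans)) stop("volume needs at least one B-scan", call. = FALSE)
  bscans <- lapply(bscans, as_bscan)
  d <- dim(bscans[[1L]]$pixels)
  ok <- vapply(bscans, function(b) identical(dim(b$pixels), d), logical(1))
  if (!all(ok))
    stop("all B-scans in a volume must share the same shape", call. = FALSE)
  if (!is.numeric(slice_pitch) || slice_pitch <= 0)
    stop("`slice_pitch` must be positive (µm)", call. = FALSE)
  structure(list(bscans = bscans, slice_pitch = slice_pitch), class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$bscans[[1L]]$pixels)
  cat(sprintf("<oct_volume> %d slices of %d x %d px, slice pitch %g um\n",
              length(x$bscans), d[1], d[2], x$slice_pitch))
  invisible(x)
}

#' @export
length.oct_volume <- function(x) length(x$bscans)

# ---- file I/O --------------------------------------------------------------

luma_weights <- c(0.299, 0.587, 0.114)

# read one image file to an integer-scale grayscale matrix
read_gray <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE, all = FALSE)
    bits <- attr(img, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(img) > 255) 16L else 8L
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    img <- img * (2^bits - 1)  # png gives [0,1]; restore source integer scale
  } else {
    stop("unsupported image format: .", ext, " (use PNG or TIFF)", call. = FALSE)
  }
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc >= 3L) {
      img <- luma_weights[1] * img[, , 1] + luma_weights[2] * img[, , 2] +
        luma_weights[3] * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  img <- round(as.matrix(img))
  if (!length(img) || !nrow(img) || !ncol(img))
    stop("zero-sized image: ", path, call. = FALSE)
  attr(img, "bits") <- as.integer(bits)
  img
}

#' Read a B-scan image
#'
#' Reads an 8- or 16-bit single-channel PNG or TIFF (RGB is accepted and
#' converted to grayscale with luma weights 0.299/0.587/0.114) and attaches
#' pixel-pitch calibration. Row 1 is the shallowest depth.
#'
#' @param path file path (PNG or TIFF).
#' @param axial_pitch,lateral_pitch calibration in µm per pixel (required;
#'   must be positive).
#' @param id optional label; defaults to the file name.
#' @return A [bscan()].
#' @export
read_bscan <- function(path, axial_pitch, lateral_pitch, id = basename(path)) {
  img <- read_gray(path)
  bits <- attr(img, "bits")
  attr(img, "bits") <- NULL
  bscan(img, axial_pitch = axial_pitch, lateral_pitch = lateral_pitch,
        bit_depth = bits, id = id)
}

#' Write a B-scan image
#'
#' Writes the pixel matrix as an 8- or 16-bit grayscale PNG or TIFF (format
#' chosen by file extension). Intensities are clamped to the target integer
#' range, so a round trip through [read_bscan()] is pixel-identical for
#' integer-valued input within range.
#'
#' @param b a [bscan()] or matrix.
#' @param path output path (.png, .tif or .tiff).
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
write_bscan <- function(b, path, bits = 16L) {
  b <- as_bscan(b)
  if (!bits %in% c(8L, 16L)) stop("`bits` must be 8 or 16", call. = FALSE)
  maxv <- 2^bits - 1
  m <- pmin(pmax(round(b$pixels), 0), maxv) / maxv
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = as.integer(bits))
  } else if (ext == "png") {
    if (bits == 16L)
      stop("16-bit output is written as TIFF; PNG output is 8-bit",
           call. = FALSE)
    png::writePNG(m, path)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read a C-scan volume
#'
#' Accepts either a multi-page TIFF or a directory of identically shaped
#' PNG/TIFF images; for a directory, lexicographic file order defines slice
#' order.
#'
#' @param path_or_dir multi-page TIFF file or directory of images.
#' @param slice_pitch µm between successive B-scans.
#' @param axial_pitch,lateral_pitch per-slice calibration (µm/px).
#' @return An [oct_volume()].
#' @export
read_volume <- function(path_or_dir, slice_pitch = 10, axial_pitch, lateral_pitch) {
  if (dir.exists(path_or_dir)) {
    files <- sort(list.files(path_or_dir, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no PNG/TIFF images in ", path_or_dir, call. = FALSE)
    bscans <- lapply(files, read_bscan, axial_pitch = axial_pitch,
                     lateral_pitch = lateral_pitch)
  } else {
    if (!file.exists(path_or_dir)) stop("not found: ", path_or_dir, call. = FALSE)
    pages <- tiff::readTIFF(path_or_dir, as.is = TRUE, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    bscans <- lapply(seq_along(pages), function(i) {
      m <- pages[[i]]
      if (length(dim(m)) == 3L)
        m <- luma_weights[1] * m[, , 1] + luma_weights[2] * m[, , 2] +
          luma_weights[3] * m[, , 3]
      bscan(round(m), axial_pitch = axial_pitch, lateral_pitch = lateral_pitch,
            id = sprintf("%s#%d", basename(path_or_dir), i))
    })
  }
  d <- dim(bscans[[1L]]$pixels)
  ok <- vapply(bscans, function(b) identical(dim(b$pixels), d), logical(1))
  if (!all(ok))
    stop("slice shape mismatch: all images in a volume must have equal size",
         call. = FALSE)
  oct_volume(bscans, slice_pitch = slice_pitch)
}

#' Write a volume as a multi-page TIFF
#' @param v an [oct_volume()].
#' @param path output .tif path.
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, bits = 16L) {
  maxv <- 2^bits - 1
  pages <- lapply(v$bscans, function(b) pmin(pmax(round(b$pixels), 0), maxv) / maxv)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Write / read a binary or label mask image
#'
#' Binary masks are written as 8-bit PNG/TIFF with values {0, 255}; integer
#' label images with more levels are written 16-bit.
#'
#' @param mask logical or small-integer matrix.
#' @param path output path.
#' @return `path` (write) or an integer matrix (read), invisibly for write.
#' @export
write_mask <- function(mask, path) {
  m <- as.matrix(mask)
  storage.mode(m) <- "double"
  mx <- max(m)
  if (mx <= 1) {
    write_bscan(bscan(m * 255), path, bits = 8L)
  } else if (mx <= 255) {
    write_bscan(bscan(m), path, bits = 8L)
  } else if (mx <= 65535) {
    write_bscan(bscan(m), path, bits = 16L)  # requires a TIFF path
  } else stop("mask labels exceed 16-bit range", call. = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- read_gray(path)
  attr(img, "bits") <- NULL
  storage.mode(img) <- "integer"
  img
}

#' Write / read a rectangular results table (CSV, UTF-8, header row)
#' @param x data frame.
#' @param path .csv path.
#' @return `path` (write) or a tibble (read).
#' @export
write_table <- function(x, path) {
  readr::write_csv(as.data.frame(x), path)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) readr::read_csv(path, show_col_types = FALSE)

#' Write / read ground-truth (or any structured) metadata as JSON
#' @param truth list-like object (matrices are stored as nested arrays).
#' @param path .json path.
#' @return `path` (write) or a list (read).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Read a YAML or JSON configuration file
#' @param path .yaml/.yml/.json path.
#' @return Named list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be YAML or JSON", call. = FALSE)
}
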