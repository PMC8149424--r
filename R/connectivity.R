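#' Parameters of the structural-connectivity pipeline
#'
#' @param log_size,log_sigma Laplacian-of-Gaussian kernel size (odd, default
#'   5) and width (default 0.5 px).
#' @param connectivity component connectivity, 4 or 8 (default 8).
#' @param se_radius,se_shape structuring element for erosion/dilation
#'   (opening), default box of radius 1.
#' @param se_close_radius structuring element radius for the closing used in
#'   total-enamel accounting and abrasion detection (default 2, the smallest
#'   closing that bridges the inter-speckle gaps left after binarization; use
#'   a larger radius, roughly half the widest abrasion to bridge, when
#'   detecting abrasion notches).
#' @param sobel_threshold gradient-magnitude cutoff as a fraction of the
#'   maximum (default 0.1).
#' @param min_component_px discard connected components smaller than this
#'   (default 20).
#' @param surface_band_px band around the detected surface inspected for
#'   closing-induced protrusions (default 15).
#' @param gap_tolerance_px lateral gap tolerance when merging protrusion
#'   columns into abrasion sites (default 2).
#' @param min_excess_px a column counts as protruding when its closing-grown
#'   pixel count inside the surface band exceeds the image-wide median grown
#'   count (the ordinary boundary growth of closing) by at least this many
#'   pixels (default 3).
#' @return An object of class `connectivity_params`.
#' @export
connectivity_params <- function(log_size = 5L, log_sigma = 0.5,
                                connectivity = 8L,
                                se_radius = 1L, se_shape = "box",
                                se_close_radius = 2L,
                                sobel_threshold = 0.1,
                                min_component_px = 20L,
                                surface_band_px = 15L,
                                gap_tolerance_px = 2L,
                                min_excess_px = 3L) {
  if (log_size %% 2 != 1 || log_size < 3)
    stop("`log_size` must be odd and >= 3", call. = FALSE)
  if (!connectivity %in% c(4L, 8L))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  if (sobel_threshold <= 0 || sobel_threshold > 1)
    stop("`sobel_threshold` must be in (0, 1]", call. = FALSE)
  structure(list(log_size = as.integer(log_size), log_sigma = log_sigma,
                 connectivity = as.integer(connectivity),
                 se_radius = as.integer(se_radius), se_shape = se_shape,
                 se_close_radius = as.integer(se_close_radius),
                 sobel_threshold = sobel_threshold,
                 min_component_px = as.integer(min_component_px),
                 surface_band_px = as.integer(surface_band_px),
                 gap_tolerance_px = as.integer(gap_tolerance_px),
                 min_excess_px = as.integer(min_excess_px)),
            class = "connectivity_params")
}

#' Laplacian-of-Gaussian filtering of a B-scan
#' @param img matrix or [bscan()].
#' @param params a [connectivity_params()].
#' @return Signed filtered matrix (a constant image filters to zero).
#' @export
log_filter <- function(img, params = connectivity_params()) {
  convolve2(img, log_kernel(params$log_size, params$log_sigma))
}

#' Trace connected components of a binary mask
#'
#' Thin wrapper over [label_components()] using the pipeline parameters:
#' maximal components under the configured connectivity, small components
#' discarded, labels by decreasing size.
#'
#' @param mask logical/0-1 matrix.
#' @param params a [connectivity_params()].
#' @param img optional intensity image for per-component intensity sums.
#' @return List with `labels` and `table` (see [label_components()]).
#' @export
trace_components <- function(mask, params = connectivity_params(), img = NULL) {
  label_components(mask, connectivity = params$connectivity,
                   min_px = params$min_component_px, img = img)
}

#' Sobel edge mask and overlay renderings
#'
#' Edge pixels are those whose Sobel gradient magnitude is at least
#' `sobel_threshold` times the image maximum. Three RGB overlays are
#' returned: edges over the grayscale image, edges over the binary mask, and
#' the fully processed rendering (edges over the mask-limited grayscale),
#' with edges in a fixed colour (red).
#'
#' @param img matrix or [bscan()].
#' @param mask binary mask from the pipeline.
#' @param params a [connectivity_params()].
#' @return List: `edge_mask` (logical), `overlay_gray`, `overlay_binary`,
#'   `overlay_processed` (H x W x 3 arrays in 0..1).
#' @export
sobel_overlay <- function(img, mask, params = connectivity_params()) {
  m <- as_pixel_matrix(img)
  g <- sobel_magnitude(m)
  mx <- max(g)
  edge <- if (mx > 0) g >= params$sobel_threshold * mx else g > 0
  gray <- if (max(m) > 0) m / max(m) else m
  mk <- as_pixel_matrix(mask) != 0
  paint <- function(base) {
    rgb <- array(rep(base, 3L), dim = c(nrow(base), ncol(base), 3L))
    rgb[, , 1][edge] <- 1
    rgb[, , 2][edge] <- 0
    rgb[, , 3][edge] <- 0
    rgb
  }
  list(edge_mask = edge,
       overlay_gray = paint(gray),
       overlay_binary = paint(mk * 1),
       overlay_processed = paint(gray * mk))
}

#' Morphological closing and total-enamel accounting
#'
#' Closes the mask (dilation then erosion with the configured element) and
#' totals the source intensities and pixel count over the closed mask — the
#' "total enamel": summed intensities of the connected structures.
#'
#' @param img source grayscale matrix or [bscan()].
#' @param mask binary mask (typically the opened component mask).
#' @param params a [connectivity_params()].
#' @return List: `closed_mask`, `total_enamel_intensity`, `total_enamel_px`.
#' @export
close_and_account <- function(img, mask, params = connectivity_params()) {
  m <- as_pixel_matrix(img)
  cl <- close_mask(mask, radius = params$se_close_radius, shape = params$se_shape)
  list(closed_mask = cl,
       total_enamel_intensity = sum(m[cl]),
       total_enamel_px = sum(cl))
}

#' Detect abrasion sites as closing-induced surface protrusions
#'
#' Protrusion pixels are those gained by morphological closing
#' (`closed_mask` minus `pre_close_mask`) that lie above the local detected
#' surface, within `surface_band_px` of it: at an abrasion the surface line
#' dips, closing bridges the dip from the neighbouring columns, and the
#' bridge sits on top of the local surface (the morphological growth of the
#' tooth surface). Growth deeper than the surface is ordinary hole-filling
#' and is ignored. Closing also grows every boundary a little, so a column counts
#' as protruding only when its laterally smoothed grown count (running
#' median over 7 columns, suppressing single-column boundary raggedness)
#' exceeds the image-wide median grown count by `min_excess_px`. Contiguous
#' lateral runs of protruding columns (up to the configured gap tolerance)
#' become sites, sorted by protrusion area descending.
#'
#' @param closed_mask,pre_close_mask same-shape binary masks (after/before
#'   closing).
#' @param surface_rows integer per-column surface rows (e.g. from
#'   [detect_surface()]); `NA` columns are skipped.
#' @param params a [connectivity_params()].
#' @return Tibble of sites: x_start, x_end, area_px; empty when none.
#' @export
detect_abrasion <- function(closed_mask, pre_close_mask, surface_rows,
                            params = connectivity_params()) {
  cl <- as_pixel_matrix(closed_mask) != 0
  pr <- as_pixel_matrix(pre_close_mask) != 0
  stopifnot(identical(dim(cl), dim(pr)),
            length(surface_rows) == ncol(cl))
  n <- nrow(cl)
  grown <- cl & !pr
  Z <- matrix(seq_len(n), n, ncol(cl))
  SR <- matrix(surface_rows, n, ncol(cl), byrow = TRUE)
  band <- !is.na(SR) & Z < SR & Z >= SR - params$surface_band_px
  prot <- grown & band
  colcount <- colSums(prot)
  smooth <- if (length(colcount) >= 7) as.numeric(stats::runmed(colcount, 7))
    else colcount
  baseline <- stats::median(smooth)
  cols <- which(smooth >= baseline + params$min_excess_px)
  if (!length(cols)) {
    return(tibble::tibble(x_start = integer(), x_end = integer(),
                          area_px = integer()))
  }
  # merge columns into runs with gap tolerance
  brk <- which(diff(cols) > params$gap_tolerance_px + 1L)
  run_id <- cumsum(c(1L, seq_along(cols)[-1] %in% (brk + 1L)))
  sites <- tibble::tibble(col = cols, run = run_id,
                          cnt = colcount[cols]) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(x_start = min(.data$col), x_end = max(.data$col),
                     area_px = as.integer(sum(.data$cnt)), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$area_px)) |>
    dplyr::select(-"run")
  sites
}

#' Run the full structural-connectivity pipeline on a B-scan
#'
#' Steps: Laplacian-of-Gaussian filtering, global-Otsu binarization of the
#' rescaled absolute response, connected-component tracing, morphological
#' opening (erosion then dilation), Sobel edge overlays, morphological
#' closing with total-enamel accounting, and (when surface rows are
#' available) abrasion-site detection from closing-induced protrusions.
#'
#' @param b a [bscan()] or matrix.
#' @param params a [connectivity_params()].
#' @param surface_rows optional per-column surface rows; when `NULL` they are
#'   detected with [detect_surface()].
#' @param surface_peak_params a [peak_params()] for surface detection.
#' @return An object of class `connectivity_result`: filtered image, binary
#'   mask + threshold, component labels and table, opened/closed masks, edge
#'   mask and overlays, `total_enamel_intensity`, `total_enamel_px`, and
#'   `abrasion_sites` (tibble).
#' @export
run_connectivity <- function(b, params = connectivity_params(),
                             surface_rows = NULL,
                             surface_peak_params = peak_params()) {
  b <- as_bscan(b)
  filt <- log_filter(b, params)
  bin <- binarize_otsu(filt)
  comp <- trace_components(bin$mask, params, img = b$pixels)
  opened <- open_mask(comp$labels > 0, radius = params$se_radius,
                      shape = params$se_shape)
  edges <- sobel_overlay(b, bin$mask, params)
  acct <- close_and_account(b, opened, params)
  if (is.null(surface_rows)) surface_rows <- detect_surface(b, surface_peak_params)
  sites <- detect_abrasion(acct$closed_mask, opened, surface_rows, params)
  structure(list(
    filtered = filt, binary_mask = bin$mask, binarize_threshold = bin$threshold,
    component_labels = comp$labels, component_table = comp$table,
    opened_mask = opened, edge_mask = edges$edge_mask,
    overlay_gray = edges$overlay_gray, overlay_binary = edges$overlay_binary,
    overlay_processed = edges$overlay_processed,
    closed_mask = acct$closed_mask,
    total_enamel_intensity = acct$total_enamel_intensity,
    total_enamel_px = acct$total_enamel_px,
    surface_rows = surface_rows, abrasion_sites = sites,
    params = params
  ), class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf(paste0("<connectivity_result> %d components, ",
                     "total enamel %.4g over %d px, %d abrasion site(s)\n"),
              nrow(x$component_table), x$total_enamel_intensity,
              x$total_enamel_px, nrow(x$abrasion_sites)))
  invisible(x)
}

#' Tidy a connectivity result into its component table
#' @param x a `connectivity_result`.
#' @param ... unused.
#' @return Tibble of connected components (label, px, bbox, intensity sum).
#' @method tidy connectivity_result
#' @export
tidy.connectivity_result <- function(x, ...) x$component_table

#' One-row summary of a connectivity result
#' @param x a `connectivity_result`.
#' @param ... unused.
#' @return One-row tibble: n_components, total_enamel_intensity,
#'   total_enamel_px, n_abrasion_sites.
#' @method glance connectivity_result
#' @export
glance.connectivity_result <- function(x, ...) {
  tibble::tibble(n_components = nrow(x$component_table),
                 total_enamel_intensity = x$total_enamel_intensity,
                 total_enamel_px = x$total_enamel_px,
                 n_abrasion_sites = nrow(x$abrasion_sites))
}
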