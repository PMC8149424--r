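#' Parameters of the intensity-based layer-segmentation pipeline
#'
#' @param median_size median-filter window (default 5, i.e. 5x5).
#' @param n_thresholds number of multilevel Otsu thresholds (default 3, so 4
#'   intensity classes).
#' @param channel_sobel_thresholds per-class Sobel gradient cutoffs as
#'   fractions of each class's maximum gradient; a single value is recycled
#'   (default 0.1).
#' @param log_size,log_sigma LoG kernel used per class (defaults 5, 0.5).
#' @param connectivity component connectivity (default 8).
#' @param se_radius opening radius per class (default 1).
#' @param se_close_radius closing radius per class (default 1).
#' @param se_shape "box" or "disc".
#' @param min_component_px minimum component size per class (default 20).
#' @param class_palette ordered colours, lowest to highest intensity class;
#'   length must be `n_thresholds + 1` (default navy, green, red, magenta).
#' @param overlay_alpha blending weight of class colours in the composite
#'   overlay (default 0.7).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(median_size = 5L, n_thresholds = 3L,
                                channel_sobel_thresholds = 0.1,
                                log_size = 5L, log_sigma = 0.5,
                                connectivity = 8L, se_radius = 1L,
                                se_close_radius = 1L, se_shape = "box",
                                min_component_px = 20L,
                                class_palette = c("#000080", "#00A000",
                                                  "#FF0000", "#FF00FF"),
                                overlay_alpha = 0.7) {
  if (n_thresholds < 1) stop("`n_thresholds` must be >= 1", call. = FALSE)
  n_classes <- n_thresholds + 1L
  if (length(channel_sobel_thresholds) == 1L)
    channel_sobel_thresholds <- rep(channel_sobel_thresholds, n_classes)
  if (length(channel_sobel_thresholds) != n_classes)
    stop("need one Sobel threshold per class", call. = FALSE)
  if (length(class_palette) != n_classes)
    stop(sprintf("`class_palette` must have %d colours (n_thresholds + 1)",
                 n_classes), call. = FALSE)
  structure(list(median_size = as.integer(median_size),
                 n_thresholds = as.integer(n_thresholds),
                 channel_sobel_thresholds = channel_sobel_thresholds,
                 log_size = as.integer(log_size), log_sigma = log_sigma,
                 connectivity = as.integer(connectivity),
                 se_radius = as.integer(se_radius),
                 se_close_radius = as.integer(se_close_radius),
                 se_shape = se_shape,
                 min_component_px = as.integer(min_component_px),
                 class_palette = class_palette,
                 overlay_alpha = overlay_alpha),
            class = "segmentation_params")
}

# connectivity_params view of the per-class processing settings
as_connectivity_params <- function(p) {
  connectivity_params(log_size = p$log_size, log_sigma = p$log_sigma,
                      connectivity = p$connectivity, se_radius = p$se_radius,
                      se_shape = p$se_shape,
                      se_close_radius = p$se_close_radius,
                      min_component_px = p$min_component_px)
}

#' Multilevel Otsu thresholds of an image
#'
#' @param img matrix or [bscan()] (typically median-filtered first).
#' @param n_thresholds number of thresholds (default 3).
#' @return Strictly increasing thresholds; see [otsu_thresholds()].
#' @export
multi_otsu <- function(img, n_thresholds = 3L)
  otsu_thresholds(img, n = n_thresholds)

#' Quantize an image into intensity classes and colorize
#'
#' Class `i` (1-based, i = 1..n+1) holds pixels with
#' `t[i-1] < v <= t[i]` (`t[0] = -Inf`, `t[n+1] = Inf`). A global Otsu
#' foreground mask is computed on the same image and stored; class-1 pixels
#' outside the foreground are flagged as background. The RGB rendering
#' paints classes by the palette.
#'
#' @param img matrix or [bscan()] (median-filtered intensities).
#' @param thresholds thresholds from [multi_otsu()].
#' @param palette one colour per class (length `length(thresholds) + 1`).
#' @return List: `class_map` (integer matrix, 1..n_classes),
#'   `foreground` (logical, global-Otsu), `background` (logical: class 1 and
#'   not foreground), `rgb` (H x W x 3 array).
#' @export
quantize_colorize <- function(img, thresholds, palette) {
  m <- as_pixel_matrix(img)
  if (length(palette) != length(thresholds) + 1L)
    stop("palette size must be length(thresholds) + 1", call. = FALSE)
  # class i holds t[i-1] < v <= t[i]: count how many thresholds lie below v
  cls <- matrix(1L + rowSums(outer(as.vector(m), thresholds, ">")),
                nrow(m), ncol(m))
  fg <- binarize_otsu(m)$mask
  rgbv <- grDevices::col2rgb(palette) / 255
  out <- array(0, dim = c(nrow(m), ncol(m), 3L))
  for (ch in 1:3) out[, , ch] <- matrix(rgbv[ch, cls], nrow(m), ncol(m))
  list(class_map = cls, foreground = fg, background = cls == 1L & !fg,
       rgb = out)
}

#' Per-class connected structures
#'
#' Processes every intensity class independently with the connectivity
#' module's machinery. Edge detection (LoG, then Sobel at the class's own
#' threshold) runs on the class-masked grayscale intensities so the filters
#' see real gradients; connected components are then traced on the extracted
#' class channel itself (connectivity 8, minimum size), opened, and
#' morphologically closed, with intensity accounting against the masked
#' grayscale. Outputs never mix classes.
#'
#' @param img source grayscale matrix or [bscan()].
#' @param class_map integer class map from [quantize_colorize()].
#' @param params a [segmentation_params()].
#' @param classes which classes to process (default all present except the
#'   lowest/background class when `drop_background = TRUE`).
#' @param drop_background skip class 1 (default TRUE).
#' @return Named list (class `k` -> list with `class_mask`, `log_edges`
#'   (binarized LoG response within the class), `edge_mask` (Sobel),
#'   `component_labels`, `component_table`, `opened_mask`, `closed_mask`,
#'   `total_intensity`, `total_px`). Empty classes yield empty masks and zero
#'   components.
#' @export
per_channel_structures <- function(img, class_map, params = segmentation_params(),
                                   classes = NULL, drop_background = TRUE) {
  m <- as_pixel_matrix(img)
  cp <- as_connectivity_params(params)
  n_classes <- params$n_thresholds + 1L
  if (is.null(classes)) {
    classes <- seq_len(n_classes)
    if (drop_background) classes <- classes[-1L]
  }
  out <- lapply(classes, function(k) {
    cmask <- class_map == k
    if (!any(cmask)) {
      empty <- matrix(FALSE, nrow(m), ncol(m))
      return(list(class_mask = empty, log_edges = empty, edge_mask = empty,
                  component_labels = matrix(0L, nrow(m), ncol(m)),
                  component_table = tibble::tibble(),
                  opened_mask = empty, closed_mask = empty,
                  total_intensity = 0, total_px = 0L))
    }
    masked <- m * cmask
    filt <- log_filter(masked, cp)
    log_edges <- suppressWarnings(binarize_otsu(filt))$mask
    thr_k <- params$channel_sobel_thresholds[k]
    g <- sobel_magnitude(masked)
    edge <- if (max(g) > 0) g >= thr_k * max(g) else g > 0
    comp <- trace_components(cmask, cp, img = masked)
    opened <- open_mask(comp$labels > 0, radius = cp$se_radius,
                        shape = cp$se_shape)
    acct <- close_and_account(masked, opened, cp)
    list(class_mask = cmask, log_edges = log_edges, edge_mask = edge,
         component_labels = comp$labels, component_table = comp$table,
         opened_mask = opened, closed_mask = acct$closed_mask,
         total_intensity = acct$total_enamel_intensity,
         total_px = acct$total_enamel_px)
  })
  names(out) <- paste0("class_", classes)
  out
}

#' Composite overlay of per-class closed structures
#'
#' Draws each class's closed mask in its palette colour over the grayscale
#' source, lowest class first and highest last (so overlaps show the higher
#' class), with configurable alpha; the source stays visible where no class
#' is drawn.
#'
#' @param img matrix or [bscan()].
#' @param structures result of [per_channel_structures()] (or a named list
#'   `class_k` -> list with `closed_mask`).
#' @param params a [segmentation_params()] (palette + alpha).
#' @return H x W x 3 RGB array in 0..1.
#' @export
compose_overlay <- function(img, structures, params = segmentation_params()) {
  m <- as_pixel_matrix(img)
  gray <- if (max(m) > 0) m / max(m) else m
  out <- array(rep(gray, 3L), dim = c(nrow(m), ncol(m), 3L))
  ks <- sort(as.integer(sub("class_", "", names(structures))))
  rgbv <- grDevices::col2rgb(params$class_palette) / 255
  a <- params$overlay_alpha
  for (k in ks) {
    mk <- structures[[paste0("class_", k)]]$closed_mask
    if (!any(mk)) next
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[mk] <- (1 - a) * plane[mk] + a * rgbv[ch, k]
      out[, , ch] <- plane
    }
  }
  out
}

#' Run the full intensity-based layer-segmentation pipeline
#'
#' Median filtering (5x5 by default), multilevel Otsu thresholding, class
#' quantization and colorization with a global-Otsu foreground mask,
#' per-class connected structures (LoG, binarize, components, opening, Sobel,
#' closing), and the composite overlay.
#'
#' @param b a [bscan()] or matrix.
#' @param params a [segmentation_params()].
#' @return An object of class `layer_segmentation`: `median_img`,
#'   `otsu_thresholds`, `class_map`, `foreground`, `background`,
#'   `quantized_rgb`, `structures` (per class), `overlay`, `params`.
#' @export
run_layer_segmentation <- function(b, params = segmentation_params()) {
  b <- as_bscan(b)
  med <- median_filter(b$pixels, params$median_size)
  thr <- multi_otsu(med, params$n_thresholds)
  q <- quantize_colorize(med, thr, params$class_palette)
  st <- per_channel_structures(b$pixels, q$class_map, params)
  ov <- compose_overlay(b$pixels, st, params)
  structure(list(median_img = med, otsu_thresholds = thr,
                 class_map = q$class_map, foreground = q$foreground,
                 background = q$background, quantized_rgb = q$rgb,
                 structures = st, overlay = ov, params = params),
            class = "layer_segmentation")
}

#' @export
print.layer_segmentation <- function(x, ...) {
  cat(sprintf("<layer_segmentation> %d classes, thresholds [%s]\n",
              x$params$n_thresholds + 1L,
              paste(signif(x$otsu_thresholds, 4), collapse = ", ")))
  invisible(x)
}

#' Per-class summary of a layer segmentation
#' @param x a `layer_segmentation`.
#' @param ... unused.
#' @return Tibble: class, n_px (class-map pixels), n_components,
#'   closed_px, closed_intensity.
#' @method tidy layer_segmentation
#' @export
tidy.layer_segmentation <- function(x, ...) {
  ks <- sort(as.integer(sub("class_", "", names(x$structures))))
  dplyr::bind_rows(lapply(ks, function(k) {
    s <- x$structures[[paste0("class_", k)]]
    tibble::tibble(class = k, n_px = sum(x$class_map == k),
                   n_components = nrow(s$component_table),
                   closed_px = as.integer(s$total_px),
                   closed_intensity = s$total_intensity)
  }))
}

#' Extract an en-face slice at a fixed depth below the detected surface
#'
#' For each (slice, column) of the volume the output pixel is the intensity
#' at row `surface_row + round(depth_um / axial_pitch)`. Columns with no
#' detected surface are set to 0 and flagged; if the requested depth falls
#' beyond the acquisition for more than half the positions, an error is
#' raised.
#'
#' @param v an [oct_volume()].
#' @param depth_um depth below the surface in µm (>= 0).
#' @param surface_rows optional matrix (slices x columns) of surface rows;
#'   detected per slice with [detect_surface()] when `NULL`.
#' @param params a [peak_params()] for surface detection.
#' @return Matrix (slices x columns) of intensities with attribute
#'   `"flagged"` (logical matrix: no-surface or out-of-range positions).
#' @export
extract_enface <- function(v, depth_um, surface_rows = NULL,
                           params = peak_params()) {
  stopifnot(inherits(v, "oct_volume"))
  if (depth_um < 0) stop("`depth_um` must be >= 0", call. = FALSE)
  ap <- v$bscans[[1L]]$axial_pitch
  dz <- as.integer(round(depth_um / ap))
  nslices <- length(v$bscans)
  p <- ncol(v$bscans[[1L]]$pixels)
  n <- nrow(v$bscans[[1L]]$pixels)
  if (is.null(surface_rows)) {
    surface_rows <- t(vapply(v$bscans, function(b) detect_surface(b, params),
                             integer(p)))
  }
  stopifnot(identical(dim(surface_rows), c(nslices, p)))
  target <- surface_rows + dz
  flagged <- is.na(target) | target > n | target < 1
  if (mean(flagged) > 0.5)
    stop("depth below surface exceeds the acquisition range for >50% of columns",
         call. = FALSE)
  out <- matrix(0, nslices, p)
  for (i in seq_len(nslices)) {
    ok <- !flagged[i, ]
    out[i, ok] <- v$bscans[[i]]$pixels[cbind(target[i, ok], which(ok))]
  }
  attr(out, "flagged") <- flagged
  out
}
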