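# Shared image primitives used by the connectivity and layer-segmentation
# pipelines. Convolutions use symmetric (reflected) border padding so filter
# responses near edges do not wrap across the image.

as_pixel_matrix <- function(x) {
  if (is_bscan(x)) x$pixels else {
    m <- as.matrix(x); storage.mode(m) <- "double"; m
  }
}

sym_pad <- function(m, mr, mc = mr) {
  n <- nrow(m); p <- ncol(m)
  if (mr >= n || mc >= p) stop("padding exceeds image size", call. = FALSE)
  ri <- c(rev(seq_len(mr)), seq_len(n), n + 1 - seq_len(mr))
  ci <- c(rev(seq_len(mc)), seq_len(p), p + 1 - seq_len(mc))
  m[ri, ci, drop = FALSE]
}

#' Rotationally symmetric Laplacian-of-Gaussian kernel
#'
#' Builds the standard sum-zero LoG kernel: a Gaussian of width `sigma`
#' multiplied by `(r^2 - 2 sigma^2) / sigma^4` and mean-centred so the kernel
#' sums to zero (a constant image filters to exactly zero).
#'
#' @param size odd kernel side length (>= 3), default 5.
#' @param sigma Gaussian width in pixels, default 0.5.
#' @return A `size` x `size` numeric matrix summing to zero.
#' @export
log_kernel <- function(size = 5L, sigma = 0.5) {
  if (size %% 2 != 1 || size < 3) stop("`size` must be odd and >= 3", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  r <- (size - 1) / 2
  xy <- seq(-r, r)
  g <- exp(-outer(xy^2, xy^2, "+") / (2 * sigma^2))
  g <- g / sum(g)
  h <- g * (outer(xy^2, xy^2, "+") - 2 * sigma^2) / sigma^4
  h - mean(h)
}

#' 2D convolution with symmetric border padding
#'
#' @param img matrix or [bscan()].
#' @param kernel odd-sized numeric matrix.
#' @return Filtered matrix, same size as the input (possibly signed).
#' @export
convolve2 <- function(img, kernel) {
  m <- as_pixel_matrix(img)
  kr <- (nrow(kernel) - 1) / 2; kc <- (ncol(kernel) - 1) / 2
  if (nrow(kernel) > nrow(m) || ncol(kernel) > ncol(m))
    stop("kernel larger than image", call. = FALSE)
  pm <- sym_pad(m, kr, kc)
  f <- EBImage::filter2(pm, kernel, boundary = "circular")
  f <- as.matrix(f)[(kr + 1):(kr + nrow(m)), (kc + 1):(kc + ncol(m)), drop = FALSE]
  f
}

#' Sobel gradient magnitude
#'
#' @param img matrix or [bscan()].
#' @return Matrix of gradient magnitudes `sqrt(gx^2 + gy^2)`.
#' @export
sobel_magnitude <- function(img) {
  gx_k <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # lateral gradient
  gy_k <- t(gx_k)                                              # axial gradient
  gx <- convolve2(img, gx_k)
  gy <- convolve2(img, gy_k)
  sqrt(gx^2 + gy^2)
}

#' 5x5 median filter
#'
#' Each output pixel is the median of its `size` x `size` neighbourhood of the
#' input, with symmetric border padding.
#'
#' @param img matrix or [bscan()] of size at least `size` x `size`.
#' @param size odd window side, default 5.
#' @return Filtered matrix.
#' @export
median_filter <- function(img, size = 5L) {
  m <- as_pixel_matrix(img)
  if (size %% 2 != 1 || size < 3) stop("`size` must be odd and >= 3", call. = FALSE)
  if (nrow(m) < size || ncol(m) < size)
    stop("image smaller than the median window", call. = FALSE)
  r <- (size - 1) / 2
  n <- nrow(m); p <- ncol(m)
  pm <- sym_pad(m, r)
  k2 <- size * size
  shifted <- matrix(0, n * p, k2)
  j <- 0L
  for (dc in 0:(size - 1)) for (dr in 0:(size - 1)) {
    j <- j + 1L
    shifted[, j] <- pm[(1 + dr):(n + dr), (1 + dc):(p + dc)]
  }
  # vectorised row medians: one global two-key sort, then take the middle column
  ri <- rep(seq_len(n * p), times = k2)
  v <- as.vector(shifted)
  srt <- matrix(v[order(ri, v)], nrow = k2)
  matrix(srt[(k2 + 1) / 2, ], n, p)
}

# ---- Otsu thresholding -----------------------------------------------------

#' Otsu thresholds (single or multilevel)
#'
#' Computes `n` thresholds maximising the between-class variance of the
#' intensity histogram (equivalently the sum over classes of
#' `weight * class_mean^2`). Uses dynamic programming over histogram bins, so
#' the optimum over all threshold placements is exact at bin resolution.
#'
#' @param img matrix, [bscan()], or numeric vector of intensities.
#' @param n number of thresholds (classes = n + 1), default 1.
#' @param n_bins histogram resolution, default 256.
#' @return Strictly increasing numeric vector of `n` thresholds. A pixel with
#'   value `v` belongs to class `i` when `t[i-1] < v <= t[i]`
#'   (with `t[0] = -Inf`, `t[n+1] = Inf`).
#' @export
otsu_thresholds <- function(img, n = 1L, n_bins = 256L) {
  v <- if (is_bscan(img)) as.vector(img$pixels) else as.numeric(img)
  v <- v[is.finite(v)]
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  nd <- length(unique(v))
  if (nd < n + 1)
    stop(sprintf("need at least %d distinct intensities for %d thresholds, got %d",
                 n + 1, n, nd), call. = FALSE)
  lo <- min(v); hi <- max(v)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  cnt <- tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
                       n_bins), nbins = n_bins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  P <- cumsum(cnt)                      # counts up to bin j
  S <- cumsum(cnt * mids)               # intensity-weighted sums
  cost <- function(i, j) {              # w * mu^2 for bins i..j (vector in i)
    w <- P[j] - c(0, P)[i]
    s <- S[j] - c(0, S)[i]
    ifelse(w > 0, s^2 / w, 0)
  }
  C <- n + 1L
  f <- matrix(-Inf, C, n_bins)
  arg <- matrix(0L, C, n_bins)
  f[1L, ] <- cost(1L, seq_len(n_bins))
  for (cl in 2:C) {
    for (j in cl:n_bins) {
      i <- cl:j                          # class `cl` occupies bins i..j
      val <- f[cl - 1L, i - 1L] + cost(i, j)
      b <- which.max(val)
      f[cl, j] <- val[b]
      arg[cl, j] <- i[b]
    }
  }
  cuts <- integer(n)
  j <- n_bins
  for (cl in C:2) {
    i <- arg[cl, j]
    cuts[cl - 1L] <- i - 1L              # last bin of the class below
    j <- i - 1L
  }
  thr <- edges[cuts + 1L]                # upper edge of the last bin in a class
  if (any(diff(thr) <= 0)) thr <- sort(unique(thr))
  thr
}

#' Binarize an image by global Otsu thresholding
#'
#' The image is taken in absolute value and min-max rescaled to 0..1; the
#' global Otsu cut is then computed on the log-transformed histogram
#' (`log(v + 1e-3)`), a variance-stabilizing choice: gradient magnitudes of
#' speckled images are heavy-tailed, and Otsu on the raw histogram places
#' the cut inside the tail instead of between the background and texture
#' modes. Foreground is strictly above the threshold. The transform is
#' monotone, so for well-separated bimodal images the cut falls between the
#' modes exactly as plain Otsu would. A constant image yields an empty
#' foreground with a warning.
#'
#' @param img matrix or [bscan()] (possibly signed, e.g. LoG output).
#' @return List with `mask` (logical matrix) and `threshold` (on the rescaled
#'   0..1 intensity scale; `NA` for constant input).
#' @export
binarize_otsu <- function(img) {
  m <- abs(as_pixel_matrix(img))
  rng <- range(m)
  if (diff(rng) == 0) {
    warning("constant image: empty foreground", call. = FALSE)
    return(list(mask = matrix(FALSE, nrow(m), ncol(m)), threshold = NA_real_))
  }
  eps <- 1e-3
  ms <- (m - rng[1]) / diff(rng)
  thr_log <- otsu_thresholds(log(ms + eps), n = 1L)
  thr <- exp(thr_log) - eps
  list(mask = ms > thr, threshold = thr)
}

# ---- connected components --------------------------------------------------

#' Label connected components of a binary mask
#'
#' Maximal connected components under 4- or 8-connectivity; components smaller
#' than `min_px` are discarded. Labels are assigned 1..K in order of
#' decreasing pixel count (ties broken by first pixel position).
#'
#' @param mask logical/0-1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @param min_px discard components with fewer pixels (default 0 = keep all).
#' @param img optional same-shape intensity image for per-component sums.
#' @return List with `labels` (integer matrix, 0 = background) and `table`
#'   (tibble: label, px, x_min, x_max, z_min, z_max, intensity_sum).
#' @export
label_components <- function(mask, connectivity = 8L, min_px = 0L, img = NULL) {
  mk <- as_pixel_matrix(mask) != 0
  if (!connectivity %in% c(4L, 8L))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  n <- nrow(mk); p <- ncol(mk)
  fg <- which(mk)
  labels <- matrix(0L, n, p)
  if (!length(fg)) {
    return(list(labels = labels,
                table = tibble::tibble(label = integer(), px = integer(),
                                       x_min = integer(), x_max = integer(),
                                       z_min = integer(), z_max = integer(),
                                       intensity_sum = double())))
  }
  vid <- matrix(0L, n, p)
  vid[fg] <- seq_along(fg)
  pair_edges <- function(dr, dc) {
    r1 <- seq_len(n - abs(dr)) + max(0, -dr)
    c1 <- seq_len(p - abs(dc)) + max(0, -dc)
    a <- vid[r1, c1, drop = FALSE]
    b <- vid[r1 + dr, c1 + dc, drop = FALSE]
    keep <- a > 0 & b > 0
    cbind(a[keep], b[keep])
  }
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  el <- do.call(rbind, lapply(offs, function(o) pair_edges(o[1], o[2])))
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(el) && nrow(el)) g <- igraph::add_edges(g, t(el))
  comp <- igraph::components(g)$membership
  sizes <- tabulate(comp)
  first_px <- vapply(seq_along(sizes), function(k) fg[match(k, comp)], integer(1))
  ord <- order(-sizes, first_px)
  keep <- sizes[ord] >= max(min_px, 1L)
  relab <- integer(length(sizes))
  relab[ord[keep]] <- seq_len(sum(keep))
  newlab <- relab[comp]
  labels[fg] <- newlab
  K <- sum(keep)
  if (K == 0L) {
    tab <- tibble::tibble(label = integer(), px = integer(),
                          x_min = integer(), x_max = integer(),
                          z_min = integer(), z_max = integer(),
                          intensity_sum = double())
    return(list(labels = labels, table = tab))
  }
  lab_fg <- newlab[newlab > 0L]
  idx_fg <- fg[newlab > 0L]
  zz <- (idx_fg - 1L) %% n + 1L
  xx <- (idx_fg - 1L) %/% n + 1L
  isum <- if (!is.null(img)) {
    im <- as_pixel_matrix(img)
    as.numeric(tapply(im[idx_fg], lab_fg, sum))
  } else rep(NA_real_, K)
  tab <- tibble::tibble(
    label = seq_len(K),
    px = as.integer(tabulate(lab_fg, nbins = K)),
    x_min = as.integer(tapply(xx, lab_fg, min)),
    x_max = as.integer(tapply(xx, lab_fg, max)),
    z_min = as.integer(tapply(zz, lab_fg, min)),
    z_max = as.integer(tapply(zz, lab_fg, max)),
    intensity_sum = isum
  )
  list(labels = labels, table = tab)
}

# ---- morphology ------------------------------------------------------------

make_se <- function(radius = 1L, shape = c("box", "disc")) {
  shape <- match.arg(shape)
  EBImage::makeBrush(2L * radius + 1L, shape = shape)
}

morph_apply <- function(mask, fun, radius, shape) {
  mk <- (as_pixel_matrix(mask) != 0) * 1
  if (radius < 1) return(mk != 0)   # radius 0: identity element
  as.matrix(fun(mk, make_se(radius, shape))) != 0
}

#' Binary morphology with a square or disc structuring element
#'
#' `erode_mask`/`dilate_mask` are single operations; `open_mask` is erosion
#' then dilation (removes specks no larger than the element);
#' `close_mask` is dilation then erosion (fills gaps no wider than the
#' element).
#'
#' @param mask logical/0-1 matrix.
#' @param radius structuring-element radius in px (side = 2*radius+1).
#' @param shape "box" (default) or "disc".
#' @return Logical matrix.
#' @export
erode_mask <- function(mask, radius = 1L, shape = "box")
  morph_apply(mask, EBImage::erode, radius, shape)

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, radius = 1L, shape = "box")
  morph_apply(mask, EBImage::dilate, radius, shape)

#' @rdname erode_mask
#' @export
open_mask <- function(mask, radius = 1L, shape = "box")
  dilate_mask(erode_mask(mask, radius, shape), radius, shape)

#' @rdname erode_mask
#' @export
close_mask <- function(mask, radius = 1L, shape = "box") {
  mk <- as_pixel_matrix(mask) != 0
  if (radius < 1) return(mk)
  n <- nrow(mk); p <- ncol(mk)
  # pad so dilation at the border behaves as on an infinite zero background,
  # keeping closing extensive (input subset of output) yet never filling
  # toward the image edge
  pad <- radius + 1L
  big <- matrix(FALSE, n + 2L * pad, p + 2L * pad)
  big[pad + seq_len(n), pad + seq_len(p)] <- mk
  cl <- erode_mask(dilate_mask(big, radius, shape), radius, shape)
  cl[pad + seq_len(n), pad + seq_len(p), drop = FALSE]
}

# ---- axial Gaussian blur (phantom point-spread emulation) ------------------

gaussian_blur_axial <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(4 * sigma)
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  n <- nrow(m)
  pm <- m[c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r)), , drop = FALSE]
  f <- stats::filter(pm, k, method = "convolution", sides = 2)
  matrix(as.numeric(f[(r + 1):(r + n), ]), n, ncol(m))
}
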