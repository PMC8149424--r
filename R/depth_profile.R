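#' Peak-detection parameters for A-scan analysis
#'
#' @param min_height minimum peak height as a fraction of the A-scan maximum
#'   (default 0.2); set `absolute = TRUE` to interpret it as an absolute
#'   intensity.
#' @param min_separation minimum depth separation between reported peaks in
#'   px (default 5).
#' @param noise_floor_k the "first peak" (surface) is the shallowest detected
#'   peak whose height exceeds `median + noise_floor_k * MAD` of the A-scan
#'   (default 3).
#' @param absolute logical; is `min_height` an absolute intensity?
#' @return An object of class `peak_params`.
#' @export
peak_params <- function(min_height = 0.2, min_separation = 5L,
                        noise_floor_k = 3, absolute = FALSE) {
  if (min_separation < 1) stop("`min_separation` must be >= 1", call. = FALSE)
  if (!absolute && (min_height <= 0 || min_height > 1))
    stop("fractional `min_height` must be in (0, 1]", call. = FALSE)
  structure(list(min_height = min_height,
                 min_separation = as.integer(min_separation),
                 noise_floor_k = noise_floor_k, absolute = absolute),
            class = "peak_params")
}

# local maxima of a 1D signal; plateaus report their first index, and
# boundary runs count as peaks when they exceed their single neighbour (a
# flattened profile peaks at index 1)
local_maxima <- function(y) {
  r <- rle(as.numeric(y))
  v <- r$values
  L <- length(v)
  if (L == 1L) return(integer())
  starts <- cumsum(c(1L, r$lengths[-L]))
  left_lo <- c(TRUE, v[-1L] > v[-L])       # run exceeds (or has no) left nbr
  right_lo <- c(v[-L] > v[-1L], TRUE)      # run exceeds (or has no) right nbr
  starts[left_lo & right_lo]
}

#' Detect intensity peaks in one A-scan
#'
#' Local maxima satisfying the minimum-height and minimum-separation rules,
#' sorted shallow to deep. When peaks violate the separation rule, the taller
#' peak wins. The A-scan's "first peak" (used as the surface during
#' flattening) is the shallowest detected peak whose height also exceeds the
#' robust noise floor `median + noise_floor_k * MAD`.
#'
#' @param ascan numeric vector (length >= 3) of non-negative intensities.
#' @param params a [peak_params()].
#' @return Integer vector of peak depth indices (1-based), strictly
#'   increasing; empty for a constant A-scan. The first-peak index is
#'   attached as attribute `"first_peak"` (`NA` if no peak clears the noise
#'   floor).
#' @export
detect_ascan_peaks <- function(ascan, params = peak_params()) {
  y <- as.numeric(ascan)
  if (length(y) < 3L) stop("A-scan must have length >= 3", call. = FALSE)
  cand <- local_maxima(y)
  hmin <- if (params$absolute) params$min_height else params$min_height * max(y)
  cand <- cand[y[cand] >= hmin & y[cand] > 0]
  if (!length(cand)) {
    out <- integer()
    attr(out, "first_peak") <- NA_integer_
    return(out)
  }
  # noise floor for the surface rule, computed before separation pruning so
  # the shallowest qualifying peak is never displaced by a taller neighbour
  floor_thr <- stats::median(y) + params$noise_floor_k * stats::mad(y)
  first_peak <- cand[y[cand] > floor_thr][1]
  if (is.na(first_peak)) first_peak <- NA_integer_
  # enforce min_separation greedily by descending height (ties: shallower)
  ord <- cand[order(-y[cand], cand)]
  kept <- integer()
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= params$min_separation))
      kept <- c(kept, i)
  }
  out <- sort(kept)
  attr(out, "first_peak") <- as.integer(first_peak)
  out
}

#' Detect the surface row of every A-scan of an image
#'
#' Vectorised per-column first-peak detection: the shallowest local maximum
#' of each column that clears both the fractional-height rule and the robust
#' noise floor (same rules as [detect_ascan_peaks()]).
#'
#' @param img matrix or [bscan()].
#' @param params a [peak_params()].
#' @return Integer vector of surface rows per column (`NA` where no peak).
#' @export
detect_surface <- function(img, params = peak_params()) {
  m <- as_pixel_matrix(img)
  n <- nrow(m); p <- ncol(m)
  up <- rbind(m[1, , drop = FALSE], m[-n, , drop = FALSE])
  dn <- rbind(m[-1, , drop = FALSE], m[n, , drop = FALSE])
  is_max <- m > up & m >= dn & m > 0
  colmax <- apply(m, 2, max)
  med <- apply(m, 2, stats::median)
  madv <- apply(m, 2, stats::mad)
  hmin <- if (params$absolute) rep(params$min_height, p) else
    params$min_height * colmax
  ok <- is_max & (m >= matrix(hmin, n, p, byrow = TRUE)) &
    (m > matrix(med + params$noise_floor_k * madv, n, p, byrow = TRUE))
  first <- apply(ok, 2, function(col) {
    i <- which(col)[1]
    if (is.na(i)) NA_integer_ else i
  })
  as.integer(first)
}

#' Flatten a lateral window of A-scans to a common surface
#'
#' Each A-scan in the window is shifted up so its first detected peak (the
#' surface) sits at flattened index 1; samples shallower than the surface are
#' discarded and the tail is zero-padded (no signal exists below the
#' acquisition depth). A-scans with no detected peak are excluded.
#'
#' @param window numeric matrix (rows = depth, cols = A-scans of one window)
#'   or [bscan()]; combine with [crop_bscan()] to select the window.
#' @param params a [peak_params()].
#' @return List with `flattened` (matrix, same shape; excluded columns all
#'   zero), `shifts` (per-column first-peak index, `NA` when excluded),
#'   `used` (logical per column), `n_ascans_used`.
#' @export
flatten_window <- function(window, params = peak_params()) {
  m <- as_pixel_matrix(window)
  n <- nrow(m); p <- ncol(m)
  flat <- matrix(0, n, p)
  shifts <- rep(NA_integer_, p)
  for (j in seq_len(p)) {
    pk <- detect_ascan_peaks(m[, j], params)
    fp <- attr(pk, "first_peak")
    if (!is.na(fp)) {
      shifts[j] <- fp
      k <- n - fp + 1L
      flat[seq_len(k), j] <- m[fp:n, j]
    }
  }
  used <- !is.na(shifts)
  list(flattened = flat, shifts = shifts, used = used,
       n_ascans_used = sum(used))
}

#' Average flattened A-scans into a normalized depth profile
#'
#' Column-wise mean over the used A-scans, divided by its maximum so the
#' profile peaks at 1; profile peaks are re-detected on the averaged curve
#' with the same parameters.
#'
#' @param flat result of [flatten_window()] (or a plain matrix, in which case
#'   all columns are used).
#' @param params a [peak_params()].
#' @param axial_pitch µm per axial pixel, carried into the profile.
#' @param window_size informational window size.
#' @return An object of class `depth_profile`: `values` (normalized averaged
#'   intensities, length = window depth), `peak_indices`, `n_ascans_used`,
#'   `window_size`, `axial_pitch`.
#' @export
average_profile <- function(flat, params = peak_params(), axial_pitch = 5,
                            window_size = NULL) {
  if (is.matrix(flat)) flat <- list(flattened = flat,
                                    used = rep(TRUE, ncol(flat)),
                                    n_ascans_used = ncol(flat))
  if (flat$n_ascans_used < 1L)
    stop("no A-scans with a detected surface peak in this window", call. = FALSE)
  avg <- rowMeans(flat$flattened[, flat$used, drop = FALSE])
  mx <- max(avg)
  values <- if (mx > 0) avg / mx else avg
  pk <- detect_ascan_peaks(values, params)
  structure(list(values = values, peak_indices = as.integer(pk),
                 first_peak = attr(pk, "first_peak"),
                 n_ascans_used = flat$n_ascans_used,
                 window_size = window_size %||% flat$n_ascans_used,
                 axial_pitch = axial_pitch),
            class = "depth_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> %d px, %d A-scans used, peaks at [%s]\n",
              length(x$values), x$n_ascans_used,
              paste(x$peak_indices, collapse = ", ")))
  invisible(x)
}

#' Measure enamel thickness from a depth profile
#'
#' On a flattened profile the surface sits at index 1; the dentinoenamel
#' junction (DEJ) is the highest-amplitude remaining peak deeper than
#' `min_separation`, where a peak's amplitude is measured above its trailing
#' baseline (the mean profile over a window starting `drop_gap` px below the
#' peak) — the DEJ is the bright interface sitting on top of the dimmer
#' dentin, and this contrast is what separates it from residual speckle
#' ripples riding on the bright shallow enamel. Ties break toward the
#' shallower index. Thickness is `(dej_index - surface_index) * axial_pitch`.
#'
#' @param profile a `depth_profile` from [average_profile()].
#' @param params a [peak_params()] (for the separation rule).
#' @param drop_gap,drop_window trailing-baseline geometry in px: the
#'   baseline under a candidate peak at depth `i` is the mean profile over
#'   `i + drop_gap .. i + drop_window` (defaults 5 and 30, clipped at the
#'   profile end).
#' @return One-row tibble: surface_index, dej_index, dej_height,
#'   thickness_um, n_peaks, dej_found. When fewer than 2 peaks are available
#'   the DEJ is recorded as missing (`dej_found = FALSE`, thickness `NA`),
#'   not an error.
#' @export
measure_enamel_thickness <- function(profile, params = peak_params(),
                                     drop_gap = 5L, drop_window = 30L) {
  stopifnot(inherits(profile, "depth_profile"))
  pk <- profile$peak_indices
  y <- profile$values
  surface <- if (length(pk) && pk[1] <= params$min_separation) pk[1] else 1L
  deeper <- pk[pk > surface + params$min_separation - 1L & pk != surface]
  if (!length(deeper)) {
    return(tibble::tibble(surface_index = surface, dej_index = NA_integer_,
                          dej_height = NA_real_, thickness_um = NA_real_,
                          n_peaks = length(pk), dej_found = FALSE))
  }
  n <- length(y)
  amp <- vapply(deeper, function(i) {
    y[i] - mean(y[min(i + drop_gap, n):min(i + drop_window, n)])
  }, numeric(1))
  dej <- deeper[order(-amp, deeper)][1]
  tibble::tibble(surface_index = as.integer(surface),
                 dej_index = as.integer(dej),
                 dej_height = profile$values[dej],
                 thickness_um = (dej - surface) * profile$axial_pitch,
                 n_peaks = length(pk), dej_found = TRUE)
}

#' Depth-intensity profile analysis of a region of interest
#'
#' Tiles the ROI into lateral windows of `window_size` A-scans (left to
#' right; a final partial window is kept when at least half full), flattens
#' each window to its per-A-scan surface peaks, averages and max-normalizes,
#' and reads enamel thickness off the averaged profile.
#'
#' @param b a [bscan()].
#' @param region a [roi()]; default whole image.
#' @param window_size A-scans per window (default 10, the value used for all
#'   samples in this workflow).
#' @param params a [peak_params()].
#' @param qc_band optional c(lo, hi) µm plausibility band for enamel
#'   thickness (default c(1000, 1500)); out-of-band measurements trigger a
#'   warning flag column, never an error.
#' @return Tibble, one row per window: window, x_start, x_end,
#'   n_ascans_used, surface_index, dej_index, dej_height, thickness_um,
#'   n_peaks, dej_found, qc_in_band, and a list-column `profile`.
#' @export
depth_profile_analysis <- function(b, region = NULL, window_size = 10L,
                                   params = peak_params(),
                                   qc_band = c(1000, 1500)) {
  b <- as_bscan(b)
  if (is.null(region))
    region <- roi(1, ncol(b$pixels), 1, nrow(b$pixels))
  check_roi(region, b$pixels)
  width <- region$x_end - region$x_start + 1L
  if (width < window_size)
    stop("ROI width must be >= window_size", call. = FALSE)
  starts <- seq(region$x_start, region$x_end, by = window_size)
  rows <- lapply(seq_along(starts), function(w) {
    x0 <- starts[w]
    x1 <- min(x0 + window_size - 1L, region$x_end)
    if ((x1 - x0 + 1L) < window_size / 2) return(NULL)  # drop tiny tail window
    win <- b$pixels[region$z_start:region$z_end, x0:x1, drop = FALSE]
    flat <- flatten_window(win, params)
    if (flat$n_ascans_used == 0L) {
      return(tibble::tibble(window = w, x_start = x0, x_end = x1,
                            n_ascans_used = 0L, surface_index = NA_integer_,
                            dej_index = NA_integer_, dej_height = NA_real_,
                            thickness_um = NA_real_, n_peaks = 0L,
                            dej_found = FALSE, qc_in_band = NA,
                            profile = list(NULL)))
    }
    prof <- average_profile(flat, params, axial_pitch = b$axial_pitch,
                            window_size = window_size)
    meas <- measure_enamel_thickness(prof, params)
    dplyr::bind_cols(
      tibble::tibble(window = w, x_start = x0, x_end = x1,
                     n_ascans_used = flat$n_ascans_used),
      meas,
      tibble::tibble(qc_in_band = !is.na(meas$thickness_um) &
                       meas$thickness_um >= qc_band[1] &
                       meas$thickness_um <= qc_band[2],
                     profile = list(prof)))
  })
  dplyr::bind_rows(rows)
}
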