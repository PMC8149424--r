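#' Synthetic layered-tooth phantom specification
#'
#' Describes a synthetic OCT B-scan of a tooth: a bright specular surface
#' line, an enamel band with lateral Hunter-Schreger-like intensity banding
#' and exponential depth fall-off, a secondary dentinoenamel-junction (DEJ)
#' reflectivity line, dimmer dentin below, multiplicative gamma speckle with
#' an additive Gaussian noise floor, and optional defects (surface abrasion
#' notches, highly reflective adhesive patches with sub-patch shadowing, thin
#' dark micro-crack lines).
#'
#' Reflectivity levels are relative units; the default surface level is well
#' above the enamel band so the per-column intensity maximum stays on the
#' surface after axial point-spread blurring.
#'
#' @param shape integer c(rows, cols); default 1407 x 2000 (one B-scan of
#'   2000 A-scans, 1407 px each).
#' @param axial_pitch,lateral_pitch µm per pixel; defaults 5 and 2.5
#'   (2.5 µm/px = 5 mm scan / 2000 A-scans).
#' @param surface per-column surface row: a single number (flat), a numeric
#'   vector of length cols, or a list `list(depth=, tilt=, amplitude=,
#'   period=)` giving `depth + tilt*(x-1) + amplitude*sin(2*pi*(x-1)/period)`.
#' @param thickness per-column enamel thickness in px: number, vector, or
#'   list `list(base=, amplitude=, period=)` for lateral sinusoidal variation.
#' @param surface_reflectivity,enamel_reflectivity,dej_reflectivity,dentin_reflectivity
#'   relative intensity levels (defaults 2, 0.45, 1.2, 0.15).
#' @param dej_thickness_px axial thickness of the DEJ reflectivity band in
#'   px (default 3, about one axial resolution element at 5 µm/px); the
#'   truth `dej_row` is the band's first (shallowest) row.
#' @param attenuation exponential fall-off coefficient µ in 1/px applied below
#'   the surface (default 0.003).
#' @param hs_band_period,hs_band_amplitude lateral sinusoidal modulation of
#'   enamel reflectivity (period px, relative amplitude; defaults 60, 0.15).
#' @param speckle_shape gamma shape k of mean-1 multiplicative speckle
#'   (`Inf` = speckle off; default 16). Contrast (CV) is `1/sqrt(k)`.
#' @param noise_sd additive Gaussian noise floor (default 0.01; intensities
#'   are clamped at 0 afterwards).
#' @param sigma_axial axial point-spread blur in px (default 1.5) so the 1-px
#'   specular surface peak has realistic width; 0 disables.
#' @param defects list of defects, each one of
#'   `list(type="notch", center=, width=, depth=)` (lowers the local surface by
#'   `depth` px and removes that much enamel),
#'   `list(type="patch", x_start=, x_end=, extra=, shadow=, thickness=8)`
#'   (adhesive remnant band on top of the surface; pixels deeper than the
#'   patch in those columns are scaled by `shadow`), or
#'   `list(type="crack", x=, tilt=0, darkening=0.3)` (thin dark line running
#'   down from the surface).
#' @param bonding_layer_px,bonding_reflectivity optional extra thin bright
#'   band on top of the surface emulating applied bonding agent (default 0 =
#'   none).
#' @param seed optional RNG seed; fixed seed gives bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(1407L, 2000L),
                         axial_pitch = 5, lateral_pitch = 2.5,
                         surface = 120, thickness = 200,
                         surface_reflectivity = 2,
                         enamel_reflectivity = 0.45,
                         dej_reflectivity = 1.2,
                         dentin_reflectivity = 0.15,
                         dej_thickness_px = 3L,
                         attenuation = 0.003,
                         hs_band_period = 60, hs_band_amplitude = 0.15,
                         speckle_shape = 16, noise_sd = 0.01,
                         sigma_axial = 1.5,
                         defects = list(),
                         bonding_layer_px = 0L, bonding_reflectivity = 1.5,
                         seed = NULL) {
  if (length(shape) != 2L || any(shape < 8))
    stop("`shape` must be c(rows, cols), each >= 8", call. = FALSE)
  if (attenuation < 0 || noise_sd < 0 || hs_band_amplitude < 0 || sigma_axial < 0)
    stop("noise/attenuation parameters must be >= 0", call. = FALSE)
  if (!is.infinite(speckle_shape) && speckle_shape <= 0)
    stop("`speckle_shape` must be positive or Inf", call. = FALSE)
  spec <- structure(as.list(environment()), class = "phantom_spec")
  resolve_phantom_geometry(spec)  # validates surface + thickness vs shape
  spec
}

resolve_lateral <- function(x, cols, what) {
  if (is.list(x)) {
    xi <- seq_len(cols) - 1
    base <- if (!is.null(x$base)) x$base else x$depth
    out <- base +
      (if (!is.null(x$tilt)) x$tilt * xi else 0) +
      (if (!is.null(x$amplitude) && !is.null(x$period))
        x$amplitude * sin(2 * pi * xi / x$period) else 0)
  } else if (length(x) == 1L) {
    out <- rep(as.numeric(x), cols)
  } else if (length(x) == cols) {
    out <- as.numeric(x)
  } else stop(sprintf("`%s` must be scalar, length-cols, or a list", what),
              call. = FALSE)
  as.integer(round(out))
}

resolve_phantom_geometry <- function(spec) {
  rows <- spec$shape[1]; cols <- spec$shape[2]
  s <- resolve_lateral(spec$surface, cols, "surface")
  th <- resolve_lateral(spec$thickness, cols, "thickness")
  # apply notch defects: surface deepens, enamel above the new surface is gone
  for (d in spec$defects) {
    if (identical(d$type, "notch")) {
      x0 <- max(1L, as.integer(round(d$center - d$width / 2)))
      x1 <- min(cols, as.integer(round(d$center + d$width / 2)))
      s[x0:x1] <- s[x0:x1] + as.integer(d$depth)
      th[x0:x1] <- th[x0:x1] - as.integer(d$depth)
    }
  }
  if (any(s < 1L) || any(th < 1L))
    stop("surface rows must be >= 1 and enamel thickness >= 1 px everywhere",
         call. = FALSE)
  dp <- if (!is.null(spec$dej_thickness_px)) as.integer(spec$dej_thickness_px) else 1L
  if (any(s + th + dp > rows))
    stop("surface_depth + enamel_thickness + DEJ band must stay inside the image",
         call. = FALSE)
  list(surface_row = s, thickness = th, dej_row = s + th, dej_px = dp)
}

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic tooth B-scan with ground truth
#'
#' Deterministic for a fixed `spec$seed`. With speckle off the per-column
#' intensity maximum is exactly the truth surface row, and the DEJ line is
#' the second local maximum of every A-scan.
#'
#' @param spec a [phantom_spec()].
#' @return List with `bscan` (a [bscan()]) and `truth`: per-column
#'   `surface_row`, `dej_row`, `thickness_px`, logical `enamel_mask`,
#'   integer `class_map` (0 background, 1 enamel incl. the surface line,
#'   2 DEJ, 3 dentin, 4 adhesive/bonding material), `defect_mask`, and the
#'   defect list echo.
#' @export
generate_bscan <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- resolve_phantom_geometry(spec)
  rows <- spec$shape[1]; cols <- spec$shape[2]
  s <- geo$surface_row; th <- geo$thickness; dej <- geo$dej_row

  dp <- geo$dej_px
  Z <- matrix(seq_len(rows), rows, cols)
  S <- matrix(s, rows, cols, byrow = TRUE)
  DEJ <- matrix(dej, rows, cols, byrow = TRUE)

  hs <- 1 + spec$hs_band_amplitude *
    sin(2 * pi * (seq_len(cols) - 1) / spec$hs_band_period)
  EN <- matrix(spec$enamel_reflectivity * hs, rows, cols, byrow = TRUE)

  R <- matrix(0, rows, cols)
  R[Z > S & Z < DEJ] <- EN[Z > S & Z < DEJ]
  R[Z >= DEJ & Z < DEJ + dp] <- spec$dej_reflectivity
  R[Z >= DEJ + dp] <- spec$dentin_reflectivity
  R[Z == S] <- spec$surface_reflectivity

  class_map <- matrix(0L, rows, cols)
  class_map[Z > S & Z < DEJ] <- 1L
  class_map[Z == S] <- 1L
  class_map[Z >= DEJ & Z < DEJ + dp] <- 2L
  class_map[Z >= DEJ + dp] <- 3L

  defect_mask <- matrix(FALSE, rows, cols)
  for (d in spec$defects) {
    if (identical(d$type, "notch")) {
      x0 <- max(1L, as.integer(round(d$center - d$width / 2)))
      x1 <- min(cols, as.integer(round(d$center + d$width / 2)))
      # region where enamel was removed: between the original and new surface
      s_orig <- s; s_orig[x0:x1] <- s[x0:x1] - as.integer(d$depth)
      SO <- matrix(s_orig, rows, cols, byrow = TRUE)
      defect_mask[Z >= SO & Z < S] <- TRUE
    }
  }

  # depth attenuation below the surface
  R <- R * exp(-spec$attenuation * pmax(Z - S, 0))

  # bonding-agent band on top of the surface
  if (spec$bonding_layer_px > 0) {
    sel <- Z >= S - spec$bonding_layer_px & Z < S
    R[sel] <- R[sel] + spec$bonding_reflectivity
    class_map[sel] <- 4L
  }

  # adhesive patches: bright band on top of the surface + shadowing below
  for (d in spec$defects) {
    if (identical(d$type, "patch")) {
      x0 <- max(1L, as.integer(d$x_start)); x1 <- min(cols, as.integer(d$x_end))
      h <- if (!is.null(d$thickness)) as.integer(d$thickness) else 8L
      colsel <- matrix(FALSE, rows, cols); colsel[, x0:x1] <- TRUE
      psel <- colsel & Z >= S - h & Z < S
      R[psel] <- R[psel] + d$extra
      class_map[psel] <- 4L
      defect_mask[psel] <- TRUE
      dsel <- colsel & Z >= S
      R[dsel] <- R[dsel] * d$shadow
    }
  }

  # micro-cracks: thin dark (multiplicatively darkened) tilted lines
  for (d in spec$defects) {
    if (identical(d$type, "crack")) {
      tilt <- if (!is.null(d$tilt)) d$tilt else 0
      dark <- if (!is.null(d$darkening)) d$darkening else 0.3
      x0 <- as.integer(d$x)
      if (x0 >= 1 && x0 <= cols) {
        z <- s[x0]:rows
        xc <- pmin(pmax(x0 + round(tilt * (z - s[x0])), 1L), cols)
        idx <- cbind(z, xc)
        R[idx] <- R[idx] * dark
        defect_mask[idx] <- TRUE
      }
    }
  }

  img <- with_local_seed(spec$seed, {
    m <- gaussian_blur_axial(R, spec$sigma_axial)
    if (is.finite(spec$speckle_shape))
      m <- m * matrix(stats::rgamma(rows * cols, shape = spec$speckle_shape,
                                    rate = spec$speckle_shape), rows, cols)
    if (spec$noise_sd > 0)
      m <- m + matrix(stats::rnorm(rows * cols, sd = spec$noise_sd), rows, cols)
    pmax(m, 0)
  })

  truth <- structure(list(
    surface_row = s, dej_row = dej, thickness_px = th,
    enamel_mask = Z > S & Z < DEJ, class_map = class_map,
    defect_mask = defect_mask, defects = spec$defects,
    axial_pitch = spec$axial_pitch
  ), class = "phantom_truth")

  list(bscan = bscan(img, axial_pitch = spec$axial_pitch,
                     lateral_pitch = spec$lateral_pitch, id = "phantom"),
       truth = truth)
}

#' Generate a treatment series of phantoms
#'
#' Emulates the four-stage bracket bonding/debonding study design as monotone
#' enamel-thickness reductions plus optional stage-specific defects: stage
#' deltas are per-stage thickness losses in px relative to the subject's
#' baseline; an optional bonding stage adds a thin bright surface band
#' (applied bonding agent); subjects get seeded baseline-thickness jitter.
#'
#' @param base_spec a [phantom_spec()] giving the baseline geometry.
#' @param stage_deltas non-negative per-stage thickness reductions in px
#'   (length = number of stages; default c(0, 10, 20, 30)).
#' @param stage_labels stage names; defaults to the four treatment-group
#'   labels (baseline, pumice/etch/bonding, first debonding, second
#'   debonding).
#' @param n_subjects number of subjects (default 1).
#' @param subject_sd SD in px of per-subject baseline-thickness jitter.
#' @param stage_defects optional list (length = stages) of defect lists added
#'   at each stage on top of `base_spec$defects`.
#' @param bonding_stage stage index that receives the bonding band (default
#'   NULL = none).
#' @param bonding_px band thickness in px when `bonding_stage` is set.
#' @param seed RNG seed; the whole series is reproducible from it.
#' @return Tibble with columns subject, stage, stage_label, thickness_px
#'   (truth mean enamel thickness), and list-columns bscan, truth.
#' @export
generate_treatment_series <- function(base_spec,
                                      stage_deltas = c(0, 10, 20, 30),
                                      stage_labels = treatment_stage_labels(),
                                      n_subjects = 1L, subject_sd = 0,
                                      stage_defects = NULL,
                                      bonding_stage = NULL, bonding_px = 4L,
                                      seed = NULL) {
  stopifnot(inherits(base_spec, "phantom_spec"))
  if (any(stage_deltas < 0)) stop("stage_deltas must be >= 0", call. = FALSE)
  n_stages <- length(stage_deltas)
  if (length(stage_labels) != n_stages)
    stage_labels <- paste("stage", seq_len(n_stages))
  if (!is.null(stage_defects) && length(stage_defects) != n_stages)
    stop("stage_defects must have one entry per stage", call. = FALSE)
  cols <- base_spec$shape[2]
  base_th <- resolve_lateral(base_spec$thickness, cols, "thickness")
  if (any(max(stage_deltas) >= base_th))
    stop("stage_deltas exceed the base enamel thickness", call. = FALSE)

  with_local_seed(seed, {
    jit <- if (subject_sd > 0)
      round(stats::rnorm(n_subjects, 0, subject_sd)) else rep(0, n_subjects)
    jit <- pmin(jit, min(base_th) - max(stage_deltas) - 1)  # keep enamel >= 1 px
    rows <- vector("list", n_subjects * n_stages)
    k <- 0L
    for (subj in seq_len(n_subjects)) {
      for (st in seq_len(n_stages)) {
        sp <- base_spec
        sp$thickness <- pmax(base_th + jit[subj] - stage_deltas[st], 1L)
        sp$seed <- NULL  # draws flow from the series RNG stream
        if (!is.null(stage_defects)) sp$defects <- c(sp$defects, stage_defects[[st]])
        if (!is.null(bonding_stage) && st == bonding_stage)
          sp$bonding_layer_px <- as.integer(bonding_px)
        out <- generate_bscan(sp)
        out$bscan$id <- sprintf("subject%02d_stage%d", subj, st)
        k <- k + 1L
        rows[[k]] <- tibble::tibble(
          subject = subj, stage = st, stage_label = stage_labels[st],
          thickness_px = mean(out$truth$thickness_px),
          bscan = list(out$bscan), truth = list(out$truth))
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Stage labels of the four treatment groups
#' @return Character vector of length 4.
#' @export
treatment_stage_labels <- function() {
  c("Baseline (Control)",
    "After Pumice, Etch, & Bonding Agent",
    "After First Debonding",
    "After Second Debonding")
}

#' Generate a phantom C-scan volume with per-slice ground truth
#'
#' @param spec a [phantom_spec()] for each slice.
#' @param n_slices number of B-scans.
#' @param slice_pitch µm between slices.
#' @param surface_shift optional numeric vector (length `n_slices`) of extra
#'   surface depth per slice, emulating occlusal curvature across slices.
#' @param seed RNG seed for the whole volume.
#' @return List with `volume` (an [oct_volume()]) and `truths` (list of
#'   per-slice truth objects).
#' @export
generate_volume <- function(spec, n_slices = 10L, slice_pitch = 10,
                            surface_shift = NULL, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(surface_shift)) surface_shift <- rep(0L, n_slices)
  stopifnot(length(surface_shift) == n_slices)
  cols <- spec$shape[2]
  base_surface <- resolve_lateral(spec$surface, cols, "surface")
  with_local_seed(seed, {
    out <- lapply(seq_len(n_slices), function(i) {
      sp <- spec
      sp$surface <- base_surface + as.integer(round(surface_shift[i]))
      sp$seed <- NULL
      generate_bscan(sp)
    })
    list(volume = oct_volume(lapply(out, `[[`, "bscan"), slice_pitch = slice_pitch),
         truths = lapply(out, `[[`, "truth"))
  })
}

#' Ground-truth en-face class image at a fixed depth below the surface
#'
#' For each (slice, column) returns the truth class at row
#' `surface_row + round(depth_um / axial_pitch)`.
#'
#' @param truths list of per-slice truth objects from [generate_volume()].
#' @param depth_um depth below the detected surface in µm (>= 0).
#' @param axial_pitch µm per axial pixel; defaults to the truth's own pitch.
#' @return Integer matrix (slices x columns) of truth classes.
#' @export
generate_enface_truth <- function(truths, depth_um, axial_pitch = NULL) {
  if (depth_um < 0) stop("`depth_um` must be >= 0", call. = FALSE)
  if (is.null(axial_pitch)) axial_pitch <- truths[[1L]]$axial_pitch
  dz <- as.integer(round(depth_um / axial_pitch))
  rows_img <- nrow(truths[[1L]]$class_map)
  t(vapply(truths, function(tr) {
    rr <- tr$surface_row + dz
    if (any(rr > rows_img))
      stop("depth exceeds the acquisition range below the surface", call. = FALSE)
    tr$class_map[cbind(rr, seq_along(rr))]
  }, integer(length(truths[[1L]]$surface_row))))
}

#' Simulate a cohort of en-face enamel metrics
#'
#' Cohort-level generator mirroring the four-stage study structure: each
#' subject's metric is `baseline_mean + subject effect + stage effect +
#' residual`, with the stage effects defaulting to the published group mean
#' differences and variance components chosen so the pooled per-stage SD is
#' comparable to the published per-group SDs (~135 µm).
#'
#' @param n_subjects subjects (default 30).
#' @param stage_effects additive stage effects in µm (default
#'   c(0, -125.40, -197.90, -267.57)).
#' @param baseline_mean grand baseline mean in µm (default 765.70).
#' @param subject_sd between-subject SD in µm (default 80).
#' @param resid_sd within-subject residual SD in µm (default 110).
#' @param seed RNG seed.
#' @return Tibble with subject, stage, stage_label, metric_um.
#' @export
simulate_enamel_metrics <- function(n_subjects = 30L,
                                    stage_effects = c(0, -125.40, -197.90, -267.57),
                                    baseline_mean = 765.70,
                                    subject_sd = 80, resid_sd = 110,
                                    seed = NULL) {
  n_stages <- length(stage_effects)
  labs <- if (n_stages == 4L) treatment_stage_labels() else
    paste("stage", seq_len(n_stages))
  with_local_seed(seed, {
    subj_eff <- stats::rnorm(n_subjects, 0, subject_sd)
    tibble::tibble(
      subject = rep(seq_len(n_subjects), each = n_stages),
      stage = rep(seq_len(n_stages), n_subjects),
      stage_label = rep(labs, n_subjects),
      metric_um = baseline_mean + rep(subj_eff, each = n_stages) +
        rep(stage_effects, n_subjects) +
        stats::rnorm(n_subjects * n_stages, 0, resid_sd)
    )
  })
}
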