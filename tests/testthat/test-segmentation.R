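test_that("quantization bins pixels by the threshold intervals", {
  img <- matrix(c(20, 100, 200, 20, 100, 200), 2, 3)
  q <- quantize_colorize(img, c(50, 150), c("#000000", "#00FF00", "#FF0000"))
  expect_equal(sort(unique(as.vector(q$class_map))), 1:3)
  expect_true(all(q$class_map[img <= 50] == 1L))
  expect_true(all(q$class_map[img > 50 & img <= 150] == 2L))
  expect_true(all(q$class_map[img > 150] == 3L))
  # boundary pixel: class i holds (t[i-1], t[i]]
  img2 <- matrix(c(50, 50.0001, 10, 10), 2, 2)
  q2 <- quantize_colorize(img2, c(50, 150), c("#000000", "#00FF00", "#FF0000"))
  expect_equal(q2$class_map[1, 1], 1L)
  expect_equal(q2$class_map[2, 1], 2L)
  # single-class map when all pixels fall below the first threshold
  q3 <- quantize_colorize(matrix(1:4 / 100, 2, 2), c(50, 150),
                          c("#000000", "#00FF00", "#FF0000"))
  expect_true(all(q3$class_map == 1L))
  expect_error(quantize_colorize(img, c(50, 150), c("#000000", "#00FF00")),
               "palette")
})

test_that("palette colorization is invertible back to the class map", {
  set.seed(12)
  img <- matrix(runif(30 * 30, 0, 255), 30, 30)
  pal <- c("#000080", "#00A000", "#FF0000", "#FF00FF")
  thr <- multi_otsu(img, 3)
  q <- quantize_colorize(img, thr, pal)
  rgbv <- grDevices::col2rgb(pal) / 255
  back <- matrix(0L, 30, 30)
  for (k in seq_along(pal)) {
    hit <- abs(q$rgb[, , 1] - rgbv[1, k]) < 1e-9 &
      abs(q$rgb[, , 2] - rgbv[2, k]) < 1e-9 &
      abs(q$rgb[, , 3] - rgbv[3, k]) < 1e-9
    back[hit] <- k
  }
  expect_equal(back, q$class_map)
})

test_that("the class map partitions every pixel at the Otsu boundaries", {
  set.seed(13)
  img <- matrix(runif(40 * 40, 0, 1), 40, 40)
  p <- segmentation_params(n_thresholds = 3)
  thr <- multi_otsu(img, 3)
  q <- quantize_colorize(img, thr, p$class_palette)
  expect_true(all(q$class_map %in% 1:4))
  recompute <- 1L + rowSums(outer(as.vector(img), thr, ">"))
  expect_equal(as.vector(q$class_map), recompute)
  # more thresholds never reduce the number of classes present
  n2 <- length(unique(as.vector(quantize_colorize(img, multi_otsu(img, 2),
                                                  p$class_palette[1:3])$class_map)))
  n3 <- length(unique(as.vector(q$class_map)))
  expect_gte(n3, n2)
})

test_that("noise-free four-level phantom recovers the truth classes", {
  out <- generate_bscan(four_level_spec())
  seg <- run_layer_segmentation(out$bscan)
  expected <- truth_to_intensity_classes(out$truth$class_map)
  expect_gte(mean(seg$class_map == expected), 0.99)
  td <- tidy(seg)
  expect_true(all(td$class %in% 2:4))
})

test_that("speckled four-level phantom still recovers most of the truth classes", {
  sp <- four_level_spec()
  sp$speckle_shape <- 16; sp$noise_sd <- 0.01; sp$seed <- 5
  out <- generate_bscan(sp)
  seg <- run_layer_segmentation(out$bscan)
  expected <- truth_to_intensity_classes(out$truth$class_map)
  expect_gte(mean(seg$class_map == expected), 0.85)
})

test_that("per-class processing equals the connectivity machinery on a single class", {
  out <- generate_bscan(noisy_spec(rows = 200, cols = 100, surface = 40,
                                   thickness = 100, seed = 4))
  m <- out$bscan$pixels
  mask <- out$truth$enamel_mask
  class_map <- matrix(1L, nrow(m), ncol(m)); class_map[mask] <- 2L
  p <- segmentation_params(n_thresholds = 1,
                           class_palette = c("#000000", "#FF0000"))
  st <- per_channel_structures(m, class_map, p)$class_2
  # oracle: the connectivity module's own functions applied to the same mask
  cp <- connectivity_params(se_close_radius = p$se_close_radius)
  masked <- m * mask
  comp <- trace_components(mask, cp, img = masked)
  opened <- open_mask(comp$labels > 0, cp$se_radius)
  acct <- close_and_account(masked, opened, cp)
  expect_identical(st$component_labels, comp$labels)
  expect_identical(st$opened_mask, opened)
  expect_identical(st$closed_mask, acct$closed_mask)
  expect_equal(st$total_intensity, acct$total_enamel_intensity)
  expect_equal(st$total_px, acct$total_enamel_px)
  # and the class's edge masks match the connectivity module's edge detectors
  expect_identical(st$log_edges,
                   suppressWarnings(binarize_otsu(log_filter(masked, cp)))$mask)
  expect_identical(st$edge_mask,
                   sobel_overlay(masked, mask, cp)$edge_mask)
})

test_that("empty classes yield empty structures and the overlay falls back to grayscale", {
  m <- matrix(runif(100, 0, 1), 10, 10)
  class_map <- matrix(1L, 10, 10)
  p <- segmentation_params(n_thresholds = 3)
  st <- per_channel_structures(m, class_map, p)
  expect_true(all(vapply(st, function(s) sum(s$closed_mask) == 0, logical(1))))
  ov <- compose_overlay(m, st, p)
  expect_equal(ov[, , 1], m / max(m))
  expect_equal(ov[, , 1], ov[, , 2])
})

test_that("overlay draws disjoint masks in their own colours, higher class on top", {
  m <- matrix(1, 10, 10)
  p <- segmentation_params(n_thresholds = 1, overlay_alpha = 1,
                           class_palette = c("#0000FF", "#FF0000"))
  mk1 <- matrix(FALSE, 10, 10); mk1[1:4, ] <- TRUE
  mk2 <- matrix(FALSE, 10, 10); mk2[4:8, ] <- TRUE   # overlaps row 4
  st <- list(class_1 = list(closed_mask = mk1), class_2 = list(closed_mask = mk2))
  ov <- compose_overlay(m, st, p)
  expect_equal(ov[2, 2, ], c(0, 0, 1))   # class 1 region: blue
  expect_equal(ov[6, 2, ], c(1, 0, 0))   # class 2 region: red
  expect_equal(ov[4, 2, ], c(1, 0, 0))   # overlap: higher class wins
  expect_equal(ov[10, 2, ], c(1, 1, 1))  # untouched: grayscale source
})

test_that("three-band image yields one closed component spanning each band", {
  m <- matrix(0.05, 90, 60)
  m[11:30, ] <- 0.3; m[41:60, ] <- 0.6; m[71:90, ] <- 0.9
  seg <- run_layer_segmentation(bscan(m))
  for (k in 2:4) {
    s <- seg$structures[[paste0("class_", k)]]
    expect_equal(nrow(s$component_table), 1L)
    expect_equal(s$component_table$x_min, 1L)
    expect_equal(s$component_table$x_max, 60L)
    expect_equal(s$total_px, 20L * 60L)  # closing preserves the solid band
  }
})

test_that("en-face extraction reads intensities at a fixed depth below the surface", {
  sp <- clean_spec(rows = 400, cols = 50, surface = 40, thickness = 150)
  v <- generate_volume(sp, n_slices = 4)
  # depth 0: the surface intensity, the per-column maximum for a clean phantom
  e0 <- extract_enface(v$volume, 0)
  expect_equal(e0[2, ], apply(v$volume$bscans[[2]]$pixels, 2, max),
               ignore_attr = TRUE)
  # flat phantom at 500 um and 5 um/px: row surface + 100 of every slice
  e500 <- extract_enface(v$volume, 500)
  expect_equal(e500[3, ], v$volume$bscans[[3]]$pixels[140, ],
               ignore_attr = TRUE)
  expect_error(extract_enface(v$volume, 5000), "acquisition")
})

test_that("en-face values land in truth enamel wherever it is thick enough", {
  sp <- clean_spec(rows = 400, cols = 120, surface = 40,
                   thickness = list(base = 120, amplitude = 60, period = 120))
  sp$surface <- list(depth = 40, tilt = 0.2)
  v <- generate_volume(sp, n_slices = 3)
  e <- extract_enface(v$volume, 500)
  etruth <- generate_enface_truth(v$truths, 500)
  thick <- t(vapply(v$truths, function(tr) tr$thickness_px > 100,
                    logical(120)))
  expect_true(all(etruth[thick] == 1L))
  # enamel positions are brighter than dentin positions on average
  expect_gt(mean(e[etruth == 1L]), mean(e[etruth == 3L]))
})
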