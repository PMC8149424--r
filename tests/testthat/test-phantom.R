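test_that("fixed seed gives bit-identical phantoms", {
  sp <- noisy_spec(seed = 42)
  a <- generate_bscan(sp)
  b <- generate_bscan(sp)
  expect_identical(a$bscan$pixels, b$bscan$pixels)
  sp2 <- noisy_spec(seed = 43)
  expect_false(identical(generate_bscan(sp2)$bscan$pixels, a$bscan$pixels))
})

test_that("noise-free phantom: surface carries the per-column maximum and the DEJ the second local maximum", {
  out <- generate_bscan(clean_spec(surface = 50, thickness = 200))
  b <- out$bscan; tr <- out$truth
  expect_equal(apply(b$pixels, 2, which.max), tr$surface_row)
  expect_true(all(tr$surface_row == 50L))
  for (j in c(1, 30, 60)) {
    pk <- detect_ascan_peaks(b$pixels[, j])
    expect_equal(as.integer(pk[1:2]), c(50L, 250L))
  }
  # enamel brighter than dentin in the mean
  expect_gt(mean(b$pixels[tr$enamel_mask]), mean(b$pixels[tr$class_map == 3L]))
})

test_that("exponential attenuation follows its closed form", {
  sp <- clean_spec(rows = 500, cols = 200, surface = 50, thickness = 300)
  sp$attenuation <- 0.01
  out <- generate_bscan(sp)
  m <- out$bscan$pixels
  r_shallow <- mean(m[50 + (10:20), ])
  r_deep <- mean(m[50 + (110:120), ])
  expect_equal(r_shallow / r_deep, exp(0.01 * 100), tolerance = 0.01)
})

test_that("gamma speckle has coefficient of variation 1/sqrt(k)", {
  for (k in c(4, 16)) {
    sp <- phantom_spec(shape = c(500, 200), surface = 50, thickness = 300,
                       speckle_shape = k, noise_sd = 0, sigma_axial = 0,
                       hs_band_amplitude = 0, attenuation = 0, seed = 11)
    out <- generate_bscan(sp)
    inside <- out$bscan$pixels[out$truth$enamel_mask]  # constant reflectivity
    expect_gt(length(inside), 1e4)
    expect_equal(sd(inside) / mean(inside), 1 / sqrt(k), tolerance = 0.05)
  }
})

test_that("abrasion notches lower the surface and remove enamel locally", {
  notch <- list(type = "notch", center = 30, width = 10, depth = 6)
  out <- generate_bscan(clean_spec(cols = 60, defects = list(notch)))
  tr <- out$truth
  expect_true(all(tr$surface_row[26:34] == 86L))
  expect_true(all(tr$surface_row[c(1:24, 37:60)] == 80L))
  expect_true(all(tr$thickness_px[26:34] == 194L))
  expect_equal(apply(out$bscan$pixels, 2, which.max), tr$surface_row)
  expect_true(any(tr$defect_mask))
})

test_that("adhesive patches brighten the patch and shadow everything deeper", {
  patch <- list(type = "patch", x_start = 20, x_end = 40, extra = 1.5,
                shadow = 0.4, thickness = 8)
  base <- generate_bscan(clean_spec(cols = 60))
  out <- generate_bscan(clean_spec(cols = 60, defects = list(patch)))
  s <- out$truth$surface_row[25]
  # patch band on top of the surface is brighter than the background there
  expect_gt(mean(out$bscan$pixels[(s - 8):(s - 1), 25]), 1)
  expect_equal(mean(base$bscan$pixels[(s - 8):(s - 1), 25]), 0)
  # all deeper pixels scaled by the shadow factor
  expect_equal(out$bscan$pixels[s:700, 25], 0.4 * base$bscan$pixels[s:700, 25])
  expect_true(all(out$truth$class_map[(s - 8):(s - 1), 25] == 4L))
})

test_that("crack lines darken a thin path below the surface", {
  crack <- list(type = "crack", x = 30, tilt = 0, darkening = 0.3)
  base <- generate_bscan(clean_spec(cols = 60))
  out <- generate_bscan(clean_spec(cols = 60, defects = list(crack)))
  expect_equal(out$bscan$pixels[100, 30], 0.3 * base$bscan$pixels[100, 30])
  expect_equal(out$bscan$pixels[100, 31], base$bscan$pixels[100, 31])
})

test_that("phantom spec validation rejects impossible geometry", {
  expect_error(phantom_spec(shape = c(100, 50), surface = 50, thickness = 60),
               "inside the image")
  expect_error(phantom_spec(shape = c(100, 50), surface = 0, thickness = 10),
               ">= 1")
  expect_error(phantom_spec(shape = c(100, 50), surface = 10, thickness = 10,
                            speckle_shape = -1), "positive")
})

test_that("treatment series applies per-stage thickness deltas to the truth", {
  base <- clean_spec(rows = 400, cols = 40, surface = 40, thickness = 200)
  ser <- generate_treatment_series(base, stage_deltas = c(0, 10, 20, 30))
  expect_equal(ser$thickness_px, c(200, 190, 180, 170))
  expect_true(all(diff(ser$thickness_px) < 0))
  expect_equal(ser$stage_label, treatment_stage_labels())
  # zero deltas: identical truth masks across stages
  ser0 <- generate_treatment_series(base, stage_deltas = c(0, 0, 0, 0))
  expect_identical(ser0$truth[[1]]$enamel_mask, ser0$truth[[4]]$enamel_mask)
  expect_error(generate_treatment_series(base, stage_deltas = c(0, 250)),
               "exceed")
})

test_that("multi-subject series is reproducible from its seed", {
  base <- noisy_spec(rows = 120, cols = 30, surface = 20, thickness = 60)
  a <- generate_treatment_series(base, c(0, 5, 10, 15), n_subjects = 3,
                                 subject_sd = 4, seed = 9)
  b <- generate_treatment_series(base, c(0, 5, 10, 15), n_subjects = 3,
                                 subject_sd = 4, seed = 9)
  expect_equal(nrow(a), 12L)
  expect_identical(a$thickness_px, b$thickness_px)
  expect_identical(a$bscan[[7]]$pixels, b$bscan[[7]]$pixels)
  # within each subject the truth thickness strictly decreases
  for (s in 1:3) {
    th <- a$thickness_px[a$subject == s]
    expect_true(all(diff(th) < 0))
  }
})

test_that("bonding stage adds a bright band above the surface", {
  base <- clean_spec(rows = 400, cols = 40, surface = 40, thickness = 200)
  ser <- generate_treatment_series(base, c(0, 10, 20, 30), bonding_stage = 2,
                                   bonding_px = 4)
  tr2 <- ser$truth[[2]]
  s <- tr2$surface_row[10]
  expect_true(all(ser$truth[[2]]$class_map[(s - 4):(s - 1), 10] == 4L))
  expect_true(all(ser$truth[[1]]$class_map[(s - 4):(s - 1), 10] == 0L))
})

test_that("en-face truth extraction picks the class at the stated depth below the surface", {
  sp <- clean_spec(rows = 400, cols = 40, surface = 40, thickness = 200)
  v <- generate_volume(sp, n_slices = 3)
  # depth 0: the surface row itself, which is enamel-classed
  e0 <- generate_enface_truth(v$truths, 0)
  expect_true(all(e0 == 1L))
  # 500 um at 5 um/px = 100 px < 200 px thickness: enamel everywhere
  e500 <- generate_enface_truth(v$truths, 500)
  expect_true(all(e500 == 1L))
  # beyond the acquisition depth
  expect_error(generate_enface_truth(v$truths, 5000), "exceeds")
})
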