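# shared phantom configurations for the tests: small geometries, chosen once

# clean flat phantom, no noise, no blur: every contract is exact
clean_spec <- function(rows = 700, cols = 60, surface = 80, thickness = 200, ...) {
  phantom_spec(shape = c(rows, cols), surface = surface, thickness = thickness,
               speckle_shape = Inf, noise_sd = 0, sigma_axial = 0, ...)
}

# default-noise phantom (gamma k = 16 speckle, PSF blur), small geometry
noisy_spec <- function(rows = 700, cols = 60, surface = 80, thickness = 200,
                       seed = 1, ...) {
  phantom_spec(shape = c(rows, cols), surface = surface, thickness = thickness,
               seed = seed, ...)
}

# four distinct flat reflectivity levels (background/dentin/enamel/DEJ),
# no attenuation or banding, so multilevel Otsu can recover classes exactly
four_level_spec <- function(rows = 200, cols = 150) {
  phantom_spec(shape = c(rows, cols), surface = 40, thickness = 100,
               surface_reflectivity = 0.45, enamel_reflectivity = 0.45,
               dej_reflectivity = 0.8, dentin_reflectivity = 0.2,
               attenuation = 0, hs_band_amplitude = 0,
               speckle_shape = Inf, noise_sd = 0, sigma_axial = 0)
}

# map truth classes (0 bg, 1 enamel, 2 dej, 3 dentin) to the intensity-ordered
# segmentation classes of a four-level phantom (1 bg < 2 dentin < 3 enamel < 4 dej)
truth_to_intensity_classes <- function(class_map) {
  conv <- c("0" = 1L, "3" = 2L, "1" = 3L, "2" = 4L)
  matrix(conv[as.character(class_map)], nrow(class_map))
}
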