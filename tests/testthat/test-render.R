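test_that("noise-free zero-jitter frames reproduce the base reflectance", {
  sc <- generate_scene(pixel_count = 96, seed = 3, pachyvessel_fraction = 0)
  pars <- acquisition_params(n_frames = 3, speckle_shape = 1e8,
                             shift_sd_px = 0, rotation_sd_deg = 0, seed = 9)
  st <- render_octa_stack(sc, pars)
  base <- ifelse(sc$capillary_mask, pars$cc_level, pars$void_level)
  for (f in st$cc)
    expect_lt(max(abs(f$intensities - base)), 1e-3)
  base_scp <- ifelse(sc$scp_mask, pars$scp_level, pars$scp_bg_level)
  expect_lt(max(abs(st$scp[[1]]$intensities - base_scp)), 1e-3)
})

test_that("stack has the requested number of frame pairs and transforms", {
  sc <- generate_scene(pixel_count = 96, seed = 4)
  st <- render_octa_stack(sc, acquisition_params(n_frames = 9, seed = 2))
  expect_length(st$cc, 9)
  expect_length(st$scp, 9)
  expect_length(st$transforms, 9)
  expect_s3_class(st$cc[[5]], "en_face_image")
  expect_identical(st$cc[[5]]$modality, "octa_cc")
  expect_identical(st$scp[[5]]$modality, "octa_scp")
  qs <- vapply(st$transforms, function(t) t$quality, numeric(1))
  expect_true(all(qs >= 0.8 & qs <= 1))
  # rendering is deterministic in the seed
  st2 <- render_octa_stack(sc, acquisition_params(n_frames = 9, seed = 2))
  expect_identical(st$cc[[3]]$intensities, st2$cc[[3]]$intensities)
})

test_that("temporal speckle variance follows the gamma law var = base^2/shape", {
  sc <- generate_scene(pixel_count = 96, seed = 6, pachyvessel_fraction = 0)
  pars <- acquisition_params(n_frames = 100, speckle_shape = 3,
                             shift_sd_px = 0, rotation_sd_deg = 0,
                             cc_level = 0.3, void_level = 0.05, seed = 13)
  st <- render_octa_stack(sc, pars)
  arr <- simplify2array(lapply(st$cc, function(f) f$intensities))
  perf <- which(sc$capillary_mask)
  v <- apply(matrix(arr, ncol = 100)[perf, ], 1, stats::var)
  expect_lt(abs(mean(v) / (0.3^2 / 3) - 1), 0.15)
})

test_that("choroid render: two-level recovery and constant bright degenerate", {
  sc <- generate_scene(pixel_count = 128, seed = 8, pachyvessel_fraction = 0.2)
  ch0 <- render_choroid_oct(sc, noise_sd = 0, seed = 1)
  # midpoint threshold recovers the vessel mask exactly
  expect_identical(ch0$intensities < (0.8 + 0.1) / 2, sc$pachyvessel_mask)
  sc_empty <- generate_scene(pixel_count = 128, seed = 8,
                             pachyvessel_fraction = 0)
  ch_empty <- render_choroid_oct(sc_empty, noise_sd = 0, seed = 1)
  expect_true(all(ch_empty$intensities == 0.8))
})

test_that("Phansalkar + inversion recovers the vessel lumens from a noisy choroid image", {
  for (s in 1:3) {
    sc <- generate_scene(pixel_count = 200, seed = 40 + s,
                         pachyvessel_fraction = 0.2)
    ch <- render_choroid_oct(sc, noise_sd = 0.05, seed = 50 + s)
    vessels <- invert_mask(phansalkar_threshold(ch), "pachyvessel")
    expect_gte(dice_coef(vessels$values, sc$pachyvessel_mask), 0.9)
  }
})
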