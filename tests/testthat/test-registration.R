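test_that("registering an image to itself gives the identity with quality 1", {
  x <- random_smooth_image(96, 1)
  img <- en_face_image(x, 10, "octa_scp")
  t <- estimate_transform(img, img)
  expect_equal(t$dx_px, 0)
  expect_equal(t$dy_px, 0)
  expect_equal(t$theta_deg, 0)
  expect_equal(t$quality, 1)
})

test_that("integer circular shifts are recovered exactly", {
  x <- random_smooth_image(96, 2)
  ref <- en_face_image(x, 10, "octa_scp")
  mov <- en_face_image(circshift(x, 3, -2), 10, "octa_scp")
  t <- estimate_transform(ref, mov, rotation_range_deg = 0)
  expect_equal(t$dx_px, 3, tolerance = 1e-8)
  expect_equal(t$dy_px, -2, tolerance = 1e-8)
})

test_that("registration is equivariant under a common pre-shift", {
  x <- random_smooth_image(96, 3)
  ref <- en_face_image(x, 10, "octa_scp")
  mov <- en_face_image(circshift(x, 4, 1), 10, "octa_scp")
  t0 <- estimate_transform(ref, mov, rotation_range_deg = 0)
  ref2 <- en_face_image(circshift(x, 2, 5), 10, "octa_scp")
  mov2 <- en_face_image(circshift(circshift(x, 4, 1), 2, 5), 10, "octa_scp")
  t1 <- estimate_transform(ref2, mov2, rotation_range_deg = 0)
  expect_equal(t1$dx_px, t0$dx_px, tolerance = 1e-6)
  expect_equal(t1$dy_px, t0$dy_px, tolerance = 1e-6)
})

test_that("sub-pixel shifts under speckle are recovered within 0.2 px", {
  errs <- vapply(1:12, function(s) {
    pr <- shifted_scp_pair(0.5, -0.5, speckle_shape = 3, seed = 1000 + s)
    t <- estimate_transform(pr$reference, pr$moving, rotation_range_deg = 0)
    max(abs(t$dx_px - 0.5), abs(t$dy_px + 0.5))
  }, numeric(1))
  expect_lt(mean(errs), 0.2)
  expect_lt(max(errs), 0.35)
})

test_that("degenerate and mismatched inputs are rejected", {
  flat <- en_face_image(matrix(0.5, 64, 64), 10, "octa_scp")
  x <- en_face_image(random_smooth_image(64, 4), 10, "octa_scp")
  expect_error(estimate_transform(x, flat), "degenerate")
  y <- en_face_image(random_smooth_image(32, 5), 10, "octa_scp")
  expect_error(estimate_transform(x, y), "shape")
})

test_that("apply_transform inverts rendered motion and composes to identity", {
  x <- random_smooth_image(96, 6)
  img <- en_face_image(x, 10, "octa_scp")
  expect_identical(apply_transform(img, frame_transform(0, 0, 0, 1)), img)

  fwd <- apply_transform(img, frame_transform(5, 0, 0, 1))
  back <- apply_transform(fwd, frame_transform(-5, 0, 0, 1))
  interior <- 11:86
  expect_lt(mean(abs(back$intensities[interior, interior] -
                     x[interior, interior]), na.rm = TRUE), 1e-6)

  # estimate-then-apply round trip on a speckled pair (single realization;
  # the tighter statistical bound over 50 seeds lives in the acceptance suite)
  pr <- shifted_scp_pair(1.5, 2.25, speckle_shape = 6, seed = 77)
  t <- estimate_transform(pr$reference, pr$moving, rotation_range_deg = 0)
  expect_lt(max(abs(c(t$dx_px - 1.5, t$dy_px - 2.25))), 0.3)
  aligned <- apply_transform(pr$moving, t)
  resid <- estimate_transform(pr$reference, aligned, rotation_range_deg = 0)
  expect_lt(max(abs(c(resid$dx_px, resid$dy_px))), 0.3)
})

test_that("averaging preserves the grid, gates on quality, and reduces variance ~1/N", {
  sc <- generate_scene(pixel_count = 128, seed = 9, pachyvessel_fraction = 0)
  pars <- acquisition_params(n_frames = 9, speckle_shape = 3, shift_sd_px = 0.7,
                             rotation_sd_deg = 0, seed = 31)
  st <- render_octa_stack(sc, pars)
  est <- c(list(frame_transform(0, 0, 0, 1)),
           lapply(2:9, function(i)
             estimate_transform(st$scp[[1]], st$scp[[i]],
                                rotation_range_deg = 0)))
  avg <- average_stack(st$cc, est, min_quality = 0.5)
  expect_identical(dim(avg$intensities), dim(st$cc[[1]]$intensities))
  expect_identical(avg$pixel_pitch_um, st$cc[[1]]$pixel_pitch_um)
  expect_equal(attr(avg, "n_retained"), 9)

  base <- ifelse(sc$capillary_mask, pars$cc_level, pars$void_level)
  base1 <- ccflow:::warp_rigid(base, st$transforms[[1]]$dx_px,
                               st$transforms[[1]]$dy_px,
                               st$transforms[[1]]$theta_deg, "forward")
  interior <- 16:113
  v_avg <- stats::var(as.vector((avg$intensities - base1)[interior, interior]))
  v_one <- stats::var(as.vector((st$cc[[1]]$intensities - base1)[interior, interior]))
  expect_lte(v_avg, v_one / 9 * 1.2)

  # single frame through an identity transform is returned unchanged
  one <- average_stack(st$cc[1], list(frame_transform(0, 0, 0, 1)), 0.5)
  expect_equal(one$intensities, st$cc[[1]]$intensities, tolerance = 1e-12)
  # identical noise-free frames average to themselves
  flatish <- en_face_image(random_smooth_image(32, 8), 10, "octa_cc")
  nine <- average_stack(rep(list(flatish), 9),
                        rep(list(frame_transform(0, 0, 0, 1)), 9), 0.5)
  expect_equal(nine$intensities, flatish$intensities, tolerance = 1e-12)
  # quality gate failure
  lowq <- lapply(1:9, function(i) frame_transform(0, 0, 0, 0.2))
  expect_error(average_stack(st$cc, lowq, min_quality = 0.5), "quality gate")
})
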