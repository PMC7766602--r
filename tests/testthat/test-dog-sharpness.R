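test_that("constant images filter to exactly zero and score zero sharpness", {
  img <- calibrated_image(matrix(128, 64, 64), 1, bit_depth = 8)
  out <- dog_filter(img)
  expect_true(all(abs(out) < 1e-12))
  expect_lt(sharpness(img)$sharpness, 1e-12)
})

test_that("an impulse response equals the DoG kernel peak", {
  m <- matrix(0, 65, 65)
  m[33, 33] <- 1
  got <- dog_filter(calibrated_image(m, 1))
  want <- oracle_dog(m)
  expect_equal(got[33, 33], want[33, 33], tolerance = 1e-12)
  # closed-form centre value: product of 1-D kernel centres, narrow minus wide
  k <- function(s) {
    w <- exp(-(-ceiling(4 * s):ceiling(4 * s))^2 / (2 * s^2)); w <- w / sum(w)
    w[(length(w) + 1) / 2]
  }
  expect_equal(got[33, 33], k(0.5)^2 - k(8)^2, tolerance = 1e-12)
})

test_that("the filter is linear in its input", {
  set.seed(21)
  i1 <- matrix(runif(48 * 48), 48, 48)
  i2 <- matrix(runif(48 * 48), 48, 48)
  lhs <- dog_filter(3 * i1 + 2 * i2, dog_params())
  rhs <- 3 * dog_filter(i1, dog_params()) + 2 * dog_filter(i2, dog_params())
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("separable filtering matches the dense convolution oracle", {
  set.seed(22)
  for (i in 1:6) {
    m <- matrix(runif(48 * 48), 48, 48)
    expect_lt(max(abs(dog_filter(m, dog_params()) - oracle_dog(m))), 1e-10)
  }
  # non-square raster
  m <- matrix(runif(40 * 56), 40, 56)
  expect_lt(max(abs(dog_filter(m, dog_params()) - oracle_dog(m))), 1e-10)
})

test_that("undersized rasters and bad parameters are rejected", {
  expect_error(dog_filter(matrix(1, 20, 64), dog_params()), "smaller")
  expect_error(dog_params(sigma_low = 8, sigma_high = 0.5), "sigma_low")
  expect_error(dog_params(sigma_low = 0), "sigma_low")
})

test_that("sharpness is homogeneous of degree 1 in intensity", {
  ph <- make_capillary_phantom(blur_sigma = 2)$image
  s1 <- sharpness(ph)$sharpness
  for (a in c(0.25, 2, 7.5)) {
    sa <- sharpness(calibrated_image(a * ph$pixels, 1))$sharpness
    expect_equal(sa, a * s1, tolerance = 1e-12)
  }
})

test_that("sharpness drops strictly with blur and is near translation-invariant", {
  sigmas <- c(0.5, 3.8, 7.2, 11, 14, 17)
  sh <- vapply(sigmas, function(s) {
    sharpness(make_capillary_phantom(blur_sigma = s)$image)$sharpness
  }, numeric(1))
  expect_true(all(diff(sh) < 0))
  # regression fixture for the default hairpin phantom
  expect_equal(sh, c(0.026646997, 0.016445312, 0.009358891,
                     0.004776606, 0.002836766, 0.001843090),
               tolerance = 1e-6)

  # shifting the capillary 5 px inside a large frame changes the score < 0.1%
  base <- make_capillary_phantom(frame_px = c(320, 320))$image$pixels
  shifted <- rbind(base[6:320, ], base[rep(320, 5), ])
  s0 <- sharpness(calibrated_image(base, 1))$sharpness
  s5 <- sharpness(calibrated_image(shifted, 1))$sharpness
  expect_lt(abs(s5 - s0) / s0, 0.001)
})

test_that("roi cropping restricts the sharpness computation", {
  ph <- make_capillary_phantom()$image
  r <- roi_rect("loop", 30, 60, 140, 140)
  s_roi <- sharpness(ph, roi = r)
  expect_equal(s_roi$roi, "loop")
  expect_equal(s_roi$sharpness, sharpness(crop(ph, r))$sharpness)
})

test_that("sharpness_table scores image-by-roi combinations tidily", {
  imgs <- list(a = make_capillary_phantom(blur_sigma = 1)$image,
               b = make_capillary_phantom(blur_sigma = 10)$image)
  rois <- list(roi_rect("left", 0, 0, 150, 128), roi_rect("right", 0, 128, 150, 128))
  tab <- sharpness_table(imgs, rois)
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$roi, c("left", "right"))
  expect_true(all(tab$sharpness[tab$image == "a"] > tab$sharpness[tab$image == "b"]))
})

test_that("relative sharpness rescales against the baseline window", {
  ser <- tibble::tibble(t = 0:2, value = c(10, 10, 5))
  out <- relative_sharpness(ser, baseline_window = c(0, 1))
  expect_equal(out$ratio, c(1, 1, 0.5))
  const <- tibble::tibble(t = 0:4, value = rep(3, 5))
  expect_equal(relative_sharpness(const, event_time = 2)$ratio, rep(1, 5))
  zero <- tibble::tibble(t = 0:2, value = c(0, 0, 1))
  expect_error(relative_sharpness(zero, baseline_window = c(0, 1)), "degenerate")
  expect_error(relative_sharpness(ser, baseline_window = c(10, 20)), "no points")
})
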