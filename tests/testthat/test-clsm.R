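seg3 <- vessel_seg_params(smooth_sigma = 3)

test_that("lumen size is recovered on noiseless ring-calibrated phantoms", {
  radii <- c(10, 15, 20, 25, 30)
  sizes <- vapply(radii, function(r) {
    segment_vessel(ring_calibrated_phantom(r)$image, seg3)$size_px
  }, numeric(1))
  expect_true(all(abs(sizes - radii * sqrt(pi)) / (radii * sqrt(pi)) < 0.05))
  expect_true(all(diff(sizes) > 0))
})

test_that("size grows strictly with radius over a fine radius sweep", {
  sizes <- vapply(seq(8, 40, by = 4), function(r) {
    segment_vessel(ring_calibrated_phantom(r)$image, seg3)$size_px
  }, numeric(1))
  expect_true(all(diff(sizes) > 0))
})

test_that("the mask is invariant under multiplicative intensity rescaling", {
  ph <- ring_calibrated_phantom(20)
  m1 <- segment_vessel(ph$image, seg3)
  half <- calibrated_image(0.5 * ph$image$pixels, 1)
  m2 <- segment_vessel(half, seg3)
  expect_identical(m1$mask$mask, m2$mask$mask)
  expect_equal(m1$size_px, sqrt(m1$area_px))
})

test_that("an all-bright region yields an empty-segmentation error", {
  flat <- calibrated_image(matrix(200, 64, 64), 1)
  expect_error(segment_vessel(flat, seg3), "empty segmentation")
})

test_that("equal-size components tie-break to the smallest centroid and flag it", {
  m <- matrix(1, 60, 60)
  m[11:20, 11:20] <- 0
  m[41:50, 41:50] <- 0
  vm <- segment_vessel(calibrated_image(m, 1), vessel_seg_params(smooth_sigma = 1))
  expect_match(vm$component_policy_used, "tie")
  idx <- which(vm$mask$mask, arr.ind = TRUE)
  expect_lt(mean(idx[, 1]), 30) # the top-left component was kept
})

test_that("segmentation agrees with brute-force smoothing on small phantoms", {
  # 64x64 disk: compare against an explicit dense Gaussian convolution
  img <- make_disk_image(10, bg = 1, n = 64)
  kern1d <- function(s) {
    r <- ceiling(4 * s); w <- exp(-(-r:r)^2 / (2 * s^2)); w / sum(w)
  }
  k <- kern1d(3); kd <- k %o% k
  p <- (length(k) - 1) / 2
  refl <- function(i, n) { i <- ifelse(i < 1, 1 - i, i); ifelse(i > n, 2 * n + 1 - i, i) }
  sm <- matrix(0, 64, 64)
  for (r in 1:64) for (cc in 1:64) {
    sm[r, cc] <- sum(kd * img$pixels[refl(r + (-p:p), 64), refl(cc + (-p:p), 64)])
  }
  brute_mask <- sm < 0.2 * max(sm)
  vm <- segment_vessel(img, seg3, keep_largest = FALSE)
  # agreement within one boundary pixel layer
  disagree <- which(vm$mask$mask != brute_mask, arr.ind = TRUE)
  if (nrow(disagree) > 0) {
    grown <- brute_mask
    for (dr in -1:1) for (dc in -1:1) {
      rs <- pmin(pmax(disagree[, 1] + dr, 1), 64)
      cs <- pmin(pmax(disagree[, 2] + dc, 1), 64)
      grown[cbind(rs, cs)] <- TRUE
    }
    expect_true(all(grown[disagree]))
  } else {
    expect_identical(vm$mask$mask, brute_mask)
  }
})

test_that("papilla brightness follows the closed-form ratio", {
  m <- matrix(120, 30, 30)
  pm <- matrix(FALSE, 30, 30); pm[5:10, 5:10] <- TRUE
  rm_ <- matrix(FALSE, 30, 30); rm_[20:25, 20:25] <- TRUE
  lm_ <- matrix(FALSE, 30, 30); lm_[5:10, 20:25] <- TRUE
  m[pm] <- 50; m[rm_] <- 200; m[lm_] <- 0
  img <- calibrated_image(m, 1)
  seg <- papilla_segmentation(pm, rm_, lm_)
  pb <- papilla_brightness(img, seg)
  expect_equal(pb$value, 100 * 50 / 200)
  # gain invariance
  pb2 <- papilla_brightness(calibrated_image(2 * m, 1), seg)
  expect_equal(pb2$value, pb$value)
  # offset covariance, by the formula: adding c shifts papilla mean only
  pb3 <- papilla_brightness(calibrated_image(m + 10, 1), seg)
  expect_equal(pb3$value, 100 * 60 / 200)
  # papilla drop 50 -> 40 gives 25 -> 20, a 20% decrease
  m4 <- m; m4[pm] <- 40
  pb4 <- papilla_brightness(calibrated_image(m4, 1), seg)
  expect_equal(pb4$value, 20)
})

test_that("contrast inversion and bad masks are rejected", {
  m <- matrix(1, 10, 10)
  a <- matrix(FALSE, 10, 10); a[1:2, 1:2] <- TRUE
  b <- matrix(FALSE, 10, 10); b[5:6, 5:6] <- TRUE
  cm <- matrix(FALSE, 10, 10); cm[9:10, 9:10] <- TRUE
  expect_error(papilla_brightness(calibrated_image(m, 1),
                                  papilla_segmentation(a, b, cm)),
               "contrast inversion")
  expect_error(papilla_segmentation(a, a, cm), "disjoint")
  expect_error(papilla_segmentation(a, b, matrix(FALSE, 10, 10)), "empty")
})

test_that("vessel size change compares medians as percent", {
  expect_equal(vessel_size_change(c(10, 10, 10), c(11, 11, 11)), 10)
  expect_equal(vessel_size_change(1:9, 1:9), 0)
  expect_error(vessel_size_change(numeric(0), 1), "non-empty")
  expect_error(vessel_size_change(c(0, 0, 0), c(1, 1, 1)), "degenerate")
})

test_that("cohort summary reports medians, change and low-n flags", {
  d <- tibble::tibble(value = c(25, 25, 25, 20, 20, 20),
                      condition = rep(c("before", "after"), each = 3))
  cs <- brightness_cohort_summary(d)
  expect_equal(cs$percent_change, -20)
  expect_true(all(tidy(cs)$low_n))

  one <- brightness_cohort_summary(tibble::tibble(value = rep(25, 12),
                                                  condition = "before"))
  expect_true(is.na(one$percent_change))
  expect_false(any(one$groups$low_n))
})
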