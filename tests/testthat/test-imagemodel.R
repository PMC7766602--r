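test_that("construction enforces the raster and calibration invariants", {
  expect_error(calibrated_image(matrix(numeric(0), 0, 0), 1), "non-empty")
  expect_error(calibrated_image(matrix(-1, 2, 2), 1), "non-negative")
  expect_error(calibrated_image(matrix(NA_real_, 2, 2), 1), "finite")
  expect_error(calibrated_image(matrix(1, 2, 2), 0), "positive")
  expect_error(calibrated_image(matrix(1, 2, 2), 1, bit_depth = 12), "bit_depth")
})

test_that("8- and 16-bit rasters round-trip bit-exactly through TIFF and PNG", {
  set.seed(11)
  for (depth in c(8L, 16L)) {
    vals <- matrix(sample(0:(2^depth - 1), 400, replace = TRUE), 20, 20)
    img <- calibrated_image(vals, pitch_um = 0.7, bit_depth = depth)
    path <- withr::local_tempfile(fileext = ".tif")
    write_image(img, path)
    back <- load_image(path, pitch_um = 0.7)
    expect_identical(back$pixels, img$pixels)
    expect_identical(back$bit_depth, depth)
  }
  img8 <- calibrated_image(matrix(sample(0:255, 100, TRUE), 10, 10),
                           pitch_um = 1, bit_depth = 8L)
  ppath <- withr::local_tempfile(fileext = ".png")
  write_image(img8, ppath)
  expect_identical(load_image(ppath, 1)$pixels, img8$pixels)
  # 16-bit PNG output is refused rather than silently truncated
  img16 <- calibrated_image(matrix(300, 4, 4), 1, bit_depth = 16L)
  expect_error(write_image(img16, withr::local_tempfile(fileext = ".png")),
               "TIFF")
})

test_that("gray RGB input reduces to the same gray level via luma weights", {
  path <- withr::local_tempfile(fileext = ".png")
  arr <- array(50 / 255, dim = c(8, 8, 3))
  png::writePNG(arr, path)
  expect_message(img <- load_image(path, 1), "luma")
  expect_true(all(img$pixels == 50))
})

test_that("normalization uses the declared full scale and is idempotent", {
  img8 <- calibrated_image(matrix(51, 4, 4), 1, bit_depth = 8)
  expect_equal(normalize_unit(img8)$pixels, matrix(0.2, 4, 4))
  img8b <- calibrated_image(matrix(255, 4, 4), 1, bit_depth = 8)
  expect_equal(normalize_unit(img8b)$pixels, matrix(1, 4, 4))
  imgf <- calibrated_image(matrix(c(0.5, 2, 1, 0), 2, 2), 1)
  n1 <- normalize_unit(imgf)
  expect_equal(max(n1$pixels), 1)
  expect_equal(normalize_unit(n1)$pixels, n1$pixels)
  expect_error(normalize_unit(calibrated_image(matrix(0, 2, 2), 1)), "all-zero")
})

test_that("cropping composes and rejects out-of-bounds regions", {
  img <- calibrated_image(matrix(seq_len(100 * 100), 100, 100), 1)
  a <- roi_rect("a", 10, 10, 20, 30)
  expect_equal(dim(crop(img, a)$pixels), c(20, 30))
  expect_error(crop(img, roi_rect("x", 95, 95, 20, 20)), "outside")
  full <- roi_rect("full", 0, 0, 100, 100)
  expect_identical(crop(img, full)$pixels, img$pixels)
  # nested crops equal one composed crop
  b <- roi_rect("b", 3, 5, 10, 12)
  composed <- roi_rect("ab", a$row0 + b$row0, a$col0 + b$col0, b$height, b$width)
  expect_identical(crop(crop(img, a), b)$pixels, crop(img, composed)$pixels)
})

test_that("landmark distances are Euclidean, calibrated, and arity-checked", {
  expect_equal(measure_distance(landmarks(rbind(c(0, 0), c(0, 10))), 0.5), 5)
  expect_equal(measure_distance(landmarks(rbind(c(3, 4), c(0, 0))), 1), 5)
  expect_equal(measure_distance(landmarks(rbind(c(2, 2), c(2, 2))), 1), 0)
  expect_error(measure_distance(landmarks(rbind(c(0, 0), c(1, 1), c(2, 2))), 1),
               "exactly 2")
  expect_error(landmarks(rbind(c(0, 0))), "at least 2")
})

test_that("roi files round-trip through JSON and read from CSV", {
  rois <- list(roi_rect("cap1", 5, 10, 20, 25), roi_rect("cap2", 40, 1, 8, 8))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_rois(rois, jpath)
  back <- read_rois(jpath)
  expect_equal(back, rois)

  cpath <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(name = "r1", row0 = 2, col0 = 3, height = 4, width = 5),
            cpath, row.names = FALSE)
  rcsv <- read_rois(cpath)
  expect_equal(rcsv[[1]]$height, 4L)
})

test_that("polygon rois rasterize by the even-odd rule", {
  sq <- structure(list(name = "sq",
                       points = rbind(c(1.5, 1.5), c(1.5, 6.5),
                                      c(6.5, 6.5), c(6.5, 1.5))),
                  class = "roi_polygon")
  mask <- as_roi_mask(sq, c(10, 10))
  # pixel centres 2..6 in both axes fall inside -> 25 pixels
  expect_equal(sum(mask$mask), 25)
  expect_true(mask$mask[3, 3])
  expect_false(mask$mask[1, 1])
  rect_mask <- as_roi_mask(roi_rect("r", 0, 0, 2, 3), c(4, 4))
  expect_equal(sum(rect_mask$mask), 6)
})

test_that("config files override only known keys", {
  cfg <- read_config(NULL)
  expect_equal(cfg$sigma_high, 8)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("pitch_um: 0.5", "threshold_frac: 0.3", "unknown_key: 7"), path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$pitch_um, 0.5)
  expect_equal(cfg2$threshold_frac, 0.3)
  expect_equal(cfg2$sigma_low, 0.5)
  expect_null(cfg2$unknown_key)
})
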