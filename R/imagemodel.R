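# Core raster data model: a calibrated grayscale image plus regions of
# interest. Coordinates are 0-based (row, col); rectangles are half-open on
# the far side, so a roi of height h starting at row0 covers rows
# row0 .. row0 + h - 1.

#' Construct a calibrated image
#'
#' A calibrated image is a 2-D non-negative intensity raster together with
#' its pixel pitch in micrometres per pixel and the bit depth of the source
#' data. Intensities are stored as doubles on the source scale (0..255 for
#' 8-bit, 0..65535 for 16-bit); nothing is rescaled implicitly — see
#' [normalize_unit()].
#'
#' @param pixels numeric matrix of intensities, all finite and `>= 0`.
#' @param pitch_um pixel pitch in micrometres per pixel (`> 0`).
#' @param bit_depth `8`, `16`, or `"float"`.
#' @param origin_label free-text provenance (file path or generator spec).
#' @return An object of class `calibrated_image`.
#' @export
#' @examples
#' img <- calibrated_image(matrix(runif(100), 10, 10), pitch_um = 1.5)
#' dim(img$pixels)
calibrated_image <- function(pixels, pitch_um, bit_depth = "float",
                             origin_label = "in-memory") {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0) {
    stop("`pixels` must be a non-empty numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(pitch_um) || length(pitch_um) != 1 || pitch_um <= 0) {
    stop("`pitch_um` must be a single positive number", call. = FALSE)
  }
  if (!identical(bit_depth, "float") && !(bit_depth %in% c(8L, 16L, 8, 16))) {
    stop("`bit_depth` must be 8, 16 or \"float\"", call. = FALSE)
  }
  storage.mode(pixels) <- "double"
  structure(
    list(pixels = pixels, pitch_um = pitch_um,
         bit_depth = if (identical(bit_depth, "float")) "float" else as.integer(bit_depth),
         origin_label = origin_label),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<calibrated_image> %d x %d px, %.4g um/px (%.4g x %.4g um), bit depth %s\n",
              d[1], d[2], x$pitch_um, d[1] * x$pitch_um, d[2] * x$pitch_um,
              as.character(x$bit_depth)))
  cat(sprintf("  intensity range [%.4g, %.4g]; origin: %s\n",
              min(x$pixels), max(x$pixels), x$origin_label))
  invisible(x)
}

full_scale <- function(bit_depth) {
  switch(as.character(bit_depth), "8" = 255, "16" = 65535,
         stop("no fixed full-scale for bit depth ", bit_depth, call. = FALSE))
}

#' Load a grayscale image from TIFF or PNG
#'
#' Reads an 8- or 16-bit TIFF or PNG raster and records the supplied pixel
#' pitch. Intensities are restored to the source integer scale (a 16-bit
#' image with maximal value reads back as 65535), never silently rescaled.
#' RGB inputs are reduced to luma with fixed Rec. 709 weights
#' (0.2126, 0.7152, 0.0722).
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param pitch_um pixel pitch in micrometres per pixel. Acquisition pitch is
#'   not stored in these formats, so it must always be supplied.
#' @return A [calibrated_image()].
#' @seealso [write_image()], [normalize_unit()]
#' @export
load_image <- function(path, pitch_um) {
  if (!file.exists(path)) stop("cannot read image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(arr, "bits.per.sample")
    if (is.null(depth)) depth <- 8L
  } else if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  depth <- as.integer(depth)
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    if (nch >= 3) {
      message("multi-channel input reduced to luma (0.2126 R + 0.7152 G + 0.0722 B): ", path)
      arr <- 0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  if (length(arr) == 0) stop("zero-size raster in ", path, call. = FALSE)
  # readTIFF/readPNG return values scaled to [0,1]; restore source scale
  pixels <- matrix(round(as.numeric(arr) * full_scale(depth)),
                   nrow = dim(arr)[1], ncol = dim(arr)[2])
  calibrated_image(pixels, pitch_um, bit_depth = depth, origin_label = path)
}

#' Write a calibrated image to TIFF or PNG
#'
#' 8- and 16-bit images round-trip bit-exactly through TIFF and PNG. Float
#' images are written 16-bit after scaling by their maximum (a lossy,
#' logged conversion).
#'
#' @param image a [calibrated_image()].
#' @param path destination `.tif`/`.tiff` or `.png` path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  ext <- tolower(tools::file_ext(path))
  if (identical(image$bit_depth, "float")) {
    mx <- max(image$pixels)
    if (mx <= 0) stop("cannot write an all-zero float raster", call. = FALSE)
    message("float raster scaled by 1/", format(mx), " and written 16-bit")
    scaled <- image$pixels / mx
    depth <- 16L
  } else {
    depth <- image$bit_depth
    scaled <- image$pixels / full_scale(depth)
  }
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = depth)
  } else if (ext == "png") {
    if (depth == 16L) {
      stop("16-bit output requires TIFF (PNG is written 8-bit)", call. = FALSE)
    }
    png::writePNG(scaled, path)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Normalize intensities to the unit interval
#'
#' Divides by the nominal full scale of the bit depth (255 or 65535); float
#' rasters are divided by their maximum. This is an explicit step because
#' the sharpness metric is linear in intensity: cross-image comparisons need
#' a declared common scale.
#'
#' @param image a [calibrated_image()].
#' @return A float-depth [calibrated_image()] with intensities in `[0, 1]`.
#' @export
normalize_unit <- function(image) {
  stopifnot(inherits(image, "calibrated_image"))
  if (max(image$pixels) <= 0) {
    stop("degenerate input: all-zero raster cannot be normalized", call. = FALSE)
  }
  div <- if (identical(image$bit_depth, "float")) max(image$pixels) else full_scale(image$bit_depth)
  calibrated_image(image$pixels / div, image$pitch_um, bit_depth = "float",
                   origin_label = paste0(image$origin_label, " [unit-normalized]"))
}

#' Rectangular region of interest
#'
#' 0-based top-left corner and pixel extents, half-open on the far side.
#'
#' @param name label for the region.
#' @param row0,col0 top-left pixel (0-based, inclusive).
#' @param height,width extents in pixels (`>= 1`).
#' @return An object of class `roi_rect`.
#' @export
roi_rect <- function(name, row0, col0, height, width) {
  if (height < 1 || width < 1) stop("roi extents must be >= 1", call. = FALSE)
  if (row0 < 0 || col0 < 0) stop("roi origin must be >= 0", call. = FALSE)
  structure(list(name = name, row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi_rect")
}

#' Binary mask region of interest
#'
#' @param name label.
#' @param mask logical matrix congruent with the image it addresses.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(name, mask) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  mask <- mask > 0
  structure(list(name = name, mask = mask), class = "roi_mask")
}

#' Crop an image to a rectangular region
#'
#' A region reaching outside the raster is rejected, never clipped silently.
#'
#' @param image a [calibrated_image()].
#' @param roi a [roi_rect()].
#' @return The cropped [calibrated_image()] (same pitch).
#' @export
crop <- function(image, roi) {
  stopifnot(inherits(image, "calibrated_image"), inherits(roi, "roi_rect"))
  d <- dim(image$pixels)
  if (roi$row0 + roi$height > d[1] || roi$col0 + roi$width > d[2]) {
    stop(sprintf("roi '%s' (%d,%d,%dx%d) lies outside a %dx%d raster",
                 roi$name, roi$row0, roi$col0, roi$height, roi$width, d[1], d[2]),
         call. = FALSE)
  }
  px <- image$pixels[(roi$row0 + 1):(roi$row0 + roi$height),
                     (roi$col0 + 1):(roi$col0 + roi$width), drop = FALSE]
  calibrated_image(px, image$pitch_um, image$bit_depth,
                   origin_label = sprintf("%s [crop %s]", image$origin_label, roi$name))
}

#' Ordered landmark points
#'
#' Sub-pixel `(row, col)` coordinates supporting annotation-based distance
#' measurements such as the capillary apical diameter or the width of the
#' perivascular zone. No detection algorithm is provided: these structures
#' are located manually.
#'
#' @param points two-column numeric matrix of `(row, col)` coordinates, at
#'   least two points.
#' @param label what is measured, e.g. `"apical_diameter"` or `"pz_width"`.
#' @return An object of class `landmarks`.
#' @export
landmarks <- function(points, label = "distance") {
  points <- as.matrix(points)
  if (ncol(points) != 2 || nrow(points) < 2) {
    stop("`points` must be a (row, col) matrix with at least 2 points", call. = FALSE)
  }
  structure(list(points = points, label = label), class = "landmarks")
}

#' Measure a calibrated point-to-point distance
#'
#' Euclidean pixel distance between exactly two landmark points, converted to
#' micrometres with the pixel pitch.
#'
#' @param landmarks a [landmarks()] object with exactly 2 points.
#' @param pitch_um pixel pitch in micrometres per pixel.
#' @return Distance in micrometres.
#' @export
#' @examples
#' measure_distance(landmarks(rbind(c(3, 4), c(0, 0))), pitch_um = 1) # 5
measure_distance <- function(landmarks, pitch_um) {
  stopifnot(inherits(landmarks, "landmarks"))
  if (nrow(landmarks$points) != 2) {
    stop("distance needs exactly 2 landmark points, got ", nrow(landmarks$points),
         call. = FALSE)
  }
  d <- landmarks$points[1, ] - landmarks$points[2, ]
  sqrt(sum(d^2)) * pitch_um
}

# ---- ROI file interchange -------------------------------------------------

#' Read regions of interest from JSON or CSV
#'
#' JSON: an array of objects `{"name":, "type":"rect", "row0":, "col0":,
#' "height":, "width":}` or `{"type":"polygon", "points":[[row,col],...]}`.
#' CSV: rectangle lists with the same columns. Polygons are returned as-is
#' and rasterized lazily with [as_roi_mask()].
#'
#' @param path a `.json` or `.csv` file.
#' @return A list of `roi_rect` / `roi_polygon` objects.
#' @export
read_rois <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    entries <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    lapply(entries, function(e) {
      type <- e$type %||% "rect"
      if (type == "rect") {
        roi_rect(e$name %||% "roi", e$row0, e$col0, e$height, e$width)
      } else if (type == "polygon") {
        pts <- do.call(rbind, lapply(e$points, unlist))
        structure(list(name = e$name %||% "roi", points = pts), class = "roi_polygon")
      } else {
        stop("unknown roi type: ", type, call. = FALSE)
      }
    })
  } else if (ext == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    needed <- c("name", "row0", "col0", "height", "width")
    if (!all(needed %in% names(df))) {
      stop("roi csv must have columns: ", paste(needed, collapse = ", "), call. = FALSE)
    }
    lapply(seq_len(nrow(df)), function(i) {
      roi_rect(df$name[i], df$row0[i], df$col0[i], df$height[i], df$width[i])
    })
  } else {
    stop("unsupported roi format: .", ext, call. = FALSE)
  }
}

#' Write rectangular regions of interest to JSON
#'
#' @param rois list of [roi_rect()] objects.
#' @param path destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  entries <- lapply(rois, function(r) {
    if (inherits(r, "roi_rect")) {
      list(name = r$name, type = "rect", row0 = r$row0, col0 = r$col0,
           height = r$height, width = r$width)
    } else if (inherits(r, "roi_polygon")) {
      list(name = r$name, type = "polygon",
           points = lapply(seq_len(nrow(r$points)), function(i) as.numeric(r$points[i, ])))
    } else stop("not a roi object", call. = FALSE)
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize a polygon region to a binary mask
#'
#' Even-odd rule at pixel centres; `(row, col)` vertex coordinates are
#' 0-based.
#'
#' @param roi a `roi_polygon` from [read_rois()] or a [roi_mask()]
#'   (returned unchanged).
#' @param dim integer vector `(rows, cols)` of the target raster.
#' @return A [roi_mask()].
#' @export
as_roi_mask <- function(roi, dim) {
  if (inherits(roi, "roi_mask")) return(roi)
  if (inherits(roi, "roi_rect")) {
    m <- matrix(FALSE, dim[1], dim[2])
    m[(roi$row0 + 1):(roi$row0 + roi$height),
      (roi$col0 + 1):(roi$col0 + roi$width)] <- TRUE
    return(roi_mask(roi$name, m))
  }
  stopifnot(inherits(roi, "roi_polygon"))
  vr <- roi$points[, 1]
  vc <- roi$points[, 2]
  nv <- length(vr)
  pr <- as.vector(row(matrix(0, dim[1], dim[2]))) - 1  # 0-based pixel centres
  pc <- as.vector(col(matrix(0, dim[1], dim[2]))) - 1
  inside <- rep(FALSE, length(pr))
  j <- nv
  for (i in seq_len(nv)) {
    crosses <- ((vr[i] > pr) != (vr[j] > pr)) &
      (pc < (vc[j] - vc[i]) * (pr - vr[i]) / (vr[j] - vr[i]) + vc[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  roi_mask(roi$name, matrix(inside, dim[1], dim[2]))
}

#' Read an analysis configuration file
#'
#' YAML with keys `pitch_um`, `normalize`, `sigma_low`, `sigma_high`,
#' `smooth_sigma`, `threshold_frac`; missing keys take the package defaults.
#'
#' @param path a `.yaml`/`.yml` file, or `NULL` for pure defaults.
#' @return A named list of parameters.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(pitch_um = 1, normalize = FALSE, sigma_low = 0.5,
                   sigma_high = 8, smooth_sigma = 15, threshold_frac = 0.2)
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  utils::modifyList(defaults, user[names(user) %in% names(defaults)])
}
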