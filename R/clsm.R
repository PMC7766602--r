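# CLSM morphometry: vessel (lumen) size from a smoothed, relatively
# thresholded region crop, and the gain-invariant papilla brightness ratio.

#' Vessel segmentation parameters
#'
#' @param smooth_sigma Gaussian smoothing standard deviation in px
#'   (default 15), suppressing speckle before thresholding.
#' @param threshold_frac fraction of the smoothed maximum below which pixels
#'   count as lumen (default 0.20).
#' @param smooth_um optional smoothing scale in micrometres; converted to
#'   pixels with the image pitch and overriding `smooth_sigma`.
#' @return A list of class `vessel_seg_params`.
#' @export
vessel_seg_params <- function(smooth_sigma = 15, threshold_frac = 0.2,
                              smooth_um = NULL) {
  if (is.null(smooth_um) && smooth_sigma <= 0) stop("`smooth_sigma` must be > 0", call. = FALSE)
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    stop("`threshold_frac` must be in (0, 1)", call. = FALSE)
  }
  structure(list(smooth_sigma = smooth_sigma, threshold_frac = threshold_frac,
                 smooth_um = smooth_um),
            class = "vessel_seg_params")
}

# 8-connected components by iterated minimum-label propagation. Returns an
# integer label matrix (0 = background). Adequate for single-capillary ROI
# crops; not tuned for large mosaics.
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(Inf, nr, nc)
  lab[mask] <- which(mask)
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
    out
  }
  repeat {
    nb <- lab
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- pmin(nb, shift(lab, dr, dc))
    }
    nb[!mask] <- Inf
    if (identical(nb, lab)) break
    lab <- nb
  }
  out <- matrix(0L, nr, nc)
  if (any(mask)) {
    ids <- lab[mask]
    out[mask] <- as.integer(factor(ids))
  }
  out
}

#' Segment the vessel lumen in a CLSM region crop
#'
#' The region (drawn around a single capillary cross-section) is blurred with
#' a Gaussian filter to suppress noise and irregularities; smoothed pixels
#' with intensity lower than `threshold_frac` of the smoothed image's maximum
#' are assigned to the vessel. By default the largest 8-connected component
#' is retained, so stray dark pixels elsewhere in the crop do not inflate the
#' area. Vessel size is the square root of the lumen area.
#'
#' @param roi_image a [calibrated_image()] crop containing the full dark
#'   lumen.
#' @param params a [vessel_seg_params()].
#' @param keep_largest retain only the largest 8-connected component
#'   (default `TRUE`); ties are broken by smallest centroid row then column
#'   and flagged in `component_policy_used`.
#' @return An object of class `vessel_measurement` with fields `mask`
#'   ([roi_mask()]), `area_px`, `size_px` (`sqrt(area_px)`), `size_um`,
#'   `component_policy_used`, `params`.
#' @export
#' @examples
#' ph <- make_papilla_phantom(lumen_radius_px = 20)
#' segment_vessel(ph$image)$size_px # close to 20 * sqrt(pi)
segment_vessel <- function(roi_image, params = vessel_seg_params(),
                           keep_largest = TRUE) {
  stopifnot(inherits(roi_image, "calibrated_image"),
            inherits(params, "vessel_seg_params"))
  sigma <- if (!is.null(params$smooth_um)) params$smooth_um / roi_image$pitch_um else params$smooth_sigma
  sm <- gaussian_blur(roi_image$pixels, sigma)
  thr <- params$threshold_frac * max(sm)
  cand <- sm < thr
  if (!any(cand)) {
    stop("empty segmentation: no pixel below ", params$threshold_frac,
         " of the smoothed maximum (is the lumen inside the region?)", call. = FALSE)
  }
  policy <- "all_subthreshold"
  mask <- cand
  if (keep_largest) {
    lab <- label_components8(cand)
    sizes <- tabulate(lab[lab > 0])
    best <- which(sizes == max(sizes))
    policy <- "largest_component"
    if (length(best) > 1) {
      # tie: smallest centroid row, then column
      cent <- t(vapply(best, function(b) {
        idx <- which(lab == b, arr.ind = TRUE)
        colMeans(idx)
      }, numeric(2)))
      best <- best[order(cent[, 1], cent[, 2])[1]]
      policy <- "largest_component_tie_min_centroid"
    }
    mask <- lab == best
  }
  area <- sum(mask)
  structure(
    list(mask = roi_mask("lumen", mask), area_px = area, size_px = sqrt(area),
         size_um = sqrt(area) * roi_image$pitch_um,
         component_policy_used = policy, params = params),
    class = "vessel_measurement"
  )
}

#' @export
print.vessel_measurement <- function(x, ...) {
  cat(sprintf("<vessel_measurement> area %d px, size %.2f px (%.2f um), policy %s\n",
              x$area_px, x$size_px, x$size_um, x$component_policy_used))
  invisible(x)
}

#' Tidy a vessel measurement
#'
#' @param x a `vessel_measurement` or list thereof.
#' @param ... unused.
#' @return One row per measurement: `area_px`, `size_px`, `size_um`,
#'   `component_policy_used`.
#' @export
tidy.vessel_measurement <- function(x, ...) {
  tibble::tibble(area_px = x$area_px, size_px = x$size_px, size_um = x$size_um,
                 component_policy_used = x$component_policy_used)
}

#' Percent change of median vessel size between conditions
#'
#' `100 * (median_after - median_before) / median_before` on `size_px`, or on
#' `size_um` when `use_um = TRUE`. Medians rather than means match how
#' capillary size changes under venous occlusion are usually reported.
#'
#' @param before,after lists of `vessel_measurement` objects or numeric
#'   vectors of sizes.
#' @param use_um compare calibrated sizes instead of pixel sizes.
#' @return Percent change (a single number).
#' @export
vessel_size_change <- function(before, after, use_um = FALSE) {
  as_sizes <- function(x) {
    if (is.numeric(x)) return(x)
    field <- if (use_um) "size_um" else "size_px"
    vapply(x, function(v) v[[field]], numeric(1))
  }
  b <- as_sizes(before); a <- as_sizes(after)
  if (length(b) == 0 || length(a) == 0) stop("both groups must be non-empty", call. = FALSE)
  mb <- stats::median(b)
  if (mb == 0) stop("degenerate input: median size before is zero", call. = FALSE)
  100 * (stats::median(a) - mb) / mb
}

#' Papilla / ring / lumen segmentation
#'
#' Three pairwise-disjoint masks per capillary cross-section: the gray
#' dermal papilla, the bright melanin ring near the dermal-epidermal
#' junction, and the dark capillary lumen. Masks are supplied (manual
#' segmentation or phantom ground truth); no automatic detector is provided.
#'
#' @param papilla,ring,lumen [roi_mask()] objects (or logical matrices) of a
#'   common shape, pairwise disjoint, each non-empty.
#' @return An object of class `papilla_segmentation`.
#' @export
papilla_segmentation <- function(papilla, ring, lumen) {
  as_mask <- function(m, nm) if (inherits(m, "roi_mask")) m else roi_mask(nm, m)
  papilla <- as_mask(papilla, "papilla")
  ring <- as_mask(ring, "ring")
  lumen <- as_mask(lumen, "lumen")
  dims <- list(dim(papilla$mask), dim(ring$mask), dim(lumen$mask))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("papilla, ring and lumen masks must share one shape", call. = FALSE)
  }
  for (m in list(papilla, ring, lumen)) {
    if (!any(m$mask)) stop("mask '", m$name, "' is empty", call. = FALSE)
  }
  if (any(papilla$mask & ring$mask) || any(papilla$mask & lumen$mask) ||
      any(ring$mask & lumen$mask)) {
    stop("papilla, ring and lumen masks must be pairwise disjoint", call. = FALSE)
  }
  structure(list(papilla = papilla, ring = ring, lumen = lumen),
            class = "papilla_segmentation")
}

#' Read a papilla segmentation from a label raster
#'
#' PNG label codes: 0 background, 1 lumen, 2 papilla, 3 ring.
#'
#' @param path a PNG label raster.
#' @return A [papilla_segmentation()].
#' @export
read_papilla_labels <- function(path) {
  img <- load_image(path, pitch_um = 1)
  lab <- img$pixels
  papilla_segmentation(papilla = lab == 2, ring = lab == 3, lumen = lab == 1)
}

#' Papilla brightness ratio
#'
#' `100 * mean(papilla) / (mean(ring) - mean(lumen))`: the average papilla
#' intensity relative to the contrast between the bright melanin ring and the
#' dark lumen, scaled by 100 for a convenient range. The ratio is invariant
#' to multiplicative detector gain, so values are comparable across frames
#' with different scanning intensity or depth; it drops when the papilla
#' becomes hyporefractive (e.g. after histamine-induced edema).
#'
#' @param image a [calibrated_image()].
#' @param seg a [papilla_segmentation()] congruent with the image.
#' @return One-row tibble: `value`, `mean_papilla`, `mean_ring`,
#'   `mean_lumen`.
#' @export
#' @examples
#' ph <- make_papilla_phantom()
#' papilla_brightness(ph$image, ph$segmentation)
papilla_brightness <- function(image, seg) {
  stopifnot(inherits(image, "calibrated_image"),
            inherits(seg, "papilla_segmentation"))
  if (!identical(dim(seg$papilla$mask), dim(image$pixels))) {
    stop("segmentation masks do not match the image shape", call. = FALSE)
  }
  mp <- mean(image$pixels[seg$papilla$mask])
  mr <- mean(image$pixels[seg$ring$mask])
  ml <- mean(image$pixels[seg$lumen$mask])
  if (mr <= ml) {
    stop(sprintf(paste0("contrast inversion: mean ring intensity (%.4g) is not above ",
                        "mean lumen intensity (%.4g) - segmentation failure or ",
                        "saturated frame"), mr, ml), call. = FALSE)
  }
  tibble::tibble(value = 100 * mp / (mr - ml),
                 mean_papilla = mp, mean_ring = mr, mean_lumen = ml)
}

#' Cohort summary of papilla brightness measurements
#'
#' Per-group median and interquartile range plus the percent change of
#' medians across two conditions. About 10-12 tiles per subject are needed
#' for a stable brightness estimate, so groups with fewer than 10
#' measurements are flagged.
#'
#' @param data tibble with a brightness `value` column and a `condition`
#'   column.
#' @param value,condition column names (tidy-eval).
#' @param min_n group size below which a warning flag is raised (default 10).
#' @return A list of class `cohort_summary`: `groups` tibble
#'   (`condition`, `n`, `median`, `q1`, `q3`, `low_n`), `percent_change`
#'   (change of medians from the first to the second condition level, `NA`
#'   for a single group).
#' @export
brightness_cohort_summary <- function(data, value = value, condition = condition,
                                      min_n = 10) {
  data <- tibble::as_tibble(data)
  v <- rlang::enquo(value); g <- rlang::enquo(condition)
  gvals <- rlang::eval_tidy(g, data)
  # condition order = first appearance, so before/after changes keep their sign
  data$.cond <- factor(gvals, levels = unique(gvals))
  groups <- data |>
    dplyr::group_by(condition = .data$.cond) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(!!v),
      q1 = unname(stats::quantile(!!v, 0.25, type = 7)),
      q3 = unname(stats::quantile(!!v, 0.75, type = 7)),
      .groups = "drop"
    ) |>
    dplyr::mutate(condition = as.character(.data$condition),
                  low_n = .data$n < min_n)
  if (nrow(groups) == 0 || any(groups$n < 1)) stop("each group needs >= 1 value", call. = FALSE)
  pc <- NA_real_
  if (nrow(groups) == 2) {
    pc <- 100 * (groups$median[2] - groups$median[1]) / groups$median[1]
  }
  structure(list(groups = groups, percent_change = pc, min_n = min_n),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$groups)
  if (!is.na(x$percent_change)) {
    cat(sprintf("  percent change of medians: %+.2f%%\n", x$percent_change))
  } else {
    cat("  single group: no condition comparison\n")
  }
  if (any(x$groups$low_n)) {
    cat(sprintf("  warning: group(s) with fewer than %d measurements (%s)\n",
                x$min_n, paste(x$groups$condition[x$groups$low_n], collapse = ", ")))
  }
  invisible(x)
}

#' @export
tidy.cohort_summary <- function(x, ...) x$groups

#' @export
glance.cohort_summary <- function(x, ...) {
  tibble::tibble(n_groups = nrow(x$groups), percent_change = x$percent_change,
                 any_low_n = any(x$groups$low_n))
}
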