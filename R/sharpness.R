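# Image sharpness scoring for NVC frames. Epidermal water accumulation blurs
# the capillary image; the mean absolute amplitude of the band-pass (DoG)
# filtered image quantifies the residual fine-scale contrast and drops as the
# image gets "foggy".

#' Sharpness of a capillary image
#'
#' The mean absolute amplitude of the difference-of-Gaussians filtered image,
#' computed after cropping to a region containing only first-row capillaries
#' when a ROI is given. The score is non-negative, zero exactly for constant
#' images, and homogeneous of degree 1 in intensity
#' (`sharpness(a * I) = a * sharpness(I)`), which is why intensities are not
#' renormalized implicitly: set `normalize = TRUE` to score on the common
#' `[0, 1]` scale of [normalize_unit()] when comparing across acquisitions
#' with different bit depths.
#'
#' @param image a [calibrated_image()].
#' @param params a [dog_params()] (defaults 0.5 / 8 px).
#' @param roi optional [roi_rect()] to crop to before filtering.
#' @param normalize apply [normalize_unit()] first (default `FALSE`).
#' @return One-row tibble with columns `roi`, `sigma_low`, `sigma_high`,
#'   `sharpness`.
#' @export
#' @examples
#' ph <- make_capillary_phantom(blur_sigma = 2)
#' sharpness(ph$image)
sharpness <- function(image, params = dog_params(), roi = NULL, normalize = FALSE) {
  stopifnot(inherits(image, "calibrated_image"))
  if (!is.null(roi)) image <- crop(image, roi)
  if (normalize) image <- normalize_unit(image)
  amp <- mean(abs(dog_filter(image, params)))
  tibble::tibble(
    roi = if (is.null(roi)) NA_character_ else roi$name,
    sigma_low = params$sigma_low, sigma_high = params$sigma_high,
    sharpness = amp
  )
}

#' Sharpness table over many images and regions
#'
#' Tidy batch interface: one row per image x ROI.
#'
#' @param images named list of [calibrated_image()] objects (names become the
#'   `image` column) or a character vector of file paths (loaded with
#'   `pitch_um`).
#' @param rois optional list of [roi_rect()]; `NULL` scores whole frames.
#' @param params a [dog_params()].
#' @param pitch_um pixel pitch used when `images` are paths.
#' @param normalize passed to [sharpness()].
#' @return Tibble with columns `image`, `roi`, `sigma_low`, `sigma_high`,
#'   `sharpness`.
#' @export
sharpness_table <- function(images, rois = NULL, params = dog_params(),
                            pitch_um = 1, normalize = FALSE) {
  if (is.character(images)) {
    nm <- images
    images <- lapply(images, load_image, pitch_um = pitch_um)
    names(images) <- nm
  }
  if (is.null(names(images))) names(images) <- paste0("image_", seq_along(images))
  roi_list <- if (is.null(rois)) list(NULL) else rois
  purrr::map(names(images), function(nm) {
    purrr::map(roi_list, function(r) {
      dplyr::mutate(sharpness(images[[nm]], params, roi = r, normalize = normalize),
                    image = nm, .before = 1)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Relative sharpness of a time series
#'
#' Divides each sharpness value by the mean over a baseline window so that
#' before/after comparisons (e.g. 5 min after histamine application) are
#' expressed as ratios with baseline at 1.
#'
#' @param series tibble/data frame with columns `t` and `value`, times
#'   strictly increasing.
#' @param baseline_window length-2 numeric `(t_from, t_to)` inclusive;
#'   `NULL` with `event_time` set uses all points before the event.
#' @param event_time optional event timestamp defining the default baseline.
#' @return The series tibble with an added `ratio` column.
#' @export
relative_sharpness <- function(series, baseline_window = NULL, event_time = NULL) {
  series <- check_series(series)
  if (is.null(baseline_window)) {
    if (is.null(event_time)) {
      stop("supply `baseline_window` or `event_time`", call. = FALSE)
    }
    in_base <- series$t < event_time
  } else {
    in_base <- series$t >= baseline_window[1] & series$t <= baseline_window[2]
  }
  if (!any(in_base)) stop("baseline window contains no points", call. = FALSE)
  base <- mean(series$value[in_base])
  if (base <= 0) stop("degenerate baseline: mean sharpness is not positive", call. = FALSE)
  dplyr::mutate(series, ratio = .data$value / base)
}

check_series <- function(series) {
  series <- tibble::as_tibble(series)
  if (!all(c("t", "value") %in% names(series))) {
    stop("series needs columns `t` and `value`", call. = FALSE)
  }
  if (is.unsorted(series$t, strictly = TRUE)) {
    stop("series times must be strictly increasing", call. = FALSE)
  }
  series
}

#' Fit a smooth curve to a sharpness time course
#'
#' Least-squares cubic smoothing spline fitted to the `(t, value)` points.
#' With `smoothing_factor = NULL` the amount of smoothing is chosen by
#' generalized cross-validation; `smoothing_factor = 0` interpolates; other
#' values are passed as the `spar` smoothing parameter of
#' [stats::smooth.spline()]. The fit reports the time of the curve minimum
#' and, when an event time is given, the first post-minimum time at which the
#' curve re-attains `recovery_frac` of the pre-event baseline.
#'
#' @param series tibble with strictly increasing `t` and `value`, at least 4
#'   points.
#' @param smoothing_factor `NULL` (GCV), `0` (interpolation) or a `spar`
#'   value in (0, 1.5].
#' @param event_time optional event timestamp; pre-event points define the
#'   baseline for recovery detection.
#' @param recovery_frac fraction of baseline that counts as recovered
#'   (default 0.9).
#' @return An object of class `timecourse_fit`; see [tidy.timecourse_fit()]
#'   and [glance.timecourse_fit()].
#' @export
fit_timecourse <- function(series, smoothing_factor = NULL, event_time = NULL,
                           recovery_frac = 0.9) {
  series <- check_series(series)
  n <- nrow(series)
  if (n < 4) stop("time-course fit needs at least 4 points, got ", n, call. = FALSE)

  rng <- diff(range(series$value))
  flat <- rng < 1e-12 * max(abs(series$value), 1)
  if (flat) {
    const <- mean(series$value)
    predict_fun <- function(t) rep(const, length(t))
    fitted <- predict_fun(series$t)
    sf_used <- NA_real_
  } else if (!is.null(smoothing_factor) && smoothing_factor == 0) {
    sp <- stats::splinefun(series$t, series$value, method = "natural")
    predict_fun <- function(t) sp(t)
    fitted <- predict_fun(series$t)
    sf_used <- 0
  } else {
    ss <- if (is.null(smoothing_factor)) {
      stats::smooth.spline(series$t, series$value, cv = FALSE)
    } else {
      stats::smooth.spline(series$t, series$value, spar = smoothing_factor)
    }
    predict_fun <- function(t) stats::predict(ss, t)$y
    fitted <- predict_fun(series$t)
    sf_used <- ss$spar
  }
  rmse <- sqrt(mean((fitted - series$value)^2))

  grid <- seq(min(series$t), max(series$t), length.out = max(512, 8 * n))
  curve <- predict_fun(grid)
  t_min <- if (flat) min(series$t) else grid[which.min(curve)]

  recovery_time <- NA_real_
  baseline <- NA_real_
  if (!is.null(event_time) && !flat) {
    pre <- series$value[series$t < event_time]
    if (length(pre) > 0) {
      baseline <- mean(pre)
      after_min <- grid > t_min
      ok <- after_min & curve >= recovery_frac * baseline
      if (any(ok)) recovery_time <- grid[which(ok)[1]]
    }
  }

  structure(
    list(series = series, predict = predict_fun, smoothing_factor = sf_used,
         rmse = rmse, t_min = t_min, recovery_time = recovery_time,
         baseline = baseline, event_time = event_time,
         recovery_frac = recovery_frac, flat = flat),
    class = "timecourse_fit"
  )
}

#' @export
print.timecourse_fit <- function(x, ...) {
  cat(sprintf("<timecourse_fit> %d points, rmse %.4g%s\n", nrow(x$series), x$rmse,
              if (x$flat) " [flat fit]" else ""))
  cat(sprintf("  minimum at t = %.4g; recovery (>= %g x baseline) at t = %s\n",
              x$t_min, x$recovery_frac,
              if (is.na(x$recovery_time)) "not reached" else format(x$recovery_time)))
  invisible(x)
}

#' Tidy a time-course fit
#'
#' @param x a `timecourse_fit`.
#' @param ... unused.
#' @return Tibble with `t`, `value`, `fitted`, `residual`.
#' @export
tidy.timecourse_fit <- function(x, ...) {
  dplyr::mutate(x$series, fitted = x$predict(.data$t),
                residual = .data$value - .data$fitted)
}

#' One-row summary of a time-course fit
#'
#' @param x a `timecourse_fit`.
#' @param ... unused.
#' @return Tibble with `n`, `rmse`, `smoothing_factor`, `t_min`,
#'   `recovery_time`, `baseline`, `flat`.
#' @export
glance.timecourse_fit <- function(x, ...) {
  tibble::tibble(n = nrow(x$series), rmse = x$rmse,
                 smoothing_factor = x$smoothing_factor, t_min = x$t_min,
                 recovery_time = x$recovery_time, baseline = x$baseline,
                 flat = x$flat)
}

#' Plot a sharpness time course and its fitted curve
#'
#' @param object a `timecourse_fit`.
#' @param ... unused.
#' @return A ggplot object: observed points, fitted curve, event time and
#'   fitted minimum marked.
#' @export
autoplot.timecourse_fit <- function(object, ...) {
  grid <- tibble::tibble(t = seq(min(object$series$t), max(object$series$t),
                                 length.out = 400))
  grid$fitted <- object$predict(grid$t)
  p <- ggplot2::ggplot(object$series, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted),
                       linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$t_min, colour = "steelblue") +
    ggplot2::labs(x = "time", y = "sharpness (mean |DoG| amplitude)") +
    ggplot2::theme_minimal()
  if (!is.null(object$event_time)) {
    p <- p + ggplot2::geom_vline(xintercept = object$event_time,
                                 linetype = "dotted")
  }
  p
}
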