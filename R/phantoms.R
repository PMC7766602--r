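# Synthetic phantoms with analytic ground truth: a dark hairpin capillary on
# a bright background under variable Gaussian blur, concentric CLSM papilla
# cross-sections, before/after effect pairs, and sharpness time courses.
# Every generator is bit-reproducible given its arguments and seed.

# Anti-aliased rendering: geometry is evaluated on a 4x supersampled grid of
# pixel-centre offsets and box-averaged down, so sub-pixel edge placement is
# smooth and blur-series monotonicity is robust.
supersample_grid <- function(rows, cols, factor = 4) {
  step <- 1 / factor
  off <- (seq_len(factor) - 0.5) * step - 0.5
  sr <- rep(seq_len(rows) - 1, each = factor) + rep(off, rows)
  sc <- rep(seq_len(cols) - 1, each = factor) + rep(off, cols)
  list(r = sr, c = sc, factor = factor)
}

downsample_box <- function(m, factor) {
  nr <- nrow(m) / factor; nc <- ncol(m) / factor
  # average factor x factor blocks
  m2 <- matrix(colMeans(matrix(m, nrow = factor)), nrow = nr, ncol = ncol(m))
  t(matrix(colMeans(matrix(t(m2), nrow = factor)), nrow = nc, ncol = nr))
}

add_noise <- function(m, noise_sigma, seed) {
  if (noise_sigma <= 0) return(m)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- m + matrix(stats::rnorm(length(m), sd = noise_sigma), nrow(m), ncol(m))
  pmin(pmax(out, 0), 1)
}

# Signed distance from points (r, c) to the hairpin centreline: two vertical
# limbs joined by a semicircular apex arc opening downward.
hairpin_distance <- function(r, c, apex_row, limb_length, separation, centre_col) {
  half <- separation / 2
  left <- centre_col - half
  right <- centre_col + half
  seg_dist <- function(cl) {
    dy <- pmax(0, apex_row - r, r - (apex_row + limb_length))
    sqrt((c - cl)^2 + dy^2)
  }
  d <- pmin(seg_dist(left), seg_dist(right))
  above <- r <= apex_row
  if (any(above)) {
    dc <- sqrt((c[above] - centre_col)^2 + (r[above] - apex_row)^2)
    d[above] <- pmin(d[above], abs(dc - half))
  }
  d
}

#' Generate a hairpin capillary phantom
#'
#' A dark U-shaped (hairpin) tube of given width on a uniform bright
#' background — the morphology of a first-row nailfold capillary — rendered
#' with 4x supersampled anti-aliased edges, then Gaussian-blurred and
#' degraded with seeded additive Gaussian noise (clipped to `[0, 1]`).
#' Increasing `blur_sigma` emulates the "foggy" capillary appearance of
#' epidermal edema. The ground-truth lumen mask is the pre-blur tube.
#'
#' @param frame_px `(rows, cols)` raster size.
#' @param limb_length_px,limb_separation_px,tube_width_px hairpin geometry in
#'   pixels.
#' @param contrast lumen-vs-background intensity gap in `[0, 1]`.
#' @param background background intensity (`contrast <= background <= 1`).
#' @param blur_sigma Gaussian blur applied after rendering, px.
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param seed integer seed for the noise.
#' @param pitch_um pixel pitch recorded on the image.
#' @return List with `image` ([calibrated_image()]), `mask` (ground-truth
#'   lumen [roi_mask()]) and `spec` (the arguments).
#' @export
#' @examples
#' ph <- make_capillary_phantom(blur_sigma = 3.8)
#' sharpness(ph$image)$sharpness
make_capillary_phantom <- function(frame_px = c(256, 256), limb_length_px = 120,
                                   limb_separation_px = 40, tube_width_px = 12,
                                   contrast = 0.5, background = 0.9,
                                   blur_sigma = 0, noise_sigma = 0, seed = 1,
                                   pitch_um = 1) {
  rows <- frame_px[1]; cols <- frame_px[2]
  if (!(contrast > 0 && contrast <= background && background <= 1)) {
    stop("need 0 < contrast <= background <= 1", call. = FALSE)
  }
  if (blur_sigma < 0) stop("`blur_sigma` must be >= 0", call. = FALSE)
  apex_row <- (rows - limb_length_px) / 2
  centre_col <- (cols - 1) / 2
  half_sep <- limb_separation_px / 2
  if (apex_row - half_sep - tube_width_px / 2 < 0 ||
      apex_row + limb_length_px + tube_width_px / 2 > rows - 1 ||
      centre_col + half_sep + tube_width_px / 2 > cols - 1) {
    stop("hairpin geometry does not fit inside the frame", call. = FALSE)
  }

  gs <- supersample_grid(rows, cols)
  R <- matrix(rep(gs$r, times = length(gs$c)), nrow = length(gs$r))
  C <- matrix(rep(gs$c, each = length(gs$r)), nrow = length(gs$r))
  dist <- hairpin_distance(as.vector(R), as.vector(C), apex_row,
                           limb_length_px, limb_separation_px, centre_col)
  inside <- matrix(as.numeric(dist <= tube_width_px / 2), nrow(R), ncol(R))
  coverage <- downsample_box(inside, gs$factor)
  raster <- background - contrast * coverage
  if (blur_sigma > 0) raster <- gaussian_blur(raster, blur_sigma)
  raster <- add_noise(raster, noise_sigma, seed)

  # ground truth at pixel centres (pre-blur tube)
  pr <- as.vector(row(raster)) - 1
  pc <- as.vector(col(raster)) - 1
  truth <- hairpin_distance(pr, pc, apex_row, limb_length_px,
                            limb_separation_px, centre_col) <= tube_width_px / 2
  spec <- list(frame_px = frame_px, limb_length_px = limb_length_px,
               limb_separation_px = limb_separation_px,
               tube_width_px = tube_width_px, contrast = contrast,
               background = background, blur_sigma = blur_sigma,
               noise_sigma = noise_sigma, seed = seed)
  list(
    image = calibrated_image(raster, pitch_um, "float",
                             origin_label = sprintf("capillary phantom (blur %.3g, seed %d)",
                                                    blur_sigma, seed)),
    mask = roi_mask("lumen_truth", matrix(truth, rows, cols)),
    spec = spec
  )
}

#' Generate a CLSM papilla cross-section phantom
#'
#' Concentric structures as seen in a confocal section through a dermal
#' papilla: a dark capillary lumen disk, a gray papilla annulus, a bright
#' melanin ring near the dermal-epidermal junction, and background. Edges are
#' anti-aliased by supersampling; exact ground-truth masks are taken at pixel
#' centres (and are pairwise disjoint by construction).
#'
#' @param frame_px `(rows, cols)` raster size.
#' @param lumen_radius_px,papilla_outer_radius_px,ring_outer_radius_px
#'   concentric radii, strictly increasing.
#' @param intensities named or positional vector
#'   `(lumen, papilla, ring, background)` in `[0, 1]` with
#'   `ring > papilla > lumen`.
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param seed integer seed.
#' @param pitch_um pixel pitch recorded on the image.
#' @param anti_alias supersample edges (default `TRUE`). With `FALSE` each
#'   pixel takes exactly the intensity of its ground-truth mask ("exact-mask"
#'   phantom), so region means reproduce the brightness formula to machine
#'   precision.
#' @return List with `image`, `segmentation` (ground-truth
#'   [papilla_segmentation()]) and `spec`.
#' @export
make_papilla_phantom <- function(frame_px = c(201, 201), lumen_radius_px = 20,
                                 papilla_outer_radius_px = 45,
                                 ring_outer_radius_px = 60,
                                 intensities = c(lumen = 0, papilla = 0.25,
                                                 ring = 1, background = 0.5),
                                 noise_sigma = 0, seed = 1, pitch_um = 1,
                                 anti_alias = TRUE) {
  r1 <- lumen_radius_px; r2 <- papilla_outer_radius_px; r3 <- ring_outer_radius_px
  if (!(r1 > 0 && r1 < r2 && r2 < r3)) {
    stop("radii must satisfy 0 < lumen < papilla_outer < ring_outer", call. = FALSE)
  }
  it <- unname(intensities)
  if (!(it[3] > it[2] && it[2] > it[1])) {
    stop("intensities must satisfy ring > papilla > lumen", call. = FALSE)
  }
  rows <- frame_px[1]; cols <- frame_px[2]
  if (2 * r3 >= min(rows, cols)) stop("rings do not fit inside the frame", call. = FALSE)
  cr <- (rows - 1) / 2; cc <- (cols - 1) / 2

  pr <- as.vector(row(matrix(0, rows, cols))) - 1
  pc <- as.vector(col(matrix(0, rows, cols))) - 1
  prad <- matrix(sqrt((pr - cr)^2 + (pc - cc)^2), rows, cols)
  if (anti_alias) {
    gs <- supersample_grid(rows, cols)
    R <- matrix(rep(gs$r, times = length(gs$c)), nrow = length(gs$r))
    C <- matrix(rep(gs$c, each = length(gs$r)), nrow = length(gs$r))
    rad <- sqrt((R - cr)^2 + (C - cc)^2)
    val <- matrix(it[4], nrow(rad), ncol(rad))
    val[rad <= r3] <- it[3]
    val[rad <= r2] <- it[2]
    val[rad <= r1] <- it[1]
    raster <- downsample_box(val, gs$factor)
  } else {
    raster <- matrix(it[4], rows, cols)
    raster[prad <= r3] <- it[3]
    raster[prad <= r2] <- it[2]
    raster[prad <= r1] <- it[1]
  }
  raster <- add_noise(raster, noise_sigma, seed)
  seg <- papilla_segmentation(
    papilla = prad > r1 & prad <= r2,
    ring = prad > r2 & prad <= r3,
    lumen = prad <= r1
  )
  spec <- list(frame_px = frame_px, lumen_radius_px = r1,
               papilla_outer_radius_px = r2, ring_outer_radius_px = r3,
               intensities = it, noise_sigma = noise_sigma, seed = seed,
               anti_alias = anti_alias)
  list(
    image = calibrated_image(raster, pitch_um, "float",
                             origin_label = sprintf("papilla phantom (seed %d)", seed)),
    segmentation = seg,
    spec = spec
  )
}

#' Generate a paired before/after effect dataset
#'
#' Emulates the three short-term edema effects used as calibration models:
#' capillary dilation under venous occlusion (`"occlusion_dilation"`, lumen
#' radius multiplied by `magnitude`, default 1.10), papilla hyporefractivity
#' after histamine (`"histamine_hyporefractivity"`, papilla intensity
#' multiplied by `1 - magnitude`, default drop fraction 0.20), and capillary
#' image blurring (`"histamine_blur"`, blur sigma raised from
#' `base_spec$blur_sigma` to `magnitude`). Per-pair jitter and pixel noise
#' are seeded; the manifest records the analytic ground truth of every pair.
#'
#' @param kind effect kind (see above).
#' @param magnitude effect size: radius factor > 1, drop fraction in (0, 1),
#'   or post-event blur sigma.
#' @param n_pairs number of before/after pairs.
#' @param seed integer seed.
#' @param base_spec named list overriding phantom defaults
#'   ([make_papilla_phantom()] arguments for the CLSM effects,
#'   [make_capillary_phantom()] arguments for `"histamine_blur"`).
#' @param radius_jitter_px standard deviation of per-pair lumen-radius jitter
#'   (CLSM effects).
#' @param noise_sigma pixel noise passed to the generators; the default 5%
#'   of unit scale emulates detector noise.
#' @return Tibble with one row per pair: `pair`, `before`, `after`
#'   (list columns of phantom objects) and ground-truth columns.
#' @export
make_effect_dataset <- function(kind = c("occlusion_dilation",
                                         "histamine_hyporefractivity",
                                         "histamine_blur"),
                                magnitude = NULL, n_pairs = 12, seed = 1,
                                base_spec = list(), radius_jitter_px = 1.5,
                                noise_sigma = 0.05) {
  kind <- match.arg(kind)
  magnitude <- magnitude %||% switch(kind,
    occlusion_dilation = 1.10,
    histamine_hyporefractivity = 0.20,
    histamine_blur = 8
  )
  ok <- switch(kind,
    occlusion_dilation = magnitude > 1 && magnitude < 2,
    histamine_hyporefractivity = magnitude > 0 && magnitude < 1,
    histamine_blur = magnitude > 0
  )
  if (!ok) stop("magnitude ", magnitude, " outside the documented range for ", kind,
                call. = FALSE)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pair_seeds <- sample.int(2^31 - 2, 2 * n_pairs)

  rows <- purrr::map(seq_len(n_pairs), function(i) {
    s_before <- pair_seeds[2 * i - 1]; s_after <- pair_seeds[2 * i]
    if (kind == "occlusion_dilation") {
      r0 <- (base_spec$lumen_radius_px %||% 20) + stats::rnorm(1, sd = radius_jitter_px)
      r0 <- max(5, r0)
      args <- utils::modifyList(list(noise_sigma = noise_sigma), base_spec)
      before <- do.call(make_papilla_phantom,
                        utils::modifyList(args, list(lumen_radius_px = r0, seed = s_before)))
      after <- do.call(make_papilla_phantom,
                       utils::modifyList(args, list(lumen_radius_px = r0 * magnitude,
                                                    seed = s_after)))
      tibble::tibble(pair = i, before = list(before), after = list(after),
                     true_radius_before = r0, true_radius_after = r0 * magnitude,
                     true_area_ratio = magnitude^2)
    } else if (kind == "histamine_hyporefractivity") {
      base_int <- base_spec$intensities %||% c(0, 0.25, 1, 0.5)
      args <- utils::modifyList(list(noise_sigma = noise_sigma), base_spec)
      before <- do.call(make_papilla_phantom,
                        utils::modifyList(args, list(intensities = base_int, seed = s_before)))
      int_after <- base_int
      int_after[2] <- base_int[2] * (1 - magnitude)
      after <- do.call(make_papilla_phantom,
                       utils::modifyList(args, list(intensities = int_after, seed = s_after)))
      tibble::tibble(pair = i, before = list(before), after = list(after),
                     true_brightness_ratio = 1 - magnitude)
    } else {
      args <- utils::modifyList(list(noise_sigma = noise_sigma), base_spec)
      sigma0 <- args$blur_sigma %||% 0.5
      before <- do.call(make_capillary_phantom,
                        utils::modifyList(args, list(blur_sigma = sigma0, seed = s_before)))
      after <- do.call(make_capillary_phantom,
                       utils::modifyList(args, list(blur_sigma = magnitude, seed = s_after)))
      tibble::tibble(pair = i, before = list(before), after = list(after),
                     blur_before = sigma0, blur_after = magnitude)
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "effect") <- list(kind = kind, magnitude = magnitude,
                              n_pairs = n_pairs, seed = seed,
                              noise_sigma = noise_sigma)
  out
}

#' Generate a sharpness time course with a step drop and recovery
#'
#' The model value is `baseline` before the event and
#' `baseline * (1/drop_factor + (1 - 1/drop_factor) * (1 - exp(-(t - t0)/tau)))`
#' after it: an immediate `drop_factor`-fold drop followed by exponential
#' return to baseline — the pattern of NVC sharpness after topical histamine.
#'
#' @param times sampling times (strictly increasing).
#' @param baseline pre-event sharpness level.
#' @param drop_factor instantaneous fold drop at the event (`> 1`; 2 = the
#'   twofold histamine drop).
#' @param recovery_tau exponential recovery time constant (same units as
#'   `times`).
#' @param event_time event timestamp.
#' @param noise_sigma Gaussian observation noise standard deviation.
#' @param seed integer seed.
#' @return List with `series` (noisy tibble `t`, `value`), `truth` (noiseless
#'   tibble) and `spec`.
#' @export
make_timecourse <- function(times = seq(-60, 240, by = 5), baseline = 1,
                            drop_factor = 2, recovery_tau = 60, event_time = 0,
                            noise_sigma = 0, seed = 1) {
  if (drop_factor <= 1) stop("`drop_factor` must be > 1", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing", call. = FALSE)
  floor_val <- baseline / drop_factor
  value <- ifelse(times < event_time, baseline,
                  floor_val + (baseline - floor_val) *
                    (1 - exp(-(times - event_time) / recovery_tau)))
  truth <- tibble::tibble(t = times, value = value)
  obs <- truth
  if (noise_sigma > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    obs$value <- pmax(0, obs$value + stats::rnorm(length(times), sd = noise_sigma))
  }
  list(series = obs, truth = truth,
       spec = list(baseline = baseline, drop_factor = drop_factor,
                   recovery_tau = recovery_tau, event_time = event_time,
                   noise_sigma = noise_sigma, seed = seed))
}
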