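# Synthetic-data generators: ROI label maps, cohorts of time-activity-curve
# parameters matching published group summaries, dynamic PET-like volumes,
# and colour scenes with ground-truth masks for the image modules.

#' Build a synthetic ROI label map
#'
#' Places ten disjoint cubic regions in a 3D grid: left/right prefrontal
#' cortex, striatum, hippocampus, thalamus and cerebellum. Left regions lie
#' entirely in the left half of the x axis, right regions in the right half.
#' The map is a stand-in for atlas-based delineation; it is synthetic and
#' makes no anatomical claim beyond laterality.
#'
#' @param dims Integer triple of grid dimensions, each >= 16.
#' @return A list of class `roi_label_map`: `map`, an integer 3D array with
#'   0 = background and labels 1-10; `rois`, a tibble mapping `label` to
#'   `roi` and `side`; `dims`.
#' @examples
#' lm <- make_label_map(c(32, 32, 32))
#' table(lm$map)
#' @export
make_label_map <- function(dims = c(64L, 64L, 64L)) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(!is.finite(dims)) || any(dims < 16L)) {
    stop_petloop("`dims` must be three integers, each >= 16.", "sizing")
  }
  structures <- c("prefrontal", "striatum", "hippocampus", "thalamus", "cerebellum")
  rois <- tibble::tibble(
    label = 1:10,
    roi = rep(structures, each = 2L),
    side = rep(c("left", "right"), 5L)
  )
  half <- max(1L, min(dims) %/% 16L)
  # One y slab per structure keeps the five structures disjoint; x quarter
  # centres keep each cube strictly within its hemisphere.
  slab <- dims[2] / 5
  ycent <- as.integer(round((seq_len(5) - 0.5) * slab))
  xcent <- c(left = as.integer(round(dims[1] * 0.25)),
             right = as.integer(round(dims[1] * 0.75)))
  zcent <- as.integer(round(dims[3] / 2))
  half_y <- min(half, as.integer(floor((slab - 1) / 2)))
  half_x <- min(half, as.integer(floor(dims[1] / 4)) - 1L)
  if (half_y < 0L || half_x < 0L) {
    stop_petloop("`dims` too small to place all regions.", "sizing")
  }

  map <- array(0L, dim = dims)
  centroids <- matrix(0L, nrow = 10L, ncol = 3L)
  for (i in seq_len(10L)) {
    s <- (i + 1L) %/% 2L
    cx <- xcent[[rois$side[i]]]
    cy <- ycent[s]
    xr <- max(1L, cx - half_x):min(dims[1], cx + half_x)
    yr <- max(1L, cy - half_y):min(dims[2], cy + half_y)
    zr <- max(1L, zcent - half):min(dims[3], zcent + half)
    if (any(map[xr, yr, zr] != 0L)) {
      stop_petloop("`dims` too small to place all regions disjointly.", "sizing")
    }
    map[xr, yr, zr] <- i
    centroids[i, ] <- c(cx, cy, zcent)
  }
  rois$centroid_x <- centroids[, 1]
  rois$centroid_y <- centroids[, 2]
  rois$centroid_z <- centroids[, 3]
  structure(list(map = map, rois = rois, dims = dims), class = "roi_label_map")
}

#' Evaluate a piecewise-linear time-activity curve
#'
#' The generator's curve model: linear rise from `start_value` at 0 min to
#' `peak_value` at `peak_time`, then linear fall to `end_value` at 150 min.
#' This is the simplest curve consistent with the endpoint-based rate
#' definitions, which it satisfies exactly.
#'
#' @param params One-row tibble (or list) with `start_value`, `peak_value`,
#'   `peak_time`, `end_value`.
#' @param times Times (minutes) at which to evaluate; default the 11-point grid.
#' @return Numeric vector of SUV values at `times`.
#' @export
eval_tac <- function(params, times = tac_times()) {
  s <- params$start_value; p <- params$peak_value
  tp <- params$peak_time; e <- params$end_value
  up <- if (tp > 0) s + (p - s) * pmin(times, tp) / tp else p
  dn <- if (tp < 150) p - (p - e) * pmax(times - tp, 0) / (150 - tp) else p
  ifelse(times <= tp, up, dn)
}

# Metrics implied by a set of curve parameters (vectorised over rows).
# Equal to the endpoint-rate definitions evaluated on the exact curve.
tac_params_metrics <- function(params) {
  pre <- ifelse(params$peak_time == 0, 0,
                (params$peak_value - params$start_value) / params$peak_time)
  post <- ifelse(params$peak_time == 150, 0,
                 (params$peak_value - params$end_value) / (150 - params$peak_time))
  tibble::tibble(
    peak_value = params$peak_value,
    peak_time = params$peak_time,
    pre_peak_rate = pre,
    post_peak_rate = post
  )
}

#' Random self-consistent curve parameters
#'
#' Draws curve parameter sets with start and end values between 0 and the
#' peak and the peak time on the interior of the 15-minute grid, so the
#' drawn rates and the curve-implied rates coincide. Used for round-trip
#' validation of the extraction pipeline.
#'
#' @param n Number of parameter sets.
#' @param seed Optional RNG seed.
#' @return Tibble with `start_value`, `peak_value`, `peak_time`, `end_value`.
#' @export
random_tac_params <- function(n, seed = NULL) {
  with_seed(seed, {
    peak <- stats::runif(n, 1.2, 3)
    tibble::tibble(
      start_value = stats::runif(n, 0, 0.8) * peak,
      peak_value = peak,
      peak_time = sample(seq(15, 135, by = 15), n, replace = TRUE),
      end_value = stats::runif(n, 0, 0.8) * peak
    )
  })
}

#' Simulate a cohort of per-subject curve parameters
#'
#' For each subject and region, the SUVmax peak, pre-peak uptake rate and
#' post-peak metabolic rate are drawn independently from normal
#' distributions with the target means and SDs. Start and end values are
#' then derived by inverting the endpoint-rate formulas at `peak_time`;
#' negative derived values are clipped to 0 with a warning (or rejected when
#' `clip_negative = FALSE`). The drawn metric values are retained unchanged:
#' they are the quantities the group summaries target.
#'
#' @param targets Tibble with columns `roi`, `side`, `metric`
#'   (`"peak"`, `"pre_rate"`, `"post_rate"`), `mean`, `sd`, and optionally
#'   `group`. Defaults to the published summaries, [reference_summaries()].
#' @param n_subjects Number of subjects (>= 1).
#' @param group When `targets` has a `group` column, which group to draw
#'   (e.g. `"healthy"` or `"gad"`).
#' @param peak_time Peak time in minutes on the 15-minute grid (default 60;
#'   no peak times are published, so this is a labelled stand-in).
#' @param seed Optional RNG seed; identical seeds give identical cohorts.
#' @param clip_negative Clip negative derived start/end values at 0
#'   (default) instead of failing.
#' @return Tibble with one row per subject x region: `subject`, `group`,
#'   `roi`, `side`, drawn `peak_value`, `pre_peak_rate`, `post_peak_rate`,
#'   and derived `peak_time`, `start_value`, `end_value`.
#' @export
sample_cohort <- function(targets = reference_summaries(), n_subjects = 20L,
                          group = "healthy", peak_time = 60, seed = NULL,
                          clip_negative = TRUE) {
  check_columns(targets, c("roi", "side", "metric", "mean", "sd"), "targets")
  if (any(targets$sd < 0)) stop_petloop("Target SDs must be >= 0.", "validation")
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) stop_petloop("`n_subjects` must be >= 1.", "validation")
  if (!peak_time %in% tac_times()) {
    stop_petloop("`peak_time` must lie on the 0-150 min 15-minute grid.", "validation")
  }
  if ("group" %in% names(targets)) {
    targets <- targets[targets$group == group, ]
    if (nrow(targets) == 0L) {
      stop_petloop(sprintf("No targets for group '%s'.", group), "validation")
    }
  }
  wide <- targets |>
    dplyr::select(dplyr::all_of(c("roi", "side", "metric", "mean", "sd"))) |>
    tidyr::pivot_wider(names_from = "metric", values_from = c("mean", "sd")) |>
    dplyr::arrange(.data$roi, .data$side)
  check_columns(
    wide, c("mean_peak", "mean_pre_rate", "mean_post_rate"), "targets (pivoted)"
  )

  cohort <- with_seed(seed, {
    grid <- tidyr::expand_grid(subject = seq_len(n_subjects), wide)
    grid$peak_value <- stats::rnorm(nrow(grid), grid$mean_peak, grid$sd_peak)
    grid$pre_peak_rate <- stats::rnorm(nrow(grid), grid$mean_pre_rate, grid$sd_pre_rate)
    grid$post_peak_rate <- stats::rnorm(nrow(grid), grid$mean_post_rate, grid$sd_post_rate)
    grid
  })
  cohort$peak_time <- peak_time
  cohort$start_value <- cohort$peak_value - cohort$pre_peak_rate * peak_time
  cohort$end_value <- cohort$peak_value - cohort$post_peak_rate * (150 - peak_time)
  neg <- cohort$start_value < 0 | cohort$end_value < 0
  if (any(neg)) {
    if (!clip_negative) {
      stop_petloop(
        "Targets imply negative SUV start/end values at this `peak_time`.",
        "validation"
      )
    }
    warning(sprintf(
      "%d of %d derived start/end values were negative and clipped to 0; drawn rates are kept.",
      sum(cohort$start_value < 0) + sum(cohort$end_value < 0), 2L * nrow(cohort)
    ), call. = FALSE)
    cohort$start_value <- pmax(cohort$start_value, 0)
    cohort$end_value <- pmax(cohort$end_value, 0)
  }
  cohort$group <- group
  cohort[, c("subject", "group", "roi", "side", "peak_value", "pre_peak_rate",
             "post_peak_rate", "peak_time", "start_value", "end_value")]
}

#' Long table of the drawn metric values of a cohort
#'
#' @param cohort Output of [sample_cohort()].
#' @return Long tibble `subject`, `group`, `roi`, `side`, `metric`, `value`
#'   with `metric` in `peak`, `pre_rate`, `post_rate` -- the shape expected
#'   by [compare_groups()].
#' @export
cohort_metrics <- function(cohort) {
  check_columns(cohort, c("subject", "roi", "side", "peak_value",
                          "pre_peak_rate", "post_peak_rate"), "cohort")
  cohort |>
    dplyr::select(dplyr::any_of(c("subject", "group", "roi", "side")),
                  peak = "peak_value", pre_rate = "pre_peak_rate",
                  post_rate = "post_peak_rate") |>
    tidyr::pivot_longer(c("peak", "pre_rate", "post_rate"),
                        names_to = "metric", values_to = "value")
}

#' Time-activity curves of a cohort
#'
#' Evaluates each subject/region parameter set on the 11-point grid.
#'
#' @param cohort Output of [sample_cohort()].
#' @return Long tibble `subject`, `group`, `roi`, `side`, `time`, `value`,
#'   `normalized = TRUE` (cohort targets are cerebellum-standardized values).
#' @export
cohort_curves <- function(cohort) {
  check_columns(cohort, c("subject", "roi", "side", "start_value",
                          "peak_value", "peak_time", "end_value"), "cohort")
  keys <- intersect(c("subject", "group", "roi", "side"), names(cohort))
  long <- tidyr::expand_grid(
    cohort[, c(keys, "start_value", "peak_value", "peak_time", "end_value")],
    time = tac_times()
  )
  rise <- ifelse(long$peak_time > 0,
                 long$start_value +
                   (long$peak_value - long$start_value) * long$time / long$peak_time,
                 long$peak_value)
  fall <- ifelse(long$peak_time < 150,
                 long$peak_value -
                   (long$peak_value - long$end_value) *
                     pmax(long$time - long$peak_time, 0) / (150 - long$peak_time),
                 long$peak_value)
  long$value <- ifelse(long$time <= long$peak_time, rise, fall)
  long$normalized <- TRUE
  long[, c(keys, "time", "value", "normalized")]
}

#' Render a dynamic PET-like volume
#'
#' Paints one subject's curves into a 4D voxel grid. In each region one
#' designated voxel (the region centroid) carries the exact curve value per
#' frame, other region voxels carry a strictly lower fraction of it, the
#' cerebellum is held constant over time, and background voxels receive
#' additive Gaussian noise truncated at 0.
#'
#' @param params Tibble of curve parameters covering all 8 loop regions
#'   (columns `roi`, `side`, `start_value`, `peak_value`, `peak_time`,
#'   `end_value`), e.g. one subject of [sample_cohort()].
#' @param labels Label map from [make_label_map()].
#' @param noise_sd SD of background noise (SUV); 0 for a noiseless phantom.
#' @param cereb_value Constant cerebellar SUVmax painted in both cerebellar
#'   regions (default 1, so standardized curves equal painted curves).
#' @param interior_frac Fraction (< 1) of the curve value painted in
#'   non-designated region voxels.
#' @param seed Optional RNG seed for the noise.
#' @return 4D numeric array (x, y, z, 11).
#' @export
render_dynamic_volume <- function(params, labels, noise_sd = 0,
                                  cereb_value = 1, interior_frac = 0.7,
                                  seed = NULL) {
  check_columns(params, c("roi", "side", "start_value", "peak_value",
                          "peak_time", "end_value"), "params")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(cereb_value, "cereb_value", lower = 0, strict = TRUE)
  if (interior_frac >= 1 || interior_frac < 0) {
    stop_petloop("`interior_frac` must be in [0, 1).", "validation")
  }
  need <- loop_rois()
  have <- dplyr::semi_join(need, params, by = c("roi", "side"))
  if (nrow(have) < nrow(need)) {
    miss <- dplyr::anti_join(need, params, by = c("roi", "side"))
    stop_petloop(
      paste0("Missing curve parameters for: ",
             paste(miss$side, miss$roi, collapse = ", "), "."),
      "configuration"
    )
  }

  dims <- labels$dims
  nt <- 11L
  vol <- array(0, dim = c(dims, nt))
  if (noise_sd > 0) {
    vol[] <- with_seed(seed, pmax(stats::rnorm(length(vol), 0, noise_sd), 0))
  }

  for (i in seq_len(nrow(labels$rois))) {
    info <- labels$rois[i, ]
    vox <- which(labels$map == info$label)
    centroid <- matrix(c(info$centroid_x, info$centroid_y, info$centroid_z),
                       nrow = 1L)
    cent_flat <- centroid[1] + (centroid[2] - 1L) * dims[1] +
      (centroid[3] - 1L) * dims[1] * dims[2]
    if (info$roi == "cerebellum") {
      tacv <- rep(cereb_value, nt)
    } else {
      p <- params[params$roi == info$roi & params$side == info$side, ][1, ]
      tacv <- eval_tac(p, tac_times())
    }
    for (f in seq_len(nt)) {
      off <- (f - 1L) * prod(dims)
      vol[vox + off] <- interior_frac * tacv[f]
      vol[cent_flat + off] <- tacv[f]
    }
  }
  vol
}

#' Specify a synthetic colour scene
#'
#' @param width,height Image dimensions in pixels.
#' @param shape Foreground shape: `"disc"` or `"square"`.
#' @param center Foreground centre (x, y) in pixels; default image centre.
#' @param radius Foreground radius (half-side for squares), strictly inside
#'   the image bounds.
#' @param fg,bg Foreground and background RGB triples in \[0, 1\]; must differ.
#' @param noise_sd SD of additive Gaussian pixel noise (clipped to \[0, 1\]).
#' @param seed RNG seed for the noise.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(width = 64L, height = 64L, shape = c("disc", "square"),
                       center = NULL, radius = NULL,
                       fg = c(0.9, 0.2, 0.2), bg = c(0.15, 0.25, 0.6),
                       noise_sd = 0, seed = NULL) {
  shape <- match.arg(shape)
  width <- as.integer(width); height <- as.integer(height)
  if (width < 8L || height < 8L) stop_petloop("Scene must be at least 8x8.", "validation")
  if (is.null(center)) center <- c(width / 2, height / 2)
  if (is.null(radius)) radius <- round(min(width, height) / 4)
  if (center[1] - radius < 1 || center[1] + radius > width ||
      center[2] - radius < 1 || center[2] + radius > height) {
    stop_petloop("Foreground must lie strictly inside the image bounds.", "validation")
  }
  if (max(abs(fg - bg)) == 0) {
    stop_petloop("Foreground and background colours must differ.", "validation")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(width = width, height = height, shape = shape, center = center,
         radius = radius, fg = fg, bg = bg, noise_sd = noise_sd, seed = seed),
    class = "scene_spec"
  )
}

#' Render a colour scene with its ground-truth mask
#'
#' A contrasting foreground shape on a (optionally noisy) background; the
#' returned mask marks foreground pixels exactly, providing ground truth for
#' the saliency and segmentation stages.
#'
#' @param spec A [scene_spec()].
#' @return List with `image` (height x width x 3 array in \[0, 1\]) and
#'   `mask` (logical height x width matrix).
#' @export
make_color_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  xs <- matrix(rep(seq_len(spec$width), each = spec$height),
               nrow = spec$height)
  ys <- matrix(rep(seq_len(spec$height), times = spec$width),
               nrow = spec$height)
  mask <- if (spec$shape == "disc") {
    (xs - spec$center[1])^2 + (ys - spec$center[2])^2 <= spec$radius^2
  } else {
    abs(xs - spec$center[1]) <= spec$radius & abs(ys - spec$center[2]) <= spec$radius
  }
  img <- array(0, dim = c(spec$height, spec$width, 3L))
  for (ch in 1:3) {
    plane <- matrix(spec$bg[ch], spec$height, spec$width)
    plane[mask] <- spec$fg[ch]
    img[, , ch] <- plane
  }
  if (spec$noise_sd > 0) {
    img <- with_seed(spec$seed, {
      img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
    })
    img <- pmin(pmax(img, 0), 1)
  }
  list(image = img, mask = mask)
}
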