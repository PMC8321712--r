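# Time-activity-curve analysis: SUVmax extraction from dynamic volumes,
# cerebellar standardization, and the three endpoint-based uptake metrics.

#' Extract an SUVmax time-activity curve from a dynamic volume
#'
#' For each of the 11 frames the maximum voxel value inside the region is
#' taken as SUVmax. The measurement is repeated `repeats` times (default 3,
#' mirroring triplicate manual measurement) and averaged; an optional random
#' ROI jitter of up to `jitter` voxels per axis perturbs the region between
#' repeats. With `jitter = 0` the repeats are identical and the average
#' equals a single measurement.
#'
#' @param vol 4D numeric array (x, y, z, frame) with 11 frames, as produced
#'   by [render_dynamic_volume()] or read from a 4D NIfTI file.
#' @param labels A label map from [make_label_map()] (list with `map` and
#'   `rois`).
#' @param roi,side Region name and side, e.g. `"prefrontal"`, `"left"`.
#' @param repeats Number of repeated measurements to average.
#' @param jitter Maximum ROI translation (voxels, per axis) applied
#'   independently per repeat. `0` disables jitter.
#' @param seed Optional seed controlling the jitter draws.
#' @return A tibble with columns `roi`, `side`, `time`, `value`,
#'   `normalized` (`FALSE`).
#' @seealso [normalize_to_cerebellum()], [uptake_metrics()]
#' @export
extract_suvmax_curve <- function(vol, labels, roi, side, repeats = 3L,
                                 jitter = 0L, seed = NULL) {
  if (length(dim(vol)) != 4L) {
    stop_petloop("`vol` must be a 4D array (x, y, z, frame).", "validation")
  }
  if (dim(vol)[4] != 11L) {
    stop_petloop(
      sprintf("`vol` must have 11 frames; got %d.", dim(vol)[4]),
      "validation"
    )
  }
  lab <- labels$rois[labels$rois$roi == roi & labels$rois$side == side, ]
  if (nrow(lab) != 1L) {
    stop_petloop(
      sprintf("Region '%s %s' not present in the label map.", side, roi),
      "lookup"
    )
  }
  idx <- which(labels$map == lab$label, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop_petloop(sprintf("Region '%s %s' is empty.", side, roi), "lookup")
  }
  repeats <- as.integer(repeats)
  if (repeats < 1L) stop_petloop("`repeats` must be >= 1.", "validation")

  dims <- dim(vol)[1:3]
  curves <- with_seed(seed, {
    vapply(seq_len(repeats), function(r) {
      shift <- if (jitter > 0) {
        sample(seq(-jitter, jitter), 3L, replace = TRUE)
      } else {
        c(0L, 0L, 0L)
      }
      pts <- sweep(idx, 2L, shift, "+")
      keep <- pts[, 1] >= 1 & pts[, 1] <= dims[1] &
        pts[, 2] >= 1 & pts[, 2] <= dims[2] &
        pts[, 3] >= 1 & pts[, 3] <= dims[3]
      pts <- pts[keep, , drop = FALSE]
      if (nrow(pts) == 0L) pts <- idx
      vapply(1:11, function(f) {
        max(vol[cbind(pts, f)])
      }, numeric(1))
    }, numeric(11))
  })

  tibble::tibble(
    roi = roi, side = side,
    time = tac_times(),
    value = rowMeans(curves),
    normalized = FALSE
  )
}

#' Standardize a curve to the ipsilateral cerebellum
#'
#' Divides the region's SUVmax by the same-side cerebellar SUVmax at each of
#' the 11 time points, treating the cerebellum as a metabolically stable
#' reference region.
#'
#' @param curve Tibble from [extract_suvmax_curve()] (columns `time`,
#'   `value`, `side`).
#' @param cereb Same-side cerebellar curve on the same time grid, with
#'   strictly positive values.
#' @return `curve` with `value` replaced by the pointwise ratio and
#'   `normalized = TRUE`.
#' @export
normalize_to_cerebellum <- function(curve, cereb) {
  check_columns(curve, c("time", "value"), "curve")
  check_columns(cereb, c("time", "value"), "cereb")
  if ("side" %in% names(curve) && "side" %in% names(cereb) &&
      !all(curve$side == cereb$side)) {
    stop_petloop("Curve and cerebellar reference must be the same side.", "validation")
  }
  if (!isTRUE(all.equal(curve$time, cereb$time))) {
    stop_petloop("Curve and cerebellar reference must share one time grid.", "validation")
  }
  if (any(cereb$value <= 0)) {
    stop_petloop("Cerebellar SUVmax must be strictly positive.", "division")
  }
  out <- curve
  out$value <- curve$value / cereb$value
  out$normalized <- TRUE
  out
}

#' Peak and rate metrics of a time-activity curve
#'
#' Computes the three summary metrics of an 11-point SUVmax curve:
#' \describe{
#'   \item{peak_value}{the maximum SUVmax over all time points;}
#'   \item{pre_peak_rate}{(peak - value at 0 min) / peak time;}
#'   \item{post_peak_rate}{(peak - value at 150 min) / (150 - peak time).}
#' }
#' Ties for the maximum are broken toward the earliest time point. When the
#' peak falls at 0 min the pre-peak rate is defined as 0; when it falls at
#' 150 min the post-peak rate is defined as 0.
#'
#' @param curve Tibble with columns `time` (the 11-point grid) and `value`.
#' @return A one-row tibble: `peak_value`, `peak_time`, `pre_peak_rate`,
#'   `post_peak_rate`. Any `roi`/`side` columns present are carried through.
#' @export
uptake_metrics <- function(curve) {
  check_columns(curve, c("time", "value"), "curve")
  if (nrow(curve) != 11L || !isTRUE(all.equal(curve$time, tac_times()))) {
    stop_petloop("`curve` must hold the 11-point 0-150 min grid.", "validation")
  }
  i <- which.max(curve$value)   # earliest index on ties
  peak <- curve$value[i]
  pt <- curve$time[i]
  pre <- if (pt == 0) 0 else (peak - curve$value[1]) / pt
  post <- if (pt == 150) 0 else (peak - curve$value[11]) / (150 - pt)
  keep <- intersect(c("subject", "group", "roi", "side"), names(curve))
  out <- tibble::tibble(
    peak_value = peak, peak_time = pt,
    pre_peak_rate = pre, post_peak_rate = post
  )
  if (length(keep) > 0) {
    out <- dplyr::bind_cols(dplyr::distinct(curve[, keep, drop = FALSE]), out)
  }
  out
}

#' Uptake metrics for a table of curves
#'
#' Applies [uptake_metrics()] to each curve in a long table of per-subject,
#' per-region time-activity curves.
#'
#' @param curves Long tibble with columns `time`, `value` and any of
#'   `subject`, `group`, `roi`, `side` identifying the curves.
#' @return One row per curve with the identifying columns and the four
#'   metric columns.
#' @export
uptake_metrics_all <- function(curves) {
  check_columns(curves, c("time", "value"), "curves")
  keys <- intersect(c("subject", "group", "roi", "side"), names(curves))
  if (length(keys) == 0L) return(uptake_metrics(curves))
  curves |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(~ uptake_metrics(.x)) |>
    dplyr::ungroup()
}

#' Injected tracer activity from body weight
#'
#' Total injected activity follows the weight-based protocol
#' body weight (kg) x 0.1 mCi.
#'
#' @param weight_kg Body weight in kilograms (> 0).
#' @return Activity in mCi.
#' @examples
#' injection_dose(60) # 6 mCi
#' @export
injection_dose <- function(weight_kg) {
  check_number(weight_kg, "weight_kg", lower = 0, strict = TRUE)
  weight_kg * 0.1
}
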