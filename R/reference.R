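#' Published group summaries for the emotional-control loop
#'
#' Returns the per-region, per-metric group summaries (mean, SD, n) reported
#' for 20 healthy controls and 20 GAD patients: cerebellum-standardized
#' SUVmax peak uptake, average pre-peak uptake rate, and average post-peak
#' metabolic rate in the bilateral prefrontal cortex, striatum, hippocampus
#' and thalamus. The printed |t| statistic accompanying each cell pair is
#' carried in `t_printed` so reproduction of the published comparison can be
#' checked cell by cell.
#'
#' These summaries are the default simulation targets for [sample_cohort()]
#' and the default input of [compare_summaries()].
#'
#' @return A tibble with one row per region x side x metric x group and
#'   columns `metric` (`"peak"`, `"pre_rate"`, `"post_rate"`), `roi`, `side`,
#'   `group` (`"healthy"` or `"gad"`), `mean`, `sd`, `n`, and `t_printed`
#'   (the published |t| for that cell pair, repeated on both group rows).
#' @examples
#' reference_summaries()
#' @export
reference_summaries <- function() {
  roi <- rep(rep(c("prefrontal", "striatum", "hippocampus", "thalamus"), each = 2L), 3L)
  side <- rep(c("left", "right"), 12L)
  metric <- rep(c("peak", "pre_rate", "post_rate"), each = 8L)

  healthy_mean <- c(
    2.41, 2.52, 1.95, 1.97, 1.65, 1.63, 1.71, 1.69,      # peak
    0.34, 0.24, 0.14, 0.09, 0.12, 0.11, 0.21, 0.08,      # pre-peak rate
    0.07, 0.05, 0.08, 0.12, 0.09, 0.11, 0.05, 0.10       # post-peak rate
  )
  healthy_sd <- c(
    0.21, 0.24, 0.17, 0.22, 0.20, 0.19, 0.17, 0.15,
    0.02, 0.02, 0.01, 0.01, 0.02, 0.02, 0.02, 0.01,
    0.01, 0.02, 0.01, 0.02, 0.01, 0.02, 0.01, 0.01
  )
  gad_mean <- c(
    2.04, 2.06, 1.41, 1.97, 1.16, 1.63, 2.13, 2.08,
    0.15, 0.15, 0.09, 0.09, 0.06, 0.11, 0.45, 0.14,
    0.10, 0.12, 0.03, 0.11, 0.05, 0.10, 0.08, 0.09
  )
  gad_sd <- c(
    0.20, 0.18, 0.19, 0.18, 0.15, 0.16, 0.24, 0.20,
    0.01, 0.02, 0.01, 0.01, 0.01, 0.01, 0.03, 0.01,
    0.01, 0.02, 0.01, 0.02, 0.01, 0.01, 0.01, 0.02
  )
  t_printed <- c(
    5.71, 6.86, 9.47, 0, 8.77, 0, 6.39, 6.98,
    38, 14.23, 15.81, 0, 12, 0, 29.77, 18.97,
    9.49, 11.07, 15.81, 1.58, 12.65, 2.1, 9.49, 2.1
  )

  cell <- tibble::tibble(
    metric = metric, roi = roi, side = side,
    healthy_mean = healthy_mean, healthy_sd = healthy_sd,
    gad_mean = gad_mean, gad_sd = gad_sd,
    t_printed = t_printed
  )
  long <- tidyr::pivot_longer(
    cell,
    cols = c("healthy_mean", "healthy_sd", "gad_mean", "gad_sd"),
    names_to = c("group", ".value"),
    names_sep = "_"
  )
  long$n <- 20L
  long[, c("metric", "roi", "side", "group", "mean", "sd", "n", "t_printed")]
}

#' The eight loop regions analysed
#'
#' @return A tibble with columns `roi` and `side` listing the bilateral
#'   prefrontal cortex, striatum, hippocampus and thalamus.
#' @export
loop_rois <- function() {
  tibble::tibble(
    roi = rep(c("prefrontal", "striatum", "hippocampus", "thalamus"), each = 2L),
    side = rep(c("left", "right"), 4L)
  )
}

#' Acquisition time grid of the dynamic scan
#'
#' Eleven frames at 15-minute intervals spanning 0-150 minutes.
#'
#' @return Numeric vector of length 11: 0, 15, ..., 150 (minutes).
#' @export
tac_times <- function() seq(0, 150, by = 15)
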