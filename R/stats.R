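# Group comparison: pooled two-sample t from summary statistics, the
# 8-region x 3-metric comparison table, and qualitative dynamics labels.

#' Pooled two-sample t-test from group summaries
#'
#' Student's t with a pooled variance estimate, computed directly from
#' (mean, SD, n) of each group:
#' \deqn{t = \frac{m_1 - m_2}{s_p\sqrt{1/n_1 + 1/n_2}}, \quad
#'       s_p^2 = \frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2},}
#' with df = n1 + n2 - 2 and a two-sided p-value. A Welch variant is
#' available via `var_equal = FALSE`. With zero pooled variance the t is 0
#' for equal means and +/-Inf otherwise (p = 1 resp. 0).
#'
#' All arguments are vectorised.
#'
#' @param mean1,sd1,n1 Summary of group 1.
#' @param mean2,sd2,n2 Summary of group 2.
#' @param var_equal Use the pooled-variance (Student) form; the default, and
#'   the form that reproduces published table statistics from their printed
#'   summaries.
#' @return Tibble with columns `t` (signed, group1 - group2), `t_abs`
#'   (|t| rounded to 2 decimals, the form tables print), `df`, `p`.
#' @examples
#' two_sample_t(2.41, 0.21, 20, 2.04, 0.20, 20) # |t| = 5.71
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2, var_equal = TRUE) {
  if (any(n1 < 2) || any(n2 < 2)) {
    stop_petloop("Both groups need n >= 2.", "validation")
  }
  if (any(sd1 < 0) || any(sd2 < 0)) {
    stop_petloop("SDs must be >= 0.", "validation")
  }
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    df <- (sd1^2 / n1 + sd2^2 / n2)^2 /
      ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
    df[se == 0] <- n1 + n2 - 2
  }
  diff <- mean1 - mean2
  t <- ifelse(se == 0, ifelse(diff == 0, 0, Inf * sign(diff)), diff / se)
  p <- ifelse(is.infinite(t), 0, 2 * stats::pt(-abs(t), df))
  tibble::tibble(t = t, t_abs = round(abs(t), 2), df = df, p = p)
}

#' Comparison table from published-style group summaries
#'
#' Runs the pooled two-sample t-test on every region x metric cell of a
#' summary table holding both groups, reproducing the layout of the
#' published peak / pre-peak-rate / post-peak-rate tables.
#'
#' @param summaries Tibble in the shape of [reference_summaries()]: columns
#'   `metric`, `roi`, `side`, `group`, `mean`, `sd`, `n` (plus optional
#'   `t_printed`, carried through).
#' @param groups Length-2 character: reference group first, comparison group
#'   second. The signed t is comparison minus reference, so a positive t
#'   means the comparison group is higher.
#' @param alpha Significance level for the `significant` flag.
#' @return A `loop_comparison` tibble: one row per region x side x metric
#'   with per-group mean/sd/n, `t` (signed), `t_abs`, `df`, `p`,
#'   `significant`.
#' @export
compare_summaries <- function(summaries = reference_summaries(),
                              groups = c("healthy", "gad"), alpha = 0.05) {
  check_columns(summaries, c("metric", "roi", "side", "group", "mean", "sd", "n"),
                "summaries")
  if (!all(groups %in% summaries$group)) {
    stop_petloop("Both `groups` must appear in `summaries$group`.", "validation")
  }
  keep <- intersect(c("metric", "roi", "side", "group", "mean", "sd", "n", "t_printed"),
                    names(summaries))
  wide <- summaries[, keep] |>
    dplyr::filter(.data$group %in% groups) |>
    dplyr::mutate(group = ifelse(.data$group == groups[1], "g1", "g2")) |>
    tidyr::pivot_wider(names_from = "group", values_from = c("mean", "sd", "n"))
  res <- two_sample_t(wide$mean_g2, wide$sd_g2, wide$n_g2,
                      wide$mean_g1, wide$sd_g1, wide$n_g1)
  out <- dplyr::bind_cols(wide, res)
  out$significant <- out$p < alpha
  names(out) <- sub("_g1$", paste0("_", groups[1]), names(out))
  names(out) <- sub("_g2$", paste0("_", groups[2]), names(out))
  attr(out, "groups") <- groups
  attr(out, "alpha") <- alpha
  class(out) <- c("loop_comparison", class(out))
  out
}

#' Compare two simulated or measured cohorts
#'
#' Summarises per-subject metric values of both cohorts into (mean, SD, n)
#' per region x metric and applies the pooled two-sample t-test, yielding
#' the 24-row comparison table (8 regions x 3 metrics).
#'
#' @param reference,comparison Long metric tables (e.g. [cohort_metrics()]
#'   or pivoted [uptake_metrics_all()] output) with columns `subject`,
#'   `roi`, `side`, `metric`, `value`. Both must cover the same 8 loop
#'   regions and 3 metrics.
#' @param groups Labels for the two cohorts (reference first).
#' @param alpha Significance level.
#' @return A `loop_comparison` tibble; see [compare_summaries()].
#' @export
compare_groups <- function(reference, comparison,
                           groups = c("healthy", "gad"), alpha = 0.05) {
  summarise_one <- function(df, label) {
    check_columns(df, c("subject", "roi", "side", "metric", "value"), label)
    need <- tidyr::expand_grid(loop_rois(), metric = c("peak", "pre_rate", "post_rate"))
    have <- dplyr::distinct(df[, c("roi", "side", "metric")])
    if (nrow(dplyr::anti_join(need, have, by = c("roi", "side", "metric"))) > 0) {
      stop_petloop(
        sprintf("`%s` must cover all 8 loop regions x 3 metrics.", label),
        "validation"
      )
    }
    df |>
      dplyr::group_by(.data$metric, .data$roi, .data$side) |>
      dplyr::summarise(
        mean = mean(.data$value), sd = stats::sd(.data$value),
        n = dplyr::n_distinct(.data$subject), .groups = "drop"
      )
  }
  s1 <- summarise_one(reference, "reference");  s1$group <- groups[1]
  s2 <- summarise_one(comparison, "comparison"); s2$group <- groups[2]
  compare_summaries(dplyr::bind_rows(s1, s2), groups = groups, alpha = alpha)
}

#' Qualitative dynamics labels per region
#'
#' Translates the three comparison rows of each region into the verbal
#' uptake-dynamics pattern: a significantly lower (higher) pre-peak rate in
#' the comparison group reads "slow-in" ("fast-in"); a significantly higher
#' (lower) post-peak rate reads "fast-out" ("slow-out"); a significantly
#' lower (higher) peak reads total "decreased" ("increased"). Non-significant
#' rows give `"none"`.
#'
#' @param comparison A `loop_comparison` from [compare_summaries()] or
#'   [compare_groups()] covering the metrics `peak`, `pre_rate`,
#'   `post_rate`.
#' @return Tibble with one row per region x side: `roi`, `side`,
#'   `in_label`, `out_label`, `total_label`.
#' @examples
#' classify_dynamics(compare_summaries())
#' @export
classify_dynamics <- function(comparison) {
  check_columns(comparison, c("metric", "roi", "side", "t", "significant"),
                "comparison")
  if (!all(c("peak", "pre_rate", "post_rate") %in% comparison$metric)) {
    stop_petloop(
      "`comparison` must contain the metrics peak, pre_rate and post_rate.",
      "validation"
    )
  }
  lab <- function(sig, t, neg, pos) {
    dplyr::case_when(sig & t < 0 ~ neg, sig & t > 0 ~ pos, .default = "none")
  }
  comparison |>
    tibble::as_tibble() |>
    dplyr::select(dplyr::all_of(c("metric", "roi", "side", "t", "significant"))) |>
    tidyr::pivot_wider(names_from = "metric", values_from = c("t", "significant")) |>
    dplyr::mutate(
      in_label = lab(.data$significant_pre_rate, .data$t_pre_rate,
                     "slow-in", "fast-in"),
      out_label = lab(.data$significant_post_rate, .data$t_post_rate,
                      "slow-out", "fast-out"),
      total_label = lab(.data$significant_peak, .data$t_peak,
                        "decreased", "increased")
    ) |>
    dplyr::select(dplyr::all_of(c("roi", "side", "in_label", "out_label",
                                  "total_label")))
}

#' Region-level significance
#'
#' A region is flagged significant when all three of its metrics (peak,
#' pre-peak rate, post-peak rate) are individually significant -- the
#' region-level reading used for qualitative pattern checks.
#'
#' @param comparison A `loop_comparison`.
#' @return Tibble `roi`, `side`, `roi_significant`.
#' @export
roi_significance <- function(comparison) {
  check_columns(comparison, c("metric", "roi", "side", "significant"), "comparison")
  comparison |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$roi, .data$side) |>
    dplyr::summarise(roi_significant = all(.data$significant), .groups = "drop")
}

#' @export
tidy.loop_comparison <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "loop_comparison")
  tibble::as_tibble(out)
}

#' @export
glance.loop_comparison <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha"),
    groups = paste(attr(x, "groups"), collapse = " vs ")
  )
}

#' @export
print.loop_comparison <- function(x, ...) {
  grp <- attr(x, "groups")
  cat(sprintf("Loop comparison: %s vs %s (alpha = %g)\n",
              grp[1], grp[2], attr(x, "alpha")))
  print(tidy(x), ...)
  invisible(x)
}

#' Plot a comparison table
#'
#' Bar chart of |t| per region and metric with the significance threshold
#' marked.
#'
#' @param object A `loop_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loop_comparison <- function(object, ...) {
  df <- tidy(object)
  df$region <- paste(df$side, df$roi)
  crit <- stats::qt(1 - attr(object, "alpha") / 2, df = df$df[1])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$t_abs,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = crit, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), ncol = 1) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "|t|", fill = "p < alpha") +
    ggplot2::theme_minimal()
}

#' Plot group time-activity curves
#'
#' Mean curve per group with a +/-1 SD ribbon over the 11 time points, one
#' panel per region.
#'
#' @param curves Long tibble with columns `group`, `roi`, `side`, `time`,
#'   `value` (e.g. [cohort_curves()] output).
#' @param rois Optional character vector restricting the regions plotted
#'   (matched against `roi`).
#' @return A ggplot object.
#' @export
plot_tac <- function(curves, rois = NULL) {
  check_columns(curves, c("group", "roi", "side", "time", "value"), "curves")
  if (!is.null(rois)) curves <- curves[curves$roi %in% rois, ]
  if (nrow(curves) == 0) stop_petloop("No curves to plot.", "validation")
  band <- curves |>
    dplyr::group_by(.data$group, .data$roi, .data$side, .data$time) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = ifelse(dplyr::n() > 1, stats::sd(.data$value), 0),
      .groups = "drop"
    )
  band$region <- paste(band$side, band$roi)
  ggplot2::ggplot(band, ggplot2::aes(x = .data$time, y = .data$mean,
                                     colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$region), scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "standardized SUVmax",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
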