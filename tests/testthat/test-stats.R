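test_that("pooled t from summaries equals t.test on raw samples", {
  set.seed(41)
  for (i in 1:20) {
    m1 <- runif(1, 0, 3); s1 <- runif(1, 0.05, 0.5); n1 <- sample(5:40, 1)
    m2 <- runif(1, 0, 3); s2 <- runif(1, 0.05, 0.5); n2 <- sample(5:40, 1)
    x <- exact_sample(m1, s1, n1)
    y <- exact_sample(m2, s2, n2)
    ours <- two_sample_t(m1, s1, n1, m2, s2, n2)
    ref <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    # Welch variant against its own reference
    welch <- two_sample_t(m1, s1, n1, m2, s2, n2, var_equal = FALSE)
    refw <- stats::t.test(x, y, var.equal = FALSE)
    expect_equal(welch$t, unname(refw$statistic), tolerance = 1e-10)
    expect_equal(welch$p, refw$p.value, tolerance = 1e-10)
  }
})

test_that("pooled t edge cases and symmetry", {
  expect_equal(two_sample_t(1.5, 0.2, 20, 1.5, 0.2, 20)$t, 0)
  z <- two_sample_t(2, 0, 20, 1, 0, 20)
  expect_true(is.infinite(z$t) && z$t > 0)
  expect_equal(z$p, 0)
  a <- two_sample_t(2.41, 0.21, 20, 2.04, 0.20, 20)
  b <- two_sample_t(2.04, 0.20, 20, 2.41, 0.21, 20)
  expect_equal(a$t, -b$t)
  expect_equal(a$t_abs, 5.71)
  expect_error(two_sample_t(1, 0.1, 1, 1, 0.1, 20), class = "petloop_validation")
})

test_that("published summaries reproduce the printed t values", {
  cmp <- compare_summaries()
  expect_s3_class(cmp, "loop_comparison")
  expect_equal(nrow(cmp), 24)
  match <- abs(cmp$t_abs - cmp$t_printed) < 0.005
  expect_gte(sum(match), 22)
  # the two known off-by-rounding cells are both post-peak right-side rows
  off <- tidy(cmp)[!match, ]
  expect_true(all(off$metric == "post_rate" & off$side == "right"))
  expect_equal(sort(off$roi), c("hippocampus", "thalamus"))
  expect_true(all(off$t_abs == 2))
  # significance flag is exactly p < alpha at df = 38
  expect_equal(cmp$significant, cmp$p < 0.05)
  expect_true(all(cmp$df == 38))
})

test_that("cohort comparison covers 24 cells and is reproducible", {
  tg <- consistent_targets()
  h <- sample_cohort(tg, 15, group = "healthy", seed = 51)
  g <- sample_cohort(tg, 15, group = "gad", seed = 52)
  cmp <- compare_groups(cohort_metrics(h), cohort_metrics(g))
  expect_equal(nrow(cmp), 24)
  expect_equal(sort(unique(cmp$metric)), c("peak", "post_rate", "pre_rate"))

  h2 <- sample_cohort(tg, 15, group = "healthy", seed = 51)
  g2 <- sample_cohort(tg, 15, group = "gad", seed = 52)
  expect_identical(tidy(cmp), tidy(compare_groups(cohort_metrics(h2), cohort_metrics(g2))))

  mh <- cohort_metrics(h)
  expect_error(
    compare_groups(mh[!(mh$roi == "thalamus" & mh$side == "left"), ],
                   cohort_metrics(g)),
    class = "petloop_validation"
  )
})

test_that("dynamics labels follow sign and significance", {
  expect_equal(classify_dynamics(compare_summaries()), expected_dynamics())
  # all-non-significant comparison -> all none
  eq <- reference_summaries()
  eq$mean <- 1; eq$sd <- 0.1
  lab <- classify_dynamics(compare_summaries(eq))
  expect_true(all(lab$in_label == "none" & lab$out_label == "none" &
                    lab$total_label == "none"))
  expect_error(
    classify_dynamics(compare_summaries()[compare_summaries()$metric == "peak", ]),
    class = "petloop_validation"
  )
})

test_that("tidy, glance and autoplot summarise a comparison", {
  cmp <- compare_summaries()
  td <- tidy(cmp)
  expect_false(inherits(td, "loop_comparison"))
  gl <- glance(cmp)
  expect_equal(gl$n_cells, 24)
  expect_equal(gl$n_significant, sum(cmp$significant))
  expect_s3_class(autoplot(cmp), "ggplot")
})

test_that("TAC plot reflects the group means", {
  tg <- consistent_targets()
  curves <- dplyr::bind_rows(
    cohort_curves(sample_cohort(tg, 4, group = "healthy", seed = 61)),
    cohort_curves(sample_cohort(tg, 4, group = "gad", seed = 62))
  )
  p <- plot_tac(curves, rois = "thalamus")
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  # plotted means equal direct column means of the input curves
  direct <- curves |>
    dplyr::filter(roi == "thalamus") |>
    dplyr::group_by(group, side, time) |>
    dplyr::summarise(mean = mean(value), .groups = "drop")
  line <- built$data[[2]]
  expect_setequal(round(line$y, 10), round(direct$mean, 10))

  f <- withr::local_tempfile(fileext = ".png")
  ggplot2::ggsave(f, p, width = 6, height = 4, dpi = 90)
  expect_gt(file.size(f), 0)

  expect_error(plot_tac(curves, rois = "amygdala"), class = "petloop_validation")
})
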