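test_that("label map places ten disjoint lateralized regions", {
  lm <- make_label_map(c(64, 64, 64))
  counts <- table(lm$map)
  expect_setequal(as.integer(names(counts)), 0:10)
  expect_true(all(counts[as.character(1:10)] > 0))

  mid <- (64 + 1) / 2
  left <- lm$rois[lm$rois$side == "left", ]
  right <- lm$rois[lm$rois$side == "right", ]
  expect_true(all(left$centroid_x < mid))
  expect_true(all(right$centroid_x > mid))
  # whole regions, not just centroids, stay in their hemisphere
  for (lab in left$label) {
    expect_true(max(which(lm$map == lab, arr.ind = TRUE)[, 1]) < mid)
  }
  expect_error(make_label_map(c(8, 64, 64)), class = "petloop_sizing")
})

test_that("label map works at the minimum grid size", {
  lm <- make_label_map(c(16, 16, 16))
  expect_equal(sort(unique(as.vector(lm$map))), 0:10)
})

test_that("cohort sampling hits its targets and is reproducible", {
  tg <- consistent_targets()
  # zero SD -> every subject equals the target means
  tg0 <- dplyr::mutate(tg, sd = 0)
  co0 <- sample_cohort(tg0, n_subjects = 3, group = "healthy", seed = 1)
  expect_true(all(abs(co0$peak_value - 2.4) < 1e-12))
  expect_true(all(abs(co0$pre_peak_rate - 0.02) < 1e-12))

  # sampled means approach the published target within 3 standard errors
  big <- suppressWarnings(
    sample_cohort(reference_summaries(), n_subjects = 10000,
                  group = "healthy", seed = 2)
  )
  lpfc <- big[big$roi == "prefrontal" & big$side == "left", ]
  se <- 0.21 / sqrt(10000)
  expect_lt(abs(mean(lpfc$peak_value) - 2.41), 3 * se)
  expect_lt(abs(stats::sd(lpfc$peak_value) - 0.21), 3 * 0.21 / sqrt(2 * 9999))

  co_a <- sample_cohort(tg, n_subjects = 5, group = "gad", seed = 9)
  co_b <- sample_cohort(tg, n_subjects = 5, group = "gad", seed = 9)
  expect_identical(co_a, co_b)

  # inconsistent targets: clipped with a warning, or rejected
  expect_warning(
    sample_cohort(reference_summaries(), n_subjects = 2, group = "healthy", seed = 1),
    "clipped"
  )
  expect_error(
    sample_cohort(reference_summaries(), n_subjects = 2, group = "healthy",
                  seed = 1, clip_negative = FALSE),
    class = "petloop_validation"
  )
})

test_that("rendered volumes carry the prescribed curves", {
  lm <- make_label_map(c(24, 24, 24))
  params <- full_loop_params(seed = 11)
  vol <- render_dynamic_volume(params, lm)

  for (i in seq_len(nrow(params))) {
    cur <- extract_suvmax_curve(vol, lm, params$roi[i], params$side[i])
    expect_equal(cur$value, eval_tac(params[i, ], tac_times()), tolerance = 1e-12)
  }
  # cerebellum painted 1.0 -> normalized equals raw
  cur <- extract_suvmax_curve(vol, lm, "thalamus", "left")
  cereb <- extract_suvmax_curve(vol, lm, "cerebellum", "left")
  expect_equal(normalize_to_cerebellum(cur, cereb)$value, cur$value)

  # with noise the per-frame ROI max is never below the painted value
  voln <- render_dynamic_volume(params, lm, noise_sd = 0.2, seed = 3)
  idx <- which(lm$map == lm$rois$label[lm$rois$roi == "striatum" &
                                         lm$rois$side == "right"])
  painted <- eval_tac(params[params$roi == "striatum" & params$side == "right", ],
                      tac_times())
  roi_max <- vapply(1:11, function(f) {
    frame <- voln[, , , f]
    max(frame[idx])
  }, numeric(1))
  expect_true(all(roi_max >= painted - 1e-12))

  expect_error(
    render_dynamic_volume(params[-1, ], lm),
    class = "petloop_configuration"
  )
})

test_that("colour scenes match their ground-truth masks", {
  sp <- scene_spec(width = 40, height = 32, shape = "disc")
  sc <- make_color_scene(sp)
  # noiseless disc: every foreground pixel has exactly the fg colour
  for (ch in 1:3) {
    plane <- sc$image[, , ch]
    expect_true(all(plane[sc$mask] == sp$fg[ch]))
    expect_true(all(plane[!sc$mask] == sp$bg[ch]))
  }
  expect_error(
    scene_spec(fg = c(0.5, 0.5, 0.5), bg = c(0.5, 0.5, 0.5)),
    class = "petloop_validation"
  )
  expect_error(
    scene_spec(width = 20, height = 20, center = c(2, 10), radius = 5),
    class = "petloop_validation"
  )

  # same seed -> identical bytes; different seed -> different noise
  s1 <- make_color_scene(scene_spec(noise_sd = 0.05, seed = 4))
  s2 <- make_color_scene(scene_spec(noise_sd = 0.05, seed = 4))
  s3 <- make_color_scene(scene_spec(noise_sd = 0.05, seed = 5))
  expect_identical(s1$image, s2$image)
  expect_false(identical(s1$image, s3$image))

  # foreground/background LAB contrast exceeds a floor (per-pixel oracle)
  lab <- grDevices::convertColor(rbind(sp$fg, sp$bg), "sRGB", "Lab") / 100
  expect_gt(sqrt(sum((lab[1, ] - lab[2, ])^2)), 0.1)
})
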