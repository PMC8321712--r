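test_that("SUVmax extraction validates input and honours repeats/jitter", {
  lm <- make_label_map(c(24, 24, 24))
  params <- full_loop_params(seed = 21)
  vol <- render_dynamic_volume(params, lm)

  expect_error(extract_suvmax_curve(vol[, , , 1:5], lm, "thalamus", "left"),
               class = "petloop_validation")
  expect_error(extract_suvmax_curve(vol, lm, "amygdala", "left"),
               class = "petloop_lookup")

  one <- extract_suvmax_curve(vol, lm, "hippocampus", "right", repeats = 1)
  three <- extract_suvmax_curve(vol, lm, "hippocampus", "right", repeats = 3)
  expect_equal(three$value, one$value)

  # jitter small enough to keep the hottest voxel inside the ROI: unchanged
  jit <- extract_suvmax_curve(vol, lm, "hippocampus", "right", repeats = 3,
                              jitter = 1, seed = 5)
  idx <- which(lm$map == lm$rois$label[lm$rois$roi == "hippocampus" &
                                         lm$rois$side == "right"])
  direct <- vapply(1:11, function(f) max(vol[, , , f][idx]), numeric(1))
  expect_equal(jit$value, direct)
})

test_that("cerebellar standardization is a pointwise ratio", {
  cur <- tibble::tibble(roi = "striatum", side = "left", time = tac_times(),
                        value = seq(1, 2, length.out = 11), normalized = FALSE)
  ones <- dplyr::mutate(cur, value = 1)
  expect_equal(normalize_to_cerebellum(cur, ones)$value, cur$value)
  expect_true(all(normalize_to_cerebellum(cur, cur)$value == 1))

  cereb <- dplyr::mutate(cur, value = 0.8)
  cur2 <- dplyr::mutate(cur, value = 2.0)
  expect_equal(normalize_to_cerebellum(cur2, cereb)$value, rep(2.5, 11))

  expect_error(normalize_to_cerebellum(cur, dplyr::mutate(cur, value = 0)),
               class = "petloop_division")
  # scale equivariance: scaling both curves leaves the ratio unchanged
  a <- 3.7
  expect_equal(
    normalize_to_cerebellum(dplyr::mutate(cur2, value = a * value),
                            dplyr::mutate(cereb, value = a * value))$value,
    normalize_to_cerebellum(cur2, cereb)$value
  )
})

test_that("uptake metrics implement the endpoint-rate definitions", {
  mk <- function(values) tibble::tibble(time = tac_times(), value = values)
  # linear rise 1.0 -> 2.2 at 60 min, then fall to 1.6 at 150 min
  v <- c(seq(1.0, 2.2, length.out = 5), seq(2.2, 1.6, length.out = 7)[-1])
  m <- uptake_metrics(mk(v))
  expect_equal(m$peak_value, 2.2)
  expect_equal(m$peak_time, 60)
  expect_equal(m$pre_peak_rate, (2.2 - 1.0) / 60)
  expect_equal(m$post_peak_rate, (2.2 - 1.6) / 90)

  flat <- uptake_metrics(mk(rep(1.5, 11)))
  expect_equal(flat$peak_time, 0)
  expect_equal(flat$pre_peak_rate, 0)
  expect_equal(flat$post_peak_rate, (1.5 - 1.5) / 150)

  rising <- uptake_metrics(mk(seq(1, 2, length.out = 11)))
  expect_equal(rising$peak_time, 150)
  expect_equal(rising$post_peak_rate, 0)
  expect_equal(rising$pre_peak_rate, 1 / 150)

  # ties break to the earliest time; peak equals brute-force max
  set.seed(31)
  for (i in 1:25) {
    v <- round(stats::runif(11, 1, 2), 2)
    m <- uptake_metrics(mk(v))
    expect_equal(m$peak_value, max(v))
    expect_equal(m$peak_time, tac_times()[which(v == max(v))[1]])
  }
})

test_that("metric extraction round-trips the generating parameters", {
  lm <- make_label_map(c(16, 16, 16))
  for (s in 1:3) {
    params <- full_loop_params(seed = 100 + s)
    vol <- render_dynamic_volume(params, lm)
    got <- lapply(seq_len(nrow(params)), function(i) {
      cur <- extract_suvmax_curve(vol, lm, params$roi[i], params$side[i])
      cereb <- extract_suvmax_curve(vol, lm, "cerebellum", params$side[i])
      uptake_metrics(normalize_to_cerebellum(cur, cereb))
    })
    got <- dplyr::bind_rows(got)
    want <- tac_params_metrics(params)
    for (col in names(want)) {
      expect_lt(max(abs(got[[col]] - want[[col]])), 1e-9)
    }
  }
})

test_that("injected activity follows the weight formula", {
  expect_equal(injection_dose(60), 6.0)
  expect_equal(injection_dose(82), 8.2)
  expect_error(injection_dose(0), class = "petloop_validation")
  expect_error(injection_dose(-3), class = "petloop_validation")
})
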