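test_that("trimap initialisation labels inside/outside the rectangle", {
  img <- array(0.5, dim = c(10, 12, 3))
  tm <- init_trimap(img, c(1, 1, 12, 10))
  expect_true(all(tm$labels == 1))
  expect_false(any(tm$hard_bg))

  tm2 <- init_trimap(img, c(3, 2, 8, 7))
  expect_true(all(tm2$labels[2:7, 3:8] == 1))
  expect_true(all(tm2$labels[, c(1:2, 9:12)] == 0))
  expect_true(all(tm2$hard_bg[1, ]))

  expect_error(init_trimap(img, c(5, 5, 4, 8)), class = "petloop_validation")
  expect_error(init_trimap(img, c(0, 1, 5, 5)), class = "petloop_validation")
})

test_that("per-class mixtures recover well-separated components", {
  set.seed(91)
  centers <- rbind(
    c(0.1, 0.1, 0.1), c(0.9, 0.1, 0.1), c(0.1, 0.9, 0.1),
    c(0.1, 0.1, 0.9), c(0.9, 0.9, 0.9)
  )
  sd0 <- 0.02
  n_per <- 400
  px <- do.call(rbind, lapply(1:5, function(k) {
    matrix(stats::rnorm(n_per * 3, rep(centers[k, ], each = n_per), sd0), ncol = 3)
  }))
  # lay the sample out as an image; interleave the classes so both contain
  # every generating cluster
  n <- nrow(px)
  img <- array(0, dim = c(n / 50, 50, 3))
  for (ch in 1:3) img[, , ch] <- matrix(pmin(pmax(px[, ch], 0), 1), ncol = 50)
  labels <- matrix(rep_len(c(1L, 0L), n), nrow = n / 50, ncol = 50)

  gmm <- fit_gmms(img, labels, grabcut_config())
  for (cls in list(gmm$fg, gmm$bg)) {
    expect_equal(cls$K, 5)
    expect_equal(sum(cls$pi), 1, tolerance = 1e-9)
    mus <- t(vapply(cls$comps, function(cm) cm$mu, numeric(3)))
    # every generating centre is recovered by some component: the nearest
    # fitted mean lies within ~2 standard errors per coordinate of truth
    for (k in 1:5) {
      d <- sqrt(rowSums(sweep(mus, 2, centers[k, ])^2))
      nk <- cls$comps[[which.min(d)]]$n
      expect_lt(min(d), 3 * sqrt(3) * sd0 / sqrt(nk) + 2e-3)
    }
  }
  # independent EM cross-check on one class (same data, different fitter)
  withr::local_package("mclust")
  mcl <- mclust::Mclust(px[seq(1, n, by = 2), ], G = 5, modelNames = "VVV",
                        verbose = FALSE)
  mclust_mus <- t(mcl$parameters$mean)
  gmm_mus <- t(vapply(gmm$fg$comps, function(cm) cm$mu, numeric(3)))
  for (k in 1:5) {
    expect_lt(min(sqrt(rowSums(sweep(gmm_mus, 2, mclust_mus[k, ])^2))), 0.05)
  }

  w <- capture_warnings(
    fit_gmms(array(0.5, dim = c(2, 2, 3)), matrix(c(1L, 0L, 1L, 0L), 2, 2),
             grabcut_config())
  )
  expect_match(w, "too few", all = TRUE)
  expect_length(w, 2)   # one reduction warning per class
  expect_error(
    fit_gmms(img, matrix(1L, n / 50, 50), grabcut_config()),
    class = "petloop_validation"
  )
})

test_that("Gibbs energy matches hand-computed base cases", {
  # two adjacent pixels, identical colours, different labels -> V = gamma
  img <- array(0.4, dim = c(1, 2, 3))
  lab01 <- matrix(c(0L, 1L), 1, 2)
  gmm <- suppressWarnings(fit_gmms(img, lab01, grabcut_config(K = 1)))
  cfg <- grabcut_config(gamma = 7.5, beta = 2, K = 1)
  e <- gibbs_energy(img, lab01, gmm, cfg)
  expect_equal(e$V, 7.5)
  expect_equal(e$E, e$U + e$V)
  # uniform labelling -> no cut pairs -> V = 0
  e0 <- gibbs_energy(img, matrix(1L, 1, 2), gmm, cfg)
  expect_equal(e0$V, 0)
})

test_that("Gibbs energy matches exhaustive enumeration on 3x3 images", {
  set.seed(92)
  img <- array(runif(3 * 3 * 3), dim = c(3, 3, 3))
  init <- matrix(rep_len(c(1L, 0L), 9), 3, 3)
  cfg <- grabcut_config(gamma = 3, beta = 4, K = 2)
  gmm <- suppressWarnings(fit_gmms(img, init, cfg))
  for (code in 0:511) {
    lab <- matrix(as.integer(intToBits(code)[1:9]), 3, 3)
    got <- gibbs_energy(img, lab, gmm, cfg)
    want <- oracle_gibbs_energy(img, lab, gmm, gamma = 3, beta = 4)
    expect_equal(got$E, want, tolerance = 1e-9)
  }
})

test_that("grabcut separates phantoms, monotonically and within constraints", {
  sc <- make_color_scene(scene_spec(width = 40, height = 40, radius = 10))
  res <- suppressWarnings(grabcut(sc$image, rect = c(6, 6, 35, 35)))
  expect_gte(mean(res$mask == sc$mask), 0.99)
  expect_true(all(diff(res$energy$E) <= 1e-6))
  # pixels outside the rectangle are never foreground
  outside <- res$mask
  outside[6:35, 6:35] <- FALSE
  expect_false(any(outside))

  # random noisy scenes: energy trace stays non-increasing
  for (s in 1:5) {
    spn <- scene_spec(width = 24, height = 24, radius = 6,
                      noise_sd = 0.1, seed = s)
    scn <- make_color_scene(spn)
    rn <- suppressWarnings(grabcut(scn$image, rect = c(4, 4, 21, 21)))
    expect_true(all(diff(rn$energy$E) <= 1e-6))
  }
})

test_that("boundary smoothing removes salt noise without eating area", {
  sp <- scene_spec(width = 48, height = 48, radius = 12)
  disc <- make_color_scene(sp)$mask
  sm <- smooth_boundary(disc)
  # an already-smooth disc changes by at most a 1-pixel boundary band
  expect_true(all(abs(as.matrix(EBImage::distmap((!sm) * 1)) -
                        as.matrix(EBImage::distmap((!disc) * 1))) <= 1.5))
  expect_lte(abs(sum(sm) - sum(disc)) / sum(disc), 0.05)

  noisy <- disc
  set.seed(93)
  bumps <- sample(which(!disc), 30)
  noisy[bumps[1:15]] <- TRUE   # salt specks just outside
  smn <- smooth_boundary(noisy)
  expect_lt(sum(smn != disc), sum(noisy != disc))
  expect_lte(abs(sum(smn) - sum(noisy)) / sum(noisy), 0.05)

  expect_error(smooth_boundary(matrix(FALSE, 5, 5)), class = "petloop_validation")
})
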