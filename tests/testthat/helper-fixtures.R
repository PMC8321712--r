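# Shared fixtures, all generated in code.

# Group-summary targets that are mutually consistent at peak_time = 60:
# derived start/end values stay non-negative, so drawn and curve-implied
# metrics coincide.
consistent_targets <- function() {
  base <- tidyr::expand_grid(
    loop_rois(),
    metric = c("peak", "pre_rate", "post_rate")
  )
  dplyr::bind_rows(
    dplyr::mutate(base, group = "healthy",
                  mean = dplyr::case_when(
                    metric == "peak" ~ 2.4,
                    metric == "pre_rate" ~ 0.02,
                    .default = 0.012
                  ),
                  sd = dplyr::if_else(metric == "peak", 0.1, 0.002)),
    dplyr::mutate(base, group = "gad",
                  mean = dplyr::case_when(
                    metric == "peak" ~ 2.1,
                    metric == "pre_rate" ~ 0.016,
                    .default = 0.014
                  ),
                  sd = dplyr::if_else(metric == "peak", 0.1, 0.002))
  )
}

# A full set of loop-region curve parameters from one draw of
# self-consistent random parameters (one parameter set per region).
full_loop_params <- function(seed) {
  rp <- random_tac_params(8, seed = seed)
  dplyr::bind_cols(loop_rois(), rp)
}

# Independent brute-force single-scale saliency: all-pairs dissimilarity
# with plain loops, then mean of the K smallest per patch.
brute_force_saliency <- function(grid, K, cc) {
  p <- nrow(grid$desc)
  D <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      dc <- sqrt(sum((grid$desc[i, ] - grid$desc[j, ])^2))
      dp <- sqrt(sum((grid$pos[i, ] - grid$pos[j, ])^2))
      D[i, j] <- dc / (1 + cc * dp)
    }
  }
  s <- numeric(p)
  for (i in seq_len(p)) {
    d <- sort(D[i, -i])
    k <- min(K, length(d))
    s[i] <- if (k < 1) 0 else 1 - exp(-mean(d[seq_len(k)]))
  }
  matrix(s, grid$n_rows, grid$n_cols)
}

# Independent Gibbs-energy oracle: direct loops over pixels and neighbour
# pairs, Gaussian densities via solve()/determinant().
oracle_gibbs_energy <- function(img, labels, gmm, gamma, beta, connectivity = 8L) {
  h <- dim(img)[1]; w <- dim(img)[2]
  px_at <- function(r, c) c(img[r, c, 1], img[r, c, 2], img[r, c, 3])
  neglog <- function(z, class_model) {
    best <- Inf
    for (k in seq_len(class_model$K)) {
      if (class_model$pi[k] <= 0) next
      cm <- class_model$comps[[k]]
      quad <- drop(t(z - cm$mu) %*% solve(cm$sigma) %*% (z - cm$mu))
      dens <- -log(class_model$pi[k]) +
        0.5 * (3 * log(2 * pi) + log(det(cm$sigma)) + quad)
      best <- min(best, dens)
    }
    min(best, 1e8)
  }
  U <- 0
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      cls <- if (labels[r, c] == 1) gmm$fg else gmm$bg
      U <- U + neglog(px_at(r, c), cls)
    }
  }
  offs <- list(c(0, 1), c(1, 0))
  if (connectivity == 8L) offs <- c(offs, list(c(1, 1), c(-1, 1)))
  V <- 0
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      for (o in offs) {
        r2 <- r + o[1]; c2 <- c + o[2]
        if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
        if (labels[r, c] != labels[r2, c2]) {
          V <- V + exp(-beta * sum((px_at(r, c) - px_at(r2, c2))^2))
        }
      }
    }
  }
  U + gamma * V
}

# A raw sample with exact mean m and exact SD s (length n >= 2).
exact_sample <- function(m, s, n) {
  x <- seq_len(n)
  x <- (x - mean(x)) / stats::sd(x)
  m + s * x
}

expected_dynamics <- function() {
  tibble::tribble(
    ~roi, ~side, ~in_label, ~out_label, ~total_label,
    "prefrontal", "left", "slow-in", "fast-out", "decreased",
    "prefrontal", "right", "slow-in", "fast-out", "decreased",
    "striatum", "left", "slow-in", "slow-out", "decreased",
    "striatum", "right", "none", "none", "none",
    "hippocampus", "left", "slow-in", "slow-out", "decreased",
    "hippocampus", "right", "none", "none", "none",
    "thalamus", "left", "fast-in", "fast-out", "increased",
    "thalamus", "right", "fast-in", "none", "increased"
  )
}
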