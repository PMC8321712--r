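# GrabCut foreground extraction: per-class K-component Gaussian mixtures in
# RGB, a Gibbs energy E = U + V with a contrast-adaptive boundary term, and
# alternating minimisation (component assignment, mixture refit, exact graph
# min-cut) that makes the energy trace non-increasing.

#' GrabCut configuration
#'
#' @param gamma Smoothness weight (> 0) of the boundary term.
#' @param beta Contrast scale of the boundary term; `NULL` (default) selects
#'   beta = 1 / (2 <||z_m - z_n||^2>) over neighbour pairs, the standard
#'   realization of "inversely proportional to the image contrast".
#' @param connectivity Neighbourhood system: 8 (default) or 4.
#' @param K Gaussian components per class.
#' @param max_iter Maximum number of refit/min-cut iterations.
#' @param tol Relative energy-change convergence tolerance.
#' @param cov_reg Ridge added to component covariances for stability on flat
#'   colour regions.
#' @return A `grabcut_config` list.
#' @export
grabcut_config <- function(gamma = 50, beta = NULL, connectivity = 8L,
                           K = 5L, max_iter = 10L, tol = 1e-3,
                           cov_reg = 1e-6) {
  check_number(gamma, "gamma", lower = 0, strict = TRUE)
  if (!is.null(beta)) check_number(beta, "beta", lower = 0, strict = TRUE)
  if (!connectivity %in% c(4L, 8L)) {
    stop_petloop("`connectivity` must be 4 or 8.", "validation")
  }
  check_number(K, "K", lower = 1)
  structure(
    list(gamma = gamma, beta = beta, connectivity = as.integer(connectivity),
         K = as.integer(K), max_iter = as.integer(max_iter), tol = tol,
         cov_reg = cov_reg),
    class = "grabcut_config"
  )
}

#' Initialize a trimap from a rectangle
#'
#' Pixels inside the rectangle become possible foreground (label 1); pixels
#' outside become hard background (label 0) and are never returned as
#' foreground by [grabcut()].
#'
#' @param img Height x width x 3 RGB array.
#' @param rect Rectangle `c(x0, y0, x1, y1)` in 1-based pixel coordinates
#'   (x = column, y = row), inclusive; must be non-degenerate and inside
#'   the image.
#' @return A `trimap` list: `labels` (0/1 matrix) and `hard_bg` (logical
#'   matrix of user-fixed background pixels).
#' @export
init_trimap <- function(img, rect) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (length(rect) != 4L) stop_petloop("`rect` must be c(x0, y0, x1, y1).", "validation")
  x0 <- rect[1]; y0 <- rect[2]; x1 <- rect[3]; y1 <- rect[4]
  if (x1 < x0 || y1 < y0) stop_petloop("`rect` is empty or degenerate.", "validation")
  if (x0 < 1 || y0 < 1 || x1 > w || y1 > h) {
    stop_petloop("`rect` must lie within the image.", "validation")
  }
  labels <- matrix(0L, h, w)
  labels[y0:y1, x0:x1] <- 1L
  structure(list(labels = labels, hard_bg = labels == 0L), class = "trimap")
}

# ---- internal GMM machinery -------------------------------------------------

pixel_matrix <- function(img) {
  cbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
}

make_component <- function(px_k, cov_reg) {
  n <- nrow(px_k)
  mu <- colMeans(px_k)
  sigma <- if (n > 1) {
    crossprod(sweep(px_k, 2, mu)) / n
  } else {
    matrix(0, 3, 3)
  }
  sigma <- sigma + diag(cov_reg, 3)
  ch <- chol(sigma)
  list(
    n = n, mu = mu, sigma = sigma,
    chol_inv = backsolve(ch, diag(3)),
    logdet = 2 * sum(log(diag(ch)))
  )
}

# Per-component -log(pi_k * N(z; mu_k, Sigma_k)) for all pixels: N x K matrix.
component_neglog <- function(px, comps, pis) {
  out <- matrix(Inf, nrow(px), length(comps))
  for (k in seq_along(comps)) {
    if (pis[k] <= 0) next
    cm <- comps[[k]]
    y <- sweep(px, 2, cm$mu) %*% cm$chol_inv
    maha <- rowSums(y^2)
    out[, k] <- -log(pis[k]) + 0.5 * (3 * log(2 * pi) + cm$logdet + maha)
  }
  out
}

fit_gmm_class <- function(px, K, cov_reg) {
  n <- nrow(px)
  n_distinct <- nrow(unique(px))
  k_eff <- min(K, n, n_distinct)
  if (k_eff < K) {
    warning(sprintf("Class has too few (distinct) pixels for K = %d; using %d components.",
                    K, k_eff), call. = FALSE)
  }
  assign <- if (k_eff == 1L) {
    rep(1L, n)
  } else {
    # deterministic initial centers: distinct pixel colours spread over the
    # class, so repeated runs on the same image agree exactly
    uq <- unique(px)
    centers <- uq[floor(seq(1L, nrow(uq), length.out = k_eff)), , drop = FALSE]
    stats::kmeans(px, centers = centers, iter.max = 30L)$cluster
  }
  refit_gmm_class(px, assign, k_eff, cov_reg)
}

refit_gmm_class <- function(px, assign, K, cov_reg, prev = NULL) {
  comps <- vector("list", K)
  pis <- numeric(K)
  for (k in seq_len(K)) {
    idx <- which(assign == k)
    if (length(idx) == 0L) {
      comps[[k]] <- if (!is.null(prev)) prev$comps[[k]] else make_component(px[1, , drop = FALSE], cov_reg)
      pis[k] <- 0
    } else {
      comps[[k]] <- make_component(px[idx, , drop = FALSE], cov_reg)
      pis[k] <- length(idx) / nrow(px)
    }
  }
  list(comps = comps, pi = pis, K = K)
}

#' Fit per-class Gaussian mixtures
#'
#' Fits a K-component full-covariance Gaussian mixture to the RGB pixels of
#' each class of a binary labelling (k-means initialisation, hard
#' assignment, maximum-likelihood refit) and records each pixel's best
#' component. Classes with fewer (distinct) pixels than K get a reduced
#' component count with a warning.
#'
#' @param img Height x width x 3 RGB array.
#' @param labels 0/1 matrix (or `trimap`) assigning each pixel to
#'   background (0) or foreground (1); both classes must be nonempty.
#' @param cfg A [grabcut_config()].
#' @return A `grabcut_gmm` list with `fg` and `bg` class models (component
#'   weights `pi` summing to 1, means, covariances) and `assign_fg`,
#'   `assign_bg` component indices for the pixels of each class.
#' @export
fit_gmms <- function(img, labels, cfg = grabcut_config()) {
  if (inherits(labels, "trimap")) labels <- labels$labels
  px <- pixel_matrix(img)
  fg_idx <- which(as.vector(labels) == 1L)
  bg_idx <- which(as.vector(labels) == 0L)
  if (length(fg_idx) == 0L || length(bg_idx) == 0L) {
    stop_petloop("Both classes must be nonempty to fit the mixtures.", "validation")
  }
  fg <- fit_gmm_class(px[fg_idx, , drop = FALSE], cfg$K, cfg$cov_reg)
  bg <- fit_gmm_class(px[bg_idx, , drop = FALSE], cfg$K, cfg$cov_reg)
  structure(
    list(
      fg = fg, bg = bg,
      assign_fg = max.col(-component_neglog(px[fg_idx, , drop = FALSE], fg$comps, fg$pi)),
      assign_bg = max.col(-component_neglog(px[bg_idx, , drop = FALSE], bg$comps, bg$pi))
    ),
    class = "grabcut_gmm"
  )
}

# Neighbour pairs (i, j) with i < j for the chosen connectivity, plus the
# squared RGB distance of each pair.
neighbour_pairs <- function(h, w, connectivity, px) {
  id <- matrix(seq_len(h * w), h, w)
  pairs <- list(
    cbind(as.vector(id[, -w]), as.vector(id[, -1])),   # horizontal
    cbind(as.vector(id[-h, ]), as.vector(id[-1, ]))    # vertical
  )
  if (connectivity == 8L && h > 1 && w > 1) {
    pairs <- c(pairs, list(
      cbind(as.vector(id[-h, -w]), as.vector(id[-1, -1])),  # down-right
      cbind(as.vector(id[-1, -w]), as.vector(id[-h, -1]))   # up-right
    ))
  }
  mn <- do.call(rbind, pairs)
  d2 <- rowSums((px[mn[, 1], , drop = FALSE] - px[mn[, 2], , drop = FALSE])^2)
  list(m = mn[, 1], n = mn[, 2], d2 = d2)
}

auto_beta <- function(d2) {
  md <- mean(d2)
  if (md <= 0) 1 else 1 / (2 * md)
}

unary_terms <- function(px, gmm) {
  list(
    fg = pmin(apply(component_neglog(px, gmm$fg$comps, gmm$fg$pi), 1, min), 1e8),
    bg = pmin(apply(component_neglog(px, gmm$bg$comps, gmm$bg$pi), 1, min), 1e8)
  )
}

#' Gibbs energy of a labelling
#'
#' E = U + V: the data term U sums, over pixels, -log of the pixel's best
#' component density (weight times Gaussian) under its class model; the
#' smoothness term V sums gamma * exp(-beta ||z_m - z_n||^2) over
#' neighbouring pixel pairs with differing labels.
#'
#' @param img Height x width x 3 RGB array.
#' @param labels 0/1 matrix (or `trimap`).
#' @param gmm A `grabcut_gmm` fitted on the same image.
#' @param cfg A [grabcut_config()]; with `beta = NULL` the contrast scale is
#'   computed from the image.
#' @return A one-row tibble `E`, `U`, `V`, `beta` with `E = U + V` exactly.
#' @export
gibbs_energy <- function(img, labels, gmm, cfg = grabcut_config()) {
  if (inherits(labels, "trimap")) labels <- labels$labels
  px <- pixel_matrix(img)
  lab <- as.vector(labels)
  un <- unary_terms(px, gmm)
  U <- sum(ifelse(lab == 1L, un$fg, un$bg))
  nb <- neighbour_pairs(dim(img)[1], dim(img)[2], cfg$connectivity, px)
  beta <- if (is.null(cfg$beta)) auto_beta(nb$d2) else cfg$beta
  cut <- lab[nb$m] != lab[nb$n]
  V <- cfg$gamma * sum(exp(-beta * nb$d2[cut]))
  tibble::tibble(E = U + V, U = U, V = V, beta = beta)
}

# One exact min-cut given unary and pairwise terms. Returns the new 0/1
# label vector. Hard-background pixels are forced to background.
mincut_labels <- function(un, nb_w, nb_m, nb_n, hard_bg, n_pix) {
  big <- 1e9
  s <- n_pix + 1L
  t <- n_pix + 2L
  # -log(pi * N) can be negative when densities exceed 1; shifting both
  # labels of a pixel by a common offset leaves the minimiser unchanged and
  # keeps all capacities non-negative, as the max-flow solver requires
  off <- pmin(un$fg, un$bg, 0)
  cap_s <- un$bg - off          # severed when pixel is background
  cap_t <- ifelse(hard_bg, big, un$fg - off)  # severed when pixel is foreground
  edges <- rbind(
    cbind(rep(s, n_pix), seq_len(n_pix)),
    cbind(seq_len(n_pix), rep(t, n_pix)),
    cbind(nb_m, nb_n)
  )
  caps <- c(cap_s, cap_t, nb_w)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  cut <- igraph::min_cut(g, source = s, target = t, capacity = caps,
                         value.only = FALSE)
  labs <- integer(n_pix)
  src_side <- setdiff(cut$partition1, c(s, t))
  if (t %in% cut$partition1) {  # partitions may come in either order
    src_side <- setdiff(cut$partition2, c(s, t))
  }
  labs[src_side] <- 1L
  labs
}

#' GrabCut foreground extraction
#'
#' Iterates component assignment, mixture refit and exact graph min-cut
#' from a rectangle initialisation until the Gibbs energy change falls
#' below `tol` (relative) or `max_iter` is reached. Each step minimises the
#' same energy, so the recorded energy trace is non-increasing. Pixels
#' outside the rectangle are hard background and are never labelled
#' foreground.
#'
#' @param img Height x width x 3 RGB array in \[0, 1\].
#' @param rect Initialisation rectangle, as in [init_trimap()].
#' @param cfg A [grabcut_config()].
#' @return A `grabcut_result` list: `mask` (logical foreground matrix),
#'   `energy` (tibble with one row per iteration: `iteration`, `E`, `U`,
#'   `V`), `beta`, `iterations`, and the final `gmm`.
#' @export
grabcut <- function(img, rect, cfg = grabcut_config()) {
  trimap <- init_trimap(img, rect)
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- pixel_matrix(img)
  n_pix <- nrow(px)
  hard_bg <- as.vector(trimap$hard_bg)
  lab <- as.vector(trimap$labels)

  nb <- neighbour_pairs(h, w, cfg$connectivity, px)
  beta <- if (is.null(cfg$beta)) auto_beta(nb$d2) else cfg$beta
  nb_w <- cfg$gamma * exp(-beta * nb$d2)

  gmm <- fit_gmms(img, matrix(lab, h, w), cfg)
  trace <- vector("list", cfg$max_iter)
  prev_E <- Inf

  for (it in seq_len(cfg$max_iter)) {
    # (1) assign components and refit the mixtures on the current labelling
    fg_idx <- which(lab == 1L)
    bg_idx <- which(lab == 0L)
    if (length(fg_idx) > 0L) {
      a_fg <- max.col(-component_neglog(px[fg_idx, , drop = FALSE],
                                        gmm$fg$comps, gmm$fg$pi))
      gmm$fg <- refit_gmm_class(px[fg_idx, , drop = FALSE], a_fg,
                                gmm$fg$K, cfg$cov_reg, prev = gmm$fg)
    }
    a_bg <- max.col(-component_neglog(px[bg_idx, , drop = FALSE],
                                      gmm$bg$comps, gmm$bg$pi))
    gmm$bg <- refit_gmm_class(px[bg_idx, , drop = FALSE], a_bg,
                              gmm$bg$K, cfg$cov_reg, prev = gmm$bg)

    # (2) exact min-cut under the refit models
    un <- unary_terms(px, gmm)
    new_lab <- mincut_labels(un, nb_w, nb$m, nb$n, hard_bg, n_pix)
    if (sum(new_lab) == 0L) {
      # degenerate cut: keep the previous labelling and stop
      break
    }
    lab <- new_lab

    # (3) energy under the current models and labelling
    U <- sum(ifelse(lab == 1L, un$fg, un$bg))
    V <- sum(nb_w[lab[nb$m] != lab[nb$n]])
    E <- U + V
    trace[[it]] <- tibble::tibble(iteration = it, E = E, U = U, V = V)
    if (is.finite(prev_E) && abs(prev_E - E) < cfg$tol * abs(prev_E)) {
      prev_E <- E
      break
    }
    prev_E <- E
  }

  energy <- dplyr::bind_rows(
    list(tibble::tibble(iteration = integer(), E = numeric(),
                        U = numeric(), V = numeric())),
    trace[!vapply(trace, is.null, logical(1))]
  )
  structure(
    list(
      mask = matrix(lab == 1L, h, w),
      energy = energy,
      beta = beta,
      iterations = nrow(energy),
      gmm = gmm
    ),
    class = "grabcut_result"
  )
}

#' Smooth a segmentation boundary
#'
#' Morphological opening and closing with a disc structuring element
#' followed by a light Gaussian contour smoothing (blur and re-threshold).
#' If the result changes the mask area by more than `max_area_change`
#' (fraction of the input area), progressively smaller discs are tried; if
#' none satisfies the bound the input mask is returned with a warning.
#'
#' @param mask Logical (or 0/1) matrix; must be nonempty.
#' @param radius Disc radius in pixels.
#' @param max_area_change Maximum tolerated fractional area change.
#' @return Logical matrix with a smoothed boundary.
#' @export
smooth_boundary <- function(mask, radius = 2L, max_area_change = 0.05) {
  m <- (mask != 0) * 1
  if (sum(m) == 0) stop_petloop("`mask` is empty.", "validation")
  area0 <- sum(m)
  for (r in seq(as.integer(radius), 1L)) {
    brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
    sm <- EBImage::closing(EBImage::opening(m, brush), brush)
    sm <- (as.matrix(EBImage::gblur(sm, sigma = max(r / 2, 0.5))) > 0.5) * 1
    if (sum(sm) > 0 && abs(sum(sm) - area0) / area0 <= max_area_change) {
      return(sm == 1)
    }
  }
  warning("No smoothing radius met the area-change bound; returning the input mask.",
          call. = FALSE)
  mask != 0
}
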