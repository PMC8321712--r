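# Context-aware saliency: LAB patch dissimilarity, K-most-similar-patch
# saliency per scale, cross-scale averaging, and context correction that
# attenuates saliency with distance from the attended (above-threshold)
# pixels.

#' Saliency configuration
#'
#' @param c Position-weight constant in the dissimilarity formula (> 0).
#' @param K Number of reference patches per block (>= 1); truncated to the
#'   available patch count on small grids.
#' @param patch_size Patch side in pixels.
#' @param scales Relative image scales averaged over (fractions of the
#'   original size).
#' @param threshold Attention threshold on the scale-averaged map, in (0, 1).
#' @param neighbor_mode How the K reference patches are chosen:
#'   `"similar"` (smallest dissimilarity, the default) or `"spatial"`
#'   (nearest patch centres).
#' @return A `saliency_config` list.
#' @export
saliency_config <- function(c = 3, K = 64L, patch_size = 8L,
                            scales = c(1, 0.5, 0.25), threshold = 0.8,
                            neighbor_mode = c("similar", "spatial")) {
  check_number(c, "c", lower = 0, strict = TRUE)
  check_number(K, "K", lower = 1)
  check_number(patch_size, "patch_size", lower = 1)
  if (length(scales) < 1 || any(scales <= 0) || any(scales > 1)) {
    stop_petloop("`scales` must be fractions in (0, 1].", "validation")
  }
  if (threshold <= 0 || threshold >= 1) {
    stop_petloop("`threshold` must lie in (0, 1).", "validation")
  }
  structure(
    list(c = c, K = as.integer(K), patch_size = as.integer(patch_size),
         scales = scales, threshold = threshold,
         neighbor_mode = match.arg(neighbor_mode)),
    class = "saliency_config"
  )
}

#' Dissimilarity of two image patches
#'
#' D = d_color / (1 + c * d_position), with both distances Euclidean: color
#' distance between the patches' LAB descriptors and position distance
#' between their normalized centres. Large color distance at small spatial
#' distance gives the largest dissimilarity.
#'
#' @param p_i,p_j Lists with elements `color` (length-3 LAB descriptor) and
#'   `position` (length-2 centre in \[0, 1\]^2).
#' @param c Position-weight constant.
#' @return The scalar dissimilarity (>= 0).
#' @examples
#' p <- list(color = c(0, 0, 0), position = c(0, 0))
#' q <- list(color = c(1, 0, 0), position = c(1, 0))
#' block_dissimilarity(p, q, c = 3) # 1 / (1 + 3) = 0.25
#' @export
block_dissimilarity <- function(p_i, p_j, c = 3) {
  d_color <- sqrt(sum((p_i$color - p_j$color)^2))
  d_position <- sqrt(sum((p_i$position - p_j$position)^2))
  d_color / (1 + c * d_position)
}

# RGB array -> N x 3 LAB matrix scaled to O(1) (L in [0,1]).
rgb_to_lab <- function(img) {
  px <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  grDevices::convertColor(px, from = "sRGB", to = "Lab") / 100
}

#' Divide an image into a patch grid
#'
#' Partitions the image into `patch_size` x `patch_size` blocks (edge blocks
#' may be smaller) and summarises each block by its mean LAB colour and its
#' normalized centre position.
#'
#' @param img Height x width x 3 RGB array in \[0, 1\].
#' @param patch_size Patch side in pixels.
#' @return A `patch_grid` list: `desc` (patches x 3 LAB descriptors), `pos`
#'   (patches x 2 centres in \[0, 1\]^2), `n_rows`, `n_cols`, `patch_size`,
#'   `dims`.
#' @export
patch_grid <- function(img, patch_size = 8L) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop_petloop("`img` must be a height x width x 3 array.", "validation")
  }
  h <- dim(img)[1]; w <- dim(img)[2]
  lab <- rgb_to_lab(img)
  prow <- ceiling(seq_len(h) / patch_size)
  pcol <- ceiling(seq_len(w) / patch_size)
  n_rows <- max(prow); n_cols <- max(pcol)
  pix_patch <- as.vector(
    matrix(prow, h, w) + (matrix(pcol, h, w, byrow = TRUE) - 1L) * n_rows
  )
  desc <- rowsum(lab, pix_patch) / tabulate(pix_patch, nbins = n_rows * n_cols)
  centers_r <- vapply(seq_len(n_rows), function(i) mean(which(prow == i)), numeric(1))
  centers_c <- vapply(seq_len(n_cols), function(j) mean(which(pcol == j)), numeric(1))
  pos <- cbind(
    rep(centers_r, times = n_cols) / h,
    rep(centers_c, each = n_rows) / w
  )
  structure(
    list(desc = unname(desc), pos = pos, n_rows = n_rows, n_cols = n_cols,
         patch_size = as.integer(patch_size), dims = c(h, w)),
    class = "patch_grid"
  )
}

# Pairwise dissimilarity matrix of a patch grid.
grid_dissimilarity <- function(grid, c) {
  dc <- as.matrix(stats::dist(grid$desc))
  dp <- as.matrix(stats::dist(grid$pos))
  dc / (1 + c * dp)
}

#' Single-scale patch saliency
#'
#' For every patch, saliency is 1 - exp(-mean dissimilarity to its K
#' reference patches): a patch that resembles many other patches (in colour,
#' nearby in space) scores low; a patch unlike everything else scores high.
#' Values always lie in \[0, 1\].
#'
#' @param grid A [patch_grid()].
#' @param cfg A [saliency_config()]; `K` is truncated to the number of
#'   other patches when the grid is small.
#' @return List with `patch_s` (per-patch saliency, `n_rows` x `n_cols`
#'   matrix) and `map` (per-pixel saliency at the grid's image size).
#' @export
single_scale_saliency <- function(grid, cfg = saliency_config()) {
  stopifnot(inherits(grid, "patch_grid"))
  p <- nrow(grid$desc)
  if (p < 1L) stop_petloop("Empty patch grid.", "validation")
  D <- grid_dissimilarity(grid, cfg$c)
  k <- min(cfg$K, p - 1L)
  s <- if (k < 1L) {
    rep(0, p)
  } else if (cfg$neighbor_mode == "similar") {
    vapply(seq_len(p), function(i) {
      d <- sort(D[i, -i], partial = k)[seq_len(k)]
      1 - exp(-mean(d))
    }, numeric(1))
  } else {
    dp <- as.matrix(stats::dist(grid$pos))
    vapply(seq_len(p), function(i) {
      nb <- order(dp[i, -i])[seq_len(k)]
      1 - exp(-mean(D[i, -i][nb]))
    }, numeric(1))
  }
  patch_s <- matrix(s, grid$n_rows, grid$n_cols)
  prow <- ceiling(seq_len(grid$dims[1]) / grid$patch_size)
  pcol <- ceiling(seq_len(grid$dims[2]) / grid$patch_size)
  list(patch_s = patch_s, map = patch_s[prow, pcol, drop = FALSE])
}

#' Context-aware saliency map
#'
#' Computes single-scale saliency at each configured scale, upsamples the
#' per-scale maps to the source size and averages them, then applies context
#' correction: pixels at or above the attention threshold keep their value,
#' and every other pixel is attenuated by its normalized Euclidean distance
#' to the nearest attended pixel (so remote pixels fade to 0). If no pixel
#' reaches the threshold the single most salient pixel is attended, with a
#' message.
#'
#' @param img Height x width x 3 RGB array in \[0, 1\].
#' @param cfg A [saliency_config()].
#' @return A `saliency_map` list: `map` (corrected saliency), `averaged`
#'   (scale-averaged map), `attended` (logical matrix), `threshold`,
#'   `scales`. All map values lie in \[0, 1\].
#' @export
context_aware_saliency <- function(img, cfg = saliency_config()) {
  if (min(img) < 0 || max(img) > 1) {
    stop_petloop("RGB values must lie in [0, 1].", "validation")
  }
  h <- dim(img)[1]; w <- dim(img)[2]
  maps <- lapply(cfg$scales, function(r) {
    scaled <- if (r == 1) {
      img
    } else {
      out <- EBImage::resize(img, w = max(round(h * r), cfg$patch_size),
                             h = max(round(w * r), cfg$patch_size))
      pmin(pmax(out, 0), 1)
    }
    m <- single_scale_saliency(patch_grid(scaled, cfg$patch_size), cfg)$map
    if (!identical(dim(m), c(h, w))) {
      m <- EBImage::resize(m, w = h, h = w)
    }
    pmin(pmax(m, 0), 1)
  })
  averaged <- Reduce(`+`, maps) / length(maps)
  attended <- averaged >= cfg$threshold
  if (!any(attended)) {
    message("No pixel reached the attention threshold; attending the maximum instead.")
    attended[which.max(averaged)] <- TRUE
  }
  d <- EBImage::distmap(1 - attended)
  d_foci <- pmin(as.matrix(d) / sqrt(h^2 + w^2), 1)
  structure(
    list(map = averaged * (1 - d_foci), averaged = averaged,
         attended = attended, threshold = cfg$threshold, scales = cfg$scales),
    class = "saliency_map"
  )
}
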