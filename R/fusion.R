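# Simplified PET/MRI fusion: linear intensity-hue-saturation colour
# transform plus a shift-invariant a-trous multiscale decomposition. The
# multiscale stage is a deliberately simple stand-in for directional
# contourlet-style transforms: it keeps the low/high frequency split and
# perfect reconstruction without requiring any filter-bank specification.

#' RGB to intensity-hue-saturation (and back)
#'
#' Linear IHS transform with intensity defined as the channel mean:
#' I = (R+G+B)/3, v1 = (R+G-2B)/sqrt(6), v2 = (R-G)/sqrt(2),
#' hue = atan2(v2, v1), saturation = sqrt(v1^2 + v2^2). The transform is
#' exactly invertible; grey pixels have saturation 0.
#'
#' @param img Height x width x 3 array with values in \[0, 1\].
#' @return A `gihs_image` list with matrices `intensity`, `hue`,
#'   `saturation`.
#' @export
rgb_to_gihs <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop_petloop("`img` must be a height x width x 3 array.", "validation")
  }
  if (min(img) < 0 || max(img) > 1) {
    stop_petloop("RGB values must lie in [0, 1].", "validation")
  }
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  v1 <- (r + g - 2 * b) / sqrt(6)
  v2 <- (r - g) / sqrt(2)
  structure(
    list(
      intensity = (r + g + b) / 3,
      hue = atan2(v2, v1),
      saturation = sqrt(v1^2 + v2^2)
    ),
    class = "gihs_image"
  )
}

#' @rdname rgb_to_gihs
#' @param gihs A `gihs_image`.
#' @return For `gihs_to_rgb()`, the reconstructed RGB array (not clipped).
#' @export
gihs_to_rgb <- function(gihs) {
  stopifnot(inherits(gihs, "gihs_image"))
  i <- gihs$intensity
  v1 <- gihs$saturation * cos(gihs$hue)
  v2 <- gihs$saturation * sin(gihs$hue)
  r <- i + v1 / sqrt(6) + v2 / sqrt(2)
  g <- i + v1 / sqrt(6) - v2 / sqrt(2)
  b <- i - 2 * v1 / sqrt(6)
  array(c(r, g, b), dim = c(dim(i), 3L))
}

# Reflecting (mirror) index into 1..n.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n - 2L
  j <- (i - 1L) %% period
  j <- ifelse(j >= n, period - j, j)
  j + 1L
}

# Separable B3-spline smoothing with taps dilated by `step` (a-trous).
atrous_smooth <- function(plane, step) {
  w <- c(1, 4, 6, 4, 1) / 16
  offs <- step * (-2:2)
  nr <- nrow(plane); nc <- ncol(plane)
  tmp <- matrix(0, nr, nc)
  for (k in seq_along(offs)) {
    tmp <- tmp + w[k] * plane[reflect_index(seq_len(nr) + offs[k], nr), , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (k in seq_along(offs)) {
    out <- out + w[k] * tmp[, reflect_index(seq_len(nc) + offs[k], nc), drop = FALSE]
  }
  out
}

#' Shift-invariant multiscale decomposition
#'
#' A-trous (stationary) wavelet decomposition with the B3-spline kernel:
#' each level smooths with a dilated kernel and stores the detail as the
#' difference of successive approximations, so every band has the source
#' resolution and the sum of all bands reconstructs the input exactly.
#'
#' @param plane 2D numeric matrix.
#' @param levels Number of detail levels L >= 1; must not exceed
#'   log2 of the smaller image dimension.
#' @return A `multiscale_stack` list: `low` (coarsest approximation) and
#'   `high` (list of L detail bands, finest first), all source-sized.
#' @export
multiscale_decompose <- function(plane, levels = 3L) {
  if (!is.matrix(plane)) stop_petloop("`plane` must be a matrix.", "validation")
  levels <- as.integer(levels)
  if (levels < 1L) stop_petloop("`levels` must be >= 1.", "validation")
  if (levels > floor(log2(min(dim(plane))))) {
    stop_petloop("`levels` exceeds log2 of the smaller image dimension.", "sizing")
  }
  high <- vector("list", levels)
  approx <- plane
  for (l in seq_len(levels)) {
    nxt <- atrous_smooth(approx, 2L^(l - 1L))
    high[[l]] <- approx - nxt
    approx <- nxt
  }
  structure(list(low = approx, high = high), class = "multiscale_stack")
}

#' @rdname multiscale_decompose
#' @param stack A `multiscale_stack`.
#' @return For `multiscale_reconstruct()`, the reconstructed matrix.
#' @export
multiscale_reconstruct <- function(stack) {
  stopifnot(inherits(stack, "multiscale_stack"))
  Reduce(`+`, stack$high, stack$low)
}

#' Fuse co-registered PET and MRI planes
#'
#' Both planes are decomposed into a low-frequency approximation and
#' high-frequency detail bands; the fused stack takes its low band from the
#' PET plane (the functional signal) and each high-band coefficient from
#' whichever modality has the larger absolute coefficient (anatomical
#' detail), then reconstructs and clips to \[0, 1\].
#'
#' @param mri_plane,pet_plane Co-registered 2D matrices of equal size with
#'   values in \[0, 1\].
#' @param levels Decomposition depth.
#' @return Fused matrix in \[0, 1\].
#' @export
fuse_pet_mri <- function(mri_plane, pet_plane, levels = 3L) {
  if (!identical(dim(mri_plane), dim(pet_plane))) {
    stop_petloop("MRI and PET planes must have identical dimensions.", "validation")
  }
  dm <- multiscale_decompose(mri_plane, levels)
  dp <- multiscale_decompose(pet_plane, levels)
  fused <- dp
  fused$high <- purrr::map2(dm$high, dp$high, function(hm, hp) {
    ifelse(abs(hm) >= abs(hp), hm, hp)
  })
  out <- multiscale_reconstruct(fused)
  pmin(pmax(out, 0), 1)
}
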