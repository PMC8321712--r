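# Thin wrappers around RNifti and png for the package's file formats.

#' Read and write volumes as NIfTI
#'
#' 4D dynamic volumes and 3D label maps are stored as NIfTI-1 files.
#'
#' @param vol Numeric array (3D or 4D).
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `write_volume_nifti()` returns `path` invisibly;
#'   `read_volume_nifti()` returns a plain numeric array.
#' @export
write_volume_nifti <- function(vol, path) {
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim = dim(arr))
}

#' Write a label map (NIfTI volume plus region table)
#'
#' @param labels A `roi_label_map` from [make_label_map()].
#' @param path Output NIfTI path; the region lookup table is written next
#'   to it as `<path>.rois.csv`.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  write_volume_nifti(labels$map, path)
  readr::write_csv(labels$rois, paste0(path, ".rois.csv"))
  invisible(path)
}

#' Read and write RGB scenes and masks as PNG
#'
#' @param img Height x width x 3 array in \[0, 1\] (or a 2D matrix for
#'   grayscale maps/masks).
#' @param path PNG path.
#' @return Writers return `path` invisibly; readers return the array.
#' @export
write_scene_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' @rdname write_scene_png
#' @export
read_scene_png <- function(path) {
  png::readPNG(path)
}

#' @rdname write_scene_png
#' @param mask Logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask != 0) * 1, path)
  invisible(path)
}

#' Write a saliency map as grayscale PNG plus raw values CSV
#'
#' @param sal A `saliency_map` from [context_aware_saliency()].
#' @param path PNG path; raw values go to `<path>.csv` as a long
#'   row/col/value table.
#' @return `path`, invisibly.
#' @export
write_saliency_map <- function(sal, path) {
  png::writePNG(pmin(pmax(sal$map, 0), 1), path)
  long <- tibble::tibble(
    row = as.vector(row(sal$map)),
    col = as.vector(col(sal$map)),
    value = as.vector(sal$map)
  )
  readr::write_csv(long, paste0(path, ".csv"))
  invisible(path)
}
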