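# Optional NIfTI path: extract per-label ROI series from a 4D image and an
# integer label image.

#' Extract ROI time series from a 4D NIfTI image and a label image
#'
#' For each integer label, collects the in-mask voxel time courses and
#' reduces them with [extract_roi_series()]. The analysis mask is the set
#' of voxels with finite, non-constant time courses; labels with fewer than
#' `min_overlap` of their voxels inside the mask are excluded (incomplete
#' brain coverage), mirroring the 50%-overlap exclusion rule used when a
#' parcellation extends beyond the acquired field of view.
#'
#' Requires the suggested `RNifti` package.
#'
#' @param image_path 4D NIfTI (X x Y x Z x T).
#' @param label_path 3D integer label NIfTI on the same grid.
#' @param min_overlap minimum in-mask voxel fraction per label (default 0.5).
#' @return list with `series` (ROI x T matrix, row names `label<v>`),
#'   `excluded` (integer labels dropped), `overlap` (named fractions).
#' @export
extract_rois_from_nifti <- function(image_path, label_path,
                                    min_overlap = 0.5) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI input")
  }
  img <- as.array(RNifti::readNifti(image_path))
  lab <- as.array(RNifti::readNifti(label_path))
  stopifnot(length(dim(img)) == 4,
            all(dim(img)[1:3] == dim(lab)[1:3]))
  t_len <- dim(img)[4]
  vox <- matrix(img, ncol = t_len)  # voxels x T
  lab_vec <- as.integer(round(as.vector(lab)))
  in_mask <- apply(vox, 1, function(v) {
    all(is.finite(v)) && stats::sd(v) > 1e-12
  })
  labels <- sort(unique(lab_vec[lab_vec > 0]))
  overlap <- vapply(labels, function(v) {
    idx <- lab_vec == v
    sum(idx & in_mask) / sum(idx)
  }, numeric(1))
  names(overlap) <- labels
  keep <- labels[overlap >= min_overlap]
  excluded <- setdiff(labels, keep)
  series <- t(vapply(keep, function(v) {
    extract_roi_series(vox[lab_vec == v & in_mask, , drop = FALSE])
  }, numeric(t_len)))
  rownames(series) <- paste0("label", keep)
  list(series = series, excluded = excluded, overlap = overlap)
}
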