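#' Voxel volume container
#'
#' A 3D grayscale image with isotropic voxel size and a declared slice axis
#' (the axis along which CT slices are indexed and along which the per-slice
#' operations of the segmentation pipeline run).
#'
#' @param values 3D numeric array of grey values.
#' @param voxel_size_um edge length of a voxel in micrometres (> 0).
#' @param slice_axis which array axis indexes slices (1, 2 or 3).
#' @param provenance free-text origin of the data.
#' @return an object of class `voxel_volume`.
#' @examples
#' v <- voxel_volume(array(0, c(4, 4, 4)), voxel_size_um = 1.41)
#' dim(v$values)
#' @export
voxel_volume <- function(values, voxel_size_um, slice_axis = 3L,
                         provenance = "") {
  d <- dim(values)
  if (is.null(d) || length(d) != 3L || any(d < 1L))
    mycomat_error("config", "values must be a 3D array with all dimensions >= 1")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      is.na(voxel_size_um) || voxel_size_um <= 0)
    mycomat_error("config", "voxel_size_um must be a single positive number")
  slice_axis <- as.integer(slice_axis)
  if (!slice_axis %in% 1:3)
    mycomat_error("config", "slice_axis must be 1, 2 or 3")
  structure(list(values = values, voxel_size_um = as.numeric(voxel_size_um),
                 slice_axis = slice_axis, provenance = provenance),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, %.4g um/voxel, slice axis %d\n",
              d[1], d[2], d[3], x$voxel_size_um, x$slice_axis))
  cat(sprintf("  grey range [%.4g, %.4g]  %s\n", min(x$values), max(x$values),
              x$provenance))
  invisible(x)
}

is_voxel_volume <- function(x) inherits(x, "voxel_volume")

# permute an array so that `axis` becomes the third dimension; returns the
# permuted array with the permutation stored for undoing
with_slice_axis_last <- function(arr, axis) {
  perm <- c(setdiff(1:3, axis), axis)
  list(arr = aperm(arr, perm), perm = perm)
}

undo_slice_axis <- function(arr, perm) {
  aperm(arr, order(perm))
}

voxel_volume_um3 <- function(vol) vol$voxel_size_um^3
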