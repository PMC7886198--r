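#' Binary voxel mask on a regular grid
#'
#' A `label_mask` is a 3-D logical array carrying its grid metadata
#' (`voxel_size` in mm and a `name`). All set operations in the pipeline
#' (lesion subtraction, mirroring, ROI intersection) act on these objects
#' and require matching grids.
#'
#' @param data 3-D logical (or coercible) array.
#' @param voxel_size Numeric length-3, mm per axis.
#' @param name Character label, e.g. `"lesion"`.
#' @return A `label_mask` object.
#' @export
label_mask <- function(data, voxel_size, name = "mask") {
  data <- array(as.logical(data), dim = dim(data))
  if (length(dim(data)) != 3L) stop("label_mask requires a 3-D array")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive numbers (mm)")
  structure(data,
            voxel_size = voxel_size,
            name = name,
            class = c("label_mask", "array"))
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask '%s'> %s voxels set of %s; voxel %s mm; volume %.3f mm^3\n",
              attr(x, "name"), sum(x), length(x),
              paste(signif(attr(x, "voxel_size"), 4), collapse = "x"),
              mask_volume(x)))
  invisible(x)
}

#' Volume of a mask in mm^3
#'
#' @param mask A [label_mask()].
#' @return Voxel count times voxel volume (mm^3).
#' @export
mask_volume <- function(mask) {
  sum(mask) * prod(attr(mask, "voxel_size"))
}

# Stop unless two masks (or a mask and an array) share grid shape and spacing.
check_same_grid <- function(a, b, what = "masks") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  va <- attr(a, "voxel_size"); vb <- attr(b, "voxel_size")
  if (!is.null(va) && !is.null(vb) && max(abs(va - vb)) > 1e-9)
    stop(sprintf("voxel size mismatch between %s", what))
  invisible(TRUE)
}

#' Ipsi- and contralesional hemisphere masks
#'
#' Splits the grid at the midsagittal plane, which must fall on a voxel
#' boundary (even extent along the mirror axis) so that reflection is an
#' exact index flip. The ipsilesional side is the high-index half of the
#' mirror axis (the study lesions one fixed side; no automatic detection).
#'
#' @param grid_shape Integer length-3 grid extent.
#' @param voxel_size Numeric length-3, mm.
#' @param axis Mirror axis (default 1, left-right).
#' @return List with `ipsi` and `contra` [label_mask()]s.
#' @export
hemisphere_masks <- function(grid_shape, voxel_size, axis = 1L) {
  n <- grid_shape[axis]
  if (n %% 2L != 0L)
    stop("mirror axis extent must be even so the midsagittal plane is a voxel boundary")
  idx <- slice.index(array(0, dim = grid_shape), axis)
  ipsi <- idx > n / 2
  list(ipsi   = label_mask(ipsi, voxel_size, "ipsi_hemisphere"),
       contra = label_mask(!ipsi, voxel_size, "contra_hemisphere"))
}

# Voxel-centre world coordinate of index i along an axis: (i - 0.5) * dx.
voxel_centres <- function(n, dx) (seq_len(n) - 0.5) * dx
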