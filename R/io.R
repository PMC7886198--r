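#' @name dwi_io
#' @title Reading and writing diffusion MRI data
#' @description
#' DWI volumes travel as 4-D NIfTI-1 files plus FSL-dialect gradient
#' tables: a `.bval` file (one row of b-values in s/mm^2) and a `.bvec`
#' file (three rows — x, y, z — of unit direction components, one column
#' per volume). T2 volumes and masks are 3-D NIfTI-1; scalar maps are
#' written as float32 sharing the source affine.
NULL

#' Read an FSL-dialect b-value file
#' @param path Path to a `.bval` file.
#' @return Numeric vector of b-values.
#' @export
read_bvals <- function(path) {
  v <- scan(path, quiet = TRUE)
  if (length(v) == 0L) stop(sprintf("no b-values found in '%s'", path))
  v
}

#' Read an FSL-dialect b-vector file
#'
#' Expects 3 rows by n volumes; a transposed (n x 3) layout is detected
#' from the shape and accepted with a warning.
#'
#' @param path Path to a `.bvec` file.
#' @return 3 x n numeric matrix.
#' @export
read_bvecs <- function(path) {
  rows <- lapply(readLines(path), function(l) {
    l <- trimws(l)
    if (nchar(l) == 0) return(NULL)
    as.numeric(strsplit(l, "[[:space:]]+")[[1]])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (any(vapply(rows, function(r) any(is.na(r)), logical(1))))
    stop(sprintf("unparseable numbers in bvec file '%s'", path))
  m <- do.call(rbind, rows)
  if (nrow(m) == 3L) return(m)
  if (ncol(m) == 3L && nrow(m) != 3L) {
    warning(sprintf("bvec file '%s' is transposed (%d x 3); accepting as n x 3",
                    path, nrow(m)))
    return(t(m))
  }
  stop(sprintf("bvec file '%s' is %d x %d; expected 3 rows (or n x 3 transposed)",
               path, nrow(m), ncol(m)))
}

#' Write FSL-dialect bval/bvec files
#' @param scheme A [gradient_scheme()].
#' @param prefix Output path prefix; writes `<prefix>.bval`, `<prefix>.bvec`.
#' @return Invisibly, the two paths.
#' @export
write_scheme <- function(scheme, prefix) {
  bval <- paste0(prefix, ".bval"); bvec <- paste0(prefix, ".bvec")
  writeLines(paste(sprintf("%.17g", scheme$bvals), collapse = " "), bval)
  writeLines(apply(scheme$bvecs, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), bvec)
  invisible(c(bval = bval, bvec = bvec))
}

#' Write a DWI volume as NIfTI + bval/bvec
#' @param dwi A `dwi_volume`.
#' @param prefix Output prefix; writes `<prefix>.nii.gz`, `.bval`, `.bvec`.
#' @return Invisibly, the NIfTI path.
#' @export
write_dwi <- function(dwi, prefix) {
  img <- RNifti::asNifti(dwi$data)
  RNifti::pixdim(img) <- c(dwi$voxel_size, 1)
  path <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(img, path, datatype = "double")
  write_scheme(dwi$scheme, prefix)
  invisible(path)
}

#' Read a DWI volume from NIfTI + bval/bvec
#'
#' Validates that the gradient table length matches the 4th NIfTI
#' dimension and that non-zero directions are unit vectors; directions
#' within 1e-3 of unit norm are renormalized silently, anything further
#' off is an error.
#'
#' @param nifti_path 4-D NIfTI file.
#' @param bval_path,bvec_path Gradient table files.
#' @param brain_mask Optional [label_mask()]; default: whole volume.
#' @return A `dwi_volume`.
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path, brain_mask = NULL) {
  img <- tryCatch(RNifti::readNifti(nifti_path),
                  error = function(e) stop(sprintf("unreadable NIfTI '%s': %s",
                                                   nifti_path, conditionMessage(e))))
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) != 4L)
    stop(sprintf("'%s' is %d-D; DWI must be 4-D", nifti_path, length(dim(data))))
  bvals <- read_bvals(bval_path)
  bvecs <- read_bvecs(bvec_path)
  nvol <- dim(data)[4]
  if (length(bvals) != nvol || ncol(bvecs) != nvol)
    stop(sprintf("gradient table length mismatch: %d b-values, %d b-vectors, %d volumes",
                 length(bvals), ncol(bvecs), nvol))
  nz <- which(bvals > 0)
  nrm <- sqrt(colSums(bvecs[, nz, drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-3))
    stop("non-unit gradient directions in bvec file (norm deviates by more than 1e-3)")
  fixup <- abs(nrm - 1) > 1e-12     # leave already-unit vectors untouched bitwise
  if (any(fixup))
    bvecs[, nz[fixup]] <- sweep(bvecs[, nz[fixup], drop = FALSE], 2L, nrm[fixup], `/`)
  vs <- RNifti::pixdim(img)[1:3]
  if (is.null(brain_mask))
    brain_mask <- label_mask(array(TRUE, dim(data)[1:3]), vs, "brain")
  structure(list(data = data,
                 scheme = validate_scheme(structure(list(bvals = bvals, bvecs = bvecs),
                                                    class = "gradient_scheme")),
                 voxel_size = vs, brain_mask = brain_mask),
            class = "dwi_volume")
}

#' Write a 3-D image or mask as NIfTI-1
#' @param img 3-D array (logical masks are written as integer labels).
#' @param path Output path.
#' @param voxel_size mm per axis; taken from the object when absent.
#' @return Invisibly, the path.
#' @export
write_volume <- function(img, path, voxel_size = attr(img, "voxel_size")) {
  if (is.null(voxel_size)) stop("voxel_size required")
  arr <- array(if (is.logical(img)) as.integer(img) else as.numeric(img), dim(img))
  dt <- if (is.logical(img)) "int16" else "float"
  nim <- RNifti::asNifti(arr)
  RNifti::pixdim(nim) <- voxel_size
  RNifti::writeNifti(nim, path, datatype = dt)
  invisible(path)
}

#' Read a NIfTI mask
#' @param path NIfTI file of 0/1 labels.
#' @param name Mask name.
#' @return A [label_mask()].
#' @export
read_mask <- function(path, name = "mask") {
  img <- RNifti::readNifti(path)
  label_mask(array(img != 0, dim(img)[1:3]), RNifti::pixdim(img)[1:3], name)
}

#' Write streamlines in TrackVis .trk format
#'
#' Minimal TrackVis writer: 1000-byte header (voxel order LPS fields
#' left at defaults, voxel-to-world scaling by voxel size) followed by
#' float32 point runs. Points are converted from mm to TrackVis's
#' voxel-mm convention unchanged (the phantom affine is diagonal).
#'
#' @param tracts A `streamline_set`.
#' @param path Output `.trk` path.
#' @return Invisibly, the path.
#' @export
write_trk <- function(tracts, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5, eos = NULL)           # id_string (6 bytes)
  writeBin(raw(1), con)
  writeBin(as.integer(tracts$grid_shape), con, size = 2)    # dim[3]
  writeBin(as.numeric(tracts$voxel_size), con, size = 4)    # voxel_size[3]
  writeBin(rep(0, 3), con, size = 4)                        # origin[3]
  writeBin(0L, con, size = 2)                               # n_scalars
  writeBin(raw(200), con)                                   # scalar names
  writeBin(0L, con, size = 2)                               # n_properties
  writeBin(raw(200), con)                                   # property names
  m <- diag(c(tracts$voxel_size, 1))                        # vox_to_ras 4x4
  writeBin(as.numeric(t(m)), con, size = 4)
  writeBin(raw(444), con)                                   # reserved
  writeChar("LAS", con, nchars = 3, eos = NULL)             # voxel_order
  writeBin(raw(1), con)
  writeChar("LAS", con, nchars = 3, eos = NULL)             # pad2
  writeBin(raw(1), con)
  writeBin(rep(0, 6), con, size = 4)                        # image orientation
  writeBin(raw(8), con)                                     # pad1 + invert/swap
  writeBin(length(tracts$streamlines), con, size = 4)       # n_count
  writeBin(2L, con, size = 4)                               # version
  writeBin(1000L, con, size = 4)                            # hdr_size
  for (s in tracts$streamlines) {
    writeBin(nrow(s), con, size = 4)
    writeBin(as.numeric(t(s)), con, size = 4)
  }
  invisible(path)
}

#' Write streamlines as a plain TSV
#'
#' Columns: streamline id, point index, x, y, z (mm).
#'
#' @param tracts A `streamline_set`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_streamlines_tsv <- function(tracts, path) {
  rows <- lapply(seq_along(tracts$streamlines), function(i) {
    s <- tracts$streamlines[[i]]
    data.frame(streamline = i, point = seq_len(nrow(s)),
               x = s[, 1], y = s[, 2], z = s[, 3])
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(streamline = integer(), point = integer(),
               x = numeric(), y = numeric(), z = numeric())
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a tidy metric table as TSV
#' @param table Data frame of tidy metric rows.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_metric_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
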