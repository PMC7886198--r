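#' Segment the ischemic lesion on a T2-weighted image
#'
#' The infarct is defined as ipsilesional voxels whose T2-weighted
#' intensity exceeds the mean plus `k` standard deviations (default
#' k = 2) of normal tissue in the contralateral hemisphere. The
#' contralateral mask should exclude CSF/ventricles (hyperintense
#' non-lesion tissue would inflate the threshold); pass
#' `contra & !ventricle_prior` for that.
#'
#' @param t2 3-D T2-weighted intensity array.
#' @param contralateral_mask [label_mask()] of contralateral normal tissue.
#' @param ipsilateral_mask [label_mask()] of the ipsilesional hemisphere.
#' @param k SD multiplier (default 2).
#' @return Lesion [label_mask()] with attributes `threshold`,
#'   `contra_mean`, `contra_sd`.
#' @export
segment_lesion <- function(t2, contralateral_mask, ipsilateral_mask, k = 2) {
  check_same_grid(t2, contralateral_mask, "T2 image and contralateral mask")
  check_same_grid(t2, ipsilateral_mask, "T2 image and ipsilateral mask")
  vals <- t2[as.logical(contralateral_mask)]
  if (length(vals) == 0L) stop("empty contralateral normal-tissue mask")
  mu <- mean(vals); sdv <- stats::sd(vals)
  if (length(vals) == 1L || is.na(sdv)) sdv <- 0
  if (sdv == 0) {
    warning("contralateral tissue has zero intensity SD; threshold equals the mean")
  }
  thr <- mu + k * sdv
  message(sprintf("[segment_lesion] threshold = %.4f (contralateral mean %.4f + %g x sd %.4f)",
                  thr, mu, k, sdv))
  out <- label_mask((t2 > thr) & unclass(ipsilateral_mask),
                    attr(ipsilateral_mask, "voxel_size"), "lesion")
  attr(out, "threshold") <- thr
  attr(out, "contra_mean") <- mu
  attr(out, "contra_sd") <- sdv
  out
}

#' Ventricular volume within a prior over contiguous slices
#'
#' Lateral-ventricle volumetry: CSF-hyperintense voxels (same mean + k SD
#' contralateral-normal-tissue rule as the lesion) counted inside a
#' ventricle prior mask restricted to a contiguous slice range (default
#' usage: 8 slices), times the voxel volume. The prior is ground truth
#' for phantoms and an atlas-guided manual tracing for real data.
#'
#' @param t2 3-D T2-weighted intensity array.
#' @param ventricle_prior [label_mask()] delimiting where ventricles may be.
#' @param slice_range Integer vector of slice indices along the third axis.
#' @param contralateral_mask [label_mask()] of contralateral normal tissue
#'   (threshold reference).
#' @param k SD multiplier (default 2).
#' @return Volume in mm^3 with attributes `n_voxels`, `threshold`.
#' @export
measure_ventricles <- function(t2, ventricle_prior, slice_range,
                               contralateral_mask, k = 2) {
  check_same_grid(t2, ventricle_prior, "T2 image and ventricle prior")
  gs <- dim(t2)
  slice_range <- as.integer(slice_range)
  if (any(slice_range < 1L) || any(slice_range > gs[3]))
    stop(sprintf("slice_range outside volume (1..%d)", gs[3]))
  vs <- attr(ventricle_prior, "voxel_size")
  if (sum(ventricle_prior) == 0L) {
    out <- 0
    attr(out, "n_voxels") <- 0L
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  vals <- t2[as.logical(contralateral_mask)]
  if (length(vals) == 0L) stop("empty contralateral normal-tissue mask")
  thr <- mean(vals) + k * stats::sd(vals)
  slab <- array(FALSE, gs)
  slab[, , slice_range] <- TRUE
  sel <- as.logical(ventricle_prior) & slab & (t2 > thr)
  out <- sum(sel) * prod(vs)
  attr(out, "n_voxels") <- sum(sel)
  attr(out, "threshold") <- thr
  out
}

#' Normalize a longitudinal volume series to day 1
#'
#' Divides each timepoint's absolute volume by the first (day-1) volume,
#' compensating for between-animal size differences; the day-1 entry is
#' 1 by construction.
#'
#' @param volumes Numeric absolute volumes (mm^3), first entry = day 1.
#' @param timepoints Optional labels (default names or index).
#' @return Data frame with `timepoint`, `volume_mm3`, `normalized`.
#' @export
normalize_series <- function(volumes, timepoints = NULL) {
  volumes <- as.numeric(volumes)
  if (any(volumes < 0)) stop("volumes must be non-negative")
  if (volumes[1] == 0) stop("day-1 volume is zero: normalization undefined")
  if (is.null(timepoints)) timepoints <- seq_along(volumes)
  data.frame(timepoint = timepoints, volume_mm3 = volumes,
             normalized = volumes / volumes[1])
}
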