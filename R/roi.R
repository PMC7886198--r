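#' Recovery region of interest by temporal lesion subtraction
#'
#' The infarct is consistently largest on day 1 and shrinks by 5 weeks;
#' the recovery ROI is the set difference day-1 lesion minus 5-week
#' lesion — tissue that was damaged acutely but no longer appears
#' lesioned at follow-up, where microstructural reorganization is
#' quantified.
#'
#' @param lesion_day1,lesion_wk5 Lesion [label_mask()]s on one grid.
#' @return Recovery [label_mask()]; empty result is allowed but warned.
#' @export
recovery_roi <- function(lesion_day1, lesion_wk5) {
  check_same_grid(lesion_day1, lesion_wk5, "day-1 and 5-week lesion masks")
  out <- label_mask(unclass(lesion_day1) & !unclass(lesion_wk5),
                    attr(lesion_day1, "voxel_size"), "recovery_roi")
  if (sum(out) == 0L)
    warning("recovery ROI is empty (5-week lesion covers the day-1 lesion)")
  out
}

#' Mirror a mask across the midsagittal plane
#'
#' Exact index reflection along the mirror axis, used to place the
#' contralesional homologous ROI. The axis extent must be even (midline
#' on a voxel boundary) unless an explicit `midline` override is given.
#' Voxel count is preserved exactly and the operation is an involution.
#'
#' @param mask A [label_mask()].
#' @param axis Mirror axis (default 1, left-right).
#' @param midline Optional midline position in voxels from the axis
#'   origin; overrides the even-extent requirement.
#' @return Mirrored [label_mask()].
#' @export
mirror_roi <- function(mask, axis = 1L, midline = NULL) {
  gs <- dim(mask)
  n <- gs[axis]
  if (is.null(midline)) {
    if (n %% 2L != 0L)
      stop("mirror axis extent is odd; supply an explicit `midline` to override")
    perm <- n + 1L - seq_len(n)
  } else {
    # reflect index i about the plane at `midline` voxels: i -> 2*midline + 1 - i
    perm <- as.integer(round(2 * midline + 1 - seq_len(n)))
    if (any(perm < 1L) || any(perm > n))
      stop("midline override reflects indices outside the grid")
  }
  idx <- rep(list(quote(expr = )), 3L)
  idx[[axis]] <- perm
  flipped <- do.call(`[`, c(list(unclass(mask)), idx, list(drop = FALSE)))
  label_mask(flipped, attr(mask, "voxel_size"),
             paste0(attr(mask, "name"), "_mirror"))
}

#' Pair an ipsilesional ROI with its mirrored contralesional control
#'
#' @param ipsi Ipsilesional [label_mask()] (e.g. from [recovery_roi()]).
#' @param contra Contralesional mask; default the exact mirror of `ipsi`.
#' @return An `roi_pair` (list with `ipsi`, `contra`).
#' @export
roi_pair <- function(ipsi, contra = mirror_roi(ipsi)) {
  check_same_grid(ipsi, contra, "ipsi and contra ROI")
  if (sum(ipsi) != sum(contra))
    stop("ipsi and contra ROI must have equal voxel counts")
  structure(list(ipsi = ipsi, contra = contra), class = "roi_pair")
}

#' Ipsi/contra relative DTI metrics over an ROI pair
#'
#' Divides the ipsilesional ROI summary of each scalar map by the
#' contralesional one (rFA, rAD, rRD), and optionally the ipsi by contra
#' fiber density (rFD). Ratios normalise away inter-animal variation; on
#' an intact symmetric brain they are 1.
#'
#' @param roi An [roi_pair()].
#' @param maps Named list of scalar maps (needs `FA`, `AD`, `RD`), as
#'   from [scalar_maps()].
#' @param fd_ipsi,fd_contra Optional fiber densities from [fiber_density()].
#' @param stat ROI summary statistic (default `mean`; `median` available).
#' @return One-row data frame with `rFA`, `rAD`, `rRD` (and `rFD` when
#'   fiber densities are supplied).
#' @export
relative_metrics <- function(roi, maps, fd_ipsi = NULL, fd_contra = NULL,
                             stat = mean) {
  if (sum(roi$ipsi) == 0L || sum(roi$contra) == 0L)
    stop("ROI pair must be non-empty on both sides")
  one <- function(map, nm) {
    check_same_grid(map, roi$ipsi, sprintf("%s map and ROI", nm))
    ip <- stat(map[as.logical(roi$ipsi)], na.rm = TRUE)
    co <- stat(map[as.logical(roi$contra)], na.rm = TRUE)
    if (!is.finite(co) || co == 0)
      stop(sprintf("contralateral ROI mean of %s is zero or undefined; ratio not computable", nm))
    ip / co
  }
  out <- data.frame(rFA = one(maps$FA, "FA"),
                    rAD = one(maps$AD, "AD"),
                    rRD = one(maps$RD, "RD"))
  if (!is.null(fd_ipsi) || !is.null(fd_contra)) {
    if (is.null(fd_ipsi) || is.null(fd_contra))
      stop("supply both fd_ipsi and fd_contra or neither")
    if (fd_contra == 0) stop("contralateral fiber density is zero; rFD not computable")
    out$rFD <- fd_ipsi / fd_contra
  }
  out
}
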