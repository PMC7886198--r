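#' Deterministic tracking parameters
#'
#' Stopping rules follow the study protocol: tracking terminates where FA
#' falls below 0.15 or where the turning angle between consecutive steps
#' exceeds 45 degrees; streamlines also stop on leaving the volume or at
#' `max_steps`, and those shorter than `min_length` are discarded.
#'
#' @param fa_threshold FA stopping threshold, in (0, 1). Default 0.15.
#' @param max_angle_deg Maximum turning angle between consecutive steps,
#'   degrees in (0, 90). Default 45.
#' @param step_size Integration step in mm; default half the smallest
#'   voxel dimension (resolved at tracking time when `NULL`).
#' @param max_steps Maximum Euler steps per direction. Default 2000.
#' @param min_length Minimum streamline length in mm; default two voxel
#'   widths (resolved at tracking time when `NULL`).
#' @param seeds_per_voxel Seeds per mask voxel; 1 (default) seeds the
#'   voxel centre, more adds reproducible uniform jitter.
#' @return A `tracking_params` list.
#' @export
tracking_params <- function(fa_threshold = 0.15, max_angle_deg = 45,
                            step_size = NULL, max_steps = 2000L,
                            min_length = NULL, seeds_per_voxel = 1L) {
  if (fa_threshold <= 0 || fa_threshold >= 1) stop("fa_threshold must be in (0, 1)")
  if (max_angle_deg <= 0 || max_angle_deg >= 90) stop("max_angle_deg must be in (0, 90)")
  if (!is.null(step_size) && step_size <= 0) stop("step_size must be positive")
  if (seeds_per_voxel < 1L) stop("seeds_per_voxel must be >= 1")
  structure(list(fa_threshold = fa_threshold, max_angle_deg = max_angle_deg,
                 step_size = step_size, max_steps = as.integer(max_steps),
                 min_length = min_length,
                 seeds_per_voxel = as.integer(seeds_per_voxel)),
            class = "tracking_params")
}

# Trilinear interpolation of a 3-D array at one world point (mm), with
# voxel centres at (i - 0.5) * voxel_size. NA voxels (outside the brain
# mask) are treated as 0, which makes FA-based stopping conservative at
# the brain edge. Returns NA outside the volume bounding box.
interp_trilinear <- function(vol, p, voxel_size) {
  gs <- dim(vol)
  u <- p / voxel_size + 0.5           # continuous 1-based voxel coordinate
  if (any(p < 0) || any(p > gs * voxel_size)) return(NA_real_)
  i0 <- pmin(pmax(floor(u), 1), gs)   # clamp so edge points use edge voxels
  i1 <- pmin(i0 + 1, gs)
  f <- pmin(pmax(u - i0, 0), 1)
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) *
         (if (dy) f[2] else 1 - f[2]) *
         (if (dz) f[3] else 1 - f[3])
    if (w > 0) {
      v <- vol[if (dx) i1[1] else i0[1], if (dy) i1[2] else i0[2],
               if (dz) i1[3] else i0[3]]
      if (is.na(v)) v <- 0
      acc <- acc + w * v
    }
  }
  acc
}

# Nearest-neighbour voxel index for a world point; NULL outside.
nn_voxel <- function(p, gs, voxel_size) {
  i <- ceiling(p / voxel_size)
  i[i < 1L] <- 1L
  if (any(p < 0) || any(p > gs * voxel_size)) return(NULL)
  pmin(pmax(i, 1), gs)
}

#' Deterministic streamline tractography
#'
#' Fixed-step Euler integration along the principal eigenvector field,
#' bidirectionally from each seed, with nearest-neighbour eigenvector
#' lookup and trilinear FA interpolation. The eigenvector sign at each
#' step is chosen to continue the previous heading. A streamline
#' terminates where interpolated FA < `fa_threshold`, where the turning
#' angle between consecutive steps exceeds `max_angle_deg`, on leaving
#' the volume, or after `max_steps`; the two half-tracks are merged and
#' streamlines shorter than `min_length` are discarded.
#'
#' @param eigs A `tensor_eigs` from [eigendecompose()].
#' @param fa_map 3-D FA array (from [scalar_maps()]), same grid.
#' @param seed_mask [label_mask()] of seed voxels (subset of the brain).
#' @param params A [tracking_params()].
#' @param seed RNG seed used only when `seeds_per_voxel > 1` (jitter).
#' @return A `streamline_set`: list of n x 3 point matrices (mm),
#'   `seed_voxel` linear index per streamline, `n_seed_voxels`,
#'   `step_size`.
#' @export
track <- function(eigs, fa_map, seed_mask, params = tracking_params(),
                  seed = 1L) {
  gs <- dim(eigs$fit_ok)
  if (!identical(dim(fa_map), gs) || !identical(dim(seed_mask)[1:3], gs))
    stop("grid mismatch between eigenvector field, FA map and seed mask")
  vs <- eigs$voxel_size
  seeds_idx <- which(as.logical(seed_mask))
  if (length(seeds_idx) == 0L) stop("empty seed mask")
  step <- if (is.null(params$step_size)) 0.5 * min(vs) else params$step_size
  min_len <- if (is.null(params$min_length)) 2 * min(vs) else params$min_length
  cos_max <- cos(params$max_angle_deg * pi / 180)

  e1 <- matrix(eigs$vectors[, , , , 1L], ncol = 3L)  # principal eigenvector, flat
  fa <- fa_map

  coords <- arrayInd(seeds_idx, gs)
  centres <- sweep(coords - 0.5, 2L, vs, `*`)
  if (params$seeds_per_voxel > 1L) {
    set.seed(seed)
    centres <- centres[rep(seq_len(nrow(centres)), each = params$seeds_per_voxel), ,
                       drop = FALSE]
    jit <- matrix(runif(length(centres), -0.5, 0.5), ncol = 3L)
    centres <- centres + sweep(jit, 2L, vs, `*`)
    seed_of <- rep(seeds_idx, each = params$seeds_per_voxel)
  } else {
    seed_of <- seeds_idx
  }

  march <- function(p0, d0) {
    pts <- matrix(NA_real_, nrow = params$max_steps, ncol = 3L)
    n <- 0L
    p <- p0; d <- d0
    repeat {
      if (n >= params$max_steps) break
      pn <- p + step * d
      fa_n <- interp_trilinear(fa, pn, vs)
      if (is.na(fa_n) || fa_n < params$fa_threshold) break
      vox <- nn_voxel(pn, gs, vs)
      if (is.null(vox)) break
      li <- vox[1] + gs[1] * (vox[2] - 1L) + gs[1] * gs[2] * (vox[3] - 1L)
      dn <- e1[li, ]
      if (any(is.na(dn))) break
      if (sum(dn * d) < 0) dn <- -dn          # continue previous heading
      if (sum(dn * d) < cos_max) break        # turning angle rule
      n <- n + 1L
      pts[n, ] <- pn
      p <- pn; d <- dn
    }
    pts[seq_len(n), , drop = FALSE]
  }

  streamlines <- vector("list", nrow(centres))
  kept <- logical(nrow(centres))
  for (k in seq_len(nrow(centres))) {
    p0 <- centres[k, ]
    if (is.na(interp_trilinear(fa, p0, vs)) ||
        interp_trilinear(fa, p0, vs) < params$fa_threshold) next
    vox <- nn_voxel(p0, gs, vs)
    li <- vox[1] + gs[1] * (vox[2] - 1L) + gs[1] * gs[2] * (vox[3] - 1L)
    d0 <- e1[li, ]
    if (any(is.na(d0)) || sum(d0^2) == 0) next
    fwd <- march(p0, d0)
    bwd <- march(p0, -d0)
    pts <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
                 matrix(p0, ncol = 3L), fwd)
    if (nrow(pts) < 2L) next
    if ((nrow(pts) - 1L) * step < min_len) next
    streamlines[[k]] <- pts
    kept[k] <- TRUE
  }
  structure(list(streamlines = streamlines[kept],
                 seed_voxel = seed_of[kept],
                 n_seed_voxels = length(seeds_idx),
                 step_size = step, voxel_size = vs, grid_shape = gs),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set> %d streamlines from %d seed voxels (FD = %.3f)\n",
              length(x$streamlines), x$n_seed_voxels, fiber_density(x)))
  invisible(x)
}

#' Fiber density
#'
#' The tract-count statistic used to summarise connectivity in a seeding
#' region: the number of reconstructed streamlines divided by the number
#' of seeding voxels.
#'
#' @param tracts A `streamline_set` from [track()].
#' @return Dimensionless FD >= 0.
#' @export
fiber_density <- function(tracts) {
  if (is.null(tracts$n_seed_voxels) || tracts$n_seed_voxels <= 0L)
    stop("fiber density undefined: zero seeding voxels")
  length(tracts$streamlines) / tracts$n_seed_voxels
}
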