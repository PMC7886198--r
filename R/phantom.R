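#' Tissue model for the synthetic rodent brain
#'
#' Each tissue class carries the diffusion-tensor eigenvalues used by the
#' DWI forward model, the principal fiber direction (white matter only;
#' isotropic tissues ignore it), and the T2-weighted intensity
#' distribution. Eigenvalues are in mm^2/s, sorted descending; intensities
#' are arbitrary units.
#'
#' @param label One of `"background"`, `"gray"`, `"white"`, `"csf"`, `"lesion"`.
#' @param eigenvalues Length-3 positive diffusivities, descending (mm^2/s).
#' @param direction Unit 3-vector, principal diffusion direction.
#' @param t2_mean,t2_sd T2-weighted intensity mean and SD (a.u.).
#' @return A `tissue_model` list.
#' @export
tissue_model <- function(label, eigenvalues, direction = c(1, 0, 0),
                         t2_mean, t2_sd) {
  label <- match.arg(label, c("background", "gray", "white", "csf", "lesion"))
  eigenvalues <- as.numeric(eigenvalues)
  if (length(eigenvalues) != 3L || any(eigenvalues <= 0))
    stop("eigenvalues must be 3 strictly positive diffusivities")
  if (any(diff(eigenvalues) > 0)) stop("eigenvalues must be sorted descending")
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-6) stop("principal direction must have unit norm")
  if (t2_sd < 0) stop("t2_sd must be non-negative")
  structure(list(label = label, eigenvalues = eigenvalues,
                 direction = direction / nrm,
                 t2_mean = t2_mean, t2_sd = t2_sd),
            class = "tissue_model")
}

#' Default tissue set
#'
#' Literature-typical rodent values: nearly isotropic gray matter, a
#' prolate white-matter tensor (FA about 0.85), free-water CSF, and a
#' lesion whose diffusivities are the gray-matter values times a
#' per-timepoint factor and whose T2 intensity is hyperintense (edema).
#' CSF is the brightest tissue on T2, as required for threshold-based
#' ventricular delineation.
#'
#' @param lesion_eigenvalue_factor Multiplier on gray-matter eigenvalues
#'   inside the lesion (default 0.6, cytotoxic-edema-like restriction).
#' @return Named list of [tissue_model()]s.
#' @export
default_tissues <- function(lesion_eigenvalue_factor = 0.6) {
  if (lesion_eigenvalue_factor <= 0) stop("lesion_eigenvalue_factor must be positive")
  list(
    background = tissue_model("background", c(1e-9, 1e-9, 1e-9), t2_mean = 0,   t2_sd = 0),
    gray  = tissue_model("gray",  c(0.8, 0.8, 0.8) * 1e-3, t2_mean = 100, t2_sd = 5),
    white = tissue_model("white", c(1.7, 0.2, 0.2) * 1e-3, direction = c(1, 0, 0),
                         t2_mean = 90,  t2_sd = 5),
    csf   = tissue_model("csf",   c(3.0, 3.0, 3.0) * 1e-3, t2_mean = 300, t2_sd = 10),
    lesion = tissue_model("lesion", sort(c(0.8, 0.8, 0.8) * 1e-3 * lesion_eigenvalue_factor,
                                         decreasing = TRUE),
                          t2_mean = 130, t2_sd = 5)
  )
}

#' Phantom specification
#'
#' Describes one animal's longitudinal phantom: grid geometry at the
#' study's acquisition resolution, the per-timepoint lesion radius
#' (non-increasing: infarcts are largest on day 1), ventricular
#' enlargement, the lesion diffusivity factor, and the acquisition SNR.
#'
#' @param grid_shape Voxels per axis (first axis even; default 64x64x16).
#' @param voxel_size mm per axis (default 0.156 x 0.156 x 0.75).
#' @param timepoints Ordered labels (default day1, wk2, wk5).
#' @param lesion_radius mm per timepoint, non-increasing; 0 = lesion-free.
#' @param ventricle_scale Dimensionless volume scale per timepoint, >= 1.
#' @param lesion_eigenvalue_factor Diffusivity multiplier inside lesion
#'   per timepoint.
#' @param snr b0 white-matter signal over noise sigma; `Inf` disables noise.
#' @param seed Integer RNG seed for this phantom.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 16L),
                         voxel_size = c(0.156, 0.156, 0.75),
                         timepoints = c("day1", "wk2", "wk5"),
                         lesion_radius = c(2.0, 1.2, 0.8),
                         ventricle_scale = c(1.0, 1.25, 1.5),
                         lesion_eigenvalue_factor = c(0.5, 0.65, 0.8),
                         snr = 30,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  nt <- length(timepoints)
  if (grid_shape[1] %% 2L != 0L)
    stop("grid_shape[1] must be even (midsagittal plane on a voxel boundary)")
  if (length(lesion_radius) != nt || length(ventricle_scale) != nt ||
      length(lesion_eigenvalue_factor) != nt)
    stop("per-timepoint parameters must match the number of timepoints")
  if (any(diff(lesion_radius) > 1e-12))
    stop("lesion_radius must be non-increasing over timepoints")
  if (any(lesion_radius < 0)) stop("lesion_radius must be non-negative")
  if (any(ventricle_scale < 1)) stop("ventricle_scale must be >= 1")
  if (snr <= 0) stop("snr must be positive (use Inf to disable noise)")
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 timepoints = timepoints,
                 lesion_radius = lesion_radius,
                 ventricle_scale = ventricle_scale,
                 lesion_eigenvalue_factor = lesion_eigenvalue_factor,
                 snr = snr, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Diffusion gradient scheme
#'
#' The study's acquisition: one b=0 volume plus 30 diffusion directions at
#' b = 1000 s/mm^2. Directions are spread near-uniformly on the sphere by
#' a deterministic Fibonacci (golden-angle) scheme, which guarantees the
#' >= 6 non-collinear directions needed for tensor identifiability.
#'
#' @param n_dirs Number of diffusion-weighted directions (default 30).
#' @param bval b-value of the weighted volumes, s/mm^2 (default 1000).
#' @param n_b0 Number of b=0 volumes (default 1).
#' @return A `gradient_scheme` with fields `bvals` (length n_b0 + n_dirs)
#'   and `bvecs` (3 x n matrix; zero columns for b=0).
#' @export
gradient_scheme <- function(n_dirs = 30L, bval = 1000, n_b0 = 1L) {
  if (n_dirs < 6L) stop("at least 6 diffusion directions are required for a tensor fit")
  if (n_b0 < 1L) stop("at least one b=0 volume is required")
  i <- seq_len(n_dirs) - 0.5
  phi <- pi * (1 + sqrt(5)) * i        # golden angle
  z <- 1 - i / n_dirs                  # upper hemisphere: antipodal dirs are equivalent
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- rbind(r * cos(phi), r * sin(phi), z, deparse.level = 0)
  bvecs <- unname(cbind(matrix(0, 3, n_b0), dirs))
  bvals <- c(rep(0, n_b0), rep(bval, n_dirs))
  validate_scheme(structure(list(bvals = bvals, bvecs = bvecs),
                            class = "gradient_scheme"))
}

validate_scheme <- function(scheme) {
  b <- scheme$bvals; g <- scheme$bvecs
  if (!is.matrix(g) || nrow(g) != 3L || ncol(g) != length(b))
    stop("bvecs must be a 3 x n matrix matching bvals")
  if (!any(b == 0)) stop("gradient scheme needs at least one b=0 entry")
  nz <- which(b > 0)
  nrm <- sqrt(colSums(g[, nz, drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("non-zero bvecs must be unit-norm (within 1e-6)")
  if (length(nz) < 6L) stop("at least 6 non-zero directions are required")
  scheme
}

# --- geometry -------------------------------------------------------------

# Default anatomical layout (mm offsets from grid centre). The brain is an
# ellipsoid, ventricles are mirrored ellipsoids near the centre, the
# white-matter bundle is a cylinder along the left-right axis, and the
# lesion is a sphere in the ipsilesional (high-x) hemisphere biting both
# bundle and gray matter.
phantom_geometry <- function(grid_shape, voxel_size) {
  fov <- grid_shape * voxel_size
  centre <- fov / 2
  semi <- 0.45 * fov                     # brain semi-axes
  list(
    centre = centre,
    brain_semi = semi,
    bundle_centre_yz = centre[2:3] + c(0, -0.28 * semi[3]),
    bundle_radius_yz = c(0.16 * semi[2], 0.15 * semi[3]),
    ventricle_offset = c(0.27 * semi[1], 0, 0.19 * semi[3]),  # +/- x, y, z from centre
    ventricle_semi = c(0.12 * semi[1], 0.20 * semi[2], 0.28 * semi[3]),
    lesion_centre = centre + c(0.46 * semi[1], 0, -0.28 * semi[3])
  )
}

#' Build the tissue label volume for one timepoint
#'
#' Voxels are labelled background / gray / white / csf / lesion in that
#' precedence order (lesion overwrites gray and white but not CSF, so the
#' ventricles stay intact). The two hemispheres are exact mirror images
#' apart from the lesion; ventricles scale symmetrically.
#'
#' @param spec A [phantom_spec()].
#' @param timepoint One of `spec$timepoints`.
#' @return List with `labels` (integer array: 0 background, 1 gray,
#'   2 white, 3 csf, 4 lesion), `masks` (named list of [label_mask()]s),
#'   `bundle_direction`, `voxel_size`, and the generating spec/timepoint.
#' @export
build_label_volume <- function(spec, timepoint) {
  ti <- match(timepoint, spec$timepoints)
  if (is.na(ti)) stop(sprintf("unknown timepoint '%s'", timepoint))
  gs <- spec$grid_shape; vs <- spec$voxel_size
  geo <- phantom_geometry(gs, vs)

  x <- voxel_centres(gs[1], vs[1])
  y <- voxel_centres(gs[2], vs[2])
  z <- voxel_centres(gs[3], vs[3])
  X <- array(rep(x, times = gs[2] * gs[3]), dim = gs)
  Y <- array(rep(rep(y, each = gs[1]), times = gs[3]), dim = gs)
  Z <- array(rep(z, each = gs[1] * gs[2]), dim = gs)

  cc <- geo$centre
  brain <- ((X - cc[1]) / geo$brain_semi[1])^2 +
           ((Y - cc[2]) / geo$brain_semi[2])^2 +
           ((Z - cc[3]) / geo$brain_semi[3])^2 <= 1

  bundle <- brain &
    (((Y - geo$bundle_centre_yz[1]) / geo$bundle_radius_yz[1])^2 +
     ((Z - geo$bundle_centre_yz[2]) / geo$bundle_radius_yz[2])^2 <= 1)

  vsc <- spec$ventricle_scale[ti]^(1 / 3)  # volume scale -> linear scale
  vent <- array(FALSE, gs)
  for (side in c(-1, 1)) {
    vc <- cc + c(side * geo$ventricle_offset[1], geo$ventricle_offset[2],
                 geo$ventricle_offset[3])
    vent <- vent | (((X - vc[1]) / (geo$ventricle_semi[1] * vsc))^2 +
                    ((Y - vc[2]) / (geo$ventricle_semi[2] * vsc))^2 +
                    ((Z - vc[3]) / (geo$ventricle_semi[3] * vsc))^2 <= 1)
  }
  vent <- vent & brain

  r <- spec$lesion_radius[ti]
  lesion <- array(FALSE, gs)
  if (r > 0) {
    lc <- geo$lesion_centre
    midplane <- gs[1] / 2 * vs[1]
    if (lc[1] - r < midplane)
      stop(sprintf("lesion radius %.2f mm crosses the midsagittal plane; it must stay in one hemisphere", r))
    lesion <- (X - lc[1])^2 + (Y - lc[2])^2 + (Z - lc[3])^2 <= r^2
    if (any(lesion & !brain))
      stop(sprintf("lesion radius %.2f mm exceeds the ipsilesional hemisphere extent (lesion voxels fall outside the brain)", r))
  }

  labels <- array(0L, gs)
  labels[brain] <- 1L
  labels[bundle] <- 2L
  labels[lesion & labels %in% c(1L, 2L)] <- 4L
  labels[vent] <- 3L

  masks <- list(
    background = label_mask(labels == 0L, vs, "background"),
    gray   = label_mask(labels == 1L, vs, "gray"),
    white  = label_mask(labels == 2L, vs, "white"),
    csf    = label_mask(labels == 3L, vs, "csf"),
    lesion = label_mask(labels == 4L, vs, "lesion"),
    brain  = label_mask(labels != 0L, vs, "brain")
  )
  structure(list(labels = labels, masks = masks,
                 bundle_direction = c(1, 0, 0),
                 voxel_size = vs, spec = spec, timepoint = timepoint),
            class = "label_volume")
}

# --- forward models -------------------------------------------------------

# Tensor from eigenvalues + principal direction: completes an orthonormal
# frame around `dir` and returns R diag(ev) R^T.
tensor_from_model <- function(eigenvalues, direction) {
  e1 <- direction / sqrt(sum(direction^2))
  ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- ref - sum(ref * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  R <- cbind(e1, e2, e3)
  R %*% diag(eigenvalues) %*% t(R)
}

#' Simulate a diffusion-weighted volume
#'
#' Monoexponential tensor forward model per voxel,
#' S_i = S0 exp(-b_i g_i' D g_i), with D assembled from each tissue's
#' eigenvalues and orientation (white matter uses the bundle direction),
#' followed by Rician noise: sqrt((S + n1)^2 + n2^2) with
#' n ~ N(0, sigma^2) and sigma = S0_white / snr. `snr = Inf` gives the
#' noiseless signal.
#'
#' @param labels A `label_volume` from [build_label_volume()], or any list
#'   with `labels`, `masks`, `voxel_size` and `bundle_direction`.
#' @param tissues Named tissue set as from [default_tissues()].
#' @param scheme A [gradient_scheme()].
#' @param snr Signal-to-noise ratio (b0 white matter over sigma).
#' @param seed Integer seed; identical seeds give bit-identical volumes.
#' @param s0 b0 signal amplitude, arbitrary units (default 1000).
#' @return A `dwi_volume`: 4-D `data` (x, y, z, volume), `scheme`,
#'   `voxel_size`, `brain_mask`.
#' @export
simulate_dwi <- function(labels, tissues, scheme, snr = 30, seed = 1L, s0 = 1000) {
  if (snr <= 0) stop("snr must be positive")
  validate_scheme(scheme)
  lab <- labels$labels
  gs <- dim(lab)
  nvol <- length(scheme$bvals)
  present <- sort(unique(as.integer(lab)))
  code <- c(background = 0L, gray = 1L, white = 2L, csf = 3L, lesion = 4L)

  # Per-tissue noiseless attenuation: tissues are homogeneous, so the
  # forward model collapses to one signal vector per tissue class.
  sig <- matrix(0, nrow = 5L, ncol = nvol)  # rows indexed by code + 1
  for (nm in names(code)) {
    k <- code[[nm]]
    if (!(k %in% present)) next
    tm <- tissues[[nm]]
    if (is.null(tm)) stop(sprintf("missing tissue model for label '%s'", nm))
    if (nm == "background") { sig[k + 1L, ] <- 0; next }
    dirn <- if (nm == "white") labels$bundle_direction else tm$direction
    D <- tensor_from_model(tm$eigenvalues, dirn)
    att <- vapply(seq_len(nvol), function(j) {
      g <- scheme$bvecs[, j]
      exp(-scheme$bvals[j] * drop(t(g) %*% D %*% g))
    }, numeric(1))
    sig[k + 1L, ] <- s0 * att
  }

  data <- array(0, dim = c(gs, nvol))
  flat <- sig[as.integer(lab) + 1L, , drop = FALSE]  # nvox x nvol
  if (is.finite(snr)) {
    set.seed(seed)
    sigma <- s0 / snr
    n1 <- matrix(rnorm(length(flat), 0, sigma), nrow = nrow(flat))
    n2 <- matrix(rnorm(length(flat), 0, sigma), nrow = nrow(flat))
    flat <- sqrt((flat + n1)^2 + n2^2)
  }
  data[] <- flat
  structure(list(data = data, scheme = scheme,
                 voxel_size = labels$voxel_size,
                 brain_mask = labels$masks$brain),
            class = "dwi_volume")
}

#' Simulate a T2-weighted volume
#'
#' Gaussian intensity per tissue class around its `t2_mean` with its
#' `t2_sd`; zero-SD tissues give a piecewise-constant image. Lesion and
#' CSF are hyperintense relative to parenchyma, as on real T2-weighted
#' images of edema and ventricles.
#'
#' @inheritParams simulate_dwi
#' @return 3-D numeric array with `voxel_size` attribute.
#' @export
simulate_t2 <- function(labels, tissues, seed = 1L) {
  lab <- labels$labels
  code <- c(background = 0L, gray = 1L, white = 2L, csf = 3L, lesion = 4L)
  means <- numeric(5); sds <- numeric(5)
  for (nm in names(code)) {
    tm <- tissues[[nm]]
    if (is.null(tm)) stop(sprintf("missing tissue model for label '%s'", nm))
    if (tm$t2_sd < 0) stop("negative t2_sd")
    means[code[[nm]] + 1L] <- tm$t2_mean
    sds[code[[nm]] + 1L] <- tm$t2_sd
  }
  set.seed(seed)
  img <- array(rnorm(length(lab),
                     mean = means[as.integer(lab) + 1L],
                     sd = sds[as.integer(lab) + 1L]),
               dim = dim(lab))
  attr(img, "voxel_size") <- labels$voxel_size
  img
}
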