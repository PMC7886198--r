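# Shared fixtures: small phantoms and hand-built fields, all generated in
# code at test time.

small_spec <- function(lesion_radius = c(0.9, 0.6, 0.4), snr = Inf, seed = 3L, ...) {
  phantom_spec(grid_shape = c(32L, 32L, 8L), lesion_radius = lesion_radius,
               snr = snr, seed = seed, ...)
}

# Noiseless DWI -> eigendecomposition -> maps for a small phantom.
small_fitted <- function(spec = small_spec(), timepoint = "day1",
                         tissues = default_tissues(spec$lesion_eigenvalue_factor[
                           match(timepoint, spec$timepoints)]),
                         snr = spec$snr, seed = 1L) {
  lv <- build_label_volume(spec, timepoint)
  dwi <- simulate_dwi(lv, tissues, gradient_scheme(), snr = snr, seed = seed)
  eigs <- eigendecompose(fit_tensor(dwi))
  list(lv = lv, dwi = dwi, eigs = eigs, maps = scalar_maps(eigs))
}

# Hand-built eigenvector/FA field: a bar of high-FA voxels whose principal
# direction is x up to the bend plane and y beyond it; isotropic elsewhere.
# Used to exercise the turning-angle stopping rule in isolation.
bend_field <- function(gs = c(20L, 20L, 5L), vs = c(0.2, 0.2, 0.2),
                       bend_at = 10L, fa_in = 0.8) {
  values <- array(NA_real_, c(gs, 3L))
  vectors <- array(NA_real_, c(gs, 3L, 3L))
  fit_ok <- array(TRUE, gs)
  fa <- array(0, gs)
  bar <- expand.grid(x = seq_len(gs[1]), y = seq_len(gs[2]), z = seq_len(gs[3]))
  # L-shape: along y = 10 for x < bend_at, then along x = bend_at for y >= 10
  inbar <- (bar$y == 10L & bar$x <= bend_at) | (bar$x == bend_at & bar$y >= 10L)
  for (k in which(inbar)) {
    i <- bar$x[k]; j <- bar$y[k]; s <- bar$z[k]
    d <- if (i < bend_at) c(1, 0, 0) else c(0, 1, 0)
    vectors[i, j, s, , 1L] <- d
    vectors[i, j, s, , 2L] <- c(0, 0, 1)
    vectors[i, j, s, , 3L] <- if (d[1] == 1) c(0, 1, 0) else c(1, 0, 0)
    values[i, j, s, ] <- c(1.7, 0.2, 0.2) * 1e-3
    fa[i, j, s] <- fa_in
  }
  eigs <- structure(list(values = values, values_clamped = pmax(values, 0),
                         vectors = vectors, fit_ok = fit_ok,
                         negative = array(FALSE, gs),
                         degenerate = array(FALSE, gs), voxel_size = vs),
                    class = "tensor_eigs")
  list(eigs = eigs, fa = fa, gs = gs, vs = vs)
}

# DWI volume with one planted tensor everywhere in a box, built from the
# closed-form signal equation (independent of simulate_dwi's label
# machinery).
dwi_from_tensor_blocks <- function(tensors, block_vox = 125L,
                                   scheme = gradient_scheme(), snr = Inf,
                                   s0 = 1000, seed = 1L,
                                   vs = c(0.156, 0.156, 0.75)) {
  nb <- length(tensors)
  nvol <- length(scheme$bvals)
  side <- round(block_vox^(1 / 3))
  gs <- c(side, side, side * nb)
  data <- array(0, c(gs, nvol))
  for (k in seq_len(nb)) {
    D <- tensors[[k]]
    att <- vapply(seq_len(nvol), function(j) {
      g <- scheme$bvecs[, j]
      exp(-scheme$bvals[j] * drop(t(g) %*% D %*% g))
    }, numeric(1))
    zset <- ((k - 1) * side + 1):(k * side)
    for (j in seq_len(nvol)) data[, , zset, j] <- s0 * att[j]
  }
  if (is.finite(snr)) {
    set.seed(seed)
    sigma <- s0 / snr
    n1 <- array(rnorm(length(data), 0, sigma), dim(data))
    n2 <- array(rnorm(length(data), 0, sigma), dim(data))
    data <- sqrt((data + n1)^2 + n2^2)
  }
  structure(list(data = data, scheme = scheme, voxel_size = vs,
                 brain_mask = label_mask(array(TRUE, gs), vs, "brain")),
            class = "dwi_volume")
}

# Prolate tensor (l1, l2, l2) with prescribed FA and mean diffusivity,
# solved from the FA definition by root finding (independent oracle for
# parameter-recovery tests).
prolate_tensor_with_fa <- function(fa, md = 0.8e-3, direction = c(1, 0, 0)) {
  stopifnot(fa >= 0, fa < 1)
  if (fa == 0) return(tensor_from_model_pub(rep(md, 3), direction))
  f <- function(r) {  # r = l1/l2 >= 1
    lam <- c(r, 1, 1)
    m <- mean(lam)
    sqrt(1.5 * sum((lam - m)^2) / sum(lam^2)) - fa
  }
  r <- stats::uniroot(f, c(1 + 1e-9, 1e6), tol = 1e-14)$root
  lam <- c(r, 1, 1) * (3 * md / (r + 2))
  tensor_from_model_pub(lam, direction)
}

# Minimal reimplementation of the eigen-frame tensor assembly so helper
# fixtures do not depend on package internals.
tensor_from_model_pub <- function(eigenvalues, direction) {
  e1 <- direction / sqrt(sum(direction^2))
  ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- ref - sum(ref * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  R <- cbind(e1, e2, e3)
  R %*% diag(eigenvalues) %*% t(R)
}

ipsi_bundle_roi <- function(lv, spec) {
  hemi <- hemisphere_masks(spec$grid_shape, spec$voxel_size)
  label_mask(unclass(lv$masks$white) & unclass(hemi$ipsi), spec$voxel_size,
             "bundle_roi")
}
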