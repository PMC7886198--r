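#' Fit the diffusion tensor per voxel
#'
#' Log-linear ordinary least squares: for each in-mask voxel, ln S is
#' regressed on the design
#' `[1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz]`,
#' giving ln S0 and the six unique tensor elements. Signals are clipped
#' to a small positive floor (1e-6 of the voxel's mean b0 signal) before
#' the log so that noise excursions to zero do not produce -Inf.
#'
#' @param dwi A `dwi_volume` (from [simulate_dwi()] or [read_dwi()]).
#' @return A `tensor_field`: `D` (4-D array, last dim the elements
#'   dxx, dyy, dzz, dxy, dxz, dyz in mm^2/s), `ln_s0`, logical `fit_ok`,
#'   plus grid metadata.
#' @export
fit_tensor <- function(dwi) {
  b <- dwi$scheme$bvals
  g <- dwi$scheme$bvecs
  if (sum(b == 0) < 1L || length(b) < 7L)
    stop("need at least one b=0 volume and 7 measurements per voxel")
  bscale <- max(b)                     # condition the design: columns O(1)
  bs <- b / bscale
  X <- cbind(1,
             -bs * g[1, ]^2, -bs * g[2, ]^2, -bs * g[3, ]^2,
             -2 * bs * g[1, ] * g[2, ], -2 * bs * g[1, ] * g[3, ],
             -2 * bs * g[2, ] * g[3, ])
  qrX <- qr(X)
  if (qrX$rank < 7L)
    stop("gradient scheme is rank-deficient (collinear directions); the tensor is not identifiable")

  gs <- dim(dwi$data)[1:3]
  mask <- as.logical(dwi$brain_mask)
  idx <- which(mask)
  flat <- matrix(dwi$data, nrow = prod(gs))[idx, , drop = FALSE]  # nvox x nvol

  s0_est <- rowMeans(flat[, b == 0, drop = FALSE])
  floor_val <- pmax(1e-6 * pmax(s0_est, .Machine$double.eps), .Machine$double.xmin)
  flat <- pmax(flat, floor_val)                  # recycles by column
  beta <- qr.coef(qrX, t(log(flat)))             # 7 x nvox
  beta[2:7, ] <- beta[2:7, , drop = FALSE] / bscale

  ok <- apply(is.finite(beta), 2L, all)
  D <- array(NA_real_, dim = c(gs, 6L))
  Dm <- matrix(D, ncol = 6L)
  Dm[idx, ] <- t(beta[2:7, , drop = FALSE])
  D[] <- Dm
  ln_s0 <- array(NA_real_, dim = gs)
  ln_s0[idx] <- beta[1L, ]
  fit_ok <- array(FALSE, dim = gs)
  fit_ok[idx] <- ok
  structure(list(D = D, ln_s0 = ln_s0, fit_ok = fit_ok,
                 voxel_size = dwi$voxel_size),
            class = "tensor_field")
}

# Vectorised eigenvalues of symmetric 3x3 matrices (trigonometric form).
# Input: n x 6 matrix (dxx, dyy, dzz, dxy, dxz, dyz). Output: n x 3,
# descending. The sum of the three values equals the trace exactly.
sym3_eigenvalues <- function(m) {
  dxx <- m[, 1]; dyy <- m[, 2]; dzz <- m[, 3]
  dxy <- m[, 4]; dxz <- m[, 5]; dyz <- m[, 6]
  q <- (dxx + dyy + dzz) / 3
  p2 <- (dxx - q)^2 + (dyy - q)^2 + (dzz - q)^2 + 2 * (dxy^2 + dxz^2 + dyz^2)
  p <- sqrt(p2 / 6)
  # det of (A - q I) / p, guarding p = 0 (isotropic voxel)
  a <- dxx - q; b <- dyy - q; c <- dzz - q
  detB <- a * (b * c - dyz^2) - dxy * (dxy * c - dyz * dxz) +
    dxz * (dxy * dyz - b * dxz)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  l2 <- pmin(pmax(l2, l3), l1)   # guard roundoff from breaking the ordering
  cbind(l1, l2, l3)
}

# Eigenvector of a batch of symmetric 3x3 matrices for given eigenvalues:
# cross products of rows of (A - lambda I); the best-conditioned pair is
# used per voxel. Returns n x 3 unit vectors and a logical 'degenerate'
# flag where no well-conditioned pair exists (repeated eigenvalue).
sym3_eigenvector <- function(m, lambda) {
  r1 <- cbind(m[, 1] - lambda, m[, 4], m[, 5])
  r2 <- cbind(m[, 4], m[, 2] - lambda, m[, 6])
  r3 <- cbind(m[, 5], m[, 6], m[, 3] - lambda)
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  c12 <- cross(r1, r2); c13 <- cross(r1, r3); c23 <- cross(r2, r3)
  n12 <- rowSums(c12^2); n13 <- rowSums(c13^2); n23 <- rowSums(c23^2)
  best <- pmax(n12, n13, n23)
  v <- c12
  use13 <- n13 == best; v[use13, ] <- c13[use13, ]
  use23 <- n23 == best; v[use23, ] <- c23[use23, ]
  scale2 <- rowSums(m^2)
  degenerate <- best <= (1e-24 * pmax(scale2, .Machine$double.xmin)^2) | best == 0
  nrm <- sqrt(pmax(best, .Machine$double.xmin))
  v <- v / nrm
  v[degenerate, ] <- rep(c(1, 0, 0), each = sum(degenerate))
  list(v = v, degenerate = degenerate)
}

# Deterministic sign convention: first component of largest magnitude
# above tolerance... we fix the sign so the first nonzero component is
# positive.
fix_sign <- function(v, tol = 1e-12) {
  s <- sign(v[, 1])
  zero1 <- abs(v[, 1]) <= tol
  s[zero1] <- sign(v[zero1, 2])
  zero2 <- zero1 & abs(v[, 2]) <= tol
  s[zero2] <- sign(v[zero2, 3])
  s[s == 0] <- 1
  v * s
}

#' Eigendecompose a tensor field
#'
#' Per-voxel eigenvalues (sorted descending) and eigenvectors of the
#' fitted tensors, computed in closed form for symmetric 3x3 matrices.
#' Negative eigenvalues (possible under noise) are clamped to zero for
#' the scalar maps but the raw values are retained; affected voxels are
#' flagged. Non-finite tensors are excluded (`fit_ok` cleared).
#'
#' @param field A `tensor_field` from [fit_tensor()].
#' @return A `tensor_eigs`: `values` (4-D, last dim 3, descending; raw),
#'   `values_clamped`, `vectors` (5-D: grid x 3 components x 3
#'   eigenvectors, sign-fixed so the first nonzero component is
#'   positive), `fit_ok`, `negative` and `degenerate` flags.
#' @export
eigendecompose <- function(field) {
  gs <- dim(field$fit_ok)
  Dm <- matrix(field$D, ncol = 6L)
  ok <- as.logical(field$fit_ok) & apply(is.finite(Dm), 1L, all)
  idx <- which(ok)
  m <- Dm[idx, , drop = FALSE]

  lam <- sym3_eigenvalues(m)
  e1 <- sym3_eigenvector(m, lam[, 1])
  e3 <- sym3_eigenvector(m, lam[, 3])
  # e2 orthogonal to both; re-orthogonalise to guard near-degenerate pairs
  e2v <- cbind(e3$v[, 2] * e1$v[, 3] - e3$v[, 3] * e1$v[, 2],
               e3$v[, 3] * e1$v[, 1] - e3$v[, 1] * e1$v[, 3],
               e3$v[, 1] * e1$v[, 2] - e3$v[, 2] * e1$v[, 1])
  n2 <- sqrt(pmax(rowSums(e2v^2), .Machine$double.xmin))
  e2v <- e2v / n2

  values <- array(NA_real_, dim = c(gs, 3L))
  vm <- matrix(values, ncol = 3L); vm[idx, ] <- lam; values[] <- vm
  clamped <- values
  clamped[] <- pmax(matrix(clamped, ncol = 1), 0)

  vectors <- array(NA_real_, dim = c(gs, 3L, 3L))
  vecm <- matrix(vectors, ncol = 9L)
  vecm[idx, 1:3] <- fix_sign(e1$v)
  vecm[idx, 4:6] <- fix_sign(e2v)
  vecm[idx, 7:9] <- fix_sign(e3$v)
  vectors[] <- vecm

  fit_ok <- array(FALSE, gs); fit_ok[idx] <- TRUE
  negative <- array(FALSE, gs); negative[idx] <- lam[, 3] < 0
  degenerate <- array(FALSE, gs); degenerate[idx] <- e1$degenerate | e3$degenerate
  structure(list(values = values, values_clamped = clamped,
                 vectors = vectors, fit_ok = fit_ok,
                 negative = negative, degenerate = degenerate,
                 voxel_size = field$voxel_size),
            class = "tensor_eigs")
}

#' Scalar diffusion maps from eigenvalues
#'
#' Standard DTI indices from the (clamped) sorted eigenvalues
#' lambda1 >= lambda2 >= lambda3:
#' \describe{
#'   \item{FA}{sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||,
#'     dimensionless in \[0, 1\]; 0 by definition when all eigenvalues
#'     are zero.}
#'   \item{AD}{lambda1 (axial diffusivity, mm^2/s).}
#'   \item{RD}{(lambda2 + lambda3) / 2 (radial diffusivity, mm^2/s).}
#'   \item{MD}{(lambda1 + lambda2 + lambda3) / 3 (mean diffusivity).}
#' }
#' Voxels that are not fit are NA in every map.
#'
#' @param eigs A `tensor_eigs` from [eigendecompose()].
#' @return Named list of 3-D arrays `FA`, `AD`, `RD`, `MD`, each with
#'   attributes `kind`, `units`, `voxel_size`.
#' @export
scalar_maps <- function(eigs) {
  gs <- dim(eigs$fit_ok)
  lam <- matrix(eigs$values_clamped, ncol = 3L)
  l1 <- lam[, 1]; l2 <- lam[, 2]; l3 <- lam[, 3]
  md <- (l1 + l2 + l3) / 3
  num <- (l1 - md)^2 + (l2 - md)^2 + (l3 - md)^2
  den <- l1^2 + l2^2 + l3^2
  fa <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  fa <- pmin(pmax(fa, 0), 1)
  shape <- function(v, kind, units) {
    a <- array(v, dim = gs)
    a[!eigs$fit_ok] <- NA_real_
    attr(a, "kind") <- kind; attr(a, "units") <- units
    attr(a, "voxel_size") <- eigs$voxel_size
    a
  }
  list(FA = shape(fa, "FA", ""),
       AD = shape(l1, "AD", "mm^2/s"),
       RD = shape((l2 + l3) / 2, "RD", "mm^2/s"),
       MD = shape(md, "MD", "mm^2/s"))
}
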