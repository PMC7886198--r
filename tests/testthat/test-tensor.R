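test_that("noiseless forward-fit round trip recovers the planted tensors", {
  fit <- small_fitted(small_spec(snr = Inf), snr = Inf)
  w <- which(unclass(fit$lv$masks$white))
  lam <- matrix(fit$eigs$values, ncol = 3)[w, , drop = FALSE]
  planted <- c(1.7, 0.2, 0.2) * 1e-3
  expect_lt(max(abs(sweep(lam, 2, planted))) / max(planted), 1e-8)
  e1 <- matrix(fit$eigs$vectors[, , , , 1L], ncol = 3)[w, , drop = FALSE]
  expect_lt(max(abs(abs(e1) - rep(c(1, 0, 0), each = nrow(e1)))), 1e-8)
  # gray matter is isotropic: MD = 0.8e-3 recovered
  g <- which(unclass(fit$lv$masks$gray))
  expect_equal(unname(fit$maps$MD[g][1:5]), rep(0.8e-3, 5), tolerance = 1e-8)
})

test_that("b0-only signal (no attenuation) fits the zero tensor", {
  sch <- gradient_scheme()
  gs <- c(4L, 4L, 2L)
  data <- array(500, c(gs, length(sch$bvals)))
  dwi <- structure(list(data = data, scheme = sch, voxel_size = c(1, 1, 1),
                        brain_mask = label_mask(array(TRUE, gs), c(1, 1, 1))),
                   class = "dwi_volume")
  tf <- fit_tensor(dwi)
  expect_lt(max(abs(tf$D)), 1e-12)
  expect_equal(unique(as.vector(tf$ln_s0)), log(500), tolerance = 1e-10)
})

test_that("closed-form eigendecomposition matches the characteristic-polynomial roots", {
  set.seed(14)
  for (k in 1:50) {
    A <- matrix(rnorm(9), 3); A <- (A + t(A)) / 2
    m <- matrix(c(A[1, 1], A[2, 2], A[3, 3], A[1, 2], A[1, 3], A[2, 3]), 1)
    lam <- strokedti:::sym3_eigenvalues(m)
    # oracle: roots of det(A - x I) via polyroot
    cp <- c(-det(A),
            A[1, 1] * A[2, 2] + A[1, 1] * A[3, 3] + A[2, 2] * A[3, 3] -
              A[1, 2]^2 - A[1, 3]^2 - A[2, 3]^2,
            -sum(diag(A)), 1)
    roots <- sort(Re(polyroot(cp)), decreasing = TRUE)
    expect_equal(as.vector(lam), roots, tolerance = 1e-10)
    v1 <- strokedti:::sym3_eigenvector(m, lam[, 1])$v
    expect_lt(max(abs(A %*% t(v1) - lam[1, 1] * t(v1))), 1e-8)
  }
})

test_that("eigenvalues are rotation invariant and sorted descending", {
  D <- diag(c(1.7, 0.2, 0.2) * 1e-3)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Dr <- R %*% D %*% t(R)
  m <- rbind(c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3]),
             c(Dr[1, 1], Dr[2, 2], Dr[3, 3], Dr[1, 2], Dr[1, 3], Dr[2, 3]))
  lam <- strokedti:::sym3_eigenvalues(m)
  expect_equal(lam[1, ], lam[2, ], tolerance = 1e-6)
  expect_true(all(diff(lam[1, ]) <= 0))
  expect_true(all(diff(lam[2, ]) <= 0))
})

test_that("scalar map formulas hit their limiting cases and the direct oracle", {
  mk_eigs <- function(lam) {
    gs <- c(1L, 1L, 1L)
    structure(list(values = array(lam, c(gs, 3)),
                   values_clamped = array(pmax(lam, 0), c(gs, 3)),
                   vectors = array(diag(3), c(gs, 3, 3)),
                   fit_ok = array(TRUE, gs), negative = array(FALSE, gs),
                   degenerate = array(FALSE, gs), voxel_size = c(1, 1, 1)),
              class = "tensor_eigs")
  }
  iso <- scalar_maps(mk_eigs(c(1, 1, 1)))
  expect_equal(as.vector(iso$FA), 0)
  expect_equal(as.vector(iso$AD), 1); expect_equal(as.vector(iso$RD), 1)
  expect_equal(as.vector(iso$MD), 1)
  stick <- scalar_maps(mk_eigs(c(1, 0, 0)))
  expect_equal(as.vector(stick$FA), 1)
  expect_equal(as.vector(stick$RD), 0)
  zero <- scalar_maps(mk_eigs(c(0, 0, 0)))
  expect_equal(as.vector(zero$FA), 0)
  lam <- c(1.7, 0.2, 0.2) * 1e-3
  oracle <- sqrt(3 / 2) * sqrt(sum((lam - mean(lam))^2)) / sqrt(sum(lam^2))
  expect_equal(as.vector(scalar_maps(mk_eigs(lam))$FA), oracle, tolerance = 1e-12)
  # scale invariance of FA
  expect_equal(as.vector(scalar_maps(mk_eigs(lam * 3.7))$FA), oracle,
               tolerance = 1e-12)
})

test_that("map invariants hold on a noisy phantom", {
  fit <- small_fitted(small_spec(snr = 30, seed = 8L), snr = 30, seed = 8L)
  ok <- fit$eigs$fit_ok
  expect_true(all(fit$maps$FA[ok] >= 0 & fit$maps$FA[ok] <= 1))
  expect_true(all(fit$maps$AD[ok] >= fit$maps$RD[ok]))
  # MD from eigenvalues equals trace(D)/3 computed without eigendecomposition
  tf <- fit_tensor(fit$dwi)
  tr3 <- (tf$D[, , , 1] + tf$D[, , , 2] + tf$D[, , , 3]) / 3
  raw_md <- (fit$eigs$values[, , , 1] + fit$eigs$values[, , , 2] +
               fit$eigs$values[, , , 3]) / 3
  expect_lt(max(abs(tr3[ok] - raw_md[ok])), 1e-10)
  # median FA error in white matter < 0.05 against the planted value
  w <- unclass(fit$lv$masks$white)
  lam_p <- c(1.7, 0.2, 0.2) * 1e-3
  fa_planted <- sqrt(1.5 * sum((lam_p - mean(lam_p))^2) / sum(lam_p^2))
  expect_lt(median(abs(fit$maps$FA[w] - fa_planted)), 0.05)
})

test_that("non-finite tensors are flagged and excluded", {
  fit <- small_fitted(small_spec(snr = Inf), snr = Inf)
  tf <- fit_tensor(fit$dwi)
  tf$D[5, 5, 4, 2] <- NaN
  ei <- eigendecompose(tf)
  expect_false(ei$fit_ok[5, 5, 4])
  expect_true(is.na(scalar_maps(ei)$FA[5, 5, 4]))
})
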