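#' Gaussian generalized estimating equations
#'
#' Marginal linear model for clustered longitudinal outcomes, fitted by
#' iteratively reweighted estimating equations with a working
#' correlation (exchangeable or independence) and a cluster-robust
#' sandwich covariance. With the independence structure and one
#' observation per cluster the estimator reduces exactly to ordinary
#' least squares.
#'
#' The default covariance applies the Mancl-DeRouen bias correction
#' (leverage-adjusted cluster residuals), which removes the downward
#' bias of the plain sandwich when the number of clusters is small —
#' the typical situation in rodent cohorts (around 18 animals here).
#' The uncorrected sandwich is available via `cov_type = "robust"`.
#'
#' @param formula Model formula, e.g. `value ~ group * timepoint`.
#' @param id Cluster identifier (subject), evaluated in `data`; may be a
#'   column name (character) or a vector.
#' @param data Data frame.
#' @param corstr Working correlation: `"exchangeable"` or `"independence"`.
#' @param cov_type `"bias_corrected"` (Mancl-DeRouen, default) or
#'   `"robust"` (plain sandwich).
#' @param maxit,tol IREE iteration control.
#' @return A `gee_fit`: coefficients, robust `vcov`, naive `vcov_naive`,
#'   working correlation `alpha`, dispersion `phi`, `n_clusters`,
#'   residuals, model frame bookkeeping.
#' @export
gee_fit <- function(formula, id, data,
                    corstr = c("exchangeable", "independence"),
                    cov_type = c("bias_corrected", "robust"),
                    maxit = 50L, tol = 1e-10) {
  corstr <- match.arg(corstr)
  cov_type <- match.arg(cov_type)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (is.character(id) && length(id) == 1L) id <- data[[id]]
  id <- as.character(id)
  if (length(id) != length(y)) stop("cluster id length must match the data")
  p <- ncol(X)
  if (qr(X)$rank < p) stop("singular design matrix; check factor coding")
  cl <- split(seq_along(y), id)
  K <- length(cl)
  Xc <- lapply(cl, function(i) X[i, , drop = FALSE])
  yc <- lapply(cl, function(i) y[i])

  beta <- stats::coef(stats::lm.fit(X, y))
  alpha <- 0; phi <- 1
  for (it in seq_len(maxit)) {
    e <- y - drop(X %*% beta)
    phi <- sum(e^2) / (length(y) - p)
    if (corstr == "exchangeable") {
      num <- 0; nstar <- 0
      for (i in seq_len(K)) {
        ei <- e[cl[[i]]]
        ni <- length(ei)
        if (ni > 1L) {
          num <- num + (sum(ei)^2 - sum(ei^2)) / 2
          nstar <- nstar + ni * (ni - 1) / 2
        }
      }
      alpha <- if (nstar > p) num / (phi * (nstar - p)) else 0
      nmax <- max(lengths(cl))
      alpha <- min(max(alpha, -1 / max(nmax - 1, 1) + 1e-6), 1 - 1e-6)
    }
    A <- matrix(0, p, p); bvec <- numeric(p)
    for (i in seq_len(K)) {
      Xi <- Xc[[i]]; ni <- nrow(Xi)
      Rinv <- exch_inverse(ni, if (corstr == "exchangeable") alpha else 0)
      XtR <- crossprod(Xi, Rinv)
      A <- A + XtR %*% Xi
      bvec <- bvec + XtR %*% yc[[i]]
    }
    beta_new <- drop(solve(A, bvec))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol * max(1, max(abs(beta)))) break
  }
  if (it == maxit && delta >= tol * max(1, max(abs(beta))))
    stop(sprintf("GEE did not converge in %d iterations (last step %.3g)", maxit, delta))

  # sandwich: B^-1 M B^-1 with V_i = phi * R_i(alpha)
  e <- y - drop(X %*% beta)
  a_use <- if (corstr == "exchangeable") alpha else 0
  B <- matrix(0, p, p)
  for (i in seq_len(K)) {
    Xi <- Xc[[i]]
    B <- B + crossprod(Xi, exch_inverse(nrow(Xi), a_use)) %*% Xi / phi
  }
  Binv <- solve(B)
  M <- matrix(0, p, p)
  for (i in seq_len(K)) {
    Xi <- Xc[[i]]; ni <- nrow(Xi)
    Vinv <- exch_inverse(ni, a_use) / phi
    ei <- e[cl[[i]]]
    if (cov_type == "bias_corrected") {
      Hii <- Xi %*% Binv %*% t(Xi) %*% Vinv
      ei <- drop(solve(diag(ni) - Hii, ei))
    }
    u <- crossprod(Xi, Vinv %*% ei)
    M <- M + tcrossprod(u)
  }
  vcov_rob <- Binv %*% M %*% Binv
  names(beta) <- colnames(X)
  dimnames(vcov_rob) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, vcov = vcov_rob, vcov_naive = Binv,
                 alpha = if (corstr == "exchangeable") alpha else 0,
                 phi = phi, n_clusters = K, corstr = corstr,
                 cov_type = cov_type, iterations = it,
                 residuals = e, formula = formula, terms = stats::terms(mf),
                 X = X),
            class = "gee_fit")
}

# Closed-form inverse of the exchangeable correlation matrix
# (1-a) I + a J for cluster size n.
exch_inverse <- function(n, a) {
  if (n == 1L) return(matrix(1, 1, 1))
  d <- 1 - a
  denom <- d * (1 + (n - 1) * a)
  diag(n) / d - matrix(a / (d * denom), n, n)
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("Gaussian GEE (%s working correlation, %s covariance)\n",
              x$corstr, x$cov_type))
  cat(sprintf("  %d clusters, alpha = %.3f, phi = %.4g, %d iterations\n",
              x$n_clusters, x$alpha, x$phi, x$iterations))
  print(cbind(estimate = x$coefficients,
              robust_se = sqrt(diag(x$vcov))))
  invisible(x)
}

#' GEE treatment-by-time interaction test
#'
#' Fits `value ~ group * timepoint` with subjects as clusters and tests
#' the full block of group x timepoint interaction coefficients with a
#' joint Wald test on the robust covariance. The default reference
#' distribution is F(q, K - p) with K the number of clusters and p the
#' number of regression parameters, which together with the
#' bias-corrected sandwich holds the test close to its nominal level
#' with the small cluster counts typical of animal studies;
#' `wald = "chisq"` gives the asymptotic chi-square version.
#'
#' @param data Data frame with columns `subject`, `group`, `timepoint`
#'   and the outcome.
#' @param outcome Outcome column name (default `"value"`).
#' @param working_correlation `"exchangeable"` (default) or
#'   `"independence"`.
#' @param wald `"f"` (default, small-sample) or `"chisq"`.
#' @param ... Passed to [gee_fit()] (e.g. `cov_type`).
#' @return A one-row data frame: `contrast`, `stat`, `df1`, `df2`
#'   (NA for chi-square), `p`; the fitted model as attribute `fit`.
#' @export
gee_interaction <- function(data, outcome = "value",
                            working_correlation = c("exchangeable", "independence"),
                            wald = c("f", "chisq"), ...) {
  working_correlation <- match.arg(working_correlation)
  wald <- match.arg(wald)
  need <- c("subject", "group", "timepoint", outcome)
  if (!all(need %in% names(data)))
    stop(sprintf("data needs columns %s", paste(need, collapse = ", ")))
  data <- data.frame(subject = as.character(data$subject),
                     group = factor(data$group),
                     timepoint = factor(data$timepoint),
                     value = data[[outcome]])
  if (anyDuplicated(data[c("subject", "timepoint")]))
    stop("each (subject, timepoint) may appear only once")
  if (nlevels(data$group) < 2L || nlevels(data$timepoint) < 2L)
    stop("interaction testing needs >= 2 groups and >= 2 timepoints")
  fit <- gee_fit(value ~ group * timepoint, id = data$subject, data = data,
                 corstr = working_correlation, ...)
  which_int <- grep(":", names(fit$coefficients))
  q <- length(which_int)
  b <- fit$coefficients[which_int]
  V <- fit$vcov[which_int, which_int, drop = FALSE]
  W <- drop(t(b) %*% solve(V, b))
  if (wald == "chisq") {
    out <- data.frame(contrast = "group:timepoint", stat = W, df1 = q,
                      df2 = NA_real_, p = stats::pchisq(W, q, lower.tail = FALSE))
  } else {
    df2 <- fit$n_clusters - length(fit$coefficients)
    if (df2 < 1) stop("too few clusters for the F reference; use wald = 'chisq'")
    out <- data.frame(contrast = "group:timepoint", stat = W / q, df1 = q,
                      df2 = df2, p = stats::pf(W / q, q, df2, lower.tail = FALSE))
  }
  attr(out, "fit") <- fit
  out
}

#' One-way ANOVA with Tukey HSD post-hoc
#'
#' Cross-sectional group comparison at a single timepoint: the overall
#' F test plus all pairwise Tukey honestly-significant-difference
#' contrasts (studentized-range adjustment). In the full pipeline this
#' is run only when the GEE interaction gate is significant.
#'
#' @param values Numeric outcome.
#' @param group Group factor (>= 2 levels, >= 2 observations each).
#' @return List with `anova` (one-row data frame: F, df1, df2, p) and
#'   `tukey` (data frame: contrast, diff, lwr, upr, p_adj).
#' @export
anova_tukey <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  tab <- table(group)
  if (any(tab < 2L))
    stop(sprintf("every group needs >= 2 observations (smallest has %d)", min(tab)))
  if (length(values) != length(group)) stop("values and group lengths differ")
  within_var <- stats::ave(values, group, FUN = function(v) v - mean(v))
  if (sum(within_var^2) <= .Machine$double.eps * sum(values^2)) {
    warning("zero within-group variance: F is unbounded; p reported as 0")
    lev <- levels(group)
    pairs <- utils::combn(lev, 2)
    gm <- tapply(values, group, mean)
    tuk <- data.frame(contrast = paste(pairs[2, ], pairs[1, ], sep = "-"),
                      diff = gm[pairs[2, ]] - gm[pairs[1, ]],
                      lwr = NA_real_, upr = NA_real_,
                      p_adj = as.numeric(gm[pairs[2, ]] == gm[pairs[1, ]]))
    rownames(tuk) <- NULL
    return(list(anova = data.frame(F = Inf, df1 = nlevels(group) - 1L,
                                   df2 = length(values) - nlevels(group),
                                   p = 0),
                tukey = tuk))
  }
  dat <- data.frame(y = values, g = group)
  fit <- stats::aov(y ~ g, data = dat)
  an <- summary(fit)[[1]]
  th <- stats::TukeyHSD(fit)$g
  list(anova = data.frame(F = an[1, "F value"], df1 = an[1, "Df"],
                          df2 = an[2, "Df"], p = an[1, "Pr(>F)"]),
       tukey = data.frame(contrast = rownames(th), diff = th[, "diff"],
                          lwr = th[, "lwr"], upr = th[, "upr"],
                          p_adj = th[, "p adj"], row.names = NULL))
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Equal-length numeric vectors (n >= 3, finite).
#' @return One-row data frame: `r`, `n`, `t`, `df`, `p` (two-sided).
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  data.frame(r = unname(ct$estimate), n = length(x),
             t = unname(ct$statistic), df = unname(ct$parameter),
             p = ct$p.value)
}
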