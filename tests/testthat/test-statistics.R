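sim_long <- function(n_per_group = 6L, rho = 0.5, effect = 0, seed = 1L) {
  # three arms, three timepoints, exchangeable within-subject correlation;
  # `effect` adds a progressive improvement to the SS arm only
  set.seed(seed)
  subj <- sprintf("s%02d", seq_len(3 * n_per_group))
  grp <- rep(c("PBS-only", "FBS-hMSCs", "SS-hMSCs"), each = n_per_group)
  d <- expand.grid(subject = subj, timepoint = c("day1", "wk2", "wk5"),
                   stringsAsFactors = FALSE)
  d$group <- grp[match(d$subject, subj)]
  b <- stats::rnorm(length(subj), 0, sqrt(rho))
  d$value <- b[match(d$subject, subj)] + stats::rnorm(nrow(d), 0, sqrt(1 - rho))
  tshift <- c(day1 = 0, wk2 = 1, wk5 = 2)[d$timepoint]
  d$value <- d$value - effect * tshift * (d$group == "SS-hMSCs")
  d
}

test_that("GEE with independence working correlation degenerates to OLS", {
  set.seed(2)
  d <- data.frame(subject = sprintf("s%d", 1:40),
                  group = rep(c("A", "B"), 20),
                  x = rnorm(40))
  d$value <- 1 + 0.5 * d$x + (d$group == "B") + rnorm(40)
  fit <- gee_fit(value ~ group + x, id = "subject", data = d,
                 corstr = "independence")
  ols <- lm(value ~ group + x, data = d)
  expect_lt(max(abs(fit$coefficients - coef(ols))), 1e-8)
  # one observation per cluster: exchangeable alpha is unidentifiable -> OLS too
  fit2 <- gee_fit(value ~ group + x, id = "subject", data = d,
                  corstr = "exchangeable")
  expect_lt(max(abs(fit2$coefficients - coef(ols))), 1e-8)
})

test_that("GEE interaction test detects the planted treatment-by-time effect", {
  d <- sim_long(effect = 1.5, seed = 33L)
  res <- gee_interaction(d)
  expect_lt(res$p, 0.01)
  # moderate power check at the generator's planted effect size
  hits <- vapply(1:40, function(k)
    gee_interaction(sim_long(effect = 1.5, seed = 100 + k))$p < 0.05, logical(1))
  expect_gt(mean(hits), 0.8)
  # null interaction is usually not rejected
  d0 <- sim_long(effect = 0, seed = 9L)
  expect_gt(gee_interaction(d0)$p, 0.05)
})

test_that("GEE guards its preconditions", {
  d <- sim_long()
  dup <- rbind(d, d[1, ])
  expect_error(gee_interaction(dup), "only once")
  one_tp <- d[d$timepoint == "day1", ]
  expect_error(gee_interaction(one_tp), ">= 2")
  expect_error(gee_fit(value ~ group + I(2 * (group == "SS-hMSCs")),
                       id = "subject", data = d), "singular")
})

test_that("two-group Tukey equals the pooled two-sample t-test", {
  set.seed(4)
  v <- c(rnorm(8, 0), rnorm(9, 0.8)); g <- rep(c("a", "b"), c(8, 9))
  tk <- anova_tukey(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_lt(abs(tk$tukey$p_adj - tt$p.value), 1e-6)
  expect_lt(abs(tk$anova$p - tt$p.value), 1e-10)
})

test_that("Tukey p-values are invariant to relabeling and location shifts", {
  set.seed(5)
  v <- rnorm(18); g <- rep(c("a", "b", "c"), 6)
  base <- anova_tukey(v, g)
  relab <- anova_tukey(v, factor(g, levels = c("c", "a", "b")))
  expect_equal(sort(base$tukey$p_adj), sort(relab$tukey$p_adj), tolerance = 1e-12)
  shift <- anova_tukey(v + 100, g)
  expect_equal(base$tukey$p_adj, shift$tukey$p_adj, tolerance = 1e-9)
  expect_error(anova_tukey(v[1:7], rep(c("a", "b"), c(6, 1))), ">= 2 observations")
})

test_that("degenerate zero-variance groups are flagged with p = 0", {
  expect_warning(res <- anova_tukey(rep(c(1, 2, 3), each = 3),
                                    rep(c("a", "b", "c"), each = 3)),
                 "zero within-group variance")
  expect_equal(res$anova$p, 0)
  expect_true(all(res$tukey$p_adj == 0))
})

test_that("Tukey family-wise error on a 3-group null stays at its nominal level", {
  set.seed(6)
  fwer <- mean(replicate(1000, {
    v <- rnorm(18); g <- rep(c("a", "b", "c"), each = 6)
    any(anova_tukey(v, g)$tukey$p_adj < 0.05)
  }))
  expect_gt(fwer, 0.03); expect_lt(fwer, 0.07)
})

test_that("Pearson correlation matches the direct covariance formula", {
  expect_equal(pearson_cor(1:10, 2 * (1:10) + 1)$r, 1.0)
  expect_equal(pearson_cor(1:10, -(1:10))$r, -1.0)
  set.seed(7)
  x <- rnorm(12); y <- rnorm(12)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearson_cor(x, y)
  expect_equal(res$r, r_direct, tolerance = 1e-12)
  # affine invariance and bounds
  expect_equal(pearson_cor(3 * x + 5, 0.1 * y - 2)$r, r_direct, tolerance = 1e-12)
  expect_lte(abs(res$r), 1)
  expect_error(pearson_cor(1:3, 1:4), "equal length")
  expect_error(pearson_cor(c(1, NA, 3), c(1, 2, 3)), "finite")
})
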