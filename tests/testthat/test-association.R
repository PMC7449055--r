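test_that("noiseless fits recover exact effects; degenerate markers handled", {
  g <- rep(0:2, length.out = 10)
  fit <- fit_marker_model(2 * g, g)
  expect_equal(fit$beta, 2)
  expect_lt(fit$p, 1e-12)
  mono <- fit_marker_model(rnorm(10), rep(1, 10))
  expect_equal(mono$reason, "monomorphic")
  expect_true(is.na(mono$p))
})

test_that("betas and SEs match a normal-equations oracle to 1e-10", {
  set.seed(21)
  n <- 8
  x1 <- rnorm(n)
  g <- sample(0:2, n, replace = TRUE)
  y <- 1 + 0.5 * x1 - 0.8 * g + rnorm(n)
  fit <- fit_marker_model(y, g, data.frame(x1 = x1))
  X <- cbind(1, x1, g)
  XtXi <- solve(t(X) %*% X)
  beta_hat <- XtXi %*% t(X) %*% y
  resid <- y - X %*% beta_hat
  s2 <- sum(resid^2) / (n - 3)
  expect_equal(fit$beta, beta_hat[3], tolerance = 1e-10)
  expect_equal(fit$se, sqrt(s2 * XtXi[3, 3]), tolerance = 1e-10)
  # variance explained: drop in SSE relative to covariate-adjusted SST
  sse_red <- sum(lm.fit(cbind(1, x1), y)$residuals^2)
  expect_equal(fit$var_explained_pct,
               100 * (sse_red - sum(resid^2)) / sse_red, tolerance = 1e-10)
})

test_that("REML variance ratio of zero reproduces the fixed-effects fit", {
  n_grp <- 6
  y <- rep(c(-1, 0.2, 0.8), n_grp)          # identical group means
  g <- rep(c(0, 1, 2), n_grp)
  grp <- rep(letters[1:n_grp], each = 3)
  fr <- fit_marker_model(y, g, random_group = grp)
  expect_equal(fr$lambda, 0)
  ff <- fit_marker_model(y, g)
  expect_equal(fr$beta, ff$beta, tolerance = 1e-8)
  expect_equal(fr$se, ff$se, tolerance = 1e-8)
})

test_that("REML fit agrees with the mixed-model reference implementation", {
  skip_if_not_installed("lme4")
  set.seed(31)
  n_grp <- 12; per <- 8
  grp <- rep(paste0("s", 1:n_grp), each = per)
  u <- rnorm(n_grp, 0, 0.7)
  g <- sample(0:2, n_grp * per, replace = TRUE)
  x1 <- rnorm(n_grp * per)
  y <- 1 + 0.4 * g + 0.3 * x1 + u[as.integer(factor(grp))] + rnorm(n_grp * per)
  fit <- fit_marker_model(y, g, data.frame(x1 = x1), random_group = grp)
  lf <- lme4::lmer(y ~ x1 + g + (1 | grp), REML = TRUE)
  expect_equal(fit$beta, unname(lme4::fixef(lf)["g"]), tolerance = 1e-4)
  expect_equal(fit$se, coef(summary(lf))["g", "Std. Error"],
               tolerance = 1e-3)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$lambda, vc$vcov[1] / vc$vcov[2], tolerance = 1e-3)
})

test_that("LD r2: identity, allele-flip invariance, symmetry, hand value", {
  g1 <- c(0, 0, 1, 1, 2, 2)
  g2 <- c(0, 1, 0, 1, 2, 2)
  expect_equal(ld_r2(g1, g1), 1)
  expect_equal(ld_r2(g1, 2 - g1), 1)
  expect_equal(ld_r2(g1, g2), cor(g1, g2)^2)
  expect_equal(ld_r2(g1, g2), ld_r2(g2, g1))
  expect_true(is.na(ld_r2(g1, rep(1, 6))))
})

test_that("Kruskal-Wallis: hand-computed H, tie guard, permutation oracle", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-12)
  same <- kruskal_wallis(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_gt(same$p, 0.5)
  tied <- kruskal_wallis(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(tied$H, 0)
  expect_equal(tied$p, 1)

  # exact permutation oracle at n = 9, 3 groups of 3 (frozen fixture with
  # moderate group separation; the chi-square reference is an approximation
  # whose error grows in the far tail at this sample size)
  vals <- c(-0.50, 0.13, -0.08, 1.69, 0.92, 1.12, 1.02, 2.31, 0.77)
  groups <- rep(1:3, each = 3)
  h_obs <- kruskal_wallis(vals, groups)$H
  h_of <- function(assign) kruskal_wallis(vals, assign)$H
  hs <- c()
  for (i1 in asplit(combn(9, 3), 2)) {
    rest <- setdiff(1:9, i1)
    for (i2 in asplit(combn(rest, 3), 2)) {
      assign <- integer(9)
      assign[i1] <- 1; assign[i2] <- 2; assign[setdiff(rest, i2)] <- 3
      hs <- c(hs, h_of(assign))
    }
  }
  p_perm <- mean(hs >= h_obs - 1e-12)
  expect_lt(abs(kruskal_wallis(vals, groups)$p - p_perm), 0.02)
})

test_that("genotype class summaries report n, mean, SE and median", {
  s <- genotype_class_summary(c(1, 2, 3, 10, 20), c(0, 0, 0, 2, 2))
  expect_equal(s$mean, c(2, 15))
  expect_equal(s$se[1], 1 / sqrt(3))
  expect_equal(s$median, c(2, 15))
  expect_equal(s$dosage, c(0, 2))   # empty class omitted
  one <- genotype_class_summary(c(1, 2), c(1, 1))
  expect_equal(nrow(one), 1)
})

test_that("Bonferroni thresholds reproduce closed forms", {
  expect_equal(bonferroni_threshold(0.05, 3128 * 14), 0.05 / 43792)
  expect_equal(bonferroni_threshold(0.05, 12), 0.05 / 12)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0))
})

test_that("marker ranking breaks ties by position then id and matches a sort oracle", {
  r <- data.frame(marker = c("a", "b", "c"), pos = c(5, 1, 3),
                  p = c(1e-8, 1e-3, 1e-8))
  expect_equal(rank_markers(r)$rank, c(2L, 3L, 1L))
  req <- data.frame(marker = c("a", "b", "c"), pos = c(9, 2, 5),
                    p = rep(0.5, 3))
  expect_equal(rank_markers(req)$rank, c(3L, 1L, 2L))
  set.seed(8)
  rr <- data.frame(marker = sprintf("m%03d", 1:100),
                   pos = sample.int(1e6, 100), p = runif(100))
  got <- rank_markers(rr)$rank
  want <- order(order(rr$p, rr$pos, rr$marker))
  expect_equal(got, want)
  rna <- data.frame(marker = c("a", "b"), pos = 1:2, p = c(NA, 0.5))
  expect_equal(rank_markers(rna)$rank, c(NA_integer_, 1L))
})

test_that("conditioning on the causal marker silences its perfect proxies", {
  set.seed(12)
  n <- 80
  g <- sample(0:2, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  gm <- genotype_matrix(
    sprintf("s%02d", 1:n),
    data.frame(id = c("causal", "proxy", "flip"),
               chrom = "c1", pos = c(10, 20, 30),
               ref = "A", alt = "G"),
    cbind(g, g, 2 - g))
  y <- setNames(1 + 0.9 * g + rnorm(n, 0, 0.5), sprintf("s%02d", 1:n))
  plain <- scan_markers(y, gm)
  expect_true(all(plain$p < 1e-6))
  cond <- scan_markers(y, gm, condition_on = "causal")
  expect_equal(cond$reason[cond$marker == "causal"], "conditioned")
  expect_true(all(cond$p[cond$marker != "causal"] > 0.99))
  expect_equal(cond$reason[cond$marker != "causal"], rep("aliased", 2))
})

test_that("scan under the null is calibrated (uniform p, type-I error)", {
  set.seed(77)
  n <- 200; m <- 400
  dos <- matrix(rbinom(n * m, 2, 0.4), n, m)
  gm <- genotype_matrix(sprintf("s%03d", 1:n),
                        data.frame(id = sprintf("m%03d", 1:m), chrom = "c1",
                                   pos = seq_len(m), ref = "A", alt = "G"),
                        dos)
  y <- setNames(rnorm(n), sprintf("s%03d", 1:n))
  res <- scan_markers(y, gm)
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
  expect_gte(mean(res$p < 0.05), 0.02)
  expect_lte(mean(res$p < 0.05), 0.08)
})

test_that("rank-deficient covariates raise an informative error", {
  set.seed(1)
  x <- rnorm(20)
  expect_error(
    fit_marker_model(rnorm(20), sample(0:2, 20, TRUE),
                     data.frame(a = x, b = 2 * x)),
    "rank-deficient")
})

test_that("missing dosages are dropped pairwise per marker", {
  set.seed(6)
  g <- sample(0:2, 40, replace = TRUE)
  y <- 0.5 * g + rnorm(40, 0, 0.1)
  g[c(3, 7)] <- NA
  fit <- fit_marker_model(y, g)
  expect_equal(fit$n, 38)
  expect_equal(fit$beta, 0.5, tolerance = 0.05)
})
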