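test_that("group t tests match the pooled-variance formula oracle", {
  a <- c(1, 2, 3)
  expect_equal(group_ttest(a, a)$value, 0)
  paired_null <- group_ttest(a, a, paired = TRUE)
  expect_equal(paired_null$value, 0)
  expect_equal(paired_null$p, 1)

  set.seed(1)
  x <- rnorm(14); y <- rnorm(11, 0.5)
  res <- group_ttest(x, y, family_size = 3)
  sp2 <- ((13 * var(x) + 10 * var(y)) / 23)
  t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 14 + 1 / 11))
  expect_lt(abs(res$value - t_oracle), 1e-10)
  expect_equal(res$dof, 23)
  expect_equal(res$alpha_adjusted, 0.05 / 3)
  expect_lt(abs(res$p - 2 * pt(-abs(t_oracle), 23)), 1e-12)
  expect_error(group_ttest(c(1, 1), c(2, 2)), "zero variance")
})

test_that("one-sample t test matches its formula and rejects degenerate input", {
  v <- c(-2, -1, 1, 2) + 5
  expect_equal(one_sample_ttest(v, mu = 5)$value, 0)
  expect_error(one_sample_ttest(c(1, 1, 1), mu = 1), "zero variance")
  set.seed(2)
  z <- rnorm(10, 0.4)
  res <- one_sample_ttest(z)
  expect_lt(abs(res$value - mean(z) / (sd(z) / sqrt(10))), 1e-10)
})

test_that("Spearman correlation matches the rank-then-Pearson construction", {
  x <- 1:10
  expect_equal(spearman_cor(x, x)$value, 1)
  expect_equal(spearman_cor(x, rev(x))$value, -1)
  set.seed(3)
  a <- rnorm(25); b <- rnorm(25)
  res <- spearman_cor(a, b)
  oracle <- cor.test(a, b, method = "spearman", exact = FALSE)
  expect_lt(abs(res$value - unname(oracle$estimate)), 1e-12)
  # t-approximation p also matches rank-then-Pearson cor.test
  p_oracle <- cor.test(rank(a), rank(b))$p.value
  expect_lt(abs(res$p - p_oracle), 1e-10)
})

test_that("partial correlation matches the residual-on-residual oracle", {
  set.seed(4)
  n <- 30
  cov1 <- rnorm(n)
  x <- rnorm(n)
  y <- 0.5 * x + 0.8 * cov1 + rnorm(n, sd = 0.3)
  res <- partial_correlation(y, x, cov1)
  # Frisch-Waugh: regress covariate out of both y and x, then regress
  ry <- resid(lm(y ~ cov1)); rx <- resid(lm(x ~ cov1))
  slope <- coef(lm(ry ~ rx))[2]
  expect_lt(abs(res$value - slope), 1e-8)

  # covariate uncorrelated with both: matches the simple regression slope
  cov0 <- resid(lm(rnorm(n) ~ x + y))
  res0 <- partial_correlation(y, x, cov0)
  expect_lt(abs(res0$value - coef(lm(y ~ x))[2]), 1e-8)

  # y fully determined by the covariate
  y2 <- 2 * cov1
  res2 <- suppressWarnings(partial_correlation(y2, x, cov1))
  expect_lt(abs(res2$value), 1e-10)
  expect_error(partial_correlation(y, x, 2 * x), "collinear")
})

test_that("mixed ANOVA matches a definitional sums-of-squares oracle", {
  # balanced two-group, two-area design computed from first principles
  set.seed(5)
  n_per <- 10
  subj <- rep(1:(2 * n_per), each = 2)
  grp <- rep(rep(c("g1", "g2"), each = n_per), each = 2)
  area <- rep(c("A", "B"), times = 2 * n_per)
  val <- rnorm(4 * n_per) + ifelse(grp == "g2" & area == "B", 1.5, 0)
  res <- mixed_anova(val, grp, area, subj)

  m <- tapply(val, list(grp, area), mean)
  gm <- mean(val)
  ss_int <- n_per * sum((m - outer(rowMeans(m) - gm, colMeans(m) - gm, "+") - gm)^2)
  subj_mean <- tapply(val, subj, mean)
  d <- val - subj_mean[as.character(subj)]
  area_eff <- tapply(d, area, mean)
  cell_eff <- tapply(d, list(grp, area), mean)
  resid_w <- d - cell_eff[cbind(grp, area)]
  ss_resid <- sum(resid_w^2)
  df_resid <- (2 * n_per - 2) * 1
  F_oracle <- (ss_int / 1) / (ss_resid / df_resid)
  expect_lt(abs(res$value - F_oracle) / F_oracle, 1e-8)
  expect_equal(res$dof, c(1, df_resid))

  # power: interaction injected in one group only is detected
  expect_lt(res$p, 0.05)
  # no interaction: F small on average
  val0 <- rnorm(4 * n_per) + ifelse(area == "B", 1, 0)
  res0 <- mixed_anova(val0, grp, area, subj)
  expect_gt(res0$p, 0.01)

  expect_error(mixed_anova(val[-1], grp[-1], area[-1], subj[-1]),
               "missing cells")
})

test_that("Mann-Whitney U is exact for small samples and handles structure", {
  a <- c(10, 11, 12); b <- c(1, 2, 3, 4)
  expect_equal(mann_whitney(a, b)$value, 12)  # complete separation: n_a*n_b
  set.seed(6)
  for (i in 1:10) {
    x <- rnorm(3); y <- rnorm(9)
    res <- mann_whitney(x, y)
    expect_lt(abs(res$p - mw_enum_p(x, y)), 1e-12)
  }
})

test_that("ICC consistency matches the ANOVA variance-components oracle", {
  s1 <- c(9, 6, 8, 7, 10, 6)
  expect_equal(icc_consistency(s1, s1)$icc, 1)

  set.seed(7)
  x1 <- rnorm(2000); x2 <- rnorm(2000)
  expect_lt(abs(icc_consistency(x1, x2)$icc), 0.05)

  y1 <- rnorm(14); y2 <- 0.8 * y1 + rnorm(14, sd = 0.5)
  res <- icc_consistency(y1, y2)
  # oracle from aov mean squares
  d <- data.frame(y = c(y1, y2), subj = factor(rep(1:14, 2)),
                  sess = factor(rep(1:2, each = 14)))
  tab <- anova(lm(y ~ subj + sess, data = d))
  msr <- tab["subj", "Mean Sq"]; mse <- tab["Residuals", "Mean Sq"]
  expect_lt(abs(res$icc - (msr - mse) / (msr + mse)), 1e-8)
  expect_lt(abs(res$F - msr / mse), 1e-8)
  expect_true(res$ci[1] <= res$icc && res$icc <= res$ci[2])
})

test_that("trial classification assigns by correlation with tie-breaking", {
  wf <- abs(sin(pi * seq(0, 11.9, by = 0.1)))
  m <- matrix(rnorm(5 * 120, sd = 0.1), 5, 120)
  m[3, ] <- m[3, ] + wf
  out <- classify_trials(list(m), wf, instructed = 3)
  expect_equal(out$assigned, 3L)
  expect_equal(out$percent_correct, 100)

  flat <- matrix(rep(wf, each = 5), 5, 120)
  expect_warning(out_t <- classify_trials(list(flat), wf), "tied")
  expect_equal(out_t$assigned, 1L)
})

test_that("stepwise selection follows the greedy exhaustive-oracle path", {
  set.seed(8)
  n <- 40
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  y <- X[, 1]
  m <- stepwise_forward(y, X)
  expect_equal(m$included, "x1")
  expect_equal(m$r2, 1)

  # orthogonalized predictors: nothing passes the threshold
  y2 <- rnorm(n)
  Xo <- apply(X, 2, function(col) resid(lm(col ~ y2)))
  colnames(Xo) <- colnames(X)
  m0 <- stepwise_forward(y2, Xo)
  expect_equal(m0$included, character(0))
  expect_equal(unname(m0$coefficients["(Intercept)"]), mean(y2))

  # two-signal construction: path matches an exhaustive greedy oracle
  y3 <- 0.8 * X[, 1] + 0.3 * X[, 2] + rnorm(n, sd = 0.3)
  m3 <- stepwise_forward(y3, X)
  oracle_path <- character(0)
  remaining <- colnames(X)
  r2_prev <- 0
  repeat {
    r2s <- sapply(remaining, function(cn)
      summary(lm(y3 ~ X[, c(oracle_path, cn)]))$r.squared)
    if (max(r2s) - r2_prev <= 0.1) break
    oracle_path <- c(oracle_path, remaining[which.max(r2s)])
    remaining <- setdiff(remaining, oracle_path)
    r2_prev <- max(r2s)
  }
  expect_equal(m3$included, oracle_path)
  # coefficients reproduce the lm fit
  fit <- lm(y3 ~ X[, m3$included])
  expect_lt(max(abs(sort(m3$coefficients) - sort(coef(fit)))), 1e-10)
  expect_lt(abs(m3$adj_r2 - summary(fit)$adj.r.squared), 1e-10)
})

test_that("bootstrap stepwise is reproducible and tracks signal strength", {
  set.seed(9)
  n <- 18
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- X[, 1]
  bs <- bootstrap_stepwise(y, X, B = 100, seed = 99)
  expect_equal(unname(bs$inclusion["x1"]), 1.0)
  bs2 <- bootstrap_stepwise(y, X, B = 100, seed = 99)
  expect_identical(bs, bs2)
  expect_true(all(bs$inclusion >= 0 & bs$inclusion <= 1))

  # pure-noise predictors are included in well under half the resamples
  y_null <- rnorm(n)
  bs0 <- bootstrap_stepwise(y_null, X, B = 200, seed = 7)
  expect_true(all(bs0$inclusion < 0.5))
})

test_that("calibrated Bayes factor obeys its limiting contracts", {
  # prior collapsing on the null drives BF to 1
  bf0 <- calibrated_bayes_factor(0.4, 0.2, 20, prior_effect = 1e-6,
                                 prior_dof = 20)
  expect_lt(abs(bf0$bf - 1), 1e-3)

  # zero effect with tight SE relative to the prior supports the null
  bfn <- calibrated_bayes_factor(0, 0.1, 20, prior_effect = 0.5,
                                 prior_dof = 20)
  expect_lt(bfn$bf, 1 / 3)
  expect_true(bfn$support_null)

  # effect at the prior-defining magnitude supports the alternative
  bfa <- calibrated_bayes_factor(0.5, 0.1, 20, prior_effect = 0.5,
                                 prior_dof = 20)
  expect_gt(bfa$bf, 3)

  expect_error(calibrated_bayes_factor(0.1, 0.1, 10, prior_effect = 0),
               "prior width")
  expect_error(calibrated_bayes_factor(0.1, -1, 10, prior_effect = 0.5),
               "se_obs")
})

test_that("Bayes factor matches the fixed-grid quadrature oracle", {
  cases <- list(c(0, 0.1, 20, 0.5), c(0.5, 0.1, 20, 0.5),
                c(0.25, 0.15, 28, 0.4), c(-0.1, 0.2, 23, 0.6),
                c(0.3, 0.3, 15, -0.5))
  for (cs in cases) {
    impl <- calibrated_bayes_factor(cs[1], cs[2], cs[3], cs[4],
                                    prior_dof = cs[3])$bf
    oracle <- bf_grid_oracle(cs[1], cs[2], cs[3], cs[4], prior_dof = cs[3])
    expect_lt(abs(impl - oracle), 1e-6)
  }
})

test_that("Bayes factor is monotone in the effect along the prior tail", {
  effects <- seq(0, 1, by = 0.1)
  bfs <- vapply(effects, function(e)
    calibrated_bayes_factor(e, 0.15, 25, prior_effect = 0.5,
                            prior_dof = 25)$bf, numeric(1))
  expect_true(all(diff(bfs) > 0))
})

test_that("Bonferroni-adjusted families control the family-wise error", {
  set.seed(10)
  n_fam <- 400
  any_rej <- vapply(1:n_fam, function(i) {
    g1 <- rnorm(12); g2 <- rnorm(18); g3 <- rnorm(13)
    ps <- c(group_ttest(g1, g2, family_size = 3)$p,
            group_ttest(g1, g3, family_size = 3)$p,
            group_ttest(g2, g3, family_size = 3)$p)
    any(ps < 0.05 / 3)
  }, logical(1))
  expect_lte(mean(any_rej), 0.08)
})
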