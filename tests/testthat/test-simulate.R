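test_that("participant simulation is deterministic given the seed", {
  cfg <- study_config(rng_seed = 5)
  p1 <- simulate_participant(cfg, "amputee", 123)
  p2 <- simulate_participant(cfg, "amputee", 123)
  expect_identical(p1, p2)
  p3 <- simulate_participant(cfg, "amputee", 124)
  expect_false(identical(p1$rois$SI_contra$betas[[1]],
                         p3$rois$SI_contra$betas[[1]]))
  expect_error(simulate_participant(cfg, "martian", 1), "unknown group")
})

test_that("zero signal scale yields identical condition means and a null RDM", {
  cfg <- study_config(noise_sd = 0, subject_sigma = 0)
  cfg$signal_scale[, ] <- 0
  p <- simulate_participant(cfg, "congenital", 9, rois = "SI_contra")
  gt <- p$ground_truth$SI_contra
  expect_equal(max(gt$mean_patterns) - min(gt$mean_patterns), 0)
  expect_true(all(gt$true_rdm == 0))
})

test_that("noiseless patterns realize signal_scale x canonical exactly", {
  p <- noiseless_participant(scale = 0.6, seed = 7)
  canon <- canonical_rdm()
  B <- p$rois$SI_contra$betas[[1]]
  V <- ncol(B)
  emp <- as.matrix(dist(B))^2 / V
  target <- unclass(canon) * 0.6
  expect_lt(max(abs(emp - target)) / max(target), 1e-8)
  # betas identical across runs in the noiseless limit
  expect_identical(p$rois$SI_contra$betas[[1]], p$rois$SI_contra$betas[[4]])
})

test_that("V5 never carries digit signal for any group", {
  cfg <- study_config()
  for (g in c("amputee", "congenital", "control")) {
    p <- simulate_participant(cfg, g, 31, rois = "V5")
    expect_true(all(p$ground_truth$V5$true_rdm == 0))
    M <- p$ground_truth$V5$mean_patterns
    expect_equal(max(M) - min(M), 0)
  }
})

test_that("kinaesthesia coupling controls the rank correlation with typicality", {
  typ <- runif(10000, 0, 1)
  cv0 <- simulate_covariates(typ, coupling = 0, seed = 1)
  expect_lt(abs(cor(cv0$kinaesthesia, typ, method = "spearman")), 0.03)

  cv1 <- simulate_covariates(typ, coupling = 1, seed = 1)
  expect_true(all(diff(cv1$kinaesthesia[order(typ)]) >= 0))
  expect_gt(cor(cv1$kinaesthesia, typ, method = "spearman"), 0.95)

  # n = 18 sampling distribution at coupling 0.7
  rhos <- vapply(1:300, function(i) {
    ty <- runif(18)
    cv <- simulate_covariates(ty, coupling = 0.7, seed = 1000 + i)
    cor(cv$kinaesthesia, ty, method = "spearman")
  }, numeric(1))
  expect_gt(median(rhos), 0.5)
  expect_lt(median(rhos), 0.85)
})

test_that("covariates respect their documented ranges", {
  cv <- simulate_covariates(runif(500), coupling = 0.5, seed = 3)
  expect_true(all(cv$kinaesthesia %in% 0:5))
  for (col in c("vividness_chronic", "vividness_acute", "pain_chronic",
                "pain_acute"))
    expect_true(all(cv[[col]] >= 0 & cv[[col]] <= 100))
  expect_true(all(cv$years_since_amputation >= 1))
  expect_error(simulate_covariates(runif(5), coupling = 1.5, seed = 1),
               "coupling")
})

test_that("force-trace performance level maps to classification accuracy", {
  instructed <- rep(1:5, each = 40)
  perfect <- simulate_force_traces(instructed, performance_level = 1, seed = 2)
  expect_equal(classify_trials(perfect)$percent_correct, 100)

  chance <- simulate_force_traces(rep(1:5, each = 400), performance_level = 0,
                                  seed = 3)
  acc <- classify_trials(chance)$percent_correct
  expect_gt(acc, 15); expect_lt(acc, 25)

  # tuned level hits a 75% target within 5 points
  lvl <- (0.75 - 0.2) / 0.8
  tuned <- simulate_force_traces(rep(1:5, 100), performance_level = lvl,
                                 seed = 4)
  acc75 <- classify_trials(tuned)$percent_correct
  expect_gt(acc75, 70); expect_lt(acc75, 80)
})

test_that("simulated time series invert through the GLM", {
  sch <- data.frame(condition = rep(paste0("D", 1:5), each = 2),
                    onset_s = c(0, 150, 30, 180, 60, 210, 90, 240, 120, 270),
                    duration_s = 12)
  B <- matrix(rnorm(5 * 8), 5, 8, dimnames = list(paste0("D", 1:5), NULL))
  ts0 <- simulate_timeseries(sch, B, noise = list(sd = 0), seed = 1,
                             n_timepoints = 200, tr_s = 1.5)
  X <- build_design(sch, 200, 1.5)
  fit <- fit_glm(ts0, X)
  expect_lt(max(abs(fit$betas - B)), 1e-9)

  # pure linear drift, zero betas: high-pass filtering then fitting ~ 0
  ts_d <- simulate_timeseries(sch, B * 0, noise = list(sd = 0, drift = c(2, 0.05)),
                              seed = 1, n_timepoints = 200, tr_s = 1.5)
  fit_d <- fit_glm(highpass_filter(ts_d, tr_s = 1.5), X)
  expect_lt(max(abs(fit_d$betas)), 0.05 * max(abs(ts_d)))

  expect_identical(ts0, simulate_timeseries(sch, B, noise = list(sd = 0),
                                            seed = 1, n_timepoints = 200,
                                            tr_s = 1.5))
})

test_that("OLS beta covariance matches the analytic form under white noise", {
  sch <- data.frame(condition = rep(c("D1", "D2"), each = 2),
                    onset_s = c(0, 60, 30, 90), duration_s = 12)
  X <- build_design(sch, 80, 1.5)
  B <- matrix(0, 2, 1, dimnames = list(c("D1", "D2"), NULL))
  betas <- t(vapply(1:300, function(i) {
    ts <- simulate_timeseries(sch, B, noise = list(sd = 1), seed = i,
                              n_timepoints = 80, tr_s = 1.5)
    fit_glm(ts, X)$betas[, 1]
  }, numeric(2)))
  emp <- cov(betas)
  ana <- solve(crossprod(X))[1:2, 1:2]
  expect_lt(max(abs(emp - ana)) / max(abs(ana)), 0.2)
})
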