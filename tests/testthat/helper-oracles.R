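# Independent oracles used across tests. These deliberately use naive,
# definitional computations (nested loops, fine grids, enumeration) so they
# share no code path with the package implementations they check.

# crossnobis by explicit quadruple loop over condition pairs and run pairs
crossnobis_brute <- function(run_betas, sigma) {
  V <- ncol(run_betas[[1]])
  R <- length(run_betas)
  sigma_inv <- solve(sigma)
  out <- matrix(0, 5, 5)
  for (a in 1:4) for (b in (a + 1):5) {
    acc <- 0; npair <- 0
    for (m in 1:(R - 1)) for (n in (m + 1):R) {
      dm <- run_betas[[m]][a, ] - run_betas[[m]][b, ]
      dn <- run_betas[[n]][a, ] - run_betas[[n]][b, ]
      acc <- acc + as.numeric(t(dm) %*% sigma_inv %*% dn) / V
      npair <- npair + 1
    }
    out[a, b] <- out[b, a] <- acc / npair
  }
  dimnames(out) <- list(paste0("D", 1:5), paste0("D", 1:5))
  out
}

# random run-beta sets with a planted geometry plus noise
random_run_betas <- function(n_runs = 4, n_voxels = 30, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(5 * n_voxels), 5, n_voxels)
  lapply(seq_len(n_runs), function(r)
    M + 0.5 * matrix(rnorm(5 * n_voxels), 5, n_voxels))
}

# random SPD covariance
random_spd <- function(p, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + diag(p)
}

# Bayes factor by Simpson quadrature on a fixed fine grid
bf_grid_oracle <- function(effect_obs, se_obs, dof_obs, prior_effect,
                           prior_dof, n_grid = 80001) {
  width <- abs(prior_effect)
  sgn <- if (prior_effect >= 0) 1 else -1
  g <- seq(0, 12 * width, length.out = n_grid) * sgn
  lik <- dt((effect_obs - g) / se_obs, df = dof_obs) / se_obs
  pri <- 2 * dt(abs(g) / width, df = prior_dof) / width
  f <- lik * pri
  h <- abs(g[2] - g[1])
  w <- rep(c(4, 2), length.out = n_grid - 2)
  integral <- h / 3 * (f[1] + f[n_grid] + sum(w * f[2:(n_grid - 1)]))
  integral / (dt(effect_obs / se_obs, df = dof_obs) / se_obs)
}

# exact Mann-Whitney two-sided p by enumeration of all rank configurations
mw_enum_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(na + nb, na)
  u_all <- apply(combs, 2, function(idx) sum(idx) - na * (na + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# small helper: a noiseless participant with known scaled geometry
noiseless_participant <- function(scale = 0.6, seed = 42, n_voxels = 100) {
  cfg <- study_config(noise_sd = 0, subject_sigma = 0)
  cfg$signal_scale["amputee", "SI_contra"] <- scale
  simulate_participant(cfg, "amputee", seed, rois = "SI_contra")
}
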