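#' Configuration of a simulated digit-mapping study
#'
#' Bundles every parameter of the synthetic study: group sizes, run structure,
#' region sizes, per-group/per-region signal scaling, noise structure, the
#' canonical-geometry parameters, and the coupling between phantom
#' kinaesthesia and realized typicality. Defaults emulate a block-design
#' digit-movement experiment: 4 runs, 12 s blocks, 3 repeats per condition per
#' run, TR 1.5 s, with three groups (18 amputees, 13 congenital one-handers,
#' 12 two-handed controls) and four regions of interest.
#'
#' `signal_scale` sets the true inter-digit geometry per group and region as a
#' multiple of the canonical RDM: controls and amputees carry near-canonical
#' structure in contralateral SI/M1 and in ipsilateral SI; congenital
#' one-handers carry almost none; V5 (a visual control region) carries none
#' for any group. The default scales are calibration constants chosen so that
#' the default pipeline lands near the group statistics the generator is meant
#' to emulate (amputee typicality around 0.75, congenital around 0.3).
#' `subject_sigma` is the SD of a per-participant log-normal multiplier on
#' signal scale, the source of between-subject typicality spread.
#'
#' @param n_per_group named integer vector: participants per group.
#' @param n_runs number of imaging runs (>= 2; default 4).
#' @param block_duration_s duration of one movement block in seconds.
#' @param repeats_per_run repeats of each condition per run.
#' @param tr_s repetition time in seconds.
#' @param n_voxels_per_roi named integer vector of voxels per region.
#' @param signal_scale group x roi matrix of non-negative signal scales.
#' @param activity_level group x roi matrix of mean univariate activation
#'   added to every condition pattern (arbitrary units).
#' @param noise_spatial_corr correlation length (in voxel index units) of the
#'   exponential-decay spatial noise correlation.
#' @param noise_sd SD scale of the trial-to-trial pattern noise.
#' @param subject_sigma SD of the per-participant log-normal signal multiplier.
#' @param canonical_params list of parameters passed to [canonical_rdm()].
#' @param covariate_coupling target Spearman correlation in [-1, 1] between
#'   phantom kinaesthesia and realized typicality.
#' @param rng_seed integer master seed.
#' @return A list of class \code{"study_config"}.
#' @export
study_config <- function(n_per_group = c(amputee = 18L, congenital = 13L, control = 12L),
                         n_runs = 4L,
                         block_duration_s = 12,
                         repeats_per_run = 3L,
                         tr_s = 1.5,
                         n_voxels_per_roi = c(SI_contra = 100L, M1_contra = 100L,
                                              SI_ipsi = 100L, V5 = 100L),
                         signal_scale = default_signal_scale(),
                         activity_level = default_activity_level(),
                         noise_spatial_corr = 5,
                         noise_sd = 3,
                         subject_sigma = 0.55,
                         canonical_params = list(a = 1, b = 0.5, c_thumb = 0.5),
                         covariate_coupling = 0.7,
                         rng_seed = 1L) {
  groups <- c("amputee", "congenital", "control")
  stopifnot(all(names(n_per_group) %in% groups), all(n_per_group >= 1))
  if (n_runs < 2) stop("n_runs must be >= 2 (cross-validation needs two runs)")
  if (block_duration_s <= 0 || repeats_per_run < 1 || tr_s <= 0)
    stop("block_duration_s, repeats_per_run and tr_s must be positive")
  if (any(n_voxels_per_roi < 1)) stop("each ROI needs at least one voxel")
  if (any(signal_scale < 0)) stop("signal_scale entries must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (abs(covariate_coupling) > 1) stop("covariate_coupling must lie in [-1, 1]")
  cfg <- list(n_per_group = n_per_group, n_runs = as.integer(n_runs),
              block_duration_s = block_duration_s,
              repeats_per_run = as.integer(repeats_per_run), tr_s = tr_s,
              n_voxels_per_roi = n_voxels_per_roi,
              signal_scale = signal_scale, activity_level = activity_level,
              noise_spatial_corr = noise_spatial_corr, noise_sd = noise_sd,
              subject_sigma = subject_sigma,
              canonical_params = canonical_params,
              covariate_coupling = covariate_coupling,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "study_config"
  cfg
}

#' @export
print.study_config <- function(x, ...) {
  cat("Simulated digit-mapping study configuration\n")
  cat("  groups:", paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
                         collapse = ", "), "\n")
  cat(sprintf("  runs: %d, block %gs x %d repeats, TR %gs\n",
              x$n_runs, x$block_duration_s, x$repeats_per_run, x$tr_s))
  cat("  ROIs:", paste(sprintf("%s(%d vox)", names(x$n_voxels_per_roi),
                               x$n_voxels_per_roi), collapse = ", "), "\n")
  cat(sprintf("  noise_sd %g, spatial corr length %g, subject_sigma %g, seed %d\n",
              x$noise_sd, x$noise_spatial_corr, x$subject_sigma, x$rng_seed))
  invisible(x)
}

roi_names <- function() c("SI_contra", "M1_contra", "SI_ipsi", "V5")

default_signal_scale <- function() {
  m <- matrix(0, 3, 4, dimnames = list(c("amputee", "congenital", "control"),
                                       roi_names()))
  m["control", ]    <- c(0.80, 0.18, 0.55, 0)
  m["amputee", ]    <- c(0.60, 0.13, 0.50, 0)
  m["congenital", ] <- c(0.08, 0.03, 0.05, 0)
  m
}

default_activity_level <- function() {
  m <- matrix(0, 3, 4, dimnames = list(c("amputee", "congenital", "control"),
                                       roi_names()))
  m["control", ]    <- c(1.0, 1.0, 0.6, 0.2)
  m["amputee", ]    <- c(0.9, 0.9, 0.6, 0.2)
  m["congenital", ] <- c(0.5, 0.7, 0.6, 0.2)
  m
}

run_timepoints <- function(config) {
  # 10 digit conditions + rest, each repeated repeats_per_run times
  n_blocks <- 11L * config$repeats_per_run
  as.integer(round(n_blocks * config$block_duration_s / config$tr_s))
}

#' Spatially correlated voxel noise covariance
#'
#' Exponential-decay correlation over a 1-D voxel index,
#' \code{corr(i, j) = exp(-|i-j| / length)}, scaled by per-voxel SDs.
#' @param n_voxels number of voxels.
#' @param corr_length correlation length; 0 gives independent voxels.
#' @param voxel_sd per-voxel SDs (recycled); default 1.
#' @return n x n covariance matrix.
#' @keywords internal
spatial_noise_cov <- function(n_voxels, corr_length, voxel_sd = 1) {
  idx <- seq_len(n_voxels)
  if (corr_length <= 0) corr <- diag(n_voxels)
  else corr <- exp(-abs(outer(idx, idx, "-")) / corr_length)
  sd <- rep_len(voxel_sd, n_voxels)
  corr * tcrossprod(sd)
}

# Condition-mean patterns whose pairwise squared Euclidean distances, divided
# by voxel count, equal exactly the entries of `target_rdm` (treated as
# squared distances). Coordinates from the eigendecomposition of the
# double-centred target are embedded into voxel space through a random
# orthonormal basis, so the realized (not just expected) geometry is exact.
mean_patterns_from_rdm <- function(target_rdm, n_voxels) {
  k0 <- nrow(target_rdm)
  Cc <- diag(k0) - 1 / k0
  G <- -0.5 * Cc %*% target_rdm %*% Cc
  e <- eigen(G, symmetric = TRUE)
  keep <- e$values > max(e$values, 0) * 1e-10
  if (!any(keep)) return(matrix(0, k0, n_voxels))
  k <- sum(keep)
  if (k > n_voxels) stop("too few voxels to embed the target geometry")
  Y <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]), k)
  Z <- matrix(stats::rnorm(n_voxels * k), n_voxels, k)
  Q <- qr.Q(qr(Z))  # n_voxels x k orthonormal
  sqrt(n_voxels) * Y %*% t(Q)
}

#' Simulate one participant's run-wise activity patterns
#'
#' Emits, for each region of interest, per-run condition-by-voxel beta
#' patterns plus a residual matrix and degrees of freedom ("beta mode").
#' Condition means are constructed so their pairwise squared pattern
#' distances (per voxel) realize \code{signal_scale x canonical RDM} exactly;
#' run-wise patterns add spatially correlated Gaussian noise, and the residual
#' matrix is drawn from the same spatial covariance so that noise-model
#' estimation and pre-whitening are non-trivial. With \code{noise_sd = 0} the
#' betas equal the true means exactly and the residuals are unit-variance
#' white noise, so the estimated whitening is approximately the identity (the
#' natural whitening when there is no noise to normalize).
#'
#' @param config a [study_config()].
#' @param group one of \code{"amputee"}, \code{"congenital"}, \code{"control"}.
#' @param participant_seed integer seed; identical seeds give bit-identical
#'   output.
#' @param rois character vector of regions to simulate (default all four).
#' @return List with elements \code{group}, \code{seed}, \code{rois} (one
#'   entry per region: \code{betas} list of condition x voxel matrices,
#'   \code{residuals} time x voxel matrix, \code{dof}), and
#'   \code{ground_truth} (\code{mean_patterns}, \code{true_rdm},
#'   \code{true_typicality}, \code{signal_multiplier} per region).
#' @export
simulate_participant <- function(config, group, participant_seed,
                                 rois = names(config$n_voxels_per_roi)) {
  stopifnot(inherits(config, "study_config"))
  if (!group %in% rownames(config$signal_scale))
    stop("unknown group label: ", group)
  if (!all(rois %in% names(config$n_voxels_per_roi)))
    stop("unknown ROI name(s): ",
         paste(setdiff(rois, names(config$n_voxels_per_roi)), collapse = ", "))
  set.seed(as.integer(participant_seed))
  canon <- do.call(canonical_rdm, config$canonical_params)
  n_t <- run_timepoints(config)
  # residuals pooled across runs (noise normalization uses pooled residuals);
  # they are direct draws from the noise covariance, so dof = rows - 1
  n_resid <- config$n_runs * n_t
  dof <- n_resid - 1L
  mult <- exp(stats::rnorm(1, 0, config$subject_sigma))
  out <- list(group = group, seed = as.integer(participant_seed),
              rois = list(), ground_truth = list())
  for (roi in rois) {
    V <- config$n_voxels_per_roi[[roi]]
    s <- config$signal_scale[group, roi] * mult
    act <- config$activity_level[group, roi]
    M <- mean_patterns_from_rdm(unclass(canon) * s, V) + act
    true_rdm <- unclass(canon) * s
    if (config$noise_sd > 0) {
      Sigma <- spatial_noise_cov(V, config$noise_spatial_corr,
                                 voxel_sd = stats::runif(V, 0.8, 1.2))
      L <- chol(Sigma)
      betas <- lapply(seq_len(config$n_runs), function(r) {
        M + config$noise_sd * (matrix(stats::rnorm(5 * V), 5, V) %*% L)
      })
      resid <- matrix(stats::rnorm(n_resid * V), n_resid, V) %*% L
    } else {
      betas <- lapply(seq_len(config$n_runs), function(r) M)
      resid <- matrix(stats::rnorm(n_resid * V), n_resid, V)
    }
    betas <- lapply(betas, function(b) {
      dimnames(b) <- list(digit_labels(), NULL); b
    })
    out$rois[[roi]] <- list(betas = betas, residuals = resid, dof = dof)
    out$ground_truth[[roi]] <- list(
      mean_patterns = M, true_rdm = true_rdm,
      true_typicality = if (s > 0) 1 else NA_real_,
      signal_multiplier = mult)
  }
  out
}

#' Simulate behavioural covariates for an amputee cohort
#'
#' Generates the amputee covariate table: phantom kinaesthesia (integer 0-5),
#' chronic and acute nonpainful phantom vividness (0-100), chronic and acute
#' phantom pain (0-100), years since amputation, age at amputation, and
#' intact-hand typicality. Kinaesthesia is coupled to the supplied (realized)
#' typicality through a Gaussian copula: the latent normal correlation is set
#' to \code{2*sin(pi*c/6)} (with \code{c} the coupling inflated by the 6-level
#' binning attenuation factor 0.978) so the Spearman correlation with
#' typicality equals \code{coupling}, and the latent noise is orthogonalized
#' within the sample so the realized latent correlation is pinned to its
#' target exactly (in the spirit of \code{MASS::mvrnorm(empirical = TRUE)}):
#' the coupling is a condition of the simulated study, not a random draw.
#' The latent score is then binned to the 0-5 integer scale, which leaves
#' only the small discretization noise in the realized rank correlation.
#' All other covariates are independent of typicality.
#'
#' @param typicality numeric vector of realized typicality values, one per
#'   participant.
#' @param coupling target Spearman correlation in [-1, 1].
#' @param seed integer seed.
#' @return data.frame with one row per participant.
#' @export
simulate_covariates <- function(typicality, coupling, seed) {
  if (abs(coupling) > 1) stop("coupling must lie in [-1, 1]")
  n <- length(typicality)
  set.seed(as.integer(seed))
  z_typ <- stats::qnorm((rank(typicality, ties.method = "average") - 0.5) / n)
  # 0.978: rank-correlation attenuation from discretizing one margin into
  # six equal-probability bins
  rho_p <- 2 * sin(pi * min(1, abs(coupling) / 0.978) / 6) * sign(coupling)
  eps <- stats::rnorm(n)
  if (n >= 3 && stats::sd(z_typ) > 0 && abs(rho_p) < 1) {
    # orthogonalize the latent noise within the sample so the realized
    # latent correlation equals the target exactly
    zs <- (z_typ - mean(z_typ)) / stats::sd(z_typ)
    eps <- stats::residuals(stats::lm(eps ~ zs))
    eps <- eps / stats::sd(eps)
    z_kin <- rho_p * zs + sqrt(1 - rho_p^2) * eps
  } else {
    z_kin <- rho_p * z_typ + sqrt(max(0, 1 - rho_p^2)) * eps
  }
  kin <- pmin(5L, as.integer(floor(6 * stats::pnorm(z_kin))))
  clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  data.frame(
    participant = seq_len(n),
    kinaesthesia = kin,
    vividness_chronic = clip(round(stats::rnorm(n, 58, 38)), 0, 100),
    vividness_acute = clip(round(stats::rnorm(n, 65, 30)), 0, 100),
    pain_chronic = clip(round(stats::rnorm(n, 46, 37)), 0, 100),
    pain_acute = clip(round(stats::rnorm(n, 21, 23)), 0, 100),
    years_since_amputation = clip(round(stats::rlnorm(n, log(15), 0.6)), 1, 60),
    age_at_amputation = clip(round(stats::rnorm(n, 33, 12)), 16, 70),
    intact_typicality = clip(stats::rnorm(n, 0.85, 0.06), -1, 1),
    typicality = typicality)
}

#' Simulate a voxel time series from a block design
#'
#' \code{series = design %*% betas + drift + noise}; exercises the GLM module
#' end-to-end ("timeseries mode").
#'
#' @param schedule data.frame with columns \code{condition}, \code{onset_s},
#'   \code{duration_s}.
#' @param true_betas condition x voxel matrix; rownames must cover the
#'   schedule's conditions.
#' @param noise list with elements \code{sd} (Gaussian noise SD, default 0)
#'   and \code{drift} (length-2 numeric, intercept and per-second linear slope
#'   of an additive drift, default c(0, 0)).
#' @param seed integer seed.
#' @param n_timepoints number of volumes; default covers the schedule.
#' @param tr_s repetition time in seconds.
#' @return time x voxel matrix.
#' @export
simulate_timeseries <- function(schedule, true_betas, noise = list(), seed = 1,
                                n_timepoints = NULL, tr_s = 1.5) {
  sd_n <- if (is.null(noise$sd)) 0 else noise$sd
  drift <- if (is.null(noise$drift)) c(0, 0) else noise$drift
  conds <- unique(as.character(schedule$condition))
  if (is.null(rownames(true_betas)) || !all(conds %in% rownames(true_betas)))
    stop("rownames of true_betas must cover the schedule conditions")
  if (is.null(n_timepoints))
    n_timepoints <- ceiling(max(schedule$onset_s + schedule$duration_s) / tr_s)
  X <- build_design(schedule, n_timepoints, tr_s)
  cond_cols <- attr(X, "condition_cols")
  set.seed(as.integer(seed))
  B <- true_betas[colnames(X)[cond_cols], , drop = FALSE]
  t_s <- (seq_len(n_timepoints) - 1) * tr_s
  series <- X[, cond_cols, drop = FALSE] %*% B +
    drift[1] + drift[2] * t_s +
    sd_n * matrix(stats::rnorm(n_timepoints * ncol(B)), n_timepoints, ncol(B))
  series
}

#' Simulate per-trial digit force traces
#'
#' Emulates the button-box task used to verify intact-hand performance: on
#' each trial one digit is cued to press at a 1 Hz cadence. With probability
#' \code{performance_level} the instructed digit produces the press waveform;
#' otherwise a uniformly random digit does, so expected classification
#' accuracy is \code{performance_level + (1 - performance_level)/5}. All five
#' channels carry measurement noise.
#'
#' @param instructed integer vector (1-5), the instructed digit per trial.
#' @param performance_level probability in [0, 1] that the instructed digit
#'   executes the trial.
#' @param seed integer seed.
#' @param duration_s trial duration in seconds (default 12).
#' @param hz sampling rate of the force recording (default 10).
#' @param noise_sd SD of the measurement noise (default 0.2).
#' @return List with \code{traces} (list of 5 x time matrices, one per trial),
#'   \code{instructed}, and \code{waveform} (the instructed time course).
#' @seealso [classify_trials()]
#' @export
simulate_force_traces <- function(instructed, performance_level, seed,
                                  duration_s = 12, hz = 10, noise_sd = 0.2) {
  if (performance_level < 0 || performance_level > 1)
    stop("performance_level must lie in [0, 1]")
  stopifnot(all(instructed %in% 1:5))
  set.seed(as.integer(seed))
  t_s <- seq(0, duration_s - 1 / hz, by = 1 / hz)
  waveform <- abs(sin(pi * t_s))  # 1 Hz half-sine presses
  traces <- lapply(seq_along(instructed), function(i) {
    m <- noise_sd * matrix(stats::rnorm(5 * length(t_s)), 5, length(t_s))
    active <- if (stats::runif(1) < performance_level) instructed[i]
              else sample.int(5, 1)
    m[active, ] <- m[active, ] + waveform
    rownames(m) <- digit_labels()
    m
  })
  list(traces = traces, instructed = as.integer(instructed), waveform = waveform)
}

#' Simulate a whole cohort
#'
#' Calls [simulate_participant()] for every participant of every group with
#' participant seeds derived deterministically from the master seed.
#'
#' @param config a [study_config()].
#' @param rois regions to simulate.
#' @return List with one element per group, each a list of participants.
#' @export
simulate_cohort <- function(config, rois = names(config$n_voxels_per_roi)) {
  stopifnot(inherits(config, "study_config"))
  groups <- names(config$n_per_group)
  out <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    out[[g]] <- lapply(seq_len(config$n_per_group[[g]]), function(i) {
      # multiplicative spreading keeps participant draws disjoint across
      # nearby master seeds
      s <- (as.numeric(config$rng_seed) * 48271 + 10000 * gi + i) %% 2147483647
      simulate_participant(config, g, participant_seed = as.integer(s),
                           rois = rois)
    })
  }
  out
}
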