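#' Estimate a shrinkage noise covariance from GLM residuals
#'
#' Multivariate noise normalization for crossnobis distances: the voxel-wise
#' noise covariance is the sample covariance of the GLM residuals (normalized
#' by the residual degrees of freedom) shrunk toward its diagonal with an
#' analytically chosen Ledoit-Wolf-style intensity, which guarantees an
#' invertible, well-conditioned estimate even when voxels outnumber
#' timepoints.
#'
#' @param residuals time x voxel residual matrix (>= 2 rows).
#' @param dof residual degrees of freedom used to normalize the covariance;
#'   defaults to \code{nrow(residuals) - 1}.
#' @param shrinkage optional fixed shrinkage intensity in [0, 1]; if NULL
#'   (default) the intensity is estimated from the data.
#' @return List of class \code{"noise_model"}: \code{sigma} (voxel x voxel
#'   covariance), \code{shrinkage}, \code{dof}.
#' @export
estimate_noise <- function(residuals, dof = NULL, shrinkage = NULL) {
  X <- as.matrix(residuals)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2) stop("need at least 2 residual rows")
  if (is.null(dof)) dof <- n - 1
  if (dof < 1) stop("dof must be >= 1")
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / dof
  if (is.null(shrinkage)) {
    # Ledoit-Wolf/Schafer-Strimmer intensity toward the diagonal target:
    # lambda = sum_{i != j} Var(s_ij) / sum_{i != j} s_ij^2
    W1 <- crossprod(Xc) / n               # mean of w_kij = x_ki x_kj
    W2 <- crossprod(Xc^2) / n             # mean of w_kij^2
    var_s <- (n / (n - 1)^2) * (W2 - W1^2)
    off <- !diag(p)
    denom <- sum(S[off]^2)
    shrinkage <- if (denom > 0) min(1, max(0, sum(var_s[off]) / denom)) else 1
  } else {
    if (shrinkage < 0 || shrinkage > 1) stop("shrinkage must lie in [0, 1]")
  }
  D <- diag(S)
  zero_var <- D <= 0
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance voxel(s); variance floored")
    floor_val <- if (any(!zero_var)) 1e-6 * max(D) else 1
    D[zero_var] <- floor_val
    S[zero_var, ] <- 0
    S[, zero_var] <- 0
    diag(S) <- D
  }
  sigma <- (1 - shrinkage) * S + shrinkage * diag(D, p)
  structure(list(sigma = sigma, shrinkage = shrinkage, dof = dof),
            class = "noise_model")
}

#' Identity noise model
#'
#' Whitening that leaves patterns untouched; the appropriate noise model for
#' noiseless data or when no residuals are available.
#' @param n_voxels number of voxels.
#' @return A \code{"noise_model"} with identity covariance.
#' @export
noise_identity <- function(n_voxels) {
  structure(list(sigma = diag(n_voxels), shrinkage = 1, dof = Inf),
            class = "noise_model")
}

# 10 x 5 contrast matrix: row per unique digit pair (canonical order), +1/-1
pair_contrasts <- function() {
  P <- matrix(0, 10, 5)
  r <- 1L
  for (i in 1:4) for (j in (i + 1):5) {
    P[r, i] <- 1; P[r, j] <- -1; r <- r + 1L
  }
  P
}

#' Cross-validated Mahalanobis (crossnobis) RDM
#'
#' For each digit pair (a, b) and each unordered pair of runs (m, n), the
#' contribution is \eqn{\delta_m' \Sigma^{-1} \delta_n / V} where
#' \eqn{\delta_r} is the pattern difference between conditions a and b in run
#' r, \eqn{\Sigma} the noise covariance, and V the voxel count (so distances
#' are comparable across region sizes); contributions are averaged over all
#' unordered run pairs. Because the two factors come from independent runs the
#' estimator is unbiased: its expected value is zero when two conditions do
#' not differ, and individual entries may be negative.
#'
#' @param run_betas list (one per run, >= 2) of condition x voxel matrices
#'   with identical dimensions and condition order (5 digit conditions).
#' @param noise a \code{"noise_model"} (see [estimate_noise()],
#'   [noise_identity()]); voxel count must match.
#' @return 5x5 symmetric RDM (zero diagonal, dimnames D1..D5), units a.u.
#' @export
crossnobis <- function(run_betas, noise) {
  if (!is.list(run_betas) || length(run_betas) < 2)
    stop("cross-validation impossible: need at least 2 runs")
  if (!inherits(noise, "noise_model")) stop("noise must be a 'noise_model'")
  dims <- lapply(run_betas, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("all runs must have identical condition x voxel dimensions")
  V <- ncol(run_betas[[1]])
  K <- nrow(run_betas[[1]])
  if (K != 5) stop("expected 5 digit conditions per run, got ", K)
  if (ncol(noise$sigma) != V)
    stop("voxel count of noise model (", ncol(noise$sigma),
         ") does not match patterns (", V, ")")
  U <- chol(noise$sigma)
  P <- pair_contrasts()
  # whitened pair differences per run: Delta_r = P B_r U^{-1}
  deltas <- lapply(run_betas, function(B) {
    t(backsolve(U, t(P %*% B), transpose = TRUE))
  })
  R <- length(deltas)
  acc <- numeric(10)
  for (m in 1:(R - 1)) for (n in (m + 1):R) {
    acc <- acc + rowSums(deltas[[m]] * deltas[[n]])
  }
  d <- acc / (V * R * (R - 1) / 2)
  pairs_to_rdm(d)
}

#' Mean dissimilarity of an RDM
#'
#' Arithmetic mean of the ten unique digit-pair dissimilarities (diagonal
#' excluded); the summary measure of representation strength.
#' @param rdm 5x5 RDM or 10-vector of unique pairs.
#' @return scalar.
#' @export
mean_dissimilarity <- function(rdm) {
  mean(rdm_pairs(rdm))
}

#' Typicality of a representational structure
#'
#' Spearman rank correlation (midranks for ties) between the ten unique pairs
#' of a measured RDM and those of a canonical reference RDM; a proxy for how
#' normal the hand representation is. Invariant under any strictly increasing
#' transform of either RDM.
#'
#' Values equal up to 10 significant digits are treated as tied: rank
#' statistics are otherwise unstable to floating-point jitter when the
#' reference contains exactly tied dissimilarities.
#'
#' @param rdm measured RDM (5x5 matrix or 10-vector).
#' @param canonical reference RDM (same conditions).
#' @return Spearman's rho in [-1, 1]; NaN with a warning if either vector is
#'   constant.
#' @export
typicality <- function(rdm, canonical) {
  x <- signif(rdm_pairs(rdm), 10)
  y <- signif(rdm_pairs(canonical), 10)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant RDM: typicality undefined")
    return(NaN)
  }
  stats::cor(x, y, method = "spearman")
}

#' Split-half consistency of an RDM
#'
#' Crossnobis RDMs are computed separately within the odd-numbered and
#' even-numbered runs (1-based run indices) and their pair vectors are
#' Spearman-correlated; a within-participant reliability measure.
#'
#' @param run_betas list of condition x voxel matrices, >= 4 runs (>= 2 per
#'   half).
#' @param noise a \code{"noise_model"}, shared by both halves (pooled
#'   estimate).
#' @return Spearman's rho.
#' @export
split_half_consistency <- function(run_betas, noise) {
  R <- length(run_betas)
  odd <- seq(1, R, by = 2)
  even <- seq(2, R, by = 2)
  if (length(odd) < 2 || length(even) < 2)
    stop("need at least 2 runs per half (4 runs total)")
  r_odd <- crossnobis(run_betas[odd], noise)
  r_even <- crossnobis(run_betas[even], noise)
  typicality(r_odd, r_even)
}
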