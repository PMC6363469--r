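#' Double-gamma hemodynamic response function
#'
#' Canonical difference-of-gammas HRF: a positive response gamma peaking at
#' \code{peak} seconds minus an undershoot gamma peaking at \code{undershoot}
#' seconds, scaled by \code{1/ratio}. Normalized to unit peak amplitude.
#'
#' @param t time in seconds (vector).
#' @param peak time-to-peak of the response (s).
#' @param undershoot time-to-peak of the undershoot (s).
#' @param ratio response-to-undershoot amplitude ratio.
#' @return numeric vector, same length as \code{t}.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / ratio
  h[t < 0] <- 0
  h / max(h)
}

#' Build a block-design matrix
#'
#' Each condition's regressor is its boxcar (1 during blocks, 0 elsewhere)
#' convolved with the double-gamma HRF, evaluated at a fine time grid and
#' sampled at the TR; a constant column is appended. Drift is handled
#' separately (see [highpass_filter()] / the \code{confounds} argument of
#' [fit_glm()]).
#'
#' @param schedule data.frame with columns \code{condition}, \code{onset_s},
#'   \code{duration_s}. May be empty (zero rows): only the constant remains.
#' @param n_timepoints number of volumes.
#' @param tr_s repetition time (s); must be > 0.
#' @param hrf_params list passed to [hrf_double_gamma()].
#' @param dt_s resolution of the internal convolution grid (s).
#' @return time x regressor matrix with labelled columns; attribute
#'   \code{"condition_cols"} gives the indices of the condition columns.
#' @export
build_design <- function(schedule, n_timepoints, tr_s, hrf_params = list(),
                         dt_s = 0.1) {
  if (tr_s <= 0) stop("tr_s must be positive")
  conds <- unique(as.character(schedule$condition))
  # reject overlapping blocks within a condition
  for (cn in conds) {
    s <- schedule[schedule$condition == cn, , drop = FALSE]
    s <- s[order(s$onset_s), , drop = FALSE]
    if (nrow(s) > 1 &&
        any(s$onset_s[-1] < (s$onset_s + s$duration_s)[-nrow(s)] - 1e-9))
      stop("overlapping blocks for condition ", cn)
  }
  total_s <- n_timepoints * tr_s
  grid <- seq(0, total_s + 32, by = dt_s)
  hrf <- do.call(hrf_double_gamma, c(list(t = seq(0, 32, by = dt_s)), hrf_params))
  sample_idx <- round(((seq_len(n_timepoints) - 1) * tr_s) / dt_s) + 1
  cols <- lapply(conds, function(cn) {
    s <- schedule[schedule$condition == cn, , drop = FALSE]
    box <- numeric(length(grid))
    for (k in seq_len(nrow(s))) {
      on <- grid >= s$onset_s[k] & grid < s$onset_s[k] + s$duration_s[k]
      box[on] <- 1
    }
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(grid)] * dt_s
    conv[sample_idx]
  })
  X <- cbind(do.call(cbind, cols), 1)
  colnames(X) <- c(conds, "constant")
  attr(X, "condition_cols") <- seq_along(conds)
  attr(X, "tr_s") <- tr_s
  X
}

# Number of DCT basis functions (including the constant) for a high-pass
# cutoff, as used by standard fMRI packages: floor(2*N*TR/cutoff + 1).
dct_n_basis <- function(n_timepoints, tr_s, cutoff_s) {
  max(1L, min(n_timepoints,
              as.integer(floor(2 * n_timepoints * tr_s / cutoff_s + 1))))
}

#' Discrete-cosine high-pass basis
#'
#' Unit-norm DCT-II basis spanning fluctuations slower than \code{cutoff_s};
#' the first column is the constant.
#'
#' @param n_timepoints number of volumes.
#' @param tr_s repetition time (s).
#' @param cutoff_s high-pass cutoff period (s); must exceed \code{2*tr_s}.
#' @return time x K matrix.
#' @export
dct_basis <- function(n_timepoints, tr_s, cutoff_s = 100) {
  if (cutoff_s <= 2 * tr_s) stop("cutoff_s must exceed 2*tr_s")
  K <- dct_n_basis(n_timepoints, tr_s, cutoff_s)
  n <- n_timepoints
  B <- sapply(0:(K - 1), function(k) cos(pi * (2 * seq_len(n) - 1) * k / (2 * n)))
  B <- as.matrix(B)
  sweep(B, 2, sqrt(colSums(B^2)), "/")
}

#' Drift basis for high-pass filtering
#'
#' The discrete-cosine basis plus an explicit centred linear trend column
#' (orthonormalized), so that constant and linear drift are removed exactly.
#' @inheritParams dct_basis
#' @return time x (K+1) matrix; first column is the constant.
#' @export
drift_basis <- function(n_timepoints, tr_s, cutoff_s = 100) {
  B <- dct_basis(n_timepoints, tr_s, cutoff_s)
  lin <- seq_len(n_timepoints) - (n_timepoints + 1) / 2
  lin <- lin - B %*% crossprod(B, lin)
  nrm <- sqrt(sum(lin^2))
  if (nrm > 1e-8) B <- cbind(B, lin / nrm)
  B
}

#' High-pass filter a time series
#'
#' Removes slow drift by projecting out the [drift_basis()] (discrete-cosine
#' set at the given cutoff period plus constant and linear trend, so the
#' output is mean-centred and detrended). Exactly linear, hence composable
#' with the GLM: filtering series and design then fitting equals fitting
#' with the basis included as confounds.
#'
#' @param series time x voxel numeric matrix (or vector).
#' @param tr_s repetition time (s).
#' @param cutoff_s cutoff period (s), default 100.
#' @return filtered series, same shape as input.
#' @export
highpass_filter <- function(series, tr_s, cutoff_s = 100) {
  series <- as.matrix(series)
  if (any(!is.finite(series))) stop("series contains non-finite values")
  B <- drift_basis(nrow(series), tr_s, cutoff_s)
  series - B %*% crossprod(B, series)
}

#' Fit a run-wise GLM
#'
#' Ordinary (or diagonally weighted) least squares of a voxel time series on
#' a design matrix. With a weight vector w, rows are scaled by sqrt(w) before
#' solving, which down-weights noisy volumes.
#'
#' @param series time x voxel matrix.
#' @param design time x regressor matrix from [build_design()].
#' @param weights optional per-timepoint positive weights.
#' @param confounds optional extra nuisance columns (e.g. [dct_basis()]).
#' @return List of class \code{"glm_result"}: \code{betas} (condition x
#'   voxel, condition columns of the design only), \code{all_betas},
#'   \code{residuals} (time x voxel), \code{dof} = n_timepoints - rank.
#' @export
fit_glm <- function(series, design, weights = NULL, confounds = NULL) {
  series <- as.matrix(series)
  if (nrow(series) != nrow(design))
    stop("series and design have different numbers of timepoints")
  cond_cols <- attr(design, "condition_cols")
  X <- design
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    colnames(confounds) <- paste0("confound", seq_len(ncol(confounds)))
    X <- cbind(X, confounds)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(weights)) {
    if (length(weights) != nrow(X) || any(weights <= 0))
      stop("weights must be positive, one per timepoint")
    sw <- sqrt(weights)
    fit <- qr(X * sw)
    coefs <- qr.coef(fit, series * sw)
    resid <- series - X %*% coefs
  } else {
    coefs <- qr.coef(qrX, series)
    resid <- qr.resid(qrX, series)
  }
  betas <- coefs[cond_cols, , drop = FALSE]
  rownames(betas) <- colnames(design)[cond_cols]
  structure(list(betas = betas, all_betas = coefs, residuals = resid,
                 dof = nrow(X) - qrX$rank),
            class = "glm_result")
}

#' Mean task-related activity
#'
#' Mean of the digit-condition betas across conditions and voxels; with rest
#' as the implicit baseline this is the average activation versus rest.
#'
#' @param betas condition x voxel matrix with condition rownames.
#' @param digit_labels conditions to average; default all rows.
#' @return scalar.
#' @export
mean_activity <- function(betas, digit_labels = rownames(betas)) {
  if (length(digit_labels) == 0) stop("no digit conditions given")
  if (!is.null(rownames(betas))) {
    missing <- setdiff(digit_labels, rownames(betas))
    if (length(missing))
      stop("conditions not present: ", paste(missing, collapse = ", "))
    betas <- betas[digit_labels, , drop = FALSE]
  }
  mean(betas)
}
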