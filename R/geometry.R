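#' Classical multidimensional scaling of an RDM
#'
#' Projects the RDM into a low-dimensional space by eigendecomposition of the
#' double-centred squared-dissimilarity matrix (via [stats::cmdscale()]),
#' preserving inter-digit dissimilarities as well as possible. Dimensions with
#' negative eigenvalues are dropped; an all-zero RDM maps every digit to the
#' origin. For visualization only.
#'
#' @param rdm 5x5 symmetric dissimilarity matrix with zero diagonal.
#' @param dims number of dimensions requested (default 2).
#' @return n x dims coordinate matrix (rownames from the RDM); columns beyond
#'   the available positive-eigenvalue dimensions are zero-filled.
#' @export
classical_mds <- function(rdm, dims = 2) {
  validate_rdm(rdm)
  n <- nrow(rdm)
  if (all(rdm == 0)) {
    out <- matrix(0, n, dims)
    rownames(out) <- rownames(rdm)
    return(out)
  }
  fit <- suppressWarnings(stats::cmdscale(rdm, k = min(dims, n - 1)))
  out <- matrix(0, n, dims)
  if (length(fit)) out[, seq_len(ncol(fit))] <- fit
  rownames(out) <- rownames(rdm)
  out
}

# Orthogonal Procrustes: rotation/reflection R minimizing ||X R - ref||_F
# for centred X, ref. Rigid (no scaling): within-configuration distances are
# preserved exactly.
procrustes_rotation <- function(X, ref) {
  s <- svd(crossprod(X, ref))
  s$u %*% t(s$v)
}

#' Procrustes alignment of MDS projections
#'
#' Aligns a set of per-participant digit projections by rigid orthogonal
#' transforms (rotation and reflection; optional translation to the common
#' centroid; no scaling by default) to remove the arbitrary rotation induced
#' by MDS, then averages them. Alignment is to the first configuration,
#' followed by one refinement pass against the running mean. Per-digit
#' dispersion is the between-participant standard error of the aligned
#' coordinates along each axis (for SE ellipses).
#'
#' @param projections list (>= 2) of point x dim coordinate matrices with
#'   identical dimensions.
#' @param translate centre each configuration at the origin first (default
#'   TRUE).
#' @param scale also match Frobenius norms (default FALSE: rigid).
#' @return List of class \code{"digit_projection"}: \code{aligned} (list of
#'   aligned matrices), \code{mean} (group-mean coordinates), \code{se}
#'   (point x dim standard errors), \code{n}.
#' @export
procrustes_align <- function(projections, translate = TRUE, scale = FALSE) {
  if (!is.list(projections) || length(projections) < 2)
    stop("need at least 2 projections")
  dims <- vapply(projections, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(dims)) != 1)
    stop("all projections must have identical dimensions")
  prep <- lapply(projections, function(p) {
    p <- as.matrix(p)
    if (translate) p <- sweep(p, 2, colMeans(p))
    p
  })
  align_to <- function(X, ref) {
    R <- procrustes_rotation(X, ref)
    Y <- X %*% R
    if (scale) {
      nrm <- sum(Y^2)
      if (nrm > 0) Y <- Y * (sum(Y * ref) / nrm)
    }
    Y
  }
  ref <- prep[[1]]
  aligned <- lapply(prep, align_to, ref = ref)
  m <- Reduce(`+`, aligned) / length(aligned)
  aligned <- lapply(prep, align_to, ref = m)
  m <- Reduce(`+`, aligned) / length(aligned)
  n <- length(aligned)
  sq <- Reduce(`+`, lapply(aligned, function(a) (a - m)^2))
  se <- sqrt(sq / (n - 1)) / sqrt(n)
  dimnames(m) <- dimnames(projections[[1]])
  dimnames(se) <- dimnames(projections[[1]])
  structure(list(aligned = aligned, mean = m, se = se, n = n),
            class = "digit_projection")
}
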