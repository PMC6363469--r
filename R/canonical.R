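#' Canonical inter-digit RDM
#'
#' Parametric reference representational dissimilarity matrix (RDM) for the
#' five digits D1 (thumb) to D5 (little finger). Dissimilarity between digits
#' i and j is \code{a + b*|i-j| + c*[i==1 or j==1]}: a baseline distance, a
#' neighbourhood gradient (adjacent digits are represented more similarly than
#' distant ones), and a thumb-distinctiveness boost. It stands in for an
#' empirical group-average hand RDM from an independent two-handed cohort;
#' users analysing real data should supply their own reference matrix to
#' [typicality()].
#'
#' With the default parameters the matrix is Euclidean-embeddable (its
#' double-centred Gram matrix is positive semi-definite), which the pattern
#' generator relies on to realize the geometry exactly.
#'
#' @param a baseline dissimilarity between any two digits; must be > 0.
#' @param b increment per unit of digit separation; >= 0.
#' @param c_thumb extra dissimilarity for pairs involving the thumb; >= 0.
#' @return A 5x5 symmetric numeric matrix with zero diagonal and dimnames
#'   \code{D1..D5}, of class \code{c("canonical_rdm", "matrix")}.
#' @examples
#' canonical_rdm()
#' canonical_rdm(a = 1, b = 0, c_thumb = 0)  # uniform geometry
#' @export
canonical_rdm <- function(a = 1, b = 0.5, c_thumb = 0.5) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' must be a single positive number")
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b < 0)
    stop("'b' must be a single non-negative number")
  if (!is.numeric(c_thumb) || length(c_thumb) != 1L || !is.finite(c_thumb) || c_thumb < 0)
    stop("'c_thumb' must be a single non-negative number")
  idx <- 1:5
  m <- outer(idx, idx, function(i, j) a + b * abs(i - j) + c_thumb * (i == 1 | j == 1))
  diag(m) <- 0
  dimnames(m) <- list(digit_labels(), digit_labels())
  class(m) <- c("canonical_rdm", class(m))
  m
}

digit_labels <- function() paste0("D", 1:5)

#' Labels of the ten unique digit pairs
#'
#' Pair order is fixed as D1D2, D1D3, D1D4, D1D5, D2D3, D2D4, D2D5, D3D4,
#' D3D5, D4D5 (row-major upper triangle) throughout the package.
#' @return Character vector of length 10.
#' @export
pair_labels <- function() {
  out <- character(0)
  for (i in 1:4) for (j in (i + 1):5) out <- c(out, paste0("D", i, "D", j))
  out
}

#' Vectorize an RDM into its ten unique pairs
#'
#' @param rdm 5x5 symmetric matrix with zero diagonal (or already a 10-vector,
#'   returned as-is).
#' @return Named numeric vector of length 10 in the canonical pair order.
#' @seealso [pairs_to_rdm()] for the inverse.
#' @export
rdm_pairs <- function(rdm) {
  if (is.numeric(rdm) && is.null(dim(rdm)) && length(rdm) == 10L) {
    names(rdm) <- pair_labels()
    return(rdm)
  }
  validate_rdm(rdm)
  v <- t(rdm)[lower.tri(rdm)]  # row-major upper triangle
  names(v) <- pair_labels()
  v
}

#' Rebuild a 5x5 RDM from its pair vector
#'
#' @param v numeric vector of length 10 in the canonical pair order.
#' @return 5x5 symmetric matrix with zero diagonal.
#' @export
pairs_to_rdm <- function(v) {
  stopifnot(is.numeric(v), length(v) == 10L)
  m <- matrix(0, 5, 5, dimnames = list(digit_labels(), digit_labels()))
  m[lower.tri(m)] <- v  # column-major lower triangle == row-major upper
  m <- m + t(m)
  m
}

validate_rdm <- function(rdm) {
  if (!is.matrix(rdm) || !is.numeric(rdm) || nrow(rdm) != ncol(rdm))
    stop("RDM must be a square numeric matrix")
  if (any(!is.finite(rdm))) stop("RDM contains non-finite entries")
  if (max(abs(rdm - t(rdm))) > 1e-8) stop("RDM must be symmetric")
  if (max(abs(diag(rdm))) > 1e-8) stop("RDM diagonal must be zero")
  invisible(rdm)
}
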