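# Preparation of the precision weight matrix used by the iterative
# bending engine.

validate_weight_matrix <- function(W, n, symmetry.tol = 1e-8) {
  W <- validate_matrix(W, symmetry.tol)
  if (nrow(W) != n) {
    pdbend_error(
      sprintf("weight matrix order (%d) does not match input matrix order (%d)",
              nrow(W), n),
      "pdbend_shape_error"
    )
  }
  if (any(W < 0)) {
    pdbend_error("weight matrix entries must be non-negative",
                 "pdbend_negative_weight_error")
  }
  W
}

#' Prepare the effective weight matrix for bending
#'
#' Builds the elementwise weights `w_ij` that control how much each matrix
#' element may move during iterative bending. Small weights protect
#' high-precision elements; a zero weight freezes an element entirely.
#'
#' The pipeline is applied in this order:
#' 1. if no weights are supplied, start from all ones (unweighted bending);
#' 2. if `reciprocal`, replace each nonzero `w_ij` by `1/w_ij` (so a matrix
#'    of record counts becomes precision weights); zeros stay zero;
#' 3. if the input being bent is a correlation matrix, zero the diagonal so
#'    unit variances are held fixed;
#' 4. if `normalize` and the maximum entry is positive, divide by the
#'    maximum entry, mapping the weights into `[0, 1]` (this rescaling
#'    shortens the iteration without changing the fixed point).
#'
#' @param raw Optional weight matrix (non-negative, symmetric). `NULL` means
#'   unweighted.
#' @param n Order of the matrix being bent.
#' @param reciprocal Use reciprocals of the nonzero entries (e.g. when `raw`
#'   holds the number of records behind each element).
#' @param is_correlation Whether the matrix being bent is a correlation
#'   matrix (diagonal then receives weight zero).
#' @param normalize Rescale by the maximum entry (default `TRUE`).
#' @return The effective weight matrix with entries in `[0, 1]`.
#' @examples
#' counts <- matrix(c(1000, 50, 50, 1000), 2, 2)
#' prepare_weights(counts, 2, reciprocal = TRUE, is_correlation = FALSE)
#' @export
prepare_weights <- function(raw, n, reciprocal = FALSE, is_correlation = FALSE,
                            normalize = TRUE) {
  W <- if (is.null(raw)) {
    matrix(1, n, n)
  } else {
    validate_weight_matrix(raw, n)
  }
  if (!is.null(raw) && reciprocal) {
    nz <- W != 0
    W[nz] <- 1 / W[nz]
  }
  if (is_correlation) diag(W) <- 0
  mx <- max(W)
  if (mx == 0) {
    pdbend_error(
      "all weights are zero: no element is allowed to change, matrix cannot be bent",
      "pdbend_unbendable_error"
    )
  }
  if (normalize) W <- W / mx
  W
}
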