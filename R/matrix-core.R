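# Core matrix validation, positive-definiteness predicates, and the
# spectral decomposition / reconstruction contract shared by all bending
# methods.

pdbend_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "pdbend_error"), call = call))
}

#' Validate a square symmetric numeric matrix
#'
#' Checks that the input is a square numeric matrix with finite entries that
#' is symmetric within tolerance, and returns it exactly symmetrized as
#' `(M + t(M)) / 2`. All bending entry points accept raw matrices and pass
#' them through this validator.
#'
#' @param raw A numeric matrix (or object coercible to one, e.g. a data
#'   frame of numbers).
#' @param symmetry.tol Relative symmetry tolerance: the maximum allowed
#'   absolute difference between `raw[i, j]` and `raw[j, i]`, as a fraction
#'   of the largest absolute entry. Asymmetry within tolerance is averaged
#'   away; beyond it the input is rejected.
#' @param labels Optional character vector of row/column names to attach.
#'
#' @return The validated, exactly symmetric numeric matrix (with `dimnames`
#'   when labels are present).
#'
#' @details Distinct error conditions are signalled for each failure mode:
#'   `pdbend_nonsquare_error`, `pdbend_nonfinite_error` and
#'   `pdbend_asymmetric_error` (all subclasses of `pdbend_error`).
#'
#' @examples
#' validate_matrix(matrix(c(4, 1, 1, 3), 2, 2))
#' @export
validate_matrix <- function(raw, symmetry.tol = 1e-8, labels = NULL) {
  if (is.data.frame(raw)) raw <- as.matrix(raw)
  if (!is.matrix(raw) || !is.numeric(raw)) {
    pdbend_error("input must be a numeric matrix", "pdbend_nonsquare_error")
  }
  if (nrow(raw) != ncol(raw)) {
    pdbend_error(
      sprintf("input must be square; got %d x %d", nrow(raw), ncol(raw)),
      "pdbend_nonsquare_error"
    )
  }
  if (any(!is.finite(raw))) {
    pdbend_error("input contains non-finite entries (NA/NaN/Inf)",
                 "pdbend_nonfinite_error")
  }
  scale <- max(abs(raw), 1e-300)
  asym <- max(abs(raw - t(raw)))
  if (asym > symmetry.tol * scale) {
    pdbend_error(
      sprintf("input is not symmetric: max |M - t(M)| = %g exceeds tolerance %g",
              asym, symmetry.tol * scale),
      "pdbend_asymmetric_error"
    )
  }
  out <- (raw + t(raw)) / 2
  if (!is.null(labels)) {
    if (length(labels) != nrow(out)) {
      pdbend_error("labels length does not match matrix order",
                   "pdbend_nonsquare_error")
    }
    dimnames(out) <- list(labels, labels)
  }
  out
}

#' Test whether a symmetric matrix is positive-definite
#'
#' A symmetric matrix is positive-definite (PD) when its smallest eigenvalue
#' is strictly greater than zero; positive semi-definite singular matrices
#' (smallest eigenvalue exactly zero) are not PD. No positive tolerance is
#' applied: the bending iterations stop at the first strictly PD iterate.
#'
#' @param M A validated symmetric numeric matrix.
#' @param symmetry.tol Passed to [validate_matrix()].
#' @return `TRUE` iff the smallest eigenvalue of `M` is strictly positive.
#' @examples
#' is_positive_definite(diag(5))        # TRUE
#' is_positive_definite(diag(c(1, 0)))  # FALSE: singular
#' @export
is_positive_definite <- function(M, symmetry.tol = 1e-8) {
  M <- validate_matrix(M, symmetry.tol)
  min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) > 0
}

#' Detect a correlation matrix
#'
#' A matrix is treated as a correlation matrix when every diagonal entry
#' equals 1 within `diag.tol`. Correlation matrices are bent with their
#' diagonal held fixed (see [bend()]).
#'
#' @param M A validated symmetric numeric matrix.
#' @param diag.tol Absolute tolerance for the diagonal test.
#' @return `TRUE` iff all diagonal entries are 1 within tolerance.
#' @examples
#' detect_correlation(diag(3))
#' @export
detect_correlation <- function(M, diag.tol = 1e-8) {
  all(abs(diag(M) - 1) <= diag.tol)
}

#' Eigendecomposition of a symmetric matrix
#'
#' Decomposes a symmetric matrix `V` as `U D U'` with eigenvalues in
#' descending order and orthonormal eigenvectors, the representation on
#' which all bending methods operate.
#'
#' @param M A validated symmetric numeric matrix.
#' @return An object of class `spectral_decomposition`: a list with
#'   `values` (descending eigenvalues) and `vectors` (orthonormal columns).
#' @examples
#' spectral_decompose(diag(c(3, 1)))$values
#' @export
spectral_decompose <- function(M) {
  M <- validate_matrix(M)
  e <- eigen(M, symmetric = TRUE)
  if (any(!is.finite(e$values)) || any(!is.finite(e$vectors))) {
    pdbend_error("eigendecomposition produced non-finite values",
                 "pdbend_numerical_error")
  }
  structure(list(values = e$values, vectors = e$vectors, n = nrow(M)),
            class = "spectral_decomposition")
}

#' Rebuild a symmetric matrix from eigenvectors and (replaced) eigenvalues
#'
#' Computes `U diag(values) U'` and enforces exact symmetry of the result
#' (floating-point reconstruction is symmetric only up to rounding).
#'
#' @param dec A `spectral_decomposition` from [spectral_decompose()].
#' @param values Replacement eigenvalues, one per original eigenvalue.
#' @return The reconstructed, exactly symmetric matrix.
#' @examples
#' d <- spectral_decompose(diag(c(2, -1)))
#' reconstruct_symmetric(d, c(2, 0.5))
#' @export
reconstruct_symmetric <- function(dec, values) {
  stopifnot(inherits(dec, "spectral_decomposition"))
  if (length(values) != dec$n) {
    pdbend_error(
      sprintf("expected %d eigenvalues, got %d", dec$n, length(values)),
      "pdbend_length_error"
    )
  }
  M <- dec$vectors %*% (values * t(dec$vectors))
  (M + t(M)) / 2
}

#' @export
print.spectral_decomposition <- function(x, ...) {
  cat("Spectral decomposition (order", x$n, ")\n")
  cat("Eigenvalues:", format(x$values, digits = 6), "\n")
  invisible(x)
}
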