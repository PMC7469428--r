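# Built-in example matrices: the classic 5 x 5 non-PD covariance matrix of
# Jorjani, Klei and Emanuelson (2003), also used by Schaeffer (2014), with
# its companion weight matrix.

#' Built-in example matrices
#'
#' Returns the 5 x 5 matrices used throughout the documentation and tests:
#'
#' * `"V"` — the classic non-positive-definite covariance matrix of Jorjani,
#'   Klei and Emanuelson (2003) (two negative eigenvalues).
#' * `"W_counts"` — the matrix of record counts behind each element of `V`.
#' * `"W"` — the weight matrix, the elementwise reciprocal of `W_counts`.
#' * `"C"` — the correlation matrix `V / 100` (the diagonal of `V` is 100).
#'
#' @param name One of `"V"`, `"W_counts"`, `"W"`, `"C"`.
#' @return The requested 5 x 5 numeric matrix.
#' @examples
#' example_matrix("V")
#' round(eigen(example_matrix("V"))$values, 2)
#' @export
example_matrix <- function(name = c("V", "W_counts", "W", "C")) {
  name <- match.arg(name)
  V <- matrix(c(
    100, 95, 80, 40, 40,
    95, 100, 95, 80, 40,
    80, 95, 100, 95, 80,
    40, 80, 95, 100, 95,
    40, 40, 80, 95, 100
  ), nrow = 5, byrow = TRUE)
  counts <- matrix(c(
    1000, 500, 20, 50, 200,
    500, 1000, 500, 5, 50,
    20, 500, 1000, 20, 20,
    50, 5, 20, 1000, 200,
    200, 50, 20, 200, 1000
  ), nrow = 5, byrow = TRUE)
  switch(name,
    V = V,
    W_counts = counts,
    W = 1 / counts,
    C = V / 100
  )
}
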