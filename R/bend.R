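# The three bending methods and the iterative weighted engine.

PD_MESSAGE <- "No action was required. The matrix is positive-definite"

#' Floor a spectrum at a small positive value (HJ03 step)
#'
#' Replaces every eigenvalue smaller than `epsilon` with `epsilon`. Note the
#' flooring applies to all eigenvalues below epsilon, not only the negative
#' ones: positive eigenvalues in `(0, epsilon)` are raised too, which is what
#' distinguishes this rule from the iterative spectral method.
#'
#' @param values Eigenvalues in descending order.
#' @param epsilon Small positive floor (the `small.positive` of [bend()]).
#' @return The floored eigenvalues, still in descending order.
#' @examples
#' hj_floor(c(399.48, 98.52, 23.65, -3.12, -18.52), 1e-4)
#' @export
hj_floor <- function(values, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    pdbend_error("epsilon (small.positive) must be a single value > 0",
                 "pdbend_epsilon_error")
  }
  pmax(values, epsilon)
}

#' Replace negative eigenvalues by small positive values in descending order
#'
#' The LRS14 rule: each of the `m` negative eigenvalues `lambda_i` is
#' replaced with `rho * (s - lambda_i)^2 / (100 * s^2 + 1)`, where `rho` is
#' the smallest positive eigenvalue and `s` is twice the sum of the negative
#' eigenvalues. The replacements are strictly positive, smaller than `rho`,
#' and decrease with the eigenvalue they replace, so the spectrum remains in
#' descending order.
#'
#' @param values Eigenvalues in descending order.
#' @return A list with `values` (the modified spectrum), `m` (number of
#'   negative eigenvalues), `s`, `rho`, and `replacements` (the `m` new
#'   values, in the order of the eigenvalues they replace).
#' @examples
#' lrs_replace(c(399.48, 98.52, 23.65, -3.12, -18.52))
#' @export
lrs_replace <- function(values) {
  neg <- values < 0
  m <- sum(neg)
  if (m == 0) {
    if (min(values) <= 0) {
      pdbend_error(
        paste("spectrum has zero but no negative eigenvalues: the negative-",
              "eigenvalue replacement rule cannot make progress.",
              "Consider method 'hj'."),
        "pdbend_stagnation_error"
      )
    }
    return(list(values = values, m = 0L, s = 0, rho = min(values),
                replacements = numeric(0)))
  }
  if (!any(values > 0)) {
    pdbend_error(
      "no positive eigenvalue: matrix cannot be bent by negative-eigenvalue replacement",
      "pdbend_unbendable_error"
    )
  }
  s <- 2 * sum(values[neg])
  rho <- min(values[values > 0])
  repl <- rho * (s - values[neg])^2 / (100 * s^2 + 1)
  out <- values
  out[neg] <- repl
  list(values = out, m = as.integer(m), s = s, rho = rho, replacements = repl)
}

#' Hadamard-weighted update step
#'
#' One step of the weighted iteration:
#' `V_{n+1} = V_n - (V_n - target) o W`, elementwise. Equivalently the convex
#' blend `V_n o (11' - W) + target o W`. Entries with `w_ij = 0` are returned
#' bit-for-bit from `current`.
#'
#' @param current Current iterate.
#' @param target Spectrally corrected reconstruction to move towards.
#' @param weights Effective weight matrix with entries in `[0, 1]`.
#' @return The updated matrix.
#' @export
weighted_update <- function(current, target, weights) {
  if (!all(dim(current) == dim(target)) || !all(dim(current) == dim(weights))) {
    pdbend_error("current, target and weights must have identical dimensions",
                 "pdbend_shape_error")
  }
  out <- current - (current - target) * weights
  # exact elementwise contract for frozen entries
  out[weights == 0] <- current[weights == 0]
  out
}

#' Covariance to correlation transform (and back)
#'
#' `cov_cor_transform()` scales a covariance matrix `V` with positive
#' diagonal to the correlation matrix `C = T^-1 V T^-1`, where
#' `T = diag(sqrt(diag(V)))`; `cor_to_cov()` inverts the transform as
#' `T C T'`, reproducing the original diagonal exactly.
#'
#' @param V Covariance matrix with strictly positive diagonal.
#' @return For `cov_cor_transform()`, a list with `C` (unit-diagonal
#'   correlation matrix) and `t_diag` (the vector of `sqrt(v_ii)`).
#' @examples
#' tr <- cov_cor_transform(matrix(c(4, 2, 2, 9), 2, 2))
#' cor_to_cov(tr$C, tr$t_diag)
#' @export
cov_cor_transform <- function(V) {
  d <- diag(V)
  if (any(d <= 0)) {
    pdbend_error("covariance matrix has non-positive diagonal entries; cannot scale to correlation",
                 "pdbend_diagonal_error")
  }
  t_diag <- sqrt(d)
  C <- V / tcrossprod(t_diag)
  diag(C) <- 1
  list(C = C, t_diag = t_diag)
}

#' @rdname cov_cor_transform
#' @param C Correlation matrix.
#' @param t_diag Vector of scale factors (`sqrt` of the target diagonal).
#' @export
cor_to_cov <- function(C, t_diag) {
  V <- C * tcrossprod(t_diag)
  diag(V) <- t_diag^2
  (V + t(V)) / 2
}

#' Smooth a correlation matrix by spectrum rescaling (DB88)
#'
#' Single-pass smoothing designed for correlation matrices: eigenvalues
#' smaller than `epsilon` are replaced with `100 * epsilon`, the spectrum is
#' rescaled, the matrix is reconstructed and renormalized to a unit
#' diagonal. Covariance matrices are handled by [bend()] via the
#' covariance/correlation round trip, so only their off-diagonal elements
#' change.
#'
#' Two rescaling dialects are provided:
#' * `"rescale_all"` (default): after flooring, all eigenvalues are scaled
#'   by `n / sum(values)` so the spectrum sums to the matrix order, the
#'   trace of a valid correlation matrix.
#' * `"rescale_positive"`: only the eigenvalues above `epsilon` are scaled,
#'   so that they sum to their own count.
#'
#' If the smallest eigenvalue is already at least `epsilon`, the matrix is
#' returned unchanged.
#'
#' @param M Correlation matrix (unit diagonal).
#' @param epsilon Eigenvalue threshold (> 0).
#' @param dialect One of `"rescale_all"`, `"rescale_positive"`.
#' @return The smoothed, unit-diagonal matrix.
#' @export
db_smooth <- function(M, epsilon = 1e-4,
                      dialect = c("rescale_all", "rescale_positive")) {
  dialect <- match.arg(dialect)
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    pdbend_error("epsilon must be a single value > 0", "pdbend_epsilon_error")
  }
  dec <- spectral_decompose(M)
  d0 <- dec$values
  n <- dec$n
  if (min(d0) >= epsilon) return(M)
  d <- d0
  d[d < epsilon] <- 100 * epsilon
  if (dialect == "rescale_all") {
    d <- d * n / sum(d)
  } else {
    hi <- d0 > epsilon
    if (any(hi)) d[hi] <- d[hi] * sum(hi) / sum(d[hi])
  }
  out <- reconstruct_symmetric(dec, d)
  sc <- 1 / sqrt(diag(out))
  out <- out * tcrossprod(sc)
  diag(out) <- 1
  (out + t(out)) / 2
}

bend_options <- function(method = c("hj", "lrs", "db"),
                         small.positive = 1e-4,
                         max.iter = 10000,
                         reciprocal = FALSE,
                         normalize.weights = TRUE,
                         db.dialect = c("rescale_all", "rescale_positive"),
                         lrs.floor = 5e-9) {
  method <- match.arg(method)
  db.dialect <- match.arg(db.dialect)
  if (!is.numeric(small.positive) || small.positive <= 0) {
    pdbend_error("small.positive must be > 0", "pdbend_epsilon_error")
  }
  if (!is.numeric(max.iter) || max.iter < 1) {
    pdbend_error("max.iter must be a positive integer", "pdbend_option_error")
  }
  list(method = method, small.positive = small.positive,
       max.iter = as.integer(max.iter), reciprocal = isTRUE(reciprocal),
       normalize.weights = isTRUE(normalize.weights),
       db.dialect = db.dialect, lrs.floor = lrs.floor)
}

#' Bend a symmetric matrix to positive-definite
#'
#' Transforms a symmetric non-positive-definite (non-PD) matrix into a PD
#' matrix by modifying its eigenvalues, optionally weighting each element by
#' its precision so that well-estimated elements move little (a zero weight
#' freezes an element). Correlation matrices are recognised automatically
#' (unit diagonal) and bent with the diagonal held fixed.
#'
#' Methods:
#' * `"hj"` — iterative weighted flooring: eigenvalues below
#'   `small.positive` are floored to it, the matrix is reconstructed, and
#'   the iterate moves towards the reconstruction under the Hadamard weight
#'   blend, until the iterate is PD. Without weights a single reconstruction
#'   suffices.
#' * `"lrs"` — negative eigenvalues are replaced by
#'   `rho (s - lambda)^2 / (100 s^2 + 1)` (see [lrs_replace()]), giving
#'   small positive replacements in descending order. With weights, the
#'   replacement is recomputed each iteration and combined with the same
#'   Hadamard update as `"hj"`. `small.positive` is ignored for this method.
#' * `"db"` — single-pass correlation smoothing ([db_smooth()]); covariance
#'   input is scaled to correlation and back, so its diagonal is unchanged.
#'   Weights are ignored (with a warning).
#'
#' @param inmat Square symmetric numeric matrix to bend.
#' @param wtmat Optional weight matrix of the same order (non-negative,
#'   symmetric). Larger `w_ij` lets `v_ij` move more; `w_ij = 0` freezes it.
#' @param method `"hj"`, `"lrs"` or `"db"`.
#' @param small.positive Eigenvalue floor for `"hj"` and threshold for
#'   `"db"` (default `1e-4`).
#' @param max.iter Iteration cap for the weighted methods (default 10000).
#' @param reciprocal If `TRUE`, nonzero weight entries are replaced by their
#'   reciprocals before use (pass a matrix of record counts directly).
#' @param normalize.weights Rescale weights by their maximum (default
#'   `TRUE`); see [prepare_weights()].
#' @param db.dialect Spectrum rescaling dialect for `"db"`; see
#'   [db_smooth()].
#' @param lrs.floor Termination guard for weighted `"lrs"`: eigenvalue
#'   replacements are bounded below by this value (default `5e-9`, of the
#'   order of the square root of machine epsilon). Near the PD boundary the
#'   replacement formula vanishes quadratically in the offending eigenvalue,
#'   so without a floor the weighted iteration can approach positive
#'   semi-definiteness without ever attaining strict positive definiteness.
#' @param symmetry.tol Relative symmetry tolerance for input validation.
#'
#' @return An object of class `bend_result`: a list with `bent` (the PD
#'   matrix), `initial.ev` and `final.ev` (spectra before/after),
#'   `iterations`, `converged`, `message`, `stats` (a
#'   [deviation_summary()] between input and output), `correlation`
#'   (whether the input was treated as a correlation matrix), `method`,
#'   `weighted`, and `effective.weights` (the prepared weight matrix, when
#'   weighted).
#'
#' @details If the input is already PD it is returned unchanged with zero
#' iterations and the message `"No action was required. The matrix is
#' positive-definite"`. If `max.iter` is reached without a PD iterate the
#' result is returned with `converged = FALSE` and a warning. If method
#' `"lrs"` encounters a spectrum with zero but no negative eigenvalues, the
#' iteration stops with `converged = FALSE` and an advisory message
#' (method `"hj"` handles such spectra).
#'
#' @examples
#' V <- example_matrix("V")
#' b <- bend(V)                     # unweighted flooring, one iteration
#' b$final.ev
#' bend(V, example_matrix("W_counts"), reciprocal = TRUE, method = "lrs")
#' @export
bend <- function(inmat, wtmat = NULL,
                 method = c("hj", "lrs", "db"),
                 small.positive = 1e-4,
                 max.iter = 10000,
                 reciprocal = FALSE,
                 normalize.weights = TRUE,
                 db.dialect = c("rescale_all", "rescale_positive"),
                 lrs.floor = 5e-9,
                 symmetry.tol = 1e-8) {
  opts <- bend_options(method, small.positive, max.iter, reciprocal,
                       normalize.weights, db.dialect, lrs.floor)
  V <- validate_matrix(inmat, symmetry.tol)
  n <- nrow(V)
  init_ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  is_cor <- detect_correlation(V)
  weighted <- !is.null(wtmat)

  finish <- function(bent, iterations, converged, msg, W_eff = NULL,
                     stats_weights = NULL) {
    final_ev <- eigen(bent, symmetric = TRUE, only.values = TRUE)$values
    stats <- deviation_summary(V, bent, weights = stats_weights,
                               correlation = is_cor)
    structure(list(
      bent = bent,
      initial.ev = init_ev,
      final.ev = final_ev,
      iterations = as.integer(iterations),
      converged = converged,
      message = msg,
      stats = stats,
      correlation = is_cor,
      method = opts$method,
      weighted = !is.null(stats_weights),
      effective.weights = W_eff,
      options = opts
    ), class = "bend_result")
  }

  if (min(init_ev) > 0) {
    message(PD_MESSAGE)
    return(finish(V, 0L, TRUE, PD_MESSAGE))
  }

  if (opts$method == "db") {
    if (weighted) {
      warning("method 'db' is unweighted; the supplied weight matrix is ignored")
    }
    if (is_cor) {
      bent <- db_smooth(V, opts$small.positive, opts$db.dialect)
    } else {
      tr <- cov_cor_transform(V)
      bent <- cor_to_cov(db_smooth(tr$C, opts$small.positive, opts$db.dialect),
                         tr$t_diag)
      diag(bent) <- diag(V)  # exact: only off-diagonal elements may change
    }
    ok <- is_positive_definite(bent)
    return(finish(bent, 1L, ok,
                  if (ok) "Matrix smoothed to positive-definite in a single pass"
                  else "Smoothing did not reach positive definiteness; try a smaller epsilon"))
  }

  if (opts$method == "lrs" && !missing(small.positive)) {
    message("small.positive is ignored for method 'lrs'")
  }

  W_eff <- prepare_weights(wtmat, n, reciprocal = opts$reciprocal,
                           is_correlation = is_cor,
                           normalize = opts$normalize.weights)
  stats_weights <- if (weighted) W_eff else NULL
  pure_unweighted <- all(W_eff == 1)

  cur <- V
  it <- 0L
  repeat {
    dec <- spectral_decompose(cur)
    if (min(dec$values) > 0) {
      return(finish(cur, it, TRUE,
                    sprintf("Convergence met after %d iteration%s", it,
                            if (it == 1) "" else "s"),
                    W_eff, stats_weights))
    }
    if (it >= opts$max.iter) {
      warning(sprintf("not positive-definite after max.iter = %d iterations",
                      opts$max.iter))
      return(finish(cur, it, FALSE,
                    sprintf("Convergence was not met after %d iterations", it),
                    W_eff, stats_weights))
    }
    delta <- if (opts$method == "hj") {
      hj_floor(dec$values, opts$small.positive)
    } else {
      rep_try <- tryCatch(lrs_replace(dec$values),
                          pdbend_stagnation_error = function(e) e)
      if (inherits(rep_try, "pdbend_stagnation_error")) {
        warning(conditionMessage(rep_try))
        return(finish(cur, it, FALSE, conditionMessage(rep_try),
                      W_eff, stats_weights))
      }
      pmax(rep_try$values, opts$lrs.floor)
    }
    target <- reconstruct_symmetric(dec, delta)
    cur <- if (pure_unweighted) target else weighted_update(cur, target, W_eff)
    it <- it + 1L
  }
}

#' @export
print.bend_result <- function(x, digits = 4, ...) {
  cat("Bending result (method ", x$method,
      if (x$weighted) ", weighted" else ", unweighted",
      if (x$correlation) ", correlation matrix" else "", ")\n", sep = "")
  cat(x$message, "\n")
  cat("Iterations:", x$iterations,
      " Converged:", x$converged, "\n")
  cat("Initial eigenvalues:", round(x$initial.ev, digits), "\n")
  cat("Final eigenvalues:  ", format(x$final.ev, digits = digits), "\n")
  cat("\nBent matrix:\n")
  print(round(x$bent, digits))
  cat("\n")
  print(x$stats, digits = digits)
  invisible(x)
}
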