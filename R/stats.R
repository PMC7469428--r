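# Deviation and correlation diagnostics between an original matrix and its
# bent counterpart.

#' Weighted Pearson correlation
#'
#' Pearson correlation with observation importance weights: means, variances
#' and the covariance are computed under weights proportional to `w`. Used
#' with weights `1/w_ij` so that high-precision (small `w_ij`) elements
#' dominate, matching the weighting convention of the weighted average
#' absolute deviation.
#'
#' @param x,y Numeric vectors of equal length (at least 2).
#' @param w Positive importance weights.
#' @return The weighted correlation, in `[-1, 1]`.
#' @examples
#' weighted_pearson(1:4, c(1.2, 1.9, 3.3, 3.9), rep(1, 4))
#' @export
weighted_pearson <- function(x, y, w) {
  if (length(x) != length(y) || length(x) != length(w) || length(x) < 2) {
    pdbend_error("x, y and w must have equal length >= 2", "pdbend_shape_error")
  }
  if (any(w <= 0)) {
    pdbend_error("weights must be strictly positive", "pdbend_negative_weight_error")
  }
  w <- w / sum(w)
  mx <- sum(w * x)
  my <- sum(w * y)
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) {
    pdbend_error("weighted variance is zero: correlation undefined",
                 "pdbend_degenerate_correlation_error")
  }
  r <- sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
  min(1, max(-1, r))
}

# Upper-triangle indices in row-major order (row by row), so that ties in
# min/max deviations resolve to the first occurrence by row then column.
upper_triangle_indices <- function(n, include_diag) {
  idx <- which(upper.tri(matrix(0, n, n), diag = include_diag), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Deviation and correlation summary between original and bent matrices
#'
#' Computes the diagnostics used to judge bending quality, over the upper
#' triangle of the deviation matrix `bent - original`. For covariance
#' matrices the upper triangle includes the diagonal (`n(n+1)/2` elements);
#' for correlation matrices it excludes it (`n(n-1)/2` elements), since the
#' diagonal never changes.
#'
#' Unweighted statistics: minimum and maximum deviation (with 1-based
#' `(row, column)` indices of the first extreme element in row-major
#' order), mean deviation, average absolute deviation
#' `AAD = sum(|d_ij|) / N`, Pearson correlation between the original and
#' bent elements, and `RMSD = sqrt(sum(d_ij^2) / N)`.
#'
#' Weighted statistics (when `weights` are supplied) are computed over the
#' elements with `w_ij > 0` only:
#' `weighted AAD = sum(|d_ij / w_ij|) / sum(1 / w_ij)`,
#' `weighted RMSD = sqrt(sum((d_ij / w_ij)^2) / sum(1 / w_ij^2))`, and the
#' weighted correlation of [weighted_pearson()] with importance weights
#' `1/w_ij`. The number of upper-triangle elements with `w_ij > 0`
#' (`w_gt_0`) is reported, as the weighted statistics rely on them.
#'
#' @param original,bent Symmetric matrices of the same order.
#' @param weights Optional weight matrix (as used for bending).
#' @param correlation Treat the pair as correlation matrices (exclude the
#'   diagonal). Default: auto-detect from `original`.
#' @return An object of class `deviation_stats`.
#' @examples
#' V <- example_matrix("V")
#' deviation_summary(V, bend(V)$bent)
#' @export
deviation_summary <- function(original, bent, weights = NULL,
                              correlation = NULL) {
  original <- validate_matrix(original)
  bent <- validate_matrix(bent)
  if (!all(dim(original) == dim(bent))) {
    pdbend_error("original and bent matrices must have the same order",
                 "pdbend_shape_error")
  }
  n <- nrow(original)
  if (is.null(correlation)) correlation <- detect_correlation(original)
  include_diag <- !correlation
  if (n == 1 && correlation) {
    pdbend_error("no off-diagonal elements in a 1 x 1 correlation matrix",
                 "pdbend_shape_error")
  }
  idx <- upper_triangle_indices(n, include_diag)
  v <- original[idx]
  vhat <- bent[idx]
  d <- vhat - v

  i_min <- which.min(d)
  i_max <- which.max(d)
  out <- list(
    min.dev = d[i_min], loc.min = unname(idx[i_min, ]),
    max.dev = d[i_max], loc.max = unname(idx[i_max, ]),
    mean.dev = mean(d),
    aad = mean(abs(d)),
    # cor() is undefined for constant vectors: identical inputs correlate
    # perfectly by convention, otherwise report NA rather than warn
    correlation = if (all(d == 0)) 1
                  else if (stats::sd(v) == 0 || stats::sd(vhat) == 0) NA_real_
                  else stats::cor(v, vhat),
    rmsd = sqrt(mean(d^2)),
    includes.diagonal = include_diag,
    n = n
  )

  if (!is.null(weights)) {
    W <- validate_weight_matrix(weights, n)
    w <- W[idx]
    keep <- w > 0
    if (!any(keep)) {
      pdbend_error("weighted statistics requested but no weight is positive",
                   "pdbend_negative_weight_error")
    }
    dw <- d[keep] / w[keep]
    out$w.gt.0 <- sum(keep)
    out$weighted.aad <- sum(abs(dw)) / sum(1 / w[keep])
    out$weighted.rmsd <- sqrt(sum(dw^2) / sum(1 / w[keep]^2))
    out$weighted.correlation <- weighted_pearson(v[keep], vhat[keep],
                                                 1 / w[keep])
  }
  structure(out, class = "deviation_stats")
}

#' Flatten a deviation summary to a named numeric vector
#'
#' Serializable key/value form of [deviation_summary()], used by the text
#' and JSON reports.
#'
#' @param stats A `deviation_stats` object.
#' @return Named numeric vector.
#' @export
deviation_stats_flat <- function(stats) {
  stopifnot(inherits(stats, "deviation_stats"))
  out <- c(
    min_dev = stats$min.dev, min_dev_row = stats$loc.min[1],
    min_dev_col = stats$loc.min[2],
    max_dev = stats$max.dev, max_dev_row = stats$loc.max[1],
    max_dev_col = stats$loc.max[2],
    mean_dev = stats$mean.dev, aad = stats$aad,
    correlation = stats$correlation, rmsd = stats$rmsd
  )
  if (!is.null(stats$weighted.aad)) {
    out <- c(out,
             weighted_aad = stats$weighted.aad,
             weighted_correlation = stats$weighted.correlation,
             weighted_rmsd = stats$weighted.rmsd,
             w_gt_0 = stats$w.gt.0)
  }
  out
}

#' @export
print.deviation_stats <- function(x, digits = 4, ...) {
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  cat("Deviation between upper-triangle elements (",
      if (x$includes.diagonal) "including" else "excluding",
      " diagonal)\n", sep = "")
  cat("  Min (dev.):  ", fmt(x$min.dev),
      sprintf("  at (%d, %d)", x$loc.min[1], x$loc.min[2]), "\n")
  cat("  Max (dev.):  ", fmt(x$max.dev),
      sprintf("  at (%d, %d)", x$loc.max[1], x$loc.max[2]), "\n")
  cat("  Mean (dev.): ", fmt(x$mean.dev), "\n")
  cat("  AAD:         ", fmt(x$aad), "\n")
  cat("  Correlation: ", fmt(x$correlation), "\n")
  cat("  RMSD:        ", fmt(x$rmsd), "\n")
  if (!is.null(x$weighted.aad)) {
    cat("  Weighted AAD: ", fmt(x$weighted.aad), "\n")
    cat("  Weighted correlation:", fmt(x$weighted.correlation), "\n")
    cat("  Weighted RMSD:", fmt(x$weighted.rmsd), "\n")
    cat("  w_gt_0:      ", x$w.gt.0, "\n")
  }
  invisible(x)
}
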