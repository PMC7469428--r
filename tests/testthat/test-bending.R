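V <- example_matrix("V")
C <- example_matrix("C")
W_counts <- example_matrix("W_counts")

test_that("eigenvalue flooring raises everything below epsilon", {
  ev <- spectral_decompose(V)$values
  fl <- hj_floor(ev, 1e-4)
  expect_identical(fl[1:3], ev[1:3])        # eigenvalues above epsilon untouched
  expect_identical(fl[4:5], c(1e-4, 1e-4))  # both negatives floored to epsilon
  expect_identical(hj_floor(c(5, 2, 1), 1e-4), c(5, 2, 1))
  expect_identical(hj_floor(c(1.0, 5e-5), 1e-4), c(1.0, 1e-4))  # sub-epsilon positive raised
  expect_error(hj_floor(c(1, 2), 0), class = "pdbend_epsilon_error")
  expect_error(hj_floor(c(1, 2), -1), class = "pdbend_epsilon_error")
})

test_that("negative-eigenvalue replacement reproduces the published first-iteration values", {
  rv <- lrs_replace(spectral_decompose(V)$values)
  expect_equal(rv$m, 2L)
  expect_equal(round(rv$replacements, 4), c(0.2036, 0.0774))
  rc <- lrs_replace(spectral_decompose(C)$values)
  expect_equal(round(rc$replacements, 4), c(0.0019, 0.0007))

  # no negatives on a PD spectrum: unchanged
  same <- lrs_replace(c(3, 1))
  expect_equal(same$values, c(3, 1))
  expect_equal(same$m, 0L)

  expect_error(lrs_replace(c(-1, -2)), class = "pdbend_unbendable_error")
  expect_error(lrs_replace(c(1, 0)), class = "pdbend_stagnation_error")
})

test_that("replacements stay in (0, rho) and preserve descending order", {
  for (seed in 1:15) {
    n <- 3 + seed %% 8
    ev <- spectral_decompose(random_nonpd(n, seed))$values
    r <- lrs_replace(ev)
    expect_true(all(r$replacements > 0))
    expect_true(all(r$replacements < r$rho))
    expect_true(all(diff(r$values) <= 1e-12))
    # less-negative eigenvalue receives the larger replacement
    if (r$m > 1) expect_true(all(diff(r$replacements) < 0))
    # positive eigenvalues untouched
    expect_identical(r$values[ev > 0], ev[ev > 0])
  }
})

test_that("the Hadamard update honours its algebraic contracts", {
  n <- 5
  cur <- random_symmetric(n, 11)
  tgt <- random_symmetric(n, 12)
  ones <- matrix(1, n, n)
  expect_equal(weighted_update(cur, tgt, ones), tgt)
  expect_identical(weighted_update(cur, tgt, ones * 0), cur)

  W <- matrix(0.3, n, n); W[2, 4] <- W[4, 2] <- 0
  out <- weighted_update(cur, tgt, W)
  expect_identical(out[2, 4], cur[2, 4])  # frozen bit-for-bit
  expect_equal(out[1, 1], cur[1, 1] - (cur[1, 1] - tgt[1, 1]) * 0.3)
  expect_error(weighted_update(cur, tgt[1:4, 1:4], W),
               class = "pdbend_shape_error")
})

test_that("weight preparation applies reciprocal, diagonal zeroing and normalization in order", {
  # counts with reciprocal: equals 1/counts scaled by its max
  W <- prepare_weights(W_counts, 5, reciprocal = TRUE)
  expect_equal(W, (1 / W_counts) / max(1 / W_counts))
  expect_equal(max(W), 1)
  expect_equal(W[2, 4], 1)  # the smallest count (5) gets the largest weight

  # absent weights, correlation: ones with zero diagonal
  Wc <- prepare_weights(NULL, 3, is_correlation = TRUE)
  expect_equal(diag(Wc), rep(0, 3))
  expect_equal(Wc[upper.tri(Wc)], rep(1, 3))

  # absent weights, covariance: all ones
  expect_equal(prepare_weights(NULL, 4), matrix(1, 4, 4))

  # zeros survive reciprocal
  Wz <- W_counts; Wz[1, 2] <- Wz[2, 1] <- 0
  expect_equal(prepare_weights(Wz, 5, reciprocal = TRUE)[1, 2], 0)

  # no normalization flag
  expect_equal(prepare_weights(W_counts, 5, reciprocal = TRUE,
                               normalize = FALSE), 1 / W_counts)

  expect_error(prepare_weights(-W_counts, 5),
               class = "pdbend_negative_weight_error")
  expect_error(prepare_weights(matrix(0, 3, 3), 3),
               class = "pdbend_unbendable_error")
  expect_error(prepare_weights(W_counts, 4), class = "pdbend_shape_error")
})

test_that("already-PD input short-circuits with the canonical message, and bending is idempotent", {
  expect_message(res <- bend(diag(5)),
                 "No action was required. The matrix is positive-definite",
                 fixed = TRUE)
  expect_identical(res$bent, diag(5))
  expect_identical(res$iterations, 0L)
  expect_true(res$converged)
  expect_equal(res$message, "No action was required. The matrix is positive-definite")

  for (method in c("hj", "lrs", "db")) {
    first <- bend(V, method = method)
    expect_message(again <- bend(first$bent, method = method),
                   "No action was required", fixed = TRUE)
    expect_identical(again$iterations, 0L)
    expect_identical(again$bent, first$bent)
  }
})

test_that("unweighted flooring obeys the spectral oracle on random non-PD matrices", {
  for (seed in c(1, 7, 23)) {
    n <- c(4, 12, 20)[which(c(1, 7, 23) == seed)]
    M <- random_nonpd(n, seed)
    res <- bend(M, small.positive = 1e-4)
    expect_identical(res$iterations, 1L)
    expect_true(res$converged)
    expect_equal(res$final.ev, hj_floor(spectral_decompose(M)$values, 1e-4),
                 tolerance = 1e-8)
  }
})

test_that("zero-weight elements never move, at any iteration", {
  Wz <- matrix(1, 5, 5)
  Wz[1, 3] <- Wz[3, 1] <- 0
  Wz[2, 5] <- Wz[5, 2] <- 0
  Wz[4, 4] <- 0
  res <- suppressWarnings(bend(V, Wz, method = "hj"))
  expect_identical(res$bent[1, 3], V[1, 3])
  expect_identical(res$bent[2, 5], V[2, 5])
  expect_identical(res$bent[4, 4], V[4, 4])
  expect_gt(res$iterations, 1)
})

test_that("correlation inputs keep a unit diagonal exactly", {
  for (method in c("hj", "lrs", "db")) {
    res <- bend(C, method = method)
    expect_identical(diag(res$bent), rep(1, 5))
    expect_true(res$converged)
    expect_true(is_positive_definite(res$bent))
  }
  # weighted too
  resw <- bend(C, W_counts, reciprocal = TRUE)
  expect_identical(diag(resw$bent), rep(1, 5))
})

test_that("an explicit all-ones weight matrix equals unweighted bending on covariances", {
  res_u <- bend(V)
  res_w <- bend(V, matrix(1, 5, 5))
  expect_equal(res_w$bent, res_u$bent, tolerance = 1e-12)
  expect_identical(res_w$iterations, res_u$iterations)
})

test_that("convergence crosses zero exactly at the accepted iterate", {
  # witness: rebuild the trajectory and check min eigenvalue signs
  res <- bend(V, W_counts, reciprocal = TRUE, method = "hj")
  W <- prepare_weights(W_counts, 5, reciprocal = TRUE)
  cur <- V
  for (i in seq_len(res$iterations)) {
    expect_lte(min(eigen(cur, symmetric = TRUE, only.values = TRUE)$values), 0)
    dec <- spectral_decompose(cur)
    cur <- weighted_update(cur, reconstruct_symmetric(dec, hj_floor(dec$values, 1e-4)), W)
  }
  expect_gt(min(eigen(cur, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(cur, res$bent, tolerance = 1e-12)
})

test_that("correlation smoothing leaves PD input alone and covariance diagonals fixed", {
  P <- diag(3); P[1, 2] <- P[2, 1] <- 0.5
  expect_identical(db_smooth(P, 1e-4), P)

  res <- bend(V, method = "db")
  expect_identical(diag(res$bent), diag(V))  # only off-diagonals change
  expect_true(is_positive_definite(res$bent))
  expect_identical(res$iterations, 1L)

  # both dialects produce PD unit-diagonal output on the example correlation
  for (dialect in c("rescale_all", "rescale_positive")) {
    sm <- db_smooth(C, 1e-4, dialect)
    expect_identical(diag(sm), rep(1, 5))
    expect_true(is_positive_definite(sm))
  }
  expect_error(db_smooth(C, 0), class = "pdbend_epsilon_error")
  # weights are ignored with a warning
  expect_warning(bend(V, W_counts, method = "db"), "ignored")
})

test_that("covariance/correlation transforms invert exactly", {
  tr <- cov_cor_transform(V)
  expect_equal(tr$C, C, tolerance = 1e-12)
  expect_equal(tr$t_diag, rep(10, 5))
  expect_equal(cor_to_cov(tr$C, tr$t_diag), V, tolerance = 1e-12)

  expect_identical(cov_cor_transform(diag(3))$C, diag(3))
  expect_error(cov_cor_transform(diag(c(1, 0, 2))),
               class = "pdbend_diagonal_error")
})

test_that("degenerate spectra are reported, not silently mangled", {
  # PSD-but-singular under lrs: stagnation, advised towards hj
  sing <- diag(c(1, 0))
  expect_warning(res <- bend(sing, method = "lrs"), "hj")
  expect_false(res$converged)
  expect_identical(res$iterations, 0L)

  # hj handles the same input in one reconstruction
  ok <- bend(sing, method = "hj")
  expect_true(ok$converged)
  expect_true(is_positive_definite(ok$bent))

  # iteration cap produces a warning and converged = FALSE, not an error
  expect_warning(capped <- bend(V, W_counts, reciprocal = TRUE, max.iter = 5),
                 "max.iter")
  expect_false(capped$converged)
  expect_identical(capped$iterations, 5L)
})
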