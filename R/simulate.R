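# Simulated genotype panels and genomic relationship matrices, for
# constructing ill-conditioned test cases (duplicated genotypes make G
# rank-deficient, hence not positive-definite).

#' Simulate a random genotype panel with duplicated individuals
#'
#' Generates unfiltered biallelic SNP genotypes (no quality control, no
#' minor-allele-frequency filtering): per-SNP allele frequencies are drawn
#' uniformly on `(0.05, 0.95)` and genotypes as two independent allele
#' copies (binomial with two trials). The last `n_duplicates` animals are
#' exact copies of the first `n_duplicates`, which makes the genomic
#' relationship matrix built from the panel rank-deficient.
#'
#' @param n_animals Number of individuals (including duplicates).
#' @param n_snps Number of SNPs.
#' @param n_duplicates Number of duplicated individuals (must be smaller
#'   than `n_animals`).
#' @param seed Optional integer seed; the global RNG state is restored on
#'   exit.
#' @return An object of class `genotype_panel`: a list with `genotypes`
#'   (`n_animals x n_snps` integer matrix of 0/1/2 reference-allele counts),
#'   `n_animals`, `n_snps`, `allele_freq` (observed per-SNP frequency of the
#'   reference allele, computed from the panel), `duplicate_map` (data frame
#'   with columns `source`, `copy`) and `seed`.
#' @examples
#' panel <- simulate_genotypes(20, 100, n_duplicates = 2, seed = 1)
#' identical(panel$genotypes[19, ], panel$genotypes[1, ])
#' @export
simulate_genotypes <- function(n_animals, n_snps, n_duplicates = 0,
                               seed = NULL) {
  if (n_animals < 1 || n_snps < 1) {
    pdbend_error("n_animals and n_snps must be positive",
                 "pdbend_option_error")
  }
  if (n_duplicates < 0 || n_duplicates >= n_animals) {
    pdbend_error("n_duplicates must be non-negative and smaller than n_animals",
                 "pdbend_option_error")
  }
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  p_true <- stats::runif(n_snps, 0.05, 0.95)
  G <- vapply(p_true, function(p) stats::rbinom(n_animals, 2L, p),
              integer(n_animals))
  dup_map <- data.frame(source = integer(0), copy = integer(0))
  if (n_duplicates > 0) {
    src <- seq_len(n_duplicates)
    cpy <- n_animals - n_duplicates + seq_len(n_duplicates)
    G[cpy, ] <- G[src, , drop = FALSE]
    dup_map <- data.frame(source = src, copy = cpy)
  }
  structure(list(
    genotypes = G,
    n_animals = as.integer(n_animals),
    n_snps = as.integer(n_snps),
    allele_freq = colMeans(G) / 2,
    duplicate_map = dup_map,
    seed = seed
  ), class = "genotype_panel")
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' Builds `G = Z Z' / (2 * sum(p_j * (1 - p_j)))`, where `Z` is the genotype
#' matrix centered by twice the observed allele frequencies. Frequencies are
#' estimated from the panel itself. Monomorphic SNPs contribute zero to both
#' numerator and denominator.
#'
#' @param panel A `genotype_panel` from [simulate_genotypes()], or a plain
#'   numeric matrix of 0/1/2 genotypes (animals in rows).
#' @return The `n_animals x n_animals` genomic relationship matrix (exactly
#'   symmetric). With duplicated individuals it is rank-deficient and not
#'   positive-definite.
#' @examples
#' panel <- simulate_genotypes(20, 200, n_duplicates = 2, seed = 1)
#' G <- vanraden_g(panel)
#' is_positive_definite(G)
#' @export
vanraden_g <- function(panel) {
  M <- if (inherits(panel, "genotype_panel")) panel$genotypes else panel
  if (!is.matrix(M) || !is.numeric(M) && !is.integer(M)) {
    pdbend_error("panel must be a genotype_panel or a numeric genotype matrix",
                 "pdbend_option_error")
  }
  p <- colMeans(M) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom == 0) {
    pdbend_error("all SNPs are monomorphic: relationship matrix undefined",
                 "pdbend_monomorphic_error")
  }
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / denom
  (G + t(G)) / 2
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("Genotype panel:", x$n_animals, "animals x", x$n_snps, "SNPs\n")
  if (nrow(x$duplicate_map) > 0) {
    cat("Duplicated individuals:",
        paste(sprintf("%d->%d", x$duplicate_map$source, x$duplicate_map$copy),
              collapse = ", "), "\n")
  }
  cat("Observed allele frequency range:",
      sprintf("%.3f - %.3f", min(x$allele_freq), max(x$allele_freq)), "\n")
  invisible(x)
}
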