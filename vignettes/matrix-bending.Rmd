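---
title: "Bending non-positive-definite matrices: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bending non-positive-definite matrices: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdbend)
```

## Why bend a matrix

Multi-trait mixed models (BLUP, selection indices) need the inverse of the
genetic and residual covariance matrices across traits, usually obtained via
Cholesky decomposition, which requires positive definiteness (PD). In
practice these matrices are assembled from heterogeneous part-analyses,
literature values and best guesses for missing elements, and the assembled
matrix is frequently not PD. Genomic relationship matrices computed from
unfiltered genotype panels have the same problem: duplicated or near-duplicate
genotypes make them rank-deficient. REML estimation also wants PD starting
values.

*Bending* modifies the eigenvalues of a symmetric non-PD matrix just enough
to make every eigenvalue strictly positive, while deviating as little as
possible from the original values. All methods in this package share one
skeleton: decompose the current iterate `V = U D U'`, modify the spectrum
`D -> Delta`, reconstruct, and (for the iterative methods) blend the
reconstruction back into the iterate.

## The three methods

**Iterative weighted flooring (`method = "hj"`).** Given a small positive
value $\epsilon$ (`small.positive`, default $10^{-4}$) and a weight matrix
$W$:

1. decompose $V_n = U_n D_n U_n'$;
2. floor the spectrum: every eigenvalue below $\epsilon$ becomes $\epsilon$
   (note: *below epsilon*, not merely negative — tiny positive eigenvalues
   are raised too, which distinguishes this rule from the iterative spectral
   method);
3. update $V_{n+1} = V_n - [V_n - U_n \Delta_n U_n'] \circ W$, where
   $\circ$ is the elementwise (Hadamard) product;
4. repeat until $V_{n+1}$ is PD.

Since the update is the convex blend
$V_n \circ (\mathbf{1}\mathbf{1}' - W) + (U_n \Delta_n U_n') \circ W$, each
element moves towards the spectrally corrected target at a rate given by its
weight: a weight of zero freezes an element exactly; the smaller $w_{ij}$,
the more certain we are about $v_{ij}$ and the less it moves. Unweighted
bending ($W = \mathbf{1}\mathbf{1}'$) reduces to a single reconstruction and
converges in one iteration.

**Negative-eigenvalue replacement (`method = "lrs"`).** Each of the $m$
negative eigenvalues $\lambda_i$ is replaced with

$$\rho\,(s - \lambda_i)^2 / (100\,s^2 + 1), \qquad
  s = 2 \sum_{i=1}^{m} \lambda_i,$$

where $\rho$ is the smallest positive eigenvalue. The replacements are
strictly positive, smaller than $\rho$, and *descending* (a more negative
eigenvalue receives a smaller replacement), unlike the equal replacements of
the flooring rule. Unweighted, this is a single pass. The weighted variant
recomputes the replacement each iteration and applies the same Hadamard
update as `"hj"`; `small.positive` is ignored for this method.

**Correlation smoothing (`method = "db"`).** Designed for correlation
matrices: eigenvalues below $\epsilon$ are replaced with $100\epsilon$, the
spectrum is rescaled, the matrix is reconstructed and renormalized to a unit
diagonal — a single pass. Covariance input is scaled to correlation form
($C = T^{-1} V T^{-1}$, $T = \mathrm{diag}(\sqrt{v_{ii}})$), smoothed, and
scaled back ($T \hat{C} T'$), so only off-diagonal elements change.

## Correlation matrices

A matrix whose diagonal is all 1 (within `diag.tol`, default $10^{-8}$) is
recognised as a correlation matrix and bent as a covariance matrix whose
diagonal must not move: the diagonal weights are set to zero (for `"hj"` and
`"lrs"`; `"db"` has its own diagonal handling). Consequently the "unweighted"
bending of a correlation matrix is internally a weighted run with
off-diagonal weights 1 and diagonal weights 0, and takes more than one
iteration. If a matrix happens to have a unit diagonal but is *not* a
correlation matrix (e.g. variables standardised to unit variance), multiply
it by a positive constant before bending and divide the result afterwards.

## Weights

`prepare_weights()` applies, in order: reciprocal conversion (so a matrix of
record counts can be passed directly with `reciprocal = TRUE`; zeros stay
zero), diagonal zeroing for correlation input, and normalization by the
maximum entry (`normalize.weights = TRUE` by default). The normalization
maps the weights onto $[0, 1]$, where the element with the largest weight
moves all the way to the spectral target each iteration; it shortens the
iteration considerably without changing which matrix the iteration converges
towards, because the update is a convex combination at every scale of $W$.

## Numerical choices

* **PD criterion.** Strictly positive smallest eigenvalue of the
  symmetrized iterate, no tolerance. A matrix that is PD on entry is
  returned untouched with the message
  `"No action was required. The matrix is positive-definite"`; bending is
  therefore idempotent.
* **Iteration counting.** One iteration = one decompose/modify/update cycle;
  the PD test is applied to the updated matrix, and a matrix PD on entry
  counts zero iterations.
* **Symmetrization.** Floating-point reconstruction `U Delta U'` is
  symmetric only up to rounding, so every reconstruction (and every update)
  is re-symmetrized as `(M + M')/2`.
* **Termination guard for weighted `"lrs"` (`lrs.floor`, default `5e-9`).**
  Near the PD boundary the replacement value behaves like
  $\rho \lambda^2$ — quadratic in the vanishing eigenvalue — so the weighted
  iteration contracts towards the PD boundary without ever crossing it: the
  smallest eigenvalue approaches zero geometrically from below and the
  strict PD test never passes. Replacements are therefore bounded below by
  `lrs.floor`, a value of the order of the square root of machine epsilon.
  Any small positive guard guarantees termination; the default keeps the
  guard far below every meaningful eigenvalue scale while converging in a
  number of iterations comparable to the flooring method. The first
  iterations are unaffected (replacement values there are orders of
  magnitude above the guard).
* **Degenerate spectra under `"lrs"`.** A spectrum with zero but no negative
  eigenvalues gives $s = 0$ and no eigenvalue to replace; the replacement
  rule cannot make progress. The iteration stops with `converged = FALSE`
  and an advisory message pointing to `"hj"`, which floors zero eigenvalues
  like any other sub-epsilon value. A spectrum with no positive eigenvalue
  has no $\rho$ and is reported as unbendable.
* **`db` dialects.** The literal rule rescales only the eigenvalues above
  $\epsilon$ so that they sum to their count (`"rescale_positive"`); the
  default `"rescale_all"` rescales the whole floored spectrum to sum to the
  matrix order $n$ (the trace of a valid correlation matrix), which is the
  behaviour of the smoothing routines in wide use and is what the deviation
  diagnostics in this package's tests pin down. Both end with an exact
  unit-diagonal renormalization.
* **Ties in the deviation indices.** The minimum/maximum deviation is
  reported with the 1-based `(row, column)` index of its first occurrence in
  row-major upper-triangle order.

## Deviation diagnostics

For the upper triangle (including the diagonal for covariance matrices,
$n(n+1)/2$ elements; excluding it for correlation matrices, $n(n-1)/2$),
with $d_{ij} = \hat v_{ij} - v_{ij}$:

$$\mathrm{AAD} = \frac{\sum |d_{ij}|}{N}, \qquad
  \mathrm{RMSD} = \sqrt{\frac{\sum d_{ij}^2}{N}},$$

plus the minimum, maximum and mean deviation and the Pearson correlation
between original and bent elements. The weighted forms are restricted to
elements with $w_{ij} > 0$ (their count is reported as `w_gt_0`):

$$\mathrm{wAAD} = \frac{\sum |d_{ij} / w_{ij}|}{\sum 1/w_{ij}}, \qquad
  \mathrm{wRMSD} = \sqrt{\frac{\sum (d_{ij}/w_{ij})^2}{\sum 1/w_{ij}^2}}.$$

The weighted correlation is a weighted Pearson coefficient with importance
weights $1/w_{ij}$, consistent with the wAAD normalization (the exact
weighted-correlation convention is a design choice; this one reproduces the
reference diagnostics on the bundled example). Absolute distance measures
(AAD, RMSD, and their weighted forms for weighted runs) are the statistics
to judge bending by; the correlations mostly show the direction of change.

All weighted statistics are invariant to rescaling $W$ by a constant, so it
does not matter whether they are computed from the raw or the
max-normalized weights.

## The genotype simulator

`simulate_genotypes()` emulates an unfiltered SNP panel: per-SNP allele
frequencies uniform on $(0.05, 0.95)$, genotypes drawn as two independent
allele copies (binomial, $n=2$), and a configurable number of individuals
duplicated exactly (placed at the end of the panel; placement does not
affect the spectrum). `vanraden_g()` builds
$G = ZZ' / (2\sum p_j(1-p_j))$ with $Z$ centered by twice the *observed*
allele frequencies, the standard construction. Duplicates make $G$ exactly
rank-deficient, hence not PD — the realistic failure mode this package
targets. What the simulator does **not** emulate: linkage disequilibrium,
minor-allele-frequency spectra of real chips, genotyping error, or
population structure. Tests passing on simulated panels therefore
demonstrate the algebraic and numerical behaviour of bending on
rank-deficient relationship matrices, not calibration on any particular
livestock population.

The uniform $(0.05, 0.95)$ frequency range guarantees polymorphism at the
simulation scales used (hundreds of SNPs and up), honouring the
"no quality control" premise without degenerate monomorphic columns.

## Problem sizes used by the test-suite

The bundled 5×5 covariance matrix, its correlation form and the 5×5
record-count weights exercise every code path at desk scale. The genomic
relationship experiment runs at 200 animals × 1000 SNPs with 5 duplicated
genotypes — large enough for the duplicate-driven rank deficiency and the
trace/n ≈ 1 scaling of the standard construction to hold, small enough that
the whole suite runs in seconds. Property-style tests use random symmetric
matrices of order up to 50 (round trips) and 20 (spectral oracle).

## Known limitations

* Bending presumes the non-PDness comes from sampling noise or assembly of
  heterogeneous estimates. It cannot repair genuinely wrong elements, and
  for relationship matrices, quality control (removing duplicates) is
  preferable to bending after the fact.
* The weighted iteration count grows roughly logarithmically as the guard
  or floor shrinks, and inversely with the smallest relative weight; very
  disparate weights mean slow convergence.
* Dense eigendecomposition is $O(n^3)$ per iteration: weighted bending of
  matrices beyond a few thousand rows is expensive.
* Sparse or banded structures are not exploited, and asymmetric input is
  rejected rather than projected.
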