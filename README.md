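# pdbend

Bending symmetric non-positive-definite matrices to positive-definite.

## The problem

Multi-trait BLUP, REML starting values and selection indices all need the
inverse of a covariance (or correlation) matrix across traits, typically via
Cholesky decomposition — which requires the matrix to be positive-definite
(PD). Matrices assembled from part-analyses over trait subsets, literature
values and phenotypic best guesses are frequently **not** PD, and genomic
relationship matrices built from unfiltered genotype panels with duplicated
genotypes are rank-deficient by construction. *Bending* modifies the
eigenvalues of such a matrix just enough to make it PD while staying as
close as possible to the original values.

`pdbend` is for quantitative geneticists and anyone else who needs a PD
matrix out of a nearly-PD one, with control over *which* elements are
allowed to move.

## Methods

All methods work on the eigendecomposition `V = U D U'`:

* **`hj` — iterative weighted flooring.** Eigenvalues below a small
  positive `ε` (`small.positive`, default `1e-4`) are floored to `ε`; the
  iterate moves towards the reconstruction under the Hadamard blend
  `V_{n+1} = V_n − (V_n − U Δ U') ∘ W` until it is PD. The weight matrix
  `W` encodes element precision: `w_ij = 0` freezes an element, small
  weights protect well-estimated elements. Weights are used as `W/max(W)`
  internally. Unweighted runs converge in a single reconstruction.
* **`lrs` — descending replacement of negative eigenvalues.** Each of the
  `m` negative eigenvalues `λ_i` becomes `ρ (s − λ_i)² / (100 s² + 1)`,
  with `ρ` the smallest positive eigenvalue and `s = 2 Σ λ_i` over the
  negatives — small positive values in *descending* order rather than one
  shared floor. A weighted variant recomputes the replacement each
  iteration inside the same Hadamard update.
* **`db` — correlation smoothing.** Eigenvalues below `ε` become `100 ε`,
  the spectrum is rescaled to sum to the matrix order, and the result is
  renormalized to a unit diagonal (single pass). Covariance input is
  round-tripped through correlation form (`T Ĉ T'`, `T² = diag(diag(V))`),
  so only off-diagonal elements change.

Correlation matrices are auto-detected (unit diagonal) and bent with the
diagonal held fixed. Deviation diagnostics between original and bent
matrices — min/max/mean deviation, average absolute deviation
`AAD = Σ|v̂_ij − v_ij| / N`, `RMSD = sqrt(Σ(v̂_ij − v_ij)² / N)`, Pearson
correlation, and precision-weighted forms over elements with `w_ij > 0` —
are computed over the upper triangle (diagonal included for covariance,
excluded for correlation input).

## Worked example

The bundled 5×5 covariance matrix `V` (a classic non-PD example) with its
record-count weight matrix; the smallest count (5 records behind element
(2,4)) marks the least reliable element, which is therefore allowed to move
the most:

```r
library(pdbend)
V <- example_matrix("V")
round(eigen(V)$values, 2)
#> [1] 399.48  98.52  23.65  -3.12 -18.52     # two negative eigenvalues

res <- bend(V, example_matrix("W_counts"), reciprocal = TRUE)
res
#> Bending result (method hj, weighted)
#> Convergence met after 428 iterations
#> Iterations: 428  Converged: TRUE
#> Initial eigenvalues: 399.476 98.5235 23.6469 -3.1229 -18.5235
#> Final eigenvalues:   3.876e+02 1.020e+02 1.230e+01 7.668e-05 1.210e-06
#>
#> Bent matrix:
#>          [,1]     [,2]     [,3]     [,4]     [,5]
#> [1,] 100.1615  94.5175  82.9384  43.5668  39.1829
#> [2,]  94.5175 100.6249  93.9815  59.9992  45.8455
#> [3,]  82.9384  93.9815 100.6955  84.8929  73.1343
#> [4,]  43.5668  59.9992  84.8929 100.3070  94.2317
#> [5,]  39.1829  45.8455  73.1343  94.2317 100.1794
#>
#> Deviation between upper-triangle elements (including diagonal)
#>   Min (dev.):   -20.0008   at (2, 4)
#>   Max (dev.):   5.8455   at (2, 5)
#>   Mean (dev.):  -1.7161
#>   AAD:          3.6253
#>   Correlation:  0.9623
#>   RMSD:         6.3687
#>   Weighted AAD:  0.6100
#>   Weighted correlation: 0.9955
#>   Weighted RMSD: 0.5327
#>   w_gt_0:       15
```

All final eigenvalues are strictly positive. The largest deviation (−20.0 at
element (2,4)) falls exactly on the least-supported element, while the
precision-weighted RMSD of 0.53 shows the well-estimated elements barely
moved — the point of weighted bending. Diagonal entries changed because this
is a covariance matrix; bend `example_matrix("C")` (= `V/100`) to see the
unit diagonal held fixed instead.

## Command line

```sh
inst/cli/pdbend bend V.txt --weights Wcounts.txt --reciprocal --method lrs --report json
inst/cli/pdbend fixtures G --animals 200 --snps 1000 --duplicates 5 --seed 7 --out G.txt
inst/cli/pdbend stats V.txt Vbent.txt
```

Matrix files are plain-text numeric grids (whitespace- or comma-delimited,
optional header row of labels). Exit codes: 0 converged (or already PD),
2 not converged, 1 validation/usage error.

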