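# canondx — nonlinear canonical decomposition diagnostics

`canondx` classifies short feature sequences by a maximum-likelihood rule
built on a **generalized nonlinear canonical decomposition**. The motivating
application is computer-aided diagnosis from electrocardiograms: each
recording is reduced to a sequence of I = 14 PQRST features (tooth heights
and widths of P, Q, R, S, T, U and the PQ, QRS, RR, QT, ST, TP intervals),
one sequence per subject, with a disease label per training subject. The
package is aimed at researchers building decision-support classifiers for
such short, strongly non-Gaussian feature sequences, and ships everything
needed to study the method without clinical data: a synthetic-sequence
workbench, baseline criteria, validation diagnostics, CSV/JSON persistence
and a command line.

## The model

A random sequence C(1), …, C(I) with class-conditional law f(c | k) is hard
to classify directly: the maximum-likelihood rule

&nbsp;&nbsp;k\* = argmax₍k₎ f_I(c(1), …, c(I) | k)

needs an I-dimensional density estimate per class. The canonical
decomposition replaces the sequence by random coefficients that are
*empirically uncorrelated by construction*. Order the monomial dictionary

&nbsp;&nbsp;C(i), C²(i), …, C^{N−1}(i), C^{ξ₂}(i−r₁)C^{ξ₁}(i), …

(all products of powers at index i and up to N−2 earlier indices, total
degree ≤ N−1) and orthogonalize it sequentially under the empirical inner
product: each centered monomial value X_m is split into its projection onto
all earlier coefficients plus a new coefficient,

&nbsp;&nbsp;P_m = X_m − Σ_{a<m} ω(a, m) P_a,&nbsp;&nbsp;
ω(a, m) = E[P_a X_m] / D_a,&nbsp;&nbsp;D_m = E[P_m²],

where every expectation is a sample mixed moment of the training set. The
*decision coefficient* of each index block is its last, maximally
conditioned entry — for N = 4: P₃(1) (the cubic residual at i = 1),
P₁;₁,₂(2) (lag 1, powers (1, 2)), and P₁,₂;₁,₁,₁(3) onward (lags (1, 2),
powers (1, 1, 1)). With higher-order dependence absorbed into the
conditioning, the class score factorizes into one-dimensional densities,
estimated by Parzen windows from the class's own training coefficients:

&nbsp;&nbsp;k\* = argmax₍k₎ Σᵢ log f̂₁(pᵢ | k).

Two baselines use the same machinery on smaller dictionaries: the **linear
criterion** (first powers only — the classical linear canonical expansion)
and the **polynomial criterion** (single-index powers 1..3). A χ²
independence report on the extracted coefficients serves as the
model-adequacy check and drives selection of the smallest adequate order N.

## Worked example

Two synthetic classes share means, variances and autocorrelation but differ
in third-order structure (the sign of E[z(i−1)² z(i)]) — invisible to
second-order statistics, visible to the nonlinear decomposition:

```r
library(canondx)

bench <- make_benchmark("quadratic_coupling", K = 2, I = 14,
                        L_train = 200, L_test = 200, seed = 7)
clf <- train_classifier(bench$train, criterion = "nonlinear", N = 4)
clf
#> canondx classifier (nonlinear criterion, N=4): 2 classes [class1, class2], I=14

benchmark_accuracy(bench)
#>    criterion class1 class2 overall
#> 1     linear   47.0   56.5    51.8
#> 2 polynomial   80.0   48.0    64.0
#> 3  nonlinear   71.5   67.0    69.2

classify(clf, bench$test[[1]]$X[1:3, ])
#>   predicted loglik_class1 loglik_class2 unknown
#> 1    class2      -102.426        -70.46   FALSE
#> 2    class1         3.400       -104.76   FALSE
#> 3    class1        -4.122        -53.27   FALSE
```

The accuracy table mirrors the criteria-by-classes layout of published
comparisons: the linear criterion is near chance (the classes match to
second order), the polynomial criterion recovers part of the structure, and
the generalized nonlinear rule does best. Each classified row reports the
per-class log-likelihood Σᵢ log f̂₁(pᵢ | k); the `unknown` flag (off by
default) marks realizations whose best log-likelihood falls below a trained
threshold — a screen for patterns unlike any trained class.

The same pipeline runs from a shell:

```sh
inst/scripts/canondx-cli simulate --kind quadratic_coupling --seed 7 --out-prefix qc
inst/scripts/canondx-cli train --train qc_train.csv --criterion nonlinear --model m.json
inst/scripts/canondx-cli classify --model m.json --data qc_test.csv --out pred.csv
inst/scripts/canondx-cli validate --model m.json --data qc_train.csv --out indep.csv
```

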