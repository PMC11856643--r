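# matrixcdm

Additive versus multiplicative cognitive diagnostic models for figural
matrix tests.

## The problem

Figural matrix items are built from a taxonomy of *change rules* (how
figural elements transform across the cells of a matrix) and *design
principles* (how the elements are visually presented). A Q-matrix
`q[j, k]` records how strongly component `k` is present in item `j`.
Two competing accounts describe how these components turn into item
difficulty:

- **Additive (LLTM).** The linear logistic test model constrains Rasch
  item difficulties to weighted sums of component base parameters:

  ```
  P(X_ij = 1) = plogis(theta_i - sum_k q[j,k] * eta_k - c),
  sigma_j = sum_k q[j,k] * eta_k + c
  ```

  Each component shifts the difficulty by a fixed amount.

- **Multiplicative / conjunctive (LSDM).** The least squares distance
  method assumes an item is solved only if *every* required component
  is mastered, so the item curve is a product of attribute curves:

  ```
  P_j(theta) = prod_k P(A_k = 1 | theta) ^ q[j,k]
  ```

  Taking logs makes this linear — `ln P = Q X` — which the LSDM solves
  per ability level by (non-negative) least squares against item
  characteristic curves (ICCs) from an externally calibrated Rasch or
  2PL model.

`matrixcdm` implements both reconstructions, the IRT calibration they
need (Rasch by conditional maximum likelihood via elementary symmetric
functions; 2PL by EM marginal maximum likelihood), and the comparison
harness that decides which effect structure describes a dataset better:
mean absolute distance (MAD) between source and reconstructed ICCs
(< 0.05 good, < 0.10 satisfactory), paired t-tests on item-level MADs,
predictive and cross-validated difficulty correlations, Steiger's Z for
dependent correlations, component rank-order agreement, and a
regression robustness check with rule-by-principle interactions. A
synthetic-data generator produces additive-true, conjunctive-true, and
2PL-true datasets so the whole chain is testable without proprietary
response data.

## Worked example

```r
library(matrixcdm)

set.seed(1)
q <- make_taxonomy_qmatrix(18, rng_seed = 3)        # 18 items x 9 components
eta <- runif(9, -0.5, 0.75)                          # additive truth
fit <- simulate_additive(q, eta, c = 0, n_persons = 600, rng_seed = 11)
cv  <- simulate_additive(q, eta, c = 0, n_persons = 600, rng_seed = 12)

report <- run_full_comparison(fit$responses, cv$responses, q, screen = FALSE)
report
```

```
Model comparison over 18 retained items

 model irt_model   mad comparison cohens_d predictive_r cross_validation_r
  LLTM     Rasch 0.007         NA       NA         0.99               0.97
  LSDM     Rasch 0.025          1    -0.45         0.86               0.82
  LSDM       2PL 0.034          2    -0.89         0.86               0.80

Paired t (LSDM-Rasch vs LLTM MADs): t = -1.91, p = 0.073
Steiger Z (LLTM vs LSDM-Rasch, calibration sample): Z = 4.6, p = 4.1e-06
Component rank agreement (LLTM vs LSDM-Rasch): r = 0.28
```

Read: each row is one reconstruction (model x source IRT calibration).
`mad` is the mean absolute distance between the calibrated ICCs and the
reconstruction (smaller is better), `cohens_d` the paired effect size
against the comparison row, and the two `r` columns correlate
reconstructed difficulties with empirical difficulties from the
calibration and the independent cross-validation sample. Here the data
were generated additively, and the LLTM correctly wins on every
criterion.

The same analysis runs end-to-end from a config file, writing all stage
CSVs, a JSON report, and a log:

```r
run_pipeline(system.file("extdata", "config-additive-demo.yaml",
                         package = "matrixcdm"))
```

or from a shell via the thin CLI wrapper:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","matrixcdm.R",package="matrixcdm"))')" \
    pipeline --config inst/extdata/config-additive-demo.yaml
```

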