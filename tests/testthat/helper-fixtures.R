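## shared fixtures, all generated in code

fixture_q18 <- function() make_taxonomy_qmatrix(18, rng_seed = 3)

## base parameters on the scale typical of a component taxonomy
fixture_eta <- function() {
  withr::with_seed(77, runif(9, -0.5, 0.75))
}

## a two-component toy taxonomy
toy_taxonomy <- function() {
  component_taxonomy(c("A", "B"), c("change_rule", "design_principle"))
}

## logistic attribute mastery probabilities, components x grid
attribute_probs_on <- function(curves, theta) {
  t(sapply(seq_len(nrow(curves)), function(k)
    plogis(curves$discrimination[k] * (theta - curves$difficulty[k]))))
}

## conjunctive source ICCs built exactly from known attribute curves,
## kept strictly inside the probability clipping band on the grid
exact_conjunctive_fixture <- function(grid = theta_grid()) {
  q <- make_taxonomy_qmatrix(18, max_weight = 1, rng_seed = 8)
  curves <- attribute_curves(difficulty = seq(-1, 1, length.out = 9),
                             discrimination = rep(0.5, 9))
  Pk <- attribute_probs_on(curves, as.numeric(grid))
  src <- icc_table(exp(unclass(q)[, , drop = FALSE] %*% log(Pk)),
                   grid, "rasch")
  list(q = q, curves = curves, Pk = Pk, source = src)
}
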