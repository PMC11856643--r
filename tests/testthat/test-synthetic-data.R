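test_that("additive generator encodes sigma = Q eta + c and a symmetric law", {
  q <- fixture_q18()
  sim0 <- simulate_additive(q, eta = rep(0, 9), c = 0, n_persons = 10,
                            rng_seed = 1)
  expect_equal(unname(sim0$truth$sigma), rep(0, 18))
  tax <- toy_taxonomy()
  q2 <- qmatrix(matrix(c(1, 0, 1, 1), 2, 2,
                       dimnames = list(NULL, c("A", "B"))), tax)
  sim <- simulate_additive(q2, eta = c(0.5, 1.0), c = 0, n_persons = 5,
                           rng_seed = 1)
  expect_equal(unname(sim$truth$sigma), c(1.5, 1.0))
  expect_error(simulate_additive(q2, eta = c(0.5, 1.0), c = 0,
                                 n_persons = 1, rng_seed = 1),
               "at least 2")
  expect_error(simulate_additive(q2, eta = 0.5, c = 0, n_persons = 5,
                                 rng_seed = 1), "per Q-matrix component")
})

test_that("additive item proportions match the model law (Monte Carlo)", {
  q <- fixture_q18()
  eta <- fixture_eta()
  sim <- simulate_additive(q, eta, c = 0, n_persons = 1000, rng_seed = 21)
  P <- plogis(outer(sim$truth$theta, sim$truth$sigma, "-"))
  expected <- colMeans(P)
  se <- sqrt(expected * (1 - expected) / nrow(P))
  observed <- colMeans(sim$responses)
  expect_true(all(abs(observed - expected) <= 3 * se))
})

test_that("conjunctive probabilities are exact products with weight exponents", {
  ## two components with P1 = 0.8, P2 = 0.5 at theta = 0
  tax <- toy_taxonomy()
  curves <- attribute_curves(difficulty = -c(qlogis(0.8), qlogis(0.5)),
                             discrimination = c(1, 1),
                             components = c("A", "B"))
  Pk <- attribute_probs_on(curves, 0)
  expect_equal(drop(Pk), c(0.8, 0.5), tolerance = 1e-12)
  expect_equal(exp(sum(c(1, 1) * log(Pk))), 0.40, tolerance = 1e-12)
  ## weight 2 acts as a repeated factor
  c2 <- attribute_curves(difficulty = -qlogis(0.7), discrimination = 1,
                         components = "A")
  expect_equal(exp(2 * log(attribute_probs_on(c2, 0))), 0.49,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a pinned component is the multiplicative identity", {
  tax <- toy_taxonomy()
  q2 <- qmatrix(matrix(c(1, 1, 1, 0), 2, 2,
                       dimnames = list(NULL, c("A", "B"))), tax)
  base <- attribute_curves(difficulty = c(0, 0), discrimination = c(1, 1),
                           components = c("A", "B"))
  pin <- attribute_curves(difficulty = c(0, 0), discrimination = c(1, 0),
                          components = c("A", "B"),
                          pinned = c(FALSE, TRUE))
  ## with B pinned, item (1,1) behaves exactly like an A-only item
  q_ref <- qmatrix(matrix(c(1, 1, 0, 0), 2, 2,
                          dimnames = list(NULL, c("A", "B"))), tax)
  s_pin <- simulate_conjunctive(q2, pin, n_persons = 50, rng_seed = 5)
  s_ref <- simulate_conjunctive(q_ref, base, n_persons = 50, rng_seed = 5)
  expect_identical(unclass(s_pin$responses), unclass(s_ref$responses))
  expect_error(attribute_curves(difficulty = 0, discrimination = -1),
               "positive")
})

test_that("conjunctive probability never exceeds its smallest component", {
  q <- fixture_q18()
  curves <- attribute_curves(difficulty = seq(-2, 1, length.out = 9),
                             discrimination = seq(0.6, 1.8, length.out = 9))
  theta <- seq(-3, 3, length.out = 11)
  Pk <- attribute_probs_on(curves, theta)
  Pitem <- exp(unclass(q)[, , drop = FALSE] %*% log(Pk))
  for (j in seq_len(nrow(q))) {
    active <- which(unclass(q)[j, ] >= 1)
    expect_true(all(Pitem[j, ] <= apply(Pk[active, , drop = FALSE], 2, min)
                    + 1e-12))
  }
})

test_that("ability draw is decoupled from the response draw", {
  q <- fixture_q18()
  eta <- fixture_eta()
  curves <- attribute_curves(difficulty = runif(9), discrimination = rep(1, 9))
  sa <- simulate_additive(q, eta, 0, 40, rng_seed = 123)
  sc <- simulate_conjunctive(q, curves, 40, rng_seed = 123)
  s2 <- simulate_2pl(rep(1, 5), rep(0, 5), 40, rng_seed = 123)
  expect_identical(sa$truth$theta, sc$truth$theta)
  expect_identical(sa$truth$theta, s2$truth$theta)
})

test_that("datasets are reproducible from their stored seed", {
  q <- fixture_q18()
  eta <- fixture_eta()
  s1 <- simulate_additive(q, eta, 0, 60, rng_seed = 314)
  s2 <- simulate_additive(q, eta, 0, 60, rng_seed = s1$seed)
  expect_identical(unclass(s1$responses), unclass(s2$responses))
})

test_that("2PL generator matches its closed form and orders by difficulty", {
  expect_error(simulate_2pl(a = c(1, 1), b = 0, n_persons = 5, rng_seed = 1),
               "equal length")
  expect_error(simulate_2pl(a = -1, b = 0, n_persons = 5, rng_seed = 1),
               "positive")
  ## logistic(2) at a = 2, b = 0, theta = 1
  expect_equal(plogis(2 * (1 - 0)), 0.8808, tolerance = 1e-4)
  s <- simulate_2pl(a = rep(1.2, 6), b = seq(-1.5, 1.5, length.out = 6),
                    n_persons = 2000, rng_seed = 17)
  pc <- colMeans(s$responses)
  expect_true(all(diff(pc) < 0))
})

test_that("simulation files round-trip through the writers", {
  q <- make_taxonomy_qmatrix(10, rng_seed = 2)
  sim <- simulate_additive(q, fixture_eta(), 0, 25, rng_seed = 9)
  d <- withr::local_tempdir()
  paths <- write_simulation(sim, d, "toy")
  r2 <- read_response_matrix(paths[["responses"]])
  expect_identical(unclass(sim$responses), unclass(r2))
  q2 <- read_qmatrix(paths[["qmatrix"]])
  expect_identical(unclass(q)[, , drop = FALSE],
                   unclass(q2)[, , drop = FALSE])
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$model, "additive")
  expect_equal(truth$sigma, unname(sim$truth$sigma), tolerance = 1e-12,
               ignore_attr = TRUE)
})
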