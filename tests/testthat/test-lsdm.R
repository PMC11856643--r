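test_that("identity Q recovers each item's log-ICC exactly", {
  tax <- default_taxonomy()
  q <- qmatrix(diag(1L, 9), tax)
  grid <- theta_grid(-3, 3, 25)
  P <- t(plogis(outer(as.numeric(grid), seq(-1, 1, length.out = 9), "-")))
  rownames(P) <- rownames(q)
  src <- icc_table(P, grid, "rasch")
  fit <- solve_attribute_logprobs(src, q)
  expect_lt(max(fit$residual_norms), 1e-8)
  expect_equal(unname(fit$X), unname(log(P)), tolerance = 1e-8)
})

test_that("a consistent conjunctive toy system is solved exactly", {
  tax <- toy_taxonomy()
  q <- qmatrix(matrix(c(1, 0, 1, 0, 1, 1), 3, 2,
                      dimnames = list(NULL, c("A", "B"))), tax)
  ## probabilities (0.8, 0.5, 0.4): consistent because 0.8 * 0.5 = 0.4
  src <- icc_table(matrix(c(0.8, 0.5, 0.4), 3, 1,
                          dimnames = list(rownames(q), NULL)), 0, "rasch")
  fit <- solve_attribute_logprobs(src, q)
  expect_equal(unname(fit$X[, 1]), log(c(0.8, 0.5)), tolerance = 1e-10)
  expect_lt(fit$residual_norms[1], 1e-10)
  expect_equal(unname(fit$reconstructed[3, 1]), 0.4, tolerance = 1e-10)
})

test_that("exact conjunctive sources are recovered to numerical precision", {
  fx <- exact_conjunctive_fixture()
  fit <- solve_attribute_logprobs(fx$source, fx$q)
  expect_lt(max(fit$residual_norms), 1e-6)
  expect_lt(max(abs(fit$attribute_probs - fx$Pk)), 1e-6)
  mads <- mad_diagnostics(fx$source, fit$reconstructed)
  expect_lt(max(mads$items$mad), 1e-6)
})

test_that("constrained solutions keep attribute probabilities at most 1", {
  q <- fixture_q18()
  sim <- simulate_additive(q, fixture_eta(), 0, 400, rng_seed = 77)
  icc <- evaluate_iccs(fit_rasch(sim$responses), theta_grid())
  fit <- solve_attribute_logprobs(icc, q, constrained = TRUE)
  expect_true(all(fit$attribute_probs <= 1 + 1e-12))
  expect_true(all(fit$reconstructed <= 1 + 1e-12))
  ## unconstrained mode may exceed 1 before clipping, and reports it
  fit_u <- solve_attribute_logprobs(icc, q, constrained = FALSE)
  expect_true(fit_u$clipped >= 0)
  expect_true(all(fit_u$attribute_probs <= 1 + 1e-12))
})

test_that("an untouched component column is rejected", {
  tax <- toy_taxonomy()
  q <- qmatrix(matrix(c(1, 1, 0, 0), 2, 2,
                      dimnames = list(NULL, c("A", "B"))), tax)
  src <- icc_table(matrix(0.5, 2, 3, dimnames = list(rownames(q), NULL)),
                   c(-1, 0, 1), "rasch")
  expect_error(solve_attribute_logprobs(src, q), "all-zero Q column")
})

test_that("MAD thresholds classify reconstruction quality as printed", {
  grid <- theta_grid(-1, 1, 21)
  base <- t(plogis(outer(as.numeric(grid), c(-0.5, 0, 0.5), "-")))
  rownames(base) <- paste0("I", 1:3)
  src <- icc_table(base, grid, "rasch")
  ## identical tables: all zero, all good
  rep0 <- mad_diagnostics(src, src)
  expect_equal(rep0$items$mad, rep(0, 3))
  expect_equal(rep0$items$label, rep("good", 3))
  ## constant gaps straddling the two thresholds
  shifted <- base
  shifted[1, ] <- pmin(base[1, ] + 0.03, 0.999)   # good
  shifted[2, ] <- pmin(base[2, ] + 0.08, 0.999)   # satisfactory
  shifted[3, ] <- pmin(base[3, ] + 0.12, 0.999)   # poor
  rep1 <- mad_diagnostics(src, icc_table(shifted, grid, "lltm"))
  expect_equal(rep1$items$mad[2], 0.08, tolerance = 1e-6)
  expect_equal(rep1$items$label, c("good", "satisfactory", "poor"))
  ## thresholds are strict: exactly-representable gaps straddle them
  b2 <- base
  b2[1, ] <- base[1, ] - 0.03125    # binary-exact gap below 0.05
  b2[2, ] <- base[2, ] - 0.0625     # binary-exact gap in [0.05, 0.10)
  b2[3, ] <- base[3, ] - 0.125      # binary-exact gap at or above 0.10
  rep2 <- mad_diagnostics(src, icc_table(b2, grid, "lltm"))
  expect_equal(rep2$items$mad, c(0.03125, 0.0625, 0.125))
  expect_equal(rep2$items$label, c("good", "satisfactory", "poor"))
})

test_that("MAD is invariant to item order and grid-point order", {
  fx <- exact_conjunctive_fixture(theta_grid(-2, 2, 11))
  noisy <- unclass(fx$source) + 0.013
  src <- fx$source
  rec <- icc_table(noisy, theta_grid(-2, 2, 11), "lsdm-reconstructed")
  m1 <- mad_diagnostics(src, rec)
  perm <- rev(seq_len(nrow(noisy)))
  rec_perm <- icc_table(noisy[perm, ], theta_grid(-2, 2, 11),
                        "lsdm-reconstructed")
  m2 <- mad_diagnostics(src, rec_perm)
  expect_equal(m1$mean, m2$mean, tolerance = 1e-12)
  gperm <- rev(seq_len(ncol(noisy)))
  rec_g <- icc_table(noisy[, gperm],
                     rev(as.numeric(theta_grid(-2, 2, 11))),
                     "lsdm-reconstructed")
  m3 <- mad_diagnostics(src, rec_g)
  expect_equal(m1$items$mad, m3$items$mad, tolerance = 1e-12)
})

test_that("implied difficulties interpolate the 0.5 crossing", {
  grid <- theta_grid(-4, 4, 81)
  P <- t(plogis(outer(as.numeric(grid), c(-1.3, 0.25, 1.7), "-")))
  rownames(P) <- paste0("I", 1:3)
  d <- implied_item_difficulty(icc_table(P, grid, "rasch"))
  expect_equal(d$difficulty, c(-1.3, 0.25, 1.7), tolerance = 0.01)
  expect_false(any(d$extrapolated))
  ## hand-computable bracketing case
  toy <- icc_table(matrix(c(0.30, 0.45, 0.60), 1), c(-1, 0, 1), "rasch")
  expect_equal(implied_item_difficulty(toy)$difficulty,
               (0.5 - 0.45) / (0.60 - 0.45), tolerance = 1e-12)
  ## a curve that never reaches 0.5 is flagged at the upper bound
  low <- icc_table(matrix(seq(0.1, 0.4, length.out = 5), 1),
                   seq(-2, 2, 1), "rasch")
  dl <- implied_item_difficulty(low)
  expect_true(dl$extrapolated)
  expect_equal(dl$difficulty, 2)
})

test_that("attribute summaries recover exact logistic curves", {
  tax <- default_taxonomy()
  q <- make_taxonomy_qmatrix(18, max_weight = 1, rng_seed = 8)
  grid <- theta_grid(-3, 3, 31)
  th <- as.numeric(grid)
  ## plant one exactly-logistic attribute and a nearly-flat one
  X <- rbind(matrix(log(plogis(th - 0.2)), 7, length(th), byrow = TRUE),
             log(plogis(th - 1)),             # logistic(theta - 1)
             log(rep(0.99, length(th))))      # nearly always mastered
  rownames(X) <- tax$id
  fit <- structure(list(X = X, attribute_probs = exp(X), theta = th,
                        q = q, epsilon = 1e-6), class = "lsdm_fit")
  s <- attribute_curve_summary(fit)
  expect_equal(s$difficulty[8], 1, tolerance = 1e-6)
  expect_equal(s$discrimination[8], 1, tolerance = 1e-6)
  expect_equal(s$r_squared[8], 1, tolerance = 1e-8)
  ## flat curve: no 0.5 crossing, near-zero slope
  expect_true(s$extrapolated[9])
  expect_lt(abs(s$discrimination[9]), 1e-6)
  expect_equal(s$kind[match("DP", s$component)], "design_principle")
})
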