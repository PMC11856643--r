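test_that("paired MAD test matches hand arithmetic and is antisymmetric", {
  a <- c(0.05, 0.07, 0.09)
  b <- a - c(0.01, 0.02, 0.03)
  res <- paired_mad_test(a, b)
  expect_equal(res$t, 0.02 / (0.01 / sqrt(3)), tolerance = 1e-6)
  expect_equal(res$t, 3.464, tolerance = 1e-3)
  expect_equal(res$d, 2.00, tolerance = 1e-10)
  expect_equal(res$df, 2)
  rev <- paired_mad_test(b, a)
  expect_equal(rev$t, -res$t, tolerance = 1e-10)
  expect_equal(rev$d, -res$d, tolerance = 1e-10)
  expect_equal(rev$p_value, res$p_value, tolerance = 1e-12)
  ## identical vectors
  same <- paired_mad_test(a, a)
  expect_equal(c(same$t, same$d), c(0, 0))
  expect_equal(same$p_value, 1)
})

test_that("difficulty agreement is exact for linear transforms", {
  x <- c(-1.2, -0.3, 0.1, 0.4, 1.1, 2.0)
  res <- difficulty_agreement(2 * x + 1, x)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_error(difficulty_agreement(rep(1, 6), x), "zero-variance")
})

test_that("Fisher-z confidence intervals cover the true correlation", {
  rho <- 0.7
  L <- chol(matrix(c(1, rho, rho, 1), 2))
  withr::with_seed(2024, {
    hits <- replicate(2000, {
      X <- matrix(rnorm(36), 18, 2) %*% L
      ci <- difficulty_agreement(X[, 1], X[, 2])$ci
      ci[1] <= rho && rho <= ci[2]
    })
  })
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("Steiger's Z matches an independent transcription of the formula", {
  ## independently coded reference (overlapping dependent correlations)
  ref <- function(r_jk, r_jh, r_kh, n) {
    z1 <- 0.5 * log((1 + r_jk) / (1 - r_jk))
    z2 <- 0.5 * log((1 + r_jh) / (1 - r_jh))
    rm2 <- ((r_jk + r_jh) / 2)^2
    cov <- (r_kh * (1 - rm2 - rm2) - 0.5 * rm2 *
              (1 - rm2 - rm2 - r_kh^2)) / ((1 - rm2)^2)
    (z1 - z2) * sqrt((n - 3) / (2 - 2 * cov))
  }
  got <- steiger_z(0.6, 0.4, 0.5, 103)
  expect_equal(got$z, ref(0.6, 0.4, 0.5, 103), tolerance = 1e-6)
  expect_equal(got$z, 2.4377034, tolerance = 1e-6)
  ## equal correlations give a null result; antisymmetry in (r_a, r_b)
  expect_equal(steiger_z(0.5, 0.5, 0.3, 50)$z, 0)
  expect_equal(steiger_z(0.5, 0.5, 0.3, 50)$p_value, 1)
  expect_equal(steiger_z(0.3, 0.6, 0.4, 40)$z,
               -steiger_z(0.6, 0.3, 0.4, 40)$z, tolerance = 1e-12)
  expect_error(steiger_z(1, 0.5, 0.3, 50), "strictly")
})

test_that("rank agreement handles perfect, reversed, and constant orders", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(rank_agreement(x, x * 2 + 1), 1)
  expect_equal(rank_agreement(x, -x), -1)
  expect_error(rank_agreement(x, rep(2, 5)), "constant")
  ## ties use average ranks
  expect_equal(rank_agreement(c(1, 2, 2, 3), c(1, 2, 2, 3)), 1)
})

test_that("additively built difficulties show no interaction gain", {
  q <- fixture_q18()
  sel <- c("CQ", "SS", "DP", "VOS")
  beta <- c(CQ = 0.4, SS = 0.2, DP = 1.0, VOS = 0.3)
  sigma <- drop(unclass(q)[, sel] %*% beta)
  res <- suppressWarnings(regression_robustness(sigma, q, sel))
  expect_equal(res$r2_main, 1, tolerance = 1e-10)
  expect_lt(res$delta_r2, 1e-10)
})

test_that("a planted rule-by-principle product is detected exactly", {
  q <- fixture_q18()
  sel <- c("CQ", "SS", "DP", "VOS")
  Qs <- unclass(q)[, sel]
  storage.mode(Qs) <- "double"
  withr::with_seed(12, {
    noise <- rnorm(18, sd = 0.05)
  })
  sigma <- drop(Qs %*% c(0.4, 0.2, 1.0, 0.3)) +
    2.0 * Qs[, "CQ"] * Qs[, "DP"] + noise
  res <- suppressWarnings(regression_robustness(sigma, q, sel))
  ## brute-force delta R-squared from explicit projections
  brute_r2 <- function(Xd, y) {
    Xd <- cbind(1, Xd)
    fit <- qr.fitted(qr(Xd), y)
    1 - sum((y - fit)^2) / sum((y - mean(y))^2)
  }
  Imat <- cbind(Qs[, "CQ"] * Qs[, "DP"], Qs[, "SS"] * Qs[, "DP"],
                Qs[, "CQ"] * Qs[, "VOS"], Qs[, "SS"] * Qs[, "VOS"])
  r2m <- brute_r2(Qs, sigma)
  r2f <- brute_r2(cbind(Qs, Imat), sigma)
  expect_equal(res$delta_r2, r2f - r2m, tolerance = 1e-8)
  expect_gt(res$delta_r2, 0.1)
  expect_lt(res$p_value, 0.05)
})

test_that("the full comparison ranks the true generating structure first", {
  q <- fixture_q18()
  eta <- fixture_eta()
  add_fit <- simulate_additive(q, eta, 0, 600, rng_seed = 501)
  add_cv <- simulate_additive(q, eta, 0, 600, rng_seed = 502)
  rep_add <- suppressWarnings(
    run_full_comparison(add_fit$responses, add_cv$responses, q,
                        screen = FALSE))
  expect_equal(which.min(rep_add$table$mad), 1)          # LLTM row
  expect_equal(which.max(rep_add$table$predictive_r), 1)
  expect_true(all(rep_add$table$mad >= 0))
  expect_s3_class(rep_add$table, "data.frame")
  expect_identical(rep_add$table$model, c("LLTM", "LSDM", "LSDM"))
  ## cross-validation r lies inside (or near) the in-sample Fisher CI
  expect_gt(rep_add$cross_validation$lltm$r,
            rep_add$predictive$lltm$ci[1] - 0.05)
  ## steiger test favors the additive reconstruction
  expect_gt(rep_add$steiger$lltm_vs_lsdm_rasch_fit$z, 0)
})
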