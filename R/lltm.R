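#' Fit the linear logistic test model by conditional maximum likelihood
#'
#' The LLTM constrains Rasch item difficulties to additive combinations
#' of component base parameters: `sigma_j = sum_k q[j,k] * eta[k] + c`.
#' The base parameters `eta` are estimated by conditional maximum
#' likelihood (the conditional likelihood does not depend on `c`, which
#' is determined afterwards from the sum-zero normalization
#' `sum_j sigma_j = 0`).
#'
#' @param responses a [response_matrix()] without missing cells.
#' @param q a [qmatrix()] covering all items in `responses`; must have
#'   full column rank, otherwise `eta` is unidentified.
#' @param max_iter,reltol optimizer control.
#' @return An `lltm_fit` with `eta` (base parameters, logit units),
#'   `eta_centered` (mean-centered for reporting), `se`, `c`,
#'   `difficulties` (reconstructed, sum-zero), `cll`, and the inputs.
#' @export
fit_lltm <- function(responses, q, max_iter = 500L, reltol = 1e-12) {
  if (!all(colnames(responses) %in% rownames(q)))
    stop("Q-matrix does not cover all items in the responses")
  q <- subset_qmatrix(q, colnames(responses))
  Qm <- unclass(q)[, , drop = FALSE]
  bad <- dependent_columns(Qm)
  if (length(bad))
    stop("Q-matrix is rank deficient; dependent columns: ",
         paste(bad, collapse = ", "))
  d <- prepare_cml_data(responses)
  K <- ncol(Qm)
  fn <- function(eta) -rasch_cll(drop(Qm %*% eta), d$sj, d$nr)
  gr <- function(eta) {
    g <- rasch_cll_grad(drop(Qm %*% eta), d$sj, d$nr)
    -drop(crossprod(Qm, g))
  }
  start <- drop(MASS::ginv(Qm) %*% (-qlogis((d$sj + 0.5) / (nrow(d$Xn) + 1))))
  opt <- optim(start, fn, gr, method = "BFGS",
               control = list(maxit = max_iter, reltol = reltol))
  if (opt$convergence != 0)
    stop("LLTM CML did not converge (optim code ", opt$convergence, ")")
  eta <- setNames(opt$par, colnames(Qm))
  se <- rep(NA_real_, K)
  H <- try(optimHess(opt$par, fn, gr), silent = TRUE)
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (inherits(V, "try-error")) V <- MASS::ginv(H)
    se <- sqrt(pmax(diag(V), 0))
  }
  sigma_raw <- drop(Qm %*% eta)
  cc <- -mean(sigma_raw)
  structure(list(eta = eta, eta_centered = eta - mean(eta),
                 se = setNames(se, colnames(Qm)), c = cc,
                 difficulties = setNames(sigma_raw + cc, rownames(Qm)),
                 cll = -opt$value,
                 convergence = list(code = opt$convergence,
                                    counts = opt$counts),
                 n_excluded = d$n_extreme, q = q, responses = responses),
            class = "lltm_fit")
}

#' @export
print.lltm_fit <- function(x, ...) {
  cat("LLTM CML fit: ", length(x$difficulties), " items, ",
      length(x$eta), " components, conditional logLik ",
      round(x$cll, 2), "\n", sep = "")
  print(round(data.frame(eta = x$eta, se = x$se,
                         eta_centered = x$eta_centered), 3))
  cat("normalization c =", round(x$c, 4), "\n")
  invisible(x)
}

#' Reconstruct item difficulties from LLTM base parameters
#'
#' Returns `Q %*% eta + c` for any Q-matrix conformable with the fitted
#' base parameters -- in-sample, or for transferring the component
#' calibration to another item set.
#'
#' @param fit an `lltm_fit`.
#' @param q a [qmatrix()] over the same components (defaults to the
#'   fitted one).
#' @return Named numeric vector of reconstructed difficulties.
#' @export
lltm_reconstructed_difficulties <- function(fit, q = fit$q) {
  if (!identical(colnames(q), names(fit$eta)))
    stop("Q-matrix components do not match the fitted base parameters")
  setNames(drop(unclass(q)[, , drop = FALSE] %*% fit$eta) + fit$c, rownames(q))
}

#' LLTM item characteristic curves
#'
#' Logistic curves `plogis(theta - sigma_hat_j)` at the reconstructed
#' difficulties, tagged with provenance `"lltm"`.
#'
#' @param fit an `lltm_fit`.
#' @param grid a [theta_grid()].
#' @param epsilon probability clipping bound.
#' @return An [icc_table()].
#' @export
lltm_icc_table <- function(fit, grid = theta_grid(), epsilon = 1e-6) {
  P <- t(plogis(outer(as.numeric(grid), fit$difficulties, "-")))
  icc_table(clip_prob(P, epsilon), grid, "lltm")
}

#' Component parameter table for an LLTM fit
#'
#' @param fit an `lltm_fit`.
#' @return Data frame with component id, kind, `eta`, `se`, and
#'   mean-centered `eta`.
#' @export
lltm_component_table <- function(fit) {
  tax <- q_taxonomy(fit$q)
  data.frame(component = names(fit$eta),
             kind = tax$kind[match(names(fit$eta), tax$id)],
             eta = unname(fit$eta), se = unname(fit$se),
             eta_centered = unname(fit$eta_centered),
             stringsAsFactors = FALSE)
}
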