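## ---- elementary symmetric functions -------------------------------------
## gamma_r(eps), r = 0..J, as polynomial coefficients of prod_j (1 + eps_j t)
esf_gammas <- function(eps) {
  g <- c(1, numeric(length(eps)))
  for (e in eps) g[-1] <- g[-1] + e * g[-length(g)]
  g
}

## conditional P(X_j = 1 | raw score r) for r = 1..J-1, given difficulties;
## pi[j, r] = eps_j * gamma_{r-1}^{(-j)} / gamma_r
rasch_cond_probs <- function(sigma) {
  J <- length(sigma)
  eps <- exp(-sigma)
  g <- esf_gammas(eps)
  pi <- matrix(0, J, J - 1)
  for (j in seq_len(J)) {
    gmj <- esf_gammas(eps[-j])            # gamma^{(-j)}_0 .. _{J-1}
    r <- seq_len(J - 1)
    pi[j, ] <- eps[j] * gmj[r] / g[r + 1]
  }
  dimnames(pi) <- list(names(sigma), as.character(seq_len(J - 1)))
  pi
}

## conditional log-likelihood and its gradient given item totals s_j and
## raw-score counts n_r (r = 1..J-1), both over non-extreme persons
rasch_cll <- function(sigma, sj, nr) {
  g <- esf_gammas(exp(-sigma))
  r <- seq_along(nr)
  -sum(sj * sigma) - sum(nr * log(g[r + 1]))
}

rasch_cll_grad <- function(sigma, sj, nr) {
  pi <- rasch_cond_probs(sigma)
  -sj + drop(pi %*% nr)
}

prepare_cml_data <- function(responses) {
  X <- unclass(responses)
  if (anyNA(X)) stop("CML estimation requires complete responses")
  J <- ncol(X)
  if (J < 2) stop("at least 2 items are required")
  r <- rowSums(X)
  extreme <- r == 0 | r == J
  Xn <- X[!extreme, , drop = FALSE]
  if (nrow(Xn) < 2) stop("too few persons with non-extreme raw scores")
  sj <- colSums(Xn)
  novar <- sj == 0 | sj == nrow(Xn)
  if (any(novar))
    stop("item(s) without variance among non-extreme persons: ",
         paste(colnames(X)[novar], collapse = ", "))
  nr <- tabulate(rowSums(Xn), nbins = J - 1)
  list(X = X, Xn = Xn, sj = sj, nr = nr,
       n_extreme = c(zero = sum(r == 0), perfect = sum(r == J)))
}

## ---- Rasch conditional maximum likelihood -------------------------------

#' Fit the Rasch model by conditional maximum likelihood
#'
#' Item difficulties are estimated by maximizing the likelihood of the
#' responses conditional on each person's raw score, which eliminates
#' the person parameters via elementary symmetric functions.  The
#' difficulties are normalized to sum to zero.  Persons with extreme
#' (all-0 or all-1) raw scores carry no conditional information and are
#' excluded from estimation but counted in the report.
#'
#' @param responses a [response_matrix()] without missing cells.
#' @param max_iter,reltol optimizer control.
#' @return A `rasch_fit` with elements `difficulties` (sum-zero, logit
#'   units), `se`, `cll` (conditional log-likelihood), `theta_table`
#'   (maximum-likelihood ability per non-extreme raw score),
#'   `convergence`, `n_excluded`, and the responses.
#' @export
fit_rasch <- function(responses, max_iter = 500L, reltol = 1e-12) {
  d <- prepare_cml_data(responses)
  J <- ncol(d$X)
  p_obs <- (d$sj + 0.5) / (nrow(d$Xn) + 1)
  start <- -qlogis(p_obs)
  start <- start - mean(start)
  ## parameterize sigma[-J] free with sigma_J = -sum(free)  (sum-zero)
  fn <- function(free) {
    sigma <- c(free, -sum(free))
    -rasch_cll(sigma, d$sj, d$nr)
  }
  gr <- function(free) {
    sigma <- c(free, -sum(free))
    g <- rasch_cll_grad(sigma, d$sj, d$nr)
    -(g[-J] - g[J])
  }
  opt <- optim(start[-J], fn, gr, method = "BFGS",
               control = list(maxit = max_iter, reltol = reltol))
  if (opt$convergence != 0)
    stop("Rasch CML did not converge (optim code ", opt$convergence, ")")
  sigma <- c(opt$par, -sum(opt$par))
  names(sigma) <- colnames(d$X)
  ## sum-zero covariance via the contrast map free -> sigma
  se <- rep(NA_real_, J)
  H <- try(optimHess(opt$par, fn, gr), silent = TRUE)
  if (!inherits(H, "try-error")) {
    Vf <- try(solve(H), silent = TRUE)
    if (inherits(Vf, "try-error")) Vf <- MASS::ginv(H)
    A <- rbind(diag(J - 1), rep(-1, J - 1))
    se <- sqrt(pmax(diag(A %*% Vf %*% t(A)), 0))
  }
  names(se) <- names(sigma)
  structure(list(difficulties = sigma, se = se,
                 cll = -opt$value,
                 theta_table = score_theta_table(sigma),
                 convergence = list(code = opt$convergence,
                                    counts = opt$counts),
                 n_excluded = d$n_extreme,
                 responses = responses),
            class = "rasch_fit")
}

## ML ability estimate for each non-extreme raw score
score_theta_table <- function(sigma) {
  J <- length(sigma)
  th <- vapply(seq_len(J - 1), function(r) {
    uniroot(function(t) sum(plogis(t - sigma)) - r,
            lower = -12, upper = 12, tol = 1e-9)$root
  }, numeric(1))
  data.frame(raw_score = seq_len(J - 1), theta = th)
}

#' @export
print.rasch_fit <- function(x, ...) {
  cat("Rasch CML fit: ", length(x$difficulties), " items, conditional logLik ",
      round(x$cll, 2), "\n", sep = "")
  cat("Difficulties (sum-zero):\n")
  print(round(x$difficulties, 3))
  invisible(x)
}
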