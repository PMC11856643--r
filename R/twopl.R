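## Gauss-Hermite quadrature adapted to a Normal(0,1) latent density
normal_quadrature <- function(nodes = 21L) {
  gh <- pracma::gaussHermite(nodes)
  list(theta = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

## expected-count weighted logistic fit  logit p = c0 + c1 * theta
## (Newton-Raphson on 2 parameters; counts may be fractional)
wlogit2 <- function(theta, r, n, start = c(0, 1), max_iter = 50L) {
  beta <- start
  for (it in seq_len(max_iter)) {
    eta <- beta[1] + beta[2] * theta
    p <- plogis(eta)
    w <- n * p * (1 - p)
    g <- c(sum(r - n * p), sum((r - n * p) * theta))
    H <- -rbind(c(sum(w), sum(w * theta)),
                c(sum(w * theta), sum(w * theta^2)))
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta - step
    if (max(abs(step)) < 1e-10) break
  }
  beta
}

## marginal log-likelihood of response matrix X given item probability
## matrix P (quadrature points x items) and weights w
marginal_loglik <- function(X, P, w) {
  logP <- log(P); log1P <- log1p(-P)
  ## persons x quadrature matrix of log f(x_i | theta_q)
  LL <- X %*% t(logP) + (1 - X) %*% t(log1P)
  M <- apply(LL, 1, max)
  sum(M + log(colSums(exp(t(LL) - rep(M, each = ncol(LL))) * w)))
}

em_posterior <- function(X, P, w) {
  LL <- X %*% t(logP <- log(P)) + (1 - X) %*% t(log1p(-P))
  A <- exp(LL - apply(LL, 1, max))
  A <- sweep(A, 2, w, "*")
  A / rowSums(A)
}

#' Fit the two-parameter logistic model by marginal maximum likelihood
#'
#' EM estimation with the latent ability fixed at Normal(0, 1),
#' approximated by Gauss-Hermite quadrature.  Item response probability
#' is `plogis(a_j * (theta - b_j))`.  Slopes diverging beyond
#' `slope_bound` (Heywood-type items) are truncated with a warning.
#'
#' @param responses a [response_matrix()] without missing cells.
#' @param quad_nodes number of quadrature nodes (default 21).
#' @param max_iter,tol EM control (change in marginal log-likelihood).
#' @param slope_bound upper bound applied to discrimination slopes.
#' @return A `twopl_fit` with `a` (discriminations), `b` (difficulties),
#'   `loglik` (marginal), `quadrature`, `convergence`, `bounded_items`,
#'   and the responses.
#' @export
fit_2pl <- function(responses, quad_nodes = 21L, max_iter = 500L,
                    tol = 1e-6, slope_bound = 6) {
  X <- unclass(responses)
  if (anyNA(X)) stop("2PL estimation requires complete responses")
  J <- ncol(X)
  if (J < 2) stop("at least 2 items are required")
  pj <- colMeans(X)
  if (any(pj == 0 | pj == 1))
    stop("item(s) without variance: ",
         paste(colnames(X)[pj == 0 | pj == 1], collapse = ", "))
  qd <- normal_quadrature(quad_nodes)
  Tq <- length(qd$theta)
  ## start: a = 1, b from classical difficulty
  a <- rep(1, J); b <- -qlogis(pj)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    P <- plogis(outer(qd$theta, b, "-") * rep(a, each = Tq))
    P <- clip_prob(P, 1e-10)
    post <- em_posterior(X, P, qd$w)        # persons x nodes
    nq <- colSums(post)                     # expected node counts
    Rq <- t(post) %*% X                     # nodes x items expected correct
    for (j in seq_len(J)) {
      beta <- wlogit2(qd$theta, Rq[, j], nq,
                      start = c(-a[j] * b[j], a[j]))
      a[j] <- beta[2]
      b[j] <- -beta[1] / beta[2]
    }
    a <- pmax(pmin(a, slope_bound), 1e-3)
    P <- plogis(outer(qd$theta, b, "-") * rep(a, each = Tq))
    ll <- marginal_loglik(X, clip_prob(P, 1e-10), qd$w)
    if (abs(ll - ll_old) < tol) { converged <- TRUE; ll_old <- ll; break }
    ll_old <- ll
  }
  bounded <- which(a >= slope_bound - 1e-8)
  if (length(bounded))
    warning("discrimination slope truncated at bound ", slope_bound,
            " for item(s): ", paste(colnames(X)[bounded], collapse = ", "))
  names(a) <- names(b) <- colnames(X)
  structure(list(a = a, b = b, loglik = ll_old,
                 quadrature = list(nodes = quad_nodes,
                                   range = range(qd$theta)),
                 convergence = list(converged = converged, iterations = it),
                 bounded_items = colnames(X)[bounded],
                 responses = responses),
            class = "twopl_fit")
}

#' @export
print.twopl_fit <- function(x, ...) {
  cat("2PL marginal ML fit: ", length(x$a), " items, logLik ",
      round(x$loglik, 2), "\n", sep = "")
  print(round(data.frame(a = x$a, b = x$b), 3))
  invisible(x)
}

## Marginal Rasch model (common slope, free difficulties) on the same
## quadrature, so its likelihood is comparable with the 2PL's.  The free
## common slope is equivalent to a free latent variance.
rasch_mml <- function(responses, quad_nodes = 21L, max_iter = 500L,
                      tol = 1e-6) {
  X <- unclass(responses)
  J <- ncol(X)
  qd <- normal_quadrature(quad_nodes)
  Tq <- length(qd$theta)
  a <- 1; b <- -qlogis(clip_prob(colMeans(X), 1e-4))
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    P <- clip_prob(plogis(a * outer(qd$theta, b, "-")), 1e-10)
    post <- em_posterior(X, P, qd$w)
    nq <- colSums(post)
    Rq <- t(post) %*% X
    ## coordinate M-step: difficulties given slope, then common slope
    for (cycle in 1:3) {
      for (j in seq_len(J)) {
        ## 1-parameter Newton in b_j
        for (nit in 1:25) {
          p <- plogis(a * (qd$theta - b[j]))
          g <- -a * sum(Rq[, j] - nq * p)
          h <- a^2 * sum(nq * p * (1 - p))
          if (!is.finite(g) || !is.finite(h) || h < 1e-12) break
          step <- max(min(g / h, 2), -2)   # g is dLL/db, curvature -h
          b[j] <- b[j] + step
          if (abs(step) < 1e-10) break
        }
      }
      for (nit in 1:25) {
        g <- 0; h <- 0
        for (j in seq_len(J)) {
          d <- qd$theta - b[j]
          p <- plogis(a * d)
          g <- g + sum((Rq[, j] - nq * p) * d)
          h <- h + sum(nq * p * (1 - p) * d^2)
        }
        if (!is.finite(g) || !is.finite(h) || h < 1e-12) break
        step <- max(min(g / h, 0.5), -0.5)  # g is dLL/da, curvature -h
        a <- max(a + step, 1e-3)
        if (abs(step) < 1e-10) break
      }
    }
    P <- clip_prob(plogis(a * outer(qd$theta, b, "-")), 1e-10)
    ll <- marginal_loglik(X, P, qd$w)
    if (abs(ll - ll_old) < tol) { ll_old <- ll; break }
    ll_old <- ll
  }
  list(a = a, b = setNames(b, colnames(X)), loglik = ll_old,
       n_params = J + 1L)
}
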