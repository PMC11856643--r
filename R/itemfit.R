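#' Screen Rasch item fit with score-group chi-square statistics
#'
#' Persons are grouped by raw score (adjacent scores pooled until each
#' group holds at least `min_group` persons).  For each item, observed
#' correct counts per group are compared with their exact conditional
#' expectations under the fitted Rasch model,
#' `P(X_j = 1 | raw score r)`, giving a Pearson-type chi-square with
#' `G - 1` degrees of freedom (one lost to item parameter estimation).
#' Infit and outfit mean squares (computed against the ML ability of
#' each raw score) are reported alongside.  Items with `p < alpha` are
#' flagged; the retained subset is the set of conforming items.
#'
#' @param fit a `rasch_fit` produced from `responses`.
#' @param responses the [response_matrix()] the fit was estimated from
#'   (defaults to the one stored in the fit).
#' @param alpha screening level (default 0.05).
#' @param min_group minimum persons per score group.
#' @return An `item_fit_report`: data frame `items` with per-item
#'   statistic, df, p-value, infit, outfit and `flagged`, plus `alpha`,
#'   `groups` (score pooling used), and `retained` (conforming item
#'   ids).
#' @export
item_fit_screen <- function(fit, responses = fit$responses, alpha = 0.05,
                            min_group = 30L) {
  if (!inherits(fit, "rasch_fit")) stop("'fit' must be a rasch_fit")
  X <- unclass(responses)
  if (!identical(colnames(X), names(fit$difficulties)))
    stop("fit and responses cover different items")
  J <- ncol(X)
  r <- rowSums(X)
  keep <- r > 0 & r < J
  Xn <- X[keep, , drop = FALSE]
  rn <- r[keep]
  nr <- tabulate(rn, nbins = J - 1)
  ## pool adjacent raw scores into groups of at least min_group persons
  grp_of_score <- integer(J - 1)
  g <- 1L; acc <- 0L
  for (s in seq_len(J - 1)) {
    grp_of_score[s] <- g
    acc <- acc + nr[s]
    if (acc >= min_group && s < J - 1) { g <- g + 1L; acc <- 0L }
  }
  if (acc < min_group && acc > 0 && g > 1) {
    grp_of_score[grp_of_score == g] <- g - 1L
    g <- g - 1L
  }
  G <- max(grp_of_score[nr > 0])
  grp_sizes <- vapply(seq_len(G), function(k) sum(nr[grp_of_score == k]),
                      numeric(1))
  if (sum(grp_sizes > 0) < 3)
    stop("fewer than 3 score groups with data; statistic undefined")
  pi <- rasch_cond_probs(fit$difficulties)   # J x (J-1)
  grp <- grp_of_score[rn]                    # group of each person
  theta_tab <- fit$theta_table$theta
  Pexp <- t(plogis(outer(theta_tab[rn], fit$difficulties, "-")))  # J x n
  stat <- df <- pval <- infit <- outfit <- numeric(J)
  for (j in seq_len(J)) {
    O <- vapply(seq_len(G), function(k) sum(Xn[grp == k, j]), numeric(1))
    E <- vapply(seq_len(G), function(k) {
      sc <- which(grp_of_score == k)
      sum(nr[sc] * pi[j, sc])
    }, numeric(1))
    V <- vapply(seq_len(G), function(k) {
      sc <- which(grp_of_score == k)
      sum(nr[sc] * pi[j, sc] * (1 - pi[j, sc]))
    }, numeric(1))
    ok <- V > 1e-10
    stat[j] <- sum((O[ok] - E[ok])^2 / V[ok])
    df[j] <- sum(ok) - 1L
    pval[j] <- pchisq(stat[j], df[j], lower.tail = FALSE)
    ## infit / outfit mean squares against score-group ML abilities
    p <- Pexp[j, ]
    z2 <- (Xn[, j] - p)^2 / (p * (1 - p))
    outfit[j] <- mean(z2)
    infit[j] <- sum((Xn[, j] - p)^2) / sum(p * (1 - p))
  }
  items <- data.frame(item = colnames(X), statistic = stat, df = df,
                      p_value = pval, infit = infit, outfit = outfit,
                      flagged = pval < alpha, stringsAsFactors = FALSE)
  structure(list(items = items, alpha = alpha,
                 groups = data.frame(raw_score = seq_len(J - 1),
                                     group = grp_of_score, n = nr),
                 retained = colnames(X)[!items$flagged]),
            class = "item_fit_report")
}

#' @export
print.item_fit_report <- function(x, ...) {
  cat("Item fit screen (alpha = ", x$alpha, "): ",
      sum(x$items$flagged), " of ", nrow(x$items), " items flagged\n",
      sep = "")
  print(transform(x$items, statistic = round(statistic, 2),
                  p_value = round(p_value, 4), infit = round(infit, 2),
                  outfit = round(outfit, 2)), row.names = FALSE)
  invisible(x)
}

#' Compare Rasch and 2PL model fit
#'
#' The likelihood-ratio test requires both models on the same
#' (marginal) likelihood scale, so the Rasch model is re-estimated by
#' marginal maximum likelihood on the same quadrature as the 2PL fit
#' (common discrimination slope free, equivalent to a free latent
#' variance; `J + 1` parameters vs the 2PL's `2J`).  Information
#' criteria use the number of persons as sample size.
#'
#' @param rasch a `rasch_fit` (or a second `twopl_fit` for a
#'   same-family comparison).
#' @param twopl a `twopl_fit` on the identical responses.
#' @param quad_nodes quadrature nodes for the marginal Rasch
#'   re-estimation (defaults to the 2PL fit's).
#' @return A `model_fit_comparison` with `chisq`, `df`, `p_value`, and
#'   `delta_aic`, `delta_bic`, `delta_caic` (second model minus first).
#' @export
compare_model_fit <- function(rasch, twopl,
                              quad_nodes = twopl$quadrature$nodes) {
  if (is.null(quad_nodes)) quad_nodes <- 21L
  marg <- function(fit) {
    if (inherits(fit, "twopl_fit"))
      list(loglik = fit$loglik, n_params = 2L * length(fit$a),
           items = names(fit$a), n = nrow(fit$responses))
    else if (inherits(fit, "rasch_fit")) {
      m <- rasch_mml(fit$responses, quad_nodes = quad_nodes)
      list(loglik = m$loglik, n_params = m$n_params,
           items = names(fit$difficulties), n = nrow(fit$responses))
    } else stop("fits must be rasch_fit or twopl_fit objects")
  }
  m0 <- marg(rasch); m1 <- marg(twopl)
  if (!identical(m0$items, m1$items))
    stop("models are not nested: different item sets")
  chisq <- max(2 * (m1$loglik - m0$loglik), 0)
  df <- m1$n_params - m0$n_params
  n <- m1$n
  ic <- function(ll, p)
    c(aic = -2 * ll + 2 * p, bic = -2 * ll + log(n) * p,
      caic = -2 * ll + (log(n) + 1) * p)
  d <- ic(m1$loglik, m1$n_params) - ic(m0$loglik, m0$n_params)
  structure(list(chisq = chisq, df = df,
                 p_value = if (df > 0)
                   pchisq(chisq, df, lower.tail = FALSE) else 1,
                 delta_aic = unname(d["aic"]), delta_bic = unname(d["bic"]),
                 delta_caic = unname(d["caic"]),
                 loglik = c(model1 = m0$loglik, model2 = m1$loglik),
                 n_params = c(model1 = m0$n_params, model2 = m1$n_params),
                 n_persons = n),
            class = "model_fit_comparison")
}

#' @export
print.model_fit_comparison <- function(x, ...) {
  cat("Likelihood ratio test: chisq = ", round(x$chisq, 2), ", df = ",
      x$df, ", p = ", format.pval(x$p_value, digits = 3), "\n",
      "delta AIC = ", round(x$delta_aic, 2), ", delta BIC = ",
      round(x$delta_bic, 2), ", delta CAIC = ", round(x$delta_caic, 2),
      "\n", sep = "")
  invisible(x)
}
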