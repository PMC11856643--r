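#' Solve the least squares distance decomposition
#'
#' At each ability grid point `theta` the LSDM solves the linear system
#' `L = Q x` in the least squares sense, where `L` is the vector of log
#' item solution probabilities at `theta` and `x` holds the unknown log
#' attribute (component) probabilities `ln P(A_k = 1 | theta)`.  Under
#' the conjunctive model each item probability is the product of its
#' component probabilities raised to the Q-matrix weights, so the log
#' system is linear.
#'
#' With `constrained = TRUE` (default) the solution enforces `x <= 0`
#' (attribute probabilities at most 1) via non-negative least squares
#' on the negated system.  With `constrained = FALSE` a plain least
#' squares solution is used and any positive entries are clipped to 0
#' afterwards, with the clip count reported.
#'
#' @param source an [icc_table()] with provenance `"rasch"` or
#'   `"twopl"`; probabilities must be strictly inside (0, 1) (clip
#'   upstream via [evaluate_iccs()]).
#' @param q a [qmatrix()] covering the source items; columns that are
#'   all zero leave the component unidentified and are an error.
#' @param constrained enforce attribute probabilities <= 1.
#' @param epsilon probability clipping bound for the logarithm.
#' @return An `lsdm_fit` with `X` (components x grid points, log
#'   attribute probabilities), `attribute_probs` (`exp(X)`),
#'   `residual_norms` (per grid point), `reconstructed` (an
#'   [icc_table()] with provenance `"lsdm-reconstructed"`),
#'   `source_provenance`, `clipped` (cell count, unconstrained mode
#'   only), `theta`, and `q`.
#' @export
solve_attribute_logprobs <- function(source, q, constrained = TRUE,
                                     epsilon = 1e-6) {
  if (!inherits(source, "icc_table")) stop("'source' must be an icc_table")
  if (!all(rownames(source) %in% rownames(q)))
    stop("Q-matrix does not cover all source items")
  q <- subset_qmatrix(q, rownames(source))
  Qm <- unclass(q)[, , drop = FALSE]
  zero_cols <- colSums(Qm) == 0
  if (any(zero_cols))
    stop("component(s) not touched by any item (all-zero Q column): ",
         paste(colnames(Qm)[zero_cols], collapse = ", "))
  storage.mode(Qm) <- "double"
  theta <- icc_theta(source)
  Lmat <- log(clip_prob(unclass(source)[, , drop = FALSE], epsilon))   # items x grid
  K <- ncol(Qm); Tg <- ncol(Lmat)
  X <- matrix(0, K, Tg, dimnames = list(colnames(Qm), NULL))
  res <- numeric(Tg)
  clipped <- 0L
  if (constrained) {
    for (t in seq_len(Tg)) {
      nn <- pracma::lsqnonneg(Qm, -Lmat[, t])
      X[, t] <- -nn$x
      res[t] <- sqrt(max(nn$resid.norm, 0))
    }
  } else {
    qrq <- qr(Qm)
    X[, ] <- qr.coef(qrq, Lmat)
    fitted <- Qm %*% X
    res <- sqrt(colSums((fitted - Lmat)^2))
    clipped <- sum(X > 0)
    X[X > 0] <- 0
  }
  fit <- structure(list(X = X, attribute_probs = exp(X),
                        residual_norms = res,
                        source_provenance = icc_provenance(source),
                        clipped = clipped, constrained = constrained,
                        theta = theta, q = q, epsilon = epsilon),
                   class = "lsdm_fit")
  fit$reconstructed <- reconstruct_iccs(fit, q)
  fit
}

#' @export
print.lsdm_fit <- function(x, ...) {
  cat("LSDM fit on ", x$source_provenance, " ICCs: ", nrow(x$X),
      " components x ", ncol(x$X), " theta points; mean residual norm ",
      round(mean(x$residual_norms), 4), "\n", sep = "")
  if (!x$constrained && x$clipped > 0)
    cat("unconstrained mode clipped", x$clipped, "positive log-prob cells\n")
  invisible(x)
}

#' Rebuild item characteristic curves from attribute probabilities
#'
#' `P_hat[j, t] = exp(sum_k q[j, k] * X[k, t])` -- the conjunctive
#' product of component probabilities.  An item whose Q-matrix row is
#' all zero would yield the empty product 1 and is rejected upstream by
#' [qmatrix()].
#'
#' @param fit an `lsdm_fit`.
#' @param q a [qmatrix()] conformable with the fitted components.
#' @return An [icc_table()] with provenance `"lsdm-reconstructed"`.
#' @export
reconstruct_iccs <- function(fit, q = fit$q) {
  if (!identical(colnames(q), rownames(fit$X)))
    stop("Q-matrix components do not match the fitted attributes")
  P <- exp(unclass(q)[, , drop = FALSE] %*% fit$X)
  icc_table(P, fit$theta, "lsdm-reconstructed")
}

#' Mean absolute distance between two ICC tables
#'
#' Per item, the mean over grid points of the absolute difference
#' between source and reconstructed solution probabilities.  Items are
#' labelled `good` (MAD < 0.05), `satisfactory` (0.05 <= MAD < 0.10),
#' or `poor` (otherwise).
#'
#' @param source,reconstructed [icc_table()]s on identical grids and
#'   item sets (item order may differ; items are matched by id).
#' @return A `mad_report`: list with `items` (data frame of per-item
#'   MAD and quality label), `mean`, and `median`.
#' @export
mad_diagnostics <- function(source, reconstructed) {
  if (!isTRUE(all.equal(sort(icc_theta(source)),
                        sort(icc_theta(reconstructed)))))
    stop("ICC tables evaluated on different theta grids")
  if (!setequal(rownames(source), rownames(reconstructed)))
    stop("ICC tables cover different item sets")
  so <- order(icc_theta(source)); ro <- order(icc_theta(reconstructed))
  S <- unclass(source)[, so, drop = FALSE]
  R <- unclass(reconstructed)[rownames(source), ro, drop = FALSE]
  mad <- rowMeans(abs(S - R))
  label <- cut(mad, c(-Inf, 0.05, 0.10, Inf),
               labels = c("good", "satisfactory", "poor"), right = FALSE)
  structure(list(items = data.frame(item = rownames(source),
                                    mad = unname(mad),
                                    label = as.character(label),
                                    stringsAsFactors = FALSE),
                 mean = mean(mad), median = median(mad)),
            class = "mad_report")
}

#' @export
print.mad_report <- function(x, ...) {
  cat("ICC reconstruction MAD: mean ", round(x$mean, 3), ", median ",
      round(x$median, 3), "\n", sep = "")
  print(x$items, row.names = FALSE)
  invisible(x)
}

#' Item difficulty implied by a reconstructed ICC
#'
#' The ability value at which the curve first crosses a 0.50 solution
#' probability, found by linear interpolation in probability between
#' the bracketing grid points.  Curves that never reach 0.5 inside the
#' grid are flagged `extrapolated` and returned at the nearer grid
#' bound.
#'
#' @param reconstructed an [icc_table()].
#' @return Data frame with `item`, `difficulty`, `extrapolated`.
#' @export
implied_item_difficulty <- function(reconstructed) {
  P <- unclass(reconstructed)[, , drop = FALSE]
  if (any(!is.finite(P))) stop("non-finite probabilities in ICC table")
  if (is.null(rownames(P)))
    rownames(P) <- sprintf("Item%02d", seq_len(nrow(P)))
  theta <- icc_theta(reconstructed)
  o <- order(theta); theta <- theta[o]; P <- P[, o, drop = FALSE]
  one <- function(p) {
    if (p[1] >= 0.5) return(c(theta[1], TRUE))       # already above 0.5
    up <- which(p[-length(p)] < 0.5 & p[-1] >= 0.5)  # first upward crossing
    if (length(up) == 0) return(c(theta[length(p)], TRUE))
    i <- up[1]
    frac <- (0.5 - p[i]) / (p[i + 1] - p[i])
    c(theta[i] + frac * (theta[i + 1] - theta[i]), FALSE)
  }
  out <- t(apply(P, 1, one))
  data.frame(item = rownames(P), difficulty = out[, 1],
             extrapolated = as.logical(out[, 2]), stringsAsFactors = FALSE)
}

#' Logistic summaries of LSDM attribute curves
#'
#' Per component, an ordinary least squares fit of
#' `logit(P(A_k = 1 | theta))` on `theta`, using only grid points where
#' the attribute probability lies strictly inside
#' (`epsilon`, 1 - `epsilon`).  The slope is the component's
#' discrimination and `-intercept/slope` its difficulty, with the fit
#' quality reported as R-squared.  Components with fewer than 3 usable
#' grid points are flagged `unfit`; a difficulty outside the grid range
#' (curve never crossing 0.5 inside the grid) is flagged
#' `extrapolated`.  Mean-centered difficulties are included for
#' tabular reporting.
#'
#' @param fit an `lsdm_fit`.
#' @param epsilon usability bound on attribute probabilities.
#' @return An `attribute_summary` data frame with columns `component`,
#'   `kind`, `difficulty`, `discrimination`, `r_squared`,
#'   `difficulty_centered`, `extrapolated`, `unfit`.
#' @export
attribute_curve_summary <- function(fit, epsilon = fit$epsilon) {
  tax <- q_taxonomy(fit$q)
  theta <- fit$theta
  rows <- lapply(rownames(fit$X), function(k) {
    pk <- fit$attribute_probs[k, ]
    use <- pk > epsilon & pk < 1 - epsilon
    if (sum(use) < 3)
      return(data.frame(component = k, difficulty = NA_real_,
                        discrimination = NA_real_, r_squared = NA_real_,
                        extrapolated = TRUE, unfit = TRUE))
    y <- qlogis(pk[use])
    m <- lm(y ~ theta[use])
    b <- coef(m)
    disc <- unname(b[2])
    diff <- if (abs(disc) > 1e-12) unname(-b[1] / b[2]) else NA_real_
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum(resid(m)^2) / sst else NA_real_
    crosses <- any(pk[-length(pk)] < 0.5 & pk[-1] >= 0.5) ||
      any(pk[-length(pk)] >= 0.5 & pk[-1] < 0.5)
    data.frame(component = k, difficulty = diff, discrimination = disc,
               r_squared = r2, extrapolated = !crosses, unfit = FALSE)
  })
  out <- do.call(rbind, rows)
  out$kind <- tax$kind[match(out$component, tax$id)]
  out$difficulty_centered <- out$difficulty -
    mean(out$difficulty[!out$unfit], na.rm = TRUE)
  out <- out[, c("component", "kind", "difficulty", "discrimination",
                 "r_squared", "difficulty_centered", "extrapolated",
                 "unfit")]
  structure(out, class = c("attribute_summary", "data.frame"))
}
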