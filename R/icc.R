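#' Ability evaluation grid
#'
#' Ordered grid of ability focal points (logit units) on which item and
#' attribute characteristic curves are evaluated.  The default 61
#' equally spaced points on \[-4, 4\] cover essentially all of a
#' Normal(0, 1) ability distribution.
#'
#' @param min,max grid range.
#' @param count number of points (>= 2, strictly increasing).
#' @return Numeric vector of class `theta_grid`.
#' @export
theta_grid <- function(min = -4, max = 4, count = 61L) {
  if (count < 2 || max <= min) stop("invalid theta grid specification")
  structure(seq(min, max, length.out = count), class = "theta_grid")
}

#' Item characteristic curve table
#'
#' @param probs items-by-grid-points matrix of solution probabilities.
#' @param theta the [theta_grid()] (or numeric vector) of focal points.
#' @param provenance one of `"rasch"`, `"twopl"`, `"lltm"`,
#'   `"lsdm-reconstructed"`.
#' @return An `icc_table`: the probability matrix with attributes
#'   `theta` and `provenance`.
#' @export
icc_table <- function(probs, theta, provenance) {
  probs <- as.matrix(probs)
  if (ncol(probs) != length(theta))
    stop("probability matrix must have one column per grid point")
  provenance <- match.arg(provenance,
                          c("rasch", "twopl", "lltm", "lsdm-reconstructed"))
  structure(probs, theta = as.numeric(theta), provenance = provenance,
            class = c("icc_table", "matrix"))
}

icc_theta <- function(x) attr(x, "theta")
icc_provenance <- function(x) attr(x, "provenance")

#' @export
print.icc_table <- function(x, ...) {
  cat("ICC table (", icc_provenance(x), "): ", nrow(x), " items x ",
      ncol(x), " theta points on [", min(icc_theta(x)), ", ",
      max(icc_theta(x)), "]\n", sep = "")
  invisible(x)
}

#' Evaluate model item characteristic curves on a theta grid
#'
#' For a Rasch fit the curve of item `j` is `plogis(theta - sigma_j)`;
#' for a 2PL fit it is `plogis(a_j * (theta - b_j))`.  Probabilities are
#' clipped away from exact 0/1 by `epsilon` so downstream logarithms are
#' finite.
#'
#' @param fit a `rasch_fit` or `twopl_fit`.
#' @param grid a [theta_grid()].
#' @param epsilon clipping bound for probabilities.
#' @return An [icc_table()] with matching provenance.
#' @export
evaluate_iccs <- function(fit, grid = theta_grid(), epsilon = 1e-6) {
  UseMethod("evaluate_iccs")
}

#' @export
evaluate_iccs.rasch_fit <- function(fit, grid = theta_grid(),
                                    epsilon = 1e-6) {
  P <- t(plogis(outer(as.numeric(grid), fit$difficulties, "-")))
  icc_table(clip_prob(P, epsilon), grid, "rasch")
}

#' @export
evaluate_iccs.twopl_fit <- function(fit, grid = theta_grid(),
                                    epsilon = 1e-6) {
  th <- as.numeric(grid)
  P <- t(plogis(outer(th, fit$b, "-") * rep(fit$a, each = length(th))))
  icc_table(clip_prob(P, epsilon), grid, "twopl")
}

#' @export
evaluate_iccs.lltm_fit <- function(fit, grid = theta_grid(),
                                   epsilon = 1e-6) {
  lltm_icc_table(fit, grid, epsilon)
}
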