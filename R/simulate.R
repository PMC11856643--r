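#' Attribute characteristic curve parameters
#'
#' Each taxonomy component is given a logistic mastery curve
#' `P(A_k = 1 | theta) = plogis(discrimination * (theta - difficulty))`:
#' the probability that a person at ability `theta` masters component
#' `k`.  A component may be *pinned*, meaning its mastery probability is
#' the constant 1 (the zero-discrimination limit), in which case it
#' contributes nothing to conjunctive item probabilities.
#'
#' @param difficulty numeric, theta at mastery probability 0.5 (logit
#'   units), one per component.
#' @param discrimination positive logistic slopes (1/logit units).
#' @param components component ids (defaults to the
#'   [default_taxonomy()] ids when lengths match).
#' @param pinned logical; `TRUE` pins the component's probability at 1.
#' @return An `attribute_curves` data frame.
#' @export
attribute_curves <- function(difficulty, discrimination,
                             components = NULL, pinned = FALSE) {
  n <- length(difficulty)
  if (length(discrimination) != n)
    stop("difficulty and discrimination must have equal length")
  pinned <- rep_len(pinned, n)
  if (any(discrimination[!pinned] <= 0))
    stop("discrimination must be positive (or the component pinned)")
  if (is.null(components)) {
    tax <- default_taxonomy()
    components <- if (n == nrow(tax)) tax$id else sprintf("C%02d", seq_len(n))
  }
  structure(data.frame(component = as.character(components),
                       difficulty = difficulty,
                       discrimination = discrimination,
                       pinned = pinned, stringsAsFactors = FALSE),
            class = c("attribute_curves", "data.frame"))
}

## components x theta matrix of mastery probabilities
attribute_prob_matrix <- function(curves, theta) {
  P <- matrix(1, nrow(curves), length(theta),
              dimnames = list(curves$component, NULL))
  for (k in seq_len(nrow(curves)))
    if (!curves$pinned[k])
      P[k, ] <- plogis(curves$discrimination[k] *
                         (theta - curves$difficulty[k]))
  P
}

new_simulation <- function(responses, q, truth, seed) {
  structure(list(responses = responses, q = q, truth = truth,
                 seed = as.integer(seed)),
            class = "cdm_simulation")
}

#' @export
print.cdm_simulation <- function(x, ...) {
  cat("Simulated dataset (", x$truth$model, " truth): ",
      nrow(x$responses), " persons x ", ncol(x$responses),
      " items, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

## abilities and responses come from independently derived substreams so
## the same seed yields the same theta under every generating model
draw_theta <- function(n_persons, rng_seed) {
  if (n_persons < 2) stop("n_persons must be at least 2")
  with_seed(rng_seed, function() rnorm(n_persons))
}

draw_bernoulli <- function(P, rng_seed) {
  with_seed(derive_seed(rng_seed, 1L), function() {
    X <- matrix(as.integer(runif(length(P)) < P), nrow(P), ncol(P))
    X
  })
}

#' Simulate responses under an additive (LLTM-true) model
#'
#' Item difficulties are additive combinations of component base
#' parameters, `sigma_j = sum_k q[j,k] * eta[k] + c`, and responses are
#' Bernoulli with probability `plogis(theta_i - sigma_j)` for abilities
#' `theta ~ Normal(0, 1)`.
#'
#' @param q a [qmatrix()].
#' @param eta per-component base difficulties (logit units).
#' @param c normalization constant added to every item difficulty.
#' @param n_persons number of persons (>= 2).
#' @param rng_seed integer seed.
#' @return A `cdm_simulation` with the response matrix, the Q-matrix,
#'   and a truth block storing `eta`, `c`, the implied `sigma`, and the
#'   drawn `theta`.
#' @export
simulate_additive <- function(q, eta, c = 0, n_persons, rng_seed) {
  if (length(eta) != ncol(q))
    stop("eta must have one entry per Q-matrix component")
  theta <- draw_theta(n_persons, rng_seed)
  sigma <- drop(unclass(q) %*% eta) + c
  P <- plogis(outer(theta, sigma, "-"))
  X <- draw_bernoulli(P, rng_seed)
  resp <- response_matrix(X, items = rownames(q))
  new_simulation(resp, q,
                 list(model = "additive", eta = setNames(eta, colnames(q)),
                      c = c, sigma = setNames(sigma, rownames(q)),
                      theta = theta),
                 rng_seed)
}

#' Simulate responses under a conjunctive (LSDM-true) model
#'
#' Item solution probability is the product of component mastery
#' probabilities, `P_ij = prod_k P_k(theta_i)^q[j,k]`: failing any
#' required component makes the item practically unsolvable.
#'
#' @param q a [qmatrix()].
#' @param curves an [attribute_curves()] covering all Q-matrix
#'   components.
#' @param n_persons number of persons (>= 2).
#' @param rng_seed integer seed.
#' @return A `cdm_simulation`; the truth block stores the curves and
#'   `theta`.
#' @export
simulate_conjunctive <- function(q, curves, n_persons, rng_seed) {
  if (!inherits(curves, "attribute_curves"))
    stop("'curves' must be an attribute_curves object")
  if (!setequal(curves$component, colnames(q)))
    stop("curves must cover exactly the Q-matrix components")
  curves <- curves[match(colnames(q), curves$component), ]
  theta <- draw_theta(n_persons, rng_seed)
  logPk <- log(attribute_prob_matrix(curves, theta))   # K x n
  logP <- t(unclass(q) %*% logPk)                      # n x J
  P <- exp(logP)
  X <- draw_bernoulli(P, rng_seed)
  resp <- response_matrix(X, items = rownames(q))
  new_simulation(resp, q,
                 list(model = "conjunctive", curves = curves, theta = theta),
                 rng_seed)
}

#' Simulate responses under a two-parameter logistic model
#'
#' Responses are Bernoulli with probability
#' `plogis(a_j * (theta_i - b_j))`.
#'
#' @param a per-item positive discrimination slopes.
#' @param b per-item real difficulties.
#' @param n_persons number of persons (>= 2).
#' @param rng_seed integer seed.
#' @param items optional item ids.
#' @return A `cdm_simulation` (without a Q-matrix; `q` is `NULL`).
#' @export
simulate_2pl <- function(a, b, n_persons, rng_seed, items = NULL) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (any(a <= 0)) stop("discrimination slopes must be positive")
  theta <- draw_theta(n_persons, rng_seed)
  P <- plogis(outer(theta, b, "-") * rep(a, each = n_persons))
  X <- draw_bernoulli(P, rng_seed)
  if (is.null(items)) items <- sprintf("Item%02d", seq_along(a))
  resp <- response_matrix(X, items = items)
  new_simulation(resp, NULL,
                 list(model = "twopl", a = setNames(a, items),
                      b = setNames(b, items), theta = theta),
                 rng_seed)
}

#' Write a simulated dataset to disk
#'
#' Writes the response matrix and (if present) the Q-matrix as CSV and
#' the truth block as JSON next to them.
#'
#' @param sim a `cdm_simulation`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(responses = file.path(dir, paste0(prefix, "_responses.csv")))
  write_response_matrix(sim$responses, paths[["responses"]])
  if (!is.null(sim$q)) {
    paths[["qmatrix"]] <- file.path(dir, paste0(prefix, "_qmatrix.csv"))
    write_qmatrix(sim$q, paths[["qmatrix"]])
  }
  paths[["truth"]] <- file.path(dir, paste0(prefix, "_truth.json"))
  truth <- sim$truth
  truth$seed <- sim$seed
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}
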