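#' Construct a validated Q-matrix
#'
#' A Q-matrix is an items-by-components grid of non-negative integer
#' weights `q[j, k]` encoding the presence and prevalence of component
#' `k` in item `j`.  Every item must load on at least one component.
#'
#' @param weights numeric matrix of non-negative integers, items in rows,
#'   components in columns.
#' @param taxonomy a [component_taxonomy()]; its ids must match the
#'   column names of `weights` (columns in a different order are
#'   reordered to the canonical taxonomy order).
#' @param items optional character vector of item ids (defaults to
#'   rownames of `weights` or `Item01`, `Item02`, ...).
#' @return A `qmatrix` object: the integer weight matrix with attributes
#'   `taxonomy`, `rank`, and `full_column_rank`.
#' @examples
#' tax <- component_taxonomy(c("A", "B"), c("change_rule", "design_principle"))
#' qmatrix(matrix(c(1, 0, 1, 0, 1, 1), 3, 2,
#'                dimnames = list(NULL, c("A", "B"))), tax)
#' @export
qmatrix <- function(weights, taxonomy, items = NULL) {
  weights <- as.matrix(weights)
  if (!inherits(taxonomy, "component_taxonomy"))
    stop("'taxonomy' must be a component_taxonomy")
  if (is.null(colnames(weights))) {
    if (ncol(weights) != nrow(taxonomy))
      stop("weights must have one column per taxonomy component")
    colnames(weights) <- taxonomy$id
  }
  if (!setequal(colnames(weights), taxonomy$id))
    stop("Q-matrix columns do not match taxonomy components: ",
         paste(setdiff(colnames(weights), taxonomy$id), collapse = ", "))
  weights <- weights[, taxonomy$id, drop = FALSE]
  if (any(!is.finite(weights)) || any(weights < 0) ||
      any(weights != round(weights)))
    stop("Q-matrix weights must be non-negative integers")
  storage.mode(weights) <- "integer"
  if (is.null(items))
    items <- if (!is.null(rownames(weights))) rownames(weights)
             else sprintf("Item%02d", seq_len(nrow(weights)))
  if (anyDuplicated(items)) stop("item ids must be unique")
  rownames(weights) <- items
  zero_rows <- rowSums(weights) == 0
  if (any(zero_rows))
    stop("every item must load on at least one component; all-zero rows: ",
         paste(items[zero_rows], collapse = ", "))
  qd <- qr(weights)
  structure(weights,
            taxonomy = taxonomy,
            rank = qd$rank,
            full_column_rank = qd$rank == ncol(weights),
            class = c("qmatrix", "matrix"))
}

q_taxonomy <- function(q) attr(q, "taxonomy")

## subset items while preserving qmatrix structure
subset_qmatrix <- function(q, items) {
  qmatrix(unclass(q)[items, , drop = FALSE], q_taxonomy(q), items = items)
}

#' @export
print.qmatrix <- function(x, ...) {
  cat("Q-matrix: ", nrow(x), " items x ", ncol(x), " components, rank ",
      attr(x, "rank"),
      if (attr(x, "full_column_rank")) " (full column rank)" else "", "\n",
      sep = "")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

## names of columns that are linearly dependent on the preceding ones
dependent_columns <- function(weights) {
  qd <- qr(weights)
  if (qd$rank == ncol(weights)) return(character(0))
  colnames(weights)[qd$pivot[-seq_len(qd$rank)]]
}

#' Generate a random taxonomy-structured Q-matrix
#'
#' Emulates the design of a rationally constructed figural matrix test:
#' each item applies one to three change rules (weights mostly 1,
#' occasionally up to `max_weight` when a rule is applied repeatedly)
#' and zero to two design principles (weight 1).  Generation is retried
#' until the matrix has full column rank, so downstream component
#' parameters are identified.
#'
#' @param n_items number of items (at least the number of components
#'   when full column rank is requested).
#' @param taxonomy a [component_taxonomy()]; defaults to the
#'   nine-component [default_taxonomy()].
#' @param max_weight maximum integer weight for a change rule.
#' @param rng_seed integer seed; generation is deterministic given it.
#' @param diagonal if `TRUE`, the first `K` rows form an identity-like
#'   block (each of the `K` components appearing alone once), which
#'   guarantees full column rank.
#' @param full_rank require full column rank (default `TRUE`).
#' @param max_tries bounded number of regeneration attempts before
#'   failing with the names of the offending columns.
#' @return A [qmatrix()].
#' @export
make_taxonomy_qmatrix <- function(n_items, taxonomy = default_taxonomy(),
                                  max_weight = 2L, rng_seed = 1L,
                                  diagonal = FALSE, full_rank = TRUE,
                                  max_tries = 50L) {
  K <- nrow(taxonomy)
  if (n_items < 1) stop("n_items must be positive")
  if (full_rank && n_items < K)
    stop("full column rank requires n_items >= ", K, " components")
  rules <- which(taxonomy$kind == "change_rule")
  dps <- which(taxonomy$kind == "design_principle")
  draw_row <- function() {
    w <- integer(K)
    if (length(rules)) {
      nr <- sample(1:min(3, length(rules)), 1)
      sel <- sample(rules, nr)
      w[sel] <- sample(seq_len(max_weight), nr, replace = TRUE,
                       prob = c(0.75, rep(0.25 / (max_weight - 1),
                                          max_weight - 1))[seq_len(max_weight)])
    }
    if (length(dps)) {
      nd <- sample(0:min(2, length(dps)), 1)
      if (nd > 0) w[sample(dps, nd)] <- 1L
    }
    if (all(w == 0)) w[sample(K, 1)] <- 1L
    w
  }
  last_bad <- character(0)
  for (try in seq_len(max_tries)) {
    w <- with_seed(derive_seed(rng_seed, try - 1L), function() {
      m <- matrix(0L, n_items, K, dimnames = list(NULL, taxonomy$id))
      start <- 1L
      if (diagonal) {
        m[seq_len(min(K, n_items)), ] <- diag(1L, min(K, n_items), K)
        start <- min(K, n_items) + 1L
      }
      if (start <= n_items)
        for (j in start:n_items) m[j, ] <- draw_row()
      m
    })
    bad <- dependent_columns(w)
    if (!full_rank || length(bad) == 0)
      return(qmatrix(w, taxonomy))
    last_bad <- bad
  }
  stop("could not reach full column rank after ", max_tries,
       " attempts; dependent columns: ", paste(last_bad, collapse = ", "))
}

#' Read / write a Q-matrix as CSV
#'
#' The CSV dialect has the item id in the first column (`item`) and one
#' integer column per taxonomy component.  Columns given in a different
#' order than the taxonomy are reordered canonically.
#'
#' @param path file path.
#' @param taxonomy a [component_taxonomy()] naming the expected columns.
#' @return `read_qmatrix()` returns a [qmatrix()]; `write_qmatrix()`
#'   returns `path` invisibly.
#' @export
read_qmatrix <- function(path, taxonomy = default_taxonomy()) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "item")
    stop_validation("Q-matrix CSV must have an 'item' first column")
  comp_cols <- names(df)[-1]
  unknown <- setdiff(comp_cols, taxonomy$id)
  if (length(unknown))
    stop_validation("unknown component columns: ",
                    paste(unknown, collapse = ", "))
  missing <- setdiff(taxonomy$id, comp_cols)
  if (length(missing))
    stop_validation("missing component columns: ",
                    paste(missing, collapse = ", "))
  w <- as.matrix(df[, taxonomy$id, drop = FALSE])
  if (any(is.na(w)) || any(w < 0) || any(w != round(w)))
    stop_validation("Q-matrix weights must be non-negative integers")
  qmatrix(w, taxonomy, items = as.character(df$item))
}

#' @rdname read_qmatrix
#' @param q a [qmatrix()] to write.
#' @export
write_qmatrix <- function(q, path) {
  df <- data.frame(item = rownames(q), unclass(q)[, , drop = FALSE], check.names = FALSE,
                   row.names = NULL)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
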