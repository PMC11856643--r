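#' Construct a validated binary response matrix
#'
#' @param scores persons-by-items matrix of 0/1 scores (`NA` allowed
#'   only when `allow_missing = TRUE`).
#' @param persons,items optional id vectors; default to dimnames or
#'   `P0001`... / `Item01`...
#' @param allow_missing permit `NA` cells (default `FALSE`).
#' @return A `response_matrix`: an integer matrix with person and item
#'   ids as dimnames.
#' @export
response_matrix <- function(scores, persons = NULL, items = NULL,
                            allow_missing = FALSE) {
  scores <- as.matrix(scores)
  if (is.null(persons))
    persons <- if (!is.null(rownames(scores))) rownames(scores)
               else sprintf("P%04d", seq_len(nrow(scores)))
  if (is.null(items))
    items <- if (!is.null(colnames(scores))) colnames(scores)
             else sprintf("Item%02d", seq_len(ncol(scores)))
  if (anyDuplicated(persons)) stop("person ids must be unique")
  if (anyDuplicated(items)) stop("item ids must be unique")
  if (!allow_missing && anyNA(scores))
    stop("missing scores are not allowed (set allow_missing = TRUE)")
  ok <- is.na(scores) | scores == 0 | scores == 1
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("scores must be 0, 1 or NA; offending cell: person ",
         persons[bad[1]], ", item ", items[bad[2]])
  }
  if (anyNA(scores)) {
    if (any(rowSums(!is.na(scores)) == 0)) stop("all-missing person row")
    if (any(colSums(!is.na(scores)) == 0)) stop("all-missing item column")
  }
  storage.mode(scores) <- "integer"
  dimnames(scores) <- list(persons, items)
  structure(scores, class = c("response_matrix", "matrix"))
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("Response matrix: ", nrow(x), " persons x ", ncol(x), " items, ",
      "mean score ", round(mean(x, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Read / write a response matrix as CSV
#'
#' CSV dialect: header row, first column `person` with person ids,
#' remaining columns named by item ids, cells `0`/`1` (token `NA` for
#' missing).  By default a missing or non-binary cell is an error; with
#' `listwise = TRUE`, persons with any missing cell are dropped and the
#' count is reported via a message.
#'
#' @param path file path.
#' @param listwise drop persons with missing cells instead of erroring.
#' @return `read_response_matrix()` returns a [response_matrix()];
#'   `write_response_matrix()` returns `path` invisibly.
#' @export
read_response_matrix <- function(path, listwise = FALSE) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "person")
    stop_validation("response CSV must have a 'person' first column")
  persons <- as.character(df$person)
  if (anyDuplicated(persons)) stop_validation("duplicate person ids")
  if (anyDuplicated(names(df)[-1])) stop_validation("duplicate item ids")
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "numeric")
  bad <- !(is.na(m) | m == 0 | m == 1)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop_validation("non-binary cell at person ", persons[idx[1]],
                    ", item ", colnames(m)[idx[2]])
  }
  if (anyNA(m)) {
    if (!listwise)
      stop_validation("missing cells present; use listwise = TRUE to drop")
    keep <- complete.cases(m)
    message(sum(!keep), " person(s) dropped by listwise deletion")
    m <- m[keep, , drop = FALSE]
    persons <- persons[keep]
  }
  response_matrix(m, persons = persons, items = colnames(m))
}

#' @rdname read_response_matrix
#' @param responses a [response_matrix()] to write.
#' @export
write_response_matrix <- function(responses, path) {
  df <- data.frame(person = rownames(responses), unclass(responses)[, , drop = FALSE],
                   check.names = FALSE, row.names = NULL)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
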