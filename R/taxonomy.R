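#' Component taxonomy
#'
#' A taxonomy is the ordered set of item construction components that a
#' Q-matrix maps onto items.  Each component is either a *change rule*
#' (a transformation governing how figural elements change across the
#' cells of a matrix) or a *design principle* (a manipulation of the
#' visual presentation of the elements).  The component order is the
#' canonical column order of every Q-matrix built from the taxonomy.
#'
#' @param ids character vector of unique short component labels.
#' @param kinds character vector, one of `"change_rule"` or
#'   `"design_principle"` per id.
#' @return An object of class `component_taxonomy`: a data frame with
#'   columns `id` and `kind`.
#' @examples
#' component_taxonomy(c("A", "B"), c("change_rule", "design_principle"))
#' @export
component_taxonomy <- function(ids, kinds) {
  ids <- as.character(ids)
  kinds <- as.character(kinds)
  if (anyDuplicated(ids)) stop("component ids must be unique")
  if (length(kinds) != length(ids))
    stop("'kinds' must have one entry per component id")
  if (!all(kinds %in% c("change_rule", "design_principle")))
    stop("kinds must be 'change_rule' or 'design_principle'")
  structure(data.frame(id = ids, kind = kinds, stringsAsFactors = FALSE),
            class = c("component_taxonomy", "data.frame"))
}

#' Default nine-component taxonomy for difficult figural matrices
#'
#' Five change rules -- addition (ADD), addition with null element (ANE),
#' completeness (COM), cutting quantities (CQ), successive sequences (SS) --
#' and four design principles -- drawing principles (DP), variation of open
#' shapes (VOS), multiple relations (MR), direction of rule application
#' (DRA).
#'
#' @return A [component_taxonomy()] with nine components.
#' @export
default_taxonomy <- function() {
  component_taxonomy(
    ids = c("ADD", "ANE", "COM", "CQ", "SS", "DP", "VOS", "MR", "DRA"),
    kinds = c(rep("change_rule", 5), rep("design_principle", 4))
  )
}

#' @export
print.component_taxonomy <- function(x, ...) {
  cat("Component taxonomy (", nrow(x), " components)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
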