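# Relative archetype paths: XPath-like step sequences ("/data[at0001]/events")
# represented internally as character vectors of steps.  List-valued
# attributes are addressed collectively, so a path never carries an index.

#' Parse a rendered path into its steps
#'
#' A path is rendered as `"/step1/step2"`; the empty string is the empty
#' path, which is the identity of [path_concat()].  Each step is an attribute
#' name, optionally qualified with a node code suffix such as `[at0001]`.
#'
#' @param x A single path string.
#' @return A character vector of steps (zero length for the empty path).
#' @examples
#' path_parse("/data[at0001]/events")
#' @export
path_parse <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  if (x == "") return(character(0))
  if (!startsWith(x, "/")) {
    stop("invalid path: must start with '/' or be empty: ", sQuote(x))
  }
  steps <- strsplit(substring(x, 2L), "/", fixed = TRUE)[[1L]]
  if (any(steps == "")) stop("invalid path: empty step in ", sQuote(x))
  steps
}

#' Render path steps to a string
#'
#' Inverse of [path_parse()]: rendering then parsing round-trips exactly.
#'
#' @param steps Character vector of steps.
#' @return A single string, `""` for the empty path.
#' @export
path_render <- function(steps) {
  if (length(steps) == 0L) return("")
  paste0("/", paste(steps, collapse = "/"))
}

#' Concatenate paths
#'
#' Associative, with the empty path (`""`) as identity.
#'
#' @param ... Rendered path strings (each `""` or `"/step1/step2"` form).
#' @return A single rendered path string.
#' @export
path_concat <- function(...) {
  parts <- as.character(unlist(list(...), use.names = FALSE))
  paste(parts, collapse = "")
}
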