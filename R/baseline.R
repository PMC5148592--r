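# Baseline sequential scan.
#
# A deliberately independent implementation of the query semantics: it reads
# every record of a corpus exactly once, enumerates archetype occurrences by
# a recursive walk of the raw tree and checks the containment chain and the
# condition with its own code (no structure registry, no path lookup, no
# shared matcher with the driver).  It serves both as the O(records)
# reference the indexed engine is benchmarked against and as the oracle the
# engine's answers are verified with.

# -- independent tree primitives ---------------------------------------------

bs_kind <- function(x) {
  if (!is.list(x)) return("leaf")
  nm <- names(x)
  if (is.null(nm)) return("array")
  if (any(nm == "archetype_class")) return("archetype")
  "attribute"
}

bs_children <- function(x) {
  x[!(names(x) %in% c("archetype_class", "path_from_parent"))]
}

bs_class_match <- function(class, pattern) {
  if (identical(pattern, "*") || identical(class, pattern)) return(TRUE)
  if (regexpr("\\.v[0-9]+", pattern) == -1L) {
    # no version in the pattern: any version (and optional label) matches
    return(substring(class, 1L, nchar(pattern) + 2L) == paste0(pattern, ".v"))
  }
  FALSE
}

# Flat table of archetype occurrences: one entry per archetype node with its
# absolute attribute-step path from the root and the index of the closest
# enclosing archetype (0 for the root).
bs_archetype_table <- function(root) {
  entries <- list()
  walk <- function(node, steps, parent) {
    k <- bs_kind(node)
    if (k == "leaf") return(invisible())
    if (k == "array") {
      for (el in node) walk(el, steps, parent)
      return(invisible())
    }
    here <- parent
    if (k == "archetype") {
      entries[[length(entries) + 1L]] <<-
        list(class = node[["archetype_class"]], steps = steps,
             parent = parent, node = node)
      here <- length(entries)
    }
    kids <- bs_children(node)
    for (key in names(kids)) walk(kids[[key]], c(steps, key), here)
    invisible()
  }
  walk(root, character(0), 0L)
  entries
}

# All values reachable from a node along attribute steps, arrays fanned out.
bs_resolve <- function(node, steps) {
  if (length(steps) == 0L) return(list(node))
  if (!is.list(node)) return(list())
  if (is.null(names(node))) {
    out <- list()
    for (el in node) out <- c(out, bs_resolve(el, steps))
    return(out)
  }
  if (!(steps[[1L]] %in% names(node))) return(list())
  child <- node[[steps[[1L]]]]
  if (is.list(child) && is.null(names(child))) {
    out <- list()
    for (el in child) out <- c(out, bs_resolve(el, steps[-1L]))
    return(out)
  }
  bs_resolve(child, steps[-1L])
}

# -- independent condition evaluation -----------------------------------------

bs_literal_eq <- function(a, b) {
  (is.numeric(a) && is.numeric(b) && isTRUE(a == b)) ||
    (is.character(a) && is.character(b) && identical(a, b)) ||
    (is.logical(a) && is.logical(b) && identical(a, b))
}

bs_eval_pred <- function(p, vars, rec, ehr_var) {
  base <- if (identical(p$variable, ehr_var)) rec$root else vars[[p$variable]]
  if (is.null(base)) return(FALSE)
  vals <- bs_resolve(base, p$path)
  if (p$operator == "exists") return(length(vals) > 0L)
  for (v in vals) {
    if (is.list(v) || length(v) != 1L) next
    ok <- switch(p$operator,
                 "="  = bs_literal_eq(v, p$value),
                 "!=" = !bs_literal_eq(v, p$value),
                 matches = any(vapply(p$value, bs_literal_eq, logical(1),
                                      a = v)),
                 {
                   if (is.numeric(v) && is.numeric(p$value)) {
                     switch(p$operator,
                            ">" = v > p$value, ">=" = v >= p$value,
                            "<" = v < p$value, "<=" = v <= p$value, FALSE)
                   } else FALSE
                 })
    if (isTRUE(ok)) return(TRUE)
  }
  FALSE
}

bs_eval_cond <- function(cond, vars, rec, ehr_var) {
  if (is.null(cond)) return(TRUE)
  switch(cond$op,
         pred = bs_eval_pred(cond, vars, rec, ehr_var),
         not  = !bs_eval_cond(cond$arg, vars, rec, ehr_var),
         and  = all(vapply(cond$args, bs_eval_cond, logical(1),
                           vars = vars, rec = rec, ehr_var = ehr_var)),
         or   = any(vapply(cond$args, bs_eval_cond, logical(1),
                           vars = vars, rec = rec, ehr_var = ehr_var)),
         stop("unknown condition node"))
}

# -- record matching ----------------------------------------------------------

# Does the record match the query?  Returns the first satisfying binding
# (list of chain variable -> archetype node) or NULL.
bs_record_binding <- function(rec, qom) {
  chain <- qom$location$chain
  n <- length(chain)
  ehr_var <- qom$location$ehr_variable
  if (n == 0L) {
    if (bs_eval_cond(qom$condition, list(), rec, ehr_var)) {
      return(list(vars = list()))
    }
    return(NULL)
  }
  tab <- bs_archetype_table(rec$root)
  patterns <- vapply(chain, function(c) if (is.na(c$pattern)) "*" else
                     c$pattern, character(1))
  var_names <- vapply(chain, `[[`, character(1), "variable")
  for (e_i in seq_along(tab)) {
    if (!bs_class_match(tab[[e_i]]$class, patterns[n])) next
    # ancestor spine of archetype entries, root first, innermost last
    spine_idx <- integer(0)
    j <- e_i
    while (j != 0L) { spine_idx <- c(j, spine_idx); j <- tab[[j]]$parent }
    m <- length(spine_idx)
    if (m < n) next
    found <- NULL
    try_assign <- function(k, start, acc) {
      if (!is.null(found)) return(invisible())
      if (k == n) {
        vars <- stats::setNames(
          lapply(c(acc, m), function(i) tab[[spine_idx[i]]]$node),
          var_names)
        if (bs_eval_cond(qom$condition, vars, rec, ehr_var)) found <<- vars
        return(invisible())
      }
      i <- start
      while (i <= m - (n - k)) {
        if (bs_class_match(tab[[spine_idx[i]]]$class, patterns[k])) {
          try_assign(k + 1L, i + 1L, c(acc, i))
          if (!is.null(found)) return(invisible())
        }
        i <- i + 1L
      }
      invisible()
    }
    try_assign(1L, 1L, integer(0))
    if (!is.null(found)) return(list(vars = found))
  }
  NULL
}

#' Baseline sequential scan of a corpus
#'
#' Evaluates a query by examining every record exactly once with an
#' implementation independent of the structure registry and the driver's
#' matcher.
#'
#' @param query AQL text or a parsed `aql_query`.
#' @param corpus A file path to a JSON-lines corpus, a character vector of
#'   JSON lines, or a list of `ehr_record` objects.
#' @param mode `"count"` or `"fetch"`.
#' @return For `"count"` the number of matching records with attributes
#'   `record_ids`, `n_examined` and `n_malformed`; for `"fetch"` an
#'   `aql_result_set` with the same attributes.
#' @export
baseline_scan <- function(query, corpus, mode = c("count", "fetch")) {
  mode <- match.arg(mode)
  qom <- if (inherits(query, "aql_query")) query else parse_aql(query)
  lines <- if (is.character(corpus) && length(corpus) == 1L &&
               file.exists(corpus)) {
    readLines(corpus, warn = FALSE, encoding = "UTF-8")
  } else corpus
  matched <- character(0)
  bindings <- list(); records <- list()
  examined <- 0L; malformed <- 0L
  for (ln in lines) {
    rec <- if (inherits(ln, "ehr_record")) ln else {
      tryCatch(read_record(ln), error = function(e) NULL)
    }
    if (is.null(rec)) { malformed <- malformed + 1L; next }
    examined <- examined + 1L
    if (!rec$active) next
    b <- bs_record_binding(rec, qom)
    if (!is.null(b)) {
      matched <- c(matched, rec$record_id)
      if (mode == "fetch") {
        bindings[[rec$record_id]] <- b
        records[[rec$record_id]] <- rec
      }
    }
  }
  if (malformed > 0L) {
    warning(malformed, " malformed line(s) skipped during baseline scan")
  }
  matched <- sort(unique(matched), method = "radix")
  out <- if (mode == "count") length(matched) else {
    build_result_set(qom, matched, records, bindings)
  }
  structure(out, record_ids = matched, n_examined = examined,
            n_malformed = malformed)
}

#' Absolute paths of innermost chain matches in one tree (reference version)
#'
#' Recursive reference implementation of containment resolution used to
#' cross-check the registry lookup: returns the rendered absolute paths of
#' all archetype occurrences that terminate the pattern chain.
#'
#' @param root An archetype node (record root or structure root).
#' @param patterns Character vector of class patterns (`"*"` = wildcard).
#' @return Sorted unique character vector of rendered paths.
#' @export
baseline_chain_paths <- function(root, patterns) {
  n <- length(patterns)
  tab <- bs_archetype_table(root)
  hits <- character(0)
  for (e_i in seq_along(tab)) {
    if (n > 0L && !bs_class_match(tab[[e_i]]$class, patterns[n])) next
    spine_idx <- integer(0)
    j <- e_i
    while (j != 0L) { spine_idx <- c(j, spine_idx); j <- tab[[j]]$parent }
    m <- length(spine_idx)
    if (m < n) next
    ok <- if (n <= 1L) TRUE else {
      # can patterns 1..n-1 be placed increasingly on the proper ancestors?
      can <- function(k, start) {
        if (k == n) return(TRUE)
        for (i in start:(m - (n - k))) {
          if (bs_class_match(tab[[spine_idx[i]]]$class, patterns[k]) &&
              can(k + 1L, i + 1L)) return(TRUE)
        }
        FALSE
      }
      can(1L, 1L)
    }
    if (ok) hits <- c(hits, path_render(tab[[e_i]]$steps))
  }
  sort(unique(hits), method = "radix")
}

#' Compare engine and baseline answers for one query
#'
#' @param sys An [ehr_system()] already holding the corpus.
#' @param query AQL text or `aql_query`.
#' @param corpus The same corpus as JSON lines or a file path.
#' @return List with `equal`, `count_engine`, `count_baseline`,
#'   `only_engine`, `only_baseline` (record-id set differences).
#' @export
compare_with_baseline <- function(sys, query, corpus) {
  qom <- if (inherits(query, "aql_query")) query else parse_aql(query)
  eng <- run_query(sys, qom, mode = "fetch")
  ids_e <- result_record_ids(eng)
  base <- baseline_scan(qom, corpus, mode = "count")
  ids_b <- attr(base, "record_ids")
  list(equal = identical(ids_e, ids_b),
       count_engine = eng$count,
       count_baseline = as.integer(base),
       only_engine = setdiff(ids_e, ids_b),
       only_baseline = setdiff(ids_b, ids_e))
}
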