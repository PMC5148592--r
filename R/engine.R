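# Query engine: orchestrates parse -> index lookup -> driver execution.
# The index lookup phase touches only the structure registry; the driver
# then examines only records whose structure id appears in the matches.

#' Create a data-access system
#'
#' Wires a driver session (via the factory) to a fresh structure registry.
#'
#' @param config A [driver_config()].
#' @return An `ehr_system` object with elements `session`, `index`, `config`.
#' @export
ehr_system <- function(config = driver_config()) {
  structure(list(session = connect_driver(config),
                 index = structure_index(),
                 config = config),
            class = "ehr_system")
}

#' @export
print.ehr_system <- function(x, ...) {
  cat(sprintf("<ehr_system driver=%s> %d structures, %d records\n",
              x$config$driver, structure_count(x$index), store_size(x$session)))
  invisible(x)
}

#' Ingest one record
#'
#' Extracts and registers the record's structure, stamps the returned
#' structure id on the record and stores it.
#'
#' @param sys An [ehr_system()].
#' @param record An `ehr_record`.
#' @param line Optional pre-serialized JSON for the record (avoids one
#'   serialization; the stored structure id is kept in the envelope).
#' @return The structure id, invisibly.
#' @export
ingest_record <- function(sys, record, line = NULL) {
  desc <- extract_structure(record)
  sid <- register_structure(sys$index, desc)
  index_count_record(sys$index, sid)
  if (is.null(line)) {
    record$structure_id <- sid
    line <- write_record(record)
  }
  put_encoded(sys$session, record$record_id, sid, line)
  invisible(sid)
}

#' Ingest a JSON-lines corpus
#'
#' @param sys An [ehr_system()].
#' @param corpus A file path or a character vector of JSON lines.
#' @return An ingest report: list with `records_stored`,
#'   `structures_registered` (registry size after the ingest), `failures`
#'   (number of lines that could not be parsed; each is logged as a
#'   warning summary).
#' @export
ingest_corpus <- function(sys, corpus) {
  lines <- if (length(corpus) == 1L && file.exists(corpus)) {
    readLines(corpus, warn = FALSE, encoding = "UTF-8")
  } else corpus
  stored <- 0L; failures <- 0L
  for (ln in lines) {
    ok <- tryCatch({
      ingest_record(sys, read_record(ln), line = ln)
      TRUE
    }, error = function(e) FALSE)
    if (ok) stored <- stored + 1L else failures <- failures + 1L
  }
  if (failures > 0L) {
    warning(failures, " record(s) failed to ingest and were skipped")
  }
  list(records_stored = stored,
       structures_registered = structure_count(sys$index),
       failures = failures)
}

#' Run an AQL query
#'
#' Pipeline: parse, extract the containment chain, resolve it against the
#' structure registry, then hand the (structure id, path) matches to the
#' driver.  In `"auto"` mode the rows are fetched when the count is at or
#' below the configured fetch threshold, otherwise only counted.
#'
#' @param sys An [ehr_system()].
#' @param query AQL text or a pre-parsed `aql_query`.
#' @param mode `"auto"`, `"count"` or `"fetch"`.
#' @return An `ehr_query_result`: list with `count`, `result` (an
#'   `aql_result_set` or `NULL` when not fetched), `fetched`, `timings`
#'   (seconds per phase: index, count, fetch) and `n_structures`.
#' @export
run_query <- function(sys, query, mode = c("auto", "count", "fetch")) {
  mode <- match.arg(mode)
  qom <- if (inherits(query, "aql_query")) query else parse_aql(query)

  t0 <- proc.time()[["elapsed"]]
  chain <- location_of(qom)
  if (length(chain$patterns) == 0L) {
    warning("query has no containment chain; falling back to all registered structures")
    ids <- sort(ls(sys$index$structures), method = "radix")
    matches <- lapply(ids, function(id) list(structure_id = id, paths = ""))
  } else {
    matches <- lookup_containment(sys$index, chain)
  }
  t_index <- proc.time()[["elapsed"]] - t0

  t0 <- proc.time()[["elapsed"]]
  count <- execute_query(sys$session, qom, matches, mode = "count")
  t_count <- proc.time()[["elapsed"]] - t0

  result <- NULL; t_fetch <- NA_real_
  do_fetch <- switch(mode,
                     count = FALSE,
                     fetch = TRUE,
                     auto = count <= sys$config$fetch_threshold)
  if (do_fetch) {
    t0 <- proc.time()[["elapsed"]]
    result <- execute_query(sys$session, qom, matches, mode = "fetch")
    t_fetch <- proc.time()[["elapsed"]] - t0
  }
  structure(list(count = count, result = result, fetched = do_fetch,
                 timings = c(index = t_index, count = t_count,
                             fetch = t_fetch),
                 n_structures = length(matches)),
            class = "ehr_query_result")
}

#' @export
print.ehr_query_result <- function(x, ...) {
  cat(sprintf("<ehr_query_result> count=%d fetched=%s structures=%d\n",
              x$count, x$fetched, x$n_structures))
  if (!is.null(x$result)) print(x$result)
  invisible(x)
}

#' Matched record ids of a query result
#' @param x An `ehr_query_result` run in fetch mode.
#' @return Character vector of record ids.
#' @export
result_record_ids <- function(x) {
  if (is.null(x$result)) stop("record ids are only available after a fetch")
  attr(x$result, "record_ids")
}

#' Explain a query without touching the record store
#'
#' @param sys An [ehr_system()].
#' @param query AQL text or `aql_query`.
#' @return List with `patterns`, `n_structures` (matching the chain),
#'   `paths_per_structure` (named integer vector) and `total_paths`.
#' @export
explain_query <- function(sys, query) {
  qom <- if (inherits(query, "aql_query")) query else parse_aql(query)
  chain <- location_of(qom)
  if (length(chain$patterns) == 0L) {
    n <- structure_count(sys$index)
    return(list(patterns = character(0), n_structures = n,
                paths_per_structure = stats::setNames(integer(0), character(0)),
                total_paths = n))
  }
  matches <- lookup_containment(sys$index, chain)
  pps <- vapply(matches, function(m) length(m$paths), integer(1))
  names(pps) <- vapply(matches, `[[`, character(1), "structure_id")
  list(patterns = chain$patterns, n_structures = length(matches),
       paths_per_structure = pps, total_paths = sum(pps))
}
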