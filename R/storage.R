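# Storage driver abstraction.
#
# A driver is obtained from the factory by name and must implement the
# contract below (connection management, CRUD with versioning, query
# execution against (structure id, path) matches, encode/decode with
# reversible escaping of reserved characters, containers and record
# split/join).  Adding a back-end requires only a factory registration plus
# an implementation of these generics; `driver_conformance()` is the
# abstract test suite any driver must pass.

driver_registry <- new.env(parent = emptyenv())

#' Register a storage driver constructor
#'
#' @param name Driver name used in [driver_config()].
#' @param constructor Function `(config) -> session`.
#' @export
register_driver <- function(name, constructor) {
  stopifnot(is.character(name), length(name) == 1L, is.function(constructor))
  assign(name, constructor, envir = driver_registry)
  invisible(name)
}

#' List registered driver names
#' @return Character vector.
#' @export
list_drivers <- function() {
  sort(ls(driver_registry), method = "radix")
}

#' Driver configuration
#'
#' @param driver Driver name (`"memory"` is the embedded reference driver;
#'   `"mongodb"` and `"elasticsearch"` are reserved factory slots).
#' @param fetch_threshold Result-count bound at or below which matching
#'   records are fetched in full rather than only counted (inclusive).
#' @param persistence_path Optional file for the reference driver's
#'   JSON-lines snapshot; loaded on connect when present.
#' @param ... Further connection parameters kept as a string map.
#' @return A `driver_config` object.
#' @export
driver_config <- function(driver = "memory", fetch_threshold = 10000L,
                          persistence_path = NULL, ...) {
  fetch_threshold <- as.integer(fetch_threshold)
  stopifnot(fetch_threshold >= 0L)
  structure(list(driver = driver, fetch_threshold = fetch_threshold,
                 persistence_path = persistence_path, params = list(...)),
            class = "driver_config")
}

#' Open a session through the driver factory
#' @param config A [driver_config()].
#' @return A driver session object (class `ehr_session`).
#' @export
connect_driver <- function(config) {
  stopifnot(inherits(config, "driver_config"))
  if (!exists(config$driver, envir = driver_registry, inherits = FALSE)) {
    stop("connection error: unknown driver ", sQuote(config$driver))
  }
  ctor <- get(config$driver, envir = driver_registry)
  ctor(config)
}

# -- generics (the driver contract) ------------------------------------------

#' @rdname driver-contract
#' @param session A driver session.
#' @export
db_disconnect <- function(session) UseMethod("db_disconnect")

#' @rdname driver-contract
#' @export
is_connected <- function(session) UseMethod("is_connected")

#' Driver contract operations
#'
#' CRUD semantics: `put_record` requires an unused record id; `get_record`
#' returns the latest version; `update_record` creates version n+1 keeping
#' history; `rollback_record` discards the latest version restoring the
#' previous one; `delete_record` hides the record from queries (history is
#' kept).  Exactly the latest active version of each record is queryable.
#'
#' @param session A driver session.
#' @param record An `ehr_record`.
#' @param record_id Record identifier.
#' @param new_root Replacement root node for an update.
#' @name driver-contract
#' @export
put_record <- function(session, record) UseMethod("put_record")

#' @rdname driver-contract
#' @export
get_record <- function(session, record_id) UseMethod("get_record")

#' @rdname driver-contract
#' @export
update_record <- function(session, record_id, new_root) {
  UseMethod("update_record")
}

#' @rdname driver-contract
#' @export
delete_record <- function(session, record_id) UseMethod("delete_record")

#' @rdname driver-contract
#' @export
rollback_record <- function(session, record_id) UseMethod("rollback_record")

#' @rdname driver-contract
#' @param record_id Record identifier.
#' @export
record_versions <- function(session, record_id) UseMethod("record_versions")

#' Execute the data phase of a query
#'
#' Only records whose structure identifier appears in `matches` are
#' examined; the condition is evaluated along the supplied paths only.
#' Unknown structure identifiers in `matches` are tolerated (stale index)
#' and ignored.
#'
#' @param session A driver session.
#' @param qom An `aql_query`.
#' @param matches Output of [lookup_containment()] for [location_of()] of
#'   `qom`.
#' @param mode `"count"` for the number of distinct matching records,
#'   `"fetch"` for a full result set.
#' @return A count, or an `aql_result_set` with fields `columns`, `rows`
#'   and `total_count` (and the matched record ids as attribute
#'   `record_ids`).
#' @export
execute_query <- function(session, qom, matches, mode = c("count", "fetch")) {
  UseMethod("execute_query")
}

#' @rdname driver-contract
#' @export
encode_record <- function(session, record) UseMethod("encode_record")

#' @rdname driver-contract
#' @param document A store document produced by `encode_record`.
#' @export
decode_record <- function(session, document) UseMethod("decode_record")

#' @rdname driver-contract
#' @param name Container name.
#' @export
create_container <- function(session, name) UseMethod("create_container")

#' @rdname driver-contract
#' @export
list_containers <- function(session) UseMethod("list_containers")

#' @rdname driver-contract
#' @export
split_record <- function(session, record) UseMethod("split_record")

#' @rdname driver-contract
#' @param parts Output of `split_record`.
#' @export
join_record <- function(session, parts) UseMethod("join_record")

# -- key escaping -------------------------------------------------------------

# Reversible escaping of characters that document stores commonly reserve in
# field names ('.', '$'); '%' escapes itself so decoding is unambiguous.
escape_key <- function(k) {
  k <- gsub("%", "%25", k, fixed = TRUE)
  k <- gsub(".", "%2E", k, fixed = TRUE)
  gsub("$", "%24", k, fixed = TRUE)
}

unescape_key <- function(k) {
  k <- gsub("%24", "$", k, fixed = TRUE)
  k <- gsub("%2E", ".", k, fixed = TRUE)
  gsub("%25", "%", k, fixed = TRUE)
}

map_tree_keys <- function(x, f) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm)) {
    keep <- nm %in% RESERVED_NODE_KEYS
    nm[!keep] <- vapply(nm[!keep], f, character(1), USE.NAMES = FALSE)
    names(x) <- nm
  }
  for (i in seq_along(x)) x[[i]] <- map_tree_keys(x[[i]], f)
  x
}

# -- abstract conformance suite ----------------------------------------------

#' Driver conformance suite
#'
#' Runs the contract checks every storage driver must pass against a fresh
#' session opened from `config`.  Returns a data frame with one row per
#' check; the `passed` column must be all `TRUE` for a conforming driver.
#'
#' @param config A [driver_config()] for the driver under test.
#' @return A data frame with columns `check`, `passed`, `detail`.
#' @export
driver_conformance <- function(config) {
  results <- list()
  note <- function(check, expr) {
    out <- tryCatch(list(ok = isTRUE(expr()), detail = ""),
                    error = function(e) list(ok = FALSE,
                                             detail = conditionMessage(e)))
    results[[length(results) + 1L]] <<-
      data.frame(check = check, passed = out$ok, detail = out$detail,
                 stringsAsFactors = FALSE)
  }
  mk <- function(id) {
    new_record(list(archetype_class = "openEHR-EHR-OBSERVATION.probe.v1",
                    data = list(value = 1)), record_id = id,
               structure_id = "conformance-s1")
  }

  s <- connect_driver(config)
  note("connect yields live session", function() is_connected(s))
  note("put/get round trip", function() {
    put_record(s, mk("c1"))
    identical(get_record(s, "c1")$root, mk("c1")$root)
  })
  note("duplicate put is an error", function() {
    inherits(tryCatch(put_record(s, mk("c1")), error = identity),
             "duplicate_record_error")
  })
  note("missing get is an error", function() {
    inherits(tryCatch(get_record(s, "nope"), error = identity),
             "missing_record_error")
  })
  note("update increments version and keeps history", function() {
    r2root <- list(archetype_class = "openEHR-EHR-OBSERVATION.probe.v1",
                   data = list(value = 2))
    update_record(s, "c1", r2root)
    g <- get_record(s, "c1")
    g$version == 2L && length(record_versions(s, "c1")$versions) == 2L
  })
  note("rollback restores the prior root", function() {
    rollback_record(s, "c1")
    g <- get_record(s, "c1")
    g$version == 1L && identical(g$root, mk("c1")$root)
  })
  note("delete hides from queries", function() {
    put_record(s, mk("c2"))
    delete_record(s, "c2")
    qom <- parse_aql("SELECT o FROM EHR e CONTAINS OBSERVATION o [openEHR-EHR-OBSERVATION.probe.v1]")
    m <- list(list(structure_id = "conformance-s1", paths = ""))
    cnt <- execute_query(s, qom, m, mode = "count")
    cnt == 1L
  })
  note("encode/decode round trip with reserved characters", function() {
    r <- new_record(list(archetype_class = "openEHR-EHR-OBSERVATION.probe.v1",
                         "a.b$c" = list("x.y" = "v")),
                    record_id = "esc1")
    doc <- encode_record(s, r)
    identical(decode_record(s, doc), r)
  })
  note("container create then list", function() {
    create_container(s, "ns1")
    "ns1" %in% list_containers(s)
  })
  note("duplicate container is an error", function() {
    inherits(tryCatch(create_container(s, "ns1"), error = identity), "error")
  })
  note("join(split(r)) identity", function() {
    r <- mk("c3")
    identical(join_record(s, split_record(s, r)), r)
  })
  note("empty matches count is zero", function() {
    qom <- parse_aql("SELECT o FROM EHR e CONTAINS OBSERVATION o [openEHR-EHR-OBSERVATION.none.v1]")
    execute_query(s, qom, list(), mode = "count") == 0L
  })
  note("disconnect is idempotent and blocks operations", function() {
    db_disconnect(s)
    db_disconnect(s)
    err <- tryCatch(get_record(s, "c1"), error = identity)
    !is_connected(s) && inherits(err, "error")
  })

  do.call(rbind, results)
}
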