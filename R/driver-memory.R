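# Embedded reference driver: an in-process document store holding each
# record version as its JSON serialization, with a secondary index from
# structure id to record ids (the driver-level mechanism that lets a query
# skip every record whose structure cannot match) and optional JSON-lines
# snapshot persistence.

memory_driver <- function(config) {
  st <- new.env(parent = emptyenv())
  st$records <- new.env(parent = emptyenv())     # id -> envelope
  st$by_structure <- new.env(parent = emptyenv())# structure_id -> id vector
  st$containers <- character(0)
  st$connected <- TRUE
  st$stale_lookups <- 0L
  session <- structure(list(state = st, config = config),
                       class = c("memory_session", "ehr_session"))
  p <- config$persistence_path
  if (!is.null(p) && file.exists(p)) load_snapshot(session, p)
  session
}

check_live <- function(session) {
  if (!isTRUE(session$state$connected)) {
    stop("session error: driver session is disconnected")
  }
  invisible(TRUE)
}

#' @export
is_connected.memory_session <- function(session) {
  isTRUE(session$state$connected)
}

#' @export
db_disconnect.memory_session <- function(session) {
  session$state$connected <- FALSE   # idempotent
  invisible(NULL)
}

structure_index_add <- function(st, sid, id) {
  if (is.na(sid)) return(invisible())
  cur <- if (exists(sid, envir = st$by_structure, inherits = FALSE)) {
    get(sid, envir = st$by_structure)
  } else character(0)
  assign(sid, c(cur, id), envir = st$by_structure)
}

# Envelope: versions (list of JSON strings, contiguous from 1),
# structure_id, deleted flag.
put_encoded <- function(session, record_id, structure_id, json) {
  check_live(session)
  st <- session$state
  if (exists(record_id, envir = st$records, inherits = FALSE)) {
    stop(structure(class = c("duplicate_record_error", "error", "condition"),
                   list(message = paste0("duplicate record id ",
                                         sQuote(record_id)),
                        call = NULL)))
  }
  assign(record_id,
         list(versions = list(json), structure_id = structure_id,
              deleted = FALSE),
         envir = st$records)
  structure_index_add(st, structure_id, record_id)
  invisible(record_id)
}

#' @export
put_record.memory_session <- function(session, record) {
  stopifnot(inherits(record, "ehr_record"))
  put_encoded(session, record$record_id, record$structure_id,
              write_record(record))
}

get_envelope <- function(session, record_id) {
  st <- session$state
  if (!exists(record_id, envir = st$records, inherits = FALSE)) {
    stop(structure(class = c("missing_record_error", "error", "condition"),
                   list(message = paste0("no such record ", sQuote(record_id)),
                        call = NULL)))
  }
  get(record_id, envir = st$records)
}

decode_envelope_version <- function(env, v) {
  rec <- read_record(env$versions[[v]])
  rec$structure_id <- env$structure_id
  rec
}

#' @export
get_record.memory_session <- function(session, record_id) {
  check_live(session)
  env <- get_envelope(session, record_id)
  decode_envelope_version(env, length(env$versions))
}

#' @export
update_record.memory_session <- function(session, record_id, new_root) {
  check_live(session)
  st <- session$state
  env <- get_envelope(session, record_id)
  latest <- decode_envelope_version(env, length(env$versions))
  latest$root <- new_root
  latest$version <- latest$version + 1L
  env$versions[[length(env$versions) + 1L]] <- write_record(latest)
  assign(record_id, env, envir = st$records)
  invisible(latest$version)
}

#' @export
rollback_record.memory_session <- function(session, record_id) {
  check_live(session)
  st <- session$state
  env <- get_envelope(session, record_id)
  if (length(env$versions) < 2L) {
    stop("version error: record ", sQuote(record_id),
         " has no previous version")
  }
  env$versions[[length(env$versions)]] <- NULL
  assign(record_id, env, envir = st$records)
  invisible(length(env$versions))
}

#' @export
delete_record.memory_session <- function(session, record_id) {
  check_live(session)
  st <- session$state
  env <- get_envelope(session, record_id)
  env$deleted <- TRUE
  assign(record_id, env, envir = st$records)
  invisible(record_id)
}

#' @export
record_versions.memory_session <- function(session, record_id) {
  check_live(session)
  env <- get_envelope(session, record_id)
  list(record_id = record_id, latest = length(env$versions),
       deleted = env$deleted,
       versions = lapply(seq_along(env$versions),
                         function(v) decode_envelope_version(env, v)))
}

#' @export
encode_record.memory_session <- function(session, record) {
  r <- record
  r$root <- map_tree_keys(r$root, escape_key)
  write_record(r)
}

#' @export
decode_record.memory_session <- function(session, document) {
  rec <- tryCatch(read_record(document), error = function(e) {
    stop("corruption error: ", conditionMessage(e))
  })
  rec$root <- map_tree_keys(rec$root, unescape_key)
  rec
}

#' @export
create_container.memory_session <- function(session, name) {
  check_live(session)
  st <- session$state
  if (name %in% st$containers) stop("container ", sQuote(name),
                                    " already exists")
  st$containers <- c(st$containers, name)
  invisible(name)
}

#' @export
list_containers.memory_session <- function(session) {
  session$state$containers
}

#' @export
split_record.memory_session <- function(session, record) {
  list(parts = list(record))   # the reference store keeps records whole
}

#' @export
join_record.memory_session <- function(session, parts) {
  parts$parts[[1L]]
}

#' Number of stored records (including deleted/inactive)
#' @param session A driver session.
#' @return Integer.
#' @export
store_size <- function(session) {
  length(ls(session$state$records))
}

# -- snapshot persistence -----------------------------------------------------

#' Write a JSON-lines snapshot of the store
#' @param session A memory-driver session.
#' @param path Output file (defaults to the configured persistence path).
#' @return The path, invisibly.
#' @export
save_snapshot <- function(session, path = session$config$persistence_path) {
  check_live(session)
  stopifnot(!is.null(path))
  st <- session$state
  ids <- sort(ls(st$records), method = "radix")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (id in ids) {
    env <- get(id, envir = st$records)
    writeLines(as.character(jsonlite::toJSON(
      list(record_id = jsonlite::unbox(id),
           structure_id = jsonlite::unbox(env$structure_id),
           deleted = jsonlite::unbox(env$deleted),
           versions = lapply(env$versions, jsonlite::unbox)),
      auto_unbox = FALSE)), con)
  }
  invisible(path)
}

load_snapshot <- function(session, path) {
  st <- session$state
  for (ln in readLines(path, warn = FALSE, encoding = "UTF-8")) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    assign(obj$record_id,
           list(versions = lapply(obj$versions, identity),
                structure_id = obj$structure_id, deleted = isTRUE(obj$deleted)),
           envir = st$records)
    if (!isTRUE(obj$deleted)) {
      structure_index_add(st, obj$structure_id, obj$record_id)
    }
  }
  invisible(session)
}

# -- query execution ----------------------------------------------------------

#' @export
execute_query.memory_session <- function(session, qom, matches,
                                         mode = c("count", "fetch")) {
  check_live(session)
  mode <- match.arg(mode)
  st <- session$state
  by_sid <- list()
  stale <- 0L
  for (m in matches) {
    sid <- m$structure_id
    if (exists(sid, envir = st$by_structure, inherits = FALSE)) {
      by_sid[[sid]] <- m$paths
    } else {
      stale <- stale + 1L   # stale index entry: tolerated
    }
  }
  st$stale_lookups <- st$stale_lookups + stale

  matched_ids <- character(0)
  bindings <- list()     # first satisfying binding per matched record
  records <- list()
  for (sid in names(by_sid)) {
    ids <- get(sid, envir = st$by_structure)
    for (id in ids) {
      env <- get(id, envir = st$records)
      if (env$deleted) next
      rec <- decode_envelope_version(env, length(env$versions))
      if (!rec$active) next
      b <- first_satisfying_binding(rec, qom, by_sid[[sid]])
      if (!is.null(b)) {
        matched_ids <- c(matched_ids, id)
        if (mode == "fetch") {
          bindings[[id]] <- b
          records[[id]] <- rec
        }
      }
    }
  }
  matched_ids <- sort(unique(matched_ids), method = "radix")
  if (mode == "count") return(length(matched_ids))
  build_result_set(qom, matched_ids, records, bindings)
}

# Resolve a rendered absolute path against a record root, keeping the spine
# of archetype nodes (root archetype through the reached node) per hit.
resolve_with_spine <- function(node, path, spine = list()) {
  kind <- node_kind(node)
  if (kind == "archetype") spine <- c(spine, list(node))
  if (length(path) == 0L) return(list(list(node = node, spine = spine)))
  if (kind == "array") {
    out <- list()
    for (el in node) out <- c(out, resolve_with_spine(el, path, spine))
    return(out)
  }
  if (kind == "leaf") return(list())
  kids <- node_attributes(node)
  step <- path[[1L]]
  if (!(step %in% names(kids))) return(list())
  spine_descend(kids[[step]], path[-1L], spine)
}

spine_descend <- function(v, rest, spine) {
  if (node_kind(v) == "array") {
    out <- list()
    for (el in v) out <- c(out, spine_descend(el, rest, spine))
    return(out)
  }
  resolve_with_spine(v, rest, spine)
}

# Enumerate all increasing assignments of the first n-1 chain patterns onto
# the spine (the last pattern is bound to the innermost node itself) and
# return the first assignment under which the condition holds, or NULL.
first_satisfying_binding <- function(rec, qom, paths) {
  chain <- qom$location$chain
  n <- length(chain)
  patterns <- vapply(chain, function(c) if (is.na(c$pattern)) "*" else
                     c$pattern, character(1))
  for (p in sort(paths, method = "radix")) {
    hits <- resolve_with_spine(rec$root, path_parse(p))
    for (h in hits) {
      if (node_kind(h$node) != "archetype") next
      if (n > 0L && !class_matches(archetype_class(h$node), patterns[n])) next
      spine <- h$spine
      m <- length(spine)
      assigns <- enumerate_assignments(spine, patterns, m)
      for (a in assigns) {
        vars <- stats::setNames(lapply(a, function(i) spine[[i]]),
                                vapply(chain, `[[`, character(1), "variable"))
        if (eval_condition(qom$condition, vars, rec, qom$location$ehr_variable)) {
          return(list(path = p, node = h$node, vars = vars))
        }
      }
      if (n == 0L) {
        # no containment chain: the record itself is the binding
        if (eval_condition(qom$condition, list(), rec,
                           qom$location$ehr_variable)) {
          return(list(path = p, node = h$node, vars = list()))
        }
      }
    }
  }
  NULL
}

# All increasing index vectors idx[1] < ... < idx[n] into the spine with
# class matches, idx[n] fixed to the innermost position.
enumerate_assignments <- function(spine, patterns, m) {
  n <- length(patterns)
  if (n == 0L) return(list())
  if (!class_matches(archetype_class(spine[[m]]), patterns[n])) return(list())
  if (n == 1L) return(list(m))
  out <- list()
  recurse <- function(k, start, acc) {
    if (k == n) { out[[length(out) + 1L]] <<- c(acc, m); return(invisible()) }
    if (start > m - (n - k)) return(invisible())
    for (i in start:(m - (n - k))) {
      if (class_matches(archetype_class(spine[[i]]), patterns[k])) {
        recurse(k + 1L, i + 1L, c(acc, i))
      }
    }
  }
  recurse(1L, 1L, integer(0))
  out
}

# Predicate and boolean evaluation; a missing value makes a predicate false.
eval_condition <- function(cond, vars, rec, ehr_var) {
  if (is.null(cond)) return(TRUE)
  if (cond$op == "pred") return(eval_predicate(cond, vars, rec, ehr_var))
  if (cond$op == "not") return(!eval_condition(cond$arg, vars, rec, ehr_var))
  if (cond$op == "and") {
    for (a in cond$args) {
      if (!eval_condition(a, vars, rec, ehr_var)) return(FALSE)
    }
    return(TRUE)
  }
  for (a in cond$args) {
    if (eval_condition(a, vars, rec, ehr_var)) return(TRUE)
  }
  FALSE
}

predicate_values <- function(cond, vars, rec, ehr_var) {
  base <- if (identical(cond$variable, ehr_var)) rec$root
          else vars[[cond$variable]]
  if (is.null(base)) return(list())
  resolve_path(base, cond$path)
}

eval_predicate <- function(cond, vars, rec, ehr_var) {
  vals <- predicate_values(cond, vars, rec, ehr_var)
  if (cond$operator == "exists") return(length(vals) > 0L)
  for (v in vals) {
    if (node_kind(v) != "leaf") next
    if (compare_scalar(v, cond$operator, cond$value)) return(TRUE)
  }
  FALSE
}

compare_scalar <- function(v, op, lit) {
  if (op == "matches") {
    for (l in lit) if (scalar_equal(v, l)) return(TRUE)
    return(FALSE)
  }
  if (op == "=") return(scalar_equal(v, lit))
  if (op == "!=") return(!scalar_equal(v, lit))
  if (!is.numeric(v) || !is.numeric(lit)) return(FALSE)
  switch(op,
         ">" = v > lit, ">=" = v >= lit, "<" = v < lit, "<=" = v <= lit,
         FALSE)
}

scalar_equal <- function(a, b) {
  if (is.numeric(a) && is.numeric(b)) return(isTRUE(a == b))
  if (is.character(a) && is.character(b)) return(identical(a, b))
  if (is.logical(a) && is.logical(b)) return(identical(a, b))
  FALSE
}

# -- result sets --------------------------------------------------------------

result_column_names <- function(qom) {
  vapply(qom$selection$items, function(it) {
    if (!is.na(it$alias)) it$alias else paste0(it$variable,
                                               path_render(it$path))
  }, character(1))
}

project_cell <- function(it, binding, rec, ehr_var) {
  if (identical(it$variable, ehr_var)) {
    if (length(it$path) == 0L) return(rec$ehr_id)
    base <- rec$root
  } else {
    base <- binding$vars[[it$variable]]
    if (is.null(base)) return(NA)
  }
  vals <- resolve_path(base, it$path)
  for (v in vals) if (node_kind(v) == "leaf") return(v)
  NA
}

build_result_set <- function(qom, matched_ids, records, bindings) {
  cols <- result_column_names(qom)
  cells <- lapply(matched_ids, function(id) {
    lapply(qom$selection$items, project_cell,
           binding = bindings[[id]], rec = records[[id]],
           ehr_var = qom$location$ehr_variable)
  })
  rows <- as.data.frame(
    stats::setNames(lapply(seq_along(cols), function(j) {
      col <- lapply(cells, `[[`, j)
      if (all(vapply(col, function(x) is.numeric(x) || all(is.na(x)),
                     logical(1)))) {
        vapply(col, function(x) if (all(is.na(x))) NA_real_ else as.double(x),
               double(1))
      } else {
        vapply(col, function(x) if (all(is.na(x))) NA_character_
               else as.character(x), character(1))
      }
    }), cols),
    optional = TRUE, stringsAsFactors = FALSE)
  structure(list(columns = cols, rows = rows,
                 total_count = length(matched_ids)),
            class = "aql_result_set", record_ids = matched_ids)
}

#' @export
print.aql_result_set <- function(x, ...) {
  cat(sprintf("<aql_result_set> %d row(s), columns: %s\n", x$total_count,
              paste(x$columns, collapse = ", ")))
  if (nrow(x$rows)) print(utils::head(x$rows, 10L))
  invisible(x)
}

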