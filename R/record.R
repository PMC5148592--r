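# Document-tree record model.
#
# A record is a finite tree whose nodes are archetype instances, attribute
# maps, arrays and scalar leaves.  Internally the tree keeps the shape of its
# JSON serialisation:
#   * archetype node  -- named list carrying the reserved key
#                        "archetype_class" (and, on disk, "path_from_parent");
#                        every other key is an attribute
#   * attribute map   -- named list without "archetype_class"
#   * array           -- unnamed list; a list-valued attribute
#   * leaf            -- length-one atomic value (string, number, boolean or
#                        ISO-8601 timestamp string)

RESERVED_RECORD_KEYS <- c("record_id", "ehr_id", "version", "active",
                          "created_at", "updated_at", "structure_id")
RESERVED_NODE_KEYS <- c("archetype_class", "path_from_parent")

ARCHETYPE_CLASS_RE <-
  "^openEHR-EHR-[A-Z][A-Z_]*\\.[A-Za-z0-9_]+(\\.v[0-9]+)?(\\.lbl-[0-9]+)?$"

#' Kind of a document-tree node
#'
#' @param x A node of a record tree.
#' @return One of `"archetype"`, `"attribute"`, `"array"`, `"leaf"`.
#' @export
node_kind <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (is.null(nm)) return("array")
    if ("archetype_class" %in% nm) return("archetype")
    return("attribute")
  }
  "leaf"
}

#' Archetype class of an archetype node
#' @param x An archetype node.
#' @return The archetype class name, e.g.
#'   `"openEHR-EHR-OBSERVATION.blood_pressure.v1"`.
#' @export
archetype_class <- function(x) {
  stopifnot(node_kind(x) == "archetype")
  x[["archetype_class"]]
}

# Attribute children of an archetype or attribute node, reserved keys removed.
node_attributes <- function(x) {
  nm <- names(x)
  x[!(nm %in% RESERVED_NODE_KEYS)]
}

#' Construct a record
#'
#' @param root Root node; must be of kind archetype.
#' @param record_id,ehr_id Identifier strings.
#' @param version Integer version, starts at 1 and increments on update.
#' @param active Logical; inactive records are invisible to queries.
#' @param created_at,updated_at ISO-8601 UTC timestamps.
#' @param structure_id Canonical structure identifier assigned at ingest
#'   (`NA` until the record passes through the index service).
#' @return An object of class `ehr_record`.
#' @export
new_record <- function(root, record_id, ehr_id = record_id, version = 1L,
                       active = TRUE,
                       created_at = "1970-01-01T00:00:00Z",
                       updated_at = created_at,
                       structure_id = NA_character_) {
  if (node_kind(root) != "archetype") {
    stop("record root must be an archetype node")
  }
  version <- as.integer(version)
  stopifnot(is.character(record_id), length(record_id) == 1L,
            nzchar(record_id), version >= 1L, is.logical(active))
  structure(list(record_id = record_id, ehr_id = ehr_id,
                 version = version, active = active,
                 created_at = created_at, updated_at = updated_at,
                 structure_id = structure_id, root = root),
            class = "ehr_record")
}

#' @export
print.ehr_record <- function(x, ...) {
  cat(sprintf("<ehr_record %s v%d%s> root=%s archetypes=%d\n",
              x$record_id, x$version, if (x$active) "" else " inactive",
              archetype_class(x$root), count_archetypes(x$root)))
  invisible(x)
}

# -- validation ---------------------------------------------------------------

validate_tree <- function(root) {
  walk <- function(x, at, rel) {
    kind <- node_kind(x)
    if (kind == "leaf") {
      if (length(x) != 1L || is.na(x) ||
          !(is.character(x) || is.numeric(x) || is.logical(x))) {
        stop("parse error at ", path_render(at),
             ": leaf must be a non-missing scalar")
      }
    } else if (kind == "archetype") {
      cls <- x[["archetype_class"]]
      if (!is.character(cls) || length(cls) != 1L ||
          !grepl(ARCHETYPE_CLASS_RE, cls)) {
        stop("parse error at ", path_render(at),
             ": invalid archetype class ", deparse(cls))
      }
      pfp <- x[["path_from_parent"]]
      if (!is.null(pfp) && !identical(pfp, path_render(rel))) {
        stop("parse error at ", path_render(at), ": path_from_parent ",
             sQuote(pfp), " does not match position ",
             sQuote(path_render(rel)))
      }
      kids <- node_attributes(x)
      nm <- names(kids)
      if (length(kids) && (is.null(nm) || any(nm == ""))) {
        stop("parse error at ", path_render(at), ": unnamed attribute")
      }
      for (k in nm) walk(kids[[k]], c(at, k), k)
    } else if (kind == "attribute") {
      nm <- names(x)
      if (length(x) && any(nm == "")) {
        stop("parse error at ", path_render(at), ": unnamed attribute")
      }
      for (k in nm) walk(x[[k]], c(at, k), c(rel, k))
    } else {
      for (el in x) walk(el, at, rel)
    }
    invisible(TRUE)
  }
  walk(root, character(0), character(0))
}

#' Count archetype nodes in a subtree
#' @param node Any record-tree node.
#' @return Integer count of archetype nodes.
#' @export
count_archetypes <- function(node) {
  kind <- node_kind(node)
  n <- if (kind == "archetype") 1L else 0L
  if (is.list(node)) {
    kids <- if (kind %in% c("archetype", "attribute")) {
      node_attributes(node)
    } else {
      node
    }
    for (el in kids) n <- n + count_archetypes(el)
  }
  n
}

# -- serialization ------------------------------------------------------------

# Drop on-disk "path_from_parent" annotations: they are derivable from the
# node's position and are recomputed on write, so the in-memory form omits
# them (keeping comparisons positional, not annotation-sensitive).
strip_path_annotations <- function(x) {
  if (!is.list(x)) return(x)
  if (node_kind(x) == "archetype") x[["path_from_parent"]] <- NULL
  for (i in seq_along(x)) x[[i]] <- strip_path_annotations(x[[i]])
  x
}

# Coerce parsed JSON scalars: integers become doubles so that a value
# round-trips to an identical R object irrespective of how jsonlite typed it.
normalize_parsed <- function(x) {
  if (is.list(x)) {
    for (i in seq_along(x)) {
      v <- normalize_parsed(x[[i]])
      if (!is.null(v)) x[[i]] <- v   # JSON null stays NULL; assigning would drop the slot
    }
    x
  } else if (is.integer(x)) {
    as.double(x)
  } else {
    x
  }
}

#' Read a record from its JSON serialization
#'
#' The on-disk dialect is a single JSON object holding the record metadata
#' (reserved keys `record_id`, `ehr_id`, `version`, `active`, `created_at`,
#' `updated_at`, `structure_id`) merged with the root archetype node.
#' Archetype nodes carry `archetype_class` and `path_from_parent`; attribute
#' maps are plain objects and list-valued attributes are arrays.
#'
#' @param text A single JSON string (one record).
#' @return An [new_record()] object.
#' @export
read_record <- function(text) {
  doc <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) stop("parse error at /: ", conditionMessage(e)))
  if (!is.list(doc) || is.null(names(doc))) {
    stop("schema error at /: record must be a JSON object")
  }
  doc <- normalize_parsed(doc)
  meta <- doc[intersect(names(doc), RESERVED_RECORD_KEYS)]
  root <- doc[!(names(doc) %in% RESERVED_RECORD_KEYS)]
  if (!("archetype_class" %in% names(root))) {
    stop("schema error at /: root is not an archetype (missing archetype_class)")
  }
  validate_tree(root)
  root <- strip_path_annotations(root)
  if (is.null(meta$record_id)) stop("schema error at /: missing record_id")
  new_record(root,
             record_id = meta$record_id,
             ehr_id = if (is.null(meta$ehr_id)) meta$record_id else meta$ehr_id,
             version = if (is.null(meta$version)) 1L else as.integer(meta$version),
             active = if (is.null(meta$active)) TRUE else isTRUE(meta$active),
             created_at = if (is.null(meta$created_at)) "1970-01-01T00:00:00Z"
                          else meta$created_at,
             updated_at = if (is.null(meta$updated_at)) {
               if (is.null(meta$created_at)) "1970-01-01T00:00:00Z"
               else meta$created_at
             } else meta$updated_at,
             structure_id = if (is.null(meta$structure_id)) NA_character_
                            else meta$structure_id)
}

#' Read a record from a JSON file
#' @param path File containing one JSON record.
#' @return An `ehr_record`.
#' @export
read_record_file <- function(path) {
  read_record(paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                    collapse = "\n"))
}

#' Serialize a record to JSON
#'
#' Deterministic: stable key ordering, so two serializations of the same
#' record are byte-identical, and `read_record(write_record(r))` reproduces
#' `r` exactly.
#'
#' @param record An `ehr_record`.
#' @return A single JSON string.
#' @export
write_record <- function(record) {
  stopifnot(inherits(record, "ehr_record"))
  root_json <- serialize_root_json(record$root, "")
  meta <- paste0(
    "\"record_id\":", json_scalar(record$record_id),
    ",\"ehr_id\":", json_scalar(record$ehr_id),
    ",\"version\":", json_scalar(as.double(record$version)),
    ",\"active\":", json_scalar(record$active),
    ",\"created_at\":", json_scalar(record$created_at),
    ",\"updated_at\":", json_scalar(record$updated_at),
    ",\"structure_id\":", json_scalar(record$structure_id))
  # splice the metadata into the root object
  paste0("{", meta, ",", substring(root_json, 2L))
}

json_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  gsub("\t", "\\t", s, fixed = TRUE)
}

json_scalar <- function(x) {
  if (is.na(x)) return("null")
  if (is.character(x)) return(paste0("\"", json_escape(x), "\""))
  if (is.logical(x)) return(if (x) "true" else "false")
  format(x, digits = 15, trim = TRUE)
}


# -- path resolution ----------------------------------------------------------

#' Resolve a relative path against a node
#'
#' Follows the steps in order; list-valued attributes fan out to all of their
#' elements, and a path never selects by list index.  An unresolvable path
#' yields an empty result rather than an error.
#'
#' @param node A record-tree node.
#' @param path Character vector of steps (see [path_parse()]).
#' @return A list of every node reachable by the path; `list(node)` for the
#'   empty path.
#' @export
resolve_path <- function(node, path) {
  if (length(path) == 0L) return(list(node))
  kind <- node_kind(node)
  if (kind == "array") {
    out <- list()
    for (el in node) out <- c(out, resolve_path(el, path))
    return(out)
  }
  if (kind == "leaf") return(list())
  kids <- node_attributes(node)
  step <- path[[1L]]
  if (!(step %in% names(kids))) return(list())
  descend_rest(kids[[step]], path[-1L])
}

# After consuming a step, transparently fan out through arrays before either
# returning the reached nodes or continuing with the remaining steps.
descend_rest <- function(v, rest) {
  if (node_kind(v) == "array") {
    out <- list()
    for (el in v) out <- c(out, descend_rest(el, rest))
    return(out)
  }
  if (length(rest) == 0L) return(list(v))
  resolve_path(v, rest)
}
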