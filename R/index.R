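# Index service: extracts each record's value-free canonical archetype
# skeleton, assigns it a content-derived identifier, deduplicates structures
# and resolves containment chains to (structure id, absolute path) matches.
# Lookup touches only the structure registry, never the record store, so its
# cost is independent of the number of stored records.

# A structure node is list(class = <archetype class>,
#                          path  = <steps from nearest containing archetype>,
#                          children = list of structure nodes, canonical order)

#' Extract the value-free structure of a record
#'
#' Walks the record tree, keeping one node per archetype instance with its
#' path relative to the nearest containing archetype; all attribute values
#' are discarded.  Children are stored in canonical order so that records
#' differing only in sibling permutations produce identical descriptors.
#'
#' @param record An `ehr_record` (or a bare archetype root node).
#' @return A `structure_descriptor`: list with elements `root` (canonical
#'   structure node) and `structure_id` (content hash, see [canonical_id()]).
#' @export
extract_structure <- function(record) {
  root <- if (inherits(record, "ehr_record")) record$root else record
  if (node_kind(root) != "archetype") stop("root is not an archetype node")
  snode <- extract_snode(root)
  cnode <- canonicalize_snode(snode)
  structure(list(root = cnode, structure_id = canonical_id_node(cnode)),
            class = "structure_descriptor")
}

extract_snode <- function(node) {
  children <- list()
  collect <- function(x, rel) {
    kind <- node_kind(x)
    if (kind == "archetype") {
      children[[length(children) + 1L]] <<- c(extract_snode(x),
                                              list(rel_override = rel))
    } else if (kind == "attribute") {
      nm <- names(x)
      for (k in nm) collect(x[[k]], c(rel, k))
    } else if (kind == "array") {
      for (el in x) collect(el, rel)
    }
    # leaves are pruned
  }
  for (k in names(node_attributes(node))) {
    collect(node[[k]], k)
  }
  children <- lapply(children, function(ch) {
    list(class = ch$class, path = ch$rel_override, children = ch$children)
  })
  list(class = archetype_class(node), path = character(0), children = children)
}

# Canonical child order: children sorted bytewise on their canonical
# serialisation (which starts with class, then rendered path, then subtree),
# giving a stable, locale-independent total order.
canonicalize_snode <- function(snode) {
  kids <- lapply(snode$children, canonicalize_snode)
  if (length(kids) > 1L) {
    sers <- vapply(kids, canonical_serialize_node, character(1))
    kids <- kids[order(sers, method = "radix")]
  }
  snode$children <- kids
  snode
}

canonical_serialize_node <- function(snode) {
  paste0("(", snode$class, "|", path_render(snode$path), "|",
         paste(vapply(snode$children, canonical_serialize_node, character(1)),
               collapse = ","), ")")
}

#' Canonical serialization of a structure descriptor
#' @param descriptor A `structure_descriptor`.
#' @return A single string; equal strings iff equal canonical forms.
#' @export
canonical_serialize <- function(descriptor) {
  canonical_serialize_node(descriptor$root)
}

canonical_id_node <- function(cnode) {
  substr(sha256_hex(canonical_serialize_node(cnode)), 1L, 16L)
}

#' Content-derived structure identifier
#'
#' Hex digest (SHA-256, truncated to 16 hex characters) of the canonical
#' serialization.  Deterministic across processes; sibling permutations of
#' the source record yield the same identifier.
#'
#' @param descriptor A `structure_descriptor`.
#' @return A 16-character identifier string.
#' @export
canonical_id <- function(descriptor) {
  canonical_id_node(descriptor$root)
}

#' Count nodes of a structure descriptor
#' @param descriptor A `structure_descriptor` (or structure node).
#' @return Number of archetype nodes in the skeleton.
#' @export
structure_size <- function(descriptor) {
  node <- if (inherits(descriptor, "structure_descriptor")) descriptor$root
          else descriptor
  1L + sum(vapply(node$children, structure_size, integer(1)))
}

#' @export
print.structure_descriptor <- function(x, ...) {
  cat(sprintf("<structure %s> %d archetype nodes, root %s\n",
              x$structure_id, structure_size(x), x$root$class))
  invisible(x)
}

# -- registry -----------------------------------------------------------------

#' Create an empty structure registry
#'
#' In-process registry mapping structure identifiers to canonical structure
#' trees, with per-structure record counts maintained at ingest.
#'
#' @return A `structure_index` object.
#' @export
structure_index <- function() {
  reg <- new.env(parent = emptyenv())
  counts <- new.env(parent = emptyenv())
  structure(list(structures = reg, counts = counts), class = "structure_index")
}

#' @export
print.structure_index <- function(x, ...) {
  cat(sprintf("<structure_index> %d unique structures\n",
              length(ls(x$structures))))
  invisible(x)
}

#' Register a structure
#'
#' Idempotent: the registry grows only when the canonical form is new.
#'
#' @param index A [structure_index()].
#' @param descriptor A `structure_descriptor` from [extract_structure()].
#' @return The structure identifier (invisibly the same as
#'   `descriptor$structure_id`).
#' @export
register_structure <- function(index, descriptor) {
  stopifnot(inherits(index, "structure_index"),
            inherits(descriptor, "structure_descriptor"))
  id <- descriptor$structure_id
  if (!exists(id, envir = index$structures, inherits = FALSE)) {
    assign(id, descriptor$root, envir = index$structures)
  }
  id
}

# Record-count bookkeeping, called by the data-management ingest path.
index_count_record <- function(index, id, delta = 1L) {
  cur <- if (exists(id, envir = index$counts, inherits = FALSE)) {
    get(id, envir = index$counts)
  } else 0L
  assign(id, cur + delta, envir = index$counts)
  invisible(cur + delta)
}

#' Number of registered structures
#' @param index A `structure_index`.
#' @return Integer count.
#' @export
structure_count <- function(index) {
  length(ls(index$structures))
}

#' Registry summary
#'
#' @param index A `structure_index`.
#' @return A list with `n_structures`, a data frame `structures` (id, number
#'   of archetype nodes, archetype depth, records counted at ingest) and a
#'   depth histogram table.
#' @export
index_stats <- function(index) {
  ids <- sort(ls(index$structures), method = "radix")
  sizes <- integer(length(ids)); depths <- integer(length(ids))
  recs <- integer(length(ids))
  for (i in seq_along(ids)) {
    node <- get(ids[i], envir = index$structures)
    sizes[i] <- structure_size(node)
    depths[i] <- snode_depth(node)
    recs[i] <- if (exists(ids[i], envir = index$counts, inherits = FALSE)) {
      get(ids[i], envir = index$counts)
    } else 0L
  }
  list(n_structures = length(ids),
       structures = data.frame(structure_id = ids, n_archetypes = sizes,
                               archetype_depth = depths, n_records = recs,
                               stringsAsFactors = FALSE),
       depth_histogram = table(depths))
}

snode_depth <- function(node) {
  if (length(node$children) == 0L) return(1L)
  1L + max(vapply(node$children, snode_depth, integer(1)))
}

#' Export the registry as JSON-lines of canonical serializations
#' @param index A `structure_index`.
#' @param path Output file; if `NULL`, the lines are returned.
#' @return Character vector of JSON lines (invisibly when written to file).
#' @export
export_registry <- function(index, path = NULL) {
  ids <- sort(ls(index$structures), method = "radix")
  lines <- vapply(ids, function(id) {
    node <- get(id, envir = index$structures)
    as.character(jsonlite::toJSON(
      list(structure_id = jsonlite::unbox(id),
           canonical = jsonlite::unbox(canonical_serialize_node(node)),
           tree = snode_to_json(node)),
      auto_unbox = FALSE))
  }, character(1))
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

snode_to_json <- function(node) {
  list(class = jsonlite::unbox(node$class),
       path_from_parent = jsonlite::unbox(path_render(node$path)),
       children = lapply(node$children, snode_to_json))
}

snode_from_json <- function(x) {
  list(class = x$class, path = path_parse(x$path_from_parent),
       children = lapply(x$children, snode_from_json))
}

#' Import a registry exported with [export_registry()]
#' @param lines Character vector of JSON lines, or a file path.
#' @return A `structure_index`.
#' @export
import_registry <- function(lines) {
  if (length(lines) == 1L && file.exists(lines)) {
    lines <- readLines(lines, warn = FALSE, encoding = "UTF-8")
  }
  index <- structure_index()
  for (ln in lines) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    node <- snode_from_json(obj$tree)
    assign(canonical_id_node(node), node, envir = index$structures)
  }
  index
}

# -- containment lookup -------------------------------------------------------

#' Build a containment chain
#'
#' @param patterns Character vector of class patterns, outermost first.  A
#'   pattern is an exact archetype class, a version-insensitive prefix (no
#'   `.vN` suffix), or `"*"` for any class.
#' @return A `containment_chain`.
#' @export
containment_chain <- function(patterns) {
  stopifnot(is.character(patterns))
  structure(list(patterns = patterns), class = "containment_chain")
}

# Does `class` satisfy `pattern`?
class_matches <- function(class, pattern) {
  if (pattern == "*") return(TRUE)
  if (class == pattern) return(TRUE)
  if (!grepl("\\.v[0-9]+", pattern)) {
    # version-insensitive: pattern up to the concept; any version / label
    return(startsWith(class, paste0(pattern, ".v")))
  }
  FALSE
}

#' Resolve a containment chain against the registry
#'
#' A registered structure matches when it contains archetype nodes
#' `a1 ... an` with `class(ai)` matching pattern `i` and each `a(i+1)` a
#' descendant (not necessarily a child) of `ai`; any number of archetypes may
#' sit between consecutive chain members.  The chain may be rooted anywhere
#' in the structure.  For every matching structure all distinct absolute
#' paths from the record root to the innermost chain archetype are reported
#' (each path is the concatenation of the `path_from_parent` of every
#' archetype on the root-to-innermost spine), deduplicated and sorted.
#'
#' @param index A [structure_index()].
#' @param chain A [containment_chain()] (or character vector of patterns).
#' @return A list of matches, each `list(structure_id, paths)` where `paths`
#'   is a character vector of rendered absolute paths; empty list when
#'   nothing matches.  Requires no record-store handle.
#' @export
lookup_containment <- function(index, chain) {
  if (is.character(chain)) chain <- containment_chain(chain)
  stopifnot(inherits(index, "structure_index"),
            inherits(chain, "containment_chain"))
  patterns <- chain$patterns
  if (length(patterns) == 0L) stop("containment chain must be non-empty")
  ids <- sort(ls(index$structures), method = "radix")
  out <- list()
  for (id in ids) {
    node <- get(id, envir = index$structures)
    paths <- chain_paths_in_structure(node, patterns)
    if (length(paths)) {
      out[[length(out) + 1L]] <- list(structure_id = id, paths = paths)
    }
  }
  out
}

# DFS carrying, per node, the set of achievable "patterns matched so far"
# states along the ancestor spine; a node is an innermost witness when the
# full chain can end at it.  Absolute paths accumulate the path_from_parent
# of every archetype on the spine (gap archetypes included).
chain_paths_in_structure <- function(root, patterns) {
  n <- length(patterns)
  hits <- character(0)
  walk <- function(node, states, abs_steps) {
    abs_here <- c(abs_steps, node$path)
    new_states <- states
    for (k in states) {
      if (k < n && class_matches(node$class, patterns[k + 1L])) {
        new_states <- union(new_states, k + 1L)
        if (k + 1L == n) hits <<- c(hits, path_render(abs_here))
      }
    }
    for (ch in node$children) walk(ch, new_states, abs_here)
  }
  walk(root, 0L, character(0))
  sort(unique(hits), method = "radix")
}
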