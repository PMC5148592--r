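# Shared fixtures and independent (test-side) oracle implementations.
# The oracles here are written against the documented semantics, not
# against the package internals, so they fail when the implementation
# drifts from the contract.

fixture_cache <- new.env(parent = emptyenv())

# The default 2600-structure library is expensive enough to share.
default_library <- function() {
  if (!exists("lib", envir = fixture_cache)) {
    assign("lib", build_structure_library(generator_profile()),
           envir = fixture_cache)
  }
  get("lib", envir = fixture_cache)
}

# A small blood-pressure record used across tests.
bp_node <- function(mag = 120, units = "mm[Hg]") {
  list(archetype_class = "openEHR-EHR-OBSERVATION.blood_pressure.v1",
       data = list(`events[at0006]` = list(list(
         value = list(magnitude = mag, units = units)))))
}

encounter_record <- function(id, mag = 120, units = "mm[Hg]", extra = NULL) {
  root <- list(archetype_class = "openEHR-EHR-COMPOSITION.encounter.v1",
               `content[at0001]` = c(list(bp_node(mag, units)), extra))
  new_record(root, id)
}

# Independent node-for-node tree comparator (never uses identical()).
trees_equal <- function(a, b) {
  if (is.list(a) != is.list(b)) return(FALSE)
  if (!is.list(a)) {
    if (length(a) != length(b)) return(FALSE)
    if (is.numeric(a) && is.numeric(b)) return(isTRUE(a == b))
    return(class(a)[1] == class(b)[1] && isTRUE(a == b))
  }
  if (length(a) != length(b)) return(FALSE)
  na <- names(a); nb <- names(b)
  if (is.null(na) != is.null(nb)) return(FALSE)
  if (!is.null(na) && !setequal(na, nb)) return(FALSE)
  for (i in seq_along(a)) {
    bi <- if (is.null(na)) b[[i]] else b[[na[i]]]
    if (!trees_equal(a[[i]], bi)) return(FALSE)
  }
  TRUE
}

# Independent random structure trees for index oracle tests.
random_archetype_tree <- function(depth_left, breadth = 2L, prefix = "rnd") {
  cls <- sprintf("openEHR-EHR-SECTION.%s_%d.v1", prefix,
                 sample.int(6L, 1L))
  node <- list(archetype_class = cls)
  if (depth_left > 1L) {
    for (k in seq_len(sample.int(breadth, 1L))) {
      key <- sprintf("slot%d[at%04d]", k, sample.int(20L, 1L))
      child <- random_archetype_tree(depth_left - 1L, breadth, prefix)
      if (stats::runif(1) < 0.4) child <- list(inner = child)  # deeper gap
      node[[key]] <- child
    }
  } else {
    node$value <- list(magnitude = round(stats::runif(1, 0, 200), 1))
  }
  node
}

# Recursive sibling shuffle of a record root (arrays and key order).
shuffle_tree <- function(x) {
  if (!is.list(x)) return(x)
  out <- lapply(x, shuffle_tree)
  nm <- names(out)
  if (length(out) > 1L) {
    ord <- sample.int(length(out))
    if (!is.null(nm)) {
      fixed <- which(nm %in% c("archetype_class", "path_from_parent"))
      ord <- c(fixed, setdiff(ord, fixed))
    }
    out <- out[ord]
  }
  out
}

# Small corpus with boosted match fractions for oracle-equivalence tests:
# every query level keeps a non-trivial planted count at ~2.5k records.
oracle_corpus <- function() {
  if (!exists("oc", envir = fixture_cache)) {
    lib <- default_library()
    lib$profile$n_records <- 2500
    lib$profile$match_fraction <- list(
      a = geometric_levels_test(0.12, 0.024),
      b = geometric_levels_test(0.06, 0.012))
    cp <- generate_corpus(lib, scale = 1)
    cp$records <- lapply(cp$lines, read_record)
    cp$queries <- lib$queries
    assign("oc", cp, envir = fixture_cache)
  }
  get("oc", envir = fixture_cache)
}

geometric_levels_test <- function(f2, f5) {
  r <- (f5 / f2)^(1 / 3)
  stats::setNames(f2 * r^(0:3), as.character(2:5))
}

# Store a record with its structure id stamped (what the ingest path does).
put_with_sid <- function(session, rec) {
  rec$structure_id <- extract_structure(rec)$structure_id
  put_record(session, rec)
  rec$structure_id
}

# Rebuild a record-like tree from a canonical structure node, so that the
# recursive reference matcher can be run against registry answers.
# Children sharing their first step are grouped into an array.
snode_as_record_tree <- function(sn) {
  node <- list(archetype_class = sn$class)
  groups <- list()
  for (ch in sn$children) {
    steps <- ch$path
    sub <- snode_as_record_tree(ch)
    for (s in rev(steps[-1])) sub <- structure(list(sub), names = s)
    key <- steps[[1]]
    groups[[key]] <- c(groups[[key]], list(sub))
  }
  for (k in names(groups)) {
    g <- groups[[k]]
    node[[k]] <- if (length(g) == 1L) g[[1L]] else g
  }
  node
}

ingest_lines <- function(lines, fetch_threshold = 10000L) {
  sys <- ehr_system(driver_config(fetch_threshold = fetch_threshold))
  ingest_corpus(sys, lines)
  sys
}
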