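test_that("profiles are validated", {
  expect_error(generator_profile(filler_fraction = 1.2), "profile error")
  expect_error(generator_profile(match_fraction = list(
    a = c("2" = 0.4, "3" = 0.3, "4" = 0.2, "5" = 0.1),
    b = c("2" = 0.4, "3" = 0.3, "4" = 0.2, "5" = 0.1))), "profile error")
  expect_error(generator_profile(match_fraction = list(
    a = c("2" = 0.01, "3" = 0.02, "4" = 0.02, "5" = 0.02),
    b = c("2" = 0.001, "3" = 0.001, "4" = 0.001, "5" = 0.001))),
    "not increase")
  expect_error(generator_profile(archetype_depth_sd = 0), "positive")
  expect_error(generator_profile(max_archetype_chain = 1), "chain cap")
})

test_that("a one-structure library is a single filler structure", {
  lib <- build_structure_library(generator_profile(n_base_structures = 1))
  expect_length(lib$entries, 1L)
  expect_true(is.na(lib$entries[[1]]$family))
  st <- validate_statistics(lib)
  expect_identical(st$n, 1L)
})

test_that("library generation is deterministic per seed", {
  p <- generator_profile(n_base_structures = 30, seed = 99)
  l1 <- build_structure_library(p)
  l2 <- build_structure_library(p)
  expect_identical(l1, l2)
  l3 <- build_structure_library(generator_profile(n_base_structures = 30,
                                                  seed = 100))
  expect_false(identical(l1$entries, l3$entries))
})

test_that("corpus generation is byte-deterministic per seed", {
  lib <- default_library()
  lib$profile$n_records <- 600
  c1 <- generate_corpus(lib, scale = 1)
  c2 <- generate_corpus(lib, scale = 1)
  expect_identical(c1$lines, c2$lines)
  expect_identical(c1$manifest, c2$manifest)
})

test_that("planted counts follow the profile and nest across levels", {
  lib <- default_library()
  lib$profile$n_records <- 4000
  cp <- generate_corpus(lib, scale = 1)
  m <- cp$manifest
  expect_identical(m$n_records, 4000L)
  for (fam in c("a", "b")) {
    type <- if (fam == "a") 1L else 3L
    for (lvl in 2:5) {
      key <- sprintf("t%d_l%d", type, lvl)
      expect_identical(
        m$counts[[key]],
        as.integer(round(lib$profile$match_fraction[[fam]][[as.character(lvl)]] * 4000)))
    }
    for (lvl in 2:4) {
      hi <- m$planted[[sprintf("t%d_l%d", type, lvl + 1L)]]
      lo <- m$planted[[sprintf("t%d_l%d", type, lvl)]]
      expect_true(all(hi %in% lo))
    }
  }
  # the two type families answer with the same sets inside each family
  expect_identical(m$planted[["t1_l3"]], m$planted[["t2_l3"]])
  expect_identical(m$planted[["t3_l4"]], m$planted[["t5_l4"]])
  expect_identical(m$n_filler, 2000L)
})

test_that("filler records match none of the twenty queries", {
  cp <- oracle_corpus()
  filler <- cp$records[vapply(cp$records, function(r)
    r$record_id %in% cp$manifest$filler_ids, logical(1))]
  expect_gt(length(filler), 0L)
  for (q in cp$queries) {
    expect_identical(as.integer(baseline_scan(q, filler)), 0L)
  }
})

test_that("generated corpora stream identically to file and memory", {
  lib <- default_library()
  lib$profile$n_records <- 300
  path <- tempfile(fileext = ".jsonl")
  on_disk <- generate_corpus(lib, scale = 1, out = path)
  in_mem <- generate_corpus(lib, scale = 1)
  expect_identical(readLines(path, warn = FALSE), in_mem$lines)
  expect_identical(on_disk$manifest, in_mem$manifest)
  unlink(path)
})

test_that("statistics agree with an independently coded traversal", {
  lib <- default_library()
  set.seed(5)
  picks <- sample.int(length(lib$entries), 40L)
  roots <- lapply(lib$entries[picks], `[[`, "root")
  st <- validate_statistics(roots)
  # independent recomputation of the same definitions, coded from scratch:
  # an entry is a key (or the root); its level is 1 + keys on the path;
  # arrays are transparent; archetype depth counts archetype nodes on a path
  depth_width <- function(root) {
    levels <- new.env(parent = emptyenv())
    levels$v <- integer(0)
    visit <- function(value, d) {
      if (d > length(levels$v)) levels$v[d] <- 0L
      levels$v[d] <- levels$v[d] + 1L
      keyed <- function(x) {
        if (!is.list(x)) return(list())
        if (is.null(names(x))) return(do.call(c, c(lapply(x, keyed),
                                                   list(list()))))
        x[!(names(x) %in% c("archetype_class", "path_from_parent"))]
      }
      for (ch in keyed(value)) visit(ch, d + 1L)
    }
    visit(root, 1L)
    arch <- function(x) {
      if (!is.list(x)) return(0L)
      if (is.null(names(x))) {
        return(if (length(x)) max(vapply(x, arch, integer(1))) else 0L)
      }
      own <- if ("archetype_class" %in% names(x)) 1L else 0L
      kids <- x[!(names(x) %in% c("archetype_class", "path_from_parent"))]
      own + (if (length(kids)) max(vapply(kids, arch, integer(1))) else 0L)
    }
    list(depth = length(levels$v), width = max(levels$v), arch = arch(root))
  }
  ind <- lapply(roots, depth_width)
  expect_identical(st$element_depths,
                   vapply(ind, function(x) as.integer(x$depth), integer(1)))
  expect_identical(st$max_widths,
                   vapply(ind, function(x) as.integer(x$width), integer(1)))
  expect_identical(st$archetype_depths,
                   vapply(ind, function(x) as.integer(x$arch), integer(1)))
})

test_that("constant-load corpus grows in ten equal steps", {
  lib <- default_library()
  lib$profile$n_records <- 400
  lib$profile$filler_fraction <- 0.9
  lib$profile$match_fraction <- list(
    a = geometric_levels_test(0.05, 0.025),
    b = geometric_levels_test(0.05, 0.025))
  steps <- generate_cl_corpus(lib, scale = 1)
  expect_length(steps, 10L)
  for (s in steps) {
    expect_identical(s$manifest$n_records, 40L)
    expect_identical(s$manifest$n_filler, 36L)
  }
  # steps differ (different seeds) but sizes are constant
  expect_false(identical(steps[[1]]$lines, steps[[2]]$lines))
  # record ids are disjoint across steps so all ten ingest cleanly
  ids <- unlist(lapply(steps, function(s)
    vapply(lapply(s$lines, read_record), `[[`, character(1), "record_id")))
  expect_identical(anyDuplicated(ids), 0L)
})
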