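# Synthetic corpus generator.
#
# Builds a library of base structures with controlled archetype depth,
# element depth and width distributions, then instantiates seeded corpora
# with planted query responders and a ground-truth manifest.
#
# Responder design: two archetype-class chains of length 5 are defined,
# family "a" (answering the projection-only query types 1 and 2) and family
# "b" (answering the predicate query types 3, 4 and 5).  A responder
# structure carries the first m chain classes of its family (its
# "maxlevel") somewhere along its archetype spine, so a record instantiated
# from it matches exactly the family's queries of containment level <= m.
# Since the level-l query chain is a prefix of the level-(l+1) chain, the
# responder sets are nested across levels by construction.  Every record of
# family "b" carries predicate-satisfying leaf values, making the counts of
# the AND and OR variants equal to the single-predicate count.  Filler
# structures use per-structure unique classes and can match no query.

# -- chain vocabulary ---------------------------------------------------------

chain_rm_type <- function(k) {
  if (k == 1L) "COMPOSITION" else if (k == 5L) "OBSERVATION" else "SECTION"
}

chain_class <- function(family, k) {
  sprintf("openEHR-EHR-%s.group_%s_%d.v1", chain_rm_type(k), family, k)
}

SKELETON_STEPS <- c("data[at0001]", "events[at0006]", "data[at0003]",
                    "items[at0004]", "value")
SKELETON_PATH <- paste0("/", paste(c(SKELETON_STEPS, "magnitude"),
                                   collapse = "/"))
SKELETON_UNITS_PATH <- paste0("/", paste(c(SKELETON_STEPS, "units"),
                                         collapse = "/"))
SKELETON_DEPTH <- 6L  # leaf depth below the carrying archetype node

# -- profile ------------------------------------------------------------------

#' Generator profile
#'
#' Parameters of the synthetic corpus designs.  Per-structure maximum
#' archetype depth is drawn from a rounded truncated normal, maximum element
#' depth from a truncated normal bounded below by what the archetype spine
#' requires, and maximum width from a binomial body with mode
#' `width_mode` mixed with a log-normal right tail.  Match fractions give,
#' per query family and containment level, the fraction of records
#' answering the query; levels 3 and 4 are geometric interpolations of the
#' level-2 and level-5 endpoints.
#'
#' @param n_records Full-scale corpus size.
#' @param filler_fraction Fraction of records labelled filler (matching no
#'   query).
#' @param n_base_structures Library size.
#' @param archetype_depth_mean,archetype_depth_sd Moments of the
#'   per-structure maximum archetype nesting depth.
#' @param element_depth_mean,element_depth_sd Moments of the per-structure
#'   maximum element nesting depth.
#' @param width_mode Modal per-structure maximum width.
#' @param width_tail_fraction Probability mass of the heavy right tail.
#' @param width_cap Upper cap for sampled widths.
#' @param max_archetype_chain Cap on archetypes along a single branch.
#' @param match_fraction Named list `a`/`b`, each a numeric vector with
#'   names `"2" ... "5"`; `NULL` selects the defaults (family a: 0.10 at
#'   level 2 to 0.0175 at level 5; family b: 0.001 to 0.000175; geometric
#'   in between).
#' @param n_datasets Number of placement variants.
#' @param seed Integer seed; same profile and seed give byte-identical
#'   output.
#' @return A `generator_profile` object.
#' @export
generator_profile <- function(n_records = 10000000, filler_fraction = 0.5,
                              n_base_structures = 2600,
                              archetype_depth_mean = 6.7,
                              archetype_depth_sd = 1.7,
                              element_depth_mean = 66,
                              element_depth_sd = 15.7,
                              width_mode = 8, width_tail_fraction = 0.12,
                              width_cap = 400,
                              max_archetype_chain = 12,
                              match_fraction = NULL,
                              n_datasets = 5, seed = 20240101) {
  if (is.null(match_fraction)) {
    match_fraction <- list(a = geometric_levels(0.10, 0.0175),
                           b = geometric_levels(0.001, 0.000175))
  }
  p <- structure(list(n_records = n_records,
                      filler_fraction = filler_fraction,
                      n_base_structures = as.integer(n_base_structures),
                      archetype_depth_mean = archetype_depth_mean,
                      archetype_depth_sd = archetype_depth_sd,
                      element_depth_mean = element_depth_mean,
                      element_depth_sd = element_depth_sd,
                      width_mode = width_mode,
                      width_tail_fraction = width_tail_fraction,
                      width_cap = width_cap,
                      max_archetype_chain = as.integer(max_archetype_chain),
                      match_fraction = match_fraction,
                      n_datasets = as.integer(n_datasets),
                      seed = as.integer(seed)),
                 class = "generator_profile")
  validate_profile(p)
  p
}

# Geometric interpolation of the level-3/4 fractions between the printed
# level-2 and level-5 endpoints.
geometric_levels <- function(f2, f5) {
  r <- (f5 / f2)^(1 / 3)
  stats::setNames(f2 * r^(0:3), as.character(2:5))
}

validate_profile <- function(p) {
  fr <- unlist(p$match_fraction)
  if (any(fr < 0) || any(fr > 1) || p$filler_fraction < 0 ||
      p$filler_fraction > 1) {
    stop("profile error: fractions must lie in [0, 1]")
  }
  responders <- sum(vapply(p$match_fraction, function(v) v[["2"]], double(1)))
  if (responders > 1 - p$filler_fraction) {
    stop("profile error: responder fractions exceed 1 - filler_fraction")
  }
  for (f in p$match_fraction) {
    if (is.unsorted(rev(f))) {
      stop("profile error: match fractions must not increase with level")
    }
  }
  if (p$max_archetype_chain <
      p$archetype_depth_mean - 3 * p$archetype_depth_sd) {
    stop("profile error: archetype chain cap below mean - 3 sd of the depth",
         " distribution")
  }
  if (p$archetype_depth_sd <= 0 || p$element_depth_sd <= 0 ||
      p$n_base_structures < 1L) {
    stop("profile error: distribution parameters must be positive")
  }
  invisible(p)
}

# Truncated normal via rejection (bounds are several sd wide here, so the
# acceptance rate is high).
rtruncnorm1 <- function(mean, sd, lower = -Inf, upper = Inf) {
  repeat {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
}

sample_width_target <- function(p) {
  if (stats::runif(1L) < p$width_tail_fraction) {
    w <- p$width_mode + 2 + round(stats::rlnorm(1L, log(25), 0.8))
  } else {
    w <- p$width_mode - 4 + stats::rbinom(1L, 8L, 0.5)
  }
  min(max(w, 2), p$width_cap)
}

# -- structure construction ---------------------------------------------------

skeleton_attrs <- function() {
  list(`data[at0001]` = list(
    `events[at0006]` = list(          # array: one event
      list(`data[at0003]` = list(
        `items[at0004]` = list(       # array: one item
          list(value = list(magnitude = 100, units = "unit"))))))))
}

# One base structure: an archetype spine of d_a nodes separated by attribute
# gap paths summing to the element-depth budget, a uniform value skeleton
# under every spine archetype, and a width-filling cluster at the root.
# `classes` are the spine classes, outermost first; the first gap step
# carries the structure index, guaranteeing a unique canonical form.
build_one_structure <- function(idx, classes, d_e, w_target) {
  d_a <- length(classes)
  budget <- d_e - 1L - SKELETON_DEPTH          # attribute steps along the spine
  gaps <- rep(1L, d_a - 1L)
  extra <- budget - (d_a - 1L)
  if (extra > 0L && d_a > 1L) {
    add <- tabulate(sample.int(d_a - 1L, extra, replace = TRUE), d_a - 1L)
    gaps <- gaps + add
  }
  node <- NULL
  for (j in rev(seq_len(d_a))) {
    arch <- c(list(archetype_class = classes[j]), skeleton_attrs())
    if (!is.null(node)) {
      g <- gaps[j]
      wrapped <- node
      if (g > 1L) {
        for (s in seq_len(g - 1L)) {
          wrapped <- list(`seg[at0011]` = wrapped)
        }
      }
      arch[[paste0("branch_", idx, "[at0010]")]] <- wrapped
    }
    node <- arch
  }
  # width filler: top the structure's natural element count at level 3 up
  # to the width target with a cluster of identical one-key items
  lc <- gen_level_counts(node)
  nat3 <- if (length(lc) >= 3L) lc[3L] else 0L
  n_wide <- w_target - nat3
  if (n_wide > 0L) {
    node$`cluster[at0002]` <-
      lapply(seq_len(n_wide), function(i) list(v = 0))
  }
  node
}

spine_classes <- function(idx, d_a, family = NULL, positions = integer(0)) {
  cls <- character(d_a)
  for (j in seq_len(d_a)) {
    k <- match(j, positions)
    cls[j] <- if (!is.na(k)) {
      chain_class(family, k)
    } else {
      sprintf("openEHR-EHR-%s.base_%d_%d.v1",
              if (j == 1L) "COMPOSITION" else "SECTION", idx, j)
    }
  }
  cls
}

# Placement of an m-class chain on a spine of length d_a (d_a >= m), per
# placement variant.
chain_positions <- function(variant, m, d_a) {
  pos <- switch(variant,
    seq_len(m),                                        # 1: from the root
    (d_a - m + 1L):d_a,                                # 2: at the bottom
    unique(round(seq(1, d_a, length.out = m))),        # 3: evenly spread
    if (d_a >= m + 1L) 2L:(m + 1L) else seq_len(m),    # 4: below the root
    sort(sample.int(d_a, m)))                          # 5: random places
  if (length(unique(pos)) != m) pos <- seq_len(m)
  as.integer(pos)
}

#' Build the base-structure library
#'
#' Produces exactly `n_base_structures` structures with pairwise-distinct
#' canonical forms.  When the library is large enough, a fixed share hosts
#' the query-responder chains: for each family, maxlevel 2–5 and placement
#' variant, `structures_per_cell` structures carry the chain.
#'
#' @param profile A [generator_profile()].
#' @return A `structure_library`: list with `profile`, `entries` (each
#'   `list(idx, family, maxlevel, variant, root)`) and `queries` (the 20
#'   AQL texts).
#' @export
build_structure_library <- function(profile = generator_profile()) {
  validate_profile(profile)
  p <- profile
  set.seed(p$seed)
  n <- p$n_base_structures
  spc <- max(1L, as.integer(floor(n * 8 / 2600)))
  cells <- expand.grid(family = c("a", "b"), maxlevel = 2:5,
                       variant = seq_len(p$n_datasets),
                       slot = seq_len(spc), stringsAsFactors = FALSE)
  n_resp <- if (n >= nrow(cells) + 40L) nrow(cells) else 0L
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    fam <- NA_character_; ml <- NA_integer_; var <- NA_integer_
    lower_da <- 2
    if (i <= n_resp) {
      fam <- cells$family[i]; ml <- as.integer(cells$maxlevel[i])
      var <- as.integer(cells$variant[i])
      lower_da <- max(2, ml)
    }
    d_a <- as.integer(round(rtruncnorm1(p$archetype_depth_mean,
                                        p$archetype_depth_sd,
                                        lower_da, p$max_archetype_chain)))
    d_e <- as.integer(round(rtruncnorm1(p$element_depth_mean,
                                        p$element_depth_sd,
                                        d_a + SKELETON_DEPTH + 1)))
    w <- sample_width_target(p)
    pos <- if (!is.na(fam)) chain_positions(var, ml, d_a) else integer(0)
    classes <- spine_classes(i, d_a, fam, pos)
    root <- build_one_structure(i, classes, d_e, w)
    entries[[i]] <- list(idx = i, family = fam, maxlevel = ml,
                         variant = var, root = root)
  }
  structure(list(profile = p, entries = entries, queries = emit_queries()),
            class = "structure_library")
}

#' @export
print.structure_library <- function(x, ...) {
  resp <- sum(!is.na(vapply(x$entries, `[[`, character(1), "family")))
  cat(sprintf("<structure_library> %d structures (%d responder hosts)\n",
              length(x$entries), resp))
  invisible(x)
}

# -- query workload -----------------------------------------------------------

#' Emit the 20-query workload
#'
#' Five query types crossed with containment levels 2–5.  Types 1–2 are
#' projection-only over the family-a chain (one and two SELECT items);
#' types 3–5 add WHERE predicates over the family-b chain (single
#' predicate, AND of two, OR of two).
#'
#' @return Named character vector of 20 AQL texts, names `"t<type>_l<level>"`.
#' @export
emit_queries <- function() {
  out <- character(0)
  for (type in 1:5) {
    fam <- if (type <= 2L) "a" else "b"
    for (level in 2:5) {
      from <- paste0("FROM EHR e")
      for (k in seq_len(level)) {
        from <- paste0(from, sprintf(" CONTAINS %s x%d [%s]",
                                     chain_rm_type(k), k,
                                     chain_class(fam, k)))
      }
      v <- paste0("x", level)
      mag <- paste0(v, SKELETON_PATH)
      uni <- paste0(v, SKELETON_UNITS_PATH)
      text <- switch(type,
        paste0("SELECT ", mag, " ", from),
        paste0("SELECT ", mag, ", ", uni, " ", from),
        paste0("SELECT ", mag, " ", from, " WHERE ", mag, " >= 140"),
        paste0("SELECT ", mag, " ", from, " WHERE ", mag,
               " >= 140 AND ", uni, " = 'mm[Hg]'"),
        paste0("SELECT ", mag, " ", from, " WHERE ", mag,
               " >= 140 OR ", uni, " = 'mm[Hg]'"))
      out[sprintf("t%d_l%d", type, level)] <- text
    }
  }
  out
}

# -- record instantiation -----------------------------------------------------

# Deep copy of a structure root with fresh leaf values and (optionally)
# shuffled sibling order.  `satisfy` plants predicate-satisfying values in
# every value skeleton; otherwise values are drawn outside the predicate
# ranges.
instantiate_root <- function(root, satisfy = FALSE, shuffle = TRUE) {
  fill <- function(x, key) {
    if (!is.list(x)) {
      if (identical(key, "magnitude")) {
        return(if (satisfy) round(stats::runif(1L, 140.1, 180), 1)
               else round(stats::runif(1L, 60, 139.5), 1))
      }
      if (identical(key, "units")) {
        return(if (satisfy) "mm[Hg]" else sample(c("kg", "cm", "bpm"), 1L))
      }
      if (identical(key, "v")) return(round(stats::runif(1L, 0, 1000), 1))
      return(x)
    }
    nm <- names(x)
    out <- x
    for (i in seq_along(x)) {
      out[[i]] <- fill(x[[i]], if (is.null(nm)) NULL else nm[[i]])
    }
    if (shuffle && length(out) > 1L) {
      ord <- sample.int(length(out))
      if (!is.null(nm)) {
        # keep archetype_class in front; permute the attribute keys
        fixed <- which(nm %in% RESERVED_NODE_KEYS)
        ord <- c(fixed, setdiff(ord, fixed))
      }
      out <- out[ord]
    }
    out
  }
  fill(root, NULL)
}

#' Instantiate one record from a library entry
#'
#' @param entry A library entry (`library$entries[[i]]`).
#' @param record_id Identifier for the new record.
#' @param satisfy Plant predicate-satisfying leaf values.
#' @param shuffle Randomly permute sibling order (structure id is invariant
#'   under this).
#' @return An `ehr_record`.
#' @export
instantiate_record <- function(entry, record_id, satisfy = FALSE,
                               shuffle = TRUE) {
  new_record(instantiate_root(entry$root, satisfy, shuffle), record_id,
             created_at = "2024-01-01T00:00:00Z")
}

# -- corpus generation --------------------------------------------------------

#' Generate a seeded corpus with a ground-truth manifest
#'
#' Plants exactly `round(match_fraction * n_records * scale)` responders
#' per family and level (responder sets nested across levels), labels
#' `round(filler_fraction * n)` records as filler and fills the remainder
#' with padding records; filler and padding instantiate non-responder
#' structures and match none of the 20 queries.
#'
#' @param library A [build_structure_library()] result.
#' @param scale Fraction of the profile's `n_records` to generate.
#' @param variant Placement variant (dataset index) used for responders.
#' @param out Optional path; when given, the JSON lines are streamed to it.
#' @param id_offset Integer added to the sequential record numbers, so that
#'   corpora generated in several batches carry disjoint record ids.
#' @return A list with `lines` (character vector, `NULL` when `out` is
#'   given), `manifest` and `path`.
#' @export
generate_corpus <- function(library, scale = 1, variant = 1L, out = NULL,
                            id_offset = 0L) {
  stopifnot(inherits(library, "structure_library"), scale > 0, scale <= 1)
  p <- library$profile
  n <- as.integer(floor(p$n_records * scale))
  set.seed(p$seed + 1L)

  counts <- lapply(p$match_fraction, function(f) {
    v <- vapply(f, function(x) as.integer(round(x * n)), integer(1))
    if (is.unsorted(rev(v))) stop("generation error: rounded per-level ",
                                  "counts increase with level")
    v
  })
  cell_sizes <- lapply(counts, function(v) {
    c(v[1:3] - v[2:4], v[4])           # records whose maxlevel is 2,3,4,5
  })
  n_resp <- sum(vapply(counts, `[[`, integer(1), "2"))
  n_filler <- as.integer(round(p$filler_fraction * n))
  n_padding <- n - n_resp - n_filler
  if (n_padding < 0L) stop("generation error: responders plus filler ",
                           "exceed the corpus size")

  fams <- vapply(library$entries, `[[`, character(1), "family")
  mls <- vapply(library$entries, `[[`, integer(1), "maxlevel")
  vars <- vapply(library$entries, `[[`, integer(1), "variant")
  filler_pool <- which(is.na(fams))
  if (n_resp > 0L) {
    pools <- lapply(c(a = "a", b = "b"), function(fam) {
      lapply(stats::setNames(2:5, as.character(2:5)), function(m) {
        pool <- which(!is.na(fams) & fams == fam & mls == m &
                        vars == as.integer(variant))
        if (!length(pool)) stop("generation error: library hosts no ",
                                "structures for family ", fam, " maxlevel ",
                                m, " variant ", variant)
        pool
      })
    })
  }
  if (!length(filler_pool) && (n_filler + n_padding) > 0L) {
    stop("generation error: library has no non-responder structures")
  }

  # role table in a seeded random emission order
  roles <- character(n); role_ml <- integer(n)
  pos <- 1L
  for (fam in names(cell_sizes)) {
    for (mi in seq_along(cell_sizes[[fam]])) {
      k <- cell_sizes[[fam]][mi]
      if (k > 0L) {
        roles[pos:(pos + k - 1L)] <- fam
        role_ml[pos:(pos + k - 1L)] <- mi + 1L
        pos <- pos + k
      }
    }
  }
  if (n_filler > 0L) { roles[pos:(pos + n_filler - 1L)] <- "filler"
                       pos <- pos + n_filler }
  if (n_padding > 0L) roles[pos:(pos + n_padding - 1L)] <- "padding"
  ord <- sample.int(n)
  roles <- roles[ord]; role_ml <- role_ml[ord]

  ids <- sprintf("rec-%07d", seq_len(n) + as.integer(id_offset))
  con <- NULL
  if (!is.null(out)) {
    con <- file(out, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
  }
  lines <- if (is.null(out)) character(n) else NULL
  for (i in seq_len(n)) {
    role <- roles[i]
    entry <- if (role %in% c("filler", "padding")) {
      library$entries[[filler_pool[sample.int(length(filler_pool), 1L)]]]
    } else {
      pool <- pools[[role]][[as.character(role_ml[i])]]
      library$entries[[pool[sample.int(length(pool), 1L)]]]
    }
    rec <- instantiate_record(entry, ids[i], satisfy = identical(role, "b"))
    ln <- write_record(rec)
    if (is.null(out)) lines[i] <- ln else writeLines(ln, con)
  }

  planted <- list()
  for (type in 1:5) {
    fam <- if (type <= 2L) "a" else "b"
    for (level in 2:5) {
      sel <- roles == fam & role_ml >= level
      planted[[sprintf("t%d_l%d", type, level)]] <- ids[sel]
    }
  }
  manifest <- list(
    seed = p$seed, scale = scale, variant = as.integer(variant),
    n_records = n,
    counts = vapply(planted, length, integer(1)),
    planted = planted,
    filler_ids = ids[roles == "filler"],
    n_filler = n_filler, n_padding = n_padding,
    profile = p[setdiff(names(p), "match_fraction")],
    match_fraction = p$match_fraction)
  list(lines = lines, manifest = manifest, path = out)
}

#' Generate a constant-load corpus in ten cumulative steps
#'
#' Each step adds `n_records * scale / 10` records with the profile's
#' responder/filler composition; step manifests are merged cumulatively.
#'
#' @param library A [build_structure_library()] result (typically with a
#'   high `filler_fraction` profile).
#' @param scale Fraction of the profile's `n_records` for the final step.
#' @return List of 10 steps, each `list(lines, manifest)` where `lines`
#'   holds only the records added by that step.
#' @export
generate_cl_corpus <- function(library, scale = 1) {
  p <- library$profile
  step_profile <- p
  step_profile$n_records <- floor(p$n_records / 10)
  step_lib <- library
  steps <- vector("list", 10L)
  n_step <- as.integer(floor(step_profile$n_records * scale))
  for (s in 1:10) {
    step_lib$profile <- step_profile
    step_lib$profile$seed <- p$seed + s
    steps[[s]] <- generate_corpus(step_lib, scale = scale,
                                  id_offset = (s - 1L) * n_step)
  }
  steps
}

# -- statistics ---------------------------------------------------------------

# Keyed children of a value: attribute/archetype entries, arrays flattened.
gen_keyed_children <- function(v) {
  if (!is.list(v)) return(list())
  nm <- names(v)
  if (is.null(nm)) {
    out <- list()
    for (el in v) out <- c(out, gen_keyed_children(el))
    return(out)
  }
  v[!(nm %in% RESERVED_NODE_KEYS)]
}

gen_level_counts <- function(root) {
  counts <- integer(0)
  walk <- function(v, d) {
    if (d > length(counts)) counts[d] <<- 0L
    counts[d] <<- counts[d] + 1L
    for (ch in gen_keyed_children(v)) walk(ch, d + 1L)
  }
  walk(root, 1L)
  counts
}

gen_element_depth <- function(root) length(gen_level_counts(root))

gen_max_width <- function(root) max(gen_level_counts(root))

gen_archetype_depth <- function(v) {
  if (!is.list(v)) return(0L)
  nm <- names(v)
  if (is.null(nm)) {      # array: elements sit at the same tree position
    if (!length(v)) return(0L)
    return(max(vapply(v, gen_archetype_depth, integer(1))))
  }
  here <- if (any(nm == "archetype_class")) 1L else 0L
  kids <- v[!(nm %in% RESERVED_NODE_KEYS)]
  if (!length(kids)) return(here)
  here + max(vapply(kids, gen_archetype_depth, integer(1)))
}

#' Distribution statistics of a library or list of trees
#'
#' Per structure: maximum archetype nesting depth, maximum element nesting
#' depth (all keyed elements, root counted at level 1, arrays transparent)
#' and maximum width (keyed elements at the widest level).
#'
#' @param x A `structure_library`, a list of root nodes, or a list of
#'   `ehr_record`s.
#' @return A list of summaries: means, sds, the width mode and table, the
#'   maxima, and the per-structure vectors.
#' @export
validate_statistics <- function(x) {
  roots <- if (inherits(x, "structure_library")) {
    lapply(x$entries, `[[`, "root")
  } else {
    lapply(x, function(e) if (inherits(e, "ehr_record")) e$root else e)
  }
  ad <- vapply(roots, gen_archetype_depth, integer(1))
  ed <- vapply(roots, gen_element_depth, integer(1))
  mw <- vapply(roots, gen_max_width, integer(1))
  wt <- table(mw)
  list(n = length(roots),
       mean_archetype_depth = mean(ad), sd_archetype_depth = stats::sd(ad),
       mean_element_depth = mean(ed), sd_element_depth = stats::sd(ed),
       mode_max_width = as.integer(names(wt)[which.max(wt)]),
       max_width = max(mw),
       max_archetype_chain = max(ad),
       width_table = wt,
       archetype_depths = ad, element_depths = ed, max_widths = mw)
}
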