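test_that("structure ids are invariant under sibling permutation", {
  set.seed(11)
  for (trial in 1:25) {
    root <- random_archetype_tree(4L)
    rec <- new_record(root, "p1")
    id1 <- extract_structure(rec)$structure_id
    for (k in 1:4) {
      shuffled <- shuffle_tree(root)
      expect_identical(extract_structure(new_record(shuffled, "p2"))$structure_id,
                       id1)
    }
  }
})

test_that("different structures get different ids", {
  a <- list(archetype_class = "openEHR-EHR-COMPOSITION.a.v1",
            x = list(archetype_class = "openEHR-EHR-SECTION.b.v1"))
  b <- list(archetype_class = "openEHR-EHR-COMPOSITION.a.v1",
            y = list(archetype_class = "openEHR-EHR-SECTION.b.v1"))
  c_ <- list(archetype_class = "openEHR-EHR-COMPOSITION.a.v1",
             x = list(archetype_class = "openEHR-EHR-SECTION.c.v1"))
  ids <- vapply(list(a, b, c_),
                function(r) extract_structure(r)$structure_id, character(1))
  expect_identical(length(unique(ids)), 3L)
  expect_match(ids, "^[0-9a-f]{16}$")
})

test_that("attribute values never influence the structure id", {
  r1 <- encounter_record("r1", mag = 1, units = "a")
  r2 <- encounter_record("r2", mag = 999, units = "zzz")
  expect_identical(extract_structure(r1)$structure_id,
                   extract_structure(r2)$structure_id)
})

test_that("registry registration is idempotent and counted", {
  idx <- structure_index()
  d <- extract_structure(encounter_record("r1"))
  expect_identical(register_structure(idx, d), d$structure_id)
  register_structure(idx, d)
  expect_identical(structure_count(idx), 1L)
  st <- index_stats(idx)
  expect_identical(st$n_structures, 1L)
  expect_identical(st$structures$n_archetypes, 2L)
})

test_that("containment lookup equals the recursive reference matcher", {
  set.seed(23)
  for (trial in 1:20) {
    idx <- structure_index()
    roots <- lapply(1:15, function(i) random_archetype_tree(sample(2:5, 1)))
    for (r in roots) register_structure(idx, extract_structure(r))
    chains <- list(
      "openEHR-EHR-SECTION.rnd_1",
      c("openEHR-EHR-SECTION.rnd_1", "openEHR-EHR-SECTION.rnd_2"),
      c("*", "openEHR-EHR-SECTION.rnd_3.v1"),
      c("openEHR-EHR-SECTION.rnd_2", "*", "openEHR-EHR-SECTION.rnd_4"))
    for (ch in chains) {
      got <- lookup_containment(idx, ch)
      # reference answer, computed per registered structure by the
      # independent recursive matcher over the same canonical trees
      for (m in got) {
        node <- get(m$structure_id, envir = idx$structures)
        rebuilt <- snode_as_record_tree(node)
        expect_identical(m$paths, baseline_chain_paths(rebuilt, ch))
      }
      # no structure outside the match set may satisfy the chain
      missed <- setdiff(ls(idx$structures),
                        vapply(got, `[[`, character(1), "structure_id"))
      for (id in missed) {
        rebuilt <- snode_as_record_tree(get(id, envir = idx$structures))
        expect_length(baseline_chain_paths(rebuilt, ch), 0L)
      }
    }
  }
})

test_that("version-insensitive and wildcard patterns match as documented", {
  root <- list(archetype_class = "openEHR-EHR-COMPOSITION.enc.v2.lbl-00042",
               c1 = list(archetype_class = "openEHR-EHR-OBSERVATION.bp.v1"))
  idx <- structure_index()
  register_structure(idx, extract_structure(root))
  expect_length(lookup_containment(idx, c("openEHR-EHR-COMPOSITION.enc",
                                          "openEHR-EHR-OBSERVATION.bp")), 1L)
  expect_length(lookup_containment(idx, c("*", "*")), 1L)
  expect_length(lookup_containment(idx, "openEHR-EHR-COMPOSITION.enc.v1"), 0L)
  expect_length(lookup_containment(idx, c("openEHR-EHR-OBSERVATION.bp",
                                          "openEHR-EHR-COMPOSITION.enc")), 0L)
})

test_that("registry export/import round trips", {
  idx <- structure_index()
  set.seed(31)
  for (i in 1:10) {
    register_structure(idx, extract_structure(random_archetype_tree(3L)))
  }
  lines <- export_registry(idx)
  idx2 <- import_registry(lines)
  expect_identical(sort(ls(idx2$structures)), sort(ls(idx$structures)))
  m1 <- lookup_containment(idx, "openEHR-EHR-SECTION.rnd_1")
  m2 <- lookup_containment(idx2, "openEHR-EHR-SECTION.rnd_1")
  expect_identical(m1, m2)
})
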