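test_that("baseline scan answers a handmade corpus with known truth", {
  # three records with hand-computable answers
  lines <- c(
    write_record(encounter_record("b1", mag = 150, units = "mm[Hg]")),
    write_record(encounter_record("b2", mag = 120, units = "mm[Hg]")),
    write_record(new_record(bp_node(160, "kg"), "b3")))  # no COMPOSITION
  chain <- paste("FROM EHR e CONTAINS COMPOSITION c [openEHR-EHR-COMPOSITION.encounter]",
                 "CONTAINS OBSERVATION o [openEHR-EHR-OBSERVATION.blood_pressure.v1]")
  sel <- "SELECT o/data/events[at0006]/value/magnitude"
  res_all <- baseline_scan(paste(sel, chain), lines)
  expect_identical(attr(res_all, "record_ids"), c("b1", "b2"))
  res_pred <- baseline_scan(
    paste(sel, chain, "WHERE o/data/events[at0006]/value/magnitude >= 140"),
    lines)
  expect_identical(attr(res_pred, "record_ids"), "b1")
  res_or <- baseline_scan(
    paste(sel, chain, "WHERE o/data/events[at0006]/value/magnitude >= 140",
          "OR o/data/events[at0006]/value/units = 'mm[Hg]'"), lines)
  expect_identical(attr(res_or, "record_ids"), c("b1", "b2"))
  expect_identical(attr(res_all, "n_examined"), 3L)
})

test_that("malformed lines are counted and skipped, not fatal", {
  lines <- c(write_record(encounter_record("ok1")), "oops", "{", "")
  expect_warning(
    res <- baseline_scan("SELECT e FROM EHR e", lines),
    "malformed")
  expect_identical(as.integer(res), 1L)
  expect_identical(attr(res, "n_malformed"), 3L)
  expect_identical(attr(res, "n_examined"), 1L)
})

test_that("every record is examined exactly once", {
  cp <- oracle_corpus()
  res <- baseline_scan(cp$queries[["t1_l2"]], cp$records)
  expect_identical(attr(res, "n_examined"), length(cp$records))
})

test_that("fetch mode produces the same result-set shape as the engine", {
  lines <- c(write_record(encounter_record("f1", mag = 150)),
             write_record(encounter_record("f2", mag = 145)))
  q <- paste("SELECT o/data/events[at0006]/value/magnitude AS mag FROM EHR e",
             "CONTAINS COMPOSITION c [openEHR-EHR-COMPOSITION.encounter]",
             "CONTAINS OBSERVATION o [openEHR-EHR-OBSERVATION.blood_pressure.v1]")
  b <- baseline_scan(q, lines, mode = "fetch")
  sys <- ingest_lines(lines)
  e <- run_query(sys, q, mode = "fetch")
  expect_identical(b$columns, e$result$columns)
  expect_identical(b$rows, e$result$rows)
})

test_that("reference chain matcher handles gap archetypes and duplicates", {
  # chain a > c must match through an intervening b, and duplicate
  # occurrences must yield deduplicated sorted paths
  leaf_c <- list(archetype_class = "openEHR-EHR-OBSERVATION.cc.v1")
  mid_b <- list(archetype_class = "openEHR-EHR-SECTION.bb.v1",
                deeper = leaf_c)
  root <- list(archetype_class = "openEHR-EHR-COMPOSITION.aa.v1",
               one = mid_b,
               two = list(leaf_c, leaf_c))   # array with duplicates
  paths <- baseline_chain_paths(root, c("openEHR-EHR-COMPOSITION.aa",
                                        "openEHR-EHR-OBSERVATION.cc"))
  expect_identical(paths, c("/one/deeper", "/two"))
  expect_identical(
    baseline_chain_paths(root, c("openEHR-EHR-SECTION.bb",
                                 "openEHR-EHR-COMPOSITION.aa")),
    character(0))
})
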