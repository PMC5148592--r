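test_that("ingest stores records with structure ids and reports failures", {
  lines <- c(write_record(encounter_record("i1")),
             "{broken json",
             write_record(encounter_record("i2", mag = 150)))
  sys <- ehr_system(driver_config())
  expect_warning(rep <- ingest_corpus(sys, lines), "failed to ingest")
  expect_identical(rep$records_stored, 2L)
  expect_identical(rep$failures, 1L)
  expect_identical(rep$structures_registered, 1L)
  g <- get_record(sys$session, "i1")
  expect_match(g$structure_id, "^[0-9a-f]{16}$")
})

test_that("run_query resolves chains through the registry only", {
  sys <- ehr_system(driver_config())
  ingest_corpus(sys, c(write_record(encounter_record("q1", mag = 150)),
                       write_record(encounter_record("q2", mag = 100))))
  q <- paste("SELECT o/data/events[at0006]/value/magnitude AS mag",
             "FROM EHR e CONTAINS COMPOSITION c [openEHR-EHR-COMPOSITION.encounter]",
             "CONTAINS OBSERVATION o [openEHR-EHR-OBSERVATION.blood_pressure.v1]",
             "WHERE o/data/events[at0006]/value/magnitude >= 140")
  res <- run_query(sys, q, mode = "fetch")
  expect_identical(res$count, 1L)
  expect_identical(result_record_ids(res), "q1")
  expect_identical(res$result$rows$mag, 150)
  ex <- explain_query(sys, q)
  expect_identical(ex$n_structures, 1L)
  expect_identical(unname(ex$paths_per_structure), 1L)
})

test_that("a query without CONTAINS falls back to the full registry", {
  sys <- ehr_system(driver_config())
  ingest_corpus(sys, c(write_record(encounter_record("f1")),
                       write_record(encounter_record("f2"))))
  expect_warning(res <- run_query(sys, "SELECT e FROM EHR e"),
                 "no containment chain")
  expect_identical(res$count, 2L)
})

test_that("auto mode fetches iff the count is at or below the threshold", {
  sys <- ehr_system(driver_config(fetch_threshold = 2L))
  lines <- vapply(1:5, function(i) {
    write_record(encounter_record(sprintf("t%d", i),
                                  mag = if (i <= 2) 150 else 100))
  }, character(1))
  ingest_corpus(sys, lines)
  base <- paste("SELECT o/data/events[at0006]/value/magnitude FROM EHR e",
                "CONTAINS COMPOSITION c [openEHR-EHR-COMPOSITION.encounter]",
                "CONTAINS OBSERVATION o [openEHR-EHR-OBSERVATION.blood_pressure.v1]")
  over <- run_query(sys, base, mode = "auto")          # count 5 > 2
  expect_false(over$fetched)
  expect_null(over$result)
  at <- run_query(sys, paste(base, "WHERE o/data/events[at0006]/value/magnitude >= 140"),
                  mode = "auto")                       # count 2 == threshold
  expect_true(at$fetched)
  expect_identical(at$result$total_count, 2L)
})

test_that("result sets have one row per matching record, id-ordered", {
  cp <- oracle_corpus()
  sys <- ingest_lines(cp$lines)
  for (nm in c("t1_l3", "t2_l2", "t4_l5")) {
    res <- run_query(sys, cp$queries[[nm]], mode = "fetch")
    rows <- res$result$rows
    ids <- result_record_ids(res)
    expect_identical(nrow(rows), res$count)
    expect_identical(ids, sort(ids, method = "radix"))
    expect_identical(length(ids), res$count)
  }
  q2 <- parse_aql(cp$queries[["t2_l2"]])
  res2 <- run_query(sys, q2, mode = "fetch")
  expect_length(res2$result$columns, 2L)
  expect_true(all(!is.na(res2$result$rows[[1]])))
})

test_that("engine counts are insensitive to the placement variant", {
  lib <- default_library()
  lib$profile$n_records <- 1200
  counts_by_variant <- lapply(1:5, function(v) {
    cp <- generate_corpus(lib, scale = 1, variant = v)
    sys <- ingest_lines(cp$lines)
    vapply(lib$queries, function(q) run_query(sys, q, mode = "count")$count,
           integer(1))
  })
  for (v in 2:5) {
    expect_identical(counts_by_variant[[v]], counts_by_variant[[1]])
  }
})
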