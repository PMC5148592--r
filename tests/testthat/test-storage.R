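test_that("the reference driver passes the conformance suite", {
  res <- driver_conformance(driver_config())
  expect_true(all(res$passed), info = paste(res$check[!res$passed],
                                            res$detail[!res$passed],
                                            collapse = "; "))
  expect_gte(nrow(res), 12L)
})

test_that("driver factory knows the embedded and reserved drivers", {
  expect_true(all(c("memory", "mongodb", "elasticsearch") %in%
                    list_drivers()))
  expect_error(connect_driver(driver_config(driver = "mongodb")),
               "driver not installed")
  expect_error(connect_driver(driver_config(driver = "nope")),
               "connection error")
})

test_that("random CRUD sequences match an independent reference model", {
  set.seed(41)
  s <- connect_driver(driver_config())
  # reference model: plain R list of version stacks, coded independently
  model <- list()
  mkroot <- function(v) {
    # leaves are doubles: JSON carries no integer/double distinction
    list(archetype_class = "openEHR-EHR-OBSERVATION.probe.v1",
         data = list(value = as.numeric(v)))
  }
  sid <- extract_structure(new_record(mkroot(0), "tmp"))$structure_id
  ids <- sprintf("m%d", 1:6)
  for (step in 1:300) {
    id <- sample(ids, 1L)
    op <- sample(c("put", "get", "update", "rollback", "delete"), 1L)
    if (op == "put") {
      r <- new_record(mkroot(step), id, structure_id = sid)
      got <- tryCatch({ put_record(s, r); "ok" }, error = function(e) "err")
      want <- if (is.null(model[[id]])) "ok" else "err"
      expect_identical(got, want)
      if (want == "ok") model[[id]] <- list(stack = list(mkroot(step)),
                                            deleted = FALSE)
    } else if (op == "get") {
      got <- tryCatch(get_record(s, id), error = function(e) "err")
      if (is.null(model[[id]])) {
        expect_identical(got, "err")
      } else {
        st <- model[[id]]$stack
        expect_identical(got$root, st[[length(st)]])
        expect_identical(got$version, length(st))
      }
    } else if (op == "update") {
      got <- tryCatch(update_record(s, id, mkroot(step + 0.5)),
                      error = function(e) "err")
      if (is.null(model[[id]])) {
        expect_identical(got, "err")
      } else {
        model[[id]]$stack <- c(model[[id]]$stack, list(mkroot(step + 0.5)))
        expect_identical(got, length(model[[id]]$stack))
      }
    } else if (op == "rollback") {
      got <- tryCatch(rollback_record(s, id), error = function(e) "err")
      if (is.null(model[[id]]) || length(model[[id]]$stack) < 2L) {
        expect_identical(got, "err")
      } else {
        model[[id]]$stack <-
          model[[id]]$stack[-length(model[[id]]$stack)]
      }
    } else {
      got <- tryCatch({ delete_record(s, id); "ok" },
                      error = function(e) "err")
      if (is.null(model[[id]])) expect_identical(got, "err")
      else model[[id]]$deleted <- TRUE
    }
  }
  # final state: queryable records are exactly the undeleted model entries
  qom <- parse_aql(
    "SELECT o FROM EHR e CONTAINS OBSERVATION o [openEHR-EHR-OBSERVATION.probe.v1]")
  live <- names(model)[vapply(model, function(m) !m$deleted, logical(1))]
  cnt <- execute_query(s, qom, list(list(structure_id = sid, paths = "")),
                       mode = "count")
  expect_identical(cnt, length(live))
})

test_that("key escaping is reversible for reserved characters", {
  s <- connect_driver(driver_config())
  r <- new_record(list(archetype_class = "openEHR-EHR-OBSERVATION.esc.v1",
                       `a.b$c%d` = list(`x.y` = "v", plain = 1)),
                  record_id = "esc")
  doc <- encode_record(s, r)
  expect_false(grepl("a.b$c%d", doc, fixed = TRUE))
  expect_identical(decode_record(s, doc), r)
  expect_error(decode_record(s, "{broken"), "corruption error")
})

test_that("snapshot persistence restores records and versions", {
  path <- tempfile(fileext = ".jsonl")
  s <- connect_driver(driver_config(persistence_path = path))
  put_with_sid(s, encounter_record("snap1", mag = 100))
  update_record(s, "snap1", encounter_record("snap1", mag = 160)$root)
  put_with_sid(s, encounter_record("snap2"))
  delete_record(s, "snap2")
  save_snapshot(s)
  s2 <- connect_driver(driver_config(persistence_path = path))
  expect_identical(store_size(s2), 2L)
  g <- get_record(s2, "snap1")
  expect_identical(g$version, 2L)
  expect_identical(length(record_versions(s2, "snap1")$versions), 2L)
  # deleted records stay hidden from queries after a reload
  sid <- extract_structure(encounter_record("x"))$structure_id
  qom <- parse_aql(
    "SELECT o FROM EHR e CONTAINS COMPOSITION c [openEHR-EHR-COMPOSITION.encounter.v1] CONTAINS OBSERVATION o [openEHR-EHR-OBSERVATION.blood_pressure.v1]")
  cnt <- execute_query(s2, qom, list(list(structure_id = sid, paths = "/content[at0001]")),
                       mode = "count")
  expect_identical(cnt, 1L)
  unlink(path)
})

test_that("stale index entries are tolerated and ignored", {
  s <- connect_driver(driver_config())
  sid <- put_with_sid(s, encounter_record("a1"))
  qom <- parse_aql(
    "SELECT o FROM EHR e CONTAINS COMPOSITION c [openEHR-EHR-COMPOSITION.encounter.v1] CONTAINS OBSERVATION o [openEHR-EHR-OBSERVATION.blood_pressure.v1]")
  matches <- list(list(structure_id = "deadbeefdeadbeef", paths = "/x"),
                  list(structure_id = sid, paths = "/content[at0001]"))
  expect_identical(execute_query(s, qom, matches, mode = "count"), 1L)
})

test_that("inactive records are invisible to queries", {
  s <- connect_driver(driver_config())
  r <- encounter_record("inact")
  r$active <- FALSE
  sid <- put_with_sid(s, r)
  qom <- parse_aql(
    "SELECT o FROM EHR e CONTAINS COMPOSITION c [openEHR-EHR-COMPOSITION.encounter.v1] CONTAINS OBSERVATION o [openEHR-EHR-OBSERVATION.blood_pressure.v1]")
  cnt <- execute_query(s, qom, list(list(structure_id = sid,
                                         paths = "/content[at0001]")),
                       mode = "count")
  expect_identical(cnt, 0L)
})
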