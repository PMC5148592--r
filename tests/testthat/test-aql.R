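test_that("queries parse into selection, location and condition", {
  q <- parse_aql(paste(
    "SELECT o/data/events[at0006]/value/magnitude AS mag, e",
    "FROM EHR e CONTAINS COMPOSITION c [openEHR-EHR-COMPOSITION.enc.v1]",
    "CONTAINS OBSERVATION o [openEHR-EHR-OBSERVATION.bp.v1]",
    "WHERE o/data/events[at0006]/value/magnitude >= 140",
    "AND NOT o/data/events[at0006]/value/units = 'kg'"))
  expect_length(q$selection$items, 2L)
  expect_identical(q$selection$items[[1]]$alias, "mag")
  expect_identical(q$location$ehr_variable, "e")
  expect_identical(containment_level(q), 2L)
  expect_identical(location_of(q)$patterns,
                   c("openEHR-EHR-COMPOSITION.enc.v1",
                     "openEHR-EHR-OBSERVATION.bp.v1"))
  expect_identical(q$condition$op, "and")
})

test_that("CONTAINS without a bracketed class is a wildcard", {
  q <- parse_aql("SELECT o FROM EHR e CONTAINS COMPOSITION c CONTAINS OBSERVATION o")
  expect_identical(location_of(q)$patterns, c("*", "*"))
})

test_that("parse and render are mutually inverse", {
  texts <- c(
    unname(emit_queries()),
    "SELECT e FROM EHR e",
    "SELECT o FROM EHR e CONTAINS OBSERVATION o [openEHR-EHR-OBSERVATION.bp.v1] WHERE EXISTS o/data/value",
    "SELECT o/v AS a, o/w AS b FROM EHR e CONTAINS OBSERVATION o WHERE o/v MATCHES {'x', 'y', 3.5} OR NOT (o/w = 1 AND o/v != 2)")
  for (t in texts) {
    q <- parse_aql(t)
    canonical <- render_aql(q)
    q2 <- parse_aql(canonical)
    expect_identical(q2, q)
    expect_identical(render_aql(q2), canonical)
  }
})

test_that("operator precedence is NOT over AND over OR", {
  q <- parse_aql(paste(
    "SELECT o FROM EHR e CONTAINS OBSERVATION o",
    "WHERE o/a = 1 OR o/b = 2 AND NOT o/c = 3"))
  expect_identical(q$condition$op, "or")
  expect_identical(q$condition$args[[2]]$op, "and")
  expect_identical(q$condition$args[[2]]$args[[2]]$op, "not")
})

test_that("unsupported clauses are rejected by name", {
  base <- "SELECT o FROM EHR e CONTAINS OBSERVATION o"
  expect_error(parse_aql(paste(base, "ORDER BY o/v")), "unsupported clause")
  expect_error(parse_aql(paste(base, "TIMEWINDOW P1Y")), "unsupported clause")
})

test_that("binding errors are reported", {
  expect_error(parse_aql("SELECT x FROM EHR e CONTAINS OBSERVATION o"),
               "unbound variable")
  expect_error(parse_aql(
    "SELECT o FROM EHR e CONTAINS OBSERVATION o WHERE z/v = 1"),
    "unbound variable")
  expect_error(parse_aql(
    "SELECT o FROM EHR o CONTAINS OBSERVATION o"),
    "duplicate variable")
})

test_that("syntax errors carry line and column positions", {
  expect_error(parse_aql("SELECT o FROM EHR e CONTAINS"), "syntax error")
  expect_error(parse_aql("SELECT , FROM EHR e"), "syntax error")
  expect_error(parse_aql("SELECT o FROM EHR e WHERE"), "syntax error")
  err <- tryCatch(parse_aql("SELECT o\nFROM EHR e ;"), error = identity)
  expect_match(conditionMessage(err), "line 2")
})

test_that("emitted workload has the documented shape", {
  qs <- emit_queries()
  expect_length(qs, 20L)
  for (nm in names(qs)) {
    q <- parse_aql(qs[[nm]])
    lvl <- as.integer(sub(".*_l", "", nm))
    type <- as.integer(sub("t(\\d).*", "\\1", nm))
    expect_identical(containment_level(q), lvl)
    expect_length(q$selection$items, if (type == 2L) 2L else 1L)
    if (type <= 2L) expect_null(q$condition)
    if (type == 3L) expect_identical(q$condition$op, "pred")
    if (type == 4L) expect_identical(q$condition$op, "and")
    if (type == 5L) expect_identical(q$condition$op, "or")
  }
})
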