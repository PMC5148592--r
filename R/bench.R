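# Benchmark harness: times the indexed engine against the sequential
# baseline over the 20-query workload, guarded by a correctness gate.

#' Run the query benchmark on a generated corpus
#'
#' First verifies, query by query, that the engine's record-id sets equal
#' the generator manifest's planted sets (and optionally the baseline
#' scanner's); timings are only reported when every query passes this
#' correctness gate.
#'
#' @param sys An [ehr_system()] already holding the corpus.
#' @param queries Named character vector of AQL texts (see
#'   [emit_queries()]).
#' @param manifest Corpus manifest from [generate_corpus()], or `NULL` to
#'   skip the manifest gate.
#' @param corpus Corpus lines or file path; when given, the baseline
#'   scanner is timed alongside the engine and included in the gate.
#' @param repetitions Number of timed repetitions per query.
#' @return A data frame with one row per query: query name, count, mean and
#'   sd of the per-phase times (index, count, fetch) and, when `corpus` is
#'   given, of the baseline scan time.
#' @export
run_benchmark <- function(sys, queries, manifest = NULL, corpus = NULL,
                          repetitions = 3L) {
  gate <- list()
  for (nm in names(queries)) {
    res <- run_query(sys, queries[[nm]], mode = "fetch")
    ids <- result_record_ids(res)
    if (!is.null(manifest)) {
      want <- sort(manifest$planted[[nm]], method = "radix")
      if (!identical(ids, want)) {
        gate[[nm]] <- list(engine = ids, expected = want)
      }
    }
    if (!is.null(corpus)) {
      b <- baseline_scan(queries[[nm]], corpus, mode = "count")
      if (!identical(ids, attr(b, "record_ids"))) {
        gate[[nm]] <- list(engine = ids, baseline = attr(b, "record_ids"))
      }
    }
  }
  if (length(gate)) {
    stop("correctness gate failed for ", length(gate), " quer",
         if (length(gate) == 1L) "y" else "ies", ": ",
         paste(names(gate), collapse = ", "))
  }

  rows <- lapply(names(queries), function(nm) {
    t_index <- t_count <- t_fetch <- t_base <- double(repetitions)
    cnt <- NA_integer_
    for (r in seq_len(repetitions)) {
      res <- run_query(sys, queries[[nm]], mode = "auto")
      cnt <- res$count
      t_index[r] <- res$timings[["index"]]
      t_count[r] <- res$timings[["count"]]
      t_fetch[r] <- res$timings[["fetch"]]
      if (!is.null(corpus)) {
        t0 <- proc.time()[["elapsed"]]
        baseline_scan(queries[[nm]], corpus, mode = "count")
        t_base[r] <- proc.time()[["elapsed"]] - t0
      }
    }
    data.frame(query = nm, count = cnt,
               index_mean = mean(t_index), index_sd = stats::sd(t_index),
               count_mean = mean(t_count), count_sd = stats::sd(t_count),
               fetch_mean = mean(t_fetch), fetch_sd = stats::sd(t_fetch),
               baseline_mean = if (is.null(corpus)) NA_real_
                               else mean(t_base),
               baseline_sd = if (is.null(corpus)) NA_real_
                             else stats::sd(t_base),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Constant-load growth benchmark
#'
#' Ingests the ten cumulative steps of a constant-load corpus and times the
#' workload after each step.
#'
#' @param library A [build_structure_library()] result.
#' @param scale Fraction of the profile's `n_records` for the final size.
#' @param repetitions Timed repetitions per step.
#' @return A data frame: step, records ingested so far, and the total
#'   workload time per step.
#' @export
run_cl_benchmark <- function(library, scale = 1, repetitions = 1L) {
  steps <- generate_cl_corpus(library, scale)
  sys <- ehr_system(driver_config())
  total <- 0L
  rows <- lapply(seq_along(steps), function(s) {
    ingest_corpus(sys, steps[[s]]$lines)
    total <<- total + length(steps[[s]]$lines)
    t <- double(repetitions)
    for (r in seq_len(repetitions)) {
      t0 <- proc.time()[["elapsed"]]
      for (q in library$queries) run_query(sys, q, mode = "count")
      t[r] <- proc.time()[["elapsed"]] - t0
    }
    data.frame(step = s, records = total, workload_mean = mean(t),
               workload_sd = if (repetitions > 1L) stats::sd(t) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
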