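---
title: "Structure-indexed containment queries over archetype-based health records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-indexed containment queries over archetype-based health records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehraql)
```

## The problem

Clinical data platforms built on two-level modelling store patient data as
deeply nested document trees. The reference model supplies generic node
types (`COMPOSITION`, `SECTION`, `OBSERVATION`, ...) and *archetypes*
constrain how those nodes nest for a particular clinical concept, e.g.
`openEHR-EHR-OBSERVATION.blood_pressure.v1`. A repository accumulates
millions of such documents, but the number of *distinct tree shapes* is
small — a hospital uses a bounded set of templates. Containment queries
("find records where a blood-pressure observation sits inside an encounter
composition") can therefore be answered in two cheap steps instead of one
expensive scan:

1. resolve the containment chain against a registry of deduplicated
   document *structures*, yielding the concrete absolute paths where the
   chain occurs, and
2. evaluate predicates only on the records whose stored `structure_id`
   points at a matching structure, at exactly those paths.

This package implements that data-access layer end to end: the record
model, the structure index, a query-language subset, a pluggable storage
driver, the indexed query engine, an independent sequential baseline, a
statistical corpus generator with ground-truth manifests, and a benchmark
harness with a correctness gate.

## Record model

A record is a JSON document with reserved metadata keys (`record_id`,
`ehr_id`, `version`, `active`, timestamps, `structure_id`) and a `root`
tree in which four node kinds are distinguished purely by shape:

* **archetype node** — a named list carrying `archetype_class`;
* **attribute map** — a named list without it;
* **array** — an unnamed list, transparent to paths (fan-out);
* **leaf** — a length-one atomic value.

`read_record()` validates the dialect strictly (class syntax, reserved
keys, path annotations) and `write_record()` serializes it back
byte-deterministically; the serializer is implemented in C++ because it
dominates corpus-generation time.

## Structure extraction and canonical identity

`extract_structure()` strips a record down to its archetype skeleton: one
node per archetype, labelled with its class and its attribute path from
the nearest containing archetype. Values, leaves and sibling order are
discarded. The skeleton is canonicalized by sorting children on their
serialization `"(" class "|" path "|" children ")"` recursively, and the
`structure_id` is the first 16 hex digits of the SHA-256 of the canonical
form. Two consequences drive the whole design:

* any permutation of siblings or array elements yields the same id
  (tested property), and
* values never influence the id, so a repository with millions of records
  holds only as many registry entries as it has template shapes.

`lookup_containment()` answers a chain of class patterns (exact,
version-insensitive, or wildcard) with every registered structure that
contains the chain, together with all distinct root-to-innermost absolute
paths, deduplicated and sorted. Gap archetypes between chain members are
allowed; the search is a DFS carrying the set of chain prefixes achievable
along the ancestor spine.

## Query language subset

`parse_aql()` accepts `SELECT` / `FROM EHR` / `CONTAINS` / `WHERE` with
comparison, `MATCHES`, `NOT`, `AND`, `OR` and parentheses; `ORDER BY` and
`TIMEWINDOW` are rejected as unsupported clauses with source positions.
The parser produces a query-object model; `render_aql()` inverts it
(`parse ∘ render` is an identity on the rendered form, a tested
property). The engine defines a record as matching when *some* instance
of the innermost chain archetype, reachable through a consistent
assignment of the chain, satisfies the condition; a missing operand makes
a predicate false, and each matching record contributes exactly one result
row, in ascending `record_id` order.

## Storage and engine

Storage is behind a driver interface (connect, put/get/update/rollback/
delete, encode/decode with reserved-character key escaping, count/fetch
given `(structure_id, paths)` matches). The in-memory reference driver
supports version stacks, snapshot persistence and a model-based
conformance suite (`driver_conformance()`); `mongodb` and
`elasticsearch` names are reserved in the factory for external backends.
`run_query()` times its three phases — registry lookup, driver count,
optional fetch — and fetches rows only when the count is at or below a
configurable threshold (auto mode).

`baseline_scan()` is a deliberately independent sequential matcher that
parses every record line and evaluates the chain recursively without any
index; `compare_with_baseline()` reports count differences and the
symmetric difference of record-id sets. The benchmark harness refuses to
report timings unless every workload query passes this gate.

## Synthetic corpus design

The generator builds a library of base structures and then instantiates
records from it; every statistical target below is a *profile parameter*,
fixed before any measurement.

**Spines and depth.** Each structure has a spine of `d_a` archetypes,
`d_a` drawn from a truncated normal (mean 6.7, sd 1.7, upper bound 12 so
the longest archetype chain stays at 12). Between consecutive spine
archetypes sit attribute gaps whose lengths sum so that the total element
depth matches a truncated-normal draw (mean 66, sd 15.7). Truncated
normals were chosen because both depth distributions are unimodal,
right-bounded by practical template limits, and need independent control
of mean and spread.

**Width.** The innermost archetype carries a cluster array sized so the
widest tree level hits a target drawn from a two-component mixture:
88% a shifted binomial centred on 8 (producing the modal width 8) and
12% a shifted log-normal tail (producing rare very wide structures, up to
a cap). A mixture is the simplest family that yields a sharp mode with a
long right tail.

**Responders and queries.** Twenty query templates are emitted — five
condition variants at containment levels 2–5. Types 1–2 target one
archetype-class family, types 3–5 a second; within a family, the level-`l`
chain is a prefix of the level-5 chain, so the responder set at level
`l+1` is by construction a subset of the responder set at level `l`
(nesting is asserted, not tuned). Records planted for a family get values
that satisfy all of that family's condition variants simultaneously, so
the five variants at one level answer with identical sets — variants probe
the evaluator, levels probe the index. Match fractions follow a geometric
progression between the level-2 and level-5 endpoints. Filler records
instantiate structures that contain neither family and match none of the
twenty queries (verified by the baseline scanner in the tests); padding
records fill the remainder of the corpus.

**Scale.** The full-size corpus is 10 million records with level-2
responder fractions of 10% (family a) and 0.1% (family b) and 50%
filler. Construction counts are verified at 1/250 scale (40,000
records), the largest factor at which every planted per-level count is an
exact integer, and multiplied back up for comparison. The manifest
written next to each corpus records the planted record-id set per query,
the filler ids and all profile parameters, making every corpus its own
ground truth.

## Problem sizes and runtime

On one CPU the default 2600-structure library builds in a few seconds;
the 40,000-record verification corpus generates in under two minutes and
ingests at roughly a millisecond per record. The twenty-query workload
runs in seconds because registry lookup touches 2600 skeletons instead of
40,000 documents; the sequential baseline on the same corpus is the
contrast the benchmark harness reports.

## Reproducing the numbers

```{r, eval = FALSE}
lib <- build_structure_library(generator_profile())
validate_statistics(lib)[c("mean_archetype_depth", "mean_element_depth",
                           "mode_max_width", "max_archetype_chain")]

cp <- generate_corpus(lib, scale = 1 / 250)
sys <- ehr_system(driver_config())
ingest_corpus(sys, cp$lines)
run_benchmark(sys, lib$queries, manifest = cp$manifest)
```

The same measurements are produced non-interactively by
`scripts/acceptance.R`.
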