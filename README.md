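# ehraql

Archetype containment queries over structured health records.

## The problem

Clinical repositories built on two-level modelling (reference model +
archetypes, as in openEHR) store patient data as deeply nested JSON
document trees. Corpora grow to millions of records, but the number of
distinct *tree shapes* stays small because records are instantiated from a
bounded set of templates. `ehraql` exploits this: every ingested record's
value-free archetype skeleton is canonicalized (sibling order and values
discarded) and hashed into a 16-hex-digit `structure_id`. A containment
query such as

> find records where a blood-pressure observation sits inside an
> encounter composition

is then answered by first resolving the chain against the small structure
registry — yielding the concrete absolute paths at which the chain occurs
in each matching shape — and only then touching the records that carry a
matching `structure_id`, at exactly those paths. No per-record tree
search is needed at query time.

The package provides, end to end:

* a strict record model (`read_record()` / `write_record()`, with a C++
  serializer for byte-deterministic output);
* the structure index (`extract_structure()`, `register_structure()`,
  `lookup_containment()`; ids are invariant under any sibling
  permutation);
* an AQL subset parser and renderer (`parse_aql()`, `render_aql()`:
  SELECT / FROM EHR / CONTAINS / WHERE with MATCHES, NOT, AND, OR);
* a storage-driver layer with an embedded in-memory reference driver
  (versioning, rollback, snapshot persistence) and a model-based
  conformance suite (`driver_conformance()`);
* the indexed engine (`ehr_system()`, `ingest_corpus()`, `run_query()`,
  with per-phase timings and count-vs-fetch auto mode);
* an index-free sequential scanner used as a correctness oracle
  (`baseline_scan()`, `compare_with_baseline()`);
* a seeded synthetic-corpus generator with planted ground truth
  (`generator_profile()`, `build_structure_library()`,
  `generate_corpus()`, `validate_statistics()`);
* a benchmark harness whose timings are gated on correctness
  (`run_benchmark()`, `run_cl_benchmark()`), plus a command-line driver
  in `inst/exec/ehraql`.

## Worked example

`inst/extdata/encounter-example.json` holds a seven-archetype encounter
record whose blood-pressure observation is nested five sections deep.

```r
library(ehraql)

path <- system.file("extdata", "encounter-example.json", package = "ehraql")
rec  <- read_record(readLines(path))

sys <- ehr_system(driver_config())
ingest_record(sys, rec)

res <- run_query(sys, "
  SELECT o/data/events[at0006]/value/magnitude AS mag
  FROM EHR e
  CONTAINS COMPOSITION c [openEHR-EHR-COMPOSITION.encounter]
  CONTAINS OBSERVATION o [openEHR-EHR-OBSERVATION.blood_pressure.v1]
  WHERE o/data/events[at0006]/value/magnitude >= 140", mode = "fetch")

res$count
#> [1] 1
result_record_ids(res)
#> [1] "encounter-0001"
res$result$rows$mag
#> [1] 142.5

explain_query(sys, "
  SELECT o FROM EHR e
  CONTAINS COMPOSITION c [openEHR-EHR-COMPOSITION.encounter]
  CONTAINS OBSERVATION o [openEHR-EHR-OBSERVATION.blood_pressure.v1]")$paths_per_structure
#> ac4d3bac73784af1
#>                1
```

The chain resolves to exactly one registered structure and one absolute
path (`/content[at0001]` repeated six times), and the predicate then runs
only against records of that structure.

## Synthetic corpora with ground truth

```r
lib <- build_structure_library(generator_profile())   # 2600 base structures
cp  <- generate_corpus(lib, scale = 1/250)            # 40,000 records + manifest

sys <- ehr_system(driver_config())
ingest_corpus(sys, cp$lines)

run_query(sys, lib$queries[["t1_l2"]], mode = "count")$count  # == length(cp$manifest$planted$t1_l2)
```

Every corpus carries a manifest with the exact planted record-id set per
query template, so correctness is checkable without any oracle run;
`compare_with_baseline()` additionally checks the engine against the
sequential scanner.

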