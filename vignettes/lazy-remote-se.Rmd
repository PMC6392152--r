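---
title: "Lazy remote-backed SummarizedExperiments: model, planning, and verification"
author: "lazyse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lazy remote-backed SummarizedExperiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(lazyse)
  library(SummarizedExperiment)
})
```

## The data model

A genome-scale assay is a matrix *Q* with *G* features on the rows and
*N* samples on the columns. `lazyse` keeps the standard
`SummarizedExperiment` container — the *G* × *F* feature table
(`rowData`), the *N* × *R* sample table (`colData`), optional per-feature
genomic ranges (`rowRanges`) — but replaces the assay with a
**LazyMatrix**: a view consisting of

* a **seed**, the storage-level object values are read from;
* a **row map** and **column map**, 1-based seed indices in presentation
  order (repetition and reordering allowed, as in R subsetting);
* an ordered list of elementwise **transforms** drawn from a closed
  whitelist (`identity`, `log2p1`, `log10p1`).

Subsetting composes maps; `lazy_apply()` appends a transform; neither
touches storage. Values move only at `realize()` (or through
`block_apply()`, which tiles a view into bounded blocks so whole-matrix
statistics never materialize the full view). Because every registered
transform is elementwise, transforming commutes with subsetting, and
realization may always be performed as *map, fetch unique cells,
replicate duplicates, then transform*.

A seed implements three things: its dimensions, its (optional) storage
chunk geometry, and a pure `read_block` over contiguous 1-based
intervals. Purity is part of the contract — identical reads return
identical blocks — which is what makes the replication of duplicated
indices after a single fetch sound. Every seed carries an append-only
read log; the package's laziness claims are stated as propositions about
that log (and, for the REST back end, about the served request log), not
as intentions.

Seeds provided: an in-memory matrix (`memory_seed()`, also the reference
implementation all oracle tests compare against), a chunked HDF5 dataset
(`h5_seed()`, via rhdf5), a remote HDF-REST dataset
(`open_remote_dataset()`), and a long-format SQL store
(`build_se_from_sql()`). Remote and SQL seeds additionally serve whole
*scattered* selections in one planned round trip; file and memory seeds
read one block per maximal contiguous run pair.

## Index conventions

Everything user-facing is 1-based and inclusive, like R and the rest of
the Bioconductor stack; genomic intervals are 1-based closed, and overlap
means closed-interval intersection (a shared boundary base counts). Two
boundaries deliberately differ:

* the REST dialect's `select=[r0:r1,c0:c1]` is 0-based half-open on the
  wire, matching HDF5 service conventions; the client converts at the
  last moment;
* BED input is 0-based half-open on disk and converted on read.

The command line accepts identifiers only — no positional indices — so
no base-convention question ever reaches a shell user.

## Request planning

A scattered selection (sorted unique rows × sorted unique columns) is
served as a set of rectangular hyperslab requests chosen by
`plan_requests()`:

1. **Coalesce** each axis into maximal consecutive runs.
2. **Merge** adjacent runs greedily, left to right: a merge is accepted
   when the merged bounding interval's wasted-cell fraction
   (wasted / fetched, on that axis) stays ≤ `waste_ratio`.
3. **Cross** the merged row-runs with the merged column-runs; each
   resulting slab is **split** along its longer axis until no request
   exceeds `max_request_cells`, with split points snapped down to chunk
   boundaries when the dataset's chunk geometry is known.

The rule is order-fixed, so identical selections always produce
identical plans. Three consequences are load-bearing and tested: every
requested cell is covered by exactly one (slab, gather) entry; total
fetched cells never exceed the bounding-box fetch; and per axis, fetched
indices never exceed requested / (1 − `waste_ratio`).

Tunables, with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `waste_ratio` | 0.5 | tolerate fetching up to one wasted cell per needed cell on an axis before splitting a request |
| `max_request_cells` | 2²⁰ (= 8 MiB of doubles) | per-request payload comfort zone for an HDF5 service |
| `block_cells` (realization) | 2²⁰ | peak dense temporary per block |
| retries | 3 attempts, backoff ×2 from 0.25 s | transport errors and 5xx only; 4xx never retried; 413 splits the slab in half and continues |

Chunk snapping is an efficiency bias only; correctness never depends on
chunk geometry. The service-side request limit (413) is handled by
recursive halving, so a conservative server bound degrades throughput,
not results.

## The REST dialect and its mock

The client speaks a minimal HDF-REST dialect: `/about`,
`/datasets?domain=`, `/datasets/{uuid}?domain=` (shape, value class,
chunk layout) and `/datasets/{uuid}/value?domain=&select=`. 2-D numeric
datasets carry the assay; 1-D datasets carry identifier vectors and
metadata columns (nested HDF5 paths are flattened with a dot:
`row_data.symbol`). Only hyperslab GETs are used; there are no write,
authentication, or point-selection endpoints.

`MockHsds` implements the dialect in-process over fixture arrays, with
three properties chosen for verification rather than realism: floats are
serialized at round-trip decimal precision so oracle comparisons can be
*exact* rather than tolerance-based; the request log is append-only and
drainable, making laziness an observable; and an optional enforced
request-size limit lets tests exercise the 413-splitting path
deterministically. `mock_transport()` routes a client through the full
JSON round trip without a socket — construction of an experiment issues
its metadata and identifier reads but zero assay-value requests, which
tests assert via `value_requests("assay")`. The same object can be served
over a real socket (`serve_hsds()`, `httpuv`); one integration test runs
the server in a background process and repeats the checks through
`curl_transport()`.

## The SQL back end

The relational layout is a deliberate clean triple store: an `assay`
table of (`feature_id`, `sample_id`, `value`) records with unique pairs,
plus keyed `features` and `samples` annotation tables (DDL shipped under
`inst/sql/`). Production warehouses with wide or nested schemas are the
loader's responsibility to map onto this layout. Annotation tables are
read eagerly and sorted by identifier — engines do not guarantee result
order, and deterministic construction matters more than fidelity to any
particular warehouse's ordering. Generated selection SQL is canonical
text (sorted, quote-escaped IN-lists, fixed ORDER BY, only
SELECT/WHERE/IN/ORDER BY), so query generation is byte-for-byte testable
and portable across engines.

A missing (feature, sample) record pivots to `NA` by default: absence of
a row is not evidence of zero expression. For genuinely sparse count
stores, `fill = 0` is an explicit opt-in. One IN-list query serves an
arbitrary scattered selection, so a one-gene analysis scans exactly *N*
records — asserted in tests via the seed's `rows_fetched` accounting.

## The fixture generator

`fixture_spec()` / `simulate_counts()` produce the matched fixtures all
back ends are tested on. Counts are negative binomial with lognormal
baseline gene means (meanlog 1.5, sdlog 1 — median mean ≈ 4.5 counts,
a plausible magnitude for the targeted-query workloads emulated here)
and dispersion 0.3. Two scenarios shape the metadata:

* **singlecell_panned** — four capture-class labels assigned uniformly,
  one designated marker gene per class with its mean multiplied by
  `effect` (default 4) inside the class; emulates an
  immunopanning-labeled single-cell matrix.
* **cohort_msi** — a continuous instability-like score per sample,
  exponential with mean 3 (so roughly a quarter of samples sit at or
  above the recipe threshold of 4 at *N* = 400), and one designated gene
  whose mean is multiplied by `effect` where the score ≥ 4.

Features are laid out as consecutive non-overlapping 100-bp intervals
with 50-bp gaps, half on chr1 and half on chr2, strands alternating — a
geometry chosen so whole-chromosome and partial region queries have
exactly computable answers. A `row_index` sentinel column in the feature
table lets tests verify that metadata stays positionally aligned with
realized assay rows through arbitrary subsetting. One explicitly seeded
Mersenne-Twister stream with a documented draw order makes fixtures
bit-reproducible; the caller's RNG state is restored afterwards.

What the generator does **not** emulate: library-size variation,
dropout/zero inflation, batch effects, correlated genes, or any real
biology. Passing tests therefore certify the *mechanics* — equality of
lazy and eager computation, planning exactness, laziness — on data of
realistic scale and type, not biological validity on real archives.

Default fixture size is 500 × 400: large enough that the 50 × 80 chunk
grid forces multi-slab plans, small enough that every eager oracle is
sub-second. At the recipe's designed 4-fold effect and *N* = 400, the
negative-binomial sampling band for the recovered count-scale group-mean
ratio is taken as [2, 8]; tests assert recovery inside that band, and
direction (high-score group higher) separately.

## Verification strategy and problem sizes

The package adopts elementwise equality with an eager oracle as its
reliability standard. The end-to-end suite (and `scripts/acceptance.R`,
which recomputes the same quantities from scratch and writes them as
JSON) runs, per fresh seed:

* 200 random selections per remote back end on the 500 × 400 fixture,
  compared for exact elementwise identity with the in-memory matrix.
  Selections are drawn from a mix of the shapes the container sees in
  practice — contiguous ranges (region and window queries), small
  scattered identifier sets (≤ 20, gene lists), and wider scatters
  (≤ 60) — unordered and with duplicates;
* a laziness audit: construction plus identifier/range subsetting issues
  zero assay-value requests, and a one-gene stratified analysis requests
  cells from exactly one assay row;
* 500 random planner audits (coverage exactly once, budget, waste bound)
  plus the three worked planning examples that pin the merge rule;
* 100 random interval sets (≤ 500 intervals each) against an all-pairs
  overlap oracle, including boundary-touch cases;
* 50 cross-back-end agreement checks (REST vs SQL, same fixture);
* effect recovery for both fixture scenarios;
* 500 random lazy operation chains against an eager reference.

These sizes are the package's declared study conditions; they were
chosen so the whole verification runs in minutes on one CPU while still
forcing multi-run, multi-slab, multi-chunk plans.

## Known limitations

* Matrices only — no higher-rank arrays, and no delayed binary
  operations between two lazy matrices.
* One assay per experiment.
* The transform whitelist is closed by design; arbitrary callables would
  break plan determinism and any future server-side pushdown. Transforms
  are currently always applied client-side after fetch.
* The REST client supports hyperslab GETs only (no point selection), and
  values travel as JSON text — exact and simple, but not a
  high-throughput binary stream.
* Overlap subsetting is intersection-only; "near"-window expansion of
  query regions is not implemented.
* Window/gap-tolerant overlap, aliquot de-duplication for cohort
  warehouses, and authenticated services are out of scope.
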