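# lazyse

Targeted queries of large expression matrices, in the
`SummarizedExperiment` idiom, without downloading the matrix.

Genome-scale assays produce a quantification matrix *Q* (*G* features ×
*N* samples, entries *q<sub>ij</sub>*) that is increasingly stored
remotely — in an HDF5 data service or a relational warehouse — while the
analyst wants to keep working with the familiar container `X[K, S]`,
`rowData`, `colData`, `rowRanges`, `subsetByOverlaps`. **lazyse** binds
feature- and sample-level metadata to a *lazy* assay: a view that records
index maps and elementwise transforms and fetches values only at
realization, as a small, planned set of rectangular reads. Filtering and
selection stay metadata-aware and cheap; numbers cross the wire only when
— and only where — they are needed.

Four storage seeds satisfy one block-reader contract:

| seed | storage | fetch unit |
|---|---|---|
| `memory_seed()` | in-memory matrix | (reference / oracle) |
| `h5_seed()` | chunked HDF5 file | hyperslab |
| `open_remote_dataset()` | minimal HDF-REST service | planned hyperslab GETs |
| `build_se_from_sql()` | long-format (feature, sample, value) SQL tables | canonical `SELECT … IN (…)` |

Scattered selections are coalesced by a deterministic, chunk-aware
planner: per axis, consecutive runs are merged while the wasted-cell
fraction of the merged bounding interval stays ≤ `waste_ratio`
(default 0.5), and each resulting slab is split to at most
`max_request_cells` (default 2²⁰) values. The package ships a conformant
in-process mock of the REST dialect with an append-only request log, so
every remote-path behavior — including the laziness guarantee itself —
is testable offline, plus an `httpuv` server that speaks the same dialect
over a real socket.

## Worked example

Simulate a tumor-cohort-style fixture (negative-binomial counts, a
continuous microsatellite-instability-like score per sample, one gene
4-fold higher where the score ≥ 4), serve it through the in-process REST
mock, and analyze it remotely:

```r
library(lazyse)

spec <- fixture_spec(n_features = 500, n_samples = 400, seed = 42,
                     scenario = "cohort_msi", effect = 4)
sim <- simulate_counts(spec)
svc <- mock_hsds(sim, chunk = c(50, 80))
se  <- se_from_hsds("http://mock", "/shared/fixture",
                    transport = mock_transport(svc))

dim(se)                            # [1] 500 400
nrow(svc$value_requests("assay"))  # [1] 0   -- nothing fetched yet

dim(subset_by_overlaps(se, parse_region("chr1:1-15000")))
# [1] 100 400                      -- still zero assay reads

g <- gene_by_group(se, "g0001", "msi_like", threshold = 4)
group_summary(g)
#   group   n     mean   median
# 1    <4 294 3.949275 4.087463
# 2   >=4 106 5.985457 6.076776

nrow(svc$value_requests("assay"))  # [1] 1
svc$value_requests("assay")$query
# [1] "domain=/shared/fixture&select=[0:1,0:400]"
```

The stratified means are log2(count + 1) values: the designed gene is
about 2 log2-units (≈4-fold) higher in the high-score group, and the
request log shows the whole analysis cost exactly one hyperslab request
covering assay row 1 — the observable form of lazy retrieval. The same
container works unchanged over a SQLite triple store
(`se_from_sqlite()`), a local HDF5 file (`se_from_h5()`), or a real HTTP
endpoint (`curl_transport()`).

A command line mirrors the library (`exec/lazyse`): `describe`, `slice`,
`overlap`, `gene-group`, `simulate`, `serve`.

```sh
Rscript exec/lazyse simulate --scenario cohort_msi --seed 42 --out-prefix /tmp/fix
Rscript exec/lazyse gene-group --backend sqlfile --path /tmp/fix.sqlite \
    --gene g0001 --group-col msi_like --ge 4
```

## Documentation

The methods vignette (`vignettes/lazy-remote-se.Rmd`) describes the data
model, the request-planning rule, the mock-service dialect, the fixture
generator's design and its limitations, and the numerical conventions.
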