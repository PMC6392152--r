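# Client + mock service conformance. Everything runs through the full
# JSON round trip of mock_transport(), so serialized-value fidelity is
# part of what these tests certify.

fixture_service <- function(G = 100L, N = 60L, chunk = c(10L, 30L),
                            limit = NULL, seed = 19L) {
  sim <- simulate_counts(fixture_spec(G, N, seed = seed,
                                      scenario = "cohort_msi"))
  list(sim = sim,
       svc = mock_hsds(sim, chunk = chunk, max_request_cells = limit))
}

test_that("the mock speaks the dialect: metadata, values, and errors", {
  f <- fixture_service()
  tr <- mock_transport(f$svc)
  about <- tr("http://mock/about")
  expect_identical(jsonlite::fromJSON(about$text)$api_version, "minimal-1")

  lst <- tr("http://mock/datasets?domain=%2Fshared%2Ffixture")
  expect_true("assay" %in% jsonlite::fromJSON(lst$text)$datasets)

  meta <- jsonlite::fromJSON(
    tr("http://mock/datasets/assay?domain=%2Fshared%2Ffixture")$text)
  expect_identical(unlist(meta$shape$dims), c(100L, 60L))
  expect_identical(unlist(meta$layout$dims), c(10L, 30L))
  expect_identical(meta$type$class, "H5T_FLOAT")

  val <- tr(paste0("http://mock/datasets/assay?domain=%2Fshared%2Ffixture"))
  expect_identical(val$status, 200L)
  v <- jsonlite::fromJSON(
    tr("http://mock/datasets/assay/value?domain=%2Fshared%2Ffixture&select=[0:2,0:2]")$text)$value
  storage.mode(v) <- "double"
  expect_identical(v, unname(f$sim$counts[1:2, 1:2]))

  expect_identical(
    tr("http://mock/datasets/assay/value?domain=%2Fshared%2Ffixture&select=[0:9999,0:1]")$status,
    400L)
  expect_identical(
    tr("http://mock/datasets/assay/value?domain=%2Fshared%2Ffixture&select=[oops]")$status,
    400L)
  expect_identical(tr("http://mock/datasets/assay/value?domain=%2Fnope&select=[0:1,0:1]")$status,
                   404L)
  expect_identical(tr("http://mock/datasets/zzz?domain=%2Fshared%2Ffixture")$status,
                   404L)
})

test_that("an enforced cell limit produces 413 on oversized selections", {
  f <- fixture_service(limit = 4L)
  tr <- mock_transport(f$svc)
  expect_identical(
    tr("http://mock/datasets/assay/value?domain=%2Fshared%2Ffixture&select=[0:2,0:4]")$status,
    413L)
  expect_identical(
    tr("http://mock/datasets/assay/value?domain=%2Fshared%2Ffixture&select=[0:2,0:2]")$status,
    200L)
})

test_that("open_remote_dataset reads metadata only and echoes geometry", {
  f <- fixture_service()
  seed <- open_remote_dataset("http://mock", "/shared/fixture", "assay",
                              transport = mock_transport(f$svc))
  expect_identical(seed_dim(seed), c(100L, 60L))
  expect_identical(seed_chunkdim(seed), c(10L, 30L))
  expect_identical(nrow(f$svc$value_requests()), 0L)

  expect_error(open_remote_dataset("http://mock", "/wrong", "assay",
                                   transport = mock_transport(f$svc)),
               class = "lazyse_data_error")
  # 1-D datasets refuse to open as matrices
  expect_error(open_remote_dataset("http://mock", "/shared/fixture",
                                   "features",
                                   transport = mock_transport(f$svc)),
               class = "lazyse_data_error", regexp = "2-D")
})

test_that("read_selection equals the eager oracle over random selections", {
  f <- fixture_service()
  seed <- open_remote_dataset("http://mock", "/shared/fixture", "assay",
                              transport = mock_transport(f$svc))
  set.seed(73)
  for (trial in 1:40) {
    rows <- random_index(100, 40); cols <- random_index(60, 30)
    got <- read_selection(seed, rows, cols)
    expect_identical(got, unname(f$sim$counts[rows, cols, drop = FALSE]))
  }
  # one full row: equality plus a sane request count
  f$svc$drain_log()
  row <- read_selection(seed, 5L, 1:60)
  expect_identical(row, unname(f$sim$counts[5, , drop = FALSE]))
  expect_gte(nrow(f$svc$value_requests("assay")), 1L)
  expect_lte(nrow(f$svc$value_requests("assay")), 2L)
  # empty selections make no requests
  f$svc$drain_log()
  expect_identical(read_selection(seed, integer(), 1:3),
                   matrix(numeric(), 0, 3))
  expect_identical(nrow(f$svc$value_requests()), 0L)
})

test_that("a service-enforced 413 limit makes the client split and succeed", {
  f <- fixture_service(limit = 64L)
  seed <- open_remote_dataset("http://mock", "/shared/fixture", "assay",
                              transport = mock_transport(f$svc))
  got <- read_selection(seed, 1:30, 1:20)     # 600 cells >> 64
  expect_identical(got, unname(f$sim$counts[1:30, 1:20]))
  # every served value request honored the limit
  served <- f$svc$value_requests("assay")
  expect_true(all(served$status %in% c(200L, 413L)))
  expect_true(any(served$status == 413L))
})

test_that("transient failures are retried and hard failures classified", {
  f <- fixture_service()
  inner <- mock_transport(f$svc)
  calls <- 0L
  flaky <- function(url) {
    calls <<- calls + 1L
    if (calls %% 3L == 1L) return(list(status = 503L, text = "{}"))
    inner(url)
  }
  seed <- open_remote_dataset("http://mock", "/shared/fixture", "assay",
                              transport = flaky, retry_base_s = 0.001)
  expect_identical(read_selection(seed, 1:3, 1:3),
                   unname(f$sim$counts[1:3, 1:3]))

  dead <- function(url) stop_transport("connection refused")
  expect_error(open_remote_dataset("http://mock", "/shared/fixture", "assay",
                                   transport = dead, retry_base_s = 0.001),
               class = "lazyse_transport_error")
})

test_that("remote experiments stay lazy until values are needed", {
  f <- fixture_service()
  tr <- mock_transport(f$svc)
  se <- se_from_hsds("http://mock", "/shared/fixture", transport = tr)
  expect_identical(dim(se), c(100L, 60L))
  expect_identical(nrow(f$svc$value_requests("assay")), 0L)

  sub <- subset_by_overlaps(subset_se(se, 1:50, 1:30), "chr1:1-3000")
  expect_identical(nrow(f$svc$value_requests("assay")), 0L)

  # gene_by_group requests cells from exactly one assay row
  f$svc$drain_log()
  g <- gene_by_group(se, "SYM0007", "msi_like", 4, lookup_col = "symbol")
  served <- f$svc$value_requests("assay")
  expect_gte(nrow(served), 1L)
  sels <- regmatches(served$query,
                     regexpr("\\[[0-9]+:[0-9]+,", served$query))
  expect_true(all(sels == "[6:7,"))       # row 7, 0-based half-open
  flag <- f$sim$col_data$msi_like >= 4
  expect_identical(g[[">=4"]], unname(log2(f$sim$counts[7, flag] + 1)))

  # two identical reads are two served requests (no server-side caching)
  f$svc$drain_log()
  r1 <- realize(assay(subset_se(se, 1L, 1:5)))
  r2 <- realize(assay(subset_se(se, 1L, 1:5)))
  expect_identical(r1, r2)
  expect_identical(nrow(f$svc$value_requests("assay")), 2L)
})

test_that("mock and eager values agree bit-for-bit through JSON", {
  sim <- small_sim(seed = 3)
  svc <- mock_hsds(sim, chunk = c(7L, 7L))
  seed <- open_remote_dataset("http://mock", "/shared/fixture", "assay",
                              transport = mock_transport(svc))
  set.seed(8)
  for (trial in 1:10) {
    r0 <- sample.int(59, 1); r1 <- sample((r0 + 1):60, 1)
    got <- read_selection(seed, r0:r1, 1:40)
    expect_identical(got, unname(sim$counts[r0:r1, 1:40]))
  }
})
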