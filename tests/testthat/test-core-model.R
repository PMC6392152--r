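# The container: construction, metadata-aligned subsetting, covariate
# binding and the single-gene stratification recipe. Laziness is asserted
# on the seed read log throughout.

make_tiny_se <- function() {
  m <- matrix(as.double(1:6), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  seed <- memory_seed(m)
  se <- make_se(lazy_matrix(seed),
                data.frame(symbol = c("A", "B", "C"),
                           row.names = rownames(m)),
                data.frame(grp = c(1, 2), row.names = colnames(m)))
  list(se = se, seed = seed, m = m)
}

test_that("construction validates shapes and identifiers, reading nothing", {
  t <- make_tiny_se()
  expect_identical(dim(t$se), c(3L, 2L))
  expect_identical(seed_read_count(t$seed), 0L)

  expect_error(
    make_se(matrix(0, 3, 2), data.frame(row.names = c("a", "b")),
            data.frame(row.names = c("s1", "s2"))),
    class = "lazyse_data_error", regexp = "row")
  expect_error(
    make_se(matrix(0, 2, 2),
            S4Vectors::DataFrame(x = 1:2, row.names = c("a", "a")),
            data.frame(row.names = c("s1", "s2"))),
    class = "lazyse_data_error", regexp = "duplicate")
  expect_error(
    make_se(matrix(0, 2, 2), data.frame(row.names = c("a", "b")),
            data.frame(row.names = c("s1", "s2")),
            row_ranges = GRanges("chr1", IRanges(1, 10))),
    class = "lazyse_data_error", regexp = "row_ranges")
})

test_that("subset_se resolves identifiers, positions and masks lazily", {
  t <- make_tiny_se()
  sub <- subset_se(t$se, c("g3", "g1"), 1L)
  expect_identical(rownames(sub), c("g3", "g1"))
  expect_identical(seed_read_count(t$seed), 0L)
  expect_identical(realize(assay(sub)), unname(t$m[c(3, 1), 1, drop = FALSE]))

  # identity subset realizes elementwise-identical
  all_se <- subset_se(t$se, NULL, "all")
  expect_identical(realize(assay(all_se)), unname(t$m))

  # duplicates repeat; masks select
  dup <- subset_se(t$se, c(2L, 2L), c(TRUE, FALSE))
  expect_identical(realize(assay(dup)), unname(t$m[c(2, 2), 1, drop = FALSE]))

  expect_error(subset_se(t$se, "gX"), class = "lazyse_data_error",
               regexp = "gX")
  expect_error(subset_se(t$se, NULL, c("s1", "sZ", "sQ")),
               class = "lazyse_data_error", regexp = "sZ, sQ")
})

test_that("subsetting composes and keeps metadata aligned with the assay", {
  sim <- small_sim()
  se <- fixture_se(sim)
  set.seed(61)
  for (trial in 1:20) {
    k1 <- random_index(nrow(se)); s1 <- random_index(ncol(se))
    a <- subset_se(se, k1, s1)
    k2 <- random_index(nrow(a)); s2 <- random_index(ncol(a))
    b <- subset_se(a, k2, s2)
    direct <- subset_se(se, k1[k2], s1[s2])
    expect_identical(realize(assay(b)), realize(assay(direct)))
    # row_index sentinel column stays aligned with realized assay rows
    expect_identical(unname(sim$counts[rowData(b)$row_index,
                                       s1[s2], drop = FALSE]),
                     realize(assay(b)))
    expect_identical(names(rowRanges(b)), rownames(b))
  }
})

test_that("overlap subsetting keeps original order and handles edge cases", {
  sim <- small_sim()
  se <- fixture_se(sim)
  # whole-chromosome ROI keeps exactly the features on that chromosome
  hit <- subset_by_overlaps(se, "chr1:1-100000")
  want <- which(as.character(seqnames(sim$row_ranges)) == "chr1")
  expect_identical(rownames(hit), rownames(se)[want])
  # brute-force oracle over a partial ROI
  roi <- parse_region("chr2:1000-2000")
  hit2 <- subset_by_overlaps(se, roi)
  mask <- seq_along(sim$row_ranges) %in%
    brute_overlaps(roi, sim$row_ranges)$subject
  expect_identical(rownames(hit2), rownames(se)[mask])
  # absent chromosome: valid empty result
  none <- subset_by_overlaps(se, "chrZ:1-100")
  expect_identical(nrow(none), 0L)
  expect_identical(ncol(none), ncol(se))
  # ROI equal to one feature's interval retains it (closed intervals)
  rr <- sim$row_ranges[5]
  one <- subset_by_overlaps(se, GRanges(seqnames(rr), ranges(rr)))
  expect_true(rownames(se)[5] %in% rownames(one))
  # unranged experiments refuse
  plain <- make_se(matrix(0, 2, 2), data.frame(row.names = c("a", "b")),
                   data.frame(row.names = c("s1", "s2")))
  expect_error(subset_by_overlaps(plain, roi), class = "lazyse_data_error",
               regexp = "ranges")
})

test_that("bind_sample_data joins by key and guards against collisions", {
  t <- make_tiny_se()
  full <- bind_sample_data(t$se,
                           data.frame(id = c("s2", "s1"), score = c(9, 4)),
                           "id")
  expect_identical(colData(full)$score, c(4, 9))
  expect_identical(ncol(full), 2L)

  half <- bind_sample_data(t$se, data.frame(id = "s2", score = 9), "id")
  expect_identical(colData(half)$score, c(NA_real_, 9))
  # stratification drops the missing sample and reports it
  g <- gene_by_group(half, "g1", "score", 5, transform = "identity")
  expect_identical(attr(g, "n_dropped"), 1L)
  expect_identical(sum(lengths(g)), 1L)

  expect_error(bind_sample_data(t$se,
                                data.frame(id = c("s1", "s1"), score = 1:2),
                                "id"),
               class = "lazyse_data_error", regexp = "duplicate")
  expect_error(bind_sample_data(full, data.frame(id = "s1", score = 2), "id"),
               class = "lazyse_data_error", regexp = "score")
})

test_that("gene_by_group fetches one row and labels threshold groups", {
  sim <- small_sim()          # cohort_msi: gene g0001 boosted where score>=4
  seed <- memory_seed(sim$counts)
  se <- make_se(lazy_matrix(seed), sim$row_data, sim$col_data,
                sim$row_ranges)
  g <- gene_by_group(se, "g0001", "msi_like", 4)
  expect_identical(names(g), c("<4", ">=4"))
  expect_identical(sum(lengths(g)), ncol(se))
  # laziness: the only seed reads cover assay row 1 exclusively
  log <- seed_read_log(seed)
  expect_gt(nrow(log), 0)
  expect_true(all(log$r0 == 1L & log$r1 == 1L))
  # values equal the eager recipe
  flag <- sim$col_data$msi_like >= 4
  expect_identical(g[[">=4"]], unname(log2(sim$counts[1, flag] + 1)))

  # symbol-style first-match lookup
  g2 <- gene_by_group(se, "SYM0001", "msi_like", 4, lookup_col = "symbol")
  expect_identical(attr(g2, "feature_index"), 1L)
  expect_error(gene_by_group(se, "NOPE", "msi_like", 4,
                             lookup_col = "symbol"),
               class = "lazyse_data_error")
  expect_error(gene_by_group(se, "g0001", "msi_like", 4, transform = "exp"),
               class = "lazyse_usage_error", regexp = "identity")
  expect_error(gene_by_group(se, "g0001", "nope", 4),
               class = "lazyse_data_error")
})

test_that("ambiguous metadata lookups warn and take the first match", {
  m <- matrix(as.double(1:4), 2, 2)
  se <- make_se(m, data.frame(symbol = c("DUP", "DUP"),
                              row.names = c("g1", "g2")),
                data.frame(s = c(0, 10), row.names = c("s1", "s2")))
  expect_warning(g <- gene_by_group(se, "DUP", "s", 5, lookup_col = "symbol",
                                    transform = "identity"),
                 regexp = "first")
  expect_identical(attr(g, "feature_index"), 1L)
})

test_that("the fixture's designed effect is recovered by the recipe", {
  sim <- simulate_counts(fixture_spec(100, 400, seed = 5,
                                      scenario = "cohort_msi", effect = 4))
  se <- fixture_se(sim)
  g <- gene_by_group(se, "g0001", "msi_like", 4)
  expect_gt(mean(g[[">=4"]]), mean(g[["<4"]]))
  ratio <- mean(2^g[[">=4"]] - 1) / mean(2^g[["<4"]] - 1)
  expect_gt(ratio, 2); expect_lt(ratio, 8)
})
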