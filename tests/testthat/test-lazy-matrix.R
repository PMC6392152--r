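test_that("subsetting composes index maps without reading the seed", {
  m <- matrix(as.double(1:12), 3, 4)
  seed <- memory_seed(m)
  a <- lazy_matrix(seed)[c(3, 1, 2), ]     # row_map (3,1,2)
  b <- a[2, ]                              # composes to seed row 1
  expect_identical(b@row_map, 1L)
  c2 <- a[c(2, 2), c(4, 1)]                # duplicates legal, order kept
  expect_identical(c2@row_map, c(1L, 1L))
  expect_identical(c2@col_map, c(4L, 1L))
  expect_identical(seed_read_count(seed), 0L)
})

test_that("out-of-range subsets fail naming the offending index", {
  a <- lazy_matrix(memory_seed(matrix(0, 3, 4)))
  expect_error(a[5, ], class = "lazyse_data_error", regexp = "5")
  expect_error(a[, 9], class = "lazyse_data_error", regexp = "9")
  expect_error(a[c(TRUE, FALSE), ], class = "lazyse_data_error",
               regexp = "length 2")
})

test_that("transforms are whitelisted, appended, and applied on realize", {
  a <- lazy_matrix(memory_seed(matrix(7, 2, 2)))
  expect_identical(realize(lazy_apply(a, "log2p1"))[1, 1], 3)   # log2(8)
  expect_identical(realize(lazy_apply(a, "identity")), realize(a))
  expect_identical(realize(lazy_apply(lazy_matrix(
    memory_seed(matrix(0, 1, 1))), "log2p1"))[1, 1], 0)
  expect_error(lazy_apply(a, "sqrt"), class = "lazyse_usage_error",
               regexp = "log2p1")
})

test_that("transform and subset commute elementwise", {
  set.seed(11)
  m <- matrix(rpois(200, 20) + 0.0, 10, 20)
  a <- lazy_matrix(memory_seed(m))
  i <- c(9, 2, 2, 5); j <- c(20, 1, 3)
  expect_identical(realize(lazy_apply(a, "log2p1")[i, j]),
                   realize(lazy_apply(a[i, j], "log2p1")))
  expect_identical(realize(lazy_apply(a[i, j], "log10p1")),
                   eager_view(m, i, j, "log10p1"))
})

test_that("random views realize equal to the eager oracle at small budgets", {
  set.seed(42)
  m <- matrix(rnorm(50 * 40), 50, 40)
  a <- lazy_matrix(memory_seed(m))
  for (trial in 1:25) {
    i <- random_index(50); j <- random_index(40)
    expect_identical(realize(a[i, j], block_cells = 64), eager_view(m, i, j))
  }
  # 0-extent views realize empty with zero reads
  seed2 <- memory_seed(m)
  b <- lazy_matrix(seed2)[integer(), ]
  expect_identical(realize(b), matrix(numeric(), 0, 40))
  expect_identical(seed_read_count(seed2), 0L)
})

test_that("an unbounded budget reads one block per contiguous run pair", {
  m <- matrix(0, 20, 20)
  seed <- memory_seed(m)
  a <- lazy_matrix(seed)[c(1:3, 7:9), c(5, 6, 11)]   # 2 row runs x 2 col runs
  realize(a, block_cells = 1e6)
  expect_identical(seed_read_count(seed), 4L)
  log <- seed_read_log(seed)
  expect_setequal(paste(log$r0, log$r1, log$c0, log$c1),
                  c("1 3 5 6", "1 3 11 11", "7 9 5 6", "7 9 11 11"))
})

test_that("realize never touches cells outside mapped rows x mapped cols", {
  m <- matrix(0, 30, 30)
  seed <- memory_seed(m)
  a <- lazy_matrix(seed)[c(2, 10, 11), c(4, 5, 20)]
  realize(a, block_cells = 7)
  log <- seed_read_log(seed)
  expect_true(all(log$r0 %in% c(2L, 10L, 11L) & log$r1 %in% c(2L, 10L, 11L)))
  expect_true(all(log$c0 %in% c(4L, 5L, 20L) & log$c1 %in% c(4L, 5L, 20L)))
})

test_that("block tiling covers the view exactly once within budget", {
  set.seed(5)
  for (trial in 1:20) {
    nr <- sample.int(15, 1); nc <- sample.int(15, 1)
    budget <- sample.int(40, 1)
    m <- matrix(rnorm(nr * nc), nr, nc)
    a <- lazy_matrix(memory_seed(m))
    tiles <- block_grid(a, budget)
    cells <- vapply(tiles, function(t)
      as.double(diff(t$rows) + 1) * (diff(t$cols) + 1), numeric(1))
    expect_true(all(cells <= budget))
    expect_identical(sum(cells), as.double(nr * nc))
    # reassembly reproduces realize()
    out <- matrix(NA_real_, nr, nc)
    for (t in tiles)
      out[t$rows[1]:t$rows[2], t$cols[1]:t$cols[2]] <-
        realize(a[t$rows[1]:t$rows[2], t$cols[1]:t$cols[2]], budget)
    expect_identical(out, m)
  }
  expect_length(block_grid(lazy_matrix(memory_seed(matrix(0, 10, 10))), 100),
                1L)
})

test_that("per-block content matches the eager oracle slice", {
  set.seed(13)
  m <- matrix(rnorm(30 * 12), 30, 12)
  a <- lazy_apply(lazy_matrix(memory_seed(abs(m)))[30:1, ], "log2p1")
  got <- block_apply(a, function(block, rows, cols) {
    expect_identical(block,
                     eager_view(abs(m), (31 - rows[1]):(31 - rows[2]),
                                cols[1]:cols[2], "log2p1"))
    sum(block)
  }, block_cells = 50)
  expect_equal(sum(unlist(got)), sum(log2(abs(m) + 1)))
})

test_that("long random op chains agree with an eager reference", {
  set.seed(99)
  m <- matrix(rpois(600, 10) + 0.0, 30, 20)
  for (trial in 1:60) {
    a <- lazy_matrix(memory_seed(m))
    rows <- seq_len(30); cols <- seq_len(20); trs <- character()
    for (op in seq_len(sample.int(6, 1))) {
      if (runif(1) < 0.6 && length(rows) && length(cols)) {
        i <- random_index(length(rows)); j <- random_index(length(cols))
        a <- a[i, j]; rows <- rows[i]; cols <- cols[j]
      } else {
        tr <- sample(transform_names(), 1)
        a <- lazy_apply(a, tr); trs <- c(trs, tr)
      }
    }
    expect_identical(realize(a, block_cells = 32),
                     eager_view(m, rows, cols, trs))
  }
})

test_that("realization agrees with DelayedArray on the same view", {
  set.seed(3)
  m <- matrix(rnorm(400), 20, 20)
  i <- c(5, 5, 1, 20); j <- c(2, 19, 3)
  ours <- realize(lazy_apply(lazy_matrix(memory_seed(m))[i, j], "log10p1"))
  theirs <- as.matrix(log10(DelayedArray::DelayedArray(m)[i, j] + 1))
  expect_equal(ours, unname(theirs))
})
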