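# Shared fixtures and independent oracles. Oracles work on plain eager
# matrices and deliberately avoid the lazy machinery they check.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(GenomicRanges)
})

small_sim <- function(seed = 7L, scenario = "cohort_msi", G = 60L, N = 40L) {
  simulate_counts(fixture_spec(G, N, seed = seed, scenario = scenario))
}

# eager reference for a (rows, cols) view with transforms
eager_view <- function(m, rows, cols, transforms = character()) {
  out <- unname(m[rows, cols, drop = FALSE])
  for (tr in transforms)
    out <- switch(tr, identity = out, log2p1 = log2(out + 1),
                  log10p1 = log10(out + 1))
  out
}

# random index vector into n positions: unordered, duplicates allowed
random_index <- function(n, max_len = n) {
  len <- sample.int(min(n, max_len), 1L)
  sample.int(n, len, replace = TRUE)
}

# a mix of the selection shapes the container sees in practice:
# contiguous ranges (region/window queries), small scattered identifier
# sets (gene lists), and wider scatters; unordered with duplicates
random_selection <- function(n) {
  kind <- sample.int(3L, 1L)
  if (kind == 1L) {
    len <- sample.int(min(n, 80L), 1L)
    start <- sample.int(n - len + 1L, 1L)
    sample(start:(start + len - 1L))          # contiguous, shuffled
  } else if (kind == 2L) {
    random_index(n, 20L)
  } else {
    random_index(n, 60L)
  }
}

# all-pairs closed-interval overlap oracle, strand-aware optional;
# enumerates the full i x j grid and tests every pair directly
brute_overlaps <- function(query, subject, strand_aware = FALSE) {
  grid <- expand.grid(query = seq_along(query),
                      subject = seq_along(subject))
  i <- grid$query; j <- grid$subject
  keep <- as.character(seqnames(query))[i] ==
            as.character(seqnames(subject))[j] &
          start(query)[i] <= end(subject)[j] &
          start(subject)[j] <= end(query)[i]
  if (strand_aware) {
    qs <- as.character(strand(query))[i]
    ss <- as.character(strand(subject))[j]
    keep <- keep & (qs == "*" | ss == "*" | qs == ss)
  }
  df <- grid[keep, , drop = FALSE]
  df <- df[order(df$query, df$subject), , drop = FALSE]
  rownames(df) <- NULL
  df
}

random_granges <- function(n, chroms = c("chr1", "chr2", "chr3"),
                           max_pos = 1000L) {
  starts <- sample.int(max_pos, n, replace = TRUE)
  widths <- sample.int(50L, n, replace = TRUE)
  GRanges(sample(chroms, n, replace = TRUE),
          IRanges(starts, starts + widths - 1L),
          strand = sample(c("+", "-", "*"), n, replace = TRUE))
}

# slab coverage audit: counts how many times each requested cell is
# covered by (slab x gather) and whether any slab exceeds the budget
audit_plan <- function(plan, rows, cols, max_cells) {
  touched <- matrix(0L, length(rows), length(cols))
  over_budget <- FALSE
  for (k in seq_len(nrow(plan$slabs))) {
    sl <- plan$slabs[k, ]
    cells <- as.double(sl$r1 - sl$r0 + 1L) * (sl$c1 - sl$c0 + 1L)
    if (cells > max_cells) over_budget <- TRUE
    g <- plan$gather[[k]]
    touched[g$out_rows, g$out_cols] <- touched[g$out_rows, g$out_cols] + 1L
  }
  list(touched = touched, over_budget = over_budget)
}
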