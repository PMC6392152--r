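# Hyperslab request planning.
#
# A remote read of scattered rows/columns is served as a small set of
# rectangular hyperslab requests. Per axis, requested indices are first
# coalesced into maximal consecutive runs; adjacent runs are then greedily
# merged (left to right) whenever the merged bounding interval's wasted-cell
# fraction (wasted / fetched, on that axis) stays within `waste_ratio`.
# Slabs are the cross product of merged row-runs and merged col-runs, each
# split along its longer axis until no slab exceeds `max_request_cells`.
# When the dataset's chunk geometry is known, split points snap down to
# chunk boundaries (correctness never depends on chunking). The greedy rule
# is order-fixed, so identical inputs always produce identical plans.

merge_runs <- function(runs, waste_ratio) {
  if (nrow(runs) <= 1L) {
    if (nrow(runs) == 0L) return(cbind(runs, needed = integer()))
    return(cbind(runs, needed = runs[, 2L] - runs[, 1L] + 1L))
  }
  out <- matrix(integer(), 0L, 3L)
  cur <- c(runs[1L, ], runs[1L, 2L] - runs[1L, 1L] + 1L) # start, end, needed
  for (k in 2L:nrow(runs)) {
    a <- runs[k, 1L]; b <- runs[k, 2L]
    fetched <- b - cur[1L] + 1L
    needed <- cur[3L] + (b - a + 1L)
    if ((fetched - needed) / fetched <= waste_ratio) {
      cur <- c(cur[1L], b, needed)
    } else {
      out <- rbind(out, cur)
      cur <- c(a, b, b - a + 1L)
    }
  }
  out <- rbind(out, cur)
  dimnames(out) <- NULL
  colnames(out) <- c("start", "end", "needed")
  out
}

# Split positions for interval [a, b] so each piece has <= max_len indices;
# snap piece lengths down to a multiple of `chunk` when that keeps >= 1.
axis_splits <- function(a, b, max_len, chunk = NULL) {
  len <- b - a + 1L
  if (len <= max_len) return(cbind(a, b, deparse.level = 0L))
  step <- max_len
  if (!is.null(chunk) && chunk >= 1L && step >= chunk)
    step <- (step %/% chunk) * chunk
  starts <- seq.int(a, b, by = step)
  cbind(starts, pmin(starts + step - 1L, b), deparse.level = 0L)
}

split_slab <- function(r0, r1, c0, c1, max_cells, chunkdim) {
  nr <- r1 - r0 + 1L; nc <- c1 - c0 + 1L
  if (as.double(nr) * nc <= max_cells)
    return(list(c(r0, r1, c0, c1)))
  out <- list()
  if (nr >= nc) {
    band <- max(1L, max_cells %/% nc)
    rs <- axis_splits(r0, r1, band, if (!is.null(chunkdim)) chunkdim[1L])
    for (k in seq_len(nrow(rs)))
      out <- c(out, split_slab(rs[k, 1L], rs[k, 2L], c0, c1,
                               max_cells, chunkdim))
  } else {
    band <- max(1L, max_cells %/% nr)
    cs <- axis_splits(c0, c1, band, if (!is.null(chunkdim)) chunkdim[2L])
    for (k in seq_len(nrow(cs)))
      out <- c(out, split_slab(r0, r1, cs[k, 1L], cs[k, 2L],
                               max_cells, chunkdim))
  }
  out
}

#' Plan hyperslab requests for a scattered selection
#'
#' @param rows,cols sorted, unique, 1-based indices to fetch
#' @param chunk_shape optional `(rows, cols)` storage chunk geometry
#' @param waste_ratio maximum tolerated wasted-cell fraction when merging
#'   adjacent runs on one axis, in `[0, 1)`; default 0.5
#' @param max_request_cells per-request cell budget; default
#'   [DEFAULT_BLOCK_CELLS]
#' @return a `request_plan`: list with `slabs` (data.frame `r0,r1,c0,c1`,
#'   1-based inclusive) and `gather` (per slab, the positions of the
#'   requested rows/cols inside the slab and inside the output), covering
#'   every requested cell exactly once
#' @export
plan_requests <- function(rows, cols, chunk_shape = NULL, waste_ratio = 0.5,
                          max_request_cells = DEFAULT_BLOCK_CELLS) {
  if (waste_ratio < 0 || waste_ratio >= 1)
    stop_usage("waste_ratio must be in [0, 1)")
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.unsorted(rows, strictly = TRUE) || is.unsorted(cols, strictly = TRUE))
    stop_usage("plan_requests() expects sorted unique indices")
  max_request_cells <- max(1L, as.integer(max_request_cells))
  if (length(rows) == 0L || length(cols) == 0L)
    return(structure(list(slabs = data.frame(r0 = integer(), r1 = integer(),
                                             c0 = integer(), c1 = integer()),
                          gather = list(), rows = rows, cols = cols),
                     class = "request_plan"))
  rmerged <- merge_runs(consecutive_runs(rows), waste_ratio)
  cmerged <- merge_runs(consecutive_runs(cols), waste_ratio)
  slabs <- list()
  for (ri in seq_len(nrow(rmerged)))
    for (ci in seq_len(nrow(cmerged)))
      slabs <- c(slabs, split_slab(rmerged[ri, 1L], rmerged[ri, 2L],
                                   cmerged[ci, 1L], cmerged[ci, 2L],
                                   max_request_cells, chunk_shape))
  slabs <- as.data.frame(do.call(rbind, slabs))
  names(slabs) <- c("r0", "r1", "c0", "c1")
  gather <- lapply(seq_len(nrow(slabs)), function(k) {
    rin <- which(rows >= slabs$r0[k] & rows <= slabs$r1[k])
    cin <- which(cols >= slabs$c0[k] & cols <= slabs$c1[k])
    list(out_rows = rin, out_cols = cin,
         slab_rows = rows[rin] - slabs$r0[k] + 1L,
         slab_cols = cols[cin] - slabs$c0[k] + 1L)
  })
  structure(list(slabs = slabs, gather = gather, rows = rows, cols = cols),
            class = "request_plan")
}

#' Total cells fetched by a plan
#' @param plan a `request_plan`
#' @return numeric cell count over all slabs
#' @export
plan_fetched_cells <- function(plan) {
  with(plan$slabs, sum(as.double(r1 - r0 + 1L) * (c1 - c0 + 1L)))
}
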