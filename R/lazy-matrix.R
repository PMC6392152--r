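# Elementwise transform whitelist. A closed registry (rather than arbitrary
# callables) keeps realization deterministic and leaves the door open for
# pushing transforms into a back end later. Transforms are nevertheless
# always applied client-side after fetch.
.transforms <- list(
  identity = function(x) x,
  log2p1   = function(x) log2(x + 1),
  log10p1  = function(x) log10(x + 1)
)

#' Registered elementwise transforms
#' @return character vector of transform names usable with [lazy_apply()]
#' @export
transform_names <- function() names(.transforms)

check_transform <- function(name) {
  if (length(name) != 1L || !name %in% names(.transforms))
    stop_usage("unknown transform '%s'; valid transforms: %s",
               paste(name, collapse = ","),
               paste(names(.transforms), collapse = ", "))
  name
}

#' LazyMatrix: a delayed view over a storage seed
#'
#' A `LazyMatrix` records *which* cells of a seed it presents (`row_map`,
#' `col_map`: 1-based seed indices, repetition and reordering allowed) and
#' *what* elementwise transforms apply, without reading any values.
#' Subsetting composes index maps; [lazy_apply()] appends a transform;
#' values move only when [realize()] (or [block_apply()]) is called.
#'
#' The class implements `dim`, `[` and (inert) `dimnames` so it can serve
#' directly as the assay of a `SummarizedExperiment`.
#'
#' @param seed an [AssaySeed]
#' @return a `LazyMatrix` viewing the whole seed
#' @aliases LazyMatrix LazyMatrix-class
#' @export
lazy_matrix <- function(seed) {
  if (!is(seed, "AssaySeed")) stop_usage("lazy_matrix() expects an AssaySeed")
  d <- seed_dim(seed)
  new("LazyMatrix", seed = seed,
      row_map = seq_len(d[1L]), col_map = seq_len(d[2L]),
      transforms = character())
}

#' @exportClass LazyMatrix
setClass("LazyMatrix",
         representation(seed = "AssaySeed", row_map = "integer",
                        col_map = "integer", transforms = "character"))

setValidity("LazyMatrix", function(object) {
  d <- seed_dim(object@seed)
  if (length(object@row_map) && (min(object@row_map) < 1L ||
                                 max(object@row_map) > d[1L]))
    return("row_map outside seed extent")
  if (length(object@col_map) && (min(object@col_map) < 1L ||
                                 max(object@col_map) > d[2L]))
    return("col_map outside seed extent")
  if (!all(object@transforms %in% names(.transforms)))
    return("unregistered transform")
  TRUE
})

#' @export
setMethod("dim", "LazyMatrix", function(x)
  c(length(x@row_map), length(x@col_map)))

# Dimnames live on the enclosing SummarizedExperiment, not on the view.
#' @export
setMethod("dimnames", "LazyMatrix", function(x) NULL)
#' @export
setReplaceMethod("dimnames", "LazyMatrix", function(x, value) x)

resolve_axis_index <- function(i, n, axis) {
  if (is.logical(i)) {
    if (length(i) != n)
      stop_data("logical %s mask has length %d; expected %d", axis, length(i), n)
    i <- which(i)
  }
  i <- as.integer(i)
  bad <- i[i < 1L | i > n]
  if (length(bad))
    stop_data("%s index out of range [1, %d]: %s", axis, n,
              paste(utils::head(bad, 5L), collapse = ", "))
  i
}

#' @export
setMethod("[", "LazyMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x))
  if (missing(j)) j <- seq_len(ncol(x))
  i <- resolve_axis_index(i, nrow(x), "row")
  j <- resolve_axis_index(j, ncol(x), "column")
  initialize(x, row_map = x@row_map[i], col_map = x@col_map[j])
})

#' Append an elementwise transform to a lazy view
#'
#' Transforms are applied at realization, in append order, after index
#' mapping. Because all registered transforms are elementwise, transforming
#' commutes with subsetting.
#'
#' @param x a [LazyMatrix]
#' @param transform one of [transform_names()]
#' @return a new `LazyMatrix`; no values are read
#' @export
lazy_apply <- function(x, transform) {
  stopifnot(is(x, "LazyMatrix"))
  initialize(x, transforms = c(x@transforms, check_transform(transform)))
}

#' @rdname lazy_matrix
#' @param x a `LazyMatrix`
#' @export
lazy_seed <- function(x) x@seed

# Maximal consecutive runs of a sorted unique integer vector, as a
# two-column matrix (start, end), 1-based inclusive.
consecutive_runs <- function(idx) {
  if (length(idx) == 0L) return(matrix(integer(), ncol = 2L))
  brk <- c(TRUE, diff(idx) != 1L)
  starts <- idx[brk]
  ends <- idx[c(brk[-1L], TRUE)]
  cbind(starts, ends, deparse.level = 0L)
}

#' Default realization block budget
#'
#' 2^20 values — a round 8 MiB of 8-byte doubles, comfortably inside a
#' single HDF5-service payload.
#' @export
DEFAULT_BLOCK_CELLS <- 1048576L

# Seeds that can serve a scattered (non-contiguous) selection in one
# round trip — a remote service with a request planner, a SQL store with
# IN-lists — override this; the default signals "contiguous blocks only".
setGeneric("seed_read_scattered",
           function(seed, rows, cols, block_cells) NULL)

# Fetch seed[rows0, cols0] (sorted unique indices) as a dense matrix.
# Seeds with native scattered selection take one planned round trip;
# otherwise read maximal contiguous run pairs, each split to <= block_cells.
fetch_unique <- function(seed, rows0, cols0, block_cells) {
  scattered <- seed_read_scattered(seed, rows0, cols0, block_cells)
  if (!is.null(scattered)) return(scattered)
  fetch_unique_blockwise(seed, rows0, cols0, block_cells)
}

fetch_unique_blockwise <- function(seed, rows0, cols0, block_cells) {
  out <- matrix(NA_real_, length(rows0), length(cols0))
  rruns <- consecutive_runs(rows0)
  cruns <- consecutive_runs(cols0)
  for (ri in seq_len(nrow(rruns))) {
    for (ci in seq_len(nrow(cruns))) {
      r0 <- rruns[ri, 1L]; r1 <- rruns[ri, 2L]
      c0 <- cruns[ci, 1L]; c1 <- cruns[ci, 2L]
      oi <- match(r0, rows0); oj <- match(c0, cols0)
      nr <- r1 - r0 + 1L; nc <- c1 - c0 + 1L
      # split the run pair into row bands (then column strips) <= budget
      band <- max(1L, block_cells %/% nc)
      for (rb in seq.int(r0, r1, by = band)) {
        rbe <- min(rb + band - 1L, r1)
        if (nc <= block_cells) {
          blk <- seed_read_block(seed, c(rb, rbe), c(c0, c1))
          out[(oi + rb - r0):(oi + rbe - r0), oj:(oj + nc - 1L)] <- blk
        } else {
          for (cb in seq.int(c0, c1, by = block_cells)) {
            cbe <- min(cb + block_cells - 1L, c1)
            blk <- seed_read_block(seed, c(rb, rbe), c(cb, cbe))
            out[(oi + rb - r0):(oi + rbe - r0),
                (oj + cb - c0):(oj + cbe - c0)] <- blk
          }
        }
      }
    }
  }
  out
}

#' Realize a lazy view as a dense matrix
#'
#' Reads only cells inside the Cartesian product of the view's mapped rows
#' and columns, in blocks of at most `block_cells` values; duplicated map
#' entries are materialized by replication after fetch, never by re-reading.
#'
#' The method is registered on the `realize` generic shared across the
#' SummarizedExperiment/DelayedArray ecosystem, so the verb keeps its usual
#' meaning when both are attached.
#'
#' @param x a [LazyMatrix]
#' @param ... ignored; present for generic compatibility
#' @param block_cells positive block budget in values
#' @return a dense base matrix of `dim(x)`
#' @name realize
#' @aliases realize,LazyMatrix-method
#' @importFrom SummarizedExperiment realize
#' @export realize
#' @exportMethods realize
setMethod("realize", "LazyMatrix", function(x, ...,
                                            block_cells = DEFAULT_BLOCK_CELLS) {
  block_cells <- max(1L, as.integer(block_cells))
  if (nrow(x) == 0L || ncol(x) == 0L) {
    out <- matrix(numeric(), nrow(x), ncol(x))
  } else {
    rows0 <- sort(unique(x@row_map))
    cols0 <- sort(unique(x@col_map))
    base <- fetch_unique(x@seed, rows0, cols0, block_cells)
    out <- base[match(x@row_map, rows0), match(x@col_map, cols0), drop = FALSE]
  }
  for (tr in x@transforms) out <- .transforms[[tr]](out)
  out
})

#' Tile a lazy view into bounded blocks
#'
#' `block_grid()` partitions the view's own index space (not the seed's)
#' into rectangles of at most `block_cells` cells; `block_apply()` realizes
#' each tile in order and calls `FUN(block, rows, cols)`. Concatenating the
#' tiles reproduces [realize()] exactly, so whole-matrix statistics can be
#' computed without ever materializing the full view.
#'
#' @param x a [LazyMatrix]
#' @param block_cells positive block budget in values
#' @return `block_grid()`: list of `list(rows = c(start, end),
#'   cols = c(start, end))` in view coordinates; `block_apply()`: list of
#'   `FUN` results in tile order.
#' @export
block_grid <- function(x, block_cells = DEFAULT_BLOCK_CELLS) {
  block_cells <- max(1L, as.integer(block_cells))
  nr <- nrow(x); nc <- ncol(x)
  if (nr == 0L || nc == 0L) return(list())
  tiles <- list()
  if (nc <= block_cells) {
    band <- max(1L, block_cells %/% nc)
    for (r0 in seq.int(1L, nr, by = band)) {
      r1 <- min(r0 + band - 1L, nr)
      tiles[[length(tiles) + 1L]] <- list(rows = c(r0, r1), cols = c(1L, nc))
    }
  } else {
    for (r0 in seq_len(nr)) {
      for (c0 in seq.int(1L, nc, by = block_cells)) {
        c1 <- min(c0 + block_cells - 1L, nc)
        tiles[[length(tiles) + 1L]] <- list(rows = c(r0, r0), cols = c(c0, c1))
      }
    }
  }
  tiles
}

#' @rdname block_grid
#' @param FUN function of `(block, rows, cols)`
#' @export
block_apply <- function(x, FUN, block_cells = DEFAULT_BLOCK_CELLS) {
  lapply(block_grid(x, block_cells), function(tile) {
    sub <- x[tile$rows[1L]:tile$rows[2L], tile$cols[1L]:tile$cols[2L]]
    FUN(realize(sub, block_cells), tile$rows, tile$cols)
  })
}

#' @export
setMethod("show", "LazyMatrix", function(object) {
  d <- seed_dim(object@seed)
  cat(sprintf("<LazyMatrix %d x %d over %s seed %d x %d; transforms: %s>\n",
              nrow(object), ncol(object), class(object@seed), d[1L], d[2L],
              if (length(object@transforms))
                paste(object@transforms, collapse = " -> ") else "none"))
})
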