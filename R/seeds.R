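#' @import methods
#' @importFrom stats rnbinom rlnorm rexp median
NULL

#' Storage seed contract
#'
#' A seed is the storage-level object a [LazyMatrix] reads dense blocks
#' from. Any S4 class providing `seed_dim()`, `seed_chunkdim()` and a
#' `read_block_impl()` method satisfies the contract. `read_block_impl()`
#' must be pure: identical calls return identical blocks, with dimensions
#' equal to the requested interval extents. All coordinates are 1-based
#' inclusive.
#'
#' Every seed carries a read log (an environment) so tests and users can
#' audit exactly which cells were requested — the observable form of the
#' laziness guarantee.
#'
#' @name AssaySeed
#' @aliases AssaySeed-class
#' @exportClass AssaySeed
setClass("AssaySeed", representation("VIRTUAL", log = "environment"))

new_seed_log <- function() {
  e <- new.env(parent = emptyenv())
  e$reads <- list()
  e
}

#' Seed dimensions
#' @param seed an [AssaySeed]
#' @return integer vector `(rows, cols)`
#' @export
setGeneric("seed_dim", function(seed) standardGeneric("seed_dim"))

#' Seed storage chunk dimensions
#' @param seed an [AssaySeed]
#' @return integer `(rows, cols)` chunk tile, or `NULL` when unknown
#' @export
setGeneric("seed_chunkdim", function(seed) standardGeneric("seed_chunkdim"))

# Implementation method: subclasses override. Do not call directly; go
# through seed_read_block() which validates and logs.
setGeneric("read_block_impl", function(seed, rows, cols, ...)
  standardGeneric("read_block_impl"))

#' Read one dense block from a seed
#'
#' Validates the requested intervals, dispatches to the seed's reader and
#' records the read in the seed's log.
#'
#' @param seed an [AssaySeed]
#' @param rows,cols integer `c(start, end)`, 1-based inclusive
#' @return a dense base matrix of extent `diff(rows)+1` by `diff(cols)+1`
#' @export
seed_read_block <- function(seed, rows, cols) {
  d <- seed_dim(seed)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (length(rows) != 2L || length(cols) != 2L)
    stop_usage("block intervals must be c(start, end)")
  if (rows[1L] < 1L || rows[2L] > d[1L] || rows[1L] > rows[2L] ||
      cols[1L] < 1L || cols[2L] > d[2L] || cols[1L] > cols[2L])
    stop_data("block [%d:%d, %d:%d] outside seed extent %d x %d",
              rows[1L], rows[2L], cols[1L], cols[2L], d[1L], d[2L])
  blk <- read_block_impl(seed, rows, cols)
  if (!identical(dim(blk), c(rows[2L] - rows[1L] + 1L, cols[2L] - cols[1L] + 1L)))
    stop_protocol("seed returned block of wrong shape for [%d:%d, %d:%d]",
                  rows[1L], rows[2L], cols[1L], cols[2L])
  seed@log$reads[[length(seed@log$reads) + 1L]] <-
    c(r0 = rows[1L], r1 = rows[2L], c0 = cols[1L], c1 = cols[2L])
  blk
}

#' Inspect or reset a seed's read log
#'
#' @param seed an [AssaySeed]
#' @return `seed_read_log()`: a data.frame with one row per block read
#'   (`r0`, `r1`, `c0`, `c1`, 1-based inclusive); `seed_read_count()`: the
#'   number of block reads issued so far.
#' @export
seed_read_log <- function(seed) {
  if (length(seed@log$reads) == 0L)
    return(data.frame(r0 = integer(), r1 = integer(),
                      c0 = integer(), c1 = integer()))
  as.data.frame(do.call(rbind, seed@log$reads))
}

#' @rdname seed_read_log
#' @export
seed_read_count <- function(seed) length(seed@log$reads)

#' @rdname seed_read_log
#' @export
seed_reset_log <- function(seed) {
  seed@log$reads <- list()
  invisible(seed)
}

# ---- In-memory seed (the eager reference backing) -------------------------

#' In-memory seed
#'
#' Wraps a dense base matrix as a seed. This is the reference backing used
#' by the fixture generator and by every oracle-equality test: realizing a
#' lazy view over a `MemorySeed` must agree elementwise with ordinary
#' matrix subsetting.
#'
#' @param x a numeric matrix
#' @param chunkdim optional integer `(rows, cols)` pretend chunk geometry,
#'   useful when exercising chunk-aware planning against in-memory data
#' @return a `MemorySeed`
#' @export
memory_seed <- function(x, chunkdim = NULL) {
  if (!is.matrix(x)) stop_usage("memory_seed() expects a matrix")
  storage.mode(x) <- "double"
  new("MemorySeed", data = x,
      chunkdim = if (is.null(chunkdim)) integer() else as.integer(chunkdim),
      log = new_seed_log())
}

#' @exportClass MemorySeed
setClass("MemorySeed", contains = "AssaySeed",
         representation(data = "matrix", chunkdim = "integer"))

setMethod("seed_dim", "MemorySeed", function(seed) dim(seed@data))
setMethod("seed_chunkdim", "MemorySeed", function(seed)
  if (length(seed@chunkdim)) seed@chunkdim else NULL)
setMethod("read_block_impl", "MemorySeed", function(seed, rows, cols, ...)
  seed@data[rows[1L]:rows[2L], cols[1L]:cols[2L], drop = FALSE])

# ---- HDF5 file seed --------------------------------------------------------

#' HDF5 file seed
#'
#' Reads blocks of a 2-D numeric dataset in a local HDF5 file through
#' chunked hyperslab access. Shape and chunk geometry are taken from the
#' file's metadata; no values are read at open time.
#'
#' @param path HDF5 file path
#' @param dataset dataset name, default `"/assay"`
#' @return an `H5Seed`
#' @export
h5_seed <- function(path, dataset = "/assay") {
  if (!file.exists(path)) stop_data("HDF5 file not found: %s", path)
  fid <- rhdf5::H5Fopen(path, flags = "H5F_ACC_RDONLY")
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  did <- rhdf5::H5Dopen(fid, dataset)
  sp <- rhdf5::H5Dget_space(did)
  dims <- rhdf5::H5Sget_simple_extent_dims(sp)$size
  pl <- rhdf5::H5Dget_create_plist(did)
  # H5Pget_chunk reports in HDF5 (C, row-major) axis order; flip to R order
  ch <- tryCatch(rev(rhdf5::H5Pget_chunk(pl)), error = function(e) NULL)
  rhdf5::H5Pclose(pl); rhdf5::H5Sclose(sp); rhdf5::H5Dclose(did)
  if (length(dims) != 2L)
    stop_data("dataset %s is %d-dimensional; a 2-D dataset is required",
              dataset, length(dims))
  new("H5Seed", path = path, dataset = dataset, dims = as.integer(dims),
      chunkdim = if (is.null(ch)) integer() else as.integer(ch),
      log = new_seed_log())
}

#' @exportClass H5Seed
setClass("H5Seed", contains = "AssaySeed",
         representation(path = "character", dataset = "character",
                        dims = "integer", chunkdim = "integer"))

setMethod("seed_dim", "H5Seed", function(seed) seed@dims)
setMethod("seed_chunkdim", "H5Seed", function(seed)
  if (length(seed@chunkdim)) seed@chunkdim else NULL)
setMethod("read_block_impl", "H5Seed", function(seed, rows, cols, ...) {
  blk <- rhdf5::h5read(seed@path, seed@dataset,
                       index = list(rows[1L]:rows[2L], cols[1L]:cols[2L]))
  storage.mode(blk) <- "double"
  blk
})
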