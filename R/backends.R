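# Assemble a full lazy SummarizedExperiment from each storage back end.
# Metadata (identifier vectors, annotation columns) is small and read
# eagerly; the assay always stays lazy.

build_range_from_columns <- function(rd) {
  if (!all(c("seqname", "start", "end") %in% names(rd))) return(NULL)
  GenomicRanges::GRanges(rd$seqname,
                         IRanges::IRanges(as.integer(rd$start),
                                          as.integer(rd$end)),
                         strand = if ("strand" %in% names(rd)) rd$strand
                                  else "*")
}

strip_range_columns <- function(rd) {
  rd[, setdiff(names(rd), c("seqname", "start", "end", "strand")),
     drop = FALSE]
}

#' Lazy SummarizedExperiment over a local HDF5 fixture file
#'
#' Expects the layout written by [write_h5_fixture()]. Only the ID vectors
#' and metadata columns are read eagerly; assay values stay behind an
#' [h5_seed()].
#'
#' @param path HDF5 file
#' @return a SummarizedExperiment
#' @export
se_from_h5 <- function(path) {
  seed <- h5_seed(path, "/assay")
  fid <- as.character(rhdf5::h5read(path, "features"))
  sid <- as.character(rhdf5::h5read(path, "samples"))
  ls <- rhdf5::h5ls(path)
  read_group <- function(group) {
    sel <- ls$group == paste0("/", group) & ls$otype == "H5I_DATASET"
    cols <- ls$name[sel]
    out <- lapply(cols, function(cn)
      as.vector(rhdf5::h5read(path, paste0(group, "/", cn))))
    names(out) <- cols
    as.data.frame(out, optional = TRUE)
  }
  rd <- read_group("row_data")
  cd <- read_group("col_data")
  ranges <- build_range_from_columns(rd)
  rd <- strip_range_columns(rd)
  rownames(rd) <- fid
  if (nrow(cd) == 0L) cd <- data.frame(row.names = sid) else rownames(cd) <- sid
  make_se(lazy_matrix(seed), rd, cd, row_ranges = ranges)
}

#' Lazy SummarizedExperiment over a remote HDF-REST domain
#'
#' Opens the `assay` dataset (metadata endpoints only) and reads the ID
#' vectors plus any `row_data.*` / `col_data.*` 1-D datasets present in
#' the domain. No assay values are requested.
#'
#' @inheritParams open_remote_dataset
#' @return a SummarizedExperiment with an [HsdsSeed]-backed lazy assay
#' @export
se_from_hsds <- function(base_url, domain, transport = curl_transport(),
                         ...) {
  seed <- open_remote_dataset(base_url, domain, dataset = "assay",
                              transport = transport, ...)
  avail <- list_remote_datasets(base_url, domain, transport)
  rv <- function(name) read_remote_vector(base_url, domain, name, transport)
  fid <- if ("features" %in% avail) as.character(rv("features"))
         else sprintf("g%04d", seq_len(seed_dim(seed)[1L]))
  sid <- if ("samples" %in% avail) as.character(rv("samples"))
         else sprintf("s%04d", seq_len(seed_dim(seed)[2L]))
  pick <- function(prefix) {
    cols <- sub(prefix, "", avail[startsWith(avail, prefix)], fixed = TRUE)
    out <- lapply(cols, function(cn) rv(paste0(prefix, cn)))
    names(out) <- cols
    as.data.frame(out, optional = TRUE)
  }
  rd <- pick("row_data.")
  cd <- pick("col_data.")
  ranges <- build_range_from_columns(rd)
  rd <- strip_range_columns(rd)
  if (nrow(rd) == 0L) rd <- data.frame(row.names = fid) else rownames(rd) <- fid
  if (nrow(cd) == 0L) cd <- data.frame(row.names = sid) else rownames(cd) <- sid
  make_se(lazy_matrix(seed), rd, cd, row_ranges = ranges)
}

#' Lazy SummarizedExperiment over a SQLite triple-store file
#'
#' @param path SQLite database written by [write_sql_fixture()] (or any
#'   database conforming to the shipped DDL)
#' @param sample_predicate,fill see [build_se_from_sql()]
#' @return a SummarizedExperiment; the connection is kept open on the seed
#' @export
se_from_sqlite <- function(path, sample_predicate = NULL, fill = NA_real_) {
  if (!file.exists(path)) stop_data("database not found: %s", path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  se <- build_se_from_sql(con, sample_predicate = sample_predicate,
                          fill = fill)
  # the seed owns the connection; close it when the seed is collected
  reg.finalizer(lazy_seed(assay(se))@log,
                function(e) try(DBI::dbDisconnect(con), silent = TRUE))
  se
}
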