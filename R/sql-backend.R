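# Relational (triple-store) back end. The assay lives in a long-format
# table (feature_id, sample_id, value); feature and sample annotations in
# their own keyed tables. Annotation tables are read eagerly (they are
# small); the assay is exposed as a lazy SQL seed that translates block
# reads into canonical SELECT ... WHERE ... IN (...) queries and pivots
# the long result to a dense block. Generated SQL restricts itself to
# SELECT/WHERE/IN/ORDER BY, portable across engines.

#' Default triple-store table names
#' @return named list with entries `assay`, `features`, `samples`
#' @export
default_schema <- function() {
  list(assay = "assay", features = "features", samples = "samples")
}

quote_sql_string <- function(x) {
  paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
}

#' Canonical SQL for a feature/sample selection
#'
#' Produces byte-deterministic SQL: one SELECT of
#' `(feature_id, sample_id, value)` with IN-lists of sorted, single-quoted,
#' quote-escaped identifiers and a fixed ORDER BY. Identical selections —
#' regardless of input order — yield identical text.
#'
#' @param features,samples non-empty character vectors of identifiers
#' @param schema named list of table names (see [default_schema()])
#' @return a single SQL string
#' @export
translate_selection_to_sql <- function(features, samples,
                                       schema = default_schema()) {
  if (length(features) == 0L || length(samples) == 0L)
    stop_usage("translate_selection_to_sql() requires non-empty ID lists")
  fin <- paste(quote_sql_string(sort(unique(as.character(features)))),
               collapse = ", ")
  sin <- paste(quote_sql_string(sort(unique(as.character(samples)))),
               collapse = ", ")
  sprintf(paste0("SELECT feature_id, sample_id, value FROM %s ",
                 "WHERE feature_id IN (%s) AND sample_id IN (%s) ",
                 "ORDER BY feature_id, sample_id"),
          schema$assay, fin, sin)
}

#' Pivot long-format assay records to a dense matrix
#'
#' `out[i, j]` is the `value` of the record keyed
#' `(feature_order[i], sample_order[j])` when present, else `fill`.
#' Records keyed outside the given orders, and duplicate keys, are errors.
#' The default fill is `NA`: absence of a record is not evidence of zero
#' expression. Pass `fill = 0` explicitly for sparse count stores.
#'
#' @param records data.frame with columns `feature_id`, `sample_id`, `value`
#' @param feature_order,sample_order identifier vectors fixing the axes
#' @param fill value for absent pairs, default `NA_real_`
#' @return dense numeric matrix with `feature_order`/`sample_order` dimnames
#' @export
pivot_long_to_dense <- function(records, feature_order, sample_order,
                                fill = NA_real_) {
  i <- match(records$feature_id, feature_order)
  j <- match(records$sample_id, sample_order)
  if (anyNA(i))
    stop_data("record(s) with feature_id outside the given order: %s",
              paste(utils::head(unique(records$feature_id[is.na(i)]), 5L),
                    collapse = ", "))
  if (anyNA(j))
    stop_data("record(s) with sample_id outside the given order: %s",
              paste(utils::head(unique(records$sample_id[is.na(j)]), 5L),
                    collapse = ", "))
  key <- paste(i, j)
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), , drop = FALSE]
    stop_data("duplicate (feature, sample) record(s): %s",
              paste(utils::head(paste0("(", d$feature_id, ",", d$sample_id,
                                       ")"), 5L), collapse = ", "))
  }
  out <- matrix(as.numeric(fill), length(feature_order), length(sample_order),
                dimnames = list(feature_order, sample_order))
  out[cbind(i, j)] <- as.numeric(records$value)
  out
}

#' Lazy SQL seed
#'
#' An [AssaySeed] whose blocks are fetched by translating the block's
#' feature/sample identifiers to SQL and pivoting the long result. The
#' number of long records fetched per read is recorded in
#' `seed@log$rows_fetched` (query-economy audits).
#'
#' @aliases SqlSeed SqlSeed-class
#' @exportClass SqlSeed
setClass("SqlSeed", contains = "AssaySeed",
         representation(con = "ANY", schema = "list",
                        feature_ids = "character", sample_ids = "character",
                        fill = "numeric"))

setMethod("seed_dim", "SqlSeed", function(seed)
  c(length(seed@feature_ids), length(seed@sample_ids)))
setMethod("seed_chunkdim", "SqlSeed", function(seed) NULL)
setMethod("read_block_impl", "SqlSeed", function(seed, rows, cols, ...) {
  f <- seed@feature_ids[rows[1L]:rows[2L]]
  s <- seed@sample_ids[cols[1L]:cols[2L]]
  sql <- translate_selection_to_sql(f, s, seed@schema)
  rec <- DBI::dbGetQuery(seed@con, sql)
  seed@log$rows_fetched <- c(seed@log$rows_fetched %||% integer(), nrow(rec))
  unname(pivot_long_to_dense(rec, f, s, fill = seed@fill))
})

# One IN-list query covers an arbitrary scattered selection; contiguity
# buys nothing in SQL, so realize a whole view in a single round trip.
setMethod("seed_read_scattered", "SqlSeed",
          function(seed, rows, cols, block_cells) {
            f <- seed@feature_ids[rows]
            s <- seed@sample_ids[cols]
            sql <- translate_selection_to_sql(f, s, seed@schema)
            rec <- DBI::dbGetQuery(seed@con, sql)
            seed@log$rows_fetched <- c(seed@log$rows_fetched %||% integer(),
                                       nrow(rec))
            seed@log$reads[[length(seed@log$reads) + 1L]] <-
              c(r0 = min(rows), r1 = max(rows),
                c0 = min(cols), c1 = max(cols))
            unname(pivot_long_to_dense(rec, f, s, fill = seed@fill))
          })

check_table_columns <- function(con, table, required) {
  if (!DBI::dbExistsTable(con, table))
    stop_data("required table '%s' is missing", table)
  have <- DBI::dbListFields(con, table)
  miss <- setdiff(required, have)
  if (length(miss))
    stop_data("table '%s' is missing mandatory column(s): %s", table,
              paste(miss, collapse = ", "))
}

.sql_comparators <- c("=", "!=", "<", "<=", ">", ">=")

#' Build a lazy SummarizedExperiment from a triple-store database
#'
#' Reads the feature and sample annotation tables eagerly, sorted by
#' identifier (result order of SQL engines is otherwise unspecified;
#' sorting makes construction deterministic), optionally restricting
#' samples with a single-column predicate. Genomic ranges are attached
#' when the feature table carries `seqname`/`start`/`end` (and optionally
#' `strand`) columns. The assay is exposed as a lazy [SqlSeed]: no
#' assay-table rows are read at build time.
#'
#' @param con a DBI connection
#' @param sample_predicate optional `list(column, comparator, constant)`
#'   restricting samples, e.g. `list("cohort", "=", "COAD")`
#' @param schema named list of table names (see [default_schema()])
#' @param fill value for absent (feature, sample) pairs, default `NA`
#' @return a SummarizedExperiment with a SQL-backed lazy assay
#' @export
build_se_from_sql <- function(con, sample_predicate = NULL,
                              schema = default_schema(), fill = NA_real_) {
  check_table_columns(con, schema$assay,
                      c("feature_id", "sample_id", "value"))
  check_table_columns(con, schema$features, "feature_id")
  check_table_columns(con, schema$samples, "sample_id")
  feat <- DBI::dbGetQuery(con, sprintf(
    "SELECT * FROM %s ORDER BY feature_id", schema$features))
  where <- ""
  if (!is.null(sample_predicate)) {
    stopifnot(length(sample_predicate) == 3L)
    col <- sample_predicate[[1L]]; cmp <- sample_predicate[[2L]]
    val <- sample_predicate[[3L]]
    if (!cmp %in% .sql_comparators)
      stop_usage("unsupported predicate comparator '%s'", cmp)
    if (!col %in% DBI::dbListFields(con, schema$samples))
      stop_data("predicate column '%s' not in table '%s'", col,
                schema$samples)
    lit <- if (is.numeric(val)) format(val, scientific = FALSE)
           else quote_sql_string(as.character(val))
    where <- sprintf(" WHERE %s %s %s", col, cmp, lit)
  }
  samp <- DBI::dbGetQuery(con, sprintf(
    "SELECT * FROM %s%s ORDER BY sample_id", schema$samples, where))
  fid <- check_ids(feat$feature_id, "feature")
  sid <- if (nrow(samp)) check_ids(samp$sample_id, "sample") else character()
  rownames(feat) <- fid
  rownames(samp) <- sid
  seed <- new("SqlSeed", con = con, schema = schema, feature_ids = fid,
              sample_ids = sid, fill = as.numeric(fill),
              log = new_seed_log())
  ranges <- NULL
  if (all(c("seqname", "start", "end") %in% names(feat)) && nrow(feat)) {
    ranges <- GenomicRanges::GRanges(
      feat$seqname, IRanges::IRanges(feat$start, feat$end),
      strand = if ("strand" %in% names(feat)) feat$strand else "*")
  }
  drop_cols <- c("feature_id", "seqname", "start", "end", "strand")
  row_data <- feat[, setdiff(names(feat), drop_cols), drop = FALSE]
  col_data <- samp[, setdiff(names(samp), "sample_id"), drop = FALSE]
  make_se(lazy_matrix(seed), row_data, col_data, row_ranges = ranges)
}
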