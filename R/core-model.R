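#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#'   rowRanges
#' @importFrom SummarizedExperiment rowData<- colData<- assay<- rowRanges<-
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom S4Vectors DataFrame
NULL

check_ids <- function(ids, what) {
  ids <- as.character(ids)
  if (any(is.na(ids) | !nzchar(ids)))
    stop_data("%s identifiers must be non-empty", what)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_data("duplicate %s identifiers: %s", what,
              paste(utils::head(dup, 5L), collapse = ", "))
  ids
}

#' Construct a lazy SummarizedExperiment
#'
#' Binds an assay (a [LazyMatrix] or a plain matrix, which is wrapped in an
#' in-memory seed) to feature- and sample-level metadata, and optionally to
#' per-feature genomic ranges. Construction touches no assay values: for a
#' remote-backed assay, zero value requests are issued.
#'
#' Feature and sample identifiers are the `row.names` of `row_data` /
#' `col_data`; they must be unique and non-empty (duplicate rownames,
#' while tolerated elsewhere in the ecosystem, would make identifier
#' selection ambiguous and are rejected here).
#'
#' @param assay a [LazyMatrix] or numeric matrix, features x samples
#' @param row_data data.frame/DataFrame of feature metadata; rownames are
#'   the feature identifiers
#' @param col_data data.frame/DataFrame of sample metadata; rownames are
#'   the sample identifiers
#' @param row_ranges optional [GenomicRanges::GRanges], one range per
#'   feature, positionally aligned with `row_data`
#' @return a [SummarizedExperiment::SummarizedExperiment] (ranged when
#'   `row_ranges` is supplied) whose assay `"x"` is lazy
#' @export
make_se <- function(assay, row_data, col_data, row_ranges = NULL) {
  if (is.matrix(assay)) assay <- lazy_matrix(memory_seed(assay))
  if (!is(assay, "LazyMatrix"))
    stop_usage("assay must be a LazyMatrix or a base matrix")
  row_data <- as(row_data, "DataFrame")
  col_data <- as(col_data, "DataFrame")
  fid <- check_ids(rownames(row_data), "feature")
  sid <- check_ids(rownames(col_data), "sample")
  if (nrow(assay) != length(fid))
    stop_data("assay has %d rows but row_data describes %d features",
              nrow(assay), length(fid))
  if (ncol(assay) != length(sid))
    stop_data("assay has %d columns but col_data describes %d samples",
              ncol(assay), length(sid))
  if (!is.null(row_ranges)) {
    if (!is(row_ranges, "GRanges"))
      stop_usage("row_ranges must be a GRanges")
    if (length(row_ranges) != length(fid))
      stop_data("row_ranges has %d entries for %d features",
                length(row_ranges), length(fid))
    names(row_ranges) <- fid
    se <- SummarizedExperiment(assays = list(x = assay),
                               rowRanges = row_ranges,
                               colData = col_data)
    rowData(se) <- row_data
    rownames(se) <- fid
  } else {
    se <- SummarizedExperiment(assays = list(x = assay),
                               rowData = row_data, colData = col_data)
    rownames(se) <- fid
  }
  se
}

resolve_selector <- function(sel, ids, axis) {
  n <- length(ids)
  if (is.null(sel)) return(seq_len(n))
  if (is.character(sel) && length(sel) == 1L && identical(sel, "all"))
    return(seq_len(n))
  if (is.logical(sel)) {
    if (length(sel) != n)
      stop_data("logical %s selector has length %d; expected %d",
                axis, length(sel), n)
    return(which(sel))
  }
  if (is.character(sel)) {
    pos <- match(sel, ids)
    if (anyNA(pos))
      stop_data("unknown %s identifier(s): %s", axis,
                paste(unique(sel[is.na(pos)]), collapse = ", "))
    return(pos)
  }
  if (is.numeric(sel)) {
    sel <- as.integer(sel)
    bad <- sel[sel < 1L | sel > n]
    if (length(bad))
      stop_data("%s position(s) out of range [1, %d]: %s", axis, n,
                paste(utils::head(bad, 5L), collapse = ", "))
    return(sel)
  }
  stop_usage("unsupported %s selector of class %s", axis, class(sel)[1L])
}

#' Subset a lazy SummarizedExperiment by feature and sample selectors
#'
#' The `X[K, S]` idiom as a function. Selectors may be `NULL`/`"all"`
#' (keep everything), character identifier vectors, 1-based positions, or
#' logical masks. Selection order is preserved and duplicated positions are
#' repeated. Metadata and ranges are filtered and reordered in step with
#' the assay view; no assay values are read.
#'
#' @param se a SummarizedExperiment from [make_se()]
#' @param features,samples selectors for the feature and sample axes
#' @return the subset SummarizedExperiment, assay still lazy
#' @export
subset_se <- function(se, features = NULL, samples = NULL) {
  k <- resolve_selector(features, rownames(se), "feature")
  s <- resolve_selector(samples, colnames(se), "sample")
  se[k, s]
}

#' Restrict features to those overlapping regions of interest
#'
#' Keeps every feature whose genomic range overlaps any `roi` interval
#' (closed-interval semantics; strand ignored by default), in the original
#' feature order. All samples are retained.
#'
#' @param se a *ranged* SummarizedExperiment from [make_se()]
#' @param roi a [GenomicRanges::GRanges] of query regions, or a region
#'   string accepted by [parse_region()]
#' @param strand_aware logical; see [overlaps_any()]
#' @return the restricted SummarizedExperiment (possibly 0 features)
#' @export
subset_by_overlaps <- function(se, roi, strand_aware = FALSE) {
  if (!is(se, "RangedSummarizedExperiment"))
    stop_data("subset_by_overlaps() requires feature genomic ranges; this experiment has none")
  if (is.character(roi)) roi <- parse_region(roi)
  mask <- overlaps_any(rowRanges(se), roi, strand_aware = strand_aware)
  subset_se(se, features = which(mask))
}

#' Bind external sample covariates onto an experiment
#'
#' Left-joins a keyed table of covariates onto the sample metadata by
#' sample identifier — the hybrid data/annotation pattern for covariates
#' (clinical scores, batch labels) that live outside the assay store.
#' Samples absent from `table` receive `NA`; downstream stratification
#' drops them and reports the count. The assay is untouched.
#'
#' @param se a SummarizedExperiment
#' @param table data.frame of covariates
#' @param key_column name of the column in `table` holding sample IDs
#' @param value_columns character vector of columns to bind (default: all
#'   non-key columns)
#' @return the SummarizedExperiment with extended `colData`
#' @export
bind_sample_data <- function(se, table, key_column,
                             value_columns = setdiff(names(table), key_column)) {
  if (!key_column %in% names(table))
    stop_usage("key column '%s' not present in table", key_column)
  missing_cols <- setdiff(value_columns, names(table))
  if (length(missing_cols))
    stop_usage("value column(s) not in table: %s",
               paste(missing_cols, collapse = ", "))
  keys <- as.character(table[[key_column]])
  if (anyDuplicated(keys))
    stop_data("duplicate key(s) in table: %s",
              paste(unique(keys[duplicated(keys)]), collapse = ", "))
  clash <- intersect(value_columns, colnames(colData(se)))
  if (length(clash))
    stop_data("column(s) already present in sample metadata: %s",
              paste(clash, collapse = ", "))
  pos <- match(colnames(se), keys)
  cd <- colData(se)
  for (vc in value_columns) cd[[vc]] <- table[[vc]][pos]
  SummarizedExperiment::colData(se) <- cd
  se
}

resolve_feature <- function(se, feature, lookup_col = NULL) {
  if (is.null(lookup_col)) {
    ind <- match(feature, rownames(se))
    if (is.na(ind)) stop_data("unknown feature identifier: %s", feature)
    return(ind)
  }
  if (!lookup_col %in% colnames(rowData(se)))
    stop_data("feature metadata has no column '%s'", lookup_col)
  vals <- rowData(se)[[lookup_col]]
  hits <- which(vals == feature)
  if (length(hits) == 0L)
    stop_data("no feature with %s == '%s'", lookup_col, feature)
  if (length(hits) > 1L)
    warning(sprintf("%d features match %s == '%s'; using the first (row %d)",
                    length(hits), lookup_col, feature, hits[1L]))
  hits[1L]
}

.comparators <- list(
  ">=" = list(fn = `>=`, neg = "<"),
  ">"  = list(fn = `>`,  neg = "<="),
  "<=" = list(fn = `<=`, neg = ">"),
  "<"  = list(fn = `<`,  neg = ">=")
)

#' One gene's transformed values, split by a thresholded sample covariate
#'
#' The single-gene stratification recipe: fetch exactly one assay row
#' (verifiable on a remote back end via its request log), transform it
#' elementwise, and split the per-sample values by comparing one sample
#' covariate against a threshold. Group labels follow the
#' `"<t"` / `">=t"` convention. Samples whose covariate is missing are
#' excluded; their count is attached as attribute `n_dropped`.
#'
#' @param se a SummarizedExperiment from [make_se()]
#' @param feature a feature identifier, or — with `lookup_col` — a value
#'   matched (first match) against a feature-metadata column, mirroring the
#'   match-on-symbol idiom
#' @param group_col name of the sample covariate to threshold
#' @param threshold numeric threshold
#' @param comparator one of `">="`, `">"`, `"<="`, `"<"`; default `">="`
#' @param transform one of [transform_names()]; default `"log2p1"`
#' @param lookup_col optional feature-metadata column for symbol-style lookup
#' @return named list of two numeric vectors (complement group first),
#'   with attributes `n_dropped` and `feature_index`
#' @export
gene_by_group <- function(se, feature, group_col, threshold,
                          comparator = ">=", transform = "log2p1",
                          lookup_col = NULL) {
  check_transform(transform)
  if (!comparator %in% names(.comparators))
    stop_usage("unknown comparator '%s'; valid: %s", comparator,
               paste(names(.comparators), collapse = ", "))
  if (!group_col %in% colnames(colData(se)))
    stop_data("sample metadata has no column '%s'", group_col)
  ind <- resolve_feature(se, feature, lookup_col)
  grp <- colData(se)[[group_col]]
  keep <- !is.na(grp)
  n_dropped <- sum(!keep)
  # exactly one assay row crosses the wire
  vals <- as.numeric(realize(lazy_apply(assay(se)[ind, , drop = FALSE],
                                        transform)))
  cmp <- .comparators[[comparator]]
  flag <- cmp$fn(grp[keep], threshold)
  labs <- c(paste0(cmp$neg, threshold), paste0(comparator, threshold))
  out <- split(vals[keep], factor(flag, levels = c(FALSE, TRUE),
                                  labels = labs))
  attr(out, "n_dropped") <- n_dropped
  attr(out, "feature_index") <- ind
  out
}

#' Summarize a gene_by_group() result
#'
#' @param groups result of [gene_by_group()]
#' @return data.frame with one row per group: `group`, `n`, `mean`, `median`
#' @export
group_summary <- function(groups) {
  data.frame(group = names(groups),
             n = vapply(groups, length, integer(1)),
             mean = vapply(groups, function(v) mean(v), numeric(1)),
             median = vapply(groups, function(v) stats::median(v), numeric(1)),
             row.names = NULL)
}
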