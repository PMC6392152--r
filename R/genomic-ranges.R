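# Interval conventions: 1-based, closed on both ends, strand in {+, -, *},
# matching GRanges semantics throughout. Overlap is closed-interval
# intersection (a shared boundary base counts); strand is ignored unless
# strand_aware = TRUE, in which case "*" is compatible with either strand.

#' Parse a region-of-interest string
#'
#' Accepts `"chr1:100-200"` or `"chr1:100-200:+"`; coordinates are 1-based
#' closed; strand defaults to `*`.
#'
#' @param text a single region string
#' @return a length-1 [GenomicRanges::GRanges]
#' @export
parse_region <- function(text) {
  if (length(text) != 1L || !is.character(text))
    stop_usage("parse_region() expects one string")
  m <- regexec("^([^:]+):([0-9]+)-([0-9]+)(?::([+*-]))?$", text)[[1]]
  if (m[1L] == -1L)
    stop_data("malformed region '%s'; expected seq:start-end[:strand]", text)
  parts <- regmatches(text, regexec("^([^:]+):([0-9]+)-([0-9]+)(?::([+*-]))?$",
                                    text))[[1]]
  start <- as.numeric(parts[3L]); end <- as.numeric(parts[4L])
  if (start < 1)
    stop_data("malformed region '%s': start must be >= 1", text)
  if (start > end)
    stop_data("malformed region '%s': start %s > end %s (at position %d)",
              text, format(start, scientific = FALSE),
              format(end, scientific = FALSE),
              as.integer(regexpr("-", text)))
  strand <- if (nzchar(parts[5L])) parts[5L] else "*"
  GenomicRanges::GRanges(parts[2L],
                         IRanges::IRanges(start, end), strand = strand)
}

#' Find overlapping interval pairs
#'
#' Returns every `(query_index, subject_index)` pair whose intervals share
#' a chromosome and intersect under closed-interval semantics
#' (`q.start <= s.end && s.start <= q.end`). With `strand_aware = TRUE`,
#' pairs must additionally have compatible strands (`*` matches both).
#'
#' @param query,subject [GenomicRanges::GRanges] objects
#' @param strand_aware logical; default ignores strand
#' @return data.frame with integer columns `query`, `subject`, sorted by
#'   `(query, subject)`
#' @export
find_overlaps <- function(query, subject, strand_aware = FALSE) {
  hits <- quiet_seqlevel_warning(
    GenomicRanges::findOverlaps(query, subject,
                                ignore.strand = !strand_aware))
  df <- data.frame(query = S4Vectors::queryHits(hits),
                   subject = S4Vectors::subjectHits(hits))
  df[order(df$query, df$subject), , drop = FALSE]
}

#' Which subject intervals overlap any query interval
#'
#' @param subject,query [GenomicRanges::GRanges] objects
#' @param strand_aware logical
#' @return logical mask over `subject`
#' @export
overlaps_any <- function(subject, query, strand_aware = FALSE) {
  quiet_seqlevel_warning(
    IRanges::overlapsAny(subject, query, ignore.strand = !strand_aware))
}

# querying a chromosome absent from the subject is a legitimate request
# with an empty answer, not a condition worth warning about
quiet_seqlevel_warning <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("sequence levels in common", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' Read regions of interest from a BED file
#'
#' BED is 0-based half-open on disk; the returned `GRanges` uses this
#' package's 1-based closed convention (the conversion adds 1 to starts).
#'
#' @param path BED file path
#' @return a [GenomicRanges::GRanges]
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_data("BED file not found: %s", path)
  rtracklayer::import(path, format = "BED")
}
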