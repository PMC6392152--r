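#' Export a realized experiment slice
#'
#' Materializes the assay of `se` and writes it in one of three plain
#' formats:
#' \describe{
#'   \item{`csv`}{one file: feature IDs in the first column, sample IDs as
#'     the header row; `.` decimal point, no thousands separators.}
#'   \item{`mtx`}{MatrixMarket coordinate format (1-based indices) at
#'     `<path>.mtx`, plus `<path>.features.txt` and `<path>.samples.txt`
#'     holding the row and column identifiers, one per line.}
#'   \item{`h5`}{a single HDF5 file with `/assay` (2-D), `/features`,
#'     `/samples`, and one dataset per metadata column under `/row_data`
#'     and `/col_data`.}
#' }
#'
#' @param se a SummarizedExperiment from [make_se()]
#' @param path output path (for `mtx`, the prefix)
#' @param format `"csv"`, `"mtx"` or `"h5"`
#' @param block_cells realization block budget
#' @return invisibly, the path(s) written
#' @export
export_se <- function(se, path, format = c("csv", "mtx", "h5"),
                      block_cells = DEFAULT_BLOCK_CELLS) {
  format <- match.arg(format)
  m <- realize(assay(se), block_cells)
  fid <- rownames(se); sid <- colnames(se)
  switch(format,
    csv = {
      df <- data.frame(feature_id = fid, m, check.names = FALSE)
      colnames(df) <- c("feature_id", sid)
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
      invisible(path)
    },
    mtx = {
      mtx <- paste0(path, ".mtx")
      Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                  "generalMatrix"), mtx)
      writeLines(fid, paste0(path, ".features.txt"))
      writeLines(sid, paste0(path, ".samples.txt"))
      invisible(c(mtx, paste0(path, ".features.txt"),
                  paste0(path, ".samples.txt")))
    },
    h5 = {
      if (file.exists(path)) file.remove(path)
      rhdf5::h5createFile(path)
      rhdf5::h5write(m, path, "assay")
      rhdf5::h5write(fid, path, "features")
      rhdf5::h5write(sid, path, "samples")
      rhdf5::h5createGroup(path, "row_data")
      rd <- rowData(se)
      for (cn in colnames(rd))
        rhdf5::h5write(as.vector(rd[[cn]]), path, paste0("row_data/", cn))
      rhdf5::h5createGroup(path, "col_data")
      cd <- colData(se)
      for (cn in colnames(cd))
        rhdf5::h5write(as.vector(cd[[cn]]), path, paste0("col_data/", cn))
      invisible(path)
    })
}
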