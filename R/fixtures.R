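# Deterministic synthetic fixtures. One explicitly seeded Mersenne-Twister
# stream, draws in documented order (gene means, sample covariates/labels,
# then the count matrix column-major), so a FixtureSpec is a stable,
# versionable promise: identical specs give bit-identical fixtures.

#' Fixture specification
#'
#' Describes one synthetic dataset. Two scenarios emulate the shapes of
#' the package's two motivating applications:
#' \describe{
#'   \item{`singlecell_panned`}{an immunopanning-style single-cell count
#'     matrix: cells carry one of four capture-class labels (column
#'     `label`), and each class has a designated marker gene whose mean is
#'     multiplied by `effect` within that class.}
#'   \item{`cohort_msi`}{a tumor-cohort matrix: samples carry a continuous
#'     microsatellite-instability-like score (column `msi_like`,
#'     exponential with mean 3), and a designated gene's mean is multiplied
#'     by `effect` in samples with score >= 4 — the threshold used by the
#'     stratified single-gene recipe.}
#' }
#' Counts are negative binomial with lognormal baseline gene means
#' (`meanlog = 1.5`, `sdlog = 1`) and dispersion `nb_dispersion`
#' (`size = 1/dispersion`). Features are laid out as non-overlapping
#' consecutive 100-bp intervals (50-bp gaps) on two chromosomes, first
#' half on chr1, second on chr2, strands alternating `+`/`-`.
#'
#' @param n_features,n_samples matrix dimensions (default 500 x 400)
#' @param seed integer RNG seed
#' @param scenario `"singlecell_panned"` or `"cohort_msi"`
#' @param effect fold-change (> 1) for marker / score-linked genes,
#'   default 4
#' @param nb_dispersion negative-binomial dispersion, default 0.3
#' @param chunk_shape HDF5 chunk geometry for [write_h5_fixture()]
#' @return a `fixture_spec` list
#' @export
fixture_spec <- function(n_features = 500L, n_samples = 400L, seed = 1L,
                         scenario = c("singlecell_panned", "cohort_msi"),
                         effect = 4, nb_dispersion = 0.3,
                         chunk_shape = c(50L, 80L)) {
  scenario <- match.arg(scenario)
  if (n_features < 8L || n_samples < 8L)
    stop_usage("fixture dimensions must be at least 8 x 8")
  if (effect <= 1) stop_usage("effect fold-change must exceed 1")
  structure(list(n_features = as.integer(n_features),
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 scenario = scenario, effect = effect,
                 nb_dispersion = nb_dispersion,
                 chunk_shape = as.integer(chunk_shape)),
            class = "fixture_spec")
}

.panned_classes <- c("selection: CD45+", "selection: Astrocyte",
                     "selection: Neuron", "selection: Endothelial")

#' Simulate a fixture
#'
#' Draws the count matrix and its metadata per the scenario in `spec`.
#' The caller's RNG state is left untouched.
#'
#' @param spec a [fixture_spec()]
#' @return list with `counts` (features x samples, dimnames set),
#'   `row_data` (data.frame; columns `symbol`, `row_index` sentinel, and
#'   per-scenario marker columns), `col_data`, and `row_ranges`
#'   ([GenomicRanges::GRanges])
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  G <- spec$n_features; N <- spec$n_samples
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  fid <- sprintf("g%04d", seq_len(G))
  sid <- sprintf("s%04d", seq_len(N))
  mu_base <- rlnorm(G, meanlog = 1.5, sdlog = 1)
  mu <- matrix(mu_base, G, N)

  row_data <- data.frame(symbol = sprintf("SYM%04d", seq_len(G)),
                         row_index = seq_len(G), row.names = fid)
  if (spec$scenario == "singlecell_panned") {
    label <- sample(.panned_classes, N, replace = TRUE)
    marker_rows <- seq_len(4L)
    for (k in seq_along(marker_rows))
      mu[marker_rows[k], label == .panned_classes[k]] <-
        mu_base[marker_rows[k]] * spec$effect
    row_data$marker_class <- NA_character_
    row_data$marker_class[marker_rows] <- .panned_classes
    col_data <- data.frame(label = label, row.names = sid)
  } else {
    msi_like <- round(rexp(N, rate = 1 / 3), 3)
    mu[1L, msi_like >= 4] <- mu_base[1L] * spec$effect
    row_data$msi_gene <- c(TRUE, rep(FALSE, G - 1L))
    col_data <- data.frame(msi_like = msi_like, row.names = sid)
  }

  counts <- matrix(as.double(rnbinom(G * N, size = 1 / spec$nb_dispersion,
                                     mu = as.vector(mu))),
                   G, N, dimnames = list(fid, sid))

  half <- G %/% 2L
  seq_pos <- c(seq_len(half), seq_len(G - half))
  starts <- 1L + (seq_pos - 1L) * 150L
  row_ranges <- GenomicRanges::GRanges(
    rep(c("chr1", "chr2"), c(half, G - half)),
    IRanges::IRanges(starts, starts + 99L),
    strand = rep_len(c("+", "-"), G))
  names(row_ranges) <- fid

  list(counts = counts, row_data = row_data, col_data = col_data,
       row_ranges = row_ranges)
}

#' In-memory SummarizedExperiment over a fixture
#' @param sim a [simulate_counts()] result
#' @return a SummarizedExperiment with a [memory_seed()]-backed lazy assay
#' @export
fixture_se <- function(sim) {
  make_se(lazy_matrix(memory_seed(sim$counts)), sim$row_data, sim$col_data,
          row_ranges = sim$row_ranges)
}

ranges_columns <- function(sim) {
  rr <- sim$row_ranges
  data.frame(seqname = as.character(GenomicRanges::seqnames(rr)),
             start = GenomicRanges::start(rr),
             end = GenomicRanges::end(rr),
             strand = as.character(GenomicRanges::strand(rr)))
}

#' Write a fixture as an HDF5 file
#'
#' Layout: `/assay` (2-D float64, chunked), `/features`, `/samples`
#' (strings), one 1-D dataset per metadata column under `/row_data` and
#' `/col_data` (genomic coordinates stored as `seqname`/`start`/`end`/
#' `strand` row columns).
#'
#' @param sim a [simulate_counts()] result
#' @param path output file
#' @param chunk_shape `(rows, cols)` chunk geometry
#' @return invisibly, `path`
#' @export
write_h5_fixture <- function(sim, path, chunk_shape = c(50L, 80L)) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  d <- dim(sim$counts)
  rhdf5::h5createDataset(path, "assay", dims = d, storage.mode = "double",
                         chunk = pmin(as.integer(chunk_shape), d))
  rhdf5::h5write(unname(sim$counts), path, "assay")
  rhdf5::h5write(rownames(sim$counts), path, "features")
  rhdf5::h5write(colnames(sim$counts), path, "samples")
  rhdf5::h5createGroup(path, "row_data")
  rd <- cbind(sim$row_data, ranges_columns(sim))
  for (cn in names(rd)) rhdf5::h5write(as.vector(rd[[cn]]), path,
                                       paste0("row_data/", cn))
  rhdf5::h5createGroup(path, "col_data")
  for (cn in names(sim$col_data))
    rhdf5::h5write(as.vector(sim$col_data[[cn]]), path,
                   paste0("col_data/", cn))
  invisible(path)
}

#' Write a fixture as a SQLite triple-store database
#'
#' Creates the three-table schema (DDL shipped at
#' `system.file("sql", "schema.sql", package = "lazyse")`): long-format
#' `assay` plus `features` and `samples` annotation tables, with genomic
#' coordinates on the feature table.
#'
#' @param sim a [simulate_counts()] result
#' @param path SQLite database path
#' @return invisibly, `path`
#' @export
write_sql_fixture <- function(sim, path) {
  if (file.exists(path)) file.remove(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  ddl <- readLines(system.file("sql", "schema.sql", package = "lazyse"))
  for (stmt in strsplit(paste(ddl, collapse = "\n"), ";", fixed = TRUE)[[1]])
    if (nzchar(trimws(stmt))) DBI::dbExecute(con, stmt)
  feat <- cbind(data.frame(feature_id = rownames(sim$counts)),
                sim$row_data, ranges_columns(sim))
  # generated feature tables may carry scenario-specific columns beyond the
  # DDL; recreate with the actual column set
  DBI::dbRemoveTable(con, "features")
  DBI::dbWriteTable(con, "features", feat)
  samp <- cbind(data.frame(sample_id = colnames(sim$counts)), sim$col_data)
  DBI::dbRemoveTable(con, "samples")
  DBI::dbWriteTable(con, "samples", samp)
  long <- data.frame(
    feature_id = rep(rownames(sim$counts), times = ncol(sim$counts)),
    sample_id = rep(colnames(sim$counts), each = nrow(sim$counts)),
    value = as.vector(sim$counts))
  DBI::dbAppendTable(con, "assay", long)
  invisible(path)
}

#' Write a fixture as a CSV bundle
#'
#' `<prefix>.assay.csv` (feature IDs first column, sample IDs header),
#' `<prefix>.row_data.csv`, `<prefix>.col_data.csv`.
#'
#' @param sim a [simulate_counts()] result
#' @param prefix output path prefix
#' @return invisibly, the paths written
#' @export
write_csv_fixture <- function(sim, prefix) {
  a <- paste0(prefix, ".assay.csv")
  df <- data.frame(feature_id = rownames(sim$counts), sim$counts,
                   check.names = FALSE)
  utils::write.csv(df, a, row.names = FALSE, quote = FALSE)
  r <- paste0(prefix, ".row_data.csv")
  utils::write.csv(cbind(data.frame(feature_id = rownames(sim$counts)),
                         sim$row_data, ranges_columns(sim)),
                   r, row.names = FALSE)
  cpath <- paste0(prefix, ".col_data.csv")
  utils::write.csv(cbind(data.frame(sample_id = colnames(sim$counts)),
                         sim$col_data), cpath, row.names = FALSE)
  invisible(c(a, r, cpath))
}
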