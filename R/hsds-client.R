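# Client for the minimal HDF-REST dialect. Opening a dataset touches only
# metadata endpoints; values move exclusively through read_selection(),
# which plans hyperslab GETs with plan_requests() and assembles the
# responses. Retry policy: up to `max_retries` attempts per slab with
# exponential backoff (x2 starting at retry_base_s), retrying only
# transport errors and 5xx; 4xx are never retried; 413 causes the slab to
# be split in half along its longer axis and re-tried as two requests.

#' Remote dataset handle (HDF-REST seed)
#'
#' Satisfies the [AssaySeed] contract over a service speaking the minimal
#' HDF-REST dialect, so a [LazyMatrix] — and hence a SummarizedExperiment —
#' can be backed by a remote matrix.
#'
#' @aliases HsdsSeed HsdsSeed-class
#' @exportClass HsdsSeed
setClass("HsdsSeed", contains = "AssaySeed",
         representation(base_url = "character", domain = "character",
                        uuid = "character", dims = "integer",
                        chunkdim = "integer", value_kind = "character",
                        transport = "function", timeout_s = "numeric",
                        max_retries = "integer", waste_ratio = "numeric",
                        max_request_cells = "integer",
                        retry_base_s = "numeric"))

setMethod("seed_dim", "HsdsSeed", function(seed) seed@dims)
setMethod("seed_chunkdim", "HsdsSeed", function(seed)
  if (length(seed@chunkdim)) seed@chunkdim else NULL)
setMethod("read_block_impl", "HsdsSeed", function(seed, rows, cols, ...)
  read_selection(seed, rows[1L]:rows[2L], cols[1L]:cols[2L], .log = FALSE))

# A remote seed serves a whole scattered selection in one planned set of
# hyperslab requests rather than one request per contiguous run.
setMethod("seed_read_scattered", "HsdsSeed",
          function(seed, rows, cols, block_cells) {
            seed@log$reads[[length(seed@log$reads) + 1L]] <-
              c(r0 = min(rows), r1 = max(rows),
                c0 = min(cols), c1 = max(cols))
            read_selection(seed, rows, cols, .log = FALSE)
          })

hsds_get_json <- function(seed_or_transport, url, max_retries = 3L,
                          retry_base_s = 0.25) {
  transport <- if (is.function(seed_or_transport)) seed_or_transport
               else seed_or_transport@transport
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    res <- tryCatch(transport(url), lazyse_transport_error = function(e) e)
    retryable <- inherits(res, "lazyse_transport_error") ||
      (is.list(res) && res$status >= 500L)
    if (!retryable) return(res)
    if (attempt >= max_retries) {
      if (inherits(res, "lazyse_transport_error")) stop(res)
      stop_transport("HTTP %d from %s after %d attempts",
                     res$status, url, attempt)
    }
    Sys.sleep(retry_base_s * 2^(attempt - 1L))
  }
}

#' Open a remote 2-D dataset
#'
#' Populates a handle from the service's metadata endpoints only: shape,
#' value kind and chunk geometry are fetched, but zero value requests are
#' issued.
#'
#' @param base_url service base URL (for a [MockHsds], any scheme/host —
#'   only the path is routed)
#' @param domain dataset-collection path on the service
#' @param dataset dataset name/uuid; `NULL` picks the dataset named
#'   `"assay"` if present, else errors
#' @param transport a transport from [mock_transport()] or
#'   [curl_transport()]
#' @param timeout_s,max_retries,retry_base_s client retry policy
#' @param waste_ratio,max_request_cells planning policy for subsequent
#'   reads (see [plan_requests()])
#' @return an `HsdsSeed`
#' @export
open_remote_dataset <- function(base_url, domain, dataset = NULL,
                                transport = curl_transport(),
                                timeout_s = 10, max_retries = 3L,
                                retry_base_s = 0.25, waste_ratio = 0.5,
                                max_request_cells = DEFAULT_BLOCK_CELLS) {
  base_url <- sub("/+$", "", base_url)
  about <- hsds_get_json(transport, paste0(base_url, "/about"),
                         max_retries, retry_base_s)
  if (about$status != 200L)
    stop_transport("service at %s did not answer /about (HTTP %d)",
                   base_url, about$status)
  if (is.null(dataset)) {
    lst <- hsds_get_json(transport,
                         sprintf("%s/datasets?domain=%s", base_url,
                                 utils::URLencode(domain, reserved = TRUE)),
                         max_retries, retry_base_s)
    if (lst$status != 200L)
      stop_data("domain %s not found (HTTP %d)", domain, lst$status)
    names_avail <- unlist(jsonlite::fromJSON(lst$text)$datasets)
    if (!"assay" %in% names_avail)
      stop_data("no dataset named 'assay' in %s; available: %s", domain,
                paste(names_avail, collapse = ", "))
    dataset <- "assay"
  }
  meta <- hsds_get_json(transport,
                        sprintf("%s/datasets/%s?domain=%s", base_url, dataset,
                                utils::URLencode(domain, reserved = TRUE)),
                        max_retries, retry_base_s)
  if (meta$status == 404L)
    stop_data("dataset '%s' in domain '%s' not found (HTTP 404)",
              dataset, domain)
  if (meta$status != 200L)
    stop_transport("metadata request failed (HTTP %d)", meta$status)
  info <- jsonlite::fromJSON(meta$text)
  dims <- as.integer(unlist(info$shape$dims))
  if (length(dims) != 2L)
    stop_data("dataset '%s' is %d-dimensional; a 2-D dataset is required",
              dataset, length(dims))
  chunk <- as.integer(unlist(info$layout$dims))
  new("HsdsSeed", base_url = base_url, domain = domain, uuid = dataset,
      dims = dims, chunkdim = chunk,
      value_kind = as.character(info$type$class %||% "H5T_FLOAT"),
      transport = transport, timeout_s = timeout_s,
      max_retries = as.integer(max_retries), waste_ratio = waste_ratio,
      max_request_cells = as.integer(max_request_cells),
      retry_base_s = retry_base_s, log = new_seed_log())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

value_url <- function(seed, r0, r1, c0, c1) {
  # wire select is 0-based half-open
  sprintf("%s/datasets/%s/value?domain=%s&select=%s",
          seed@base_url, seed@uuid,
          utils::URLencode(seed@domain, reserved = TRUE),
          utils::URLencode(sprintf("[%d:%d,%d:%d]", r0 - 1L, r1, c0 - 1L, c1),
                           reserved = TRUE))
}

fetch_slab <- function(seed, r0, r1, c0, c1) {
  res <- tryCatch(
    hsds_get_json(seed, value_url(seed, r0, r1, c0, c1),
                  seed@max_retries, seed@retry_base_s),
    lazyse_transport_error = function(e)
      stop_transport("slab [%d:%d, %d:%d]: %s", r0, r1, c0, c1,
                     conditionMessage(e)))
  if (res$status == 413L) return(NULL)   # caller splits
  if (res$status != 200L)
    stop_transport("slab [%d:%d, %d:%d]: HTTP %d", r0, r1, c0, c1, res$status)
  v <- jsonlite::fromJSON(res$text, simplifyMatrix = TRUE)$value
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
  if (!identical(dim(v), c(r1 - r0 + 1L, c1 - c0 + 1L)))
    stop_protocol("slab [%d:%d, %d:%d]: response shape %s does not match",
                  r0, r1, c0, c1, paste(dim(v), collapse = "x"))
  storage.mode(v) <- "double"
  v
}

#' Read an arbitrary selection from a remote dataset
#'
#' Plans hyperslab requests for the selection (see [plan_requests()]),
#' issues one GET per slab with the retry policy, and assembles the
#' responses so that `out[i, j]` equals the remote value at
#' `(rows[i], cols[j])`. Order is preserved and duplicates are replicated
#' client-side — each cell crosses the wire at most once per call.
#' A 413 (service-enforced request limit) splits the offending slab in
#' half along its longer axis and continues.
#'
#' @param seed an `HsdsSeed` from [open_remote_dataset()]
#' @param rows,cols 1-based indices, any order, duplicates allowed
#' @param .log internal; record this read in the seed log
#' @return a dense matrix `length(rows)` by `length(cols)`
#' @export
read_selection <- function(seed, rows, cols, .log = TRUE) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  d <- seed_dim(seed)
  bad <- c(rows[rows < 1L | rows > d[1L]], cols[cols < 1L | cols > d[2L]])
  if (length(bad))
    stop_data("selection index out of range: %s",
              paste(utils::head(bad, 5L), collapse = ", "))
  if (length(rows) == 0L || length(cols) == 0L)
    return(matrix(numeric(), length(rows), length(cols)))
  rows0 <- sort(unique(rows)); cols0 <- sort(unique(cols))
  plan <- plan_requests(rows0, cols0, chunk_shape = seed_chunkdim(seed),
                        waste_ratio = seed@waste_ratio,
                        max_request_cells = seed@max_request_cells)
  base <- matrix(NA_real_, length(rows0), length(cols0))
  queue <- lapply(seq_len(nrow(plan$slabs)), function(k)
    as.integer(plan$slabs[k, ]))
  while (length(queue)) {
    sl <- queue[[1L]]; queue <- queue[-1L]
    blk <- fetch_slab(seed, sl[1L], sl[2L], sl[3L], sl[4L])
    if (is.null(blk)) {                       # 413: split along longer axis
      nr <- sl[2L] - sl[1L] + 1L; nc <- sl[4L] - sl[3L] + 1L
      if (nr == 1L && nc == 1L)
        stop_protocol("service rejected a single-cell request (413)")
      if (nr >= nc) {
        mid <- sl[1L] + nr %/% 2L - 1L
        queue <- c(list(c(sl[1L], mid, sl[3L], sl[4L]),
                        c(mid + 1L, sl[2L], sl[3L], sl[4L])), queue)
      } else {
        mid <- sl[3L] + nc %/% 2L - 1L
        queue <- c(list(c(sl[1L], sl[2L], sl[3L], mid),
                        c(sl[1L], sl[2L], mid + 1L, sl[4L])), queue)
      }
      next
    }
    rin <- which(rows0 >= sl[1L] & rows0 <= sl[2L])
    cin <- which(cols0 >= sl[3L] & cols0 <= sl[4L])
    base[rin, cin] <- blk[rows0[rin] - sl[1L] + 1L,
                          cols0[cin] - sl[3L] + 1L, drop = FALSE]
  }
  if (.log)
    seed@log$reads[[length(seed@log$reads) + 1L]] <-
      c(r0 = min(rows), r1 = max(rows), c0 = min(cols), c1 = max(cols))
  base[match(rows, rows0), match(cols, cols0), drop = FALSE]
}

#' Read a 1-D remote dataset in full
#'
#' Identifier vectors and metadata columns are served as 1-D datasets;
#' this fetches one whole vector (strings or numbers).
#'
#' @param base_url,domain,dataset,transport as in [open_remote_dataset()]
#' @param max_retries,retry_base_s retry policy
#' @return a character or numeric vector
#' @export
read_remote_vector <- function(base_url, domain, dataset,
                               transport = curl_transport(),
                               max_retries = 3L, retry_base_s = 0.25) {
  base_url <- sub("/+$", "", base_url)
  dom <- utils::URLencode(domain, reserved = TRUE)
  meta <- hsds_get_json(transport,
                        sprintf("%s/datasets/%s?domain=%s", base_url, dataset,
                                dom), max_retries, retry_base_s)
  if (meta$status != 200L)
    stop_data("dataset '%s' in '%s' not found (HTTP %d)", dataset, domain,
              meta$status)
  info <- jsonlite::fromJSON(meta$text)
  dims <- as.integer(unlist(info$shape$dims))
  if (length(dims) != 1L)
    stop_data("dataset '%s' is not 1-D", dataset)
  res <- hsds_get_json(transport,
                       sprintf("%s/datasets/%s/value?domain=%s&select=%s",
                               base_url, dataset, dom,
                               utils::URLencode(sprintf("[0:%d]", dims),
                                                reserved = TRUE)),
                       max_retries, retry_base_s)
  if (res$status != 200L)
    stop_transport("value request for '%s' failed (HTTP %d)", dataset,
                   res$status)
  unlist(jsonlite::fromJSON(res$text)$value)
}

#' List datasets in a remote domain
#' @inheritParams read_remote_vector
#' @return character vector of dataset names/uuids
#' @export
list_remote_datasets <- function(base_url, domain,
                                 transport = curl_transport(),
                                 max_retries = 3L, retry_base_s = 0.25) {
  base_url <- sub("/+$", "", base_url)
  res <- hsds_get_json(transport,
                       sprintf("%s/datasets?domain=%s", base_url,
                               utils::URLencode(domain, reserved = TRUE)),
                       max_retries, retry_base_s)
  if (res$status != 200L)
    stop_data("domain %s not found (HTTP %d)", domain, res$status)
  unlist(jsonlite::fromJSON(res$text)$datasets)
}
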