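# In-process mock of the minimal HDF-REST dialect.
#
# Dialect (all GET, all JSON):
#   {base}/about                          -> {"api_version": "minimal-1"}
#   {base}/datasets?domain=D              -> {"datasets": [uuid, ...]}
#   {base}/datasets/{uuid}?domain=D       -> {"shape":{"dims":[...]},
#                                             "type":{"class": ...},
#                                             "layout":{"dims":[cr,cc]}}
#   {base}/datasets/{uuid}/value?domain=D&select=[r0:r1,c0:c1]
#                                         -> {"value": row-major nested lists}
# `select` bounds are 0-based half-open. 2-D numeric datasets use the
# two-axis select; 1-D datasets (identifier vectors, metadata columns) use
# select=[a:b]. Dataset "uuids" are simply the dataset names (nested HDF5
# paths flattened with "."): the dialect has no name-lookup endpoint, so
# this makes open-by-name well defined.
#
# Floats are serialized with round-trip decimal precision (digits = NA), so
# client/oracle comparisons can demand exact equality, not tolerances.
# The request log is append-only and is the test surface for laziness
# claims. The service is read-only over its fixtures and single-threaded.

#' @importFrom R6 R6Class
#' @export
MockHsds <- R6::R6Class("MockHsds",
  public = list(
    #' @field domains named list: domain -> named list of datasets, each
    #'   `list(data=, chunk=)`
    domains = NULL,
    #' @field max_request_cells optional enforced per-request cell limit;
    #'   larger value selections receive status 413
    max_request_cells = NULL,

    #' @description Create a mock service.
    #' @param domains see field `domains`; vectors are treated as 1-D
    #'   datasets, matrices as 2-D
    #' @param max_request_cells optional 413 threshold
    initialize = function(domains, max_request_cells = NULL) {
      self$domains <- domains
      self$max_request_cells <- max_request_cells
    },

    #' @description Handle one request against the dialect.
    #' @param method HTTP method
    #' @param path URL path (no query string)
    #' @param query named list of decoded query parameters
    #' @return `list(status =, body =)`; the body is an R object that the
    #'   transport serializes to JSON
    handle = function(method, path, query = list()) {
      res <- private$route(method, path, query)
      qstr <- paste(sprintf("%s=%s", names(query), unlist(query)),
                    collapse = "&")
      private$log_records[[length(private$log_records) + 1L]] <-
        list(method = method, path = path, query = qstr,
             status = res$status)
      res
    },

    #' @description Return and clear the request log.
    drain_log = function() {
      log <- self$request_log
      private$log_records <- list()
      log
    },

    #' @description Served value-request log entries.
    #' @param dataset optional dataset name filter; laziness audits of the
    #'   numerical payload pass `"assay"` (identifier and metadata vectors
    #'   are 1-D datasets read once at construction)
    value_requests = function(dataset = NULL) {
      sel <- grepl("/value$", self$request_log$path)
      if (!is.null(dataset))
        sel <- sel & self$request_log$path ==
          sprintf("/datasets/%s/value", dataset)
      self$request_log[sel, , drop = FALSE]
    }
  ),

  active = list(
    #' @field request_log data.frame of served requests (append-only;
    #'   cleared by `drain_log()`)
    request_log = function(value) {
      if (!missing(value)) stop_usage("request_log is read-only")
      if (length(private$log_records) == 0L)
        return(data.frame(method = character(), path = character(),
                          query = character(), status = integer()))
      data.frame(
        method = vapply(private$log_records, `[[`, character(1), "method"),
        path = vapply(private$log_records, `[[`, character(1), "path"),
        query = vapply(private$log_records, `[[`, character(1), "query"),
        status = vapply(private$log_records, `[[`, integer(1), "status"))
    }
  ),

  private = list(
    log_records = list(),

    route = function(method, path, query) {
      if (!identical(method, "GET"))
        return(list(status = 405L, body = list(error = "GET only")))
      if (path == "/about")
        return(list(status = 200L, body = list(api_version = "minimal-1")))
      dom <- query$domain
      if (path == "/datasets") {
        if (is.null(dom) || is.null(self$domains[[dom]]))
          return(list(status = 404L, body = list(error = "unknown domain")))
        return(list(status = 200L,
                    body = list(datasets = as.list(names(self$domains[[dom]])))))
      }
      if (!startsWith(path, "/datasets/"))
        return(list(status = 404L, body = list(error = "no such endpoint")))
      rest <- substring(path, 11L)
      want_value <- endsWith(rest, "/value")
      name <- if (want_value) substring(rest, 1L, nchar(rest) - 6L) else rest
      if (!nzchar(name) || grepl("/", name, fixed = TRUE))
        return(list(status = 404L, body = list(error = "no such endpoint")))
      if (is.null(dom) || is.null(self$domains[[dom]]))
        return(list(status = 404L, body = list(error = "unknown domain")))
      ds <- self$domains[[dom]][[name]]
      if (is.null(ds))
        return(list(status = 404L, body = list(error = "unknown dataset")))
      if (!want_value) private$metadata(ds) else private$value(ds, query)
    },

    metadata = function(ds) {
      x <- ds$data
      dims <- if (is.matrix(x)) dim(x) else length(x)
      cls <- if (is.character(if (is.matrix(x)) x[1] else x))
        "H5T_STRING" else "H5T_FLOAT"
      body <- list(shape = list(dims = as.list(as.integer(dims))),
                   type = list(class = cls))
      if (!is.null(ds$chunk))
        body$layout <- list(dims = as.list(as.integer(ds$chunk)))
      list(status = 200L, body = body)
    },

    value = function(ds, query) {
      sel <- query$select
      x <- ds$data
      nd <- if (is.matrix(x)) 2L else 1L
      if (is.null(sel))
        return(list(status = 400L, body = list(error = "select required")))
      pat <- if (nd == 2L) "^\\[([0-9]+):([0-9]+),([0-9]+):([0-9]+)\\]$"
             else "^\\[([0-9]+):([0-9]+)\\]$"
      m <- regmatches(sel, regexec(pat, sel))[[1]]
      if (length(m) == 0L)
        return(list(status = 400L, body = list(error = "malformed select")))
      b <- as.integer(m[-1L])
      if (nd == 2L) {
        if (b[1L] >= b[2L] || b[3L] >= b[4L] ||
            b[2L] > nrow(x) || b[4L] > ncol(x))
          return(list(status = 400L, body = list(error = "select out of bounds")))
        ncells <- as.double(b[2L] - b[1L]) * (b[4L] - b[3L])
        if (!is.null(self$max_request_cells) &&
            ncells > self$max_request_cells)
          return(list(status = 413L, body = list(error = "selection too large")))
        blk <- x[(b[1L] + 1L):b[2L], (b[3L] + 1L):b[4L], drop = FALSE]
        list(status = 200L, body = list(value = blk))
      } else {
        if (b[1L] >= b[2L] || b[2L] > length(x))
          return(list(status = 400L, body = list(error = "select out of bounds")))
        if (!is.null(self$max_request_cells) &&
            (b[2L] - b[1L]) > self$max_request_cells)
          return(list(status = 413L, body = list(error = "selection too large")))
        list(status = 200L, body = list(value = x[(b[1L] + 1L):b[2L]]))
      }
    }
  )
)

#' Build a mock service around one fixture
#'
#' Serves `sim` (a [simulate_counts()] result, or a bare matrix) under a
#' single domain using the layout `assay`, `features`, `samples`,
#' `row_data.<col>`, `col_data.<col>`.
#'
#' @param sim a fixture from [simulate_counts()] or a numeric matrix
#' @param domain domain path string the datasets live under
#' @param chunk `(rows, cols)` declared chunk geometry for `/assay`
#' @param max_request_cells optional enforced request limit (413 beyond)
#' @return a [MockHsds]
#' @export
mock_hsds <- function(sim, domain = "/shared/fixture", chunk = c(50L, 80L),
                      max_request_cells = NULL) {
  if (is.matrix(sim)) sim <- list(counts = sim)
  ds <- list(assay = list(data = sim$counts, chunk = as.integer(chunk)))
  if (!is.null(rownames(sim$counts)))
    ds$features <- list(data = rownames(sim$counts))
  if (!is.null(sim$row_data)) {
    ds$features <- list(data = rownames(sim$row_data))
    rd <- sim$row_data
    if (!is.null(sim$row_ranges)) rd <- cbind(rd, ranges_columns(sim))
    for (cn in names(rd))
      ds[[paste0("row_data.", cn)]] <- list(data = rd[[cn]])
  }
  if (!is.null(sim$col_data)) {
    ds$samples <- list(data = rownames(sim$col_data))
    for (cn in names(sim$col_data))
      ds[[paste0("col_data.", cn)]] <- list(data = sim$col_data[[cn]])
  }
  domains <- list()
  domains[[domain]] <- ds
  MockHsds$new(domains, max_request_cells = max_request_cells)
}

#' Mock service from an HDF5 fixture file
#'
#' Loads the fixture layout written by [write_h5_fixture()] ("/assay",
#' "/features", "/samples", "/row_data/*", "/col_data/*") into memory and
#' serves it; nested HDF5 paths become dotted dataset names. The declared
#' chunk geometry is read from the file.
#'
#' @param path HDF5 fixture path
#' @param domain domain to serve under
#' @param max_request_cells optional enforced request limit
#' @return a [MockHsds]
#' @export
mock_hsds_from_h5 <- function(path, domain = "/shared/fixture",
                              max_request_cells = NULL) {
  seed <- h5_seed(path, "/assay")
  counts <- rhdf5::h5read(path, "assay")
  storage.mode(counts) <- "double"
  ls <- rhdf5::h5ls(path)
  ds <- list(assay = list(data = counts, chunk = seed_chunkdim(seed)))
  for (k in seq_len(nrow(ls))) {
    if (ls$otype[k] != "H5I_DATASET") next
    full <- file.path(ls$group[k], ls$name[k])
    full <- sub("^/+", "", full)
    if (full == "assay") next
    name <- gsub("/", ".", full)
    v <- as.vector(rhdf5::h5read(path, full))
    ds[[name]] <- list(data = v)
  }
  domains <- list()
  domains[[domain]] <- ds
  MockHsds$new(domains, max_request_cells = max_request_cells)
}

encode_body <- function(body) {
  jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA, null = "null")
}

parse_url_parts <- function(url) {
  rest <- sub("^[a-z]+://[^/]*", "", url)
  qpos <- regexpr("?", rest, fixed = TRUE)
  if (qpos == -1L) return(list(path = rest, query = list()))
  path <- substr(rest, 1L, qpos - 1L)
  qstr <- substr(rest, qpos + 1L, nchar(rest))
  kv <- strsplit(strsplit(qstr, "&", fixed = TRUE)[[1]], "=", fixed = TRUE)
  query <- lapply(kv, function(p) {
    v <- paste(p[-1L], collapse = "=")
    if (grepl("%", v, fixed = TRUE)) utils::URLdecode(v) else v
  })
  names(query) <- vapply(kv, `[[`, character(1), 1L)
  list(path = path, query = query)
}

#' Transports: how the client reaches a service
#'
#' A transport is a function `f(url)` returning
#' `list(status = <int>, text = <JSON string>)`, or signalling a
#' `lazyse_transport_error` when the service cannot be reached at all.
#' `mock_transport()` routes requests to an in-process [MockHsds] —
#' including full JSON serialization, so byte-level fidelity is exercised —
#' and `curl_transport()` performs real HTTP.
#'
#' @param service a [MockHsds]
#' @return a transport function
#' @export
mock_transport <- function(service) {
  force(service)
  function(url) {
    parts <- parse_url_parts(url)
    res <- service$handle("GET", parts$path, parts$query)
    list(status = res$status, text = as.character(encode_body(res$body)))
  }
}

#' @rdname mock_transport
#' @param timeout_s per-request timeout, seconds
#' @export
curl_transport <- function(timeout_s = 10) {
  function(url) {
    h <- curl::new_handle(timeout = timeout_s)
    res <- tryCatch(curl::curl_fetch_memory(url, handle = h),
                    error = function(e)
                      stop_transport("request failed for %s: %s", url,
                                     conditionMessage(e)))
    list(status = res$status_code, text = rawToChar(res$content))
  }
}

#' Serve a mock service over real HTTP
#'
#' Wraps a [MockHsds] as an httpuv application and blocks serving it on
#' `127.0.0.1`. Two admin endpoints sit outside the dialect so an
#' out-of-process client can audit laziness: `GET /__admin__/log` returns
#' the request log as JSON and `GET /__admin__/drain` returns it and
#' clears it.
#'
#' @param service a [MockHsds]
#' @param port TCP port
#' @param host interface to bind, default loopback
#' @return does not return; interrupt to stop
#' @export
serve_hsds <- function(service, port, host = "127.0.0.1") {
  httpuv::runServer(host, port, hsds_app(service))
}

#' @rdname serve_hsds
#' @export
hsds_app <- function(service) {
  list(call = function(req) {
    path <- req$PATH_INFO
    qstr <- req$QUERY_STRING
    if (startsWith(path, "/__admin__")) {
      log <- if (path == "/__admin__/drain") service$drain_log()
             else service$request_log
      return(list(status = 200L,
                  headers = list("Content-Type" = "application/json"),
                  body = as.character(encode_body(list(log = log)))))
    }
    query <- list()
    if (nzchar(qstr)) {
      q <- sub("^\\?", "", qstr)
      kv <- strsplit(strsplit(q, "&", fixed = TRUE)[[1]], "=", fixed = TRUE)
      query <- lapply(kv, function(p)
        utils::URLdecode(paste(p[-1L], collapse = "=")))
      names(query) <- vapply(kv, `[[`, character(1), 1L)
    }
    res <- service$handle("GET", path, query)
    list(status = res$status,
         headers = list("Content-Type" = "application/json"),
         body = as.character(encode_body(res$body)))
  })
}

#' Serve an HDF5 fixture file over the dialect (blocking)
#'
#' Convenience entry point for [serve_hsds()] used by the CLI `serve`
#' command and by out-of-process tests.
#'
#' @inheritParams mock_hsds_from_h5
#' @inheritParams serve_hsds
#' @export
serve_h5_fixture <- function(path, port, domain = "/shared/fixture",
                             max_request_cells = NULL, host = "127.0.0.1") {
  serve_hsds(mock_hsds_from_h5(path, domain, max_request_cells), port, host)
}
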