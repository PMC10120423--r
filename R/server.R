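# Stateless JSON facade. The heart is vm_handle(): a pure function of
# (application state loaded from disk, request) -> response, so identical
# requests always produce byte-identical bodies. vm_serve() is a thin
# optional HTTP binding over httpuv; it adds nothing beyond transport.

#' Build a server application object
#'
#' @param ds a `vm_dataset`.
#' @param ann optional `vm_annotation` (with label map); gene search and
#'   GFF3 export are flagged disabled without it.
#' @param config configuration list (see [infer_config()]); recognized keys:
#'   `pca_max_variants`, `count_exon_variants`, `gene_links`,
#'   `ontology_link`, `chromosomes` (labels with optional lengths),
#'   `features`.
#' @return a `vm_app` object for [vm_handle()] / [vm_serve()].
#' @export
vm_app <- function(ds, ann = NULL, config = list()) {
  structure(list(ds = ds, ann = ann, config = config), class = "vm_app")
}

vm_http_status <- function(code) {
  switch(code,
         lookup = 404L,
         analysis = 422L,
         internal = 500L,
         400L)
}

vm_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null",
                   null = "null")
}

vm_response <- function(status, body, content_type = "application/json") {
  list(status = status, content_type = content_type, body = body)
}

#' Handle one request against the application
#'
#' Every endpoint is a pure function of the dataset on disk and the request
#' body; errors surface as JSON bodies carrying the engine's
#' machine-readable error codes.
#'
#' Routes (all under `/v1`): `GET /v1/configuration`, `POST /v1/slice`,
#' `POST /v1/pca`, `POST /v1/sort`, `POST /v1/gene-search`,
#' `POST /v1/export-vcf`, `POST /v1/export-gff3`, `POST /v1/blast`
#' (stub, always "feature disabled").
#'
#' @param app a [vm_app()].
#' @param method HTTP method string.
#' @param path request path.
#' @param body request body: an R list or a JSON string.
#' @return a list with `status`, `content_type` and `body` (a JSON string,
#'   or plain document text for the export endpoints).
#' @export
vm_handle <- function(app, method, path, body = NULL) {
  stopifnot(inherits(app, "vm_app"))
  if (is.character(body) && length(body) == 1L)
    body <- jsonlite::fromJSON(body, simplifyVector = TRUE)
  if (is.null(body)) body <- list()
  route <- paste(toupper(method), path)
  handler <- switch(route,
    "GET /v1/configuration" = vm_ep_configuration,
    "POST /v1/slice" = vm_ep_slice,
    "POST /v1/pca" = vm_ep_pca,
    "POST /v1/sort" = vm_ep_sort,
    "POST /v1/gene-search" = vm_ep_gene_search,
    "POST /v1/export-vcf" = vm_ep_export_vcf,
    "POST /v1/export-gff3" = vm_ep_export_gff3,
    "POST /v1/blast" = vm_ep_blast,
    NULL)
  if (is.null(handler))
    return(vm_response(404L, as.character(vm_json(list(error = list(
      code = "lookup", message = paste("no such endpoint:", route)))))))
  tryCatch(handler(app, body), vm_error = function(e) {
    vm_response(vm_http_status(vm_error_code(e)),
                as.character(vm_json(list(error = list(
                  code = vm_error_code(e),
                  message = conditionMessage(e))))))
  })
}

vm_config_get <- function(app, key, default) {
  v <- app$config[[key]]
  if (is.null(v)) default else v
}

vm_ep_configuration <- function(app, body) {
  ds <- app$ds
  conf_chroms <- vm_config_get(app, "chromosomes", NULL)
  chroms <- lapply(ds$chromosomes, function(c) {
    len <- NULL
    if (!is.null(conf_chroms)) {
      for (cc in conf_chroms)
        if (identical(cc$label, c) && !is.null(cc$length)) len <- cc$length
    }
    if (is.null(len))
      len <- if (ds$n_variants[[c]] > 0L) max(ds$index[[c]]$positions) else 0L
    list(label = c, length = len,
         n_variants = unname(ds$n_variants[[c]]))
  })
  out <- list(
    chromosomes = chroms,
    samples = I(ds$samples),
    sample_count = length(ds$samples),
    ploidy = ds$ploidy,
    features = list(
      gene_search = !is.null(app$ann),
      gff3_export = !is.null(app$ann),
      pca = TRUE,
      blast = FALSE))
  vm_response(200L, as.character(vm_json(out)))
}

# Slice endpoint. With criteria set, excluded variants are dropped and the
# engine keeps reading forward so the response still carries `count`
# passing variants when the chromosome has them; the cursor
# (next_start_position) then points past the last variant examined.
vm_ep_slice <- function(app, body) {
  ds <- app$ds
  if (is.null(body$chromosome) || is.null(body$start_position) ||
      is.null(body$count))
    vm_abort("argument", "slice needs chromosome, start_position, count")
  count <- as.integer(body$count)
  panel <- if (is.null(body$panel)) ds$samples else as.character(body$panel)
  criteria <- if (is.null(body$criteria)) NULL else as_vm_criteria(body$criteria)
  vm_check_chrom(ds, body$chromosome)
  chrom_n <- ds$n_variants[[body$chromosome]]
  start <- as.numeric(body$start_position)

  pieces <- list(); got <- 0L; scanned_to <- NULL; exhausted <- FALSE
  repeat {
    sl <- slice_by_count(ds, body$chromosome, start, count, panel)
    if (sl$width == 0L) { exhausted <- TRUE; break }
    st <- compute_stats(sl)
    keep <- if (is.null(criteria)) rep(TRUE, sl$width)
            else apply_filter(st, sl, criteria)
    pieces[[length(pieces) + 1L]] <- list(slice = sl, stats = st, keep = keep)
    got <- got + sum(keep)
    last_index <- sl$first_index + sl$width - 1L
    exhausted <- last_index >= chrom_n
    scanned_to <- sl$positions[sl$width]
    if (got >= count || exhausted) break
    start <- scanned_to + 1L
  }
  take <- function(field) {
    if (!length(pieces)) return(NULL)
    do.call(c, lapply(pieces, function(p) p$slice[[field]][p$keep]))
  }
  take_stat <- function(field) {
    if (!length(pieces)) return(NULL)
    do.call(c, lapply(pieces, function(p) p$stats[[field]][p$keep]))
  }
  positions <- as.integer(take("positions")); n_all <- length(positions)
  n_use <- min(n_all, count)
  idx <- seq_len(n_use)
  positions <- positions[idx]
  dos <- if (length(pieces))
    do.call(cbind, lapply(pieces, function(p)
      p$slice$dosages[, p$keep, drop = FALSE]))[, idx, drop = FALSE]
  else matrix(VM_MISSING, nrow = length(panel), ncol = 0L,
              dimnames = list(panel, NULL))
  ann_raw <- as.character(take("ann"))[idx]
  effects <- lapply(ann_raw, function(a) parse_ann(a))
  next_start <- if (exhausted && n_all <= count) NULL
                else positions[n_use] + 1L
  first_index <- if (length(pieces)) pieces[[1]]$slice$first_index else
    chrom_n + 1L
  calls <- stats::setNames(lapply(panel, function(s) I(unname(dos[s, ]))),
                           panel)
  out <- list(
    chromosome = body$chromosome,
    first_index = first_index,
    width = n_use,
    next_start_position = next_start,
    positions = I(positions),
    ref = I(as.character(take("ref"))[idx]),
    alt = I(as.character(take("alt"))[idx]),
    qual = I(as.numeric(take("qual"))[idx]),
    mq = I(as.numeric(take("mq"))[idx]),
    maf = I(as.numeric(take_stat("maf"))[idx]),
    het_fraction = I(as.numeric(take_stat("het_fraction"))[idx]),
    missing_fraction = I(as.numeric(take_stat("missing_fraction"))[idx]),
    n_called = I(as.integer(take_stat("n_called"))[idx]),
    ann = I(ann_raw),
    effects = effects,
    calls = calls)
  vm_response(200L, as.character(vm_json(out)))
}

vm_parse_region <- function(body) {
  r <- body$region
  if (is.null(r)) vm_abort("argument", "request needs a region")
  do.call(vm_region, r)
}

vm_ep_pca <- function(app, body) {
  region <- vm_parse_region(body)
  panel <- if (is.null(body$panel)) NULL else as.character(body$panel)
  criteria <- if (is.null(body$criteria)) NULL else as_vm_criteria(body$criteria)
  k <- if (is.null(body$k)) 2L else as.integer(body$k)
  res <- run_pca(app$ds, region, panel = panel, criteria = criteria, k = k,
                 max_variants = vm_config_get(app, "pca_max_variants", 10000L),
                 ann = app$ann)
  out <- list(
    samples = I(rownames(res$coordinates)),
    coordinates = lapply(seq_len(nrow(res$coordinates)), function(i)
      I(unname(res$coordinates[i, ]))),
    explained_variance_ratio = I(res$explained_variance_ratio),
    n_variants_used = res$n_variants_used,
    variants_excluded_by_filter = res$variants_excluded_by_filter)
  vm_response(200L, as.character(vm_json(out)))
}

vm_ep_sort <- function(app, body) {
  mode <- if (is.null(body$mode)) "alpha_asc" else body$mode
  panel <- if (is.null(body$panel)) NULL else as.character(body$panel)
  region <- if (is.null(body$region)) NULL else do.call(vm_region, body$region)
  res <- sort_samples(app$ds, panel = panel, mode = mode, region = region,
                      ann = app$ann)
  out <- list(order = I(res$order), key = I(res$key), mode = res$mode)
  vm_response(200L, as.character(vm_json(out)))
}

vm_ep_gene_search <- function(app, body) {
  if (is.null(app$ann))
    vm_abort("config", "gene search is disabled: no annotation loaded")
  hits <- search_genes(
    app$ann, app$ds,
    query = body$query,
    chromosome = body$chromosome,
    range = if (is.null(body$range)) NULL else as.numeric(body$range),
    count_exon_variants = isTRUE(vm_config_get(app, "count_exon_variants",
                                               FALSE)),
    config = app$config)
  rows <- lapply(seq_len(nrow(hits)), function(i) list(
    gene_id = hits$gene_id[i],
    description = hits$description[i],
    chromosome = hits$chromosome[i],
    start = hits$start[i],
    end = hits$end[i],
    strand = hits$strand[i],
    n_variants_gene = hits$n_variants_gene[i],
    n_variants_exons = if (is.na(hits$n_variants_exons[i])) NULL
                       else hits$n_variants_exons[i],
    links = I(hits$links[[i]])))
  vm_response(200L, as.character(vm_json(list(genes = rows))))
}

vm_ep_export_vcf <- function(app, body) {
  region <- vm_parse_region(body)
  panel <- if (is.null(body$panel)) NULL else as.character(body$panel)
  criteria <- if (is.null(body$criteria)) NULL else as_vm_criteria(body$criteria)
  tmp <- tempfile(fileext = ".vcf")
  on.exit(unlink(tmp))
  export_vcf(app$ds, tmp, region, panel = panel, criteria = criteria,
             ann = app$ann)
  vm_response(200L, paste0(paste(readLines(tmp), collapse = "\n"), "\n"),
              content_type = "text/vcf")
}

vm_ep_export_gff3 <- function(app, body) {
  if (is.null(app$ann))
    vm_abort("config", "GFF3 export is disabled: no annotation loaded")
  if (is.null(body$chromosome) || is.null(body$start) || is.null(body$end))
    vm_abort("argument", "GFF3 export needs chromosome, start, end")
  tmp <- tempfile(fileext = ".gff3")
  on.exit(unlink(tmp))
  export_gff3(app$ann, tmp, body$chromosome, as.numeric(body$start),
              as.numeric(body$end))
  vm_response(200L, paste0(paste(readLines(tmp), collapse = "\n"), "\n"),
              content_type = "text/gff3")
}

# BLAST entry point requires an external alignment service; this engine
# ships only the interface stub.
vm_ep_blast <- function(app, body) {
  vm_response(501L, as.character(vm_json(list(error = list(
    code = "config",
    message = "BLAST entry point is not configured in this instance")))))
}

#' Serve the application over HTTP
#'
#' Thin binding of [vm_handle()] onto httpuv. Requires the `httpuv` package.
#'
#' @param app a [vm_app()].
#' @param host interface to bind.
#' @param port TCP port; 0 picks a random free port.
#' @return the httpuv server handle; stop it with `httpuv::stopServer()`.
#' @export
vm_serve <- function(app, host = "127.0.0.1", port = 8090L) {
  if (!requireNamespace("httpuv", quietly = TRUE))
    vm_abort("config", "vm_serve requires the httpuv package")
  if (port == 0L) port <- httpuv::randomPort()
  srv <- httpuv::startServer(host, port, list(
    call = function(req) {
      body <- NULL
      if (!is.null(req$rook.input)) {
        raw <- req$rook.input$read()
        if (length(raw)) body <- rawToChar(raw)
      }
      res <- vm_handle(app, req$REQUEST_METHOD, req$PATH_INFO, body)
      list(status = res$status,
           headers = list("Content-Type" = res$content_type,
                          "Access-Control-Allow-Origin" = "*"),
           body = res$body)
    }))
  message(sprintf("varmat server listening on http://%s:%d", host, port))
  srv
}
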