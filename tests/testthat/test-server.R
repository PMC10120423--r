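server_app <- function(config = list()) {
  fix <- the_fixture()
  vm_app(fix$ds, fix$ann, config)
}

test_that("the configuration descriptor reflects the dataset and is stable", {
  app <- server_app()
  r1 <- vm_handle(app, "GET", "/v1/configuration")
  r2 <- vm_handle(app, "GET", "/v1/configuration")
  expect_equal(r1$status, 200L)
  expect_identical(r1$body, r2$body)      # byte-identical repeats
  cfg <- jsonlite::fromJSON(r1$body, simplifyVector = FALSE)
  expect_equal(length(cfg$chromosomes), 2)
  expect_equal(cfg$chromosomes[[1]]$label, "chr1")
  expect_equal(cfg$chromosomes[[1]]$n_variants, 120)
  expect_equal(cfg$sample_count, 30)
  expect_true(cfg$features$gene_search)
  expect_false(cfg$features$blast)
  # without annotation, gene search is flagged off
  fix <- the_fixture()
  bare <- vm_app(fix$ds, NULL, list())
  cfg2 <- jsonlite::fromJSON(vm_handle(bare, "GET", "/v1/configuration")$body,
                             simplifyVector = FALSE)
  expect_false(cfg2$features$gene_search)
})

test_that("the slice endpoint equals the library-level composition", {
  app <- server_app()
  fix <- the_fixture()
  req <- list(chromosome = "chr1", start_position = 1, count = 25)
  res <- jsonlite::fromJSON(vm_handle(app, "POST", "/v1/slice", req)$body,
                            simplifyVector = TRUE)
  sl <- slice_by_count(fix$ds, "chr1", 1, 25)
  st <- compute_stats(sl)
  expect_equal(res$positions, sl$positions)
  expect_equal(res$ref, sl$ref)
  expect_equal(res$maf, st$maf)
  expect_equal(res$het_fraction, st$het_fraction)
  expect_equal(res$missing_fraction, st$missing_fraction)
  expect_equal(res$next_start_position, sl$positions[25] + 1L)
  expect_equal(res$calls[["S001"]], unname(sl$dosages["S001", ]))
  # dosage rows follow the requested panel order
  req2 <- list(chromosome = "chr1", start_position = 1, count = 5,
               panel = c("S010", "S002"))
  res2 <- jsonlite::fromJSON(vm_handle(app, "POST", "/v1/slice", req2)$body,
                             simplifyVector = TRUE)
  expect_equal(names(res2$calls), c("S010", "S002"))
})

test_that("undefined statistics serialize as JSON null, not 0", {
  rows <- c(vcf_row("1", 10, c("./.", "./.")),
            vcf_row("1", 20, c("0/1", "0/0")))
  ds <- convert_vcf(write_test_vcf(rows, c("a", "b")), tempfile())
  app <- vm_app(ds)
  body <- vm_handle(app, "POST", "/v1/slice",
                    list(chromosome = "1", start_position = 1,
                         count = 2))$body
  parsed <- jsonlite::fromJSON(body, simplifyVector = FALSE)
  expect_null(parsed$maf[[1]])
  expect_equal(parsed$maf[[2]], 0.25)
  expect_true(grepl("\"maf\":[null,0.25]", body, fixed = TRUE))
})

test_that("filtered slices drop excluded variants and advance the cursor", {
  app <- server_app()
  fix <- the_fixture()
  crit <- list(maf_range = c(0.15, 0.5))
  res <- jsonlite::fromJSON(
    vm_handle(app, "POST", "/v1/slice",
              list(chromosome = "chr1", start_position = 1, count = 10,
                   criteria = crit))$body, simplifyVector = TRUE)
  sl <- slice_by_range(fix$ds, "chr1", 1, 1e9)
  mask <- apply_filter(compute_stats(sl), sl, filter_criteria(maf_range = c(0.15, 0.5)))
  want <- sl$positions[mask][1:10]
  expect_equal(res$positions, want)     # 10 passing variants, gaps skipped
  expect_equal(res$width, 10)
  # criteria excluding everything -> well-formed empty body
  res2 <- jsonlite::fromJSON(
    vm_handle(app, "POST", "/v1/slice",
              list(chromosome = "chr1", start_position = 1, count = 10,
                   criteria = list(qual_min = 1e9)))$body,
    simplifyVector = TRUE)
  expect_equal(res2$width, 0)
  expect_equal(length(res2$positions), 0)
  expect_null(res2$next_start_position)
})

test_that("pca/sort/gene-search endpoints delegate to the library", {
  app <- server_app(list(pca_max_variants = 40, count_exon_variants = TRUE))
  fix <- the_fixture()
  reg <- list(chromosome = "chr1", start = 1, end = 1e9)
  pr <- jsonlite::fromJSON(
    vm_handle(app, "POST", "/v1/pca", list(region = reg, k = 3))$body,
    simplifyVector = TRUE)
  lib <- run_pca(fix$ds, reg, k = 3, max_variants = 40)
  expect_equal(pr$n_variants_used, 40)
  expect_equal(pr$samples, rownames(lib$coordinates))
  expect_equal(pr$coordinates, unname(lib$coordinates), tolerance = 1e-12)
  expect_equal(pr$explained_variance_ratio, lib$explained_variance_ratio)

  sr <- jsonlite::fromJSON(
    vm_handle(app, "POST", "/v1/sort",
              list(mode = "distance", region = reg))$body,
    simplifyVector = TRUE)
  libs <- sort_samples(fix$ds, mode = "distance", region = reg)
  expect_equal(sr$order, libs$order)

  gr <- jsonlite::fromJSON(
    vm_handle(app, "POST", "/v1/gene-search",
              list(query = fix$gf$truth$gene_id[1]))$body,
    simplifyVector = FALSE)
  expect_equal(gr$genes[[1]]$n_variants_gene,
               fix$gf$truth$n_variants_gene[1])
  expect_equal(gr$genes[[1]]$n_variants_exons,
               fix$gf$truth$n_variants_exons[1])
})

test_that("export endpoints stream parseable documents", {
  app <- server_app()
  r <- vm_handle(app, "POST", "/v1/export-vcf",
                 list(region = list(chromosome = "chr2", start = 1,
                                    end = 1e9)))
  expect_equal(r$status, 200L)
  expect_equal(r$content_type, "text/vcf")
  tmp <- tempfile(fileext = ".vcf")
  writeLines(sub("\n$", "", r$body), tmp)
  ds2 <- convert_vcf(tmp, tempfile())
  expect_equal(unname(ds2$n_variants[["chr2"]]), 60L)

  g <- vm_handle(app, "POST", "/v1/export-gff3",
                 list(chromosome = "chr1", start = 1, end = 1e9))
  expect_equal(g$status, 200L)
  expect_match(g$body, "^##gff-version 3")
})

test_that("errors map to the library's machine-readable codes", {
  app <- server_app()
  unknown <- vm_handle(app, "POST", "/v1/slice",
                       list(chromosome = "chrZ", start_position = 1,
                            count = 5))
  expect_equal(unknown$status, 404L)
  expect_equal(jsonlite::fromJSON(unknown$body)$error$code, "lookup")

  badpanel <- vm_handle(app, "POST", "/v1/slice",
                        list(chromosome = "chr1", start_position = 1,
                             count = 5, panel = "ghost"))
  expect_equal(badpanel$status, 400L)
  expect_equal(jsonlite::fromJSON(badpanel$body)$error$code, "panel")

  toofew <- vm_handle(app, "POST", "/v1/pca",
                      list(region = list(chromosome = "chr1", start = 2,
                                         end = 3)))
  expect_equal(toofew$status, 422L)
  expect_equal(jsonlite::fromJSON(toofew$body)$error$code, "analysis")

  nowhere <- vm_handle(app, "GET", "/v1/nope")
  expect_equal(nowhere$status, 404L)

  blast <- vm_handle(app, "POST", "/v1/blast", list(sequence = "ACGT"))
  expect_equal(blast$status, 501L)
  expect_equal(jsonlite::fromJSON(blast$body)$error$code, "config")
})

test_that("identical requests give byte-identical bodies across endpoints", {
  app <- server_app(list(count_exon_variants = TRUE))
  reqs <- list(
    list("POST", "/v1/slice", list(chromosome = "chr1", start_position = 1,
                                   count = 30)),
    list("POST", "/v1/pca", list(region = list(chromosome = "chr1",
                                               start = 1, end = 1e9))),
    list("POST", "/v1/sort", list(mode = "alpha_desc")),
    list("POST", "/v1/gene-search", list(chromosome = "chr1",
                                         range = c(1, 1e9))))
  for (rq in reqs) {
    b1 <- do.call(vm_handle, c(list(app), rq))$body
    b2 <- do.call(vm_handle, c(list(app), rq))$body
    expect_identical(b1, b2)
  }
})

test_that("JSON string bodies are accepted as-is", {
  app <- server_app()
  raw <- '{"chromosome":"chr1","start_position":1,"count":3}'
  a <- vm_handle(app, "POST", "/v1/slice", raw)
  b <- vm_handle(app, "POST", "/v1/slice",
                 list(chromosome = "chr1", start_position = 1, count = 3))
  expect_identical(a$body, b$body)
})
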