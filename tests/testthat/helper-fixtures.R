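# Shared helpers: tiny hand-written VCF/GFF3 builders and a cached medium
# fixture dataset reused across test files.

vm_test_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"mq\">",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"ann\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

# rows: character vector of body lines (tab-separated already)
write_test_vcf <- function(rows, samples, path = tempfile(fileext = ".vcf")) {
  writeLines(c(vm_test_header(samples), rows), path)
  path
}

vcf_row <- function(chrom, pos, gts, ref = "A", alt = "T", qual = ".",
                    info = ".", format = "GT") {
  paste(c(chrom, pos, ".", ref, alt, qual, ".", info, format, gts),
        collapse = "\t")
}

# dataset used by many tests: 2 chromosomes, diploid, converted once
the_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      td <- file.path(tempdir(), "varmat-shared-fixture")
      dir.create(td, showWarnings = FALSE)
      spec <- fixture_spec(n_samples = 30L,
                          n_variants = c(chr1 = 120L, chr2 = 60L),
                          seed = 101L, missing_rate = 0.08)
      fx <- generate_vcf(spec, file.path(td, "fixture.vcf"))
      ds <- convert_vcf(fx$path, file.path(td, "store"),
                        chunk_variants = 37L)
      gf <- generate_gff3(fx, file.path(td, "fixture.gff3"))
      ann <- load_gff3(gf$path)
      ann <- set_label_map(ann, infer_label_map(
        ds$chromosomes, unique(ann$features$chromosome)))
      cache <<- list(spec = spec, fx = fx, ds = ds, gf = gf, ann = ann)
    }
    cache
  }
})
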