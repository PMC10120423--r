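# Deterministic synthetic VCF / GFF3 generator.
#
# The generator stands in for real resequencing panels: per-variant allele
# frequencies are drawn once, genotypes are drawn per sample under
# Hardy-Weinberg equilibrium at that frequency, and missing calls are
# injected independently at a fixed rate. Alongside each file it returns
# ground-truth tables (dosages, frequencies, per-gene variant counts) so
# every downstream module can be tested against an oracle without any
# external download.

#' Describe a synthetic variant-panel fixture
#'
#' A fixture specification captures the "world" a synthetic dataset is drawn
#' from: panel size, variants per chromosome, ploidy, the allele-frequency
#' distribution, and the rates of missingness and annotation.
#'
#' @param n_samples number of genotype samples (rows of the call matrix).
#' @param n_variants named integer vector: variants per chromosome; the names
#'   are the VCF chromosome labels.
#' @param ploidy 1 or 2.
#' @param seed integer seed; a fixed seed yields byte-identical files.
#' @param freq_range range of the uniform distribution the per-variant
#'   alternate-allele frequency is drawn from.
#' @param missing_rate probability that any single genotype call is missing.
#' @param multiallelic_fraction fraction of sites with two alternate alleles.
#' @param phased_fraction fraction of diploid genotypes written with the
#'   phased separator `|` (dosage is phase-invariant; this exercises that).
#' @param half_call_fraction fraction of injected missing diploid genotypes
#'   written as half-calls such as `./1` instead of `./.`.
#' @param ann_fraction fraction of variants carrying a SnpEff-style INFO/ANN
#'   string.
#' @param qual_range,mq_range ranges for per-variant QUAL and INFO/MQ.
#' @param qual_missing_rate fraction of variants with QUAL (and MQ) absent.
#' @param gff_labels chromosome labels used in the GFF3 file; defaults to the
#'   VCF labels with a leading "chr" stripped, so the label-mapping heuristic
#'   has something to infer.
#' @param genes_per_chromosome number of non-overlapping genes to annotate.
#' @return an object of class `vm_fixture_spec`.
#' @export
fixture_spec <- function(n_samples = 50L,
                         n_variants = c(chr1 = 200L),
                         ploidy = 2L,
                         seed = 1L,
                         freq_range = c(0.02, 0.5),
                         missing_rate = 0.05,
                         multiallelic_fraction = 0.1,
                         phased_fraction = 0.2,
                         half_call_fraction = 0.2,
                         ann_fraction = 0.2,
                         qual_range = c(20, 60),
                         mq_range = c(20, 60),
                         qual_missing_rate = 0.05,
                         gff_labels = NULL,
                         genes_per_chromosome = 4L) {
  if (is.null(names(n_variants)) || any(!nzchar(names(n_variants))))
    vm_abort("argument", "n_variants must be a named vector (names = chromosome labels)")
  if (!ploidy %in% c(1L, 2L))
    vm_abort("argument", "ploidy must be 1 or 2")
  rates <- c(missing_rate, multiallelic_fraction, phased_fraction,
             half_call_fraction, ann_fraction, qual_missing_rate)
  if (any(rates < 0 | rates > 1))
    vm_abort("argument", "rates and fractions must lie in [0, 1]")
  if (any(n_variants < 0))
    vm_abort("argument", "n_variants must be non-negative")
  if (is.null(gff_labels)) gff_labels <- sub("^[Cc]hr", "", names(n_variants))
  structure(list(
    n_samples = as.integer(n_samples),
    n_variants = stats::setNames(as.integer(n_variants), names(n_variants)),
    ploidy = as.integer(ploidy),
    seed = as.integer(seed),
    freq_range = freq_range,
    missing_rate = missing_rate,
    multiallelic_fraction = multiallelic_fraction,
    phased_fraction = phased_fraction,
    half_call_fraction = half_call_fraction,
    ann_fraction = ann_fraction,
    qual_range = qual_range,
    mq_range = mq_range,
    qual_missing_rate = qual_missing_rate,
    gff_labels = stats::setNames(gff_labels, names(n_variants)),
    genes_per_chromosome = as.integer(genes_per_chromosome)
  ), class = "vm_fixture_spec")
}

# Run code with a locally seeded RNG, restoring global state afterwards.
with_fixture_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

vm_bases <- c("A", "C", "G", "T")

#' Generate a synthetic VCF file with ground truth
#'
#' Writes a VCF 4.2 file drawn from a [fixture_spec()] and returns the file
#' path together with ground-truth tables: per-chromosome dosage matrices
#' (missing = -1), positions, alleles, the true alternate-allele frequency of
#' every variant, and QUAL/MQ/ANN metadata. The ground truth is exactly what
#' the file encodes, so naive re-parsing must reproduce it.
#'
#' @param spec a [fixture_spec()].
#' @param path output path for the VCF; `.gz` suffix triggers gzip
#'   compression.
#' @return invisibly, a list with `path`, `spec` and `truth`; `truth` is a
#'   named list per chromosome with elements `positions`, `ref`, `alt`
#'   (comma-joined), `freq`, `qual`, `mq`, `ann` and `dosage`
#'   (samples x variants, -1 for missing).
#' @export
generate_vcf <- function(spec, path) {
  stopifnot(inherits(spec, "vm_fixture_spec"))
  with_fixture_seed(spec$seed, {
    samples <- sprintf("S%03d", seq_len(spec$n_samples))
    truth <- list()
    body <- character(0)
    for (chrom in names(spec$n_variants)) {
      nv <- spec$n_variants[[chrom]]
      if (nv == 0L) { truth[[chrom]] <- NULL; next }
      pos <- cumsum(sample(1:300, nv, replace = TRUE)) + sample(0:100, 1)
      ref <- sample(vm_bases, nv, replace = TRUE)
      n_alt <- 1L + (stats::runif(nv) < spec$multiallelic_fraction)
      alt <- vapply(seq_len(nv), function(j) {
        paste(sample(setdiff(vm_bases, ref[j]), n_alt[j]), collapse = ",")
      }, character(1))
      p <- stats::runif(nv, spec$freq_range[1], spec$freq_range[2])
      qual <- round(stats::runif(nv, spec$qual_range[1], spec$qual_range[2]), 1)
      mq <- round(stats::runif(nv, spec$mq_range[1], spec$mq_range[2]), 1)
      no_qual <- stats::runif(nv) < spec$qual_missing_rate
      qual[no_qual] <- NA_real_
      mq[no_qual] <- NA_real_
      ann <- rep(NA_character_, nv)
      has_ann <- stats::runif(nv) < spec$ann_fraction
      first_alt <- sub(",.*", "", alt)
      gene_tag <- sprintf("FIXG%04d", seq_len(nv))
      ann[has_ann] <- paste0(
        first_alt[has_ann], "|missense_variant|MODERATE|", gene_tag[has_ann],
        "|", gene_tag[has_ann], "|transcript|", gene_tag[has_ann],
        ".1|protein_coding|1/1|c.1A>G|p.Lys1Glu")

      dosage <- matrix(0L, nrow = spec$n_samples, ncol = nv,
                       dimnames = list(samples, NULL))
      gt <- matrix("", nrow = spec$n_samples, ncol = nv)
      for (j in seq_len(nv)) {
        # Hardy-Weinberg draw: each of `ploidy` alleles is alternate w.p. p_j
        alleles <- matrix(stats::runif(spec$n_samples * spec$ploidy) < p[j],
                          nrow = spec$n_samples)
        # distribute alternate alleles over ALT indices (first alt favoured)
        idx <- matrix(0L, nrow = spec$n_samples, ncol = spec$ploidy)
        n_nonref <- sum(alleles)
        if (n_nonref > 0) {
          choice <- if (n_alt[j] == 1L) rep(1L, n_nonref)
                    else sample(seq_len(n_alt[j]), n_nonref, replace = TRUE,
                                prob = c(0.8, 0.2))
          idx[alleles] <- choice
        }
        dosage[, j] <- as.integer(rowSums(idx != 0L))
        miss <- stats::runif(spec$n_samples) < spec$missing_rate
        if (spec$ploidy == 1L) {
          g <- as.character(idx[, 1])
          g[miss] <- "."
        } else {
          a1 <- as.character(idx[, 1]); a2 <- as.character(idx[, 2])
          half <- miss & (stats::runif(spec$n_samples) < spec$half_call_fraction)
          a1[miss] <- "."
          a2[miss & !half] <- "."
          sep <- ifelse(stats::runif(spec$n_samples) < spec$phased_fraction,
                        "|", "/")
          g <- paste0(a1, sep, a2)
        }
        dosage[miss, j] <- -1L
        gt[, j] <- g
      }
      info <- ifelse(is.na(mq), ".", paste0("MQ=", format(mq, trim = TRUE)))
      info <- ifelse(is.na(ann), info,
                     paste0(ifelse(info == ".", "", paste0(info, ";")),
                            "ANN=", ann))
      qual_s <- ifelse(is.na(qual), ".", format(qual, trim = TRUE))
      rows <- paste(chrom, pos, ".", ref, alt, qual_s, ".", info, "GT",
                    sep = "\t")
      rows <- paste0(rows, "\t", apply(gt, 2, paste, collapse = "\t"))
      body <- c(body, rows)
      truth[[chrom]] <- list(positions = as.integer(pos), ref = ref, alt = alt,
                             freq = p, qual = qual, mq = mq, ann = ann,
                             dosage = dosage)
    }
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=varmat-fixture",
      "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
      "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", samples), collapse = "\t"))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    writeLines(c(header, body), con, sep = "\n")
    close(con)
    invisible(list(path = path, spec = spec, truth = truth))
  })
}

#' Generate a synthetic GFF3 annotation matched to a VCF fixture
#'
#' Lays out non-overlapping genes (each with an mRNA and 1-3 non-overlapping
#' exons) along every chromosome of a VCF fixture, using the fixture's GFF3
#' chromosome labels, and returns ground-truth per-gene variant counts
#' computed from the VCF truth: variants inside the gene body and variants
#' inside the union of the gene's exons.
#'
#' @param fixture the return value of [generate_vcf()].
#' @param path output path for the GFF3 file.
#' @param seed optional seed; defaults to `spec$seed + 1`.
#' @return invisibly, a list with `path` and `truth`, a data frame with one
#'   row per gene: `gene_id`, `chromosome` (GFF3 label), `vcf_chromosome`,
#'   `start`, `end`, `strand`, `description`, `n_variants_gene`,
#'   `n_variants_exons`.
#' @export
generate_gff3 <- function(fixture, path, seed = NULL) {
  spec <- fixture$spec
  if (is.null(seed)) seed <- spec$seed + 1L
  descriptions <- c("dwarf growth habit", "flowering time regulator",
                    "disease resistance protein", "kernel size determinant",
                    "plant height control", "awn development factor")
  go_terms <- c("GO:0008150", "GO:0003674", "GO:0005575")
  with_fixture_seed(seed, {
    lines <- "##gff-version 3"
    truth <- list()
    gi <- 0L
    for (chrom in names(fixture$truth)) {
      tr <- fixture$truth[[chrom]]
      glabel <- spec$gff_labels[[chrom]]
      ng <- spec$genes_per_chromosome
      if (ng == 0L || length(tr$positions) == 0L) next
      span <- range(tr$positions)
      if (diff(span) < 20L * ng)
        vm_abort("argument", sprintf(
          "gene density too high for chromosome %s: span %d cannot hold %d genes",
          chrom, diff(span), ng))
      # alternate gene / intergenic blocks of equal width -> no overlap
      block <- floor((span[2] - span[1] + 1) / (2 * ng))
      for (g in seq_len(ng)) {
        gi <- gi + 1L
        gstart <- span[1] + (2L * (g - 1L)) * block
        gend <- gstart + block - 1L
        gid <- sprintf("GENE%03d", gi)
        strand <- sample(c("+", "-"), 1)
        desc <- sample(descriptions, 1)
        onto <- if (stats::runif(1) < 0.5)
          paste0(";Ontology_term=", sample(go_terms, 1)) else ""
        lines <- c(lines, paste(glabel, "fixture", "gene", gstart, gend, ".",
                                strand, ".",
                                paste0("ID=", gid, ";Name=", gid,
                                       ";description=", desc, onto),
                                sep = "\t"))
        mid <- paste0(gid, ".1")
        lines <- c(lines, paste(glabel, "fixture", "mRNA", gstart, gend, ".",
                                strand, ".",
                                paste0("ID=", mid, ";Parent=", gid),
                                sep = "\t"))
        nex <- sample(1:3, 1)
        eblock <- floor((gend - gstart + 1) / (2 * nex))
        estarts <- gstart + (2L * (seq_len(nex) - 1L)) * eblock
        eends <- pmin(estarts + eblock - 1L, gend)
        ex_lines <- paste(glabel, "fixture", "exon", estarts, eends, ".",
                          strand, ".",
                          paste0("ID=", mid, ".exon", seq_len(nex),
                                 ";Parent=", mid),
                          sep = "\t")
        lines <- c(lines, ex_lines)
        in_gene <- tr$positions >= gstart & tr$positions <= gend
        in_exon <- rep(FALSE, length(tr$positions))
        for (e in seq_len(nex))
          in_exon <- in_exon | (tr$positions >= estarts[e] &
                                tr$positions <= eends[e])
        truth[[gi]] <- data.frame(
          gene_id = gid, chromosome = glabel, vcf_chromosome = chrom,
          start = gstart, end = gend, strand = strand, description = desc,
          n_variants_gene = sum(in_gene), n_variants_exons = sum(in_exon),
          stringsAsFactors = FALSE)
      }
    }
    writeLines(lines, path)
    invisible(list(path = path,
                   truth = do.call(rbind, truth)))
  })
}

#' Write fixture ground truth as tab-separated tables
#'
#' @param fixture return value of [generate_vcf()].
#' @param dir directory to write one `<chromosome>.dosage.tsv` and
#'   `<chromosome>.variants.tsv` per chromosome into.
#' @return invisibly, the paths written.
#' @export
write_truth_tables <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (chrom in names(fixture$truth)) {
    tr <- fixture$truth[[chrom]]
    vp <- file.path(dir, paste0(chrom, ".variants.tsv"))
    utils::write.table(
      data.frame(position = tr$positions, ref = tr$ref, alt = tr$alt,
                 freq = tr$freq, qual = tr$qual, mq = tr$mq, ann = tr$ann),
      vp, sep = "\t", row.names = FALSE, quote = FALSE, na = ".")
    dp <- file.path(dir, paste0(chrom, ".dosage.tsv"))
    utils::write.table(tr$dosage, dp, sep = "\t", quote = FALSE,
                       col.names = FALSE)
    paths <- c(paths, vp, dp)
  }
  invisible(paths)
}
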