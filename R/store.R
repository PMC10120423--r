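# Chunked dosage store.
#
# A converted dataset lives in a directory:
#   meta.json                store format version, ploidy, samples,
#                            chromosome labels and variant counts, chunk size
#   <chrom-dir>/variants.tsv per-variant position, REF, ALT (comma-joined),
#                            QUAL, MQ, ANN
#   <chrom-dir>/calls-<k>.bin.gz
#                            gzip-compressed int32 dosage block, column-major
#                            (samples x chunk-width), missing = -1
#
# Chunking is along the variant axis with all samples per chunk, because
# slices are variant windows across a sample panel. Random access reads only
# the chunks overlapping the requested index range.

VM_MISSING <- -1L
VM_STORE_VERSION <- 1L

vm_chrom_dir <- function(i) sprintf("chrom-%03d", i)

#' Convert a VCF file into a chunked dosage store
#'
#' Streams through a VCF 4.x file (plain or gzip/BGZF-compressed), converts
#' every genotype to an alternate-allele dosage and writes a chunked,
#' compressed store that supports random access by variant index or physical
#' position. Memory use is bounded by the chunk size, not the file size.
#'
#' Dosage encoding: the count of non-reference alleles in the GT call
#' (0..ploidy). Multi-allelic sites are collapsed - every alternate allele
#' counts 1 towards the dosage. Phased (`|`) and unphased (`/`) separators
#' are equivalent. Any genotype containing a missing allele (`.`), including
#' half-calls such as `./1`, is stored as wholly missing (-1).
#'
#' @param vcf_path path to the VCF file.
#' @param out_path directory to create the store in (created, may exist).
#' @param chunk_variants number of variants per chunk (all samples are kept
#'   together in one chunk row-wise).
#' @return a `vm_dataset` handle, as returned by [open_dataset()].
#' @section Errors: mixed or unsupported ploidy raises a ploidy error naming
#'   the first offending record; unsorted or duplicated positions within a
#'   chromosome raise an ordering error; a missing GT FORMAT field raises a
#'   format error.
#' @export
convert_vcf <- function(vcf_path, out_path, chunk_variants = 5000L) {
  chunk_variants <- as.integer(chunk_variants)
  if (is.na(chunk_variants) || chunk_variants < 1L)
    vm_abort("argument", "chunk_variants must be a positive integer")
  if (!file.exists(vcf_path))
    vm_abort("argument", sprintf("VCF file not found: %s", vcf_path))
  con <- if (grepl("\\.gz$", vcf_path)) gzfile(vcf_path, "rt")
         else file(vcf_path, "rt")
  on.exit(close(con), add = TRUE)

  # ---- header ----
  samples <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      vm_abort("format", "no #CHROM header line found in VCF")
    if (startsWith(line, "#CHROM")) {
      fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(fields) < 10L)
        vm_abort("format", "VCF has no sample columns")
      if (!identical(fields[9], "FORMAT"))
        vm_abort("format", "VCF #CHROM line lacks a FORMAT column")
      samples <- fields[-(1:9)]
      break
    }
    if (!startsWith(line, "##"))
      vm_abort("format", sprintf("unexpected header line: %s", line))
  }
  if (anyDuplicated(samples))
    vm_abort("format", "duplicate sample identifiers in VCF header")
  n_samples <- length(samples)
  nf <- 9L + n_samples

  dir.create(out_path, recursive = TRUE, showWarnings = FALSE)

  # close any per-chromosome writer still open if conversion aborts
  on.exit({
    if (!is.null(cur) && !is.null(cur$var_con))
      try(close(cur$var_con), silent = TRUE)
  }, add = TRUE)

  ploidy <- NA_integer_
  chromosomes <- character(0)
  n_variants <- integer(0)
  # per-chromosome accumulation state
  cur <- NULL  # list(label, dir, n, last_pos, buf = list of int matrices, buf_n, chunk_i, var_con)
  flush_chunk <- function() {
    if (cur$buf_n == 0L) return(invisible())
    block <- do.call(cbind, cur$buf)
    f <- gzfile(file.path(out_path, cur$dir,
                          sprintf("calls-%06d.bin.gz", cur$chunk_i)), "wb")
    writeBin(as.integer(block), f, size = 4L)
    close(f)
    cur$chunk_i <<- cur$chunk_i + 1L
    cur$buf <<- list(); cur$buf_n <<- 0L
  }
  close_chrom <- function() {
    if (is.null(cur)) return(invisible())
    flush_chunk()
    close(cur$var_con)
    chromosomes <<- c(chromosomes, cur$label)
    n_variants <<- c(n_variants, cur$n)
    cur <<- NULL
  }
  open_chrom <- function(label) {
    if (label %in% chromosomes)
      vm_abort("ordering", sprintf(
        "chromosome %s appears in non-contiguous blocks; VCF must be sorted",
        label))
    d <- vm_chrom_dir(length(chromosomes) + 1L)
    dir.create(file.path(out_path, d), showWarnings = FALSE)
    vc <- file(file.path(out_path, d, "variants.tsv"), "wt")
    writeLines("pos\tref\talt\tqual\tmq\tann", vc)
    cur <<- list(label = label, dir = d, n = 0L, last_pos = 0L,
                 buf = list(), buf_n = 0L, chunk_i = 1L, var_con = vc)
  }

  repeat {
    lines <- readLines(con, n = chunk_variants)
    if (length(lines) == 0L) break
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) next
    parts <- strsplit(lines, "\t", fixed = TRUE)
    lens <- lengths(parts)
    bad <- which(lens != nf)
    if (length(bad)) {
      p <- parts[[bad[1]]]
      vm_abort("format", sprintf("record at %s:%s has %d fields, expected %d",
                                 p[1], p[2], lens[bad[1]], nf))
    }
    m <- matrix(unlist(parts, use.names = FALSE), ncol = nf, byrow = TRUE)
    fmt <- m[, 9]
    gt_at <- vm_gt_position(fmt)
    bad_fmt <- which(is.na(gt_at))
    if (length(bad_fmt))
      vm_abort("format", sprintf("record at %s:%s has no GT in FORMAT",
                                 m[bad_fmt[1], 1], m[bad_fmt[1], 2]))
    gtm <- m[, 10:nf, drop = FALSE]
    # extract the GT subfield (FORMAT position of GT, ":"-separated)
    if (any(gt_at != 1L)) {
      for (r in which(gt_at != 1L))
        gtm[r, ] <- vapply(strsplit(gtm[r, ], ":", fixed = TRUE),
                           function(x) x[gt_at[r]], character(1))
    } else {
      gtm[] <- sub(":.*", "", gtm)
    }
    gtm[] <- gsub("|", "/", gtm, fixed = TRUE)
    has_sep <- grepl("/", gtm, fixed = TRUE)
    row_ploidy <- ifelse(rowSums(matrix(has_sep, nrow = nrow(m))) == n_samples,
                         2L,
                         ifelse(rowSums(matrix(has_sep, nrow = nrow(m))) == 0L,
                                1L, NA_integer_))
    if (anyNA(row_ploidy)) {
      r <- which(is.na(row_ploidy))[1]
      vm_abort("ploidy", sprintf(
        "record at %s:%s mixes haploid and diploid GT calls",
        m[r, 1], m[r, 2]))
    }
    if (is.na(ploidy)) ploidy <- row_ploidy[1]
    if (any(row_ploidy != ploidy)) {
      r <- which(row_ploidy != ploidy)[1]
      vm_abort("ploidy", sprintf(
        "record at %s:%s is %s but the file started %s",
        m[r, 1], m[r, 2],
        c("haploid", "diploid")[row_ploidy[r]], c("haploid", "diploid")[ploidy]))
    }
    extra <- grepl("/.*/", gtm)
    if (any(extra)) {
      r <- which(rowSums(matrix(extra, nrow = nrow(m))) > 0)[1]
      vm_abort("ploidy", sprintf(
        "record at %s:%s has ploidy > 2, which is unsupported",
        m[r, 1], m[r, 2]))
    }
    dos <- vm_gt_to_dosage(gtm, ploidy)  # n_records x n_samples

    pos <- as.integer(m[, 2])
    qual <- suppressWarnings(as.numeric(ifelse(m[, 6] == ".", NA, m[, 6])))
    info <- m[, 8]
    mq <- suppressWarnings(as.numeric(vm_info_field(info, "MQ")))
    ann <- vm_info_field(info, "ANN")

    for (i in seq_len(nrow(m))) {
      label <- m[i, 1]
      if (is.null(cur) || cur$label != label) {
        close_chrom()
        open_chrom(label)
      }
      if (cur$n > 0L) {
        if (pos[i] == cur$last_pos)
          vm_abort("ordering", sprintf(
            "duplicate position %s:%d; positions must be strictly increasing",
            label, pos[i]))
        if (pos[i] < cur$last_pos)
          vm_abort("ordering", sprintf(
            "unsorted position %s:%d after %d", label, pos[i], cur$last_pos))
      }
      cur$last_pos <- pos[i]
      cur$n <- cur$n + 1L
      cur$buf[[length(cur$buf) + 1L]] <- matrix(dos[i, ], ncol = 1L)
      cur$buf_n <- cur$buf_n + 1L
      writeLines(paste(pos[i], m[i, 4], m[i, 5],
                       ifelse(is.na(qual[i]), ".", qual[i]),
                       ifelse(is.na(mq[i]), ".", mq[i]),
                       ifelse(is.na(ann[i]), ".", ann[i]), sep = "\t"),
                 cur$var_con)
      if (cur$buf_n == chunk_variants) flush_chunk()
    }
  }
  close_chrom()

  meta <- list(format = "varmat-store", version = VM_STORE_VERSION,
               ploidy = if (is.na(ploidy)) 2L else ploidy,
               samples = samples,
               chromosomes = as.list(chromosomes),
               n_variants = as.list(stats::setNames(as.integer(n_variants),
                                                    chromosomes)),
               chunk_variants = chunk_variants)
  jsonlite::write_json(meta, file.path(out_path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  open_dataset(out_path)
}

# position of "GT" in the ":"-separated FORMAT string, NA if absent
vm_gt_position <- function(fmt) {
  vapply(strsplit(fmt, ":", fixed = TRUE),
         function(x) { i <- match("GT", x); if (is.na(i)) NA_integer_ else i },
         integer(1))
}

# INFO field extraction, NA when absent
vm_info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexpr(pat, info, perl = TRUE))
  out <- rep(NA_character_, length(info))
  hit <- grepl(pat, info, perl = TRUE)
  out[hit] <- sub(pat, "\\1", regmatches(info, regexpr(pat, info, perl = TRUE)),
                  perl = TRUE)
  out
}

# gtm: records x samples character matrix of bare GT calls with "/" separators
# returns records x samples integer dosage, -1 missing
vm_gt_to_dosage <- function(gtm, ploidy) {
  dm <- matrix(VM_MISSING, nrow = nrow(gtm), ncol = ncol(gtm))
  if (ploidy == 1L) {
    ok <- gtm != "."
    dm[ok] <- as.integer(gtm[ok] != "0")
  } else {
    a1 <- sub("/.*", "", gtm)
    a2 <- sub(".*/", "", gtm)
    ok <- a1 != "." & a2 != "."
    dm[ok] <- (a1[ok] != "0") + (a2[ok] != "0")
  }
  dm
}

#' Open an existing dosage store
#'
#' @param path store directory created by [convert_vcf()].
#' @return a `vm_dataset`: a handle holding the store path, ploidy, the
#'   ordered sample list, chromosome labels, and the per-chromosome variant
#'   index (positions, alleles, QUAL, MQ, ANN).
#' @export
open_dataset <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    vm_abort("argument", sprintf("not a varmat store (no meta.json): %s", path))
  meta <- tryCatch(jsonlite::read_json(meta_path, simplifyVector = TRUE),
                   error = function(e)
                     vm_abort("parse", sprintf("corrupt store metadata: %s",
                                               conditionMessage(e))))
  if (!identical(meta$format, "varmat-store"))
    vm_abort("argument", sprintf("not a varmat store: %s", path))
  chromosomes <- as.character(unlist(meta$chromosomes))
  index <- list()
  for (i in seq_along(chromosomes)) {
    vt <- utils::read.table(
      file.path(path, vm_chrom_dir(i), "variants.tsv"),
      header = TRUE, sep = "\t", quote = "", comment.char = "",
      na.strings = ".", colClasses = c("integer", "character", "character",
                                       "numeric", "numeric", "character"))
    index[[chromosomes[i]]] <- list(
      positions = vt$pos, ref = vt$ref, alt = vt$alt,
      qual = vt$qual, mq = vt$mq, ann = vt$ann)
  }
  structure(list(
    path = path,
    ploidy = as.integer(meta$ploidy),
    samples = as.character(meta$samples),
    chromosomes = chromosomes,
    n_variants = vapply(index, function(x) length(x$positions), integer(1)),
    chunk_variants = as.integer(meta$chunk_variants),
    index = index
  ), class = "vm_dataset")
}

#' @export
print.vm_dataset <- function(x, ...) {
  cat("<vm_dataset> ", x$path, "\n",
      "  samples: ", length(x$samples),
      "  ploidy: ", x$ploidy, "\n", sep = "")
  for (c in x$chromosomes)
    cat("  ", c, ": ", x$n_variants[[c]], " variants\n", sep = "")
  invisible(x)
}

vm_check_chrom <- function(ds, chromosome) {
  i <- match(chromosome, ds$chromosomes)
  if (is.na(i))
    vm_abort("lookup", sprintf("unknown chromosome: %s", chromosome),
             known = ds$chromosomes)
  i
}

vm_check_panel <- function(ds, panel) {
  if (is.null(panel)) return(ds$samples)
  bad <- setdiff(panel, ds$samples)
  if (length(bad))
    vm_abort("panel", sprintf("unknown sample(s) in panel: %s",
                              paste(bad, collapse = ", ")))
  if (anyDuplicated(panel))
    vm_abort("panel", "panel contains duplicate sample identifiers")
  panel
}

# Read dosages for variant indices [first, first+width-1] (1-based) on one
# chromosome, restricted to `panel` rows. Only touches overlapping chunks.
vm_read_dosages <- function(ds, chrom_i, first, width, panel) {
  chrom <- ds$chromosomes[chrom_i]
  rows <- match(panel, ds$samples)
  n_samples <- length(ds$samples)
  if (width == 0L)
    return(matrix(VM_MISSING, nrow = length(panel), ncol = 0L,
                  dimnames = list(panel, NULL)))
  cw <- ds$chunk_variants
  last <- first + width - 1L
  chunks <- unique(((first:last) - 1L) %/% cw)
  blocks <- lapply(chunks, function(k) {
    f <- gzfile(file.path(ds$path, vm_chrom_dir(chrom_i),
                          sprintf("calls-%06d.bin.gz", k + 1L)), "rb")
    on.exit(close(f))
    n_in_chunk <- min(cw, ds$n_variants[[chrom]] - k * cw)
    v <- readBin(f, "integer", n = n_samples * n_in_chunk, size = 4L)
    matrix(v, nrow = n_samples)
  })
  full <- do.call(cbind, blocks)
  offset <- chunks[1] * cw
  out <- full[rows, (first - offset):(last - offset), drop = FALSE]
  dimnames(out) <- list(panel, NULL)
  out
}

vm_make_slice <- function(ds, chrom_i, first, width, panel) {
  chrom <- ds$chromosomes[chrom_i]
  idx <- ds$index[[chrom]]
  sel <- if (width > 0L) first:(first + width - 1L) else integer(0)
  structure(list(
    chromosome = chrom,
    first_index = first,           # 1-based index into the chromosome
    width = width,
    positions = idx$positions[sel],
    ref = idx$ref[sel],
    alt = idx$alt[sel],
    qual = idx$qual[sel],
    mq = idx$mq[sel],
    ann = idx$ann[sel],
    panel = panel,
    ploidy = ds$ploidy,
    dosages = vm_read_dosages(ds, chrom_i, first, width, panel)
  ), class = "vm_slice")
}

#' @export
print.vm_slice <- function(x, ...) {
  cat("<vm_slice> ", x$chromosome, " [", x$first_index, ", ",
      x$first_index + x$width, ") — ", x$width, " variants x ",
      length(x$panel), " samples\n", sep = "")
  invisible(x)
}

#' Slice the next `count` variants at or after a physical position
#'
#' This is the gapless-display primitive: regardless of physical spacing the
#' slice holds a fixed number of consecutive variants, with their physical
#' coordinates carried alongside. Position lookup is a binary search on the
#' chromosome's sorted positions.
#'
#' @param ds a `vm_dataset`.
#' @param chromosome chromosome label (VCF dialect).
#' @param start_position 1-based physical position; the slice starts at the
#'   first variant with position >= `start_position`.
#' @param count maximum number of variants to return (>= 1); fewer are
#'   returned at the chromosome end.
#' @param panel ordered subset of sample identifiers; `NULL` means all
#'   samples in VCF header order.
#' @return a `vm_slice`: positions, alleles, QUAL/MQ/ANN metadata and the
#'   panel-restricted dosage matrix (rows in panel order, missing = -1).
#' @export
slice_by_count <- function(ds, chromosome, start_position, count,
                           panel = NULL) {
  count <- as.integer(count)
  if (is.na(count) || count < 1L)
    vm_abort("argument", "count must be a positive integer")
  chrom_i <- vm_check_chrom(ds, chromosome)
  panel <- vm_check_panel(ds, panel)
  pos <- ds$index[[chromosome]]$positions
  # findInterval is a binary search; first index with pos >= start_position
  first <- findInterval(start_position - 1L, pos) + 1L
  width <- max(0L, min(count, length(pos) - first + 1L))
  if (first > length(pos)) { first <- length(pos) + 1L; width <- 0L }
  vm_make_slice(ds, chrom_i, first, width, panel)
}

#' Slice all variants within a physical range
#'
#' @inheritParams slice_by_count
#' @param start,end 1-based inclusive physical bounds, `start <= end`.
#' @return a `vm_slice` holding exactly the variants with
#'   `start <= position <= end`.
#' @export
slice_by_range <- function(ds, chromosome, start, end, panel = NULL) {
  if (start > end)
    vm_abort("argument", sprintf("start (%s) must be <= end (%s)", start, end))
  chrom_i <- vm_check_chrom(ds, chromosome)
  panel <- vm_check_panel(ds, panel)
  pos <- ds$index[[chromosome]]$positions
  first <- findInterval(start - 1L, pos) + 1L
  lastv <- findInterval(end, pos)
  width <- max(0L, lastv - first + 1L)
  if (width == 0L) first <- min(first, length(pos) + 1L)
  vm_make_slice(ds, chrom_i, first, width, panel)
}
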