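# Standards-compliant VCF / GFF3 export for a region, with optional filter
# application and panel restriction.
#
# Lossiness, documented: the store keeps dosages, not allele-resolved
# genotypes, so exports re-serialize genotypes from dosage (collapsed
# multi-allelic calls come back as allele "1"), all diploid genotypes are
# written unphased, and INFO is reconstructed minimally (MQ and ANN only).

#' Export a genomic region as a VCF document
#'
#' Writes a VCF 4.2 file for the variants of a region, restricted to a
#' sample panel and optionally to the variants passing filter criteria.
#' Genotypes are re-serialized from dosage: diploid `0 -> 0/0`, `1 -> 0/1`,
#' `2 -> 1/1`, missing `-> ./.`; haploid `0 / 1 / .`.
#'
#' @param ds a `vm_dataset`.
#' @param path output file path; `.gz` suffix writes gzip-compressed text.
#' @param region a [vm_region()] resolving to a single chromosome.
#' @param panel sample subset (default: all samples), exported in panel
#'   order.
#' @param criteria optional [filter_criteria()]; only mask-passing variants
#'   are written.
#' @param ann annotation, for feature regions.
#' @return invisibly, the number of variant records written.
#' @export
export_vcf <- function(ds, path, region, panel = NULL, criteria = NULL,
                       ann = NULL) {
  panel <- vm_check_panel(ds, panel)
  slice <- resolve_region(ds, region, panel, ann)
  keep <- rep(TRUE, slice$width)
  if (!is.null(criteria) && slice$width > 0L) {
    st <- compute_stats(slice)
    keep <- apply_filter(st, slice, criteria)
  }
  chrom <- slice$chromosome
  contig_len <- if (ds$n_variants[[chrom]] > 0L)
    max(ds$index[[chrom]]$positions) else 0L
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=varmat-", as.character(utils::packageVersion("varmat"))),
    sprintf("##contig=<ID=%s,length=%d>", chrom, contig_len),
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel), collapse = "\t"))
  sel <- which(keep)
  body <- character(length(sel))
  if (length(sel)) {
    gt_map <- if (ds$ploidy == 2L) c("0/0", "0/1", "1/1") else c("0", "1")
    gt_missing <- if (ds$ploidy == 2L) "./." else "."
    for (k in seq_along(sel)) {
      j <- sel[k]
      d <- slice$dosages[, j]
      gt <- gt_map[pmax(d, 0L) + 1L]  # index 0 would drop entries
      gt[d == VM_MISSING] <- gt_missing
      info <- character(0)
      if (!is.na(slice$mq[j]))
        info <- c(info, paste0("MQ=", format(slice$mq[j], trim = TRUE)))
      if (!is.na(slice$ann[j]))
        info <- c(info, paste0("ANN=", slice$ann[j]))
      body[k] <- paste(c(
        chrom, slice$positions[j], ".", slice$ref[j],
        ifelse(is.na(slice$alt[j]), ".", slice$alt[j]),
        ifelse(is.na(slice$qual[j]), ".",
               format(slice$qual[j], trim = TRUE)),
        ".",
        if (length(info)) paste(info, collapse = ";") else ".",
        "GT", gt), collapse = "\t")
    }
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  writeLines(c(header, body), con, sep = "\n")
  close(con)
  invisible(length(sel))
}

#' Export the annotation of a genomic region as a GFF3 document
#'
#' Writes every feature overlapping the region, together with all its
#' ancestors, so the output is referentially closed (every `Parent` id it
#' mentions is present). Features are written whole, with unmodified
#' coordinates, even when they only partially overlap the region.
#'
#' @param ann a `vm_annotation`.
#' @param path output file path.
#' @param chromosome chromosome label in the ANNOTATION dialect, or a store
#'   label if a label map is set (tried in that order).
#' @param start,end 1-based inclusive physical range.
#' @return invisibly, the number of feature lines written (directive
#'   excluded).
#' @export
export_gff3 <- function(ann, path, chromosome, start, end) {
  if (start > end)
    vm_abort("argument", sprintf("start (%s) must be <= end (%s)", start, end))
  f <- ann$features
  glabel <- chromosome
  if (!glabel %in% f$chromosome && !is.null(ann$label_map)) {
    mapped <- ann$label_map[[chromosome]]
    if (!is.null(mapped) && !is.na(mapped)) glabel <- mapped
  }
  sel <- which(f$chromosome == glabel & f$start <= end & f$end >= start)
  # referential closure: pull in ancestors of every selected feature
  added <- TRUE
  while (added) {
    parents <- unique(unlist(strsplit(
      f$parent[sel][!is.na(f$parent[sel])], ",", fixed = TRUE)))
    pidx <- which(f$id %in% parents)
    new <- setdiff(pidx, sel)
    added <- length(new) > 0L
    sel <- c(sel, new)
  }
  sel <- sort(sel)  # original file order
  lines <- "##gff-version 3"
  if (length(sel)) {
    ff <- f[sel, , drop = FALSE]
    lines <- c(lines, paste(ff$chromosome, ff$source, ff$type, ff$start,
                            ff$end, ff$score, ff$strand, ff$phase,
                            ff$attributes, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(length(sel))
}
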