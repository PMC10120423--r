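# GFF3 annotation: parsing with line-numbered diagnostics, ID/Parent
# hierarchy, chromosome-label mapping to the variant store, gene search with
# per-gene / exon-union variant counts, SnpEff ANN parsing, and external
# link rendering.

#' Load a GFF3 annotation file
#'
#' Parses a (possibly gzip-compressed) GFF3 file into a feature table with
#' the ID/Parent hierarchy resolved. Coordinates stay 1-based inclusive.
#' `##` directives and `#` comments are tolerated; an embedded `##FASTA`
#' section stops parsing. A feature whose `Parent` id never appears raises a
#' dangling-reference warning but is kept; a child extending beyond its
#' parent's bounds is flagged in the `within_parent` column.
#'
#' @param path path to the GFF3 file.
#' @return a `vm_annotation`: `features` (data frame with `line`, `id`,
#'   `type`, `chromosome`, `start`, `end`, `strand`, `parent`, `name`,
#'   `description`, `ontology_terms`, `attributes` (raw column 9),
#'   `within_parent`) and `label_map` (initially `NULL`; see
#'   [infer_label_map()]).
#' @export
load_gff3 <- function(path) {
  if (!file.exists(path))
    vm_abort("argument", sprintf("GFF3 file not found: %s", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  lines <- readLines(con)
  close(con)
  fasta <- which(lines == "##FASTA")
  if (length(fasta)) lines <- lines[seq_len(fasta[1] - 1L)]
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(structure(list(features = vm_empty_features(), label_map = NULL),
                     class = "vm_annotation"))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  lens <- lengths(parts)
  if (any(lens != 9L))
    vm_abort("parse", sprintf(
      "GFF3 line %d has %d columns, expected 9",
      lineno[lens != 9L][1], lens[lens != 9L][1]))
  m <- matrix(unlist(parts, use.names = FALSE), ncol = 9L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    vm_abort("parse", sprintf("GFF3 line %d has non-numeric coordinates",
                              lineno[bad[1]]))
  bad <- which(end < start)
  if (length(bad))
    vm_abort("parse", sprintf(
      "GFF3 line %d has end (%d) < start (%d)",
      lineno[bad[1]], end[bad[1]], start[bad[1]]))
  attr_get <- function(attrs, key) {
    pat <- paste0("(?:^|;)", key, "=([^;]*)")
    hit <- regexpr(pat, attrs, perl = TRUE)
    out <- rep(NA_character_, length(attrs))
    ok <- hit > 0
    out[ok] <- sub(pat, "\\1", regmatches(attrs, hit), perl = TRUE)
    # percent-decoding per the GFF3 attribute escaping rules
    ifelse(is.na(out), out,
           vapply(out, function(s) utils::URLdecode(s), character(1),
                  USE.NAMES = FALSE))
  }
  attrs <- m[, 9]
  feats <- data.frame(
    line = lineno,
    id = attr_get(attrs, "ID"),
    type = m[, 3],
    chromosome = m[, 1],
    source = m[, 2],
    start = start,
    end = end,
    score = m[, 6],
    strand = m[, 7],
    phase = m[, 8],
    parent = attr_get(attrs, "Parent"),
    name = attr_get(attrs, "Name"),
    description = attr_get(attrs, "description"),
    note = attr_get(attrs, "Note"),
    ontology_terms = attr_get(attrs, "Ontology_term"),
    attributes = attrs,
    stringsAsFactors = FALSE)
  # dangling parents: warn, keep
  parent1 <- sub(",.*", "", feats$parent)
  known <- feats$id[!is.na(feats$id)]
  dangling <- !is.na(parent1) & !(parent1 %in% known)
  if (any(dangling))
    warning(sprintf("GFF3: %d feature(s) reference unknown Parent ids (first at line %d)",
                    sum(dangling), feats$line[dangling][1]))
  # child-within-parent check (first parent only)
  pi <- match(parent1, feats$id)
  within <- rep(NA, nrow(feats))
  has_p <- !is.na(pi)
  within[has_p] <- feats$start[has_p] >= feats$start[pi[has_p]] &
                   feats$end[has_p] <= feats$end[pi[has_p]]
  feats$within_parent <- within
  if (any(!within[has_p]))
    warning(sprintf("GFF3: %d feature(s) extend beyond their parent's bounds",
                    sum(!within[has_p])))
  structure(list(features = feats, label_map = NULL),
            class = "vm_annotation")
}

vm_empty_features <- function() {
  data.frame(line = integer(0), id = character(0), type = character(0),
             chromosome = character(0), source = character(0),
             start = integer(0), end = integer(0), score = character(0),
             strand = character(0), phase = character(0),
             parent = character(0),
             name = character(0), description = character(0),
             note = character(0), ontology_terms = character(0),
             attributes = character(0), within_parent = logical(0),
             stringsAsFactors = FALSE)
}

#' @export
print.vm_annotation <- function(x, ...) {
  cat("<vm_annotation> ", nrow(x$features), " features on ",
      length(unique(x$features$chromosome)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Infer the chromosome-label map between a variant store and an annotation
#'
#' Maps every variant-store chromosome label to an annotation label: exact
#' match first, then match after stripping a leading "chr"/"Chr"/"CHR"
#' prefix from either side. The result is injective; labels that cannot be
#' resolved map to `NA` and must be configured manually.
#'
#' @param vcf_labels chromosome labels of the variant store.
#' @param gff_labels chromosome labels occurring in the annotation.
#' @return a named character vector: `names` are store labels, values the
#'   matched annotation labels (or NA).
#' @export
infer_label_map <- function(vcf_labels, gff_labels) {
  strip <- function(x) sub("^[Cc][Hh][Rr]", "", x)
  out <- stats::setNames(rep(NA_character_, length(vcf_labels)), vcf_labels)
  taken <- character(0)
  for (v in vcf_labels) {
    cand <- gff_labels[!(gff_labels %in% taken)]
    hit <- cand[match(v, cand)]
    if (is.na(hit)) hit <- cand[match(strip(v), cand)]
    if (is.na(hit)) hit <- cand[match(strip(v), strip(cand))]
    if (is.na(hit)) hit <- cand[match(v, strip(cand))]
    if (!is.na(hit)) { out[[v]] <- hit; taken <- c(taken, hit) }
  }
  out
}

#' Attach a label map to an annotation
#'
#' @param ann a `vm_annotation`.
#' @param label_map named character vector (store label -> annotation
#'   label); must be injective.
#' @return the annotation with `label_map` set.
#' @export
set_label_map <- function(ann, label_map) {
  label_map <- unlist(label_map)  # tolerate list form from YAML configs
  vals <- label_map[!is.na(label_map)]
  if (anyDuplicated(vals))
    vm_abort("mapping", "label map must be injective (duplicate GFF3 labels)")
  ann$label_map <- label_map
  ann
}

# annotation label for a store label
vm_map_label <- function(ann, vcf_label) {
  if (is.null(ann$label_map))
    vm_abort("mapping", "annotation has no chromosome label map; call set_label_map()")
  i <- match(vcf_label, names(ann$label_map))
  if (is.na(i) || is.na(ann$label_map[i]))
    vm_abort("mapping", sprintf("chromosome %s is not mapped to the annotation",
                                vcf_label))
  unname(ann$label_map[i])
}

# store label for an annotation label
vm_reverse_label <- function(ann, gff_label) {
  if (is.null(ann$label_map))
    vm_abort("mapping", "annotation has no chromosome label map; call set_label_map()")
  i <- match(gff_label, ann$label_map)
  if (is.na(i))
    vm_abort("mapping", sprintf("annotation chromosome %s is not mapped to the store",
                                gff_label))
  names(ann$label_map)[i]
}

# exon intervals belonging to a gene id: exons whose parent chain reaches it
vm_gene_exons <- function(ann, gene_id) {
  f <- ann$features
  # resolve each feature's top ancestor lazily via first-parent chain
  anc <- function(i) {
    seen <- integer(0)
    while (!is.na(f$parent[i])) {
      p <- sub(",.*", "", f$parent[i])
      j <- match(p, f$id)
      if (is.na(j) || j %in% seen) break
      seen <- c(seen, j)
      i <- j
    }
    i
  }
  ex <- which(f$type == "exon")
  keep <- vapply(ex, function(i) {
    top <- anc(i)
    identical(f$id[top], gene_id)
  }, logical(1))
  f[ex[keep], c("start", "end"), drop = FALSE]
}

# union of intervals -> data.frame(start, end), disjoint and sorted
vm_interval_union <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  out_s <- iv$start[1]; out_e <- iv$end[1]
  res <- list()
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= out_e + 1L) out_e <- max(out_e, iv$end[i])
    else { res[[length(res) + 1L]] <- c(out_s, out_e)
           out_s <- iv$start[i]; out_e <- iv$end[i] }
  }
  res[[length(res) + 1L]] <- c(out_s, out_e)
  m <- do.call(rbind, res)
  data.frame(start = m[, 1], end = m[, 2])
}

# number of store variants on chromosome label within [start, end]
vm_count_variants <- function(ds, chromosome, start, end) {
  pos <- ds$index[[chromosome]]$positions
  max(0L, findInterval(end, pos) - findInterval(start - 1L, pos))
}

#' Search genes in the annotation
#'
#' Finds genes by case-insensitive substring match on their id, name,
#' description or Note, and/or by chromosome and physical range (interval
#' overlap). For every hit, the number of store variants inside the gene
#' body is counted; when `count_exon_variants` is `TRUE`, variants inside
#' the union of the gene's exon intervals are counted as well (never
#' exceeding the gene-body count).
#'
#' @param ann a `vm_annotation` with a label map set.
#' @param ds a `vm_dataset`.
#' @param query optional search text.
#' @param chromosome optional chromosome label (variant-store dialect).
#' @param range optional `c(start, end)` physical range; requires
#'   `chromosome`.
#' @param count_exon_variants whether to compute exon-union variant counts
#'   (config key `count_exon_variants`).
#' @param gene_types GFF3 feature types treated as genes.
#' @param config optional configuration list providing `gene_links` /
#'   `ontology_link` templates for [render_links()].
#' @return a data frame of gene hits, in position order for positional
#'   queries: `gene_id`, `description`, `chromosome` (store label),
#'   `start`, `end`, `strand`, `n_variants_gene`, `n_variants_exons` (NA
#'   when not requested), plus a `links` list-column of rendered URLs.
#' @export
search_genes <- function(ann, ds, query = NULL, chromosome = NULL,
                         range = NULL, count_exon_variants = FALSE,
                         gene_types = "gene", config = NULL) {
  if (is.null(query) && is.null(chromosome) && is.null(range))
    vm_abort("argument", "at least one of query/chromosome/range is required")
  if (!is.null(range) && is.null(chromosome))
    vm_abort("argument", "range search requires a chromosome")
  f <- ann$features
  sel <- f$type %in% gene_types
  if (!is.null(chromosome)) {
    glabel <- vm_map_label(ann, chromosome)  # mapping error if unknown
    sel <- sel & f$chromosome == glabel
  }
  if (!is.null(range)) {
    if (length(range) != 2L || range[1] > range[2])
      vm_abort("argument", "range must be c(start, end) with start <= end")
    sel <- sel & f$start <= range[2] & f$end >= range[1]
  }
  if (!is.null(query)) {
    q <- tolower(query)
    hay <- tolower(paste(vm_na_empty(f$id), vm_na_empty(f$name),
                         vm_na_empty(f$description), vm_na_empty(f$note)))
    sel <- sel & grepl(q, hay, fixed = TRUE)
  }
  hits <- f[sel, , drop = FALSE]
  hits <- hits[order(hits$chromosome, hits$start), , drop = FALSE]
  n <- nrow(hits)
  ng <- integer(n); ne <- rep(NA_integer_, n); links <- vector("list", n)
  store_label <- character(n)
  for (i in seq_len(n)) {
    store_label[i] <- vm_reverse_label(ann, hits$chromosome[i])
    ng[i] <- vm_count_variants(ds, store_label[i], hits$start[i], hits$end[i])
    if (isTRUE(count_exon_variants)) {
      ex <- vm_interval_union(vm_gene_exons(ann, hits$id[i]))
      ne[i] <- if (nrow(ex)) sum(vapply(seq_len(nrow(ex)), function(j)
        vm_count_variants(ds, store_label[i], ex$start[j], ex$end[j]),
        integer(1))) else 0L
    }
    links[[i]] <- render_links(hits$id[i], hits$ontology_terms[i], config)
  }
  out <- data.frame(
    gene_id = hits$id, description = vm_na_empty(hits$description),
    chromosome = store_label, start = hits$start, end = hits$end,
    strand = hits$strand, n_variants_gene = ng, n_variants_exons = ne,
    stringsAsFactors = FALSE)
  out$links <- links
  rownames(out) <- NULL
  out
}

vm_na_empty <- function(x) ifelse(is.na(x), "", x)

#' Parse a SnpEff INFO/ANN annotation string
#'
#' ANN strings hold one annotation per comma-separated entry; each entry is
#' pipe-delimited: `Allele|Annotation|Impact|Gene_Name|Gene_ID|Feature_Type|
#' Feature_ID|Transcript_BioType|...`. Extra subfields are ignored.
#'
#' @param ann_string raw ANN value (may be `NA` or empty).
#' @return a data frame with one row per annotation: `allele`, `effect`,
#'   `impact`, `gene_name`, `gene_id`, `feature_type`, `feature_id`; empty
#'   for absent input.
#' @export
parse_ann <- function(ann_string) {
  empty <- data.frame(allele = character(0), effect = character(0),
                      impact = character(0), gene_name = character(0),
                      gene_id = character(0), feature_type = character(0),
                      feature_id = character(0), stringsAsFactors = FALSE)
  if (is.null(ann_string) || length(ann_string) == 0L ||
      is.na(ann_string) || !nzchar(ann_string))
    return(empty)
  entries <- strsplit(ann_string, ",", fixed = TRUE)[[1]]
  rows <- lapply(entries, function(e) {
    p <- strsplit(e, "|", fixed = TRUE)[[1]]
    p <- c(p, rep("", max(0, 7 - length(p))))
    data.frame(allele = p[1], effect = p[2], impact = p[3],
               gene_name = p[4], gene_id = p[5], feature_type = p[6],
               feature_id = p[7], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Render configured external links for a gene
#'
#' Substitutes the `{id}` placeholder of every configured gene link
#' template with the URL-encoded gene id, and of the ontology link template
#' with each of the gene's ontology term ids.
#'
#' @param gene_id gene identifier.
#' @param ontology_terms comma-separated ontology terms of the gene (may be
#'   NA).
#' @param config list with optional `gene_links` (character vector of
#'   templates) and `ontology_link` (single template); templates must
#'   contain `{id}`.
#' @return character vector of URLs (empty when nothing is configured).
#' @export
render_links <- function(gene_id, ontology_terms = NA, config = NULL) {
  if (is.null(config)) return(character(0))
  templates <- config$gene_links
  onto_template <- config$ontology_link
  fill <- function(tpl, id) {
    if (!grepl("{id}", tpl, fixed = TRUE))
      vm_abort("config", sprintf("link template lacks the {id} placeholder: %s",
                                 tpl))
    sub("{id}", utils::URLencode(id, reserved = TRUE), tpl, fixed = TRUE)
  }
  out <- character(0)
  for (tpl in templates) out <- c(out, fill(tpl, gene_id))
  if (!is.null(onto_template) && !is.na(ontology_terms) &&
      nzchar(ontology_terms)) {
    for (term in strsplit(ontology_terms, ",", fixed = TRUE)[[1]])
      out <- c(out, fill(onto_template, trimws(term)))
  }
  out
}
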