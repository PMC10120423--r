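# On-demand analysis: mean imputation, PCA over a genomic window / gene /
# explicit range, Euclidean genetic distance to the reference, and sample
# ordering.

#' Describe a genomic region for analysis and export
#'
#' A region is one of: a viewport window (`start` + `count` variants), an
#' explicit physical range (`start` + `end`), or an annotated feature
#' (`feature` id, resolved through the annotation's bounds and label map).
#'
#' @param chromosome chromosome label in the variant-store dialect (not
#'   needed for feature regions).
#' @param start 1-based physical start.
#' @param end 1-based inclusive physical end (range region).
#' @param count number of variants (window region).
#' @param feature feature id from the annotation (feature region).
#' @return a `vm_region` object.
#' @export
vm_region <- function(chromosome = NULL, start = NULL, end = NULL,
                      count = NULL, feature = NULL) {
  kind <- if (!is.null(feature)) "feature"
          else if (!is.null(end)) "range"
          else if (!is.null(count)) "window"
          else vm_abort("argument",
                        "region needs one of: end (range), count (window), feature")
  if (kind != "feature" && (is.null(chromosome) || is.null(start)))
    vm_abort("argument", "range/window regions need chromosome and start")
  structure(list(kind = kind, chromosome = chromosome, start = start,
                 end = end, count = count, feature = feature),
            class = "vm_region")
}

# Resolve a region to a vm_slice over `panel`.
resolve_region <- function(ds, region, panel = NULL, ann = NULL) {
  if (!inherits(region, "vm_region")) {
    if (is.list(region)) region <- do.call(vm_region, region)
    else vm_abort("argument", "region must be a vm_region or a list")
  }
  switch(region$kind,
    range = slice_by_range(ds, region$chromosome, region$start, region$end,
                           panel),
    window = slice_by_count(ds, region$chromosome, region$start,
                            region$count, panel),
    feature = {
      if (is.null(ann))
        vm_abort("argument", "feature region requires an annotation")
      f <- ann$features[!is.na(ann$features$id) &
                        ann$features$id == region$feature, , drop = FALSE]
      if (nrow(f) == 0L)
        vm_abort("lookup", sprintf("unknown feature id: %s", region$feature))
      vcf_label <- vm_reverse_label(ann, f$chromosome[1])
      slice_by_range(ds, vcf_label, f$start[1], f$end[1], panel)
    })
}

#' Impute missing dosages by the per-variant mean
#'
#' Replaces every missing entry by the mean dosage of the called genotypes
#' at that variant; called entries are unchanged. Variants with zero called
#' genotypes must be excluded before imputation.
#'
#' @param dosages integer dosage matrix (samples x variants, missing = -1).
#' @return a numeric matrix of the same shape with no missing values.
#' @export
impute_missing <- function(dosages) {
  x <- matrix(as.numeric(dosages), nrow = nrow(dosages),
              dimnames = dimnames(dosages))
  miss <- dosages == VM_MISSING
  if (!any(miss)) return(x)
  n_called <- colSums(!miss)
  if (any(n_called == 0L))
    vm_abort("internal",
             "variant with zero called genotypes reached imputation; exclude upstream")
  x[miss] <- NA_real_
  mu <- colMeans(x, na.rm = TRUE)
  fill <- which(miss, arr.ind = TRUE)
  x[fill] <- mu[fill[, 2]]
  x
}

# Internal core shared by run_pca and the tests' region plumbing: select the
# variant columns entering the analysis. Returns list(slice, keep, excluded).
vm_analysis_columns <- function(ds, region, panel, criteria, ann) {
  slice <- resolve_region(ds, region, panel, ann)
  st <- if (slice$width > 0L) compute_stats(slice) else NULL
  defined <- if (is.null(st)) logical(0) else st$n_called > 0L
  keep <- defined
  excluded_by_filter <- 0L
  if (!is.null(criteria) && slice$width > 0L) {
    mask <- apply_filter(st, slice, criteria)
    excluded_by_filter <- sum(defined & !mask)
    keep <- defined & mask
  }
  list(slice = slice, keep = keep, excluded = excluded_by_filter)
}

#' On-demand principal component analysis of a genomic region
#'
#' Runs a PCA of the panel's genotype dosage vectors over the variants of a
#' region, optionally restricted by filter criteria. Variants with no called
#' genotype are always excluded; the remaining variants are capped at
#' `max_variants` keeping the left-most (smallest-position) ones. Missing
#' dosages are mean-imputed per variant, columns are mean-centered, and no
#' variance standardization is applied, so monomorphic variants are inert.
#' Each component's sign is fixed so that its largest-magnitude variant
#' loading is positive, making the output deterministic.
#'
#' @param ds a `vm_dataset`.
#' @param region a [vm_region()] (or list with its fields).
#' @param panel sample panel (default: all samples); at least 2.
#' @param criteria optional [filter_criteria()].
#' @param k number of components to return; truncated to
#'   `min(panel size - 1, variants used)`.
#' @param max_variants cap on the number of variants entering the PCA
#'   (config key `pca_max_variants`).
#' @param ann annotation, required for feature regions.
#' @return a `vm_pca`: `coordinates` (panel x k, rownames = panel),
#'   `explained_variance_ratio`, `n_variants_used`,
#'   `variants_excluded_by_filter`.
#' @export
run_pca <- function(ds, region, panel = NULL, criteria = NULL, k = 2L,
                    max_variants = 10000L, ann = NULL) {
  panel <- vm_check_panel(ds, panel)
  if (length(panel) < 2L)
    vm_abort("analysis", "PCA needs a panel of at least 2 samples",
             n_samples = length(panel))
  cols <- vm_analysis_columns(ds, region, panel, criteria, ann)
  keep_idx <- which(cols$keep)
  if (length(keep_idx) > max_variants)
    keep_idx <- keep_idx[seq_len(max_variants)]  # left-most by position
  if (length(keep_idx) < 2L)
    vm_abort("analysis", sprintf(
      "PCA needs >= 2 usable variants, got %d (of %d in region, %d excluded by filter)",
      length(keep_idx), cols$slice$width, cols$excluded),
      n_variants = length(keep_idx), n_region = cols$slice$width,
      n_excluded = cols$excluded)
  d <- cols$slice$dosages[, keep_idx, drop = FALSE]
  x <- impute_missing(d)
  x <- sweep(x, 2L, colMeans(x))
  k <- min(as.integer(k), length(panel) - 1L, ncol(x))
  sv <- svd(x)
  # sign convention: largest-magnitude loading of each component positive
  for (j in seq_len(k)) {
    v <- sv$v[, j]
    s <- sign(v[which.max(abs(v))])
    if (s < 0) { sv$v[, j] <- -v; sv$u[, j] <- -sv$u[, j] }
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], nrow = k)
  rownames(scores) <- panel
  colnames(scores) <- paste0("PC", seq_len(k))
  evr <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  structure(list(
    coordinates = scores,
    explained_variance_ratio = evr,
    n_variants_used = length(keep_idx),
    variants_excluded_by_filter = cols$excluded
  ), class = "vm_pca")
}

#' @export
print.vm_pca <- function(x, ...) {
  cat("<vm_pca> ", nrow(x$coordinates), " samples x ",
      ncol(x$coordinates), " components; ", x$n_variants_used,
      " variants (", x$variants_excluded_by_filter, " filtered out)\n",
      "  explained variance ratio: ",
      paste(signif(x$explained_variance_ratio, 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Euclidean genetic distance to the reference genome
#'
#' The reference genome carries zero alternate alleles everywhere, so the
#' genetic distance of a sample is the Euclidean norm of its (imputed)
#' dosage vector: `sqrt(sum_j dosage_j^2)`.
#'
#' @param imputed numeric matrix from [impute_missing()] (samples x
#'   variants).
#' @return a named non-negative numeric vector, one entry per sample.
#' @export
distance_to_reference <- function(imputed) {
  sqrt(rowSums(imputed^2))
}

#' Order a sample panel alphabetically or by genetic distance
#'
#' Alphabetical modes sort case-insensitively, ties keeping the original
#' panel order. Distance mode sorts ascending by [distance_to_reference()]
#' computed over a region (variants without any called genotype are
#' excluded before imputation), ties broken by sample identifier.
#'
#' @param ds a `vm_dataset`.
#' @param panel sample panel (default: all samples).
#' @param mode one of `"alpha_asc"`, `"alpha_desc"`, `"distance"`.
#' @param region a [vm_region()]; required for distance mode.
#' @param ann annotation, for feature regions.
#' @return a `vm_ordering`: `order` (panel identifiers in sorted order),
#'   `key` (per-sample sort key, in sorted order), `mode`.
#' @export
sort_samples <- function(ds, panel = NULL,
                         mode = c("alpha_asc", "alpha_desc", "distance"),
                         region = NULL, ann = NULL) {
  mode <- match.arg(mode)
  panel <- vm_check_panel(ds, panel)
  if (mode %in% c("alpha_asc", "alpha_desc")) {
    key <- tolower(panel)
    rk <- xtfrm(key)
    ord <- if (mode == "alpha_asc") order(rk, seq_along(panel))
           else order(-rk, seq_along(panel))
    return(structure(list(order = panel[ord], key = key[ord], mode = mode),
                     class = "vm_ordering"))
  }
  if (is.null(region))
    vm_abort("argument", "distance mode requires a region")
  slice <- resolve_region(ds, region, panel, ann)
  usable <- integer(0)
  if (slice$width > 0L)
    usable <- which(colSums(slice$dosages != VM_MISSING) > 0L)
  if (length(usable) == 0L)
    vm_abort("analysis", "distance sorting needs a region with >= 1 usable variant",
             n_region = slice$width)
  x <- impute_missing(slice$dosages[, usable, drop = FALSE])
  dist <- distance_to_reference(x)
  ord <- order(dist, panel)
  structure(list(order = panel[ord], key = unname(dist[ord]), mode = mode),
            class = "vm_ordering")
}

#' @export
print.vm_ordering <- function(x, ...) {
  cat("<vm_ordering> mode=", x$mode, ": ",
      paste(utils::head(x$order, 5), collapse = ", "),
      if (length(x$order) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}
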