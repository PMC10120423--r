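# Ad hoc per-variant statistics over the currently selected genotype panel.
#
# Conventions (documented because the choice matters):
#  * alternate-allele frequency p and the heterozygosity fraction are
#    computed over CALLED genotypes only (n_called);
#  * the missing fraction is computed over the FULL panel;
#  * a variant with no called genotype has maf and het_fraction undefined,
#    surfaced as NA (and null in JSON payloads) - never as 0, because 0 is a
#    meaningful value for both statistics.

#' Compute per-variant statistics for a slice
#'
#' For every variant of the slice, over the slice's panel: the alternate
#' allele frequency `p = sum(dosage) / (ploidy * n_called)`, the folded minor
#' allele frequency `maf = min(p, 1 - p)`, the heterozygosity fraction
#' (dosage == 1 among called diploid genotypes; identically 0 for haploid
#' data), and the missing fraction (missing calls / panel size).
#'
#' @param slice a `vm_slice` with a non-empty panel.
#' @return a `vm_stats` object: a list of parallel vectors `maf`,
#'   `het_fraction`, `missing_fraction`, `n_called` (NA marks an undefined
#'   statistic).
#' @export
compute_stats <- function(slice) {
  stopifnot(inherits(slice, "vm_slice"))
  n_panel <- length(slice$panel)
  if (n_panel == 0L)
    vm_abort("argument", "panel must be non-empty for statistics")
  d <- slice$dosages
  called <- d != VM_MISSING
  n_called <- colSums(called)
  alt_sum <- colSums(d * called)
  p <- ifelse(n_called > 0L, alt_sum / (slice$ploidy * n_called), NA_real_)
  maf <- pmin(p, 1 - p)
  if (slice$ploidy == 2L) {
    het <- ifelse(n_called > 0L, colSums(d == 1L & called) / n_called,
                  NA_real_)
  } else {
    het <- ifelse(n_called > 0L, 0, NA_real_)
  }
  structure(list(
    maf = as.numeric(maf),
    het_fraction = as.numeric(het),
    # missing count / panel size: equals 1 - n_called/n_panel in exact
    # rational arithmetic, and bit-exact against integer-count oracles
    missing_fraction = as.numeric(colSums(!called) / n_panel),
    n_called = as.integer(n_called)
  ), class = "vm_stats")
}

#' @export
print.vm_stats <- function(x, ...) {
  cat("<vm_stats> ", length(x$maf), " variants; maf range [",
      if (all(is.na(x$maf))) "NA, NA" else
        paste(signif(range(x$maf, na.rm = TRUE), 3), collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

#' Recompute statistics for two panels over the same window
#'
#' Convenience wrapper demonstrating the panel dependence of the ad hoc
#' statistics: the same genomic window is sliced twice, once per panel, and
#' statistics are computed independently for each.
#'
#' @param ds a `vm_dataset`.
#' @param chromosome chromosome label.
#' @param start,end 1-based inclusive physical range.
#' @param panel_a,panel_b two non-empty sample panels.
#' @return a list with elements `a` and `b`, each a `vm_stats`.
#' @export
stats_for_panel_change <- function(ds, chromosome, start, end,
                                   panel_a, panel_b) {
  if (length(panel_a) == 0L || length(panel_b) == 0L)
    vm_abort("argument", "both panels must be non-empty")
  list(
    a = compute_stats(slice_by_range(ds, chromosome, start, end, panel_a)),
    b = compute_stats(slice_by_range(ds, chromosome, start, end, panel_b))
  )
}
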