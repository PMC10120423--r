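# Range filters over ad hoc statistics and VCF-derived variant attributes.
# All bounds are inclusive. A variant whose statistic is undefined (NA)
# fails any criterion set on that statistic, so all-missing variants can
# never leak into PCA or export through a filter.

#' Build a variant filter criteria object
#'
#' @param maf_range optional `c(lo, hi)` within `[0, 0.5]`.
#' @param het_range optional `c(lo, hi)` within `[0, 1]`.
#' @param missing_range optional `c(lo, hi)` within `[0, 1]`.
#' @param qual_min optional lower bound (inclusive) on the VCF QUAL value.
#' @param mq_min optional lower bound (inclusive) on INFO/MQ.
#' @return a `vm_criteria` object; with no argument set it selects every
#'   variant.
#' @export
filter_criteria <- function(maf_range = NULL, het_range = NULL,
                            missing_range = NULL, qual_min = NULL,
                            mq_min = NULL) {
  check_range <- function(r, name, lo_lim, hi_lim) {
    if (is.null(r)) return(NULL)
    r <- as.numeric(r)
    if (length(r) != 2L || anyNA(r))
      vm_abort("argument", sprintf("%s must be c(lo, hi)", name))
    if (r[1] > r[2])
      vm_abort("argument", sprintf("%s: lo (%s) > hi (%s)", name, r[1], r[2]))
    if (r[1] < lo_lim || r[2] > hi_lim)
      vm_abort("argument", sprintf("%s must lie within [%s, %s]",
                                   name, lo_lim, hi_lim))
    r
  }
  structure(list(
    maf_range = check_range(maf_range, "maf_range", 0, 0.5),
    het_range = check_range(het_range, "het_range", 0, 1),
    missing_range = check_range(missing_range, "missing_range", 0, 1),
    qual_min = if (is.null(qual_min)) NULL else as.numeric(qual_min),
    mq_min = if (is.null(mq_min)) NULL else as.numeric(mq_min)
  ), class = "vm_criteria")
}

# accept a vm_criteria or a plain list (e.g. deserialized JSON)
as_vm_criteria <- function(x) {
  if (is.null(x)) return(filter_criteria())
  if (inherits(x, "vm_criteria")) return(x)
  if (!is.list(x)) vm_abort("argument", "criteria must be a list")
  unknown <- setdiff(names(x), c("maf_range", "het_range", "missing_range",
                                 "qual_min", "mq_min"))
  if (length(unknown))
    vm_abort("argument", sprintf("unknown filter criteria: %s",
                                 paste(unknown, collapse = ", ")))
  do.call(filter_criteria, x)
}

#' Apply filter criteria to a slice's statistics
#'
#' @param stats a `vm_stats` for the variants under consideration.
#' @param index the matching `vm_slice` (or any list with parallel `qual`
#'   and `mq` vectors) covering the same variants.
#' @param criteria a [filter_criteria()] object (or a plain list of its
#'   fields, as deserialized from JSON).
#' @return a logical mask, one entry per variant; `TRUE` iff every set
#'   criterion holds. Variants with an undefined (NA) statistic fail any
#'   criterion on that statistic; variants without QUAL/MQ fail
#'   `qual_min`/`mq_min` only when that bound is set.
#' @export
apply_filter <- function(stats, index, criteria) {
  stopifnot(inherits(stats, "vm_stats"))
  criteria <- as_vm_criteria(criteria)
  n <- length(stats$maf)
  if (!is.null(index$qual) && length(index$qual) != n)
    vm_abort("argument", "stats and index cover different variant counts")
  mask <- rep(TRUE, n)
  in_range <- function(x, r) !is.na(x) & x >= r[1] & x <= r[2]
  if (!is.null(criteria$maf_range))
    mask <- mask & in_range(stats$maf, criteria$maf_range)
  if (!is.null(criteria$het_range))
    mask <- mask & in_range(stats$het_fraction, criteria$het_range)
  if (!is.null(criteria$missing_range))
    mask <- mask & in_range(stats$missing_fraction, criteria$missing_range)
  if (!is.null(criteria$qual_min))
    mask <- mask & !is.na(index$qual) & index$qual >= criteria$qual_min
  if (!is.null(criteria$mq_min))
    mask <- mask & !is.na(index$mq) & index$mq >= criteria$mq_min
  mask
}
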