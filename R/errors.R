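# Error taxonomy shared by the library, the JSON handler and the CLI.
# Every engine error is a classed condition "vm_<code>_error" so callers
# (and the HTTP facade) can map failures to machine-readable codes.

vm_error_codes <- c(
  "ploidy",   # unsupported or mixed ploidy at conversion time
  "ordering", # unsorted or duplicated positions within a chromosome
  "format",   # malformed VCF structure (e.g. missing GT)
  "lookup",   # unknown chromosome / feature id
  "panel",    # sample identifier not part of the dataset
  "argument", # invalid user arguments (ranges, criteria, counts)
  "analysis", # not enough data after filtering for PCA / sorting
  "mapping",  # chromosome label cannot be mapped between VCF and GFF3
  "parse",    # malformed GFF3 / YAML input
  "config",   # invalid configuration values
  "internal"  # contract violation inside the engine
)

vm_abort <- function(code, message, ..., call. = FALSE) {
  stopifnot(code %in% vm_error_codes)
  cond <- structure(
    class = c(paste0("vm_", code, "_error"), "vm_error", "error", "condition"),
    list(message = message, code = code, details = list(...))
  )
  stop(cond)
}

#' Extract the machine-readable code of an engine error
#'
#' @param cond a condition object raised by varmat.
#' @return a single string (one of the engine's error codes), or `"internal"`
#'   for conditions that did not originate in the engine.
#' @export
vm_error_code <- function(cond) {
  if (!is.null(cond$code)) cond$code else "internal"
}
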