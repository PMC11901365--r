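# Structured error conditions. Every reason-coded failure in the pipeline maps
# to one condition class so callers (and run_pipeline) can catch by reason.

ab_stop <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "ab_error")))
}

#' @keywords internal
ab_classes <- c(
  "ab_invalid_alphabet", "ab_unnumberable", "ab_grid_overflow",
  "ab_missing_region", "ab_unknown_residue", "ab_nonconvergence",
  "ab_degenerate_input", "ab_insufficient_data", "ab_degenerate_kernel",
  "ab_dimension_mismatch", "ab_degenerate_ellipse", "ab_insufficient_reference",
  "ab_empty_group", "ab_single_class", "ab_pad_mismatch",
  "ab_adapter_unavailable", "ab_unknown_index", "ab_parse_error",
  "ab_too_few_samples"
)
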