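#' @title Condition constructors
#' @description Classed conditions used across the package so callers can
#'   distinguish chemistry failures from configuration mistakes.
#' @name dckdesign-conditions
#' @keywords internal
NULL

# All package errors inherit from "dckdesign_error" so tests and CLIs can
# catch them as a family.
dck_error <- function(class, message, ...) {
  structure(
    class = c(class, "dckdesign_error", "error", "condition"),
    list(message = message, ...)
  )
}

stop_chemistry <- function(message, fragment_id = NULL) {
  stop(dck_error("ChemistryError", message, fragment_id = fragment_id))
}

stop_attachment <- function(message) {
  stop(dck_error("AttachmentError", message))
}

stop_empty_library <- function(message, failure_counts = NULL) {
  stop(dck_error("EmptyLibraryError", message, failure_counts = failure_counts))
}

stop_config <- function(message) {
  stop(dck_error("ConfigError", message))
}

stop_no_template_overlap <- function(message) {
  stop(dck_error("NoTemplateOverlapError", message))
}

stop_degenerate_alignment <- function(message) {
  stop(dck_error("DegenerateAlignmentError", message))
}

stop_embedding <- function(message) {
  stop(dck_error("EmbeddingError", message))
}

stop_no_transition <- function(message) {
  stop(dck_error("NoTransitionError", message))
}

stop_nonlinear_trace <- function(message) {
  stop(dck_error("NonLinearTraceError", message))
}

stop_fit <- function(message, diagnostics = NULL) {
  stop(dck_error("FitError", message, diagnostics = diagnostics))
}

stop_no_binding_signal <- function(message) {
  stop(dck_error("NoBindingSignalError", message))
}

stop_censored_value <- function(message) {
  stop(dck_error("CensoredValueError", message))
}

stop_ledger_integrity <- function(message) {
  stop(dck_error("LedgerIntegrityError", message))
}

stop_empty_input <- function(message) {
  stop(dck_error("EmptyInputError", message))
}

stop_empty_selection <- function(message) {
  stop(dck_error("EmptySelectionError", message))
}
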