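#' @title Structured error conditions
#' @description Every user-facing failure in eavflat is signalled as a classed
#'   condition so callers (and the CLI) can react programmatically. Classes:
#'   `eavflat_missing_column_error`, `eavflat_empty_event_error`,
#'   `eavflat_malformed_csv_error`, `eavflat_config_schema_error`,
#'   `eavflat_config_consistency_error`, `eavflat_unmapped_attribute_error`,
#'   `eavflat_duplicate_measurement_error`,
#'   `eavflat_missing_target_column_error`, `eavflat_missing_row_error`,
#'   `eavflat_cell_conflict_error`, `eavflat_duplicate_row_key_error`,
#'   `eavflat_unknown_field_error`, `eavflat_transport_error`,
#'   `eavflat_server_rejection_error`. All inherit from `eavflat_error`.
#' @name eavflat-conditions
#' @keywords internal
NULL

stop_eavflat <- function(class, message, ..., call. = FALSE) {
  cond <- errorCondition(
    message,
    ...,
    class = c(paste0("eavflat_", class), "eavflat_error")
  )
  stop(cond)
}

warn_eavflat <- function(class, message, ...) {
  cond <- warningCondition(
    message,
    ...,
    class = c(paste0("eavflat_", class), "eavflat_warning")
  )
  warning(cond)
}
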