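#' Entity-attribute-value tables
#'
#' Instrument exports carry one measurement per row: who (entity), on which
#' occasion (event), when (an opaque date string), which biomarker
#' (attribute), and the measured value. An `eav_table` is a data frame with
#' character columns `entity_id`, `event_id`, `date`, `attribute`, `value`,
#' in source-row order, plus attributes `source_columns` (the original
#' header) and `n_skipped` (blank rows dropped on read).
#'
#' Values are conserved byte-for-byte: no numeric parsing or reformatting
#' happens before validation, so `"6.50"` stays `"6.50"`. Identifiers are
#' trimmed of surrounding whitespace because they are join keys; values are
#' not trimmed.
#'
#' @param entity_id,event_id,date,attribute,value Character vectors of equal
#'   length.
#' @param source_columns Original header names of the source file.
#' @param n_skipped Number of blank rows skipped on read.
#' @return An object of classes `eav_table` and `data.frame`.
#' @export
eav_table <- function(entity_id = character(0), event_id = character(0),
                      date = character(0), attribute = character(0),
                      value = character(0),
                      source_columns = character(0), n_skipped = 0L) {
  df <- data.frame(entity_id = as.character(entity_id),
                   event_id = as.character(event_id),
                   date = as.character(date),
                   attribute = as.character(attribute),
                   value = as.character(value),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0L) {
    bad <- !nzchar(df$entity_id) | !nzchar(df$event_id) | !nzchar(df$attribute)
    if (any(bad)) {
      stop_eavflat("empty_event_error",
                   sprintf("record(s) %s have an empty entity, event or attribute",
                           paste(which(bad), collapse = ", ")))
    }
  }
  structure(df,
            source_columns = as.character(source_columns),
            n_skipped = as.integer(n_skipped),
            class = c("eav_table", "data.frame"))
}

#' Read an instrument EAV CSV export
#'
#' Reads a comma-separated file with a header row into an [eav_table()],
#' using `config` to find the entity, event, date, attribute and value
#' columns. Event columns are coalesced in the config's priority order: the
#' first non-empty cell on a row becomes its `event_id` (an instrument file
#' that splits scheduled visits and exacerbations across two columns leaves
#' one of them empty per row). Entirely blank rows are skipped and counted.
#'
#' @param source Path or connection to a CSV file (LF or CRLF, UTF-8).
#' @param config A [mapping_config()] whose bound columns all appear in the
#'   file header.
#' @param strict If `TRUE` (default), a data row whose event columns are all
#'   empty raises an `eavflat_empty_event_error`; if `FALSE` such rows are
#'   skipped with a warning.
#' @return An `eav_table`; records in source-row order.
#' @export
read_eav <- function(source, config, strict = TRUE) {
  stopifnot(inherits(config, "mapping_config"))
  df <- read_csv_strict(source)
  needed <- c(config$entity_column, config$event_columns,
              config$date_column, config$attribute_column, config$value_column)
  absent <- setdiff(needed, names(df))
  if (length(absent) > 0L) {
    stop_eavflat("missing_column_error",
                 sprintf("column(s) bound by the config are absent from the header: %s",
                         paste(absent, collapse = ", ")))
  }
  blank <- if (nrow(df) == 0L) logical(0) else
    apply(df, 1L, function(r) all(!nzchar(trimws_id(r))))
  n_skipped <- sum(blank)
  if (n_skipped > 0L) {
    message(sprintf("read_eav: skipped %d blank row(s)", n_skipped))
    df <- df[!blank, , drop = FALSE]
  }
  ev <- rep(NA_character_, nrow(df))
  for (col in config$event_columns) {
    cell <- trimws_id(df[[col]])
    take <- is.na(ev) & nzchar(cell)
    ev[take] <- cell[take]
  }
  if (anyNA(ev)) {
    rows <- which(is.na(ev))
    if (strict) {
      stop_eavflat("empty_event_error",
                   sprintf("data row(s) %s have no event in column(s) %s",
                           paste(rows, collapse = ", "),
                           paste(config$event_columns, collapse = ", ")))
    }
    warn_eavflat("empty_event_warning",
                 sprintf("skipping %d row(s) with no event token", length(rows)))
    df <- df[!is.na(ev), , drop = FALSE]
    n_skipped <- n_skipped + length(rows)
    ev <- ev[!is.na(ev)]
  }
  eav_table(
    entity_id = trimws_id(df[[config$entity_column]]),
    event_id = ev,
    date = if (is.null(config$date_column)) rep("", nrow(df)) else
      trimws_id(df[[config$date_column]]),
    attribute = trimws_id(df[[config$attribute_column]]),
    value = df[[config$value_column]],
    source_columns = names(df),
    n_skipped = n_skipped
  )
}

#' Write an EAV table back to the instrument CSV dialect
#'
#' Emits the table's original `source_columns` (header order preserved).
#' The event token is written into the first event column the config binds;
#' any other bound event columns, and unbound extra columns, are written
#' blank. Writing then re-reading with the same config reproduces an equal
#' `eav_table`. Output is deterministic: the same table always yields the
#' same bytes (LF line endings, minimal quoting).
#'
#' @param table An `eav_table`.
#' @param sink Path or writable connection.
#' @param config The [mapping_config()] naming the column roles.
#' @return `sink`, invisibly.
#' @export
write_eav <- function(table, sink, config) {
  stopifnot(inherits(table, "eav_table"), inherits(config, "mapping_config"))
  cols <- attr(table, "source_columns")
  if (length(cols) == 0L) {
    cols <- c(config$entity_column, config$event_columns,
              config$date_column, config$attribute_column, config$value_column)
  }
  out <- as.data.frame(
    matrix("", nrow = nrow(table), ncol = length(cols),
           dimnames = list(NULL, cols)),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  out[[config$entity_column]] <- table$entity_id
  out[[config$event_columns[[1L]]]] <- table$event_id
  if (!is.null(config$date_column)) out[[config$date_column]] <- table$date
  out[[config$attribute_column]] <- table$attribute
  out[[config$value_column]] <- table$value
  write_csv_lf(out, sink)
  invisible(sink)
}

#' @export
print.eav_table <- function(x, ...) {
  cat(sprintf("<eav_table> %d record(s), %d blank row(s) skipped on read\n",
              nrow(x), attr(x, "n_skipped") %||% 0L))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more\n")
  invisible(x)
}

eav_equal <- function(a, b) {
  isTRUE(all.equal(as.data.frame(a), as.data.frame(b), check.attributes = FALSE)) &&
    identical(attr(a, "source_columns"), attr(b, "source_columns"))
}
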