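#' Flat (wide) tables in the EDC import/export dialect
#'
#' A `flat_table` mirrors the CSV a longitudinal REDCap-style project
#' exports and imports: the first column is the record id, the second the
#' event name, and every remaining column one data field. Rows are keyed by
#' the (record id, event name) pair, which must be unique. All cells are
#' character; the empty string means blank.
#'
#' @param ids,events Character vectors: record ids and event names.
#' @param fields Data frame (or named list) of field columns, all character;
#'   may have zero columns.
#' @param id_column_name,event_column_name Header names of the two key
#'   columns.
#' @return An object of classes `flat_table` and `data.frame`; the key
#'   column names are stored in attributes `id_column_name` and
#'   `event_column_name`.
#' @export
flat_table <- function(ids = character(0), events = character(0),
                       fields = NULL,
                       id_column_name = "patient_id",
                       event_column_name = "redcap_event_name") {
  ids <- as.character(ids)
  events <- as.character(events)
  stopifnot(length(ids) == length(events))
  if (is.null(fields)) fields <- data.frame(row.names = seq_along(ids))
  fields <- as.data.frame(fields, stringsAsFactors = FALSE, check.names = FALSE,
                          row.names = NULL)
  if (nrow(fields) == 0L && length(ids) > 0L) {
    fields <- as.data.frame(
      matrix("", nrow = length(ids), ncol = ncol(fields),
             dimnames = list(NULL, names(fields))),
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  fields[] <- lapply(fields, as.character)
  key <- paste(ids, events, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop_eavflat("duplicate_row_key_error",
                 sprintf("duplicate (record id, event) row key: (%s)",
                         gsub("\r", ", ", dup, fixed = TRUE)))
  }
  df <- cbind(
    stats::setNames(data.frame(ids, events, stringsAsFactors = FALSE),
                    c(id_column_name, event_column_name)),
    fields
  )
  rownames(df) <- NULL
  structure(df,
            id_column_name = id_column_name,
            event_column_name = event_column_name,
            class = c("flat_table", "data.frame"))
}

#' Field (data) columns of a flat table
#' @param table A `flat_table`.
#' @return Character vector of field column names (header minus the two key
#'   columns).
#' @export
field_columns <- function(table) {
  stopifnot(inherits(table, "flat_table"))
  names(table)[-(1:2)]
}

#' Read a flat-table CSV (EDC export or import file)
#'
#' The first two header columns are taken as record id and event name; all
#' remaining columns are field columns. Blank cells become empty strings.
#' Duplicate (id, event) keys raise `eavflat_duplicate_row_key_error`.
#'
#' @param source Path or connection to the CSV file.
#' @return A [flat_table()].
#' @export
read_flat <- function(source) {
  df <- read_csv_strict(source)
  if (ncol(df) < 2L) {
    stop_eavflat("malformed_csv_error",
                 "a flat table needs at least record-id and event-name columns")
  }
  flat_table(
    ids = trimws_id(df[[1L]]),
    events = trimws_id(df[[2L]]),
    fields = df[-(1:2)],
    id_column_name = names(df)[[1L]],
    event_column_name = names(df)[[2L]]
  )
}

#' Write a flat table as an EDC import CSV
#'
#' Header is `[id column, event column, field columns...]`; blanks are
#' written as empty fields; LF line endings and minimal quoting, so a
#' template read with [read_flat()] and written back unchanged is
#' byte-identical to its source. `read_flat(write_flat(t))` equals `t`.
#'
#' @param table A `flat_table`.
#' @param sink Path or writable connection.
#' @return `sink`, invisibly.
#' @export
write_flat <- function(table, sink) {
  stopifnot(inherits(table, "flat_table"))
  write_csv_lf(as.data.frame(table), sink)
  invisible(sink)
}

flat_to_chr <- function(table) {
  # canonical byte representation used by both write_flat and the API client
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  write_csv_lf(as.data.frame(table), con)
  rawToChar(rawConnectionValue(con))
}

row_key_index <- function(table, entity, event) {
  which(table[[1L]] == entity & table[[2L]] == event)
}

#' @export
print.flat_table <- function(x, ...) {
  cat(sprintf("<flat_table> %d row(s) x %d field column(s) [keys: %s, %s]\n",
              nrow(x), length(field_columns(x)),
              attr(x, "id_column_name"), attr(x, "event_column_name")))
  filled <- if (nrow(x) == 0L || ncol(x) <= 2L) 0L else
    sum(nzchar(as.matrix(x[-(1:2)])))
  cat(sprintf("  %d non-empty data cell(s)\n", filled))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}
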