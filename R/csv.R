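# Shared CSV plumbing. Parsing is delegated to utils::read.csv after a
# structural pre-check (unbalanced quotes, ragged rows). Writing uses a
# minimal-quoting RFC-4180 serializer so that a template read and re-written
# unchanged is byte-identical to its source: cells are quoted only when they
# contain a comma, a double quote or a line break. LF line endings, UTF-8.

read_csv_strict <- function(source) {
  lines <- tryCatch(
    readLines(source, warn = FALSE, encoding = "UTF-8"),
    error = function(e) {
      stop_eavflat("malformed_csv_error", paste0("cannot read CSV: ", conditionMessage(e)))
    }
  )
  if (length(lines) == 0L) {
    stop_eavflat("malformed_csv_error", "empty file: a header row is required")
  }
  fields <- tryCatch(
    utils::count.fields(textConnection(lines), sep = ",", quote = "\"",
                        blank.lines.skip = FALSE),
    error = function(e) {
      stop_eavflat("malformed_csv_error", paste0("unparseable CSV: ", conditionMessage(e)))
    }
  )
  # count.fields reports NA for a row whose quoted field spans onto the next
  # physical line; such multi-line fields are balanced iff the *next* count
  # resumes. An NA on the final line means an unterminated quote.
  if (length(fields) > 0L && is.na(fields[length(fields)])) {
    stop_eavflat("malformed_csv_error", "unbalanced quotes in CSV input")
  }
  widths <- fields[!is.na(fields)]
  # rows of width 0 are blank physical lines; they are skipped downstream
  if (length(unique(widths[widths > 0L])) > 1L) {
    stop_eavflat("malformed_csv_error",
                 sprintf("ragged CSV: rows have %s fields",
                         paste(sort(unique(widths)), collapse = ", ")))
  }
  df <- utils::read.csv(textConnection(lines), colClasses = "character",
                        check.names = FALSE, blank.lines.skip = FALSE,
                        na.strings = character(0))
  df
}

csv_quote_cell <- function(x) {
  needs <- grepl('[",\n\r]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs], fixed = TRUE), '"')
  x
}

csv_format_rows <- function(df) {
  header <- paste(csv_quote_cell(names(df)), collapse = ",")
  if (nrow(df) == 0L) return(header)
  cells <- vapply(df, function(col) csv_quote_cell(as.character(col)),
                  character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  body <- apply(cells, 1L, paste, collapse = ",")
  c(header, body)
}

write_csv_lf <- function(df, sink) {
  lines <- csv_format_rows(df)
  tryCatch({
    con <- if (inherits(sink, "connection")) sink else file(sink, open = "wb")
    if (!inherits(sink, "connection")) on.exit(close(con), add = TRUE)
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  }, error = function(e) {
    stop_eavflat("io_error", paste0("cannot write CSV: ", conditionMessage(e)))
  })
  invisible(NULL)
}

trimws_id <- function(x) trimws(x, which = "both")
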