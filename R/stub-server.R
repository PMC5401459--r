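#' Minimal local record-import stub server
#'
#' A single-purpose HTTP endpoint emulating the record-import call of a
#' REDCap-style web API, used to test [import_records()] hermetically: it
#' binds a loopback port, accepts form-encoded POSTs with fields `token`,
#' `content`, `format` and `data`, counts the CSV data rows, and answers
#' with JSON `{"count": n}`. It exists for tests and demos only and
#' implements nothing beyond that one call.
#'
#' Behaviour knobs: a wrong token gets HTTP 403 `{"error": ...}`; when
#' `reject_event` is set, any data row whose second CSV field equals it gets
#' the whole batch rejected with HTTP 400, an explanatory `error` message
#' and `count` = number of acceptable rows. The raw `data` payload of the
#' last request is written to `capture_file` so tests can compare it
#' byte-for-byte with [write_flat()] output.
#'
#' The function blocks while serving; run it in a background process (the
#' test suite uses `callr::r_bg()`). The port actually bound is written as
#' a single line to `port_file` once the socket is listening.
#'
#' @param port_file Path the chosen port number is written to.
#' @param expected_token Token the stub requires.
#' @param capture_file Optional path; the last request's decoded CSV payload
#'   is written here verbatim.
#' @param reject_event Optional event name whose presence rejects a batch.
#' @param max_requests Serve this many requests, then return.
#' @param port Port to bind, or 0 to probe for a free one.
#' @return Invisibly, the number of requests served.
#' @export
stub_server_run <- function(port_file, expected_token = "stub-token",
                            capture_file = NULL, reject_event = NULL,
                            max_requests = 32L, port = 0L) {
  srv <- NULL
  if (port > 0L) {
    srv <- serverSocket(port)
  } else {
    for (p in sample(20000:40000, 50L)) {
      srv <- tryCatch(serverSocket(p), error = function(e) NULL)
      if (!is.null(srv)) { port <- p; break }
    }
    if (is.null(srv)) stop("stub: no free port found")
  }
  on.exit(close(srv), add = TRUE)
  writeLines(as.character(port), port_file)
  served <- 0L
  while (served < max_requests) {
    socketSelect(list(srv))
    con <- socketAccept(srv, blocking = FALSE, open = "r+b")
    req <- tryCatch(stub_read_request(con), error = function(e) NULL)
    if (!is.null(req)) {
      fields <- stub_parse_form(req$body)
      resp <- stub_respond(fields, expected_token, reject_event, capture_file)
      writeBin(charToRaw(paste0("HTTP/1.1 ", resp$status, "\r\n",
                                "Content-Type: application/json\r\n",
                                "Content-Length: ", nchar(resp$body, type = "bytes"), "\r\n",
                                "Connection: close\r\n\r\n",
                                resp$body)),
               con)
      flush(con)
      served <- served + 1L
    }
    close(con)
  }
  invisible(served)
}

stub_read_avail <- function(con, n = 65536L, timeout = 10) {
  # non-blocking socket: wait for readability, then take what is there
  if (!socketSelect(list(con), timeout = timeout)) return(raw(0))
  readBin(con, what = "raw", n = n)
}

stub_read_request <- function(con) {
  head_raw <- raw(0)
  while (!length(grepRaw("\r\n\r\n", head_raw))) {
    chunk <- stub_read_avail(con)
    if (length(chunk) == 0L) break
    head_raw <- c(head_raw, chunk)
  }
  split_at <- grepRaw("\r\n\r\n", head_raw)[1]
  if (is.na(split_at)) stop("incomplete request")
  header_txt <- rawToChar(head_raw[seq_len(split_at - 1L)])
  body <- head_raw[-seq_len(split_at + 3L)]
  len_line <- grep("^content-length:", strsplit(header_txt, "\r\n")[[1]],
                   ignore.case = TRUE, value = TRUE)
  clen <- if (length(len_line)) as.integer(trimws(sub("^[^:]+:", "", len_line[1]))) else 0L
  while (length(body) < clen) {
    chunk <- stub_read_avail(con)
    if (length(chunk) == 0L) break
    body <- c(body, chunk)
  }
  list(header = header_txt, body = rawToChar(body))
}

stub_parse_form <- function(body) {
  pairs <- strsplit(body, "&", fixed = TRUE)[[1]]
  kv <- strsplit(pairs, "=", fixed = TRUE)
  vals <- vapply(kv, function(p) {
    if (length(p) < 2L) "" else utils::URLdecode(chartr("+", " ", paste(p[-1L], collapse = "=")))
  }, character(1))
  names(vals) <- vapply(kv, `[[`, character(1), 1L)
  vals
}

stub_respond <- function(fields, expected_token, reject_event, capture_file) {
  if (!identical(unname(fields["token"]), expected_token)) {
    return(list(status = "403 Forbidden",
                body = jsonlite::toJSON(list(error = "invalid token"), auto_unbox = TRUE)))
  }
  if (!identical(unname(fields["content"]), "record") ||
      !identical(unname(fields["format"]), "csv")) {
    return(list(status = "400 Bad Request",
                body = jsonlite::toJSON(list(error = "unsupported content or format"),
                                        auto_unbox = TRUE)))
  }
  data <- unname(fields["data"])
  if (is.na(data)) data <- ""
  if (!is.null(capture_file)) {
    con <- file(capture_file, open = "wb")
    writeChar(data, con, eos = NULL)
    close(con)
  }
  lines <- strsplit(data, "\n", fixed = TRUE)[[1]]
  body_lines <- if (length(lines) > 1L) lines[-1L] else character(0)
  body_lines <- body_lines[nzchar(body_lines)]
  events <- vapply(strsplit(body_lines, ",", fixed = TRUE), function(f) {
    if (length(f) >= 2L) f[[2L]] else ""
  }, character(1))
  if (!is.null(reject_event) && any(events == reject_event)) {
    n_ok <- sum(events != reject_event)
    return(list(status = "400 Bad Request",
                body = jsonlite::toJSON(
                  list(error = sprintf("event '%s' is not defined in this project", reject_event),
                       count = n_ok),
                  auto_unbox = TRUE)))
  }
  list(status = "200 OK",
       body = jsonlite::toJSON(list(count = length(body_lines)), auto_unbox = TRUE))
}
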