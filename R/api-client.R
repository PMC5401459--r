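#' Push a flat table to a REDCap-compatible record-import API
#'
#' Serializes the table through the same writer as [write_flat()] (the
#' payload posted is byte-identical to the CSV file) and submits it as one
#' form-encoded HTTP POST with the de-facto record-import fields:
#' `token`, `content=record`, `format=csv`, `data=<csv payload>`.
#'
#' Transport failures (connection refused, timeouts, HTTP-level transport
#' errors) are retried up to `max_attempts` times with exponential backoff
#' (`backoff`, `2*backoff`, ...); after the last attempt an
#' `eavflat_transport_error` is raised. A reachable server that rejects the
#' import yields an `ImportResult` with `success = FALSE` and the server's
#' messages verbatim (or, with `strict = TRUE`, an
#' `eavflat_server_rejection_error`). The token never appears in logs,
#' messages or error conditions.
#'
#' An empty table sends no request and returns a successful result with
#' `n_submitted = 0`.
#'
#' @param endpoint URL of the record-import endpoint.
#' @param token API token (secret). Prefer sourcing it from an environment
#'   variable or a token file rather than a shell argument.
#' @param table A [flat_table()], normally validated with [validate_flat()]
#'   first.
#' @param strict If `TRUE`, a server rejection raises an error instead of
#'   returning `success = FALSE`.
#' @param max_attempts Transport retry budget (default 3).
#' @param backoff Initial backoff in seconds (default 0.5; doubled per
#'   retry).
#' @param timeout Per-request timeout in seconds.
#' @return An `import_result`: list with `n_submitted`, `n_accepted`,
#'   `server_messages`, `success`.
#' @export
import_records <- function(endpoint, token, table, strict = FALSE,
                           max_attempts = 3L, backoff = 0.5, timeout = 30) {
  stopifnot(inherits(table, "flat_table"))
  if (!nzchar(token)) {
    stop_eavflat("config_schema_error", "API token must be non-empty")
  }
  if (nrow(table) == 0L) {
    return(import_result(0L, 0L, character(0), TRUE))
  }
  payload <- flat_to_chr(table)
  form <- paste(
    c(paste0("token=", curl::curl_escape(token)),
      "content=record",
      "format=csv",
      paste0("data=", curl::curl_escape(payload))),
    collapse = "&")
  resp <- NULL
  for (attempt in seq_len(max_attempts)) {
    h <- curl::new_handle(
      post = TRUE, postfields = form,
      timeout = timeout,
      httpheader = "Content-Type: application/x-www-form-urlencoded"
    )
    resp <- tryCatch(curl::curl_fetch_memory(endpoint, handle = h),
                     error = function(e) e)
    if (!inherits(resp, "error")) break
    if (attempt < max_attempts) Sys.sleep(backoff * 2^(attempt - 1L))
  }
  if (inherits(resp, "error")) {
    stop_eavflat("transport_error",
                 sprintf("import failed after %d attempt(s): %s",
                         max_attempts, redact(conditionMessage(resp), token)))
  }
  body <- rawToChar(resp$content)
  parsed <- tryCatch(jsonlite::fromJSON(body), error = function(e) NULL)
  n_sub <- nrow(table)
  if (resp$status_code >= 200L && resp$status_code < 300L) {
    n_acc <- if (!is.null(parsed$count)) as.integer(parsed$count) else n_sub
    msgs <- if (!is.null(parsed$message)) as.character(parsed$message) else character(0)
    res <- import_result(n_sub, n_acc, msgs, n_acc == n_sub)
  } else {
    msgs <- if (!is.null(parsed$error)) as.character(parsed$error) else redact(body, token)
    n_acc <- if (!is.null(parsed$count)) as.integer(parsed$count) else 0L
    res <- import_result(n_sub, n_acc, msgs, FALSE)
  }
  if (strict && !res$success) {
    stop_eavflat("server_rejection_error",
                 sprintf("server rejected the import (%d/%d accepted): %s",
                         res$n_accepted, res$n_submitted,
                         redact(paste(res$server_messages, collapse = "; "), token)))
  }
  res
}

import_result <- function(n_submitted, n_accepted, server_messages, success) {
  stopifnot(!success || n_accepted == n_submitted)
  structure(list(n_submitted = as.integer(n_submitted),
                 n_accepted = as.integer(n_accepted),
                 server_messages = as.character(server_messages),
                 success = isTRUE(success)),
            class = "import_result")
}

redact <- function(text, token) {
  gsub(token, "<redacted>", text, fixed = TRUE)
}

#' @export
print.import_result <- function(x, ...) {
  cat(sprintf("<import_result> %s: %d/%d row(s) accepted\n",
              if (x$success) "success" else "REJECTED",
              x$n_accepted, x$n_submitted))
  for (m in x$server_messages) cat("  server:", m, "\n")
  invisible(x)
}

#' Read an API token from a file or environment variable
#'
#' Tokens are clinical credentials: they should come from a file or the
#' `EAVFLAT_TOKEN` environment variable, never a bare shell argument. The
#' first non-empty line of `token_file` wins; the environment variable is
#' the fallback.
#'
#' @param token_file Optional path to a file whose first line is the token.
#' @return The token string.
#' @export
read_token <- function(token_file = NULL) {
  if (!is.null(token_file) && nzchar(token_file)) {
    lines <- readLines(token_file, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      stop_eavflat("config_schema_error", "token file is empty")
    }
    return(trimws(lines[[1L]]))
  }
  tok <- Sys.getenv("EAVFLAT_TOKEN", "")
  if (!nzchar(tok)) {
    stop_eavflat("config_schema_error",
                 "no token: set EAVFLAT_TOKEN or pass --token-file")
  }
  tok
}
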