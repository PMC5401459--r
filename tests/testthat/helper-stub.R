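# Launch the bundled record-import stub on a loopback port in a background
# R process; returns handle, base URL and the payload capture file.
start_stub <- function(expected_token = "stub-token", reject_event = NULL,
                       max_requests = 16L) {
  port_file <- tempfile("stub-port-")
  capture_file <- tempfile("stub-capture-")
  bg <- callr::r_bg(
    function(pf, tok, cap, rej, mx) {
      eavflat::stub_server_run(pf, expected_token = tok, capture_file = cap,
                               reject_event = rej, max_requests = mx)
    },
    args = list(pf = port_file, tok = expected_token, cap = capture_file,
                rej = reject_event, mx = max_requests),
    package = FALSE
  )
  for (i in 1:200) {
    if (file.exists(port_file) && length(readLines(port_file, warn = FALSE)) > 0L) break
    if (!bg$is_alive()) stop("stub server died: ", bg$read_all_error())
    Sys.sleep(0.05)
  }
  port <- readLines(port_file, warn = FALSE)[[1L]]
  list(bg = bg, url = sprintf("http://127.0.0.1:%s/api/", port),
       capture_file = capture_file)
}

stop_stub <- function(stub) {
  if (stub$bg$is_alive()) stub$bg$kill()
  invisible(NULL)
}

read_file_bytes <- function(path) {
  readChar(path, file.size(path), useBytes = TRUE)
}
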