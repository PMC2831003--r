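# Minimal HTTP/1.0 front end over the in-process resolver, so the tool can
# be served from a shell.  Single-threaded, GET-oriented, no keep-alive; the
# resolver itself carries the whole resource contract and is what the test
# suite exercises.

#' Format a resource response as an HTTP/1.0 message
#'
#' @param response A `resource_response` from [resolve()].
#' @return Character scalar containing status line, headers and body.
#' @export
format_http_response <- function(response) {
  reason <- c(`200` = "OK", `404` = "Not Found", `405` = "Method Not Allowed",
              `406` = "Not Acceptable")[[as.character(response$status)]]
  sprintf("HTTP/1.0 %d %s\r\nContent-Type: %s\r\nContent-Length: %d\r\nConnection: close\r\n\r\n%s",
          response$status, reason, response$media_type,
          nchar(response$body, type = "bytes"), response$body)
}

accept_to_format <- function(accept) {
  if (is.null(accept)) return(NULL)
  if (grepl("application/xml|text/xml", accept)) "xml"
  else if (grepl("application/json", accept)) "json"
  else if (grepl("text/plain", accept)) "fasta"
  else NULL
}

#' Serve a dataset over HTTP
#'
#' Blocking single-threaded loop answering GET requests via [resolve()].
#'
#' @param dataset A `mir_dataset` with plugins registered.
#' @param port TCP port.
#' @param max_requests Stop after this many requests (default: run forever).
#' @return Number of requests served, invisibly.
#' @export
serve <- function(dataset, port = 4567L, max_requests = Inf) {
  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  mirkit_log("info", sprintf("serving on port %d", port))
  n <- 0
  while (n < max_requests) {
    con <- socketAccept(srv, blocking = TRUE, open = "r+b")
    req <- tryCatch({
      request_line <- readLines(con, n = 1L, warn = FALSE)
      headers <- character()
      repeat {
        h <- readLines(con, n = 1L, warn = FALSE)
        if (length(h) == 0L || !nzchar(h)) break
        headers <- c(headers, h)
      }
      parts <- strsplit(request_line, " ", fixed = TRUE)[[1]]
      accept <- sub("^[Aa]ccept:\\s*", "",
                    grep("^[Aa]ccept:", headers, value = TRUE)[1])
      list(method = parts[[1]], path = parts[[2]],
           format = accept_to_format(if (is.na(accept)) NULL else accept))
    }, error = function(e) NULL)
    resp <- if (is.null(req)) {
      resource_response(404L, "text/plain", "404 unreadable request\n")
    } else {
      tryCatch(resolve(dataset, req$method, req$path, format = req$format),
               error = function(e) resource_response(
                 404L, "text/plain", sprintf("404 %s\n", conditionMessage(e))))
    }
    writeChar(format_http_response(resp), con, eos = NULL)
    close(con)
    n <- n + 1
  }
  invisible(n)
}
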