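# The in-process request resolver: maps (HTTP verb, path, negotiated format)
# onto the data model and renders a response.  Every outcome is a status code
# (200/404/405/406), never an unhandled failure; GET is the only verb.
# Format negotiation: path suffix (.xml/.fasta/.html/.json) is primary, the
# `format` argument (Accept-header equivalent) is the fallback, HTML the
# default; on conflict the suffix wins.

MEDIA_TYPES <- c(html = "text/html", xml = "application/xml",
                 fasta = "text/plain", json = "application/json",
                 txt = "text/plain")

resource_response <- function(status, media_type, body) {
  structure(list(status = status, media_type = media_type, body = body),
            class = "resource_response")
}

#' @export
print.resource_response <- function(x, ...) {
  cat(sprintf("<resource_response %d %s, %d bytes>\n", x$status, x$media_type,
              nchar(x$body, type = "bytes")))
  invisible(x)
}

response_404 <- function(what) resource_response(
  404L, "text/plain", sprintf("404 not found: %s\n", what))

split_query <- function(path) {
  qpos <- regexpr("?", path, fixed = TRUE)
  if (qpos < 0L) return(list(path = path, query = list()))
  raw <- substr(path, qpos + 1L, nchar(path))
  path <- substr(path, 1L, qpos - 1L)
  kv <- strsplit(strsplit(raw, "&", fixed = TRUE)[[1]], "=", fixed = TRUE)
  query <- stats::setNames(
    lapply(kv, function(p) utils::URLdecode(p[2] %||% "")),
    vapply(kv, `[[`, "", 1))
  list(path = path, query = query)
}

split_format <- function(segment) {
  m <- regmatches(segment,
                  regexec("^(.*)\\.(html|xml|fasta|json|txt)$", segment))[[1]]
  if (length(m) == 3L) list(segment = m[[2]], format = m[[3]])
  else list(segment = segment, format = NULL)
}

paginate <- function(ents, query) {
  per_page <- query$per_page %||% "100"
  if (identical(per_page, "all")) return(ents)
  per_page <- max(1L, suppressWarnings(as.integer(per_page)))
  if (is.na(per_page)) per_page <- 100L
  page <- suppressWarnings(as.integer(query$page %||% "1"))
  if (is.na(page) || page < 1L) page <- 1L
  lo <- (page - 1L) * per_page + 1L
  if (lo > length(ents)) return(list())
  ents[lo:min(length(ents), lo + per_page - 1L)]
}

render_as <- function(x, format, kind, ds) {
  body <- switch(format,
    xml = render_xml(x, kind = kind, dataset = ds),
    json = render_json(x, kind = kind, dataset = ds),
    fasta = render_fasta(x),
    html = render_html(x, kind = kind, dataset = ds))
  resource_response(200L, unname(MEDIA_TYPES[[format]]), body)
}

#' Resolve a request against the dataset
#'
#' Understands collection paths (`/precursors`), member paths
#' (`/precursors/hsa-mir-21`), nested association paths
#' (`/precursors/hsa-mir-21/matures`), the route listing
#' (`/described_routes.txt` / `.xml`), a format suffix on the last segment,
#' percent-encoded identifiers, and `page` / `per_page` query parameters on
#' collections (`per_page=all` disables paging).
#'
#' @param dataset A `mir_dataset` (with any plugins already registered).
#' @param method HTTP verb; anything but `"GET"` yields 405.
#' @param path Request path, optionally with format suffix and query string.
#' @param format Fallback representation when the path has no suffix
#'   (`"html"`, `"xml"`, `"fasta"`, `"json"`); the suffix wins on conflict.
#' @return A `resource_response` (`status`, `media_type`, `body`).
#' @export
resolve <- function(dataset, method, path, format = NULL) {
  if (!identical(toupper(method), "GET")) {
    return(resource_response(405L, "text/plain",
                             "405 method not allowed: resources are read-only\n"))
  }
  pq <- split_query(path)
  segments <- strsplit(sub("^/", "", pq$path), "/", fixed = TRUE)[[1]]
  segments <- segments[nzchar(segments)]

  if (length(segments) == 0L) {
    kinds <- vapply(dataset$kinds, `[[`, "", "plural")
    body <- paste0("<!DOCTYPE html>\n<html><body><h1>release ",
                   html_escape(dataset$release_version), "</h1>\n<ul>\n",
                   paste(sprintf('<li><a href="/%s">%s</a></li>',
                                 kinds, kinds), collapse = "\n"),
                   "\n</ul></body></html>\n")
    return(resource_response(200L, "text/html", body))
  }

  sf <- split_format(segments[[length(segments)]])
  segments[[length(segments)]] <- sf$segment
  fmt <- sf$format %||% format %||% "html"

  if (identical(segments, "described_routes")) {
    if (!fmt %in% c("txt", "xml", "html"))
      return(resource_response(406L, "text/plain",
                               "406 not acceptable for described_routes\n"))
    if (fmt == "html") fmt <- "txt"
    body <- described_routes(dataset, format = fmt)
    if (fmt == "txt") body <- paste0(body, "\n")
    return(resource_response(200L, unname(MEDIA_TYPES[[fmt]]), body))
  }
  if (!fmt %in% c("html", "xml", "fasta", "json")) {
    return(resource_response(406L, "text/plain",
                             sprintf("406 unknown representation '%s'\n", fmt)))
  }

  kind <- kind_for_plural(dataset, segments[[1]])
  if (is.null(kind)) return(response_404(pq$path))

  answer <- function(x, target_kind, collection) {
    if (!fmt %in% representations_for_kind(dataset, target_kind)) {
      return(resource_response(406L, "text/plain", sprintf(
        "406 %s is not renderable as %s\n", target_kind, fmt)))
    }
    if (collection) x <- paginate(x, pq$query)
    render_as(x, fmt, target_kind, dataset)
  }

  if (length(segments) == 1L) {
    return(answer(list_entities(dataset, kind), kind, collection = TRUE))
  }

  id <- decode_segment(segments[[2]])
  entity <- tryCatch(get_entity(dataset, kind, id),
                     mirkit_not_found = function(e) NULL)
  if (is.null(entity)) return(response_404(pq$path))

  if (length(segments) == 2L) {
    return(answer(entity, kind, collection = FALSE))
  }
  if (length(segments) > 3L) return(response_404(pq$path))

  assoc <- dataset$associations[[assoc_key(kind, segments[[3]])]]
  if (is.null(assoc)) return(response_404(pq$path))
  res <- traverse(entity, segments[[3]])
  if (assoc$cardinality == "one") {
    if (is.null(res)) return(response_404(
      sprintf("%s (no linked %s)", pq$path, assoc$name)))
    return(answer(res, assoc$target_kind, collection = FALSE))
  }
  answer(res, assoc$target_kind, collection = TRUE)
}
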