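# Representation renderers.  XML is the machine contract: element name =
# singular kind, one child per public attribute, associations as <link>
# elements carrying the nested resource path (never embedded objects), lists
# wrapped in a plural root with a count attribute.  parse(render_xml(e))
# recovers every attribute verbatim.

entity_attributes <- function(entity) {
  ds <- attr(entity, "dataset")
  attrs <- ds$kinds[[entity_kind(entity)]]$attributes
  vals <- lapply(attrs, function(a) {
    v <- entity[[a]]
    if (is.null(v) || length(v) == 0L || is.na(v)) "" else as.character(v)
  })
  stats::setNames(vals, attrs)
}

# Associations embedded in a document are those declared by the entity
# kind's own provenance (core for core kinds, the owning plugin for plugin
# kinds).  Plugin-registered associations on core kinds still resolve and
# are listed by described_routes, but are not injected into core documents,
# so core representations are byte-stable under plugin activation.
entity_links <- function(entity) {
  ds <- attr(entity, "dataset")
  kind_plugin <- ds$kinds[[entity_kind(entity)]]$plugin
  assocs <- associations_of(ds, entity_kind(entity))
  assocs <- assocs[vapply(assocs, function(a)
    identical(a$plugin, kind_plugin), logical(1))]
  nms <- vapply(assocs, `[[`, "", "name")
  hrefs <- vapply(nms, function(n) route_for(n, nested_under = entity), "")
  stats::setNames(hrefs, nms)
}

xml_entity_node <- function(parent, entity) {
  kind <- entity_kind(entity)
  node <- if (is.null(parent)) xml2::xml_new_root(kind)
          else xml2::xml_add_child(parent, kind)
  xml2::xml_set_attr(node, "href", route_for(entity))
  for (a in names(attrs <- entity_attributes(entity))) {
    xml2::xml_add_child(node, a, attrs[[a]])
  }
  links <- entity_links(entity)
  for (n in names(links)) {
    xml2::xml_add_child(node, "link", rel = n, href = links[[n]])
  }
  node
}

collection_root_name <- function(x, kind = NULL) {
  if (!is.null(kind)) return(kind)
  if (length(x)) return(entity_kind(x[[1]]))
  "collection"
}

#' Render an entity or collection as XML
#'
#' @param x A `mir_entity` or a list of them.
#' @param kind Kind of the collection elements (needed only for an empty
#'   list with a known kind; plural root naming falls back to
#'   `"collection"`).
#' @param dataset Dataset, required for an empty collection of a named kind.
#' @return XML document as a character scalar.
#' @export
render_xml <- function(x, kind = NULL, dataset = NULL) {
  if (inherits(x, "mir_entity")) {
    return(as.character(xml_entity_node(NULL, x)))
  }
  ds <- dataset %||% (if (length(x)) attr(x[[1]], "dataset"))
  root_kind <- collection_root_name(x, kind)
  root_name <- if (!is.null(ds) && !is.null(ds$kinds[[root_kind]]))
    ds$kinds[[root_kind]]$plural else root_kind
  doc <- xml2::xml_new_root(root_name, count = as.character(length(x)))
  for (e in x) xml_entity_node(doc, e)
  as.character(doc)
}

#' Render sequence-bearing entities as FASTA
#'
#' One record per entity: header `">name accession"`, sequence on a single
#' line, collection order preserved.
#'
#' @param x A `mir_entity` with a sequence, or a list of them.
#' @return FASTA text (character scalar).
#' @export
render_fasta <- function(x) {
  if (inherits(x, "mir_entity")) x <- list(x)
  recs <- vapply(x, function(e) {
    if (is.null(e$sequence) || is.na(e$sequence) || !nzchar(e$sequence) ||
        is.null(e$accession)) {
      mirkit_error("mirkit_not_sequence_bearing", sprintf(
        "%s entities carry no renderable sequence", entity_kind(e)))
    }
    sprintf(">%s %s\n%s", e$name, e$accession, e$sequence)
  }, "")
  paste0(paste(recs, collapse = "\n"), "\n")
}

#' Render an entity or collection as JSON
#'
#' @inheritParams render_xml
#' @return JSON text.
#' @export
render_json <- function(x, kind = NULL, dataset = NULL) {
  one <- function(e) c(entity_attributes(e),
                       list(`_links` = as.list(entity_links(e)),
                            `_href` = route_for(e)))
  body <- if (inherits(x, "mir_entity")) one(x) else lapply(x, one)
  jsonlite::toJSON(body, auto_unbox = TRUE, pretty = TRUE)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render an entity or collection as minimal HTML
#'
#' An attribute table plus association links for members; a link list for
#' collections.  Visual design is deliberately out of scope.
#'
#' @inheritParams render_xml
#' @return HTML text.
#' @export
render_html <- function(x, kind = NULL, dataset = NULL) {
  page <- function(title, body) sprintf(
    "<!DOCTYPE html>\n<html><head><title>%s</title></head>\n<body>\n<h1>%s</h1>\n%s\n</body></html>\n",
    html_escape(title), html_escape(title), body)
  if (inherits(x, "mir_entity")) {
    attrs <- entity_attributes(x)
    rows <- paste(sprintf("<tr><th>%s</th><td>%s</td></tr>",
                          html_escape(names(attrs)),
                          html_escape(unlist(attrs))), collapse = "\n")
    links <- entity_links(x)
    lis <- paste(sprintf('<li><a href="%s">%s</a></li>',
                         links, html_escape(names(links))), collapse = "\n")
    return(page(sprintf("%s %s", entity_kind(x), entity_id(x)),
                sprintf("<table>\n%s\n</table>\n<ul>\n%s\n</ul>", rows, lis)))
  }
  lis <- paste(vapply(x, function(e) sprintf(
    '<li><a href="%s">%s</a></li>', route_for(e), html_escape(entity_id(e))), ""),
    collapse = "\n")
  title <- sprintf("%s (%d)", collection_root_name(x, kind), length(x))
  page(title, sprintf("<ul>\n%s\n</ul>", lis))
}
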