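# Resource routes: every entity kind, collection and association is bound to
# a canonical URL path template with a fixed set of renderable
# representations.  FASTA is only offered where the addressed objects carry
# sequences (precursors and matures, and associations targeting them).

representations_for_kind <- function(ds, kind) {
  base <- c("html", "xml", "json")
  if (isTRUE(ds$kinds[[kind]]$sequence_bearing)) c(base, "fasta") else base
}

#' Table of registered resource routes
#'
#' One row per route: collection and member routes for every registered kind
#' (core and plugin) plus one nested route per association.
#'
#' @param dataset A `mir_dataset`.
#' @return Data frame with `path_template`, `kind`, `association`,
#'   `cardinality`, `representations` (comma-joined).
#' @export
routes_table <- function(dataset) {
  rows <- list()
  add <- function(template, kind, association, cardinality, reps) {
    rows[[length(rows) + 1L]] <<- df(
      path_template = template, kind = kind,
      association = association, cardinality = cardinality,
      representations = paste(reps, collapse = ","))
  }
  for (kind in names(dataset$kinds)) {
    plural <- dataset$kinds[[kind]]$plural
    reps <- representations_for_kind(dataset, kind)
    add(sprintf("/%s", plural), kind, NA_character_, "many", reps)
    add(sprintf("/%s/{id}", plural), kind, NA_character_, "one", reps)
  }
  for (a in dataset$associations) {
    plural <- dataset$kinds[[a$kind]]$plural
    reps <- representations_for_kind(dataset, a$target_kind)
    add(sprintf("/%s/{id}/%s", plural, a$name), a$target_kind, a$name,
        a$cardinality, reps)
  }
  out <- do.call(rbind, rows)
  out[lex_order(out$path_template), , drop = FALSE]
}

#' Canonical URL path of an entity, collection or nested association
#'
#' @param x A `mir_entity` (member path), or a kind / association name
#'   (collection or nested path).
#' @param nested_under Owner entity for a nested association path, or `NULL`.
#' @param dataset Needed only when `x` is a kind name and `nested_under` is
#'   `NULL`.
#' @return URL path string with RFC-reserved characters percent-encoded
#'   (literal `*` kept, as star-strand names carry it).
#' @export
route_for <- function(x, nested_under = NULL, dataset = NULL) {
  if (inherits(x, "mir_entity")) {
    ds <- attr(x, "dataset")
    info <- ds$kinds[[entity_kind(x)]]
    return(sprintf("/%s/%s", info$plural, encode_segment(entity_id(x))))
  }
  if (!is.null(nested_under)) {
    if (!inherits(nested_under, "mir_entity"))
      mirkit_error("mirkit_unregistered_kind", "nested_under must be an entity")
    ds <- attr(nested_under, "dataset")
    key <- assoc_key(entity_kind(nested_under), x)
    if (is.null(ds$associations[[key]]))
      mirkit_error("mirkit_unregistered_kind",
                   sprintf("'%s' is not an association of %s", x,
                           entity_kind(nested_under)))
    return(sprintf("%s/%s", route_for(nested_under), x))
  }
  if (is.null(dataset))
    mirkit_error("mirkit_unregistered_kind",
                 "collection routes need a dataset argument")
  info <- dataset$kinds[[x]]
  if (is.null(info))
    mirkit_error("mirkit_unregistered_kind", sprintf("unknown kind '%s'", x))
  sprintf("/%s", info$plural)
}

#' Self-describing route listing
#'
#' Every registered route (core and plugin) with its representations, as
#' plain text (one route per line) or as an XML document.
#'
#' @param dataset A `mir_dataset`.
#' @param format `"txt"` or `"xml"`.
#' @return Character scalar.
#' @export
described_routes <- function(dataset, format = c("txt", "xml")) {
  format <- match.arg(format)
  rt <- routes_table(dataset)
  if (format == "txt") {
    return(paste0(sprintf("%-55s [%s]", rt$path_template, rt$representations),
                  collapse = "\n"))
  }
  doc <- xml2::xml_new_root("routes", count = as.character(nrow(rt)))
  for (i in seq_len(nrow(rt))) {
    xml2::xml_add_child(doc, "route",
                        path = rt$path_template[i],
                        representations = rt$representations[i],
                        cardinality = rt$cardinality[i])
  }
  as.character(doc)
}
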