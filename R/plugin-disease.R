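# Example plugin: disease annotation of mature miRNAs, shaped like a
# disease-association resource.  Two kinds: diseases (keyed by a Disease
# Ontology identifier) and disease links, each link tying one mature miRNA to
# one disease with a PubMed reference and reported target genes.  The link's
# composite identifier concatenates DOID, mature name and PubMed id.  The
# bundled data under inst/extdata/m2d_synthetic is synthetic.

disease_link_id <- function(doid, mature_name, pubmed_id) {
  paste(doid, mature_name, pubmed_id, sep = "+")
}

load_m2d_source <- function(dataset, source) {
  dis_path <- file.path(source, "m2d_diseases.tsv")
  link_path <- file.path(source, "m2d_disease_links.tsv")
  if (!file.exists(dis_path) || !file.exists(link_path))
    mirkit_error("mirkit_source_missing", sprintf(
      "expected m2d_diseases.tsv and m2d_disease_links.tsv under %s", source))
  dis <- utils::read.delim(dis_path, header = TRUE, colClasses = "character")
  links <- utils::read.delim(link_path, header = TRUE, colClasses = "character")

  dis <- dis[!duplicated(dis$doid), c("doid", "name"), drop = FALSE]
  dataset$tab$m2d_disease <- dis

  known <- links$mature_name %in% dataset$tab$mature$name
  for (nm in unique(links$mature_name[!known])) {
    mirkit_log("warn", sprintf(
      "disease link names unknown mature '%s'; skipped", nm))
  }
  links <- links[known, , drop = FALSE]
  dataset$tab$m2d_disease_link <- df(
    link_id = disease_link_id(links$doid, links$mature_name, links$pubmed_id),
    doid = links$doid, mature_name = links$mature_name,
    pubmed_id = links$pubmed_id, target_genes = links$target_genes)
  dataset$tab$m2d_disease_link <-
    dataset$tab$m2d_disease_link[!duplicated(dataset$tab$m2d_disease_link$link_id), ,
                                 drop = FALSE]
  invisible(dataset)
}

m2d_tests <- function(dataset) {
  fails <- character()
  dis <- dataset$tab$m2d_disease
  links <- dataset$tab$m2d_disease_link
  if (anyDuplicated(dis$doid))
    fails <- c(fails, "duplicate DOID among diseases")
  if (anyDuplicated(links$link_id))
    fails <- c(fails, "duplicate composite link identifier")
  bad <- setdiff(links$mature_name, dataset$tab$mature$name)
  if (length(bad))
    fails <- c(fails, sprintf("links reference unknown matures: %s",
                              paste(bad, collapse = ", ")))
  bad_doid <- setdiff(links$doid, dis$doid)
  if (length(bad_doid))
    fails <- c(fails, sprintf("links reference unknown diseases: %s",
                              paste(bad_doid, collapse = ", ")))
  recomputed <- disease_link_id(links$doid, links$mature_name, links$pubmed_id)
  if (!identical(recomputed, links$link_id))
    fails <- c(fails, "link identifiers are not DOID+mature+PubMed concatenations")
  fails
}

#' The example disease-annotation plugin
#'
#' Declares the `m2d_disease` and `m2d_disease_link` kinds, a one-many
#' association from matures to their disease links, and a loader for a
#' directory holding `m2d_diseases.tsv` (doid, name) and
#' `m2d_disease_links.tsv` (doid, mature_name, pubmed_id, target_genes).
#' A synthetic example source ships under
#' `system.file("extdata", "m2d_synthetic", package = "mirkit")`.
#'
#' @return A [plugin_manifest()].
#' @export
disease_plugin <- function() {
  plugin_manifest(
    name = "m2d",
    types = list(
      m2d_disease = list(
        plural = "m2d_diseases", id_field = "doid",
        attributes = c("doid", "name"), sequence_bearing = FALSE),
      m2d_disease_link = list(
        plural = "m2d_disease_links", id_field = "link_id",
        attributes = c("link_id", "doid", "mature_name", "pubmed_id",
                       "target_genes"),
        sequence_bearing = FALSE)
    ),
    associations = list(
      list(kind = "mature", name = "m2d_disease_links",
           target_kind = "m2d_disease_link", cardinality = "many",
           fetch = function(ds, e) {
             l <- ds$tab$m2d_disease_link
             l$link_id[l$mature_name == e$name]
           }),
      list(kind = "m2d_disease_link", name = "mature",
           target_kind = "mature", cardinality = "one",
           fetch = function(ds, e) e$mature_name),
      list(kind = "m2d_disease_link", name = "m2d_disease",
           target_kind = "m2d_disease", cardinality = "one",
           fetch = function(ds, e) e$doid),
      list(kind = "m2d_disease", name = "m2d_disease_links",
           target_kind = "m2d_disease_link", cardinality = "many",
           fetch = function(ds, e) {
             l <- ds$tab$m2d_disease_link
             l$link_id[l$doid == e$doid]
           })
    ),
    loader = load_m2d_source,
    tests = m2d_tests
  )
}
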