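# Shared fixtures, generated once per test run.  `cached_fixture()` returns
# the default synthetic release and an ingested+derived dataset; tests that
# mutate a dataset (plugin registration, re-derivation) take a fresh one via
# `fresh_dataset()`.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function() {
  if (is.null(.fixture_cache$gen)) {
    dir <- file.path(tempdir(), "mirkit-default-release")
    unlink(dir, recursive = TRUE)
    .fixture_cache$gen <- generate_release(fixture_spec(), dir)
    .fixture_cache$ds <- derive_all(build_dataset(.fixture_cache$gen$bundle))
  }
  list(gen = .fixture_cache$gen, ds = .fixture_cache$ds)
}

derive_all <- function(ds, max_gap = 10000) {
  build_seed_families(ds, 6L)
  build_seed_families(ds, 7L)
  build_precursor_clusters(ds, cluster_params(max_gap = max_gap))
  ds
}

fresh_dataset <- function(derive = TRUE) {
  gen <- cached_fixture()$gen
  ds <- build_dataset(gen$bundle)
  if (derive) derive_all(ds)
  ds
}

# A minimal hand-built dataset around explicit genomic intervals, for the
# interval-arithmetic examples.  `positions` rows: xsome, start, end, strand.
toy_position_dataset <- function(positions, species = "syn") {
  ds <- new_dataset("toy")
  n <- nrow(positions)
  names_ <- sprintf("%s-mir-%d", species, seq_len(n))
  ds$tab$species <- data.frame(
    abbreviation = species, name = "Toy species", division = "SYN",
    taxonomy = "Toy.", genome_assembly = "TOY1", stringsAsFactors = FALSE)
  ds$tab$precursor <- data.frame(
    name = names_, accession = sprintf("MI9%06d", seq_len(n)),
    description = "", sequence = strrep("ACGU", 20), comment = "",
    species_abbreviation = species, family_name = NA_character_,
    cluster_name = NA_character_, stringsAsFactors = FALSE)
  ds$tab$genome_position <- data.frame(
    id = sprintf("%s-pos-1", names_), precursor_name = names_,
    xsome = positions$xsome, contig_start = as.integer(positions$start),
    contig_end = as.integer(positions$end), strand = positions$strand,
    stringsAsFactors = FALSE)
  ds
}

cluster_members <- function(ds) {
  p <- ds$tab$precursor
  out <- split(p$name[!is.na(p$cluster_name)], p$cluster_name[!is.na(p$cluster_name)])
  lapply(out, function(x) sort(x, method = "radix"))
}

# random single-species position sets for oracle-equivalence properties
random_positions <- function(n, n_xsome = 3, span = 50000) {
  s <- sample.int(span, n, replace = TRUE)
  data.frame(
    precursor_name = sprintf("syn-mir-%d", seq_len(n)),
    xsome = sample(sprintf("chr%d", seq_len(n_xsome)), n, replace = TRUE),
    contig_start = s,
    contig_end = s + sample(60:120, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

toy_from_positions <- function(pos) {
  toy_position_dataset(data.frame(xsome = pos$xsome, start = pos$contig_start,
                                  end = pos$contig_end, strand = pos$strand))
}

entity_id_of <- function(e) mirkit:::entity_id(e)

m2d_source <- function() system.file("extdata", "m2d_synthetic", package = "mirkit")

register_and_load_m2d <- function(ds, source = m2d_source()) {
  register_plugin(ds, disease_plugin())
  load_plugin_data(ds, "m2d", source)
  ds
}

# enumerate every concrete resolvable path of the core model for a dataset
crawl_paths <- function(ds, formats = c("xml")) {
  paths <- character()
  for (kind in names(ds$kinds)) {
    plural <- ds$kinds[[kind]]$plural
    paths <- c(paths, sprintf("/%s", plural))
    for (e in list_entities(ds, kind)) {
      paths <- c(paths, route_for(e))
      for (a in names(mirkit:::entity_links(e))) {
        paths <- c(paths, route_for(a, nested_under = e))
      }
    }
  }
  unique(paths)
}
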