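# The in-memory relational universe of one ingested release.
#
# A `mir_dataset` is an environment (reference semantics, so derivation steps
# and plugin registration mutate in place) holding one data frame per entity
# kind, association tables, and a registry describing kinds, their canonical
# identifiers, public attributes and traversable associations.  Plugins extend
# the registry without touching core tables.

CORE_KINDS <- list(
  species = list(
    plural = "species", id_field = "abbreviation",
    attributes = c("abbreviation", "name", "division", "taxonomy", "genome_assembly"),
    sequence_bearing = FALSE
  ),
  precursor = list(
    plural = "precursors", id_field = "name",
    attributes = c("name", "accession", "description", "sequence", "comment"),
    sequence_bearing = TRUE
  ),
  mature = list(
    plural = "matures", id_field = "name",
    attributes = c("name", "accession", "evidence", "experiment", "similarity", "sequence"),
    sequence_bearing = TRUE
  ),
  precursor_family = list(
    plural = "precursor_families", id_field = "name",
    attributes = c("name", "accession", "description"),
    sequence_bearing = FALSE
  ),
  genome_position = list(
    plural = "genome_positions", id_field = "id",
    attributes = c("id", "xsome", "contig_start", "contig_end", "strand"),
    sequence_bearing = FALSE
  ),
  genome_context = list(
    plural = "genome_contexts", id_field = "id",
    attributes = c("id", "overlap_sense", "overlap_type", "transcript_source", "transcript_name"),
    sequence_bearing = FALSE
  ),
  precursor_cluster = list(
    plural = "precursor_clusters", id_field = "name",
    attributes = c("name"),
    sequence_bearing = FALSE
  ),
  seed_family = list(
    plural = "seed_families", id_field = "name",
    attributes = c("name", "sequence"),
    sequence_bearing = FALSE
  ),
  paper = list(
    plural = "papers", id_field = "medline",
    attributes = c("medline", "title", "author", "journal"),
    sequence_bearing = FALSE
  )
)

empty_core_tables <- function() {
  list(
    species = df(abbreviation = empty_chr, name = empty_chr, division = empty_chr,
                 taxonomy = empty_chr, genome_assembly = empty_chr),
    precursor = df(name = empty_chr, accession = empty_chr, description = empty_chr,
                   sequence = empty_chr, comment = empty_chr,
                   species_abbreviation = empty_chr, family_name = empty_chr,
                   cluster_name = empty_chr),
    mature = df(name = empty_chr, accession = empty_chr, evidence = empty_chr,
                experiment = empty_chr, similarity = empty_chr, sequence = empty_chr),
    precursor_family = df(name = empty_chr, accession = empty_chr, description = empty_chr),
    genome_position = df(id = empty_chr, precursor_name = empty_chr, xsome = empty_chr,
                         contig_start = integer(0), contig_end = integer(0),
                         strand = empty_chr),
    genome_context = df(id = empty_chr, precursor_name = empty_chr,
                        overlap_sense = empty_chr, overlap_type = empty_chr,
                        transcript_source = empty_chr, transcript_name = empty_chr),
    precursor_cluster = df(name = empty_chr),
    seed_family = df(name = empty_chr, sequence = empty_chr, k = integer(0)),
    paper = df(medline = empty_chr, title = empty_chr, author = empty_chr,
               journal = empty_chr),
    # association tables
    precursor_mature = df(precursor_name = empty_chr, mature_name = empty_chr),
    precursor_paper = df(precursor_name = empty_chr, medline = empty_chr),
    mature_seed_family = df(mature_name = empty_chr, family_name = empty_chr,
                            k = integer(0))
  )
}

#' Create an empty dataset
#'
#' A dataset holds every entity of one release plus the association tables and
#' the kind/association registry that the query, resource and plugin layers
#' share.  It has reference semantics: ingest, derivation and plugin loading
#' mutate it in place.
#'
#' @param release_version Version string recorded as provenance.
#' @return A `mir_dataset` object.
#' @export
new_dataset <- function(release_version = "unversioned") {
  ds <- new.env(parent = emptyenv())
  ds$release_version <- release_version
  ds$tab <- empty_core_tables()
  ds$kinds <- CORE_KINDS
  ds$associations <- core_associations()
  ds$plugins <- list()
  class(ds) <- "mir_dataset"
  ds
}

#' @export
print.mir_dataset <- function(x, ...) {
  cat(sprintf("<mir_dataset release %s>\n", x$release_version))
  for (kind in names(x$kinds)) {
    cat(sprintf("  %-18s %d\n", x$kinds[[kind]]$plural, nrow(x$tab[[kind]])))
  }
  invisible(x)
}

kind_info <- function(ds, kind) {
  info <- ds$kinds[[kind]]
  if (is.null(info)) {
    mirkit_error("mirkit_invalid_kind",
                 sprintf("unknown entity kind '%s' (valid: %s)", kind,
                         paste(names(ds$kinds), collapse = ", ")))
  }
  info
}

kind_for_plural <- function(ds, plural) {
  hits <- names(ds$kinds)[vapply(ds$kinds, function(k) k$plural == plural, logical(1))]
  if (length(hits)) hits[[1]] else NULL
}

entity_from_row <- function(ds, kind, row) {
  e <- as.list(row)
  attr(e, "kind") <- kind
  attr(e, "dataset") <- ds
  class(e) <- c(paste0("mir_", kind), "mir_entity")
  e
}

#' @export
print.mir_entity <- function(x, ...) {
  kind <- attr(x, "kind")
  cat(sprintf("<%s %s>\n", kind, entity_id(x)))
  flds <- setdiff(names(x), c("species_abbreviation", "precursor_name",
                              "family_name", "cluster_name", "k"))
  for (f in flds) cat(sprintf("  %s: %s\n", f, x[[f]]))
  invisible(x)
}

entity_kind <- function(entity) attr(entity, "kind")

entity_id <- function(entity) {
  ds <- attr(entity, "dataset")
  entity[[ds$kinds[[entity_kind(entity)]]$id_field]]
}

#' Fetch one entity by its canonical identifier
#'
#' Canonical identifiers are the `name` for precursors, matures, species
#' (abbreviation), families, clusters and seed families; the Medline id for
#' papers; synthetic `<precursor>-pos-<n>` / `<precursor>-ctx-<n>` ids for
#' genomic placements; and plugin-declared keys for plugin kinds.  Matching is
#' case-sensitive: `hsa-mir-21` (precursor) and `hsa-miR-21` (mature) are
#' distinct identifiers in distinct namespaces.
#'
#' @param dataset A `mir_dataset`.
#' @param kind Entity kind, e.g. `"precursor"`.
#' @param identifier Canonical identifier string.
#' @return The matching entity (a `mir_entity` list).
#' @export
get_entity <- function(dataset, kind, identifier) {
  info <- kind_info(dataset, kind)
  tab <- dataset$tab[[kind]]
  i <- which(tab[[info$id_field]] == identifier)
  if (length(i) == 0L) {
    mirkit_error("mirkit_not_found",
                 sprintf("no %s with %s '%s'", kind, info$id_field, identifier))
  }
  entity_from_row(dataset, kind, tab[i[[1]], , drop = FALSE])
}

#' List entities of a kind
#'
#' @param dataset A `mir_dataset`.
#' @param kind Entity kind.
#' @param filter Either `NULL`, a predicate `function(entity) -> logical`, or a
#'   named list of `field = value` equality constraints.
#' @param window Either `NULL` or `c(offset, limit)` (0-based offset applied
#'   after ordering; `limit` rows are returned).
#' @return List of entities in lexicographic order of canonical identifier.
#' @export
list_entities <- function(dataset, kind, filter = NULL, window = NULL) {
  info <- kind_info(dataset, kind)
  tab <- dataset$tab[[kind]]
  tab <- tab[lex_order(tab[[info$id_field]]), , drop = FALSE]
  ents <- lapply(seq_len(nrow(tab)), function(i)
    entity_from_row(dataset, kind, tab[i, , drop = FALSE]))
  if (!is.null(filter)) {
    keep <- if (is.function(filter)) {
      vapply(ents, function(e) isTRUE(filter(e)), logical(1))
    } else {
      vapply(ents, function(e)
        all(vapply(names(filter), function(f) identical(e[[f]], filter[[f]]),
                   logical(1))), logical(1))
    }
    ents <- ents[keep]
  }
  if (!is.null(window)) {
    offset <- as.integer(window[[1]]); limit <- as.integer(window[[2]])
    idx <- seq_len(length(ents))
    idx <- idx[idx > offset][seq_len(min(limit, max(0L, length(ents) - offset)))]
    ents <- ents[idx]
  }
  ents
}

entities_by_id <- function(ds, kind, ids) {
  ids <- sort(unique(ids), method = "radix")
  lapply(ids, function(i) get_entity(ds, kind, i))
}

# -- association registry -----------------------------------------------------

assoc_key <- function(kind, name) paste(kind, name, sep = ".")

# Each association: owner kind, name (the path segment), target kind,
# cardinality ("one" | "many"), and a fetch closure (ds, entity) returning
# an id vector ("many") or a single id / NA ("one").
core_associations <- function() {
  a <- list()
  add <- function(kind, name, target, card, fetch) {
    a[[assoc_key(kind, name)]] <<- list(kind = kind, name = name,
                                        target_kind = target,
                                        cardinality = card, fetch = fetch)
  }

  add("precursor", "species", "species", "one", function(ds, e) e$species_abbreviation)
  add("precursor", "matures", "mature", "many", function(ds, e) {
    pm <- ds$tab$precursor_mature
    pm$mature_name[pm$precursor_name == e$name]
  })
  add("precursor", "genome_positions", "genome_position", "many", function(ds, e) {
    gp <- ds$tab$genome_position
    gp$id[gp$precursor_name == e$name]
  })
  add("precursor", "genome_contexts", "genome_context", "many", function(ds, e) {
    gc <- ds$tab$genome_context
    gc$id[gc$precursor_name == e$name]
  })
  add("precursor", "papers", "paper", "many", function(ds, e) {
    pp <- ds$tab$precursor_paper
    unique(pp$medline[pp$precursor_name == e$name])
  })
  add("precursor", "precursor_family", "precursor_family", "one",
      function(ds, e) e$family_name)
  add("precursor", "precursor_cluster", "precursor_cluster", "one",
      function(ds, e) e$cluster_name)

  add("mature", "precursors", "precursor", "many", function(ds, e) {
    pm <- ds$tab$precursor_mature
    unique(pm$precursor_name[pm$mature_name == e$name])
  })
  # Deduplicated union over linked precursors: papers annotate precursors, but
  # a mature's literature is reachable through every hairpin it derives from.
  add("mature", "papers", "paper", "many", function(ds, e) {
    pm <- ds$tab$precursor_mature
    pre <- pm$precursor_name[pm$mature_name == e$name]
    pp <- ds$tab$precursor_paper
    unique(pp$medline[pp$precursor_name %in% pre])
  })
  add("mature", "seed_families", "seed_family", "many", function(ds, e) {
    ms <- ds$tab$mature_seed_family
    unique(ms$family_name[ms$mature_name == e$name])
  })

  add("species", "precursors", "precursor", "many", function(ds, e) {
    p <- ds$tab$precursor
    p$name[p$species_abbreviation == e$abbreviation]
  })
  add("species", "matures", "mature", "many", function(ds, e) {
    p <- ds$tab$precursor
    pre <- p$name[p$species_abbreviation == e$abbreviation]
    pm <- ds$tab$precursor_mature
    unique(pm$mature_name[pm$precursor_name %in% pre])
  })

  add("precursor_family", "precursors", "precursor", "many", function(ds, e) {
    p <- ds$tab$precursor
    p$name[!is.na(p$family_name) & p$family_name == e$name]
  })
  add("precursor_cluster", "precursors", "precursor", "many", function(ds, e) {
    p <- ds$tab$precursor
    p$name[!is.na(p$cluster_name) & p$cluster_name == e$name]
  })
  add("seed_family", "matures", "mature", "many", function(ds, e) {
    ms <- ds$tab$mature_seed_family
    unique(ms$mature_name[ms$family_name == e$name])
  })
  add("paper", "precursors", "precursor", "many", function(ds, e) {
    pp <- ds$tab$precursor_paper
    unique(pp$precursor_name[pp$medline == e$medline])
  })
  add("paper", "matures", "mature", "many", function(ds, e) {
    pp <- ds$tab$precursor_paper
    pre <- pp$precursor_name[pp$medline == e$medline]
    pm <- ds$tab$precursor_mature
    unique(pm$mature_name[pm$precursor_name %in% pre])
  })
  add("genome_position", "precursor", "precursor", "one",
      function(ds, e) e$precursor_name)
  add("genome_context", "precursor", "precursor", "one",
      function(ds, e) e$precursor_name)
  a
}

# Declared inverse pairs; association symmetry is asserted over these.
CORE_INVERSES <- list(
  c("precursor.matures", "mature.precursors"),
  c("precursor.species", "species.precursors"),
  c("precursor.papers", "paper.precursors"),
  c("precursor.genome_positions", "genome_position.precursor"),
  c("precursor.genome_contexts", "genome_context.precursor"),
  c("precursor.precursor_family", "precursor_family.precursors"),
  c("precursor.precursor_cluster", "precursor_cluster.precursors"),
  c("mature.seed_families", "seed_family.matures"),
  c("mature.papers", "paper.matures")
)

associations_of <- function(ds, kind) {
  ds$associations[vapply(ds$associations, function(a) a$kind == kind, logical(1))]
}

#' Traverse an association from an entity
#'
#' `"one"` associations return a single entity or `NULL`; `"many"`
#' associations return a list of entities in lexicographic order of canonical
#' identifier.
#'
#' @param entity A `mir_entity` obtained from [get_entity()] /
#'   [list_entities()] / a previous traversal.
#' @param association Association name declared for the entity's kind (core or
#'   plugin-registered), e.g. `"matures"` for a precursor.
#' @return Entity, list of entities, or `NULL`.
#' @export
traverse <- function(entity, association) {
  ds <- attr(entity, "dataset")
  kind <- entity_kind(entity)
  a <- ds$associations[[assoc_key(kind, association)]]
  if (is.null(a)) {
    valid <- vapply(associations_of(ds, kind), `[[`, "", "name")
    mirkit_error("mirkit_unknown_association",
                 sprintf("'%s' is not an association of kind '%s' (valid: %s)",
                         association, kind, paste(sort(valid), collapse = ", ")))
  }
  ids <- a$fetch(ds, entity)
  if (a$cardinality == "one") {
    if (length(ids) == 0L || is.na(ids[[1]])) return(NULL)
    return(get_entity(ds, a$target_kind, ids[[1]]))
  }
  entities_by_id(ds, a$target_kind, ids[!is.na(ids)])
}

# -- integrity ----------------------------------------------------------------

#' Check every data-model invariant of a dataset
#'
#' Violations are data, not errors: the report is a data frame with one row
#' per violated invariant (`rule`, `kind`, `identifier`, `detail`).  An empty
#' report means the dataset satisfies all core invariants.
#'
#' @param dataset A `mir_dataset`.
#' @return A data frame of violations (zero rows when valid).
#' @export
validate_dataset <- function(dataset) {
  v <- list()
  bad <- function(rule, kind, identifier, detail) {
    v[[length(v) + 1L]] <<- df(rule = rule, kind = kind,
                               identifier = identifier, detail = detail)
  }
  tab <- dataset$tab

  check_unique <- function(kind, field) {
    x <- tab[[kind]][[field]]
    for (d in unique(x[duplicated(x)])) {
      bad("unique_identifier", kind, d, sprintf("duplicate %s", field))
    }
  }
  for (kind in names(dataset$kinds)) {
    check_unique(kind, dataset$kinds[[kind]]$id_field)
  }
  check_unique("precursor", "accession")
  check_unique("mature", "accession")

  p <- tab$precursor
  for (i in seq_len(nrow(p))) {
    if (!grepl("^MI\\d+$", p$accession[i]))
      bad("accession_shape", "precursor", p$name[i], p$accession[i])
    if (is.na(p$sequence[i]) || !nzchar(p$sequence[i]))
      bad("empty_sequence", "precursor", p$name[i], "sequence is empty")
    if (!p$species_abbreviation[i] %in% tab$species$abbreviation)
      bad("dangling_species", "precursor", p$name[i], p$species_abbreviation[i])
    else if (!startsWith(p$name[i], paste0(p$species_abbreviation[i], "-")))
      bad("species_prefix", "precursor", p$name[i],
          sprintf("name does not start with '%s-'", p$species_abbreviation[i]))
    if (!is.na(p$family_name[i]) && !p$family_name[i] %in% tab$precursor_family$name)
      bad("dangling_family", "precursor", p$name[i], p$family_name[i])
  }

  m <- tab$mature
  pm <- tab$precursor_mature
  for (i in seq_len(nrow(m))) {
    if (!grepl("^MIMAT\\d+$", m$accession[i]))
      bad("accession_shape", "mature", m$name[i], m$accession[i])
    pres <- pm$precursor_name[pm$mature_name == m$name[i]]
    if (length(pres) == 0L)
      bad("orphan_mature", "mature", m$name[i], "linked to no precursor")
    for (pn in pres) {
      j <- match(pn, p$name)
      if (is.na(j)) {
        bad("dangling_precursor_link", "mature", m$name[i], pn)
      } else if (!grepl(m$sequence[i], p$sequence[j], fixed = TRUE)) {
        bad("substring_law", "mature", m$name[i],
            sprintf("sequence not a substring of precursor %s", pn))
      }
    }
  }

  gp <- tab$genome_position
  for (i in seq_len(nrow(gp))) {
    if (!gp$precursor_name[i] %in% p$name)
      bad("orphan_position", "genome_position", gp$id[i], gp$precursor_name[i])
    if (gp$contig_start[i] < 1L || gp$contig_start[i] > gp$contig_end[i])
      bad("coordinate_order", "genome_position", gp$id[i],
          sprintf("%d..%d", gp$contig_start[i], gp$contig_end[i]))
    if (!gp$strand[i] %in% c("+", "-"))
      bad("strand_value", "genome_position", gp$id[i], gp$strand[i])
  }
  gc <- tab$genome_context
  for (i in seq_len(nrow(gc))) {
    if (!gc$precursor_name[i] %in% p$name)
      bad("orphan_context", "genome_context", gc$id[i], gc$precursor_name[i])
  }

  pf <- tab$precursor_family
  for (i in seq_len(nrow(pf))) {
    if (!any(!is.na(p$family_name) & p$family_name == pf$name[i]))
      bad("empty_family", "precursor_family", pf$name[i], "no member precursors")
  }

  pp <- tab$precursor_paper
  for (i in seq_len(nrow(tab$paper))) {
    if (!tab$paper$medline[i] %in% pp$medline)
      bad("orphan_paper", "paper", tab$paper$medline[i], "linked to no precursor")
  }
  for (i in seq_len(nrow(pp))) {
    if (!pp$precursor_name[i] %in% p$name)
      bad("dangling_paper_link", "paper", pp$medline[i], pp$precursor_name[i])
  }

  sf <- tab$seed_family
  ms <- tab$mature_seed_family
  for (i in seq_len(nrow(sf))) {
    members <- ms$mature_name[ms$family_name == sf$name[i] & ms$k == sf$k[i]]
    for (mn in members) {
      j <- match(mn, m$name)
      if (is.na(j) || substr(m$sequence[j], 2L, 1L + sf$k[i]) != sf$sequence[i])
        bad("seed_mismatch", "seed_family", sf$name[i], mn)
    }
  }

  if (length(v) == 0L) {
    return(df(rule = empty_chr, kind = empty_chr, identifier = empty_chr,
              detail = empty_chr))
  }
  do.call(rbind, v)
}

# -- fingerprint & persistence ------------------------------------------------

order_stable_snapshot <- function(ds) {
  tabs <- lapply(ds$tab, function(t) {
    t <- t[do.call(order, c(unname(as.list(t)), list(method = "radix"))), ,
           drop = FALSE]
    rownames(t) <- NULL
    t
  })
  list(release_version = ds$release_version, tab = tabs[sort(names(tabs))])
}

#' Content fingerprint of a dataset
#'
#' MD5 of an order-stable serialization of every table; used to assert that
#' the resource layer is read-only.
#'
#' @param dataset A `mir_dataset`.
#' @return A character MD5 digest.
#' @export
dataset_fingerprint <- function(dataset) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(order_stable_snapshot(dataset), tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Save / load a dataset
#'
#' Serializes the tables and provenance (not the registry closures; plugins
#' must be re-registered after loading).
#'
#' @param dataset A `mir_dataset`.
#' @param path File path.
#' @return `dataset_load` returns a `mir_dataset`.
#' @export
dataset_save <- function(dataset, path) {
  saveRDS(list(release_version = dataset$release_version, tab = dataset$tab,
               plugin_tabs = dataset$tab[setdiff(names(dataset$tab),
                                                 names(empty_core_tables()))]),
          path)
  invisible(path)
}

#' @rdname dataset_save
#' @export
dataset_load <- function(path) {
  snap <- readRDS(path)
  ds <- new_dataset(snap$release_version)
  for (nm in names(snap$tab)) ds$tab[[nm]] <- snap$tab[[nm]]
  ds
}
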