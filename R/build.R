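# Restructure a parsed release bundle into the relational data model.

read_fasta_named <- function(path) {
  set <- Biostrings::readBStringSet(path)
  # header is "<name> <accession> ..."; index by accession when present,
  # falling back to the name token
  headers <- names(set)
  toks <- strsplit(headers, "\\s+")
  key <- vapply(toks, function(t) if (length(t) >= 2L) t[[2]] else t[[1]], "")
  stats::setNames(as_rna(as.character(set)), key)
}

#' Build a dataset from a release bundle
#'
#' Parses every member of the bundle and resolves all cross-file links by
#' accession: matures appearing under several hairpin records are
#' deduplicated by accession (establishing the precursor--mature
#' many-to-many), family members and coordinate rows are matched to
#' precursors, and species records come from the species table or are
#' synthesized from name prefixes when the table is absent.  Where the FASTA
#' members disagree with the record file the record file wins and the
#' disagreement is logged.  Seed families and precursor clusters are *not*
#' derived here; run [build_seed_families()] and [build_precursor_clusters()]
#' explicitly.
#'
#' @param bundle A `release_bundle`.
#' @return A validated `mir_dataset` (run [validate_dataset()] to confirm).
#' @export
build_dataset <- function(bundle) {
  if (!inherits(bundle, "release_bundle"))
    mirkit_error("mirkit_bad_bundle", "build_dataset() expects a release_bundle")
  records <- parse_hairpin_records(bundle$hairpin_records)
  if (length(records) == 0L)
    mirkit_error("mirkit_bad_bundle", "hairpin record file yielded no records")

  ds <- new_dataset(bundle$version)

  species_code <- function(name) sub("-.*$", "", name)

  # precursors
  pre <- do.call(rbind, lapply(records, function(r) {
    df(name = r$name, accession = r$accession, description = r$description,
       sequence = r$sequence, comment = r$comment,
       species_abbreviation = species_code(r$name),
       family_name = NA_character_, cluster_name = NA_character_)
  }))
  dup <- duplicated(pre$name) | duplicated(pre$accession)
  if (any(dup)) {
    mirkit_log("warn", sprintf("dropping %d duplicate precursor record(s): %s",
                               sum(dup), paste(pre$name[dup], collapse = ", ")))
    keep <- !dup
    records <- records[keep]
    pre <- pre[keep, , drop = FALSE]
  }

  # matures, deduplicated by accession across records
  mat_rows <- list()
  pm_rows <- list()
  seen <- new.env(parent = emptyenv())
  for (r in records) {
    fm <- r$matures
    for (i in seq_len(nrow(fm))) {
      acc <- fm$accession[i]
      seqm <- substr(r$sequence, fm$start[i], fm$end[i])
      if (is.na(acc) || !nzchar(acc)) {
        mirkit_log("warn", sprintf("mature feature without accession in %s", r$name))
        next
      }
      pname <- if (is.na(fm$product[i]) || !nzchar(fm$product[i])) acc
               else fm$product[i]
      if (!exists(acc, envir = seen)) {
        assign(acc, pname, envir = seen)
        mat_rows[[length(mat_rows) + 1L]] <- df(
          name = pname, accession = acc,
          evidence = fm$evidence[i], experiment = fm$experiment[i],
          similarity = fm$similarity[i], sequence = seqm)
      } else {
        prev <- mat_rows[[which(vapply(mat_rows, `[[`, "", "accession") == acc)[1]]]
        if (!identical(prev$sequence, seqm)) {
          mirkit_log("warn", sprintf(
            "mature %s has differing excised sequences across precursors; keeping first", acc))
        }
      }
      pm_rows[[length(pm_rows) + 1L]] <- df(
        precursor_name = r$name, mature_name = get(acc, envir = seen))
    }
  }
  mat <- if (length(mat_rows)) do.call(rbind, mat_rows) else ds$tab$mature
  pm <- if (length(pm_rows)) unique(do.call(rbind, pm_rows)) else
    ds$tab$precursor_mature

  # papers, deduplicated by medline
  pap_rows <- list()
  ppl_rows <- list()
  for (r in records) {
    refs <- r$references
    for (i in seq_len(nrow(refs))) {
      med <- refs$medline[i]
      if (is.na(med)) next
      if (!med %in% vapply(pap_rows, `[[`, "", "medline")) {
        pap_rows[[length(pap_rows) + 1L]] <- df(
          medline = med, title = refs$title[i], author = refs$author[i],
          journal = refs$journal[i])
      }
      ppl_rows[[length(ppl_rows) + 1L]] <- df(precursor_name = r$name,
                                              medline = med)
    }
  }

  # species: table if present, else synthesized from prefixes
  if (!is.null(bundle$species)) {
    sp <- parse_species_table(bundle$species)
    attr(sp, "skipped") <- NULL
    missing <- setdiff(unique(pre$species_abbreviation), sp$abbreviation)
    if (length(missing)) {
      mirkit_log("warn", sprintf("species table lacks %s; synthesizing",
                                 paste(missing, collapse = ", ")))
      sp <- rbind(sp, df(abbreviation = missing, name = missing, division = "",
                         taxonomy = "", genome_assembly = ""))
    }
  } else {
    codes <- sort(unique(pre$species_abbreviation), method = "radix")
    sp <- df(abbreviation = codes, name = codes, division = "",
             taxonomy = "", genome_assembly = "")
  }

  # families
  fam_tab <- ds$tab$precursor_family
  if (!is.null(bundle$family)) {
    fams <- parse_family_file(bundle$family)
    fam_rows <- list()
    for (f in fams) {
      fam_rows[[length(fam_rows) + 1L]] <- df(
        name = f$name, accession = f$accession %||% "", description = "")
      for (acc in f$members) {
        j <- match(acc, pre$accession)
        if (is.na(j)) {
          mirkit_log("warn", sprintf("family %s member %s unknown", f$name, acc))
        } else {
          pre$family_name[j] <- f$name
        }
      }
    }
    if (length(fam_rows)) fam_tab <- do.call(rbind, fam_rows)
  }

  # genome positions
  gp_tab <- ds$tab$genome_position
  if (!is.null(bundle$coordinates)) {
    gp_rows <- list()
    ordinal <- new.env(parent = emptyenv())
    codes <- names(bundle$coordinates) %||% rep(NA_character_,
                                                length(bundle$coordinates))
    for (i in seq_along(bundle$coordinates)) {
      coords <- parse_coordinates(bundle$coordinates[[i]], species = codes[[i]])
      for (j in seq_len(nrow(coords))) {
        id <- coords$identifier[j]
        k <- match(id, pre$accession)
        if (is.na(k)) k <- match(id, pre$name)
        if (is.na(k)) {
          mirkit_log("warn", sprintf("coordinates reference unknown precursor %s", id))
          next
        }
        pn <- pre$name[k]
        n <- (if (exists(pn, envir = ordinal)) get(pn, envir = ordinal) else 0L) + 1L
        assign(pn, n, envir = ordinal)
        gp_rows[[length(gp_rows) + 1L]] <- df(
          id = sprintf("%s-pos-%d", pn, n), precursor_name = pn,
          xsome = coords$xsome[j], contig_start = coords$contig_start[j],
          contig_end = coords$contig_end[j], strand = coords$strand[j])
      }
    }
    if (length(gp_rows)) gp_tab <- do.call(rbind, gp_rows)
  }

  # genome contexts
  gc_tab <- ds$tab$genome_context
  if (!is.null(bundle$context)) {
    ctx <- parse_context_table(bundle$context)
    gc_rows <- list()
    ordinal <- new.env(parent = emptyenv())
    for (j in seq_len(nrow(ctx))) {
      id <- ctx$identifier[j]
      k <- match(id, pre$accession)
      if (is.na(k)) k <- match(id, pre$name)
      if (is.na(k)) {
        mirkit_log("warn", sprintf("context row references unknown precursor %s", id))
        next
      }
      pn <- pre$name[k]
      n <- (if (exists(pn, envir = ordinal)) get(pn, envir = ordinal) else 0L) + 1L
      assign(pn, n, envir = ordinal)
      gc_rows[[length(gc_rows) + 1L]] <- df(
        id = sprintf("%s-ctx-%d", pn, n), precursor_name = pn,
        overlap_sense = ctx$overlap_sense[j], overlap_type = ctx$overlap_type[j],
        transcript_source = ctx$transcript_source[j],
        transcript_name = ctx$transcript_name[j])
    }
    if (length(gc_rows)) gc_tab <- do.call(rbind, gc_rows)
  }

  # FASTA cross-consistency: record file wins, disagreement is logged
  if (!is.null(bundle$hairpin_fasta)) {
    fa <- read_fasta_named(bundle$hairpin_fasta)
    hit <- intersect(names(fa), pre$accession)
    bad <- hit[fa[hit] != pre$sequence[match(hit, pre$accession)]]
    for (b in bad) mirkit_log("warn", sprintf(
      "hairpin FASTA sequence for %s disagrees with record file; record wins", b))
  }
  if (!is.null(bundle$mature_fasta) && nrow(mat)) {
    fa <- read_fasta_named(bundle$mature_fasta)
    hit <- intersect(names(fa), mat$accession)
    bad <- hit[fa[hit] != mat$sequence[match(hit, mat$accession)]]
    for (b in bad) mirkit_log("warn", sprintf(
      "mature FASTA sequence for %s disagrees with record file; record wins", b))
  }

  ds$tab$species <- sp
  ds$tab$precursor <- pre
  ds$tab$mature <- mat
  ds$tab$precursor_mature <- pm
  if (length(pap_rows)) ds$tab$paper <- do.call(rbind, pap_rows)
  if (length(ppl_rows)) ds$tab$precursor_paper <- unique(do.call(rbind, ppl_rows))
  ds$tab$precursor_family <- fam_tab
  ds$tab$genome_position <- gp_tab
  ds$tab$genome_context <- gc_tab
  rownames(ds$tab$precursor) <- NULL
  ds
}
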