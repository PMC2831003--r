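# Deterministic synthetic-release generator.  Emits a complete release
# bundle in the exact dialects the ingest layer consumes, together with a
# ground-truth manifest that ingestion and derivation must reproduce.
# Planted structures: a mature shared by two hairpins (many-to-many), a star
# mature with '*' in its name, a precursor with two genomic loci, a paper
# cited by two precursors, consecutive loci whose gaps equal max_gap and
# max_gap + 1 (bracketing the clustering threshold), a strand flip, and
# groups of matures forced to share their 7mer seed.
# Accession namespaces MI9xxxxxxx / MIMAT9xxxxxxx are synthetic and collide
# with no real release.

#' Parameters of a synthetic release
#'
#' @param seed RNG seed; identical seeds give byte-identical bundles.
#' @param n_species Number of species (the last one, when more than one, has
#'   no genome assembly and no coordinates, which is legal).
#' @param precursors_per_species Hairpins per species.
#' @param star_fraction Probability that a hairpin carries a second (star)
#'   mature.
#' @param shared_mature Plant one mature shared by the last two hairpins of
#'   the first species?
#' @param seed_share_group_sizes Integer vector; group g forces the first
#'   matures of that many hairpins of species g to share one 7mer seed.
#' @param papers_per_precursor Maximum literature references per hairpin.
#' @param contexts_per_precursor Maximum genome-context rows per hairpin.
#' @param cluster_max_gap The clustering threshold the planted locus gaps
#'   bracket; also the `max_gap` the manifest's expected clusters assume.
#' @param version Release version string.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 101L, n_species = 3L,
                         precursors_per_species = 5L, star_fraction = 0.5,
                         shared_mature = TRUE,
                         seed_share_group_sizes = c(3L, 2L),
                         papers_per_precursor = 2L,
                         contexts_per_precursor = 2L,
                         cluster_max_gap = 10000L,
                         version = "synth-1.0") {
  stopifnot(n_species >= 1L, precursors_per_species >= 1L,
            star_fraction >= 0, star_fraction <= 1,
            papers_per_precursor >= 1L, contexts_per_precursor >= 0L,
            cluster_max_gap >= 0L)
  structure(as.list(environment()), class = "fixture_spec")
}

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                              collapse = "")

#' Brute-force clustering oracle
#'
#' O(n^2) pairwise adjacency (same chromosome, optionally same strand,
#' interval-hull gap <= max_gap) followed by transitive closure.  Kept
#' independent of [build_precursor_clusters()] so the two can be compared.
#'
#' @param positions Data frame with `precursor_name`, `xsome`,
#'   `contig_start`, `contig_end`, `strand`.
#' @param max_gap,same_strand_required As in [cluster_params()].
#' @param species_of Named character vector mapping precursor names to
#'   species codes, or `NULL` for single-genome positions.  Chromosome names
#'   recur across assemblies, so adjacency additionally requires equal
#'   species when given.
#' @return List of character vectors (sorted member names), one per
#'   component of size >= 2, ordered by leftmost start.
#' @export
brute_force_clusters <- function(positions, max_gap = 10000,
                                 same_strand_required = TRUE,
                                 species_of = NULL) {
  pre <- sort(unique(positions$precursor_name), method = "radix")
  n <- length(pre)
  if (n == 0L) return(list())
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (!is.null(species_of) && species_of[[pre[i]]] != species_of[[pre[j]]]) {
      adj[i, j] <- adj[j, i] <- FALSE
      next
    }
    a <- positions[positions$precursor_name == pre[i], , drop = FALSE]
    b <- positions[positions$precursor_name == pre[j], , drop = FALSE]
    hit <- FALSE
    for (x in seq_len(nrow(a))) for (y in seq_len(nrow(b))) {
      if (a$xsome[x] != b$xsome[y]) next
      if (same_strand_required && a$strand[x] != b$strand[y]) next
      gap <- max(a$contig_start[x], b$contig_start[y]) -
        min(a$contig_end[x], b$contig_end[y])
      if (max(0, gap) <= max_gap) { hit <- TRUE; break }
    }
    adj[i, j] <- adj[j, i] <- hit
  }
  # transitive closure (Warshall)
  for (k in seq_len(n)) adj <- adj | (adj[, k] %o% adj[k, ])
  seen <- rep(FALSE, n)
  comps <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    members <- pre[adj[i, ]]
    seen[adj[i, ]] <- TRUE
    if (length(members) >= 2L) comps[[length(comps) + 1L]] <- sort(members)
  }
  lefts <- vapply(comps, function(m)
    min(positions$contig_start[positions$precursor_name %in% m]), numeric(1))
  comps[order(lefts)]
}

# Name brute-force components with the production naming rule so manifests
# carry full expected cluster names.
name_components <- function(comps, positions, species_of) {
  named <- list()
  counters <- new.env(parent = emptyenv())
  meta <- lapply(comps, function(m) {
    sub <- positions[positions$precursor_name %in% m, , drop = FALSE]
    j <- which.min(sub$contig_start)
    list(members = m, species = species_of[[sub$precursor_name[j]]],
         xsome = sub$xsome[j], left = sub$contig_start[j])
  })
  key <- vapply(meta, function(m) paste(m$species, m$xsome), "")
  for (i in order(key, vapply(meta, function(m) m$left, numeric(1)),
                  method = "radix")) {
    m <- meta[[i]]
    kk <- paste(m$species, m$xsome)
    nn <- (if (exists(kk, envir = counters)) get(kk, envir = counters) else 0L) + 1L
    assign(kk, nn, envir = counters)
    named[[sprintf("%s-cluster-%s-%d", m$species, m$xsome, nn)]] <- m$members
  }
  named
}

#' Generate a synthetic release
#'
#' Writes every bundle member (EMBL-dialect hairpin records, family file,
#' per-species GFF, genome-context and species tables, hairpin and mature
#' FASTA, VERSION, manifest.json) under `destination` and returns the bundle
#' plus the ground-truth manifest.  Output is byte-identical for identical
#' specs.
#'
#' @param spec A [fixture_spec()].
#' @param destination Writable directory (created if needed).
#' @return `list(bundle = release_bundle, manifest = list)`.
#' @export
generate_release <- function(spec = fixture_spec(), destination = tempfile("release")) {
  stopifnot(inherits(spec, "fixture_spec"))
  ok <- dir.create(destination, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(destination))
    mirkit_error("mirkit_io_failure", sprintf("cannot create %s", destination))
  set.seed(spec$seed)

  codes <- paste0("sy", letters[seq_len(spec$n_species)])
  species <- df(
    abbreviation = codes,
    name = sprintf("Synthia %s", letters[seq_len(spec$n_species)]),
    division = "SYN",
    taxonomy = "Synthetica; Testales; Synthiidae; Synthia.",
    genome_assembly = ifelse(seq_len(spec$n_species) == spec$n_species &
                               spec$n_species > 1L, "",
                             sprintf("SYN%d", seq_len(spec$n_species))))

  n_per <- spec$precursors_per_species
  pre_rows <- list(); mat_rows <- list(); pm_rows <- list()
  feats <- list()  # per precursor: data frame of features for the EMBL writer

  mi_acc <- function(si, i) sprintf("MI9%02d%04d", si, i)
  mimat_acc <- function(si, i, j) sprintf("MIMAT9%02d%03d%d", si, i, j)

  # first pass: sequences and features
  for (si in seq_len(spec$n_species)) {
    sp <- codes[si]
    for (i in seq_len(n_per)) {
      pname <- sprintf("%s-mir-%d", sp, i)
      len1 <- sample(20:24, 1L)
      s1 <- sample(5:10, 1L)
      m1 <- list(accession = mimat_acc(si, i, 1L),
                 product = sprintf("%s-miR-%d", sp, i),
                 seq = rand_rna(len1), start = s1, end = s1 + len1 - 1L,
                 evidence = "experimental", experiment = "cloned",
                 similarity = "")
      fl <- list(m1)
      if (stats::runif(1) < spec$star_fraction) {
        len2 <- sample(20:24, 1L)
        s2 <- m1$end + sample(6:12, 1L)
        fl[[2]] <- list(accession = mimat_acc(si, i, 2L),
                        product = sprintf("%s-miR-%d*", sp, i),
                        seq = rand_rna(len2), start = s2, end = s2 + len2 - 1L,
                        evidence = "experimental", experiment = "cloned",
                        similarity = m1$product)
      }
      L <- max(62L, fl[[length(fl)]]$end + sample(8:20, 1L))
      pre_rows[[pname]] <- list(
        name = pname, accession = mi_acc(si, i),
        description = sprintf("%s %s stem-loop", species$name[si], pname),
        comment = sprintf("synthetic hairpin %s generated for integration testing; no biological meaning", pname),
        species = sp, length = L)
      feats[[pname]] <- fl
    }
  }

  # planted 7mer seed sharing: group g patches the first matures of the first
  # size_g hairpins of species g
  for (g in seq_along(spec$seed_share_group_sizes)) {
    size <- min(spec$seed_share_group_sizes[[g]], n_per)
    if (g > spec$n_species || size < 2L) next
    shared7 <- rand_rna(7L)
    for (i in seq_len(size)) {
      pname <- sprintf("%s-mir-%d", codes[g], i)
      f <- feats[[pname]][[1]]
      substr(f$seq, 2L, 8L) <- shared7
      feats[[pname]][[1]] <- f
    }
  }

  # planted shared mature: the last hairpin of species 1 carries the first
  # mature of its predecessor as an additional feature
  if (isTRUE(spec$shared_mature) && n_per >= 2L) {
    donor <- sprintf("%s-mir-%d", codes[1], n_per - 1L)
    host <- sprintf("%s-mir-%d", codes[1], n_per)
    dm <- feats[[donor]][[1]]
    hl <- feats[[host]]
    s <- hl[[length(hl)]]$end + sample(6:12, 1L)
    shared <- dm
    shared$start <- s; shared$end <- s + nchar(dm$seq) - 1L
    feats[[host]] <- c(hl, list(shared))
    pre_rows[[host]]$length <- max(pre_rows[[host]]$length,
                                   shared$end + sample(8:15, 1L))
  }

  # hairpin sequences with matures embedded
  for (pname in names(pre_rows)) {
    L <- pre_rows[[pname]]$length
    seqp <- rand_rna(L)
    for (f in feats[[pname]]) substr(seqp, f$start, f$end) <- f$seq
    pre_rows[[pname]]$sequence <- seqp
    # embedding may overwrite: re-read the authoritative excised sequences
    feats[[pname]] <- lapply(feats[[pname]], function(f) {
      f$seq <- substr(seqp, f$start, f$end); f
    })
  }

  # mature and association tables (dedup by accession)
  seen <- character()
  for (pname in names(pre_rows)) {
    for (f in feats[[pname]]) {
      if (!f$accession %in% seen) {
        seen <- c(seen, f$accession)
        mat_rows[[f$accession]] <- df(
          name = f$product, accession = f$accession, evidence = f$evidence,
          experiment = f$experiment, similarity = f$similarity, sequence = f$seq)
      }
      pm_rows[[length(pm_rows) + 1L]] <- df(precursor_name = pname,
                                            mature_name = f$product)
    }
  }

  # families: two families over species 1 (members 1..3) and species 2
  # (members 1..3), when they exist; remaining precursors are family-free
  fam_rows <- list()
  fam_of <- stats::setNames(rep(NA_character_, length(pre_rows)), names(pre_rows))
  nf <- min(2L, spec$n_species)
  for (g in seq_len(nf)) {
    size <- min(3L, n_per)
    fname <- sprintf("syn-fam-%d", g)
    members <- sprintf("%s-mir-%d", codes[g], seq_len(size))
    fam_rows[[g]] <- list(name = fname,
                          accession = sprintf("MIPF9%06d", g),
                          members = vapply(members, function(p)
                            pre_rows[[p]]$accession, ""))
    fam_of[members] <- fname
  }

  # papers: a pool; hairpins 1 and 2 of species 1 share paper 1
  n_pre_total <- length(pre_rows)
  pool_n <- max(2L, ceiling(n_pre_total * 0.8))
  paper_pool <- df(
    medline = sprintf("90%06d", seq_len(pool_n)),
    title = sprintf("Synthetic annotation study %d of small RNA loci", seq_len(pool_n)),
    author = "Doe J., Roe R.",
    journal = sprintf("J Synth RNA %d:1-10(2009)", seq_len(pool_n)))
  refs_of <- list()
  gi <- 0L
  for (pname in names(pre_rows)) {
    gi <- gi + 1L
    n_refs <- sample(seq_len(spec$papers_per_precursor), 1L)
    picks <- sample(pool_n, n_refs)
    if (gi <= 2L) picks <- unique(c(1L, picks))[seq_len(max(1L, n_refs))]
    refs_of[[pname]] <- sort(picks)
  }
  used_papers <- sort(unique(unlist(refs_of)))

  # genome positions: chr1 ladder per assembled species, gaps bracketing the
  # threshold; strand flip on the second hairpin of species 2; hairpin 1 of
  # species 1 gets a second locus on chr9
  gap_pattern <- c(500, spec$cluster_max_gap, spec$cluster_max_gap + 1, 700)
  pos_rows <- list()
  for (si in seq_len(spec$n_species)) {
    if (!nzchar(species$genome_assembly[si])) next
    sp <- codes[si]
    gaps <- rep(gap_pattern, length.out = max(0L, n_per - 1L))
    start <- 1000L
    for (i in seq_len(n_per)) {
      pname <- sprintf("%s-mir-%d", sp, i)
      width <- pre_rows[[pname]]$length
      strand <- if (si == 2L && i == 2L) "-" else "+"
      pos_rows[[length(pos_rows) + 1L]] <- df(
        precursor_name = pname, xsome = "chr1",
        contig_start = start, contig_end = start + width - 1L, strand = strand)
      if (si == 1L && i == 1L) {
        pos_rows[[length(pos_rows) + 1L]] <- df(
          precursor_name = pname, xsome = "chr9",
          contig_start = 1000000L, contig_end = 1000000L + width - 1L,
          strand = "+")
      }
      # next interval starts so that the hull gap equals the planted value:
      # gap metric = start_next - end_this when positive
      if (i < n_per) start <- start + width - 1L + as.integer(gaps[[i]])
    }
  }
  positions <- if (length(pos_rows)) do.call(rbind, pos_rows) else
    df(precursor_name = empty_chr, xsome = empty_chr,
       contig_start = integer(0), contig_end = integer(0), strand = empty_chr)
  # synthetic position ids in file order per precursor
  ordn <- stats::setNames(rep(0L, length(pre_rows)), names(pre_rows))
  positions$id <- vapply(seq_len(nrow(positions)), function(r) {
    p <- positions$precursor_name[r]
    ordn[[p]] <<- ordn[[p]] + 1L
    sprintf("%s-pos-%d", p, ordn[[p]])
  }, "")

  # genome contexts
  ctx_rows <- list()
  for (pname in names(pre_rows)) {
    n_ctx <- sample(0:spec$contexts_per_precursor, 1L)
    for (j in seq_len(n_ctx)) {
      ctx_rows[[length(ctx_rows) + 1L]] <- df(
        id = sprintf("%s-ctx-%d", pname, j), precursor_name = pname,
        overlap_sense = sample(c("sense", "antisense", "unknown"), 1L),
        overlap_type = sample(c("intron", "exon", "intergenic"), 1L),
        transcript_source = "synthdb",
        transcript_name = sprintf("GENE%03d", sample(999L, 1L)))
    }
  }
  contexts <- if (length(ctx_rows)) do.call(rbind, ctx_rows) else
    df(id = empty_chr, precursor_name = empty_chr, overlap_sense = empty_chr,
       overlap_type = empty_chr, transcript_source = empty_chr,
       transcript_name = empty_chr)

  # ---- write the bundle ----------------------------------------------------
  precursors <- do.call(rbind, lapply(names(pre_rows), function(p) {
    r <- pre_rows[[p]]
    df(name = r$name, accession = r$accession, description = r$description,
       sequence = r$sequence, comment = r$comment, species = r$species,
       family = unname(fam_of[[p]]))
  }))
  matures <- do.call(rbind, unname(mat_rows))
  pm <- unique(do.call(rbind, pm_rows))

  write_bundle_files(destination, spec$version, species, precursors, matures,
                     feats, pre_rows, fam_rows, paper_pool, refs_of, used_papers,
                     positions, contexts)

  species_of <- stats::setNames(precursors$species, precursors$name)
  comps <- brute_force_clusters(positions, max_gap = spec$cluster_max_gap,
                                same_strand_required = TRUE,
                                species_of = species_of)
  clusters <- name_components(comps, positions, species_of)

  seed_fams <- lapply(c(6L, 7L), function(k) {
    s <- split(matures$name, substr(matures$sequence, 2L, k + 1L))
    lapply(s, function(x) sort(x, method = "radix"))
  })
  names(seed_fams) <- c("k6", "k7")

  manifest <- list(
    version = spec$version,
    counts = list(
      species = nrow(species), precursor = nrow(precursors),
      mature = nrow(matures), precursor_family = length(fam_rows),
      paper = length(used_papers), genome_position = nrow(positions),
      genome_context = nrow(contexts)),
    species = species,
    precursors = precursors,
    matures = matures,
    precursor_mature = pm,
    papers = paper_pool[used_papers, , drop = FALSE],
    precursor_paper = do.call(rbind, lapply(names(refs_of), function(p)
      df(precursor_name = p, medline = paper_pool$medline[refs_of[[p]]]))),
    families = df(name = vapply(fam_rows, `[[`, "", "name"),
                  accession = vapply(fam_rows, `[[`, "", "accession")),
    positions = positions[, c("id", "precursor_name", "xsome", "contig_start",
                              "contig_end", "strand")],
    contexts = contexts,
    seed_families = seed_fams,
    clusters = list(params = list(max_gap = spec$cluster_max_gap,
                                  same_strand_required = TRUE),
                    members = clusters)
  )
  jsonlite::write_json(manifest, file.path(destination, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  list(bundle = read_release_bundle(destination, version = spec$version),
       manifest = manifest)
}

wrap_seq <- function(s, width = 60L, indent = "     ") {
  n <- nchar(s)
  starts <- seq(1L, n, by = width)
  lines <- vapply(starts, function(i) {
    chunk <- substr(s, i, min(n, i + width - 1L))
    # blocks of 10, miRBase style, with the running total right-aligned
    grouped <- paste(regmatches(chunk,
      gregexpr(".{1,10}", chunk))[[1]], collapse = " ")
    sprintf("%s%-66s%6d", indent, tolower(grouped), min(n, i + width - 1L))
  }, "")
  paste(lines, collapse = "\n")
}

write_bundle_files <- function(dir, version, species, precursors, matures,
                               feats, pre_rows, fam_rows, paper_pool, refs_of,
                               used_papers, positions, contexts) {
  writeLines(version, file.path(dir, "VERSION"))

  # EMBL-dialect hairpin records
  out <- character()
  for (p in precursors$name) {
    r <- pre_rows[[p]]
    seqp <- r$sequence
    counts <- vapply(c("A", "C", "G", "U"), function(b)
      sum(strsplit(seqp, "")[[1]] == b), integer(1))
    rec <- c(
      sprintf("ID   %s    standard; RNA; %s; %d BP.", r$name,
              toupper(r$species), nchar(seqp)),
      "XX",
      sprintf("AC   %s;", r$accession),
      "XX",
      sprintf("DE   %s", r$description),
      "XX")
    for (ri in seq_along(refs_of[[p]])) {
      pp <- paper_pool[refs_of[[p]][ri], ]
      rec <- c(rec,
               sprintf("RN   [%d]", ri),
               sprintf("RX   MEDLINE; %s.", pp$medline),
               sprintf("RA   %s;", pp$author),
               sprintf("RT   \"%s\";", pp$title),
               sprintf("RL   %s.", pp$journal),
               "XX")
    }
    rec <- c(rec, sprintf("CC   %s", r$comment), "XX")
    for (f in feats[[p]]) {
      rec <- c(rec,
               sprintf("FT   miRNA           %d..%d", f$start, f$end),
               sprintf("FT                   /accession=\"%s\"", f$accession),
               sprintf("FT                   /product=\"%s\"", f$product),
               sprintf("FT                   /evidence=%s", f$evidence),
               sprintf("FT                   /experiment=\"%s\"", f$experiment))
      if (nzchar(f$similarity))
        rec <- c(rec, sprintf("FT                   /similarity=\"%s\"", f$similarity))
    }
    rec <- c(rec, "XX",
             sprintf("SQ   Sequence %d BP; %d A; %d C; %d G; %d U; 0 other;",
                     nchar(seqp), counts[["A"]], counts[["C"]], counts[["G"]],
                     counts[["U"]]),
             wrap_seq(seqp),
             "//")
    out <- c(out, rec)
  }
  writeLines(out, file.path(dir, "miRNA.dat"))

  # family file
  fam_lines <- character()
  for (f in fam_rows) {
    fam_lines <- c(fam_lines,
                   sprintf("AC   %s", f$accession),
                   sprintf("ID   %s", f$name),
                   sprintf("MI   %s  %s", f$members, names(f$members)),
                   "//")
  }
  writeLines(fam_lines, file.path(dir, "miFam.dat"))

  # per-species GFF (GFF2-style attribute dialect)
  dir.create(file.path(dir, "genomes"), showWarnings = FALSE)
  acc_of <- stats::setNames(precursors$accession, precursors$name)
  sp_of <- stats::setNames(precursors$species, precursors$name)
  for (sp in unique(unname(sp_of[positions$precursor_name]))) {
    sub <- positions[sp_of[positions$precursor_name] == sp, , drop = FALSE]
    lines <- c(sprintf("# synthetic genome coordinates, species %s", sp),
               sprintf("%s\t.\tmiRNA\t%d\t%d\t.\t%s\t.\tACC=\"%s\"; ID=\"%s\";",
                       sub$xsome, sub$contig_start, sub$contig_end, sub$strand,
                       acc_of[sub$precursor_name], sub$precursor_name))
    writeLines(lines, file.path(dir, "genomes", sprintf("%s.gff", sp)))
  }

  # genome-context table
  writeLines(sprintf("%s\t%s\t%s\t%s\t%s",
                     acc_of[contexts$precursor_name], contexts$transcript_source,
                     contexts$transcript_name, contexts$overlap_sense,
                     contexts$overlap_type),
             file.path(dir, "genome_context.txt"))

  # species table
  writeLines(sprintf("%s\t%s\t%s\t%s\t%s", species$abbreviation, species$name,
                     species$division, species$taxonomy,
                     species$genome_assembly),
             file.path(dir, "organisms.txt"))

  # FASTA pair
  writeLines(sprintf(">%s %s %s\n%s", precursors$name, precursors$accession,
                     precursors$description, precursors$sequence),
             file.path(dir, "hairpin.fa"), sep = "\n")
  writeLines(sprintf(">%s %s\n%s", matures$name, matures$accession,
                     matures$sequence),
             file.path(dir, "mature.fa"), sep = "\n")
  invisible(dir)
}

#' Compare an ingested (and optionally derived) dataset to a manifest
#'
#' @param dataset A `mir_dataset` built from a generated bundle.
#' @param manifest The manifest returned by [generate_release()].
#' @param check_derived Also compare seed families (k = 6, 7) and clusters
#'   (under the manifest's stated parameters); requires the derivations to
#'   have been run.
#' @return Character vector of discrepancy descriptions; empty means exact
#'   agreement.
#' @export
compare_to_manifest <- function(dataset, manifest, check_derived = FALSE) {
  bad <- character()
  note <- function(...) bad <<- c(bad, sprintf(...))
  cmp_set <- function(what, got, want) {
    got <- sort(got, method = "radix"); want <- sort(want, method = "radix")
    if (!identical(got, want)) {
      note("%s differ: %d ingested vs %d expected (e.g. %s)", what,
           length(got), length(want),
           paste(utils::head(c(setdiff(want, got), setdiff(got, want)), 3L),
                 collapse = ", "))
    }
  }
  t <- dataset$tab
  cmp_set("species", t$species$abbreviation, manifest$species$abbreviation)
  cmp_set("precursor names", t$precursor$name, manifest$precursors$name)
  cmp_set("mature names", t$mature$name, manifest$matures$name)
  cmp_set("paper medlines", t$paper$medline, manifest$papers$medline)
  cmp_set("position ids", t$genome_position$id, manifest$positions$id)
  cmp_set("context ids", t$genome_context$id, manifest$contexts$id)
  cmp_set("family names", t$precursor_family$name, manifest$families$name)

  m <- manifest$precursors
  for (i in seq_len(nrow(m))) {
    j <- match(m$name[i], t$precursor$name)
    if (is.na(j)) next
    if (t$precursor$sequence[j] != m$sequence[i])
      note("precursor %s sequence differs", m$name[i])
    if (t$precursor$accession[j] != m$accession[i])
      note("precursor %s accession differs", m$name[i])
    if (t$precursor$comment[j] != m$comment[i])
      note("precursor %s comment differs", m$name[i])
    fam <- t$precursor$family_name[j]
    if (!identical(is.na(fam), is.na(m$family[i])) ||
        (!is.na(fam) && fam != m$family[i]))
      note("precursor %s family differs", m$name[i])
  }
  mm <- manifest$matures
  for (i in seq_len(nrow(mm))) {
    j <- match(mm$name[i], t$mature$name)
    if (is.na(j)) next
    if (t$mature$sequence[j] != mm$sequence[i])
      note("mature %s sequence differs", mm$name[i])
    if (t$mature$accession[j] != mm$accession[i])
      note("mature %s accession differs", mm$name[i])
  }
  cmp_set("precursor-mature links",
          paste(t$precursor_mature$precursor_name, t$precursor_mature$mature_name),
          paste(manifest$precursor_mature$precursor_name,
                manifest$precursor_mature$mature_name))
  cmp_set("precursor-paper links",
          paste(t$precursor_paper$precursor_name, t$precursor_paper$medline),
          paste(manifest$precursor_paper$precursor_name,
                manifest$precursor_paper$medline))
  pos <- manifest$positions
  cmp_set("position coordinates",
          sprintf("%s:%s:%d-%d%s", t$genome_position$id, t$genome_position$xsome,
                  t$genome_position$contig_start, t$genome_position$contig_end,
                  t$genome_position$strand),
          sprintf("%s:%s:%d-%d%s", pos$id, pos$xsome, pos$contig_start,
                  pos$contig_end, pos$strand))

  if (isTRUE(check_derived)) {
    for (kk in c(6L, 7L)) {
      want <- manifest$seed_families[[sprintf("k%d", kk)]]
      ms <- t$mature_seed_family[t$mature_seed_family$k == kk, , drop = FALSE]
      got <- split(ms$mature_name, ms$family_name)
      got <- lapply(got, function(x) sort(x, method = "radix"))
      cmp_set(sprintf("%dmer seed family names", kk), names(got), names(want))
      for (s in intersect(names(got), names(want))) {
        if (!identical(got[[s]], want[[s]]))
          note("%dmer family %s membership differs", kk, s)
      }
    }
    want <- manifest$clusters$members
    p <- t$precursor
    got <- split(p$name[!is.na(p$cluster_name)],
                 p$cluster_name[!is.na(p$cluster_name)])
    got <- lapply(got, function(x) sort(x, method = "radix"))
    cmp_set("cluster names", names(got), names(want))
    for (s in intersect(names(got), names(want))) {
      if (!identical(got[[s]], unname(sort(unlist(want[[s]]), method = "radix"))))
        note("cluster %s membership differs", s)
    }
  }
  bad
}
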