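# Derived groupings: seed families of matures and genomic precursor clusters.
# Both are computed from the dataset, never read from input files, and both
# derivations are idempotent (rerunning replaces the previous result).

#' Extract the seed of a mature miRNA
#'
#' The seed is bases 2--7 (6mer) or 2--8 (7mer) of the mature sequence, the
#' primary determinant of target recognition.
#'
#' @param sequence RNA string.
#' @param k Seed length, 6 or 7.
#' @return RNA string of length `k`.
#' @export
extract_seed <- function(sequence, k = 7L) {
  k <- as.integer(k)
  if (!k %in% c(6L, 7L))
    mirkit_error("mirkit_bad_seed_length", "seed length k must be 6 or 7")
  if (nchar(sequence) < k + 1L)
    mirkit_error("mirkit_too_short", sprintf(
      "sequence of length %d is too short for a %dmer seed (needs >= %d nt)",
      nchar(sequence), k, k + 1L))
  substr(sequence, 2L, k + 1L)
}

#' Derive seed families
#'
#' Partitions every mature of length >= k+1 into families of identical k-mer
#' seed.  Families are named by their seed sequence (collision-free and
#' self-describing).  Families for the 6mer and 7mer groupings coexist,
#' distinguished by sequence length; rerunning for a given `k` replaces that
#' grouping only.  Matures too short to have a seed are left unassigned and
#' logged.
#'
#' @param dataset A `mir_dataset` (mutated in place).
#' @param k Seed length, 6 or 7.
#' @return The dataset, invisibly.
#' @export
build_seed_families <- function(dataset, k = 7L) {
  k <- as.integer(k)
  if (!k %in% c(6L, 7L))
    mirkit_error("mirkit_bad_seed_length", "seed length k must be 6 or 7")
  m <- dataset$tab$mature
  long_enough <- nchar(m$sequence) >= k + 1L
  for (nm in m$name[!long_enough]) {
    mirkit_log("warn", sprintf("mature %s too short for %dmer seed; unassigned",
                               nm, k))
  }
  seeds <- substr(m$sequence[long_enough], 2L, k + 1L)
  fam <- df(name = sort(unique(seeds), method = "radix"))
  fam$sequence <- fam$name
  fam$k <- k

  keep_f <- dataset$tab$seed_family$k != k
  dataset$tab$seed_family <- rbind(dataset$tab$seed_family[keep_f, , drop = FALSE],
                                   fam)
  keep_m <- dataset$tab$mature_seed_family$k != k
  dataset$tab$mature_seed_family <- rbind(
    dataset$tab$mature_seed_family[keep_m, , drop = FALSE],
    df(mature_name = m$name[long_enough], family_name = seeds, k = k))
  rownames(dataset$tab$seed_family) <- NULL
  rownames(dataset$tab$mature_seed_family) <- NULL
  invisible(dataset)
}

#' Clustering parameters
#'
#' @param max_gap Maximum gap in nucleotides between the interval hulls of
#'   two precursor loci for them to be adjacent (0 for overlapping
#'   intervals).  Default 10000, the conventional scale of miRNA
#'   polycistrons.
#' @param same_strand_required Whether adjacency additionally requires equal
#'   strand (default `TRUE`: co-transcribed hairpins share one primary
#'   transcript).
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(max_gap = 10000L, same_strand_required = TRUE) {
  max_gap <- as.numeric(max_gap)
  if (!is.finite(max_gap) || max_gap < 0)
    mirkit_error("mirkit_bad_params", "max_gap must be finite and >= 0")
  structure(list(max_gap = max_gap,
                 same_strand_required = isTRUE(same_strand_required)),
            class = "cluster_params")
}

interval_gap <- function(s1, e1, s2, e2) pmax(0, pmax(s1, s2) - pmin(e1, e2))

#' Derive precursor clusters
#'
#' Single-linkage connected components over genomic proximity: two precursors
#' are adjacent iff they have loci on the same chromosome (and strand, when
#' `same_strand_required`) whose interval gap is at most `max_gap`.
#' Components of two or more precursors become clusters named
#' `"<species>-cluster-<xsome>-<ordinal>"`, with ordinals assigned per
#' species and chromosome in order of leftmost start.  Singletons and
#' precursors without genome positions stay unclustered.  Idempotent.
#'
#' @param dataset A `mir_dataset` (mutated in place).
#' @param params A [cluster_params()] object.
#' @return The dataset, invisibly.
#' @export
build_precursor_clusters <- function(dataset, params = cluster_params()) {
  gp <- dataset$tab$genome_position
  pre <- dataset$tab$precursor
  dataset$tab$precursor$cluster_name <- NA_character_
  dataset$tab$precursor_cluster <- df(name = empty_chr)
  if (nrow(gp) == 0L) return(invisible(dataset))

  # union-find over precursors
  parent <- stats::setNames(seq_len(nrow(pre)), pre$name)
  find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[[max(ri, rj)]] <<- min(ri, rj)
  }

  # single-linkage sweep per species + chromosome (and strand, when
  # required): chromosome names are only unique within one species' assembly,
  # so proximity never crosses species.  Intervals sorted by start; a new
  # interval joins the running component when its start is within max_gap of
  # the furthest end seen so far.
  sp <- pre$species_abbreviation[match(gp$precursor_name, pre$name)]
  grp <- if (params$same_strand_required) paste(sp, gp$xsome, gp$strand)
         else paste(sp, gp$xsome)
  for (g in unique(grp)) {
    sub <- gp[grp == g, , drop = FALSE]
    sub <- sub[order(sub$contig_start, sub$contig_end, sub$precursor_name,
                     method = "radix"), , drop = FALSE]
    run_end <- NULL
    run_anchor <- NULL
    for (i in seq_len(nrow(sub))) {
      pi <- match(sub$precursor_name[i], pre$name)
      if (is.na(pi)) next
      if (!is.null(run_end) && sub$contig_start[i] - run_end <= params$max_gap) {
        union_(run_anchor, pi)
        run_end <- max(run_end, sub$contig_end[i])
      } else {
        run_anchor <- pi
        run_end <- sub$contig_end[i]
      }
    }
  }

  roots <- vapply(seq_len(nrow(pre)), find, integer(1))
  comp <- split(pre$name, roots)
  comp <- comp[vapply(comp, length, integer(1)) >= 2L]
  if (length(comp) == 0L) return(invisible(dataset))

  # name components by species + chromosome of their leftmost locus,
  # ordinals per (species, xsome) by leftmost start
  meta <- lapply(comp, function(members) {
    sub <- gp[gp$precursor_name %in% members, , drop = FALSE]
    j <- which.min(sub$contig_start)
    left <- sub[j, , drop = FALSE]
    sp <- pre$species_abbreviation[match(left$precursor_name, pre$name)]
    list(members = members, species = sp, xsome = left$xsome,
         leftmost = left$contig_start)
  })
  key <- vapply(meta, function(m) paste(m$species, m$xsome), "")
  ord <- order(key, vapply(meta, function(m) m$leftmost, numeric(1)),
               method = "radix")
  counters <- new.env(parent = emptyenv())
  cl_rows <- list()
  for (i in ord) {
    m <- meta[[i]]
    kk <- paste(m$species, m$xsome)
    n <- (if (exists(kk, envir = counters)) get(kk, envir = counters) else 0L) + 1L
    assign(kk, n, envir = counters)
    cname <- sprintf("%s-cluster-%s-%d", m$species, m$xsome, n)
    cl_rows[[length(cl_rows) + 1L]] <- df(name = cname)
    dataset$tab$precursor$cluster_name[
      match(m$members, dataset$tab$precursor$name)] <- cname
  }
  dataset$tab$precursor_cluster <- do.call(rbind, cl_rows)
  invisible(dataset)
}

#' Precursors in a genomic neighborhood
#'
#' All other precursors of the same species having a locus on the same
#' chromosome overlapping `[start - window, end + window]` for any locus of
#' the query precursor, ordered by the start coordinate of their leftmost
#' qualifying locus.
#'
#' @param dataset A `mir_dataset`.
#' @param precursor A precursor entity or its name.
#' @param window Window size in nucleotides (default 1000).
#' @return List of precursor entities.
#' @export
neighborhood <- function(dataset, precursor, window = 1000L) {
  name <- if (inherits(precursor, "mir_entity")) precursor$name else precursor
  gp <- dataset$tab$genome_position
  pre <- dataset$tab$precursor
  sp <- pre$species_abbreviation[match(gp$precursor_name, pre$name)]
  my_sp <- pre$species_abbreviation[match(name, pre$name)]
  mine <- gp[gp$precursor_name == name, , drop = FALSE]
  if (nrow(mine) == 0L)
    mirkit_error("mirkit_no_position",
                 sprintf("precursor %s has no genome position", name))
  hits <- list()
  for (i in seq_len(nrow(mine))) {
    lo <- mine$contig_start[i] - window
    hi <- mine$contig_end[i] + window
    sub <- gp[sp == my_sp & gp$xsome == mine$xsome[i] &
                gp$precursor_name != name &
                gp$contig_start <= hi & gp$contig_end >= lo, , drop = FALSE]
    hits[[length(hits) + 1L]] <- sub
  }
  hits <- do.call(rbind, hits)
  if (nrow(hits) == 0L) return(list())
  starts <- tapply(hits$contig_start, hits$precursor_name, min)
  nms <- names(starts)[order(as.vector(starts), names(starts), method = "radix")]
  lapply(nms, function(n) get_entity(dataset, "precursor", n))
}
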