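# Parsers for the remaining bundle members: family file (miFam dialect),
# per-species genome coordinates (GFF, both attribute dialects), and the
# tab-delimited genome-context and species dumps.

skipped_attr <- function(skipped) {
  if (length(skipped)) do.call(rbind, skipped)
  else df(line = integer(0), reason = empty_chr)
}

#' Parse the precursor-family file
#'
#' Blocks of `AC` / `ID` / `MI` lines terminated by `//`; every `MI` line
#' names one member precursor accession (second token may repeat the
#' precursor name and is ignored).
#'
#' @param text File path, single string, or character vector of lines.
#' @return List of `list(accession, name, members)`; attribute `"skipped"`
#'   records malformed blocks.
#' @export
parse_family_file <- function(text) {
  lines <- as_lines(text)
  fams <- list()
  skipped <- list()
  cur <- list(accession = NA_character_, name = NA_character_, members = empty_chr)
  cur_start <- 1L
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    tag <- substr(line, 1L, 2L)
    body <- trimws(sub("^..\\s*", "", line))
    if (tag == "//") {
      if (!is.na(cur$name) && length(cur$members)) {
        fams[[length(fams) + 1L]] <- cur
      } else if (!is.na(cur$name) || !is.na(cur$accession)) {
        skipped[[length(skipped) + 1L]] <-
          df(line = cur_start, reason = "family block without ID or MI members")
        mirkit_log("warn", sprintf("family block at line %d skipped", cur_start))
      }
      cur <- list(accession = NA_character_, name = NA_character_,
                  members = empty_chr)
      cur_start <- i + 1L
    } else if (tag == "AC") {
      cur$accession <- strip_trailing(strsplit(body, "\\s+")[[1]][[1]], ";")
    } else if (tag == "ID") {
      cur$name <- strsplit(body, "\\s+")[[1]][[1]]
    } else if (tag == "MI") {
      acc <- strsplit(body, "\\s+")[[1]][[1]]
      cur$members <- c(cur$members, strip_trailing(acc, ";"))
    }
  }
  structure(fams, skipped = skipped_attr(skipped))
}

# Extract the precursor identifier from a GFF attribute column.  Accepts the
# GFF2-style 'ACC="MI0000001"; ID="hsa-mir-21";' dialect and GFF3-style
# 'ID=MI0000001;Name=hsa-mir-21' key=value pairs.  Accession preferred.
gff_identifier <- function(attrs) {
  take <- function(keys) {
    for (key in keys) {
      m <- regmatches(attrs, regexec(
        sprintf('%s[= ]+"?([^";]+)"?', key), attrs))[[1]]
      if (length(m) == 2L && nzchar(m[[2]])) return(trimws(m[[2]]))
    }
    NULL
  }
  acc <- take(c("ACC", "accession_number", "accession"))
  if (!is.null(acc) && grepl("^MI\\d+$", acc)) return(acc)
  id <- take("ID")
  if (!is.null(id) && grepl("^MI\\d+$", id)) return(id)
  take(c("Name", "ID", "derives_from")) %||% acc %||% NA_character_
}

#' Parse a genome-coordinates (GFF) stream
#'
#' Coordinates are kept 1-based inclusive exactly as in the file.  Lines with
#' a bad column count, non-integer coordinates, `start > end`, or an
#' unrecognizable strand are skipped and logged, never fatal.
#'
#' @param text File path, single string, or character vector of lines.
#' @param species Species code the file belongs to (recorded, not validated).
#' @return Data frame (`identifier`, `xsome`, `contig_start`, `contig_end`,
#'   `strand`, `species`); attribute `"skipped"` lists skipped lines.
#' @export
parse_coordinates <- function(text, species = NA_character_) {
  lines <- as_lines(text)
  rows <- list()
  skipped <- list()
  note <- function(i, reason) {
    skipped[[length(skipped) + 1L]] <<- df(line = i, reason = reason)
    mirkit_log("warn", sprintf("coordinates line %d: %s", i, reason))
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 9L) { note(i, "fewer than 9 tab-delimited columns"); next }
    start <- suppressWarnings(as.integer(parts[[4]]))
    end <- suppressWarnings(as.integer(parts[[5]]))
    if (is.na(start) || is.na(end)) { note(i, "non-integer coordinates"); next }
    if (start > end) { note(i, sprintf("start %d > end %d", start, end)); next }
    strand <- parts[[7]]
    if (!strand %in% c("+", "-")) { note(i, sprintf("bad strand '%s'", strand)); next }
    id <- gff_identifier(parts[[9]])
    if (is.na(id)) { note(i, "no precursor identifier in attributes"); next }
    rows[[length(rows) + 1L]] <- df(
      identifier = id, xsome = parts[[1]], contig_start = start,
      contig_end = end, strand = strand, species = species)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    df(identifier = empty_chr, xsome = empty_chr, contig_start = integer(0),
       contig_end = integer(0), strand = empty_chr, species = empty_chr)
  structure(out, skipped = skipped_attr(skipped))
}

parse_tab_table <- function(text, n_cols, col_names, what) {
  lines <- as_lines(text)
  rows <- list()
  skipped <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    # a trailing empty field is legal (e.g. absent genome assembly)
    if (length(parts) == n_cols - 1L && grepl("\t$", line)) parts <- c(parts, "")
    if (length(parts) != n_cols) {
      skipped[[length(skipped) + 1L]] <- df(line = i, reason = sprintf(
        "expected %d columns, found %d", n_cols, length(parts)))
      mirkit_log("warn", sprintf("%s line %d skipped (%d columns)",
                                 what, i, length(parts)))
      next
    }
    r <- as.list(parts)
    names(r) <- col_names
    rows[[length(rows) + 1L]] <- as.data.frame(r, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    r <- rep(list(empty_chr), n_cols); names(r) <- col_names
    as.data.frame(r, stringsAsFactors = FALSE)
  }
  structure(out, skipped = skipped_attr(skipped))
}

#' Parse the genome-context table
#'
#' Tab-delimited, one row per overlap: precursor id (accession or name),
#' transcript_source, transcript_name, overlap_sense, overlap_type.
#' Duplicate rows are kept (each is a distinct overlap record).
#'
#' @param text File path, single string, or character vector of lines.
#' @return Data frame with one row per overlap; attribute `"skipped"` lists
#'   rows with a wrong column count.
#' @export
parse_context_table <- function(text) {
  parse_tab_table(text, 5L,
    c("identifier", "transcript_source", "transcript_name",
      "overlap_sense", "overlap_type"),
    "genome context")
}

#' Parse the species table
#'
#' Tab-delimited: abbreviation, name, division, taxonomy, genome_assembly
#' (the last may be empty for species without an assembly).
#'
#' @param text File path, single string, or character vector of lines.
#' @return Data frame of species rows; attribute `"skipped"` as elsewhere.
#' @export
parse_species_table <- function(text) {
  parse_tab_table(text, 5L,
    c("abbreviation", "name", "division", "taxonomy", "genome_assembly"),
    "species table")
}
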