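# Parser for the EMBL-dialect hairpin record file (miRNA.dat).
#
# Each record is a block of two-letter-tagged lines terminated by "//":
#   ID    name + metadata            AC  accession (MIxxxxxxx;)
#   DE    description                CC  free-text comment lines
#   RN/RX/RA/RT/RL                   literature reference blocks
#   FT milRNA a..b + /qualifiers     mature features within the hairpin
#   SQ + continuation lines          the hairpin sequence (DNA or RNA case)
# No installed R package parses EMBL feature tables, so this parser is
# hand-written; it is total: malformed records are reported and skipped.

new_raw_record <- function() {
  list(name = NA_character_, accession = NA_character_,
       description = "", comment = empty_chr, sequence = "",
       matures = df(accession = empty_chr, product = empty_chr,
                    start = integer(0), end = integer(0),
                    evidence = empty_chr, experiment = empty_chr,
                    similarity = empty_chr),
       references = df(medline = empty_chr, title = empty_chr,
                       author = empty_chr, journal = empty_chr))
}

strip_trailing <- function(x, chars = "[.;]") sub(paste0(chars, "\\s*$"), "", x)

ft_qualifier <- function(line) {
  m <- regmatches(line, regexec("^FT\\s+/([a-z_]+)=?\"?([^\"]*)\"?\\s*$", line))[[1]]
  if (length(m) == 3L) list(name = m[[2]], value = m[[3]]) else NULL
}

#' Parse EMBL-dialect hairpin records
#'
#' Turns the hairpin record file of a release into a list of raw precursor
#' records (name, accession, description, comment, species code, sequence,
#' mature features, literature references).  Comment (`CC`) lines are joined
#' with single spaces; reference authors keep their `RA` text with the
#' trailing `;` stripped.  Sequences are normalized to uppercase RNA.
#' Records whose mature features fall outside `1..nchar(sequence)` are
#' reported and skipped; parsing never fails on malformed input.
#'
#' @param text File path, single string, or character vector of lines.
#' @return List of raw records; attribute `"skipped"` is a data frame
#'   (`line`, `reason`) describing every skipped record or line.
#' @export
parse_hairpin_records <- function(text) {
  lines <- as_lines(text)
  records <- list()
  skipped <- list()
  note_skip <- function(line_no, reason) {
    skipped[[length(skipped) + 1L]] <<- df(line = line_no, reason = reason)
    mirkit_log("warn", sprintf("hairpin record line %d: %s", line_no, reason))
  }

  rec <- NULL
  rec_start <- 1L
  refs <- list()
  cur_ref <- NULL
  feats <- list()
  cur_feat <- NULL
  in_seq <- FALSE
  seq_chunks <- character()

  flush_ref <- function() {
    if (!is.null(cur_ref)) refs[[length(refs) + 1L]] <<- cur_ref
    cur_ref <<- NULL
  }
  flush_feat <- function() {
    if (!is.null(cur_feat)) feats[[length(feats) + 1L]] <<- cur_feat
    cur_feat <<- NULL
  }

  reset <- function(line_no) {
    rec <<- new_raw_record()
    rec_start <<- line_no
    refs <<- list(); cur_ref <<- NULL
    feats <<- list(); cur_feat <<- NULL
    in_seq <<- FALSE
    seq_chunks <<- character()
  }
  reset(1L)

  finish_record <- function(line_no) {
    flush_ref(); flush_feat()
    rec$sequence <- as_rna(paste(seq_chunks, collapse = ""))
    if (is.na(rec$name) || !nzchar(rec$name)) {
      note_skip(rec_start, "record without ID line")
      return(invisible())
    }
    if (is.na(rec$accession)) {
      note_skip(rec_start, sprintf("record %s without AC line", rec$name))
      return(invisible())
    }
    if (!nzchar(rec$sequence)) {
      note_skip(rec_start, sprintf("record %s without sequence", rec$name))
      return(invisible())
    }
    if (length(feats)) {
      fdf <- do.call(rbind, feats)
      n <- nchar(rec$sequence)
      ok <- fdf$start >= 1L & fdf$start <= fdf$end & fdf$end <= n
      if (!all(ok)) {
        note_skip(rec_start, sprintf(
          "record %s: mature feature outside 1..%d (%s)", rec$name, n,
          paste(sprintf("%d..%d", fdf$start[!ok], fdf$end[!ok]), collapse = ", ")))
        return(invisible())
      }
      rec$matures <- fdf
    }
    if (length(refs)) {
      rec$references <- do.call(rbind, lapply(refs, function(r) {
        df(medline = r$medline %||% NA_character_,
           title = r$title %||% "",
           author = r$author %||% "",
           journal = r$journal %||% "")
      }))
    }
    rec$comment <- paste(rec$comment, collapse = " ")
    records[[length(records) + 1L]] <<- rec
    invisible()
  }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    tag <- substr(line, 1L, 2L)
    if (tag == "//") {
      finish_record(i)
      reset(i + 1L)
      next
    }
    if (in_seq) {
      seq_chunks <- c(seq_chunks, gsub("[^A-Za-z]", "", line))
      next
    }
    body <- sub("^..\\s+", "", line)
    switch(tag,
      "ID" = {
        rec$name <- strsplit(body, "\\s+")[[1]][[1]]
      },
      "AC" = {
        rec$accession <- strip_trailing(strsplit(body, "\\s+")[[1]][[1]], ";")
      },
      "DE" = {
        rec$description <- paste(c(
          if (nzchar(rec$description)) rec$description, body), collapse = " ")
      },
      "CC" = {
        rec$comment <- c(rec$comment, trimws(body))
      },
      "RN" = {
        flush_ref()
        cur_ref <- list()
      },
      "RX" = {
        if (is.null(cur_ref)) cur_ref <- list()
        m <- regmatches(body, regexec("^(MEDLINE|PUBMED);\\s*(\\d+)", body))[[1]]
        if (length(m) == 3L) cur_ref$medline <- m[[3]]
      },
      "RA" = {
        if (is.null(cur_ref)) cur_ref <- list()
        cur_ref$author <- paste(c(cur_ref$author, strip_trailing(body, ";")),
                                collapse = ", ")
      },
      "RT" = {
        if (is.null(cur_ref)) cur_ref <- list()
        t <- gsub("\"", "", strip_trailing(body, ";"))
        cur_ref$title <- paste(c(cur_ref$title, t), collapse = " ")
      },
      "RL" = {
        if (is.null(cur_ref)) cur_ref <- list()
        cur_ref$journal <- paste(c(cur_ref$journal, strip_trailing(body, "\\.")),
                                 collapse = " ")
      },
      "FT" = {
        loc <- regmatches(line,
          regexec("^FT\\s+miRNA\\s+(\\d+)\\.\\.(\\d+)\\s*$", line))[[1]]
        if (length(loc) == 3L) {
          flush_feat()
          cur_feat <- df(accession = NA_character_, product = NA_character_,
                         start = as.integer(loc[[2]]), end = as.integer(loc[[3]]),
                         evidence = "", experiment = "", similarity = "")
        } else {
          q <- ft_qualifier(line)
          if (!is.null(q) && !is.null(cur_feat)) {
            if (q$name == "accession") cur_feat$accession <- q$value
            else if (q$name == "product") cur_feat$product <- q$value
            else if (q$name %in% c("evidence", "experiment", "similarity"))
              cur_feat[[q$name]] <- q$value
          } else if (grepl("^FT\\s+\\S+\\s+\\d+\\.\\.\\d+", line)) {
            # a non-miRNA feature: ignored
          } else if (!grepl("^FT\\s+/", line)) {
            note_skip(i, sprintf("unparseable FT line: %s", trimws(line)))
          }
        }
      },
      "SQ" = {
        in_seq <- TRUE
      },
      "XX" = NULL,
      {
        if (nzchar(trimws(line))) note_skip(i, sprintf("unknown line tag '%s'", tag))
      }
    )
  }
  if (!is.null(rec) && (!is.na(rec$name) || length(seq_chunks))) {
    # trailing partial record (no terminating //)
    if (!is.na(rec$name)) note_skip(rec_start, "record not terminated by //")
  }

  structure(records,
            skipped = if (length(skipped)) do.call(rbind, skipped)
                      else df(line = integer(0), reason = empty_chr))
}
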