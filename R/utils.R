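# Shared helpers: classed conditions, logging, URL escaping, text input.

mirkit_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "mirkit_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' @keywords internal
mirkit_log <- function(level, ...) {
  if (isTRUE(getOption("mirkit.quiet", TRUE)) && level == "info") return(invisible())
  message(sprintf("[mirkit %s] %s", level, paste0(...)))
  invisible()
}

# Accept a file path, a single string with embedded newlines, or a character
# vector of lines; return a character vector of lines.  .gz paths are
# decompressed transparently.
as_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    con <- if (grepl("\\.gz$", text)) gzfile(text, "rt") else file(text, "rt")
    on.exit(close(con))
    return(readLines(con, warn = FALSE))
  }
  if (length(text) == 1L) return(strsplit(text, "\n", fixed = TRUE)[[1]])
  as.character(text)
}

# Percent-encode a path segment.  RFC-reserved characters are escaped except
# the literal '*', which miRBase star-strand names carry as a sub-delimiter.
encode_segment <- function(x) {
  enc <- vapply(x, utils::URLencode, "", reserved = TRUE, USE.NAMES = FALSE)
  gsub("%2A", "*", enc, fixed = TRUE)
}

decode_segment <- function(x) {
  vapply(x, utils::URLdecode, "", USE.NAMES = FALSE)
}

# Deterministic lexicographic order, independent of the session locale.
lex_order <- function(x) order(x, method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_chr <- character(0)

df <- function(...) data.frame(..., stringsAsFactors = FALSE)

# Normalize a nucleotide string to uppercase RNA (T -> U).
as_rna <- function(x) chartr("T", "U", toupper(x))
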