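# Release bundles: the set of flat files constituting one versioned release.
# Only the hairpin record file is mandatory; every other member degrades
# model coverage when absent.

#' Construct a release bundle
#'
#' @param version Release version string.
#' @param hairpin_records Path to the EMBL-dialect hairpin record file
#'   (mandatory).
#' @param family Path to the family file, or `NULL`.
#' @param coordinates Named character vector of per-species GFF paths (names
#'   are species codes), or `NULL`.
#' @param context Path to the genome-context table, or `NULL`.
#' @param species Path to the species table, or `NULL`.
#' @param hairpin_fasta,mature_fasta FASTA paths, or `NULL`.
#' @return A `release_bundle`.
#' @export
release_bundle <- function(version, hairpin_records, family = NULL,
                           coordinates = NULL, context = NULL, species = NULL,
                           hairpin_fasta = NULL, mature_fasta = NULL) {
  if (is.null(version) || !nzchar(version))
    mirkit_error("mirkit_bad_bundle", "release version must be non-empty")
  if (is.null(hairpin_records))
    mirkit_error("mirkit_bad_bundle", "hairpin record file is mandatory")
  structure(list(version = version, hairpin_records = hairpin_records,
                 family = family, coordinates = coordinates, context = context,
                 species = species, hairpin_fasta = hairpin_fasta,
                 mature_fasta = mature_fasta),
            class = "release_bundle")
}

#' @export
print.release_bundle <- function(x, ...) {
  cat(sprintf("<release_bundle %s>\n", x$version))
  for (m in setdiff(names(x), "version")) {
    cat(sprintf("  %-16s %s\n", m,
                if (is.null(x[[m]])) "(absent)" else paste(x[[m]], collapse = ", ")))
  }
  invisible(x)
}

bundle_member_names <- list(
  hairpin_records = c("miRNA.dat", "miRNA.dat.gz", "hairpin.dat"),
  family = c("miFam.dat", "miFam.dat.gz"),
  context = c("genome_context.txt"),
  species = c("organisms.txt", "species.txt"),
  hairpin_fasta = c("hairpin.fa", "hairpin.fa.gz", "hairpin.fasta"),
  mature_fasta = c("mature.fa", "mature.fa.gz", "mature.fasta")
)

#' Read a release bundle from a directory
#'
#' Looks for the canonical member file names (`miRNA.dat`, `miFam.dat`,
#' `genomes/<code>.gff`, `genome_context.txt`, `organisms.txt`,
#' `hairpin.fa`, `mature.fa`, `VERSION`).
#'
#' @param dir Directory containing the release files.
#' @param version Version string; defaults to the `VERSION` file content or
#'   the directory name.
#' @return A `release_bundle`.
#' @export
read_release_bundle <- function(dir, version = NULL) {
  if (!dir.exists(dir))
    mirkit_error("mirkit_bad_bundle", sprintf("no such directory: %s", dir))
  pick <- function(cands) {
    for (f in cands) {
      p <- file.path(dir, f)
      if (file.exists(p)) return(p)
    }
    NULL
  }
  if (is.null(version)) {
    vf <- file.path(dir, "VERSION")
    version <- if (file.exists(vf)) trimws(readLines(vf, warn = FALSE)[[1]])
               else basename(normalizePath(dir))
  }
  gffs <- sort(list.files(file.path(dir, "genomes"), pattern = "\\.gff3?(\\.gz)?$",
                          full.names = TRUE))
  coords <- if (length(gffs)) {
    stats::setNames(gffs, sub("\\.gff3?(\\.gz)?$", "", basename(gffs)))
  } else NULL
  release_bundle(
    version = version,
    hairpin_records = pick(bundle_member_names$hairpin_records) %||%
      mirkit_error("mirkit_bad_bundle",
                   sprintf("no hairpin record file (miRNA.dat) in %s", dir)),
    family = pick(bundle_member_names$family),
    coordinates = coords,
    context = pick(bundle_member_names$context),
    species = pick(bundle_member_names$species),
    hairpin_fasta = pick(bundle_member_names$hairpin_fasta),
    mature_fasta = pick(bundle_member_names$mature_fasta)
  )
}

#' Fetch a versioned release from the public archive
#'
#' Downloads the flat files of the requested (or current) release into
#' `destination` and returns a bundle referencing them.  Idempotent: members
#' already present are not re-downloaded.  Requires network access; all
#' tests and the bundled fixtures work without it.
#'
#' @param version Release version such as `"14.0"`, or `NULL` for the
#'   current release.
#' @param destination Writable directory.
#' @param base_url Archive root.
#' @return A `release_bundle`.
#' @export
fetch_release <- function(version = NULL, destination,
                          base_url = "https://www.mirbase.org/download_version_files") {
  dir.create(destination, showWarnings = FALSE, recursive = TRUE)
  ver <- version %||% "CURRENT"
  root <- sprintf("%s/%s", base_url, ver)
  members <- c("miRNA.dat.gz", "miFam.dat.gz", "hairpin.fa.gz", "mature.fa.gz")
  for (m in members) {
    dest <- file.path(destination, m)
    if (file.exists(dest)) next
    status <- tryCatch(
      utils::download.file(sprintf("%s/%s", root, m), dest,
                           quiet = TRUE, mode = "wb"),
      error = function(e) e, warning = function(w) w)
    if (inherits(status, "condition")) {
      unlink(dest)
      if (m == "miRNA.dat.gz") {
        cls <- if (!is.null(version)) "mirkit_unknown_version"
               else "mirkit_network_failure"
        mirkit_error(cls, sprintf("could not fetch %s/%s: %s", root, m,
                                  conditionMessage(status)))
      }
      mirkit_log("warn", sprintf("optional member %s not fetched", m))
    }
  }
  writeLines(ver, file.path(destination, "VERSION"))
  read_release_bundle(destination, version = ver)
}
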