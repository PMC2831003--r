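# Flat-file parsers and dataset assembly.

embl_record <- function(name = "syn-mir-1", acc = "MI9000001", seq = NULL,
                        features = "FT   miRNA           17..38
FT                   /accession=\"MIMAT9000001\"
FT                   /product=\"syn-miR-1\"
FT                   /evidence=experimental
FT                   /experiment=\"cloned\"") {
  if (is.null(seq)) seq <- strrep("acguacguag", 9)  # 90 nt
  sprintf("ID   %s    standard; RNA; SYN; %d BP.
XX
AC   %s;
XX
DE   Synthetic %s stem-loop
XX
RN   [1]
RX   MEDLINE; 90000001.
RA   Doe J., Roe R.;
RT   \"A synthetic study\";
RL   J Synth RNA 1:1-10(2009).
XX
CC   first comment line
CC   second comment line
XX
%s
XX
SQ   Sequence %d BP; 1 A; 1 C; 1 G; 1 U; 0 other;
     %s
//", name, nchar(seq), acc, name, features, nchar(seq), seq)
}

test_that("EMBL-dialect records parse into raw precursor records", {
  recs <- parse_hairpin_records(embl_record())
  expect_length(recs, 1L)
  r <- recs[[1]]
  expect_equal(r$name, "syn-mir-1")
  expect_equal(r$accession, "MI9000001")
  expect_equal(r$comment, "first comment line second comment line")
  expect_equal(nchar(r$sequence), 90L)
  expect_false(grepl("[^ACGUN]", r$sequence))
  expect_equal(nrow(r$matures), 1L)
  expect_equal(r$matures$accession, "MIMAT9000001")
  expect_equal(r$matures$product, "syn-miR-1")
  expect_equal(r$matures$evidence, "experimental")
  # the feature excises a substring of the hairpin
  expect_identical(substr(r$sequence, r$matures$start, r$matures$end),
                   substr(r$sequence, 17, 38))
  expect_equal(r$references$medline, "90000001")
  expect_equal(r$references$author, "Doe J., Roe R.")
  expect_equal(r$references$title, "A synthetic study")
})

test_that("records without features parse; out-of-bounds features skip the record", {
  no_feat <- parse_hairpin_records(embl_record(features = "XX"))
  expect_length(no_feat, 1L)
  expect_equal(nrow(no_feat[[1]]$matures), 0L)

  bad <- parse_hairpin_records(paste(
    embl_record(name = "syn-mir-8", acc = "MI9000008",
                features = "FT   miRNA           17..9999
FT                   /accession=\"MIMAT9000008\"
FT                   /product=\"syn-miR-8\""),
    embl_record(name = "syn-mir-9", acc = "MI9000009"),
    sep = "\n"))
  expect_length(bad, 1L)            # the sound record survives
  expect_equal(bad[[1]]$name, "syn-mir-9")
  skips <- attr(bad, "skipped")
  expect_true(any(grepl("outside", skips$reason)))
})

test_that("parser is total on malformed streams", {
  expect_length(parse_hairpin_records(""), 0L)
  expect_length(parse_hairpin_records("garbage\nmore garbage\n//"), 0L)
  mixed <- parse_hairpin_records(paste("nonsense line", embl_record(), sep = "\n"))
  expect_length(mixed, 1L)
  expect_gt(nrow(attr(mixed, "skipped")), 0L)
})

test_that("family file parses blocks of AC/ID/MI lines", {
  fams <- parse_family_file("AC   MIPF9000001
ID   syn-fam-1
MI   MI9000001  syn-mir-1
MI   MI9000002  syn-mir-2
MI   MI9000003  syn-mir-3
//")
  expect_length(fams, 1L)
  expect_equal(fams[[1]]$name, "syn-fam-1")
  expect_identical(unname(fams[[1]]$members),
                   c("MI9000001", "MI9000002", "MI9000003"))
  expect_length(parse_family_file(""), 0L)
})

test_that("GFF coordinates keep 1-based inclusive positions in both dialects", {
  line <- "chr1\t.\tmiRNA\t100\t180\t.\t+\t.\tACC=\"MI9000001\"; ID=\"syn-mir-1\";"
  got <- parse_coordinates(line)
  expect_equal(nrow(got), 1L)
  expect_equal(got$identifier, "MI9000001")
  expect_equal(got$xsome, "chr1")
  expect_equal(got$contig_start, 100L)
  expect_equal(got$contig_end, 180L)
  expect_equal(got$strand, "+")

  gff3 <- "chr2\tsrc\tmiRNA_primary_transcript\t5\t99\t.\t-\t.\tID=MI9000002;Name=syn-mir-2"
  got3 <- parse_coordinates(gff3)
  expect_equal(got3$identifier, "MI9000002")
  expect_equal(got3$strand, "-")

  expect_equal(nrow(parse_coordinates("# header only\n# another")), 0L)

  multi <- parse_coordinates(paste(line, line, sep = "\n"))
  expect_equal(nrow(multi), 2L)  # multi-copy locus: one row per line

  bad <- parse_coordinates(paste(
    "chr1\t.\tmiRNA\t200\t100\t.\t+\t.\tACC=\"MI9000001\";",  # start > end
    "chr1\t.\tmiRNA\tx\t100\t.\t+\t.\tACC=\"MI9000001\";",    # non-integer
    "chr1\tonly\tthree",                                        # bad columns
    line, sep = "\n"))
  expect_equal(nrow(bad), 1L)
  expect_equal(nrow(attr(bad, "skipped")), 3L)
})

test_that("context rows map 1:1 and duplicates are kept", {
  row <- "MI9000001\tsynthdb\tGENE42\tantisense\tintron"
  got <- parse_context_table(paste(row, row, sep = "\n"))
  expect_equal(nrow(got), 2L)
  expect_equal(got$overlap_sense[1], "antisense")
  expect_equal(got$overlap_type[1], "intron")
  expect_equal(nrow(parse_context_table("")), 0L)
  short <- parse_context_table("just\ttwo")
  expect_equal(nrow(short), 0L)
  expect_equal(nrow(attr(short, "skipped")), 1L)
})

test_that("build_dataset reproduces the generator manifest exactly", {
  fx <- cached_fixture()
  ds <- build_dataset(fx$gen$bundle)
  expect_identical(compare_to_manifest(ds, fx$gen$manifest), character(0))
  expect_identical(nrow(validate_dataset(ds)), 0L)
  # provenance
  expect_identical(ds$release_version, fx$gen$manifest$version)
})

test_that("a mature shared by two hairpins becomes one entity with two links", {
  ds <- cached_fixture()$ds
  pm <- ds$tab$precursor_mature
  hosts <- pm$precursor_name[pm$mature_name == "sya-miR-4"]
  expect_setequal(hosts, c("sya-mir-4", "sya-mir-5"))
  expect_equal(sum(ds$tab$mature$name == "sya-miR-4"), 1L)
})

test_that("optional bundle members degrade gracefully", {
  fx <- cached_fixture()
  b <- fx$gen$bundle
  slim <- release_bundle(version = b$version, hairpin_records = b$hairpin_records)
  ds <- build_dataset(slim)
  expect_equal(nrow(ds$tab$genome_position), 0L)
  expect_equal(nrow(ds$tab$genome_context), 0L)
  expect_equal(nrow(ds$tab$precursor_family), 0L)
  # species synthesized from name prefixes
  expect_setequal(ds$tab$species$abbreviation, c("sya", "syb", "syc"))
  expect_equal(nrow(ds$tab$precursor), nrow(fx$gen$manifest$precursors))
  expect_identical(nrow(validate_dataset(ds)), 0L)
})

test_that("hairpin FASTA, mature FASTA and records agree on the fixture", {
  fx <- cached_fixture()
  fa <- Biostrings::readBStringSet(fx$gen$bundle$hairpin_fasta)
  keys <- vapply(strsplit(names(fa), "\\s+"), `[[`, "", 1)
  p <- fx$gen$manifest$precursors
  expect_setequal(keys, p$name)
  expect_identical(unname(as.character(fa)[match(p$name, keys)]), p$sequence)

  ma <- Biostrings::readBStringSet(fx$gen$bundle$mature_fasta)
  mkeys <- vapply(strsplit(names(ma), "\\s+"), `[[`, "", 1)
  m <- fx$gen$manifest$matures
  expect_setequal(mkeys, m$name)
  expect_identical(unname(as.character(ma)[match(m$name, mkeys)]), m$sequence)
})

test_that("a missing hairpin file is the only fatal ingest defect", {
  expect_error(release_bundle(version = "x", hairpin_records = NULL),
               class = "mirkit_bad_bundle")
  expect_error(read_release_bundle(tempfile("nodir")), class = "mirkit_bad_bundle")
})
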