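Package: mirkit
Title: Relational Model, Derived Groupings and Resource Layer for
    microRNA Sequence Releases
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Ingests a miRBase-style microRNA release (EMBL-dialect
    hairpin records, family file, per-species genome coordinates, genome
    context and species tables, FASTA) into a validated, inter-connected
    in-memory data model of precursors, matures, species, families,
    papers and genomic placements; derives seed families (6mer/7mer,
    bases 2-7/2-8) and genomic precursor clusters; and exposes every
    entity, collection and association as uniformly addressable read-only
    resources with HTML, XML, FASTA and JSON representations, extensible
    by declarative plugins.  A deterministic synthetic-release generator
    with a ground-truth manifest makes the whole pipeline testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
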