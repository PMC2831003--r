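# mirkit

`mirkit` turns a miRBase-style microRNA release — the flat files a curator
publishes (EMBL-dialect hairpin records, a precursor-family file, per-species
genome coordinates in GFF, genome-context and species tables, and the
hairpin/mature FASTA pair) — into one inter-connected, queryable data model,
derives the two groupings that are *not* in the files, and exposes every
entity and relationship as uniformly addressable read-only resources.

It is written for miRNA researchers and bioinformaticians who are tired of
re-parsing release files by hand: instead of one ad-hoc script per question,
you get a relational universe you can traverse in R
(`precursor → matures → papers`), query over an in-process REST-style
resolver (`/species/cel/matures.fasta`), extend with plugins, and serve over
HTTP from a shell.

## The data model

Nine entity kinds, linked exactly as the release links them:

| Kind | Canonical id | Attributes |
|---|---|---|
| `precursor` | name (`hsa-mir-21`) | name, accession (`MI…`), description, sequence, comment |
| `mature` | name (`hsa-miR-21`, star strands `…*`) | name, accession (`MIMAT…`), evidence, experiment, similarity, sequence |
| `species` | abbreviation (`hsa`) | abbreviation, name, division, taxonomy, genome_assembly |
| `precursor_family` | name (`mir-17`) | name, accession, description |
| `genome_position` | `<precursor>-pos-<n>` | xsome, contig_start, contig_end (1-based inclusive), strand |
| `genome_context` | `<precursor>-ctx-<n>` | overlap_sense, overlap_type, transcript_source, transcript_name |
| `paper` | Medline id | medline, title, author, journal |
| `seed_family` *(derived)* | seed sequence | name, sequence |
| `precursor_cluster` *(derived)* | cluster name | name |

Precursors and matures are many-to-many (one mature sequence can be excised
from several hairpins); every mature sequence is a substring of each linked
hairpin; lookups are case-sensitive, so the precursor `hsa-mir-21` and the
mature `hsa-miR-21` never alias.

The two starred kinds are **computed, never parsed**:

- **Seed families.** The seed of a mature miRNA is bases 2–7 (6mer) or 2–8
  (7mer) — the primary determinant of target recognition. For each seed
  length k, matures partition into families of identical seed; both
  groupings are kept side by side, and families are named by their seed
  sequence.
- **Precursor clusters.** Single-linkage connected components of hairpin
  loci on the same species' chromosome (and, by default, strand) whose
  interval-hull gap is at most `max_gap` (default 10,000 nt — the
  conventional scale of miRNA polycistrons, presumed co-transcribed).
  Components of ≥ 2 hairpins become clusters; a `neighborhood()` query
  (default ± 1,000 nt) answers the ad-hoc version of the same question.

## Worked example

```r
library(mirkit)

dir <- tempfile("release")
gen <- generate_release(fixture_spec(seed = 101), dir)  # synthetic release
ds  <- build_dataset(gen$bundle)                        # ingest
build_seed_families(ds, 7)                              # derive 7mer families
build_precursor_clusters(ds, cluster_params(max_gap = 10000))
ds
#> <mir_dataset release synth-1.0>
#>   species            3
#>   precursors         15
#>   matures            23
#>   precursor_families 2
#>   genome_positions   11
#>   genome_contexts    11
#>   precursor_clusters 3
#>   seed_families      20
#>   papers             10

p <- get_entity(ds, "precursor", "sya-mir-1")
traverse(p, "precursor_cluster")$name
#> [1] "sya-cluster-chr1-1"
vapply(neighborhood(ds, p, 1000), function(e) e$name, "")
#> [1] "sya-mir-2"

cat(resolve(ds, "GET", "/precursors/sya-mir-1.fasta")$body)
#> >sya-mir-1 MI9010001
#> AGGCCUGGAGGAGCGUGUAUGGCUUCCUGCGCCUGAGACUAAGCUCUACUCGAAACAUGUUUUAGGAUGCGAG
```

The 15 synthetic hairpins ingest into 23 matures (some hairpins carry a star
strand, one mature is shared by two hairpins), the planted locus ladder
yields 3 clusters split exactly at the `max_gap` threshold, and `sya-mir-1`'s
only neighbor within ± 1,000 nt is the hairpin planted 500 nt away.

Every entity answers at a canonical URL with content negotiation (`.html`,
`.xml`, `.fasta`, `.json`; suffix wins over the Accept-style fallback), the
route set is self-describing at `/described_routes.txt`, and plugins — see
`disease_plugin()` for a complete disease-annotation example — add new kinds,
associations and routes without perturbing a single core response byte.

A command-line wrapper covers the same lifecycle:

```sh
exec/mirkit fixtures --seed 7 --out release/
exec/mirkit ingest   --release release/ --db mirna.rds
exec/mirkit derive   --db mirna.rds --seed-k 6,7 --max-gap 10000
exec/mirkit export   --db mirna.rds --collection species/syb/matures --format fasta
exec/mirkit serve    --db mirna.rds --port 4567
```

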