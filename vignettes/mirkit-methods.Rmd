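---
title: "mirkit: model, derivations and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirkit: model, derivations and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirkit)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what the bundled tests do and do not show
about real data.

## The relational model

A release is modeled as nine entity kinds held in one `mir_dataset`:
species, precursors (hairpins, `MI…` accessions), matures (`MIMAT…`),
curated precursor families, literature references, per-precursor genomic
loci and genome-context annotations, plus the two derived kinds (seed
families, precursor clusters). The container is an environment of plain
data frames with reference semantics: ingest, derivation and plugin
registration mutate one dataset in place, which mirrors how a relational
backend would behave while keeping everything inspectable.

Decisions worth calling out:

- **Case-sensitive canonical identifiers.** miRNA nomenclature distinguishes
  the hairpin `xxx-mir-NN` from the mature `xxx-miR-NN` by case alone. The
  two live in different namespaces, but case-insensitive matching would
  invite silent aliasing, so lookups are exact.
- **Synthetic ids for loci and contexts.** The source files give genomic
  placements no identifier, yet every resource must be addressable; loci are
  keyed `<precursor>-pos-<n>` and contexts `<precursor>-ctx-<n>`, with `n`
  assigned in file order. These ids are stable for a given release file but
  not across releases.
- **Mature → papers is a derived union.** Literature is curated per hairpin;
  a mature's papers are defined as the Medline-deduplicated union over all
  hairpins it derives from.
- **A precursor without coordinates is legal** — not every species has an
  assembly — and sequences are stored as uppercase RNA (`T` is normalized to
  `U` at ingest, since releases publish RNA).

`validate_dataset()` re-checks every invariant (identifier uniqueness,
accession shapes, the substring law between matures and their hairpins,
referential integrity, coordinate sanity, seed consistency) at runtime and
reports violations as data rather than errors, so a defective release can be
inspected instead of refused.

## Ingest

The hairpin record file is the only mandatory bundle member; family file,
coordinates, context and species tables, and the FASTA pair each add model
coverage when present. The EMBL-dialect feature-table parser is hand-written
(no installed R package parses this dialect); FASTA members are read with
Biostrings. Two policies govern ingest:

- **Totality.** No input stream raises an unhandled failure. Malformed lines
  and records are skipped with a logged reason (and surfaced on the parse
  result), with one exception: a missing or empty hairpin file is fatal,
  because nothing can be modeled without it.
- **The record file wins.** Hairpin FASTA, mature FASTA and the record file
  overlap in content; where they disagree, the disagreement is logged and
  the record file is authoritative.

Coordinates are kept 1-based inclusive end to end, exactly as GFF states
them; both the `ACC="…"; ID="…";` and the `ID=…;Name=…` attribute dialects
are accepted. The genome-context and species tables have no documented
public layout, so this package fixes a simple tab-delimited dialect (defined
in `?parse_context_table` / `?parse_species_table`) that its own generator
emits — an artifact decision, flagged as such.

## Seed families

The seed of a mature miRNA is bases 2–7 (6mer) or 2–8 (7mer). For a given
seed length k, `build_seed_families()` partitions every mature of length
≥ k+1 by its exact seed; shorter matures (none occur at realistic mature
lengths of 20–24 nt) are left unassigned and logged. Nothing in the source
material privileges one k, so both groupings are materialized side by side,
keyed by seed length, and a mature traverses to one family per k. Families
are named by their seed sequence — collision-free, self-describing, and
stable across releases, where an ordinal scheme would not be.

## Precursor clusters

Clustered hairpins are a proxy for polycistronic transcription: loci close
together on one strand are presumably transcribed together. The definition
used here:

- the distance between two loci is the gap between their interval hulls,
  `max(start1, start2) − min(end1, end2)` floored at 0 (overlapping or
  book-ended loci are at distance 0);
- two precursors are adjacent iff they have loci on the same chromosome *of
  the same species* (chromosome labels such as `chr1` recur in every
  assembly, so proximity never crosses species), on the same strand when
  `same_strand_required` (the default, following the co-transcription
  rationale), with gap ≤ `max_gap`;
- clusters are the single-linkage connected components of size ≥ 2,
  implemented as a sorted sweep with union–find across multi-copy loci, and
  named `<species>-cluster-<xsome>-<ordinal>` with ordinals assigned per
  species and chromosome by leftmost start.

`max_gap` defaults to 10,000 nt, the conventional scale of miRNA
polycistrons. This threshold is a declared package default, not a claim
about any particular prior system; the ± 1,000 nt figure familiar from
ad-hoc neighborhood queries is instead the default window of
`neighborhood()`, which answers the one-off version of the question without
materializing clusters. Both derivations are idempotent — rerunning replaces
the previous grouping — and the cluster partition provably coarsens
monotonically in `max_gap` (asserted property-style in the tests).

The independent check for all of this is `brute_force_clusters()`: O(n²)
pairwise adjacency plus Warshall transitive closure, kept deliberately
separate from the sweep implementation. Tests compare the two on random
instances up to 500 loci.

## The resource layer

Every kind has `/plural` and `/plural/{id}` routes; every association adds
`/plural/{id}/assoc`. Design choices:

- **Negotiation**: path suffix (`.html`, `.xml`, `.fasta`, `.json`) first,
  an Accept-style fallback second, HTML default; the suffix wins on
  conflict. FASTA is offered only where the addressed objects carry
  sequences (precursors, matures, and associations targeting them); asking
  elsewhere is a 406. JSON is a convenience representation beyond the
  HTML/XML/FASTA contract.
- **XML is the machine contract**: element name = singular kind, one child
  per public attribute, associations rendered as `<link rel href>` elements
  (never embedded objects), collections wrapped in a plural root with a
  `count` attribute. Parse-back of a rendered document recovers every
  attribute verbatim, which the tests assert for every fixture entity.
- **Pagination** via `page`/`per_page` (default 100, `per_page=all`
  opts out); concatenated pages equal the unpaginated listing.
- **Read-only**: only GET resolves (anything else is 405), and an
  order-stable MD5 fingerprint of all tables is unchanged by any request
  sequence.
- **Identifiers in URLs** are percent-encoded except the literal `*`, which
  star-strand names (`hsa-miR-21*`) carry as a legal sub-delimiter.
- `/described_routes.txt` (and `.xml`) lists every registered template —
  core and plugin — and the listing provably equals the routable set.

`serve()` wraps the resolver in a minimal single-threaded HTTP/1.0 loop over
base-R sockets so the tool can be served from a shell; the resolver, not the
socket loop, carries the whole contract and is what the tests exercise.

## Plugins

A plugin is a declarative manifest: new kinds (with canonical id and public
attributes), associations binding them to core kinds, a loader, and a test
suite that `run_plugin_tests()` federates with the core checks. Registration
refuses kind/route/association collisions and dangling endpoints.

One choice was genuinely open: a plugin that registers an association on a
core kind (the example disease plugin hangs `m2d_disease_links` off
matures) could either inject its link into core documents or not. Injecting
would make core responses depend on which plugins happen to be active, so
`mirkit` forbids representation overrides entirely: plugin-registered
associations on core kinds resolve and appear in `described_routes`, but are
not embedded in core documents. Core routes are therefore byte-identical
with and without plugins, and plugin load order cannot matter (asserted
pairwise in the tests). The bundled disease data is synthetic; links are
keyed by the concatenation DOID + mature name + PubMed id.

## The synthetic generator, and what the tests do not show

`generate_release()` emits a complete release in the exact dialects ingest
consumes, plus a ground-truth manifest, deterministically per seed. Its
defaults — 3 species × 5 hairpins, hairpins of 60–120 nt, matures of
20–24 nt drawn uniformly over {A,C,G,U} then patched to plant structure, a
star strand on about half the hairpins, one mature shared by two hairpins,
one hairpin with two loci, one paper cited by two hairpins, two curated
families, locus ladders whose consecutive gaps are 500, `max_gap`,
`max_gap + 1` and 700 nt, a strand flip, and one species without an
assembly — are chosen so that every contract edge (many-to-many links, the
clustering threshold on both sides, the strand rule, multi-copy loci,
absent coordinates) exists in every generated release at a scale where the
brute-force oracles stay exact. Expected clusters in the manifest come from
the brute-force oracle, never from the production sweep, so
generate → ingest → derive → compare is a genuine dual-route check.

What the generator does *not* emulate: secondary structure, sequence
conservation, realistic base composition, the long-tailed species and
family-size distributions of a real release, or its sheer size (a real
release has hundreds of species and > 10,000 hairpins). Passing the fixture
suite therefore demonstrates the correctness of the parsing, modeling,
derivation and resource contracts — not performance at full scale, and not
robustness to every oddity a decade of curation can produce. The ingest
defect policy (skip and log, never crash) is the designed mitigation for
the latter. The network fetch layer is isolated behind the bundle
abstraction precisely so that nothing else depends on it; it is exercised
only when a user actually downloads a release.

## Problem sizes and tolerances

All checks are exact (set and string equality); there are no numeric
tolerances anywhere. The bundled suites use the default 15-hairpin fixture
for contract checks, 20 generator seeds for round-trip fidelity, random
instances of 50–500 loci for cluster-oracle equivalence, and a four-point
`max_gap` ladder (10² … 10⁵ nt) for monotonicity — sizes at which the O(n²)
oracle is still comfortably exact while exercising every code path.
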