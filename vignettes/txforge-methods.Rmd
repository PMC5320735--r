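---
title: "txforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{txforge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txforge)
```

txforge integrates the downstream artifacts of a de novo transcriptome
project — assembled transcripts, structural and functional annotation, BLAST
alignments, molecular markers, replicate-structured expression — into one
queryable store. This vignette records the model, the parameters that
matter, the numerical and design choices, and what the shipped synthetic
fixtures do and do not demonstrate.

## The ontology model

A controlled vocabulary is a directed graph of terms connected by typed
relations. Annotation inheritance is defined over a configurable set of
*closure predicates*, defaulting to `is_a` and `part_of` — the two relations
along which functional annotation is conventionally propagated in the Gene
Ontology. All other relation types (`regulates`, custom labels from arbitrary
OBO files) are stored and reported but never traversed.

Three structural assumptions are enforced at load time, because inheritance
is only well defined under them:

* the subgraph over the closure predicates must be **acyclic** — a cycle is a
  hard load error naming the offending terms, not a warning;
* every relation endpoint must be a declared term (dangling ids are load
  errors);
* obsolete terms may be loaded and may carry direct annotations, but they
  have no outgoing closure edges: they are excluded from inheritance and from
  term counting, with a warning when annotations reference them.

`ancestors()` computes the set of terms reachable over closure edges,
excluding the start term. Ancestor sets are **memoized on demand** (an
iterative traversal filling a per-graph cache) rather than materialized as a
precomputed transitive-closure table. For vocabularies the size of GO
(tens of thousands of terms) a dense closure table is quadratic in memory
while typical sessions touch a small fraction of terms; on-demand
memoization gives amortized closure-table speed at traversal-cache cost. The
test suite holds this implementation against an independent brute-force
boolean-matrix transitive closure on hundreds of random DAGs.

### Direct vs inherited annotation, and counting semantics

`propagate_annotations()` splits every feature's term set into *direct*
(asserted) and *inherited* (ancestors of asserted terms, minus the direct
set); the two are disjoint by construction. A feature annotated to a term
through several paths — the diamond case — inherits each ancestor exactly
once.

`term_count_summary()` implements the pie-chart semantics of classification
views: for each direct child of a focus term it counts the **distinct
features annotated at or below that child**, and separately the distinct
total under the focus itself. Because membership is per-child and features
can be annotated under several children, slice counts may legitimately sum to
more than the total. Counting never de-duplicates across slices; it only
de-duplicates features within one slice. Membership is upward-closed, so a
parent's count is always at least each child's count, and the count at a
namespace root equals the number of features with at least one non-obsolete
annotation in that namespace — both are property-tested.

## The store

Data live in a modular relational store patterned on the Chado schema: five
core module groups (Sequence, General, Publication, Audit, Controlled
vocabularies) and seven additional groups (Organism, Companalysis, Phenotype,
Strain, Genetics, Stock, Expression). The grouping is queryable metadata
(`tx_modules()`), not just documentation. Publication, Phenotype, Strain and
Stock are instantiated as tables but receive no loaders — only the surface
the toolkit actually exercises gets write paths, and the Audit group is a
minimal append-only operation log.

The backend is an in-package collection of typed tables whose persistent
form is a deterministic, diffable plain-text dump with a version header;
that same dump is the backup format, and `restore(backup(s))` is
observationally equal to `s` (identical per-table counts and identical query
results — tested, including on the full toy project). A truncated or
version-mismatched dump is rejected before anything is written, so a failed
restore never leaves a partial store. All loaders write exclusively through
the typed operations (`upsert_feature()`, `add_location()`, ...), which
enforce referential integrity; deletes cascade to dependents (locations,
annotations, alleles, expression values) and report the number of records
removed.

**Coordinates.** Storage is interbase — 0-based, half-open, the Chado
convention — so a feature covering bases 1..100 is stored as `(0, 100)`.
GFF3 and InterProScan (1-based inclusive) and VCF (`POS`) are converted at
the I/O boundary; every report converts back to 1-based inclusive for
display. Centralizing the conversion is what makes the GFF3 coordinate
round trip exact.

## Loaders

Each loader returns a load report with `read = loaded + skipped` and a
line-numbered warning table; warnings are never fatal, and every loader is
idempotent (reloading a file reproduces the same store state). Choices the
formats leave open:

* **FASTA** — the unique name is the first whitespace token of the header;
  the remainder becomes the display name; residues are stored verbatim.
* **GFF3** — two-pass, so `Parent=` may reference an `ID` defined later.
  Unknown column-3 types fall back to the generic region type with a
  warning rather than failing the file; records with `end < start` are
  rejected per record.
* **BLAST XML** — one stored hit per HSP (not per-hit aggregates: per-HSP
  values are unambiguous and testable); identity percent is
  `identities / alignment length x 100`.
* **ANNOT** — the dialect is fixed here as 2–3 TAB-separated columns
  (feature, term CURIE, optional description). Terms whose prefix matches a
  loaded ontology must resolve in it; CURIEs with unknown prefixes (EC
  numbers) are stored as-is.
* **InterProScan** — InterProScan-5 column layout by default, with the
  column positions configurable; InterPro accessions map to ontology terms
  through a dbxref table (interpro2go style), the optional GO column loads
  directly, and unmapped accessions are reported, not fatal.
* **VCF markers** — both SNPs and SSRs ride the VCF path; for SSRs the motif
  is taken from the INFO key `MOTIF`. This key is this package's convention:
  dedicated SSR-discovery outputs vary too much to parse natively, and VCF
  is the one standardized carrier. Sample `GT` fields translate to allele
  strings (`1/1` with REF A/ALT G becomes `G/G`); missing calls (`./.`)
  store nothing.

## Expression

An experiment is one condition, described by terms from any loaded ontology
(anatomy ontologies serve well for phenological state and sex) and owning one
library per replicate. Raw counts may be fractional — pseudo-aligned counts
are stored unchanged; the package takes no position on how counts were
produced.

RPKM uses the standard scaling constant `10^9` (per kilobase x per million):
`count x 10^9 / (length_bp x total_reads)`. The arithmetic is done in double
precision (the `length x total` product overflows 32-bit integers for
ordinary library sizes). When every read is assigned to exactly one
transcript, `sum(RPKM x length) = 10^9` exactly, which the tests verify to
`1e-6` relative on random count vectors.

Replicate summaries report the arithmetic mean and the *sample* standard
deviation (n−1 denominator). With a single replicate the SD is reported as
0 — not NA — with `n` exposed so callers can distinguish "no variation" from
"cannot estimate"; error-bar displays expect a number, and the replicate
count is the honest signal.

## Queries and reports

Name searches follow SQL LIKE semantics (`%` any run, `_` one character),
translated internally to anchored regular expressions, case-insensitive by
default. Term searches flag each row direct or indirect, with direct taking
precedence when both apply. Gene-level rows aggregate the annotations of
features related one hop by `part_of`/`derives_from`, so a locus row shows
the annotation of all its isoforms. The sequence report has six sections
(residues, relationships, structural annotation, functional annotation with
the reduced sub-DAG of direct+inherited terms, BLAST results, expression
profile); a residue-less feature gets the general report with only the
relationships section. Reports hold no values that are not re-derivable from
store queries at call time.

## The synthetic project generator

`make_toy_project()` emulates the *structure* of a 454/Newbler de novo
project: isotigs grouped into isogroups (the latter residue-less), GFF3
mRNA/exon/CDS per transcript, planted SSR tracts and SNPs with two genotype
columns, split annotation routes (ANNOT, InterProScan GO column, dbxref-
mapped accessions), and a three-condition design — `male_larvae`,
`male_adult`, `female_adult`, one library per condition, 10^6 reads each —
with one locus planted as strongly larvae-biased. Defaults: 10 isogroups,
1–3 isoforms each, transcript lengths 300–900 bp, 8 SSRs, 10 SNPs, a
30-term toy ontology with a guaranteed diamond, a designated
reproductive-development focus term with children, and one obsolete term.
These sizes keep the full pipeline replay around a second while leaving
every query non-trivial (multi-parent overlap, partial SSR/term overlap).

Two properties make the generator usable as an oracle: byte-determinism
under its seed, and a ground-truth manifest computed by **independent
brute-force code paths** (boolean-matrix closure, set scans over the master
annotation table) that never call the loaders or queries under test.

What it does *not* emulate: sequence content is uniform-random nucleotides
(no codon structure, no homology behind the BLAST fixtures), expression is
Poisson noise plus a planted shift (no over-dispersion, no library-size
imbalance), and markers are at most one SSR and one SNP per transcript.
Passing tests therefore demonstrate the correctness of integration, closure
and query logic — not robustness to the messiness of real annotation
pipelines (malformed headers, inconsistent naming across tools), which the
loaders handle only through their skip-and-warn paths.

## Degenerate inputs and tie-breaks

* Empty OBO files parse to empty graphs; a single-term ontology has no
  edges; `ancestors(root)` is the empty set.
* Query results order by unique name ascending unless a sort key is given,
  so result sets are deterministic regardless of load order.
* `upsert_feature()` on an existing name updates in place and keeps the id;
  re-upserting identical content is a no-op.
* Features without sequence length are skipped (with a warning) by RPKM
  conversion rather than erroring the library.
* Experiments with zero stored replicate values are absent from profiles,
  not reported as zero.

## Scope and limitations

Differential-expression testing is out of scope: the package stores and
summarizes expression, it does not test it. Read mapping and counting happen
upstream. Only OBO is parsed (no OWL/RDF reasoning). The store is
single-writer; there is no access control. BLAST execution against store
sequences is possible by exporting FASTA and shelling out, but is not part
of the tested surface.
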