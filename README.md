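# txforge

Ontology-driven data integration for de novo transcriptome projects, as an R
package.

## The problem

A de novo RNA-seq project on a non-model organism (no reference genome) ends
with a pile of heterogeneous downstream results: assembled transcript contigs
("isotigs" in Newbler nomenclature) grouped into gene loci ("isogroups"),
GFF3 structural annotation, BLAST alignments, Blast2GO/InterProScan
functional annotation, SSR and SNP markers in VCF, and replicate-structured
expression measurements. Small research groups need to query these *jointly*
— "which transcripts carry a microsatellite **and** are annotated under a
given GO term, and how are they expressed across conditions?" — without
standing up a genome-database stack.

txforge loads all of these standard formats into a Chado-inspired modular
relational store (five core module groups — Sequence, General, Publication,
Audit, Controlled vocabularies — plus Organism, Companalysis, Phenotype,
Strain, Genetics, Stock and Expression) held in a single plain-text file, and
answers ontology-aware integrated queries over it. It is headless: the
interfaces are tidyverse-style R functions returning tibbles, plus a thin
command-line wrapper.

## The core machinery

**Ontology DAGs and annotation propagation.** Controlled vocabularies (GO,
SO, or any OBO file) are parsed into directed acyclic graphs. Annotations
propagate upward along the closure predicates (default `is_a`, `part_of`):
a feature directly annotated to term *t* is inheritedly annotated to every
ancestor of *t*, with the direct and inherited sets kept disjoint. Ancestor
sets are memoized on demand rather than materialized as a full closure
table. Term-count summaries under a focus term count *distinct* features at
or below each child, so slices legitimately overlap: a feature annotated
under two children is counted in both, and child counts may sum to more than
the distinct total.

**Expression.** Experiments are ontology-described conditions owning one
library per replicate. Stored raw counts (fractional pseudocounts allowed)
convert to RPKM with the standard scaling,

    RPKM = count x 10^9 / (transcript_length_bp x library_total_reads)

and per-condition profiles report the arithmetic mean and sample standard
deviation (n−1; reported as 0 with `n = 1` exposed) over replicates.

**Coordinates.** Storage is interbase (0-based half-open, the Chado
convention); GFF3, VCF, BLAST and InterProScan coordinates are converted at
the I/O boundary, and all reports display 1-based inclusive positions.

## Worked example

The package ships a deterministic generator for a complete toy project
(isotigs, isogroups, GFF3, BLAST XML, ANNOT, InterProScan + dbxref map, SNP
and SSR VCFs, genotypes, a three-condition expression design), and a replay
of the full tutorial pipeline:

```r
library(txforge)

dir    <- tempfile("demo")
bundle <- make_toy_project(fixture_spec(seed = 1), dir)
store  <- replay_project(dir)
store
#> <tx_store> /tmp/.../file...txdb
#>   91 feature(s), 47 annotation(s), 18 marker(s), 90 expression value(s), 3 ontologies
```

The combined case-study question — transcripts with at least one SSR that
are annotated (directly or by inheritance) under the reproductive-development
focus term — composes the query surface:

```r
focus <- bundle$manifest$focus_term   # "TGO:0000005"
case_study_query(store, focus)
#> <query result> >=1 SSR and annotated under TGO:0000005
#> # A tibble: 7 x 7
#>   feature_id unique_name display_name            so_type  seqlen terms n_markers
#> 1          1 isotig001   len=886 gene=isogroup01 SO:0000…    886 TGO:…         1
#> 2          3 isotig003   len=763 gene=isogroup02 SO:0000…    763 TGO:…         1
#> ...
```

Seven transcripts pass both filters; the generator's brute-force ground
truth (`bundle$manifest$ssr_under_focus`) lists exactly the same seven.
Each one's expression profile across the three conditions:

```r
expression_profile(store, bundle$manifest$planted_isotigs[1], measure = "RPKM")
#> # A tibble: 3 x 6
#>   experiment   genotype measure    mean    sd     n
#> 1 female_adult <NA>     RPKM       1.25     0     1
#> 2 male_adult   <NA>     RPKM       4.99     0     1
#> 3 male_larvae  <NA>     RPKM    1973.       0     1
```

— the planted larvae-biased locus is three orders of magnitude higher in
`male_larvae` than in either adult condition. The RPKM arithmetic itself:

```r
compute_rpkm(10, 500, 1e6)
#> [1] 20
```

The same pipeline is available from a shell through `inst/cli/txforge`
(`init`, `load-fasta`, `load-gff`, `load-markers`, `search --term ...
--with-marker SSR`, `report`, `backup`, `restore`, ...).

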