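---
title: "chadolite: data model, loader semantics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chadolite: data model, loader semantics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chadolite is an embedded genomics data store for desk-scale integration
work: one file holds controlled vocabularies, an ontology-typed feature
graph, computed evidence, expression values and publications, and the
package provides the loaders, queries and search index that a genome
annotation portal needs behind its pages.  This vignette explains the data
model, the semantics every loader guarantees, and the design choices that
were genuinely open.

## The data model

The tables mirror the subset of the GMOD Chado 1.31 relational schema that
annotation portals actually touch: `cv`/`cvterm`/`cvterm_relationship` for
controlled vocabularies, `organism`, `feature`/`featureloc`/
`feature_relationship`/`featureprop` for the sequence module,
`feature_cvterm` for functional annotation, `analysis`/`analysisfeature`
for computed evidence, `pub`/`feature_pub` for literature, and
`db`/`dbxref` for accessions.  Keeping Chado's table and column names means
the store's content maps one-to-one onto a real Chado instance; the
on-disk format here is a single serialized file, which trades multi-user
access (out of scope) for zero-dependency reproducibility.

Chado has no small expression model — its MAGE module spans a dozen
tables the source material never details.  The package deliberately
collapses it to two tables, `assay` (name, biomaterial, treatment) and
`expression_value` (feature, assay, value), which is exactly what the
search facets and the feature-page expression card require.  Values are
stored as given (TPM or whatever the upstream pipeline produced); no
normalization is attempted, since expression processing happens upstream.

The store is append-only.  There is no delete or update path, so
referential integrity cannot be broken after insertion, and every
uniqueness key — `(vocabulary, name)` for terms, `(organism, uniquename,
type)` for features, `(program, programversion, sourcename)` for analyses
— is enforced at insert time with a typed error, never a silent
overwrite.

### Bootstrap terms

Loaders need relationship types (`part_of`, `translation_of`, ...) and
feature-property types (`description`, `orthologous group`, `coexpression
group`) before any ontology has been loaded.  A fresh store therefore
seeds these seven terms; `load_obo()` upserts onto them (filling in
accession and definition from the matching `[Typedef]` stanza) rather than
duplicating.  This resolves the chicken-and-egg between "ontologies first"
and "the relationship ontology is itself a load", while the load-order
checks stay strict for everything else.

## Coordinates

Internally everything is interbase: 0-based, half-open, counting the gaps
between bases, which is Chado's native convention and makes length
arithmetic trivial (`length = fmax - fmin`).  GFF3 and BLAST coordinates
(1-based, closed) are converted on the way in as `fmin = start - 1`,
`fmax = end`, and back on the way out.  The region query API speaks
interbase; a 1-based serialization shim belongs to whatever HTTP adapter
sits on top, not to this layer.

Overlap is strictly half-open: a feature overlaps a window `[start, end)`
iff `fmin < end` and `fmax > start`, so touching endpoints never overlap.
One consequence worth knowing: a zero-width feature (an insertion point,
`fmin == fmax`) can never overlap anything under this rule; the fixture
generator never produces such features.

## Load order and atomicity

The dependency discipline is: organism → ontologies → genome FASTA → GFF3
→ protein FASTA → evidence (BLAST, InterProScan, ortholog groups,
coexpression clusters, publications) → assays → expression matrix → search
index.  Each loader checks its prerequisites up front and fails with an
error naming the command to run first — a GFF3 whose `seqid`s are not in
the store points at `load_fasta`, an expression matrix naming an unknown
assay points at `load_assays`, an InterProScan file carrying GO IDs with
no Gene Ontology loaded points at `load_obo`.

Every loader runs in one transaction: a hard failure restores the
in-memory tables and leaves the store file untouched.  Recoverable
per-record problems (a BLAST row with the wrong column count, an unknown
protein ID, a non-numeric expression cell) do not abort; they become error
entries — `(line, message)` pairs — in the returned load report, and the
valid records still commit.  The rule of thumb: violations of *structural*
prerequisites abort; violations of *record* expectations are reported.

Load reports carry `records_seen`, `created`, `skipped` and the error
list.  For record-per-entity loaders (FASTA, assays, publications) the
three counts plus errors add up to the records seen.  Two loader families
count differently, by necessity: GFF3 counts feature *lines* as records,
with lines merged into an already-created feature (discontiguous CDS)
counted as skipped; the group loaders (orthologs, coexpression) count
group *lines* as records and membership *properties* as created, with
singleton groups counted as skipped — a one-member group carries no
grouping information and would pollute the facets.

## GFF3 specifics

Parsing goes through `rtracklayer::import()`; the loader adds the Chado
semantics on top:

* Two-pass `ID`/`Parent` resolution, so forward references are legal.
* `Parent` links become `part_of` relationships regardless of child type,
  matching the behaviour of Chado's own bulk loaders; an explicit
  `Derives_from` is honoured.  Type-conditional predicates would add
  complexity without changing any query in this package.
* Lines sharing an `ID` merge into one feature with rank-ordered
  locations (ranked by `fmin`).
* ID-less leaf features get a synthesized uniquename
  `<type>:<srcfeature>:<fmin>..<fmax>:<strand>` — deterministic, and
  collision-free for distinct locations.
* `Name` becomes the feature name; `Note`/`description`/`product` become
  `description` properties; `Dbxref` becomes cross-references; every other
  attribute becomes a property typed by the attribute name (auto-created
  in the `feature_property` vocabulary).  Lossless attribute capture is
  what feeds the search index's text fields.
* An embedded `##FASTA` section is loaded as reference sequences before
  the feature lines are processed.
* Lines with `start > end` are filtered to per-line error entries before
  the parser sees them, because GenomicRanges rejects negative widths for
  the whole file at once.

## Match features

Similarity evidence (BLAST, InterProScan) is stored the Chado way: each
kept row becomes a feature of type `match` located on the *query* via
`featureloc`, carrying the subject ID as property and cross-reference, and
one `analysisfeature` row holds the scores (bitscore as rawscore, E-value
as significance, percent identity).  Subjects are not materialized as
features — they live in external databases, and fabricating organisms for
them would pollute every organism-scoped query.  Match uniquenames embed
the analysis sourcename and the row number, which keeps them unique per
run and reproducible across runs.

## Ontology queries

`term_ancestors()` computes the exact transitive closure over a chosen
predicate set by breadth-first search with a visited set.  `is_a` graphs
should be acyclic; a cycle through the start term is detected and aborts
with an error naming it, because silently truncating a cyclic closure is
worse than failing.  (A cycle elsewhere in the graph still yields a
well-defined reachable set and is tolerated.)  `alt_id` accessions resolve
to their primary term, since GO annotation files routinely carry them.

## The region query contract

`region_query()` returns the *top-level* features overlapping the window —
those with no `part_of` parent among the overlap candidates — each with
its complete `part_of` subtree nested, children ordered by `fmin` then
uniquename.  The alternative contract (clip every feature to the window)
was rejected: a genome browser renders a gene model whole even when only
partially in view, so the whole-subtree contract is what a JBrowse-style
adapter needs.  Orphan features are their own top-level subtree.  The
property suite asserts this contract against a brute-force interval scan
plus independent subtree expansion.

## The search index

`build_index()` denormalizes one document per gene, mRNA and polypeptide —
the types a portal's result list summarizes.  The text blob gathers name,
uniquename, description properties, GO term names and similarity-hit
descriptions; tokenization lowercases, splits on non-alphanumerics and
keeps tokens of length ≥ 2.  Facet dimensions are organism, type,
orthology and coexpression (boolean presence flags, since group values are
unbounded), annotation (the GO namespaces present on the feature), and
expression biomaterial/treatment.

Query semantics: AND over tokens, where a token matches an indexed keyword
exactly or as a prefix.  Applying prefix matching to *every* token (not
only the last, as type-ahead boxes often do) was chosen because the
operation's contract is then uniform and order-independent; the practical
difference at desk scale is negligible and the property tests pin the
chosen behaviour.  Ranking is the summed frequency of matching tokens,
ties broken by uniquename — a deliberately simple, deterministic stand-in
for a relevance model; the tests assert determinism and set-correctness,
not any particular relevance ordering.  Facet counts follow standard
faceted navigation: each dimension's counts are computed on the query
match set with all *other* dimensions' filters applied, so a selected
filter never hides its own alternatives.

The index is a pure function of store state: documents are ordered by
feature id and keyword tables are sorted, so rebuilding over an unchanged
store is bit-identical.  Rebuild is always authoritative; the persisted
index file is a cache.

## Parallelism

Loaders accept a worker count.  Parallelism applies to parsing/staging
only — records are split into order-preserving chunks — and all writes are
applied serially in input order, so the final store state is identical for
any worker count.  That is the strongest multi-threading contract that
keeps loads reproducible, and the determinism tests hold it to it.

## The fixture generator

`generate_bundle()` writes a miniature genome project with one consistent
ID space across all files: random-ACGT chromosomes; non-overlapping gene
models (gene → mRNA → 2-3 exons → CDS) on both strands with GFF3 phases
chained in transcription order and total CDS length a codon multiple;
protein FASTA translated from the spliced CDS with the standard code, so
sequence round trips are exact; BLAST and InterProScan rows over real
protein IDs with seeded scores; ortholog groups and coexpression clusters
partitioning subsets of the features, each with one deliberate singleton;
BibTeX entries; assay metadata and an expression matrix.  Every
ground-truth count lands in the manifest so load reports can be checked
against it.

What it does *not* emulate: codon bias, realistic intron lengths, UTRs,
alternative splicing, sequence-similarity structure behind the BLAST
scores (scores are seeded draws), or biologically meaningful expression
covariance.  Passing tests therefore demonstrate the correctness of
storage, conversion, graph wiring, querying and search over realistically
*shaped* data — not performance or statistical behaviour on real genomes.
Proteins translated from random DNA contain internal stop codons; they
are kept verbatim (`*` characters), which is irrelevant to every contract
tested.  `generate_broken_bundle()` adds the negative cases: an unknown
`Parent`, a non-numeric E-value, a singleton-only group file.

Determinism: the generator seeds R's RNG locally (restoring any prior RNG
state), formats all numbers explicitly, and writes with fixed line
endings, so one seed yields byte-identical bundles on every run.

## Problem sizes

The test suite's study conditions: the end-to-end bundle is 2 chromosomes
× 100 kb with 50 genes and 4 assays; region queries are checked on 1,000
random windows per chromosome; ontology closure on 100 random DAGs of up
to 100 nodes; search contracts on 20 independently seeded 4-gene stores;
the shared unit-test fixture is a 10-gene bundle.  These sizes exercise
every merge, boundary and filter path while keeping the whole suite quick
enough to run on every change.

## Known limitations

* Single-writer, in-process use only; no concurrency control.
* The Chado subset covers what the loaders populate, not all ~200 tables;
  attaching to a live PostgreSQL Chado is out of scope.
* BLAST input is the 12-column tabular dialect; XML is not read.
  HSP coordinates are stored on the query side only.
* GFF2/GTF, GAF, and CIGAR/Gap alignment semantics are out of scope.
* Search has no fuzzy matching and no relevance model beyond token
  frequency; the coexpression file dialect (one cluster per line) is an
  assumption about upstream MCL-style output.
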