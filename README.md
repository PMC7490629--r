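# chadolite

An embedded, Chado-compatible genomics data store for R — with loaders,
a query layer and an in-process faceted search index.

Research groups that run genome projects need one place where a genome
assembly, its annotation, computed evidence (BLAST, InterProScan, ortholog
groups, coexpression clusters), expression data and literature all live
together and stay queryable: a feature page for every gene, transcript and
protein; a region query for a genome browser; a single search box with
autocomplete and facet filters.  chadolite provides that integration layer
at desk scale, with no database server and no search service.  Its tables
mirror the subset of the GMOD Chado 1.31 relational schema used by
annotation portals — features typed by Sequence Ontology terms, a
`part_of`/`derives_from`/`translation_of` feature graph, interbase
(0-based, half-open) genomic coordinates — so everything in a store maps
one-to-one onto Chado's vocabulary.

What the package enforces, beyond storage:

* **Load order.** Ontologies before features, reference sequences before
  annotation, assays before expression values.  A loader invoked too early
  fails with an error naming the prerequisite command, and leaves the
  store unchanged (every load is one transaction).
* **ID consistency.** Evidence files must reference features that exist;
  violations surface as per-line error entries in a uniform load report
  (`records_seen` / `created` / `skipped` / `errors`).
* **Coordinate discipline.** GFF3 and BLAST coordinates (1-based, closed)
  are converted to interbase on the way in (`fmin = start − 1`,
  `fmax = end`) and back on the way out; region queries use strict
  half-open overlap (`fmin < end` and `fmax > start`).
* **Reproducibility.** Duplicate keys are typed errors (or explicit
  skips), loads are deterministic for any worker count, and a rebuilt
  search index is a pure function of store state.

## Worked example

The package ships a deterministic fixture generator that writes a complete
miniature genome project — genome FASTA, GFF3 gene models, translated
protein FASTA, miniature ontologies, BLAST/InterProScan results, ortholog
groups, coexpression clusters, BibTeX, assay metadata and an expression
matrix — with one consistent ID space:

```r
library(chadolite)

st <- initialize_store()            # or initialize_store("my.chado")
m  <- generate_bundle(seed = 42, n_chromosomes = 2, chrom_length = 100000,
                      n_genes = 50, n_assays = 4, out_dir = tempfile())
reports <- load_bundle(st, m)       # the full dependency-ordered load
reports$gff
#> load report: 360 records, 280 created, 80 skipped, 0 errors (0.66s)
```

360 GFF3 lines became 280 features (50 genes, 50 mRNAs, 130 exons, 50
multi-segment CDS features; the 80 "skipped" lines are CDS segments merged
into an existing feature).  The store now holds the whole project:

```r
st
#> chado_store: <in memory>
#>   cv                     6
#>   cvterm                 30
#>   cvterm_relationship    16
#>   organism               1
#>   feature                432
#>   featureloc             460
#>   feature_relationship   280
#>   featureprop            418
#>   feature_cvterm         40
#>   analysisfeature        100
#>   pub                    3
#>   assay                  4
#>   expression_value       200
#>   ...
```

Feature pages, genome-browser region queries and sequence export are
direct store projections:

```r
feature_detail(st, get_feature(st, "Atest synthetica", "mRNA0001",
                               "polypeptide"))
#> mRNA0001 [polypeptide] Atest synthetica
#>   relationships: 1, locations: 0, properties: 1, GO terms: 2
#>   similarity hits: 1, expression values: 0, publications: 0
#>   ortholog group: OG0002

region_query(st, "chr1", 0, 5000, types = "gene")
#> (1 gene: gene0001 at interbase [185, 473), with its mRNA/exon/CDS
#>  subtree nested)

cat(export_fasta(st, "gene0003"))
#> >gene0003
#> GCGATAATTGGGTAAAGTTCGGCGCCTATACAGGAGTATAATAATGGGATATAGCTCTGA
#> ...
```

The search index covers every gene, mRNA and polypeptide, with keyword
autocomplete and faceted filtering:

```r
idx <- build_index(st)
idx
#> chado_search_index: 150 documents, 267 keywords

autocomplete(idx, "kin", 5)
#> [1] "kinase"

search_features(idx, "kinase", filters = list(type = "polypeptide"))
#> search page 1 (7 rows of 7 hits)
#>  uniquename         organism        type score
#>    mRNA0001 Atest synthetica polypeptide     3
#>    mRNA0009 Atest synthetica polypeptide     3
#>    ...
```

Facet counts (organism, type, orthology, coexpression, GO namespace,
biomaterial, treatment) come back with every result page, computed on the
match set with all other dimensions' filters applied.

## Command line

The same operations are available as management commands via
`inst/cli/chadolite` (or `cli_run()` from R):

```sh
chadolite --store my.chado init
chadolite --store my.chado load-organism Atest synthetica
chadolite --store my.chado load-ontology mini_so.obo
chadolite --store my.chado load-fasta genome.fasta --organism 'Atest synthetica'
chadolite --store my.chado load-gff annotation.gff3 --organism 'Atest synthetica'
# ... load-protein-fasta, load-blast, load-interproscan, load-orthologs,
#     load-coexpression, load-bibtex, load-assays, load-expression ...
chadolite --store my.chado build-index
chadolite --store my.chado search kinase --filter type=polypeptide
chadolite --store my.chado region chr1 0 50000 --types gene
chadolite --store my.chado stats
```

Loaders stream progress to stderr (suppress with `--quiet`), accept
`--threads N` (staging only; final state is identical for any worker
count) and `--on-duplicate {error,skip}`; `--strict` turns per-record
error entries into a nonzero exit.

## Scope

HTML rendering, a HTTP service, and a real external search engine are out
of scope: the package implements the data contracts behind such interfaces
(the nested region-feature shape a JBrowse-style adapter consumes, the
TSV/FASTA download writers, the facet-count model) in-process.  See the
methods vignette (`vignettes/chadolite-methods.Rmd`) for the data model,
loader semantics and design rationale.
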