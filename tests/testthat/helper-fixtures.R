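# Shared fixtures built once per test run.  small_bundle()/small_store()
# memoise a 10-gene bundle and its fully loaded store; tests that mutate a
# store must build their own.

.fixture_cache <- new.env(parent = emptyenv())

small_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    .fixture_cache$bundle <- generate_bundle(
      seed = 7L, n_chromosomes = 2L, chrom_length = 50000L,
      n_genes = 10L, n_assays = 3L,
      out_dir = file.path(tempdir(), "chadolite-small-bundle")
    )
  }
  .fixture_cache$bundle
}

small_store <- function() {
  if (is.null(.fixture_cache$store)) {
    st <- initialize_store()
    .fixture_cache$reports <- load_bundle(st, small_bundle())
    .fixture_cache$store <- st
  }
  .fixture_cache$store
}

small_reports <- function() {
  small_store()
  .fixture_cache$reports
}

# the full-size study bundle: 2 chromosomes x 100 kb, 50 genes, 4 assays
full_bundle <- function() {
  if (is.null(.fixture_cache$full_bundle)) {
    .fixture_cache$full_bundle <- generate_bundle(
      seed = 42L, n_chromosomes = 2L, chrom_length = 100000L,
      n_genes = 50L, n_assays = 4L,
      out_dir = file.path(tempdir(), "chadolite-full-bundle")
    )
  }
  .fixture_cache$full_bundle
}

full_store <- function() {
  if (is.null(.fixture_cache$full_store)) {
    st <- initialize_store()
    .fixture_cache$full_reports <- load_bundle(st, full_bundle())
    .fixture_cache$full_store <- st
  }
  .fixture_cache$full_store
}

full_reports <- function() {
  full_store()
  .fixture_cache$full_reports
}

# minimal store with just the fixture ontologies and one organism
ontology_store <- function() {
  b <- small_bundle()
  st <- initialize_store()
  add_organism(st, "Atest", "synthetica")
  load_obo(st, b$paths$so_obo)
  load_obo(st, b$paths$go_obo)
  st
}

# independent brute-force oracles ------------------------------------------

# transitive closure by breadth-first search over an edge list
bfs_closure <- function(edges, start) {
  seen <- integer()
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(edges$object[edges$subject %in% frontier])
    nxt <- setdiff(nxt, c(seen, start))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

# all feature ids with any location overlapping [start, end) on src,
# by direct scan of the featureloc table
brute_overlap <- function(store, src_id, start, end) {
  fl <- store$tables$featureloc
  hit <- fl[fl$srcfeature_id == src_id & fl$fmin < end & fl$fmax > start, ]
  sort(unique(hit$feature_id))
}

# flatten a region_query result into all uniquenames in the trees
flatten_region <- function(nodes) {
  out <- character()
  walk <- function(n) {
    out <<- c(out, n$uniquename)
    for (ch in n$children) walk(ch)
  }
  for (n in nodes) walk(n)
  out
}

# reverse complement without Biostrings
naive_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", a = "t", c = "g", g = "c",
           t = "a", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

fasta_residues <- function(path) {
  lines <- readLines(path)
  idx <- cumsum(startsWith(lines, ">"))
  headers <- sub("^>", "", lines[startsWith(lines, ">")])
  headers <- vapply(strsplit(headers, "[[:space:]]+"), `[`, character(1), 1)
  seqs <- vapply(split(lines[!startsWith(lines, ">")],
                       idx[!startsWith(lines, ">")]),
                 paste, character(1), collapse = "")
  stats::setNames(as.character(seqs), headers)
}
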