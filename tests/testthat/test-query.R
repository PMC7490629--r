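test_that("feature_detail reflects every store section exactly", {
  st <- small_store()
  m <- small_bundle()
  # a polypeptide with GO terms, one InterProScan hit and a group
  poly <- get_feature(st, "Atest synthetica", "mRNA0001", "polypeptide")
  d <- feature_detail(st, poly)
  expect_s3_class(d, "chado_feature_detail")
  expect_equal(d$type, "polypeptide")
  expect_setequal(d$go_terms$accession, c("GO:0016301", "GO:0006468"))
  expect_equal(nrow(d$similarity), 1L)          # InterProScan match
  expect_false(is.null(d$orthologous_group) &&
                 is.null(d$coexpression_group))

  # an mRNA: gene via part_of, polypeptide via inverse translation_of
  dm <- feature_detail(st, get_feature(st, "Atest synthetica", "mRNA0001",
                                       "mRNA"))
  rel <- dm$relationships
  expect_true(any(rel$predicate == "part_of" & rel$direction == "out" &
                    rel$other_uniquename == "gene0001"))
  expect_true(any(rel$predicate == "translation_of" & rel$direction == "in" &
                    rel$other_type == "polypeptide"))
  expect_equal(nrow(dm$expression), m$counts$assays)

  # a bare feature: all evidence sections present but empty
  st2 <- ontology_store()
  load_fasta(st2, c(">lonely", "ACGT"), "Atest synthetica")
  db <- feature_detail(st2, "lonely")
  expect_equal(nrow(db$relationships), 0L)
  expect_equal(nrow(db$go_terms), 0L)
  expect_equal(nrow(db$similarity), 0L)
  expect_equal(nrow(db$expression), 0L)
  expect_equal(nrow(db$publications), 0L)
  expect_null(db$orthologous_group)

  expect_error(feature_detail(st, "does_not_exist"),
               class = "chado_not_found_error")
})

test_that("region_query uses half-open overlap semantics", {
  st <- ontology_store()
  load_fasta(st, c(">chr1", paste(rep("A", 300), collapse = "")),
             "Atest synthetica")
  load_gff3(st, c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1\t100\t.\t+\t.\tID=ga",    # interbase [0,100)
    "chr1\ttest\tgene\t151\t200\t.\t+\t.\tID=gb"   # interbase [150,200)
  ), "Atest synthetica")
  hit <- function(s, e) vapply(region_query(st, "chr1", s, e),
                               function(n) n$uniquename, character(1))
  expect_setequal(hit(90, 160), c("ga", "gb"))
  expect_length(hit(100, 150), 0)     # touching endpoints do not overlap
  expect_equal(hit(99, 100), "ga")
  expect_equal(hit(150, 151), "gb")
  expect_length(hit(0, 0), 0)         # empty window
  expect_error(region_query(st, "chrZ", 0, 10),
               class = "chado_not_found_error")
  expect_error(region_query(st, "chr1", 10, 5),
               class = "chado_parameter_error")
})

test_that("region_query returns whole subtrees of overlapping top-level features", {
  st <- small_store()
  m <- small_bundle()
  g <- m$genes[3, ]                       # a known gene model
  # window covering only the first base of the gene
  r <- region_query(st, g$chrom, g$start - 1, g$start)
  expect_length(r, 1)
  expect_equal(r[[1]]$uniquename, g$gene)
  flat <- flatten_region(r)
  # the whole subtree comes along: mRNA + exons + CDS
  expect_true(g$mrna %in% flat)
  expect_equal(length(flat), 2L + g$n_exons + 1L)

  # types filter: all genes of a chromosome, count against a full scan
  ft <- st$tables$feature
  ct <- st$tables$cvterm
  fl <- st$tables$featureloc
  gene_t <- ct$cvterm_id[ct$name == "gene"]
  src <- ft$feature_id[ft$uniquename == "chr1"]
  want <- sum(ft$type_id[match(unique(fl$feature_id[fl$srcfeature_id == src]),
                               ft$feature_id)] == gene_t)
  got <- region_query(st, "chr1", 0, 10^9, types = "gene")
  expect_equal(length(got), want)
  # ordered by fmin then uniquename
  starts <- vapply(got, function(n) n$start, numeric(1))
  expect_true(!is.unsorted(starts))
})

test_that("random windows agree with a brute-force interval scan", {
  st <- small_store()
  ft <- st$tables$feature
  fr <- st$tables$feature_relationship
  ct <- st$tables$cvterm
  part_of <- ct$cvterm_id[ct$name == "part_of" & ct$is_relationshiptype == 1]
  kids_of <- function(ids) fr$subject_id[fr$type_id == part_of &
                                           fr$object_id %in% ids]
  full_subtree <- function(id) {
    out <- id
    frontier <- id
    while (length(frontier)) {
      frontier <- setdiff(kids_of(frontier), out)
      out <- c(out, frontier)
    }
    out
  }
  set.seed(99)
  src <- ft$feature_id[ft$uniquename == "chr2"]
  for (i in 1:60) {
    s <- sample(0:49999, 1)
    e <- s + sample(0:5000, 1)
    cand <- brute_overlap(st, src, s, e)
    top <- cand[!vapply(cand, function(f) {
      any(fr$object_id[fr$type_id == part_of & fr$subject_id == f] %in% cand)
    }, logical(1))]
    want <- sort(ft$uniquename[match(unique(unlist(lapply(top, full_subtree))),
                                     ft$feature_id)])
    got <- sort(flatten_region(region_query(st, "chr2", s, e)))
    expect_equal(got, want)
  }
})

test_that("export_fasta round-trips chromosomes and slices minus strands", {
  st <- small_store()
  b <- small_bundle()
  input <- fasta_residues(b$paths$genome)
  out <- fasta_residues(textConnection(export_fasta(st, names(input))))
  expect_identical(out, input)

  # minus-strand slice against an independent oracle
  st2 <- ontology_store()
  ref <- "ACGTACGTACGTACGTACGT"
  load_fasta(st2, c(">mini", ref), "Atest synthetica")
  load_gff3(st2, c(
    "##gff-version 3",
    "mini\ttest\tgene\t11\t16\t.\t-\t.\tID=neg1"    # interbase [10,16)
  ), "Atest synthetica")
  got <- fasta_residues(textConnection(export_fasta(st2, "neg1")))[["neg1"]]
  expect_equal(got, naive_revcomp(substr(ref, 11, 16)))

  # 60-column wrapping
  txt <- export_fasta(st, "chr1")
  widths <- nchar(strsplit(txt, "\n")[[1]][-1])
  expect_true(all(widths <= 60))
  expect_true(all(widths[-length(widths)] == 60))

  err <- tryCatch(export_fasta(st2, "neg1x"), error = function(e) e)
  expect_s3_class(err, "chado_not_found_error")
})

test_that("a feature without residues or a single location refuses to export", {
  st <- small_store()
  # a located gene without stored residues slices from its reference
  expect_match(export_fasta(st, "gene0002"), "^>gene0002\n[ACGT\n]+$")
  # a multi-segment CDS has no residues and no single location
  err <- tryCatch(export_fasta(st, "mRNA0001.cds"), error = function(e) e)
  expect_s3_class(err, "chado_export_error")
  expect_match(conditionMessage(err), "mRNA0001.cds", fixed = TRUE)
})

test_that("export_table writes one row per feature and survives tabs", {
  st <- small_store()
  txt <- export_table(st, c("gene0001", "gene0002", "gene0003"))
  lines <- strsplit(txt, "\n")[[1]]
  expect_length(lines, 4)
  expect_equal(strsplit(lines[1], "\t")[[1]][1:4],
               c("organism", "uniquename", "name", "type"))
  parsed <- strsplit(lines[-1], "\t")
  expect_true(all(vapply(parsed, length, integer(1)) >= 5))

  expect_equal(strsplit(export_table(st, character()), "\n")[[1]],
               strsplit(txt, "\n")[[1]][1])   # empty input: header only

  # a description containing tabs/newlines parses back to one cell
  st2 <- ontology_store()
  load_fasta(st2, c(">chrT", "ACGTACGT"), "Atest synthetica")
  load_gff3(st2, c(
    "##gff-version 3",
    "chrT\ttest\tgene\t1\t4\t.\t+\t.\tID=gt1;Note=has%09tab%0Aand newline"
  ), "Atest synthetica")
  txt2 <- export_table(st2, "gt1")
  # trailing empty group fields are dropped by strsplit; pad them back
  row <- strsplit(strsplit(txt2, "\n")[[1]][2], "\t")[[1]]
  length(row) <- 7L
  expect_equal(row[5], "has tab and newline")
})
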