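# helper: a store with the mini ontologies, one organism and one 200 bp
# chromosome "chr1" whose residues we control
seq_store <- function(chr_seq = paste(rep("ACGT", 50), collapse = "")) {
  st <- ontology_store()
  load_fasta(st, c(">chr1", chr_seq), "Atest synthetica")
  st
}

test_that("FASTA records load with verbatim residues and exact lengths", {
  st <- ontology_store()
  rep <- load_fasta(st, c(
    ">chr1 some description", "ACGTacgt", "NNNN",
    ">chr2", "acgtACGT"
  ), "Atest synthetica")
  expect_equal(rep$created, 2L)
  f1 <- get_feature(st, "Atest synthetica", "chr1")
  expect_equal(f1$residues, "ACGTacgtNNNN")   # case preserved
  expect_equal(f1$seqlen, 12L)
  expect_equal(get_feature(st, "Atest synthetica", "chr2")$seqlen, 8L)

  rep2 <- load_fasta(st, c(">chr1", "AC", ">chr2", "GT"),
                     "Atest synthetica", on_duplicate = "skip")
  expect_equal(rep2$created, 0L)
  expect_equal(rep2$skipped, 2L)
  expect_equal(get_feature(st, "Atest synthetica", "chr1")$seqlen, 12L)
})

test_that("GFF3 coordinates convert to interbase exactly", {
  st <- seq_store()
  load_gff3(st, c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chr1\ttest\tgene\t101\t150\t.\t-\t.\tID=g2",
    "chr1\ttest\tgene\t151\t151\t.\t.\t.\tID=g3"
  ), "Atest synthetica")
  fl <- st$tables$featureloc
  ft <- st$tables$feature
  loc_of <- function(u) fl[fl$feature_id ==
                             ft$feature_id[ft$uniquename == u], ]
  g1 <- loc_of("g1")
  expect_equal(c(g1$fmin, g1$fmax, g1$strand), c(0L, 100L, 1L))
  g2 <- loc_of("g2")
  expect_equal(c(g2$fmin, g2$fmax, g2$strand), c(100L, 150L, -1L))
  g3 <- loc_of("g3")
  expect_equal(c(g3$fmin, g3$fmax, g3$strand), c(150L, 151L, 0L))
})

test_that("Parent attributes build the part_of graph, two-pass", {
  st <- seq_store()
  rep <- load_gff3(st, c(
    "##gff-version 3",
    # child precedes parent: forward reference must be legal
    "chr1\ttest\texon\t1\t40\t.\t+\t.\tID=e1;Parent=m1",
    "chr1\ttest\texon\t61\t100\t.\t+\t.\tID=e2;Parent=m1",
    "chr1\ttest\tmRNA\t1\t100\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\ttest\tgene\t1\t100\t.\t+\t.\tID=g1"
  ), "Atest synthetica")
  expect_equal(rep$created, 4L)
  expect_equal(nrow(rep$errors), 0L)
  fr <- st$tables$feature_relationship
  ft <- st$tables$feature
  ct <- st$tables$cvterm
  part_of <- ct$cvterm_id[ct$name == "part_of" & ct$is_relationshiptype == 1]
  uname <- function(id) ft$uniquename[match(id, ft$feature_id)]
  got <- sprintf("%s part_of %s",
                 uname(fr$subject_id[fr$type_id == part_of]),
                 uname(fr$object_id[fr$type_id == part_of]))
  expect_setequal(got, c("m1 part_of g1", "e1 part_of m1", "e2 part_of m1"))
})

test_that("discontiguous lines sharing an ID merge into ranked locations", {
  st <- seq_store()
  rep <- load_gff3(st, c(
    "##gff-version 3",
    "chr1\ttest\tCDS\t61\t100\t.\t+\t0\tID=c1",
    "chr1\ttest\tCDS\t1\t30\t.\t+\t0\tID=c1"
  ), "Atest synthetica")
  expect_equal(rep$created, 1L)
  expect_equal(rep$skipped, 1L)
  ft <- st$tables$feature
  fl <- st$tables$featureloc
  locs <- fl[fl$feature_id == ft$feature_id[ft$uniquename == "c1"], ]
  locs <- locs[order(locs$rank), ]
  expect_equal(locs$rank, c(0L, 1L))
  expect_equal(locs$fmin, c(0L, 60L))   # rank order follows fmin
})

test_that("per-line problems are error entries, not aborts", {
  st <- seq_store()
  rep <- load_gff3(st, c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1\t100\t.\t+\t.\tID=ok1",
    "chr1\ttest\tnot_a_type\t1\t50\t.\t+\t.\tID=bad1",
    "chr1\ttest\tgene\t90\t40\t.\t+\t.\tID=bad2",
    "chr1\ttest\tmRNA\t1\t100\t.\t+\t.\tID=ok2;Parent=missing_gene"
  ), "Atest synthetica")
  expect_equal(rep$created, 2L)
  msgs <- rep$errors$message
  expect_true(any(grepl("not_a_type", msgs)))
  expect_true(any(grepl("start.*end|90", msgs)))
  expect_true(any(grepl("missing_gene", msgs)))
})

test_that("loading GFF3 before its reference sequences is refused atomically", {
  st <- ontology_store()
  before <- store_stats(st)
  err <- tryCatch(
    load_gff3(st, c(
      "##gff-version 3",
      "chrZ\ttest\tgene\t1\t100\t.\t+\t.\tID=g1"
    ), "Atest synthetica"),
    error = function(e) e
  )
  expect_s3_class(err, "chado_load_order_error")
  expect_match(conditionMessage(err), "load_fasta")
  expect_equal(store_stats(st), before)
})

test_that("an embedded ##FASTA section is honoured as reference sequence", {
  st <- ontology_store()
  rep <- load_gff3(st, c(
    "##gff-version 3",
    "chrF\ttest\tgene\t1\t20\t.\t+\t.\tID=gf1",
    "##FASTA",
    ">chrF",
    "ACGTACGTACGTACGTACGTACGT"
  ), "Atest synthetica")
  expect_equal(rep$created, 1L)
  expect_equal(get_feature(st, "Atest synthetica", "chrF")$seqlen, 24L)
  expect_equal(get_feature(st, "Atest synthetica", "gf1")$type, "gene")
})

test_that("ID-less leaf features get a synthesized uniquename", {
  st <- seq_store()
  load_gff3(st, c(
    "##gff-version 3",
    "chr1\ttest\texon\t11\t30\t.\t-\t.\t."
  ), "Atest synthetica")
  got <- get_feature(st, "Atest synthetica", "exon:chr1:10..30:-1")
  expect_equal(got$type, "exon")
})

test_that("attributes map to name, description and typed properties", {
  st <- seq_store()
  load_gff3(st, c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1\t100\t.\t+\t.\tID=g1;Name=ABC1;Note=putative kinase;custom_tag=hello"
  ), "Atest synthetica")
  d <- feature_detail(st, "g1")
  expect_equal(d$name, "ABC1")
  expect_true(any(d$properties$type == "description" &
                    d$properties$value == "putative kinase"))
  expect_true(any(d$properties$type == "custom_tag" &
                    d$properties$value == "hello"))
})

test_that("length is conserved through interbase conversion (whole bundle)", {
  st <- small_store()
  b <- small_bundle()
  lines <- readLines(b$paths$gff)
  lines <- lines[!startsWith(lines, "#")]
  cols <- strsplit(lines, "\t", fixed = TRUE)
  want <- sort(vapply(cols, function(f) {
    as.integer(f[5]) - as.integer(f[4]) + 1L
  }, integer(1)))
  ft <- st$tables$feature
  fl <- st$tables$featureloc
  match_type <- st$tables$cvterm$cvterm_id[st$tables$cvterm$name == "match"]
  gff_locs <- fl[!fl$feature_id %in%
                   ft$feature_id[ft$type_id == match_type], ]
  expect_equal(sort(gff_locs$fmax - gff_locs$fmin), want)
})

test_that("every mRNA has exactly one part_of path to a gene", {
  st <- small_store()
  ft <- st$tables$feature
  ct <- st$tables$cvterm
  fr <- st$tables$feature_relationship
  part_of <- ct$cvterm_id[ct$name == "part_of" & ct$is_relationshiptype == 1]
  mrna_t <- ct$cvterm_id[ct$name == "mRNA"]
  gene_t <- ct$cvterm_id[ct$name == "gene"]
  for (mid in ft$feature_id[ft$type_id == mrna_t]) {
    parents <- fr$object_id[fr$subject_id == mid & fr$type_id == part_of]
    expect_length(parents, 1)
    expect_equal(ft$type_id[match(parents, ft$feature_id)], gene_t)
  }
})

test_that("protein FASTA links translation_of and flags orphans", {
  st <- seq_store()
  load_gff3(st, c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t1\t100\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\ttest\tmRNA\t1\t100\t.\t+\t.\tID=m2;Parent=g1"
  ), "Atest synthetica")
  rep <- load_protein_fasta(st, c(
    ">m1", "MKV", ">m2", "MLL", ">orphan", "MAA"
  ), "Atest synthetica")
  expect_equal(rep$created, 2L)
  expect_equal(nrow(rep$errors), 1L)
  expect_match(rep$errors$message[1], "orphan")
  d <- feature_detail(st, "m1", type_name = "polypeptide")
  expect_true(any(d$relationships$predicate == "translation_of" &
                    d$relationships$other_uniquename == "m1" &
                    d$relationships$other_type == "mRNA"))
})
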