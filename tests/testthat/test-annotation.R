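# store with a couple of mRNAs and polypeptides ready for evidence
evidence_store <- function() {
  st <- ontology_store()
  load_fasta(st, c(">chr1", paste(rep("ACGT", 60), collapse = "")),
             "Atest synthetica")
  load_gff3(st, c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t1\t100\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\ttest\tgene\t101\t200\t.\t+\t.\tID=g2",
    "chr1\ttest\tmRNA\t101\t200\t.\t+\t.\tID=m2;Parent=g2"
  ), "Atest synthetica")
  load_protein_fasta(st, c(">m1", "MKVLL", ">m2", "MAAAA"),
                     "Atest synthetica")
  st
}

blast_row <- function(q, evalue, n = 1) {
  sprintf("%s\tsubj%d\t95.0\t50\t2\t0\t1\t50\t1\t50\t%s\t180.5", q, n, evalue)
}

test_that("BLAST rows become match features with scores on the query", {
  st <- evidence_store()
  rep <- load_blast(st, c(
    blast_row("m1", "1e-10", 1),
    blast_row("m1", "1e-3", 2),
    blast_row("m2", "1e-7", 3)
  ), list(program = "blastp", programversion = "2", sourcename = "b1"))
  expect_equal(rep$created, 3L)
  d <- feature_detail(st, "m1", type_name = "mRNA")
  expect_equal(nrow(d$similarity), 2L)
  expect_setequal(d$similarity$significance, c(1e-10, 1e-3))
  expect_equal(unique(d$similarity$program), "blastp")
  expect_equal(d$similarity$fmin, c(0L, 0L))   # interbase on the query
  expect_equal(d$similarity$fmax, c(50L, 50L))
})

test_that("the E-value threshold skips rows and bad rows become errors", {
  st <- evidence_store()
  rep <- load_blast(st, c(
    blast_row("m1", "1e-10", 1),
    blast_row("m1", "1e-3", 2),
    blast_row("m2", "1e-7", 3)
  ), list(program = "blastp", programversion = "2", sourcename = "b2"),
  min_significance = 1e-5)
  expect_equal(rep$created, 2L)
  expect_equal(rep$skipped, 1L)

  st2 <- evidence_store()
  rep2 <- load_blast(st2, c(
    blast_row("nobody", "1e-10", 1),
    "m1\tonly\tthree",
    blast_row("m1", "not_a_number", 2)
  ), list(program = "blastp", programversion = "2", sourcename = "b3"))
  expect_equal(rep2$created, 0L)
  expect_equal(nrow(rep2$errors), 3L)
  expect_true(any(grepl("nobody", rep2$errors$message)))
  expect_true(any(grepl("12", rep2$errors$message)))
  expect_true(any(grepl("not_a_number", rep2$errors$message)))
})

ipr_row <- function(id, go = "-", ipr = "IPR000001") {
  sprintf("%s\t%s\t5\tPfam\tPF00069\tkinase domain\t1\t5\t1.0E-30\tT\t01-01-2020\t%s\tkinase family\t%s",
          id, strrep("0", 32), ipr, go)
}

test_that("InterProScan rows attach matches and dispatch GO terms", {
  st <- evidence_store()
  rep <- load_interproscan(st, c(
    ipr_row("m1", go = "GO:0016301"),
    ipr_row("m2", go = "-", ipr = "-")
  ), list(program = "iprscan", programversion = "5", sourcename = "i1"))
  expect_equal(rep$created, 2L)
  d1 <- feature_detail(st, "m1", type_name = "polypeptide")
  expect_equal(nrow(d1$similarity), 1L)
  expect_equal(d1$go_terms$name, "kinase activity")
  d2 <- feature_detail(st, "m2", type_name = "polypeptide")
  expect_equal(nrow(d2$similarity), 1L)
  expect_equal(nrow(d2$go_terms), 0L)
})

test_that("GO column without the Gene Ontology aborts atomically", {
  st <- initialize_store()
  add_organism(st, "Atest", "synthetica")
  load_obo(st, small_bundle()$paths$so_obo)      # SO only, no GO
  load_fasta(st, c(">chr1", "ACGTACGTACGT"), "Atest synthetica")
  load_gff3(st, c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1\t10\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t1\t10\t.\t+\t.\tID=m1;Parent=g1"
  ), "Atest synthetica")
  load_protein_fasta(st, c(">m1", "MKV"), "Atest synthetica")
  before <- store_stats(st)
  err <- tryCatch(
    load_interproscan(st, ipr_row("m1", go = "GO:0016301"),
                      list(program = "iprscan", programversion = "5",
                           sourcename = "i2")),
    error = function(e) e
  )
  expect_s3_class(err, "chado_load_order_error")
  expect_match(conditionMessage(err), "load_obo")
  expect_equal(store_stats(st), before)
})

test_that("assign_go_terms creates only novel pairs and resolves alt_ids", {
  st <- evidence_store()
  f <- get_feature(st, "Atest synthetica", "m1", "polypeptide")
  expect_equal(assign_go_terms(st, f, c("GO:0016301", "GO:0006468")), 2L)
  expect_equal(assign_go_terms(st, f, c("GO:0016301", "GO:0006468")), 0L)
  # one novel + one duplicate (via alt_id of an assigned term)
  expect_equal(assign_go_terms(st, f, c("GO:0050337", "GO:0005737")), 1L)
  expect_error(assign_go_terms(st, f, "GO:9999999"),
               class = "chado_missing_term_error")
})

test_that("ortholog groups assign properties and skip singletons", {
  st <- evidence_store()
  rep <- load_ortholog_groups(st, c(
    "OG1: ath|m1 bdi|m2",
    "OG2: ath|m1",
    "OG3: ath|m2 xyz|unknown_prot"
  ))
  expect_equal(rep$skipped, 1L)                      # OG2 singleton
  expect_equal(nrow(rep$errors), 1L)                 # unknown member
  expect_equal(rep$created, 3L)                      # m1+m2 in OG1, m2 in OG3
  og1 <- group_members(st, "orthologous group", "OG1")
  expect_equal(og1$uniquename, c("m1", "m2"))
  expect_equal(unique(og1$type), "polypeptide")
  expect_equal(nrow(group_members(st, "orthologous group", "OG2")), 0L)
})

test_that("coexpression clusters are named CLUSTER<k> in line order", {
  st <- evidence_store()
  rep <- load_coexpression_clusters(st, c(
    "m1\tm2",
    "",
    "g1 g2",
    "m1"
  ))
  expect_equal(rep$created, 4L)
  expect_equal(rep$skipped, 1L)                      # the singleton line
  expect_setequal(group_members(st, "coexpression group",
                                "CLUSTER1")$uniquename, c("m1", "m2"))
  expect_setequal(group_members(st, "coexpression group",
                                "CLUSTER2")$uniquename, c("g1", "g2"))
  expect_equal(nrow(group_members(st, "coexpression group", "CLUSTER3")), 0L)
})

test_that("group membership equals a brute-force group-by over properties", {
  st <- small_store()
  fp <- st$tables$featureprop
  ct <- st$tables$cvterm
  for (kind in c("orthologous group", "coexpression group")) {
    pt <- ct$cvterm_id[ct$name == kind]
    props <- fp[fp$type_id == pt, ]
    for (gid in unique(props$value)) {
      want <- sort(st$tables$feature$uniquename[
        match(props$feature_id[props$value == gid],
              st$tables$feature$feature_id)
      ])
      got <- group_members(st, kind, gid)$uniquename
      expect_equal(sort(got), want)
    }
  }
})

test_that("BibTeX entries load and attach to features", {
  st <- evidence_store()
  bib <- c(
    "@article{smith2020,",
    "  title = {A study of things},",
    "  author = {Smith, A.},",
    "  year = {2020}",
    "}",
    "@article{jones2021,",
    "  title = {More things},",
    "  author = {Jones, B. and Smith, A.},",
    "  year = {2021}",
    "}"
  )
  rep <- load_bibtex(st, bib, link_to = c("g1", "g2"))
  expect_equal(rep$created, 2L)
  expect_equal(sort(feature_detail(st, "g1")$publications$uniquename),
               c("jones2021", "smith2020"))
  expect_equal(nrow(feature_detail(st, "g2")$publications), 2L)
  expect_equal(nrow(feature_detail(st, "m1",
                                   type_name = "mRNA")$publications), 0L)
  before <- store_stats(st)
  expect_error(load_bibtex(st, bib), class = "chado_unique_error")
  expect_equal(store_stats(st), before)              # atomic abort
})

test_that("every analysis score points at a match of its own run", {
  st <- small_store()
  af <- st$tables$analysisfeature
  ft <- st$tables$feature
  ct <- st$tables$cvterm
  match_t <- ct$cvterm_id[ct$name == "match"]
  expect_gt(nrow(af), 0)
  expect_true(all(ft$type_id[match(af$feature_id, ft$feature_id)] == match_t))
  # match uniquenames embed the sourcename of their analysis run
  an <- st$tables$analysis
  src <- an$sourcename[match(af$analysis_id, an$analysis_id)]
  expect_true(all(startsWith(
    ft$uniquename[match(af$feature_id, ft$feature_id)], src
  )))
})

test_that("the broken bundle trips exactly the intended guards", {
  br <- generate_broken_bundle(out_dir = tempfile("broken"))
  st <- evidence_store()
  rep_g <- load_gff3(st, br$gff, "Atest synthetica")
  expect_true(any(grepl("no_such_gene", rep_g$errors$message)))
  rep_b <- load_blast(st, br$blast, list(program = "b", programversion = "1",
                                         sourcename = "broken"))
  expect_equal(rep_b$created, 0L)
  expect_true(any(grepl("not_a_number", rep_b$errors$message)))
  rep_o <- load_ortholog_groups(st, br$orthologs)
  expect_equal(rep_o$created, 0L)
  expect_equal(rep_o$skipped, 1L)
})
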