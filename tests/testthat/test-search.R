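test_that("the index covers exactly the genes, mRNAs and polypeptides", {
  st <- small_store()
  idx <- build_index(st)
  ft <- st$tables$feature
  ct <- st$tables$cvterm
  want <- sum(ct$name[match(ft$type_id, ct$cvterm_id)] %in%
                c("gene", "mRNA", "polypeptide"))
  expect_equal(idx$report$documents, want)
  expect_equal(nrow(idx$docs), want)

  # a store holding only chromosomes indexes nothing
  st2 <- ontology_store()
  load_fasta(st2, c(">c1", "ACGT", ">c2", "ACGT"), "Atest synthetica")
  expect_equal(build_index(st2)$report$documents, 0L)

  # rebuilding is deterministic
  expect_identical(build_index(st), idx)
})

test_that("autocomplete equals a linear prefix scan, ranked by frequency", {
  st <- ontology_store()
  load_fasta(st, c(">chr1", strrep("ACGT", 40)), "Atest synthetica")
  load_gff3(st, c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1\t20\t.\t+\t.\tID=ga;Note=kinase kin",
    "chr1\ttest\tgene\t21\t40\t.\t+\t.\tID=gb;Note=kinesin",
    "chr1\ttest\tgene\t41\t60\t.\t+\t.\tID=gc;Note=kinase"
  ), "Atest synthetica")
  idx <- build_index(st)
  expect_equal(autocomplete(idx, "kin", 10),
               c("kinase", "kin", "kinesin"))    # freq 2, then lexicographic
  expect_equal(autocomplete(idx, "kinas", 10), "kinase")
  expect_equal(autocomplete(idx, "KIN", 2), c("kinase", "kin"))
  expect_length(autocomplete(idx, "zzz", 10), 0)

  # completeness: every keyword appears for each of its prefixes
  kw <- idx$keywords$keyword
  for (k in kw) {
    for (p in seq_len(nchar(k))) {
      expect_true(k %in% autocomplete(idx, substr(k, 1, p), 10^6))
    }
  }
  # oracle equivalence on arbitrary prefixes
  for (p in c("g", "ki", "kine", "c")) {
    want <- kw[startsWith(kw, p)]
    expect_setequal(autocomplete(idx, p, 10^6), want)
  }
})

test_that("search uses AND-of-tokens with prefix matching and stable order", {
  st <- small_store()
  idx <- build_index(st)
  pg <- search_features(idx, "kinase", page_size = 100)
  expect_gt(pg$total, 0)
  mk <- match_docs(idx, "kinase")
  expect_equal(sort(paste(pg$rows$uniquename, pg$rows$type)),
               sort(paste(idx$docs$uniquename[mk], idx$docs$type[mk])))
  # AND semantics: both tokens must match
  pg2 <- search_features(idx, "protein kinase", page_size = 100)
  expect_true(all(pg2$rows$uniquename %in% pg$rows$uniquename))
  pg3 <- search_features(idx, "kinase zzznothing", page_size = 100)
  expect_equal(pg3$total, 0L)
  # rows ordered by score desc then uniquename
  sc <- pg$rows$score
  expect_true(all(diff(sc) <= 0))
})

test_that("filters compose as set intersection over every dimension", {
  st <- small_store()
  idx <- build_index(st)
  base <- all_rows(idx, "", list())$rows$uniquename
  for (dim in c("organism", "type", "orthology", "coexpression",
                "annotation", "biomaterial", "treatment")) {
    vals <- unique(unlist(lapply(seq_len(nrow(idx$docs)),
                                 function(k) doc_values(idx, dim, k))))
    for (v in vals) {
      got <- all_rows(idx, "", stats::setNames(list(v), dim))$rows$uniquename
      want_idx <- which(vapply(seq_len(nrow(idx$docs)), function(k) {
        v %in% doc_values(idx, dim, k)
      }, logical(1)))
      expect_setequal(got, idx$docs$uniquename[want_idx])
      expect_setequal(intersect(base, got), got)
    }
  }
  expect_error(search_features(idx, "", list(flavour = "sweet")),
               class = "chado_parameter_error")
})

test_that("facet counts equal a brute-force group-by on the match set", {
  st <- small_store()
  idx <- build_index(st)
  for (q in c("", "kinase", "transporter")) {
    pg <- search_features(idx, q, page_size = 1000)
    mk <- match_docs(idx, q)
    for (dim in unique(pg$facets$dimension)) {
      vals <- unlist(lapply(mk, function(k) doc_values(idx, dim, k)))
      want <- table(vals)
      fc <- pg$facets[pg$facets$dimension == dim, ]
      expect_setequal(fc$value, names(want))
      for (v in fc$value) {
        expect_equal(fc$count[fc$value == v], unname(want[[v]]))
      }
    }
    # organism facet counts sum to total hits (one organism per hit)
    org <- pg$facets[pg$facets$dimension == "organism", ]
    expect_equal(sum(org$count), pg$total)
  }
})

test_that("facets ignore their own dimension's filter but honour others", {
  st <- small_store()
  idx <- build_index(st)
  pg <- search_features(idx, "kinase", list(type = "polypeptide"),
                        page_size = 1000)
  expect_true(all(pg$rows$type == "polypeptide"))
  # the type facet still counts the other types of the unfiltered match set
  type_fc <- pg$facets[pg$facets$dimension == "type", ]
  mk <- match_docs(idx, "kinase")
  want <- table(idx$docs$type[mk])
  expect_setequal(type_fc$value, names(want))
  # every other facet is computed on the type-filtered set
  orth <- pg$facets[pg$facets$dimension == "orthology", ]
  mk_f <- mk[idx$docs$type[mk] == "polypeptide"]
  want_o <- table(ifelse(idx$docs$orthology[mk_f], "yes", "no"))
  for (v in orth$value) {
    expect_equal(orth$count[orth$value == v], unname(want_o[[v]]))
  }
})

test_that("pagination partitions the ordered result set", {
  st <- small_store()
  idx <- build_index(st)
  full <- search_features(idx, "", page_size = 10^6)
  for (ps in c(3L, 7L, 10L)) {
    pieces <- all_rows(idx, "", list(), page_size = ps)
    expect_equal(pieces$rows$uniquename, full$rows$uniquename)
    expect_equal(anyDuplicated(paste(pieces$rows$uniquename,
                                     pieces$rows$type)), 0L)
    expect_equal(pieces$total, full$total)
  }
  beyond <- search_features(idx, "", page = 10^4, page_size = 10L)
  expect_equal(nrow(beyond$rows), 0L)
  expect_equal(beyond$total, full$total)
})
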