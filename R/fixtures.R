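# Deterministic synthetic fixture bundle: a miniature genome annotation
# project whose files share one consistent set of feature IDs, so the whole
# load order is exercisable with no download.  Residues are uniform-random
# ACGT; proteins are true translations of the spliced CDS (standard code),
# so sequence round trips are meaningful.  No codon bias, intron-length
# model or realistic scores are attempted.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mini_so_obo <- function() {
  c("format-version: 1.2",
    "default-namespace: sequence",
    "",
    "[Term]", "id: SO:0000110", "name: sequence_feature",
    "[Term]", "id: SO:0000001", "name: region", "is_a: SO:0000110",
    "[Term]", "id: SO:0000340", "name: chromosome", "is_a: SO:0000001",
    "[Term]", "id: SO:0000704", "name: gene", "is_a: SO:0000001",
    "[Term]", "id: SO:0000673", "name: transcript", "is_a: SO:0000001",
    "[Term]", "id: SO:0000234", "name: mRNA", "is_a: SO:0000673",
    "[Term]", "id: SO:0000147", "name: exon", "is_a: SO:0000001",
    "[Term]", "id: SO:0000316", "name: CDS", "is_a: SO:0000001",
    "[Term]", "id: SO:0000104", "name: polypeptide", "is_a: SO:0000001",
    "[Term]", "id: SO:0000343", "name: match", "is_a: SO:0000001",
    "[Typedef]", "id: part_of", "name: part_of",
    "[Typedef]", "id: derives_from", "name: derives_from",
    "[Typedef]", "id: translation_of", "name: translation_of")
}

.mini_go_obo <- function() {
  c("format-version: 1.2",
    "",
    "[Term]", "id: GO:0003674", "name: molecular_function",
    "namespace: molecular_function",
    "[Term]", "id: GO:0003824", "name: catalytic activity",
    "namespace: molecular_function", "is_a: GO:0003674",
    "[Term]", "id: GO:0016740", "name: transferase activity",
    "namespace: molecular_function", "is_a: GO:0003824",
    "[Term]", "id: GO:0016301", "name: kinase activity",
    "namespace: molecular_function", "alt_id: GO:0050337",
    "is_a: GO:0016740",
    "[Term]", "id: GO:0008150", "name: biological_process",
    "namespace: biological_process",
    "[Term]", "id: GO:0006468", "name: protein phosphorylation",
    "namespace: biological_process", "is_a: GO:0008150",
    "[Term]", "id: GO:0006810", "name: transport",
    "namespace: biological_process", "is_a: GO:0008150",
    "[Term]", "id: GO:0005575", "name: cellular_component",
    "namespace: cellular_component",
    "[Term]", "id: GO:0005737", "name: cytoplasm",
    "namespace: cellular_component", "is_a: GO:0005575",
    "[Term]", "id: GO:0016020", "name: membrane",
    "namespace: cellular_component", "is_a: GO:0005575")
}

.fixture_products <- c(
  "protein kinase", "sugar transporter", "acid phosphatase",
  "transcription factor", "heat shock protein", "cell wall hydrolase",
  "zinc finger protein", "dna binding protein"
)

# GO accessions attached per product class (via the InterProScan fixture)
.fixture_go_for <- function(product) {
  if (grepl("kinase", product)) return(c("GO:0016301", "GO:0006468"))
  if (grepl("transporter", product)) return(c("GO:0006810", "GO:0016020"))
  if (grepl("phosphatase", product)) return(c("GO:0003824", "GO:0005737"))
  character()
}

#' Generate a mutually consistent synthetic fixture bundle
#'
#' Writes a miniature genome project into `out_dir`: genome FASTA, GFF3
#' gene models (gene - mRNA - exons - CDS, non-overlapping, mixed strands),
#' protein FASTA translated from the spliced CDS, a miniature
#' Sequence-Ontology-like OBO and a miniature Gene Ontology, BLAST tabular
#' and InterProScan TSV rows referencing real protein IDs with seeded
#' scores, OrthoMCL-style ortholog groups and MCL coexpression clusters
#' partitioning subsets of the features (each including one deliberate
#' singleton), BibTeX entries, and assay metadata plus an expression
#' matrix.  The returned manifest records every ground-truth count the
#' loaders' reports can be checked against.  The same seed always produces
#' a byte-identical bundle.
#'
#' @param seed Integer RNG seed.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome (bases).
#' @param n_genes Total number of genes (distributed round-robin over the
#'   chromosomes); each gene needs about 400 bases of room, otherwise a
#'   parameter error is raised.
#' @param n_assays Number of expression assays.
#' @param out_dir Output directory (created if needed).
#' @return A `chado_bundle_manifest` list: `paths`, `counts`, `organism`,
#'   and the per-gene model table `genes`.
#' @export
generate_bundle <- function(seed = 42L, n_chromosomes = 2L,
                            chrom_length = 100000L, n_genes = 50L,
                            n_assays = 4L, out_dir = tempfile("bundle")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(seed, {
    chrom_ids <- sprintf("chr%d", seq_len(n_chromosomes))
    gene_chrom <- ((seq_len(n_genes) - 1L) %% n_chromosomes) + 1L
    per_chrom <- tabulate(gene_chrom, n_chromosomes)
    slot <- chrom_length %/% max(per_chrom, 1L)
    if (any(per_chrom > 0) && slot < 400L) {
      stop_parameter(sprintf(
        "infeasible geometry: %d genes on a %d bp chromosome leave %d bp per gene (need >= 400)",
        max(per_chrom), chrom_length, slot
      ))
    }

    genome <- lapply(chrom_ids, function(.) .rand_dna(chrom_length))
    names(genome) <- chrom_ids

    gff <- c("##gff-version 3")
    prot_headers <- character(n_genes)
    prot_seqs <- character(n_genes)
    gene_tab <- vector("list", n_genes)
    slot_counter <- integer(n_chromosomes)
    gff_lines <- 0L
    n_exons_total <- 0L
    n_cds_lines <- 0L

    for (g in seq_len(n_genes)) {
      cj <- gene_chrom[g]
      chrom <- chrom_ids[cj]
      slot_counter[cj] <- slot_counter[cj] + 1L
      slot_start <- (slot_counter[cj] - 1L) * slot + 1L
      glen <- sample(200:300, 1)
      gstart <- slot_start + sample(20:(slot - glen - 20L), 1)
      gend <- gstart + glen - 1L
      strand <- sample(c("+", "-"), 1)
      n_ex <- sample(2:3, 1)

      # exon/intron partition of the gene span (exons >= 30, introns >= 20)
      introns <- n_ex - 1L
      base <- 30L * n_ex + 20L * introns
      extra <- glen - base
      add <- if (extra > 0) as.vector(stats::rmultinom(1, extra, rep(1, n_ex)))
             else rep(0L, n_ex)
      ex_len <- 30L + add
      pos <- gstart
      ex <- matrix(0L, n_ex, 2)
      for (e in seq_len(n_ex)) {
        ex[e, ] <- c(pos, pos + ex_len[e] - 1L)
        pos <- pos + ex_len[e] + 20L
      }
      ex[n_ex, 2] <- gend
      ex_len[n_ex] <- ex[n_ex, 2] - ex[n_ex, 1] + 1L

      # CDS = exons with the last transcribed segment trimmed to a multiple
      # of 3 in total length
      cds <- ex
      total <- sum(cds[, 2] - cds[, 1] + 1L)
      trim <- total %% 3L
      if (trim > 0) {
        if (strand == "+") cds[n_ex, 2] <- cds[n_ex, 2] - trim
        else cds[1, 1] <- cds[1, 1] + trim
      }
      tx_order <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
      cum <- 0L
      phase <- integer(n_ex)
      for (e in tx_order) {
        phase[e] <- (3L - cum %% 3L) %% 3L
        cum <- cum + cds[e, 2] - cds[e, 1] + 1L
      }

      gid <- sprintf("gene%04d", g)
      mid <- sprintf("mRNA%04d", g)
      product <- .fixture_products[((g - 1L) %% length(.fixture_products)) + 1L]
      note <- sprintf("%s %d", product, g)

      gff <- c(gff, sprintf(
        "%s\tfixture\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;Note=%s",
        chrom, gstart, gend, strand, gid, toupper(gid), note
      ))
      gff <- c(gff, sprintf(
        "%s\tfixture\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        chrom, gstart, gend, strand, mid, gid
      ))
      for (e in seq_len(n_ex)) {
        gff <- c(gff, sprintf(
          "%s\tfixture\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
          chrom, ex[e, 1], ex[e, 2], strand, mid, e, mid
        ))
      }
      for (e in seq_len(n_ex)) {
        gff <- c(gff, sprintf(
          "%s\tfixture\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
          chrom, cds[e, 1], cds[e, 2], strand, phase[e], mid, mid
        ))
      }
      gff_lines <- gff_lines + 2L + 2L * n_ex
      n_exons_total <- n_exons_total + n_ex
      n_cds_lines <- n_cds_lines + n_ex

      spliced <- paste(vapply(seq_len(n_ex), function(e) {
        substr(genome[[chrom]], cds[e, 1], cds[e, 2])
      }, character(1)), collapse = "")
      if (strand == "-") spliced <- .revcomp(spliced)
      prot_headers[g] <- mid
      prot_seqs[g] <- as.character(
        Biostrings::translate(Biostrings::DNAString(spliced),
                              if.fuzzy.codon = "X")
      )
      gene_tab[[g]] <- data.frame(
        gene = gid, mrna = mid, chrom = chrom, start = gstart, end = gend,
        strand = strand, n_exons = n_ex, product = product,
        stringsAsFactors = FALSE
      )
    }
    gene_tab <- do.call(rbind, gene_tab)

    paths <- list(
      genome = file.path(out_dir, "genome.fasta"),
      gff = file.path(out_dir, "annotation.gff3"),
      proteins = file.path(out_dir, "proteins.fasta"),
      so_obo = file.path(out_dir, "mini_so.obo"),
      go_obo = file.path(out_dir, "mini_go.obo"),
      blast = file.path(out_dir, "blast.tsv"),
      interpro = file.path(out_dir, "interproscan.tsv"),
      orthologs = file.path(out_dir, "orthologs.txt"),
      clusters = file.path(out_dir, "clusters.mcl"),
      bibtex = file.path(out_dir, "publications.bib"),
      assays = file.path(out_dir, "assays.tsv"),
      expression = file.path(out_dir, "expression.tsv")
    )

    fa <- unlist(lapply(chrom_ids, function(cid) {
      c(paste0(">", cid), .wrap60(genome[[cid]]))
    }))
    writeLines(fa, paths$genome)
    writeLines(gff, paths$gff)
    writeLines(unlist(lapply(seq_len(n_genes), function(g) {
      c(paste0(">", prot_headers[g]), .wrap60(prot_seqs[g]))
    })), paths$proteins)
    writeLines(.mini_so_obo(), paths$so_obo)
    writeLines(.mini_go_obo(), paths$go_obo)

    # BLAST tabular: one hit per mRNA, seeded scores
    blast <- vapply(seq_len(n_genes), function(g) {
      qlen <- 90L + sample(0:20, 1)
      sprintf("%s\tsp|P%05d|SUBJ%d\t%.1f\t%d\t%d\t%d\t1\t%d\t%d\t%d\t%s\t%.1f",
              gene_tab$mrna[g], 10000 + g, g,
              80 + stats::runif(1) * 20, qlen, sample(0:5, 1),
              sample(0:2, 1), qlen, 10L, 9L + qlen,
              sprintf("1e-%d", sample(3:50, 1)),
              100 + stats::runif(1) * 400)
    }, character(1))
    writeLines(blast, paths$blast)

    # InterProScan TSV: one row per protein; GO column by product class
    go_assignments <- 0L
    ipr <- vapply(seq_len(n_genes), function(g) {
      gos <- .fixture_go_for(gene_tab$product[g])
      go_assignments <<- go_assignments + length(gos)
      plen <- nchar(prot_seqs[g])
      sprintf("%s\t%s\t%d\tPfam\tPF%05d\t%s domain\t1\t%d\t%s\tT\t01-01-2020\tIPR%06d\t%s family\t%s",
              gene_tab$mrna[g], paste(rep("0", 32), collapse = ""), plen,
              1000 + (g %% 50), gene_tab$product[g], max(plen - 2L, 1L),
              sprintf("%.1E", 10^-(5 + stats::runif(1) * 40)),
              20000 + (g %% 40), gene_tab$product[g],
              if (length(gos)) paste(gos, collapse = "|") else "-")
    }, character(1))
    writeLines(ipr, paths$interpro)

    # ortholog groups over proteins: pairs/triplets + one singleton
    shuffled <- sample(gene_tab$mrna)
    og_lines <- character()
    og_props <- 0L
    og_groups <- 0L
    i <- 1L
    k <- 0L
    while (i + 1L <= length(shuffled) && k < max(1L, n_genes %/% 3L)) {
      size <- min(sample(2:3, 1), length(shuffled) - i + 1L)
      if (size < 2) break
      k <- k + 1L
      members <- shuffled[i:(i + size - 1L)]
      og_lines <- c(og_lines, sprintf(
        "OG%04d: %s", k, paste(paste0("ath|", members), collapse = " ")
      ))
      og_props <- og_props + size
      og_groups <- og_groups + 1L
      i <- i + size
    }
    if (i <= length(shuffled)) {
      og_lines <- c(og_lines, sprintf("OG%04d: ath|%s", k + 1L, shuffled[i]))
    }
    writeLines(og_lines, paths$orthologs)

    # coexpression clusters over mRNAs: lines of 2-4 + one singleton line
    shuffled2 <- sample(gene_tab$mrna)
    cl_lines <- character()
    cl_props <- 0L
    cl_clusters <- 0L
    i <- 1L
    while (i + 1L <= length(shuffled2) && cl_clusters < max(1L, n_genes %/% 4L)) {
      size <- min(sample(2:4, 1), length(shuffled2) - i + 1L)
      if (size < 2) break
      cl_lines <- c(cl_lines, paste(shuffled2[i:(i + size - 1L)],
                                    collapse = "\t"))
      cl_props <- cl_props + size
      cl_clusters <- cl_clusters + 1L
      i <- i + size
    }
    if (i <= length(shuffled2)) {
      cl_lines <- c(cl_lines, shuffled2[i])
    }
    writeLines(cl_lines, paths$clusters)

    writeLines(c(
      "@article{fixture2020a,",
      "  title = {A synthetic genome annotation exercise},",
      "  author = {Doe, J. and Roe, R.},",
      "  year = {2020},",
      "  doi = {10.0000/synthetic.1}",
      "}",
      "",
      "@article{fixture2021b,",
      "  title = {Coexpression in an imaginary plant},",
      "  author = {Roe, R.},",
      "  year = {2021},",
      "  doi = {10.0000/synthetic.2}",
      "}",
      "",
      "@misc{fixture2022c,",
      "  title = {Notes on controlled vocabularies},",
      "  author = {Doe, J.},",
      "  year = {2022}",
      "}"
    ), paths$bibtex)

    biomat <- c("leaf", "root", "seed")
    treat <- c("control", "drought", "heat")
    assay_names <- sprintf("SRR%06d", 100000L + seq_len(n_assays))
    writeLines(c(
      "assay\tbiomaterial\ttreatment",
      vapply(seq_len(n_assays), function(a) {
        sprintf("%s\t%s\t%s", assay_names[a],
                biomat[((a - 1L) %% length(biomat)) + 1L],
                treat[((a - 1L) %% length(treat)) + 1L])
      }, character(1))
    ), paths$assays)

    expr_rows <- vapply(seq_len(n_genes), function(g) {
      paste(c(gene_tab$mrna[g],
              sprintf("%.2f", stats::runif(n_assays) * 100)),
            collapse = "\t")
    }, character(1))
    writeLines(c(paste(c("feature", assay_names), collapse = "\t"),
                 expr_rows), paths$expression)

    structure(list(
      paths = paths,
      organism = list(genus = "Atest", species = "synthetica"),
      genes = gene_tab,
      counts = list(
        chromosomes = n_chromosomes,
        genes = n_genes,
        mrnas = n_genes,
        exons = n_exons_total,
        cds_features = n_genes,
        cds_lines = n_cds_lines,
        gff_lines = gff_lines,
        proteins = n_genes,
        so_records = 13L,
        so_relationships = 9L,
        go_records = 10L,
        go_relationships = 7L,
        blast_rows = n_genes,
        interpro_rows = n_genes,
        go_assignments = go_assignments,
        ortholog_groups = og_groups,
        ortholog_lines = length(og_lines),
        ortholog_properties = og_props,
        coexpression_clusters = cl_clusters,
        coexpression_lines = length(cl_lines),
        coexpression_properties = cl_props,
        publications = 3L,
        assays = n_assays,
        expression_cells = n_genes * n_assays
      )
    ), class = "chado_bundle_manifest")
  })
}

#' Generate a deliberately inconsistent bundle for negative tests
#'
#' Three files that violate the consistency rules: a GFF3 whose `Parent`
#' references an unknown ID, a BLAST tabular file with a non-numeric
#' E-value field, and an ortholog groups file containing only a singleton
#' group.
#'
#' @param out_dir Output directory.
#' @return List of paths (`gff`, `blast`, `orthologs`).
#' @export
generate_broken_bundle <- function(out_dir = tempfile("broken")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gff <- file.path(out_dir, "broken.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tfixture\tgene\t1\t100\t.\t+\t.\tID=geneX",
    "chr1\tfixture\tmRNA\t1\t100\t.\t+\t.\tID=mrnaX;Parent=no_such_gene"
  ), gff)
  blast <- file.path(out_dir, "broken_blast.tsv")
  writeLines(c(
    "mRNA0001\tsubj1\t90.0\t100\t2\t0\t1\t100\t1\t100\tnot_a_number\t200.0"
  ), blast)
  orthologs <- file.path(out_dir, "broken_orthologs.txt")
  writeLines("OG1: ath|mRNA0001", orthologs)
  list(gff = gff, blast = blast, orthologs = orthologs)
}

#' Load a generated bundle in the documented order
#'
#' Runs the full dependency-ordered load: organism, ontologies, genome
#' FASTA, GFF3, protein FASTA, BLAST, InterProScan, ortholog groups,
#' coexpression clusters, publications, assays, expression matrix.
#'
#' @param store A `chado_store`.
#' @param manifest A manifest from [generate_bundle()].
#' @param threads Worker count passed to the staged loaders.
#' @param quiet Suppress progress output.
#' @return Named list of load reports.
#' @export
load_bundle <- function(store, manifest, threads = 1L, quiet = TRUE) {
  org <- manifest$organism
  add_organism(store, org$genus, org$species, on_duplicate = "skip")
  org_label <- paste(org$genus, org$species)
  p <- manifest$paths
  list(
    so = load_obo(store, p$so_obo, quiet = quiet),
    go = load_obo(store, p$go_obo, quiet = quiet),
    genome = load_fasta(store, p$genome, org_label,
                        sequence_type = "chromosome", quiet = quiet),
    gff = load_gff3(store, p$gff, org_label, threads = threads,
                    quiet = quiet),
    proteins = load_protein_fasta(store, p$proteins, org_label,
                                  quiet = quiet),
    blast = load_blast(store, p$blast, list(
      program = "blastx", programversion = "2.17.0",
      sourcename = basename(p$blast)
    ), threads = threads, quiet = quiet),
    interpro = load_interproscan(store, p$interpro, list(
      program = "interproscan", programversion = "5.0",
      sourcename = basename(p$interpro)
    ), threads = threads, quiet = quiet),
    orthologs = load_ortholog_groups(store, p$orthologs, quiet = quiet),
    coexpression = load_coexpression_clusters(store, p$clusters,
                                              quiet = quiet),
    bibtex = load_bibtex(store, p$bibtex,
                         link_to = manifest$genes$gene[1], quiet = quiet),
    assays = load_assays(store, p$assays, quiet = quiet),
    expression = load_expression_matrix(store, p$expression, quiet = quiet)
  )
}
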