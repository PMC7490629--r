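# Computed-evidence loaders: BLAST tabular, InterProScan TSV, GO term
# assignment, OrthoMCL-style ortholog groups, MCL coexpression clusters and
# BibTeX publications.  Every loader attaches evidence to features that must
# already exist (feature-ID consistency across files); every loader is
# transactional.

.new_analysis <- function(store, analysis_meta) {
  req <- c("program", "programversion", "sourcename")
  if (!all(req %in% names(analysis_meta))) {
    stop_parameter(
      "analysis_meta needs program, programversion and sourcename"
    )
  }
  an <- store$tables$analysis
  hit <- which(an$program == analysis_meta$program &
                 an$programversion == analysis_meta$programversion &
                 an$sourcename == analysis_meta$sourcename)
  if (length(hit)) {
    stop_duplicate("analysis", paste(
      analysis_meta$program, analysis_meta$programversion,
      analysis_meta$sourcename
    ))
  }
  id <- .next_id(store, "analysis")
  .append(store, "analysis", data.frame(
    analysis_id = id, program = analysis_meta$program,
    programversion = analysis_meta$programversion,
    sourcename = analysis_meta$sourcename,
    algorithm = analysis_meta$algorithm %||% NA_character_,
    timeexecuted = format(Sys.time(), "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    stringsAsFactors = FALSE
  ))
  id
}

.add_match_feature <- function(store, org_id, uniquename, query_id,
                               fmin, fmax, match_type_id) {
  res <- .add_feature(store, org_id, uniquename, match_type_id,
                      on_duplicate = "error", checksum = FALSE)
  .add_featureloc(store, res$feature_id, query_id, fmin, fmax, strand = 0L)
  res$feature_id
}

#' Load BLAST tabular (outfmt 6) results
#'
#' Requires the standard 12 columns (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore).  Per kept row one match
#' feature (type `"match"`) is located on the query (interbase-converted,
#' rank 0), the subject ID is stored as a property and cross-reference, and
#' one analysis score records bitscore (rawscore), E-value (significance)
#' and percent identity.  Rows with E-value above `min_significance` are
#' skipped; rows with a wrong column count, a non-numeric E-value or an
#' unknown query ID become error entries.
#'
#' @param store A `chado_store`.
#' @param tabular Path to the tabular file (or its text).
#' @param analysis_meta List with `program`, `programversion`, `sourcename`
#'   (and optional `algorithm`) identifying the analysis run.
#' @param min_significance Optional E-value cutoff; rows above it are
#'   counted as skipped.
#' @param threads Worker count for parse staging.
#' @param quiet Suppress progress output.
#' @return A load report.
#' @export
load_blast <- function(store, tabular, analysis_meta,
                       min_significance = NULL, threads = 1L, quiet = TRUE) {
  t0 <- as.numeric(Sys.time())
  lines <- .read_lines(tabular)
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  match_type <- resolve_term(store, "match", vocabulary = "sequence")$cvterm_id
  with_transaction(store, {
    log <- .err_log()
    created <- 0L
    skipped <- 0L
    an_id <- .new_analysis(store, analysis_meta)
    subj_term <- .prop_term(store, "subject_id")
    desc_term <- .prop_term(store, "description")

    parsed <- .stage_chunks(keep, function(ix) {
      lapply(ix, function(i) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        list(line = i, fields = f)
      })
    }, threads = threads)

    n <- length(parsed)
    for (k in seq_len(n)) {
      p <- parsed[[k]]
      f <- p$fields
      if (length(f) != 12) {
        .err_add(log, p$line,
                 sprintf("expected 12 tab-separated columns, got %d", length(f)))
        next
      }
      evalue <- suppressWarnings(as.numeric(f[11]))
      if (is.na(evalue)) {
        .err_add(log, p$line, sprintf("E-value '%s' is not numeric", f[11]))
        next
      }
      if (!is.null(min_significance) && evalue > min_significance) {
        skipped <- skipped + 1L
        next
      }
      qid <- .feature_id_by_uniquename(store, f[1])
      if (is.na(qid)) {
        .err_add(log, p$line, sprintf("unknown query ID '%s'", f[1]))
        next
      }
      ft <- store$tables$feature
      org_id <- ft$organism_id[match(qid, ft$feature_id)]
      qstart <- as.integer(f[7]); qend <- as.integer(f[8])
      mid <- .add_match_feature(
        store, org_id,
        sprintf("%s:match:%06d", analysis_meta$sourcename, k),
        qid, fmin = min(qstart, qend) - 1L, fmax = max(qstart, qend),
        match_type_id = match_type
      )
      .add_featureprop(store, mid, subj_term, f[2])
      .add_featureprop(store, mid, desc_term, f[2])
      .append(store, "feature_dbxref", data.frame(
        feature_dbxref_id = .next_id(store, "feature_dbxref"),
        feature_id = mid,
        dbxref_id = .ensure_dbxref(
          store, if (grepl(":", f[2], fixed = TRUE)) f[2] else paste0("BLAST:", f[2])
        ),
        stringsAsFactors = FALSE
      ))
      .append(store, "analysisfeature", data.frame(
        analysisfeature_id = .next_id(store, "analysisfeature"),
        analysis_id = an_id, feature_id = mid,
        rawscore = suppressWarnings(as.numeric(f[12])),
        normscore = NA_real_, significance = evalue,
        identity = suppressWarnings(as.numeric(f[3])),
        stringsAsFactors = FALSE
      ))
      created <- created + 1L
      .progress_tick(k, n, t0, "load_blast", quiet)
    }
    .progress_done(quiet)
    new_load_report(n, created, skipped, .err_df(log),
                    as.numeric(Sys.time()) - t0)
  })
}

#' Load InterProScan TSV results
#'
#' Needs at least 11 tab-separated columns per row (protein accession, MD5,
#' length, analysis, signature accession, signature description, start,
#' stop, score, status, date), with optional InterPro accession/description
#' (columns 12-13) and GO annotations (column 14, `|`-separated).  Per row a
#' match feature with an analysis score (significance = column 9) is placed
#' on the polypeptide; signature and InterPro accessions/descriptions are
#' stored as properties; GO IDs are dispatched to [assign_go_terms()].
#'
#' If any row carries GO IDs but no Gene Ontology terms are in the store,
#' the whole load aborts with a load-order error (and the store is left
#' unchanged).
#'
#' @inheritParams load_blast
#' @param tsv Path to the InterProScan TSV (or its text).
#' @return A load report.
#' @export
load_interproscan <- function(store, tsv, analysis_meta, threads = 1L,
                              quiet = TRUE) {
  t0 <- as.numeric(Sys.time())
  lines <- .read_lines(tsv)
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  match_type <- resolve_term(store, "match", vocabulary = "sequence")$cvterm_id
  with_transaction(store, {
    log <- .err_log()
    created <- 0L
    an_id <- .new_analysis(store, analysis_meta)
    desc_term <- .prop_term(store, "description")
    sig_term <- .prop_term(store, "signature")
    ipr_term <- .prop_term(store, "interpro")

    rows <- .stage_chunks(keep, function(ix) {
      lapply(ix, function(i) list(line = i,
                                  fields = strsplit(lines[i], "\t",
                                                    fixed = TRUE)[[1]]))
    }, threads = threads)

    extract_go <- function(f) {
      if (length(f) < 14 || f[14] %in% c("", "-")) return(character())
      toks <- strsplit(f[14], "|", fixed = TRUE)[[1]]
      toks <- sub("\\(.*\\)$", "", toks)      # strip "(InterPro)" suffixes
      toks[grepl("^GO:\\d+$", toks)]
    }

    # load-order check before any write beyond the analysis row
    any_go <- any(vapply(rows, function(p) length(extract_go(p$fields)) > 0,
                         logical(1)))
    if (any_go) {
      db <- store$tables$db
      if (!"GO" %in% db$name) {
        stop_load_order(
          "rows carry GO annotations but the Gene Ontology is not loaded",
          "load_obo (Gene Ontology)"
        )
      }
    }

    n <- length(rows)
    for (k in seq_len(n)) {
      p <- rows[[k]]
      f <- p$fields
      if (length(f) < 11) {
        .err_add(log, p$line,
                 sprintf("expected >= 11 columns, got %d", length(f)))
        next
      }
      pid <- .feature_id_by_uniquename(store, f[1],
                                       type_names = "polypeptide")
      if (is.na(pid)) {
        .err_add(log, p$line,
                 sprintf("unknown polypeptide ID '%s'", f[1]))
        next
      }
      ft <- store$tables$feature
      org_id <- ft$organism_id[match(pid, ft$feature_id)]
      mid <- .add_match_feature(
        store, org_id,
        sprintf("%s:match:%06d", analysis_meta$sourcename, k),
        pid, fmin = as.integer(f[7]) - 1L, fmax = as.integer(f[8]),
        match_type_id = match_type
      )
      if (!f[5] %in% c("", "-")) .add_featureprop(store, mid, sig_term, f[5])
      if (!f[6] %in% c("", "-")) .add_featureprop(store, mid, desc_term, f[6])
      if (length(f) >= 12 && !f[12] %in% c("", "-")) {
        .add_featureprop(store, mid, ipr_term, f[12])
      }
      if (length(f) >= 13 && !f[13] %in% c("", "-")) {
        .add_featureprop(store, mid, desc_term, f[13])
      }
      score <- suppressWarnings(as.numeric(f[9]))
      .append(store, "analysisfeature", data.frame(
        analysisfeature_id = .next_id(store, "analysisfeature"),
        analysis_id = an_id, feature_id = mid,
        rawscore = NA_real_, normscore = NA_real_,
        significance = score, identity = NA_real_,
        stringsAsFactors = FALSE
      ))
      gos <- extract_go(f)
      if (length(gos)) assign_go_terms(store, pid, gos, .in_transaction = TRUE)
      created <- created + 1L
      .progress_tick(k, n, t0, "load_interproscan", quiet)
    }
    .progress_done(quiet)
    new_load_report(n, created, 0L, .err_df(log),
                    as.numeric(Sys.time()) - t0)
  })
}

#' Assign GO terms to a feature
#'
#' One term assignment per novel (feature, term) pair; duplicates are
#' skipped.  Accessions may be `alt_id`s, which resolve to their primary
#' term.  An unresolvable accession raises a missing-term error.
#'
#' @param store A `chado_store`.
#' @param feature Feature id, or a row from [get_feature()].
#' @param go_accessions Character vector of `GO:nnnnnnn` accessions.
#' @param publication Optional publication citekey to attach as provenance.
#' @param evidence Optional evidence code text.
#' @param .in_transaction Internal: skip the transaction wrapper.
#' @return Number of assignments created (invisibly 0 when all were
#'   duplicates).
#' @export
assign_go_terms <- function(store, feature, go_accessions,
                            publication = NULL, evidence = NULL,
                            .in_transaction = FALSE) {
  feature_id <- if (is.data.frame(feature)) feature$feature_id[1] else
    as.integer(feature)
  body <- function() {
    pub_id <- NA_integer_
    if (!is.null(publication)) {
      pub <- store$tables$pub
      pub_id <- pub$pub_id[match(publication, pub$uniquename)]
      if (is.na(pub_id)) stop_not_found("publication", publication)
    }
    n <- 0L
    for (acc in go_accessions) {
      term <- resolve_term(store, acc)
      fc <- store$tables$feature_cvterm
      if (any(fc$feature_id == feature_id & fc$cvterm_id == term$cvterm_id)) {
        next
      }
      .append(store, "feature_cvterm", data.frame(
        feature_cvterm_id = .next_id(store, "feature_cvterm"),
        feature_id = feature_id, cvterm_id = term$cvterm_id,
        pub_id = pub_id, evidence = evidence %||% NA_character_,
        stringsAsFactors = FALSE
      ))
      n <- n + 1L
    }
    n
  }
  if (.in_transaction) body() else with_transaction(store, body())
}

# shared engine for the two group-membership loaders
.load_groups <- function(store, lines, prop_name, make_group_id,
                         split_members, member_types, quiet, t0, label) {
  with_transaction(store, {
    log <- .err_log()
    created <- 0L
    skipped <- 0L
    prop <- .prop_term(store, prop_name)
    keep <- which(nzchar(trimws(lines)))
    n <- length(keep)
    for (k in seq_len(n)) {
      i <- keep[k]
      parsed <- split_members(lines[i])
      if (is.null(parsed)) {
        .err_add(log, i, "malformed group line")
        next
      }
      members <- parsed$members
      if (length(members) < 2) {          # singleton groups carry no signal
        skipped <- skipped + 1L
        next
      }
      gid <- make_group_id(parsed, k)
      for (m in members) {
        fid <- .feature_id_by_uniquename(store, m, type_names = member_types)
        if (is.na(fid)) {
          .err_add(log, i, sprintf("unknown member ID '%s'", m))
          next
        }
        .add_featureprop(store, fid, prop, gid)
        created <- created + 1L
      }
      .progress_tick(k, n, t0, label, quiet)
    }
    .progress_done(quiet)
    new_load_report(n, created, skipped, .err_df(log),
                    as.numeric(Sys.time()) - t0)
  })
}

#' Load OrthoMCL-style ortholog groups
#'
#' Input lines look like `OG1: taxonA|prot1 taxonB|prot2 ...`; the optional
#' `taxon|` prefix is stripped and each member must resolve to a polypeptide
#' feature, which then carries an `"orthologous group"` property with the
#' group ID as value.  Singleton groups are skipped entirely; an
#' unresolvable member becomes an error entry while the other members still
#' load.  In the report `records_seen` counts group lines and `created`
#' counts membership properties.
#'
#' @param store A `chado_store`.
#' @param groups Path to the groups file (or its text).
#' @param quiet Suppress progress output.
#' @return A load report.
#' @export
load_ortholog_groups <- function(store, groups, quiet = TRUE) {
  t0 <- as.numeric(Sys.time())
  lines <- .read_lines(groups)
  .load_groups(
    store, lines, "orthologous group",
    make_group_id = function(parsed, k) parsed$id,
    split_members = function(line) {
      m <- regmatches(line, regexec("^([^:[:space:]]+):(.*)$", line))[[1]]
      if (length(m) != 3) return(NULL)
      members <- strsplit(trimws(m[3]), "[[:space:]]+")[[1]]
      members <- members[nzchar(members)]
      members <- sub("^[^|]*\\|", "", members)   # strip taxon| prefix
      list(id = m[2], members = members)
    },
    member_types = "polypeptide", quiet = quiet, t0 = t0,
    label = "load_ortholog_groups"
  )
}

#' Load MCL coexpression clusters
#'
#' One cluster per line (whitespace/tab-separated feature IDs, as written by
#' `mcl`).  Cluster *k* — numbering non-empty lines from 1 — assigns a
#' `"coexpression group"` property with value `CLUSTER<k>` to each resolved
#' member.  Singleton lines are skipped; unresolvable members become error
#' entries.  `records_seen` counts cluster lines, `created` counts
#' membership properties.
#'
#' @param store A `chado_store`.
#' @param clusters Path to the cluster file (or its text).
#' @param analysis_meta Optional analysis metadata recorded as provenance.
#' @param quiet Suppress progress output.
#' @return A load report.
#' @export
load_coexpression_clusters <- function(store, clusters, analysis_meta = NULL,
                                       quiet = TRUE) {
  t0 <- as.numeric(Sys.time())
  lines <- .read_lines(clusters)
  if (!is.null(analysis_meta)) {
    with_transaction(store, .new_analysis(store, analysis_meta))
  }
  .load_groups(
    store, lines, "coexpression group",
    make_group_id = function(parsed, k) sprintf("CLUSTER%d", k),
    split_members = function(line) {
      members <- strsplit(trimws(line), "[[:space:]]+")[[1]]
      list(id = NA_character_, members = members[nzchar(members)])
    },
    member_types = NULL, quiet = quiet, t0 = t0,
    label = "load_coexpression_clusters"
  )
}

# -- BibTeX ------------------------------------------------------------------

# Minimal BibTeX entry parser: @type{citekey, field = {value}|"value"|bare,}
.parse_bibtex <- function(lines) {
  text <- paste(lines, collapse = "\n")
  entries <- list()
  starts <- gregexpr("@[A-Za-z]+[[:space:]]*\\{", text)[[1]]
  if (starts[1] < 0) return(entries)
  line_of_pos <- function(pos) sum(strsplit(substr(text, 1, pos), "")[[1]] == "\n") + 1L
  for (s in starts) {
    etype <- sub("^@([A-Za-z]+).*", "\\1", substr(text, s, s + 40))
    open <- regexpr("{", substr(text, s, nchar(text)), fixed = TRUE) + s - 1
    depth <- 0L
    end <- NA_integer_
    for (p in open:nchar(text)) {
      ch <- substr(text, p, p)
      if (ch == "{") depth <- depth + 1L
      if (ch == "}") {
        depth <- depth - 1L
        if (depth == 0L) { end <- p; break }
      }
    }
    if (is.na(end)) next
    body <- substr(text, open + 1, end - 1)
    comma <- regexpr(",", body, fixed = TRUE)
    citekey <- if (comma > 0) trimws(substr(body, 1, comma - 1)) else trimws(body)
    fields <- list()
    rest <- if (comma > 0) substr(body, comma + 1, nchar(body)) else ""
    # split fields on top-level commas
    depth <- 0L; buf <- ""; parts <- character()
    for (p in seq_len(nchar(rest))) {
      ch <- substr(rest, p, p)
      if (ch == "{") depth <- depth + 1L
      if (ch == "}") depth <- depth - 1L
      if (ch == "," && depth == 0L) { parts <- c(parts, buf); buf <- "" }
      else buf <- paste0(buf, ch)
    }
    parts <- c(parts, buf)
    for (part in parts) {
      eq <- regexpr("=", part, fixed = TRUE)
      if (eq < 0) next
      fname <- tolower(trimws(substr(part, 1, eq - 1)))
      fval <- trimws(substr(part, eq + 1, nchar(part)))
      fval <- sub("^\\{", "", sub("\\}$", "", fval))
      fval <- sub("^\"", "", sub("\"$", "", fval))
      fields[[fname]] <- fval
    }
    entries[[length(entries) + 1L]] <- list(
      type = tolower(etype), citekey = citekey, fields = fields,
      line = line_of_pos(s)
    )
  }
  entries
}

#' Load BibTeX publications
#'
#' One publication per entry (key = citekey).  `link_to` optionally attaches
#' every loaded publication to the named features, which then list it in
#' their feature-page detail.
#'
#' @param store A `chado_store`.
#' @param bibtex Path to a BibTeX file (or its text).
#' @param link_to Optional character vector of feature uniquenames.
#' @param on_duplicate `"error"` (default, aborts) or `"skip"` for known
#'   citekeys.
#' @param quiet Suppress progress output.
#' @return A load report.
#' @export
load_bibtex <- function(store, bibtex, link_to = NULL,
                        on_duplicate = c("error", "skip"), quiet = TRUE) {
  on_duplicate <- match.arg(on_duplicate)
  t0 <- as.numeric(Sys.time())
  entries <- .parse_bibtex(.read_lines(bibtex))
  with_transaction(store, {
    log <- .err_log()
    created <- 0L
    skipped <- 0L
    link_ids <- integer()
    for (u in link_to %||% character()) {
      fid <- .feature_id_by_uniquename(store, u)
      if (is.na(fid)) {
        .err_add(log, NA_integer_, sprintf("unknown link target '%s'", u))
      } else {
        link_ids <- c(link_ids, fid)
      }
    }
    for (e in entries) {
      if (is.na(e$citekey) || !nzchar(e$citekey)) {
        .err_add(log, e$line, "entry without citekey")
        next
      }
      pub <- store$tables$pub
      if (e$citekey %in% pub$uniquename) {
        if (on_duplicate == "error") stop_duplicate("publication", e$citekey)
        skipped <- skipped + 1L
        next
      }
      year <- suppressWarnings(as.integer(e$fields$year))
      pid <- .next_id(store, "pub")
      .append(store, "pub", data.frame(
        pub_id = pid, uniquename = e$citekey,
        title = e$fields$title %||% NA_character_,
        authors = e$fields$author %||% NA_character_,
        pyear = if (length(year)) year else NA_integer_,
        doi = e$fields$doi %||% NA_character_,
        stringsAsFactors = FALSE
      ))
      for (fid in link_ids) {
        .append(store, "feature_pub", data.frame(
          feature_pub_id = .next_id(store, "feature_pub"),
          feature_id = fid, pub_id = pid, stringsAsFactors = FALSE
        ))
      }
      created <- created + 1L
    }
    .progress_done(quiet)
    new_load_report(length(entries), created, skipped, .err_df(log),
                    as.numeric(Sys.time()) - t0)
  })
}
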