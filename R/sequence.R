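# Genome / protein sequence ingestion.  FASTA goes through Biostrings
# (readBStringSet keeps residue case verbatim); GFF3 goes through
# rtracklayer::import, after splitting off any embedded ##FASTA section.
# All coordinates are converted to Chado interbase (0-based, half-open) on
# the way in: fmin = start - 1, fmax = end.

.as_text_file <- function(x, ext) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) return(x)
  tf <- tempfile(fileext = ext)
  writeLines(.read_lines(x), tf)
  tf
}

#' Load a FASTA file as features
#'
#' One feature per record; the uniquename is the first whitespace-delimited
#' token of the header.  Residues are stored verbatim (case preserved),
#' `seqlen` is the residue count and an MD5 checksum is recorded.
#'
#' @param store A `chado_store`.
#' @param fasta Path to a FASTA file (or FASTA text).
#' @param organism Organism id or `"Genus species"`; must be registered.
#' @param sequence_type Sequence Ontology type name for the records
#'   (e.g. `"chromosome"`); must resolve in the `"sequence"` vocabulary.
#' @param on_duplicate `"error"` (default, aborts naming the record) or
#'   `"skip"`.
#' @param quiet Suppress progress output.
#' @return A load report.
#' @export
load_fasta <- function(store, fasta, organism, sequence_type = "chromosome",
                       on_duplicate = c("error", "skip"), quiet = TRUE) {
  on_duplicate <- match.arg(on_duplicate)
  t0 <- as.numeric(Sys.time())
  org_id <- .organism_id(store, organism)
  type_id <- resolve_term(store, sequence_type, vocabulary = "sequence")$cvterm_id
  path <- .as_text_file(fasta, ".fasta")
  seqs <- Biostrings::readBStringSet(path)
  with_transaction(store, {
    created <- 0L
    skipped <- 0L
    n <- length(seqs)
    unames <- vapply(names(seqs), function(h) strsplit(h, "[[:space:]]+")[[1]][1],
                     character(1), USE.NAMES = FALSE)
    for (i in seq_len(n)) {
      res <- .add_feature(
        store, org_id, unames[i], type_id,
        residues = as.character(seqs[[i]]), on_duplicate = on_duplicate
      )
      if (res$created) created <- created + 1L else skipped <- skipped + 1L
      .progress_tick(i, n, t0, "load_fasta", quiet)
    }
    .progress_done(quiet)
    new_load_report(n, created, skipped, NULL, as.numeric(Sys.time()) - t0)
  })
}

# Split a GFF3 line vector into the annotation part and an embedded ##FASTA
# part (either may be empty).
.split_gff_fasta <- function(lines) {
  cut <- which(trimws(lines) == "##FASTA")
  if (length(cut) == 0) {
    # a bare ">" line also starts an implicit FASTA section
    cut <- which(startsWith(lines, ">"))
    if (length(cut) == 0) return(list(gff = lines, fasta = NULL))
    cut <- cut[1]
    return(list(gff = lines[seq_len(cut - 1L)], fasta = lines[cut:length(lines)]))
  }
  cut <- cut[1]
  fasta <- if (cut < length(lines)) lines[(cut + 1L):length(lines)] else character()
  list(gff = lines[seq_len(cut - 1L)], fasta = fasta)
}

.strand_int <- function(s) {
  s <- as.character(s)
  ifelse(s == "+", 1L, ifelse(s == "-", -1L, 0L))
}

#' Load a GFF3 annotation file
#'
#' Builds the ontology-typed feature graph: per GFF3 line group one feature
#' typed by column 3 (resolved against the Sequence Ontology), a
#' `featureloc` with `fmin = start - 1`, `fmax = end` (interbase
#' conversion), strand mapped `+/-/.` to `+1/-1/0` and phase from column 8.
#' `ID`/`Parent` attributes become `part_of` relationships (`Derives_from`
#' is honoured when stated); resolution is two-pass, so forward references
#' are legal.  Lines sharing one `ID` (discontiguous CDS) merge into one
#' feature whose locations are rank-ordered by `fmin`.  `Name` becomes the
#' feature name; `Note`/`description`/`product` become `description`
#' properties; `Dbxref` becomes cross-references; every other attribute
#' becomes a feature property typed by the attribute name.  An embedded
#' `##FASTA` section is loaded as reference sequences first.
#'
#' Reference sequences named in column 1 must already exist (load-order
#' enforcement): a missing one aborts with an error naming `load_fasta`.
#' Per-line problems (unresolvable type, `start > end`, unknown `Parent`)
#' become error entries.  In the report, `records_seen` counts GFF3 feature
#' lines, `created` counts features, and `skipped` counts lines merged into
#' an already-created feature, so the three plus the error count add up to
#' the line count.
#'
#' @param store A `chado_store`.
#' @param gff Path to a GFF3 file (or GFF3 text).
#' @param organism Organism id or `"Genus species"`.
#' @param fasta_type Type for records of an embedded `##FASTA` section.
#' @param threads Worker count for staging (final state is identical for any
#'   value).
#' @param on_duplicate `"error"` or `"skip"` for duplicate feature keys.
#' @param quiet Suppress progress output.
#' @return A load report.
#' @export
load_gff3 <- function(store, gff, organism, fasta_type = "chromosome",
                      threads = 1L, on_duplicate = c("error", "skip"),
                      quiet = TRUE) {
  on_duplicate <- match.arg(on_duplicate)
  t0 <- as.numeric(Sys.time())
  org_id <- .organism_id(store, organism)
  lines <- .read_lines(gff)
  parts <- .split_gff_fasta(lines)

  with_transaction(store, {
    if (!is.null(parts$fasta) && any(startsWith(parts$fasta, ">"))) {
      load_fasta(store, paste(parts$fasta, collapse = "\n"), org_id,
                 sequence_type = fasta_type, on_duplicate = "skip",
                 quiet = TRUE)
    }

    log <- .err_log()
    body <- parts$gff
    is_data <- !startsWith(body, "#") & nzchar(trimws(body))
    data_idx <- which(is_data)

    # pre-filter start > end lines: GenomicRanges rejects negative widths
    bad <- integer()
    for (i in data_idx) {
      f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 8) {
        .err_add(log, i, "fewer than 8 tab-separated columns")
        bad <- c(bad, i)
      } else if (suppressWarnings(as.numeric(f[4]) > as.numeric(f[5]))) {
        .err_add(log, i, sprintf("start %s > end %s", f[4], f[5]))
        bad <- c(bad, i)
      }
    }
    keep <- setdiff(data_idx, bad)
    n_lines <- length(data_idx)

    gr <- NULL
    if (length(keep)) {
      tf <- tempfile(fileext = ".gff3")
      writeLines(c("##gff-version 3", body[keep]), tf)
      gr <- rtracklayer::import(tf, format = "gff3")
      unlink(tf)
    }
    if (is.null(gr) || length(gr) == 0) {
      .progress_done(quiet)
      return(new_load_report(n_lines, 0L, 0L, .err_df(log),
                             as.numeric(Sys.time()) - t0))
    }

    # load-order: every seqid must already be a feature of this organism
    ft <- store$tables$feature
    org_feats <- ft[ft$organism_id == org_id, ]
    seqids <- unique(as.character(GenomicRanges::seqnames(gr)))
    missing_src <- setdiff(seqids, org_feats$uniquename)
    if (length(missing_src)) {
      stop_load_order(
        sprintf("reference sequence '%s' is not in the store", missing_src[1]),
        "load_fasta"
      )
    }
    src_ids <- stats::setNames(
      org_feats$feature_id[match(seqids, org_feats$uniquename)], seqids
    )

    mc_s4 <- S4Vectors::mcols(gr)
    # flatten to plain vectors/lists once: S4 subsetting per line is slow
    mc <- lapply(stats::setNames(names(mc_s4), names(mc_s4)), function(a) {
      col <- mc_s4[[a]]
      if (methods::is(col, "List")) as.list(col) else as.vector(col)
    })
    types <- as.character(mc$type)
    starts <- GenomicRanges::start(gr)
    ends <- GenomicRanges::end(gr)
    strands <- .strand_int(GenomicRanges::strand(gr))
    phases <- if ("phase" %in% names(mc)) as.integer(mc$phase) else
      rep(NA_integer_, length(gr))
    ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else
      rep(NA_character_, length(gr))
    feat_names <- if ("Name" %in% names(mc)) as.character(mc$Name) else
      rep(NA_character_, length(gr))
    srcs <- as.character(GenomicRanges::seqnames(gr))
    line_of <- keep[seq_along(gr)]  # original line numbers

    # type resolution, cached per distinct column-3 value
    type_cache <- new.env(parent = emptyenv())
    type_id_of <- function(tp) {
      hit <- mget(tp, envir = type_cache, ifnotfound = list(NULL))[[1]]
      if (!is.null(hit)) return(hit)
      id <- tryCatch(
        resolve_term(store, tp, vocabulary = "sequence")$cvterm_id,
        chado_error = function(e) NA_integer_
      )
      assign(tp, id, envir = type_cache)
      id
    }

    # synthesize uniquenames for ID-less lines
    eff_ids <- ids
    for (i in seq_along(gr)) {
      if (is.na(eff_ids[i])) {
        eff_ids[i] <- sprintf("%s:%s:%d..%d:%d", types[i], srcs[i],
                              starts[i] - 1L, ends[i], strands[i])
      }
    }

    created <- 0L
    skipped <- 0L
    id2feat <- new.env(parent = emptyenv())   # GFF ID -> feature_id
    drop_line <- logical(length(gr))

    # pass 1: features + locations (+ properties on first line of a group)
    groups <- split(seq_along(gr), eff_ids)
    order_first <- vapply(groups, function(ix) min(ix), integer(1))
    groups <- groups[order(order_first)]
    n_groups <- length(groups)
    gi <- 0L
    skip_attrs <- c("type", "score", "phase", "source", "ID", "Name",
                    "Parent", "Derives_from", "Dbxref")
    for (grp in groups) {
      gi <- gi + 1L
      first <- grp[1]
      tid <- type_id_of(types[first])
      if (is.na(tid)) {
        for (i in grp) {
          .err_add(log, line_of[i],
                   sprintf("type '%s' does not resolve in the sequence ontology",
                           types[i]))
          drop_line[i] <- TRUE
        }
        next
      }
      res <- .add_feature(store, org_id, eff_ids[first], tid,
                          name = feat_names[first],
                          on_duplicate = on_duplicate)
      if (res$created) created <- created + 1L else skipped <- skipped + 1L
      skipped <- skipped + (length(grp) - 1L)
      if (!is.na(ids[first])) assign(ids[first], res$feature_id, envir = id2feat)
      if (!res$created) next
      fid <- res$feature_id
      # rank-ordered locations by fmin
      ord <- grp[order(starts[grp], ends[grp])]
      for (r in seq_along(ord)) {
        i <- ord[r]
        .add_featureloc(store, fid, src_ids[[srcs[i]]],
                        fmin = starts[i] - 1L, fmax = ends[i],
                        strand = strands[i], phase = phases[i],
                        rank = r - 1L)
      }
      # attribute mapping (from the first line of the group)
      for (attr in names(mc)) {
        if (attr %in% skip_attrs) next
        val <- mc[[attr]][first]
        vals <- unlist(as.list(val))
        vals <- vals[!is.na(vals)]
        if (length(vals) == 0) next
        pt <- if (tolower(attr) %in% c("note", "description", "product")) {
          .prop_term(store, "description")
        } else {
          .prop_term(store, attr)
        }
        for (v in vals) .add_featureprop(store, fid, pt, as.character(v))
      }
      if ("Dbxref" %in% names(mc)) {
        vals <- unlist(as.list(mc$Dbxref[first]))
        vals <- vals[!is.na(vals)]
        for (v in vals) {
          .append(store, "feature_dbxref", data.frame(
            feature_dbxref_id = .next_id(store, "feature_dbxref"),
            feature_id = fid, dbxref_id = .ensure_dbxref(store, v),
            stringsAsFactors = FALSE
          ))
        }
      }
      .progress_tick(gi, n_groups, t0, "load_gff3", quiet)
    }

    # pass 2: Parent / Derives_from relationships
    part_of <- .relationship_type_id(store, "part_of")
    derives <- .relationship_type_id(store, "derives_from")
    seen_groups <- new.env(parent = emptyenv())
    for (i in seq_along(gr)) {
      if (drop_line[i]) next
      key <- eff_ids[i]
      if (!is.null(mget(key, envir = seen_groups,
                        ifnotfound = list(NULL))[[1]])) next
      assign(key, TRUE, envir = seen_groups)
      subj <- mget(key, envir = id2feat, ifnotfound = NA)[[1]]
      if (is.na(subj)) {
        subj <- .feature_id_by_uniquename(store, key)
        if (is.na(subj)) next
      }
      link <- function(targets, pred) {
        for (p in targets) {
          obj <- mget(p, envir = id2feat, ifnotfound = NA)[[1]]
          if (is.na(obj)) {
            .err_add(log, line_of[i],
                     sprintf("Parent '%s' references an unknown ID", p))
            next
          }
          .add_feature_relationship(store, subj, obj, pred)
        }
      }
      if ("Parent" %in% names(mc)) {
        ps <- unlist(as.list(mc$Parent[i]))
        link(ps[!is.na(ps)], part_of)
      }
      if ("Derives_from" %in% names(mc)) {
        ds <- unlist(as.list(mc$Derives_from[i]))
        link(ds[!is.na(ds)], derives)
      }
    }

    .progress_done(quiet)
    new_load_report(n_lines, created, skipped, .err_df(log),
                    as.numeric(Sys.time()) - t0)
  })
}

#' Load a protein FASTA and link polypeptides to their mRNAs
#'
#' One polypeptide feature per record whose header ID matches an existing
#' mRNA uniquename, plus a `translation_of` relationship from the
#' polypeptide to the mRNA.  Records with no matching mRNA become error
#' entries (the feature-ID consistency check across files).
#'
#' @inheritParams load_fasta
#' @return A load report.
#' @export
load_protein_fasta <- function(store, fasta, organism,
                               on_duplicate = c("error", "skip"),
                               quiet = TRUE) {
  on_duplicate <- match.arg(on_duplicate)
  t0 <- as.numeric(Sys.time())
  org_id <- .organism_id(store, organism)
  poly_id <- resolve_term(store, "polypeptide", vocabulary = "sequence")$cvterm_id
  mrna_type <- resolve_term(store, "mRNA", vocabulary = "sequence")$cvterm_id
  path <- .as_text_file(fasta, ".fasta")
  seqs <- Biostrings::readBStringSet(path)
  trans_of <- .relationship_type_id(store, "translation_of")
  with_transaction(store, {
    log <- .err_log()
    created <- 0L
    skipped <- 0L
    ft <- store$tables$feature
    mrnas <- ft[ft$organism_id == org_id & ft$type_id == mrna_type, ]
    n <- length(seqs)
    for (i in seq_len(n)) {
      uname <- strsplit(names(seqs)[i], "[[:space:]]+")[[1]][1]
      mrna_row <- match(uname, mrnas$uniquename)
      if (is.na(mrna_row)) {
        .err_add(log, i, sprintf("protein '%s' has no matching mRNA", uname))
        next
      }
      res <- .add_feature(store, org_id, uname, poly_id,
                          residues = as.character(seqs[[i]]),
                          on_duplicate = on_duplicate)
      if (res$created) {
        created <- created + 1L
        .add_feature_relationship(store, res$feature_id,
                                  mrnas$feature_id[mrna_row], trans_of)
      } else {
        skipped <- skipped + 1L
      }
      .progress_tick(i, n, t0, "load_protein_fasta", quiet)
    }
    .progress_done(quiet)
    new_load_report(n, created, skipped, .err_df(log),
                    as.numeric(Sys.time()) - t0)
  })
}
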