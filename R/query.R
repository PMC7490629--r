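# Query layer: the data contracts behind a feature page, a genome-browser
# region endpoint, group membership pages and the text/sequence download
# buttons.  Everything here is a read-only assembly of store tables.

.resolve_feature_arg <- function(store, feature, type_name = NULL) {
  if (is.data.frame(feature)) return(feature$feature_id[1])
  if (is.numeric(feature)) {
    ft <- store$tables$feature
    if (!feature %in% ft$feature_id) {
      stop_not_found("feature", as.character(feature))
    }
    return(as.integer(feature))
  }
  fid <- .feature_id_by_uniquename(store, as.character(feature),
                                  type_names = type_name)
  if (is.na(fid)) stop_not_found("feature", as.character(feature))
  fid
}

#' Assemble the full detail record for one feature
#'
#' Mirrors the cards of an annotation-portal feature page: core identity,
#' typed relationships in both directions, genomic locations, text
#' annotations (properties), functional (GO) annotation, similarity-search
#' hits with their scores, ortholog and coexpression group membership,
#' expression values with assay metadata, the sequence, and related
#' publications.  Sections with no content are present but empty, and every
#' section is a direct projection of store tables.
#'
#' @param store A `chado_store`.
#' @param feature Feature id, uniquename, or a [get_feature()] row.
#' @param type_name Optional type disambiguation for uniquename lookup.
#' @return A `chado_feature_detail` list.
#' @export
feature_detail <- function(store, feature, type_name = NULL) {
  fid <- .resolve_feature_arg(store, feature, type_name)
  ft <- store$tables$feature
  row <- ft[ft$feature_id == fid, ]
  ct <- store$tables$cvterm

  # relationships, both directions
  fr <- store$tables$feature_relationship
  out_rel <- fr[fr$subject_id == fid, ]
  in_rel <- fr[fr$object_id == fid, ]
  rel_df <- rbind(
    if (nrow(out_rel)) data.frame(
      predicate = .term_name(store, out_rel$type_id),
      direction = "out",
      other_uniquename = ft$uniquename[match(out_rel$object_id, ft$feature_id)],
      other_type = .term_name(store, ft$type_id[match(out_rel$object_id,
                                                      ft$feature_id)]),
      stringsAsFactors = FALSE
    ),
    if (nrow(in_rel)) data.frame(
      predicate = .term_name(store, in_rel$type_id),
      direction = "in",
      other_uniquename = ft$uniquename[match(in_rel$subject_id, ft$feature_id)],
      other_type = .term_name(store, ft$type_id[match(in_rel$subject_id,
                                                      ft$feature_id)]),
      stringsAsFactors = FALSE
    )
  )
  if (is.null(rel_df)) {
    rel_df <- data.frame(predicate = character(), direction = character(),
                         other_uniquename = character(),
                         other_type = character(), stringsAsFactors = FALSE)
  }

  fl <- store$tables$featureloc
  locs <- fl[fl$feature_id == fid, ]
  if (nrow(locs)) {
    locs$srcfeature <- ft$uniquename[match(locs$srcfeature_id, ft$feature_id)]
  } else {
    locs$srcfeature <- character()
  }

  fp <- store$tables$featureprop
  props <- fp[fp$feature_id == fid, ]
  props_df <- data.frame(
    type = .term_name(store, props$type_id),
    value = props$value, rank = props$rank, stringsAsFactors = FALSE
  )

  fc <- store$tables$feature_cvterm
  go_rows <- fc[fc$feature_id == fid, ]
  go_df <- data.frame(
    accession = vapply(go_rows$cvterm_id, function(id)
      .curie_of(store, ct$dbxref_id[match(id, ct$cvterm_id)]), character(1)),
    name = .term_name(store, go_rows$cvterm_id),
    namespace = .cv_name_of_term(store, go_rows$cvterm_id),
    evidence = go_rows$evidence,
    stringsAsFactors = FALSE
  )

  # similarity hits: match features located on this feature, with scores
  match_type <- tryCatch(
    resolve_term(store, "match", vocabulary = "sequence")$cvterm_id,
    chado_error = function(e) NA_integer_
  )
  hits_df <- data.frame(
    match_uniquename = character(), subject = character(),
    description = character(), program = character(),
    rawscore = numeric(), significance = numeric(), identity = numeric(),
    fmin = integer(), fmax = integer(), stringsAsFactors = FALSE
  )
  if (!is.na(match_type)) {
    on_me <- fl[fl$srcfeature_id == fid, ]
    mids <- on_me$feature_id[ft$type_id[match(on_me$feature_id,
                                              ft$feature_id)] == match_type]
    if (length(mids)) {
      af <- store$tables$analysisfeature
      an <- store$tables$analysis
      subj_term <- .prop_term(store, "subject_id")
      desc_term <- .prop_term(store, "description")
      hits_df <- do.call(rbind, lapply(mids, function(mid) {
        sc <- af[af$feature_id == mid, ]
        loc <- fl[fl$feature_id == mid, ][1, ]
        p <- fp[fp$feature_id == mid, ]
        data.frame(
          match_uniquename = ft$uniquename[match(mid, ft$feature_id)],
          subject = if (any(p$type_id == subj_term))
            p$value[p$type_id == subj_term][1] else NA_character_,
          description = if (any(p$type_id == desc_term))
            p$value[p$type_id == desc_term][1] else NA_character_,
          program = if (nrow(sc))
            an$program[match(sc$analysis_id[1], an$analysis_id)] else
              NA_character_,
          rawscore = if (nrow(sc)) sc$rawscore[1] else NA_real_,
          significance = if (nrow(sc)) sc$significance[1] else NA_real_,
          identity = if (nrow(sc)) sc$identity[1] else NA_real_,
          fmin = loc$fmin, fmax = loc$fmax,
          stringsAsFactors = FALSE
        )
      }))
    }
  }

  group_of <- function(kind) {
    pt <- .prop_term(store, kind)
    v <- fp$value[fp$feature_id == fid & fp$type_id == pt]
    if (length(v)) v[1] else NULL
  }

  ev <- store$tables$expression_value
  as_tab <- store$tables$assay
  expr_rows <- ev[ev$feature_id == fid, ]
  expr_df <- data.frame(
    assay = as_tab$name[match(expr_rows$assay_id, as_tab$assay_id)],
    biomaterial = as_tab$biomaterial[match(expr_rows$assay_id, as_tab$assay_id)],
    treatment = as_tab$treatment[match(expr_rows$assay_id, as_tab$assay_id)],
    value = expr_rows$value, stringsAsFactors = FALSE
  )

  fpub <- store$tables$feature_pub
  pub <- store$tables$pub
  pub_df <- pub[pub$pub_id %in% fpub$pub_id[fpub$feature_id == fid], ,
                drop = FALSE]
  rownames(pub_df) <- NULL

  structure(list(
    feature_id = fid,
    uniquename = row$uniquename,
    name = row$name,
    type = .term_name(store, row$type_id),
    organism = .organism_label(store, row$organism_id),
    seqlen = row$seqlen,
    relationships = rel_df,
    locations = locs[, c("srcfeature", "fmin", "fmax", "strand", "phase",
                         "rank")],
    properties = props_df,
    go_terms = go_df,
    similarity = hits_df,
    orthologous_group = group_of("orthologous group"),
    coexpression_group = group_of("coexpression group"),
    expression = expr_df,
    residues = row$residues,
    publications = pub_df
  ), class = "chado_feature_detail")
}

#' @export
print.chado_feature_detail <- function(x, ...) {
  cat(sprintf("%s [%s] %s\n", x$uniquename, x$type, x$organism))
  if (!is.na(x$name)) cat("  name:", x$name, "\n")
  cat(sprintf(
    "  relationships: %d, locations: %d, properties: %d, GO terms: %d\n",
    nrow(x$relationships), nrow(x$locations), nrow(x$properties),
    nrow(x$go_terms)
  ))
  cat(sprintf(
    "  similarity hits: %d, expression values: %d, publications: %d\n",
    nrow(x$similarity), nrow(x$expression), nrow(x$publications)
  ))
  if (!is.null(x$orthologous_group)) {
    cat("  ortholog group:", x$orthologous_group, "\n")
  }
  if (!is.null(x$coexpression_group)) {
    cat("  coexpression group:", x$coexpression_group, "\n")
  }
  invisible(x)
}

# part_of children of a set of features (subject part_of object)
.children_of <- function(store, feature_ids) {
  fr <- store$tables$feature_relationship
  part_of <- .relationship_type_id(store, "part_of")
  fr$subject_id[fr$type_id == part_of & fr$object_id %in% feature_ids]
}

.parents_of <- function(store, feature_ids) {
  fr <- store$tables$feature_relationship
  part_of <- .relationship_type_id(store, "part_of")
  fr$object_id[fr$type_id == part_of & fr$subject_id %in% feature_ids]
}

.region_node <- function(store, fid, src_id) {
  ft <- store$tables$feature
  fl <- store$tables$featureloc
  locs <- fl[fl$feature_id == fid & fl$srcfeature_id == src_id, ]
  locs <- locs[order(locs$rank), ]
  kids <- sort(unique(.children_of(store, fid)))
  kid_nodes <- lapply(kids, .region_node, store = store, src_id = src_id)
  # order children by fmin then uniquename
  if (length(kid_nodes)) {
    kmin <- vapply(kid_nodes, function(n) {
      if (is.null(n$start)) .Machine$integer.max else n$start
    }, numeric(1))
    kun <- vapply(kid_nodes, function(n) n$uniquename, character(1))
    kid_nodes <- kid_nodes[order(kmin, kun)]
  }
  i <- match(fid, ft$feature_id)
  list(
    uniquename = ft$uniquename[i],
    type = .term_name(store, ft$type_id[i]),
    start = if (nrow(locs)) min(locs$fmin) else NULL,
    end = if (nrow(locs)) max(locs$fmax) else NULL,
    strand = if (nrow(locs)) locs$strand[1] else NULL,
    phase = if (nrow(locs)) locs$phase[1] else NULL,
    segments = if (nrow(locs)) locs[, c("fmin", "fmax", "rank")] else NULL,
    children = kid_nodes
  )
}

#' Genome-browser region query
#'
#' Returns the top-level features (those with no `part_of` parent among the
#' overlap candidates) having any location overlapping the half-open
#' interbase window `[start, end)` — overlap means `fmin < end` and
#' `fmax > start`, so touching endpoints do not overlap — each carrying its
#' complete nested `part_of` subtree, the way a genome browser renders a
#' whole gene model even when only partially in view.  Results are ordered
#' by `fmin`, then uniquename.
#'
#' @param store A `chado_store`.
#' @param srcfeature Reference feature (uniquename, id, or row).
#' @param start,end Interbase window, `0 <= start <= end`.
#' @param types Optional character vector restricting the *top-level*
#'   feature types returned (e.g. `"gene"`).
#' @return List of nested region-feature records (uniquename, type,
#'   start/end in interbase on the reference, strand, phase, location
#'   segments, children).
#' @export
region_query <- function(store, srcfeature, start, end, types = NULL) {
  if (start < 0 || start > end) {
    stop_parameter("need 0 <= start <= end (interbase)")
  }
  src_id <- .resolve_feature_arg(store, srcfeature)
  fl <- store$tables$featureloc
  cand_locs <- fl[fl$srcfeature_id == src_id & fl$fmin < end & fl$fmax > start, ]
  cand <- unique(cand_locs$feature_id)
  if (length(cand) == 0) return(list())
  # top-level: no part_of parent within the candidate set
  fr <- store$tables$feature_relationship
  part_of <- .relationship_type_id(store, "part_of")
  has_parent_in_cand <- vapply(cand, function(f) {
    pars <- fr$object_id[fr$type_id == part_of & fr$subject_id == f]
    any(pars %in% cand)
  }, logical(1))
  top <- cand[!has_parent_in_cand]
  ft <- store$tables$feature
  if (!is.null(types)) {
    top <- top[.term_name(store, ft$type_id[match(top, ft$feature_id)]) %in% types]
  }
  if (length(top) == 0) return(list())
  nodes <- lapply(top, .region_node, store = store, src_id = src_id)
  starts <- vapply(nodes, function(n) as.numeric(n$start %||% Inf), numeric(1))
  unames <- vapply(nodes, function(n) n$uniquename, character(1))
  nodes[order(starts, unames)]
}

#' Members of an ortholog or coexpression group
#'
#' @param store A `chado_store`.
#' @param group_kind `"orthologous group"` or `"coexpression group"`.
#' @param group_id Group value, e.g. `"OG1"` or `"CLUSTER2"`.
#' @return Data frame of member features ordered by (organism, uniquename);
#'   empty for an unknown group id.
#' @export
group_members <- function(store, group_kind = c("orthologous group",
                                                "coexpression group"),
                          group_id) {
  group_kind <- match.arg(group_kind)
  pt <- .prop_term(store, group_kind)
  fp <- store$tables$featureprop
  fids <- fp$feature_id[fp$type_id == pt & fp$value == group_id]
  ft <- store$tables$feature
  out <- ft[ft$feature_id %in% fids,
            c("feature_id", "organism_id", "uniquename", "name", "type_id")]
  out$organism <- .organism_label(store, out$organism_id)
  out$type <- .term_name(store, out$type_id)
  out <- out[order(out$organism, out$uniquename), ]
  rownames(out) <- NULL
  out[, c("feature_id", "organism", "uniquename", "name", "type")]
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

.wrap60 <- function(seq) {
  if (nchar(seq) == 0) return(character())
  starts <- seq(1L, nchar(seq), by = 60L)
  vapply(starts, function(s) substr(seq, s, min(s + 59L, nchar(seq))),
         character(1))
}

#' Export features as FASTA text
#'
#' One record per feature, header = uniquename, residues wrapped at 60
#' columns.  A feature without stored residues is sliced from its single
#' location's reference sequence (`[fmin, fmax)` interbase) and
#' reverse-complemented when on the minus strand.  A feature with neither
#' residues nor a resolvable location raises an error naming it.
#'
#' @param store A `chado_store`.
#' @param features Vector of feature ids or uniquenames, or a data frame
#'   with a `feature_id` (or `uniquename`) column.
#' @return FASTA text (single string, records separated by newlines).
#' @export
export_fasta <- function(store, features) {
  fids <- .feature_id_vector(store, features)
  ft <- store$tables$feature
  fl <- store$tables$featureloc
  out <- character()
  for (fid in fids) {
    i <- match(fid, ft$feature_id)
    uname <- ft$uniquename[i]
    res <- ft$residues[i]
    if (is.na(res)) {
      locs <- fl[fl$feature_id == fid, ]
      if (nrow(locs) != 1) {
        stop_chado(
          sprintf("feature '%s' has no residues and no single location", uname),
          "chado_export_error"
        )
      }
      j <- match(locs$srcfeature_id[1], ft$feature_id)
      src_res <- ft$residues[j]
      if (is.na(src_res)) {
        stop_chado(
          sprintf("feature '%s' is located on a reference without residues",
                  uname),
          "chado_export_error"
        )
      }
      res <- substr(src_res, locs$fmin[1] + 1L, locs$fmax[1])
      if (!is.na(locs$strand[1]) && locs$strand[1] == -1L) {
        res <- .revcomp(res)
      }
    }
    out <- c(out, paste0(">", uname), .wrap60(res))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

.feature_id_vector <- function(store, features) {
  if (is.data.frame(features)) {
    if ("feature_id" %in% names(features)) return(features$feature_id)
    features <- features$uniquename
  }
  vapply(features, function(f) .resolve_feature_arg(store, f), integer(1),
         USE.NAMES = FALSE)
}

.sanitize_tsv <- function(x) {
  # documented rule: tabs and newlines inside a field become single spaces
  gsub("[\t\r\n]+", " ", x)
}

#' Export features as a TSV table
#'
#' Header plus one row per feature: organism, uniquename, name, type,
#' description, orthologous group, coexpression group.  Tab or newline
#' characters inside a field are replaced by single spaces so the output
#' always parses back to the same cells.
#'
#' @param store A `chado_store`.
#' @param rows Feature ids/uniquenames, a data frame with `feature_id`, or
#'   a search result page.
#' @return TSV text (UTF-8, single string).
#' @export
export_table <- function(store, rows) {
  if (inherits(rows, "chado_search_page")) rows <- rows$rows
  fids <- if (is.data.frame(rows) && nrow(rows) == 0) integer() else
    .feature_id_vector(store, rows)
  ft <- store$tables$feature
  fp <- store$tables$featureprop
  desc_term <- .prop_term(store, "description")
  og_term <- .prop_term(store, "orthologous group")
  cg_term <- .prop_term(store, "coexpression group")
  header <- paste(c("organism", "uniquename", "name", "type", "description",
                    "orthologous_group", "coexpression_group"),
                  collapse = "\t")
  lines <- vapply(fids, function(fid) {
    i <- match(fid, ft$feature_id)
    p <- fp[fp$feature_id == fid, ]
    first_val <- function(tid) {
      v <- p$value[p$type_id == tid]
      if (length(v)) v[1] else ""
    }
    fields <- c(
      .organism_label(store, ft$organism_id[i]),
      ft$uniquename[i],
      if (is.na(ft$name[i])) "" else ft$name[i],
      .term_name(store, ft$type_id[i]),
      first_val(desc_term), first_val(og_term), first_val(cg_term)
    )
    paste(.sanitize_tsv(fields), collapse = "\t")
  }, character(1))
  paste0(paste(c(header, lines), collapse = "\n"), "\n")
}
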