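# In-process search index: one denormalized document per gene, mRNA and
# polypeptide feature, an inverted keyword map for autocomplete, and
# faceted filtering with counts.  The rebuilt index is a pure function of
# store state: documents are ordered by feature id and the keyword table is
# sorted, so two builds over the same store are identical.

.tokenize <- function(text) {
  text <- tolower(paste(text[!is.na(text)], collapse = " "))
  toks <- strsplit(text, "[^a-z0-9]+")[[1]]
  toks[nchar(toks) >= 2]
}

.facet_dimensions <- c("organism", "type", "orthology", "coexpression",
                       "annotation", "biomaterial", "treatment")

#' Build the search index
#'
#' Indexes every gene, mRNA and polypeptide feature.  Each document's text
#' blob gathers the name, uniquename, description properties, GO term names
#' and similarity-hit descriptions; tokens are lowercased, split on
#' non-alphanumerics, and kept when at least 2 characters long.  Facet
#' dimensions: organism, type, orthology (in a group: yes/no), coexpression
#' (yes/no), annotation (GO namespaces present), expression biomaterial and
#' expression treatment.
#'
#' @param store A `chado_store`.
#' @return A `chado_search_index`; its `report` element gives documents
#'   indexed and distinct keywords extracted.
#' @export
build_index <- function(store) {
  ft <- store$tables$feature
  indexable <- c("gene", "mRNA", "polypeptide")
  type_names <- .term_name(store, ft$type_id)
  rows <- which(type_names %in% indexable)
  rows <- rows[order(ft$feature_id[rows])]

  fp <- store$tables$featureprop
  fc <- store$tables$feature_cvterm
  fl <- store$tables$featureloc
  ev <- store$tables$expression_value
  as_tab <- store$tables$assay
  desc_term <- .prop_term(store, "description")
  og_term <- .prop_term(store, "orthologous group")
  cg_term <- .prop_term(store, "coexpression group")
  match_type <- tryCatch(
    resolve_term(store, "match", vocabulary = "sequence")$cvterm_id,
    chado_error = function(e) NA_integer_
  )
  match_ids <- if (is.na(match_type)) integer() else
    ft$feature_id[ft$type_id == match_type]

  n <- length(rows)
  docs <- data.frame(
    feature_id = ft$feature_id[rows],
    uniquename = ft$uniquename[rows],
    name = ft$name[rows],
    organism = .organism_label(store, ft$organism_id[rows]),
    type = type_names[rows],
    orthology = logical(n),
    coexpression = logical(n),
    stringsAsFactors = FALSE
  )
  annotation <- vector("list", n)
  biomaterial <- vector("list", n)
  treatment <- vector("list", n)
  tokens <- vector("list", n)

  for (k in seq_len(n)) {
    fid <- docs$feature_id[k]
    p <- fp[fp$feature_id == fid, ]
    descs <- p$value[p$type_id == desc_term]
    docs$orthology[k] <- any(p$type_id == og_term)
    docs$coexpression[k] <- any(p$type_id == cg_term)
    go_ids <- fc$cvterm_id[fc$feature_id == fid]
    go_names <- .term_name(store, go_ids)
    annotation[[k]] <- sort(unique(.cv_name_of_term(store, go_ids)))
    hit_descs <- character()
    if (length(match_ids)) {
      on_me <- intersect(fl$feature_id[fl$srcfeature_id == fid], match_ids)
      if (length(on_me)) {
        hp <- fp[fp$feature_id %in% on_me & fp$type_id == desc_term, ]
        hit_descs <- hp$value
      }
    }
    aids <- ev$assay_id[ev$feature_id == fid]
    biomaterial[[k]] <- sort(unique(as_tab$biomaterial[match(aids,
                                                             as_tab$assay_id)]))
    treatment[[k]] <- sort(unique(as_tab$treatment[match(aids,
                                                         as_tab$assay_id)]))
    toks <- .tokenize(c(docs$name[k], docs$uniquename[k], descs, go_names,
                        hit_descs))
    tokens[[k]] <- if (length(toks)) table(toks) else
      table(character())
  }

  all_kw <- sort(unique(unlist(lapply(tokens, names))))
  doc_freq <- vapply(all_kw, function(kw) {
    sum(vapply(tokens, function(tb) kw %in% names(tb), logical(1)))
  }, integer(1))
  keywords <- data.frame(keyword = all_kw, doc_freq = unname(doc_freq),
                         stringsAsFactors = FALSE)

  structure(list(
    docs = docs,
    annotation = annotation,
    biomaterial = biomaterial,
    treatment = treatment,
    tokens = tokens,
    keywords = keywords,
    report = list(documents = n, keywords = nrow(keywords))
  ), class = "chado_search_index")
}

#' @export
print.chado_search_index <- function(x, ...) {
  cat(sprintf("chado_search_index: %d documents, %d keywords\n",
              x$report$documents, x$report$keywords))
  invisible(x)
}

#' Keyword autocomplete
#'
#' All and only indexed keywords having the case-folded prefix, ranked by
#' document frequency (descending) then lexicographically, truncated to
#' `limit`.
#'
#' @param index A `chado_search_index`.
#' @param prefix Prefix text, at least 1 character.
#' @param limit Maximum number of suggestions.
#' @return Character vector of keywords.
#' @export
autocomplete <- function(index, prefix, limit = 10L) {
  if (!nzchar(prefix)) stop_parameter("prefix must have at least 1 character")
  prefix <- tolower(prefix)
  kw <- index$keywords
  hit <- kw[startsWith(kw$keyword, prefix), ]
  hit <- hit[order(-hit$doc_freq, hit$keyword), ]
  utils::head(hit$keyword, limit)
}

# values of one facet dimension for doc k (character vector; multi-valued
# dimensions may contribute several values, boolean flags yield yes/no)
.doc_dim_values <- function(index, dim, k) {
  switch(dim,
    organism = index$docs$organism[k],
    type = index$docs$type[k],
    orthology = if (index$docs$orthology[k]) "yes" else "no",
    coexpression = if (index$docs$coexpression[k]) "yes" else "no",
    annotation = index$annotation[[k]],
    biomaterial = index$biomaterial[[k]],
    treatment = index$treatment[[k]]
  )
}

.filter_mask <- function(index, filters) {
  n <- nrow(index$docs)
  mask <- rep(TRUE, n)
  for (dim in names(filters)) {
    vals <- as.character(filters[[dim]])
    ok <- vapply(seq_len(n), function(k) {
      any(.doc_dim_values(index, dim, k) %in% vals)
    }, logical(1))
    mask <- mask & ok
  }
  mask
}

# query match: every token must match (exact keyword or keyword prefix);
# score = summed frequency of matching keywords.  Empty query matches all
# documents with score 0.
.query_match <- function(index, query) {
  n <- nrow(index$docs)
  toks <- strsplit(tolower(query %||% ""), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  score <- numeric(n)
  mask <- rep(TRUE, n)
  for (tok in toks) {
    tok_hit <- logical(n)
    for (k in seq_len(n)) {
      tb <- index$tokens[[k]]
      kws <- names(tb)
      m <- kws == tok | startsWith(kws, tok)
      if (any(m)) {
        tok_hit[k] <- TRUE
        score[k] <- score[k] + sum(tb[m])
      }
    }
    mask <- mask & tok_hit
  }
  list(mask = mask, score = score)
}

#' Search the index
#'
#' A document matches when every query token matches (AND semantics; a
#' token matches an indexed keyword exactly or as a prefix).  Filters
#' intersect the match set; `orthology`/`coexpression` take values
#' `"yes"`/`"no"`.  Facet counts are computed on the query match set with
#' all *other* dimensions' filters applied (standard faceted navigation).
#' Rows are ordered by match score (summed matching-token frequency,
#' descending) then uniquename; pagination is stable.  An empty query
#' matches every document, so filters can be used alone.
#'
#' @param index A `chado_search_index`.
#' @param query Query text (default `""`).
#' @param filters Named list, dimension -> character vector of accepted
#'   values.  Valid dimensions: organism, type, orthology, coexpression,
#'   annotation, biomaterial, treatment.
#' @param page 1-based page number.
#' @param page_size Rows per page.
#' @return A `chado_search_page`: total, page, page_size, rows (data
#'   frame with uniquename, organism, type, name, score) and facets (data
#'   frame with dimension, value, count).
#' @export
search_features <- function(index, query = "", filters = list(),
                            page = 1L, page_size = 25L) {
  bad <- setdiff(names(filters), .facet_dimensions)
  if (length(bad)) {
    stop_parameter(sprintf(
      "unknown facet dimension '%s' (valid: %s)", bad[1],
      paste(.facet_dimensions, collapse = ", ")
    ))
  }
  qm <- .query_match(index, query)
  full_mask <- qm$mask & .filter_mask(index, filters)
  hits <- which(full_mask)
  ord <- hits[order(-qm$score[hits], index$docs$uniquename[hits])]

  facets <- do.call(rbind, lapply(.facet_dimensions, function(dim) {
    other <- filters[setdiff(names(filters), dim)]
    dim_mask <- qm$mask & .filter_mask(index, other)
    ks <- which(dim_mask)
    vals <- unlist(lapply(ks, function(k) .doc_dim_values(index, dim, k)))
    if (length(vals) == 0) return(NULL)
    tb <- table(vals)
    data.frame(dimension = dim, value = names(tb),
               count = as.integer(tb), stringsAsFactors = FALSE)
  }))
  if (is.null(facets)) {
    facets <- data.frame(dimension = character(), value = character(),
                         count = integer(), stringsAsFactors = FALSE)
  }

  from <- (page - 1L) * page_size + 1L
  to <- min(length(ord), page * page_size)
  page_idx <- if (from > length(ord)) integer() else ord[from:to]
  rows <- data.frame(
    feature_id = index$docs$feature_id[page_idx],
    uniquename = index$docs$uniquename[page_idx],
    organism = index$docs$organism[page_idx],
    type = index$docs$type[page_idx],
    name = index$docs$name[page_idx],
    score = qm$score[page_idx],
    stringsAsFactors = FALSE
  )
  structure(list(
    total = length(ord), page = as.integer(page),
    page_size = as.integer(page_size), rows = rows, facets = facets
  ), class = "chado_search_page")
}

#' @export
print.chado_search_page <- function(x, ...) {
  cat(sprintf("search page %d (%d rows of %d hits)\n",
              x$page, nrow(x$rows), x$total))
  if (nrow(x$rows)) {
    print(x$rows[, c("uniquename", "organism", "type", "score")],
          row.names = FALSE)
  }
  invisible(x)
}

# Persist/reload an index beside its store (rebuild is always authoritative)
save_index <- function(index, path) {
  saveRDS(index, path)
  invisible(path)
}

load_index <- function(path) {
  if (!file.exists(path)) {
    stop_load_order("no search index found", "build-index")
  }
  readRDS(path)
}
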