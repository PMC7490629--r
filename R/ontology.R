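# OBO flat-file loading and transitive-closure queries over the vocabulary
# graph.  The parser covers the OBO 1.2/1.4 stanza subset that ontology
# releases of the Sequence Ontology / Gene Ontology / relations ontology
# actually use for typing: [Term] and [Typedef] stanzas with id, name,
# namespace, def, is_a, relationship, alt_id, synonym, is_obsolete.

# -- parser ------------------------------------------------------------------

# Returns list(stanzas = list of list(type, line, tags = named list of
# character vectors), errors = list(line, message)).
.parse_obo <- function(lines) {
  stanzas <- list()
  errors <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) stanzas[[length(stanzas) + 1L]] <<- cur
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- sub("!.*$", "", lines[i])   # trailing comments
    ln <- trimws(ln)
    if (ln == "") next
    m <- regmatches(ln, regexec("^\\[([A-Za-z_]+)\\]$", ln))[[1]]
    if (length(m) == 2) {
      flush()
      cur <- list(type = m[2], line = i, tags = list())
      next
    }
    if (is.null(cur)) next                       # header tag-values ignored
    colon <- regexpr(":", ln, fixed = TRUE)
    if (colon < 0) {
      errors[[length(errors) + 1L]] <-
        list(line = i, message = sprintf("malformed tag line: '%s'", ln))
      next
    }
    tag <- substr(ln, 1, colon - 1)
    val <- trimws(substr(ln, colon + 1, nchar(ln)))
    cur$tags[[tag]] <- c(cur$tags[[tag]], val)
  }
  flush()
  list(stanzas = stanzas, errors = errors)
}

.obo_tag1 <- function(stanza, tag) {
  v <- stanza$tags[[tag]]
  if (is.null(v)) NA_character_ else v[1]
}

# 'def: "text" [refs]' -> text
.obo_def <- function(stanza) {
  d <- .obo_tag1(stanza, "def")
  if (is.na(d)) return(NA_character_)
  m <- regmatches(d, regexec("^\"(.*)\"", d))[[1]]
  if (length(m) == 2) m[2] else d
}

# 'synonym: "text" EXACT []' -> text
.obo_synonyms <- function(stanza) {
  syns <- stanza$tags[["synonym"]]
  if (is.null(syns)) return(character())
  out <- vapply(syns, function(s) {
    m <- regmatches(s, regexec("^\"(.*)\"", s))[[1]]
    if (length(m) == 2) m[2] else s
  }, character(1), USE.NAMES = FALSE)
  unique(out)
}

#' Load an OBO ontology file
#'
#' Creates one term per `[Term]` stanza (obsolete stanzas are stored with the
#' obsolete flag set and are excluded from [resolve_term()] by default), one
#' relationship-type term per `[Typedef]` stanza, one typed edge per `is_a:`
#' and `relationship:` line, and stores synonyms and alternate accessions
#' (`alt_id`) alongside.  The stanza `namespace` (falling back to
#' `default_vocabulary`, falling back to the header's `default-namespace`)
#' selects the vocabulary.
#'
#' Typedef stanzas whose name matches a bootstrap relationship term upsert
#' onto the seeded term (filling in accession and definition) instead of
#' creating a duplicate.
#'
#' The load is transactional: a hard failure leaves the store unchanged.
#' Malformed stanzas (e.g. missing `id:`) become error entries and are
#' skipped.
#'
#' @param store A `chado_store`.
#' @param obo Path to an OBO file, or the OBO text itself.
#' @param default_vocabulary Vocabulary name used when a stanza has no
#'   `namespace` tag.
#' @param on_duplicate `"error"` (default) or `"skip"` for stanzas whose
#'   (vocabulary, name) already exists.
#' @param quiet Suppress progress output (default `TRUE`).
#' @return A load report; `records_seen` counts stanzas.
#' @export
load_obo <- function(store, obo, default_vocabulary = NULL,
                     on_duplicate = c("error", "skip"), quiet = TRUE) {
  on_duplicate <- match.arg(on_duplicate)
  t0 <- as.numeric(Sys.time())
  lines <- .read_lines(obo)
  parsed <- .parse_obo(lines)

  # header default-namespace fallback
  header_ns <- NULL
  for (ln in lines) {
    if (grepl("^\\[", ln)) break
    if (startsWith(ln, "default-namespace:")) {
      header_ns <- trimws(sub("^default-namespace:", "", ln))
    }
  }
  fallback_cv <- default_vocabulary %||% header_ns %||% "default"

  with_transaction(store, {
    log <- .err_log()
    for (e in parsed$errors) .err_add(log, e$line, e$message)
    created <- 0L
    skipped <- 0L
    pending_rel <- list()   # edges resolved after all terms exist
    id2term <- new.env(parent = emptyenv())   # obo id -> cvterm_id

    register <- function(obo_id, cvterm_id) {
      assign(obo_id, cvterm_id, envir = id2term)
    }

    n <- length(parsed$stanzas)
    n_records <- 0L
    for (k in seq_len(n)) {
      st <- parsed$stanzas[[k]]
      if (!st$type %in% c("Term", "Typedef")) next
      n_records <- n_records + 1L
      obo_id <- .obo_tag1(st, "id")
      if (is.na(obo_id)) {
        .err_add(log, st$line, sprintf("[%s] stanza missing id:", st$type))
        next
      }
      nm <- .obo_tag1(st, "name")
      if (is.na(nm)) nm <- obo_id
      ns <- .obo_tag1(st, "namespace")
      cv_name <- if (is.na(ns)) fallback_cv else ns
      obsolete <- identical(.obo_tag1(st, "is_obsolete"), "true")
      is_rel <- st$type == "Typedef"
      accession <- if (grepl(":", obo_id, fixed = TRUE)) obo_id else NULL

      # Typedef upsert onto bootstrap relationship terms
      if (is_rel) {
        ct <- store$tables$cvterm
        hit <- which(ct$name == nm & ct$is_relationshiptype == 1L)
        if (length(hit)) {
          if (!is.null(accession) && is.na(ct$dbxref_id[hit[1]])) {
            store$tables$cvterm$dbxref_id[hit[1]] <-
              .ensure_dbxref(store, accession)
          }
          if (is.na(ct$definition[hit[1]])) {
            store$tables$cvterm$definition[hit[1]] <- .obo_def(st)
          }
          register(obo_id, ct$cvterm_id[hit[1]])
          created <- created + 1L
          next
        }
      }

      cv_id <- .ensure_cv(store, cv_name)
      ct <- store$tables$cvterm
      dup <- which(ct$cv_id == cv_id & ct$name == nm)
      if (length(dup)) {
        if (on_duplicate == "error") {
          stop_duplicate("term", sprintf("%s in vocabulary '%s'", nm, cv_name))
        }
        register(obo_id, ct$cvterm_id[dup[1]])
        skipped <- skipped + 1L
        next
      }

      term_id <- .new_term(
        store, cv_id, nm, accession = accession, definition = .obo_def(st),
        is_obsolete = obsolete, is_relationshiptype = is_rel
      )
      register(obo_id, term_id)
      created <- created + 1L

      for (alt in st$tags[["alt_id"]] %||% character()) {
        .append(store, "cvterm_dbxref", data.frame(
          cvterm_dbxref_id = .next_id(store, "cvterm_dbxref"),
          cvterm_id = term_id, dbxref_id = .ensure_dbxref(store, alt),
          stringsAsFactors = FALSE
        ))
      }
      for (syn in .obo_synonyms(st)) {
        .append(store, "cvtermsynonym", data.frame(
          cvtermsynonym_id = .next_id(store, "cvtermsynonym"),
          cvterm_id = term_id, synonym = syn, stringsAsFactors = FALSE
        ))
      }
      for (tgt in st$tags[["is_a"]] %||% character()) {
        tgt_id <- trimws(sub("!.*$", "", tgt))
        pending_rel[[length(pending_rel) + 1L]] <-
          list(line = st$line, subject = obo_id, predicate = "is_a",
               object = tgt_id)
      }
      for (rel in st$tags[["relationship"]] %||% character()) {
        parts <- strsplit(trimws(rel), "[[:space:]]+")[[1]]
        if (length(parts) < 2) {
          .err_add(log, st$line, sprintf("malformed relationship: '%s'", rel))
          next
        }
        pending_rel[[length(pending_rel) + 1L]] <-
          list(line = st$line, subject = obo_id, predicate = parts[1],
               object = parts[2])
      }
      .progress_tick(k, n, t0, "load_obo", quiet)
    }

    for (pr in pending_rel) {
      subj <- mget(pr$subject, envir = id2term, ifnotfound = NA)[[1]]
      obj <- mget(pr$object, envir = id2term, ifnotfound = NA)[[1]]
      if (is.na(obj)) {
        # target may predate this file (already loaded ontology)
        obj <- tryCatch(
          resolve_term(store, pr$object)$cvterm_id,
          chado_error = function(e) NA_integer_
        )
      }
      if (is.na(subj) || is.na(obj)) {
        .err_add(log, pr$line,
                 sprintf("relationship target '%s' not found", pr$object))
        next
      }
      pred_id <- .relationship_type_id(store, pr$predicate, id2term)
      if (is.na(pred_id)) {
        .err_add(log, pr$line,
                 sprintf("unknown relationship type '%s'", pr$predicate))
        next
      }
      if (pr$predicate == "is_a" && subj == obj) {
        .err_add(log, pr$line, "is_a self-loop rejected")
        next
      }
      cr <- store$tables$cvterm_relationship
      dup <- any(cr$type_id == pred_id & cr$subject_id == subj &
                   cr$object_id == obj)
      if (dup) next
      .append(store, "cvterm_relationship", data.frame(
        cvterm_relationship_id = .next_id(store, "cvterm_relationship"),
        type_id = pred_id, subject_id = subj, object_id = obj,
        stringsAsFactors = FALSE
      ))
    }

    .progress_done(quiet)
    new_load_report(
      records_seen = n_records,
      created = created, skipped = skipped, errors = .err_df(log),
      elapsed = as.numeric(Sys.time()) - t0
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# predicate name (or obo id) -> cvterm_id of a relationship-type term
.relationship_type_id <- function(store, name, id2term = NULL) {
  if (!is.null(id2term)) {
    hit <- mget(name, envir = id2term, ifnotfound = NA)[[1]]
    if (!is.na(hit)) return(hit)
  }
  ct <- store$tables$cvterm
  hit <- which(ct$name == name & ct$is_relationshiptype == 1L)
  if (length(hit)) return(ct$cvterm_id[hit[1]])
  NA_integer_
}

# -- lookup ------------------------------------------------------------------

#' Resolve a term by accession or name
#'
#' Accession lookup (`PREFIX:ID`, including `alt_id` accessions which resolve
#' to their primary term) is exact and vocabulary-independent; name lookup is
#' exact within the given vocabulary (or across all vocabularies when
#' unambiguous).  Obsolete terms are excluded unless requested.
#'
#' @param store A `chado_store`.
#' @param key Accession (`"SO:0000704"`) or name (`"gene"`).
#' @param vocabulary Optional vocabulary name restricting name lookup.
#' @param include_obsolete Also match obsolete terms (default `FALSE`).
#' @return One-row data frame of the cvterm row plus `accession` and
#'   `vocabulary` columns.
#' @export
resolve_term <- function(store, key, vocabulary = NULL,
                         include_obsolete = FALSE) {
  ct <- store$tables$cvterm
  rows <- integer()
  if (grepl("^[A-Za-z_][A-Za-z0-9_-]*:\\S+$", key)) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    db <- store$tables$db
    dx <- store$tables$dbxref
    db_id <- db$db_id[match(parts[1], db$name)]
    if (!is.na(db_id)) {
      dbxref_id <- dx$dbxref_id[
        which(dx$db_id == db_id &
                dx$accession == paste(parts[-1], collapse = ":"))
      ]
      if (length(dbxref_id)) {
        rows <- which(ct$dbxref_id == dbxref_id[1])
        if (length(rows) == 0) {    # alt_id -> primary term
          cd <- store$tables$cvterm_dbxref
          alt <- cd$cvterm_id[cd$dbxref_id == dbxref_id[1]]
          rows <- which(ct$cvterm_id %in% alt)
        }
      }
    }
  }
  if (length(rows) == 0) {
    rows <- which(ct$name == key)
    if (!is.null(vocabulary)) {
      cv <- store$tables$cv
      cv_id <- cv$cv_id[match(vocabulary, cv$name)]
      rows <- rows[ct$cv_id[rows] %in% cv_id]
    }
  }
  if (!include_obsolete) rows <- rows[ct$is_obsolete[rows] == 0L]
  if (length(rows) == 0) stop_missing_term(key, vocabulary)
  if (length(rows) > 1) {
    stop_chado(
      sprintf("term '%s' is ambiguous across vocabularies %s; pass vocabulary=",
              key,
              paste(unique(.cv_name_of_term(store, ct$cvterm_id[rows])),
                    collapse = ", ")),
      "chado_ambiguity_error"
    )
  }
  out <- ct[rows, , drop = FALSE]
  out$accession <- .curie_of(store, out$dbxref_id)
  out$vocabulary <- .cv_name_of_term(store, out$cvterm_id)
  rownames(out) <- NULL
  out
}

#' Transitive ancestors of a term
#'
#' Breadth-first transitive closure over the chosen relationship predicates;
#' the start term itself is excluded.  A cycle through the start term aborts
#' with an error naming it.
#'
#' @param store A `chado_store`.
#' @param term Accession, name, or a row returned by [resolve_term()].
#' @param predicates Character vector of relationship-type names
#'   (default `"is_a"`).
#' @return Data frame of ancestor cvterm rows (one per distinct ancestor),
#'   ordered by cvterm id.
#' @export
term_ancestors <- function(store, term, predicates = "is_a") {
  if (is.data.frame(term)) {
    start <- term$cvterm_id[1]
  } else {
    start <- resolve_term(store, term)$cvterm_id
  }
  pred_ids <- vapply(predicates, function(p) {
    id <- .relationship_type_id(store, p)
    if (is.na(id)) stop_not_found("relationship type", p)
    id
  }, integer(1))
  cr <- store$tables$cvterm_relationship
  edges <- cr[cr$type_id %in% pred_ids, c("subject_id", "object_id")]
  visited <- integer()
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(edges$object_id[edges$subject_id %in% frontier])
    if (start %in% nxt) stop_cycle(.term_name(store, start))
    nxt <- setdiff(nxt, visited)
    visited <- c(visited, nxt)
    frontier <- nxt
  }
  ct <- store$tables$cvterm
  out <- ct[ct$cvterm_id %in% visited, , drop = FALSE]
  out <- out[order(out$cvterm_id), , drop = FALSE]
  out$accession <- vapply(out$dbxref_id, function(d) .curie_of(store, d),
                          character(1))
  rownames(out) <- NULL
  out
}
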