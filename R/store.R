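# Embedded relational store.  Tables and columns follow the subset of the
# GMOD Chado 1.31 schema used by the loaders (cv/cvterm/cvterm_relationship,
# organism, feature/featureloc/feature_relationship/featureprop,
# feature_cvterm, analysis/analysisfeature, pub/feature_pub, dbxref) plus a
# deliberately collapsed expression pair (assay, expression_value).
# Semantics are append-only: there is no delete/update path, so referential
# integrity cannot be broken after insertion.

.empty <- function(...) {
  cols <- list(...)
  as.data.frame(cols, stringsAsFactors = FALSE)[0, , drop = FALSE]
}

.chado_schema <- function() {
  int <- integer()
  chr <- character()
  num <- numeric()
  list(
    cv = .empty(cv_id = int, name = chr, definition = chr),
    db = .empty(db_id = int, name = chr),
    dbxref = .empty(dbxref_id = int, db_id = int, accession = chr),
    cvterm = .empty(
      cvterm_id = int, cv_id = int, name = chr, definition = chr,
      dbxref_id = int, is_obsolete = int, is_relationshiptype = int
    ),
    cvterm_dbxref = .empty(
      cvterm_dbxref_id = int, cvterm_id = int, dbxref_id = int
    ),
    cvtermsynonym = .empty(
      cvtermsynonym_id = int, cvterm_id = int, synonym = chr
    ),
    cvterm_relationship = .empty(
      cvterm_relationship_id = int, type_id = int,
      subject_id = int, object_id = int
    ),
    organism = .empty(
      organism_id = int, genus = chr, species = chr,
      infraspecific_name = chr, abbreviation = chr, common_name = chr
    ),
    feature = .empty(
      feature_id = int, organism_id = int, name = chr, uniquename = chr,
      residues = chr, seqlen = int, md5checksum = chr, type_id = int,
      is_obsolete = int
    ),
    featureloc = .empty(
      featureloc_id = int, feature_id = int, srcfeature_id = int,
      fmin = int, fmax = int, strand = int, phase = int, rank = int
    ),
    feature_relationship = .empty(
      feature_relationship_id = int, subject_id = int, object_id = int,
      type_id = int
    ),
    featureprop = .empty(
      featureprop_id = int, feature_id = int, type_id = int,
      value = chr, rank = int
    ),
    feature_cvterm = .empty(
      feature_cvterm_id = int, feature_id = int, cvterm_id = int,
      pub_id = int, evidence = chr
    ),
    feature_dbxref = .empty(
      feature_dbxref_id = int, feature_id = int, dbxref_id = int
    ),
    analysis = .empty(
      analysis_id = int, program = chr, programversion = chr,
      sourcename = chr, algorithm = chr, timeexecuted = chr
    ),
    analysisfeature = .empty(
      analysisfeature_id = int, analysis_id = int, feature_id = int,
      rawscore = num, normscore = num, significance = num, identity = num
    ),
    pub = .empty(
      pub_id = int, uniquename = chr, title = chr, authors = chr,
      pyear = int, doi = chr
    ),
    feature_pub = .empty(
      feature_pub_id = int, feature_id = int, pub_id = int
    ),
    assay = .empty(
      assay_id = int, name = chr, biomaterial = chr, treatment = chr
    ),
    expression_value = .empty(
      expression_value_id = int, feature_id = int, assay_id = int,
      value = num
    )
  )
}

# Relationship and feature-property terms every loader needs before the real
# ontologies arrive; load_obo() upserts onto these rather than duplicating.
.bootstrap_terms <- function(store) {
  rel_cv <- .ensure_cv(store, "relationship")
  for (nm in c("is_a", "part_of", "derives_from", "translation_of")) {
    .new_term(store, rel_cv, nm, is_relationshiptype = 1L)
  }
  prop_cv <- .ensure_cv(store, "feature_property")
  for (nm in c("description", "orthologous group", "coexpression group")) {
    .new_term(store, prop_cv, nm)
  }
  .ensure_cv(store, "sequence")
  invisible(store)
}

#' Open or create an embedded Chado-compatible store
#'
#' Creates a fresh store at `location` (a single file), re-opens an existing
#' compatible one without modifying it, or — with `location = NULL` or
#' `":memory:"` — keeps the store purely in memory.  Opening validates that
#' every table of the schema subset is present; the first missing table is
#' named in a schema-mismatch error.
#'
#' A fresh store is seeded with a minimal internal vocabulary (the
#' relationship types `is_a`, `part_of`, `derives_from`, `translation_of` and
#' the feature-property types `description`, `orthologous group`,
#' `coexpression group`) so that loaders can run before the full relations
#' ontology has been loaded; [load_obo()] upserts onto these seeds.
#'
#' @param location Path of the store file, or `NULL`/`":memory:"` for an
#'   in-memory store.
#' @return A `chado_store` handle.
#' @examples
#' st <- initialize_store()
#' store_stats(st)[["feature"]]
#' @export
initialize_store <- function(location = NULL) {
  in_memory <- is.null(location) || identical(location, ":memory:")
  store <- new.env(parent = emptyenv())
  class(store) <- "chado_store"
  store$location <- if (in_memory) NA_character_ else location
  schema <- .chado_schema()
  if (!in_memory && file.exists(location)) {
    obj <- tryCatch(readRDS(location), error = function(e) NULL)
    if (!is.list(obj) || is.null(obj$tables)) {
      stop_schema_mismatch(names(schema)[1], location)
    }
    for (tab in names(schema)) {
      if (is.null(obj$tables[[tab]])) stop_schema_mismatch(tab, location)
    }
    store$tables <- obj$tables
    store$seq <- obj$seq
    return(store)
  }
  store$tables <- schema
  store$seq <- stats::setNames(integer(length(schema)), names(schema))
  .bootstrap_terms(store)
  if (!in_memory) store_save(store)
  store
}

#' @export
print.chado_store <- function(x, ...) {
  loc <- if (is.na(x$location)) "<in memory>" else x$location
  cat("chado_store:", loc, "\n")
  s <- store_stats(x)
  s <- s[s > 0]
  if (length(s) == 0) {
    cat("  (empty)\n")
  } else {
    for (nm in names(s)) cat(sprintf("  %-22s %d\n", nm, s[[nm]]))
  }
  invisible(x)
}

# Atomic single-file persistence (write to sibling temp file, then rename).
store_save <- function(store) {
  if (is.na(store$location)) return(invisible(store))
  tmp <- paste0(store$location, ".tmp")
  saveRDS(list(tables = store$tables, seq = store$seq), tmp)
  file.rename(tmp, store$location)
  invisible(store)
}

#' Entity counts per table
#'
#' @param store A `chado_store`.
#' @return Named integer vector: exact row count of every table at call time.
#' @export
store_stats <- function(store) {
  vapply(store$tables, nrow, integer(1))
}

# All writes of one loader happen inside one transaction: on any error the
# in-memory tables are restored and nothing is persisted.
with_transaction <- function(store, expr) {
  snap_tables <- store$tables
  snap_seq <- store$seq
  res <- tryCatch(expr, error = function(e) {
    store$tables <- snap_tables
    store$seq <- snap_seq
    stop(e)
  })
  store_save(store)
  res
}

.next_id <- function(store, table, n = 1L) {
  ids <- store$seq[[table]] + seq_len(n)
  store$seq[[table]] <- store$seq[[table]] + n
  ids
}

.append <- function(store, table, rows) {
  tab <- store$tables[[table]]
  rows <- rows[, names(tab), drop = FALSE]
  store$tables[[table]] <- rbind(tab, rows)
  invisible(store)
}

## -- vocabulary / term primitives ------------------------------------------

.ensure_cv <- function(store, name) {
  cv <- store$tables$cv
  hit <- which(cv$name == name)
  if (length(hit)) return(cv$cv_id[hit[1]])
  id <- .next_id(store, "cv")
  .append(store, "cv", data.frame(
    cv_id = id, name = name, definition = NA_character_,
    stringsAsFactors = FALSE
  ))
  id
}

.ensure_dbxref <- function(store, curie) {
  parts <- strsplit(curie, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2) {
    stop_format(sprintf("accession '%s' is not in PREFIX:ID form", curie))
  }
  prefix <- parts[1]
  local <- paste(parts[-1], collapse = ":")
  db <- store$tables$db
  hit <- which(db$name == prefix)
  if (length(hit)) {
    db_id <- db$db_id[hit[1]]
  } else {
    db_id <- .next_id(store, "db")
    .append(store, "db", data.frame(
      db_id = db_id, name = prefix, stringsAsFactors = FALSE
    ))
  }
  dx <- store$tables$dbxref
  hit <- which(dx$db_id == db_id & dx$accession == local)
  if (length(hit)) return(dx$dbxref_id[hit[1]])
  id <- .next_id(store, "dbxref")
  .append(store, "dbxref", data.frame(
    dbxref_id = id, db_id = db_id, accession = local,
    stringsAsFactors = FALSE
  ))
  id
}

.curie_of <- function(store, dbxref_id) {
  if (is.na(dbxref_id)) return(NA_character_)
  dx <- store$tables$dbxref
  row <- dx[dx$dbxref_id == dbxref_id, ]
  if (nrow(row) == 0) return(NA_character_)
  db <- store$tables$db
  paste0(db$name[match(row$db_id[1], db$db_id)], ":", row$accession[1])
}

.new_term <- function(store, cv_id, name, accession = NULL,
                      definition = NA_character_, is_obsolete = 0L,
                      is_relationshiptype = 0L) {
  ct <- store$tables$cvterm
  hit <- which(ct$cv_id == cv_id & ct$name == name)
  if (length(hit)) stop_duplicate("term", name)
  dbxref_id <- if (is.null(accession)) NA_integer_ else .ensure_dbxref(store, accession)
  id <- .next_id(store, "cvterm")
  .append(store, "cvterm", data.frame(
    cvterm_id = id, cv_id = cv_id, name = name, definition = definition,
    dbxref_id = dbxref_id, is_obsolete = as.integer(is_obsolete),
    is_relationshiptype = as.integer(is_relationshiptype),
    stringsAsFactors = FALSE
  ))
  id
}

# find-or-create a feature-property type term (auto-created for arbitrary
# GFF3 attribute names)
.prop_term <- function(store, name) {
  cv_id <- .ensure_cv(store, "feature_property")
  ct <- store$tables$cvterm
  hit <- which(ct$cv_id == cv_id & ct$name == name)
  if (length(hit)) return(ct$cvterm_id[hit[1]])
  .new_term(store, cv_id, name)
}

.term_name <- function(store, cvterm_id) {
  ct <- store$tables$cvterm
  ct$name[match(cvterm_id, ct$cvterm_id)]
}

.cv_name_of_term <- function(store, cvterm_id) {
  ct <- store$tables$cvterm
  cv <- store$tables$cv
  cv$name[match(ct$cv_id[match(cvterm_id, ct$cvterm_id)], cv$cv_id)]
}

## -- organisms --------------------------------------------------------------

#' Register an organism
#'
#' @param store A `chado_store`.
#' @param genus,species Binomial parts.
#' @param infraspecific_name,abbreviation,common_name Optional extras.
#' @param on_duplicate `"error"` (default) or `"skip"`.
#' @return The organism id, invisibly.
#' @export
add_organism <- function(store, genus, species,
                         infraspecific_name = NA_character_,
                         abbreviation = NA_character_,
                         common_name = NA_character_,
                         on_duplicate = c("error", "skip")) {
  on_duplicate <- match.arg(on_duplicate)
  org <- store$tables$organism
  same <- org$genus == genus & org$species == species &
    (is.na(org$infraspecific_name) & is.na(infraspecific_name) |
       !is.na(org$infraspecific_name) & !is.na(infraspecific_name) &
       org$infraspecific_name == infraspecific_name)
  if (any(same, na.rm = TRUE)) {
    if (on_duplicate == "error") {
      stop_duplicate("organism", paste(genus, species))
    }
    return(invisible(org$organism_id[which(same)[1]]))
  }
  id <- .next_id(store, "organism")
  .append(store, "organism", data.frame(
    organism_id = id, genus = genus, species = species,
    infraspecific_name = infraspecific_name, abbreviation = abbreviation,
    common_name = common_name, stringsAsFactors = FALSE
  ))
  store_save(store)
  invisible(id)
}

# organism may be an id, "Genus species" text, or c(genus, species)
.organism_id <- function(store, organism) {
  org <- store$tables$organism
  if (is.numeric(organism)) {
    if (!organism %in% org$organism_id) {
      stop_not_found("organism", as.character(organism))
    }
    return(as.integer(organism))
  }
  if (length(organism) == 1) organism <- strsplit(organism, "[ _]+")[[1]]
  if (length(organism) < 2) stop_parameter("organism needs genus and species")
  hit <- which(org$genus == organism[1] & org$species == organism[2])
  if (length(hit) == 0) {
    stop_load_order(
      sprintf("organism '%s %s' is not registered", organism[1], organism[2]),
      "load-organism"
    )
  }
  org$organism_id[hit[1]]
}

.organism_label <- function(store, organism_id) {
  org <- store$tables$organism
  i <- match(organism_id, org$organism_id)
  paste(org$genus[i], org$species[i])
}

## -- features ---------------------------------------------------------------

.md5_hex <- function(text) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeChar(text, tf, eos = NULL)
  unname(tools::md5sum(tf))
}

# Insert one feature enforcing the (organism, uniquename, type) key.
# Returns list(feature_id=, created=logical).
.add_feature <- function(store, organism_id, uniquename, type_id,
                         name = NA_character_, residues = NA_character_,
                         on_duplicate = "error", checksum = TRUE) {
  ft <- store$tables$feature
  hit <- which(ft$organism_id == organism_id &
                 ft$uniquename == uniquename & ft$type_id == type_id)
  if (length(hit)) {
    if (on_duplicate == "skip") {
      return(list(feature_id = ft$feature_id[hit[1]], created = FALSE))
    }
    stop_duplicate(
      "feature",
      sprintf("%s [%s]", uniquename, .term_name(store, type_id))
    )
  }
  seqlen <- if (is.na(residues)) 0L else nchar(residues)
  md5 <- if (checksum && !is.na(residues)) .md5_hex(residues) else NA_character_
  id <- .next_id(store, "feature")
  .append(store, "feature", data.frame(
    feature_id = id, organism_id = organism_id, name = name,
    uniquename = uniquename, residues = residues, seqlen = seqlen,
    md5checksum = md5, type_id = type_id, is_obsolete = 0L,
    stringsAsFactors = FALSE
  ))
  list(feature_id = id, created = TRUE)
}

#' Fetch a feature by its Chado uniqueness key
#'
#' Looks up `(organism, uniquename, type)`.  When `type_name` is omitted and
#' several features of different types share the uniquename (a common Chado
#' situation for mRNA/polypeptide pairs), an ambiguity error lists the
#' candidate types.
#'
#' @param store A `chado_store`.
#' @param organism Organism id or `"Genus species"` text.
#' @param uniquename Feature uniquename.
#' @param type_name Optional Sequence Ontology type name.
#' @return One-row data frame (feature columns plus `type` and `organism`
#'   labels), or `NULL` when absent.
#' @export
get_feature <- function(store, organism, uniquename, type_name = NULL) {
  org_id <- .organism_id(store, organism)
  ft <- store$tables$feature
  rows <- ft[ft$organism_id == org_id & ft$uniquename == uniquename, ,
             drop = FALSE]
  if (!is.null(type_name)) {
    rows <- rows[.term_name(store, rows$type_id) == type_name, , drop = FALSE]
  }
  if (nrow(rows) == 0) return(NULL)
  if (nrow(rows) > 1) {
    stop_ambiguous(uniquename, sort(.term_name(store, rows$type_id)))
  }
  rows$type <- .term_name(store, rows$type_id)
  rows$organism <- .organism_label(store, rows$organism_id)
  rownames(rows) <- NULL
  rows
}

# uniquename -> feature_id across types; used by evidence loaders whose
# files identify features by bare ID.  type_names restricts the candidates.
.feature_id_by_uniquename <- function(store, uniquename, type_names = NULL) {
  ft <- store$tables$feature
  rows <- which(ft$uniquename == uniquename)
  if (!is.null(type_names) && length(rows)) {
    rows <- rows[.term_name(store, ft$type_id[rows]) %in% type_names]
  }
  if (length(rows) == 0) return(NA_integer_)
  ft$feature_id[rows[1]]
}

.next_prop_rank <- function(store, feature_id, type_id) {
  fp <- store$tables$featureprop
  r <- fp$rank[fp$feature_id == feature_id & fp$type_id == type_id]
  if (length(r) == 0) 0L else max(r) + 1L
}

.add_featureprop <- function(store, feature_id, type_id, value) {
  id <- .next_id(store, "featureprop")
  .append(store, "featureprop", data.frame(
    featureprop_id = id, feature_id = feature_id, type_id = type_id,
    value = value, rank = .next_prop_rank(store, feature_id, type_id),
    stringsAsFactors = FALSE
  ))
  id
}

.add_feature_relationship <- function(store, subject_id, object_id, type_id) {
  fr <- store$tables$feature_relationship
  if (subject_id == object_id) {
    stop_parameter("feature relationship subject and object must differ")
  }
  hit <- which(fr$subject_id == subject_id & fr$object_id == object_id &
                 fr$type_id == type_id)
  if (length(hit)) return(fr$feature_relationship_id[hit[1]])
  id <- .next_id(store, "feature_relationship")
  .append(store, "feature_relationship", data.frame(
    feature_relationship_id = id, subject_id = subject_id,
    object_id = object_id, type_id = type_id, stringsAsFactors = FALSE
  ))
  id
}

.add_featureloc <- function(store, feature_id, srcfeature_id, fmin, fmax,
                            strand, phase = NA_integer_, rank = 0L) {
  if (fmin > fmax) stop_parameter("featureloc fmin must be <= fmax")
  id <- .next_id(store, "featureloc")
  .append(store, "featureloc", data.frame(
    featureloc_id = id, feature_id = feature_id,
    srcfeature_id = srcfeature_id, fmin = as.integer(fmin),
    fmax = as.integer(fmax), strand = as.integer(strand),
    phase = as.integer(phase), rank = as.integer(rank),
    stringsAsFactors = FALSE
  ))
  id
}
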