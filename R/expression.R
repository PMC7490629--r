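# Expression metadata and values.  The full Chado MAGE module is
# deliberately collapsed to two tables: assay (name, biomaterial,
# treatment) and expression_value (feature, assay, value) — exactly what
# the search facets and the feature-page expression card need.

#' Load assay metadata
#'
#' TSV with header columns `assay`, `biomaterial`, `treatment` (any order;
#' a missing column is a hard format error).  One assay per row.
#'
#' @param store A `chado_store`.
#' @param tsv Path to the TSV (or its text).
#' @param on_duplicate `"error"` (default) or `"skip"` for known assay
#'   names.
#' @param quiet Suppress progress output.
#' @return A load report.
#' @export
load_assays <- function(store, tsv, on_duplicate = c("error", "skip"),
                        quiet = TRUE) {
  on_duplicate <- match.arg(on_duplicate)
  t0 <- as.numeric(Sys.time())
  lines <- .read_lines(tsv)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_format("assay TSV is empty")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("assay", "biomaterial", "treatment")
  if (!all(need %in% header)) {
    stop_format(sprintf(
      "assay TSV must have columns assay, biomaterial, treatment (missing: %s)",
      paste(setdiff(need, header), collapse = ", ")
    ))
  }
  idx <- match(need, header)
  with_transaction(store, {
    log <- .err_log()
    created <- 0L
    skipped <- 0L
    body <- lines[-1]
    for (i in seq_along(body)) {
      f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < max(idx)) {
        .err_add(log, i + 1L, "too few columns")
        next
      }
      nm <- f[idx[1]]
      if (!nzchar(nm)) {
        .err_add(log, i + 1L, "empty assay name")
        next
      }
      as_tab <- store$tables$assay
      if (nm %in% as_tab$name) {
        if (on_duplicate == "error") stop_duplicate("assay", nm)
        skipped <- skipped + 1L
        next
      }
      .append(store, "assay", data.frame(
        assay_id = .next_id(store, "assay"), name = nm,
        biomaterial = f[idx[2]], treatment = f[idx[3]],
        stringsAsFactors = FALSE
      ))
      created <- created + 1L
    }
    new_load_report(length(body), created, skipped, .err_df(log),
                    as.numeric(Sys.time()) - t0)
  })
}

#' Load a per-feature expression matrix
#'
#' TSV whose first column holds feature IDs and whose remaining header
#' columns name registered assays — an unregistered assay name aborts with
#' a load-order error pointing at [load_assays()].  One expression value per
#' (row, assay) cell; rows with unknown feature IDs and cells that do not
#' parse as non-negative numbers become error entries.  The cell accounting
#' satisfies created + cell errors == rows-with-known-feature x assay
#' columns.
#'
#' @param store A `chado_store`.
#' @param tsv Path to the matrix TSV (or its text).
#' @param quiet Suppress progress output.
#' @return A load report (`records_seen` counts cells of known-feature
#'   rows).
#' @export
load_expression_matrix <- function(store, tsv, quiet = TRUE) {
  t0 <- as.numeric(Sys.time())
  lines <- .read_lines(tsv)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_format("expression matrix is empty")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  assay_names <- header[-1]
  with_transaction(store, {
    as_tab <- store$tables$assay
    unknown <- setdiff(assay_names, as_tab$name)
    if (length(unknown)) {
      stop_load_order(
        sprintf("assay '%s' is not registered", unknown[1]),
        "load_assays"
      )
    }
    assay_ids <- as_tab$assay_id[match(assay_names, as_tab$name)]
    log <- .err_log()
    created <- 0L
    cells_seen <- 0L
    body <- lines[-1]
    n <- length(body)
    new_rows <- vector("list", n)
    for (i in seq_len(n)) {
      f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
      fid <- .feature_id_by_uniquename(store, f[1])
      if (is.na(fid)) {
        .err_add(log, i + 1L, sprintf("unknown feature ID '%s'", f[1]))
        next
      }
      vals <- suppressWarnings(as.numeric(f[-1]))
      length(vals) <- length(assay_ids)
      cells_seen <- cells_seen + length(assay_ids)
      ok <- !is.na(vals) & vals >= 0
      for (j in which(!ok)) {
        .err_add(log, i + 1L, sprintf(
          "cell for assay '%s' is not a non-negative number ('%s')",
          assay_names[j], if (j + 1 <= length(f)) f[j + 1] else ""
        ))
      }
      if (any(ok)) {
        ev <- store$tables$expression_value
        dup <- paste(fid, assay_ids[ok]) %in% paste(ev$feature_id, ev$assay_id)
        ok_idx <- which(ok)[!dup]
        if (length(ok_idx)) {
          ids <- .next_id(store, "expression_value", length(ok_idx))
          new_rows[[i]] <- data.frame(
            expression_value_id = ids, feature_id = fid,
            assay_id = assay_ids[ok_idx], value = vals[ok_idx],
            stringsAsFactors = FALSE
          )
          created <- created + length(ok_idx)
        }
      }
      .progress_tick(i, n, t0, "load_expression_matrix", quiet)
    }
    rows <- do.call(rbind, new_rows[!vapply(new_rows, is.null, logical(1))])
    if (!is.null(rows)) .append(store, "expression_value", rows)
    .progress_done(quiet)
    new_load_report(cells_seen, created, 0L, .err_df(log),
                    as.numeric(Sys.time()) - t0)
  })
}
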