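# Uniform loader result record.  For record-per-entity loaders the counts
# satisfy created + skipped + nrow(errors) == records_seen; group-shaped
# loaders (GFF3 line groups, ortholog/coexpression groups) document their
# own accounting in the loader help pages.

new_load_report <- function(records_seen, created, skipped, errors, elapsed) {
  if (is.null(errors) || length(errors) == 0) {
    errors <- data.frame(line = integer(), message = character(),
                         stringsAsFactors = FALSE)
  } else if (is.list(errors) && !is.data.frame(errors)) {
    errors <- do.call(rbind, lapply(errors, function(e) {
      data.frame(line = as.integer(e$line), message = e$message,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(
    list(
      records_seen = as.integer(records_seen),
      created = as.integer(created),
      skipped = as.integer(skipped),
      errors = errors,
      elapsed = as.numeric(elapsed)
    ),
    class = "chado_load_report"
  )
}

#' @export
print.chado_load_report <- function(x, ...) {
  cat(sprintf(
    "load report: %d records, %d created, %d skipped, %d errors (%.2fs)\n",
    x$records_seen, x$created, x$skipped, nrow(x$errors), x$elapsed
  ))
  if (nrow(x$errors) > 0) {
    n <- min(nrow(x$errors), 10L)
    for (i in seq_len(n)) {
      cat(sprintf("  line %s: %s\n", x$errors$line[i], x$errors$message[i]))
    }
    if (nrow(x$errors) > n) cat(sprintf("  ... and %d more\n", nrow(x$errors) - n))
  }
  invisible(x)
}

# error-entry accumulator used inside loaders
.err_log <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env
}

.err_add <- function(log, line, message) {
  log$rows[[length(log$rows) + 1L]] <- list(line = line, message = message)
  invisible(log)
}

.err_df <- function(log) {
  if (length(log$rows) == 0) {
    return(data.frame(line = integer(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(log$rows, function(e) {
    data.frame(line = as.integer(e$line), message = e$message,
               stringsAsFactors = FALSE)
  }))
}

# Streaming progress to stderr: records/sec, and percent when the total is
# known.  Loaders call it once per chunk; silent when quiet.
.progress_tick <- function(done, total, t0, label, quiet) {
  if (quiet) return(invisible(NULL))
  dt <- as.numeric(Sys.time()) - t0
  rate <- if (dt > 0) done / dt else done
  if (!is.na(total) && total > 0) {
    message(sprintf("\r%s: %d/%d (%.0f%%) %.0f rec/s",
                    label, done, total, 100 * done / total, rate),
            appendLF = FALSE)
  } else {
    message(sprintf("\r%s: %d records, %.0f rec/s", label, done, rate),
            appendLF = FALSE)
  }
  invisible(NULL)
}

.progress_done <- function(quiet) {
  if (!quiet) message("")
  invisible(NULL)
}

# Parse/stage records in order-preserving chunks, optionally on several
# workers.  Commits are always applied serially by the caller, so the final
# store state is identical for any worker count.
.stage_chunks <- function(items, fn, threads = 1L, chunk_size = 500L) {
  n <- length(items)
  if (n == 0) return(list())
  starts <- seq(1L, n, by = chunk_size)
  chunks <- lapply(starts, function(s) items[s:min(s + chunk_size - 1L, n)])
  workers <- max(1L, as.integer(threads))
  if (workers > 1L && .Platform$OS.type == "unix") {
    out <- parallel::mclapply(chunks, fn, mc.cores = workers)
  } else {
    out <- lapply(chunks, fn)
  }
  unlist(out, recursive = FALSE)
}

# Accept either a file path or a character vector of lines.
.read_lines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1 && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }
}
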