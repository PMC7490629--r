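# Typed conditions used across the package.  Every recoverable failure is a
# classed condition so callers (and the CLI) can react to the category, not
# the message text.

chado_error <- function(message, class, ...) {
  structure(
    class = c(class, "chado_error", "error", "condition"),
    list(message = message, ...)
  )
}

stop_chado <- function(message, class, ...) {
  stop(chado_error(message, class, ...))
}

#' @noRd
stop_schema_mismatch <- function(missing_table, location) {
  stop_chado(
    sprintf(
      "store at '%s' is not schema-compatible: missing table '%s'",
      location, missing_table
    ),
    "chado_schema_error",
    missing_table = missing_table
  )
}

stop_missing_term <- function(key, vocabulary = NULL, hint = NULL) {
  if (is.null(hint)) {
    hint <- "load the required ontology first (load_obo / load-ontology)"
  }
  voc <- if (is.null(vocabulary)) "" else sprintf(" in vocabulary '%s'", vocabulary)
  stop_chado(
    sprintf("term '%s' not found%s; %s", key, voc, hint),
    "chado_missing_term_error",
    key = key, vocabulary = vocabulary
  )
}

stop_load_order <- function(message, prerequisite) {
  stop_chado(
    sprintf("%s (run %s first)", message, prerequisite),
    "chado_load_order_error",
    prerequisite = prerequisite
  )
}

stop_duplicate <- function(what, key) {
  stop_chado(
    sprintf("duplicate %s: %s", what, key),
    "chado_unique_error",
    what = what, key = key
  )
}

stop_not_found <- function(what, key) {
  stop_chado(
    sprintf("%s '%s' not found", what, key),
    "chado_not_found_error",
    what = what, key = key
  )
}

stop_ambiguous <- function(uniquename, types) {
  stop_chado(
    sprintf(
      "feature '%s' is ambiguous without a type: candidate types are %s",
      uniquename, paste(types, collapse = ", ")
    ),
    "chado_ambiguity_error",
    uniquename = uniquename, candidate_types = types
  )
}

stop_format <- function(message) {
  stop_chado(message, "chado_format_error")
}

stop_parameter <- function(message) {
  stop_chado(message, "chado_parameter_error")
}

stop_cycle <- function(member) {
  stop_chado(
    sprintf("relationship cycle detected involving term '%s'", member),
    "chado_cycle_error",
    member = member
  )
}
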