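# brute-force search oracles working on the public index fields

doc_values <- function(idx, dim, k) {
  switch(dim,
    organism = idx$docs$organism[k],
    type = idx$docs$type[k],
    orthology = if (idx$docs$orthology[k]) "yes" else "no",
    coexpression = if (idx$docs$coexpression[k]) "yes" else "no",
    annotation = idx$annotation[[k]],
    biomaterial = idx$biomaterial[[k]],
    treatment = idx$treatment[[k]]
  )
}

match_docs <- function(idx, query) {
  toks <- strsplit(tolower(query), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  which(vapply(seq_len(nrow(idx$docs)), function(k) {
    kws <- names(idx$tokens[[k]])
    all(vapply(toks, function(t) any(kws == t | startsWith(kws, t)),
               logical(1)))
  }, logical(1)))
}

all_rows <- function(idx, query, filters, page_size = 7L) {
  out <- NULL
  p <- 1L
  repeat {
    pg <- search_features(idx, query, filters, page = p,
                          page_size = page_size)
    out <- rbind(out, pg$rows)
    if (nrow(pg$rows) < page_size) return(list(rows = out, total = pg$total))
    p <- p + 1L
  }
}
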