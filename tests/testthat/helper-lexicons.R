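# In-code fixture builders shared across the suite.

# concepts from a named list of character vectors: first string = label,
# rest = synonyms
mk_concepts <- function(reps) {
  lapply(names(reps), function(id) {
    v <- reps[[id]]
    raw_concept(id, labels = v[1L], synonyms = if (length(v) > 1L) v[-1L] else character())
  })
}

mk_profiles <- function(reps, case_sensitive = FALSE) {
  build_profiles(mk_concepts(reps), case_sensitive = case_sensitive)
}

# a small OBO file on disk, returned as a path
write_tmp_obo <- function(lines) {
  path <- tempfile(fileext = ".obo")
  writeLines(lines, path)
  path
}

# brute-force PMI oracle from first principles (independent of mi_stats
# internals): counts recomputed by direct enumeration over representations
oracle_pmi <- function(rep_tokens, x, y) {
  uni <- table(unlist(rep_tokens))
  total_tokens <- sum(uni)
  bigrams <- do.call(rbind, lapply(rep_tokens, function(t) {
    if (length(t) < 2L) return(NULL)
    cbind(t[-length(t)], t[-1L])
  }))
  total_bigrams <- nrow(bigrams)
  c_xy <- sum(bigrams[, 1L] == x & bigrams[, 2L] == y)
  log((c_xy / total_bigrams) / ((uni[[x]] / total_tokens) * (uni[[y]] / total_tokens)))
}

# brute-force binomial weight oracle for integer tfn via dbinom
oracle_weight <- function(TF, tf, N) -log2(dbinom(tf, size = TF, prob = 1 / N))
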