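#' Build entity profiles and corpus statistics
#'
#' An entity profile aggregates all lexical representations (labels and
#' synonyms) of one concept, normalized into token sequences. Corpus-level
#' statistics treat each profile as a "document" of the collection: `TF(t)` is
#' the total occurrence count of token `t` across all profiles, `df(t)` the
#' number of profiles containing it, `sl` the mean token count over all
#' representations in the lexicon, and `p = 1/N`, `q = 1 - p` with `N` the
#' number of profiles.
#'
#' Concepts whose every representation normalizes to zero tokens are excluded
#' with a warning.
#'
#' @param concepts list of [raw_concept()] objects.
#' @param case_sensitive logical; normalization mode (see [normalize_text()]).
#' @param lemmatizer,stoplist passed to [normalize_text()].
#' @return a list with elements `profiles` (list of `entity_profile`) and
#'   `stats` (a `corpus_stats` object with fields `N`, `TF`, `df`, `sl`, `p`,
#'   `q`, `case_sensitive`).
#' @export
build_profiles <- function(concepts, case_sensitive = FALSE,
                           lemmatizer = default_lemmatizer,
                           stoplist = default_stoplist()) {
  stopifnot(length(concepts) > 0L)
  profiles <- list()
  dropped <- character()
  for (rc in concepts) {
    texts <- c(rc$labels, rc$synonyms)
    reps <- list()
    for (tx in texts) {
      if (!nzchar(tx)) next
      ts <- normalize_text(tx, case_sensitive = case_sensitive,
                           lemmatizer = lemmatizer, stoplist = stoplist)
      if (length(ts) > 0L) reps[[length(reps) + 1L]] <- ts
    }
    if (length(reps) == 0L) {
      dropped <- c(dropped, rc$concept_id)
      next
    }
    lens <- vapply(reps, length, 1L)
    profiles[[length(profiles) + 1L]] <- structure(
      list(concept_id = rc$concept_id, representations = reps,
           dl = mean(lens)),
      class = "entity_profile"
    )
  }
  if (length(dropped) > 0L) {
    warning("excluded ", length(dropped),
            " concept(s) with no non-empty representation: ",
            paste(utils::head(dropped, 5L), collapse = ", "))
  }
  if (length(profiles) == 0L) stop("no profile survived normalization")
  all_lens <- unlist(lapply(profiles, function(p)
    vapply(p$representations, length, 1L)))
  all_tokens <- unlist(lapply(profiles, function(p)
    unlist(lapply(p$representations, `[[`, "tokens"))))
  per_profile_unique <- unlist(lapply(profiles, function(p)
    unique(unlist(lapply(p$representations, `[[`, "tokens")))))
  TF <- table(all_tokens)
  df <- table(per_profile_unique)
  N <- length(profiles)
  stats <- structure(
    list(N = N,
         TF = stats::setNames(as.integer(TF), names(TF)),
         df = stats::setNames(as.integer(df), names(df)),
         sl = mean(all_lens),
         p = 1 / N, q = 1 - 1 / N,
         case_sensitive = case_sensitive),
    class = "corpus_stats"
  )
  list(profiles = profiles, stats = stats)
}

#' @export
print.entity_profile <- function(x, ...) {
  cat("<entity_profile> ", x$concept_id, ": ", length(x$representations),
      " representation(s), dl = ", format(x$dl), "\n", sep = "")
  invisible(x)
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat("<corpus_stats> N = ", x$N, ", vocabulary = ", length(x$TF),
      ", sl = ", format(x$sl), ", case_sensitive = ", x$case_sensitive,
      "\n", sep = "")
  invisible(x)
}

# token count of token t inside profile p (summed over representations)
profile_tf <- function(profile, token) {
  sum(unlist(lapply(profile$representations, `[[`, "tokens")) == token)
}
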