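#' Positional encoding of a token sequence
#'
#' The token at 1-based position `i` of an `L`-token representation receives
#' the value `L - i + 1`; repeated tokens accumulate their values by
#' summation. For a representation with distinct tokens the values are a
#' permutation of `1..L` and sum to `L(L+1)/2`.
#'
#' @param tokens character vector or [token_sequence()].
#' @return named numeric vector mapping token to positional value.
#' @export
positional_encoding <- function(tokens) {
  if (inherits(tokens, "token_sequence")) tokens <- tokens$tokens
  stopifnot(length(tokens) >= 1L)
  L <- length(tokens)
  vals <- rev(seq_len(L))
  enc <- tapply(vals, tokens, sum)
  stats::setNames(as.numeric(enc), names(enc))
}

#' Build the concept-token index
#'
#' One row per distinct (concept, normalized token sequence), covering every
#' representation of every profile plus, optionally, generated variants. Each
#' row stores the positional encoding, the representation length `C_N` and the
#' value sum `sum C_ti`; an inverted index maps each token to the rows
#' containing it. Identical sequences indexed for different concepts both keep
#' their rows — the ambiguity surfaces at annotation time.
#'
#' @param profiles list of `entity_profile` objects.
#' @param variants optional `variant_set` from [generate_variants()].
#' @param case_sensitive logical, the normalization mode the index was built
#'   under (recorded as metadata and applied to queries).
#' @param stats optional `corpus_stats` snapshot to record.
#' @return a `concept_index` object.
#' @export
build_index <- function(profiles, variants = NULL, case_sensitive = FALSE,
                        stats = NULL) {
  seqs <- list()
  ids <- character()
  for (p in profiles) {
    for (r in p$representations) {
      seqs[[length(seqs) + 1L]] <- r$tokens
      ids <- c(ids, p$concept_id)
    }
  }
  if (!is.null(variants) && nrow(variants) > 0L) {
    for (i in seq_len(nrow(variants))) {
      seqs[[length(seqs) + 1L]] <- strsplit(variants$variant[i], " ",
                                            fixed = TRUE)[[1L]]
      ids <- c(ids, variants$concept_id[i])
    }
  }
  keys <- paste(ids, vapply(seqs, paste, "", collapse = "\r"), sep = "\r\r")
  keep <- !duplicated(keys)
  seqs <- seqs[keep]
  ids <- ids[keep]
  rows <- vector("list", length(seqs))
  inverted <- new.env(parent = emptyenv())
  for (i in seq_along(seqs)) {
    enc <- positional_encoding(seqs[[i]])
    rows[[i]] <- list(concept_id = ids[i], tokens = seqs[[i]], enc = enc,
                      c_n = length(seqs[[i]]), value_sum = sum(enc))
    for (t in names(enc)) {
      assign(t, c(if (exists(t, envir = inverted, inherits = FALSE))
        get(t, envir = inverted) else integer(), i), envir = inverted)
    }
  }
  structure(list(rows = rows, inverted = inverted,
                 case_sensitive = case_sensitive,
                 max_len = if (length(seqs)) max(vapply(seqs, length, 1L)) else 0L,
                 stats = stats),
            class = "concept_index")
}

#' @export
print.concept_index <- function(x, ...) {
  cat("<concept_index> ", length(x$rows), " rows, ",
      length(ls(x$inverted)), " tokens, max length ", x$max_len,
      ", case_sensitive = ", x$case_sensitive, "\n", sep = "")
  invisible(x)
}

#' Score a query against an index row
#'
#' `Score(Q, C) = (Q_N - Q_NF) / Q_N * sum(C_qi) / sum(C_ti)` where `Q_N` is
#' the query token count, `Q_NF` the number of query tokens absent from the
#' row, `C_qi` the row's positional value of distinct query token `i` and
#' `C_ti` the row's positional values. An exact match is a score of exactly 1
#' together with `Q_N = C_N` (the token-count guard that makes the value-sum
#' equality a multiset-equality surrogate).
#'
#' @param query character vector or [token_sequence()] of query tokens.
#' @param row an index row (element of `concept_index$rows`).
#' @return the score, a real in `[0, 1]` for queries matching at most the row.
#' @export
score_query <- function(query, row) {
  if (inherits(query, "token_sequence")) query <- query$tokens
  stopifnot(length(query) >= 1L)
  q_n <- length(query)
  present <- query %in% names(row$enc)
  q_nf <- sum(!present)
  uq <- unique(query[present])
  sum_q <- if (length(uq)) sum(row$enc[uq]) else 0
  (q_n - q_nf) / q_n * sum_q / row$value_sum
}

# exact-boundary match predicate (integer arithmetic, no epsilon)
is_exact_match <- function(query, row) {
  q_n <- length(query)
  if (q_n != row$c_n) return(FALSE)
  if (!all(query %in% names(row$enc))) return(FALSE)
  sum(row$enc[unique(query)]) == row$value_sum
}

.abbreviations <- c("e.g", "i.e", "etc", "cf", "vs", "fig", "figs", "al",
                    "dr", "no", "st")

#' Split text into sentences
#'
#' Rule-based: a run of `.`, `!` or `?` followed by whitespace (or end of
#' text) ends a sentence, unless the preceding word is a known abbreviation.
#'
#' @param text a single string.
#' @param abbreviations lowercased abbreviation list (without trailing dot).
#' @return data.frame with 0-based half-open columns `start`, `end`.
#' @export
split_sentences <- function(text, abbreviations = .abbreviations) {
  m <- gregexpr("[.!?]+(\\s+|$)", text)[[1L]]
  bounds <- integer()
  if (m[1L] != -1L) {
    for (j in seq_along(m)) {
      pos <- as.integer(m[j])  # 1-based position of the punctuation run
      prefix <- substring(text, 1L, pos - 1L)
      last_word <- tolower(sub("^.*?(\\S+)$", "\\1", prefix))
      last_word <- gsub("\\.$", "", last_word)
      if (last_word %in% abbreviations) next
      bounds <- c(bounds, pos + attr(m, "match.length")[j] - 1L)  # 1-based end
    }
  }
  starts <- c(0L, bounds)
  ends <- c(bounds, nchar(text))
  keep <- starts < ends
  df <- data.frame(start = starts[keep], end = ends[keep])
  # trim whitespace-only fragments
  df[vapply(seq_len(nrow(df)), function(i)
    grepl("\\S", substring(text, df$start[i] + 1L, df$end[i])), NA), ,
    drop = FALSE]
}

#' Generate annotation candidates from a document
#'
#' Splits the document into sentences, normalizes each sentence under the
#' index's case mode, and emits every contiguous window of 1..`max_len`
#' normalized tokens together with the character span of its surviving tokens
#' on the original text (stripped stop tokens at the window edges never widen
#' the span, and spans never cross sentence boundaries).
#'
#' @param text document text.
#' @param max_len maximum window length in normalized tokens.
#' @param case_sensitive normalization mode.
#' @param lemmatizer,stoplist passed to [normalize_text()].
#' @return a list of candidates, each a list with `tokens`, `start`, `end`
#'   (0-based half-open on `text`).
#' @export
generate_candidates <- function(text, max_len, case_sensitive = FALSE,
                                lemmatizer = default_lemmatizer,
                                stoplist = default_stoplist()) {
  stopifnot(nzchar(text), max_len >= 1L)
  sents <- split_sentences(text)
  out <- list()
  for (s in seq_len(nrow(sents))) {
    s0 <- sents$start[s]
    stext <- substring(text, s0 + 1L, sents$end[s])
    ts <- normalize_text(stext, case_sensitive = case_sensitive,
                         lemmatizer = lemmatizer, stoplist = stoplist)
    ntok <- length(ts)
    if (ntok == 0L) next
    for (i in seq_len(ntok)) {
      for (j in i:min(ntok, i + max_len - 1L)) {
        out[[length(out) + 1L]] <- list(
          tokens = ts$tokens[i:j],
          start = s0 + ts$starts[i],
          end = s0 + ts$ends[j])
      }
    }
  }
  out
}

#' Annotate documents with exact-boundary concept matches
#'
#' Runs candidate generation on each document and emits one annotation per
#' (span, concept) whose candidate scores exactly 1 against some index row
#' ("find all matches": overlapping and nested exact matches are all
#' reported; duplicates via label and variant of the same concept collapse).
#'
#' @param docs named character vector of document texts (names are doc ids),
#'   or a character vector of file paths (ids are base names without
#'   extension).
#' @param index a [build_index()] result.
#' @param lemmatizer,stoplist passed to [normalize_text()].
#' @return a data.frame with columns `doc_id`, `start`, `end`, `concept_id`,
#'   `text`, `score` (0-based half-open spans on the original text).
#' @export
annotate <- function(docs, index, lemmatizer = default_lemmatizer,
                     stoplist = default_stoplist()) {
  if (is.null(names(docs))) {
    stopifnot(all(file.exists(docs)))
    ids <- sub("\\.[^.]*$", "", basename(docs))
    docs <- stats::setNames(vapply(docs, function(p)
      paste(readLines(p, encoding = "UTF-8", warn = FALSE), collapse = "\n"),
      ""), ids)
  }
  res <- list()
  for (doc_id in names(docs)) {
    text <- docs[[doc_id]]
    if (!nzchar(text)) next
    cands <- generate_candidates(text, index$max_len,
                                 case_sensitive = index$case_sensitive,
                                 lemmatizer = lemmatizer, stoplist = stoplist)
    for (cand in cands) {
      toks <- cand$tokens
      # postings lookup via the rarest token; any missing token => no match
      posting <- NULL
      for (t in unique(toks)) {
        if (!exists(t, envir = index$inverted, inherits = FALSE)) {
          posting <- integer(); break
        }
        pl <- get(t, envir = index$inverted)
        if (is.null(posting) || length(pl) < length(posting)) posting <- pl
      }
      if (length(posting) == 0L) next
      for (ri in posting) {
        row <- index$rows[[ri]]
        if (is_exact_match(toks, row)) {
          res[[length(res) + 1L]] <- data.frame(
            doc_id = doc_id, start = cand$start, end = cand$end,
            concept_id = row$concept_id,
            text = substring(text, cand$start + 1L, cand$end),
            score = 1, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(doc_id = character(), start = integer(),
                      end = integer(), concept_id = character(),
                      text = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  ann <- do.call(rbind, res)
  ann <- ann[!duplicated(ann[, c("doc_id", "start", "end", "concept_id")]), ]
  ann <- ann[order(ann$doc_id, ann$start, ann$end, ann$concept_id), ]
  rownames(ann) <- NULL
  ann
}
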