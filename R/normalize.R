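#' @importFrom stats quantile sd
#' @importFrom utils head tail
NULL

# Punctuation stripped from raw-token edges before any shape check. Hyphen,
# slash and comma are deliberately absent: they are separator characters and
# may legitimately occur inside case-sensitive tokens ("C3/C5", "cellular-E10").
.edge_punct <- "[.;:!?\"'`()\\[\\]{}]"

popsd <- function(x) {
  x <- as.numeric(x)
  sqrt(mean((x - mean(x))^2))
}

#' Construct a token sequence
#'
#' A `token_sequence` holds normalized tokens together with 0-based, half-open
#' character spans into the original string, so that annotations can report
#' exact boundaries on the raw text.
#'
#' @param tokens character vector of normalized tokens.
#' @param source_text the original string.
#' @param starts,ends integer vectors of 0-based half-open spans, one per token.
#' @return an object of class `token_sequence`.
#' @export
token_sequence <- function(tokens, source_text, starts, ends) {
  stopifnot(length(tokens) == length(starts), length(starts) == length(ends))
  structure(
    list(tokens = as.character(tokens), source_text = source_text,
         starts = as.integer(starts), ends = as.integer(ends)),
    class = "token_sequence"
  )
}

#' @export
print.token_sequence <- function(x, ...) {
  cat("<token_sequence> ", paste(x$tokens, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
length.token_sequence <- function(x) length(x$tokens)

#' Default rule-based English lemmatizer
#'
#' Strips common plural inflections (`studies -> study`, `boxes -> box`,
#' `cells -> cell`). Intentionally conservative and idempotent; a heavier
#' lemmatizer (e.g. one backed by a POS tagger) can be plugged into
#' [normalize_text()] instead.
#'
#' @param token a lower-cased token.
#' @return the lemmatized token.
#' @export
default_lemmatizer <- function(token) {
  n <- nchar(token)
  if (n <= 3L) return(token)
  if (grepl("[a-z]ies$", token)) return(sub("ies$", "y", token))
  if (grepl("(s|x|z|ch|sh)es$", token)) return(sub("es$", "", token))
  if (grepl("[^su]s$", token) && !grepl("is$", token)) return(sub("s$", "", token))
  token
}

#' Default stoplist (determiners and prepositions)
#'
#' @param path optional path to a one-token-per-line UTF-8 stoplist file; the
#'   packaged list is used when omitted.
#' @return character vector of stop tokens.
#' @export
default_stoplist <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stoplist.txt", package = "ontosieve")
  }
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

# Raw whitespace-delimited tokens with 0-based half-open spans.
.raw_tokens <- function(text) {
  m <- gregexpr("\\S+", text)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(token = character(), start = integer(), end = integer()))
  }
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  data.frame(token = substring(text, m, m + lens - 1L),
             start = starts, end = starts + lens, stringsAsFactors = FALSE)
}

# Strip edge punctuation, returning the core substring and its offset shift.
.strip_edges <- function(token) {
  lead <- regmatches(token, regexpr(paste0("^", .edge_punct, "+"), token,
                                    perl = TRUE))
  n_lead <- if (length(lead)) nchar(lead) else 0L
  core <- substring(token, n_lead + 1L)
  trail <- regmatches(core, regexpr(paste0(.edge_punct, "+$"), core,
                                    perl = TRUE))
  n_trail <- if (length(trail)) nchar(trail) else 0L
  core <- substring(core, 1L, nchar(core) - n_trail)
  list(core = core, offset = n_lead)
}

#' Normalize text into a token sequence
#'
#' Applies the entity-profile normalization pipeline: whitespace tokenization,
#' edge-punctuation stripping, a token-shape check (see
#' [is_case_sensitive_token()]), separator splitting on hyphen/slash/comma,
#' lemmatization, lower-casing, and stoplist removal. Under
#' `case_sensitive = TRUE`, raw tokens matching a case-sensitive shape are kept
#' verbatim: they are not split, lemmatized or lower-cased. The shape check runs
#' on the whole raw token (before separator splitting), so e.g. `"C3/C5"`
#' survives intact in case-sensitive mode.
#'
#' @param text a single string.
#' @param case_sensitive logical; process under case-sensitive rules.
#' @param lemmatizer a `function(token) -> token` applied to lower-cased plain
#'   tokens.
#' @param stoplist character vector of tokens to drop.
#' @return a [token_sequence()]; zero surviving tokens is not an error but the
#'   result carries attribute `empty = TRUE`.
#' @export
normalize_text <- function(text, case_sensitive = FALSE,
                           lemmatizer = default_lemmatizer,
                           stoplist = default_stoplist()) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  raw <- .raw_tokens(text)
  toks <- character()
  starts <- integer()
  ends <- integer()
  for (k in seq_len(nrow(raw))) {
    st <- .strip_edges(raw$token[k])
    core <- st$core
    if (!nzchar(core)) next
    core_start <- raw$start[k] + st$offset
    if (case_sensitive && is_case_sensitive_token(core)) {
      toks <- c(toks, core)
      starts <- c(starts, core_start)
      ends <- c(ends, core_start + nchar(core))
      next
    }
    low <- tolower(core)
    pm <- gregexpr("[^-/,]+", low)[[1L]]
    if (pm[1L] == -1L) next
    plens <- attr(pm, "match.length")
    for (j in seq_along(pm)) {
      piece <- substring(low, pm[j], pm[j] + plens[j] - 1L)
      lemma <- lemmatizer(piece)
      if (!nzchar(lemma) || lemma %in% stoplist) next
      toks <- c(toks, lemma)
      starts <- c(starts, core_start + pm[j] - 1L)
      ends <- c(ends, core_start + pm[j] - 1L + plens[j])
    }
  }
  out <- token_sequence(toks, text, starts, ends)
  if (length(toks) == 0L) attr(out, "empty") <- TRUE
  out
}
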