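#' Case-sensitive token shapes
#'
#' A token is case sensitive when it matches one of three shapes:
#' (a) camel case — at least one lowercase letter and at least one uppercase
#' letter beyond the first character (`MetaMap`); (b) all upper case — at least
#' two characters, at least two uppercase letters and no lowercase (`STAR`,
#' `FGFR3`); (c) mixed — at least one uppercase letter together with a digit or
#' a non-alphanumeric symbol (`Tyr336`). Ordinary initial capitalization
#' (`Protein`) matches none of them.
#'
#' @param token character vector of raw (unnormalized) tokens.
#' @return logical vector.
#' @export
is_case_sensitive_token <- function(token) {
  stopifnot(is.character(token), all(nzchar(token)))
  has_lower <- grepl("[a-z]", token)
  has_upper <- grepl("[A-Z]", token)
  upper_late <- grepl("^.+[A-Z]", token)          # uppercase at position > 0
  n_upper <- nchar(gsub("[^A-Z]", "", token))
  has_digit_sym <- grepl("[0-9]|[^A-Za-z0-9]", token)
  camel <- has_lower & upper_late
  all_upper <- !has_lower & n_upper >= 2L & nchar(token) >= 2L
  mixed <- has_upper & has_digit_sym
  camel | all_upper | mixed
}

#' Is a concept case sensitive?
#'
#' A concept is case sensitive iff any raw token of any of its lexical
#' representations (shape-checked on the unnormalized text) is case sensitive.
#'
#' @param x an `entity_profile` or [raw_concept()].
#' @return logical scalar.
#' @export
concept_is_case_sensitive <- function(x) {
  texts <- if (inherits(x, "entity_profile")) {
    vapply(x$representations, `[[`, "", "source_text")
  } else {
    c(x$labels, x$synonyms)
  }
  for (tx in texts) {
    raw <- .raw_tokens(tx)$token
    if (length(raw) == 0L) next
    cores <- vapply(raw, function(t) .strip_edges(t)$core, "")
    cores <- cores[nzchar(cores)]
    if (length(cores) > 0L && any(is_case_sensitive_token(cores))) return(TRUE)
  }
  FALSE
}

#' Ontology-level case sensitivity status (CSS)
#'
#' From an ordered sequence of per-concept case-sensitivity flags, computes
#' `CSS = 1/2 * (exp(-D) - D/e + Freq_CS / N_C)` where `Freq_CS` is the number
#' of case-sensitive concepts, `N_C` the total, and `D` (`delta_cs`) the
#' population standard deviation of the window gaps `W_i` — the counts of
#' non-case-sensitive concepts between consecutive case-sensitive concepts.
#' CSS reaches its maximum of 1 exactly when every concept is case sensitive.
#' With fewer than two case-sensitive concepts the statistic is undefined
#' (`css = NA`) and the ontology is classified non-case-sensitive. Otherwise
#' the ontology is classified case sensitive iff `css > threshold` (default
#' -1, from clustering CSS values over a broad ontology sample).
#'
#' @param flags logical vector, one flag per concept, in a fixed concept order.
#' @param threshold classification threshold on CSS.
#' @return a `case_report` list: `n_c`, `freq_cs`, `n_cs`, `gaps`, `delta_cs`,
#'   `css`, `is_case_sensitive`, `threshold`.
#' @export
compute_css <- function(flags, threshold = -1) {
  stopifnot(is.logical(flags), length(flags) > 0L, !anyNA(flags))
  n_c <- length(flags)
  idx <- which(flags)
  freq_cs <- length(idx)
  if (freq_cs < 2L) {
    return(structure(list(n_c = n_c, freq_cs = freq_cs, n_cs = freq_cs,
                          gaps = integer(), delta_cs = NA_real_,
                          css = NA_real_, is_case_sensitive = FALSE,
                          threshold = threshold),
                     class = "case_report"))
  }
  gaps <- diff(idx) - 1L   # non-CS concepts between consecutive CS concepts
  delta_cs <- popsd(gaps)
  css <- 0.5 * (exp(-delta_cs) - delta_cs / exp(1) + freq_cs / n_c)
  structure(list(n_c = n_c, freq_cs = freq_cs, n_cs = freq_cs, gaps = gaps,
                 delta_cs = delta_cs, css = css,
                 is_case_sensitive = css > threshold, threshold = threshold),
            class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat("Case sensitivity report\n")
  cat("  concepts (N_C):        ", x$n_c, "\n")
  cat("  case-sensitive (Freq): ", x$freq_cs, "\n")
  cat("  Delta_CS (gap SD):     ",
      if (is.na(x$delta_cs)) "undefined" else format(x$delta_cs), "\n")
  cat("  CSS:                   ",
      if (is.na(x$css)) "undefined" else format(x$css), "\n")
  cat("  classification:        ",
      if (x$is_case_sensitive) "CASE SENSITIVE" else "case insensitive",
      " (threshold ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Case-sensitivity census of a lexicon
#'
#' Convenience wrapper: flags every concept with [concept_is_case_sensitive()]
#' in a deterministic order and runs [compute_css()].
#'
#' @param concepts list of [raw_concept()] objects.
#' @param order `"id"` (ascending lexicographic concept-id order, the default)
#'   or `"file"` (input order).
#' @param threshold classification threshold on CSS.
#' @return a `case_report` (see [compute_css()]).
#' @export
css_report <- function(concepts, order = c("id", "file"), threshold = -1) {
  order <- match.arg(order)
  ids <- vapply(concepts, `[[`, "", "concept_id")
  if (order == "id") concepts <- concepts[base::order(ids, method = "radix")]
  flags <- vapply(concepts, concept_is_case_sensitive, NA)
  compute_css(flags, threshold = threshold)
}
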