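#' Variant-generation parameters
#'
#' @param m,n independence-interval constants (see [mi_stats()]).
#' @param k global low-IG outlier constant: threshold `mean_IG - k * sd_IG`.
#' @param enable_bigram_split apply the balance rules to bigrams without
#'   low-IG tokens.
#' @return a `variant_params` list.
#' @export
variant_params <- function(m = 1, n = 0, k = 3, enable_bigram_split = TRUE) {
  stopifnot(m > 0, n >= 0, k > 0)
  structure(list(m = m, n = n, k = k,
                 enable_bigram_split = isTRUE(enable_bigram_split)),
            class = "variant_params")
}

#' Per-ontology parameter presets
#'
#' Best-known independence-interval settings for the six CRAFT
#' ontologies (`k = 3` throughout): CL `m=0.8, n=0`; GO_CC `m=0.9, n=0`;
#' GO_BPMF `m=1, n=0.1`; ChEBI `m=0.9, n=0`; PRO `m=1, n=0.2`; SO `m=0.7, n=0`.
#'
#' @param name one of `"craft-CL"`, `"craft-GO_CC"`, `"craft-GO_BPMF"`,
#'   `"craft-ChEBI"`, `"craft-PRO"`, `"craft-SO"`.
#' @return a [variant_params()] object.
#' @export
variant_preset <- function(name) {
  presets <- list(
    "craft-CL"      = c(m = 0.8, n = 0),
    "craft-GO_CC"   = c(m = 0.9, n = 0),
    "craft-GO_BPMF" = c(m = 1.0, n = 0.1),
    "craft-ChEBI"   = c(m = 0.9, n = 0),
    "craft-PRO"     = c(m = 1.0, n = 0.2),
    "craft-SO"      = c(m = 0.7, n = 0)
  )
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  p <- presets[[name]]
  variant_params(m = p[["m"]], n = p[["n"]], k = 3)
}

#' Mark low-IG outlier tokens within a multi-token representation
#'
#' Given the information-gain values of the tokens of one representation
#' (length >= 3), marks as outliers all tokens whose IG lies strictly below
#' `mean(ig) - popSD(ig)` (population standard deviation).
#'
#' @param ig numeric vector of per-token gains, in token order.
#' @return integer vector of outlier indices (possibly empty).
#' @export
label_outliers <- function(ig) {
  stopifnot(length(ig) >= 3L)
  which(ig < mean(ig) - popsd(ig))
}

#' Retain or discard an outlier token
#'
#' An outlier is retained iff it forms a highly correlated bigram with at
#' least one adjacent token — i.e. the pairwise MI of (left neighbour,
#' outlier) or (outlier, right neighbour) falls strictly outside the
#' independence interval. Unseen bigrams and MI values inside the interval
#' (inclusive bounds) count as independent, so the outlier is discarded.
#'
#' @param tokens character vector, the representation's tokens.
#' @param index position of the outlier token.
#' @param stats an [mi_stats()] object (carries the interval).
#' @return `"RETAIN"` or `"DISCARD"`.
#' @export
resolve_outlier <- function(tokens, index, stats) {
  stopifnot(index >= 1L, index <= length(tokens), length(tokens) >= 2L)
  correlated <- FALSE
  if (index > 1L) {
    v <- pairwise_mi(stats, tokens[index - 1L], tokens[index])
    if (!mi_inside_ii(stats, v)) correlated <- TRUE
  }
  if (!correlated && index < length(tokens)) {
    v <- pairwise_mi(stats, tokens[index], tokens[index + 1L])
    if (!mi_inside_ii(stats, v)) correlated <- TRUE
  }
  if (correlated) "RETAIN" else "DISCARD"
}

#' Global low-IG token statistics
#'
#' For each token, its global IG is the unweighted mean of its per-profile
#' gains over the profiles where it occurs in at least one representation of
#' two or more tokens (values from single-token representations are excluded).
#' The low-IG set collects tokens whose global IG falls strictly below
#' `mean_IG - k * sd_IG` (population SD over the per-token global IG values).
#'
#' @param profiles list of `entity_profile` objects.
#' @param gains a [gain_table()] for the same profiles.
#' @param params a [variant_params()] (supplies `k`).
#' @return a `global_ig_stats` list: `table` (data.table `token`,
#'   `global_ig`), `mean_ig`, `sd_ig`, `threshold`, `low_ig_tokens`, `k`.
#' @export
global_low_ig <- function(profiles, gains, params = variant_params()) {
  # tokens eligible per profile: those occurring in a representation of len >= 2
  elig <- lapply(profiles, function(p) {
    toks <- unique(unlist(lapply(p$representations, function(r)
      if (length(r) >= 2L) r$tokens else character())))
    if (length(toks) == 0L) return(NULL)
    data.table::data.table(concept_id = p$concept_id, token = toks)
  })
  elig <- data.table::rbindlist(elig[!vapply(elig, is.null, NA)])
  if (nrow(elig) == 0L) {
    return(structure(list(table = data.table::data.table(token = character(),
                                                         global_ig = numeric()),
                          mean_ig = NA_real_, sd_ig = NA_real_,
                          threshold = NA_real_, low_ig_tokens = character(),
                          k = params$k),
                     class = "global_ig_stats"))
  }
  dt <- merge(elig, gains[, .(concept_id, token, gain)],
              by = c("concept_id", "token"))
  tab <- dt[, .(global_ig = mean(gain)), by = token]
  if (nrow(tab) < 2L) {
    low <- character()
    mean_ig <- mean(tab$global_ig)
    sd_ig <- 0
    thr <- NA_real_
  } else {
    mean_ig <- mean(tab$global_ig)
    sd_ig <- popsd(tab$global_ig)
    thr <- mean_ig - params$k * sd_ig
    low <- tab[global_ig < thr, token]
  }
  structure(list(table = tab, mean_ig = mean_ig, sd_ig = sd_ig,
                 threshold = thr, low_ig_tokens = low, k = params$k),
            class = "global_ig_stats")
}

#' @export
print.global_ig_stats <- function(x, ...) {
  cat("<global_ig_stats> ", nrow(x$table), " tokens, mean IG = ",
      format(x$mean_ig), ", SD = ", format(x$sd_ig), ", threshold (k = ",
      x$k, ") = ", format(x$threshold), "\n", sep = "")
  if (length(x$low_ig_tokens)) {
    cat("  low-IG tokens: ",
        paste(utils::head(x$low_ig_tokens, 10L), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Split decision for a two-token representation
#'
#' Implements the bigram rules: (a) if either token is in the global low-IG
#' set, split iff the bigram MI is inside the independence interval, retaining
#' the token with the higher global IG; (b) otherwise, if the bigram MI lies
#' outside the interval (correlated), apply [sign_balance()] +
#' [balance_correlated()]: a positive subunitary value retains the right
#' token, a negative subunitary value the left; (c) otherwise (independent),
#' apply [balance_independent()]: a positive subunitary value retains the
#' right token, a negative overunitary value the left. Every other outcome
#' (including undefined balances and `S = 0`) is "no split".
#'
#' @param tokens character vector of exactly two tokens `c(LT, RT)`.
#' @param global_stats a [global_low_ig()] result.
#' @param stats an [mi_stats()] object.
#' @param params a [variant_params()].
#' @return a list `decision` (`"none"` or `"split"`), `retained` (`"left"`,
#'   `"right"` or `NA`), `rule` (`"BIGRAM_LOW_IG_SPLIT"`,
#'   `"BIGRAM_BALANCE_SPLIT"` or `NA`), `balance` (the balance value or `NA`).
#' @export
process_bigram <- function(tokens, global_stats, stats,
                           params = variant_params()) {
  stopifnot(length(tokens) == 2L)
  lt <- tokens[1L]; rt <- tokens[2L]
  no_split <- list(decision = "none", retained = NA_character_,
                   rule = NA_character_, balance = NA_real_)
  mi_val <- pairwise_mi(stats, lt, rt)
  low_set <- global_stats$low_ig_tokens
  if (lt %in% low_set || rt %in% low_set) {
    if (!mi_inside_ii(stats, mi_val)) return(no_split)
    ig <- stats::setNames(global_stats$table$global_ig, global_stats$table$token)
    g_lt <- ig[lt]; g_rt <- ig[rt]
    if (is.na(g_lt) || is.na(g_rt) || g_lt == g_rt) return(no_split)
    return(list(decision = "split",
                retained = if (g_lt > g_rt) "left" else "right",
                rule = "BIGRAM_LOW_IG_SPLIT", balance = NA_real_))
  }
  if (!params$enable_bigram_split) return(no_split)
  lt_l <- position_mi(stats, lt, "left")
  lt_r <- position_mi(stats, lt, "right")
  rt_l <- position_mi(stats, rt, "left")
  rt_r <- position_mi(stats, rt, "right")
  s <- sign_balance(lt_r, rt_l)
  if (s == 0L) return(no_split)
  if (!mi_inside_ii(stats, mi_val)) {
    v <- balance_correlated(lt_l, lt_r, rt_l, rt_r, s)
    if (is.na(v)) return(no_split)
    if (v > 0 && v < 1) {
      return(list(decision = "split", retained = "right",
                  rule = "BIGRAM_BALANCE_SPLIT", balance = v))
    }
    if (v < 0 && v > -1) {
      return(list(decision = "split", retained = "left",
                  rule = "BIGRAM_BALANCE_SPLIT", balance = v))
    }
    return(no_split)
  }
  v <- balance_independent(lt_r, rt_l, s)
  if (is.na(v)) return(no_split)
  if (v > 0 && v < 1) {
    return(list(decision = "split", retained = "right",
                rule = "BIGRAM_BALANCE_SPLIT", balance = v))
  }
  if (v < -1) {
    return(list(decision = "split", retained = "left",
                rule = "BIGRAM_BALANCE_SPLIT", balance = v))
  }
  no_split
}

#' Generate alternative labels for a lexicon
#'
#' Applies the multi-token outlier machinery ([label_outliers()] +
#' [resolve_outlier()]) to every representation of three or more tokens —
#' removing all discarded outliers in one pass — and the bigram rules
#' ([process_bigram()]) to every two-token representation. Single-token
#' representations are untouched. Generated variants are strict token
#' subsequences of their source, never empty, never equal to the source, and
#' deduplicated per (concept, token sequence). Statistics are computed on the
#' original representations only; variants never feed back into them.
#'
#' @param profiles list of `entity_profile` objects.
#' @param gains a [gain_table()] for the same profiles.
#' @param stats an [mi_stats()] object for the same profiles.
#' @param global_stats optionally a precomputed [global_low_ig()]; computed
#'   from `gains` when `NULL`.
#' @param params a [variant_params()].
#' @return a `variant_set`: data.table with columns `concept_id`, `source`
#'   (source representation, space-joined), `variant` (generated sequence,
#'   space-joined), `rule`.
#' @export
generate_variants <- function(profiles, gains, stats, global_stats = NULL,
                              params = variant_params()) {
  if (is.null(global_stats)) {
    global_stats <- global_low_ig(profiles, gains, params)
  }
  if (is.na(stats$ii_low)) {
    warning("independence interval undefined: no variants generated")
    return(.empty_variant_set())
  }
  gain_lookup <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(gains))) {
    assign(paste0(gains$concept_id[i], "\r", gains$token[i]), gains$gain[i],
           envir = gain_lookup)
  }
  out <- list()
  for (p in profiles) {
    for (r in p$representations) {
      toks <- r$tokens
      L <- length(toks)
      if (L < 2L) next
      if (L == 2L) {
        dec <- process_bigram(toks, global_stats, stats, params)
        if (dec$decision == "split") {
          kept <- if (dec$retained == "left") toks[1L] else toks[2L]
          out[[length(out) + 1L]] <- data.table::data.table(
            concept_id = p$concept_id,
            source = paste(toks, collapse = " "),
            variant = kept, rule = dec$rule)
        }
        next
      }
      ig <- vapply(toks, function(t)
        get(paste0(p$concept_id, "\r", t), envir = gain_lookup), 0)
      outliers <- label_outliers(ig)
      if (length(outliers) == 0L) next
      drop <- outliers[vapply(outliers, function(i)
        resolve_outlier(toks, i, stats) == "DISCARD", NA)]
      if (length(drop) == 0L || length(drop) == L) next
      kept <- toks[-drop]
      out[[length(out) + 1L]] <- data.table::data.table(
        concept_id = p$concept_id,
        source = paste(toks, collapse = " "),
        variant = paste(kept, collapse = " "),
        rule = "MULTI_TOKEN_DROP")
    }
  }
  if (length(out) == 0L) return(.empty_variant_set())
  vs <- data.table::rbindlist(out)
  vs <- unique(vs, by = c("concept_id", "variant"))
  vs <- vs[variant != source]
  data.table::setattr(vs, "class", c("variant_set", class(vs)))
  vs[]
}

.empty_variant_set <- function() {
  vs <- data.table::data.table(concept_id = character(), source = character(),
                               variant = character(), rule = character())
  data.table::setattr(vs, "class", c("variant_set", class(vs)))
  vs[]
}
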