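#' Normalized within-profile term frequency
#'
#' `tfn = tf * log(1 + sl/dl)` (log base configurable, default 2): the raw
#' within-profile frequency rescaled by how the profile's mean representation
#' length `dl` compares to the corpus mean `sl`.
#'
#' @param tf within-profile frequency (>= 0).
#' @param dl mean token count of the profile's representations (> 0).
#' @param sl mean token count over all representations in the lexicon (> 0).
#' @param log_base logarithm base (2 or `exp(1)`).
#' @return tfn, a non-negative real.
#' @export
normalized_tf <- function(tf, dl, sl, log_base = 2) {
  stopifnot(all(tf >= 0), all(sl > 0))
  if (any(dl <= 0)) stop("dl must be > 0 (profile with no tokens)")
  tf * log(1 + sl / dl, base = log_base)
}

# log binomial coefficient continuously extended to real k via log-gamma
# (base::lchoose rounds non-integer k, which would kink the weight)
.lchoose_real <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)

#' Binomial divergence-from-randomness weight
#'
#' `weight = -log[ C(TF, tfn) * p^tfn * q^(TF - tfn) ]` with `p = 1/N`,
#' `q = 1 - p`: the negative log-probability, under a binomial model of
#' randomness, of observing frequency `tfn` of a token with collection
#' frequency `TF` in one of `N` profiles. The binomial coefficient is
#' continuously extended via log-gamma for non-integer `tfn`. `tfn > TF` is
#' clamped to `TF` with a warning (can occur when `sl >> dl`). The weight is
#' floored at 0 so downstream gains are never negative.
#'
#' @param TF collection frequency of the token (>= 1).
#' @param tfn normalized within-profile frequency (>= 0).
#' @param N number of entity profiles (>= 2).
#' @param log_base logarithm base.
#' @return the weight, in bits for base 2.
#' @export
binomial_weight <- function(TF, tfn, N, log_base = 2) {
  stopifnot(all(TF >= 1), all(tfn >= 0), N >= 2)
  if (any(tfn > TF)) {
    warning("tfn > TF for ", sum(tfn > TF), " entr(y/ies); clamping to TF")
    tfn <- pmin(tfn, TF)
  }
  p <- 1 / N
  q <- 1 - p
  log_pmf <- .lchoose_real(TF, tfn) + tfn * log(p) + (TF - tfn) * log(q)
  pmax(-log_pmf / log(log_base), 0)
}

#' Information gain of a token within an entity profile
#'
#' The DFR weight rescaled by the risk factor `P_risk = TF / (df * (tfn + 1))`:
#' `gain = weight(TF, tfn, N) * TF / (df * (tfn + 1))`. High-frequency tokens
#' spread over many profiles (large `df`, `tfn` near its random expectation)
#' gain little; tokens concentrated in a small elite set of profiles gain much.
#'
#' @param TF,tfn,N,log_base as in [binomial_weight()].
#' @param df number of profiles containing the token (>= 1).
#' @return the information gain, a non-negative real.
#' @export
dfr_gain <- function(TF, tfn, df, N, log_base = 2) {
  if (any(df <= 0)) stop("df = 0 for an occurring token: inconsistent corpus stats")
  binomial_weight(TF, tfn, N, log_base = log_base) * TF / (df * (tfn + 1))
}

#' Per-profile, per-token information gain table
#'
#' Computes `tf` (within-profile count, summed over the profile's
#' representations), `tfn`, the DFR `weight`, `p_risk` and `gain` for every
#' (concept, token) pair of the lexicon.
#'
#' @param profiles list of `entity_profile` objects (from [build_profiles()]).
#' @param stats the matching `corpus_stats`.
#' @param log_base logarithm base (default 2: gains in bits).
#' @return a `data.table` with columns `concept_id`, `token`, `tf`, `tfn`,
#'   `weight`, `p_risk`, `gain`, carrying attribute `log_base`.
#' @export
gain_table <- function(profiles, stats, log_base = 2) {
  rows <- lapply(profiles, function(p) {
    tab <- table(unlist(lapply(p$representations, `[[`, "tokens")))
    data.table::data.table(concept_id = p$concept_id,
                           token = names(tab),
                           tf = as.integer(tab),
                           dl = p$dl)
  })
  dt <- data.table::rbindlist(rows)
  dt[, `:=`(TF = stats$TF[token], df = stats$df[token])]
  dt[, tfn := normalized_tf(tf, dl, stats$sl, log_base = log_base)]
  clamped <- dt$tfn > dt$TF
  if (any(clamped)) {
    warning("tfn > TF for ", sum(clamped), " entries; clamped to TF")
    dt[clamped, tfn := as.numeric(TF)]
  }
  p <- stats$p
  q <- stats$q
  dt[, weight := pmax(-(.lchoose_real(TF, tfn) + tfn * log(p) +
                          (TF - tfn) * log(q)) / log(log_base), 0)]
  dt[, p_risk := TF / (df * (tfn + 1))]
  dt[, gain := weight * p_risk]
  dt[, dl := NULL]
  data.table::setattr(dt, "log_base", log_base)
  dt[]
}
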