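#' Bigram mutual-information statistics of a lexicon
#'
#' Tallies unigram occurrences and adjacent bigram occurrences over the
#' normalized lexical representations, computes the pointwise mutual
#' information `MI(x, y) = ln[ p(x,y) / (p(x) p(y)) ]` of every observed
#' bigram (with `p(x,y)` = bigram count / total bigram occurrences and `p(x)`
#' = unigram count / total token occurrences), the quartiles of the bigram-MI
#' distribution (linear interpolation, quantile type 7), the independence
#' interval `[m*Q1 - n*IQR, m*Q3 + n*IQR]`, and the per-token position MI —
#' the mean pairwise MI over all distinct bigrams with the token on a given
#' side.
#'
#' Bigram MI values strictly outside the independence interval denote
#' correlated pairs (the tails of the distribution); values inside (inclusive)
#' denote independence. Fewer than 4 observed bigrams leave the interval
#' undefined, with a warning (variant generation is then disabled).
#'
#' @param profiles list of `entity_profile` objects.
#' @param m,n independence-interval constants (`m > 0`, `n >= 0`).
#' @return an `mi_stats` object: `bigram` (data.table `left`, `right`, `count`,
#'   `mi`), `unigram` (named counts), `total_tokens`, `total_bigrams`, `q1`,
#'   `q3`, `iqr`, `ii_low`, `ii_high`, `m`, `n`, `pos_left`, `pos_right`
#'   (named numeric position-MI lookups).
#' @export
mi_stats <- function(profiles, m = 1, n = 0) {
  stopifnot(m > 0, n >= 0)
  reps <- unlist(lapply(profiles, function(p)
    lapply(p$representations, `[[`, "tokens")), recursive = FALSE)
  all_tokens <- unlist(reps)
  unigram <- table(all_tokens)
  unigram <- stats::setNames(as.integer(unigram), names(unigram))
  total_tokens <- length(all_tokens)
  lefts <- unlist(lapply(reps, function(t)
    if (length(t) >= 2L) t[-length(t)] else character()))
  rights <- unlist(lapply(reps, function(t)
    if (length(t) >= 2L) t[-1L] else character()))
  if (length(lefts) == 0L) {
    bigram <- data.table::data.table(left = character(), right = character(),
                                     count = integer(), mi = numeric())
  } else {
    bigram <- data.table::data.table(left = lefts, right = rights)
    bigram <- bigram[, .(count = .N), by = .(left, right)]
  }
  total_bigrams <- sum(bigram$count)
  if (nrow(bigram) > 0L) {
    bigram[, mi := log((count / total_bigrams) * total_tokens^2 /
                         (unigram[left] * unigram[right]))]
  }
  if (nrow(bigram) >= 4L) {
    qs <- stats::quantile(bigram$mi, c(0.25, 0.75), type = 7, names = FALSE)
    q1 <- qs[1L]; q3 <- qs[2L]; iqr <- q3 - q1
    ii_low <- m * q1 - n * iqr
    ii_high <- m * q3 + n * iqr
  } else {
    warning("fewer than 4 observed bigrams: independence interval undefined")
    q1 <- q3 <- iqr <- ii_low <- ii_high <- NA_real_
  }
  pos_left <- if (nrow(bigram)) {
    agg <- bigram[, .(mi = mean(mi)), by = left]
    stats::setNames(agg$mi, agg$left)
  } else stats::setNames(numeric(), character())
  pos_right <- if (nrow(bigram)) {
    agg <- bigram[, .(mi = mean(mi)), by = right]
    stats::setNames(agg$mi, agg$right)
  } else stats::setNames(numeric(), character())
  structure(list(bigram = bigram, unigram = unigram,
                 total_tokens = total_tokens, total_bigrams = total_bigrams,
                 q1 = q1, q3 = q3, iqr = iqr,
                 ii_low = ii_low, ii_high = ii_high, m = m, n = n,
                 pos_left = pos_left, pos_right = pos_right),
            class = "mi_stats")
}

#' @export
print.mi_stats <- function(x, ...) {
  cat("<mi_stats> ", nrow(x$bigram), " distinct bigrams, ",
      length(x$unigram), " tokens\n", sep = "")
  if (!is.na(x$ii_low)) {
    cat("  Q1 = ", format(x$q1), ", Q3 = ", format(x$q3),
        ", II = [", format(x$ii_low), ", ", format(x$ii_high), "] (m = ",
        x$m, ", n = ", x$n, ")\n", sep = "")
  }
  invisible(x)
}

#' Pointwise MI of one observed bigram
#'
#' @param stats an `mi_stats` object.
#' @param x,y left and right tokens.
#' @return the MI value, or `NA` if the bigram was never observed.
#' @export
pairwise_mi <- function(stats, x, y) {
  hit <- stats$bigram[left == x & right == y]
  if (nrow(hit) == 0L) NA_real_ else hit$mi[1L]
}

#' Independence interval from an MI distribution
#'
#' `[m*Q1 - n*IQR, m*Q3 + n*IQR]`, quartiles by linear interpolation.
#'
#' @param mi_values numeric vector of at least 4 bigram-MI values.
#' @param m,n interval constants.
#' @return numeric length-2 vector `c(low, high)`.
#' @export
independence_interval <- function(mi_values, m = 1, n = 0) {
  if (length(mi_values) < 4L) stop("need >= 4 MI values for the interval")
  qs <- stats::quantile(mi_values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- qs[2L] - qs[1L]
  c(m * qs[1L] - n * iqr, m * qs[2L] + n * iqr)
}

#' Position-dependent global MI of a token
#'
#' The arithmetic mean of the pairwise MI over all distinct bigrams holding the
#' token at the given side; 0 when the token occurs in no bigram at that side.
#'
#' @param stats an `mi_stats` object.
#' @param token a token.
#' @param side `"left"` or `"right"`.
#' @return the position MI (0 when absent).
#' @export
position_mi <- function(stats, token, side = c("left", "right")) {
  side <- match.arg(side)
  tab <- if (side == "left") stats$pos_left else stats$pos_right
  v <- tab[token]
  if (is.na(v)) 0 else unname(v)
}

#' Sign function of a bigram
#'
#' `S = sign(MI(LT -> POS_R) - MI(RT -> POS_L))`: which token carries the lower
#' global MI for the position opposite to its own.
#'
#' @param mi_lt_right position MI of the left token at the right position.
#' @param mi_rt_left position MI of the right token at the left position.
#' @return -1, 0 or +1.
#' @export
sign_balance <- function(mi_lt_right, mi_rt_left) {
  as.integer(sign(mi_lt_right - mi_rt_left))
}

#' Balance score for a correlated bigram
#'
#' For `s = +1`: `(MI(LT->L) / MI(LT->R)) * (MI(RT->L) * MI(RT->R))`; for
#' `s = -1` the mirrored expression with the token roles swapped, negated:
#' `-(MI(RT->R) / MI(RT->L)) * (MI(LT->L) * MI(LT->R))`. Undefined (`NA`) when
#' the required denominator is 0. A positive subunitary value retains the
#' right token, a negative subunitary value the left; anything else (including
#' `NA`) means no split.
#'
#' @param lt_left,lt_right position MIs of the left token (left/right side).
#' @param rt_left,rt_right position MIs of the right token.
#' @param s the sign from [sign_balance()]; must be non-zero.
#' @return the balance value, or `NA` when undefined.
#' @export
balance_correlated <- function(lt_left, lt_right, rt_left, rt_right, s) {
  stopifnot(s %in% c(-1L, 1L))
  if (s == 1L) {
    if (lt_right == 0) return(NA_real_)
    (lt_left / lt_right) * (rt_left * rt_right)
  } else {
    if (rt_left == 0) return(NA_real_)
    -(rt_right / rt_left) * (lt_left * lt_right)
  }
}

#' Balance score for an independent bigram
#'
#' `s * MI(LT->R) / MI(RT->L)`; undefined (`NA`) when `MI(RT->L) = 0`. A
#' positive subunitary value retains the right token, a negative overunitary
#' value the left; anything else (including `NA`) means no split.
#'
#' @param lt_right position MI of the left token at the right side.
#' @param rt_left position MI of the right token at the left side.
#' @param s the sign from [sign_balance()]; must be non-zero.
#' @return the balance value, or `NA` when undefined.
#' @export
balance_independent <- function(lt_right, rt_left, s) {
  stopifnot(s %in% c(-1L, 1L))
  if (rt_left == 0) return(NA_real_)
  s * lt_right / rt_left
}

# is an MI value inside the independence interval (inclusive)?
mi_inside_ii <- function(stats, value) {
  if (is.na(stats$ii_low) || is.na(stats$ii_high)) return(TRUE)
  if (is.na(value)) return(TRUE)  # unseen bigram: treated as independent
  value >= stats$ii_low && value <= stats$ii_high
}
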