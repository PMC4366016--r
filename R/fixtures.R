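#' Synthetic fixture specification
#'
#' A stated world for seeded synthetic ontologies and corpora: labels combine
#' Zipf-distributed modifier tokens with a unique head token per
#' representation (mirroring the specific-head / generic-suffix structure of
#' real bio-ontology terms), a planted low-information-gain suffix token
#' appended to a controlled fraction of representations (the
#' "activity"-like token), and optional case-sensitive acronym synonyms for a
#' controlled, placeable fraction of concepts.
#'
#' @param seed integer RNG seed (mandatory).
#' @param n_concepts number of concepts.
#' @param vocab_size size of the Zipf modifier vocabulary.
#' @param zipf_exponent exponent of the Zipf rank distribution.
#' @param cs_fraction fraction of concepts given a case-sensitive token.
#' @param cs_placement `"uniform"` (evenly spaced) or `"clustered"`
#'   (contiguous block).
#' @param suffix_token the planted low-IG token.
#' @param suffix_prevalence fraction of representations carrying the suffix.
#' @param synonyms_per_concept synonyms generated per concept.
#' @param docs,mentions_per_doc corpus shape for [make_corpus()].
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed, n_concepts = 200, vocab_size = 300,
                         zipf_exponent = 1.1, cs_fraction = 0,
                         cs_placement = c("uniform", "clustered"),
                         suffix_token = "activityx", suffix_prevalence = 0.9,
                         synonyms_per_concept = 2, docs = 5,
                         mentions_per_doc = 3) {
  cs_placement <- match.arg(cs_placement)
  stopifnot(is.numeric(seed), length(seed) == 1L,
            n_concepts >= 2, vocab_size >= 5,
            cs_fraction >= 0, cs_fraction <= 1,
            suffix_prevalence >= 0, suffix_prevalence <= 1,
            synonyms_per_concept >= 0, docs >= 1, mentions_per_doc >= 1)
  structure(list(seed = as.integer(seed), n_concepts = as.integer(n_concepts),
                 vocab_size = as.integer(vocab_size),
                 zipf_exponent = zipf_exponent, cs_fraction = cs_fraction,
                 cs_placement = cs_placement, suffix_token = suffix_token,
                 suffix_prevalence = suffix_prevalence,
                 synonyms_per_concept = as.integer(synonyms_per_concept),
                 docs = as.integer(docs),
                 mentions_per_doc = as.integer(mentions_per_doc)),
            class = "fixture_spec")
}

.syllables <- c("ba", "be", "bi", "bo", "bu", "da", "de", "di", "do", "du",
                "ka", "ke", "ki", "ko", "ku", "la", "le", "li", "lo", "lu",
                "ma", "me", "mi", "mo", "mu", "na", "ne", "ni", "no", "nu",
                "ra", "re", "ri", "ro", "ru", "ta", "te", "ti", "tu", "ty",
                "va", "ve", "vi", "vo", "vu", "za", "ze", "zi", "zo", "zu")

# deterministic pseudo-word vocabularies: 2-syllable modifiers, 3-syllable
# unique heads; disjoint by construction (different lengths of syllable count)
.modifier_vocab <- function(size) {
  ns <- length(.syllables)
  if (size > ns^2) stop("vocab too small: at most ", ns^2, " modifier words")
  i <- seq_len(size) - 1L
  paste0(.syllables[i %/% ns + 1L], .syllables[i %% ns + 1L])
}

.head_word <- function(i) {
  ns <- length(.syllables)
  i <- i - 1L
  paste0(.syllables[i %/% (ns^2) + 1L],
         .syllables[(i %/% ns) %% ns + 1L],
         .syllables[i %% ns + 1L])
}

# Modifier tokens are drawn from Zipf ranks below the planted suffix: in real
# ontologies the very top of the token-frequency distribution is occupied by
# the generic tokens themselves ("activity", "protein", "complex"), so the
# modifier vocabulary starts at a rank offset.
.zipf_rank_offset <- 200L

# maximally even placement of k marks among n slots (exact spacing when k | n)
.evenly_spaced <- function(n, k) {
  if (k == 0L) return(integer())
  if (k >= n) return(seq_len(n))
  floor((seq_len(k) - 1L) * (n / k)) + 1L
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic ontology
#'
#' Deterministic given the spec's seed. Every representation is built as
#' `[0-2 Zipf modifiers] + [unique head] (+ suffix token)`; the suffix is
#' appended independently per representation with probability
#' `suffix_prevalence`. Case-sensitive concepts additionally receive an
#' all-uppercase acronym synonym (the uppercased head of their label); their
#' labels are forced to at least two tokens so that the acronym is the only
#' single-token ambiguity surface.
#'
#' @param spec a [fixture_spec()].
#' @param path optional path; when given, the ontology is also written as an
#'   OBO flat file.
#' @return a `synthetic_ontology` list: `concepts` (list of [raw_concept()]),
#'   `reps` (data.frame `concept_id`, `text`, `is_label`, `has_suffix`,
#'   `is_cs_synonym`, `head`), `cs_concepts`, `spec`, `path`.
#' @export
make_ontology <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_concepts
  n_reps <- n * (1L + spec$synonyms_per_concept)
  if (n_reps > length(.syllables)^3) stop("vocab too small for distinct heads")
  with_seed(spec$seed, {
    vocab <- .modifier_vocab(spec$vocab_size)
    zipf_p <- (seq_len(spec$vocab_size) + .zipf_rank_offset)^(-spec$zipf_exponent)
    zipf_p <- zipf_p / sum(zipf_p)
    head_ids <- sample.int(length(.syllables)^3, n_reps)
    n_cs <- round(spec$cs_fraction * n)
    cs_idx <- switch(spec$cs_placement,
                     uniform = .evenly_spaced(n, n_cs),
                     clustered = seq_len(n_cs))
    concepts <- vector("list", n)
    reps <- list()
    h <- 0L
    for (i in seq_len(n)) {
      cid <- sprintf("SYNO:%07d", i)
      is_cs <- i %in% cs_idx
      # the suffix is a concept-level property: every representation of a
      # suffixed concept carries it, as every synonym of a real "... activity"
      # concept names an activity
      concept_suffixed <- stats::runif(1L) < spec$suffix_prevalence
      strings <- character(1L + spec$synonyms_per_concept)
      heads <- character(length(strings))
      suffixed <- logical(length(strings))
      for (r in seq_along(strings)) {
        h <- h + 1L
        head <- .head_word(head_ids[h])
        n_mod <- sample(0:2, 1L, prob = c(0.35, 0.45, 0.20))
        # CS concepts: label needs >= 2 tokens so the acronym synonym is the
        # only representation colliding with the bare lowercase head
        if (r == 1L && is_cs && n_mod == 0L && !concept_suffixed) n_mod <- 1L
        mods <- if (n_mod > 0L) sample(vocab, n_mod, prob = zipf_p) else character()
        toks <- c(mods, head)
        if (concept_suffixed) toks <- c(toks, spec$suffix_token)
        strings[r] <- paste(toks, collapse = " ")
        heads[r] <- head
        suffixed[r] <- concept_suffixed
      }
      synonyms <- strings[-1L]
      if (is_cs) synonyms <- c(synonyms, toupper(heads[1L]))
      concepts[[i]] <- raw_concept(cid, labels = strings[1L],
                                   synonyms = synonyms)
      reps[[i]] <- data.frame(
        concept_id = cid, text = strings,
        is_label = seq_along(strings) == 1L,
        has_suffix = suffixed, is_cs_synonym = FALSE, head = heads,
        stringsAsFactors = FALSE)
      if (is_cs) {
        reps[[i]] <- rbind(reps[[i]], data.frame(
          concept_id = cid, text = toupper(heads[1L]), is_label = FALSE,
          has_suffix = FALSE, is_cs_synonym = TRUE, head = heads[1L],
          stringsAsFactors = FALSE))
      }
    }
    reps <- do.call(rbind, reps)
    rownames(reps) <- NULL
    if (!is.null(path)) write_obo(concepts, path)
    structure(list(concepts = concepts, reps = reps,
                   cs_concepts = sprintf("SYNO:%07d", cs_idx),
                   spec = spec, path = path),
              class = "synthetic_ontology")
  })
}

.filler_words <- c("meadow", "river", "stone", "cloud", "winter", "garden",
                   "bright", "silver", "morning", "quiet", "travel", "wonder",
                   "simple", "gentle", "yellow", "harbor", "candle", "velvet",
                   "autumn", "breeze", "copper", "lantern", "marble", "forest",
                   "willow", "amber", "drift", "hollow", "ember", "frost")

#' Generate a synthetic annotated corpus
#'
#' Documents embed sampled lexical representations verbatim between filler
#' sentences drawn from a fixed word list disjoint from the ontology
#' vocabulary (so every false positive is attributable). Deterministic given
#' the spec's seed. Three modes:
#' \describe{
#'   \item{`verbatim`}{mentions are concept labels, inserted verbatim; gold
#'     records their exact spans.}
#'   \item{`short_form`}{mentions are suffix-bearing labels with the planted
#'     suffix token removed — recoverable only through generated variants;
#'     gold records the short span with the source concept.}
#'   \item{`case_homograph`}{mentions are lower-cased versions of the
#'     case-sensitive acronym synonyms — homographs of common words that a
#'     case-insensitive matcher wrongly annotates. They are recorded in
#'     `baits`, not in `gold`.}
#' }
#'
#' @param ontology a [make_ontology()] result.
#' @param mode one of `"verbatim"`, `"short_form"`, `"case_homograph"`.
#' @param dir optional directory; when given, writes `doc_XX.txt` files and
#'   `gold.tsv`.
#' @return a `synthetic_corpus` list: `docs` (named character vector),
#'   `gold` (data.frame `doc_id`, `start`, `end`, `concept_id`), `baits`
#'   (same shape; only for `case_homograph`), `mode`, `dir`.
#' @export
make_corpus <- function(ontology,
                        mode = c("verbatim", "short_form", "case_homograph"),
                        dir = NULL) {
  stopifnot(inherits(ontology, "synthetic_ontology"))
  mode <- match.arg(mode)
  spec <- ontology$spec
  reps <- ontology$reps
  pool <- switch(mode,
    verbatim = reps[reps$is_label, , drop = FALSE],
    short_form = reps[reps$is_label & reps$has_suffix, , drop = FALSE],
    case_homograph = reps[reps$is_cs_synonym, , drop = FALSE])
  if (nrow(pool) == 0L) {
    stop("no representation available for corpus mode '", mode, "'")
  }
  with_seed(spec$seed + 1L, {
    docs <- character(spec$docs)
    names(docs) <- sprintf("doc_%02d", seq_len(spec$docs))
    gold <- list()
    baits <- list()
    for (d in seq_len(spec$docs)) {
      doc_id <- names(docs)[d]
      parts <- character()
      cur <- 0L
      for (k in seq_len(spec$mentions_per_doc)) {
        filler <- sample(.filler_words, 6L, replace = TRUE)
        fsent <- paste0(paste(filler[1:3], collapse = " "), ".")
        parts <- c(parts, fsent)
        cur <- cur + nchar(fsent) + 1L
        ri <- sample.int(nrow(pool), 1L)
        mention <- switch(mode,
          verbatim = pool$text[ri],
          short_form = sub(paste0("\\s+", spec$suffix_token, "$"), "",
                           pool$text[ri]),
          case_homograph = tolower(pool$text[ri]))
        pre <- paste0(paste(filler[4:5], collapse = " "), " ")
        post <- paste0(" ", filler[6L], ".")
        start <- cur + nchar(pre)
        end <- start + nchar(mention)
        rec <- data.frame(doc_id = doc_id, start = start, end = end,
                          concept_id = pool$concept_id[ri],
                          stringsAsFactors = FALSE)
        if (mode == "case_homograph") {
          baits[[length(baits) + 1L]] <- rec
        } else {
          gold[[length(gold) + 1L]] <- rec
        }
        parts <- c(parts, paste0(pre, mention, post))
        cur <- cur + nchar(pre) + nchar(mention) + nchar(post) + 1L
      }
      docs[d] <- paste(parts, collapse = " ")
    }
    gold <- if (length(gold)) do.call(rbind, gold) else
      data.frame(doc_id = character(), start = integer(), end = integer(),
                 concept_id = character(), stringsAsFactors = FALSE)
    baits <- if (length(baits)) do.call(rbind, baits) else
      data.frame(doc_id = character(), start = integer(), end = integer(),
                 concept_id = character(), stringsAsFactors = FALSE)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      for (doc_id in names(docs)) {
        writeLines(docs[[doc_id]], file.path(dir, paste0(doc_id, ".txt")))
      }
      utils::write.table(gold, file.path(dir, "gold.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = TRUE)
    }
    structure(list(docs = docs, gold = gold, baits = baits, mode = mode,
                   dir = dir),
              class = "synthetic_corpus")
  })
}
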