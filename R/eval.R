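#' Load gold-standard annotations from standoff TSV
#'
#' Expects tab-separated columns `doc_id`, `start`, `end`, `concept_id`
#' (0-based half-open character offsets); a header row is detected and
#' skipped. Rows with non-integer offsets or `start >= end` are rejected with
#' a row-level error report; exact duplicates are dropped with a warning.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `doc_id`, `start`, `end`, `concept_id`.
#' @export
load_gold <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(doc_id = character(), start = integer(),
                      end = integer(), concept_id = character(),
                      stringsAsFactors = FALSE))
  }
  first <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  has_header <- length(first) >= 3L && is.na(suppressWarnings(as.integer(first[2L])))
  body <- if (has_header) lines[-1L] else lines
  rows <- list()
  errors <- character()
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    line_no <- i + if (has_header) 1L else 0L
    if (length(f) < 4L) {
      errors <- c(errors, paste0("line ", line_no, ": expected 4 columns"))
      next
    }
    st <- suppressWarnings(as.integer(f[2L]))
    en <- suppressWarnings(as.integer(f[3L]))
    if (is.na(st) || is.na(en)) {
      errors <- c(errors, paste0("line ", line_no, ": non-integer offsets"))
      next
    }
    if (st >= en) {
      errors <- c(errors, paste0("line ", line_no, ": start >= end"))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(doc_id = f[1L], start = st,
                                            end = en, concept_id = f[4L],
                                            stringsAsFactors = FALSE)
  }
  if (length(errors) > 0L) {
    stop("invalid gold rows:\n  ", paste(errors, collapse = "\n  "))
  }
  if (length(rows) == 0L) {
    return(data.frame(doc_id = character(), start = integer(),
                      end = integer(), concept_id = character(),
                      stringsAsFactors = FALSE))
  }
  gold <- do.call(rbind, rows)
  dup <- duplicated(gold)
  if (any(dup)) {
    warning("dropped ", sum(dup), " duplicate gold annotation(s)")
    gold <- gold[!dup, ]
  }
  rownames(gold) <- NULL
  gold
}

#' Write annotations as standoff TSV
#'
#' @param annotations a data.frame with at least `doc_id`, `start`, `end`,
#'   `concept_id` (a `text` column is included when present).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  cols <- intersect(c("doc_id", "start", "end", "concept_id", "text"),
                    names(annotations))
  utils::write.table(annotations[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.normalize_id <- function(id) sub("_", ":", trimws(id))

#' Exact-boundary evaluation of predicted annotations
#'
#' Micro-averaged over all documents: a prediction is a true positive iff its
#' `(doc_id, start, end, concept_id)` quadruple matches a gold record exactly
#' (concept ids are compared after normalizing the `PREFIX:NUMBER` form).
#' Precision and recall are 0 by convention when their denominators are 0.
#'
#' @param predicted,gold data.frames with columns `doc_id`, `start`, `end`,
#'   `concept_id` (set semantics; duplicates collapse).
#' @return an `eval_result`: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
compare_annotations <- function(predicted, gold) {
  key <- function(df) {
    if (nrow(df) == 0L) return(character())
    unique(paste(df$doc_id, df$start, df$end,
                 .normalize_id(df$concept_id), sep = "\t"))
  }
  pk <- key(predicted)
  gk <- key(gold)
  tp <- length(intersect(pk, gk))
  fp <- length(pk) - tp
  fn <- length(gk) - tp
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("P = %.4f  R = %.4f  F1 = %.4f  (tp %d, fp %d, fn %d)\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}
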