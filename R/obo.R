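#' Construct a raw concept
#'
#' @param concept_id non-empty string identifier (e.g. `"GO:0000010"`).
#' @param labels character vector of labels (preferred + alternative).
#' @param synonyms character vector of synonym strings (all scopes).
#' @return an object of class `raw_concept`.
#' @export
raw_concept <- function(concept_id, labels, synonyms = character()) {
  stopifnot(is.character(concept_id), length(concept_id) == 1L, nzchar(concept_id))
  structure(list(concept_id = concept_id,
                 labels = as.character(labels),
                 synonyms = as.character(synonyms)),
            class = "raw_concept")
}

#' @export
print.raw_concept <- function(x, ...) {
  cat("<raw_concept> ", x$concept_id, ": ", length(x$labels), " label(s), ",
      length(x$synonyms), " synonym(s)\n", sep = "")
  invisible(x)
}

.synonym_tags <- c("synonym", "exact_synonym", "related_synonym",
                   "narrow_synonym", "broad_synonym")

#' Parse an OBO flat file into a lexicon
#'
#' Reads `[Term]` stanzas from an OBO 1.2/1.4 flat file, keeping `id`, `name`
#' and all `synonym` lines (any scope). Obsolete terms (`is_obsolete: true`)
#' are excluded. File order of concepts is preserved.
#'
#' @param path path to an OBO file.
#' @return a list of [raw_concept()] objects.
#' @export
parse_obo <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  concepts <- list()
  in_term <- FALSE
  cur <- NULL
  cur_line <- NA_integer_
  flush <- function(cur, line_no) {
    if (is.null(cur)) return(NULL)
    if (isTRUE(cur$obsolete)) return(NULL)
    if (is.null(cur$id) || !nzchar(cur$id)) {
      stop("malformed [Term] stanza starting at line ", line_no, ": missing id")
    }
    if (is.null(cur$name)) {
      stop("malformed [Term] stanza starting at line ", line_no,
           " (", cur$id, "): missing name")
    }
    raw_concept(cur$id, labels = cur$name, synonyms = cur$synonyms)
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "[Term]") {
      rc <- flush(cur, cur_line)
      if (!is.null(rc)) concepts[[length(concepts) + 1L]] <- rc
      cur <- list(id = NULL, name = NULL, synonyms = character(), obsolete = FALSE)
      cur_line <- i
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", line)) { # a non-Term stanza ends the current term
      rc <- flush(cur, cur_line)
      if (!is.null(rc)) concepts[[length(concepts) + 1L]] <- rc
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(line)) next
    tag <- sub(":.*$", "", line)
    value <- trimws(sub("^[^:]+:", "", line))
    if (tag == "id") {
      cur$id <- value
    } else if (tag == "name") {
      cur$name <- c(cur$name, value)
    } else if (tag %in% .synonym_tags) {
      m <- regmatches(value, regexec('^"(.*)"', value))[[1L]]
      if (length(m) < 2L) {
        stop("malformed synonym line at line ", i, ": ", lines[i])
      }
      cur$synonyms <- c(cur$synonyms, m[2L])
    } else if (tag == "is_obsolete") {
      cur$obsolete <- identical(tolower(value), "true")
    }
  }
  rc <- flush(cur, cur_line)
  if (!is.null(rc)) concepts[[length(concepts) + 1L]] <- rc
  if (length(concepts) == 0L) {
    stop("empty lexicon: no non-obsolete [Term] stanza found in ", path)
  }
  ids <- vapply(concepts, `[[`, "", "concept_id")
  if (anyDuplicated(ids)) {
    stop("duplicate concept ids in lexicon: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  concepts
}

#' Read a plain JSON lexicon
#'
#' Accepts either `{"ID": ["label", ...]}` (first string is the label, the rest
#' synonyms) or `{"ID": {"labels": [...], "synonyms": [...]}}`.
#'
#' @param path path to a JSON file.
#' @return a list of [raw_concept()] objects.
#' @export
read_lexicon_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (length(x) == 0L) stop("empty lexicon: ", path)
  concepts <- vector("list", length(x))
  for (i in seq_along(x)) {
    v <- x[[i]]
    if (is.list(v) && !is.null(v$labels)) {
      concepts[[i]] <- raw_concept(names(x)[i], v$labels,
                                   if (is.null(v$synonyms)) character() else v$synonyms)
    } else {
      v <- as.character(v)
      concepts[[i]] <- raw_concept(names(x)[i], v[1L],
                                   if (length(v) > 1L) v[-1L] else character())
    }
  }
  concepts
}

#' Write a lexicon as an OBO flat file
#'
#' @param concepts list of [raw_concept()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(concepts, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (rc in concepts) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", rc$concept_id), con)
    writeLines(paste0("name: ", rc$labels[1L]), con)
    for (lab in rc$labels[-1L]) {
      writeLines(paste0("synonym: \"", lab, "\" EXACT []"), con)
    }
    for (syn in rc$synonyms) {
      writeLines(paste0("synonym: \"", syn, "\" EXACT []"), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
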