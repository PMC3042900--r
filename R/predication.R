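# Core data model: predications, corpora, predicate count tables.

PRED_COLS <- c(
  "citation_id", "subject_name", "subject_cui", "subject_semtype",
  "predicate", "object_name", "object_cui", "object_semtype"
)

#' Construct a predication corpus
#'
#' A predication corpus is an ordered collection of semantic predications:
#' subject--PREDICATE--object assertions in which each argument carries a
#' concept name, an optional concept identifier (CUI), and a semantic-type
#' code (e.g. `gngm` for Gene or Genome, `neop` for Neoplastic Process).
#' Record order is preserved and duplicate records are allowed: predication
#' frequency carries the statistical signal the saliency metrics use.
#'
#' @param records A data frame with columns `citation_id`, `subject_name`,
#'   `subject_semtype`, `predicate`, `object_name`, `object_semtype` and
#'   optionally `subject_cui`, `object_cui` (`NA` when absent).
#' @param provenance Free-text label describing where the records came from.
#' @param validate Check record invariants (non-empty delimiter-free
#'   predicates, lowercase semantic-type codes)? Default `TRUE`.
#' @return An object of class `predication_corpus` (a data frame).
#' @examples
#' rec <- data.frame(
#'   citation_id = "12345", subject_name = "IGF1R gene",
#'   subject_semtype = "gngm", predicate = "ASSOCIATED_WITH",
#'   object_name = "Carcinoma of bladder", object_semtype = "neop"
#' )
#' predication_corpus(rec, provenance = "example")
#' @export
predication_corpus <- function(records = NULL, provenance = "", validate = TRUE) {
  if (is.null(records) || nrow(as.data.frame(records)) == 0L) {
    records <- as.data.frame(
      stats::setNames(rep(list(character()), length(PRED_COLS)), PRED_COLS)
    )
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"subject_cui" %in% names(records)) records$subject_cui <- NA_character_
  if (!"object_cui" %in% names(records)) records$object_cui <- NA_character_
  missing_cols <- setdiff(PRED_COLS, names(records))
  if (length(missing_cols)) {
    stop_validation(sprintf(
      "predication records lack required columns: %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  records <- records[, PRED_COLS]
  for (col in PRED_COLS) records[[col]] <- as.character(records[[col]])
  rownames(records) <- NULL
  if (validate && nrow(records)) {
    problems <- validate_predications(records)
    if (length(problems)) {
      stop_validation(paste(
        c("invalid predication records:", problems), collapse = "\n  "
      ))
    }
  }
  structure(records,
    provenance = provenance,
    class = c("predication_corpus", "data.frame")
  )
}

# Returns a character vector of invariant violations (empty when clean).
validate_predications <- function(records) {
  problems <- character()
  bad <- function(idx, what) {
    if (any(idx)) {
      sprintf("%s (records %s)", what,
              paste(utils::head(which(idx), 5L), collapse = ", "))
    } else NULL
  }
  pred <- records$predicate
  problems <- c(problems,
    bad(is.na(pred) | !nzchar(pred), "empty predicate"),
    bad(grepl("|", pred, fixed = TRUE), "predicate contains field delimiter '|'")
  )
  for (side in c("subject", "object")) {
    st <- records[[paste0(side, "_semtype")]]
    nm <- records[[paste0(side, "_name")]]
    problems <- c(problems,
      bad(is.na(st) | !grepl("^[a-z][a-z0-9]*$", st),
          sprintf("%s_semtype is not a non-empty lowercase token", side)),
      bad(is.na(nm) | !nzchar(nm), sprintf("empty %s_name", side)),
      bad(grepl("|", nm, fixed = TRUE),
          sprintf("%s_name contains field delimiter '|'", side))
    )
  }
  unlist(problems)
}

# Plain data.frame view (drops the corpus class so base methods apply).
as_plain_df <- function(x) {
  class(x) <- "data.frame"
  attr(x, "provenance") <- NULL
  attr(x, "n_malformed") <- NULL
  x
}

#' @export
print.predication_corpus <- function(x, ...) {
  cat(sprintf(
    "<predication_corpus> %d record(s), %d unique predicate(s)%s\n",
    nrow(x), length(unique(x$predicate)),
    if (nzchar(attr(x, "provenance") %||% "")) {
      sprintf(" [%s]", attr(x, "provenance"))
    } else ""
  ))
  if (nrow(x)) print(utils::head(as_plain_df(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

# Subsetting keeps the class and provenance.
#' @export
`[.predication_corpus` <- function(x, i, ...) {
  out <- as_plain_df(x)[i, , drop = FALSE]
  predication_corpus(out, provenance = attr(x, "provenance") %||% "",
                     validate = FALSE)
}

corpus_provenance <- function(x) attr(x, "provenance") %||% ""

#' Construct a predicate count table
#'
#' Maps each predicate to its occurrence count over some restriction of a
#' corpus (for example, all predications containing a given seed topic).
#' Count tables back the background ("all points of view") distribution Q of
#' the divergence metric for users who cannot share full background corpora.
#'
#' @param counts Named non-negative integer vector (names are predicates),
#'   or a two-column data frame `predicate`, `count`.
#' @param restriction Free-text description of the subset counted.
#' @return An object of class `predicate_count_table`.
#' @export
predicate_count_table <- function(counts = integer(), restriction = "") {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(counts[[2L]], as.character(counts[[1L]]))
  }
  if (length(counts)) counts <- counts[order(names(counts), method = "radix")]
  storage.mode(counts) <- "double"
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      stop_validation("predicate count table requires named counts")
    }
    if (anyDuplicated(names(counts))) {
      stop_validation("duplicate predicates in count table")
    }
    if (any(counts < 1) || any(counts != floor(counts))) {
      stop_validation("predicate counts must be positive integers")
    }
  }
  structure(list(counts = counts, restriction = restriction),
            class = "predicate_count_table")
}

#' @export
print.predicate_count_table <- function(x, ...) {
  cat(sprintf("<predicate_count_table> %d predicate(s), total %d%s\n",
              length(x$counts), as.integer(sum(x$counts)),
              if (nzchar(x$restriction)) sprintf(" [%s]", x$restriction) else ""))
  if (length(x$counts)) {
    print(utils::head(sort(x$counts, decreasing = TRUE), 10L))
  }
  invisible(x)
}

#' Tally predicate occurrences in a corpus
#'
#' @param corpus A `predication_corpus`.
#' @param restriction Label recorded on the resulting table; defaults to the
#'   corpus provenance.
#' @return A `predicate_count_table`; the counts sum to `nrow(corpus)`.
#' @export
predicate_counts <- function(corpus, restriction = NULL) {
  if (is.null(restriction)) restriction <- corpus_provenance(corpus)
  if (!nrow(corpus)) {
    return(predicate_count_table(integer(), restriction = restriction))
  }
  tab <- table(corpus$predicate)
  predicate_count_table(stats::setNames(as.integer(tab), names(tab)),
                        restriction = restriction)
}

# Row-wise match of `concept` against a record argument: case-insensitive
# exact name equality, or exact CUI equality when the record carries a CUI.
concept_matches <- function(names, cuis, concept) {
  hit <- tolower(names) == tolower(concept)
  has_cui <- !is.na(cuis) & nzchar(cuis)
  hit | (has_cui & cuis == concept)
}

record_has_concept <- function(corpus, concept) {
  concept_matches(corpus$subject_name, corpus$subject_cui, concept) |
    concept_matches(corpus$object_name, corpus$object_cui, concept)
}

#' Restrict a corpus to predications mentioning a concept
#'
#' Keeps the records in which `concept` appears as the subject or the object
#' argument. Matching is case-insensitive exact equality on the argument
#' name; when records carry concept identifiers (CUIs), an exact CUI match
#' also selects the record, so synonymous surface names that share a CUI can
#' be retrieved by identifier.
#'
#' @param corpus A `predication_corpus`.
#' @param concept Concept name (or CUI) to match; must be non-empty.
#' @param negate Return the complement instead (records *not* mentioning the
#'   concept)? Default `FALSE`.
#' @return A `predication_corpus` with order preserved.
#' @export
filter_by_concept <- function(corpus, concept, negate = FALSE) {
  if (!nzchar(concept)) stop_validation("concept must be non-empty")
  if (!nrow(corpus)) return(corpus)
  hit <- record_has_concept(corpus, concept)
  corpus[if (negate) !hit else hit, ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validation errors carry a dedicated condition class so the CLI can map
# them to exit code 2 (user input) rather than 1 (internal).
stop_validation <- function(msg, call. = FALSE) {
  stop(structure(
    class = c("combosum_validation_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}
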