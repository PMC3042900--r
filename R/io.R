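# Readers and writers for the pipe-delimited predication dialect and the
# tab-separated side tables (predicate counts, normalization, validity,
# reference standard).
#
# Dialect: one predication per line,
#   citation_id|subject_name|[subject_cui|]subject_semtype|PREDICATE|object_name|[object_cui|]object_semtype
# i.e. 6 fields without CUIs or 8 fields with them; '#' starts a comment
# line; blank lines are ignored; UTF-8.

#' Read a predication file
#'
#' Parses the pipe-delimited predication dialect (6 fields per line, or 8
#' when concept identifiers are present). Comment lines starting with `#`
#' and blank lines are skipped. An empty file yields an empty corpus.
#'
#' @param source Path to a file, or a character vector of lines.
#' @param strict If `TRUE` (default) any malformed line aborts with an error
#'   naming the line number; if `FALSE`, malformed lines are counted, warned
#'   about, and skipped.
#' @param provenance Label for the resulting corpus; defaults to the path.
#' @return A `predication_corpus`; the number of skipped lines (lax mode) is
#'   available as `attr(x, "n_malformed")`.
#' @export
read_predications <- function(source, strict = TRUE, provenance = NULL) {
  if (length(source) == 1L && file.exists(source)) {
    lines <- readLines(source, encoding = "UTF-8", warn = FALSE)
    if (is.null(provenance)) provenance <- source
  } else {
    lines <- as.character(source)
    if (is.null(provenance)) provenance <- "<lines>"
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) {
    out <- predication_corpus(provenance = provenance)
    attr(out, "n_malformed") <- 0L
    return(out)
  }
  parts <- strsplit(lines[idx], "|", fixed = TRUE)
  nf <- lengths(parts)
  ok <- nf == 6L | nf == 8L
  rows <- lapply(seq_along(parts), function(i) {
    if (!ok[i]) return(NULL)
    f <- trimws(parts[[i]])
    if (nf[i] == 6L) {
      c(f[1L], f[2L], NA_character_, f[3L], f[4L], f[5L], NA_character_, f[6L])
    } else {
      c(f[1L], f[2L], f[3L], f[4L], f[5L], f[6L], f[7L], f[8L])
    }
  })
  df <- as.data.frame(
    stats::setNames(
      lapply(seq_along(PRED_COLS), function(j) {
        vapply(rows[ok], `[[`, character(1L), j)
      }),
      PRED_COLS
    )
  )
  bad_field <- if (nrow(df)) validate_per_record(df) else logical(0)
  malformed_lines <- sort(c(idx[!ok], idx[ok][bad_field]))
  if (length(malformed_lines)) {
    if (strict) {
      stop_validation(sprintf(
        "malformed predication line(s) at line %s of %s",
        paste(utils::head(malformed_lines, 5L), collapse = ", "), provenance
      ))
    }
    warning(sprintf("skipped %d malformed line(s) in %s",
                    length(malformed_lines), provenance))
    df <- df[!bad_field, , drop = FALSE]
  }
  out <- predication_corpus(df, provenance = provenance, validate = FALSE)
  attr(out, "n_malformed") <- length(malformed_lines)
  out
}

# Per-record invariant check used to reject malformed lines.
validate_per_record <- function(df) {
  bad <- !nzchar(df$predicate) |
    !grepl("^[a-z][a-z0-9]*$", df$subject_semtype) |
    !grepl("^[a-z][a-z0-9]*$", df$object_semtype) |
    !nzchar(df$subject_name) | !nzchar(df$object_name)
  bad
}

#' Write a predication file
#'
#' Emits the same dialect [read_predications()] accepts. Records whose CUI
#' fields are both absent are written as 6-field lines; any record carrying
#' a CUI is written as an 8-field line (absent CUI rendered as the empty
#' field). Output is deterministic for a given corpus, so write-then-read
#' round-trips reproduce the record sequence exactly.
#'
#' @param corpus A `predication_corpus`.
#' @param sink File path, or `NULL` to return the lines invisibly.
#' @return Invisibly, the character vector of lines written.
#' @export
write_predications <- function(corpus, sink = NULL) {
  lines <- format_predication_lines(corpus)
  if (!is.null(sink)) {
    con <- tryCatch(file(sink, open = "wb"),
                    error = function(e) stop(sprintf(
                      "cannot open '%s' for writing: %s", sink, conditionMessage(e)
                    ), call. = FALSE))
    on.exit(close(con))
    writeLines(lines, con, useBytes = TRUE)
  }
  invisible(lines)
}

format_predication_lines <- function(corpus) {
  if (!nrow(corpus)) return(character())
  has_cui <- (!is.na(corpus$subject_cui) & nzchar(corpus$subject_cui)) |
    (!is.na(corpus$object_cui) & nzchar(corpus$object_cui))
  blank <- function(x) ifelse(is.na(x), "", x)
  ifelse(
    has_cui,
    paste(corpus$citation_id, corpus$subject_name, blank(corpus$subject_cui),
          corpus$subject_semtype, corpus$predicate, corpus$object_name,
          blank(corpus$object_cui), corpus$object_semtype, sep = "|"),
    paste(corpus$citation_id, corpus$subject_name, corpus$subject_semtype,
          corpus$predicate, corpus$object_name, corpus$object_semtype,
          sep = "|")
  )
}

#' Read a predicate count table
#'
#' Two-column tab-separated text: `predicate<TAB>count`, `#` comments.
#'
#' @param path File path.
#' @param restriction Restriction label; defaults to the path.
#' @return A `predicate_count_table`.
#' @export
read_count_table <- function(path, restriction = NULL) {
  if (is.null(restriction)) restriction <- path
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = c("predicate", "count"),
                          colClasses = c("character", "integer"),
                          blank.lines.skip = TRUE)
  predicate_count_table(stats::setNames(df$count, df$predicate),
                        restriction = restriction)
}

#' Write a predicate count table
#'
#' @param table A `predicate_count_table`.
#' @param path File path.
#' @export
write_count_table <- function(table, path) {
  lines <- c(
    if (nzchar(table$restriction)) sprintf("# restriction: %s", table$restriction),
    sprintf("%s\t%d", names(table$counts), as.integer(table$counts))
  )
  writeLines(lines, path)
  invisible(path)
}
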