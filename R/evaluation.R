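# Curation-task evaluation: extract genetic entities from salient
# predications, normalize their names to gene symbols via a user-supplied
# table, and score recall / precision / F against a reference standard.

#' Extract genetic entity names from predications
#'
#' Collects the unique argument names whose slot carries one of the entity
#' semantic types (both subject and object slots are inspected).
#'
#' @param predications A `predication_corpus` (typically salient output).
#' @param entity_semtypes Semantic-type codes counted as genetic entities;
#'   default `gngm` (Gene or Genome) and `aapp` (Amino Acid, Peptide, or
#'   Protein). Must be non-empty.
#' @return Sorted character vector of unique raw entity names.
#' @export
extract_entities <- function(predications, entity_semtypes = c("gngm", "aapp")) {
  if (!length(entity_semtypes)) {
    stop_validation("entity_semtypes must be non-empty")
  }
  if (!nrow(predications)) return(character())
  names <- c(
    predications$subject_name[predications$subject_semtype %in% entity_semtypes],
    predications$object_name[predications$object_semtype %in% entity_semtypes]
  )
  sort(unique(names), method = "radix")
}

#' Construct a name-normalization table
#'
#' Maps raw entity names (case-insensitive) to gene symbols. Raw names too
#' general to be attributed to a single gene map to the marker `"DISCARD"`
#' and produce no output symbol.
#'
#' @param mapping Named character vector: `names()` are raw entity names,
#'   values are gene symbols or `"DISCARD"`.
#' @return A `normalization_table`.
#' @export
normalization_table <- function(mapping = character()) {
  if (length(mapping)) {
    if (is.null(names(mapping)) || any(!nzchar(names(mapping)))) {
      stop_validation("normalization mapping requires non-empty raw names")
    }
    names(mapping) <- tolower(names(mapping))
    if (anyDuplicated(names(mapping))) {
      stop_validation("duplicate raw names in normalization table")
    }
  }
  structure(list(mapping = mapping), class = "normalization_table")
}

#' Read a normalization table
#'
#' Two-column tab-separated text: `raw name<TAB>symbol-or-DISCARD`,
#' `#` comments.
#'
#' @param path File path.
#' @return A `normalization_table`.
#' @export
read_normalization_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = c("raw", "symbol"),
                          colClasses = "character", blank.lines.skip = TRUE)
  normalization_table(stats::setNames(df$symbol, df$raw))
}

#' Normalize entity names to gene symbols
#'
#' @param names Raw entity names (a set; duplicates collapse).
#' @param table A [normalization_table()].
#' @param strict If `TRUE`, an unmapped name is an error listing the names;
#'   if `FALSE` (default), unmapped names are dropped with a warning.
#' @return Sorted character vector of unique gene symbols; DISCARD-mapped
#'   and unmapped names contribute nothing.
#' @export
normalize_entities <- function(names, table, strict = FALSE) {
  stopifnot(inherits(table, "normalization_table"))
  names <- unique(names)
  sym <- unname(table$mapping[tolower(names)])
  unmapped <- names[is.na(sym)]
  if (length(unmapped)) {
    msg <- sprintf("unmapped entity name(s): %s",
                   paste(sort(unmapped), collapse = "; "))
    if (strict) stop_validation(msg)
    warning(msg)
  }
  sort(unique(sym[!is.na(sym) & sym != "DISCARD"]), method = "radix")
}

# Floor-truncation guarded against floating-point noise immediately below
# a representable boundary (e.g. 61.999999999 from 0.62*100).
trunc_at <- function(x, digits) {
  floor(round(x * 10^digits, 9)) / 10^digits
}

#' Score asserted genes against a reference standard
#'
#' Implements the curation evaluation protocol: genes in the reference
#' standard count as true positives when asserted and false negatives when
#' missed; asserted genes outside the reference must carry an external
#' validity label (`"TP"` for genes whose curated annotations confirm
#' disease involvement, `"FP"` otherwise), since that judgment is a manual
#' curation decision, never computed here.
#'
#' Reported percentages are floor-truncated integers (61.54% prints as 61%)
#' and the F-score is computed from the truncated two-decimal precision and
#' recall, then itself truncated to two decimals; the exact untruncated
#' values are reported alongside.
#'
#' @param asserted Character vector of asserted gene symbols (a set).
#' @param reference Character vector of reference-standard symbols.
#' @param validity Named character vector (`"TP"`/`"FP"`) covering every
#'   asserted symbol outside the reference; extra labels are ignored.
#' @return An `evaluation_result` list: `tp`, `fp`, `fn`, `recall_pct`,
#'   `precision_pct`, `f_score`, `exact_recall`, `exact_precision`,
#'   `exact_f`, plus the contributing symbol sets.
#' @export
evaluate_genes <- function(asserted, reference, validity = character()) {
  asserted <- unique(as.character(asserted))
  reference <- unique(as.character(reference))
  extras <- setdiff(asserted, reference)
  missing <- setdiff(extras, names(validity))
  if (length(missing)) {
    stop_validation(sprintf(
      "asserted gene(s) outside the reference lack validity labels: %s",
      paste(sort(missing), collapse = "; ")
    ))
  }
  lab <- validity[extras]
  if (length(lab) && !all(lab %in% c("TP", "FP"))) {
    stop_validation("validity labels must be 'TP' or 'FP'")
  }
  tp_ref <- intersect(asserted, reference)
  tp_extra <- extras[lab == "TP"]
  fp_set <- extras[lab == "FP"]
  fn_set <- setdiff(reference, asserted)

  tp <- length(tp_ref) + length(tp_extra)
  fp <- length(fp_set)
  fn <- length(fn_set)

  # Recall is judged against the reference standard alone (reference genes
  # recovered over reference size); precision takes the additional
  # curation-validated true positives into account. The two tallies use
  # different TP sets by design.
  exact_recall <- if (length(tp_ref) + fn > 0) {
    length(tp_ref) / (length(tp_ref) + fn)
  } else NA_real_
  exact_precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  exact_f <- if (!is.na(exact_recall) && !is.na(exact_precision) &&
                 (exact_recall + exact_precision) > 0) {
    2 * exact_precision * exact_recall / (exact_precision + exact_recall)
  } else NA_real_

  recall_pct <- if (is.na(exact_recall)) NA_integer_ else
    as.integer(trunc_at(exact_recall * 100, 0))
  precision_pct <- if (is.na(exact_precision)) NA_integer_ else
    as.integer(trunc_at(exact_precision * 100, 0))
  f_score <- if (is.na(recall_pct) || is.na(precision_pct) ||
                 (recall_pct + precision_pct) == 0L) NA_real_ else {
    r2 <- recall_pct / 100
    p2 <- precision_pct / 100
    trunc_at(2 * p2 * r2 / (p2 + r2), 2)
  }

  structure(
    list(tp = tp, fp = fp, fn = fn,
         recall_pct = recall_pct, precision_pct = precision_pct,
         f_score = f_score,
         exact_recall = exact_recall, exact_precision = exact_precision,
         exact_f = exact_f,
         tp_reference = sort(tp_ref), tp_additional = sort(tp_extra),
         fp_genes = sort(fp_set), fn_genes = sort(fn_set)),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  fmt_pct <- function(p) if (is.na(p)) "undefined" else sprintf("%d%%", p)
  cat("<evaluation_result>\n")
  cat(sprintf("  TP %d (reference %d + additional %d)   FP %d   FN %d\n",
              x$tp, length(x$tp_reference), length(x$tp_additional),
              x$fp, x$fn))
  cat(sprintf("  Recall    %s  (exact %.4f)\n", fmt_pct(x$recall_pct),
              x$exact_recall))
  cat(sprintf("  Precision %s  (exact %s)\n", fmt_pct(x$precision_pct),
              if (is.na(x$exact_precision)) "undefined" else
                sprintf("%.4f", x$exact_precision)))
  cat(sprintf("  F-score   %s  (exact %s)\n",
              if (is.na(x$f_score)) "undefined" else sprintf("%.2f", x$f_score),
              if (is.na(x$exact_f)) "undefined" else sprintf("%.4f", x$exact_f)))
  invisible(x)
}

#' Read a reference standard (one gene symbol per line)
#'
#' @param path File path; `#` comments and blank lines ignored.
#' @return Character vector of symbols.
#' @export
read_reference_standard <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Read validity labels (symbol<TAB>TP|FP)
#'
#' @param path File path.
#' @return Named character vector of `"TP"`/`"FP"` labels.
#' @export
read_validity_labels <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = c("symbol", "label"),
                          colClasses = "character", blank.lines.skip = TRUE)
  stats::setNames(df$label, df$symbol)
}

#' Write an evaluation report
#'
#' JSON with the tallies, truncated and exact metrics, and the contributing
#' gene sets.
#'
#' @param result An `evaluation_result`.
#' @param path File path.
#' @export
write_evaluation_report <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
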