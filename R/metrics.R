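# Saliency metrics: per-predicate Kullback-Leibler divergence terms, RlogF
# semantic-type binding strength, PredScal vocabulary scaling, and their
# Combo composition applied to predication patterns.

#' Relative predicate frequencies
#'
#' Converts predicate counts into the discrete distribution the divergence
#' metric compares: each predicate's proportion of all predication instances
#' in the (restricted) corpus behind the counts.
#'
#' @param x A `predicate_count_table`, a `predication_corpus`, or a named
#'   numeric vector of counts.
#' @return A `predicate_distribution`: list with `rel_freq` (named
#'   proportions summing to 1, all positive) and `support_total`.
#' @export
predicate_distribution <- function(x) {
  if (inherits(x, "predication_corpus")) x <- predicate_counts(x)
  counts <- if (inherits(x, "predicate_count_table")) x$counts else x
  if (!length(counts) || sum(counts) <= 0) {
    stop_validation("cannot form a predicate distribution from empty counts")
  }
  if (any(counts <= 0)) {
    stop_validation("predicate distribution requires strictly positive counts")
  }
  structure(
    list(rel_freq = counts / sum(counts),
         support_total = as.integer(sum(counts))),
    class = "predicate_distribution"
  )
}

#' @export
print.predicate_distribution <- function(x, ...) {
  cat(sprintf("<predicate_distribution> %d predicate(s) over %d record(s)\n",
              length(x$rel_freq), x$support_total))
  print(round(sort(x$rel_freq, decreasing = TRUE), 4))
  invisible(x)
}

#' Per-predicate Kullback-Leibler divergence terms
#'
#' For each predicate shared by a foreground distribution P and a background
#' distribution Q, returns the term P(x) * log2(P(x)/Q(x)) — that
#' predicate's contribution to D(P||Q). A large positive term marks a
#' predicate over-represented in the query-focused foreground relative to
#' the all-points-of-view background; negative terms (under-represented
#' predicates) are kept and simply rank low. Only shared predicates are
#' compared; the relative frequencies are computed over each corpus's full
#' predicate set and are *not* renormalized after the restriction to the
#' shared support.
#'
#' @param p Foreground [predicate_distribution()] (or anything coercible).
#' @param q Background distribution, likewise.
#' @return Named numeric vector of divergence terms in bits, one per shared
#'   predicate, in `p`'s predicate order.
#' @examples
#' p <- predicate_distribution(c(ASSOCIATED_WITH = 29, OTHER = 71))
#' q <- predicate_distribution(c(ASSOCIATED_WITH = 76, OTHER = 924))
#' round(kld_terms(p, q)[["ASSOCIATED_WITH"]], 4)  # 0.5603
#' @export
kld_terms <- function(p, q) {
  if (!inherits(p, "predicate_distribution")) p <- predicate_distribution(p)
  if (!inherits(q, "predicate_distribution")) q <- predicate_distribution(q)
  shared <- intersect(names(p$rel_freq), names(q$rel_freq))
  if (!length(shared)) {
    stop_validation("disjoint distributions: no shared predicates to compare")
  }
  px <- p$rel_freq[shared]
  qx <- q$rel_freq[shared]
  stats::setNames(px * log2(px / qx), shared)
}

#' RlogF binding strength of a semantic type to a predicate
#'
#' `log2(count) * (count / total)`: the conditional probability that a
#' predication with this predicate binds this (non-seed) semantic type,
#' weighted by the log of the binding's raw frequency. The log term flattens
#' the probability's dynamic range so that very strong bindings and very
#' frequent moderate bindings both score well. Zero iff `count == 1`.
#'
#' @param count Occurrences of the specific semantic type with the
#'   predicate (`1 <= count <= total`).
#' @param total Occurrences of all semantic types with the predicate.
#' @return The RlogF score (vectorized over `count`/`total`).
#' @examples
#' rlogf_score(107, 171)  # 4.218344839
#' @export
rlogf_score <- function(count, total) {
  if (any(count < 1) || any(total < 1) || any(count > total)) {
    stop_validation("rlogf_score requires 1 <= count <= total")
  }
  log2(count) * (count / total)
}

#' PredScal vocabulary scaling factor
#'
#' `1 / log2(c)` where `c` is the number of unique predicates in the
#' dataset. RlogF expresses a binding between one predicate and its semantic
#' types while the divergence terms express proportions across the whole
#' predicate vocabulary; PredScal shrinks RlogF by the (log) vocabulary size
#' so the two live on comparable scales. For the degenerate vocabularies
#' `c = 1` and `c = 2` the factor is defined as 1 (no scaling): `log2(1)`
#' would divide by zero, and scaling is meaningless with two predicates.
#'
#' @param c Count of unique predicates (positive integer, vectorized).
#' @return The scaling factor in (0, 1].
#' @examples
#' predscal(16)  # 0.25
#' @export
predscal <- function(c) {
  if (any(c < 1) || any(c != floor(c))) {
    stop_validation("predscal requires a positive integer predicate count")
  }
  ifelse(c <= 2, 1, 1 / log2(c))
}

#' Combo composite score
#'
#' The triple product `(rlogf * predscal) * kld_term` ranking a predication
#' pattern by how strongly its semantic type binds its predicate (RlogF,
#' scaled by PredScal) and how over-represented the predicate is in the
#' foreground (divergence term). The sign follows the divergence term.
#'
#' @param rlogf RlogF score.
#' @param predscal Scaling factor, must be positive.
#' @param kld_term Per-predicate divergence term.
#' @return The composite score (vectorized).
#' @export
combo_score <- function(rlogf, predscal, kld_term) {
  if (any(predscal <= 0)) stop_validation("predscal factor must be positive")
  (rlogf * predscal) * kld_term
}

# Per-record pattern keys: which argument slot carries the anchor (the seed
# concept, or the shared semantic type), and therefore which slot's semantic
# type is the "bound" non-anchor type RlogF assesses. When the anchor could
# match both slots the subject is taken as the anchor slot, so the bound
# type comes from the object; this keeps one key per record.
pattern_keys <- function(corpus, anchor, anchor_is = c("concept", "semtype")) {
  anchor_is <- match.arg(anchor_is)
  if (anchor_is == "concept") {
    on_subj <- concept_matches(corpus$subject_name, corpus$subject_cui, anchor)
    on_obj <- concept_matches(corpus$object_name, corpus$object_cui, anchor)
  } else {
    on_subj <- corpus$subject_semtype == anchor
    on_obj <- corpus$object_semtype == anchor
  }
  if (any(!on_subj & !on_obj)) {
    stop_validation(sprintf(
      "%d record(s) do not contain the stage anchor '%s'",
      sum(!on_subj & !on_obj), anchor
    ))
  }
  side <- ifelse(on_subj, "OBJECT", "SUBJECT")
  data.frame(
    predicate = corpus$predicate,
    bound_semtype = ifelse(side == "OBJECT",
                           corpus$object_semtype, corpus$subject_semtype),
    side = side,
    anchor_semtype = ifelse(side == "OBJECT",
                            corpus$subject_semtype, corpus$object_semtype),
    stringsAsFactors = FALSE
  )
}

# Deterministic pattern ordering: best score first, then larger support,
# then predicate, side (SUBJECT before OBJECT), bound type lexicographically.
order_patterns <- function(df, score_col) {
  order(-df[[score_col]], -df$count,
        df$predicate, df$side != "SUBJECT", df$bound_semtype,
        method = "radix")
}

#' Score predication patterns for one summarization stage
#'
#' Builds the foreground predicate distribution P from `foreground`, the
#' background distribution Q from `background_counts`, and computes for
#' every (predicate, bound semantic type, argument side) pattern its RlogF
#' (the bound-type count over the predicate's pooled non-anchor total),
#' the stage PredScal (from the foreground's unique-predicate count), the
#' predicate's divergence term, and the Combo product, ranked by descending
#' Combo under a deterministic tie rule.
#'
#' `foreground` must already be restricted to the stage's subset: the
#' seed-topic records for the relevance stage (anchor = the seed concept),
#' or the seed-free anchor-semtype records for the connectivity stage
#' (anchor = the shared semantic type). `background_counts` must be
#' restricted the same way. Predicates absent from the background cannot
#' receive a divergence term; their patterns are excluded with a warning.
#'
#' @param foreground A non-empty `predication_corpus` (the stage subset).
#' @param background_counts A `predicate_count_table` (or corpus) for the
#'   equally-restricted background.
#' @param anchor The seed concept name (relevance) or the shared semantic
#'   type code (connectivity).
#' @param anchor_is `"concept"` or `"semtype"`.
#' @return A data frame of class `pattern_scores` with columns `rank`,
#'   `predicate`, `bound_semtype`, `side`, `count`, `total`, `rlogf`,
#'   `predscal`, `kld_term`, `combo`. Attributes: `n_predicates` (the c of
#'   PredScal), `excluded_predicates`, `anchor`, `anchor_is`,
#'   `anchor_semtype` (modal semantic type observed on the anchor slot).
#' @export
score_patterns <- function(foreground, background_counts, anchor,
                           anchor_is = c("concept", "semtype")) {
  anchor_is <- match.arg(anchor_is)
  if (!nrow(foreground)) stop_validation("empty stage input: no foreground records")
  if (inherits(background_counts, "predication_corpus")) {
    background_counts <- predicate_counts(background_counts)
  }
  p <- predicate_distribution(foreground)
  q <- predicate_distribution(background_counts)
  kld <- kld_terms(p, q)
  excluded <- setdiff(names(p$rel_freq), names(q$rel_freq))
  if (length(excluded)) {
    warning(sprintf(
      "predicate(s) absent from background excluded from scoring: %s",
      paste(excluded, collapse = ", ")
    ))
  }

  keys <- pattern_keys(foreground, anchor, anchor_is)
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(keys))),
    by = keys[c("predicate", "bound_semtype", "side")], FUN = sum
  )
  pred_tot <- tapply(agg$count, agg$predicate, sum)
  agg$total <- as.integer(pred_tot[agg$predicate])

  n_pred <- length(unique(foreground$predicate))
  ps <- predscal(n_pred)

  agg <- agg[agg$predicate %in% names(kld), , drop = FALSE]
  agg$rlogf <- rlogf_score(agg$count, agg$total)
  agg$predscal <- ps
  agg$kld_term <- unname(kld[agg$predicate])
  agg$combo <- combo_score(agg$rlogf, agg$predscal, agg$kld_term)

  agg <- agg[order_patterns(agg, "combo"), , drop = FALSE]
  agg$rank <- seq_len(nrow(agg))
  agg <- agg[, c("rank", "predicate", "bound_semtype", "side", "count",
                 "total", "rlogf", "predscal", "kld_term", "combo")]
  rownames(agg) <- NULL

  anchor_st <- if (anchor_is == "semtype") anchor else {
    tab <- table(keys$anchor_semtype)
    names(tab)[which.max(tab)]
  }
  structure(agg,
    class = c("pattern_scores", "data.frame"),
    n_predicates = n_pred,
    excluded_predicates = excluded,
    anchor = anchor, anchor_is = anchor_is,
    anchor_semtype = anchor_st
  )
}

# "[gngm] ASSOCIATED_WITH neop" display convention: the bound (non-anchor)
# semantic type is bracketed; the anchor slot shows the anchor semtype.
pattern_label <- function(df, anchor_semtype) {
  ifelse(df$side == "SUBJECT",
         sprintf("[%s] %s %s", df$bound_semtype, df$predicate, anchor_semtype),
         sprintf("%s %s [%s]", anchor_semtype, df$predicate, df$bound_semtype))
}

#' @export
print.pattern_scores <- function(x, n = 10L, ...) {
  cat(sprintf(
    "<pattern_scores> %d pattern(s); c = %s predicate(s); anchor %s '%s'\n",
    nrow(x), attr(x, "n_predicates") %||% "?",
    attr(x, "anchor_is") %||% "?", attr(x, "anchor") %||% "?"
  ))
  if (nrow(x)) {
    shown <- utils::head(as.data.frame(x), n)
    shown$pattern <- pattern_label(shown, attr(x, "anchor_semtype") %||% "*")
    print(shown[, c("rank", "pattern", "count", "total", "rlogf",
                    "kld_term", "combo")], digits = 6)
  }
  if (length(attr(x, "excluded_predicates"))) {
    cat("excluded (absent from background):",
        paste(attr(x, "excluded_predicates"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a pattern score report
#'
#' Tab-separated: rank, side-annotated pattern (bound type bracketed),
#' count, total, rlogf, predscal, kld_term, combo.
#'
#' @param patterns A `pattern_scores` data frame.
#' @param path File path.
#' @export
write_pattern_report <- function(patterns, path) {
  df <- as.data.frame(patterns)
  out <- data.frame(
    rank = df$rank,
    pattern = pattern_label(df, attr(patterns, "anchor_semtype")),
    count = df$count, total = df$total,
    rlogf = df$rlogf, predscal = df$predscal,
    kld_term = df$kld_term, combo = df$combo
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
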