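# Four-filter summarization pipeline: Novelty -> Relevance -> Connectivity
# -> Saliency, with the Combo composite as the saliency mechanism and
# single-metric (divergence-only, RlogF-only) comparison arms.

#' Summarization configuration
#'
#' @param seed_concept The seed-topic concept name (or CUI) anchoring the
#'   summary, e.g. `"Carcinoma of bladder"`.
#' @param method Saliency mechanism: `"COMBO"` (the composite), `"KLD_ONLY"`
#'   (rank predicates by divergence term alone), or `"RLOGF_ONLY"` (rank
#'   predicate/semantic-type pairs by RlogF alone).
#' @param top_relevance_patterns Number of top relevance-stage patterns kept
#'   as salient (default 4).
#' @param top_connectivity_patterns Number of top connectivity-stage
#'   patterns kept (default 1).
#' @param novelty_stoplist Concept names considered too general to be
#'   informative; predications mentioning them are removed by the novelty
#'   filter. Default empty.
#' @param entity_semtypes Semantic-type codes treated as genetic entities at
#'   evaluation time (default `gngm`, `aapp`).
#' @return A `summary_config` list.
#' @export
summary_config <- function(seed_concept,
                           method = c("COMBO", "KLD_ONLY", "RLOGF_ONLY"),
                           top_relevance_patterns = 4L,
                           top_connectivity_patterns = 1L,
                           novelty_stoplist = character(),
                           entity_semtypes = c("gngm", "aapp")) {
  method <- match.arg(method)
  if (!nzchar(seed_concept)) stop_validation("seed_concept must be non-empty")
  if (top_relevance_patterns < 1L || top_connectivity_patterns < 1L) {
    stop_validation("top-k pattern counts must be >= 1")
  }
  structure(
    list(seed_concept = seed_concept, method = method,
         top_relevance_patterns = as.integer(top_relevance_patterns),
         top_connectivity_patterns = as.integer(top_connectivity_patterns),
         novelty_stoplist = as.character(novelty_stoplist),
         entity_semtypes = as.character(entity_semtypes)),
    class = "summary_config"
  )
}

#' Novelty filter
#'
#' Removes predications asserting generally-known facts by discarding every
#' record whose subject or object name is on a stoplist of overly general
#' concepts (case-insensitive). An empty stoplist is the identity.
#'
#' @param corpus A `predication_corpus`.
#' @param stoplist Character vector of concept names.
#' @return The filtered `predication_corpus`, order preserved.
#' @export
novelty_filter <- function(corpus, stoplist = character()) {
  if (!length(stoplist) || !nrow(corpus)) return(corpus)
  stop_lc <- tolower(stoplist)
  hit <- tolower(corpus$subject_name) %in% stop_lc |
    tolower(corpus$object_name) %in% stop_lc
  corpus[!hit, ]
}

#' Select the anchor semantic type for the connectivity stage
#'
#' From the selected top relevance patterns, picks the non-seed semantic
#' type occurring in the most patterns; ties are broken by the larger
#' summed score (the active arm's metric), then lexicographically.
#'
#' @param top_patterns A `pattern_scores` data frame (already cut to the
#'   selected top-k).
#' @param score_col Metric column used for tie-breaking: `"combo"`
#'   (default), `"kld_term"`, or `"rlogf"`.
#' @return A semantic-type code.
#' @export
select_anchor_semtype <- function(top_patterns, score_col = "combo") {
  df <- as.data.frame(top_patterns)
  if (!nrow(df)) stop_validation("cannot select an anchor from zero patterns")
  agg <- stats::aggregate(
    list(n = rep(1L, nrow(df)), score = df[[score_col]]),
    by = list(semtype = df$bound_semtype), FUN = sum
  )
  agg <- agg[order(-agg$n, -agg$score, agg$semtype, method = "radix"), ]
  agg$semtype[1L]
}

#' Connectivity-stage subset
#'
#' Records that do *not* mention the seed concept as either argument but do
#' carry the anchor semantic type on at least one argument slot.
#'
#' @param corpus A `predication_corpus`.
#' @param seed_concept The seed concept to exclude.
#' @param anchor Anchor semantic-type code (non-empty).
#' @return A `predication_corpus`.
#' @export
connectivity_subset <- function(corpus, seed_concept, anchor) {
  if (!nzchar(anchor)) stop_validation("anchor semantic type must be non-empty")
  if (!nrow(corpus)) return(corpus)
  no_seed <- !record_has_concept(corpus, seed_concept)
  has_anchor <- corpus$subject_semtype == anchor | corpus$object_semtype == anchor
  corpus[no_seed & has_anchor, ]
}

# --- stage helpers ------------------------------------------------------

# Background accessor: a corpus (restricted stagewise here) or a named list
# of pre-aggregated predicate_count_tables ($relevance, $connectivity).
stage_background <- function(background, stage, restrict) {
  if (inherits(background, "predication_corpus")) {
    restricted <- restrict(background)
    if (!nrow(restricted)) return(NULL)
    return(predicate_counts(restricted, restriction = stage))
  }
  if (inherits(background, "predicate_count_table")) {
    if (stage == "relevance") return(background)
    stop_validation(
      "background lacking the connectivity-stage restriction: supply a list with $relevance and $connectivity count tables"
    )
  }
  if (is.list(background)) {
    tab <- background[[stage]]
    if (is.null(tab)) {
      stop_validation(sprintf(
        "background lacking the %s-stage restriction (no $%s count table)",
        stage, stage
      ))
    }
    return(tab)
  }
  stop_validation("background must be a predication_corpus, a predicate_count_table, or a list of stage count tables")
}

# Selection of salient records for one stage under one method arm.
# Returns list(patterns = full ranked table, selected = top-k rows used for
# selection, salient = deduplicated-by-pattern record subset, note).
stage_saliency <- function(subset_corpus, bg_counts, anchor, anchor_is,
                           method, top_k) {
  pats <- score_patterns(subset_corpus, bg_counts, anchor, anchor_is)
  keys <- pattern_keys(subset_corpus, anchor, anchor_is)
  note <- NULL

  if (method == "COMBO") {
    score_col <- "combo"
    sel <- utils::head(pats, top_k)
    hit <- paste(keys$predicate, keys$bound_semtype, keys$side) %in%
      paste(sel$predicate, sel$bound_semtype, sel$side)
  } else if (method == "KLD_ONLY") {
    score_col <- "kld_term"
    # Predicate-level ranking: one row per predicate, divergence term only.
    preds <- unique(as.data.frame(pats)[c("predicate", "total", "kld_term")])
    preds <- preds[order(-preds$kld_term, -preds$total, preds$predicate,
                         method = "radix"), ]
    top_preds <- utils::head(preds$predicate, top_k)
    sel <- pats[pats$predicate %in% top_preds, , drop = FALSE]
    hit <- keys$predicate %in% top_preds
  } else { # RLOGF_ONLY
    score_col <- "rlogf"
    # Pool both argument sides per (predicate, bound semtype) pair, as the
    # pair ranking ignores which slot the bound type occupies.
    df <- as.data.frame(pats)
    pair <- stats::aggregate(list(count = df$count),
                             by = df[c("predicate", "bound_semtype")], FUN = sum)
    tot <- unique(df[c("predicate", "total")])
    pair$total <- tot$total[match(pair$predicate, tot$predicate)]
    pair$rlogf <- rlogf_score(pair$count, pair$total)
    pair <- pair[order(-pair$rlogf, -pair$count, pair$predicate,
                       pair$bound_semtype, method = "radix"), ]
    top_pairs <- utils::head(paste(pair$predicate, pair$bound_semtype), top_k)
    sel <- pats[paste(pats$predicate, pats$bound_semtype) %in% top_pairs, ,
                drop = FALSE]
    hit <- paste(keys$predicate, keys$bound_semtype) %in% top_pairs
  }

  if (nrow(pats) && all(abs(pats[[score_col]]) < 1e-12)) {
    note <- "all stage scores are zero; selection fell back to the tie rule"
  }
  list(patterns = pats, selected = sel,
       salient = subset_corpus[hit, ], score_col = score_col, note = note)
}

#' Run the four-filter summarization pipeline
#'
#' Applies, in order: the novelty filter (stoplist); the relevance stage
#' (restrict to predications mentioning the seed concept, score patterns
#' against the equally-restricted background, keep records matching the
#' top-k patterns); anchor selection (the non-seed semantic type most
#' prominent in the selected patterns); and the connectivity stage
#' (seed-free records carrying the anchor type, scored with the anchor type
#' playing the seed role, keeping records matching the top connectivity
#' patterns). The saliency mechanism is the configured method arm: the
#' Combo composite, the divergence term alone (predicate-level selection),
#' or RlogF alone (predicate/semantic-type pair selection).
#'
#' @param foreground A non-empty `predication_corpus`.
#' @param background A `predication_corpus` covering the same seed topic
#'   from all points of view (restricted per stage internally), or a named
#'   list of pre-aggregated `predicate_count_table`s with elements
#'   `$relevance` and `$connectivity`.
#' @param config A [summary_config()].
#' @return A `summary_result` list: `relevance_patterns`,
#'   `relevance_selected`, `relevance_salient`, `anchor_semtype`,
#'   `connectivity_patterns`, `connectivity_selected`,
#'   `connectivity_salient`, `config`, `log`.
#' @export
summarize_corpus <- function(foreground, background, config) {
  stopifnot(inherits(config, "summary_config"))
  if (!nrow(foreground)) stop_validation("foreground corpus is empty")
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  novel <- novelty_filter(foreground, config$novelty_stoplist)
  note("novelty: %d of %d record(s) retained", nrow(novel), nrow(foreground))

  bg_is_corpus <- inherits(background, "predication_corpus")
  bg_novel <- if (bg_is_corpus) {
    novelty_filter(background, config$novelty_stoplist)
  } else background

  rel_fore <- filter_by_concept(novel, config$seed_concept)
  if (!nrow(rel_fore)) {
    args <- unique(c(novel$subject_name, novel$object_name))
    dist <- utils::adist(tolower(config$seed_concept), tolower(args))
    nearest <- args[order(dist)][seq_len(min(5L, length(args)))]
    stop_validation(sprintf(
      "seed not found: no predication mentions '%s'; nearest argument names: %s",
      config$seed_concept, paste(nearest, collapse = "; ")
    ))
  }
  note("relevance: %d seed-topic record(s)", nrow(rel_fore))

  rel_bg <- stage_background(
    bg_novel, "relevance",
    function(bg) filter_by_concept(bg, config$seed_concept)
  )
  if (is.null(rel_bg)) {
    stop_validation("background contains no records mentioning the seed concept")
  }

  rel <- stage_saliency(rel_fore, rel_bg, config$seed_concept, "concept",
                        config$method, config$top_relevance_patterns)
  if (!is.null(rel$note)) note("relevance: %s", rel$note)
  note("relevance: %d pattern(s) scored, %d selected, %d salient record(s)",
       nrow(rel$patterns), nrow(rel$selected), nrow(rel$salient))

  anchor <- if (config$method == "KLD_ONLY") {
    # Most frequent non-seed semantic type among the salient records; ties
    # by the larger summed divergence of the records' predicates, then
    # lexicographically.
    if (!nrow(rel$salient)) {
      stop_validation("cannot select an anchor from zero salient records")
    }
    keys <- pattern_keys(rel$salient, config$seed_concept, "concept")
    kld_by_pred <- stats::setNames(rel$patterns$kld_term, rel$patterns$predicate)
    agg <- stats::aggregate(
      list(n = rep(1L, nrow(keys)), score = unname(kld_by_pred[keys$predicate])),
      by = list(semtype = keys$bound_semtype), FUN = sum
    )
    agg <- agg[order(-agg$n, -agg$score, agg$semtype, method = "radix"), ]
    agg$semtype[1L]
  } else {
    select_anchor_semtype(rel$selected, rel$score_col)
  }
  note("anchor semantic type: %s", anchor)

  conn_fore <- connectivity_subset(novel, config$seed_concept, anchor)
  empty_pats <- structure(
    data.frame(rank = integer(), predicate = character(),
               bound_semtype = character(), side = character(),
               count = integer(), total = integer(), rlogf = numeric(),
               predscal = numeric(), kld_term = numeric(), combo = numeric()),
    class = c("pattern_scores", "data.frame"),
    n_predicates = 0L, excluded_predicates = character(),
    anchor = anchor, anchor_is = "semtype", anchor_semtype = anchor
  )
  conn <- NULL
  if (!nrow(conn_fore)) {
    note("connectivity: no seed-free records carry the anchor type; stage skipped")
  } else {
    conn_bg <- stage_background(
      bg_novel, "connectivity",
      function(bg) connectivity_subset(bg, config$seed_concept, anchor)
    )
    if (is.null(conn_bg)) {
      note("connectivity: background has no records under the stage restriction; stage skipped")
    } else {
      conn <- stage_saliency(conn_fore, conn_bg, anchor, "semtype",
                             config$method, config$top_connectivity_patterns)
      if (!is.null(conn$note)) note("connectivity: %s", conn$note)
      note("connectivity: %d pattern(s) scored, %d selected, %d salient record(s)",
           nrow(conn$patterns), nrow(conn$selected), nrow(conn$salient))
    }
  }
  if (is.null(conn)) {
    conn <- list(patterns = empty_pats, selected = empty_pats,
                 salient = predication_corpus(provenance = "connectivity"))
  }

  structure(
    list(
      relevance_patterns = rel$patterns,
      relevance_selected = rel$selected,
      relevance_salient = rel$salient,
      anchor_semtype = anchor,
      connectivity_patterns = conn$patterns,
      connectivity_selected = conn$selected,
      connectivity_salient = conn$salient,
      config = config,
      log = log
    ),
    class = "summary_result"
  )
}

#' @export
print.summary_result <- function(x, ...) {
  cat(sprintf("<summary_result> method %s, seed '%s'\n",
              x$config$method, x$config$seed_concept))
  cat(sprintf("relevance: %d salient record(s) from %d pattern(s); anchor %s\n",
              nrow(x$relevance_salient), nrow(x$relevance_selected),
              x$anchor_semtype))
  cat(sprintf("connectivity: %d salient record(s) from %d pattern(s)\n",
              nrow(x$connectivity_salient), nrow(x$connectivity_selected)))
  invisible(x)
}

#' Write a summarization report
#'
#' JSON document with per-stage pattern tables and the salient predications
#' rendered in the predication file dialect, or a pair of tab-separated
#' pattern tables plus dialect files when `format = "tsv"`.
#'
#' @param result A `summary_result`.
#' @param path Output path (JSON) or path prefix (TSV mode writes
#'   `<path>.relevance.tsv`, `<path>.connectivity.tsv`,
#'   `<path>.relevance.psv`, `<path>.connectivity.psv`).
#' @param format `"json"` or `"tsv"`.
#' @return Invisibly, the path(s) written.
#' @export
write_summary_report <- function(result, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  pat_df <- function(p) {
    df <- as.data.frame(p)
    if (nrow(df)) df$pattern <- pattern_label(df, attr(p, "anchor_semtype"))
    df
  }
  if (format == "json") {
    doc <- list(
      method = result$config$method,
      seed_concept = result$config$seed_concept,
      anchor_semtype = result$anchor_semtype,
      relevance = list(
        patterns = pat_df(result$relevance_patterns),
        selected = pat_df(result$relevance_selected),
        salient = format_predication_lines(result$relevance_salient)
      ),
      connectivity = list(
        patterns = pat_df(result$connectivity_patterns),
        selected = pat_df(result$connectivity_selected),
        salient = format_predication_lines(result$connectivity_salient)
      ),
      log = result$log
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(path))
  }
  paths <- paste0(path, c(".relevance.tsv", ".connectivity.tsv",
                          ".relevance.psv", ".connectivity.psv"))
  write_pattern_report(result$relevance_patterns, paths[1L])
  write_pattern_report(result$connectivity_patterns, paths[2L])
  write_predications(result$relevance_salient, paths[3L])
  write_predications(result$connectivity_salient, paths[4L])
  invisible(paths)
}
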