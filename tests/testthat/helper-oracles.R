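# Independent brute-force oracles and small random-corpus builders used by
# the unit and property tests. The oracles recompute everything with plain
# loops and the direct formulas, sharing no code path with the package's
# vectorized implementations.

# Direct-formula divergence terms: p * log(p/q) / log(2), one predicate at
# a time over the shared support.
oracle_kld <- function(p_counts, q_counts) {
  p <- p_counts / sum(p_counts)
  q <- q_counts / sum(q_counts)
  shared <- intersect(names(p), names(q))
  out <- numeric(0)
  for (x in shared) {
    out[x] <- p[[x]] * log(p[[x]] / q[[x]]) / log(2)
  }
  out
}

# One-pass tally of predicate counts.
oracle_predicate_tally <- function(corpus) {
  out <- integer(0)
  for (i in seq_len(nrow(corpus))) {
    p <- corpus$predicate[i]
    out[p] <- (if (p %in% names(out)) out[[p]] else 0L) + 1L
  }
  out
}

# Record-by-record recount of pattern scores: for each record decide the
# anchor slot, tally (predicate, bound type, side), then apply the three
# formulas directly.
oracle_pattern_scores <- function(fg, bg_counts, anchor,
                                  anchor_is = c("concept", "semtype")) {
  anchor_is <- match.arg(anchor_is)
  counts <- list()
  totals <- integer(0)
  for (i in seq_len(nrow(fg))) {
    if (anchor_is == "concept") {
      on_subj <- tolower(fg$subject_name[i]) == tolower(anchor) ||
        (!is.na(fg$subject_cui[i]) && nzchar(fg$subject_cui[i]) &&
           fg$subject_cui[i] == anchor)
    } else {
      on_subj <- fg$subject_semtype[i] == anchor
    }
    if (on_subj) {
      side <- "OBJECT"; bound <- fg$object_semtype[i]
    } else {
      side <- "SUBJECT"; bound <- fg$subject_semtype[i]
    }
    key <- paste(fg$predicate[i], bound, side, sep = "\r")
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    p <- fg$predicate[i]
    totals[p] <- (if (p %in% names(totals)) totals[[p]] else 0L) + 1L
  }
  p_tally <- oracle_predicate_tally(fg)
  kld <- oracle_kld(p_tally, bg_counts$counts)
  cc <- length(unique(fg$predicate))
  ps <- if (cc <= 2) 1 else 1 / (log(cc) / log(2))
  rows <- list()
  for (key in names(counts)) {
    f <- strsplit(key, "\r", fixed = TRUE)[[1]]
    if (!f[1] %in% names(kld)) next
    cnt <- counts[[key]]
    tot <- totals[[f[1]]]
    rl <- (log(cnt) / log(2)) * (cnt / tot)
    rows[[key]] <- data.frame(
      predicate = f[1], bound_semtype = f[2], side = f[3],
      count = cnt, total = tot, rlogf = rl, predscal = ps,
      kld_term = kld[[f[1]]], combo = (rl * ps) * kld[[f[1]]],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, unname(rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A modest random corpus with a seed topic, several predicates and mixed
# semantic types; used by round-trip, partition and pipeline properties.
random_corpus_config <- function(seed, n = 400, seed_inclusion_rate = 0.6) {
  synth_config(
    n_records = n,
    predicate_weights = c(
      ASSOCIATED_WITH = 5, PREDISPOSES = 3, TREATS = 4, AFFECTS = 2,
      COEXISTS_WITH = 2, PART_OF = 1, ISA = 1
    ),
    semtype_pair_weights = c(
      "gngm|neop" = 4, "aapp|neop" = 2, "dsyn|neop" = 2,
      "topp|neop" = 2, "gngm|dsyn" = 1, "aapp|gngm" = 1
    ),
    seed_concept = "Carcinoma of bladder",
    seed_semtype = "neop",
    seed_inclusion_rate = seed_inclusion_rate,
    seed_side_rate = 0.8,
    entity_vocab = list(
      gngm = sprintf("G%02d gene", 1:15),
      aapp = sprintf("P%02d protein", 1:8),
      dsyn = c("Cystitis", "Hematuria", "Nephritis"),
      topp = c("Chemotherapy", "Cystectomy"),
      neop = c("Neoplasm progression", "Carcinoma, Transitional Cell")
    ),
    rng_seed = seed
  )
}

random_corpus <- function(seed, n = 400, seed_inclusion_rate = 0.6) {
  generate_corpus(random_corpus_config(seed, n, seed_inclusion_rate))
}

# Foreground/background pair with one strongly enriched
# (predicate, semantic type) pattern in the foreground; both corpora are
# pure relevance-stage material (every record mentions the seed).
planted_pair_configs <- function(seed, n = 5000) {
  vocab <- list(
    gngm = sprintf("G%02d gene", 1:20),
    aapp = sprintf("P%02d protein", 1:10),
    dsyn = c("Cystitis", "Hematuria", "Nephritis"),
    topp = c("Chemotherapy", "Cystectomy")
  )
  shared <- list(
    seed_concept = "Carcinoma of bladder", seed_semtype = "neop",
    seed_inclusion_rate = 1, seed_side_rate = 1, entity_vocab = vocab,
    n_records = n
  )
  fg <- do.call(synth_config, c(shared, list(
    predicate_weights = c(
      ASSOCIATED_WITH = 0.30, TREATS = 0.20, COEXISTS_WITH = 0.15,
      PART_OF = 0.15, AFFECTS = 0.10, ISA = 0.10
    ),
    semtype_pair_weights = list(
      ASSOCIATED_WITH = c("gngm|neop" = 0.6, "aapp|neop" = 0.2,
                          "dsyn|neop" = 0.2),
      .default = c("dsyn|neop" = 0.4, "aapp|neop" = 0.3, "topp|neop" = 0.3)
    ),
    rng_seed = seed
  )))
  bg <- do.call(synth_config, c(shared, list(
    predicate_weights = c(
      ASSOCIATED_WITH = 0.08, TREATS = 0.25, COEXISTS_WITH = 0.20,
      PART_OF = 0.17, AFFECTS = 0.15, ISA = 0.15
    ),
    semtype_pair_weights = c("dsyn|neop" = 0.4, "aapp|neop" = 0.3,
                             "gngm|neop" = 0.15, "topp|neop" = 0.15),
    rng_seed = seed + 1000000L
  )))
  list(foreground = fg, background = bg)
}
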