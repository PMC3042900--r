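# Synthetic predication corpora: a weighted-categorical generator for
# property-style testing, and deterministic fixtures reproducing the score
# and evaluation arithmetic of the bladder-cancer worked example.

#' Synthetic-corpus configuration
#'
#' Describes the statistical structure of a generated corpus: the predicate
#' distribution, the semantic-type pair distribution (optionally per
#' predicate), how often and on which side the seed topic appears, and the
#' name vocabulary per semantic type. The generator emulates the shape the
#' saliency metrics assume — a foreground whose predicate distribution is
#' skewed toward a point of view, over a seed topic, against a flatter
#' background.
#'
#' @param n_records Number of predications to draw.
#' @param predicate_weights Named positive weights, one per predicate.
#' @param semtype_pair_weights Named positive weights where each name is
#'   `"subject_semtype|object_semtype"`; or a named list of such vectors
#'   keyed by predicate (with optional key `".default"`) for per-predicate
#'   pair distributions.
#' @param seed_concept Seed topic name planted into records.
#' @param seed_semtype Semantic type of the seed topic (default `"neop"`).
#' @param seed_inclusion_rate Probability a record mentions the seed.
#' @param seed_side_rate Probability the seed occupies the object slot
#'   (vs the subject slot) when included. Default 1.
#' @param entity_vocab Named list: semantic-type code -> character vector of
#'   names to draw arguments from. Must cover every semtype used.
#' @param rng_seed Integer seed; identical configurations yield
#'   byte-identical corpora.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_records,
                         predicate_weights,
                         semtype_pair_weights,
                         seed_concept = "Carcinoma of bladder",
                         seed_semtype = "neop",
                         seed_inclusion_rate = 1,
                         seed_side_rate = 1,
                         entity_vocab = list(),
                         rng_seed = 1L) {
  problems <- character()
  if (n_records < 0) problems <- c(problems, "n_records must be >= 0")
  chk_weights <- function(w, what) {
    if (!length(w) || is.null(names(w)) || any(!nzchar(names(w))) ||
        any(w <= 0)) {
      sprintf("%s must be a non-empty named vector of positive weights", what)
    } else NULL
  }
  problems <- c(problems, chk_weights(predicate_weights, "predicate_weights"))
  pair_sets <- if (is.list(semtype_pair_weights)) semtype_pair_weights else
    list(.default = semtype_pair_weights)
  for (nm in names(pair_sets)) {
    problems <- c(problems, chk_weights(pair_sets[[nm]],
                                        sprintf("semtype_pair_weights[%s]", nm)))
  }
  if (!all(grepl("\\|", unlist(lapply(pair_sets, names))))) {
    problems <- c(problems,
                  "semtype pair names must be 'subject_semtype|object_semtype'")
  }
  if (seed_inclusion_rate < 0 || seed_inclusion_rate > 1) {
    problems <- c(problems, "seed_inclusion_rate must be in [0, 1]")
  }
  if (seed_side_rate < 0 || seed_side_rate > 1) {
    problems <- c(problems, "seed_side_rate must be in [0, 1]")
  }
  used_types <- unique(unlist(strsplit(unlist(lapply(pair_sets, names)), "|",
                                       fixed = TRUE)))
  uncovered <- setdiff(used_types, c(names(entity_vocab), seed_semtype))
  if (length(uncovered)) {
    problems <- c(problems, sprintf(
      "entity_vocab lacks name lists for semantic type(s): %s",
      paste(uncovered, collapse = ", ")
    ))
  }
  if (any(!lengths(entity_vocab))) {
    problems <- c(problems, "entity_vocab lists must be non-empty")
  }
  if (length(problems)) {
    stop_validation(paste(c("invalid synthetic-corpus config:", problems),
                          collapse = "\n  "))
  }
  structure(
    list(n_records = as.integer(n_records),
         predicate_weights = predicate_weights,
         semtype_pair_weights = pair_sets,
         seed_concept = seed_concept, seed_semtype = seed_semtype,
         seed_inclusion_rate = seed_inclusion_rate,
         seed_side_rate = seed_side_rate,
         entity_vocab = entity_vocab,
         rng_seed = as.integer(rng_seed)),
    class = "synth_config"
  )
}

# Runs expr under a local RNG stream so generation neither disturbs nor
# depends on the caller's RNG state.
with_local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic predication corpus
#'
#' Draws `n_records` predications: a predicate from the predicate weights, a
#' semantic-type pair from the (per-predicate) pair weights, argument names
#' uniformly from the per-type vocabularies, and — with the configured rate
#' and side — the seed topic overriding one argument slot. Identical
#' configurations (including `rng_seed`) produce identical corpora, and
#' empirical frequencies converge to the weights as `n_records` grows.
#'
#' @param config A [synth_config()].
#' @return A `predication_corpus`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_records
  if (n == 0L) return(predication_corpus(provenance = "synthetic"))
  with_local_rng(config$rng_seed, {
    pw <- config$predicate_weights
    predicate <- sample(names(pw), n, replace = TRUE, prob = pw)

    pick_pairs <- function(pred_name, k) {
      w <- config$semtype_pair_weights[[pred_name]] %||%
        config$semtype_pair_weights[[".default"]]
      if (is.null(w)) {
        stop_validation(sprintf(
          "no semantic-type pair weights for predicate %s and no .default",
          pred_name
        ))
      }
      sample(names(w), k, replace = TRUE, prob = w)
    }
    pairs <- character(n)
    for (pred_name in unique(predicate)) {
      idx <- predicate == pred_name
      pairs[idx] <- pick_pairs(pred_name, sum(idx))
    }
    st <- strsplit(pairs, "|", fixed = TRUE)
    subject_semtype <- vapply(st, `[[`, character(1L), 1L)
    object_semtype <- vapply(st, `[[`, character(1L), 2L)

    draw_name <- function(semtypes) {
      out <- character(length(semtypes))
      for (tp in unique(semtypes)) {
        idx <- semtypes == tp
        vocab <- config$entity_vocab[[tp]] %||% config$seed_concept
        out[idx] <- vocab[sample.int(length(vocab), sum(idx), replace = TRUE)]
      }
      out
    }
    subject_name <- draw_name(subject_semtype)
    object_name <- draw_name(object_semtype)

    has_seed <- stats::runif(n) < config$seed_inclusion_rate
    seed_on_object <- stats::runif(n) < config$seed_side_rate
    obj_seed <- has_seed & seed_on_object
    subj_seed <- has_seed & !seed_on_object
    object_name[obj_seed] <- config$seed_concept
    object_semtype[obj_seed] <- config$seed_semtype
    subject_name[subj_seed] <- config$seed_concept
    subject_semtype[subj_seed] <- config$seed_semtype

    predication_corpus(
      data.frame(
        citation_id = sprintf("SYN%07d", seq_len(n)),
        subject_name = subject_name, subject_semtype = subject_semtype,
        predicate = predicate,
        object_name = object_name, object_semtype = object_semtype
      ),
      provenance = sprintf("synthetic (seed %d)", config$rng_seed)
    )
  })
}

#' Worked-example divergence fixture
#'
#' The smallest integer count tables that exactly realize the worked
#' example's relative frequencies: a foreground in which ASSOCIATED_WITH has
#' relative frequency 29/100 = 0.290 and a background in which it has
#' 76/1000 = 0.076, so its divergence term is 0.5603 at four decimals.
#'
#' @return List with `foreground` and `background`
#'   `predicate_count_table`s.
#' @export
fixture_kld_example <- function() {
  list(
    foreground = predicate_count_table(
      c(ASSOCIATED_WITH = 29, OTHER = 71),
      restriction = "seed-topic predications, point-of-view query"
    ),
    background = predicate_count_table(
      c(ASSOCIATED_WITH = 76, OTHER = 924),
      restriction = "seed-topic predications, all points of view"
    )
  )
}

# --- deterministic record builders --------------------------------------

# n records of one pattern; subject/object names cycled from vectors.
build_records <- function(n, subj_names, subj_st, pred, obj_names, obj_st) {
  data.frame(
    citation_id = NA_character_,
    subject_name = rep_len(subj_names, n), subject_semtype = subj_st,
    predicate = pred,
    object_name = rep_len(obj_names, n), object_semtype = obj_st,
    stringsAsFactors = FALSE
  )
}

seal_corpus <- function(rows, provenance, id_start = 1L) {
  rows <- lapply(rows, function(df) {
    if (!"subject_cui" %in% names(df)) df$subject_cui <- NA_character_
    if (!"object_cui" %in% names(df)) df$object_cui <- NA_character_
    df[, PRED_COLS]
  })
  df <- do.call(rbind, rows)
  df$citation_id <- sprintf("FIX%07d", seq.int(id_start, length.out = nrow(df)))
  predication_corpus(df, provenance = provenance)
}

SEED_BLADDER <- "Carcinoma of bladder"

# Relevance-stage composition (seed-topic records, 16 unique predicates).
# ASSOCIATED_WITH carries 171 non-seed slots of which gngm fills 107, so
# RlogF(gngm, ASSOCIATED_WITH) = log2(107)*(107/171) and PredScal = 1/4.
relevance_composition <- function() {
  list(
    ASSOCIATED_WITH = c(gngm = 107, aapp = 40, bpoc = 15, celc = 9),
    PREDISPOSES     = c(gngm = 32, aapp = 17, dsyn = 9),
    TREATS          = c(topp = 12),
    ISA             = c(neop = 11),
    AFFECTS         = c(gngm = 8),
    PART_OF         = c(gngm = 7),
    CAUSES          = c(hzca = 6),
    COEXISTS_WITH   = c(dsyn = 6),
    INTERACTS_WITH  = c(gngm = 5),
    INHIBITS        = c(phsu = 5),
    STIMULATES      = c(phsu = 4),
    AUGMENTS        = c(celf = 4),
    DISRUPTS        = c(celf = 3),
    LOCATION_OF     = c(tisu = 3),
    PROCESS_OF      = c(humn = 3),
    DIAGNOSES       = c(diap = 2)
  )
}

# Generic per-semtype name pools for fixture slots that carry no planted
# gene identity.
fixture_name_pool <- function(tp, k) {
  pools <- list(
    gngm = sprintf("GENERIC%02d gene", 1:12),
    aapp = sprintf("GENERIC%02d protein", 1:12),
    bpoc = c("Urinary bladder", "Bladder neck", "Urothelium"),
    celc = c("Transitional cell", "Urothelial cell"),
    dsyn = c("Cystitis", "Hematuria", "Schistosomiasis"),
    topp = c("Chemotherapy regimen", "Radical cystectomy"),
    neop = c("Carcinoma, Transitional Cell", "Neoplasm progression"),
    hzca = c("Tobacco smoke", "Aromatic amines"),
    phsu = c("Gemcitabine", "Cisplatin"),
    celf = c("Cell proliferation", "Apoptosis"),
    tisu = c("Bladder wall", "Mucous membrane"),
    humn = c("Patients", "Study subjects"),
    diap = c("Cystoscopy", "Urinalysis")
  )
  rep_len(pools[[tp]] %||% sprintf("%s concept", toupper(tp)), k)
}

#' Relevance-stage worked-example fixture
#'
#' A deterministic seed-topic corpus with exactly 16 unique predicates in
#' which the semantic type `gngm` binds the predicate ASSOCIATED_WITH in
#' 107 of its 171 non-seed argument slots: on this corpus the RlogF of
#' (gngm, ASSOCIATED_WITH) is log2(107)*(107/171) = 4.218344839 and the
#' PredScal factor is 1/log2(16) = 0.25.
#'
#' @param gene_names Optional per-semtype name lists overriding the generic
#'   pools (used by the full-pipeline fixture to plant gene identities).
#' @return A `predication_corpus` of 308 seed-topic records.
#' @export
fixture_relevance <- function(gene_names = NULL) {
  comp <- relevance_composition()
  rows <- list()
  for (pred in names(comp)) {
    for (tp in names(comp[[pred]])) {
      n <- comp[[pred]][[tp]]
      nm <- (gene_names[[pred]][[tp]] %||% fixture_name_pool(tp, n))
      rows[[length(rows) + 1L]] <- if (pred == "PROCESS_OF") {
        # Seed as the subject ("seed PROCESS_OF patients"): exercises
        # OBJECT-side bound types.
        build_records(n, SEED_BLADDER, "neop", pred, nm, tp)
      } else {
        build_records(n, nm, tp, pred, SEED_BLADDER, "neop")
      }
    }
  }
  seal_corpus(rows, "fixture: relevance worked example")
}

# Background composition over the same seed topic (flatter, treatment-heavy
# point-of-view mixture), total 1000 records.
background_relevance_composition <- function() {
  c(ASSOCIATED_WITH = 150, PREDISPOSES = 20, TREATS = 320, ISA = 120,
    AFFECTS = 60, PART_OF = 60, CAUSES = 50, COEXISTS_WITH = 50,
    INTERACTS_WITH = 30, INHIBITS = 25, STIMULATES = 20, AUGMENTS = 20,
    DISRUPTS = 20, LOCATION_OF = 25, PROCESS_OF = 20, DIAGNOSES = 10)
}

# Connectivity-stage foreground (seed-free, gngm-anchored) and background.
connectivity_composition <- function() {
  list(
    foreground = list(
      ASSOCIATED_WITH = list(n = 60, obj = "neop"),
      PART_OF = list(n = 10, obj = "bpoc"),
      INTERACTS_WITH = list(n = 8, obj = "aapp"),
      STIMULATES = list(n = 4, obj = "celf")
    ),
    background = c(ASSOCIATED_WITH = 100, PART_OF = 80,
                   INTERACTS_WITH = 60, STIMULATES = 40)
  )
}

#' Full-pipeline evaluation fixture
#'
#' A deterministic bundle exercising the whole pipeline. By construction
#' the Combo relevance stage selects, in order, the patterns
#' (gngm, ASSOCIATED_WITH), (gngm, PREDISPOSES), (aapp, ASSOCIATED_WITH),
#' (aapp, PREDISPOSES); the anchor type is gngm; and the top connectivity
#' pattern is gngm ASSOCIATED_WITH \[neop\]. The gene names planted in the
#' salient records normalize to 74 symbols: 8 reference-standard genes
#' (13-gene reference, so 5 are missed) and 66 additional synthetic symbols
#' labelled 52 TP / 14 FP, so the evaluation yields TP=60, FP=14, FN=5 —
#' recall 61%, precision 81%, F 0.69 under the truncation policy.
#'
#' The reference standard is the 13-gene curated bladder-cancer list; the
#' additional symbols (`BCG01`..`BCG66`), their validity labels and the
#' normalization table are synthetic stand-ins for manual curation inputs.
#'
#' @return List with `foreground`, `background` (predication corpora),
#'   `reference` (13 symbols), `validity` (named TP/FP labels),
#'   `normalization` (a `normalization_table`), and a ready-made `config`
#'   ([summary_config()] for the Combo arm, including the novelty
#'   stoplist).
#' @export
fixture_full_pipeline <- function() {
  reference <- c("FGFR3", "XPD", "RAG1", "TP53", "MTCYB", "HRAS", "NAT2",
                 "RB1", "TSC1", "ATM", "TGFB1", "MDM2", "ERBB3")
  ref_hit <- c("FGFR3", "XPD", "TP53", "HRAS", "NAT2", "RB1", "TSC1", "MDM2")
  ref_miss <- setdiff(reference, ref_hit)
  extra <- sprintf("BCG%02d", 1:66)

  gene_raw <- function(sym) paste(sym, "gene")
  prot_raw <- function(sym) paste(sym, "protein")

  # Planted identities for the salient relevance patterns.
  plant <- list(
    ASSOCIATED_WITH = list(
      gngm = gene_raw(c(ref_hit, extra[1:30])),
      aapp = c(prot_raw(extra[41:55]), "Proteins")  # "Proteins" -> DISCARD
    ),
    PREDISPOSES = list(
      gngm = gene_raw(extra[31:40]),
      aapp = prot_raw(extra[56:60])
    ),
    # Missed reference genes live only in non-salient patterns.
    AFFECTS = list(gngm = gene_raw(ref_miss)),
    PART_OF = list(gngm = gene_raw(ref_miss)),
    INTERACTS_WITH = list(gngm = gene_raw(ref_miss))
  )
  relevance <- fixture_relevance(gene_names = plant)

  # Overly general assertions the novelty stoplist removes.
  general <- build_records(3, SEED_BLADDER, "neop", "ISA", "Neoplasms", "neop")

  conn <- connectivity_composition()
  conn_rows <- list()
  conn_names <- list(
    ASSOCIATED_WITH = gene_raw(c(extra[61:66], "FGFR3", "TP53")),
    PART_OF = gene_raw(ref_miss),
    INTERACTS_WITH = gene_raw(ref_miss),
    STIMULATES = gene_raw("BCG01")
  )
  for (pred in names(conn$foreground)) {
    spec <- conn$foreground[[pred]]
    conn_rows[[pred]] <- build_records(
      spec$n, conn_names[[pred]], "gngm", pred,
      fixture_name_pool(spec$obj, spec$n), spec$obj
    )
  }

  foreground <- seal_corpus(
    c(list(as_plain_df(relevance), general), conn_rows),
    "fixture: full pipeline foreground"
  )

  # Background: seed-topic records with the flat predicate mixture, plus
  # seed-free gngm records for the connectivity restriction.
  bg_rel <- background_relevance_composition()
  bg_rows <- lapply(names(bg_rel), function(pred) {
    build_records(bg_rel[[pred]], fixture_name_pool("gngm", bg_rel[[pred]]),
                  "gngm", pred, SEED_BLADDER, "neop")
  })
  bg_conn <- conn$background
  bg_rows <- c(bg_rows, lapply(names(bg_conn), function(pred) {
    build_records(bg_conn[[pred]], fixture_name_pool("gngm", bg_conn[[pred]]),
                  "gngm", pred, "Neoplasm progression", "neop")
  }))
  background <- seal_corpus(bg_rows, "fixture: full pipeline background",
                            id_start = 5000001L)

  asserted <- c(ref_hit, extra)
  validity <- stats::setNames(
    c(rep("TP", 52), rep("FP", 14)), extra
  )
  mapping <- c(
    stats::setNames(asserted, gene_raw(asserted)),
    stats::setNames(asserted, prot_raw(asserted)),
    stats::setNames(reference, gene_raw(reference))[paste(ref_miss, "gene")],
    Proteins = "DISCARD"
  )
  mapping <- mapping[!duplicated(tolower(names(mapping)))]

  list(
    foreground = foreground,
    background = background,
    reference = reference,
    validity = validity,
    normalization = normalization_table(mapping),
    config = summary_config(
      seed_concept = SEED_BLADDER, method = "COMBO",
      novelty_stoplist = "Neoplasms"
    )
  )
}
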