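# Four-filter pipeline: novelty, relevance, connectivity, saliency, and
# the three method arms.

test_that("the novelty stoplist removes general assertions and partitions", {
  corp <- read_predications(c(
    "1|Coronary Arteriosclerosis|dsyn|ISA|Vascular Diseases|dsyn",
    "2|Coronary Arteriosclerosis|dsyn|COEXISTS_WITH|Inflammation|patf"
  ))
  kept <- novelty_filter(corp, "Vascular Diseases")
  expect_equal(kept$citation_id, "2")
  expect_equal(as.data.frame(novelty_filter(corp, character())),
               as.data.frame(corp))

  for (seed in 41:44) {
    corp <- random_corpus(seed, n = 150)
    stop <- c("Cystitis", "Chemotherapy")
    kept <- novelty_filter(corp, stop)
    removed <- nrow(corp) - nrow(kept)
    manual <- sum(tolower(corp$subject_name) %in% tolower(stop) |
                    tolower(corp$object_name) %in% tolower(stop))
    expect_equal(removed, manual)
  }
})

test_that("anchor selection counts pattern membership with summed-score ties", {
  # two types each in two of the four top patterns; the summed composite
  # decides (gngm: 0.592531 + 0.205778 vs aapp: 0.152883 + 0.039868)
  top4 <- data.frame(
    predicate = c("ASSOCIATED_WITH", "PREDISPOSES",
                  "ASSOCIATED_WITH", "PREDISPOSES"),
    bound_semtype = c("gngm", "gngm", "aapp", "aapp"),
    side = "SUBJECT",
    count = c(107L, 32L, 40L, 17L),
    combo = c(0.592531, 0.205778, 0.152883, 0.039868)
  )
  expect_equal(select_anchor_semtype(top4), "gngm")

  expect_equal(select_anchor_semtype(top4[3, ]), "aapp")

  tie3 <- data.frame(
    predicate = c("A", "B", "C"), bound_semtype = c("zz", "mm", "aa"),
    side = "SUBJECT", count = 1L, combo = 0.5
  )
  expect_equal(select_anchor_semtype(tie3), "aa")

  expect_error(select_anchor_semtype(top4[0, ]), "zero patterns")
})

test_that("the connectivity subset excludes the seed and requires the anchor type", {
  corp <- read_predications(c(
    "1|FGFR3 gene|gngm|ASSOCIATED_WITH|Carcinoma of bladder|neop",
    "2|TP53 gene|gngm|ASSOCIATED_WITH|Neoplasm progression|neop",
    "3|Excision|topp|TREATS|Neoplasm progression|neop",
    "4|Carcinoma of bladder|neop|PROCESS_OF|Patients|humn"
  ))
  sub <- connectivity_subset(corp, "Carcinoma of bladder", "gngm")
  # record 1 is excluded although its subject is anchor-typed: it mentions
  # the seed; record 3 lacks the anchor type entirely
  expect_equal(sub$citation_id, "2")

  rel <- filter_by_concept(corp, "Carcinoma of bladder")
  expect_equal(nrow(merge(as.data.frame(sub), as.data.frame(rel))), 0L)
})

test_that("the full pipeline recovers the planted pattern ranking", {
  fx <- fixture_full_pipeline()
  res <- summarize_corpus(fx$foreground, fx$background, fx$config)

  sel <- as.data.frame(res$relevance_selected)
  expect_equal(sel$bound_semtype, c("gngm", "gngm", "aapp", "aapp"))
  expect_equal(sel$predicate, c("ASSOCIATED_WITH", "PREDISPOSES",
                                "ASSOCIATED_WITH", "PREDISPOSES"))
  expect_equal(res$anchor_semtype, "gngm")
  conn <- as.data.frame(res$connectivity_selected)
  expect_equal(conn$predicate, "ASSOCIATED_WITH")
  expect_equal(conn$bound_semtype, "neop")

  # stage containment and disjointness
  novel <- novelty_filter(fx$foreground, fx$config$novelty_stoplist)
  rel_pool <- filter_by_concept(novel, fx$config$seed_concept)
  expect_true(nrow(merge(as.data.frame(res$relevance_salient),
                         as.data.frame(rel_pool))) > 0)
  expect_equal(
    nrow(merge(unique(as.data.frame(res$relevance_salient)[-1]),
               unique(as.data.frame(res$connectivity_salient))[-1])),
    0L
  )
  # salient records all mention the seed (relevance) or avoid it while
  # carrying the anchor type (connectivity)
  expect_true(all(
    res$relevance_salient$subject_name == fx$config$seed_concept |
      res$relevance_salient$object_name == fx$config$seed_concept
  ))
  expect_true(all(
    res$connectivity_salient$subject_name != fx$config$seed_concept &
      res$connectivity_salient$object_name != fx$config$seed_concept
  ))
  expect_true(all(
    res$connectivity_salient$subject_semtype == "gngm" |
      res$connectivity_salient$object_semtype == "gngm"
  ))

  # determinism, including rank order
  res2 <- summarize_corpus(fx$foreground, fx$background, fx$config)
  expect_equal(res2, res)
})

test_that("an all-zero stage is flagged and falls back to the tie rule", {
  corp <- read_predications(c(
    "1|A gene|gngm|ASSOCIATED_WITH|Seed disease|neop",
    "2|B protein|aapp|ASSOCIATED_WITH|Seed disease|neop",
    "3|C drug|phsu|TREATS|Seed disease|neop"
  ))
  cfg <- summary_config("Seed disease", method = "COMBO",
                        top_relevance_patterns = 2L)
  res <- summarize_corpus(corp, corp, cfg)
  expect_true(all(abs(res$relevance_patterns$combo) < 1e-12))
  expect_true(any(grepl("tie rule", res$log)))
})

test_that("missing seeds and missing stage backgrounds raise validation errors", {
  corp <- read_predications("1|A gene|gngm|ASSOCIATED_WITH|B disease|neop")
  cfg <- summary_config("Unseen concept")
  expect_error(summarize_corpus(corp, corp, cfg), "seed not found")
  expect_error(summarize_corpus(corp, corp, cfg), "B disease")

  # pre-aggregated background without the connectivity table
  fx <- fixture_full_pipeline()
  bg_rel <- predicate_counts(filter_by_concept(fx$background,
                                               "Carcinoma of bladder"))
  expect_error(
    summarize_corpus(fx$foreground, list(relevance = bg_rel), fx$config),
    "connectivity-stage restriction"
  )
  # with both stage tables the corpus- and table-mode pipelines agree
  bg_conn <- predicate_counts(connectivity_subset(
    fx$background, "Carcinoma of bladder", "gngm"
  ))
  res_tab <- summarize_corpus(fx$foreground,
                              list(relevance = bg_rel, connectivity = bg_conn),
                              fx$config)
  res_cor <- summarize_corpus(fx$foreground, fx$background, fx$config)
  expect_equal(as.data.frame(res_tab$relevance_patterns),
               as.data.frame(res_cor$relevance_patterns))
  expect_equal(as.data.frame(res_tab$connectivity_patterns),
               as.data.frame(res_cor$connectivity_patterns))
})

test_that("the divergence-only arm selects whole predicates", {
  fx <- fixture_full_pipeline()
  cfg <- summary_config("Carcinoma of bladder", method = "KLD_ONLY",
                        novelty_stoplist = "Neoplasms")
  res <- summarize_corpus(fx$foreground, fx$background, cfg)

  # independent predicate-level ranking by divergence term
  novel <- novelty_filter(fx$foreground, "Neoplasms")
  rel <- filter_by_concept(novel, "Carcinoma of bladder")
  kld <- kld_terms(
    predicate_distribution(rel),
    predicate_distribution(filter_by_concept(fx$background,
                                             "Carcinoma of bladder"))
  )
  top4 <- names(sort(kld, decreasing = TRUE))[1:4]
  expect_setequal(unique(res$relevance_selected$predicate), top4)
  # every salient record carries a selected predicate and the seed
  expect_true(all(res$relevance_salient$predicate %in% top4))
  expect_equal(nrow(res$relevance_salient),
               sum(rel$predicate %in% top4))
  expect_equal(res$anchor_semtype, "gngm")
})

test_that("the RlogF-only arm selects predicate/semantic-type pairs", {
  fx <- fixture_full_pipeline()
  cfg <- summary_config("Carcinoma of bladder", method = "RLOGF_ONLY",
                        novelty_stoplist = "Neoplasms")
  res <- summarize_corpus(fx$foreground, fx$background, cfg)
  sel_pairs <- unique(paste(res$relevance_selected$predicate,
                            res$relevance_selected$bound_semtype))
  # independent pooled-pair ranking
  novel <- novelty_filter(fx$foreground, "Neoplasms")
  rel <- filter_by_concept(novel, "Carcinoma of bladder")
  oracle <- oracle_pattern_scores(
    rel, predicate_counts(filter_by_concept(fx$background,
                                            "Carcinoma of bladder")),
    "Carcinoma of bladder", "concept"
  )
  pooled <- aggregate(count ~ predicate + bound_semtype + total,
                      data = oracle, FUN = sum)
  pooled$rlogf <- log2(pooled$count) * pooled$count / pooled$total
  pooled <- pooled[order(-pooled$rlogf), ]
  expect_setequal(sel_pairs,
                  paste(pooled$predicate, pooled$bound_semtype)[1:4])
})

test_that("the composite and RlogF arms agree when divergence is flat and positive", {
  # one bound type per predicate, equal foreground shares, and a background
  # that halves every shared predicate's share: all divergence terms are
  # equal and positive, so composite ranking reduces to RlogF ranking
  mk <- function(pred, st, n) {
    data.frame(citation_id = sprintf("%s%03d", pred, seq_len(n)),
               subject_name = sprintf("%s arg", st), subject_semtype = st,
               predicate = pred, object_name = "Seed disease",
               object_semtype = "neop")
  }
  fg <- predication_corpus(rbind(
    mk("ASSOCIATED_WITH", "gngm", 30), mk("TREATS", "topp", 30),
    mk("AFFECTS", "dsyn", 30), mk("COEXISTS_WITH", "aapp", 30)
  ))
  bg <- predicate_count_table(c(
    ASSOCIATED_WITH = 10, TREATS = 10, AFFECTS = 10, COEXISTS_WITH = 10,
    OTHER_PREDICATE = 40
  ))
  for (k in 1:3) {
    cfg_c <- summary_config("Seed disease", method = "COMBO",
                            top_relevance_patterns = k)
    cfg_r <- summary_config("Seed disease", method = "RLOGF_ONLY",
                            top_relevance_patterns = k)
    bgl <- list(relevance = bg,
                connectivity = bg)
    res_c <- suppressWarnings(summarize_corpus(fg, bgl, cfg_c))
    res_r <- suppressWarnings(summarize_corpus(fg, bgl, cfg_r))
    expect_true(all(res_c$relevance_patterns$kld_term > 0))
    expect_lt(diff(range(res_c$relevance_patterns$kld_term)), 1e-12)
    expect_setequal(unique(res_c$relevance_selected$predicate),
                    unique(res_r$relevance_selected$predicate))
  }
})

test_that("salient output is contained in the novelty-filtered input for all arms", {
  stop <- c("Cystitis", "Chemotherapy")
  for (seed in 51:56) {
    fg <- random_corpus(seed, n = 350)
    bg <- random_corpus(seed + 700L, n = 900)
    for (method in c("COMBO", "KLD_ONLY", "RLOGF_ONLY")) {
      cfg <- summary_config("Carcinoma of bladder", method = method,
                            novelty_stoplist = stop)
      res <- suppressWarnings(summarize_corpus(fg, bg, cfg))
      pool <- as.data.frame(novelty_filter(fg, stop))
      sal <- rbind(as.data.frame(res$relevance_salient),
                   as.data.frame(res$connectivity_salient))
      expect_true(all(
        do.call(paste, sal) %in% do.call(paste, pool)
      ))
    }
  }
})
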