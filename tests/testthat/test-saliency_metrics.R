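# The three saliency metrics and their composition.

test_that("divergence terms reproduce the worked example and the identity case", {
  fx <- fixture_kld_example()
  terms <- kld_terms(predicate_distribution(fx$foreground),
                     predicate_distribution(fx$background))
  expect_equal(round(terms[["ASSOCIATED_WITH"]], 4), 0.5603)

  p <- predicate_distribution(c(A = 3, B = 5, C = 2))
  expect_equal(unname(kld_terms(p, p)), c(0, 0, 0))

  expect_error(
    kld_terms(predicate_distribution(c(A = 1)),
              predicate_distribution(c(B = 1))),
    "disjoint"
  )
})

test_that("divergence terms match the direct formula on random distributions", {
  set.seed(42)
  for (rep in 1:10) {
    p_counts <- setNames(sample(1:50, 5), paste0("P", 1:5))
    q_counts <- setNames(sample(1:50, 6), paste0("P", 1:6))
    terms <- kld_terms(predicate_distribution(p_counts),
                       predicate_distribution(q_counts))
    oracle <- oracle_kld(p_counts, q_counts)
    expect_equal(terms[sort(names(terms))], oracle[sort(names(oracle))],
                 tolerance = 1e-12)
    # restriction to the shared support never renormalizes
    expect_setequal(names(terms), paste0("P", 1:5))
  }
})

test_that("divergence over equal supports is non-negative in total", {
  set.seed(7)
  for (rep in 1:5) {
    p_counts <- setNames(sample(1:60, 6), paste0("P", 1:6))
    q_counts <- setNames(sample(1:60, 6), paste0("P", 1:6))
    terms <- kld_terms(predicate_distribution(p_counts),
                       predicate_distribution(q_counts))
    expect_gte(sum(terms), 0)
  }
})

test_that("RlogF reproduces the worked example and its boundary identities", {
  expect_equal(rlogf_score(107, 171), 4.218344839, tolerance = 1e-9)
  expect_equal(round(rlogf_score(107, 171), 2), 4.22)
  for (total in c(1, 7, 171)) expect_equal(rlogf_score(1, total), 0)
  for (tt in c(2, 16, 107)) expect_equal(rlogf_score(tt, tt), log2(tt))
  expect_error(rlogf_score(5, 4), "count <= total")
  expect_error(rlogf_score(0, 4), "count <= total")
})

test_that("RlogF is strictly increasing in count and obeys its closed form", {
  for (total in c(10, 57, 200)) {
    scores <- rlogf_score(2:total, total)
    expect_true(all(diff(scores) > 0))
  }
  # rlogf(k*a, k*b) = log2(k*a) * (a/b)
  a <- 3; b <- 7
  for (k in c(2, 5, 11)) {
    expect_equal(rlogf_score(k * a, k * b), log2(k * a) * (a / b))
  }
})

test_that("PredScal matches the worked example and its degenerate rules", {
  expect_equal(predscal(16), 0.25)
  expect_equal(predscal(2), 1.0)
  expect_equal(predscal(1), 1.0)
  expect_equal(round(predscal(24), 6), 0.218104)
  cc <- 3:50
  expect_true(all(diff(predscal(cc)) < 0))
  expect_error(predscal(0), "positive integer")
})

test_that("the composite is the exact triple product with the divergence sign", {
  expect_equal(combo_score(4, 0.25, 0.5), 0.5)
  expect_equal(combo_score(4, 0.25, -0.5), -0.5)
  expect_equal(combo_score(0, 0.25, 0.9), 0)
  expect_equal(combo_score(3.2, 0.5, 0), 0)
  expect_error(combo_score(1, 0, 1), "positive")
})

test_that("pattern scoring on the worked-example corpus composes the three metrics", {
  fx <- fixture_full_pipeline()
  rel_fore <- filter_by_concept(novelty_filter(fx$foreground, "Neoplasms"),
                                "Carcinoma of bladder")
  rel_bg <- predicate_counts(filter_by_concept(fx$background,
                                               "Carcinoma of bladder"))
  pats <- score_patterns(rel_fore, rel_bg, "Carcinoma of bladder", "concept")

  expect_equal(attr(pats, "n_predicates"), 16L)
  expect_equal(unique(pats$predscal), 0.25)

  top <- pats[1, ]
  expect_equal(top$predicate, "ASSOCIATED_WITH")
  expect_equal(top$bound_semtype, "gngm")
  expect_equal(top$count, 107L)
  expect_equal(top$total, 171L)
  expect_equal(top$rlogf, rlogf_score(107, 171))

  kld <- kld_terms(predicate_distribution(rel_fore),
                   predicate_distribution(rel_bg))
  expect_equal(top$combo,
               rlogf_score(107, 171) * 0.25 * kld[["ASSOCIATED_WITH"]])
  # stored components multiply out exactly for every row
  expect_equal(pats$combo, (pats$rlogf * pats$predscal) * pats$kld_term)
  # ranks are 1..n in descending combo order
  expect_equal(pats$rank, seq_len(nrow(pats)))
  expect_true(all(diff(pats$combo) <= 0))
})

test_that("identical foreground and background yield all-zero composites", {
  corp <- read_predications(c(
    "1|A gene|gngm|ASSOCIATED_WITH|Seed disease|neop",
    "2|B gene|gngm|ASSOCIATED_WITH|Seed disease|neop"
  ))
  pats <- score_patterns(corp, predicate_counts(corp), "Seed disease", "concept")
  expect_equal(pats$kld_term, 0)
  expect_equal(pats$combo, 0)
})

test_that("pattern scores equal an independent recount on random corpora", {
  for (seed in c(101L, 102L, 103L)) {
    fg <- filter_by_concept(random_corpus(seed, n = 800,
                                          seed_inclusion_rate = 1),
                            "Carcinoma of bladder")
    bg <- predicate_counts(filter_by_concept(
      random_corpus(seed + 500L, n = 1200, seed_inclusion_rate = 1),
      "Carcinoma of bladder"
    ))
    pats <- score_patterns(fg, bg, "Carcinoma of bladder", "concept")
    oracle <- oracle_pattern_scores(fg, bg, "Carcinoma of bladder", "concept")

    got <- as.data.frame(pats)
    got <- got[order(got$predicate, got$bound_semtype, got$side), ]
    oracle <- oracle[order(oracle$predicate, oracle$bound_semtype,
                           oracle$side), ]
    expect_equal(got$count, oracle$count)
    expect_equal(got$total, oracle$total)
    expect_equal(got$rlogf, oracle$rlogf, tolerance = 1e-12)
    expect_equal(got$kld_term, oracle$kld_term, tolerance = 1e-12)
    expect_equal(got$combo, oracle$combo, tolerance = 1e-12)

    # support conservation: bound-type counts partition each predicate's
    # total, and predicate totals sum to the foreground size
    per_pred <- tapply(got$count, got$predicate, sum)
    tot_pred <- tapply(got$total, got$predicate, unique)
    expect_equal(per_pred[names(tot_pred)], tot_pred)
    expect_equal(sum(tot_pred), nrow(fg))
  }
})

test_that("predicates missing from the background are excluded with a warning", {
  fg <- read_predications(c(
    "1|A gene|gngm|ASSOCIATED_WITH|Seed|neop",
    "2|B gene|gngm|NOVEL_PREDICATE|Seed|neop"
  ))
  bg <- predicate_count_table(c(ASSOCIATED_WITH = 10, TREATS = 30))
  expect_warning(score_patterns(fg, bg, "Seed", "concept"),
                 "NOVEL_PREDICATE")
  pats <- suppressWarnings(score_patterns(fg, bg, "Seed", "concept"))
  expect_false("NOVEL_PREDICATE" %in% pats$predicate)
  # but the excluded predicate still counts toward the vocabulary size
  expect_equal(attr(pats, "n_predicates"), 2L)
  expect_equal(attr(pats, "excluded_predicates"), "NOVEL_PREDICATE")

  expect_error(score_patterns(predication_corpus(), bg, "Seed", "concept"),
               "empty stage input")
})
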