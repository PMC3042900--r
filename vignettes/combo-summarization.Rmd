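---
title: "Combo summarization of semantic predications: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combo summarization of semantic predications: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combosum)
```

## The model

A semantic predication is a normalized assertion
`subject | semtype | PREDICATE | object | semtype` extracted from a
citation's title or abstract. `combosum` assumes two predication corpora
about the same *seed topic* (a disease, say "Carcinoma of bladder"):

- a **foreground** produced by a point-of-view-focused query (e.g. genetic
  etiology), whose predicate frequencies are skewed by that point of view;
- a **background** representing the seed topic from all points of view,
  supplied either as a predication corpus or as pre-aggregated per-stage
  predicate count tables (backgrounds built from licensed bibliographic
  databases often cannot be redistributed as records).

Writing $P(x)$ and $Q(x)$ for a predicate's relative frequency in the
foreground and background restriction of a stage, each *pattern* — a
predicate $i$ bound to a non-seed semantic type — receives

$$\mathrm{Combo}_i \;=\; \underbrace{\log_2(f_i)\,\frac{f_i}{F_i}}_{\mathrm{RlogF}}
\times \underbrace{\frac{1}{\log_2 c}}_{\mathrm{PredScal}}
\times \underbrace{P(x_i)\log_2\!\frac{P(x_i)}{Q(x_i)}}_{\text{KLD term}}$$

where $f_i$ counts the bound type with the predicate, $F_i$ counts all
non-seed types with the predicate (pooled over both argument sides), and
$c$ is the number of unique predicates in the stage's foreground. The KLD
term rewards predicates over-represented in the foreground; RlogF rewards
semantic types that bind a predicate strongly or frequently; PredScal puts
the single-predicate RlogF scale onto the divergence's whole-vocabulary
scale. The three factors are stored on every `pattern_scores` row, and the
`combo` column is exactly their product.

### The four-filter pipeline

`summarize_corpus()` composes four filters:

1. **Novelty** — remove records whose argument is on a stoplist of overly
   general concepts. Generality judgments normally come from a concept
   hierarchy; to stay dependency-free the package accepts an explicit
   stoplist (default empty) instead of computing hierarchy depth.
2. **Relevance** — restrict to records mentioning the seed concept, score
   patterns against the equally restricted background, keep records
   matching the `top_relevance_patterns` best patterns (default 4).
3. **Anchor selection** — the non-seed semantic type present in the most
   selected patterns (ties: larger summed score, then lexicographic)
   becomes the *anchor* carried into connectivity.
4. **Connectivity** — among seed-free records carrying the anchor type,
   score patterns with the anchor playing the seed role (RlogF uses the
   semantic type *other than* the anchor; both P and Q are restricted to
   seed-free anchor-carrying records; $c$ is this stage's own unique
   predicate count), and keep records matching the
   `top_connectivity_patterns` best patterns (default 1).

The default top-k values (4 and 1) reflect how the method is used for
curation triage; there is deliberately no score-threshold mode, since the
composite's absolute scale varies with corpus size and vocabulary.

Two single-metric arms support head-to-head comparison. `KLD_ONLY` ranks
whole predicates by divergence term and keeps every novel seed-containing
record with a top-4 predicate (its anchor is the most frequent non-seed
type among the salient records). `RLOGF_ONLY` ranks
predicate/semantic-type *pairs* by RlogF, pooling both argument sides, and
keeps records matching the top-4 pairs.

## Numerical and degenerate-input choices

- **Base-2 logarithms everywhere**; natural-log intermediate forms are
  converted.
- **No renormalization after support restriction.** Relative frequencies
  are computed over each corpus's full predicate set; predicates absent
  from one side are then dropped from the comparison. The restriction is a
  comparison scope, not a re-scaling, and per-predicate terms — not the
  summed divergence — are the ranking quantity.
- **Predicates missing from the background** cannot receive a divergence
  term. They are excluded from pattern scoring with a warning rather than
  smoothed: smoothing would invent background probability mass. They still
  count toward $c$, which is a property of the foreground vocabulary.
- **Negative divergence terms are kept**; under-represented predicates
  simply rank at the bottom.
- **PredScal degenerate inputs**: $c = 2$ gives $1/\log_2 2 = 1$
  analytically; $c = 1$ would divide by zero and is defined as 1 — with at
  most two predicates there is no vocabulary to scale by.
- **Tie rule** (total order, so results are reproducible): descending
  score, then descending support count, then predicate, then SUBJECT side
  before OBJECT, then bound type lexicographically — all string comparisons
  in C locale.
- **Anchor slot ambiguity**: if a record could anchor on either argument
  (seed on both sides, or both types equal the anchor), the subject slot is
  taken as the anchor and the object's type as the bound type, so every
  record contributes exactly one pattern key.
- **Concept matching** is case-insensitive exact equality on argument
  names, with an exact identifier (CUI) match also accepted when records
  carry CUIs — the reproducible proxy for thesaurus-based concept mapping,
  which is out of scope.
- **Empty connectivity stages degrade gracefully**: if no seed-free record
  carries the anchor type (common in small corpora), or a corpus-mode
  background has no records under the stage restriction, the stage is
  skipped with a log note and empty connectivity output; a pre-aggregated
  background that *lacks* the stage table, by contrast, is a hard error,
  because the caller promised per-stage counts.
- **Evaluation truncation policy**: reported percentages floor-truncate
  (61.54% → 61%), and the F-score is the harmonic mean of the truncated
  two-decimal precision and recall, itself truncated (0.6959 → 0.69);
  exact values are always reported alongside. Floors are guarded against
  floating-point noise by rounding at the ninth decimal first. Recall is
  judged against the reference standard alone, while precision also counts
  the additional externally validated true positives — the two tallies use
  different TP sets by design of the curation protocol.

## The synthetic-data generator

`generate_corpus()` draws records from a configured predicate distribution,
per-predicate semantic-type-pair distributions, per-type name vocabularies,
and a seed-inclusion/side model, under a fixed RNG seed (the caller's
random stream is saved and restored). It emulates exactly the statistical
structure the metrics consume: multinomial predicate profiles with a
seed-topic anchor and controllable foreground/background skew.

It does **not** emulate natural-language extraction: no citation text, no
extraction errors, no correlation between a citation's predications, no
thesaurus synonymy, and no realistic heavy-tailed concept vocabulary.
Passing tests therefore demonstrate the statistical machinery — score
arithmetic, ranking, filter algebra, recovery of planted enrichment — not
robustness to extraction noise in real bibliographic data.

Three deterministic fixtures reproduce the published worked-example
arithmetic at exact integer compositions:

- `fixture_kld_example()` — the smallest integer count tables realizing
  foreground/background relative frequencies 0.290 and 0.076 (29/100,
  76/1000), whose divergence term is 0.5603 at four decimals;
- `fixture_relevance()` — 308 seed-topic records over exactly 16 unique
  predicates, with `gngm` bound to ASSOCIATED_WITH in 107 of 171 non-seed
  slots (RlogF 4.218344839, PredScal 0.25);
- `fixture_full_pipeline()` — an end-to-end bundle (foreground, background,
  13-gene reference standard, validity labels, normalization table) whose
  planted top patterns are, in order, (gngm, ASSOCIATED_WITH),
  (gngm, PREDISPOSES), (aapp, ASSOCIATED_WITH), (aapp, PREDISPOSES), whose
  anchor is `gngm`, and whose 74 asserted genes (8 reference hits, 52
  validated extras, 14 false positives) evaluate to 61% recall, 81%
  precision, F 0.69. The reference list is the curated bladder-cancer gene
  set; the 66 additional symbols (`BCG01`–`BCG66`), their validity labels
  and the normalization table are synthetic stand-ins for manual curation
  inputs.

```{r fixture}
fx <- fixture_full_pipeline()
res <- summarize_corpus(fx$foreground, fx$background, fx$config)
print(res$relevance_patterns, n = 4)
```

## Problem sizes used in the test suite

Property-style checks run on generated corpora at sizes chosen to make the
statistical assertions sharp while keeping the suite quick on a laptop:
round-trip, partition and tally properties on corpora of 120–400 records;
metric-versus-brute-force equivalence (tolerance 1e-12) on corpora up to
10,000 records; planted-pattern recovery on 200 replicates of 5,000-record
foreground/background pairs (the enriched pattern must rank first in at
least 95% of replicates — with the default enrichment, foreground
ASSOCIATED_WITH share 0.30 versus background 0.08 and a 0.6 `gngm` binding,
recovery is essentially certain); and pipeline containment, partition and
determinism on 100 random 250-record corpora.

## Known limitations

- Generality (novelty) is stoplist-based, not hierarchy-based; users with a
  concept hierarchy must flatten it into a stoplist themselves.
- Name normalization and validity judgments are external inputs; the
  package never decides whether a gene is "really" implicated.
- Backgrounds must share predicates with the foreground; a foreground
  dominated by predicates the background lacks will lose most patterns to
  the shared-support rule (a warning reports the exclusions).
- Scores are descriptive ranks, not calibrated probabilities; no
  significance testing or smoothing is provided, by design.
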