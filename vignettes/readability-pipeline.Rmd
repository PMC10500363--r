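---
title: "Methods: readability scoring, agreement, and group comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: readability scoring, agreement, and group comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pemread)
```

This vignette is the package's account of what it computes and why the
design is the way it is: the four readability formulas and their shared
surface statistics, the agreement and comparison analyses built on top of
them, the synthetic-corpus generator used to exercise everything, and the
numerical conventions adopted where the classical formula descriptions are
silent.

## 1. From text to surface statistics

All four traditional readability measures are functions of a handful of
surface counts. `compute_surface_metrics()` produces them with
deliberately simple, auditable rules:

* **Sentences** are split at `.`, `!`, `?` (optionally followed by closing
  quotes/brackets). A short exception list protects common abbreviations
  ("Dr.", "e.g.", "etc."). Text with no terminal punctuation is one
  sentence. This is a pragmatic splitter, not a statistical one: the
  formulas only consume the sentence *count*, and for the plain prose of
  patient education materials simple splitting is accurate and fully
  deterministic.
* **Words** are whitespace-delimited tokens with leading/trailing
  punctuation stripped. Internal apostrophes and hyphens are kept, so a
  hyphenated compound is one word (its syllables are summed over the
  parts). Purely numeric tokens count as words.
* **Syllables** come from a two-stage counter. A small packaged
  pronunciation lexicon (`inst/extdata/syllable_lexicon.tsv`, hand-curated)
  is consulted first; it covers words with vowel hiatus ("idea",
  "period", "menstruation") that letter-based rules merge into one vowel
  group. Everything else uses a vowel-group heuristic: count maximal runs
  of `aeiouy`, subtract one for silent final `e` (including `-es`/`-ed`
  endings where the `e` is not pronounced, but not consonant-`le` as in
  "table", nor `-ted`/`-ded`, `-shes`/`-ches` and similar), floor at one.
  Numeric tokens are pronounced digit by digit (one syllable per digit).
  The suite validates the counter the way automated scoring is classically
  validated — against a hand-tallied 100-word list — requiring at least
  90% exact agreement (it currently achieves 94%; the misses are
  multi-hiatus words like "bacteria").
* **Hard words** are words absent from an easy-word list, the Dale-Chall
  notion of difficulty. Lookup is case-insensitive and strips regular
  inflections (`-s`, `-es`, `-ies`, `-ed`, `-ing`, with consonant
  undoubling and final-e restoration) so "running" and "baked" are as easy
  as "run" and "bake". Numerals are treated as familiar. The packaged
  list is an openly written ~800-word approximation of the (copyrighted)
  New Dale-Chall list — adequate for testing and simulation; for
  publication-grade Dale-Chall scores, pass the genuine ~3,000-word list
  to `load_easy_words()`.

Degenerate inputs are classed conditions, not crashes: empty/whitespace
documents raise `pemread_empty_document`, an empty easy list
`pemread_config_error`.

## 2. The four measures and their grade scale

With $w$ = words/sentence, $s$ = syllables/word, $P$ = polysyllable count,
$N$ = words, $n$ = sentences, $H$ = hard words:

| Measure | Definition | Output |
|---|---|---|
| FKGL | $0.39w + 11.8s - 15.59$ | real, unclamped |
| GFI | $0.4(w + 100P/N)$, needs $N \ge 100$ | real, unclamped |
| SMOG | see below | integer, 5–18 |
| Dale-Chall | raw $0.0496w + 15.79H/N + 3.6365$, mapped piecewise | integer, 4–16 |

Conventions worth spelling out:

* **The 100-word minimum.** GFI is undefined below 100 words, so the
  pipeline screens such documents out of *all* analyses (they are counted
  in the report but contribute to nothing else). The word count used for
  screening is the tokenizer's count on cleaned text.
* **SMOG's two branches.** With $\ge 30$ sentences the grade is
  $3 + \sqrt{S}$, $S$ the perfect square nearest $P$ — a tie between two
  squares resolves to the lower (conservative) one. With fewer sentences
  the polysyllable count is scaled to 30 sentences,
  $\mathrm{raw} = 30P/n$, rounded half-up (`floor(x + 0.5)`, not banker's
  rounding, for determinism on `.5` values) and converted through the
  interval table: grade 5 for raw 1–6, grade $R$ for raw in
  $[R^2-7R+13, (R-2)(R-3)]$ with $R = 6..17$, grade 18 from raw 211 up.
  These intervals tile the integers exactly (the suite checks 1–300); a
  scaled raw below 1 (a document with no polysyllables) sits below the
  table and is assigned the bottom grade 5.
* **Dale-Chall mapping.** The classical piecewise map is stated for raw
  "between 5 and 8" ($2\cdot\mathrm{raw}-5$) and "9" ($3\cdot\mathrm{raw}-14$),
  leaving $(8,9)$ unassigned; the first piece is extended to $[5,9)$,
  which keeps the map monotone and continuous into the second piece at 9.
  Grades take the integer part and clamp to 4–16. The 3.6365 constant is
  added unconditionally; `dcl_raw(..., classical = TRUE)` restores the
  classical behaviour of adding it only when hard words exceed 5%.
* **Composites.** The per-document composite is the mean (or median) of
  the four grade values with FKGL and GFI kept real-valued — truncation to
  the integer 4–16 scale (`to_grade_category()`) happens only when a grade
  *category* is needed (binning, the grade-distribution table). Averaging
  reals first avoids compounding two rounding steps; whether one floors
  before or after averaging shifts composites by at most half a grade, and
  the choice is exposed by the function boundaries for sensitivity
  analysis.

## 3. Inter-measure agreement

Each measure's integerized grade is binned under three schemes — one
category per grade (13 bins, 4–16), below-6 / 6–8 / above-8, and the
recommendation split at 8 (≤8 / >8) — and agreement across the four
measures is Fleiss' $\kappa = (\bar P - \bar P_e)/(1 - \bar P_e)$,
computed from the category marginals. Conventions:

* Declared-but-unused categories carry zero marginal probability and do
  not alter $\kappa$ (checked by test).
* If every rating lands in one category, $\bar P_e = 1$ and $\kappa$ is
  undefined; the package signals a degenerate-agreement condition and
  reports `NA` rather than a fabricated value. On a uniformly difficult
  corpus the 2- and 3-category schemes do exactly this — which is itself
  an informative finding about coarse binning.
* Interpretation bands (poor below 0, slight to 0.20, fair to 0.40,
  moderate to 0.60, substantial to 0.80, almost perfect above) are stated
  to two decimals, so $\kappa$ is rounded to two decimals before band
  lookup; values inside the printed gaps (e.g. 0.205) are thereby resolved
  by rounding.
* Documents screened out by the 100-word rule are excluded listwise from
  all agreement analyses.

## 4. The comparison battery

The distributional analyses run on the composite score:

1. **Normality gate** — Shapiro-Wilk at $\alpha = 0.05$; readability
   composites are bounded, lattice-like (quarter-grade steps) and skewed,
   so the nonparametric branch is the expected path. Samples beyond the
   test's 5000-value limit are thinned deterministically (fixed stride).
2. **Against the recommendation** — one-sample Wilcoxon signed-rank of
   the composites against grade 8, one-sided ("greater"), values equal to
   8 dropped.
3. **Between categories** — Kruskal-Wallis (tie-corrected, chi-square
   approximation with $g-1$ df) as the main effect for source and for
   primary topic, then all $\binom{g}{2}$ pairwise two-sided Mann-Whitney
   tests. Bonferroni is applied as an adjusted significance threshold
   $\alpha/\binom{g}{2}$ (0.05/6 ≈ 0.0083 for four sources, 0.05/10 =
   0.005 for five topics) against the raw p-values, the convention used
   when pairwise tables report unadjusted p. Exact p-values are used when
   both groups have ≤ 8 observations and the pooled data are tie-free;
   otherwise the tie-corrected normal approximation with continuity
   correction. Composites concentrate on quarter-grade steps, so ties are
   the norm at realistic sizes and the corrected approximation is the
   branch that matters; the suite checks the two branches agree within
   0.02 at $n_1 = n_2 = 8$ and that the exact branch matches full
   enumeration.

The standard tests are delegated to `stats::shapiro.test`,
`stats::wilcox.test` and `stats::kruskal.test`; Fleiss' $\kappa$ has no
base-R implementation and is computed by the package, with an
independently written brute-force version serving as the test oracle.

## 5. The synthetic corpus generator

`generate_corpus()` exists because crawled PEM collections are typically
not redistributable: it produces corpora whose surface statistics are
known *by construction*, so every pipeline stage can be tested without any
download.

* **Words** are built from consonant-vowel-consonant units ("zab", "lun",
  ...), one unit per requested syllable. The units avoid `e` and never
  create adjacent vowel groups or silent-ending patterns, so the intended
  and counted syllables agree exactly — generator correctness is decoupled
  from syllable-heuristic edge cases. Easy words are drawn from the
  packaged easy list among entries with the requested counted syllable
  length; hard words from the unit inventory, which is disjoint from the
  list. (A request for an easy word of a length the list lacks — in
  practice 5 syllables — falls back to a unit word and counts as hard.)
* **Lengths** use discretized gamma specs `dist_spec(mean, sd, min)`:
  gamma draws rounded and clamped below. `sd = 0` collapses to a
  constant, giving zero-variance configurations whose FKGL/GFI/Dale-Chall
  values are exact closed forms (12-word monosyllabic easy sentences give
  FKGL $0.39 \cdot 12 + 11.8 - 15.59 = 0.89$ to 1e-9) — the sharpest
  possible formula check.
* **Category structure.** The default layout crosses four sources
  (government, commercial, nonprofit, educational) with five topics
  (pregnancy, general disease, procedure, menstruation, cancer) in
  proportions echoing a real crawled collection — pregnancy-dominated,
  mostly educational/nonprofit — scaled to 149 documents for fast tests.
  `per_cell_shifts` adds complexity shifts (words-per-sentence mean,
  probability mass moved onto 3-syllable words) to any source or topic,
  creating known group differences for power checks.
* **Defaults as study conditions.** Sentences/document 12 ± 4, words/
  sentence 15 ± 4, syllable distribution (0.45, 0.30, 0.15, 0.07, 0.03)
  over 1–5 syllables (≈1.93 syllables/word), hard-word rate 0.25. These
  were fixed once to land documents in the 10th–14th grade band that
  audits of online patient materials repeatedly report, with essentially
  all documents above grade 8. One consequence is embraced rather than
  hidden: under the 2- and 3-category binnings such a corpus uses a single
  category and $\kappa$ is degenerate (Section 3).
* **Reproducibility.** All randomness flows from the config seed; the
  caller's RNG state is saved and restored, and identical seed + config
  yields byte-identical corpora and reports.

What the generator does **not** emulate: natural-language vocabulary,
topic-specific terminology, discourse structure, or the correlation
patterns of real prose (e.g. long sentences co-occurring with rare words).
Passing tests on synthetic corpora therefore demonstrate that the
*computations* are correct and calibrated — not that any particular real
collection has these properties.

## 6. Calibration checks and problem sizes

The suite's statistical checks run at sizes chosen to balance Monte-Carlo
error against runtime, fixed in advance of any tuning:

* **Type-I error**: 500 replicates of a null corpus (four identical
  source categories, 25 documents each, ~130 words/document); the
  Kruskal-Wallis rejection rate at $\alpha = 0.05$ must lie in
  [0.03, 0.07] (the two-sided Monte-Carlo band around 0.05 at 500
  replicates).
* **Power**: 100 replicates with a +4 words-per-sentence shift in one
  source (50 documents/group); the shifted category must have all three
  of its Bonferroni-corrected pairwise comparisons significant in ≥ 95%
  of replicates.
* **Oracle equivalence**: 1000 random small ratings matrices against the
  brute-force Fleiss sums (tolerance 1e-12); exact Mann-Whitney p against
  full enumeration for all group sizes up to 8.
* **Screening**: a 1,576-document corpus constructed with exactly 93
  sub-100-word documents must yield exactly 1,483 analyzed.

## 7. Known limitations

* The easy-word list and pronunciation lexicon are compact stand-ins;
  Dale-Chall scores against the genuine list will differ (typically
  downward, since a larger list finds fewer "hard" words).
* The syllable heuristic miscounts some multi-hiatus and loan words;
  grade-level impact is small because the formulas use per-word averages
  and polysyllable counts, but individual short documents can shift.
* Sentence splitting trusts punctuation; list-heavy or punctuation-poor
  web text degrades toward the single-sentence fallback, inflating
  words-per-sentence. Cleaning such text is the caller's responsibility
  (`clean_text()` removes only markup and layout noise).
* Grade levels above 12 are extrapolations for every one of these
  formulas; differences among 13+ composites should be read as ordinal,
  not as meaningful year counts.
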