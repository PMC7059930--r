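---
title: "Quantifying narrative sentiment and linguistic abstraction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying narrative sentiment and linguistic abstraction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcmsent)
```

## The measurement model

`lcmsent` quantifies two psycholinguistic properties of a narrative language
sample — its emotional polarity and its level of abstraction — plus a
morphosyntactic frequency profile, and compares them between two groups of
speakers (clinically, an autism-spectrum group and typically developing
controls narrating during two standardized elicitation tasks: telling a
story from a picture book, and describing a single picture).

**Sentiment** is dictionary-based at the lemma level: a token contributes to
the positive or negative count when its disambiguated lemma appears in a
sentiment lexicon (`lemma → positive|negative`). Lemma-level matching
deliberately avoids word-sense disambiguation: it is coarser but far more
robust, and transfers across inflected forms, which matters in a
morphologically rich language. All parts of speech are eligible — the
worked example tags an *adjective* positive — because emotional vocabulary
is not confined to verbs and adjectives.

**Abstraction** follows the Linguistic Category Model (LCM), which orders
verb categories by increasing abstraction: descriptive action verbs (DAV,
concrete observable actions, weight 1), interpretative action verbs (IAV,
actions with an evaluative component, weight 2), and state verbs (SV,
mental and emotional states, weight 3). A sample's abstraction score is the
weighted sum

$$\mathrm{abstraction} = \mathrm{DAV} + 2\,\mathrm{IAV} + 3\,\mathrm{SV}$$

over its verb tokens. The score is *always* computed from the category
counts; nowhere in the package (including the simulator) is it an
independent quantity, so the formula's deterministic dependence on counts
is preserved everywhere.

The LCM dictionary has three tiers consulted in order: sense-level entries
(consulted when an upstream word-sense id is available), lemma-level
entries, and an automatically inferred default tier. Only tokens whose
grammatical class (the first field of the positional morphosyntactic tag)
is verbal are eligible; the verbal-class set defaults to
`fin, praet, inf, impt, imps, bedzie, winien, pred` and is configurable,
since dictionaries differ on which verb flexemes they annotate. Sentiment
and LCM are independent channels: an IAV may simultaneously be a negative
sentiment word. Context-dependent valence shifts of inherently neutral DAVs
are not modeled.

## Upstream interface, not upstream reimplementation

Morphological analysis, probabilistic tag disambiguation and word-sense
disambiguation are *inputs*, consumed through a fixed token-table format
(UTF-8 TSV: `utterance_index, surface, lemma, msd_tag, probability,
sense_id`). `select_interpretation()` is a contract over the upstream
disambiguator's probability scores — take the maximum, break ties by the
lexicographically smallest (lemma, tag) pair — not a re-implemented CRF.
Punctuation carries the class `interp` and is excluded from all counts.

## CHAT reading conventions

Transcripts follow the CHAT transcription format. The source conventions do
not record which inline codes the original transcribers used, so the
package fixes a documented cleaning convention rather than claiming a
reconstruction: retracing/repetition markers (`[/]`, `[//]`) remove the
material they scope — the preceding `<...>` group when present, otherwise
the longest run of preceding words repeated verbatim after the marker (a
single word when nothing repeats); events (`&=...`) and pause codes are
dropped; fillers are kept as tokens; utterance terminators become sentence
punctuation. One main tier is one utterance. Examiner tiers are excluded
from every count (examiners deliver only scripted prompts). Dependent tiers
are ignored.

## Feature aggregation

Per participant and task: non-punctuation token count, utterance count,
MLU, sentiment counts, DAV/IAV/SV counts, the abstraction score, and
morphosyntactic frequencies — one count per grammatical class plus
marginals over the inflectional categories case, number, gender, person,
aspect and degree (configurable), yielding the "nearly 70" screening
variables; unresolved dotted tag values (e.g. `nom.acc`) are skipped in the
marginals rather than guessed. Counts are raw, not length-normalized: group
token totals are compared separately, and the two groups' material is of
similar volume by design.

MLU is computed per participant as total tokens / total utterances. A
pooled utterance-level variant (`utterance_lengths()`) exists because the
two aggregations answer different questions and published summaries are
ambiguous about the unit of analysis; the per-participant ratio is primary
since participants, not utterances, are the sampling units.

## The statistical battery

* **Two-group comparisons** (`compare_groups`) are assumption-gated:
  Shapiro-Wilk on each group *and* Levene's test with median centering
  (Brown-Forsythe) across groups, both at α = .05. Pass → Student's
  pooled-variance t (df = n₁+n₂−2); fail → Mann-Whitney U with midranks and
  the tie-corrected normal approximation. The gating tests themselves are a
  convention (the standard pair), chosen because only the gating *logic* is
  specified by the source analyses; they are configurable. A constant
  sample is treated as failing normality rather than crashing the gate.
* **Effect sizes**: Cohen's d = 2t/√df on the t branch — this convention
  (not mean difference over pooled SD) reproduces all published effect
  sizes from the published t values — and r = |Z|/√N on the U branch.
* **`t_from_summaries`** recomputes the pooled t from printed (M, SD, n)
  summaries, the only route to auditing published comparisons when raw
  data are unavailable.
* **Mixed ANOVA** (2 between × 2 within) uses complete cases, tests
  effects on the subject-mean / subject-difference decomposition with
  unweighted (type III) means so unbalanced groups behave as in standard
  software, and reports classical η² = SS_effect/SS_total, verified against
  an explicit sums-of-squares oracle. With two within-subject levels
  Mauchly's statistic is degenerate, so sphericity is reported as satisfied
  by construction. Post-hoc task contrasts are paired t-tests with
  Bonferroni adjustment (per-group contrasts adjusted for two comparisons).
  "Marginally significant" is not a category: exact p values are always
  reported.
* **Bonferroni screen**: per-variable gated comparisons with adjusted
  threshold α/m and adjusted p = min(1, p·m).

## The synthetic world

The generator emulates the *statistical structure* of the clinical corpus,
not its linguistics: two groups of 25, two tasks, per-sample category
counts drawn from negative binomials moment-matched to the published
Book-Task group summaries (negative binomial because the printed SDs, e.g.
2.41 at mean 2.28 for a count variable, show overdispersion; the Poisson
limit applies when SD² ≤ mean, and SD → 0 degenerates to fixed counts).
Three parameters are not published and were fixed once:

* **IAV means** — derived from the abstraction identity applied to the
  published DAV/SV/abstraction means: ASD 8.00, TD 10.28; SDs (5, 6) set to
  the same coefficient of variation as the neighboring categories.
* **Picture-task rates** — scaled to ~40% of book-task verb rates with
  fewer negative words and similar positive words, matching the direction
  and rough size of the published task main effects (abstraction and
  negative sentiment much lower on the picture task, positive sentiment
  task effect absent).
* **Missingness** — picture-task samples are missing with probability
  11/50 = 0.22, reproducing the 39 complete cases implied by the published
  mixed-ANOVA denominator df of 37; the original missingness mechanism is
  unexplained, so it is modeled as missing completely at random.

`generate_corpus` materializes the drawn counts as CHAT files and token
tables over *closed vocabularies* (positive/negative lemmas, DAV/IAV/SV
verbs, neutral fillers, kept disjoint across channels), so the pipeline
recovers the generating counts exactly — a closed-loop identity that tests
the whole chain. What the generator does **not** emulate: within-utterance
syntax, discourse coherence, lexical diversity, examiner interaction, or
any correlation between sentiment and abstraction beyond what the count
model induces. A green closed-loop test therefore establishes that
counting, scoring and bookkeeping are exact — not that the pipeline
handles real disfluent clinical speech, which enters only through the CHAT
cleaning conventions above.

## Numerical and degenerate-input choices

Ties in interpretation selection are broken lexicographically for
determinism. The Mann-Whitney p uses the tie-corrected normal
approximation at all n (exactness at small n is guarded by an enumeration
oracle in the tests). Zero-variance-everywhere inputs are an explicit
error in `compare_groups`; a constant ANOVA response returns F = 0 across
effects. Empty LCM tiers are valid (the fallback is simply absent).
Unknown lemmas stay unlabeled — dictionary coverage, not an error.

## Known limitations

The package ships toy lexicons only; scientific use requires real
sentiment and LCM dictionaries in the same TSV formats. The published
utterance-length comparison and one published U/Z/r triple are not
internally consistent with the printed group sizes, so neither is used as
a check anywhere; the package reports internally consistent statistics
instead. η² conventions differ across software (classical vs partial);
this package's choice is classical, oracle-verified, and stated.
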