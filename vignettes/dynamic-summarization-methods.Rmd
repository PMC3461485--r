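---
title: "Dynamic summarization of semantic predications: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic summarization of semantic predications: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semsumm)
```

## The problem and the model

A semantic predication is a subject–predicate–object assertion extracted
from biomedical citation text, with semantic-type codes on both arguments:
*cetuximab*[phsu]–TREATS–*Endometrial carcinoma*[neop]. Given a set of
predications retrieved for a disease topic and a point of view (treatment,
prevention), the summarization task is to return the small subset a reader
should look at first.

`semsumm` implements a four-tier cascade. Relevance and Connectivity
define the candidate set (seed-bearing predications, plus predications
sharing a non-seed argument's semantic type with them); Novelty removes
vague assertions; Saliency ranks (semantic type, predicate) patterns and
keeps predications matching the top four patterns of each tier. The
saliency statistic for a pattern $(s, v)$ is the product

$$\mathrm{Combo}(s,v) = \underbrace{P(v)\log_2\frac{P(v)}{Q(v)}}_{\text{KLD term}}
  \cdot \underbrace{\log_2(f_{sv})\,\frac{f_{sv}}{F_v}}_{\text{RlogF}}
  \cdot \underbrace{\frac{1}{\log_2 c}}_{\text{PredScal}}$$

where $P$ is the predicate relative-frequency distribution of the
(novelty-filtered) dataset, $Q$ a background predicate distribution from a
broad corpus, $f_{sv}$ the frequency of semantic type $s$ paired with
predicate $v$ in the tier being profiled, $F_v$ the total semantic-type
frequency paired with $v$ in that tier, and $c$ the number of unique
predicates in the dataset ($\mathrm{PredScal} = 1$ when $c = 1$, where the
formula is undefined).

The three factors play different roles: the KLD term asks *which relations
are characteristic of this query* (TREATS is enriched in a drug-therapy
retrieval relative to the background literature); RlogF asks *which
argument category dominates that relation here* — it grows with both the
conditional probability $f_{sv}/F_v$ and (logarithmically) the absolute
support $f_{sv}$, so a pattern seen once scores zero; PredScal rescales
RlogF, whose raw magnitude often exceeds the KLD term, by the predicate
diversity of the dataset.

Modeling assumptions worth stating: predicate frequencies are treated as
exchangeable draws (no within-citation correlation); concept names are
compared as normalized strings (no synonym resolution — two spellings of
one drug form two subject groups); and the background is taken on faith as
a representative predicate marginal.

## Tunable parameters

* **`top_k`** (default 4, per tier): the summary keeps predications
  matching the best `top_k` relevance and `top_k` connectivity patterns.
  Four per tier is the method's standard operating point; raising it
  trades precision for recall.
* **`smoothing`** (default 0): additive pseudo-count on the background.
  At 0, only predicates present in both distributions receive KLD terms
  (the strict shared-support rule); a positive value admits query-only
  predicates. Off by default because silently scoring unseen predicates
  changes the statistic's meaning; the unscored predicates are reported
  instead.
* **`semtype_mode`** (`"all"` / `"primary"`): an argument carrying several
  semantic types contributes one pattern count per type by default, which
  is the permissive reading; `"primary"` counts only the first listed
  type for corpora where multi-typing would double-count.
* **`kld_mode`** (`"per_predicate"` / `"summed"`): whether each pattern is
  multiplied by its own predicate's KLD term (default — the per-predicate
  terms are computed "before summing", which is what makes predicates
  comparable) or by the total divergence, kept as a comparison mode in
  which KLD no longer discriminates between patterns.
* **`position_restricted`** (default `FALSE`): whether a connectivity
  match requires the shared semantic type in the same argument position
  (subject/object) where it was observed. The permissive both-positions
  default matches the tier's description; the restricted variant is
  available because the narrow reading is also defensible.
* **Novelty stoplist**: shipped default of five generic clinical concepts
  (`pharmaceutical preparation`, `patients`, ...). A stoplist is a
  deliberate, auditable substitute for an ontology-based generality model;
  real deployments should extend it.
* **Baseline `sd_type`** (`"population"` / `"sample"`): the term table is
  the entire group, not a sample drawn from one, so the population
  (divide-by-N) standard deviation is the default; the worked numbers the
  baseline is known by (mean 35.8, SD 154.4, threshold 190.2–190.3 on a
  1784-term table) cannot discriminate between the two at one decimal.
  Retention is strict `count > threshold`: "exceeds" is read literally,
  and a term sitting exactly at the threshold is excluded.

## Pipeline order and other design choices

The cascade is applied as Novelty → Relevance → Connectivity → Saliency:
novelty filtering is record-wise, so it commutes with relevance filtering
(a property the test suite asserts), and applying it first means both the
distribution $P$ and the pattern profile are computed over novel
predications only — the saliency stage is meant to rank *novel*
predications, so vague records should not contribute probability mass
either.

Other decisions that were genuinely open:

* $P$ is computed from the **whole** novelty-filtered dataset, not only
  seed-bearing records: the enrichment question ("is TREATS
  characteristic of this retrieval?") concerns the retrieval, not the
  seed's immediate neighborhood. $c$ in PredScal counts unique predicates
  in the same set, not the background.
* Relevance-tier patterns take the semantic type of the argument
  *opposite* the seed (for *cetuximab*[phsu]–TREATS–seed, the pattern is
  `(phsu, TREATS)`); a record whose two arguments both name the seed
  yields no pattern. Connectivity-tier patterns use the type(s) that
  licensed the record's inclusion.
* RlogF's denominator $F_v$ is accumulated **within a tier**: the
  conditional probability of a relevance pattern is taken among relevance
  patterns, so the two tiers' rankings do not interfere.
* KLD terms are kept **signed**. An under-enriched predicate gets a
  negative term and its patterns sink to the bottom of the ranking, which
  preserves the intent of enrichment-based ordering; clamping at zero
  would erase the distinction between "not enriched" and "depleted".
* Tie-breaking at the selection boundary is total and deterministic:
  descending Combo, then descending pattern frequency, then lexicographic
  (semtype, predicate). When every scorable Combo value is zero (the
  degenerate case $P = Q$), the selection is flagged `no_enrichment`
  rather than silently presented as a ranking.
* Negated predications are parsed, preserved in round-trips, and excluded
  from scoring by default (`include_negated = FALSE`): a negated TREATS
  is evidence *against* the pattern, not for it.

Degenerate inputs are handled by classed conditions: empty files, a seed
absent from the dataset (reported with the nearest concept names by edit
distance), a background with no mass, and an all-stoplisted dataset all
raise `semsumm_empty_input_error`, which the command-line wrapper maps to
exit code 3.

## The synthetic-data generator

`generate_corpus()` emulates the statistics the method feeds on: a
background predicate marginal (apportioned exactly proportional to the
configured weights, so corpus-versus-background goodness-of-fit questions
are well-posed); a corpus in which a configurable fraction of records
(default 0.3) bears the seed disease as object; Zipf-skewed concept-name
frequencies (exponent 1.2 — literature term frequencies are heavy-tailed,
which is precisely what the baseline's mean-plus-one-SD threshold
exploits); a small vague stratum (2%) exercising the Novelty tier; and a
small negated stratum (2%). Planted patterns multiply the joint
(semantic type, predicate) probability of seed-bearing records by an
enrichment factor, giving ground truth for ranking: at the default study
conditions (n = 5,000, one pattern at multiplier 8) the planted pattern
tops the relevance ranking in at least 95% of corpora, which the
acceptance suite verifies over 50 replicates.

What the generator does **not** emulate: citation text (sentences are
template strings), correlated predications from a shared abstract,
synonymy and spelling variation of concept names, multi-word term
extraction noise, and semantic-type assignment errors. Passing tests
therefore demonstrate the statistic and its implementation, not robustness
to extraction noise — on real extractor output, name normalization and the
stoplist do more work than they do here.

Problem sizes used by the validation battery (chosen to exercise each
property at the smallest informative scale): the kernel-versus-oracle
comparison uses 100 corpora of 25–60 records; distribution identities use
1,000 random pairs over a 12-predicate vocabulary; planted-pattern
recovery uses 50 corpora of 5,000 records; goodness-of-fit uses a single
100,000-record corpus; the reproducibility check runs the full
simulate–summarize–evaluate path twice at 1,200 records and compares
bytes.

## Evaluation harness

Recall is matched reference interventions over reference size; precision
is true-positive subject groups over all subject groups (a group is one
normalized subject name among the point-of-view-conformant predications,
e.g. *X*–TREATS–*disease* for treatment); F1 is the balanced harmonic
mean, defined as 0 when P + R = 0. Where a human judge would credit an
indirect match (a summary's *Dietary Modification* standing for the
reference's *reduce sodium intake*), the harness requires an explicit
alias-map entry instead of fuzzy matching — reproducible and auditable,
at the cost of understating recall relative to a human evaluation.
Inter-annotator agreement is the simple proportion
`matches / (matches + non-matches)`; with no chance correction it is not
comparable to kappa-type coefficients.

## Known limitations

* Name-based matching throughout: no concept-identifier resolution, so
  synonyms fragment subject groups and depress measured precision/recall.
* The Connectivity tier can be promiscuous when a licensed semantic type
  (e.g. `phsu`) is ubiquitous; the position-restricted mode only partly
  mitigates this.
* The background distribution is user-supplied; a mismatched background
  (different era, different extractor) shifts every KLD term. Predicates
  missing from it are unscored unless smoothing is enabled.
* Combo mixes a signed factor with two non-negative ones, so the ranking
  among *depleted* predicates (negative KLD) inverts the RlogF order
  within those predicates; in practice selection happens among enriched
  predicates and the effect is confined to the bottom of the table.
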