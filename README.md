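# semsumm

Dynamic summarization of biomedical semantic predications.

Literature search for point-of-care questions ("what drugs treat this
disease?", "what prevents it?") returns far more citations than a clinician
can read. One way to compress them is to run the citations through a
semantic extractor that emits *predications* — compact
subject–predicate–object assertions such as

```
cetuximab [phsu]  TREATS  Endometrial carcinoma [neop]
```

with UMLS-style semantic-type codes on each argument — and then filter the
predication set down to the assertions most salient for a chosen disease
topic and *point of view* (treatment, prevention, ...). Classic
implementations of that filtering hard-code a pattern schema per point of
view. `semsumm` implements the dynamic alternative: a statistic computed on
the fly from the dataset itself, so a single program summarizes for any
point of view. It is aimed at biomedical NLP researchers and decision-support
builders who already have predication-shaped data (or want to simulate it).

## The method

Input predications pass through four sequential tiers:

1. **Relevance** — keep predications naming the user-selected seed topic
   (e.g. *Hypertensive disease*).
2. **Connectivity** — add predications that share a semantic type with a
   non-seed argument of a relevant predication (e.g. everything carrying
   `phsu`, pharmacological substance).
3. **Novelty** — drop vague predications such as *pharmaceutical
   preparation*–TREATS–*patients*, via a configurable stoplist.
4. **Saliency** — score (semantic type, predicate) patterns and keep the
   predications matching the four best Relevance patterns and the four best
   Connectivity patterns.

The saliency score of a pattern *(s, v)* is the **Combo** product

```
Combo(s, v) = KLD(v) · RlogF(s, v) · PredScal
```

where, with P the predicate relative-frequency distribution of the dataset
and Q the distribution of a broad background corpus,

* `KLD(v) = P(v) · log2(P(v) / Q(v))` — the predicate's (signed)
  contribution to the Kullback–Leibler divergence D(P‖Q), i.e. its
  enrichment in the query dataset over the background; only predicates
  present in both distributions are scored;
* `RlogF(s, v) = log2(f) · f / F` — Riloff's pattern-relevance statistic,
  with `f` the frequency of semantic type *s* paired with predicate *v*
  and `F` the total semantic-type frequency paired with *v*;
* `PredScal = 1 / log2(c)` — a scaling factor over the count `c` of unique
  predicates in the dataset (defined as 1 when `c = 1`).

The package also ships the two companion procedures used to benchmark such
a summarizer: a **baseline** that retains terms whose frequency exceeds the
group mean plus one standard deviation (with a prevention trigger-phrase
line filter and category exclusion), and an **evaluation harness** that
scores any summary against a reference-standard intervention list
(reference recall, subject-group precision, balanced F1, and
inter-annotator agreement `matches / (matches + non-matches)`).

## Worked example

Everything below runs offline: the synthetic-corpus generator plants an
8-fold enriched `(phsu, TREATS)` pattern among the seed-bearing records of
a 5,000-predication corpus, and emits the matching background table and
ground truth.

```r
library(semsumm)

spec <- corpus_spec(
  n_records = 5000,
  planted_patterns = data.frame(semtype = "phsu", predicate = "TREATS",
                                multiplier = 8),
  rng_seed = 42)
corpus <- generate_corpus(spec)

res <- summarize_predications(corpus$predications,
                              seed_topic("Hypertensive disease"),
                              corpus$background)
print(res)
#> Combo dynamic summarization
#>   records: 5000 in -> 4804 novel -> 714 summary
#>   unique predicates (c): 6, PredScal 0.3869
#>   selected patterns:
#>     [connectivity] topp__TREATS  freq=156  combo=0.03062
#>     [connectivity] phsu__TREATS  freq=155  combo=0.03039
#>     [connectivity] orch__TREATS  freq=152  combo=0.02968
#>     [connectivity] aapp__TREATS  freq=146  combo=0.02828
#>     [relevance] phsu__TREATS  freq=241  combo=0.1288
#>     [relevance] dsyn__TREATS  freq=31  combo=0.01037
#>     [relevance] diap__TREATS  freq=22  combo=0.006627
#>     [relevance] aapp__TREATS  freq=20  combo=0.005839
```

The planted `phsu__TREATS` relevance pattern dominates the ranking
(Combo 0.1288, an order of magnitude above the runner-up): TREATS is
enriched over the background, and `phsu` claims most of the semantic-type
mass paired with it. 714 of the 4,804 novel predications match a selected
pattern and form the summary.

Evaluating the summary against a generated reference standard whose
overlap with the achievable interventions is 50% by construction:

```r
ref <- generate_reference(corpus, n_items = 20, overlap = 0.5, rng_seed = 42)
groups <- group_subjects(res, pov = "treatment",
                         disease_names = "Hypertensive disease")
match_reference(groups, ref$reference)
#> Evaluation [synthetic]
#>   recall    0.500 (10/20 interventions matched)
#>   precision 0.263 (10/38 subject groups true)
#>   F1        0.345
```

Recall is exactly the constructed overlap — the summary recovered all 10
reachable interventions — while precision reflects the extra intervention
names the corpus attached to the planted pattern.

The same pipeline is scriptable through the installed `semsumm` executable
(`simulate`, `summarize`, `baseline`, `evaluate` subcommands), which writes
plain TSV/JSON outputs with provenance headers and uses exit codes
0 / 2 / 3 for success / usage error / empty input.

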