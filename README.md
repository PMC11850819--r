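# milscreen

Multi-instance learning (MIL) for depression screening from clinical
interview transcripts.

Screening interviews (DAIC-WOZ-style corpora) yield long transcripts in
which depressive information is sparse: most answers from a depressed
participant are ordinary conversation, and healthy participants
occasionally produce answers that *sound* depressive. `milscreen` treats
each participant's session as a MIL **bag** whose **instances** are the
merged responses to individual interviewer questions. A pluggable scorer
assigns each instance a depression confidence score ν ∈ [0, 1]; the bag
verdict comes from a decision rule with two thresholds:

* **majority criterion** — more than half of the instances exceed a
  high-confidence threshold **α**;
* **count criterion** — more than **β** instances are *depressive*
  (score > 0.5).

Either criterion flags the bag (variants expose the single-instance
reading of α and each criterion alone). This keeps one emotional answer
from a healthy participant from flipping the bag — the failure mode of the
classical "any positive instance" MIL rule and of max pooling — while β
still catches mild cases whose scores never reach α.

The package covers the full pipeline:

* **Preprocessing** — `read_transcript()`, `build_qa_pairs()`,
  `merge_answers()`, `rank_instances()`, `canonicalize_key_answers()`,
  `strip_interviewer_text()`, `build_bag()`: timestamp-ordered
  segmentation, answer merging, word-count ranking, canonical sentences
  for key yes/no diagnostic answers, embedded-question removal.
* **Scoring** — the `mil_scorer()` contract, a reproducible bag-of-words
  logistic baseline (`fit_baseline_scorer()`), exact average-vote
  ensembling of two scorers (`ensemble_scores()`), and Monte-Carlo repeat
  uncertainty (`mc_uncertainty()`, default 10 repeats).
* **Decision** — `decide_bag()`, `decide_dataset()`,
  `classical_bag_label()`, `pool()`.
* **Evaluation** — `classification_metrics()`, `roc_curve()` (trapezoid
  AUC, tie-aware), `sweep_alpha_beta()` grid sweeps, `compare_pooling()`
  ablations.
* **Explanation** — `explain_instance()`: perturbation-based local
  surrogate (LIME-style) attribution of one instance's score to its
  tokens.
* **Synthetic data** — `synth_config()`, `generate_score_bags()`,
  `generate_text_bags()`: interviews with the statistical structure the
  analysis assumes (minority-positive prevalence, sparse depressive
  signal, occasional spurious depressive instances in negative bags), so
  everything is testable without the access-restricted corpora.

A command-line entry point wrapping the same functions is installed at
`inst/cli/milscreen` (`milscreen simulate|preprocess|run|sweep|explain`).

## Worked example

Generate a small synthetic interview corpus, fit the baseline scorer,
score and decide every bag, and evaluate:

```r
library(milscreen)

cfg <- synth_config(n_participants = 20, instances_per_bag = c(8, 15))
dat <- generate_text_bags(cfg, seed = 42)

scorer <- fit_baseline_scorer(dat$bags)
scored <- lapply(dat$bags, function(b) score_bag(scorer, b))
res <- decide_dataset(scored, decision_config(alpha = 0.9, beta = 1))

res$confusion
#>   TP=7 FP=2 TN=11 FN=0
classification_metrics(res$confusion)
#> Acc=0.9000 P=0.7778 R=1.0000 F1=0.8750
```

So with α = 0.9 and β = 1, 18 of 20 participants are classified
correctly; every depressed participant is caught (recall 1.0) at the cost
of two false positives (precision 0.78). Individual verdicts carry their
evidence:

```r
decide_bag(scored[[1]], decision_config(alpha = 0.9, beta = 1))
#> <decision synth-001> label=1 (majority=FALSE, count=TRUE); 0/12 above alpha, 8 depressive
```

This bag is flagged by the count criterion — 8 of its 12 instances score
above 0.5 — even though no single score clears α. Instance-level
attribution for one response of a flagged participant:

```r
explain_instance(scorer, dat$bags[[1]]$instances[[1]],
                 n_samples = 1000, seed = 1)
#> <explanation> 10 feature(s), intercept 0.2154, local R^2 0.937
#>   +0.1318  empty
#>   +0.0969  numb
#>   +0.0775  holiday
#>   +0.0723  crying
#>   ...
```

Positive weights push the score toward depressive; here the planted
depressive vocabulary ("empty", "numb", "crying") carries the largest
positive contributions.

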