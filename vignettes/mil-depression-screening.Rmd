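---
title: "Multi-instance learning for depression screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-instance learning for depression screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(milscreen)
```

## The problem and the model

Clinical screening interviews (the DAIC-WOZ family of corpora is the
canonical example) produce long transcripts in which depressive information
is *sparse*: most of a depressed participant's answers are ordinary
conversation, and occasionally a non-depressed participant produces an
answer that sounds depressive. A single document-level classifier over the
concatenated transcript must cope with both very long inputs and this
diluted signal.

`milscreen` instead treats the session as a **multi-instance learning
(MIL)** problem. Each merged response to one interviewer question is an
*instance* \(x_j\); the participant's full set of responses is a *bag*
\(b = \{x_1, \dots, x_n\}\) carrying the diagnostic label. Instance labels
are latent — supervision exists only at the bag level. In the classical MIL
convention a bag is positive iff it contains at least one positive
instance:

\[
Y_b = \begin{cases} 0 & \text{if } \sum_{j=1}^n y_j = 0 \\ 1 & \text{otherwise,} \end{cases}
\]

implemented by `classical_bag_label()`. An instance scorer \(f\) assigns
each instance a depression confidence score \(\nu_j \in [0,1]\), and a
permutation-invariant aggregation \(g\) produces the bag verdict
(`pool()` provides the max/mean baselines).

The classical rule is brittle in this domain: one emotional answer from a
healthy participant flips the whole bag. The package's central object is
therefore an **improved decision rule** (`decide_bag()`) with two
thresholds:

* **majority criterion** — the bag is flagged when *more than half* of its
  instances exceed a high-confidence threshold \(\alpha\);
* **count criterion** — an instance with score above 0.5 is *depressive*,
  and the bag is flagged when it contains *more than* \(\beta\) depressive
  instances.

Both inequalities are strict ("exceeds", "more than"): a score exactly at
\(\alpha\) or at 0.5 fires no flag, and an exact half-split at even \(n\)
does not satisfy the majority criterion. The default combination is the
disjunction (either criterion suffices). Empty bags are errors, not
negatives: the rule is undefined on an interview with no responses.

### Variants

The two descriptions of \(\alpha\) in circulation differ: "more than half
of the instances exceed \(\alpha\)" versus "a single instance can directly
determine the bag". Rather than silently pick one, `decision_config()`
exposes both readings (`majority_or_count`, `single_or_count`) plus each
criterion alone (`majority_only`, `count_only`) for ablations. The package
default is `majority_or_count`, the more conservative reading. `count_only`
with \(\beta = 0\) recovers the classical rule under the 0.5 cutoff, which
is property-tested.

\(\beta\) is an absolute count by default ("more than \(\beta\) depressive
instances"); `beta_fraction = TRUE` rescales it by bag size for corpora
with very heterogeneous interview lengths.

## Transcript preprocessing

`read_transcript()` ingests delimited transcripts (tab-separated with an
"Ellie" interviewer tag, comma-separated participant-only exports, or a
sniffed generic dialect), returns utterances sorted by start time (stable
on ties — the format gives no other ordering), and refuses malformed rows
unless `lenient = TRUE` (then they are dropped and counted; silent loss is
never the default).

`build_qa_pairs()` performs ordered segmentation: each maximal run of
participant turns following an interviewer turn becomes one question-answer
pair, and `merge_answers()` joins the run into one comprehensive response
(single-space joiner, so total word count is conserved). Sessions *without*
interviewer rows are handled the way the corpora handle them: each turn
becomes its own question-less instance and nothing is merged.

Three further normalizations, each by its own function so pipelines can opt
in per dialect:

* `rank_instances()` — stable sort by word count, longest first, on the
  assumption that longer answers carry more emotional content. Nothing is
  truncated by default; `top_n` exposes truncation for users who want it.
* `canonicalize_key_answers()` — a bare "yes"/"no" to the prior-diagnosis
  question is decisive but one word long, so it is replaced by a full
  canonical sentence (positive or negative diagnosis). Detection is by
  leading-token lists (`yes`, `yeah`, `yep`, `i have` / `no`, `nope`,
  `never`, `i haven't`); an answer matching neither list is left unchanged
  with a warning, since no authoritative handling exists for that case.
* `strip_interviewer_text()` — removes interviewer questions embedded in
  response text (matching after lowercasing and ASCII-punctuation
  stripping); total removal flags the instance empty rather than deleting
  it, leaving the drop decision to the caller.

Word counting is whitespace tokenization throughout (`tokenize_words()`).
It is the simplest reproducible rule, and using the same tokenizer for
counting, scoring features and explanation features keeps the modules
coherent.

## Instance scoring

Scorers satisfy a small contract (`mil_scorer()`): instance in, score in
\([0,1]\) out, independence across instances, and declared stochasticity.
The reference corpora pair the framework with fine-tuned transformer
classifiers; those are deliberately behind the contract — any model that
emits a per-instance probability plugs in.

The package ships a fully reproducible desk-scale scorer,
`fit_baseline_scorer()`: binary token-presence features, ridge-penalized
logistic regression (via glmnet, small fixed \(\lambda\) for a
deterministic fit), instances inheriting their bag's label for training —
the standard MIL weak-label assumption, matching how bag-level supervision
is used upstream. Its fitted weights are exposed via `coef()` because the
explanation module is validated against them.

`ensemble_scores()` fuses two scorers by the average vote,
\(\nu_j = \tfrac{1}{2}(m_j + r_j)\), exactly and per instance. The
formulation indexes instances, so fusion happens at the instance-score
level; decision-level voting would be a different operator and is not
silently substituted.

`mc_uncertainty()` scores one instance repeatedly (default 10 repeats, the
usual Monte-Carlo dropout protocol) and reports the sample mean and the
*population* variance (divide by \(N\); the protocol says only "the
variance", and the population form makes a deterministic scorer's variance
exactly zero).

## Evaluation

`classification_metrics()` computes accuracy, precision, recall and F1
from confusion counts. Zero-denominator metrics are flagged `NA` rather
than coerced to 0 — coercion would silently reward degenerate classifiers.

`roc_curve()` sweeps thresholds over the unique observed scores (ties
grouped), anchors the curve at (0,0) and (1,1), and integrates by
trapezoid. The decision rule is binary, so ROC analysis needs a continuous
bag score: `bag_score()` defaults to the mean instance score (max and
depressive-count-fraction are alternatives), and the choice is recorded by
the caller, not hidden. The AUC is cross-checked in the test suite against
the Mann–Whitney pairwise statistic and against pROC.

`sweep_alpha_beta()` evaluates the full Cartesian grid (defaults
\(\alpha \in \{0.50, 0.55, \dots, 1.00\}\), \(\beta \in \{0,\dots,10\}\);
the fine step near 1 is where useful optima concentrate) and reports the
arg-max row for a chosen metric. Accuracy is typically *flat* in \(\alpha\)
beyond some point — once \(\alpha\) clears every spurious instance, raising
it further changes nothing. Ties are therefore broken toward the smallest
\(\alpha\) (then smallest \(\beta\)): the plateau onset is the reported
optimum, which is also the conventional way a flat-topped threshold sweep
is read.

`compare_pooling()` reruns the same data under max pooling, mean pooling
(both thresholded at 0.5) and the \(\alpha/\beta\) rule — the standard
ablation showing why the rule exists: max pooling is destroyed by one
spurious instance per negative bag, mean pooling dilutes sparse signal to
nothing.

## Local surrogate explanations

`explain_instance()` implements the perturbation-surrogate (LIME-style)
procedure for text: distinct lowercased tokens are the features; binary
masks drawn uniformly over mask sizes *remove* masked tokens (no
placeholder token — removal matches how the scorer actually sees text);
the scorer evaluates each perturbed text; samples are weighted by
\(\exp(-d^2/w^2)\) with \(d\) the cosine distance to the unperturbed mask
and \(w = 0.75\sqrt{d_{\text{tokens}}}\) by default; a weighted ridge
surrogate is fitted and the `max_features` largest-magnitude weights are
refitted and reported. Defaults (1000 samples, 10 features) follow common
LIME-for-text practice; all are arguments.

Two design consequences worth stating: for a scorer exactly linear in
token presence the surrogate family contains the truth, so weights converge
to the scorer's coefficients (the test suite checks near-exact recovery at
5000 samples); and a scorer with no local variation yields an all-zero,
flagged "flat" explanation instead of noise.

## The synthetic generator

The restricted corpora cannot ship with the package, so `synth_config()` +
`generate_score_bags()` / `generate_text_bags()` generate data with the
statistical structure the analysis assumes. The defaults are the study
conditions; they were chosen once, on the following grounds, and are not
tuned per experiment:

* **47 participants, prevalence 14/47** — the size and minority-positive
  balance of the usual held-out interview split.
* **40–100 instances per bag** — the observed range of question–answer
  turns per session.
* **Score distributions** — truly depressive instances draw from
  Beta(12, 2) (mean ≈ 0.86, substantial mass above 0.9); ordinary
  instances from Beta(2, 8) (mean 0.2). This reproduces the qualitative
  contrast seen in real score heatmaps: only depressed participants' bags
  place real mass above 0.9.
* **Depressive fraction 0.2** — depressive signal confined to a minority
  of a positive bag's instances, the premise that motivates MIL here.
* **Spurious instances** — with probability 0.15 a negative bag contains
  *one* depressive-looking instance drawn from Beta(6, 4) (mean 0.6): above
  the 0.5 depressive cutoff but almost never above 0.9. This encodes the
  documented phenomenon of healthy participants producing emotionally
  depressive answers — instances that read as depressive without being
  extreme — and it is what makes \(\beta\) meaningful. A separate
  distribution is used rather than the positive-bag high Beta precisely
  because spurious answers in real negative bags do not reach the extreme
  scores that truly depressive instances do.
* **Text generation** — instance texts are random word sequences over
  disjoint depressive/neutral lexicons (depressive-word rate 0.35 in
  planted instances vs 0.02 background), emitted both as gold bags and as
  raw transcript rows (question + 1–3 split answer turns; ~2% of sessions
  question-less) so the preprocessing path is exercised end to end and
  must reconstruct the generator's instances exactly.

What the generator does *not* emulate: linguistic realism, topical
coherence, inter-annotator noise in labels, or any actual corpus content.
Passing tests on synthetic data therefore demonstrates that the *machinery*
is correct under the assumed statistical structure — not that any
particular accuracy carries over to real interviews.

## The parameter-recovery study

`tests/testthat/test-acceptance.R` and `scripts/acceptance.R` run a
recovery study at 300 participants: generate score bags at the defaults,
sweep the grid, and ask whether the sweep finds the planted structure. The
sweep runs under `single_or_count`. This is a pre-registered design choice,
for a structural reason: under the majority reading, no bag of ~70
instances with signal in 20% of them ever has a majority above any
\(\alpha\), so accuracy is constant in \(\alpha\) and "the best
\(\alpha\)" is undefined. The single-instance reading is the one under
which \(\alpha\) is identified — and it is also the reading the
hyper-parameter description itself uses. Under it the recovered optimum
lands at the planted boundary (\(\alpha \in [0.85, 0.95]\), the grid
neighborhood of 0.9) with \(\beta \geq 1\), and the \(\alpha/\beta\) rule's
F1 dominates max pooling in at least 15 of 20 seeds.

Problem sizes in the checks (multiset enumeration to \(n = 6\) for the
decision oracle, 500 random sets for the AUC oracle, 300 bags and 20 seeds
for the recovery study, 5000 perturbation samples for the explainer,
10\(^4\) repeats for the Bernoulli variance check) were chosen so the whole
suite runs comfortably on a laptop while keeping Monte-Carlo error well
below the asserted tolerances.

## Numerical and degenerate-input policy

* Strict inequalities at every threshold; boundary equality never fires.
* Empty bags, empty grids, single-class training sets, single-class ROC
  input and all-zero confusion tables are *errors with named classes*, not
  silent defaults.
* Sorting is stable everywhere a tie is possible (timestamps, word-count
  ranking, sweep arg-max).
* All randomness flows through explicit seeds (`with_seed` semantics:
  the caller's RNG stream is untouched); same seed, byte-identical output,
  which is itself under test.
* The explainer's ridge stabilizer (\(10^{-6}\)) exists only to keep the
  normal equations well-posed under collinear masks; it is orders of
  magnitude below any reported weight.

## A worked example

```{r example}
cfg <- synth_config(n_participants = 20, instances_per_bag = c(8, 15))
dat <- generate_text_bags(cfg, seed = 42)
scorer <- fit_baseline_scorer(dat$bags)
scored <- lapply(dat$bags, function(b) score_bag(scorer, b))
res <- decide_dataset(scored, decision_config(alpha = 0.9, beta = 1))
res$confusion
classification_metrics(res$confusion)
```

## Known limitations

* The baseline scorer is a bag-of-words model: adequate to exercise and
  validate the MIL machinery, far below a fine-tuned transformer on real
  language. Transformer adapters belong behind the `mil_scorer` contract.
* \(\alpha\)-recovery is only meaningful under `single_or_count`; under
  the default variant the sweep will (correctly) report a flat
  \(\alpha\) profile on data like the generator's.
* The yes/no detector for canonicalization is leading-token matching;
  hedged answers ("well, maybe") pass through with a warning by design.
* JSON score files do not carry instance text, so explanation workflows
  need the original bag file, not the scored file.
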