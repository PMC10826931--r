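---
title: "Keyword-flag classification of opioid overdoses in EMS records: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Keyword-flag classification of opioid overdoses in EMS records: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Emergency medical services (EMS) encounter records are one of the few data
sources that see the full range of opioid overdose events — deaths,
transports, and patients stabilized in the field who refuse transport and
therefore never generate an emergency-department record. But EMS records
carry no reliable diagnosis code: the dispatcher's *call nature* is a guess
from caller description, and on-scene *impressions* are assessments of
presentation ("altered mental status") rather than diagnoses. Identifying
overdoses therefore requires reading the narrative text.

`emsflags` implements an interpretable classification pipeline for this
problem: count curated opioid and overdose keywords per narrative field
("flag" features), feed the counts to standard learners, stack the learners
with a linear combiner, and report discrimination with honest confidence
intervals. Two heavier featurizers — TF-IDF and clinical concept-embedding
vectors — are implemented as comparison baselines. Because real EMS records
are protected health information, the package also ships a seeded synthetic
cohort generator that emulates the documented structure of such data, so
every pipeline stage is exercisable and testable end to end.

## Flag featurization

Two curated term sets drive the featurizer (`default_term_sets()`): 18
opioid terms (opioid, opiate, Narcan, naloxone, heroin, methadone, fentanyl,
Percocet, oxycontin, oxycodone, Vicodin, morphine, crack, cocaine,
Tylenol 3, codeine, oxy, tramadol) and 7 overdose terms (ingestion,
substance, abuse, intox, poisoning, OD, overdose). The lists are used
verbatim — including "crack" and "cocaine", which are pharmacologically
non-opioid — because fidelity to the curated lists matters more than
taxonomic purity; they overlap substantially with the opioid/overdose flags
used by CDC drug-overdose surveillance.

Matching rules (`count_term_matches()`):

* case-insensitive, with a word boundary required on **both** sides of every
  term — "OD" never fires inside "body" or "blood";
* `intox` alone is a **left-anchored prefix** so that "intoxicated" and
  "intoxication" match; the package treats this as the only prefix term
  because it is the only list entry that is a morphological stem;
* multi-word terms ("Tylenol 3") match across any single whitespace run, and
  numerals count as word characters for boundary purposes;
* counting is non-overlapping with longest-match preference, so "oxycodone"
  is one match, never "oxy" plus a remainder.

The feature layout is one **integer count** per (term set × field): 12
columns for the default sets over the six text fields (call nature, primary
impression, chief complaint, chief narrative, medication list, medical
history). Counts, not binary flags, are used because error analysis of this
approach shows that behavior like denying several named opioids *raises*
the count — a property a binary flag cannot express and a classifier can
learn to discount. The per-field layout (rather than a per-record total)
lets importance analysis localize signal, e.g. opioid terms in the chief
narrative versus the medication list. No stemming, lemmatization, spelling
correction, or negation handling is attempted; the approach is deliberately
lexical, and its documented failure modes (below) follow from that.

## Comparison featurizers

**TF-IDF** (`fit_tfidf()` / `transform_tfidf()`): documents are the
concatenation of all six text fields — chosen for parity with the flag
featurizer; a narrative-only configuration is available. Tokens are word
runs of at least two characters, lowercased. The smoothed dialect
`idf(t) = ln((1 + N) / (1 + df(t))) + 1` with L2 row normalization is used
and documented here because the plain "tf × idf product" definition leaves
the smoothing unstated; test-set transforms reuse the training idf and
ignore out-of-vocabulary terms.

**Concept embeddings** (`vectorize_narrative()`): a pluggable
surface-to-concept lexicon plus a concept-to-vector table stand in for a
UMLS-style concept model. Matching is case-insensitive, longest-match-first
and non-overlapping; the record vector is the unweighted mean of matched
concept vectors with multiplicity (the minimal aggregation rule; it is
recorded in reports). Only the chief narrative is vectorized — it is the one
field intended as a complete encounter summary, and restricting to it
limits the overfitting risk that embedding all fields invites. Real
pre-trained concept vectors can be supplied as TSV files
(`read_lexicon()`, `read_embeddings()`); the package ships a small
deterministic synthetic lexicon/table (`synthetic_concept_resources()`)
that carries no clinical semantics and exists so the pathway is testable
offline.

## Training protocol

Four architectures (`train_model()`): maximum-likelihood logistic
regression (optionally with a tiny ridge, default `1e-8` off, for separable
inputs), a single-hidden-layer feed-forward network with logistic output
(hidden size tuned over 1–10, weight decay over `10^[-5, 0]`), Gaussian
naive Bayes with a variance floor and a tuned kernel-density flag, and
gradient-boosted trees (rounds 50–300, depth 1–6, learning rate
`10^[-2, -0.5]`, row and column subsampling 0.5–1).

All models share one protocol: stratified k-fold cross-validation (default
k = 5, 10 repeats) with random-search hyperparameter optimization (default
30 draws) selected on AUROC. Every candidate is evaluated on the **same**
fold assignments within a repeat, so candidates are compared on identical
data. Ties go to the smaller model (a per-architecture complexity key),
then to the earlier draw. The winner is refit on all training rows.
Class imbalance is handled by stratified folds only — no resampling or
class weights. Everything is deterministic given the CV seed.

Out-of-fold predictions from the first repeat of the winning candidate are
retained on the model object: they are the stacking inputs.
`fit_ensemble()` fits an unpenalized logistic regression of the labels on
the base models' out-of-fold probabilities (probabilities, not logits —
the convention of linear model ensembling), so the combiner never sees an
in-sample base prediction. Collinear bases receive aliased coefficients
treated as zero, which leaves predictions well defined. Greedy
non-negative weighting is deliberately not implemented: the linear
approach is the one mirrored here.

## Evaluation

* `auroc()`: Mann–Whitney with ties counted one half, computed from
  midranks.
* `delong_ci()`: variance from placement values,
  `var(V10)/n1 + var(V01)/n0`, algebraically identical to the all-pairs
  structural-components computation; Wald CI truncated to [0, 1]. Perfect
  separation gives zero variance and a zero-width CI at the estimate — a
  degenerate but honest report. No paired test between correlated curves is
  provided; models are compared by overlapping CIs, and a paired DeLong
  test is a natural extension.
* `confusion_at_threshold()`: threshold 0.5 by default (exposed as a flag;
  reporting uses the predicted-class convention). Ratios with zero
  denominators are reported as unknown (`NA`), never as 0.
* `variable_importance()`: each column scored as a classifier on its own —
  raw AUROC plus the direction-agnostic score `max(auc, 1 − auc)`, because
  a count that is predictive in reverse is still informative. Constant
  columns score 0.5. Ranks break ties by column name.
* `parity_tests()`: per-group error rates (false negatives over condition
  positives; false positives over condition negatives) compared pairwise
  with the two-proportion chi-square test with Yates continuity correction
  — the common default of equality-of-proportions testing in this
  ecosystem. No multiplicity adjustment by default (Holm available),
  matching how such tests are usually reported in this setting.
* `icc()`: ICC(2,1) — two-way random effects, absolute agreement, single
  rater — from the two-way ANOVA mean squares, for inter-annotator
  reliability. A ratings matrix with no variance has an undefined ICC and
  is reported as unknown with a note.

## The synthetic cohort generator

`cohort_config()` / `generate_cohort()` emulate the documented structure of
an annotated EMS cohort; defaults are the package's reference study
conditions:

* n = 3000 records at 15% positive prevalence (matching a 438-in-2958
  annotated corpus), county strata weighted 1635 : 747 : 576;
* positives' ages uniform on 16–90; positive gender mix 71.9% male;
  ethnicity mix matching the documented positive shares;
* text fields are neutral clinical filler (validated at config time to
  contain **no** keyword match under the term-set rules, so planted counts
  are exactly recoverable — the generation-truth object and
  `truth_flag_counts()` give an exact oracle for the featurizer);
* positive records receive at least one opioid and one overdose term in
  field `f` with probability `field_signal[f]`, plus a Poisson number of
  extra terms. Defaults (narrative 0.60, impression 0.45, complaint 0.25,
  others 0.10) concentrate signal in the chief narrative and primary
  impression — the fields that dominate importance analyses — and leave
  roughly one positive in eight with no keyword at all. That calibration
  reflects the documented reality that a large minority of true overdoses
  are identified by annotators from context (symptoms, naloxone response)
  rather than named substances: near-certain signal probabilities would
  make every benchmark saturate at AUROC 1.0 and emulate none of the
  documented failure modes, whereas these defaults put flags models in the
  low-to-mid 0.9 range;
* five confounders at rates proportional to the documented 25 : 8 : 6 : 3 : 3
  error tally, rescaled to a total mass of 0.12: a negative gaining
  "Narcan" plus a no-improvement phrase; a negative with a detailed denial
  of three named opioids; a negative with opioid terms only in medical
  history or medication list; a positive whose narrative keywords are
  replaced by behavioral-health language; and a positive whose opioid terms
  are replaced by "unknown pain pills";
* negative-class keyword base rate defaults to 0 (a config knob): how often
  terms like "substance" appear innocuously in real negatives is not
  quantified anywhere usable, and a zero default keeps the featurizer
  oracle exact. This is a modeling choice, not a claim about real data.

What passing tests on this generator do **not** show: the filler text has
none of the linguistic structure of real narratives (templated phrases
suffice for featurizer testing), negatives are keyword-free by default, and
the confounder taxonomy is a stylized version of a much messier reality.
Synthetic benchmarks validate the machinery and its contracts, not
real-world performance.

## The benchmark

`run_benchmark()` executes the 3-featurizer × 4-architecture grid plus a
linear ensemble per featurizer — 15 cells — on a single stratified 80/20
split shared by every cell, so feature methods are compared on identical
held-out records. Each cell reports AUROC with a DeLong 95% CI; the report
carries the best ensemble's confusion table and the flags features'
per-predictor importance, and is a byte-deterministic function of the
config. `select_annotation_batch()` implements model-assisted oversampling
for annotation: equal-sized samples of predicted positives and negatives at
threshold 0.5, order-randomized, with the predicted class withheld to a
sealed side-file so annotators are blinded. `stopping_rule()` ends
annotation rounds once some cell's CI lower endpoint reaches 0.90; the
bound is configurable because reasonable protocols could also bound the
point estimate, and the choice should be explicit.

Problem sizes used by the shipped test suite and the acceptance script:
the default benchmark runs the full 15-cell grid at n = 3000 with CV sized
k = 5, repeats = 2, search_n = 4 (the GLM has no tunable parameters and the
naive-Bayes grid has two points, so those cells are unaffected by the
search budget); oracle-equivalence suites use 1000 random texts and
200-instance AUROC batches; interval calibration uses 1000 binormal
simulations at true AUROC 0.8 with 100 cases per class. These sizes are the
package's reference experiment and keep a full run on one core in the
low minutes.

## Numerical and degenerate-input choices

Empty text fields featurize to zero counts (records are never dropped).
Splits use per-stratum half-up rounding with any remainder against the
overall target resolved in the largest stratum. The naive-Bayes variance
floor is `max(1e-6, 0.001 × column sd)`; kernel densities fall back to the
Gaussian for within-class constant features and density evaluations are
floored at `1e-10` before logs. The neural network is fit by `nnet` but
predictions always go through the package's own forward pass from the
stored weight vector, so a model restored from JSON predicts identically to
the in-session object. GLM coefficients for aliased (perfectly collinear)
columns are treated as zero. All randomness flows from explicit seeds
through a deterministic seed-derivation chain; user RNG state is saved and
restored around every internal draw.

## Known limitations

The classifier is lexical: it cannot relate "Narcan" to a subsequent
response, detect negation, or recognize unnamed products ("blue pills") —
the documented main sources of false negatives and false positives for
this approach. The generator inherits those limits in stylized form. ICC
confidence intervals are not computed (only the point estimate), and no
paired DeLong test between correlated models is provided.
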