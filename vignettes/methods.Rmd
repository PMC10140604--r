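---
title: "Registry-supervised oncology abstraction: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registry-supervised oncology abstraction: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A cancer registry stores, per patient, structured attribute values — tumor
site and histology codes, and coarse clinical/pathologic TNM staging (T in
0–4 or *in situ*; N in 0 vs 1+; M in 0 vs 1) — that human registrars
abstract from free-text clinical documentation. The evidence for one
patient is scattered across many documents: the tumor location is typically
described in an imaging report, the malignant diagnosis in a pathology
report, and pathologic staging in an operative/resection report weeks
later. OncoAbstract treats abstraction as *patient-level* classification:
for each attribute, the input is the patient's pathology, radiology and
operative notes inside a day window around diagnosis, concatenated
chronologically and split into sentences, and the label is the registry
value (with `"NULL"` for "not documented"). No sentence- or span-level
annotation is used anywhere: the registry label is the only supervision,
and the model is expected to find the pertinent sentences itself.

## Model

The classifier is a three-stage hierarchy matching that problem structure:

1. **Sentence encoding.** Each sentence (subword-tokenized; sentences
   longer than `max_tokens` are split into fragments encoded separately) is
   encoded by a small trainable transformer — 2 layers, 2 heads, width 64,
   learned position embeddings, post-layer-norm blocks — and pooled at a
   summary position prepended to every fragment. The summary position's
   final-layer self-attention row, averaged over heads and renormalized
   over the sentence's tokens, is kept as the token-level importance
   signal. The encoder is a pluggable contract (any map from a token
   sequence to one pooled vector plus simplex token weights would do); the
   bundled one is trained from scratch because the package's corpora are
   synthetic and small. Pretrained-checkpoint loading would slot in at the
   same interface but is not a requirement here.
2. **Contextualization.** A bidirectional GRU runs over the sentence
   vectors in chronological order, so every sentence representation sees
   the whole cross-document sequence — this is what lets evidence in one
   note (a site named only in the imaging report) combine with evidence in
   another (malignancy asserted only in pathology).
3. **Aggregation and classification.** Two levels of learned attention
   pool sentences into note vectors and note vectors into one patient
   vector (each weight set is a simplex within its group), followed by a
   linear layer and softmax over the attribute's full label list,
   `"NULL"` included. Cross-entropy on the patient-level label is
   minimized with Adam (batch 8, learning rate 2e-3), early-stopped on dev
   micro-AUPRC with patience 10 within a 50-epoch cap.

One model is trained per attribute; case finding reuses the identical
architecture with binary labels over patient-*days*. Forward and backward
passes are implemented in compiled code (RcppArmadillo) with analytically
derived gradients; a finite-difference check in the test suite validates
every parameter group.

### Numerical and tie-break conventions

* Argmax ties break toward the first label in schema order.
* Attention softmaxes subtract the within-group maximum before
  exponentiation; layer norm uses eps 1e-5.
* Dropout (default 0.1) applies to sentence vectors and the patient vector
  during training only, driven by the R RNG so a fixed seed reproduces a
  run bit-for-bit (single-threaded BLAS assumed, as installed).
* Zero-initialized recurrent blocks pass nothing: with the whole GRU
  parameter block zero the contextual outputs are constant across
  positions, which the tests use as a degenerate-parameter check.

## Subword vocabulary

The tokenizer lowercases, splits words at non-alphanumerics, and applies
greedy pair merging induced from the training corpus (most frequent
adjacent symbol pair merged repeatedly; ties broken lexicographically so
induction is deterministic), capped at 2,000 units by default. Unseen
units map to `[UNK]`. At desk scale the cap is rarely reached; the knob
exists because the vocabulary is rebuilt per training corpus.

## Windows

Notes are selected in a closed day interval around the diagnosis date,
`[-30, 30]` by default. Pathologic staging evidence comes from resection
reports that can trail the diagnostic biopsy by weeks, so `[-30, 90]` is
the appropriate window there; the package exposes the window as an argument
and the acceptance suite measures the ablation both ways. Intra-day order
is note-id-lexicographic (nothing in the data model orders same-day notes
otherwise); dates are ISO-8601 calendar dates and offsets are 0-based,
half-open, over Unicode code points.

## The synthetic corpus generator

No public corpus of linked notes and registry labels exists (EMR data is
private), so the generator is a first-class module that emulates the
structures the method must handle, via deterministic template realization
(never a generative language model — determinism and manifest traceability
are the point):

* **Cross-document evidence.** Each cancer patient gets a radiology note
  (day −7..−1) carrying the site mention and clinical staging phrases, a
  pathology note (day 0) carrying the histology and malignancy assertion,
  and, usually, an operative note (day 5..60 by default) carrying
  pathologic staging. With probability `p_split_evidence` the site term
  appears *only* in the radiology note while the malignancy assertion
  appears only in pathology — the integration case.
* **Negated distractors.** With probability `p_distractor_site` per note, a
  negated organ review is inserted: 2–4 wrong sites, each negated once or
  twice ("No evidence of malignancy in the liver."), as radiology reports
  carry routinely. This is the designed trap for mention counting: the
  negated organs can outnumber the single true-site mention, so an
  assertion-blind lexicon matcher is systematically misled while a
  sentence-level encoder can read the negation.
* **Epidemiology-shaped labels.** Sites follow a Zipf distribution
  (rank-1/k), mirroring the imbalance that motivates AUPRC reporting, and
  histology is sampled *conditional on site* (hepatocellular carcinoma in
  liver, urothelial carcinoma in bladder, ...), so histology terms carry
  legitimate correlated signal about site, as in real data. The histology
  marginal is therefore the site-Zipf mixture of those conditionals rather
  than an independent Zipf.
* **Surface variation.** Each label has several lexicon aliases; evidence
  realization draws them Zipf-weighted, the canonical form dominating, as
  surface forms do in practice.
* **Pre-diagnosis notes.** With probability `p_prediagnosis_note` a cancer
  patient has a hedged note 8–365 days before diagnosis — hedged imaging
  ("cannot rule out malignancy") or an inconclusive biopsy/cytology report
  naming the eventual histology under uncertainty cues ("suspicious for",
  "definitive diagnosis deferred"). These days are the substrate for hard
  negatives in case finding.
* **Noise knobs.** `label_noise_rate` replaces registry labels with random
  wrong ones (the clean labels are retained separately for evaluation);
  `p_missing_note` drops radiology/operative notes. The pathology note is
  never dropped: it anchors the diagnosis day, and case-finding positives
  would otherwise vanish.
* **Manifest.** Every planted evidence span is recorded with note id,
  character offsets, attribute and label; each span literally contains a
  lexicon alias of its label. The manifest is what rationale-alignment
  tests and the noiseless-oracle invariant check against.

What the generator does **not** emulate: realistic clinical style and
discourse, multi-tumor patients, genuinely out-of-lexicon paraphrase,
OCR/layout noise, longitudinal treatment narratives, non-English text.
Passing tests on this corpus show that the architecture integrates
split evidence, reads negation and hedging, survives label noise, and
orders systems the expected way — not that it reaches any particular
accuracy on real notes.

## Baselines

* **Ontology**: case-insensitive, word-boundary-anchored, longest-first
  alias matching; prediction is the most frequently matched label (ties:
  earliest match), probabilities are normalized match counts, no match
  gives `"NULL"`. Deliberately negation-blind.
* **BOW**: multinomial logistic regression (ridge-penalized, fitted with
  glmnet along its regularization path and read out at lambda 0.01) on
  token *presence* features of the concatenated instance text minus a small
  stopword list. Binary presence was chosen over raw counts after measuring
  both: clinical notes repeat negated mentions routinely (a negated organ
  review names a wrong organ once or twice per note), so raw counts hand
  the learned baseline the same mention-frequency failure mode that defines
  the lexicon matcher, whereas presence features let it be a credible
  reference system; `binary = FALSE` restores raw counts. Classes with
  fewer than two training instances cannot be fitted by the solver and are
  dropped from the fit (they then score zero).

## Case finding

An instance is all of one patient's notes on one day. Positives are
diagnosis-day instances of cancer patients. Default negatives: one random
documented day per non-cancer patient. The hard-negative scheme adds each
cancer patient's documented days at offsets in `[-365, -8]` (capped,
default 3 per patient). Evaluation is patient-level: the first flagged day
must fall in the closed `[-7, 30]` window around diagnosis. A cancer
patient flagged only outside the window counts as *both* a false negative
(the case was missed) and a false positive (a spurious alarm was raised);
the evaluation needs an explicit precision/recall bookkeeping and this
rule is applied consistently and printed in the decision table as
`"FN+FP"`. F1 is the harmonic mean, 0 when undefined.

## Metrics

Micro AUROC and micro AUPRC flatten (instance, label) cells one-vs-rest and
pool everything. AUROC is the tie-aware pairwise probability (computed via
midranks). AUPRC is average precision with step interpolation, tie blocks
processed whole — chosen over trapezoidal interpolation as the standard,
conservative convention. `"NULL"` participates as an ordinary class by
default (an `exclude_null` toggle exists). Both implementations are tested
against brute-force oracles (exhaustive pair comparison; threshold-walking
step sum) on thousands of random tables. The fairness audit computes a
metric per demographic subgroup and flags any subgroup under 80% of the
reference ("disparate impact" screen); subgroups below a minimum size
(default 100) are annotated unstable, since their ratios are dominated by
sampling noise.

## Rationale extraction

Token, sentence and note attention compose multiplicatively into one
probability distribution over the instance's tokens — multiplicative
combination is the one choice that preserves the simplex across levels.
Subword weights are summed within words so every reported span carries
exact character offsets into its source note. The package reports how often
the top-weighted sentence coincides with a manifest-planted evidence span
(the alignment rate), and ships a counterfactual probe that swaps the
planted site alias for another site's and checks whether the prediction
moves — reported as a rate, not gated, since attention weights are an
explanation heuristic, not a guarantee.

## Problem sizes and evaluation design

The reference experiments run on generated corpora of 400 cancer + 100
non-cancer patients for abstraction (≈280 training patients after the
70/15/15 patient-level split), 150+150 for case finding, and 250+50 for
the window ablation — sizes at which every property of interest (noiseless
learnability above 0.95 micro-AUROC, the ontology < BOW < hierarchical
ordering, the hard-negative gain, the window-ablation direction, noise
robustness) is comfortably measurable while a full training run stays in
the tens of seconds on one CPU. The full-scale phenomenon these mirror
comes from private registry-linked EMR corpora orders of magnitude larger;
nothing here attempts to reproduce absolute numbers from such data, only
the directions and the machinery.

## Known limitations

* The 10-fold patient partition of the original protocol is simplified to
  one seeded train/dev/test split; fold bookkeeping adds no behavior worth
  testing here.
* Near-duplicate notes (addenda, amended reports) are not deduplicated
  before concatenation.
* The GRU runs over sentence vectors, not tokens; the source description
  admits either reading, and sentence-level recurrence is what makes
  long cross-document inputs tractable.
* The multinomial softmax head is the implementation; per-label binary
  probabilities are exposed as a read-out of it.
* Attention-based rationales are a heuristic; beyond manifest alignment
  and the counterfactual probe, faithfulness is out of scope.
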