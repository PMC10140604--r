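# OncoAbstract

Registry-supervised abstraction of structured oncology attributes from a
patient's full stream of clinical notes, in R.

Cancer registries record, per patient, structured values — tumor site and
histology codes and coarse TNM staging (T ∈ {0..4, is}, N ∈ {0, 1+},
M ∈ {0, 1}) — that registrars abstract by reading free-text pathology,
radiology and operative notes. The evidence is scattered: the site is
typically named in an imaging report, the malignant diagnosis asserted in a
pathology report, pathologic staging in a resection report weeks later, and
the text is full of negated mentions ("no evidence of malignancy in the
liver") and hedges ("cannot rule out"). OncoAbstract is for NLP/clinical
informatics researchers who want a complete, testable desk-scale
implementation of cross-document abstraction under *patient-level* (distant)
supervision: the registry label is the only training signal, with no span
or sentence annotation anywhere.

## What is inside

* **Hierarchical attention classifier** — for each attribute, the
  patient's in-window notes are concatenated chronologically and sentence
  segmented; a small trainable transformer encodes each sentence (pooled at
  a summary position whose self-attention row gives token importances), a
  bidirectional GRU propagates information across sentences and documents,
  two levels of learned attention pool sentences → notes → one patient
  vector, and a linear+softmax head produces multinomial probabilities over
  the label list (`"NULL"` included):

  p(a | T) = softmax(W · HAN(BiGRU(Enc(s₁), …, Enc(sₙ))))

  Training is cross-entropy with Adam, early-stopped on dev micro-AUPRC.
  Forward and analytic backward passes are compiled (RcppArmadillo) and
  gradient-checked in the test suite.
* **Case finding** — patient-day binary classification with the same
  architecture; self-supervision either from non-cancer patients' days
  (default) or additionally from cancer patients' documented days 8–365
  days *before* diagnosis (hard negatives). Patient-level evaluation: the
  first flagged day must fall in [−7, 30] days of diagnosis;
  F1 = 2/(1/precision + 1/recall).
* **Baselines** — an ontology/lexicon matcher (longest-match-first,
  deliberately negation-blind) and bag-of-words multinomial logistic
  regression (glmnet ridge).
* **Metrics** — micro-averaged AUROC (tie-aware), AUPRC (average
  precision, tie blocks whole), accuracy, and a disparate-impact (80%
  rule) fairness audit with small-subgroup annotation.
* **Rationale extraction** — token × sentence × note attention composed
  into one probability distribution over tokens, emitted as
  provenance-bearing character spans.
* **Synthetic corpus generator** — seeded, template-based patients with
  split evidence, negated organ-review distractors, hedged pre-diagnosis
  notes, label noise and a ground-truth evidence manifest. All sampling is
  byte-reproducible from one seed.

## Worked example

```r
library(OncoAbstract)

cfg <- syntheticConfig(n_cancer = 120, n_noncancer = 30, seed = 42)
syn <- generateCorpus(cfg)
syn
#> SyntheticCorpus (seed 42 )
#> ClinicalCorpus: 150 patients ( 120 cancer / 30 non-cancer ), 537 notes
#>   split: dev=22 test=23 train=105
#>   manifest: 875 planted evidence spans; 0 patients with corrupted labels

cc    <- corpus(syn)
site  <- defaultSchemas()$site
train <- buildAbstractionInstances(cc, "site", split = "train")
dev   <- buildAbstractionInstances(cc, "site", split = "dev")
test  <- buildAbstractionInstances(cc, "site", split = "test")

model <- trainHierModel(train, schemaLabels(site),
                        hierModelConfig(seed = 1), dev_instances = dev)
model
#> HierModel for 'site' - 13 labels, 105101 parameters, 31 epochs trained

s <- scoreInstances(model, test)
sprintf("test micro-AUROC %.3f | micro-AUPRC %.3f | accuracy %.3f",
        microAUROC(s$truth, s$scores), microAUPRC(s$truth, s$scores),
        mean(s$predicted == s$truth))
#> "test micro-AUROC 0.964 | micro-AUPRC 0.870 | accuracy 0.762"

predictHier(model, test[[1]])
#> Prediction C00010 / site :  LUNG (p=0.969)

head(extractRationale(model, test[[1]], top_k = 3))
#>     note_id sentence_index start end      token     weight
#> 1 C00010-01              3   146 150       lung 0.51974725
#> 2 C00010-02              2   100 104       lung 0.40527254
#> 3 C00010-01              2    99 109 pancreatic 0.02938819
```

The micro scores pool every (patient, label) decision one-vs-rest, so
frequent sites dominate proportionally — the reason AUPRC is reported
alongside AUROC under the Zipf-imbalanced label distribution. The rationale
table says the prediction leaned on the token "lung" in two different
notes, with exact character offsets into each source note.

Case finding, baselines, the fairness audit and the window ablation follow
the same pattern; see the methods vignette (`vignettes/methods.Rmd`) for
the model, the generator's design and its limitations, and every numerical
convention. A thin command-line front end over the same functions ships in
`inst/scripts/oncoabstract` (generate / train / predict / baseline /
casefind-train / casefind-eval / rationale).

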