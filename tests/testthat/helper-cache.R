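# Heavy shared objects (corpora, trained models) built once per test session.
.tcache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.tcache[[key]])) .tcache[[key]] <- force(expr)
  .tcache[[key]]
}

# the noiseless learnability corpus: 400 cancer + 100 non-cancer patients,
# evidence split across notes for half the patients, no label noise
noiseless_corpus <- function() cached("noiseless", generateCorpus(
  syntheticConfig(n_cancer = 400, n_noncancer = 100, p_split_evidence = 0.5,
                  label_noise_rate = 0, seed = 11)))

noiseless_site_model <- function() cached("site_model", {
  cc <- corpus(noiseless_corpus())
  tr <- buildAbstractionInstances(cc, "site", split = "train")
  dv <- buildAbstractionInstances(cc, "site", split = "dev")
  trainHierModel(tr, schemaLabels(defaultSchemas()$site),
                 hierModelConfig(seed = 5), dev_instances = dv)
})

noiseless_site_test <- function() cached("site_test",
  buildAbstractionInstances(corpus(noiseless_corpus()), "site", split = "test"))

# independent O(n^2)/step-sum metric oracles (never share code with the
# package implementations)
oracle_auroc <- function(y, s) {
  pos <- s[y == 1L]; neg <- s[y == 0L]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

oracle_auprc <- function(y, s) {
  # walk thresholds (unique scores, descending); AP = sum over threshold
  # steps of precision * added recall, counting from scratch each time
  th <- sort(unique(s), decreasing = TRUE)
  P <- sum(y == 1L)
  ap <- 0; prev_rec <- 0
  for (t in th) {
    sel <- s >= t
    prec <- sum(y[sel] == 1L) / sum(sel)
    rec <- sum(y[sel] == 1L) / P
    ap <- ap + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  ap
}
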