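test_that("zero patients give an empty corpus without error", {
  sc <- generateCorpus(syntheticConfig(n_cancer = 0, n_noncancer = 0, seed = 1))
  expect_equal(nrow(notes(corpus(sc))), 0L)
  expect_equal(nrow(registry(corpus(sc))), 0L)
  expect_equal(nrow(manifest(sc)), 0L)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- syntheticConfig(n_cancer = 30, n_noncancer = 10, seed = 7)
  a <- generateCorpus(cfg); b <- generateCorpus(cfg)
  expect_identical(notes(corpus(a)), notes(corpus(b)))
  expect_identical(registry(corpus(a)), registry(corpus(b)))
  expect_identical(manifest(a), manifest(b))
  expect_identical(corpusSplit(corpus(a)), corpusSplit(corpus(b)))
})

test_that("manifest spans literally contain the lexicon alias for the label", {
  sc <- generateCorpus(syntheticConfig(n_cancer = 40, n_noncancer = 5, seed = 9))
  nt <- notes(corpus(sc)); mf <- manifest(sc)
  schemas <- defaultSchemas()
  expect_gt(nrow(mf), 0)
  for (i in seq_len(nrow(mf))) {
    txt <- nt$text[nt$note_id == mf$note_id[i]]
    piece <- tolower(substr(txt, mf$start[i] + 1, mf$end[i]))
    expect_identical(piece, tolower(mf$alias[i]))
    expect_true(tolower(mf$alias[i]) %in%
                  tolower(schemaLexicon(schemas[[mf$attribute[i]]])[[mf$label[i]]]))
  }
})

test_that("with p_split_evidence = 1 site and diagnosis evidence never share a note", {
  sc <- generateCorpus(syntheticConfig(n_cancer = 200, n_noncancer = 0,
                                       p_split_evidence = 1, seed = 13))
  mf <- manifest(sc)
  for (pid in unique(mf$patient_id)) {
    m <- mf[mf$patient_id == pid, ]
    site_notes <- m$note_id[m$attribute == "site"]
    hist_notes <- m$note_id[m$attribute == "histology"]
    expect_length(intersect(site_notes, hist_notes), 0L)
  }
})

test_that("a manifest oracle reaches 100% accuracy on the noiseless corpus", {
  sc <- generateCorpus(syntheticConfig(n_cancer = 50, n_noncancer = 10,
                                       p_missing_note = 0,
                                       label_noise_rate = 0, seed = 17))
  mf <- manifest(sc); rg <- registry(corpus(sc))
  for (a in OncoAbstract:::ATTRIBUTES) {
    m <- mf[mf$attribute == a, ]
    for (pid in unique(m$patient_id)) {
      lab <- unique(m$label[m$patient_id == pid])
      expect_length(lab, 1L)
      expect_identical(lab, rg[[a]][rg$patient_id == pid])
    }
  }
})

test_that("site marginals follow the Zipf class distribution", {
  sc <- generateCorpus(syntheticConfig(n_cancer = 600, n_noncancer = 0,
                                       notes_mean = 3, seed = 19))
  rg <- registry(corpus(sc))
  sites <- setdiff(schemaLabels(defaultSchemas()$site), "NULL")
  p <- (1 / seq_along(sites)) / sum(1 / seq_along(sites))
  obs <- as.integer(table(factor(rg$site, levels = sites)))
  # each count within 5 binomial standard deviations of expectation
  for (k in seq_along(sites)) {
    mu <- 600 * p[k]; sd <- sqrt(600 * p[k] * (1 - p[k]))
    expect_lt(abs(obs[k] - mu), 5 * sd + 1)
  }
})

test_that("corruptLabels follows the requested rate", {
  sc <- generateCorpus(syntheticConfig(n_cancer = 60, n_noncancer = 0, seed = 23))
  rg <- registry(corpus(sc))
  same <- corruptLabels(rg, 0, seed = 1)
  expect_identical(same$registry, rg)
  expect_length(same$corrupted_ids, 0L)

  all_changed <- corruptLabels(rg, 1, seed = 2)
  changed <- !is.na(rg$site) &
    (is.na(all_changed$registry$site) | all_changed$registry$site != rg$site)
  expect_true(all(changed[!is.na(rg$site)]))

  # rate 0.1 on 1000 site labels: corrupted count in the binomial 99% band
  big <- rg[rep(seq_len(nrow(rg)), length.out = 1000), ]
  big$patient_id <- sprintf("Q%04d", seq_len(1000))
  for (a in setdiff(OncoAbstract:::ATTRIBUTES, "site")) big[[a]] <- NA_character_
  out <- corruptLabels(big, 0.1, seed = 3)
  ndiff <- sum(is.na(out$registry$site) | out$registry$site != big$site)
  expect_gte(ndiff, 72); expect_lte(ndiff, 130)
  expect_equal(length(out$corrupted_ids), ndiff)
})
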