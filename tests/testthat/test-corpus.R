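test_that("readCorpus parses the toy fixture field by field", {
  dir <- write_toy_corpus_files()
  cc <- readCorpus(file.path(dir, "notes.jsonl"), file.path(dir, "registry.csv"))
  expect_s4_class(cc, "ClinicalCorpus")
  expect_equal(nrow(registry(cc)), 2L)
  expect_length(corpusSplit(cc), 0L)   # unassigned
  nt <- notes(cc)
  expect_equal(nt$patient_id, c("P1", "P1", "P2"))
  expect_equal(nt$note_type, c("radiology", "pathology", "radiology"))
  expect_equal(nt$date[1], as.Date("2020-01-05"))
  rg <- registry(cc)
  expect_equal(rg$site[rg$patient_id == "P1"], "LUNG")
  expect_equal(rg$clinical_T[rg$patient_id == "P1"], "2")
  expect_true(is.na(rg$diagnosis_date[rg$patient_id == "P2"]))
  expect_true(all(is.na(unlist(rg[rg$patient_id == "P2",
                                  c("site", "histology", "clinical_M")]))))
})

test_that("empty files give an empty corpus", {
  nf <- tempfile(); rf <- tempfile()
  writeLines(character(), nf)
  writeLines(paste(OncoAbstract:::REGISTRY_COLS, collapse = ","), rf)
  cc <- readCorpus(nf, rf)
  expect_equal(nrow(notes(cc)), 0L)
  expect_equal(nrow(registry(cc)), 0L)
})

test_that("malformed inputs are reported with line numbers and field names", {
  dir <- write_toy_corpus_files()
  nf <- file.path(dir, "bad_notes.jsonl")
  writeLines(c('{"patient_id":"P1","note_id":"N1","note_type":"radiology","date":"2020-01-05","text":"ok."}',
               '{"patient_id":"P1","note_id":"N2","note_type":"radiology","text":"missing date."}'),
             nf)
  expect_error(readCorpus(nf, file.path(dir, "registry.csv")),
               "line 2.*'date'|'date'.*line 2")
  nf2 <- file.path(dir, "bad_date.jsonl")
  writeLines('{"patient_id":"P1","note_id":"N1","note_type":"radiology","date":"Jan 5 2020","text":"x."}',
             nf2)
  expect_error(readCorpus(nf2, file.path(dir, "registry.csv")),
               "format error.*ISO-8601")
  rf <- file.path(dir, "bad_registry.csv")
  writeLines(c(paste(OncoAbstract:::REGISTRY_COLS, collapse = ","),
               "P1,2020-01-10,LUNG,ADENOCARCINOMA,7,,,,,,f,g"), rf)
  expect_error(readCorpus(file.path(dir, "notes.jsonl"), rf),
               "clinical_T.*'7'.*0, 1, 2, 3, 4, is")
})

test_that("write/read round trip reproduces the corpus field for field", {
  sc <- generateCorpus(syntheticConfig(n_cancer = 6, n_noncancer = 3, seed = 2))
  cc <- corpus(sc)
  nf <- tempfile(); rf <- tempfile()
  writeCorpus(cc, nf, rf)
  back <- readCorpus(nf, rf)
  expect_equal(notes(back), notes(cc))
  expect_equal(registry(back), registry(cc))
})

test_that("selectWindow keeps the closed interval and orders notes", {
  dx <- as.Date("2020-06-01")
  offs <- c(-40, -10, 0, 30, 35)
  nt <- make_note_df("P1", sprintf("N%02d", seq_along(offs)), "radiology",
                     dx + offs, "Text here.")
  sel <- selectWindow(nt, dx, c(-30, 30))
  expect_equal(as.integer(sel$date - dx), c(-10, 0, 30))
  sel2 <- selectWindow(nt, dx, c(-30, 90))
  expect_equal(as.integer(sel2$date - dx), c(-10, 0, 30, 35))
  expect_equal(nrow(selectWindow(nt[0, ], dx, c(-30, 30))), 0L)
  expect_error(selectWindow(nt, as.Date(NA), c(-30, 30)), "cancer")
  expect_error(selectWindow(nt, dx, c(30, -30)), "lo <= hi")
  # same-day ties break by note_id
  nt2 <- make_note_df("P1", c("B", "A"), "radiology", dx, "Text here.")
  expect_equal(selectWindow(nt2, dx, c(0, 0))$note_id, c("A", "B"))
})

test_that("window monotonicity: enlarging the window never drops a note", {
  set.seed(42)
  dx <- as.Date("2019-01-01")
  for (rep in 1:20) {
    offs <- sample(-100:100, 12)
    nt <- make_note_df("P", sprintf("N%03d", 1:12), "radiology", dx + offs, "T.")
    w1 <- sort(sample(-60:60, 2))
    w2 <- c(w1[1] - sample(0:20, 1), w1[2] + sample(0:20, 1))
    s1 <- selectWindow(nt, dx, w1)
    s2 <- selectWindow(nt, dx, w2)
    expect_true(all(s1$note_id %in% s2$note_id))
  }
})

test_that("segmentSentences produces exact offsets and reconstructable spans", {
  segs <- segmentSentences("No tumor seen. Margins clear.")
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$start, c(0L, 15L))
  expect_equal(segs$end, c(14L, 29L))
  expect_equal(segs$text, c("No tumor seen.", "Margins clear."))

  one <- segmentSentences("no terminal punctuation here")
  expect_equal(nrow(one), 1L)
  expect_equal(one$text, "no terminal punctuation here")

  hdr <- segmentSentences("FINDINGS:\nThe lung is clear. No nodules.")
  expect_equal(hdr$text, c("FINDINGS:", "The lung is clear.", "No nodules."))

  expect_equal(nrow(segmentSentences("   \n \n")), 0L)

  # offsets always slice the literal substring, on arbitrary generated text
  set.seed(7)
  sc <- generateCorpus(syntheticConfig(n_cancer = 8, n_noncancer = 4, seed = 3))
  for (txt in notes(corpus(sc))$text) {
    segs <- segmentSentences(txt)
    expect_true(all(substr(rep(txt, nrow(segs)), segs$start + 1, segs$end) ==
                      segs$text))
  }
})

test_that("abstraction instances order sentences chronologically across notes", {
  dx <- as.Date("2020-01-10")
  nt <- rbind(
    make_note_df("P1", "P1-PATH", "pathology", dx, "Malignant cells present."),
    make_note_df("P1", "P1-RAD", "radiology", dx - 5, "Mass in the lung."))
  rg <- registry(corpus(generateCorpus(syntheticConfig(0, 0, seed = 1))))
  rg <- rbind(rg, data.frame(patient_id = "P1", diagnosis_date = dx,
                             site = "LUNG", histology = NA, clinical_T = NA,
                             clinical_N = NA, clinical_M = NA,
                             pathologic_T = NA, pathologic_N = NA,
                             pathologic_M = NA, gender = "f", ethnicity = "g",
                             stringsAsFactors = FALSE))
  cc <- new("ClinicalCorpus", notes = nt, registry = rg, split = character())
  inst <- buildAbstractionInstances(cc, "site")
  expect_length(inst, 1L)
  s <- inst[[1]]@sentences
  expect_equal(unique(s$note_id), c("P1-RAD", "P1-PATH"))  # radiology first
  expect_equal(inst[[1]]@label, "LUNG")
  expect_error(buildAbstractionInstances(cc, "grade"),
               "unknown attribute.*site")
})

test_that("patients with all notes outside the window are skipped", {
  sc <- generateCorpus(syntheticConfig(n_cancer = 3, n_noncancer = 0, seed = 5))
  cc <- corpus(sc)
  nt <- notes(cc); rg <- registry(cc)
  # push every note of the first patient out of range
  pid <- rg$patient_id[1]
  nt$date[nt$patient_id == pid] <- rg$diagnosis_date[1] + 400
  cc2 <- new("ClinicalCorpus", notes = nt, registry = rg, split = corpusSplit(cc))
  inst <- buildAbstractionInstances(cc2, "site")
  expect_length(inst, 2L)
  expect_equal(attr(inst, "skipped"), pid)
})

test_that("instance sentence offsets always slice valid note text", {
  sc <- generateCorpus(syntheticConfig(n_cancer = 10, n_noncancer = 3, seed = 8))
  cc <- corpus(sc)
  nt <- notes(cc)
  for (inst in buildAbstractionInstances(cc, "histology")) {
    s <- inst@sentences
    for (i in seq_len(nrow(s))) {
      txt <- nt$text[nt$note_id == s$note_id[i]]
      expect_identical(substr(txt, s$start[i] + 1, s$end[i]), s$text[i])
    }
  }
})

test_that("split is a partition of patients", {
  sc <- generateCorpus(syntheticConfig(n_cancer = 40, n_noncancer = 10, seed = 4))
  sp <- corpusSplit(corpus(sc))
  rg <- registry(corpus(sc))
  expect_setequal(names(sp), rg$patient_id)
  expect_false(anyDuplicated(names(sp)) > 0)
  expect_true(all(sp %in% c("train", "dev", "test")))
})
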