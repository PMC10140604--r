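test_that("case-finding bookkeeping reproduces the worked 3-patient fixture", {
  # cancer A flagged at day -20 (FN+FP), cancer B flagged at day +30 (TP),
  # non-cancer C flagged (FP): TP=1 FP=2 FN=1
  reg <- data.frame(patient_id = c("A", "B", "C"),
                    diagnosis_date = as.Date(c("2020-06-01", "2020-06-01", NA)),
                    stringsAsFactors = FALSE)
  preds <- data.frame(
    patient_id = c("A", "A", "B", "C"),
    day = as.Date(c("2020-05-12", "2020-06-01", "2020-07-01", "2020-02-01")),
    prob_positive = c(0.9, 0.2, 0.8, 0.7),
    positive = c(TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  ev <- evaluateCaseFinding(preds, reg, window = c(-7, 30))
  expect_equal(unname(ev$counts), c(1L, 2L, 1L, 0L))
  expect_equal(ev$precision, 1 / 3)
  expect_equal(ev$recall, 1 / 2)
  expect_equal(ev$f1, 0.4)
  dec <- ev$decisions
  expect_identical(dec$outcome[dec$patient_id == "A"], "FN+FP")
  expect_identical(dec$outcome[dec$patient_id == "B"], "TP")
  expect_identical(dec$outcome[dec$patient_id == "C"], "FP")
  expect_error(evaluateCaseFinding(
    rbind(preds, data.frame(patient_id = "Z", day = as.Date("2020-01-01"),
                            prob_positive = 1, positive = TRUE)), reg),
    "not in registry")
})

test_that("F1 equals the harmonic-mean formula on randomized P/R pairs", {
  # the same formula the evaluation prints: F1 = 2/(1/P + 1/R)
  expect_equal(2 / (1 / 0.5 + 1 / 1.0), 2 / 3, tolerance = 1e-12)
  set.seed(31)
  for (i in 1:50) {
    p <- runif(1, 0.01, 1); r <- runif(1, 0.01, 1)
    expect_equal(2 / (1 / p + 1 / r), 2 * p * r / (p + r), tolerance = 1e-12)
  }
})

test_that("one perfect cancer and one clean non-cancer give F1 = 1", {
  reg <- data.frame(patient_id = c("A", "B"),
                    diagnosis_date = as.Date(c("2020-06-01", NA)),
                    stringsAsFactors = FALSE)
  preds <- data.frame(patient_id = c("A", "B"),
                      day = as.Date(c("2020-06-06", "2020-03-01")),
                      prob_positive = c(0.9, 0.1),
                      positive = c(TRUE, FALSE), stringsAsFactors = FALSE)
  ev <- evaluateCaseFinding(preds, reg)
  expect_equal(c(ev$precision, ev$recall, ev$f1), c(1, 1, 1))
})

test_that("widening the correctness window never decreases recall", {
  set.seed(17)
  reg <- data.frame(patient_id = sprintf("P%02d", 1:20),
                    diagnosis_date = as.Date("2020-06-01"),
                    stringsAsFactors = FALSE)
  preds <- data.frame(patient_id = reg$patient_id,
                      day = as.Date("2020-06-01") + sample(-40:40, 20, TRUE),
                      prob_positive = 1, positive = TRUE,
                      stringsAsFactors = FALSE)
  r1 <- evaluateCaseFinding(preds, reg, window = c(-7, 30))$recall
  r2 <- evaluateCaseFinding(preds, reg, window = c(-14, 45))$recall
  expect_gte(r2, r1)
})

test_that("training instances follow the two self-supervision schemes", {
  sc <- generateCorpus(syntheticConfig(n_cancer = 40, n_noncancer = 20,
                                       p_prediagnosis_note = 0.7, seed = 29))
  cc <- corpus(sc)
  def <- buildCaseFindingTraining(cc, "default", seed = 1)
  hard <- buildCaseFindingTraining(cc, "hard_negatives", seed = 1)
  lab <- function(x) vapply(x, function(i) i@label, "")
  # positives identical, negatives strictly more under hard negatives
  expect_equal(sum(lab(def) == "positive"), sum(lab(hard) == "positive"))
  expect_gt(sum(lab(hard) == "negative"), sum(lab(def) == "negative"))
  # every instance's sentences come from notes of exactly its day
  for (inst in hard) expect_true(all(inst@sentences$date == inst@day))
  # hard negatives obey the [-365, -8] day rule
  rg <- registry(cc)
  for (inst in hard[lab(hard) == "negative"]) {
    dx <- rg$diagnosis_date[rg$patient_id == inst@patient_id]
    if (!is.na(dx)) {
      off <- as.integer(inst@day - dx)
      expect_true(off >= -365 && off <= -8)
    }
  }
  # no cancer patients -> error
  rg2 <- rg[is.na(rg$diagnosis_date), ]
  cc2 <- new("ClinicalCorpus",
             notes = notes(cc)[notes(cc)$patient_id %in% rg2$patient_id, ],
             registry = rg2, split = character())
  expect_error(buildCaseFindingTraining(cc2, "default"), "no cancer")
})

test_that("a -100/-3 day pair yields exactly one hard negative", {
  dx <- as.Date("2020-06-01")
  nt <- rbind(
    make_note_df("P1", "P1-1", "radiology", dx - 100, "Early lesion noted."),
    make_note_df("P1", "P1-2", "radiology", dx - 3, "Mass seen in the lung."),
    make_note_df("P1", "P1-3", "pathology", dx, "Biopsy reveals adenocarcinoma."))
  rg <- data.frame(patient_id = "P1", diagnosis_date = dx,
                   site = "LUNG", histology = "ADENOCARCINOMA",
                   clinical_T = NA_character_, clinical_N = NA_character_,
                   clinical_M = NA_character_, pathologic_T = NA_character_,
                   pathologic_N = NA_character_, pathologic_M = NA_character_,
                   gender = "f", ethnicity = "g", stringsAsFactors = FALSE)
  cc <- new("ClinicalCorpus", notes = nt, registry = rg, split = character())
  hard <- buildCaseFindingTraining(cc, "hard_negatives", seed = 1)
  lab <- vapply(hard, function(i) i@label, "")
  negs <- hard[lab == "negative"]
  expect_length(negs, 1L)
  expect_equal(as.integer(negs[[1]]@day - dx), -100L)
})
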