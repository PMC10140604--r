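#' Patient-day case-finding instance
#'
#' One classification instance per patient per calendar day: all of that
#' day's notes, sentence-segmented, with a binary label (`"positive"` on the
#' diagnosis day of a cancer patient, `"negative"` otherwise).
#'
#' @slot day the calendar date; all sentences come from notes dated exactly
#'   this day.
#' @export
setClass("CaseFindingInstance", contains = "AbstractionInstance",
         representation(day = "Date"))

setValidity("CaseFindingInstance", function(object) {
  s <- object@sentences
  if (nrow(s) && any(s$date != object@day))
    return("all sentences must come from notes dated exactly `day`")
  if (!(object@label %in% c("positive", "negative")))
    return("label must be positive/negative")
  TRUE
})

CASEFINDING_LABELS <- c("negative", "positive")

.day_instance <- function(nt, pid, day, label) {
  sel <- nt[nt$patient_id == pid & nt$date == day, , drop = FALSE]
  sel <- sel[order(sel$note_id), , drop = FALSE]
  sents <- .sentences_for_notes(sel)
  if (!nrow(sents)) return(NULL)
  new("CaseFindingInstance", patient_id = pid, attribute = "case_finding",
      sentences = sents, label = label, day = day)
}

#' Build case-finding training instances under a self-supervision scheme
#'
#' Positives are the diagnosis-day instances of cancer patients with at
#' least one note that day. Under the `"default"` scheme, negatives are one
#' randomly chosen documented day per non-cancer patient. The
#' `"hard_negatives"` scheme additionally adds, per cancer patient, documented
#' days at least a week and at most a year before diagnosis (day offset in
#' \[-365, -8\]), capped at `max_hard_per_patient` sampled days.
#'
#' @param corpus a [ClinicalCorpus-class].
#' @param scheme `"default"` or `"hard_negatives"`.
#' @param seed integer seed for the day sampling.
#' @param split restrict to patients of these splits (`NULL` = all).
#' @param max_hard_per_patient cap on hard negatives per cancer patient.
#' @return list of [CaseFindingInstance-class].
#' @export
buildCaseFindingTraining <- function(corpus, scheme = c("default", "hard_negatives"),
                                     seed = 1L, split = NULL,
                                     max_hard_per_patient = 3L) {
  scheme <- match.arg(scheme)
  rg <- registry(corpus)
  if (!is.null(split)) {
    sp <- corpusSplit(corpus)
    rg <- rg[rg$patient_id %in% names(sp)[sp %in% split], , drop = FALSE]
  }
  cancer <- rg[!is.na(rg$diagnosis_date), , drop = FALSE]
  noncancer <- rg[is.na(rg$diagnosis_date), , drop = FALSE]
  if (!nrow(cancer)) stop("corpus has no cancer patients")
  nt <- notes(corpus)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  out <- list()
  for (i in seq_len(nrow(cancer))) {
    inst <- .day_instance(nt, cancer$patient_id[i], cancer$diagnosis_date[i],
                          "positive")
    if (!is.null(inst)) out[[length(out) + 1L]] <- inst
  }
  for (i in seq_len(nrow(noncancer))) {
    pid <- noncancer$patient_id[i]
    days <- sort(unique(nt$date[nt$patient_id == pid]))
    if (!length(days)) next
    day <- days[sample.int(length(days), 1L)]
    inst <- .day_instance(nt, pid, day, "negative")
    if (!is.null(inst)) out[[length(out) + 1L]] <- inst
  }
  if (scheme == "hard_negatives") {
    for (i in seq_len(nrow(cancer))) {
      pid <- cancer$patient_id[i]
      dx <- cancer$diagnosis_date[i]
      days <- sort(unique(nt$date[nt$patient_id == pid]))
      off <- as.integer(days - dx)
      days <- days[off >= -365L & off <= -8L]
      if (!length(days)) next
      if (length(days) > max_hard_per_patient)
        days <- sort(days[sample.int(length(days), max_hard_per_patient)])
      for (day in as.list(days)) {
        inst <- .day_instance(nt, pid, day, "negative")
        if (!is.null(inst)) out[[length(out) + 1L]] <- inst
      }
    }
  }
  out
}

#' Build one instance per documented patient-day (for inference)
#'
#' @param corpus a [ClinicalCorpus-class].
#' @param split restrict to patients of these splits (`NULL` = all).
#' @return list of [CaseFindingInstance-class] labelled by the registry
#'   (positive only on a cancer patient's diagnosis day).
#' @export
buildCaseFindingDays <- function(corpus, split = NULL) {
  rg <- registry(corpus)
  if (!is.null(split)) {
    sp <- corpusSplit(corpus)
    rg <- rg[rg$patient_id %in% names(sp)[sp %in% split], , drop = FALSE]
  }
  nt <- notes(corpus)
  out <- list()
  for (i in seq_len(nrow(rg))) {
    pid <- rg$patient_id[i]
    days <- sort(unique(nt$date[nt$patient_id == pid]))
    for (day in as.list(days)) {
      lab <- if (!is.na(rg$diagnosis_date[i]) && day == rg$diagnosis_date[i])
        "positive" else "negative"
      inst <- .day_instance(nt, pid, day, lab)
      if (!is.null(inst)) out[[length(out) + 1L]] <- inst
    }
  }
  out
}

#' Train the case-finding classifier
#'
#' Same hierarchical architecture as abstraction, trained separately on
#' patient-day instances with binary labels.
#'
#' @param corpus a [ClinicalCorpus-class] with cancer and non-cancer
#'   patients.
#' @param scheme self-supervision scheme, see [buildCaseFindingTraining()].
#' @param config a [hierModelConfig()].
#' @param seed seed for negative-day sampling (model seed is in `config`).
#' @param max_hard_per_patient cap on hard negatives per cancer patient.
#' @return a [HierModel-class] over labels negative/positive.
#' @export
trainCaseFinding <- function(corpus, scheme = "default",
                             config = hierModelConfig(max_epochs = 30L),
                             seed = 1L, max_hard_per_patient = 3L) {
  train <- buildCaseFindingTraining(corpus, scheme, seed = seed,
                                    split = "train",
                                    max_hard_per_patient = max_hard_per_patient)
  dev <- buildCaseFindingTraining(corpus, scheme, seed = seed + 1L,
                                  split = "dev",
                                  max_hard_per_patient = max_hard_per_patient)
  trainHierModel(train, CASEFINDING_LABELS, config, dev_instances = dev)
}

#' Per-day positive probabilities for case finding
#'
#' @param model a case-finding [HierModel-class].
#' @param instances list of [CaseFindingInstance-class] (typically from
#'   [buildCaseFindingDays()]).
#' @param threshold probability above which a day is flagged positive.
#' @return data.frame (patient_id, day, prob_positive, positive).
#' @export
caseFindingPredict <- function(model, instances, threshold = 0.5) {
  preds <- predictHier(model, instances)
  data.frame(
    patient_id = vapply(instances, function(x) x@patient_id, ""),
    day = as.Date(vapply(instances, function(x) as.character(x@day), "")),
    prob_positive = vapply(preds, function(p) unname(p@probs["positive"]),
                           numeric(1)),
    positive = vapply(preds, function(p) p@probs[["positive"]] > threshold,
                      logical(1)),
    stringsAsFactors = FALSE)
}

#' Patient-level case-finding evaluation
#'
#' For each patient the first day with a positive classification is taken.
#' A cancer patient is a true positive if that day falls within the closed
#' `window` around diagnosis; otherwise the patient counts as a false
#' negative, and additionally as a false positive if some day was flagged
#' (a spurious alarm was raised while the true case was missed). A
#' non-cancer patient is a true negative if never flagged, else a false
#' positive. F1 = 2/(1/precision + 1/recall), 0 when undefined.
#'
#' @param predictions data.frame from [caseFindingPredict()]; must cover
#'   every documented day of every evaluated patient.
#' @param registry registry data.frame (all predicted patients must appear).
#' @param window closed day window for a correct detection, default
#'   `c(-7, 30)`.
#' @return list: precision, recall, f1, counts, and a per-patient
#'   `decisions` data.frame (patient_id, first_positive_day, correct,
#'   outcome).
#' @export
evaluateCaseFinding <- function(predictions, registry, window = c(-7, 30)) {
  unknown <- setdiff(unique(predictions$patient_id), registry$patient_id)
  if (length(unknown))
    stop("patients in predictions but not in registry: ",
         paste(unknown, collapse = ", "))
  pids <- unique(predictions$patient_id)
  TP <- FP <- FN <- TN <- 0L
  dec <- list()
  for (pid in pids) {
    sub <- predictions[predictions$patient_id == pid, , drop = FALSE]
    flagged <- sub$day[sub$positive]
    first_pos <- if (length(flagged)) min(flagged) else as.Date(NA)
    dx <- registry$diagnosis_date[match(pid, registry$patient_id)]
    if (!is.na(dx)) {
      if (!is.na(first_pos)) {
        off <- as.integer(first_pos - dx)
        if (off >= window[1] && off <= window[2]) {
          TP <- TP + 1L; outcome <- "TP"; correct <- TRUE
        } else {
          FN <- FN + 1L; FP <- FP + 1L; outcome <- "FN+FP"; correct <- FALSE
        }
      } else {
        FN <- FN + 1L; outcome <- "FN"; correct <- FALSE
      }
    } else {
      if (is.na(first_pos)) {
        TN <- TN + 1L; outcome <- "TN"; correct <- TRUE
      } else {
        FP <- FP + 1L; outcome <- "FP"; correct <- FALSE
      }
    }
    dec[[length(dec) + 1L]] <- data.frame(
      patient_id = pid, first_positive_day = first_pos, correct = correct,
      outcome = outcome, stringsAsFactors = FALSE)
  }
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  recall <- if (TP + FN > 0) TP / (TP + FN) else 0
  f1 <- if (precision > 0 && recall > 0) 2 / (1 / precision + 1 / recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       counts = c(TP = TP, FP = FP, FN = FN, TN = TN),
       decisions = do.call(rbind, dec))
}
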