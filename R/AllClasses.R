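#' @import methods
NULL

NOTE_TYPES <- c("pathology", "radiology", "operative")
NULL_LABEL <- "NULL"
T_LEVELS <- c("0", "1", "2", "3", "4", "is")
N_LEVELS <- c("0", "1+")
M_LEVELS <- c("0", "1")
ATTRIBUTES <- c("site", "histology",
                "clinical_T", "clinical_N", "clinical_M",
                "pathologic_T", "pathologic_N", "pathologic_M")

REGISTRY_COLS <- c("patient_id", "diagnosis_date", "site", "histology",
                   "clinical_T", "clinical_N", "clinical_M",
                   "pathologic_T", "pathologic_N", "pathologic_M",
                   "gender", "ethnicity")

.attr_levels <- function(attribute) {
  switch(attribute,
         clinical_T = , pathologic_T = T_LEVELS,
         clinical_N = , pathologic_N = N_LEVELS,
         clinical_M = , pathologic_M = M_LEVELS,
         NULL)
}

#' Clinical corpus container
#'
#' Holds a collection of dated free-text clinical notes (pathology, radiology,
#' operative), the matching registry records carrying patient-level labels
#' (tumor site, histology, coarse clinical/pathologic TNM), and a patient-level
#' train/dev/test split assignment. Labels absent from the registry (non-cancer
#' patients, unstaged attributes) are stored as `NA` and mapped to the `"NULL"`
#' class when instances are built.
#'
#' @slot notes data.frame with columns patient_id, note_id, note_type
#'   (one of pathology/radiology/operative), date (`Date`), text.
#' @slot registry data.frame with the registry columns (see [readCorpus()]);
#'   `diagnosis_date` is `Date`, attribute columns are character with `NA`
#'   for NULL.
#' @slot split named character vector mapping patient_id to one of
#'   `"train"`, `"dev"`, `"test"`; may be empty (unassigned).
#' @export
setClass("ClinicalCorpus",
         representation(notes = "data.frame",
                        registry = "data.frame",
                        split = "character"))

setValidity("ClinicalCorpus", function(object) {
  msgs <- character()
  nt <- object@notes
  rg <- object@registry
  need_n <- c("patient_id", "note_id", "note_type", "date", "text")
  if (!all(need_n %in% names(nt)))
    msgs <- c(msgs, paste("notes is missing columns:",
                          paste(setdiff(need_n, names(nt)), collapse = ", ")))
  if (!all(REGISTRY_COLS %in% names(rg)))
    msgs <- c(msgs, paste("registry is missing columns:",
                          paste(setdiff(REGISTRY_COLS, names(rg)), collapse = ", ")))
  if (length(msgs)) return(msgs)
  if (nrow(nt)) {
    if (any(!nzchar(nt$text))) msgs <- c(msgs, "notes contain empty text")
    if (!all(nt$note_type %in% NOTE_TYPES))
      msgs <- c(msgs, paste("note_type must be one of",
                            paste(NOTE_TYPES, collapse = "/")))
    if (anyDuplicated(paste(nt$patient_id, nt$note_id, sep = "\r")))
      msgs <- c(msgs, "(patient_id, note_id) pairs are not unique")
  }
  if (nrow(rg)) {
    if (anyDuplicated(rg$patient_id))
      msgs <- c(msgs, "duplicate patient_id in registry")
    for (a in ATTRIBUTES[-(1:2)]) {
      lv <- .attr_levels(a)
      bad <- !is.na(rg[[a]]) & !(rg[[a]] %in% lv)
      if (any(bad))
        msgs <- c(msgs, sprintf("%s values must be NULL or one of {%s}; got %s",
                                a, paste(lv, collapse = ","),
                                paste(unique(rg[[a]][bad]), collapse = ",")))
    }
    noncancer <- is.na(rg$diagnosis_date)
    has_lab <- Reduce(`|`, lapply(ATTRIBUTES, function(a) !is.na(rg[[a]])))
    if (any(noncancer & has_lab))
      msgs <- c(msgs, "non-cancer patients (no diagnosis_date) must have all attribute labels NULL")
  }
  if (length(object@split)) {
    if (is.null(names(object@split)) || any(!nzchar(names(object@split))))
      msgs <- c(msgs, "split must be named by patient_id")
    if (!all(object@split %in% c("train", "dev", "test")))
      msgs <- c(msgs, "split values must be train/dev/test")
    if (anyDuplicated(names(object@split)))
      msgs <- c(msgs, "split assigns a patient more than once")
  }
  if (length(msgs)) msgs else TRUE
})

#' Attribute schema with label list and lexicon
#'
#' An ordered label inventory for one abstraction attribute, always including
#' the `"NULL"` class, together with a per-label alias lexicon used by the
#' ontology baseline and the synthetic generator.
#'
#' @slot attribute attribute name (e.g. `"site"`, `"clinical_T"`).
#' @slot labels character vector of unique labels; contains `"NULL"`.
#' @slot lexicon named list mapping each non-NULL label to a non-empty
#'   character vector of surface aliases.
#' @export
setClass("AttributeSchema",
         representation(attribute = "character",
                        labels = "character",
                        lexicon = "list"))

setValidity("AttributeSchema", function(object) {
  msgs <- character()
  if (length(object@attribute) != 1L)
    msgs <- c(msgs, "attribute must be a single string")
  if (anyDuplicated(object@labels)) msgs <- c(msgs, "labels must be unique")
  if (!(NULL_LABEL %in% object@labels))
    msgs <- c(msgs, "labels must include NULL")
  lex <- object@lexicon
  if (length(lex)) {
    if (is.null(names(lex)) || !all(names(lex) %in% object@labels))
      msgs <- c(msgs, "lexicon names must be labels")
    ok <- vapply(lex, function(x) is.character(x) && length(x) > 0 && all(nzchar(x)),
                 logical(1))
    if (!all(ok)) msgs <- c(msgs, "lexicon entries must be non-empty strings")
  }
  if (length(msgs)) msgs else TRUE
})

#' Windowed, sentence-segmented note bundle for one patient and attribute
#'
#' The unit of abstraction: all of a patient's in-window notes, segmented into
#' sentences and ordered chronologically across notes, with the registry label
#' for one attribute attached.
#'
#' @slot patient_id patient identifier.
#' @slot attribute attribute name.
#' @slot sentences data.frame ordered by (date, note_id, sentence_index) with
#'   columns note_id, note_type, date, sentence_index, start, end (0-based
#'   half-open character offsets into the source note text), text, and a
#'   `tokens` list-column of lowercased word tokens.
#' @slot label label from the attribute schema (`"NULL"` for absent).
#' @export
setClass("AbstractionInstance",
         representation(patient_id = "character",
                        attribute = "character",
                        sentences = "data.frame",
                        label = "character"))

setValidity("AbstractionInstance", function(object) {
  s <- object@sentences
  msgs <- character()
  need <- c("note_id", "note_type", "date", "sentence_index",
            "start", "end", "text", "tokens")
  if (!all(need %in% names(s)))
    return(paste("sentences is missing columns:",
                 paste(setdiff(need, names(s)), collapse = ", ")))
  if (nrow(s)) {
    o <- order(as.integer(s$date), s$note_id, s$sentence_index)
    if (!identical(o, seq_len(nrow(s))))
      msgs <- c(msgs, "sentences must be ordered by (date, note_id, sentence_index)")
    if (any(s$start < 0 | s$end <= s$start))
      msgs <- c(msgs, "offsets must satisfy 0 <= start < end")
    if (any(lengths(s$tokens) == 0L))
      msgs <- c(msgs, "token lists must be non-empty")
  }
  if (length(msgs)) msgs else TRUE
})

#' Per-instance prediction with attention weights
#'
#' @slot patient_id patient identifier.
#' @slot attribute attribute (or `"case_finding"`).
#' @slot probs named numeric vector of per-label probabilities (sums to 1).
#' @slot label argmax label (ties broken by schema label order).
#' @slot sentence_weights data.frame (note_id, sentence_index, weight); the
#'   weights within each note sum to 1.
#' @slot note_weights named numeric vector over note_ids summing to 1.
#' @export
setClass("Prediction",
         representation(patient_id = "character",
                        attribute = "character",
                        probs = "numeric",
                        label = "character",
                        sentence_weights = "data.frame",
                        note_weights = "numeric"))

setValidity("Prediction", function(object) {
  msgs <- character()
  if (abs(sum(object@probs) - 1) > 1e-6)
    msgs <- c(msgs, "probabilities must sum to 1")
  if (any(object@probs < -1e-12)) msgs <- c(msgs, "probabilities must be non-negative")
  if (length(object@note_weights) &&
      abs(sum(object@note_weights) - 1) > 1e-6)
    msgs <- c(msgs, "note weights must sum to 1")
  sw <- object@sentence_weights
  if (nrow(sw)) {
    bynote <- tapply(sw$weight, sw$note_id, sum)
    if (any(abs(bynote - 1) > 1e-6))
      msgs <- c(msgs, "sentence weights must sum to 1 within each note")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ClinicalCorpus", function(object) {
  rg <- object@registry
  cat("ClinicalCorpus:", nrow(rg), "patients (",
      sum(!is.na(rg$diagnosis_date)), "cancer /",
      sum(is.na(rg$diagnosis_date)), "non-cancer ),",
      nrow(object@notes), "notes\n")
  if (length(object@split)) {
    tb <- table(object@split)
    cat("  split:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  } else cat("  split: unassigned\n")
})

setMethod("show", "AttributeSchema", function(object) {
  cat("AttributeSchema", sQuote(object@attribute), "with",
      length(object@labels), "labels,",
      sum(lengths(object@lexicon)), "lexicon aliases\n")
})

setMethod("show", "AbstractionInstance", function(object) {
  cat("AbstractionInstance:", object@patient_id, "/", object@attribute,
      "-", nrow(object@sentences), "sentences in",
      length(unique(object@sentences$note_id)), "notes; label =",
      object@label, "\n")
})

setMethod("show", "Prediction", function(object) {
  p <- sort(object@probs, decreasing = TRUE)
  cat("Prediction", object@patient_id, "/", object@attribute, ": ",
      object@label, sprintf("(p=%.3f)", p[1]), "\n")
})

#' @rdname ClinicalCorpus-class
#' @param object,x a `ClinicalCorpus`
#' @export
setGeneric("notes", function(x) standardGeneric("notes"))
#' @rdname ClinicalCorpus-class
#' @export
setGeneric("registry", function(x) standardGeneric("registry"))
#' @rdname ClinicalCorpus-class
#' @export
setGeneric("corpusSplit", function(x) standardGeneric("corpusSplit"))

#' @rdname ClinicalCorpus-class
#' @export
setMethod("notes", "ClinicalCorpus", function(x) x@notes)
#' @rdname ClinicalCorpus-class
#' @export
setMethod("registry", "ClinicalCorpus", function(x) x@registry)
#' @rdname ClinicalCorpus-class
#' @export
setMethod("corpusSplit", "ClinicalCorpus", function(x) x@split)

#' @rdname AttributeSchema-class
#' @param x an `AttributeSchema`
#' @export
setGeneric("schemaLabels", function(x) standardGeneric("schemaLabels"))
#' @rdname AttributeSchema-class
#' @export
setMethod("schemaLabels", "AttributeSchema", function(x) x@labels)
#' @rdname AttributeSchema-class
#' @export
setGeneric("schemaLexicon", function(x) standardGeneric("schemaLexicon"))
#' @rdname AttributeSchema-class
#' @export
setMethod("schemaLexicon", "AttributeSchema", function(x) x@lexicon)
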