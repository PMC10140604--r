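#' Configuration for the synthetic clinical-corpus generator
#'
#' Captures the statistical/linguistic structure the abstraction method must
#' handle: evidence split across documents (site named only in radiology,
#' malignancy asserted only in pathology), negated wrong-site distractors,
#' hedged pre-diagnosis notes, non-cancer patients, missing notes, and
#' registry label noise. A fixed seed gives byte-identical output.
#'
#' @slot n_cancer,n_noncancer patient counts.
#' @slot p_split_evidence probability the site term appears only in the
#'   radiology note while the malignancy assertion appears only in pathology.
#' @slot p_distractor_site per-note probability of inserting a negated
#'   mention of a wrong site.
#' @slot p_missing_note probability a radiology/operative note is dropped
#'   (the pathology note, the diagnosis anchor, is never dropped).
#' @slot label_noise_rate probability a non-NULL registry label is replaced
#'   by a random different label.
#' @slot p_prediagnosis_note probability of a hedged "suspicious finding"
#'   note 8-365 days before diagnosis.
#' @slot p_null_stage probability each staging attribute is unstaged (NULL).
#' @slot p_operative_note probability of an operative note.
#' @slot op_day_range day-offset range of the operative note (default 5-60;
#'   set to e.g. `c(31, 90)` to push pathologic-staging evidence outside the
#'   default abstraction window).
#' @slot notes_mean target mean notes per cancer patient (Poisson filler
#'   notes on top of the mandatory radiology/pathology pair).
#' @slot split_fractions patient-level train/dev/test fractions.
#' @slot seed integer seed driving all sampling.
#' @export
setClass("SyntheticConfig",
         representation(n_cancer = "numeric", n_noncancer = "numeric",
                        p_split_evidence = "numeric",
                        p_distractor_site = "numeric",
                        p_missing_note = "numeric",
                        label_noise_rate = "numeric",
                        p_prediagnosis_note = "numeric",
                        p_null_stage = "numeric",
                        p_operative_note = "numeric",
                        op_day_range = "numeric",
                        notes_mean = "numeric",
                        split_fractions = "numeric",
                        seed = "numeric"))

setValidity("SyntheticConfig", function(object) {
  msgs <- character()
  pr <- c(object@p_split_evidence, object@p_distractor_site,
          object@p_missing_note, object@label_noise_rate,
          object@p_prediagnosis_note, object@p_null_stage,
          object@p_operative_note)
  if (any(pr < 0 | pr > 1)) msgs <- c(msgs, "probabilities must lie in [0, 1]")
  if (object@n_cancer < 0 || object@n_noncancer < 0)
    msgs <- c(msgs, "patient counts must be >= 0")
  if (length(object@op_day_range) != 2L ||
      object@op_day_range[1] > object@op_day_range[2] ||
      object@op_day_range[1] < 1)
    msgs <- c(msgs, "op_day_range must be c(lo, hi) with 1 <= lo <= hi")
  if (abs(sum(object@split_fractions) - 1) > 1e-8)
    msgs <- c(msgs, "split_fractions must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' @rdname SyntheticConfig-class
#' @param n_cancer,n_noncancer,p_split_evidence,p_distractor_site,p_missing_note,label_noise_rate,p_prediagnosis_note,p_null_stage,p_operative_note,op_day_range,notes_mean,split_fractions,seed see slots.
#' @export
syntheticConfig <- function(n_cancer = 100, n_noncancer = 25,
                            p_split_evidence = 0.5,
                            p_distractor_site = 0.25,
                            p_missing_note = 0,
                            label_noise_rate = 0,
                            p_prediagnosis_note = 0.3,
                            p_null_stage = 0.1,
                            p_operative_note = 0.7,
                            op_day_range = c(5, 60),
                            notes_mean = 4,
                            split_fractions = c(train = 0.7, dev = 0.15,
                                                test = 0.15),
                            seed = 1L) {
  new("SyntheticConfig", n_cancer = n_cancer, n_noncancer = n_noncancer,
      p_split_evidence = p_split_evidence,
      p_distractor_site = p_distractor_site, p_missing_note = p_missing_note,
      label_noise_rate = label_noise_rate,
      p_prediagnosis_note = p_prediagnosis_note, p_null_stage = p_null_stage,
      p_operative_note = p_operative_note, op_day_range = op_day_range,
      notes_mean = notes_mean, split_fractions = split_fractions, seed = seed)
}

#' Synthetic corpus bundle: corpus, evidence manifest, clean labels
#'
#' @slot corpus the generated [ClinicalCorpus-class] (its registry may carry
#'   label noise if configured).
#' @slot manifest data.frame of planted evidence spans: patient_id, note_id,
#'   attribute, label, alias, start, end (0-based half-open offsets into the
#'   note text at which the lexicon alias literally occurs).
#' @slot truth clean (pre-noise) registry data.frame.
#' @slot corrupted_ids patient_ids whose registry labels were corrupted.
#' @slot config the [SyntheticConfig-class] used.
#' @export
setClass("SyntheticCorpus",
         representation(corpus = "ClinicalCorpus", manifest = "data.frame",
                        truth = "data.frame", corrupted_ids = "character",
                        config = "SyntheticConfig"))

setMethod("show", "SyntheticCorpus", function(object) {
  cat("SyntheticCorpus (seed", object@config@seed, ")\n")
  show(object@corpus)
  cat("  manifest:", nrow(object@manifest), "planted evidence spans;",
      length(object@corrupted_ids), "patients with corrupted labels\n")
})

#' @rdname SyntheticCorpus-class
#' @param x a `SyntheticCorpus`
#' @export
setGeneric("corpus", function(x) standardGeneric("corpus"))
#' @rdname SyntheticCorpus-class
#' @export
setMethod("corpus", "SyntheticCorpus", function(x) x@corpus)
#' @rdname SyntheticCorpus-class
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))
#' @rdname SyntheticCorpus-class
#' @export
setMethod("manifest", "SyntheticCorpus", function(x) x@manifest)
#' @rdname SyntheticCorpus-class
#' @export
setGeneric("truthRegistry", function(x) standardGeneric("truthRegistry"))
#' @rdname SyntheticCorpus-class
#' @export
setMethod("truthRegistry", "SyntheticCorpus", function(x) x@truth)

.pick <- function(x) x[[sample.int(length(x), 1L)]]

.zipf_sample <- function(labels) {
  w <- 1 / seq_along(labels)
  labels[sample.int(length(labels), 1L, prob = w / sum(w))]
}

# surface forms are Zipf-distributed too: the canonical alias dominates
.pick_alias <- function(aliases) .zipf_sample(aliases)

# histology sampled conditional on site, mirroring clinical epidemiology
# (hepatocellular carcinoma arises in liver, urothelial in bladder, ...)
.HIST_GIVEN_SITE <- list(
  LUNG      = c(ADENOCARCINOMA = 0.45, SQUAMOUS = 0.30, SMALL_CELL = 0.25),
  BREAST    = c(DUCTAL = 0.80, ADENOCARCINOMA = 0.20),
  COLON     = c(ADENOCARCINOMA = 1),
  PROSTATE  = c(ADENOCARCINOMA = 1),
  PANCREAS  = c(ADENOCARCINOMA = 1),
  LIVER     = c(HEPATOCELLULAR = 0.90, ADENOCARCINOMA = 0.10),
  KIDNEY    = c(CLEAR_CELL = 0.80, PAPILLARY = 0.20),
  BLADDER   = c(TRANSITIONAL = 0.90, SQUAMOUS = 0.10),
  STOMACH   = c(ADENOCARCINOMA = 1),
  OVARY     = c(ADENOCARCINOMA = 0.50, PAPILLARY = 0.30, CLEAR_CELL = 0.20),
  ESOPHAGUS = c(SQUAMOUS = 0.50, ADENOCARCINOMA = 0.50),
  THYROID   = c(PAPILLARY = 1))

# stage sampling distributions (clinical practice-shaped, fixed)
.T_PROBS <- c("0" = 0.08, "1" = 0.30, "2" = 0.27, "3" = 0.18, "4" = 0.12,
              "is" = 0.05)
.N_PROBS <- c("0" = 0.60, "1+" = 0.40)
.M_PROBS <- c("0" = 0.85, "1" = 0.15)

.sample_stage <- function(probs) names(probs)[sample.int(length(probs), 1L,
                                                         prob = probs)]

# --- template realization -----------------------------------------------
# Each realizer returns list(text, alias): a sentence literally containing
# `alias` (case-insensitively) once.

.site_evidence <- function(alias) {
  size <- .pick(c("1.2", "2.3", "3.1", "4.5", "0.8"))
  t <- .pick(c(
    sprintf("There is a %s cm mass in the %s.", size, alias),
    sprintf("Imaging demonstrates a suspicious lesion involving the %s.", alias),
    sprintf("A %s cm enhancing mass is seen in the %s.", size, alias)))
  list(text = t, alias = alias)
}

.site_path_evidence <- function(alias) {
  t <- .pick(c(
    sprintf("The specimen from the %s shows malignant cells.", alias),
    sprintf("Tumor is present in the %s specimen.", alias)))
  list(text = t, alias = alias)
}

.histology_evidence <- function(alias) {
  t <- .pick(c(
    sprintf("Biopsy reveals %s, consistent with malignancy.", alias),
    sprintf("Final diagnosis: %s.", alias),
    sprintf("Microscopic sections show %s.", alias)))
  list(text = t, alias = alias)
}

.ct_evidence <- function(label) {
  if (label == "is")
    return(list(text = "Appearance is that of carcinoma in situ.",
                alias = "carcinoma in situ"))
  alias <- paste0("cT", label)
  list(text = .pick(c(
    sprintf("Findings are compatible with clinical stage %s.", alias),
    sprintf("Clinical staging assessment: %s.", alias))),
    alias = tolower(alias))
}

.cn_evidence <- function(label) {
  if (label == "0")
    list(text = "There are no enlarged lymph nodes.",
         alias = "no enlarged lymph nodes")
  else
    list(text = "Multiple enlarged regional lymph nodes are present.",
         alias = "enlarged regional lymph nodes")
}

.cm_evidence <- function(label) {
  if (label == "0")
    list(text = "There is no evidence of distant metastasis.",
         alias = "no evidence of distant metastasis")
  else if (runif(1) < 0.5)
    list(text = "Findings are consistent with distant metastasis.",
         alias = "distant metastasis")
  else
    list(text = "Scattered lesions compatible with metastatic disease.",
         alias = "metastatic disease")
}

.pt_evidence <- function(label) {
  if (label == "is")
    return(list(text = "Final pathology demonstrates pathologic carcinoma in situ.",
                alias = "pathologic carcinoma in situ"))
  alias <- paste0("pT", label)
  list(text = sprintf("Pathologic staging of the resection specimen: %s.",
                      alias),
       alias = tolower(alias))
}

.pn_evidence <- function(label) {
  if (label == "0")
    list(text = "Examined lymph nodes negative for tumor.",
         alias = "nodes negative for tumor")
  else
    list(text = "Three of twelve lymph nodes positive for tumor.",
         alias = "nodes positive for tumor")
}

.pm_evidence <- function(label) {
  if (label == "0")
    list(text = "No distant spread identified at operation.",
         alias = "no distant spread identified")
  else
    list(text = "Peritoneal implants noted; distant metastasis confirmed.",
         alias = "distant metastasis confirmed")
}

# A negated organ review, as radiology reports carry routinely: each wrong
# site is negated once or twice (findings and impression sections repeat
# negatives in real reports). This is the designed trap for mention counting
# (entity recognition without assertion status): the negated organs can
# outnumber the single true-site mention.
.distractor_sentences <- function(alias) {
  n <- sample(1:2, 1L)
  vapply(seq_len(n), function(i) .pick(c(
    sprintf("No evidence of malignancy in the %s.", alias),
    sprintf("The %s is unremarkable with no suspicious lesion.", alias),
    sprintf("No suspicious focal lesion is seen in the %s.", alias),
    sprintf("Negative for tumor involvement of the %s.", alias))), "")
}

# Pre-diagnosis notes: hedged imaging, or an inconclusive biopsy/cytology
# report naming the (eventual) histology under uncertainty cues. The latter
# are the lexical near-misses that make pre-diagnosis days hard negatives.
.hedged_note <- function(site_alias, hist_alias) {
  r <- runif(1)
  if (r < 0.4)
    list(type = "radiology", header = "IMPRESSION:",
         text = .pick(c(
           sprintf("Imaging shows a small lesion in the %s; cannot rule out malignancy.",
                   site_alias),
           sprintf("There is a nodule in the %s suspicious for malignancy; tissue sampling recommended.",
                   site_alias))))
  else
    list(type = "pathology", header = "REPORT:",
         text = .pick(c(
           sprintf("Fine needle aspiration: atypical cells, suspicious for %s; definitive diagnosis deferred.",
                   hist_alias),
           sprintf("Cytology shows atypical cells; %s cannot be excluded on this sample.",
                   hist_alias),
           sprintf("Scant atypical cells present, suspicious for %s; rebiopsy recommended.",
                   hist_alias))))
}

.benign_sentence <- function(alias) {
  .pick(c(
    "Unremarkable screening examination.",
    sprintf("Benign-appearing cyst in the %s; no suspicious features.", alias),
    sprintf("No evidence of malignancy in the %s.", alias),
    "Stable postoperative changes with no new findings.",
    "Mild degenerative changes are noted."))
}

.filler_sentence <- function() {
  .pick(c("Comparison with prior imaging shows no interval change.",
          "Technically adequate study.",
          "Clinical correlation is recommended.",
          "Mild degenerative changes are noted."))
}

# Assemble a note from a header and sentence list; evidence is a list of
# (sentence_position, attribute, label, alias) to resolve into note offsets.
.assemble_note <- function(header, sentences, evidence) {
  body <- paste(sentences, collapse = " ")
  text <- paste0(header, "\n", body)
  # 0-based start offset of each sentence within the note text
  starts <- nchar(header) + 1L +
    c(0L, cumsum(nchar(sentences) + 1L))[seq_along(sentences)]
  spans <- lapply(evidence, function(ev) {
    if (is.na(ev$alias)) return(NULL)
    pos <- regexpr(tolower(ev$alias), tolower(sentences[ev$pos]),
                   fixed = TRUE)[1]
    if (pos < 0) stop("internal: alias not found in its template")
    s0 <- starts[ev$pos] + pos - 1L
    data.frame(attribute = ev$attribute, label = ev$label, alias = ev$alias,
               start = s0, end = s0 + nchar(ev$alias),
               stringsAsFactors = FALSE)
  })
  list(text = text, spans = do.call(rbind, spans))
}

#' Generate a synthetic clinical corpus with a ground-truth manifest
#'
#' For each cancer patient: true labels for all eight attributes; a radiology
#' note (site + clinical staging evidence) at day -7..-1, a pathology note
#' (histology + malignancy assertion, and the site unless evidence is split)
#' at day 0, and optionally an operative note carrying pathologic-staging
#' evidence. Negated wrong-site distractors, hedged pre-diagnosis notes, and
#' benign filler are inserted per the configuration; non-cancer patients get
#' benign notes and all-NULL labels. The manifest records every planted
#' evidence span. Registry label noise, if configured, is applied with
#' [corruptLabels()] (the clean labels are kept in `truthRegistry()`).
#'
#' @param config a [SyntheticConfig-class].
#' @return a [SyntheticCorpus-class].
#' @export
generateCorpus <- function(config) {
  validObject(config)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config@seed)
  schemas <- defaultSchemas()
  sites <- setdiff(schemaLabels(schemas$site), NULL_LABEL)
  hists <- setdiff(schemaLabels(schemas$histology), NULL_LABEL)
  site_lex <- schemaLexicon(schemas$site)
  hist_lex <- schemaLexicon(schemas$histology)

  notes_rows <- list(); reg_rows <- list(); man_rows <- list()
  add_note <- function(pid, nid, type, date, text) {
    notes_rows[[length(notes_rows) + 1L]] <<- data.frame(
      patient_id = pid, note_id = nid, note_type = type, date = date,
      text = text, stringsAsFactors = FALSE)
  }
  add_manifest <- function(pid, nid, spans) {
    if (is.null(spans) || !nrow(spans)) return()
    spans$patient_id <- pid; spans$note_id <- nid
    man_rows[[length(man_rows) + 1L]] <<- spans
  }

  n_filler_lambda <- max(0, config@notes_mean - 3)

  for (i in seq_len(config@n_cancer)) {
    pid <- sprintf("C%05d", i)
    dx <- as.Date("2016-01-01") + sample.int(1460, 1L)
    site <- .zipf_sample(sites)
    hd <- .HIST_GIVEN_SITE[[site]]
    hist <- if (is.null(hd)) .zipf_sample(hists)
            else names(hd)[sample.int(length(hd), 1L, prob = hd)]
    stg <- list(clinical_T = .sample_stage(.T_PROBS),
                clinical_N = .sample_stage(.N_PROBS),
                clinical_M = .sample_stage(.M_PROBS),
                pathologic_T = .sample_stage(.T_PROBS),
                pathologic_N = .sample_stage(.N_PROBS),
                pathologic_M = .sample_stage(.M_PROBS))
    for (a in names(stg)) if (runif(1) < config@p_null_stage) stg[[a]] <- NA
    split_ev <- runif(1) < config@p_split_evidence
    nctr <- 0L
    next_nid <- function() { nctr <<- nctr + 1L; sprintf("%s-%02d", pid, nctr) }

    # hedged pre-diagnosis note, 8-365 days before diagnosis
    if (runif(1) < config@p_prediagnosis_note) {
      day <- -sample(8:365, 1L)
      h <- .hedged_note(.pick_alias(site_lex[[site]]),
                        .pick_alias(hist_lex[[hist]]))
      add_note(pid, next_nid(), h$type, dx + day,
               paste0(h$header, "\n", h$text))
    }

    # radiology note, day -7..-1: site + clinical staging evidence
    if (config@p_missing_note == 0 || runif(1) >= config@p_missing_note) {
      ev <- list(); sent <- character()
      a1 <- .pick_alias(site_lex[[site]])
      e <- .site_evidence(a1)
      sent <- c(sent, e$text)
      ev[[length(ev) + 1L]] <- list(pos = length(sent), attribute = "site",
                                    label = site, alias = e$alias)
      stage_fns <- list(clinical_T = .ct_evidence, clinical_N = .cn_evidence,
                        clinical_M = .cm_evidence)
      for (a in names(stage_fns)) {
        if (is.na(stg[[a]])) next
        e <- stage_fns[[a]](stg[[a]])
        sent <- c(sent, e$text)
        ev[[length(ev) + 1L]] <- list(pos = length(sent), attribute = a,
                                      label = stg[[a]], alias = e$alias)
      }
      if (runif(1) < config@p_distractor_site) {
        wrongs <- sample(setdiff(sites, site), sample(2:4, 1L))
        for (w in wrongs)
          sent <- c(sent, .distractor_sentences(.pick(site_lex[[w]])))
      }
      # shuffle sentence order, keeping evidence positions in sync
      perm <- sample.int(length(sent))
      ev <- lapply(ev, function(x) { x$pos <- match(x$pos, perm); x })
      nid <- next_nid()
      nb <- .assemble_note("IMPRESSION:", sent[perm], ev)
      add_note(pid, nid, "radiology", dx - sample(1:7, 1L), nb$text)
      add_manifest(pid, nid, nb$spans)
    }

    # pathology note, day 0 (never dropped): histology + malignancy assertion
    {
      ev <- list(); sent <- character()
      e <- .histology_evidence(.pick_alias(hist_lex[[hist]]))
      sent <- c(sent, e$text)
      ev[[length(ev) + 1L]] <- list(pos = 1L, attribute = "histology",
                                    label = hist, alias = e$alias)
      if (!split_ev) {
        e <- .site_path_evidence(.pick_alias(site_lex[[site]]))
        sent <- c(sent, e$text)
        ev[[length(ev) + 1L]] <- list(pos = length(sent), attribute = "site",
                                      label = site, alias = e$alias)
      } else {
        sent <- c(sent, "The biopsy specimen shows malignant cells.")
      }
      if (runif(1) < config@p_distractor_site) {
        wrongs <- sample(setdiff(sites, site), sample(1:2, 1L))
        for (w in wrongs)
          sent <- c(sent, .distractor_sentences(.pick(site_lex[[w]])))
      }
      nid <- next_nid()
      nb <- .assemble_note("FINAL DIAGNOSIS:", sent, ev)
      add_note(pid, nid, "pathology", dx, nb$text)
      add_manifest(pid, nid, nb$spans)
    }

    # operative note: pathologic staging evidence
    has_pstage <- any(!is.na(unlist(stg[c("pathologic_T", "pathologic_N",
                                          "pathologic_M")])))
    if (runif(1) < config@p_operative_note && has_pstage &&
        (config@p_missing_note == 0 || runif(1) >= config@p_missing_note)) {
      ev <- list()
      sent <- "Patient underwent surgical resection of the primary tumor."
      stage_fns <- list(pathologic_T = .pt_evidence, pathologic_N = .pn_evidence,
                        pathologic_M = .pm_evidence)
      for (a in names(stage_fns)) {
        if (is.na(stg[[a]])) next
        e <- stage_fns[[a]](stg[[a]])
        sent <- c(sent, e$text)
        ev[[length(ev) + 1L]] <- list(pos = length(sent), attribute = a,
                                      label = stg[[a]], alias = e$alias)
      }
      day <- sample(seq(config@op_day_range[1], config@op_day_range[2]), 1L)
      nid <- next_nid()
      nb <- .assemble_note("OPERATIVE REPORT:", sent, ev)
      add_note(pid, nid, "operative", dx + day, nb$text)
      add_manifest(pid, nid, nb$spans)
    } else {
      stg[c("pathologic_T", "pathologic_N", "pathologic_M")] <- NA
    }

    # benign filler notes inside the default window
    n_fill <- stats::rpois(1L, n_filler_lambda)
    for (k in seq_len(n_fill))
      add_note(pid, next_nid(), "radiology", dx + sample(-20:20, 1L),
               paste0("IMPRESSION:\n", .filler_sentence()))

    reg_rows[[length(reg_rows) + 1L]] <- data.frame(
      patient_id = pid, diagnosis_date = dx, site = site, histology = hist,
      clinical_T = stg$clinical_T, clinical_N = stg$clinical_N,
      clinical_M = stg$clinical_M, pathologic_T = stg$pathologic_T,
      pathologic_N = stg$pathologic_N, pathologic_M = stg$pathologic_M,
      gender = .pick(c("female", "male")),
      ethnicity = .zipf_sample(c("group_a", "group_b", "group_c", "group_d")),
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(config@n_noncancer)) {
    pid <- sprintf("N%05d", i)
    base <- as.Date("2016-01-01") + sample.int(1460, 1L)
    for (k in seq_len(sample(1:3, 1L))) {
      alias <- .pick(site_lex[[.pick(sites)]])
      add_note(pid, sprintf("%s-%02d", pid, k),
               .pick(c("radiology", "pathology")),
               base + sample(0:600, 1L),
               paste0("IMPRESSION:\n", .benign_sentence(alias)))
    }
    reg_rows[[length(reg_rows) + 1L]] <- data.frame(
      patient_id = pid, diagnosis_date = as.Date(NA),
      site = NA_character_, histology = NA_character_,
      clinical_T = NA_character_, clinical_N = NA_character_,
      clinical_M = NA_character_, pathologic_T = NA_character_,
      pathologic_N = NA_character_, pathologic_M = NA_character_,
      gender = .pick(c("female", "male")),
      ethnicity = .zipf_sample(c("group_a", "group_b", "group_c", "group_d")),
      stringsAsFactors = FALSE)
  }

  nt <- if (length(notes_rows)) do.call(rbind, notes_rows) else .empty_notes()
  rg <- if (length(reg_rows)) do.call(rbind, reg_rows) else .empty_registry()
  mf <- if (length(man_rows)) {
    m <- do.call(rbind, man_rows)
    m[, c("patient_id", "note_id", "attribute", "label", "alias",
          "start", "end")]
  } else data.frame(patient_id = character(), note_id = character(),
                    attribute = character(), label = character(),
                    alias = character(), start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
  rownames(nt) <- rownames(rg) <- rownames(mf) <- NULL

  truth <- rg
  corrupted <- character()
  if (config@label_noise_rate > 0 && nrow(rg)) {
    cl <- corruptLabels(rg, config@label_noise_rate,
                        seed = config@seed + 7919L)
    rg <- cl$registry
    corrupted <- cl$corrupted_ids
  }
  cc <- new("ClinicalCorpus", notes = nt, registry = rg, split = character())
  cc <- assignSplit(cc, config@split_fractions, seed = config@seed + 104729L)
  validObject(cc)
  new("SyntheticCorpus", corpus = cc, manifest = mf, truth = truth,
      corrupted_ids = corrupted, config = config)
}

#' Corrupt registry labels at a given rate
#'
#' Each non-NULL attribute label is independently replaced, with the given
#' rate, by a label drawn uniformly from the rest of that attribute's schema
#' labels (emulating registry annotation inconsistency).
#'
#' @param registry a registry data.frame.
#' @param rate corruption probability in \[0, 1\].
#' @param seed integer seed.
#' @param schemas attribute schemas (default [defaultSchemas()]).
#' @return list with the corrupted `registry` and the affected
#'   `corrupted_ids`.
#' @export
corruptLabels <- function(registry, rate, seed = 1L,
                          schemas = defaultSchemas()) {
  stopifnot(rate >= 0, rate <= 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  touched <- character()
  for (a in ATTRIBUTES) {
    labs <- schemaLabels(schemas[[a]])
    idx <- which(!is.na(registry[[a]]))
    if (!length(idx)) next
    hit <- idx[stats::runif(length(idx)) < rate]
    for (i in hit) {
      pool <- setdiff(labs, registry[[a]][i])
      registry[[a]][i] <- pool[sample.int(length(pool), 1L)]
    }
    touched <- c(touched, registry$patient_id[hit])
  }
  # a "NULL" draw is stored as NA only for non-cancer semantics; keep the
  # literal label for cancer patients so validity still holds
  for (a in ATTRIBUTES)
    registry[[a]][!is.na(registry[[a]]) & registry[[a]] == NULL_LABEL] <-
      NA_character_
  list(registry = registry, corrupted_ids = sort(unique(touched)))
}
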