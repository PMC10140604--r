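NOTE_KEYS <- c("patient_id", "note_id", "note_type", "date", "text")

.parse_iso_date <- function(x, what, line = NA) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- !is.na(x) & nzchar(x) & is.na(d)
  if (any(bad)) {
    where <- if (is.na(line[1])) "" else sprintf(" at line %d", line[which(bad)[1]])
    stop(sprintf("format error: unparseable %s '%s'%s (expected ISO-8601 YYYY-MM-DD)",
                 what, x[which(bad)[1]], where), call. = FALSE)
  }
  d
}

#' Read a clinical corpus from JSONL notes and a CSV registry
#'
#' Notes are one JSON object per line with keys exactly
#' `patient_id, note_id, note_type, date, text`; the registry is a CSV with
#' the standard header (empty cell = NULL). Malformed rows are reported with
#' their line number.
#'
#' @param notes_path path to the JSONL notes file.
#' @param registry_path path to the registry CSV.
#' @return a validated [ClinicalCorpus-class] with an unassigned split.
#' @export
readCorpus <- function(notes_path, registry_path) {
  lines <- readLines(notes_path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop(sprintf(
                      "schema error: invalid JSON at notes line %d: %s",
                      i, conditionMessage(e)), call. = FALSE))
    missing <- setdiff(NOTE_KEYS, names(obj))
    if (length(missing))
      stop(sprintf("schema error: notes line %d is missing required field '%s'",
                   i, missing[1]), call. = FALSE)
    if (!(obj$note_type %in% NOTE_TYPES))
      stop(sprintf(
        "schema error: notes line %d: note_type '%s' must be one of {%s}",
        i, obj$note_type, paste(NOTE_TYPES, collapse = ", ")), call. = FALSE)
    obj$date <- .parse_iso_date(obj$date, "date", i)
    recs[[i]] <- obj[NOTE_KEYS]
  }
  nt <- if (length(recs)) {
    data.frame(patient_id = vapply(recs, `[[`, "", "patient_id"),
               note_id    = vapply(recs, `[[`, "", "note_id"),
               note_type  = vapply(recs, `[[`, "", "note_type"),
               date       = as.Date(vapply(recs, function(r) as.integer(r$date),
                                           integer(1))),
               text       = vapply(recs, `[[`, "", "text"),
               stringsAsFactors = FALSE)
  } else .empty_notes()

  rg <- utils::read.csv(registry_path, colClasses = "character",
                        stringsAsFactors = FALSE)
  missing <- setdiff(REGISTRY_COLS, names(rg))
  if (length(missing))
    stop(sprintf("schema error: registry is missing required field '%s'",
                 missing[1]), call. = FALSE)
  rg <- rg[REGISTRY_COLS]
  for (col in setdiff(REGISTRY_COLS, c("patient_id", "diagnosis_date")))
    rg[[col]][!nzchar(rg[[col]]) | is.na(rg[[col]])] <- NA_character_
  for (a in ATTRIBUTES[-(1:2)]) {
    lv <- .attr_levels(a)
    bad <- which(!is.na(rg[[a]]) & !(rg[[a]] %in% lv))
    if (length(bad))
      stop(sprintf(
        "schema error: registry line %d: %s value '%s' must be empty (NULL) or one of the coarse categories {%s}",
        bad[1] + 1L, a, rg[[a]][bad[1]], paste(lv, collapse = ", ")),
        call. = FALSE)
  }
  dd <- rg$diagnosis_date
  dd[is.na(dd) | !nzchar(dd)] <- NA_character_
  rg$diagnosis_date <- .parse_iso_date(dd, "diagnosis_date",
                                       seq_len(nrow(rg)) + 1L)
  corpus <- new("ClinicalCorpus", notes = nt, registry = rg,
                split = character())
  validObject(corpus)
  corpus
}

.empty_notes <- function() {
  data.frame(patient_id = character(), note_id = character(),
             note_type = character(), date = as.Date(character()),
             text = character(), stringsAsFactors = FALSE)
}

.empty_registry <- function() {
  out <- as.data.frame(stats::setNames(
    rep(list(character()), length(REGISTRY_COLS)), REGISTRY_COLS),
    stringsAsFactors = FALSE)
  out$diagnosis_date <- as.Date(character())
  out
}

#' Write a clinical corpus back to JSONL notes and a CSV registry
#'
#' Inverse of [readCorpus()]: `readCorpus()` on the written files reproduces
#' the corpus field-for-field.
#'
#' @param corpus a [ClinicalCorpus-class].
#' @param notes_path,registry_path output paths.
#' @return `corpus`, invisibly.
#' @export
writeCorpus <- function(corpus, notes_path, registry_path) {
  nt <- notes(corpus)
  con <- file(notes_path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(nt)) {
    for (i in seq_len(nrow(nt))) {
      writeLines(jsonlite::toJSON(list(
        patient_id = nt$patient_id[i], note_id = nt$note_id[i],
        note_type = nt$note_type[i], date = format(nt$date[i]),
        text = nt$text[i]), auto_unbox = TRUE), con)
    }
  }
  rg <- registry(corpus)
  out <- rg
  out$diagnosis_date <- ifelse(is.na(rg$diagnosis_date), "",
                               format(rg$diagnosis_date))
  for (col in setdiff(REGISTRY_COLS, c("patient_id", "diagnosis_date")))
    out[[col]][is.na(out[[col]])] <- ""
  utils::write.csv(out, registry_path, row.names = FALSE, quote = TRUE)
  invisible(corpus)
}

#' Assign a seeded patient-level train/dev/test split
#'
#' Every patient lands in exactly one split; no patient's notes are shared
#' across splits.
#'
#' @param corpus a [ClinicalCorpus-class].
#' @param fractions named numeric `c(train=, dev=, test=)` summing to 1.
#' @param seed integer seed.
#' @return the corpus with its `split` slot filled.
#' @export
assignSplit <- function(corpus, fractions = c(train = 0.7, dev = 0.15, test = 0.15),
                        seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8,
            all(c("train", "dev", "test") %in% names(fractions)))
  ids <- registry(corpus)$patient_id
  n <- length(ids)
  if (n == 0L) { corpus@split <- character(); return(corpus) }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  perm <- sample(ids)
  n_train <- round(n * fractions[["train"]])
  n_dev <- round(n * fractions[["dev"]])
  lab <- rep("test", n)
  lab[seq_len(n_train)] <- "train"
  if (n_dev > 0) lab[n_train + seq_len(min(n_dev, n - n_train))] <- "dev"
  corpus@split <- stats::setNames(lab, perm)
  validObject(corpus)
  corpus
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Select the notes inside a diagnosis-anchored day window
#'
#' Keeps notes whose day offset from the diagnosis date lies in the closed
#' interval `[window[1], window[2]]`, in chronological order with intra-day
#' ties broken by `note_id` (lexicographic).
#'
#' @param notes data.frame of notes (as in [notes()]).
#' @param diagnosis_date a `Date`; selection only applies to cancer patients.
#' @param window integer vector `c(lo, hi)` in days, `lo <= hi`.
#'   Default `c(-30, 30)`; pathologic staging benefits from `c(-30, 90)`.
#' @return the selected, ordered subset of `notes`.
#' @export
selectWindow <- function(notes, diagnosis_date, window = c(-30, 30)) {
  if (length(window) != 2L || window[1] > window[2])
    stop("window must be c(lo, hi) with lo <= hi")
  if (length(diagnosis_date) != 1L || is.na(diagnosis_date))
    stop("diagnosis_date is absent: window selection only applies to cancer patients")
  if (nrow(notes) == 0L) return(notes)
  off <- as.integer(notes$date - as.Date(diagnosis_date))
  keep <- off >= window[1] & off <= window[2]
  sel <- notes[keep, , drop = FALSE]
  sel[order(as.integer(sel$date), sel$note_id), , drop = FALSE]
}

#' Segment note text into sentences with character offsets
#'
#' Rule-based and deterministic: the text is split at newlines (so
#' section headers like `"FINDINGS:"` become their own sentences) and, within
#' lines, after runs of terminal punctuation (`.?!`) followed by whitespace.
#' Offsets are 0-based, half-open, over Unicode code points; each returned
#' span is a literal substring of the note text and spans are non-overlapping
#' and in order, so the note text can be reconstructed from them plus the
#' gaps. Whitespace-only input yields zero sentences.
#'
#' @param text a single note text string.
#' @return data.frame with columns `start`, `end`, `text`.
#' @export
segmentSentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  out <- list()
  nl <- c(0L, which(strsplit(text, "", fixed = TRUE)[[1]] == "\n"),
          nchar(text) + 1L)
  # line i spans 1-based [nl[i]+1, nl[i+1]-1]
  for (i in seq_len(length(nl) - 1L)) {
    ls <- nl[i] + 1L; le <- nl[i + 1L] - 1L
    if (le < ls) next
    line <- substr(text, ls, le)
    # split after terminal punctuation followed by whitespace
    m <- gregexpr("[.?!]+(?=\\s)", line, perl = TRUE)[[1]]
    cut <- if (m[1] == -1L) integer()
           else as.integer(m) + attr(m, "match.length") - 1L  # last punct char
    bounds <- c(0L, cut, nchar(line))
    for (j in seq_len(length(bounds) - 1L)) {
      a <- bounds[j] + 1L; b <- bounds[j + 1L]
      if (b < a) next
      seg <- substr(line, a, b)
      # trim, keeping offsets honest
      lead <- nchar(sub("^(\\s*).*$", "\\1", seg))
      trail <- nchar(sub("^.*?(\\s*)$", "\\1", seg))
      a2 <- a + lead; b2 <- b - trail
      if (b2 < a2) next
      out[[length(out) + 1L]] <-
        c(start = ls + a2 - 2L, end = ls + b2 - 1L)  # 0-based half-open
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE))
  df <- as.data.frame(do.call(rbind, out))
  df$text <- substr(rep(text, nrow(df)), df$start + 1L, df$end)
  df
}

#' Lowercased word tokens of a string (with in-string offsets)
#'
#' @param text a single string.
#' @return data.frame `token`, `start`, `end` (0-based half-open).
#' @keywords internal
wordTokens <- function(text) {
  m <- gregexpr("[[:alnum:]]+", tolower(text))[[1]]
  if (m[1] == -1L)
    return(data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  data.frame(token = regmatches(tolower(text), list(m))[[1]],
             start = as.integer(m) - 1L,
             end = as.integer(m) + attr(m, "match.length") - 1L,
             stringsAsFactors = FALSE)
}

.sentences_for_notes <- function(sel) {
  rows <- list()
  for (k in seq_len(nrow(sel))) {
    segs <- segmentSentences(sel$text[k])
    if (!nrow(segs)) next
    toks <- lapply(segs$text, function(s) wordTokens(s)$token)
    keep <- lengths(toks) > 0L
    if (!any(keep)) next
    segs <- segs[keep, , drop = FALSE]; toks <- toks[keep]
    rows[[length(rows) + 1L]] <- data.frame(
      note_id = sel$note_id[k], note_type = sel$note_type[k],
      date = sel$date[k],
      sentence_index = seq_len(nrow(segs)) - 1L,
      start = segs$start, end = segs$end, text = segs$text,
      tokens = I(toks), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(note_id = character(), note_type = character(),
                      date = as.Date(character()), sentence_index = integer(),
                      start = integer(), end = integer(), text = character(),
                      tokens = I(list()), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Build abstraction instances for one attribute
#'
#' One instance per cancer patient with at least one note inside the window;
#' sentences are ordered chronologically across notes and the label is taken
#' from the registry (`NA` mapped to `"NULL"`). Patients whose notes all fall
#' outside the window are skipped and recorded in the `"skipped"` attribute
#' of the result.
#'
#' @param corpus a [ClinicalCorpus-class].
#' @param attribute one of the eight abstraction attributes.
#' @param window day window around diagnosis, default `c(-30, 30)`.
#' @param split restrict to patients of this split (`NULL` = all).
#' @return list of [AbstractionInstance-class] objects.
#' @export
buildAbstractionInstances <- function(corpus, attribute, window = c(-30, 30),
                                      split = NULL) {
  if (!(attribute %in% ATTRIBUTES))
    stop(sprintf("unknown attribute '%s'; valid attributes are: %s",
                 attribute, paste(ATTRIBUTES, collapse = ", ")))
  rg <- registry(corpus)
  rg <- rg[!is.na(rg$diagnosis_date), , drop = FALSE]
  if (!is.null(split)) {
    sp <- corpusSplit(corpus)
    rg <- rg[rg$patient_id %in% names(sp)[sp %in% split], , drop = FALSE]
  }
  nt <- notes(corpus)
  out <- list(); skipped <- character()
  for (i in seq_len(nrow(rg))) {
    pid <- rg$patient_id[i]
    sel <- selectWindow(nt[nt$patient_id == pid, , drop = FALSE],
                        rg$diagnosis_date[i], window)
    sents <- .sentences_for_notes(sel)
    if (!nrow(sents)) { skipped <- c(skipped, pid); next }
    lab <- rg[[attribute]][i]
    out[[length(out) + 1L]] <- new("AbstractionInstance",
      patient_id = pid, attribute = attribute, sentences = sents,
      label = if (is.na(lab)) NULL_LABEL else lab)
  }
  attr(out, "skipped") <- skipped
  out
}
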