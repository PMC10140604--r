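#' Extract attention-based rationale spans for a prediction
#'
#' Runs the model forward and combines the three attention levels
#' multiplicatively: token weight (summary-position self-attention within the
#' sentence fragment) x sentence weight (within its note) x note weight.
#' Subword weights are summed within each word so every span has exact
#' character offsets into its source note; the combined weights over all
#' words of the instance form a probability distribution.
#'
#' @param model a trained [HierModel-class].
#' @param instance an [AbstractionInstance-class] (or case-finding instance).
#' @param top_k number of top spans to return (all spans if larger).
#' @return data.frame of rationale spans (note_id, sentence_index, start,
#'   end, token, weight) sorted by weight descending, ties by document
#'   order; the full sentence-level weight table is attached as attribute
#'   `"sentence_weights"`.
#' @export
extractRationale <- function(model, instance, top_k = 20L) {
  stopifnot(top_k >= 1)
  if (instance@attribute != model@attribute)
    stop(sprintf("schema mismatch: model is for '%s', instance is for '%s'",
                 model@attribute, instance@attribute))
  vocab <- .as_vocab(model)
  fr <- .instance_frags(vocab, instance, model@config$max_tokens)
  res <- cppForward(model@params, model@cfg, fr$toks, fr$note_idx,
                    want_attn = TRUE)
  s <- instance@sentences
  rows <- list()
  sent_rows <- list()
  for (f in seq_along(fr$toks)) {
    srow <- match(paste(fr$frag_map$note_id[f], fr$frag_map$sentence_index[f]),
                  paste(s$note_id, s$sentence_index))
    wt <- wordTokens(s$text[srow])
    combined_frag <- res$sent_w[f] * res$note_w[fr$note_idx[f] + 1L]
    tok_w <- res$token_attn[[f]] * combined_frag
    word_w <- as.vector(rowsum(tok_w, fr$word_of[[f]]))
    widx <- sort(unique(fr$word_of[[f]]))
    rows[[f]] <- data.frame(
      note_id = s$note_id[srow], sentence_index = s$sentence_index[srow],
      start = s$start[srow] + wt$start[widx],
      end = s$start[srow] + wt$end[widx],
      token = wt$token[widx], weight = word_w, stringsAsFactors = FALSE)
    sent_rows[[f]] <- data.frame(
      note_id = s$note_id[srow], sentence_index = s$sentence_index[srow],
      weight = combined_frag, stringsAsFactors = FALSE)
  }
  spans <- do.call(rbind, rows)
  ord <- order(-spans$weight, seq_len(nrow(spans)))
  spans <- spans[ord, , drop = FALSE]
  rownames(spans) <- NULL
  out <- utils::head(spans, top_k)
  sw <- do.call(rbind, sent_rows)
  sw <- stats::aggregate(weight ~ note_id + sentence_index, data = sw, sum)
  attr(out, "sentence_weights") <- sw[order(-sw$weight), ]
  attr(out, "prediction_probs") <- stats::setNames(res$probs, model@labels)
  out
}

#' Serialize rationale spans into a per-note highlight document
#'
#' @param spans data.frame from [extractRationale()].
#' @param corpus the [ClinicalCorpus-class] the spans refer to.
#' @return a list (one entry per note: note_id, note_type, date, spans) that
#'   survives a JSON round trip losslessly via [jsonlite::toJSON()] with
#'   `auto_unbox = TRUE, digits = NA`.
#' @export
renderRationale <- function(spans, corpus) {
  nt <- notes(corpus)
  dangling <- setdiff(unique(spans$note_id), nt$note_id)
  if (length(dangling))
    stop("spans reference notes absent from the corpus: ",
         paste(dangling, collapse = ", "))
  if (!nrow(spans)) return(list(notes = list()))
  by_note <- split(spans, spans$note_id)
  # preserve first-appearance order
  by_note <- by_note[unique(spans$note_id)]
  entries <- lapply(names(by_note), function(nid) {
    i <- match(nid, nt$note_id)
    sp <- by_note[[nid]]
    list(note_id = nid, note_type = nt$note_type[i],
         date = format(nt$date[i]),
         spans = lapply(seq_len(nrow(sp)), function(r)
           list(sentence_index = sp$sentence_index[r],
                start = sp$start[r], end = sp$end[r],
                token = sp$token[r], weight = sp$weight[r])))
  })
  list(notes = entries)
}

#' Counterfactual site probe
#'
#' For sampled noiseless test instances, replaces the planted site alias in
#' the evidence sentence with an alias of a different site and re-predicts;
#' returns the fraction of probes in which the predicted site changes. This
#' is a reported diagnostic of whether the model reads the evidence span it
#' highlights, not a hard gate.
#'
#' @param model a site [HierModel-class].
#' @param syn a [SyntheticCorpus-class].
#' @param instances site instances to probe (e.g. test split).
#' @param n_probe number of probes.
#' @param seed sampling seed.
#' @return list: `flip_rate`, `n`.
#' @export
counterfactualProbe <- function(model, syn, instances, n_probe = 20L,
                                seed = 1L) {
  mf <- manifest(syn)
  mf <- mf[mf$attribute == "site", , drop = FALSE]
  schemas <- defaultSchemas()
  site_lex <- schemaLexicon(schemas$site)
  sites <- names(site_lex)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  cand <- instances[vapply(instances, function(x)
    x@patient_id %in% mf$patient_id, logical(1))]
  if (!length(cand)) return(list(flip_rate = NA_real_, n = 0L))
  cand <- cand[sample.int(length(cand), min(n_probe, length(cand)))]
  nt <- notes(corpus(syn))
  flips <- 0L; n_done <- 0L
  for (inst in cand) {
    rows <- mf[mf$patient_id == inst@patient_id, , drop = FALSE]
    r <- rows[1L, ]
    other <- .pick(setdiff(sites, r$label))
    new_alias <- site_lex[[other]][[1L]]
    note_text <- nt$text[nt$note_id == r$note_id]
    if (!length(note_text)) next
    patched <- paste0(substr(note_text, 1L, r$start),
                      new_alias,
                      substr(note_text, r$end + 1L, nchar(note_text)))
    # rebuild the instance with the patched note text
    s <- inst@sentences
    probe <- inst
    sel <- s$note_id == r$note_id
    if (!any(sel)) next
    note_rows <- which(sel)
    segs <- segmentSentences(patched)
    toks <- lapply(segs$text, function(x) wordTokens(x)$token)
    keep <- lengths(toks) > 0L
    segs <- segs[keep, , drop = FALSE]; toks <- toks[keep]
    repl <- data.frame(note_id = r$note_id,
                       note_type = s$note_type[note_rows[1]],
                       date = s$date[note_rows[1]],
                       sentence_index = seq_len(nrow(segs)) - 1L,
                       start = segs$start, end = segs$end, text = segs$text,
                       tokens = I(toks), stringsAsFactors = FALSE)
    s2 <- rbind(s[seq_len(min(note_rows) - 1L), , drop = FALSE], repl,
                s[setdiff(seq_len(nrow(s)), c(note_rows, seq_len(min(note_rows) - 1L))), ,
                  drop = FALSE])
    probe@sentences <- s2
    base <- predictHier(model, inst)@label
    alt <- predictHier(model, probe)@label
    n_done <- n_done + 1L
    if (!identical(base, alt)) flips <- flips + 1L
  }
  list(flip_rate = if (n_done) flips / n_done else NA_real_, n = n_done)
}
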