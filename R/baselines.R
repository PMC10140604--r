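#' Lexicon index for the ontology baseline
#'
#' Case-insensitive alias-to-label index with longest-match-first,
#' word-boundary-anchored matching. Aliases must be unique per attribute
#' after case folding.
#'
#' @param schema an [AttributeSchema-class].
#' @return data.frame (alias, label, nchar) sorted longest first.
#' @export
buildLexiconIndex <- function(schema) {
  lex <- schemaLexicon(schema)
  al <- tolower(unlist(lex, use.names = FALSE))
  lb <- rep(names(lex), lengths(lex))
  if (anyDuplicated(al))
    stop("aliases are not unique after case folding: ",
         paste(unique(al[duplicated(al)]), collapse = ", "))
  idx <- data.frame(alias = al, label = lb, nchar = nchar(al),
                    stringsAsFactors = FALSE)
  idx[order(-idx$nchar, idx$alias), ]
}

#' Ontology-aware rule-based classification
#'
#' Scans every sentence for lexicon aliases (case-insensitive, word-boundary
#' anchored, longest match first, non-overlapping) and predicts the most
#' frequently matched label, breaking ties by earliest match position; with
#' no match it predicts `"NULL"`. Probabilities are normalized match counts.
#' The matcher is deliberately negation-blind: "no evidence of malignancy in
#' the liver" still counts as a liver mention, which is exactly the weakness
#' that motivates going beyond entity recognition.
#'
#' @param instance an [AbstractionInstance-class].
#' @param schema the matching [AttributeSchema-class].
#' @return a [Prediction-class] (attention slots empty).
#' @export
ontologyClassify <- function(instance, schema) {
  if (instance@attribute != schema@attribute)
    stop("schema is for a different attribute than the instance")
  idx <- buildLexiconIndex(schema)
  labels <- schemaLabels(schema)
  counts <- stats::setNames(numeric(length(labels)), labels)
  first_pos <- stats::setNames(rep(Inf, length(labels)), labels)
  offset <- 0
  for (si in seq_len(nrow(instance@sentences))) {
    txt <- tolower(instance@sentences$text[si])
    cand <- list()
    for (k in seq_len(nrow(idx))) {
      pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                                idx$alias[k]), "\\b")
      m <- gregexpr(pat, txt, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      for (j in seq_along(m))
        cand[[length(cand) + 1L]] <- c(start = m[j],
                                       len = attr(m, "match.length")[j],
                                       k = k)
    }
    if (length(cand)) {
      cm <- do.call(rbind, cand)
      cm <- cm[order(cm[, "start"], -cm[, "len"]), , drop = FALSE]
      taken_end <- 0
      for (r in seq_len(nrow(cm))) {
        s <- cm[r, "start"]; e <- s + cm[r, "len"] - 1
        if (s <= taken_end) next   # overlaps a longer, earlier match
        taken_end <- e
        lb <- idx$label[cm[r, "k"]]
        counts[lb] <- counts[lb] + 1
        first_pos[lb] <- min(first_pos[lb], offset + s)
      }
    }
    offset <- offset + nchar(txt) + 1
  }
  tot <- sum(counts)
  if (tot == 0) {
    probs <- stats::setNames(numeric(length(labels)), labels)
    probs[NULL_LABEL] <- 1
    lab <- NULL_LABEL
  } else {
    probs <- counts / tot
    mx <- max(counts)
    cands <- names(counts)[counts == mx]
    lab <- cands[which.min(first_pos[cands])]
  }
  new("Prediction", patient_id = instance@patient_id,
      attribute = instance@attribute, probs = probs, label = lab,
      sentence_weights = data.frame(note_id = character(),
                                    sentence_index = integer(),
                                    weight = numeric()),
      note_weights = numeric())
}

BOW_STOPWORDS <- c("the", "a", "an", "of", "in", "and", "with", "is", "are",
                   "to", "for", "on", "at")

#' Train the bag-of-words logistic-regression baseline
#'
#' Features are token presences over the concatenated instance text (minus
#' a small stopword list); the classifier is multinomial logistic regression
#' with an L2 penalty (ridge), fitted at a fixed small lambda so the fit is
#' deterministic. Binary presence is the default rather than raw counts:
#' clinical notes repeat negated mentions routinely, and raw counts would
#' hand the bag-of-words model the same mention-frequency failure mode as
#' the lexicon matcher (set `binary = FALSE` for raw counts).
#'
#' @param instances training [AbstractionInstance-class] list.
#' @param labels full ordered label list.
#' @param lambda ridge penalty (default 0.01).
#' @param stopwords tokens excluded from the feature space.
#' @param binary use 0/1 token presence (default) instead of raw counts.
#' @return list of class `"BowModel"`.
#' @export
bowTrain <- function(instances, labels, lambda = 0.01,
                     stopwords = BOW_STOPWORDS, binary = TRUE) {
  truth <- vapply(instances, function(x) x@label, "")
  if (length(unique(truth)) < 2L)
    stop("training set contains a single label; need at least 2 distinct labels")
  toks <- lapply(instances, function(x)
    unlist(x@sentences$tokens, use.names = FALSE))
  toks <- lapply(toks, function(tk) tk[!(tk %in% stopwords)])
  if (binary) toks <- lapply(toks, unique)
  vocab <- sort(unique(unlist(toks, use.names = FALSE)))
  ii <- rep(seq_along(toks), lengths(toks))
  jj <- match(unlist(toks, use.names = FALSE), vocab)
  x <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(length(toks), length(vocab)))
  # classes with a single training instance cannot be fitted; drop them
  tab <- table(truth)
  keep <- truth %in% names(tab)[tab >= 2L]
  if (!all(keep)) {
    x <- x[keep, , drop = FALSE]; truth <- truth[keep]
    if (length(unique(truth)) < 2L)
      stop("training set contains a single fittable label")
  }
  # fit the full regularization path (glmnet's coordinate descent relies on
  # warm starts) and predict at the requested lambda
  fit <- suppressWarnings(
    glmnet::glmnet(x, factor(truth), family = "multinomial", alpha = 0,
                   standardize = FALSE, nlambda = 60,
                   lambda.min.ratio = min(1e-4, lambda / 10)))
  structure(list(fit = fit, lambda = lambda, vocab = vocab, labels = labels,
                 classes = levels(factor(truth)), stopwords = stopwords,
                 binary = binary, attribute = instances[[1]]@attribute),
            class = "BowModel")
}

#' Classify an instance with the bag-of-words baseline
#'
#' @param model a `"BowModel"` from [bowTrain()].
#' @param instance an [AbstractionInstance-class].
#' @return a [Prediction-class].
#' @export
bowClassify <- function(model, instance) {
  tk <- unlist(instance@sentences$tokens, use.names = FALSE)
  tk <- tk[!(tk %in% model$stopwords)]
  if (isTRUE(model$binary)) tk <- unique(tk)
  j <- match(tk, model$vocab)
  j <- j[!is.na(j)]
  x <- Matrix::sparseMatrix(i = rep(1L, length(j)), j = j, x = 1,
                            dims = c(1L, length(model$vocab)))
  # with constant features glmnet's lambda path degenerates (NaN/0 entries);
  # fall back to the final path point (the least-penalized fit) there
  lam <- model$fit$lambda
  if (sum(is.finite(lam) & !duplicated(lam)) >= 2L) {
    pr <- drop(stats::predict(model$fit, newx = x, type = "response",
                              s = model$lambda))
  } else {
    arr <- stats::predict(model$fit, newx = x, type = "response")
    pr <- NULL
    for (j in rev(seq_len(dim(arr)[3]))) {
      v <- arr[1L, , j]
      if (all(is.finite(v)) && abs(sum(v) - 1) < 1e-6) { pr <- v; break }
    }
    if (is.null(pr)) stop("bag-of-words fit did not converge at any lambda")
  }
  probs <- stats::setNames(numeric(length(model$labels)), model$labels)
  probs[names(pr)] <- pr
  probs <- probs / sum(probs)
  new("Prediction", patient_id = instance@patient_id,
      attribute = instance@attribute, probs = probs,
      label = model$labels[which.max(probs)],
      sentence_weights = data.frame(note_id = character(),
                                    sentence_index = integer(),
                                    weight = numeric()),
      note_weights = numeric())
}

#' @export
print.BowModel <- function(x, ...) {
  cat("BowModel for", sQuote(x$attribute), "-", length(x$vocab),
      "features,", length(x$classes), "observed classes\n")
  invisible(x)
}
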