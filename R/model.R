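#' Configuration for the hierarchical abstraction model
#'
#' Desk-scale defaults: a 2-layer, 2-head, 64-dimensional transformer
#' sentence encoder trained from scratch, a bidirectional GRU over sentence
#' vectors (hidden 32 per direction), 32-dimensional attention projections at
#' both hierarchy levels, and an Adam loop with early stopping on dev
#' micro-AUPRC.
#'
#' @param emb_dim encoder width (divisible by `n_heads`).
#' @param n_layers,n_heads transformer depth and heads.
#' @param ffn_dim encoder feed-forward width.
#' @param gru_hidden GRU hidden size per direction.
#' @param attn_dim attention projection size (both levels).
#' @param max_tokens max subword tokens per sentence fragment (longer
#'   sentences are split at this boundary and fragments encoded separately).
#' @param vocab_size target subword vocabulary size.
#' @param dropout dropout rate on sentence and patient vectors in training.
#' @param lr,batch_size,max_epochs,patience Adam learning rate, minibatch
#'   size, epoch cap, and early-stopping patience (epochs without dev
#'   improvement).
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return list of class `"HierModelConfig"`.
#' @export
hierModelConfig <- function(emb_dim = 64L, n_layers = 2L, n_heads = 2L,
                            ffn_dim = 128L, gru_hidden = 32L, attn_dim = 32L,
                            max_tokens = 32L, vocab_size = 2000L,
                            dropout = 0.1, lr = 2e-3, batch_size = 8L,
                            max_epochs = 50L, patience = 10L, seed = 1L) {
  stopifnot(emb_dim > 0, n_layers > 0, n_heads > 0, emb_dim %% n_heads == 0,
            ffn_dim > 0, gru_hidden > 0, attn_dim > 0, max_tokens > 1,
            dropout >= 0, dropout < 1, lr > 0, batch_size >= 1,
            max_epochs >= 1, patience >= 1)
  structure(list(emb_dim = as.integer(emb_dim), n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), ffn_dim = as.integer(ffn_dim),
                 gru_hidden = as.integer(gru_hidden),
                 attn_dim = as.integer(attn_dim),
                 max_tokens = as.integer(max_tokens),
                 vocab_size = as.integer(vocab_size), dropout = dropout,
                 lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "HierModelConfig")
}

#' Trained hierarchical abstraction model
#'
#' @slot params flat numeric parameter vector (fixed walk order).
#' @slot cfg list passed to the compiled core (`vocab_size`, `emb_dim`,
#'   `n_layers`, `n_heads`, `ffn_dim`, `gru_hidden`, `attn_dim`, `n_labels`,
#'   `max_tokens`).
#' @slot config the `"HierModelConfig"` used for training.
#' @slot vocab the `"SubwordVocab"` built from the training corpus.
#' @slot labels schema label order (defines the softmax head and argmax
#'   tie-breaking).
#' @slot attribute attribute the model was trained for.
#' @slot history per-epoch data.frame (epoch, train_loss, dev_metric).
#' @export
setClass("HierModel",
         representation(params = "numeric", cfg = "list", config = "list",
                        vocab = "list", labels = "character",
                        attribute = "character", history = "data.frame"))

setMethod("show", "HierModel", function(object) {
  cat("HierModel for", sQuote(object@attribute), "-",
      length(object@labels), "labels,",
      length(object@params), "parameters,",
      nrow(object@history), "epochs trained\n")
})

# fragment an instance into encoder inputs:
#   toks: list of 0-based subword id vectors (one per fragment)
#   note_idx: 0-based note index per fragment
#   frag_map: data.frame(note_id, sentence_index) per fragment
.instance_frags <- function(vocab, instance, max_tokens) {
  s <- instance@sentences
  if (!nrow(s)) stop("no sentences in window")
  note_of_sent <- cumsum(!duplicated(s$note_id)) - 1L
  toks <- list(); note_idx <- integer(); nid <- character(); sidx <- integer()
  word_of <- list()
  for (i in seq_len(nrow(s))) {
    ids <- encodeTokens(vocab, s$tokens[[i]])
    wo <- attr(ids, "word_of")
    nfrag <- ceiling(length(ids) / max_tokens)
    for (k in seq_len(nfrag)) {
      lo <- (k - 1L) * max_tokens + 1L
      hi <- min(k * max_tokens, length(ids))
      toks[[length(toks) + 1L]] <- as.integer(ids[lo:hi]) - 1L  # 0-based
      word_of[[length(word_of) + 1L]] <- wo[lo:hi]
      note_idx <- c(note_idx, note_of_sent[i])
      nid <- c(nid, s$note_id[i]); sidx <- c(sidx, s$sentence_index[i])
    }
  }
  list(toks = toks, note_idx = note_idx,
       frag_map = data.frame(note_id = nid, sentence_index = sidx,
                             stringsAsFactors = FALSE),
       word_of = word_of)
}

.model_cfg <- function(config, vocab, n_labels) {
  list(vocab_size = length(vocab$units) + 2L, emb_dim = config$emb_dim,
       n_layers = config$n_layers, n_heads = config$n_heads,
       ffn_dim = config$ffn_dim, gru_hidden = config$gru_hidden,
       attn_dim = config$attn_dim, n_labels = as.integer(n_labels),
       max_tokens = config$max_tokens)
}

.dev_metric <- function(model_params, cfg, vocab, config, instances, labels) {
  scores <- matrix(NA_real_, length(instances), length(labels),
                   dimnames = list(NULL, labels))
  truth <- character(length(instances))
  for (i in seq_along(instances)) {
    fr <- .instance_frags(vocab, instances[[i]], config$max_tokens)
    out <- cppForward(model_params, cfg, fr$toks, fr$note_idx)
    scores[i, ] <- out$probs
    truth[i] <- instances[[i]]@label
  }
  list(auprc = microAUPRC(truth, scores), truth = truth, scores = scores)
}

#' Train the hierarchical model on abstraction instances
#'
#' Minimizes cross-entropy on patient-level labels with Adam; one model per
#' attribute. With `dev_instances`, training early-stops on dev micro-AUPRC
#' (patience from the config) and the best-epoch parameters are kept;
#' otherwise the epoch cap applies. A fixed seed makes the run (shuffling,
#' initialization, dropout) exactly reproducible.
#'
#' @param instances list of [AbstractionInstance-class] (training split).
#' @param labels full ordered label list (e.g. `schemaLabels(schema)`).
#' @param config a [hierModelConfig()].
#' @param dev_instances optional dev-split instances for early stopping.
#' @param verbose print per-epoch progress.
#' @return a [HierModel-class].
#' @export
trainHierModel <- function(instances, labels, config = hierModelConfig(),
                           dev_instances = NULL, verbose = FALSE) {
  stopifnot(length(instances) > 0)
  truth <- vapply(instances, function(x) x@label, "")
  if (length(unique(truth)) < 2L)
    stop("training set contains a single label; need at least 2 distinct labels")
  if (!all(truth %in% labels))
    stop("training labels outside the schema label list: ",
         paste(setdiff(truth, labels), collapse = ", "))
  attribute <- instances[[1]]@attribute
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)

  texts <- unlist(lapply(instances, function(x) x@sentences$text))
  vocab <- buildSubwordVocab(texts, config$vocab_size)
  cfg <- .model_cfg(config, vocab, length(labels))
  frags <- lapply(instances, .instance_frags, vocab = vocab,
                  max_tokens = config$max_tokens)
  y <- match(truth, labels) - 1L

  params <- cppInitParams(cfg)
  m <- numeric(length(params)); v <- numeric(length(params))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
  n <- length(instances)
  best_params <- params; best_metric <- -Inf; best_epoch <- 0L; wait <- 0L
  hist <- list()

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    total_loss <- 0
    bstart <- seq(1L, n, by = config$batch_size)
    for (bs in bstart) {
      idx <- ord[bs:min(bs + config$batch_size - 1L, n)]
      gsum <- NULL
      for (i in idx) {
        out <- cppForward(params, cfg, frags[[i]]$toks, frags[[i]]$note_idx,
                          label = y[i], dropout = config$dropout,
                          training = TRUE, want_grad = TRUE)
        if (!is.finite(out$loss))
          stop(sprintf(
            "training aborted: non-finite loss at epoch %d (instance %s); try a lower learning rate",
            epoch, instances[[i]]@patient_id))
        total_loss <- total_loss + out$loss
        gsum <- if (is.null(gsum)) out$grad else gsum + out$grad
      }
      g <- gsum / length(idx)
      step <- step + 1L
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g * g
      mh <- m / (1 - b1^step)
      vh <- v / (1 - b2^step)
      params <- params - config$lr * mh / (sqrt(vh) + eps)
    }
    train_loss <- total_loss / n
    dev_metric <- NA_real_
    if (!is.null(dev_instances) && length(dev_instances)) {
      dev_metric <- .dev_metric(params, cfg, vocab, config, dev_instances,
                                labels)$auprc
      metric_now <- dev_metric
    } else metric_now <- -train_loss
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                dev_metric = dev_metric)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  dev %.4f", epoch, train_loss,
                      dev_metric))
    if (metric_now > best_metric + 1e-9) {
      best_metric <- metric_now; best_params <- params
      best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  history <- do.call(rbind, hist)
  attr(history, "best_epoch") <- best_epoch
  new("HierModel", params = as.numeric(best_params), cfg = cfg,
      config = unclass(config), vocab = unclass(vocab), labels = labels,
      attribute = attribute, history = history)
}

.as_vocab <- function(model) {
  v <- model@vocab
  class(v) <- "SubwordVocab"
  if (is.null(v$cache) || !is.environment(v$cache))
    v$cache <- new.env(parent = emptyenv())
  v
}

#' Predict one or many instances with a trained hierarchical model
#'
#' Deterministic given the model; argmax ties break toward the first label in
#' schema order. Batch prediction equals instance-by-instance prediction.
#'
#' @param model a [HierModel-class].
#' @param instances one [AbstractionInstance-class] or a list of them.
#' @return a [Prediction-class], or a list of them for a list input.
#' @export
predictHier <- function(model, instances) {
  single <- methods::is(instances, "AbstractionInstance")
  if (single) instances <- list(instances)
  vocab <- .as_vocab(model)
  out <- lapply(instances, function(inst) {
    if (inst@attribute != model@attribute)
      stop(sprintf("schema mismatch: model is for '%s', instance is for '%s'",
                   model@attribute, inst@attribute))
    fr <- .instance_frags(vocab, inst, model@config$max_tokens)
    res <- cppForward(model@params, model@cfg, fr$toks, fr$note_idx)
    probs <- stats::setNames(res$probs, model@labels)
    sw <- fr$frag_map
    sw$weight <- res$sent_w
    # merge fragments of the same sentence
    agg <- stats::aggregate(weight ~ note_id + sentence_index, data = sw, sum)
    agg <- agg[order(match(agg$note_id, unique(fr$frag_map$note_id)),
                     agg$sentence_index), ]
    rownames(agg) <- NULL
    nw <- stats::setNames(res$note_w, unique(fr$frag_map$note_id))
    new("Prediction", patient_id = inst@patient_id, attribute = inst@attribute,
        probs = probs, label = model@labels[which.max(probs)],
        sentence_weights = agg, note_weights = nw)
  })
  if (single) out[[1]] else out
}

#' Per-label score matrix for a set of instances
#'
#' @param model a [HierModel-class].
#' @param instances list of instances.
#' @return list with `truth` (character) and `scores` (matrix, labels as
#'   columns).
#' @export
scoreInstances <- function(model, instances) {
  preds <- predictHier(model, instances)
  scores <- do.call(rbind, lapply(preds, function(p) p@probs))
  colnames(scores) <- model@labels
  list(truth = vapply(instances, function(x) x@label, ""),
       scores = scores,
       predicted = vapply(preds, function(p) p@label, ""))
}

#' Encode an instance into ordered sentence-fragment vectors
#'
#' One pooled vector per sentence fragment (sentences longer than
#' `max_tokens` subwords are split at the chunk boundary and each fragment is
#' encoded separately), plus the per-fragment token attention rows (summary
#' position to each token, averaged over heads; each row sums to 1).
#'
#' @param model a [HierModel-class].
#' @param instance an [AbstractionInstance-class].
#' @return list: `vectors` (emb_dim x n_fragments), `token_attn`,
#'   `note_idx` (0-based per fragment), `frag_map`.
#' @export
encodeInstance <- function(model, instance) {
  fr <- .instance_frags(.as_vocab(model), instance, model@config$max_tokens)
  enc <- cppEncode(model@params, model@cfg, fr$toks)
  list(vectors = enc$vectors, token_attn = enc$token_attn,
       note_idx = fr$note_idx, frag_map = fr$frag_map, word_of = fr$word_of)
}

#' Contextualize sentence vectors with the bidirectional GRU
#'
#' Same count and order as the input; each output column depends on the
#' whole sequence.
#'
#' @param model a [HierModel-class].
#' @param vectors emb_dim x n matrix of sentence vectors.
#' @return 2*gru_hidden x n matrix.
#' @export
contextualizeSentences <- function(model, vectors) {
  stopifnot(nrow(vectors) >= 1, ncol(vectors) >= 1)
  cppContextualize(model@params, model@cfg, vectors)
}

#' Two-level attention pooling: sentences to notes to patient
#'
#' @param model a [HierModel-class].
#' @param ctx 2*gru_hidden x n matrix of contextual vectors.
#' @param note_idx 0-based nondecreasing note index per column.
#' @return list: `patient` vector, `sent_w` (within-note simplex),
#'   `note_w` (simplex over notes).
#' @export
aggregateSentences <- function(model, ctx, note_idx) {
  cppAggregate(model@params, model@cfg, ctx, as.integer(note_idx))
}

#' Classify a patient vector into label probabilities
#'
#' @param model a [HierModel-class].
#' @param pvec patient vector of length 2*gru_hidden.
#' @return named probability vector over the model's labels.
#' @export
classifyVector <- function(model, pvec) {
  stats::setNames(cppClassify(model@params, model@cfg, pvec), model@labels)
}

#' Write a model checkpoint to a directory (text files)
#'
#' Writes `config.yaml` (architecture, labels, attribute), `weights.txt`
#' (one parameter per line, full precision), and `vocab.txt` (merges and
#' units).
#'
#' @param model a [HierModel-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeHierModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(list(cfg = model@cfg, config = model@config,
                        labels = as.list(model@labels),
                        attribute = model@attribute),
                   file.path(dir, "config.yaml"))
  writeLines(sprintf("%.17g", model@params), file.path(dir, "weights.txt"))
  writeLines(c(paste("#merges", length(model@vocab$merges)),
               model@vocab$merges, "#units", model@vocab$units),
             file.path(dir, "vocab.txt"))
  invisible(dir)
}

#' Read a model checkpoint written by [writeHierModel()]
#' @param dir checkpoint directory.
#' @return a [HierModel-class].
#' @export
readHierModel <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "config.yaml"))
  params <- as.numeric(readLines(file.path(dir, "weights.txt")))
  vl <- readLines(file.path(dir, "vocab.txt"))
  nm <- as.integer(strsplit(vl[1], " ")[[1]][2])
  merges <- if (nm > 0) vl[2:(1 + nm)] else character()
  units <- vl[(nm + 3):length(vl)]
  vocab <- list(merges = merges, units = units,
                unit_ids = stats::setNames(seq_along(units) + 2L, units),
                cache = new.env(parent = emptyenv()))
  new("HierModel", params = params,
      cfg = lapply(meta$cfg, function(x) if (is.numeric(x)) as.integer(x) else x),
      config = meta$config, vocab = vocab,
      labels = unlist(meta$labels), attribute = meta$attribute,
      history = data.frame())
}
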