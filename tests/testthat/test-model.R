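cpp <- function(name) get(name, envir = asNamespace("OncoAbstract"))

small_cfg <- list(vocab_size = 15L, emb_dim = 8L, n_layers = 2L, n_heads = 2L,
                  ffn_dim = 12L, gru_hidden = 5L, attn_dim = 4L,
                  n_labels = 3L, max_tokens = 10L)

test_that("analytic gradients match finite differences", {
  set.seed(42)
  params <- cpp("cppInitParams")(small_cfg)
  toks <- list(c(2L, 5L, 7L), c(3L, 3L, 9L, 10L), c(1L, 4L), c(6L, 2L, 8L))
  nidx <- c(0L, 0L, 1L, 2L)
  out <- cpp("cppForward")(params, small_cfg, toks, nidx, label = 1L,
                           want_grad = TRUE)
  g <- out$grad
  set.seed(7)
  idx <- sample(length(params), 80)
  eps <- 1e-5
  num <- vapply(idx, function(i) {
    p1 <- params; p1[i] <- p1[i] + eps
    p2 <- params; p2[i] <- p2[i] - eps
    (cpp("cppForward")(p1, small_cfg, toks, nidx, label = 1L)$loss -
       cpp("cppForward")(p2, small_cfg, toks, nidx, label = 1L)$loss) / (2 * eps)
  }, numeric(1))
  rel <- abs(num - g[idx]) / pmax(1e-6, abs(num) + abs(g[idx]))
  expect_lt(max(rel), 1e-4)
})

test_that("attention weights are simplex-valued at every level", {
  set.seed(1)
  params <- cpp("cppInitParams")(small_cfg)
  toks <- list(c(2L, 5L), c(3L, 9L, 10L), c(1L, 4L, 6L), c(6L, 2L))
  nidx <- c(0L, 0L, 1L, 1L)
  out <- cpp("cppForward")(params, small_cfg, toks, nidx, want_attn = TRUE)
  expect_equal(sum(out$probs), 1, tolerance = 1e-9)
  expect_true(all(out$probs >= 0))
  expect_equal(as.vector(tapply(out$sent_w, nidx, sum)), c(1, 1),
               tolerance = 1e-9)
  expect_equal(sum(out$note_w), 1, tolerance = 1e-9)
  for (a in out$token_attn) {
    expect_true(all(a >= 0))
    expect_equal(sum(a), 1, tolerance = 1e-9)
  }
})

test_that("the encoder is pure: identical fragments get identical vectors", {
  set.seed(2)
  params <- cpp("cppInitParams")(small_cfg)
  toks <- list(c(2L, 5L, 7L), c(9L, 4L), c(11L, 3L), c(8L, 6L),
               c(2L, 5L, 7L))
  enc <- cpp("cppEncode")(params, small_cfg, toks)
  expect_equal(enc$vectors[, 1], enc$vectors[, 5], tolerance = 1e-12)
})

test_that("long sentences are chunked with full token coverage", {
  sc <- generateCorpus(syntheticConfig(n_cancer = 4, n_noncancer = 0, seed = 6))
  insts <- buildAbstractionInstances(corpus(sc), "site")
  texts <- unlist(lapply(insts, function(x) x@sentences$text))
  vocab <- buildSubwordVocab(texts, 200)
  inst <- insts[[1]]
  max_tokens <- 4L
  fr <- OncoAbstract:::.instance_frags(vocab, inst, max_tokens)
  # fragments cover each sentence's subword sequence exactly, in order
  sent_ids <- lapply(seq_len(nrow(inst@sentences)), function(i)
    as.integer(encodeTokens(vocab, inst@sentences$tokens[[i]])) - 1L)
  key <- paste(fr$frag_map$note_id, fr$frag_map$sentence_index)
  for (i in seq_len(nrow(inst@sentences))) {
    k <- paste(inst@sentences$note_id[i], inst@sentences$sentence_index[i])
    got <- unlist(fr$toks[key == k])
    expect_identical(got, sent_ids[[i]])
    expect_true(all(lengths(fr$toks[key == k]) <= max_tokens))
  }
})

test_that("contextualization is order-sensitive but shape-preserving", {
  set.seed(3)
  params <- cpp("cppInitParams")(small_cfg)
  one <- matrix(rnorm(8), 8, 1)
  expect_equal(dim(cpp("cppContextualize")(params, small_cfg, one)), c(10L, 1L))
  S <- matrix(rnorm(8 * 4), 8, 4)
  C1 <- cpp("cppContextualize")(params, small_cfg, S)
  C2 <- cpp("cppContextualize")(params, small_cfg, S[, c(3, 1, 4, 2)])
  expect_gt(max(abs(C1[, 1] - C2[, 2])), 1e-8)  # not a bag of sentences
  # zeroed parameters: recurrence passes nothing, outputs constant
  zero <- rep(0, length(params))
  C0 <- cpp("cppContextualize")(zero, small_cfg, S)
  expect_equal(max(abs(C0 - C0[, 1])), 0)
})

test_that("aggregation matches a hand-computed weighted-sum oracle", {
  set.seed(4)
  params <- cpp("cppInitParams")(small_cfg)
  G <- small_cfg$gru_hidden
  Ctx <- matrix(rnorm(2 * G * 4), 2 * G, 4)
  nidx <- c(0L, 0L, 1L, 1L)
  out <- cpp("cppAggregate")(params, small_cfg, Ctx, nidx)
  # independent R reimplementation with the unpacked parameter tensors
  A <- small_cfg$attn_dim
  npar <- length(params)
  C <- small_cfg$n_labels
  # parameter walk order: ..., Wa(A x 2G), ba, ua, Wn, bn, un, Wc(C x 2G), bc
  tail_len <- 2 * (A * 2 * G + A + A) + C * 2 * G + C
  off <- npar - tail_len
  take <- function(n) { v <- params[(off + 1):(off + n)]; off <<- off + n; v }
  Wa <- matrix(take(A * 2 * G), A, 2 * G); ba <- take(A); ua <- take(A)
  Wn <- matrix(take(A * 2 * G), A, 2 * G); bn <- take(A); un <- take(A)
  sc <- as.vector(t(ua) %*% tanh(Wa %*% Ctx + ba))
  al <- c(exp(sc[1:2]) / sum(exp(sc[1:2])), exp(sc[3:4]) / sum(exp(sc[3:4])))
  N <- cbind(Ctx[, 1:2] %*% al[1:2], Ctx[, 3:4] %*% al[3:4])
  ns <- as.vector(t(un) %*% tanh(Wn %*% N + bn))
  be <- exp(ns) / sum(exp(ns))
  pat <- N %*% be
  expect_equal(out$sent_w, al, tolerance = 1e-9)
  expect_equal(out$note_w, be, tolerance = 1e-9)
  expect_equal(out$patient, as.vector(pat), tolerance = 1e-9)

  # single note, single sentence: identity pooling, all weights 1
  one <- cpp("cppAggregate")(params, small_cfg, Ctx[, 1, drop = FALSE], 0L)
  expect_equal(one$patient, Ctx[, 1], tolerance = 1e-12)
  expect_equal(one$sent_w, 1); expect_equal(one$note_w, 1)

  # two identical notes: note weights split evenly by symmetry
  Ctx2 <- cbind(Ctx[, 1:2], Ctx[, 1:2])
  two <- cpp("cppAggregate")(params, small_cfg, Ctx2, c(0L, 0L, 1L, 1L))
  expect_equal(two$note_w, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("the softmax head reproduces closed-form probabilities", {
  npar <- cpp("cppNParams")(small_cfg)
  G <- small_cfg$gru_hidden; C <- small_cfg$n_labels
  zero <- rep(0, npar)
  pvec <- rnorm(2 * G)
  expect_equal(cpp("cppClassify")(zero, small_cfg, pvec), rep(1 / C, C))
  # engineer logits (2, 0, 0): Wc[1,1] = 1, patient vector e1 * 2
  params <- zero
  wc_off <- npar - (C * 2 * G + C)
  params[wc_off + 1] <- 1          # column-major: Wc[1,1]
  p <- cpp("cppClassify")(params, small_cfg, c(2, rep(0, 2 * G - 1)))
  expect_equal(p[1], exp(2) / (exp(2) + 2), tolerance = 1e-12)
  # the two-label closed form printed in the docs
  expect_equal(exp(2) / (exp(2) + 1), 0.8808, tolerance = 1e-4)
})

test_that("training memorizes a separable toy set and is seed-reproducible", {
  insts <- toy_separable_set()
  labels <- c("NULL", "LUNG", "LIVER")
  cfgA <- tiny_model_cfg(labels, seed = 13)
  m1 <- trainHierModel(insts, labels, cfgA)
  expect_lte(nrow(m1@history), 50L)
  preds <- predictHier(m1, insts)
  got <- vapply(preds, function(p) p@label, "")
  want <- vapply(insts, function(x) x@label, "")
  expect_equal(mean(got == want), 1)

  m2 <- trainHierModel(insts, labels, cfgA)
  expect_identical(m1@params, m2@params)
  expect_identical(m1@history$train_loss, m2@history$train_loss)

  expect_error(trainHierModel(insts[c(1, 3)], labels, cfgA), "single label")
})

test_that("batch prediction equals instance-by-instance prediction", {
  insts <- toy_separable_set(4)
  labels <- c("NULL", "LUNG", "LIVER")
  m <- trainHierModel(insts, labels, tiny_model_cfg(labels, seed = 3))
  batch <- predictHier(m, insts)
  for (i in seq_along(insts)) {
    single <- predictHier(m, insts[[i]])
    expect_identical(single@probs, batch[[i]]@probs)
  }
  # empty instance propagates the encoder guard
  empty <- insts[[1]]
  empty@sentences <- empty@sentences[0, ]
  expect_error(predictHier(m, empty), "no sentences in window")
  # schema mismatch
  wrong <- insts[[1]]
  wrong@attribute <- "histology"
  expect_error(predictHier(m, wrong), "schema mismatch")
})

test_that("checkpoints round-trip through text files", {
  insts <- toy_separable_set(3)
  labels <- c("NULL", "LUNG", "LIVER")
  m <- trainHierModel(insts, labels, tiny_model_cfg(labels, seed = 5))
  dir <- tempfile()
  writeHierModel(m, dir)
  m2 <- readHierModel(dir)
  expect_equal(m2@params, m@params)
  p1 <- predictHier(m, insts[[1]]); p2 <- predictHier(m2, insts[[1]])
  expect_equal(p1@probs, p2@probs)
  expect_identical(p1@label, p2@label)
})
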