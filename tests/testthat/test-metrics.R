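test_that("micro AUROC/AUPRC behave on the canonical edge cases", {
  labels <- c("A", "B", "C")
  truth <- c("A", "B", "C")
  perfect <- diag(3); colnames(perfect) <- labels
  expect_equal(microAUROC(truth, perfect), 1)
  expect_equal(microAUPRC(truth, perfect), 1)

  flat <- matrix(1 / 3, 3, 3, dimnames = list(NULL, labels))
  expect_equal(microAUROC(truth, flat), 0.5)
  # all ties: AUPRC equals the positive fraction q
  expect_equal(microAUPRC(truth, flat), 3 / 9)

  expect_error(microAUROC(c("A", "A"),
                          matrix(c(1, 1), 2, 1, dimnames = list(NULL, "A"))),
               "degenerate")
})

test_that("micro metrics match the brute-force oracles exactly", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(2:8, 1); k <- sample(2:6, 1)
    labels <- LETTERS[1:k]
    truth <- sample(labels, n, replace = TRUE)
    scores <- matrix(sample(0:5, n * k, replace = TRUE) / 5, n, k,
                     dimnames = list(NULL, labels))
    y <- as.integer(as.vector(outer(truth, labels, `==`)))
    s <- as.vector(scores)
    if (sum(y) == 0 || sum(y) == length(y)) next
    expect_equal(microAUROC(truth, scores), oracle_auroc(y, s),
                 tolerance = 1e-12)
    expect_equal(microAUPRC(truth, scores), oracle_auprc(y, s),
                 tolerance = 1e-12)
  }
})

test_that("micro metrics are invariant under strictly monotone score maps", {
  set.seed(5)
  labels <- LETTERS[1:4]
  truth <- sample(labels, 12, replace = TRUE)
  scores <- matrix(runif(48), 12, 4, dimnames = list(NULL, labels))
  f <- function(x) exp(3 * x) + 1        # strictly increasing
  expect_equal(microAUROC(truth, scores), microAUROC(truth, f(scores)))
  expect_equal(microAUPRC(truth, scores), microAUPRC(truth, f(scores)))
})

test_that("accuracy counts argmax hits with schema-order tie-breaks", {
  labels <- c("A", "B")
  truth <- c(rep("A", 7), rep("B", 3))
  scores <- rbind(matrix(rep(c(1, 0), 7), ncol = 2, byrow = TRUE),
                  matrix(rep(c(1, 0), 3), ncol = 2, byrow = TRUE))
  colnames(scores) <- labels
  out <- accuracyScore(truth, scores)
  expect_equal(out$accuracy, 0.7)
  expect_equal(as.integer(out$confusion["B", "A"]), 3L)
  # exact tie goes to the first label in schema order
  tie <- matrix(c(0.5, 0.5), 1, 2, dimnames = list(NULL, labels))
  expect_equal(accuracyScore("B", tie)$accuracy, 0)
})

test_that("fairness audit applies the 80% rule and the small-n annotation", {
  # constructed so group accuracies are exactly 48.3% and 69.6%
  mk <- function(n_right, n_wrong) {
    truth <- c(rep("A", n_right), rep("B", n_wrong))
    scores <- matrix(rep(c(1, 0), n_right + n_wrong), ncol = 2, byrow = TRUE,
                     dimnames = list(NULL, c("A", "B")))
    list(truth = truth, scores = scores)
  }
  g1 <- mk(483, 517); g2 <- mk(696, 304)
  truth <- c(g1$truth, g2$truth)
  scores <- rbind(g1$scores, g2$scores)
  grp <- c(rep("islander", 1000), rep("reference", 1000))
  rep_ <- fairnessAudit(truth, scores, grp, reference_group = "reference")
  expect_equal(rep_$ratio[rep_$subgroup == "reference"], 1)
  r <- rep_$ratio[rep_$subgroup == "islander"]
  expect_equal(round(r, 3), 0.694)
  expect_true(rep_$flagged[rep_$subgroup == "islander"])
  expect_false(rep_$flagged[rep_$subgroup == "reference"])

  # identical performance: no flags
  same <- fairnessAudit(truth, scores, rep(c("x", "y"), 1000), "x")
  expect_true(all(abs(same$ratio - 1) < 0.05))
  expect_false(any(same$flagged))

  # a 29-member subgroup is annotated unstable regardless of its ratio
  grp2 <- c(rep("small", 29), rep("big", 1971))
  rep2 <- fairnessAudit(truth, scores, grp2, "big")
  expect_true(rep2$unstable[rep2$subgroup == "small"])
  expect_false(rep2$unstable[rep2$subgroup == "big"])

  expect_error(fairnessAudit(truth, scores, grp, "nope"), "unknown reference")
})
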