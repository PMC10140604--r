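.flatten_ovr <- function(truth, scores, labels) {
  stopifnot(is.matrix(scores), length(truth) == nrow(scores))
  if (is.null(labels)) labels <- colnames(scores)
  stopifnot(!is.null(labels), ncol(scores) == length(labels),
            all(truth %in% labels))
  y <- as.integer(outer(truth, labels, `==`))
  list(y = as.vector(y), s = as.vector(scores))
}

#' Micro-averaged AUROC over one-vs-rest flattened pairs
#'
#' Every (instance, label) cell becomes one binary decision: indicator of the
#' true label against its score. AUROC is the probability that a positive
#' cell outscores a negative cell, with ties counted 1/2 (computed via
#' midranks, which is exactly the pairwise definition).
#'
#' @param truth character vector of true labels.
#' @param scores numeric matrix (instances x labels) with labels as colnames
#'   (or supplied via `labels`).
#' @param labels label order matching the score columns.
#' @param exclude_null drop the `"NULL"` column from micro aggregation.
#' @return AUROC in \[0, 1\].
#' @export
microAUROC <- function(truth, scores, labels = colnames(scores),
                       exclude_null = FALSE) {
  if (exclude_null) {
    keep <- labels != NULL_LABEL
    scores <- scores[, keep, drop = FALSE]; labels <- labels[keep]
    ok <- truth %in% labels
    truth <- truth[ok]; scores <- scores[ok, , drop = FALSE]
  }
  fl <- .flatten_ovr(truth, scores, labels)
  npos <- sum(fl$y == 1L); nneg <- sum(fl$y == 0L)
  if (npos == 0L || nneg == 0L)
    stop("degenerate input: need at least one positive and one negative pair")
  r <- rank(fl$s, ties.method = "average")
  (sum(r[fl$y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Micro-averaged AUPRC (average precision) over flattened pairs
#'
#' Area under the precision-recall curve computed as average precision with
#' step interpolation: cells are sorted by decreasing score, equal scores are
#' processed as one block, and each block contributes its end-of-block
#' precision weighted by the recall it adds.
#'
#' @inheritParams microAUROC
#' @return AUPRC in \[0, 1\].
#' @export
microAUPRC <- function(truth, scores, labels = colnames(scores),
                       exclude_null = FALSE) {
  if (exclude_null) {
    keep <- labels != NULL_LABEL
    scores <- scores[, keep, drop = FALSE]; labels <- labels[keep]
    ok <- truth %in% labels
    truth <- truth[ok]; scores <- scores[ok, , drop = FALSE]
  }
  fl <- .flatten_ovr(truth, scores, labels)
  P <- sum(fl$y == 1L)
  if (P == 0L) stop("degenerate input: no positive pairs")
  o <- order(fl$s, decreasing = TRUE)
  y <- fl$y[o]; s <- fl$s[o]
  # tie blocks
  block <- cumsum(!duplicated(s))
  pos_in <- as.vector(rowsum(y, block))           # groups sorted numerically
  n_in <- as.vector(rowsum(rep(1L, length(y)), block))
  cum_pos <- cumsum(pos_in); cum_n <- cumsum(n_in)
  prec <- cum_pos / cum_n
  sum(prec * (pos_in / P))
}

#' Argmax accuracy and per-class confusion table
#'
#' Ties at the argmax are broken by schema label order (first column wins).
#'
#' @inheritParams microAUROC
#' @return list with `accuracy` and `confusion` (truth x predicted table).
#' @export
accuracyScore <- function(truth, scores, labels = colnames(scores)) {
  stopifnot(ncol(scores) == length(labels))
  pred <- labels[apply(scores, 1L, which.max)]
  list(accuracy = mean(pred == truth),
       confusion = table(truth = factor(truth, levels = labels),
                         predicted = factor(pred, levels = labels)))
}

#' Disparate-impact fairness audit (80% rule)
#'
#' Computes a metric per demographic subgroup, its ratio to the reference
#' subgroup, and flags subgroups whose ratio falls below 0.8. Subgroups
#' smaller than `min_n` are annotated as unstable (small n) since their
#' ratios are dominated by sampling noise.
#'
#' @param truth true labels per instance.
#' @param scores score matrix per instance.
#' @param subgroup character vector assigning each instance to a subgroup.
#' @param reference_group subgroup used as denominator (ratio 1 by
#'   construction).
#' @param metric function(truth, scores) -> scalar; default argmax accuracy.
#' @param labels label order for the score columns.
#' @param min_n minimum subgroup size for a stable estimate (default 100).
#' @return data.frame of class `"FairnessReport"` with columns subgroup, n,
#'   value, ratio, flagged, unstable.
#' @export
fairnessAudit <- function(truth, scores, subgroup, reference_group,
                          metric = function(tr, sc) accuracyScore(tr, sc)$accuracy,
                          labels = colnames(scores), min_n = 100L) {
  stopifnot(length(subgroup) == length(truth), !anyNA(subgroup))
  if (!(reference_group %in% subgroup))
    stop(sprintf("unknown reference group '%s'", reference_group))
  groups <- unique(c(reference_group, sort(unique(subgroup))))
  vals <- vapply(groups, function(g) {
    idx <- subgroup == g
    metric(truth[idx], scores[idx, , drop = FALSE])
  }, numeric(1))
  ref <- vals[[1L]]
  out <- data.frame(subgroup = groups,
                    n = as.integer(table(factor(subgroup, levels = groups))[groups]),
                    value = unname(vals),
                    ratio = unname(vals) / ref,
                    stringsAsFactors = FALSE)
  out$flagged <- out$ratio < 0.8
  out$unstable <- out$n < min_n
  class(out) <- c("FairnessReport", "data.frame")
  out
}

#' @export
print.FairnessReport <- function(x, ...) {
  cat("Fairness audit (80% rule); reference =", x$subgroup[1], "\n")
  y <- as.data.frame(x)
  y$note <- ifelse(x$unstable, "unstable (small n)", "")
  y$note[x$flagged] <- paste(y$note[x$flagged], "FLAGGED")
  print(y, row.names = FALSE, ...)
  invisible(x)
}
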