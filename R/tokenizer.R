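#' Build a subword vocabulary by greedy pair merging
#'
#' Word-internal byte-pair-style induction: starting from characters, the
#' most frequent adjacent symbol pair (ties broken lexicographically, for
#' determinism) is merged repeatedly until the unit inventory reaches
#' `vocab_size` (less the two specials) or no pair occurs at least twice.
#'
#' @param texts character vector of training texts.
#' @param vocab_size target total vocabulary size including the `[CLS]` and
#'   `[UNK]` specials.
#' @return an object of class `"SubwordVocab"`: merge list, unit inventory,
#'   and id mapping (ids 1 and 2 are reserved for `[CLS]` and `[UNK]`).
#' @export
buildSubwordVocab <- function(texts, vocab_size = 2000) {
  words <- unlist(lapply(texts, function(t) wordTokens(t)$token))
  if (!length(words)) stop("no tokens in training texts")
  wf <- table(words)
  freq <- as.integer(wf)
  syms <- lapply(names(wf), function(w) strsplit(w, "", fixed = TRUE)[[1]])
  merges <- character()
  repeat {
    units <- unique(unlist(syms, use.names = FALSE))
    if (length(units) + 2L >= vocab_size) break
    # count adjacent pairs weighted by word frequency
    keys <- character(); cnts <- integer()
    tallies <- new.env(parent = emptyenv())
    for (i in seq_along(syms)) {
      s <- syms[[i]]
      if (length(s) < 2L) next
      prs <- paste(s[-length(s)], s[-1L], sep = "\t")
      for (p in unique(prs)) {
        k <- sum(prs == p) * freq[i]
        tallies[[p]] <- (if (is.null(tallies[[p]])) 0L else tallies[[p]]) + k
      }
    }
    keys <- ls(tallies)
    if (!length(keys)) break
    cnts <- vapply(keys, function(k) tallies[[k]], integer(1))
    best <- max(cnts)
    if (best < 2L) break
    cand <- sort(keys[cnts == best])[1L]
    merges <- c(merges, cand)
    ab <- strsplit(cand, "\t", fixed = TRUE)[[1]]
    syms <- lapply(syms, .apply_merge, ab[1], ab[2])
  }
  units <- sort(unique(unlist(syms, use.names = FALSE)))
  vocab <- list(merges = merges, units = units,
                unit_ids = stats::setNames(seq_along(units) + 2L, units),
                cache = new.env(parent = emptyenv()))
  class(vocab) <- "SubwordVocab"
  vocab
}

.apply_merge <- function(s, a, b, joined = paste0(a, b)) {
  n <- length(s)
  if (n < 2L) return(s)
  out <- character(n); j <- 0L; i <- 1L
  while (i <= n) {
    if (i < n && s[i] == a && s[i + 1L] == b) {
      j <- j + 1L; out[j] <- joined; i <- i + 2L
    } else {
      j <- j + 1L; out[j] <- s[i]; i <- i + 1L
    }
  }
  out[seq_len(j)]
}

#' Encode word tokens into subword ids
#'
#' Applies the learned merges to each word (memoized) and maps units to ids;
#' units never seen in training map to `[UNK]` (id 2).
#'
#' @param vocab a `"SubwordVocab"`.
#' @param tokens character vector of (lowercased) word tokens.
#' @return integer vector of subword ids; attribute `"word_of"` gives, for
#'   each subword, the index of the word it came from.
#' @export
encodeTokens <- function(vocab, tokens) {
  ids <- lapply(tokens, function(w) {
    hit <- vocab$cache[[w]]
    if (!is.null(hit)) return(hit)
    s <- strsplit(w, "", fixed = TRUE)[[1]]
    for (m in vocab$merges) {
      ab <- strsplit(m, "\t", fixed = TRUE)[[1]]
      s <- .apply_merge(s, ab[1], ab[2])
      if (length(s) == 1L) break
    }
    v <- unname(vocab$unit_ids[s])
    v[is.na(v)] <- 2L
    vocab$cache[[w]] <- v
    v
  })
  out <- as.integer(unlist(ids, use.names = FALSE))
  attr(out, "word_of") <- rep(seq_along(tokens), lengths(ids))
  out
}

#' @export
print.SubwordVocab <- function(x, ...) {
  cat("SubwordVocab:", length(x$units) + 2L, "ids (",
      length(x$merges), "merges )\n")
  invisible(x)
}
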