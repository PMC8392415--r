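#' Hypergeometric specificity test for one word
#'
#' Tests whether a word occurs more frequently in a condition subcorpus than
#' expected from the pooled corpus: with N total tokens in the corpus, K of
#' them the word in question, and a subcorpus of n tokens containing k of
#' the word, the one-sided upper-tail p-value is P(X >= k) for
#' X ~ Hypergeometric(N, K, n). Under-representation (lower tail,
#' P(X <= k)) is available behind `tail = "under"` but off by default.
#'
#' @param N Corpus token total.
#' @param K Word count in the whole corpus.
#' @param n Subcorpus token total.
#' @param k Word count in the subcorpus.
#' @param alpha Significance level (default 0.05).
#' @param tail `"over"` (default) or `"under"`.
#' @return A `specificity_result` list: the counts, `p_value`,
#'   `significant`.
#' @export
specificity_test <- function(N, K, n, k, alpha = 0.05, tail = c("over", "under")) {
  tail <- match.arg(tail)
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1, length(k) == 1)
  if (K > N || n > N || k > min(K, n) || k < max(0, K + n - N) ||
      any(c(N, K, n, k) < 0))
    stop("inconsistent counts: need 0 <= k <= min(K, n), K <= N, n <= N")
  p <- if (tail == "over")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  else
    stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  structure(list(corpus_size = N, corpus_count = K,
                 subcorpus_size = n, subcorpus_count = k,
                 p_value = p, alpha = alpha, tail = tail,
                 significant = p <= alpha),
            class = "specificity_result")
}

#' @export
print.specificity_result <- function(x, ...) {
  cat(sprintf("hypergeometric %s-representation: k=%d/%d vs K=%d/%d, p = %.4g%s\n",
              x$tail, x$subcorpus_count, x$subcorpus_size,
              x$corpus_count, x$corpus_size, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Condition-wise descriptor specificity analysis
#'
#' For every condition, tests each lemma of a descriptor corpus for
#' over-representation in that condition's subcorpus relative to the pooled
#' corpus, and reports the words significant at `alpha`, sorted by p-value.
#' No multiple-testing correction is applied (raw per-word flags).
#'
#' @param words data.frame with columns `condition` and `word` (one row per
#'   token, words already lemmatized), e.g. the `descriptors` of a
#'   [sorting_data()] joined with condition labels.
#' @param alpha Significance level (default 0.05).
#' @param all_results Return every test instead of only the significant
#'   ones?
#' @return data.frame: `condition`, `word`, `subcorpus_count`,
#'   `subcorpus_size`, `corpus_count`, `corpus_size`, `rel_freq_condition`,
#'   `rel_freq_corpus`, `p_value`, `significant`.
#' @export
condition_specificities <- function(words, alpha = 0.05, all_results = FALSE) {
  stopifnot(is.data.frame(words),
            all(c("condition", "word") %in% names(words)))
  words <- words[!is.na(words$word) & words$word != "", , drop = FALSE]
  conds <- unique(as.character(words$condition))
  if (length(conds) < 2) stop("need at least two conditions")
  N <- nrow(words)
  K_tab <- table(words$word)
  out <- list()
  for (cond in conds) {
    sub <- words$word[words$condition == cond]
    n <- length(sub)
    if (n == 0) {
      warning("empty subcorpus for condition ", cond, "; skipped")
      next
    }
    k_tab <- table(sub)
    res <- do.call(rbind, lapply(names(k_tab), function(w) {
      k <- as.integer(k_tab[[w]]); K <- as.integer(K_tab[[w]])
      st <- specificity_test(N, K, n, k, alpha = alpha)
      data.frame(condition = cond, word = w,
                 subcorpus_count = k, subcorpus_size = n,
                 corpus_count = K, corpus_size = N,
                 rel_freq_condition = k / n, rel_freq_corpus = K / N,
                 p_value = st$p_value, significant = st$significant,
                 stringsAsFactors = FALSE)
    }))
    res <- res[order(res$p_value, res$word), , drop = FALSE]
    out[[cond]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (!all_results) out <- out[out$significant, , drop = FALSE]
  out
}

#' Tokenize group descriptors for specificity analysis
#'
#' Splits free-text group descriptions on whitespace and punctuation
#' (underscores kept, so multiword tags like `south_africa` survive),
#' normalizes, and looks each token up in a lexicon for lemmatization;
#' unknown tokens pass through normalized.
#'
#' @param text Character vector of group descriptions.
#' @param lx Optional [lexicon()] for lemma lookup.
#' @return Character vector of descriptor lemmas (one element per token).
#' @export
tokenize_descriptors <- function(text, lx = NULL) {
  toks <- unlist(strsplit(normalize_term(text), "[^[:alnum:]_']+"))
  toks <- toks[toks != ""]
  if (!is.null(lx)) {
    stopifnot(inherits(lx, "lexicon"))
    hit <- match(toks, lx$term)
    toks <- ifelse(is.na(hit), toks, lx$lemma[hit])
  }
  toks
}
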