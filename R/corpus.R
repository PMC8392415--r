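#' Construct a word-association corpus
#'
#' Long-format container for a free word-association task: one row per
#' participant x evoked word, with 1-7 importance and 1-7 valence ratings and
#' a panel (country) label. An optional `condition` column carries the
#' experimental condition. The `lemma` and `category` columns are filled by
#' [lemmatize()].
#'
#' @param records data.frame with at least `participant_id`, `country`,
#'   `word`, `importance`, `valence`.
#' @return An `association_corpus` (validated data.frame).
#' @export
association_corpus <- function(records) {
  req <- c("participant_id", "country", "word", "importance", "valence")
  stopifnot(is.data.frame(records), all(req %in% names(records)))
  rec <- as.data.frame(records, stringsAsFactors = FALSE)
  rec$participant_id <- as.character(rec$participant_id)
  rec$country <- as.character(rec$country)
  rec$word <- as.character(rec$word)
  ok <- function(x) is.numeric(x) && !anyNA(x) && all(x >= 1 & x <= 7)
  if (!ok(rec$importance) || !ok(rec$valence))
    stop("importance and valence ratings must be numeric in [1, 7]")
  if (!nrow(rec)) stop("empty corpus")
  class(rec) <- c("association_corpus", "data.frame")
  rec
}

#' Lemmatize an association corpus
#'
#' Maps each raw evoked word through the lexicon's term-to-lemma map and
#' attaches the lemma's semantic category. Terms absent from the lexicon
#' fall back to their normalized form (lower-cased, diacritics folded,
#' whitespace collapsed) with a warning listing them; their category is `NA`
#' until the lexicon is extended. The operation is idempotent.
#'
#' @param corpus An [association_corpus()].
#' @param lx A [lexicon()].
#' @return The corpus with `lemma` and `category` columns filled.
#' @export
lemmatize <- function(corpus, lx = default_lexicon()) {
  stopifnot(inherits(corpus, "association_corpus"), inherits(lx, "lexicon"))
  key <- normalize_term(corpus$word)
  hit <- match(key, lx$term)
  lemma <- ifelse(is.na(hit), key, lx$lemma[hit])
  # lemmas are themselves valid keys, so rerunning is a fixed point
  unmapped <- sort(unique(key[is.na(hit) & is.na(match(key, lx$lemma))]))
  if (length(unmapped))
    warning("terms not in lexicon, passed through normalized: ",
            paste(unmapped, collapse = ", "))
  corpus$lemma <- lemma
  corpus$category <- lx$category[match(lemma, lx$lemma)]
  corpus
}

#' Corpus diversity index
#'
#' Ratio of distinct evoked words to total evoked words; 1 means every token
#' is unique (maximum diversity), small values indicate a shared, structured
#' vocabulary.
#'
#' @param distinct_lemmas Number of distinct lemmatized words.
#' @param total_tokens Total number of evoked words.
#' @return Ratio in (0, 1].
#' @export
diversity_index <- function(distinct_lemmas, total_tokens) {
  if (length(total_tokens) != 1L || is.na(total_tokens) || total_tokens <= 0)
    stop("diversity index undefined: total token count must be positive")
  stopifnot(distinct_lemmas >= 0, distinct_lemmas <= total_tokens)
  distinct_lemmas / total_tokens
}

#' Corpus rarity index
#'
#' Proportion of hapaxes (words cited exactly once) among distinct words.
#'
#' @param hapax_count Number of hapaxes.
#' @param distinct_lemmas Number of distinct words.
#' @return Ratio in [0, 1].
#' @export
rarity_index <- function(hapax_count, distinct_lemmas) {
  if (length(distinct_lemmas) != 1L || is.na(distinct_lemmas) ||
      distinct_lemmas <= 0)
    stop("rarity index undefined: distinct word count must be positive")
  stopifnot(hapax_count >= 0, hapax_count <= distinct_lemmas)
  hapax_count / distinct_lemmas
}

#' Summarize a lemmatized corpus
#'
#' Token totals, distinct lemma and hapax counts, diversity and rarity
#' indices, token counts per semantic category and per-category mean
#' importance and valence. Every evoked token counts once (a participant
#' repeating a lemma contributes each citation) unless
#' `per_participant = TRUE`, which collapses repeated citations of a lemma
#' by the same participant to one.
#'
#' @param corpus A lemmatized [association_corpus()].
#' @param per_participant Count each participant's repeated lemma once?
#' @return A `corpus_summary` list.
#' @export
corpus_summary <- function(corpus, per_participant = FALSE) {
  stopifnot(inherits(corpus, "association_corpus"))
  if (is.null(corpus$lemma)) stop("corpus must be lemmatized first")
  cp <- corpus
  if (per_participant)
    cp <- cp[!duplicated(cp[, c("participant_id", "lemma")]), , drop = FALSE]
  tab <- table(cp$lemma)
  total <- nrow(cp)
  distinct <- length(tab)
  hapax <- sum(tab == 1L)
  cat_counts <- integer(length(wa_categories()))
  names(cat_counts) <- wa_categories()
  obs <- table(factor(cp$category, levels = wa_categories()))
  cat_counts[names(obs)] <- as.integer(obs)
  mean_by <- function(v) {
    m <- tapply(v, factor(cp$category, levels = wa_categories()), mean)
    as.numeric(m)
  }
  out <- list(
    n_participants = length(unique(cp$participant_id)),
    total_tokens = total,
    distinct_lemmas = distinct,
    hapax_count = hapax,
    diversity_index = diversity_index(distinct, total),
    rarity_index = rarity_index(hapax, distinct),
    category_counts = cat_counts,
    mean_importance = stats::setNames(mean_by(cp$importance), wa_categories()),
    mean_valence = stats::setNames(mean_by(cp$valence), wa_categories())
  )
  class(out) <- "corpus_summary"
  out
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat(sprintf(
    "Word-association corpus: %d participants, %d tokens, %d distinct lemmas\n",
    x$n_participants, x$total_tokens, x$distinct_lemmas))
  cat(sprintf("  diversity %.2f   rarity %.2f   hapaxes %d\n",
              x$diversity_index, x$rarity_index, x$hapax_count))
  df <- data.frame(count = x$category_counts,
                   importance = round(x$mean_importance, 2),
                   valence = round(x$mean_valence, 2))
  print(df, ...)
  invisible(x)
}

#' Per-country category frequency table
#'
#' Cross-tabulates token counts per semantic category by panel, with
#' per-category mean importance and valence, in the layout of a published
#' category-frequency table. Every lemma must be categorized.
#'
#' @param corpus A lemmatized, fully categorized [association_corpus()].
#' @param by Grouping column, default `"country"`.
#' @return data.frame: `category`, then one count / mean-importance /
#'   mean-valence column per group; class `category_table`.
#' @export
category_table <- function(corpus, by = "country") {
  stopifnot(inherits(corpus, "association_corpus"))
  if (is.null(corpus$lemma)) stop("corpus must be lemmatized first")
  if (anyNA(corpus$category)) {
    offenders <- sort(unique(corpus$lemma[is.na(corpus$category)]))
    stop("uncategorized lemmas: ", paste(offenders, collapse = ", "))
  }
  g <- factor(corpus[[by]])
  cats <- factor(corpus$category, levels = wa_categories())
  out <- data.frame(category = wa_categories(), stringsAsFactors = FALSE)
  for (lev in levels(g)) {
    sel <- g == lev
    counts <- table(cats[sel])
    out[[paste0("count_", lev)]] <- as.integer(counts)
    out[[paste0("importance_", lev)]] <-
      as.numeric(tapply(corpus$importance[sel], cats[sel], mean))
    out[[paste0("valence_", lev)]] <-
      as.numeric(tapply(corpus$valence[sel], cats[sel], mean))
  }
  class(out) <- c("category_table", "data.frame")
  out
}

#' Per-lemma citation frequency and mean importance
#'
#' Frequency is the number of distinct participants citing the lemma (the
#' degree of sharing), not the token count; importance is averaged over all
#' citations. This is the word table feeding the prototypical analysis.
#'
#' @param corpus A lemmatized [association_corpus()].
#' @return data.frame `lemma`, `frequency`, `mean_importance`, ordered by
#'   decreasing frequency.
#' @export
word_stats <- function(corpus) {
  stopifnot(inherits(corpus, "association_corpus"))
  if (is.null(corpus$lemma)) stop("corpus must be lemmatized first")
  freq <- tapply(corpus$participant_id, corpus$lemma,
                 function(p) length(unique(p)))
  imp <- tapply(corpus$importance, corpus$lemma, mean)
  out <- data.frame(lemma = names(freq),
                    frequency = as.integer(freq),
                    mean_importance = as.numeric(imp[names(freq)]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$lemma), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write association corpora as long-format TSV
#'
#' Columns: `participant_id`, `country`, `condition`, `word`, `importance`,
#' `valence` (plus `lemma`/`category` when present). Header comment lines
#' starting with `#` are ignored on read and may carry the simulation seed.
#'
#' @param path File path.
#' @return `read_associations()` returns an [association_corpus()].
#' @export
read_associations <- function(path) {
  association_corpus(utils::read.delim(path, stringsAsFactors = FALSE,
                                       quote = "", comment.char = "#"))
}

#' @rdname read_associations
#' @param corpus An [association_corpus()].
#' @param header_comment Optional comment string written as a `#` first line.
#' @export
write_associations <- function(corpus, path, header_comment = NULL) {
  stopifnot(inherits(corpus, "association_corpus"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(as.data.frame(corpus), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
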