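#' Semantic categories used for word-association corpora
#'
#' The closed set of eight semantic categories into which lemmatized evoked
#' words are grouped: Sensorial, Viti/Enology, Consumption mode, Emotional,
#' Origin, Food, Other, Usage.
#'
#' @return Character vector of the eight category labels, in canonical order.
#' @export
wa_categories <- function() {
  c("Sensorial", "Viti/Enology", "Consumption mode", "Emotional",
    "Origin", "Food", "Other", "Usage")
}

#' Normalize a raw term for lexicon lookup
#'
#' Lower-cases, folds diacritics to ASCII, collapses internal whitespace and
#' trims. Used both when building lexica and when lemmatizing corpora, so
#' hand-built bilingual lexica are matched case- and accent-insensitively.
#'
#' @param x Character vector of raw terms.
#' @return Normalized character vector.
#' @export
normalize_term <- function(x) {
  x <- tolower(trimws(as.character(x)))
  folded <- iconv(x, from = "", to = "ASCII//TRANSLIT")
  x[!is.na(folded)] <- folded[!is.na(folded)]
  gsub("[[:space:]]+", " ", x)
}

#' Construct a lexicon
#'
#' A lexicon maps raw evoked terms to lemmas and lemmas to one of the eight
#' semantic categories (see [wa_categories()]). Both maps must be functions:
#' a raw term may not map to two lemmas, nor a lemma to two categories.
#'
#' @param terms data.frame with columns `term`, `lemma`, `category`.
#' @return A `lexicon` object (validated data.frame).
#' @seealso [read_lexicon()], [default_lexicon()]
#' @export
lexicon <- function(terms) {
  stopifnot(is.data.frame(terms),
            all(c("term", "lemma", "category") %in% names(terms)))
  lx <- data.frame(term = normalize_term(terms$term),
                   lemma = normalize_term(terms$lemma),
                   category = as.character(terms$category),
                   stringsAsFactors = FALSE)
  if (any(lx$lemma == ""))
    stop("lexicon contains empty lemmas")
  bad_cat <- setdiff(unique(lx$category), wa_categories())
  if (length(bad_cat))
    stop("unknown categories in lexicon: ", paste(bad_cat, collapse = ", "))
  dup_term <- unique(lx$term[duplicated(lx[, c("term")])])
  dup_term <- dup_term[vapply(dup_term, function(t)
    length(unique(lx$lemma[lx$term == t])) > 1L, logical(1))]
  if (length(dup_term))
    stop("terms mapped to more than one lemma: ",
         paste(dup_term, collapse = ", "))
  per_lemma <- tapply(lx$category, lx$lemma, function(c) length(unique(c)))
  if (any(per_lemma > 1L))
    stop("lemmas mapped to more than one category: ",
         paste(names(per_lemma)[per_lemma > 1L], collapse = ", "))
  lx <- lx[!duplicated(lx$term), , drop = FALSE]
  rownames(lx) <- NULL
  class(lx) <- c("lexicon", "data.frame")
  lx
}

#' Read / write a lexicon as 3-column TSV
#'
#' The on-disk format is a tab-separated file with header
#' `term<TAB>lemma<TAB>category`.
#'
#' @param path File path.
#' @return `read_lexicon()` returns a `lexicon`; `write_lexicon()` returns
#'   `path` invisibly.
#' @export
read_lexicon <- function(path) {
  lexicon(utils::read.delim(path, stringsAsFactors = FALSE,
                            quote = "", comment.char = "#"))
}

#' @rdname read_lexicon
#' @param lx A `lexicon` object.
#' @export
write_lexicon <- function(lx, path) {
  stopifnot(inherits(lx, "lexicon"))
  utils::write.table(as.data.frame(lx), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Vocabulary of the bundled demonstration lexicon. Sensorial is deliberately
# the largest pool (mirrors real dry-white-wine corpora, where aroma/taste
# terms dominate); every category has >= 4 lemmas so degenerate profiles that
# put all mass on one category remain simulable. A few inflected raw variants
# are included so lemmatization is exercised end to end.
default_lexicon_table <- function() {
  pools <- list(
    "Sensorial" = c("fruity", "acidic", "crisp", "white", "fresh", "dry",
                    "wood", "tropical", "taste", "aroma", "citrus", "mineral",
                    "floral", "sour", "apple", "butter", "astringent", "sweet",
                    "green", "yellow", "bitter", "light", "smooth", "honey",
                    "guava", "grass", "spicy", "straw", "clear", "cold",
                    "rough", "pale", "vegetal", "oxidative", "ripe"),
    "Viti/Enology" = c("wine", "cultivar", "vine", "grape", "white wine",
                       "variety", "vintage", "harvest", "cellar", "barrel",
                       "vineyard", "winemaker"),
    "Consumption mode" = c("aperitif", "meal", "summer", "friends", "sun",
                           "festive", "conviviality", "family", "evening",
                           "holiday"),
    "Emotional" = c("pleasant", "joy", "delicious", "nice", "happy",
                    "relaxing"),
    "Origin" = c("loire", "anjou", "terroir", "south africa", "saumur",
                 "vouvray", "stellenbosch", "region"),
    "Food" = c("fish", "shellfish", "crustacean", "cheese", "oyster",
               "seafood"),
    "Other" = c("alcohol", "path", "kir", "glass bottle", "label"),
    "Usage" = c("drink", "bottle", "glass", "tasting", "cork", "pour")
  )
  base <- do.call(rbind, lapply(names(pools), function(cat)
    data.frame(term = pools[[cat]], lemma = pools[[cat]], category = cat,
               stringsAsFactors = FALSE)))
  variants <- data.frame(
    term = c("fruits", "fruité", "acid", "woody", "wines", "grapes",
             "fresh ", "Crispy", "meals", "friend", "aperitive",
             "south-africa", "tastings", "bottles", "fishes", "delicius"),
    lemma = c("fruity", "fruity", "acidic", "wood", "wine", "grape",
              "fresh", "crisp", "meal", "friends", "aperitif",
              "south africa", "tasting", "bottle", "fish", "delicious"),
    stringsAsFactors = FALSE)
  variants$category <- base$category[match(variants$lemma, base$lemma)]
  rbind(base, variants)
}

#' Bundled demonstration lexicon
#'
#' A ready-made English wine lexicon covering all eight semantic categories,
#' with a Sensorial pool large enough to emulate sensory-dominated corpora
#' and a handful of inflected variants mapping onto their lemmas. Intended
#' for simulation and examples; real studies supply their own lexicon via
#' [read_lexicon()].
#'
#' @return A `lexicon` object.
#' @export
default_lexicon <- function() lexicon(default_lexicon_table())
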