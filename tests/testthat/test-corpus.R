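test_that("lemmatization maps raw terms, falls back normalized, and is idempotent", {
  lx <- lexicon(data.frame(term = c("fruits", "fruit"),
                           lemma = c("fruit", "fruit"),
                           category = "Sensorial"))
  cp <- association_corpus(data.frame(
    participant_id = c("p1", "p1", "p2"), country = "FR",
    word = c("fruits", "Fruit ", "Terroir"),
    importance = c(5, 4, 6), valence = c(6, 6, 5)))
  expect_warning(out <- lemmatize(cp, lx), "terroir")
  expect_equal(out$lemma, c("fruit", "fruit", "terroir"))
  expect_equal(out$category, c("Sensorial", "Sensorial", NA))
  again <- suppressWarnings(lemmatize(out, lx))
  expect_identical(again$lemma, out$lemma)
})

test_that("diversity and rarity indices follow their defining ratios", {
  expect_equal(diversity_index(154, 500), 0.308)
  expect_equal(round(diversity_index(154, 500), 2), 0.31)
  expect_equal(round(diversity_index(180, 535), 2), 0.34)
  expect_equal(diversity_index(10, 10), 1.0)
  expect_error(diversity_index(0, 0), "positive")
  expect_equal(rarity_index(0, 20), 0.0)
  expect_equal(rarity_index(7, 7), 1.0)
  # counts {a:3, b:1, c:1, d:2}: hapaxes b, c among 4 distinct words
  counts <- c(a = 3, b = 1, c = 1, d = 2)
  expect_equal(rarity_index(sum(counts == 1), length(counts)), 0.5)
  expect_error(rarity_index(0, 0), "positive")
})

test_that("corpus summary agrees with a brute-force recount on a small corpus", {
  lx <- default_lexicon()
  words <- c("fruity", "fruity", "wood", "wine", "loire", "fish",
             "pleasant", "drink", "fruity", "acidic")
  cp <- lemmatize(association_corpus(data.frame(
    participant_id = rep(c("p1", "p2", "p3"), c(4, 4, 2)), country = "SA",
    word = words, importance = 1:10 %% 7 + 1, valence = rep(5, 10))), lx)
  s <- corpus_summary(cp)
  tab <- table(words)
  expect_equal(s$total_tokens, 10)
  expect_equal(s$distinct_lemmas, length(tab))
  expect_equal(s$hapax_count, sum(tab == 1))
  expect_equal(s$diversity_index, length(tab) / 10)
  expect_equal(sum(s$category_counts), s$total_tokens)
  expect_equal(unname(s$category_counts["Sensorial"]),
               sum(words %in% c("fruity", "wood", "acidic")))
})

test_that("duplicating a token strictly decreases diversity, participant order is immaterial", {
  cp <- lemmatize(simulate_associations(sa_panel_profile(), seed = 11))
  s1 <- corpus_summary(cp)
  dup <- association_corpus(rbind(as.data.frame(cp), as.data.frame(cp)[1, ]))
  s2 <- corpus_summary(lemmatize(dup))
  expect_lt(s2$diversity_index, s1$diversity_index)
  perm <- association_corpus(as.data.frame(cp)[sample(nrow(cp)), ])
  s3 <- corpus_summary(lemmatize(perm))
  expect_equal(s3$rarity_index, s1$rarity_index)
  expect_equal(s3$category_counts, s1$category_counts)
})

test_that("category table counts tokens and averages ratings per panel", {
  lx <- default_lexicon()
  cp <- lemmatize(association_corpus(data.frame(
    participant_id = "p1", country = "SA", word = "fruity",
    importance = 5, valence = 6)), lx)
  tab <- category_table(cp)
  expect_equal(tab$count_SA[tab$category == "Sensorial"], 1L)
  expect_equal(sum(tab$count_SA), 1L)
  expect_equal(tab$importance_SA[tab$category == "Sensorial"], 5)
  expect_equal(tab$valence_SA[tab$category == "Sensorial"], 6)

  # degenerate profile: all mass on one category -> single nonzero row
  w <- stats::setNames(c(1, rep(0, 7)), wa_categories())
  prof <- panel_profile("X", 12, w, importance_means = rep(4, 8),
                        valence_means = rep(4, 8))
  cpx <- lemmatize(simulate_associations(prof, lx, seed = 3), lx)
  tabx <- category_table(cpx)
  expect_equal(tabx$count_X[tabx$category == "Sensorial"], 48L)
  expect_equal(sum(tabx$count_X), 48L)

  # uncategorized lemmas are a hard error listing offenders
  bad <- cp
  bad$category[1] <- NA
  expect_error(category_table(bad), "fruity")
})

test_that("token counts are conserved through lemmatization", {
  cp <- simulate_associations(fr_panel_profile(), seed = 5)
  lm <- lemmatize(cp)
  expect_equal(nrow(lm), nrow(cp))
  expect_equal(sum(corpus_summary(lm)$category_counts), nrow(cp))
})

test_that("association TSV round-trips through read/write", {
  cp <- lemmatize(simulate_associations(sa_panel_profile(), seed = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_associations(cp, path, header_comment = "seed 2")
  back <- read_associations(path)
  expect_equal(as.data.frame(back)$word, as.data.frame(cp)$word)
  expect_equal(as.data.frame(back)$importance, as.data.frame(cp)$importance)
})

test_that("word_stats counts citing participants, not tokens", {
  lx <- default_lexicon()
  cp <- lemmatize(association_corpus(data.frame(
    participant_id = c("p1", "p1", "p2"), country = "FR",
    word = c("fruity", "fruits", "fruity"),
    importance = c(4, 6, 5), valence = 5)), lx)
  ws <- word_stats(cp)
  expect_equal(ws$frequency[ws$lemma == "fruity"], 2L)  # p1 counted once
  expect_equal(ws$mean_importance[ws$lemma == "fruity"], 5)
})
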