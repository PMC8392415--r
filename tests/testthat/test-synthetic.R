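test_that("association simulation honours its contract and is seed-deterministic", {
  prof <- sa_panel_profile()
  c1 <- simulate_associations(prof, seed = 42)
  c2 <- simulate_associations(prof, seed = 42)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- simulate_associations(prof, seed = 43)
  expect_false(identical(as.data.frame(c1), as.data.frame(c3)))
  expect_equal(nrow(c1), 4 * prof$n_participants)
  expect_true(all(c1$importance %in% 1:7) && all(c1$valence %in% 1:7))
  # four distinct lemmas per participant
  lm <- lemmatize(c1)
  per <- tapply(lm$lemma, lm$participant_id, function(w)
    length(unique(w)))
  expect_true(all(per == 4))
})

test_that("degenerate weights produce a single-category corpus; empty weighted categories error", {
  w <- stats::setNames(c(1, rep(0, 7)), wa_categories())
  prof <- panel_profile("X", 25, w, rep(4, 8), rep(4, 8))
  cp <- lemmatize(simulate_associations(prof, seed = 1))
  expect_true(all(cp$category == "Sensorial"))
  lx_small <- lexicon(data.frame(term = c("a", "b", "c"), lemma = c("a", "b", "c"),
                                 category = "Sensorial"))
  expect_error(simulate_associations(prof, lx_small, seed = 1),
               "fewer than 4")
})

test_that("with no word-choice skew, category frequencies track the weights within 3 SE", {
  prof <- panel_profile("X", 2000, sa_panel_profile()$category_weights,
                        rep(4, 8), rep(4, 8), zipf_exponent = 0)
  cp <- lemmatize(simulate_associations(prof, seed = 8))
  n <- nrow(cp)
  obs <- table(factor(cp$category, levels = wa_categories())) / n
  for (cat in wa_categories()) {
    p <- prof$category_weights[[cat]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(obs[[cat]] - p), 3 * se + 1e-12)
  }
})

test_that("a sensory-dominant panel at study size keeps its sensory token share", {
  # Sensorial weight 0.59 at n = 107: binomial 95% interval for the share at
  # n*4 tokens is well inside [0.50, 0.68]; check across seeds
  prof <- sa_panel_profile()
  share <- vapply(1:20, function(s) {
    cp <- lemmatize(simulate_associations(prof, seed = 100 + s))
    mean(cp$category == "Sensorial")
  }, numeric(1))
  expect_gte(mean(share >= 0.50 & share <= 0.68), 0.95)
})

test_that("sorting simulation yields valid, seed-stable partitions within the group range", {
  prof <- sorting_profile(50, origin_weight = 0.5, noise_sd = 0.3)
  sd1 <- simulate_sorting(prof, seed = 7)
  sd2 <- simulate_sorting(prof, seed = 7)
  expect_identical(sd1$sorts, sd2$sorts)
  expect_identical(sd1$descriptors, sd2$descriptors)
  parts <- partitions(sd1)
  expect_length(parts, 50)
  for (p in parts) {
    expect_setequal(names(p), chenin_stimuli()$code)
    expect_false(anyNA(p))
    k <- length(unique(p))
    expect_gte(k, 2); expect_lte(k, 10)
    expect_true(all(table(p) >= 1))  # every block nonempty
  }
  expect_error(simulate_sorting(
    sorting_profile(5, n_groups_range = c(20, 25)), seed = 1), "infeasible")
})

test_that("noiseless fully origin-driven sorts reproduce the origin partition exactly", {
  prof <- sorting_profile(10, origin_weight = 1, noise_sd = 0,
                          n_groups_range = c(2, 2))
  sd0 <- simulate_sorting(prof, seed = 3)
  origin_part <- stats::setNames(chenin_stimuli()$origin,
                                 chenin_stimuli()$code)
  for (p in partitions(sd0))
    expect_equal(rand_index(p, origin_part), 1.0)
})

test_that("rand index matches pair enumeration and detects origin salience", {
  withr::with_seed(12, {
    for (rep in 1:10) {
      a <- random_partition(10, 3)
      b <- random_partition(10, 4)
      expect_equal(rand_index(a, b), oracle_rand(a, b))
    }
  })
  origin_part <- stats::setNames(chenin_stimuli()$origin,
                                 chenin_stimuli()$code)
  mean_rand <- function(w, seed) {
    sd1 <- simulate_sorting(sorting_profile(30, origin_weight = w,
                                            noise_sd = 0.25), seed = seed)
    mean(vapply(partitions(sd1), rand_index, numeric(1), b = origin_part))
  }
  expect_gt(mean_rand(1, 5), mean_rand(0, 5))
})

test_that("origin/partition agreement is monotone in origin salience", {
  origin_part <- stats::setNames(chenin_stimuli()$origin,
                                 chenin_stimuli()$code)
  agree <- vapply(c(0.1, 0.5, 0.9), function(w) {
    sd1 <- simulate_sorting(sorting_profile(40, origin_weight = w,
                                            noise_sd = 0.25), seed = 9)
    mean(vapply(partitions(sd1), rand_index, numeric(1), b = origin_part))
  }, numeric(1))
  expect_true(all(diff(agree) > 0))
})

test_that("sorting TSV round-trips through read/write", {
  sd1 <- make_sorting_fixture(8, seed = 31)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sorting(sd1, path, header_comment = "seed 31")
  back <- read_sorting(path, chenin_stimuli())
  expect_equal(partitions(back), partitions(sd1))
  expect_setequal(back$descriptors$descriptor, sd1$descriptors$descriptor)
  expect_equal(back$condition, "fix")
})
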