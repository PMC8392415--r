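#' Word-association panel profile
#'
#' Describes the statistical structure of a simulated panel: how its evoked
#' words distribute over the eight semantic categories, the per-category
#' mean importance and valence on the 1-7 scales, and a Zipf exponent
#' controlling within-category word-choice skew (0 = uniform choice, larger
#' values concentrate citations on few words and raise the hapax rate).
#'
#' @param name Panel label (used as the `country` column).
#' @param n_participants Positive integer.
#' @param category_weights Probability vector over [wa_categories()]
#'   (named or in canonical order); must sum to 1.
#' @param importance_means,valence_means Per-category means in [1, 7].
#' @param zipf_exponent Nonnegative within-category rank-frequency skew.
#' @param rating_sd SD of the latent normal behind the discretized 1-7
#'   ratings.
#' @return A `panel_profile` object.
#' @export
panel_profile <- function(name, n_participants, category_weights,
                          importance_means, valence_means,
                          zipf_exponent = 1, rating_sd = 1.2) {
  cats <- wa_categories()
  fix <- function(x, what) {
    if (!is.null(names(x))) {
      stopifnot(setequal(names(x), cats))
      x <- x[cats]
    }
    stopifnot(length(x) == length(cats))
    stats::setNames(as.numeric(x), cats)
  }
  w <- fix(category_weights)
  if (abs(sum(w) - 1) > 1e-9 || any(w < 0))
    stop("category_weights must be a probability vector summing to 1")
  im <- fix(importance_means); vm <- fix(valence_means)
  stopifnot(all(im >= 1 & im <= 7), all(vm >= 1 & vm <= 7),
            n_participants >= 1, zipf_exponent >= 0, rating_sd >= 0)
  structure(list(name = as.character(name),
                 n_participants = as.integer(n_participants),
                 category_weights = w, importance_means = im,
                 valence_means = vm, zipf_exponent = zipf_exponent,
                 rating_sd = rating_sd),
            class = "panel_profile")
}

#' Built-in panel profiles emulating the published study conditions
#'
#' `sa_panel_profile()`: 107 participants with the South African category
#' mix (sensory-dominant: 59% of tokens Sensorial). `fr_panel_profile()`:
#' 99 participants with the French mix (viti/enology- and origin-dominant).
#' Category weights are the published token shares; valence means are the
#' published per-category valences; importance means place the
#' panel-characteristic categories above the 1-7 midpoint so the
#' prototypical cores reproduce the published contrast.
#'
#' @return A [panel_profile()].
#' @export
sa_panel_profile <- function() {
  t3 <- chenin_table3()
  panel_profile(
    name = "SA", n_participants = 107,
    category_weights = t3$count_sa / sum(t3$count_sa),
    importance_means = c(5.6, 4.8, 4.5, 5.4, 4.2, 4.5, 4.0, 4.3),
    valence_means = t3$valence_sa,
    zipf_exponent = 1)
}

#' @rdname sa_panel_profile
#' @export
fr_panel_profile <- function() {
  t3 <- chenin_table3()
  panel_profile(
    name = "FR", n_participants = 99,
    category_weights = t3$count_fr / sum(t3$count_fr),
    importance_means = c(5.0, 5.8, 4.6, 5.2, 5.7, 4.6, 4.0, 4.4),
    valence_means = t3$valence_fr,
    zipf_exponent = 1)
}

#' Free-sorting panel profile
#'
#' @param n_participants Positive integer.
#' @param origin_weight Relative salience of the origin axis vs the style
#'   axis, in [0, 1]: 1 = participants perceive only the origin contrast,
#'   0 = only stylistic differences.
#' @param noise_sd SD of the Gaussian perceptual noise added to each latent
#'   coordinate.
#' @param n_groups_range Integer interval for admissible group counts.
#' @param link_threshold Range from which each participant's single-linkage
#'   merge threshold is drawn.
#' @return A `sorting_profile` object.
#' @export
sorting_profile <- function(n_participants, origin_weight = 0.5,
                            noise_sd = 0.25, n_groups_range = c(2L, 10L),
                            link_threshold = c(0.3, 0.8)) {
  stopifnot(n_participants >= 1,
            origin_weight >= 0, origin_weight <= 1, noise_sd >= 0,
            length(n_groups_range) == 2,
            n_groups_range[1] >= 1, n_groups_range[1] <= n_groups_range[2],
            length(link_threshold) == 2, link_threshold[1] > 0,
            link_threshold[1] <= link_threshold[2])
  structure(list(n_participants = as.integer(n_participants),
                 origin_weight = origin_weight, noise_sd = noise_sd,
                 n_groups_range = as.integer(n_groups_range),
                 link_threshold = link_threshold),
            class = "sorting_profile")
}

#' Simulate a word-association panel
#'
#' Each simulated participant evokes four distinct words: a semantic
#' category is drawn from the profile's category weights, a word within the
#' category from a Zipf-ranked choice distribution, and importance/valence
#' ratings are discretized truncated normals around the profile's
#' per-category means on the 1-7 scales. The raw written form is sampled
#' among the lexicon terms mapping to the chosen lemma, so downstream
#' lemmatization is exercised. Identical (profile, lexicon, seed) gives an
#' identical corpus.
#'
#' @param profile A [panel_profile()].
#' @param lx A [lexicon()]; every category with nonzero weight needs at
#'   least four lemmas.
#' @param seed Integer seed.
#' @param condition Optional condition label column.
#' @return An [association_corpus()] (not yet lemmatized).
#' @export
simulate_associations <- function(profile, lx = default_lexicon(), seed = 1L,
                                  condition = NA_character_) {
  stopifnot(inherits(profile, "panel_profile"), inherits(lx, "lexicon"))
  cats <- wa_categories()
  vocab <- lapply(cats, function(cc) unique(lx$lemma[lx$category == cc]))
  names(vocab) <- cats
  active <- cats[profile$category_weights > 0]
  short <- active[vapply(vocab[active], length, integer(1)) < 4L]
  if (length(short))
    stop("lexicon has fewer than 4 words for weighted categories: ",
         paste(short, collapse = ", "))
  rate <- function(mu) {
    r <- round(stats::rnorm(1, mu, profile$rating_sd))
    min(7L, max(1L, r))
  }
  withr::with_seed(seed, {
    rows <- vector("list", profile$n_participants)
    for (p in seq_len(profile$n_participants)) {
      # categories first (exactly multinomial), then distinct words within
      # each category; pools are disjoint across categories, so the four
      # words are distinct by construction
      pcats <- sample(cats, 4L, replace = TRUE,
                      prob = profile$category_weights)
      lemmas <- character(0)
      for (cc in unique(pcats)) {
        pool <- vocab[[cc]]
        wgt <- seq_along(pool)^(-profile$zipf_exponent)
        lemmas <- c(lemmas, sample(pool, sum(pcats == cc), prob = wgt))
      }
      pcats <- pcats[order(match(pcats, unique(pcats)))]
      raw <- vapply(lemmas, function(l) {
        forms <- lx$term[lx$lemma == l]
        if (length(forms) > 1L) sample(forms, 1L) else forms
      }, character(1))
      rows[[p]] <- data.frame(
        participant_id = sprintf("%s%03d", profile$name, p),
        country = profile$name, condition = condition,
        word = unname(raw),
        importance = vapply(profile$importance_means[pcats], rate, numeric(1)),
        valence = vapply(profile$valence_means[pcats], rate, numeric(1)),
        stringsAsFactors = FALSE)
    }
    association_corpus(do.call(rbind, rows))
  })
}

#' Simulate a free-sorting panel
#'
#' Participants perceive the stimuli as latent 2-D points — the origin axis
#' scaled by `origin_weight`, the style axis by `1 - origin_weight` — plus
#' Gaussian perceptual noise, and group them by single-linkage clustering
#' cut at a per-participant threshold; group counts falling outside
#' `n_groups_range` are re-cut at the nearest admissible count. Each group
#' receives sensory descriptors keyed to the quadrant of its perceived
#' centroid; optionally, origin-pure groups are additionally labelled with
#' the matching origin name (`loire` / `south_africa`) with probability
#' `origin_term_prob`, emulating origin-aware vocabularies under an
#' informed condition.
#'
#' @param profile A [sorting_profile()].
#' @param stimuli A [stimulus_set()], e.g. [chenin_stimuli()].
#' @param seed Integer seed.
#' @param condition Condition label stored on the dataset.
#' @param origin_term_prob Probability that an origin-pure group is tagged
#'   with its origin name (default 0).
#' @return A [sorting_data()].
#' @export
simulate_sorting <- function(profile, stimuli = chenin_stimuli(), seed = 1L,
                             condition = NA, origin_term_prob = 0) {
  stopifnot(inherits(profile, "sorting_profile"),
            inherits(stimuli, "stimulus_set"))
  n <- nrow(stimuli)
  if (n < 2) stop("need at least two stimuli")
  if (profile$n_groups_range[1] > n)
    stop("n_groups_range infeasible for ", n, " stimuli")
  kmin <- profile$n_groups_range[1]
  kmax <- min(profile$n_groups_range[2], n)
  pools <- list(
    origin_neg = c("fruity", "floral", "fresh", "citrus"),
    origin_pos = c("wood", "vegetal", "spicy", "oxidative"),
    style_pos = c("ripe", "rich", "sweet"),
    style_neg = c("acidic", "crisp", "lean"))
  origin_name <- function(o) if (o == "FR") "loire" else "south_africa"
  withr::with_seed(seed, {
    sort_rows <- vector("list", profile$n_participants)
    desc_rows <- list()
    for (p in seq_len(profile$n_participants)) {
      pid <- sprintf("P%03d", p)
      X <- cbind(profile$origin_weight * stimuli$axis_origin,
                 (1 - profile$origin_weight) * stimuli$axis_style) +
        matrix(stats::rnorm(2 * n, 0, profile$noise_sd), n, 2)
      hc <- stats::hclust(stats::dist(X), method = "single")
      h <- stats::runif(1, profile$link_threshold[1],
                        profile$link_threshold[2])
      g <- stats::cutree(hc, h = h)
      k <- max(g)
      if (k < kmin || k > kmax)
        g <- stats::cutree(hc, k = max(kmin, min(kmax, k)))
      sort_rows[[p]] <- data.frame(
        participant_id = pid, stimulus = stimuli$code, group_id = g,
        stringsAsFactors = FALSE)
      for (gid in sort(unique(g))) {
        members <- g == gid
        ctr <- colMeans(X[members, , drop = FALSE])
        main <- if (abs(ctr[1]) >= abs(ctr[2])) {
          if (ctr[1] >= 0) pools$origin_pos else pools$origin_neg
        } else {
          if (ctr[2] >= 0) pools$style_pos else pools$style_neg
        }
        words <- sample(main, min(2L, length(main)))
        side <- if (ctr[2] >= 0) pools$style_pos else pools$style_neg
        if (stats::runif(1) < 0.5)
          words <- c(words, sample(side, 1L))
        oc <- table(stimuli$origin[members])
        purity <- max(oc) / sum(oc)
        if (origin_term_prob > 0 && purity >= 0.75 &&
            stats::runif(1) < origin_term_prob)
          words <- c(words, origin_name(names(oc)[which.max(oc)]))
        desc_rows[[length(desc_rows) + 1L]] <- data.frame(
          participant_id = pid, group_id = gid, descriptor = unique(words),
          stringsAsFactors = FALSE)
      }
    }
    sorting_data(do.call(rbind, sort_rows),
                 do.call(rbind, desc_rows), stimuli, condition = condition)
  })
}

#' Rand index between two partitions
#'
#' Proportion of stimulus pairs on which two partitions agree (together in
#' both or separated in both); 1 means identical partitions.
#'
#' @param a,b Group-label vectors over the same stimuli (aligned by name
#'   when both are named).
#' @return Rand index in [0, 1].
#' @export
rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    stopifnot(setequal(names(a), names(b)))
    b <- b[names(a)]
  }
  stopifnot(length(a) == length(b), length(a) >= 2)
  same_a <- outer(a, a, `==`); same_b <- outer(b, b, `==`)
  up <- upper.tri(same_a)
  mean(same_a[up] == same_b[up])
}
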