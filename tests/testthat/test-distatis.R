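test_that("partition encoding gives 0/1 co-occurrence distances", {
  expect_equal(encode_distance(c(A = 1, B = 1, C = 1)),
               matrix(0L, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3])))
  d <- encode_distance(c(A = 1, B = 2, C = 3))
  expect_equal(d[upper.tri(d)], rep(1L, 3))
  d2 <- encode_distance(c(A = 1, B = 1, C = 2))
  expect_equal(unname(d2["A", "B"]), 0L)
  expect_equal(unname(d2["A", "C"]), 1L)
  expect_equal(unname(d2["B", "C"]), 1L)
  expect_error(encode_distance(c(1, 2)), "named")
})

test_that("cross-products are doubly centered, unit-first-eigenvalue, and PSD for sorting data", {
  s <- cross_product(matrix(c(0, 1, 1, 0), 2))
  expect_equal(s, matrix(c(0.5, -0.5, -0.5, 0.5), 2), tolerance = 1e-12)
  withr::with_seed(3, {
    for (rep in 1:10) {
      part <- stats::setNames(random_partition(8, sample(2:5, 1)),
                              letters[1:8])
      S <- cross_product(encode_distance(part))
      expect_equal(max(abs(rowSums(S))), 0, tolerance = 1e-10)
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      expect_equal(ev[1], 1, tolerance = 1e-10)
      expect_gt(min(ev), -1e-10)
    }
  })
  expect_warning(cross_product(matrix(0, 3, 3)), "all-zero")
})

test_that("RV coefficient matches the direct trace formula and its invariances", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      Sa <- cross_product(encode_distance(
        stats::setNames(random_partition(7, 3), letters[1:7])))
      Sb <- cross_product(encode_distance(
        stats::setNames(random_partition(7, 4), letters[1:7])))
      direct <- sum(diag(Sa %*% Sb)) /
        sqrt(sum(diag(Sa %*% Sa)) * sum(diag(Sb %*% Sb)))
      expect_equal(rv_coefficient(Sa, Sb), direct, tolerance = 1e-12)
      expect_equal(rv_coefficient(Sa, Sa), 1, tolerance = 1e-12)
      expect_equal(rv_coefficient(Sa, 3.7 * Sa), 1, tolerance = 1e-12)
      expect_gte(rv_coefficient(Sa, Sb), 0)
      expect_lte(rv_coefficient(Sa, Sb), 1 + 1e-12)
    }
  })
  expect_error(rv_coefficient(matrix(0, 2, 2), diag(2)), "zero")
})

test_that("identical tables get equal weights and return the common compromise", {
  S <- cross_product(encode_distance(c(A = 1, B = 1, C = 2, D = 3)))
  res <- distatis(list(S, S, S))
  expect_equal(unname(res$alpha), rep(1 / 3, 3))
  expect_equal(res$compromise, S, tolerance = 1e-12)
})

test_that("weighted partial scores average back to the compromise scores", {
  sd1 <- make_sorting_fixture(10, seed = 19)
  res <- distatis_sorting(sd1)
  avg <- Reduce(`+`, Map(`*`, res$partial_scores, res$alpha))
  expect_equal(avg, res$factor_scores, tolerance = 1e-10)
  expect_equal(sum(res$explained_variance), 1, tolerance = 1e-12)
  expect_gt(min(eigen(res$compromise, symmetric = TRUE,
                      only.values = TRUE)$values), -1e-10)
  expect_equal(sum(res$alpha), 1, tolerance = 1e-12)
})

test_that("the full pipeline equals an independent step-by-step computation", {
  d_list <- lapply(fixture_partitions(), encode_distance)
  res <- distatis(lapply(d_list, cross_product))
  orc <- oracle_distatis(d_list)
  expect_equal(unname(res$alpha), orc$alpha, tolerance = 1e-8)
  expect_equal(res$eigenvalues, orc$lambda, tolerance = 1e-8)
  expect_equal(unname(res$factor_scores), unname(orc$F), tolerance = 1e-8)
  for (k in seq_along(d_list))
    expect_equal(unname(res$partial_scores[[k]]), unname(orc$partial[[k]]),
                 tolerance = 1e-8)
})

test_that("pairs sorted together more often end up closer in the full compromise space", {
  sd1 <- make_sorting_fixture(25, seed = 23)
  Dsum <- sum_distances(distance_matrices(sd1))
  S <- cross_product(Dsum)
  # squared compromise distances from the cross-product
  d2 <- outer(diag(S), diag(S), `+`) - 2 * S
  up <- which(upper.tri(Dsum), arr.ind = TRUE)
  for (a in seq_len(nrow(up) - 1)) for (b in (a + 1):nrow(up)) {
    if (Dsum[up[a, 1], up[a, 2]] < Dsum[up[b, 1], up[b, 2]])
      expect_lt(d2[up[a, 1], up[a, 2]], d2[up[b, 1], up[b, 2]])
  }
})

test_that("RV map recovers condition similarity structure and ignores participant order", {
  prof <- sorting_profile(20, origin_weight = 0.3)
  sd_a <- simulate_sorting(prof, seed = 11, condition = "a")
  sd_b <- simulate_sorting(prof, seed = 11, condition = "b")   # identical sorts
  sd_c <- simulate_sorting(sorting_profile(20, origin_weight = 0.9),
                           seed = 12, condition = "c")
  sums <- list(a = sum_distances(distance_matrices(sd_a)),
               b = sum_distances(distance_matrices(sd_b)),
               c = sum_distances(distance_matrices(sd_c)))
  map <- rv_map(sums)
  expect_equal(map$rv_matrix["a", "b"], 1, tolerance = 1e-12)
  expect_equal(map$coordinates["a", ], map$coordinates["b", ],
               tolerance = 1e-8)
  expect_lt(map$rv_matrix["a", "c"], 1)
  # permuting participants leaves the summed matrix unchanged
  dl <- distance_matrices(sd_a)
  expect_equal(sum_distances(dl[sample(length(dl))]), sums$a)
  expect_error(rv_map(sums[1]), "two conditions")
})

test_that("bootstrap regions are seed-stable, collapse without noise, and shrink with panel size", {
  sd0 <- simulate_sorting(sorting_profile(12, origin_weight = 1,
                                          noise_sd = 0,
                                          n_groups_range = c(2, 2)),
                          seed = 2)
  b0 <- suppressWarnings(bootstrap_regions(sd0, n_boot = 60, seed = 1))
  expect_equal(max(b0$regions$semi_major), 0, tolerance = 1e-10)
  expect_warning(bootstrap_regions(sd0, n_boot = 60, seed = 1), "100")

  sd_small <- make_sorting_fixture(20, seed = 41, noise_sd = 0.35)
  sd_big <- make_sorting_fixture(80, seed = 41, noise_sd = 0.35)
  b_small <- bootstrap_regions(sd_small, n_boot = 200, seed = 6)
  b_big <- bootstrap_regions(sd_big, n_boot = 200, seed = 6)
  expect_lt(mean(b_big$regions$area), mean(b_small$regions$area))
  b_rep <- bootstrap_regions(sd_small, n_boot = 200, seed = 6)
  expect_identical(b_small$replicates, b_rep$replicates)
})

test_that("descriptor projection is the column-profile barycentre of stimulus scores", {
  sd1 <- make_sorting_fixture(10, seed = 53)
  res <- distatis_sorting(sd1)
  n <- nrow(res$factor_scores)
  M <- cbind(only_A = c(5L, rep(0L, n - 1)),
             uniform = rep(2L, n),
             dead = rep(0L, n))
  rownames(M) <- rownames(res$factor_scores)
  expect_warning(pr <- project_descriptors(res, M), "dead")
  expect_equal(pr$coordinates["only_A", ],
               res$factor_scores[1, ], tolerance = 1e-12)
  expect_equal(unname(pr$coordinates["uniform", ]),
               unname(colMeans(res$factor_scores)), tolerance = 1e-12)
  # centroid of doubly-centered scores is the origin
  expect_equal(max(abs(pr$coordinates["uniform", ])), 0, tolerance = 1e-10)
})

test_that("origin barycentres separate on dimension 1 for origin-driven panels", {
  sd1 <- simulate_sorting(sorting_profile(30, origin_weight = 0.9,
                                          noise_sd = 0.2), seed = 61)
  res <- distatis_sorting(sd1)
  bc <- origin_barycentres(res, chenin_stimuli())
  gap_dim1 <- abs(diff(bc[, 1]))
  expect_gt(gap_dim1, abs(diff(bc[, 2])))
  expect_gt(gap_dim1, 0.1)
})
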