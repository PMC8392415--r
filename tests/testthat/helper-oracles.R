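# Independent brute-force oracles used across the suite. These deliberately
# recompute every quantity with elementary loops / closed forms rather than
# calling the package's own code paths.

# Pearson chi-square of independence, cell by cell
oracle_chisq_independence <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

# Rand index by explicit pair enumeration
oracle_rand <- function(a, b) {
  n <- length(a)
  agree <- 0L; total <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    total <- total + 1L
    if ((a[i] == a[j]) == (b[i] == b[j])) agree <- agree + 1L
  }
  agree / total
}

# Upper-tail hypergeometric probability by direct combinatorial summation
oracle_hyper_upper <- function(N, K, n, k) {
  jmax <- min(K, n)
  if (k > jmax) return(0)
  js <- k:jmax
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Frequency cut-off by exhaustive scan over all adjacent pairs
oracle_freq_cutoff <- function(freqs) {
  u <- sort(unique(freqs), decreasing = TRUE)
  best_gap <- -Inf; best <- NA
  for (i in seq_len(length(u) - 1)) {
    gap <- u[i] - u[i + 1]
    if (gap > best_gap) { best_gap <- gap; best <- u[i + 1] }
  }
  best
}

# Full DISTATIS recomputed step by step: explicit double-centering formula,
# elementwise RV sums, loop-built compromise. Shares only base eigen() with
# the implementation.
oracle_distatis <- function(d_list) {
  n <- nrow(d_list[[1]])
  S <- lapply(d_list, function(D) {
    rm <- rowMeans(D); gm <- mean(D)
    s <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n)
      s[i, j] <- -0.5 * (D[i, j] - rm[i] - rm[j] + gm)
    s / max(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
  })
  K <- length(S)
  C <- matrix(0, K, K)
  for (a in 1:K) for (b in 1:K) {
    num <- 0; na <- 0; nb <- 0
    for (i in 1:n) for (j in 1:n) {
      num <- num + S[[a]][i, j] * S[[b]][i, j]
      na <- na + S[[a]][i, j]^2
      nb <- nb + S[[b]][i, j]^2
    }
    C[a, b] <- num / sqrt(na * nb)
  }
  u <- eigen(C, symmetric = TRUE)$vectors[, 1]
  if (sum(u) < 0) u <- -u
  alpha <- u / sum(u)
  Splus <- matrix(0, n, n)
  for (k in 1:K) Splus <- Splus + alpha[k] * S[[k]]
  e <- eigen(Splus, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-12
  lam <- e$values[keep]
  V <- e$vectors[, keep, drop = FALSE]
  for (j in seq_along(lam)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  Fm <- V %*% diag(sqrt(lam), length(lam))
  partial <- lapply(S, function(s) s %*% V %*% diag(1 / sqrt(lam), length(lam)))
  list(alpha = alpha, lambda = lam, F = Fm, partial = partial)
}

# Small fixed sorting fixture: 3 participants x 4 stimuli
fixture_partitions <- function() {
  list(P1 = c(A = 1, B = 1, C = 2, D = 2),
       P2 = c(A = 1, B = 1, C = 1, D = 2),
       P3 = c(A = 1, B = 2, C = 3, D = 3))
}

# Random valid partition of n stimuli into k groups (each group nonempty)
random_partition <- function(n, k) {
  g <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
  sample(g)
}

make_sorting_fixture <- function(n_participants = 12, seed = 42,
                                 origin_weight = 0.6, noise_sd = 0.25) {
  simulate_sorting(sorting_profile(n_participants,
                                   origin_weight = origin_weight,
                                   noise_sd = noise_sd),
                   chenin_stimuli(), seed = seed, condition = "fix")
}
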