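#' Encode a sorting partition as a 0/1 distance matrix
#'
#' One participant's free sort is encoded as a stimulus x stimulus matrix
#' with 0 when two stimuli were put in the same group and 1 otherwise
#' (symmetric, zero diagonal).
#'
#' @param partition Named vector mapping stimulus code to group id, covering
#'   every stimulus exactly once.
#' @return Integer n x n matrix with stimulus codes as dimnames.
#' @export
encode_distance <- function(partition) {
  if (is.null(names(partition)) || anyNA(partition) || anyNA(names(partition)))
    stop("partition must be a complete named stimulus -> group map")
  if (anyDuplicated(names(partition)))
    stop("stimulus appears twice in partition")
  g <- as.integer(factor(partition))
  D <- 1L * outer(g, g, `!=`)
  dimnames(D) <- list(names(partition), names(partition))
  D
}

#' Sum per-participant distance matrices
#'
#' @param d_list List of conformable distance matrices.
#' @return Summed matrix (entry = number of participants separating a pair).
#' @export
sum_distances <- function(d_list) {
  stopifnot(length(d_list) >= 1)
  Reduce(`+`, d_list)
}

#' Double-centered, first-eigenvalue-normalized cross-product
#'
#' Transforms a (summed) sorting distance matrix D into the cross-product
#' matrix S = -1/2 * C D C' with centering matrix C = I - 1 m' and uniform
#' masses m = 1/n, then divides by its first eigenvalue so that
#' lambda_1(S) = 1. This is the table-normalization step of DISTATIS, which
#' puts every participant or condition on the same scale before weighting.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @return Normalized cross-product matrix (symmetric, PSD for sorting data).
#' @export
cross_product <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n == ncol(d), isTRUE(all.equal(d, t(d), tolerance = 1e-10)),
            all(abs(diag(d)) < 1e-12))
  C <- diag(n) - matrix(1 / n, n, n)
  S <- -0.5 * C %*% d %*% C
  S <- (S + t(S)) / 2
  dimnames(S) <- dimnames(d)
  l1 <- eigen(S, symmetric = TRUE, only.values = TRUE)$values[1]
  if (l1 <= .Machine$double.eps * n) {
    warning("all-zero distance matrix: normalization skipped")
    return(S)
  }
  S / l1
}

#' RV coefficient between two cross-product matrices
#'
#' Matrix correlation trace(Sa Sb) / sqrt(trace(Sa^2) trace(Sb^2)); the
#' multivariate generalization of a squared Pearson correlation. For PSD
#' inputs it lies in [0, 1], 1 meaning identical configurations up to scale.
#'
#' @param s_a,s_b Conformable symmetric PSD matrices.
#' @return RV coefficient.
#' @export
rv_coefficient <- function(s_a, s_b) {
  s_a <- as.matrix(s_a); s_b <- as.matrix(s_b)
  stopifnot(all(dim(s_a) == dim(s_b)))
  na <- sum(s_a * s_a); nb <- sum(s_b * s_b)
  if (na == 0 || nb == 0) stop("RV undefined for a zero matrix")
  sum(s_a * s_b) / sqrt(na * nb)
}

rv_matrix <- function(s_list) {
  K <- length(s_list)
  C <- diag(1, K)
  for (i in seq_len(K)) for (j in seq_len(K)) if (j > i)
    C[i, j] <- C[j, i] <- rv_coefficient(s_list[[i]], s_list[[j]])
  dimnames(C) <- list(names(s_list), names(s_list))
  C
}

# Orient eigenvectors so each column's largest-magnitude loading is positive
# (reproducible maps across BLAS implementations).
orient_eigenvectors <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' DISTATIS of a set of cross-product tables
#'
#' Three-way MDS of K sorting tables describing the same n stimuli. The K x K
#' RV coefficient matrix measures between-table agreement; its first
#' eigenvector, rescaled to sum to 1, gives the table weights alpha_k; the
#' compromise S+ = sum alpha_k S_k is eigendecomposed into factor scores
#' F = V Lambda^1/2 (stimulus map) and per-table partial scores
#' F_k = S_k V Lambda^-1/2, whose alpha-weighted average is F.
#'
#' @param tables List of >= 2 normalized cross-product matrices (see
#'   [cross_product()]), all n x n.
#' @return A `distatis` object: `rv_matrix`, `alpha`, `compromise`,
#'   `eigenvalues`, `explained_variance`, `factor_scores`,
#'   `partial_scores` (list of per-table score matrices), `eigenvectors`.
#' @export
distatis <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2)
  n <- nrow(tables[[1]])
  if (!all(vapply(tables, function(s) all(dim(s) == n), logical(1))))
    stop("all tables must share the same stimulus dimension")
  C <- rv_matrix(tables)
  ec <- eigen(C, symmetric = TRUE)
  u <- ec$vectors[, 1]
  if (sum(u) < 0) u <- -u
  if (any(u < -1e-8))
    stop("first eigenvector of the RV matrix is not nonnegative")
  u <- pmax(u, 0)
  alpha <- u / sum(u)
  S_plus <- Reduce(`+`, Map(`*`, tables, alpha))
  S_plus <- (S_plus + t(S_plus)) / 2
  es <- eigen(S_plus, symmetric = TRUE)
  keep <- es$values > max(es$values) * 1e-12
  lambda <- es$values[keep]
  V <- orient_eigenvectors(es$vectors[, keep, drop = FALSE])
  F_mat <- V %*% diag(sqrt(lambda), length(lambda))
  proj <- V %*% diag(1 / sqrt(lambda), length(lambda))
  partial <- lapply(tables, function(s) {
    P <- s %*% proj
    dimnames(P) <- dimnames(F_mat)
    P
  })
  dn <- rownames(tables[[1]])
  dimn <- paste0("dim", seq_along(lambda))
  dimnames(F_mat) <- list(dn, dimn)
  partial <- lapply(partial, function(P) {
    dimnames(P) <- list(dn, dimn); P
  })
  structure(list(rv_matrix = C,
                 alpha = stats::setNames(alpha, names(tables)),
                 compromise = S_plus,
                 eigenvalues = lambda,
                 explained_variance = lambda / sum(lambda),
                 factor_scores = F_mat,
                 partial_scores = partial,
                 eigenvectors = V),
            class = "distatis")
}

#' @export
print.distatis <- function(x, ...) {
  cat(sprintf("DISTATIS: %d tables, %d stimuli, %d retained dimensions\n",
              length(x$partial_scores), nrow(x$factor_scores),
              length(x$eigenvalues)))
  cat("explained variance:",
      paste0(round(100 * x$explained_variance[1:min(4, length(x$eigenvalues))], 1),
             "%", collapse = ", "), "\n")
  invisible(x)
}

#' RV map of experimental conditions
#'
#' Compares conditions (e.g. panel x information) through their summed
#' sorting distance matrices: each is converted to a normalized
#' cross-product, the pairwise RV matrix is computed, and its
#' eigendecomposition gives condition coordinates — nearby conditions
#' elicited similar sorts.
#'
#' @param condition_distances Named list of >= 2 summed distance matrices.
#' @param dims Dimensions to return (default 2; needs >= 3 conditions for a
#'   2-D map).
#' @return List: `rv_matrix`, `coordinates` (condition x dims),
#'   `eigenvalues`.
#' @export
rv_map <- function(condition_distances, dims = 2L) {
  if (!is.list(condition_distances) || length(condition_distances) < 2)
    stop("need at least two conditions")
  if (dims >= length(condition_distances))
    dims <- length(condition_distances) - 1L
  s_list <- lapply(condition_distances, cross_product)
  C <- rv_matrix(s_list)
  e <- eigen(C, symmetric = TRUE)
  V <- orient_eigenvectors(e$vectors[, seq_len(dims), drop = FALSE])
  coord <- V %*% diag(sqrt(pmax(e$values[seq_len(dims)], 0)), dims)
  dimnames(coord) <- list(names(condition_distances),
                          paste0("dim", seq_len(dims)))
  list(rv_matrix = C, coordinates = coord, eigenvalues = e$values)
}
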