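#' Construct a free-sorting dataset
#'
#' Container for one experimental condition of a free-sorting task: each
#' participant's partition of the stimuli into groups, the free-text
#' descriptors they attached to each group, and the stimulus metadata.
#'
#' @param sorts Long data.frame: `participant_id`, `stimulus`, `group_id`
#'   (one row per participant x stimulus; every participant must cover all
#'   stimuli exactly once). Optional `country`/`condition` columns.
#' @param descriptors data.frame `participant_id`, `group_id`, `descriptor`
#'   (one row per group descriptor token), or NULL.
#' @param stimuli A [stimulus_set()].
#' @param condition Condition label (e.g. `"FR_info"`).
#' @return A `sorting_data` object.
#' @export
sorting_data <- function(sorts, descriptors = NULL, stimuli, condition = NA) {
  stopifnot(is.data.frame(sorts),
            all(c("participant_id", "stimulus", "group_id") %in% names(sorts)),
            inherits(stimuli, "stimulus_set"))
  sorts$participant_id <- as.character(sorts$participant_id)
  sorts$stimulus <- as.character(sorts$stimulus)
  for (p in unique(sorts$participant_id)) {
    st <- sorts$stimulus[sorts$participant_id == p]
    if (length(st) != nrow(stimuli) || !setequal(st, stimuli$code) ||
        anyDuplicated(st))
      stop("participant ", p, " does not partition the stimulus set")
  }
  if (!is.null(descriptors)) {
    stopifnot(all(c("participant_id", "group_id", "descriptor") %in%
                  names(descriptors)))
    descriptors$participant_id <- as.character(descriptors$participant_id)
    descriptors$descriptor <- normalize_term(descriptors$descriptor)
  }
  structure(list(sorts = sorts, descriptors = descriptors,
                 stimuli = stimuli, condition = condition),
            class = "sorting_data")
}

#' @export
print.sorting_data <- function(x, ...) {
  cat(sprintf("Free-sorting data [%s]: %d participants x %d stimuli\n",
              x$condition, length(unique(x$sorts$participant_id)),
              nrow(x$stimuli)))
  invisible(x)
}

#' Per-participant partitions and distance matrices
#'
#' @param sd A [sorting_data()] object.
#' @return `partitions()`: named list of stimulus -> group vectors;
#'   `distance_matrices()`: named list of 0/1 matrices (see
#'   [encode_distance()]).
#' @export
partitions <- function(sd) {
  stopifnot(inherits(sd, "sorting_data"))
  ids <- unique(sd$sorts$participant_id)
  out <- lapply(ids, function(p) {
    rows <- sd$sorts[sd$sorts$participant_id == p, ]
    stats::setNames(rows$group_id, rows$stimulus)[sd$stimuli$code]
  })
  stats::setNames(out, ids)
}

#' @rdname partitions
#' @export
distance_matrices <- function(sd) {
  lapply(partitions(sd), encode_distance)
}

#' DISTATIS of a sorting dataset
#'
#' Convenience wrapper: encodes every participant's partition as a 0/1
#' distance matrix, normalizes each into a cross-product table and runs
#' [distatis()].
#'
#' @param sd A [sorting_data()] object.
#' @return A `distatis` object.
#' @export
distatis_sorting <- function(sd) {
  distatis(lapply(distance_matrices(sd), cross_product))
}

#' Stimulus x descriptor contingency table
#'
#' Counts, for every descriptor token, how often it was attached to a group
#' containing each stimulus: each (participant, group, descriptor) record
#' contributes one count to every stimulus of that group.
#'
#' @param sd A [sorting_data()] with descriptors.
#' @return Integer matrix, stimuli in rows, descriptor lemmas in columns.
#' @export
build_contingency <- function(sd) {
  stopifnot(inherits(sd, "sorting_data"))
  if (is.null(sd$descriptors) || !nrow(sd$descriptors))
    stop("sorting data carries no descriptors")
  de <- sd$descriptors
  words <- sort(unique(de$descriptor))
  M <- matrix(0L, nrow(sd$stimuli), length(words),
              dimnames = list(sd$stimuli$code, words))
  parts <- partitions(sd)
  for (i in seq_len(nrow(de))) {
    part <- parts[[de$participant_id[i]]]
    members <- names(part)[part == de$group_id[i]]
    M[members, de$descriptor[i]] <- M[members, de$descriptor[i]] + 1L
  }
  M
}

#' Project descriptors into a compromise space
#'
#' Supplementary projection of descriptor words: each descriptor is placed
#' at the barycentre of the stimulus factor scores weighted by its column
#' profile (n_id / n_.d). A descriptor used for a single stimulus lands
#' exactly on that stimulus; a uniformly used one lands at the centroid.
#' Origin labels can be projected the same way as pseudo-descriptors via
#' [origin_barycentres()].
#'
#' @param result A [distatis()] result.
#' @param contingency Stimulus x descriptor count matrix with rows aligned
#'   to the result's stimuli (see [build_contingency()]).
#' @return List: `contingency`, `coordinates` (descriptor x dims).
#' @export
project_descriptors <- function(result, contingency) {
  stopifnot(inherits(result, "distatis"))
  M <- as.matrix(contingency)
  F_mat <- result$factor_scores
  if (nrow(M) != nrow(F_mat))
    stop("contingency rows do not align with the stimuli")
  if (!is.null(rownames(M)) && !is.null(rownames(F_mat)) &&
      !identical(rownames(M), rownames(F_mat)))
    M <- M[rownames(F_mat), , drop = FALSE]
  cs <- colSums(M)
  if (any(cs == 0)) {
    warning("dropping all-zero descriptor columns: ",
            paste(colnames(M)[cs == 0], collapse = ", "))
    M <- M[, cs > 0, drop = FALSE]
    cs <- cs[cs > 0]
  }
  P <- sweep(M, 2, cs, `/`)           # column profiles
  coords <- t(P) %*% F_mat
  list(contingency = M, coordinates = coords)
}

#' Origin barycentres in the compromise space
#'
#' Projects each stimulus-origin label as a pseudo-descriptor attached to
#' all stimuli of that origin, i.e. the unweighted barycentre of the origin's
#' factor scores.
#'
#' @param result A [distatis()] result.
#' @param stimuli A [stimulus_set()] aligned with the result.
#' @return Matrix origin x dims.
#' @export
origin_barycentres <- function(result, stimuli) {
  stopifnot(inherits(result, "distatis"), inherits(stimuli, "stimulus_set"))
  M <- stats::model.matrix(~ 0 + origin, data = stimuli)
  colnames(M) <- sub("^origin", "", colnames(M))
  rownames(M) <- stimuli$code
  project_descriptors(result, M)$coordinates
}

#' Bootstrap confidence regions for stimulus positions
#'
#' Resamples participants with replacement, recomputes the table weights and
#' compromise on each replicate, and projects the replicate compromise onto
#' the reference eigenvectors (F_rep = S_rep V Lambda^-1/2) so all
#' replicates live in the fixed compromise space (no per-replicate
#' eigendecomposition, hence no axis-flipping artifacts). Per stimulus the
#' replicate cloud is summarized by a 95% normal-theory ellipse on the
#' retained dimensions.
#'
#' @param sd A [sorting_data()] with >= 2 participants.
#' @param result Optional precomputed [distatis_sorting()] result for `sd`.
#' @param n_boot Number of bootstrap replicates (default 1000; < 100 warns).
#' @param seed Integer seed.
#' @param dims Dimensions retained for the regions (default 2).
#' @param level Coverage of the ellipse (default 0.95).
#' @return A `bootstrap_regions` object: `replicates` (n_boot x n x dims
#'   array), `regions` data.frame (stimulus, centre, semi-axes, angle,
#'   area), `level`.
#' @export
bootstrap_regions <- function(sd, result = NULL, n_boot = 1000L, seed = 1L,
                              dims = 2L, level = 0.95) {
  stopifnot(inherits(sd, "sorting_data"))
  tables <- lapply(distance_matrices(sd), cross_product)
  K <- length(tables)
  if (K < 2) stop("need at least two participants to bootstrap")
  if (n_boot < 100) warning("fewer than 100 bootstrap replicates")
  if (is.null(result)) result <- distatis(tables)
  dims <- min(dims, length(result$eigenvalues))
  proj <- result$eigenvectors[, seq_len(dims), drop = FALSE] %*%
    diag(1 / sqrt(result$eigenvalues[seq_len(dims)]), dims)
  C_full <- result$rv_matrix
  n <- nrow(result$factor_scores)
  reps <- array(NA_real_, c(n_boot, n, dims),
                dimnames = list(NULL, rownames(result$factor_scores),
                                paste0("dim", seq_len(dims))))
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(K, K, replace = TRUE)
      Cb <- C_full[idx, idx]
      u <- eigen(Cb, symmetric = TRUE)$vectors[, 1]
      if (sum(u) < 0) u <- -u
      u <- pmax(u, 0)
      alpha <- u / sum(u)
      S_rep <- Reduce(`+`, Map(`*`, tables[idx], alpha))
      reps[b, , ] <- S_rep %*% proj
    }
  })
  q <- stats::qchisq(level, df = dims)
  regions <- do.call(rbind, lapply(seq_len(n), function(i) {
    cloud <- reps[, i, , drop = TRUE]
    if (is.null(dim(cloud))) cloud <- matrix(cloud, ncol = dims)
    ctr <- colMeans(cloud)
    S <- stats::cov(cloud)
    ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
    vals <- pmax(ev$values, 0)
    semi <- sqrt(vals * q)
    data.frame(stimulus = rownames(result$factor_scores)[i],
               centre_1 = ctr[1], centre_2 = if (dims > 1) ctr[2] else NA,
               semi_major = semi[1],
               semi_minor = if (dims > 1) semi[2] else NA,
               angle = if (dims > 1)
                 atan2(ev$vectors[2, 1], ev$vectors[1, 1]) else 0,
               area = if (dims > 1) pi * semi[1] * semi[2] else NA,
               stringsAsFactors = FALSE)
  }))
  rownames(regions) <- NULL
  structure(list(replicates = reps, regions = regions, level = level,
                 n_boot = n_boot, dims = dims),
            class = "bootstrap_regions")
}

#' @export
print.bootstrap_regions <- function(x, ...) {
  cat(sprintf("Bootstrap regions: %d replicates, %d%% ellipses on %d dims\n",
              x$n_boot, round(100 * x$level), x$dims))
  print(x$regions, digits = 3, ...)
  invisible(x)
}

#' Read / write sorting datasets as long-format TSV
#'
#' Columns: `participant_id`, `country`, `condition`, `stimulus`,
#' `group_id`, `descriptors` (comma-joined per group; repeated on each of
#' the group's rows). `#` header comment lines are ignored on read.
#'
#' @param path File path.
#' @param stimuli A [stimulus_set()]; reconstructed from the file's stimulus
#'   codes (origin = first letter) when omitted.
#' @return `read_sorting()` returns a [sorting_data()].
#' @export
read_sorting <- function(path, stimuli = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (is.null(stimuli)) {
    codes <- unique(df$stimulus)
    stimuli <- stimulus_set(codes, substr(codes, 1, 1))
  }
  de <- NULL
  if ("descriptors" %in% names(df)) {
    grp <- df[!duplicated(df[, c("participant_id", "group_id")]),
              c("participant_id", "group_id", "descriptors")]
    grp <- grp[!is.na(grp$descriptors) & grp$descriptors != "", , drop = FALSE]
    if (nrow(grp)) {
      toks <- strsplit(grp$descriptors, ",")
      de <- data.frame(
        participant_id = rep(grp$participant_id, lengths(toks)),
        group_id = rep(grp$group_id, lengths(toks)),
        descriptor = trimws(unlist(toks)), stringsAsFactors = FALSE)
    }
  }
  cond <- if ("condition" %in% names(df)) df$condition[1] else NA
  sorting_data(df, de, stimuli, condition = cond)
}

#' @rdname read_sorting
#' @param sd A [sorting_data()].
#' @param header_comment Optional `#` first line (e.g. recording the seed).
#' @export
write_sorting <- function(sd, path, header_comment = NULL) {
  stopifnot(inherits(sd, "sorting_data"))
  df <- sd$sorts
  df$condition <- sd$condition
  if (!is.null(sd$descriptors)) {
    key <- paste(sd$descriptors$participant_id, sd$descriptors$group_id)
    joined <- tapply(sd$descriptors$descriptor, key,
                     paste, collapse = ",")
    df$descriptors <- as.character(
      joined[paste(df$participant_id, df$group_id)])
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
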