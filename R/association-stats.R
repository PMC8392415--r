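#' Global category-by-panel chi-square
#'
#' Pearson chi-square of independence on the full category x panel count
#' table (no continuity correction), testing whether the distribution of
#' evoked words over semantic categories differs between panels.
#'
#' @param counts Numeric matrix or data.frame of counts, categories in rows,
#'   panels in columns (e.g. 8 x 2).
#' @return A `chisq_result` list: `statistic`, `df`, `p_value`, `observed`,
#'   `expected`.
#' @export
global_category_chisq <- function(counts) {
  m <- as.matrix(counts)
  if (!is.numeric(m) || any(m < 0) || anyNA(m))
    stop("counts must be a nonnegative numeric table")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate table: zero row or column marginal")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value),
                 observed = ct$observed,
                 expected = ct$expected),
            class = "chisq_result")
}

#' Per-category two-panel chi-square
#'
#' Goodness-of-fit chi-square of a single category's two panel counts
#' against equal expected counts (a + b) / 2, df = 1, no continuity
#' correction. This is the per-row test form that reproduces published
#' category tables; it does not adjust for unequal panel sizes.
#'
#' @param count_a,count_b Token counts of the category in the two panels.
#' @return A `chisq_result` list.
#' @export
per_category_chisq <- function(count_a, count_b) {
  stopifnot(length(count_a) == 1L, length(count_b) == 1L,
            count_a >= 0, count_b >= 0)
  if (count_a + count_b == 0) stop("degenerate input: both counts are zero")
  ct <- suppressWarnings(
    stats::chisq.test(c(count_a, count_b), p = c(0.5, 0.5), correct = FALSE))
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value),
                 observed = ct$observed,
                 expected = ct$expected),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("chi-square = %.3f, df = %d, p = %.5g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' One-way ANOVA on ratings by panel
#'
#' Standard one-way analysis of variance of per-token importance or valence
#' ratings on a grouping factor (typically panel country), reporting F, the
#' degrees of freedom, the p-value and R-squared (SS_between / SS_total).
#' Groups with no rating variance at all yield F = 0 by convention.
#'
#' @param values Numeric ratings.
#' @param groups Grouping labels, same length as `values`.
#' @return An `anova_result` list: `F`, `df_between`, `df_within`,
#'   `p_value`, `r_squared`.
#' @export
category_anova <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), !anyNA(values))
  if (nlevels(droplevels(groups)) < 2)
    stop("need at least two groups")
  if (length(values) - nlevels(droplevels(groups)) < 1)
    stop("need at least one group with two or more values")
  if (stats::var(values) == 0) {
    g <- droplevels(groups)
    return(structure(list(F = 0, df_between = nlevels(g) - 1L,
                          df_within = length(values) - nlevels(g),
                          p_value = 1, r_squared = 0),
                     class = "anova_result"))
  }
  fit <- stats::lm(values ~ groups)
  av <- stats::anova(fit)
  structure(list(F = av[1, "F value"],
                 df_between = av[1, "Df"],
                 df_within = av[2, "Df"],
                 p_value = av[1, "Pr(>F)"],
                 r_squared = summary(fit)$r.squared),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("F(%d,%d) = %.3f, p = %.5g, R2 = %.3f\n",
              x$df_between, x$df_within, x$F, x$p_value, x$r_squared))
  invisible(x)
}

#' Category table with per-row chi-squares
#'
#' Convenience wrapper producing the published layout: for a two-panel
#' [category_table()], appends the per-category equal-expected chi-square
#' and its p-value to every row.
#'
#' @param tab A two-group `category_table` (or any data.frame whose first
#'   two `count_*` columns hold the panel counts).
#' @return The table with `chi_square` and `p_value` columns appended.
#' @export
category_chisq_table <- function(tab) {
  cc <- grep("^count_", names(tab), value = TRUE)
  if (length(cc) != 2)
    stop("expected exactly two count_* columns")
  res <- mapply(function(a, b) {
    r <- per_category_chisq(a, b)
    c(r$statistic, r$p_value)
  }, tab[[cc[1]]], tab[[cc[2]]])
  tab$chi_square <- res[1, ]
  tab$p_value <- res[2, ]
  tab
}
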