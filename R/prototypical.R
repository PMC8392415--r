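#' Frequency cut-off for prototypical analysis
#'
#' Sorts the distinct citation frequencies in decreasing order and locates
#' the adjacent pair with the largest drop; the cut-off is the lower
#' frequency of that pair, so words strictly above it are "high frequency".
#' When several drops tie, the pair occurring at higher frequency wins.
#'
#' @param stats A [word_stats()] data.frame (or anything with a `frequency`
#'   column), or a bare numeric vector of frequencies.
#' @return Integer cut-off frequency.
#' @export
frequency_cutoff <- function(stats) {
  freq <- if (is.data.frame(stats)) stats$frequency else stats
  u <- sort(unique(as.numeric(freq)), decreasing = TRUE)
  if (length(u) < 2)
    stop("all citation frequencies are equal; choose a cut-off manually")
  gaps <- u[-length(u)] - u[-1]
  i <- which.max(gaps)   # which.max takes the first maximum = highest pair
  u[i + 1]
}

#' Importance cut-off for prototypical analysis
#'
#' Unweighted mean of the per-word mean importance ratings over the retained
#' words. On anchored 1-7 scales this typically lands near the scale
#' midpoint-plus (both published corpora used 5).
#'
#' @param stats A [word_stats()] data.frame or numeric vector of per-word
#'   mean importances.
#' @return Numeric cut-off.
#' @export
importance_cutoff <- function(stats) {
  imp <- if (is.data.frame(stats)) stats$mean_importance else stats
  if (!length(imp)) stop("no retained words")
  mean(imp)
}

#' Classify words into the four representational zones
#'
#' Cross-tabulates retained words by frequency and importance relative to
#' the two cut-offs (strict `>` defines "high" on both axes):
#' central core (high/high), first periphery (high frequency, low
#' importance), contrast zone (low frequency, high importance), third
#' periphery (low/low). Words cited by `min_frequency` or fewer participants
#' are dropped before classification.
#'
#' @param stats A [word_stats()] data.frame.
#' @param frequency_cutoff,importance_cutoff The two cut-offs; by default
#'   recomputed from the retained words via [frequency_cutoff()] and
#'   [importance_cutoff()].
#' @param min_frequency Words with frequency <= this are dropped (default 2,
#'   i.e. only words cited more than twice are kept).
#' @return A `prototypical_table`: data.frame `lemma`, `frequency`,
#'   `mean_importance`, `zone`, with the cut-offs as attributes.
#' @export
classify_zones <- function(stats, frequency_cutoff = NULL,
                           importance_cutoff = NULL, min_frequency = 2L) {
  stopifnot(is.data.frame(stats),
            all(c("lemma", "frequency", "mean_importance") %in% names(stats)))
  kept <- stats[stats$frequency > min_frequency, , drop = FALSE]
  if (!nrow(kept)) stop("no words above the minimum frequency")
  f_cut <- if (is.null(frequency_cutoff)) sensorep::frequency_cutoff(kept)
           else frequency_cutoff
  i_cut <- if (is.null(importance_cutoff)) sensorep::importance_cutoff(kept)
           else importance_cutoff
  stopifnot(is.finite(f_cut), is.finite(i_cut))
  hi_f <- kept$frequency > f_cut
  hi_i <- kept$mean_importance > i_cut
  zone <- ifelse(hi_f & hi_i, "central_core",
          ifelse(hi_f & !hi_i, "first_periphery",
          ifelse(!hi_f & hi_i, "contrast_zone", "third_periphery")))
  out <- data.frame(lemma = kept$lemma, frequency = kept$frequency,
                    mean_importance = kept$mean_importance, zone = zone,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, -out$mean_importance, out$lemma), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "frequency_cutoff") <- f_cut
  attr(out, "importance_cutoff") <- i_cut
  attr(out, "min_frequency") <- min_frequency
  class(out) <- c("prototypical_table", "data.frame")
  out
}

#' Render a prototypical table as a 2 x 2 layout
#'
#' Markdown rendering of the central core and the three peripheries in the
#' conventional frequency x importance quadrant layout.
#'
#' @param x A `prototypical_table`.
#' @return Character vector of markdown lines (invisibly printed by
#'   `print.prototypical_table`).
#' @export
format_prototypical <- function(x) {
  stopifnot(inherits(x, "prototypical_table"))
  f_cut <- attr(x, "frequency_cutoff")
  i_cut <- attr(x, "importance_cutoff")
  cell <- function(zone) {
    w <- x$lemma[x$zone == zone]
    if (!length(w)) "-" else paste(w, collapse = ", ")
  }
  c(sprintf("High importance > %.3g; high frequency > %.3g", i_cut, f_cut),
    "",
    "|  | High importance | Low importance |",
    "|---|---|---|",
    sprintf("| High frequency | %s | %s |",
            cell("central_core"), cell("first_periphery")),
    sprintf("| Low frequency | %s | %s |",
            cell("contrast_zone"), cell("third_periphery")))
}

#' @export
print.prototypical_table <- function(x, ...) {
  writeLines(format_prototypical(x))
  invisible(x)
}
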