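#' Plot a DISTATIS compromise map
#'
#' Stimulus map on two compromise dimensions, optionally colored by origin,
#' with bootstrap confidence ellipses and supplementary descriptor or
#' barycentre coordinates overlaid.
#'
#' @param result A [distatis()] result.
#' @param stimuli Optional [stimulus_set()] for origin coloring.
#' @param regions Optional [bootstrap_regions()] result.
#' @param supplementary Optional coordinate matrix (e.g. from
#'   [project_descriptors()] or [origin_barycentres()]).
#' @param dims Two dimensions to display (default 1:2).
#' @return A ggplot object.
#' @export
plot_compromise <- function(result, stimuli = NULL, regions = NULL,
                            supplementary = NULL, dims = c(1L, 2L)) {
  stopifnot(inherits(result, "distatis"),
            max(dims) <= ncol(result$factor_scores))
  F_mat <- result$factor_scores[, dims, drop = FALSE]
  df <- data.frame(code = rownames(F_mat), x = F_mat[, 1], y = F_mat[, 2],
                   stringsAsFactors = FALSE)
  df$origin <- if (!is.null(stimuli))
    stimuli$origin[match(df$code, stimuli$code)] else "stimulus"
  ev <- round(100 * result$explained_variance[dims], 1)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$origin), size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$code,
                                    colour = .data$origin),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = sprintf("Dimension %d (%.1f%%)", dims[1], ev[1]),
                  y = sprintf("Dimension %d (%.1f%%)", dims[2], ev[2]),
                  colour = "origin") +
    ggplot2::theme_minimal()
  if (!is.null(regions)) {
    ell <- do.call(rbind, lapply(seq_len(nrow(regions$regions)), function(i) {
      r <- regions$regions[i, ]
      t <- seq(0, 2 * pi, length.out = 73)
      xy <- cbind(r$semi_major * cos(t), r$semi_minor * sin(t)) %*%
        rbind(c(cos(r$angle), sin(r$angle)), c(-sin(r$angle), cos(r$angle)))
      data.frame(code = r$stimulus, x = r$centre_1 + xy[, 1],
                 y = r$centre_2 + xy[, 2])
    }))
    p <- p + ggplot2::geom_path(
      data = ell, ggplot2::aes(group = .data$code),
      colour = "grey50", linewidth = 0.3)
  }
  if (!is.null(supplementary)) {
    sup <- data.frame(label = rownames(supplementary),
                      x = supplementary[, dims[1]],
                      y = supplementary[, dims[2]])
    p <- p + ggplot2::geom_text(data = sup,
      ggplot2::aes(label = .data$label), colour = "grey30",
      fontface = "italic", size = 2.8)
  }
  p
}

#' Plot an RV map of conditions
#'
#' @param map Result of [rv_map()].
#' @return A ggplot object.
#' @export
plot_rv_map <- function(map) {
  df <- data.frame(condition = rownames(map$coordinates),
                   x = map$coordinates[, 1], y = map$coordinates[, 2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$condition),
                       vjust = -0.9, size = 3.2) +
    ggplot2::labs(x = "Dimension 1", y = "Dimension 2") +
    ggplot2::theme_minimal()
}
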