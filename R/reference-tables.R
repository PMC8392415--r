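#' Published cross-cultural Chenin blanc category table
#'
#' Category frequencies (token counts) and mean valences from the published
#' cross-cultural Chenin blanc word-association study: 107 South African and
#' 99 French consumers each evoked four words, giving 535 and 500 tokens
#' respectively. Bundled so the category chi-square statistics can be
#' recomputed from the printed counts.
#'
#' @return data.frame with columns `category`, `count_sa`, `count_fr`,
#'   `valence_sa`, `valence_fr`.
#' @seealso [global_category_chisq()], [per_category_chisq()]
#' @export
chenin_table3 <- function() {
  data.frame(
    category = wa_categories(),
    count_sa = c(316L, 66L, 63L, 33L, 20L, 17L, 12L, 8L),
    count_fr = c(104L, 146L, 72L, 9L, 76L, 43L, 29L, 21L),
    valence_sa = c(5.39, 6.05, 6.15, 5.74, 6.00, 6.12, 5.33, 5.63),
    valence_fr = c(5.24, 6.08, 6.78, 5.88, 5.76, 5.56, 4.10, 5.19),
    stringsAsFactors = FALSE
  )
}

#' Construct a stimulus set
#'
#' A stimulus set describes the products sorted by the panel: unique codes,
#' a binary origin label per product, and latent 2-D coordinates (origin
#' axis, style axis) that drive the sorting simulator.
#'
#' @param codes Character vector of unique stimulus labels.
#' @param origin Factor/character of per-stimulus origin labels (two levels).
#' @param latent_coords Numeric matrix (n x 2): column 1 the origin axis,
#'   column 2 a within-origin style axis. Defaults place the first origin
#'   level at -1 and the second at +1 on axis 1 and spread styles evenly in
#'   [-1, 1] within each origin on axis 2.
#' @return A `stimulus_set` (data.frame `code`, `origin`, `axis_origin`,
#'   `axis_style`).
#' @export
stimulus_set <- function(codes, origin, latent_coords = NULL) {
  codes <- as.character(codes)
  if (anyDuplicated(codes)) stop("stimulus codes must be unique")
  origin <- as.character(origin)
  stopifnot(length(origin) == length(codes))
  if (is.null(latent_coords)) {
    lev <- sort(unique(origin))
    ax1 <- ifelse(origin == lev[1], -1, 1)
    ax2 <- numeric(length(codes))
    for (l in lev) {
      k <- sum(origin == l)
      ax2[origin == l] <- if (k == 1) 0 else seq(-1, 1, length.out = k)
    }
    latent_coords <- cbind(ax1, ax2)
  }
  latent_coords <- as.matrix(latent_coords)
  stopifnot(ncol(latent_coords) == 2, nrow(latent_coords) == length(codes),
            all(is.finite(latent_coords)))
  out <- data.frame(code = codes, origin = origin,
                    axis_origin = latent_coords[, 1],
                    axis_style = latent_coords[, 2],
                    stringsAsFactors = FALSE)
  class(out) <- c("stimulus_set", "data.frame")
  out
}

#' The 14 Chenin blanc study wines
#'
#' Stimulus set of the published experiment: seven Loire (FR) and seven
#' South African (SA) dry Chenin blanc wines, identified by their serving
#' codes. Latent coordinates follow the [stimulus_set()] defaults (origin
#' axis FR = -1, SA = +1; styles spread within origin).
#'
#' @return A `stimulus_set` with 14 rows.
#' @export
chenin_stimuli <- function() {
  codes <- c("FBAU", "FCLP", "FCLL", "FHUE", "FCAR", "FROC", "FROU",
             "SFED", "SRAA", "SREY", "SBEA", "SRAD", "SRUD", "SKLE")
  origin <- rep(c("FR", "SA"), each = 7L)
  stimulus_set(codes, origin)
}
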