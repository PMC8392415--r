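#' Default pipeline configuration
#'
#' Returns the configuration of the bundled demonstration pipeline: two
#' word-association panels (the SA- and FR-like profiles) and four sorting
#' conditions (country x information). The information conditions differ
#' only for the FR-like panel, whose origin salience rises when origins are
#' disclosed, while the SA-like panel sorts on style in both conditions —
#' the cross-cultural contrast the analysis is designed to detect.
#'
#' @param seed Integer master seed.
#' @param n_sorters Participants per sorting condition.
#' @param alpha Significance level for the specificity analysis.
#' @param n_boot Bootstrap replicates.
#' @param dims Retained compromise dimensions.
#' @return A named list understood by [run_pipeline()].
#' @export
default_config <- function(seed = 1L, n_sorters = 50L, alpha = 0.05,
                           n_boot = 500L, dims = 2L) {
  list(
    seed = as.integer(seed), alpha = alpha, n_boot = as.integer(n_boot),
    dims = as.integer(dims), min_frequency = 2L,
    association_panels = list(SA = sa_panel_profile(),
                              FR = fr_panel_profile()),
    sorting_conditions = list(
      SA_noinfo = list(profile = sorting_profile(n_sorters,
                         origin_weight = 0.25), origin_term_prob = 0),
      SA_info = list(profile = sorting_profile(n_sorters,
                       origin_weight = 0.25), origin_term_prob = 0.1),
      FR_noinfo = list(profile = sorting_profile(n_sorters,
                         origin_weight = 0.25), origin_term_prob = 0),
      FR_info = list(profile = sorting_profile(n_sorters,
                       origin_weight = 0.85), origin_term_prob = 0.6)),
    stimuli = chenin_stimuli()
  )
}

#' Run the full representation-analysis pipeline
#'
#' Simulates (or accepts) word-association and sorting panels, then runs
#' every analysis stage: corpus summaries and category tables with
#' chi-squares and ANOVAs, prototypical zone classification per panel, the
#' condition RV map, per-condition DISTATIS with bootstrap regions and
#' descriptor/origin projections, and the condition specificity analysis.
#' All tables are written as TSV/JSON under `out_dir` together with a
#' Markdown report and a checksum manifest; identical configurations
#' produce identical outputs.
#'
#' @param config A configuration list (see [default_config()]) or the path
#'   to a YAML file with scalar overrides (`seed`, `alpha`, `n_boot`,
#'   `dims`, `n_sorters`).
#' @param out_dir Output directory (created if needed), or NULL to skip all
#'   file output.
#' @return Invisibly, a list with every intermediate and final result.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) {
    ov <- yaml::read_yaml(config)
    config <- do.call(default_config, ov[intersect(names(ov),
      c("seed", "n_sorters", "alpha", "n_boot", "dims"))])
  }
  stopifnot(is.list(config), !is.null(config$seed))
  lx <- default_lexicon()
  seed <- config$seed

  # --- word association -----------------------------------------------------
  corpora <- Map(function(prof, i)
    lemmatize(simulate_associations(prof, lx, seed = seed + i), lx),
    config$association_panels,
    seq_along(config$association_panels))
  corpus_all <- association_corpus(do.call(rbind, lapply(corpora,
                                                         as.data.frame)))
  class(corpus_all) <- c("association_corpus", "data.frame")
  summaries <- lapply(corpora, corpus_summary)
  cat_tab <- category_chisq_table(category_table(corpus_all))
  cc <- grep("^count_", names(cat_tab), value = TRUE)
  global_chi <- global_category_chisq(as.matrix(cat_tab[, cc]))
  anovas <- list(
    importance = category_anova(corpus_all$importance, corpus_all$country),
    valence = category_anova(corpus_all$valence, corpus_all$country))
  prototypes <- lapply(corpora, function(cp)
    classify_zones(word_stats(cp), min_frequency = config$min_frequency))

  # --- sorting --------------------------------------------------------------
  sortings <- Map(function(spec, i, nm)
    simulate_sorting(spec$profile, config$stimuli, seed = seed + 100L + i,
                     condition = nm,
                     origin_term_prob = spec$origin_term_prob),
    config$sorting_conditions, seq_along(config$sorting_conditions),
    names(config$sorting_conditions))
  condition_sums <- lapply(sortings, function(sd)
    sum_distances(distance_matrices(sd)))
  map <- rv_map(condition_sums)
  per_condition <- lapply(names(sortings), function(nm) {
    sd <- sortings[[nm]]
    res <- distatis_sorting(sd)
    boot <- bootstrap_regions(sd, res, n_boot = config$n_boot,
                              seed = seed + 200L, dims = config$dims)
    proj <- project_descriptors(res, build_contingency(sd))
    list(distatis = res, bootstrap = boot, projection = proj,
         origin_barycentres = origin_barycentres(res, config$stimuli))
  })
  names(per_condition) <- names(sortings)

  # --- specificity over sorting descriptors ---------------------------------
  desc_words <- do.call(rbind, lapply(names(sortings), function(nm) {
    de <- sortings[[nm]]$descriptors
    data.frame(condition = nm, word = de$descriptor,
               stringsAsFactors = FALSE)
  }))
  specific <- condition_specificities(desc_words, alpha = config$alpha)

  results <- list(config = config, corpora = corpora, summaries = summaries,
                  category_table = cat_tab, global_chisq = global_chi,
                  anovas = anovas, prototypes = prototypes,
                  sortings = sortings, rv_map = map,
                  per_condition = per_condition, specificity = specific)
  if (!is.null(out_dir)) write_report_bundle(results, out_dir)
  invisible(results)
}

write_report_bundle <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- results$config$seed
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  files <- character(0)
  files <- c(files, tsv(results$category_table, "category_table.tsv"))
  for (nm in names(results$corpora))
    files <- c(files, {
      p <- file.path(out_dir, paste0("associations_", nm, ".tsv"))
      write_associations(results$corpora[[nm]], p,
                         header_comment = paste("seed", seed))
      p
    })
  for (nm in names(results$prototypes))
    files <- c(files, tsv(as.data.frame(results$prototypes[[nm]]),
                          paste0("prototypical_", nm, ".tsv")))
  for (nm in names(results$sortings))
    files <- c(files, {
      p <- file.path(out_dir, paste0("sorting_", nm, ".tsv"))
      write_sorting(results$sortings[[nm]], p,
                    header_comment = paste("seed", seed))
      p
    })
  rvm <- results$rv_map$rv_matrix
  files <- c(files, tsv(data.frame(condition = rownames(rvm),
                                   round(rvm, 4)), "rv_matrix.tsv"))
  for (nm in names(results$per_condition)) {
    pc <- results$per_condition[[nm]]
    files <- c(files,
      tsv(data.frame(stimulus = rownames(pc$distatis$factor_scores),
                     round(pc$distatis$factor_scores, 5)),
          paste0("factor_scores_", nm, ".tsv")))
    ell <- file.path(out_dir, paste0("ellipses_", nm, ".json"))
    jsonlite::write_json(pc$bootstrap$regions, ell, digits = 8,
                         dataframe = "rows")
    files <- c(files, ell)
  }
  files <- c(files, tsv(results$specificity, "specificity.tsv"))
  report <- file.path(out_dir, "report.md")
  writeLines(render_report(results), report)
  files <- c(files, report)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(list(seed = seed, files = manifest),
                       file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(out_dir)
}

render_report <- function(results) {
  t <- results$category_table
  lines <- c("# Consumer representation analysis report", "",
             sprintf("Seed: %d", results$config$seed), "",
             "## Word association", "",
             sprintf("Global category chi-square: %.3f (df = %d, p = %.3g)",
                     results$global_chisq$statistic, results$global_chisq$df,
                     results$global_chisq$p_value), "")
  for (nm in names(results$summaries)) {
    s <- results$summaries[[nm]]
    lines <- c(lines, sprintf(
      "- %s: %d tokens, %d distinct lemmas, diversity %.2f, rarity %.2f",
      nm, s$total_tokens, s$distinct_lemmas, s$diversity_index,
      s$rarity_index))
  }
  lines <- c(lines, "", "| category | " ,
             paste0("| ", paste(names(t), collapse = " | "), " |"),
             paste0("|", paste(rep("---", ncol(t)), collapse = "|"), "|"))
  lines <- lines[lines != "| category | "]
  for (i in seq_len(nrow(t)))
    lines <- c(lines, paste0("| ", paste(
      vapply(t[i, ], function(v)
        if (is.numeric(v)) formatC(v, digits = 4, format = "fg") else
          as.character(v), character(1)), collapse = " | "), " |"))
  lines <- c(lines, "", "## Prototypical structure", "")
  for (nm in names(results$prototypes))
    lines <- c(lines, paste0("### ", nm), "",
               format_prototypical(results$prototypes[[nm]]), "")
  lines <- c(lines, "## Sorting (DISTATIS)", "",
             "RV matrix of conditions:", "```",
             utils::capture.output(print(round(results$rv_map$rv_matrix, 3))),
             "```", "", "## Condition-specific descriptors", "", "```",
             utils::capture.output(print(results$specificity,
                                         row.names = FALSE)),
             "```")
  lines
}
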