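#' @title End-to-end analysis pipeline
#' @description
#' Ties the stages together: load or simulate a cohort, classify each
#' episode against the reference standard, score the five candidate tests,
#' apply the bedside decision tool, evaluate diagnostic accuracy, grow the
#' CHAID tree, and compare observed with theoretical antibiotic LOT. All
#' artifacts are written as CSV/JSON plus a run manifest, and the whole
#' bundle is a deterministic function of the configuration and seed.
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Exactly one of `input` (path to an episode CSV) and `synthetic` (a
#' [cohort_config()]) must be given.
#'
#' @param input path to an episode CSV, or `NULL`.
#' @param synthetic a [cohort_config()], or `NULL`.
#' @param output_dir directory the bundle is written to.
#' @param seed integer seed for every stochastic stage.
#' @param crp_cutoff CRP cutoff in mg/L (default 10).
#' @param neohop_threshold NeoHoP positivity threshold (default 2).
#' @param chaid a [chaid_config()].
#' @param quartiles quartile convention for summaries.
#' @param mw_mode Mann-Whitney mode for the LOT comparison.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            output_dir = "results", seed = 1L,
                            crp_cutoff = 10, neohop_threshold = 2,
                            chaid = chaid_config(),
                            quartiles = c("tukey", "linear"),
                            mw_mode = c("normal_approx", "exact")) {
  if (is.null(input) == is.null(synthetic))
    stop("exactly one of 'input' and 'synthetic' must be set", call. = FALSE)
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "cohort_config"))
  structure(list(input = input, synthetic = synthetic,
                 output_dir = output_dir, seed = as.integer(seed),
                 crp_cutoff = crp_cutoff,
                 neohop_threshold = as.integer(neohop_threshold),
                 chaid = chaid, quartiles = match.arg(quartiles),
                 mw_mode = match.arg(mw_mode)),
            class = "pipeline_config")
}

# NeoHoP score banded for the tree: 0 / 1 / >= 2
.score_band <- function(total) {
  ifelse(is.na(total), NA_character_,
         ifelse(total >= 2, "2+", as.character(total)))
}

#' Run the full analysis pipeline
#'
#' Writes into `output_dir`: `episodes_augmented.csv` (episode-level data
#' with classification, score, recommendation and theoretical LOT),
#' `metrics_table.csv` / `.json` (accuracy of the five candidate tests on
#' the cohort), `chaid_tree.txt` / `.json`, `lot_comparison.csv` and
#' `manifest.json` (seed, options, exclusion counts, branch counts).
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the in-memory versions of every
#'   artifact: `episodes`, `metrics`, `tree`, `lot`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  episodes <- if (!is.null(config$input)) {
    read_episodes(config$input)
  } else {
    cc <- config$synthetic
    cc$seed <- NULL  # the pipeline seed governs
    generate_cohort(cc)
  }

  val <- validate_episodes(episodes)
  if (!isTRUE(attr(val, "ok")))
    stop("input failed validation: ", nrow(val), " violation(s); first: ",
         val$message[1], " (episode ", val$episode_id[1], ")", call. = FALSE)

  cl <- classify_hai(episodes, crp_cutoff = config$crp_cutoff)
  episodes <- cbind(episodes, cl)
  episodes <- apply_decision_tool(episodes, config$crp_cutoff,
                                  config$neohop_threshold)

  # diagnostic accuracy of the five candidate tests on classified episodes
  classified <- !is.na(episodes$any_hai)
  specs <- all_test_specs(config$crp_cutoff, config$neohop_threshold)
  calls <- test_positivity_all(episodes[classified, , drop = FALSE], specs)
  cms <- lapply(calls, confusion_matrix, truth = episodes$any_hai[classified])
  counts <- data.frame(
    test = names(cms),
    tp = vapply(cms, `[[`, 0, "tp"), tn = vapply(cms, `[[`, 0, "tn"),
    fp = vapply(cms, `[[`, 0, "fp"), fn = vapply(cms, `[[`, 0, "fn"),
    stringsAsFactors = FALSE)
  metrics <- metrics_table(counts)

  # CHAID tree over the banded score and the t24 CRP call
  sc <- compute_neohop(episodes, config$crp_cutoff, config$neohop_threshold)
  feats <- data.frame(
    neohop_band = .score_band(sc$total),
    crp_t24_pos = crp_positive(episodes$crp_t24, config$crp_cutoff),
    stringsAsFactors = FALSE)
  tree_rows <- classified & !is.na(feats$neohop_band)
  tree <- grow_tree(feats[tree_rows, , drop = FALSE],
                    episodes$any_hai[tree_rows], config$chaid)

  lot <- lot_comparison(episodes, quartiles = config$quartiles,
                        mw_mode = config$mw_mode)

  manifest <- list(
    seed = config$seed,
    n_episodes = nrow(episodes),
    source = if (is.null(config$input)) "synthetic" else config$input,
    crp_cutoff = config$crp_cutoff,
    neohop_threshold = config$neohop_threshold,
    quartiles = config$quartiles,
    mw_mode = config$mw_mode,
    n_unclassifiable = sum(!classified),
    n_tool_not_evaluable = attr(episodes, "n_not_evaluable"),
    n_excluded_per_test = lapply(cms, `[[`, "n_excluded"),
    tool_branch_counts = tool_branch_counts(episodes),
    r_version = as.character(getRversion())
  )

  out <- file.path(config$output_dir, c(
    "episodes_augmented.csv", "metrics_table.csv", "metrics_table.json",
    "chaid_tree.txt", "chaid_tree.json", "lot_comparison.csv",
    "manifest.json"))
  write_episodes(episodes, out[1])
  utils::write.csv(metrics, out[2], row.names = FALSE)
  writeLines(jsonlite::toJSON(metrics, dataframe = "rows",
                              auto_unbox = TRUE, pretty = TRUE, digits = NA),
             out[3])
  writeLines(format_chaid(tree), out[4])
  writeLines(jsonlite::toJSON(chaid_to_list(tree), auto_unbox = TRUE,
                              pretty = TRUE, digits = NA), out[5])
  utils::write.csv(lot, out[6], row.names = FALSE)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), out[7])

  invisible(list(episodes = episodes, metrics = metrics, tree = tree,
                 lot = lot, manifest = manifest))
}
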