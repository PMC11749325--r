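#' @title Bedside antibiotic decision tool and theoretical length of therapy
#' @description
#' The tool applies the NeoHoP score at presentation, then a point-of-care
#' CRP 24 h later: a score of 0 means no antibiotics and no further
#' investigations; a score of 1 means start antibiotics and let the t24 CRP
#' decide between cessation after 24 h and continuation; a score of >= 2
#' prompts a full course per institutional guidelines. The theoretical
#' antibiotic length of therapy (LOT) under the tool is 0 days for
#' no-antibiotics, 1 day for early cessation, and the observed LOT when the
#' tool would have continued or given a full course.
#' @name decision_tool
NULL

.recommendations <- c("no_antibiotics", "start_then_stop_24h",
                      "start_then_continue", "full_course")

#' Tool recommendation from the NeoHoP total and the t24 CRP
#'
#' @param neohop_total integer vector of NeoHoP totals (0-5); `NA` = score
#'   not evaluable.
#' @param crp_t24 CRP at t24 in mg/L; `NA` = not measured.
#' @param cutoff CRP cutoff, default 10 mg/L.
#' @return character vector over the recommendations
#'   `"no_antibiotics"`, `"start_then_stop_24h"`, `"start_then_continue"`,
#'   `"full_course"`; `NA` where the tool is not evaluable (score 1 with no
#'   t24 CRP, or score unknown).
#' @export
recommend_tool <- function(neohop_total, crp_t24, cutoff = 10) {
  stopifnot(length(neohop_total) == length(crp_t24), cutoff > 0)
  out <- rep(NA_character_, length(neohop_total))
  known <- !is.na(neohop_total)
  out[known & neohop_total == 0] <- "no_antibiotics"
  out[known & neohop_total >= 2] <- "full_course"
  one <- known & neohop_total == 1
  out[one & !is.na(crp_t24) & crp_t24 < cutoff] <- "start_then_stop_24h"
  out[one & !is.na(crp_t24) & crp_t24 >= cutoff] <- "start_then_continue"
  out
}

#' Theoretical antibiotic LOT implied by a recommendation
#'
#' @param recommendation character vector over the tool recommendations
#'   (`NA` allowed: not evaluable).
#' @param observed_lot_days observed LOT in days, inherited by the
#'   continue / full-course branches.
#' @return numeric vector of theoretical LOT in days (`NA` where the tool
#'   was not evaluable).
#' @export
theoretical_lot <- function(recommendation, observed_lot_days) {
  stopifnot(length(recommendation) == length(observed_lot_days))
  bad <- !is.na(recommendation) & !recommendation %in% .recommendations
  if (any(bad))
    stop("unknown recommendation(s): ",
         paste(unique(recommendation[bad]), collapse = ", "), call. = FALSE)
  if (any(!is.na(observed_lot_days) & observed_lot_days < 0))
    stop("observed_lot_days must be >= 0", call. = FALSE)
  ifelse(is.na(recommendation), NA_real_,
    ifelse(recommendation == "no_antibiotics", 0,
      ifelse(recommendation == "start_then_stop_24h", 1,
             observed_lot_days)))
}

#' Apply the decision tool to a cohort
#'
#' Computes the NeoHoP score, the tool recommendation and the theoretical
#' LOT for every episode. Episodes where the tool is not evaluable (score 1
#' with a missing t24 CRP) are counted and carried with `NA` outcomes; no
#' imputation is performed.
#'
#' @param episodes episode `data.frame`.
#' @param crp_cutoff CRP cutoff in mg/L, default 10.
#' @param neohop_threshold NeoHoP positivity threshold, default 2 (used for
#'   the score's `positive` flag only; the tool branches on the raw total).
#' @return the episode `data.frame` with appended columns `neohop_total`,
#'   `recommendation`, `theoretical_lot_days`. Attribute
#'   `n_not_evaluable` counts episodes without a tool outcome.
#' @export
apply_decision_tool <- function(episodes, crp_cutoff = 10,
                                neohop_threshold = 2) {
  sc <- compute_neohop(episodes, crp_cutoff, neohop_threshold)
  rec <- recommend_tool(sc$total, episodes$crp_t24, crp_cutoff)
  out <- episodes
  out$neohop_total <- sc$total
  out$recommendation <- rec
  out$theoretical_lot_days <- theoretical_lot(rec, episodes$observed_lot_days)
  attr(out, "n_not_evaluable") <- sum(is.na(rec))
  out
}

#' Branch counts of the decision tool over a cohort
#'
#' @param episodes result of [apply_decision_tool()].
#' @return named list with one count per recommendation plus
#'   `not_evaluable`.
#' @export
tool_branch_counts <- function(episodes) {
  stopifnot("recommendation" %in% names(episodes))
  counts <- as.list(table(factor(episodes$recommendation,
                                 levels = .recommendations)))
  counts <- lapply(counts, as.integer)
  counts$not_evaluable <- sum(is.na(episodes$recommendation))
  counts
}
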