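#' @title NeoHoP score and CRP test positivity
#' @description
#' The NeoHoP score is a five-item bedside infection-prediction score for
#' neonates investigated for suspected healthcare-associated infection:
#' capillary refill time > 3 s, lethargy, abdominal distention, central
#' venous catheter in situ or within the preceding 48 h, and CRP >= 10 mg/L,
#' one point each, positive at a total of >= 2. Five candidate tests are
#' evaluated against the any-HAI reference standard: CRP at t0, the NeoHoP
#' score at t0, CRP at t24, "CRP at t0 or t24" combined, and the stepwise
#' "NeoHoP at t0 then CRP at t24" rule used by the bedside decision tool.
#' @name scoring
NULL

.test_names <- c("crp_t0", "neohop_t0", "crp_t24",
                 "crp_t0_and_t24_combined", "neohop_t0_and_crp_t24_combined")

#' Specification of a candidate diagnostic test
#'
#' @param name one of `"crp_t0"`, `"neohop_t0"`, `"crp_t24"`,
#'   `"crp_t0_and_t24_combined"`, `"neohop_t0_and_crp_t24_combined"`.
#' @param crp_cutoff CRP positivity cutoff in mg/L; comparisons are
#'   inclusive (>= cutoff). Default 10.
#' @param neohop_threshold score positivity threshold (inclusive), in 1..5.
#'   Default 2.
#' @return an object of class `test_spec`.
#' @export
test_spec <- function(name, crp_cutoff = 10, neohop_threshold = 2) {
  name <- match.arg(name, .test_names)
  stopifnot(is.numeric(crp_cutoff), length(crp_cutoff) == 1L, crp_cutoff > 0,
            neohop_threshold %in% 1:5)
  structure(list(name = name, crp_cutoff = crp_cutoff,
                 neohop_threshold = as.integer(neohop_threshold)),
            class = "test_spec")
}

#' All five candidate test specifications
#'
#' @inheritParams test_spec
#' @return named list of [test_spec()] objects.
#' @export
all_test_specs <- function(crp_cutoff = 10, neohop_threshold = 2) {
  specs <- lapply(.test_names, test_spec, crp_cutoff = crp_cutoff,
                  neohop_threshold = neohop_threshold)
  names(specs) <- .test_names
  specs
}

#' CRP thresholding
#'
#' Inclusive comparison against the cutoff; a missing measurement is
#' `"not_evaluable"`, never silently negative.
#'
#' @param value CRP concentration(s) in mg/L; `NA` = not measured.
#' @param cutoff positivity cutoff in mg/L (default 10).
#' @return character vector over `"positive"`, `"negative"`,
#'   `"not_evaluable"`.
#' @export
crp_positive <- function(value, cutoff = 10) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  if (any(!is.na(value) & value < 0))
    stop("CRP concentrations must be >= 0", call. = FALSE)
  ifelse(is.na(value), "not_evaluable",
         ifelse(value >= cutoff, "positive", "negative"))
}

#' Compute the NeoHoP score
#'
#' The CRP component uses the t0 point-of-care measurement, scored at
#' presentation together with the clinical items. Episodes with no t0 CRP
#' cannot be scored: their total and positivity are `NA`.
#'
#' @param episodes episode `data.frame` (see [episodes]).
#' @param crp_cutoff CRP component cutoff in mg/L (default 10).
#' @param threshold positivity threshold on the total (default 2).
#' @return `data.frame` with the five component flags, `total` (0-5) and
#'   `positive`.
#' @export
compute_neohop <- function(episodes, crp_cutoff = 10, threshold = 2) {
  stopifnot(is.data.frame(episodes), threshold %in% 1:5)
  crp_comp <- crp_positive(episodes$crp_t0, crp_cutoff) == "positive"
  crp_comp[is.na(episodes$crp_t0)] <- NA
  comp <- data.frame(
    crt_gt_3s = episodes$crt_gt_3s,
    lethargy = episodes$lethargy,
    abdominal_distention = episodes$abdominal_distention,
    cvc_in_situ_or_48h = episodes$cvc_in_situ_or_48h,
    crp_ge_cutoff = crp_comp
  )
  total <- rowSums(comp)  # NA whenever any component is unknown
  data.frame(comp, total = as.integer(total),
             positive = total >= threshold)
}

#' Positivity of one candidate test for every episode
#'
#' Rules: `crp_t0` / `crp_t24` threshold the respective measurement;
#' `neohop_t0` is the score at its threshold; `crp_t0_and_t24_combined` is
#' positive when either time point is >= cutoff, negative when all available
#' measurements are below it with t0 present, and not evaluable when a
#' negative t0 is not backed by a t24 measurement; the stepwise
#' `neohop_t0_and_crp_t24_combined` rule is positive at score >= 2,
#' negative at score 0, and defers score-1 episodes to the t24 CRP.
#'
#' @param episodes episode `data.frame`.
#' @param spec a [test_spec()].
#' @return character vector over `"positive"`, `"negative"`,
#'   `"not_evaluable"`.
#' @export
test_positivity <- function(episodes, spec) {
  stopifnot(inherits(spec, "test_spec"))
  cutoff <- spec$crp_cutoff
  switch(spec$name,
    crp_t0 = crp_positive(episodes$crp_t0, cutoff),
    crp_t24 = crp_positive(episodes$crp_t24, cutoff),
    neohop_t0 = {
      sc <- compute_neohop(episodes, cutoff, spec$neohop_threshold)
      ifelse(is.na(sc$positive), "not_evaluable",
             ifelse(sc$positive, "positive", "negative"))
    },
    crp_t0_and_t24_combined = {
      p0 <- crp_positive(episodes$crp_t0, cutoff)
      p24 <- crp_positive(episodes$crp_t24, cutoff)
      ifelse(p0 == "positive" | p24 == "positive", "positive",
             ifelse(p0 == "negative" & p24 == "negative", "negative",
                    "not_evaluable"))
    },
    neohop_t0_and_crp_t24_combined = {
      sc <- compute_neohop(episodes, cutoff, spec$neohop_threshold)
      p24 <- crp_positive(episodes$crp_t24, cutoff)
      out <- rep("not_evaluable", nrow(episodes))
      known <- !is.na(sc$total)
      out[known & sc$total >= 2] <- "positive"
      out[known & sc$total == 0] <- "negative"
      one <- known & sc$total == 1
      out[one] <- p24[one]  # positive / negative / not_evaluable at t24
      out
    },
    stop("unknown test name: ", spec$name, call. = FALSE)
  )
}

#' Positivity of all candidate tests
#'
#' @param episodes episode `data.frame`.
#' @param specs list of [test_spec()] objects, default [all_test_specs()].
#' @return `data.frame` of tri-state calls, one column per test.
#' @export
test_positivity_all <- function(episodes, specs = all_test_specs()) {
  out <- lapply(specs, function(s) test_positivity(episodes, s))
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Clamp CRP values to the point-of-care device measuring range
#'
#' The bedside assay reports 1.0-200 mg/L; values outside the range are
#' stored at the range limit with a censoring flag.
#'
#' @param value CRP concentration(s) in mg/L.
#' @param lower,upper device measuring range (default 1-200 mg/L).
#' @return `data.frame` with `value` (clamped), `censored_low`,
#'   `censored_high`.
#' @export
clamp_poc_crp <- function(value, lower = 1, upper = 200) {
  lo <- !is.na(value) & value < lower
  hi <- !is.na(value) & value > upper
  data.frame(value = pmin(pmax(value, lower), upper),
             censored_low = lo, censored_high = hi)
}
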