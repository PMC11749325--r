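test_that("CoNS adjudication follows the paired-culture and CRP criteria", {
  paired <- list(organism_class = "cons", n_positive_cultures = 2,
                 paired_cultures_24_48h_apart = TRUE)
  single <- list(organism_class = "cons", n_positive_cultures = 1,
                 paired_cultures_24_48h_apart = FALSE)
  expect_equal(classify_cons(paired, crp = 3, clinical_signs = FALSE),
               "infection")
  expect_equal(classify_cons(single, crp = 15, clinical_signs = TRUE),
               "infection")
  expect_equal(classify_cons(single, crp = 6, clinical_signs = TRUE),
               "contamination")
  expect_equal(classify_cons(single, crp = 15, clinical_signs = FALSE),
               "contamination")
  expect_error(classify_cons(list(organism_class = "pathogen",
                                  n_positive_cultures = 1,
                                  paired_cultures_24_48h_apart = FALSE),
                             crp = 15, clinical_signs = TRUE),
               "CoNS")
})

test_that("episodes classify into proven / presumed / none per the definitions", {
  proven <- make_episode(organism_class = "pathogen",
                         n_positive_cultures = 1,
                         collected_after_72h_admission = TRUE,
                         clinical_signs_present = TRUE, lab_crp = 40,
                         symptoms_short_lived = FALSE,
                         abx_stopped_within_72h = FALSE,
                         observed_lot_days = 10,
                         antibiotics_continued_ge_5d = TRUE)
  presumed <- make_episode(lab_crp = 22, observed_lot_days = 7,
                           antibiotics_continued_ge_5d = TRUE,
                           symptoms_short_lived = FALSE,
                           abx_stopped_within_72h = FALSE)
  none <- make_episode(lab_crp = 4, observed_lot_days = 2,
                       symptoms_short_lived = TRUE,
                       abx_stopped_within_72h = TRUE)
  out <- classify_hai(make_episodes(proven, presumed, none))
  expect_equal(out$hai_label, c("proven", "presumed", "none"))
  expect_equal(out$any_hai, c(TRUE, TRUE, FALSE))
  expect_true(all(nzchar(out$rationale)))
})

test_that("CoNS infection counts as proven; contaminants behave as negative", {
  cons_inf <- make_episode(organism_class = "cons", n_positive_cultures = 2,
                           paired_cultures_24_48h_apart = TRUE,
                           clinical_signs_present = TRUE)
  contam <- make_episode(organism_class = "contaminant_other",
                         n_positive_cultures = 1, lab_crp = 22,
                         observed_lot_days = 7,
                         antibiotics_continued_ge_5d = TRUE,
                         symptoms_short_lived = FALSE,
                         abx_stopped_within_72h = FALSE)
  cons_contam <- make_episode(organism_class = "cons",
                              n_positive_cultures = 1, lab_crp = 4,
                              symptoms_short_lived = TRUE,
                              abx_stopped_within_72h = TRUE)
  out <- classify_hai(make_episodes(cons_inf, contam, cons_contam))
  expect_equal(out$hai_label, c("proven", "presumed", "none"))
})

test_that("episodes matching no definition are surfaced, never defaulted", {
  # CRP below cutoff but antibiotics continued and symptoms not short-lived
  odd <- make_episode(lab_crp = 4, observed_lot_days = 7,
                      antibiotics_continued_ge_5d = FALSE,
                      symptoms_short_lived = FALSE,
                      abx_stopped_within_72h = FALSE)
  expect_warning(out <- classify_hai(odd), "unclassifiable")
  expect_equal(out$hai_label, "unclassifiable")
  expect_true(is.na(out$any_hai))
  expect_match(out$rationale, "no definition matched")
})

test_that("the definition CRP falls back to the t0 point-of-care value", {
  ep <- make_episode(crp_t0 = 22, lab_crp = NA, observed_lot_days = 7,
                     antibiotics_continued_ge_5d = TRUE,
                     symptoms_short_lived = FALSE,
                     abx_stopped_within_72h = FALSE)
  expect_equal(classify_hai(ep)$hai_label, "presumed")
  suppressWarnings(
    expect_equal(classify_hai(ep, lab_crp = 4)$hai_label, "unclassifiable"))
})

test_that("classification is deterministic and labels partition", {
  coh <- generate_cohort(cohort_config(n_episodes = 400, seed = 5))
  a <- classify_hai(coh)
  b <- classify_hai(coh)
  expect_identical(a, b)
  expect_true(all(a$hai_label %in% c("proven", "presumed", "none")))
  expect_equal(a$any_hai, a$hai_label %in% c("proven", "presumed"))
})
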