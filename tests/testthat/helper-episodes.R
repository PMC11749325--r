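# Build a well-formed episode record with overridable fields.
make_episode <- function(...) {
  base <- list(
    episode_id = "E0001", subject_id = "S0001", postnatal_age_days = 14,
    crt_gt_3s = FALSE, lethargy = FALSE, abdominal_distention = FALSE,
    cvc_in_situ_or_48h = FALSE, crp_t0 = 4, crp_t24 = 5,
    organism_class = "negative", n_positive_cultures = 0,
    paired_cultures_24_48h_apart = FALSE,
    collected_after_72h_admission = TRUE, clinical_signs_present = FALSE,
    observed_lot_days = 3, antibiotics_continued_ge_5d = FALSE,
    symptoms_short_lived = TRUE, abx_stopped_within_72h = TRUE,
    lab_crp = NA_real_
  )
  over <- list(...)
  base[names(over)] <- over
  as.data.frame(base, stringsAsFactors = FALSE)
}

make_episodes <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# Independent two-sided exact Mann-Whitney p by complete enumeration of all
# choose(n, n_a) group assignments (test oracle; the package uses a dynamic
# program instead).
enumerate_mw_p <- function(a, b) {
  pool <- c(a, b)
  r <- rank(pool)
  n_a <- length(a)
  idx <- utils::combn(length(pool), n_a)
  us <- apply(idx, 2, function(s) sum(r[s]) - n_a * (n_a + 1) / 2)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}
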