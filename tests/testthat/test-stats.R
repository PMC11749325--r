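test_that("median and Tukey-hinge quartiles match hand evaluation", {
  s <- median_iqr(c(1, 2, 3, 4, 5))
  expect_equal(c(s$q1, s$median, s$q3), c(2, 3, 4))
  expect_equal(s$n, 5)

  const <- median_iqr(c(7, 7, 7))
  expect_equal(c(const$q1, const$median, const$q3), c(7, 7, 7))
  expect_equal(const$sd, 0)

  single <- median_iqr(9)
  expect_equal(c(single$q1, single$median, single$q3), c(9, 9, 9))

  lin <- median_iqr(c(1, 2, 3, 4, 5, 6, 7, 8), quartiles = "linear")
  expect_equal(c(lin$q1, lin$q3),
               unname(quantile(1:8, c(0.25, 0.75), type = 7)))

  expect_error(median_iqr(numeric(0)), "empty")
  expect_error(median_iqr(NA_real_), "empty")
})

test_that("exact Mann-Whitney p-values match full enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(r$u, 0)
  expect_equal(r$p_value, 0.1)  # 2/20 arrangements as extreme

  tied <- mann_whitney_u(rep(2, 4), rep(2, 6), mode = "exact")
  expect_equal(tied$u, 4 * 6 / 2)
  expect_equal(tied$p_value, 1)

  set.seed(11)
  for (i in 1:8) {
    a <- sample(1:6, sample(3:6, 1), replace = TRUE)
    b <- sample(1:6, sample(3:6, 1), replace = TRUE)
    got <- mann_whitney_u(a, b, mode = "exact")
    expect_equal(got$p_value, enumerate_mw_p(a, b), info = paste("case", i))
  }

  expect_error(mann_whitney_u(1:40, 1:40, mode = "exact"), "normal_approx")
})

test_that("normal approximation converges to the exact p as n grows", {
  gap <- function(a, b) {
    abs(mann_whitney_u(a, b, mode = "exact")$p_value -
          mann_whitney_u(a, b, mode = "normal_approx")$p_value)
  }
  set.seed(5)
  gap8 <- replicate(20, gap(rnorm(8), rnorm(8, 0.5)))
  gap15 <- replicate(20, gap(rnorm(15), rnorm(15, 0.5)))
  expect_lt(max(gap8), 0.02)
  expect_lt(max(gap15), 0.01)   # agreement tightens with n
  expect_lt(mean(gap15), mean(gap8))
})

test_that("the approximate p agrees with the standard R implementation", {
  set.seed(8)
  a <- rpois(30, 4); b <- rpois(35, 5)
  got <- mann_whitney_u(a, b)
  ref <- suppressWarnings(wilcox.test(a, b, correct = TRUE, exact = FALSE))
  expect_equal(got$u, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("a tool that always continues leaves LOT unchanged with p = 1", {
  eps <- make_episodes(
    make_episode(episode_id = "A", observed_lot_days = 5),
    make_episode(episode_id = "B", observed_lot_days = 8),
    make_episode(episode_id = "C", observed_lot_days = 3)
  )
  eps$hai_label <- c("proven", "presumed", "none")
  eps$theoretical_lot_days <- eps$observed_lot_days  # full course everywhere
  tab <- lot_comparison(eps)
  expect_equal(tab$observed_median, tab$theoretical_median)
  expect_true(all(tab$p_value[tab$n > 0] == 1))
})

test_that("a hand-built six-episode cohort summarises cell by cell", {
  eps <- do.call(rbind, lapply(1:6, function(i) make_episode(
    episode_id = paste0("E", i))))
  eps$hai_label <- c("none", "none", "none", "presumed", "presumed", "proven")
  eps$observed_lot_days <- c(2, 3, 3, 7, 9, 12)
  eps$theoretical_lot_days <- c(0, 0, 1, 7, 9, 12)
  tab <- lot_comparison(eps)

  ov <- tab[tab$group == "overall", ]
  expect_equal(ov$n, 6)
  expect_equal(ov$observed_median, median(eps$observed_lot_days))
  expect_equal(ov$theoretical_median, median(eps$theoretical_lot_days))

  nh <- tab[tab$group == "no_hai", ]
  expect_equal(nh$n, 3)
  expect_equal(nh$observed_median, 3)
  expect_equal(nh$theoretical_median, 0)
  expect_equal(nh$observed_q1, 2.5)  # Tukey hinge of (2, 3, 3)

  ah <- tab[tab$group == "any_hai", ]
  expect_equal(ah$observed_median, ah$theoretical_median)
  expect_equal(ah$p_value, 1)

  expect_equal(sum(tab$n[tab$group %in% c("no_hai", "any_hai")]), 6)
  expect_equal(sum(tab$n[tab$group %in% c("proven", "presumed")]),
               ah$n)
})

test_that("empty strata are reported with n = 0 and undefined summaries", {
  eps <- make_episode()
  eps$hai_label <- "none"
  eps$theoretical_lot_days <- 0
  tab <- lot_comparison(eps)
  pr <- tab[tab$group == "proven", ]
  expect_equal(pr$n, 0)
  expect_true(is.na(pr$observed_median))
})

test_that("group sizes sum to cohort n minus exclusions", {
  coh <- generate_cohort(cohort_config(n_episodes = 400, seed = 17))
  aug <- apply_decision_tool(coh)
  aug$hai_label <- classify_hai(coh)$hai_label
  tab <- lot_comparison(aug)
  n_excl <- tab$n_excluded[tab$group == "overall"]
  expect_equal(tab$n[tab$group == "overall"], nrow(coh) - n_excl)
  expect_equal(tab$n[tab$group == "no_hai"] + tab$n[tab$group == "any_hai"],
               tab$n[tab$group == "overall"])
})

test_that("the paired signed-rank alternative is available behind the flag", {
  eps <- do.call(rbind, lapply(1:8, function(i) make_episode(
    episode_id = paste0("E", i))))
  eps$hai_label <- rep("none", 8)
  eps$observed_lot_days <- c(2, 3, 3, 2.5, 3, 2, 3, 3)
  eps$theoretical_lot_days <- c(0, 0, 1, 0, 3, 0, 1, 0)
  mw <- lot_comparison(eps)
  sr <- lot_comparison(eps, test = "wilcoxon_signed_rank")
  expect_true(is.finite(sr$p_value[1]))
  expect_false(identical(mw$p_value[1], sr$p_value[1]))
})
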