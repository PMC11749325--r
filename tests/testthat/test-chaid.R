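test_that("chi-square matches the hand-summed (O-E)^2/E formula", {
  # perfect 2x2 association with 20 per class: statistic equals n
  perfect <- matrix(c(20, 0, 0, 20), 2)
  res <- chi_square_independence(perfect)
  expect_equal(res$statistic, 40)

  # identical rows: no association
  flat <- matrix(c(10, 10, 5, 5), 2, byrow = TRUE)
  res0 <- chi_square_independence(flat)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  # 2x3 toy table against direct summation
  tab <- matrix(c(8, 2, 5, 5, 1, 9), nrow = 2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat_hand <- sum((tab - expected)^2 / expected)
  res2 <- chi_square_independence(tab)
  expect_equal(res2$statistic, stat_hand)
  expect_equal(res2$df, 2)
  expect_equal(res2$p_value, pchisq(stat_hand, 2, lower.tail = FALSE))

  # zero margins are collapsed before testing
  padded <- rbind(cbind(tab, 0), 0)
  expect_equal(chi_square_independence(padded)$statistic, stat_hand)

  # likelihood-ratio variant equals 2 * sum(O * log(O/E))
  g2 <- 2 * sum(tab * log(tab / expected))
  expect_equal(chi_square_independence(tab, "likelihood_ratio")$statistic, g2)
})

test_that("Stirling partition numbers are correct for small cases", {
  expect_equal(stirling2(3, 2), 3)
  expect_equal(stirling2(4, 2), 7)
  expect_equal(stirling2(5, 3), 25)
  expect_equal(stirling2(4, 4), 1)
})

test_that("best_grouping keeps binary predictors whole and merges equal-rate categories", {
  cfg <- chaid_config(min_child_size = 1)
  x <- rep(c("a", "b"), each = 30)
  y <- c(rep(TRUE, 25), rep(FALSE, 5), rep(TRUE, 5), rep(FALSE, 25))
  bg <- best_grouping(x, y, cfg)
  expect_length(bg$groups, 2)
  expect_equal(bg$multiplier, 1)

  # three categories, two with identical outcome rates -> merged;
  # oracle: brute force over all three 2-group partitions plus the identity
  x3 <- rep(c("a", "b", "c"), each = 40)
  y3 <- c(rep(c(TRUE, FALSE), c(8, 32)),   # a: 20%
          rep(c(TRUE, FALSE), c(8, 32)),   # b: 20%
          rep(c(TRUE, FALSE), c(36, 4)))   # c: 90%
  bg3 <- best_grouping(x3, y3, cfg)
  partitions <- list(list(c("a", "b"), "c"), list(c("a", "c"), "b"),
                     list(c("b", "c"), "a"), list("a", "b", "c"))
  adj <- vapply(partitions, function(gr) {
    g <- vapply(x3, function(v) which(vapply(gr, function(s) v %in% s, TRUE)), 1L)
    p <- chi_square_independence(table(g, y3))$p_value
    min(1, p * stirling2(3, length(gr)))
  }, 0)
  best <- partitions[[which.min(adj)]]
  expect_equal(bg3$groups[order(lengths(bg3$groups))],
               best[order(lengths(best))])
  expect_true(any(vapply(bg3$groups, function(g) setequal(g, c("a", "b")), TRUE)))
  expect_equal(bg3$adjusted_p, min(adj))

  # single category: no grouping possible
  expect_null(best_grouping(rep("a", 10), rep(TRUE, 10), cfg))
})

test_that("no grouping is significant when the outcome is independent", {
  set.seed(123)
  x <- sample(c("a", "b", "c"), 300, TRUE)
  y <- runif(300) < 0.5
  bg <- best_grouping(x, y, chaid_config(min_child_size = 1))
  expect_gt(bg$adjusted_p, 0.05)
})

test_that("trees split on separating predictors and stay rooted otherwise", {
  x <- data.frame(flag = rep(c("yes", "no"), each = 25),
                  noise = sample(c("u", "v"), 50, TRUE))
  y <- rep(c(TRUE, FALSE), each = 25)
  tr <- grow_tree(x, y, chaid_config(min_parent_size = 10, min_child_size = 5))
  expect_equal(tr$split_predictor, "flag")
  expect_length(tr$children, 2)
  purity <- vapply(tr$children, function(ch) max(ch$class_counts) / ch$n, 0)
  expect_equal(purity, c(1, 1))

  const <- grow_tree(x, rep(TRUE, 50), chaid_config())
  expect_null(const$split_predictor)
  expect_error(grow_tree(x[0, , drop = FALSE], logical(0)), "empty")
})

test_that("class counts conserve from parent to children at every node", {
  coh <- generate_cohort(cohort_config(n_episodes = 800, seed = 13))
  sc <- compute_neohop(coh)
  feats <- data.frame(
    neohop_band = ifelse(sc$total >= 2, "2+", as.character(sc$total)),
    crp_t24_pos = crp_positive(coh$crp_t24),
    stringsAsFactors = FALSE)
  tr <- grow_tree(feats, coh$hai_class_sampled != "none", chaid_config())
  check <- function(node) {
    if (!length(node$children)) return(invisible())
    kids <- Reduce(`+`, lapply(node$children, `[[`, "class_counts"))
    expect_equal(as.numeric(kids), as.numeric(node$class_counts))
    for (ch in node$children) check(ch)
  }
  check(tr)
})

test_that("on two binary predictors the root split matches exhaustive search", {
  set.seed(31)
  for (rep_i in 1:5) {
    n <- 120
    a <- sample(c("l", "r"), n, TRUE)
    b <- sample(c("l", "r"), n, TRUE)
    y <- runif(n) < ifelse(a == "l", 0.75, 0.3) * ifelse(b == "l", 1, 0.7)
    dat <- data.frame(a = a, b = b)
    tr <- grow_tree(dat, y, chaid_config(min_parent_size = 10,
                                         min_child_size = 5))
    # oracle: binary predictors need no merging, so the root split is just
    # the predictor with the smaller chi-square p (ties by statistic, name)
    p_a <- chi_square_independence(table(a, y))
    p_b <- chi_square_independence(table(b, y))
    best <- if (p_a$p_value < p_b$p_value ||
                (p_a$p_value == p_b$p_value &&
                 p_a$statistic >= p_b$statistic)) "a" else "b"
    if (min(p_a$p_value, p_b$p_value) <= 0.05) {
      expect_equal(tr$split_predictor, best)
    } else {
      expect_null(tr$split_predictor)
    }
  }
})

test_that("permuted outcomes rarely produce spurious splits", {
  set.seed(99)
  n_splits <- 0
  for (i in 1:100) {
    x <- data.frame(p1 = sample(c("a", "b"), 80, TRUE),
                    p2 = sample(c("a", "b", "c"), 80, TRUE))
    y <- sample(rep(c(TRUE, FALSE), 40))
    tr <- grow_tree(x, y, chaid_config(min_parent_size = 20,
                                       min_child_size = 7))
    if (!is.null(tr$split_predictor)) n_splits <- n_splits + 1
  }
  # two predictors at alpha 0.05 with Bonferroni-adjusted groupings:
  # familywise spurious-split rate should stay near alpha
  expect_lt(n_splits / 100, 0.15)
})

test_that("records route deterministically to leaves", {
  x <- data.frame(a = rep(c("l", "r"), each = 30),
                  b = rep(c("u", "v"), 30))
  y <- c(rep(TRUE, 30), rep(c(TRUE, FALSE), c(6, 24)))
  tr <- grow_tree(x, y, chaid_config(min_parent_size = 10, min_child_size = 5,
                                     alpha_split = 0.2))
  combos <- expand.grid(a = c("l", "r"), b = c("u", "v"),
                        stringsAsFactors = FALSE)
  pred <- predict_node(tr, combos)
  # hand lookup: each combo must land on a leaf whose observed class
  # proportion equals the empirical rate of y in that cell's leaf subset
  expect_equal(nrow(pred), 4)
  expect_true(all(pred$prop_TRUE >= 0 & pred$prop_TRUE <= 1))
  expect_equal(pred$prop_TRUE + pred$prop_FALSE, rep(1, 4))

  root_only <- grow_tree(x, y, chaid_config(alpha_split = 1e-12))
  pr <- predict_node(root_only, combos[1, , drop = FALSE])
  expect_equal(pr$prop_TRUE, mean(y))

  pure <- grow_tree(data.frame(f = rep(c("p", "q"), each = 20)),
                    rep(c(TRUE, FALSE), each = 20),
                    chaid_config(min_parent_size = 10, min_child_size = 5))
  pp <- predict_node(pure, data.frame(f = "p"))
  expect_equal(pp$prop_TRUE, 1)

  expect_error(predict_node(pure, data.frame(f = "z")), "not covered")
})

test_that("tree export round-trips through text and JSON", {
  x <- data.frame(f = rep(c("p", "q"), each = 20))
  y <- rep(c(TRUE, FALSE), each = 20)
  tr <- grow_tree(x, y, chaid_config(min_parent_size = 10, min_child_size = 5))
  txt <- format_chaid(tr)
  expect_true(any(grepl("split=f", txt)))
  lst <- chaid_to_list(tr)
  expect_equal(lst$split_predictor, "f")
  expect_length(lst$children, 2)
  js <- jsonlite::fromJSON(jsonlite::toJSON(lst, auto_unbox = TRUE),
                           simplifyVector = FALSE)
  expect_equal(js$n, 40)
})
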