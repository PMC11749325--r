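#' @title Distribution summaries and group comparisons for the LOT analysis
#' @description
#' Antibiotic length-of-therapy (LOT) distributions are skewed, so they are
#' summarised as median and interquartile range and compared with the
#' Mann-Whitney U test. The exact null distribution of U is computed by a
#' dynamic program over the pooled midranks (so ties are handled exactly);
#' the large-sample mode uses the normal approximation with tie-corrected
#' variance and continuity correction.
#' @name lot_stats
NULL

#' Median and interquartile range
#'
#' Quartiles follow the Tukey hinge convention by default (the hinges of
#' [stats::fivenum()]); linear interpolation (type-7 quantiles) is
#' available. At the integer-valued sample sizes summarised here the two
#' conventions rarely differ.
#'
#' @param values non-empty numeric vector (missing values dropped).
#' @param quartiles `"tukey"` or `"linear"`.
#' @return list with `n`, `median`, `q1`, `q3`, `mean`, `sd`.
#' @export
median_iqr <- function(values, quartiles = c("tukey", "linear")) {
  quartiles <- match.arg(quartiles)
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty input", call. = FALSE)
  if (quartiles == "tukey") {
    fn <- stats::fivenum(values)
    q1 <- fn[2]; med <- fn[3]; q3 <- fn[4]
  } else {
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    q1 <- q[1]; med <- q[2]; q3 <- q[3]
  }
  list(n = length(values), median = med, q1 = q1, q3 = q3,
       mean = mean(values), sd = stats::sd(values))
}

# Exact null distribution of the rank sum of sample a via dynamic
# programming over doubled midranks (doubling keeps tied midranks integer).
# Returns P(R_a = s) on the doubled scale as a named numeric vector.
.ranksum_distribution <- function(doubled_ranks, n_a) {
  total <- sum(doubled_ranks)
  # f[k+1, s+1] = number of size-k subsets with doubled rank sum s
  f <- matrix(0, nrow = n_a + 1, ncol = total + 1)
  f[1, 1] <- 1
  for (w in doubled_ranks) {
    for (k in n_a:1) {
      # shift row k-1 by w into row k
      src <- f[k, 1:(total + 1 - w)]
      f[k + 1, (w + 1):(total + 1)] <- f[k + 1, (w + 1):(total + 1)] + src
    }
  }
  counts <- f[n_a + 1, ]
  counts / sum(counts)
}

#' Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties. In `"exact"` mode
#' the two-sided p-value comes from the exact permutation distribution of U
#' over all ways to assign the pooled observations to the two groups
#' (computed by dynamic programming, valid under ties); in
#' `"normal_approx"` mode from the normal approximation with tie-corrected
#' variance and continuity correction. The two-sided exact p is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param a,b non-empty numeric vectors.
#' @param mode `"exact"` or `"normal_approx"`.
#' @param max_exact_n largest combined sample size accepted in exact mode
#'   (default 60).
#' @return list with `u` (U statistic of sample `a`), `p_value`, `mode`.
#' @export
mann_whitney_u <- function(a, b, mode = c("normal_approx", "exact"),
                           max_exact_n = 60) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n_a <- length(a); n_b <- length(b)
  if (n_a == 0 || n_b == 0) stop("both samples must be non-empty", call. = FALSE)
  n <- n_a + n_b
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2

  if (mode == "exact") {
    if (n > max_exact_n)
      stop(sprintf("combined n = %d exceeds the exact-mode bound (%d); use mode = 'normal_approx'",
                   n, max_exact_n), call. = FALSE)
    dist <- .ranksum_distribution(as.integer(round(2 * r)), n_a)
    # doubled rank sum s corresponds to U = s/2 - n_a(n_a+1)/2
    s_obs <- round(2 * sum(r[seq_len(n_a)]))
    s_vals <- seq_along(dist) - 1
    p_le <- sum(dist[s_vals <= s_obs + 1e-9])
    p_ge <- sum(dist[s_vals >= s_obs - 1e-9])
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n_a * n_b / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(u = u, p_value = p, mode = mode)
}

.lot_groups <- function(hai_label) {
  list(overall = rep(TRUE, length(hai_label)),
       no_hai = hai_label == "none",
       any_hai = hai_label %in% c("proven", "presumed"),
       proven = hai_label == "proven",
       presumed = hai_label == "presumed")
}

#' Observed vs theoretical LOT comparison table
#'
#' For the whole cohort and each reference-standard stratum (no HAI, any
#' HAI, proven, presumed): median and IQR of the observed and the
#' theoretical antibiotic LOT, and a two-sided test of the difference.
#' Episodes without a tool outcome (score 1 with missing t24 CRP, or an
#' unclassifiable reference label for the strata) are excluded pairwise and
#' counted.
#'
#' @param episodes `data.frame` carrying `hai_label`, `observed_lot_days`,
#'   `theoretical_lot_days` (e.g. the output of [apply_decision_tool()]
#'   joined with [classify_hai()]).
#' @param test `"mann_whitney"` (the default, comparing the two LOT vectors
#'   as groups) or `"wilcoxon_signed_rank"` (paired alternative).
#' @param quartiles quartile convention, see [median_iqr()].
#' @param mw_mode Mann-Whitney mode, see [mann_whitney_u()].
#' @return `data.frame`, one row per group: `group`, `n`, `n_excluded`,
#'   `observed_median`, `observed_q1`, `observed_q3`, `theoretical_median`,
#'   `theoretical_q1`, `theoretical_q3`, `p_value`.
#' @export
lot_comparison <- function(episodes,
                           test = c("mann_whitney", "wilcoxon_signed_rank"),
                           quartiles = c("tukey", "linear"),
                           mw_mode = c("normal_approx", "exact")) {
  test <- match.arg(test)
  quartiles <- match.arg(quartiles)
  mw_mode <- match.arg(mw_mode)
  stopifnot(all(c("hai_label", "observed_lot_days", "theoretical_lot_days")
                %in% names(episodes)))
  groups <- .lot_groups(episodes$hai_label)
  rows <- lapply(names(groups), function(g) {
    sel <- groups[[g]] & !is.na(episodes$hai_label)
    evaluable <- sel & !is.na(episodes$theoretical_lot_days) &
      !is.na(episodes$observed_lot_days)
    obs <- episodes$observed_lot_days[evaluable]
    theo <- episodes$theoretical_lot_days[evaluable]
    if (!length(obs)) {
      return(data.frame(group = g, n = 0L, n_excluded = sum(sel) - 0L,
                        observed_median = NA_real_, observed_q1 = NA_real_,
                        observed_q3 = NA_real_, theoretical_median = NA_real_,
                        theoretical_q1 = NA_real_, theoretical_q3 = NA_real_,
                        p_value = NA_real_))
    }
    so <- median_iqr(obs, quartiles)
    st <- median_iqr(theo, quartiles)
    p <- if (all(obs == theo)) 1 else if (test == "mann_whitney") {
      mann_whitney_u(obs, theo, mode = mw_mode)$p_value
    } else {
      suppressWarnings(stats::wilcox.test(obs, theo, paired = TRUE)$p.value)
    }
    data.frame(group = g, n = length(obs),
               n_excluded = sum(sel) - length(obs),
               observed_median = so$median, observed_q1 = so$q1,
               observed_q3 = so$q3, theoretical_median = st$median,
               theoretical_q1 = st$q1, theoretical_q3 = st$q3,
               p_value = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
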