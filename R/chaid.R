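#' @title Exhaustive CHAID decision trees over categorical predictors
#' @description
#' Chi-squared Automatic Interaction Detection (CHAID) grows a decision
#' tree by, at each node, merging predictor categories that do not differ
#' in outcome distribution and splitting on the predictor whose best
#' category grouping is most significant after a Bonferroni adjustment for
#' the number of ways the original categories can be grouped. The
#' exhaustive variant scans the full merge sequence — from all categories
#' separate down to two groups — and keeps the grouping with the smallest
#' adjusted p-value, rather than stopping at the first non-significant
#' merge. Used here to derive the two-variable tree (NeoHoP score band,
#' then t24 CRP) that underlies the bedside decision tool.
#' @name chaid
NULL

#' CHAID configuration
#'
#' @param alpha_split significance level a predictor's adjusted p must
#'   reach for a node to split (default 0.05, the analysis-wide alpha).
#' @param alpha_merge significance level for category merging; retained for
#'   completeness, the exhaustive search scans the entire merge sequence
#'   and does not stop at `alpha_merge`.
#' @param min_parent_size smallest node that may be split (default 20).
#' @param min_child_size smallest child a split may create (default 7).
#' @param max_depth maximum tree depth, root = depth 0 (default 3).
#' @param bonferroni apply the Bonferroni multiplier (default `TRUE`).
#' @param test `"pearson"` (default) or `"likelihood_ratio"` chi-square.
#' @return object of class `chaid_config`.
#' @export
chaid_config <- function(alpha_split = 0.05, alpha_merge = 0.05,
                         min_parent_size = 20, min_child_size = 7,
                         max_depth = 3, bonferroni = TRUE,
                         test = c("pearson", "likelihood_ratio")) {
  stopifnot(alpha_split > 0, alpha_split <= 1, alpha_merge > 0,
            alpha_merge <= 1, min_parent_size >= 1, min_child_size >= 1,
            max_depth >= 1)
  structure(list(alpha_split = alpha_split, alpha_merge = alpha_merge,
                 min_parent_size = min_parent_size,
                 min_child_size = min_child_size, max_depth = max_depth,
                 bonferroni = isTRUE(bonferroni), test = match.arg(test)),
            class = "chaid_config")
}

#' Stirling number of the second kind
#'
#' S(c, g): the number of ways to partition c labelled categories into g
#' non-empty unordered groups — the Bonferroni multiplier for a nominal
#' predictor reduced from c categories to g groups.
#'
#' @param c,g non-negative integers, `g <= c`.
#' @return S(c, g) as a double.
#' @export
stirling2 <- function(c, g) {
  stopifnot(c >= 0, g >= 0)
  if (g > c) return(0)
  if (g == 0) return(as.numeric(c == 0))
  i <- 0:(g - 1)
  sum((-1)^i * (g - i)^c / (factorial(i) * factorial(g - i)))
}

#' Chi-square test of independence on a two-way count table
#'
#' Pearson chi-square without continuity correction (or the
#' likelihood-ratio G-square), with p from the chi-square distribution on
#' (r-1)(c-1) degrees of freedom. Rows and columns with zero margins are
#' collapsed (dropped) before testing. Degenerate tables (fewer than two
#' non-empty rows or columns) return statistic 0, p 1.
#'
#' @param tab a matrix or table of non-negative counts.
#' @param test `"pearson"` or `"likelihood_ratio"`.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_square_independence <- function(tab, test = c("pearson", "likelihood_ratio")) {
  test <- match.arg(test)
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    return(list(statistic = 0, df = 0L, p_value = 1))
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  if (test == "pearson") {
    stat <- suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$statistic)
    stat <- unname(stat)
  } else {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    nz <- tab > 0
    stat <- 2 * sum(tab[nz] * log(tab[nz] / expected[nz]))
  }
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# p-value and statistic of a grouping (list of category sets) vs outcome
.grouping_test <- function(groups, x, y, test) {
  g <- rep(NA_integer_, length(x))
  for (i in seq_along(groups)) g[x %in% groups[[i]]] <- i
  tab <- table(g, y)
  res <- chi_square_independence(tab, test)
  res$sizes <- as.integer(table(factor(g, levels = seq_along(groups))))
  res
}

#' Best category grouping of one predictor (exhaustive merge search)
#'
#' Starting from all observed categories separate, the least significantly
#' different pair of (compound) categories is merged repeatedly until two
#' groups remain. Each intermediate grouping is tested against the outcome
#' and its p-value is Bonferroni-adjusted by the number of ways to
#' partition the c original categories into that number of groups
#' (`stirling2(c, g)`); the grouping with the smallest adjusted p wins.
#' Groupings that would create a group smaller than `min_child_size` are
#' not eligible.
#'
#' @param x categorical predictor (factor or character).
#' @param y outcome labels (factor, character or logical).
#' @param config a [chaid_config()].
#' @return `NULL` when no eligible grouping exists (e.g. a single observed
#'   category), else a list with `groups` (list of character vectors of
#'   original categories), `p_value` (unadjusted), `adjusted_p`,
#'   `statistic`, `df`, `multiplier`.
#' @export
best_grouping <- function(x, y, config = chaid_config()) {
  x <- as.character(x)
  cats <- sort(unique(x))
  c_orig <- length(cats)
  if (c_orig < 2) return(NULL)
  groups <- as.list(cats)

  evaluate <- function(groups) {
    res <- .grouping_test(groups, x, y, config$test)
    mult <- if (config$bonferroni) stirling2(c_orig, length(groups)) else 1
    list(groups = groups, p_value = res$p_value,
         adjusted_p = min(1, res$p_value * mult),
         statistic = res$statistic, df = res$df, multiplier = mult,
         eligible = all(res$sizes >= config$min_child_size))
  }

  sequence <- list(evaluate(groups))
  while (length(groups) > 2) {
    # merge the least-significantly-different pair of (compound) categories
    best_pair <- NULL
    best_p <- -Inf
    for (i in seq_len(length(groups) - 1)) {
      for (j in (i + 1):length(groups)) {
        in_pair <- x %in% c(groups[[i]], groups[[j]])
        pair_tab <- table(
          factor(ifelse(x[in_pair] %in% groups[[i]], "a", "b"),
                 levels = c("a", "b")),
          y[in_pair])
        p <- chi_square_independence(pair_tab, config$test)$p_value
        if (p > best_p) {
          best_p <- p
          best_pair <- c(i, j)
        }
      }
    }
    merged <- sort(c(groups[[best_pair[1]]], groups[[best_pair[2]]]))
    groups <- c(groups[-best_pair], list(merged))
    groups <- groups[order(vapply(groups, `[`, "", 1))]
    sequence[[length(sequence) + 1L]] <- evaluate(groups)
  }

  eligible <- Filter(function(e) e$eligible, sequence)
  if (!length(eligible)) return(NULL)
  best <- eligible[[which.min(vapply(eligible, `[[`, 0, "adjusted_p"))]]
  best$eligible <- NULL
  best
}

#' Grow an exhaustive-CHAID tree
#'
#' At each node every categorical predictor is reduced to its best grouping
#' ([best_grouping()]); the node splits on the predictor with the smallest
#' adjusted p-value, provided it reaches `alpha_split` and the size and
#' depth limits allow. Ties break deterministically by smaller adjusted p,
#' then larger chi-square, then lexicographic predictor name.
#'
#' @param data `data.frame` of categorical predictors (factors, characters
#'   or logicals).
#' @param outcome outcome labels, one per row of `data`.
#' @param config a [chaid_config()].
#' @return the root `chaid_node`: a nested list with `node_id`, `n`,
#'   `class_counts`, and for internal nodes `split_predictor`,
#'   `groupings`, `adjusted_p`, `chi_square` and `children`.
#' @export
grow_tree <- function(data, outcome, config = chaid_config()) {
  stopifnot(is.data.frame(data), nrow(data) == length(outcome))
  if (nrow(data) == 0) stop("empty data", call. = FALSE)
  if (anyNA(outcome)) stop("outcome must have no missing values", call. = FALSE)
  y <- factor(outcome)
  for (nm in names(data)) data[[nm]] <- as.character(data[[nm]])
  counter <- new.env()
  counter$id <- 0L

  build <- function(idx, depth) {
    counter$id <- counter$id + 1L
    node <- list(node_id = counter$id, depth = depth, n = length(idx),
                 class_counts = table(y[idx]), split_predictor = NULL,
                 groupings = NULL, adjusted_p = NA_real_,
                 chi_square = NA_real_, children = list())
    class(node) <- "chaid_node"
    if (depth >= config$max_depth || length(idx) < config$min_parent_size ||
        length(unique(y[idx])) < 2)
      return(node)

    candidates <- list()
    for (nm in sort(names(data))) {
      bg <- best_grouping(data[[nm]][idx], y[idx], config)
      if (is.null(bg)) next
      if (bg$adjusted_p <= config$alpha_split)
        candidates[[nm]] <- bg
    }
    if (!length(candidates)) return(node)
    ord <- order(vapply(candidates, `[[`, 0, "adjusted_p"),
                 -vapply(candidates, `[[`, 0, "statistic"),
                 names(candidates))
    nm <- names(candidates)[ord[1]]
    bg <- candidates[[nm]]
    node$split_predictor <- nm
    node$groupings <- bg$groups
    node$adjusted_p <- bg$adjusted_p
    node$chi_square <- bg$statistic
    node$children <- lapply(bg$groups, function(g) {
      build(idx[data[[nm]][idx] %in% g], depth + 1L)
    })
    node
  }
  build(seq_along(y), 0L)
}

#' Route records to leaves of a CHAID tree
#'
#' @param tree a `chaid_node` (root).
#' @param newdata `data.frame` containing every predictor the tree splits
#'   on. A category not covered by any child grouping is an error.
#' @return `data.frame` with `node_id` of the reached leaf and one
#'   proportion column per outcome class (`prop_<class>`), the leaf's
#'   class counts normalised.
#' @export
predict_node <- function(tree, newdata) {
  stopifnot(inherits(tree, "chaid_node"), is.data.frame(newdata))
  classes <- names(tree$class_counts)
  route <- function(node, row) {
    if (!length(node$children)) return(node)
    val <- as.character(row[[node$split_predictor]])
    for (k in seq_along(node$groupings)) {
      if (val %in% node$groupings[[k]]) return(route(node$children[[k]], row))
    }
    stop(sprintf("category '%s' of predictor '%s' not covered by any grouping",
                 val, node$split_predictor), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(newdata)), function(i) {
    leaf <- route(tree, newdata[i, , drop = FALSE])
    props <- as.numeric(leaf$class_counts) / max(1, sum(leaf$class_counts))
    out <- data.frame(node_id = leaf$node_id)
    for (k in seq_along(classes)) out[[paste0("prop_", classes[k])]] <- props[k]
    out
  })
  do.call(rbind, rows)
}

#' @export
print.chaid_node <- function(x, ...) {
  cat(format_chaid(x), sep = "\n")
  invisible(x)
}

#' Format a CHAID tree as indented text
#'
#' @param tree a `chaid_node`.
#' @return character vector of lines.
#' @export
format_chaid <- function(tree) {
  lines <- character()
  walk <- function(node, indent, label) {
    counts <- paste(sprintf("%s=%d", names(node$class_counts),
                            as.integer(node$class_counts)), collapse = ", ")
    head <- sprintf("%s%s[node %d] n=%d (%s)", strrep("  ", indent), label,
                    node$node_id, node$n, counts)
    if (!is.null(node$split_predictor)) {
      head <- paste0(head, sprintf(" split=%s adj_p=%.3g chisq=%.3f",
                                   node$split_predictor, node$adjusted_p,
                                   node$chi_square))
    }
    lines <<- c(lines, head)
    for (k in seq_along(node$children)) {
      lab <- sprintf("%s in {%s} -> ", node$split_predictor,
                     paste(node$groupings[[k]], collapse = ","))
      walk(node$children[[k]], indent + 1L, lab)
    }
  }
  walk(tree, 0L, "")
  lines
}

#' Convert a CHAID tree to a plain list (JSON-ready)
#'
#' @param tree a `chaid_node`.
#' @return nested list mirroring the tree, suitable for
#'   `jsonlite::toJSON()`.
#' @export
chaid_to_list <- function(tree) {
  out <- list(node_id = tree$node_id, n = tree$n,
              class_counts = as.list(tree$class_counts))
  if (!is.null(tree$split_predictor)) {
    out$split_predictor <- tree$split_predictor
    out$groupings <- tree$groupings
    out$adjusted_p <- tree$adjusted_p
    out$chi_square <- tree$chi_square
    out$children <- lapply(tree$children, chaid_to_list)
  }
  out
}
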