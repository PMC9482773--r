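# Group invariance of centrality profiles: per-group network fits and the
# paired Wilcoxon signed-rank test on each centrality index across the
# common node set.

# Exact null distribution of W+ over ranks r (possibly midranks): probability
# generating function by convolution over independent sign flips.
.signrank_tail_geq <- function(ranks, w) {
  # P(W+ >= w) under random signs; ranks on a half-unit grid to keep
  # midranks (x.5) on integer support
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  probs <- numeric(total + 1L)  # support 0..total in half-units
  probs[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), probs[seq_len(total + 1L - r)])
    probs <- (probs + shifted) / 2
  }
  sum(probs[(round(2 * w) : total) + 1L])
}

#' Paired Wilcoxon signed-rank test
#'
#' Computes the positive and negative rank sums of the paired differences
#' `x - y`. Zero differences are dropped before ranking; tied absolute
#' differences receive midranks. The two-sided p-value is exact (full
#' enumeration of sign assignments) when no more than `exact_max` nonzero
#' differences remain and the absolute differences are free of ties;
#' otherwise a normal approximation with continuity correction and the
#' tie-corrected variance `n'(n'+1)(2n'+1)/24 - sum(t^3 - t)/48` is used.
#'
#' @param x,y paired numeric vectors of equal length (>= 2).
#' @param exact_max largest tie-free `n'` for which the exact distribution
#'   is enumerated (default 25).
#' @return object of class `"wilcoxon_signed_rank"`: list with `w_plus`,
#'   `w_minus`, `n_effective`, `p_value`, `method` (`"exact"`,
#'   `"normal_approximation"`, or `"degenerate"`), and `degenerate`.
#' @examples
#' wilcoxon_signed_rank(c(1, 3, 2, 5), c(2, 1, 2, 3))
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  d <- d[d != 0]
  n_eff <- length(d)
  if (n_eff == 0) {
    return(structure(list(w_plus = 0, w_minus = 0, n_effective = 0,
                          p_value = 1, method = "degenerate",
                          degenerate = TRUE),
                     class = "wilcoxon_signed_rank"))
  }
  r <- rank(abs(d))  # midranks for ties
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  ties <- any(duplicated(abs(d)))
  if (!ties && n_eff <= exact_max) {
    w_obs <- max(w_plus, w_minus)
    # symmetric null: two-sided p doubles the upper tail at the larger sum
    p <- min(1, 2 * .signrank_tail_geq(r, w_obs))
    method <- "exact"
  } else {
    mu <- n_eff * (n_eff + 1) / 4
    tie_tab <- table(abs(d))
    sigma2 <- n_eff * (n_eff + 1) * (2 * n_eff + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
    if (w_plus == mu) z <- 0
    p <- 2 * pnorm(-abs(z))
    p <- min(1, p)
    method <- "normal_approximation"
  }
  structure(list(w_plus = w_plus, w_minus = w_minus, n_effective = n_eff,
                 p_value = p, method = method, degenerate = FALSE),
            class = "wilcoxon_signed_rank")
}

#' @export
print.wilcoxon_signed_rank <- function(x, ...) {
  cat("Wilcoxon signed-rank: W+ =", x$w_plus, ", W- =", x$w_minus,
      ", n' =", x$n_effective, ", p =", signif(x$p_value, 3),
      paste0("(", x$method, ")"), "\n")
  invisible(x)
}

#' Fit per-group directed networks and centrality tables
#'
#' Splits the data by a grouping column and runs the polychoric ->
#' dependency-TMFG -> centrality pipeline independently in each group. An
#' item degenerate (single occupied category) in any group is dropped from
#' all groups so the paired comparison uses a common node set.
#'
#' @param data item-response data frame.
#' @param group_column name of the grouping column (>= 2 levels).
#' @param items item column names (default `D1...D9` intersected with the
#'   data).
#' @param min_group_n warn when a group has fewer respondents (default 50).
#' @return named list per group: `network` (`"directed_network"`),
#'   `centrality` (`"centrality_table"`), `n`.
#' @export
split_and_fit <- function(data, group_column, items = NULL, min_group_n = 50) {
  stopifnot(group_column %in% names(data))
  if (is.null(items)) {
    items <- intersect(paste0("D", 1:99), names(data))
  }
  groups <- sort(unique(as.character(data[[group_column]])))
  if (length(groups) < 2) stop("grouping column has fewer than 2 levels")

  # drop items degenerate in any group from all groups
  degenerate <- character(0)
  for (g in groups) {
    sub <- data[data[[group_column]] == g, items, drop = FALSE]
    for (it in items) {
      if (length(unique(sub[[it]][!is.na(sub[[it]])])) < 2) {
        degenerate <- union(degenerate, it)
      }
    }
  }
  if (length(degenerate)) {
    warning("item(s) degenerate in at least one group dropped everywhere: ",
            paste(degenerate, collapse = ", "))
    items <- setdiff(items, degenerate)
  }

  out <- list()
  for (g in groups) {
    sub <- data[data[[group_column]] == g, , drop = FALSE]
    if (nrow(sub) < min_group_n) {
      warning("group '", g, "' has only ", nrow(sub), " respondents")
    }
    poly <- polychoric(sub, items = items)
    net <- fit_directed(poly)
    out[[g]] <- list(network = net, centrality = centrality(net, sort = FALSE),
                     n = nrow(sub))
  }
  out
}

#' Centrality invariance across two groups
#'
#' Fits per-group directed networks with [split_and_fit()] and applies the
#' paired Wilcoxon signed-rank test to each centrality index (out-strength,
#' in-strength, betweenness, closeness) across the common node set.
#'
#' @param data item-response data frame.
#' @param group_column grouping column name (exactly 2 levels used; more
#'   levels error).
#' @param items item columns (see [split_and_fit()]).
#' @return object of class `"invariance_result"`: list with `groups`
#'   (labels and sizes), `centrality` (per-group tables), `tests` (data
#'   frame: index, w_plus, w_minus, n_effective, p_value, method).
#' @export
centrality_invariance <- function(data, group_column, items = NULL) {
  fits <- split_and_fit(data, group_column, items)
  if (length(fits) != 2) {
    stop("invariance testing compares exactly two groups; found ",
         length(fits))
  }
  g1 <- fits[[1]]$centrality
  g2 <- fits[[2]]$centrality
  stopifnot(identical(g1$node, g2$node))
  indices <- c("out_strength", "in_strength", "betweenness", "closeness")
  tests <- do.call(rbind, lapply(indices, function(idx) {
    wt <- wilcoxon_signed_rank(g1[[idx]], g2[[idx]])
    data.frame(index = idx, w_plus = wt$w_plus, w_minus = wt$w_minus,
               n_effective = wt$n_effective, p_value = wt$p_value,
               method = wt$method, stringsAsFactors = FALSE)
  }))
  structure(list(groups = data.frame(label = names(fits),
                                     n = vapply(fits, `[[`, numeric(1), "n")),
                 centrality = lapply(fits, `[[`, "centrality"),
                 tests = tests),
            class = "invariance_result")
}

#' @export
print.invariance_result <- function(x, ...) {
  cat("Centrality invariance across groups:",
      paste(x$groups$label, collapse = " vs "), "\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Invariance table in the two-group publication layout
#'
#' Flattens an `"invariance_result"` into one row per node with per-group
#' columns for each index, plus the test statistics as an attribute —
#' the layout used for per-gender / per-age-group centrality tables.
#'
#' @param inv an `"invariance_result"`.
#' @return data frame with attribute `tests`.
#' @export
invariance_table <- function(inv) {
  stopifnot(inherits(inv, "invariance_result"))
  g <- names(inv$centrality)
  t1 <- inv$centrality[[1]]
  t2 <- inv$centrality[[2]]
  out <- data.frame(node = t1$node, stringsAsFactors = FALSE)
  for (idx in c("out_strength", "in_strength", "betweenness", "closeness")) {
    out[[paste0(idx, ".", g[1])]] <- t1[[idx]]
    out[[paste0(idx, ".", g[2])]] <- t2[[idx]]
  }
  attr(out, "tests") <- inv$tests
  out
}
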