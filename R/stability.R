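# Case-dropping bootstrap of centrality indices: subsample a fixed fraction
# of respondents without replacement, re-estimate the directed network, and
# correlate the replication-averaged centralities with the full-sample ones.

#' Case-dropping bootstrap stability of centrality indices
#'
#' For each retention level `q`, draws `reps` subsamples of
#' `floor(q * N)` respondents without replacement, reruns the polychoric ->
#' dependency-TMFG -> centrality pipeline on each, averages every node's
#' centrality value across replications, and reports the Spearman rank
#' correlation between the averaged and the full-sample values, per index.
#' A rank-averaged variant (mean of per-replication ranks, then correlated)
#' is reported alongside. Replications are seeded as `seed + replication`
#' so runs are reproducible and independent of `reps`.
#'
#' @param data item-response data frame.
#' @param items item column names (default `D1...` columns present).
#' @param retention_levels fractions of the sample retained, in (0, 1]
#'   (default `c(0.7, 0.6, 0.5)`).
#' @param reps replications per level (default 1000).
#' @param seed master integer seed.
#' @param min_subsample warn when `floor(q * N)` falls below this (default 50).
#' @return object of class `"stability_result"`: list with `correlations`
#'   (data frame: retention x index, columns `value_mean` and `rank_mean`
#'   Spearman correlations), `full` (full-sample centrality table),
#'   `failures` (per level), `reps`, `seed`.
#' @export
centrality_stability <- function(data, items = NULL,
                                 retention_levels = c(0.7, 0.6, 0.5),
                                 reps = 1000, seed = 1, min_subsample = 50) {
  stopifnot(all(retention_levels > 0), all(retention_levels <= 1), reps >= 1)
  retention_levels <- sort(retention_levels, decreasing = TRUE)
  if (is.null(items)) items <- intersect(paste0("D", 1:99), names(data))
  N <- nrow(data)
  indices <- c("out_strength", "in_strength", "betweenness", "closeness")

  fit_one <- function(d) {
    net <- fit_directed(polychoric(d, items = items))
    ct <- centrality(net, sort = FALSE)
    as.matrix(ct[, indices])
  }
  full <- fit_directed(polychoric(data, items = items))
  full_ct <- centrality(full, sort = FALSE)
  full_mat <- as.matrix(full_ct[, indices])

  old <- .save_rng()
  on.exit(.restore_rng(old))

  rows <- list()
  failures <- integer(length(retention_levels))
  names(failures) <- paste0("q", retention_levels)
  for (li in seq_along(retention_levels)) {
    q <- retention_levels[li]
    m <- floor(q * N)
    if (m < min_subsample) {
      warning("retention ", q, " keeps only ", m, " respondents")
    }
    acc_val <- matrix(0, nrow(full_mat), length(indices))
    acc_rank <- matrix(0, nrow(full_mat), length(indices))
    ok <- 0L
    for (r in seq_len(reps)) {
      if (q == 1) {
        sub_mat <- full_mat
      } else {
        set.seed(seed + r)
        idx <- sample.int(N, m)
        sub_mat <- tryCatch(fit_one(data[idx, , drop = FALSE]),
                            error = function(e) NULL)
      }
      if (is.null(sub_mat) || nrow(sub_mat) != nrow(full_mat)) {
        failures[li] <- failures[li] + 1L
        next
      }
      acc_val <- acc_val + sub_mat
      acc_rank <- acc_rank + apply(sub_mat, 2, rank)
      ok <- ok + 1L
    }
    if (ok == 0) stop("all replications failed at retention ", q)
    if (failures[li] > 0.05 * reps) {
      warning(failures[li], " of ", reps, " replications failed at retention ",
              q)
    }
    for (ii in seq_along(indices)) {
      rows[[length(rows) + 1]] <- data.frame(
        retention = q, index = indices[ii],
        value_mean = stats::cor(acc_val[, ii] / ok, full_mat[, ii],
                                method = "spearman"),
        rank_mean = stats::cor(acc_rank[, ii] / ok, full_mat[, ii],
                               method = "spearman"),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(correlations = do.call(rbind, rows), full = full_ct,
                 failures = failures, reps = reps, seed = seed,
                 retention_levels = retention_levels),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, digits = 2, ...) {
  cat("Case-dropping bootstrap stability (", x$reps, " replications):\n",
      sep = "")
  print(stability_table(x, digits))
  invisible(x)
}

#' Stability correlations in the wide publication layout
#'
#' Rows are centrality indices, columns the retention levels; entries are
#' the Spearman correlations of replication-averaged with full-sample
#' centrality values.
#'
#' @param x a `"stability_result"`.
#' @param digits rounding for display (NULL keeps full precision).
#' @return data frame.
#' @export
stability_table <- function(x, digits = NULL) {
  stopifnot(inherits(x, "stability_result"))
  cc <- x$correlations
  wide <- stats::reshape(cc[, c("retention", "index", "value_mean")],
                         direction = "wide", idvar = "index",
                         timevar = "retention")
  names(wide) <- sub("value_mean\\.", "retained_", names(wide))
  rownames(wide) <- NULL
  if (!is.null(digits)) wide[-1] <- lapply(wide[-1], round, digits)
  wide
}
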