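# The main model fit: polychoric correlations, EBIC-glasso undirected
# network, dependency-TMFG directed network, and centrality, as one classed
# object.

#' Fit the symptom-network model to ordinal questionnaire data
#'
#' Runs the core estimation pipeline on an item-response table: (1) item
#' thresholds and the polychoric correlation matrix by two-step maximum
#' likelihood, (2) the undirected regularized partial-correlation network by
#' graphical lasso with EBIC selection, (3) the directed weighted network by
#' the dependency matrix filtered with the TMFG triangulation, and (4) the
#' centrality table of the directed network. The fit is deterministic: no
#' randomness enters the estimation itself.
#'
#' @param data data frame of ordinal item responses (plus any covariates).
#' @param items item column names; default the `D1`, `D2`, ... columns
#'   present in `data`.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param lambda_count,lambda_min_ratio penalty-grid settings passed to
#'   [fit_undirected()].
#' @param missing `"listwise"` or `"pairwise"` missing-data handling in the
#'   polychoric stage.
#' @param config optional [pipeline_config()] overriding the arguments above.
#' @return object of class `"symptom_network"`: list with `polychoric`,
#'   `undirected`, `directed`, `centrality`, `items`, `n`, `call`.
#' @examples
#' spec <- make_ground_truth("chain", 9, 0.3, n_respondents = 400, seed = 1)
#' fit <- symptom_network(simulate_responses(spec))
#' fit
#' head(summary(fit)$centrality)
#' @export
symptom_network <- function(data, items = NULL, gamma = 0.5,
                            lambda_count = 100, lambda_min_ratio = 0.01,
                            missing = "listwise", config = NULL) {
  if (!is.null(config)) {
    stopifnot(inherits(config, "pipeline_config"))
    items <- config$item_columns
    gamma <- config$ebic_gamma
    lambda_count <- config$lambda_count
    lambda_min_ratio <- config$lambda_min_ratio
    missing <- config$missing_policy
  }
  if (is.null(items)) items <- intersect(paste0("D", 1:99), names(data))
  if (length(items) < 3) stop("need at least 3 item columns")
  poly <- polychoric(data, items = items, missing = missing)
  undirected <- fit_undirected(poly, gamma = gamma,
                               lambda_count = lambda_count,
                               lambda_min_ratio = lambda_min_ratio)
  directed <- fit_directed(poly)
  ct <- centrality(directed)
  structure(list(polychoric = poly, undirected = undirected,
                 directed = directed, centrality = ct, items = items,
                 n = poly$n, call = match.call()),
            class = "symptom_network")
}

#' @export
print.symptom_network <- function(x, ...) {
  cat("Symptom network fit: ", length(x$directed$nodes), " items, n = ",
      x$n, "\n", sep = "")
  cat("  undirected (EBIC-glasso): ", x$undirected$n_edges, " edges, lambda = ",
      signif(x$undirected$lambda_selected, 4), "\n", sep = "")
  cat("  directed (dependency-TMFG): ", nrow(x$directed$skeleton),
      " skeleton edges, ", nrow(x$directed$arcs), " arcs\n", sep = "")
  top <- x$centrality$node[1:min(3, nrow(x$centrality))]
  cat("  highest out-strength:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.symptom_network <- function(object, ...) {
  structure(list(n = object$n, items = object$items,
                 smoothed = object$polychoric$smoothed,
                 lambda_selected = object$undirected$lambda_selected,
                 gamma = object$undirected$gamma,
                 n_edges_undirected = object$undirected$n_edges,
                 n_edges_directed = nrow(object$directed$skeleton),
                 centrality = as.data.frame(object$centrality)),
            class = "summary.symptom_network")
}

#' @export
print.summary.symptom_network <- function(x, ...) {
  cat("Symptom network summary (n = ", x$n, ", ", length(x$items),
      " items)\n", sep = "")
  cat("EBIC-glasso: lambda = ", signif(x$lambda_selected, 4), ", gamma = ",
      x$gamma, ", ", x$n_edges_undirected, " edges",
      if (x$smoothed) "; polychoric matrix was PD-smoothed" else "", "\n",
      sep = "")
  cat("TMFG skeleton: ", x$n_edges_directed, " edges\n\n", sep = "")
  y <- x$centrality[, c("node", "out_strength", "in_strength",
                        "relative_influence", "betweenness", "closeness")]
  y[-1] <- lapply(y[-1], round, 2)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
coef.symptom_network <- function(object, network = c("directed", "undirected"),
                                 ...) {
  network <- match.arg(network)
  if (network == "directed") object$directed$D else object$undirected$weights
}

#' @export
plot.symptom_network <- function(x, which = c("directed", "undirected"), ...) {
  which <- match.arg(which)
  if (which == "directed") {
    g <- .as_igraph_directed(x$directed)
    igraph::plot.igraph(g, edge.width = 1 + 4 * igraph::E(g)$abs_weight /
                          max(igraph::E(g)$abs_weight), ...)
  } else {
    w <- x$undirected$weights
    el <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = x$undirected$nodes[el[, 1]],
                 to = x$undirected$nodes[el[, 2]],
                 weight = w[el]),
      directed = FALSE, vertices = data.frame(name = x$undirected$nodes))
    igraph::plot.igraph(g, edge.width = 1 + 4 * abs(igraph::E(g)$weight) /
                          max(abs(igraph::E(g)$weight)), ...)
  }
  invisible(x)
}

#' Simulate ordinal responses from a fitted symptom network
#'
#' Draws new item-response tables from the fitted latent model: multivariate
#' normal with the estimated polychoric correlation matrix, discretized at
#' the estimated thresholds.
#'
#' @param object a `"symptom_network"` fit.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param n rows per dataset (default: the fitted sample size).
#' @param ... unused.
#' @return list of data frames (a single data frame when `nsim = 1`).
#' @export
simulate.symptom_network <- function(object, nsim = 1, seed = 1,
                                     n = object$n, ...) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  rho <- object$polychoric$rho
  p <- ncol(rho)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    z <- MASS::mvrnorm(n, rep(0, p), rho)
    items <- matrix(NA_integer_, n, p)
    for (j in seq_len(p)) {
      cuts <- c(-Inf, object$polychoric$thresholds[[j]], Inf)
      lv <- object$polychoric$levels_used[[j]]
      items[, j] <- lv[as.integer(cut(z[, j], breaks = cuts, labels = FALSE))]
    }
    colnames(items) <- colnames(rho)
    out[[s]] <- as.data.frame(items)
  }
  if (nsim == 1) out[[1]] else out
}

#' Run the full pipeline and collect a report bundle
#'
#' Fits the symptom network, optionally adds the case-dropping stability
#' analysis and the group-invariance tests, and returns everything as one
#' bundle carrying the seed and configuration used. The bundle is
#' deterministic given (data, config).
#'
#' @param data item-response data frame.
#' @param config a [pipeline_config()].
#' @param stability run the case-dropping bootstrap (default TRUE).
#' @param invariance run invariance tests for `config$group_column`
#'   (default: whenever the column is set).
#' @return object of class `"symptom_report"`: list with `fit`,
#'   `stability` (or NULL), `invariance` (or NULL), `config`, `timings`.
#' @export
run_pipeline <- function(data, config = pipeline_config(), stability = TRUE,
                         invariance = !is.null(config$group_column)) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- c()
  tic <- function(expr, label) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", label, "' failed: ", conditionMessage(e))
    })
    timings[[label]] <<- proc.time()[["elapsed"]] - t0
    message(sprintf("stage %-12s %6.2fs", label, timings[[label]]))
    out
  }
  fit <- tic(symptom_network(data, config = config), "fit")
  stab <- NULL
  if (stability) {
    stab <- tic(centrality_stability(
      data, items = config$item_columns,
      retention_levels = config$retention_levels,
      reps = config$bootstrap_reps, seed = config$seed), "stability")
  }
  inv <- NULL
  if (invariance) {
    if (is.null(config$group_column)) stop("config$group_column is not set")
    inv <- tic(centrality_invariance(data, config$group_column,
                                     items = config$item_columns),
               "invariance")
  }
  structure(list(fit = fit, stability = stab, invariance = inv,
                 config = config, timings = timings),
            class = "symptom_report")
}

#' Write a report bundle to disk
#'
#' Emits a machine-readable JSON report plus CSV tables: the centrality
#' table, the stability correlations (index x retention layout), the
#' per-group invariance table with test statistics, and the two network
#' edge lists (CSV + GraphML). File contents depend only on the report
#' object, so identical runs produce byte-identical output.
#'
#' @param report a `"symptom_report"` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "symptom_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  p <- function(f) file.path(dir, f)
  ct <- as.data.frame(report$fit$centrality)
  utils::write.csv(ct, p("centrality.csv"), row.names = FALSE)
  paths <- c(paths, p("centrality.csv"))
  write_network(report$fit$undirected, p("network_undirected.csv"))
  write_network(report$fit$directed, p("network_directed.csv"))
  paths <- c(paths, p("network_undirected.csv"), p("network_directed.csv"))
  json <- list(n = report$fit$n, items = report$fit$items,
               seed = report$config$seed,
               config = unclass(report$config),
               lambda_selected = report$fit$undirected$lambda_selected,
               n_edges_undirected = report$fit$undirected$n_edges,
               centrality = ct)
  if (!is.null(report$stability)) {
    st <- stability_table(report$stability)
    utils::write.csv(st, p("stability.csv"), row.names = FALSE)
    paths <- c(paths, p("stability.csv"))
    json$stability <- report$stability$correlations
    json$bootstrap_reps <- report$stability$reps
  }
  if (!is.null(report$invariance)) {
    it <- invariance_table(report$invariance)
    tests <- attr(it, "tests")
    utils::write.csv(it, p("invariance_groups.csv"), row.names = FALSE)
    utils::write.csv(tests, p("invariance_tests.csv"), row.names = FALSE)
    paths <- c(paths, p("invariance_groups.csv"), p("invariance_tests.csv"))
    json$invariance <- tests
  }
  jsonlite::write_json(json, p("report.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p("report.json"))
  invisible(paths)
}

#' Published reference centrality tables
#'
#' Small reference tables bundled with the package: directed-network
#' centrality indices of the nine PHQ-9 symptoms as published from a 2020
#' community survey, overall and split by gender and by age group. Used in
#' examples and to exercise the relative-influence and Wilcoxon machinery on
#' real published values.
#'
#' @param which `"overall"`, `"gender"`, or `"age"`.
#' @return data frame (overall: one row per symptom with strength,
#'   relative influence, betweenness, closeness; group tables: per-group
#'   columns for each index).
#' @export
phq9_reference <- function(which = c("overall", "gender", "age")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("phq9_reference_centrality_", which, ".csv"),
                   package = "symptomnet", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE, check.names = FALSE)
}
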