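# Data intake, validation, configuration, and network/report writers.

#' Pipeline configuration
#'
#' Collects the tunable parameters of the full pipeline with validated
#' defaults. Serializable to/from YAML via [write_config()] /
#' [read_config()].
#'
#' @param item_columns item column names (default `D1`..`D9`).
#' @param group_column optional grouping column for invariance testing.
#' @param ebic_gamma EBIC hyperparameter (>= 0, default 0.5).
#' @param lambda_count penalty-grid size (default 100).
#' @param lambda_min_ratio smallest/largest penalty ratio in (0,1)
#'   (default 0.01).
#' @param bootstrap_reps case-dropping replications (default 1000).
#' @param retention_levels retained fractions in (0,1], sorted descending
#'   (default `c(0.7, 0.6, 0.5)`).
#' @param seed integer master seed.
#' @param missing_policy `"listwise"` or `"pairwise"` handling of missing
#'   item responses.
#' @return object of class `"pipeline_config"` (a validated list).
#' @export
pipeline_config <- function(item_columns = paste0("D", 1:9),
                            group_column = NULL, ebic_gamma = 0.5,
                            lambda_count = 100, lambda_min_ratio = 0.01,
                            bootstrap_reps = 1000,
                            retention_levels = c(0.7, 0.6, 0.5), seed = 1,
                            missing_policy = c("listwise", "pairwise")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(length(item_columns) >= 3, ebic_gamma >= 0, lambda_count >= 1,
            lambda_min_ratio > 0, lambda_min_ratio < 1, bootstrap_reps >= 1,
            all(retention_levels > 0), all(retention_levels <= 1))
  structure(list(item_columns = item_columns, group_column = group_column,
                 ebic_gamma = ebic_gamma, lambda_count = lambda_count,
                 lambda_min_ratio = lambda_min_ratio,
                 bootstrap_reps = bootstrap_reps,
                 retention_levels = sort(retention_levels, decreasing = TRUE),
                 seed = as.integer(seed), missing_policy = missing_policy),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `"pipeline_config"`.
#' @param path file path for the YAML serialization.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Read and validate an ordinal item-response CSV
#'
#' Reads a header CSV, checks that the configured item columns are present
#' and hold integers in `[0, max_level]` (or NA), derives `age_group` from
#' `age_years` when available, and applies the missing-data policy
#' (`"listwise"` drops incomplete rows here; `"pairwise"` defers to the
#' polychoric stage).
#'
#' @param path CSV file path.
#' @param config a [pipeline_config()].
#' @param max_level largest valid item code (default 3).
#' @param drop_invalid reject out-of-range rows with a message instead of
#'   erroring (default FALSE: error listing the offending rows).
#' @return validated data frame.
#' @export
read_responses <- function(path, config = pipeline_config(), max_level = 3,
                           drop_invalid = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(config$item_columns, names(x))
  if (length(miss)) {
    stop("missing item column(s): ", paste(miss, collapse = ", "))
  }
  bad <- NULL
  for (col in config$item_columns) {
    v <- x[[col]]
    bad_rows <- which(!is.na(v) &
                        (!is.numeric(v) | v != round(v) | v < 0 | v > max_level))
    if (!is.numeric(v)) bad_rows <- seq_len(nrow(x))
    if (length(bad_rows)) {
      bad <- rbind(bad, data.frame(row = bad_rows, column = col,
                                   value = as.character(v[bad_rows])))
    }
  }
  if (!is.null(bad)) {
    if (drop_invalid) {
      drop <- unique(bad$row)
      message("rejected ", length(drop), " row(s) failing ordinal-range ",
              "validation")
      x <- x[-drop, , drop = FALSE]
    } else {
      stop("item values outside 0..", max_level, ": ",
           paste(sprintf("row %d %s=%s", bad$row, bad$column, bad$value),
                 collapse = "; "))
    }
  }
  if ("age_years" %in% names(x) && !"age_group" %in% names(x)) {
    x$age_group <- age_group_of(x$age_years)
  }
  if (config$missing_policy == "listwise") {
    keep <- stats::complete.cases(x[, config$item_columns, drop = FALSE])
    if (any(!keep)) {
      message("listwise deletion removed ", sum(!keep), " incomplete row(s)")
    }
    x <- x[keep, , drop = FALSE]
  }
  if (nrow(x) < 1) stop("no valid rows remain")
  x
}

# edge list of either network class: columns source, target, weight, directed
.network_edge_list <- function(net) {
  if (inherits(net, "directed_network")) {
    data.frame(source = net$arcs$from, target = net$arcs$to,
               weight = net$arcs$weight,
               directed = rep(TRUE, nrow(net$arcs)),
               stringsAsFactors = FALSE)
  } else if (inherits(net, "undirected_network")) {
    up <- which(upper.tri(net$weights) & net$weights != 0, arr.ind = TRUE)
    data.frame(source = net$nodes[up[, 1]], target = net$nodes[up[, 2]],
               weight = net$weights[up], directed = rep(FALSE, nrow(up)),
               stringsAsFactors = FALSE)
  } else {
    stop("not a network object")
  }
}

#' Write a network as edge-list CSV and GraphML
#'
#' The edge list has columns `source,target,weight,directed`; weights are
#' written with 17 significant digits so a round-trip through
#' [read_network_csv()] reproduces them exactly. A GraphML file (same stem,
#' `.graphml`) is written through igraph.
#'
#' @param net an `"undirected_network"` or `"directed_network"`.
#' @param path output CSV path.
#' @param graphml also write the GraphML companion file (default TRUE).
#' @return invisibly, the CSV path.
#' @export
write_network <- function(net, path, graphml = TRUE) {
  el <- .network_edge_list(net)
  out <- el
  out$weight <- formatC(el$weight, digits = 17, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (graphml) {
    g <- igraph::graph_from_data_frame(el[, c("source", "target", "weight")],
                                       directed = el$directed[1] %||% TRUE,
                                       vertices = data.frame(name = net$nodes))
    igraph::write_graph(g, sub("\\.csv$", ".graphml", path),
                        format = "graphml")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' @rdname write_network
#' @export
read_network_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(source = "character",
                                      target = "character",
                                      weight = "character"))
  x$weight <- as.numeric(x$weight)
  x
}
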