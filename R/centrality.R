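# Centrality of the directed weighted network: in-/out-strength, relative
# influence, and shortest-path betweenness and closeness under the standard
# inverse-absolute-weight distance transform.

#' Relative influence of a node
#'
#' `(out - in) / (out + in)`: positive when a node sends more weighted
#' influence than it receives. Vectorized; a node with `out + in = 0` is
#' isolated and scores 0 (see the `isolated` attribute).
#'
#' @param out_strength,in_strength non-negative numerics.
#' @return numeric in `[-1, 1]`, with attribute `isolated` flagging nodes
#'   where both strengths were zero.
#' @examples
#' relative_influence(3.05, 2.61)   # 0.0777... -> prints as 0.08 at 2 dp
#' @export
relative_influence <- function(out_strength, in_strength) {
  stopifnot(length(out_strength) == length(in_strength),
            all(out_strength >= 0), all(in_strength >= 0))
  tot <- out_strength + in_strength
  iso <- tot == 0
  ri <- ifelse(iso, 0, (out_strength - in_strength) / ifelse(iso, 1, tot))
  attr(ri, "isolated") <- iso
  ri
}

#' Node strength of a directed network
#'
#' Out-strength is the sum of absolute weights of arcs starting at a node;
#' in-strength the same over arcs ending there. Each arc contributes once to
#' an out-strength and once to an in-strength, so the two columns always sum
#' to the same total.
#'
#' @param net a `"directed_network"`.
#' @return data frame with `node`, `out_strength`, `in_strength`.
#' @export
strength <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  aw <- abs(net$arcs$weight)
  out_s <- vapply(net$nodes, function(v) sum(aw[net$arcs$from == v]), numeric(1))
  in_s <- vapply(net$nodes, function(v) sum(aw[net$arcs$to == v]), numeric(1))
  data.frame(node = net$nodes, out_strength = unname(out_s),
             in_strength = unname(in_s), stringsAsFactors = FALSE)
}

#' Betweenness centrality of a directed weighted network
#'
#' Arc length is `1 / |weight|`; for every ordered pair of other nodes the
#' node is credited with the fraction of tied shortest directed paths
#' passing through it (Brandes counting). Reported raw (unnormalized); the
#' normalized variant divides by `(n - 1)(n - 2)`.
#'
#' @param net a `"directed_network"`.
#' @param normalized divide by the number of ordered pairs excluding the node.
#' @return named numeric vector.
#' @export
betweenness <- function(net, normalized = FALSE) {
  g <- .as_igraph_directed(net)
  b <- igraph::betweenness(g, directed = TRUE,
                           weights = igraph::E(g)$length)
  if (normalized) {
    n <- length(net$nodes)
    b <- b / ((n - 1) * (n - 2))
  }
  b[net$nodes]
}

#' Closeness centrality of a directed weighted network
#'
#' `(n - 1) / sum_j d(X, j)` with `d` the shortest directed distance under
#' arc lengths `1 / |weight|`. When some nodes are unreachable the average
#' is taken over the reachable set and the result carries a `coverage`
#' attribute (fraction of other nodes reached); a node reaching no one
#' scores 0.
#'
#' @param net a `"directed_network"`.
#' @return named numeric vector with attribute `coverage`.
#' @export
closeness <- function(net) {
  g <- .as_igraph_directed(net)
  d <- igraph::distances(g, mode = "out", weights = igraph::E(g)$length)
  d <- d[net$nodes, net$nodes]
  diag(d) <- NA
  reach <- is.finite(d)
  cov <- rowSums(reach, na.rm = TRUE) / (length(net$nodes) - 1)
  cl <- vapply(seq_len(nrow(d)), function(i) {
    di <- d[i, reach[i, ] & !is.na(d[i, ])]
    if (length(di) == 0) 0 else length(di) / sum(di)
  }, numeric(1))
  names(cl) <- net$nodes
  if (any(cov < 1)) {
    warning("some nodes do not reach the whole network; closeness computed ",
            "over the reachable set")
  }
  attr(cl, "coverage") <- cov
  cl
}

#' Centrality table of a directed network
#'
#' Assembles the per-node out-strength, in-strength, relative influence,
#' betweenness and closeness, sorted by descending out-strength, together
#' with z-score-transformed columns.
#'
#' @param net a `"directed_network"`.
#' @param sort sort rows by descending out-strength (default TRUE).
#' @return object of class `"centrality_table"` (a data frame with columns
#'   `node`, `out_strength`, `in_strength`, `relative_influence`,
#'   `betweenness`, `closeness` and their `z_`-prefixed transforms).
#' @export
centrality <- function(net, sort = TRUE) {
  s <- strength(net)
  tab <- data.frame(
    node = s$node,
    out_strength = s$out_strength,
    in_strength = s$in_strength,
    relative_influence = as.numeric(relative_influence(s$out_strength,
                                                       s$in_strength)),
    betweenness = unname(betweenness(net)),
    closeness = as.numeric(closeness(net)),
    stringsAsFactors = FALSE)
  for (col in c("out_strength", "in_strength", "relative_influence",
                "betweenness", "closeness")) {
    tab[[paste0("z_", col)]] <- as.numeric(scale(tab[[col]]))
  }
  if (sort) tab <- tab[order(-tab$out_strength), ]
  rownames(tab) <- NULL
  class(tab) <- c("centrality_table", "data.frame")
  tab
}

#' @export
print.centrality_table <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)[, c("node", "out_strength", "in_strength",
                            "relative_influence", "betweenness", "closeness")]
  y[-1] <- lapply(y[-1], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
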