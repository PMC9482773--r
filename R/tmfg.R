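# Directed symptom network: node-dependency matrix from the zero-order
# correlations, planar skeleton by the Triangulated Maximally Filtered Graph
# (TMFG) greedy triangulation, arcs weighted by the dependency entries.

# First-order partial correlation of i and k controlling for j, closed form.
.pcor1 <- function(r_ik, r_ij, r_jk) {
  den <- sqrt((1 - r_ij^2) * (1 - r_jk^2))
  (r_ik - r_ij * r_jk) / den
}

#' Node-dependency matrix of a correlation matrix
#'
#' `D[i, j]` measures how much node i's correlations with the remaining
#' nodes rely on node j (the influence of j on i): the average, over
#' k outside \{i, j\}, of the drop from the zero-order correlation
#' `r(i, k)` to the first-order partial correlation of i and k controlling
#' for j. The matrix is generally asymmetric with zero diagonal.
#'
#' @param rho correlation matrix (n >= 3) or a `"polychoric"` object.
#' @return square matrix `D` with `D[i, j]` = dependency of i on j.
#' @examples
#' r <- matrix(0.5, 3, 3); diag(r) <- 1
#' dependency_matrix(r)  # every off-diagonal entry = 0.5 - 1/3 = 1/6
#' @export
dependency_matrix <- function(rho) {
  if (inherits(rho, "polychoric")) rho <- rho$rho
  rho <- as.matrix(rho)
  p <- ncol(rho)
  stopifnot(p >= 3)
  if (any(abs(rho[upper.tri(rho)]) >= 1)) {
    stop("a correlation of magnitude 1 makes the partial correlations degenerate")
  }
  D <- matrix(0, p, p, dimnames = dimnames(rho))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      ks <- setdiff(seq_len(p), c(i, j))
      drop_ <- rho[i, ks] - .pcor1(rho[i, ks], rho[i, j], rho[j, ks])
      D[i, j] <- mean(drop_)
    }
  }
  D
}

#' Triangulated Maximally Filtered Graph skeleton
#'
#' Greedy planar triangulation retaining `3n - 6` edges: the seed is the
#' 4-clique over the four nodes with the largest total association to all
#' others; each remaining node is then inserted into the triangular face
#' that maximizes the summed weight of the three new edges (the best
#' node/face pair over all remaining nodes at each step), splitting that
#' face in three. Ties are broken by lowest node index, then lowest face
#' index (faces in creation order).
#'
#' @param assoc symmetric matrix of non-negative association weights
#'   (the diagonal is ignored); `n >= 4`.
#' @return list with `edges` (two-column matrix of node indices, i < j),
#'   `faces` (list of final triangular faces), and `insertion` (data frame
#'   recording each inserted node, its face, and the gained weight).
#' @export
tmfg_skeleton <- function(assoc) {
  A <- as.matrix(assoc)
  n <- ncol(A)
  stopifnot(n >= 4, all(is.finite(A)))
  A <- (A + t(A)) / 2
  diag(A) <- 0

  # seed: 4 nodes with largest total association, ties to lowest index
  tot <- rowSums(A)
  seed <- order(-tot, seq_len(n))[1:4]
  seed <- sort(seed)
  in_graph <- logical(n)
  in_graph[seed] <- TRUE
  edges <- t(combn(seed, 2))
  faces <- combn(seed, 3, simplify = FALSE)  # 4 faces of the K4

  remaining <- setdiff(seq_len(n), seed)
  insertion <- data.frame(node = integer(0), face = I(list()),
                          gain = numeric(0))
  while (length(remaining) > 0) {
    # best (node, face) pair; ties: lowest node index, then lowest face index
    best <- NULL
    for (f_idx in seq_along(faces)) {
      f <- faces[[f_idx]]
      for (v in remaining) {
        g <- sum(A[v, f])
        if (is.null(best) || g > best$gain + 1e-12) {
          best <- list(v = v, f_idx = f_idx, gain = g)
        } else if (abs(g - best$gain) <= 1e-12 &&
                   (v < best$v || (v == best$v && f_idx < best$f_idx))) {
          best <- list(v = v, f_idx = f_idx, gain = g)
        }
      }
    }
    f <- faces[[best$f_idx]]
    v <- best$v
    edges <- rbind(edges, cbind(pmin(v, f), pmax(v, f)))
    faces[[best$f_idx]] <- NULL
    faces <- c(faces, list(sort(c(f[1], f[2], v)), sort(c(f[1], f[3], v)),
                           sort(c(f[2], f[3], v))))
    insertion <- rbind(insertion,
                       data.frame(node = v, face = I(list(f)), gain = best$gain))
    remaining <- setdiff(remaining, v)
    in_graph[v] <- TRUE
  }
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("i", "j"))
  list(edges = edges, faces = faces, insertion = insertion)
}

#' Fit the directed dependency network
#'
#' Computes the node-dependency matrix of the polychoric correlations,
#' extracts the TMFG planar skeleton from the symmetrized dependency
#' strengths `max(|D[i,j]|, |D[j,i]|)`, and attaches to every retained
#' skeleton edge \{i, j\} the two opposing arcs: arc `i -> j` carries
#' `D[j, i]` (the dependency of j on i, i.e. the influence of i on j) and
#' arc `j -> i` carries `D[i, j]`. The arc with the larger absolute weight
#' is flagged as the edge's dominant direction.
#'
#' @param poly a `"polychoric"` object or a correlation matrix.
#' @param skeleton_on `"dependency"` (default) builds the skeleton from the
#'   symmetrized dependency strengths; `"correlation"` uses the absolute
#'   zero-order correlations instead.
#' @return object of class `"directed_network"`: list with `nodes`,
#'   `skeleton` (edge index matrix), `arcs` (data frame: from, to, weight,
#'   dominant), `D` (dependency matrix), `rho`, `n`.
#' @export
fit_directed <- function(poly, skeleton_on = c("dependency", "correlation")) {
  skeleton_on <- match.arg(skeleton_on)
  n_obs <- NA_integer_
  if (inherits(poly, "polychoric")) {
    rho <- poly$rho
    n_obs <- poly$n
  } else {
    rho <- as.matrix(poly)
  }
  p <- ncol(rho)
  nodes <- colnames(rho)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(p))
  D <- dependency_matrix(rho)
  assoc <- if (skeleton_on == "dependency") pmax(abs(D), t(abs(D))) else abs(rho)
  sk <- tmfg_skeleton(assoc)
  e <- sk$edges
  arcs <- data.frame(
    from = nodes[c(e[, 1], e[, 2])],
    to = nodes[c(e[, 2], e[, 1])],
    weight = c(D[cbind(e[, 2], e[, 1])], D[cbind(e[, 1], e[, 2])]),
    stringsAsFactors = FALSE)
  # dominant flag per skeleton edge: arc with strictly larger |weight|
  m <- nrow(e)
  w_fwd <- abs(arcs$weight[seq_len(m)])
  w_bwd <- abs(arcs$weight[m + seq_len(m)])
  arcs$dominant <- c(w_fwd > w_bwd, w_bwd > w_fwd)
  structure(list(nodes = nodes, skeleton = e, arcs = arcs, D = D, rho = rho,
                 n = n_obs, skeleton_on = skeleton_on),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat("TMFG directed dependency network:", length(x$nodes), "nodes,",
      nrow(x$skeleton), "skeleton edges,", nrow(x$arcs), "arcs\n")
  invisible(x)
}

# igraph view of a directed network (zero-weight arcs dropped: they carry no
# influence and would break the 1/|w| distance transform).
.as_igraph_directed <- function(net) {
  arcs <- net$arcs[net$arcs$weight != 0, , drop = FALSE]
  g <- igraph::graph_from_data_frame(arcs, directed = TRUE,
                                     vertices = data.frame(name = net$nodes))
  igraph::E(g)$abs_weight <- abs(arcs$weight)
  igraph::E(g)$length <- 1 / abs(arcs$weight)
  g
}
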