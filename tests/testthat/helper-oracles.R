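# Independent brute-force oracles used across the test files. These are
# deliberately naive re-derivations (exhaustive enumeration, closed forms)
# kept free of the package's own code paths.

# all simple directed paths s -> t over an arc data frame (from, to, length)
.bf_all_paths <- function(arcs, s, t, nodes) {
  paths <- list()
  recurse <- function(path, len) {
    last <- path[length(path)]
    if (last == t) {
      paths[[length(paths) + 1]] <<- list(path = path, len = len)
      return()
    }
    out <- arcs[arcs$from == last & !(arcs$to %in% path), , drop = FALSE]
    for (r in seq_len(nrow(out))) {
      recurse(c(path, out$to[r]), len + out$length[r])
    }
  }
  recurse(s, 0)
  paths
}

# Brandes-style betweenness and closeness by exhaustive path enumeration.
bf_centrality <- function(net) {
  arcs <- net$arcs[net$arcs$weight != 0, , drop = FALSE]
  arcs$length <- 1 / abs(arcs$weight)
  nodes <- net$nodes
  btw <- setNames(numeric(length(nodes)), nodes)
  dist <- matrix(Inf, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  diag(dist) <- 0
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    paths <- .bf_all_paths(arcs, s, t, nodes)
    if (length(paths) == 0) next
    lens <- vapply(paths, `[[`, numeric(1), "len")
    dmin <- min(lens)
    dist[s, t] <- dmin
    shortest <- paths[abs(lens - dmin) < 1e-9]
    inner <- unlist(lapply(shortest, function(p)
      setdiff(p$path, c(s, t))))
    if (length(inner)) {
      tab <- table(inner)
      btw[names(tab)] <- btw[names(tab)] + as.numeric(tab) / length(shortest)
    }
  }
  clo <- vapply(nodes, function(s) {
    d <- dist[s, setdiff(nodes, s)]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else length(d) / sum(d)
  }, numeric(1))
  list(betweenness = btw, closeness = clo, dist = dist)
}

# Replay a TMFG fit step by step, maintaining an independent face list, and
# check that every recorded insertion achieved the maximum possible gain.
bf_check_tmfg_greedy <- function(A, sk) {
  A <- (A + t(A)) / 2
  diag(A) <- 0
  n <- ncol(A)
  tot <- rowSums(A)
  seed <- sort(order(-tot, seq_len(n))[1:4])
  faces <- combn(seed, 3, simplify = FALSE)
  remaining <- setdiff(seq_len(n), seed)
  for (step in seq_len(nrow(sk$insertion))) {
    rec_node <- sk$insertion$node[step]
    rec_face <- sk$insertion$face[[step]]
    rec_gain <- sk$insertion$gain[step]
    best_gain <- -Inf
    for (f in faces) for (v in remaining) {
      best_gain <- max(best_gain, sum(A[v, f]))
    }
    if (abs(rec_gain - best_gain) > 1e-9) return(FALSE)
    if (abs(sum(A[rec_node, rec_face]) - rec_gain) > 1e-9) return(FALSE)
    # update face list with the recorded choice
    hit <- which(vapply(faces, function(f) identical(sort(f), sort(rec_face)),
                        logical(1)))[1]
    if (is.na(hit)) return(FALSE)
    f <- faces[[hit]]
    faces[[hit]] <- NULL
    faces <- c(faces, list(sort(c(f[1], f[2], rec_node)),
                           sort(c(f[1], f[3], rec_node)),
                           sort(c(f[2], f[3], rec_node))))
    remaining <- setdiff(remaining, rec_node)
  }
  length(remaining) == 0
}

# Exact two-sided signed-rank p-value by enumeration of all 2^n sign vectors.
bf_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w_obs <- max(w_plus, w_minus)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  mean(w_all >= w_obs) * 2
}

# small deterministic ordinal dataset from a latent bivariate normal
bf_sim_pair <- function(n, rho, tau = c(-0.6745, 0, 0.6745), seed = 1) {
  set.seed(seed)
  z <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, rho, rho, 1), 2))
  cuts <- c(-Inf, tau, Inf)
  data.frame(x = as.integer(cut(z[, 1], cuts)) - 1L,
             y = as.integer(cut(z[, 2], cuts)) - 1L)
}

# contingency table of two ordinal vectors over fixed levels 0..3
bf_pair_table <- function(x, y, k = 4) {
  table(factor(x, levels = 0:(k - 1)), factor(y, levels = 0:(k - 1)))
}
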