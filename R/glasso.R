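# Graphical lasso with extended-BIC model selection. The penalized precision
# is fitted by the standard block coordinate-descent on the covariance
# estimate W (one lasso regression per column per sweep); only off-diagonal
# entries are penalized, so the diagonal of W equals that of the input.

# Lasso coordinate descent: minimize 1/2 b'Vb - s'b + lam*|b|_1.
.lasso_cd <- function(V, s, lam, beta0 = NULL, tol = 1e-8, maxit = 1000L) {
  p <- length(s)
  beta <- if (is.null(beta0)) numeric(p) else beta0
  for (it in seq_len(maxit)) {
    delta <- 0
    for (j in seq_len(p)) {
      r <- s[j] - sum(V[j, ] * beta) + V[j, j] * beta[j]
      bj <- sign(r) * max(abs(r) - lam, 0) / V[j, j]
      delta <- max(delta, abs(bj - beta[j]))
      beta[j] <- bj
    }
    if (delta < tol) break
  }
  beta
}

#' Graphical lasso at a single penalty
#'
#' Maximizes `log det(Theta) - tr(R Theta) - lambda * sum_{i != j} |Theta_ij|`
#' over positive-definite precision matrices by block coordinate descent.
#'
#' @param R positive-definite correlation (sample covariance) matrix.
#' @param lambda non-negative scalar L1 penalty on off-diagonal entries.
#' @param tol convergence threshold on the maximum change of the working
#'   covariance between sweeps.
#' @param maxit maximum number of sweeps.
#' @return list with `theta` (precision), `W` (fitted covariance),
#'   `iterations`, and `converged`.
#' @export
glasso_fit <- function(R, lambda, tol = 1e-4, maxit = 200L) {
  R <- as.matrix(R)
  p <- ncol(R)
  stopifnot(isTRUE(all.equal(R, t(R), tolerance = 1e-8)), lambda >= 0)
  W <- R
  B <- matrix(0, p - 1, p)  # lasso coefficients per column, warm-started
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      beta <- .lasso_cd(W[idx, idx, drop = FALSE], R[idx, j], lambda,
                        beta0 = B[, j])
      B[, j] <- beta
      w12 <- W[idx, idx, drop = FALSE] %*% beta
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (max(abs(W - W_old)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("graphical lasso did not converge at lambda = ", signif(lambda, 4))
  }
  theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    beta <- B[, j]
    t22 <- 1 / (W[j, j] - sum(W[idx, j] * beta))
    theta[j, j] <- t22
    theta[idx, j] <- -beta * t22
  }
  theta <- (theta + t(theta)) / 2
  # exact zeros come from the lasso coefficients: an entry survives only if
  # at least one of the two column problems kept it active
  supp <- matrix(FALSE, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    supp[idx, j] <- B[, j] != 0
  }
  supp <- supp | t(supp)
  theta[!supp & row(theta) != col(theta)] <- 0
  dimnames(theta) <- dimnames(R)
  dimnames(W) <- dimnames(R)
  list(theta = theta, W = W, iterations = it, converged = converged)
}

#' Graphical-lasso solution path
#'
#' Fits [glasso_fit()] at each penalty of a grid, from the largest down
#' (warm starts are implicit in the per-fit coordinate descent).
#'
#' @param R positive-definite correlation matrix.
#' @param lambda_grid decreasing vector of positive penalties.
#' @return list of `glasso_fit()` results, one per penalty.
#' @export
glasso_path <- function(R, lambda_grid) {
  stopifnot(all(lambda_grid > 0))
  lapply(lambda_grid, function(l) glasso_fit(R, l))
}

#' Extended Bayesian information criterion of a precision matrix
#'
#' `EBIC = -n * (log det Theta - tr(R Theta)) + E log n + 4 E gamma log p`,
#' where `E` is the number of nonzero upper-triangle entries of `Theta` and
#' `p` the node count. `gamma = 0` recovers the ordinary BIC penalty.
#'
#' @param theta positive-definite precision matrix.
#' @param R correlation matrix the model was fitted to.
#' @param n sample size.
#' @param gamma non-negative EBIC hyperparameter.
#' @param edge_tol entries with absolute value below this are not edges.
#' @return scalar criterion value (smaller is better).
#' @export
ebic_score <- function(theta, R, n, gamma = 0.5, edge_tol = 1e-6) {
  ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("precision matrix is not positive definite")
  E <- sum(abs(theta[upper.tri(theta)]) > edge_tol)
  p <- ncol(theta)
  loglik <- sum(log(ev)) - sum(R * theta)  # log det - tr(R Theta)
  -n * loglik + E * log(n) + 4 * E * gamma * log(p)
}

#' Fit the EBIC-selected undirected partial-correlation network
#'
#' Runs the graphical lasso along a log-spaced penalty grid from
#' `lambda_max` (the largest absolute off-diagonal correlation) down to
#' `lambda_max * lambda_min_ratio`, scores each fit by [ebic_score()], and
#' returns the network at the EBIC-minimizing penalty, with precision
#' entries converted to partial correlations. EBIC ties are broken toward
#' the larger penalty (the sparser model).
#'
#' @param poly a `"polychoric"` object, or a correlation matrix (then `n`
#'   must be given).
#' @param n sample size (taken from `poly` when available).
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param lambda_count number of grid points (default 100).
#' @param lambda_min_ratio smallest penalty as a fraction of the largest
#'   (default 0.01).
#' @param edge_tol absolute weight below which an entry is treated as zero.
#' @return object of class `"undirected_network"`: list with `weights`
#'   (partial-correlation matrix, zero diagonal), `theta`, `lambda_selected`,
#'   `gamma`, `ebic_value`, `n_edges`, `path` (data frame: lambda, edges,
#'   ebic), `nodes`, `n`.
#' @export
fit_undirected <- function(poly, n = NULL, gamma = 0.5, lambda_count = 100,
                           lambda_min_ratio = 0.01, edge_tol = 1e-6) {
  if (inherits(poly, "polychoric")) {
    R <- poly$rho
    if (is.null(n)) n <- poly$n
  } else {
    R <- as.matrix(poly)
    if (is.null(n)) stop("supply the sample size n with a bare matrix")
  }
  p <- ncol(R)
  lam_max <- max(abs(R[upper.tri(R)]))
  if (lam_max <= 0) lam_max <- 0.1  # identity input: any grid gives 0 edges
  grid <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                  length.out = lambda_count))
  fits <- glasso_path(R, grid)
  ebic <- vapply(fits, function(f) ebic_score(f$theta, R, n, gamma, edge_tol),
                 numeric(1))
  edges <- vapply(fits, function(f)
    sum(abs(f$theta[upper.tri(f$theta)]) > edge_tol), numeric(1))
  best <- which(ebic <= min(ebic) + 1e-9)[1]  # first index = largest lambda
  theta <- fits[[best]]$theta
  d <- sqrt(diag(theta))
  w <- -theta / tcrossprod(d)
  diag(w) <- 0
  w[abs(w) < edge_tol] <- 0
  w <- (w + t(w)) / 2
  nodes <- colnames(R)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(p))
  dimnames(w) <- list(nodes, nodes)
  structure(list(weights = w, theta = theta, lambda_selected = grid[best],
                 gamma = gamma, ebic_value = ebic[best],
                 n_edges = sum(w[upper.tri(w)] != 0),
                 path = data.frame(lambda = grid, edges = edges, ebic = ebic),
                 nodes = nodes, n = n),
            class = "undirected_network")
}

#' @export
print.undirected_network <- function(x, ...) {
  cat("EBIC-glasso undirected network:", length(x$nodes), "nodes,",
      x$n_edges, "edges (lambda =", signif(x$lambda_selected, 4),
      ", gamma =", x$gamma, ")\n")
  invisible(x)
}
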