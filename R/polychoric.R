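# Two-step polychoric correlation estimation for ordinal items: thresholds
# from the marginal category proportions, then each pairwise latent
# correlation by one-dimensional maximum likelihood over the bivariate-normal
# rectangle probabilities.

#' Estimate latent thresholds from ordinal category counts
#'
#' Each ordinal item is modelled as a discretized standard normal variable;
#' the threshold after category k is the normal quantile of the cumulative
#' proportion through k. Empty categories collapse (the item then has fewer
#' thresholds); the retained category codes are recorded.
#'
#' @param counts non-negative integer vector of per-category counts, in
#'   category order (names, if present, are kept as category labels).
#' @return list with `tau` (strictly increasing thresholds, length =
#'   non-empty categories - 1), `levels_used` (indices of non-empty
#'   categories), `n` (total count), and `degenerate` (TRUE when fewer than
#'   two categories are occupied).
#' @examples
#' estimate_thresholds(c(250, 250, 250, 250))$tau  # -0.6745 0 0.6745
#' @export
estimate_thresholds <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  n <- sum(counts)
  if (n <= 0) stop("threshold estimation needs a positive total count")
  keep <- which(counts > 0)
  if (length(keep) < 2L) {
    return(list(tau = numeric(0), levels_used = keep, n = n, degenerate = TRUE))
  }
  cum <- cumsum(counts[keep]) / n
  tau <- qnorm(cum[-length(cum)])
  list(tau = tau, levels_used = keep, n = n, degenerate = FALSE)
}

# Rectangle log-likelihood of a two-way ordinal table at latent correlation
# rho, given the two items' thresholds. tab is the observed contingency table
# over the non-empty categories of each item.
.polychoric_loglik <- function(rho, tab, tau_i, tau_j) {
  ti <- c(-Inf, tau_i, Inf)
  tj <- c(-Inf, tau_j, Inf)
  ri <- nrow(tab)
  rj <- ncol(tab)
  hi <- rep(ti[-1], times = rj)
  lo_i <- rep(ti[-length(ti)], times = rj)
  hj <- rep(tj[-1], each = ri)
  lo_j <- rep(tj[-length(tj)], each = ri)
  p <- pbvnorm(hi, hj, rho) - pbvnorm(lo_i, hj, rho) -
    pbvnorm(hi, lo_j, rho) + pbvnorm(lo_i, lo_j, rho)
  p <- pmax(p, 1e-12)
  sum(as.vector(tab) * log(p))
}

#' Polychoric correlation of one item pair
#'
#' Maximizes the two-step likelihood of the observed contingency table over
#' the latent correlation, the thresholds being held at their marginal
#' estimates. The estimate is constrained to `[-0.999, 0.999]`; a table
#' implying perfect association returns the boundary with `boundary = TRUE`.
#'
#' @param tab contingency table (matrix of counts) of item i by item j over
#'   their non-empty categories.
#' @param tau_i,tau_j threshold vectors of the two items.
#' @param se logical; also compute a numerical-information standard error.
#' @return list with `rho`, `se` (NA unless requested), `loglik`,
#'   `boundary`, and `n` (table total).
#' @export
polychoric_rho <- function(tab, tau_i, tau_j, se = FALSE) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  if (n < 10) stop("pairwise table total below 10; too few observations")
  stopifnot(nrow(tab) == length(tau_i) + 1L, ncol(tab) == length(tau_j) + 1L)
  opt <- optimize(.polychoric_loglik, c(-0.999, 0.999), tab = tab,
                  tau_i = tau_i, tau_j = tau_j, maximum = TRUE,
                  tol = 1e-7)
  rho <- opt$maximum
  ll <- opt$objective
  boundary <- FALSE
  # optimize() cannot land exactly on a bound; probe both ends explicitly.
  for (b in c(-0.999, 0.999)) {
    llb <- .polychoric_loglik(b, tab, tau_i, tau_j)
    if (llb >= ll) {
      rho <- b
      ll <- llb
      boundary <- TRUE
    }
  }
  se_val <- NA_real_
  if (se && !boundary) {
    h <- 1e-4
    d2 <- (.polychoric_loglik(rho + h, tab, tau_i, tau_j) - 2 * ll +
             .polychoric_loglik(rho - h, tab, tau_i, tau_j)) / h^2
    if (is.finite(d2) && d2 < 0) se_val <- sqrt(-1 / d2)
  }
  list(rho = rho, se = se_val, loglik = ll, boundary = boundary, n = n)
}

#' Polychoric correlation matrix of an item-response table
#'
#' Estimates per-item thresholds and all pairwise polychoric correlations for
#' the ordinal item columns of `data`. Items with a single occupied category
#' are degenerate and excluded with a warning. When the assembled pairwise
#' matrix is not positive definite it is repaired by eigenvalue clipping
#' (eigenvalues floored at `pd_tol`, then rescaled to unit diagonal) and
#' `smoothed` is set.
#'
#' @param data data frame or matrix of ordinal responses (integer codes);
#'   non-item columns should be excluded by the caller.
#' @param items character or integer vector selecting the item columns
#'   (default: all columns).
#' @param missing one of `"listwise"` (drop rows with any NA first) or
#'   `"pairwise"` (each pair uses its complete rows).
#' @param pd_tol eigenvalue floor used by the positive-definiteness repair.
#' @return an object of class `"polychoric"`: list with `rho` (correlation
#'   matrix, unit diagonal), `thresholds` (named list of tau vectors),
#'   `levels_used`, `n_used` (pairwise effective sample sizes), `smoothed`,
#'   `boundary` (logical matrix), `dropped_items`, and `n`.
#' @seealso [partial_correlations()], [symptom_network()]
#' @export
polychoric <- function(data, items = NULL, missing = c("listwise", "pairwise"),
                       pd_tol = 1e-6) {
  missing <- match.arg(missing)
  x <- as.data.frame(data)
  if (is.null(items)) {
    items <- names(x)[vapply(x, is.numeric, logical(1))]
    items <- setdiff(items, c("age_years"))
  }
  x <- x[, items, drop = FALSE]
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (missing == "listwise") x <- x[stats::complete.cases(x), , drop = FALSE]
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(p))
  labs <- colnames(x)

  # recode each item onto 1..K over its observed categories
  thresholds <- vector("list", p)
  levels_used <- vector("list", p)
  codes <- matrix(NA_integer_, nrow(x), p)
  degenerate <- logical(p)
  for (j in seq_len(p)) {
    v <- x[, j]
    lv <- sort(unique(v[!is.na(v)]))
    counts <- vapply(lv, function(l) sum(v == l, na.rm = TRUE), integer(1))
    th <- estimate_thresholds(stats::setNames(counts, lv))
    thresholds[[j]] <- th$tau
    levels_used[[j]] <- lv
    degenerate[j] <- th$degenerate
    codes[, j] <- match(v, lv)
  }
  if (any(degenerate)) {
    warning("degenerate item(s) excluded (single occupied category): ",
            paste(labs[degenerate], collapse = ", "))
  }
  keep <- which(!degenerate)
  if (length(keep) < 2L) stop("fewer than 2 non-degenerate items")

  rho <- diag(1, p)
  dimnames(rho) <- list(labs, labs)
  n_used <- matrix(nrow(x), p, p, dimnames = dimnames(rho))
  boundary <- matrix(FALSE, p, p, dimnames = dimnames(rho))
  for (a in seq_along(keep)[-length(keep)]) {
    for (b in seq((a + 1), length(keep))) {
      i <- keep[a]; j <- keep[b]
      ok <- !is.na(codes[, i]) & !is.na(codes[, j])
      ki <- length(levels_used[[i]])
      kj <- length(levels_used[[j]])
      tab <- matrix(tabulate((codes[ok, j] - 1L) * ki + codes[ok, i],
                             nbins = ki * kj), ki, kj)
      fit <- polychoric_rho(tab, thresholds[[i]], thresholds[[j]])
      rho[i, j] <- rho[j, i] <- fit$rho
      n_used[i, j] <- n_used[j, i] <- fit$n
      boundary[i, j] <- boundary[j, i] <- fit$boundary
    }
  }
  rho <- rho[keep, keep, drop = FALSE]
  n_used <- n_used[keep, keep, drop = FALSE]
  boundary <- boundary[keep, keep, drop = FALSE]

  smoothed <- FALSE
  ev <- eigen(rho, symmetric = TRUE)
  if (min(ev$values) < pd_tol) {
    vals <- pmax(ev$values, pd_tol)
    rho <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(rho))
    rho <- rho / tcrossprod(d)
    diag(rho) <- 1
    rho <- (rho + t(rho)) / 2
    dimnames(rho) <- list(labs[keep], labs[keep])
    smoothed <- TRUE
  }

  structure(list(rho = rho,
                 thresholds = stats::setNames(thresholds[keep], labs[keep]),
                 levels_used = stats::setNames(levels_used[keep], labs[keep]),
                 n_used = n_used, smoothed = smoothed, boundary = boundary,
                 dropped_items = labs[degenerate], n = nrow(x)),
            class = "polychoric")
}

#' @export
print.polychoric <- function(x, digits = 3, ...) {
  cat("Polychoric correlations:", ncol(x$rho), "items, n =", x$n,
      if (x$smoothed) "(PD-smoothed)" else "", "\n")
  print(round(x$rho, digits))
  invisible(x)
}

#' Partial correlations from a correlation matrix
#'
#' Inverts the correlation matrix and standardizes the negated precision
#' entries: `p[i,j] = -theta[i,j] / sqrt(theta[i,i] * theta[j,j])`. The
#' diagonal of the result is zero.
#'
#' @param rho positive-definite correlation (or covariance) matrix, or a
#'   `"polychoric"` object.
#' @return symmetric matrix of partial correlations with zero diagonal.
#' @export
partial_correlations <- function(rho) {
  if (inherits(rho, "polychoric")) rho <- rho$rho
  rho <- as.matrix(rho)
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("matrix is singular or indefinite; apply positive-definite smoothing first")
  }
  theta <- solve(rho)
  d <- sqrt(diag(theta))
  pc <- -theta / tcrossprod(d)
  diag(pc) <- 0
  (pc + t(pc)) / 2
}
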