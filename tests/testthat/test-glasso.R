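# correlation matrix of a random sparse GGM, for reuse below
.rand_corr <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p, sd = 0.3), p)
  cov2cor(crossprod(A) + diag(p))
}

test_that("full shrinkage empties the graph and no penalty recovers the inverse", {
  R <- .rand_corr(5, 1)
  lam_max <- max(abs(R[upper.tri(R)]))
  f <- glasso_fit(R, lam_max * 1.001)
  off <- f$theta[upper.tri(f$theta)]
  expect_true(all(off == 0))
  f0 <- glasso_fit(R, 1e-7, tol = 1e-8)
  expect_lt(max(abs(f0$theta - solve(R))), 1e-3)
})

test_that("identity input gives an empty graph at every penalty", {
  path <- glasso_path(diag(6), c(0.5, 0.1, 0.01, 0.001))
  for (f in path) {
    expect_true(all(f$theta[upper.tri(f$theta)] == 0))
  }
})

test_that("glasso solves the penalized likelihood (Nelder-Mead oracle, 4 nodes)", {
  pen_obj <- function(theta, R, lam) {
    ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return(1e10)
    -(sum(log(ev)) - sum(R * theta)) + lam * sum(abs(theta[upper.tri(theta)])) * 2
  }
  to_theta <- function(par) {
    theta <- diag(exp(par[1:4]))
    theta[upper.tri(theta)] <- par[5:10]
    theta[lower.tri(theta)] <- t(theta)[lower.tri(theta)]
    theta
  }
  for (seed in 1:3) {
    R <- .rand_corr(4, seed)
    lam <- 0.1
    fit <- glasso_fit(R, lam, tol = 1e-6)
    # polish with many Nelder-Mead restarts from random starts and the fit
    starts <- c(list(c(log(diag(fit$theta)), fit$theta[upper.tri(fit$theta)])),
                lapply(1:5, function(i) {
                  set.seed(100 + i)
                  c(rep(0, 4), rnorm(6, sd = 0.2))
                }))
    best <- Inf
    for (s in starts) {
      o <- optim(s, function(p) pen_obj(to_theta(p), R, lam),
                 method = "Nelder-Mead",
                 control = list(maxit = 20000, reltol = 1e-12))
      best <- min(best, o$value)
    }
    expect_lt(pen_obj(fit$theta, R, lam), best + 1e-3)
  }
})

test_that("EBIC formula: edge-count linearity and the BIC limit", {
  R <- .rand_corr(5, 2)
  n <- 400
  theta_dense <- solve(R)
  # zero one weak edge: fit difference is small, penalty difference exact
  ij <- which(abs(theta_dense) == min(abs(theta_dense[upper.tri(theta_dense)])),
              arr.ind = TRUE)[1, ]
  theta_sparse <- theta_dense
  theta_sparse[ij[1], ij[2]] <- theta_sparse[ij[2], ij[1]] <- 0
  gamma <- 0.5
  e_dense <- ebic_score(theta_dense, R, n, gamma)
  e_sparse <- ebic_score(theta_sparse, R, n, gamma)
  fit_term <- function(th) -n * (sum(log(eigen(th, symmetric = TRUE,
                                               only.values = TRUE)$values)) -
                                   sum(R * th))
  expect_equal(e_dense - e_sparse,
               (fit_term(theta_dense) - fit_term(theta_sparse)) +
                 log(n) + 4 * gamma * log(5),
               tolerance = 1e-8)
  expect_equal(ebic_score(theta_dense, R, n, gamma = 0),
               fit_term(theta_dense) +
                 sum(abs(theta_dense[upper.tri(theta_dense)]) > 1e-6) * log(n),
               tolerance = 1e-8)
  expect_error(ebic_score(diag(c(1, -1, 1, 1, 1)), R, n), "positive definite")
})

test_that("EBIC prefers the empty model on independent data", {
  set.seed(10)
  d <- as.data.frame(matrix(sample(0:3, 1000 * 5, replace = TRUE,
                                   prob = c(0.4, 0.3, 0.2, 0.1)), ncol = 5))
  net <- fit_undirected(polychoric(d))
  expect_equal(net$n_edges, 0)
})

test_that("identity input selects zero edges and refits deterministically", {
  net1 <- fit_undirected(diag(7), n = 500)
  expect_equal(net1$n_edges, 0)
  R <- .rand_corr(6, 3)
  a <- fit_undirected(R, n = 300)
  b <- fit_undirected(R, n = 300)
  expect_identical(a$lambda_selected, b$lambda_selected)
  expect_identical(a$weights, b$weights)
})

test_that("edge count is non-increasing in the penalty along the path", {
  spec <- make_ground_truth("random_sparse", 7, c(0.15, 0.3),
                            n_respondents = 800, seed = 8)
  poly <- polychoric(simulate_responses(spec))
  net <- fit_undirected(poly)
  path <- net$path  # ordered from largest lambda down
  expect_true(all(diff(path$edges) >= 0))
  expect_true(net$lambda_selected %in% path$lambda)
  # weights are partial correlations: symmetric, zero diagonal, bounded
  expect_equal(net$weights, t(net$weights))
  expect_true(all(abs(net$weights) <= 1))
  expect_true(all(diag(net$weights) == 0))
})

test_that("selected weights are sign-consistent shrunken partials on the support", {
  spec <- make_ground_truth("chain", 6, 0.3, n_respondents = 2000, seed = 12)
  poly <- polychoric(simulate_responses(spec))
  net <- fit_undirected(poly)
  pc <- partial_correlations(poly)
  supp <- net$weights != 0
  expect_true(all(sign(net$weights[supp]) == sign(pc[supp])))
  expect_true(all(abs(net$weights[supp]) <= abs(pc[supp]) + 1e-6))
})
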