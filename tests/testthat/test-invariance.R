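test_that("signed-rank statistics reproduce the published per-gender values", {
  g <- phq9_reference("gender")
  cases <- list(
    list(idx = "out_strength", wp = 22, wm = 23),
    list(idx = "in_strength", wp = 23, wm = 22),
    list(idx = "betweenness", wp = 13, wm = 15),
    list(idx = "closeness", wp = 18, wm = 27))
  for (cs in cases) {
    wt <- wilcoxon_signed_rank(g[[paste0(cs$idx, ".male")]],
                               g[[paste0(cs$idx, ".female")]])
    expect_equal(wt$w_plus, cs$wp)
    expect_equal(wt$w_minus, cs$wm)
  }
  # betweenness: two zero differences dropped before ranking
  wt <- wilcoxon_signed_rank(g$betweenness.male, g$betweenness.female)
  expect_equal(wt$n_effective, 7)
})

test_that("signed-rank statistics reproduce the published per-age-group values", {
  a <- phq9_reference("age")
  cases <- list(
    list(idx = "out_strength", wp = 18, wm = 27),
    list(idx = "in_strength", wp = 14, wm = 31),
    list(idx = "betweenness", wp = 13, wm = 15),
    list(idx = "closeness", wp = 9.5, wm = 35.5))  # midranks for tied |d|
  for (cs in cases) {
    wt <- wilcoxon_signed_rank(a[[paste0(cs$idx, ".18-28")]],
                               a[[paste0(cs$idx, ".29plus")]])
    expect_equal(wt$w_plus, cs$wp)
    expect_equal(wt$w_minus, cs$wm)
  }
})

test_that("rank-sum identity and antisymmetry hold on random pairs", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    x <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties/zeros
    y <- round(rnorm(n), 1)
    wt <- wilcoxon_signed_rank(x, y)
    np <- wt$n_effective
    expect_equal(wt$w_plus + wt$w_minus, np * (np + 1) / 2)
    rev <- wilcoxon_signed_rank(y, x)
    expect_equal(rev$w_plus, wt$w_minus)
    expect_equal(rev$w_minus, wt$w_plus)
    expect_equal(rev$p_value, wt$p_value)
    expect_gt(wt$p_value, 0)
    expect_lte(wt$p_value, 1)
  }
})

test_that("exact p-values agree with full sign enumeration up to n' = 12", {
  set.seed(33)
  for (i in 1:15) {
    n <- sample(4:12, 1)
    d <- rnorm(n)
    wt <- wilcoxon_signed_rank(d + 0.3, rep(0.0, n) + 0.0 * d)
    if (wt$method != "exact") next
    expect_equal(wt$p_value, min(1, bf_wilcoxon_exact(d + 0.3)),
                 tolerance = 1e-12)
  }
  # and against the reference implementation on a tie-free case
  d <- c(1.3, -0.4, 2.2, -3.1, 0.7, 1.9, -0.2, 0.5)
  wt <- wilcoxon_signed_rank(d, rep(0, 8))
  ref <- suppressWarnings(wilcox.test(d, exact = TRUE))
  expect_equal(wt$method, "exact")
  expect_equal(wt$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("ties and large n fall back to the corrected normal approximation", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  y <- c(2, 1, 5, 2, 7, 4, 5, 10)  # tied |d| values
  wt <- wilcoxon_signed_rank(x, y)
  expect_equal(wt$method, "normal_approximation")
  ref <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                      correct = TRUE))
  expect_equal(wt$p_value, ref$p.value, tolerance = 1e-9)
  big <- wilcoxon_signed_rank(rnorm(30) + seq(0.1, 3, length.out = 30),
                              rnorm(30))
  expect_equal(big$method, "normal_approximation")
})

test_that("identical vectors give the degenerate flagged result", {
  wt <- wilcoxon_signed_rank(1:5, 1:5)
  expect_true(wt$degenerate)
  expect_equal(wt$w_plus, 0)
  expect_equal(wt$w_minus, 0)
  expect_equal(wt$p_value, 1)
})

test_that("per-group fits share a common node set and are deterministic", {
  spec <- make_ground_truth("chain", 9, 0.3, n_respondents = 1200, seed = 2)
  d <- simulate_responses(spec)
  fits <- split_and_fit(d, "gender")
  expect_named(fits, c("female", "male"))
  expect_identical(fits$female$centrality$node, fits$male$centrality$node)
  fits2 <- split_and_fit(d, "gender")
  expect_equal(fits$female$centrality, fits2$female$centrality)
  d1 <- d
  d1$gender <- "female"
  expect_error(split_and_fit(d1, "gender"), "fewer than 2 levels")
})

test_that("degenerate items are dropped from every group", {
  spec <- make_ground_truth("chain", 5, 0.3, n_respondents = 600, seed = 3)
  d <- simulate_responses(spec)
  d$D2[d$gender == "male"] <- 1L  # constant in one group only
  expect_warning(fits <- split_and_fit(d, "gender"), "degenerate")
  expect_false("D2" %in% fits$female$centrality$node)
  expect_false("D2" %in% fits$male$centrality$node)
})

test_that("exchangeable groups give similar profiles and no systematic rejection", {
  # ~2000 respondents per group; the same latent model generates both groups
  sim_ok <- 0
  pvals <- NULL
  for (seed in 1:10) {
    spec <- make_ground_truth("random_sparse", 9, c(0.15, 0.35),
                              n_respondents = 5700, seed = seed)
    d <- simulate_responses(spec)
    inv <- centrality_invariance(d, "gender")
    c1 <- inv$centrality[[1]]
    c2 <- inv$centrality[[2]]
    if (cor(c1$out_strength, c2$out_strength, method = "spearman") > 0.8) {
      sim_ok <- sim_ok + 1
    }
    pvals <- rbind(pvals, setNames(inv$tests$p_value, inv$tests$index))
  }
  expect_gte(sim_ok, 9)
  # no index rejects systematically under the null: median p clears 0.05
  # (individual runs can reject because the node-wise differences share the
  # network-level sampling error; see the methods vignette)
  expect_true(all(apply(pvals, 2, median) > 0.05))
})

test_that("a strong group effect is detected more often than a null one", {
  p_null <- p_alt <- NULL
  for (seed in 1:3) {
    spec0 <- make_ground_truth("random_sparse", 9, c(0.15, 0.35),
                               n_respondents = 4000, seed = seed)
    spec1 <- make_ground_truth("random_sparse", 9, c(0.15, 0.35),
                               n_respondents = 4000, group_effect = 0.1,
                               seed = seed)
    inv0 <- centrality_invariance(simulate_responses(spec0), "gender")
    inv1 <- centrality_invariance(simulate_responses(spec1), "gender")
    p_null <- c(p_null, inv0$tests$p_value)
    p_alt <- c(p_alt, inv1$tests$p_value)
  }
  expect_lt(median(p_alt), median(p_null))
})
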