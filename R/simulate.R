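# Synthetic ordinal symptom data with known latent network structure.
# Latent vectors are multivariate normal with the correlation matrix implied
# by a sparse partial-correlation (Gaussian graphical model) ground truth;
# each coordinate is discretized by per-item thresholds into 0..3.

# Correlation matrix implied by a partial-correlation matrix: build the
# standardized precision (unit diagonal, off-diagonal -p), invert, rescale.
.pcor_to_cor <- function(pcor) {
  p <- ncol(pcor)
  omega <- diag(p) - pcor
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("partial-correlation structure implies a non-positive-definite ",
         "precision matrix (min eigenvalue ", signif(min(ev), 3), ")")
  }
  sigma <- solve(omega)
  stats::cov2cor(sigma)
}

#' Construct a synthetic-data specification with known network structure
#'
#' Builds a `symptom_sim_spec`: a sparse latent partial-correlation matrix
#' with a requested support pattern, per-item thresholds, and group settings,
#' from which [simulate_responses()] draws ordinal datasets. The implied
#' precision matrix is checked for positive definiteness at construction.
#'
#' Support patterns: `"chain"` links consecutive items; `"hub"` links item 1
#' to all others; `"random_sparse"` draws each pair independently with
#' probability `edge_prob`; `"planar"` builds a fan triangulation (a planar
#' graph with `3K - 6` edges), useful for TMFG-recovery experiments.
#'
#' @param structure one of `"chain"`, `"hub"`, `"random_sparse"`, `"planar"`.
#' @param n_items number of items (>= 4).
#' @param edge_weight_range numeric length-2; nonzero partial correlations
#'   are drawn uniformly from this range (a single value gives constant
#'   weights).
#' @param n_respondents default number of rows simulated.
#' @param thresholds numeric vector of strictly increasing latent cut-points
#'   used for every item (default `c(0.25, 0.9, 1.6)`, giving the
#'   right-skewed marginals typical of community PHQ-9 data).
#' @param gender_split probability of the reference gender label
#'   (default 0.65 female).
#' @param age_group_split probability of the younger age group (default 0.5).
#' @param group_effect multiplier applied to the latent edges of the
#'   non-reference gender group; 1 keeps the groups exchangeable.
#' @param edge_prob edge probability for `"random_sparse"`.
#' @param seed integer seed controlling the random support/weights here and
#'   the default seed of [simulate_responses()].
#' @return object of class `"symptom_sim_spec"`.
#' @examples
#' spec <- make_ground_truth("chain", 9, 0.3, seed = 1)
#' sum(spec$partial != 0) / 2  # 8 chain edges
#' @export
make_ground_truth <- function(structure = c("chain", "hub", "random_sparse",
                                            "planar"),
                              n_items = 9, edge_weight_range = 0.3,
                              n_respondents = 975,
                              thresholds = c(0.25, 0.9, 1.6),
                              gender_split = 0.65, age_group_split = 0.5,
                              group_effect = 1, edge_prob = 0.3, seed = 1) {
  structure <- match.arg(structure)
  stopifnot(n_items >= 4, all(diff(thresholds) > 0),
            gender_split > 0, gender_split < 1,
            age_group_split > 0, age_group_split < 1)
  if (length(edge_weight_range) == 1) {
    edge_weight_range <- rep(edge_weight_range, 2)
  }
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)

  adj <- matrix(0, n_items, n_items)
  if (structure == "chain") {
    for (i in seq_len(n_items - 1)) adj[i, i + 1] <- 1
  } else if (structure == "hub") {
    adj[1, 2:n_items] <- 1
  } else if (structure == "random_sparse") {
    for (i in seq_len(n_items - 1)) {
      for (j in seq(i + 1, n_items)) adj[i, j] <- rbinom(1, 1, edge_prob)
    }
  } else { # planar: apollonian triangulation, each vertex stacked on {1,2,prev}
    adj[1, 2] <- adj[1, 3] <- adj[2, 3] <- 1
    if (n_items >= 4) {
      for (v in seq(4, n_items)) {
        adj[1, v] <- adj[2, v] <- adj[v - 1, v] <- 1
      }
    }
  }
  adj <- adj + t(adj)
  adj[adj > 0] <- 1

  w <- matrix(0, n_items, n_items)
  up <- upper.tri(adj) & adj == 1
  w[up] <- runif(sum(up), edge_weight_range[1], edge_weight_range[2])
  w <- w + t(w)
  cor_implied <- .pcor_to_cor(w)  # errors if non-PD
  if (group_effect != 1) .pcor_to_cor(w * group_effect)

  labs <- paste0("D", seq_len(n_items))
  dimnames(w) <- list(labs, labs)
  structure(list(structure = structure, partial = w,
                 cor_implied = cor_implied,
                 n_respondents = n_respondents, n_items = n_items,
                 thresholds = thresholds, gender_split = gender_split,
                 age_group_split = age_group_split,
                 group_effect = group_effect, seed = seed),
            class = "symptom_sim_spec")
}

#' @export
print.symptom_sim_spec <- function(x, ...) {
  cat("Synthetic symptom-data spec:", x$structure, "structure,",
      x$n_items, "items,", sum(x$partial != 0) / 2, "latent edges, n =",
      x$n_respondents, "\n")
  invisible(x)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate an ordinal item-response table from a specification
#'
#' Draws latent multivariate-normal vectors with the correlation matrix
#' implied by the spec's partial-correlation ground truth, discretizes each
#' coordinate by the item thresholds into ordinal codes 0..3 (or 0..K), and
#' attaches `gender`, `age_years` and the derived `age_group` covariates.
#' When `group_effect != 1` the non-reference gender group is simulated from
#' the edge-scaled latent structure, giving a controllable violation of
#' group invariance.
#'
#' @param spec a `"symptom_sim_spec"` from [make_ground_truth()].
#' @param n number of respondents (default `spec$n_respondents`).
#' @param seed integer seed (default `spec$seed`).
#' @return data frame with `respondent_id`, item columns `D1...`, `gender`,
#'   `age_years`, `age_group`.
#' @export
simulate_responses <- function(spec, n = spec$n_respondents,
                               seed = spec$seed) {
  stopifnot(inherits(spec, "symptom_sim_spec"), n >= 1)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)

  p <- spec$n_items
  gender <- ifelse(runif(n) < spec$gender_split, "female", "male")
  young <- runif(n) < spec$age_group_split
  age_years <- ifelse(young, sample(18:28, n, replace = TRUE),
                      sample(29:68, n, replace = TRUE))

  z <- matrix(NA_real_, n, p)
  sigma_ref <- spec$cor_implied
  idx_ref <- which(gender == "female")
  if (length(idx_ref)) {
    z[idx_ref, ] <- MASS::mvrnorm(length(idx_ref), mu = rep(0, p),
                                  Sigma = sigma_ref)
  }
  idx_alt <- which(gender == "male")
  if (length(idx_alt)) {
    sigma_alt <- if (spec$group_effect == 1) sigma_ref else
      .pcor_to_cor(spec$partial * spec$group_effect)
    z[idx_alt, ] <- MASS::mvrnorm(length(idx_alt), mu = rep(0, p),
                                  Sigma = sigma_alt)
  }

  cuts <- c(-Inf, spec$thresholds, Inf)
  items <- matrix(as.integer(cut(z, breaks = cuts, labels = FALSE)) - 1L, n, p)
  colnames(items) <- paste0("D", seq_len(p))

  out <- data.frame(respondent_id = sprintf("R%05d", seq_len(n)),
                    items, gender = gender, age_years = age_years,
                    age_group = age_group_of(age_years),
                    stringsAsFactors = FALSE)
  out
}

#' Age-group assignment
#'
#' Dichotomizes age in years at 28/29 into the groups `"18-28"` (<= 28) and
#' `"29+"` (>= 29), the split used for the invariance analysis.
#'
#' @param age_years positive numeric vector of ages.
#' @param cut last age included in the younger group (default 28).
#' @return character vector of group labels.
#' @export
age_group_of <- function(age_years, cut = 28) {
  stopifnot(all(age_years > 0, na.rm = TRUE))
  ifelse(age_years <= cut, paste0("18-", cut), paste0(cut + 1, "+"))
}
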