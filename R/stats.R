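#' Significance flags for adjusted p-values
#'
#' `"*"` for p_adj < 0.05, `"#"` for marginal 0.05 <= p_adj < 0.1, `""`
#' otherwise.
#'
#' @param p_adj numeric vector of adjusted p-values.
#' @param sig,marginal thresholds for `"*"` and `"#"`.
#' @return character vector of flags.
#' @export
significance_flag <- function(p_adj, sig = 0.05, marginal = 0.1) {
  ifelse(p_adj < sig, "*", ifelse(p_adj < marginal, "#", ""))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (a validated wrapper around
#' `p.adjust(method = "BH")`).
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, clipped to 1.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Kruskal-Wallis H-test
#'
#' Midrank H with tie correction and a chi-square p on k-1 df (delegating
#' to `stats::kruskal.test`). The fully tied case, where the tie-corrected
#' statistic is undefined, is returned as H = 0, p = 1.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) == 0)) stop("groups must be non-empty")
  vals <- unlist(groups, use.names = FALSE)
  df <- length(groups) - 1L
  if (length(unique(vals)) == 1)
    return(list(H = 0, p = 1, df = df))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(vals, g)
  list(H = unname(kt$statistic), p = kt$p.value, df = df)
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics from the shared midranks of the pooled data with
#' the pooled tie-corrected variance, two-sided normal p-values, and a
#' Benjamini-Hochberg adjustment across the pairwise family. Flags follow
#' [significance_flag()].
#'
#' @param groups named list of >= 2 non-empty numeric vectors.
#' @param adjust only `"bh"` is supported.
#' @return data.frame with one row per pair: `group1`, `group2`, `z`, `p`,
#'   `p_adj`, `flag`.
#' @export
dunn_posthoc <- function(groups, adjust = "bh") {
  adjust <- match.arg(adjust, "bh")
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) == 0)) stop("groups must be non-empty")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  vals <- unlist(groups, use.names = FALSE)
  gi <- rep(seq_along(groups), lengths(groups))
  N <- length(vals)
  r <- rank(vals)
  rbar <- tapply(r, gi, mean)
  n <- lengths(groups)
  ties <- table(vals)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(length(groups), 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(v0 * (1 / n[i] + 1 / n[j]))
    z[k] <- if (se == 0) 0 else (rbar[i] - rbar[j]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  p_adj <- bh_adjust(p)
  data.frame(group1 = names(groups)[pairs[1, ]],
             group2 = names(groups)[pairs[2, ]],
             z = z, p = p, p_adj = p_adj,
             flag = significance_flag(p_adj),
             stringsAsFactors = FALSE)
}

## Exact two-sided signed-rank p by enumerating all 2^n sign assignments of
## the observed midranks (handles ties, unlike the closed-form null).
signed_rank_exact_p <- function(ranks, W) {
  n <- length(ranks)
  ## distribution of W over all sign vectors, via convolution on the
  ## (possibly tied) rank values scaled to integers
  sc <- ranks * 2            # midranks -> integers
  tot <- sum(sc)
  dist <- numeric(tot + 1)   # index = value + 1
  dist[1] <- 1
  for (s in sc) {
    shifted <- c(numeric(s), dist[seq_len(length(dist) - s)])
    dist <- dist + shifted
  }
  dist <- dist / 2^n
  w2 <- round(W * 2)
  lo <- sum(dist[seq_len(w2 + 1)])
  hi <- sum(dist[(w2 + 1):length(dist)])
  min(1, 2 * min(lo, hi))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped. For n <= `exact_max` remaining pairs the
#' two-sided p is exact, from full enumeration of the 2^n sign assignments
#' of the observed midranks (so ties are handled exactly); beyond that a
#' normal approximation with tie-corrected variance is used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_max largest n for which the exact enumeration is used.
#' @return list with `W` (positive-rank sum), `p`, `n` (non-zero pairs),
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 12) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; p = 1")
    return(list(W = 0, p = 1, n = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    return(list(W = W, p = signed_rank_exact_p(r, W), n = n, method = "exact"))
  }
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (W - mu) / sqrt(sigma2)
  list(W = W, p = 2 * stats::pnorm(-abs(z)), n = n, method = "normal_approx")
}

#' One-way PERMANOVA on a distance matrix
#'
#' Total sum of squares is `sum_{i<j} d_ij^2 / n`; within-group SS is the
#' analogous quantity per group; pseudo-F is
#' `(SS_between/(k-1)) / (SS_within/(n-k))`. The p-value is
#' `(1 + #{F_perm >= F_obs}) / (1 + n_perm)` over seeded label
#' permutations.
#'
#' @param d a [distance_matrix()] (or square symmetric matrix).
#' @param labels group label per sample (length n, >= 2 groups, every
#'   group with >= 2 samples).
#' @param n_perm number of permutations (values below 99 draw a warning).
#' @param seed integer seed for the permutations.
#' @return list with `R2`, `F`, `p`, `n_perm`, `seed`, `SS_total`,
#'   `SS_between`, `SS_within`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1) {
  m <- unclass(as.matrix(d))
  n <- nrow(m)
  labels <- as.character(labels)
  if (length(labels) != n) stop("one label per sample required")
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("every group needs >= 2 samples")
  if (n_perm < 99) warning("n_perm < 99 gives a coarse p-value")
  d2 <- m^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  k <- length(tab)
  ss_within_of <- function(lab) {
    s <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      s <- s + sum(d2[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
    }
    s
  }
  f_of <- function(lab) {
    ssw <- ss_within_of(lab)
    ssb <- ss_total - ssw
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  ss_within <- ss_within_of(labels)
  ss_between <- ss_total - ss_within
  f_obs <- (ss_between / (k - 1)) / (ss_within / (n - k))
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm))
    if (f_of(sample(labels)) >= f_obs) exceed <- exceed + 1L
  list(R2 = ss_between / ss_total, F = f_obs,
       p = (1 + exceed) / (1 + n_perm),
       n_perm = as.integer(n_perm), seed = as.integer(seed),
       SS_total = ss_total, SS_between = ss_between, SS_within = ss_within)
}

#' PERMANOVA against a continuous covariate
#'
#' McArdle-Anderson form: the Gower-centered inner-product matrix
#' `G = C(-d^2/2)C` is regressed on the covariate via its hat matrix;
#' `R2 = tr(HG)/tr(G)` and the permutation p-value shuffles the covariate
#' across samples.
#'
#' @param d a [distance_matrix()].
#' @param z numeric covariate, one value per sample.
#' @inheritParams permanova
#' @return list with `R2`, `F`, `p`, `n_perm`, `seed`.
#' @export
permanova_continuous <- function(d, z, n_perm = 999, seed = 1) {
  m <- unclass(as.matrix(d))
  n <- nrow(m)
  if (length(z) != n) stop("one covariate value per sample required")
  if (stats::sd(z) == 0) stop("covariate is constant")
  A <- -0.5 * m^2
  G <- A - matrix(rowMeans(A), n, n) - matrix(colMeans(A), n, n, byrow = TRUE) +
    mean(A)
  trG <- sum(diag(G))
  stat_of <- function(zz) {
    X <- cbind(1, zz)
    H <- X %*% solve(crossprod(X), t(X))
    trHG <- sum(H * G)        # = tr(HG), H symmetric
    r2 <- trHG / trG
    f <- (trHG / 1) / ((trG - trHG) / (n - 2))
    c(r2, f)
  }
  obs <- stat_of(z)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm))
    if (stat_of(sample(z))[2] >= obs[2]) exceed <- exceed + 1L
  list(R2 = obs[1], F = obs[2], p = (1 + exceed) / (1 + n_perm),
       n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided hypergeometric p (sum of tables at most as probable as the
#' observed one). A zero row or column margin makes the odds ratio
#' undefined; the test then returns p = 1 with `degenerate = TRUE`.
#'
#' @param tab 2x2 matrix of non-negative integers.
#' @return list with `odds_ratio` (conditional MLE; `NA` when degenerate),
#'   `p`, `degenerate`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2)) stop("need a 2x2 table")
  if (any(tab < 0) || max(abs(tab - round(tab))) > 0) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(odds_ratio = NA_real_, p = 1, degenerate = TRUE))
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, degenerate = FALSE)
}

#' Per-feature Spearman association with a response, FDR-adjusted
#'
#' Spearman rho and p for every column of `X` against `y`, with
#' Benjamini-Hochberg adjustment across all features jointly. Constant
#' features get rho = 0, p = 1 and `constant = TRUE`.
#'
#' @param X samples x features numeric matrix.
#' @param y numeric response, one value per sample.
#' @return data.frame: `feature`, `rho`, `p`, `fdr`, `constant`.
#' @export
spearman_with_fdr <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("y must have one value per sample")
  feats <- colnames(X)
  if (is.null(feats)) feats <- paste0("f", seq_len(ncol(X)))
  rho <- p <- numeric(ncol(X))
  const <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    if (stats::sd(v) == 0 || stats::sd(y) == 0) {
      rho[j] <- 0; p[j] <- 1; const[j] <- TRUE
    } else {
      ct <- suppressWarnings(stats::cor.test(v, y, method = "spearman",
                                             exact = FALSE))
      rho[j] <- unname(ct$estimate); p[j] <- ct$p.value
    }
  }
  data.frame(feature = feats, rho = rho, p = p, fdr = bh_adjust(p),
             constant = const, stringsAsFactors = FALSE)
}
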