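test_that("Kruskal-Wallis matches the rank-sum definition and degenerates cleanly", {
  g <- list(c(1, 2, 3), c(4, 5, 6))
  kw <- kruskal_wallis(g)
  expect_equal(kw$H, 27 / 7, tolerance = 1e-9)   # 3.857..., hand-computed
  expect_equal(kw$H, brute_kw_H(g), tolerance = 1e-9)

  set.seed(14)
  for (rep in 1:5) {
    g <- lapply(sample(2:4), function(n) sample(1:8, n + 2, replace = TRUE))
    expect_equal(kruskal_wallis(g)$H, brute_kw_H(g), tolerance = 1e-9)
  }

  same <- list(c(2, 2, 2), c(2, 2))
  expect_equal(kruskal_wallis(same), list(H = 0, p = 1, df = 1))
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$H, 0,
               tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
})

test_that("Dunn post-hoc has correct z, monotone effects, and BH flags", {
  # identical groups: all z = 0, p_adj = 1, no flags
  g0 <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  d0 <- dunn_posthoc(g0)
  expect_true(all(abs(d0$z) < 1e-12))
  expect_true(all(d0$p_adj == 1))
  expect_true(all(d0$flag == ""))

  # z recomputed independently from the definition on a tied fixture
  g <- list(a = c(1, 2, 2, 5), b = c(3, 3, 4), c = c(6, 7, 7, 8, 9))
  d <- dunn_posthoc(g)
  vals <- unlist(g); r <- rank(vals)
  idx <- rep(1:3, lengths(g)); N <- length(vals)
  ties <- table(vals)
  v0 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  for (k in seq_len(nrow(d))) {
    i <- match(d$group1[k], names(g)); j <- match(d$group2[k], names(g))
    zref <- (mean(r[idx == i]) - mean(r[idx == j])) /
      sqrt(v0 * (1 / lengths(g)[i] + 1 / lengths(g)[j]))
    expect_equal(d$z[k], unname(zref), tolerance = 1e-9)
  }

  # one clearly shifted group owns the smallest adjusted p-values
  set.seed(2)
  gs <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8) + 4)
  ds <- dunn_posthoc(gs)
  with_c <- ds$group1 == "c" | ds$group2 == "c"
  expect_true(max(ds$p_adj[with_c]) < min(ds$p_adj[!with_c]))
  expect_error(dunn_posthoc(list(a = 1:3, b = numeric(0))), "non-empty")
})

test_that("BH step-up matches hand evaluation and bounds", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.05, 0.05)), c(0.05, 0.05))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- runif(20)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_identical(significance_flag(c(0.01, 0.07, 0.5)), c("*", "#", ""))
})

test_that("signed-rank test is exact by enumeration for small n, approximate beyond", {
  expect_warning(w0 <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_equal(w0$p, 1)
  w <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(w$p, 1 / 16)                    # 2 * 1/32, full enumeration
  expect_identical(w$method, "exact")

  set.seed(6)
  for (rep in 1:4) {
    x <- rnorm(8); y <- rnorm(8)
    expect_equal(wilcoxon_signed_rank(x, y)$p, brute_signed_rank_p(x - y),
                 tolerance = 1e-12)
  }
  # ties handled exactly too
  x <- c(3, 3, 5, 1, 2, 2); y <- c(1, 1, 2, 2, 4, 4)
  expect_equal(wilcoxon_signed_rank(x, y)$p, brute_signed_rank_p(x - y),
               tolerance = 1e-12)

  # the large-sample branch tracks the tie-corrected normal approximation
  set.seed(9)
  x <- rnorm(20); y <- rnorm(20)
  big <- wilcoxon_signed_rank(x, y)
  expect_identical(big$method, "normal_approx")
  ref <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                      correct = FALSE))
  expect_equal(big$p, ref$p.value, tolerance = 1e-9)
  expect_warning(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
})

test_that("PERMANOVA matches adonis2 and exact label enumeration", {
  set.seed(12)
  X <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(paste0("s", 1:6), NULL))
  X[4:6, ] <- X[4:6, ] + 1.2
  D <- as.matrix(dist(X))
  labels <- rep(c("g1", "g2"), each = 3)
  pv <- permanova(distance_matrix(D, "euclid"), labels, n_perm = 1999, seed = 5)
  ref <- vegan::adonis2(as.dist(D) ~ grp,
                        data = data.frame(grp = labels), permutations = 999)
  expect_equal(pv$R2, ref$R2[1], tolerance = 1e-9)
  expect_equal(pv$F, ref$F[1], tolerance = 1e-9)
  exact_p <- brute_permanova_exact_p(D, labels)
  expect_lt(abs(pv$p - exact_p), 0.05)

  # degenerate separation: two tight, distant clouds
  X2 <- rbind(matrix(0.001 * rnorm(8), 4, 2), matrix(0.001 * rnorm(8) + 10, 4, 2))
  rownames(X2) <- paste0("s", 1:8)
  D2 <- as.matrix(dist(X2))
  pv2 <- permanova(distance_matrix(D2, "euclid"), rep(c("a", "b"), each = 4),
                   n_perm = 999, seed = 1)
  expect_gt(pv2$R2, 0.99)
  # minimal attainable p: only relabelings reproducing the partition tie F
  expect_lt(pv2$p, 2 * (2 / choose(8, 4)) + 0.02)

  expect_error(permanova(distance_matrix(D, "x"), rep("a", 6)), "2 groups")
  expect_error(permanova(distance_matrix(D, "x"), c("a", rep("b", 5))),
               ">= 2 samples")
  # reproducible given the seed
  expect_identical(permanova(distance_matrix(D, "e"), labels, 199, seed = 7),
                   permanova(distance_matrix(D, "e"), labels, 199, seed = 7))
})

test_that("continuous-covariate PERMANOVA agrees with adonis2", {
  set.seed(31)
  X <- matrix(rnorm(10 * 5), 10, 5, dimnames = list(paste0("s", 1:10), NULL))
  z <- rnorm(10) + X[, 1]
  D <- as.matrix(dist(X))
  pv <- permanova_continuous(distance_matrix(D, "euclid"), z,
                             n_perm = 999, seed = 3)
  ref <- vegan::adonis2(as.dist(D) ~ z, data = data.frame(z = z),
                        permutations = 999)
  expect_equal(pv$R2, ref$R2[1], tolerance = 1e-9)
  expect_equal(pv$F, ref$F[1], tolerance = 1e-9)
  expect_lt(abs(pv$p - ref$`Pr(>F)`[1]), 0.07)
})

test_that("Fisher 2x2 equals hypergeometric enumeration, degenerate margins flagged", {
  ft <- fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, 2))
  expect_equal(ft$p, 2 / choose(10, 5), tolerance = 1e-12)
  # direct hypergeometric two-sided sum as oracle
  tab <- matrix(c(7, 2, 3, 8), 2, 2)
  probs <- dhyper(0:9, 9, 11, 10)
  obs <- dhyper(7, 9, 11, 10)
  expect_equal(fisher_exact_2x2(tab)$p, sum(probs[probs <= obs + 1e-12]),
               tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2, 2))$p, 1)
  degen <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 1)
})

test_that("per-feature Spearman screen flags constants and controls FDR", {
  set.seed(18)
  y <- rnorm(30)
  X <- cbind(exact = y, flipped = -y, flat = rep(1, 30),
             matrix(rnorm(30 * 5), 30, 5))
  a <- spearman_with_fdr(X, y)
  expect_equal(a$rho[1], 1)
  expect_equal(a$rho[2], -1)
  expect_true(a$constant[3] && a$rho[3] == 0 && a$p[3] == 1)
  expect_true(all(a$fdr >= a$p))

  # 20 null features + 1 perfect: the planted feature always survives
  # FDR < 0.1, and null features only rarely tag along (BH admits a null
  # at rank 2 with p <= 0.1 * 2/21, i.e. in a sizeable minority of draws)
  found <- 0; false_total <- 0
  for (r in 1:200) {
    set.seed(1000 + r)
    y <- rnorm(25)
    X <- cbind(signal = y, matrix(rnorm(25 * 20), 25, 20))
    a <- spearman_with_fdr(X, y)
    surv <- a$feature[a$fdr < 0.1]
    found <- found + ("signal" %in% surv)
    false_total <- false_total + (length(surv) - ("signal" %in% surv))
  }
  expect_gte(found, 195)
  expect_lte(false_total / 200, 0.5)   # mean false discoveries well below 1
})
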