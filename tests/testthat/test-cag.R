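make_long_meta <- function(n_subj = 3, tps = c("W0", "W2", "W4", "W6")) {
  g <- expand.grid(subject_id = sprintf("S%d", seq_len(n_subj)),
                   timepoint = tps, stringsAsFactors = FALSE)
  g$sample_id <- paste(g$subject_id, g$timepoint, sep = "_")
  g$group <- "young"
  g
}

test_that("mean temporal trend averages samples within each time point", {
  meta <- make_long_meta(3)
  set.seed(51)
  p <- matrix(runif(nrow(meta) * 4), nrow(meta), 4,
              dimnames = list(meta$sample_id, paste0("o", 1:4)))
  tr <- mean_temporal_trend(p, meta)
  for (tp in c("W0", "W2", "W4", "W6"))
    expect_equal(tr[, tp],
                 colMeans(p[meta$sample_id[meta$timepoint == tp], ]),
                 tolerance = 1e-12)
  # single sample per time point: the trend is those samples verbatim
  meta1 <- make_long_meta(1)
  p1 <- p[meta1$sample_id, ]
  expect_equal(unname(mean_temporal_trend(p1, meta1)),
               unname(t(p1)), tolerance = 1e-12)
  # constant OTU: flat trend
  p2 <- p; p2[, "o2"] <- 0.2
  expect_true(all(mean_temporal_trend(p2, meta)["o2", ] == 0.2))
  expect_error(mean_temporal_trend(p, meta[meta$timepoint != "W4", ]), "W4")
})

test_that("Kendall trend distance follows (1 - tau)/2 with the literal variant", {
  tr <- rbind(up1 = c(1, 2, 3, 4), up2 = c(2, 5, 7, 9),
              down = c(9, 6, 4, 2), mixed = c(1, 3, 2, 4))
  d <- kendall_distance_matrix(tr)
  expect_equal(d["up1", "up2"], 0)             # identical rank order
  expect_equal(d["up1", "down"], 1)            # reversed order
  expect_equal(d["up1", "mixed"], 1 / 6)       # tau = 2/3 by pair enumeration
  lit <- kendall_distance_matrix(tr, formula = "one_minus_half_tau")
  expect_equal(lit["up1", "up2"], 1 / 2)       # 1 - 1/2
  expect_equal(lit["up1", "down"], 3 / 2)      # 1 - (-1)/2
  # constant trend: undefined tau -> 0.5 and flagged
  trc <- rbind(tr, flat = c(1, 1, 1, 1))
  expect_warning(dc <- kendall_distance_matrix(trc), regexp = NA)
  expect_equal(unname(dc["flat", "up1"]), 0.5)
  expect_identical(attr(dc, "flagged"), "flat")
})

test_that("Ward-D2 recovers planted trend blocks and is order-invariant", {
  set.seed(61)
  n_half <- 15
  trend <- rbind(
    matrix(rep(c(1, 2, 3, 4), each = n_half) + rnorm(4 * n_half, 0, 0.05),
           n_half, 4),
    matrix(rep(c(4, 3, 2, 1), each = n_half) + rnorm(4 * n_half, 0, 0.05),
           n_half, 4))
  rownames(trend) <- sprintf("o%02d", seq_len(2 * n_half))
  d <- kendall_distance_matrix(trend)
  asg <- ward_cluster(d, 2, trend = trend)
  planted <- rep(c("A", "B"), each = n_half)
  expect_equal(adjusted_rand_index(planted, asg$labels[rownames(trend)]), 1)
  # and agreement with the external ARI implementation
  expect_equal(adjusted_rand_index(planted, asg$labels[rownames(trend)]),
               mclust::adjustedRandIndex(planted, asg$labels[rownames(trend)]),
               tolerance = 1e-12)

  # permuting OTUs permutes labels but not the partition
  perm <- sample(rownames(trend))
  asg2 <- ward_cluster(kendall_distance_matrix(trend[perm, ]), 2,
                       trend = trend[perm, ])
  expect_equal(adjusted_rand_index(asg$labels, asg2$labels[names(asg$labels)]), 1)

  # k = n gives singletons; k out of range errors
  asg_n <- ward_cluster(d, nrow(trend))
  expect_equal(length(unique(asg_n$labels)), nrow(trend))
  expect_error(ward_cluster(d, nrow(trend) + 1), "between 1")

  # label ordering: C1 has the larger mean trend at the earliest
  # differing time point (here W0: block B starts at 4)
  means <- tapply(trend[, 1], asg$labels[rownames(trend)], mean)
  expect_gt(means["C1"], means["C2"])
})

test_that("CAG abundances cumulate members and conserve totals", {
  meta <- make_long_meta(2)
  set.seed(71)
  p <- matrix(runif(nrow(meta) * 6), nrow(meta), 6,
              dimnames = list(meta$sample_id, paste0("o", 1:6)))
  p <- p / rowSums(p)
  one <- stats::setNames(rep("C1", 6), colnames(p))
  expect_equal(unname(cag_abundance(p, one)[, "C1"]), unname(rowSums(p)))
  two <- stats::setNames(rep(c("C1", "C2"), each = 3), colnames(p))
  ca <- cag_abundance(p, two)
  expect_equal(rowSums(ca), rowSums(p), tolerance = 1e-12)
  expect_equal(ca[, "C2"], rowSums(p[, 4:6]), tolerance = 1e-12)
  expect_error(cag_abundance(p[, 1:4], two), "missing")
})

test_that("CAG time-point contrasts delegate to the shared rank machinery", {
  meta <- make_long_meta(6)
  set.seed(81)
  ca <- matrix(runif(nrow(meta) * 2), nrow(meta), 2,
               dimnames = list(meta$sample_id, c("C1", "C2")))
  # a stationary CAG gets no flags; a strongly trending one is flagged
  ca[, "C2"] <- as.numeric(factor(meta$timepoint, levels = unique(meta$timepoint)))
  tt <- cag_timepoint_tests(ca, meta)
  expect_true(all(tt$flag[tt$cag == "C1"] == ""))
  expect_true(any(tt$flag[tt$cag == "C2"] == "*"))
  # flags reproduce stats_core outputs on identical inputs
  groups <- split(ca[, "C2"], meta$timepoint)[c("W0", "W2", "W4", "W6")]
  ref <- dunn_posthoc(groups)
  sub <- tt[tt$cag == "C2", c("group1", "group2", "z", "p", "p_adj", "flag")]
  rownames(sub) <- NULL
  expect_equal(sub, ref, tolerance = 1e-12)
})

test_that("species frequency counts classified members only and conserves totals", {
  labels <- stats::setNames(c("C1", "C1", "C1", "C2", "C2"), paste0("o", 1:5))
  tax <- data.frame(otu_id = paste0("o", 1:5),
                    species = c("sp_a", "sp_a", "", "sp_b", NA),
                    row.names = paste0("o", 1:5), stringsAsFactors = FALSE)
  sf <- species_frequency(labels, tax)
  expect_equal(sf$n_otus[sf$cag == "C1" & sf$species == "sp_a"], 2L)
  expect_equal(sum(sf$n_otus), 3L)   # only species-classified OTUs counted
  # no classified OTUs -> empty profile
  tax0 <- tax; tax0$species <- ""
  expect_equal(nrow(species_frequency(labels, tax0)), 0L)
  # totals match classified member counts on a random fixture
  set.seed(91)
  labs <- stats::setNames(sample(paste0("C", 1:3), 40, TRUE), paste0("x", 1:40))
  spp <- sample(c("s1", "s2", "s3", ""), 40, TRUE)
  taxr <- data.frame(otu_id = names(labs), species = spp,
                     row.names = names(labs), stringsAsFactors = FALSE)
  sfr <- species_frequency(labs, taxr)
  expect_equal(sum(sfr$n_otus), sum(spp != ""))
})
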