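# Brute-force oracles, kept deliberately independent of the package's
# implementations: tree traversal goes through phangorn::Descendants, rank
# statistics are recomputed from first definitions with plain loops.

# enumerate every branch of an ape tree with its descendant tip set
brute_branches <- function(tree) {
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  lapply(seq_len(nrow(tree$edge)), function(e)
    list(length = tree$edge.length[e],
         tips = tree$tip.label[desc[[e]]]))
}

brute_unifrac <- function(a, b, tree, weighted, normalized = TRUE) {
  br <- brute_branches(tree)
  pa <- vapply(br, function(x) sum(a[intersect(names(a), x$tips)]), 0)
  pb <- vapply(br, function(x) sum(b[intersect(names(b), x$tips)]), 0)
  l <- vapply(br, `[[`, 0, "length")
  if (!weighted) {
    obs <- sum(l[pa > 0 | pb > 0])
    if (obs == 0) return(0)
    return(sum(l[xor(pa > 0, pb > 0)]) / obs)
  }
  raw <- sum(l * abs(pa - pb))
  if (!normalized) return(raw)
  den <- sum(l * (pa + pb))
  if (den == 0) 0 else raw / den
}

brute_pd <- function(present_tips, tree) {
  br <- brute_branches(tree)
  sum(vapply(br, function(x)
    if (length(intersect(x$tips, present_tips))) x$length else 0, 0))
}

# Kruskal-Wallis H from the definition, with tie correction
brute_kw_H <- function(groups) {
  vals <- unlist(groups)
  N <- length(vals)
  r <- rank(vals)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, function(x) length(x) * mean(x)^2)) - 3 * (N + 1)
  ties <- table(vals)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# signed-rank two-sided p by looping over all 2^n sign vectors
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- as.integer(intToBits(mask))[seq_len(n)]
    sum(r[signs == 1])
  }, 0)
  min(1, 2 * min(mean(ws <= W), mean(ws >= W)))
}

# exact PERMANOVA p for two equal groups by enumerating label assignments
brute_permanova_exact_p <- function(d, labels) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  groups <- unique(labels)
  f_of <- function(lab) {
    sst <- sum(d2[upper.tri(d2)]) / n
    ssw <- 0
    for (g in groups) {
      idx <- which(lab == g)
      ssw <- ssw + sum(d2[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
    }
    ((sst - ssw) / (length(groups) - 1)) / (ssw / (n - length(groups)))
  }
  f_obs <- f_of(labels)
  picks <- utils::combn(n, sum(labels == groups[1]))
  fs <- apply(picks, 2, function(ix) {
    lab <- rep(groups[2], n); lab[ix] <- groups[1]
    f_of(lab)
  })
  mean(fs >= f_obs)
}

random_otu_table <- function(n_samples, n_otus, seed, max_count = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_otus, max_count / 5), n_samples, n_otus,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("o%03d", seq_len(n_otus))))
  otu_table(m)
}

small_human_sim <- function(seed, ...) {
  simulate_human_study(human_config(n_otus = 120, depth = 4000, seed = seed, ...))
}
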