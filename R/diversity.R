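#' Symmetric sample dissimilarity matrix
#'
#' Light container enforcing the invariants every distance consumer relies
#' on: zero diagonal, symmetry, non-negative entries.
#'
#' @param m square numeric matrix with dimnames.
#' @param metric label recorded in the `metric` attribute.
#' @return a `dist_matrix` object.
#' @export
distance_matrix <- function(m, metric = "unknown") {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(rownames(m))) stop("distance matrix needs dimnames")
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(m) != 0)) stop("distance matrix must have zero diagonal")
  if (any(m < 0)) stop("distances must be non-negative")
  colnames(m) <- rownames(m)
  structure(m, class = c("dist_matrix", "matrix", "array"), metric = metric)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix: %d samples, metric '%s'\n", nrow(x), attr(x, "metric")))
  invisible(x)
}

## Per-edge tip incidence for a rooted ape tree: rows follow tree$edge after
## postorder reordering, so a child's subtree is complete before its own
## edge is read off.
edge_tip_incidence <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  desc <- matrix(FALSE, nn, nt)
  desc[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[p, ] <- desc[p, ] | desc[ch, ]
  }
  inc <- desc[tree$edge[, 2], , drop = FALSE]
  colnames(inc) <- tree$tip.label
  list(incidence = inc, lengths = tree$edge.length, tree = tree)
}

check_tree <- function(tree, ids) {
  if (is.null(tree)) stop("a rooted phylogenetic tree is required")
  ## ape trees always have a single basal node, which is treated as the
  ## root; basal polytomies (star trees) are allowed
  if (is.null(tree$edge.length) || anyNA(tree$edge.length) ||
      any(tree$edge.length < 0) || any(!is.finite(tree$edge.length)))
    stop("tree must have finite non-negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("tree leaf labels must be unique")
  missing <- setdiff(ids, tree$tip.label)
  if (length(missing))
    stop("OTUs missing from tree: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal rooted subtree spanning the leaves
#' observed in each sample (the path to the root is included).
#'
#' @param x samples x OTUs matrix of counts or abundances; presence is
#'   `> 0`.
#' @param tree rooted `ape::phylo` whose tips cover the table's OTUs.
#' @return named numeric vector of PD values, one per sample.
#' @export
faith_pd <- function(x, tree) {
  m <- unclass(as.matrix(x))
  check_tree(tree, colnames(m))
  et <- edge_tip_incidence(tree)
  pres <- (m[, colnames(et$incidence), drop = FALSE] > 0)
  ## edge observed in a sample iff any descendant tip present
  obs <- pres %*% t(et$incidence) > 0
  pd <- as.numeric(obs %*% et$lengths)
  names(pd) <- rownames(m)
  pd
}

#' Alpha-diversity indices per sample
#'
#' Shannon entropy (natural log), Gini-Simpson (1 - sum p^2), bias-corrected
#' Chao1 richness, observed species (count > 0) and, when a tree is given,
#' Faith's PD.
#'
#' Chao1 is S_obs + F1(F1-1) / (2(F2+1)) with F1/F2 the singleton/doubleton
#' counts; it needs raw integer counts and refuses proportions.
#'
#' @param x an [otu_table()] of raw counts.
#' @param tree optional rooted `ape::phylo`; required for `pd`.
#' @return data.frame with one row per sample: `observed_species`,
#'   `shannon`, `simpson`, `chao1` and, if a tree was supplied, `pd`.
#' @export
alpha_diversity <- function(x, tree = NULL) {
  m <- unclass(as.matrix(x))
  if (any(m < 0)) stop("counts must be non-negative")
  if (max(abs(m - round(m))) > 1e-8)
    stop("alpha_diversity needs raw integer counts (Chao1 is undefined on proportions)")
  totals <- rowSums(m)
  p <- m / ifelse(totals == 0, 1, totals)
  plogp <- p * log(p)
  plogp[p == 0] <- 0
  shannon <- -rowSums(plogp)
  simpson <- 1 - rowSums(p^2)
  observed <- rowSums(m > 0)
  f1 <- rowSums(m == 1)
  f2 <- rowSums(m == 2)
  chao1 <- observed + f1 * (f1 - 1) / (2 * (f2 + 1))
  out <- data.frame(sample_id = rownames(m), observed_species = observed,
                    shannon = shannon, simpson = simpson, chao1 = chao1,
                    row.names = rownames(m), stringsAsFactors = FALSE)
  if (!is.null(tree)) out$pd <- faith_pd(m, tree)
  out
}

#' UniFrac dissimilarity between two communities
#'
#' @param a,b named relative-abundance vectors over the tree's leaves
#'   (missing leaves are taken as absent).
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param weighted if TRUE, abundance-weighted UniFrac; otherwise the
#'   presence/absence form (unique branch length over total observed branch
#'   length).
#' @param normalized for weighted UniFrac, divide
#'   `sum l_b |pA_b - pB_b|` by `sum l_b (pA_b + pB_b)` so the result lies
#'   in [0, 1]; ignored for unweighted.
#' @return a single dissimilarity.
#' @export
unifrac <- function(a, b, tree, weighted = TRUE, normalized = TRUE) {
  if (is.null(names(a)) || is.null(names(b)))
    stop("abundance vectors must be named by OTU id")
  extra <- setdiff(union(names(a), names(b)), tree$tip.label)
  if (length(extra))
    stop("OTUs missing from tree: ", paste(extra, collapse = ", "))
  check_tree(tree, character())
  et <- edge_tip_incidence(tree)
  tips <- colnames(et$incidence)
  va <- stats::setNames(numeric(length(tips)), tips); va[names(a)] <- a
  vb <- stats::setNames(numeric(length(tips)), tips); vb[names(b)] <- b
  pa <- as.numeric(et$incidence %*% va)
  pb <- as.numeric(et$incidence %*% vb)
  l <- et$lengths
  if (!weighted) {
    ia <- pa > 0; ib <- pb > 0
    obs <- sum(l[ia | ib])
    if (obs == 0) return(0)
    return(sum(l[xor(ia, ib)]) / obs)
  }
  raw <- sum(l * abs(pa - pb))
  if (!normalized) return(raw)
  denom <- sum(l * (pa + pb))
  if (denom == 0) return(0)
  raw / denom
}

#' Pairwise UniFrac distance matrix
#'
#' @param p samples x OTUs relative-abundance matrix.
#' @inheritParams unifrac
#' @return a [distance_matrix()].
#' @export
unifrac_matrix <- function(p, tree, weighted = TRUE, normalized = TRUE) {
  m <- unclass(as.matrix(p))
  check_tree(tree, colnames(m))
  et <- edge_tip_incidence(tree)
  tips <- colnames(et$incidence)
  full <- matrix(0, nrow(m), length(tips), dimnames = list(rownames(m), tips))
  full[, colnames(m)] <- m
  E <- full %*% t(et$incidence)   # samples x edges: descendant-proportion sums
  l <- et$lengths
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!weighted) {
      ia <- E[i, ] > 0; ib <- E[j, ] > 0
      obs <- sum(l[ia | ib])
      d[i, j] <- if (obs == 0) 0 else sum(l[xor(ia, ib)]) / obs
    } else {
      raw <- sum(l * abs(E[i, ] - E[j, ]))
      if (normalized) {
        denom <- sum(l * (E[i, ] + E[j, ]))
        d[i, j] <- if (denom == 0) 0 else raw / denom
      } else d[i, j] <- raw
    }
    d[j, i] <- d[i, j]
  }
  metric <- if (!weighted) "unweighted_unifrac" else
    if (normalized) "weighted_unifrac_normalized" else "weighted_unifrac_raw"
  distance_matrix(d, metric)
}

#' Spearman correlation distance between samples
#'
#' d(i, j) = 1 - rho_spearman(profile_i, profile_j), range [0, 2]. A sample
#' whose profile is constant (zero rank variance) has undefined rho; its
#' distances are set to 1 with a warning.
#'
#' @param p samples x features abundance matrix (>= 2 features).
#' @return a [distance_matrix()] with metric `"spearman_1mrho_0to2"`.
#' @export
spearman_distance_matrix <- function(p) {
  m <- unclass(as.matrix(p))
  if (ncol(m) < 2) stop("need at least 2 features")
  rho <- suppressWarnings(stats::cor(t(m), method = "spearman"))
  if (anyNA(rho)) {
    warning("constant sample profile(s); their distances set to 1")
    rho[is.na(rho)] <- 0
  }
  d <- 1 - rho
  diag(d) <- 0
  d[d < 0] <- 0   # clip -1e-16 rounding
  distance_matrix(d, "spearman_1mrho_0to2")
}

#' Classical principal coordinates analysis
#'
#' Double-centers -0.5 * d^2 and eigendecomposes. Coordinates are built
#' from the positive eigenvalues only; negative eigenvalues (possible for
#' non-Euclidean dissimilarities) are retained in the report but excluded
#' from the proportion-explained denominator.
#'
#' @param d a [distance_matrix()] (or square symmetric matrix), n >= 3.
#' @param n_axes maximum number of coordinate axes returned.
#' @return list with `coordinates` (samples x axes), `eigenvalues`
#'   (descending, all of them) and `proportion_explained` (over positive
#'   eigenvalues).
#' @export
pcoa_classic <- function(d, n_axes = NULL) {
  m <- unclass(as.matrix(d))
  n <- nrow(m)
  if (n < 3) stop("PCoA needs at least 3 samples")
  A <- -0.5 * m^2
  B <- A - matrix(rowMeans(A), n, n) - matrix(colMeans(A), n, n, byrow = TRUE) +
    mean(A)
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values
  tol <- max(abs(ev)) * 1e-9
  pos <- which(ev > tol)
  if (is.null(n_axes)) n_axes <- length(pos)
  keep <- pos[seq_len(min(n_axes, length(pos)))]
  coords <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev[keep]), length(keep))
  rownames(coords) <- rownames(m)
  colnames(coords) <- paste0("PCo", seq_along(keep))
  list(coordinates = coords,
       eigenvalues = ev,
       proportion_explained = if (length(pos)) ev[keep] / sum(ev[pos]) else numeric(0))
}
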