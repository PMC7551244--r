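#' Mean temporal trend of every OTU
#'
#' Arithmetic mean relative abundance per OTU per time point over all
#' samples of that time point (both age groups pooled), the input to the
#' Kendall-distance clustering that defines co-abundance groups.
#'
#' @param p samples x OTUs relative-abundance matrix.
#' @param meta metadata with `sample_id` and `timepoint`.
#' @param timepoints ordered time-point labels; each must have >= 1
#'   sample.
#' @return OTUs x timepoints matrix of means.
#' @export
mean_temporal_trend <- function(p, meta,
                                timepoints = c("W0", "W2", "W4", "W6")) {
  m <- unclass(as.matrix(p))
  meta <- meta[match(rownames(m), meta$sample_id), , drop = FALSE]
  out <- sapply(timepoints, function(tp) {
    idx <- which(meta$timepoint == tp)
    if (!length(idx)) stop("no samples at time point ", tp)
    colMeans(m[idx, , drop = FALSE])
  })
  rownames(out) <- colnames(m)
  out
}

#' Kendall distance between OTU temporal trends
#'
#' Pairwise tie-corrected Kendall tau-b over the trend vectors, converted
#' to a distance. The default conversion is the conventional correlation
#' distance `(1 - tau) / 2` (tau = 1 -> 0, tau = -1 -> 1); the variant
#' `1 - tau/2` is selectable. The two differ by an affine shift, which can
#' change Ward-D2 merge order, hence the explicit switch. OTUs with a
#' constant trend have undefined tau; their distances are set to 0.5 and
#' the ids recorded in the `flagged` attribute.
#'
#' @param trend OTUs x timepoints matrix from [mean_temporal_trend()].
#' @param formula `"half_one_minus_tau"` for (1 - tau)/2 (default) or
#'   `"one_minus_half_tau"` for 1 - tau/2.
#' @return an OTU x OTU [distance_matrix()].
#' @export
kendall_distance_matrix <- function(trend,
                                    formula = c("half_one_minus_tau",
                                                "one_minus_half_tau")) {
  formula <- match.arg(formula)
  if (ncol(trend) < 2) stop("need at least 2 time points")
  tau <- suppressWarnings(stats::cor(t(trend), method = "kendall"))
  flagged <- rownames(trend)[apply(trend, 1, function(v) stats::sd(v) == 0)]
  d <- if (formula == "half_one_minus_tau") (1 - tau) / 2 else 1 - tau / 2
  d[is.na(d)] <- 0.5
  diag(d) <- 0
  d[d < 0] <- 0
  dm <- distance_matrix(d, paste0("kendall_", formula))
  attr(dm, "flagged") <- flagged
  dm
}

#' Ward-D2 clustering of OTUs into co-abundance groups
#'
#' Agglomerative clustering with the Ward-D2 criterion (merge cost on
#' squared distances, `stats::hclust(method = "ward.D2")`), cut at `k`
#' clusters. Labels C1..Ck are assigned deterministically: when a trend
#' matrix is supplied, clusters are ordered by decreasing mean member
#' trend at the earliest time point where the cluster means differ;
#' otherwise by decreasing size with first-OTU order as tie-break.
#'
#' @param d OTU x OTU [distance_matrix()].
#' @param k number of clusters (1 <= k <= number of OTUs).
#' @param trend optional OTUs x timepoints matrix used for label ordering.
#' @return list of class `cag_assignment`: `labels` (named character
#'   vector otu -> "C1".."Ck"), `k`, `hclust` (the linkage record).
#' @export
ward_cluster <- function(d, k, trend = NULL) {
  m <- unclass(as.matrix(d))
  if (k < 1 || k > nrow(m)) stop("k must be between 1 and the number of OTUs")
  hc <- stats::hclust(stats::as.dist(m), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  ord <- if (!is.null(trend)) {
    means <- do.call(rbind, lapply(seq_len(k), function(g)
      colMeans(trend[names(raw)[raw == g], , drop = FALSE])))
    ## order() on successive columns = earliest differing time point first
    do.call(order, c(lapply(seq_len(ncol(means)), function(j) -means[, j])))
  } else {
    order(-tabulate(raw, k), vapply(seq_len(k), function(g)
      min(which(raw == g)), integer(1)))
  }
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- stats::setNames(paste0("C", relabel[raw]), names(raw))
  structure(list(labels = labels, k = as.integer(k), hclust = hc),
            class = "cag_assignment")
}

#' @export
print.cag_assignment <- function(x, ...) {
  cat(sprintf("cag_assignment: %d OTUs in %d CAGs (%s)\n",
              length(x$labels), x$k,
              paste(sprintf("%s:%d", names(table(x$labels)),
                            table(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Cumulated CAG abundances per sample
#'
#' @param p samples x OTUs relative-abundance matrix containing every
#'   assigned OTU.
#' @param assignment a `cag_assignment` from [ward_cluster()] (or a named
#'   otu -> label vector).
#' @return samples x CAGs matrix of summed member abundances.
#' @export
cag_abundance <- function(p, assignment) {
  labels <- if (inherits(assignment, "cag_assignment")) assignment$labels else assignment
  m <- unclass(as.matrix(p))
  missing <- setdiff(names(labels), colnames(m))
  if (length(missing))
    stop("assigned OTUs missing from table: ", paste(missing, collapse = ", "))
  lv <- sort(unique(labels))
  out <- sapply(lv, function(cg)
    rowSums(m[, names(labels)[labels == cg], drop = FALSE]))
  rownames(out) <- rownames(m)
  out
}

#' CAG abundance contrasts across time points
#'
#' For each CAG, Kruskal-Wallis across the time points followed by Dunn's
#' pairwise post-hoc with BH adjustment (family = that CAG's pairs) and
#' the `*`/`#` flags.
#'
#' @param ca samples x CAGs matrix from [cag_abundance()].
#' @param meta metadata with `sample_id` and `timepoint`.
#' @param timepoints ordered time-point labels.
#' @return data.frame: `cag`, `kw_H`, `kw_p`, `group1`, `group2` (time
#'   points), `z`, `p`, `p_adj`, `flag`.
#' @export
cag_timepoint_tests <- function(ca, meta,
                                timepoints = c("W0", "W2", "W4", "W6")) {
  m <- unclass(as.matrix(ca))
  meta <- meta[match(rownames(m), meta$sample_id), , drop = FALSE]
  have <- timepoints[timepoints %in% meta$timepoint]
  if (length(have) < 2) stop("need >= 2 time points with samples")
  rows <- lapply(colnames(m), function(cg) {
    groups <- lapply(have, function(tp) m[meta$timepoint == tp, cg])
    names(groups) <- have
    kw <- kruskal_wallis(groups)
    dn <- dunn_posthoc(groups)
    cbind(cag = cg, kw_H = kw$H, kw_p = kw$p, dn)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Species frequency profile per CAG
#'
#' Counts, within each CAG, how many member OTUs carry each defined
#' species label; OTUs without a species classification are ignored.
#'
#' @param assignment a `cag_assignment` (or named otu -> label vector).
#' @param taxonomy data.frame with rownames = OTU ids and a `species`
#'   column (empty/NA = unclassified).
#' @return data.frame: `cag`, `species`, `n_otus`.
#' @export
species_frequency <- function(assignment, taxonomy) {
  labels <- if (inherits(assignment, "cag_assignment")) assignment$labels else assignment
  sp <- rep(NA_character_, length(labels))
  idx <- match(names(labels), rownames(taxonomy))
  if ("species" %in% colnames(taxonomy))
    sp[!is.na(idx)] <- as.character(taxonomy$species[idx[!is.na(idx)]])
  sp[sp %in% c("", "unclassified")] <- NA
  keep <- !is.na(sp)
  if (!any(keep))
    return(data.frame(cag = character(0), species = character(0),
                      n_otus = integer(0), stringsAsFactors = FALSE))
  tab <- as.data.frame(table(cag = labels[keep], species = sp[keep]),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  names(tab)[3] <- "n_otus"
  tab <- tab[order(tab$cag, -tab$n_otus, tab$species), ]
  rownames(tab) <- NULL
  tab
}

#' Adjusted Rand index between two partitions
#'
#' Used to score recovery of planted CAG partitions by the clustering.
#'
#' @param a,b two label vectors over the same items (same length; matched
#'   by position, or by names when both are named).
#' @return the adjusted Rand index (1 = identical partitions, ~0 =
#'   chance).
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  if (length(a) != length(b) || anyNA(b)) stop("partitions must cover the same items")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
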