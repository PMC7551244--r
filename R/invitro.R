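#' Default supplementation super-groups
#'
#' The two super-groups of supplementation regimes whose fermenter
#' microbiotas cluster together: G1 = anthocyanins/flavonol glycosides,
#' prebiotic mix, proanthocyanidins; G2 = sugar/acid fraction, total
#' polyphenols. The unsupplemented control belongs to neither and is
#' excluded from within/across contrasts.
#'
#' @return named character vector: regime -> super-group label.
#' @export
g1_g2_partition <- function() {
  c("ANTH/FLAV" = "G1", "MIX" = "G1", "PACs" = "G1",
    "S/A" = "G2", "TPP" = "G2")
}

#' Pool samples of selected fermentation time points per regime
#'
#' Collects, for every supplementation regime, the sample ids observed at
#' the requested time points (by default 16 h and 24 h combined, excluding
#' the 0 h baseline).
#'
#' @param meta metadata data.frame with `sample_id`, `group`, `timepoint`.
#' @param points character vector of time points to pool.
#' @param regimes regimes to include; defaults to all present.
#' @return named list: regime -> character vector of sample ids.
#' @export
pool_timepoints <- function(meta, points = c("16h", "24h"), regimes = NULL) {
  sel <- meta[meta$timepoint %in% points, , drop = FALSE]
  if (is.null(regimes)) regimes <- unique(meta$group)
  pools <- lapply(regimes, function(g) sel$sample_id[sel$group == g])
  names(pools) <- regimes
  empty <- names(pools)[lengths(pools) == 0]
  if (length(empty))
    stop("no samples at ", paste(points, collapse = "/"), " for regime(s): ",
         paste(empty, collapse = ", "))
  pools
}

#' Differentially abundant taxa across supplementation regimes
#'
#' For every taxon, a Kruskal-Wallis test across the pooled regimes
#' followed by Dunn's pairwise post-hoc. The BH adjustment is applied, by
#' default, over the full family of (taxon x pair) p-values of the
#' analysis; `bh_scope = "per_taxon"` restricts each family to one taxon's
#' pairs.
#'
#' @param p samples x taxa relative-abundance matrix (already aggregated
#'   to the desired rank).
#' @param pools named list from [pool_timepoints()].
#' @param bh_scope `"pooled"` (default) or `"per_taxon"`.
#' @return data.frame with one row per taxon x regime pair: `taxon`,
#'   `kw_H`, `kw_p`, `group1`, `group2`, `z`, `p`, `p_adj`, `flag`.
#'   Taxa absent from every pooled sample are skipped (attribute
#'   `skipped_taxa`).
#' @export
differential_taxa <- function(p, pools, bh_scope = c("pooled", "per_taxon")) {
  bh_scope <- match.arg(bh_scope)
  if (length(pools) < 2) stop("need at least 2 regimes")
  m <- unclass(as.matrix(p))
  used <- unlist(pools, use.names = FALSE)
  missing <- setdiff(used, rownames(m))
  if (length(missing))
    stop("pooled samples missing from abundance table: ",
         paste(missing, collapse = ", "))
  rows <- list()
  skipped <- character(0)
  for (taxon in colnames(m)) {
    groups <- lapply(pools, function(ids) m[ids, taxon])
    if (all(unlist(groups) == 0)) { skipped <- c(skipped, taxon); next }
    kw <- kruskal_wallis(groups)
    dn <- dunn_posthoc(groups)
    dn$taxon <- taxon
    dn$kw_H <- kw$H
    dn$kw_p <- kw$p
    rows[[taxon]] <- dn
  }
  if (!length(rows))
    return(structure(data.frame(), skipped_taxa = skipped))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (bh_scope == "pooled") {
    out$p_adj <- bh_adjust(out$p)
    out$flag <- significance_flag(out$p_adj)
  }
  out <- out[, c("taxon", "kw_H", "kw_p", "group1", "group2",
                 "z", "p", "p_adj", "flag")]
  structure(out, skipped_taxa = skipped)
}

#' Paired 16 h vs 24 h stability check per taxon
#'
#' Wilcoxon signed-rank test of each taxon's abundance at the two
#' fermentation time points, paired by vessel within regime. Vessels
#' missing one of the two time points are dropped with a warning.
#'
#' @param p samples x taxa relative-abundance matrix.
#' @param meta metadata with `sample_id`, `subject_id` (vessel),
#'   `group`, `timepoint`.
#' @param points exactly two time points, earlier first.
#' @return data.frame: `taxon`, `n_pairs`, `W`, `p`.
#' @export
timepoint_stability <- function(p, meta, points = c("16h", "24h")) {
  if (length(points) != 2) stop("exactly two time points required")
  m <- unclass(as.matrix(p))
  a <- meta[meta$timepoint == points[1], , drop = FALSE]
  b <- meta[meta$timepoint == points[2], , drop = FALSE]
  key_a <- paste(a$group, a$subject_id)
  key_b <- paste(b$group, b$subject_id)
  shared <- intersect(key_a, key_b)
  dropped <- setdiff(union(key_a, key_b), shared)
  if (length(dropped))
    warning("unpaired vessel(s) dropped: ", paste(dropped, collapse = ", "))
  if (!length(shared)) stop("no paired vessels between the two time points")
  ids_a <- a$sample_id[match(shared, key_a)]
  ids_b <- b$sample_id[match(shared, key_b)]
  res <- lapply(colnames(m), function(taxon) {
    w <- suppressWarnings(wilcoxon_signed_rank(m[ids_a, taxon], m[ids_b, taxon]))
    data.frame(taxon = taxon, n_pairs = length(shared), W = w$W, p = w$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Within- vs across-super-group median distances
#'
#' For every sample of a super-group, the median distance to all other
#' samples of the same super-group and the median distance to all samples
#' of the other super-group (self excluded), compared by a Wilcoxon
#' rank-sum test over the two collections of per-sample medians.
#'
#' @param d a [distance_matrix()] covering the pooled samples.
#' @param meta metadata with `sample_id` and `group`.
#' @param partition named vector regime -> super-group (see
#'   [g1_g2_partition()]); regimes absent from it are excluded.
#' @return list with `per_sample` (data.frame: `sample_id`, `supergroup`,
#'   `median_within`, `median_across`) and `wilcox_p`.
#' @export
within_across_distances <- function(d, meta, partition = g1_g2_partition()) {
  m <- unclass(as.matrix(d))
  meta <- meta[match(rownames(m), meta$sample_id), , drop = FALSE]
  sg <- unname(partition[meta$group])
  keep <- which(!is.na(sg))
  if (length(unique(sg[keep])) != 2) stop("need exactly 2 super-groups with samples")
  for (g in unique(sg[keep]))
    if (sum(sg[keep] == g) < 2) stop("super-group ", g, " has < 2 samples")
  per <- lapply(keep, function(i) {
    same <- setdiff(which(!is.na(sg) & sg == sg[i]), i)
    other <- which(!is.na(sg) & sg != sg[i])
    data.frame(sample_id = rownames(m)[i], supergroup = sg[i],
               median_within = stats::median(m[i, same]),
               median_across = stats::median(m[i, other]),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  wt <- suppressWarnings(stats::wilcox.test(per$median_within,
                                            per$median_across))
  list(per_sample = per, wilcox_p = wt$p.value)
}
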