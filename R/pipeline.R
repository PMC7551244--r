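write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_square_tsv <- function(m, path, id_column = "sample_id") {
  df <- data.frame(rownames(m), unclass(as.matrix(m)), check.names = FALSE)
  colnames(df) <- c(id_column, colnames(m))
  write_tsv(df, path)
}

#' Write a pipeline run report to disk
#'
#' Emits every tabular stage as TSV, the machine-readable summary as JSON
#' (deterministic for a given seed: no timestamps or environment details),
#' and a plain-text log carrying timestamps, package version, seed and
#' parameters.
#'
#' @param report a report list from [run_invitro()] or [run_human()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$tables))
    write_tsv(report$tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  for (nm in names(report$matrices))
    write_square_tsv(report$matrices[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  jsonlite::write_json(report$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  log_lines <- c(sprintf("run: %s", report$summary$arm),
                 sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                 sprintf("package: cagmark %s",
                         as.character(utils::packageVersion("cagmark"))),
                 sprintf("R: %s", R.version.string),
                 sprintf("seed: %s", report$summary$seed),
                 paste0("param ", names(report$summary$params), ": ",
                        vapply(report$summary$params, function(x)
                          paste(format(x), collapse = ","), character(1))),
                 report$log)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Run the in vitro colon-model workflow
#'
#' Normalizes counts, computes alpha diversity, builds the beta-diversity
#' matrix over the pooled 16/24 h samples, tests differential taxa across
#' supplementation regimes (Kruskal-Wallis + Dunn + BH with `*`/`#`
#' flags), checks 16 h vs 24 h stability, computes the within/across
#' super-group median-distance statistic, and runs a per-time-point
#' PERMANOVA across regimes.
#'
#' @param data list with `counts` ([otu_table()]), `metadata`, `taxonomy`
#'   and optionally `tree` — e.g., the output of [simulate_invitro()] or
#'   assembled from the readers.
#' @param beta_metric `"weighted_unifrac"` (needs a tree) or
#'   `"spearman"`.
#' @param rank taxonomic rank for the differential-taxa stage.
#' @param partition regime -> super-group map; see [g1_g2_partition()].
#' @param n_perm PERMANOVA permutations.
#' @param seed integer seed for all stochastic stages.
#' @param out_dir if non-NULL, the report is also written there via
#'   [write_report()].
#' @return a report list: `tables`, `matrices`, `summary`, `log`.
#' @export
run_invitro <- function(data, beta_metric = c("weighted_unifrac", "spearman"),
                        rank = "genus", partition = g1_g2_partition(),
                        n_perm = 999, seed = 1, out_dir = NULL) {
  beta_metric <- match.arg(beta_metric)
  counts <- data$counts; meta <- data$metadata
  validate_metadata(counts, meta)
  if (beta_metric == "weighted_unifrac" && is.null(data$tree))
    stop("weighted UniFrac needs a tree; use beta_metric = \"spearman\" as a fallback")
  log <- character(0)
  rel <- relative_abundance(counts)
  zero <- attr(rel, "zero_total")
  if (length(zero)) {
    log <- c(log, paste("zero-total samples excluded:", paste(zero, collapse = ",")))
    keep <- setdiff(rownames(rel), zero)
    rel <- rel[keep, , drop = FALSE]
    counts <- counts[keep, , drop = FALSE]
    meta <- meta[meta$sample_id %in% keep, , drop = FALSE]
  }
  alpha <- alpha_diversity(counts, data$tree)
  regimes <- intersect(names(partition), unique(meta$group))
  pooled_meta <- meta[meta$timepoint %in% c("16h", "24h") &
                        meta$group %in% regimes, , drop = FALSE]
  d <- if (beta_metric == "weighted_unifrac")
    unifrac_matrix(rel[pooled_meta$sample_id, , drop = FALSE], data$tree)
  else spearman_distance_matrix(rel[pooled_meta$sample_id, , drop = FALSE])
  genus <- aggregate_taxa(rel, data$taxonomy, rank)
  pools <- pool_timepoints(meta, c("16h", "24h"), regimes)
  diff <- differential_taxa(genus, pools)
  if (length(attr(diff, "skipped_taxa")))
    log <- c(log, paste("taxa absent everywhere skipped:",
                        paste(attr(diff, "skipped_taxa"), collapse = ",")))
  stab_meta <- meta[meta$group %in% regimes, , drop = FALSE]
  stab <- timepoint_stability(genus[stab_meta$sample_id, , drop = FALSE],
                              stab_meta)
  wa <- within_across_distances(d, pooled_meta, partition)
  perm <- lapply(c("16h", "24h"), function(tp) {
    idx <- pooled_meta$sample_id[pooled_meta$timepoint == tp]
    pv <- permanova(unclass(d)[idx, idx], pooled_meta$group[match(idx, pooled_meta$sample_id)],
                    n_perm = n_perm, seed = derive_seed(seed, match(tp, c("16h", "24h"))))
    data.frame(timepoint = tp, R2 = pv$R2, F = pv$F, p = pv$p,
               n_perm = pv$n_perm, stringsAsFactors = FALSE)
  })
  perm <- do.call(rbind, perm)
  report <- list(
    tables = list(alpha_diversity = alpha,
                  differential_taxa = as.data.frame(diff),
                  timepoint_stability = stab,
                  within_across = wa$per_sample,
                  permanova = perm),
    matrices = list(beta_distance = d),
    summary = list(arm = "invitro", seed = as.integer(seed),
                   params = list(beta_metric = beta_metric, rank = rank,
                                 n_perm = as.integer(n_perm),
                                 regimes = regimes),
                   n_samples = nrow(counts), n_otus = ncol(counts),
                   within_across_p = wa$wilcox_p,
                   n_flagged_pairs = sum(diff$flag == "*"),
                   permanova = lapply(seq_len(nrow(perm)), function(i)
                     list(timepoint = perm$timepoint[i], R2 = perm$R2[i],
                          F = perm$F[i], p = perm$p[i]))),
    log = log)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Run the longitudinal human-study workflow
#'
#' Normalizes counts, computes alpha diversity per age group and time
#' point, constructs co-abundance groups (Kendall distance on mean
#' temporal trends, Ward-D2, cut at `k_cags`), tests CAG abundances
#' across time points, runs OTU- and CAG-level PERMANOVA against the
#' plasma covariates, and — when a plasma panel is present — the full
#' random-forest marker procedure (leave-one-out validation, iterated
#' importances, top-N + FDR marker selection, marker vs non-marker model
#' comparison, per-CAG Fisher enrichment, delta-change associations).
#'
#' @param data list with `counts`, `metadata`, `taxonomy`, optional
#'   `tree` — e.g., the output of [simulate_human_study()].
#' @param k_cags number of CAGs to cut.
#' @param timepoints ordered time-point labels.
#' @param rf_n_iter,rf_train_frac,rf_ntree,rf_top_n,rf_fdr random-forest
#'   marker-procedure settings.
#' @param n_perm PERMANOVA permutations.
#' @param seed integer seed for all stochastic stages.
#' @param out_dir if non-NULL, the report is also written there.
#' @return a report list: `tables`, `matrices`, `summary`, `log`, plus
#'   `objects` (assignment, marker set, rf results) for programmatic use.
#' @export
run_human <- function(data, k_cags = 6,
                      timepoints = c("W0", "W2", "W4", "W6"),
                      rf_n_iter = 100, rf_train_frac = 0.5, rf_ntree = 500,
                      rf_top_n = 150, rf_fdr = 0.1,
                      n_perm = 999, seed = 1, out_dir = NULL) {
  counts <- data$counts; meta <- data$metadata
  validate_metadata(counts, meta)
  log <- character(0)
  rel <- relative_abundance(counts)
  zero <- attr(rel, "zero_total")
  if (length(zero)) {
    log <- c(log, paste("zero-total samples excluded:", paste(zero, collapse = ",")))
    keep <- setdiff(rownames(rel), zero)
    rel <- rel[keep, , drop = FALSE]
    counts <- counts[keep, , drop = FALSE]
    meta <- meta[meta$sample_id %in% keep, , drop = FALSE]
  }
  alpha <- alpha_diversity(counts, data$tree)
  alpha$group <- meta$group[match(alpha$sample_id, meta$sample_id)]
  alpha$timepoint <- meta$timepoint[match(alpha$sample_id, meta$sample_id)]
  trend <- mean_temporal_trend(rel, meta, timepoints)
  kd <- kendall_distance_matrix(trend)
  assignment <- ward_cluster(kd, k_cags, trend = trend)
  ca <- cag_abundance(rel, assignment)
  cag_tests <- cag_timepoint_tests(ca, meta, timepoints)
  plasma_vars <- intersect(c("crp", "glucose", "frap"), colnames(meta))
  has_plasma <- length(plasma_vars) > 0 &&
    any(stats::complete.cases(meta[, plasma_vars, drop = FALSE]))
  d_otu <- spearman_distance_matrix(rel)
  d_cag <- spearman_distance_matrix(ca)
  perm_tab <- NULL
  if (has_plasma) {
    rows <- list()
    for (v in plasma_vars) {
      ok <- meta$sample_id[!is.na(meta[[v]])]
      for (lvl in c("otu", "cag")) {
        dm <- if (lvl == "otu") d_otu else d_cag
        pv <- permanova_continuous(unclass(dm)[ok, ok],
                                   meta[[v]][match(ok, meta$sample_id)],
                                   n_perm = n_perm,
                                   seed = derive_seed(seed, 10 + length(rows)))
        rows[[length(rows) + 1]] <- data.frame(
          covariate = v, level = lvl, R2 = pv$R2, p = pv$p,
          n = length(ok), stringsAsFactors = FALSE)
      }
    }
    perm_tab <- do.call(rbind, rows)
  }
  tables <- list(alpha_diversity = alpha,
                 mean_trend = data.frame(otu_id = rownames(trend), trend,
                                         check.names = FALSE),
                 cag_membership = data.frame(otu_id = names(assignment$labels),
                                             cag = unname(assignment$labels),
                                             stringsAsFactors = FALSE),
                 cag_abundance = data.frame(sample_id = rownames(ca), ca,
                                            check.names = FALSE),
                 cag_timepoint_tests = cag_tests,
                 species_frequency = species_frequency(assignment, data$taxonomy))
  if (!is.null(perm_tab)) tables$permanova_plasma <- perm_tab
  objects <- list(assignment = assignment, trend = trend)
  summary <- list(arm = "human", seed = as.integer(seed),
                  params = list(k_cags = as.integer(k_cags),
                                rf_n_iter = as.integer(rf_n_iter),
                                rf_train_frac = rf_train_frac,
                                rf_ntree = as.integer(rf_ntree),
                                rf_top_n = as.integer(rf_top_n),
                                rf_fdr = rf_fdr,
                                n_perm = as.integer(n_perm)),
                  n_samples = nrow(counts), n_otus = ncol(counts),
                  cag_sizes = as.list(table(assignment$labels)),
                  n_cag_flags = sum(cag_tests$flag == "*"))
  if (!is.null(perm_tab))
    summary$permanova_plasma <- lapply(seq_len(nrow(perm_tab)), function(i)
      list(covariate = perm_tab$covariate[i], level = perm_tab$level[i],
           R2 = perm_tab$R2[i], p = perm_tab$p[i]))
  if (has_plasma && "frap" %in% plasma_vars) {
    ok <- meta$sample_id[!is.na(meta$frap)]
    X <- unclass(rel)[ok, , drop = FALSE]
    y <- meta$frap[match(ok, meta$sample_id)]
    loo <- rf_loo_validate(X, y, seed = derive_seed(seed, 31), ntree = rf_ntree)
    iters <- rf_importance_iterations(X, y, n_iter = rf_n_iter,
                                      train_frac = rf_train_frac,
                                      seed = derive_seed(seed, 32),
                                      ntree = rf_ntree)
    markers <- select_markers(iters, X, y, top_n = rf_top_n,
                              fdr_threshold = rf_fdr)
    mk_tab <- markers$table[markers$table$class != "", , drop = FALSE]
    mk_tab$cag <- unname(assignment$labels[mk_tab$feature])
    tables$markers <- data.frame(otu = mk_tab$feature, rho = mk_tab$rho,
                                 fdr = mk_tab$fdr, class = mk_tab$class,
                                 cag = mk_tab$cag, stringsAsFactors = FALSE)
    summary$loo_rho <- loo$rho; summary$loo_p <- loo$p
    summary$iterated_rho <- iters$rho
    summary$markers_positive <- markers$positive
    summary$markers_negative <- markers$negative
    summary$knee_top_n <- markers$knee_top_n
    objects$loo <- loo; objects$iterations <- iters; objects$markers <- markers
    if (length(markers$positive) + length(markers$negative) > 0) {
      cmp <- compare_marker_models(X, y, markers, n_iter = rf_n_iter,
                                   train_frac = rf_train_frac,
                                   seed = derive_seed(seed, 33),
                                   ntree = rf_ntree)
      summary$marker_model_median_rho <- cmp$median_markers
      summary$nonmarker_model_median_rho <- cmp$median_nonmarkers
      summary$marker_model_p <- cmp$p
      objects$comparison <- cmp
      if (length(markers$positive)) {
        enr <- lapply(sort(unique(assignment$labels)), function(cg)
          data.frame(cag = cg,
                     p = cag_enrichment(markers, assignment, cg)$p,
                     odds_ratio = cag_enrichment(markers, assignment, cg)$odds_ratio,
                     stringsAsFactors = FALSE))
        tables$cag_enrichment <- do.call(rbind, enr)
        pos_ab <- rowSums(unclass(rel)[, markers$positive, drop = FALSE])
        dd <- meta
        dd$marker_abundance <- pos_ab[dd$sample_id]
        da_glu <- delta_association(dd, "frap", "glucose", timepoints)
        da_mk <- delta_association(dd, "frap", "marker_abundance", timepoints)
        tables$delta_association <- data.frame(
          pair = c("frap_vs_glucose", "frap_vs_marker_abundance"),
          rho = c(da_glu$rho, da_mk$rho), p = c(da_glu$p, da_mk$p),
          n_deltas = c(da_glu$n_deltas, da_mk$n_deltas),
          stringsAsFactors = FALSE)
        summary$delta_frap_glucose_rho <- da_glu$rho
        summary$delta_frap_glucose_p <- da_glu$p
        summary$delta_frap_marker_rho <- da_mk$rho
      }
    }
  } else {
    log <- c(log, "plasma panel absent: marker stages skipped")
  }
  report <- list(tables = tables,
                 matrices = list(spearman_otu = d_otu, spearman_cag = d_cag),
                 summary = summary, log = log, objects = objects)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}
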