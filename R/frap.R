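#' FRAP value from assay absorbances
#'
#' Ferric-reducing antioxidant power in umol/L:
#' `(sample - blank) / (standard - blank) * standard_conc`, with technical
#' replicates averaged before the ratio and the blank subtracted first.
#'
#' @param sample_abs absorbance(s) of the plasma sample (AU); replicates
#'   are averaged.
#' @param standard_abs absorbance(s) of the ferrous sulfate assay
#'   standard (AU).
#' @param blank_abs absorbance(s) of the blank (AU); default 0.
#' @param standard_conc concentration of the assay standard, default
#'   1000 umol/L.
#' @return the FRAP value in umol/L.
#' @export
frap_value <- function(sample_abs, standard_abs, blank_abs = 0,
                       standard_conc = 1000) {
  s <- mean(sample_abs); st <- mean(standard_abs); bl <- mean(blank_abs)
  denom <- st - bl
  if (denom <= 0) stop("blank-subtracted standard absorbance must be positive")
  (s - bl) / denom * standard_conc
}

## deterministic per-step seed stream derived from one user seed
## (double arithmetic: products stay exact below 2^53, result < 2^31)
derive_seed <- function(seed, step) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(step) * 104729) %% 2147483629)
}

## mtry = NULL uses the engine's regression default (floor(p/3))
rf_fit_predict <- function(X_tr, y_tr, X_te, ntree, seed, mtry = NULL) {
  set.seed(seed)
  if (is.null(mtry)) mtry <- max(floor(ncol(X_tr) / 3), 1)
  fit <- randomForest::randomForest(x = X_tr, y = y_tr, ntree = ntree,
                                    mtry = mtry, importance = FALSE)
  list(pred = as.numeric(stats::predict(fit, X_te)),
       importance = fit$importance[, "IncNodePurity"])
}

#' Leave-one-out random-forest validation of a phenotype model
#'
#' Each sample is predicted by a random-forest regressor trained on the
#' other n-1 samples; the overall Spearman correlation between predicted
#' and actual phenotype measures how much phenotype signal the feature
#' table carries.
#'
#' @param X samples x features numeric matrix (e.g., OTU relative
#'   abundances).
#' @param y numeric phenotype (e.g., FRAP, umol/L), one value per sample;
#'   must not be constant.
#' @param seed integer seed; every fold's forest is seeded from it.
#' @param ntree trees per forest.
#' @param mtry features tried per split; NULL = the engine's regression
#'   default, floor(p/3).
#' @return list with `predicted` (named vector), `rho`, `p`, `ntree`,
#'   `seed`.
#' @export
rf_loo_validate <- function(X, y, seed = 1, ntree = 500, mtry = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 5) stop("need at least 5 samples")
  if (stats::sd(y) == 0) stop("phenotype is constant")
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fp <- rf_fit_predict(X[-i, , drop = FALSE], y[-i],
                         X[i, , drop = FALSE], ntree,
                         derive_seed(seed, i), mtry)
    pred[i] <- fp$pred
  }
  names(pred) <- rownames(X)
  ct <- suppressWarnings(stats::cor.test(pred, y, method = "spearman",
                                         exact = FALSE))
  list(predicted = pred, rho = unname(ct$estimate), p = ct$p.value,
       ntree = ntree, seed = as.integer(seed))
}

#' Iterated 50/50-split random-forest importance procedure
#'
#' Runs `n_iter` seeded rounds, each training a random-forest regressor on
#' a random `train_frac` of the samples and predicting the held-out rest.
#' Reports the per-feature mean importance (IncNodePurity) across
#' iterations, and correlates each sample's mean out-of-split prediction
#' with the actual phenotype.
#'
#' @inheritParams rf_loo_validate
#' @param n_iter number of split/train/score rounds.
#' @param train_frac fraction of samples used for training each round.
#' @return list of class `rf_iterations`: `records` (per iteration: seed,
#'   train/test ids, importance, predictions, test-set Spearman rho),
#'   `mean_importance` (named vector), `mean_prediction`, `rho`, `p`,
#'   `params`.
#' @export
rf_importance_iterations <- function(X, y, n_iter = 100, train_frac = 0.5,
                                     seed = 1, ntree = 500, mtry = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 6) stop("need at least 6 samples")
  if (is.null(rownames(X))) rownames(X) <- paste0("s", seq_len(n))
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  n_train <- floor(n * train_frac)
  records <- vector("list", n_iter)
  imp_sum <- stats::setNames(numeric(ncol(X)), colnames(X))
  pred_sum <- pred_n <- stats::setNames(numeric(n), rownames(X))
  for (it in seq_len(n_iter)) {
    it_seed <- derive_seed(seed, it)
    set.seed(it_seed)
    repeat {   # degenerate splits (train or test < 2) are redrawn
      tr <- sort(sample(n, n_train))
      if (length(tr) >= 2 && n - length(tr) >= 2) break
    }
    te <- setdiff(seq_len(n), tr)
    fp <- rf_fit_predict(X[tr, , drop = FALSE], y[tr],
                         X[te, , drop = FALSE], ntree,
                         derive_seed(it_seed, 1), mtry)
    rho_it <- if (stats::sd(y[te]) == 0) NA_real_ else
      suppressWarnings(stats::cor(fp$pred, y[te], method = "spearman"))
    records[[it]] <- list(iteration = it, seed = it_seed,
                          train_ids = rownames(X)[tr],
                          test_ids = rownames(X)[te],
                          importance = fp$importance,
                          predicted = stats::setNames(fp$pred, rownames(X)[te]),
                          rho = rho_it)
    imp_sum <- imp_sum + fp$importance
    pred_sum[te] <- pred_sum[te] + fp$pred
    pred_n[te] <- pred_n[te] + 1
  }
  seen <- pred_n > 0
  mean_pred <- ifelse(seen, pred_sum / pmax(pred_n, 1), NA_real_)
  ct <- suppressWarnings(stats::cor.test(mean_pred[seen], y[seen],
                                         method = "spearman", exact = FALSE))
  structure(list(records = records,
                 mean_importance = imp_sum / n_iter,
                 mean_prediction = mean_pred,
                 rho = unname(ct$estimate), p = ct$p.value,
                 params = list(n_iter = as.integer(n_iter),
                               train_frac = train_frac,
                               ntree = ntree, seed = as.integer(seed))),
            class = "rf_iterations")
}

## knee of the sorted log-importance curve: maximal second difference
importance_knee <- function(mean_importance) {
  v <- sort(mean_importance)               # increasing, as ranked in the field
  lv <- log(pmax(v, .Machine$double.xmin))
  if (length(lv) < 3) return(length(lv))
  d2 <- diff(diff(lv))
  knee_at <- which.max(d2) + 1L            # index in increasing order
  length(lv) - knee_at + 1L                # number of features above the knee
}

#' Select phenotype-marker features from iterated importances
#'
#' Features are ranked by mean random-forest importance; the `top_n`
#' highest (default 150) are filtered by Spearman association with the
#' phenotype at BH-FDR < `fdr_threshold` (default 0.1). Survivors are
#' split into positive and negative markers by the sign of rho. A knee
#' estimate of the importance curve (maximal second difference of the
#' sorted log-importance) is reported alongside the fixed `top_n`.
#'
#' By default the BH adjustment is computed over all features jointly
#' (`fdr_scope = "all"`), the family in which the per-feature p-values
#' are exchangeable null draws; restricting the family to the
#' importance-selected top set (`fdr_scope = "top"`) makes the adjustment
#' anti-conservative, because importance ranking preferentially admits
#' features whose chance association with the phenotype is large.
#'
#' @param iterations an `rf_iterations` object (or a named mean-importance
#'   vector).
#' @param X samples x features matrix (same features as the iterations).
#' @param y numeric phenotype per sample.
#' @param top_n number of top-importance features carried into the FDR
#'   filter.
#' @param fdr_threshold BH-FDR cutoff.
#' @param fdr_scope BH family: `"all"` features (default) or the `"top"`
#'   set only.
#' @return list of class `marker_set`: `positive`, `negative` (feature
#'   ids), `table` (feature, rho, p, fdr, class for the full top set),
#'   `top_features`, `knee_top_n`, `params`.
#' @export
select_markers <- function(iterations, X, y, top_n = 150,
                           fdr_threshold = 0.1,
                           fdr_scope = c("all", "top")) {
  fdr_scope <- match.arg(fdr_scope)
  imp <- if (inherits(iterations, "rf_iterations"))
    iterations$mean_importance else iterations
  X <- as.matrix(X)
  if (is.null(names(imp)) || !all(names(imp) %in% colnames(X)))
    stop("importance names must match feature columns")
  top_n <- min(top_n, length(imp))
  ord <- order(imp, decreasing = TRUE)
  top <- names(imp)[ord[seq_len(top_n)]]
  assoc <- if (fdr_scope == "all") {
    a <- spearman_with_fdr(X, y)
    a[match(top, a$feature), , drop = FALSE]
  } else {
    spearman_with_fdr(X[, top, drop = FALSE], y)
  }
  rownames(assoc) <- NULL
  assoc$class <- ifelse(assoc$fdr < fdr_threshold,
                        ifelse(assoc$rho > 0, "positive", "negative"),
                        "")
  pos <- assoc$feature[assoc$class == "positive"]
  neg <- assoc$feature[assoc$class == "negative"]
  if (!length(pos) && !length(neg))
    message("no features survive the FDR filter; marker set is empty")
  structure(list(positive = pos, negative = neg, table = assoc,
                 top_features = top,
                 knee_top_n = importance_knee(imp),
                 params = list(top_n = as.integer(top_n),
                               fdr_threshold = fdr_threshold,
                               fdr_scope = fdr_scope)),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: %d positive, %d negative (top_n = %d, FDR < %g)\n",
              length(x$positive), length(x$negative),
              x$params$top_n, x$params$fdr_threshold))
  invisible(x)
}

#' Compare marker-only and non-marker random-forest models
#'
#' Iterated 50/50-split forests restricted to (a) the marker features and
#' (b) all remaining features, on identical splits, yielding two
#' per-iteration distributions of test-set Spearman rho that are compared
#' by a Wilcoxon rank-sum test.
#'
#' @inheritParams rf_importance_iterations
#' @param markers a `marker_set` (or character vector of marker feature
#'   ids).
#' @return list with `rho_markers`, `rho_nonmarkers` (length `n_iter`),
#'   `median_markers`, `median_nonmarkers`, `p` (rank-sum), `params`.
#' @export
compare_marker_models <- function(X, y, markers, n_iter = 100,
                                  train_frac = 0.5, seed = 1, ntree = 500,
                                  mtry = NULL) {
  X <- as.matrix(X)
  ids <- if (inherits(markers, "marker_set"))
    c(markers$positive, markers$negative) else as.character(markers)
  ids <- intersect(ids, colnames(X))
  other <- setdiff(colnames(X), ids)
  if (!length(ids)) stop("marker set is empty")
  if (!length(other)) stop("non-marker complement is empty")
  n <- nrow(X)
  n_train <- floor(n * train_frac)
  rho_m <- rho_o <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    it_seed <- derive_seed(seed, it)
    set.seed(it_seed)
    repeat {
      tr <- sort(sample(n, n_train))
      if (length(tr) >= 2 && n - length(tr) >= 2) break
    }
    te <- setdiff(seq_len(n), tr)
    pm <- rf_fit_predict(X[tr, ids, drop = FALSE], y[tr],
                         X[te, ids, drop = FALSE], ntree,
                         derive_seed(it_seed, 1), mtry)
    po <- rf_fit_predict(X[tr, other, drop = FALSE], y[tr],
                         X[te, other, drop = FALSE], ntree,
                         derive_seed(it_seed, 2), mtry)
    rho_m[it] <- suppressWarnings(stats::cor(pm$pred, y[te], method = "spearman"))
    rho_o[it] <- suppressWarnings(stats::cor(po$pred, y[te], method = "spearman"))
  }
  wt <- suppressWarnings(stats::wilcox.test(rho_m, rho_o))
  list(rho_markers = rho_m, rho_nonmarkers = rho_o,
       median_markers = stats::median(rho_m, na.rm = TRUE),
       median_nonmarkers = stats::median(rho_o, na.rm = TRUE),
       p = wt$p.value,
       params = list(n_iter = as.integer(n_iter), train_frac = train_frac,
                     ntree = ntree, seed = as.integer(seed)))
}

#' CAG enrichment of a marker set
#'
#' Fisher's exact test on the 2x2 table (marker vs non-marker OTU) x
#' (member of the target CAG(s) vs not), over all CAG-labelled OTUs.
#' Marker OTUs without a CAG label are excluded with a message.
#'
#' @param markers a `marker_set` or character vector of marker OTU ids.
#' @param assignment a `cag_assignment` (or named otu -> label vector)
#'   defining the OTU universe.
#' @param target_cags CAG label(s) forming the target set, e.g.
#'   `c("C1", "C6")`.
#' @param class which markers to test: `"positive"`, `"negative"` or
#'   `"all"` (ignored when `markers` is a plain vector).
#' @return list with `table` (the 2x2 matrix), `odds_ratio`, `p`,
#'   `target_cags`.
#' @export
cag_enrichment <- function(markers, assignment, target_cags,
                           class = c("positive", "negative", "all")) {
  class <- match.arg(class)
  labels <- if (inherits(assignment, "cag_assignment")) assignment$labels else assignment
  ids <- if (inherits(markers, "marker_set")) switch(class,
    positive = markers$positive, negative = markers$negative,
    all = c(markers$positive, markers$negative)) else as.character(markers)
  if (!length(ids)) stop("marker set is empty")
  unlabelled <- setdiff(ids, names(labels))
  if (length(unlabelled)) {
    message(length(unlabelled), " marker OTU(s) without CAG label excluded")
    ids <- setdiff(ids, unlabelled)
    if (!length(ids)) stop("no CAG-labelled markers left")
  }
  is_marker <- names(labels) %in% ids
  in_target <- labels %in% target_cags
  tab <- matrix(c(sum(is_marker & in_target), sum(is_marker & !in_target),
                  sum(!is_marker & in_target), sum(!is_marker & !in_target)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("marker", "non_marker"),
                                c("in_target", "not_in_target")))
  ft <- fisher_exact_2x2(tab)
  list(table = tab, odds_ratio = ft$odds_ratio, p = ft$p,
       target_cags = target_cags)
}

#' Association between per-subject changes of two measures
#'
#' Computes, for every subject, the change of each measure between
#' consecutive shared time points (ordered as given), then the Spearman
#' correlation over all pooled deltas — e.g., delta-FRAP vs delta-glucose.
#'
#' @param data data.frame with columns `subject_id`, `timepoint`, and the
#'   two measure columns.
#' @param var1,var2 names of the two measure columns.
#' @param timepoint_order ordered vector of time-point labels.
#' @return list with `deltas` (subject, interval, delta1, delta2), `rho`,
#'   `p`, `n_deltas`. Subjects with < 2 complete time points are excluded
#'   with a message.
#' @export
delta_association <- function(data, var1, var2,
                              timepoint_order = c("W0", "W2", "W4", "W6")) {
  need <- c("subject_id", "timepoint", var1, var2)
  miss <- setdiff(need, colnames(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  rows <- list()
  excluded <- character(0)
  for (subj in unique(data$subject_id)) {
    d <- data[data$subject_id == subj &
                !is.na(data[[var1]]) & !is.na(data[[var2]]), , drop = FALSE]
    d <- d[match(intersect(timepoint_order, d$timepoint), d$timepoint), ,
           drop = FALSE]
    if (nrow(d) < 2) { excluded <- c(excluded, as.character(subj)); next }
    for (i in seq_len(nrow(d) - 1))
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = subj,
        interval = paste0(d$timepoint[i], "->", d$timepoint[i + 1]),
        delta1 = d[[var1]][i + 1] - d[[var1]][i],
        delta2 = d[[var2]][i + 1] - d[[var2]][i],
        stringsAsFactors = FALSE)
  }
  if (length(excluded))
    message("subject(s) with < 2 time points excluded: ",
            paste(excluded, collapse = ", "))
  if (!length(rows)) stop("no subject contributes >= 2 shared time points")
  deltas <- do.call(rbind, rows)
  ct <- suppressWarnings(stats::cor.test(deltas$delta1, deltas$delta2,
                                         method = "spearman", exact = FALSE))
  list(deltas = deltas, rho = unname(ct$estimate), p = ct$p.value,
       n_deltas = nrow(deltas))
}
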