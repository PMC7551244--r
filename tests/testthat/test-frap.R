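test_that("FRAP arithmetic follows the blank-subtracted standard ratio", {
  expect_equal(frap_value(0.5, 1.0, 0), 500)
  expect_equal(frap_value(1.0, 1.0, 0), 1000)
  expect_equal(frap_value(0.6, 1.2, 0.1), 0.5 / 1.1 * 1000, tolerance = 1e-12)
  # technical replicates averaged before the ratio
  expect_equal(frap_value(c(0.58, 0.62), c(1.25, 1.15), c(0.1, 0.1)),
               0.5 / 1.1 * 1000, tolerance = 1e-12)
  expect_error(frap_value(0.5, 0.1, 0.2), "positive")
})

test_that("leave-one-out forests recover a noiseless signal and nothing from noise", {
  set.seed(24)
  n <- 30
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(paste0("s", 1:n), paste0("f", 1:5)))
  y <- 3 * X[, 1]
  loo <- rf_loo_validate(X, y, seed = 2, ntree = 200, mtry = 3)
  expect_gte(loo$rho, 0.9)
  # bit-for-bit reproducible under the same seed
  expect_identical(loo, rf_loo_validate(X, y, seed = 2, ntree = 200, mtry = 3))
  # null phenotype: only weak apparent skill
  rhos <- vapply(1:10, function(s) {
    set.seed(400 + s)
    rf_loo_validate(X, rnorm(n), seed = s, ntree = 100)$rho
  }, 0)
  expect_lt(median(abs(rhos)), 0.3)
  expect_error(rf_loo_validate(X, rep(1, n)), "constant")
})

test_that("iterated importances rank a planted feature first and serialize", {
  set.seed(25)
  n <- 40
  X <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:20)))
  y <- 2 * X[, 5] + rnorm(n, 0, 0.3)
  it <- rf_importance_iterations(X, y, n_iter = 20, seed = 3, ntree = 150)
  expect_identical(names(which.max(it$mean_importance)), "f5")
  top1 <- vapply(it$records, function(r) names(which.max(r$importance)), "")
  expect_gte(mean(top1 == "f5"), 0.95)
  expect_gt(it$rho, 0.8)
  # every record keeps train and test disjoint
  for (r in it$records)
    expect_length(intersect(r$train_ids, r$test_ids), 0)
  # records survive a JSON round trip (named vectors written as objects)
  f <- withr::local_tempfile(fileext = ".json")
  r1 <- it$records[[1]]
  out <- lapply(r1, function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x)
  jsonlite::write_json(out, f, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(unlist(back$importance), r1$importance, tolerance = 1e-12)
  expect_equal(unlist(back$predicted), r1$predicted, tolerance = 1e-12)
  expect_identical(back$test_ids, r1$test_ids)
  expect_identical(back$seed, r1$seed)
})

test_that("marker selection recovers planted features and has sane limits", {
  set.seed(26)
  n <- 60; p <- 120
  u <- rnorm(n)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:p)))
  planted <- paste0("f", 1:10)
  X[, planted] <- X[, planted] * 0.7 + u %o% c(rep(1, 7), rep(-1, 3))
  y <- 100 + 20 * u + rnorm(n, 0, 8)
  it <- rf_importance_iterations(X, y, n_iter = 25, seed = 4, ntree = 200)
  mk <- select_markers(it, X, y, top_n = 30, fdr_threshold = 0.1)
  sel <- c(mk$positive, mk$negative)
  expect_gte(mean(sel %in% planted), 0.7)
  expect_gte(mean(planted %in% sel), 0.7)
  expect_setequal(intersect(mk$positive, planted), paste0("f", 1:7))
  expect_length(intersect(mk$positive, mk$negative), 0)
  expect_true(all(sel %in% mk$top_features))

  # top_n = all features reduces to the plain Spearman screen
  mk_all <- select_markers(it, X, y, top_n = p, fdr_scope = "top")
  ref <- spearman_with_fdr(X, y)
  surviving <- sort(ref$feature[ref$fdr < 0.1])
  expect_setequal(sort(c(mk_all$positive, mk_all$negative)), surviving)
})

test_that("marker/non-marker model comparison separates planted signal", {
  set.seed(27)
  n <- 50; p <- 60
  u <- rnorm(n)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:p)))
  planted <- paste0("f", 1:8)
  X[, planted] <- X[, planted] * 0.5 + u
  y <- 10 * u + rnorm(n)
  cmp <- compare_marker_models(X, y, planted, n_iter = 40, seed = 6, ntree = 150)
  expect_gt(cmp$median_markers, cmp$median_nonmarkers)
  expect_lt(cmp$p, 0.01)
  # identical feature sets under one seed give identical distributions
  cmp2 <- compare_marker_models(X, y, planted, n_iter = 40, seed = 6, ntree = 150)
  expect_identical(cmp$rho_markers, cmp2$rho_markers)
  expect_error(compare_marker_models(X, y, character(0)), "empty")
})

test_that("CAG enrichment builds the right table and tracks concentration", {
  labels <- stats::setNames(paste0("C", rep(1:5, each = 20)), paste0("o", 1:100))
  # all 10 markers inside C1 (20 of 100 OTUs): strong enrichment
  mk_in <- paste0("o", 1:10)
  e1 <- cag_enrichment(mk_in, labels, "C1")
  expect_equal(unname(e1$table["marker", ]), c(10, 0))
  expect_equal(unname(rowSums(e1$table)), c(10, 90))
  expect_lt(e1$p, 1e-4)
  # markers spread proportionally to CAG sizes: no signal
  mk_prop <- paste0("o", seq(1, 100, by = 10))
  e2 <- cag_enrichment(mk_prop, labels, "C1")
  expect_gt(e2$p, 0.5)
  # monotone in concentration
  e_half <- cag_enrichment(paste0("o", c(1:5, 21, 41, 61, 81, 96)), labels, "C1")
  expect_lt(e1$p, e_half$p)
  expect_message(cag_enrichment(c(mk_in, "zz"), labels, "C1"), "without CAG")
})

test_that("delta associations difference consecutive shared time points", {
  df <- data.frame(
    subject_id = rep(c("A", "B"), each = 3),
    timepoint = rep(c("W0", "W2", "W6"), 2),
    frap = c(100, 150, 130, 200, 180, 240),
    glucose = c(90, 85, 88, 80, 84, 78))
  suppressMessages(da <- delta_association(df, "frap", "glucose"))
  expect_equal(da$n_deltas, 4)
  expect_equal(da$deltas$delta1, c(50, -20, -20, 60))
  expect_equal(da$deltas$delta2, c(-5, 3, 4, -6))
  expect_lt(da$rho, -0.9)    # opposed changes (a tie in delta1 keeps |rho|<1)
  # subject with one usable time point is excluded with a message
  df2 <- rbind(df, data.frame(subject_id = "C", timepoint = "W0",
                              frap = 1, glucose = 1))
  expect_message(delta_association(df2, "frap", "glucose"), "excluded: C")
  # exact negatives give rho = -1 regardless of scale
  df3 <- df; df3$glucose <- -df3$frap
  suppressMessages(da3 <- delta_association(df3, "frap", "glucose"))
  expect_equal(da3$rho, -1)
})
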