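# Cross-validation hygiene, confusion/metric arithmetic, paired testing.

test_that("48 ids reproduce the 38/5/5 x 9 + 40/5/3 fold structure", {
  ids <- sprintf("PB%02d", 1:48)
  plan <- make_folds(ids, n_folds = 10, seed = 4)
  sizes <- t(vapply(plan$folds, function(f) {
    c(train = length(f$train), val = length(f$val), test = length(f$test))
  }, integer(3)))
  expect_equal(sizes[1:9, "test"], rep(5L, 9), ignore_attr = TRUE)
  expect_equal(sizes[10, "test"], 3L, ignore_attr = TRUE)
  expect_equal(sizes[1:9, "train"], rep(38L, 9), ignore_attr = TRUE)
  expect_equal(sizes[10, "train"], 40L, ignore_attr = TRUE)
  expect_true(all(sizes[, "val"] == 5L))
  # each id tested exactly once; sets disjoint within folds
  all_test <- unlist(lapply(plan$folds, `[[`, "test"))
  expect_setequal(all_test, ids)
  expect_equal(anyDuplicated(all_test), 0L)
  for (f in plan$folds) {
    expect_equal(length(intersect(f$train, f$val)), 0L)
    expect_equal(length(intersect(f$train, f$test)), 0L)
    expect_equal(length(intersect(f$val, f$test)), 0L)
    expect_setequal(c(f$train, f$val, f$test), ids)
  }
  # determinism
  expect_identical(plan, make_folds(ids, n_folds = 10, seed = 4))
  expect_error(make_folds(ids[1:5], n_folds = 10), "cannot fill")
})

test_that("10 ids across 5 folds give test sets of size 2", {
  plan <- make_folds(letters[1:10], n_folds = 5, seed = 2)
  expect_true(all(vapply(plan$folds, function(f) length(f$test), integer(1)) == 2L))
  expect_setequal(unlist(lapply(plan$folds, `[[`, "test")), letters[1:10])
})

test_that("confusion matrices match an independent tally", {
  octaline:::with_seed(71, {
    t_lab <- sample(1:3, 1000, replace = TRUE)
    p_lab <- sample(1:3, 1000, replace = TRUE)
    cm <- confusion(t_lab, p_lab)
    ref <- unclass(table(factor(t_lab, levels = 1:3), factor(p_lab, levels = 1:3)))
    expect_equal(unname(unclass(cm)), unname(ref))
    expect_equal(sum(cm), 1000L)
    # perfect prediction: diagonal with row sums = supports
    cmp <- confusion(t_lab, t_lab)
    expect_true(all(cmp[upper.tri(cmp) | lower.tri(cmp)] == 0))
    expect_equal(diag(cmp), tabulate(t_lab, 3), ignore_attr = TRUE)
    # all predicted "other": third column only
    cmo <- confusion(t_lab, rep(3L, 1000))
    expect_true(all(cmo[, 1:2] == 0))
    # validity mask excludes positions
    v <- rep(c(TRUE, FALSE), 500)
    expect_equal(sum(confusion(t_lab, p_lab, v)), 500L)
    expect_error(confusion(c(1, 4), c(1, 1)), "3-class")
  })
})

test_that("metrics match the formula oracle", {
  cm <- matrix(c(50, 5, 10, 5, 40, 10, 5, 5, 70), 3, 3) # by column: preds
  m <- classification_metrics(cm)
  expect_equal(m$per_class$sensitivity[1], 50 / 60, tolerance = 1e-12)
  expect_equal(m$per_class$f1[1], 2 * 50 / (2 * 50 + 15 + 10), tolerance = 1e-12)
  expect_equal(m$per_class$specificity[1], (sum(cm) - 60 - 15) / (sum(cm) - 60), tolerance = 1e-12)
  expect_equal(m$per_class$accuracy, diag(cm) / rowSums(cm), tolerance = 1e-12)
  expect_equal(m$overall_accuracy, 160 / sum(cm), tolerance = 1e-12)
  # identity matrix: everything 1
  mi <- classification_metrics(diag(c(10, 20, 30)))
  expect_true(all(unlist(mi$per_class[, c("accuracy", "sensitivity", "specificity", "f1")]) == 1))
  # permutation symmetry: swapping classes permutes rows of the metric table
  perm <- c(2, 1, 3)
  mp <- classification_metrics(cm[perm, perm])
  expect_equal(mp$per_class$f1, m$per_class$f1[perm], tolerance = 1e-12)
  # zero-support class: NA, not zero
  cm0 <- cm; cm0[2, ] <- 0
  expect_true(is.na(classification_metrics(cm0)$per_class$f1[2]))
})

test_that("paired fold test matches the reference implementation to 1e-8", {
  a <- c(0.30, 0.28, 0.33, 0.29, 0.31)
  b <- c(0.25, 0.24, 0.27, 0.26, 0.25)
  got <- paired_fold_test(a, b)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(got$p, ref$p.value, tolerance = 1e-8)
  expect_equal(got$df, unname(ref$parameter))
  # identical vectors: t = 0, p = 1 (zero-variance edge case)
  expect_warning(same <- paired_fold_test(a, a), "zero variance")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # consistent small shifts are significant
  octaline:::with_seed(72, {
    d <- b + 0.04 + rnorm(5, 0, 1e-3)
    expect_lt(paired_fold_test(d, b)$p, 0.05)
  })
  expect_error(paired_fold_test(1, 1:2), "equal-length")
})

test_that("cross-validation produces a structured, deterministic report", {
  dataset <- small_sim_dataset()
  cfg <- net_config("ann", max_epochs = 4, batch_size = 128, seed = 3)
  res <- run_crossval(dataset, list(ann = cfg), n_folds = 2, seed = 5,
                      max_train = 1500, max_val = 400)
  expect_s3_class(res, "fold_results")
  r <- res$arch$ann
  for (f in 1:2) {
    expect_equal(dim(r$cm_pre[[f]]), c(3L, 3L))
    expect_equal(dim(r$cm_post[[f]]), c(3L, 3L))
  }
  # conservation: all test A-lines tallied exactly once across folds
  n_labeled <- sum(vapply(dataset, function(d) {
    sum(d$processed$index$label %in% octaline:::PLAQUE_CLASSES)
  }, numeric(1)))
  expect_equal(sum(r$pooled_pre), n_labeled)
  expect_equal(sum(r$pooled_post), n_labeled)
  # aggregates recomputable from the per-fold values
  expect_equal(r$mean_acc_pre, mean(r$acc_pre), tolerance = 1e-12)
  expect_equal(r$se_acc_pre, sd(r$acc_pre) / sqrt(2), tolerance = 1e-12)
  # determinism of the full report
  res2 <- run_crossval(dataset, list(ann = cfg), n_folds = 2, seed = 5,
                       max_train = 1500, max_val = 400)
  expect_identical(res$arch, res2$arch)
})

test_that("two architectures yield a paired comparison", {
  dataset <- small_sim_dataset()
  cfgs <- list(cnn = net_config("cnn", max_epochs = 2, batch_size = 128, seed = 3),
               ann = net_config("ann", max_epochs = 2, batch_size = 128, seed = 3))
  res <- run_crossval(dataset, cfgs, n_folds = 2, seed = 6,
                      max_train = 800, max_val = 300)
  expect_named(res$arch, c("cnn", "ann"))
  expect_true(is.numeric(res$paired_test$t))
  expect_true(res$paired_test$p >= 0 && res$paired_test$p <= 1)
})
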