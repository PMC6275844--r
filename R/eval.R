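# Pullback-held-out cross-validation, confusion matrices, class-wise
# metrics, and the cross-fold paired comparison of two learning systems.

#' Pullback-held-out fold plan
#'
#' Partitions pullback ids into `n_folds` test sets so each id is tested
#' exactly once. Test sets take `round(n / n_folds)` ids for the first
#' `n_folds - 1` folds and the remainder for the last; with 48 ids and 10
#' folds this reproduces the reference 9 x (38 train / 5 val / 5 test)
#' plus one (40 / 5 / 3) split. Validation sets take `max(1, round(n /
#' 10))` ids from the non-test remainder; training takes the rest.
#'
#' @param ids character or integer vector of pullback ids.
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed for the shuffle.
#' @return a `fold_plan`: list of folds, each with `train`, `val`, `test`.
#' @export
make_folds <- function(ids, n_folds = 10L, seed = 1L) {
  ids <- unique(ids)
  n <- length(ids)
  if (n < n_folds) stopf("make_folds: %d ids cannot fill %d folds", n, n_folds)
  with_seed(seed, {
    shuffled <- sample(ids)
    per <- if (n_folds == 1L) n else
      max(1L, min(round(n / n_folds), (n - 1L) %/% (n_folds - 1L)))
    folds <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      lo <- (f - 1L) * per + 1L
      hi <- if (f == n_folds) n else f * per
      test <- shuffled[lo:hi]
      rest <- setdiff(shuffled, test)
      m <- length(rest)
      n_val <- min(m - 1L, max(1L, round(n / 10)))
      # rotate the remainder so validation sets differ across folds
      rest <- rest[wrap_idx(seq_len(m) + (f - 1L) * n_val, m)]
      val <- rest[seq_len(n_val)]
      train <- rest[(n_val + 1L):m]
      folds[[f]] <- list(train = train, val = val, test = test)
    }
    structure(list(folds = folds, seed = seed, n_folds = n_folds), class = "fold_plan")
  })
}

#' 3 x 3 confusion matrix over valid A-lines
#'
#' Rows are true classes, columns predicted, in the order (fibrocalcific,
#' fibrolipidic, other).
#'
#' @param truth,predicted integer vectors (1..3), factors, or class-name
#'   character vectors of equal length.
#' @param valid optional logical mask; only TRUE positions are tallied.
#' @return integer 3 x 3 matrix with dimnames.
#' @export
confusion <- function(truth, predicted, valid = NULL) {
  t_i <- as.integer(factor_labels(truth))
  p_i <- as.integer(factor_labels(predicted))
  if (length(t_i) != length(p_i)) stopf("confusion: length mismatch")
  if (!is.null(valid)) {
    t_i <- t_i[valid]; p_i <- p_i[valid]
  }
  if (any(is.na(t_i)) || any(is.na(p_i)) || any(t_i > 3L) || any(p_i > 3L)) {
    stopf("confusion: labels outside the 3-class set on valid positions")
  }
  cm <- matrix(0L, 3L, 3L, dimnames = list(true = PLAQUE_CLASSES, predicted = PLAQUE_CLASSES))
  for (k in seq_along(t_i)) cm[t_i[k], p_i[k]] <- cm[t_i[k], p_i[k]] + 1L
  cm
}

#' Class-wise and overall metrics from a confusion matrix
#'
#' Per class (one-vs-rest): sensitivity `TP / (TP + FN)`, specificity
#' `TN / (TN + FP)`, F1 `2 TP / (2 TP + FP + FN)`, and class-wise accuracy
#' (the row-normalised diagonal, i.e. recall). Zero-support classes yield
#' `NA` rather than 0.
#'
#' @param cm 3 x 3 confusion matrix (rows true, columns predicted).
#' @return list with `per_class` data.frame (class, support, accuracy,
#'   sensitivity, specificity, f1) and `overall_accuracy`.
#' @export
classification_metrics <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  per <- lapply(1:3, function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    support <- tp + fn
    if (support == 0L) {
      return(data.frame(class = PLAQUE_CLASSES[k], support = 0L, accuracy = NA_real_,
                        sensitivity = NA_real_, specificity = tn / (tn + fp),
                        f1 = NA_real_))
    }
    data.frame(class = PLAQUE_CLASSES[k], support = support,
               accuracy = tp / support,
               sensitivity = tp / (tp + fn),
               specificity = tn / (tn + fp),
               f1 = 2 * tp / (2 * tp + fp + fn))
  })
  list(per_class = do.call(rbind, per), overall_accuracy = sum(diag(cm)) / total)
}

#' Paired two-tailed t-test across folds
#'
#' Classical paired t on the per-fold differences, with the two-tailed p
#' from the t distribution on `n - 1` degrees of freedom. Zero variance of
#' the differences is reported as the exact edge case (p = 1 when the mean
#' difference is also 0, else p = 0) with a warning.
#'
#' @param errors_a,errors_b equal-length (>= 2) vectors of per-fold error
#'   rates for the two systems.
#' @return list with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_fold_test <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b) || length(errors_a) < 2L) {
    stopf("paired_fold_test: need equal-length paired vectors of length >= 2")
  }
  d <- errors_a - errors_b
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    warnf("paired_fold_test: zero variance of differences")
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                p = if (mean(d) == 0) 1 else 0, df = n - 1L, mean_diff = mean(d)))
  }
  tstat <- mean(d) / (sd_d / sqrt(n))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = n - 1L),
       df = n - 1L, mean_diff = mean(d))
}

#' Pullback-held-out cross-validation on a labeled dataset
#'
#' For each fold: trains each configured network on the training pullbacks
#' (early stopping on the validation pullbacks), predicts the test
#' pullbacks, assembles per-pullback en-face probability maps, cleans them
#' with the CRF and area opening, and tallies confusion matrices before and
#' after cleaning. Train/val/test pullback sets are asserted disjoint.
#'
#' @param dataset list of per-pullback entries, each a list with
#'   `pullback_id`, `processed` (an `oct_processed` whose index carries
#'   labels), `n_alines`, and `guidewire` (logical matrix).
#' @param net_configs named list of [net_config()]s (e.g. `list(cnn = ...,
#'   ann = ...)`); each is trained per fold.
#' @param crf a [crf_params()].
#' @param n_folds,seed passed to [make_folds()].
#' @param max_train,max_val optional caps on the number of training /
#'   validation A-lines per fold (seeded subsample), to bound run time.
#' @return a `fold_results` list: `plan`, and per architecture: per-fold
#'   confusion matrices pre/post cleaning, pooled matrices, per-fold
#'   overall accuracies and error rates, aggregate mean and standard
#'   error; plus `paired_test` comparing the first two architectures on
#'   per-fold pre-cleaning error rates when two are given.
#' @export
run_crossval <- function(dataset, net_configs, crf = crf_params(),
                         n_folds = 10L, seed = 1L,
                         max_train = Inf, max_val = Inf) {
  ids <- vapply(dataset, `[[`, character(1), "pullback_id")
  names(dataset) <- ids
  plan <- make_folds(ids, n_folds = n_folds, seed = seed)
  if (is.null(names(net_configs))) names(net_configs) <- vapply(net_configs, `[[`, character(1), "arch")
  arch_res <- lapply(net_configs, function(cfg) {
    list(cm_pre = vector("list", n_folds), cm_post = vector("list", n_folds),
         acc_pre = numeric(n_folds), acc_post = numeric(n_folds))
  })

  gather <- function(pids) {
    x <- do.call(rbind, lapply(pids, function(p) dataset[[p]]$processed$values))
    idx <- do.call(rbind, lapply(pids, function(p) dataset[[p]]$processed$index))
    y <- factor_labels(idx$label)
    keep <- !is.na(y) & y %in% PLAQUE_CLASSES
    list(x = x[keep, , drop = FALSE], y = y[keep], index = idx[keep, , drop = FALSE],
         pullback_id = idx$pullback_id[keep])
  }
  for (f in seq_len(plan$n_folds)) {
    fold <- plan$folds[[f]]
    stopifnot(length(intersect(fold$train, fold$val)) == 0L,
              length(intersect(fold$train, fold$test)) == 0L,
              length(intersect(fold$val, fold$test)) == 0L)
    tr <- gather(fold$train); va <- gather(fold$val); te <- gather(fold$test)
    if (nlevels(droplevels(tr$y)) < 3L) {
      stopf("run_crossval: fold %d training set is missing a class", f)
    }
    tr <- subsample_set(tr, max_train, derive_seed(seed, 100L + f))
    va <- subsample_set(va, max_val, derive_seed(seed, 200L + f))
    for (an in names(net_configs)) {
      oct_log("fold %d/%d: training %s on %d A-lines", f, plan$n_folds, an, nrow(tr$x))
      model <- build_model(net_configs[[an]])
      trained <- train_model(model, tr, va)
      probs <- predict(trained, te$x)
      pred_pre <- max.col(probs, ties.method = "first")
      arch_res[[an]]$cm_pre[[f]] <- confusion(te$y, PLAQUE_CLASSES[pred_pre])
      # per-pullback en-face cleaning
      pred_post <- integer(length(pred_pre))
      for (p in fold$test) {
        rows <- which(te$index$pullback_id == p)
        ef <- build_enface(probs[rows, , drop = FALSE], te$index$aline[rows],
                           te$index$frame[rows], dataset[[p]]$n_alines)
        mf <- mean_field_infer(ef, crf)
        lab <- area_open_cleanup(mf$labels)
        pred_post[rows] <- lab[cbind(te$index$aline[rows] + 1L,
                                     te$index$frame[rows] - ef$frame0 + 1L)]
      }
      arch_res[[an]]$cm_post[[f]] <- confusion(te$y, PLAQUE_CLASSES[pred_post])
      arch_res[[an]]$acc_pre[f] <- sum(diag(arch_res[[an]]$cm_pre[[f]])) / sum(arch_res[[an]]$cm_pre[[f]])
      arch_res[[an]]$acc_post[f] <- sum(diag(arch_res[[an]]$cm_post[[f]])) / sum(arch_res[[an]]$cm_post[[f]])
    }
  }
  for (an in names(net_configs)) {
    r <- arch_res[[an]]
    arch_res[[an]]$pooled_pre <- Reduce(`+`, r$cm_pre)
    arch_res[[an]]$pooled_post <- Reduce(`+`, r$cm_post)
    arch_res[[an]]$mean_acc_pre <- mean(r$acc_pre)
    arch_res[[an]]$se_acc_pre <- stats::sd(r$acc_pre) / sqrt(plan$n_folds)
    arch_res[[an]]$mean_acc_post <- mean(r$acc_post)
    arch_res[[an]]$se_acc_post <- stats::sd(r$acc_post) / sqrt(plan$n_folds)
  }
  out <- list(plan = plan, arch = arch_res)
  if (length(net_configs) >= 2L) {
    a <- names(net_configs)[1L]; b <- names(net_configs)[2L]
    out$paired_test <- paired_fold_test(1 - arch_res[[a]]$acc_pre, 1 - arch_res[[b]]$acc_pre)
  }
  structure(out, class = "fold_results")
}

subsample_set <- function(set, cap, seed) {
  n <- nrow(set$x)
  if (n <= cap) return(set)
  with_seed(seed, {
    rows <- sort(sample.int(n, cap))
    list(x = set$x[rows, , drop = FALSE], y = set$y[rows],
         index = if (is.null(set$index)) NULL else set$index[rows, , drop = FALSE],
         pullback_id = set$pullback_id[rows])
  })
}

#' @export
print.fold_results <- function(x, ...) {
  cat(sprintf("<fold_results: %d folds>\n", x$plan$n_folds))
  for (an in names(x$arch)) {
    r <- x$arch[[an]]
    cat(sprintf("  %s: accuracy pre %.4f +- %.4f, post %.4f +- %.4f\n",
                an, r$mean_acc_pre, r$se_acc_pre, r$mean_acc_post, r$se_acc_post))
  }
  if (!is.null(x$paired_test)) {
    cat(sprintf("  paired t-test (pre-cleaning error rates): t = %.4f, p = %.3g\n",
                x$paired_test$t, x$paired_test$p))
  }
  invisible(x)
}
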