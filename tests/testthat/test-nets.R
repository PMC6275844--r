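# Networks: architecture arithmetic, loss and weight operations, training
# protocol, and classifier behaviour.

test_that("CNN layer lengths follow the padding arithmetic", {
  m <- build_cnn(net_config("cnn"))
  expect_identical(m$shape,
                   list(pad = 210L, conv1 = 200L, pool1 = 100L, conv2 = 92L,
                        pool2 = 46L, flatten = 2944L))
  # conv1 output equals the input length: the stated purpose of padding
  expect_equal(m$shape$conv1, 200L)
  # inconsistent pooling arithmetic is rejected
  expect_error(build_cnn(net_config("cnn", conv1_len = 12)), "divisible")
})

test_that("replicate padding copies the edge samples", {
  X <- array(rep(c(3, 1, 4, 1, 5), each = 1), c(1, 5, 1))
  P <- octaline:::pad_replicate_fwd(X, 2L)
  expect_equal(as.numeric(P[1, , 1]), c(3, 3, 3, 1, 4, 1, 5, 5, 5))
  C <- array(7, c(2, 6, 1))
  expect_true(all(octaline:::pad_replicate_fwd(C, 5L) == 7))
})

test_that("ANN parameter count and degenerate outputs are exact", {
  m <- build_ann(net_config("ann"))
  expect_equal(n_params(m), 200 * 100 + 100 + 100 * 50 + 50 + 50 * 3 + 3) # 25303
  # zero weights -> uniform softmax for any input
  for (i in seq_along(m$layers)) {
    if (!is.null(m$layers[[i]]$W)) {
      m$layers[[i]]$W[] <- 0
      m$layers[[i]]$b[] <- 0
    }
  }
  P <- octaline:::softmax_rows(octaline:::model_forward(m, matrix(rnorm(400), 2))$logits)
  expect_equal(P, matrix(1 / 3, 2, 3), tolerance = 1e-12)
})

test_that("softmax outputs are normalised probabilities", {
  octaline:::with_seed(61, {
    for (m in list(build_cnn(tiny_cnn_cfg(seed = 2)), build_ann(net_config("ann", input_len = 24, seed = 2)))) {
      X <- matrix(rnorm(7 * 24, sd = 3), 7)
      P <- octaline:::softmax_rows(octaline:::model_forward(m, X)$logits)
      expect_equal(rowSums(P), rep(1, 7), tolerance = 1e-6)
      expect_true(all(P >= 0 & P <= 1))
    }
  })
})

test_that("standardization modes behave as specified", {
  octaline:::with_seed(62, {
    X <- matrix(rnorm(30 * 20, mean = 5, sd = 2), 30)
    # none: identity
    expect_identical(standardize(X, mode = "none")$train, X)
    # samplewise: each row mean 0, sd 1
    sw <- standardize(matrix(1:200, 1), mode = "samplewise")$train
    expect_equal(mean(sw), 0, tolerance = 1e-12)
    expect_equal(sd(sw), 1, tolerance = 1e-12)
    # featurewise: training statistics applied unchanged to other sets
    Xc <- X; Xc[, 3] <- 4 # constant feature: std floor -> maps to 0
    Y <- matrix(rnorm(10 * 20, mean = 5), 10); Y[, 3] <- 4
    fw <- standardize(Xc, list(val = Y), mode = "featurewise")
    expect_equal(fw$train[, 3], rep(0, 30))
    expect_equal(fw$apply_sets$val[, 3], rep(0, 10))
    # oracle: direct recomputation
    mu <- colMeans(Xc); sdv <- apply(Xc, 2, sd); sdv[sdv == 0] <- 1
    expect_equal(fw$apply_sets$val, sweep(sweep(Y, 2, mu), 2, sdv, "/"), tolerance = 1e-12)
    expect_error(standardize(X[0, , drop = FALSE], mode = "featurewise"), "empty")
  })
})

test_that("class weights reproduce the inverse-proportion convention", {
  expect_equal(class_weights(c(100, 100, 400)), c(4, 4, 1))
  expect_equal(class_weights(c(5, 5, 5)), c(1, 1, 1))
  expect_equal(class_weights(c(0.25, 0.25, 0.5) * 1000), c(2, 2, 1))
  expect_error(class_weights(c(fibrocalcific = 0, fibrolipidic = 5, other = 5)),
               "fibrocalcific")
})

test_that("weighted cross-entropy matches hand oracles", {
  expect_equal(weighted_cross_entropy(matrix(c(1, 0, 0), 1), matrix(c(1, 0, 0), 1)), 0)
  expect_equal(weighted_cross_entropy(matrix(c(1, 0, 0), 1), matrix(c(0.5, 0.25, 0.25), 1)),
               -log(0.5), tolerance = 1e-10)
  # linear in the true class's weight
  l1 <- weighted_cross_entropy(matrix(c(1, 0, 0), 1), matrix(c(0.3, 0.4, 0.3), 1), c(1, 1, 1))
  l2 <- weighted_cross_entropy(matrix(c(1, 0, 0), 1), matrix(c(0.3, 0.4, 0.3), 1), c(2, 1, 1))
  expect_equal(l2, 2 * l1, tolerance = 1e-10)
  # batch loss is the mean over examples
  Y <- rbind(c(1, 0, 0), c(0, 1, 0))
  P <- rbind(c(0.5, 0.3, 0.2), c(0.1, 0.6, 0.3))
  w <- c(4, 4, 1)
  expect_equal(weighted_cross_entropy(Y, P, w),
               mean(c(4 * -log(0.5), 4 * -log(0.6))), tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences (1e-5)", {
  octaline:::with_seed(63, {
    for (cfg in list(tiny_cnn_cfg(seed = 3),
                     net_config("ann", input_len = 24, hidden1 = 7, hidden2 = 5, seed = 3))) {
      m <- build_model(cfg)
      X <- matrix(rnorm(4 * 24), 4)
      y <- c(1L, 2L, 3L, 2L)
      w <- c(2, 1.5, 1)
      loss_at <- function(model) {
        P <- octaline:::softmax_rows(octaline:::model_forward(model, X)$logits)
        weighted_cross_entropy(octaline:::onehot(y, 3), P, w)
      }
      fwd <- octaline:::model_forward(m, X, keep_cache = TRUE)
      P <- octaline:::softmax_rows(fwd$logits)
      bwd <- octaline:::model_backward(m, fwd, octaline:::ce_softmax_grad(P, octaline:::onehot(y, 3), w))
      for (li in seq_along(m$layers)) {
        if (is.null(m$layers[[li]]$W)) next
        for (nm in c("W", "b")) {
          g <- if (nm == "W") bwd$grads[[li]]$dW else bwd$grads[[li]]$db
          arr <- m$layers[[li]][[nm]]
          for (j in sample(length(arr), min(6, length(arr)))) {
            eps <- 1e-6
            mp <- m; mp$layers[[li]][[nm]][j] <- arr[j] + eps
            mm <- m; mm$layers[[li]][[nm]][j] <- arr[j] - eps
            expect_equal(g[j], (loss_at(mp) - loss_at(mm)) / (2 * eps), tolerance = 1e-5)
          }
        }
      }
    }
  })
})

test_that("the early-stopping rule matches the hand-traced example", {
  tr <- early_stopping_trace(c(1.0, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9))
  expect_equal(tr$stop_epoch, 7L)
  expect_equal(tr$best_epoch, 2L)
  # monotonically improving: never stops early
  tr2 <- early_stopping_trace(exp(-(1:100) / 10))
  expect_equal(tr2$stop_epoch, 100L)
  expect_equal(tr2$best_epoch, 100L)
  # improvement below the relative threshold counts as stalling (the first
  # epoch always improves on the initial Inf)
  tr3 <- early_stopping_trace(1 - (1:20) * 1e-6)
  expect_equal(tr3$stop_epoch, 6L)
})

test_that("training is deterministic and enforces pullback disjointness", {
  tr <- make_aline_set(40, seed = 640)
  va <- make_aline_set(10, seed = 641)
  cfg <- tiny_cnn_cfg(max_epochs = 2, batch_size = 32, seed = 5)
  tr24 <- list(x = tr$x[, 1:24], y = tr$y)
  va24 <- list(x = va$x[, 1:24], y = va$y)
  m1 <- train_model(build_cnn(cfg), tr24, va24)
  m2 <- train_model(build_cnn(cfg), tr24, va24)
  expect_identical(m1$layers, m2$layers)
  expect_identical(m1$history, m2$history)
  expect_error(
    train_model(build_cnn(cfg),
                c(tr24, list(pullback_id = rep("A", nrow(tr$x)))),
                c(va24, list(pullback_id = rep("A", nrow(va$x))))),
    "share pullback")
})

test_that("prediction is batch-consistent and rejects bad lengths", {
  tr <- make_aline_set(40, seed = 650)
  va <- make_aline_set(10, seed = 651)
  cfg <- tiny_cnn_cfg(max_epochs = 1, batch_size = 32, seed = 5)
  m <- train_model(build_cnn(cfg), list(x = tr$x[, 1:24], y = tr$y),
                   list(x = va$x[, 1:24], y = va$y))
  X <- va$x[1:9, 1:24]
  pb <- predict(m, X)
  p1 <- t(vapply(1:9, function(i) predict(m, X[i, ])[1, ], numeric(3)))
  expect_equal(pb, p1, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rowSums(pb), rep(1, 9), tolerance = 1e-6)
  expect_error(predict(m, matrix(0, 2, 200)), "length")
})

test_that("trained CNN tolerates border translation (spatial invariance)", {
  m <- trained_probe_cnn()
  octaline:::with_seed(66, {
    n <- 150
    base <- make_aline_set(0, seed = 1)$x # unused; keep RNG stream simple
    changed <- 0L
    k <- octaline:::gaussian_kernel_1d(7, 1)
    smooth1d <- function(v) {
      pad <- c(rep(v[1], 3), v, rep(v[200], 3))
      as.numeric(stats::filter(pad, k, sides = 2))[4:203]
    }
    for (i in 1:n) {
      cap <- round(runif(1, 25, 45))
      shift <- sample(c(-10, 10), 1)
      mk <- function(cp) {
        prof <- generate_aline_profile("fibrocalcific", 240, cap_px = cp, calcium_px = 90)[1:200]
        smooth1d(log1p(apply_speckle(prof, 2)))
      }
      p0 <- predict(m, mk(cap))
      p1 <- predict(m, mk(cap + shift))
      changed <- changed + (which.max(p0) != which.max(p1))
    }
    expect_lte(changed / n, 0.10)
  })
})

test_that("class weighting prevents collapse on a 10:10:80 imbalanced set", {
  octaline:::with_seed(67, {
    idx_for <- function(set, counts) {
      rows <- c(sample(which(set$y == "fibrocalcific"), counts[1]),
                sample(which(set$y == "fibrolipidic"), counts[2]),
                sample(which(set$y == "other"), counts[3]))
      list(x = set$x[rows, ], y = set$y[rows])
    }
    pool <- make_aline_set(900, seed = 670)
    tr <- idx_for(pool, c(100, 100, 800))
    vpool <- make_aline_set(120, seed = 671)
    va <- idx_for(vpool, c(15, 15, 120))
    cfg <- net_config("ann", max_epochs = 25, batch_size = 128, seed = 6)
    m <- train_model(build_ann(cfg), tr, va) # weights on by default
    te <- make_aline_set(100, seed = 672)
    pred <- octaline:::PLAQUE_CLASSES[max.col(predict(m, te$x), ties.method = "first")]
    recall <- vapply(levels(te$y), function(cl) mean(pred[te$y == cl] == cl), numeric(1))
    expect_lt(max(recall) - min(recall), 0.15)
  })
})
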