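# A-line classifier networks: a small 1-D CNN and a fully connected
# baseline (ANN), trained with class-weighted categorical cross-entropy,
# Adam, and validation-loss early stopping.

#' Network configuration
#'
#' The CNN default reproduces the reference 7-layer architecture: replicate
#' padding of 5 px, conv(32 filters, length 11, valid), max-pool(2, 2),
#' conv(64 filters, length 9, valid), max-pool(2, 2), dense 100 (ReLU),
#' dense 3 (softmax); along r the lengths run
#' 200 -> 210 -> 200 -> 100 -> 92 -> 46 -> flatten 2944 -> 100 -> 3.
#' The ANN is 200 -> 100 (ReLU) -> 50 (ReLU) -> 3 (softmax).
#'
#' @param arch `"cnn"` or `"ann"`.
#' @param input_len A-line length (default 200).
#' @param pad replicate padding per edge before the first convolution.
#' @param conv1_filters,conv1_len,conv2_filters,conv2_len convolution sizes.
#' @param pool pooling size and stride.
#' @param fc_units CNN dense-layer width.
#' @param hidden1,hidden2 ANN hidden widths.
#' @param n_classes output classes (3).
#' @param standardization `"none"`, `"samplewise"` or `"featurewise"`.
#' @param lr Adam learning rate (default 1e-4).
#' @param max_epochs epoch cap (default 100).
#' @param patience early-stopping patience in epochs (default 5).
#' @param min_rel_improvement minimum relative validation-loss improvement
#'   that resets the patience counter (default 1e-4, i.e. 0.01%).
#' @param batch_size minibatch size (default 256).
#' @param seed RNG seed for initialisation and shuffling.
#' @return a `net_config` list.
#' @export
net_config <- function(arch = c("cnn", "ann"),
                       input_len = 200L, pad = 5L,
                       conv1_filters = 32L, conv1_len = 11L,
                       pool = 2L,
                       conv2_filters = 64L, conv2_len = 9L,
                       fc_units = 100L,
                       hidden1 = 100L, hidden2 = 50L,
                       n_classes = 3L,
                       standardization = c("none", "samplewise", "featurewise"),
                       lr = 1e-4, max_epochs = 100L, patience = 5L,
                       min_rel_improvement = 1e-4,
                       batch_size = 256L, seed = 1L) {
  arch <- match.arg(arch)
  standardization <- match.arg(standardization)
  cfg <- as.list(environment())
  for (f in c("input_len", "pad", "conv1_filters", "conv1_len", "pool",
              "conv2_filters", "conv2_len", "fc_units", "hidden1", "hidden2",
              "n_classes", "max_epochs", "batch_size")) {
    if (!is_count(cfg[[f]], min = if (f == "pad") 0L else 1L)) {
      stopf("net_config: '%s' must be a count", f)
    }
  }
  if (cfg$lr <= 0) stopf("net_config: lr must be > 0")
  if (!is_count(cfg$patience)) stopf("net_config: patience must be >= 1")
  class(cfg) <- "net_config"
  cfg
}

# Layer lengths along r implied by a CNN config; errors if the pooling
# arithmetic does not divide evenly.
cnn_shape <- function(cfg) {
  l_pad <- cfg$input_len + 2L * cfg$pad
  l_c1 <- l_pad - cfg$conv1_len + 1L
  if (l_c1 < 1L) stopf("build_cnn: conv1 length exceeds padded input")
  if (l_c1 %% cfg$pool != 0L) stopf("build_cnn: conv1 output %d not divisible by pool %d", l_c1, cfg$pool)
  l_p1 <- l_c1 %/% cfg$pool
  l_c2 <- l_p1 - cfg$conv2_len + 1L
  if (l_c2 < 1L) stopf("build_cnn: conv2 length exceeds its input")
  if (l_c2 %% cfg$pool != 0L) stopf("build_cnn: conv2 output %d not divisible by pool %d", l_c2, cfg$pool)
  l_p2 <- l_c2 %/% cfg$pool
  list(pad = l_pad, conv1 = l_c1, pool1 = l_p1, conv2 = l_c2, pool2 = l_p2,
       flatten = l_p2 * cfg$conv2_filters)
}

#' Build the untrained 1-D CNN
#' @param config a [net_config()] with `arch = "cnn"`.
#' @return an `oct_model`.
#' @export
build_cnn <- function(config = net_config("cnn")) {
  if (config$arch != "cnn") stopf("build_cnn: config$arch must be 'cnn'")
  shp <- cnn_shape(config)
  with_seed(config$seed, {
    layers <- list(
      list(type = "pad", pad = config$pad),
      list(type = "conv",
           W = glorot_uniform(config$conv1_len, config$conv1_len * config$conv1_filters,
                              c(config$conv1_len, 1L, config$conv1_filters)),
           b = numeric(config$conv1_filters)),
      list(type = "relu"),
      list(type = "pool"),
      list(type = "conv",
           W = glorot_uniform(config$conv2_len * config$conv1_filters,
                              config$conv2_len * config$conv2_filters,
                              c(config$conv2_len, config$conv1_filters, config$conv2_filters)),
           b = numeric(config$conv2_filters)),
      list(type = "relu"),
      list(type = "pool"),
      list(type = "flatten"),
      list(type = "dense",
           W = glorot_uniform(shp$flatten, config$fc_units, c(shp$flatten, config$fc_units)),
           b = numeric(config$fc_units)),
      list(type = "relu"),
      list(type = "dense",
           W = glorot_uniform(config$fc_units, config$n_classes,
                              c(config$fc_units, config$n_classes)),
           b = numeric(config$n_classes))
    )
    structure(list(config = config, layers = layers, shape = shp), class = "oct_model")
  })
}

#' Build the untrained fully connected baseline (ANN)
#' @param config a [net_config()] with `arch = "ann"`.
#' @return an `oct_model`.
#' @export
build_ann <- function(config = net_config("ann")) {
  if (config$arch != "ann") stopf("build_ann: config$arch must be 'ann'")
  with_seed(config$seed, {
    layers <- list(
      list(type = "flatten"),
      list(type = "dense",
           W = glorot_uniform(config$input_len, config$hidden1,
                              c(config$input_len, config$hidden1)),
           b = numeric(config$hidden1)),
      list(type = "relu"),
      list(type = "dense",
           W = glorot_uniform(config$hidden1, config$hidden2,
                              c(config$hidden1, config$hidden2)),
           b = numeric(config$hidden2)),
      list(type = "relu"),
      list(type = "dense",
           W = glorot_uniform(config$hidden2, config$n_classes,
                              c(config$hidden2, config$n_classes)),
           b = numeric(config$n_classes))
    )
    structure(list(config = config, layers = layers, shape = NULL), class = "oct_model")
  })
}

#' Build a model from its configuration
#' @param config a [net_config()].
#' @return an `oct_model`.
#' @export
build_model <- function(config) {
  switch(config$arch, cnn = build_cnn(config), ann = build_ann(config))
}

#' Number of trainable parameters
#' @param model an `oct_model` or `oct_trained_model`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$layers, function(l) {
    length(l$W %||% numeric(0)) + length(l$b %||% numeric(0))
  }, numeric(1)))
}

# Forward pass through the layer stack. X: (n, input_len) matrix. Returns
# logits plus, when keep_cache, per-layer inputs/caches for the backward
# pass.
model_forward <- function(model, X, keep_cache = FALSE) {
  n <- nrow(X)
  A <- X
  if (model$config$arch == "cnn") dim(A) <- c(n, ncol(X), 1L)
  caches <- if (keep_cache) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    cache <- list(in_dim = dim(A))
    A <- switch(l$type,
      pad = pad_replicate_fwd(A, l$pad),
      conv = {
        out <- conv1d_fwd(A, l$W, l$b)
        cache$P <- out$P
        out$Y
      },
      relu = {
        out <- relu_fwd(A)
        cache$pos <- out$pos
        out$Y
      },
      pool = {
        out <- maxpool2_fwd(A)
        cache$first <- out$first
        out$Y
      },
      flatten = {
        if (is.matrix(A)) A else { dim(A) <- c(dim(A)[1], prod(dim(A)[-1])); A }
      },
      dense = {
        cache$X <- A
        dense_fwd(A, l$W, l$b)
      },
      stopf("unknown layer type '%s'", l$type)
    )
    if (keep_cache) caches[[i]] <- cache
  }
  list(logits = A, caches = caches)
}

# Backward pass from a gradient at the logits. Returns per-layer parameter
# gradients (same list structure as the layers) and the input gradient.
# guided = TRUE applies the guided-backpropagation ReLU rule.
model_backward <- function(model, fwd, dLogits, guided = FALSE) {
  grads <- vector("list", length(model$layers))
  dA <- dLogits
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    cache <- fwd$caches[[i]]
    if (l$type == "pad") {
      dA <- pad_replicate_bwd(dA, l$pad, cache$in_dim[2])
    } else if (l$type == "conv") {
      out <- conv1d_bwd(dA, cache$P, cache$in_dim, l$W)
      grads[[i]] <- list(dW = out$dW, db = out$db)
      dA <- out$dX
    } else if (l$type == "relu") {
      dA <- relu_bwd(dA, cache$pos, guided = guided)
    } else if (l$type == "pool") {
      dA <- maxpool2_bwd(dA, cache$first, cache$in_dim)
    } else if (l$type == "flatten") {
      dim(dA) <- cache$in_dim
    } else if (l$type == "dense") {
      out <- dense_bwd(dA, cache$X, l$W)
      grads[[i]] <- list(dW = out$dW, db = out$db)
      dA <- out$dX
    }
  }
  list(grads = grads, dInput = dA)
}

#' Standardize A-line sets
#'
#' `none` returns the inputs unchanged; `samplewise` centres and scales
#' each A-line by its own mean and standard deviation; `featurewise`
#' computes a per-radial-index mean and standard deviation on the training
#' set only and applies them unchanged to every set. Zero standard
#' deviations are replaced by 1.
#'
#' @param train n x d training matrix.
#' @param apply_sets named list of further matrices transformed with the
#'   training statistics.
#' @param mode one of `"none"`, `"samplewise"`, `"featurewise"`.
#' @return list with `train`, `apply_sets`, and `stats` (`mean`/`sd`
#'   vectors for featurewise mode, `NULL` otherwise).
#' @export
standardize <- function(train, apply_sets = list(), mode = c("none", "samplewise", "featurewise")) {
  mode <- match.arg(mode)
  if (mode == "none") {
    return(list(train = train, apply_sets = apply_sets, stats = list(mode = mode)))
  }
  if (mode == "samplewise") {
    f <- function(X) {
      mu <- rowMeans(X)
      sd <- sqrt(rowMeans((X - mu)^2) * ncol(X) / (ncol(X) - 1L))
      sd[sd == 0] <- 1
      (X - mu) / sd
    }
    return(list(train = f(train), apply_sets = lapply(apply_sets, f),
                stats = list(mode = mode)))
  }
  if (nrow(train) == 0L) stopf("standardize: empty training set in featurewise mode")
  mu <- colMeans(train)
  sd <- apply(train, 2L, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  f <- function(X) sweep(sweep(X, 2L, mu, "-"), 2L, sd, "/")
  list(train = f(train), apply_sets = lapply(apply_sets, f),
       stats = list(mode = mode, mean = mu, sd = sd))
}

apply_standardization <- function(X, stats) {
  if (is.null(stats) || stats$mode == "none") return(X)
  if (stats$mode == "samplewise") {
    mu <- rowMeans(X)
    sd <- sqrt(rowMeans((X - mu)^2) * ncol(X) / (ncol(X) - 1L))
    sd[sd == 0] <- 1
    return((X - mu) / sd)
  }
  sweep(sweep(X, 2L, stats$mean, "-"), 2L, stats$sd, "/")
}

#' Inverse-proportion class weights
#'
#' Weights are the inverse class proportions of the training set,
#' normalised so the most frequent class has weight 1; for proportions
#' (1/6, 1/6, 2/3) this yields (4, 4, 1).
#'
#' @param counts named or ordered vector of per-class training counts
#'   (fibrocalcific, fibrolipidic, other).
#' @return numeric weight vector in the same order.
#' @export
class_weights <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts <= 0)) {
    nm <- names(counts) %||% PLAQUE_CLASSES[seq_along(counts)]
    stopf("class_weights: zero training count for class '%s'", nm[which(counts <= 0)[1]])
  }
  max(counts) / counts
}

#' Train a model with Adam and early stopping
#'
#' Minimises the class-weighted categorical cross-entropy with Adam at the
#' configured learning rate. After each epoch the (weighted) validation
#' loss is computed; training stops when the relative improvement over the
#' running best is below `min_rel_improvement` for `patience` consecutive
#' epochs, or at `max_epochs`. The returned model carries the parameters of
#' the epoch with the minimum validation loss.
#'
#' @param model an `oct_model` from [build_model()].
#' @param train,val lists with `x` (n x input_len matrix), `y` (integer
#'   classes 1..3 or factor), and optionally `pullback_id` per row; when
#'   both sets carry pullback ids they must be disjoint.
#' @param weights class weight vector; computed with [class_weights()] from
#'   the training labels when `NULL`.
#' @return an `oct_trained_model` with elements `config`, `layers`
#'   (trained), `stand_stats`, `weights`, `history`, `best_epoch`.
#' @export
train_model <- function(model, train, val, weights = NULL) {
  cfg <- model$config
  y_tr <- as.integer(factor_labels(train$y))
  y_va <- as.integer(factor_labels(val$y))
  if (!is.null(train$pullback_id) && !is.null(val$pullback_id)) {
    shared <- intersect(unique(train$pullback_id), unique(val$pullback_id))
    if (length(shared)) stopf("train_model: train/val share pullback id(s): %s",
                              paste(shared, collapse = ", "))
  }
  std <- standardize(train$x, list(val = val$x), mode = cfg$standardization)
  X_tr <- std$train; X_va <- std$apply_sets$val
  if (is.null(weights)) {
    weights <- class_weights(tabulate(y_tr, nbins = cfg$n_classes))
  }
  Y_tr <- onehot(y_tr, cfg$n_classes)
  Y_va <- onehot(y_va, cfg$n_classes)

  n <- nrow(X_tr)
  params <- flatten_params(model$layers)
  opt <- adam_init(params)
  best <- list(loss = Inf, layers = model$layers, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0), val_loss = numeric(0))
  stall <- 0L

  with_seed(derive_seed(cfg$seed, 17L), {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        rows <- ord[start:min(start + cfg$batch_size - 1L, n)]
        fwd <- model_forward(model, X_tr[rows, , drop = FALSE], keep_cache = TRUE)
        P <- softmax_rows(fwd$logits)
        ep_loss <- ep_loss + weighted_cross_entropy(Y_tr[rows, , drop = FALSE], P, weights) * length(rows)
        dZ <- ce_softmax_grad(P, Y_tr[rows, , drop = FALSE], weights)
        bwd <- model_backward(model, fwd, dZ)
        g <- flatten_params(grads_as_layers(model$layers, bwd$grads))
        upd <- adam_step(opt, params, g, cfg$lr)
        opt <- upd$state
        params <- upd$params
        model$layers <- unflatten_params(model$layers, params)
      }
      ep_loss <- ep_loss / n
      if (!is.finite(ep_loss)) stopf("train_model: non-finite training loss at epoch %d", epoch)
      val_loss <- batched_loss(model, X_va, Y_va, weights, cfg$batch_size)
      if (!is.finite(val_loss)) stopf("train_model: non-finite validation loss at epoch %d", epoch)
      history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss, val_loss = val_loss))
      oct_log("epoch %d: train %.5f val %.5f", epoch, ep_loss, val_loss)
      if (val_loss < best$loss * (1 - cfg$min_rel_improvement)) {
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, layers = model$layers, epoch = epoch)
      }
      if (stall >= cfg$patience) break
    }
  })
  structure(list(config = cfg, layers = best$layers, shape = model$shape,
                 stand_stats = std$stats, weights = weights,
                 history = history, best_epoch = best$epoch),
            class = c("oct_trained_model", "oct_model"))
}

#' Replay the early-stopping rule on a validation-loss sequence
#'
#' Pure function implementing the stopping rule used by [train_model()]:
#' the patience counter increments whenever the relative improvement over
#' the running best validation loss is below `min_rel_improvement`, resets
#' otherwise, and training stops once it reaches `patience` (or at the end
#' of the sequence). Exposed so the rule itself is testable.
#'
#' @param val_losses per-epoch validation losses.
#' @param patience consecutive non-improving epochs tolerated.
#' @param min_rel_improvement relative improvement threshold.
#' @return list with `stop_epoch` (last epoch run) and `best_epoch` (epoch
#'   of minimum validation loss among those run).
#' @export
early_stopping_trace <- function(val_losses, patience = 5L, min_rel_improvement = 1e-4) {
  best <- Inf; best_epoch <- 0L; stall <- 0L
  for (e in seq_along(val_losses)) {
    v <- val_losses[e]
    if (v < best * (1 - min_rel_improvement)) stall <- 0L else stall <- stall + 1L
    if (v < best) { best <- v; best_epoch <- e }
    if (stall >= patience) return(list(stop_epoch = e, best_epoch = best_epoch))
  }
  list(stop_epoch = length(val_losses), best_epoch = best_epoch)
}

batched_loss <- function(model, X, Y, weights, batch_size) {
  n <- nrow(X)
  tot <- 0
  for (start in seq(1L, n, by = batch_size)) {
    rows <- start:min(start + batch_size - 1L, n)
    P <- softmax_rows(model_forward(model, X[rows, , drop = FALSE])$logits)
    tot <- tot + weighted_cross_entropy(Y[rows, , drop = FALSE], P, weights) * length(rows)
  }
  tot / n
}

factor_labels <- function(y) {
  if (is.factor(y)) return(y)
  if (is.character(y)) return(factor(y, levels = PLAQUE_CLASSES))
  factor(PLAQUE_CLASSES[as.integer(y)], levels = PLAQUE_CLASSES)
}

flatten_params <- function(layers) {
  out <- list()
  for (i in seq_along(layers)) {
    if (!is.null(layers[[i]]$W)) {
      out[[sprintf("L%d.W", i)]] <- layers[[i]]$W
      out[[sprintf("L%d.b", i)]] <- layers[[i]]$b
    }
  }
  out
}

grads_as_layers <- function(layers, grads) {
  for (i in seq_along(layers)) {
    if (!is.null(grads[[i]])) {
      layers[[i]]$W <- grads[[i]]$dW
      layers[[i]]$b <- grads[[i]]$db
    } else if (!is.null(layers[[i]]$W)) {
      layers[[i]]$W <- array(0, dim(layers[[i]]$W))
      layers[[i]]$b <- numeric(length(layers[[i]]$b))
    }
  }
  layers
}

unflatten_params <- function(layers, params) {
  for (i in seq_along(layers)) {
    if (!is.null(layers[[i]]$W)) {
      layers[[i]]$W <- params[[sprintf("L%d.W", i)]]
      layers[[i]]$b <- params[[sprintf("L%d.b", i)]]
    }
  }
  layers
}

#' Predict class probabilities for processed A-lines
#'
#' Applies the model's stored standardization statistics, then the forward
#' pass and softmax. Rows are independent: batch prediction equals
#' per-example prediction.
#'
#' @param object an `oct_trained_model`.
#' @param newdata n x input_len matrix, or an `oct_processed`.
#' @param batch_size forward batch size.
#' @param ... unused.
#' @return n x 3 matrix of class probabilities (columns fibrocalcific,
#'   fibrolipidic, other), rows summing to 1.
#' @export
predict.oct_trained_model <- function(object, newdata, batch_size = 1024L, ...) {
  X <- if (inherits(newdata, "oct_processed")) newdata$values else newdata
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != object$config$input_len) {
    stopf("predict: A-lines have length %d, expected %d", ncol(X), object$config$input_len)
  }
  X <- apply_standardization(X, object$stand_stats)
  out <- matrix(0, nrow(X), object$config$n_classes)
  for (start in seq(1L, nrow(X), by = batch_size)) {
    rows <- start:min(start + batch_size - 1L, nrow(X))
    out[rows, ] <- softmax_rows(model_forward(object, X[rows, , drop = FALSE])$logits)
  }
  colnames(out) <- PLAQUE_CLASSES
  out
}

#' @export
print.oct_model <- function(x, ...) {
  trained <- inherits(x, "oct_trained_model")
  cat(sprintf("<oct_%smodel '%s': %d parameters%s>\n",
              if (trained) "trained_" else "", x$config$arch, n_params(x),
              if (trained) sprintf(", best epoch %d", x$best_epoch) else ""))
  invisible(x)
}
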