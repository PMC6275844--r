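# Shared fixtures, built lazily and memoised for the whole test run.
# Everything is generated in code; no data files.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fx[[name]])) assign(name, make(), envir = .fx)
  get(name, envir = .fx)
}

# A labeled set of standalone processed-style A-lines (aligned at the
# lumen, speckled, log-compressed, lightly smoothed), with known border
# positions. Emulates the per-A-line view of the full preprocessing chain.
make_aline_set <- function(n_per_class, seed, speckle_shape = 2,
                           cap_px = NULL, calcium_px = NULL) {
  octaline:::with_seed(seed, {
    k <- octaline:::gaussian_kernel_1d(7, 1)
    smooth1d <- function(v) {
      pad <- c(rep(v[1], 3), v, rep(v[200], 3))
      as.numeric(stats::filter(pad, k, sides = 2))[4:203]
    }
    classes <- rep(c("fibrocalcific", "fibrolipidic", "other"), each = n_per_class)
    x <- matrix(0, length(classes), 200)
    borders <- vector("list", length(classes))
    for (i in seq_along(classes)) {
      cap <- if (is.null(cap_px)) round(runif(1, 10, 60)) else cap_px
      calc <- if (is.null(calcium_px)) round(runif(1, 60, 120)) else calcium_px
      prof <- generate_aline_profile(classes[i], 240, cap_px = cap,
                                     calcium_px = calc, jitter = TRUE)[1:200]
      noisy <- apply_speckle(prof, speckle_shape)
      x[i, ] <- smooth1d(log1p(noisy))
      borders[[i]] <- attr(prof, "borders")
    }
    list(x = x, y = factor(classes, levels = octaline:::PLAQUE_CLASSES),
         borders = borders)
  })
}

# A quickly trained full-width CNN on standalone A-lines; reused by the
# translation-tolerance, saliency-border, and acceptance tests.
trained_probe_cnn <- function() {
  fixture("probe_cnn", function() {
    tr <- make_aline_set(400, seed = 401)
    va <- make_aline_set(80, seed = 402)
    cfg <- net_config("cnn", max_epochs = 6, batch_size = 128, seed = 7)
    train_model(build_cnn(cfg), list(x = tr$x, y = tr$y), list(x = va$x, y = va$y))
  })
}

# A small multi-pullback simulated dataset for cross-validation tests.
small_sim_dataset <- function() {
  fixture("small_dataset", function() {
    simulate_dataset(6, seed = 17, n_frames = 10, n_alines = 64, depth_px = 300,
                     guidewire_width_alines = 4)
  })
}

# Tiny net configs for fast structural tests.
tiny_cnn_cfg <- function(...) {
  net_config("cnn", input_len = 24, pad = 2, conv1_filters = 3, conv1_len = 5,
             conv2_filters = 4, conv2_len = 3, fc_units = 6, ...)
}

# Exhaustive enumeration oracle for the circular-contour DP: enumerates
# every feasible circular path on an edge map (small frames only).
enumerate_best_path <- function(edge, dmax) {
  depth <- nrow(edge); n <- ncol(edge)
  offsets <- as.matrix(do.call(expand.grid, rep(list(-dmax:dmax), n - 1L)))
  best <- -Inf
  for (r0 in seq_len(depth)) {
    pos <- cbind(r0, r0 + t(apply(offsets, 1L, cumsum)))
    ok <- rowSums(pos < 1L | pos > depth) == 0L
    ok <- ok & abs(pos[, n] - r0) <= dmax # circular closure
    if (!any(ok)) next
    pos_ok <- pos[ok, , drop = FALSE]
    sc <- rowSums(matrix(edge[cbind(as.vector(pos_ok),
                                    rep(seq_len(n), each = nrow(pos_ok)))],
                         nrow(pos_ok), n))
    best <- max(best, max(sc))
  }
  best
}
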