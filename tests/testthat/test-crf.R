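# En-face CRF cleaning: assembly, unaries, energy, mean-field inference,
# area opening.

random_enface <- function(n_t, n_z, seed, drop_frac = 0) {
  octaline:::with_seed(seed, {
    P <- matrix(rgamma(n_t * n_z * 3, 1), n_t * n_z)
    P <- P / rowSums(P)
    ef <- build_enface(P, rep(seq_len(n_t) - 1L, times = n_z),
                       rep(seq_len(n_z) - 1L, each = n_t), n_t)
    if (drop_frac > 0) ef$valid <- ef$valid & (matrix(runif(n_t * n_z), n_t) > drop_frac)
    ef
  })
}

test_that("en-face assembly round-trips and validates its inputs", {
  octaline:::with_seed(81, {
    n_t <- 48L; n_z <- 55L
    P <- matrix(rgamma(n_t * n_z * 3, 1), n_t * n_z)
    P <- P / rowSums(P)
    al <- rep(seq_len(n_t) - 1L, times = n_z)
    fr <- rep(seq_len(n_z) - 1L + 10L, each = n_t) # arbitrary frame origin
    ef <- build_enface(P, al, fr, n_t)
    expect_equal(dim(ef$probs), c(n_t, n_z, 3L))
    expect_true(all(ef$valid))
    # scatter then gather returns the input probabilities exactly
    for (k in 1:3) expect_equal(ef$probs[cbind(al + 1L, fr - 9L, k)], P[, k])
    expect_error(build_enface(P[1:96, ], al[1:96], c(rep(0L, 48), rep(2L, 48)), n_t),
                 "gaps")
    # guidewire mask invalidates pixels
    gw <- matrix(FALSE, n_t, n_z); gw[3, ] <- TRUE
    ef2 <- build_enface(P, al, fr, n_t, guidewire = gw)
    expect_true(all(!ef2$valid[3, ]))
  })
})

test_that("unary potentials are -log probabilities with an epsilon floor", {
  P <- rbind(c(1, 0, 0), c(1 / 3, 1 / 3, 1 / 3))
  ef <- build_enface(P, c(0L, 1L), c(0L, 0L), 2)
  U <- unary_potentials(ef)
  expect_equal(U[1, 1, ], c(0, -log(1e-12), -log(1e-12)), tolerance = 1e-10)
  expect_equal(U[2, 1, ], rep(log(3), 3), tolerance = 1e-12)
  # monotone: larger probability, smaller unary
  octaline:::with_seed(82, {
    Pr <- matrix(rgamma(3000, 1), 1000); Pr <- Pr / rowSums(Pr)
    efr <- build_enface(Pr, rep(0:999, 1), rep(0L, 1000), 1000)
    Ur <- unary_potentials(efr)
    ord_p <- t(apply(Pr, 1, order))
    for (i in sample(1000, 50)) {
      expect_equal(order(Ur[i, 1, ], decreasing = TRUE), ord_p[i, ])
    }
  })
})

test_that("energy reduces to the unary sum without the smoothness kernel", {
  ef <- random_enface(5, 4, seed = 83)
  lab <- matrix(sample(1:3, 20, replace = TRUE), 5, 4)
  U <- unary_potentials(ef)
  e0 <- crf_energy(lab, ef, crf_params(w2 = 0))
  expect_equal(e0, sum(U[cbind(which(ef$valid, arr.ind = TRUE), lab[ef$valid])]),
               tolerance = 1e-10)
  # uniform labeling: pairwise term vanishes regardless of w2
  lab1 <- matrix(2L, 5, 4)
  expect_equal(crf_energy(lab1, ef, crf_params(w2 = 50)),
               crf_energy(lab1, ef, crf_params(w2 = 0)), tolerance = 1e-10)
})

test_that("2-pixel toy: mean-field argmax matches exhaustive MAP enumeration", {
  # discordance penalty w2 * exp(-1/2) ~ 6.07 dominates the unary gap
  probs <- rbind(c(0.9, 0.1, 1e-9), c(0.45, 0.55, 1e-9))
  probs <- probs / rowSums(probs)
  ef <- build_enface(probs, c(0L, 1L), c(0L, 0L), 2, theta_circular = FALSE)
  pt <- crf_params(w2 = 10, sigma_theta = 1, sigma_z = 1, n_iter = 5)
  grid <- expand.grid(l1 = 1:3, l2 = 1:3)
  energies <- apply(grid, 1, function(g) crf_energy(matrix(as.integer(g), 2, 1), ef, pt))
  map <- as.integer(grid[which.min(energies), ])
  expect_equal(map, c(1L, 1L)) # smoothing flips the weak pixel to class 1
  mf <- mean_field_infer(ef, pt)
  expect_equal(as.integer(mf$labels[, 1]), map)
})

test_that("filtered mean-field matches the dense all-pairs oracle to 1e-6", {
  for (s in 1:8) {
    ef <- random_enface(6, 6, seed = 840 + s, drop_frac = if (s %% 2) 0 else 0.15)
    params <- crf_params(w2 = 1, sigma_theta = 1.5, sigma_z = 1.5, n_iter = 5,
                         kernel_halfwidth = 5) # window covers the whole grid
    a <- mean_field_infer(ef, params)
    b <- mean_field_dense(ef, params)
    expect_lt(max(abs(a$marginals - b$marginals), na.rm = TRUE), 1e-6)
    expect_identical(a$labels, b$labels)
  }
})

test_that("w2 = 0 reduces inference to the per-pixel argmax", {
  ef <- random_enface(10, 8, seed = 85, drop_frac = 0.1)
  for (n_iter in c(1L, 5L)) {
    r <- mean_field_infer(ef, crf_params(w2 = 0, n_iter = n_iter))
    ref <- apply(ef$probs, c(1, 2), which.max)
    expect_equal(r$labels[ef$valid], ref[ef$valid])
    expect_true(all(r$labels[!ef$valid] == 4L))
  }
})

test_that("marginals stay normalised and labels respect the guidewire mask", {
  ef <- random_enface(12, 9, seed = 86, drop_frac = 0.2)
  r <- mean_field_infer(ef, crf_params(w2 = 3, n_iter = 7))
  s <- r$marginals[, , 1] + r$marginals[, , 2] + r$marginals[, , 3]
  expect_equal(s[ef$valid], rep(1, sum(ef$valid)), tolerance = 1e-9)
  expect_true(all(is.na(s[!ef$valid])))
  expect_true(all(r$labels[!ef$valid] == 4L))
})

test_that("inference is equivariant under label permutation", {
  ef <- random_enface(8, 8, seed = 87)
  perm <- c(3L, 1L, 2L)
  ef_p <- ef
  ef_p$probs <- ef$probs[, , perm]
  params <- crf_params(w2 = 1.5, n_iter = 5)
  r <- mean_field_infer(ef, params)
  r_p <- mean_field_infer(ef_p, params)
  expect_equal(r_p$marginals, r$marginals[, , perm], tolerance = 1e-10)
  expect_equal(match(r$labels, perm), as.vector(r_p$labels))
})

test_that("very large w2 drives a connected region to a single label", {
  ef <- random_enface(8, 8, seed = 88)
  r <- mean_field_infer(ef, crf_params(w2 = 1e3, sigma_theta = 4, sigma_z = 4, n_iter = 10))
  expect_equal(length(unique(as.vector(r$labels))), 1L)
})

test_that("area opening removes sub-threshold components and keeps the rest", {
  base <- matrix(3L, 20, 20)
  m1 <- base; m1[5:7, 5:7] <- 1L # area 9 < 10
  expect_true(all(area_open_cleanup(m1) == 3L))
  m2 <- base; m2[5:8, 5:7] <- 1L # area 12 survives every pass
  expect_equal(sum(area_open_cleanup(m2) == 1L), 12L)
  expect_identical(area_open_cleanup(base), base) # uniform map unchanged
  # guidewire pixels are never touched
  m3 <- m1; m3[1, ] <- 4L
  out3 <- area_open_cleanup(m3)
  expect_true(all(out3[1, ] == 4L))
})

test_that("area opening counts theta-wrapping components as one", {
  base <- matrix(3L, 20, 20)
  m <- base; m[c(19, 20, 1, 2), 5:7] <- 1L # area 12 across the seam
  expect_equal(sum(area_open_cleanup(m) == 1L), 12L)
  m2 <- base; m2[c(20, 1, 2), 5:7] <- 1L # area 9 across the seam
  expect_true(all(area_open_cleanup(m2) == 3L))
  # without wrapping the same pixels form two sub-threshold pieces
  expect_true(all(area_open_cleanup(m, theta_circular = FALSE) == 3L))
})

test_that("8-connectivity joins diagonal neighbours", {
  base <- matrix(3L, 15, 15)
  # diagonal staircase of 10 pixels: one 8-connected component, area 10
  for (i in 1:10) base[i, i] <- 1L
  out <- area_open_cleanup(base)
  expect_equal(sum(out == 1L), 10L)
})

test_that("cleaning strictly improves accuracy on noisy simulated en-face maps", {
  octaline:::with_seed(89, {
    improved <- 0L
    for (s in 1:10) {
      cfg <- sim_config(n_frames = 24, n_alines = 64, depth_px = 250,
                        guidewire_width_alines = 4, seed = 8900 + s)
      truth <- generate_pullback(cfg)$truth
      lab_true <- matrix(match(truth$labels, octaline:::LABEL_LEVELS), 64, 24)
      valid <- !truth$guidewire
      # probabilities: confident at the true label, 25% i.i.d. label flips
      n <- sum(valid)
      obs <- lab_true
      flip <- which(valid)[runif(n) < 0.25]
      obs[flip] <- sample(1:3, length(flip), replace = TRUE)
      P <- matrix(0.1, n, 3)
      P[cbind(seq_len(n), obs[valid])] <- 0.8
      idx <- which(valid, arr.ind = TRUE)
      ef <- build_enface(P, idx[, 1] - 1L, idx[, 2] - 1L, 64, guidewire = truth$guidewire)
      noisy_acc <- mean(obs[valid] == lab_true[valid])
      r <- mean_field_infer(ef, crf_params())
      lab <- area_open_cleanup(r$labels)
      clean_acc <- mean(lab[valid] == lab_true[valid])
      improved <- improved + (clean_acc > noisy_acc)
    }
    expect_gte(improved, 9L)
  })
})
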