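# En-face (theta, z) classification noise cleaning: smoothness-only fully
# connected CRF (appearance kernel dropped, w1 = 0) solved by mean-field
# approximation, followed by a three-pass morphological area opening.
#
# Grid convention: rows = theta (A-line index, circular), columns = z
# (frame index, not circular). Guidewire pixels are removed from the graph
# (no messages pass through them) and re-inserted as "guidewire" labels.

#' CRF parameters
#'
#' The pairwise potential is `mu(li, lj) * w2 * exp(-d(i,j)^2 / 2)` with
#' `d(i,j)^2 = (dtheta / sigma_theta)^2 + (dz / sigma_z)^2`, `dtheta` the
#' circular angular difference, and `mu = 1` iff the labels differ. The
#' Gaussian filter realising message passing is truncated at
#' `kernel_halfwidth * sigma` per axis. A filter window extent of (19, 5)
#' in (theta, z) with truncation at +-2 sigma corresponds to
#' `sigma_theta = 4.75`, `sigma_z = 1.25` — the defaults.
#'
#' The default `w2 = 0.25` balances a confident unary gap
#' (`log(0.8 / 0.1) ~ 2.1`) against the ~8 near neighbours within one
#' sigma of the smoothness kernel, so isolated misclassifications flip
#' while lesion-scale regions survive; larger values over-smooth small
#' lesions.
#'
#' @param w2 smoothness weight (>= 0).
#' @param sigma_theta,sigma_z kernel scales per axis, in pixels.
#' @param n_iter mean-field iterations (default 5).
#' @param kernel_halfwidth truncation radius in units of sigma.
#' @return a `crf_params` list.
#' @export
crf_params <- function(w2 = 0.25, sigma_theta = 19 / 4, sigma_z = 5 / 4,
                       n_iter = 5L, kernel_halfwidth = 2) {
  if (w2 < 0) stopf("crf_params: w2 must be >= 0")
  if (sigma_theta <= 0 || sigma_z <= 0) stopf("crf_params: sigmas must be > 0")
  if (!is_count(n_iter)) stopf("crf_params: n_iter must be >= 1")
  structure(list(w2 = w2, sigma_theta = sigma_theta, sigma_z = sigma_z,
                 n_iter = as.integer(n_iter), kernel_halfwidth = kernel_halfwidth),
            class = "crf_params")
}

#' Assemble per-A-line probabilities into an en-face map
#'
#' @param probs matrix (n x 3) of class probabilities for the listed
#'   A-lines.
#' @param aline,frame 0-based A-line and frame indices per row of `probs`;
#'   frames must form a consecutive range.
#' @param n_alines grid height.
#' @param guidewire optional logical n_alines x n_frames matrix; pixels not
#'   covered by `probs` are invalid too.
#' @param theta_circular treat theta as circular (default TRUE).
#' @return an `oct_enface`: list with `probs` (n_alines x n_frames x 3
#'   array), `valid` (logical matrix), `frame0` (first frame index),
#'   `theta_circular`.
#' @export
build_enface <- function(probs, aline, frame, n_alines,
                         guidewire = NULL, theta_circular = TRUE) {
  fr <- sort(unique(frame))
  if (length(fr) > 1L && any(diff(fr) != 1L)) {
    stopf("build_enface: frame range has gaps (%s)", paste(utils::head(fr), collapse = ","))
  }
  n_frames <- length(fr)
  P <- array(NA_real_, c(n_alines, n_frames, 3L))
  valid <- matrix(FALSE, n_alines, n_frames)
  rows <- cbind(aline + 1L, frame - fr[1L] + 1L)
  for (k in 1:3) P[cbind(rows, k)] <- probs[, k]
  valid[rows] <- TRUE
  if (!is.null(guidewire)) valid <- valid & !guidewire
  P[is.na(P)] <- 0
  structure(list(probs = P, valid = valid, frame0 = fr[1L],
                 theta_circular = isTRUE(theta_circular)),
            class = "oct_enface")
}

#' Unary potentials of an en-face map
#'
#' `theta_i(l) = -log(max(P_i(l), 1e-12))`; invalid pixels get NA.
#'
#' @param enface an `oct_enface`.
#' @return n_alines x n_frames x 3 array of unary potentials.
#' @export
unary_potentials <- function(enface) {
  U <- -log(pmax(enface$probs, 1e-12))
  for (k in 1:3) {
    Uk <- U[, , k]
    Uk[!enface$valid] <- NA_real_
    U[, , k] <- Uk
  }
  U
}

# Squared scaled circular distance matrix helpers for the dense routines.
pair_kernel <- function(enface, params) {
  n_t <- nrow(enface$valid); n_z <- ncol(enface$valid)
  idx <- which(enface$valid, arr.ind = TRUE)
  dt <- abs(outer(idx[, 1L], idx[, 1L], "-"))
  if (enface$theta_circular) dt <- pmin(dt, n_t - dt)
  dz <- outer(idx[, 2L], idx[, 2L], "-")
  K <- exp(-((dt / params$sigma_theta)^2 + (dz / params$sigma_z)^2) / 2)
  diag(K) <- 0
  list(K = K, idx = idx)
}

#' CRF energy of a labeling
#'
#' `E(l) = sum_i theta_i(l_i) + sum_{i<j} mu(l_i, l_j) w2 k(i, j)` over the
#' valid pixels, with the pairwise sum counted once per unordered pair and
#' the Gaussian smoothness kernel `k` evaluated on scaled (circular-theta)
#' distances.
#'
#' @param labels n_alines x n_frames integer matrix (1..3) on valid pixels.
#' @param enface an `oct_enface` (supplies unaries and validity).
#' @param params a [crf_params()].
#' @return scalar energy.
#' @export
crf_energy <- function(labels, enface, params) {
  U <- unary_potentials(enface)
  idx <- which(enface$valid, arr.ind = TRUE)
  l <- labels[enface$valid]
  e_unary <- sum(U[cbind(idx, l)])
  pk <- pair_kernel(enface, params)
  diff <- outer(l, l, "!=")
  e_pair <- params$w2 * sum(pk$K[diff]) / 2
  e_unary + e_pair
}

# Separable truncated Gaussian filtering of one class plane, with validity
# masking (invalid pixels contribute nothing and receive nothing).
# Returns the filtered field including the self term; callers subtract it.
enface_filter <- function(Q, valid, params, theta_circular) {
  n_t <- nrow(Q); n_z <- ncol(Q)
  Qm <- Q * valid
  # z axis: ordinary truncated kernel
  hz <- min(n_z - 1L, max(1L, ceiling(params$kernel_halfwidth * params$sigma_z)))
  kz <- exp(-((-hz:hz) / params$sigma_z)^2 / 2)
  out <- matrix(0, n_t, n_z)
  for (j in -hz:hz) {
    cols <- seq_len(n_z) + j
    ok <- cols >= 1L & cols <= n_z
    out[, ok] <- out[, ok, drop = FALSE] + kz[j + hz + 1L] * Qm[, cols[ok], drop = FALSE]
  }
  ht <- ceiling(params$kernel_halfwidth * params$sigma_theta)
  out2 <- matrix(0, n_t, n_z)
  if (theta_circular) {
    # ring kernel over offsets 0..n_t-1 weighted by circular distance, so
    # each neighbour is counted exactly once even when the window is wide
    off <- 0:(n_t - 1L)
    dt <- pmin(off, n_t - off)
    kt <- ifelse(dt <= ht, exp(-(dt / params$sigma_theta)^2 / 2), 0)
    for (o in which(kt > 0)) {
      rows <- wrap_idx(seq_len(n_t) + (o - 1L), n_t)
      out2 <- out2 + kt[o] * out[rows, , drop = FALSE]
    }
  } else {
    ht <- min(ht, n_t - 1L)
    for (s in -ht:ht) {
      rows <- seq_len(n_t) + s
      ok <- rows >= 1L & rows <= n_t
      out2[ok, ] <- out2[ok, , drop = FALSE] +
        exp(-(s / params$sigma_theta)^2 / 2) * out[rows[ok], , drop = FALSE]
    }
  }
  out2 * valid
}

#' Mean-field inference on the en-face CRF
#'
#' Marginals Q are initialised to the input probabilities. Each iteration
#' Gaussian-filters Q per class over the valid grid (self-contribution
#' excluded), applies the label-compatibility transform (penalty `w2` on
#' the filtered mass of *other* classes), adds the unaries, and
#' renormalises with a softmax (synchronous updates, no damping). After
#' `n_iter` iterations labels are the per-pixel argmax; invalid pixels pass
#' through as class 4 ("guidewire").
#'
#' @param enface an `oct_enface`.
#' @param params a [crf_params()].
#' @return list with `labels` (n_alines x n_frames integer matrix, 1..3 on
#'   valid pixels, 4 elsewhere) and `marginals` (n_alines x n_frames x 3).
#' @export
mean_field_infer <- function(enface, params) {
  P <- enface$probs
  valid <- enface$valid
  n_t <- dim(P)[1]; n_z <- dim(P)[2]
  plane <- function(A, k) {
    M <- A[, , k, drop = FALSE]
    dim(M) <- dim(A)[1:2]
    M
  }
  U <- array(0, dim(P))
  for (k in 1:3) {
    Uk <- -log(pmax(plane(P, k), 1e-12))
    Uk[!valid] <- 0
    U[, , k] <- Uk
  }
  Q <- P
  for (it in seq_len(params$n_iter)) {
    filt <- array(0, dim(Q))
    for (k in 1:3) {
      filt[, , k] <- enface_filter(plane(Q, k), valid, params, enface$theta_circular) -
        plane(Q, k) * valid # remove self-contribution (kernel value 1 at 0)
    }
    tot <- plane(filt, 1) + plane(filt, 2) + plane(filt, 3)
    Z <- array(0, dim(Q))
    for (k in 1:3) Z[, , k] <- -plane(U, k) - params$w2 * (tot - plane(filt, k))
    m <- pmax(pmax(plane(Z, 1), plane(Z, 2)), plane(Z, 3))
    for (k in 1:3) Z[, , k] <- exp(plane(Z, k) - m)
    s <- plane(Z, 1) + plane(Z, 2) + plane(Z, 3)
    for (k in 1:3) Q[, , k] <- plane(Z, k) / s
    if (!all(is.finite(Q))) stopf("mean_field_infer: non-finite marginals at iteration %d", it)
  }
  labels <- apply(Q, c(1, 2), which.max)
  labels[!valid] <- 4L
  for (k in 1:3) {
    Qk <- Q[, , k]
    Qk[!valid] <- NA_real_
    Q[, , k] <- Qk
  }
  list(labels = labels, marginals = Q)
}

# Independent dense (all-pairs, no truncation) mean-field reference. Used
# as the oracle in tests; kept exported for transparency.

#' Dense all-pairs mean-field reference implementation
#'
#' Literal implementation over the explicit pairwise kernel matrix, with no
#' truncation or filtering tricks. Quadratic in the number of valid pixels;
#' intended for small grids and used as an independent check of
#' [mean_field_infer()].
#'
#' @inheritParams mean_field_infer
#' @return as [mean_field_infer()].
#' @export
mean_field_dense <- function(enface, params) {
  pk <- pair_kernel(enface, params)
  K <- pk$K; idx <- pk$idx
  n <- nrow(idx)
  P <- t(apply(idx, 1L, function(ij) enface$probs[ij[1L], ij[2L], ]))
  U <- -log(pmax(P, 1e-12))
  Q <- P
  for (it in seq_len(params$n_iter)) {
    M <- K %*% Q # filtered per-class mass at each pixel (diag(K) = 0)
    Z <- -U - params$w2 * (rowSums(M) - M)
    Z <- exp(Z - apply(Z, 1L, max))
    Q <- Z / rowSums(Z)
  }
  labels <- matrix(4L, nrow(enface$valid), ncol(enface$valid))
  labels[idx] <- max.col(Q, ties.method = "first")
  marg <- array(NA_real_, dim(enface$probs))
  for (k in 1:3) {
    mk <- matrix(NA_real_, nrow(enface$valid), ncol(enface$valid))
    mk[idx] <- Q[, k]
    marg[, , k] <- mk
  }
  list(labels = labels, marginals = marg)
}

# 8-connected component labeling with optional theta wrap, via repeated
# label propagation (grids are small; simplicity over asymptotics).
connected_components <- function(mask, theta_circular = TRUE) {
  n_t <- nrow(mask); n_z <- ncol(mask)
  lab <- matrix(0L, n_t, n_z)
  lab[mask] <- seq_len(sum(mask))
  shift_t <- function(M, s) {
    if (s == 0L) return(M)
    if (theta_circular) M[wrap_idx(seq_len(n_t) + s, n_t), , drop = FALSE]
    else {
      out <- matrix(0L, n_t, n_z)
      rows <- seq_len(n_t) + s
      ok <- rows >= 1L & rows <= n_t
      out[ok, ] <- M[rows[ok], , drop = FALSE]
      out
    }
  }
  shift_z <- function(M, s) {
    if (s == 0L) return(M)
    out <- matrix(0L, n_t, n_z)
    cols <- seq_len(n_z) + s
    ok <- cols >= 1L & cols <= n_z
    out[, ok] <- M[, cols[ok], drop = FALSE]
    out
  }
  repeat {
    new <- lab
    for (st in -1:1) for (sz in -1:1) {
      if (st == 0L && sz == 0L) next
      nb <- shift_z(shift_t(lab, st), sz)
      new <- pmax(new, nb * (new > 0L))
    }
    new[!mask] <- 0L
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

#' Three-pass morphological area opening of an en-face label map
#'
#' Each pass designates one class as background; 8-connected components
#' (theta wrap-aware) of the union of the other two classes with area below
#' `area_threshold` are relabeled to that pass's background class. Passes
#' run serially in `pass_order`. Guidewire pixels (label 4) are untouched.
#'
#' @param labels n_alines x n_frames integer label matrix (1..3, 4 =
#'   guidewire).
#' @param area_threshold minimum surviving component area (default 10).
#' @param pass_order background-class order of the three passes (default:
#'   other, fibrocalcific, fibrolipidic).
#' @param theta_circular wrap components across the theta seam.
#' @param bridge_invalid let guidewire pixels bridge connectivity (the
#'   tissue continues behind the occluded sector, so a lesion split by the
#'   shadow is one component); they contribute no area and are never
#'   relabeled.
#' @return cleaned label matrix.
#' @export
area_open_cleanup <- function(labels, area_threshold = 10L,
                              pass_order = c(3L, 1L, 2L), theta_circular = TRUE,
                              bridge_invalid = TRUE) {
  gw <- labels == 4L
  for (bg in pass_order) {
    fg <- labels != bg & !gw
    if (!any(fg)) next
    comp <- connected_components(if (bridge_invalid) fg | gw else fg, theta_circular)
    comp_fg <- comp
    comp_fg[!fg] <- 0L # guidewire bridges carry no area and are untouched
    sizes <- tabulate(comp_fg[comp_fg > 0L])
    small <- which(sizes > 0L & sizes < area_threshold)
    if (length(small)) labels[comp_fg %in% small] <- bg
  }
  labels
}

#' @export
print.oct_enface <- function(x, ...) {
  cat(sprintf("<oct_enface: %d A-lines x %d frames, %d valid pixels, frame0 = %d>\n",
              nrow(x$valid), ncol(x$valid), sum(x$valid), x$frame0))
  invisible(x)
}
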