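# Preprocessing chain: raw polar frame -> aligned, log-compressed,
# smoothed 200-sample A-lines.
#
# Steps, in order: (1) lumen boundary detection by dynamic programming on a
# radial edge map, (2) guidewire column zeroing, (3) pixel shifting so depth
# index 0 is the first sample beyond the lumen boundary, (4) crop to the
# first 200 px (~1 mm at 5 um/px), (5) log(1 + x) compression, (6) 7 x 7
# Gaussian smoothing (sigma = 1). All indices are 0-based in the interfaces
# that expose radial positions.

#' Normalised Gaussian kernel (unit sum)
#' @param size odd kernel size.
#' @param sigma standard deviation in pixels.
#' @return numeric vector of length `size` summing to 1.
#' @keywords internal
gaussian_kernel_1d <- function(size = 7L, sigma = 1) {
  h <- (size - 1L) / 2
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

# 2-D smoothing, separable: replicate padding along r (rows), circular along
# theta (columns). `size` x `size` kernel of the given sigma.
smooth_frame <- function(frame, size = 7L, sigma = 1) {
  k <- gaussian_kernel_1d(size, sigma)
  h <- (size - 1L) / 2
  nr <- nrow(frame); nc <- ncol(frame)
  # rows: replicate
  padr <- frame[c(rep(1L, h), seq_len(nr), rep(nr, h)), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (j in seq_len(size)) out <- out + k[j] * padr[(j - 1L) + seq_len(nr), , drop = FALSE]
  # columns: circular
  padc <- out[, wrap_idx((1L - h):(nc + h), nc), drop = FALSE]
  out2 <- matrix(0, nr, nc)
  for (j in seq_len(size)) out2 <- out2 + k[j] * padc[, (j - 1L) + seq_len(nc), drop = FALSE]
  out2
}

# Radial edge strength: positive part of the radial (row-wise) forward
# difference of the Gaussian-smoothed frame. Row i holds the evidence that
# the lumen boundary sits at radial index i (0-based row i-1).
lumen_edge_map <- function(frame, size = 7L, sigma = 1) {
  s <- smooth_frame(frame, size, sigma)
  d <- rbind(s[-1L, , drop = FALSE] - s[-nrow(s), , drop = FALSE], 0)
  pmax(d, 0)
}

#' Optimal circular contour by dynamic programming
#'
#' Finds the contour `r(theta)` maximising the summed edge strength subject
#' to the smoothness constraint `|r(theta+1) - r(theta)| <= dmax` and the
#' circular closure `|r(first) - r(last)| <= dmax`. Exact when the number of
#' anchor states is not limited; for deep frames the anchor set is
#' restricted to a window around the unconstrained (open-chain) optimum,
#' which is exact whenever the open optimum already satisfies closure.
#'
#' @param edge depth x n_alines non-negative edge-strength matrix.
#' @param dmax maximum radial step between adjacent A-lines (pixels).
#' @param anchor_window half-width of the anchor candidate window for deep
#'   frames; `Inf` forces the exact all-anchors search.
#' @return list with `radius_px` (0-based radial indices, length n_alines)
#'   and `score` (the maximised cumulative edge strength).
#' @export
lumen_dp <- function(edge, dmax = 2L, anchor_window = 16L) {
  depth <- nrow(edge); n <- ncol(edge)
  if (n == 1L) {
    r <- which.max(edge[, 1L])
    return(list(radius_px = r - 1L, score = edge[r, 1L]))
  }
  shifts <- -dmax:dmax
  run_open <- function() {
    # unconstrained-start DP, used only to seed the anchor window
    val <- edge[, 1L]
    ptr <- matrix(0L, depth, n)
    for (t in 2L:n) {
      best <- rep(-Inf, depth); barg <- integer(depth)
      for (s in shifts) {
        idx <- seq_len(depth) + s
        ok <- idx >= 1L & idx <= depth
        cand <- rep(-Inf, depth)
        cand[ok] <- val[idx[ok]]
        upd <- cand > best
        best[upd] <- cand[upd]; barg[upd] <- idx[upd]
      }
      ptr[, t] <- barg
      val <- best + edge[, t]
    }
    end <- which.max(val)
    path <- integer(n); path[n] <- end
    for (t in n:2L) path[t - 1L] <- ptr[path[t], t]
    path
  }
  anchors <- if (depth <= 2L * anchor_window + 1L || is.infinite(anchor_window)) {
    seq_len(depth)
  } else {
    op <- run_open()
    aw <- unique(pmin(pmax(c(outer(-anchor_window:anchor_window, c(op[1L], op[n]), "+")), 1L), depth))
    sort(aw)
  }
  # anchored DP, vectorised across anchors: V[r, a] = best score of a path
  # ending at radius r given it started at anchors[a]
  na <- length(anchors)
  V <- matrix(-Inf, depth, na)
  V[cbind(anchors, seq_len(na))] <- edge[anchors, 1L]
  ptrs <- vector("list", n)
  for (t in 2L:n) {
    best <- matrix(-Inf, depth, na); barg <- matrix(0L, depth, na)
    for (s in shifts) {
      idx <- seq_len(depth) + s
      ok <- idx >= 1L & idx <= depth
      cand <- matrix(-Inf, depth, na)
      cand[ok, ] <- V[idx[ok], , drop = FALSE]
      upd <- cand > best
      best[upd] <- cand[upd]
      barg[upd] <- idx[row(barg)[upd]]
    }
    ptrs[[t]] <- barg
    V <- best + edge[, t]
  }
  # closure: end radius within dmax of the anchor
  bscore <- -Inf; bend <- 1L; banc <- 1L
  for (a in seq_len(na)) {
    lo <- max(1L, anchors[a] - dmax); hi <- min(depth, anchors[a] + dmax)
    sc <- V[lo:hi, a]
    m <- which.max(sc)
    if (sc[m] > bscore) { bscore <- sc[m]; bend <- lo + m - 1L; banc <- a }
  }
  path <- integer(n); path[n] <- bend
  for (t in n:2L) path[t - 1L] <- ptrs[[t]][path[t], banc]
  list(radius_px = path - 1L, score = bscore)
}

#' Detect the lumen boundary on a polar frame
#'
#' Computes the radial edge map (positive radial derivative of the
#' Gaussian-smoothed frame) and runs [lumen_dp()] to find the closed contour
#' of greatest cumulative edge strength.
#'
#' @param frame depth x n_alines non-negative intensity matrix.
#' @param dmax maximum radial step per A-line (default 2 px).
#' @param anchor_window passed to [lumen_dp()].
#' @return a `lumen_contour`: list with `radius_px` (0-based, length
#'   n_alines), `score`, and `degenerate` flag (all-zero frame).
#' @export
detect_lumen <- function(frame, dmax = 2L, anchor_window = 16L) {
  if (any(frame < 0)) stopf("detect_lumen: frame must be non-negative")
  if (all(frame == 0)) {
    warnf("detect_lumen: all-zero frame; returning contour at r = 0")
    return(structure(list(radius_px = rep(0L, ncol(frame)), score = 0,
                          degenerate = TRUE), class = "lumen_contour"))
  }
  edge <- lumen_edge_map(frame)
  dp <- lumen_dp(edge, dmax = dmax, anchor_window = anchor_window)
  structure(list(radius_px = as.integer(dp$radius_px), score = dp$score,
                 degenerate = FALSE), class = "lumen_contour")
}

#' Zero out guidewire-shadow columns
#' @param frame depth x n_alines matrix.
#' @param guidewire_mask integer vector of 1-based column indices, or a
#'   logical vector of length n_alines.
#' @return frame with the masked columns identically zero.
#' @export
zero_guidewire <- function(frame, guidewire_mask) {
  if (is.logical(guidewire_mask)) {
    if (length(guidewire_mask) != ncol(frame)) {
      stopf("zero_guidewire: logical mask length must equal n_alines")
    }
    guidewire_mask <- which(guidewire_mask)
  }
  if (length(guidewire_mask) == 0L) return(frame)
  if (any(guidewire_mask < 1L | guidewire_mask > ncol(frame))) {
    stopf("zero_guidewire: mask indices out of range")
  }
  frame[, guidewire_mask] <- 0
  frame
}

#' Stand-in guidewire shadow detector
#'
#' Flags columns whose summed intensity beyond the lumen boundary falls
#' below `fraction` of the frame's median column sum, then dilates the flags
#' by `dilate` columns (circularly). This is a deliberately simple stand-in:
#' simulated masks should be preferred where available.
#'
#' @param frame depth x n_alines matrix.
#' @param contour a `lumen_contour` for the frame (optional; computed if
#'   missing).
#' @param fraction threshold as a fraction of the median column sum.
#' @param dilate dilation half-width in columns.
#' @return logical vector of length n_alines (TRUE = guidewire).
#' @export
detect_guidewire <- function(frame, contour = NULL, fraction = 0.1, dilate = 2L) {
  n <- ncol(frame)
  contour <- contour %||% detect_lumen(frame)
  sums <- vapply(seq_len(n), function(a) {
    r0 <- contour$radius_px[a] + 2L # first tissue sample, 1-based
    if (r0 > nrow(frame)) return(0)
    sum(frame[r0:nrow(frame), a])
  }, numeric(1))
  flag <- sums < fraction * stats::median(sums)
  if (any(flag) && dilate > 0L) {
    idx <- which(flag)
    idx <- unique(wrap_idx(c(outer(-dilate:dilate, idx, "+")), n))
    flag[idx] <- TRUE
  }
  flag
}

#' Pixel-shift each A-line to the lumen boundary
#'
#' Shifts column theta up by `radius_px(theta) + 1` samples so index 0 of
#' the output is the first sample after the lumen boundary; vacated deep
#' samples are zero-filled (no wrap-around). A contour value of -1 denotes a
#' boundary before the first sample and yields the identity shift.
#'
#' @param frame depth x n_alines matrix.
#' @param contour a `lumen_contour` or an integer vector of 0-based radii.
#' @return shifted frame of identical shape.
#' @export
pixel_shift <- function(frame, contour) {
  radius <- if (inherits(contour, "lumen_contour")) contour$radius_px else as.integer(contour)
  depth <- nrow(frame); n <- ncol(frame)
  if (length(radius) != n) stopf("pixel_shift: contour length must equal n_alines")
  if (any(radius >= depth)) stopf("pixel_shift: contour deeper than frame")
  if (any(radius < -1L)) stopf("pixel_shift: contour indices must be >= -1")
  out <- matrix(0, depth, n)
  for (a in seq_len(n)) {
    sh <- radius[a] + 1L
    if (sh == 0L) out[, a] <- frame[, a]
    else out[seq_len(depth - sh), a] <- frame[(sh + 1L):depth, a]
  }
  out
}

#' Crop, log-compress, and smooth a shifted frame
#'
#' Keeps the first 200 rows, applies `log(1 + x)` (defined at zero, unlike a
#' bare logarithm), and smooths with the unit-sum 7 x 7, sigma = 1 Gaussian
#' kernel (circular along theta, replicate along r).
#'
#' @param shifted non-negative depth x n_alines matrix (depth >= 200).
#' @param crop_px number of rows kept (default 200).
#' @return processed `crop_px` x n_alines matrix.
#' @export
crop_log_smooth <- function(shifted, crop_px = 200L) {
  if (nrow(shifted) < crop_px) stopf("crop_log_smooth: frame shallower than crop_px")
  if (any(shifted < 0)) stopf("crop_log_smooth: negative intensities")
  smooth_frame(log1p(shifted[seq_len(crop_px), , drop = FALSE]))
}

#' Run the full preprocessing chain over a pullback
#'
#' Applies, per frame: guidewire zeroing, lumen detection (unless contours
#' are supplied), pixel shifting, cropping to 200 px, log compression, and
#' Gaussian smoothing. Guidewire A-lines carry no tissue signal and are
#' excluded from the output.
#'
#' @param pullback an `oct_pullback`.
#' @param contours optional list (or n_alines x n_frames matrix) of 0-based
#'   lumen radii per frame; computed with [detect_lumen()] when `NULL`.
#' @param masks optional logical n_alines x n_frames guidewire matrix;
#'   detected with [detect_guidewire()] when `NULL`.
#' @param labels optional n_alines x n_frames label matrix carried through
#'   to the output index.
#' @return an `oct_processed` list: `values` (n_kept x 200 matrix, one row
#'   per retained A-line) and `index` (data.frame with `pullback_id`,
#'   `frame` and `aline` 0-based indices, and `label`).
#' @export
preprocess_pullback <- function(pullback, contours = NULL, masks = NULL, labels = NULL) {
  frames <- pullback$frames
  n_fr <- length(frames)
  shp <- vapply(frames, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1])) {
    stopf("preprocess_pullback: frames differ in shape")
  }
  n_al <- shp[2, 1]
  if (is.matrix(contours)) contours <- lapply(seq_len(ncol(contours)), function(z) contours[, z])
  vals <- vector("list", n_fr)
  idx <- vector("list", n_fr)
  for (z in seq_len(n_fr)) {
    fr <- frames[[z]]
    storage.mode(fr) <- "double"
    mask <- if (is.null(masks)) detect_guidewire(fr) else masks[, z]
    contour <- if (is.null(contours)) detect_lumen(zero_guidewire_soft(fr, mask)) else contours[[z]]
    fr <- zero_guidewire(fr, mask)
    proc <- crop_log_smooth(pixel_shift(fr, contour))
    keep <- which(!mask)
    vals[[z]] <- t(proc[, keep, drop = FALSE])
    idx[[z]] <- data.frame(
      pullback_id = pullback$pullback_id, frame = z - 1L, aline = keep - 1L,
      label = if (is.null(labels)) NA_character_ else labels[keep, z],
      stringsAsFactors = FALSE
    )
  }
  structure(list(values = do.call(rbind, vals), index = do.call(rbind, idx)),
            class = "oct_processed")
}

# For lumen detection only: replace guidewire columns by their circular
# neighbours so the DP can interpolate smoothly across the shadow.
zero_guidewire_soft <- function(frame, mask) {
  if (is.logical(mask)) mask <- which(mask)
  if (length(mask) == 0L) return(frame)
  n <- ncol(frame)
  ok <- setdiff(seq_len(n), mask)
  if (length(ok) == 0L) return(frame)
  for (a in mask) {
    d <- pmin(abs(ok - a), n - abs(ok - a))
    frame[, a] <- frame[, ok[which.min(d)]]
  }
  frame
}

#' @export
print.oct_processed <- function(x, ...) {
  cat(sprintf("<oct_processed: %d A-lines x %d samples from %d frame(s)>\n",
              nrow(x$values), ncol(x$values), length(unique(x$index$frame))))
  invisible(x)
}
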