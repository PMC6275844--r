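# Synthetic polar-domain pullback simulator.
#
# Emulates the qualitative appearance of intravascular OCT plaque classes on
# raw (r, theta) frames: an eccentric dark lumen bounded by a bright tissue
# edge, a guidewire shadow sector drifting across frames, a fibrous surface
# layer of variable thickness, calcific regions (signal-poor with sharp
# front/back borders), lipidic regions (fast diffuse signal drop-off),
# multiplicative gamma speckle, and lesions that are contiguous blocks in the
# en-face (theta, z) plane. Labels are generated per A-line directly, so
# ground truth is exact by construction.

PLAQUE_CLASSES <- c("fibrocalcific", "fibrolipidic", "other")
LABEL_LEVELS <- c(PLAQUE_CLASSES, "guidewire")

#' Simulator configuration
#'
#' Builds the configuration object consumed by [generate_pullback()]. The
#' defaults encode the acquisition geometry of clinical frequency-domain
#' IVOCT (448 A-lines per frame, 968 samples per A-line, 16-bit) with an
#' axial sampling of 5 um/px, so 200 px correspond to ~1 mm of tissue and a
#' 65 um thin fibrous cap to ~13 px.
#'
#' @param n_frames number of frames in the pullback.
#' @param n_alines A-lines per frame (columns of the polar frame).
#' @param depth_px samples along each A-line (rows).
#' @param axial_um_per_px axial pixel pitch in micrometres.
#' @param frame_pitch_mm catheter travel between frames, millimetres.
#' @param lumen_radius_base_px,lumen_eccentricity_px mean lumen radius and
#'   amplitude of its sinusoidal angular eccentricity, in pixels.
#' @param guidewire_width_alines width of the guidewire shadow sector.
#' @param cap_thickness_range_px closed interval from which per-lesion
#'   fibrous-cap thicknesses are drawn (spans the ~13 px thin-cap regime).
#' @param calcium_thickness_range_px interval for the calcific core extent.
#' @param lesion_arc_range_alines,lesion_len_range_frames intervals for the
#'   angular arc and frame extent of a lesion block in the en-face plane.
#' @param coverage_fibrocalcific,coverage_fibrolipidic target fraction of
#'   A-lines covered by each lesion class; the defaults (1/6 each) leave
#'   roughly two thirds "other", so inverse-proportion class weights come
#'   out around (4, 4, 1).
#' @param speckle_shape gamma shape of the unit-mean multiplicative speckle;
#'   larger means less noise, `Inf` disables speckle.
#' @param profile list of class-conditional profile parameters, see
#'   [generate_aline_profile()].
#' @param seed integer RNG seed; identical (config, seed) pairs generate
#'   bit-identical pullbacks.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_frames = 40L,
                       n_alines = 448L,
                       depth_px = 968L,
                       axial_um_per_px = 5,
                       frame_pitch_mm = 0.2,
                       lumen_radius_base_px = 120,
                       lumen_eccentricity_px = 30,
                       guidewire_width_alines = 24L,
                       cap_thickness_range_px = c(10, 60),
                       calcium_thickness_range_px = c(60, 150),
                       lesion_arc_range_alines = NULL,
                       lesion_len_range_frames = NULL,
                       coverage_fibrocalcific = 1 / 6,
                       coverage_fibrolipidic = 1 / 6,
                       speckle_shape = 2,
                       profile = list(),
                       seed = 1L) {
  lesion_arc_range_alines <- lesion_arc_range_alines %||%
    round(c(0.1, 0.3) * n_alines)
  lesion_len_range_frames <- lesion_len_range_frames %||%
    pmax(1, round(c(0.2, 0.6) * n_frames))
  cfg <- list(
    n_frames = as.integer(n_frames), n_alines = as.integer(n_alines),
    depth_px = as.integer(depth_px),
    axial_um_per_px = axial_um_per_px, frame_pitch_mm = frame_pitch_mm,
    lumen_radius_base_px = lumen_radius_base_px,
    lumen_eccentricity_px = lumen_eccentricity_px,
    guidewire_width_alines = as.integer(guidewire_width_alines),
    cap_thickness_range_px = cap_thickness_range_px,
    calcium_thickness_range_px = calcium_thickness_range_px,
    lesion_arc_range_alines = lesion_arc_range_alines,
    lesion_len_range_frames = lesion_len_range_frames,
    coverage_fibrocalcific = coverage_fibrocalcific,
    coverage_fibrolipidic = coverage_fibrolipidic,
    speckle_shape = speckle_shape,
    profile = utils::modifyList(default_profile_params(), profile),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

# Class-conditional profile parameters, 16-bit intensity scale.
default_profile_params <- function() {
  list(
    fibrous_level = 12000,     # bright homogeneous fibrous plateau
    calcium_level = 1200,      # signal-poor calcific core
    behind_calcium_level = 6000, # partial signal recovery behind calcium
    sharp_border_px = 1,       # calcific border transition width (<= 2 px)
    lipid_decay_px = 15,       # fast drop-off inside lipid
    diffuse_border_px = 12,    # lipid border transition width (>= 10 px)
    other_level = 9000,        # surface level of normal wall
    other_decay_px = 70,       # moderate decay of normal wall
    layer_banding = TRUE,      # intima/media/adventitia banding for "other"
    media_start_px = 50, media_width_px = 25, media_factor = 0.55,
    adventitia_factor = 0.9,
    floor_level = 60,          # detector noise floor
    lumen_level = 90,          # blood-cleared lumen interior
    level_jitter = 0.1         # per-A-line relative amplitude jitter
  )
}

validate_sim_config <- function(cfg) {
  for (f in c("n_frames", "n_alines", "depth_px", "guidewire_width_alines")) {
    if (!is_count(cfg[[f]])) stopf("sim_config: '%s' must be a count >= 1", f)
  }
  if (cfg$cap_thickness_range_px[1] < 0 ||
      cfg$cap_thickness_range_px[2] >= cfg$depth_px ||
      diff(cfg$cap_thickness_range_px) < 0) {
    stopf("sim_config: cap_thickness_range_px must lie within [0, depth_px)")
  }
  for (f in c("coverage_fibrocalcific", "coverage_fibrolipidic")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) stopf("sim_config: '%s' must be in [0,1]", f)
  }
  if (cfg$coverage_fibrocalcific + cfg$coverage_fibrolipidic >= 1) {
    stopf("sim_config: lesion coverages must sum to < 1")
  }
  if (!is.numeric(cfg$speckle_shape) || cfg$speckle_shape <= 0) {
    stopf("sim_config: speckle_shape must be > 0")
  }
  if (cfg$depth_px < 200) stopf("sim_config: depth_px must be >= 200")
  invisible(cfg)
}

#' Generate one clean (noise-free) A-line intensity profile
#'
#' Returns the radial intensity profile of the tissue beyond the lumen
#' boundary for one plaque class. Fibrocalcific profiles are a bright
#' fibrous plateau of `cap_px` samples followed by a step drop (transition
#' width <= 2 px) into a signal-poor calcific core with a sharp back border;
#' fibrolipidic profiles follow the plateau with a fast exponential signal
#' drop-off blended over a diffuse (>= 10 px) border; "other" profiles decay
#' moderately from the surface with optional three-layer
#' (intima/media/adventitia) banding.
#'
#' @param class_label one of `"fibrocalcific"`, `"fibrolipidic"`, `"other"`.
#' @param depth_px length of the returned profile (>= 200).
#' @param params profile parameter list, see [default_profile_params()]
#'   entries in [sim_config()].
#' @param cap_px fibrous-cap thickness in pixels (ignored for "other").
#' @param calcium_px calcific core extent (fibrocalcific only).
#' @param jitter if `TRUE`, apply a small random relative amplitude jitter
#'   (uses the current RNG stream).
#' @param pure_exponential if `TRUE` with class "other", disable banding and
#'   the floor so the profile is exactly `A * exp(-k / decay)`.
#' @return numeric vector of length `depth_px` with attributes `borders`
#'   (radial indices, 0-based, of the class-defining borders) and `cap_px`.
#' @export
generate_aline_profile <- function(class_label, depth_px, params = default_profile_params(),
                                   cap_px = 20, calcium_px = 100,
                                   jitter = FALSE, pure_exponential = FALSE) {
  if (!is.character(class_label) || length(class_label) != 1L ||
      !class_label %in% PLAQUE_CLASSES) {
    stopf("generate_aline_profile: unknown class label '%s' (expected one of %s)",
          paste(class_label, collapse = ","), paste(PLAQUE_CLASSES, collapse = ", "))
  }
  if (depth_px < 200) stopf("generate_aline_profile: depth_px must be >= 200")
  k <- seq_len(depth_px) - 1 # 0-based radial index from the lumen boundary
  amp <- if (jitter) 1 + stats::runif(1, -params$level_jitter, params$level_jitter) else 1

  if (class_label == "other") {
    if (pure_exponential) {
      prof <- params$other_level * exp(-k / params$other_decay_px)
      attr(prof, "borders") <- integer(0)
      attr(prof, "cap_px") <- NA_integer_
      return(prof)
    }
    prof <- amp * params$other_level * exp(-k / params$other_decay_px)
    if (isTRUE(params$layer_banding)) {
      # darker media band sandwiched between intima and adventitia
      m0 <- params$media_start_px; mw <- params$media_width_px
      band <- ifelse(k >= m0 & k < m0 + mw, params$media_factor,
                     ifelse(k >= m0 + mw, params$adventitia_factor, 1))
      prof <- prof * band
    }
    prof <- pmax(prof, params$floor_level)
    attr(prof, "borders") <- integer(0)
    attr(prof, "cap_px") <- NA_integer_
    return(prof)
  }

  cap_px <- max(1L, round(cap_px))
  if (class_label == "fibrocalcific") {
    calcium_px <- max(2L, round(calcium_px))
    front <- cap_px
    back <- min(cap_px + calcium_px, depth_px - 1L)
    w <- max(params$sharp_border_px, .Machine$double.eps)
    # logistic steps of width <= 2 px at the front and back calcium borders
    step_front <- 1 / (1 + exp((k - front + 0.5) / (w / 4)))
    step_back <- 1 / (1 + exp((k - back + 0.5) / (w / 4)))
    plateau <- amp * params$fibrous_level
    low <- params$calcium_level
    behind <- params$behind_calcium_level * exp(-pmax(k - back, 0) / params$other_decay_px)
    prof <- plateau * step_front + (1 - step_front) * (low * step_back + (1 - step_back) * behind)
    prof <- pmax(prof, params$floor_level)
    attr(prof, "borders") <- c(front, back)
    attr(prof, "cap_px") <- cap_px
    return(prof)
  }

  # fibrolipidic: plateau, then fast decay entered through a diffuse border
  w <- max(params$diffuse_border_px, 1) / 4
  blend <- 1 / (1 + exp((k - cap_px) / w)) # ~1 inside the cap, ~0 in lipid
  decay <- exp(-pmax(k - cap_px, 0) / params$lipid_decay_px)
  prof <- amp * params$fibrous_level * (blend + (1 - blend) * decay)
  prof <- pmax(prof, params$floor_level)
  attr(prof, "borders") <- cap_px
  attr(prof, "cap_px") <- cap_px
  prof
}

#' Apply unit-mean multiplicative gamma speckle
#'
#' Multiplies each sample by an i.i.d. gamma variate with shape
#' `speckle_shape` and mean 1, so the expected profile is preserved and the
#' noise is log-stabilisable. `speckle_shape = Inf` returns the input
#' unchanged (degenerate m = 1).
#'
#' @param profile non-negative numeric vector or matrix.
#' @param speckle_shape gamma shape parameter (> 0); SNR grows with shape.
#' @return noisy profile of the same shape.
#' @export
apply_speckle <- function(profile, speckle_shape) {
  if (!is.numeric(speckle_shape) || length(speckle_shape) != 1L || speckle_shape <= 0) {
    stopf("apply_speckle: speckle_shape must be a positive scalar")
  }
  if (any(profile < 0)) stopf("apply_speckle: profile must be non-negative")
  if (is.infinite(speckle_shape)) return(profile)
  m <- stats::rgamma(length(profile), shape = speckle_shape, rate = speckle_shape)
  out <- profile * m
  if (is.matrix(profile)) dim(out) <- dim(profile)
  out
}

# Place lesion blocks of one class into the label grid. Blocks are
# rectangles in (theta, z) with per-frame arc jitter; theta wraps. Existing
# non-"other" labels are never overwritten, and the lesion count is chosen
# from a Poisson-coverage argument so the realised coverage tracks the
# target despite overlaps.
place_lesions <- function(labels, class_label, target_cov, cfg, lesion_params) {
  n_al <- cfg$n_alines; n_fr <- cfg$n_frames
  if (target_cov <= 0) return(list(labels = labels, lesions = list()))
  avail <- mean(labels == "other")
  p_eff <- min(0.95, target_cov / max(avail, 1e-9))
  mean_area <- mean(cfg$lesion_arc_range_alines) * mean(cfg$lesion_len_range_frames)
  n_lesions <- max(1L, round(-log(1 - p_eff) * n_al * n_fr / mean_area))
  lesions <- vector("list", n_lesions)
  for (i in seq_len(n_lesions)) {
    arc <- round(stats::runif(1, cfg$lesion_arc_range_alines[1], cfg$lesion_arc_range_alines[2]))
    len <- round(stats::runif(1, cfg$lesion_len_range_frames[1], cfg$lesion_len_range_frames[2]))
    len <- min(len, n_fr)
    th0 <- sample.int(n_al, 1)
    z0 <- sample.int(max(1L, n_fr - len + 1L), 1)
    cap <- round(stats::runif(1, cfg$cap_thickness_range_px[1], cfg$cap_thickness_range_px[2]))
    calc <- round(stats::runif(1, cfg$calcium_thickness_range_px[1], cfg$calcium_thickness_range_px[2]))
    for (z in z0:(z0 + len - 1L)) {
      jit <- round(stats::rnorm(2, 0, 0.05 * arc)) # ragged block edges
      a0 <- th0 + jit[1]; a1 <- th0 + arc - 1L + jit[2]
      if (a1 < a0) a1 <- a0
      cols <- wrap_idx(a0:a1, n_al)
      keep <- labels[cols, z] == "other"
      labels[cols[keep], z] <- class_label
    }
    lesions[[i]] <- list(class = class_label, theta0 = th0, arc = arc,
                         z0 = z0, len = len, cap_px = cap, calcium_px = calc)
  }
  list(labels = labels, lesions = lesions)
}

#' Generate a synthetic pullback with exact ground truth
#'
#' Renders a full polar-domain pullback under a [sim_config()]: smoothly
#' varying eccentric lumen, drifting guidewire shadow, blocky lesion regions
#' in the en-face plane, class-conditional A-line profiles, and
#' multiplicative speckle. Identical (config, seed) pairs are bit-identical.
#'
#' @param config a [sim_config()].
#' @param pullback_id identifier stored in the output.
#' @return a list with elements `pullback` (class `oct_pullback`: `frames`
#'   list of depth x n_alines integer matrices plus metadata) and `truth`
#'   (class `oct_ground_truth`: `labels` and `lumen` as n_alines x n_frames
#'   matrices, `guidewire` logical matrix, `lesions` list).
#' @export
generate_pullback <- function(config, pullback_id = sprintf("sim-%04d", config$seed)) {
  validate_sim_config(config)
  if (max(config$lesion_len_range_frames) > config$n_frames) {
    stopf("generate_pullback: lesion frame extent exceeds n_frames")
  }
  if (max(config$lesion_arc_range_alines) > config$n_alines) {
    stopf("generate_pullback: lesion arc exceeds n_alines")
  }
  with_seed(config$seed, {
    n_al <- config$n_alines; n_fr <- config$n_frames; depth <- config$depth_px
    pp <- config$profile

    # --- labels -----------------------------------------------------------
    labels <- matrix("other", n_al, n_fr)
    fc <- place_lesions(labels, "fibrocalcific", config$coverage_fibrocalcific, config, pp)
    fl <- place_lesions(fc$labels, "fibrolipidic", config$coverage_fibrolipidic, config, pp)
    labels <- fl$labels
    lesions <- c(fc$lesions, fl$lesions)

    # per-A-line lesion geometry (cap / calcium thickness maps)
    cap_map <- matrix(NA_real_, n_al, n_fr)
    calc_map <- matrix(NA_real_, n_al, n_fr)
    for (les in lesions) {
      for (z in les$z0:(les$z0 + les$len - 1L)) {
        cols <- wrap_idx(les$theta0:(les$theta0 + les$arc - 1L), n_al)
        sel <- cols[labels[cols, z] == les$class]
        cap_map[sel, z] <- les$cap_px
        calc_map[sel, z] <- les$calcium_px
      }
    }

    # --- lumen geometry: smooth in theta, slow drift in z -----------------
    theta <- 2 * pi * (seq_len(n_al) - 1) / n_al
    phase <- cumsum(stats::rnorm(n_fr, 0, 0.15))
    base_z <- config$lumen_radius_base_px +
      config$lumen_eccentricity_px * 0.3 * sin(2 * pi * seq_len(n_fr) / max(n_fr, 2))
    lumen <- matrix(0L, n_al, n_fr)
    for (z in seq_len(n_fr)) {
      r <- base_z[z] + config$lumen_eccentricity_px * sin(theta + phase[z])
      lumen[, z] <- as.integer(round(pmin(pmax(r, 2), depth - 202)))
    }

    # --- guidewire shadow: contiguous arc drifting across frames ----------
    gw_start <- sample.int(n_al, 1)
    drift <- round(cumsum(stats::rnorm(n_fr, 0, 1.5)))
    guidewire <- matrix(FALSE, n_al, n_fr)
    for (z in seq_len(n_fr)) {
      cols <- wrap_idx((gw_start + drift[z]):(gw_start + drift[z] + config$guidewire_width_alines - 1L), n_al)
      guidewire[cols, z] <- TRUE
    }
    labels[guidewire] <- "guidewire"

    # --- render frames ----------------------------------------------------
    frames <- vector("list", n_fr)
    for (z in seq_len(n_fr)) {
      fr <- matrix(pp$floor_level, depth, n_al)
      for (a in seq_len(n_al)) {
        lab <- labels[a, z]
        rad <- lumen[a, z]
        if (lab == "guidewire") next # shadow: stays at the noise floor
        tissue_len <- depth - rad - 1L
        prof <- generate_aline_profile(
          if (lab == "guidewire") "other" else lab,
          max(200L, tissue_len), pp,
          cap_px = cap_map[a, z] %|na|% 25,
          calcium_px = calc_map[a, z] %|na|% 100,
          jitter = TRUE
        )[seq_len(tissue_len)]
        col <- fr[, a]
        if (rad >= 1L) col[seq_len(rad)] <- pp$lumen_level
        col[rad + 1L] <- 0.6 * prof[1] # ramp sample at the boundary itself
        col[(rad + 2L):depth] <- prof
        fr[, a] <- col
      }
      fr <- apply_speckle(fr, config$speckle_shape)
      fr[, guidewire[, z]] <- fr[, guidewire[, z], drop = FALSE] * 0.05
      storage.mode(fr) <- "integer"
      fr[fr < 0L] <- 0L; fr[fr > 65535L] <- 65535L
      frames[[z]] <- fr
    }

    pullback <- structure(list(
      frames = frames, pullback_id = pullback_id,
      axial_um_per_px = config$axial_um_per_px,
      frame_pitch_mm = config$frame_pitch_mm,
      n_alines = n_al, depth_px = depth
    ), class = "oct_pullback")
    truth <- structure(list(
      labels = labels, lumen = lumen, guidewire = guidewire, lesions = lesions
    ), class = "oct_ground_truth")
    list(pullback = pullback, truth = truth)
  })
}

`%|na|%` <- function(a, b) if (length(a) == 1L && is.na(a)) b else a

#' @export
print.oct_pullback <- function(x, ...) {
  cat(sprintf("<oct_pullback '%s': %d frames of %d x %d (depth x A-lines), %g um/px axial>\n",
              x$pullback_id, length(x$frames), x$depth_px, x$n_alines, x$axial_um_per_px))
  invisible(x)
}

#' @export
print.oct_ground_truth <- function(x, ...) {
  tab <- table(factor(x$labels, levels = LABEL_LEVELS))
  cat("<oct_ground_truth> label counts:\n")
  print(tab)
  invisible(x)
}
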