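# On-disk formats.
#
# Pullbacks travel as multi-page 16-bit grayscale TIFF (one page per frame,
# rows = r, columns = theta) plus a JSON sidecar with metadata and config
# echo. No TIFF library is available in this R stack, so a minimal
# uncompressed little-endian baseline-TIFF subset (grayscale, 16-bit, one
# strip per page) is implemented here with readBin/writeBin; it
# round-trips its own output bit-exactly and is readable by standard tools.
# Ground truth and en-face maps are CSV; model checkpoints are JSON.

TIFF_TAGS <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, samples = 277L,
               rows_per_strip = 278L, strip_bytes = 279L)

#' Write a pullback as multi-page 16-bit TIFF + JSON sidecar
#'
#' @param pullback an `oct_pullback`.
#' @param tiff_path,json_path output paths.
#' @param extra named list merged into the sidecar (e.g. config echo,
#'   seed).
#' @return invisibly, the two paths.
#' @export
write_pullback <- function(pullback, tiff_path, json_path, extra = list()) {
  frames <- pullback$frames
  n <- length(frames)
  depth <- nrow(frames[[1L]]); width <- ncol(frames[[1L]])
  con <- file(tiff_path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  n_tags <- 9L
  ifd_size <- 2L + 12L * n_tags + 4L
  data_bytes <- 2L * depth * width
  # layout: header(8) | page1 data | page1 IFD | page2 data | ...
  offs_data <- 8L + (seq_len(n) - 1L) * (data_bytes + ifd_size)
  offs_ifd <- offs_data + data_bytes
  writeBin(offs_ifd[1L], con, size = 4, endian = "little") # first IFD pointer
  for (i in seq_len(n)) {
    fr <- frames[[i]]
    if (any(fr < 0) || any(fr > 65535)) stopf("write_pullback: intensities outside 16-bit range")
    writeBin(as.integer(t(fr)), con, size = 2, endian = "little", useBytes = TRUE)
    tags <- list(
      c(TIFF_TAGS[["width"]], 3L, 1L, width),
      c(TIFF_TAGS[["height"]], 3L, 1L, depth),
      c(TIFF_TAGS[["bits"]], 3L, 1L, 16L),
      c(TIFF_TAGS[["compression"]], 3L, 1L, 1L),
      c(TIFF_TAGS[["photometric"]], 3L, 1L, 1L),
      c(TIFF_TAGS[["strip_offsets"]], 4L, 1L, offs_data[i]),
      c(TIFF_TAGS[["samples"]], 3L, 1L, 1L),
      c(TIFF_TAGS[["rows_per_strip"]], 3L, 1L, depth),
      c(TIFF_TAGS[["strip_bytes"]], 4L, 1L, data_bytes)
    )
    writeBin(n_tags, con, size = 2, endian = "little")
    for (tg in tags) {
      writeBin(tg[1L], con, size = 2, endian = "little")
      writeBin(tg[2L], con, size = 2, endian = "little")
      writeBin(tg[3L], con, size = 4, endian = "little")
      if (tg[2L] == 3L) { # SHORT value, left-justified in the 4-byte slot
        writeBin(tg[4L], con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(tg[4L], con, size = 4, endian = "little")
      }
    }
    writeBin(if (i < n) offs_ifd[i + 1L] else 0L, con, size = 4, endian = "little")
  }
  meta <- utils::modifyList(list(
    pullback_id = pullback$pullback_id,
    axial_um_per_px = pullback$axial_um_per_px,
    frame_pitch_mm = pullback$frame_pitch_mm,
    n_frames = n, n_alines = width, depth_px = depth
  ), extra)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tiff_path, json_path))
}

#' Read a pullback written by [write_pullback()]
#'
#' @param tiff_path,json_path input paths.
#' @return an `oct_pullback`.
#' @export
read_pullback <- function(tiff_path, json_path) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  for (key in c("pullback_id", "axial_um_per_px", "frame_pitch_mm")) {
    if (is.null(meta[[key]])) stopf("read_pullback: sidecar missing key '%s'", key)
  }
  raw <- readBin(tiff_path, "raw", n = file.size(tiff_path))
  if (rawToChar(raw[1:2]) != "II") stopf("read_pullback: not a little-endian TIFF")
  u16 <- function(off) readBin(raw[off + 1:2], "integer", size = 2, signed = FALSE, endian = "little")
  u32 <- function(off) readBin(raw[off + 1:4], "integer", size = 4, endian = "little")
  ifd <- u32(4L)
  frames <- list()
  shape <- NULL
  while (ifd != 0L) {
    n_tags <- u16(ifd)
    ent <- list()
    for (k in seq_len(n_tags)) {
      base <- ifd + 2L + (k - 1L) * 12L
      tag <- u16(base); typ <- u16(base + 2L)
      val <- if (typ == 3L) u16(base + 8L) else u32(base + 8L)
      ent[[as.character(tag)]] <- val
    }
    width <- ent[["256"]]; height <- ent[["257"]]
    if (is.null(width) || is.null(height)) stopf("read_pullback: page missing size tags")
    if ((ent[["258"]] %||% 16L) != 16L) stopf("read_pullback: only 16-bit supported")
    if ((ent[["259"]] %||% 1L) != 1L) stopf("read_pullback: compressed TIFF not supported")
    off <- ent[["273"]]
    nb <- ent[["279"]] %||% (2L * width * height)
    px <- readBin(raw[off + seq_len(nb)], "integer", n = width * height,
                  size = 2, signed = FALSE, endian = "little")
    fr <- matrix(px, nrow = height, ncol = width, byrow = TRUE)
    if (is.null(shape)) shape <- dim(fr)
    else if (!identical(shape, dim(fr))) stopf("read_pullback: page shape mismatch")
    frames[[length(frames) + 1L]] <- fr
    ifd <- u32(ifd + 2L + n_tags * 12L)
  }
  structure(list(frames = frames, pullback_id = meta$pullback_id,
                 axial_um_per_px = meta$axial_um_per_px,
                 frame_pitch_mm = meta$frame_pitch_mm,
                 n_alines = shape[2L], depth_px = shape[1L]),
            class = "oct_pullback")
}

#' Write / read ground truth as CSV
#'
#' Columns: `frame_index`, `aline_index` (0-based), `label`,
#' `lumen_radius_px`, `is_guidewire`.
#'
#' @param truth an `oct_ground_truth`.
#' @param path CSV path.
#' @return `write_ground_truth`: invisibly the path; `read_ground_truth`:
#'   an `oct_ground_truth`.
#' @export
write_ground_truth <- function(truth, path) {
  n_al <- nrow(truth$labels); n_fr <- ncol(truth$labels)
  df <- data.frame(
    frame_index = rep(seq_len(n_fr) - 1L, each = n_al),
    aline_index = rep(seq_len(n_al) - 1L, times = n_fr),
    label = as.vector(truth$labels),
    lumen_radius_px = as.vector(truth$lumen),
    is_guidewire = as.integer(as.vector(truth$guidewire))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  n_fr <- max(df$frame_index) + 1L
  n_al <- max(df$aline_index) + 1L
  ord <- order(df$frame_index, df$aline_index)
  df <- df[ord, ]
  structure(list(
    labels = matrix(df$label, n_al, n_fr),
    lumen = matrix(df$lumen_radius_px, n_al, n_fr),
    guidewire = matrix(df$is_guidewire == 1L, n_al, n_fr),
    lesions = NULL
  ), class = "oct_ground_truth")
}

#' Write / read processed A-lines (flat binary matrix + CSV index)
#'
#' The binary file holds the n x 200 value matrix as little-endian
#' float64, row by row; the CSV index carries `pullback_id`, `frame`,
#' `aline` (0-based) and `label` per row.
#'
#' @param processed an `oct_processed`.
#' @param bin_path,csv_path output paths.
#' @return `write_processed`: invisibly the paths; `read_processed`: an
#'   `oct_processed`.
#' @export
write_processed <- function(processed, bin_path, csv_path) {
  con <- file(bin_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(t(processed$values)), con, size = 8, endian = "little")
  utils::write.csv(processed$index, csv_path, row.names = FALSE)
  invisible(c(bin_path, csv_path))
}

#' @rdname write_processed
#' @param n_samples A-line length (default 200).
#' @export
read_processed <- function(bin_path, csv_path, n_samples = 200L) {
  index <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  v <- readBin(bin_path, "double", n = nrow(index) * n_samples, size = 8, endian = "little")
  structure(list(values = matrix(v, nrow(index), n_samples, byrow = TRUE), index = index),
            class = "oct_processed")
}

#' Write / read an en-face probability map as long-format CSV
#'
#' Columns: `aline`, `frame` (0-based), `p_fc`, `p_fl`, `p_other`,
#' `valid`.
#'
#' @param enface an `oct_enface`.
#' @param path CSV path.
#' @return `write_enface_csv`: invisibly the path; `read_enface_csv`: an
#'   `oct_enface`.
#' @export
write_enface_csv <- function(enface, path) {
  n_t <- nrow(enface$valid); n_z <- ncol(enface$valid)
  df <- data.frame(
    aline = rep(seq_len(n_t) - 1L, times = n_z),
    frame = rep(seq_len(n_z) - 1L + enface$frame0, each = n_t),
    p_fc = as.vector(enface$probs[, , 1L]),
    p_fl = as.vector(enface$probs[, , 2L]),
    p_other = as.vector(enface$probs[, , 3L]),
    valid = as.integer(as.vector(enface$valid))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_enface_csv
#' @export
read_enface_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  keep <- df$valid == 1L
  build_enface(as.matrix(df[keep, c("p_fc", "p_fl", "p_other")]),
               df$aline[keep], df$frame[keep], n_alines = max(df$aline) + 1L)
}

#' Save / load a trained model checkpoint (JSON)
#'
#' Single-file JSON checkpoint: config, standardization statistics,
#' training history, best epoch, and per-layer parameter tensors with
#' their dimensions.
#'
#' @param model an `oct_trained_model`.
#' @param path output path.
#' @return `save_model`: invisibly the path; `load_model`: an
#'   `oct_trained_model`.
#' @export
save_model <- function(model, path) {
  layers <- lapply(model$layers, function(l) {
    out <- list(type = l$type)
    if (!is.null(l$pad)) out$pad <- l$pad
    if (!is.null(l$W)) {
      out$W_dim <- dim(l$W) %||% length(l$W)
      out$W <- as.vector(l$W)
      out$b <- as.vector(l$b)
    }
    out
  })
  obj <- list(config = unclass(model$config), stand_stats = model$stand_stats,
              weights = model$weights, history = model$history,
              best_epoch = model$best_epoch, layers = layers)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  class(cfg) <- "net_config"
  layers <- lapply(seq_len(nrow(obj$layers)), function(i) {
    l <- list(type = obj$layers$type[i])
    if (!is.null(obj$layers$pad) && !is.na(obj$layers$pad[i])) l$pad <- obj$layers$pad[i]
    W <- obj$layers$W[[i]]
    if (!is.null(W) && length(W)) {
      l$W <- array(W, unlist(obj$layers$W_dim[[i]]))
      l$b <- as.numeric(obj$layers$b[[i]])
    }
    l
  })
  stats <- obj$stand_stats
  if (!is.null(stats$mean)) stats$mean <- as.numeric(stats$mean)
  if (!is.null(stats$sd)) stats$sd <- as.numeric(stats$sd)
  structure(list(config = cfg, layers = layers,
                 shape = if (cfg$arch == "cnn") cnn_shape(cfg) else NULL,
                 stand_stats = stats, weights = as.numeric(obj$weights),
                 history = obj$history, best_epoch = obj$best_epoch),
            class = c("oct_trained_model", "oct_model"))
}

#' Render an en-face label map to PNG
#'
#' Palette: red (fibrocalcific), green (fibrolipidic), blue (other), black
#' (guidewire). Requires a PNG-capable graphics device.
#'
#' @param labels integer label matrix (1..4).
#' @param path output path.
#' @return invisibly the path.
#' @export
write_enface_png <- function(labels, path) {
  if (!capabilities("png")) stopf("write_enface_png: no PNG device available")
  pal <- c("red", "green", "blue", "black")
  grDevices::png(path, width = ncol(labels) * 4L, height = nrow(labels) * 2L)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::image(t(labels)[, rev(seq_len(nrow(labels))), drop = FALSE],
                  col = pal, zlim = c(1, 4), axes = FALSE, useRaster = TRUE)
  invisible(path)
}
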