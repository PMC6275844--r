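# Guided backpropagation saliency: which input samples drive a class
# activation. The backward pass starts from the chosen class's pre-softmax
# activation; at each ReLU the gradient is zeroed where the forward input
# was negative (standard rule) or where the flowing gradient is negative
# (the guided rule). Max-pool routes gradient to the forward argmax (ties
# to the first index).

#' Guided backpropagation saliency for one or more A-lines
#'
#' @param model an `oct_trained_model` (an untrained `oct_model` is
#'   accepted, mainly for analytic checks).
#' @param alines length-200 numeric vector or n x 200 matrix of processed
#'   A-lines (raw, un-standardized; the model's statistics are applied).
#' @param class_index class whose activation is differentiated (1 =
#'   fibrocalcific, 2 = fibrolipidic, 3 = other).
#' @param rectify return `|gradient|` (default) or the signed gradient.
#' @param guided apply the guided ReLU rule; `FALSE` gives the plain input
#'   gradient.
#' @return n x 200 matrix of relevance scores (non-negative when
#'   `rectify`).
#' @export
guided_backprop <- function(model, alines, class_index, rectify = TRUE, guided = TRUE) {
  cfg <- model$config
  if (!is_count(class_index) || class_index > cfg$n_classes) {
    stopf("guided_backprop: class_index must be in 1..%d", cfg$n_classes)
  }
  X <- if (is.vector(alines)) matrix(alines, nrow = 1L) else as.matrix(alines)
  if (ncol(X) != cfg$input_len) {
    stopf("guided_backprop: A-lines have length %d, expected %d", ncol(X), cfg$input_len)
  }
  X <- apply_standardization(X, model$stand_stats)
  fwd <- model_forward(model, X, keep_cache = TRUE)
  dZ <- matrix(0, nrow(X), cfg$n_classes)
  dZ[, class_index] <- 1
  bwd <- model_backward(model, fwd, dZ, guided = guided)
  g <- bwd$dInput
  if (length(dim(g)) == 3L) dim(g) <- dim(g)[1:2]
  if (rectify) abs(g) else g
}

#' Per-frame saliency grid
#'
#' Column-stacks per-A-line saliency maps for one processed frame;
#' guidewire columns are zero.
#'
#' @param model an `oct_trained_model`.
#' @param frame_alines n_alines x 200 matrix of processed A-lines for one
#'   frame (rows in A-line order).
#' @param class_index as in [guided_backprop()].
#' @param guidewire optional logical vector marking guidewire A-lines.
#' @param ... passed to [guided_backprop()].
#' @return 200 x n_alines saliency matrix.
#' @export
frame_saliency <- function(model, frame_alines, class_index, guidewire = NULL, ...) {
  S <- guided_backprop(model, frame_alines, class_index, ...)
  out <- t(S)
  if (!is.null(guidewire)) out[, guidewire] <- 0
  out
}
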