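#' Segmentation result
#'
#' Whole-video label assignment with per-clip provenance: `fine_init`
#' (taken from the fine-level initialisation), `model` (produced by the
#' sequential model) or `filter` (mode-average smoothing).
#'
#' @param labels A [clip_labels()] sequence covering the video.
#' @param provenance Character vector of the same length.
#' @param method Short method tag.
#' @return A list of class `segmentation_result`.
#' @export
segmentation_result <- function(labels, provenance, method) {
  stopifnot(length(labels) == length(provenance))
  structure(list(labels = labels, provenance = provenance, method = method),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %s | %d clips | provenance: %s\n",
              x$method, length(x$labels),
              paste(sprintf("%s=%d", names(table(x$provenance)),
                            as.integer(table(x$provenance))), collapse = ", ")))
  invisible(x)
}

#' @rdname segmentation_result
#' @param x A `segmentation_result`.
#' @param ... Unused.
#' @method tidy segmentation_result
#' @export
tidy.segmentation_result <- function(x, ...) {
  tibble::tibble(clip = seq_along(x$labels) - 1L,
                 label = codes(x$labels),
                 provenance = x$provenance)
}

# accept a seq_model, a surgseq_fit, or a bare function(features, target)
as_predictor <- function(model) {
  if (is.function(model)) return(list(fn = model, config = NULL))
  if (inherits(model, "surgseq_fit")) model <- model$model
  stopifnot(inherits(model, "seq_model"))
  list(fn = function(features, target) predict_window(model, features, target),
       config = model$config)
}

resolve_geometry <- function(pred, window_len, out_len, shift) {
  if (!is.null(pred$config)) {
    cfg <- pred$config
    window_len <- window_len %||% cfg$window_len
    out_len <- out_len %||% cfg$out_len
    shift <- shift %||% cfg$shift
  }
  if (is.null(window_len) || is.null(out_len) || is.null(shift)) {
    abort("window geometry required (pass a seq_model or window_len/out_len/shift)")
  }
  list(window_len = as.integer(window_len), out_len = as.integer(out_len),
       shift = as.integer(shift))
}

#' Time-synchronous whole-video segmentation
#'
#' Tiles the video with consecutive non-overlapping windows of
#' `window_len` clips; each window's decoder target is the fine-level
#' prediction for the same span and the window outputs are concatenated.
#' When the video length is not a multiple of the window, a final window is
#' right-aligned to the video end and clips already covered keep the
#' earlier window's label.
#'
#' @param model A fitted `seq_model`/`surgseq_fit`, or a function
#'   `(features, target) -> label codes` (useful for oracles in tests).
#' @param features Whole-video feature matrix (clips x feature_dim).
#' @param fine_preds Whole-video fine-level [clip_labels()].
#' @param window_len Window length; inferred from the model when possible.
#' @return A [segmentation_result()].
#' @export
segment_time_synchronous <- function(model, features, fine_preds,
                                     window_len = NULL) {
  pred <- as_predictor(model)
  geo <- resolve_geometry(pred, window_len, window_len, 0L)
  wl <- geo$window_len
  n <- nrow(features)
  if (length(fine_preds) != n) abort("fine_preds must cover the whole video")
  if (n < wl) {
    abort(sprintf(paste0("video has %d clips but the window needs %d; ",
                         "use the fine-level predictions directly"), n, wl))
  }
  fine <- codes(fine_preds)
  out <- rep(NA_integer_, n)
  starts <- seq(0L, n - wl, by = wl)
  if (utils::tail(starts, 1L) + wl < n) starts <- c(starts, n - wl)
  for (s in starts) {
    idx <- (s + 1L):(s + wl)
    labs <- pred$fn(features[idx, , drop = FALSE], fine[idx])
    fresh <- idx[is.na(out[idx])]
    out[fresh] <- labs[match(fresh, idx)]
  }
  segmentation_result(clip_labels(out, attr(fine_preds, "clip_len_frames") %||% 16L),
                      rep("model", n), "time_synchronous")
}

#' Time-shifted recursive whole-video segmentation
#'
#' The first `out_len` clips are initialised from the fine-level
#' predictions; windows then advance by `stride` clips (default: the model
#' shift), each using the current working labels of its first `out_len`
#' positions as the decoder target and emitting predictions for its last
#' `out_len` positions. After each window the working labels are updated
#' recursively; the final label of every clip is the mode over all
#' predictions recorded for it (ties to the lowest code).
#'
#' @inheritParams segment_time_synchronous
#' @param stride Window advance in clips (default = shift).
#' @param out_len,shift Geometry; inferred from the model when possible.
#' @param update `"latest"` (default) updates working labels with the most
#'   recent window's predictions during recursion; `"mode"` uses the
#'   running per-clip mode instead.
#' @return A [segmentation_result()].
#' @export
segment_time_shifted <- function(model, features, fine_preds, stride = NULL,
                                 window_len = NULL, out_len = NULL,
                                 shift = NULL, update = c("latest", "mode")) {
  update <- match.arg(update)
  pred <- as_predictor(model)
  geo <- resolve_geometry(pred, window_len, out_len, shift)
  wl <- geo$window_len; ol <- geo$out_len; sh <- geo$shift
  if (sh < 1L) abort("time-shifted segmentation requires shift >= 1")
  stride <- as.integer(stride %||% sh)
  if (stride < 1L) abort("stride must be >= 1")
  if (stride > sh) {
    warn(sprintf(paste0("stride (%d) exceeds the shift (%d): some clips get ",
                        "no model prediction and keep fine-level labels"),
                 stride, sh))
  }
  n <- nrow(features)
  if (length(fine_preds) != n) abort("fine_preds must cover the whole video")
  if (n < wl) {
    abort(sprintf("video has %d clips but the window needs %d", n, wl))
  }
  fine <- codes(fine_preds)
  working <- fine
  candidates <- vector("list", n)
  starts <- seq(0L, n - wl, by = stride)
  if (utils::tail(starts, 1L) < n - wl) starts <- c(starts, n - wl)
  for (s in starts) {
    tgt_idx <- (s + 1L):(s + ol)
    out_idx <- (s + sh + 1L):(s + wl)
    labs <- pred$fn(features[(s + 1L):(s + wl), , drop = FALSE], working[tgt_idx])
    for (j in seq_along(out_idx)) {
      pos <- out_idx[j]
      candidates[[pos]] <- c(candidates[[pos]], labs[j])
      working[pos] <- if (update == "latest") labs[j] else {
        mode_lowest(candidates[[pos]])
      }
    }
  }
  has_model <- !vapply(candidates, is.null, logical(1L))
  final <- fine
  final[has_model] <- vapply(candidates[has_model], mode_lowest, integer(1L))
  prov <- ifelse(has_model, "model", "fine_init")
  segmentation_result(clip_labels(final, attr(fine_preds, "clip_len_frames") %||% 16L),
                      prov, "time_shifted")
}

#' Mode-average filter
#'
#' Sliding-window majority smoother: the output label at position `t` is
#' the mode of the input labels in a centred window of `width` clips
#' (clipped at the sequence bounds; ties to the lowest code). The baseline
#' coarse-level smoother for fine-level predictions.
#'
#' @param labels A [clip_labels()] sequence.
#' @param width Odd window width in clips (default 101).
#' @return A [clip_labels()] sequence.
#' @export
mode_average_filter <- function(labels, width = 101L) {
  width <- as.integer(width)
  if (width < 1L || width %% 2L == 0L) abort("width must be odd and >= 1")
  x <- codes(labels)
  if (width == 1L) return(labels)
  half <- (width - 1L) %/% 2L
  n <- length(x)
  out <- integer(n)
  for (t in seq_len(n)) {
    lo <- max(1L, t - half)
    hi <- min(n, t + half)
    out[t] <- mode_lowest(x[lo:hi])
  }
  clip_labels(out, attr(labels, "clip_len_frames") %||% 16L)
}
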