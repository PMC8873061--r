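#' Phase label vocabulary
#'
#' Laparoscopic sacrocolpopexy is annotated with five surgical phases plus
#' two auxiliary classes. Integer codes are used throughout the package:
#'
#' * `1`–`5`: promontory preparation; dissection of vault and gutter; mesh
#'   fixation to vault; mesh fixation to promontory; peritonealisation.
#' * `6` (`TRANSITION`): the span after one phase ends and before the next
#'   begins. Down-weighted 10x in the training loss and excluded from
#'   macro-averaged metrics.
#' * `0` (`NONPHASE`): before the first phase starts and after the last
#'   phase ends. Excluded from all analysis.
#'
#' @return `phase_vocabulary()` returns a tibble with columns `code`,
#'   `name` and `is_phase`.
#' @export
phase_vocabulary <- function() {
  tibble::tibble(
    code = c(0L, 1L, 2L, 3L, 4L, 5L, 6L),
    name = c("non-phase", "promontory preparation",
             "dissection of vault and gutter", "mesh fixation to vault",
             "mesh fixation to promontory", "peritonealisation",
             "transition"),
    is_phase = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
}

#' @rdname phase_vocabulary
#' @export
PHASE_CODES <- 1:5

#' @rdname phase_vocabulary
#' @export
TRANSITION <- 6L

#' @rdname phase_vocabulary
#' @export
NONPHASE <- 0L

all_codes <- function() c(0L, 1:5, 6L)

validate_codes <- function(x, what = "labels") {
  bad <- which(!(x %in% all_codes()))
  if (length(bad) > 0L) {
    abort(sprintf("%s contain invalid label code %s at position %d",
                  what, x[bad[1L]], bad[1L]))
  }
  invisible(x)
}

#' Frame-level label sequence
#'
#' An ordered vector of phase label codes, one per downsampled video frame.
#'
#' @param labels Integer vector of label codes (see [phase_vocabulary()]).
#' @param fps Frames per second of the downsampled timeline (default 2.4).
#' @return An integer vector of class `frame_labels` with attribute `fps`.
#' @export
frame_labels <- function(labels, fps = 2.4) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) abort("frame label sequence must be non-empty")
  if (!is.numeric(fps) || fps <= 0) abort("fps must be > 0")
  validate_codes(labels, "frame labels")
  structure(labels, fps = fps, class = "frame_labels")
}

#' Clip-level label sequence
#'
#' The atomic unit of coarse-level modelling: one label per clip of
#' `clip_len_frames` consecutive frames (default 16).
#'
#' @param labels Integer vector of label codes.
#' @param clip_len_frames Frames per clip.
#' @return An integer vector of class `clip_labels`.
#' @export
clip_labels <- function(labels, clip_len_frames = 16L) {
  labels <- as.integer(labels)
  if (length(labels) < 1L) abort("clip label sequence must have length >= 1")
  if (clip_len_frames < 1L) abort("clip_len_frames must be >= 1")
  validate_codes(labels, "clip labels")
  structure(labels, clip_len_frames = as.integer(clip_len_frames),
            class = "clip_labels")
}

#' @export
print.frame_labels <- function(x, ...) {
  cat(sprintf("<frame_labels> %d frames @ %.2f fps\n", length(x), attr(x, "fps")))
  print(utils::head(unclass(x), 25L))
  invisible(x)
}

#' @export
print.clip_labels <- function(x, ...) {
  cat(sprintf("<clip_labels> %d clips (%d frames/clip)\n",
              length(x), attr(x, "clip_len_frames")))
  print(utils::head(unclass(x), 25L))
  invisible(x)
}

# strip class/attrs for arithmetic
codes <- function(x) as.integer(unclass(x))
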