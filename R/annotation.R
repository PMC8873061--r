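#' Phase annotation for one procedure
#'
#' Timestamped start / pause / resume / end events for each surgical phase
#' of a single video, as produced by a clinical annotator (or the workflow
#' simulator). Stored as a tibble of events with the video duration and
#' native frame rate as attributes.
#'
#' @param events A data frame with columns `phase_id` (1-5), `event`
#'   (`"start"`, `"pause"`, `"resume"`, `"end"`) and `time_s` (seconds from
#'   video start).
#' @param video_duration_s Total video duration in seconds.
#' @param fps_native Native recording frame rate (default 24).
#' @return A tibble of class `phase_annotation`.
#' @export
phase_annotation <- function(events, video_duration_s, fps_native = 24) {
  events <- tibble::as_tibble(events)
  required <- c("phase_id", "event", "time_s")
  if (!all(required %in% names(events))) {
    abort("events must have columns phase_id, event, time_s")
  }
  events$phase_id <- as.integer(events$phase_id)
  events$event <- as.character(events$event)
  events$time_s <- as.numeric(events$time_s)
  ann <- tibble::new_tibble(events, video_duration_s = as.numeric(video_duration_s),
                            fps_native = as.numeric(fps_native),
                            class = "phase_annotation")
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  ev <- ann
  dur <- attr(ann, "video_duration_s")
  if (!is.numeric(dur) || dur <= 0) abort("video_duration_s must be > 0")
  if (nrow(ev) == 0L) return(invisible(ann))
  if (!all(ev$event %in% c("start", "pause", "resume", "end"))) {
    bad <- which(!(ev$event %in% c("start", "pause", "resume", "end")))[1L]
    abort(sprintf("unknown event kind '%s' (event %d)", ev$event[bad], bad))
  }
  if (!all(ev$phase_id %in% 1:5)) abort("phase_id must be in 1..5")
  if (is.unsorted(ev$time_s)) abort("annotation events must be time-sorted")
  if (any(ev$time_s < 0) || any(ev$time_s > dur)) {
    abort("event times must lie within [0, video_duration_s]")
  }
  # per-phase state machine: start -> (pause -> resume)* -> end
  for (p in unique(ev$phase_id)) {
    kinds <- ev$event[ev$phase_id == p]
    state <- "closed"
    for (k in kinds) {
      ok <- switch(state,
        closed = k == "start",
        open = k %in% c("pause", "end"),
        paused = k == "resume")
      if (!ok) abort(sprintf("phase %d: event '%s' not valid in state '%s'",
                             p, k, state))
      state <- switch(k, start = "open", pause = "paused",
                      resume = "open", end = "closed")
    }
    if (state != "closed") abort(sprintf("phase %d: start not closed by end", p))
  }
  invisible(ann)
}

# active (unpaused) spans [t0, t1) of each phase, plus the overall
# [start, end) envelope; one phase may start/end at most once
phase_spans <- function(ann) {
  out <- list()
  for (p in sort(unique(ann$phase_id))) {
    ev <- ann[ann$phase_id == p, ]
    active <- matrix(numeric(0), ncol = 2)
    open_at <- NA_real_
    for (i in seq_len(nrow(ev))) {
      k <- ev$event[i]; t <- ev$time_s[i]
      if (k %in% c("start", "resume")) open_at <- t
      if (k %in% c("pause", "end")) {
        active <- rbind(active, c(open_at, t))
        open_at <- NA_real_
      }
    }
    out[[as.character(p)]] <- list(
      phase = p,
      envelope = c(min(ev$time_s), max(ev$time_s)),
      active = active
    )
  }
  out
}

#' Convert a phase annotation to per-frame labels
#'
#' Samples the annotation at frame resolution: frame `t` (0-based) is
#' labelled with the phase active at time `t / fps`. Gaps between phases and
#' paused spans of a phase map to `TRANSITION`; time before the first phase
#' start and at/after the last phase end maps to `NONPHASE`.
#'
#' @param ann A [phase_annotation()].
#' @param fps Sampling rate in frames per second (default 2.4).
#' @return A [frame_labels()] sequence of length `floor(duration * fps)`.
#' @export
intervals_to_frame_labels <- function(ann, fps = 2.4) {
  stopifnot(inherits(ann, "phase_annotation"))
  if (!is.numeric(fps) || fps <= 0) abort("fps must be > 0")
  dur <- attr(ann, "video_duration_s")
  n <- floor(dur * fps)
  if (n < 1L) abort("annotation too short for any frame at this fps")
  labs <- rep(NONPHASE, n)
  if (nrow(ann) > 0L) {
    spans <- phase_spans(ann)
    tt <- (seq_len(n) - 1L) / fps
    first_start <- min(vapply(spans, function(s) s$envelope[1L], 0))
    last_end <- max(vapply(spans, function(s) s$envelope[2L], 0))
    inside <- tt >= first_start & tt < last_end
    labs[inside] <- TRANSITION
    claimed <- rep(NA_integer_, n)
    for (s in spans) {
      for (r in seq_len(nrow(s$active))) {
        hit <- tt >= s$active[r, 1L] & tt < s$active[r, 2L]
        collide <- hit & !is.na(claimed) & claimed != s$phase
        if (any(collide)) {
          i <- which(collide)[1L]
          abort(sprintf(
            "overlapping active phases at t=%.3f s: phase %d collides with phase %d",
            tt[i], s$phase, claimed[i]))
        }
        claimed[hit] <- s$phase
        labs[hit] <- s$phase
      }
    }
  }
  frame_labels(labs, fps = fps)
}

#' Collapse frame labels into clip labels
#'
#' Consecutive non-overlapping blocks of `clip_len` frames become clips; the
#' clip label is the modal frame label of the block (ties broken by lowest
#' code). A trailing partial block is dropped.
#'
#' @param fls A [frame_labels()] sequence.
#' @param clip_len Frames per clip (default 16).
#' @return A [clip_labels()] sequence.
#' @export
frames_to_clips <- function(fls, clip_len = 16L) {
  stopifnot(inherits(fls, "frame_labels"))
  clip_len <- as.integer(clip_len)
  if (clip_len < 1L) abort("clip_len must be >= 1")
  n_clips <- length(fls) %/% clip_len
  if (n_clips < 1L) {
    abort(sprintf("need at least %d frames to form one clip, got %d",
                  clip_len, length(fls)))
  }
  x <- codes(fls)[seq_len(n_clips * clip_len)]
  blocks <- matrix(x, nrow = clip_len)
  labs <- apply(blocks, 2L, mode_lowest)
  clip_labels(labs, clip_len_frames = clip_len)
}
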