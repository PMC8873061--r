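#' Read and write annotation and label files
#'
#' Annotations are CSV files with header `phase_id,event,time_s` (times in
#' seconds, written with at least 3 decimals); label sequences are
#' single-column CSV files of integer label codes (header `label`). Write
#' followed by read is the identity on valid objects.
#'
#' @param ann A [phase_annotation()].
#' @param path File path.
#' @param video_duration_s,fps_native Used on read: duration defaults to the
#'   last event time (rounded up to the next second) when not given.
#' @name workflow_io
NULL

#' @rdname workflow_io
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "phase_annotation"))
  df <- as.data.frame(ann)
  df$time_s <- sprintf("%.3f", df$time_s)
  header <- sprintf("# video_duration_s=%.3f fps_native=%g",
                    attr(ann, "video_duration_s"), attr(ann, "fps_native"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname workflow_io
#' @export
read_annotation <- function(path, video_duration_s = NULL, fps_native = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0L) abort(sprintf("%s: empty file", path))
  offset <- 0L
  if (startsWith(lines[1L], "#")) {
    meta <- lines[1L]
    m <- regmatches(meta, regexec("video_duration_s=([0-9.eE+-]+)", meta))[[1L]]
    if (length(m) == 2L && is.null(video_duration_s)) {
      video_duration_s <- as.numeric(m[2L])
    }
    m <- regmatches(meta, regexec("fps_native=([0-9.eE+-]+)", meta))[[1L]]
    if (length(m) == 2L && is.null(fps_native)) fps_native <- as.numeric(m[2L])
    offset <- 1L
  }
  df <- utils::read.csv(text = lines[(offset + 1L):length(lines)],
                        stringsAsFactors = FALSE)
  if (!all(c("phase_id", "event", "time_s") %in% names(df))) {
    abort(sprintf("%s: expected header phase_id,event,time_s", path))
  }
  bad <- which(!(df$event %in% c("start", "pause", "resume", "end")))
  if (length(bad) > 0L) {
    abort(sprintf("%s: unknown event kind '%s' at line %d",
                  path, df$event[bad[1L]], bad[1L] + offset + 1L))
  }
  if (is.unsorted(df$time_s)) {
    i <- which(diff(df$time_s) < 0)[1L] + 1L
    abort(sprintf("%s: events not time-sorted at line %d", path, i + offset + 1L))
  }
  if (is.null(video_duration_s)) video_duration_s <- ceiling(max(df$time_s))
  if (is.null(fps_native)) fps_native <- 24
  phase_annotation(df, video_duration_s, fps_native)
}

#' @rdname workflow_io
#' @param labels A [clip_labels()] or [frame_labels()] sequence.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(data.frame(label = codes(labels)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname workflow_io
#' @param as Return type for `read_labels`: `"clip"` or `"frame"`.
#' @param ... Passed to [clip_labels()] or [frame_labels()].
#' @export
read_labels <- function(path, as = c("clip", "frame"), ...) {
  as <- match.arg(as)
  df <- utils::read.csv(path)
  x <- df[[1L]]
  bad <- which(!(x %in% all_codes()))
  if (length(bad) > 0L) {
    abort(sprintf("%s: invalid label code %s at line %d", path, x[bad[1L]],
                  bad[1L] + 1L))
  }
  if (as == "clip") clip_labels(x, ...) else frame_labels(x, ...)
}

#' @rdname workflow_io
#' @param features A numeric matrix (clips x feature dimensions).
#' @export
write_features <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_clips=%d feature_dim=%d", nrow(features),
                     ncol(features)), con)
  utils::write.table(features, con, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  invisible(path)
}

#' @rdname workflow_io
#' @export
read_features <- function(path) {
  lines <- readLines(path)
  offset <- if (startsWith(lines[1L], "#")) 1L else 0L
  m <- as.matrix(utils::read.csv(text = lines[(offset + 1L):length(lines)],
                                 header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) abort(sprintf("%s: non-finite feature values", path))
  m
}
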