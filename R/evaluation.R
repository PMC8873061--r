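#' Extract events of one class from a label sequence
#'
#' An event is a maximal run of the class, reported with inclusive 0-based
#' start and stop clip indices.
#'
#' @param labels A label sequence (clip or frame labels, or integer codes).
#' @param class Label code of the class of interest.
#' @return A tibble with columns `class`, `start`, `stop`.
#' @export
extract_events <- function(labels, class) {
  x <- codes(labels)
  r <- rle(x == class)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(class = as.integer(class),
                 start = starts[keep] - 1L,
                 stop = ends[keep] - 1L)
}

overlaps <- function(a_start, a_stop, b_start, b_stop) {
  a_start <= b_stop & b_start <= a_stop
}

#' Event-based Ward scoring of a segmentation
#'
#' Scores each groundtruth event of each phase class against the predicted
#' events of the same class (overlap = sharing at least one clip index):
#'
#' * groundtruth side: `C` correct (one-to-one match), `D` deletion (no
#'   overlapping prediction), `F` fragmentation (split across several
#'   predictions), `M` merge (its single prediction also covers another
#'   groundtruth event), `FM` fragmented and merged;
#' * prediction side: `C` (the same matched pairs), `I'` insertion, `F'`
#'   fragmenting, `M'` merging, `FM'` both.
#'
#' Counts are summed over the scored classes (phases 1-5 by default;
#' transition and non-phase remain in the timeline, separating runs, but
#' are not scored). The event ratio is the number of groundtruth events
#' over the number of predicted events: close to 1 means the number of
#' phase transitions is preserved, close to 0 means over-fragmentation.
#'
#' @param gt,pred Label sequences of equal length.
#' @param classes Integer codes of the scored classes (default `1:5`).
#' @return A list of class `ward_summary` with elements `counts` (named
#'   C, D, F, M, FM, Ip, Fp, Mp, FMp), `n_gt_events`, `n_pred_events`,
#'   `event_ratio` and a per-class tibble `per_class`.
#' @export
ward_score <- function(gt, pred, classes = 1:5) {
  g <- codes(gt); p <- codes(pred)
  if (length(g) != length(p)) {
    abort(sprintf("length mismatch: gt has %d labels, pred has %d",
                  length(g), length(p)))
  }
  cats <- c("C", "D", "F", "M", "FM", "Ip", "Fp", "Mp", "FMp")
  per_class <- list()
  for (cl in classes) {
    ge <- extract_events(g, cl)
    pe <- extract_events(p, cl)
    cnt <- setNames(integer(9L), cats)
    # overlap structure
    gp <- lapply(seq_len(nrow(ge)), function(i) {
      which(overlaps(ge$start[i], ge$stop[i], pe$start, pe$stop))
    })
    pg <- lapply(seq_len(nrow(pe)), function(j) {
      which(overlaps(pe$start[j], pe$stop[j], ge$start, ge$stop))
    })
    for (i in seq_len(nrow(ge))) {
      ps <- gp[[i]]
      merged <- any(vapply(ps, function(j) length(pg[[j]]) > 1L, logical(1L)))
      cat_i <- if (length(ps) == 0L) "D"
        else if (length(ps) > 1L && merged) "FM"
        else if (length(ps) > 1L) "F"
        else if (merged) "M"
        else "C"
      cnt[[cat_i]] <- cnt[[cat_i]] + 1L
    }
    for (j in seq_len(nrow(pe))) {
      gs <- pg[[j]]
      fragged <- any(vapply(gs, function(i) length(gp[[i]]) > 1L, logical(1L)))
      cat_j <- if (length(gs) == 0L) "Ip"
        else if (length(gs) > 1L && fragged) "FMp"
        else if (length(gs) > 1L) "Mp"
        else if (fragged) "Fp"
        else NA_character_  # matched pair; C already counted on the GT side
      if (!is.na(cat_j)) cnt[[cat_j]] <- cnt[[cat_j]] + 1L
    }
    per_class[[length(per_class) + 1L]] <- tibble::tibble(
      class = as.integer(cl), !!!as.list(cnt),
      n_gt_events = nrow(ge), n_pred_events = nrow(pe))
  }
  per_class <- dplyr::bind_rows(per_class)
  counts <- as.list(colSums(per_class[cats]))
  n_gt <- sum(per_class$n_gt_events)
  n_pred <- sum(per_class$n_pred_events)
  ratio <- if (n_pred == 0L) 0 else n_gt / n_pred
  structure(list(counts = counts, n_gt_events = n_gt, n_pred_events = n_pred,
                 event_ratio = ratio, per_class = per_class),
            class = "ward_summary")
}

#' @export
print.ward_summary <- function(x, ...) {
  cat(sprintf("<ward_summary> %d GT events vs %d predicted | event ratio %.3f\n",
              x$n_gt_events, x$n_pred_events, x$event_ratio))
  cat(" GT side:   ", sprintf("C=%d D=%d F=%d M=%d FM=%d", x$counts$C,
                              x$counts$D, x$counts$F, x$counts$M, x$counts$FM), "\n")
  cat(" Pred side: ", sprintf("C=%d I'=%d F'=%d M'=%d FM'=%d", x$counts$C,
                              x$counts$Ip, x$counts$Fp, x$counts$Mp,
                              x$counts$FMp), "\n")
  invisible(x)
}

#' @rdname ward_score
#' @param x A `ward_summary`.
#' @param ... Unused.
#' @method tidy ward_summary
#' @export
tidy.ward_summary <- function(x, ...) x$per_class

#' @rdname ward_score
#' @method glance ward_summary
#' @export
glance.ward_summary <- function(x, ...) {
  tibble::tibble(!!!x$counts, n_gt_events = x$n_gt_events,
                 n_pred_events = x$n_pred_events,
                 event_ratio = x$event_ratio)
}

#' F1 score from macro precision and recall
#'
#' Harmonic mean `2PR / (P + R)`, with P and R in percent and the result
#' on the 0-1 scale (the convention used in reported workflow results).
#'
#' @param precision,recall Macro-averaged precision and recall in percent.
#' @return F1 on the 0-1 scale.
#' @export
f1_from_pr <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall) / 100
}

#' Frame-based (clip-based) classification metrics
#'
#' Macro-averaged precision and recall over the 5 phases (transition
#' predictions count as errors but the transition class is excluded from
#' the macro average; non-phase positions are excluded entirely), F1 from
#' the macro values, and micro accuracy over positions whose groundtruth
#' is a phase.
#'
#' @param gt,pred Label sequences of equal length.
#' @return A one-row tibble with `macro_precision`, `macro_recall`
#'   (percent), `f1` (0-1) and `micro_accuracy` (percent).
#' @export
frame_metrics <- function(gt, pred) {
  g <- codes(gt); p <- codes(pred)
  if (length(g) != length(p)) {
    abort(sprintf("length mismatch: gt has %d labels, pred has %d",
                  length(g), length(p)))
  }
  keep <- g != NONPHASE
  g <- g[keep]; p <- p[keep]
  phases <- intersect(1:5, unique(g))
  if (length(phases) == 0L) {
    abort("no phase positions in groundtruth: metrics undefined")
  }
  prec <- rec <- numeric(length(phases))
  for (k in seq_along(phases)) {
    cl <- phases[k]
    tp <- sum(g == cl & p == cl)
    prec[k] <- if (sum(p == cl) == 0L) 0 else tp / sum(p == cl)
    rec[k] <- tp / sum(g == cl)
  }
  macro_p <- mean(prec) * 100
  macro_r <- mean(rec) * 100
  phase_pos <- g %in% 1:5
  acc <- sum(g[phase_pos] == p[phase_pos]) / sum(phase_pos) * 100
  tibble::tibble(macro_precision = macro_p, macro_recall = macro_r,
                 f1 = f1_from_pr(macro_p, macro_r), micro_accuracy = acc)
}

#' Row-normalised confusion matrix over phases
#'
#' Rows are the groundtruth phases present in the sequence; columns the
#' predicted classes (phases 1-5, plus any other predicted class that
#' occurs). Each row is divided by that phase's groundtruth count, so rows
#' sum to 1. Groundtruth transition and non-phase positions are excluded.
#'
#' @param gt,pred Label sequences of equal length.
#' @return A numeric matrix with dimnames giving codes.
#' @export
confusion_matrix <- function(gt, pred) {
  g <- codes(gt); p <- codes(pred)
  if (length(g) != length(p)) {
    abort(sprintf("length mismatch: gt has %d labels, pred has %d",
                  length(g), length(p)))
  }
  keep <- g %in% 1:5
  g <- g[keep]; p <- p[keep]
  if (length(g) == 0L) abort("no phase positions in groundtruth")
  rows <- intersect(1:5, unique(g))
  cols <- c(1:5, sort(setdiff(unique(p), 1:5)))
  m <- matrix(0, length(rows), length(cols),
              dimnames = list(gt = as.character(rows),
                              pred = as.character(cols)))
  for (i in seq_along(rows)) {
    sel <- g == rows[i]
    tab <- table(factor(p[sel], levels = cols))
    m[i, ] <- as.numeric(tab) / sum(sel)
  }
  m
}

#' Full evaluation report
#'
#' Frame metrics, Ward summary, and confusion matrix in one call.
#'
#' @param gt,pred Label sequences of equal length.
#' @return A list with `frame` (tibble), `ward` (`ward_summary`) and
#'   `confusion` (matrix).
#' @export
evaluate_segmentation <- function(gt, pred) {
  if (inherits(pred, "segmentation_result")) pred <- pred$labels
  list(frame = frame_metrics(gt, pred),
       ward = ward_score(gt, pred),
       confusion = confusion_matrix(gt, pred))
}
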