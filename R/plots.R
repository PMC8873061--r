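#' @importFrom ggplot2 autoplot ggplot aes geom_rect geom_line geom_col
#'   geom_tile labs theme_minimal scale_fill_brewer scale_fill_gradient
#'   facet_wrap
NULL

#' @export
ggplot2::autoplot

label_runs <- function(x, track) {
  r <- rle(codes(x))
  ends <- cumsum(r$lengths)
  tibble::tibble(track = track, label = r$values,
                 start = ends - r$lengths, stop = ends)
}

#' Phase diagram of groundtruth vs prediction
#'
#' Horizontal bars of the label runs over clip index, one track per
#' sequence, in the style used to inspect whole-video segmentations.
#'
#' @param gt Groundtruth label sequence.
#' @param ... Named predicted sequences (or `segmentation_result`s).
#' @return A ggplot object.
#' @export
plot_phase_diagram <- function(gt, ...) {
  preds <- list(...)
  runs <- label_runs(gt, "groundtruth")
  for (nm in names(preds)) {
    p <- preds[[nm]]
    if (inherits(p, "segmentation_result")) p <- p$labels
    runs <- dplyr::bind_rows(runs, label_runs(p, nm))
  }
  runs$track <- factor(runs$track, levels = rev(unique(runs$track)))
  voc <- phase_vocabulary()
  runs$phase <- factor(voc$name[match(runs$label, voc$code)], levels = voc$name)
  ggplot(runs, aes(xmin = .data$start, xmax = .data$stop,
                   ymin = as.integer(.data$track) - 0.4,
                   ymax = as.integer(.data$track) + 0.4,
                   fill = .data$phase)) +
    geom_rect() +
    ggplot2::scale_y_continuous(breaks = seq_along(levels(runs$track)),
                                labels = levels(runs$track)) +
    labs(x = "clip index", y = NULL, fill = "phase") +
    theme_minimal()
}

#' @rdname segmentation_result
#' @param object A `segmentation_result`.
#' @method autoplot segmentation_result
#' @export
autoplot.segmentation_result <- function(object, ...) {
  plot_phase_diagram(object$labels) +
    labs(title = sprintf("segmentation (%s)", object$method))
}

#' @rdname ward_score
#' @param object A `ward_summary`.
#' @method autoplot ward_summary
#' @export
autoplot.ward_summary <- function(object, ...) {
  cnt <- object$counts
  df <- tibble::tibble(
    side = rep(c("groundtruth events", "predicted events"), c(5L, 5L)),
    category = factor(c("C", "D", "F", "M", "FM",
                        "C", "I'", "F'", "M'", "FM'"),
                      levels = c("C", "D", "I'", "F", "F'", "M", "M'",
                                 "FM", "FM'")),
    count = c(cnt$C, cnt$D, cnt$F, cnt$M, cnt$FM,
              cnt$C, cnt$Ip, cnt$Fp, cnt$Mp, cnt$FMp))
  ggplot(df, aes(x = .data$category, y = .data$count)) +
    geom_col() +
    facet_wrap(~side, scales = "free_x") +
    labs(title = sprintf("Ward event categories (event ratio %.3f)",
                         object$event_ratio),
         x = NULL, y = "events") +
    theme_minimal()
}

#' @rdname train_seq2seq
#' @param object A `surgseq_fit`.
#' @method autoplot surgseq_fit
#' @export
autoplot.surgseq_fit <- function(object, ...) {
  ggplot(object$history, aes(x = .data$step, y = .data$loss)) +
    geom_line() +
    labs(x = "optimisation step", y = "weighted cross-entropy") +
    theme_minimal()
}

#' Heatmap of a phase confusion matrix
#'
#' @param m A matrix from [confusion_matrix()].
#' @return A ggplot object.
#' @export
plot_confusion <- function(m) {
  df <- as.data.frame(as.table(m))
  names(df) <- c("gt", "pred", "fraction")
  ggplot(df, aes(x = .data$pred, y = .data$gt, fill = .data$fraction)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    labs(x = "predicted class", y = "groundtruth phase") +
    theme_minimal()
}
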