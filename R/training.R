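#' Per-class loss weights
#'
#' Surgical phases carry weight 1; the transition class is down-weighted by
#' a factor of 10 to avoid its overestimation; non-phase positions are
#' excluded (weight 0).
#'
#' @param n_classes Number of network output classes (default 6).
#' @param transition_weight Weight of the transition class (default 0.1).
#' @return A numeric vector of length `n_classes` (class columns 1-5 are
#'   phases, column 6 transition).
#' @export
loss_weights <- function(n_classes = 6L, transition_weight = 0.1) {
  w <- rep(1, n_classes)
  if (n_classes >= 6L) w[6L] <- transition_weight
  w
}

weight_for_code <- function(code, w = loss_weights()) {
  out <- numeric(length(code))
  phase <- code %in% 1:5
  out[phase] <- w[code[phase]]
  out[code == TRANSITION] <- if (length(w) >= 6L) w[6L] else 0
  out  # non-phase stays 0
}

#' Weighted cross-entropy loss
#'
#' The sequential-model loss: given softmax outputs `x` and one-hot labels
#' `y` over `t` time steps, batch size `d` and `n` classes,
#' `loss = -(1/(t*d)) * sum_k sum_j sum_i w_i * y[i,j,k] * log(x[i,j,k])`.
#' With `t = 1` this reduces to the per-clip classification loss.
#'
#' @param probs Softmax outputs: a `d x n` matrix (`t = 1`) or a
#'   `t x d x n` array.
#' @param onehot One-hot labels of the same shape.
#' @param w Per-class weights (length `n`), see [loss_weights()].
#' @param eps Probabilities are clamped below at `eps` before the log.
#' @return A nonnegative scalar loss.
#' @export
weighted_cross_entropy <- function(probs, onehot, w, eps = 1e-12) {
  if (is.matrix(probs)) {
    probs <- array(probs, c(1L, dim(probs)))
    onehot <- array(onehot, c(1L, dim(onehot)))
  }
  stopifnot(length(dim(probs)) == 3L, all(dim(probs) == dim(onehot)))
  n <- dim(probs)[3L]
  stopifnot(length(w) == n)
  clamped <- pmax(probs, eps)
  if (any(probs[onehot > 0] < eps)) {
    rlang::inform("weighted_cross_entropy: zero probability at a true class clamped to eps")
  }
  wa <- array(rep(w, each = prod(dim(probs)[1:2])), dim(probs))
  -sum(wa * onehot * log(clamped)) / prod(dim(probs)[1:2])
}

#' Inject label noise into a target sequence
#'
#' Replaces exactly `round(rate * length)` positions, chosen uniformly
#' without replacement, by a label drawn uniformly from the phase +
#' transition vocabulary excluding the original label. This simulates
#' fine-level classification errors during training so the seq2seq decoder
#' learns a filtering action instead of copying its target (exposure bias).
#'
#' @param labels A [clip_labels()] sequence (or integer codes).
#' @param rate Fraction of positions to corrupt, in `[0, 1]` (default 0.4).
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (so a seeded training loop stays reproducible end to end).
#' @return A [clip_labels()] sequence of the same length.
#' @export
inject_noise <- function(labels, rate = 0.4, seed = NULL) {
  if (rate < 0 || rate > 1) abort("rate must be in [0, 1]")
  x <- codes(labels)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  k <- round_half_up(rate * length(x))
  if (k > 0L) {
    pos <- sample.int(length(x), k)
    for (p in pos) {
      pool <- setdiff(1:6, x[p])
      x[p] <- pool[sample.int(length(pool), 1L)]
    }
  }
  clip_labels(x, clip_len_frames = attr(labels, "clip_len_frames") %||% 16L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the decoder target sequence for a training strategy
#'
#' * `baseline`: groundtruth labels.
#' * `noised`: groundtruth with 40% of labels randomly replaced
#'   ([inject_noise()]).
#' * `pred`: the fine-level classifier's predicted labels, which may
#'   preserve internal error structure.
#'
#' @param strategy One of `"baseline"`, `"noised"`, `"pred"`.
#' @param gt Groundtruth [clip_labels()].
#' @param fine_preds Fine-level predicted [clip_labels()] (aligned with `gt`).
#' @param noise_rate Corruption rate for the `noised` strategy.
#' @return A [clip_labels()] target sequence.
#' @export
build_target <- function(strategy, gt, fine_preds = NULL, noise_rate = 0.4) {
  switch(strategy,
    baseline = gt,
    noised = inject_noise(gt, noise_rate),
    pred = {
      if (is.null(fine_preds)) abort("strategy 'pred' requires fine_preds")
      if (length(fine_preds) != length(gt)) {
        abort("gt and fine_preds must be aligned")
      }
      fine_preds
    },
    abort(sprintf("unknown training strategy '%s'", strategy))
  )
}

#' Evenly spaced sliding-window start positions
#'
#' A fixed number of windows is sampled from each video with their interval
#' depending on total video length: starts are evenly spaced over
#' `[0, n_clips - window_len]` (0-based), with the first at 0 and the last
#' flush with the video end.
#'
#' @param n_clips Total clips in the video.
#' @param n_windows Number of windows to sample (default 200).
#' @param window_len Window length in clips (default 100).
#' @return Integer vector of 0-based start indices.
#' @export
sample_window_starts <- function(n_clips, n_windows = 200L, window_len = 100L) {
  if (n_clips < window_len) {
    abort(sprintf("video has %d clips; need at least window_len = %d",
                  n_clips, window_len))
  }
  if (n_windows < 1L) abort("n_windows must be >= 1")
  span <- n_clips - window_len
  if (n_windows == 1L) return(0L)
  i <- seq_len(n_windows) - 1L
  as.integer(round_half_up(i * span / (n_windows - 1L)))
}

#' Training configuration
#'
#' Defaults follow the production recipe: Adam with learning rate `1e-5`
#' decayed by a factor 0.93 every fifth epoch, 200 windows per video,
#' same-index batching across videos, validation 4 times per epoch with
#' best-checkpoint selection, and a 40% noise rate for the `noised`
#' strategy.
#'
#' @param strategy Target-sequence strategy, see [build_target()].
#' @param noise_rate Noise rate for `"noised"` (default 0.4); resampled
#'   fresh at every epoch.
#' @param windows_per_video Sliding windows sampled per video.
#' @param epochs Training epochs.
#' @param lr,lr_decay,decay_every Adam learning-rate schedule.
#' @param validations_per_epoch Validation evaluations per epoch.
#' @param val_windows Windows per validation video used for the accuracy
#'   estimate.
#' @param seed RNG seed for the run.
#' @return A list of class `train_config`.
#' @export
train_config <- function(strategy = c("baseline", "noised", "pred"),
                         noise_rate = 0.4, windows_per_video = 200L,
                         epochs = 1L, lr = 1e-5, lr_decay = 0.93,
                         decay_every = 5L, validations_per_epoch = 4L,
                         val_windows = 8L, seed = 1L) {
  strategy <- match.arg(strategy)
  if (noise_rate < 0 || noise_rate > 1) abort("noise_rate must be in [0, 1]")
  if (windows_per_video < 1L) abort("windows_per_video must be >= 1")
  structure(list(strategy = strategy, noise_rate = noise_rate,
                 windows_per_video = as.integer(windows_per_video),
                 epochs = as.integer(epochs), lr = lr, lr_decay = lr_decay,
                 decay_every = as.integer(decay_every),
                 validations_per_epoch = as.integer(validations_per_epoch),
                 val_windows = as.integer(val_windows),
                 seed = as.integer(seed)),
            class = "train_config")
}

# one Adam step over a named list of parameter matrices
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# supervision vectors (class indices + weights) matching the logits row
# order emitted by fwd_graph
supervision_rows <- function(gt_windows, order, w) {
  Tn <- length(gt_windows[[1L]])
  B <- length(gt_windows)
  if (order == "time_major") {
    flat <- unlist(lapply(seq_len(Tn), function(t) {
      vapply(gt_windows, `[`, integer(1L), t)
    }))
  } else {
    flat <- unlist(gt_windows)
  }
  list(y = class_index(flat), w = weight_for_code(flat, w))
}

window_slices <- function(video, start, cfg) {
  wl <- cfg$window_len
  idx <- (start + 1L):(start + wl)
  gt <- codes(video$labels)[idx]
  fine <- if (!is.null(video$fine_preds)) codes(video$fine_preds)[idx] else NULL
  list(feats = video$features[idx, , drop = FALSE], gt = gt, fine = fine)
}

# target covers window positions 1..out_len; supervision covers positions
# shift+1..window_len (identical spans when shift = 0)
target_and_supervision <- function(slice, mcfg, tcfg) {
  tgt_span <- seq_len(mcfg$out_len)
  sup_span <- (mcfg$shift + 1L):mcfg$window_len
  gt_t <- clip_labels(slice$gt[tgt_span])
  fine_t <- if (!is.null(slice$fine)) clip_labels(slice$fine[tgt_span])
  tgt <- codes(build_target(tcfg$strategy, gt_t, fine_t, tcfg$noise_rate))
  list(target = tgt, gt_sup = slice$gt[sup_span])
}

# deployment-style accuracy on evenly spaced windows of one video: targets
# come from fine-level predictions, accuracy counts positions whose
# groundtruth is one of the 5 phases
eval_video_accuracy <- function(params, mcfg, video, n_windows) {
  model <- structure(list(config = mcfg, params = params), class = "seq_model")
  starts <- sample_window_starts(length(video$labels), n_windows, mcfg$window_len)
  correct <- 0L
  total <- 0L
  for (s in starts) {
    slice <- window_slices(video, s, mcfg)
    tgt <- if (mcfg$arch == "lstm_m2m") NULL else {
      src <- slice$fine %||% slice$gt
      src[seq_len(mcfg$out_len)]
    }
    pred <- predict_window(model, slice$feats, tgt)
    gt_sup <- slice$gt[(mcfg$shift + 1L):mcfg$window_len]
    keep <- gt_sup %in% 1:5
    correct <- correct + sum(pred[keep] == gt_sup[keep])
    total <- total + sum(keep)
  }
  if (total == 0L) return(NA_real_)
  correct / total
}

#' Train a sequential model
#'
#' Runs the sliding-window training loop: from each video a fixed number of
#' evenly spaced windows is sampled, and windows with the same index across
#' videos form one batch (so each batch holds the same relative positions
#' in all videos). The loss is the weighted cross-entropy of the model
#' outputs against the groundtruth labels of the supervised span.
#' Validation micro accuracy (phases only, transition and non-phase
#' excluded) is computed several times per epoch and the parameters with
#' the best accuracy in history are retained.
#'
#' @param videos List of training videos; each a list with elements
#'   `features` (clips x feature_dim matrix), `labels` ([clip_labels()]
#'   groundtruth) and optionally `fine_preds` ([clip_labels()]).
#' @param model A [seq_model()].
#' @param cfg A [train_config()].
#' @param validation Optional list of validation videos (same structure).
#' @return An object of class `surgseq_fit`: the trained model (best
#'   checkpoint when validation data are given), the training history as a
#'   tibble, and summary fields. [tidy()] returns the history;
#'   [glance()] a one-row summary.
#' @export
train_seq2seq <- function(videos, model, cfg, validation = NULL) {
  stopifnot(inherits(model, "seq_model"), inherits(cfg, "train_config"))
  if (length(videos) < 1L) abort("need at least one training video")
  mcfg <- model$config
  set.seed(cfg$seed)
  w <- loss_weights(mcfg$n_classes)
  starts <- lapply(videos, function(v) {
    sample_window_starts(length(v$labels), cfg$windows_per_video, mcfg$window_len)
  })
  params <- model$params
  state <- list(t = 0L,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  history <- list()
  best <- list(acc = -Inf, params = params)
  step <- 0L
  W <- cfg$windows_per_video
  val_every <- max(1L, W %/% max(1L, cfg$validations_per_epoch))
  for (epoch in seq_len(cfg$epochs)) {
    lr_e <- cfg$lr * cfg$lr_decay^((epoch - 1L) %/% cfg$decay_every)
    for (i in sample.int(W)) {
      step <- step + 1L
      feats <- vector("list", length(videos))
      targets <- vector("list", length(videos))
      gts <- vector("list", length(videos))
      for (v in seq_along(videos)) {
        slice <- window_slices(videos[[v]], starts[[v]][i], mcfg)
        ts <- target_and_supervision(slice, mcfg, cfg)
        feats[[v]] <- slice$feats
        targets[[v]] <- ts$target
        gts[[v]] <- ts$gt_sup
      }
      ad_tape_start()
      ps <- params_as_nodes(params, trainable = TRUE)
      res <- fwd_graph(mcfg, ps, feats,
                       if (mcfg$arch == "lstm_m2m") NULL else targets)
      sup <- supervision_rows(gts, res$order, w)
      loss_node <- ad_wce(res$logits, sup$y, sup$w, res$T_out * res$B)
      loss <- as.numeric(ad_value(loss_node))
      if (!is.finite(loss)) {
        ad_tape_stop()
        abort(sprintf("training diverged: non-finite loss at step %d (epoch %d)",
                      step, epoch))
      }
      ad_backward(loss_node)
      grads <- lapply(ps, function(n) n$grad)
      ad_tape_stop()
      upd <- adam_step(params, grads, state, lr_e)
      params <- upd$params
      state <- upd$state
      val_acc <- NA_real_
      if (!is.null(validation) && (step %% val_every == 0L)) {
        accs <- vapply(validation, function(v) {
          eval_video_accuracy(params, mcfg, v, cfg$val_windows)
        }, numeric(1L))
        val_acc <- mean(accs, na.rm = TRUE)
        if (is.finite(val_acc) && val_acc > best$acc) {
          best$acc <- val_acc
          best$params <- params
        }
      }
      history[[step]] <- tibble::tibble(step = step, epoch = epoch,
                                        lr = lr_e, loss = loss,
                                        val_accuracy = val_acc)
    }
  }
  final_params <- if (is.finite(best$acc)) best$params else params
  fitted <- structure(list(config = mcfg, params = final_params),
                      class = "seq_model")
  structure(list(model = fitted, train_config = cfg,
                 history = dplyr::bind_rows(history),
                 best_val_accuracy = if (is.finite(best$acc)) best$acc else NA_real_,
                 final_loss = history[[step]]$loss),
            class = "surgseq_fit")
}

#' @export
print.surgseq_fit <- function(x, ...) {
  cat(sprintf("<surgseq_fit> %s | %d steps | final loss %.4f | best val acc %s\n",
              x$model$config$arch, nrow(x$history), x$final_loss,
              ifelse(is.na(x$best_val_accuracy), "NA",
                     sprintf("%.3f", x$best_val_accuracy))))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname train_seq2seq
#' @param x A `surgseq_fit`.
#' @param ... Unused.
#' @method tidy surgseq_fit
#' @export
tidy.surgseq_fit <- function(x, ...) x$history

#' @rdname train_seq2seq
#' @method glance surgseq_fit
#' @export
glance.surgseq_fit <- function(x, ...) {
  tibble::tibble(arch = x$model$config$arch,
                 steps = nrow(x$history),
                 epochs = max(x$history$epoch),
                 final_loss = x$final_loss,
                 best_val_accuracy = x$best_val_accuracy)
}
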