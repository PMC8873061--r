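#' Feature/prediction emitter configuration
#'
#' Stand-in for the fine-level video backbone: emits a per-clip feature
#' vector and a noisy per-clip label prediction for a given groundtruth
#' clip sequence. Each label class has a fixed mean direction in feature
#' space (drawn once from `mean_seed`, shared across videos); consecutive
#' phase pairs are pulled closer together by `adjacency_shrink` to emulate
#' the confusability of neighbouring phases. Fine-level predictions are
#' corrupted in geometric-length bursts so the error process is temporally
#' correlated, as real clip classifiers are.
#'
#' @param feature_dim Feature dimension (production default 1200; tests use
#'   32).
#' @param class_separation Distance scale between class mean vectors.
#' @param adjacency_shrink Factor in `[0, 1]` pulling consecutive-phase
#'   means toward their midpoint (0 = none).
#' @param noise_sd Isotropic feature noise standard deviation.
#' @param fine_accuracy Target fraction of correct fine-level predictions
#'   (default 0.69, the ballpark of a clip-level 3D-CNN on this procedure).
#' @param error_burst_len Expected run length of erroneous labels.
#' @param seed Per-video seed for noise and error draws.
#' @param mean_seed Seed for the shared class mean directions; keep it
#'   identical across videos of one experiment.
#' @return A list of class `emitter_config`.
#' @export
emitter_config <- function(feature_dim = 1200L, class_separation = 3,
                           adjacency_shrink = 0.3, noise_sd = 1,
                           fine_accuracy = 0.69, error_burst_len = 5,
                           seed = 1L, mean_seed = 42L) {
  if (feature_dim < 2L) abort("feature_dim must be >= 2")
  if (fine_accuracy <= 0 || fine_accuracy > 1) {
    abort("fine_accuracy must be in (0, 1]")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (adjacency_shrink < 0 || adjacency_shrink > 1) {
    abort("adjacency_shrink must be in [0, 1]")
  }
  if (error_burst_len < 1) abort("error_burst_len must be >= 1")
  structure(list(feature_dim = as.integer(feature_dim),
                 class_separation = class_separation,
                 adjacency_shrink = adjacency_shrink, noise_sd = noise_sd,
                 fine_accuracy = fine_accuracy,
                 error_burst_len = error_burst_len,
                 seed = as.integer(seed), mean_seed = as.integer(mean_seed)),
            class = "emitter_config")
}

#' Class mean vectors of the emitter
#'
#' One row per label code 0..6 (row = code + 1): random unit directions
#' scaled by `class_separation`, with consecutive phase pairs (1,2), (2,3),
#' (3,4), (4,5) shrunk toward their pairwise midpoints by
#' `adjacency_shrink`.
#'
#' @param cfg An [emitter_config()].
#' @return A `7 x feature_dim` matrix.
#' @export
class_means <- function(cfg) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$mean_seed)
  m <- matrix(rnorm(7L * cfg$feature_dim), 7L)
  m <- m / sqrt(rowSums(m * m)) * cfg$class_separation
  a <- cfg$adjacency_shrink
  if (a > 0) {
    phases <- m[2:6, , drop = FALSE]  # rows for codes 1..5
    orig <- phases
    for (k in 1:4) {
      mid <- (orig[k, ] + orig[k + 1L, ]) / 2
      phases[k, ] <- phases[k, ] + (a / 2) * (mid - orig[k, ])
      phases[k + 1L, ] <- phases[k + 1L, ] + (a / 2) * (mid - orig[k + 1L, ])
    }
    m[2:6, ] <- phases
  }
  m
}

#' Emit per-clip feature vectors
#'
#' Row `i` is the class mean vector of clip `i`'s label plus isotropic
#' Gaussian noise. Deterministic given `cfg$seed`.
#'
#' @param clips A [clip_labels()] sequence.
#' @param cfg An [emitter_config()].
#' @return An `n_clips x feature_dim` numeric matrix.
#' @export
emit_features <- function(clips, cfg = emitter_config()) {
  if (length(clips) < 1L) abort("clips must be non-empty")
  means <- class_means(cfg)
  set.seed(cfg$seed)
  x <- codes(clips)
  out <- means[x + 1L, , drop = FALSE]
  if (cfg$noise_sd > 0) {
    out <- out + matrix(rnorm(length(out), sd = cfg$noise_sd),
                        nrow(out), ncol(out))
  }
  out
}

# wrong-label draw biased toward phase neighbours of the true label
draw_wrong_label <- function(true) {
  pool <- setdiff(1:6, true)
  wts <- rep(1, length(pool))
  if (true %in% 1:5) {
    wts[pool %in% c(true - 1L, true + 1L) & pool %in% 1:5] <- 3
  }
  pool[sample.int(length(pool), 1L, prob = wts)]
}

#' Emit noisy fine-level label predictions
#'
#' Corrupts the groundtruth clip labels with a two-state Markov error
#' process: erroneous positions occur in geometric-length bursts with mean
#' `error_burst_len`, the stationary error fraction equals
#' `1 - fine_accuracy`, and each burst holds one wrong label drawn among
#' phases + transition with a bias toward phase neighbours. Deterministic
#' given `cfg$seed`.
#'
#' @inheritParams emit_features
#' @return A [clip_labels()] sequence of the same length.
#' @export
emit_fine_predictions <- function(clips, cfg = emitter_config()) {
  if (length(clips) < 1L) abort("clips must be non-empty")
  x <- codes(clips)
  if (cfg$fine_accuracy >= 1) {
    return(clip_labels(x, attr(clips, "clip_len_frames") %||% 16L))
  }
  set.seed(cfg$seed)
  pi_e <- 1 - cfg$fine_accuracy
  q <- 1 / cfg$error_burst_len          # error -> correct
  p <- min(1, q * pi_e / (1 - pi_e))    # correct -> error
  n <- length(x)
  out <- x
  in_error <- runif(1) < pi_e
  held <- if (in_error) draw_wrong_label(x[1L]) else NA_integer_
  for (i in seq_len(n)) {
    if (i > 1L) {
      if (in_error) {
        if (runif(1) < q) {
          in_error <- FALSE
        }
      } else if (runif(1) < p) {
        in_error <- TRUE
        held <- draw_wrong_label(x[i])
      }
    }
    if (in_error) out[i] <- held
  }
  clip_labels(out, attr(clips, "clip_len_frames") %||% 16L)
}

#' Simulate a complete synthetic video
#'
#' Convenience wrapper chaining [simulate_workflow()],
#' [intervals_to_frame_labels()], [frames_to_clips()], [emit_features()]
#' and [emit_fine_predictions()] into the video-record structure consumed
#' by [train_seq2seq()] and the segmenters.
#'
#' @param sim_cfg A [workflow_sim_config()].
#' @param emit_cfg An [emitter_config()].
#' @param clip_len Frames per clip (default 16).
#' @return A list with `annotation`, `labels`, `features`, `fine_preds`.
#' @export
simulate_video <- function(sim_cfg = workflow_sim_config(),
                           emit_cfg = emitter_config(), clip_len = 16L) {
  ann <- simulate_workflow(sim_cfg)
  fls <- intervals_to_frame_labels(ann, fps = sim_cfg$fps)
  clips <- frames_to_clips(fls, clip_len = clip_len)
  feats <- emit_features(clips, emit_cfg)
  fine_cfg <- emit_cfg
  fine_cfg$seed <- derive_seed(emit_cfg$seed, "fine_preds")
  fine <- emit_fine_predictions(clips, fine_cfg)
  list(annotation = ann, labels = clips, features = feats, fine_preds = fine)
}
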