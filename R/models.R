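#' Sequential model configuration
#'
#' Geometry and architecture of the coarse-level temporal models. Two
#' window configurations are supported: *time-synchronous* (target, input
#' and output sequences all cover the same `window_len` clips; `shift = 0`)
#' and *time-shifted* (the decoder target covers the first `out_len` clips
#' of the window and the output the last `out_len`, with
#' `out_len + shift == window_len`), which enables recursive whole-video
#' inference seeded only by the first fine-level predictions.
#'
#' Defaults mirror the production-scale setup: 100-clip windows,
#' `d_model` 1200, 3-layer LSTMs, and a 6-layer 8-head transformer with a
#' 1000-unit feed-forward inner layer and sinusoidal positional encoding.
#' Tests and examples use much smaller geometries.
#'
#' @param arch One of `"lstm_m2m"`, `"lstm_seq2seq"`, `"transformer_seq2seq"`.
#' @param window_len Input window length in clips.
#' @param shift Time shift in clips between target and output (0 for the
#'   time-synchronous configuration, 10 in the canonical time-shifted one).
#' @param out_len Output length in clips; defaults to `window_len - shift`.
#' @param n_classes Output classes (default 6: 5 phases + transition).
#' @param d_model Hidden width / model dimension.
#' @param feature_dim Dimension of the per-clip input feature vectors.
#' @param lstm_layers Stacked LSTM layers (encoder and decoder each).
#' @param tf_layers,tf_heads,ffn_dim Transformer depth, heads, and
#'   feed-forward inner dimension.
#' @param label_embed_dim Dimension of the learned label embedding fed to
#'   the decoder (defaults to `d_model`).
#' @param causal_decoder Keep causal self-attention masking in the
#'   transformer decoder (default `TRUE`).
#' @return A list of class `seq_model_config`.
#' @export
seq_model_config <- function(arch = c("lstm_m2m", "lstm_seq2seq", "transformer_seq2seq"),
                             window_len = 100L, shift = 0L, out_len = NULL,
                             n_classes = 6L, d_model = 1200L,
                             feature_dim = 1200L, lstm_layers = 3L,
                             tf_layers = 6L, tf_heads = 8L, ffn_dim = 1000L,
                             label_embed_dim = NULL, causal_decoder = TRUE) {
  arch <- match.arg(arch)
  window_len <- as.integer(window_len)
  shift <- as.integer(shift)
  if (is.null(out_len)) out_len <- window_len - shift
  out_len <- as.integer(out_len)
  if (shift < 0L || window_len < 1L || out_len < 1L) {
    abort("window_len and out_len must be >= 1 and shift >= 0")
  }
  if (out_len + shift != window_len) {
    abort(sprintf("out_len + shift must equal window_len (got %d + %d != %d)",
                  out_len, shift, window_len))
  }
  if (arch == "lstm_m2m" && shift != 0L) {
    abort("many-to-many models are time-synchronous (shift must be 0)")
  }
  if (arch == "transformer_seq2seq" && d_model %% tf_heads != 0L) {
    abort("d_model must be divisible by tf_heads")
  }
  if (is.null(label_embed_dim)) label_embed_dim <- d_model
  structure(list(arch = arch, window_len = window_len, out_len = out_len,
                 shift = shift, n_classes = as.integer(n_classes),
                 d_model = as.integer(d_model),
                 feature_dim = as.integer(feature_dim),
                 lstm_layers = as.integer(lstm_layers),
                 tf_layers = as.integer(tf_layers),
                 tf_heads = as.integer(tf_heads),
                 ffn_dim = as.integer(ffn_dim),
                 label_embed_dim = as.integer(label_embed_dim),
                 causal_decoder = isTRUE(causal_decoder)),
            class = "seq_model_config")
}

#' Sinusoidal positional encoding
#'
#' Entry `(t, 2i)` is `sin(t / 10000^(2i/d))` and entry `(t, 2i + 1)` is
#' `cos(t / 10000^(2i/d))`, with `t` and `i` 0-based.
#'
#' @param length Number of time steps.
#' @param d Encoding dimension (even, >= 2).
#' @return A `length x d` matrix with entries in `[-1, 1]`.
#' @export
positional_encoding <- function(length, d) {
  if (length < 1L) abort("length must be >= 1")
  if (d < 2L || d %% 2L != 0L) abort("encoding dimension must be even and >= 2")
  t <- seq_len(length) - 1L
  i <- seq_len(d %/% 2L) - 1L
  freq <- 1 / 10000^(2 * i / d)
  ang <- outer(t, freq)
  out <- matrix(0, length, d)
  out[, 2L * i + 1L] <- sin(ang)
  out[, 2L * i + 2L] <- cos(ang)
  out
}

# label code (0..6) -> decoder embedding row, and -> output class column
embed_index <- function(code) as.integer(code) + 1L
class_index <- function(code) {
  idx <- as.integer(code)
  idx[idx == 0L] <- 1L  # non-phase carries weight 0; column is arbitrary
  idx
}
class_to_code <- function(idx) as.integer(idx)  # columns 1..5 phases, 6 transition

#' Build a sequential model
#'
#' Initialises the parameters of the architecture described by `config`
#' (Glorot-uniform weights, zero biases, LSTM forget-gate bias 1).
#'
#' @param config A [seq_model_config()].
#' @param init_seed Seed for parameter initialisation.
#' @return A list of class `seq_model` with elements `config` and `params`.
#' @export
seq_model <- function(config, init_seed = 1L) {
  stopifnot(inherits(config, "seq_model_config"))
  set.seed(init_seed)
  d <- config$d_model
  p <- list()
  if (config$arch == "lstm_m2m") {
    nin <- config$feature_dim
    for (l in seq_len(config$lstm_layers)) {
      p <- init_lstm_layer(p, sprintf("enc%d", l), nin, d)
      nin <- d
    }
    p <- init_linear(p, "head", d, config$n_classes)
  } else if (config$arch == "lstm_seq2seq") {
    nin <- config$feature_dim
    for (l in seq_len(config$lstm_layers)) {
      p <- init_lstm_layer(p, sprintf("enc%d", l), nin, d)
      nin <- d
    }
    p$embed <- glorot(7L, config$label_embed_dim)
    nin <- config$label_embed_dim
    for (l in seq_len(config$lstm_layers)) {
      p <- init_lstm_layer(p, sprintf("dec%d", l), nin, d)
      nin <- d
    }
    p <- init_linear(p, "head", d, config$n_classes)
  } else {
    p <- init_linear(p, "in_proj", config$feature_dim, d)
    for (l in seq_len(config$tf_layers)) {
      p <- init_encoder_layer(p, sprintf("enc%d", l), d, config$ffn_dim)
    }
    p$embed <- glorot(7L, d)
    for (l in seq_len(config$tf_layers)) {
      p <- init_decoder_layer(p, sprintf("dec%d", l), d, config$ffn_dim)
    }
    p <- init_linear(p, "head", d, config$n_classes)
  }
  structure(list(config = config, params = p), class = "seq_model")
}

#' @export
print.seq_model <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, integer(1L)))
  cat(sprintf("<seq_model> %s | window %d -> out %d (shift %d) | d_model %d | %d parameters\n",
              cfg$arch, cfg$window_len, cfg$out_len, cfg$shift, cfg$d_model, n_par))
  invisible(x)
}

params_as_nodes <- function(params, trainable = FALSE) {
  maker <- if (trainable) ad_param else ad_const
  lapply(params, maker)
}

# ---- forward graphs --------------------------------------------------
# Batched input: `feats` is a list over batch items of window_len x
# feature_dim matrices; `targets` a list of integer label-code vectors.
# Returns a single logits node of (out_len * B) rows in time-major order
# (all batch items for t=1, then t=2, ...), plus the layout.

time_major_steps <- function(feats) {
  B <- length(feats)
  Tn <- nrow(feats[[1L]])
  lapply(seq_len(Tn), function(t) {
    ad_const(do.call(rbind, lapply(feats, function(f) f[t, , drop = FALSE])))
  })
}

fwd_graph <- function(cfg, ps, feats, targets = NULL) {
  B <- length(feats)
  if (cfg$arch == "lstm_m2m") {
    xs <- time_major_steps(feats)
    enc <- lstm_stack(ps, "enc", xs, cfg$d_model, cfg$lstm_layers)
    h_all <- ad_rbind(enc$hs)
    logits <- ad_linear(ps, "head", h_all)
    return(list(logits = logits, T_out = cfg$window_len, B = B,
                order = "time_major"))
  }
  if (cfg$arch == "lstm_seq2seq") {
    xs <- time_major_steps(feats)
    enc <- lstm_stack(ps, "enc", xs, cfg$d_model, cfg$lstm_layers)
    T_out <- length(targets[[1L]])
    dec_in <- lapply(seq_len(T_out), function(t) {
      idx <- embed_index(vapply(targets, `[`, integer(1L), t))
      ad_embed(ps$embed, idx)
    })
    dec <- lstm_stack(ps, "dec", dec_in, cfg$d_model, cfg$lstm_layers,
                      states = enc$states)
    h_all <- ad_rbind(dec$hs)
    logits <- ad_linear(ps, "head", h_all)
    return(list(logits = logits, T_out = T_out, B = B,
                order = "time_major"))
  }
  # transformer: per-item graphs (attention is per sequence)
  T_out <- length(targets[[1L]])
  pe_in <- positional_encoding(cfg$window_len, cfg$d_model)
  pe_out <- positional_encoding(T_out, cfg$d_model)
  mask <- if (cfg$causal_decoder) causal_mask(T_out) else NULL
  per_item <- vector("list", B)
  for (b in seq_len(B)) {
    x <- ad_add_const(ad_linear(ps, "in_proj", ad_const(feats[[b]])), pe_in)
    for (l in seq_len(cfg$tf_layers)) {
      x <- transformer_encoder_layer(ps, sprintf("enc%d", l), x, cfg$tf_heads)
    }
    y <- ad_add_const(ad_embed(ps$embed, embed_index(targets[[b]])), pe_out)
    for (l in seq_len(cfg$tf_layers)) {
      y <- transformer_decoder_layer(ps, sprintf("dec%d", l), y, x,
                                     cfg$tf_heads, mask = mask)
    }
    per_item[[b]] <- ad_linear(ps, "head", y)
  }
  list(logits = ad_rbind(per_item), T_out = T_out, B = B,
       order = "item_major")
}

check_features <- function(model, features) {
  cfg <- model$config
  if (!is.matrix(features) || !is.numeric(features)) {
    abort("features must be a numeric matrix")
  }
  if (nrow(features) != cfg$window_len) {
    abort(sprintf("feature window must have %d rows, got %d",
                  cfg$window_len, nrow(features)))
  }
  if (ncol(features) != cfg$feature_dim) {
    abort(sprintf("feature dimension mismatch: expected %d, got %d",
                  cfg$feature_dim, ncol(features)))
  }
}

check_target <- function(model, target) {
  cfg <- model$config
  target <- codes(target)
  if (length(target) != cfg$out_len) {
    abort(sprintf("target length must be %d (out_len), got %d",
                  cfg$out_len, length(target)))
  }
  validate_codes(target, "target labels")
  target
}

#' Forward pass of a many-to-many model
#'
#' @param model A `seq_model` with `arch = "lstm_m2m"`.
#' @param features A `window_len x feature_dim` matrix.
#' @return A `window_len x n_classes` matrix of pre-softmax logits.
#' @export
m2m_forward <- function(model, features) {
  stopifnot(inherits(model, "seq_model"), model$config$arch == "lstm_m2m")
  check_features(model, features)
  ps <- params_as_nodes(model$params)
  res <- fwd_graph(model$config, ps, list(features))
  ad_value(res$logits)
}

#' Forward pass of a seq2seq model
#'
#' Encoder consumes the feature window (plus positional encoding for the
#' transformer); decoder consumes the embedded target label sequence in a
#' single pass (the full target is known, so no autoregressive loop).
#'
#' @param model A `seq_model` with a seq2seq architecture.
#' @param features A `window_len x feature_dim` matrix.
#' @param target A label-code vector of length `out_len`.
#' @return An `out_len x n_classes` matrix of pre-softmax logits.
#' @export
seq2seq_forward <- function(model, features, target) {
  stopifnot(inherits(model, "seq_model"),
            model$config$arch %in% c("lstm_seq2seq", "transformer_seq2seq"))
  check_features(model, features)
  target <- check_target(model, target)
  ps <- params_as_nodes(model$params)
  res <- fwd_graph(model$config, ps, list(features), list(target))
  ad_value(res$logits)
}

#' Predict label codes for one window
#'
#' Runs the appropriate forward pass and takes the arg-max class per output
#' position, mapped back to label codes (1-5 phases, 6 transition).
#'
#' @inheritParams seq2seq_forward
#' @return An integer vector of `out_len` label codes.
#' @export
predict_window <- function(model, features, target = NULL) {
  logits <- if (model$config$arch == "lstm_m2m") {
    m2m_forward(model, features)
  } else {
    seq2seq_forward(model, features, target)
  }
  class_to_code(max.col(logits, ties.method = "first"))
}

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}
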