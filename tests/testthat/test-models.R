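test_that("positional encoding matches the sinusoidal formula", {
  pe <- positional_encoding(10, 8)
  expect_equal(pe[1, seq(1, 7, by = 2)], rep(0, 4))  # sin(0)
  expect_equal(pe[1, seq(2, 8, by = 2)], rep(1, 4))  # cos(0)
  expect_equal(pe[2, 1], sin(1), tolerance = 1e-12)
  expect_equal(pe[2, 2], cos(1), tolerance = 1e-12)
  expect_equal(pe[4, 3], sin(3 / 10000^(2 / 8)), tolerance = 1e-12)
  expect_true(all(pe >= -1 & pe <= 1))
  expect_error(positional_encoding(5, 7), "even")
})

test_that("window geometry is validated at construction", {
  cfg <- seq_model_config("lstm_seq2seq", window_len = 100, shift = 10)
  expect_equal(cfg$out_len, 90L)
  expect_equal(cfg$out_len + cfg$shift, cfg$window_len)
  sync <- seq_model_config("transformer_seq2seq", window_len = 100, shift = 0,
                           d_model = 32, tf_heads = 2)
  expect_equal(sync$out_len, 100L)
  expect_error(seq_model_config("lstm_seq2seq", window_len = 100, shift = 10,
                                out_len = 100), "out_len \\+ shift")
  expect_error(seq_model_config("transformer_seq2seq", d_model = 30,
                                tf_heads = 8), "divisible")
  expect_error(seq_model_config("lstm_m2m", shift = 5), "time-synchronous")
})

tiny_lstm_cfg <- seq_model_config("lstm_seq2seq", window_len = 12, shift = 2,
                                  d_model = 8, feature_dim = 5, lstm_layers = 2)
tiny_tf_cfg <- seq_model_config("transformer_seq2seq", window_len = 12,
                                shift = 2, d_model = 8, feature_dim = 5,
                                tf_layers = 1, tf_heads = 2, ffn_dim = 16)

test_that("forward passes honour shape contracts and are deterministic", {
  set.seed(1)
  X <- matrix(rnorm(12 * 5), 12, 5)
  tgt <- sample(1:5, 10, replace = TRUE)

  m <- seq_model(tiny_lstm_cfg, 1)
  lg <- seq2seq_forward(m, X, tgt)
  expect_equal(dim(lg), c(10L, 6L))
  expect_identical(lg, seq2seq_forward(m, X, tgt))
  # softmax rows normalise
  p <- exp(lg) / rowSums(exp(lg))
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-6)

  mt <- seq_model(tiny_tf_cfg, 2)
  lgt <- seq2seq_forward(mt, X, tgt)
  expect_equal(dim(lgt), c(10L, 6L))
  expect_identical(lgt, seq2seq_forward(mt, X, tgt))

  m2m <- seq_model(seq_model_config("lstm_m2m", window_len = 12, d_model = 8,
                                    feature_dim = 5, lstm_layers = 1), 3)
  expect_equal(dim(m2m_forward(m2m, X)), c(12L, 6L))

  # time-synchronous geometry: target and output both span the window
  msync <- seq_model(seq_model_config("lstm_seq2seq", window_len = 12,
                                      shift = 0, d_model = 8, feature_dim = 5,
                                      lstm_layers = 1), 4)
  expect_equal(nrow(seq2seq_forward(msync, X, sample(1:5, 12, TRUE))), 12L)

  # shape errors
  expect_error(seq2seq_forward(m, X[1:5, ], tgt), "window must have")
  expect_error(seq2seq_forward(m, X, tgt[1:4]), "target length")
  expect_error(seq2seq_forward(m, X, c(tgt[-1], 9L)), "invalid label code")
})

test_that("decoder output depends on the target sequence", {
  set.seed(2)
  X <- matrix(rnorm(12 * 5), 12, 5)
  tgt <- c(rep(1L, 5), rep(2L, 5))
  for (m in list(seq_model(tiny_lstm_cfg, 5), seq_model(tiny_tf_cfg, 6))) {
    a <- seq2seq_forward(m, X, tgt)
    b <- seq2seq_forward(m, X, rev(tgt))
    expect_false(isTRUE(all.equal(a, b)))
  }
})

test_that("autodiff gradients match finite differences", {
  set.seed(3)
  X <- matrix(rnorm(12 * 5), 12, 5)
  tgt <- sample(1:5, 10, replace = TRUE)
  gt <- sample(c(1:5, 6L), 10, replace = TRUE)
  w <- loss_weights()
  for (spec in list(list(cfg = tiny_lstm_cfg, seed = 1,
                         pars = c("enc1.Wx", "dec2.Wh", "embed", "head.W")),
                    list(cfg = tiny_tf_cfg, seed = 2,
                         pars = c("in_proj.W", "enc1.self.q.W", "enc1.ln1.g",
                                  "dec1.cross.v.W", "dec1.ffn.1.W", "head.b")))) {
    m <- seq_model(spec$cfg, spec$seed)
    loss_of <- function(params) {
      ps <- lapply(params, surgseq:::ad_const)
      res <- surgseq:::fwd_graph(spec$cfg, ps, list(X), list(tgt))
      s <- surgseq:::supervision_rows(list(gt), res$order, w)
      as.numeric(surgseq:::ad_value(
        surgseq:::ad_wce(res$logits, s$y, s$w, res$T_out * res$B)))
    }
    surgseq:::ad_tape_start()
    ps <- surgseq:::params_as_nodes(m$params, trainable = TRUE)
    res <- surgseq:::fwd_graph(spec$cfg, ps, list(X), list(tgt))
    s <- surgseq:::supervision_rows(list(gt), res$order, w)
    surgseq:::ad_backward(surgseq:::ad_wce(res$logits, s$y, s$w,
                                           res$T_out * res$B))
    for (nm in spec$pars) {
      i <- sample(length(m$params[[nm]]), 1)
      eps <- 1e-5
      up <- m$params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- m$params; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (loss_of(up) - loss_of(dn)) / (2 * eps)
      expect_equal(ps[[nm]]$grad[i], num, tolerance = 1e-4)
    }
    surgseq:::ad_tape_stop()
  }
})

test_that("tiny models can overfit a single synthetic window", {
  v <- tiny_video(1)
  for (spec in list(list(cfg = seq_model_config("lstm_seq2seq",
                                                window_len = 100, shift = 10,
                                                d_model = 32, feature_dim = 16,
                                                lstm_layers = 1),
                         lr = 5e-3, steps = 80),
                    list(cfg = seq_model_config("transformer_seq2seq",
                                                window_len = 100, shift = 10,
                                                d_model = 32, feature_dim = 16,
                                                tf_layers = 1, tf_heads = 2,
                                                ffn_dim = 32),
                         lr = 2e-3, steps = 120))) {
    fit <- train_seq2seq(list(v), seq_model(spec$cfg, 1),
                         train_config("baseline", windows_per_video = 1,
                                      epochs = spec$steps, lr = spec$lr,
                                      seed = 2))
    expect_lt(fit$final_loss, 0.1)
  }
})
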