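# Layer primitives composed from autodiff nodes. Parameters are passed as
# a named list of nodes (`ps`); each layer draws its weights by name.

ad_linear <- function(ps, name, x) {
  ad_add_bias(ad_matmul(x, ps[[paste0(name, ".W")]]), ps[[paste0(name, ".b")]])
}

# one LSTM layer over a list of timestep inputs (each B x in), returning
# the per-step hidden states plus final (h, c) for encoder-decoder coupling.
# The input-to-gate product (plus bias) is computed for all timesteps in
# one matmul and sliced per step, keeping the tape small.
lstm_layer <- function(ps, name, xs, d, h0 = NULL, c0 = NULL) {
  B <- nrow(xs[[1L]]$value)
  wx <- ps[[paste0(name, ".Wx")]]
  wh <- ps[[paste0(name, ".Wh")]]
  b <- ps[[paste0(name, ".b")]]
  xw <- ad_add_bias(ad_matmul(ad_rbind(xs), wx), b)
  h <- if (is.null(h0)) ad_const(matrix(0, B, d)) else h0
  cc <- if (is.null(c0)) ad_const(matrix(0, B, d)) else c0
  hs <- vector("list", length(xs))
  for (t in seq_along(xs)) {
    gates <- ad_add(ad_rows_block(xw, (t - 1L) * B + 1L, t * B),
                    ad_matmul(h, wh))
    cc <- ad_lstm_cell(gates, cc, d)
    h <- ad_lstm_out(gates, cc, d)
    hs[[t]] <- h
  }
  list(hs = hs, h = h, c = cc)
}

# stacked LSTM; states is an optional list of per-layer list(h, c)
lstm_stack <- function(ps, name, xs, d, n_layers, states = NULL) {
  out_states <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    st <- if (is.null(states)) NULL else states[[l]]
    res <- lstm_layer(ps, sprintf("%s%d", name, l), xs, d,
                      h0 = if (is.null(st)) NULL else st$h,
                      c0 = if (is.null(st)) NULL else st$c)
    xs <- res$hs
    out_states[[l]] <- list(h = res$h, c = res$c)
  }
  list(hs = xs, states = out_states)
}

# multi-head attention for a single sequence (queries Tq x d, keys Tk x d);
# mask (if given) is a constant Tq x Tk matrix added to the scores
mha <- function(ps, name, xq, xkv, n_heads, mask = NULL) {
  d <- ncol(xq$value)
  dk <- d %/% n_heads
  q <- ad_linear(ps, paste0(name, ".q"), xq)
  k <- ad_linear(ps, paste0(name, ".k"), xkv)
  v <- ad_linear(ps, paste0(name, ".v"), xkv)
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    qh <- ad_cols(q, idx)
    kh <- ad_cols(k, idx)
    vh <- ad_cols(v, idx)
    scores <- ad_scale(ad_matmul_nt(qh, kh), 1 / sqrt(dk))
    if (!is.null(mask)) scores <- ad_add_const(scores, mask)
    heads[[h]] <- ad_matmul(ad_softmax_rows(scores), vh)
  }
  ad_linear(ps, paste0(name, ".o"), ad_cbind(heads))
}

ffn_block <- function(ps, name, x) {
  ad_linear(ps, paste0(name, ".2"), ad_relu(ad_linear(ps, paste0(name, ".1"), x)))
}

ln <- function(ps, name, x) {
  ad_layernorm(x, ps[[paste0(name, ".g")]], ps[[paste0(name, ".b")]])
}

transformer_encoder_layer <- function(ps, name, x, n_heads) {
  x <- ln(ps, paste0(name, ".ln1"), ad_add(x, mha(ps, paste0(name, ".self"), x, x, n_heads)))
  ln(ps, paste0(name, ".ln2"), ad_add(x, ffn_block(ps, paste0(name, ".ffn"), x)))
}

transformer_decoder_layer <- function(ps, name, x, memory, n_heads, mask = NULL) {
  x <- ln(ps, paste0(name, ".ln1"),
          ad_add(x, mha(ps, paste0(name, ".self"), x, x, n_heads, mask = mask)))
  x <- ln(ps, paste0(name, ".ln2"),
          ad_add(x, mha(ps, paste0(name, ".cross"), x, memory, n_heads)))
  ln(ps, paste0(name, ".ln3"), ad_add(x, ffn_block(ps, paste0(name, ".ffn"), x)))
}

causal_mask <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- -1e9
  m
}

# ---- parameter initialisation ---------------------------------------

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -r, r), nr, nc)
}

init_linear <- function(params, name, nin, nout) {
  params[[paste0(name, ".W")]] <- glorot(nin, nout)
  params[[paste0(name, ".b")]] <- matrix(0, 1L, nout)
  params
}

init_lstm_layer <- function(params, name, nin, d) {
  params[[paste0(name, ".Wx")]] <- glorot(nin, 4L * d)
  params[[paste0(name, ".Wh")]] <- glorot(d, 4L * d)
  b <- matrix(0, 1L, 4L * d)
  b[1L, (d + 1L):(2L * d)] <- 1  # forget-gate bias
  params[[paste0(name, ".b")]] <- b
  params
}

init_mha <- function(params, name, d) {
  for (part in c("q", "k", "v", "o")) {
    params <- init_linear(params, paste0(name, ".", part), d, d)
  }
  params
}

init_ln <- function(params, name, d) {
  params[[paste0(name, ".g")]] <- matrix(1, 1L, d)
  params[[paste0(name, ".b")]] <- matrix(0, 1L, d)
  params
}

init_encoder_layer <- function(params, name, d, ffn) {
  params <- init_mha(params, paste0(name, ".self"), d)
  params <- init_ln(params, paste0(name, ".ln1"), d)
  params <- init_linear(params, paste0(name, ".ffn.1"), d, ffn)
  params <- init_linear(params, paste0(name, ".ffn.2"), ffn, d)
  init_ln(params, paste0(name, ".ln2"), d)
}

init_decoder_layer <- function(params, name, d, ffn) {
  params <- init_mha(params, paste0(name, ".self"), d)
  params <- init_ln(params, paste0(name, ".ln1"), d)
  params <- init_mha(params, paste0(name, ".cross"), d)
  params <- init_ln(params, paste0(name, ".ln2"), d)
  params <- init_linear(params, paste0(name, ".ffn.1"), d, ffn)
  params <- init_linear(params, paste0(name, ".ffn.2"), ffn, d)
  init_ln(params, paste0(name, ".ln3"), d)
}
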