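# LSTM / BiLSTM numerical core.
#
# All recurrences are batched: a "sequence" is a list of T_len input matrices
# of shape (batch x input_dim); hidden states are (batch x hidden) matrices.
# Gate order in the packed weight matrices is [input, forget, cell, output].
# Backward passes are hand-derived reverse-mode gradients; correctness is
# guarded by finite-difference tests.

sigmoid <- function(x) 1 / (1 + exp(-x))

init_lstm_dir <- function(input_dim, hidden, scale, runif_fn) {
  list(
    Wx = matrix(runif_fn(input_dim * 4 * hidden, scale), input_dim, 4 * hidden),
    Wh = matrix(runif_fn(hidden * 4 * hidden, scale), hidden, 4 * hidden),
    b  = runif_fn(4 * hidden, scale)
  )
}

init_bilstm <- function(input_dim, hidden, scale, runif_fn) {
  list(
    fwd = init_lstm_dir(input_dim, hidden, scale, runif_fn),
    bwd = init_lstm_dir(input_dim, hidden, scale, runif_fn)
  )
}

# xs: list of (M x p) matrices. Returns list(h = list of (M x H), cache).
lstm_forward <- function(pm, xs) {
  T_len <- length(xs)
  M <- nrow(xs[[1]])
  H <- ncol(pm$Wh) / 4L
  h <- matrix(0, M, H)
  c_st <- matrix(0, M, H)
  hs <- vector("list", T_len)
  cache <- vector("list", T_len)
  idx_i <- seq_len(H)
  idx_f <- H + idx_i
  idx_g <- 2L * H + idx_i
  idx_o <- 3L * H + idx_i
  for (t in seq_len(T_len)) {
    a <- xs[[t]] %*% pm$Wx + h %*% pm$Wh
    a <- sweep(a, 2, pm$b, "+")
    gi <- sigmoid(a[, idx_i, drop = FALSE])
    gf <- sigmoid(a[, idx_f, drop = FALSE])
    gg <- tanh(a[, idx_g, drop = FALSE])
    go <- sigmoid(a[, idx_o, drop = FALSE])
    c_new <- gf * c_st + gi * gg
    tc <- tanh(c_new)
    h_new <- go * tc
    cache[[t]] <- list(x = xs[[t]], h_prev = h, c_prev = c_st,
                       gi = gi, gf = gf, gg = gg, go = go, tc = tc)
    h <- h_new
    c_st <- c_new
    hs[[t]] <- h_new
  }
  list(h = hs, cache = cache)
}

# dh: list of gradients on each step's hidden output (or NULL entries).
# Returns parameter gradients and per-step input gradients.
lstm_backward <- function(pm, cache, dh, need_dx = TRUE) {
  T_len <- length(cache)
  M <- nrow(cache[[1]]$x)
  H <- ncol(pm$Wh) / 4L
  dWx <- matrix(0, nrow(pm$Wx), ncol(pm$Wx))
  dWh <- matrix(0, nrow(pm$Wh), ncol(pm$Wh))
  db <- numeric(length(pm$b))
  dx <- if (need_dx) vector("list", T_len) else NULL
  dh_next <- matrix(0, M, H)
  dc_next <- matrix(0, M, H)
  for (t in rev(seq_len(T_len))) {
    cc <- cache[[t]]
    dht <- dh_next
    if (!is.null(dh[[t]])) dht <- dht + dh[[t]]
    c_new <- cc$gf * cc$c_prev + cc$gi * cc$gg
    do <- dht * cc$tc
    dc <- dc_next + dht * cc$go * (1 - cc$tc^2)
    di <- dc * cc$gg
    dg <- dc * cc$gi
    df <- dc * cc$c_prev
    dc_next <- dc * cc$gf
    da <- cbind(
      di * cc$gi * (1 - cc$gi),
      df * cc$gf * (1 - cc$gf),
      dg * (1 - cc$gg^2),
      do * cc$go * (1 - cc$go)
    )
    dWx <- dWx + crossprod(cc$x, da)
    dWh <- dWh + crossprod(cc$h_prev, da)
    db <- db + colSums(da)
    if (need_dx) dx[[t]] <- da %*% t(pm$Wx)
    dh_next <- da %*% t(pm$Wh)
  }
  list(dWx = dWx, dWh = dWh, db = db, dx = dx)
}

# Bidirectional run. Returns per-step concatenated outputs
# (out[[t]] = [h_fwd_t, h_bwd_{T+1-t}]), the final states
# last = [h_fwd_T, h_bwd_T] (forward end + backward end), and caches.
bilstm_forward <- function(pm, xs) {
  T_len <- length(xs)
  fw <- lstm_forward(pm$fwd, xs)
  bw <- lstm_forward(pm$bwd, rev(xs))
  out <- lapply(seq_len(T_len), function(t) {
    cbind(fw$h[[t]], bw$h[[T_len + 1L - t]])
  })
  last <- cbind(fw$h[[T_len]], bw$h[[T_len]])
  list(out = out, last = last, fw = fw, bw = bw)
}

# dout: list (per original step) of grads on concatenated outputs or NULL;
# dlast: grad on the concatenated final state or NULL.
bilstm_backward <- function(pm, fwdpass, dout = NULL, dlast = NULL,
                            need_dx = TRUE) {
  T_len <- length(fwdpass$fw$cache)
  M <- nrow(fwdpass$fw$cache[[1]]$x)
  Hf <- ncol(pm$fwd$Wh) / 4L
  dh_f <- vector("list", T_len)
  dh_b <- vector("list", T_len)
  add_to <- function(lst, t, g) {
    if (is.null(lst[[t]])) lst[[t]] <- g else lst[[t]] <- lst[[t]] + g
    lst
  }
  if (!is.null(dout)) {
    for (t in seq_len(T_len)) {
      if (is.null(dout[[t]])) next
      dh_f <- add_to(dh_f, t, dout[[t]][, seq_len(Hf), drop = FALSE])
      dh_b <- add_to(dh_b, T_len + 1L - t,
                     dout[[t]][, Hf + seq_len(Hf), drop = FALSE])
    }
  }
  if (!is.null(dlast)) {
    dh_f <- add_to(dh_f, T_len, dlast[, seq_len(Hf), drop = FALSE])
    dh_b <- add_to(dh_b, T_len, dlast[, Hf + seq_len(Hf), drop = FALSE])
  }
  gf <- lstm_backward(pm$fwd, fwdpass$fw$cache, dh_f, need_dx)
  gb <- lstm_backward(pm$bwd, fwdpass$bw$cache, dh_b, need_dx)
  dx <- NULL
  if (need_dx) {
    dx <- lapply(seq_len(T_len), function(t) {
      g <- gf$dx[[t]]
      if (!is.null(gb$dx[[T_len + 1L - t]])) {
        g <- g + gb$dx[[T_len + 1L - t]]
      }
      g
    })
  }
  list(
    fwd = list(Wx = gf$dWx, Wh = gf$dWh, b = gf$db),
    bwd = list(Wx = gb$dWx, Wh = gb$dWh, b = gb$db),
    dx = dx
  )
}
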