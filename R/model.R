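#' Model configuration
#'
#' Hyperparameters of the region-to-global spatiotemporal BiLSTM network.
#' The published full-scale configuration uses hidden sizes of 64 for all
#' four BiLSTM families, an attention perception width of 128 and dropout
#' 0.7; the defaults here are that configuration. Smaller settings train in
#' seconds on a CPU and are used throughout the examples and tests.
#'
#' @param d_r,d_g,d_rt,d_gt Hidden sizes of the regional-spatial,
#'   global-spatial, regional-temporal and global-temporal BiLSTMs
#'   (each contributes twice its size after the bidirectional concat).
#' @param attn_hidden Width of the single-layer attention perception net.
#' @param K Compressed global sequence length (the projection that mixes the
#'   N global-spatial positions down to K).
#' @param C Number of emotion classes.
#' @param T_seg Segments per sample.
#' @param dropout Dropout rate applied to each BiLSTM family's output
#'   during training, in `[0, 1)`.
#' @param activation Nonlinearity of the compression layer
#'   (`"relu"`, `"tanh"`, `"identity"`).
#' @param grl_lambda Gradient-reversal scale for the adversarial path.
#' @param attention `"learned"` (default), `"uniform"` (all weights 1/N;
#'   the V3 ablation), or `"none"` (layer removed).
#' @param temporal_input `"pre"` (default) feeds the regional temporal
#'   stream the raw regional encodings; `"post"` feeds it the
#'   attention-weighted features instead.
#' @param use_regional_temporal Keep the regional temporal stream
#'   (`FALSE` in the V1/V2 ablations).
#' @param use_discriminator Keep the domain discriminator
#'   (`FALSE` in the V4 ablation).
#' @param disc_hidden Hidden width of the 2-layer domain discriminator.
#' @param init_scale Half-width of the uniform weight initialization.
#' @return A `model_config` list.
#' @export
model_config <- function(d_r = 64, d_g = 64, d_rt = 64, d_gt = 64,
                         attn_hidden = 128, K = 4, C = 3, T_seg = 5,
                         dropout = 0.7, activation = c("relu", "tanh", "identity"),
                         grl_lambda = 1.0,
                         attention = c("learned", "uniform", "none"),
                         temporal_input = c("pre", "post"),
                         use_regional_temporal = TRUE,
                         use_discriminator = TRUE,
                         disc_hidden = 64, init_scale = 0.1) {
  stopifnot(
    d_r >= 1, d_g >= 1, d_rt >= 1, d_gt >= 1, attn_hidden >= 1,
    K >= 1, C >= 2, T_seg >= 1, dropout >= 0, dropout < 1,
    init_scale > 0
  )
  structure(
    list(
      d_r = d_r, d_g = d_g, d_rt = d_rt, d_gt = d_gt,
      attn_hidden = attn_hidden, K = K, C = C, T_seg = T_seg,
      dropout = dropout, activation = match.arg(activation),
      grl_lambda = grl_lambda, attention = match.arg(attention),
      temporal_input = match.arg(temporal_input),
      use_regional_temporal = use_regional_temporal,
      use_discriminator = use_discriminator,
      disc_hidden = disc_hidden, init_scale = init_scale
    ),
    class = "model_config"
  )
}

#' Ablation variants of the model configuration
#'
#' * `V1` removes the attention layer and the regional temporal stream;
#' * `V2` keeps attention but classifies from the global temporal feature
#'   alone;
#' * `V3` fixes all attention weights to the uniform value (every region
#'   equally weighted);
#' * `V4` removes the domain discriminator;
#' * `full` is the unmodified configuration.
#'
#' @param config A `model_config`.
#' @param variant One of `"full"`, `"V1"`, `"V2"`, `"V3"`, `"V4"`.
#' @return The modified `model_config`.
#' @export
variant_config <- function(config, variant = c("full", "V1", "V2", "V3", "V4")) {
  variant <- match.arg(variant)
  switch(variant,
    full = config,
    V1 = {
      config$attention <- "none"
      config$use_regional_temporal <- FALSE
      config
    },
    V2 = {
      config$use_regional_temporal <- FALSE
      config
    },
    V3 = {
      config$attention <- "uniform"
      config
    },
    V4 = {
      config$use_discriminator <- FALSE
      config
    }
  )
}

fused_dim <- function(config, N) {
  d <- 2 * config$d_gt
  if (config$use_regional_temporal) d <- d + N * 2 * config$d_rt
  d
}

runif_nonzero <- function(n, scale) {
  x <- stats::runif(n, -scale, scale)
  x[x == 0] <- scale / 2
  x
}

#' Initialize model parameters
#'
#' All weights are drawn uniformly from `(-init_scale, init_scale)`
#' (nonzero) using the current RNG state; seed the RNG for reproducible
#' initialization. Parameters are partitioned into the feature extractor
#' (`rs`, `att`, `gs`, `comp`, `rt`, `gt`), the classifier (`cls`) and the
#' discriminator (`dsc`); the training loops address exactly these groups.
#'
#' @param config A `model_config`.
#' @param partition A `region_partition` (fixes N).
#' @param d Number of per-channel features (bands).
#' @return Nested list of parameter arrays.
#' @export
init_params <- function(config, partition, d) {
  N <- n_regions(partition)
  sc <- config$init_scale
  p <- list(
    rs = init_bilstm(d, config$d_r, sc, runif_nonzero),
    gs = init_bilstm(2 * config$d_r, config$d_g, sc, runif_nonzero),
    comp = list(
      P = matrix(runif_nonzero(N * config$K, sc), N, config$K),
      bg = runif_nonzero(2 * config$d_g, sc)
    ),
    gt = init_bilstm(config$K * 2 * config$d_g, config$d_gt, sc, runif_nonzero)
  )
  if (config$attention == "learned") {
    p$att <- list(
      U = matrix(runif_nonzero(N * config$attn_hidden, sc), N, config$attn_hidden),
      V = matrix(runif_nonzero(config$attn_hidden * 2 * config$d_r, sc),
                 config$attn_hidden, 2 * config$d_r),
      br = runif_nonzero(config$attn_hidden, sc)
    )
  }
  if (config$use_regional_temporal) {
    p$rt <- init_bilstm(2 * config$d_r, config$d_rt, sc, runif_nonzero)
  }
  Dz <- fused_dim(config, N)
  p$cls <- list(
    Q = matrix(runif_nonzero(config$C * Dz, sc), config$C, Dz),
    bc = runif_nonzero(config$C, sc)
  )
  if (config$use_discriminator) {
    p$dsc <- list(
      W1 = matrix(runif_nonzero(config$disc_hidden * Dz, sc),
                  config$disc_hidden, Dz),
      b1 = runif_nonzero(config$disc_hidden, sc),
      W2 = matrix(runif_nonzero(2 * config$disc_hidden, sc), 2, config$disc_hidden),
      b2 = runif_nonzero(2, sc)
    )
  }
  p
}

#' Number of learnable parameters
#'
#' @param params Parameter list from [init_params()] (or a fitted model's
#'   `params`).
#' @return Total count of scalar parameters.
#' @export
num_params <- function(params) {
  if (inherits(params, "r2g_model")) params <- params$params
  length(unlist(params, use.names = FALSE))
}

feature_param_names <- c("rs", "att", "gs", "comp", "rt", "gt")

row_softmax <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

#' Region-attention weights of one segment
#'
#' Computes the N x N attention matrix from the regional feature matrix
#' `H` (2 d_r x N): logits `L = U tanh(V H + b 1')` followed by a row-wise
#' softmax. Row `i` of the result holds the mixture weights over source
#' regions used to build output position `i`, so every row sums to 1 and
#' all entries are positive. Each region's total contribution is the sum
#' of the weight it receives across rows (its column total), the quantity
#' [region_contribution_map()] aggregates.
#'
#' @param H 2 d_r x N regional feature matrix (columns = regions).
#' @param att Attention parameters: list with `U` (N x attn_hidden),
#'   `V` (attn_hidden x 2 d_r), `br` (attn_hidden).
#' @return N x N row-stochastic matrix.
#' @export
attention_weights <- function(H, att) {
  pre <- att$V %*% H + att$br
  L <- att$U %*% tanh(pre)
  if (any(!is.finite(L))) {
    stop("non-finite attention logits; check parameter scales", call. = FALSE)
  }
  row_softmax(L)
}

#' Apply attention weights to regional features
#'
#' Output column `i` is the row-`i` weighted mixture of the regional
#' feature columns: `Hhat = H %*% t(W)`.
#'
#' @param H 2 d_r x N regional feature matrix.
#' @param W N x N attention matrix (rows = output mixtures).
#' @return 2 d_r x N weighted feature matrix.
#' @export
apply_attention <- function(H, W) {
  stopifnot(ncol(H) == ncol(W), nrow(W) == ncol(W))
  H %*% t(W)
}

#' Compress a global feature sequence
#'
#' Position-mixing projection: column `k` of the result is
#' `act(sum_j P[j, k] * H[, j] + bg)`.
#'
#' @param H 2 d_g x N matrix of per-position global features.
#' @param P N x K projection matrix.
#' @param bg Length-2 d_g bias.
#' @param activation `"relu"`, `"tanh"` or `"identity"`.
#' @return 2 d_g x K compressed feature matrix.
#' @export
compress_global <- function(H, P, bg, activation = "relu") {
  pre <- H %*% P + bg
  switch(activation,
    relu = pmax(pre, 0),
    tanh = tanh(pre),
    identity = pre,
    stop("unknown activation", call. = FALSE)
  )
}

#' Linear classifier with softmax
#'
#' @param z Fused feature vector (or matrix with samples in rows).
#' @param Q C x dim(z) projection matrix.
#' @param bc Length-C bias.
#' @return List with `logits`, `prob` (rows sum to 1) and `label`
#'   (1-based argmax index per sample).
#' @export
classify <- function(z, Q, bc) {
  if (is.vector(z)) z <- matrix(z, nrow = 1)
  logits <- z %*% t(Q) + rep(bc, each = nrow(z))
  if (any(!is.finite(logits))) stop("non-finite logits", call. = FALSE)
  prob <- row_softmax(logits)
  list(logits = logits, prob = prob, label = max.col(prob, ties.method = "first"))
}

#' Summed cross-entropy loss of the classifier
#'
#' `L_c = sum_i -log P(true class of i)`, the batch-summed categorical
#' cross-entropy; probabilities are clipped at 1e-12 before the log.
#'
#' @param prob Samples x C matrix of class probabilities.
#' @param labels 1-based true-class indices.
#' @return Nonnegative scalar loss.
#' @export
classifier_loss <- function(prob, labels) {
  stopifnot(nrow(prob) == length(labels),
            all(labels >= 1), all(labels <= ncol(prob)))
  p <- prob[cbind(seq_len(nrow(prob)), labels)]
  -sum(log(pmax(p, 1e-12)))
}

#' Domain discriminator forward pass
#'
#' Two-layer perception net with ReLU hidden layer and 2-way softmax over
#' (source, target).
#'
#' @param z Fused feature matrix (samples in rows).
#' @param dsc Discriminator parameters: `W1`, `b1`, `W2`, `b2`.
#' @return Samples x 2 matrix of domain probabilities; column 1 is
#'   P(source), column 2 P(target); rows sum to 1.
#' @export
discriminator_forward <- function(z, dsc) {
  if (is.vector(z)) z <- matrix(z, nrow = 1)
  h1 <- pmax(z %*% t(dsc$W1) + rep(dsc$b1, each = nrow(z)), 0)
  row_softmax(h1 %*% t(dsc$W2) + rep(dsc$b2, each = nrow(z)))
}

#' Domain discriminator loss
#'
#' `L_d = -sum_i log P(source | source sample i)
#'        -sum_j log P(target | target sample j)`.
#'
#' @param prob_source Domain-probability matrix of source samples.
#' @param prob_target Domain-probability matrix of target samples.
#' @return Nonnegative scalar loss.
#' @export
discriminator_loss <- function(prob_source, prob_target) {
  -sum(log(pmax(prob_source[, 1], 1e-12))) -
    sum(log(pmax(prob_target[, 2], 1e-12)))
}

#' Gradient reversal
#'
#' The gradient-reversal layer is the identity in the forward pass
#' ([grl_forward()]) and multiplies the incoming gradient by `-lambda` in
#' the backward pass ([grl_backward()]). Inserted between the fused feature
#' and the discriminator, it turns the feature extractor's maximization of
#' the domain loss into a minimization the optimizer can perform, so that
#' the discriminator descends its own loss while the features ascend it.
#'
#' @param x Any array (forward input).
#' @param grad Upstream gradient (same shape as `x`).
#' @param lambda Reversal scale (default 1).
#' @return `grl_forward()` returns `x` unchanged; `grl_backward()` returns
#'   `-lambda * grad`.
#' @export
grl_forward <- function(x) x

#' @rdname grl_forward
#' @export
grl_backward <- function(grad, lambda = 1) -lambda * grad

#' Total adversarial objective
#'
#' `L = L_c - L_d`: the classifier loss minus the discriminator loss.
#'
#' @param l_c Classifier loss.
#' @param l_d Discriminator loss (0 when the discriminator is disabled).
#' @return Scalar total loss.
#' @export
total_loss <- function(l_c, l_d) l_c - l_d

# ---- full network forward/backward -----------------------------------------

# X: array (d, n, T, B), channels in layout order.
# reg_idx: list of channel-index vectors per region.
# Returns a trace with every intermediate needed for the backward pass.
model_forward <- function(params, config, reg_idx, X, training = FALSE) {
  dm <- dim(X)
  d <- dm[1]; T_len <- dm[3]; B <- dm[4]
  N <- length(reg_idx)
  M <- B * T_len
  dr2 <- 2 * config$d_r
  dg2 <- 2 * config$d_g
  drop_p <- if (training) config$dropout else 0

  draw_mask <- function(dims) {
    if (drop_p <= 0) return(NULL)
    array(stats::rbinom(prod(dims), 1, 1 - drop_p) / (1 - drop_p), dim = dims)
  }
  ch_step <- function(ch) {
    # (M x d) matrix for channel ch; row (b-1)*T + t
    matrix(aperm(X[, ch, , , drop = FALSE], c(3, 4, 1, 2)), M, d)
  }

  # regional spatial BiLSTM (weights shared across regions)
  Hr <- array(0, dim = c(M, dr2, N))
  rs_pass <- vector("list", N)
  for (j in seq_len(N)) {
    xs <- lapply(reg_idx[[j]], ch_step)
    rs_pass[[j]] <- bilstm_forward(params$rs, xs)
    Hr[, , j] <- rs_pass[[j]]$last
  }
  mask_hr <- draw_mask(dim(Hr))
  Hrm <- if (is.null(mask_hr)) Hr else Hr * mask_hr

  # attention
  Warr <- NULL; att_cache <- NULL
  if (config$attention == "learned") {
    Hmat <- matrix(aperm(Hrm, c(1, 3, 2)), M * N, dr2)
    Mact <- tanh(sweep(Hmat %*% t(params$att$V), 2, params$att$br, "+"))
    if (any(!is.finite(Mact))) {
      stop("non-finite attention activations", call. = FALSE)
    }
    Marr <- array(Mact, dim = c(M, N, config$attn_hidden))
    Larr <- array(0, dim = c(M, N, N))
    for (j in seq_len(N)) {
      Larr[, , j] <- Marr[, j, ] %*% t(params$att$U)
    }
    mx <- Larr[, , 1]
    for (j in seq_len(N)[-1]) mx <- pmax(mx, Larr[, , j])
    Warr <- array(0, dim = c(M, N, N))
    S <- matrix(0, M, N)
    for (j in seq_len(N)) {
      Warr[, , j] <- exp(Larr[, , j] - mx)
      S <- S + Warr[, , j]
    }
    for (j in seq_len(N)) Warr[, , j] <- Warr[, , j] / S
    att_cache <- list(Hmat = Hmat, Mact = Mact, Marr = Marr)
    Hhat <- array(0, dim = c(M, dr2, N))
    for (i in seq_len(N)) {
      for (j in seq_len(N)) {
        Hhat[, , i] <- Hhat[, , i] + Hrm[, , j] * Warr[, i, j]
      }
    }
  } else if (config$attention == "uniform") {
    mean_hr <- Hrm[, , 1]
    for (j in seq_len(N)[-1]) mean_hr <- mean_hr + Hrm[, , j]
    mean_hr <- mean_hr / N
    Hhat <- array(mean_hr, dim = c(M, dr2, N))
  } else {
    Hhat <- Hrm
  }

  # global spatial BiLSTM over the N region positions
  gs_pass <- bilstm_forward(
    params$gs,
    lapply(seq_len(N), function(i) matrix(Hhat[, , i], M, dr2))
  )
  Hg <- array(0, dim = c(M, dg2, N))
  for (i in seq_len(N)) Hg[, , i] <- gs_pass$out[[i]]
  mask_hg <- draw_mask(dim(Hg))
  Hgm <- if (is.null(mask_hg)) Hg else Hg * mask_hg

  # compression across the N positions
  Hg_mat <- matrix(Hgm, M * dg2, N)
  Cpre <- Hg_mat %*% params$comp$P + rep(rep(params$comp$bg, each = M),
                                         times = config$K)
  Cmat <- switch(config$activation,
    relu = pmax(Cpre, 0), tanh = tanh(Cpre), identity = Cpre)
  Comp <- array(Cmat, dim = c(M, dg2, config$K))

  # global temporal BiLSTM over the T segments
  Compflat <- matrix(Comp, M, dg2 * config$K)
  t_rows <- lapply(seq_len(T_len), function(t) t + T_len * (0:(B - 1)))
  gt_pass <- bilstm_forward(
    params$gt,
    lapply(seq_len(T_len), function(t) Compflat[t_rows[[t]], , drop = FALSE])
  )
  mask_gt <- draw_mask(dim(gt_pass$last))
  z_gt <- if (is.null(mask_gt)) gt_pass$last else gt_pass$last * mask_gt

  # regional temporal BiLSTM over the T segments of every region
  rt_pass <- NULL; z_rt <- NULL; mask_rt <- NULL
  if (config$use_regional_temporal) {
    rt_src <- if (identical(config$temporal_input, "post")) Hhat else Hrm
    rt_xs <- lapply(seq_len(T_len), function(t) {
      Xt <- matrix(0, B * N, dr2)
      for (j in seq_len(N)) {
        Xt[(0:(B - 1)) * N + j, ] <- matrix(rt_src[t_rows[[t]], , j], B, dr2)
      }
      Xt
    })
    rt_pass <- bilstm_forward(params$rt, rt_xs)
    drt2 <- 2 * config$d_rt
    arr <- array(rt_pass$last, dim = c(N, B, drt2))
    z_rt_raw <- matrix(aperm(arr, c(2, 3, 1)), B, drt2 * N)
    mask_rt <- draw_mask(dim(z_rt_raw))
    z_rt <- if (is.null(mask_rt)) z_rt_raw else z_rt_raw * mask_rt
    z <- cbind(z_rt, z_gt)
  } else {
    z <- z_gt
  }

  out <- classify(z, params$cls$Q, params$cls$bc)
  list(
    Hr = Hr, Hrm = Hrm, Warr = Warr, att_cache = att_cache, Hhat = Hhat,
    Hg = Hg, Hgm = Hgm, Hg_mat = Hg_mat, Cpre = Cpre, Cmat = Cmat,
    Comp = Comp, Compflat = Compflat, z_gt = z_gt, z_rt = z_rt, z = z,
    logits = out$logits, prob = out$prob, label = out$label,
    rs_pass = rs_pass, gs_pass = gs_pass, gt_pass = gt_pass, rt_pass = rt_pass,
    masks = list(hr = mask_hr, hg = mask_hg, gt = mask_gt, rt = mask_rt),
    t_rows = t_rows, dims = list(d = d, N = N, T_len = T_len, B = B, M = M)
  )
}

zero_like <- function(x) {
  if (is.list(x)) return(lapply(x, zero_like))
  x * 0
}

# Losses and parameter gradients of one (possibly mixed source/target) batch.
# labels: 1-based class index or NA (unlabeled target rows).
# domain: 0 = source, 1 = target, or NULL to skip the adversarial path.
# Gradient-reversal scale `lambda` applies to the feature-extractor gradient
# of the discriminator loss; the discriminator's own gradient is unreversed.
model_loss_grads <- function(params, config, reg_idx, trace,
                             labels, domain = NULL,
                             lambda = config$grl_lambda) {
  dims <- trace$dims
  N <- dims$N; B <- dims$B; T_len <- dims$T_len; M <- dims$M
  dr2 <- 2 * config$d_r
  dg2 <- 2 * config$d_g
  grads <- list()

  # classifier
  labeled <- which(!is.na(labels))
  dlogits <- trace$prob
  if (length(labeled) < nrow(dlogits)) {
    dlogits[setdiff(seq_len(nrow(dlogits)), labeled), ] <- 0
  }
  dlogits[cbind(labeled, labels[labeled])] <-
    dlogits[cbind(labeled, labels[labeled])] - 1
  l_c <- classifier_loss(trace$prob[labeled, , drop = FALSE], labels[labeled])
  grads$cls <- list(
    Q = crossprod(dlogits, trace$z),
    bc = colSums(dlogits)
  )
  dz <- dlogits %*% params$cls$Q

  # discriminator through the gradient-reversal layer
  l_d <- 0
  if (!is.null(domain) && config$use_discriminator) {
    zg <- grl_forward(trace$z)
    h1pre <- zg %*% t(params$dsc$W1) + rep(params$dsc$b1, each = nrow(zg))
    h1 <- pmax(h1pre, 0)
    pd <- row_softmax(h1 %*% t(params$dsc$W2) + rep(params$dsc$b2, each = nrow(zg)))
    idx <- cbind(seq_along(domain), domain + 1L)
    l_d <- -sum(log(pmax(pd[idx], 1e-12)))
    dpl <- pd
    dpl[idx] <- dpl[idx] - 1
    grads$dsc <- list(
      W2 = crossprod(dpl, h1),
      b2 = colSums(dpl),
      W1 = NULL, b1 = NULL
    )
    dh1 <- (dpl %*% params$dsc$W2) * (h1pre > 0)
    grads$dsc$W1 <- crossprod(dh1, zg)
    grads$dsc$b1 <- colSums(dh1)
    dz_d <- dh1 %*% params$dsc$W1
    dz <- dz + grl_backward(dz_d, lambda)
  }

  # split fused gradient
  if (config$use_regional_temporal) {
    drt2 <- 2 * config$d_rt
    dz_rt <- dz[, seq_len(N * drt2), drop = FALSE]
    dz_gt <- dz[, N * drt2 + seq_len(2 * config$d_gt), drop = FALSE]
  } else {
    dz_rt <- NULL
    dz_gt <- dz
  }

  dHrm <- array(0, dim = c(M, dr2, N))
  rt_post <- identical(config$temporal_input, "post")

  # regional temporal backward; input gradients flow to the raw regional
  # encodings ("pre") or to the attention-weighted features ("post")
  dRT <- NULL
  if (config$use_regional_temporal) {
    if (!is.null(trace$masks$rt)) dz_rt <- dz_rt * trace$masks$rt
    arr3 <- array(dz_rt, dim = c(B, drt2, N))
    dlast_rt <- matrix(aperm(arr3, c(3, 1, 2)), N * B, drt2)
    # bilstm final state is (fwd_T, bwd_T): width 2*d_rt
    g_rt <- bilstm_backward(params$rt, trace$rt_pass, dlast = dlast_rt)
    grads$rt <- list(fwd = g_rt$fwd, bwd = g_rt$bwd)
    dRT <- array(0, dim = c(M, dr2, N))
    for (t in seq_len(T_len)) {
      for (j in seq_len(N)) {
        dRT[trace$t_rows[[t]], , j] <- dRT[trace$t_rows[[t]], , j] +
          g_rt$dx[[t]][(0:(B - 1)) * N + j, , drop = FALSE]
      }
    }
    if (!rt_post) {
      dHrm <- dHrm + dRT
      dRT <- NULL
    }
  }

  # global temporal backward
  if (!is.null(trace$masks$gt)) dz_gt <- dz_gt * trace$masks$gt
  g_gt <- bilstm_backward(params$gt, trace$gt_pass, dlast = dz_gt)
  grads$gt <- list(fwd = g_gt$fwd, bwd = g_gt$bwd)
  dCompflat <- matrix(0, M, dg2 * config$K)
  for (t in seq_len(T_len)) {
    dCompflat[trace$t_rows[[t]], ] <- g_gt$dx[[t]]
  }

  # compression backward
  dCmat <- matrix(dCompflat, M * dg2, config$K)
  dact <- switch(config$activation,
    relu = (trace$Cpre > 0) * 1,
    tanh = 1 - trace$Cmat^2,
    identity = 1)
  dCpre <- dCmat * dact
  grads$comp <- list(
    P = crossprod(trace$Hg_mat, dCpre),
    bg = colSums(matrix(rowSums(dCpre), M, dg2))
  )
  dHg_mat <- dCpre %*% t(params$comp$P)
  dHg <- array(dHg_mat, dim = c(M, dg2, N))
  if (!is.null(trace$masks$hg)) dHg <- dHg * trace$masks$hg

  # global spatial backward
  g_gs <- bilstm_backward(params$gs, trace$gs_pass,
                          dout = lapply(seq_len(N), function(i) {
                            matrix(dHg[, , i], M, dg2)
                          }))
  grads$gs <- list(fwd = g_gs$fwd, bwd = g_gs$bwd)
  dHhat <- array(0, dim = c(M, dr2, N))
  for (i in seq_len(N)) dHhat[, , i] <- g_gs$dx[[i]]
  if (!is.null(dRT)) dHhat <- dHhat + dRT

  # attention backward
  if (config$attention == "learned") {
    Warr <- trace$Warr
    ac <- trace$att_cache
    dWarr <- array(0, dim = c(M, N, N))
    for (i in seq_len(N)) {
      for (j in seq_len(N)) {
        dHrm[, , j] <- dHrm[, , j] + dHhat[, , i] * Warr[, i, j]
        dWarr[, i, j] <- rowSums(matrix(dHhat[, , i] * trace$Hrm[, , j], M))
      }
    }
    dLarr <- array(0, dim = c(M, N, N))
    for (i in seq_len(N)) {
      Wi <- matrix(Warr[, i, ], M, N)
      dWi <- matrix(dWarr[, i, ], M, N)
      s <- rowSums(dWi * Wi)
      dLarr[, i, ] <- Wi * (dWi - s)
    }
    dU <- matrix(0, N, config$attn_hidden)
    dMact <- matrix(0, M * N, config$attn_hidden)
    for (j in seq_len(N)) {
      dLj <- matrix(dLarr[, , j], M, N)
      dMact[(j - 1) * M + seq_len(M), ] <- dLj %*% params$att$U
      dU <- dU + crossprod(dLj, matrix(ac$Marr[, j, ], M, config$attn_hidden))
    }
    dPre <- dMact * (1 - ac$Mact^2)
    grads$att <- list(
      U = dU,
      V = crossprod(dPre, ac$Hmat),
      br = colSums(dPre)
    )
    dHmat <- dPre %*% params$att$V
    dHrm <- dHrm + aperm(array(dHmat, dim = c(M, N, dr2)), c(1, 3, 2))
  } else if (config$attention == "uniform") {
    dmean <- dHhat[, , 1]
    for (i in seq_len(N)[-1]) dmean <- dmean + dHhat[, , i]
    dmean <- dmean / N
    for (j in seq_len(N)) dHrm[, , j] <- dHrm[, , j] + dmean
  } else {
    dHrm <- dHrm + dHhat
  }

  # dropout on regional features, then shared regional spatial backward
  if (!is.null(trace$masks$hr)) dHrm <- dHrm * trace$masks$hr
  grads$rs <- NULL
  for (j in seq_len(N)) {
    g_j <- bilstm_backward(params$rs, trace$rs_pass[[j]],
                           dlast = matrix(dHrm[, , j], M, dr2),
                           need_dx = FALSE)
    g_j <- list(fwd = g_j$fwd, bwd = g_j$bwd)
    grads$rs <- if (is.null(grads$rs)) g_j else add_grads(grads$rs, g_j)
  }

  list(l_c = l_c, l_d = l_d, l_total = total_loss(l_c, l_d), grads = grads)
}

add_grads <- function(a, b) {
  if (is.list(a)) {
    return(stats::setNames(
      lapply(names(a), function(nm) add_grads(a[[nm]], b[[nm]])), names(a)
    ))
  }
  a + b
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint (RDS) holding the configuration, partition and all
#' named parameter arrays; loading restores a model whose forward outputs
#' are identical to the saved one.
#'
#' @param model An `r2g_model` (see [train_supervised()]).
#' @param path File path.
#' @return `load_model()` returns the restored `r2g_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "r2g_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "r2g_model"))
  model
}

#' Predict emotion classes for feature samples
#'
#' @param object An `r2g_model`.
#' @param features An `eeg_features` object (or a d x n x T x B array in
#'   layout channel order).
#' @param type `"class"` (factor of predicted labels) or `"prob"`
#'   (samples x C probability matrix).
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return Factor of predictions or a probability matrix.
#' @export
predict.r2g_model <- function(object, features, type = c("class", "prob"),
                              batch_size = 256, ...) {
  type <- match.arg(type)
  X <- if (inherits(features, "eeg_features")) features$features else features
  stopifnot(length(dim(X)) == 4)
  B <- dim(X)[4]
  reg_idx <- region_channel_indices(object$partition)
  probs <- matrix(0, B, object$config$C)
  for (start in seq(1, B, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, B)
    tr <- model_forward(object$params, object$config, reg_idx,
                        X[, , , idx, drop = FALSE], training = FALSE)
    probs[idx, ] <- tr$prob
  }
  if (type == "prob") return(probs)
  factor(emotion_levels()[max.col(probs, ties.method = "first")],
         levels = emotion_levels())
}

#' @export
print.r2g_model <- function(x, ...) {
  cat(sprintf(
    "<r2g_model: %d regions (%s), %s attention, %s, %d parameters>\n",
    n_regions(x$partition), x$partition$layout_id, x$config$attention,
    if (x$config$use_discriminator) "adversarial" else "supervised",
    num_params(x$params)
  ))
  if (!is.null(x$history) && nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs; final L_c %.3f, train acc %.3f",
                nrow(x$history), last$l_c, last$train_acc))
    if (!is.na(last$val_acc)) cat(sprintf(", val acc %.3f", last$val_acc))
    cat("\n")
  }
  invisible(x)
}
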