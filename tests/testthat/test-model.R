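test_that("forward pass honors the dimension contract on the 12-region montage", {
  part <- build_partition("deap32")
  reg_idx <- region_channel_indices(part)
  cfg <- tiny_model_cfg(d_r = 3, d_rt = 3, d_gt = 3)
  set.seed(1)
  params <- init_params(cfg, part, d = 2)
  X <- array(rnorm(2 * 32 * 3 * 2), dim = c(2, 32, 3, 2))
  tr <- eegr2g:::model_forward(params, cfg, reg_idx, X)
  N <- 12
  expect_equal(dim(tr$Hr), c(2 * 3, 2 * 3, N))       # M x 2 d_r x N
  expect_equal(dim(tr$Warr), c(6, N, N))
  expect_equal(dim(tr$Hg), c(6, 2 * cfg$d_g, N))
  expect_equal(dim(tr$Comp), c(6, 2 * cfg$d_g, cfg$K))
  expect_equal(ncol(tr$z), N * 2 * cfg$d_rt + 2 * cfg$d_gt)
  expect_equal(rowSums(tr$prob), rep(1, 2), tolerance = 1e-6)
})

test_that("forward pass succeeds across region counts and segment counts", {
  for (N in c(2, 7, 12)) {
    for (T_len in c(1, 3, 5)) {
      part <- tiny_partition(rep(2, N))
      cfg <- tiny_model_cfg(T_seg = T_len)
      set.seed(N * 10 + T_len)
      params <- init_params(cfg, part, d = 2)
      X <- array(rnorm(2 * 2 * N * T_len * 2), dim = c(2, 2 * N, T_len, 2))
      reg_idx <- split(seq_len(2 * N), rep(seq_len(N), each = 2))
      tr <- eegr2g:::model_forward(params, cfg, reg_idx, X)
      expect_equal(ncol(tr$z), N * 2 * cfg$d_rt + 2 * cfg$d_gt)
      expect_equal(rowSums(tr$prob), rep(1, 2), tolerance = 1e-6)
    }
  }
})

test_that("shared regional weights give identical encodings for identical regions", {
  part <- build_partition("deap32")
  reg_idx <- region_channel_indices(part)
  cfg <- tiny_model_cfg()
  set.seed(4)
  params <- init_params(cfg, part, d = 2)
  X <- array(rnorm(2 * 32 * 3 * 2), dim = c(2, 32, 3, 2))
  # make the two 2-electrode regions "Bilateral frontal" and
  # "Frontal central" carry identical channel features
  X[, reg_idx[["Frontal central"]], , ] <- X[, reg_idx[["Bilateral frontal"]], , ]
  tr <- eegr2g:::model_forward(params, cfg, reg_idx, X)
  j1 <- which(part$region_names == "Bilateral frontal")
  j2 <- which(part$region_names == "Frontal central")
  expect_equal(tr$Hr[, , j1], tr$Hr[, , j2])
})

test_that("zero inputs with zero parameters stay at the zero fixed point", {
  part <- tiny_partition(c(2, 2))
  cfg <- tiny_model_cfg()
  set.seed(1)
  params <- zero_params(init_params(cfg, part, d = 2))
  X <- array(0, dim = c(2, 4, 3, 2))
  tr <- eegr2g:::model_forward(params, cfg, list(1:2, 3:4), X)
  expect_equal(max(abs(tr$Hr)), 0)
  expect_equal(max(abs(tr$z)), 0)
  expect_equal(tr$prob, matrix(1 / 3, 2, 3), ignore_attr = TRUE)
})

test_that("attention weights are a row-stochastic matrix", {
  set.seed(11)
  att <- list(U = matrix(rnorm(12 * 8), 12, 8),
              V = matrix(rnorm(8 * 6), 8, 6),
              br = rnorm(8))
  for (i in 1:100) {
    H <- matrix(rnorm(6 * 12), 6, 12)
    W <- attention_weights(H, att)
    expect_equal(rowSums(W), rep(1, 12), tolerance = 1e-6)
    expect_true(all(W > 0))
  }
})

test_that("zero attention projection gives uniform weights", {
  att <- list(U = matrix(0, 5, 4), V = matrix(rnorm(4 * 6), 4, 6),
              br = rnorm(4))
  W <- attention_weights(matrix(rnorm(6 * 5), 6, 5), att)
  expect_equal(W, matrix(1 / 5, 5, 5), ignore_attr = TRUE)
})

test_that("attention matches a hand-rolled softmax oracle at N = 3", {
  set.seed(2)
  att <- list(U = matrix(rnorm(3 * 4), 3, 4), V = matrix(rnorm(4 * 2), 4, 2),
              br = rnorm(4))
  H <- matrix(rnorm(2 * 3), 2, 3)
  W <- attention_weights(H, att)
  L <- att$U %*% tanh(att$V %*% H + att$br %*% t(rep(1, 3)))
  oracle <- t(apply(L, 1, function(r) exp(r) / sum(exp(r))))
  expect_equal(W, oracle, tolerance = 1e-12)
})

test_that("applying attention mixes regional features as convex combinations", {
  set.seed(3)
  H <- matrix(rnorm(4 * 3), 4, 3)
  expect_equal(apply_attention(H, diag(3)), H)
  Wu <- matrix(1 / 3, 3, 3)
  mixed <- apply_attention(H, Wu)
  expect_equal(mixed, matrix(rowMeans(H), 4, 3), ignore_attr = TRUE)
  # brute-force triple-loop oracle
  W <- matrix(runif(9), 3, 3)
  W <- W / rowSums(W)
  got <- apply_attention(H, W)
  want <- matrix(0, 4, 3)
  for (f in 1:4) for (i in 1:3) for (j in 1:3) {
    want[f, i] <- want[f, i] + H[f, j] * W[i, j]
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("global compression reduces to identity and sums in special cases", {
  set.seed(5)
  H <- abs(matrix(rnorm(4 * 3), 4, 3))     # nonnegative
  expect_equal(compress_global(H, diag(3), rep(0, 4), "relu"), H)
  s1 <- compress_global(H, matrix(1, 3, 1), rep(0, 4), "relu")
  expect_equal(s1, pmax(matrix(rowSums(H), 4, 1), 0))
  # random case vs naive loop oracle
  P <- matrix(rnorm(3 * 2), 3, 2)
  bg <- rnorm(4)
  got <- compress_global(H, P, bg, "relu")
  want <- matrix(0, 4, 2)
  for (f in 1:4) for (k in 1:2) {
    acc <- bg[f]
    for (j in 1:3) acc <- acc + P[j, k] * H[f, j]
    want[f, k] <- max(acc, 0)
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("the classifier softmax follows the closed form", {
  out <- classify(c(1, 1), matrix(0, 3, 2), rep(0, 3))
  expect_equal(out$prob, matrix(1 / 3, 1, 3), ignore_attr = TRUE)
  # logits (2, 1, 0)
  out2 <- classify(1, matrix(c(2, 1, 0), 3, 1), rep(0, 3))
  expect_equal(as.vector(out2$prob), c(0.66524096, 0.24472847, 0.09003057),
               tolerance = 1e-7)
  expect_equal(out2$label, 1)
  # shift invariance
  out3 <- classify(1, matrix(c(2, 1, 0), 3, 1), rep(5, 3))
  expect_equal(out2$prob, out3$prob, tolerance = 1e-12)
})

test_that("classifier loss equals the summed cross-entropy double loop", {
  p1 <- matrix(c(1, 0, 0), 1, 3)
  expect_equal(classifier_loss(p1, 1), 0)
  expect_equal(classifier_loss(matrix(1 / 3, 1, 3), 2), log(3),
               tolerance = 1e-12)
  set.seed(6)
  P <- matrix(runif(8 * 3), 8, 3)
  P <- P / rowSums(P)
  y <- sample(1:3, 8, replace = TRUE)
  naive <- 0
  for (i in 1:8) {
    for (c in 1:3) {
      naive <- naive - (y[i] == c) * log(P[i, c])
    }
  }
  expect_equal(classifier_loss(P, y), naive, tolerance = 1e-10)
})

test_that("discriminator outputs a two-way probability and matches a naive oracle", {
  dsc0 <- list(W1 = matrix(0, 3, 4), b1 = rep(0, 3),
               W2 = matrix(0, 2, 3), b2 = rep(0, 2))
  expect_equal(discriminator_forward(rnorm(4), dsc0),
               matrix(0.5, 1, 2), ignore_attr = TRUE)
  set.seed(8)
  dsc <- list(W1 = matrix(rnorm(12), 3, 4), b1 = rnorm(3),
              W2 = matrix(rnorm(6), 2, 3), b2 = rnorm(2))
  Z <- matrix(rnorm(5 * 4), 5, 4)
  got <- discriminator_forward(Z, dsc)
  expect_equal(rowSums(got), rep(1, 5), tolerance = 1e-10)
  for (r in 1:5) {
    h <- pmax(dsc$W1 %*% Z[r, ] + dsc$b1, 0)
    o <- as.vector(dsc$W2 %*% h + dsc$b2)
    expect_equal(got[r, ], exp(o) / sum(exp(o)), tolerance = 1e-10)
  }
})

test_that("discriminator loss follows its closed form and a naive oracle", {
  perfect_s <- matrix(c(1, 0), 2, 2, byrow = TRUE)[1, , drop = FALSE]
  perfect_t <- matrix(c(0, 1), 1, 2)
  expect_equal(discriminator_loss(perfect_s, perfect_t), 0)
  half <- matrix(0.5, 4, 2)
  expect_equal(discriminator_loss(half, half), 8 * log(2), tolerance = 1e-12)
  set.seed(9)
  ps <- matrix(runif(3 * 2), 3, 2); ps <- ps / rowSums(ps)
  pt <- matrix(runif(4 * 2), 4, 2); pt <- pt / rowSums(pt)
  naive <- 0
  for (i in 1:3) naive <- naive - log(ps[i, 1])
  for (j in 1:4) naive <- naive - log(pt[j, 2])
  expect_equal(discriminator_loss(ps, pt), naive, tolerance = 1e-10)
})

test_that("gradient reversal is identity forward and sign flip backward", {
  x <- matrix(rnorm(6), 2, 3)
  expect_identical(grl_forward(x), x)
  expect_equal(grl_backward(x, 1), -x)
  expect_equal(grl_backward(x, 0.5), -0.5 * x)
})

test_that("total loss is the classifier loss minus the discriminator loss", {
  expect_equal(total_loss(2.0, 0.5), 1.5)
  expect_equal(total_loss(3.7, 0), 3.7)       # no-discriminator limit
  set.seed(10)
  lc <- runif(5); ld <- runif(5)
  expect_equal(total_loss(lc, ld) + ld - lc, rep(0, 5))
})

test_that("ablation variants produce well-formed forward passes", {
  part <- tiny_partition(c(2, 2, 2))
  reg_idx <- list(1:2, 3:4, 5:6)
  base <- tiny_model_cfg()
  set.seed(12)
  X <- array(rnorm(2 * 6 * 3 * 2), dim = c(2, 6, 3, 2))
  for (v in c("full", "V1", "V2", "V3", "V4")) {
    cfg <- variant_config(base, v)
    set.seed(30)
    params <- init_params(cfg, part, d = 2)
    tr <- eegr2g:::model_forward(params, cfg, reg_idx, X)
    expect_equal(rowSums(tr$prob), rep(1, 2), tolerance = 1e-6)
    if (v %in% c("V1", "V2")) {
      expect_equal(tr$z, tr$z_gt)            # global temporal feature only
    }
    if (v == "V1") expect_null(tr$Warr)      # attention removed
    if (v == "V3") expect_null(tr$Warr)      # uniform weights, not learned
    if (v == "V4") expect_null(params$dsc)
  }
  # V3 equals a learned-attention model whose weights are forced uniform
  cfg3 <- variant_config(base, "V3")
  set.seed(30)
  p3 <- init_params(cfg3, part, d = 2)
  tr3 <- eegr2g:::model_forward(p3, cfg3, reg_idx, X)
  mean_col <- apply(tr3$Hr, c(1, 2), mean)
  expect_equal(tr3$Hhat[, , 2], mean_col)    # every position the region mean
})

test_that("fused feature concatenates both temporal streams verbatim", {
  part <- tiny_partition(c(2, 2))
  cfg <- tiny_model_cfg()
  set.seed(14)
  params <- init_params(cfg, part, d = 2)
  X <- array(rnorm(2 * 4 * 3 * 2), dim = c(2, 4, 3, 2))
  tr <- eegr2g:::model_forward(params, cfg, list(1:2, 3:4), X)
  expect_equal(tr$z, cbind(tr$z_rt, tr$z_gt))
})

test_that("checkpoints round-trip with identical forward outputs", {
  f <- small_feats()
  cfg <- tiny_model_cfg(T_seg = 5)
  set.seed(15)
  part <- build_partition("deap32")
  model <- structure(
    list(params = init_params(cfg, part, 4), config = cfg, partition = part),
    class = "r2g_model"
  )
  p1 <- predict(model, f, type = "prob")
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  p2 <- predict(load_model(path), f, type = "prob")
  expect_identical(p1, p2)
})

test_that("parameter groups are exhaustive and disjoint", {
  part <- build_partition("deap32")
  cfg <- tiny_model_cfg()
  set.seed(16)
  params <- init_params(cfg, part, d = 4)
  expect_setequal(names(params),
                  c("rs", "att", "gs", "comp", "rt", "gt", "cls", "dsc"))
  expect_equal(num_params(params), length(unlist(params)))
  expect_true(all(unlist(params) != 0))      # nonzero initialization
})

test_that("post-attention temporal inputs backpropagate correctly", {
  cfg <- tiny_model_cfg(T_seg = 2, temporal_input = "post",
                        use_discriminator = FALSE, init_scale = 0.3)
  part <- tiny_partition(c(2, 2))
  reg_idx <- list(1:2, 3:4)
  set.seed(18)
  params <- init_params(cfg, part, d = 2)
  X <- array(rnorm(2 * 4 * 2 * 3), dim = c(2, 4, 2, 3))
  y <- c(1L, 2L, 3L)
  tr <- eegr2g:::model_forward(params, cfg, reg_idx, X)
  ana <- unlist(eegr2g:::model_loss_grads(params, cfg, reg_idx, tr, y)$grads)
  lc_of <- function(p) {
    tr2 <- eegr2g:::model_forward(p, cfg, reg_idx, X)
    classifier_loss(tr2$prob, y)
  }
  flat <- unlist(params)
  set.seed(19)
  probe <- sample(seq_along(flat), 60)
  fd <- vapply(probe, function(k) {
    up <- flat; up[k] <- up[k] + 1e-4
    dn <- flat; dn[k] <- dn[k] - 1e-4
    (lc_of(utils::relist(up, params)) - lc_of(utils::relist(dn, params))) / 2e-4
  }, 0)
  expect_lt(max(abs(fd - ana[names(flat)[probe]])) / max(abs(fd)), 1e-4)
  # the option really changes the forward pass
  cfg_pre <- tiny_model_cfg(T_seg = 2, use_discriminator = FALSE,
                            init_scale = 0.3)
  tr_pre <- eegr2g:::model_forward(params, cfg_pre, reg_idx, X)
  expect_false(identical(tr$z_rt, tr_pre$z_rt))
})

test_that("the gradient-reversal ramp schedule only rescales the adversarial path", {
  f <- small_feats()
  src <- subset_features(f, seq_len(24))
  tgt <- subset_features(f, 25:36)
  tgt$labels[] <- NA
  cfg <- tiny_model_cfg(T_seg = 5, dropout = 0, grl_lambda = 0)
  tc <- train_config(learning_rate = 0.05, batch_size = 12, epochs = 2,
                     patience = Inf, grl_ramp = TRUE, seed = 3)
  # with grl_lambda = 0 the ramp is identically zero: still reduces to
  # the supervised trajectory
  sup <- train_supervised(src, cfg, tc)
  adv <- train_adversarial(src, tgt, cfg, tc)
  shared <- c("rs", "att", "gs", "comp", "rt", "gt", "cls")
  expect_equal(unlist(sup$params[shared]), unlist(adv$params[shared]),
               tolerance = 1e-12)
  # with a nonzero lambda the ramped and constant schedules differ
  cfg1 <- tiny_model_cfg(T_seg = 5, dropout = 0, grl_lambda = 1)
  tc_const <- train_config(learning_rate = 0.05, batch_size = 12, epochs = 2,
                           patience = Inf, seed = 3)
  tc_ramp <- train_config(learning_rate = 0.05, batch_size = 12, epochs = 2,
                          patience = Inf, grl_ramp = TRUE, seed = 3)
  a1 <- train_adversarial(src, tgt, cfg1, tc_const)
  a2 <- train_adversarial(src, tgt, cfg1, tc_ramp)
  expect_false(identical(a1$params, a2$params))
})
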