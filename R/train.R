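#' Training configuration
#'
#' The published configuration trains with SGD under the AdaGrad
#' per-parameter step rule, learning rate 0.001, batch size 120, up to
#' 200 epochs with early stopping when validation accuracy stops
#' improving. One master seed derives the initialization, shuffling and
#' dropout streams, so a `(seed, config, data)` triple reproduces the
#' run exactly.
#'
#' @param learning_rate Step size (alpha).
#' @param batch_size Mini-batch size.
#' @param epochs Maximum epochs.
#' @param optimizer `"adagrad"` (default) or `"sgd"`.
#' @param patience Early-stop patience in epochs (improvement is measured
#'   on validation accuracy when a validation set is given, otherwise on
#'   training loss); `Inf` disables early stopping.
#' @param grl_ramp Ramp the gradient-reversal scale from 0 to
#'   `grl_lambda` over the epochs with the sigmoid schedule
#'   `2 / (1 + exp(-10 p)) - 1` (off by default: the scale is constant).
#' @param seed Master seed.
#' @param verbose Print per-epoch progress.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 120,
                         epochs = 200, optimizer = c("adagrad", "sgd"),
                         patience = 20, grl_ramp = FALSE, seed = 1,
                         verbose = FALSE) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(
    list(
      learning_rate = learning_rate, batch_size = batch_size,
      epochs = epochs, optimizer = match.arg(optimizer),
      patience = patience, grl_ramp = grl_ramp, seed = seed,
      verbose = verbose
    ),
    class = "train_config"
  )
}

#' Hyperparameter search space
#'
#' The enumerations searched when tuning: one knob is varied at a time
#' with all others held at the base configuration.
#'
#' @return Named list of candidate values per knob.
#' @export
default_search_space <- function() {
  list(
    hidden_size = c(32, 64, 128, 256),
    batch_size = c(30, 60, 80, 120),
    learning_rate = c(0.1, 0.01, 0.001, 0.0001),
    dropout = c(0.5, 0.6, 0.7),
    epochs = c(100, 200, 300, 500)
  )
}

derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 7919 + offset * 104729) %% 2147483647)
}

# Evaluate expr under its own RNG stream, leaving the caller's stream
# untouched (keeps the supervised and adversarial loops' main streams
# aligned, so grl_lambda = 0 reduces exactly to supervised training).
with_isolated_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

adagrad_state <- function(params) zero_like(params)

apply_update <- function(params, grads, state, lr, optimizer, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p)) {
      upd <- lapply(names(p), function(nm) walk(p[[nm]], g[[nm]], s[[nm]]))
      names(upd) <- names(p)
      return(list(
        p = stats::setNames(lapply(upd, `[[`, "p"), names(p)),
        s = stats::setNames(lapply(upd, `[[`, "s"), names(p))
      ))
    }
    if (optimizer == "adagrad") {
      s <- s + g^2
      p <- p - lr * g / (sqrt(s) + eps)
    } else {
      p <- p - lr * g
    }
    list(p = p, s = s)
  }
  walk(params, grads, state)
}

labels_to_idx <- function(labels) {
  if (is.factor(labels)) as.integer(labels) else as.integer(labels)
}

accuracy_of <- function(model, features, labels_idx) {
  prob <- predict.r2g_model(model, features, type = "prob")
  mean(max.col(prob, ties.method = "first") == labels_idx)
}

empty_history <- function() {
  data.frame(
    epoch = integer(), l_c = numeric(), l_d = numeric(),
    l_total = numeric(), train_acc = numeric(), val_acc = numeric(),
    seconds = numeric()
  )
}

new_r2g_model <- function(params, config, partition, history, train_cfg) {
  structure(
    list(params = params, config = config, partition = partition,
         history = history, train_config = train_cfg),
    class = "r2g_model"
  )
}

#' Supervised training of the emotion classifier
#'
#' Minimizes the batch-summed cross-entropy of the classifier by
#' mini-batch gradient descent with the AdaGrad step rule. The
#' discriminator is disabled. Deterministic under a fixed seed.
#'
#' @param features Labeled `eeg_features` training set.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param partition A `region_partition` (default: the feature set's
#'   layout).
#' @param val Optional validation `eeg_features` for early stopping and
#'   per-epoch accuracy.
#' @param init Optional initial parameters (default: fresh [init_params()]
#'   from the derived init seed).
#' @return An `r2g_model` with fitted `params` and a per-epoch `history`
#'   data.frame (`l_c`, `l_d`, `l_total`, `train_acc`, `val_acc`,
#'   `seconds`). When a validation set is given, the returned parameters
#'   are those of the epoch with the highest validation accuracy.
#' @export
train_supervised <- function(features, model_cfg, train_cfg,
                             partition = build_partition(features$layout_id),
                             val = NULL, init = NULL) {
  cfg <- model_cfg
  cfg$use_discriminator <- FALSE
  train_loop(features, NULL, cfg, train_cfg, partition, val, init)
}

#' Adversarial training with a domain discriminator
#'
#' Joint per-batch updates: the feature extractor and classifier descend
#' the classifier loss on the labeled source data while the discriminator
#' descends the domain loss on source-vs-target batches; the
#' gradient-reversal layer makes the feature extractor ascend the domain
#' loss, driving features toward domain invariance. Target labels are
#' never read.
#'
#' @param source Labeled source-domain `eeg_features`.
#' @param target Unlabeled target-domain `eeg_features` (labels, if
#'   present, are ignored).
#' @inheritParams train_supervised
#' @return An `r2g_model`.
#' @export
train_adversarial <- function(source, target, model_cfg, train_cfg,
                              partition = build_partition(source$layout_id),
                              val = NULL, init = NULL) {
  cfg <- model_cfg
  cfg$use_discriminator <- TRUE
  train_loop(source, target, cfg, train_cfg, partition, val, init)
}

train_loop <- function(source, target, cfg, train_cfg, partition,
                       val = NULL, init = NULL) {
  stopifnot(inherits(source, "eeg_features"))
  reg_idx <- region_channel_indices(partition)
  X <- source$features
  y <- labels_to_idx(source$labels)
  stopifnot(!anyNA(y))
  n_src <- dim(X)[4]
  adversarial <- !is.null(target) && cfg$use_discriminator
  if (adversarial) Xt <- target$features

  set.seed(derive_seed(train_cfg$seed, 1))
  params <- if (is.null(init)) init_params(cfg, partition, dim(X)[1]) else init
  state <- adagrad_state(params)
  set.seed(derive_seed(train_cfg$seed, 2))

  y_val <- if (!is.null(val)) labels_to_idx(val$labels) else NULL
  hist <- empty_history()
  best_metric <- -Inf
  best_lc <- Inf
  best_params <- params
  stale <- 0
  for (epoch in seq_len(train_cfg$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    order_idx <- sample.int(n_src)
    batches <- split(order_idx, ceiling(seq_along(order_idx) / train_cfg$batch_size))
    tgt_batches <- NULL
    if (adversarial) {
      tgt_batches <- with_isolated_rng(
        derive_seed(train_cfg$seed, 3) %% 2147483000 + epoch,
        lapply(batches, function(b) {
          sample.int(dim(Xt)[4], length(b), replace = TRUE)
        })
      )
    }
    ep_lc <- 0; ep_ld <- 0
    ep_hits <- 0; ep_n <- 0
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      Xb <- X[, , , b, drop = FALSE]
      yb <- y[b]
      dom <- NULL
      if (adversarial) {
        tb <- tgt_batches[[bi]]
        Xb <- array(c(Xb, Xt[, , , tb, drop = FALSE]),
                    dim = c(dim(Xb)[1:3], 2 * length(b)))
        yb <- c(yb, rep(NA_integer_, length(b)))
        dom <- c(rep(0L, length(b)), rep(1L, length(b)))
      }
      lambda_now <- cfg$grl_lambda
      if (isTRUE(train_cfg$grl_ramp)) {
        p_frac <- epoch / train_cfg$epochs
        lambda_now <- cfg$grl_lambda * (2 / (1 + exp(-10 * p_frac)) - 1)
      }
      trace <- model_forward(params, cfg, reg_idx, Xb, training = TRUE)
      res <- model_loss_grads(params, cfg, reg_idx, trace, yb, dom,
                              lambda = lambda_now)
      if (!is.finite(res$l_c) || !is.finite(res$l_d)) {
        stop(sprintf(
          "training diverged at epoch %d (l_c = %g, l_d = %g); lower the learning rate",
          epoch, res$l_c, res$l_d
        ), call. = FALSE)
      }
      upd <- apply_update(params, res$grads, state,
                          train_cfg$learning_rate, train_cfg$optimizer)
      params <- upd$p
      state <- upd$s
      ep_lc <- ep_lc + res$l_c
      ep_ld <- ep_ld + res$l_d
      lab_rows <- seq_along(b)
      ep_hits <- ep_hits + sum(trace$label[lab_rows] == yb[lab_rows])
      ep_n <- ep_n + length(b)
    }
    # training accuracy is the running estimate over the epoch's batches
    tr_acc <- ep_hits / ep_n
    v_acc <- if (!is.null(val)) {
      model_now <- new_r2g_model(params, cfg, partition, hist, train_cfg)
      accuracy_of(model_now, val, y_val)
    } else {
      NA_real_
    }
    hist <- rbind(hist, data.frame(
      epoch = epoch, l_c = ep_lc, l_d = ep_ld,
      l_total = total_loss(ep_lc, ep_ld),
      train_acc = tr_acc, val_acc = v_acc,
      seconds = proc.time()[["elapsed"]] - t0
    ))
    if (train_cfg$verbose) {
      message(sprintf(
        "epoch %3d  L_c %8.2f  L_d %8.2f  train %.3f  val %s",
        epoch, ep_lc, ep_ld, tr_acc,
        if (is.na(v_acc)) "-" else sprintf("%.3f", v_acc)
      ))
    }
    metric <- if (!is.null(val)) v_acc else -ep_lc
    if (metric > best_metric + 1e-12) {
      best_metric <- metric
      best_lc <- ep_lc
      best_params <- params
      stale <- 0
    } else {
      # a coarse validation fold plateaus in steps; among epochs tied on
      # validation accuracy keep the one with the lowest training loss
      if (metric >= best_metric - 1e-12 && ep_lc < best_lc) {
        best_lc <- ep_lc
        best_params <- params
      }
      stale <- stale + 1
    }
    if (is.finite(train_cfg$patience) && stale >= train_cfg$patience) break
  }
  # with a validation set, keep the epoch with the best validation accuracy
  final <- if (!is.null(val)) best_params else params
  new_r2g_model(final, cfg, partition, hist, train_cfg)
}

#' Early-stopping decision
#'
#' Stop when the monitored accuracy has shown no improvement over its
#' running best for `patience` consecutive epochs.
#'
#' @param history Numeric vector of per-epoch validation accuracies (or a
#'   training-history data.frame with a `val_acc` column).
#' @param patience Number of epochs without improvement tolerated.
#' @return `TRUE` if training should stop after the last recorded epoch.
#' @export
early_stop <- function(history, patience) {
  acc <- if (is.data.frame(history)) history$val_acc else history
  stopifnot(length(acc) >= 1)
  best <- -Inf
  stale <- 0
  for (a in acc) {
    if (a > best + 1e-12) {
      best <- a
      stale <- 0
    } else {
      stale <- stale + 1
    }
  }
  stale >= patience
}

#' Coordinate-wise hyperparameter search
#'
#' Varies one knob at a time over its enumeration while all other knobs
#' stay at the base configuration, trains on the training set and scores
#' validation accuracy. Returns the best configuration and the full
#' leaderboard. Deterministic given the seed in `train_cfg`.
#'
#' @param space Named list of candidate values (see
#'   [default_search_space()]); recognized knobs: `hidden_size`,
#'   `batch_size`, `learning_rate`, `dropout`, `epochs`.
#' @param train,val Labeled `eeg_features` sets.
#' @param model_cfg,train_cfg Base configurations.
#' @param partition Region partition.
#' @return List with `best` (list of knob settings), `best_val_acc`, and
#'   `leaderboard` (data.frame: knob, value, val_acc).
#' @export
grid_search <- function(space, train, val, model_cfg, train_cfg,
                        partition = build_partition(train$layout_id)) {
  if (length(space) == 0 || all(lengths(space) == 0)) {
    stop("empty search space", call. = FALSE)
  }
  rows <- list()
  for (knob in names(space)) {
    for (value in space[[knob]]) {
      mc <- model_cfg
      tc <- train_cfg
      switch(knob,
        hidden_size = {
          mc$d_r <- mc$d_g <- mc$d_rt <- mc$d_gt <- value
        },
        batch_size = tc$batch_size <- value,
        learning_rate = tc$learning_rate <- value,
        dropout = mc$dropout <- value,
        epochs = tc$epochs <- value,
        stop(sprintf("unknown search knob '%s'", knob), call. = FALSE)
      )
      fit <- train_supervised(train, mc, tc, partition, val = val)
      rows[[length(rows) + 1]] <- data.frame(
        knob = knob, value = value,
        val_acc = max(fit$history$val_acc, na.rm = TRUE)
      )
    }
  }
  leaderboard <- do.call(rbind, rows)
  best_row <- leaderboard[which.max(leaderboard$val_acc), ]
  list(
    best = stats::setNames(list(best_row$value), best_row$knob),
    best_val_acc = best_row$val_acc,
    leaderboard = leaderboard
  )
}
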