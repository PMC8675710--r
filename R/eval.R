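#' Trial-wise stratified split
#'
#' Assigns whole trials to train/validation/test folds, stratified by
#' class, so that no trial's segments ever span folds (the guard against
#' data leakage). The published protocol draws about 10% of each class's
#' trials for test, another 10% for validation and keeps 80% for
#' training.
#'
#' @param trial_ids Character vector of trial identifiers, one entry per
#'   trial (not per sample).
#' @param labels Class label of each trial.
#' @param fractions Length-3 numeric `(train, val, test)` summing to 1.
#' @param seed RNG seed for the draw.
#' @return List with character vectors `train`, `val`, `test` of trial
#'   ids (pairwise disjoint, union = all ids).
#' @export
trial_wise_split <- function(trial_ids, labels,
                             fractions = c(0.8, 0.1, 0.1), seed = 1) {
  stopifnot(length(trial_ids) == length(labels),
            abs(sum(fractions) - 1) < 1e-8, all(fractions >= 0))
  if (anyDuplicated(trial_ids)) {
    stop("trial_ids must be unique (one entry per trial)", call. = FALSE)
  }
  set.seed(seed)
  classes <- unique(labels)
  n_per_class <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  # largest-remainder allocation per fold so that class-level counts add up
  # to the global round(fraction * n) (40 balanced trials with 0.8/0.1/0.1
  # give the canonical 32/4/4)
  alloc <- function(frac) {
    if (frac == 0) return(rep(0L, length(classes)))
    target <- frac * n_per_class
    base <- pmax(1L, floor(target))
    want <- max(sum(base), round(frac * sum(n_per_class)))
    extra <- want - sum(base)
    if (extra > 0) {
      ord <- order(target - floor(target), decreasing = TRUE)
      base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1L
    }
    base
  }
  n_test_c <- alloc(fractions[3])
  n_val_c <- alloc(fractions[2])
  train <- character(); val <- character(); test <- character()
  for (k in seq_along(classes)) {
    ids <- trial_ids[labels == classes[k]]
    n <- length(ids)
    n_test <- n_test_c[k]
    n_val <- n_val_c[k]
    if (n_test + n_val >= n) {
      stop(sprintf(
        "class '%s' has %d trial(s); not enough for the requested folds",
        as.character(classes[k]), n
      ), call. = FALSE)
    }
    ids <- sample(ids)
    test <- c(test, ids[seq_len(n_test)])
    val <- c(val, ids[n_test + seq_len(n_val)])
    train <- c(train, ids[(n_test + n_val + 1):n])
  }
  list(train = train, val = val, test = test)
}

#' Leave-one-subject-out folds
#'
#' One fold per subject: that subject's data is the test set (and the
#' unlabeled target domain for adversarial training); all other subjects
#' train. Folds are ordered by sorted subject id.
#'
#' @param subject_ids Character vector of subject identifiers (repeats
#'   allowed; the unique set defines the folds).
#' @return List of lists with elements `train` (subject ids) and `test`
#'   (single subject id).
#' @export
loso_folds <- function(subject_ids) {
  subjects <- sort(unique(subject_ids))
  if (length(subjects) < 2) {
    stop("LOSO needs at least 2 subjects", call. = FALSE)
  }
  lapply(subjects, function(s) {
    list(train = setdiff(subjects, s), test = s)
  })
}

#' Evaluate a fitted model on a test set
#'
#' @param model An `r2g_model`.
#' @param test Labeled `eeg_features` test set.
#' @return A `metrics_report`: list with `accuracy`, `n`, and `confusion`
#'   (C x C matrix, rows = true class, columns = predicted).
#' @export
evaluate_model <- function(model, test) {
  stopifnot(inherits(test, "eeg_features"))
  if (dim(test$features)[4] == 0) stop("empty test set", call. = FALSE)
  pred <- predict.r2g_model(model, test, type = "class")
  lv <- levels(test$labels)
  confusion <- table(
    true = factor(test$labels, levels = lv),
    predicted = factor(pred, levels = lv)
  )
  structure(
    list(
      accuracy = mean(pred == test$labels),
      n = length(pred),
      confusion = unclass(confusion)
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report: ACC %.4f on %d samples>\n", x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}

split_features_by_trial <- function(features, split) {
  list(
    train = subset_features(features, features$trial %in% split$train),
    val = subset_features(features, features$trial %in% split$val),
    test = subset_features(features, features$trial %in% split$test)
  )
}

trial_table <- function(features) {
  keep <- !duplicated(features$trial)
  list(ids = features$trial[keep], labels = features$labels[keep])
}

#' Within-subject experiment on one subject's feature set
#'
#' Trial-wise stratified split, supervised (or adversarial, if a target
#' set is supplied) training, and test-set evaluation.
#'
#' @param features One subject's labeled `eeg_features`.
#' @param model_cfg,train_cfg Configurations.
#' @param fractions Train/val/test trial fractions.
#' @param seed Split seed (training uses `train_cfg$seed`).
#' @return List with the fitted `model`, the `metrics_report`, and the
#'   `split`.
#' @export
within_subject_run <- function(features, model_cfg, train_cfg,
                               fractions = c(0.8, 0.1, 0.1), seed = 1) {
  tt <- trial_table(features)
  split <- trial_wise_split(tt$ids, tt$labels, fractions, seed)
  parts <- split_features_by_trial(features, split)
  model <- train_supervised(parts$train, model_cfg, train_cfg,
                            val = parts$val)
  list(model = model,
       metrics = evaluate_model(model, parts$test),
       split = split)
}

#' Per-band classification experiment
#'
#' Extracts single-band DE features (d = 1) per band, runs a
#' within-subject experiment per subject on each, and tabulates mean
#' accuracy per band.
#'
#' @param trials List of `raw_trial` objects (possibly several subjects).
#' @param bands Character vector of band names (default theta, alpha,
#'   beta, gamma).
#' @param model_cfg,train_cfg Configurations (the model is fitted per
#'   band and subject).
#' @param layout_id Electrode layout of the trials.
#' @param T_seg Segments per sample.
#' @param fractions,seed Split settings.
#' @return Data.frame with one row per band: `band`, `acc` (mean over
#'   subjects), `sd` (over subjects; NA for one subject).
#' @export
band_experiment <- function(trials, bands = c("theta", "alpha", "beta", "gamma"),
                            model_cfg, train_cfg, layout_id = "deap32",
                            T_seg = 5, fractions = c(0.8, 0.1, 0.1),
                            seed = 1) {
  rows <- list()
  for (band in bands) {
    feats <- extract_features(trials, bands = band_specs(band),
                              T_seg = T_seg, layout_id = layout_id)
    accs <- c()
    for (s in sort(unique(feats$subject))) {
      fs_sub <- subset_features(feats, feats$subject == s)
      run <- within_subject_run(fs_sub, model_cfg, train_cfg,
                                fractions, seed)
      accs <- c(accs, run$metrics$accuracy)
    }
    rows[[length(rows) + 1]] <- data.frame(
      band = band, acc = mean(accs),
      sd = if (length(accs) > 1) stats::sd(accs) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Ablation comparison
#'
#' Trains and evaluates the requested model variants on identical
#' splits and seeds and tabulates test accuracy (see [variant_config()]
#' for the variant definitions). With a `target` set, variants that keep
#' the discriminator are trained adversarially.
#'
#' @param features Labeled source `eeg_features`.
#' @param model_cfg,train_cfg Base configurations.
#' @param variants Subset of `c("V1", "V2", "V3", "V4", "full")`.
#' @param target Optional unlabeled target `eeg_features`; when given,
#'   evaluation is on the target (whose labels are used only for
#'   scoring, never for training).
#' @param fractions,seed Split settings (within-subject mode).
#' @return Data.frame: `variant`, `acc`.
#' @export
ablation_run <- function(features, model_cfg, train_cfg,
                         variants = c("V1", "V2", "V3", "full"),
                         target = NULL, fractions = c(0.8, 0.1, 0.1),
                         seed = 1) {
  unknown <- setdiff(variants, c("V1", "V2", "V3", "V4", "full"))
  if (length(unknown) > 0) {
    stop(sprintf("unknown variant(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  rows <- list()
  for (v in variants) {
    cfg <- variant_config(model_cfg, v)
    if (is.null(target)) {
      run <- within_subject_run(features, cfg, train_cfg, fractions, seed)
      acc <- run$metrics$accuracy
    } else {
      model <- if (cfg$use_discriminator) {
        train_adversarial(features, target, cfg, train_cfg)
      } else {
        train_supervised(features, cfg, train_cfg)
      }
      acc <- evaluate_model(model, target)$accuracy
    }
    rows[[length(rows) + 1]] <- data.frame(variant = v, acc = acc,
                                           stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Region-contribution map from attention weights
#'
#' Runs the model over a test set collecting the attention matrices and
#' aggregates, per region, the total weight the region receives across
#' output positions (its column total in the row-stochastic attention
#' matrix), averaged over all segments and samples. The mean over regions
#' is 1 by construction; regions above 1 contribute more than average.
#'
#' @param model A fitted `r2g_model` with learned attention.
#' @param features `eeg_features` to aggregate over.
#' @param aggregate `"mean"` (default) or `"median"` across segments and
#'   samples.
#' @param batch_size Forward batch size.
#' @return Data.frame: `region`, `contribution`, sorted in region order.
#' @export
region_contribution_map <- function(model, features,
                                    aggregate = c("mean", "median"),
                                    batch_size = 256) {
  aggregate <- match.arg(aggregate)
  if (model$config$attention != "learned") {
    stop("region contributions need a model with learned attention",
         call. = FALSE)
  }
  X <- if (inherits(features, "eeg_features")) features$features else features
  reg_idx <- region_channel_indices(model$partition)
  N <- n_regions(model$partition)
  B <- dim(X)[4]
  sums <- list()
  for (start in seq(1, B, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, B)
    tr <- model_forward(model$params, model$config, reg_idx,
                        X[, , , idx, drop = FALSE], training = FALSE)
    # column totals per (sample x segment): sum over output positions i
    M <- tr$dims$M
    cs <- matrix(0, M, N)
    for (j in seq_len(N)) {
      cs[, j] <- rowSums(matrix(tr$Warr[, , j], M, N))
    }
    sums[[length(sums) + 1]] <- cs
  }
  allc <- do.call(rbind, sums)
  contrib <- if (aggregate == "mean") colMeans(allc) else
    apply(allc, 2, stats::median)
  data.frame(region = model$partition$region_names,
             contribution = contrib, stringsAsFactors = FALSE)
}

#' Paired t-test with multiple-comparison correction
#'
#' Paired two-sided t-test between two accuracy vectors with the p-value
#' corrected for `n_comparisons` tests by Benjamini-Hochberg (default) or
#' Bonferroni.
#'
#' @param a,b Equal-length paired numeric vectors (n >= 2).
#' @param n_comparisons Number of comparisons corrected for.
#' @param method `"BH"` or `"bonferroni"`.
#' @return List with `t`, `df`, `p` (uncorrected), `p_corrected`, and
#'   `significant` (at 0.05 after correction).
#' @export
paired_t_test_corrected <- function(a, b, n_comparisons = 1,
                                    method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0 && any(d != 0)) {
    stop("degenerate case: constant nonzero difference (zero variance)",
         call. = FALSE)
  }
  if (all(d == 0)) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(d) - 1),
               p.value = 1)
  } else {
    tt <- stats::t.test(a, b, paired = TRUE)
  }
  p_corr <- stats::p.adjust(tt$p.value, method = method, n = n_comparisons)
  list(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, p_corrected = p_corr,
    significant = p_corr < 0.05
  )
}
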