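test_that("trial-wise splits are stratified, disjoint and reproducible", {
  ids <- sprintf("t%02d", 1:40)
  labs <- rep(emotion_levels(), length.out = 40)
  sp <- trial_wise_split(ids, labs, c(0.8, 0.1, 0.1), seed = 4)
  expect_equal(length(sp$train), 32)
  expect_equal(length(sp$val), 4)
  expect_equal(length(sp$test), 4)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$val, sp$test), 0)
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_identical(sp, trial_wise_split(ids, labs, c(0.8, 0.1, 0.1), seed = 4))
  expect_false(identical(sp, trial_wise_split(ids, labs, seed = 5)))
  # every fold keeps at least one trial per class
  for (fold in sp) {
    expect_true(all(table(labs[ids %in% fold]) >= 1))
  }
  expect_error(trial_wise_split(c("a", "b"), c("x", "y"), c(0.4, 0.3, 0.3)),
               "not enough")
})

test_that("LOSO folds cover every subject exactly once", {
  subj <- sprintf("s%02d", rep(1:32, each = 3))
  folds <- loso_folds(subj)
  expect_equal(length(folds), 32)
  tests <- vapply(folds, function(f) f$test, "")
  expect_setequal(tests, sprintf("s%02d", 1:32))
  expect_true(all(vapply(folds, function(f) length(f$train), 0L) == 31))
  for (f in folds) expect_false(f$test %in% f$train)
  expect_error(loso_folds("s01"), "at least 2")
})

test_that("evaluation conserves confusion-matrix mass and matches accuracy", {
  f <- small_feats()
  cfg <- tiny_model_cfg(T_seg = 5)
  set.seed(2)
  part <- build_partition("deap32")
  model <- structure(
    list(params = init_params(cfg, part, 4), config = cfg, partition = part),
    class = "r2g_model"
  )
  m <- evaluate_model(model, f)
  expect_equal(sum(m$confusion), m$n)
  expect_equal(m$n, dim(f$features)[4])
  expect_equal(rowSums(m$confusion), as.vector(table(f$labels)),
               ignore_attr = TRUE)
  expect_equal(m$accuracy, sum(diag(m$confusion)) / m$n)
  expect_error(evaluate_model(model, subset_features(f, integer(0))), "empty")
})

test_that("region contributions are nonnegative, average 1, and uniform under flat attention", {
  f <- small_feats()
  cfg <- tiny_model_cfg(T_seg = 5)
  set.seed(3)
  part <- build_partition("deap32")
  params <- init_params(cfg, part, 4)
  params$att$U[] <- 0                       # flat logits -> uniform weights
  model <- structure(
    list(params = params, config = cfg, partition = part),
    class = "r2g_model"
  )
  cm <- region_contribution_map(model, subset_features(f, 1:6))
  expect_equal(cm$contribution, rep(1, 12), tolerance = 1e-9)
  set.seed(4)
  params2 <- init_params(cfg, part, 4)
  model2 <- structure(
    list(params = params2, config = cfg, partition = part),
    class = "r2g_model"
  )
  cm2 <- region_contribution_map(model2, subset_features(f, 1:6))
  expect_true(all(cm2$contribution >= 0))
  expect_equal(mean(cm2$contribution), 1, tolerance = 1e-9)
  # attention-free models cannot produce a contribution map
  cfg3 <- variant_config(cfg, "V3")
  model3 <- structure(
    list(params = init_params(cfg3, part, 4), config = cfg3, partition = part),
    class = "r2g_model"
  )
  expect_error(region_contribution_map(model3, f), "learned attention")
})

test_that("paired t-tests match the textbook formula and are corrected", {
  a <- c(0.8, 0.9, 0.85, 0.7, 0.95)
  res <- paired_t_test_corrected(a, a)
  expect_equal(res$t, 0)
  expect_equal(res$p_corrected, 1)
  expect_error(paired_t_test_corrected(a, a - 0.1), "degenerate")
  set.seed(5)
  b <- a + rnorm(5, 0.02, 0.05)
  got <- paired_t_test_corrected(a, b, n_comparisons = 3,
                                 method = "bonferroni")
  d <- a - b
  t_ref <- mean(d) / (sd(d) / sqrt(5))
  p_ref <- 2 * pt(-abs(t_ref), df = 4)
  expect_equal(got$t, t_ref, tolerance = 1e-10)
  expect_equal(got$p, p_ref, tolerance = 1e-10)
  expect_equal(got$p_corrected, min(1, 3 * p_ref), tolerance = 1e-10)
  bh <- paired_t_test_corrected(a, b, n_comparisons = 3, method = "BH")
  expect_equal(bh$p_corrected, p.adjust(p_ref, "BH", n = 3))
})

test_that("ablation tables cover the requested variants on identical folds", {
  f <- small_feats()
  cfg <- tiny_model_cfg(T_seg = 5)
  tc <- train_config(learning_rate = 0.05, batch_size = 12, epochs = 2,
                     patience = Inf, seed = 6)
  tab <- ablation_run(f, cfg, tc, variants = c("V1", "V3", "full"),
                      fractions = c(0.6, 0.2, 0.2), seed = 6)
  expect_equal(tab$variant, c("V1", "V3", "full"))
  expect_true(all(tab$acc >= 0 & tab$acc <= 1))
  expect_error(ablation_run(f, cfg, tc, variants = "V9"), "unknown variant")
})

test_that("metrics and contributions export to CSV", {
  f <- small_feats()
  cfg <- tiny_model_cfg(T_seg = 5)
  set.seed(7)
  part <- build_partition("deap32")
  model <- structure(
    list(params = init_params(cfg, part, 4), config = cfg, partition = part),
    class = "r2g_model"
  )
  m <- evaluate_model(model, f)
  path <- tempfile(fileext = ".csv")
  export_metrics_csv(m, path)
  back <- utils::read.csv(path)
  expect_equal(back$accuracy, m$accuracy)
  conf <- utils::read.csv(sub("\\.csv$", "_confusion.csv", path), row.names = 1)
  expect_equal(sum(conf), m$n)
  cpath <- tempfile(fileext = ".csv")
  cm <- data.frame(region = part$region_names, contribution = rep(1, 12))
  export_contributions_csv(cm, cpath)
  expect_equal(utils::read.csv(cpath)$contribution, rep(1, 12))
})

test_that("the command-line front end runs a tiny synth-features cycle", {
  cli <- system.file("cli", "r2g", package = "eegr2g")
  expect_true(file.exists(cli))
  td <- tempfile(); dir.create(td)
  cfg_path <- file.path(td, "synth.yaml")
  yaml::write_yaml(
    list(n_subjects = 1, trials_per_subject = 2, trial_seconds = 5, seed = 3),
    cfg_path
  )
  data_path <- file.path(td, "data.rds")
  out1 <- system2("Rscript", c(cli, "synth", "--config", cfg_path,
                               "--out", data_path),
                  stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(data_path))
  feat_path <- file.path(td, "feats.rds")
  out2 <- system2("Rscript", c(cli, "features", "--in", data_path,
                               "--T", "5", "--out", feat_path),
                  stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(feat_path))
  feats <- load_features(feat_path)
  expect_equal(dim(feats$features)[1:3], c(4, 32, 5))
})
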