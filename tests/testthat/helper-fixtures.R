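# Shared fixtures: tiny partitions/configs and one small planted dataset,
# built in code at test time.

tiny_partition <- function(sizes, prefix = "R") {
  nms <- paste0(prefix, seq_along(sizes))
  elec <- split(
    sprintf("E%02d", seq_len(sum(sizes))),
    rep(seq_along(sizes), times = sizes)
  )
  structure(
    list(layout_id = "tiny", region_names = nms,
         regions = stats::setNames(lapply(elec, unname), nms)),
    class = "region_partition"
  )
}

tiny_model_cfg <- function(...) {
  defaults <- list(
    d_r = 2, d_g = 2, d_rt = 2, d_gt = 2, attn_hidden = 4, K = 2, C = 3,
    T_seg = 3, dropout = 0, init_scale = 0.2, disc_hidden = 3
  )
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

zero_params <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

# small strongly separable single-subject set (9 trials x 20 s -> 36 samples)
small_feats <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- synth_config(
        n_subjects = 1, trials_per_subject = 9, trial_seconds = 20,
        effect_size = 2.0, domain_shift_sd = 0, seed = 42
      )
      cache <<- extract_features(generate_subject(sc, 1),
                                 layout_id = "deap32")
    }
    cache
  }
})

desk_model_cfg <- function(...) {
  defaults <- list(
    d_r = 12, d_g = 12, d_rt = 12, d_gt = 12, attn_hidden = 24, K = 4,
    C = 3, T_seg = 5, dropout = 0.2, init_scale = 0.1
  )
  do.call(model_config, utils::modifyList(defaults, list(...)))
}
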