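#' Synthetic multi-subject EEG configuration
#'
#' The generator emulates a fixed-protocol affect-elicitation acquisition:
#' per-subject sets of fixed-length trials of pink-noise (1/f) background
#' EEG with a class-dependent band-limited oscillation planted on the
#' channels of selected brain regions, plus subject-specific per-channel
#' gain and DC-offset domain shifts. Defaults mirror the 32-channel
#' protocol shape: 40 trials of 60 s at 128 Hz per subject.
#'
#' The class effect is ordinal: classes negative/neutral/positive carry
#' oscillation log band-power offsets of (0, 1/2, 1) x `effect_size`
#' (amplitude multiplier `exp(level / 2)`), so `effect_size` is the log
#' band-power ratio between the extreme classes and `effect_size = 0` is
#' an exact null. Oscillation frequency is drawn uniformly within the
#' planted band per trial; phases are random per channel.
#'
#' @param n_subjects Number of subjects.
#' @param trials_per_subject Trials per subject.
#' @param trial_seconds Trial length (s).
#' @param fs Sampling rate (Hz).
#' @param layout_id Electrode layout (`"deap32"` or `"seed62"`).
#' @param class_probs Length-3 class probabilities (negative, neutral,
#'   positive); must sum to 1.
#' @param planted_regions Region names or indices carrying the signal.
#' @param planted_band Band name (see [band_specs()]).
#' @param effect_size Log band-power ratio between extreme classes
#'   (>= 0).
#' @param noise_sd Pink-noise standard deviation (microvolts).
#' @param osc_amplitude Baseline oscillation amplitude (microvolts).
#' @param domain_shift_sd Per-subject channel log-gain and offset scale
#'   (0 disables the shift).
#' @param balanced_labels Deal labels in exact configured proportions
#'   (shuffled) instead of multinomial sampling.
#' @param seed Master seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 4, trials_per_subject = 40,
                         trial_seconds = 60, fs = 128,
                         layout_id = "deap32",
                         class_probs = c(1, 1, 1) / 3,
                         planted_regions = c("Pre-frontal", "Frontal"),
                         planted_band = "beta", effect_size = 1.0,
                         noise_sd = 1.0, osc_amplitude = 1.0,
                         domain_shift_sd = 0.25,
                         balanced_labels = TRUE, seed = 1) {
  stopifnot(
    n_subjects >= 1, trials_per_subject >= 1, trial_seconds > 0, fs > 0,
    effect_size >= 0, noise_sd > 0, osc_amplitude >= 0,
    domain_shift_sd >= 0, length(class_probs) == 3,
    abs(sum(class_probs) - 1) < 1e-8
  )
  part <- build_partition(layout_id)
  if (is.numeric(planted_regions)) {
    if (any(planted_regions < 1 | planted_regions > n_regions(part))) {
      stop("planted region index out of range", call. = FALSE)
    }
    planted_regions <- part$region_names[planted_regions]
  }
  unknown <- setdiff(planted_regions, part$region_names)
  if (length(unknown) > 0) {
    stop(sprintf("unknown planted region(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  band <- band_specs(c("delta", "theta", "alpha", "beta", "gamma"))
  if (!planted_band %in% names(band)) {
    stop(sprintf("unknown planted band '%s'", planted_band), call. = FALSE)
  }
  structure(
    list(
      n_subjects = n_subjects, trials_per_subject = trials_per_subject,
      trial_seconds = trial_seconds, fs = fs, layout_id = layout_id,
      class_probs = class_probs, planted_regions = planted_regions,
      planted_band = planted_band, effect_size = effect_size,
      noise_sd = noise_sd, osc_amplitude = osc_amplitude,
      domain_shift_sd = domain_shift_sd,
      balanced_labels = balanced_labels, seed = seed
    ),
    class = "synth_config"
  )
}

# 1/f-amplitude (pink) Gaussian noise, one column per channel.
pink_noise <- function(n, n_ch, sd) {
  white <- matrix(stats::rnorm(n * n_ch), n, n_ch)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f)              # two-sided frequency index
  amp <- 1 / sqrt(f)
  x <- Re(stats::mvfft(stats::mvfft(white) * amp, inverse = TRUE)) / n
  x <- sweep(x, 2, apply(x, 2, stats::sd), "/") * sd
  sweep(x, 2, colMeans(x), "-")
}

#' Generate one synthetic subject
#'
#' See [synth_config()] for the generative model. Fully seeded: the same
#' `(config, subject_index)` pair always produces byte-identical trials.
#'
#' @param config A `synth_config`.
#' @param subject_index 1-based subject number (drives the subject's seed
#'   and domain shift).
#' @return List of `raw_trial` objects with labels in
#'   [emotion_levels()].
#' @export
generate_subject <- function(config, subject_index = 1) {
  stopifnot(inherits(config, "synth_config"), subject_index >= 1)
  set.seed(derive_seed(config$seed, 1000 + subject_index))
  layout <- electrode_layout(config$layout_id)
  part <- build_partition(config$layout_id)
  reg_idx <- region_channel_indices(part, layout)
  planted_ch <- sort(unique(unlist(reg_idx[config$planted_regions])))
  n_ch <- length(layout$electrodes)
  n_samp <- round(config$trial_seconds * config$fs)
  band <- band_specs(c("delta", "theta", "alpha", "beta",
                       "gamma"))[[config$planted_band]]
  n_tr <- config$trials_per_subject

  # per-subject domain shift: channel gains and DC offsets
  gain <- exp(stats::rnorm(n_ch, 0, config$domain_shift_sd))
  offset <- stats::rnorm(n_ch, 0, config$domain_shift_sd)

  # trial labels
  if (config$balanced_labels) {
    counts <- floor(config$class_probs * n_tr)
    rem <- n_tr - sum(counts)
    if (rem > 0) {
      extra <- sample.int(3, rem, prob = config$class_probs)
      for (e in extra) counts[e] <- counts[e] + 1
    }
    cls <- sample(rep(seq_len(3), times = counts))
  } else {
    cls <- sample.int(3, n_tr, replace = TRUE, prob = config$class_probs)
  }
  levels3 <- emotion_levels()

  tt <- seq_len(n_samp) / config$fs
  lapply(seq_len(n_tr), function(k) {
    x <- pink_noise(n_samp, n_ch, config$noise_sd)
    if (length(planted_ch) > 0 && config$osc_amplitude > 0) {
      freq <- stats::runif(1, band[1], band[2])
      level <- c(0, 0.5, 1)[cls[k]] * config$effect_size
      amp <- config$osc_amplitude * exp(level / 2)
      for (ch in planted_ch) {
        phase <- stats::runif(1, 0, 2 * pi)
        x[, ch] <- x[, ch] + amp * sin(2 * pi * freq * tt + phase)
      }
    }
    x <- sweep(sweep(x, 2, gain, "*"), 2, offset, "+")
    raw_trial(
      t(x), config$fs, label = levels3[cls[k]],
      trial_id = sprintf("s%02d_t%02d", subject_index, k),
      subject_id = sprintf("s%02d", subject_index)
    )
  })
}

#' Generate a full synthetic dataset
#'
#' @param config A `synth_config`.
#' @return Flat list of `raw_trial` objects over all subjects.
#' @export
generate_dataset <- function(config) {
  unlist(lapply(seq_len(config$n_subjects), function(s) {
    generate_subject(config, s)
  }), recursive = FALSE)
}

#' Planted-effect summary of a feature set
#'
#' Per region x band: class-conditional DE means (averaged over the
#' region's channels and all segments) and a standardized effect — the
#' range of the class means divided by the pooled within-class standard
#' deviation of the per-sample region-band means. Serves as the
#' generator-side oracle for attention-recovery experiments: the planted
#' region/band should top the standardized-effect ranking.
#'
#' @param features An `eeg_features` object.
#' @param partition A `region_partition` (default from the feature set's
#'   layout).
#' @return Data.frame with columns `region`, `band`, one `mean_<class>`
#'   column per class, and `effect`, sorted as region x band.
#' @export
planted_effect_report <- function(features,
                                  partition = build_partition(features$layout_id)) {
  stopifnot(inherits(features, "eeg_features"))
  reg_idx <- region_channel_indices(partition)
  X <- features$features          # d x n x T x S
  lab <- features$labels
  classes <- levels(lab)
  rows <- list()
  for (j in seq_along(reg_idx)) {
    for (b in seq_len(dim(X)[1])) {
      # per-sample mean DE over the region's channels and segments
      v <- apply(X[b, reg_idx[[j]], , , drop = FALSE], 4, mean)
      mns <- tapply(v, lab, mean)
      sds <- tapply(v, lab, stats::sd)
      pooled <- sqrt(mean(sds^2, na.rm = TRUE))
      eff <- if (is.finite(pooled) && pooled > 0) {
        (max(mns, na.rm = TRUE) - min(mns, na.rm = TRUE)) / pooled
      } else {
        0
      }
      row <- data.frame(region = partition$region_names[j],
                        band = features$bands[b], effect = eff,
                        stringsAsFactors = FALSE)
      for (cl in classes) row[[paste0("mean_", cl)]] <- unname(mns[cl])
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}
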