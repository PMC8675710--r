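#' Standard EEG frequency bands
#'
#' Band edges in Hz: delta 1--4, theta 5--8, alpha 9--14, beta 15--30,
#' gamma 31--50. With the 4--45 Hz acquisition band-pass applied to
#' 128 Hz recordings, delta carries no signal and the four bands
#' theta/alpha/beta/gamma are the default feature set (d = 4).
#'
#' @param names Band names to return (subset of delta, theta, alpha, beta,
#'   gamma). Defaults to the four-band set.
#' @return Named list of `c(lo, hi)` numeric pairs.
#' @export
band_specs <- function(names = c("theta", "alpha", "beta", "gamma")) {
  all <- list(
    delta = c(1, 4), theta = c(5, 8), alpha = c(9, 14),
    beta = c(15, 30), gamma = c(31, 50)
  )
  unknown <- setdiff(names, names(all))
  if (length(unknown) > 0) {
    stop(sprintf("unknown band(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  all[names]
}

#' Construct a raw EEG trial
#'
#' @param data Numeric matrix, channels x samples (microvolts), channel rows
#'   in layout order.
#' @param fs Sampling rate in Hz.
#' @param label Emotion class (factor/character) or `NA`.
#' @param rating Optional raw 1--9 affect rating.
#' @param trial_id,subject_id Identifiers.
#' @return A `raw_trial` object.
#' @export
raw_trial <- function(data, fs, label = NA, rating = NULL,
                      trial_id = NA_character_, subject_id = NA_character_) {
  stopifnot(is.matrix(data), is.numeric(data), fs > 0)
  if (anyNA(data)) stop("trial data contains NA", call. = FALSE)
  structure(
    list(data = data, fs = fs, label = label, rating = rating,
         trial_id = trial_id, subject_id = subject_id),
    class = "raw_trial"
  )
}

#' @export
print.raw_trial <- function(x, ...) {
  cat(sprintf(
    "<raw_trial %s/%s: %d ch x %d samples @ %g Hz, label %s>\n",
    x$subject_id, x$trial_id, nrow(x$data), ncol(x$data), x$fs,
    as.character(x$label)
  ))
  invisible(x)
}

# Zero-phase Butterworth band-pass of a channels-in-columns matrix.
# method "fft" multiplies the FFT of the reflection-padded signal by the
# squared magnitude response of the order-`order` Butterworth band-pass --
# the same transfer function filtfilt applies, without its edge transients
# and vectorized across channels. method "filtfilt" delegates per channel
# to signal::filtfilt.
butter_zero_phase <- function(x, lo, hi, fs, order = 4,
                              method = c("fft", "filtfilt")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  ns <- nrow(x)
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  if (method == "filtfilt") {
    return(apply(x, 2, function(col) signal::filtfilt(bf, col)))
  }
  pad <- min(ns - 1, max(3 * order * 10, 256))
  xp <- rbind(
    x[rev(seq_len(pad) + 1), , drop = FALSE],
    x,
    x[ns - seq_len(pad), , drop = FALSE]
  )
  np <- nrow(xp)
  w <- 2 * pi * seq(0, np - 1) / np
  ejw <- exp(-1i * outer(w, 0:(length(bf$b) - 1)))
  h <- as.vector(ejw %*% bf$b) / as.vector(ejw %*% bf$a)
  gain <- Mod(h)^2
  y <- Re(stats::mvfft(stats::mvfft(xp) * gain, inverse = TRUE)) / np
  y[pad + seq_len(ns), , drop = FALSE]
}

#' Zero-phase band-pass filter a trial
#'
#' Applies an order-`order` zero-phase Butterworth band-pass to every
#' channel of a trial; shape is preserved. The default applies the
#' squared-magnitude Butterworth response in the frequency domain on a
#' reflection-padded signal, which matches forward-backward IIR filtering
#' away from the edges while vectorizing over channels;
#' `method = "filtfilt"` uses [signal::filtfilt()] per channel.
#'
#' @param trial A `raw_trial`.
#' @param lo,hi Band edges in Hz, `0 < lo < hi < fs/2`.
#' @param order Butterworth order (default 4).
#' @param method `"fft"` (default) or `"filtfilt"`.
#' @return A `raw_trial` with filtered data.
#' @export
bandpass_filter <- function(trial, lo, hi, order = 4,
                            method = c("fft", "filtfilt")) {
  stopifnot(inherits(trial, "raw_trial"))
  if (!(lo > 0 && lo < hi && hi < trial$fs / 2)) {
    stop(sprintf(
      "invalid band edges (%g, %g) Hz for fs = %g Hz: need 0 < lo < hi < fs/2",
      lo, hi, trial$fs
    ), call. = FALSE)
  }
  filtered <- t(butter_zero_phase(t(trial$data), lo, hi, trial$fs,
                                  order = order, method = match.arg(method)))
  out <- trial
  out$data <- filtered
  out
}

#' Cut a trial into non-overlapping fixed-length segments
#'
#' Consecutive half-open windows of `seg_seconds` starting at the trial
#' onset; trailing samples that do not fill a window are dropped.
#'
#' @param trial A `raw_trial`.
#' @param seg_seconds Window length in seconds (default 1).
#' @return List of channels x samples matrices.
#' @export
segment_trial <- function(trial, seg_seconds = 1) {
  stopifnot(inherits(trial, "raw_trial"))
  len <- round(seg_seconds * trial$fs)
  n <- ncol(trial$data)
  k <- n %/% len
  if (k < 1) {
    stop(sprintf(
      "trial shorter than one segment (%d samples < %d)", n, len
    ), call. = FALSE)
  }
  lapply(seq_len(k), function(i) {
    trial$data[, ((i - 1) * len + 1):(i * len), drop = FALSE]
  })
}

#' Differential entropy of a segment
#'
#' DE = 1/2 log(2 pi e sigma^2) in nats, where sigma^2 is the sample
#' variance of the (optionally band-filtered) segment: the Gaussian
#' closed form, the standard definition for band-limited EEG segments.
#' A variance floor prevents -Inf on (near-)constant segments.
#'
#' @param x Numeric vector of samples from one channel (length >= 8), or a
#'   band-filtered segment when `band` is `NULL`.
#' @param band Optional `c(lo, hi)` band in Hz; when given, `x` is
#'   band-filtered before the variance is taken (requires `fs`).
#' @param fs Sampling rate in Hz (only needed with `band`).
#' @param var_floor Variance floor (default 1e-12).
#' @return DE value in nats.
#' @export
differential_entropy <- function(x, band = NULL, fs = NULL,
                                 var_floor = 1e-12) {
  stopifnot(is.numeric(x), length(x) >= 8)
  if (!is.null(band)) {
    stopifnot(!is.null(fs), length(band) == 2, band[1] < band[2])
    x <- as.vector(butter_zero_phase(matrix(x, ncol = 1),
                                     band[1], band[2], fs))
  }
  v <- max(stats::var(x), var_floor)
  0.5 * log(2 * pi * exp(1) * v)
}

#' Per-band, per-channel DE features of one segment
#'
#' @param segment Channels x samples matrix (channel rows in layout order).
#' @param bands Named list of `c(lo, hi)` pairs (see [band_specs()]).
#' @param fs Sampling rate in Hz.
#' @param var_floor Variance floor passed to [differential_entropy()].
#' @return d x n matrix (bands x channels) of DE values; rows named by band.
#' @export
extract_segment_features <- function(segment, bands, fs, var_floor = 1e-12) {
  stopifnot(is.matrix(segment), length(bands) >= 1)
  out <- matrix(0, length(bands), nrow(segment),
                dimnames = list(names(bands), rownames(segment)))
  for (b in seq_along(bands)) {
    filt <- butter_zero_phase(t(segment), bands[[b]][1], bands[[b]][2], fs)
    v <- pmax(apply(filt, 2, stats::var), var_floor)
    out[b, ] <- 0.5 * log(2 * pi * exp(1) * v)
  }
  out
}

#' Group consecutive segment features into samples
#'
#' Stacks consecutive non-overlapping groups of `T` segment feature
#' matrices into d x n x T tensors; a trailing remainder of fewer than `T`
#' segments is dropped. Grouping never crosses a trial boundary (callers
#' pass one trial's segments at a time; [extract_features()] enforces it).
#'
#' @param segment_features List of d x n matrices from one trial, in time
#'   order.
#' @param T_seg Segments per sample (default 5).
#' @return List of d x n x T arrays (possibly empty).
#' @export
assemble_samples <- function(segment_features, T_seg = 5) {
  stopifnot(T_seg >= 1, length(segment_features) >= 0)
  k <- length(segment_features) %/% T_seg
  if (k == 0) return(list())
  d <- nrow(segment_features[[1]])
  n <- ncol(segment_features[[1]])
  lapply(seq_len(k), function(i) {
    grp <- segment_features[((i - 1) * T_seg + 1):(i * T_seg)]
    array(unlist(grp), dim = c(d, n, T_seg),
          dimnames = list(rownames(segment_features[[1]]), NULL, NULL))
  })
}

#' Threshold continuous 1--9 affect ratings into three classes
#'
#' Ratings at or below `low` are negative, above `high` positive, and
#' in between neutral (the conventional 4/7 thresholds).
#'
#' @param rating Numeric vector of ratings in `[1, 9]`.
#' @param low,high Class thresholds with `low < high` (defaults 4 and 7).
#' @return Factor with levels negative, neutral, positive.
#' @export
threshold_ratings <- function(rating, low = 4, high = 7) {
  stopifnot(low < high)
  if (any(rating < 1 | rating > 9)) {
    stop("ratings must lie in [1, 9]", call. = FALSE)
  }
  cls <- ifelse(rating <= low, "negative",
                ifelse(rating <= high, "neutral", "positive"))
  factor(cls, levels = emotion_levels())
}

#' @rdname threshold_ratings
#' @export
emotion_levels <- function() c("negative", "neutral", "positive")

#' Feature-extraction pipeline: raw trials to DE feature samples
#'
#' For each trial: optional acquisition band-pass (4--45 Hz by default),
#' 1-s segmentation, per-band zero-phase filtering at the trial level
#' followed by per-segment variances (an order-4 IIR response does not
#' settle within a 1-s segment, so filtering whole trials is both faster
#' and cleaner), DE via the Gaussian closed form, and grouping of `T_seg`
#' adjacent segments into one sample. Samples inherit the trial's label
#' and never span trials.
#'
#' @param trials List of `raw_trial` objects (one or more subjects).
#' @param bands Named list of bands (default [band_specs()], d = 4).
#' @param T_seg Segments per sample (default 5).
#' @param seg_seconds Segment length in seconds (default 1).
#' @param prefilter `c(lo, hi)` acquisition band-pass in Hz, or `NULL` to
#'   skip (default `c(4, 45)`).
#' @param layout_id Layout identifier recorded in the result.
#' @param var_floor Variance floor for DE.
#' @return An `eeg_features` object: list with `features`
#'   (d x n x T x n_samples array), `labels` (factor), `subject`, `trial`
#'   (vectors, one entry per sample), plus `bands`, `fs`, `T_seg`,
#'   `layout_id`.
#' @export
extract_features <- function(trials, bands = band_specs(), T_seg = 5,
                             seg_seconds = 1, prefilter = c(4, 45),
                             layout_id = NA_character_, var_floor = 1e-12) {
  stopifnot(length(trials) >= 1, T_seg >= 1)
  d <- length(bands)
  tensors <- list()
  labels <- character()
  subjects <- character()
  trial_ids <- character()
  for (tr in trials) {
    x <- tr$data
    fs <- tr$fs
    if (!is.null(prefilter)) {
      x <- t(butter_zero_phase(t(x), prefilter[1], prefilter[2], fs))
    }
    len <- round(seg_seconds * fs)
    nseg <- ncol(x) %/% len
    if (nseg < T_seg) next
    n_ch <- nrow(x)
    de <- array(0, dim = c(d, n_ch, nseg))
    for (b in seq_len(d)) {
      filt <- butter_zero_phase(t(x), bands[[b]][1], bands[[b]][2], fs)
      for (s in seq_len(nseg)) {
        seg <- filt[((s - 1) * len + 1):(s * len), , drop = FALSE]
        m <- colMeans(seg)
        v <- pmax((colSums(seg^2) - len * m^2) / (len - 1), var_floor)
        de[b, , s] <- 0.5 * log(2 * pi * exp(1) * v)
      }
    }
    k <- nseg %/% T_seg
    for (i in seq_len(k)) {
      tensors[[length(tensors) + 1]] <-
        de[, , ((i - 1) * T_seg + 1):(i * T_seg), drop = FALSE]
      labels <- c(labels, as.character(tr$label))
      subjects <- c(subjects, tr$subject_id)
      trial_ids <- c(trial_ids, tr$trial_id)
    }
  }
  if (length(tensors) == 0) {
    stop("no trial produced at least T_seg segments", call. = FALSE)
  }
  n_ch <- dim(tensors[[1]])[2]
  feat <- array(unlist(tensors),
                dim = c(d, n_ch, T_seg, length(tensors)),
                dimnames = list(names(bands), NULL, NULL, NULL))
  structure(
    list(
      features = feat,
      labels = factor(labels, levels = emotion_levels()),
      subject = subjects,
      trial = trial_ids,
      bands = names(bands),
      fs = trials[[1]]$fs,
      T_seg = T_seg,
      layout_id = layout_id
    ),
    class = "eeg_features"
  )
}

#' @export
print.eeg_features <- function(x, ...) {
  d <- dim(x$features)
  cat(sprintf(
    "<eeg_features: %d samples of %d band(s) x %d ch x T=%d, %d subject(s)>\n",
    d[4], d[1], d[2], d[3], length(unique(x$subject))
  ))
  print(table(x$labels))
  invisible(x)
}

#' Subset an eeg_features object by sample index
#'
#' @param x An `eeg_features` object.
#' @param idx Integer or logical sample index.
#' @return The subset `eeg_features`.
#' @export
subset_features <- function(x, idx) {
  stopifnot(inherits(x, "eeg_features"))
  out <- x
  out$features <- x$features[, , , idx, drop = FALSE]
  out$labels <- x$labels[idx]
  out$subject <- x$subject[idx]
  out$trial <- x$trial[idx]
  out
}

#' Expected sample counts of the segmentation pipeline
#'
#' Exact count arithmetic for a fixed-protocol acquisition: samples per
#' trial, segments per trial/subject, feature samples per subject and for
#' the whole dataset. Matches what [extract_features()] produces on
#' generated data (checked in the test suite).
#'
#' @param n_subjects,trials_per_subject,trial_seconds Protocol shape.
#' @param fs Sampling rate (Hz).
#' @param seg_seconds Segment length (s).
#' @param T_seg Segments per sample.
#' @return Named list of counts.
#' @export
pipeline_counts <- function(n_subjects, trials_per_subject, trial_seconds,
                            fs, seg_seconds = 1, T_seg = 5) {
  samples_per_trial <- floor(trial_seconds * fs)
  segs_per_trial <- samples_per_trial %/% round(seg_seconds * fs)
  segs_per_subject <- segs_per_trial * trials_per_subject
  samples_per_subject <- (segs_per_trial %/% T_seg) * trials_per_subject
  list(
    raw_samples_per_trial = samples_per_trial,
    segments_per_trial = segs_per_trial,
    segments_per_subject = segs_per_subject,
    feature_samples_per_subject = samples_per_subject,
    feature_samples_total = samples_per_subject * n_subjects
  )
}
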