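# End-to-end sound pipeline: synthetic sound-event generation, SN-MFCC
# feature extraction through a resonator bank, and the one-layer
# STDP-trained SCTN classifier with its cross-validation protocol.
#
# The package's default classification study is a scaled emulation of the
# ten-class sound-event benchmark: 10 synthetic classes x 40 samples,
# 20/20 train/test split per class, a mel-spaced resonator bank, and a
# 96 kHz pulse clock whose (LF, LP) grid covers the 20-300 Hz
# analysis band holding the generator's class signatures (the
# band and the bank resolution scale together with the clock, as in the
# full-rate system). The vignette discusses these choices.

PIPE_CLOCK_HZ <- 96000
PIPE_BAND_HZ <- c(20, 300)
PIPE_TONE_HZ <- c(28, 100)

mel_of <- function(f) 2595 * log10(1 + f / 700)
mel_inv <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel-spaced centre frequencies for a resonator bank
#'
#' @param n Number of resonators.
#' @param fmin_hz,fmax_hz Band edges in Hz.
#' @return Numeric vector of `n` mel-spaced frequencies.
#' @export
bank_frequencies <- function(n, fmin_hz = PIPE_BAND_HZ[1],
                             fmax_hz = PIPE_BAND_HZ[2]) {
  stopifnot(n >= 1, fmin_hz > 0, fmax_hz > fmin_hz)
  mel_inv(seq(mel_of(fmin_hz), mel_of(fmax_hz), length.out = n))
}

#' Synthetic isolated sound-event dataset
#'
#' Emulates short recorded sound events from distinct classes: each class
#' has a harmonic spectral signature of 2-4 component tones (a fundamental
#' placed log-uniformly across the band so dominant frequencies are
#' pairwise distinct, plus 1-3 partials at integer multiples with
#' amplitudes decaying roughly as 1/k), an attack-decay onset envelope,
#' small per-sample frequency/phase jitter (inharmonicity), and additive
#' Gaussian background noise at a configurable SNR. Same seed, same
#' dataset, bit for bit.
#'
#' @param n_classes Number of classes (`>= 2`).
#' @param n_per_class Samples per class.
#' @param seed Integer seed; the generator restores the global RNG state.
#' @param rate_hz Sample rate (16 kHz default).
#' @param duration_range Event duration range in seconds.
#' @param freq_range Band in which the class fundamentals are placed (Hz);
#'   partials extend to small integer multiples.
#' @param snr_db Signal-to-noise ratio of the added background noise.
#' @return Object of class `sound_dataset`: waveforms, integer labels,
#'   class signatures, and the generation parameters.
#' @export
make_synthetic_dataset <- function(n_classes = 10, n_per_class = 40,
                                   seed = 1L, rate_hz = 16000,
                                   duration_range = c(0.5, 1.0),
                                   freq_range = PIPE_TONE_HZ,
                                   snr_db = 15) {
  if (n_classes < 2) stop("need at least 2 classes", call. = FALSE)
  if (any(freq_range >= rate_hz / 2))
    stop("tone band must lie below Nyquist", call. = FALSE)
  withr::with_seed(seed, {
    dom <- exp(seq(log(freq_range[1] * 1.1), log(freq_range[2] * 0.9),
                   length.out = n_classes))
    signatures <- lapply(seq_len(n_classes), function(c) {
      k <- sample(1:3, 1) # partials above the fundamental
      harm <- 1 + seq_len(k)
      list(freq_hz = dom[c] * c(1, harm),
           amp = c(1, runif(k, 0.7, 1.3) / harm))
    })
    waves <- list()
    labels <- integer(0)
    for (c in seq_len(n_classes)) {
      sig <- signatures[[c]]
      for (s in seq_len(n_per_class)) {
        dur <- runif(1, duration_range[1], duration_range[2])
        t <- seq(0, dur, by = 1 / rate_hz)
        t <- t[-length(t)]
        env <- (1 - exp(-t / 0.01)) * exp(-t / (dur / 3))
        x <- numeric(length(t))
        for (j in seq_along(sig$freq_hz)) {
          f <- sig$freq_hz[j] * runif(1, 0.995, 1.005)
          x <- x + sig$amp[j] * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
        }
        x <- x * env
        p_sig <- mean(x^2)
        x <- x + rnorm(length(x), sd = sqrt(p_sig / 10^(snr_db / 10)))
        x <- 0.9 * x / max(abs(x))
        waves[[length(waves) + 1L]] <- waveform(x, rate_hz)
        labels <- c(labels, c)
      }
    }
    structure(list(waves = waves, labels = labels,
                   class_names = sprintf("class%02d", seq_len(n_classes)),
                   signatures = signatures, rate_hz = rate_hz,
                   seed = seed, snr_db = snr_db,
                   freq_range = freq_range),
              class = "sound_dataset")
  })
}

#' @export
print.sound_dataset <- function(x, ...) {
  cat(sprintf(
    "<sound_dataset> %d samples, %d classes @ %g Hz (seed %d, SNR %g dB)\n",
    length(x$waves), length(x$class_names), x$rate_hz, x$seed, x$snr_db))
  invisible(x)
}

#' Extract SN-MFCC features from a waveform
#'
#' PDM-encodes the waveform once at the bank's pulse clock, drives every
#' resonator of the bank over the full stream (no framing), and bins each
#' resonator's output spike train: the SN-MFCC coefficients are the
#' per-bin output spike rates, one column per resonator.
#'
#' @param wave A [waveform()].
#' @param bank An [build_bank()] resonator bank.
#' @param bin_s Feature bin width in seconds.
#' @return An `snmfcc` matrix (bins x resonators, rates in Hz) with
#'   attributes `bank_hz` (centre frequencies) and `bin_s`.
#' @export
extract_snmfcc <- function(wave, bank, bin_s = 0.01) {
  if (!inherits(bank, "sctn_bank") || length(bank) == 0)
    stop("`bank` must be a non-empty sctn_bank", call. = FALSE)
  stopifnot(inherits(wave, "waveform"))
  clock <- bank[[1]]$spec$clock_hz
  train <- pdm_encode(wave, clock)
  bin_ticks <- max(1L, as.integer(round(bin_s * clock)))
  counts <- bank_extract_cpp(train$bits,
                             lapply(bank, function(r) reso_params(r$spec)),
                             bin_ticks)
  rates <- counts / (bin_ticks / clock)
  structure(rates, class = c("snmfcc", "matrix", "array"),
            bank_hz = attr(bank, "achieved_hz"), bin_s = bin_s)
}

#' Extract features for a whole dataset
#'
#' @param dataset A [make_synthetic_dataset()] result (or any list with
#'   `waves` and `labels`).
#' @param bank A resonator bank.
#' @param bin_s Feature bin width in seconds.
#' @param progress Print a progress line every 50 samples.
#' @return `list(features = list of snmfcc matrices, labels, bank_hz)`.
#' @export
extract_features <- function(dataset, bank, bin_s = 0.01,
                             progress = FALSE) {
  feats <- vector("list", length(dataset$waves))
  for (i in seq_along(dataset$waves)) {
    feats[[i]] <- extract_snmfcc(dataset$waves[[i]], bank, bin_s)
    if (progress && i %% 50 == 0)
      message(sprintf("extracted %d / %d", i, length(feats)))
  }
  list(features = feats, labels = dataset$labels,
       bank_hz = attr(bank, "achieved_hz"), bin_s = bin_s)
}

# Feature conditioning before rate-coding into the classifier: scale each
# sample to peak density 1 (loudness-invariant), floor away the resonators'
# residual idle activity, and zero columns whose above-floor activity is
# not temporally persistent. Tone-driven resonators stay active across
# most of the event while background-noise excursions flicker in scattered
# bins; the persistence gate keeps the former and silences the latter, so
# that uninformative synapses carry no pre spikes at all (and hence, by
# the STDP window rule, never drift toward saturation over long training).
normalize_features <- function(f, floor = 0.25, persistence = 0.65) {
  m <- max(f)
  if (m <= 0) return(f)
  d <- pmax((f / m - floor) / (1 - floor), 0)
  if (nrow(d) > 1) d[, colMeans(d > 0) < persistence] <- 0
  d
}

classifier_neuron <- function(n_syn, lf = 5L, lp = 0L, threshold = NULL) {
  if (is.null(threshold)) threshold <- 0.3 * n_syn
  list(lf = lf, lp = lp, theta = 0, phi = 0, threshold = threshold,
       v_reset = 0, membrane_bounds = c(-1e6, 1e6))
}

#' Train the one-layer SCTN classifier with STDP
#'
#' One dedicated binary-activation SCTN neuron per class, each trained
#' independently and unsupervised on its own class's feature streams: the
#' per-bin SN-MFCC rates are rate-coded into per-synapse spike densities at
#' the learning clock, and the event-matrix/B-register STDP update runs
#' whenever the delayed postsynaptic spike exits the delay line. Weights
#' start from a seeded uniform draw on `[0.4, 0.6]` of the weight range.
#'
#' @param features_by_class List (one element per class) of lists of
#'   `snmfcc` matrices.
#' @param epochs Training epochs (one cycle through the class's samples).
#' @param stdp_cfg An [stdp_config()].
#' @param seed Integer seed for the weight initialisation (per-class
#'   sub-seeds are derived from it).
#' @param lf,lp,threshold Classifier-neuron leak and threshold presets;
#'   `threshold` defaults to `0.3 * n_synapses`.
#' @param tick_ms Learning-clock tick in ms (must divide the feature bin).
#' @return Object of class `sctn_classifier` with the trained weight
#'   matrix (synapses x classes) and per-epoch response counts.
#' @export
train_classifier <- function(features_by_class, epochs = 20,
                             stdp_cfg = stdp_config(), seed = 1L,
                             lf = 5L, lp = 0L, threshold = NULL,
                             tick_ms = 1) {
  if (length(features_by_class) < 1 ||
      any(vapply(features_by_class, length, 1L) == 0))
    stop("every class needs at least one training sample", call. = FALSE)
  if (epochs < 0) stop("`epochs` must be >= 0", call. = FALSE)
  nsyn <- ncol(features_by_class[[1]][[1]])
  bin_s <- attr(features_by_class[[1]][[1]], "bin_s")
  if (is.null(bin_s)) bin_s <- 0.01
  ticks_per_bin <- max(1L, as.integer(round(bin_s * 1000 / tick_ms)))
  neuron <- classifier_neuron(nsyn, lf, lp, threshold)
  wb <- stdp_cfg$weight_bounds
  nclass <- length(features_by_class)
  weights <- matrix(NA_real_, nsyn, nclass)
  history <- vector("list", nclass)
  for (c in seq_len(nclass)) {
    samples <- lapply(features_by_class[[c]], normalize_features)
    w0 <- withr::with_seed(seed + c, runif(nsyn, 0.4, 0.6) *
                             (wb[2] - wb[1]) + wb[1])
    if (epochs == 0) {
      weights[, c] <- w0
      history[[c]] <- matrix(numeric(0), 0, length(samples))
      next
    }
    res <- stdp_train_cpp(samples, w0, neuron, stdp_cfg$b_kernel,
                          stdp_cfg$lw, wb[1], wb[2], epochs,
                          ticks_per_bin, TRUE)
    weights[, c] <- res$weights
    history[[c]] <- res$epoch_spikes
  }
  structure(list(weights = weights, n_classes = nclass,
                 neuron = neuron, stdp_cfg = stdp_cfg,
                 tick_ms = tick_ms, ticks_per_bin = ticks_per_bin,
                 bin_s = bin_s, history = history, seed = seed,
                 epochs = epochs),
            class = "sctn_classifier")
}

#' @export
print.sctn_classifier <- function(x, ...) {
  cat(sprintf(
    "<sctn_classifier> %d classes x %d synapses, %d epoch(s)\n",
    x$n_classes, nrow(x$weights), x$epochs))
  invisible(x)
}

# Response rate (Hz at the learning clock) of each class neuron.
class_response_rates <- function(model, features) {
  f <- normalize_features(features)
  dur_s <- nrow(f) * model$ticks_per_bin * model$tick_ms / 1000
  vapply(seq_len(model$n_classes), function(c) {
    res <- stdp_train_cpp(list(f), model$weights[, c], model$neuron,
                          model$stdp_cfg$b_kernel, model$stdp_cfg$lw,
                          model$stdp_cfg$weight_bounds[1],
                          model$stdp_cfg$weight_bounds[2],
                          1L, model$ticks_per_bin, FALSE)
    res$epoch_spikes[1, 1] / dur_s
  }, numeric(1))
}

#' Classify an SN-MFCC feature matrix
#'
#' Plays the rate-coded features into every class neuron and picks the one
#' with the highest output spike rate. Exact ties (including the
#' all-silent degenerate case) resolve to the lowest class index with a
#' warning.
#'
#' @param model An [train_classifier()] model.
#' @param features An `snmfcc` matrix with the model's synapse count.
#' @return `list(label = class index, rates = per-class output rates in Hz)`.
#' @export
classify <- function(model, features) {
  stopifnot(inherits(model, "sctn_classifier"))
  if (ncol(features) != nrow(model$weights))
    stop("feature column count does not match the model's synapses",
         call. = FALSE)
  rates <- class_response_rates(model, features)
  top <- which(rates == max(rates))
  if (length(top) > 1)
    warning(sprintf(
      "tie between classes {%s}%s; choosing the lowest index",
      paste(top, collapse = ", "),
      if (max(rates) == 0) " (degenerate all-silent input)" else ""),
      call. = FALSE)
  list(label = top[1], rates = rates)
}

split_features_by_class <- function(features, labels, ids) {
  lab <- labels[ids]
  lapply(sort(unique(labels)), function(c) features[ids[lab == c]])
}

#' Cross-validated classification accuracy
#'
#' Mirrors the evaluation protocol: per round, a seeded random partition
#' of each class's samples into train/test halves, independent STDP
#' training of each class neuron on its own class's training features,
#' winner-take-all testing on the held-out samples, and averaging over
#' rounds.
#'
#' Accepts either a `sound_dataset` (a bank of `bank_size` mel-spaced
#' resonators is then built and features extracted first) or a
#' precomputed feature list as returned by [extract_features()].
#'
#' @param x A `sound_dataset`, or `list(features, labels)`.
#' @param bank_size Number of resonators when `x` is a dataset.
#' @param epochs Training epochs per round.
#' @param rounds Cross-validation rounds.
#' @param seed Integer seed controlling the partitions and weight draws.
#' @param n_train,n_test Per-class split sizes.
#' @param clock_hz,band_hz Bank clock and frequency span (dataset input).
#' @param lf_range,lp_range Bank design grid (dataset input).
#' @param bin_s Feature bin width (dataset input).
#' @param stdp_cfg An [stdp_config()].
#' @param ... Further arguments to [train_classifier()].
#' @return Object of class `sctn_cv`: per-round accuracies, their
#'   mean/sd, and the per-round predictions.
#' @export
cross_validate <- function(x, bank_size = 200, epochs = 20, rounds = 10,
                           seed = 1L, n_train = 20, n_test = 20,
                           clock_hz = PIPE_CLOCK_HZ,
                           band_hz = PIPE_BAND_HZ,
                           lf_range = 4:8, lp_range = 1:200,
                           bin_s = 0.01, stdp_cfg = stdp_config(), ...) {
  if (inherits(x, "sound_dataset")) {
    bank <- build_bank(bank_frequencies(bank_size, band_hz[1], band_hz[2]),
                       clock_hz, lf_range, lp_range)
    x <- extract_features(x, bank, bin_s)
  }
  features <- x$features
  labels <- x$labels
  classes <- sort(unique(labels))
  per_class <- lapply(classes, function(c) which(labels == c))
  if (any(vapply(per_class, length, 1L) < n_train + n_test))
    stop(sprintf("need >= %d samples per class", n_train + n_test),
         call. = FALSE)
  acc <- numeric(rounds)
  details <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    split <- withr::with_seed(seed * 1000 + r, lapply(per_class, function(ids) {
      ids <- sample(ids)
      list(train = ids[seq_len(n_train)],
           test = ids[n_train + seq_len(n_test)])
    }))
    train_ids <- unlist(lapply(split, `[[`, "train"))
    test_ids <- unlist(lapply(split, `[[`, "test"))
    by_class <- split_features_by_class(features, labels, train_ids)
    model <- train_classifier(by_class, epochs = epochs,
                              stdp_cfg = stdp_cfg,
                              seed = seed * 1000 + r, ...)
    pred <- vapply(test_ids, function(i)
      suppressWarnings(classify(model, features[[i]])$label), numeric(1))
    truth <- match(labels[test_ids], classes)
    acc[r] <- mean(pred == truth)
    details[[r]] <- data.frame(id = test_ids, truth = truth, pred = pred)
  }
  structure(list(accuracy = acc, mean = mean(acc), sd = sd(acc),
                 rounds = rounds, epochs = epochs, seed = seed,
                 details = details),
            class = "sctn_cv")
}

#' @export
print.sctn_cv <- function(x, ...) {
  cat(sprintf(
    "<sctn_cv> mean accuracy %.3f (sd %.3f) over %d round(s), %d epochs\n",
    x$mean, ifelse(is.na(x$sd), 0, x$sd), x$rounds, x$epochs))
  cat("  per round:", paste(sprintf("%.3f", x$accuracy), collapse = " "),
      "\n")
  invisible(x)
}
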