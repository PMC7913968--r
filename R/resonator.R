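# The SCTN resonator: analytic design math (cutoff formula, RC oracle) and
# the 17-neuron / 10-layer spiking band-pass network.
#
# Design summary. A single phase-shift stage is an SCTN leaky integrator
# whose analog cutoff is f0 = f_pulses * 2^-LF / (2*pi*LP); at f0 it shifts
# by ~-45 degrees and attenuates by ~1/sqrt(2), mirroring a first-order RC
# filter. Eight chained stages give -360 degrees at f0; the output of stage
# 4 (-180 degrees) is fed back negatively into stage 1, so the loop phase at
# f0 is 0 and the loop gain equals the feedback gain: resonance without
# self-oscillation for feedback_gain < 1. Four binary "blocker" neurons and
# four identity "rectifier" neurons sit on the taps at 90-degree spacing;
# the output neuron sums the four rectified (positive-part) phases, so its
# pulse rate tracks the oscillation envelope and peaks at f0.

#' Analog cutoff frequency of an SCTN leaky integrator
#'
#' `f0 = clock_hz * 2^-lf / (2 * pi * max(lp, 1))`: the leak retains
#' `alpha = 1 - 2^-lf` every `lp` ticks, giving a one-pole response whose
#' cutoff this evaluates. Vectorised over `lf` and `lp`.
#'
#' @param lf Leakage factor (non-negative integer).
#' @param lp Leakage period in ticks (non-negative integer; `lp <= 1`
#'   leaks every tick).
#' @param clock_hz Pulse clock in Hz.
#' @return Cutoff/resonance frequency in Hz.
#' @examples
#' cutoff_frequency(5, 73, 1.536e6) # 104.65 Hz
#' @export
cutoff_frequency <- function(lf, lp, clock_hz) {
  if (any(lf < 0) || any(lf != round(lf)) || any(lp < 0) ||
      any(lp != round(lp)) || any(clock_hz <= 0))
    stop("need lf >= 0, lp >= 0 (integers) and clock_hz > 0", call. = FALSE)
  clock_hz * 2^(-lf) / (2 * pi * pmax(lp, 1))
}

#' Radial resonance frequency (delay-line form)
#'
#' `omega0 = (1 - alpha) * f_pulses / lp`, the reciprocal of the stage delay
#' `tau = T_pulses * lp / (1 - alpha)`; identical to
#' `2 * pi * cutoff_frequency(...)` for all parameters.
#' @inheritParams cutoff_frequency
#' @return Radial frequency in rad/s.
#' @export
resonator_omega0 <- function(lf, lp, clock_hz) {
  (1 - effective_alpha(lf)) * clock_hz / pmax(lp, 1)
}

#' Tabulate resonance frequencies over an (LF, LP) grid
#'
#' @param lf_range,lp_range Integer vectors of leakage factors and periods.
#' @param clock_hz Pulse clock in Hz.
#' @return Data frame with columns `lf`, `lp`, `f0_hz`; `f0_hz` is strictly
#'   decreasing in `lp` at fixed `lf` and in `lf` at fixed `lp`.
#' @export
frequency_grid <- function(lf_range, lp_range, clock_hz) {
  if (length(lf_range) == 0 || length(lp_range) == 0)
    stop("ranges must be non-empty", call. = FALSE)
  g <- expand.grid(lp = lp_range, lf = lf_range)[, c("lf", "lp")]
  g$f0_hz <- cutoff_frequency(g$lf, g$lp, clock_hz)
  g
}

#' Invert the cutoff formula by grid search
#'
#' Returns the `(lf, lp)` pair whose resonance frequency is closest to the
#' target; ties break toward smaller `lf`, then smaller `lp`.
#'
#' @param target_hz Desired resonance frequency.
#' @param clock_hz Pulse clock in Hz.
#' @param lf_range,lp_range Search grid (non-empty integer vectors).
#' @return List with `lf`, `lp`, and `achieved_hz`.
#' @examples
#' design_for_frequency(104.65, 1.536e6, lf_range = 5, lp_range = 1:200)
#' @export
design_for_frequency <- function(target_hz, clock_hz = 1.536e6,
                                 lf_range = 1:8, lp_range = 1:200) {
  g <- frequency_grid(lf_range, lp_range, clock_hz)
  span <- range(g$f0_hz)
  if (target_hz < span[1] || target_hz > span[2])
    stop(sprintf(
      "target %.4g Hz outside the achievable span [%.4g, %.4g] Hz",
      target_hz, span[1], span[2]), call. = FALSE)
  g <- g[order(abs(g$f0_hz - target_hz), g$lf, g$lp), ]
  list(lf = g$lf[1], lp = g$lp[1], achieved_hz = g$f0_hz[1])
}

# --- analytic first-order RC oracle ------------------------------------------

#' First-order RC low-pass transfer function
#'
#' `H(jw) = 1 / (1 + j f/fc)`: magnitude `1/sqrt(2)` and phase -45 degrees
#' at the cutoff. Serves as the analytic oracle for the single-stage phase
#' shift.
#'
#' @param freq_hz Frequencies at which to evaluate (Hz).
#' @param cutoff_hz Cutoff frequency `1/(2*pi*R*C)` (Hz).
#' @return Complex vector `H(j 2 pi f)`.
#' @export
rc_transfer <- function(freq_hz, cutoff_hz) {
  if (cutoff_hz <= 0) stop("`cutoff_hz` must be positive", call. = FALSE)
  1 / (1 + 1i * freq_hz / cutoff_hz)
}

#' Apply the RC oracle filter to a waveform
#'
#' Exact frequency-domain application of [rc_transfer()] (circular; use on
#' periodic or windowed signals).
#'
#' @param wave A [waveform()].
#' @param cutoff_hz RC cutoff in Hz.
#' @return Filtered [waveform()].
#' @export
rc_filter <- function(wave, cutoff_hz) {
  stopifnot(inherits(wave, "waveform"))
  n <- length(wave$samples)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) *
    wave$rate_hz / n
  y <- Re(fft(fft(wave$samples) * rc_transfer(f, cutoff_hz),
              inverse = TRUE)) / n
  waveform(pmin(pmax(y, -1), 1), wave$rate_hz)
}

# --- resonator construction --------------------------------------------------

#' Resonator specification
#'
#' Fixes the `(lf, lp)` tuning, pulse clock, and gain presets of a
#' 17-neuron resonator. The membrane bound of the phase stages is derived
#' so that one stage has unit gain at the resonance frequency (DC gain
#' `sqrt(2)`), letting the feedback loop resonate with loop gain
#' `feedback_gain` at `f0`.
#'
#' @param lf,lp Leakage factor and period shared by the 8 phase stages.
#' @param clock_hz Pulse clock in Hz.
#' @param stage_gain Synaptic weight of each phase-stage input.
#' @param feedback_gain Magnitude of the negative feedback weight relative
#'   to `stage_gain`; must lie in `(0, 1)` for stability (loop gain at
#'   `f0` below 1).
#' @param input_gain Input weight relative to `stage_gain`; keeps the
#'   resonant swing (amplified by `1/(1 - feedback_gain)`) inside the
#'   membrane bounds for a full-scale PDM input.
#' @param tap_stages The four stages (90-degree spacing) whose outputs feed
#'   the blocker/rectifier layer.
#' @param output_threshold Firing threshold of the integrate-and-fire
#'   output neuron; defaults to `clock_hz / 4800`, scaling the output rate
#'   with the clock.
#' @return Object of class `resonator_spec` with the derived `f0_hz`.
#' @export
resonator_spec <- function(lf, lp, clock_hz = 1.536e6, stage_gain = 1,
                           feedback_gain = 0.9, input_gain = 0.1,
                           tap_stages = c(2L, 4L, 6L, 8L),
                           output_threshold = NULL) {
  if (feedback_gain <= 0 || feedback_gain >= 1)
    stop("`feedback_gain` must lie in (0, 1): loop gain at f0 must stay ",
         "below 1", call. = FALSE)
  if (input_gain <= 0) stop("`input_gain` must be positive", call. = FALSE)
  if (lf < 1)
    stop("phase stages need lf >= 1 (lf = 0 clears the membrane on every ",
         "leak tick and cannot integrate)", call. = FALSE)
  if (length(tap_stages) != 4 || any(!tap_stages %in% 1:8))
    stop("`tap_stages` must name four of the eight phase stages",
         call. = FALSE)
  f0 <- cutoff_frequency(lf, lp, clock_hz)
  alpha <- effective_alpha(lf)
  lp_eff <- max(lp, 1)
  # membrane swing per unit bipolar amplitude at DC, then scaled so the
  # stage gain is 1 at f0 (a one-pole stage attenuates by sqrt(2) there)
  v_bound <- (stage_gain / 2) * alpha * lp_eff / (1 - alpha) / sqrt(2)
  if (is.null(output_threshold))
    output_threshold <- max(2, round(clock_hz / 4800))
  structure(list(
    lf = as.integer(lf), lp = as.integer(lp), clock_hz = clock_hz,
    f0_hz = f0, stage_gain = stage_gain, feedback_gain = feedback_gain,
    input_gain = input_gain, tap_stages = as.integer(sort(tap_stages)),
    v_bound = v_bound, output_threshold = output_threshold,
    blocker_threshold = 0.05 * v_bound, lf_out = 24L),
    class = "resonator_spec")
}

#' @export
print.resonator_spec <- function(x, ...) {
  cat(sprintf(
    "<resonator_spec> LF=%d LP=%d @ %g Hz clock -> f0 = %.4g Hz\n",
    x$lf, x$lp, x$clock_hz, x$f0_hz))
  invisible(x)
}

# Parameter list consumed by the specialized C++ kernel.
reso_params <- function(spec) {
  list(lf = spec$lf, lp = spec$lp,
       stage_gain = spec$stage_gain,
       w_in = spec$input_gain * spec$stage_gain,
       w_fb = -spec$feedback_gain * spec$stage_gain,
       v_bound = spec$v_bound,
       blocker_threshold = spec$blocker_threshold,
       output_threshold = spec$output_threshold,
       alpha_out = effective_alpha(spec$lf_out),
       tap_stages = spec$tap_stages)
}

#' Build the 17-neuron, 10-layer resonator network
#'
#' Layers 1-8 hold one identity-activation phase-shift neuron each (stage 1
#' also receives the negative feedback edge from stage 4, read with a
#' one-tick delay); layer 9 holds four binary blockers thresholded at the
#' bipolar midpoint and four identity rectifiers (membrane bounded below at
#' zero, so only the positive part is re-encoded), all fed by the tap
#' stages; layer 10 is the integrate-and-fire output neuron summing the
#' four rectified phases (0, 90, 180, 270 degrees).
#'
#' @param spec A [resonator_spec()].
#' @return Object of class `sctn_resonator`: the spec plus the 17
#'   [sctn_neuron()] records with their wiring (`src` < 0 denotes the
#'   external PDM input; `delayed` marks feedback edges).
#' @export
build_resonator <- function(spec) {
  stopifnot(inherits(spec, "resonator_spec"))
  w <- spec$stage_gain
  V <- spec$v_bound
  w_in <- spec$input_gain * w
  w_fb <- -spec$feedback_gain * w
  nodes <- vector("list", 17)
  # phase chain
  nodes[[1]] <- list(
    neuron = sctn_neuron(c(w_in, w_fb), lf = spec$lf, lp = spec$lp,
                         phi = -(w_in + w_fb) / 2, activation = "identity",
                         membrane_bounds = c(-V, V), threshold = V),
    src = c(-1L, 4L), delayed = c(FALSE, TRUE), role = "phase", layer = 1L)
  for (i in 2:8) {
    nodes[[i]] <- list(
      neuron = sctn_neuron(w, lf = spec$lf, lp = spec$lp, phi = -w / 2,
                           activation = "identity",
                           membrane_bounds = c(-V, V), threshold = V),
      src = i - 1L, delayed = FALSE, role = "phase", layer = i)
  }
  for (k in 1:4) {
    nodes[[8 + k]] <- list(
      neuron = sctn_neuron(w, lf = spec$lf, lp = spec$lp, phi = -w / 2,
                           activation = "binary",
                           membrane_bounds = c(-V, V),
                           threshold = spec$blocker_threshold),
      src = spec$tap_stages[k], delayed = FALSE, role = "blocker",
      layer = 9L)
    nodes[[12 + k]] <- list(
      neuron = sctn_neuron(w, lf = spec$lf, lp = spec$lp, phi = -w / 2,
                           activation = "identity",
                           membrane_bounds = c(0, V), threshold = V,
                           v_reset = 1e-9),
      src = spec$tap_stages[k], delayed = FALSE, role = "rectifier",
      layer = 9L)
  }
  nodes[[17]] <- list(
    neuron = sctn_neuron(rep(1, 4), lf = spec$lf_out, lp = 0L,
                         activation = "binary",
                         membrane_bounds = c(-1e12, 1e12),
                         threshold = spec$output_threshold),
    src = 13:16, delayed = rep(FALSE, 4), role = "output", layer = 10L)
  structure(list(spec = spec, nodes = nodes), class = "sctn_resonator")
}

#' @export
print.sctn_resonator <- function(x, ...) {
  cat(sprintf(
    "<sctn_resonator> f0 = %.4g Hz (LF=%d LP=%d @ %g Hz), %d neurons / %d layers\n",
    x$spec$f0_hz, x$spec$lf, x$spec$lp, x$spec$clock_hz,
    length(x$nodes), max(vapply(x$nodes, `[[`, 1L, "layer"))))
  invisible(x)
}

network_engine_list <- function(network) {
  lapply(network$nodes, function(nd)
    as_engine_neuron(nd$neuron, nd$src, nd$delayed))
}

#' Simulate a resonator on a PDM spike train
#'
#' @param network An [sctn_resonator()] from [build_resonator()].
#' @param input A bipolar [spike_train()] at the spec's clock.
#' @param bin_s Optional bin width in seconds: when given, per-bin output
#'   spike rates are returned instead of the full output train.
#' @param return_taps Also return the 8 phase-stage output trains.
#' @param engine `"fast"` uses the specialized resonator kernel;
#'   `"generic"` runs the same topology through the generic network engine
#'   (the two are bit-identical).
#' @param seed Seed for the engine's generator (unused by the default
#'   activation modes; kept for reproducibility of stochastic variants).
#' @return List with `output` (a [spike_train()], or `NULL` when binned),
#'   `rates` (data frame `time_s`, `rate_hz`, or `NULL`), and `taps`.
#' @export
simulate_resonator <- function(network, input, bin_s = NULL,
                               return_taps = FALSE,
                               engine = c("fast", "generic"), seed = 1L) {
  stopifnot(inherits(network, "sctn_resonator"),
            inherits(input, "spike_train"))
  engine <- match.arg(engine)
  spec <- network$spec
  if (!isTRUE(all.equal(input$clock_hz, spec$clock_hz)))
    stop("input clock does not match the resonator clock", call. = FALSE)
  bin_ticks <- if (is.null(bin_s)) 0L else
    max(1L, as.integer(round(bin_s * spec$clock_hz)))
  return_bits <- is.null(bin_s)
  if (engine == "fast") {
    res <- resonator_sim_cpp(input$bits, reso_params(spec), bin_ticks,
                             return_bits, return_taps)
    out_bits <- res$bits
    counts <- res$counts
    taps <- res$taps
  } else {
    rec <- c(17L, if (return_taps) 1:8)
    res <- run_network_cpp(network_engine_list(network),
                           matrix(input$bits, ncol = 1), rec,
                           as.numeric(seed), bin_ticks, return_bits)
    out_bits <- if (return_bits) res$bits[, 1] else NULL
    counts <- if (!is.null(res$counts)) res$counts[, 1] else NULL
    taps <- if (return_taps && return_bits) res$bits[, -1, drop = FALSE]
  }
  rates <- NULL
  if (!is.null(bin_s)) {
    nb <- length(counts)
    rates <- data.frame(
      time_s = ((seq_len(nb) - 0.5) * bin_ticks) / spec$clock_hz,
      rate_hz = as.numeric(counts) / (bin_ticks / spec$clock_hz))
  }
  list(output = if (return_bits)
         spike_train(out_bits, spec$clock_hz, "unipolar"),
       rates = rates,
       taps = if (return_taps && !is.null(taps))
         apply(taps, 2, function(b) spike_train(b, spec$clock_hz),
               simplify = FALSE))
}

#' Steady-state output rate across probe tones
#'
#' Plays a pure tone at each probe frequency into the resonator and counts
#' output spikes after a settling interval.
#'
#' @param network An [sctn_resonator()].
#' @param probe_hz Probe frequencies (positive, below clock/2).
#' @param duration_s Tone duration per probe; defaults to
#'   `settle_s + max(0.2, 20 / f0)`.
#' @param settle_s Discarded settling interval; defaults to `10 / f0`.
#' @param amplitude Tone amplitude.
#' @return Data frame with `freq_hz` and steady-state `rate_hz`.
#' @export
frequency_response <- function(network, probe_hz, duration_s = NULL,
                               settle_s = NULL, amplitude = 1) {
  stopifnot(inherits(network, "sctn_resonator"))
  if (length(probe_hz) == 0)
    return(data.frame(freq_hz = numeric(), rate_hz = numeric()))
  spec <- network$spec
  if (any(probe_hz <= 0) || any(probe_hz >= spec$clock_hz / 2))
    stop("probes must lie in (0, clock/2)", call. = FALSE)
  if (is.null(settle_s)) settle_s <- 10 / spec$f0_hz
  if (is.null(duration_s)) duration_s <- settle_s + max(0.2, 20 / spec$f0_hz)
  rate_hz <- vapply(probe_hz, function(f) {
    wav_rate <- min(spec$clock_hz / 8, max(8 * f, 4000))
    tone <- sine_wave(f, duration_s, wav_rate, amplitude = amplitude)
    tr <- pdm_encode(tone, spec$clock_hz)
    sim <- simulate_resonator(network, tr, bin_s = duration_s - settle_s)
    utils::tail(sim$rates$rate_hz, 1)
  }, numeric(1))
  data.frame(freq_hz = probe_hz, rate_hz = rate_hz)
}

#' Resonator response along a linear chirp
#'
#' Plays a linear chirp through the resonator and bins its output spikes
#' against the chirp's instantaneous frequency; the rate peaks at the
#' resonance frequency.
#'
#' @param network An [sctn_resonator()].
#' @param f_start,f_end Chirp endpoints in Hz.
#' @param duration_s Sweep duration (slower sweeps resolve the peak more
#'   sharply against the resonator's settling time).
#' @param bin_hz Frequency bin width in Hz.
#' @return Data frame with bin centres `freq_hz` and output `rate_hz`.
#' @export
chirp_response <- function(network, f_start, f_end, duration_s = 20,
                           bin_hz = 5) {
  stopifnot(inherits(network, "sctn_resonator"))
  spec <- network$spec
  wav_rate <- min(spec$clock_hz / 8, max(8 * max(f_start, f_end), 4000))
  ch <- chirp_wave(f_start, f_end, duration_s, wav_rate)
  tr <- pdm_encode(ch, spec$clock_hz)
  bin_s <- bin_hz * duration_s / abs(f_end - f_start)
  sim <- simulate_resonator(network, tr, bin_s = bin_s)
  data.frame(freq_hz = f_start + (f_end - f_start) *
               sim$rates$time_s / duration_s,
             rate_hz = sim$rates$rate_hz)
}

#' The 20 audio-band detection frequencies used for the demo filter bank
#' @return Integer vector of 20 centre frequencies in Hz (155 to 18750).
#' @export
bank20_frequencies <- function() {
  c(155, 304, 480, 703, 937, 1242, 1593, 2015, 2484, 3000, 3750, 4500,
    5437, 6562, 7875, 9375, 11062, 13125, 15750, 18750)
}

#' Build a bank of resonators tuned to a frequency list
#'
#' Designs `(lf, lp)` for each target by [design_for_frequency()] and
#' builds one 17-neuron resonator per target.
#'
#' @param target_hz Vector of target centre frequencies.
#' @param clock_hz Pulse clock shared by the bank.
#' @param lf_range,lp_range Design grid.
#' @param ... Gain presets forwarded to [resonator_spec()].
#' @return Object of class `sctn_bank`: list of [sctn_resonator()]s with an
#'   `achieved_hz` attribute.
#' @export
build_bank <- function(target_hz, clock_hz = 1.536e6, lf_range = 1:8,
                       lp_range = 1:200, ...) {
  if (length(target_hz) == 0) stop("empty target list", call. = FALSE)
  nets <- lapply(target_hz, function(f) {
    d <- tryCatch(
      design_for_frequency(f, clock_hz, lf_range, lp_range),
      error = function(e) stop(sprintf(
        "target %.4g Hz is unachievable: %s", f, conditionMessage(e)),
        call. = FALSE))
    build_resonator(resonator_spec(d$lf, d$lp, clock_hz, ...))
  })
  structure(nets, class = "sctn_bank",
            achieved_hz = vapply(nets, function(n) n$spec$f0_hz, numeric(1)),
            target_hz = as.numeric(target_hz))
}

#' @export
print.sctn_bank <- function(x, ...) {
  cat(sprintf(
    "<sctn_bank> %d resonators (%d neurons), %.4g - %.4g Hz @ %g Hz clock\n",
    length(x), 17 * length(x), min(attr(x, "achieved_hz")),
    max(attr(x, "achieved_hz")), x[[1]]$spec$clock_hz))
  invisible(x)
}
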