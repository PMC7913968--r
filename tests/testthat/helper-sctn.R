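# Shared fixtures: all signals are generated in code at test time.

# A fast-clock resonator (f0 ~ 53 Hz at 96 kHz) keeps simulations short.
test_reso_spec <- function(lf = 5, lp = 9, clock_hz = 96000, ...) {
  resonator_spec(lf, lp, clock_hz, ...)
}

encode_tone <- function(freq_hz, duration_s, clock_hz, amplitude = 0.8,
                        rate_hz = 16000) {
  pdm_encode(sine_wave(freq_hz, duration_s, rate_hz, amplitude), clock_hz)
}

# Steady-state output rate of a network for a tone (settling discarded).
tone_rate <- function(network, freq_hz, duration_s = 0.6, settle_s = 0.2,
                      amplitude = 0.8) {
  tr <- encode_tone(freq_hz, duration_s, network$spec$clock_hz, amplitude)
  sim <- simulate_resonator(network, tr, bin_s = duration_s - settle_s)
  utils::tail(sim$rates$rate_hz, 1)
}

# Brute-force pair-sum oracle for STDP (times in learning ticks, tick_ms
# applied explicitly), independent of stdp_delta's vectorised path.
pair_sum_oracle <- function(t_pre, t_post, cfg) {
  total <- 0
  for (tp in t_pre) for (to in t_post) {
    dt <- (to - tp) * cfg$tick_ms
    causal <- if (cfg$causality == "pre_before_post") dt >= 0 else dt <= 0
    total <- total + if (causal) cfg$eta_plus * exp(-abs(dt) / cfg$tau_plus)
    else -cfg$eta_minus * exp(-abs(dt) / cfg$tau_minus)
  }
  total
}

# A tiny dataset + matching low-count bank for pipeline tests.
tiny_dataset <- function(n_classes = 4, n_per_class = 6, seed = 3) {
  make_synthetic_dataset(n_classes = n_classes, n_per_class = n_per_class,
                         seed = seed, duration_range = c(0.4, 0.5))
}

tiny_bank <- function(n = 24) {
  build_bank(bank_frequencies(n, 30, 250), 96000, 4:8, 1:200)
}
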