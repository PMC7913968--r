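# STDP in two interchangeable forms: the analytic pair-based rule and the
# hardware-style event-matrix / B-register realisation. For spike trains
# whose pre/post lags all fall inside the +/-Lw window the two are exactly
# equivalent (see run_stdp() and the test suite).

#' STDP configuration
#'
#' Defaults follow the sound-classification setup: learning rates
#' `eta_plus = 0.005`, `eta_minus = 0.004`, time constants
#' `tau_plus = tau_minus = 15` ms, and a half-window of `lw = 16` learning
#' ticks. By the standard causal convention a presynaptic spike preceding
#' the postsynaptic spike potentiates; `causality` flips it.
#'
#' @param eta_plus,eta_minus Non-negative potentiation/depression rates
#'   (weight units).
#' @param tau_plus,tau_minus Positive time constants in ms.
#' @param lw Half-window length in learning ticks (`>= 1`).
#' @param tick_ms Milliseconds per learning tick (sets the kernel sampling).
#' @param b_kernel Optional custom B register: `2*lw + 1` signed weights
#'   indexed by lag `u = -lw:lw`; defaults to [exponential_b_kernel()].
#' @param weight_bounds Clamp range for the weights.
#' @param causality `"pre_before_post"` (default) or `"post_before_pre"`:
#'   which sign of `dt = t_post - t_pre` potentiates.
#' @return Object of class `stdp_config` (with the realised `b_kernel`).
#' @export
stdp_config <- function(eta_plus = 0.005, eta_minus = 0.004,
                        tau_plus = 15, tau_minus = 15, lw = 16L,
                        tick_ms = 1, b_kernel = NULL,
                        weight_bounds = c(0, 1),
                        causality = c("pre_before_post",
                                      "post_before_pre")) {
  causality <- match.arg(causality)
  if (eta_plus < 0 || eta_minus < 0)
    stop("learning rates must be non-negative", call. = FALSE)
  if (tau_plus <= 0 || tau_minus <= 0)
    stop("time constants must be positive", call. = FALSE)
  if (lw < 1 || lw != round(lw)) stop("`lw` must be an integer >= 1",
                                      call. = FALSE)
  if (tick_ms <= 0) stop("`tick_ms` must be positive", call. = FALSE)
  if (length(weight_bounds) != 2 || weight_bounds[1] >= weight_bounds[2])
    stop("`weight_bounds` must be c(w_min, w_max)", call. = FALSE)
  cfg <- structure(list(
    eta_plus = eta_plus, eta_minus = eta_minus, tau_plus = tau_plus,
    tau_minus = tau_minus, lw = as.integer(lw), tick_ms = tick_ms,
    b_kernel = NULL, weight_bounds = as.numeric(weight_bounds),
    causality = causality), class = "stdp_config")
  if (is.null(b_kernel)) {
    cfg$b_kernel <- exponential_b_kernel(cfg, tick_ms)
  } else {
    if (length(b_kernel) != 2 * lw + 1)
      stop("`b_kernel` must have 2*lw + 1 entries", call. = FALSE)
    cfg$b_kernel <- as.numeric(b_kernel)
  }
  cfg
}

#' @export
print.stdp_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<stdp_config> eta+=%g eta-=%g tau+=%g ms tau-=%g ms Lw=%d ",
    "(tick %g ms), %s potentiates\n"),
    x$eta_plus, x$eta_minus, x$tau_plus, x$tau_minus, x$lw, x$tick_ms,
    x$causality))
  invisible(x)
}

#' Analytic pair-based STDP weight change
#'
#' Sums the exponential pair rule over all pre/post spike pairs: a causal
#' pair contributes `+eta_plus * exp(-|dt|/tau_plus)`, an anti-causal pair
#' `-eta_minus * exp(-|dt|/tau_minus)`, with `dt = t_post - t_pre` and
#' causality per the configuration. Times share the unit of the taus (ms).
#'
#' @param t_pre,t_post Spike time sets (numeric vectors, ms).
#' @param cfg An [stdp_config()].
#' @return Total weight change over all pairs.
#' @examples
#' cfg <- stdp_config()
#' stdp_delta(0, 0, cfg)           # +eta_plus
#' stdp_delta(0, 15, cfg)          # +eta_plus * exp(-1)
#' @export
stdp_delta <- function(t_pre, t_post, cfg) {
  stopifnot(inherits(cfg, "stdp_config"))
  if (length(t_pre) == 0 || length(t_post) == 0) return(0)
  if (any(!is.finite(t_pre)) || any(!is.finite(t_post)))
    stop("spike times must be finite", call. = FALSE)
  dt <- outer(t_post, t_pre, "-") # t_post - t_pre
  causal <- if (cfg$causality == "pre_before_post") dt >= 0 else dt <= 0
  sum(ifelse(causal,
             cfg$eta_plus * exp(-abs(dt) / cfg$tau_plus),
             -cfg$eta_minus * exp(-abs(dt) / cfg$tau_minus)))
}

#' Exponential B register sampled from the pair rule
#'
#' Samples the analytic kernel at integer lags `u = -lw:lw` learning ticks;
#' the causal side carries `+eta_plus` amplitudes, the anti-causal side
#' `-eta_minus`. Entry `u` applies to a pre spike `u` ticks before the
#' (delayed) postsynaptic spike.
#'
#' @param cfg An [stdp_config()].
#' @param tick_ms Milliseconds per learning tick.
#' @return Numeric vector of length `2*lw + 1`, lag order `-lw:lw`.
#' @export
exponential_b_kernel <- function(cfg, tick_ms = cfg$tick_ms) {
  stopifnot(inherits(cfg, "stdp_config"))
  if (tick_ms <= 0) stop("`tick_ms` must be positive", call. = FALSE)
  u <- -cfg$lw:cfg$lw
  causal <- if (cfg$causality == "pre_before_post") u >= 0 else u <= 0
  ifelse(causal,
         cfg$eta_plus * exp(-abs(u) * tick_ms / cfg$tau_plus),
         -cfg$eta_minus * exp(-abs(u) * tick_ms / cfg$tau_minus))
}

#' Per-synapse spike-history registers (time event matrix)
#'
#' One shift register per input synapse holding the last `2*lw + 1` learning
#' ticks of presynaptic activity (so every lag in `[-lw, lw]` relative to
#' the delayed postsynaptic spike is visible), plus the postsynaptic delay
#' line of length `lw`.
#'
#' @param n_syn Number of input synapses.
#' @param lw Half-window length in learning ticks.
#' @return Object of class `event_matrix`.
#' @export
event_matrix <- function(n_syn, lw) {
  stopifnot(n_syn >= 1, lw >= 1)
  structure(list(
    registers = matrix(0L, nrow = n_syn, ncol = 2L * lw + 1L),
    post_delay = integer(lw + 1L),
    lw = as.integer(lw), n_syn = as.integer(n_syn),
    post_exit = 0L), class = "event_matrix")
}

#' Shift one learning tick into the event matrix
#'
#' Every register and the delay line shift by one position; the new bits
#' enter at offset 0 (register column 1). `$post_exit` is set to the
#' postsynaptic bit leaving the delay line (the spike from `lw` ticks ago),
#' which is the trigger for [apply_post_spike_update()].
#'
#' @param matrix_ An [event_matrix()].
#' @param pre_bits Binary vector, one per synapse.
#' @param post_bit Postsynaptic output bit for this tick.
#' @return The shifted matrix.
#' @export
record_tick <- function(matrix_, pre_bits, post_bit) {
  stopifnot(inherits(matrix_, "event_matrix"))
  if (length(pre_bits) != matrix_$n_syn)
    stop("`pre_bits` width does not match the matrix", call. = FALSE)
  nc <- ncol(matrix_$registers)
  matrix_$registers <- cbind(as.integer(pre_bits),
                             matrix_$registers[, -nc, drop = FALSE])
  lw <- matrix_$lw
  matrix_$post_delay <- c(as.integer(post_bit),
                          matrix_$post_delay[seq_len(lw)])
  matrix_$post_exit <- matrix_$post_delay[lw + 1L]
  matrix_
}

#' Windowed B-register weight update on a delayed postsynaptic spike
#'
#' For each synapse the weight change is the convolution of its shift
#' register with the B kernel: a pre spike recorded `o` ticks ago pairs
#' with the exiting post spike (from `lw` ticks ago) at lag
#' `u = o - lw`, so `dw_j = sum_o register_j[o] * B[o - lw]`. Synapses with
#' no spikes in the window are unchanged; results are clamped to the
#' configured weight bounds.
#'
#' @param matrix_ An [event_matrix()] (call when `$post_exit == 1`).
#' @param weights Current weight vector.
#' @param cfg An [stdp_config()].
#' @return The updated weight vector.
#' @export
apply_post_spike_update <- function(matrix_, weights, cfg) {
  stopifnot(inherits(matrix_, "event_matrix"), inherits(cfg, "stdp_config"))
  if (length(weights) != matrix_$n_syn)
    stop("weight vector width does not match the matrix", call. = FALSE)
  # column o+1 holds the pre bit from o ticks ago; its lag against the
  # exiting post spike is u = o - lw, which is entry o+1 of the
  # ascending-lag kernel (u = -lw at column 1: the newest pre bit sits lw
  # ticks after the delayed post spike, hence maximally anti-causal).
  dw <- as.numeric(matrix_$registers %*% cfg$b_kernel)
  pmin(pmax(weights + dw, cfg$weight_bounds[1]), cfg$weight_bounds[2])
}

#' Drive the event-matrix mechanism over whole spike trains
#'
#' Reference driver for the hardware-style update: shifts every learning
#' tick and applies the B-register convolution whenever a delayed
#' postsynaptic spike exits the delay line. Equals the windowed analytic
#' pair sum when all pair lags fall within `[-lw, lw]`.
#'
#' @param pre_bits Matrix of presynaptic bits, ticks x synapses.
#' @param post_bits Postsynaptic bit vector (same tick count).
#' @param weights Initial weights, one per synapse.
#' @param cfg An [stdp_config()].
#' @return `list(weights, n_updates)`.
#' @export
run_stdp <- function(pre_bits, post_bits, weights, cfg) {
  pre_bits <- as.matrix(pre_bits)
  if (nrow(pre_bits) != length(post_bits))
    stop("pre/post tick counts differ", call. = FALSE)
  m <- event_matrix(ncol(pre_bits), cfg$lw)
  n_up <- 0L
  # run lw extra ticks so trailing post spikes clear the delay line
  for (t in seq_len(nrow(pre_bits) + cfg$lw)) {
    pre <- if (t <= nrow(pre_bits)) pre_bits[t, ] else integer(ncol(pre_bits))
    post <- if (t <= length(post_bits)) post_bits[t] else 0L
    m <- record_tick(m, pre, post)
    if (m$post_exit == 1L) {
      weights <- apply_post_spike_update(m, weights, cfg)
      n_up <- n_up + 1L
    }
  }
  list(weights = weights, n_updates = n_up)
}
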