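# SCTN neuron: configuration, single-tick dynamics, and full-train simulation.
#
# The membrane update is
#   Vm(t) = Vm(t-1) + sum_j w_j I_j + phi + Theta          (ordinary tick)
#   Vm(t) = alpha * (Vm(t-1) + sum_j w_j I_j + phi) + Theta (leak tick)
# with alpha = 1 - 2^-LF and the leak applied every LP ticks (t mod LP == 0,
# ticks counted from 1; LP <= 1 leaks every tick). This schedule makes the
# neuron's analog cutoff f0 = f_pulses * 2^-LF / (2*pi*LP), the convention
# used throughout the resonator design math.

ACTIVATIONS <- c(binary = 0L, identity = 1L, stochastic_sigmoid = 2L)

#' Leak coefficient from the leakage factor
#'
#' The SCTN leaky integrator retains a fraction \eqn{\alpha = 1 - 2^{-LF}} of
#' its membrane on each leak tick; LF is a non-negative integer so the
#' multiply reduces to a shift-subtract in hardware.
#'
#' @param lf Non-negative integer leakage factor.
#' @return The retention coefficient in `[0, 1)`.
#' @examples
#' effective_alpha(5) # 0.96875
#' @export
effective_alpha <- function(lf) {
  if (any(!is.finite(lf)) || any(lf < 0) || any(lf != round(lf))) {
    stop("`lf` must be a non-negative integer", call. = FALSE)
  }
  1 - 2^(-lf)
}

#' SCTN neuron configuration
#'
#' Bundles every per-neuron parameter: synaptic weights, the (LF, LP) leak
#' schedule, pre-/post-leak biases, firing threshold and reset, activation
#' mode, and saturation bounds for the membrane register.
#'
#' @param weights Numeric vector of synaptic weights (one per input synapse).
#' @param lf Leakage factor (non-negative integer); retention
#'   `alpha = 1 - 2^-lf` on leak ticks.
#' @param lp Leakage period: the leak is applied every `lp` ticks
#'   (`lp <= 1` leaks on every tick).
#' @param theta Post-leak bias added every tick (membrane units).
#' @param phi Pre-leak bias accumulated with the weighted inputs.
#' @param threshold Firing threshold (binary and stochastic modes).
#' @param v_reset Membrane value after a spike.
#' @param activation One of `"binary"`, `"identity"`,
#'   `"stochastic_sigmoid"`. Identity neurons re-encode the (bounded)
#'   membrane as a sigma-delta spike train and never reset; the stochastic
#'   mode compares the membrane against a fresh uniform draw over the
#'   membrane bounds.
#' @param membrane_bounds Saturation limits `c(v_min, v_max)` of the
#'   membrane register (finite; the identity and stochastic modes use them
#'   to normalise the membrane).
#' @param legacy_mu Optional constant leak: when non-`NULL` the neuron runs
#'   the plain LIF recursion `Vm <- Vm + sum(w*I) - mu` with no scheduled
#'   leak or biases.
#' @param vm0 Initial membrane potential.
#' @return An object of class `sctn_neuron`.
#' @examples
#' n <- sctn_neuron(weights = c(2, -3), lf = 2, lp = 1, phi = 1, theta = 2,
#'                  threshold = 100)
#' @export
sctn_neuron <- function(weights, lf = 0L, lp = 0L, theta = 0, phi = 0,
                        threshold = 1, v_reset = 0,
                        activation = c("binary", "identity",
                                       "stochastic_sigmoid"),
                        membrane_bounds = c(-1e9, 1e9),
                        legacy_mu = NULL, vm0 = 0) {
  activation <- match.arg(activation)
  if (!is.numeric(weights) || length(weights) < 1 || any(!is.finite(weights)))
    stop("`weights` must be finite numeric, one per synapse", call. = FALSE)
  if (length(lf) != 1 || !is.finite(lf) || lf < 0 || lf != round(lf))
    stop("`lf` must be a non-negative integer", call. = FALSE)
  if (length(lp) != 1 || !is.finite(lp) || lp < 0 || lp != round(lp))
    stop("`lp` must be a non-negative integer", call. = FALSE)
  for (nm in c("theta", "phi", "threshold", "v_reset", "vm0")) {
    v <- get(nm)
    if (length(v) != 1 || !is.finite(v))
      stop(sprintf("`%s` must be a finite scalar", nm), call. = FALSE)
  }
  if (length(membrane_bounds) != 2 || any(!is.finite(membrane_bounds)) ||
      membrane_bounds[1] >= membrane_bounds[2])
    stop("`membrane_bounds` must be finite c(v_min, v_max), v_min < v_max",
         call. = FALSE)
  if (membrane_bounds[1] >= v_reset || v_reset > threshold ||
      threshold > membrane_bounds[2])
    stop("require v_min < v_reset <= threshold <= v_max", call. = FALSE)
  if (!is.null(legacy_mu) && (length(legacy_mu) != 1 || !is.finite(legacy_mu)))
    stop("`legacy_mu` must be NULL or a finite scalar", call. = FALSE)
  structure(list(
    weights = as.numeric(weights), lf = as.integer(lf), lp = as.integer(lp),
    theta = theta, phi = phi, threshold = threshold, v_reset = v_reset,
    activation = activation, membrane_bounds = as.numeric(membrane_bounds),
    legacy_mu = legacy_mu, vm0 = vm0), class = "sctn_neuron")
}

#' @export
print.sctn_neuron <- function(x, ...) {
  cat(sprintf(
    "<sctn_neuron> %d synapse(s), LF=%d LP=%d (alpha=%.6g), %s activation\n",
    length(x$weights), x$lf, x$lp, effective_alpha(x$lf), x$activation))
  cat(sprintf("  threshold=%g v_reset=%g theta=%g phi=%g bounds=[%g, %g]\n",
              x$threshold, x$v_reset, x$theta, x$phi,
              x$membrane_bounds[1], x$membrane_bounds[2]))
  invisible(x)
}

#' Fresh simulation state for a neuron
#'
#' @param neuron An [sctn_neuron()].
#' @return List with the membrane potential `vm`, the tick counter, and the
#'   sigma-delta accumulator used by the identity activation.
#' @export
neuron_state <- function(neuron) {
  stopifnot(inherits(neuron, "sctn_neuron"))
  list(vm = neuron$vm0, tick = 0L, sigma_delta_acc = 0)
}

is_leak_tick <- function(t, lp) t %% max(lp, 1L) == 0L

#' Advance the membrane by one tick
#'
#' Applies the weighted-input accumulation, the scheduled leak, and the bias
#' terms for tick `t`, then saturates the membrane to the configured bounds.
#'
#' @param state State list from [neuron_state()].
#' @param neuron An [sctn_neuron()].
#' @param inputs Binary vector, one bit per synapse.
#' @param t Tick index (1-based); a leak tick is `t %% lp == 0`.
#' @return The updated state; `state$tick` is set to `t`.
#' @examples
#' n <- sctn_neuron(c(2, -3), lf = 2, lp = 1, phi = 1, theta = 2,
#'                  threshold = 100)
#' s <- neuron_state(n); s$vm <- 10
#' membrane_step(s, n, c(1, 1), t = 1)$vm # 0.75*(10+2-3+1)+2 = 9.5
#' @export
membrane_step <- function(state, neuron, inputs, t = state$tick + 1L) {
  if (length(inputs) != length(neuron$weights))
    stop("input length does not match the number of synapses", call. = FALSE)
  if (any(is.na(inputs)) || !all(inputs %in% c(0, 1)))
    stop("`inputs` must be binary", call. = FALSE)
  usum <- sum(neuron$weights * inputs)
  if (!is.null(neuron$legacy_mu)) {
    vm <- state$vm + usum - neuron$legacy_mu
  } else if (is_leak_tick(t, neuron$lp)) {
    vm <- effective_alpha(neuron$lf) * (state$vm + usum + neuron$phi) +
      neuron$theta
  } else {
    vm <- state$vm + usum + neuron$phi + neuron$theta
  }
  state$vm <- min(max(vm, neuron$membrane_bounds[1]), neuron$membrane_bounds[2])
  state$tick <- as.integer(t)
  state
}

#' Threshold/activation stage: emit a spike bit
#'
#' Binary mode spikes when `vm >= threshold` and resets the membrane.
#' Stochastic mode compares `vm` with a fresh uniform draw over the membrane
#' bounds (uses R's RNG; seed with [set.seed()]), resetting only on a spike.
#' Identity mode sigma-delta re-encodes the membrane normalised to the
#' bounds and never resets.
#'
#' @param state State list (after [membrane_step()] for this tick).
#' @param neuron An [sctn_neuron()].
#' @return `list(spike = 0 or 1, state = updated state)`.
#' @export
fire <- function(state, neuron) {
  b <- neuron$membrane_bounds
  spike <- 0L
  if (neuron$activation == "binary") {
    if (state$vm >= neuron$threshold) {
      spike <- 1L
      state$vm <- neuron$v_reset
    }
  } else if (neuron$activation == "stochastic_sigmoid") {
    draw <- runif(1, b[1], b[2])
    if (state$vm >= draw) {
      spike <- 1L
      state$vm <- neuron$v_reset
    }
  } else if (neuron$activation == "identity") {
    tgt <- min(max((state$vm - b[1]) / (b[2] - b[1]), 0), 1)
    state$sigma_delta_acc <- state$sigma_delta_acc + tgt
    if (state$sigma_delta_acc >= 1) {
      spike <- 1L
      state$sigma_delta_acc <- state$sigma_delta_acc - 1
    }
  } else {
    stop("unknown activation mode: ", neuron$activation, call. = FALSE)
  }
  list(spike = spike, state = state)
}

# Engine-format list consumed by the C++ kernels.
as_engine_neuron <- function(neuron, src, delayed) {
  list(lf = neuron$lf, lp = neuron$lp, theta = neuron$theta, phi = neuron$phi,
       threshold = neuron$threshold, v_reset = neuron$v_reset,
       membrane_bounds = neuron$membrane_bounds,
       activation_code = ACTIVATIONS[[neuron$activation]],
       legacy_mu = neuron$legacy_mu, vm0 = neuron$vm0,
       src = as.integer(src), w = neuron$weights,
       delayed = as.logical(delayed))
}

#' Run a neuron over full input spike trains
#'
#' Drives [membrane_step()] and the activation stage over every tick of the
#' input trains (compiled loop). Deterministic given the configuration, the
#' inputs, and `seed` (which feeds the stochastic activation's generator).
#'
#' @param neuron An [sctn_neuron()].
#' @param inputs A [spike_train()] or a list of them, one per synapse; all
#'   trains must share clock and length.
#' @param seed Integer seed for the stochastic activation mode.
#' @param trace If `TRUE`, also return the per-tick membrane trace.
#' @return A [spike_train()] at the input clock (with attribute
#'   `"vm_trace"` when `trace = TRUE`).
#' @export
run_neuron <- function(neuron, inputs, seed = 1L, trace = FALSE) {
  stopifnot(inherits(neuron, "sctn_neuron"))
  if (inherits(inputs, "spike_train")) inputs <- list(inputs)
  if (length(inputs) != length(neuron$weights))
    stop("need one input train per synapse", call. = FALSE)
  clocks <- vapply(inputs, function(tr) tr$clock_hz, numeric(1))
  lens <- vapply(inputs, function(tr) length(tr$bits), numeric(1))
  if (length(unique(clocks)) != 1 || length(unique(lens)) != 1)
    stop("input trains must share clock_hz and length", call. = FALSE)
  mat <- do.call(cbind, lapply(inputs, function(tr) tr$bits))
  res <- run_neuron_cpp(as_engine_neuron(neuron, integer(), logical()),
                        mat, as.numeric(seed), trace)
  out <- spike_train(res$bits[, 1], clocks[1],
                     encoding = inputs[[1]]$encoding)
  if (trace) attr(out, "vm_trace") <- res$vm_trace
  out
}
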