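# Config (de)serialisation: neurons, resonator specs, banks, and STDP
# configs round-trip through JSON or YAML with all defaults written out.

config_fields <- function(x) {
  if (inherits(x, "sctn_neuron")) {
    list(type = "sctn_neuron",
         weights = x$weights, lf = x$lf, lp = x$lp, theta = x$theta,
         phi = x$phi, threshold = x$threshold, v_reset = x$v_reset,
         activation = x$activation, membrane_bounds = x$membrane_bounds,
         legacy_mu = x$legacy_mu, vm0 = x$vm0)
  } else if (inherits(x, "resonator_spec")) {
    list(type = "resonator_spec",
         lf = x$lf, lp = x$lp, clock_hz = x$clock_hz,
         stage_gain = x$stage_gain, feedback_gain = x$feedback_gain,
         input_gain = x$input_gain, tap_stages = x$tap_stages,
         output_threshold = x$output_threshold)
  } else if (inherits(x, "sctn_resonator")) {
    f <- config_fields(x$spec)
    f$type <- "sctn_resonator"
    f
  } else if (inherits(x, "sctn_bank")) {
    list(type = "sctn_bank",
         target_hz = attr(x, "target_hz"),
         clock_hz = x[[1]]$spec$clock_hz,
         specs = lapply(x, function(r) config_fields(r$spec)))
  } else if (inherits(x, "stdp_config")) {
    list(type = "stdp_config",
         eta_plus = x$eta_plus, eta_minus = x$eta_minus,
         tau_plus = x$tau_plus, tau_minus = x$tau_minus, lw = x$lw,
         tick_ms = x$tick_ms, b_kernel = x$b_kernel,
         weight_bounds = x$weight_bounds, causality = x$causality)
  } else {
    stop("don't know how to serialise objects of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
}

restore_config <- function(cfg) {
  type <- cfg$type
  cfg$type <- NULL
  num <- function(v) if (is.null(v)) NULL else as.numeric(unlist(v))
  switch(type,
    sctn_neuron = sctn_neuron(
      weights = num(cfg$weights), lf = cfg$lf, lp = cfg$lp,
      theta = cfg$theta, phi = cfg$phi, threshold = cfg$threshold,
      v_reset = cfg$v_reset, activation = cfg$activation,
      membrane_bounds = num(cfg$membrane_bounds),
      legacy_mu = cfg$legacy_mu, vm0 = cfg$vm0),
    resonator_spec = resonator_spec(
      lf = cfg$lf, lp = cfg$lp, clock_hz = cfg$clock_hz,
      stage_gain = cfg$stage_gain, feedback_gain = cfg$feedback_gain,
      input_gain = cfg$input_gain, tap_stages = num(cfg$tap_stages),
      output_threshold = cfg$output_threshold),
    sctn_resonator = build_resonator(restore_config(
      c(cfg, list(type = "resonator_spec")))),
    sctn_bank = {
      nets <- lapply(cfg$specs, function(s)
        build_resonator(restore_config(s)))
      structure(nets, class = "sctn_bank",
                achieved_hz = vapply(nets, function(n) n$spec$f0_hz,
                                     numeric(1)),
                target_hz = num(cfg$target_hz))
    },
    stdp_config = stdp_config(
      eta_plus = cfg$eta_plus, eta_minus = cfg$eta_minus,
      tau_plus = cfg$tau_plus, tau_minus = cfg$tau_minus, lw = cfg$lw,
      tick_ms = cfg$tick_ms, b_kernel = num(cfg$b_kernel),
      weight_bounds = num(cfg$weight_bounds), causality = cfg$causality),
    stop("unknown config type: ", type, call. = FALSE))
}

#' Write a configuration object to JSON or YAML
#'
#' All fields (including defaults) are written out; [read_config()]
#' restores an identical object (bit-exact numerics for JSON; YAML is
#' written at 16 significant digits).
#'
#' @param x An `sctn_neuron`, `resonator_spec`, `sctn_resonator`,
#'   `sctn_bank`, or `stdp_config`.
#' @param path Destination; format chosen by extension (`.json`,
#'   `.yaml`/`.yml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(x, path) {
  cfg <- config_fields(x)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(cfg, path, precision = 16L)
  } else {
    stop("unsupported config extension: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read a configuration object written by [write_config()]
#' @param path Path to a `.json` or `.yaml`/`.yml` config.
#' @return The restored object.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported config extension: .", ext, call. = FALSE)
  }
  restore_config(cfg)
}
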