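test_that("cutoff formula reproduces the worked design points", {
  expect_equal(round(cutoff_frequency(5, 73, 1.536e6), 2), 104.65)
  expect_equal(cutoff_frequency(5, 200, 1.536e6), 38.0, tolerance = 0.01)
  expect_equal(cutoff_frequency(0, 0, 48000), 48000 / (2 * pi))
  expect_error(cutoff_frequency(-1, 10, 1000), "lf >= 0")
  expect_error(cutoff_frequency(2, 10, -1), "clock_hz > 0")
})

test_that("radial and cutoff forms agree algebraically on the whole grid", {
  g <- expand.grid(lf = 1:8, lp = c(1, 2, 7, 73, 200))
  expect_equal(resonator_omega0(g$lf, g$lp, 1.536e6),
               2 * pi * cutoff_frequency(g$lf, g$lp, 1.536e6))
})

test_that("frequency grid has full cardinality and is monotone", {
  g <- frequency_grid(4:5, 1:200, 1.536e6)
  expect_equal(nrow(g), 400)
  expect_equal(g$f0_hz[g$lf == 5 & g$lp == 73], 104.65, tolerance = 1e-4)
  for (lf in 4:5) {
    f <- g$f0_hz[g$lf == lf]
    expect_true(all(diff(f[order(g$lp[g$lf == lf])]) < 0))
  }
  expect_true(all(g$f0_hz[g$lf == 5] < g$f0_hz[g$lf == 4]))
})

test_that("grid search inverts the cutoff formula", {
  d <- design_for_frequency(104.65, 1.536e6, lf_range = 5, lp_range = 1:200)
  expect_equal(d$lp, 73)
  # a target sitting exactly on a grid point is achieved with zero error
  target <- cutoff_frequency(4, 37, 1.536e6)
  d2 <- design_for_frequency(target, 1.536e6, 4:5, 1:200)
  expect_equal(d2$achieved_hz, target)
  expect_error(design_for_frequency(1e6, 1.536e6, 4:5, 1:200),
               "achievable span")
})

test_that("RC oracle: magnitude and phase at cutoff", {
  H <- rc_transfer(250, 250)
  expect_equal(Mod(H), 1 / sqrt(2))
  expect_equal(Arg(H) * 180 / pi, -45)
  # DC gain 1, high-frequency rolloff
  expect_equal(Mod(rc_transfer(0, 250)), 1)
  expect_lt(Mod(rc_transfer(2500, 250)), 0.11)
})

test_that("resonator topology: 17 neurons in 10 layers, wired as designed", {
  net <- build_resonator(test_reso_spec())
  expect_length(net$nodes, 17)
  roles <- vapply(net$nodes, `[[`, "", "role")
  expect_equal(sum(roles == "phase"), 8)
  expect_equal(sum(roles == "blocker"), 4)
  expect_equal(sum(roles == "rectifier"), 4)
  expect_equal(sum(roles == "output"), 1)
  layers <- vapply(net$nodes, `[[`, 1L, "layer")
  expect_equal(max(layers), 10L)
  expect_equal(layers[1:8], 1:8)
  # feedback edge: stage 1 reads stage 4's previous-tick output negatively
  expect_equal(net$nodes[[1]]$src, c(-1L, 4L))
  expect_true(net$nodes[[1]]$delayed[2])
  expect_lt(net$nodes[[1]]$neuron$weights[2], 0)
  expect_equal(net$spec$tap_stages, c(2L, 4L, 6L, 8L))
  # blockers binary, rectifiers identity with a non-negative membrane
  expect_true(all(vapply(net$nodes[9:12],
                         function(nd) nd$neuron$activation, "") == "binary"))
  expect_true(all(vapply(net$nodes[13:16],
                         function(nd) nd$neuron$activation, "") == "identity"))
  expect_true(all(vapply(net$nodes[13:16],
                         function(nd) nd$neuron$membrane_bounds[1], 1) == 0))
  expect_error(resonator_spec(5, 9, feedback_gain = 1.2), "loop gain")
})

test_that("built networks round-trip losslessly through serialization", {
  net <- build_resonator(test_reso_spec(feedback_gain = 0.85))
  p <- file.path(tempdir(), "reso.json")
  write_config(net, p)
  expect_equal(read_config(p), net)
})

test_that("resonator is a band-pass: DC rejected, peak at f0", {
  net <- build_resonator(test_reso_spec()) # f0 ~ 53 Hz
  f0 <- net$spec$f0_hz
  # DC input: density 0.5, zero amplitude
  dc <- pdm_encode(waveform(rep(0, 0.4 * 16000), 16000), net$spec$clock_hz)
  sim <- simulate_resonator(net, dc, bin_s = 0.2)
  r_dc <- utils::tail(sim$rates$rate_hz, 1)
  r <- vapply(c(f0 / 2, f0, 2 * f0), function(f) tone_rate(net, f),
              numeric(1))
  expect_gt(r[2], r[1])
  expect_gt(r[2], r[3])
  expect_gt(r[2], 10 * max(r_dc, 1))
})

test_that("output rate falls monotonically with detuning on each side", {
  net <- build_resonator(test_reso_spec())
  f0 <- net$spec$f0_hz
  below <- vapply(f0 * c(0.4, 0.7, 1), function(f) tone_rate(net, f),
                  numeric(1))
  above <- vapply(f0 * c(1, 1.5, 2.2), function(f) tone_rate(net, f),
                  numeric(1))
  expect_true(all(diff(below) > 0))
  expect_true(all(diff(above) < 0))
})

test_that("fast and generic engines produce identical simulations", {
  net <- build_resonator(test_reso_spec(lp = 7))
  tr <- encode_tone(net$spec$f0_hz, 0.25, net$spec$clock_hz)
  a <- simulate_resonator(net, tr, engine = "fast", return_taps = TRUE)
  b <- simulate_resonator(net, tr, engine = "generic", return_taps = TRUE)
  expect_identical(a$output$bits, b$output$bits)
  for (k in 1:8) expect_identical(a$taps[[k]]$bits, b$taps[[k]]$bits)
  expect_error(simulate_resonator(net, spike_train(0:1, 48000)),
               "clock")
})

test_that("frequency_response is empty on an empty probe list", {
  net <- build_resonator(test_reso_spec())
  expect_equal(nrow(frequency_response(net, numeric(0))), 0)
})

test_that("banks have one resonator (17 neurons) per target", {
  bank <- build_bank(bank20_frequencies())
  expect_length(bank, 20)
  expect_equal(sum(vapply(bank, function(r) length(r$nodes), 1L)), 340)
  one <- build_bank(500)
  expect_length(one, 1)
  expect_length(one[[1]]$nodes, 17)
  # achieved frequencies sit within the local grid spacing of each target
  ach <- attr(bank, "achieved_hz")
  for (i in seq_along(bank)) {
    lf <- bank[[i]]$spec$lf
    lp <- bank[[i]]$spec$lp
    neighbour <- cutoff_frequency(lf, max(lp - 1, 1), 1.536e6)
    gap <- abs(neighbour - ach[i]) + 1e-9
    expect_lt(abs(ach[i] - bank20_frequencies()[i]), gap + 1e-9)
  }
  expect_error(build_bank(c(500, 5e6)), "unachievable")
})

test_that("a small bank separates tones at its centre frequencies", {
  targets <- c(50, 90, 150, 230)
  bank <- build_bank(targets, 96000, 4:8, 1:200)
  ach <- attr(bank, "achieved_hz")
  for (k in seq_along(targets)) {
    f <- extract_snmfcc(sine_wave(ach[k], 0.4, 16000, 0.8), bank,
                        bin_s = 0.4)
    expect_equal(which.max(colSums(f)), k)
  }
})
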