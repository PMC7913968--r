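test_that("effective_alpha follows the shift-subtract law", {
  expect_equal(effective_alpha(0), 0)
  expect_equal(effective_alpha(5), 0.96875)
  expect_equal(effective_alpha(4), 0.9375)
  expect_error(effective_alpha(-1), "non-negative")
  expect_error(effective_alpha(1.5), "non-negative integer")
})

test_that("membrane_step accumulates, leaks on schedule, and saturates", {
  n <- sctn_neuron(1, threshold = 10)
  s <- neuron_state(n)
  # plain accumulation on a non-leak tick (lf = 0 with lp = 3: leak at t = 3)
  n2 <- sctn_neuron(1, lf = 0, lp = 3, threshold = 10)
  s2 <- membrane_step(neuron_state(n2), n2, 1, t = 1)
  expect_equal(s2$vm, 1)
  expect_equal(s2$tick, 1L)
  # pure leak halving: lf = 1 on a leak tick
  n3 <- sctn_neuron(1, lf = 1, lp = 1, threshold = 10)
  s3 <- neuron_state(n3)
  s3$vm <- 1
  expect_equal(membrane_step(s3, n3, 0, t = 1)$vm, 0.5)
  # full update on a leak tick: 0.75*(10 + 2 - 3 + 1) + 2 = 9.5
  n4 <- sctn_neuron(c(2, -3), lf = 2, lp = 1, phi = 1, theta = 2,
                    threshold = 100)
  s4 <- neuron_state(n4)
  s4$vm <- 10
  expect_equal(membrane_step(s4, n4, c(1, 1), t = 1)$vm, 9.5)
  # saturation at the membrane bounds (non-leak tick)
  n5 <- sctn_neuron(10, lp = 3, membrane_bounds = c(-2, 2), threshold = 2)
  s5 <- membrane_step(neuron_state(n5), n5, 1, t = 2)
  expect_equal(s5$vm, 2)
  # argument validation
  expect_error(membrane_step(neuron_state(n), n, c(1, 1), t = 1),
               "does not match")
  expect_error(membrane_step(neuron_state(n), n, 2, t = 1), "binary")
})

test_that("leak schedule fires every LP ticks", {
  n <- sctn_neuron(0.0001, lf = 1, lp = 4, theta = 0, threshold = 10)
  s <- neuron_state(n)
  s$vm <- 1
  vms <- numeric(8)
  for (t in 1:8) {
    s <- membrane_step(s, n, 0, t = t)
    vms[t] <- s$vm
  }
  # halves at t = 4 and t = 8 only (weight contribution is negligible)
  expect_equal(round(vms, 3), c(1, 1, 1, 0.5, 0.5, 0.5, 0.5, 0.25),
               tolerance = 1e-2)
})

test_that("binary firing thresholds and resets; ties fire", {
  n <- sctn_neuron(1, threshold = 3, v_reset = 0)
  s <- neuron_state(n)
  s$vm <- 5
  r <- fire(s, n)
  expect_equal(r$spike, 1L)
  expect_equal(r$state$vm, 0)
  s$vm <- 2
  r <- fire(s, n)
  expect_equal(r$spike, 0L)
  expect_equal(r$state$vm, 2)
  s$vm <- 3 # exact tie fires (>= comparison)
  expect_equal(fire(s, n)$spike, 1L)
})

test_that("stochastic activation fires at the membrane's relative level", {
  n <- sctn_neuron(1, activation = "stochastic_sigmoid",
                   membrane_bounds = c(-10, 10), threshold = 10)
  set.seed(42)
  mid <- replicate(1e4, {
    s <- neuron_state(n)
    s$vm <- 0 # midpoint of [-10, 10]
    fire(s, n)$spike
  })
  expect_equal(mean(mid), 0.5, tolerance = 0.04) # binomial CI ~ +/-0.01
  set.seed(42)
  hi <- replicate(2e3, {
    s <- neuron_state(n)
    s$vm <- 8 # 90% of the range
    fire(s, n)$spike
  })
  expect_equal(mean(hi), 0.9, tolerance = 0.05)
})

test_that("identity activation sigma-delta re-encodes the membrane level", {
  n <- sctn_neuron(1, activation = "identity", membrane_bounds = c(0, 4),
                   threshold = 4, v_reset = 1e-9)
  s <- neuron_state(n)
  s$vm <- 1 # 25% of range
  bits <- integer(100)
  for (i in 1:100) {
    r <- fire(s, n)
    bits[i] <- r$spike
    s <- r$state
  }
  expect_equal(mean(bits), 0.25, tolerance = 0.01)
})

test_that("run_neuron matches tick-by-tick R stepping", {
  set.seed(7)
  for (act in c("binary", "identity")) {
    n <- sctn_neuron(c(0.8, -0.3), lf = 2, lp = 3, phi = 0.05, theta = -0.01,
                     threshold = 2, activation = act,
                     membrane_bounds = c(-5, 5))
    bits1 <- rbinom(200, 1, 0.4)
    bits2 <- rbinom(200, 1, 0.2)
    out <- run_neuron(n, list(spike_train(bits1, 1000),
                              spike_train(bits2, 1000)))
    s <- neuron_state(n)
    ref <- integer(200)
    for (t in 1:200) {
      s <- membrane_step(s, n, c(bits1[t], bits2[t]), t = t)
      r <- fire(s, n)
      ref[t] <- r$spike
      s <- r$state
    }
    expect_identical(out$bits, ref)
  }
})

test_that("run_neuron contracts: silence, determinism, clock checks", {
  n <- sctn_neuron(1, threshold = 0.5)
  zeros <- spike_train(integer(500), 48000)
  expect_equal(sum(run_neuron(n, zeros)$bits), 0)

  ns <- sctn_neuron(1, activation = "stochastic_sigmoid",
                    membrane_bounds = c(-2, 2), threshold = 2)
  inp <- spike_train(rep(c(1L, 0L), 250), 48000)
  a <- run_neuron(ns, inp, seed = 9)
  b <- run_neuron(ns, inp, seed = 9)
  expect_identical(a$bits, b$bits)
  c_ <- run_neuron(ns, inp, seed = 10)
  expect_false(identical(a$bits, c_$bits))

  expect_error(
    run_neuron(sctn_neuron(c(1, 1), threshold = 1),
               list(spike_train(0:1, 1000), spike_train(0:1, 2000))),
    "share clock")
})

test_that("identity neuron saturates to full output density on DC drive", {
  n <- sctn_neuron(1, lf = 0, lp = 1000, activation = "identity",
                   membrane_bounds = c(-4, 4), threshold = 4)
  ones <- spike_train(rep(1L, 400), 1000)
  out <- run_neuron(n, ones)
  expect_equal(mean(out$bits[100:400]), 1)
})

test_that("legacy constant-leak mode reproduces the plain LIF recursion", {
  n <- sctn_neuron(c(1, 0.5), legacy_mu = 0.2, threshold = 1e8,
                   membrane_bounds = c(-1e9, 1e9))
  set.seed(11)
  i1 <- rbinom(300, 1, 0.5)
  i2 <- rbinom(300, 1, 0.3)
  out <- run_neuron(n, list(spike_train(i1, 1000), spike_train(i2, 1000)),
                    trace = TRUE)
  vm <- 0
  ref <- numeric(300)
  for (t in 1:300) {
    vm <- vm + 1 * i1[t] + 0.5 * i2[t] - 0.2
    ref[t] <- vm
  }
  expect_equal(attr(out, "vm_trace"), ref)
})

test_that("membrane stays within the closed-form leak bound", {
  set.seed(13)
  for (rep in 1:15) {
    lf <- sample(1:6, 1)
    lp <- sample(1:40, 1)
    w <- runif(2, -2, 2)
    phi <- runif(1, -0.5, 0.5)
    theta <- runif(1, -0.5, 0.5)
    n <- sctn_neuron(w, lf = lf, lp = lp, phi = phi, theta = theta,
                     threshold = 1e8, membrane_bounds = c(-1e9, 1e9))
    alpha <- effective_alpha(lf)
    lpe <- max(lp, 1)
    cmax <- sum(abs(w)) + abs(phi) + abs(theta)
    bound <- (alpha * lpe * cmax + abs(theta)) / (1 - alpha) +
      (lpe + 1) * cmax
    inputs <- list(spike_train(rbinom(600, 1, runif(1)), 1000),
                   spike_train(rbinom(600, 1, runif(1)), 1000))
    out <- run_neuron(n, inputs, trace = TRUE)
    expect_lt(max(abs(attr(out, "vm_trace"))), bound)
  }
})

test_that("neuron configs round-trip through JSON and YAML", {
  n <- sctn_neuron(c(0.25, -1.5), lf = 3, lp = 7, phi = -0.125, theta = 0.5,
                   threshold = 2.25, activation = "identity",
                   membrane_bounds = c(-3.5, 3.5), v_reset = 0.1)
  for (ext in c("json", "yaml")) {
    p <- file.path(tempdir(), paste0("neuron.", ext))
    write_config(n, p)
    expect_equal(read_config(p), n)
  }
})
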