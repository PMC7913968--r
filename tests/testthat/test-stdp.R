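test_that("pair rule evaluates the exponential STDP kernel", {
  cfg <- stdp_config() # eta+ 0.005, eta- 0.004, tau 15 ms
  expect_equal(stdp_delta(0, 0, cfg), 0.005)
  expect_equal(stdp_delta(0, 15, cfg), 0.005 * exp(-1))
  expect_equal(stdp_delta(15, 0, cfg), -0.004 * exp(-1))
  # multiple spikes: sum over all pairs, cross-checked by explicit loops
  set.seed(21)
  for (rep in 1:5) {
    pre <- sort(runif(6, 0, 60))
    post <- sort(runif(4, 0, 60))
    cfg1 <- stdp_config(tick_ms = 1)
    expect_equal(stdp_delta(pre, post, cfg1),
                 pair_sum_oracle(pre, post, cfg1))
  }
})

test_that("causality convention flips which lag sign potentiates", {
  cfg <- stdp_config(causality = "post_before_pre")
  expect_equal(stdp_delta(15, 0, cfg), 0.005 * exp(-1)) # pre after post
  expect_equal(stdp_delta(0, 15, cfg), -0.004 * exp(-1))
  k <- exponential_b_kernel(cfg)
  u <- -cfg$lw:cfg$lw
  expect_true(all(k[u <= 0] > 0)) # anti-causal side now potentiates
  expect_true(all(k[u > 0] < 0))
  expect_equal(k, vapply(u, function(ui) stdp_delta(0, ui, cfg),
                         numeric(1)))
})

test_that("exponential B register samples the pair rule at integer lags", {
  cfg <- stdp_config(lw = 16, tau_plus = 15, tau_minus = 15)
  k <- exponential_b_kernel(cfg, tick_ms = 1)
  expect_length(k, 33)
  expect_equal(k[17], 0.005) # u = 0
  # strict decay in |u| on each side
  expect_true(all(diff(abs(k[17:33])) < 0))
  expect_true(all(diff(abs(k[1:17])) > 0))
  # pointwise match with stdp_delta at the same offsets
  u <- -16:16
  expect_equal(k, vapply(u, function(ui)
    stdp_delta(0, ui, cfg), numeric(1)))
})

test_that("event matrix shift-register semantics", {
  m <- event_matrix(4, lw = 3)
  expect_equal(dim(m$registers), c(4, 7))
  m <- record_tick(m, c(0, 0, 1, 0), 0)
  expect_equal(which(m$registers[3, ] == 1), 1L)
  expect_equal(sum(m$registers), 1)
  # spikes age by one column per tick and leave after 2*lw + 1 ticks
  for (i in 1:7) m <- record_tick(m, rep(0, 4), 0)
  expect_equal(sum(m$registers), 0)
  # two spikes k ticks apart occupy offsets 0 and k
  m <- event_matrix(1, lw = 4)
  m <- record_tick(m, 1, 0)
  m <- record_tick(m, 0, 0)
  m <- record_tick(m, 0, 0)
  m <- record_tick(m, 1, 0)
  expect_equal(which(m$registers[1, ] == 1), c(1L, 4L))
  expect_error(record_tick(m, c(1, 0), 0), "width")
})

test_that("post-spike update applies exactly the B entry of each lag", {
  # distinct kernel entries expose any indexing error in the convolution
  lw <- 4
  b <- seq_len(2 * lw + 1) # stands in for B_u, u = -lw..lw
  cfg <- stdp_config(lw = lw, b_kernel = b, weight_bounds = c(-100, 100))
  for (u in -lw:lw) {
    # one pre spike at lag u relative to a single post spike
    ticks <- 2 * lw + 2
    pre <- matrix(0L, ticks, 1)
    post <- integer(ticks)
    t_post <- lw + 1
    post[t_post] <- 1L
    pre[t_post + u, 1] <- 1L
    res <- run_stdp(pre, post, weights = 0, cfg = cfg)
    # a pre spike u ticks after the post spike has dt = t_post - t_pre = -u
    expect_equal(res$weights, b[lw + 1 - u],
                 label = sprintf("lag %d", u))
  }
})

test_that("no postsynaptic spike means no weight change", {
  cfg <- stdp_config()
  set.seed(5)
  pre <- matrix(rbinom(40 * 3, 1, 0.4), 40, 3)
  res <- run_stdp(pre, integer(40), weights = c(0.2, 0.5, 0.8), cfg = cfg)
  expect_equal(res$weights, c(0.2, 0.5, 0.8))
  expect_equal(res$n_updates, 0L)
})

test_that("event-matrix updates equal the windowed analytic pair sum", {
  # all spikes confined to lw ticks, so every pair lag is within +/- lw
  set.seed(31)
  cfg <- stdp_config(lw = 16, weight_bounds = c(-1e6, 1e6))
  for (rep in 1:8) {
    ticks <- 60
    burst <- sample(ticks - cfg$lw, 1) + seq_len(cfg$lw) - 1
    pre <- matrix(0L, ticks, 2)
    post <- integer(ticks)
    pre[sample(burst, 4), 1] <- 1L
    pre[sample(burst, 3), 2] <- 1L
    post[sample(burst, 3)] <- 1L
    res <- run_stdp(pre, post, weights = c(0, 0), cfg = cfg)
    exp1 <- pair_sum_oracle(which(pre[, 1] == 1), which(post == 1), cfg)
    exp2 <- pair_sum_oracle(which(pre[, 2] == 1), which(post == 1), cfg)
    expect_equal(res$weights, c(exp1, exp2), tolerance = 1e-12)
  }
})

test_that("updates are linear in the learning rates and clamp to bounds", {
  set.seed(41)
  ticks <- 50
  pre <- matrix(rbinom(ticks * 2, 1, 0.3), ticks, 2)
  post <- rbinom(ticks, 1, 0.2)
  cfg1 <- stdp_config(weight_bounds = c(-1e6, 1e6))
  cfg2 <- stdp_config(eta_plus = 0.01, eta_minus = 0.008,
                      weight_bounds = c(-1e6, 1e6))
  d1 <- run_stdp(pre, post, c(0, 0), cfg1)$weights
  d2 <- run_stdp(pre, post, c(0, 0), cfg2)$weights
  expect_equal(d2, 2 * d1, tolerance = 1e-12)

  cfgb <- stdp_config(eta_plus = 1, eta_minus = 1, weight_bounds = c(0, 1))
  w <- run_stdp(pre, post, c(0.5, 0.5), cfgb)$weights
  expect_true(all(w >= 0 & w <= 1))
})

test_that("compiled trainer matches the R event-matrix reference", {
  # small rate-coded sample, replayed tick by tick in R with the same
  # sigma-delta encoding, membrane update, and B-register rule
  set.seed(51)
  nsyn <- 3
  nbins <- 6
  tpb <- 4
  dens <- matrix(runif(nbins * nsyn, 0, 0.9), nbins, nsyn)
  cfg <- stdp_config(lw = 3, weight_bounds = c(0, 1))
  neuron <- list(lf = 2L, lp = 0L, theta = 0, phi = 0, threshold = 1.2,
                 v_reset = 0, membrane_bounds = c(-100, 100))
  w0 <- c(0.5, 0.6, 0.4)
  res <- sctnsim:::stdp_train_cpp(list(dens), w0, neuron, cfg$b_kernel,
                                  cfg$lw, 0, 1, 1L, tpb, TRUE)
  # R reference
  w <- w0
  vm <- 0
  acc <- numeric(nsyn)
  m <- event_matrix(nsyn, cfg$lw)
  alpha <- effective_alpha(neuron$lf)
  nsp <- 0
  for (t in seq_len(nbins * tpb)) {
    bin <- (t - 1) %/% tpb + 1
    bits <- integer(nsyn)
    for (j in seq_len(nsyn)) {
      acc[j] <- acc[j] + dens[bin, j]
      if (acc[j] >= 1) { acc[j] <- acc[j] - 1; bits[j] <- 1L }
    }
    u <- sum(w * bits)
    vm <- alpha * (vm + u) # lp 0 -> leak every tick; theta = phi = 0
    post <- 0L
    if (vm >= neuron$threshold) { vm <- 0; post <- 1L; nsp <- nsp + 1 }
    m <- record_tick(m, bits, post)
    if (m$post_exit == 1L) w <- apply_post_spike_update(m, w, cfg)
  }
  expect_equal(as.numeric(res$weights), w, tolerance = 1e-12)
  expect_equal(res$epoch_spikes[1, 1], nsp)
})

test_that("stdp configs round-trip through serialization", {
  cfg <- stdp_config(eta_plus = 0.007, lw = 8, tick_ms = 2,
                     causality = "post_before_pre")
  p <- file.path(tempdir(), "stdp.json")
  write_config(cfg, p)
  expect_equal(read_config(p), cfg)
})
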