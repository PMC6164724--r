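make_trace <- function(times, d, events = data.frame(label = "starter",
                                                     time = 60)) {
  dissipation_trace(times = times, dissipation = d, events = events)
}

test_that("baseline gate passes stable traces and measures programmed drift", {
  t <- seq(0, 120, by = 1)
  ev <- data.frame(label = "starter", time = 100)

  flat <- dissipation_trace(t, rep(5e-4, length(t)), events = ev)
  chk <- baseline_stable(flat, window = 60)
  expect_true(chk$pass)
  expect_equal(chk$drift_per_min, 0, tolerance = 1e-12)

  # programmed ramp of 4e-6/min fails, with the drift measured to 5%
  ramp <- dissipation_trace(t, 5e-4 + (4e-6 / 60) * t, events = ev)
  chk4 <- baseline_stable(ramp, window = 60)
  expect_false(chk4$pass)
  expect_equal(chk4$drift_per_min, 4e-6, tolerance = 0.05)

  # 1e-6/min stays under the 2e-6/min gate
  slow <- dissipation_trace(t, 5e-4 + (1e-6 / 60) * t, events = ev)
  expect_true(baseline_stable(slow, window = 60)$pass)

  # window longer than the pre-event record
  expect_error(baseline_stable(flat, window = 300), "insufficient baseline")
})

test_that("smoothed derivative tracks linear, logistic and sinusoidal slopes", {
  t <- seq(0, 200, by = 1)
  ev <- data.frame(label = "starter", time = 10)

  lin <- dissipation_trace(t, 1e-6 * t, events = ev)
  d <- smoothed_derivative(lin, smooth_window = 11)
  interior <- 12:(length(t) - 12)
  expect_equal(d[interior], rep(1e-6, length(interior)), tolerance = 1e-9)
  expect_length(d, length(t))

  lgs <- dissipation_trace(t, 1e-4 * plogis((t - 120) / 5), events = ev)
  dl <- smoothed_derivative(lgs, smooth_window = 11)
  expect_lte(abs(t[which.max(dl)] - 120), 1)

  # sine against the analytic cosine, 50 samples per period
  tt <- seq(0, 10, by = 0.02)
  per <- 1
  sine <- dissipation_trace(tt, sin(2 * pi * tt / per),
                            events = data.frame(label = "starter", time = 5))
  ds <- smoothed_derivative(sine, smooth_window = 3)
  truth <- (2 * pi / per) * cos(2 * pi * tt / per)
  inner <- 5:(length(tt) - 5)
  rel_rms <- sqrt(mean((ds[inner] - truth[inner])^2)) / sqrt(mean(truth[inner]^2))
  expect_lt(rel_rms, 0.02)

  expect_error(smoothed_derivative(lin, smooth_window = 4), "odd")
  expect_error(smoothed_derivative(lin, smooth_window = 1), "odd")
})

test_that("endpoint detection recovers programmed clot times noiselessly", {
  for (ct in c(60, 150, 300, 600)) {
    for (w in c(5, 15, 30)) {
      sc <- test_scenario(sigmoid_center_t = 60 + ct, seed = 1, noise_sd = 0,
                          sigmoid_width = w, duration = 60 + ct + 240)
      sim <- simulate_trace(sc)
      res <- detect_endpoint(sim$trace)
      expect_lte(abs(res$clot_time - sim$truth_clot_time), sc$sample_interval)
      expect_equal(res$start_time, 60)
    }
  }
})

test_that("blanking excludes the loading artifact even when it out-slews the burst", {
  # artifact rises much faster than the burst, with its rising flank inside
  # the blanking window (longer than the smoothing window, so the spurious
  # positive derivative cannot be absorbed by the moving average)
  sc <- test_scenario(sigmoid_center_t = 360, seed = 1, noise_sd = 0,
                      artifact_amplitude = 1e-3, artifact_duration = 16)
  sim <- simulate_trace(sc)
  deriv_all <- smoothed_derivative(sim$trace, 11)
  in_artifact <- sim$trace$times > 60 & sim$trace$times < 70
  expect_gt(max(deriv_all[in_artifact]),
            max(deriv_all[sim$trace$times > 340 & sim$trace$times < 380]))

  res <- detect_endpoint(sim$trace, blanking = 10)
  expect_lte(abs(res$end_time - sim$truth_end_time), 1)

  # monotone blanking: increasing it never moves the end point earlier
  ends <- vapply(c(0, 5, 10, 30, 120), function(b) {
    detect_endpoint(sim$trace, blanking = b)$end_time
  }, numeric(1))
  expect_true(all(diff(ends) >= 0))
})

test_that("clot time survives noise at the liquid stability level", {
  hits <- 0L
  for (r in 1:100) {
    sim <- simulate_trace(test_scenario(sigmoid_center_t = 360, seed = 3000 + r))
    res <- detect_endpoint(sim$trace)
    if (abs(res$end_time - sim$truth_end_time) <= 3) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("endpoint detection is shift-equivariant and amplitude-invariant", {
  sc <- test_scenario(sigmoid_center_t = 360, seed = 8)
  sim <- simulate_trace(sc)
  res <- detect_endpoint(sim$trace)

  shift <- 37.5
  tr_s <- dissipation_trace(sim$trace$times + shift, sim$trace$dissipation,
                            events = transform(sim$trace$events,
                                               time = time + shift))
  res_s <- detect_endpoint(tr_s)
  expect_equal(res_s$start_time, res$start_time + shift)
  expect_equal(res_s$end_time, res$end_time + shift)
  expect_equal(res_s$clot_time, res$clot_time)

  tr_a <- dissipation_trace(sim$trace$times, 3.7 * sim$trace$dissipation,
                            events = sim$trace$events)
  expect_equal(detect_endpoint(tr_a)$end_time, res$end_time)
})

test_that("missing events, flat traces and QC flags behave as documented", {
  sim <- simulate_trace(test_scenario(seed = 2))
  expect_error(detect_endpoint(sim$trace, start_event_label = "pt_reagent"),
               "no event labelled")

  t <- seq(0, 300, by = 1)
  flat <- make_trace(t, rep(5e-4, length(t)))
  expect_error(detect_endpoint(flat), "no clot")

  falling <- make_trace(t, 5e-4 - 1e-6 * t)
  expect_error(detect_endpoint(falling), "no clot")

  # drifting baseline is flagged, not fatal
  drifty <- simulate_trace(test_scenario(seed = 4, drift_rate = 1e-5))
  expect_true("baseline_drift" %in% detect_endpoint(drifty$trace)$qc_flags)
})

test_that("rigidity check separates Sauerbrey and coagulation regimes", {
  expect_identical(rigidity_check(0.5e-6, 10)$classification, "rigid")
  coag <- rigidity_check(2.5e-6, 10)
  expect_identical(coag$classification, "viscoelastic")
  expect_equal(coag$ratio, 2.5e-6)
  # boundary is viscoelastic: the rigid criterion is a strict '<'
  expect_identical(rigidity_check(1e-6, 10)$classification, "viscoelastic")
  expect_identical(rigidity_check(1e-6, -10)$classification, "viscoelastic")
  expect_error(rigidity_check(1e-6, 0), "undefined ratio")
})

test_that("trace container validates monotone time, lengths and events", {
  expect_error(dissipation_trace(c(0, 1, 1), c(1, 2, 3)), "non-monotone")
  expect_error(dissipation_trace(c(0, 1, 2), c(1, 2)), "lengths differ")
  expect_error(dissipation_trace(c(0, 1, 2), c(1, 2, 3),
                                 events = data.frame(label = "x", time = 9)),
               "outside the sampled span")
})
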