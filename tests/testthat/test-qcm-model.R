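test_that("sensing depth matches the closed form and its scaling laws", {
  plasma <- liquid_params(eta = 1.42e-3, rho = 1.03e3)
  d <- sensing_depth(plasma, f0 = 1e7)
  # plasma on a 10 MHz crystal: ~210 nm
  expect_equal(d, 2.0948388690288347e-7, tolerance = 1e-12)
  expect_equal(round(d * 1e9 / 10) * 10, 210)

  # frozen arbitrary-precision evaluation of the closed form
  expect_equal(sensing_depth(liquid_params(eta = 1e-3, rho = 1e3), 5e6),
               2.5231325220201600e-7, tolerance = 1e-14)

  # square-root scaling: delta(4 eta) = 2 delta(eta); delta(4 f0) = delta/2
  base <- sensing_depth(liquid_params(eta = 1e-3, rho = 1e3), 1e7)
  expect_equal(sensing_depth(liquid_params(eta = 4e-3, rho = 1e3), 1e7),
               2 * base, tolerance = 1e-14)
  expect_equal(sensing_depth(liquid_params(eta = 1e-3, rho = 1e3), 4e7),
               base / 2, tolerance = 1e-14)
  # monotone: decreasing in rho
  expect_lt(sensing_depth(liquid_params(eta = 1e-3, rho = 2e3), 1e7), base)

  expect_error(sensing_depth(plasma, f0 = -1), "f0")
  expect_error(liquid_params(eta = 0), "eta")
})

test_that("Kelvin-Voigt dissipation shift matches the symbolic oracle", {
  res <- resonator_params(f0 = 1e7, rho0 = 2648, h0 = 1.67e-4)
  liq <- liquid_params(eta = 1.42e-3, rho = 1.03e3)
  film <- film_params(h1 = 1e-7, mu1 = 1e5, eta1 = 1e-3)

  # frozen arbitrary-precision evaluation of the full expression
  expect_equal(dissipation_shift_kelvin_voigt(res, liq, film),
               4.8792536866080379e-4, tolerance = 1e-12)

  # h1 = 0: exactly the bulk-liquid term eta / (pi f0 rho0 h0 delta)
  bare <- dissipation_shift_kelvin_voigt(res, liq, film_params())
  delta <- sensing_depth(liq, res$f0)
  expect_identical(bare, liq$eta / (pi * res$f0 * res$rho0 * res$h0 * delta))
  expect_equal(bare, 4.8792536568095676e-4, tolerance = 1e-12)

  # film contribution is linear in h1
  f1 <- dissipation_shift_kelvin_voigt(res, liq, film) - bare
  film2 <- film_params(h1 = 2e-7, mu1 = 1e5, eta1 = 1e-3)
  f2 <- dissipation_shift_kelvin_voigt(res, liq, film2) - bare
  expect_equal(f2, 2 * f1, tolerance = 1e-10)
  expect_gt(f1, 0)

  # degenerate film rejected both at construction and at evaluation
  expect_error(film_params(h1 = 1e-7, mu1 = 0, eta1 = 0), "degenerate film")
  bad <- film_params(h1 = 0)
  bad$h1 <- 1e-7
  expect_error(dissipation_shift_kelvin_voigt(res, liq, bad),
               "degenerate film")
})

test_that("dissipation shift is monotone increasing in liquid viscosity", {
  res <- resonator_params()
  film <- film_params(h1 = 1e-7, mu1 = 1e5, eta1 = 1e-3)
  etas <- seq(0.8e-3, 4e-3, length.out = 12)
  vals <- vapply(etas, function(e) {
    dissipation_shift_kelvin_voigt(res, liquid_params(eta = e), film)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("magnitude response obeys the 3 dB bandwidth contract", {
  res <- resonator_params(f0 = 1e7)
  D <- 1e-4
  # -3 dB crossings at fs +/- D*fs/2 = +/- 500 Hz
  H0 <- magnitude_response(res, D, 1e7)
  Hpm <- magnitude_response(res, D, 1e7 + c(-500, 500))
  expect_equal(Mod(H0) / Mod(Hpm), c(sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(Arg(H0), 0)
  # phase sign flips across resonance
  expect_gt(Arg(magnitude_response(res, D, 1e7 - 100)), 0)
  expect_lt(Arg(magnitude_response(res, D, 1e7 + 100)), 0)

  # BW/fs = D over a grid of (fs, D): recompute D from the -3 dB width
  for (fs in c(1e6, 1e7, 1e8)) {
    for (D in c(1e-6, 1e-4, 1e-3)) {
      resx <- resonator_params(f0 = fs)
      target <- Mod(magnitude_response(resx, D, fs)) / sqrt(2)
      lo <- uniroot(function(f) Mod(magnitude_response(resx, D, f)) - target,
                    c(fs * (1 - 10 * D), fs), tol = fs * 1e-13)$root
      hi <- uniroot(function(f) Mod(magnitude_response(resx, D, f)) - target,
                    c(fs, fs * (1 + 10 * D)), tol = fs * 1e-13)$root
      expect_equal((hi - lo) / fs, D, tolerance = 1e-6)
    }
  }

  # symmetric magnitude about fs
  off <- c(10, 100, 1000)
  expect_equal(Mod(magnitude_response(res, 1e-4, 1e7 + off)),
               Mod(magnitude_response(res, 1e-4, 1e7 - off)),
               tolerance = 1e-12)
})

test_that("trace simulator is seeded, additive and truthful", {
  sc <- test_scenario(seed = 11)
  sim1 <- simulate_trace(sc)
  sim2 <- simulate_trace(sc)
  expect_identical(sim1$trace$dissipation, sim2$trace$dissipation)
  expect_identical(sim1$trace$frequency, sim2$trace$frequency)

  # noiseless, no artifact, no drift: derivative argmax at the logistic centre
  clean <- test_scenario(seed = 1, noise_sd = 0, artifact_amplitude = 0,
                         drift_rate = 0, slow_rise_rate = 0)
  simc <- simulate_trace(clean)
  d <- diff(simc$trace$dissipation)
  tmax <- simc$trace$times[which.max(d)]
  expect_lte(abs(tmax - clean$sigmoid_center_t), clean$sample_interval)
  expect_lte(abs(simc$truth_end_time - clean$sigmoid_center_t),
             clean$sample_interval)

  # frequency channel is the programmed linear coupling
  sim <- simulate_trace(sc, f0 = 1e7)
  expect_equal(sim$trace$frequency,
               1e7 - sc$freq_coupling * (sim$trace$dissipation - sc$baseline_D),
               tolerance = 1e-12)

  # noise residuals: mean ~0, sd within 10% of noise_sd at n = 1e4
  big <- test_scenario(seed = 3, duration = 1e4, sigmoid_center_t = 9000,
                       sample_interval = 1)
  simb <- simulate_trace(big)
  resid <- simb$trace$dissipation -
    qcmcoag:::scenario_curve(big, simb$trace$times)
  expect_lt(abs(mean(resid)), 3 * big$noise_sd / sqrt(length(resid)))
  expect_equal(sd(resid), big$noise_sd, tolerance = 0.1)

  expect_error(trace_scenario(sigmoid_center_t = 300, seed = 1,
                              event_times = c(starter = 700)),
               "scenario error")
  expect_error(trace_scenario(sigmoid_center_t = 30, seed = 1),
               "after the start event")
})
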