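test_that("AP detection finds constructed spikes and nothing else", {
  # flat trace: no APs
  rate <- 5e4
  t <- seq(0, 0.2, by = 1 / rate)
  flat <- cc_sweep(t, rep(-70, length(t)), rate)
  expect_length(detect_aps(flat), 0L)

  # single Gaussian spike to +30 mV
  one <- generate_traces(list(0.1), amplitudes = 100, duration = 0.2)
  aps <- detect_aps(one$sweeps[[1]])
  expect_length(aps, 1L)

  # two well-separated spikes recovered at the constructed times
  two <- generate_traces(list(c(0.05, 0.15)), amplitudes = 100,
                         duration = 0.2)
  aps2 <- detect_aps(two$sweeps[[1]])
  expect_length(aps2, 2L)
  # detection happens on the rising flank, within ~1 ms before each peak
  expect_true(all(abs(aps2 - c(0.05, 0.15)) < 1.5e-3))

  # time reversal kills the upward dV/dt crossing: real APs rise fast and
  # decay slowly, so build an asymmetric spike (0.5 ms rise, 25 ms decay)
  t2 <- seq(0, 0.1, by = 1 / rate)
  up <- pmax(0, pmin(1, (t2 - 0.04) / 5e-4))
  down <- exp(-pmax(0, t2 - 0.0405) / 0.025)
  asym <- cc_sweep(t2, -70 + 100 * pmin(up, down), rate)
  expect_length(detect_aps(asym), 1L)
  rev_sweep <- cc_sweep(asym$time, rev(asym$voltage), rate)
  expect_length(detect_aps(rev_sweep), 0L)

  # sub-peak depolarizations are rejected by the min_peak rule
  small <- generate_traces(list(0.1), amplitudes = 40, duration = 0.2)
  expect_length(detect_aps(small$sweeps[[1]]), 0L) # peaks at -30 mV

  expect_error(cc_sweep(c(0, 1e-5, 3e-5, 4e-5, 5e-5), rep(0, 5), 1e5),
               "non-uniform")
})

test_that("rise speed equals the analytic derivative of known waveforms", {
  rate <- 5e4
  t <- seq(0, 0.05, by = 1 / rate)

  # linear ramp of 200 mV/ms from -70 to +30 starting at 20 ms
  ramp_start <- 0.02
  v <- ifelse(t < ramp_start, -70,
              pmin(30, -70 + 200 * (t - ramp_start) * 1000))
  sw <- cc_sweep(t, v, rate)
  aps <- detect_aps(sw)
  expect_length(aps, 1L)
  expect_equal(ap_rise_speed(sw, aps[1]), 200, tolerance = 0.01)

  # sinusoidal rise 50 sin(2 pi 500 t): analytic max dV/dt = 2 pi f A
  vs <- 50 * sin(2 * pi * 500 * t)
  ss <- cc_sweep(t, vs, rate)
  aps_s <- detect_aps(ss)
  analytic <- 2 * pi * 500 * 50 / 1000 # V/s
  expect_equal(ap_rise_speed(ss, aps_s[1]), analytic, tolerance = 0.01)

  # linearity: doubling the amplitude doubles the rise speed
  g1 <- generate_traces(list(0.1), amplitudes = 100, duration = 0.2)
  g2 <- generate_traces(list(0.1), amplitudes = 200, duration = 0.2)
  r1 <- ap_rise_speed(g1$sweeps[[1]], detect_aps(g1$sweeps[[1]])[1])
  r2 <- ap_rise_speed(g2$sweeps[[1]], detect_aps(g2$sweeps[[1]])[1])
  expect_equal(r2 / r1, 2, tolerance = 1e-6)

  # constant voltage offset leaves the rise speed unchanged
  off <- cc_sweep(g1$sweeps[[1]]$time, g1$sweeps[[1]]$voltage + 15, rate)
  expect_equal(ap_rise_speed(off, detect_aps(off)[1]), r1, tolerance = 1e-9)
})

test_that("generated traces carry closed-form truth recovered within tolerance", {
  # 50 kHz: within 1%
  g <- generate_traces(list(0.05, 0.12), amplitudes = c(100, 120),
                       duration = 0.2, sampling_rate = 5e4)
  for (j in 1:2) {
    sw <- g$sweeps[[j]]
    r <- ap_rise_speed(sw, detect_aps(sw)[1])
    expect_equal(r, g$truth$max_dvdt[g$truth$sweep == j][1],
                 tolerance = 0.01)
  }
  # 10 kHz: within 5%
  g10 <- generate_traces(list(0.05), amplitudes = 100, duration = 0.2,
                         sampling_rate = 1e4)
  r10 <- ap_rise_speed(g10$sweeps[[1]], detect_aps(g10$sweeps[[1]])[1])
  expect_equal(r10, g10$truth$max_dvdt[1], tolerance = 0.05)

  # determinism and the no-spike case
  a <- generate_traces(list(numeric(), 0.1), noise_sd = 0.5, seed = 4)
  b <- generate_traces(list(numeric(), 0.1), noise_sd = 0.5, seed = 4)
  expect_identical(a$sweeps[[2]]$voltage, b$sweeps[[2]]$voltage)
  expect_equal(sum(a$truth$sweep == 1), 0L)
  expect_length(detect_aps(a$sweeps[[1]]), 0L)

  expect_error(generate_traces(list(c(0.1, 0.1005))), "waveform support")
  expect_error(generate_traces(list(0.5), duration = 0.2), "outside")
})

test_that("cell rise speed averages first-AP speeds over suprathreshold sweeps", {
  # construct sweeps whose first-AP rise speeds differ via amplitude
  g <- generate_traces(list(0.05, c(0.05, 0.15), numeric()),
                       amplitudes = c(100, 150, 100), duration = 0.2)
  res <- cell_rise_speed(g$sweeps)
  sp <- res$per_sweep
  expect_equal(nrow(sp), 3L)
  expect_equal(sp$n_aps, c(1L, 2L, 0L))
  expect_true(is.na(sp$first_ap_rise_speed[3]))
  expect_equal(res$cell_rise_speed,
               mean(sp$first_ap_rise_speed[1:2]))
  # first AP of sweep 2 is the 0.05 s spike, not the later one
  expect_lt(abs(sp$first_ap_time[2] - 0.05), 1.5e-3)

  # one sweep: identity
  single <- cell_rise_speed(g$sweeps[[1]])
  expect_equal(single$cell_rise_speed, sp$first_ap_rise_speed[1])

  expect_error(cell_rise_speed(g$sweeps[3]), "no suprathreshold")
})
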