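fs <- 1000
t_axis <- seq(-1, 2, by = 1 / fs)

test_that("notch attenuates line frequency >= 30 dB and preserves neighbours", {
  tone60 <- signal_epochs(function(t) sin(2 * pi * 60 * t), t = t_axis)
  out60 <- notch_line_noise(tone60)
  interior <- t_axis > -0.7 & t_axis < 1.7
  expect_lt(db_ratio(out60$voltages[1, interior], tone60$voltages[1, interior]), -30)

  tone85 <- signal_epochs(function(t) sin(2 * pi * 85 * t), t = t_axis)
  out85 <- notch_line_noise(tone85)
  expect_lt(abs(db_ratio(out85$voltages[1, interior], tone85$voltages[1, interior])), 1)
})

test_that("notch dips only at 60/120 Hz bins (FFT oracle on broadband noise)", {
  x <- withr::with_seed(4, rnorm(length(t_axis)))
  ep <- signal_epochs(function(t) 0, t = t_axis, n_trials = 1)
  ep$voltages[1, ] <- x
  out <- notch_line_noise(ep)
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  gain_db <- 20 * log10(Mod(fft(out$voltages[1, ])) / Mod(fft(x)))
  sel <- f > 5 & f < 200
  notched <- abs(f - 60) < 4 | abs(f - 120) < 4
  expect_lt(max(gain_db[sel & !notched]), 3) # no spurious gain
  expect_gt(mean(gain_db[sel & !notched] > -3), 0.99) # passband essentially flat
  # deep dips at the notch bins (finite because of single-periodogram leakage)
  expect_lt(min(gain_db[abs(f - 60) < 0.5]), -15)
  expect_lt(min(gain_db[abs(f - 120) < 0.5]), -15)
})

test_that("gamma band-pass: in-band passes within 1 dB, out-of-band >= 30 dB down", {
  interior <- t_axis > -0.7 & t_axis < 1.7
  for (case in list(c(90, 1), c(40, -30), c(150, -30))) {
    tone <- signal_epochs(function(t) sin(2 * pi * case[1] * t), t = t_axis)
    out <- bandpass_gamma(tone)
    g <- db_ratio(out$voltages[1, interior], tone$voltages[1, interior])
    if (case[2] > 0) expect_lt(abs(g), case[2]) else expect_lt(g, case[2])
  }
})

test_that("measured band-pass response matches the designed filter (chirp sweep)", {
  # linear chirp 10 -> 200 Hz over the epoch; compare the empirical transfer
  # function against |H|^2 of the designed filter (applied twice: zero-phase)
  dur <- 3
  k <- (200 - 10) / dur
  tt <- t_axis - t_axis[1]
  chirp <- sin(2 * pi * (10 * tt + k * tt^2 / 2))
  ep <- signal_epochs(function(t) 0, t = t_axis, n_trials = 1)
  ep$voltages[1, ] <- chirp
  out <- bandpass_gamma(ep, pad_s = 0) # measure the filter itself, no padding
  n <- length(chirp)
  f <- (seq_len(n) - 1) * fs / n
  emp <- Mod(fft(out$voltages[1, ])) / Mod(fft(chirp))
  flt <- gammasel:::design_gamma_filter(fs)
  sel <- f > 0 & f < 500
  w <- 2 * pi * f[sel] / fs
  H <- vapply(w, function(wi) { # transfer function evaluated on the unit circle
    z <- exp(-1i * wi * (seq_along(flt$b) - 1))
    Mod(sum(flt$b * z) / sum(flt$a * exp(-1i * wi * (seq_along(flt$a) - 1))))
  }, numeric(1))
  des <- H^2 # forward-backward application squares the magnitude
  keep <- des > 10^(-20 / 20) # compare where the response is not ~0
  err_db <- abs(20 * log10(emp[sel][keep]) - 20 * log10(des[keep]))
  expect_lt(stats::quantile(err_db, 0.98), 1)
})

test_that("zero-phase filtering does not shift an injected burst (<= 1 sample)", {
  burst_env <- exp(-((t_axis - 0.5)^2) / (2 * 0.05^2))
  ep <- signal_epochs(function(t) 0, t = t_axis, n_trials = 1)
  ep$voltages[1, ] <- burst_env * sin(2 * pi * 90 * t_axis)
  out <- analytic_amplitude(bandpass_gamma(notch_line_noise(ep)))
  expect_lte(abs(which.max(out$voltages[1, ]) - which.max(burst_env)), 1)
})

test_that("analytic amplitude recovers tone and AM envelopes", {
  interior <- t_axis > -0.6 & t_axis < 1.6
  tone <- signal_epochs(function(t) 3.7 * sin(2 * pi * 80 * t), t = t_axis,
                        n_trials = 1)
  env <- analytic_amplitude(tone)
  expect_lt(max(abs(env$voltages[1, interior] - 3.7)) / 3.7, 0.01)

  am_true <- 1 + 0.5 * sin(2 * pi * 4 * t_axis)
  am <- signal_epochs(function(t) (1 + 0.5 * sin(2 * pi * 4 * t)) *
                        sin(2 * pi * 90 * t), t = t_axis, n_trials = 1)
  env2 <- analytic_amplitude(am)
  expect_lt(max(abs(env2$voltages[1, interior] - am_true[interior])), 0.05)

  zero <- signal_epochs(function(t) 0 * t, t = t_axis, n_trials = 1)
  expect_equal(max(abs(analytic_amplitude(zero)$voltages)), 0)
})

test_that("analytic amplitude rejects epochs shorter than the smoothing frame", {
  short <- signal_epochs(function(t) sin(2 * pi * 80 * t),
                         t = seq(0, 0.1, by = 1 / fs), n_trials = 1)
  expect_error(analytic_amplitude(short), "frame")
})

test_that("percent change: stationarity, amplitude doubling, rejected mask", {
  n <- length(t_axis)
  flat <- epoch_set(matrix(2, 3, n), fs, category = rep("face", 3), time = t_axis)
  pc <- percent_change(flat)
  expect_lt(max(abs(pc$pct)), 1e-9)

  # envelope doubles at t = 0: power quadruples, percent change -> +300
  env <- matrix(1, 3, n)
  env[, t_axis >= 0] <- 2
  pc2 <- percent_change(epoch_set(env, fs, category = rep("face", 3), time = t_axis))
  expect_equal(unname(pc2$mean[t_axis > 0.1][1]), 300, tolerance = 1e-9)

  # rejected trials are excluded from the mean trace
  env3 <- matrix(1, 4, n)
  env3[3:4, ] <- 5 # would distort the mean if included
  env3[1:2, t_axis >= 0] <- 2
  ep3 <- epoch_set(env3, fs, category = rep("face", 4), time = t_axis,
                   rejected = c(FALSE, FALSE, TRUE, TRUE))
  pc3 <- percent_change(ep3)
  expect_equal(unname(pc3$mean[t_axis > 0.1][1]), 300, tolerance = 1e-9)

  zero <- epoch_set(matrix(0, 2, n), fs, category = rep("a", 2), time = t_axis)
  expect_error(percent_change(zero), "baseline")
})

test_that("window-mean BGA matches constant, ramp, and brute-force oracles", {
  n <- length(t_axis)
  in_win <- t_axis >= 0.1 & t_axis <= 0.4
  # constant
  bga <- fake_bga(matrix(7.5, 2, n), t_axis, fs, rep("face", 2))
  expect_equal(window_mean_bga(bga)$bga, c(7.5, 7.5))
  # linear ramp 0 -> 100 over the window: mean 50
  ramp <- rep(0, n)
  ramp[in_win] <- seq(0, 100, length.out = sum(in_win))
  bga2 <- fake_bga(matrix(ramp, 1, n, byrow = TRUE), t_axis, fs, "face")
  expect_equal(window_mean_bga(bga2)$bga, 50)
  # random traces vs arithmetic-mean oracle
  m <- withr::with_seed(9, matrix(rnorm(5 * n), 5, n))
  bga3 <- fake_bga(m, t_axis, fs, rep(c("a", "b"), c(2, 3)))
  oracle <- apply(m[, in_win], 1, mean)
  expect_equal(window_mean_bga(bga3)$bga, oracle, tolerance = 1e-12)
  expect_error(window_mean_bga(bga3, window = c(5, 6)), "window")
})

test_that("percent-change BGA is invariant to overall recording gain", {
  ds <- simulate_dataset(fast_sim_config(n_subjects = 1,
                                         electrodes_per_subject = 1, seed = 21))
  ep <- ds$epochs$data[[1]]
  scaled <- ep
  scaled$voltages <- ep$voltages * 3.7
  a <- extract_bga(ep, notch = FALSE)
  b <- extract_bga(scaled, notch = FALSE)
  expect_equal(a$pct, b$pct, tolerance = 1e-9)
  # and the pipeline is deterministic
  expect_identical(a$pct, extract_bga(ep, notch = FALSE)$pct)
})

test_that("baseline percent change is centred near zero under the null", {
  ds <- simulate_dataset(fast_sim_config(
    n_subjects = 1, electrodes_per_subject = 1, trials_per_category = 12,
    selectivity_effect = null_effect(), seed = 31
  ))
  bga <- extract_bga(ds$epochs$data[[1]], notch = FALSE)
  mid <- which.min(abs(bga$time - (-0.45)))
  sem <- bga$sd[mid] / sqrt(sum(!bga$rejected))
  expect_lt(abs(mean(bga$pct[, mid])), 3 * sem)
})

test_that("notch rejects line frequencies at or above Nyquist", {
  ep <- signal_epochs(function(t) sin(2 * pi * 10 * t), t = t_axis, n_trials = 1)
  expect_error(notch_line_noise(ep, line_hz = 510, max_hz = 510), "Nyquist")
  expect_error(bandpass_gamma(ep, band = c(120, 60)), "band")
})
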