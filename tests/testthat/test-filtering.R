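test_that("rough bands reproduce the fixed cutoffs", {
  b <- rough_bands(44)
  expect_equal(b$resp$low, 2 / 60)
  expect_equal(b$resp$high, 40 / 60)
  expect_equal(b$cardiac$low, 40 / 60)
  # 400 bpm exceeds 95% of Nyquist at 44 Hz, so the cap applies
  expect_equal(b$cardiac$high, min(400 / 60, 0.95 * 22))
})

test_that("band-pass design meets its stop-band and DC contracts", {
  fs <- 44
  band <- band_spec(2 / 60, 40 / 60)
  filt <- design_bandpass(band, fs)          # uncapped design order
  # forward-backward gain: >= 40 dB down at 0.5*low and 1.5*high
  g_stop <- filter_response(filt, c(0.5 * band$low, 1.5 * band$high),
                            zero_phase = TRUE)
  expect_true(all(10 * log10(g_stop) < -40))
  # pass-band close to unity inside the band
  g_pass <- filter_response(filt, c(band$low, 0.1, 0.3, band$high),
                            zero_phase = TRUE)
  expect_true(all(abs(g_pass - 1) < 0.04))
  # DC rejection: constant input comes out < 1% of its value
  dc <- apply_zero_phase(rep(2, 3 * length(filt$coef) + 100), filt)
  expect_lt(max(abs(dc)), 0.01 * 2)
  # Nyquist violation is an error
  expect_error(design_bandpass(band_spec(1, 30), fs), "Nyquist")
})

test_that("zero-phase filtering preserves in-band sinusoids with zero lag", {
  fs <- 44
  filt <- design_bandpass(band_spec(0.6, 3), fs, n_samples = 4000)
  tt <- (0:3999) / fs
  for (f in c(0.8, 1.2, 2.0)) {
    x <- sin(2 * pi * f * tt)
    y <- apply_zero_phase(x, filt)
    core <- 500:3500
    expect_equal(max(abs(y[core])), 1, tolerance = 0.02)
    expect_identical(xcorr_peak_lag(x[core], y[core], 30), 0L)
  }
})

test_that("stop-band attenuation matches the frequency-response oracle", {
  fs <- 44
  band <- band_spec(0.6, 3)
  filt <- design_bandpass(band, fs, n_samples = 6000)
  f_stop <- 0.25 * band$low
  tt <- (0:5999) / fs
  y <- apply_zero_phase(sin(2 * pi * f_stop * tt), filt)
  amp <- max(abs(y[1000:5000]))
  expect_lt(20 * log10(amp), -40)
  predicted <- filter_response(filt, f_stop, zero_phase = TRUE)
  expect_lt(amp, 10 * predicted + 1e-6)   # same order as the response oracle
})

test_that("zero-phase filtering is linear and validates signal length", {
  fs <- 44
  filt <- design_bandpass(band_spec(0.6, 3), fs, n_samples = 2000)
  set.seed(2)
  a <- rnorm(2000); b <- rnorm(2000)
  ya <- apply_zero_phase(a, filt)
  yb <- apply_zero_phase(b, filt)
  yab <- apply_zero_phase(a + b, filt)
  expect_equal(yab, ya + yb, tolerance = 1e-9)
  expect_error(apply_zero_phase(rnorm(3 * length(filt$coef)), filt),
               "signal length")
})

test_that("matrix filtering equals column-wise filtering", {
  fs <- 44
  filt <- design_bandpass(band_spec(0.6, 3), fs, n_samples = 1500)
  set.seed(3)
  X <- matrix(rnorm(1500 * 4), 1500, 4)
  Y <- apply_zero_phase(X, filt)
  for (j in 1:4)
    expect_equal(Y[, j], apply_zero_phase(X[, j], filt), tolerance = 1e-12)
})

test_that("rough split concentrates breath and pulse energy in their bands", {
  d <- default_rec()
  sub <- subtract_reference(d$rec$movie)
  region <- region_mask(d$geom$lung_mask, "lung")
  rs <- rough_split(sub, region)
  pg_r <- periodogram_power(rs$resp, rs$fs)
  pg_c <- periodogram_power(rs$cardiac, rs$fs)
  expect_lt(abs(pg_r$freq[which.max(pg_r$power)] - d$rec$truth$true_f_RR),
            pg_r$bin)
  expect_lt(abs(pg_c$freq[which.max(pg_c$power)] - d$rec$truth$true_f_HR),
            pg_c$bin)
})

test_that("a pure-noise region shows no spectral peak and rates error out", {
  set.seed(4)
  segs <- data.frame(label = "breathing", start = 0L, end = 1600L)
  m <- pixel_movie(array(rnorm(1600 * 64), dim = c(1600, 8, 8)), fs = 44,
                   segments = segs)
  region <- region_mask(matrix(TRUE, 8, 8), "lung")
  rs <- rough_split(m, region)
  bands <- rough_bands(44)
  check_band <- function(x, band) {
    pg <- periodogram_power(x, 44)
    sel <- pg$freq >= band$low & pg$freq <= band$high
    # white-noise periodogram maxima sit at ~log(m) times the in-band
    # mean; a coherent peak would be orders of magnitude higher
    expect_lt(max(pg$power[sel]), 15 * mean(pg$power[sel]))
  }
  check_band(rs$resp, bands$resp)
  check_band(rs$cardiac, bands$cardiac)
  expect_error(estimate_rates(rs$resp, rs$cardiac, 44), "noise floor")
})

test_that("rates are recovered within one resolution bin on a synthetic recording", {
  d <- default_rec()
  sub <- subtract_reference(d$rec$movie)
  rs <- rough_split(sub, find_reference_region(sub))
  rates <- estimate_rates(rs$resp, rs$cardiac, 44)
  expect_lt(abs(rates$f_RR - d$rec$truth$true_f_RR), rates$bin_width)
  expect_lt(abs(rates$f_HR - d$rec$truth$true_f_HR), rates$bin_width)
  expect_false(rates$harmonic_conflict)
})

test_that("a cardiac peak at an exact respiratory harmonic raises the conflict flag", {
  fs <- 44
  tt <- (0:(45 * fs - 1)) / fs
  f_RR <- 0.3
  resp <- sin(2 * pi * f_RR * tt)
  cardiac <- 0.1 * sin(2 * pi * 4 * f_RR * tt)
  est <- estimate_rates(resp, cardiac, fs)
  expect_true(est$harmonic_conflict)
  expect_identical(est$conflict_resolution, "unresolved")
  # an unresolved conflict blocks refinement
  d <- default_rec()
  expect_error(refine_movies(subtract_reference(d$rec$movie), est),
               "harmonic conflict")
})

test_that("a genuine cardiac peak survives a harmonic conflict via next_peak", {
  fs <- 44
  tt <- (0:(45 * fs - 1)) / fs
  f_RR <- 0.3
  resp <- sin(2 * pi * f_RR * tt)
  # strong spurious component exactly on the 4th harmonic plus the true pulse
  cardiac <- 0.3 * sin(2 * pi * 4 * f_RR * tt) + 0.25 * sin(2 * pi * 1.43 * tt)
  est <- estimate_rates(resp, cardiac, fs)
  expect_true(est$harmonic_conflict)
  expect_identical(est$conflict_resolution, "next_peak")
  expect_lt(abs(est$f_HR - 1.43), 2 * est$bin_width)
})

test_that("refined movies separate the two components almost completely", {
  geom <- make_geometry(16, seed = 4)
  p <- sim_params(breathing_duration = 30, apnea_duration = 5, noise_sd = 0,
                  seed = 21)
  rec <- simulate_recording(p, geom)
  sub <- subtract_reference(rec$movie)
  rs <- rough_split(sub, find_reference_region(sub))
  rates <- estimate_rates(rs$resp, rs$cardiac, 44)
  ref <- refine_movies(sub, rates)
  lung <- region_mask(geom$lung_mask, "lung")
  br <- segment_frames(sub, "breathing")
  band_power <- function(x, lo, hi) {
    pg <- periodogram_power(x, 44)
    sum(pg$power[pg$freq >= lo & pg$freq <= hi])
  }
  resp_tr <- region_trace(ref$resp, lung)[br]
  card_tr <- region_trace(ref$cardiac, lung)[br]
  # cardiac-band leakage in the respiratory movie and vice versa < 5%
  expect_lt(band_power(resp_tr, 0.8 * rates$f_HR, 2.6 * rates$f_HR),
            0.05 * band_power(resp_tr, 0, 22))
  expect_lt(band_power(card_tr, 0.5 * rates$f_RR, 1.5 * rates$f_RR),
            0.05 * band_power(card_tr, 0, 22))
})

test_that("the strict band keeps only the cardiac fundamental", {
  fs <- 44
  f_HR <- 1.2
  tt <- (0:(60 * fs - 1)) / fs
  pulse <- cos(2 * pi * f_HR * tt) + 0.5 * cos(2 * pi * 2 * f_HR * tt) +
    0.2 * cos(2 * pi * 3 * f_HR * tt)
  filt <- design_bandpass(band_spec(0.8 * f_HR, 1.2 * f_HR), fs,
                          n_samples = length(pulse))
  y <- apply_zero_phase(pulse, filt)
  pg <- periodogram_power(y[200:2400], fs)
  p_at <- function(f) max(pg$power[abs(pg$freq - f) < 0.1])
  expect_gt(10 * log10(p_at(f_HR) / p_at(2 * f_HR)), 20)
  expect_gt(10 * log10(p_at(f_HR) / p_at(3 * f_HR)), 20)
})

test_that("overlapping refined bands cap the respiratory upper edge", {
  rates <- feit:::rate_estimate(0.3, 1.5, 1, 1, FALSE, "none", 0.02)
  b <- refined_bands(rates, 44)
  expect_equal(b$resp$high, 0.9 * 0.5 * 1.5)  # capped below cardiac low edge
  expect_lt(b$resp$high, b$cardiac$low)
})
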