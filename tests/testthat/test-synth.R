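test_that("geometry regions are disjoint, inside the body, and big enough", {
  for (seed in c(0, 1, 9)) {
    g <- make_geometry(32, seed = seed)
    expect_false(any(g$lung_mask & g$heart_mask))
    expect_true(all(g$body_mask[g$lung_mask | g$heart_mask]))
    expect_gte(sum(g$heart_mask), 4)
    expect_gte(sum(g$left_lung_mask), 4)
    expect_gte(sum(g$right_lung_mask), 4)
  }
  g16 <- make_geometry(16, seed = 2)
  expect_false(any(g16$lung_mask & g16$heart_mask))
})

test_that("geometry is deterministic in the seed and rejects tiny grids", {
  a <- make_geometry(32, seed = 1)
  b <- make_geometry(32, seed = 1)
  expect_identical(a$lung_mask, b$lung_mask)
  expect_identical(a$heart_mask, b$heart_mask)
  expect_error(make_geometry(8), "at least 16")
})

test_that("simulation is bit-reproducible given the seed", {
  geom <- make_geometry(16, seed = 4)
  p <- sim_params(breathing_duration = 20, apnea_duration = 5, seed = 123)
  r1 <- simulate_recording(p, geom)
  r2 <- simulate_recording(p, geom)
  expect_identical(r1$movie$data, r2$movie$data)
  expect_identical(r1$flow$samples, r2$flow$samples)
  expect_identical(r1$truth$breaths, r2$truth$breaths)
})

test_that("noise-free constant-amplitude breaths have peak-to-trough 2*resp_amplitude", {
  geom <- make_geometry(16, seed = 4)
  p <- sim_params(breathing_duration = 20, apnea_duration = 5, noise_sd = 0,
                  rate_jitter_cv = 0, amplitude_jitter_cv = 0,
                  resp_amplitude = 1.3, seed = 1)
  r <- simulate_recording(p, geom)
  expect_true(all(abs(r$truth$breaths$amplitude - 2 * 1.3) < 1e-12))
  # on a (near) cardiac-free simulation the pixel trace itself shows it
  p0 <- sim_params(breathing_duration = 20, apnea_duration = 5, noise_sd = 0,
                   rate_jitter_cv = 0, amplitude_jitter_cv = 0,
                   resp_amplitude = 1.3, cardiac_amplitude = 1e-12, seed = 1)
  r0 <- simulate_recording(p0, geom)
  px <- which(geom$lung_mask)[1]
  tr0 <- movie_matrix(r0$movie)[, px]
  t_s <- (seq_along(tr0) - 1) / p0$fs
  for (i in c(1, 2)) {
    sel <- t_s >= r0$truth$breaths$start_s[i] & t_s < r0$truth$breaths$end_s[i]
    expect_equal(max(tr0[sel]) - min(tr0[sel]), 2 * 1.3, tolerance = 1e-3)
  }
})

test_that("a 180 degree phase shift is a half-period delay of the heart trace", {
  geom <- make_geometry(16, seed = 4)
  # f_HR chosen so the delay is an integer number of frames (20)
  p <- sim_params(breathing_duration = 20, apnea_duration = 5, noise_sd = 0,
                  rate_jitter_cv = 0, amplitude_jitter_cv = 0,
                  f_HR = 1.1, heart_phase_shift = 180, seed = 1)
  r <- simulate_recording(p, geom)
  m <- movie_matrix(r$movie)
  heart_px <- which(geom$heart_mask)[1]
  lung_px <- which(geom$lung_mask)[1]
  ap <- segment_frames(r$movie, "apnea")
  heart <- m[ap, heart_px]
  lung_cardiac <- m[ap, lung_px]        # apnea: cardiac only
  shift <- 20                            # 0.5 / 1.1 Hz * 44 Hz
  n <- length(ap)
  expect_equal(heart[(shift + 1):n],
               p$heart_amplitude_factor * lung_cardiac[1:(n - shift)],
               tolerance = 1e-10)
})

test_that("the generated spectrum peaks at the true rates (direct spectral oracle)", {
  d <- default_rec()
  br <- segment_frames(d$rec$movie, "breathing")
  lung_trace <- region_trace(d$rec$movie, d$geom$lung_mask)[br]
  pg <- periodogram_power(lung_trace, d$rec$movie$fs)
  resp_sel <- pg$freq > 0.05 & pg$freq < 0.6
  f_resp <- pg$freq[resp_sel][which.max(pg$power[resp_sel])]
  card_sel <- pg$freq > 0.8 & pg$freq < 2
  f_card <- pg$freq[card_sel][which.max(pg$power[card_sel])]
  expect_lt(abs(f_resp - d$rec$truth$true_f_RR), pg$bin)
  expect_lt(abs(f_card - d$rec$truth$true_f_HR), pg$bin)
})

test_that("respiratory-band power nearly vanishes during apnea", {
  d <- default_rec()
  movie <- d$rec$movie
  trace <- region_trace(movie, d$geom$lung_mask)
  filt <- design_bandpass(band_spec(0.125, 0.625), movie$fs,
                          n_samples = length(trace))
  resp <- apply_zero_phase(trace - mean(trace), filt)
  br <- segment_frames(movie, "breathing")
  ap <- segment_frames(movie, "apnea")
  # drop a transition zone of one breath around the apnea onset
  guard <- round(movie$fs / 0.2)
  expect_lt(var(resp[ap[-seq_len(guard)]]),
            0.1 * var(resp[br[seq_len(length(br) - guard)]]))
})

test_that("per-breath flow integrals recover the tidal volumes to 0.5%", {
  d <- default_rec()
  vol <- integrate_flow(d$rec$flow)
  t_s <- (seq_along(vol) - 1) / d$rec$flow$fs
  br <- d$rec$truth$breaths
  for (i in seq_len(nrow(br))) {
    sel <- t_s >= br$start_s[i] & t_s < br$end_s[i]
    vt <- max(vol[sel]) - min(vol[sel])
    expect_equal(vt, br$tidal_volume[i], tolerance = 0.005)
  }
})

test_that("simulation rejects a breathing segment with fewer than 3 breaths", {
  geom <- make_geometry(16, seed = 4)
  p <- sim_params(breathing_duration = 8, apnea_duration = 5, f_RR = 0.25,
                  seed = 1)
  expect_error(simulate_recording(p, geom), "3 full respiratory cycles")
})

test_that("parameter invariants are enforced", {
  expect_error(sim_params(f_HR = 10), "Nyquist|exceed")
  expect_error(sim_params(cardiac_amplitude = 2), "smaller than")
  expect_error(sim_params(heart_phase_shift = 90), "150")
  expect_error(sim_params(apnea_duration = 0), "positive")
})

test_that("point-spread blur preserves the frame mean and spreads signal", {
  geom <- make_geometry(16, seed = 4)
  p0 <- sim_params(breathing_duration = 20, apnea_duration = 5, noise_sd = 0,
                   seed = 9, psf_sigma = 0)
  p1 <- sim_params(breathing_duration = 20, apnea_duration = 5, noise_sd = 0,
                   seed = 9, psf_sigma = 1)
  r0 <- simulate_recording(p0, geom)
  r1 <- simulate_recording(p1, geom)
  f0 <- r0$movie$data[200, , ]
  f1 <- r1$movie$data[200, , ]
  # edge renormalisation makes mean preservation approximate
  expect_equal(mean(f1), mean(f0), tolerance = 0.01)
  outside <- !geom$lung_mask & !geom$heart_mask
  expect_gt(sum(abs(f1[outside])), sum(abs(f0[outside])))
})
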