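# Shared fixtures, computed lazily and cached for the whole test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# default-geometry recording with default parameters (45 s + 15 s @ 44 Hz)
default_rec <- function() {
  fixture("default_rec", {
    geom <- make_geometry(32, seed = 1)
    list(geom = geom, rec = simulate_recording(sim_params(seed = 42), geom))
  })
}

# a noise- and jitter-free recording (deterministic waveforms)
clean_rec <- function() {
  fixture("clean_rec", {
    geom <- make_geometry(32, seed = 1)
    p <- sim_params(noise_sd = 0, rate_jitter_cv = 0, amplitude_jitter_cv = 0,
                    seed = 7)
    list(geom = geom, rec = simulate_recording(p, geom))
  })
}

# small, fast recording for pipeline round trips (16 px grid, short)
small_rec <- function(seed = 3, position = "upright", replicate = 1,
                      subject_id = "S01", ...) {
  geom <- make_geometry(16, seed = 5)
  p <- sim_params(breathing_duration = 22, apnea_duration = 5,
                  seed = seed, position = position, replicate = replicate,
                  subject_id = subject_id, ...)
  c(list(geom = geom), simulate_recording(p, geom))
}

# circular absolute difference of two angles in degrees
circ_abs_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# lag (in samples) of the maximum of the cross-correlation of x and y,
# searched over +/- max_lag; positive lag means y lags x
xcorr_peak_lag <- function(x, y, max_lag) {
  n <- length(x)
  lags <- (-max_lag):max_lag
  cc <- vapply(lags, function(l) {
    if (l >= 0) sum(x[seq_len(n - l)] * y[(1 + l):n])
    else sum(x[(1 - l):n] * y[seq_len(n + l)])
  }, numeric(1))
  lags[which.max(cc)]
}

# build a small cardiac-domain movie with prescribed per-pixel delays (deg)
delay_movie <- function(delays_deg, f_HR = 1.1, fs = 44, dur = 30,
                        noise_sd = 0.01, seed = 1) {
  set.seed(seed)
  tt <- (0:(dur * fs - 1)) / fs
  g <- 12
  n_px <- length(delays_deg)
  stopifnot(n_px + 5 <= g * g - 2 * g)
  base <- array(rnorm(length(tt) * g * g, sd = noise_sd),
                dim = c(length(tt), g, g))
  wave <- function(d_deg) {
    tau <- (d_deg / 360) / f_HR
    cos(2 * pi * f_HR * (tt - tau)) + 0.3 * cos(4 * pi * f_HR * (tt - tau))
  }
  refmask <- matrix(FALSE, g, g)
  refmask[2, 2] <- refmask[1, 2] <- refmask[3, 2] <- refmask[2, 1] <-
    refmask[2, 3] <- TRUE
  for (px in which(refmask)) {
    rc <- arrayInd(px, c(g, g))
    base[, rc[1], rc[2]] <- base[, rc[1], rc[2]] + wave(0)
  }
  free <- setdiff(seq_len(g * g), c(which(refmask), 1:(2 * g)))
  px_at <- free[seq_len(n_px)]
  for (i in seq_len(n_px)) {
    rc <- arrayInd(px_at[i], c(g, g))
    base[, rc[1], rc[2]] <- base[, rc[1], rc[2]] + wave(delays_deg[i])
  }
  segs <- data.frame(label = "breathing", start = 0L, end = length(tt))
  list(movie = pixel_movie(base, fs = fs, segments = segs),
       reference = region_mask(refmask, "reference"),
       pixels = px_at)
}

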