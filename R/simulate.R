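#' Simulation parameters for a synthetic EIT recording
#'
#' Defaults reproduce the acquisition conditions the pipeline targets:
#' 44 Hz frame rate, ~45 s of spontaneous breathing followed by ~15 s of
#' apnea, a respiratory rate of 15 bpm, a heart rate of 69 bpm (4.6 times
#' the breathing rate, i.e. halfway between respiratory harmonics, the
#' non-degenerate case; rate-locked subjects need the manual override the
#' analysis provides), and a
#' cardiac impedance amplitude one order of magnitude below the
#' respiratory amplitude. The heart-region cardiac waveform is a pure time
#' delay of the lung cardiac waveform, with the delay expressed as a phase
#' shift of the cardiac fundamental (150-180 degrees).
#'
#' @param fs frame rate in Hz.
#' @param breathing_duration,apnea_duration segment durations in seconds.
#' @param f_RR,f_HR nominal respiratory and heart rates in Hz.
#' @param resp_amplitude respiratory impedance amplitude (arbitrary units);
#'   the per-breath peak-to-trough excursion of a lung pixel is
#'   `2 * resp_amplitude`.
#' @param cardiac_amplitude cardiac impedance amplitude in the lung
#'   (default `resp_amplitude / 10`); per-beat peak-to-trough is
#'   `2 * cardiac_amplitude`.
#' @param heart_amplitude_factor ratio of heart-region to lung-region
#'   cardiac amplitude (default 2: the heart signal dominates locally).
#' @param heart_phase_shift phase shift of the heart-region cardiac signal
#'   relative to the lung, in degrees within `[150, 180]`.
#' @param noise_sd standard deviation of additive white pixel noise
#'   (arbitrary units). See [noise_sd_for_snr()].
#' @param rate_jitter_cv coefficient of variation of breath and beat
#'   periods (default 3%).
#' @param amplitude_jitter_cv coefficient of variation of per-breath and
#'   per-beat amplitudes (default 3%).
#' @param psf_sigma isotropic Gaussian blur applied to each frame, in
#'   pixels; 0 disables blurring.
#' @param tidal_volume nominal tidal volume in litres; per-breath tidal
#'   volumes co-vary with the respiratory amplitude jitter.
#' @param position,subject_id,replicate recording metadata.
#' @param seed integer seed; the simulation is bit-reproducible given the
#'   seed.
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(fs = 44, breathing_duration = 45, apnea_duration = 15,
                       f_RR = 0.25, f_HR = 1.15,
                       resp_amplitude = 1,
                       cardiac_amplitude = resp_amplitude / 10,
                       heart_amplitude_factor = 2,
                       heart_phase_shift = 165,
                       noise_sd = 0.01,
                       rate_jitter_cv = 0.03, amplitude_jitter_cv = 0.03,
                       psf_sigma = 0, tidal_volume = 0.5,
                       position = "upright", subject_id = "S01",
                       replicate = 1L, seed = 1L) {
  p <- list(fs = fs, breathing_duration = breathing_duration,
            apnea_duration = apnea_duration, f_RR = f_RR, f_HR = f_HR,
            resp_amplitude = resp_amplitude,
            cardiac_amplitude = cardiac_amplitude,
            heart_amplitude_factor = heart_amplitude_factor,
            heart_phase_shift = heart_phase_shift, noise_sd = noise_sd,
            rate_jitter_cv = rate_jitter_cv,
            amplitude_jitter_cv = amplitude_jitter_cv,
            psf_sigma = psf_sigma, tidal_volume = tidal_volume,
            position = match.arg(position, POSITIONS),
            subject_id = subject_id, replicate = as.integer(replicate),
            seed = as.integer(seed))
  if (p$fs <= 2 * (2.5 * p$f_HR))
    stop("fs must exceed twice the refined cardiac band edge (2 * 2.5 * f_HR)")
  if (p$cardiac_amplitude >= p$resp_amplitude)
    stop("cardiac_amplitude must be smaller than resp_amplitude")
  if (p$heart_phase_shift < 150 || p$heart_phase_shift > 180)
    stop("heart_phase_shift must lie in [150, 180] degrees")
  if (p$breathing_duration <= 0 || p$apnea_duration <= 0)
    stop("durations must be positive")
  if (p$f_RR <= 0 || p$f_HR <= p$f_RR)
    stop("rates must satisfy 0 < f_RR < f_HR")
  if (p$noise_sd < 0 || p$psf_sigma < 0 || p$tidal_volume <= 0)
    stop("noise_sd and psf_sigma must be >= 0, tidal_volume > 0")
  class(p) <- "sim_params"
  p
}

#' Noise level giving a target respiratory signal-to-noise ratio
#'
#' The per-pixel respiratory component `a * (1 - cos)` has variance
#' `a^2 / 2`; this returns the white-noise standard deviation that sets
#' `10 log10(signal var / noise var)` to `snr_db`.
#'
#' @param snr_db target SNR in dB.
#' @param resp_amplitude respiratory amplitude `a`.
#' @return noise standard deviation.
#' @export
noise_sd_for_snr <- function(snr_db, resp_amplitude = 1) {
  sqrt(resp_amplitude^2 / 2 / 10^(snr_db / 10))
}

# Multi-harmonic cardiac waveform, unit peak-to-trough amplitude 1 (i.e.
# peak-to-trough 2 after multiplying by a per-beat amplitude). Harmonic
# weights (1, 0.5, 0.2) decay the way pulsatile impedance waveforms do;
# the 3rd harmonic lies outside the refined cardiac pass-band [0.5, 2.5]*f,
# which is what makes the strict/loose filter comparison non-trivial.
CARDIAC_HARMONICS <- c(1, 0.5, 0.2)

cardiac_waveform <- function(phase) {
  w <- CARDIAC_HARMONICS[1] * cos(2 * pi * phase) +
    CARDIAC_HARMONICS[2] * cos(4 * pi * phase) +
    CARDIAC_HARMONICS[3] * cos(6 * pi * phase)
  # peak-to-trough of the raw sum is 2.4; rescale to exactly 2
  w / 1.2
}

# Draw jittered cycle periods covering [t0, t1]; returns boundary vector.
draw_periods <- function(t0, t1, nominal_period, cv) {
  bounds <- t0
  while (tail(bounds, 1L) < t1) {
    z <- max(-3, min(3, rnorm(1)))
    bounds <- c(bounds, tail(bounds, 1L) + nominal_period * (1 + cv * z))
  }
  bounds
}

#' Simulate one EIT recording with ground truth
#'
#' Generates a pixel movie, a synchronized spirometric flow trace and a
#' ground-truth record. Lung pixels carry a raised-cosine respiratory
#' component (breathing segment only) plus a multi-harmonic cardiac
#' component; heart pixels carry the cardiac waveform delayed by
#' `heart_phase_shift` (expressed as a time delay at the cardiac
#' fundamental period) with `heart_amplitude_factor` times the lung
#' cardiac amplitude; all pixels receive additive white noise, and each
#' frame can optionally be blurred with an isotropic Gaussian point-spread
#' function to emulate reconstruction smoothing. The flow trace is the
#' analytic time derivative of a per-breath raised-cosine volume curve
#' whose excursion equals the (jittered) tidal volume.
#'
#' @param params a [sim_params()] object.
#' @param geometry a [make_geometry()] object.
#' @return list with elements `movie` ([pixel_movie()]), `flow`
#'   ([flow_trace()]) and `truth` (ground-truth record: realized rates,
#'   per-breath and per-beat tables, per-cycle amplitude lists, the
#'   geometry and the phase shift).
#' @export
simulate_recording <- function(params, geometry) {
  stopifnot(inherits(params, "sim_params"), inherits(geometry, "thorax_geometry"))
  p <- params
  restore <- save_rng(); on.exit(restore())
  set.seed(p$seed)

  fs <- p$fs
  nb <- round(p$breathing_duration * fs)
  N <- nb + round(p$apnea_duration * fs)
  t <- (seq_len(N) - 1) / fs
  total_dur <- N / fs

  ## ---- breaths (breathing segment only, complete breaths + end pause) ----
  all_bounds <- draw_periods(0, p$breathing_duration, 1 / p$f_RR, p$rate_jitter_cv)
  # keep only breaths that fit completely before the apnea onset
  breath_bounds <- all_bounds[all_bounds <= p$breathing_duration + 1e-9]
  n_breaths <- length(breath_bounds) - 1L
  if (n_breaths < 3L)
    stop("breathing segment holds fewer than 3 full respiratory cycles; lengthen it or raise f_RR")
  breath_T <- diff(breath_bounds)
  zb <- pmax(-3, pmin(3, rnorm(n_breaths)))
  breath_amp <- p$resp_amplitude * (1 + p$amplitude_jitter_cv * zb)
  breath_vt <- p$tidal_volume * breath_amp / p$resp_amplitude

  resp <- numeric(N); vol <- numeric(N); flow <- numeric(N)
  k <- findInterval(t, breath_bounds, rightmost.closed = FALSE)
  in_breath <- k >= 1L & k <= n_breaths & t < breath_bounds[n_breaths + 1L]
  kk <- k[in_breath]
  tau <- (t[in_breath] - breath_bounds[kk]) / breath_T[kk]
  resp[in_breath] <- breath_amp[kk] * (1 - cos(2 * pi * tau))
  vol[in_breath] <- breath_vt[kk] * 0.5 * (1 - cos(2 * pi * tau))
  flow[in_breath] <- breath_vt[kk] * 0.5 * (2 * pi / breath_T[kk]) * sin(2 * pi * tau)

  ## ---- beats (whole recording, extended margin for the heart delay) ----
  margin <- 2 / p$f_HR
  beat_bounds <- draw_periods(-margin, total_dur + margin, 1 / p$f_HR,
                              p$rate_jitter_cv)
  n_beats <- length(beat_bounds) - 1L
  beat_T <- diff(beat_bounds)
  za <- pmax(-3, pmin(3, rnorm(n_beats)))
  beat_amp <- p$cardiac_amplitude * (1 + p$amplitude_jitter_cv * za)

  cardiac_at <- function(tv) {
    j <- findInterval(tv, beat_bounds, rightmost.closed = FALSE)
    j <- pmax(1L, pmin(n_beats, j))
    phase <- (tv - beat_bounds[j]) / beat_T[j]
    beat_amp[j] * cardiac_waveform(phase)
  }
  delay <- (p$heart_phase_shift / 360) / p$f_HR
  cardiac_lung <- cardiac_at(t)
  cardiac_heart <- p$heart_amplitude_factor * cardiac_at(t - delay)

  ## ---- assemble movie ----
  g <- geometry$grid_size
  movie_mat <- if (p$noise_sd > 0)
    matrix(rnorm(N * g * g, sd = p$noise_sd), N) else matrix(0, N, g * g)
  lung_px <- which(as.vector(geometry$lung_mask))
  heart_px <- which(as.vector(geometry$heart_mask))
  movie_mat[, lung_px] <- movie_mat[, lung_px] + (resp + cardiac_lung)
  movie_mat[, heart_px] <- movie_mat[, heart_px] + cardiac_heart
  if (p$psf_sigma > 0)
    movie_mat <- movie_mat %*% t(psf_matrix(g, p$psf_sigma))

  segs <- data.frame(label = c("breathing", "apnea"),
                     start = c(0L, nb), end = c(nb, N))
  movie <- pixel_movie(array(movie_mat, dim = c(N, g, g)), fs = fs,
                       position = p$position, subject_id = p$subject_id,
                       replicate = p$replicate, segments = segs)

  ## ---- ground truth ----
  in_rec <- beat_bounds[-length(beat_bounds)] >= 0 &
    beat_bounds[-1L] <= total_dur + 1e-9
  beats <- data.frame(start_s = beat_bounds[-length(beat_bounds)][in_rec],
                      end_s = beat_bounds[-1L][in_rec],
                      amplitude = 2 * beat_amp[in_rec])
  beats$segment <- ifelse(beats$end_s <= nb / fs + 1e-9, "breathing",
                          ifelse(beats$start_s >= nb / fs - 1e-9, "apnea",
                                 "boundary"))
  breaths <- data.frame(start_s = breath_bounds[-length(breath_bounds)],
                        end_s = breath_bounds[-1L],
                        amplitude = 2 * breath_amp,
                        tidal_volume = breath_vt)
  truth <- list(
    geometry = geometry,
    true_f_RR = 1 / mean(breath_T),
    true_f_HR = 1 / mean(beat_T),
    breaths = breaths, beats = beats,
    true_resp_amplitude_per_cycle = breaths$amplitude,
    true_cardiac_amplitude_per_cycle = beats$amplitude,
    true_tidal_volumes = breaths$tidal_volume,
    true_heart_phase_shift = p$heart_phase_shift,
    params = p
  )
  list(movie = movie, flow = flow_trace(flow, fs), truth = truth)
}

# (K %x% K) row-normalised truncated-Gaussian blur operator for a g x g
# frame, acting on column-major pixel vectors.
psf_matrix <- function(g, sigma) {
  idx <- seq_len(g)
  K <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
  K[K < 1e-8] <- 0
  K <- K / rowSums(K)
  kronecker(K, K)
}
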