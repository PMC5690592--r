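#' Frequency band specification
#'
#' @param low,high band edges in Hz, `0 < low < high`.
#' @return object of class `band_spec`.
#' @export
band_spec <- function(low, high) {
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || high <= low)
    stop("band edges must satisfy 0 < low < high")
  structure(list(low = low, high = high), class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %.4g-%.4g Hz (%.1f-%.1f bpm)\n",
              x$low, x$high, 60 * x$low, 60 * x$high))
  invisible(x)
}

#' Rough separation bands
#'
#' The fixed first-stage bands: 2-40 bpm for respiration and 40-400 bpm
#' for cardiac activity, the cardiac upper edge capped at 95% of the
#' Nyquist frequency.
#'
#' @param fs sampling rate in Hz.
#' @return list with `band_spec` elements `resp` and `cardiac`.
#' @export
rough_bands <- function(fs) {
  list(resp = band_spec(2 / 60, 40 / 60),
       cardiac = band_spec(40 / 60, min(400 / 60, 0.95 * fs / 2)))
}

#' FIR band-pass order for a band
#'
#' Windowed-sinc (Hamming) design rule: the transition width is 30% of the
#' lower band edge and the order is the smallest even integer >=
#' `3.3 * fs / transition_width`. When `n_samples` is given the order is
#' capped so that the filter remains applicable by [apply_zero_phase()]
#' (signal longer than 3 filter lengths), trading low-edge roll-off for
#' record length.
#'
#' @param band a [band_spec()].
#' @param fs sampling rate in Hz.
#' @param n_samples optional record length used to cap the order.
#' @return even integer filter order (number of taps minus one).
#' @export
bandpass_order <- function(band, fs, n_samples = NULL) {
  tw <- 0.3 * band$low
  ord <- ceiling(3.3 * fs / tw)
  ord <- ord + ord %% 2L
  if (!is.null(n_samples)) {
    max_taps <- floor((n_samples - 1) / 3)
    max_ord <- max_taps - 1L
    max_ord <- max_ord - max_ord %% 2L
    if (max_ord < 16L)
      stop("record too short to design a band-pass filter (need > ~51 samples)")
    ord <- min(ord, max_ord)
  }
  as.integer(ord)
}

#' Design a linear-phase FIR band-pass filter
#'
#' Hamming-windowed sinc design via [signal::fir1()]. The -6 dB cutoffs
#' are placed half a transition width outside the nominal band so that
#' `[low, high]` is flat pass-band; applied forward-backward the filter
#' then preserves in-band amplitudes and achieves >= 40 dB stop-band
#' attenuation at `0.5 * low` and `1.5 * high` (at the uncapped design
#' order).
#'
#' @param band a [band_spec()]; must satisfy `high < fs / 2`.
#' @param fs sampling rate in Hz.
#' @param order filter order; defaults to [bandpass_order()] (optionally
#'   capped via `n_samples`).
#' @param n_samples optional record length used to cap the default order.
#' @return object of class `fir_filter`: coefficients `coef` plus design
#'   metadata.
#' @export
design_bandpass <- function(band, fs, order = NULL, n_samples = NULL) {
  stopifnot(inherits(band, "band_spec"))
  if (band$high >= fs / 2)
    stop(sprintf("band edge %.4g Hz reaches or exceeds the Nyquist frequency %.4g Hz",
                 band$high, fs / 2))
  if (is.null(order)) order <- bandpass_order(band, fs, n_samples)
  tw <- 0.3 * band$low
  lo_c <- band$low - tw / 2
  hi_c <- min(band$high + tw / 2, (band$high + fs / 2) / 2)
  h <- signal::fir1(order, c(lo_c, hi_c) / (fs / 2), type = "pass")
  structure(list(coef = as.numeric(h), band = band, fs = fs,
                 order = as.integer(order), transition_width = tw,
                 cutoffs = c(lo_c, hi_c)),
            class = "fir_filter")
}

#' @export
print.fir_filter <- function(x, ...) {
  cat(sprintf("<fir_filter> pass-band %.4g-%.4g Hz @ %g Hz, order %d (%d taps)\n",
              x$band$low, x$band$high, x$fs, x$order, length(x$coef)))
  invisible(x)
}

#' Frequency response of an FIR filter
#'
#' @param filt a [fir_filter()] or coefficient vector.
#' @param freqs frequencies in Hz.
#' @param fs sampling rate (taken from `filt` when available).
#' @param zero_phase if `TRUE` return the forward-backward magnitude
#'   `|H|^2` instead of the single-pass complex response.
#' @return complex response, or numeric magnitude when `zero_phase`.
#' @export
filter_response <- function(filt, freqs, fs = NULL, zero_phase = FALSE) {
  if (inherits(filt, "fir_filter")) {
    fs <- filt$fs
    h <- filt$coef
  } else h <- as.numeric(filt)
  if (is.null(fs)) stop("`fs` required for a bare coefficient vector")
  k <- seq_along(h) - 1
  H <- vapply(freqs, function(f) sum(h * exp(-2i * pi * f * k / fs)),
              complex(1))
  if (zero_phase) Mod(H)^2 else H
}

#' Apply an FIR filter with zero phase (forward-backward)
#'
#' Equivalent to filtering forward and backward: the effective impulse
#' response is the autocorrelation of the filter taps, which is symmetric,
#' so the output has zero group delay at every frequency. Edges are
#' handled by odd-reflection padding of one filter length at each end; the
#' convolution is evaluated by FFT.
#'
#' @param x numeric vector, or matrix with one signal per column.
#' @param filt a [fir_filter()] or FIR coefficient vector.
#' @return filtered signal(s), same shape as `x`.
#' @export
apply_zero_phase <- function(x, filt) {
  h <- if (inherits(filt, "fir_filter")) filt$coef else as.numeric(filt)
  taps <- length(h)
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1L) else x
  N <- nrow(X)
  if (N <= 3L * taps)
    stop(sprintf("signal length (%d) must exceed 3 x the filter length (%d taps): need more than %d samples",
                 N, taps, 3L * taps))
  p <- taps
  top <- 2 * X[rep(1L, p), , drop = FALSE] - X[(p + 1L):2L, , drop = FALSE]
  bottom <- 2 * X[rep(N, p), , drop = FALSE] -
    X[(N - 1L):(N - p), , drop = FALSE]
  XP <- rbind(top, X, bottom)
  M <- N + 2L * p

  # symmetric zero-phase kernel: autocorrelation of the taps
  nh <- 2L^ceiling(log2(2L * taps))
  Hf <- fft(c(h, numeric(nh - taps)))
  ac <- Re(fft(Hf * Conj(Hf), inverse = TRUE)) / nh
  g <- c(rev(ac[2:taps]), ac[1:taps])        # lags -(taps-1) .. (taps-1)

  nf <- fast_fft_size(M + 2L * taps)
  G <- fft(c(g, numeric(nf - length(g))))
  XF <- mvfft(rbind(XP, matrix(0, nf - M, ncol(XP))))
  Y <- Re(mvfft(XF * G, inverse = TRUE)) / nf
  out <- Y[(taps - 1L + p) + seq_len(N), , drop = FALSE]
  if (vec) out[, 1L] else out
}

# smallest FFT length >= n of the form 2^a, 3*2^a or 5*2^a
fast_fft_size <- function(n) {
  cand <- c(2^ceiling(log2(n)),
            3 * 2^ceiling(log2(n / 3)),
            5 * 2^ceiling(log2(n / 5)))
  as.integer(min(cand[cand >= n]))
}

#' Rough band split of a region trace
#'
#' Mean signal over a region during the breathing segment, band-passed
#' with the fixed rough respiratory (2-40 bpm) and cardiac (40-400 bpm,
#' capped below Nyquist) bands. Filter orders are capped by the record
#' length.
#'
#' @param movie a [pixel_movie()] with a breathing segment (already
#'   reference-subtracted).
#' @param region a [region_mask()] or binary matrix; must be non-empty.
#' @return list with elements `resp`, `cardiac` (numeric traces) and `fs`.
#' @export
rough_split <- function(movie, region) {
  fr <- segment_frames(movie, "breathing")
  if (is.null(fr)) stop("movie has no breathing segment")
  trace <- region_trace(movie, region)[fr]
  trace <- trace - mean(trace)
  bands <- rough_bands(movie$fs)
  n <- length(trace)
  list(resp = apply_zero_phase(trace, design_bandpass(bands$resp, movie$fs,
                                                      n_samples = n)),
       cardiac = apply_zero_phase(trace, design_bandpass(bands$cardiac,
                                                         movie$fs,
                                                         n_samples = n)),
       fs = movie$fs)
}

#' Periodogram power spectrum
#'
#' Rectangular window on the linearly detrended signal, zero-padded to at
#' least 4x the record length (rounded to a power of two) for peak
#' localisation. The physical frequency resolution of the record,
#' `fs / n`, is reported as `bin`.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param pad_factor zero-padding factor (default 4).
#' @return list with `freq`, `power` and `bin`.
#' @export
periodogram_power <- function(x, fs, pad_factor = 4) {
  n <- length(x)
  tt <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, tt), x)
  xd <- fit$residuals
  nfft <- 2L^ceiling(log2(pad_factor * n))
  X <- fft(c(xd, numeric(nfft - n)))
  half <- seq_len(nfft %/% 2 + 1L)
  list(freq = (half - 1) * fs / nfft,
       power = Mod(X[half])^2 / n,
       bin = fs / n)
}

#' Estimate respiratory and heart rates from rough-filtered traces
#'
#' The rates are the frequencies of the maximal periodogram peaks within
#' the rough respiratory and cardiac bands. A peak is only accepted if it
#' exceeds 15x the mean in-band periodogram power (the noise floor: white
#' noise peaks at roughly log(m) times the in-band mean). A
#' harmonic conflict is flagged when the cardiac peak lies within one
#' frequency-resolution bin (`fs / n`) of an integer multiple (>= 2) of
#' the respiratory rate; the estimate then moves to the strongest
#' non-harmonic cardiac peak if that peak retains at least 50% of the
#' maximal power, and is otherwise left unresolved (manual override
#' required downstream).
#'
#' @param resp_signal,cardiac_signal rough-filtered traces from
#'   [rough_split()], at least 20 s long.
#' @param fs sampling rate in Hz.
#' @param bands rough bands (default [rough_bands()]).
#' @return a `rate_estimate` object.
#' @export
estimate_rates <- function(resp_signal, cardiac_signal, fs,
                           bands = rough_bands(fs)) {
  if (length(resp_signal) < 20 * fs || length(cardiac_signal) < 20 * fs)
    stop("rate estimation needs at least 20 s of signal")

  peak_in_band <- function(x, band, what) {
    pg <- periodogram_power(x, fs)
    sel <- pg$freq >= band$low & pg$freq <= band$high
    pw <- pg$power[sel]; fq <- pg$freq[sel]
    i <- which.max(pw)
    # noise floor: mean in-band power away from the peak's neighbourhood
    # (+/- 2 resolution bins). White-noise maxima reach ~log(m) times
    # that floor; a coherent oscillation sits orders of magnitude higher.
    away <- abs(fq - fq[i]) > 2 * pg$bin
    floor_pw <- if (any(away)) mean(pw[away]) else median(pw)
    if (pw[i] < 30 * floor_pw)
      stop(sprintf("no clear spectral peak above the noise floor in the %s band (%.3g-%.3g Hz)",
                   what, band$low, band$high))
    list(f = fq[i], power = pw[i], freq = fq, pw = pw, bin = pg$bin)
  }
  rp <- peak_in_band(resp_signal, bands$resp, "respiratory")
  cp <- peak_in_band(cardiac_signal, bands$cardiac, "cardiac")
  bin <- cp$bin

  f_RR <- rp$f; f_HR <- cp$f
  ks <- 2:max(2L, floor(bands$cardiac$high / f_RR))
  conflict <- any(abs(f_HR - ks * f_RR) < bin)
  resolution <- "none"
  if (conflict) {
    pw <- cp$pw; fq <- cp$freq; m <- length(pw)
    is_peak <- c(FALSE, pw[2:(m - 1)] > pw[1:(m - 2)] &
                   pw[2:(m - 1)] >= pw[3:m], FALSE)
    cand <- which(is_peak)
    harmonic <- vapply(fq[cand], function(f)
      any(abs(f - ks * f_RR) < bin), logical(1))
    cand <- cand[!harmonic]
    if (length(cand) && max(pw[cand]) >= 0.5 * cp$power) {
      i <- cand[which.max(pw[cand])]
      f_HR <- fq[i]
      resolution <- "next_peak"
      cp$power <- pw[i]
    } else {
      resolution <- "unresolved"
    }
  }
  rate_estimate(f_RR = f_RR, f_HR = f_HR, resp_peak_power = rp$power,
                cardiac_peak_power = cp$power, harmonic_conflict = conflict,
                conflict_resolution = resolution, bin_width = bin)
}

#' Refined pass-bands derived from the detected rates
#'
#' `[0.5, 2.5] * f_RR` for respiration, `[0.5, 2.5] * f_HR` for the
#' cardiac domain and `[0.8, 1.2] * f_HR` for the strict cardiac domain.
#' When the respiratory band would overlap the cardiac band, its upper
#' edge is capped at 90% of the cardiac lower edge.
#'
#' @param rates a `rate_estimate`.
#' @param fs sampling rate in Hz.
#' @return list of [band_spec()]: `resp`, `cardiac`, `cardiac_strict`.
#' @export
refined_bands <- function(rates, fs) {
  if (2.5 * rates$f_HR >= fs / 2)
    stop("refined cardiac band exceeds the Nyquist frequency")
  resp_hi <- 2.5 * rates$f_RR
  card_lo <- 0.5 * rates$f_HR
  if (resp_hi >= card_lo) resp_hi <- 0.9 * card_lo
  list(resp = band_spec(0.5 * rates$f_RR, resp_hi),
       cardiac = band_spec(0.5 * rates$f_HR, 2.5 * rates$f_HR),
       cardiac_strict = band_spec(0.8 * rates$f_HR, 1.2 * rates$f_HR))
}

#' Refined band-pass filtering of every pixel trace
#'
#' Produces the three filtered movies of the separation stage: the
#' respiratory-domain movie, the cardiac-domain movie and the strictly
#' filtered cardiac movie. Every pixel time trace is filtered with
#' [apply_zero_phase()]; filter orders are capped by the record length.
#'
#' @param movie a reference-subtracted [pixel_movie()].
#' @param rates a `rate_estimate`; an unresolved harmonic conflict is an
#'   error (supply a manual rate override instead).
#' @param bands which of the three movies to compute (default all).
#' @return list of [pixel_movie()]s: `resp`, `cardiac`, `cardiac_strict`
#'   (or the requested subset).
#' @export
refine_movies <- function(movie, rates,
                          bands = c("resp", "cardiac", "cardiac_strict")) {
  check_rates(rates)
  bands <- refined_bands(rates, movie$fs)[match.arg(bands, several.ok = TRUE)]
  N <- n_frames(movie)
  m <- movie_matrix(movie)
  out <- lapply(bands, function(b) {
    filt <- design_bandpass(b, movie$fs, n_samples = N)
    fm <- movie
    fm$data <- array(apply_zero_phase(m, filt), dim = dim(movie$data))
    fm
  })
  names(out) <- names(bands)
  out
}

#' Refined band-pass filtering of a single trace
#'
#' Same bands and filters as [refine_movies()], applied to one signal.
#' Because the filters are linear, filtering the mean trace of a region
#' is exactly the mean of the region's filtered pixel traces.
#'
#' @param trace numeric signal.
#' @param rates a `rate_estimate`.
#' @param fs sampling rate in Hz.
#' @return list of numeric traces `resp`, `cardiac`, `cardiac_strict`.
#' @export
refine_traces <- function(trace, rates, fs) {
  check_rates(rates)
  bands <- refined_bands(rates, fs)
  n <- length(trace)
  lapply(bands, function(b)
    apply_zero_phase(trace, design_bandpass(b, fs, n_samples = n)))
}

check_rates <- function(rates) {
  stopifnot(inherits(rates, "rate_estimate"))
  if (identical(rates$conflict_resolution, "unresolved"))
    stop("harmonic conflict between f_HR and f_RR is unresolved; inspect the spectra and supply a manual rate override")
  invisible(rates)
}
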