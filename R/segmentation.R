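#' Find the cross-correlation reference region
#'
#' The pixel with the highest temporal standard deviation of the
#' respiratory-domain filtered movie lies, with high probability, inside
#' the lung; that pixel and its in-grid 4-connected neighbours form the
#' reference region whose cardiac-domain mean trace anchors the phase
#' map. Ties are broken in row-major order (first occurrence).
#'
#' @param resp_movie respiratory-domain filtered [pixel_movie()].
#' @return a [region_mask()] of kind `"reference"` (up to 5 pixels).
#' @export
find_reference_region <- function(resp_movie) {
  d <- dim(resp_movie$data)
  sds <- pixel_sd(resp_movie)
  mx <- max(sds)
  if (mx == 0) stop("movie is identically zero; cannot locate a reference region")
  cand <- which(sds == mx, arr.ind = TRUE)
  cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]  # row-major
  r <- cand[1L, 1L]; cl <- cand[1L, 2L]
  mask <- matrix(FALSE, d[2L], d[3L])
  mask[r, cl] <- TRUE
  if (r > 1L) mask[r - 1L, cl] <- TRUE
  if (r < d[2L]) mask[r + 1L, cl] <- TRUE
  if (cl > 1L) mask[r, cl - 1L] <- TRUE
  if (cl < d[3L]) mask[r, cl + 1L] <- TRUE
  region_mask(mask, "reference")
}

# per-pixel temporal standard deviation as an H x W matrix
pixel_sd <- function(movie, frames = NULL) {
  m <- movie_matrix(movie)
  if (!is.null(frames)) m <- m[frames, , drop = FALSE]
  n <- nrow(m)
  mu <- colMeans(m)
  v <- colSums(m^2) / n - mu^2
  d <- dim(movie$data)
  matrix(sqrt(pmax(v, 0) * n / (n - 1)), d[2L], d[3L])
}

#' Cross-correlation phase map of the cardiac-domain movie
#'
#' Each pixel's cardiac-domain trace is cross-correlated with the mean
#' trace of the reference region over integer lags spanning one centred
#' cardiac period (`T = fs / f_HR` frames). The lag of maximal normalised
#' correlation, converted to degrees of the cardiac cycle, is the pixel's
#' phase; positive phase means the pixel lags the reference. Pixels whose
#' cardiac-band temporal standard deviation falls below 10% of the
#' reference trace's are marked invalid (their phase is `NA`).
#'
#' @param cardiac_movie cardiac-domain filtered [pixel_movie()].
#' @param reference a [region_mask()] (kind `"reference"`).
#' @param f_HR heart rate in Hz; the period must span at least 4 frames.
#' @return object of class `phase_map`: `H x W` matrices `phase`
#'   (degrees in `(-180, 180]`), `correlation` and logical `valid`.
#' @export
compute_phase_map <- function(cardiac_movie, reference, f_HR) {
  stopifnot(inherits(reference, "region_mask"))
  fs <- cardiac_movie$fs
  period <- fs / f_HR
  if (period < 4)
    stop(sprintf("cardiac period spans only %.2f frames at fs = %g Hz; need at least 4",
                 period, fs))
  L <- floor(period / 2)
  d <- dim(cardiac_movie$data)
  m <- movie_matrix(cardiac_movie)
  N <- nrow(m)
  ref <- rowMeans(m[, as.vector(reference$mask), drop = FALSE])
  ref <- ref - mean(ref)
  ref_sd <- sd(ref)
  if (ref_sd == 0) stop("reference trace has zero variance")

  px_sd <- sqrt(pmax(colSums(m^2) / N - colMeans(m)^2, 0) * N / (N - 1))
  valid_px <- which(px_sd >= 0.1 * ref_sd)

  mc <- sweep(m[, valid_px, drop = FALSE], 2L,
              colMeans(m[, valid_px, drop = FALSE]))
  norms <- sqrt(colSums(mc^2)) * sqrt(sum(ref^2))
  lags <- (-L):L
  cc <- matrix(NA_real_, length(lags), length(valid_px))
  for (i in seq_along(lags)) {
    l <- lags[i]
    if (l >= 0) {
      cc[i, ] <- crossprod(ref[seq_len(N - l)],
                           mc[(1L + l):N, , drop = FALSE]) / norms
    } else {
      cc[i, ] <- crossprod(ref[(1L - l):N],
                           mc[seq_len(N + l), , drop = FALSE]) / norms
    }
  }
  best <- max.col(t(cc), ties.method = "first")
  phase_v <- 360 * lags[best] / period
  phase_v[phase_v <= -180] <- phase_v[phase_v <= -180] + 360

  phase <- matrix(NA_real_, d[2L], d[3L])
  corr <- matrix(NA_real_, d[2L], d[3L])
  valid <- matrix(FALSE, d[2L], d[3L])
  phase[valid_px] <- phase_v
  corr[valid_px] <- cc[cbind(best, seq_along(valid_px))]
  valid[valid_px] <- TRUE
  structure(list(phase = phase, correlation = corr, valid = valid,
                 f_HR = f_HR, fs = fs, period_frames = period),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %dx%d, %d valid pixels, period %.1f frames\n",
              nrow(x$phase), ncol(x$phase), sum(x$valid), x$period_frames))
  invisible(x)
}

#' Heart mask from a phase map
#'
#' Valid pixels whose |phase| exceeds the threshold (default 30 degrees)
#' are attributed to the heart. The binary image is cleaned with a
#' morphological closing (fill holes) followed by an opening (remove
#' isolated pixels), both with a 3x3 cross; if several 4-connected
#' components remain, the largest is kept. An empty mask is a legal
#' result.
#'
#' @param phase_map a `phase_map` from [compute_phase_map()].
#' @param threshold phase threshold in degrees (default 30).
#' @return a [region_mask()] of kind `"heart"`.
#' @export
heart_mask <- function(phase_map, threshold = 30) {
  raw <- phase_map$valid & !is.na(phase_map$phase) &
    abs(phase_map$phase) > threshold
  cleaned <- mask_opening(mask_closing(raw))
  region_mask(largest_component4(cleaned), "heart")
}

#' Lung mask from the respiratory-domain movie
#'
#' Pixels whose respiratory-band temporal standard deviation reaches 25%
#' of the grid maximum, minus the heart mask, then an opening with the
#' 3x3 cross. The selection criterion is this package's construction (a
#' ventilation-amplitude threshold); there is no canonical definition of
#' the lung region of interest in functional EIT.
#'
#' @param resp_movie respiratory-domain filtered [pixel_movie()].
#' @param heart a [region_mask()] of kind `"heart"` (or `NULL`).
#' @param threshold_frac fraction of the maximal respiratory standard
#'   deviation (default 0.25).
#' @return a [region_mask()] of kind `"lung"`.
#' @export
lung_mask <- function(resp_movie, heart = NULL, threshold_frac = 0.25) {
  sds <- pixel_sd(resp_movie)
  raw <- sds >= threshold_frac * max(sds)
  if (!is.null(heart)) {
    if (inherits(heart, "region_mask")) heart <- heart$mask
    raw <- raw & !heart
  }
  if (!any(raw))
    stop("no lung pixels above the ventilation threshold; lower `threshold_frac`")
  cleaned <- mask_opening(raw)
  if (!any(cleaned))
    stop("lung mask empty after morphological opening; lower `threshold_frac`")
  region_mask(cleaned, "lung")
}
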