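#' Body positions recognised throughout the package
#' @keywords internal
#' @noRd
POSITIONS <- c("upright", "supine", "prone", "left_lateral", "right_lateral")

#' Construct a pixel movie
#'
#' The central container of the pipeline: a reconstructed EIT movie of
#' `N` frames of `H x W` impedance values (arbitrary units), together with
#' the frame rate, recording metadata and breathing/apnea segment labels.
#'
#' Segment boundaries follow the on-disk convention used everywhere in this
#' package: 0-based, half-open frame intervals `[start, end)`. Use
#' [segment_frames()] to translate a segment into 1-based R frame indices.
#'
#' @param data numeric array `N x H x W` (frame, row, column).
#' @param fs frame rate in Hz (> 0).
#' @param position one of `"upright"`, `"supine"`, `"prone"`,
#'   `"left_lateral"`, `"right_lateral"`.
#' @param subject_id subject identifier string.
#' @param replicate replicate number (>= 1).
#' @param segments `data.frame` with columns `label` (`"breathing"` or
#'   `"apnea"`), `start`, `end` (0-based half-open frame indices), or `NULL`
#'   if the recording has not been segmented yet.
#' @return an object of class `pixel_movie`.
#' @export
pixel_movie <- function(data, fs, position = "upright", subject_id = "S01",
                        replicate = 1L, segments = NULL) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (frames x rows x columns)")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  position <- match.arg(position, POSITIONS)
  if (!is.null(segments)) segments <- validate_segments(segments, dim(data)[1L])
  m <- structure(list(
    data = data, fs = fs, position = position,
    subject_id = as.character(subject_id), replicate = as.integer(replicate),
    segments = segments
  ), class = "pixel_movie")
  m
}

validate_segments <- function(segments, n_frames) {
  req <- c("label", "start", "end")
  if (!is.data.frame(segments) || !all(req %in% names(segments)))
    stop("`segments` must be a data.frame with columns label, start, end")
  if (!all(segments$label %in% c("breathing", "apnea")))
    stop("segment labels must be 'breathing' or 'apnea'")
  if (any(segments$start < 0) || any(segments$end > n_frames) ||
      any(segments$end <= segments$start))
    stop("segments must satisfy 0 <= start < end <= n_frames (0-based, half-open)")
  o <- order(segments$start)
  segments <- segments[o, , drop = FALSE]
  if (nrow(segments) > 1L &&
      any(segments$start[-1L] < segments$end[-nrow(segments)]))
    stop("segments must not overlap")
  rownames(segments) <- NULL
  segments
}

#' @export
print.pixel_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<pixel_movie> %d frames x %d x %d @ %g Hz (%.1f s)\n",
              d[1], d[2], d[3], x$fs, d[1] / x$fs))
  cat(sprintf("  subject %s, %s, replicate %d\n",
              x$subject_id, x$position, x$replicate))
  if (!is.null(x$segments)) {
    for (i in seq_len(nrow(x$segments)))
      cat(sprintf("  segment %-9s [%d, %d)\n", x$segments$label[i],
                  x$segments$start[i], x$segments$end[i]))
  } else cat("  (no segment labels)\n")
  invisible(x)
}

#' Number of frames of a pixel movie
#' @param movie a [pixel_movie()].
#' @return integer frame count.
#' @export
n_frames <- function(movie) dim(movie$data)[1L]

#' View the movie as a frames-by-pixels matrix
#'
#' Pixels are ordered column-major over the `H x W` grid, matching
#' `as.vector()` on an `H x W` mask matrix.
#'
#' @param movie a [pixel_movie()].
#' @return numeric matrix `N x (H*W)`.
#' @export
movie_matrix <- function(movie) {
  d <- dim(movie$data)
  m <- movie$data
  dim(m) <- c(d[1L], d[2L] * d[3L])
  m
}

#' 1-based frame indices of a labelled segment
#'
#' @param movie a [pixel_movie()] with segment labels.
#' @param label `"breathing"` or `"apnea"`.
#' @param which_segment which occurrence of the label to return (default
#'   first).
#' @return integer vector of frame indices, or `NULL` if the label is absent.
#' @export
segment_frames <- function(movie, label, which_segment = 1L) {
  if (is.null(movie$segments)) stop("movie has no segment labels")
  rows <- which(movie$segments$label == label)
  if (length(rows) < which_segment) return(NULL)
  r <- rows[which_segment]
  seq.int(movie$segments$start[r] + 1L, movie$segments$end[r])
}

#' Mean time trace over a region of a movie
#'
#' @param movie a [pixel_movie()].
#' @param mask logical/binary `H x W` matrix or a [region_mask()].
#' @return numeric vector of length `n_frames(movie)`.
#' @export
region_trace <- function(movie, mask) {
  if (inherits(mask, "region_mask")) mask <- mask$mask
  px <- which(as.vector(mask != 0))
  if (length(px) == 0L) stop("region is empty")
  rowMeans(movie_matrix(movie)[, px, drop = FALSE])
}

#' Construct a spirometric flow trace
#'
#' @param samples numeric vector of flow values in L/s, sampled synchronously
#'   with the paired movie.
#' @param fs sampling rate in Hz; must equal the movie frame rate.
#' @return an object of class `flow_trace`.
#' @export
flow_trace <- function(samples, fs) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("`samples` must be a non-empty numeric vector")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  structure(list(samples = as.numeric(samples), fs = fs), class = "flow_trace")
}

#' @export
print.flow_trace <- function(x, ...) {
  cat(sprintf("<flow_trace> %d samples @ %g Hz (%.1f s), range [%.3g, %.3g] L/s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Construct a binary region mask
#'
#' @param mask logical or 0/1 `H x W` matrix.
#' @param kind `"lung"`, `"heart"` or `"reference"`.
#' @return an object of class `region_mask`.
#' @export
region_mask <- function(mask, kind = c("lung", "heart", "reference")) {
  kind <- match.arg(kind)
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  m <- structure(list(mask = mask != 0, kind = kind), class = "region_mask")
  if (kind == "reference" && sum(m$mask) > 5L)
    stop("a reference mask has at most 5 pixels (seed plus 4-connected neighbours)")
  m
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> kind=%s, %d of %d pixels\n",
              x$kind, sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; returns `NaN` when both masks are empty.
#'
#' @param a,b binary matrices or [region_mask()] objects of equal size.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (inherits(a, "region_mask")) a <- a$mask
  if (inherits(b, "region_mask")) b <- b$mask
  a <- a != 0; b <- b != 0
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Construct a rate estimate
#' @keywords internal
#' @noRd
rate_estimate <- function(f_RR, f_HR, resp_peak_power, cardiac_peak_power,
                          harmonic_conflict, conflict_resolution, bin_width) {
  structure(list(f_RR = f_RR, f_HR = f_HR,
                 resp_peak_power = resp_peak_power,
                 cardiac_peak_power = cardiac_peak_power,
                 harmonic_conflict = harmonic_conflict,
                 conflict_resolution = conflict_resolution,
                 bin_width = bin_width),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> f_RR = %.4f Hz (%.1f bpm), f_HR = %.4f Hz (%.1f bpm)\n",
              x$f_RR, 60 * x$f_RR, x$f_HR, 60 * x$f_HR))
  cat(sprintf("  harmonic conflict: %s (resolution: %s); bin width %.4f Hz\n",
              x$harmonic_conflict, x$conflict_resolution, x$bin_width))
  invisible(x)
}

#' Construct a per-cycle amplitude record
#'
#' @param kind one of `"dZ_RR"`, `"dZ_CR"`, `"dZ_CA"`, `"V_T"`.
#' @param values per-cycle peak-to-trough amplitudes (impedance units, or L
#'   for `V_T`).
#' @param cycle_bounds `data.frame` with columns `start`, `end` (1-based
#'   sample indices into the analysed trace), ordered and non-overlapping.
#' @param subject_id,position,replicate recording metadata.
#' @return an object of class `cycle_amplitudes`.
#' @export
cycle_amplitudes <- function(kind, values, cycle_bounds,
                             subject_id = "S01", position = "upright",
                             replicate = 1L) {
  kind <- match.arg(kind, c("dZ_RR", "dZ_CR", "dZ_CA", "V_T"))
  if (length(values) != nrow(cycle_bounds))
    stop("`values` and `cycle_bounds` must have matching length")
  if (any(values <= 0)) stop("cycle amplitudes must be positive")
  structure(list(kind = kind, values = as.numeric(values),
                 cycle_bounds = cycle_bounds,
                 subject_id = subject_id, position = position,
                 replicate = as.integer(replicate)),
            class = "cycle_amplitudes")
}

#' @export
print.cycle_amplitudes <- function(x, ...) {
  cat(sprintf("<cycle_amplitudes> %s: %d cycles, mean %.4g (%s %s rep %d)\n",
              x$kind, length(x$values), mean(x$values),
              x$subject_id, x$position, x$replicate))
  invisible(x)
}

#' Construct a hypothesis-test result
#' @keywords internal
#' @noRd
test_result <- function(statistic, p_value, method, ...) {
  structure(c(list(statistic = statistic, p_value = p_value,
                   method = method, alpha = 0.05), list(...)),
            class = "feit_test")
}

#' @export
print.feit_test <- function(x, ...) {
  cat(sprintf("<%s>\n  statistic = %.4g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("  pairwise corrected p-values:\n")
    print(round(x$pairwise, 4))
  }
  invisible(x)
}
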