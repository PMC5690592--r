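#' Write a recording to a directory container
#'
#' A recording is stored as a small directory: `meta.json` (frame rate,
#' metadata, segment table, array dimensions), `frames.dat` (float64
#' little-endian, frames-by-pixels in the column-major pixel order of
#' [movie_matrix()]), `flow.csv` (columns `time_s`, `flow_Ls`) and an
#' optional `truth.json` ground-truth sidecar. Segment indices are 0-based
#' half-open.
#'
#' @param movie a [pixel_movie()].
#' @param path directory to create (must not be an existing file).
#' @param flow optional [flow_trace()]; must match the movie in length and
#'   sampling rate.
#' @param truth optional ground-truth record from [simulate_recording()]
#'   (stored without the geometry masks, which are kept as run-length
#'   encoded index lists).
#' @return `path`, invisibly.
#' @export
write_recording <- function(movie, path, flow = NULL, truth = NULL) {
  stopifnot(inherits(movie, "pixel_movie"))
  if (!is.null(flow)) {
    stopifnot(inherits(flow, "flow_trace"))
    if (length(flow$samples) != n_frames(movie))
      stop(sprintf("flow length (%d) does not match frame count (%d)",
                   length(flow$samples), n_frames(movie)))
    if (flow$fs != movie$fs) stop("flow and movie sampling rates differ")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(movie$data)
  meta <- list(format = "feit-recording-v1", fs = movie$fs,
               dims = d, position = movie$position,
               subject_id = movie$subject_id, replicate = movie$replicate,
               segments = movie$segments, byte_order = "little")
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(file.path(path, "frames.dat"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(movie_matrix(movie)), con, size = 8L, endian = "little")
  if (!is.null(flow)) {
    write.csv(data.frame(time_s = (seq_along(flow$samples) - 1) / flow$fs,
                         flow_Ls = flow$samples),
              file.path(path, "flow.csv"), row.names = FALSE)
  }
  if (!is.null(truth)) {
    tr <- truth
    tr$geometry <- list(grid_size = truth$geometry$grid_size,
                        lung_pixels = which(truth$geometry$lung_mask),
                        heart_pixels = which(truth$geometry$heart_mask))
    tr$params <- unclass(tr$params)
    jsonlite::write_json(tr, file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path recording directory.
#' @return list with elements `movie` ([pixel_movie()]) and `flow`
#'   ([flow_trace()] or `NULL` with a warning when no flow channel was
#'   stored).
#' @export
read_recording <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) stop("not a recording directory: ", path)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("recording has no `fs` attribute: ", path)
  if (is.null(meta$segments) || length(meta$segments) == 0L)
    stop("recording has no segment labels; run segmentation and rewrite it")
  d <- as.integer(meta$dims)
  n_values <- prod(d)
  con <- file(file.path(path, "frames.dat"), "rb")
  on.exit(close(con), add = TRUE)
  dat <- readBin(con, "numeric", n = n_values + 1L, size = 8L,
                 endian = "little")
  if (length(dat) != n_values)
    stop(sprintf("frames.dat holds %d values but meta.json declares %d",
                 length(dat), n_values))
  movie <- pixel_movie(array(dat, dim = d), fs = as.numeric(meta$fs),
                       position = meta$position,
                       subject_id = meta$subject_id,
                       replicate = meta$replicate,
                       segments = as.data.frame(meta$segments))
  flow_file <- file.path(path, "flow.csv")
  flow <- NULL
  if (file.exists(flow_file)) {
    ft <- read.csv(flow_file)
    if (nrow(ft) != d[1L])
      stop(sprintf("flow length (%d) does not match frame count (%d)",
                   nrow(ft), d[1L]))
    flow <- flow_trace(ft$flow_Ls, meta$fs)
  } else {
    warning("recording has no flow channel: ", path)
  }
  list(movie = movie, flow = flow)
}

#' Integrate a flow trace to volume
#'
#' Cumulative trapezoidal integration of the flow signal at the trace's
#' sampling interval; the volume starts at 0 L.
#'
#' @param flow a [flow_trace()] (or a plain numeric vector with `fs`).
#' @param fs sampling rate, required when `flow` is a bare vector.
#' @return numeric vector of volumes (L), same length as the flow.
#' @export
integrate_flow <- function(flow, fs = NULL) {
  if (inherits(flow, "flow_trace")) {
    fs <- flow$fs
    flow <- flow$samples
  }
  if (is.null(fs)) stop("`fs` is required when `flow` is a plain vector")
  if (length(flow) == 0L) stop("flow trace is empty")
  if (length(flow) == 1L) return(0)
  pracma::cumtrapz((seq_along(flow) - 1) / fs, flow)[, 1L]
}

#' Locate the most stable window of the first breathing segment
#'
#' The "stable phase" used for reference frames is operationalised as the
#' contiguous window (default 5 s) inside the first breathing segment that
#' minimises the variance of the mean-image signal.
#'
#' @param movie a [pixel_movie()] with segment labels.
#' @param duration window length in seconds.
#' @return integer vector `c(start, end)`, 0-based half-open frame interval.
#' @export
stable_window <- function(movie, duration = 5) {
  fr <- segment_frames(movie, "breathing")
  if (is.null(fr)) stop("movie has no breathing segment")
  w <- round(duration * movie$fs)
  if (length(fr) < w) stop("breathing segment shorter than the requested window")
  s <- rowMeans(movie_matrix(movie)[fr, , drop = FALSE])
  # rolling variance via cumulative sums
  cs <- cumsum(c(0, s)); cs2 <- cumsum(c(0, s^2))
  n_win <- length(s) - w + 1L
  i <- seq_len(n_win)
  m <- (cs[i + w] - cs[i]) / w
  v <- (cs2[i + w] - cs2[i]) / w - m^2
  best <- which.min(v)
  c(fr[best] - 1L, fr[best] - 1L + w)
}

#' Subtract a reference frame from a movie
#'
#' Difference imaging baseline removal. In `local` mode the per-pixel mean
#' over a reference interval of this movie is subtracted; in `global` mode
#' a supplied per-pixel baseline (typically [reference_baseline()] of the
#' subject's first upright recording) is subtracted.
#'
#' @param movie a [pixel_movie()].
#' @param mode `"local"` or `"global"`.
#' @param reference_interval 0-based half-open frame interval inside a
#'   breathing segment, at least 1 s long; defaults to [stable_window()].
#' @param external_reference `H x W` baseline matrix, required in global
#'   mode.
#' @return the movie with the baseline subtracted; the applied baseline is
#'   stored in attribute `"reference"`.
#' @export
subtract_reference <- function(movie, mode = c("local", "global"),
                               reference_interval = NULL,
                               external_reference = NULL) {
  mode <- match.arg(mode)
  if (mode == "global") {
    if (is.null(external_reference))
      stop("global mode requires `external_reference` (per-pixel baseline)")
    baseline <- external_reference
  } else {
    if (is.null(reference_interval)) reference_interval <- stable_window(movie)
    baseline <- reference_baseline(movie, reference_interval)
  }
  d <- dim(movie$data)
  m <- movie_matrix(movie)
  m <- m - rep(as.vector(baseline), each = d[1L])
  out <- movie
  out$data <- array(m, dim = d)
  attr(out, "reference") <- baseline
  out
}

#' Per-pixel baseline over a reference interval
#'
#' @param movie a [pixel_movie()].
#' @param reference_interval 0-based half-open frame interval; must lie in
#'   a breathing segment and span at least 1 s. Defaults to
#'   [stable_window()].
#' @return `H x W` matrix of per-pixel means.
#' @export
reference_baseline <- function(movie, reference_interval = NULL) {
  if (is.null(reference_interval)) reference_interval <- stable_window(movie)
  ri <- reference_interval
  if (length(ri) != 2L || ri[2L] <= ri[1L])
    stop("`reference_interval` must be c(start, end), 0-based half-open")
  if ((ri[2L] - ri[1L]) < movie$fs)
    stop("reference interval must span at least 1 s of frames")
  if (!is.null(movie$segments)) {
    br <- movie$segments[movie$segments$label == "breathing", , drop = FALSE]
    if (!any(ri[1L] >= br$start & ri[2L] <= br$end))
      stop("reference interval must lie inside a breathing segment")
  }
  fr <- seq.int(ri[1L] + 1L, ri[2L])
  d <- dim(movie$data)
  matrix(colMeans(movie_matrix(movie)[fr, , drop = FALSE]), d[2L], d[3L])
}
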