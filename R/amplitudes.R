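#' Detect cycles (breaths or beats) in a band-limited trace
#'
#' Extrema are located where the first difference changes sign and
#' classified by the sign of the second difference; plateaus are resolved
#' to their last sample. Extrema closer together than `0.3 / f_center`
#' seconds are merged, keeping the more extreme one (the larger departure
#' from the trace median for a min/max pair), and residual same-type runs
#' are collapsed. Cycles run minimum-to-minimum on `boundary_signal` when
#' given (the strictly filtered cardiac trace), otherwise on `signal`
#' itself; only complete cycles are returned, so cycles truncated by the
#' segment edges are implicitly discarded.
#'
#' @param signal numeric trace (used for reporting only; boundaries come
#'   from `boundary_signal` when supplied).
#' @param fs sampling rate in Hz.
#' @param f_center centre frequency of the band the trace lives in (Hz);
#'   sets the extremum merging window.
#' @param boundary_signal optional trace on which cycle boundaries are
#'   detected.
#' @return `data.frame` with columns `start`, `end`, `min_frame`,
#'   `max_frame` (1-based sample indices into the trace).
#' @export
detect_cycles <- function(signal, fs, f_center, boundary_signal = NULL) {
  b <- if (is.null(boundary_signal)) signal else boundary_signal
  if (length(b) != length(signal))
    stop("`boundary_signal` must have the same length as `signal`")
  n <- length(b)
  d <- diff(b)
  if (all(d == 0)) stop("signal is constant: no cycles to detect")
  s <- sign(d)
  # carry the last non-zero slope through plateaus
  nz <- s != 0
  idx <- cumsum(nz)
  s <- c(s[nz][1L], s[nz])[idx + 1L]

  ch <- which(s[-1L] != s[-length(s)])
  if (length(ch) == 0L) stop("fewer than 2 complete cycles detected")
  pos <- ch + 1L
  type <- ifelse(s[ch] > 0, "max", "min")

  # merge extrema closer than the debounce window
  w <- round(0.3 / f_center * fs)
  med <- median(b)
  while (length(pos) >= 2L) {
    gaps <- diff(pos)
    j <- which.min(gaps)
    if (gaps[j] >= w) break
    keep_first <-
      if (type[j] == type[j + 1L]) {
        if (type[j] == "max") b[pos[j]] >= b[pos[j + 1L]]
        else b[pos[j]] <= b[pos[j + 1L]]
      } else {
        abs(b[pos[j]] - med) >= abs(b[pos[j + 1L]] - med)
      }
    drop <- if (keep_first) j + 1L else j
    pos <- pos[-drop]; type <- type[-drop]
  }
  # collapse any remaining same-type runs to the more extreme member
  i <- 1L
  while (i < length(pos)) {
    if (type[i] == type[i + 1L]) {
      keep_first <- if (type[i] == "max") b[pos[i]] >= b[pos[i + 1L]]
      else b[pos[i]] <= b[pos[i + 1L]]
      drop <- if (keep_first) i + 1L else i
      pos <- pos[-drop]; type <- type[-drop]
    } else i <- i + 1L
  }

  mins <- pos[type == "min"]
  if (length(mins) < 2L) stop("fewer than 2 complete cycles detected")
  cyc <- data.frame(start = mins[-length(mins)], end = mins[-1L])
  cyc$min_frame <- mapply(function(a, z) a - 1L + which.min(b[a:z]),
                          cyc$start, cyc$end)
  cyc$max_frame <- mapply(function(a, z) a - 1L + which.max(b[a:z]),
                          cyc$start, cyc$end)
  # a complete cycle must contain a maximum strictly inside
  ok <- cyc$max_frame > cyc$start & cyc$max_frame < cyc$end
  cyc <- cyc[ok, , drop = FALSE]
  if (nrow(cyc) < 2L) stop("fewer than 2 complete cycles detected")
  rownames(cyc) <- NULL
  cyc
}

#' Peak-to-trough amplitude of each cycle
#'
#' The amplitude of a breath or heartbeat is the difference between the
#' maximum and the minimum of `signal` within the cycle. For cardiac
#' amplitudes the cycle boundaries come from the strictly filtered trace
#' while the amplitude is read from the loosely filtered (or raw) trace.
#'
#' @param signal numeric trace.
#' @param cycles cycle table from [detect_cycles()].
#' @return numeric vector of per-cycle amplitudes.
#' @export
amplitude_per_cycle <- function(signal, cycles) {
  vapply(seq_len(nrow(cycles)), function(i) {
    seg <- signal[cycles$start[i]:cycles$end[i]]
    max(seg) - min(seg)
  }, numeric(1))
}

#' Extract all per-cycle amplitude series of one recording
#'
#' Computes, over the lung-mask mean trace of a reference-subtracted
#' movie:
#' * `dZ_RR` - respiratory amplitudes from the respiratory-domain trace,
#'   breathing segment, cycles detected on the trace itself;
#' * `dZ_CR` - cardiac amplitudes during breathing from the
#'   cardiac-domain trace, beat boundaries from the strict trace;
#' * `dZ_CA` - cardiac amplitudes during apnea from the raw
#'   (reference-subtracted, otherwise untouched) trace, beat boundaries
#'   from the strict trace;
#' * `V_T` - per-breath tidal volumes from the integrated flow trace.
#'
#' Band filters are applied to the lung-mean trace; by linearity this
#' equals averaging the filtered pixel traces over the lung mask.
#'
#' @param movie reference-subtracted [pixel_movie()] with segment labels.
#' @param lung a [region_mask()] of kind `"lung"` (or binary matrix).
#' @param rates a `rate_estimate` from [estimate_rates()].
#' @param flow optional [flow_trace()], required for `V_T`.
#' @param kinds subset of `c("dZ_RR", "dZ_CR", "dZ_CA", "V_T")`.
#' @return named list of [cycle_amplitudes()]; `dZ_CA` is skipped with a
#'   warning when the recording has no apnea segment, `V_T` when no flow
#'   is available.
#' @export
extract_amplitudes <- function(movie, lung, rates, flow = NULL,
                               kinds = c("dZ_RR", "dZ_CR", "dZ_CA", "V_T")) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  fs <- movie$fs
  trace <- region_trace(movie, lung)
  ref <- refine_traces(trace, rates, fs)
  br <- segment_frames(movie, "breathing")
  ap <- segment_frames(movie, "apnea")
  meta <- list(subject_id = movie$subject_id, position = movie$position,
               replicate = movie$replicate)

  # guard against fabricating cycles from band leakage when the expected
  # oscillation is absent: detected cycle lengths must match the rate
  check_period <- function(cycles, f, what) {
    med <- median(cycles$end - cycles$start) / fs
    if (med < 0.5 / f || med > 2 / f)
      stop(sprintf("detected %s cycle length (median %.2f s) is inconsistent with the detected rate (%.2f s); the component may be absent",
                   what, med, 1 / f))
    cycles
  }

  # a cardiac trace below 1% of the total signal spread is band leakage,
  # not a pulse
  check_presence <- function(strict_slice, raw_slice, what) {
    if (sd(strict_slice) < 0.01 * sd(raw_slice))
      stop(sprintf("no %s component detected: strict-band energy is below 1%% of the trace", what))
    invisible(NULL)
  }

  # cycles touching the edges of the analysed slice sit in the filter's
  # edge-transient zone; drop one nominal cycle (capped at 10% of the
  # slice) at each end
  trim_edges <- function(cycles, f, n_slice) {
    guard <- min(1 / f, 0.1 * n_slice / fs) * fs
    keep <- (cycles$start - 1) > guard & cycles$end < n_slice - guard
    out <- cycles[keep, , drop = FALSE]
    if (nrow(out) < 2L)
      stop("fewer than 2 complete cycles away from the segment edges")
    out
  }

  make <- function(kind, sig, cycles, offset) {
    cb <- cycles
    cb$start <- cb$start + offset; cb$end <- cb$end + offset
    cb$min_frame <- cb$min_frame + offset; cb$max_frame <- cb$max_frame + offset
    cycle_amplitudes(kind, amplitude_per_cycle(sig, cycles), cb,
                     subject_id = meta$subject_id, position = meta$position,
                     replicate = meta$replicate)
  }

  out <- list()
  if ("dZ_RR" %in% kinds) {
    sig <- ref$resp[br]
    cyc <- check_period(detect_cycles(sig, fs, rates$f_RR), rates$f_RR, "breath")
    cyc <- trim_edges(cyc, rates$f_RR, length(sig))
    out$dZ_RR <- make("dZ_RR", sig, cyc, br[1L] - 1L)
  }
  if ("dZ_CR" %in% kinds) {
    sig <- ref$cardiac[br]
    check_presence(ref$cardiac_strict[br], trace[br], "cardiac")
    cyc <- check_period(detect_cycles(sig, fs, rates$f_HR,
                                      boundary_signal = ref$cardiac_strict[br]),
                        rates$f_HR, "beat")
    cyc <- trim_edges(cyc, rates$f_HR, length(sig))
    out$dZ_CR <- make("dZ_CR", sig, cyc, br[1L] - 1L)
  }
  if ("dZ_CA" %in% kinds) {
    if (is.null(ap)) {
      warning("recording has no apnea segment; dZ_CA skipped")
    } else {
      sig <- trace[ap] - mean(trace[ap])
      check_presence(ref$cardiac_strict[ap], sig, "cardiac")
      cyc <- check_period(detect_cycles(sig, fs, rates$f_HR,
                                        boundary_signal = ref$cardiac_strict[ap]),
                          rates$f_HR, "beat")
      cyc <- trim_edges(cyc, rates$f_HR, length(sig))
      out$dZ_CA <- make("dZ_CA", sig, cyc, ap[1L] - 1L)
    }
  }
  if ("V_T" %in% kinds) {
    if (is.null(flow)) {
      warning("no flow trace available; V_T skipped")
    } else {
      vol <- integrate_flow(flow)[br]
      cyc <- detect_cycles(vol, fs, rates$f_RR)
      cyc <- trim_edges(cyc, rates$f_RR, length(vol))
      out$V_T <- make("V_T", vol, cyc, br[1L] - 1L)
    }
  }
  out
}

#' Tidy table of per-cycle amplitudes
#'
#' @param amps a list of [cycle_amplitudes()] (possibly nested, as
#'   returned by [extract_amplitudes()] over several recordings).
#' @return `data.frame` with columns `subject_id`, `position`,
#'   `replicate`, `kind`, `cycle_index`, `amplitude`.
#' @export
amplitude_table <- function(amps) {
  flat <- list()
  collect <- function(x) {
    if (inherits(x, "cycle_amplitudes")) flat[[length(flat) + 1L]] <<- x
    else if (is.list(x)) lapply(x, collect)
    invisible(NULL)
  }
  collect(amps)
  do.call(rbind, lapply(flat, function(a)
    data.frame(subject_id = a$subject_id, position = a$position,
               replicate = a$replicate, kind = a$kind,
               cycle_index = seq_along(a$values), amplitude = a$values)))
}

#' Two-level amplitude summary for one subject
#'
#' Per-cycle amplitudes are first averaged within each recording
#' (subject, position, replicate), then the replicate means are averaged
#' into the reported triplicate mean per position and amplitude kind. The
#' volume-normalised respiratory amplitude `dZ_RR_per_VT` (mean dZ_RR /
#' mean V_T per replicate) is added when both kinds are present.
#'
#' @param amps list of [cycle_amplitudes()] for one subject (all
#'   positions/replicates; may be nested).
#' @return `data.frame` with columns `subject_id`, `position`, `kind`,
#'   `mean_amplitude`, `n_replicates`; the replicate-level means are
#'   attached as attribute `"replicate_means"`.
#' @export
summarize_amplitudes <- function(amps) {
  tab <- amplitude_table(amps)
  if (length(unique(tab$subject_id)) > 1L)
    stop("summarize_amplitudes() expects a single subject; got: ",
         paste(unique(tab$subject_id), collapse = ", "))
  rep_means <- stats::aggregate(amplitude ~ subject_id + position + replicate + kind,
                                tab, mean)
  # volume-normalised respiratory amplitude, per replicate
  wide_keys <- unique(rep_means[, c("subject_id", "position", "replicate")])
  extra <- NULL
  for (i in seq_len(nrow(wide_keys))) {
    sel <- rep_means$position == wide_keys$position[i] &
      rep_means$replicate == wide_keys$replicate[i]
    rr <- rep_means$amplitude[sel & rep_means$kind == "dZ_RR"]
    vt <- rep_means$amplitude[sel & rep_means$kind == "V_T"]
    if (length(rr) == 1L && length(vt) == 1L && vt > 0) {
      extra <- rbind(extra, data.frame(
        subject_id = wide_keys$subject_id[i], position = wide_keys$position[i],
        replicate = wide_keys$replicate[i], kind = "dZ_RR_per_VT",
        amplitude = rr / vt))
    }
  }
  rep_means <- rbind(rep_means, extra)
  out <- stats::aggregate(amplitude ~ subject_id + position + kind,
                          rep_means, mean)
  nrep <- stats::aggregate(replicate ~ subject_id + position + kind,
                           rep_means, function(x) length(unique(x)))
  out <- merge(out, nrep, by = c("subject_id", "position", "kind"))
  names(out)[names(out) == "amplitude"] <- "mean_amplitude"
  names(out)[names(out) == "replicate"] <- "n_replicates"
  out <- out[order(out$position, out$kind), ]
  rownames(out) <- NULL
  attr(out, "replicate_means") <- rep_means
  out
}
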