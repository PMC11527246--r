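#' Peak latency and amplitude of an evoked average
#'
#' Finds the extremum of the stated polarity inside a search window of the
#' average trace and reports its latency and amplitude. The peak counts as
#' visible when its magnitude reaches `detection_k` baseline standard
#' deviations; otherwise `visible = FALSE` and the amplitude is read at the
#' group-level fallback latency (mirroring the practice of estimating the
#' latency from the group average when a potential is not identifiable in an
#' individual).
#'
#' @param avg_trace numeric vector (one average trace).
#' @param time_ms time axis in ms, same length (e.g., from an `esg_epochs`).
#' @param search_ms `c(lo, hi)` search window.
#' @param polarity `-1` for a negative peak, `+1` for positive.
#' @param detection_k visibility threshold in baseline SDs (default 2).
#' @param group_latency_ms fallback latency; required when the peak may be
#'   invisible.
#' @param baseline_ms window for the baseline SD (default `c(-110, -10)`).
#' @param source label recorded in the result (channel or component id).
#' @return an `evoked_measure`: list with `latency_ms`, `amplitude`, `snr`
#'   (`NA` here; see [snr()]), `visible`, `source`.
#' @export
peak_measure <- function(avg_trace, time_ms, search_ms, polarity = -1,
                         detection_k = 2, group_latency_ms = NULL,
                         baseline_ms = c(-110, -10), source = "trace") {
  stopifnot(length(avg_trace) == length(time_ms))
  sel <- time_ms >= search_ms[1] & time_ms <= search_ms[2]
  if (!any(sel)) stop("search window lies outside the trace")
  seg <- polarity * avg_trace[sel]
  ipk <- which.max(seg)
  lat <- time_ms[sel][ipk]
  amp <- avg_trace[sel][ipk]
  bsel <- time_ms >= baseline_ms[1] & time_ms <= baseline_ms[2]
  bsd <- if (any(bsel)) stats::sd(avg_trace[bsel]) else NA_real_
  visible <- is.na(bsd) || abs(amp) >= detection_k * bsd
  if (!visible) {
    if (is.null(group_latency_ms))
      stop("peak not visible and no group fallback latency given")
    lat <- group_latency_ms
    amp <- avg_trace[which.min(abs(time_ms - group_latency_ms))]
  }
  structure(list(latency_ms = lat, amplitude = amp, snr = NA_real_,
                 visible = visible, source = source),
            class = "evoked_measure")
}

#' @export
print.evoked_measure <- function(x, ...) {
  cat("<evoked_measure> ", x$source, ": ", sprintf("%.2f", x$amplitude),
      " at ", sprintf("%.1f", x$latency_ms), " ms",
      if (!is.na(x$snr)) paste0(", SNR ", sprintf("%.1f", x$snr)) else "",
      if (!x$visible) " (not visible; group-latency fallback)" else "",
      "\n", sep = "")
  invisible(x)
}

#' Signal-to-noise ratio of an evoked average
#'
#' RMS of the signal in a +/- `halfwidth_ms` window around the peak latency,
#' divided by the RMS of a same-length pre-stimulus window. The noise window
#' is placed mirrored at minus the peak latency by default
#' (`noise = "mirror"`); `noise = "pre"` instead ends the noise window at
#' -10 ms.
#'
#' @param avg_trace numeric vector.
#' @param time_ms time axis in ms.
#' @param latency_ms peak latency.
#' @param halfwidth_ms half-width of both windows (default 1 ms).
#' @param noise `"mirror"` or `"pre"`.
#' @return a scalar SNR (`Inf` with a warning when the noise RMS is zero).
#' @export
snr <- function(avg_trace, time_ms, latency_ms, halfwidth_ms = 1,
                noise = c("mirror", "pre")) {
  noise <- match.arg(noise)
  pick <- function(center) {
    sel <- time_ms >= center - halfwidth_ms & time_ms <= center + halfwidth_ms
    if (!any(sel)) stop("SNR window lies outside the trace")
    avg_trace[sel]
  }
  sig <- pick(latency_ms)
  nz <- if (noise == "mirror") pick(-latency_ms)
        else pick(-10 - halfwidth_ms)
  rms <- function(x) sqrt(mean(x^2))
  if (rms(nz) == 0) {
    warning("zero noise RMS; returning Inf")
    return(Inf)
  }
  rms(sig) / rms(nz)
}

#' Time-frequency map of an evoked average
#'
#' Continuous short-time Fourier transform: a Hann-tapered sliding window
#' (hop of one sample) of `win_ms` length, zero-padded to `n_fft` points;
#' the magnitude of each frequency row is divided by its mean over the
#' baseline interval.
#'
#' @param avg_trace numeric vector.
#' @param time_ms time axis in ms.
#' @param fs sampling rate in Hz.
#' @param win_ms window length (default 21 ms).
#' @param baseline_ms baseline interval for normalization (default
#'   `c(-200, -10)`).
#' @param n_fft zero-padded FFT length (default 1024).
#' @return list with `map` (frequencies x times, baseline-normalized
#'   magnitude), `freq_hz`, `time_ms` (window centres), and
#'   `native_resolution_hz` (1 / window length).
#' @export
time_frequency <- function(avg_trace, time_ms, fs, win_ms = 21,
                           baseline_ms = c(-200, -10), n_fft = 1024) {
  n_win <- ms_to_samples(win_ms, fs)
  if (n_win %% 2 == 0) n_win <- n_win + 1L
  half <- (n_win - 1L) %/% 2L
  n <- length(avg_trace)
  if (n < n_win) stop("trace shorter than the analysis window")
  centers <- (half + 1L):(n - half)
  t_out <- time_ms[centers]
  # the window half-length is shaved off both trace ends; clip the baseline
  # to the centres actually available
  if (baseline_ms[2] < min(t_out) || baseline_ms[1] > max(t_out) ||
      baseline_ms[2] - baseline_ms[1] < win_ms)
    stop("baseline interval not covered by the windowed trace")
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_win) / (n_win + 1))
  segs <- vapply(centers,
                 function(c0) avg_trace[(c0 - half):(c0 + half)] * taper,
                 numeric(n_win))
  segs <- rbind(segs, matrix(0, n_fft - n_win, length(centers)))
  spec <- abs(stats::mvfft(segs))[seq_len(n_fft %/% 2 + 1L), , drop = FALSE]
  freq <- (seq_len(n_fft %/% 2 + 1L) - 1L) * fs / n_fft
  bsel <- t_out >= baseline_ms[1] & t_out <= baseline_ms[2]
  bmean <- rowMeans(spec[, bsel, drop = FALSE])
  bmean[bmean == 0] <- .Machine$double.eps
  list(map = spec / bmean, freq_hz = freq, time_ms = t_out,
       native_resolution_hz = 1000 / (n_win * 1000 / fs))
}

#' Measure a component or channel average: peak, amplitude, SNR
#'
#' Convenience wrapper combining [peak_measure()] and [snr()].
#'
#' @inheritParams peak_measure
#' @inheritParams snr
#' @return an `evoked_measure` with the `snr` field filled in.
#' @export
measure_evoked <- function(avg_trace, time_ms, search_ms, polarity = -1,
                           detection_k = 2, group_latency_ms = NULL,
                           halfwidth_ms = 1, source = "trace") {
  m <- peak_measure(avg_trace, time_ms, search_ms, polarity, detection_k,
                    group_latency_ms, source = source)
  m$snr <- snr(avg_trace, time_ms, m$latency_ms, halfwidth_ms)
  m
}
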