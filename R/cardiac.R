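#' Detect R-peaks in an ECG channel
#'
#' A simple envelope detector: the ECG is band-pass filtered to the QRS band
#' (5-30 Hz), squared, smoothed with a 120 ms moving average, and regions
#' above half the 98th percentile of the envelope are taken as beat
#' candidates; the peak is placed at the maximum of the absolute raw signal
#' inside each region. A 300 ms refractory period is enforced. Externally
#' supplied annotations (e.g., from visual inspection) are accepted verbatim
#' via `override`.
#'
#' @param ecg numeric vector (single-channel ECG, microvolts), or an
#'   `esg_recording` whose first `ecg`-role channel is used.
#' @param fs sampling rate in Hz (ignored when `ecg` is a recording).
#' @param override optional integer vector of 0-based peak samples to accept
#'   verbatim.
#' @param refractory_ms minimum distance between successive peaks.
#' @return an `r_peaks` object: list with `peak_samples` (0-based, strictly
#'   increasing) and `median_rr` (samples).
#' @export
detect_r_peaks <- function(ecg, fs = NULL, override = NULL,
                           refractory_ms = 300) {
  if (inherits(ecg, "esg_recording")) {
    fs <- ecg$fs
    ecg <- ecg$data[channel_idx(ecg, role = "ecg")[1], ]
  }
  stopifnot(!is.null(fs))
  if (!is.null(override)) {
    pk <- sort(as.integer(override))
  } else {
    if (length(ecg) < 5 * fs) stop("need at least 5 s of ECG signal")
    if (anyNA(ecg) || stats::sd(ecg) == 0)
      stop("flat or undefined ECG signal; cannot detect R-peaks")
    bf <- signal::butter(2, c(5, 30) / (fs / 2), "pass")
    env <- zero_phase(ecg, bf)^2
    w <- as.integer(round(0.12 * fs))
    env <- stats::filter(env, rep(1 / w, w), sides = 2)
    env[is.na(env)] <- 0
    thr <- 0.5 * stats::quantile(env, 0.98)
    above <- env > thr
    if (!any(above)) stop("no QRS-like activity found in ECG")
    runs <- rle(as.vector(above))
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    pk <- integer(0)
    for (i in which(runs$values)) {
      seg <- starts[i]:ends[i]
      pk <- c(pk, seg[which.max(abs(ecg[seg]))] - 1L)
    }
    refr <- refractory_ms * fs / 1000
    keep <- rep(TRUE, length(pk))
    last <- -Inf
    for (i in seq_along(pk)) {
      if (pk[i] - last < refr) keep[i] <- FALSE else last <- pk[i]
    }
    pk <- pk[keep]
  }
  if (length(pk) < 2) stop("fewer than two R-peaks detected")
  structure(list(peak_samples = pk,
                 median_rr = stats::median(diff(pk))),
            class = "r_peaks")
}

#' @export
print.r_peaks <- function(x, ...) {
  cat("<r_peaks> ", length(x$peak_samples), " peaks, median RR ",
      x$median_rr, " samples\n", sep = "")
  invisible(x)
}

#' Fit a per-channel optimal basis set to cardiac artifacts
#'
#' Collects the signal in a window of -0.5 to +0.5 median RR intervals
#' around each R-peak into an artifact x time matrix, computes a principal
#' component analysis on it (after removing the mean artifact, so that the
#' basis is non-redundant), and returns the optimal basis set: the mean
#' artifact plus the first `n_pc` principal components.
#'
#' @param channel numeric vector (one channel's continuous signal).
#' @param peaks an `r_peaks` object.
#' @param n_pc number of principal components (default 4).
#' @param var_threshold optional: instead of a fixed `n_pc`, keep as many
#'   components as needed to explain this fraction of the centred variance.
#' @return an `obs_model`: list with `basis` (window-length x (1 + n_pc)
#'   matrix, first column the mean artifact), `half_width` (samples),
#'   `explained` (variance fractions of the kept PCs).
#' @export
fit_obs <- function(channel, peaks, n_pc = 4, var_threshold = NULL) {
  hw <- as.integer(floor(0.5 * peaks$median_rr))
  n <- length(channel)
  pk <- peaks$peak_samples
  complete <- pk[pk - hw >= 0L & pk + hw < n]
  if (length(complete) < 6)
    stop("need at least 6 complete artifact windows to fit a basis")
  if (length(complete) < 10)
    warning("fewer than 10 complete artifact windows; basis may be unstable")
  A <- t(vapply(complete,
                function(p) channel[(p - hw):(p + hw) + 1L],
                numeric(2L * hw + 1L)))
  mu <- colMeans(A)
  Ac <- sweep(A, 2, mu)
  pc <- stats::prcomp(Ac, center = FALSE)
  ev <- pc$sdev^2
  expl <- ev / max(sum(ev), .Machine$double.eps)
  if (!is.null(var_threshold))
    n_pc <- max(1L, which(cumsum(expl) >= var_threshold)[1])
  n_pc <- min(n_pc, ncol(pc$rotation))
  structure(list(basis = cbind(mean = mu, pc$rotation[, seq_len(n_pc),
                                                      drop = FALSE]),
                 half_width = hw, n_artifacts = length(complete),
                 explained = expl[seq_len(n_pc)]),
            class = "obs_model")
}

#' @export
print.obs_model <- function(x, ...) {
  cat("<obs_model> window ", 2 * x$half_width + 1, " samples, basis ",
      ncol(x$basis), " vectors (mean + ", ncol(x$basis) - 1,
      " PCs) from ", x$n_artifacts, " artifacts\n", sep = "")
  invisible(x)
}

#' Remove cardiac artifacts with a fitted optimal basis set
#'
#' For every R-peak, the windowed segment is projected onto the basis by
#' ordinary least squares and the fitted artifact is subtracted within the
#' window. When successive R-peaks are closer than the window length, the
#' windows are clipped at the midpoint between the adjacent peaks; windows
#' that exceed the recording bounds are truncated (with a warning). Samples
#' outside all cardiac windows are returned unchanged.
#'
#' @param channel numeric vector (one channel's continuous signal).
#' @param model an `obs_model` fitted with [fit_obs()] (on this channel).
#' @param peaks an `r_peaks` object.
#' @return the cleaned signal, same length as `channel`.
#' @export
remove_cardiac <- function(channel, model, peaks) {
  hw <- model$half_width
  n <- length(channel)
  pk <- peaks$peak_samples
  out <- channel
  truncated <- FALSE
  for (i in seq_along(pk)) {
    lo <- pk[i] - hw
    hi <- pk[i] + hw
    if (i > 1) lo <- max(lo, floor((pk[i - 1] + pk[i]) / 2) + 1L)
    if (i < length(pk)) hi <- min(hi, floor((pk[i] + pk[i + 1]) / 2))
    if (lo < 0L || hi >= n) { truncated <- TRUE }
    lo2 <- max(lo, 0L); hi2 <- min(hi, n - 1L)
    if (hi2 <= lo2) next
    rows <- (lo2 - (pk[i] - hw) + 1L):(hi2 - (pk[i] - hw) + 1L)
    B <- model$basis[rows, , drop = FALSE]
    seg <- out[(lo2:hi2) + 1L]
    coef <- stats::lm.fit(B, seg)$coefficients
    coef[is.na(coef)] <- 0
    out[(lo2:hi2) + 1L] <- seg - drop(B %*% coef)
  }
  if (truncated)
    warning("edge beats fitted on truncated windows")
  out
}

#' Cardiac cleanup of a whole recording
#'
#' Convenience wrapper: detects R-peaks on the ECG channel (unless supplied)
#' and applies [fit_obs()] + [remove_cardiac()] to every channel of the given
#' roles.
#'
#' @param rec an `esg_recording` containing an `ecg`-role channel.
#' @param peaks optional precomputed `r_peaks`.
#' @param roles channel roles to clean (default `"esg"`).
#' @param n_pc principal components per channel.
#' @return list with `recording` (cleaned) and `peaks`.
#' @export
remove_cardiac_recording <- function(rec, peaks = NULL, roles = "esg",
                                     n_pc = 4) {
  if (is.null(peaks)) peaks <- detect_r_peaks(rec)
  out <- rec
  for (ch in channel_idx(rec, role = roles)) {
    m <- fit_obs(rec$data[ch, ], peaks, n_pc = n_pc)
    out$data[ch, ] <- remove_cardiac(rec$data[ch, ], m, peaks)
  }
  list(recording = out, peaks = peaks)
}

#' Read / write R-peak annotations as a one-column TSV
#'
#' @param peaks an `r_peaks` object.
#' @param path file path.
#' @return `read_r_peaks` returns an `r_peaks` object.
#' @export
write_r_peaks <- function(peaks, path) {
  utils::write.table(data.frame(peak_sample = peaks$peak_samples), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_r_peaks
#' @export
read_r_peaks <- function(path) {
  pk <- utils::read.delim(path)$peak_sample
  structure(list(peak_samples = as.integer(pk),
                 median_rr = stats::median(diff(pk))),
            class = "r_peaks")
}
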