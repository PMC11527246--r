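#' Zero-phase IIR filtering core
#'
#' Forward-backward application of an IIR filter with odd-reflection padding
#' at both ends (so steps and DC offsets do not ring into the data), giving
#' zero phase and the squared magnitude response of the one-pass design.
#'
#' @param x numeric vector.
#' @param filt a `signal::Arma`-style list with `b` and `a`.
#' @return filtered vector, same length as `x`.
#' @keywords internal
zero_phase <- function(x, filt) {
  n <- length(x)
  pad <- min(n - 1L, max(96L, 3L * (max(length(filt$a), length(filt$b)) - 1L)))
  xe <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  y <- signal::filter(filt$b, filt$a, xe)
  y <- rev(signal::filter(filt$b, filt$a, rev(y)))
  y[(pad + 1):(pad + n)]
}

# Second-order IIR notch at f0 with -3 dB bandwidth bw_hz (pole-radius
# design; zeros on the unit circle at +-f0).
notch_biquad <- function(f0, bw_hz, fs) {
  w0 <- 2 * pi * f0 / fs
  r <- max(0, 1 - pi * bw_hz / fs)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  g <- sum(a) / sum(b)   # unit gain at DC
  list(b = b * g, a = a)
}

#' Zero-phase Butterworth band-pass / notch / comb filtering
#'
#' Applies, in order, a band-stop (notch), a comb of second-order notch
#' sections at a base frequency and its harmonics, and a band-pass — each a
#' Butterworth design run forward and backward (fourth-order design, eighth
#' effective order for the band filters), so the result is zero phase and the
#' band-edge amplitude is 0.5 (the squared half-power gain).
#'
#' @param rec an `esg_recording`.
#' @param band `c(lo, hi)` band-pass corner frequencies in Hz, or `NULL`.
#' @param notch `c(lo, hi)` band-stop corners in Hz, or `NULL`.
#' @param comb `list(base = 50, n_harmonics = , bandwidth = 0.003)` or
#'   `NULL`. `bandwidth` is the -3 dB notch width as a fraction of the
#'   Nyquist frequency; harmonics above Nyquist are ignored, and
#'   `n_harmonics = NULL` means all harmonics below Nyquist.
#' @param order Butterworth design order (default 4).
#' @param channels integer indices to filter (default: all).
#' @return the filtered `esg_recording`.
#' @export
filter_zero_phase <- function(rec, band = c(30, 400), notch = NULL,
                              comb = NULL, order = 4, channels = NULL) {
  fs <- rec$fs
  ny <- fs / 2
  filts <- list()
  if (!is.null(notch)) {
    stopifnot(notch[1] < notch[2], notch[2] < ny)
    filts <- c(filts, list(signal::butter(order, notch / ny, "stop")))
  }
  if (!is.null(comb)) {
    base <- comb$base
    bw_hz <- (if (is.null(comb$bandwidth)) 0.003 else comb$bandwidth) * ny
    kmax <- floor((ny - 1) / base)
    if (!is.null(comb$n_harmonics)) kmax <- min(kmax, comb$n_harmonics)
    for (k in seq_len(kmax))
      filts <- c(filts, list(notch_biquad(k * base, bw_hz, fs)))
  }
  if (!is.null(band)) {
    stopifnot(band[1] < band[2], band[2] < ny)
    filts <- c(filts, list(signal::butter(order, band / ny, "pass")))
  }
  if (is.null(channels)) channels <- seq_len(n_channels(rec))
  out <- rec
  for (ch in channels) {
    x <- rec$data[ch, ]
    for (f in filts) x <- zero_phase(x, f)
    out$data[ch, ] <- x
  }
  out
}

#' Detect the stimulation-artifact window
#'
#' Electrical stimulation leaves a brief high-amplitude transient in all
#' channels at stimulus time. The window is found on the grand mean over all
#' events and all channels of one spinal patch: samples where the mean
#' exceeds `k` baseline standard deviations mark the artifact core, which is
#' then expanded outwards to where the mean re-enters `reentry_sd` baseline
#' SDs. If nothing exceeds the threshold, a default window of -1 to +4 ms is
#' returned with `fallback = TRUE`. The automatic criterion approximates what
#' is otherwise done by visual inspection, so the result carries enough
#' diagnostics to be overridden from a config.
#'
#' @param rec an `esg_recording`.
#' @param events event sample indices; default: all events of `rec`.
#' @param patch which grid patch's channels to average (`"cervical"` or
#'   `"lumbar"`); alternatively `channels` gives explicit indices.
#' @param channels optional explicit channel indices.
#' @param search_ms `c(lo, hi)` search window around the stimulus (must
#'   contain 0); the portion up to -5 ms serves as the baseline segment.
#' @param k detection threshold in baseline SDs.
#' @param reentry_sd re-entry level in baseline SDs.
#' @return an `artifact_window`: list with `start_ms`, `end_ms`, `patch`,
#'   `fallback`, and the detection `threshold_uv`.
#' @export
detect_stim_artifact_window <- function(rec, events = NULL,
                                        patch = "cervical", channels = NULL,
                                        search_ms = c(-20, 20), k = 8,
                                        reentry_sd = 1) {
  if (is.null(events)) events <- event_samples(rec)
  if (length(events) < 10) stop("need at least 10 events")
  stopifnot(search_ms[1] < 0, search_ms[2] > 0)
  if (is.null(channels)) channels <- channel_idx(rec, patch = patch)
  fs <- rec$fs
  s0 <- ms_to_samples(search_ms[1], fs)
  s1 <- ms_to_samples(search_ms[2], fs)
  rel <- s0:s1
  acc <- numeric(length(rel))
  for (ev in events)
    acc <- acc + colMeans(rec$data[channels, ev + rel + 1L, drop = FALSE])
  avg <- acc / length(events)
  t_ms <- rel * 1000 / fs
  basel <- t_ms <= -5
  avg <- avg - mean(avg[basel])
  sd0 <- max(stats::sd(avg[basel]), 1e-12)
  exceed <- abs(avg) > k * sd0
  if (!any(exceed))
    return(structure(list(start_ms = -1, end_ms = 4, patch = patch,
                          fallback = TRUE, threshold_uv = k * sd0),
                     class = "artifact_window"))
  # the artifact core is the contiguous suprathreshold run containing the
  # largest deflection; detached runs (e.g., the evoked response itself,
  # which also clears k small baseline SDs of an averaged trace) stay out
  runs <- rle(as.vector(exceed))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  imax <- which.max(abs(avg))
  ri <- which(runs$values & starts <= imax & ends >= imax)
  if (!length(ri)) ri <- which(runs$values)[1]
  lo <- starts[ri[1]]; hi <- ends[ri[1]]
  # re-entry level: baseline SDs, floored at 1% of the artifact peak so the
  # expansion tracks the artifact's own tail and cannot creep into the
  # evoked response (which is orders of magnitude below the transient)
  re_lvl <- max(reentry_sd * sd0, 0.01 * max(abs(avg)))
  while (lo > 1 && abs(avg[lo - 1]) > re_lvl) lo <- lo - 1
  while (hi < length(avg) && abs(avg[hi + 1]) > re_lvl) hi <- hi + 1
  structure(list(start_ms = t_ms[lo], end_ms = t_ms[hi], patch = patch,
                 fallback = FALSE, threshold_uv = k * sd0),
            class = "artifact_window")
}

#' Interpolate stimulation artifacts
#'
#' Replaces the samples inside each event's artifact window by a
#' shape-preserving piecewise-cubic Hermite interpolant (PCHIP) anchored on
#' `n_context` samples on each side of the window. Samples outside the
#' windows are untouched.
#'
#' @param rec an `esg_recording`.
#' @param window an `artifact_window` (or list with `start_ms`, `end_ms`).
#' @param events event samples; default: all events of `rec`.
#' @param channels channel indices to interpolate (default: all).
#' @param n_context anchor samples on each side.
#' @return the repaired `esg_recording`.
#' @export
interpolate_artifact <- function(rec, window, events = NULL,
                                 channels = NULL, n_context = 5) {
  if (is.null(events)) events <- event_samples(rec)
  if (is.null(channels)) channels <- seq_len(n_channels(rec))
  fs <- rec$fs
  w0 <- ms_to_samples(window$start_ms, fs)
  w1 <- ms_to_samples(window$end_ms, fs)
  stopifnot(w0 < w1)
  ev <- sort(events)
  if (length(ev) > 1 &&
      any(diff(ev) <= (w1 - w0 + 2 * n_context)))
    stop("artifact windows (plus context) overlap across consecutive events")
  out <- rec
  n <- n_samples(rec)
  for (e in ev) {
    gap <- (e + w0):(e + w1)
    anchors <- c((e + w0 - n_context):(e + w0 - 1L),
                 (e + w1 + 1L):(e + w1 + n_context))
    if (min(anchors) < 0L || max(anchors) >= n) next  # edge events untouched
    for (ch in channels) {
      out$data[ch, gap + 1L] <-
        pracma::pchip(anchors, rec$data[ch, anchors + 1L], gap)
    }
  }
  out
}

#' Downsample a recording
#'
#' Applies a zero-phase Butterworth anti-alias low-pass with corner at 0.9
#' of the target Nyquist frequency, then decimates (integer ratios) or
#' polyphase-resamples (rational ratios). Event sample indices are remapped
#' by index scaling.
#'
#' @param rec an `esg_recording`.
#' @param target_fs new sampling rate in Hz (`<= rec$fs`).
#' @return the resampled `esg_recording`.
#' @export
resample_recording <- function(rec, target_fs) {
  if (target_fs <= 0) stop("target_fs must be positive")
  if (target_fs > rec$fs) stop("upsampling is not supported")
  if (target_fs == rec$fs) return(rec)
  fs <- rec$fs
  ratio <- fs / target_fs
  aa <- signal::butter(4, 0.9 * target_fs / fs)  # 0.9 * target Nyquist
  filt <- t(apply(rec$data, 1, zero_phase, filt = aa))
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1, ncol(filt), by = round(ratio))
    newdata <- filt[, idx, drop = FALSE]
  } else {
    pq <- as.integer(c(target_fs, fs) /
                       pracma::gcd(as.integer(target_fs), as.integer(fs)))
    newdata <- t(apply(filt, 1, signal::resample, p = pq[1], q = pq[2]))
  }
  ev <- rec$events
  ev$sample <- as.integer(round(ev$sample * target_fs / fs))
  ev <- ev[ev$sample < ncol(newdata), , drop = FALSE]
  new_recording(newdata, target_fs, rec$channels,
                reference = rec$reference, events = ev)
}

#' Re-reference a recording
#'
#' Subtracts a new reference signal (a named channel, or the per-sample mean
#' over the re-referenced channels for `"average"`) from a set of channels.
#' If `keep_old = TRUE` and the current reference is not among the channels,
#' it is first added as a flat channel, so that re-referencing is invertible.
#'
#' @param rec an `esg_recording`.
#' @param reference channel label, or `"average"`.
#' @param channels indices of channels to re-reference (default: all
#'   non-ECG channels).
#' @param keep_old retain the old reference as a data channel.
#' @return the re-referenced `esg_recording`.
#' @export
rereference <- function(rec, reference, channels = NULL, keep_old = TRUE) {
  if (keep_old && !(rec$reference %in% rec$channels$label) &&
      reference != "average") {
    rec$data <- rbind(rec$data, 0)
    new_row <- rec$channels[1, , drop = FALSE]
    new_row[1, ] <- NA
    new_row$label <- rec$reference
    new_row$role <- "other"
    if ("patch" %in% names(new_row)) new_row$patch <- "none"
    rec$channels <- rbind(rec$channels, new_row)
    rownames(rec$channels) <- NULL
  }
  if (is.null(channels))
    channels <- which(rec$channels$role != "ecg")
  if (reference == "average") {
    ref_sig <- colMeans(rec$data[channels, , drop = FALSE])
    new_lab <- "average"
  } else {
    ri <- channel_idx(rec, reference)
    ref_sig <- rec$data[ri, ]
    new_lab <- reference
    if (ri %in% channels && all(rec$data[ri, ] == ref_sig))
      if (identical(new_lab, rec$reference))
        warning("re-referencing to the current reference yields a zero channel")
  }
  rec$data[channels, ] <- sweep(rec$data[channels, , drop = FALSE], 2, ref_sig)
  rec$reference <- new_lab
  rec
}

#' Threshold-based rejection of noisy time points
#'
#' Each rule flags samples on the channels of one role, either where the
#' absolute (optionally band-filtered) signal exceeds a fixed microvolt
#' threshold, or where it exceeds a multiple of the channel's standard
#' deviation. A channel in which more than `drop_frac` of samples are
#' flagged is dropped as a whole instead of contributing to the sample mask;
#' the masks of the remaining channels are unioned.
#'
#' @param rec an `esg_recording`.
#' @param rules list of rules; each rule is a list with `role`, and either
#'   `threshold_uv` or `sd_mult`, plus optional `band = c(lo, hi)` to apply
#'   the rule on a band-filtered copy. [esg_rejection_rules()] and
#'   [eeg_rejection_rules()] give the standard rule sets (100 uV absolute
#'   for spinal channels; 5 SD in 1-15 Hz and 60 uV in 15-45 Hz for EEG).
#' @param drop_frac channel-drop fraction (default 0.5).
#' @return list with `keep` (logical per sample, TRUE = retained),
#'   `dropped` (labels of dropped channels), and `summary` (per-channel
#'   data.frame with flagged counts).
#' @export
reject_timepoints <- function(rec, rules = esg_rejection_rules(),
                              drop_frac = 0.5) {
  n <- n_samples(rec)
  keep <- rep(TRUE, n)
  dropped <- character(0)
  sm <- data.frame(label = rec$channels$label, n_masked = 0L,
                   dropped = FALSE, stringsAsFactors = FALSE)
  for (rule in rules) {
    chans <- channel_idx(rec, role = rule$role)
    if (!length(chans)) next
    src <- if (!is.null(rule$band))
      filter_zero_phase(rec, band = rule$band, channels = chans)
    else rec
    for (ch in chans) {
      x <- src$data[ch, ]
      thr <- if (!is.null(rule$threshold_uv)) rule$threshold_uv
             else rule$sd_mult * stats::sd(x)
      flag <- abs(x) > thr
      sm$n_masked[ch] <- sm$n_masked[ch] + sum(flag)
      if (mean(flag) > drop_frac) {
        dropped <- union(dropped, rec$channels$label[ch])
        sm$dropped[ch] <- TRUE
      } else {
        keep <- keep & !flag
      }
    }
  }
  if (length(dropped) == nrow(rec$channels))
    stop("all channels dropped by rejection rules")
  list(keep = keep, dropped = dropped, summary = sm)
}

#' @rdname reject_timepoints
#' @export
esg_rejection_rules <- function() list(list(role = "esg", threshold_uv = 100))

#' @rdname reject_timepoints
#' @export
eeg_rejection_rules <- function()
  list(list(role = "eeg", band = c(1, 15), sd_mult = 5),
       list(role = "eeg", band = c(15, 45), threshold_uv = 60))

#' Cut epochs and baseline-correct
#'
#' Cuts stimulus-locked epochs over `window_ms` (endpoints inclusive: -200
#' to 700 ms at 1 kHz gives 901 samples) and subtracts the per-trial,
#' per-channel mean over `baseline_ms`. Trials that overlap masked samples
#' are marked `retained = FALSE` and excluded from downstream averages.
#'
#' @param rec an `esg_recording`.
#' @param events event samples; default: all events of `rec`.
#' @param window_ms `c(t0, t1)` epoch window (ms relative to stimulus).
#' @param baseline_ms `c(b0, b1)` baseline window, inside `window_ms`.
#' @param mask optional logical keep-mask per sample (from
#'   [reject_timepoints()]).
#' @param channels channel indices to include (default: all).
#' @return an `esg_epochs`: list with `data` (trials x channels x time),
#'   `time_ms`, `window_ms`, `baseline_ms`, `fs`, `retained`, `events`,
#'   `channels`.
#' @export
epoch_and_baseline <- function(rec, events = NULL,
                               window_ms = c(-200, 700),
                               baseline_ms = c(-110, -10),
                               mask = NULL, channels = NULL) {
  if (is.null(events)) events <- event_samples(rec)
  if (!length(events)) stop("no events to epoch around")
  stopifnot(baseline_ms[1] >= window_ms[1], baseline_ms[2] <= window_ms[2])
  if (is.null(channels)) channels <- seq_len(n_channels(rec))
  fs <- rec$fs
  s0 <- ms_to_samples(window_ms[1], fs)
  s1 <- ms_to_samples(window_ms[2], fs)
  rel <- s0:s1
  n_t <- length(rel)
  if (any(events + s0 < 0) || any(events + s1 >= n_samples(rec)))
    stop("epoch window extends outside the recording for some events")
  time_ms <- rel * 1000 / fs
  bsel <- time_ms >= baseline_ms[1] & time_ms <= baseline_ms[2]
  n_trial <- length(events)
  dat <- array(0, c(n_trial, length(channels), n_t))
  retained <- rep(TRUE, n_trial)
  for (k in seq_len(n_trial)) {
    idx <- events[k] + rel + 1L
    if (!is.null(mask) && any(!mask[idx])) retained[k] <- FALSE
    ep <- rec$data[channels, idx, drop = FALSE]
    ep <- ep - rowMeans(ep[, bsel, drop = FALSE])
    dat[k, , ] <- ep
  }
  if (!any(retained)) stop("no retained trials after masking")
  structure(list(data = dat, time_ms = time_ms, window_ms = window_ms,
                 baseline_ms = baseline_ms, fs = fs, retained = retained,
                 events = events,
                 channels = rec$channels[channels, , drop = FALSE]),
            class = "esg_epochs")
}

#' @export
print.esg_epochs <- function(x, ...) {
  cat("<esg_epochs> ", dim(x$data)[1], " trials (", sum(x$retained),
      " retained) x ", dim(x$data)[2], " channels x ", dim(x$data)[3],
      " samples, ", x$window_ms[1], "..", x$window_ms[2], " ms @ ",
      x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Trial average of an epoch set
#'
#' @param epochs an `esg_epochs`.
#' @param channels optional channel subset (indices or labels).
#' @return channels x time matrix averaged over retained trials.
#' @export
epoch_average <- function(epochs, channels = NULL) {
  sel <- which(epochs$retained)
  dat <- epochs$data[sel, , , drop = FALSE]
  avg <- apply(dat, c(2, 3), mean)
  rownames(avg) <- epochs$channels$label
  if (!is.null(channels)) {
    if (is.character(channels))
      channels <- match(channels, epochs$channels$label)
    avg <- avg[channels, , drop = FALSE]
  }
  avg
}
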