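#' Simulation configuration for synthetic grid recordings
#'
#' Bundles everything [generate_recording()] needs: stimulus train timing,
#' the planted evoked source, cardiac-artifact structure, stimulation
#' transients, and noise. Defaults emulate a desk-scale version of a
#' mixed-nerve electrospinography session: a 763 ms inter-stimulus interval
#' with +/-50 ms uniform jitter, a triphasic spinal response peaking
#' (negatively) at 13 ms on a radial-dipole topography over the 17-electrode
#' cervical grid, cardiac artifacts locked to R-peaks with ~1 s RR intervals,
#' brief high-amplitude stimulation transients, and white + 1/f + 50 Hz line
#' noise. The sampling rate defaults to 1 kHz, the rate at which all analysis
#' happens after downsampling.
#'
#' @param fs sampling rate in Hz (>= 1000).
#' @param n_trials number of stimuli.
#' @param isi_ms mean inter-stimulus interval (must exceed the epoch span).
#' @param jitter_ms half-width of the uniform ISI jitter (1 ms steps).
#' @param source a [source_spec()].
#' @param cardiac a [cardiac_spec()], or `NULL` to disable cardiac artifacts.
#' @param stim_artifact list with `amplitude_uv` and `window_ms = c(lo, hi)`;
#'   amplitude 0 disables the transient.
#' @param noise list with `white_sd_uv`, `pink_sd_uv`, `pink_exponent`
#'   (spectral slope beta of the 1/f^beta noise), `line_amp_uv` (50 Hz
#'   amplitude; two harmonics are added at -20 dB each).
#' @param montage a `montage_spec` for the grid geometry.
#' @param lead_ms quiet lead-in/lead-out around the stimulus train.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(fs = 1000, n_trials = 200, isi_ms = 763,
                       jitter_ms = 50,
                       source = source_spec(),
                       cardiac = cardiac_spec(),
                       stim_artifact = list(amplitude_uv = 500,
                                            window_ms = c(-2, 4)),
                       noise = list(white_sd_uv = 3, pink_sd_uv = 2,
                                    pink_exponent = 1, line_amp_uv = 1),
                       montage = builtin_montage("cervical"),
                       lead_ms = 2000, seed = 1) {
  stopifnot(fs >= 1000, n_trials >= 1, jitter_ms < isi_ms / 2)
  structure(list(fs = fs, n_trials = n_trials, isi_ms = isi_ms,
                 jitter_ms = jitter_ms, source = source, cardiac = cardiac,
                 stim_artifact = stim_artifact, noise = noise,
                 montage = montage, lead_ms = lead_ms, seed = seed),
            class = "sim_config")
}

#' Planted evoked source
#'
#' The temporal template is a triphasic wave (small initial positive lobe,
#' main negative lobe, slow late positive lobe), built as a difference of
#' Gaussians and scaled so that the main negative peak has amplitude
#' `-amplitude_uv` at `latency_ms`. The spatial pattern is a unit-norm
#' radial-dipole falloff over the grid (see [dipole_pattern()]).
#'
#' @param pattern unit-norm per-electrode weights; `NULL` means "compute a
#'   dipole pattern centred on the grid target at generation time".
#' @param latency_ms latency of the main (negative) peak.
#' @param width_ms temporal scale of the main lobe.
#' @param amplitude_uv peak amplitude of the main lobe (positive number; the
#'   planted peak is negative).
#' @param amplitude_cv trial-to-trial coefficient of variation of the
#'   amplitude.
#' @return a `source_spec` list.
#' @export
source_spec <- function(pattern = NULL, latency_ms = 13, width_ms = 3,
                        amplitude_uv = 1, amplitude_cv = 0.3) {
  stopifnot(width_ms > 0, amplitude_cv >= 0)
  structure(list(pattern = pattern, latency_ms = latency_ms,
                 width_ms = width_ms, amplitude_uv = amplitude_uv,
                 amplitude_cv = amplitude_cv),
            class = "source_spec")
}

#' Cardiac artifact model for the simulator
#'
#' R-peak times are drawn from a truncated normal RR distribution (minimum
#' 300 ms). Each beat deposits, on every grid channel, a stereotyped artifact
#' waveform scaled by a per-channel weight, plus a random amount of one
#' stored shape-variation axis (the waveform's temporal derivative), so that
#' the beat-to-beat shape variability is rank one by construction. A large,
#' clean ECG complex is written to the ECG channel for R-peak detection.
#'
#' @param rr_mean_ms,rr_sd_ms RR-interval mean and SD.
#' @param amplitude_uv peak artifact amplitude on the most affected channel.
#' @param pc_jitter SD of the coefficient on the shape-variation axis,
#'   relative to the template amplitude.
#' @param rank2_sd optional SD of a second variation axis (a stress mode for
#'   basis-dimension experiments); 0 keeps the variability rank one.
#' @return a `cardiac_spec` list.
#' @export
cardiac_spec <- function(rr_mean_ms = 1000, rr_sd_ms = 50,
                         amplitude_uv = 40, pc_jitter = 0.2, rank2_sd = 0) {
  stopifnot(rr_mean_ms > 0, rr_sd_ms >= 0)
  structure(list(rr_mean_ms = rr_mean_ms, rr_sd_ms = rr_sd_ms,
                 amplitude_uv = amplitude_uv, pc_jitter = pc_jitter,
                 rank2_sd = rank2_sd),
            class = "cardiac_spec")
}

#' Radial-dipole spatial pattern on a grid
#'
#' Unit-norm, nonnegative Gaussian falloff of electrode weight with distance
#' from a centre point, the surface signature of a radial source under the
#' grid.
#'
#' @param montage a `montage_spec`.
#' @param center `c(x, y)` in cm.
#' @param scale_cm spatial scale of the falloff (> 0).
#' @return numeric vector of length `nrow(montage$electrodes)` with unit
#'   Euclidean norm.
#' @export
dipole_pattern <- function(montage, center = c(0, 0), scale_cm = 2) {
  stopifnot(scale_cm > 0)
  el <- montage$electrodes
  if (center[1] < min(el$x_cm) - 2 || center[1] > max(el$x_cm) + 2 ||
      center[2] < min(el$y_cm) - 2 || center[2] > max(el$y_cm) + 2)
    warning("dipole centre lies well outside the electrode grid")
  d2 <- (el$x_cm - center[1])^2 + (el$y_cm - center[2])^2
  w <- exp(-d2 / (2 * scale_cm^2))
  w / sqrt(sum(w^2))
}

#' Source amplitude for a target planted single-trial SNR
#'
#' The planted single-trial SNR of a simulation is defined as the
#' signal-to-noise power ratio in the source projection within an analysis
#' window: `E[a^2] * mean(template^2 over the window) / sigma^2`, where `a`
#' is the per-trial source amplitude and `sigma` the per-channel noise SD
#' (the noise power is projection invariant for spatially white noise). This
#' is the customary SNR parameter in spatial-filter simulation studies and
#' maps directly onto the attainable single-trial/average canonical
#' correlation (roughly `sqrt(SNR / (1 + SNR))`).
#'
#' @param snr target power SNR (> 0).
#' @param noise_sd_uv per-channel noise SD in microvolts.
#' @param source a [source_spec()] supplying latency, width, and amplitude
#'   CV.
#' @param window_ms analysis window over which the signal power is taken
#'   (default: +/-5 ms around the source latency).
#' @param fs sampling rate.
#' @return the `amplitude_uv` giving the requested planted SNR.
#' @export
amplitude_for_snr <- function(snr, noise_sd_uv, source = source_spec(),
                              window_ms = NULL, fs = 1000) {
  stopifnot(snr > 0, noise_sd_uv > 0)
  if (is.null(window_ms)) window_ms <- source$latency_ms + c(-5, 5)
  tmpl <- triphasic_template(source$latency_ms, source$width_ms, fs)
  t_ms <- seq(0, by = 1000 / fs, length.out = length(tmpl))
  mw <- mean(tmpl[t_ms >= window_ms[1] & t_ms <= window_ms[2]]^2)
  sqrt(snr * noise_sd_uv^2 / ((1 + source$amplitude_cv^2) * mw))
}

# Triphasic temporal template sampled at `fs`, over support [0, span_ms].
# Scaled so the minimum equals -1; multiply by the trial amplitude.
triphasic_template <- function(latency_ms, width_ms, fs) {
  span_ms <- latency_ms + 10 * width_ms
  t <- seq(0, span_ms, by = 1000 / fs)
  g <- function(mu, s) exp(-(t - mu)^2 / (2 * s^2))
  w <- 0.30 * g(latency_ms - 1.8 * width_ms, 0.8 * width_ms) -
       1.00 * g(latency_ms, width_ms) +
       0.45 * g(latency_ms + 2.5 * width_ms, 2.5 * width_ms)
  w / abs(min(w))
}

# ECG-like waveform (R spike + T wave), peak normalized to 1, for the ECG
# channel and as the grid artifact template. `span_ms` on each side of 0.
ecg_waveform <- function(fs, span_ms = 350) {
  t <- seq(-span_ms, span_ms, by = 1000 / fs)
  q <- -0.15 * exp(-(t + 25)^2 / (2 * 8^2))
  r <- exp(-t^2 / (2 * 9^2))
  s <- -0.2 * exp(-(t - 25)^2 / (2 * 8^2))
  tw <- 0.25 * exp(-(t - 180)^2 / (2 * 35^2))
  w <- q + r + s + tw
  list(t_ms = t, w = w / max(w))
}

# 1/f^beta noise via spectral shaping of white Gaussian noise, unit SD.
pink_noise <- function(n, beta) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)             # symmetric frequency magnitude
  X <- X * f^(-beta / 2)
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  (y - mean(y)) / stats::sd(y)
}

simulate_core <- function(config, with_signal) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs
  ms <- function(x) as.integer(round(x * fs / 1000))
  # one seeded substream per stochastic ingredient, so that configurations
  # differing in one ingredient (e.g., cardiac on/off, task vs rest) share
  # bit-identical realizations of the others
  stage_seed <- function(k) set.seed((as.integer(config$seed) + k) %% 2147483000L)

  # --- stimulus train ---------------------------------------------------
  stage_seed(0L)
  jit <- if (config$jitter_ms > 0)
    sample(seq(-config$jitter_ms, config$jitter_ms), config$n_trials,
           replace = TRUE) else rep(0, config$n_trials)
  onsets_ms <- config$lead_ms + (seq_len(config$n_trials) - 1) *
    config$isi_ms + jit
  ev <- ms(onsets_ms)
  n_samp <- ms(config$lead_ms * 2 + config$n_trials * config$isi_ms)

  # --- planted source ---------------------------------------------------
  src <- config$source
  pattern <- src$pattern
  if (is.null(pattern))
    pattern <- dipole_pattern(config$montage, c(0, 0), 2)
  if (all(pattern == 0)) stop("degenerate source pattern (all zeros)")
  pattern <- pattern / sqrt(sum(pattern^2))
  template <- triphasic_template(src$latency_ms, src$width_ms, fs)
  stage_seed(1L)
  amps <- src$amplitude_uv *
    (1 + src$amplitude_cv * stats::rnorm(config$n_trials))

  el <- config$montage$electrodes
  n_grid <- nrow(el)
  chans <- data.frame(label = c(el$label, "ECG"),
                      role = c(rep("esg", n_grid), "ecg"),
                      patch = c(el$patch, "none"),
                      x_cm = c(el$x_cm, NA), y_cm = c(el$y_cm, NA),
                      stringsAsFactors = FALSE)
  data <- matrix(0, n_grid + 1L, n_samp)

  # --- cardiac artifacts ------------------------------------------------
  r_peaks <- integer(0)
  if (!is.null(config$cardiac)) {
    stage_seed(2L)
    cs <- config$cardiac
    t_acc <- stats::runif(1, 200, 200 + cs$rr_mean_ms)
    times <- t_acc
    while (max(times) < 1000 * n_samp / fs - 400) {
      d <- stats::rnorm(1, cs$rr_mean_ms, cs$rr_sd_ms)
      d <- max(d, 300)
      times <- c(times, max(times) + d)
    }
    times <- times[times < 1000 * n_samp / fs - 400]
    r_peaks <- ms(times)
    wf <- ecg_waveform(fs)
    n_w <- length(wf$w)
    half <- (n_w - 1L) %/% 2L
    # variation axes: temporal derivative (rank-1 default), optional 2nd
    ax1 <- c(diff(wf$w), 0); ax1 <- ax1 / max(abs(ax1))
    ax2 <- wf$w * (wf$t_ms / 100)
    if (max(abs(ax2)) > 0) ax2 <- ax2 / max(abs(ax2))
    # per-channel artifact weights: smooth spatial profile over the grid
    wch <- 0.5 + 0.5 * exp(-((el$x_cm + 1)^2 + (el$y_cm + 2)^2) / (2 * 4^2))
    wch <- cs$amplitude_uv * wch / max(wch)
    c1 <- cs$pc_jitter * stats::rnorm(length(r_peaks))
    c2 <- if (cs$rank2_sd > 0) cs$rank2_sd * stats::rnorm(length(r_peaks))
          else numeric(length(r_peaks))
    for (b in seq_along(r_peaks)) {
      i0 <- r_peaks[b] - half
      idx <- seq(i0, i0 + n_w - 1L)
      ok <- idx >= 0L & idx < n_samp
      beat <- wf$w + c1[b] * ax1 + c2[b] * ax2
      data[seq_len(n_grid), idx[ok] + 1L] <-
        data[seq_len(n_grid), idx[ok] + 1L] + outer(wch, beat[ok])
      data[n_grid + 1L, idx[ok] + 1L] <-
        data[n_grid + 1L, idx[ok] + 1L] + 800 * wf$w[ok]
    }
  }

  # --- noise (identical realization for task and rest runs) -------------
  stage_seed(3L)
  no <- config$noise
  for (ch in seq_len(n_grid + 1L)) {
    z <- numeric(n_samp)
    if (no$white_sd_uv > 0) z <- z + no$white_sd_uv * stats::rnorm(n_samp)
    if (no$pink_sd_uv > 0)
      z <- z + no$pink_sd_uv * pink_noise(n_samp, no$pink_exponent)
    data[ch, ] <- data[ch, ] + z
  }
  if (no$line_amp_uv > 0) {
    tt <- (seq_len(n_samp) - 1) / fs
    line <- no$line_amp_uv * (sin(2 * pi * 50 * tt + 0.7) +
      0.1 * sin(2 * pi * 100 * tt + 1.1) + 0.1 * sin(2 * pi * 150 * tt + 2.3))
    data[seq_len(n_grid), ] <- data[seq_len(n_grid), ] +
      matrix(line, n_grid, n_samp, byrow = TRUE)
  }

  # --- evoked responses and stimulation transients (task runs only) -----
  if (with_signal) {
    n_t <- length(template)
    for (k in seq_len(config$n_trials)) {
      idx <- ev[k] + seq_len(n_t) - 1L
      ok <- idx < n_samp
      data[seq_len(n_grid), idx[ok] + 1L] <-
        data[seq_len(n_grid), idx[ok] + 1L] +
        outer(pattern * amps[k], template[ok])
    }
    sa <- config$stim_artifact
    if (!is.null(sa) && sa$amplitude_uv > 0) {
      w0 <- ms(sa$window_ms[1]); w1 <- ms(sa$window_ms[2])
      for (k in seq_len(config$n_trials)) {
        idx <- (ev[k] + w0):(ev[k] + w1)
        idx <- idx[idx >= 0L & idx < n_samp]
        data[seq_len(n_grid + 1L), idx + 1L] <-
          data[seq_len(n_grid + 1L), idx + 1L] + sa$amplitude_uv
      }
    }
  }

  rec <- new_recording(data, fs, chans, reference = "TH6",
                       events = data.frame(sample = ev, code = "S  1"))
  # ground-truth average response over the standard epoch window
  ep0 <- ms(-200); ep1 <- ms(700)
  n_ep <- ep1 - ep0 + 1L
  clean <- matrix(0, n_grid, n_ep)
  pos <- which(seq(ep0, ep1) >= 0L)[seq_along(template)]
  pos <- pos[!is.na(pos)]
  clean[, pos] <- outer(pattern * src$amplitude_uv,
                        template[seq_along(pos)])
  truth <- list(event_samples = ev, r_peak_samples = r_peaks,
                clean_evoked = clean, clean_window_ms = c(-200, 700),
                pattern = pattern, template = template,
                trial_amplitudes = if (with_signal) amps else rep(0, config$n_trials))
  list(recording = rec, truth = truth)
}

#' Generate a synthetic task recording with ground truth
#'
#' Produces a continuous grid recording containing the planted evoked
#' response at each stimulus, cardiac artifacts, stimulation transients, and
#' noise, together with a ground-truth sidecar (`sim_truth`): event samples,
#' R-peak samples, the noiseless trial-average response over the standard
#' epoch window (-200..700 ms), the source pattern and temporal template, and
#' the per-trial amplitudes. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with elements `recording` (an `esg_recording`) and `truth`.
#' @seealso [generate_resting_state()] for the matched surrogate run.
#' @export
generate_recording <- function(config) simulate_core(config, TRUE)

#' Generate a matched resting-state (surrogate) recording
#'
#' Identical noise and cardiac structure to [generate_recording()] under the
#' same config and seed — the random number stream is consumed in the same
#' order — but with no evoked sources and no stimulation transients. The
#' surrogate event times (same stimulation sequence) are carried in the
#' returned truth, so that rest epochs can be cut with identical trial
#' timings.
#'
#' @inheritParams generate_recording
#' @return list with elements `recording` and `truth`.
#' @export
generate_resting_state <- function(config) simulate_core(config, FALSE)

#' Write a simulated recording and its ground truth to disk
#'
#' Thin wrapper over [generate_recording()] + [write_recording()]; the truth
#' sidecar is written as plain TSV files next to the BrainVision triplet
#' (`<base>_truth_events.tsv` with event and R-peak samples and trial
#' amplitudes, `<base>_truth_evoked.tsv` with the noiseless average,
#' `<base>_truth_pattern.tsv` with the source pattern).
#'
#' @param config a [sim_config()].
#' @param base output path without extension.
#' @param rest also write the matched resting-state run as `<base>_rest`?
#' @return `base`, invisibly.
#' @export
simulate_to_disk <- function(config, base, rest = FALSE) {
  sim <- generate_recording(config)
  write_recording(sim$recording, base)
  tr <- sim$truth
  utils::write.table(
    data.frame(event_sample = tr$event_samples,
               trial_amplitude = tr$trial_amplitudes),
    paste0(base, "_truth_events.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(data.frame(r_peak_sample = tr$r_peak_samples),
    paste0(base, "_truth_rpeaks.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(as.data.frame(tr$clean_evoked),
    paste0(base, "_truth_evoked.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(pattern = tr$pattern),
    paste0(base, "_truth_pattern.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (rest) {
    rs <- generate_resting_state(config)
    write_recording(rs$recording, paste0(base, "_rest"))
  }
  invisible(base)
}
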