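# Shared fixture builders and small numeric helpers.

cos_sim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# quadrature amplitude of a sinusoid at frequency f in x (middle portion)
sine_amplitude <- function(x, f, fs, trim = 0.2) {
  n <- length(x)
  i <- seq(floor(n * trim), ceiling(n * (1 - trim)))
  tt <- (i - 1) / fs
  co <- cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))
  sqrt(sum(stats::lm.fit(co, x[i])$coefficients^2))
}

# quiet task fixture: evoked + white noise only (no cardiac / stim / line)
quiet_config <- function(n_trials = 60, seed = 1, amplitude_uv = 1,
                         white_sd = 3, amplitude_cv = 0.3, ...) {
  sim_config(n_trials = n_trials, seed = seed, cardiac = NULL,
             stim_artifact = list(amplitude_uv = 0, window_ms = c(-2, 4)),
             noise = list(white_sd_uv = white_sd, pink_sd_uv = 0,
                          pink_exponent = 1, line_amp_uv = 0),
             source = source_spec(amplitude_uv = amplitude_uv,
                                  amplitude_cv = amplitude_cv), ...)
}

# fabricate a bare recording from a data matrix
make_recording <- function(data, fs = 1000, roles = NULL, events = NULL,
                           labels = NULL) {
  n_ch <- nrow(data)
  if (is.null(roles)) roles <- rep("esg", n_ch)
  if (is.null(labels)) labels <- paste0("CH", seq_len(n_ch))
  ch <- data.frame(label = labels, role = roles,
                   patch = ifelse(roles == "esg", "cervical", "none"),
                   stringsAsFactors = FALSE)
  if (is.null(events)) events <- data.frame(sample = integer(0),
                                            code = character(0))
  new_recording(data, fs, ch, events = events)
}

# fabricate an esg_epochs object directly (trials x channels x time)
make_epochs <- function(data, fs = 1000, window_ms = NULL, labels = NULL) {
  n_t <- dim(data)[3]
  if (is.null(window_ms)) window_ms <- c(0, (n_t - 1) * 1000 / fs)
  time_ms <- seq(window_ms[1], window_ms[2], length.out = n_t)
  if (is.null(labels)) labels <- paste0("CH", seq_len(dim(data)[2]))
  structure(list(data = data, time_ms = time_ms, window_ms = window_ms,
                 baseline_ms = window_ms, fs = fs,
                 retained = rep(TRUE, dim(data)[1]),
                 events = seq_len(dim(data)[1]),
                 channels = data.frame(label = labels, role = "esg",
                                       patch = "cervical",
                                       stringsAsFactors = FALSE)),
            class = "esg_epochs")
}
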