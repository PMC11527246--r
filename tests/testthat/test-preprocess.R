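test_that("stimulation-artifact windows contain the planted transient", {
  fs <- 1000
  n <- 40000
  ev <- seq(2000, n - 2000, by = 500)
  dat <- matrix(0.0, 3, n)
  for (e in ev) dat[, (e - 2):(e + 4) + 1L] <- 200  # -2..4 ms square
  rec <- make_recording(dat, fs,
                        events = data.frame(sample = ev, code = "S"))
  w <- detect_stim_artifact_window(rec, patch = "cervical")
  expect_false(w$fallback)
  expect_lte(w$start_ms, -2)
  expect_gte(w$end_ms, 4)
  expect_gte(w$start_ms, -3)   # within one sample of the true edge
  expect_lte(w$end_ms, 5)
})

test_that("zero-amplitude artifacts fall back to the default window", {
  set.seed(2)
  ev <- seq(2000, 30000, by = 500)
  rec <- make_recording(matrix(rnorm(2 * 35000), 2), 1000,
                        events = data.frame(sample = ev, code = "S"))
  w <- detect_stim_artifact_window(rec, patch = "cervical")
  expect_true(w$fallback)
  expect_equal(c(w$start_ms, w$end_ms), c(-1, 4))
  expect_error(detect_stim_artifact_window(rec, events = ev[1:5]),
               "at least 10")
})

test_that("detected windows widen with the planted artifact duration", {
  fs <- 1000
  widths <- c(2, 6, 10)
  spans <- vapply(widths, function(wd) {
    ev <- seq(2000, 38000, by = 500)
    dat <- matrix(0.0, 2, 40000)
    for (e in ev) dat[, e:(e + wd) + 1L] <- 150
    rec <- make_recording(dat, fs,
                          events = data.frame(sample = ev, code = "S"))
    w <- detect_stim_artifact_window(rec, patch = "cervical")
    w$end_ms - w$start_ms
  }, 0)
  expect_true(all(diff(spans) > 0))
})

test_that("PCHIP interpolation reproduces linear data and is local", {
  fs <- 1000
  x <- seq(0, 40, length.out = 20000)  # linear ramp
  rec <- make_recording(rbind(x), fs,
                        events = data.frame(sample = c(5000L, 9000L),
                                            code = "S"))
  w <- list(start_ms = -2, end_ms = 4)
  out <- interpolate_artifact(rec, w)
  expect_equal(out$data[1, ], rec$data[1, ], tolerance = 1e-9)

  set.seed(3)
  y <- rnorm(20000)
  rec2 <- make_recording(rbind(y), fs,
                         events = data.frame(sample = 5000L, code = "S"))
  out2 <- interpolate_artifact(rec2, w)
  inside <- 5000 + (-2:4) + 1L
  expect_identical(out2$data[1, -inside], rec2$data[1, -inside])
  expect_false(all(out2$data[1, inside] == rec2$data[1, inside]))
})

test_that("PCHIP is shape preserving across the gap", {
  # monotone context data -> monotone interpolant, no overshoot
  fs <- 1000
  y <- 1 / (1 + exp(-seq(-6, 6, length.out = 2001)))  # sigmoid
  y[995:1015] <- 5  # artifact to replace
  rec <- make_recording(rbind(y), fs,
                        events = data.frame(sample = 1004L, code = "S"))
  out <- interpolate_artifact(rec, list(start_ms = -10, end_ms = 11))
  seg <- out$data[1, 985:1025]
  expect_true(all(diff(seg) >= -1e-12))
  expect_true(all(seg >= min(seg[1], seg[41]) - 1e-12 &
                    seg <= max(seg[1], seg[41]) + 1e-12))
})

test_that("overlapping artifact windows across events are an error", {
  rec <- make_recording(rbind(rnorm(1000)), 1000,
                        events = data.frame(sample = c(500L, 505L),
                                            code = "S"))
  expect_error(interpolate_artifact(rec, list(start_ms = -2, end_ms = 4)),
               "overlap")
})

test_that("resampling preserves passband sinusoids and remaps events", {
  fs <- 10000
  t <- (0:(fs * 2 - 1)) / fs
  x <- sin(2 * pi * 100 * t)
  rec <- make_recording(rbind(x), fs,
                        events = data.frame(sample = 10000L, code = "S"))
  out <- resample_recording(rec, 1000)
  expect_equal(out$fs, 1000)
  expect_equal(ncol(out$data), 2000)
  expect_equal(out$events$sample, 1000L)
  expect_equal(sine_amplitude(out$data[1, ], 100, 1000), 1, tolerance = 0.01)
})

test_that("resampling suppresses energy above the new Nyquist", {
  set.seed(8)
  fs <- 10000
  x <- rnorm(fs * 2)
  rec <- make_recording(rbind(x), fs)
  out <- resample_recording(rec, 1000)
  pow <- function(sig, f_lo, fsamp) {
    sp <- abs(fft(sig))^2
    f <- (seq_along(sp) - 1) * fsamp / length(sp)
    sum(sp[f >= f_lo & f <= fsamp / 2]) / length(sp)
  }
  # energy at 450..500 Hz in the output vs the input's above-500 energy
  expect_lt(pow(out$data[1, ], 450, 1000), 0.01 * pow(x, 500, fs))
  expect_error(resample_recording(rec, -5), "positive")
})

test_that("band-pass is zero-phase with half-power band edges", {
  fs <- 1000
  t <- (0:(20 * fs - 1)) / fs
  mk <- function(f) make_recording(rbind(sin(2 * pi * f * t)), fs)
  # passband: amplitude ~1, no lag
  y100 <- filter_zero_phase(mk(100), band = c(30, 400))$data[1, ]
  expect_equal(sine_amplitude(y100, 100, fs), 1, tolerance = 0.005)
  lag <- which.max(ccf(y100[2000:18000], sin(2 * pi * 100 * t)[2000:18000],
                       lag.max = 3, plot = FALSE)$acf) - 4
  expect_equal(lag, 0)
  # 30 Hz corner: |H|^2 = 0.5 after the two passes
  y30 <- filter_zero_phase(mk(30), band = c(30, 400))$data[1, ]
  expect_equal(sine_amplitude(y30, 30, fs), 0.5, tolerance = 0.02)
  # DC rejection
  ydc <- filter_zero_phase(make_recording(rbind(rep(10, 8000)), fs),
                           band = c(30, 400))$data[1, ]
  expect_lt(abs(mean(ydc)), 0.01)
})

test_that("notch and comb filters attenuate line components", {
  fs <- 1000
  t <- (0:(10 * fs - 1)) / fs
  x50 <- sin(2 * pi * 50 * t)
  y <- filter_zero_phase(make_recording(rbind(x50), fs), band = NULL,
                         notch = c(48, 53))$data[1, ]
  expect_lt(sine_amplitude(y, 50, fs), 0.01)
  cmb <- list(base = 50, bandwidth = 0.003)
  y2 <- filter_zero_phase(make_recording(rbind(x50), fs), band = NULL,
                          comb = cmb)$data[1, ]
  expect_lt(sine_amplitude(y2, 50, fs), 0.05)
  y3 <- filter_zero_phase(make_recording(rbind(sin(2 * pi * 150 * t)), fs),
                          band = NULL, comb = cmb)$data[1, ]
  expect_lt(sine_amplitude(y3, 150, fs), 0.05)  # harmonic notched
  y4 <- filter_zero_phase(make_recording(rbind(sin(2 * pi * 80 * t)), fs),
                          band = NULL, comb = cmb)$data[1, ]
  expect_equal(sine_amplitude(y4, 80, fs), 1, tolerance = 0.02)
})

test_that("filtering is linear", {
  set.seed(5)
  x <- rnorm(4000); y <- rnorm(4000)
  f <- function(v) filter_zero_phase(make_recording(rbind(v), 1000),
                                     band = c(30, 400),
                                     notch = c(48, 53))$data[1, ]
  lhs <- f(2 * x - 3 * y)
  rhs <- 2 * f(x) - 3 * f(y)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-6)
})

test_that("re-referencing centres, inverts, and boosts opposite poles", {
  set.seed(6)
  dat <- matrix(rnorm(4 * 1000), 4)
  rec <- make_recording(dat, 1000, roles = rep("esg", 4))
  # average reference: per-sample mean is zero
  ar <- rereference(rec, "average")
  expect_equal(max(abs(colMeans(ar$data))), 0, tolerance = 1e-12)
  # re-reference to CH2, then back to the retained old reference
  r1 <- rereference(rec, "CH2")
  expect_equal(r1$reference, "CH2")
  r2 <- rereference(r1, "REF")   # old reference kept as flat channel
  expect_equal(r2$data[1:4, ], rec$data, tolerance = 1e-12)
  # opposite-pole ventral reference doubles the target amplitude
  s <- sin(2 * pi * 13 * (0:999) / 1000)
  two <- make_recording(rbind(s, -0.5 * s), 1000,
                        roles = c("esg", "esg"),
                        labels = c("TGT", "VENT"))
  rv <- rereference(two, "VENT")
  expect_gt(max(abs(rv$data[1, ])), 1.4 * max(abs(s)))
})

test_that("rejection masks exceedances and drops bad channels", {
  set.seed(7)
  dat <- matrix(rnorm(3 * 10000), 3)
  dat[1, 500] <- 150                       # single spike
  dat[2, 1:6500] <- 200                    # 65% of samples bad
  rec <- make_recording(dat, 1000)
  rj <- reject_timepoints(rec)
  expect_false(rj$keep[500])
  expect_equal(sum(!rj$keep), 1)
  expect_equal(rj$dropped, "CH2")
  expect_true(rj$summary$dropped[2])
  # clean data: nothing masked
  rj2 <- reject_timepoints(make_recording(matrix(rnorm(2000), 2), 1000))
  expect_true(all(rj2$keep))
  expect_length(rj2$dropped, 0)
})

test_that("the EEG rules flag on band-filtered copies", {
  set.seed(8)
  fs <- 1000
  dat <- matrix(rnorm(2 * 20000), 2)
  t <- (0:19999) / fs
  dat[1, 5000:5300] <- dat[1, 5000:5300] + 80 * sin(2 * pi * 25 * t[5000:5300])
  rec <- make_recording(dat, fs, roles = c("eeg", "eeg"))
  rj <- reject_timepoints(rec, eeg_rejection_rules())
  expect_gt(sum(!rj$keep[5000:5300]), 0)
  expect_true(all(rj$keep[10000:19000]))
})

test_that("epoching uses inclusive bounds and zeroes the baseline", {
  sim <- generate_recording(quiet_config(n_trials = 12, seed = 13))
  ep <- epoch_and_baseline(sim$recording, window_ms = c(-200, 700),
                           baseline_ms = c(-110, -10), channels = 1:17)
  expect_equal(dim(ep$data)[3], 901)
  bsel <- ep$time_ms >= -110 & ep$time_ms <= -10
  bm <- apply(ep$data[, , bsel, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(bm)), 1e-9)
})

test_that("masked samples exclude overlapping trials at the expected rate", {
  set.seed(9)
  n <- 120000
  ev <- seq(100, n - 100, by = 50)
  rec <- make_recording(rbind(rnorm(n)), 1000,
                        events = data.frame(sample = ev, code = "S"))
  mask <- runif(n) > 0.01            # 1% masked uniformly
  ep <- epoch_and_baseline(rec, window_ms = c(-10, 10),
                           baseline_ms = c(-10, 0), mask = mask)
  expected <- 0.99^21
  expect_equal(mean(ep$retained), expected, tolerance = 0.05)
  expect_error(epoch_and_baseline(rec, window_ms = c(-10, 10),
                                  baseline_ms = c(-10, 0),
                                  mask = rep(FALSE, n)),
               "no retained")
})
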