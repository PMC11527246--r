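test_that("R-peaks are found within 10 ms with no extras", {
  cfg <- sim_config(n_trials = 40, seed = 17,
                    cardiac = cardiac_spec(rr_mean_ms = 1000, rr_sd_ms = 50))
  sim <- generate_recording(cfg)
  pk <- detect_r_peaks(sim$recording)
  truth <- sim$truth$r_peak_samples
  expect_equal(length(pk$peak_samples), length(truth))
  offs <- vapply(pk$peak_samples,
                 function(p) min(abs(truth - p)), 0L)
  expect_lte(max(offs), 10)
  expect_true(all(diff(pk$peak_samples) > 0))
  # median_rr is the median of successive peak differences
  expect_equal(pk$median_rr, median(diff(pk$peak_samples)))
})

test_that("flat or short ECG signals are detection errors", {
  expect_error(detect_r_peaks(rep(0, 10000), fs = 1000), "flat")
  expect_error(detect_r_peaks(rnorm(1000), fs = 1000), "5 s")
  # external annotations accepted verbatim
  pk <- detect_r_peaks(rep(0, 10), fs = 1000,
                       override = c(5000L, 1000L, 3000L))
  expect_equal(pk$peak_samples, c(1000L, 3000L, 5000L))
})

test_that("identical artifacts give a pure-mean basis", {
  set.seed(20)
  fs <- 1000
  n <- 40000
  x <- numeric(n)
  peaks_at <- seq(1000, n - 1000, by = 900)
  shape <- exp(-(-200:200)^2 / (2 * 30^2))
  for (p in peaks_at) x[p + (-200:200) + 1L] <- shape
  pk <- detect_r_peaks(x, fs, override = peaks_at)
  m <- fit_obs(x, pk)
  expect_equal(ncol(m$basis), 5)
  expect_equal(2L * floor(0.5 * pk$median_rr) + 1L, nrow(m$basis))
  hw <- m$half_width
  expect_equal(m$basis[, 1], x[peaks_at[3] + (-hw:hw) + 1L],
               tolerance = 1e-12)
  expect_lt(sum(m$explained), 1e-12)  # no variance beyond the mean
})

test_that("rank-1 amplitude variability loads on the first component", {
  set.seed(21)
  n <- 60000
  x <- numeric(n)
  peaks_at <- seq(1000, n - 1000, by = 950)
  shape <- exp(-(-300:300)^2 / (2 * 40^2))
  gains <- 1 + 0.5 * rnorm(length(peaks_at))
  for (i in seq_along(peaks_at))
    x[peaks_at[i] + (-300:300) + 1L] <- gains[i] * shape
  pk <- detect_r_peaks(x, 1000, override = peaks_at)
  m <- fit_obs(x, pk)
  expect_gt(m$explained[1], 0.99)
  expect_error(fit_obs(x, detect_r_peaks(x, 1000,
                                         override = peaks_at[1:4])),
               "at least 6")
})

test_that("OBS removal is exact on spanned artifacts and local", {
  cfg <- sim_config(n_trials = 30, seed = 23,
                    stim_artifact = list(amplitude_uv = 0,
                                         window_ms = c(-2, 4)),
                    source = source_spec(amplitude_uv = 0),
                    noise = list(white_sd_uv = 0, pink_sd_uv = 0,
                                 pink_exponent = 1, line_amp_uv = 0))
  sim <- generate_recording(cfg)   # pure cardiac on the grid
  x <- sim$recording$data[1, ]
  pk <- detect_r_peaks(sim$recording)
  m <- fit_obs(x, pk)
  cl <- suppressWarnings(remove_cardiac(x, m, pk))
  # artifacts lie in the span of mean + PC1 (rank-1 shape variability)
  expect_lt(sqrt(mean(cl^2)), 0.05 * sqrt(mean(x^2)))
  # locality: samples outside all cardiac windows are untouched
  hw <- m$half_width
  inwin <- rep(FALSE, length(x))
  for (p in pk$peak_samples) {
    lo <- max(p - hw, 0); hi <- min(p + hw, length(x) - 1)
    inwin[(lo:hi) + 1L] <- TRUE
  }
  expect_identical(cl[!inwin], x[!inwin])
})

test_that("OBS nearly leaves artifact-free signals alone", {
  # a realistic 10-minute channel: enough beats that the 4-PC basis cannot
  # overfit the noise (in-sample PC projection shrinks as beats grow)
  set.seed(29)
  n <- 600000
  x <- 3 * rnorm(n)
  tmpl <- esgtools:::triphasic_template(13, 3, 1000)
  for (e in seq(1000, n - 1000, by = 763))
    x[e + seq_along(tmpl)] <- x[e + seq_along(tmpl)] + tmpl
  pk <- detect_r_peaks(rep(0, 10), fs = 1000,
                       override = seq(1000, n - 1500, by = 1000))
  m <- fit_obs(x, pk)
  cl <- suppressWarnings(remove_cardiac(x, m, pk))
  expect_lt(abs(sqrt(mean(cl^2)) - sqrt(mean(x^2))) / sqrt(mean(x^2)), 0.02)
})

test_that("OBS removal preserves the trial-averaged evoked response", {
  base <- sim_config(n_trials = 100, seed = 31,
                     stim_artifact = list(amplitude_uv = 0,
                                          window_ms = c(-2, 4)))
  cfg_ev <- base
  cfg_ev$cardiac <- NULL
  cfg_ev$noise <- list(white_sd_uv = 0, pink_sd_uv = 0, pink_exponent = 1,
                       line_amp_uv = 0)
  sim <- generate_recording(base)
  simE <- generate_recording(cfg_ev)   # same evoked component, in isolation
  pk <- detect_r_peaks(sim$recording)
  recL <- simE$recording
  for (ch in c(3, 8)) {
    m <- fit_obs(sim$recording$data[ch, ], pk)
    recL$data[ch, ] <- suppressWarnings(
      remove_cardiac(simE$recording$data[ch, ], m, pk))
  }
  epE <- epoch_and_baseline(simE$recording, channels = c(3, 8))
  epL <- epoch_and_baseline(recL, channels = c(3, 8))
  i13 <- which.min(abs(epE$time_ms - 13))
  aE <- epoch_average(epE)[, i13]
  aL <- epoch_average(epL)[, i13]
  expect_lt(max(abs(aL - aE) / abs(aE)), 0.05)
})

test_that("repeating the removal changes almost nothing further", {
  cfg <- sim_config(n_trials = 60, seed = 37,
                    stim_artifact = list(amplitude_uv = 0,
                                         window_ms = c(-2, 4)))
  sim <- generate_recording(cfg)
  x <- sim$recording$data[2, ]
  pk <- detect_r_peaks(sim$recording)
  m <- fit_obs(x, pk)
  c1 <- suppressWarnings(remove_cardiac(x, m, pk))
  c2 <- suppressWarnings(remove_cardiac(c1, m, pk))
  first <- abs(sqrt(mean(c1^2)) - sqrt(mean(x^2)))
  second <- abs(sqrt(mean(c2^2)) - sqrt(mean(c1^2)))
  expect_lt(second, 0.01 * first)
})

test_that("R-peak annotations round-trip as TSV", {
  pk <- detect_r_peaks(rep(0, 10), fs = 1000,
                       override = c(100L, 1100L, 2050L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_r_peaks(pk, path)
  pk2 <- read_r_peaks(path)
  expect_equal(pk2$peak_samples, pk$peak_samples)
  expect_equal(pk2$median_rr, pk$median_rr)
})
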