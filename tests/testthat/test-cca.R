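test_that("training matrices tile the average with 11 samples per trial", {
  set.seed(40)
  ep <- make_epochs(array(rnorm(20 * 3 * 30), c(20, 3, 30)),
                    window_ms = c(0, 29))
  tm <- build_train_matrices(ep, c(8, 18))
  expect_equal(tm$n_win, 11)
  expect_equal(ncol(tm$X), 20 * 11)
  expect_equal(dim(tm$X), dim(tm$Y))
  # Y is the tiled average of the X segments
  avg <- matrix(0, 3, 11)
  for (k in 1:20) avg <- avg + ep$data[k, , 9:19] / 20
  expect_equal(tm$Y[, 1:11], avg)
  expect_equal(tm$Y[, 12:22], avg)
  # column count arithmetic at scale: N trials x 11 samples
  expect_equal(2000 * 11, 22000)
})

test_that("two identical trials make X equal Y", {
  one <- matrix(rnorm(3 * 30), 3)
  dat <- array(0, c(2, 3, 30))
  dat[1, , ] <- one; dat[2, , ] <- one
  tm <- build_train_matrices(make_epochs(dat, window_ms = c(0, 29)),
                             c(8, 18))
  expect_equal(tm$X, tm$Y)
  expect_error(build_train_matrices(make_epochs(dat, window_ms = c(0, 29)),
                                    c(25, 40)),
               "outside")
})

test_that("noiseless rank-1 data give correlation 1 and the true pattern", {
  p <- c(0.8, 0.5, 0.33); p <- p / sqrt(sum(p^2))
  tmpl <- sin(seq(0, pi, length.out = 11))
  dat <- array(0, c(12, 3, 30))
  for (k in 1:12) dat[k, , 9:19] <- outer(p, tmpl)
  tm <- build_train_matrices(make_epochs(dat, window_ms = c(0, 29)),
                             c(8, 18))
  m <- suppressWarnings(train_ccar(tm))
  expect_equal(m$corrs[1], 1, tolerance = 1e-5)
  expect_equal(cos_sim(m$patterns[, 1], p), 1, tolerance = 1e-6)
})

test_that("train_ccar matches the brute-force generalized eigensolution", {
  set.seed(42)
  for (rep in 1:5) {
    n_ch <- sample(3:5, 1)
    n_tr <- sample(6:20, 1)
    dat <- array(rnorm(n_tr * n_ch * 30), c(n_tr, n_ch, 30))
    # plant a weak structured component so correlations are not pure noise
    p <- rnorm(n_ch)
    for (k in seq_len(n_tr))
      dat[k, , 9:19] <- dat[k, , 9:19] + outer(p, sin(1:11))
    tm <- build_train_matrices(make_epochs(dat, window_ms = c(0, 29)),
                               c(8, 18))
    m <- suppressWarnings(train_ccar(tm, regularization = 0))
    or <- oracle_cca(tm$X, tm$Y)
    expect_equal(m$corrs, or$corrs[seq_along(m$corrs)], tolerance = 1e-8)
    for (k in seq_len(ncol(m$Wx)))
      expect_equal(cos_sim(m$Wx[, k], or$Wx[, k]), 1, tolerance = 1e-6)
    # canonical correlations are in [0, 1] and non-increasing
    expect_true(all(diff(m$corrs) <= 1e-12))
    expect_true(all(m$corrs <= 1 + 1e-12 & m$corrs >= 0))
  }
})

test_that("train_ccar agrees with the stats::cancor reference", {
  set.seed(43)
  dat <- array(rnorm(30 * 4 * 30), c(30, 4, 30))
  tm <- build_train_matrices(make_epochs(dat, window_ms = c(0, 29)),
                             c(8, 18))
  m <- suppressWarnings(train_ccar(tm, regularization = 0))
  cc <- stats::cancor(t(tm$X), t(tm$Y))
  expect_equal(m$corrs[1:4], cc$cor[1:4], tolerance = 1e-8)
})

test_that("rank-deficient data error without regularization", {
  dat <- array(rnorm(10 * 3 * 30), c(10, 3, 30))
  dat[, 3, ] <- dat[, 1, ]           # duplicate channel
  tm <- build_train_matrices(make_epochs(dat, window_ms = c(0, 29)),
                             c(8, 18))
  expect_error(suppressWarnings(train_ccar(tm, regularization = 0)),
               "rank-deficient")
  expect_silent(suppressWarnings(train_ccar(tm, regularization = 1e-6)))
})

test_that("a sample-to-feature warning fires on short training data", {
  dat <- array(rnorm(4 * 3 * 30), c(4, 3, 30))
  tm <- build_train_matrices(make_epochs(dat, window_ms = c(0, 29)),
                             c(8, 18))
  expect_warning(train_ccar(tm), "samples per feature")
})

test_that("component selection finds the planted response and its sign", {
  sim <- generate_recording(quiet_config(n_trials = 300, seed = 44,
                                         amplitude_uv = 3, white_sd = 3))
  ep <- epoch_and_baseline(sim$recording, channels = 1:17)
  tm <- build_train_matrices(ep, c(8, 18))
  m <- select_component(train_ccar(tm), ep, 13, -1, 5, "SC6")
  expect_equal(m$selected, 1L)
  tr <- apply_filter(m, ep)
  avg <- colMeans(tr[ep$retained, ])
  i <- which(ep$time_ms >= 0)
  ipk <- i[which.max(abs(avg[i]))]
  expect_lt(avg[ipk], 0)                     # negative peak
  expect_lt(abs(ep$time_ms[ipk] - 13), 3)
  # latency-tolerance sweep: 3 ms and 5 ms select the same component
  m3 <- select_component(train_ccar(tm), ep, 13.3, -1, 3, "SC6")
  expect_equal(m3$selected, m$selected)
  # global sign flip of the input leaves the selected time-course unchanged
  ep2 <- ep; ep2$data <- -ep$data
  m2 <- select_component(train_ccar(build_train_matrices(ep2, c(8, 18))),
                         ep2, 13, -1, 5, "SC6")
  tr2 <- apply_filter(m2, ep2)
  a1 <- colMeans(tr[ep$retained, ]); a2 <- colMeans(tr2[ep$retained, ])
  expect_equal(a2 / max(abs(a2)), a1 / max(abs(a1)), tolerance = 1e-6)
  # failure lists diagnostics
  expect_error(select_component(train_ccar(tm), ep, 100, -1, 2, "SC6"),
               "no component qualifies")
})

test_that("apply_filter is the linear projection it claims to be", {
  sim <- generate_recording(quiet_config(n_trials = 40, seed = 45,
                                         amplitude_uv = 3))
  ep <- epoch_and_baseline(sim$recording, channels = 1:17)
  m <- suppressWarnings(
    select_component(train_ccar(build_train_matrices(ep, c(8, 18))),
                     ep, 13, -1, 5, "SC6"))
  tr <- apply_filter(m, ep)
  k <- 5
  expect_equal(tr[k, ], drop(m$sign * crossprod(m$Wx[, m$selected],
                                                ep$data[k, , ])))
  # zero epochs give zero traces
  ep0 <- ep; ep0$data[] <- 0
  expect_true(all(apply_filter(m, ep0) == 0))
  # channel mismatch is an error
  epx <- ep; epx$channels$label[1] <- "WRONG"
  expect_error(apply_filter(m, epx), "channel order")
})

test_that("the component average beats the anatomical channel in SNR", {
  # SNRs as in the full analysis: band-passed averages, individual peak
  # latencies; the anatomical target channel carries the largest planted
  # signal of any single grid channel
  res <- vapply(1:20, function(s) {
    sim <- generate_recording(quiet_config(n_trials = 200, seed = 500 + s,
                                           amplitude_uv = 2, white_sd = 4))
    rec <- filter_zero_phase(sim$recording, band = c(30, 400),
                             channels = 1:17)
    ep <- epoch_and_baseline(rec, channels = 1:17)
    m <- tryCatch(
      select_component(train_ccar(build_train_matrices(ep, c(8, 18))),
                       ep, 13, -1, 5, "SC6"),
      error = function(e) NULL)
    if (is.null(m)) return(c(NA, NA))
    avg_c <- colMeans(apply_filter(m, ep)[ep$retained, ])
    mc <- measure_evoked(avg_c, ep$time_ms, c(8, 18), -1,
                         group_latency_ms = 13)
    mt <- measure_evoked(epoch_average(ep, "SC6")[1, ], ep$time_ms,
                         c(8, 18), -1, group_latency_ms = 13)
    c(mc$snr, mt$snr)
  }, c(0, 0))
  expect_gte(mean(res[1, ] >= res[2, ], na.rm = TRUE), 0.9)
  # and the median SNR gain is at least two-fold
  expect_gte(median(res[1, ] / res[2, ], na.rm = TRUE), 2)
})

test_that("subsample stability separates task from rest", {
  cfg <- quiet_config(n_trials = 80, seed = 46, amplitude_uv = 4,
                      white_sd = 3)
  task <- generate_recording(cfg)
  rest <- generate_resting_state(cfg)
  ep_t <- epoch_and_baseline(task$recording, channels = 1:17)
  ep_r <- epoch_and_baseline(rest$recording,
                             events = rest$truth$event_samples,
                             channels = 1:17)
  st <- suppressWarnings(
    stability_control(ep_t, ep_r, c(8, 18), frac = 0.5, n_rep = 60,
                      seed = 2))
  expect_gt(st$task_mean_abs_corr, st$rest_mean_abs_corr + 0.2)
  expect_gt(st$task_mean_abs_corr, 0.9)
  # no subsampling: all repetitions identical
  st1 <- suppressWarnings(
    stability_control(ep_t, NULL, c(8, 18), frac = 1, n_rep = 5, seed = 1))
  expect_equal(st1$task_mean_abs_corr, 1)
  # deterministic under a fixed seed
  st2 <- suppressWarnings(
    stability_control(ep_t, NULL, c(8, 18), frac = 0.5, n_rep = 10,
                      seed = 7))
  st3 <- suppressWarnings(
    stability_control(ep_t, NULL, c(8, 18), frac = 0.5, n_rep = 10,
                      seed = 7))
  expect_identical(st2$task_corrs, st3$task_corrs)
  expect_error(stability_control(ep_t, NULL, c(8, 18), n_rep = 1), "n_rep")
})
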