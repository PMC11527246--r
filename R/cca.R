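#' Build CCAR training matrices from an epoch set
#'
#' Canonical correlation average regression (CCAR) trains on two channel x
#' sample matrices of equal size: `X` holds all retained single-trial
#' segments within a short window around the expected evoked peak,
#' concatenated in time, and `Y` holds the trial average of those segments
#' tiled once per trial. With the standard +/-5 ms window at 1 kHz every
#' trial contributes 11 samples.
#'
#' @param epochs an `esg_epochs`.
#' @param window_ms `c(t0, t1)` training window (ms relative to stimulus),
#'   inside the epoch window.
#' @return a `train_matrices` list with `X`, `Y` (channels x
#'   (n_trials * n_win)), `n_trials`, `n_win`, `window_ms`, `fs`,
#'   `channel_labels`, and `trial_segments` (channels x n_win x n_trials
#'   array, for reuse).
#' @export
build_train_matrices <- function(epochs, window_ms) {
  sel <- which(epochs$retained)
  if (length(sel) < 2) stop("need at least 2 retained trials")
  tol <- 1e-9
  if (window_ms[1] < epochs$window_ms[1] - tol ||
      window_ms[2] > epochs$window_ms[2] + tol)
    stop("training window lies outside the epoch window")
  widx <- which(epochs$time_ms >= window_ms[1] - tol &
                epochs$time_ms <= window_ms[2] + tol)
  n_win <- length(widx)
  n_ch <- dim(epochs$data)[2]
  seg <- array(0, c(n_ch, n_win, length(sel)))
  for (k in seq_along(sel))
    seg[, , k] <- epochs$data[sel[k], , widx]
  X <- matrix(seg, n_ch, n_win * length(sel))
  avg <- apply(seg, c(1, 2), mean)
  Y <- matrix(avg, n_ch, n_win * length(sel))  # tiled average
  structure(list(X = X, Y = Y, n_trials = length(sel), n_win = n_win,
                 window_ms = window_ms, fs = epochs$fs,
                 channel_labels = epochs$channels$label,
                 trial_segments = seg),
            class = "train_matrices")
}

# Inverse principal square root of a symmetric PSD matrix, dropping
# directions below `tol` times the leading eigenvalue. Returns the kept rank.
inv_sqrt_sym <- function(S, tol = 1e-12) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  list(W = e$vectors[, keep, drop = FALSE] %*%
         diag(1 / sqrt(e$values[keep]), sum(keep)),
       rank = sum(keep))
}

#' Train a CCAR spatial filter
#'
#' Solves the canonical correlation problem between the concatenated
#' single-trial matrix `X` and the tiled-average matrix `Y`: finds weight
#' vectors `w_x`, `w_y` maximizing `cor(w_x' X, w_y' Y)`, via whitening of
#' the two covariance matrices and a singular value decomposition of the
#' whitened cross-covariance. Components are ordered by canonical
#' correlation. Activation patterns — the sensor-space topography of each
#' component — are the filter weights multiplied by the covariance matrix of
#' `X`.
#'
#' A ridge term `regularization * trace(C)/d` is added to each covariance
#' diagonal for conditioning; with `regularization = 0` a rank-deficient `X`
#' is an error. A warning is issued when the sample-to-feature ratio falls
#' below 50 columns per channel, below which canonical correlations become
#' unreliable.
#'
#' @param tm a `train_matrices` object from [build_train_matrices()].
#' @param regularization relative ridge weight (default `1e-6`).
#' @return a `ccar_model`: list with `Wx`, `Wy` (channels x components),
#'   `corrs` (descending, in `[0, 1]`), `patterns` (channels x components),
#'   `train_window_ms`, `fs`, `channel_labels`, `selected` (`NA` until
#'   [select_component()]), `sign`.
#' @export
train_ccar <- function(tm, regularization = 1e-6) {
  X <- tm$X - rowMeans(tm$X)
  Y <- tm$Y - rowMeans(tm$Y)
  n <- ncol(X)
  d <- nrow(X)
  if (n < 50 * d)
    warning("only ", round(n / d, 1), " samples per feature; ",
            "at least 50 are advisable for stable canonical correlations")
  Cxx <- tcrossprod(X) / (n - 1)
  Cyy <- tcrossprod(Y) / (n - 1)
  Cxy <- tcrossprod(X, Y) / (n - 1)
  if (regularization > 0) {
    Cxx_r <- Cxx + diag(regularization * sum(diag(Cxx)) / d, d)
    Cyy_r <- Cyy + diag(regularization * sum(diag(Cyy)) / d, d)
  } else {
    Cxx_r <- Cxx; Cyy_r <- Cyy
    if (inv_sqrt_sym(Cxx)$rank < d || inv_sqrt_sym(Cyy)$rank < d)
      stop("rank-deficient training data with zero regularization; ",
           "set `regularization > 0` or drop collinear channels")
  }
  wx <- inv_sqrt_sym(Cxx_r)
  wy <- inv_sqrt_sym(Cyy_r)
  K <- crossprod(wx$W, Cxy) %*% wy$W
  sv <- svd(K)
  corrs <- pmin(pmax(sv$d, 0), 1)
  Wx <- wx$W %*% sv$u
  Wy <- wy$W %*% sv$v
  patterns <- Cxx %*% Wx
  rownames(patterns) <- rownames(Wx) <- rownames(Wy) <- tm$channel_labels
  structure(list(Wx = Wx, Wy = Wy, corrs = corrs, patterns = patterns,
                 train_window_ms = tm$window_ms, fs = tm$fs,
                 channel_labels = tm$channel_labels,
                 selected = NA_integer_, sign = 1),
            class = "ccar_model")
}

#' @export
print.ccar_model <- function(x, ...) {
  cat("<ccar_model> ", length(x$channel_labels), " channels, ",
      ncol(x$Wx), " components; corrs: ",
      paste(sprintf("%.3f", utils::head(x$corrs, 4)), collapse = ", "),
      if (ncol(x$Wx) > 4) ", ..." else "", "\n", sep = "")
  if (!is.na(x$selected))
    cat("  selected component ", x$selected, " (sign ",
        ifelse(x$sign > 0, "+", "-"), ")\n", sep = "")
  invisible(x)
}

#' Select and sign-normalize a CCAR component
#'
#' Among the first `n_candidates` components (by canonical correlation),
#' selects the one whose filtered trial average has its dominant extremum
#' within `latency_tol_ms` of the expected latency, and — when a target
#' channel is given — whose activation pattern is focal over the grid
#' target: the target electrode must carry at least `pattern_frac` of the
#' largest absolute pattern weight. The pattern criterion is deliberately
#' polarity-free (absolute pattern polarity depends on the reference
#' convention, and CCA itself is sign blind), standing in for the visual
#' check that the topography is the expected radial dipole over the cord.
#' CCA is insensitive to polarity, so the filter sign is then set so the
#' average peak has the expected polarity; a global sign flip of the input
#' therefore leaves the selected component time-course unchanged. Ties
#' break to the lower component index.
#'
#' @param model a `ccar_model`.
#' @param epochs the `esg_epochs` the model was trained on.
#' @param expected_latency_ms expected peak latency (e.g., 13 for the
#'   cervical response to upper-limb stimulation, 24 for the lumbar one).
#' @param expected_polarity `-1` (negative peak) or `+1`.
#' @param latency_tol_ms acceptance half-width around the expected latency.
#' @param target_channel optional grid channel label for the pattern
#'   focality check.
#' @param n_candidates number of leading components eligible (default 2).
#' @param pattern_frac minimum |pattern| at the target relative to the
#'   largest |pattern| weight (default 0.5, loose enough for the
#'   rostro-caudal shifts seen in real topographies).
#' @return the model with `selected` and `sign` set.
#' @export
select_component <- function(model, epochs, expected_latency_ms,
                             expected_polarity = -1, latency_tol_ms = 5,
                             target_channel = NULL, n_candidates = 2,
                             pattern_frac = 0.5) {
  avg <- epoch_average(epochs)
  post <- epochs$time_ms >= 0
  diag_lines <- character(0)
  for (k in seq_len(min(n_candidates, ncol(model$Wx)))) {
    trace <- drop(crossprod(model$Wx[, k], avg))
    tr_post <- trace[post]
    t_post <- epochs$time_ms[post]
    ipk <- which.max(abs(tr_post))
    s <- expected_polarity * sign(tr_post[ipk])
    if (s == 0) next
    lat <- t_post[ipk]
    lat_ok <- abs(lat - expected_latency_ms) <= latency_tol_ms
    pat_ok <- TRUE
    if (!is.null(target_channel)) {
      pt <- model$patterns[match(target_channel, model$channel_labels), k]
      pat_ok <- abs(pt) >= pattern_frac * max(abs(model$patterns[, k]))
    }
    if (lat_ok && pat_ok) {
      model$selected <- k
      model$sign <- s
      return(model)
    }
    diag_lines <- c(diag_lines, sprintf(
      "component %d: peak at %.1f ms (expected %.1f +/- %.1f), pattern %s",
      k, lat, expected_latency_ms, latency_tol_ms,
      if (pat_ok) "focal at target" else "not focal at target"))
  }
  stop("no component qualifies:\n  ", paste(diag_lines, collapse = "\n  "))
}

#' Apply a CCAR spatial filter to epochs
#'
#' Projects every epoch onto the selected (sign-normalized) component,
#' yielding single-trial component traces in arbitrary units. The epoch set
#' must have the same channel order the model was trained on.
#'
#' @param model a `ccar_model` with a selected component (or pass
#'   `component` to override).
#' @param epochs an `esg_epochs`.
#' @param component optional explicit component index.
#' @return matrix trials x time (all trials, including non-retained ones);
#'   attribute `"time_ms"` carries the epoch time axis.
#' @export
apply_filter <- function(model, epochs, component = NULL) {
  if (is.null(component)) component <- model$selected
  if (is.na(component)) stop("no component selected; run select_component()")
  if (!identical(as.character(epochs$channels$label),
                 as.character(model$channel_labels)))
    stop("channel order of epochs does not match the trained model")
  w <- model$sign * model$Wx[, component]
  n_trial <- dim(epochs$data)[1]
  traces <- matrix(0, n_trial, dim(epochs$data)[3])
  for (k in seq_len(n_trial))
    traces[k, ] <- drop(crossprod(w, epochs$data[k, , ]))
  attr(traces, "time_ms") <- epochs$time_ms
  traces
}

#' Subsample-stability control for CCAR
#'
#' Overfitting control: CCAR is retrained on random halves (fraction `frac`)
#' of the trials, the first component's time course within the training
#' window is stored for each repetition, and the mean pairwise absolute
#' correlation between repetitions is computed. Repeated genuine evoked
#' responses give near-perfect stability; on matched resting-state surrogate
#' epochs (identical trial timings, no evoked response) the filters chase
#' noise and the stability drops. The per-participant means feed a one-tailed
#' paired comparison across participants (see [paired_t()]).
#'
#' @param epochs_task task epochs.
#' @param epochs_rest surrogate epochs from resting-state data with
#'   identical trial timings (may be `NULL` to analyse only the task run).
#' @param window_ms CCA training window.
#' @param frac fraction of trials per subsample (without replacement).
#' @param n_rep number of repetitions (>= 2).
#' @param seed RNG seed.
#' @param regularization passed to [train_ccar()].
#' @return list with `task_mean_abs_corr`, `rest_mean_abs_corr` (NA when no
#'   rest data), and the full pairwise `task_corrs` / `rest_corrs`
#'   distributions (upper-triangle values).
#' @export
stability_control <- function(epochs_task, epochs_rest = NULL, window_ms,
                              frac = 0.5, n_rep = 1000, seed = 1,
                              regularization = 1e-6) {
  if (n_rep < 2) stop("n_rep must be at least 2")
  one_condition <- function(epochs) {
    tm_full <- build_train_matrices(epochs, window_ms)
    seg <- tm_full$trial_segments
    n_tr <- dim(seg)[3]
    n_ch <- dim(seg)[1]; n_win <- dim(seg)[2]
    n_sub <- max(2L, round(frac * n_tr))
    courses <- matrix(0, n_win, n_rep)
    for (r in seq_len(n_rep)) {
      idx <- if (n_sub >= n_tr) seq_len(n_tr)
             else sample.int(n_tr, n_sub)
      sub <- seg[, , idx, drop = FALSE]
      X <- matrix(sub, n_ch, n_win * n_sub)
      avg <- apply(sub, c(1, 2), mean)
      tm <- structure(list(X = X, Y = matrix(avg, n_ch, n_win * n_sub),
                           n_trials = n_sub, n_win = n_win,
                           window_ms = window_ms, fs = epochs$fs,
                           channel_labels = epochs$channels$label,
                           trial_segments = sub),
                      class = "train_matrices")
      m <- suppressWarnings(train_ccar(tm, regularization))
      courses[, r] <- drop(crossprod(m$Wx[, 1], avg))
    }
    cc <- abs(stats::cor(courses))
    cc[upper.tri(cc)]
  }
  set.seed(seed)
  task <- one_condition(epochs_task)
  rest <- if (!is.null(epochs_rest)) one_condition(epochs_rest) else NULL
  list(task_mean_abs_corr = mean(task),
       rest_mean_abs_corr = if (is.null(rest)) NA_real_ else mean(rest),
       task_corrs = task, rest_corrs = rest)
}
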