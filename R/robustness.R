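#' Per-participant trial-count robustness curve
#'
#' How many trials does a single participant need for a significant evoked
#' amplitude? For every participant and every trial count, single-trial
#' amplitudes are resampled with replacement, tested against zero with a
#' one-sample t test, and the procedure is repeated `n_rep` times; the
#' reported cell value is the proportion of significant repetitions.
#'
#' @param amplitudes list of numeric vectors (single-trial amplitudes, one
#'   vector per participant), or a single vector for one participant.
#' @param trial_counts increasing vector of trial counts (default: the
#'   5-to-1000-in-steps-of-10 grid plus 1000).
#' @param n_rep repetitions per cell.
#' @param alpha significance level.
#' @param tail `"two"` (default) or `"one"`.
#' @param seed RNG seed.
#' @return a `robustness_curve`: list with `proportions` (participants x
#'   trial counts matrix), `trial_counts`, `n_rep`, `alpha`, `seed`,
#'   `mode = "participant"`.
#' @export
participant_trial_curve <- function(amplitudes,
                                    trial_counts = default_trial_grid(),
                                    n_rep = 1000, alpha = 0.05,
                                    tail = c("two", "one"), seed = 1) {
  tail <- match.arg(tail)
  if (!is.list(amplitudes)) amplitudes <- list(amplitudes)
  if (any(vapply(amplitudes, length, 0L) < 2))
    stop("every participant needs at least 2 trial amplitudes")
  stopifnot(all(diff(trial_counts) > 0))
  set.seed(seed)
  prop <- matrix(0, length(amplitudes), length(trial_counts))
  for (p in seq_along(amplitudes)) {
    v <- amplitudes[[p]]
    for (j in seq_along(trial_counts)) {
      nt <- trial_counts[j]
      draws <- matrix(sample(v, n_rep * nt, replace = TRUE), n_rep, nt)
      prop[p, j] <- mean(t_sig_rows(draws, alpha, tail))
    }
  }
  dimnames(prop) <- list(names(amplitudes), trial_counts)
  structure(list(proportions = prop, trial_counts = trial_counts,
                 participant_counts = NULL, n_rep = n_rep, alpha = alpha,
                 seed = seed, mode = "participant"),
            class = "robustness_curve")
}

#' Group-level experiment simulation
#'
#' Monte-Carlo estimate of the joint number of participants and trials
#' needed for a significant group effect: per simulated experiment,
#' participants are sampled with replacement, then trials with replacement
#' within each sampled participant (independently per occurrence); the
#' trials are averaged per participant and the participant means are tested
#' against zero with a one-sample t test. Reported is the proportion of
#' significant experiments per (participants, trials) cell.
#'
#' @param amplitudes list of per-participant single-trial amplitude vectors.
#' @param participant_counts increasing vector of group sizes (>= 2 each).
#' @param trial_counts increasing vector of trial counts.
#' @inheritParams participant_trial_curve
#' @return a `robustness_curve` with `proportions` (participant counts x
#'   trial counts) and `mode = "group"`.
#' @export
group_experiment_sim <- function(amplitudes, participant_counts,
                                 trial_counts = default_trial_grid(),
                                 n_rep = 1000, alpha = 0.05,
                                 tail = c("two", "one"), seed = 1) {
  tail <- match.arg(tail)
  stopifnot(is.list(amplitudes), length(amplitudes) >= 2)
  if (any(participant_counts < 2))
    stop("participant counts of 1 give no group variance")
  stopifnot(all(diff(participant_counts) > 0), all(diff(trial_counts) > 0))
  set.seed(seed)
  P <- length(amplitudes)
  prop <- matrix(0, length(participant_counts), length(trial_counts))
  for (i in seq_along(participant_counts)) {
    np <- participant_counts[i]
    for (j in seq_along(trial_counts)) {
      nt <- trial_counts[j]
      means <- matrix(0, n_rep, np)
      ids <- matrix(sample.int(P, n_rep * np, replace = TRUE), n_rep, np)
      for (r in seq_len(n_rep)) {
        for (q in seq_len(np)) {
          v <- amplitudes[[ids[r, q]]]
          means[r, q] <- mean(v[sample.int(length(v), nt, replace = TRUE)])
        }
      }
      prop[i, j] <- mean(t_sig_rows(means, alpha, tail))
    }
  }
  dimnames(prop) <- list(participant_counts, trial_counts)
  structure(list(proportions = prop, trial_counts = trial_counts,
                 participant_counts = participant_counts, n_rep = n_rep,
                 alpha = alpha, seed = seed, mode = "group"),
            class = "robustness_curve")
}

#' @rdname participant_trial_curve
#' @export
default_trial_grid <- function() unique(c(seq(5, 995, by = 10), 1000))

# Row-wise one-sample t significance on a matrix of resamples.
t_sig_rows <- function(x, alpha, tail) {
  n <- ncol(x)
  m <- rowMeans(x)
  s2 <- (rowSums(x^2) - n * m^2) / (n - 1)
  s2[s2 < 0] <- 0
  tt <- m / sqrt(s2 / n)
  tt[!is.finite(tt)] <- 0
  if (tail == "two") 2 * stats::pt(-abs(tt), n - 1) < alpha
  else stats::pt(-abs(tt), n - 1) < alpha
}

#' @export
print.robustness_curve <- function(x, ...) {
  cat("<robustness_curve> mode=", x$mode, ", ",
      if (!is.null(x$participant_counts))
        paste0(length(x$participant_counts), " group sizes x ") else "",
      length(x$trial_counts), " trial counts, n_rep=", x$n_rep,
      ", alpha=", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Export a robustness curve as long-format TSV
#'
#' Columns: `level` (participant index or group size), `n_trials`,
#' `proportion`.
#'
#' @param curve a `robustness_curve`.
#' @param path file path.
#' @export
write_robustness_curve <- function(curve, path) {
  pr <- curve$proportions
  lev <- if (curve$mode == "group") curve$participant_counts
         else seq_len(nrow(pr))
  long <- data.frame(level = rep(lev, times = ncol(pr)),
                     n_trials = rep(curve$trial_counts, each = nrow(pr)),
                     proportion = as.vector(pr))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
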