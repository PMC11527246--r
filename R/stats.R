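#' One-sample t test with effect size
#'
#' Standard one-sample t test of a mean against zero, reporting the
#' statistic, p value, two-sided 95% confidence interval of the mean, and
#' Cohen's d (`mean / SD`).
#'
#' @param values numeric vector (n >= 2, nonzero variance).
#' @param tail `"two"` or `"one"`; a one-tailed test is directional in the
#'   sign of the observed mean.
#' @return a `test_result`: list with `statistic`, `p_value`, `ci_95`,
#'   `cohens_d`, `n`, `tail`, `degenerate` (TRUE when the variance was zero
#'   and the test is reported as p = 1).
#' @export
one_sample_t <- function(values, tail = c("two", "one")) {
  tail <- match.arg(tail)
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  s <- stats::sd(values)
  if (s == 0) stop("zero variance; t statistic undefined")
  m <- mean(values)
  tt <- m / (s / sqrt(n))
  p <- if (tail == "two") 2 * stats::pt(-abs(tt), n - 1)
       else stats::pt(-abs(tt), n - 1)
  ci <- m + stats::qt(c(0.025, 0.975), n - 1) * s / sqrt(n)
  structure(list(statistic = tt, p_value = p, ci_95 = ci, cohens_d = m / s,
                 n = n, tail = tail, degenerate = FALSE),
            class = "test_result")
}

#' Paired t test
#'
#' A one-sample t test on the pairwise differences `a - b`. Identical
#' vectors (zero-variance differences) are reported as `p = 1` with
#' `degenerate = TRUE` rather than as an error, since an exactly null paired
#' contrast is a meaningful outcome.
#'
#' @param a,b paired numeric vectors of equal length.
#' @inheritParams one_sample_t
#' @return a `test_result` (see [one_sample_t()]).
#' @export
paired_t <- function(a, b, tail = c("two", "one")) {
  tail <- match.arg(tail)
  stopifnot(length(a) == length(b))
  d <- a - b
  if (stats::sd(d) == 0) {
    return(structure(list(statistic = 0, p_value = 1,
                          ci_95 = c(mean(d), mean(d)), cohens_d = 0,
                          n = length(d), tail = tail, degenerate = TRUE),
                     class = "test_result"))
  }
  one_sample_t(d, tail)
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g (%s-tailed), d = %.2f, 95%% CI [%.3f; %.3f]%s\n",
              x$n - 1, x$statistic, x$p_value, x$tail, x$cohens_d,
              x$ci_95[1], x$ci_95[2],
              if (isTRUE(x$degenerate)) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' Interaction ratio
#'
#' Quantifies integrative processing under simultaneous two-digit
#' stimulation as the percentage attenuation of the double-digit response
#' relative to the sum of the single-digit responses:
#' `IR = 100 * ((d1 + d2) - d12) / (d1 + d2)`. 0% means purely additive
#' responses (no integration), 100% full suppression, negative values
#' amplification. The ratio is scale invariant, so it applies equally to
#' microvolt amplitudes and to arbitrary-unit component amplitudes.
#'
#' @param d1,d2 response amplitudes to the two single-digit stimulations.
#' @param d12 amplitude to simultaneous double-digit stimulation.
#' @return IR in percent (vectorized over the inputs).
#' @export
interaction_ratio <- function(d1, d2, d12) {
  s <- d1 + d2
  if (any(s == 0)) stop("IR undefined: single-digit amplitudes sum to zero")
  100 * (s - d12) / s
}

#' Minimal sample size from noncentral-t power
#'
#' Smallest n such that a one-sample t test on n observations with true
#' effect size d (noncentrality `|d| * sqrt(n)`) reaches the target power at
#' the given alpha level.
#'
#' @param d effect size (Cohen's d, nonzero).
#' @param alpha significance level.
#' @param power target power (`alpha < power < 1`).
#' @param tail `"one"` or `"two"`.
#' @param n_max search cap.
#' @return minimal integer n.
#' @export
#' @examples
#' sample_size_power(0.5, tail = "one")    # 36
#' sample_size_power(0.62, tail = "one")   # 24
sample_size_power <- function(d, alpha = 0.05, power = 0.9,
                              tail = c("one", "two"), n_max = 1e6) {
  tail <- match.arg(tail)
  if (d == 0) stop("effect size must be nonzero")
  if (!(alpha > 0 && alpha < power && power < 1))
    stop("need 0 < alpha < power < 1")
  pow_at <- function(n) {
    df <- n - 1
    ncp <- abs(d) * sqrt(n)
    if (tail == "one") {
      1 - stats::pt(stats::qt(1 - alpha, df), df, ncp = ncp)
    } else {
      crit <- stats::qt(1 - alpha / 2, df)
      1 - stats::pt(crit, df, ncp = ncp) + stats::pt(-crit, df, ncp = ncp)
    }
  }
  for (n in 2:n_max) if (pow_at(n) >= power) return(n)
  stop("target power unreachable within n_max")
}

#' Spatiotemporal cluster-based permutation test
#'
#' Compares two paired conditions (participants x channels x time) with
#' family-wise error control over the whole channel x time grid: a paired t
#' test at every sample, clustering of suprathreshold samples (two-sided at
#' `cluster_alpha`) by spatiotemporal adjacency within one t-sign, cluster
#' mass as the sum of t values, and a null distribution of the maximum
#' absolute cluster mass under random per-participant condition swaps (sign
#' flips of the paired differences). When `2^n <= 4096` the sign flips are
#' enumerated exhaustively; otherwise `n_perm` random flips are drawn and
#' the observed labelling is included in the null.
#'
#' @param cond_a,cond_b numeric arrays, participants x channels x time,
#'   matched along the first dimension.
#' @param adjacency logical channels x channels adjacency matrix (e.g., from
#'   [montage_adjacency()]); a warning lists disconnected islands.
#' @param time_ms optional time axis for reporting (defaults to sample
#'   indices).
#' @param time_window optional `c(lo, hi)` restriction of the tested window
#'   (in `time_ms` units).
#' @param n_perm random permutations when exhaustive enumeration is not
#'   feasible (default 1000; < 100 warns).
#' @param cluster_alpha cluster-forming threshold alpha (two-sided paired t).
#' @param alpha cluster-level significance (reported, not enforced).
#' @param seed RNG seed for random permutations.
#' @return a `cluster_result`: list with `clusters` (data.frame: id, sign,
#'   n_cells, t_start, t_end, mass, p_value, channels as comma-joined
#'   labels), `t_field`, `label_field`, `t_crit`, `n_permutations`,
#'   `exhaustive`, `cluster_alpha`, `alpha`, `time_ms`.
#' @export
cluster_permutation <- function(cond_a, cond_b, adjacency, time_ms = NULL,
                                time_window = NULL, n_perm = 1000,
                                cluster_alpha = 0.05, alpha = 0.05,
                                seed = 1) {
  stopifnot(identical(dim(cond_a), dim(cond_b)))
  n <- dim(cond_a)[1]; nch <- dim(cond_a)[2]; nt <- dim(cond_a)[3]
  stopifnot(nrow(adjacency) == nch)
  if (n_perm < 100) warning("fewer than 100 permutations; p values coarse")
  if (is.null(time_ms)) time_ms <- seq_len(nt) - 1
  if (!is.null(time_window)) {
    keep <- time_ms >= time_window[1] & time_ms <= time_window[2]
    cond_a <- cond_a[, , keep, drop = FALSE]
    cond_b <- cond_b[, , keep, drop = FALSE]
    time_ms <- time_ms[keep]
    nt <- sum(keep)
  }
  # connectivity diagnostics: islands under the adjacency
  comp <- rep(0L, nch)
  cid <- 0L
  for (s0 in seq_len(nch)) {
    if (comp[s0] != 0L) next
    cid <- cid + 1L
    front <- s0
    comp[s0] <- cid
    while (length(front)) {
      nxt <- which(adjacency[front[1], ] & comp == 0L)
      comp[nxt] <- cid
      front <- c(front[-1], nxt)
    }
  }
  if (cid > 1L)
    warning("adjacency graph has ", cid, " disconnected islands: ",
            paste(tapply(seq_len(nch), comp, paste, collapse = "+"),
                  collapse = " | "))
  adj_list <- lapply(seq_len(nch), function(c) which(adjacency[c, ]) - 1L)

  D <- matrix(cond_a - cond_b, n)          # participants x (nch * nt)
  ss <- colSums(D^2)
  t_of_means <- function(m) {
    varnum <- ss - n * m^2
    varnum[varnum < 0] <- 0
    se <- sqrt(varnum / (n - 1) / n)
    tt <- m / se
    tt[!is.finite(tt)] <- 0
    tt
  }
  t_obs <- t_of_means(colMeans(D))
  t_crit <- stats::qt(1 - cluster_alpha / 2, n - 1)
  t_field <- matrix(t_obs, nch, nt)
  lab <- cluster_label_cpp(t_field, t_crit, adj_list)

  exhaustive <- 2^n <= 4096
  if (exhaustive) {
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    set.seed(seed)
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    S <- rbind(rep(1, n), S)               # include the observed labelling
  }
  Tperm <- t_of_means(crossprod(D, t(S)) / n)     # (nch*nt) x nperm
  null_max <- perm_max_mass_cpp(Tperm, nch, nt, t_crit, adj_list)

  masses <- lab$mass
  clusters <- data.frame(id = integer(0), sign = integer(0),
                         n_cells = integer(0), t_start = numeric(0),
                         t_end = numeric(0), mass = numeric(0),
                         p_value = numeric(0), channels = character(0),
                         stringsAsFactors = FALSE)
  ch_labels <- rownames(adjacency)
  if (is.null(ch_labels)) ch_labels <- as.character(seq_len(nch))
  for (k in seq_along(masses)) {
    cells <- which(lab$label == k, arr.ind = TRUE)
    clusters <- rbind(clusters, data.frame(
      id = k, sign = sign(masses[k]), n_cells = nrow(cells),
      t_start = min(time_ms[cells[, 2]]), t_end = max(time_ms[cells[, 2]]),
      mass = masses[k],
      p_value = mean(null_max >= abs(masses[k])),
      channels = paste(ch_labels[sort(unique(cells[, 1]))], collapse = ","),
      stringsAsFactors = FALSE))
  }
  if (nrow(clusters)) clusters <- clusters[order(clusters$p_value), ]
  structure(list(clusters = clusters, t_field = t_field,
                 label_field = lab$label, t_crit = t_crit,
                 n_permutations = length(null_max), exhaustive = exhaustive,
                 cluster_alpha = cluster_alpha, alpha = alpha,
                 time_ms = time_ms, null_max = null_max),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", nrow(x$clusters), " cluster(s), ",
      x$n_permutations,
      if (x$exhaustive) " exhaustive sign flips" else " permutations",
      ", cluster-forming |t| > ", sprintf("%.2f", x$t_crit), "\n", sep = "")
  if (nrow(x$clusters))
    print(x$clusters[, c("id", "sign", "n_cells", "t_start", "t_end",
                         "mass", "p_value")], row.names = FALSE)
  invisible(x)
}

#' Export a cluster report as TSV
#'
#' @param result a `cluster_result`.
#' @param path file path.
#' @export
write_cluster_report <- function(result, path) {
  utils::write.table(result$clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
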