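# Independent oracles, deliberately naive implementations kept separate from
# the package's code paths.

# Brute-force CCA via the generalized eigenproblem on explicit covariance
# inverses (no whitening, no SVD).
oracle_cca <- function(X, Y) {
  X <- X - rowMeans(X); Y <- Y - rowMeans(Y)
  n <- ncol(X)
  Cxx <- tcrossprod(X) / (n - 1)
  Cyy <- tcrossprod(Y) / (n - 1)
  Cxy <- tcrossprod(X, Y) / (n - 1)
  M <- solve(Cxx, Cxy) %*% solve(Cyy, t(Cxy))
  e <- eigen(M)
  ord <- order(Re(e$values), decreasing = TRUE)
  list(corrs = sqrt(pmax(Re(e$values[ord]), 0)),
       Wx = Re(e$vectors[, ord, drop = FALSE]))
}

# Naive spatiotemporal clustering of a t-field (channels x time): BFS over
# suprathreshold cells of one sign.
oracle_clusters <- function(tf, thresh, adj) {
  nch <- nrow(tf); nt <- ncol(tf)
  lab <- matrix(0L, nch, nt)
  masses <- numeric(0)
  nid <- 0L
  for (j in seq_len(nt)) for (c in seq_len(nch)) {
    if (lab[c, j] != 0L || abs(tf[c, j]) <= thresh) next
    nid <- nid + 1L
    pos <- tf[c, j] > 0
    queue <- list(c(c, j)); lab[c, j] <- nid; m <- 0
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      m <- m + tf[cur[1], cur[2]]
      nbrs <- list()
      for (dj in c(-1, 1)) {
        j2 <- cur[2] + dj
        if (j2 >= 1 && j2 <= nt) nbrs <- c(nbrs, list(c(cur[1], j2)))
      }
      for (c2 in which(adj[cur[1], ])) nbrs <- c(nbrs, list(c(c2, cur[2])))
      for (nb in nbrs) {
        v <- tf[nb[1], nb[2]]
        if (lab[nb[1], nb[2]] == 0L && abs(v) > thresh &&
            (v > 0) == pos) {
          lab[nb[1], nb[2]] <- nid
          queue <- c(queue, list(nb))
        }
      }
    }
    masses <- c(masses, m)
  }
  list(label = lab, mass = masses)
}

# Exhaustive sign-flip null of the max |cluster mass| for paired data.
oracle_exact_cluster_p <- function(D3, adj, cluster_alpha = 0.05) {
  n <- dim(D3)[1]; nch <- dim(D3)[2]; nt <- dim(D3)[3]
  D <- matrix(D3, n)
  tcrit <- qt(1 - cluster_alpha / 2, n - 1)
  tstat <- function(M) {
    m <- colMeans(M); s <- apply(M, 2, sd)
    tt <- m / (s / sqrt(n)); tt[!is.finite(tt)] <- 0; tt
  }
  obs <- oracle_clusters(matrix(tstat(D), nch, nt), tcrit, adj)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null_max <- apply(signs, 1, function(s) {
    oc <- oracle_clusters(matrix(tstat(D * s), nch, nt), tcrit, adj)
    if (length(oc$mass)) max(abs(oc$mass)) else 0
  })
  list(obs = obs,
       p = vapply(obs$mass, function(m) mean(null_max >= abs(m)), 0))
}

# Closed-form power of a one-sample t test (noncentral t), independent of
# the package's search routine.
oracle_power <- function(d, n, alpha = 0.05, tail = "one") {
  df <- n - 1; ncp <- abs(d) * sqrt(n)
  if (tail == "one") 1 - pt(qt(1 - alpha, df), df, ncp = ncp)
  else {
    cr <- qt(1 - alpha / 2, df)
    1 - pt(cr, df, ncp = ncp) + pt(-cr, df, ncp = ncp)
  }
}
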