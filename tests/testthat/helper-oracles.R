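# independent oracles used across tests

# exhaustive enumeration of the three monitoring statistics (slow triple
# loops; the reference the vectorized implementation is checked against)
oracle_stat_paths <- function(W, n) {
  k <- nrow(W)
  mn <- mx <- cs <- numeric(k)
  for (kk in seq_len(k)) {
    lo <- apply(W[seq_len(kk), , drop = FALSE], 2, min)
    hi <- apply(W[seq_len(kk), , drop = FALSE], 2, max)
    mn[kk] <- max(abs(lo - W[kk, ])) / sqrt(n)
    mx[kk] <- max(abs(hi - W[kk, ])) / sqrt(n)
    best <- 0
    if (kk >= 2) for (j in 2:kk) for (i in seq_len(j - 1)) {
      best <- max(best, sqrt(sum(((i / j) * W[j, ] - W[i, ])^2)))
    }
    cs[kk] <- best / sqrt(n)
  }
  list(min = mn, max = mx, cusum = cs)
}

# central finite differences of the averaged DPD objective in theta
fd_objective_grad <- function(y, theta, alpha, fam, x1, h = 1e-6) {
  vapply(1:3, function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (mdpde_objective(y, tp, alpha, fam, x1 = x1) -
       mdpde_objective(y, tm, alpha, fam, x1 = x1)) / (2 * h)
  }, numeric(1))
}

random_psd <- function(d = 3) {
  A <- matrix(rnorm(d * d), d)
  crossprod(A) + diag(d) * 0.1
}
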