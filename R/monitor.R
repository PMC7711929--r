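# Score-based CUSUM monitoring of an INGARCH(1,1) count stream against a
# training sample: normalized partial-sum process
#   W_k = Khat^{-1/2} sum_{t<=k} s_t
# (scores at the known theta0, or at the MDPDE from the training sample),
# with three closed-end charts over a planned horizon n:
#   min  : max_k n^{-1/2} || min_{j<=k} W_j - W_k ||_max
#   max  : max_k n^{-1/2} || max_{j<=k} W_j - W_k ||_max
#   cusum: max_{i<j<=k} n^{-1/2} || (i/j) W_j - W_i ||   (Euclidean)

#' Symmetric inverse square root of a PSD matrix
#'
#' Eigendecomposition-based \eqn{M} with \eqn{M \Sigma M \approx I};
#' eigenvalues are floored at \code{floor} times the largest one to guard
#' near-singular score covariances from short training samples.
#'
#' @param mat symmetric positive semidefinite matrix.
#' @param floor relative eigenvalue floor.
#' @return matrix of the same dimension.
#' @export
psd_inv_sqrt <- function(mat, floor = 1e-10) {
  mat <- as.matrix(mat)
  if (max(abs(mat - t(mat))) > 1e-8) stop("matrix is not symmetric")
  if (all(mat == 0)) stop("all-zero matrix has no inverse square root")
  e <- eigen((mat + t(mat)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, floor * max(e$values))
  e$vectors %*% (t(e$vectors) / sqrt(ev))
}

#' Normalized cumulative score process
#'
#' @param sp a \code{\link{score_path}} (or n x d score matrix) on the
#'   monitoring stream.
#' @param khat score covariance from the training sample.
#' @param mode \code{"known"} (scores at the true parameter) or
#'   \code{"estimated"} (scores at the training-sample MDPDE); carried as
#'   metadata.
#' @return object of class \code{"w_process"} with the n x d matrix
#'   \code{w}, \code{khat} and \code{mode}.
#' @export
w_process <- function(sp, khat, mode = c("estimated", "known")) {
  mode <- match.arg(mode)
  S <- if (inherits(sp, "score_path")) sp$scores else as.matrix(sp)
  cs <- apply(S, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)
  structure(list(w = cs %*% psd_inv_sqrt(khat), khat = khat, mode = mode),
            class = "w_process")
}

#' Monitoring statistic paths
#'
#' Per-step values of the three charts over a planned closed-end horizon
#' \code{n}; all statistics are scaled by \eqn{n^{-1/2}} with \code{n} the
#' planned horizon even at interim steps.
#'
#' @param w a \code{\link{w_process}} (or k x d matrix) with \code{k <= n}
#'   rows.
#' @param n planned monitoring horizon.
#' @return list with elements \code{min}, \code{max}, \code{cusum}, each a
#'   numeric path of length k (the cusum path is nondecreasing).
#' @export
stat_paths <- function(w, n) {
  W <- if (inherits(w, "w_process")) w$w else as.matrix(w)
  k <- nrow(W)
  if (k > n) stop("monitoring steps exceed the planned horizon n")
  rowmax <- function(M) do.call(pmax, as.data.frame(abs(M)))
  lo <- apply(W, 2, cummin); hi <- apply(W, 2, cummax)
  if (is.null(dim(lo))) { lo <- matrix(lo, 1L); hi <- matrix(hi, 1L) }
  p_min <- rowmax(lo - W) / sqrt(n)
  p_max <- rowmax(hi - W) / sqrt(n)
  cand <- numeric(k)
  if (k > 1L) for (j in 2:k) {
    i <- seq_len(j - 1L)
    D <- (i / j) %o% W[j, ] - W[i, , drop = FALSE]
    cand[j] <- sqrt(max(.rowSums(D * D, j - 1L, ncol(W))))
  }
  list(min = as.numeric(p_min), max = as.numeric(p_max),
       cusum = cummax(cand) / sqrt(n))
}

alarm_from_path <- function(path, limit) {
  hit <- which(path > limit)
  if (length(hit)) hit[1L] else NA_integer_
}

#' Online monitoring of parameter change in an INGARCH(1,1) stream
#'
#' Runs the score-based CUSUM chart(s) on a monitoring stream given a
#' training sample. In \code{mode = "known"} the score vectors are
#' evaluated at a supplied \code{theta0} and the score covariance
#' \eqn{\hat K_\alpha} comes from the training scores at \code{theta0};
#' in \code{mode = "estimated"} both use the MDPDE
#' \eqn{\hat\theta_{\alpha,m}} fitted on the training sample. An alarm is
#' raised at the first step whose statistic exceeds the control limit.
#'
#' Control limits: \code{"analytic"} uses the Brownian sup quantile
#' (min/max charts only), \code{"mc"} the Monte Carlo quantile of the
#' pairwise bridge functional (cusum chart), \code{"bootstrap"} a
#' parametric bootstrap from the fitted model (any chart; recommended in
#' estimated mode, where parameter estimation inflates the finite-sample
#' distribution).
#'
#' @param stream monitoring count series (length n, the planned horizon).
#' @param train training count series (length m; a warning is given below
#'   50, where \eqn{\hat K} is unstable).
#' @param fam a \code{\link{count_family}}.
#' @param alpha DPD tuning parameter for scores (and the fit, in
#'   estimated mode).
#' @param mode \code{"estimated"} or \code{"known"}.
#' @param theta0 true parameter, required in known mode.
#' @param statistic chart(s) to run: subset of
#'   \code{c("min", "max", "cusum")}.
#' @param level nominal probability of any false alarm within the horizon.
#' @param limit \code{"analytic"}, \code{"mc"} or \code{"bootstrap"}.
#' @param boot_B bootstrap replicates.
#' @param mc_grid,mc_reps settings for the Monte Carlo limit.
#' @param seed optional seed for limit simulation.
#' @return an object of class \code{"ingarch_monitor"} (a list with one
#'   element per requested chart): each holds \code{statistic},
#'   \code{path}, \code{overall}, \code{limit}, \code{limit_source},
#'   \code{alarm_time}, plus shared metadata (\code{alpha}, \code{mode},
#'   \code{theta}, \code{fit}, \code{level}, \code{n}, \code{m}).
#' @export
monitor_change <- function(stream, train, fam = count_family("poisson"),
                           alpha = 0, mode = c("estimated", "known"),
                           theta0 = NULL,
                           statistic = c("min", "max", "cusum"),
                           level = 0.05,
                           limit = c("analytic", "mc", "bootstrap"),
                           boot_B = 500L, mc_grid = 2000L, mc_reps = 20000L,
                           seed = NULL) {
  mode <- match.arg(mode)
  limit <- match.arg(limit)
  statistic <- match.arg(statistic, several.ok = TRUE)
  stream <- check_counts(stream); train <- check_counts(train)
  if (length(train) < 50L)
    warning("training sample below 50 observations: score covariance may be unstable")
  x1 <- mean(train)
  fit <- NULL
  if (mode == "known") {
    if (is.null(theta0)) stop("known mode needs theta0")
    th <- as_theta(theta0)
  } else {
    fit <- mdpde(train, alpha = alpha, fam = fam, x1 = x1)
    th <- unclass(fit$theta_hat)
  }
  ftr <- ingarch_filter(train, th, x1 = x1, fam = fam)
  khat <- score_cov(score_path(train, ftr, alpha, fam))
  fst <- ingarch_filter(stream, th, x1 = x1, fam = fam)
  sp <- score_path(stream, fst, alpha, fam)
  n <- length(stream)
  paths <- stat_paths(w_process(sp, khat, mode), n)

  lim_for <- function(kind) {
    if (limit == "analytic") {
      if (kind == "cusum")
        stop("no analytic limit for the cusum chart; use limit = 'mc' or 'bootstrap'")
      bm_sup_quantile(3, level)
    } else if (limit == "mc") {
      if (kind != "cusum")
        bm_sup_quantile(3, level)
      else
        bridge_sup_quantile(3, level, grid = mc_grid, reps = mc_reps, seed = seed)
    } else {
      bfit <- if (!is.null(fit)) fit else list(
        theta_hat = ingarch_params(th[1], th[2], th[3]), alpha = alpha,
        converged = TRUE)
      bootstrap_limit(bfit, m = length(train), n = n, alpha = alpha,
                      statistic = kind, level = level, B = boot_B,
                      fam = fam, seed = seed)
    }
  }
  res <- lapply(statistic, function(kind) {
    lim <- lim_for(kind)
    path <- paths[[kind]]
    list(statistic = kind, path = path, overall = max(path), limit = lim,
         limit_source = limit, alarm_time = alarm_from_path(path, lim))
  })
  names(res) <- statistic
  structure(list(charts = res, alpha = alpha, mode = mode, theta = th,
                 fit = fit, level = level, n = n, m = length(train)),
            class = "ingarch_monitor")
}

#' @export
print.ingarch_monitor <- function(x, ...) {
  cat(sprintf("INGARCH monitoring (%s parameter, alpha = %g, m = %d, n = %d)\n",
              x$mode, x$alpha, x$m, x$n))
  cat(sprintf("theta used: omega = %.4f, a = %.4f, b = %.4f\n",
              x$theta[1], x$theta[2], x$theta[3]))
  for (ch in x$charts) {
    cat(sprintf("  %-5s chart: statistic %.4f vs limit %.4f (%s) -> %s\n",
                ch$statistic, ch$overall, ch$limit, ch$limit_source,
                if (is.na(ch$alarm_time)) "no alarm"
                else sprintf("alarm at k = %d", ch$alarm_time)))
  }
  invisible(x)
}

# fit + statistic on one simulated (train, stream) pair at given alpha;
# shared by the parametric bootstrap and the warp-speed scheme.
refit_stat <- function(train, stream, alpha, fam, statistic, tol = 1e-12) {
  f <- try(mdpde(train, alpha = alpha, fam = fam), silent = TRUE)
  if (inherits(f, "try-error")) return(list(ok = FALSE, stat = NA_real_))
  th <- unclass(f$theta_hat)
  x1 <- mean(train)
  khat <- score_cov(score_path(train, ingarch_filter(train, th, x1, fam),
                               alpha, fam, tol))
  sp <- score_path(stream, ingarch_filter(stream, th, x1, fam), alpha, fam, tol)
  W <- w_process(sp, khat, "estimated")
  st <- stat_paths(W, length(stream))[[statistic]]
  list(ok = isTRUE(f$converged), stat = max(st))
}

#' Parametric bootstrap control limit
#'
#' Simulates \code{B} series of length \code{m + n} from the fitted model,
#' re-fits the MDPDE on the first \code{m} observations of each, computes
#' the chart statistic over the last \code{n}, and returns the empirical
#' \code{1 - level} quantile. Replicates whose re-fit fails to converge
#' are dropped (with a logged count); more than 20 percent failures is an
#' error.
#'
#' @param fit an \code{"mdpde_fit"} from the training sample.
#' @param m,n training and monitoring lengths for the bootstrap series.
#' @param alpha DPD tuning parameter.
#' @param statistic one of \code{"min"}, \code{"max"}, \code{"cusum"}.
#' @param level nominal size.
#' @param B bootstrap replicates (at least 100).
#' @param fam a \code{\link{count_family}}.
#' @param seed optional integer seed.
#' @param burn stationary burn-in for the simulated series.
#' @return the control limit.
#' @export
bootstrap_limit <- function(fit, m, n, alpha = fit$alpha,
                            statistic = c("min", "max", "cusum"),
                            level = 0.05, B = 500L,
                            fam = count_family("poisson"), seed = NULL,
                            burn = 500L) {
  statistic <- match.arg(statistic)
  stopifnot(B >= 100L)
  if (!isTRUE(fit$converged)) stop("bootstrap needs a converged fit")
  th <- fit$theta_hat
  if (!is.null(seed)) set.seed(seed)
  stats_b <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    path <- simulate_ingarch(th, m + n, fam = fam, burn = burn)
    r <- refit_stat(path[seq_len(m)], path[m + seq_len(n)], alpha, fam, statistic)
    if (r$ok) stats_b[b] <- r$stat
  }
  nfail <- sum(is.na(stats_b))
  if (nfail > 0)
    message(sprintf("bootstrap_limit: dropped %d/%d failed re-fits", nfail, B))
  if (nfail > 0.2 * B) stop("more than 20% of bootstrap re-fits failed")
  unname(stats::quantile(stats_b, 1 - level, na.rm = TRUE))
}
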