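# Size/power study runner: empirical rejection rates of the monitoring
# charts over replicated scenario draws, with analytic limits in
# known-parameter mode and warp-speed parametric bootstrap limits (one
# bootstrap replicate per Monte Carlo replication, pooled into a common
# critical value) in estimated mode.

# counter-based replication seeds: cells and replications are
# independently reproducible from one master seed (kept below 2^31).
derive_seed <- function(master, cell = 0L, rep = 0L) {
  as.integer((as.numeric(master) %% 1e6 * 1009 + cell * 1e5 + rep * 7 + 1) %%
               2147483629)
}

known_stat_once <- function(sc, alpha, statistics, fam, seed, tol = 1e-12) {
  d <- simulate_scenario(sc, seed = seed)
  x1 <- mean(d$train)
  th <- sc$theta0
  khat <- score_cov(score_path(d$train,
                               ingarch_filter(d$train, th, x1, fam),
                               alpha, fam, tol))
  sp <- score_path(d$stream, ingarch_filter(d$stream, th, x1, fam),
                   alpha, fam, tol)
  paths <- stat_paths(w_process(sp, khat, "known"), sc$n)
  vapply(statistics, function(s) max(paths[[s]]), numeric(1))
}

# one warp-speed replication: statistic on the scenario draw at the
# training-sample MDPDE, plus one bootstrap statistic simulated from that
# same fit (clean model law, no change, no contamination).
warp_once <- function(sc, alpha, statistic, fam, seed) {
  d <- simulate_scenario(sc, seed = seed)
  f <- try(mdpde(d$train, alpha = alpha, fam = fam), silent = TRUE)
  if (inherits(f, "try-error") || !isTRUE(f$converged))
    return(c(real = NA_real_, boot = NA_real_))
  th <- unclass(f$theta_hat)
  x1 <- mean(d$train)
  khat <- score_cov(score_path(d$train, ingarch_filter(d$train, th, x1, fam),
                               alpha, fam))
  sp <- score_path(d$stream, ingarch_filter(d$stream, th, x1, fam), alpha, fam)
  real <- max(stat_paths(w_process(sp, khat, "estimated"), sc$n)[[statistic]])
  set.seed(derive_seed(seed, cell = 9L))
  bpath <- simulate_ingarch(f$theta_hat, sc$m + sc$n, fam, burn = sc$burn)
  rb <- refit_stat(bpath[seq_len(sc$m)], bpath[sc$m + seq_len(sc$n)],
                   alpha, fam, statistic)
  c(real = real, boot = if (rb$ok) rb$stat else NA_real_)
}

#' Warp-speed bootstrap control limit for one scenario cell
#'
#' Runs \code{R} Monte Carlo replications of a scenario in estimated mode
#' and draws one parametric bootstrap replicate per replication (series of
#' length \eqn{m + n} from that replication's training fit, re-fitted on
#' the first \eqn{m}, statistic over the last \eqn{n}); the
#' \code{1 - level} quantile of the \code{R} pooled bootstrap statistics
#' is the common control limit.
#'
#' @param sc a \code{\link{change_scenario}}.
#' @param alpha DPD tuning parameter.
#' @param statistic chart kind.
#' @param level nominal size.
#' @param R replications.
#' @param seed master seed.
#' @return list with \code{limit}, the per-replication \code{real} and
#'   \code{boot} statistics, and the failure count \code{nfail}.
#' @export
warp_limit <- function(sc, alpha = 0, statistic = c("cusum", "min", "max"),
                       level = 0.05, R = 200L, seed = 1L) {
  statistic <- match.arg(statistic)
  fam <- count_family(sc$family, r = sc$r)
  out <- vapply(seq_len(R),
                function(r) warp_once(sc, alpha, statistic, fam,
                                      derive_seed(seed, cell = 1L, rep = r)),
                numeric(2))
  ok <- stats::complete.cases(t(out))
  nfail <- sum(!ok)
  if (nfail > 0.2 * R) stop("more than 20% of warp replications failed")
  list(limit = unname(stats::quantile(out["boot", ok], 1 - level)),
       real = out["real", ok], boot = out["boot", ok], nfail = nfail)
}

#' Empirical size/power of the monitoring charts over a scenario grid
#'
#' For each combination of scenario, tuning parameter and chart, draws
#' \code{R} independent (training, stream) pairs, monitors each, and
#' reports the fraction of replications whose overall statistic exceeds
#' the control limit, with its binomial standard error.
#'
#' In \code{mode = "known"} the charts use the true \code{theta0} and the
#' limit is analytic (min/max: Brownian sup quantile) or Monte Carlo
#' (cusum). In \code{mode = "estimated"} with \code{limit = "warp"} the
#' warp-speed bootstrap limit is computed cell by cell.
#'
#' @param scenarios a \code{\link{change_scenario}} or list of them.
#' @param alphas DPD tuning parameters to run.
#' @param statistics chart kinds to run.
#' @param mode \code{"known"} or \code{"estimated"}.
#' @param limit \code{"analytic"} (and/or MC for cusum) in known mode;
#'   \code{"warp"} in estimated mode.
#' @param level nominal size.
#' @param R replications per cell.
#' @param seed master seed; replication seeds are derived by counter.
#' @param mc_grid,mc_reps settings for the Monte Carlo cusum limit in
#'   known mode.
#' @return a long data.frame with one row per cell: scenario descriptors,
#'   \code{statistic}, \code{alpha}, \code{rate}, \code{se}, \code{R},
#'   \code{nfail}, \code{limit}, \code{limit_source}.
#' @export
run_size_power <- function(scenarios, alphas = 0,
                           statistics = c("min", "max", "cusum"),
                           mode = c("known", "estimated"),
                           limit = c("analytic", "warp"),
                           level = 0.05, R = 500L, seed = 1L,
                           mc_grid = 1000L, mc_reps = 5000L) {
  mode <- match.arg(mode)
  limit <- match.arg(limit)
  if (inherits(scenarios, "change_scenario")) scenarios <- list(scenarios)
  statistics <- match.arg(statistics, c("min", "max", "cusum"),
                          several.ok = TRUE)
  rows <- list()
  cell <- 0L
  for (sc in scenarios) for (alpha in alphas) {
    cell <- cell + 1L
    fam <- count_family(sc$family, r = sc$r)
    if (mode == "known") {
      stats_mat <- vapply(seq_len(R), function(r)
        known_stat_once(sc, alpha, statistics, fam,
                        derive_seed(seed, cell, r)),
        numeric(length(statistics)))
      stats_mat <- matrix(stats_mat, nrow = length(statistics))
      for (i in seq_along(statistics)) {
        kind <- statistics[i]
        lim <- if (kind == "cusum")
          bridge_sup_quantile(3, level, grid = mc_grid, reps = mc_reps,
                              seed = derive_seed(seed, cell, 0L))
        else bm_sup_quantile(3, level)
        rate <- mean(stats_mat[i, ] > lim)
        rows[[length(rows) + 1L]] <- data.frame(
          statistic = kind, alpha = alpha, n = sc$n, m = sc$m, tau = sc$tau,
          case = sc$case, delta = sc$delta, p = sc$p,
          lam = if (is.null(sc$lam)) NA_real_ else sc$lam,
          rate = rate, se = sqrt(rate * (1 - rate) / R), R = R, nfail = 0L,
          limit = lim,
          limit_source = if (kind == "cusum") "mc" else "analytic")
      }
    } else {
      for (kind in statistics) {
        wl <- warp_limit(sc, alpha, kind, level, R,
                         seed = derive_seed(seed, cell, 0L))
        Ru <- length(wl$real)
        rate <- mean(wl$real > wl$limit)
        rows[[length(rows) + 1L]] <- data.frame(
          statistic = kind, alpha = alpha, n = sc$n, m = sc$m, tau = sc$tau,
          case = sc$case, delta = sc$delta, p = sc$p,
          lam = if (is.null(sc$lam)) NA_real_ else sc$lam,
          rate = rate, se = sqrt(rate * (1 - rate) / Ru), R = Ru,
          nfail = wl$nfail, limit = wl$limit, limit_source = "warp")
      }
    }
  }
  do.call(rbind, rows)
}
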