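# Control limits from the limiting functionals of the monitoring
# statistics: T = sup_{0<=s<=1} ||B_d(s)||_max for the min/max charts and
# T' = sup_{0<s<=s'<=1} ||(s/s') B_d(s') - B_d(s)|| for the pairwise
# cusum chart (B_d a d-dimensional standard Brownian motion; the bridge
# terms of T' cancel, so plain Brownian paths are simulated).

#' Boundary-crossing probability of |Brownian motion| on [0,1]
#'
#' \eqn{P(\sup_{0\le s\le 1}|B(s)| \ge c)} by the alternating reflection
#' series
#' \eqn{1 - (4/\pi)\sum_{k\ge 0} \frac{(-1)^k}{2k+1}
#'      \exp\{-\pi^2(2k+1)^2/(8c^2)\}},
#' summed until terms fall below 1e-14.
#'
#' @param c positive threshold(s).
#' @return tail probabilities.
#' @export
bm_sup_tail <- function(c) {
  stopifnot(all(c > 0))
  vapply(c, function(ci) {
    s <- 0
    for (k in 0:200) {
      term <- ((-1)^k / (2 * k + 1)) * exp(-pi^2 * (2 * k + 1)^2 / (8 * ci^2))
      s <- s + term
      if (abs(term) < 1e-14) break
    }
    max(0, min(1, 1 - 4 / pi * s))
  }, numeric(1))
}

#' Quantile of the sup-max-norm of d-dimensional Brownian motion
#'
#' Control limit \eqn{c} for the min/max-type charts: solves, per
#' independent component, \eqn{P(\sup|B(s)| \ge c) = 1 - (1-level)^{1/d}}
#' by bracketed root finding on the reflection series.
#'
#' @param d dimension (3 for the INGARCH(1,1) parameter).
#' @param level nominal size in (0,1).
#' @return the control limit \eqn{c}.
#' @examples
#' bm_sup_quantile(3, 0.05)  # 2.633
#' @export
bm_sup_quantile <- function(d, level) {
  stopifnot(d >= 1, level > 0, level < 1)
  target <- 1 - (1 - level)^(1 / d)
  stats::uniroot(function(c) bm_sup_tail(c) - target,
                 lower = 1e-4, upper = 50, tol = 1e-9)$root
}

# sup over grid pairs i <= j of ||(i/j) W_j - W_i|| (Euclidean norm),
# shared by the cusum statistic and the Monte Carlo limit below.
pair_sup <- function(W) {
  n <- nrow(W)
  best <- 0
  for (j in 2:n) {
    i <- seq_len(j - 1L)
    D <- (i / j) %o% W[j, ] - W[i, , drop = FALSE]
    m <- max(.rowSums(D * D, j - 1L, ncol(W)))
    if (m > best) best <- m
  }
  sqrt(best)
}

#' Monte Carlo quantile of the pairwise Brownian-bridge functional
#'
#' Simulates d-dimensional Brownian paths on a uniform grid and returns
#' the empirical \code{1 - level} quantile of
#' \eqn{\sup_{s\le s'} \|(s/s')B^\circ(s') - B^\circ(s)\|}; since the
#' bridge terms cancel in the weighted difference, Brownian motion is
#' used directly. Results can be cached to a JSON file keyed by the
#' settings.
#'
#' @param d dimension.
#' @param level nominal size.
#' @param grid number of grid steps (discretization bias shrinks like
#'   \code{grid^-1/2}).
#' @param reps Monte Carlo replications.
#' @param seed optional integer seed.
#' @param cache optional path of a JSON cache file.
#' @return the control limit \eqn{c'}.
#' @export
bridge_sup_quantile <- function(d, level, grid = 2000L, reps = 20000L,
                                seed = NULL, cache = NULL) {
  stopifnot(d >= 1, level > 0, level < 1, grid >= 2, reps >= 1)
  key <- sprintf("d%d_grid%d_reps%d_seed%s_level%g",
                 d, grid, reps, if (is.null(seed)) "NA" else seed, level)
  if (!is.null(cache) && file.exists(cache)) {
    store <- jsonlite::fromJSON(cache)
    if (!is.null(store[[key]])) return(as.numeric(store[[key]]))
  }
  if (!is.null(seed)) set.seed(seed)
  sups <- vapply(seq_len(reps), function(r) {
    W <- apply(matrix(stats::rnorm(grid * d, sd = sqrt(1 / grid)), grid, d),
               2, cumsum)
    pair_sup(W)
  }, numeric(1))
  q <- unname(stats::quantile(sups, 1 - level))
  if (!is.null(cache)) {
    store <- if (file.exists(cache)) jsonlite::fromJSON(cache) else list()
    store[[key]] <- q
    jsonlite::write_json(store, cache, auto_unbox = TRUE, digits = NA)
  }
  q
}
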