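# Scenario generator: stationary INGARCH(1,1) paths, parameter changes at
# a known time, and Bernoulli-Poisson outlier contamination applied after
# generation (outliers do not feed back into the conditional mean).

sim_core <- function(theta0, theta1, tau, n, fam, burn) {
  th0 <- as_theta(theta0)
  th1 <- if (is.null(theta1)) th0 else as_theta(theta1)
  if (!contraction_check(th0, 0) || !contraction_check(th1, 0))
    stop("simulation parameters must satisfy the contraction a + b < 1")
  x <- stationary_mean(th0)
  y <- numeric(n)
  rmu <- fam$rmu
  total <- burn + n
  for (t in seq_len(total)) {
    k <- t - burn             # stream index; <= 0 during burn-in
    th <- if (!is.null(tau) && k >= tau) th1 else th0
    if (k >= 2 || (k == 1 && burn > 0) || (k <= 0 && t > 1))
      x <- th[1] + th[2] * x + th[3] * yprev
    yt <- rmu(1L, x)
    if (k >= 1) y[k] <- yt
    yprev <- yt
  }
  y
}

#' Simulate a stationary INGARCH(1,1) count path
#'
#' Iterates the conditional-mean recursion
#' \eqn{X_t = \omega + a X_{t-1} + b Y_{t-1}}, drawing
#' \eqn{Y_t} from the family at mean \eqn{X_t}. The recursion starts at
#' the stationary mean and a burn-in prefix is discarded; geometric
#' ergodicity makes residual initialization bias negligible at
#' \eqn{a + b \le 0.8} with the default burn-in.
#'
#' @param theta \code{\link{ingarch_params}}.
#' @param n path length returned.
#' @param fam a \code{\link{count_family}}.
#' @param burn burn-in length discarded.
#' @return integer count vector of length \code{n}.
#' @export
simulate_ingarch <- function(theta, n, fam = count_family("poisson"),
                             burn = 500L) {
  stopifnot(n >= 1, burn >= 0)
  sim_core(theta, NULL, NULL, n, fam, burn)
}

#' Simulate a monitoring stream with a parameter change
#'
#' The recursion uses \code{theta0} for stream indices \eqn{t < \tau} and
#' \code{theta1} from \eqn{t \ge \tau} on, carrying the conditional mean
#' continuously across the change. With \code{theta1 = theta0} (or
#' \code{tau = NULL}) the stream is a pure no-change path and, seed for
#' seed, identical to \code{\link{simulate_ingarch}}.
#'
#' @param theta0,theta1 pre- and post-change parameters.
#' @param tau change index within the stream (\code{NULL} for no change).
#' @param n stream length.
#' @param fam a \code{\link{count_family}}.
#' @param burn burn-in (generated under \code{theta0}).
#' @return integer count vector of length \code{n}.
#' @export
simulate_change <- function(theta0, theta1, tau, n,
                            fam = count_family("poisson"), burn = 500L) {
  if (!is.null(tau)) stopifnot(tau >= 1, tau <= n)
  sim_core(theta0, theta1, tau, n, fam, burn)
}

#' Replace counts by Poisson outliers at Bernoulli times
#'
#' The contaminated series is \eqn{(1-p_t)Y_t + p_t Z_t} with iid
#' \eqn{p_t \sim} Bernoulli(\code{p}) and \eqn{Z_t \sim} Poisson
#' (\code{lam}), all independent of the clean process; contamination is
#' applied after generation and never feeds back into the recursion.
#'
#' @param y clean count series.
#' @param p contamination probability in \eqn{[0,1)}.
#' @param lam outlier intensity (> 0 when \code{p > 0}).
#' @return contaminated count vector.
#' @export
contaminate <- function(y, p, lam = NULL) {
  y <- check_counts(y)
  stopifnot(p >= 0, p < 1)
  if (p == 0) return(y)
  if (is.null(lam) || lam <= 0) stop("lam must be positive when p > 0")
  flag <- stats::rbinom(length(y), 1L, p) == 1L
  y[flag] <- stats::rpois(sum(flag), lam)
  y
}

#' Define a size/power study scenario
#'
#' Encodes one cell of the monitoring study: a baseline parameter, one of
#' four change patterns applied at \code{tau} with multiplier
#' \eqn{\delta}, sample sizes, and optional outlier contamination.
#' Change patterns: case 1 scales all of \eqn{(\omega, a, b)} by
#' \eqn{1+\delta}; cases 2-4 scale only \eqn{\omega}, \eqn{a} or \eqn{b}.
#'
#' @param theta0 baseline \code{\link{ingarch_params}}.
#' @param case change pattern, 1-4.
#' @param delta change multiplier (0 for a no-change cell).
#' @param tau change index in the stream; default \code{floor(n / 2)}.
#' @param n,m monitoring and training lengths.
#' @param family family name (\code{"poisson"} or \code{"nb"}).
#' @param r negative binomial size (if \code{family = "nb"}).
#' @param p,lam contamination probability and outlier intensity
#'   (\code{p = 0} for clean data).
#' @param burn simulation burn-in.
#' @return an object of class \code{"change_scenario"}.
#' @export
change_scenario <- function(theta0, case = 1L, delta = 0, tau = NULL,
                            n = 500L, m = n, family = "poisson", r = NULL,
                            p = 0, lam = NULL, burn = 500L) {
  th0 <- as_theta(theta0)
  stopifnot(case %in% 1:4, p >= 0, p < 1)
  mult <- c(1, 1, 1)
  if (case == 1L) mult <- rep(1 + delta, 3) else mult[case - 1L] <- 1 + delta
  th1 <- th0 * mult
  if (!contraction_check(th0, 0) || !contraction_check(th1, 0))
    stop("pre- or post-change parameters violate the contraction condition")
  if (is.null(tau)) tau <- max(1L, floor(n / 2))
  stopifnot(tau >= 1, tau <= n)
  structure(list(theta0 = th0, theta1 = th1, case = case, delta = delta,
                 tau = tau, n = as.integer(n), m = as.integer(m),
                 family = family, r = r, p = p, lam = lam,
                 burn = as.integer(burn)),
            class = "change_scenario")
}

#' Draw one (training, stream) pair from a scenario
#'
#' The training sample comes from the no-change law; the stream switches
#' parameters at \code{tau} (a pure no-change stream when
#' \code{delta = 0}). Under contamination both samples are drawn from the
#' contaminated law.
#'
#' @param sc a \code{\link{change_scenario}}.
#' @param seed optional integer seed.
#' @return list with integer vectors \code{train} and \code{stream}.
#' @export
simulate_scenario <- function(sc, seed = NULL) {
  stopifnot(inherits(sc, "change_scenario"))
  if (!is.null(seed)) set.seed(seed)
  fam <- count_family(sc$family, r = sc$r)
  train <- simulate_ingarch(sc$theta0, sc$m, fam, burn = sc$burn)
  stream <- simulate_change(sc$theta0,
                            if (sc$delta == 0) sc$theta0 else sc$theta1,
                            sc$tau, sc$n, fam, burn = sc$burn)
  if (sc$p > 0) {
    train <- contaminate(train, sc$p, sc$lam)
    stream <- contaminate(stream, sc$p, sc$lam)
  }
  list(train = train, stream = stream)
}
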