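#' INGARCH(1,1) parameter vector
#'
#' Parameters \eqn{\theta = (\omega, a, b)} of the linear conditional-mean
#' recursion \eqn{X_t = \omega + a X_{t-1} + b Y_{t-1}}. Stationarity and
#' ergodicity require the contraction \eqn{a + b < 1}.
#'
#' @param omega intercept, \eqn{\omega > 0}.
#' @param a feedback coefficient on the previous conditional mean,
#'   \eqn{a \ge 0}.
#' @param b coefficient on the previous observation, \eqn{b \ge 0}.
#' @return a named numeric vector of class \code{"ingarch_params"}.
#' @export
ingarch_params <- function(omega, a, b) {
  th <- c(omega = as.numeric(omega), a = as.numeric(a), b = as.numeric(b))
  if (anyNA(th)) stop("parameters must be finite")
  if (omega <= 0) stop("omega must be positive")
  if (a < 0 || b < 0) stop("a and b must be non-negative")
  if (a + b >= 1) stop("contraction violated: a + b must be < 1")
  structure(th, class = "ingarch_params")
}

as_theta <- function(theta) {
  if (inherits(theta, "ingarch_params")) return(unclass(theta))
  th <- as.numeric(theta)
  if (length(th) != 3L) stop("theta must have 3 components (omega, a, b)")
  names(th) <- c("omega", "a", "b")
  th
}

#' Check membership in the interior of the compact parameter space
#'
#' TRUE iff \eqn{\omega > 0}, \eqn{a, b \ge 0} and
#' \eqn{a + b \le 1 - \epsilon}.
#'
#' @param theta parameter vector (any numeric of length 3 is accepted so
#'   that invalid candidates can be screened).
#' @param epsilon distance kept from the unit-root boundary.
#' @return logical.
#' @export
contraction_check <- function(theta, epsilon = 1e-3) {
  th <- suppressWarnings(as.numeric(theta))
  length(th) == 3L && all(is.finite(th)) &&
    th[1] > 0 && th[2] >= 0 && th[3] >= 0 && th[2] + th[3] <= 1 - epsilon
}

#' Stationary mean of the INGARCH(1,1) model
#'
#' @param theta parameters \eqn{(\omega, a, b)} with \eqn{a + b < 1}.
#' @return \eqn{\omega / (1 - a - b)}.
#' @export
stationary_mean <- function(theta) {
  th <- as_theta(theta)
  if (th[2] + th[3] >= 1) stop("stationary mean undefined: a + b >= 1")
  unname(th[1] / (1 - th[2] - th[3]))
}

#' Filter a count series through the INGARCH(1,1) recursion
#'
#' One-pass evaluation of the conditional means
#' \eqn{\tilde X_t(\theta) = \omega + a \tilde X_{t-1}(\theta) + b Y_{t-1}},
#' \eqn{t \ge 2}, from the initial value \eqn{\tilde X_1 = x_1}, together
#' with the natural parameters \eqn{\tilde\eta_t = B^{-1}(\tilde X_t)} and
#' the gradient recursion
#' \eqn{\partial\tilde X_t/\partial\theta =
#'   (1, \tilde X_{t-1}, Y_{t-1})^T + a\,\partial\tilde X_{t-1}/\partial\theta}
#' with \eqn{\partial\tilde X_1/\partial\theta = 0} (the start is a
#' constant). The linear recursions run through
#' \code{stats::filter(method = "recursive")}.
#'
#' The initial value is asymptotically immaterial: two starts contract at
#' geometric rate \eqn{a^{t-1}}. The default is the sample mean of the
#' series being filtered; pass the training-sample mean when filtering a
#' monitoring stream.
#'
#' @param y count series.
#' @param theta \code{\link{ingarch_params}}.
#' @param x1 initial conditional mean (positive); default \code{mean(y)},
#'   falling back to \code{y[1] + 1} for a length-one series of zeros.
#' @param fam a \code{\link{count_family}}.
#' @return list of class \code{"ingarch_filter"} with elements
#'   \code{means}, \code{etas}, \code{grads} (n x 3 matrix), \code{x1}.
#' @export
ingarch_filter <- function(y, theta, x1 = NULL, fam = count_family("poisson")) {
  y <- check_counts(y)
  th <- as_theta(theta)
  if (is.null(x1)) {
    x1 <- mean(y)
    if (x1 <= 0) x1 <- y[1] + 1
  }
  if (x1 <= 0) stop("x1 must be positive")
  n <- length(y)
  means <- rep.int(x1, n)
  g <- matrix(0, n, 3L, dimnames = list(NULL, c("omega", "a", "b")))
  if (n > 1L) {
    lag <- y[-n]
    means[-1L] <- stats::filter(th[1] + th[3] * lag, th[2], "recursive", init = x1)
    g[-1L, 1L] <- stats::filter(rep.int(1, n - 1L), th[2], "recursive", init = 0)
    g[-1L, 2L] <- stats::filter(means[-n], th[2], "recursive", init = 0)
    g[-1L, 3L] <- stats::filter(lag, th[2], "recursive", init = 0)
  }
  structure(list(means = means, etas = fam$Binv(means), grads = g, x1 = x1),
            class = "ingarch_filter")
}
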