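#' One-parameter exponential-family count distributions
#'
#' Constructs the conditional law used by the INGARCH model,
#' \eqn{p(y|\eta) = \exp\{\eta y - A(\eta)\} h(y)}, for the Poisson family
#' (\eqn{A(\eta)=e^\eta}, any real \eqn{\eta}) or the negative binomial
#' family with fixed integer size \eqn{r} (natural parameter
#' \eqn{\eta = \log(1-p) < 0}, mean \eqn{r e^\eta/(1-e^\eta)}).
#'
#' The returned object bundles the log-partition \eqn{A}, the mean map
#' \eqn{B = A'}, the conditional variance \eqn{B' = A''}, the inverse mean
#' map \eqn{B^{-1}}, the carrier \eqn{\log h(y)}, log-pmf evaluation and
#' sampling. pmf work is done in log space throughout.
#'
#' @param name family name, one of \code{"poisson"}, \code{"nb"}.
#' @param r negative binomial size parameter (positive integer); required
#'   and used only for \code{name = "nb"}.
#' @return an object of class \code{"count_family"}.
#' @examples
#' fam <- count_family("poisson")
#' family_pmf(fam, 2, log(2))   # = 2 exp(-2)
#' @export
count_family <- function(name = c("poisson", "nb"), r = NULL) {
  name <- match.arg(name)
  if (name == "poisson") {
    fam <- list(
      name = "poisson", r = NULL,
      A = function(eta) exp(eta),
      B = function(eta) exp(eta),
      Bprime = function(eta) exp(eta),
      Binv = function(mu) log(mu),
      logh = function(y) -lgamma(y + 1),
      logpmf = function(y, eta) stats::dpois(y, exp(eta), log = TRUE),
      qtail = function(p, eta) stats::qpois(p, exp(eta)),
      rmu = function(n, mu) stats::rpois(n, mu),
      eta_ok = function(eta) is.finite(eta)
    )
  } else {
    if (is.null(r) || length(r) != 1L || r < 1 || r != round(r))
      stop("the negative binomial family needs a fixed positive integer size 'r'")
    r <- as.integer(r)
    fam <- list(
      name = "nb", r = r,
      A = function(eta) -r * log1p(-exp(eta)),
      B = function(eta) r * exp(eta) / (1 - exp(eta)),
      Bprime = function(eta) r * exp(eta) / (1 - exp(eta))^2,
      Binv = function(mu) log(mu / (mu + r)),
      logh = function(y) lchoose(y + r - 1, y),
      logpmf = function(y, eta) stats::dnbinom(y, size = r, prob = 1 - exp(eta), log = TRUE),
      qtail = function(p, eta) stats::qnbinom(p, size = r, prob = 1 - exp(eta)),
      rmu = function(n, mu) stats::rnbinom(n, size = r, mu = mu),
      eta_ok = function(eta) is.finite(eta) & eta < 0
    )
  }
  class(fam) <- "count_family"
  fam
}

#' @export
print.count_family <- function(x, ...) {
  cat("<count_family>", x$name,
      if (!is.null(x$r)) sprintf("(size r = %d)", x$r), "\n")
  invisible(x)
}

check_eta <- function(fam, eta) {
  if (!all(fam$eta_ok(eta)))
    stop(sprintf("natural parameter out of domain for the '%s' family", fam$name))
  invisible(eta)
}

check_counts <- function(y) {
  if (length(y) == 0L) stop("empty count series")
  if (anyNA(y) || any(y < 0) || any(y != round(y)))
    stop("counts must be non-negative integers")
  invisible(as.numeric(y))
}

#' Probability mass function of a count family
#'
#' @param fam a \code{\link{count_family}}.
#' @param y non-negative integer count(s).
#' @param eta natural parameter(s); recycled against \code{y}.
#' @return probabilities in \eqn{[0,1]}.
#' @export
family_pmf <- function(fam, y, eta) {
  check_counts(y)
  check_eta(fam, eta)
  exp(fam$logpmf(y, eta))
}

#' Draw counts from a family at a given natural parameter
#'
#' Sampling is delegated to the family's native generator and is
#' reproducible under \code{set.seed}.
#'
#' @inheritParams family_pmf
#' @param n number of draws.
#' @return integer vector of length \code{n}.
#' @export
family_sample <- function(fam, n, eta) {
  check_eta(fam, eta)
  fam$rmu(n, fam$B(eta))
}

#' Support truncation point for infinite sums over the pmf
#'
#' Smallest count \eqn{y^*} whose cumulative probability reaches
#' \eqn{1 - tol}, capped at a hard ceiling. Used to evaluate the infinite
#' sums in the density-power-divergence loss at a controlled tail mass.
#' For vector \code{eta} the bound covers every component.
#'
#' @inheritParams family_pmf
#' @param tol tail mass allowed beyond the bound, in (0,1).
#' @param ceiling hard cap on the bound.
#' @return integer truncation point.
#' @export
truncation_bound <- function(fam, eta, tol = 1e-12, ceiling = 10000L) {
  stopifnot(tol > 0, tol < 1)
  check_eta(fam, eta)
  b <- max(fam$qtail(1 - tol, eta))
  if (b > ceiling) {
    warning(sprintf("truncation ceiling %d reached before tail mass %g", ceiling, tol))
    b <- ceiling
  }
  as.integer(b)
}
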