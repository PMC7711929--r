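# Density-power-divergence loss, scores and the MDPDE fit.
#
# Per-observation loss at tuning parameter alpha:
#   alpha > 0 : sum_y p^{1+a}(y|eta_t) - (1 + 1/a) p^a(Y_t|eta_t)
#   alpha = 0 : -log p(Y_t|eta_t)          (negative log-likelihood)
# The infinite sum over the support is truncated at a tail mass `tol`.
# Scores follow by the chain rule through eta_t = B^{-1}(X_t):
#   d loss / d theta = u_t * dX_t/dtheta, with
#   u_t = (1+a) [ S_t - p^a(Y_t)(Y_t - X_t) ] / B'(eta_t),
#   S_t = sum_y p^{1+a}(y)(y - X_t)        (alpha > 0)
#   u_t = -(Y_t - X_t) / B'(eta_t)         (alpha = 0)

dpd_terms <- function(y, means, etas, alpha, fam, tol = 1e-12) {
  vB <- fam$Bprime(etas)
  if (alpha == 0) {
    list(loss = -fam$logpmf(y, etas), u = -(y - means) / vB)
  } else {
    M <- truncation_bound(fam, etas, tol)
    yy <- 0:M
    logP <- outer(yy, etas, fam$logpmf)
    P1a <- exp((1 + alpha) * logP)
    s0 <- .colSums(P1a, M + 1L, length(etas))
    s1 <- .colSums(yy * P1a, M + 1L, length(etas))
    lobs <- fam$logpmf(y, etas)
    pa <- exp(alpha * lobs)
    loss <- s0 - (1 + 1 / alpha) * pa
    u <- (1 + alpha) * ((s1 - means * s0) - pa * (y - means)) / vB
    list(loss = loss, u = u)
  }
}

#' Per-observation density power divergence loss
#'
#' Evaluates the DPD loss of observed counts against the family law at
#' natural parameter(s) \code{eta}. At \code{alpha = 0} this is the
#' negative log pmf; for \code{alpha > 0} the support sum is truncated at
#' tail mass \code{tol}.
#'
#' @param y observed count(s).
#' @param eta natural parameter(s), recycled against \code{y}.
#' @param alpha DPD tuning parameter, \eqn{\alpha \ge 0}. \eqn{\alpha = 0}
#'   is maximum likelihood; larger values trade efficiency for robustness.
#' @param fam a \code{\link{count_family}}.
#' @param tol support-sum truncation tail mass.
#' @return numeric vector of losses.
#' @export
dpd_loss <- function(y, eta, alpha = 0, fam = count_family("poisson"),
                     tol = 1e-12) {
  stopifnot(alpha >= 0)
  check_counts(y)
  check_eta(fam, eta)
  n <- max(length(y), length(eta))
  y <- rep_len(as.numeric(y), n); eta <- rep_len(eta, n)
  out <- dpd_terms(y, fam$B(eta), eta, alpha, fam, tol)$loss
  if (alpha == 0 && any(!is.finite(out)))
    warning("zero pmf at an observed count: loss is +Inf")
  out
}

#' Losses and score vectors along a filtered path
#'
#' Combines the filtered state (means, natural parameters, mean gradients)
#' with the DPD loss to produce the per-observation losses and the
#' 3-dimensional score vectors
#' \eqn{\partial \tilde l_{\alpha,t}(\theta)/\partial\theta} used by both
#' estimation and monitoring.
#'
#' @param y count series.
#' @param fs an \code{\link{ingarch_filter}} state for \code{y}.
#' @param alpha DPD tuning parameter.
#' @param fam a \code{\link{count_family}}.
#' @param tol truncation tail mass for the support sums.
#' @return list of class \code{"score_path"}: \code{alpha}, \code{losses},
#'   \code{scores} (n x 3 matrix).
#' @export
score_path <- function(y, fs, alpha = 0, fam = count_family("poisson"),
                       tol = 1e-12) {
  stopifnot(inherits(fs, "ingarch_filter"), alpha >= 0)
  y <- check_counts(y)
  tm <- dpd_terms(y, fs$means, fs$etas, alpha, fam, tol)
  structure(list(alpha = alpha, losses = tm$loss, scores = fs$grads * tm$u),
            class = "score_path")
}

#' Averaged DPD objective of an INGARCH model on a series
#'
#' \eqn{\tilde L_{\alpha,n}(\theta) = n^{-1}\sum_t \tilde l_{\alpha,t}(\theta)}
#' along the filtered conditional-mean path. At \code{alpha = 0} this is
#' the mean negative conditional log-likelihood.
#'
#' @inheritParams score_path
#' @param theta \code{\link{ingarch_params}} (or numeric length 3).
#' @param x1 filter initial value; default \code{mean(y)}.
#' @return scalar objective value.
#' @export
mdpde_objective <- function(y, theta, alpha = 0, fam = count_family("poisson"),
                            x1 = NULL, tol = 1e-12) {
  fs <- ingarch_filter(y, theta, x1 = x1, fam = fam)
  mean(dpd_terms(check_counts(y), fs$means, fs$etas, alpha, fam, tol)$loss)
}

#' Empirical score covariance (outer-product information estimate)
#'
#' \eqn{\hat K_\alpha = m^{-1} \sum_t s_t s_t^T} over the score vectors of a
#' sample; symmetric positive semidefinite by construction.
#'
#' @param sp a \code{\link{score_path}} or an n x 3 score matrix.
#' @return 3 x 3 matrix.
#' @export
score_cov <- function(sp) {
  S <- if (inherits(sp, "score_path")) sp$scores else as.matrix(sp)
  if (nrow(S) < 3L) stop("need at least 3 score vectors")
  crossprod(S) / nrow(S)
}

# map between the unconstrained optimizer space u and theta:
# omega = exp(u1); s = a + b = eps + (1-2 eps) logistic(u2);
# a = s v, b = s (1-v), v = logistic(u3). Enforces omega > 0 and the
# interior contraction eps <= a+b <= 1-eps without constrained solvers
# (the omega box [w1, w2] is handled by a guard in the objective).
theta_of_u <- function(u, eps) {
  p2 <- stats::plogis(u[2]); v <- stats::plogis(u[3])
  s <- eps + (1 - 2 * eps) * p2
  c(exp(u[1]), s * v, s * (1 - v))
}

u_of_theta <- function(th, eps) {
  clip <- function(p) pmin(pmax(p, 1e-8), 1 - 1e-8)
  s <- th[2] + th[3]
  c(log(max(th[1], 1e-10)),
    stats::qlogis(clip((s - eps) / (1 - 2 * eps))),
    stats::qlogis(clip(if (s > 0) th[2] / s else 0.5)))
}

jac_theta_u <- function(u, eps) {
  dl <- function(x) stats::plogis(x) * (1 - stats::plogis(x))
  p2 <- stats::plogis(u[2]); v <- stats::plogis(u[3])
  s <- eps + (1 - 2 * eps) * p2
  ds <- (1 - 2 * eps) * dl(u[2]); dv <- dl(u[3])
  matrix(c(exp(u[1]), 0, 0,
           0, v * ds, s * dv,
           0, (1 - v) * ds, -s * dv),
         3L, 3L, byrow = TRUE)  # rows: omega, a, b; cols: u1, u2, u3
}

#' Minimum density power divergence estimation of an INGARCH(1,1) model
#'
#' Minimizes the averaged DPD objective over the compact parameter space
#' \eqn{\{\omega_1 \le \omega \le \omega_2,\ \epsilon \le a+b \le 1-\epsilon\}}
#' via a smooth reparameterization and BFGS with the analytic score-based
#' gradient. \code{alpha = 0} gives the conditional MLE. The sandwich
#' covariance \eqn{\hat J^{-1}\hat K\hat J^{-1}/n} uses the outer-product
#' estimate \eqn{\hat K} and a numerical Hessian \eqn{\hat J}
#' (\code{stats::optimHess}).
#'
#' @param y count series (length at least 30).
#' @param alpha DPD tuning parameter.
#' @param fam a \code{\link{count_family}}.
#' @param init \code{"moments"} (start at \eqn{a=b=0.2},
#'   \eqn{\omega=0.6\bar Y}) or an \code{\link{ingarch_params}}.
#' @param x1 filter initial value; default \code{mean(y)}.
#' @param eps interior margin of the parameter space.
#' @param omega_bounds length-2 bounds for \eqn{\omega}; default
#'   \code{c(1e-3, max(10 * mean(y), 10))}.
#' @param tol truncation tail mass for support sums.
#' @param starts extra jittered restarts attempted when the first
#'   optimization does not report convergence.
#' @return object of class \code{"mdpde_fit"}: \code{theta_hat},
#'   \code{alpha}, \code{objective_value}, \code{khat}, \code{jhat},
#'   \code{cov}, \code{converged}, \code{n_obs}, \code{x1}, \code{family}.
#' @examples
#' set.seed(1)
#' y <- simulate_ingarch(ingarch_params(2, 0.3, 0.3), 300)
#' mdpde(y, alpha = 0.1)
#' @export
mdpde <- function(y, alpha = 0, fam = count_family("poisson"),
                  init = "moments", x1 = NULL, eps = 1e-3,
                  omega_bounds = NULL, tol = 1e-12, starts = 3L) {
  y <- check_counts(y)
  if (length(y) < 30L) stop("need at least 30 observations to fit")
  if (is.null(x1)) x1 <- mean(y)
  if (is.null(omega_bounds)) omega_bounds <- c(1e-3, max(10 * mean(y), 10))
  w1 <- omega_bounds[1]; w2 <- omega_bounds[2]

  # objective/gradient share one filter pass via a small cache
  cache <- new.env(parent = emptyenv())
  eval_at <- function(u) {
    key <- paste(format(u, digits = 17), collapse = ",")
    if (identical(cache$key, key)) return(cache$val)
    th <- theta_of_u(u, eps)
    val <- NULL
    if (th[1] < w1 || th[1] > w2 || !is.finite(th[1])) {
      val <- list(obj = 1e10 + sum(u^2), grad_u = 2 * u)
    } else {
      fs <- ingarch_filter(y, th, x1 = x1, fam = fam)
      if (any(!is.finite(fs$means)) || max(fs$means) > 1e7) {
        val <- list(obj = 1e10 + sum(u^2), grad_u = 2 * u)
      } else {
        tm <- dpd_terms(y, fs$means, fs$etas, alpha, fam, tol)
        obj <- mean(tm$loss)
        if (!is.finite(obj)) {
          val <- list(obj = 1e10 + sum(u^2), grad_u = 2 * u)
        } else {
          gth <- colMeans(fs$grads * tm$u)
          val <- list(obj = obj,
                      grad_u = drop(crossprod(jac_theta_u(u, eps), gth)))
        }
      }
    }
    cache$key <- key; cache$val <- val
    val
  }

  th0 <- if (identical(init, "moments")) {
    c(min(max(0.6 * mean(y), w1 * 1.01), w2 * 0.99), 0.2, 0.2)
  } else as_theta(init)
  if (!contraction_check(th0, eps)) stop("initial value outside the parameter space")
  u0 <- u_of_theta(th0, eps)

  run <- function(u) {
    o <- stats::nlminb(u, objective = function(u) eval_at(u)$obj,
                       gradient = function(u) eval_at(u)$grad_u,
                       control = list(iter.max = 300, eval.max = 500))
    o$value <- o$objective
    o
  }
  # declared converged when the optimizer reports success or the
  # (scale-adjusted) gradient at the returned point is numerically zero
  done <- function(o) o$convergence == 0 || max(abs(eval_at(o$par)$grad_u)) < 1e-4
  opt <- run(u0)
  if (!done(opt) && starts > 0L) {
    for (k in seq_len(starts)) {
      o2 <- try(run(u0 + stats::rnorm(3, sd = 0.5)), silent = TRUE)
      if (!inherits(o2, "try-error") && o2$value < opt$value) opt <- o2
      if (done(opt)) break
    }
  }
  converged <- done(opt)

  th_hat <- theta_of_u(opt$par, eps)
  fs <- ingarch_filter(y, th_hat, x1 = x1, fam = fam)
  sp <- score_path(y, fs, alpha, fam, tol)
  khat <- score_cov(sp)
  obj_theta <- function(th) {
    if (!contraction_check(th, eps / 2) || th[1] < w1 / 2) return(1e10)
    mdpde_objective(y, th, alpha, fam, x1 = x1, tol = tol)
  }
  jhat <- tryCatch(stats::optimHess(th_hat, obj_theta), error = function(e) NULL)
  cov <- NULL
  if (!is.null(jhat)) {
    jhat <- (jhat + t(jhat)) / 2
    cov <- tryCatch(solve(jhat, khat) %*% solve(jhat) / length(y),
                    error = function(e) NULL)
  }
  structure(list(
    theta_hat = ingarch_params(th_hat[1], th_hat[2], th_hat[3]),
    alpha = alpha, objective_value = opt$value,
    khat = khat, jhat = jhat, cov = cov,
    converged = converged, n_obs = length(y),
    x1 = x1, family = fam$name
  ), class = "mdpde_fit")
}

#' @export
print.mdpde_fit <- function(x, ...) {
  cat(sprintf("MDPDE fit (alpha = %g, family = %s, n = %d)\n",
              x$alpha, x$family, x$n_obs))
  th <- unclass(x$theta_hat)
  se <- if (!is.null(x$cov)) sqrt(pmax(diag(x$cov), 0)) else rep(NA_real_, 3)
  out <- rbind(estimate = th, se = se)
  print(round(out, 4))
  cat(sprintf("objective = %.6f, converged = %s\n",
              x$objective_value, x$converged))
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' @param fit an \code{"mdpde_fit"}.
#' @return a JSON string with the estimate, tuning parameter, objective,
#'   covariance, convergence flag and sample size.
#' @export
fit_json <- function(fit) {
  stopifnot(inherits(fit, "mdpde_fit"))
  jsonlite::toJSON(list(
    theta_hat = as.list(unclass(fit$theta_hat)), alpha = fit$alpha,
    objective_value = fit$objective_value,
    cov = if (is.null(fit$cov)) NULL else unname(apply(fit$cov, 1, as.list)),
    converged = fit$converged, n_obs = fit$n_obs
  ), auto_unbox = TRUE, digits = NA)
}
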