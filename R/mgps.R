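# Multi-item gamma-Poisson shrinker: DuMouchel's empirical-Bayes model for
# observed/expected report counts. The relative reporting rate lambda of
# each event has a two-component gamma mixture prior
#   lambda ~ w Gamma(alpha1, beta1) + (1 - w) Gamma(alpha2, beta2)
# (shape/rate), and a ~ Poisson(lambda E). Marginally a is a mixture of
# negative binomials, which is what the prior is fitted to; posteriors are
# conjugate gamma mixtures, giving EBGM (the geometric-mean shrunk ratio)
# and EB05 (the posterior 5th percentile) in closed or near-closed form.

new_mgps_prior <- function(alpha1, beta1, alpha2, beta2, w,
                           loglik = NA_real_, convergence = NULL) {
  if (any(c(alpha1, beta1, alpha2, beta2) <= 0) || w <= 0 || w >= 1) {
    stop("mgps_prior: shapes and rates must be positive and w in (0, 1)")
  }
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
    beta2 = beta2, w = w, loglik = loglik, convergence = convergence),
    class = "mgps_prior")
}

#' Construct an MGPS mixture prior
#'
#' @param alpha1,beta1 shape and rate of the first gamma component.
#' @param alpha2,beta2 shape and rate of the second gamma component.
#' @param w mixture weight of the first component, in (0, 1).
#' @return an `mgps_prior` object.
#' @export
mgps_prior <- function(alpha1, beta1, alpha2, beta2, w) {
  new_mgps_prior(alpha1, beta1, alpha2, beta2, w)
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat(sprintf(
    "MGPS two-component gamma mixture prior\n  component 1: Gamma(%.4g, %.4g)  weight %.3f\n  component 2: Gamma(%.4g, %.4g)  weight %.3f\n",
    x$alpha1, x$beta1, x$w, x$alpha2, x$beta2, 1 - x$w))
  if (!is.na(x$loglik)) cat(sprintf("  marginal log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}

# Mixture negative-binomial log-likelihood of counts a with expecteds e
# under parameters theta = (log a1, log b1, log a2, log b2, logit w).
mgps_negloglik <- function(theta, a, e) {
  a1 <- exp(theta[1]); b1 <- exp(theta[2])
  a2 <- exp(theta[3]); b2 <- exp(theta[4])
  w <- stats::plogis(theta[5])
  # extreme proposals can push dnbinom outside its numeric range; the
  # resulting non-finite likelihood is rejected below, so silence the NaNs
  l1 <- suppressWarnings(stats::dnbinom(a, size = a1, prob = b1 / (b1 + e), log = TRUE))
  l2 <- suppressWarnings(stats::dnbinom(a, size = a2, prob = b2 / (b2 + e), log = TRUE))
  m <- pmax(l1, l2)
  ll <- sum(m + log(w * exp(l1 - m) + (1 - w) * exp(l2 - m)))
  if (!is.finite(ll)) return(1e10)
  -ll
}

# Fixed multi-start grid: the classical DuMouchel starting point plus
# dispersed alternatives covering shrink-to-null and signal-rich shapes.
mgps_starts <- function() {
  list(
    c(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4, w = 1 / 3),
    c(alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1.2, w = 0.5),
    c(alpha1 = 0.5, beta1 = 0.5, alpha2 = 5, beta2 = 2, w = 0.2),
    c(alpha1 = 2, beta1 = 2, alpha2 = 0.2, beta2 = 0.2, w = 0.7),
    c(alpha1 = 10, beta1 = 10, alpha2 = 0.5, beta2 = 0.1, w = 0.9),
    c(alpha1 = 0.1, beta1 = 0.05, alpha2 = 1.5, beta2 = 1.5, w = 0.4)
  )
}

#' Fit the MGPS mixture prior by marginal maximum likelihood
#'
#' Maximizes the marginal likelihood of the observed event counts, which
#' under the gamma-Poisson model is a two-component negative-binomial
#' mixture evaluated at each table's expected count E. Optimization runs
#' quasi-Newton (BFGS) on log/logit-transformed parameters from six fixed
#' starting points; the best converged optimum is returned with its
#' log-likelihood and convergence metadata.
#'
#' @param tables tibble of 2x2 tables (needs >= 20 rows; five
#'   hyperparameters are not identifiable from fewer events).
#' @param stratified_e optional expected-count override.
#' @return an `mgps_prior` with `loglik` and `convergence` metadata.
#' @export
fit_mgps_prior <- function(tables, stratified_e = NULL) {
  if (nrow(tables) < 20) {
    stop("fit_mgps_prior: need at least 20 tables to fit the mixture prior (got ",
      nrow(tables), ")")
  }
  a <- tables$a
  e <- stratified_e %||% expected_count(tables)

  fits <- lapply(mgps_starts(), function(s) {
    theta0 <- c(log(s[1:4]), stats::qlogis(s[5]))
    tryCatch(
      stats::optim(theta0, mgps_negloglik, a = a, e = e, method = "BFGS",
        control = list(maxit = 500, reltol = 1e-12)),
      error = function(err) list(value = Inf, convergence = 99, message = conditionMessage(err))
    )
  })
  values <- vapply(fits, function(f) f$value, numeric(1))
  converged <- vapply(fits, function(f) isTRUE(f$convergence == 0), logical(1))
  if (!any(converged)) {
    best <- fits[[which.min(values)]]
    stop("fit_mgps_prior: no start converged; best incumbent -loglik = ",
      format(best$value), " (convergence code ", best$convergence, ")")
  }
  idx <- which(converged)[which.min(values[converged])]
  best <- fits[[idx]]
  th <- best$par
  # an optimum on the boundary of the transformed space (|logit w| or
  # |log alpha| huge) is an effectively degenerate mixture; clamp into the
  # open parameter space instead of failing construction
  shapes <- pmin(pmax(exp(th[1:4]), 1e-12), 1e12)
  new_mgps_prior(
    alpha1 = shapes[1], beta1 = shapes[2],
    alpha2 = shapes[3], beta2 = shapes[4],
    w = min(max(stats::plogis(th[5]), 1e-12), 1 - 1e-12),
    loglik = -best$value,
    convergence = list(start = idx, counts = best$counts,
      code = best$convergence, n_converged = sum(converged))
  )
}

#' Posterior EBGM and EB05 scores
#'
#' Given the fitted prior, the posterior of the relative reporting rate for
#' a table with count `a` and expected `E` is again a two-component gamma
#' mixture with shapes `alpha_j + a`, rates `beta_j + E` and weight updated
#' by the component marginal likelihoods. `EBGM = 2^(E[log2 lambda])` uses
#' the digamma closed form per component; `EB05` is the 5th percentile of
#' the posterior mixture, found by bracketed root-finding on the mixture
#' CDF (absolute tolerance 1e-9). Signal flag: EB05 > 2.
#'
#' @param tables tibble of 2x2 tables.
#' @param prior an `mgps_prior`.
#' @param stratified_e optional expected-count override.
#' @return tibble with `ebgm`, `eb05`, `mgps_flag`.
#' @export
mgps_scores <- function(tables, prior, stratified_e = NULL) {
  if (!inherits(prior, "mgps_prior")) stop("mgps_scores: prior must be an mgps_prior")
  a <- tables$a
  e <- stratified_e %||% expected_count(tables)

  l1 <- stats::dnbinom(a, size = prior$alpha1, prob = prior$beta1 / (prior$beta1 + e), log = TRUE)
  l2 <- stats::dnbinom(a, size = prior$alpha2, prob = prior$beta2 / (prior$beta2 + e), log = TRUE)
  m <- pmax(l1, l2)
  q1 <- prior$w * exp(l1 - m)
  q2 <- (1 - prior$w) * exp(l2 - m)
  q <- q1 / (q1 + q2)  # posterior weight of component 1

  sh1 <- prior$alpha1 + a; rt1 <- prior$beta1 + e
  sh2 <- prior$alpha2 + a; rt2 <- prior$beta2 + e

  mean_log <- q * (digamma(sh1) - log(rt1)) + (1 - q) * (digamma(sh2) - log(rt2))
  ebgm <- exp(mean_log)

  eb05 <- vapply(seq_along(a), function(i) {
    posterior_mixture_quantile(0.05, q[i], sh1[i], rt1[i], sh2[i], rt2[i])
  }, numeric(1))

  tibble::tibble(ebgm = ebgm, eb05 = eb05, mgps_flag = eb05 > 2)
}

# Quantile of w Gamma(sh1, rt1) + (1 - w) Gamma(sh2, rt2) by root-finding
# on the mixture CDF, bracketed by the component quantiles.
posterior_mixture_quantile <- function(p, w, sh1, rt1, sh2, rt2) {
  cdf <- function(x) {
    w * stats::pgamma(x, shape = sh1, rate = rt1) +
      (1 - w) * stats::pgamma(x, shape = sh2, rate = rt2)
  }
  q1 <- stats::qgamma(p, shape = sh1, rate = rt1)
  q2 <- stats::qgamma(p, shape = sh2, rate = rt2)
  lo <- min(q1, q2)
  hi <- max(q1, q2)
  if (hi - lo < 1e-12) return(lo)
  # pad the component-quantile bracket against floating-point slack in the
  # mixture CDF; CDF(0) - p = -p < 0 makes 0 an always-valid lower bound
  lo <- max(0, lo * (1 - 1e-9))
  hi <- hi * (1 + 1e-9) + 1e-300
  f_lo <- cdf(lo) - p
  f_hi <- cdf(hi) - p
  if (f_lo > 0) lo <- 0
  if (f_hi < 0) {
    stop("posterior_mixture_quantile: bracket failure [", lo, ", ", hi,
      "] with CDF offsets ", f_lo, ", ", f_hi)
  }
  stats::uniroot(function(x) cdf(x) - p, lower = lo, upper = hi,
    tol = 1e-10)$root
}
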