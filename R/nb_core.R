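# Negative binomial primitives shared by the simulator and the DE tests.
#
# Parameterisation used throughout: NB(mean = mu, dispersion = phi) with
# var = mu * (1 + phi * mu). Internally this maps to R's (size, mu) form via
# size = 1/phi; phi = 0 is the Poisson limit.

PHI_MIN <- 1e-8
PHI_MAX <- 50

#' Negative binomial parameters (mean-dispersion form)
#'
#' Container for a per-transcript NB law \eqn{K \sim NB(\mu, \phi)} with
#' \eqn{E(K) = \mu} and \eqn{Var(K) = \mu(1 + \phi\mu)}. `dispersion = 0`
#' denotes the Poisson limit.
#'
#' @param mean Positive expected count per lane.
#' @param dispersion Non-negative dispersion \eqn{\phi} (unitless).
#' @return An object of class `"nb_params"`.
#' @export
#' @examples
#' nb_params(mean = 5, dispersion = 0.4)
nb_params <- function(mean, dispersion) {
  check_scalar_number(mean, "mean", lower = 0, allow_boundary = FALSE)
  check_scalar_number(dispersion, "dispersion", lower = 0)
  structure(list(mean = mean, dispersion = dispersion, degenerate = FALSE),
            class = "nb_params")
}

#' @export
print.nb_params <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<nb_params> degenerate (all-zero counts)\n")
  } else {
    cat(sprintf("<nb_params> mean = %g, dispersion = %g (var = %g)\n",
                x$mean, x$dispersion, x$mean * (1 + x$dispersion * x$mean)))
  }
  invisible(x)
}

#' Negative binomial probability mass function
#'
#' Probability of observing `k` counts under `NB(mean, var = mean(1 +
#' dispersion * mean))`. At `dispersion = 0` this is the Poisson pmf.
#'
#' @param k Vector of non-negative integers.
#' @param params An [nb_params()] object.
#' @param log Return log-probabilities?
#' @return Probabilities in `[0, 1]` (or their logs).
#' @export
#' @examples
#' nb_pmf(0, nb_params(1, 1)) # (1 + phi*mu)^(-1/phi) = 0.5
nb_pmf <- function(k, params, log = FALSE) {
  stopifnot(inherits(params, "nb_params"))
  if (isTRUE(params$degenerate)) {
    stop_input("cannot evaluate the pmf of a degenerate transcript")
  }
  k <- check_count_vector(k, "k")
  if (params$dispersion == 0) {
    dpois(k, lambda = params$mean, log = log)
  } else {
    dnbinom(k, size = 1 / params$dispersion, mu = params$mean, log = log)
  }
}

#' Distribution of a sum of independent NB replicates
#'
#' The sum of `n_reps` iid `NB(mu, phi)` draws is again negative binomial
#' (the gamma shape parameters add), with mean `n_reps * mu` and dispersion
#' `phi / n_reps`. This is the per-condition pooled law on which the exact
#' conditional test is built.
#'
#' @param params An [nb_params()] object for a single replicate.
#' @param n_reps Number of independent replicates (>= 1).
#' @return An [nb_params()] object for the sum.
#' @export
#' @examples
#' pooled_sum_params(nb_params(3, 0.6), n_reps = 2) # mean 6, dispersion 0.3
pooled_sum_params <- function(params, n_reps) {
  stopifnot(inherits(params, "nb_params"))
  check_scalar_number(n_reps, "n_reps", lower = 1)
  if (n_reps != round(n_reps)) stop_input("`n_reps` must be an integer")
  nb_params(mean = n_reps * params$mean,
            dispersion = params$dispersion / n_reps)
}

# Profile log-likelihood of phi with the mean fixed at its MLE (the sample
# mean): the NB mean MLE is free of phi, so one-dimensional optimisation over
# phi is the full MLE.
nb_profile_loglik <- function(counts, mean, phi) {
  if (phi == 0) {
    sum(dpois(counts, lambda = mean, log = TRUE))
  } else {
    sum(dnbinom(counts, size = 1 / phi, mu = mean, log = TRUE))
  }
}

#' Maximum likelihood fit of NB mean and dispersion
#'
#' Fits `NB(mu, phi)` to a vector of replicate counts. The mean estimate is
#' the sample mean; the dispersion maximises the profile log-likelihood over
#' `[phi_min, phi_max]` (bounded search on the log scale). When the sample
#' variance does not exceed the sample mean there is no evidence of
#' overdispersion and the dispersion is clamped to `phi_min`. An all-zero
#' vector carries no information about either parameter and is returned as a
#' degenerate sentinel (`mean = 0`, `dispersion = NA`) that downstream
#' simulation refuses to use.
#'
#' @param counts Vector of non-negative integer counts, length >= 2.
#' @param phi_min,phi_max Dispersion search bounds.
#' @param tol Optimisation tolerance (on log-phi).
#' @return An [nb_params()] object; check `$degenerate`.
#' @export
#' @examples
#' estimate_nb_mle(c(5, 5, 5, 5)) # mean 5, dispersion clamped at phi_min
estimate_nb_mle <- function(counts, phi_min = PHI_MIN, phi_max = PHI_MAX,
                            tol = 1e-8) {
  counts <- check_count_vector(counts)
  if (length(counts) < 2L) stop_input("need at least 2 replicate counts")
  check_scalar_number(phi_min, "phi_min", lower = 0, allow_boundary = FALSE)
  check_scalar_number(phi_max, "phi_max", lower = phi_min)
  m <- mean(counts)
  if (m == 0) {
    return(structure(list(mean = 0, dispersion = NA_real_, degenerate = TRUE),
                     class = "nb_params"))
  }
  v <- var(counts)
  if (v <= m) {
    phi <- phi_min
  } else {
    opt <- optimize(function(lphi) nb_profile_loglik(counts, m, exp(lphi)),
                    interval = log(c(phi_min, phi_max)),
                    maximum = TRUE, tol = tol)
    phi <- min(max(exp(opt$maximum), phi_min), phi_max)
  }
  nb_params(mean = m, dispersion = phi)
}

#' Fit the parametric mean-dispersion trend phi = a + b / mu
#'
#' Models the dispersion as an asymptotic value `a` plus a shot-noise-like
#' `b / mu` term, the trend used by the max-parametric strategy. The fit is a
#' gamma-family generalised linear model with identity link on the covariate
#' `1/mu`, initialised from ordinary least squares; if the GLM fails or does
#' not converge, the OLS coefficients (clamped at zero) are used instead.
#' Only strictly positive dispersions enter the fit.
#'
#' @param means Per-transcript means (> 0).
#' @param dispersions Per-transcript dispersion estimates (>= 0); zeros are
#'   dropped before fitting.
#' @return An object of class `"parametric_dispersion_fit"` with fields `a`,
#'   `b`, `method` ("gamma-glm" or "ols") and `converged`.
#' @export
#' @examples
#' mu <- c(5, 20, 100, 400)
#' fit <- fit_parametric_dispersion(mu, 0.1 + 50 / mu)
#' c(fit$a, fit$b)
fit_parametric_dispersion <- function(means, dispersions) {
  if (length(means) != length(dispersions)) {
    stop_input("`means` and `dispersions` must have the same length")
  }
  ok <- is.finite(means) & is.finite(dispersions) & means > 0 & dispersions > 0
  if (sum(ok) < 3L) stop_input("need at least 3 usable (mean, dispersion) pairs")
  x <- 1 / means[ok]
  y <- dispersions[ok]
  ols <- coef(lm(y ~ x))
  a <- NA_real_
  b <- NA_real_
  method <- "ols"
  converged <- FALSE
  start <- pmax(unname(ols), 1e-8) # identity-link gamma needs positive fitted values
  fit <- tryCatch(
    suppressWarnings(glm(y ~ x, family = Gamma(link = "identity"),
                         start = start, control = list(maxit = 100))),
    error = function(e) NULL
  )
  if (!is.null(fit) && fit$converged && all(is.finite(coef(fit)))) {
    a <- max(unname(coef(fit)[1]), 0)
    b <- max(unname(coef(fit)[2]), 0)
    method <- "gamma-glm"
    converged <- TRUE
  } else {
    a <- max(unname(ols[1]), 0)
    b <- max(unname(ols[2]), 0)
  }
  if (a == 0 && b == 0) a <- max(mean(y), PHI_MIN)
  structure(list(a = a, b = b, method = method, converged = converged,
                 n_points = sum(ok)),
            class = "parametric_dispersion_fit")
}

#' @export
print.parametric_dispersion_fit <- function(x, ...) {
  cat(sprintf("<parametric_dispersion_fit> phi = %g + %g/mu (%s, %d points)\n",
              x$a, x$b, x$method, x$n_points))
  invisible(x)
}

#' Predicted dispersion from a parametric trend fit
#' @param object A `"parametric_dispersion_fit"`.
#' @param means Means at which to predict.
#' @param ... Unused.
#' @return Predicted dispersions `a + b / means`.
#' @export
predict.parametric_dispersion_fit <- function(object, means, ...) {
  object$a + object$b / means
}

#' Fit the power-law mean-dispersion trend phi = c * mu^(alpha - 2)
#'
#' A linear relationship between log-dispersion and log-mean: the regression
#' of `log(phi)` on `log(mu)` has slope `alpha - 2` and intercept `log(c)`.
#' `alpha = 2` is the constant-dispersion (NB2) case and `alpha = 1` the NB1
#' case. Zero dispersions are excluded before fitting; if all means are
#' identical the slope is taken as 0 (constant dispersion).
#'
#' @param means Per-transcript means (> 0).
#' @param dispersions Per-transcript dispersions (> 0 after exclusion).
#' @return An object of class `"powerlaw_dispersion_fit"` with fields `c`,
#'   `alpha`, and the regression standard errors `se_log_c`, `se_slope`.
#' @export
#' @examples
#' mu <- 10^seq(0, 4, length.out = 50)
#' fit <- fit_powerlaw_dispersion(mu, 0.364 * mu^(1.7 - 2))
#' c(fit$c, fit$alpha)
fit_powerlaw_dispersion <- function(means, dispersions) {
  if (length(means) != length(dispersions)) {
    stop_input("`means` and `dispersions` must have the same length")
  }
  ok <- is.finite(means) & is.finite(dispersions) & means > 0 & dispersions > 0
  if (sum(ok) < 3L) stop_input("need at least 3 positive (mean, dispersion) pairs")
  lx <- log(means[ok])
  ly <- log(dispersions[ok])
  if (diff(range(lx)) < .Machine$double.eps^0.5) {
    slope <- 0
    intercept <- mean(ly)
    se <- c(intercept = NA_real_, slope = NA_real_)
  } else {
    fit <- lm(ly ~ lx)
    cf <- suppressWarnings(coef(summary(fit))) # exact fits trip summary.lm

    intercept <- cf[1, 1]
    slope <- cf[2, 1]
    se <- c(intercept = cf[1, 2], slope = cf[2, 2])
  }
  structure(list(c = exp(intercept), alpha = slope + 2,
                 se_log_c = unname(se["intercept"]),
                 se_slope = unname(se["slope"]),
                 n_points = sum(ok)),
            class = "powerlaw_dispersion_fit")
}

#' @export
print.powerlaw_dispersion_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_dispersion_fit> phi = %g * mu^(%g - 2) (%d points)\n",
              x$c, x$alpha, x$n_points))
  invisible(x)
}

#' Predicted dispersion from a power-law trend fit
#' @param object A `"powerlaw_dispersion_fit"`.
#' @param means Means at which to predict.
#' @param ... Unused.
#' @return Predicted dispersions `c * means^(alpha - 2)`.
#' @export
predict.powerlaw_dispersion_fit <- function(object, means, ...) {
  object$c * means^(object$alpha - 2)
}
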