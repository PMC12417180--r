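# Kaplan-Meier estimation, between-arm comparison statistics, maximum
# likelihood fitting of six accelerated failure time families, AIC-based
# family selection, and extrapolation.
#
# Parameterizations (fixed; t > 0 throughout):
#   exponential  S(t) = exp(-rate * t)
#   weibull      S(t) = exp(-(t/scale)^shape)
#   lognormal    S(t) = 1 - Phi((log t - meanlog)/sdlog)
#   loglogistic  S(t) = 1 / (1 + (t/scale)^shape)
#   gompertz     S(t) = exp(-(rate/shape) (exp(shape t) - 1)), shape in R
#   gengamma     Prentice (mu, sigma, Q) form; Q = 0 is lognormal

AFT_FAMILIES <- c("exponential", "weibull", "lognormal", "loglogistic",
                  "gompertz", "gengamma")

.N_PARAMS <- c(exponential = 1L, weibull = 2L, lognormal = 2L,
               loglogistic = 2L, gompertz = 2L, gengamma = 3L)

#' Kaplan-Meier estimate for one arm
#'
#' Product-limit estimator (events before censorings at tied times) with
#' Greenwood standard errors, computed via [survival::survfit()].
#'
#' @param ipd An [ipd_dataset()].
#' @param arm Arm label to estimate; defaults to the only arm present.
#' @return An object of class `km_estimate`: data frame with columns `time`,
#'   `n_risk`, `n_event`, `surv`, `std_err`.
#' @export
km_estimate <- function(ipd, arm = NULL) {
  stopifnot(inherits(ipd, "ipd"))
  if (is.null(arm)) {
    arms <- unique(ipd$arm)
    if (length(arms) != 1L) stop("multiple arms present; specify 'arm'", call. = FALSE)
    arm <- arms
  }
  d <- ipd[ipd$arm == arm, , drop = FALSE]
  if (nrow(d) == 0L) stop(sprintf("no records for arm '%s'", arm), call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  structure(
    data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
               surv = sf$surv, std_err = sf$std.err * sf$surv),
    arm_id = arm, n = nrow(d),
    class = c("km_estimate", "data.frame")
  )
}

#' Evaluate a KM step function at arbitrary times
#'
#' Right-continuous step evaluation: S(t) is the estimate after all events at
#' times <= t; S = 1 before the first event.
#'
#' @param km A [km_estimate()].
#' @param times Times at which to evaluate.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, times) {
  sf <- stats::stepfun(km$time, c(1, km$surv), right = FALSE)
  sf(times)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank statistic via [survival::survdiff()];
#' p-value from the chi-square distribution with 1 df.
#'
#' @param ipd An [ipd_dataset()] with exactly two arms.
#' @return List with `chi2` and `p`.
#' @export
logrank_test <- function(ipd) {
  stopifnot(inherits(ipd, "ipd"))
  arms <- unique(ipd$arm)
  if (length(arms) != 2L) stop("log-rank test requires exactly two arms", call. = FALSE)
  for (a in arms) {
    if (sum(ipd$event[ipd$arm == a]) == 0L) {
      stop(sprintf("arm '%s' has no events", a), call. = FALSE)
    }
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ arm, data = ipd)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards ratio between two arms
#'
#' Partial-likelihood estimate with Breslow tie handling and a Wald 95%
#' confidence interval on the log scale. The hazard ratio is for `arm`
#' relative to `ref`.
#'
#' @param ipd An [ipd_dataset()] with exactly two arms.
#' @param ref Reference arm label; default the first arm in sort order.
#' @return An object of class `comparison_stats`: list with `hazard_ratio`,
#'   `hr_ci95` (low, high), `logrank_chi2`, `logrank_p`.
#' @export
cox_hazard_ratio <- function(ipd, ref = NULL) {
  stopifnot(inherits(ipd, "ipd"))
  arms <- sort(unique(ipd$arm))
  if (length(arms) != 2L) stop("hazard ratio requires exactly two arms", call. = FALSE)
  if (sum(ipd$event) == 0L) stop("no events in either arm", call. = FALSE)
  if (is.null(ref)) ref <- arms[1L]
  d <- as.data.frame(ipd)
  d$arm <- stats::relevel(factor(d$arm, levels = arms), ref = ref)
  fit <- survival::coxph(survival::Surv(time, event) ~ arm, data = d,
                         ties = "breslow")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1L, 1L]))
  lr <- logrank_test(ipd)
  structure(list(
    hazard_ratio = exp(beta),
    hr_ci95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
    logrank_chi2 = lr$chi2, logrank_p = lr$p,
    arm = setdiff(arms, ref), ref = ref
  ), class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf("HR (%s vs %s) = %.3f [%.3f-%.3f]; log-rank chi2 = %.2f, p = %.4g\n",
              x$arm, x$ref, x$hazard_ratio, x$hr_ci95[1L], x$hr_ci95[2L],
              x$logrank_chi2, x$logrank_p))
  invisible(x)
}

## ---- family survival / density / hazard -------------------------------

#' Survival function of a fitted (or specified) AFT family
#'
#' @param fit A `parametric_fit`, or a family name with `params` supplied.
#' @param t Non-negative times (the fit's time unit).
#' @param params Named parameter vector when `fit` is a family name.
#' @return S(t) in \[0, 1\].
#' @export
survival_at <- function(fit, t, params = NULL) {
  if (inherits(fit, "parametric_fit")) {
    family <- fit$family; params <- fit$params
  } else {
    family <- fit
  }
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  .check_params(family, params)
  p <- as.list(params)
  s <- switch(family,
    exponential = exp(-p$rate * t),
    weibull = exp(-(t / p$scale)^p$shape),
    lognormal = stats::plnorm(t, p$meanlog, p$sdlog, lower.tail = FALSE),
    loglogistic = 1 / (1 + (t / p$scale)^p$shape),
    gompertz = {
      a <- p$shape; b <- p$rate
      if (abs(a) < 1e-12) exp(-b * t) else exp(-(b / a) * (exp(a * t) - 1))
    },
    gengamma = .sgengamma(t, p$mu, p$sigma, p$Q),
    stop(sprintf("unknown family '%s'", family), call. = FALSE)
  )
  pmin(pmax(s, 0), 1)
}

# log density per family (vectorized over t > 0)
.log_density <- function(family, params, t) {
  p <- as.list(params)
  switch(family,
    exponential = log(p$rate) - p$rate * t,
    weibull = stats::dweibull(t, p$shape, p$scale, log = TRUE),
    lognormal = stats::dlnorm(t, p$meanlog, p$sdlog, log = TRUE),
    loglogistic = {
      z <- (t / p$scale)^p$shape
      log(p$shape) - log(p$scale) + (p$shape - 1) * (log(t) - log(p$scale)) -
        2 * log1p(z)
    },
    gompertz = {
      a <- p$shape; b <- p$rate
      h <- log(b) + a * t
      cum <- if (abs(a) < 1e-12) b * t else (b / a) * (exp(a * t) - 1)
      h - cum
    },
    gengamma = .dgengamma_log(t, p$mu, p$sigma, p$Q)
  )
}

# Generalized gamma, Prentice (mu, sigma, Q) parameterization.
.sgengamma <- function(t, mu, sigma, Q) {
  s <- numeric(length(t))
  pos <- t > 0
  s[!pos] <- 1
  if (any(pos)) {
    w <- (log(t[pos]) - mu) / sigma
    if (abs(Q) < 1e-8) {
      s[pos] <- stats::pnorm(w, lower.tail = FALSE)
    } else {
      k <- Q^-2
      u <- k * exp(Q * w)
      s[pos] <- if (Q > 0) stats::pgamma(u, k, lower.tail = FALSE)
                else stats::pgamma(u, k, lower.tail = TRUE)
    }
  }
  s
}

.dgengamma_log <- function(t, mu, sigma, Q) {
  w <- (log(t) - mu) / sigma
  if (abs(Q) < 1e-8) {
    return(stats::dlnorm(t, mu, sigma, log = TRUE))
  }
  k <- Q^-2
  log(abs(Q)) - log(sigma * t) + k * log(k) + k * (Q * w - exp(Q * w)) - lgamma(k)
}

.check_params <- function(family, params) {
  need <- switch(family,
    exponential = "rate", weibull = c("shape", "scale"),
    lognormal = c("meanlog", "sdlog"), loglogistic = c("shape", "scale"),
    gompertz = c("shape", "rate"), gengamma = c("mu", "sigma", "Q"),
    stop(sprintf("unknown family '%s'", family), call. = FALSE))
  if (!all(need %in% names(params))) {
    stop(sprintf("family '%s' needs parameters: %s", family,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  pos <- switch(family,
    exponential = "rate", weibull = c("shape", "scale"),
    lognormal = "sdlog", loglogistic = c("shape", "scale"),
    gompertz = "rate", gengamma = "sigma")
  if (any(!is.finite(unlist(params[need]))) || any(unlist(params[pos]) <= 0)) {
    stop(sprintf("invalid parameters for family '%s'", family), call. = FALSE)
  }
  invisible(TRUE)
}

#' Median survival time of a fitted family
#'
#' Closed form where available; otherwise solves S(m) = 1/2. Returns `Inf`
#' for a Gompertz fit whose survival plateaus above 1/2 (negative shape).
#'
#' @inheritParams survival_at
#' @return Median survival time in the fit's time unit.
#' @export
median_survival <- function(fit, params = NULL) {
  if (inherits(fit, "parametric_fit")) {
    family <- fit$family; params <- fit$params
  } else {
    family <- fit
  }
  .check_params(family, params)
  p <- as.list(params)
  switch(family,
    exponential = log(2) / p$rate,
    weibull = p$scale * log(2)^(1 / p$shape),
    lognormal = exp(p$meanlog),
    loglogistic = p$scale,
    gompertz = {
      a <- p$shape; b <- p$rate
      if (abs(a) < 1e-12) return(log(2) / b)
      z <- 1 + a * log(2) / b
      if (z <= 0) Inf else log(z) / a  # plateau above 1/2: never reached
    },
    gengamma = {
      if (abs(p$Q) < 1e-8) exp(p$mu)
      else {
        k <- p$Q^-2
        u <- if (p$Q > 0) stats::qgamma(0.5, k, lower.tail = FALSE)
             else stats::qgamma(0.5, k, lower.tail = TRUE)
        exp(p$mu + p$sigma * log(u / k) / p$Q)
      }
    }
  )
}

## ---- maximum likelihood fitting ---------------------------------------

#' Fit a parametric AFT family to right-censored IPD by maximum likelihood
#'
#' Maximizes the right-censored log-likelihood
#' \eqn{\ell = \sum_{events} \log f(t_i) + \sum_{censored} \log S(t_i)}
#' under the package's fixed parameterizations. Positive parameters are
#' log-transformed; optimization is gradient-based (BFGS, numerical
#' gradients) from three deterministic moment-style starting points, keeping
#' the best converged solution. The exponential rate is closed-form
#' (events / total time at risk).
#'
#' @param ipd An [ipd_dataset()].
#' @param arm Arm to fit; defaults to the only arm present.
#' @param family One of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`, `"gompertz"`, `"gengamma"`.
#' @return An object of class `parametric_fit`: list with `family`, `params`
#'   (named), `loglik`, `aic`, `n_params`, `n`, `n_events`, `converged`,
#'   `arm_id`, `endpoint`, `time_unit`.
#' @export
fit_parametric <- function(ipd, arm = NULL, family = AFT_FAMILIES) {
  family <- match.arg(family)
  stopifnot(inherits(ipd, "ipd"))
  if (is.null(arm)) {
    arms <- unique(ipd$arm)
    if (length(arms) != 1L) stop("multiple arms present; specify 'arm'", call. = FALSE)
    arm <- arms
  }
  d <- ipd[ipd$arm == arm, , drop = FALSE]
  t <- pmax(d$time, 1e-8)  # zero times are outside every family's support
  ev <- d$event
  if (sum(ev) < .N_PARAMS[[family]]) {
    stop(sprintf("arm '%s' has %d events; family '%s' needs at least %d",
                 arm, sum(ev), family, .N_PARAMS[[family]]), call. = FALSE)
  }

  if (family == "exponential") {
    rate <- sum(ev) / sum(t)
    params <- c(rate = rate)
    ll <- .censored_loglik(family, params, t, ev)
    converged <- TRUE
  } else {
    fit <- .fit_mle(family, t, ev)
    if (is.null(fit)) {
      stop(sprintf("fit failure: '%s' did not converge for arm '%s'",
                   family, arm), call. = FALSE)
    }
    params <- fit$params
    ll <- fit$loglik
    converged <- TRUE
  }
  k <- .N_PARAMS[[family]]
  structure(list(
    family = family, params = params, loglik = ll, aic = 2 * k - 2 * ll,
    n_params = k, n = length(t), n_events = sum(ev), converged = converged,
    arm_id = arm, endpoint = attr(ipd, "endpoint"),
    time_unit = attr(ipd, "time_unit")
  ), class = "parametric_fit")
}

# right-censored log-likelihood at a named parameter vector
.censored_loglik <- function(family, params, t, ev) {
  ll <- numeric(length(t))
  if (any(ev == 1)) ll[ev == 1] <- .log_density(family, params, t[ev == 1])
  if (any(ev == 0)) {
    s <- survival_at(family, t[ev == 0], params = params)
    ll[ev == 0] <- log(pmax(s, 1e-300))
  }
  sum(ll)
}

# parameter transforms: positive parameters live on the log scale
.to_natural <- function(family, theta) {
  switch(family,
    weibull = c(shape = exp(theta[1L]), scale = exp(theta[2L])),
    lognormal = c(meanlog = theta[1L], sdlog = exp(theta[2L])),
    loglogistic = c(shape = exp(theta[1L]), scale = exp(theta[2L])),
    gompertz = c(shape = theta[1L], rate = exp(theta[2L])),
    gengamma = c(mu = theta[1L], sigma = exp(theta[2L]), Q = theta[3L])
  )
}

# three deterministic moment-style starts per family
.start_points <- function(family, t, ev) {
  te <- t[ev == 1]
  m <- mean(log(te)); s <- max(stats::sd(log(te)), 0.1)
  if (!is.finite(s)) s <- 0.5
  rate0 <- sum(ev) / sum(t)
  switch(family,
    weibull = list(c(0, log(1 / rate0)), c(log(1.5), log(exp(m))),
                   c(log(0.75), log(1 / rate0))),
    lognormal = list(c(m, log(s)), c(m, log(2 * s)), c(m + s^2 / 2, log(s / 2))),
    loglogistic = list(c(log(1 / s), m), c(log(1.5 / s), m), c(0, log(1 / rate0))),
    gompertz = list(c(0.001, log(rate0)), c(0.5 * rate0, log(rate0)),
                    c(-0.5 * rate0, log(rate0))),
    gengamma = list(c(m, log(s), 0.01), c(m, log(s), 1), c(m, log(s), -1))
  )
}

.fit_mle <- function(family, t, ev) {
  nll <- function(theta) {
    params <- .to_natural(family, theta)
    if (any(!is.finite(params))) return(1e10)
    # extreme trial parameters legitimately under/overflow; treat as infeasible
    v <- suppressWarnings(-.censored_loglik(family, params, t, ev))
    if (!is.finite(v)) 1e10 else v
  }
  best <- NULL
  for (theta0 in .start_points(family, t, ev)) {
    opt <- tryCatch(
      stats::optim(theta0, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) {
      opt <- tryCatch(
        stats::optim(theta0, nll, method = "Nelder-Mead",
                     control = list(maxit = 2000)),
        error = function(e) NULL)
    }
    if (!is.null(opt) && is.finite(opt$value) && opt$value < 1e9 &&
        (is.null(best) || opt$value < best$value)) {
      best <- opt
    }
  }
  if (is.null(best)) return(NULL)
  # polish with Nelder-Mead in case BFGS stalled on a numerical-gradient kink
  pol <- tryCatch(stats::optim(best$par, nll, method = "Nelder-Mead",
                               control = list(maxit = 2000, reltol = 1e-12)),
                  error = function(e) NULL)
  if (!is.null(pol) && pol$value < best$value) best <- pol
  list(params = .to_natural(family, best$par), loglik = -best$value)
}

#' Fit all six AFT families to one arm
#'
#' Families whose optimizer fails are reported as failed rather than raising.
#'
#' @inheritParams fit_parametric
#' @param families Subset of [AFT_FAMILIES] to fit.
#' @return Named list of `parametric_fit` objects (failed families omitted,
#'   with a warning naming them).
#' @export
fit_all_families <- function(ipd, arm = NULL, families = AFT_FAMILIES) {
  fits <- list()
  failed <- character(0)
  for (fam in families) {
    f <- tryCatch(fit_parametric(ipd, arm = arm, family = fam),
                  error = function(e) e)
    if (inherits(f, "error")) failed <- c(failed, fam) else fits[[fam]] <- f
  }
  if (length(failed)) {
    warning(sprintf("fit failed for: %s", paste(failed, collapse = ", ")),
            call. = FALSE)
  }
  if (length(fits) == 0L) stop("all parametric fits failed", call. = FALSE)
  fits
}

#' Select the best fit by AIC
#'
#' Minimal AIC wins; ties are broken by fewer parameters, then by the fixed
#' family order (exponential, weibull, lognormal, loglogistic, gompertz,
#' gengamma).
#'
#' @param fits List of `parametric_fit` objects (e.g. [fit_all_families()]).
#' @return The selected `parametric_fit`.
#' @export
select_by_aic <- function(fits) {
  fits <- Filter(function(f) inherits(f, "parametric_fit"), fits)
  if (length(fits) == 0L) stop("no successful fits to select from", call. = FALSE)
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  k <- vapply(fits, `[[`, numeric(1), "n_params")
  fam_rank <- match(vapply(fits, `[[`, character(1), "family"), AFT_FAMILIES)
  ord <- order(aic, k, fam_rank)
  fits[[ord[1L]]]
}

#' Tabulate a set of fits for reporting
#'
#' @param fits Named list of `parametric_fit` objects.
#' @param selected Optionally, the fit returned by [select_by_aic()].
#' @return Data frame with one row per family: arm, endpoint, family,
#'   parameter string, loglik, AIC and a selected flag.
#' @export
fit_report <- function(fits, selected = NULL) {
  if (is.null(selected)) selected <- select_by_aic(fits)
  do.call(rbind, lapply(fits, function(f) {
    data.frame(
      arm = f$arm_id, endpoint = f$endpoint, family = f$family,
      params = paste(sprintf("%s=%.6g", names(f$params), f$params),
                     collapse = "; "),
      loglik = f$loglik, aic = f$aic,
      selected = identical(f$family, selected$family),
      row.names = NULL)
  }))
}

#' @export
print.parametric_fit <- function(x, ...) {
  cat(sprintf("Parametric fit: %s (%s, arm '%s'), logLik = %.3f, AIC = %.3f\n",
              x$family, x$endpoint, x$arm_id, x$loglik, x$aic))
  cat("  params:", paste(sprintf("%s = %.5g", names(x$params), x$params),
                         collapse = ", "), "\n")
  invisible(x)
}
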