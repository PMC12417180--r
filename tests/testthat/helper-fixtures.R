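# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# a parametric_fit object with known parameters, bypassing the optimizer
make_fit <- function(family, params, arm = "a", endpoint = "PFS",
                     time_unit = "years") {
  structure(list(
    family = family, params = params, loglik = 0,
    aic = 2 * length(params), n_params = length(params), n = 0L,
    n_events = 0L, converged = TRUE, arm_id = arm, endpoint = endpoint,
    time_unit = time_unit
  ), class = "parametric_fit")
}

# exponential fits for both endpoints of one arm
exp_fits <- function(rate_pfs, rate_os, arm = "a") {
  list(pfs = make_fit("exponential", c(rate = rate_pfs), arm, "PFS"),
       os = make_fit("exponential", c(rate = rate_os), arm, "OS"))
}

# a minimal two-arm cost table with constant costs
flat_cost_table <- function(n_cycles, sd_exp = 100, sd_ctrl = 50,
                            pd = 0, indep = 0) {
  series <- function(x) rep(x, n_cycles)
  cost_table(
    sd_cost = list(
      experimental = list(SD = series(sd_exp), PD = series(pd)),
      control = list(SD = series(sd_ctrl), PD = series(pd))),
    indep_cost = list(experimental = series(indep), control = series(indep)))
}

# right-censored exponential IPD for one arm
rexp_ipd <- function(n, rate, cens_rate = 0, arm = "a", endpoint = "PFS",
                     time_unit = "years") {
  t_ev <- stats::rexp(n, rate)
  if (cens_rate > 0) {
    cens <- stats::rexp(n, cens_rate)
    ipd_dataset(pmin(t_ev, cens), as.integer(t_ev <= cens), arm,
                endpoint = endpoint, time_unit = time_unit)
  } else {
    ipd_dataset(t_ev, rep(1L, n), arm, endpoint = endpoint,
                time_unit = time_unit)
  }
}

# independent brute-force evaluation of the right-censored log-likelihood
# using numerical densities (finite differences of the survival function)
numeric_loglik <- function(fit, times, events, h = 1e-6) {
  s <- function(t) survival_at(fit, t)
  ll <- 0
  for (i in seq_along(times)) {
    t <- times[i]
    if (events[i] == 1) {
      dens <- (s(max(t - h, 0)) - s(t + h)) / (t + h - max(t - h, 0))
      ll <- ll + log(dens)
    } else {
      ll <- ll + log(s(t))
    }
  }
  ll
}
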