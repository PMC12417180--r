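# Three-state partitioned survival model: per-cycle state occupancies read
# off the PFS and OS survival functions, per-cycle transition probabilities,
# beta-sampled utilities, and discounted QALY accumulation.

#' Economic model settings
#'
#' @param cycle_length_weeks Model/treatment cycle length in weeks (default 3,
#'   the Q3W convention in oncology regimens).
#' @param n_cycles Number of cycles in the lifetime horizon; usually inferred
#'   from the cost table length.
#' @param discount_rate_annual Annual discount rate (e.g. 0.05).
#' @param n_sims Number of Monte-Carlo simulations (default 1000).
#' @param seed Integer seed for all sampling.
#' @param wtp Reference willingness-to-pay threshold (currency per QALY).
#' @return An object of class `econ_settings`. The implied lifetime horizon in
#'   years is `n_cycles * cycle_length_weeks / (365.25/7)`.
#' @export
econ_settings <- function(cycle_length_weeks = 3, n_cycles,
                          discount_rate_annual = 0.05, n_sims = 1000L,
                          seed = 1L, wtp) {
  stopifnot(cycle_length_weeks > 0, n_cycles >= 1, discount_rate_annual >= 0,
            n_sims >= 1, wtp > 0)
  structure(list(
    cycle_length_weeks = cycle_length_weeks,
    n_cycles = as.integer(n_cycles),
    discount_rate_annual = discount_rate_annual,
    n_sims = as.integer(n_sims), seed = as.integer(seed), wtp = wtp,
    horizon_years = n_cycles * cycle_length_weeks / WEEKS_PER_YEAR
  ), class = "econ_settings")
}

#' Health-state utility specification
#'
#' Utilities for the stable-disease (SD) and progressive-disease (PD) states,
#' sampled in the probabilistic analysis from beta distributions whose
#' relative range is interpreted as +/- 2 standard deviations: SD of the
#' sampled utility = `u * relative_range / 2`.
#'
#' @param u_sd,u_pd Mean utilities in (0, 1\].
#' @param relative_range Relative sampling range (default 0.20, i.e. +/-20%).
#' @return An object of class `utility_spec`.
#' @export
utility_spec <- function(u_sd, u_pd, relative_range = 0.20) {
  stopifnot(u_sd > 0, u_sd <= 1, u_pd > 0, u_pd <= 1, relative_range >= 0)
  if (u_pd > u_sd) {
    warning("u_pd exceeds u_sd; progressed disease is usually valued lower",
            call. = FALSE)
  }
  structure(list(u_sd = u_sd, u_pd = u_pd, relative_range = relative_range),
            class = "utility_spec")
}

#' Build the partitioned-survival trace for one arm
#'
#' At each cycle boundary `t_c = c * cycle_length` the cohort is partitioned
#' by the two fitted survival functions: stable disease `p_sd = S_PFS(t_c)`,
#' progressed `p_pd = S_OS(t_c) - S_PFS(t_c)` (clamped at 0 when the
#' extrapolated curves cross), dead `1 - S_OS(t_c)`. Per-cycle occupancy is
#' the mean of the two boundary values (half-cycle correction).
#'
#' @param fit_pfs,fit_os `parametric_fit` objects for the arm's PFS and OS,
#'   sharing a time unit.
#' @param settings An [econ_settings()].
#' @return An object of class `psm_trace`: list with boundary vectors
#'   (`time_years`, `p_sd`, `p_pd`, `p_death`, length `n_cycles + 1`),
#'   per-cycle occupancy matrices (`occ_sd`, `occ_pd`, `occ_death`, length
#'   `n_cycles`), and `n_crossings` (boundaries where S_PFS > S_OS was
#'   clamped).
#' @export
build_trace <- function(fit_pfs, fit_os, settings) {
  stopifnot(inherits(fit_pfs, "parametric_fit"), inherits(fit_os, "parametric_fit"),
            inherits(settings, "econ_settings"))
  if (!identical(fit_pfs$time_unit, fit_os$time_unit)) {
    stop("PFS and OS fits must share a time unit", call. = FALSE)
  }
  cyc_years <- settings$cycle_length_weeks / WEEKS_PER_YEAR
  t_years <- (0:settings$n_cycles) * cyc_years
  t_fit <- convert_time_unit(t_years, "years", fit_pfs$time_unit)
  s_pfs <- survival_at(fit_pfs, t_fit)
  s_os <- survival_at(fit_os, t_fit)
  if (any(s_pfs < 0) || any(s_os < 0)) stop("negative survival from fit", call. = FALSE)
  crossing <- s_pfs > s_os + 1e-12
  p_sd <- ifelse(crossing, s_os, s_pfs)
  p_pd <- pmax(0, s_os - s_pfs)
  p_death <- 1 - s_os
  if (any(crossing)) {
    warning(sprintf("extrapolated S_PFS exceeded S_OS at %d boundaries; PD clamped to 0",
                    sum(crossing)), call. = FALSE)
  }
  nb <- length(t_years)
  occ <- function(x) (x[-nb] + x[-1L]) / 2  # trapezoidal half-cycle correction
  structure(list(
    arm_id = fit_pfs$arm_id,
    time_years = t_years, cycle_years = cyc_years,
    p_sd = p_sd, p_pd = p_pd, p_death = p_death,
    occ_sd = occ(p_sd), occ_pd = occ(p_pd), occ_death = occ(p_death),
    n_crossings = sum(crossing)
  ), class = "psm_trace")
}

#' Per-cycle transition probabilities from a PSM trace
#'
#' Derives the three transitions named in a three-state PSM: progression
#' before death (`p_sd.pd`), death from stable disease (`p_sd.d`) and death
#' after progression (`p_pd.d`). Two survival curves alone do not identify
#' how deaths split between states, so the default convention applies the
#' same per-cycle death probability in both alive states:
#' `p_sd.d = p_pd.d = 1 - S_OS(t+D)/S_OS(t)` and
#' `p_sd.pd = max(0, p_exit_sd - p_death)` with
#' `p_exit_sd = 1 - S_PFS(t+D)/S_PFS(t)`. The alternative `"pd_first"`
#' convention attributes deaths to PD while any PD occupancy remains.
#' Once a curve reaches 0 the corresponding exit probability is fixed at 1
#' (absorbing).
#'
#' @param trace A [build_trace()] result.
#' @param mode `"equal_hazard"` (default) or `"pd_first"`.
#' @return Data frame with columns `cycle`, `p_sd.pd`, `p_sd.d`, `p_pd.d`,
#'   all in \[0, 1\].
#' @export
transition_probabilities <- function(trace, mode = c("equal_hazard", "pd_first")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "psm_trace"))
  nb <- length(trace$time_years)
  # p_sd is S_PFS except at clamped crossings; the ratio convention uses the
  # clamped value so the three transitions stay mutually consistent
  s_pfs <- trace$p_sd
  s_os <- 1 - trace$p_death
  ratio <- function(s) {
    r <- ifelse(s[-nb] > 0, s[-1L] / pmax(s[-nb], 1e-300), 0)
    pmin(pmax(r, 0), 1)
  }
  p_exit_sd <- 1 - ratio(s_pfs)
  p_death_any <- 1 - ratio(s_os)
  p_exit_sd[s_pfs[-nb] <= 0] <- 1
  p_death_any[s_os[-nb] <= 0] <- 1
  if (mode == "equal_hazard") {
    p_sd_d <- p_death_any
    p_pd_d <- p_death_any
    p_sd_pd <- pmax(0, p_exit_sd - p_death_any)
  } else {
    # deaths drawn from PD occupancy first
    deaths <- trace$p_death[-1L] - trace$p_death[-nb]
    pd_occ <- trace$p_pd[-nb]
    from_pd <- pmin(deaths, pd_occ)
    p_pd_d <- ifelse(pd_occ > 0, from_pd / pd_occ, 1)
    p_sd_d <- ifelse(s_pfs[-nb] > 0, (deaths - from_pd) / s_pfs[-nb], 1)
    p_sd_pd <- pmax(0, p_exit_sd - p_sd_d)
  }
  clamp <- function(x) pmin(pmax(x, 0), 1)
  data.frame(cycle = seq_len(nb - 1L),
             p_sd.pd = clamp(p_sd_pd), p_sd.d = clamp(p_sd_d),
             p_pd.d = clamp(p_pd_d))
}

#' Sample health-state utilities for the probabilistic analysis
#'
#' Each utility with mean `u` is drawn from a beta distribution matched by
#' the method of moments to mean `u` and standard deviation
#' `u * relative_range / 2`. With `relative_range = 0` the draws are
#' degenerate at `u`. Draws are clipped to (0, 1\].
#'
#' @param spec A [utility_spec()].
#' @param n_sims Number of draws.
#' @param seed Optional seed (set only when non-NULL, so callers managing a
#'   common random-number stream can pass NULL).
#' @return List with numeric vectors `u_sd`, `u_pd` of length `n_sims`.
#' @export
sample_utilities <- function(spec, n_sims, seed = NULL) {
  stopifnot(inherits(spec, "utility_spec"))
  if (!is.null(seed)) set.seed(seed)
  draw <- function(u) {
    if (spec$relative_range == 0) return(rep(u, n_sims))
    sdev <- u * spec$relative_range / 2
    v <- sdev^2
    if (v >= u * (1 - u)) {
      stop(sprintf(
        "beta moment matching infeasible for mean %.3f, sd %.3f: need sd^2 < u(1-u); reduce relative_range",
        u, sdev), call. = FALSE)
    }
    nu <- u * (1 - u) / v - 1
    x <- stats::rbeta(n_sims, u * nu, (1 - u) * nu)
    pmin(pmax(x, 1e-12), 1)
  }
  list(u_sd = draw(spec$u_sd), u_pd = draw(spec$u_pd))
}

#' Discounted quality-adjusted life years from a PSM trace
#'
#' QALY per simulation `s` is
#' \eqn{\sum_c [occ_{sd}(c) u_{sd,s} + occ_{pd}(c) u_{pd,s}] \Delta_{yr}
#' (1+r)^{-t_{mid}(c)}} with half-cycle-corrected occupancies, cycle length
#' \eqn{\Delta_{yr}} in years and discounting at the cycle midpoint.
#'
#' @param trace A [build_trace()] result.
#' @param utilities List with vectors `u_sd`, `u_pd` (see
#'   [sample_utilities()]).
#' @param settings An [econ_settings()].
#' @return Numeric vector of total discounted QALYs, one per simulation.
#' @export
qalys <- function(trace, utilities, settings) {
  stopifnot(inherits(trace, "psm_trace"), inherits(settings, "econ_settings"))
  disc <- discount_factors(settings)
  dy <- trace$cycle_years
  a_sd <- sum(trace$occ_sd * dy * disc)
  a_pd <- sum(trace$occ_pd * dy * disc)
  utilities$u_sd * a_sd + utilities$u_pd * a_pd
}

#' Midpoint discount factors per cycle
#'
#' `(1 + r)^(-t_mid)` with `t_mid` the cycle midpoint in years and `r` the
#' annual discount rate.
#'
#' @param settings An [econ_settings()].
#' @return Numeric vector of length `n_cycles`.
#' @export
discount_factors <- function(settings) {
  dy <- settings$cycle_length_weeks / WEEKS_PER_YEAR
  t_mid <- (seq_len(settings$n_cycles) - 0.5) * dy
  (1 + settings$discount_rate_annual)^(-t_mid)
}

#' Export a PSM trace as a per-cycle data frame
#'
#' @param trace A [build_trace()] result.
#' @return Data frame with boundary probabilities and per-cycle occupancies.
#' @export
trace_table <- function(trace) {
  n <- length(trace$occ_sd)
  data.frame(
    arm = trace$arm_id, cycle = seq_len(n),
    p_sd = trace$p_sd[-1L], p_pd = trace$p_pd[-1L],
    p_death = trace$p_death[-1L],
    occ_sd = trace$occ_sd, occ_pd = trace$occ_pd, occ_death = trace$occ_death)
}
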