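# Fully synthetic two-arm oncology trials: true IPD from known survival
# laws, digitizer-style curve exports with consistent risk tables, and
# treatment-schedule-shaped cost tables, so every pipeline stage can be
# exercised against a known ground truth.

#' Define a synthetic two-arm trial scenario
#'
#' The default scenario mirrors the shape of a contemporary first-line
#' advanced-NSCLC immunotherapy trial: a 2:1 experimental/control allocation
#' (300/150), 3-week treatment cycles over a ~10-year horizon, first-line
#' induction followed by cheaper maintenance for at most 2 years of
#' treatment, no post-progression drug cost, and periodic imaging (6-weekly
#' through month 12, 9-weekly thereafter) on top of constant per-cycle lab
#' and supportive-care costs. Overall survival is constructed per subject as
#' progression time plus a post-progression survival draw, so S_PFS <= S_OS
#' by construction.
#'
#' @param n_experimental,n_control Subjects per arm.
#' @param pfs_experimental,pfs_control True progression-time law: list with
#'   `family` and `params` as in [survival_at()] (times in years).
#' @param post_experimental,post_control True post-progression survival law.
#' @param censor_years Range (min, max) of uniform administrative censoring
#'   times in years, applied to both endpoints per subject.
#' @param n_clicks Digitization grid density per curve.
#' @param risk_interval_years Risk-table reporting interval in years.
#' @param jitter_sd Additive digitization noise SD (survival units).
#' @param cycle_length_weeks,n_cycles Economic cycle structure.
#' @param first_line_cycles Number of induction cycles.
#' @param cost_first_line,cost_maintenance Per-cycle SD drug cost by phase,
#'   named vectors with elements `experimental` and `control`.
#' @param max_treatment_cycles Last cycle with any drug cost.
#' @param cost_imaging,cost_lab,cost_supportive Per-event imaging cost and
#'   per-cycle lab/supportive costs (state-independent).
#' @param u_sd,u_pd,utility_range Utility specification.
#' @param discount_rate_annual,n_sims,wtp Economic settings.
#' @param seed Base seed for all draws in the scenario.
#' @return An object of class `trial_scenario` (a list of the above).
#' @export
trial_scenario <- function(
    n_experimental = 300L, n_control = 150L,
    pfs_experimental = list(family = "exponential", params = c(rate = log(2) / 0.9)),
    pfs_control = list(family = "exponential", params = c(rate = log(2) / 0.5)),
    post_experimental = list(family = "exponential", params = c(rate = log(2) / 1.1)),
    post_control = list(family = "exponential", params = c(rate = log(2) / 1.0)),
    censor_years = c(2.5, 3.5),
    n_clicks = 60L, risk_interval_years = 0.5, jitter_sd = 0,
    cycle_length_weeks = 3, n_cycles = 170L,
    first_line_cycles = 4L,
    cost_first_line = c(experimental = 4900, control = 3000),
    cost_maintenance = c(experimental = 3400, control = 1500),
    max_treatment_cycles = 35L,
    cost_imaging = 600, cost_lab = 200, cost_supportive = 150,
    u_sd = 0.80, u_pd = 0.65, utility_range = 0.20,
    discount_rate_annual = 0.05, n_sims = 1000L, wtp = 268200,
    seed = 1L) {
  stopifnot(n_experimental >= 2, n_control >= 2, n_clicks >= 10,
            first_line_cycles >= 1, max_treatment_cycles <= n_cycles,
            censor_years[1L] <= censor_years[2L])
  structure(as.list(environment()), class = "trial_scenario")
}

# draw event times from one of the package's parametric families
.rsurv <- function(law, n) {
  p <- as.list(law$params)
  switch(law$family,
    exponential = stats::rexp(n, rate = p$rate),
    weibull = stats::rweibull(n, shape = p$shape, scale = p$scale),
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
    loglogistic = {
      u <- stats::runif(n)
      p$scale * (u / (1 - u))^(1 / p$shape)  # inverse CDF
    },
    gompertz = {
      a <- p$shape; b <- p$rate
      u <- stats::runif(n)
      if (abs(a) < 1e-12) -log(u) / b
      else {
        z <- 1 - a * log(u) / b
        ifelse(z > 0, log(z) / a, Inf)  # plateau mass never fails
      }
    },
    stop(sprintf("no sampler for family '%s'", law$family), call. = FALSE)
  )
}

#' Generate true individual patient data for a scenario
#'
#' Per subject, a progression time and an independent post-progression
#' survival time are drawn from the arm's laws; overall survival time is
#' their sum, so the OS time dominates the PFS time for every subject. A
#' uniform administrative censoring time is applied to both endpoints.
#'
#' @param scenario A [trial_scenario()].
#' @param seed Seed (defaults to the scenario's).
#' @return List with [ipd_dataset()] elements `pfs` and `os` (times in
#'   years, arms `experimental` and `control`) and the per-subject truth in
#'   `truth`.
#' @export
generate_true_ipd <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "trial_scenario"))
  set.seed(seed)
  one_arm <- function(n, pfs_law, post_law, arm) {
    t_prog <- .rsurv(pfs_law, n)
    t_post <- .rsurv(post_law, n)
    t_os <- t_prog + t_post
    cens <- stats::runif(n, scenario$censor_years[1L], scenario$censor_years[2L])
    data.frame(
      arm = arm,
      pfs_time = pmin(t_prog, cens), pfs_event = as.integer(t_prog <= cens),
      os_time = pmin(t_os, cens), os_event = as.integer(t_os <= cens)
    )
  }
  d <- rbind(
    one_arm(scenario$n_experimental, scenario$pfs_experimental,
            scenario$post_experimental, "experimental"),
    one_arm(scenario$n_control, scenario$pfs_control,
            scenario$post_control, "control")
  )
  list(
    pfs = ipd_dataset(d$pfs_time, d$pfs_event, d$arm, endpoint = "PFS",
                      time_unit = "years"),
    os = ipd_dataset(d$os_time, d$os_event, d$arm, endpoint = "OS",
                     time_unit = "years"),
    truth = d
  )
}

#' Digitize a KM curve the way a plot digitizer would
#'
#' Computes the exact Kaplan-Meier step function of one arm, samples it on a
#' uniform time grid (optionally with additive Gaussian jitter), and builds
#' the matching number-at-risk table from the true at-risk counts.
#'
#' @param ipd An [ipd_dataset()].
#' @param arm Arm to digitize.
#' @param n_clicks Number of grid points (>= 10), spanning \[0, max time\].
#' @param risk_interval Risk-table interval in the IPD's time unit.
#' @param jitter_sd SD of additive noise on the clicked survival values
#'   (default 0 = exact clicks).
#' @param seed Optional seed for the jitter.
#' @return List with `curve` (a [digitized_curve()]) and `risk`
#'   (a [risk_table()]).
#' @export
digitize_km <- function(ipd, arm, n_clicks = 60L, risk_interval,
                        jitter_sd = 0, seed = NULL) {
  stopifnot(inherits(ipd, "ipd"), n_clicks >= 10L)
  if (!is.null(seed)) set.seed(seed)
  d <- ipd[ipd$arm == arm, , drop = FALSE]
  km <- km_estimate(ipd, arm = arm)
  t_max <- max(d$time)
  grid <- seq(0, t_max, length.out = n_clicks)
  s <- km_survival_at(km, grid)
  if (jitter_sd > 0) s <- s + stats::rnorm(n_clicks, 0, jitter_sd)
  # a real digitizer's jitter never turns the trace non-monotone by much;
  # widen the repair tolerance with the injected noise level
  tol <- max(0.005, 6 * jitter_sd)
  curve <- digitized_curve(grid, s, arm_id = arm,
                           endpoint = attr(ipd, "endpoint"),
                           time_unit = attr(ipd, "time_unit"), tol = tol)
  r_times <- seq(0, t_max, by = risk_interval)
  n_risk <- vapply(r_times, function(t) sum(d$time >= t), numeric(1))
  keep <- n_risk > 0
  list(curve = curve, risk = risk_table(r_times[keep], n_risk[keep]))
}

#' Generate the scenario's cycle-indexed cost tables
#'
#' Stable-disease drug cost is the first-line cost for cycles
#' `1..first_line_cycles`, the maintenance cost through
#' `max_treatment_cycles`, then 0; post-progression drug cost is 0
#' throughout. State-independent cost is a constant lab + supportive-care
#' cost per cycle plus the imaging cost at scan cycles: scans at baseline and
#' every 6 weeks through month 12, every 9 weeks thereafter, each charged to
#' the cycle containing the scan week.
#'
#' @param scenario A [trial_scenario()].
#' @return A [cost_table()] with arms `experimental` and `control`.
#' @export
generate_cost_tables <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  nc <- scenario$n_cycles
  w <- scenario$cycle_length_weeks
  if (scenario$max_treatment_cycles > nc) {
    stop("treatment schedule longer than the cycle horizon", call. = FALSE)
  }
  sd_series <- function(arm) {
    v <- numeric(nc)
    k <- scenario$first_line_cycles
    v[seq_len(min(k, nc))] <- scenario$cost_first_line[[arm]]
    if (scenario$max_treatment_cycles > k) {
      v[(k + 1L):scenario$max_treatment_cycles] <- scenario$cost_maintenance[[arm]]
    }
    v
  }
  imaging_cycles <- scan_cycles(w, nc)
  indep <- rep(scenario$cost_lab + scenario$cost_supportive, nc)
  indep[imaging_cycles] <- indep[imaging_cycles] + scenario$cost_imaging
  arms <- c("experimental", "control")
  cost_table(
    sd_cost = stats::setNames(lapply(arms, function(a) {
      list(SD = sd_series(a), PD = numeric(nc))
    }), arms),
    indep_cost = stats::setNames(lapply(arms, function(a) indep), arms)
  )
}

#' Imaging-scan cycles for a 6-weekly-then-9-weekly schedule
#'
#' Scans occur at week 0 (baseline), then every 6 weeks through month 12
#' (12/1 year in weeks), then every 9 weeks; a scan in week `t` is charged to
#' cycle `floor(t / cycle_length) + 1`.
#'
#' @param cycle_length_weeks Cycle length in weeks.
#' @param n_cycles Number of cycles.
#' @return Integer vector of cycle indices containing a scan.
#' @export
scan_cycles <- function(cycle_length_weeks, n_cycles) {
  year1 <- WEEKS_PER_YEAR  # 12 months
  horizon <- n_cycles * cycle_length_weeks
  weeks <- seq(0, year1, by = 6)
  wk <- max(weeks)
  while (wk + 9 <= horizon) {
    wk <- wk + 9
    weeks <- c(weeks, wk)
  }
  cyc <- floor(weeks / cycle_length_weeks) + 1L
  sort(unique(cyc[cyc <= n_cycles]))
}

#' Write a complete synthetic input bundle to a directory
#'
#' Emits everything the pipeline needs: digitized curve and risk-table CSVs
#' for both arms and endpoints, the two cost CSVs, and a YAML run
#' configuration pointing at them. The bundle is a drop-in input for
#' [run_pipeline()].
#'
#' @param scenario A [trial_scenario()].
#' @param dir Output directory (created if needed).
#' @param seed Seed for data generation (defaults to the scenario's).
#' @return The path to the written config file, invisibly.
#' @export
write_demo_bundle <- function(scenario, dir, seed = scenario$seed) {
  stopifnot(inherits(scenario, "trial_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- generate_true_ipd(scenario, seed = seed)
  paths <- list()
  i <- 0L
  for (ep in c("pfs", "os")) {
    for (arm in c("experimental", "control")) {
      i <- i + 1L
      dig <- digitize_km(truth[[ep]], arm, n_clicks = scenario$n_clicks,
                         risk_interval = scenario$risk_interval_years,
                         jitter_sd = scenario$jitter_sd, seed = seed + 100L + i)
      cpath <- file.path(dir, sprintf("curve_%s_%s.csv", ep, arm))
      rpath <- file.path(dir, sprintf("risk_%s_%s.csv", ep, arm))
      utils::write.csv(data.frame(time = dig$curve$time,
                                  survival = dig$curve$surv),
                       cpath, row.names = FALSE, quote = FALSE)
      utils::write.csv(data.frame(time = dig$risk$time,
                                  n_risk = dig$risk$n_risk),
                       rpath, row.names = FALSE, quote = FALSE)
      paths[[sprintf("%s_%s", ep, arm)]] <- list(curve = cpath, risk = rpath)
    }
  }
  ct <- generate_cost_tables(scenario)
  sd_rows <- do.call(rbind, lapply(ct$arms, function(a) {
    do.call(rbind, lapply(c("SD", "PD"), function(st) {
      data.frame(cycle = seq_len(ct$n_cycles), arm = a, state = st,
                 cost = ct$sd_cost[[a]][[st]])
    }))
  }))
  imaging <- numeric(ct$n_cycles)
  imaging[scan_cycles(scenario$cycle_length_weeks, ct$n_cycles)] <- scenario$cost_imaging
  si_rows <- do.call(rbind, lapply(ct$arms, function(a) {
    data.frame(cycle = seq_len(ct$n_cycles), arm = a, imaging = imaging,
               lab = rep(scenario$cost_lab, ct$n_cycles),
               supportive = rep(scenario$cost_supportive, ct$n_cycles))
  }))
  sd_path <- file.path(dir, "costs_state_dependent.csv")
  si_path <- file.path(dir, "costs_state_independent.csv")
  utils::write.csv(sd_rows, sd_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(si_rows, si_path, row.names = FALSE, quote = FALSE)

  config <- list(
    time_unit = "years",
    arms = list(
      experimental = list(
        pfs_curve = basename(paths$pfs_experimental$curve),
        pfs_risk = basename(paths$pfs_experimental$risk),
        os_curve = basename(paths$os_experimental$curve),
        os_risk = basename(paths$os_experimental$risk)),
      control = list(
        pfs_curve = basename(paths$pfs_control$curve),
        pfs_risk = basename(paths$pfs_control$risk),
        os_curve = basename(paths$os_control$curve),
        os_risk = basename(paths$os_control$risk))),
    costs = list(state_dependent = basename(sd_path),
                 state_independent = basename(si_path),
                 cv = 0.20),
    utilities = list(sd = scenario$u_sd, pd = scenario$u_pd,
                     relative_range = scenario$utility_range),
    economics = list(cycle_length_weeks = scenario$cycle_length_weeks,
                     discount_rate_annual = scenario$discount_rate_annual,
                     n_sims = scenario$n_sims, seed = scenario$seed,
                     wtp = scenario$wtp)
  )
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}
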