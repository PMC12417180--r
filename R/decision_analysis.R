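# Monte-Carlo probabilistic sensitivity analysis and decision metrics:
# ICER with dominance flags, net monetary benefit, cost-effectiveness
# acceptability curves and the expected value of perfect information.

#' Run the probabilistic sensitivity analysis
#'
#' Orchestrates the full economic evaluation for two arms: builds the PSM
#' trace of each arm from its selected PFS and OS fits, samples utilities
#' (beta) and the cost cube (gamma) under one seeded random-number stream
#' (utilities first — SD then PD — followed by the cost cube arm by arm in
#' the order experimental, control), then accumulates discounted QALYs and
#' state-weighted costs per simulation. Survival parameters are treated as
#' fixed at their maximum-likelihood estimates; only utilities and costs are
#' sampled.
#'
#' @param fits Named list with elements `experimental` and `control`, each a
#'   list with `parametric_fit` elements `pfs` and `os`.
#' @param costs A [cost_table()] whose arms match `names(fits)`.
#' @param utility A [utility_spec()].
#' @param settings An [econ_settings()]; `n_cycles` must equal the cost
#'   table's cycle count.
#' @param cost_cv Coefficient of variation for gamma cost sampling
#'   (default 0.20).
#' @param indep_weighting Passed to [state_weighted_cost()].
#' @return An object of class `psa_result`: list with `sims` (data frame of
#'   per-simulation cost and QALY per arm plus increments), `traces`,
#'   `settings`, `wtp`, and a `summary` list (ICER and dominance flag, mean
#'   increments with 95% percentile intervals, probability cost-effective at
#'   the reference WTP).
#' @export
run_psa <- function(fits, costs, utility, settings, cost_cv = 0.20,
                    indep_weighting = "alive") {
  stopifnot(inherits(costs, "cost_table"), inherits(utility, "utility_spec"),
            inherits(settings, "econ_settings"))
  arms <- c("experimental", "control")
  if (!setequal(names(fits), arms)) {
    stop("fits must be named 'experimental' and 'control'", call. = FALSE)
  }
  if (!setequal(costs$arms, arms)) {
    stop("cost table arms must be 'experimental' and 'control'", call. = FALSE)
  }
  if (costs$n_cycles != settings$n_cycles) {
    stop(sprintf("settings specify %d cycles but the cost table has %d",
                 settings$n_cycles, costs$n_cycles), call. = FALSE)
  }
  for (a in arms) {
    if (!inherits(fits[[a]]$pfs, "parametric_fit") ||
        !inherits(fits[[a]]$os, "parametric_fit")) {
      stop(sprintf("arm '%s': fits must provide parametric_fit elements 'pfs' and 'os'", a),
           call. = FALSE)
    }
  }

  traces <- lapply(fits, function(f) build_trace(f$pfs, f$os, settings))

  # one documented stream: utilities, then costs (experimental, control)
  set.seed(settings$seed)
  u <- sample_utilities(utility, settings$n_sims, seed = NULL)
  cube <- sample_cost_cube(costs, cv = cost_cv, n_sims = settings$n_sims,
                           seed = NULL)

  qaly <- lapply(traces, qalys, utilities = u, settings = settings)
  cost <- lapply(arms, function(a) {
    state_weighted_cost(cube, traces[[a]], settings, arm = a,
                        indep_weighting = indep_weighting)
  })
  names(cost) <- arms

  sims <- data.frame(
    sim = seq_len(settings$n_sims),
    cost_experimental = cost$experimental$total,
    cost_control = cost$control$total,
    qaly_experimental = qaly$experimental,
    qaly_control = qaly$control
  )
  sims$dcost <- sims$cost_experimental - sims$cost_control
  sims$dqaly <- sims$qaly_experimental - sims$qaly_control
  sims$inmb <- settings$wtp * sims$dqaly - sims$dcost

  res <- structure(list(
    sims = sims, traces = traces, settings = settings, wtp = settings$wtp,
    utility = utility, cost_cv = cost_cv,
    per_cycle_cost = lapply(cost, `[[`, "per_cycle")
  ), class = "psa_result")
  res$summary <- summarize_psa(res)
  res
}

# central summary used by print/report
summarize_psa <- function(result) {
  s <- result$sims
  ci <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  ic <- icer(result)
  list(
    icer = ic$icer, dominance = ic$flag,
    dcost_mean = mean(s$dcost), dcost_ci95 = ci(s$dcost),
    dqaly_mean = mean(s$dqaly), dqaly_ci95 = ci(s$dqaly),
    prob_ce_at_wtp = mean(s$inmb > 0) + 0.5 * mean(s$inmb == 0),
    wtp = result$wtp, n_sims = nrow(s)
  )
}

#' Incremental cost-effectiveness ratio with dominance flags
#'
#' The ICER is the ratio of mean increments, `mean(dcost) / mean(dqaly)`
#' (not the mean of per-simulation ratios, which is unstable near zero QALY
#' gain). Flags: `"dominant"` when the experimental arm is cheaper and more
#' effective, `"dominated"` when costlier and less effective, `"undefined"`
#' when the mean QALY gain is below `tol` in magnitude, otherwise `"icer"`.
#'
#' @param result A [run_psa()] result (or any list with a `sims` data frame
#'   containing `dcost`, `dqaly`).
#' @param tol Magnitude of mean QALY gain below which the ratio is flagged
#'   undefined. Default 1e-9.
#' @return List with `icer` (NA unless flag is `"icer"` or the ratio is
#'   meaningful) and `flag`.
#' @export
icer <- function(result, tol = 1e-9) {
  dc <- mean(result$sims$dcost)
  dq <- mean(result$sims$dqaly)
  if (abs(dq) < tol) return(list(icer = NA_real_, flag = "undefined"))
  flag <- if (dc < 0 && dq > 0) "dominant"
          else if (dc > 0 && dq < 0) "dominated"
          else "icer"
  list(icer = dc / dq, flag = flag)
}

#' Net monetary benefit at a willingness-to-pay threshold
#'
#' `NMB = wtp * QALY - cost` per arm and simulation;
#' `iNMB = wtp * dQALY - dcost`.
#'
#' @param result A [run_psa()] result.
#' @param wtp Willingness-to-pay per QALY (>= 0).
#' @return Data frame with per-simulation `nmb_experimental`, `nmb_control`,
#'   `inmb`.
#' @export
nmb <- function(result, wtp) {
  stopifnot(wtp >= 0)
  s <- result$sims
  data.frame(
    sim = s$sim,
    nmb_experimental = wtp * s$qaly_experimental - s$cost_experimental,
    nmb_control = wtp * s$qaly_control - s$cost_control,
    inmb = wtp * s$dqaly - s$dcost
  )
}

#' Default willingness-to-pay grid
#'
#' 101 evenly spaced points from 0 to twice the reference threshold.
#'
#' @param wtp Reference willingness-to-pay.
#' @return Numeric vector of length 101.
#' @export
wtp_grid <- function(wtp) seq(0, 2 * wtp, length.out = 101L)

#' Cost-effectiveness acceptability curves
#'
#' For each threshold, the probability (fraction of simulations) that each
#' arm has the higher net monetary benefit; ties are split evenly, so the two
#' curves sum to 1.
#'
#' @param result A [run_psa()] result.
#' @param wtp_values Non-empty numeric vector of thresholds (>= 0).
#' @return Data frame with columns `wtp`, `p_experimental`, `p_control`.
#' @export
ceac <- function(result, wtp_values = wtp_grid(result$wtp)) {
  stopifnot(length(wtp_values) >= 1L, all(wtp_values >= 0))
  s <- result$sims
  p_exp <- vapply(wtp_values, function(w) {
    inmb <- w * s$dqaly - s$dcost
    mean(inmb > 0) + 0.5 * mean(inmb == 0)
  }, numeric(1))
  data.frame(wtp = wtp_values, p_experimental = p_exp,
             p_control = 1 - p_exp)
}

#' Expected value of perfect information
#'
#' `EVPI(wtp) = E[max over arms of NMB] - max over arms of E[NMB]`: the
#' expected gain, per decision, of resolving all parameter uncertainty before
#' choosing an arm. Non-negative at every threshold.
#'
#' @inheritParams ceac
#' @return Data frame with columns `wtp`, `evpi`.
#' @export
evpi <- function(result, wtp_values = wtp_grid(result$wtp)) {
  stopifnot(length(wtp_values) >= 1L, all(wtp_values >= 0))
  s <- result$sims
  ev <- vapply(wtp_values, function(w) {
    nmb_e <- w * s$qaly_experimental - s$cost_experimental
    nmb_c <- w * s$qaly_control - s$cost_control
    mean(pmax(nmb_e, nmb_c)) - max(mean(nmb_e), mean(nmb_c))
  }, numeric(1))
  data.frame(wtp = wtp_values, evpi = pmax(ev, 0))
}

#' @export
print.psa_result <- function(x, ...) {
  sm <- x$summary
  cat(sprintf("PSA over %d simulations (WTP = %s/QALY)\n", sm$n_sims,
              format(sm$wtp, big.mark = ",")))
  cat(sprintf("  incremental cost: %.2f (95%% CI %.2f to %.2f)\n",
              sm$dcost_mean, sm$dcost_ci95[1L], sm$dcost_ci95[2L]))
  cat(sprintf("  incremental QALY: %.4f (95%% CI %.4f to %.4f)\n",
              sm$dqaly_mean, sm$dqaly_ci95[1L], sm$dqaly_ci95[2L]))
  if (sm$dominance == "icer") {
    cat(sprintf("  ICER: %.2f per QALY\n", sm$icer))
  } else {
    cat(sprintf("  ICER: %s\n", sm$dominance))
  }
  cat(sprintf("  P(cost-effective at reference WTP): %.3f\n", sm$prob_ce_at_wtp))
  invisible(x)
}
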