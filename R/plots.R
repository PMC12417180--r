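# ggplot2 figures for each pipeline stage.

#' Reconstructed KM curve against the digitized input
#'
#' @param curve The [digitized_curve()].
#' @param ipd The reconstructed [ipd_dataset()] (single arm).
#' @param fit Optional `parametric_fit` to overlay as a smooth curve.
#' @return A ggplot object.
#' @export
plot_reconstruction <- function(curve, ipd, fit = NULL) {
  km <- km_estimate(ipd, arm = unique(ipd$arm)[1L])
  step_df <- data.frame(time = c(0, km$time), surv = c(1, km$surv))
  p <- ggplot2::ggplot() +
    ggplot2::geom_step(data = step_df,
                       ggplot2::aes(x = .data$time, y = .data$surv,
                                    colour = "reconstructed KM")) +
    ggplot2::geom_point(data = as.data.frame(curve),
                        ggplot2::aes(x = .data$time, y = .data$surv,
                                     colour = "digitized"),
                        size = 0.8, alpha = 0.7) +
    ggplot2::labs(x = sprintf("time (%s)", attr(curve, "time_unit")),
                  y = "survival probability",
                  colour = NULL,
                  title = sprintf("%s, arm %s", attr(curve, "endpoint"),
                                  attr(curve, "arm_id"))) +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
  if (!is.null(fit)) {
    tt <- seq(0, max(curve$time), length.out = 200L)
    p <- p + ggplot2::geom_line(
      data = data.frame(time = tt, surv = survival_at(fit, tt)),
      ggplot2::aes(x = .data$time, y = .data$surv, colour = "parametric fit"),
      linetype = 2)
  }
  p
}

#' AIC bar chart across fitted families
#'
#' @param report A [fit_report()] data frame (possibly several arms/endpoints).
#' @return A ggplot object.
#' @export
plot_aic <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(x = stats::reorder(.data$family, .data$aic),
                               y = .data$aic, fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~ arm + endpoint, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "AIC", fill = "selected") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' State probabilities per cycle (stacked)
#'
#' @param traces Named list of [build_trace()] results.
#' @return A ggplot object.
#' @export
plot_state_probabilities <- function(traces) {
  df <- do.call(rbind, lapply(traces, function(tr) {
    tab <- trace_table(tr)
    stats::reshape(tab[, c("arm", "cycle", "occ_sd", "occ_pd", "occ_death")],
                   direction = "long",
                   varying = c("occ_sd", "occ_pd", "occ_death"),
                   v.names = "probability", timevar = "state",
                   times = c("SD", "PD", "death"))
  }))
  df$state <- factor(df$state, levels = c("death", "PD", "SD"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle, y = .data$probability,
                                   fill = .data$state)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::facet_wrap(~ arm) +
    ggplot2::labs(x = "treatment cycle", y = "state probability") +
    ggplot2::theme_minimal()
}

#' State-weighted cost per treatment cycle
#'
#' @param cost_summaries Data frame from [cycle_cost_summary()] (rows for
#'   both arms).
#' @return A ggplot object.
#' @export
plot_cycle_costs <- function(cost_summaries) {
  ggplot2::ggplot(cost_summaries,
                  ggplot2::aes(x = .data$cycle, y = .data$mean,
                               colour = .data$arm, fill = .data$arm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q2.5, ymax = .data$q97.5),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "treatment cycle", y = "state-weighted cost per cycle") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane with WTP rays
#'
#' @param result A [run_psa()] result.
#' @param wtp_lines Thresholds to draw as rays through the origin.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(result, wtp_lines = result$wtp) {
  s <- result$sims
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$dqaly, y = .data$dcost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "incremental QALY", y = "incremental cost") +
    ggplot2::theme_minimal()
  for (w in wtp_lines) {
    p <- p + ggplot2::geom_abline(slope = w, intercept = 0,
                                  linetype = 2, colour = "grey40")
  }
  p
}

#' Cost-effectiveness acceptability curves
#'
#' @param ceac_df A [ceac()] data frame.
#' @param wtp_ref Optional reference threshold drawn as a vertical line.
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_df, wtp_ref = NULL) {
  p <- ggplot2::ggplot(ceac_df, ggplot2::aes(x = .data$wtp)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p_experimental,
                                    colour = "experimental")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p_control, colour = "control")) +
    ggplot2::labs(x = "willingness to pay per QALY",
                  y = "P(most cost-effective)", colour = NULL) +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
  if (!is.null(wtp_ref)) {
    p <- p + ggplot2::geom_vline(xintercept = wtp_ref, linetype = 2)
  }
  p
}

#' Expected value of perfect information curve
#'
#' @param evpi_df An [evpi()] data frame.
#' @return A ggplot object.
#' @export
plot_evpi <- function(evpi_df) {
  ggplot2::ggplot(evpi_df, ggplot2::aes(x = .data$wtp, y = .data$evpi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "willingness to pay per QALY",
                  y = "EVPI per decision") +
    ggplot2::theme_minimal()
}
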