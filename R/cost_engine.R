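# Treatment-cycle-indexed cost tables, gamma sampling of cost uncertainty
# into the (arm, state, cycle, simulation) cost structure, and discounted
# state-weighted cost accumulation.

#' Construct a cycle-indexed cost table
#'
#' Costs are split into state-dependent drug costs (per alive state, per
#' treatment cycle) and state-independent care costs (imaging, labs,
#' supportive care, summed per cycle). All arms share one cycle count, which
#' drives the model's lifetime horizon.
#'
#' @param sd_cost Named list (one element per arm) of lists with numeric
#'   vectors `SD` and `PD`, each of length `n_cycles`: drug cost per cycle in
#'   that state.
#' @param indep_cost Named list (same arms) of numeric vectors of length
#'   `n_cycles`: state-independent cost per cycle.
#' @return An object of class `cost_table` with fields `arms`, `n_cycles`,
#'   `sd_cost`, `indep_cost`.
#' @export
cost_table <- function(sd_cost, indep_cost) {
  arms <- names(sd_cost)
  if (is.null(arms) || !setequal(arms, names(indep_cost))) {
    stop("sd_cost and indep_cost must be named by the same arms", call. = FALSE)
  }
  lens <- unlist(lapply(arms, function(a) {
    c(length(sd_cost[[a]]$SD), length(sd_cost[[a]]$PD), length(indep_cost[[a]]))
  }))
  if (length(unique(lens)) != 1L) {
    stop("all cost series must share one cycle count", call. = FALSE)
  }
  vals <- c(unlist(lapply(sd_cost, unlist)), unlist(indep_cost))
  if (any(vals < 0)) stop("costs must be non-negative", call. = FALSE)
  structure(list(arms = arms, n_cycles = unique(lens),
                 sd_cost = sd_cost, indep_cost = indep_cost),
            class = "cost_table")
}

#' Read cycle-indexed cost tables from CSV
#'
#' The state-dependent file has columns `cycle,arm,state,cost` with
#' `state` in `{SD, PD}`; the state-independent file has columns
#' `cycle,arm,<category...>` whose category columns are summed into one
#' series per arm. Cycles must run 1..n contiguously for every arm; the row
#' count fixes `n_cycles` and hence the lifetime horizon.
#'
#' @param sd_path Path to the state-dependent cost CSV.
#' @param indep_path Path to the state-independent cost CSV.
#' @param arms Optional character vector restricting/validating the arm set.
#' @return A [cost_table()].
#' @export
read_cost_tables <- function(sd_path, indep_path, arms = NULL) {
  sd <- utils::read.csv(sd_path, header = TRUE)
  si <- utils::read.csv(indep_path, header = TRUE)
  need <- c("cycle", "arm", "state", "cost")
  if (!all(need %in% names(sd))) {
    stop("state-dependent cost CSV needs columns cycle,arm,state,cost", call. = FALSE)
  }
  if (!all(c("cycle", "arm") %in% names(si))) {
    stop("state-independent cost CSV needs columns cycle,arm,<categories>", call. = FALSE)
  }
  found <- sort(unique(c(sd$arm, si$arm)))
  if (is.null(arms)) arms <- found
  if (!setequal(found, arms)) {
    stop(sprintf("arm mismatch: expected {%s}, found {%s}",
                 paste(arms, collapse = ", "), paste(found, collapse = ", ")),
         call. = FALSE)
  }
  check_contiguous <- function(cyc, what) {
    cyc <- sort(unique(cyc))
    n <- max(cyc)
    missing <- setdiff(seq_len(n), cyc)
    if (length(missing)) {
      stop(sprintf("%s: missing cycle(s) %s", what,
                   paste(utils::head(missing, 5L), collapse = ", ")), call. = FALSE)
    }
    n
  }
  sd_cost <- list(); indep_cost <- list()
  n_all <- integer(0)
  cat_cols <- setdiff(names(si), c("cycle", "arm"))
  if (length(cat_cols) == 0L) stop("no cost category columns in state-independent CSV", call. = FALSE)
  for (a in arms) {
    sda <- sd[sd$arm == a, , drop = FALSE]
    sia <- si[si$arm == a, , drop = FALSE]
    per_state <- list()
    for (st in c("SD", "PD")) {
      rows <- sda[sda$state == st, , drop = FALSE]
      n <- check_contiguous(rows$cycle, sprintf("arm %s state %s", a, st))
      v <- numeric(n)
      v[rows$cycle] <- rows$cost
      per_state[[st]] <- v
    }
    n <- check_contiguous(sia$cycle, sprintf("arm %s state-independent", a))
    ind <- rowSums(as.matrix(sia[order(sia$cycle), cat_cols, drop = FALSE]))
    sd_cost[[a]] <- per_state
    indep_cost[[a]] <- as.numeric(ind)
    n_all <- c(n_all, length(per_state$SD), length(per_state$PD), n)
  }
  if (length(unique(n_all)) != 1L) {
    stop("cost tables disagree on the number of cycles across arms/files", call. = FALSE)
  }
  cost_table(sd_cost, indep_cost)
}

#' Sample the cost uncertainty cube
#'
#' Every positive cost cell with mean `mu` is drawn from a gamma distribution
#' with shape `1/cv^2` and scale `mu * cv^2` (mean `mu`, SD `mu * cv`);
#' zero-mean cells are exactly 0 in every simulation. `cv = 0` is the
#' degenerate deterministic path (all draws equal the mean).
#'
#' @param table A [cost_table()].
#' @param cv Coefficient of variation of each cost cell (default 0.20).
#' @param n_sims Number of simulations.
#' @param seed Optional seed (NULL to use the ambient RNG stream).
#' @return An object of class `cost_cube`: list per arm of matrices `SD`,
#'   `PD`, `indep` of dimension `n_cycles x n_sims`.
#' @export
sample_cost_cube <- function(table, cv = 0.20, n_sims, seed = NULL) {
  stopifnot(inherits(table, "cost_table"))
  if (cv < 0) stop("cv must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(mu) {
    out <- matrix(0, nrow = length(mu), ncol = n_sims)
    pos <- which(mu > 0)
    if (length(pos)) {
      if (cv == 0) {
        out[pos, ] <- mu[pos]
      } else {
        shape <- 1 / cv^2
        out[pos, ] <- stats::rgamma(length(pos) * n_sims, shape = shape,
                                    scale = rep(mu[pos], n_sims) * cv^2)
      }
    }
    out
  }
  cube <- lapply(table$arms, function(a) {
    list(SD = draw(table$sd_cost[[a]]$SD),
         PD = draw(table$sd_cost[[a]]$PD),
         indep = draw(table$indep_cost[[a]]))
  })
  names(cube) <- table$arms
  structure(list(arms = table$arms, n_cycles = table$n_cycles,
                 n_sims = n_sims, cv = cv, draws = cube),
            class = "cost_cube")
}

#' Discounted state-weighted cost per cycle and in total
#'
#' Cycle cost is `occ_sd * cost_SD + occ_pd * cost_PD +
#' (occ_sd + occ_pd) * cost_indep`, discounted at the cycle midpoint.
#' State-independent costs are charged to alive occupancy by default
#' (`indep_weighting = "alive"`); `"full"` charges them to the whole cohort.
#'
#' @param cube A [sample_cost_cube()] result.
#' @param trace The arm's [build_trace()] result.
#' @param settings An [econ_settings()].
#' @param arm Arm label within the cube; defaults to the trace's arm.
#' @param indep_weighting `"alive"` (default) or `"full"`.
#' @return List with `total` (numeric vector, one discounted total per
#'   simulation) and `per_cycle` (matrix `n_cycles x n_sims` of discounted
#'   cycle costs).
#' @export
state_weighted_cost <- function(cube, trace, settings, arm = NULL,
                                indep_weighting = c("alive", "full")) {
  indep_weighting <- match.arg(indep_weighting)
  stopifnot(inherits(cube, "cost_cube"), inherits(trace, "psm_trace"),
            inherits(settings, "econ_settings"))
  if (is.null(arm)) arm <- trace$arm_id
  if (!arm %in% cube$arms) stop(sprintf("arm '%s' not in cost cube", arm), call. = FALSE)
  if (cube$n_cycles != settings$n_cycles ||
      length(trace$occ_sd) != cube$n_cycles) {
    stop("cost cube, trace and settings disagree on the number of cycles",
         call. = FALSE)
  }
  d <- cube$draws[[arm]]
  disc <- discount_factors(settings)
  alive <- trace$occ_sd + trace$occ_pd
  w_ind <- if (indep_weighting == "alive") alive else rep(1, length(alive))
  per_cycle <- disc * (trace$occ_sd * d$SD + trace$occ_pd * d$PD + w_ind * d$indep)
  list(total = colSums(per_cycle), per_cycle = per_cycle)
}

#' Summarize per-cycle costs across simulations
#'
#' @param per_cycle Matrix of discounted cycle costs (`n_cycles x n_sims`).
#' @param arm Arm label for the output.
#' @return Data frame with columns `arm`, `cycle`, `mean`, `q2.5`, `q97.5`.
#' @export
cycle_cost_summary <- function(per_cycle, arm) {
  qs <- t(apply(per_cycle, 1L, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE))
  data.frame(arm = arm, cycle = seq_len(nrow(per_cycle)),
             mean = rowMeans(per_cycle), q2.5 = qs[, 1L], q97.5 = qs[, 2L])
}
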