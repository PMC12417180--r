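# Cycle-indexed cost tables, gamma sampling, state-weighted discounting.

write_cost_csvs <- function(dir, n_cycles = 10, arms = c("experimental", "control"),
                            sd_cost = 100, imaging = c(500, 0), lab = 200,
                            drop_cycle = NULL) {
  sd_rows <- do.call(rbind, lapply(arms, function(a) {
    do.call(rbind, lapply(c("SD", "PD"), function(st) {
      data.frame(cycle = 1:n_cycles, arm = a, state = st,
                 cost = if (st == "SD") sd_cost else 0)
    }))
  }))
  if (!is.null(drop_cycle)) sd_rows <- sd_rows[sd_rows$cycle != drop_cycle, ]
  si_rows <- do.call(rbind, lapply(arms, function(a) {
    data.frame(cycle = 1:n_cycles, arm = a,
               imaging = rep_len(imaging, n_cycles), lab = lab)
  }))
  sd_path <- file.path(dir, "sd.csv"); si_path <- file.path(dir, "si.csv")
  write.csv(sd_rows, sd_path, row.names = FALSE)
  write.csv(si_rows, si_path, row.names = FALSE)
  list(sd = sd_path, si = si_path)
}

test_that("cost CSVs are read, summed by category, and validated", {
  dir <- withr::local_tempdir()
  p <- write_cost_csvs(dir, n_cycles = 10)
  ct <- read_cost_tables(p$sd, p$si)
  expect_equal(ct$n_cycles, 10)
  expect_setequal(ct$arms, c("experimental", "control"))
  # indirect categories are summed per row: imaging 500 + lab 200
  expect_equal(ct$indep_cost$experimental[1], 700)
  expect_equal(ct$indep_cost$experimental[2], 200)
  expect_equal(ct$sd_cost$control$SD, rep(100, 10))
  expect_equal(ct$sd_cost$control$PD, rep(0, 10))

  # a 172-row 3-week table spans just under 10 years
  horizon <- econ_settings(cycle_length_weeks = 3, n_cycles = 172,
                           n_sims = 1, seed = 1, wtp = 1)$horizon_years
  expect_equal(horizon, 172 * 3 * 7 / 365.25, tolerance = 1e-12)
  expect_lt(abs(horizon - 9.89), 0.01)

  # a gap in the cycle index is a validation error naming the cycle
  p2 <- write_cost_csvs(dir, drop_cycle = 5)
  expect_error(read_cost_tables(p2$sd, p2$si), "5")

  # arm mismatch is caught
  expect_error(read_cost_tables(p$sd, p$si, arms = c("experimental", "placebo")),
               "arm mismatch")
})

test_that("gamma sampling is moment-matched and degenerates cleanly", {
  ct <- flat_cost_table(4, sd_exp = 100, pd = 0, indep = 50)
  # mu = 100, cv = 0.2 -> shape 25, scale 4 (moment algebra held by rgamma
  # parameterization); check the sampled moments
  cube <- sample_cost_cube(ct, cv = 0.2, n_sims = 25000, seed = 42)
  draws <- cube$draws$experimental$SD[1, ]
  expect_lt(abs(mean(draws) - 100) / 100, 0.01)
  expect_lt(abs(sd(draws) - 20) / 20, 0.05)
  # zero-mean cells stay exactly zero in every simulation
  expect_true(all(cube$draws$experimental$PD == 0))
  # cv = 0: every draw equals the mean
  cube0 <- sample_cost_cube(ct, cv = 0, n_sims = 5, seed = 1)
  expect_true(all(cube0$draws$experimental$SD == 100))
  expect_true(all(cube0$draws$control$indep == 50))
  expect_error(sample_cost_cube(ct, cv = -0.1, n_sims = 5), "non-negative")
})

test_that("state-weighted cost matches brute-force discounted sums", {
  st <- econ_settings(cycle_length_weeks = 365.25 / 7, n_cycles = 10,
                      discount_rate_annual = 0, n_sims = 1, seed = 1, wtp = 1)
  # everyone stays in SD: undiscounted total is the plain sum
  tr <- build_trace(make_fit("exponential", c(rate = 1e-12), arm = "experimental"),
                    make_fit("exponential", c(rate = 1e-12),
                             arm = "experimental", endpoint = "OS"), st)
  ct <- flat_cost_table(10, sd_exp = 100, pd = 0, indep = 0)
  cube <- sample_cost_cube(ct, cv = 0, n_sims = 1)
  swc <- state_weighted_cost(cube, tr, st)
  expect_equal(swc$total, 1000, tolerance = 1e-9)

  # everyone dead from the first boundary: occupancy-weighting zeroes costs
  trd <- list(arm_id = "experimental", time_years = (0:10), cycle_years = 1,
              p_sd = c(1, rep(0, 10)), p_pd = rep(0, 11),
              p_death = c(0, rep(1, 10)),
              occ_sd = c(0.5, rep(0, 9)), occ_pd = rep(0, 10),
              occ_death = c(0.5, rep(1, 9)), n_crossings = 0)
  class(trd) <- "psm_trace"
  ct2 <- flat_cost_table(10, sd_exp = 0, pd = 500, indep = 0)
  cube2 <- sample_cost_cube(ct2, cv = 0, n_sims = 1)
  expect_equal(state_weighted_cost(cube2, trd, st)$total, 0, tolerance = 1e-12)

  # 2 cycles of 0.5 yr at r = 0.05: midpoint-discounted closed sum
  st3 <- econ_settings(cycle_length_weeks = 365.25 / 7 / 2, n_cycles = 2,
                       discount_rate_annual = 0.05, n_sims = 1, seed = 1, wtp = 1)
  tr3 <- build_trace(make_fit("exponential", c(rate = 1e-12), arm = "experimental"),
                     make_fit("exponential", c(rate = 1e-12),
                              arm = "experimental", endpoint = "OS"), st3)
  ct3 <- flat_cost_table(2, sd_exp = 100, pd = 0, indep = 0)
  cube3 <- sample_cost_cube(ct3, cv = 0, n_sims = 1)
  expect_equal(state_weighted_cost(cube3, tr3, st3)$total,
               100 * 1.05^-0.25 + 100 * 1.05^-0.75, tolerance = 1e-9)
})

test_that("total cost is monotone in cost entries and reflects imaging periodicity", {
  st <- econ_settings(cycle_length_weeks = 3, n_cycles = 20,
                      discount_rate_annual = 0.05, n_sims = 1, seed = 1, wtp = 1)
  tr <- build_trace(make_fit("exponential", c(rate = 0.5), arm = "experimental"),
                    make_fit("exponential", c(rate = 0.25),
                             arm = "experimental", endpoint = "OS"), st)
  base <- flat_cost_table(20, sd_exp = 100, pd = 50, indep = 10)
  tot0 <- state_weighted_cost(sample_cost_cube(base, cv = 0, n_sims = 1), tr, st)$total
  for (bump in list(c("SD", 1), c("PD", 7), c("indep", 20))) {
    ct <- base
    if (bump[[1]] == "indep") {
      ct$indep_cost$experimental[as.integer(bump[2])] <- 999
    } else {
      ct$sd_cost$experimental[[bump[1]]][as.integer(bump[2])] <- 999
    }
    tot <- state_weighted_cost(sample_cost_cube(ct, cv = 0, n_sims = 1), tr, st)$total
    expect_gt(tot, tot0)
  }

  # periodic state-independent costs produce periodic cost spikes
  per <- flat_cost_table(20, sd_exp = 0, pd = 0, indep = 0)
  per$indep_cost$experimental[seq(2, 20, by = 2)] <- 600
  swc <- state_weighted_cost(sample_cost_cube(per, cv = 0, n_sims = 1), tr, st)
  cyc <- swc$per_cycle[, 1]
  expect_true(all(cyc[seq(2, 20, by = 2)] > 0))
  expect_true(all(cyc[seq(1, 19, by = 2)] == 0))

  # full-cohort weighting for state-independent costs is available and larger
  swc_full <- state_weighted_cost(sample_cost_cube(per, cv = 0, n_sims = 1),
                                  tr, st, indep_weighting = "full")
  expect_gt(sum(swc_full$total), sum(swc$total))
})
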