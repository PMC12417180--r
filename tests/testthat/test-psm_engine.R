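# Three-state partitioned survival model, transitions, utilities, QALYs.

yr_settings <- function(n_cycles, cycle_years = 1, r = 0, ...) {
  econ_settings(cycle_length_weeks = cycle_years * 365.25 / 7,
                n_cycles = n_cycles, discount_rate_annual = r,
                n_sims = 1L, seed = 1L, wtp = 1, ...)
}

test_that("trace partitions the cohort by the two survival curves", {
  st <- yr_settings(2)
  tr <- build_trace(make_fit("exponential", c(rate = 0.2)),
                    make_fit("exponential", c(rate = 0.1), endpoint = "OS"), st)
  # boundary condition at t = 0
  expect_equal(c(tr$p_sd[1], tr$p_pd[1], tr$p_death[1]), c(1, 0, 0))
  # direct evaluation at t = 1 yr
  expect_equal(tr$p_sd[2], exp(-0.2), tolerance = 1e-12)
  expect_equal(tr$p_pd[2], exp(-0.1) - exp(-0.2), tolerance = 1e-12)
  expect_equal(tr$p_death[2], 1 - exp(-0.1), tolerance = 1e-12)
  # occupancy conservation at every boundary and cycle
  expect_true(all(abs(tr$p_sd + tr$p_pd + tr$p_death - 1) < 1e-9))
  expect_true(all(abs(tr$occ_sd + tr$occ_pd + tr$occ_death - 1) < 1e-9))
  expect_true(all(diff(tr$p_death) >= -1e-12))

  # identical curves: no progressed state, ever
  tr2 <- build_trace(make_fit("exponential", c(rate = 0.2)),
                     make_fit("exponential", c(rate = 0.2), endpoint = "OS"),
                     yr_settings(10))
  expect_true(all(tr2$p_pd == 0))

  # crossing extrapolations are clamped and counted
  expect_warning(
    tr3 <- build_trace(make_fit("exponential", c(rate = 0.1)),
                       make_fit("exponential", c(rate = 0.2), endpoint = "OS"),
                       yr_settings(5)),
    "clamped")
  expect_gt(tr3$n_crossings, 0)
  expect_true(all(tr3$p_pd == 0))
  expect_true(all(abs(tr3$p_sd + tr3$p_pd + tr3$p_death - 1) < 1e-9))
})

test_that("transition probabilities follow the equal-mortality-hazard convention", {
  st <- yr_settings(3)
  tr <- build_trace(make_fit("exponential", c(rate = 0.2)),
                    make_fit("exponential", c(rate = 0.1), endpoint = "OS"), st)
  tp <- transition_probabilities(tr)
  # constant hazards: identical transitions every cycle, closed forms
  expect_equal(tp$p_sd.d, rep(1 - exp(-0.1), 3), tolerance = 1e-12)
  expect_equal(tp$p_pd.d, tp$p_sd.d)
  expect_equal(tp$p_sd.pd, rep(exp(-0.1) - exp(-0.2), 3), tolerance = 1e-12)

  # no progression when the curves coincide
  tr2 <- build_trace(make_fit("exponential", c(rate = 0.2)),
                     make_fit("exponential", c(rate = 0.2), endpoint = "OS"), st)
  expect_true(all(transition_probabilities(tr2)$p_sd.pd == 0))

  # absorbing once survival reaches zero (numerically)
  trh <- build_trace(make_fit("weibull", c(shape = 4, scale = 0.5)),
                     make_fit("weibull", c(shape = 4, scale = 0.6),
                              endpoint = "OS"), yr_settings(5))
  tph <- transition_probabilities(trh)
  expect_equal(tph$p_pd.d[5], 1)

  # the pd-first convention still yields probabilities in [0, 1]
  tpa <- transition_probabilities(tr, mode = "pd_first")
  expect_true(all(unlist(tpa[-1]) >= 0 & unlist(tpa[-1]) <= 1))
})

test_that("utility sampling is moment-matched beta with a degenerate limit", {
  # method-of-moments algebra: u = 0.5, range 0.2 -> alpha = beta = 49.5
  spec <- utility_spec(0.5, 0.5, relative_range = 0.2)
  v <- (0.5 * 0.2 / 2)^2
  nu <- 0.5 * 0.5 / v - 1
  expect_equal(0.5 * nu, 49.5)

  # stochastic moment check
  u <- sample_utilities(utility_spec(0.8, 0.6), n_sims = 1e5, seed = 123)
  expect_lt(abs(mean(u$u_sd) - 0.8) / 0.8, 0.005)
  expect_lt(abs(sd(u$u_sd) - 0.08) / 0.08, 0.05)
  expect_true(all(u$u_sd > 0 & u$u_sd <= 1))

  # zero range: degenerate draws
  u0 <- sample_utilities(utility_spec(0.7, 0.5, relative_range = 0),
                         n_sims = 10, seed = 1)
  expect_true(all(u0$u_sd == 0.7) && all(u0$u_pd == 0.5))

  # infeasible moment matching is refused with guidance
  expect_error(sample_utilities(utility_spec(0.99, 0.9, relative_range = 1.9),
                                n_sims = 5, seed = 1),
               "relative_range")
  expect_warning(utility_spec(0.5, 0.9), "u_pd exceeds u_sd")
})

test_that("QALY accumulation matches brute-force discounted sums", {
  # full health for exactly one year, no discounting
  st1 <- econ_settings(cycle_length_weeks = 365.25 / 7 / 10, n_cycles = 10,
                       discount_rate_annual = 0, n_sims = 1, seed = 1, wtp = 1)
  tr1 <- build_trace(make_fit("exponential", c(rate = 1e-12)),
                     make_fit("exponential", c(rate = 1e-12), endpoint = "OS"), st1)
  expect_equal(qalys(tr1, list(u_sd = 1, u_pd = 1), st1), 1, tolerance = 1e-9)

  # survival drops 1 -> 0 at the single cycle boundary: half-cycle credit
  st2 <- yr_settings(1, cycle_years = 0.5)
  tr2 <- list(arm_id = "a", time_years = c(0, 0.5), cycle_years = 0.5,
              p_sd = c(1, 0), p_pd = c(0, 0), p_death = c(0, 1),
              occ_sd = 0.5, occ_pd = 0, occ_death = 0.5, n_crossings = 0)
  class(tr2) <- "psm_trace"
  expect_equal(qalys(tr2, list(u_sd = 1, u_pd = 1), st2), 0.25, tolerance = 1e-12)

  # 2 cycles of 0.5 yr in SD at r = 0.05: midpoint-discounted sum
  st3 <- econ_settings(cycle_length_weeks = 365.25 / 7 / 2, n_cycles = 2,
                       discount_rate_annual = 0.05, n_sims = 1, seed = 1, wtp = 1)
  tr3 <- build_trace(make_fit("exponential", c(rate = 1e-12)),
                     make_fit("exponential", c(rate = 1e-12), endpoint = "OS"), st3)
  expect_equal(qalys(tr3, list(u_sd = 1, u_pd = 1), st3),
               0.5 * 1.05^-0.25 + 0.5 * 1.05^-0.75, tolerance = 1e-9)
})

test_that("QALYs are monotone in utilities and antitone in the discount rate", {
  mk <- function(r) {
    st <- econ_settings(cycle_length_weeks = 3, n_cycles = 100,
                        discount_rate_annual = r, n_sims = 1, seed = 1, wtp = 1)
    tr <- build_trace(make_fit("exponential", c(rate = 0.6)),
                      make_fit("exponential", c(rate = 0.3), endpoint = "OS"), st)
    list(st = st, tr = tr)
  }
  m <- mk(0.03)
  q_base <- qalys(m$tr, list(u_sd = 0.8, u_pd = 0.6), m$st)
  expect_gt(qalys(m$tr, list(u_sd = 0.9, u_pd = 0.6), m$st), q_base)
  expect_gt(qalys(m$tr, list(u_sd = 0.8, u_pd = 0.7), m$st), q_base)
  m2 <- mk(0.08)
  expect_lt(qalys(m2$tr, list(u_sd = 0.8, u_pd = 0.6), m2$st), q_base)

  # r = 0, all utilities 1: QALY equals the trapezoid area under S_OS
  m0 <- mk(0)
  s_os <- 1 - m0$tr$p_death
  auc <- sum((s_os[-1] + s_os[-length(s_os)]) / 2) * m0$tr$cycle_years
  expect_equal(qalys(m0$tr, list(u_sd = 1, u_pd = 1), m0$st), auc,
               tolerance = 1e-9)
})
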