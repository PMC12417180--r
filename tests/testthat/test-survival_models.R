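# KM estimation, comparison statistics, AFT likelihoods and AIC selection.

test_that("KM estimator matches hand product-limit computations", {
  # 4 events, no censoring
  ip <- ipd_dataset(1:4, rep(1, 4), "a")
  km <- km_estimate(ip)
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))

  # all censored: S stays 1
  ip2 <- ipd_dataset(c(1, 2, 3), c(0, 0, 0), "a")
  expect_true(all(km_estimate(ip2)$surv == 1))

  # events at 1 and 3, censoring at 2, n = 3: S(1) = 2/3, S(3) = 2/3 * 0 = 0
  ip3 <- ipd_dataset(c(1, 2, 3), c(1, 0, 1), "a")
  km3 <- km_estimate(ip3)
  expect_equal(km_survival_at(km3, c(0.5, 1, 2.5, 3)), c(1, 2/3, 2/3, 0))

  expect_error(km_estimate(ip, arm = "nope"), "no records")
})

test_that("log-rank test matches a brute-force observed-minus-expected computation", {
  # identical arms: no signal
  ip0 <- ipd_dataset(rep(1:4, 2), rep(1, 8), rep(c("a", "b"), each = 4))
  lr0 <- logrank_test(ip0)
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)

  # separated arms, hand O-E/V sums over distinct event times
  ip <- ipd_dataset(c(1, 2, 3, 4), rep(1, 4), c("a", "a", "b", "b"))
  oe <- 0; v <- 0
  at_risk <- data.frame(t = c(1, 2, 3, 4), n_a = c(2, 1, 0, 0),
                        n_b = c(2, 2, 2, 1), d_a = c(1, 1, 0, 0))
  for (i in 1:4) {
    n <- at_risk$n_a[i] + at_risk$n_b[i]
    e_a <- at_risk$n_a[i] / n            # one event at each time
    oe <- oe + at_risk$d_a[i] - e_a
    v <- v + e_a * (1 - e_a)             # hypergeometric variance, d = 1
  }
  expect_equal(logrank_test(ip)$chi2, oe^2 / v, tolerance = 1e-10)

  expect_error(logrank_test(ipd_dataset(1:3, c(1, 1, 1), "a")), "two arms")
})

test_that("Cox hazard ratio recovers a known rate ratio and is relabeling-symmetric", {
  set.seed(71)
  n <- 2000
  ip <- ipd_dataset(c(rexp(n, 0.2), rexp(n, 0.1)), rep(1, 2 * n),
                    rep(c("treated", "reference"), each = n))
  cs <- cox_hazard_ratio(ip, ref = "reference")
  expect_lt(abs(cs$hazard_ratio - 2) / 2, 0.10)
  expect_true(cs$hr_ci95[1] <= cs$hazard_ratio && cs$hazard_ratio <= cs$hr_ci95[2])

  # swapping the reference inverts the ratio
  cs_rev <- cox_hazard_ratio(ip, ref = "treated")
  expect_equal(cs$hazard_ratio * cs_rev$hazard_ratio, 1, tolerance = 1e-8)

  # identical arms: HR ~ 1 and the CI covers 1
  set.seed(72)
  t0 <- rexp(500, 0.3)
  ip0 <- ipd_dataset(rep(t0, 2), rep(1, 1000), rep(c("a", "b"), each = 500))
  cs0 <- cox_hazard_ratio(ip0)
  expect_equal(cs0$hazard_ratio, 1, tolerance = 1e-6)
  expect_true(cs0$hr_ci95[1] <= 1 && 1 <= cs0$hr_ci95[2])
})

test_that("exponential MLE is the closed form d / sum(t) with matching AIC", {
  ip <- ipd_dataset(c(1, 2, 3, 4), rep(1, 4), "a")
  fit <- fit_parametric(ip, family = "exponential")
  expect_equal(fit$params[["rate"]], 0.4)
  expect_equal(fit$loglik, 4 * log(0.4) - 0.4 * 10, tolerance = 1e-12)
  expect_equal(fit$aic, 2 - 2 * fit$loglik, tolerance = 1e-12)

  # censoring enters through the survivor term
  ipc <- ipd_dataset(c(1, 2, 3, 4), c(1, 1, 0, 0), "a")
  fitc <- fit_parametric(ipc, family = "exponential")
  expect_equal(fitc$params[["rate"]], 2 / 10)
})

test_that("maximum likelihood recovers generating parameters", {
  set.seed(5)
  t <- rweibull(1000, shape = 1.5, scale = 2)
  ip <- ipd_dataset(t, rep(1, 1000), "a")
  fit <- fit_parametric(ip, family = "weibull")
  expect_lt(abs(fit$params[["shape"]] - 1.5) / 1.5, 0.10)
  expect_lt(abs(fit$params[["scale"]] - 2) / 2, 0.10)

  # reported loglik equals an independent numerical evaluation at the params
  sub <- ipd_dataset(t[1:50], rep(1, 50), "a")
  fit50 <- fit_parametric(sub, family = "weibull")
  expect_equal(fit50$loglik,
               numeric_loglik(fit50, sub$time, sub$event), tolerance = 1e-4)
})

test_that("fits agree with an independent AFT implementation", {
  set.seed(9)
  t_ev <- rexp(400, 0.5)
  cens <- runif(400, 0, 4)
  ip <- ipd_dataset(pmin(t_ev, cens), as.integer(t_ev <= cens), "a")
  d <- data.frame(time = pmax(ip$time, 1e-8), event = ip$event)
  for (fam in c("weibull", "lnorm", "llogis", "gompertz")) {
    ours <- fit_parametric(ip, family = switch(fam, lnorm = "lognormal",
                                               llogis = "loglogistic", fam))
    ref <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = d,
                                 dist = fam)
    expect_equal(ours$loglik, ref$loglik, tolerance = 1e-4,
                 label = sprintf("loglik (%s)", fam))
  }
})

test_that("AIC selection takes the argmin with parsimony tie-breaks", {
  fits <- list(
    weibull = make_fit("weibull", c(shape = 1, scale = 1)),
    loglogistic = make_fit("loglogistic", c(shape = 1, scale = 1)))
  fits$weibull$aic <- 100; fits$loglogistic$aic <- 98.5
  expect_equal(select_by_aic(fits)$family, "loglogistic")

  # ties: fewer parameters win
  tie <- list(
    weibull = make_fit("weibull", c(shape = 1, scale = 1)),
    exponential = make_fit("exponential", c(rate = 1)))
  tie$weibull$aic <- 100; tie$exponential$aic <- 100
  expect_equal(select_by_aic(tie)$family, "exponential")

  # equal loglik across nested families: AIC never prefers the richer one
  ip <- ipd_dataset(rexp(200, 0.5), rep(1, 200), "a")
  f1 <- fit_parametric(ip, family = "exponential")
  f2 <- fit_parametric(ip, family = "weibull")
  expect_gte(f2$loglik, f1$loglik - 1e-6)  # nesting
  if (abs(f2$loglik - f1$loglik) < 1e-6) {
    expect_equal(select_by_aic(list(f1, f2))$family, "exponential")
  } else {
    expect_lte(f2$aic - f1$aic, 2 + 1e-6)
  }
})

test_that("survival and median functions follow the closed forms", {
  expect_equal(median_survival("exponential", params = c(rate = 0.5)),
               log(2) / 0.5)
  expect_equal(median_survival("loglogistic", params = c(shape = 3, scale = 2)), 2)
  expect_equal(survival_at("loglogistic", 2, params = c(shape = 3, scale = 2)), 0.5)
  expect_equal(median_survival("weibull", params = c(shape = 2, scale = 3)),
               3 * log(2)^0.5)
  expect_equal(median_survival("lognormal", params = c(meanlog = 1.2, sdlog = 0.4)),
               exp(1.2))

  # weibull with shape 1 is exponential with rate 1/scale
  tt <- seq(0, 10, by = 0.25)
  expect_equal(survival_at("weibull", tt, params = c(shape = 1, scale = 2)),
               survival_at("exponential", tt, params = c(rate = 0.5)),
               tolerance = 1e-12)

  # gompertz and gengamma medians satisfy S(m) = 1/2
  for (p in list(list(f = "gompertz", par = c(shape = 0.3, rate = 0.2)),
                 list(f = "gompertz", par = c(shape = -0.1, rate = 0.5)),
                 list(f = "gengamma", par = c(mu = 0.5, sigma = 0.8, Q = 1.2)),
                 list(f = "gengamma", par = c(mu = 0.5, sigma = 0.8, Q = -0.7)))) {
    m <- median_survival(p$f, params = p$par)
    expect_equal(survival_at(p$f, m, params = p$par), 0.5, tolerance = 1e-9)
  }

  # gompertz with negative shape can plateau above 1/2: median is infinite
  expect_equal(median_survival("gompertz", params = c(shape = -1, rate = 0.1)), Inf)
})

test_that("every family gives a valid survival function", {
  cases <- list(
    exponential = c(rate = 0.7),
    weibull = c(shape = 1.7, scale = 2.2),
    lognormal = c(meanlog = 0.3, sdlog = 0.9),
    loglogistic = c(shape = 2.5, scale = 1.4),
    gompertz = c(shape = 0.4, rate = 0.3),
    gengamma = c(mu = 0.2, sigma = 0.7, Q = 0.8))
  tt <- c(seq(0, 30, by = 0.5), 100)
  for (fam in names(cases)) {
    s <- survival_at(fam, tt, params = cases[[fam]])
    expect_equal(s[1], 1, info = fam)
    expect_true(all(diff(s) <= 1e-12), info = fam)
    expect_lt(s[length(s)], 1e-3)
    # density integrates against the survival decrement
    expect_true(all(is.finite(psmcea:::.log_density(fam, cases[[fam]],
                                                    c(0.5, 1, 5)))))
  }
  # gompertz with negative shape plateaus (documented exemption)
  s_plateau <- survival_at("gompertz", c(0, 1e3), params = c(shape = -1, rate = 0.1))
  expect_gt(s_plateau[2], 0.9)
})
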