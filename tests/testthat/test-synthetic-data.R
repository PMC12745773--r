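test_that("null configuration produces a flat expected rate", {
  cfg <- generator_config(n_departments = 2, years = 2000:2001,
                          fe_year_sd = 0, fe_doy_sd = 0,
                          beta_main = matrix(0, 6, 4),
                          beta_comp = matrix(0, 6, 4),
                          beta_clim = matrix(0, 6, 4),
                          lambda_rh = rep(0, 6), lambda_precip = rep(0, 6),
                          noise = "expected_value", seed = 5)
  p <- generate_panel(cfg)
  rate <- p$expected_deaths / p$population * 1e5
  expect_equal(rate, rep(exp(cfg$baseline_log_rate), nrow(p)),
               tolerance = 1e-12)
})

test_that("temperature anomalies have the configured AR(1) autocorrelation", {
  cfg <- generator_config(n_departments = 1, years = 1950:1999, rho = 0.7,
                          noise = "expected_value", seed = 8)
  p <- generate_panel(cfg)
  seas <- ave(p$tmean_c, p$cday, FUN = mean)
  a <- p$tmean_c - seas
  r1 <- acf(a, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(r1 - 0.7), 0.03)
})

test_that("configured department mean climates are recovered", {
  cfg <- generator_config(n_departments = 10, years = 1980:2009,
                          tbar_range = c(8, 18), noise = "expected_value",
                          seed = 9)
  p <- generate_panel(cfg)
  est <- department_mean_temperature(p)
  expect_equal(unname(est), seq(8, 18, length.out = 10), tolerance = 0.1)
  # single-department config centered on the range midpoint
  cfg1 <- generator_config(n_departments = 1, years = 1990:2019,
                           tbar_range = c(13, 13), noise = "expected_value",
                           seed = 10)
  expect_equal(unname(department_mean_temperature(generate_panel(cfg1))),
               13, tolerance = 0.1)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_gen_config(seed = 77)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(p1$deaths, p2$deaths)
  expect_identical(p1$tmean_c, p2$tmean_c)
  p3 <- generate_panel(small_gen_config(seed = 78))
  expect_false(identical(p1$tmean_c, p3$tmean_c))
})

test_that("true_log_response is normalized at the reference and separable", {
  cfg <- small_gen_config()
  ref <- rep(cfg$t_ref, cfg$n_lags + 2)
  expect_equal(true_log_response(cfg, ref, tbar = cfg$tbar_ref), 0)
  # compounding off -> independent of the deepest (purely previous) day
  cfg0 <- small_gen_config(beta_comp = matrix(0, 6, 4))
  h1 <- c(30, 25, 20, 20, 20, 25, 5)
  h2 <- c(30, 25, 20, 20, 20, 25, 35)
  expect_equal(true_log_response(cfg0, h1, 13),
               true_log_response(cfg0, h2, 13))
  # with compounding weight on the deepest lag the same change matters
  cfg1 <- small_gen_config(beta_comp = matrix(0.05, 6, 4))
  expect_false(isTRUE(all.equal(true_log_response(cfg1, h1, 13),
                                true_log_response(cfg1, h2, 13))))
})

test_that("generator internal rates match true_log_response exactly", {
  p <- small_gen_panel()
  truth <- attr(p, "truth")
  cfg <- truth$config
  L <- cfg$n_lags
  d <- p[p$department_id == "D02", ]
  i <- sample(seq((L + 2), nrow(d)), 25)
  hist <- t(vapply(i, function(k) d$tmean_c[k - 0:(L + 1)],
                   numeric(L + 2)))
  resp <- true_log_response(cfg, hist, d$tbar_c[1])
  rows <- match(paste("D02", d$date[i]), paste(p$department_id, p$date))
  eta <- log(p$expected_deaths[rows] / p$population[rows] * 1e5)
  resp_panel <- eta - cfg$baseline_log_rate - truth$fe[rows] - truth$ctrl[rows]
  expect_equal(resp_panel, resp, tolerance = 1e-10)
})

test_that("event injection perturbs only affected days and obeys its oracle", {
  fx <- event_fixture()
  cfg <- fx$config
  # zero uplift leaves an expected_value panel identical
  ev0 <- event_spec(2003, 214, 227, peak_uplift = 0)
  inj0 <- inject_event(fx$panel0, ev0)
  expect_equal(inj0$panel$deaths, fx$panel0$deaths, tolerance = 1e-12)
  # positive uplift raises aggregate expected deaths in the window; the
  # response is U-shaped, so the strict increase is asserted on
  # department-days already at or above the response minimum (~20 deg C)
  win_rows <- fx$panel$date %in% fx$window
  expect_gt(sum(fx$panel$expected_deaths[win_rows]),
            sum(fx$panel0$expected_deaths[win_rows]))
  warm <- win_rows & fx$panel0$tmean_c >= 20
  expect_gt(sum(warm), 0)
  expect_true(all(fx$panel$expected_deaths[warm] >
                    fx$panel0$expected_deaths[warm]))
  # unaffected days identical
  aff_dates <- unique(fx$affected$date)
  expect_equal(fx$panel$expected_deaths[!fx$panel$date %in% aff_dates],
               fx$panel0$expected_deaths[!fx$panel0$date %in% aff_dates])
  # Poisson-mode realized excess within 3 sd of the closed-form expectation
  cfgp <- generator_config(n_departments = 5, years = 1990:2003,
                           noise = "poisson", seed = 510)
  p0 <- generate_panel(cfgp)
  injp <- inject_event(p0, event_spec(2003, 214, 227, 8))
  true_ex <- true_event_excess(p0, injp$panel)
  aff <- injp$panel$date %in% unique(injp$affected_days$date)
  realized <- sum(injp$panel$deaths[aff]) - sum(injp$panel$expected_deaths[aff] -
    (injp$panel$expected_deaths[aff] - p0$expected_deaths[aff]))
  # realized excess of the event panel about its own expectation:
  realized_excess <- sum(injp$panel$deaths[aff] - p0$expected_deaths[aff])
  sd_pois <- sqrt(sum(injp$panel$expected_deaths[aff]))
  expect_lt(abs(realized_excess - true_ex), 3 * sd_pois)
  # edge proximity is an error
  expect_error(inject_event(fx$panel0, event_spec(1990, 2, 10, 5)),
               "edge|start")
})

test_that("delta tables validate and average as expected", {
  win <- seq(as.Date("2003-08-02"), as.Date("2003-08-15"), by = "day")
  d <- make_delta_series(win, list("GMT+0.0" = -1.2, "GMT+1.5" = 0.9))
  expect_equal(nrow(d), 28)
  expect_equal(mean(d$delta_c[d$scenario_label == "GMT+0.0"]), -1.2)
  mixed <- make_delta_series(win, list(mix = c(rep(-2, 7), rep(1, 7))))
  expect_equal(mean(mixed$delta_c), mean(c(rep(-2, 7), rep(1, 7))))
  expect_error(make_delta_series(c(win, win[1]), list(a = 0)), "duplicate")
})
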