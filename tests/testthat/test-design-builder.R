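test_that("design column counts match the specification enumeration", {
  p <- small_gen_panel()
  # P=4, L=5, no compounding, no climate interaction, 1 lagged control
  d1 <- build_design(p, model_spec(climate_interaction = FALSE,
                                   controls = "rh"))
  expect_equal(ncol(d1$X), 4 * 6 + 6)
  # P=4, L=5, climate interaction + previous_level compounding, 2 controls
  d2 <- build_design(p, model_spec(compounding = "previous_level"))
  expect_equal(ncol(d2$X), (4 + 4 + 4) * 6 + 2 * 6)
  # spline compounding adds two basis columns per (lag, power)
  d3 <- build_design(p, model_spec(compounding = "previous_spline"))
  expect_equal(ncol(d3$X), (4 + 4 + 2 * 4) * 6 + 2 * 6)
})

test_that("rows lacking lags are dropped and counted per department-series", {
  p <- small_gen_panel()
  spec <- model_spec(compounding = "none")
  d <- build_design(p, spec)
  n_dept <- length(unique(p$department_id))
  # contiguous multi-year series: the first L days per department lack lags
  expect_equal(d$n_lag_excluded, spec$n_lags * n_dept)
  expect_equal(length(d$y), nrow(p) - d$n_lag_excluded - d$n_zero_excluded)
  # compounding needs one more history day
  d2 <- build_design(p, model_spec(compounding = "previous_level"))
  expect_equal(d2$n_lag_excluded, (spec$n_lags + 1) * n_dept)
})

test_that("previous-day transforms behave per mode", {
  expect_equal(previous_day_transform(c(5, 10), "previous_level")[, 1],
               c(5, 10))
  expect_equal(previous_day_transform(c(5, 10), "previous_anomaly",
                                      clim_values = c(5, 10))[, 1],
               c(0, 0))
  expect_error(previous_day_transform(1:3, "previous_anomaly"),
               "climatology")
  # natural cubic spline: continuous value, first and second derivative at
  # the knot (finite differences), and exactly two basis columns
  knot <- 11.7
  b <- function(x) previous_day_transform(x, "previous_spline", knot = knot,
                                          boundary_knots = c(-10, 35))
  expect_equal(ncol(b(0)), 2)
  h <- 1e-4
  for (k in 1:2) {
    f <- function(x) b(x)[, k]
    d2l <- (f(knot - 2 * h) - 2 * f(knot - h) + f(knot)) / h^2
    d2r <- (f(knot) - 2 * f(knot + h) + f(knot + 2 * h)) / h^2
    expect_lt(abs(f(knot + h) - f(knot - h)), 1e-2)          # continuity
    expect_lt(abs((f(knot + h) - f(knot)) / h -
                    (f(knot) - f(knot - h)) / h), 1e-2)       # C1
    expect_lt(abs(d2l - d2r), 0.05 * max(1, abs(d2l)))        # C2
  }
})

test_that("design equals a naive per-cell construction for the plain distributed lag", {
  p <- toy_panel(n_dept = 2, n_years = 2, n_days = 25)
  spec <- model_spec(poly_order = 3, n_lags = 2, climate_interaction = FALSE,
                     controls = character(0))
  d <- build_design(p, spec)
  # brute force: for each kept row find lagged temps by explicit date search
  for (r in sample(seq_along(d$y), 20)) {
    dept <- d$rows$department_id[r]
    date <- d$rows$date[r]
    for (j in 0:2) {
      tj <- p$tmean_c[p$department_id == dept & p$date == date - j]
      for (pw in 1:3) {
        expect_equal(unname(d$X[r, sprintf("t_l%d_p%d", j, pw)]), tj^pw)
      }
    }
    expect_equal(d$y[r],
                 log(p$deaths[p$department_id == dept & p$date == date] /
                       p$population[p$department_id == dept & p$date == date] * 1e5))
  }
})

test_that("design construction is deterministic", {
  p <- small_gen_panel()
  spec <- model_spec(compounding = "previous_level")
  d1 <- build_design(p, spec)
  d2 <- build_design(p, spec)
  expect_identical(d1$X, d2$X)
  expect_identical(d1$y, d2$y)
})

test_that("lags never cross gaps in a department's series", {
  p <- toy_panel(n_dept = 2, n_years = 2, n_days = 25)
  # remove one mid-series day: following L days lose their lag history
  drop_date <- as.Date("2000-01-10")
  p2 <- as_heat_panel(as.data.frame(p)[!(p$department_id == "D01" &
                                           p$date == drop_date), ])
  spec <- model_spec(poly_order = 2, n_lags = 3, climate_interaction = FALSE,
                     controls = character(0))
  d <- build_design(p2, spec)
  k <- d$rows$department_id == "D01" &
    d$rows$date > drop_date & d$rows$date <= drop_date + 3
  expect_equal(sum(k), 0)
})

test_that("support mask covers exactly the observed consecutive pairs", {
  df <- data.frame(department_id = "A",
                   date = as.Date("2000-07-01") + 0:1,
                   deaths = 5, population = 1e5,
                   tmean_c = c(20.3, 25.6), rh_pct = 60, precip_mm = 0)
  # need 2 departments? support_mask works on any panel
  s <- support_mask(as_heat_panel(df))
  expect_equal(sum(s$mask), 1)
  expect_true(support_lookup(s, 20.3, 25.6))
  expect_true(support_lookup(s, 20.9, 25.1))   # same 1-degree cell
  expect_false(support_lookup(s, 21.2, 25.6))
  expect_error(support_mask(as_heat_panel(df), bin_width = 0), "positive")
})

test_that("support concentrates near the diagonal under strong persistence", {
  frac_supported <- function(rho, seed) {
    cfg <- generator_config(n_departments = 2, years = 1990:1999, rho = rho,
                            noise = "expected_value", seed = seed)
    s <- support_mask(generate_panel(cfg))
    mean(s$mask)
  }
  expect_lt(frac_supported(0.9, 21), frac_supported(0, 21))
})

test_that("support mask is invariant to department order", {
  p <- small_gen_panel()
  idx <- order(match(p$department_id, rev(unique(p$department_id))))
  p2 <- as_heat_panel(as.data.frame(p)[idx, ])
  s1 <- support_mask(p)
  s2 <- support_mask(p2)
  expect_identical(s1$mask, s2$mask)
})

test_that("alternative exposure variables and design export work", {
  p <- toy_panel(n_dept = 2, n_years = 2, n_days = 20)
  spec_max <- model_spec(poly_order = 2, n_lags = 1,
                         climate_interaction = FALSE,
                         controls = character(0),
                         temperature_variable = "max")
  expect_error(build_design(p, spec_max), "tmax_c")
  p$tmax_c <- p$tmean_c + 5
  d <- build_design(p, spec_max)
  expect_equal(unname(d$X[1, "t_l0_p1"]),
               p$tmax_c[p$department_id == d$rows$department_id[1] &
                          p$date == d$rows$date[1]])
  f <- withr::local_tempfile(fileext = ".csv")
  write_design(d, f)
  back <- read.csv(f, check.names = FALSE)
  expect_equal(nrow(back), length(d$y))
  expect_equal(back$log_rate, unname(d$y), tolerance = 1e-10)
})
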