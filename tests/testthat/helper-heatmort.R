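# Shared fixtures, built in code. Expensive objects are memoized per test
# run so several test files can reuse the same small synthetic panel.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Hand-built toy panel: 3 departments x 2 years x 30 days, deterministic
# weather, Poisson-free death counts derived from a smooth rate so logs are
# well defined.
toy_panel <- function(n_dept = 3, n_years = 2, n_days = 30, seed = 42) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_dept)) {
    for (y in seq_len(n_years)) {
      dates <- seq(as.Date(sprintf("%d-01-01", 1999 + y)), by = "day",
                   length.out = n_days)
      tm <- 10 + 2 * i + 5 * sin(seq_len(n_days) / 5) + rnorm(n_days)
      rows[[length(rows) + 1]] <- data.frame(
        department_id = sprintf("D%02d", i), date = dates,
        deaths = 15 + rpois(n_days, 4),
        population = 1e5 * i,
        tmean_c = tm,
        rh_pct = 70 + rnorm(n_days, 0, 5),
        precip_mm = round(pmax(0, rnorm(n_days, 1, 2)), 2))
    }
  }
  as_heat_panel(do.call(rbind, rows))
}

# Small generator panel reused across test files (4 departments x 8 years).
small_gen_config <- function(seed = 301, ...) {
  generator_config(n_departments = 4, years = 1992:1999, seed = seed, ...)
}

small_gen_panel <- function() {
  memo("small_gen_panel", function() {
    with_department_climate(generate_panel(small_gen_config()))
  })
}

# Medium expected-value panel with an injected event, reused by excess /
# attribution tests (exact oracle; no sampling noise).
event_fixture <- function() {
  memo("event_fixture", function() {
    cfg <- generator_config(n_departments = 5, years = 1990:2003,
                            noise = "expected_value", seed = 510)
    panel0 <- generate_panel(cfg)
    ev <- event_spec(2003, 214, 227, peak_uplift = 8, profile = "constant")
    inj <- inject_event(panel0, ev)
    panel <- with_department_climate(inj$panel, period = c(1990, 2002))
    panel0 <- with_department_climate(panel0, period = c(1990, 2002))
    list(config = cfg, panel0 = panel0, panel = panel,
         event_days = inj$event_days, affected = inj$affected_days,
         window = sort(unique(inj$event_days$date)),
         affected_dates = sort(unique(inj$affected_days$date)))
  })
}

# Shared attribution fixture: expected-value event panel, compounding fit
# on the pre-event period, observed scenario over the event window.
attrib_fixture <- function() {
  memo("attrib_fixture", function() {
    fx <- event_fixture()
    spec <- model_spec(compounding = "previous_level")
    des <- build_design(fx$panel, spec, period = c(1990, 2002))
    fit <- fit_erf(des, period = c(1990, 2002))
    samples <- sample_coefficients(fit, 200, seed = 41)
    clim <- build_climatology(fx$panel, c(1990, 2002))
    scen <- scenario_from_panel(fx$panel, fx$affected_dates, spec)
    list(fx = fx, spec = spec, fit = fit, samples = samples, clim = clim,
         scen = scen)
  })
}

# Hand-built coefficient-sample object for closed-form contrast tests.
manual_samples <- function(beta, draws = NULL, spec = model_spec(),
                           g_info = list(mode = spec$compounding,
                                         knot = spec$spline_knot,
                                         boundary_knots = NULL),
                           period = NULL) {
  if (is.null(draws)) {
    draws <- matrix(rep(beta, each = 10), nrow = 10,
                    dimnames = list(NULL, names(beta)))
  }
  structure(list(draws = draws, beta = beta, spec = spec, g_info = g_info,
                 period = period, seed = 0L, n = nrow(draws)),
            class = "coef_samples")
}
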