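#' Configuration for the synthetic panel generator
#'
#' Describes a known data-generating process with the structure the
#' estimation stage assumes: per-department seasonal temperature cycles
#' with AR(1) anomalies and a spatial gradient in mean climate, and Poisson
#' death counts whose log expected rate is a distributed-lag polynomial in
#' temperature with optional compounding (previous-day) and climate
#' interactions, two-way fixed-effect noise, and humidity/precipitation
#' control effects.
#'
#' The true temperature response is parameterized on centered, scaled
#' coordinates: `u = (T - t_ref) / 10`, previous-day `v = (T_prev - t_ref)
#' / 10`, climate `w = (tbar - tbar_ref) / 5`. Per lag j (0..n_lags) and
#' power p (1..poly_order) the log-rate contribution is
#' `beta_main[j,p] u^p + beta_comp[j,p] u^p v + beta_clim[j,p] u^p w`.
#' Polynomials have no constant term, so the response is exactly 0 when all
#' temperatures sit at `t_ref`. Any polynomial of this form lies in the
#' span of the regression design (raw powers and interactions), up to
#' constants absorbed by the fixed effects, so fitted contrasts are
#' comparable with the generator truth.
#'
#' @param n_departments number of departments.
#' @param years integer vector of simulated years; a length-2 vector is
#'   interpreted as an inclusive range.
#' @param tbar_range range (deg C) over which department mean temperatures
#'   are evenly spaced.
#' @param seasonal_amplitude amplitude (deg C) of the seasonal cycle,
#'   peaking around 20 July.
#' @param rho AR(1) coefficient of daily temperature anomalies, in [0, 1).
#' @param innovation_sd sd (deg C) of AR(1) innovations.
#' @param baseline_log_rate log mortality rate (deaths per 100,000 per day)
#'   when all temperatures are at `t_ref` and controls at their centers.
#' @param fe_year_sd,fe_doy_sd sds of department-by-year and
#'   department-by-day-of-year fixed-effect draws (log scale).
#' @param poly_order,n_lags polynomial order P and lag depth L of the true
#'   response.
#' @param beta_main,beta_comp,beta_clim (L+1) x P coefficient matrices (see
#'   Details); defaults concentrate heat effects in the first lags, with a
#'   positive compounding interaction and a negative climate interaction.
#' @param lambda_rh,lambda_precip length-(L+1) control coefficient vectors
#'   applied to lagged `(rh - 70)/10` and precipitation (mm).
#' @param population per-department population (scalar or vector).
#' @param noise `"poisson"` (counts drawn Poisson) or `"expected_value"`
#'   (deaths column stores the exact expectation; an exact oracle).
#' @param t_ref,tbar_ref centering constants (deg C).
#' @param adaptation optional `list(year =, factor =)`: from `year` onward
#'   all temperature-response coefficients are multiplied by `factor`,
#'   emulating a moderation of the heat-mortality relationship (e.g. heat
#'   action plans adopted after a severe event).
#' @param seed integer RNG seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_departments = 10,
                             years = 1980:2004,
                             tbar_range = c(8, 18),
                             seasonal_amplitude = 8,
                             rho = 0.7,
                             innovation_sd = 2.5,
                             baseline_log_rate = log(2.7),
                             fe_year_sd = 0.05,
                             fe_doy_sd = 0.05,
                             poly_order = 4,
                             n_lags = 5,
                             beta_main = NULL,
                             beta_comp = NULL,
                             beta_clim = NULL,
                             lambda_rh = NULL,
                             lambda_precip = NULL,
                             population = 650000,
                             noise = c("poisson", "expected_value"),
                             t_ref = 20,
                             tbar_ref = 13,
                             adaptation = NULL,
                             seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(rho >= 0, rho < 1, seasonal_amplitude >= 0,
            all(population > 0), poly_order >= 1, n_lags >= 0)
  if (length(years) == 2 && years[2] > years[1] + 1) years <- years[1]:years[2]
  L <- n_lags
  P <- poly_order
  pad <- function(shape) c(shape, rep(0, P))[seq_len(P)]
  # Default response: U-shaped with a flat thermal-comfort zone (under +5%
  # between ~12 and 25 C), rising at cold and heat extremes, heat effects
  # concentrated in the first lags; a hot day after another hot day has
  # ~1.8x the effect of a hot day after a mild day (lag-0: +22% for 30
  # after 20 C, +43% for consecutive 30 C days), mirroring the relative
  # strength of temporal compounding observed in pre-2003 France. The
  # compounding shape satisfies Q(u) = 0 at T = 0 C (u = -2), so the
  # centered truth maps onto the raw-power interaction columns without
  # leaking pure previous-day terms into the lag-1 main effect.
  w_lag <- c(1, 0.25, 0.12, 0.06, 0.02, 0.01, rep(0, L))[seq_len(L + 1)]
  w_comp <- c(1, 0.3, 0.1, rep(0, L))[seq_len(L + 1)]
  if (is.null(beta_main)) beta_main <- outer(w_lag, pad(c(0.02, 0.10, 0.06, 0.02)))
  if (is.null(beta_comp)) beta_comp <- outer(w_comp, pad(c(0.1067, 0.0533, 0, 0)))
  if (is.null(beta_clim)) beta_clim <- outer(w_lag, pad(c(0, -0.03, -0.02, 0)))
  for (nm in c("beta_main", "beta_comp", "beta_clim")) {
    b <- get(nm)
    if (!is.matrix(b) || !all(dim(b) == c(L + 1, P))) {
      stop(nm, " must be a (n_lags+1) x poly_order matrix")
    }
  }
  if (is.null(lambda_rh)) lambda_rh <- 0.01 * w_lag
  if (is.null(lambda_precip)) lambda_precip <- -0.002 * w_lag
  stopifnot(length(lambda_rh) == L + 1, length(lambda_precip) == L + 1)
  population <- rep_len(population, n_departments)
  structure(list(
    n_departments = n_departments, years = as.integer(years),
    tbar_range = tbar_range, seasonal_amplitude = seasonal_amplitude,
    rho = rho, innovation_sd = innovation_sd,
    baseline_log_rate = baseline_log_rate,
    fe_year_sd = fe_year_sd, fe_doy_sd = fe_doy_sd,
    poly_order = P, n_lags = L,
    beta_main = beta_main, beta_comp = beta_comp, beta_clim = beta_clim,
    lambda_rh = lambda_rh, lambda_precip = lambda_precip,
    population = population, noise = noise,
    t_ref = t_ref, tbar_ref = tbar_ref, adaptation = adaptation,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' True temperature log-rate response of the generator
#'
#' Evaluates the generator's exact temperature response for focal days with
#' a supplied temperature history: the sum over lags j = 0..L of the main
#' polynomial, the compounding interaction with the temperature on the day
#' preceding lag j, and the climate interaction. Normalized so that a
#' history entirely at `t_ref` yields 0. This is the single source of truth
#' for every downstream oracle (parameter recovery, event excess,
#' attribution).
#'
#' @param config a `generator_config`.
#' @param temps numeric matrix, one row per focal day, `n_lags + 2` columns
#'   ordered lag 0 (the focal day), lag 1, ..., lag L+1. A vector is
#'   treated as one row.
#' @param tbar department long-term mean temperature (scalar or per-row).
#' @return numeric vector of log-rate contributions.
#' @export
true_log_response <- function(config, temps, tbar) {
  if (is.null(dim(temps))) temps <- matrix(temps, nrow = 1)
  L <- config$n_lags
  P <- config$poly_order
  if (ncol(temps) != L + 2) {
    stop("temps must have n_lags + 2 = ", L + 2, " columns (lag 0..L+1)")
  }
  u <- (temps - config$t_ref) / 10
  w <- (tbar - config$tbar_ref) / 5
  out <- numeric(nrow(temps))
  for (j in 0:L) {
    uj <- u[, j + 1]
    vj <- u[, j + 2]
    up <- uj
    for (p in 1:P) {
      out <- out + config$beta_main[j + 1, p] * up +
        config$beta_comp[j + 1, p] * up * vj +
        config$beta_clim[j + 1, p] * up * w
      up <- up * uj
    }
  }
  out
}

#' True lag-0 marginal contrast of the generator
#'
#' The generator-truth analog of [marginal_effect()]: the difference in the
#' lag-0 regression terms between a (current, previous) scenario and a
#' reference pair, at climate `tbar`, expressed in percent.
#'
#' The estimand is defined by the regression's raw-power lag-0 columns
#' (T^p, T^p x previous, T^p x tbar, p >= 1). Monomials of the true
#' response of degree zero in the current day's temperature (pure
#' previous-day terms arising when the centered compounding polynomial is
#' expanded) belong to the lag-1 main-effect columns, so this oracle nets
#' them out: each lag-0 evaluation is taken relative to the same previous
#' day at a current-day temperature of 0 deg C (the raw basis pivot).
#'
#' @inheritParams true_log_response
#' @param scenario,reference length-2 vectors `c(current, previous)` deg C.
#' @return percent change in mortality (e.g. 58 for +58%).
#' @export
true_marginal_effect <- function(config, scenario, reference = c(20, 20),
                                 tbar) {
  lag0 <- function(cur, prev) {
    u <- (cur - config$t_ref) / 10
    v <- (prev - config$t_ref) / 10
    w <- (tbar - config$tbar_ref) / 5
    up <- u^(seq_len(config$poly_order))
    sum(config$beta_main[1, ] * up) + sum(config$beta_comp[1, ] * up) * v +
      sum(config$beta_clim[1, ] * up) * w
  }
  h <- function(cur, prev) lag0(cur, prev) - lag0(0, prev)
  d <- h(scenario[1], scenario[2]) - h(reference[1], reference[2])
  100 * (exp(d) - 1)
}

#' Era-specific generator configuration
#'
#' Returns the configuration whose response coefficients apply in a given
#' year: identical to `config` before the adaptation year, scaled by the
#' adaptation factor from that year onward.
#'
#' @param config a `generator_config`.
#' @param year focal year (the year mortality occurs in).
#' @return a `generator_config`.
#' @export
era_config <- function(config, year) {
  ad <- config$adaptation
  if (is.null(ad) || year < ad$year) return(config)
  config$beta_main <- config$beta_main * ad$factor
  config$beta_comp <- config$beta_comp * ad$factor
  config$beta_clim <- config$beta_clim * ad$factor
  config
}

# Control contribution (log scale) for focal rows given lagged humidity and
# precipitation matrices with columns lag 0..L.
true_control_response <- function(config, rh, precip) {
  L <- config$n_lags
  out <- numeric(nrow(rh))
  for (j in 0:L) {
    out <- out + config$lambda_rh[j + 1] * (rh[, j + 1] - 70) / 10 +
      config$lambda_precip[j + 1] * precip[, j + 1]
  }
  out
}

# Shift a series by j days (newer index = later day); first j entries NA.
shift_lag <- function(x, j) {
  if (j == 0) return(x)
  c(rep(NA_real_, j), x[seq_len(length(x) - j)])
}

#' Generate a synthetic department-day panel with known ground truth
#'
#' Simulates daily temperatures (seasonal cycle plus AR(1) anomalies,
#' centered so each department's realized long-term mean equals its
#' configured value exactly), humidity and precipitation, and death counts
#' from the configured log-linear response. A weather burn-in before the
#' first panel day supplies lag histories for the earliest rows. The
#' returned panel carries `tbar_c` and `expected_deaths` columns and a
#' `truth` attribute (config, per-row fixed-effect and control terms) used
#' by [inject_event()] and the oracles.
#'
#' @param config a `generator_config`.
#' @return a `heat_panel`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(substream_seed(config$seed, "panel"))
  L <- config$n_lags
  burn <- max(40, L + 2)
  years <- config$years
  start <- as.Date(sprintf("%d-01-01", min(years)))
  end <- as.Date(sprintf("%d-12-31", max(years)))
  dates_all <- seq(start - burn, end, by = "day")
  panel_idx <- which(dates_all >= start)
  n_all <- length(dates_all)
  cday_all <- calendar_day(dates_all)
  nd <- config$n_departments
  depts <- sprintf("D%02d", seq_len(nd))
  tbar <- if (nd == 1) mean(config$tbar_range) else
    seq(config$tbar_range[1], config$tbar_range[2], length.out = nd)
  names(tbar) <- depts

  seas <- config$seasonal_amplitude * cos(2 * pi * (cday_all - 201) / 365.25)
  seas <- seas - mean(seas[panel_idx])

  fe_year <- matrix(rnorm(nd * length(years), 0, config$fe_year_sd),
                    nrow = nd, dimnames = list(depts, years))
  fe_doy <- matrix(rnorm(nd * 366, 0, config$fe_doy_sd),
                   nrow = nd, dimnames = list(depts, 1:366))

  rows <- vector("list", nd)
  for (i in seq_len(nd)) {
    anom <- as.numeric(stats::filter(rnorm(n_all, 0, config$innovation_sd),
                                     config$rho, method = "recursive"))
    anom <- anom - mean(anom[panel_idx])
    tm <- tbar[i] + seas + anom
    rh <- pmin(100, pmax(20, rnorm(n_all, 70, 10)))
    pr <- rbinom(n_all, 1, 0.4) * rgamma(n_all, shape = 0.7, scale = 5)

    lagm <- function(x, k) sapply(0:k, function(j) shift_lag(x, j))
    tm_l <- lagm(tm, L + 1)[panel_idx, , drop = FALSE]
    rh_l <- lagm(rh, L)[panel_idx, , drop = FALSE]
    pr_l <- lagm(pr, L)[panel_idx, , drop = FALSE]

    yr <- as.integer(format(dates_all[panel_idx], "%Y"))
    resp <- true_log_response(config, tm_l, tbar[i])
    if (!is.null(config$adaptation)) {
      post <- yr >= config$adaptation$year
      if (any(post)) {
        resp[post] <- true_log_response(era_config(config, config$adaptation$year),
                                        tm_l[post, , drop = FALSE], tbar[i])
      }
    }
    ctrl <- true_control_response(config, rh_l, pr_l)
    cd <- cday_all[panel_idx]
    fe <- fe_year[i, as.character(yr)] + fe_doy[i, cd]
    eta <- config$baseline_log_rate + fe + resp + ctrl
    mu <- exp(eta) * config$population[i] / 1e5
    rows[[i]] <- data.frame(
      department_id = depts[i], date = dates_all[panel_idx],
      deaths = mu,  # replaced below in poisson mode
      population = config$population[i],
      tmean_c = tm[panel_idx], rh_pct = rh[panel_idx],
      precip_mm = pr[panel_idx], tbar_c = unname(tbar[i]),
      expected_deaths = mu,
      stringsAsFactors = FALSE
    )
    rows[[i]]$.fe <- unname(fe)
    rows[[i]]$.ctrl <- ctrl
  }
  out <- do.call(rbind, rows)
  if (config$noise == "poisson") {
    out$deaths <- rpois(nrow(out), out$expected_deaths)
  }
  fe_col <- out$.fe
  ctrl_col <- out$.ctrl
  out$.fe <- NULL
  out$.ctrl <- NULL
  panel <- as_heat_panel(out, integer_deaths = config$noise == "poisson")
  # as_heat_panel reorders; re-align truth vectors by key
  key_in <- paste(out$department_id, out$date)
  key_out <- paste(panel$department_id, panel$date)
  idx <- match(key_out, key_in)
  attr(panel, "truth") <- list(config = config, fe = fe_col[idx],
                               ctrl = ctrl_col[idx], tbar = tbar)
  panel
}

#' Heat-wave event specification
#'
#' @param year event year.
#' @param start_cday,end_cday first and last calendar day of the event.
#' @param peak_uplift peak temperature uplift (deg C).
#' @param pattern `"uniform"` or a named per-department weight vector
#'   multiplying the uplift.
#' @param profile `"constant"` (uplift flat across the window) or
#'   `"triangular"` (ramp to the peak at mid-window and decay).
#' @return an `event_spec` list.
#' @export
event_spec <- function(year, start_cday, end_cday, peak_uplift,
                       pattern = "uniform",
                       profile = c("constant", "triangular")) {
  profile <- match.arg(profile)
  stopifnot(start_cday <= end_cday, is.finite(peak_uplift))
  structure(list(year = as.integer(year), start_cday = start_cday,
                 end_cday = end_cday, peak_uplift = peak_uplift,
                 pattern = pattern, profile = profile),
            class = "event_spec")
}

#' Inject a heat-wave event into a synthetic panel
#'
#' Raises window temperatures per the event profile and re-simulates
#' mortality from the generator's true response on every day whose lag
#' history touches the modified temperatures (the window plus L+1 trailing
#' days). Days outside that set are unchanged: in Poisson mode only
#' affected days are redrawn (from a derived seed), and in expected_value
#' mode the panel is an exact oracle, so the event's true excess deaths are
#' computable in closed form via [true_event_excess()].
#'
#' @param panel a generator-produced `heat_panel` (carries the `truth`
#'   attribute).
#' @param event an `event_spec`.
#' @return list with `panel` (the modified panel), `event_days` (data frame
#'   of in-window department-days), and `affected_days` (including the lag
#'   tail).
#' @export
inject_event <- function(panel, event) {
  truth <- attr(panel, "truth")
  if (is.null(truth)) stop("panel lacks generator truth; inject_event needs a generate_panel() output")
  config <- truth$config
  L <- config$n_lags
  dates <- sort(unique(panel$date))
  ev_dates <- dates[format(dates, "%Y") == as.character(event$year)]
  ev_cday <- calendar_day(ev_dates)
  win <- ev_dates[ev_cday >= event$start_cday & ev_cday <= event$end_cday]
  if (length(win) == 0) stop("event window outside panel range")
  if (min(win) - min(dates) < L + 2 || max(dates) - max(win) < L + 1) {
    stop("event window within ", L + 2, " days of panel edge; lags would be truncated")
  }
  nwin <- length(win)
  uplift <- switch(event$profile,
    constant = rep(event$peak_uplift, nwin),
    triangular = {
      mid <- (nwin + 1) / 2
      event$peak_uplift * (1 - abs(seq_len(nwin) - mid) / mid)
    })
  weights <- if (identical(event$pattern, "uniform")) {
    setNames(rep(1, length(truth$tbar)), names(truth$tbar))
  } else event$pattern

  new_panel <- panel
  in_win <- new_panel$date %in% win
  shift <- uplift[match(new_panel$date, win)]
  shift[!in_win] <- 0
  wt <- weights[new_panel$department_id]
  if (anyNA(wt)) stop("event pattern missing department weight(s)")
  new_panel$tmean_c <- new_panel$tmean_c + shift * unname(wt)

  # recompute expected deaths for days whose lag history includes the window
  affected_dates <- dates[dates >= min(win) & dates <= max(win) + L + 1]
  aff <- new_panel$date %in% affected_dates
  depts <- unique(new_panel$department_id)
  mu_new <- new_panel$expected_deaths
  for (d in depts) {
    sel <- new_panel$department_id == d
    tm <- new_panel$tmean_c[sel]
    dsel_dates <- new_panel$date[sel]
    focal <- which(dsel_dates %in% affected_dates)
    hist_idx <- outer(focal, 0:(L + 1), `-`)
    if (any(hist_idx < 1)) stop("event window too close to panel start")
    tm_l <- matrix(tm[hist_idx], nrow = length(focal))
    resp <- true_log_response(config, tm_l, truth$tbar[d])
    if (!is.null(config$adaptation)) {
      yrs <- as.integer(format(dsel_dates[focal], "%Y"))
      post <- yrs >= config$adaptation$year
      if (any(post)) {
        resp[post] <- true_log_response(era_config(config, config$adaptation$year),
                                        tm_l[post, , drop = FALSE],
                                        truth$tbar[d])
      }
    }
    rows <- which(sel)[focal]
    eta <- config$baseline_log_rate + truth$fe[rows] + truth$ctrl[rows] + resp
    mu_new[rows] <- exp(eta) * new_panel$population[rows] / 1e5
  }
  changed <- abs(mu_new - new_panel$expected_deaths) > 1e-12
  new_panel$expected_deaths <- mu_new
  if (config$noise == "poisson") {
    set.seed(substream_seed(config$seed, "inject"))
    new_panel$deaths[changed] <- rpois(sum(changed), mu_new[changed])
  } else {
    new_panel$deaths <- mu_new
  }
  attr(new_panel, "truth") <- truth
  list(panel = new_panel,
       event_days = data.frame(
         department_id = new_panel$department_id[in_win],
         date = new_panel$date[in_win]),
       affected_days = data.frame(
         department_id = new_panel$department_id[aff],
         date = new_panel$date[aff]))
}

#' Closed-form true excess deaths of an injected event
#'
#' Sum over affected department-days of the difference in generator
#' expected deaths between the event panel and the original panel. In
#' expected_value mode this is exact; in Poisson mode it is the expectation
#' of the realized excess.
#'
#' @param original,injected panels before and after [inject_event()].
#' @return scalar expected excess deaths.
#' @export
true_event_excess <- function(original, injected) {
  stopifnot(nrow(original) == nrow(injected))
  sum(injected$expected_deaths - original$expected_deaths)
}

#' Add deaths directly to selected department-days
#'
#' A pure death-count injection (no temperature change), used to validate
#' excess-mortality recovery against a known increment.
#'
#' @param panel a `heat_panel`.
#' @param department department id.
#' @param dates Date vector of days to modify.
#' @param extra deaths added per day.
#' @return the modified panel.
#' @export
inject_deaths <- function(panel, department, dates, extra) {
  sel <- panel$department_id == department & panel$date %in% dates
  if (sum(sel) != length(dates)) stop("some target days absent from panel")
  panel$deaths[sel] <- panel$deaths[sel] + extra
  if (!is.null(panel$expected_deaths)) {
    panel$expected_deaths[sel] <- panel$expected_deaths[sel] + extra
  }
  panel
}

#' Build a per-day counterfactual delta table
#'
#' Region-wide daily temperature deltas per scenario label (and optionally
#' per source, emulating an ensemble of counterfactual predictions).
#'
#' @param dates Date vector of event days.
#' @param deltas named list: label -> scalar or per-day vector of deg C
#'   deltas (counterfactual minus observed).
#' @param source_id identifier for the delta source (default "synthetic").
#' @return data frame `date, scenario_label, source_id, delta_c`.
#' @export
make_delta_series <- function(dates, deltas, source_id = "synthetic") {
  stopifnot(is.list(deltas), length(names(deltas)) == length(deltas))
  out <- do.call(rbind, lapply(names(deltas), function(lb) {
    v <- rep_len(deltas[[lb]], length(dates))
    data.frame(date = dates, scenario_label = lb, source_id = source_id,
               delta_c = v, stringsAsFactors = FALSE)
  }))
  key <- paste(out$date, out$scenario_label, out$source_id)
  if (anyDuplicated(key)) {
    stop("duplicate (day, label, source) in delta table: ",
         key[anyDuplicated(key)])
  }
  out
}
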