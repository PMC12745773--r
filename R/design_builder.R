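#' Declarative exposure-response model specification
#'
#' Describes the regression of log mortality rate on distributed lags of a
#' temperature polynomial with optional interactions, lagged weather
#' controls, and two-way fixed effects (department-by-year and
#' department-by-day-of-year; always included).
#'
#' @param poly_order polynomial order P of the temperature response
#'   (default 4).
#' @param n_lags number of temperature lags L (default 5; 3, 10 and 30 are
#'   supported sensitivity settings).
#' @param compounding how the previous day enters: `"none"` (standard
#'   model), `"previous_level"` (each lag-j polynomial interacted with the
#'   raw temperature at lag j+1), `"previous_anomaly"` (interacted with the
#'   lag j+1 temperature anomaly from climatology), or `"previous_spline"`
#'   (interacted with a two-column natural cubic spline basis in the lag
#'   j+1 temperature, one interior knot).
#' @param climate_interaction interact every lag's polynomial terms with
#'   the department long-term mean temperature (default TRUE).
#' @param controls subset of `c("rh", "precip")` entered as controls.
#' @param control_lags enter controls with the same 0..L lag structure
#'   (default TRUE); FALSE uses only the contemporaneous value.
#' @param temperature_variable exposure variable: `"mean"` (default, column
#'   `tmean_c`), `"max"` (`tmax_c`) or `"min"` (`tmin_c`); the latter two
#'   require the corresponding column on the panel.
#' @param spline_knot interior knot (deg C) for `previous_spline`
#'   (typically the sample median daily temperature, about 11.7 deg C in
#'   mid-latitude panels).
#' @param zero_deaths `"drop"` zero-death rows (default; the count is
#'   reported on the design) or `"add_half"` (continuity correction adding
#'   0.5 deaths before taking logs).
#' @return a `model_spec` list.
#' @export
model_spec <- function(poly_order = 4, n_lags = 5,
                       compounding = c("none", "previous_level",
                                       "previous_anomaly", "previous_spline"),
                       climate_interaction = TRUE,
                       controls = c("rh", "precip"),
                       control_lags = TRUE,
                       temperature_variable = c("mean", "max", "min"),
                       spline_knot = 11.7,
                       zero_deaths = c("drop", "add_half")) {
  compounding <- match.arg(compounding)
  zero_deaths <- match.arg(zero_deaths)
  temperature_variable <- match.arg(temperature_variable)
  stopifnot(poly_order >= 1, n_lags >= 0)
  if (compounding == "previous_spline" && !is.finite(spline_knot)) {
    stop("previous_spline mode requires a finite spline_knot")
  }
  controls <- intersect(controls, c("rh", "precip"))
  structure(list(poly_order = as.integer(poly_order),
                 n_lags = as.integer(n_lags),
                 compounding = compounding,
                 climate_interaction = isTRUE(climate_interaction),
                 controls = controls, control_lags = isTRUE(control_lags),
                 temperature_variable = temperature_variable,
                 spline_knot = spline_knot, zero_deaths = zero_deaths),
            class = "model_spec")
}

#' Transform a previous-day temperature series
#'
#' The g() applied to the day preceding each lag in the compounding models:
#' identity for `previous_level`, anomaly from climatology for
#' `previous_anomaly`, and a natural cubic spline basis (one interior knot,
#' two columns) for `previous_spline`.
#'
#' @param prev numeric vector of previous-day temperatures (deg C).
#' @param mode one of `"previous_level"`, `"previous_anomaly"`,
#'   `"previous_spline"`.
#' @param clim_values climatological mean temperatures aligned with `prev`
#'   (anomaly mode only).
#' @param knot interior knot (spline mode only).
#' @param boundary_knots length-2 boundary knots (spline mode; fixed at the
#'   estimation-sample range so the basis is reproducible at prediction
#'   time).
#' @return numeric matrix with one column (level/anomaly) or two (spline).
#' @export
previous_day_transform <- function(prev, mode, clim_values = NULL,
                                   knot = NULL, boundary_knots = NULL) {
  if (mode == "previous_level") {
    return(matrix(prev, ncol = 1))
  }
  if (mode == "previous_anomaly") {
    if (is.null(clim_values)) stop("previous_anomaly mode requires climatology values")
    if (length(clim_values) != length(prev)) stop("clim_values length mismatch")
    return(matrix(prev - clim_values, ncol = 1))
  }
  if (mode == "previous_spline") {
    if (is.null(knot) || !is.finite(knot)) stop("previous_spline mode requires a knot")
    if (is.null(boundary_knots)) boundary_knots <- range(prev)
    b <- splines::ns(prev, knots = knot, Boundary.knots = boundary_knots)
    return(matrix(as.numeric(b), ncol = 2))
  }
  stop("unknown previous-day transform mode: ", mode)
}

# Lagged value matrices on the calendar grid of one department: column j+1
# holds the value j days before each row's date; NA where the panel has a
# gap (lags never cross gaps or the series start).
lag_matrix_by_dept <- function(panel, column, max_lag) {
  n <- nrow(panel)
  out <- matrix(NA_real_, n, max_lag + 1)
  for (d in unique(panel$department_id)) {
    sel <- which(panel$department_id == d)
    dates <- panel$date[sel]
    grid <- seq(min(dates), max(dates), by = "day")
    pos <- match(dates, grid)
    full <- rep(NA_real_, length(grid))
    full[pos] <- panel[[column]][sel]
    for (j in 0:max_lag) {
      lag_pos <- pos - j
      ok <- lag_pos >= 1
      v <- rep(NA_real_, length(sel))
      v[ok] <- full[lag_pos[ok]]
      out[sel, j + 1] <- v
    }
  }
  out
}

#' Build the numeric regression design for an exposure-response model
#'
#' Realizes the model: outcome log(deaths / population x 100,000);
#' regressors, for each lag j in 0..L, the temperature powers T^p
#' (p = 1..P), optionally T^p x tbar (climate interaction) and
#' T^p x g(T at lag j+1) (compounding; so the deepest lag requires L+1
#' lagged temperatures); lagged controls; and fixed-effect group labels
#' (department-by-year, department-by-day-of-year) plus department cluster
#' labels. Rows lacking any required lag are excluded and counted, as are
#' zero-death rows under the default policy. Column names encode
#' (lag, power, interaction partner), e.g. `t_l2_p3_x_prev`.
#'
#' @param panel a `heat_panel` (with `tbar_c` when the climate interaction
#'   is on).
#' @param spec a `model_spec`.
#' @param climatology a `heat_climatology` (required for
#'   `previous_anomaly`).
#' @param period optional year range restricting the estimation sample.
#' @return a `heat_design` list: `y`, `X` (matrix), `fe1`, `fe2`,
#'   `cluster` (factors), `rows` (row index back to department-days),
#'   `spec`, `g_info`, exclusion counts.
#' @export
build_design <- function(panel, spec, climatology = NULL, period = NULL) {
  stopifnot(inherits(panel, "heat_panel"), inherits(spec, "model_spec"))
  if (!is.null(period)) {
    years <- expand_period(period, panel$year)
    panel <- panel[panel$year %in% years, ]
    class(panel) <- c("heat_panel", "data.frame")
  }
  if (length(unique(panel$department_id)) < 2) {
    stop("design requires at least 2 departments")
  }
  if (length(unique(panel$year)) < 2) {
    stop("design requires at least 2 years")
  }
  if (spec$climate_interaction && is.null(panel$tbar_c)) {
    stop("climate interaction requires tbar_c; call with_department_climate()")
  }
  L <- spec$n_lags
  P <- spec$poly_order
  comp <- spec$compounding != "none"
  if (comp && spec$compounding == "previous_anomaly" && is.null(climatology)) {
    stop("previous_anomaly compounding requires a climatology")
  }
  tcol <- switch(spec$temperature_variable %||% "mean",
                 mean = "tmean_c", max = "tmax_c", min = "tmin_c")
  if (is.null(panel[[tcol]])) {
    stop("panel lacks the requested temperature column: ", tcol)
  }
  max_lag <- if (comp) L + 1 else L
  TL <- lag_matrix_by_dept(panel, tcol, max_lag)
  ctrl_lag <- if (spec$control_lags) L else 0
  RL <- if ("rh" %in% spec$controls) lag_matrix_by_dept(panel, "rh_pct", ctrl_lag)
  PL <- if ("precip" %in% spec$controls) lag_matrix_by_dept(panel, "precip_mm", ctrl_lag)

  need <- complete.cases(TL)
  if (!is.null(RL)) need <- need & complete.cases(RL)
  if (!is.null(PL)) need <- need & complete.cases(PL)
  n_lag_excluded <- sum(!need)

  deaths <- panel$deaths
  if (spec$zero_deaths == "add_half") deaths <- deaths + 0.5
  zero <- deaths <= 0
  n_zero_excluded <- sum(zero & need)
  keep <- need & !zero

  panel_k <- panel[keep, ]
  TLk <- TL[keep, , drop = FALSE]
  y <- log(deaths[keep] / panel_k$population * 1e5)

  g_info <- list(mode = spec$compounding, knot = spec$spline_knot,
                 boundary_knots = NULL)
  if (spec$compounding == "previous_spline") {
    g_info$boundary_knots <- range(TLk[, 2:(L + 2)])
  }
  g_cols <- if (!comp) 0 else if (spec$compounding == "previous_spline") 2 else 1

  n_temp_cols <- (L + 1) * P * (1 + spec$climate_interaction + g_cols)
  n_ctrl_cols <- length(spec$controls) * (ctrl_lag + 1)
  X <- matrix(NA_real_, nrow(panel_k), n_temp_cols + n_ctrl_cols)
  cn <- character(ncol(X))
  col <- 0
  for (j in 0:L) {
    Tj <- TLk[, j + 1]
    gj <- NULL
    if (comp) {
      prev <- TLk[, j + 2]
      cv <- NULL
      if (spec$compounding == "previous_anomaly") {
        cv <- climatology_lookup(climatology, panel_k$department_id,
                                 calendar_day(panel_k$date - (j + 1)))
      }
      gj <- previous_day_transform(prev, spec$compounding, clim_values = cv,
                                   knot = g_info$knot,
                                   boundary_knots = g_info$boundary_knots)
    }
    Tp <- Tj
    for (p in 1:P) {
      col <- col + 1
      X[, col] <- Tp
      cn[col] <- sprintf("t_l%d_p%d", j, p)
      if (spec$climate_interaction) {
        col <- col + 1
        X[, col] <- Tp * panel_k$tbar_c
        cn[col] <- sprintf("t_l%d_p%d_x_tbar", j, p)
      }
      if (comp) {
        for (k in seq_len(ncol(gj))) {
          col <- col + 1
          X[, col] <- Tp * gj[, k]
          cn[col] <- if (ncol(gj) == 1) sprintf("t_l%d_p%d_x_prev", j, p)
                     else sprintf("t_l%d_p%d_x_prev%d", j, p, k)
        }
      }
      Tp <- Tp * Tj
    }
  }
  if ("rh" %in% spec$controls) {
    RLk <- RL[keep, , drop = FALSE]
    for (j in 0:ctrl_lag) {
      col <- col + 1
      X[, col] <- RLk[, j + 1]
      cn[col] <- sprintf("rh_l%d", j)
    }
  }
  if ("precip" %in% spec$controls) {
    PLk <- PL[keep, , drop = FALSE]
    for (j in 0:ctrl_lag) {
      col <- col + 1
      X[, col] <- PLk[, j + 1]
      cn[col] <- sprintf("precip_l%d", j)
    }
  }
  colnames(X) <- cn

  fe1 <- factor(paste(panel_k$department_id, panel_k$year, sep = ":"))
  fe2 <- factor(paste(panel_k$department_id, panel_k$cday, sep = ":"))
  if (nlevels(fe1) < 2 || nlevels(fe2) < 2) {
    stop("fewer than 2 fixed-effect groups in a dimension")
  }
  rows <- data.frame(department_id = panel_k$department_id,
                     date = panel_k$date, year = panel_k$year,
                     cday = panel_k$cday, population = panel_k$population,
                     deaths = panel_k$deaths,
                     tbar_c = panel_k$tbar_c %||% NA_real_,
                     stringsAsFactors = FALSE)
  structure(list(y = y, X = X, fe1 = fe1, fe2 = fe2,
                 cluster = factor(panel_k$department_id),
                 rows = rows, spec = spec, g_info = g_info,
                 n_lag_excluded = n_lag_excluded,
                 n_zero_excluded = n_zero_excluded),
            class = "heat_design")
}

#' @export
print.heat_design <- function(x, ...) {
  cat("heat_design:", length(x$y), "rows x", ncol(x$X), "regressors;",
      nlevels(x$fe1), "+", nlevels(x$fe2), "fixed-effect groups;",
      x$n_lag_excluded, "rows dropped for missing lags,",
      x$n_zero_excluded, "for zero deaths\n")
  invisible(x)
}

#' Export a design matrix to CSV for external verification
#'
#' One row per estimation observation: the key columns (department, date),
#' the outcome, and every regressor.
#'
#' @param design a `heat_design`.
#' @param path output CSV path.
#' @export
write_design <- function(design, path) {
  out <- data.frame(department_id = design$rows$department_id,
                    date = format(design$rows$date, "%Y-%m-%d"),
                    log_rate = design$y,
                    design$X, check.names = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Observed support of (previous-day, current-day) temperature pairs
#'
#' Bins all consecutive-day temperature pairs in the panel on a regular
#' grid (half-open bins [a, a + width)). A cell is supported iff at least
#' one pair falls in it; compounding surfaces report no value outside the
#' support. Also records, per previous-day bin, the min/max observed
#' current-day temperature (the conditional range used to flag
#' extrapolation on response curves).
#'
#' @param panel a `heat_panel` (subset to the estimation period first).
#' @param bin_width bin width in deg C (default 1).
#' @return a `heat_support` list: `bin_width`, `prev_edges`, `cur_edges`,
#'   `mask` (logical matrix, previous x current), `range_by_prev`.
#' @export
support_mask <- function(panel, bin_width = 1) {
  stopifnot(inherits(panel, "heat_panel"), nrow(panel) > 0)
  if (bin_width <= 0) stop("bin width must be positive")
  prev <- cur <- numeric(0)
  for (d in unique(panel$department_id)) {
    sel <- which(panel$department_id == d)
    o <- sel[order(panel$date[sel])]
    consec <- which(diff(panel$date[o]) == 1)
    prev <- c(prev, panel$tmean_c[o][consec])
    cur <- c(cur, panel$tmean_c[o][consec + 1])
  }
  if (length(prev) == 0) stop("no consecutive-day pairs in panel")
  ed <- function(x) seq(floor(min(x) / bin_width) * bin_width,
                        floor(max(x) / bin_width) * bin_width, by = bin_width)
  prev_edges <- ed(prev)
  cur_edges <- ed(cur)
  pi_ <- findInterval(prev, c(prev_edges, Inf))
  ci_ <- findInterval(cur, c(cur_edges, Inf))
  mask <- matrix(FALSE, length(prev_edges), length(cur_edges),
                 dimnames = list(prev_edges, cur_edges))
  mask[cbind(pi_, ci_)] <- TRUE
  rng <- do.call(rbind, lapply(seq_along(prev_edges), function(i) {
    inbin <- pi_ == i
    if (!any(inbin)) return(NULL)
    data.frame(prev_bin = prev_edges[i], min_cur = min(cur[inbin]),
               max_cur = max(cur[inbin]))
  }))
  structure(list(bin_width = bin_width, prev_edges = prev_edges,
                 cur_edges = cur_edges, mask = mask, range_by_prev = rng),
            class = "heat_support")
}

#' Query a support mask
#'
#' @param support a `heat_support`.
#' @param prev,cur temperatures (deg C), recycled to equal length.
#' @return logical: is the (previous, current) bin supported? Pairs outside
#'   the binned range are unsupported.
#' @export
support_lookup <- function(support, prev, cur) {
  n <- max(length(prev), length(cur))
  prev <- rep_len(prev, n)
  cur <- rep_len(cur, n)
  pe <- support$prev_edges
  ce <- support$cur_edges
  bw <- support$bin_width
  pi_ <- findInterval(prev, c(pe, max(pe) + bw))
  ci_ <- findInterval(cur, c(ce, max(ce) + bw))
  out <- logical(n)
  ok <- pi_ >= 1 & pi_ <= length(pe) & ci_ >= 1 & ci_ <= length(ce)
  out[ok] <- support$mask[cbind(pi_[ok], ci_[ok])]
  out
}
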