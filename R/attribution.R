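#' Temperature scenario for an event window
#'
#' A per-department-day temperature series covering an event window plus
#' enough preceding history for lagged prediction, labelled by scenario
#' (e.g. "observed", "GMT+0.0") and provenance (observed or delta-shifted).
#'
#' @param panel a `heat_panel` with `tbar_c`.
#' @param window_dates Date vector of event days.
#' @param spec a `model_spec` (determines required history depth).
#' @return a `heat_scenario`: data frame `department_id, date, tmean_c`
#'   with attributes `label`, `window`, `tbar`, `deltas` (zero for the
#'   observed scenario), `source_id`.
#' @export
scenario_from_panel <- function(panel, window_dates, spec) {
  stopifnot(inherits(panel, "heat_panel"), inherits(spec, "model_spec"))
  if (is.null(panel$tbar_c)) stop("scenario requires tbar_c on the panel")
  window_dates <- sort(window_dates)
  hist_n <- spec$n_lags + 1 + as.integer(spec$compounding != "none")
  need <- seq(min(window_dates) - hist_n, max(window_dates), by = "day")
  sel <- panel$date %in% need
  sub <- panel[sel, c("department_id", "date", "tmean_c", "tbar_c",
                      "population")]
  got <- table(sub$department_id)
  if (any(got < length(need))) {
    stop("scenario lacks department-days for lagged prediction (need ",
         length(need), " days per department)")
  }
  out <- as.data.frame(sub)
  rownames(out) <- NULL
  structure(out, label = "observed", window = window_dates,
            source_id = "observed",
            base_tmean = out$tmean_c,
            delta_row = rep(0, nrow(out)),
            deltas = setNames(rep(0, length(window_dates)),
                              format(window_dates, "%Y-%m-%d")),
            class = c("heat_scenario", "data.frame"))
}

#' Shift a scenario by region-wide daily temperature deltas
#'
#' Applies the per-day region-wide delta uniformly to every department's
#' temperature on that day (the delta-method bias correction used with
#' counterfactual event predictions). History days preceding the delta
#' table reuse the first day's delta, so no spurious jump enters the lag
#' structure; set `history_delta = 0` to leave history unshifted.
#'
#' @param scenario a `heat_scenario` (typically the observed one).
#' @param deltas data frame `date, delta_c` (plus optional
#'   `scenario_label`, `source_id` used for labelling), or a single number
#'   recycled over the window.
#' @param label scenario label (e.g. "GMT+0.0"); defaults to the table's
#'   `scenario_label`.
#' @param history_delta delta applied to pre-window history days
#'   (default: the first window day's delta).
#' @return the shifted `heat_scenario`.
#' @export
apply_deltas <- function(scenario, deltas, label = NULL,
                         history_delta = NULL) {
  stopifnot(inherits(scenario, "heat_scenario"))
  win <- attr(scenario, "window")
  if (is.numeric(deltas) && is.null(dim(deltas))) {
    deltas <- data.frame(date = win, delta_c = rep_len(deltas, length(win)))
  }
  if (is.null(label)) {
    label <- if (!is.null(deltas$scenario_label)) deltas$scenario_label[1]
             else "counterfactual"
  }
  source_id <- if (!is.null(deltas$source_id)) deltas$source_id[1] else "unspecified"
  idx <- match(win, deltas$date)
  if (anyNA(idx)) {
    stop("delta table missing event day(s): ",
         paste(format(head(win[is.na(idx)], 5)), collapse = ", "))
  }
  dvec <- deltas$delta_c[idx]
  hd <- history_delta %||% dvec[1]
  shift <- ifelse(scenario$date %in% win,
                  dvec[match(scenario$date, win)], hd)
  out <- scenario
  # deltas accumulate on the observed base series, so shifts compose
  # algebraically (+d then -d restores the observed scenario exactly)
  cum <- attr(scenario, "delta_row") + shift
  out$tmean_c <- attr(scenario, "base_tmean") + cum
  attr(out, "delta_row") <- cum
  attr(out, "label") <- label
  attr(out, "source_id") <- source_id
  attr(out, "deltas") <- setNames(dvec, format(win, "%Y-%m-%d"))
  out
}

#' Predict heat-related deaths for an event under a scenario
#'
#' For each coefficient draw and department-day of the event window,
#' computes the cumulative (all-lag) log contrast between the scenario
#' temperature path and the climatological path for the same calendar
#' days, maps it to a percent change in mortality, and multiplies by the
#' climatological mean death count for that department and calendar day.
#' Negative values (days cooler than climatology) are retained.
#'
#' @param samples a `coef_samples`.
#' @param scenario a `heat_scenario`.
#' @param climatology a `heat_climatology` covering the window and history.
#' @param tbar optional named per-department climate override (defaults to
#'   the scenario's `tbar_c`).
#' @return a `heat_prediction`: `deaths` (n_draws x n_cells matrix),
#'   `cells` (department-day metadata incl. climatological deaths),
#'   `label`, `source_id`, and the draw fingerprint for pairing checks.
#' @export
predict_event_deaths <- function(samples, scenario, climatology,
                                 tbar = NULL) {
  stopifnot(inherits(samples, "coef_samples"),
            inherits(scenario, "heat_scenario"))
  spec <- samples$spec
  win <- attr(scenario, "window")
  hist_n <- spec$n_lags + 1 + as.integer(spec$compounding != "none")
  cn <- colnames(samples$draws)
  depts <- unique(scenario$department_id)
  anomaly <- spec$compounding == "previous_anomaly"

  cells <- list()
  rows <- list()
  k <- 0
  for (d in depts) {
    sel <- which(scenario$department_id == d)
    o <- sel[order(scenario$date[sel])]
    sdates <- scenario$date[o]
    stemp <- scenario$tmean_c[o]
    tb <- if (!is.null(tbar)) unname(tbar[d]) else scenario$tbar_c[o][1]
    for (day in as.list(win)) {
      k <- k + 1
      hist_dates <- seq(day, by = -1, length.out = hist_n)
      pos <- match(hist_dates, sdates)
      if (anyNA(pos)) stop("scenario history gap for ", d, " at ", day)
      path <- stemp[pos]
      cd <- calendar_day(hist_dates)
      clim_path <- climatology_lookup(climatology, rep(d, hist_n), cd)
      ch <- if (anomaly) clim_path else NULL
      rs <- full_row(cn, spec, samples$g_info, path, tb, ch)
      rr <- full_row(cn, spec, samples$g_info, clim_path, tb, ch)
      rows[[k]] <- rs - rr
      cells[[k]] <- data.frame(
        department_id = d, date = day,
        deaths_clim = climatology_lookup(climatology, d, cd[1],
                                         "deaths_clim"),
        tmean_scenario = path[1], tmean_clim = clim_path[1],
        stringsAsFactors = FALSE)
    }
  }
  C <- do.call(rbind, rows)
  cells <- do.call(rbind, cells)
  pop <- tapply(scenario$population, scenario$department_id, mean)
  cells$population <- unname(pop[cells$department_id])
  delta_log <- samples$draws %*% t(C)
  deaths <- (exp(delta_log) - 1) *
    matrix(cells$deaths_clim, nrow(samples$draws), nrow(cells), byrow = TRUE)
  structure(list(deaths = deaths, cells = cells,
                 label = attr(scenario, "label"),
                 source_id = attr(scenario, "source_id"),
                 draw_seed = samples$seed, n_draws = samples$n,
                 period = samples$period),
            class = "heat_prediction")
}

#' Per-draw total deaths of a prediction
#' @param prediction a `heat_prediction`.
#' @return numeric vector, one total per draw.
#' @export
prediction_totals <- function(prediction) {
  rowSums(prediction$deaths)
}

summarize_draws <- function(x) {
  c(mean = mean(x), lo = unname(quantile(x, 0.025)),
    hi = unname(quantile(x, 0.975)))
}

#' Deaths attributable to the difference between two scenarios
#'
#' Pairs predictions draw by draw: attributable deaths per draw are that
#' draw's observed-scenario prediction minus the same draw's counterfactual
#' prediction, never a difference of summaries. With an ensemble of
#' counterfactual delta sources (a list of predictions), paired differences
#' are pooled across sources, so the ensemble size is n_draws x n_sources.
#' The attributable fraction is computed per draw as the attributable total
#' over the observed-scenario total, then summarized.
#'
#' @param observed a `heat_prediction` under observed temperatures.
#' @param counterfactual a `heat_prediction`, or a list of them (one per
#'   delta source).
#' @return an `attribution_result`: `total` (mean/lo/hi), `fraction_pct`,
#'   `by_day`, `by_department` (incl. deaths per 100,000), `draws`
#'   (per-draw totals), `ensemble_size`.
#' @export
attributable_deaths <- function(observed, counterfactual) {
  cfs <- if (inherits(counterfactual, "heat_prediction")) list(counterfactual)
         else counterfactual
  key_o <- paste(observed$cells$department_id, observed$cells$date)
  diffs <- lapply(cfs, function(cf) {
    if (!inherits(cf, "heat_prediction")) stop("counterfactual must be heat_prediction(s)")
    if (!identical(dim(cf$deaths), dim(observed$deaths))) {
      stop("unpaired ensembles: prediction dimensions differ")
    }
    if (!identical(cf$draw_seed, observed$draw_seed) ||
        !identical(cf$n_draws, observed$n_draws)) {
      stop("unpaired ensembles: coefficient draws differ (seed/n mismatch)")
    }
    if (!identical(paste(cf$cells$department_id, cf$cells$date), key_o)) {
      stop("unpaired ensembles: department-day cells differ")
    }
    observed$deaths - cf$deaths
  })
  A <- do.call(rbind, diffs)                    # (draws x sources) x cells
  obs_tot <- rep(rowSums(observed$deaths), length(cfs))
  attr_tot <- rowSums(A)
  frac <- 100 * attr_tot / obs_tot

  cells <- observed$cells
  day_groups <- split(seq_len(nrow(cells)), as.character(cells$date))
  by_day <- do.call(rbind, lapply(names(day_groups), function(dt) {
    s <- summarize_draws(rowSums(A[, day_groups[[dt]], drop = FALSE]))
    data.frame(date = as.Date(dt), mean = s["mean"], lo = s["lo"],
               hi = s["hi"], row.names = NULL)
  }))
  dep_groups <- split(seq_len(nrow(cells)), cells$department_id)
  by_dep <- do.call(rbind, lapply(names(dep_groups), function(d) {
    idx <- dep_groups[[d]]
    s <- summarize_draws(rowSums(A[, idx, drop = FALSE]))
    pop <- cells$population[idx][1]
    data.frame(department_id = d, mean = s["mean"], lo = s["lo"],
               hi = s["hi"], rate_per_100k = s["mean"] / pop * 1e5,
               row.names = NULL)
  }))
  structure(list(total = summarize_draws(attr_tot),
                 fraction_pct = summarize_draws(frac),
                 by_day = by_day, by_department = by_dep,
                 draws = attr_tot, observed_draws = obs_tot,
                 ensemble_size = length(attr_tot),
                 labels = c(observed$label,
                            paste(vapply(cfs, `[[`, "", "label"),
                                  collapse = "+"))),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("attributable deaths (%s - %s): %.1f [%.1f, %.1f], %.1f%% of event total; ensemble %d\n",
              x$labels[1], x$labels[2], x$total["mean"], x$total["lo"],
              x$total["hi"], x$fraction_pct["mean"], x$ensemble_size))
  invisible(x)
}

#' Project event mortality with a period-tagged response function
#'
#' Predicts event deaths under a (typically warmed) scenario using
#' coefficient samples from a stated estimation period, enabling the
#' adaptation contrast: the same scenario projected with pre-event versus
#' post-event response functions.
#'
#' @param samples a `coef_samples` whose `period` is set (error otherwise).
#' @inheritParams predict_event_deaths
#' @return a `heat_prediction` carrying the period tag.
#' @export
project_event <- function(samples, scenario, climatology, tbar = NULL) {
  if (is.null(samples$period)) {
    stop("project_event requires period-tagged coefficient samples")
  }
  predict_event_deaths(samples, scenario, climatology, tbar = tbar)
}
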