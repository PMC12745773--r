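# --- regressor-row builders -------------------------------------------------
# Build the temperature-term values of design columns for hypothetical
# temperatures, matched by column name to a coefficient vector. Columns the
# fit dropped as FE-collinear are simply absent and contribute nothing.

g_value <- function(g_info, previous, prev_clim = NULL) {
  switch(g_info$mode,
    previous_level = matrix(previous, ncol = 1),
    previous_anomaly = {
      if (is.null(prev_clim)) {
        stop("previous_anomaly mode needs the previous day's climatological mean")
      }
      matrix(previous - prev_clim, ncol = 1)
    },
    previous_spline = previous_day_transform(previous, "previous_spline",
                                             knot = g_info$knot,
                                             boundary_knots = g_info$boundary_knots),
    stop("no previous-day transform in mode: ", g_info$mode))
}

# Named vector of lag-0 temperature-column values at (current, previous).
lag0_row <- function(coef_names, spec, g_info, current, previous, tbar,
                     prev_clim = NULL) {
  row <- setNames(numeric(length(coef_names)), coef_names)
  comp <- spec$compounding != "none"
  g <- if (comp) g_value(g_info, previous, prev_clim) else NULL
  tp <- current
  for (p in seq_len(spec$poly_order)) {
    set_if <- function(nm, val) {
      if (nm %in% coef_names) row[nm] <<- val
    }
    set_if(sprintf("t_l0_p%d", p), tp)
    if (spec$climate_interaction) set_if(sprintf("t_l0_p%d_x_tbar", p), tp * tbar)
    if (comp) {
      if (ncol(g) == 1) {
        set_if(sprintf("t_l0_p%d_x_prev", p), tp * g[1, 1])
      } else {
        set_if(sprintf("t_l0_p%d_x_prev1", p), tp * g[1, 1])
        set_if(sprintf("t_l0_p%d_x_prev2", p), tp * g[1, 2])
      }
    }
    tp <- tp * current
  }
  row
}

# Named vector over all lags for a focal day, from a newest-first
# temperature history of length L+1 (L+2 under compounding). Controls are
# not part of temperature contrasts and stay zero. clim_hist (same length
# as temps) supplies climatological means for anomaly-mode transforms.
full_row <- function(coef_names, spec, g_info, temps, tbar, clim_hist = NULL) {
  L <- spec$n_lags
  comp <- spec$compounding != "none"
  need <- L + 1 + as.integer(comp)
  if (length(temps) < need) {
    stop("temperature history shorter than required: need ", need,
         " days, got ", length(temps))
  }
  row <- setNames(numeric(length(coef_names)), coef_names)
  for (j in 0:L) {
    Tj <- temps[j + 1]
    g <- NULL
    if (comp) {
      pc <- if (!is.null(clim_hist)) clim_hist[j + 2] else NULL
      g <- g_value(g_info, temps[j + 2], pc)
    }
    tp <- Tj
    for (p in seq_len(spec$poly_order)) {
      nm <- sprintf("t_l%d_p%d", j, p)
      if (nm %in% coef_names) row[nm] <- tp
      if (spec$climate_interaction) {
        nm <- sprintf("t_l%d_p%d_x_tbar", j, p)
        if (nm %in% coef_names) row[nm] <- tp * tbar
      }
      if (comp) {
        if (ncol(g) == 1) {
          nm <- sprintf("t_l%d_p%d_x_prev", j, p)
          if (nm %in% coef_names) row[nm] <- tp * g[1, 1]
        } else {
          for (k in 1:2) {
            nm <- sprintf("t_l%d_p%d_x_prev%d", j, p, k)
            if (nm %in% coef_names) row[nm] <- tp * g[1, k]
          }
        }
      }
      tp <- tp * Tj
    }
  }
  row
}

summarize_pct <- function(pct_draws) {
  list(draws = pct_draws,
       mean = mean(pct_draws),
       lo = unname(quantile(pct_draws, 0.025)),
       hi = unname(quantile(pct_draws, 0.975)))
}

#' Marginal effect of a (current, previous) temperature scenario
#'
#' For each coefficient draw, the difference in the lag-0 temperature terms
#' between the scenario and the reference pair (including climate and
#' compounding interactions), mapped to a percent change in mortality as
#' 100 (exp(delta) - 1). Summaries are the mean and the 2.5th/97.5th
#' percentiles across draws. At scenario = reference the effect is exactly
#' zero for every draw.
#'
#' @param samples a `coef_samples`.
#' @param scenario,reference length-2 numeric `c(current, previous)` deg C;
#'   default reference is two consecutive days at 20 deg C.
#' @param tbar department mean climate at which to evaluate (deg C),
#'   typically the population-weighted average.
#' @param prev_clim climatological mean of the previous day (anomaly-mode
#'   compounding only).
#' @param approximate use the linear approximation 100 x delta instead of
#'   the exact exponential transform (default FALSE).
#' @return list: `draws` (percent change per draw), `mean`, `lo`, `hi`.
#' @export
marginal_effect <- function(samples, scenario, reference = c(20, 20), tbar,
                            prev_clim = NULL, approximate = FALSE) {
  stopifnot(inherits(samples, "coef_samples"))
  cn <- colnames(samples$draws)
  rs <- lag0_row(cn, samples$spec, samples$g_info, scenario[1], scenario[2],
                 tbar, prev_clim)
  rr <- lag0_row(cn, samples$spec, samples$g_info, reference[1], reference[2],
                 tbar, prev_clim)
  d <- as.numeric(samples$draws %*% (rs - rr))
  pct <- if (approximate) 100 * d else 100 * (exp(d) - 1)
  summarize_pct(pct)
}

#' Cumulative (all-lag) effect of a temperature path for one focal day
#'
#' Sums contributions over lags 0..L for a focal day given its realized
#' newest-first temperature history, relative to a reference history, per
#' coefficient draw. Under compounding one extra history day is required.
#' Effects of disjoint perturbations add exactly on the log scale.
#'
#' @param samples a `coef_samples`.
#' @param path,ref_path newest-first temperature histories (deg C) of
#'   length at least L+1 (L+2 under compounding).
#' @param tbar evaluation climate (deg C).
#' @param clim_hist,ref_clim_hist climatological-mean histories aligned
#'   with the paths (anomaly mode only).
#' @inheritParams marginal_effect
#' @return list: `draws` (percent), `mean`, `lo`, `hi`.
#' @export
cumulative_effect <- function(samples, path, ref_path, tbar,
                              clim_hist = NULL, ref_clim_hist = NULL,
                              approximate = FALSE) {
  stopifnot(inherits(samples, "coef_samples"))
  cn <- colnames(samples$draws)
  rs <- full_row(cn, samples$spec, samples$g_info, path, tbar, clim_hist)
  rr <- full_row(cn, samples$spec, samples$g_info, ref_path, tbar,
                 ref_clim_hist)
  d <- as.numeric(samples$draws %*% (rs - rr))
  pct <- if (approximate) 100 * d else 100 * (exp(d) - 1)
  summarize_pct(pct)
}

#' Exposure-response curve over a current-day temperature grid
#'
#' Percent change in mortality at each grid temperature relative to the
#' reference pair, conditional on a previous-day temperature and a climate
#' value, with percentile bands across draws and extrapolation flags
#' (outside the observed current-day range conditional on the previous-day
#' bin, when a support mask is supplied).
#'
#' @param samples a `coef_samples`.
#' @param current_grid numeric grid of current-day temperatures (deg C).
#' @param previous conditioning previous-day temperature (deg C).
#' @param tbar evaluation climate.
#' @param reference reference `c(current, previous)` pair.
#' @param support optional `heat_support` for extrapolation flags.
#' @inheritParams marginal_effect
#' @return data frame: `current_c, previous_c, tbar_c, mean_pct, lo_pct,
#'   hi_pct, extrapolated`.
#' @export
response_curve <- function(samples, current_grid, previous = 20, tbar,
                           reference = c(20, 20), support = NULL,
                           prev_clim = NULL) {
  res <- lapply(current_grid, function(tc) {
    marginal_effect(samples, c(tc, previous), reference, tbar, prev_clim)
  })
  extrap <- rep(NA, length(current_grid))
  if (!is.null(support)) {
    rb <- support$range_by_prev
    bin <- floor(previous / support$bin_width) * support$bin_width
    row <- rb[rb$prev_bin == bin, ]
    extrap <- if (nrow(row) == 1) {
      current_grid < row$min_cur | current_grid > row$max_cur
    } else rep(TRUE, length(current_grid))
  }
  data.frame(current_c = current_grid, previous_c = previous, tbar_c = tbar,
             mean_pct = vapply(res, `[[`, numeric(1), "mean"),
             lo_pct = vapply(res, `[[`, numeric(1), "lo"),
             hi_pct = vapply(res, `[[`, numeric(1), "hi"),
             extrapolated = extrap)
}

#' Two-dimensional compounding surface
#'
#' Mean percent change in mortality for each (previous, current)
#' temperature cell relative to the reference pair (default two
#' consecutive days at 20 deg C), across coefficient draws. Cells outside
#' the supplied support mask carry NA: combinations of days that never
#' occur in the estimation sample are not reported.
#'
#' @param samples a `coef_samples`.
#' @param prev_grid,cur_grid numeric grids (deg C).
#' @param tbar evaluation climate.
#' @param reference reference pair; must lie inside both grids' ranges.
#' @param support optional `heat_support` mask.
#' @inheritParams marginal_effect
#' @return a `heat_surface`: `prev_grid`, `cur_grid`, `mean_pct` matrix
#'   (previous x current), `supported` logical matrix.
#' @export
compounding_surface <- function(samples, prev_grid, cur_grid, tbar,
                                reference = c(20, 20), support = NULL,
                                prev_clim = NULL) {
  stopifnot(inherits(samples, "coef_samples"))
  if (reference[1] < min(cur_grid) || reference[1] > max(cur_grid) ||
      reference[2] < min(prev_grid) || reference[2] > max(prev_grid)) {
    stop("reference pair outside the evaluation grid")
  }
  cn <- colnames(samples$draws)
  rr <- lag0_row(cn, samples$spec, samples$g_info, reference[1], reference[2],
                 tbar, prev_clim)
  cells <- expand.grid(prev = prev_grid, cur = cur_grid)
  C <- t(vapply(seq_len(nrow(cells)), function(i) {
    lag0_row(cn, samples$spec, samples$g_info, cells$cur[i], cells$prev[i],
             tbar, prev_clim) - rr
  }, numeric(length(cn))))
  mean_log <- as.numeric(C %*% colMeans(samples$draws))
  # mean percent across draws requires the draw-level nonlinearity
  pct_mean <- colMeans(100 * (exp(samples$draws %*% t(C)) - 1))
  M <- matrix(pct_mean, length(prev_grid), length(cur_grid),
              dimnames = list(prev_grid, cur_grid))
  supp <- matrix(TRUE, length(prev_grid), length(cur_grid))
  if (!is.null(support)) {
    supp <- outer(prev_grid, cur_grid,
                  function(p, c) support_lookup(support, p, c))
    M[!supp] <- NA_real_
  }
  structure(list(prev_grid = prev_grid, cur_grid = cur_grid,
                 mean_pct = M, supported = supp, tbar = tbar,
                 reference = reference, mean_log = mean_log),
            class = "heat_surface")
}

#' Export a compounding surface to CSV
#'
#' Long format: `previous_c, current_c, tbar_c, mean_pct, supported`.
#'
#' @param surface a `heat_surface`.
#' @param path output path.
#' @export
write_surface <- function(surface, path) {
  g <- expand.grid(previous_c = surface$prev_grid,
                   current_c = surface$cur_grid)
  g$tbar_c <- surface$tbar
  g$mean_pct <- as.numeric(surface$mean_pct)
  g$supported <- as.logical(surface$supported)
  write.csv(g, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
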