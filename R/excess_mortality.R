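#' Fit the seasonal-and-trend mortality baseline
#'
#' Least-squares fit of the additive two-way model for log mortality rates:
#' a department-by-year level term plus a department-by-day-of-year
#' seasonal term, letting each department carry its own seasonal cycle and
#' long-term trend. Solved by alternating within-group means per
#' department (the exact OLS solution for a saturated two-way layout).
#' The level ambiguity of the decomposition is fixed by constraining each
#' department's seasonal terms to mean zero over calendar days; predictions
#' are invariant to this choice.
#'
#' @param panel a `heat_panel`.
#' @param period years used for fitting (default: all).
#' @param tol,maxit convergence controls for the alternating means.
#' @return a `heat_baseline`: data frames `mu` (department, year, value)
#'   and `delta` (department, cday, value), fit metadata.
#' @export
fit_baseline <- function(panel, period = NULL, tol = 1e-11, maxit = 10000) {
  stopifnot(inherits(panel, "heat_panel"))
  years <- expand_period(period, panel$year)
  sub <- panel[panel$year %in% years, ]
  if (length(unique(sub$year)) < 2) stop("baseline requires at least 2 years")
  zero <- sub$deaths <= 0
  n_zero <- sum(zero)
  sub <- sub[!zero, ]
  y <- log(sub$deaths / sub$population * 1e5)

  mu_list <- list()
  delta_list <- list()
  resid <- numeric(nrow(sub))
  for (d in unique(sub$department_id)) {
    sel <- which(sub$department_id == d)
    yy <- y[sel]
    fy <- factor(sub$year[sel])
    fd <- factor(sub$cday[sel])
    if (nlevels(fd) < length(unique(sub$cday))) {
      miss <- setdiff(unique(sub$cday), levels(fd))
      if (length(miss) > 0) {
        stop("department ", d, " has no usable observations for calendar day(s): ",
             paste(head(miss, 5), collapse = ", "))
      }
    }
    mu <- tapply(yy, fy, mean)
    delta <- rep(0, nlevels(fd))
    names(delta) <- levels(fd)
    for (it in seq_len(maxit)) {
      mu_new <- tapply(yy - delta[as.character(fd)], fy, mean)
      delta_new <- tapply(yy - mu_new[as.character(fy)], fd, mean)
      chg <- max(abs(mu_new - mu), abs(delta_new - delta))
      mu <- mu_new
      delta <- delta_new
      if (chg < tol) break
    }
    if (chg >= tol) stop("baseline fit did not converge; last change ", chg)
    shift <- mean(delta)
    delta <- delta - shift
    mu <- mu + shift
    mu_list[[d]] <- data.frame(department_id = d,
                               year = as.integer(names(mu)),
                               mu = as.numeric(mu))
    delta_list[[d]] <- data.frame(department_id = d,
                                  cday = as.integer(names(delta)),
                                  delta = as.numeric(delta))
    resid[sel] <- yy - mu[as.character(fy)] - delta[as.character(fd)]
  }
  structure(list(mu = do.call(rbind, mu_list),
                 delta = do.call(rbind, delta_list),
                 period = range(years), n_obs = nrow(sub),
                 n_zero_excluded = n_zero,
                 sigma2 = mean(resid^2)),
            class = "heat_baseline")
}

#' Predict baseline log mortality rates
#'
#' @param baseline a `heat_baseline`.
#' @param department_id,year,cday vectors of equal length.
#' @return predicted log rate (deaths per 100,000 per day, log scale);
#'   errors on cells outside the fit.
#' @export
predict_baseline <- function(baseline, department_id, year, cday) {
  mu <- baseline$mu$mu[match(paste(department_id, year),
                             paste(baseline$mu$department_id, baseline$mu$year))]
  de <- baseline$delta$delta[match(paste(department_id, cday),
                                   paste(baseline$delta$department_id,
                                         baseline$delta$cday))]
  if (anyNA(mu) || anyNA(de)) {
    bad <- which(is.na(mu) | is.na(de))
    stop("baseline has no term for ",
         paste(head(paste(department_id[bad], year[bad], cday[bad]), 5),
               collapse = "; "))
  }
  mu + de
}

#' Excess deaths relative to the baseline
#'
#' For each department-day in the window, observed deaths minus the
#' baseline-expected count (exp of the predicted log rate, converted to
#' deaths via population / 100,000). The aggregate is the sum over the
#' window; sub-window excesses are additive.
#'
#' @param panel a `heat_panel`.
#' @param baseline a `heat_baseline`.
#' @param dates Date vector defining the window.
#' @param departments optional department subset.
#' @return a list: `table` (per department-day: observed, expected, excess)
#'   and `total`.
#' @export
excess_deaths <- function(panel, baseline, dates, departments = NULL) {
  sel <- panel$date %in% dates
  if (!is.null(departments)) sel <- sel & panel$department_id %in% departments
  sub <- panel[sel, ]
  want <- length(dates) * length(departments %||% unique(panel$department_id))
  if (nrow(sub) < want) stop("window cells missing from panel")
  pred <- predict_baseline(baseline, sub$department_id, sub$year, sub$cday)
  expected <- exp(pred) * sub$population / 1e5
  tab <- data.frame(department_id = sub$department_id, date = sub$date,
                    observed_deaths = sub$deaths,
                    expected_deaths = expected,
                    excess_deaths = sub$deaths - expected,
                    stringsAsFactors = FALSE)
  list(table = tab, total = sum(tab$excess_deaths))
}

#' @rdname excess_deaths
#' @param excess result of `excess_deaths`.
#' @param path output CSV path.
#' @export
write_excess <- function(excess, path) {
  out <- excess$table
  out$date <- format(out$date, "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
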