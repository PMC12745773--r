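#' Department-day mortality panels
#'
#' A `heat_panel` is a data frame with one row per department-day holding
#' daily death counts, population, and weather. Canonical columns:
#' `department_id` (character), `date` (Date), `deaths`, `population`,
#' `tmean_c` (daily mean temperature, deg C), `rh_pct` (daily mean relative
#' humidity, %), `precip_mm` (daily accumulated precipitation, mm). Derived
#' columns `year` and `cday` (calendar-day index, see [calendar_day()]) are
#' added on construction; `tbar_c` (per-department long-term mean
#' temperature) is added by [with_department_climate()]. Synthetic panels
#' carry an `expected_deaths` column (the generator's exact expected count).
#'
#' @param x data frame with the canonical columns.
#' @param integer_deaths require integral death counts (default TRUE; the
#'   generator's `expected_value` mode stores exact expectations, which are
#'   not integral, and sets this FALSE).
#' @return validated `heat_panel` data frame.
#' @export
as_heat_panel <- function(x, integer_deaths = TRUE) {
  required <- c("department_id", "date", "deaths", "population",
                "tmean_c", "rh_pct", "precip_mm")
  miss <- setdiff(required, names(x))
  if (length(miss) > 0) {
    stop("panel schema error: missing column(s): ", paste(miss, collapse = ", "))
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  x$department_id <- as.character(x$department_id)
  if (!inherits(x$date, "Date")) {
    d <- as.Date(as.character(x$date), format = "%Y-%m-%d")
    if (anyNA(d)) {
      stop("panel parse error: unparseable date at row(s): ",
           paste(head(which(is.na(d)), 5), collapse = ", "))
    }
    x$date <- d
  }
  for (col in c("deaths", "population", "tmean_c", "rh_pct", "precip_mm")) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
      if (anyNA(vn) && !anyNA(v)) {
        stop("panel parse error: non-numeric '", col, "' at row(s): ",
             paste(head(which(is.na(vn)), 5), collapse = ", "))
      }
      v <- vn
      x[[col]] <- v
    }
    if (anyNA(v)) {
      stop("panel integrity error: missing values in '", col, "' at row(s): ",
           paste(head(which(is.na(v)), 5), collapse = ", "))
    }
  }
  if (any(x$population <= 0)) {
    stop("panel integrity error: non-positive population at row(s): ",
         paste(head(which(x$population <= 0), 5), collapse = ", "))
  }
  if (any(x$deaths < 0)) {
    stop("panel integrity error: negative deaths at row(s): ",
         paste(head(which(x$deaths < 0), 5), collapse = ", "))
  }
  if (integer_deaths && any(abs(x$deaths - round(x$deaths)) > 1e-8)) {
    stop("panel integrity error: non-integral deaths at row(s): ",
         paste(head(which(abs(x$deaths - round(x$deaths)) > 1e-8), 5),
               collapse = ", "))
  }
  key <- paste(x$department_id, x$date)
  if (anyDuplicated(key)) {
    stop("panel integrity error: duplicate (department, date) key: ",
         key[anyDuplicated(key)])
  }
  x <- x[order(x$department_id, x$date), , drop = FALSE]
  rownames(x) <- NULL
  x$year <- as.integer(format(x$date, "%Y"))
  x$cday <- calendar_day(x$date)
  if (!is.null(x$tbar_c)) {
    rng <- tapply(x$tbar_c, x$department_id, function(v) diff(range(v)))
    if (any(rng > 1e-9)) {
      stop("panel integrity error: tbar_c varies within department(s): ",
           paste(names(rng)[rng > 1e-9], collapse = ", "))
    }
  }
  class(x) <- c("heat_panel", "data.frame")
  x
}

#' Calendar-day index of a date
#'
#' Maps a date to an index 1..366 aligned on the calendar (month, day), with
#' the leap-year numbering used in both common and leap years: 1 Mar is 61
#' always, and 60 (29 Feb) occurs only in leap years. This makes "the same
#' calendar day" comparable across years, and climatologies for 29 Feb are
#' built from leap years only.
#'
#' @param date Date vector.
#' @return integer vector in 1..366.
#' @export
calendar_day <- function(date) {
  md <- format(date, "%m-%d")
  ref <- seq(as.Date("2000-01-01"), as.Date("2000-12-31"), by = "day")
  idx <- setNames(seq_along(ref), format(ref, "%m-%d"))
  unname(idx[md])
}

#' Read or write a department-day panel CSV
#'
#' The CSV dialect has header columns `department_id, date, deaths,
#' population, tmean_c, rh_pct, precip_mm` (ISO-8601 dates, UTF-8). Extra
#' numeric columns (e.g. `tbar_c`, `expected_deaths`) round-trip unchanged.
#'
#' @param path file path.
#' @param integer_deaths passed to [as_heat_panel()].
#' @param departments optional include-list of department ids (e.g. to
#'   restrict an analysis to a contiguous subset of regions); other
#'   departments are dropped before validation.
#' @return `read_panel`: a validated `heat_panel`.
#' @export
read_panel <- function(path, integer_deaths = TRUE, departments = NULL) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(departments)) {
    x <- x[as.character(x$department_id) %in% departments, , drop = FALSE]
    if (nrow(x) == 0) stop("no rows left after department filter")
  }
  as_heat_panel(x, integer_deaths = integer_deaths)
}

#' @rdname read_panel
#' @param panel a `heat_panel`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "heat_panel"))
  out <- as.data.frame(panel)
  out$year <- NULL
  out$cday <- NULL
  out$date <- format(out$date, "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Long-term mean temperature per department
#'
#' Unweighted mean of daily mean temperature over all days of the period,
#' per department: the climate moderator interacted with the temperature
#' polynomial in the exposure-response models.
#'
#' @param panel a `heat_panel`.
#' @param period integer year range (vector of years, or c(first, last)).
#' @return named numeric vector (deg C) indexed by department.
#' @export
department_mean_temperature <- function(panel, period = NULL) {
  stopifnot(inherits(panel, "heat_panel"))
  years <- expand_period(period, panel$year)
  sub <- panel[panel$year %in% years, ]
  all_depts <- unique(panel$department_id)
  absent <- setdiff(all_depts, unique(sub$department_id))
  if (length(absent) > 0) {
    stop("no records in period for department(s): ",
         paste(absent, collapse = ", "))
  }
  tm <- tapply(sub$tmean_c, sub$department_id, mean)
  setNames(as.numeric(tm), names(tm))
}

#' Attach per-department long-term mean temperature
#'
#' @param panel a `heat_panel`.
#' @param period years over which to average (default: all panel years).
#' @param values optional named vector of supplied means, overriding the
#'   computed ones.
#' @return the panel with a `tbar_c` column.
#' @export
with_department_climate <- function(panel, period = NULL, values = NULL) {
  tbar <- if (is.null(values)) department_mean_temperature(panel, period) else values
  miss <- setdiff(unique(panel$department_id), names(tbar))
  if (length(miss) > 0) stop("tbar_c missing for department(s): ",
                             paste(miss, collapse = ", "))
  panel$tbar_c <- unname(tbar[panel$department_id])
  panel
}

#' Population-weighted daily average of a panel variable
#'
#' For each selected day, sum(pop_i * x_i) / sum(pop_i) across departments.
#' Invariant to rescaling all populations by a positive constant.
#'
#' @param panel a `heat_panel`.
#' @param variable column name (default `tmean_c`).
#' @param dates optional Date vector restricting the days.
#' @return data frame with columns `date`, `value`.
#' @export
population_weighted_average <- function(panel, variable = "tmean_c",
                                        dates = NULL) {
  stopifnot(inherits(panel, "heat_panel"), variable %in% names(panel))
  sub <- if (is.null(dates)) panel else panel[panel$date %in% dates, ]
  if (nrow(sub) == 0) stop("empty selection for population-weighted average")
  num <- tapply(sub$population * sub[[variable]], sub$date, sum)
  den <- tapply(sub$population, sub$date, sum)
  data.frame(date = as.Date(names(num)), value = unname(num / den),
             row.names = NULL)
}

#' Population-weighted mean department climate
#'
#' Single evaluation climate used when presenting response functions "for
#' the average department": departments' long-term mean temperatures
#' weighted by their mean populations.
#'
#' @param panel a `heat_panel` with `tbar_c`.
#' @return scalar deg C.
#' @export
population_weighted_tbar <- function(panel) {
  stopifnot(inherits(panel, "heat_panel"))
  if (is.null(panel$tbar_c)) stop("panel lacks tbar_c; call with_department_climate()")
  pop <- tapply(panel$population, panel$department_id, mean)
  tb <- tapply(panel$tbar_c, panel$department_id, mean)
  sum(pop * tb) / sum(pop)
}

#' Day-of-calendar climatology of temperature and deaths
#'
#' For each (department, calendar day), the mean over reference years of
#' daily mean temperature and of daily death counts. 29 Feb entries average
#' leap years only (calendar-date matching).
#'
#' @param panel a `heat_panel`.
#' @param period reference years (vector or c(first, last)).
#' @return `heat_climatology`: data frame `department_id, cday,
#'   tmean_clim_c, deaths_clim` with the reference period as attribute.
#' @export
build_climatology <- function(panel, period) {
  stopifnot(inherits(panel, "heat_panel"))
  years <- expand_period(period, panel$year)
  if (!all(years %in% panel$year)) {
    stop("reference period years absent from panel: ",
         paste(setdiff(years, panel$year), collapse = ", "))
  }
  sub <- panel[panel$year %in% years, ]
  key <- interaction(sub$department_id, sub$cday, drop = TRUE)
  agg <- data.frame(
    department_id = tapply(sub$department_id, key, `[`, 1),
    cday = as.integer(tapply(sub$cday, key, `[`, 1)),
    tmean_clim_c = as.numeric(tapply(sub$tmean_c, key, mean)),
    deaths_clim = as.numeric(tapply(sub$deaths, key, mean)),
    row.names = NULL
  )
  agg <- agg[order(agg$department_id, agg$cday), ]
  rownames(agg) <- NULL
  attr(agg, "period") <- range(years)
  class(agg) <- c("heat_climatology", "data.frame")
  agg
}

#' Look up climatology values for (department, calendar day) pairs
#'
#' @param clim a `heat_climatology`.
#' @param department_id,cday vectors of equal length.
#' @param what `"tmean_clim_c"` or `"deaths_clim"`.
#' @return numeric vector; errors if any pair is missing.
#' @export
climatology_lookup <- function(clim, department_id, cday,
                               what = c("tmean_clim_c", "deaths_clim")) {
  what <- match.arg(what)
  key <- paste(clim$department_id, clim$cday)
  q <- paste(department_id, cday)
  idx <- match(q, key)
  if (anyNA(idx)) {
    stop("climatology gap: no entry for ",
         paste(head(unique(q[is.na(idx)]), 5), collapse = "; "))
  }
  clim[[what]][idx]
}

#' @rdname build_climatology
#' @param clim a `heat_climatology`.
#' @param path file path (CSV: department_id, day_of_year, tmean_clim_c,
#'   deaths_clim).
#' @export
write_climatology <- function(clim, path) {
  out <- data.frame(department_id = clim$department_id,
                    day_of_year = clim$cday,
                    tmean_clim_c = clim$tmean_clim_c,
                    deaths_clim = clim$deaths_clim)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname build_climatology
#' @export
read_climatology <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("department_id", "day_of_year", "tmean_clim_c", "deaths_clim")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) stop("climatology schema error: missing ",
                             paste(miss, collapse = ", "))
  out <- data.frame(department_id = as.character(x$department_id),
                    cday = as.integer(x$day_of_year),
                    tmean_clim_c = x$tmean_clim_c,
                    deaths_clim = x$deaths_clim)
  class(out) <- c("heat_climatology", "data.frame")
  out
}

# Interpret a period argument: NULL -> all years present; length-2 -> range.
expand_period <- function(period, panel_years) {
  if (is.null(period)) return(sort(unique(panel_years)))
  period <- as.integer(period)
  if (length(period) == 2 && period[2] >= period[1]) {
    period <- period[1]:period[2]
  }
  if (!any(period %in% panel_years)) {
    stop("period does not overlap panel years")
  }
  sort(unique(period))
}
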