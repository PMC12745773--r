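#' Default pipeline configuration
#'
#' A nested list configuring the full synthetic analysis: generator
#' settings, event window, estimation periods (which must not include the
#' event year, so the event prediction is out-of-sample), counterfactual
#' scenario deltas (deg C, region-wide, labelled by annual GMT anomaly),
#' model specifications, number of coefficient draws, and the master seed
#' from which all stage seeds are derived.
#'
#' @param master_seed integer master seed.
#' @param output_dir output directory.
#' @return a `pipeline_config` list.
#' @export
default_pipeline_config <- function(master_seed = 1L, output_dir = "heatmort_out") {
  structure(list(
    master_seed = as.integer(master_seed),
    output_dir = output_dir,
    n_samples = 500,
    generator = list(n_departments = 10, years = 1980:2012,
                     noise = "poisson",
                     adaptation = list(year = 2004, factor = 0.5)),
    event = list(year = 2003, start_cday = 214, end_cday = 227,
                 peak_uplift = 8, profile = "triangular"),
    periods = list(pre = c(1980, 2002), post = c(2004, 2012)),
    scenarios = list("GMT+0.0" = -1.2, "GMT+1.5" = 0.9, "GMT+2.0" = 1.5),
    model = list(poly_order = 4, n_lags = 5,
                 compounding = "previous_level"),
    log_level = "info"
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys present in the file override the defaults; `config_show()` prints
#' the fully resolved configuration.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  for (k in names(user)) {
    cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      modifyList(cfg[[k]], user[[k]])
    } else user[[k]]
  }
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
config_show <- function(config = default_pipeline_config()) {
  cat(yaml::as.yaml(lapply(unclass(config), function(x) x)))
  invisible(config)
}

validate_pipeline_config <- function(cfg) {
  ev <- cfg$event$year
  for (p in names(cfg$periods)) {
    pr <- cfg$periods[[p]]
    if (ev >= pr[1] && ev <= pr[2]) {
      stop("configuration error: estimation period '", p,
           "' includes the event year ", ev,
           "; event prediction must be out-of-sample")
    }
  }
  if (!is.null(cfg$generator$years)) {
    yrs <- cfg$generator$years
    if (length(yrs) == 2) yrs <- yrs[1]:yrs[2]
    if (!(ev %in% yrs)) stop("configuration error: event year outside generator years")
  }
  invisible(cfg)
}

pipeline_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message("[heatmort] ", ...)
}

write_manifest <- function(dir, files, cfg, extra = list()) {
  hashes <- tools::md5sum(files)
  manifest <- c(list(
    config = lapply(unclass(cfg), function(x) x),
    master_seed = cfg$master_seed,
    r_version = as.character(getRversion()),
    files = lapply(seq_along(files), function(i) {
      list(path = basename(files[i]), md5 = unname(hashes[i]))
    })), extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Simulate a panel, event, and delta tables from a configuration
#'
#' Generates the synthetic panel, injects the configured heat-wave event,
#' builds the counterfactual delta tables, and writes `panel.csv` (the
#' event panel), `panel_noevent.csv`, `deltas.csv`, `truth.json` (true
#' coefficients and the closed-form true event excess), and a manifest
#' with content hashes. Re-running with the same configuration and seed
#' reproduces identical outputs.
#'
#' @param config a `pipeline_config`.
#' @param overwrite allow writing into an existing output directory.
#' @return invisibly, a list with the panels, event, deltas and paths.
#' @export
run_simulate <- function(config = default_pipeline_config(),
                         overwrite = FALSE) {
  validate_pipeline_config(config)
  if (is.null(config$generator)) stop("configuration error: generator settings absent")
  dir <- config$output_dir
  if (dir.exists(dir) && !overwrite &&
      length(list.files(dir)) > 0) {
    stop("output directory not empty (use overwrite = TRUE): ", dir)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen_args <- config$generator
  gen_args$seed <- substream_seed(config$master_seed, "generate")
  gcfg <- do.call(generator_config, gen_args)
  pipeline_log(config, "simulating panel: ", gcfg$n_departments,
               " departments x ", length(gcfg$years), " years")
  panel0 <- generate_panel(gcfg)
  ev <- config$event
  espec <- event_spec(ev$year, ev$start_cday, ev$end_cday, ev$peak_uplift,
                      profile = ev$profile %||% "constant")
  inj <- inject_event(panel0, espec)
  win <- sort(unique(inj$event_days$date))
  deltas <- do.call(rbind, lapply(names(config$scenarios), function(lb) {
    make_delta_series(win, setNames(list(config$scenarios[[lb]]), lb))
  }))
  true_excess <- true_event_excess(panel0, inj$panel)

  p_panel <- file.path(dir, "panel.csv")
  p_panel0 <- file.path(dir, "panel_noevent.csv")
  p_deltas <- file.path(dir, "deltas.csv")
  p_truth <- file.path(dir, "truth.json")
  write_panel(inj$panel, p_panel)
  write_panel(panel0, p_panel0)
  dl <- deltas
  dl$date <- format(dl$date, "%Y-%m-%d")
  write.csv(dl, p_deltas, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(
    beta_main = gcfg$beta_main, beta_comp = gcfg$beta_comp,
    beta_clim = gcfg$beta_clim, t_ref = gcfg$t_ref,
    tbar_ref = gcfg$tbar_ref, adaptation = gcfg$adaptation,
    true_event_excess = true_excess,
    event_window = format(win, "%Y-%m-%d")
  ), p_truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(p_panel, p_panel0, p_deltas, p_truth)
  mpath <- write_manifest(dir, files, config)
  pipeline_log(config, "true event excess: ", round(true_excess, 1),
               " deaths; outputs in ", dir)
  invisible(list(panel = inj$panel, panel_noevent = panel0,
                 event_days = inj$event_days, deltas = deltas,
                 generator = gcfg, true_event_excess = true_excess,
                 paths = c(files, mpath)))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the analysis end to end on simulated data: (1) fit the
#' standard exposure-response model on the pre-event period and predict
#' the event out-of-sample against climatology; (2) fit the compounding
#' model and repeat; (3) attribute event deaths to the factual-minus-
#' counterfactual temperature difference using the configured deltas;
#' (4) refit both models on the post-event period; (5) project the event
#' under warmed scenarios with the pre- and post-period response
#' functions. Writes curves, surface, excess table, attribution summary
#' JSON, and a manifest.
#'
#' @param config a `pipeline_config`.
#' @param overwrite allow writing into a non-empty output directory.
#' @return a list of stage results (fits, predictions, attribution,
#'   projections, summary).
#' @export
run_full <- function(config = default_pipeline_config(), overwrite = FALSE) {
  validate_pipeline_config(config)
  dir <- config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- run_simulate(config, overwrite = TRUE)
  panel <- sim$panel
  pre <- config$periods$pre
  post <- config$periods$post
  win <- sort(unique(sim$event_days$date))

  panel <- with_department_climate(panel, period = pre)
  clim <- build_climatology(panel, pre)
  tbar_eval <- population_weighted_tbar(panel)

  m <- config$model
  spec_std <- model_spec(poly_order = m$poly_order, n_lags = m$n_lags,
                         compounding = "none")
  spec_cmp <- model_spec(poly_order = m$poly_order, n_lags = m$n_lags,
                         compounding = m$compounding)

  pipeline_log(config, "stage 1-2: fitting pre-period models (",
               pre[1], "-", pre[2], ")")
  fits <- list()
  samples <- list()
  for (nm in c("std", "cmp")) {
    spec <- if (nm == "std") spec_std else spec_cmp
    des <- build_design(panel, spec, climatology = clim, period = pre)
    fits[[paste0(nm, "_pre")]] <- fit_erf(des, period = pre)
    samples[[paste0(nm, "_pre")]] <- sample_coefficients(
      fits[[paste0(nm, "_pre")]], n = config$n_samples,
      seed = substream_seed(config$master_seed, paste0("samples_", nm, "_pre")))
  }

  pipeline_log(config, "stage 1: excess mortality baseline")
  baseline <- fit_baseline(panel)
  excess <- excess_deaths(panel, baseline, win)

  pipeline_log(config, "stage 3: event prediction and attribution")
  scen_obs <- scenario_from_panel(panel, win, spec_cmp)
  pred_obs <- list(
    std = predict_event_deaths(samples$std_pre, scen_obs, clim),
    cmp = predict_event_deaths(samples$cmp_pre, scen_obs, clim))
  cf_lab <- names(config$scenarios)[1]
  scen_cf <- apply_deltas(scen_obs,
                          data.frame(date = win,
                                     delta_c = rep_len(config$scenarios[[cf_lab]],
                                                       length(win))),
                          label = cf_lab)
  pred_cf <- predict_event_deaths(samples$cmp_pre, scen_cf, clim)
  attribution <- attributable_deaths(pred_obs$cmp, pred_cf)

  pipeline_log(config, "stage 4: post-period refits")
  projections <- list()
  post_ok <- !is.null(post) && post[2] > post[1]
  if (post_ok) {
    for (nm in c("std", "cmp")) {
      spec <- if (nm == "std") spec_std else spec_cmp
      des <- build_design(panel, spec, climatology = clim, period = post)
      fits[[paste0(nm, "_post")]] <- fit_erf(des, period = post)
      samples[[paste0(nm, "_post")]] <- sample_coefficients(
        fits[[paste0(nm, "_post")]], n = config$n_samples,
        seed = substream_seed(config$master_seed, paste0("samples_", nm, "_post")))
    }
    pipeline_log(config, "stage 5: warmed-scenario projections")
    warm_labels <- names(config$scenarios)[-1]
    for (lb in warm_labels) {
      scen_w <- apply_deltas(scen_obs,
                             data.frame(date = win,
                                        delta_c = rep_len(config$scenarios[[lb]],
                                                          length(win))),
                             label = lb)
      projections[[paste0("pre_", lb)]] <-
        project_event(samples$cmp_pre, scen_w, clim)
      projections[[paste0("post_", lb)]] <-
        project_event(samples$cmp_post, scen_w, clim)
    }
  }

  pre_panel <- panel[panel$year >= pre[1] & panel$year <= pre[2], ]
  class(pre_panel) <- c("heat_panel", "data.frame")
  supp <- support_mask(pre_panel)
  curve <- response_curve(samples$cmp_pre, seq(-5, 35, by = 1),
                          previous = 20, tbar = tbar_eval, support = supp)
  surface <- compounding_surface(samples$cmp_pre,
                                 prev_grid = seq(0, 35, by = 1),
                                 cur_grid = seq(0, 35, by = 1),
                                 tbar = tbar_eval, support = supp)

  p_curve <- file.path(dir, "curve.csv")
  write.csv(curve, p_curve, row.names = FALSE, quote = FALSE)
  p_surface <- file.path(dir, "surface.csv")
  write_surface(surface, p_surface)
  p_excess <- file.path(dir, "excess.csv")
  write_excess(excess, p_excess)

  summary <- list(
    event_window = format(range(win), "%Y-%m-%d"),
    excess_deaths = excess$total,
    true_event_excess = sim$true_event_excess,
    predicted_deaths_standard = as.list(summarize_draws(prediction_totals(pred_obs$std))),
    predicted_deaths_compounding = as.list(summarize_draws(prediction_totals(pred_obs$cmp))),
    attributable_deaths = as.list(attribution$total),
    attributable_fraction_pct = as.list(attribution$fraction_pct))
  if (post_ok && length(projections) > 0) {
    summary$projections <- lapply(projections, function(p) {
      as.list(summarize_draws(prediction_totals(p)))
    })
  }
  p_summary <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, p_summary, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(p_curve, p_surface, p_excess, p_summary)
  write_manifest(dir, files, config,
                 extra = list(stages = c("simulate", "fit_pre", "excess",
                                         "attribute",
                                         if (post_ok) c("fit_post", "project"))))
  pipeline_log(config, "done; summary in ", p_summary)
  list(fits = fits, samples = samples, baseline = baseline,
       excess = excess, predictions = pred_obs,
       attribution = attribution, projections = projections,
       surface = surface, curve = curve, summary = summary,
       sim = sim, climatology = clim, tbar_eval = tbar_eval)
}
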