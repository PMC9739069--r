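# End-to-end orchestration of the four-step route: (1) fit per-class
# logistic suitability on drivers, (2) calibrate the Markov matrix on the
# first observed interval and validate the CA simulation against the last
# observed map, (3) forecast one step beyond the record, (4) account
# biocapacity and landscape metrics for every date.

#' Resolve a scenario-like argument into grids + drivers
#' @noRd
as_pipeline_inputs <- function(x) {
  if (inherits(x, "lulc_scenario"))
    return(list(grids = x$grids, drivers = x$drivers))
  if (is.list(x) && !is.null(x$grids) && !is.null(x$drivers))
    return(list(grids = x$grids, drivers = x$drivers))
  stop("expected an `lulc_scenario` or a list with $grids and $drivers")
}

#' Validation leg: calibrate on t0 -> t1, simulate and score t2
#'
#' Estimates the transition matrix from the first interval, fits suitability
#' models at t1, allocates t1 forward with the CA, and cross-validates the
#' simulated map against the observed t2: confusion matrix, Kappa (with
#' qualitative band) and per-class ROC of the suitability fits.
#'
#' @param x An `lulc_scenario` or list with `$grids` (three dated
#'   [lulc_grid]s) and `$drivers` (a standardized `driver_stack`).
#' @param n_per_class Sampling size per class for the logistic fits.
#' @param ca A [ca_config()].
#' @param seed Integer seed for sampling (and CA tie-breaking if random).
#' @return List: `transition`, `models`, `roc` (named per class), `atlas`,
#'   `simulated`, `confusion`, `kappa`, `seed`.
#' @export
run_validation_leg <- function(x, n_per_class = 5000L, ca = ca_config(),
                               seed = 1L) {
  inp <- as_pipeline_inputs(x)
  if (length(inp$grids) < 3L)
    stop("validation needs three dated maps; with two, ",
         "use run_forecast_leg()")
  t0 <- inp$grids[[1]]; t1 <- inp$grids[[2]]; t2 <- inp$grids[[3]]
  trans <- estimate_transition(t0, t1)
  obs <- sample_observations(t1, inp$drivers, n_per_class, seed = seed)
  models <- fit_suitability(obs, seed = seed)
  atlas <- predict_suitability(models, inp$drivers, reference = t1)
  sim <- simulate_ca(t1, atlas, trans, ca, label = t2$label)
  cm <- cross_tabulate(t2, sim)
  kap <- kappa_statistic(cm)
  list(transition = trans, models = models,
       roc = atlas_roc(atlas, t1),
       atlas = atlas, simulated = sim, confusion = cm, kappa = kap,
       seed = seed)
}

#' Forecast leg: calibrate on t1 -> t2, simulate one step beyond
#'
#' Estimates the transition matrix from the most recent observed interval,
#' refits suitability at the latest observed date, allocates one step ahead,
#' and derives area tables, biocapacity reports with trend, and landscape
#' metric reports with a first-to-last change table.
#'
#' @inheritParams run_validation_leg
#' @param horizon_label Label (year) of the forecast map.
#' @param factors Biocapacity factor table ([bc_factors()]); if the horizon
#'   epoch is missing from it, the latest available epoch is used with a
#'   warning.
#' @param connectivity Patch connectivity for the metric reports.
#' @return List: `transition`, `models`, `roc`, `forecast` ([lulc_grid]),
#'   `areas` (per-date area tables), `bc` ([bc_timeseries()] output),
#'   `metrics` (per-date `metrics_report`s), `metrics_change`, `seed`.
#' @export
run_forecast_leg <- function(x, horizon_label = "2030",
                             n_per_class = 5000L, ca = ca_config(),
                             factors = bc_factors(), connectivity = 8L,
                             seed = 1L) {
  inp <- as_pipeline_inputs(x)
  ng <- length(inp$grids)
  if (ng < 2L) stop("forecast needs at least two dated maps")
  t1 <- inp$grids[[ng - 1L]]; t2 <- inp$grids[[ng]]
  trans <- estimate_transition(t1, t2)
  obs <- sample_observations(t2, inp$drivers, n_per_class, seed = seed)
  models <- fit_suitability(obs, seed = seed)
  atlas <- predict_suitability(models, inp$drivers, reference = t2)
  sim <- simulate_ca(t2, atlas, trans, ca, label = horizon_label)
  all_grids <- c(inp$grids, list(sim))
  if (!horizon_label %in% factors$epoch) {
    latest <- as.character(max(as.numeric(unique(factors$epoch))))
    warning("no biocapacity factors for epoch '", horizon_label,
            "'; using epoch '", latest, "'")
    add <- factors[factors$epoch == latest, ]
    add$epoch <- horizon_label
    factors <- rbind(factors, add)
  }
  bc <- bc_timeseries(all_grids, factors)
  mets <- lapply(all_grids, metrics_report, connectivity = connectivity)
  names(mets) <- vapply(all_grids, function(g) g$label, character(1))
  list(transition = trans, models = models,
       roc = atlas_roc(atlas, t2),
       forecast = sim,
       areas = lapply(all_grids, class_areas),
       bc = bc, metrics = mets,
       metrics_change = metrics_change(mets[[1]], mets[[length(mets)]]),
       seed = seed)
}

#' FNV-1a hash of a configuration (hex string)
#' @noRd
config_hash <- function(cfg) {
  bytes <- utf8ToInt(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                      force = TRUE, digits = NA))
  h <- 2166136261
  for (b in bytes) h <- ((h + b) * 16777619) %% 2147483647
  sprintf("%08x", h)
}

#' Write a forecast bundle to disk
#'
#' Writes the forecast map (ASCII grid + sidecar), transition model and
#' suitability models as JSON, biocapacity and metrics tables as CSV, and a
#' run log carrying the seed and a hash of the configuration, so reruns are
#' checkable file by file.
#'
#' @param bundle Output of [run_forecast_leg()] (optionally with a
#'   `$validation` element from [run_validation_leg()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_forecast_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(seed = bundle$seed,
                config_hash = config_hash(list(seed = bundle$seed)))
  write_lulc(bundle$forecast, file.path(dir, "forecast.asc"))
  jsonlite::write_json(
    c(list(classes = bundle$transition$classes,
           counts = bundle$transition$counts,
           P = bundle$transition$P), stamp),
    file.path(dir, "transition.json"), digits = NA, auto_unbox = TRUE,
    matrix = "rowmajor")
  jsonlite::write_json(
    c(lapply(unclass(bundle$models), function(m)
      list(intercept = m$intercept,
           coefficients = as.list(m$coefficients),
           roc = m$roc, subset = m$subset)), stamp),
    file.path(dir, "suitability.json"), digits = NA, auto_unbox = TRUE)
  if (!is.null(bundle$validation)) {
    v <- bundle$validation
    jsonlite::write_json(
      c(list(counts = v$confusion$counts, P0 = v$kappa$P0, Pc = v$kappa$Pc,
             kappa = v$kappa$kappa, band = v$kappa$band), stamp),
      file.path(dir, "validation.json"), digits = NA, auto_unbox = TRUE,
      matrix = "rowmajor")
  }
  bcad <- bundle$bc$by_date
  utils::write.csv(bcad, file.path(dir, "biocapacity.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$bc$trend))
    utils::write.csv(bundle$bc$trend, file.path(dir, "bc_trend.csv"),
                     row.names = FALSE)
  met <- do.call(rbind, lapply(names(bundle$metrics), function(nm)
    cbind(date = nm, bundle$metrics[[nm]]$landscape)))
  utils::write.csv(met, file.path(dir, "metrics.csv"), row.names = FALSE)
  writeLines(c(sprintf("seed: %d", bundle$seed),
               sprintf("config_hash: %s", stamp$config_hash),
               sprintf("written: %s", paste(list.files(dir),
                                            collapse = ", "))),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}
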