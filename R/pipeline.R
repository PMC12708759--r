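#' Monthly series CSV helpers
#'
#' Series are exchanged between pipeline stages as two-column CSVs with
#' an ISO month column (`"YYYY-MM"`) and a value column.
#'
#' @param x monthly `ts`.
#' @param path CSV path.
#' @param name value column name.
#' @return `write_series_csv` returns `path` invisibly; `read_series_csv`
#'   returns a monthly `ts`.
#' @export
write_series_csv <- function(x, path, name = "value") {
  df <- data.frame(month = format(ts_months(x), "%Y-%m"),
                   value = as.numeric(x))
  names(df)[2] <- name
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  time <- as.Date(paste0(df[[1]], "-01"))
  check_monthly_axis(time)
  as_month_ts(df[[2]], time)
}

#' Pipeline configuration
#'
#' Bundles every stage's parameters. All randomness in a run derives from
#' the single `seed` (the generator and the bootstrap draw from fixed
#' offsets of it), so identical configurations produce byte-identical
#' artifacts.
#'
#' @param synth a [synthetic_config()] for the regional domain.
#' @param seed master seed for the run.
#' @param region region name for the event series (default `"CDNI"`).
#' @param k,min_duration event detection parameters (see
#'   [detect_extreme_events()]).
#' @param season peak-season filter (see [filter_by_peak_season()]).
#' @param lags composite lags in months.
#' @param n_resamples,alpha bootstrap parameters (see
#'   [bootstrap_significance()]); the default 2000 resamples keeps a full
#'   run fast — raise to 10000 for production-grade masks.
#' @param cutoff_years,hov_band wave-stage parameters.
#' @param global_synth optional [synthetic_config()] for a coarse global
#'   SST grid feeding the index stage; `NULL` builds a default one.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synthetic_config(), seed = 1,
                            region = "CDNI", k = 0.8, min_duration = 2,
                            season = "MAM", lags = -3:3,
                            n_resamples = 2000, alpha = 0.05,
                            cutoff_years = 10, hov_band = 1,
                            global_synth = NULL) {
  if (is.null(global_synth)) {
    global_synth <- synthetic_config(
      n_years = synth$n_years, start_year = synth$start_year,
      lat = seq(-62.5, 62.5, by = 5), lon = seq(-177.5, 177.5, by = 5),
      land_lon_min = 360,  # all ocean
      variables = default_variables()["sst"],
      ar1_phi = synth$ar1_phi, events = NULL, wave = NULL)
  }
  structure(list(synth = synth, seed = seed, region = region, k = k,
                 min_duration = min_duration, season = season, lags = lags,
                 n_resamples = n_resamples, alpha = alpha,
                 cutoff_years = cutoff_years, hov_band = hov_band,
                 global_synth = global_synth),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes, in order: field generation -> detrended anomalies ->
#' region-mean series -> extreme-event detection (with peak-season
#' filter) -> lag composites with bootstrap significance (series and SST
#' maps) -> heat-budget composite, closure residual and Q'/H'
#' decomposition -> climate indices (AMV, Nino3.4/ONI) with a sliding
#' correlation -> coastal Hovmoeller with high-pass and 1-2-1 filtering
#' and a propagation-lag estimate. Every stage output is serialized
#' eagerly under `out_dir` and a manifest with parameters, seed and
#' per-file MD5 hashes is written last.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created; existing files overwritten).
#' @param quiet suppress per-stage log lines.
#' @return invisibly, a list with the key in-memory results (`events`,
#'   `composite`, `budget`, `indices`, `waves`) and `files` (all written
#'   paths).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  log_stage <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, paste(...)))
  }
  emit <- function(path) { files <<- c(files, path); path }

  # --- synth ---------------------------------------------------------
  log_stage("synth", "generating fields, seed", config$seed)
  gen <- generate_fields(config$synth, seed = config$seed)
  paths <- write_synthetic_run(gen, file.path(out_dir, "synth"))
  files <- c(files, paths)

  # --- anomalies -----------------------------------------------------
  log_stage("anoms", "detrending + deseasonalizing")
  anoms <- lapply(gen$fields[c("npp", "sst", "sla")], detrended_anomalies)
  write_fields(anoms, emit(file.path(out_dir, "anoms.json")))
  series <- area_mean(anoms$npp, config$region)
  write_series_csv(series, emit(file.path(out_dir, "cdni_nppa.csv")),
                   name = "nppa")

  # --- events --------------------------------------------------------
  events <- detect_extreme_events(series, k = config$k,
                                  min_duration = config$min_duration)
  season_events <- filter_by_peak_season(events, config$season)
  log_stage("events", nrow(events), "detected,", nrow(season_events),
            "peaking in", config$season)
  utils::write.csv(event_summary(season_events)$events,
                   emit(file.path(out_dir, "events.csv")),
                   row.names = FALSE)

  composite <- NULL
  budget_out <- NULL
  if (nrow(season_events) > 0) {
    # composites key to the low-productivity events (the extreme type the
    # analysis centres on); with no low events the high ones are used
    low <- season_events[season_events$sign == "low", ]
    peaks <- if (nrow(low) > 0) low$peak else season_events$peak

    # --- composites --------------------------------------------------
    log_stage("composite", length(peaks), "events, lags",
              paste(range(config$lags), collapse = ".."))
    comp <- composite_at_lags(series, peaks, config$lags)
    comp <- bootstrap_significance(series, comp,
                                   n_resamples = config$n_resamples,
                                   alpha = config$alpha,
                                   seed = config$seed + 100L)
    utils::write.csv(
      data.frame(lag = comp$lags, mean = comp$mean,
                 n_events = comp$n_events,
                 lower = comp$percentile_bounds$lower,
                 upper = comp$percentile_bounds$upper,
                 significant = comp$sig_mask),
      emit(file.path(out_dir, "composite_series.csv")), row.names = FALSE)

    comp_sst <- composite_at_lags(anoms$sst, peaks, config$lags)
    comp_sst <- bootstrap_significance(anoms$sst, comp_sst,
                                       n_resamples = config$n_resamples,
                                       alpha = config$alpha,
                                       seed = config$seed + 101L)
    jsonlite::write_json(
      list(lags = comp_sst$lags, n_events = comp_sst$n_events,
           mean = comp_sst$mean, sig_mask = comp_sst$sig_mask),
      emit(file.path(out_dir, "composite_sst.json")),
      digits = I(17), na = "null")
    composite <- list(series = comp, sst = comp_sst)

    # --- heat budget -------------------------------------------------
    log_stage("budget", "composite + Q'/H' decomposition")
    bgt <- generate_budget(config$synth, seed = config$seed)
    term_anoms <- lapply(unclass(bgt$terms), detrended_anomalies)
    comp_terms <- vapply(term_anoms, function(s)
      composite_at_lags(s, peaks, config$lags)$mean,
      numeric(length(config$lags)))
    comp_terms <- matrix(comp_terms, nrow = length(config$lags),
                         dimnames = list(NULL, names(term_anoms)))
    utils::write.csv(
      cbind(data.frame(lag = config$lags), as.data.frame(comp_terms)),
      emit(file.path(out_dir, "budget_composite.csv")), row.names = FALSE)

    lag0 <- which(config$lags == 0)
    contrib <- NULL
    if (length(lag0) == 1) {
      vals <- comp_terms[lag0, rhs_names]
      dir_ <- if (comp_terms[lag0, "tot"] >= 0) "warming" else "cooling"
      contrib <- tryCatch(contribution_percentages(vals, dir_),
                          error = function(e) NULL)
      if (!is.null(contrib))
        utils::write.csv(contrib,
                         emit(file.path(out_dir, "budget_contributions.csv")),
                         row.names = FALSE)
    }

    qh <- decompose_qnet(bgt$Q, bgt$H)
    utils::write.csv(
      data.frame(month = format(ts_months(bgt$Q), "%Y-%m"),
                 qnet_ano = as.numeric(qh$qnet_ano),
                 q_term = as.numeric(qh$q_term),
                 h_term = as.numeric(qh$h_term),
                 residual = as.numeric(qh$residual),
                 closure_residual = as.numeric(closure_residual(bgt$terms))),
      emit(file.path(out_dir, "qnet_decomposition.csv")), row.names = FALSE)
    budget_out <- list(terms = bgt$terms, composite = comp_terms,
                       contributions = contrib, qh = qh)
  } else {
    log_stage("composite", "no seasonal events; composite stages skipped")
    utils::write.csv(empty_event_set(),
                     emit(file.path(out_dir, "composite_series.csv")),
                     row.names = FALSE)
  }

  # --- indices -------------------------------------------------------
  log_stage("indices", "AMV + Nino3.4/ONI on the global synthetic grid")
  glob <- generate_fields(config$global_synth, seed = config$seed + 1000L)
  sst_glob <- detrended_anomalies(glob$fields$sst)
  amv <- amv_index(sst_glob)
  oni <- nino34_oni(sst_glob)
  utils::write.csv(
    data.frame(year = stats::time(amv), amv = as.numeric(amv),
               amv_annual = as.numeric(attr(amv, "annual"))),
    emit(file.path(out_dir, "amv.csv")), row.names = FALSE)
  utils::write.csv(
    data.frame(month = format(ts_months(oni), "%Y-%m"),
               oni = as.numeric(oni), phase = attr(oni, "phase")),
    emit(file.path(out_dir, "nino34_oni.csv")), row.names = FALSE)

  nino_djf <- seasonal_mean(stats::ts(as.numeric(oni),
                                      start = stats::start(oni),
                                      frequency = 12), "DJF")
  npp_mam <- seasonal_mean(series, "MAM")
  yrs <- intersect(stats::time(nino_djf), stats::time(npp_mam))
  corr <- NULL
  if (length(yrs) >= 21) {
    xw <- stats::window(nino_djf, start = min(yrs), end = max(yrs))
    yw <- stats::window(npp_mam, start = min(yrs), end = max(yrs))
    corr <- sliding_pearson(xw, yw, window_years = 21, alpha = config$alpha)
    utils::write.csv(corr, emit(file.path(out_dir, "sliding_corr.csv")),
                     row.names = FALSE)
  }

  # --- waves ---------------------------------------------------------
  log_stage("waves", "Hovmoeller + filtering + propagation lag")
  path <- coastal_path_from_field(gen$fields$sla, name = "nw_coast")
  hov <- build_hovmoeller(anoms$sla, path, band_width = config$hov_band)
  hov <- smooth_121(highpass_fft(hov, config$cutoff_years))
  hov_df <- as.data.frame(hov$values)
  names(hov_df) <- sprintf("pos_%g", hov$positions)
  utils::write.csv(cbind(data.frame(month = format(hov$time, "%Y-%m")),
                         hov_df),
                   emit(file.path(out_dir, "hovmoeller.csv")),
                   row.names = FALSE)
  pos <- range(hov$positions)
  plag <- tryCatch(
    propagation_lag(hov, hov$positions[1],
                    hov$positions[which.min(abs(hov$positions -
                                                  (hov$positions[1] + 10)))]),
    error = function(e) list(lag = NA_integer_, r = NA_real_))
  utils::write.csv(data.frame(pos_a = hov$positions[1],
                              pos_b = hov$positions[1] + 10,
                              lag = plag$lag, r = plag$r,
                              true_speed = gen$truth$wave_speed),
                   emit(file.path(out_dir, "propagation.csv")),
                   row.names = FALSE)

  # --- manifest ------------------------------------------------------
  files <- unname(files)
  rel <- sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", out_dir),
                    "/?"), "", files)
  hashes <- stats::setNames(as.list(unname(tools::md5sum(files))), rel)
  manifest <- list(
    package = "upwellr",
    version = as.character(utils::packageVersion("upwellr")),
    seed = config$seed,
    parameters = list(region = config$region, k = config$k,
                      min_duration = config$min_duration,
                      season = config$season, lags = config$lags,
                      n_resamples = config$n_resamples,
                      alpha = config$alpha,
                      cutoff_years = config$cutoff_years,
                      hov_band = config$hov_band,
                      n_years = config$synth$n_years,
                      start_year = config$synth$start_year),
    files = hashes
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = I(17), auto_unbox = TRUE, pretty = TRUE)

  invisible(list(events = season_events, all_events = events,
                 composite = composite, budget = budget_out,
                 indices = list(amv = amv, oni = oni, corr = corr),
                 waves = list(hovmoeller = hov, propagation = plag),
                 files = c(files, file.path(out_dir, "manifest.json"))))
}
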