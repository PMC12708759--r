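#' Configuration of the synthetic-data generator
#'
#' Describes an idealized eastern-boundary upwelling domain with a
#' meridional coastline: every variable is built as
#' `climatology(month) + trend * t + AR(1) noise`, plus injected
#' multi-month extreme-event anomalies over the coastal (CDNI) band for
#' NPP and SST (with opposite signs, reproducing their observed
#' anti-phase) and a poleward-propagating coastal pulse for sea level
#' anomaly. Defaults emulate the statistical structure of the real
#' satellite/model fields: a 21-year monthly record starting 2003, a
#' 1-degree grid with land east of 0E, an NPP seasonal cycle peaking in
#' April (MAM maximum), SST peaking in September, weak pointwise linear
#' trends, lag-1 autocorrelation 0.3, and nine MAM-peaking events (six
#' low-NPP, three high-NPP) of 3 months at 3 noise standard deviations.
#'
#' @param n_years record length in years (>= 3).
#' @param start_year first calendar year.
#' @param lat,lon grid cell-center coordinates (degrees).
#' @param land_lon_min cells with `lon >= land_lon_min` are land.
#' @param variables named list of per-variable settings: `mean`,
#'   `seasonal_amplitude`, `peak_month`, `trend` (units yr-1, scalar or
#'   `[lat, lon]` map), `noise_sd`.
#' @param ar1_phi lag-1 autocorrelation of the noise, `|phi| < 1`.
#' @param events data frame with columns `start` (month index),
#'   `duration` (>= 1), `sign` (+1 high-NPP / -1 low-NPP) and `amplitude`
#'   in sigma units: multiples of each variable's `sigma_event` (which
#'   defaults to its `noise_sd`, and can be set explicitly, e.g. for
#'   noise-free runs). Injected as half-sine pulses so the peak month is
#'   unambiguous.
#' @param wave coastal SLA pulse: list with `speed` (degrees latitude per
#'   month), `amplitude` (cm), `start` (month index at the southern
#'   origin), `width` (temporal Gaussian half-width, months),
#'   `origin_lat`, `band_width` (degrees from the coast).
#' @param spatial_corr if `TRUE`, AR(1) innovations are spatially blurred
#'   with a 3x3 kernel instead of being i.i.d. across cells.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_years = 21, start_year = 2003,
                             lat = seq(0.5, 24.5, by = 1),
                             lon = seq(-9.5, 0.5, by = 1),
                             land_lon_min = 0,
                             variables = default_variables(),
                             ar1_phi = 0.3,
                             events = default_events(),
                             wave = list(speed = 5, amplitude = 5,
                                         start = 100, width = 2,
                                         origin_lat = 0, band_width = 1.5),
                             spatial_corr = FALSE) {
  if (n_years < 3) stop("n_years must be >= 3", call. = FALSE)
  if (abs(ar1_phi) >= 1) stop("|ar1_phi| must be < 1", call. = FALSE)
  n_months <- n_years * 12L
  if (!is.null(events) && nrow(events) > 0) {
    if (any(events$duration < 1)) stop("event durations must be >= 1",
                                       call. = FALSE)
    if (any(events$start < 1 | events$start + events$duration - 1 > n_months))
      stop("an event extends past the time axis", call. = FALSE)
  }
  structure(list(n_years = n_years, start_year = start_year,
                 lat = lat, lon = lon, land_lon_min = land_lon_min,
                 variables = variables, ar1_phi = ar1_phi,
                 events = events, wave = wave,
                 spatial_corr = spatial_corr, n_months = n_months),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_variables <- function() {
  list(
    npp = list(mean = 2.5, seasonal_amplitude = 1.2, peak_month = 4,
               trend = -0.01, noise_sd = 0.25, units = "gC m-2 day-1"),
    sst = list(mean = 24, seasonal_amplitude = 2.5, peak_month = 9,
               trend = 0.02, noise_sd = 0.35, units = "degC"),
    sla = list(mean = 0, seasonal_amplitude = 2, peak_month = 10,
               trend = 0.3, noise_sd = 1.5, units = "cm"),
    taux = list(mean = -0.05, seasonal_amplitude = 0.02, peak_month = 1,
                trend = 0, noise_sd = 0.01, units = "N m-2"),
    tauy = list(mean = 0.02, seasonal_amplitude = 0.01, peak_month = 7,
                trend = 0, noise_sd = 0.008, units = "N m-2")
  )
}

# nine MAM-peaking coastal events over 21 years: six low-NPP, three
# high-NPP, duration 3 (Mar-May, peak April), 3 sigma half-sine pulses
default_events <- function() {
  low_years <- c(3, 6, 8, 18, 19, 21)
  high_years <- c(10, 13, 14)
  data.frame(
    start = c((low_years - 1) * 12 + 3, (high_years - 1) * 12 + 3),
    duration = 3L,
    sign = c(rep(-1, length(low_years)), rep(1, length(high_years))),
    amplitude = 3
  )
}

# fixed per-variable offsets of the seed so variables can be regenerated
# independently of one another
seed_offsets <- c(npp = 1L, sst = 2L, sla = 3L, taux = 4L, tauy = 5L,
                  budget = 10L)

half_sine <- function(duration) {
  p <- sin(pi * (seq_len(duration) - 0.5) / duration)
  (p + rev(p)) / 2  # enforce exact symmetry so even-length ties are exact
}

#' Generate synthetic monthly gridded fields with recorded ground truth
#'
#' @param config a [synthetic_config()].
#' @param seed integer; identical seed implies bit-identical output.
#' @return list with `fields` (named list of `gridded_field`s: npp, sst,
#'   sla, taux, tauy) and `truth` (class `synthetic_truth`): injected
#'   events (start/end/peak/sign/amplitude in physical units), per-cell
#'   trend maps, the monthly climatologies used, the wave phase speed and
#'   per-variable noise sd.
#' @export
generate_fields <- function(config, seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_months
  time <- month_seq(config$start_year, 1, n)
  mask <- outer(rep(TRUE, length(config$lat)),
                config$lon < config$land_lon_min, `&`)
  ncell <- length(config$lat) * length(config$lon)
  mcal <- as.integer(format(time, "%m"))
  t_years <- (seq_len(n) - 1) / 12

  fields <- list()
  truth_clim <- list()
  truth_trend <- list()
  for (var in names(config$variables)) {
    vc <- config$variables[[var]]
    set.seed(seed + seed_offsets[[var]])
    clim <- vc$mean + vc$seasonal_amplitude *
      cos(2 * pi * (1:12 - vc$peak_month) / 12)
    trend_map <- if (is.matrix(vc$trend)) vc$trend
                 else matrix(vc$trend, length(config$lat),
                             length(config$lon))
    base <- outer(clim[mcal], rep(1, ncell)) +
      outer(t_years, as.vector(trend_map))
    noise <- ar1_noise(n, ncell, config$ar1_phi, vc$noise_sd,
                       config$spatial_corr, dim_grid = c(length(config$lat),
                                                         length(config$lon)))
    v <- base + noise
    fields[[var]] <- gridded_field(array(v, c(n, length(config$lat),
                                              length(config$lon))),
                                   lat = config$lat, lon = config$lon,
                                   time = time, name = var,
                                   units = vc$units %||% "", mask = mask)
    truth_clim[[var]] <- clim
    truth_trend[[var]] <- trend_map
  }

  # inject coastal events into NPP (configured sign) and SST (opposite
  # sign: low productivity co-occurs with anomalous warming)
  ev <- config$events
  truth_events <- empty_event_set()
  if (!is.null(ev) && nrow(ev) > 0) {
    band <- region_mask(fields$npp, "CDNI")
    # sigma unit for amplitudes: noise sd unless overridden (so a
    # noise-free world keeps physical event amplitudes)
    unit_of <- function(vc) vc$sigma_event %||% vc$noise_sd
    amp_npp <- ev$amplitude * unit_of(config$variables$npp)
    amp_sst <- ev$amplitude * unit_of(config$variables$sst)
    rows <- lapply(seq_len(nrow(ev)), function(i) {
      idx <- ev$start[i] + seq_len(ev$duration[i]) - 1L
      pulse <- half_sine(ev$duration[i])
      for (cell in which(as.vector(band))) {
        arr_idx <- arrayInd(cell, dim(band))
        fields$npp$values[idx, arr_idx[1], arr_idx[2]] <<-
          fields$npp$values[idx, arr_idx[1], arr_idx[2]] +
          ev$sign[i] * amp_npp[i] * pulse
        fields$sst$values[idx, arr_idx[1], arr_idx[2]] <<-
          fields$sst$values[idx, arr_idx[1], arr_idx[2]] -
          ev$sign[i] * amp_sst[i] * pulse
      }
      pk <- idx[which.max(pulse)]
      data.frame(sign = if (ev$sign[i] > 0) "high" else "low",
                 start = ev$start[i], end = idx[length(idx)], peak = pk,
                 peak_year = as.integer(format(time[pk], "%Y")),
                 peak_month = as.integer(format(time[pk], "%m")),
                 duration = ev$duration[i],
                 peak_value = ev$sign[i] * amp_npp[i],
                 sigma = NA_real_, threshold = NA_real_,
                 stringsAsFactors = FALSE)
    })
    truth_events <- do.call(rbind, rows)
    truth_events <- truth_events[order(truth_events$start), ]
  }

  # poleward-propagating coastal SLA pulse at the configured phase speed
  wv <- config$wave
  if (!is.null(wv) && wv$amplitude != 0) {
    band <- coastal_band_cells(fields$sla, wv$band_width)
    for (cell in which(as.vector(band))) {
      arr_idx <- arrayInd(cell, dim(band))
      arrival <- wv$start + (config$lat[arr_idx[1]] - wv$origin_lat) /
        wv$speed
      pulse <- wv$amplitude * exp(-0.5 * ((seq_len(n) - arrival) /
                                            wv$width)^2)
      fields$sla$values[, arr_idx[1], arr_idx[2]] <-
        fields$sla$values[, arr_idx[1], arr_idx[2]] + pulse
    }
  }

  truth <- structure(
    list(events = truth_events, trend_map = truth_trend,
         climatology = truth_clim,
         wave_speed = if (is.null(wv)) NA_real_ else wv$speed,
         noise_sd = vapply(config$variables, `[[`, numeric(1), "noise_sd"),
         ar1_phi = config$ar1_phi, seed = seed),
    class = "synthetic_truth")
  list(fields = fields, truth = truth)
}

# full-latitude coastal band mask (no latitude restriction)
coastal_band_cells <- function(field, band_width) {
  region_mask(field, region("coastal_band", min(field$lat) - 1,
                            max(field$lat) + 1, band_width = band_width,
                            name = "wave_band"))
}

# AR(1) noise matrix [n, ncell] with stationary marginal sd `sd`;
# 60-month burn-in from a zero state; optional 3x3 spatial blur of the
# innovations (blur renormalized to keep the marginal sd)
ar1_noise <- function(n, ncell, phi, sd, spatial_corr = FALSE,
                      dim_grid = NULL) {
  burn <- 60L
  innov <- matrix(stats::rnorm((n + burn) * ncell,
                               sd = sd * sqrt(1 - phi^2)),
                  n + burn, ncell)
  if (spatial_corr && !is.null(dim_grid)) {
    innov <- t(apply(innov, 1, blur3x3, nlat = dim_grid[1],
                     nlon = dim_grid[2]))
  }
  x <- apply(innov, 2, function(e) stats::filter(e, phi,
                                                 method = "recursive"))
  x[(burn + 1):(burn + n), , drop = FALSE]
}

blur3x3 <- function(v, nlat, nlon) {
  m <- matrix(v, nlat, nlon)
  p <- matrix(0, nlat + 2, nlon + 2)
  p[2:(nlat + 1), 2:(nlon + 1)] <- m
  s <- p[1:nlat, 2:(nlon + 1)] + p[3:(nlat + 2), 2:(nlon + 1)] +
    p[2:(nlat + 1), 1:nlon] + p[2:(nlat + 1), 3:(nlon + 2)] +
    4 * m
  as.vector(s / 8) * (8 / sqrt(20))  # restore unit variance (interior)
}

#' Generate a synthetic mixed-layer heat budget with closure by construction
#'
#' Draws the six right-hand-side terms as seasonal cycles plus AR(1)
#' noise, builds the flux storage term from consistent surface fluxes and
#' mixed-layer depth via [qnet_storage()], and sets
#' `tot = xadv + yadv + zadv + ldf + zdf + qnet` exactly, so the closure
#' residual is zero by construction.
#'
#' @param config a [synthetic_config()] (time axis and AR(1) settings are
#'   used).
#' @param seed integer seed.
#' @param budget_params optional overrides: list with per-term `mean`,
#'   `amplitude`, `peak_month`, `noise_sd` entries under `terms`, plus
#'   `mld` and fluxes `qns`, `qsr`, `f_penetration`, and constants
#'   `rho0`, `cp`.
#' @return list with `terms` (a [heat_budget_terms()] of monthly `ts` in
#'   degC day-1), `flux` (an [air_sea_flux()]), `Q` (total flux
#'   `qns + qsr (1 - f)`, W m-2), `H` (mixed-layer depth, m) and `truth`.
#' @export
generate_budget <- function(config, seed = 1, budget_params = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  p <- utils::modifyList(default_budget_params(), budget_params %||% list())
  n <- config$n_months
  time <- month_seq(config$start_year, 1, n)
  mcal <- as.integer(format(time, "%m"))
  set.seed(seed + seed_offsets[["budget"]])

  seasonal <- function(s) s$mean + s$amplitude *
    cos(2 * pi * (1:12 - s$peak_month) / 12)
  draw <- function(s) {
    seasonal(s)[mcal] + ar1_noise(n, 1, config$ar1_phi, s$noise_sd)[, 1]
  }

  qns <- draw(p$qns)
  qsr <- draw(p$qsr)
  mld <- draw(p$mld)
  if (any(mld <= 0))
    stop("configured mixed-layer depth reaches zero or below", call. = FALSE)
  flux <- air_sea_flux(qns = qns, qsr = qsr, mld = mld,
                       f_penetration = p$f_penetration,
                       rho0 = p$rho0, cp = p$cp)
  qnet <- qnet_storage(flux)

  as_ts <- function(v) as_month_ts(v, time)
  rhs <- lapply(p$terms, draw)
  tot <- rhs$xadv + rhs$yadv + rhs$zadv + rhs$ldf + rhs$zdf + qnet
  terms <- heat_budget_terms(
    tot = as_ts(tot), xadv = as_ts(rhs$xadv), yadv = as_ts(rhs$yadv),
    zadv = as_ts(rhs$zadv), ldf = as_ts(rhs$ldf), zdf = as_ts(rhs$zdf),
    qnet = as_ts(qnet))

  Q <- qns + qsr * (1 - p$f_penetration)
  truth <- structure(
    list(params = p, ar1_phi = config$ar1_phi, seed = seed,
         closure_exact = TRUE),
    class = "synthetic_truth")
  list(terms = terms, flux = flux, Q = as_ts(Q), H = as_ts(mld),
       truth = truth)
}

default_budget_params <- function() {
  list(
    terms = list(
      xadv = list(mean = -0.010, amplitude = 0.020, peak_month = 4,
                  noise_sd = 0.010),
      yadv = list(mean = 0.005, amplitude = 0.010, peak_month = 8,
                  noise_sd = 0.008),
      zadv = list(mean = -0.030, amplitude = 0.030, peak_month = 3,
                  noise_sd = 0.012),
      ldf = list(mean = 0.010, amplitude = 0.010, peak_month = 5,
                 noise_sd = 0.008),
      zdf = list(mean = -0.020, amplitude = 0.015, peak_month = 2,
                 noise_sd = 0.010)
    ),
    qns = list(mean = -60, amplitude = 40, peak_month = 12, noise_sd = 15),
    qsr = list(mean = 220, amplitude = 50, peak_month = 6, noise_sd = 10),
    mld = list(mean = 30, amplitude = 10, peak_month = 2, noise_sd = 2),
    f_penetration = 0.1, rho0 = 1027, cp = 4000
  )
}

#' Serialize a synthetic run: fields, truth sidecar and events CSV
#'
#' @param gen output of [generate_fields()].
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_synthetic_run <- function(gen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fields_path <- file.path(dir, "fields.json")
  write_fields(gen$fields, fields_path)
  truth_path <- file.path(dir, "truth.json")
  tr <- gen$truth
  jsonlite::write_json(
    list(wave_speed = tr$wave_speed, noise_sd = as.list(tr$noise_sd),
         ar1_phi = tr$ar1_phi, seed = tr$seed,
         climatology = tr$climatology,
         events = tr$events),
    truth_path, digits = I(17), na = "null", auto_unbox = TRUE)
  events_path <- file.path(dir, "events_truth.csv")
  utils::write.csv(tr$events, events_path, row.names = FALSE)
  invisible(c(fields = fields_path, truth = truth_path,
              events = events_path))
}
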