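# fixtures are built in code: small grids, analytic series, tiny configs

# uniform-value field on a small all-ocean grid
make_uniform_field <- function(value = 1, n_months = 24, nlat = 4, nlon = 5,
                               lat0 = 0.5, lon0 = -9.5, name = "x") {
  gridded_field(array(value, c(n_months, nlat, nlon)),
                lat = seq(lat0, by = 1, length.out = nlat),
                lon = seq(lon0, by = 1, length.out = nlon),
                time = month_seq(2003, 1, n_months),
                name = name, units = "u")
}

# field with a meridional coastline: cells with lon >= 0 are land
make_coastal_field <- function(values = NULL, n_months = 24,
                               lat = seq(0.5, 24.5, by = 1),
                               lon = seq(-9.5, 0.5, by = 1)) {
  if (is.null(values)) values <- array(1, c(n_months, length(lat),
                                            length(lon)))
  mask <- outer(rep(TRUE, length(lat)), lon < 0, `&`)
  gridded_field(values, lat = lat, lon = lon,
                time = month_seq(2003, 1, n_months), name = "x",
                units = "u", mask = mask)
}

# monthly ts from components: trend per month, 12-cycle, noise
make_series <- function(n_years = 21, start = c(2003, 1), trend = 0,
                        cycle_amp = 0, peak_month = 4, noise = NULL) {
  n <- n_years * 12
  m <- rep(1:12, n_years)
  x <- trend * seq_len(n) +
    cycle_amp * cos(2 * pi * (m - peak_month) / 12)
  if (!is.null(noise)) x <- x + noise
  stats::ts(x, start = start, frequency = 12)
}

# tiny single-row generator config (fast property tests)
tiny_config <- function(n_years = 10, ...) {
  synthetic_config(
    n_years = n_years,
    lat = c(9.5, 10.5), lon = c(-2.5, -1.5, -0.5, 0.5),
    variables = default_variables()[c("npp", "sst")],
    events = NULL, wave = NULL, ...)
}
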