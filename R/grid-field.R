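#' Monthly gridded field
#'
#' The common currency of the package: a monthly `lat x lon x time` array of
#' one geophysical variable (NPP, SST, wind stress, sea level anomaly,
#' heat-budget terms, ...) together with its coordinate vectors, units and a
#' land/ocean mask. Values are stored as a 3-D array with dimensions
#' `[time, lat, lon]`; cells outside the ocean mask are `NA` and excluded
#' from every statistic downstream.
#'
#' @param values numeric array `[time, lat, lon]`.
#' @param lat,lon strictly monotonic coordinate vectors, degrees north/east.
#'   Longitudes are kept in `[-180, 180)`; dateline-crossing domains are not
#'   supported.
#' @param time either a `Date` vector of first-of-month dates (contiguous,
#'   monthly step) or a list `list(start_year=, start_month=)` from which a
#'   monthly axis of length `dim(values)[1]` is built.
#' @param name,units variable name and unit string.
#' @param mask logical `[lat, lon]` ocean mask; defaults to cells with at
#'   least one finite value over the record.
#' @return An object of class `gridded_field`.
#' @export
gridded_field <- function(values, lat, lon, time, name = "field", units = "",
                          mask = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D [time, lat, lon] array", call. = FALSE)
  if (dim(values)[2] != length(lat) || dim(values)[3] != length(lon))
    stop("dimensions of `values` do not match `lat`/`lon`", call. = FALSE)
  if (!is_strictly_monotonic(lat) || !is_strictly_monotonic(lon))
    stop("`lat` and `lon` must be strictly monotonic", call. = FALSE)
  if (any(lon < -180 | lon >= 180))
    stop("longitudes must lie in [-180, 180)", call. = FALSE)

  if (is.list(time) && !inherits(time, "Date"))
    time <- month_seq(time$start_year, time$start_month, dim(values)[1])
  time <- as.Date(time)
  if (length(time) != dim(values)[1])
    stop("`time` length does not match the first dimension of `values`",
         call. = FALSE)
  check_monthly_axis(time)

  if (is.null(mask)) {
    mask <- apply(values, c(2, 3), function(v) any(is.finite(v)))
  }
  mask <- matrix(as.logical(mask), length(lat), length(lon))
  # enforce the mask: land cells are NA at every time step
  if (any(!mask)) {
    land <- which(!mask, arr.ind = TRUE)
    for (i in seq_len(nrow(land)))
      values[, land[i, 1], land[i, 2]] <- NA_real_
  }

  structure(
    list(name = name, units = units, lat = as.numeric(lat),
         lon = as.numeric(lon), time = time, values = values, mask = mask),
    class = "gridded_field"
  )
}

#' @export
print.gridded_field <- function(x, ...) {
  cat(sprintf("<gridded_field> %s [%s]\n", x$name, x$units))
  cat(sprintf("  grid : %d lat x %d lon (%.2f..%.2fN, %.2f..%.2fE)\n",
              length(x$lat), length(x$lon), min(x$lat), max(x$lat),
              min(x$lon), max(x$lon)))
  cat(sprintf("  time : %d months, %s .. %s\n", length(x$time),
              format(x$time[1], "%Y-%m"),
              format(x$time[length(x$time)], "%Y-%m")))
  cat(sprintf("  ocean: %d / %d cells\n", sum(x$mask), length(x$mask)))
  invisible(x)
}

#' @export
dim.gridded_field <- function(x) dim(x$values)

is_strictly_monotonic <- function(v) {
  d <- diff(v)
  length(v) == 1L || all(d > 0) || all(d < 0)
}

#' Build a contiguous monthly Date axis
#'
#' @param start_year,start_month calendar start of the axis.
#' @param n number of months.
#' @return `Date` vector of first-of-month dates.
#' @export
month_seq <- function(start_year, start_month, n) {
  seq(as.Date(sprintf("%04d-%02d-01", start_year, start_month)),
      by = "month", length.out = n)
}

check_monthly_axis <- function(time) {
  if (anyNA(time)) stop("time axis contains NA", call. = FALSE)
  if (length(time) > 1L) {
    key <- as.integer(format(time, "%Y")) * 12L + as.integer(format(time, "%m"))
    if (any(diff(key) != 1L))
      stop("time axis is not a contiguous monthly sequence", call. = FALSE)
  }
  invisible(time)
}

#' Calendar months (1-12) of a field's time axis
#' @param field a `gridded_field` (or a `Date` vector).
#' @return integer vector of calendar months.
#' @export
calendar_months <- function(field) {
  time <- if (inherits(field, "gridded_field")) field$time else as.Date(field)
  as.integer(format(time, "%m"))
}

calendar_years <- function(field) {
  time <- if (inherits(field, "gridded_field")) field$time else as.Date(field)
  as.integer(format(time, "%Y"))
}

#' Wrap a vector on a field's time axis as a monthly `ts`
#'
#' Region-mean series and index series are returned as base `ts` objects
#' with `frequency = 12` so that `stats::cycle()` resolves calendar months.
#'
#' @param x numeric vector.
#' @param time `Date` vector (first-of-month) of the same length, or a
#'   `gridded_field` whose axis is used.
#' @return monthly `ts`.
#' @export
as_month_ts <- function(x, time) {
  if (inherits(time, "gridded_field")) time <- time$time
  time <- as.Date(time)
  stats::ts(as.numeric(x), frequency = 12,
            start = c(as.integer(format(time[1], "%Y")),
                      as.integer(format(time[1], "%m"))))
}

#' Date axis of a monthly ts
#' @param x a monthly `ts` (frequency 12).
#' @return `Date` vector of first-of-month dates.
#' @export
ts_months <- function(x) {
  s <- stats::start(x)
  month_seq(s[1], s[2], length(x))
}

# flatten [time, lat, lon] to [time, cell] (cells in lat-major order
# matching as.vector of a [lat, lon] matrix)
field_matrix <- function(field) {
  d <- dim(field$values)
  matrix(field$values, nrow = d[1], ncol = d[2] * d[3])
}

matrix_to_field_values <- function(m, field) {
  array(m, dim = dim(field$values))
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$lat, b$lat)) && isTRUE(all.equal(a$lon, b$lon)) &&
    identical(a$time, b$time)
}
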