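#' Anomaly construction: detrending and deseasonalization
#'
#' Monthly detrended anomalies are built in two steps applied pointwise:
#' the ordinary-least-squares linear trend over the time index is removed
#' (slope and intercept), then the climatological mean seasonal cycle
#' evaluated over the whole record is subtracted. Both steps operate on
#' whole `gridded_field`s (per cell) or on monthly `ts` series.
#'
#' `remove_linear_trend` stores the fitted slope/intercept in the
#' `"trend"` attribute so the removed signal can be reconstructed;
#' `deseasonalize` stores the 12-month climatology in `"climatology"`;
#' the `"provenance"` attribute tracks which steps have been applied.
#'
#' @param x a `gridded_field` or a monthly `ts` (frequency 12).
#' @return An object of the same shape as `x` with anomaly values and
#'   provenance attributes.
#' @name anomalies
NULL

provenance_of <- function(x) attr(x, "provenance") %||% "raw"

add_provenance <- function(x, step) {
  p <- provenance_of(x)
  attr(x, "provenance") <- if (identical(p, "raw")) step
                           else paste(p, step, sep = "+")
  x
}

#' @rdname anomalies
#' @export
remove_linear_trend <- function(x) UseMethod("remove_linear_trend")

#' @export
remove_linear_trend.default <- function(x) {
  n <- length(x)
  if (n < 24L) stop("need at least 24 time steps to detrend", call. = FALSE)
  t_idx <- seq_len(n)
  fit <- ols_by_column(matrix(as.numeric(x), ncol = 1), t_idx)
  out <- x - (fit$intercept[1] + fit$slope[1] * t_idx)
  attr(out, "trend") <- c(slope = fit$slope[1], intercept = fit$intercept[1])
  add_provenance(out, "detrended")
}

#' @export
remove_linear_trend.gridded_field <- function(x) {
  n <- length(x$time)
  if (n < 24L) stop("need at least 24 time steps to detrend", call. = FALSE)
  t_idx <- seq_len(n)
  v <- field_matrix(x)
  fit <- ols_by_column(v, t_idx)
  pred <- outer(t_idx, fit$slope) +
    matrix(fit$intercept, n, length(fit$slope), byrow = TRUE)
  out <- x
  out$values <- matrix_to_field_values(v - pred, x)
  out$trend <- list(
    slope = matrix(fit$slope, length(x$lat), length(x$lon)),
    intercept = matrix(fit$intercept, length(x$lat), length(x$lon))
  )
  add_provenance(out, "detrended")
}

# vectorized NA-aware OLS of each column of v on t; columns with < 2 valid
# points get NA slope/intercept (the cell is set missing downstream)
ols_by_column <- function(v, t_idx) {
  valid <- !is.na(v)
  v0 <- v; v0[!valid] <- 0
  tv <- t_idx * valid
  nv <- colSums(valid)
  sx <- colSums(tv)
  sxx <- colSums(t_idx^2 * valid)
  sy <- colSums(v0)
  sxy <- colSums(t_idx * v0)
  den <- nv * sxx - sx^2
  slope <- ifelse(nv >= 2 & den > 0, (nv * sxy - sx * sy) / den, NA_real_)
  intercept <- ifelse(nv >= 2, (sy - slope * sx) / nv, NA_real_)
  list(slope = slope, intercept = intercept)
}

#' @rdname anomalies
#' @export
monthly_climatology <- function(x) UseMethod("monthly_climatology")

#' @export
monthly_climatology.default <- function(x) {
  if (is.null(stats::tsp(x)) || stats::frequency(x) != 12)
    stop("series must be a monthly ts (frequency 12)", call. = FALSE)
  m <- as.integer(stats::cycle(x))
  out <- rep(NA_real_, 12)
  means <- tapply(as.numeric(x), m, mean, na.rm = TRUE)
  out[as.integer(names(means))] <- means
  out[is.nan(out)] <- NA_real_
  names(out) <- month.abb
  out
}

#' @export
monthly_climatology.gridded_field <- function(x) {
  m <- calendar_months(x)
  v <- field_matrix(x)
  valid <- !is.na(v)
  v0 <- v; v0[!valid] <- 0
  sums <- rowsum(v0, m)
  cnts <- rowsum(valid + 0, m)
  clim <- matrix(NA_real_, 12, ncol(v))
  clim[as.integer(rownames(sums)), ] <- ifelse(cnts > 0, sums / cnts,
                                               NA_real_)
  array(clim, dim = c(12, length(x$lat), length(x$lon)))
}

#' @rdname anomalies
#' @param climatology optional precomputed climatology (12 values for a
#'   series; `[12, lat, lon]` array for a field); default: computed from
#'   `x` over the whole record.
#' @export
deseasonalize <- function(x, climatology = NULL) UseMethod("deseasonalize")

#' @export
deseasonalize.default <- function(x, climatology = NULL) {
  if (is.null(climatology)) climatology <- monthly_climatology(x)
  m <- as.integer(stats::cycle(x))
  out <- x - unname(climatology)[m]
  attr(out, "trend") <- attr(x, "trend")
  attr(out, "climatology") <- climatology
  attr(out, "provenance") <- attr(x, "provenance")
  add_provenance(out, "deseasonalized")
}

#' @export
deseasonalize.gridded_field <- function(x, climatology = NULL) {
  if (is.null(climatology)) climatology <- monthly_climatology(x)
  m <- calendar_months(x)
  cm <- matrix(climatology, nrow = 12)  # [12, cell]
  v <- field_matrix(x) - cm[m, , drop = FALSE]
  out <- x
  out$values <- matrix_to_field_values(v, x)
  out$climatology <- climatology
  add_provenance(out, "deseasonalized")
}

#' @rdname anomalies
#' @details
#' `detrended_anomalies` removes the trend and the seasonal cycle as a
#' single joint least-squares fit (time index plus twelve calendar-month
#' means). At finite monthly sampling a seasonal cycle is not exactly
#' orthogonal to the time index, so applying [remove_linear_trend()] and
#' [deseasonalize()] in sequence leaves a small cross-term (relative
#' order `6 * amplitude / n^2` in the fitted slope, i.e. ~1e-4 on a
#' 21-year record — negligible for real data but not exactly zero);
#' iterating the two steps converges to the joint fit, which this
#' function computes directly. On a pure trend + cycle input the joint
#' anomalies are zero to machine precision, the re-fit slope vanishes,
#' and the monthly climatology of the output is zero for every calendar
#' month.
#' @export
detrended_anomalies <- function(x) UseMethod("detrended_anomalies")

#' @export
detrended_anomalies.default <- function(x) {
  n <- length(x)
  if (n < 24L) stop("need at least 24 time steps to detrend", call. = FALSE)
  if (is.null(stats::tsp(x)) || stats::frequency(x) != 12)
    stop("series must be a monthly ts (frequency 12)", call. = FALSE)
  m <- as.integer(stats::cycle(x))
  fit <- joint_fit(matrix(as.numeric(x), ncol = 1), m)
  out <- stats::ts(fit$anom[, 1], start = stats::start(x), frequency = 12)
  attr(out, "trend") <- c(slope = fit$slope[1], intercept = 0)
  clim <- fit$clim[, 1]
  names(clim) <- month.abb
  attr(out, "climatology") <- clim
  attr(out, "provenance") <- "detrended+deseasonalized"
  out
}

#' @export
detrended_anomalies.gridded_field <- function(x) {
  n <- length(x$time)
  if (n < 24L) stop("need at least 24 time steps to detrend", call. = FALSE)
  m <- calendar_months(x)
  fit <- joint_fit(field_matrix(x), m)
  out <- x
  out$values <- matrix_to_field_values(fit$anom, x)
  out$trend <- list(
    slope = matrix(fit$slope, length(x$lat), length(x$lon)),
    intercept = matrix(0, length(x$lat), length(x$lon))
  )
  out$climatology <- array(fit$clim, c(12, length(x$lat), length(x$lon)))
  attr(out, "provenance") <- "detrended+deseasonalized"
  out
}

# joint OLS of each column on [time index, 12 monthly dummies]; the
# residual is exactly orthogonal to both the trend and every calendar
# month, so anomalies sum to zero within months and overall
joint_fit <- function(v, months) {
  n <- nrow(v)
  t_c <- seq_len(n) - (n + 1) / 2
  dummies <- outer(months, 1:12, `==`) + 0
  X <- cbind(t_c, dummies)
  qrX <- qr(X)
  complete <- !apply(is.na(v), 2, any)

  anom <- matrix(NA_real_, n, ncol(v))
  slope <- rep(NA_real_, ncol(v))
  clim <- matrix(NA_real_, 12, ncol(v))

  if (any(complete)) {
    vc <- v[, complete, drop = FALSE]
    coefs <- qr.coef(qrX, vc)
    anom[, complete] <- vc - X %*% coefs
    slope[complete] <- coefs[1, ]
    # climatology at the record-centre of the trend line
    clim[, complete] <- coefs[2:13, , drop = FALSE]
  }
  for (j in which(!complete)) {
    ok <- !is.na(v[, j])
    if (sum(ok) < 14L || length(unique(months[ok])) < 12L) next
    fit <- stats::lm.fit(X[ok, , drop = FALSE], v[ok, j])
    anom[ok, j] <- fit$residuals
    slope[j] <- fit$coefficients[1]
    clim[, j] <- fit$coefficients[2:13]
  }
  list(anom = anom, slope = slope, clim = clim)
}

#' Per-calendar-month standard deviation of anomalies
#'
#' Sample standard deviation (denominator n-1) of the anomalies falling in
#' each calendar month; a month with fewer than 2 samples is missing.
#'
#' @param x monthly `ts` of anomalies, or an anomaly `gridded_field`.
#' @return named 12-vector (series) or `[12, lat, lon]` array (field).
#' @export
monthly_std <- function(x) UseMethod("monthly_std")

#' @export
monthly_std.default <- function(x) {
  m <- as.integer(stats::cycle(x))
  out <- rep(NA_real_, 12)
  for (mm in 1:12) {
    v <- as.numeric(x)[m == mm]
    v <- v[!is.na(v)]
    if (length(v) >= 2) out[mm] <- stats::sd(v)
  }
  names(out) <- month.abb
  out
}

#' @export
monthly_std.gridded_field <- function(x) {
  m <- calendar_months(x)
  v <- field_matrix(x)
  valid <- !is.na(v)
  v0 <- v; v0[!valid] <- 0
  cnts <- rowsum(valid + 0, m)
  sums <- rowsum(v0, m)
  sq <- rowsum(v0^2, m)
  mean_ <- ifelse(cnts > 0, sums / cnts, NA_real_)
  var_ <- ifelse(cnts >= 2, (sq - cnts * mean_^2) / (cnts - 1), NA_real_)
  var_[var_ < 0] <- 0  # numerical guard
  out <- matrix(NA_real_, 12, ncol(v))
  out[as.integer(rownames(cnts)), ] <- sqrt(var_)
  array(out, dim = c(12, length(x$lat), length(x$lon)))
}

#' Seasonal means of a monthly series
#'
#' Averages the listed calendar months within each (season-)year. Seasons
#' that span the turn of the year (DJF, DJFM, ...) are assigned to the
#' January year: December counts toward the following year, so the first
#' value of a DJF series on a record starting in January is missing.
#' A year missing any requested month is missing.
#'
#' @param series monthly `ts` (frequency 12).
#' @param months integer calendar months (1-12) or a season name built
#'   from month initials, e.g. `"MAM"`, `"DJF"`, `"DJFM"`, `"FMA"`.
#' @return annual `ts` (frequency 1) indexed by season-year.
#' @export
seasonal_mean <- function(series, months) {
  months <- season_months(months)
  if (length(months) == 0L) stop("empty month set", call. = FALSE)
  m <- as.integer(stats::cycle(series))
  yr <- calendar_years(ts_months(series))
  season_year <- yr + wraps_to_next_year(m, months)
  keep <- m %in% months
  if (!any(keep)) stop("no requested months in the record", call. = FALSE)
  vals <- as.numeric(series)[keep]
  sy <- season_year[keep]
  years <- seq(min(sy), max(sy))
  out <- vapply(years, function(y) {
    v <- vals[sy == y]
    if (length(v) != length(months) || anyNA(v)) NA_real_ else mean(v)
  }, numeric(1))
  stats::ts(out, start = years[1], frequency = 1)
}

# +1 for months belonging to the December side of a wrapping season
wraps_to_next_year <- function(m, months) {
  months <- sort(unique(months))
  if (!(12L %in% months && 1L %in% months)) return(integer(length(m)))
  # months contiguous with December (walking backwards from 12)
  dec_side <- 12L
  while ((dec_side - 1L) %in% months) dec_side <- dec_side - 1L
  as.integer(m >= dec_side & m %in% months)
}

#' Resolve a season name to calendar months
#'
#' Seasons are named by month initials (`JFMAMJJASOND`): `"MAM"` is
#' March-April-May, `"DJFM"` December-March. The match must be unique.
#'
#' @param season character season name or integer months (returned as-is).
#' @return integer vector of calendar months.
#' @export
season_months <- function(season) {
  if (is.numeric(season)) {
    season <- as.integer(season)
    if (any(season < 1L | season > 12L))
      stop("months must be in 1..12", call. = FALSE)
    return(season)
  }
  initials <- c("J", "F", "M", "A", "M", "J", "J", "A", "S", "O", "N", "D")
  want <- strsplit(toupper(season), "")[[1]]
  k <- length(want)
  if (k < 1L || k > 12L) stop("invalid season name: ", season, call. = FALSE)
  hits <- Filter(function(s) {
    all(initials[((s - 1L + seq_len(k) - 1L) %% 12L) + 1L] == want)
  }, 1:12)
  if (length(hits) == 0L)
    stop("season name matches no month sequence: ", season, call. = FALSE)
  if (length(hits) > 1L)
    stop("ambiguous season name: ", season, call. = FALSE)
  ((hits[[1]] - 1L + seq_len(k) - 1L) %% 12L) + 1L
}
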