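#' Extreme-event detection on a region-mean anomaly series
#'
#' An extreme event is a maximal run of consecutive months in which the
#' detrended, deseasonalized anomaly exceeds `+k*sigma` (high event) or
#' falls below `-k*sigma` (low event) for at least `min_duration`
#' consecutive months, where `sigma` is the pooled standard deviation of
#' the full anomaly series (all calendar months). Exceedance is strict
#' (`>` / `<`). The event peak is the month of maximum absolute anomaly
#' within the run, ties broken toward the earlier month. Runs are never
#' merged across a sub-threshold month.
#'
#' @param series monthly anomaly `ts` (frequency 12), already detrended
#'   and deseasonalized.
#' @param k threshold in multiples of sigma (default 0.8).
#' @param min_duration minimum run length in months (default 2).
#' @param sigma optional externally supplied sigma; default: pooled sample
#'   standard deviation of `series`. May also be a 12-vector of
#'   per-calendar-month sigmas (then the threshold varies by month).
#' @return An `event_set`: a data frame with one row per event and columns
#'   `sign` ("high"/"low"), `start`, `end`, `peak` (month indices into the
#'   series), `peak_year`, `peak_month` (calendar), `duration`,
#'   `peak_value`, `sigma`, `threshold`.
#' @export
detect_extreme_events <- function(series, k = 0.8, min_duration = 2,
                                  sigma = NULL) {
  x <- as.numeric(series)
  n <- length(x)
  if (sum(!is.na(x)) < min_duration)
    stop("series too short for detection", call. = FALSE)
  if (is.null(sigma)) sigma <- stats::sd(x, na.rm = TRUE)
  if (length(sigma) == 1L) {
    if (!is.finite(sigma) || sigma <= 0)
      stop("degenerate series: sigma is zero or undefined", call. = FALSE)
    thr <- rep(k * sigma, n)
    sig_used <- rep(sigma, n)
  } else {
    if (length(sigma) != 12L)
      stop("sigma must be scalar or a 12-vector", call. = FALSE)
    if (any(!is.finite(sigma)) || any(sigma <= 0))
      stop("degenerate per-month sigma", call. = FALSE)
    m <- as.integer(stats::cycle(series))
    thr <- k * sigma[m]
    sig_used <- sigma[m]
  }

  state <- integer(n)  # +1 above, -1 below, 0 neutral/NA
  state[!is.na(x) & x > thr] <- 1L
  state[!is.na(x) & x < -thr] <- -1L

  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L & r$lengths >= min_duration

  months <- ts_months(series)
  rows <- lapply(which(keep), function(i) {
    s <- starts[i]; e <- ends[i]
    seg <- abs(x[s:e])
    pk <- s + which.max(seg) - 1L  # which.max: earliest tie wins
    data.frame(
      sign = if (r$values[i] > 0) "high" else "low",
      start = s, end = e, peak = pk,
      peak_year = as.integer(format(months[pk], "%Y")),
      peak_month = as.integer(format(months[pk], "%m")),
      duration = e - s + 1L,
      peak_value = x[pk],
      sigma = sig_used[pk],
      threshold = thr[pk],
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else empty_event_set()
  structure(out, class = c("event_set", "data.frame"),
            k = k, min_duration = min_duration)
}

empty_event_set <- function() {
  data.frame(sign = character(0), start = integer(0), end = integer(0),
             peak = integer(0), peak_year = integer(0),
             peak_month = integer(0), duration = integer(0),
             peak_value = numeric(0), sigma = numeric(0),
             threshold = numeric(0), stringsAsFactors = FALSE)
}

#' Keep only events peaking in a given season
#'
#' @param events an `event_set`.
#' @param season calendar months or a season name (default `"MAM"`); an
#'   event is retained iff its peak month's calendar month is in the
#'   season — start and end months do not matter.
#' @return filtered `event_set`.
#' @export
filter_by_peak_season <- function(events, season = "MAM") {
  months <- season_months(season)
  out <- events[events$peak_month %in% months, , drop = FALSE]
  attributes(out)[c("k", "min_duration")] <-
    attributes(events)[c("k", "min_duration")]
  class(out) <- class(events)
  out
}

#' Tabulate an event set
#'
#' @param events an `event_set`.
#' @return list with `$events` (CSV-ready per-event table: sign, peak year
#'   and month, duration, peak value) and `$counts` (named vector: number
#'   of high and low events).
#' @export
event_summary <- function(events) {
  tab <- data.frame(
    sign = events$sign,
    peak_year = events$peak_year,
    peak_month = events$peak_month,
    start = events$start, end = events$end, peak = events$peak,
    duration = events$duration,
    peak_value = events$peak_value,
    stringsAsFactors = FALSE
  )
  counts <- c(high = sum(events$sign == "high"),
              low = sum(events$sign == "low"))
  list(events = tab, counts = counts)
}
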