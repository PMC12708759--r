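#' Hovmoeller diagram along a coastal path
#'
#' Band-averages an anomaly field along an ordered path (equator or
#' coastline) to a `[time, position]` matrix, ordered by the path labels
#' from the equatorial/Gulf-of-Guinea origin poleward — the standard view
#' for tracking equatorial Kelvin and coastal-trapped wave signatures.
#'
#' @param field anomaly `gridded_field` (e.g. sea level anomaly, cm).
#' @param path a [coastal_path()].
#' @param band_width averaging radius in degrees (default 1).
#' @return object of class `hovmoeller`: list with `values`
#'   `[time, position]`, `positions`, `time`, `path_name`.
#' @export
build_hovmoeller <- function(field, path, band_width = 1) {
  m <- extract_along_path(field, path, band_width)
  structure(list(values = unclass_matrix(m),
                 positions = attr(m, "positions"),
                 time = attr(m, "time"),
                 path_name = path$name),
            class = "hovmoeller")
}

unclass_matrix <- function(m) {
  attr(m, "positions") <- NULL
  attr(m, "time") <- NULL
  m
}

#' @export
print.hovmoeller <- function(x, ...) {
  cat(sprintf("<hovmoeller> %s: %d months x %d positions (%.1f..%.1f deg)\n",
              x$path_name, nrow(x$values), ncol(x$values),
              min(x$positions), max(x$positions)))
  invisible(x)
}

#' High-pass FFT filter (decadal-signal removal)
#'
#' Removes the mean and all Fourier components with period longer than
#' `cutoff_years` by hard spectral truncation: forward FFT, zeroing of
#' the low-frequency coefficients (including the zero frequency; the
#' coefficient exactly at the cutoff period is retained), inverse FFT.
#' Applied column-wise to matrices and Hovmoeller diagrams. The data must
#' be evenly spaced monthly values without internal gaps.
#'
#' @param x numeric series, matrix `[time, position]`, or `hovmoeller`.
#' @param cutoff_years cutoff period in years (default 10, i.e. a cutoff
#'   frequency of 0.1 cycles per year).
#' @return filtered object of the same shape.
#' @export
highpass_fft <- function(x, cutoff_years = 10) {
  if (inherits(x, "hovmoeller")) {
    x$values <- highpass_fft(x$values, cutoff_years)
    return(x)
  }
  if (is.matrix(x)) return(apply(x, 2, highpass_fft_one,
                                 cutoff_months = cutoff_years * 12))
  out <- highpass_fft_one(as.numeric(x), cutoff_years * 12)
  if (!is.null(stats::tsp(x))) out <- stats::ts(out, start = stats::start(x),
                                                frequency = stats::frequency(x))
  out
}

highpass_fft_one <- function(v, cutoff_months) {
  if (anyNA(v))
    stop("internal gaps: fill or split the segment before filtering",
         call. = FALSE)
  n <- length(v)
  co <- stats::fft(v)
  k <- seq_len(n) - 1L                 # 0 .. n-1
  kf <- pmin(k, n - k)                 # folded frequency index
  period <- ifelse(kf == 0, Inf, n / kf)
  co[period > cutoff_months] <- 0 + 0i # zero freq removed; cutoff kept
  Re(stats::fft(co, inverse = TRUE)) / n
}

#' 1-2-1 running weighted average (subseasonal smoothing)
#'
#' `y_t = 0.25 x_{t-1} + 0.5 x_t + 0.25 x_{t+1}`; the endpoints use
#' renormalized two-point weights `(2,1)/3` and `(1,2)/3`. Applied
#' column-wise to matrices and Hovmoeller diagrams.
#'
#' @param x numeric series (length >= 3), matrix, or `hovmoeller`.
#' @return smoothed object of the same shape.
#' @export
smooth_121 <- function(x) {
  if (inherits(x, "hovmoeller")) {
    x$values <- smooth_121(x$values)
    return(x)
  }
  if (is.matrix(x)) return(apply(x, 2, smooth_121_one))
  out <- smooth_121_one(as.numeric(x))
  if (!is.null(stats::tsp(x))) out <- stats::ts(out, start = stats::start(x),
                                                frequency = stats::frequency(x))
  out
}

smooth_121_one <- function(v) {
  n <- length(v)
  if (n < 3L) stop("need at least 3 points for 1-2-1 smoothing",
                   call. = FALSE)
  out <- as.numeric(stats::filter(v, c(0.25, 0.5, 0.25), sides = 2))
  out[1] <- (2 * v[1] + v[2]) / 3
  out[n] <- (v[n - 1] + 2 * v[n]) / 3
  out
}

#' Propagation lag between two positions of a Hovmoeller diagram
#'
#' Lag (in months) maximizing the Pearson cross-correlation of the series
#' at `pos_b` against the series at `pos_a`; a positive lag means the
#' signal at `pos_b` follows the signal at `pos_a` (poleward
#' propagation). Ties are broken toward the smaller absolute lag, then
#' toward the earlier lag.
#'
#' @param hov a `hovmoeller`.
#' @param pos_a,pos_b along-path coordinates (degrees); the nearest path
#'   positions are used.
#' @param max_lag maximum |lag| searched, months (default 12).
#' @return list with `lag` (months) and `r` (correlation at that lag).
#' @export
propagation_lag <- function(hov, pos_a, pos_b, max_lag = 12) {
  stopifnot(inherits(hov, "hovmoeller"))
  a <- hov$values[, which.min(abs(hov$positions - pos_a))]
  b <- hov$values[, which.min(abs(hov$positions - pos_b))]
  n <- length(a)
  if (n < 3 * max_lag)
    stop("insufficient overlap for the requested max_lag", call. = FALSE)
  lags <- -max_lag:max_lag
  rs <- vapply(lags, function(L) {
    if (L >= 0) { x <- a[seq_len(n - L)]; y <- b[seq_len(n - L) + L] }
    else { x <- a[seq_len(n + L) - L]; y <- b[seq_len(n + L)] }
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(NA_real_)
    stats::cor(x[ok], y[ok])
  }, numeric(1))
  if (all(is.na(rs))) stop("no valid overlap at any lag", call. = FALSE)
  ord <- order(-rs, abs(lags), lags, na.last = TRUE)
  best <- ord[1]
  list(lag = lags[best], r = rs[best])
}
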