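#' Atlantic multidecadal variability (AMV) index
#'
#' Monthly SST anomalies averaged over the North Atlantic box
#' (80W-0E, 0-60N) minus the global-ocean band mean (60S-60N), both
#' cos(latitude)-weighted; annual (calendar-year) means are then smoothed
#' with an 11-year centered running mean, leaving 5 missing values at
#' each end.
#'
#' @param sst_anoms SST anomaly `gridded_field` covering both regions.
#' @param smooth_years centered smoothing window in years (odd, default 11).
#' @return annual `ts` (frequency 1) of the smoothed index, with the
#'   unsmoothed annual series in attribute `"annual"` and the monthly
#'   series in attribute `"monthly"`.
#' @export
amv_index <- function(sst_anoms, smooth_years = 11) {
  if (smooth_years %% 2 != 1)
    stop("smoothing window must be odd and centered", call. = FALSE)
  na <- area_mean(sst_anoms, "amv_north_atlantic")
  gl <- area_mean(sst_anoms, "global_band")
  monthly <- na - gl
  annual <- annual_mean(monthly)
  k <- smooth_years
  sm <- stats::filter(annual, rep(1 / k, k), sides = 2)
  out <- stats::ts(as.numeric(sm), start = stats::start(annual),
                   frequency = 1)
  attr(out, "annual") <- annual
  attr(out, "monthly") <- monthly
  out
}

annual_mean <- function(monthly) {
  yr <- calendar_years(ts_months(monthly))
  years <- seq(min(yr), max(yr))
  out <- vapply(years, function(y) {
    v <- as.numeric(monthly)[yr == y]
    if (length(v) != 12L || anyNA(v)) NA_real_ else mean(v)
  }, numeric(1))
  stats::ts(out, start = years[1], frequency = 1)
}

#' Nino3.4 index with ONI-style smoothing
#'
#' Area-mean SST anomaly in the Nino3.4 box (5S-5N, 170W-120W), smoothed
#' with a 3-month centered running mean; months are classified warm /
#' cold / neutral at the +/- 0.5 degC threshold. Anomalies are expected
#' from the single-period climatology of the [anomalies] pipeline (no
#' rolling 30-year base periods).
#'
#' @param sst_anoms SST anomaly `gridded_field` covering the Nino3.4 box.
#' @param threshold classification threshold in degC (default 0.5).
#' @return monthly `ts` of the smoothed index with attribute `"phase"`
#'   (character vector "warm"/"cold"/"neutral") and `"raw"` (unsmoothed
#'   box mean).
#' @export
nino34_oni <- function(sst_anoms, threshold = 0.5) {
  raw <- area_mean(sst_anoms, "nino34")
  sm <- stats::filter(raw, rep(1 / 3, 3), sides = 2)
  out <- stats::ts(as.numeric(sm), start = stats::start(raw),
                   frequency = 12)
  phase <- rep("neutral", length(out))
  phase[!is.na(out) & out > threshold] <- "warm"
  phase[!is.na(out) & out < -threshold] <- "cold"
  attr(out, "phase") <- phase
  attr(out, "raw") <- raw
  out
}

#' Sliding-window Pearson correlation with analytic significance
#'
#' Pearson correlation of two aligned annual series inside centered
#' sliding windows, with the critical value from a two-tailed Student-t
#' test. Following the convention that a `w`-year window yields `w - 1`
#' degrees of freedom, the default 21-year window gives 20 dof and a 95%
#' critical value of 0.42 (set `dof = window_years - 2` for the n-2
#' convention). Pairs with missing values are dropped within each window;
#' windows with fewer than 3 complete pairs are missing.
#'
#' @param x,y aligned annual series (`ts` frequency 1 or plain vectors).
#' @param window_years odd window length in years (default 21).
#' @param alpha two-sided significance level (default 0.05).
#' @param dof degrees of freedom for the critical value (default
#'   `window_years - 1`).
#' @return data frame with `center` (window-center year or index), `r`,
#'   `n` (complete pairs) and `significant`; attributes `r_crit`, `dof`.
#' @export
sliding_pearson <- function(x, y, window_years = 21, alpha = 0.05,
                            dof = window_years - 1) {
  if (length(x) != length(y))
    stop("series must be aligned (equal length)", call. = FALSE)
  n <- length(x)
  if (n < window_years) stop("series shorter than the window", call. = FALSE)
  half <- (window_years - 1) %/% 2
  start_year <- if (!is.null(stats::tsp(x))) stats::start(x)[1] else 1
  centers <- (half + 1):(n - half)
  rows <- lapply(centers, function(c0) {
    xs <- as.numeric(x)[(c0 - half):(c0 + half)]
    ys <- as.numeric(y)[(c0 - half):(c0 + half)]
    ok <- !is.na(xs) & !is.na(ys)
    r <- if (sum(ok) >= 3) stats::cor(xs[ok], ys[ok]) else NA_real_
    data.frame(center = start_year + c0 - 1, r = r, n = sum(ok))
  })
  out <- do.call(rbind, rows)
  rc <- critical_r(dof, alpha)
  out$significant <- !is.na(out$r) & abs(out$r) > rc
  attr(out, "r_crit") <- rc
  attr(out, "dof") <- dof
  attr(out, "alpha") <- alpha
  out
}

#' Critical Pearson correlation for a two-tailed t test
#'
#' `r_crit = t* / sqrt(t*^2 + dof)` with `t*` the two-tailed Student-t
#' quantile at `1 - alpha/2` on `dof` degrees of freedom. At 20 dof and
#' alpha 0.05 this is 0.423, i.e. the familiar 0.42 threshold for 21-year
#' windows.
#'
#' @param dof degrees of freedom (>= 1).
#' @param alpha two-sided significance level.
#' @return critical |r| threshold.
#' @export
critical_r <- function(dof, alpha = 0.05) {
  if (dof < 1) stop("dof must be >= 1", call. = FALSE)
  tstar <- stats::qt(1 - alpha / 2, df = dof)
  tstar / sqrt(tstar^2 + dof)
}

#' Basic comparison statistics between two series
#'
#' @param a,b aligned series; pairs with a missing value are dropped.
#' @return list with `bias` (mean of a - b), `rmse`, and `pearson_r`.
#' @export
compare_series <- function(a, b) {
  if (length(a) != length(b))
    stop("series must be aligned (equal length)", call. = FALSE)
  a <- as.numeric(a); b <- as.numeric(b)
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  d <- a[ok] - b[ok]
  list(bias = mean(d), rmse = sqrt(mean(d^2)),
       pearson_r = stats::cor(a[ok], b[ok]))
}
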