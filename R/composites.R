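#' Lag composites keyed to event peaks
#'
#' For each lag in `lags`, the arithmetic mean across events of the
#' anomaly at `peak + lag` (per grid cell for fields). An event whose
#' `peak + lag` falls outside the record is dropped at that lag and the
#' per-lag event count is tracked.
#'
#' @param x monthly anomaly `ts` or an anomaly `gridded_field`.
#' @param peaks integer month indices of the event peaks.
#' @param lags integer lags in months (default `-3:3`).
#' @return A `composite_result`: list with `lags`, `mean` (vector per lag
#'   for series; `[lag, lat, lon]` array for fields), `n_events` (per
#'   lag), and `type` ("series"/"field"). Significance slots are filled by
#'   [bootstrap_significance()].
#' @export
composite_at_lags <- function(x, peaks, lags = -3:3) {
  if (length(peaks) < 1L) stop("need at least one event peak", call. = FALSE)
  is_field <- inherits(x, "gridded_field")
  v <- if (is_field) field_matrix(x) else matrix(as.numeric(x), ncol = 1)
  n <- nrow(v)
  mean_ <- matrix(NA_real_, length(lags), ncol(v))
  n_ev <- integer(length(lags))
  for (i in seq_along(lags)) {
    idx <- peaks + lags[i]
    idx <- idx[idx >= 1L & idx <= n]
    n_ev[i] <- length(idx)
    if (length(idx) > 0)
      mean_[i, ] <- colMeans(v[idx, , drop = FALSE], na.rm = TRUE)
  }
  mean_[is.nan(mean_)] <- NA_real_
  out <- list(
    lags = lags,
    mean = if (is_field) array(mean_, c(length(lags), length(x$lat),
                                        length(x$lon)))
           else drop(mean_),
    n_events = n_ev,
    type = if (is_field) "field" else "series",
    sig_mask = NULL, percentile_bounds = NULL
  )
  class(out) <- "composite_result"
  out
}

#' @export
print.composite_result <- function(x, ...) {
  cat(sprintf("<composite_result> %s, lags %s, n_events %s%s\n", x$type,
              paste(range(x$lags), collapse = ".."),
              paste(unique(x$n_events), collapse = "/"),
              if (is.null(x$sig_mask)) "" else ", with significance mask"))
  invisible(x)
}

#' Bootstrap significance of a composite (resampling without replacement)
#'
#' The null distribution is built by resampling the input record: each of
#' `n_resamples` artificial composites averages `n_events` *distinct*
#' months drawn uniformly from all valid months of the record (per cell
#' for fields). The artificial averages are sorted and a composite value
#' is significant at level `alpha` iff it falls outside the
#' `100*alpha/2`th-`100*(1-alpha/2)`th percentile range (type-7
#' percentiles). Per-cell tests are independent (no multiple-testing
#' correction). Deterministic for a fixed `seed`.
#'
#' @param x the same anomaly `ts` or `gridded_field` the composite was
#'   built from.
#' @param composite a `composite_result` from [composite_at_lags()].
#' @param n_resamples number of artificial averages (default 10000).
#' @param alpha two-sided significance level (default 0.05).
#' @param seed integer seed for the resampling stream.
#' @param exclude_months optional month indices removed from the null pool
#'   (e.g. the event months themselves); default: none, i.e. the full
#'   initial monthly data set is resampled.
#' @param pool_months optional calendar months (or season name) to which
#'   the null pool is restricted (season-matched null); default: all.
#' @return the `composite_result` with `sig_mask` (logical per lag, and
#'   per cell for fields) and `percentile_bounds` filled in.
#' @export
bootstrap_significance <- function(x, composite, n_resamples = 10000,
                                   alpha = 0.05, seed = 1,
                                   exclude_months = NULL,
                                   pool_months = NULL) {
  stopifnot(inherits(composite, "composite_result"))
  is_field <- inherits(x, "gridded_field")
  v <- if (is_field) field_matrix(x) else matrix(as.numeric(x), ncol = 1)
  pool <- seq_len(nrow(v))
  if (!is.null(pool_months)) {
    mm <- if (is_field) calendar_months(x)
          else as.integer(stats::cycle(x))
    pool <- pool[mm[pool] %in% season_months(pool_months)]
  }
  if (!is.null(exclude_months)) pool <- setdiff(pool, exclude_months)
  pool <- pool[rowSums(!is.na(v[pool, , drop = FALSE])) > 0]

  probs <- c(alpha / 2, 1 - alpha / 2)
  nlag <- length(composite$lags)
  mean_m <- if (is_field) matrix(composite$mean, nlag) else
    matrix(composite$mean, nlag, 1)
  lo <- hi <- matrix(NA_real_, nlag, ncol(v))
  sig <- matrix(NA, nlag, ncol(v))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  for (ne in unique(composite$n_events[composite$n_events > 0])) {
    if (ne > length(pool))
      stop("n_events exceeds the number of valid months in the pool",
           call. = FALSE)
    draws <- vapply(seq_len(n_resamples),
                    function(i) pool[sample.int(length(pool), ne)],
                    integer(ne))
    draws <- matrix(draws, nrow = ne)
    # artificial averages: [n_resamples, cell]
    if (ncol(v) == 1L) {
      avg <- matrix(colMeans(matrix(v[as.vector(draws), 1], nrow = ne)),
                    ncol = 1)
    } else {
      big <- v[as.vector(draws), , drop = FALSE]
      grp <- rep(seq_len(n_resamples), each = ne)
      cnt <- rowsum((!is.na(big)) + 0, grp)
      big[is.na(big)] <- 0
      avg <- rowsum(big, grp) / ifelse(cnt > 0, cnt, NA)
    }
    qs <- apply(avg, 2, stats::quantile, probs = probs, na.rm = TRUE,
                names = FALSE, type = 7)
    rows <- which(composite$n_events == ne)
    for (r in rows) {
      lo[r, ] <- qs[1, ]
      hi[r, ] <- qs[2, ]
      sig[r, ] <- mean_m[r, ] < qs[1, ] | mean_m[r, ] > qs[2, ]
    }
  }

  shape <- function(m) {
    if (is_field) array(m, c(nlag, length(x$lat), length(x$lon)))
    else drop(m)
  }
  composite$percentile_bounds <- list(lower = shape(lo), upper = shape(hi))
  composite$sig_mask <- shape(sig)
  composite$alpha <- alpha
  composite$n_resamples <- n_resamples
  composite$seed <- seed
  composite
}
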