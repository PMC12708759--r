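#' Mixed layer heat-budget terms
#'
#' Container for the seven terms of the mixed-layer temperature budget,
#' all in degC day-1 on one common monthly axis: `tot` (total mixed-layer
#' temperature tendency), `xadv`/`yadv`/`zadv` (zonal, meridional and
#' vertical advection), `ldf` (lateral diffusion), `zdf` (vertical
#' diffusion/mixing) and `qnet` (air-sea heat-flux storage). The terms are
#' consumed as given (computed online upstream by an ocean model); this
#' module never differentiates temperature itself.
#'
#' @param tot,xadv,yadv,zadv,ldf,zdf,qnet monthly `ts` series (or equal
#'   length numeric vectors) in degC day-1.
#' @return object of class `heat_budget_terms` (a named list of series).
#' @export
heat_budget_terms <- function(tot, xadv, yadv, zadv, ldf, zdf, qnet) {
  terms <- list(tot = tot, xadv = xadv, yadv = yadv, zadv = zadv,
                ldf = ldf, zdf = zdf, qnet = qnet)
  n <- unique(vapply(terms, length, integer(1)))
  if (length(n) != 1L)
    stop("budget terms must share one time axis", call. = FALSE)
  tsps <- lapply(terms, stats::tsp)
  ref <- tsps[[1]]
  ok <- vapply(tsps, function(tp) is.null(tp) == is.null(ref) &&
                 (is.null(tp) || isTRUE(all.equal(tp, ref))), logical(1))
  if (!all(ok)) stop("budget terms must share one time axis", call. = FALSE)
  structure(terms, class = "heat_budget_terms")
}

rhs_names <- c("xadv", "yadv", "zadv", "ldf", "zdf", "qnet")

#' Air-sea heat flux inputs for the storage term
#'
#' @param qns non-solar heat flux (latent + sensible + longwave), W m-2.
#' @param qsr solar (shortwave) flux, W m-2.
#' @param mld mixed-layer depth H, m (must be > 0; computed upstream with
#'   a 0.03 kg m-3 density criterion relative to 10 m).
#' @param f_penetration fraction of shortwave reaching the mixed-layer
#'   base, in `[0, 1]`.
#' @param rho0 seawater density, kg m-3 (default 1027).
#' @param cp specific heat capacity of seawater, J kg-1 K-1 (default 4000).
#' @return object of class `air_sea_flux`.
#' @export
air_sea_flux <- function(qns, qsr, mld, f_penetration = 0,
                         rho0 = 1027, cp = 4000) {
  if (any(mld <= 0, na.rm = TRUE))
    stop("mixed-layer depth must be positive", call. = FALSE)
  if (any(f_penetration < 0 | f_penetration > 1, na.rm = TRUE))
    stop("f_penetration must lie in [0, 1]", call. = FALSE)
  structure(list(qns = qns, qsr = qsr, mld = mld,
                 f_penetration = f_penetration, rho0 = rho0, cp = cp),
            class = "air_sea_flux")
}

#' Air-sea heat-flux storage term of the mixed-layer budget
#'
#' `Qnet = (Q_ns + Q_sr (1 - f)) / (rho0 cp H)`, converted from K s-1 to
#' degC day-1 (x 86400).
#'
#' @param flux an [air_sea_flux()] object.
#' @return series in degC day-1 (same shape as the flux inputs).
#' @export
qnet_storage <- function(flux) {
  stopifnot(inherits(flux, "air_sea_flux"))
  with(flux, (qns + qsr * (1 - f_penetration)) / (rho0 * cp * mld) * 86400)
}

#' Budget closure residual
#'
#' `tot` minus the sum of the six right-hand-side terms; identically zero
#' for budgets that close by construction.
#'
#' @param terms a `heat_budget_terms` object.
#' @return series in degC day-1.
#' @export
closure_residual <- function(terms) {
  stopifnot(inherits(terms, "heat_budget_terms"))
  terms$tot - (terms$xadv + terms$yadv + terms$zadv +
                 terms$ldf + terms$zdf + terms$qnet)
}

#' Q'/H' decomposition of the air-sea flux storage anomalies
#'
#' Splits the detrended anomaly of the storage term
#' `delta(Q / (rho0 cp H))` into the contribution of net surface
#' heat-flux anomalies acting on the climatological mixed-layer depth
#' (Q' term, `deltaQ / (rho0 cp Hbar)`), the contribution of mixed-layer
#' depth anomalies acting on the climatological heating/cooling (H' term,
#' `deltaH Qbar / (rho0 cp Hbar^2)`, entering with a minus sign), and a
#' residual defined as the exact remainder, so that
#' `qnet_ano = q_term - h_term + residual` holds to machine precision.
#' Anomalies (`delta`) are detrended + deseasonalized; the overbars are
#' 12-month climatologies, both from the [anomalies] pipeline.
#'
#' @param Q total net surface heat flux series, W m-2 (monthly `ts`).
#' @param H mixed-layer depth series, m (monthly `ts`, > 0).
#' @param rho0,cp constants as in [air_sea_flux()].
#' @return list of class `qnet_decomposition` with monthly `ts` components
#'   `q_term`, `h_term`, `residual`, `qnet_ano`, all in degC day-1.
#' @export
decompose_qnet <- function(Q, H, rho0 = 1027, cp = 4000) {
  if (any(H <= 0, na.rm = TRUE))
    stop("mixed-layer depth must be positive", call. = FALSE)
  clim_q <- monthly_climatology(Q)
  clim_h <- monthly_climatology(H)
  if (any(clim_h <= 0, na.rm = TRUE))
    stop("degenerate mixed-layer depth climatology", call. = FALSE)
  m <- as.integer(stats::cycle(Q))
  qbar <- clim_q[m]
  hbar <- clim_h[m]
  dq <- strip_attrs(detrended_anomalies(Q))
  dh <- strip_attrs(detrended_anomalies(H))
  storage <- Q / (rho0 * cp * H) * 86400
  qnet_ano <- strip_attrs(detrended_anomalies(storage))
  q_term <- dq / (rho0 * cp * hbar) * 86400
  h_term <- dh * qbar / (rho0 * cp * hbar^2) * 86400
  residual <- qnet_ano - q_term + h_term
  structure(list(q_term = q_term, h_term = h_term, residual = residual,
                 qnet_ano = qnet_ano),
            class = "qnet_decomposition")
}

strip_attrs <- function(x) {
  attr(x, "trend") <- NULL
  attr(x, "climatology") <- NULL
  attr(x, "provenance") <- NULL
  x
}

#' Relative contributions of budget terms to a composite anomaly
#'
#' At one composite lag, the anomalous warming (cooling) of the mixed
#' layer is the sum of the term anomalies with positive (negative)
#' values; each contributing term's percentage is `100 * term / total`,
#' so percentages always sum to 100 over the contributing terms. Terms of
#' the opposing sign are reported with their value but no percentage.
#'
#' @param term_values named numeric vector of per-term anomaly values at
#'   one lag (degC day-1), e.g. the six RHS terms plus a residual.
#' @param direction `"warming"` (positive terms contribute, default) or
#'   `"cooling"` (negative terms contribute).
#' @return data frame with columns `term`, `value`, `percentage` (NA for
#'   non-contributing terms).
#' @export
contribution_percentages <- function(term_values,
                                     direction = c("warming", "cooling")) {
  direction <- match.arg(direction)
  v <- unlist(term_values)
  if (is.null(names(v)) || any(names(v) == ""))
    stop("term values must be named", call. = FALSE)
  contributes <- if (direction == "warming") v > 0 else v < 0
  if (!any(contributes, na.rm = TRUE))
    stop(sprintf("no %s terms: %s contribution undefined", direction,
                 direction), call. = FALSE)
  total <- sum(v[which(contributes)])
  pct <- ifelse(contributes, 100 * v / total, NA_real_)
  data.frame(term = names(v), value = as.numeric(v),
             percentage = as.numeric(pct), row.names = NULL,
             stringsAsFactors = FALSE)
}
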