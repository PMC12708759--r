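#' Wind stress curl on a latitude-longitude grid
#'
#' Computes `curl(tau) = d(tauy)/dx - d(taux)/dy` with the spherical metric
#' `dx = R cos(phi) dlambda`, `dy = R dphi` (R = 6 371 000 m, angles in
#' radians). Centered differences in the interior, one-sided at the domain
#' edges; derivatives touching land or missing cells are set missing.
#'
#' @param taux,tauy zonal and meridional surface wind stress
#'   (`gridded_field`s on identical grids, N m-2).
#' @return `gridded_field` of curl values in N m-3.
#' @export
wind_stress_curl <- function(taux, tauy) {
  stopifnot(inherits(taux, "gridded_field"), inherits(tauy, "gridded_field"))
  if (!same_grid(taux, tauy))
    stop("taux and tauy must be on identical grids", call. = FALSE)
  R <- 6371000
  lam <- taux$lon * pi / 180
  phi <- taux$lat * pi / 180
  d <- dim(taux$values)

  dtauy_dlam <- diff_along(tauy$values, lam, dim = 3L)
  dtaux_dphi <- diff_along(taux$values, phi, dim = 2L)

  cosphi <- array(rep(cos(phi), each = d[1]), dim = d)
  curl <- dtauy_dlam / (R * cosphi) - dtaux_dphi / R
  gridded_field(curl, lat = taux$lat, lon = taux$lon, time = taux$time,
                name = "wind_stress_curl", units = "N m-3")
}

# centered finite differences along dim (2=lat, 3=lon) of [time,lat,lon],
# one-sided at the two edges; NA propagates from missing neighbors
diff_along <- function(arr, coord, dim) {
  n <- dim(arr)[dim]
  if (n < 2L) stop("need at least 2 points to differentiate", call. = FALSE)
  slice <- function(i) {
    if (dim == 2L) arr[, i, , drop = FALSE] else arr[, , i, drop = FALSE]
  }
  out <- array(NA_real_, dim(arr))
  assign_slice <- function(i, v) {
    if (dim == 2L) out[, i, ] <<- v else out[, , i] <<- v
  }
  for (i in seq_len(n)) {
    lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
    assign_slice(i, (slice(hi) - slice(lo)) / (coord[hi] - coord[lo]))
  }
  out
}

#' Ordered path of points along a coastline (or the equator)
#'
#' @param lat,lon point coordinates in path order.
#' @param labels strictly monotonic along-path coordinate in degrees;
#'   defaults to `lat` when latitude is strictly monotonic (a meridional
#'   coastal path), else to cumulative along-path distance in degrees.
#' @param name path name.
#' @return object of class `coastal_path`.
#' @export
coastal_path <- function(lat, lon, labels = NULL, name = "path") {
  stopifnot(length(lat) == length(lon), length(lat) >= 1L)
  if (is.null(labels)) {
    labels <- if (is_strictly_monotonic(lat) && length(lat) > 1L) lat
              else c(0, cumsum(sqrt(diff(lat)^2 + diff(lon)^2)))
  }
  if (!is_strictly_monotonic(labels))
    stop("path labels must be strictly monotonic", call. = FALSE)
  structure(list(lat = as.numeric(lat), lon = as.numeric(lon),
                 labels = as.numeric(labels), name = name),
            class = "coastal_path")
}

#' @export
print.coastal_path <- function(x, ...) {
  cat(sprintf("<coastal_path> %s: %d points, %.2f .. %.2f deg\n", x$name,
              length(x$lat), min(x$labels), max(x$labels)))
  invisible(x)
}

#' Read a coastal path from a YAML config
#' @param path YAML file with fields `name`, `lat`, `lon`, optional `labels`.
#' @return `coastal_path`.
#' @export
read_path <- function(path) {
  cfg <- yaml::read_yaml(path)
  coastal_path(lat = cfg$lat, lon = cfg$lon, labels = cfg$labels,
               name = cfg$name %||% "path")
}

#' Trace the coastline of a field's ocean mask as a path
#'
#' For each latitude row in `[lat_min, lat_max]` that contains both ocean
#' and land, the easternmost ocean cell west of the land is taken as the
#' coastal point; rows without land contribute the easternmost ocean cell.
#'
#' @param field a `gridded_field`.
#' @param lat_min,lat_max latitude range of the path.
#' @param name path name.
#' @return `coastal_path` ordered south to north.
#' @export
coastal_path_from_field <- function(field, lat_min = min(field$lat),
                                    lat_max = max(field$lat),
                                    name = "coast") {
  rows <- which(field$lat >= lat_min & field$lat <= lat_max)
  rows <- rows[order(field$lat[rows])]
  lats <- lons <- numeric(0)
  for (i in rows) {
    oc <- which(field$mask[i, ])
    if (length(oc) == 0L) next
    land <- which(!field$mask[i, ])
    j <- if (length(land) > 0) {
      west <- oc[field$lon[oc] < min(field$lon[land])]
      if (length(west) == 0L) next
      west[which.max(field$lon[west])]
    } else oc[which.max(field$lon[oc])]
    lats <- c(lats, field$lat[i]); lons <- c(lons, field$lon[j])
  }
  if (length(lats) == 0L) stop("no coastal points found", call. = FALSE)
  coastal_path(lats, lons, name = name)
}

#' Band-average a field along a path
#'
#' For each path point, the cos(latitude)-weighted mean over ocean cells
#' whose centers lie within `band_width` degrees (plain degree distance
#' `sqrt(dlat^2 + dlon^2)`) of the point, per time step. A point with no
#' ocean cell in range yields a missing column.
#'
#' @param field a `gridded_field`.
#' @param path a `coastal_path`.
#' @param band_width search radius in degrees.
#' @return numeric matrix `[time, position]` with attributes `positions`
#'   (path labels) and `time`.
#' @export
extract_along_path <- function(field, path, band_width) {
  stopifnot(inherits(field, "gridded_field"), inherits(path, "coastal_path"),
            band_width > 0)
  if (any(path$lat < min(field$lat) - band_width |
          path$lat > max(field$lat) + band_width))
    stop("path points outside the grid domain", call. = FALSE)
  nlat <- length(field$lat); nlon <- length(field$lon)
  cell_lat <- rep(field$lat, times = nlon)
  cell_lon <- rep(field$lon, each = nlat)
  w_all <- cos(cell_lat * pi / 180)
  vm <- field_matrix(field)
  ocean <- as.vector(field$mask)

  out <- matrix(NA_real_, nrow(vm), length(path$lat))
  for (p in seq_along(path$lat)) {
    dist <- sqrt((cell_lat - path$lat[p])^2 + (cell_lon - path$lon[p])^2)
    sel <- ocean & dist <= band_width
    if (!any(sel)) next
    v <- vm[, sel, drop = FALSE]
    wm <- matrix(w_all[sel], nrow(v), sum(sel), byrow = TRUE)
    wm[is.na(v)] <- NA
    den <- rowSums(wm, na.rm = TRUE)
    out[, p] <- ifelse(den > 0, rowSums(v * wm, na.rm = TRUE) / den,
                       NA_real_)
  }
  structure(out, positions = path$labels, time = field$time)
}
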