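#' Analysis regions
#'
#' A region is either a latitude/longitude box or a coastal band: ocean
#' cells within `band_width` degrees of longitude westward of the nearest
#' coastline cell at the same latitude, restricted to `[lat_min, lat_max]`.
#' The coastal-band reading suits quasi-meridional eastern-boundary coasts
#' such as NW Africa; the geometry (longitude offset vs point distance) is
#' the package's documented choice.
#'
#' @param kind `"latlon_box"` or `"coastal_band"`.
#' @param lat_min,lat_max latitude bounds, degrees north.
#' @param lon_min,lon_max longitude bounds (box only), degrees east.
#' @param band_width band width in degrees of longitude (coastal band only).
#' @param name optional region name.
#' @return An object of class `region`.
#' @export
region <- function(kind = c("latlon_box", "coastal_band"),
                   lat_min, lat_max, lon_min = NULL, lon_max = NULL,
                   band_width = NULL, name = NULL) {
  kind <- match.arg(kind)
  if (lat_min >= lat_max) stop("lat_min must be < lat_max", call. = FALSE)
  if (kind == "latlon_box") {
    if (is.null(lon_min) || is.null(lon_max))
      stop("a latlon_box needs lon_min and lon_max", call. = FALSE)
    if (lon_min >= lon_max) stop("lon_min must be < lon_max", call. = FALSE)
  } else {
    if (is.null(band_width) || band_width <= 0)
      stop("a coastal_band needs band_width > 0", call. = FALSE)
  }
  structure(list(kind = kind, name = name, lat_min = lat_min,
                 lat_max = lat_max, lon_min = lon_min, lon_max = lon_max,
                 band_width = band_width),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  if (x$kind == "latlon_box")
    cat(sprintf("<region> %s box %g..%gN %g..%gE\n",
                x$name %||% "", x$lat_min, x$lat_max, x$lon_min, x$lon_max))
  else
    cat(sprintf("<region> %s coastal band %g..%gN, width %g deg\n",
                x$name %||% "", x$lat_min, x$lat_max, x$band_width))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Built-in region registry
#'
#' Ships the regions used throughout the analysis: the coastal Dakar Nino
#' Index band (CDNI, 9-18N, 2 deg coastal band), the Nino3.4 box
#' (5S-5N, 170W-120W), the North Atlantic box used for the AMV index
#' (0-60N, 80W-0E) and the 60S-60N global band.
#'
#' @return named list of `region` objects.
#' @export
region_registry <- function() {
  list(
    CDNI = region("coastal_band", 9, 18, band_width = 2, name = "CDNI"),
    nino34 = region("latlon_box", -5, 5, -170, -120, name = "nino34"),
    amv_north_atlantic = region("latlon_box", 0, 60, -80, 0,
                                name = "amv_north_atlantic"),
    global_band = region("latlon_box", -60, 60, -180, 179.999,
                         name = "global_band")
  )
}

#' Read named region definitions from a YAML config
#'
#' Each top-level key is a region name mapping to fields `kind`,
#' `lat_min`, `lat_max` and either `lon_min`/`lon_max` or `band_width`.
#'
#' @param path YAML file.
#' @return named list of `region` objects.
#' @export
read_regions <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(nm) {
    r <- cfg[[nm]]
    region(kind = r$kind, lat_min = r$lat_min, lat_max = r$lat_max,
           lon_min = r$lon_min, lon_max = r$lon_max,
           band_width = r$band_width, name = nm)
  })
  stats::setNames(out, names(cfg))
}

resolve_region <- function(region) {
  if (is.character(region)) {
    reg <- region_registry()
    if (!region %in% names(reg))
      stop("unknown region name: ", region, call. = FALSE)
    return(reg[[region]])
  }
  stopifnot(inherits(region, "region"))
  region
}

#' Boolean lat x lon membership mask for a region
#'
#' Box regions select ocean cells whose centers fall inside the box
#' (no partial-cell weighting). Coastal bands select, per latitude row,
#' ocean cells within `band_width` degrees of longitude westward of the
#' westernmost land cell in that row (rows without land use the eastern
#' domain edge as the coast). Always intersected with the ocean mask.
#'
#' @param field a `gridded_field`.
#' @param region a `region` or a name in [region_registry()].
#' @return logical `[lat, lon]` matrix.
#' @export
region_mask <- function(field, region) {
  region <- resolve_region(region)
  nlat <- length(field$lat); nlon <- length(field$lon)
  in_lat <- field$lat >= region$lat_min & field$lat <= region$lat_max
  m <- matrix(FALSE, nlat, nlon)

  if (region$kind == "latlon_box") {
    in_lon <- field$lon >= region$lon_min & field$lon <= region$lon_max
    m <- outer(in_lat, in_lon, `&`)
  } else {
    dlon <- if (nlon > 1) stats::median(abs(diff(field$lon))) else 1
    for (i in which(in_lat)) {
      row_ocean <- field$mask[i, ]
      land <- which(!row_ocean)
      coast_lon <- if (length(land) > 0) min(field$lon[land])
                   else max(field$lon) + dlon
      sel <- row_ocean & field$lon < coast_lon &
        (coast_lon - field$lon) <= region$band_width
      m[i, ] <- sel
    }
  }
  m <- m & field$mask
  if (!any(m))
    stop("region does not intersect the ocean grid (empty region)",
         call. = FALSE)
  m
}

#' Area-weighted region-mean time series
#'
#' Per-time-step mean over the region's ocean cells, weighted by
#' `cos(latitude)`; missing cells are excluded per time step. Returns a
#' monthly `ts`; a time step with no valid cell is `NA`.
#'
#' @inheritParams region_mask
#' @return monthly `ts` on the field's time axis.
#' @export
area_mean <- function(field, region) {
  m <- region_mask(field, region)
  w2d <- matrix(cos(field$lat * pi / 180), length(field$lat),
                length(field$lon))
  w <- as.vector(w2d)[as.vector(m)]
  v <- field_matrix(field)[, as.vector(m), drop = FALSE]
  wm <- matrix(w, nrow(v), length(w), byrow = TRUE)
  wm[is.na(v)] <- NA
  num <- rowSums(v * wm, na.rm = TRUE)
  den <- rowSums(wm, na.rm = TRUE)
  out <- ifelse(den > 0, num / den, NA_real_)
  as_month_ts(out, field$time)
}
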