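#' Read and write gridded monthly fields
#'
#' Fields are serialized to a self-describing plain-text JSON container:
#' coordinate vectors, a `"YYYY-MM"` time axis, the ocean mask, and one or
#' more named variables with units. Missing values are stored as JSON
#' `null` (the `_FillValue` role). Values are written with full double
#' precision so that a write/read round trip is the identity.
#'
#' @param field a `gridded_field` (or, for `write_fields`, a list of them
#'   sharing one grid and time axis).
#' @param path file path (conventionally `.json`).
#' @return `write_field` returns `path` invisibly; `read_field` returns a
#'   `gridded_field`.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "gridded_field"))
  write_fields(stats::setNames(list(field), field$name), path)
}

#' @rdname write_field
#' @param fields named list of `gridded_field`s on a common grid.
#' @export
write_fields <- function(fields, path) {
  stopifnot(is.list(fields), length(fields) >= 1L)
  ref <- fields[[1]]
  for (f in fields) {
    if (!same_grid(f, ref))
      stop("all fields in one file must share grid and time axis",
           call. = FALSE)
  }
  vars <- lapply(fields, function(f) {
    list(units = f$units, values = as.vector(f$values))
  })
  obj <- list(
    format = "upwellr-grid-1",
    dims = c(time = length(ref$time), lat = length(ref$lat),
             lon = length(ref$lon)),
    lat = ref$lat, lon = ref$lon,
    time = format(ref$time, "%Y-%m"),
    mask = as.vector(ref$mask),
    variables = vars
  )
  jsonlite::write_json(obj, path, digits = I(17), na = "null",
                       auto_unbox = FALSE, pretty = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @param variable name of the variable to extract; default: the first one.
#' @export
read_field <- function(path, variable = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "upwellr-grid-1"))
    stop("not an upwellr gridded-field file: ", path, call. = FALSE)
  if (is.null(variable)) variable <- names(obj$variables)[1]
  if (!variable %in% names(obj$variables))
    stop(sprintf("variable '%s' not found in %s (has: %s)", variable, path,
                 paste(names(obj$variables), collapse = ", ")),
         call. = FALSE)
  time <- as.Date(paste0(obj$time, "-01"))
  check_monthly_axis(time)
  d <- c(length(time), length(obj$lat), length(obj$lon))
  v <- obj$variables[[variable]]
  vals <- as.numeric(v$values)
  if (length(vals) != prod(d))
    stop("value length does not match dims in ", path, call. = FALSE)
  gridded_field(array(vals, dim = d), lat = obj$lat, lon = obj$lon,
                time = time, name = variable,
                units = if (is.null(v$units)) "" else v$units,
                mask = matrix(obj$mask, d[2], d[3]))
}

#' List the variables stored in a gridded-field file
#' @param path file path written by [write_field()] / [write_fields()].
#' @return character vector of variable names.
#' @export
field_file_variables <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  names(obj$variables)
}
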