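test_that("field construction validates axes and enforces the mask", {
  f <- make_coastal_field()
  expect_s3_class(f, "gridded_field")
  expect_true(all(is.na(f$values[, , f$lon >= 0])))

  expect_error(gridded_field(array(1, c(3, 2, 2)), lat = c(1, 1),
                             lon = c(0, 1), time = month_seq(2003, 1, 3)),
               "monotonic")
  bad_time <- month_seq(2003, 1, 24)[-5]
  expect_error(gridded_field(array(1, c(23, 2, 2)), lat = 1:2,
                             lon = c(-2, -1), time = bad_time),
               "contiguous monthly")
})

test_that("write_field -> read_field round trip is the identity", {
  set.seed(42)
  f <- make_uniform_field(n_months = 24, nlat = 10, nlon = 10)
  f$values[] <- rnorm(length(f$values))
  f$values[, 3, 4] <- NA  # a masked-out cell survives the trip
  f <- gridded_field(f$values, f$lat, f$lon, f$time, name = "npp",
                     units = "gC m-2 day-1")
  path <- withr::local_tempfile(fileext = ".json")
  write_field(f, path)
  g <- read_field(path, "npp")
  expect_identical(g$values, f$values)
  expect_identical(g$lat, f$lat)
  expect_identical(g$lon, f$lon)
  expect_identical(g$time, f$time)
  expect_identical(g$units, f$units)
  expect_identical(g$mask, f$mask)
  expect_equal(dim(g), c(24L, 10L, 10L))

  expect_error(read_field(path, "nope"), "not found")
  expect_error(read_field(tempfile()), "file not found")
})

test_that("multi-variable files keep variables separate", {
  a <- make_uniform_field(1, name = "a")
  b <- make_uniform_field(2, name = "b")
  path <- withr::local_tempfile(fileext = ".json")
  write_fields(list(a = a, b = b), path)
  expect_equal(field_file_variables(path), c("a", "b"))
  expect_equal(read_field(path, "b")$values[1, 1, 1], 2)
})

test_that("region masks: boxes by cell-center containment, bands by
           longitude offset from the coast", {
  f <- make_coastal_field()
  # box covering the whole grid equals the ocean mask
  full <- region_mask(f, region("latlon_box", -90, 90, -180, 179))
  expect_identical(full, f$mask)

  # 0.25-degree grid, meridional coast at lon 0, band 2 deg -> 8 cells/row
  lat <- seq(10.125, 12.875, by = 0.25)
  lon <- seq(-4.875, 0.875, by = 0.25)
  mask <- outer(rep(TRUE, length(lat)), lon < 0, `&`)
  g <- gridded_field(array(1, c(24, length(lat), length(lon))), lat, lon,
                     month_seq(2003, 1, 24), mask = mask)
  band <- region_mask(g, region("coastal_band", 10, 13, band_width = 2))
  expect_true(all(rowSums(band) == 8))
  # selected cells are the 8 immediately west of the coast
  expect_true(all(g$lon[colSums(band) > 0] >= -1.875 &
                    g$lon[colSums(band) > 0] < 0))

  # CDNI band is inside the 9-18N box (set intersection property)
  cf <- make_coastal_field()
  cdni <- region_mask(cf, "CDNI")
  box <- region_mask(cf, region("latlon_box", 9, 18, -180, 179))
  expect_identical(cdni & box, cdni)

  # box fully on land -> empty-region error
  expect_error(region_mask(cf, region("latlon_box", 9, 18, 0, 1)),
               "empty")
})

test_that("area_mean: cos-latitude weighting, uniform exactness, NA policy", {
  f <- make_uniform_field(3.7)
  s <- area_mean(f, region("latlon_box", -90, 90, -180, 179))
  expect_equal(as.numeric(s), rep(3.7, 24))
  expect_equal(stats::frequency(s), 12)

  # two latitudes 0 and 60 with values 0 and 1 -> weighted mean 1/3
  v <- array(0, c(12, 2, 1)); v[, 2, 1] <- 1
  g <- gridded_field(v, lat = c(0, 60), lon = -10,
                     time = month_seq(2003, 1, 12))
  s <- area_mean(g, region("latlon_box", -90, 90, -180, 179))
  expect_equal(as.numeric(s), rep(cos(pi / 3) / (1 + cos(pi / 3)), 12),
               tolerance = 1e-12)
  expect_equal(as.numeric(s)[1], 1 / 3, tolerance = 1e-12)

  # one cell missing at t=5: mean over the remaining cells only
  v2 <- array(1, c(12, 2, 2)); v2[5, 1, 1] <- NA; v2[, 2, ] <- 2
  h <- gridded_field(v2, lat = c(0, 60), lon = c(-10, -9),
                     time = month_seq(2003, 1, 12))
  s2 <- area_mean(h, region("latlon_box", -90, 90, -180, 179))
  w0 <- cos(0); w60 <- cos(pi / 3)
  expect_equal(as.numeric(s2)[5],
               (1 * w0 + 2 * 2 * w60) / (w0 + 2 * w60), tolerance = 1e-12)
})

test_that("wind stress curl matches analytic derivatives", {
  R <- 6371000
  lat <- seq(0.5, 20.5, by = 1)
  lon <- seq(-20.5, -0.5, by = 1)
  nt <- 24
  mk <- function(fun) {
    v <- array(0, c(nt, length(lat), length(lon)))
    for (i in seq_along(lat)) for (j in seq_along(lon))
      v[, i, j] <- fun(lat[i], lon[j])
    gridded_field(v, lat, lon, month_seq(2003, 1, nt), units = "N m-2")
  }
  zero <- mk(function(la, lo) 0)

  # uniform stress -> identically zero curl
  curl0 <- wind_stress_curl(mk(function(la, lo) 0.1),
                            mk(function(la, lo) -0.2))
  expect_equal(max(abs(curl0$values)), 0)

  # tauy = a * lambda (radians) -> curl = a / (R cos(phi))
  a <- 0.05
  curl1 <- wind_stress_curl(zero, mk(function(la, lo) a * lo * pi / 180))
  expected <- a / (R * cos(lat * pi / 180))
  for (i in seq_along(lat))
    expect_equal(curl1$values[1, i, 5], expected[i], tolerance = 1e-10)

  # taux = b * phi (radians) -> curl = -b / R
  b <- 0.08
  curl2 <- wind_stress_curl(mk(function(la, lo) b * la * pi / 180), zero)
  expect_equal(as.numeric(curl2$values[3, 7, 9]), -b / R,
               tolerance = 1e-10)

  # grid mismatch -> alignment error
  other <- make_uniform_field(nlat = 3, nlon = 3)
  expect_error(wind_stress_curl(zero, other), "identical grids")
})

test_that("extract_along_path band-averages around each point", {
  f <- make_coastal_field()
  # field equal to the latitude value
  for (i in seq_along(f$lat)) f$values[, i, f$lon < 0] <- f$lat[i]
  path <- coastal_path(lat = c(5.5, 10.5, 15.5), lon = rep(-0.5, 3))
  m <- extract_along_path(f, path, band_width = 1)
  # column i equals the path latitude within one grid cell
  expect_true(all(abs(m[1, ] - c(5.5, 10.5, 15.5)) <= 1))

  # uniform field -> constant array
  u <- make_coastal_field()
  mu <- extract_along_path(u, path, band_width = 1)
  expect_true(all(mu == 1))

  # a point too far offshore with a tiny band -> missing column
  far <- coastal_path(lat = 5.5, lon = -5.25)
  g <- make_coastal_field(lat = seq(0.5, 24.5, 1), lon = seq(-9.5, 0.5, 1))
  mfar <- extract_along_path(g, far, band_width = 0.2)
  expect_true(all(is.na(mfar)))
})

test_that("coastal_path_from_field traces the easternmost ocean cells", {
  f <- make_coastal_field()
  p <- coastal_path_from_field(f, lat_min = 9, lat_max = 18)
  expect_true(all(p$lon == -0.5))
  expect_equal(p$lat, seq(9.5, 17.5, by = 1))
})

test_that("region YAML configs round-trip through read_regions", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "CDNI:", "  kind: coastal_band", "  lat_min: 9", "  lat_max: 18",
    "  band_width: 2",
    "box:", "  kind: latlon_box", "  lat_min: -5", "  lat_max: 5",
    "  lon_min: -170", "  lon_max: -120"), path)
  regs <- read_regions(path)
  expect_equal(regs$CDNI$band_width, 2)
  expect_equal(regs$box$lon_min, -170)
  f <- make_coastal_field()
  expect_identical(region_mask(f, regs$CDNI), region_mask(f, "CDNI"))
})
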