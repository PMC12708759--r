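test_that("config validation enforces the stated invariants", {
  expect_error(synthetic_config(n_years = 2), "n_years")
  expect_error(synthetic_config(ar1_phi = 1), "ar1_phi")
  expect_error(synthetic_config(
    events = data.frame(start = 1, duration = 0, sign = -1,
                        amplitude = 2)), "duration")
  expect_error(synthetic_config(
    n_years = 3,
    events = data.frame(start = 35, duration = 3, sign = -1,
                        amplitude = 2)), "past the time axis")
})

test_that("identical seed gives bit-identical fields; different seeds differ", {
  cfg <- tiny_config()
  a <- generate_fields(cfg, seed = 7)
  b <- generate_fields(cfg, seed = 7)
  expect_identical(a$fields$npp$values, b$fields$npp$values)
  expect_identical(a$fields$sst$values, b$fields$sst$values)
  c <- generate_fields(cfg, seed = 8)
  expect_false(identical(a$fields$npp$values, c$fields$npp$values))
})

test_that("zero noise, zero trend, no events -> pure climatology", {
  vars <- default_variables()["npp"]
  vars$npp$noise_sd <- 0
  vars$npp$trend <- 0
  cfg <- synthetic_config(n_years = 4, lat = c(9.5, 10.5),
                          lon = c(-1.5, -0.5, 0.5), variables = vars,
                          events = NULL, wave = NULL)
  gen <- generate_fields(cfg, seed = 1)
  f <- gen$fields$npp
  clim <- gen$truth$climatology$npp
  m <- calendar_months(f)
  expect_equal(f$values[, 1, 1], clim[m], tolerance = 1e-12)
  # deseasonalized anomalies identically zero
  a <- deseasonalize(f)
  expect_equal(max(abs(a$values), na.rm = TRUE), 0, tolerance = 1e-12)
})

test_that("generated NPP climatology peaks in the configured month", {
  cfg <- tiny_config(n_years = 30)
  gen <- generate_fields(cfg, seed = 4)
  clim <- monthly_climatology(area_mean(gen$fields$npp,
                                        region("latlon_box", 0, 90,
                                               -180, 179)))
  expect_equal(unname(which.max(clim)), 4L)  # MAM maximum, April peak
})

test_that("anomaly noise matches the configured AR(1) model at n=200", {
  vars <- default_variables()["npp"]
  cfg <- synthetic_config(n_years = 200, lat = 9.5,
                          lon = c(-1.5, -0.5, 0.5), variables = vars,
                          ar1_phi = 0.3, events = NULL, wave = NULL)
  gen <- generate_fields(cfg, seed = 9)
  a <- detrended_anomalies(gen$fields$npp)
  x <- a$values[, 1, 1]
  expect_lt(abs(mean(x)), 0.05 * vars$npp$noise_sd)
  r1 <- stats::cor(x[-1], x[-length(x)])
  expect_lt(abs(r1 - 0.3), 0.05)
  expect_lt(abs(stats::sd(x) - vars$npp$noise_sd),
            0.05 * vars$npp$noise_sd)
})

test_that("event injection only touches the configured windows and band", {
  ev <- data.frame(start = 50, duration = 3, sign = -1, amplitude = 2)
  cfg_ev <- synthetic_config(events = ev, wave = NULL)
  cfg_no <- synthetic_config(events = NULL, wave = NULL)
  with_ev <- generate_fields(cfg_ev, seed = 6)
  without <- generate_fields(cfg_no, seed = 6)
  d <- with_ev$fields$npp$values - without$fields$npp$values
  changed <- which(apply(abs(d) > 0, 1, any, na.rm = TRUE))
  expect_equal(changed, 50:52)
  # spatial footprint is the CDNI band
  band <- region_mask(without$fields$npp, "CDNI")
  touched <- apply(abs(d[50:52, , , drop = FALSE]) > 0, c(2, 3), any)
  touched[is.na(touched)] <- FALSE
  expect_identical(touched, band)
  # SST carries the opposite sign
  dsst <- with_ev$fields$sst$values - without$fields$sst$values
  expect_true(all(dsst[51, , ][band] > 0))  # low NPP event warms SST
  expect_true(all(d[51, , ][band] < 0))
})

test_that("half-sine pulses have an unambiguous early-tie peak", {
  expect_equal(half_sine(3), sin(pi * c(0.5, 1.5, 2.5) / 3),
               tolerance = 1e-12)
  expect_equal(which.max(half_sine(3)), 2L)
  expect_equal(which.max(half_sine(2)), 1L)  # symmetric tie -> earlier
})

test_that("spatially correlated mode produces cross-cell correlation", {
  base <- tiny_config(n_years = 60)
  iid <- generate_fields(base, seed = 3)
  cor_cfg <- synthetic_config(n_years = 60, lat = c(9.5, 10.5),
                              lon = c(-2.5, -1.5, -0.5, 0.5),
                              variables = default_variables()[c("npp",
                                                                "sst")],
                              events = NULL, wave = NULL,
                              spatial_corr = TRUE)
  blurred <- generate_fields(cor_cfg, seed = 3)
  cor_of <- function(gen) {
    a <- detrended_anomalies(gen$fields$npp)
    stats::cor(a$values[, 1, 1], a$values[, 2, 1])
  }
  expect_gt(cor_of(blurred), cor_of(iid) + 0.2)
})

test_that("generate_budget closes exactly and emits consistent fluxes", {
  cfg <- tiny_config(n_years = 10)
  bgt <- generate_budget(cfg, seed = 2)
  res <- closure_residual(bgt$terms)
  expect_equal(max(abs(res)), 0, tolerance = 1e-15)

  # qnet really is Q/(rho0 cp H) in degC/day
  expect_equal(as.numeric(bgt$terms$qnet),
               as.numeric(bgt$Q / (1027 * 4000 * bgt$H) * 86400),
               tolerance = 1e-12)

  # determinism
  bgt2 <- generate_budget(cfg, seed = 2)
  expect_identical(as.numeric(bgt2$terms$tot), as.numeric(bgt$terms$tot))

  # H <= 0 configs are rejected
  expect_error(
    generate_budget(cfg, seed = 2,
                    budget_params = list(mld = list(mean = 0.5,
                                                    amplitude = 2,
                                                    peak_month = 2,
                                                    noise_sd = 0))),
    "zero or below")
})

test_that("Q'-dominated config yields var(q_term) > var(h_term)", {
  cfg <- tiny_config(n_years = 20)
  # sigma_Q = 25 W/m2 vs sigma_H * Qbar / Hbar ~ 2 * 180/30 = 12 W/m2
  bgt <- generate_budget(cfg, seed = 12)
  qh <- decompose_qnet(bgt$Q, bgt$H)
  expect_gt(stats::var(qh$q_term), stats::var(qh$h_term))

  # and the reverse config flips the ordering
  bgt2 <- generate_budget(cfg, seed = 12, budget_params = list(
    qns = list(mean = -60, amplitude = 40, peak_month = 12, noise_sd = 0.5),
    qsr = list(mean = 220, amplitude = 50, peak_month = 6, noise_sd = 0.5),
    mld = list(mean = 30, amplitude = 10, peak_month = 2, noise_sd = 6)))
  qh2 <- decompose_qnet(bgt2$Q, bgt2$H)
  expect_gt(stats::var(qh2$h_term), stats::var(qh2$q_term))
})

test_that("write_synthetic_run serializes fields, truth and events", {
  dir <- withr::local_tempdir()
  gen <- generate_fields(synthetic_config(), seed = 1)
  paths <- write_synthetic_run(gen, dir)
  f <- read_field(paths[["fields"]], "npp")
  expect_identical(f$values, gen$fields$npp$values)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$wave_speed, 5)
  ev <- utils::read.csv(paths[["events"]])
  expect_equal(nrow(ev), 9)
})
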