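test_that("CSV with all channels reads in time order", {
  rec <- read_records(full_record_csv())
  expect_equal(nrow(rec), 3)
  expect_s3_class(rec$timestamp, "POSIXct")
  expect_true(!is.unsorted(rec$timestamp))
  expect_equal(rec$ta, c(25.0, 25.2, 25.4))
  expect_equal(rec$v, c(0.0, 1.7, 0.3))
})

test_that("missing wind column yields absent channel, not zero", {
  rec <- read_records(indoor_record_csv())
  expect_true(all(is.na(rec$v)))
  expect_false(any(rec$v %in% 0))
})

test_that("out-of-range humidity and malformed timestamps are row-addressed errors", {
  bad_rh <- write_fixture_csv(c(
    "timestamp,device_id,ta_c,rh_pct,tg_c,lw_wm2,tirt_c,light_lx,wind_ms",
    "2021-08-08T10:00:00Z,d,25,50,,,,0,",
    "2021-08-08T10:05:00Z,d,25,120,,,,0,"
  ))
  expect_error(read_records(bad_rh), "\\[0, 100\\].*2")
  bad_ts <- write_fixture_csv(c(
    "timestamp,device_id,ta_c,rh_pct,tg_c,lw_wm2,tirt_c,light_lx,wind_ms",
    "not-a-time,d,25,50,,,,0,"
  ))
  expect_error(read_records(bad_ts), "timestamp")
})

test_that("vapor pressure follows the Magnus curve", {
  expect_equal(vapor_pressure(31, 0), 0)
  expect_equal(vapor_pressure(20, 100), 23.32596, tolerance = 1e-6)
  expect_equal(vapor_pressure(25, 50), 15.800285, tolerance = 1e-6)
  expect_error(vapor_pressure(20, 120), "\\[0, 100\\]")
})

test_that("vapor pressure is monotonic in temperature and humidity", {
  ta <- seq(-10, 45, by = 2.5)
  expect_true(all(diff(vapor_pressure(ta, 60)) > 0))
  rh <- seq(0, 100, by = 5)
  expect_true(all(diff(vapor_pressure(20, rh)) > 0))
  expect_equal(vapor_pressure(ta, 100), saturation_vapor_pressure(ta))
})

test_that("effective wind floors at 0.1 m/s", {
  expect_equal(effective_wind(NULL), 0.1)
  expect_equal(effective_wind(NA_real_), 0.1)
  expect_equal(effective_wind(0), 0.1)
  expect_equal(effective_wind(1.7), 1.7)
  expect_error(effective_wind(-0.2), "non-negative")
  v <- c(NA, 0, 0.05, 0.3, 2)
  expect_true(all(effective_wind(v) >= 0.1))
})

test_that("alignment pairs a 10-min reference against a 5-min device grid", {
  a <- grid_records("2021-08-08 10:00:00", 5, 12)   # device, 5 min
  b <- grid_records("2021-08-08 10:00:00", 10, 6)   # reference, 10 min
  pairs <- align_series(a, b, tolerance = 150)
  expect_equal(nrow(pairs), 6)                      # every reference paired
  expect_equal(length(unique(pairs$a)), 6)          # half the device unused
  expect_equal(pairs$a, seq(1, 11, by = 2))

  same <- align_series(a, a, tolerance = 150)
  expect_equal(same$a, same$b)

  disjoint <- align_series(a, grid_records("2021-08-09 10:00:00", 10, 4))
  expect_equal(nrow(disjoint), 0)
  expect_equal(nrow(align_series(a[0, ], b)), 0)
})

test_that("write/read round-trip is lossless at 3-decimal precision", {
  rec <- read_records(full_record_csv())
  rec <- derive_records(rec)
  out <- tempfile(fileext = ".csv")
  write_records(rec, out)
  back <- read_records(out)
  for (ch in c("ta", "rh", "tg", "light", "v")) {
    expect_equal(back[[ch]], round(rec[[ch]], 3), tolerance = 1e-9)
  }
  header <- strsplit(readLines(out, n = 1), ",")[[1]]
  expect_equal(header[1:9],
               c("timestamp", "device_id", "ta_c", "rh_pct", "tg_c",
                 "lw_wm2", "tirt_c", "light_lx", "wind_ms"))
  expect_true(all(c("vp_hpa", "sw_wm2", "v_eff_ms") %in% header))

  empty <- tempfile(fileext = ".csv")
  write_records(rec[0, ], empty)
  expect_equal(length(readLines(empty)), 1L)  # header only
  expect_equal(nrow(read_records(empty)), 0L)
})

test_that("deriving fills the lw/tirt complement consistently", {
  rec <- derived_one()
  expect_equal(lw_from_brightness(rec$tirt), rec$lw, tolerance = 1e-9)
  rec2 <- derive_records(data.frame(
    timestamp = as.POSIXct("2021-08-08 10:00:00", tz = "UTC"),
    device_id = "d", ta = 25, rh = 50, tg = NA_real_, lw = NA_real_,
    tirt = 26.85, light = 0, v = NA_real_))
  expect_equal(rec2$lw, 459.27, tolerance = 1e-6)
})
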