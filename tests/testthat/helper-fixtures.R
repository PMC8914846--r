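# Shared fixtures, built in code at test time.

# Write a small canonical CSV and return its path.
write_fixture_csv <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}

full_record_csv <- function() {
  write_fixture_csv(c(
    "timestamp,device_id,ta_c,rh_pct,tg_c,lw_wm2,tirt_c,light_lx,wind_ms",
    "2021-08-08T10:00:00Z,dev-1,25.0,50.0,27.5,430.0,,1200,0.0",
    "2021-08-08T10:05:00Z,dev-1,25.2,49.5,27.8,432.0,,1500,1.7",
    "2021-08-08T10:10:00Z,dev-1,25.4,49.0,28.1,434.0,,1800,0.3"
  ))
}

indoor_record_csv <- function() {
  write_fixture_csv(c(
    "timestamp,device_id,ta_c,rh_pct,tg_c,lw_wm2,tirt_c,light_lx",
    "2021-08-08T22:00:00Z,dev-2,22.0,55.0,22.1,420.0,,0",
    "2021-08-08T22:05:00Z,dev-2,21.9,55.2,22.0,419.5,,0"
  ))
}

# Regular time grids as minimal record frames for alignment tests.
grid_records <- function(start, step_min, n, device = "g") {
  t0 <- as.POSIXct(start, tz = "UTC")
  data.frame(timestamp = t0 + (seq_len(n) - 1) * step_min * 60,
             device_id = device, ta = 20, rh = 50, tg = NA_real_,
             lw = NA_real_, tirt = NA_real_, light = 0, v = NA_real_,
             stringsAsFactors = FALSE)
}

# One derived record with every channel present.
derived_one <- function(ta = 25, rh = 50, tg = 27, lw = 430, light = 1000,
                        v = NA_real_) {
  derive_records(data.frame(
    timestamp = as.POSIXct("2021-08-08 10:00:00", tz = "UTC"),
    device_id = "dev", ta = ta, rh = rh, tg = tg, lw = lw,
    tirt = NA_real_, light = light, v = v, stringsAsFactors = FALSE))
}
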