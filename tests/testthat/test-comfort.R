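# Expected states/PET values below were computed with the independent
# Python coding of the same three-node balance (tools/pet_oracle.py) and
# frozen; pet-oracle-grid.csv holds the 50-point oracle grid.

test_that("energy balance at neutral conditions matches the oracle state", {
  st <- solve_energy_balance(22, 12, 22, 0.1)
  expect_equal(st$t_core, 36.720129, tolerance = 1e-4)
  expect_equal(st$t_skin, 28.119207, tolerance = 1e-4)
  expect_equal(st$t_clothing, 24.493039, tolerance = 1e-4)
  expect_lt(max(abs(st$residuals)), 1e-3)
  expect_true(st$t_core > 30 && st$t_core < 45)
  expect_lt(st$t_skin, st$t_core)
})

test_that("skin temperature rises monotonically with radiant temperature", {
  tmrt <- seq(20, 60, by = 5)
  tsk <- vapply(tmrt,
                function(tr) solve_energy_balance(25, 12, tr, 0.1)$t_skin,
                numeric(1))
  expect_true(all(diff(tsk) > 0))
})

test_that("the balance solver is deterministic", {
  a <- solve_energy_balance(28, 15, 35, 0.3)
  b <- solve_energy_balance(28, 15, 35, 0.3)
  expect_identical(a, b)
})

test_that("PET reproduces the reference environment identity", {
  for (T in c(10, 15, 20, 25, 30, 35)) {
    expect_lt(abs(pet(T, 12, T, 0.1) - T), 0.5)
  }
})

test_that("PET agrees with the independent oracle on the input grid", {
  grid <- utils::read.csv(test_path("pet-oracle-grid.csv"))
  got <- pet(grid$ta, grid$vp, grid$tmrt, grid$v)
  expect_lt(max(abs(got - grid$pet)), 0.1)
})

test_that("PET increases with radiant and air temperature, hot case above air", {
  expect_gt(pet(25, 15, 45, 0.1), 25)
  tmrt <- seq(20, 55, by = 5)
  p1 <- pet(rep(25, length(tmrt)), 12, tmrt, 0.1)
  expect_true(all(diff(p1) > 0))
  ta <- seq(16, 36, by = 4)
  p2 <- pet(ta, 12, ta, 0.1)
  expect_true(all(diff(p2) > 0))
})

test_that("raising wind changes PET monotonically in the warm regime", {
  v <- c(0.1, 0.3, 0.6, 1.0)
  p <- pet(rep(30, length(v)), 15, 30, v)
  expect_true(all(diff(p) < 0) || all(diff(p) > 0))
})

test_that("stress classification covers nine exhaustive half-open classes", {
  expect_equal(as.character(classify_pet(20)), "no thermal stress")
  expect_equal(as.character(classify_pet(30)), "moderate heat stress")
  expect_equal(as.character(classify_pet(-5)), "extreme cold stress")
  expect_equal(as.character(classify_pet(50)), "extreme heat stress")
  # boundaries are left-closed, right-open
  expect_equal(as.character(classify_pet(c(18, 23, 29, 35, 41))),
               c("no thermal stress", "slight heat stress",
                 "moderate heat stress", "strong heat stress",
                 "extreme heat stress"))
  expect_equal(as.character(classify_pet(22.999)), "no thermal stress")
  # total and exhaustive over a fine sweep
  sweep <- classify_pet(seq(-20, 60, by = 0.1))
  expect_false(anyNA(sweep))
  expect_equal(nlevels(sweep), 9)
  expect_true(!is.unsorted(as.integer(sweep)))
})

test_that("stress labels are localized with nine entries per language", {
  for (lang in c("en", "de", "fr")) {
    expect_length(stress_levels(lang), 9)
  }
  expect_equal(stress_levels("en")[5], "no thermal stress")
})

test_that("the comfort pipeline retains intermediates and preserves order", {
  rec <- read_records(full_record_csv())
  tc <- thermal_comfort(rec, method = "globe")
  expect_s3_class(tc, "thermal_comfort")
  expect_equal(nrow(tc), 3)
  expect_true(all(c("vp", "sw", "v_eff", "tmrt", "mrt_method", "pet",
                    "stress") %in% names(tc)))
  expect_equal(tc$timestamp, sort(rec$timestamp))
  expect_false(anyNA(tc$pet))

  no_globe <- rec; no_globe$tg <- NA_real_
  expect_error(thermal_comfort(no_globe, method = "globe"),
               "channel 'tg' missing")
})

test_that("person configuration validates physiological bounds", {
  expect_error(person_config(height = 3), "height")
  expect_error(person_config(weight = 10), "weight")
  expect_error(person_config(clothing = 0.01), "clothing")
  expect_error(person_config(work_metabolism = -5), "work_metabolism")
  p <- person_config(sex = "female", age = 28, clothing = 0.5)
  expect_s3_class(p, "person_config")
  # a different person yields a different PET in the same environment
  expect_false(isTRUE(all.equal(pet(30, 15, 40, 0.1, p),
                                pet(30, 15, 40, 0.1))))
})
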