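# Synthetic forcing: weather generator, day/night split, radiation, and
# the soil/grid fixture generators.

test_that("weather generator is deterministic under a fixed seed", {
  arch <- climate_archetype("temperate")
  w1 <- synth_weather(arch, 1, seed = 5)
  w2 <- synth_weather(arch, 1, seed = 5)
  expect_identical(w1, w2)
  w3 <- synth_weather(arch, 1, seed = 6)
  expect_false(identical(w1$t_avg, w3$t_avg))
  expect_error(synth_weather(arch, 0, seed = 1), "positive")
})

test_that("long-run mean temperature matches the archetype within 0.5 degC", {
  arch <- climate_archetype("subtropical")
  w <- synth_weather(arch, 30, seed = 1)
  expect_equal(mean(w$t_avg), arch$t_mean_annual, tolerance = 0.5)
})

test_that("annual precipitation and wet-day frequency track the archetype", {
  arch <- climate_archetype("subtropical")
  w <- synth_weather(arch, 30, seed = 2)
  annual_p <- tapply(w$precip, w$year, sum)
  expect_equal(mean(annual_p), arch$precip_annual, tolerance = 0.15 * arch$precip_annual)
  expect_equal(mean(w$precip > 0), arch$wet_day_prob, tolerance = 0.05)
})

test_that("a zero wet-day probability yields an entirely dry series", {
  arch <- climate_archetype("temperate", wet_day_prob = 0)
  w <- synth_weather(arch, 2, seed = 3)
  expect_true(all(w$precip == 0))
})

test_that("every generated day satisfies the forcing invariants over a century", {
  for (name in c("cold-temperate", "tropical")) {
    w <- synth_weather(climate_archetype(name), 100, seed = 17)
    expect_true(all(w$t_min <= w$t_avg & w$t_avg <= w$t_max))
    expect_true(all(w$d_sun >= 0 & w$d_sun <= 24))
    expect_true(all(w$precip >= 0))
    expect_true(all(w$rh >= 0 & w$rh <= 1))
    expect_true(all(w$par_noon >= 0))
    expect_true(all(w$t_night <= w$t_day + 1e-9))
  }
})

test_that("day/night split is energy consistent and ordered", {
  w <- data.frame(t_avg = 15, t_max = 20, t_min = 10, d_sun = 12)
  out <- derive_daynight_temps(w)
  expect_equal(out$t_day + out$t_night, 30)                # D = 12 balance
  expect_equal(12 * out$t_day + 12 * out$t_night, 24 * 15) # weighted mean
  # isothermal day
  iso <- derive_daynight_temps(data.frame(t_avg = 10, t_max = 10,
                                          t_min = 10, d_sun = 8))
  expect_equal(c(iso$t_day, iso$t_night), c(10, 10))
  # 24-hour day has no night
  polar <- derive_daynight_temps(data.frame(t_avg = 5, t_max = 9,
                                            t_min = 2, d_sun = 24))
  expect_equal(polar$t_day, 5)
  expect_error(derive_daynight_temps(data.frame(t_avg = 5, t_max = 9,
                                                t_min = 2, d_sun = 30)),
               "24")
})

test_that("energy consistency holds across random days", {
  set.seed(55)
  t_avg <- runif(50, -20, 30)
  spread <- runif(50, 0, 10)
  d <- runif(50, 0.5, 23.5)
  w <- derive_daynight_temps(data.frame(t_avg = t_avg,
                                        t_max = t_avg + spread,
                                        t_min = t_avg - spread, d_sun = d))
  expect_equal(d * w$t_day + (24 - d) * w$t_night, 24 * t_avg,
               tolerance = 1e-9)
  expect_true(all(w$t_night <= w$t_day + 1e-12))
})

test_that("astronomical day length matches solar geometry at the equinox", {
  expect_equal(day_length(0, 80), 12, tolerance = 0.2)
  expect_equal(day_length(45, 80), 12, tolerance = 0.3)
  # polar night / polar day
  expect_identical(day_length(80, 355), 0)
  expect_identical(day_length(80, 172), 24)
})

test_that("noon PAR has the diffuse floor at zero sunshine and grows with sunshine", {
  lat <- 30; doy <- 150
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  sin_elev <- sin(lat * pi / 180) * sin(decl) + cos(lat * pi / 180) * cos(decl)
  floor_par <- 0.25 * 0.48 * 1367 * sin_elev
  expect_equal(noon_par_from_sunshine(lat, doy, 0), floor_par,
               tolerance = 1e-9)
  d <- seq(0, 20, by = 0.5)
  par <- noon_par_from_sunshine(lat, doy, d)
  expect_true(all(diff(par) >= 0))
  # clamped beyond the astronomical day length
  dl <- day_length(lat, doy)
  expect_equal(noon_par_from_sunshine(lat, doy, dl + 3),
               noon_par_from_sunshine(lat, doy, dl))
})

test_that("synthetic soil is reproducible, positive and water-saturated", {
  s1 <- synth_soil("DBF", seed = 9)
  s2 <- synth_soil("DBF", seed = 9)
  expect_identical(s1, s2)
  expect_true(all(s1$c_pools > 0))
  expect_gt(sum(s1$c_pools), 0)
  expect_identical(s1$w_s, s1$w_f)
  expect_error(synth_soil("XYZ", 1), "forest_type")
})

test_that("soil totals across seeds match the generator's configured dispersion", {
  totals <- vapply(1:100, function(s) sum(synth_soil("ECF", s)$c_pools),
                   numeric(1))
  cv <- sd(totals) / mean(totals)
  expect_equal(cv, 0.20, tolerance = 0.30 * 0.20 + 0.04)
})

test_that("grid generator respects the type mix and NDVI bounds", {
  mix <- stats::setNames(rep(1 / 8, 8), forest_types())
  cells <- synth_grid(8, mix, seed = 4)
  expect_setequal(vapply(cells, `[[`, character(1), "forest_type"),
                  forest_types())
  for (cl in cells) {
    sp <- cl$species
    expect_gte(cl$ndvi, sp$ndvi_min)
    expect_lte(cl$ndvi, sp$ndvi_max)
    expect_gt(cl$coverage, 0)
    expect_lte(cl$coverage, 1)
  }
  ecf_only <- synth_grid(5, stats::setNames(1, "ECF"), seed = 4)
  expect_true(all(vapply(ecf_only, `[[`, character(1), "forest_type") == "ECF"))
  expect_identical(synth_grid(3, mix, seed = 8), synth_grid(3, mix, seed = 8))
  expect_error(synth_grid(3, numeric(0), seed = 1), "empty")
})

test_that("forcing CSV round-trips through the tidy writer", {
  w <- synth_weather(climate_archetype("temperate"), 1, seed = 21)
  path <- tempfile(fileext = ".csv")
  write_forcing_csv(w, path)
  expect_true(startsWith(readLines(path, n = 1), "# units:"))
  back <- read_forcing_csv(path)
  expect_equal(back$t_avg, w$t_avg, tolerance = 1e-12)
  expect_equal(back$precip, w$precip, tolerance = 1e-12)
  expect_identical(back$date, w$date)
})
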