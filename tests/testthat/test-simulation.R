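# Orchestration: spin-up, deterministic runs, carbon closure, regional
# aggregation, contributions, and monthly evaluation.

test_that("identical cells under identical forcing give identical outputs", {
  cfg <- default_config(); cfg$n_trees <- 8
  cells <- synth_grid(2, stats::setNames(1, "DBF"), seed = 40, cfg)
  w <- synth_weather(climate_archetype("warm-temperate"), 1, seed = 41)
  r1 <- simulate_cell(cells[[1]], w, cfg)
  r2 <- simulate_cell(cells[[1]], w, cfg)
  expect_identical(r1$annual, r2$annual)
})

test_that("lightless forcing makes the cell a pure carbon source", {
  cfg <- default_config(); cfg$n_trees <- 6
  cell <- synth_grid(1, stats::setNames(1, "EBF"), seed = 42, cfg)[[1]]
  w <- make_const_forcing(t_avg = 15, d_sun = 0, par_noon = 0, precip = 2)
  run <- simulate_cell(cell, w, cfg)
  expect_identical(run$annual$gpp, 0)
  expect_gt(run$annual$rs, 0)
  expect_equal(run$annual$nep, run$annual$npp - run$annual$rs)
  expect_lt(run$annual$nep, 0)
})

test_that("cumulative NEP equals the ecosystem carbon change on a mixed grid", {
  cfg <- default_config(); cfg$n_trees <- 10
  mix <- c(ECF = 0.2, DBF = 0.2, EBF = 0.2, DCF = 0.2, RF = 0.2)
  cells <- synth_grid(5, mix, seed = 50, cfg)
  forcing <- lapply(seq_along(cells), function(i) {
    synth_weather(archetype_for_type_test(cells[[i]]$forest_type), 3,
                  seed = 50 + i)
  })
  res <- run_simulation(cells, forcing, cfg)
  for (i in seq_along(res$runs)) {
    run <- res$runs[[i]]
    cum_nep <- sum(run$annual$nep)
    delta <- run$annual$eco_c[nrow(run$annual)] -
      (run$initial$veg_c + run$initial$soil_c)
    expect_equal(cum_nep, delta,
                 tolerance = 1e-6 * max(abs(delta), 1e-3))
    expect_equal(run$annual$nep, run$annual$npp - run$annual$rs,
                 tolerance = 1e-12)
  }
})

test_that("spin-up equilibrates a single-pool toy soil to the analytic steady state", {
  cfg <- default_config()
  cfg$n_trees <- 5
  # only the above-ground metabolic pool is active: all leaf litter is
  # metabolic, every other turnover is off, decomposition fully respired
  cfg$soil_params <- soil_params(p_u = rep(1, 10))
  cfg$species$ECF <- list(leaf_turn = 1e-5, froot_turn = 0, branch_turn = 0,
                          stem_turn = 0, croot_turn = 0, metab_leaf = 1,
                          decid_frac = 0)
  cell <- synth_grid(1, stats::setNames(1, "ECF"), seed = 60, cfg)[[1]]
  cell$soil$c_pools[] <- 0
  # no sunshine: PET = 0 so the soil stays at field capacity and both rate
  # modifiers are constant once soil temperature has relaxed to 20 degC
  w <- make_const_forcing(t_avg = 20, precip = 0, d_sun = 0, par_noon = 0)
  eq <- quiet_spinup(cell, w, tol = 1e-6, max_cycles = 400, cfg)
  traj <- attr(eq, "soilc_trajectory")
  sp <- cell$species
  daily_input <- 1e-5 * sum(cell$trees$c_leaf) / cell$patch_area
  g_t <- temp_effect(eq$soil$t_s)
  g_w <- water_effect(eq$soil$w_s, eq$soil$w_f)
  k <- 0.021 * g_t * g_w
  expect_equal(sum(eq$soil$c_pools), daily_input * (1 - k) / k,
               tolerance = 5e-3)
  expect_true(all(diff(traj) >= -1e-12))
})

test_that("spin-up converges faster with a looser tolerance and flags exhaustion", {
  cfg <- default_config(); cfg$n_trees <- 6
  cell <- synth_grid(1, stats::setNames(1, "CBF"), seed = 61, cfg)[[1]]
  w <- synth_weather(climate_archetype("temperate"), 1, seed = 62)
  loose <- quiet_spinup(cell, w, tol = 1e-2, max_cycles = 100, cfg)
  tight <- quiet_spinup(cell, w, tol = 1e-4, max_cycles = 100, cfg)
  expect_lte(attr(loose, "cycles"), attr(tight, "cycles"))
  expect_warning(spinup(cell, w, tol = 1e-12, max_cycles = 2, cfg),
                 "not converged")
})

test_that("regional aggregation converts units correctly and honors coverage", {
  # one 10 km x 10 km cell, full coverage, NEP 100 gC m-2 a-1 -> 0.01 TgC
  fx <- data.frame(cell = 1, forest_type = "ECF", area = 1e8, coverage = 1,
                   nep = 0.1)  # kgC m-2 a-1
  reg <- aggregate_regional(fx)
  expect_equal(unname(reg$per_type_tg["ECF"]), 0.01)
  zero_cov <- aggregate_regional(transform(fx, coverage = 0))
  expect_identical(unname(zero_cov$per_type_tg["ECF"]), 0)
  # grouped sums equal a brute-force per-cell accumulation
  set.seed(77)
  fx2 <- data.frame(cell = 1:12,
                    forest_type = sample(forest_types(), 12, replace = TRUE),
                    area = 1e8, coverage = runif(12),
                    nep = rnorm(12, 0.05, 0.05))
  reg2 <- aggregate_regional(fx2)
  brute <- tapply(fx2$nep * fx2$area * fx2$coverage * 1e-9,
                  fx2$forest_type, sum)
  expect_equal(sort(as.numeric(reg2$per_type_tg)),
               sort(as.numeric(brute)), tolerance = 1e-12)
  expect_equal(reg2$national_pg, sum(reg2$per_type_tg) / 1e3)
})

test_that("contributions normalize to 100 and handle sources and rescaling", {
  x <- c(A = 60, B = 30, C = 10)
  expect_equal(sum(contributions(x)), 100, tolerance = 1e-9)
  expect_equal(unname(contributions(c(A = 5))), 100)
  expect_error(contributions(c(A = 1, B = -1)), "zero")
  # invariant under uniform rescaling
  expect_equal(contributions(x), contributions(x * 3.7), tolerance = 1e-12)
  # negative (source) entries keep the sum at 100
  y <- c(A = 50, B = -10, C = 60)
  expect_equal(sum(contributions(y)), 100, tolerance = 1e-9)
  expect_lt(contributions(y)["B"], 0)
})

test_that("monthly evaluation reproduces hand-computed metrics", {
  dates <- seq(as.Date("2003-01-01"), as.Date("2003-12-31"), by = "day")
  set.seed(99)
  sim <- data.frame(date = dates, nep = rnorm(length(dates), 1, 0.3))
  month <- as.integer(format(dates, "%m"))
  sim_m <- tapply(sim$nep, month, sum)
  obs <- data.frame(year = 2003, month = 1:12,
                    nee = -(as.numeric(sim_m) + rnorm(12, 0, 2)))
  m <- evaluate_monthly(sim, obs)
  nep_obs <- -obs$nee
  expect_equal(m$bias, mean(as.numeric(sim_m) - nep_obs), tolerance = 1e-9)
  expect_equal(m$rmse, sqrt(mean((as.numeric(sim_m) - nep_obs)^2)),
               tolerance = 1e-9)
  expect_equal(m$r, cor(as.numeric(sim_m), nep_obs), tolerance = 1e-9)
  expect_identical(m$n_months, 12L)
})

test_that("monthly evaluation is exact on identical series and shift-invariant in r", {
  dates <- seq(as.Date("2003-01-01"), as.Date("2003-12-31"), by = "day")
  sim <- data.frame(date = dates, nep = sin(seq_along(dates) / 30))
  month <- as.integer(format(dates, "%m"))
  sim_m <- as.numeric(tapply(sim$nep, month, sum))
  perfect <- data.frame(year = 2003, month = 1:12, nep = sim_m)
  m0 <- evaluate_monthly(sim, perfect, obs_is_nep = TRUE)
  expect_equal(m0$bias, 0, tolerance = 1e-12)
  expect_equal(m0$rmse, 0, tolerance = 1e-12)
  expect_equal(m0$r, 1, tolerance = 1e-12)
  shifted <- data.frame(year = 2003, month = 1:12, nep = sim_m + 5)
  m5 <- evaluate_monthly(sim, shifted, obs_is_nep = TRUE)
  expect_equal(m5$bias, -5, tolerance = 1e-12)
  expect_equal(m5$r, 1, tolerance = 1e-12)
  none <- data.frame(year = 1999, month = 1:12, nep = sim_m)
  expect_error(evaluate_monthly(sim, none, obs_is_nep = TRUE), "overlap")
})
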