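# Shared fixtures: constant-weather forcing (analytic checks), toy cells,
# and a quiet spin-up wrapper.

# one calendar year of identical days (no leap year: 2001)
make_const_forcing <- function(t_avg = 15, dtr = 8, precip = 0, d_sun = 12,
                               rh = 0.7, par_noon = 400, co2 = 360,
                               year = 2001) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  w <- data.frame(date = dates, year = year,
                  doy = as.integer(format(dates, "%j")),
                  t_max = t_avg + dtr / 2, t_min = t_avg - dtr / 2,
                  t_avg = t_avg, precip = precip, d_sun = d_sun, rh = rh,
                  par_noon = par_noon, co2 = co2)
  derive_daynight_temps(w)
}

# standard small cell (few trees for speed)
make_test_cell <- function(type = "ECF", seed = 42, n_trees = 10) {
  cfg <- default_config()
  cfg$n_trees <- n_trees
  synth_grid(1, stats::setNames(1, type), seed, cfg)[[1]]
}

quiet_spinup <- function(...) suppressWarnings(spinup(...))

# default climate archetype for a forest type (mirrors the generator's map)
archetype_for_type_test <- function(type) {
  map <- c(ECF = "temperate", DCF = "cold-temperate", CBF = "temperate",
           DBF = "warm-temperate", EBF = "subtropical", EDBF = "subtropical",
           SRF = "tropical", RF = "tropical")
  climate_archetype(map[[type]])
}

# total stand carbon incl. the buffer [kgC]
tree_carbon_total <- function(trees) {
  sum(trees$c_leaf + trees$c_froot + trees$c_branch + trees$c_stem +
        trees$c_croot + trees$c_buffer)
}

# shift a forcing table's temperatures uniformly
warm_forcing <- function(w, dt) {
  for (col in c("t_max", "t_min", "t_avg", "t_day", "t_night")) {
    w[[col]] <- w[[col]] + dt
  }
  w
}
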