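#' Astronomical day length
#'
#' Standard solar geometry: declination
#' `delta = 23.45 * sin(2*pi*(284 + doy)/365)` degrees and half-day hour
#' angle `H = acos(-tan(lat) tan(delta))` (argument clamped to \[-1, 1\],
#' so polar day/night return 24 or 0 h).
#'
#' @param lat Latitude \[deg\], positive north.
#' @param doy Day of year (1-366), vectorized.
#' @return Day length \[h\].
#' @export
day_length <- function(lat, doy) {
  abort_if(any(abs(lat) > 90), "latitude must lie in [-90, 90]")
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  x <- pmin(pmax(-tan(lat * pi / 180) * tan(decl), -1), 1)
  24 * acos(x) / pi
}

#' Noon photosynthetically active radiation from sunshine hours
#'
#' Angstrom-Prescott atmospheric transmittance applied to the
#' top-of-atmosphere noon irradiance:
#' `PAR = par_frac * (a + b * D / D_astr) * S0 * sin(elev_noon)` with
#' `sin(elev_noon) = sin(lat) sin(delta) + cos(lat) cos(delta)`. Sunshine
#' hours are clamped to the astronomical day length, so the output is
#' non-decreasing in `d_sun`; at `d_sun = 0` the diffuse floor
#' `a * par_frac * S0 * sin(elev)` remains.
#'
#' @param lat Latitude \[deg\].
#' @param doy Day of year, vectorized.
#' @param d_sun Observed sunshine hours \[h\].
#' @param a,b Angstrom-Prescott coefficients, defaults 0.25 and 0.50.
#' @param par_frac PAR fraction of shortwave irradiance, default 0.48.
#' @param solar_constant Top-of-atmosphere irradiance \[W m^-2\],
#'   default 1367.
#' @return Noon canopy PAR \[W m^-2\].
#' @export
noon_par_from_sunshine <- function(lat, doy, d_sun, a = 0.25, b = 0.50,
                                   par_frac = 0.48, solar_constant = 1367) {
  abort_if(any(d_sun < 0), "d_sun must be >= 0")
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  latr <- lat * pi / 180
  sin_elev <- pmax(sin(latr) * sin(decl) + cos(latr) * cos(decl), 0)
  d_astr <- day_length(lat, doy)
  frac <- ifelse(d_astr > 0, pmin(d_sun, d_astr) / d_astr, 0)
  par_frac * (a + b * frac) * solar_constant * sin_elev
}

#' Split daily mean temperature into day and night means
#'
#' Daytime mean `T_d = T_avg + k_d * (T_max - T_avg)` with the nighttime
#' mean chosen so the day-length-weighted average recovers the daily mean:
#' `D * T_d + (24 - D) * T_n = 24 * T_avg`. Guarantees `T_n <= T_d`; for a
#' 24-hour day (or an isothermal day) both equal `T_avg`.
#'
#' @param weather Data frame with columns `t_avg`, `t_max`, `t_min`,
#'   `d_sun` (daily mean/max/min temperature \[degC\] and sunshine hours).
#' @param k_d Position of the daytime mean between the daily mean and the
#'   maximum, default 0.5.
#' @return `weather` with columns `t_day` and `t_night` added/replaced.
#' @export
derive_daynight_temps <- function(weather, k_d = 0.5) {
  abort_if(!all(c("t_avg", "t_max", "t_min", "d_sun") %in% names(weather)),
           "weather needs columns t_avg, t_max, t_min, d_sun")
  abort_if(any(weather$d_sun < 0) || any(weather$d_sun > 24),
           "d_sun must lie in [0, 24]")
  abort_if(any(weather$t_min > weather$t_max + 1e-9), "t_min must be <= t_max")
  d <- weather$d_sun
  t_day <- weather$t_avg + k_d * (weather$t_max - weather$t_avg)
  full_day <- d >= 24 - 1e-12
  t_day[full_day] <- weather$t_avg[full_day]
  t_night <- ifelse(full_day, weather$t_avg,
                    (24 * weather$t_avg - d * t_day) / (24 - d))
  weather$t_day <- t_day
  weather$t_night <- t_night
  weather
}

#' Climate archetype for the synthetic weather generator
#'
#' A small set of named climates spanning the latitudinal range of the
#' eight forest types, or a fully custom parameterization. Fields: annual
#' mean temperature and seasonal semi-amplitude \[degC\], annual
#' precipitation \[mm\], wet-day probability, mean relative humidity,
#' mean daily sunshine \[h\], representative latitude \[deg\], and the CO2
#' starting level \[ppm\] and trend \[ppm a^-1\].
#'
#' @param name One of `"cold-temperate"`, `"temperate"`,
#'   `"warm-temperate"`, `"subtropical"`, `"tropical"`, or `"custom"`.
#' @param ... For `name = "custom"` (or to override a preset): any of
#'   `t_mean_annual`, `t_amplitude`, `precip_annual`, `wet_day_prob`,
#'   `rh_mean`, `sunshine_mean`, `lat`, `co2_start`, `co2_trend`.
#' @return A list of class `gapflux_archetype`.
#' @export
climate_archetype <- function(name = c("temperate", "cold-temperate",
                                       "warm-temperate", "subtropical",
                                       "tropical", "custom"), ...) {
  name <- match.arg(name)
  presets <- list(
    "cold-temperate" = list(t_mean_annual = -2, t_amplitude = 21,
                            precip_annual = 450, wet_day_prob = 0.25,
                            rh_mean = 0.65, sunshine_mean = 7, lat = 50),
    "temperate"      = list(t_mean_annual = 6, t_amplitude = 16,
                            precip_annual = 650, wet_day_prob = 0.30,
                            rh_mean = 0.65, sunshine_mean = 7, lat = 43),
    "warm-temperate" = list(t_mean_annual = 13, t_amplitude = 13,
                            precip_annual = 900, wet_day_prob = 0.32,
                            rh_mean = 0.68, sunshine_mean = 7, lat = 35),
    "subtropical"    = list(t_mean_annual = 18, t_amplitude = 9,
                            precip_annual = 1500, wet_day_prob = 0.45,
                            rh_mean = 0.76, sunshine_mean = 5.5, lat = 26),
    "tropical"       = list(t_mean_annual = 23, t_amplitude = 5,
                            precip_annual = 2000, wet_day_prob = 0.50,
                            rh_mean = 0.80, sunshine_mean = 5.5, lat = 21),
    "custom"         = list(t_mean_annual = 10, t_amplitude = 12,
                            precip_annual = 800, wet_day_prob = 0.3,
                            rh_mean = 0.7, sunshine_mean = 7, lat = 35)
  )
  arch <- presets[[name]]
  arch$co2_start <- 340
  arch$co2_trend <- 1.8
  dots <- list(...)
  bad <- setdiff(names(dots), names(arch))
  abort_if(length(bad) > 0, "unknown archetype field(s): %s",
           paste(bad, collapse = ", "))
  arch[names(dots)] <- dots
  arch$name <- name
  abort_if(arch$precip_annual <= 0, "precip_annual must be positive")
  abort_if(arch$wet_day_prob < 0 || arch$wet_day_prob >= 1,
           "wet_day_prob must lie in [0, 1)")
  structure(arch, class = "gapflux_archetype")
}

# internal: default archetype for each forest type
archetype_for_type <- function(type) {
  map <- c(ECF = "temperate", DCF = "cold-temperate", CBF = "temperate",
           DBF = "warm-temperate", EBF = "subtropical", EDBF = "subtropical",
           SRF = "tropical", RF = "tropical")
  climate_archetype(map[[type]])
}

#' Synthetic daily weather series
#'
#' Seeded stochastic generator with the structure the simulator assumes:
#' a sinusoidal annual temperature cycle (warmest in mid-July) with
#' first-order autocorrelated residuals; precipitation occurrence from a
#' two-state first-order chain whose stationary wet-day frequency matches
#' the archetype, with exponentially distributed wet-day amounts; sunshine
#' fraction drawn from separate beta distributions on wet and dry days;
#' relative humidity responsive to wet days and cloudiness; a linear
#' annual CO2 trend; and derived day/night temperatures and noon PAR.
#' Identical seeds give identical series.
#'
#' @param archetype A [climate_archetype()].
#' @param n_years Number of years, >= 1.
#' @param seed Integer seed for all stochastic draws.
#' @param start_year First calendar year, default 2001.
#' @param calendar `"gregorian"` (real leap days, default) or `"noleap"`.
#' @return Data frame with one row per day and columns `date`, `year`,
#'   `doy`, `t_max`, `t_min`, `t_avg`, `precip` \[mm\], `d_sun` \[h\],
#'   `rh`, `t_day`, `t_night`, `par_noon` \[W m^-2\], `co2` \[ppm\].
#' @export
synth_weather <- function(archetype, n_years, seed, start_year = 2001,
                          calendar = c("gregorian", "noleap")) {
  abort_if(!inherits(archetype, "gapflux_archetype"),
           "archetype must come from climate_archetype()")
  abort_if(!is.numeric(n_years) || length(n_years) != 1 || n_years < 1,
           "n_years must be a positive count")
  calendar <- match.arg(calendar)
  n_years <- as.integer(n_years)
  years <- start_year + seq_len(n_years) - 1L
  if (calendar == "gregorian") {
    dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
                 as.Date(sprintf("%d-12-31", years[n_years])), by = "day")
    year <- as.integer(format(dates, "%Y"))
    doy <- as.integer(format(dates, "%j"))
  } else {
    year <- rep(years, each = 365L)
    doy <- rep(seq_len(365L), n_years)
    dates <- as.Date(sprintf("%d-%03d", year, doy), format = "%Y-%j")
  }
  n <- length(doy)

  set.seed(as.integer(seed))
  # temperature: seasonal cycle + AR(1) residual
  t_base <- archetype$t_mean_annual +
    archetype$t_amplitude * cos(2 * pi * (doy - 196) / 365.25)
  rho <- 0.7
  sigma <- 3
  resid <- as.numeric(stats::filter(stats::rnorm(n, 0, sigma * sqrt(1 - rho^2)),
                                    rho, method = "recursive"))
  t_avg <- t_base + resid

  # precipitation: two-state occurrence chain, exponential amounts
  p <- archetype$wet_day_prob
  wet <- logical(n)
  if (p > 0) {
    p_ww <- min(0.95, p + 0.35)
    p_dw <- p * (1 - p_ww) / (1 - p)
    u <- stats::runif(n)
    wet[1] <- u[1] < p
    for (i in seq_len(n)[-1]) {
      wet[i] <- u[i] < if (wet[i - 1]) p_ww else p_dw
    }
  }
  mean_amt <- archetype$precip_annual / (365.25 * max(p, 1e-12))
  precip <- numeric(n)
  if (any(wet)) precip[wet] <- stats::rexp(sum(wet), rate = 1 / mean_amt)

  # sunshine fraction of the astronomical day
  d_astr <- day_length(archetype$lat, doy)
  m_dry <- min(max(archetype$sunshine_mean / 12, 0.3), 0.85)
  frac <- numeric(n)
  frac[!wet] <- stats::rbeta(sum(!wet), 10 * m_dry, 10 * (1 - m_dry))
  if (any(wet)) frac[wet] <- stats::rbeta(sum(wet), 2, 6)
  d_sun <- d_astr * frac

  # diurnal range larger on clear days
  dtr <- 5 + 7 * frac
  t_max <- t_avg + 0.55 * dtr
  t_min <- t_avg - 0.45 * dtr

  rh <- archetype$rh_mean + 0.12 * wet - 0.10 * (frac - 0.5) +
    stats::rnorm(n, 0, 0.05)
  rh <- pmin(pmax(rh, 0.15), 1)

  co2 <- archetype$co2_start + archetype$co2_trend * (year - years[1])

  out <- data.frame(
    date = dates, year = year, doy = doy,
    t_max = t_max, t_min = t_min, t_avg = t_avg,
    precip = precip, d_sun = d_sun, rh = rh,
    par_noon = noon_par_from_sunshine(archetype$lat, doy, d_sun),
    co2 = co2
  )
  derive_daynight_temps(out)
}

#' Write / read a forcing series as tidy CSV
#'
#' One row per day (or per cell-day when a `cell` column is present), with
#' a commented header line recording the column units so files are
#' self-describing. [read_forcing_csv()] restores the `date` column type;
#' the pair round-trips exactly at full double precision.
#'
#' @param weather Forcing data frame from [synth_weather()].
#' @param path Output file path.
#' @return `write_forcing_csv()` returns `path` invisibly;
#'   `read_forcing_csv()` returns the data frame.
#' @export
write_forcing_csv <- function(weather, path) {
  units <- c(date = "date", year = "a", doy = "d", t_max = "degC",
             t_min = "degC", t_avg = "degC", precip = "mm d-1",
             d_sun = "h", rh = "fraction", t_day = "degC",
             t_night = "degC", par_noon = "W m-2", co2 = "ppm",
             cell = "id")
  hdr <- paste0("# units: ", paste0(names(weather), "=",
                                    units[names(weather)], collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(weather, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_forcing_csv
#' @export
read_forcing_csv <- function(path) {
  out <- utils::read.csv(path, comment.char = "#")
  if ("date" %in% names(out)) out$date <- as.Date(out$date)
  out
}
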