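# Daily/annual orchestration: the per-cell simulation loop, soil spin-up,
# and multi-cell runs.

#' Simulate one grid cell over a span of daily forcing
#'
#' Runs the full module chain day by day: soil temperature relaxation,
#' Thornthwaite PET and the bucket water balance; phenology (a 10-day
#' smoothed air temperature gates the deciduous canopy fraction);
#' big-leaf canopy GPP with CO2, water, temperature and nitrogen
#' modifiers; per-tree maintenance and growth respiration charged to the
#' photosynthate buffer; constant-rate litterfall (with a full deciduous
#' shed at leaf-off); litter partition into the ten soil pools;
#' decomposition with heterotrophic respiration and net nitrogen
#' mineralization. At each calendar year end the buffered assimilate is
#' allocated to structure ([annual_growth()]) and the annual fluxes are
#' closed: `NPP = sum(GPP_d - R_m - R_g)`, `R_s = sum(daily R_s)`,
#' `NEP = NPP - R_s`.
#'
#' All annual fluxes are on a ground-area basis \[kgC m^-2 a^-1\];
#' per-tree quantities are normalized by the patch area.
#'
#' @param cell A grid cell from [synth_grid()].
#' @param forcing Daily forcing data frame covering whole calendar years
#'   ([synth_weather()] columns).
#' @param config Run configuration from [default_config()].
#' @param record_daily Keep a per-day NEP series (for monthly
#'   evaluation)?
#' @return List of class `gapflux_run` with `annual` (one row per year:
#'   `year`, `gpp`, `ra`, `npp`, `rs`, `nep`, `veg_c`, `soil_c`, `eco_c`,
#'   `litter`), `cell` (final state), `initial` (starting vegetation and
#'   soil carbon) and optionally `daily` (`date`, `nep`).
#' @export
simulate_cell <- function(cell, forcing, config = default_config(),
                          record_daily = FALSE) {
  sp <- cell$species
  soilp <- config$soil_params
  area <- cell$patch_area
  trees <- cell$trees
  soil <- cell$soil
  c0_ref <- config$co2_reference %||% forcing$co2[1]

  years <- unique(forcing$year)
  init_veg <- tree_carbon(trees) / area
  init_soil <- sum(soil$c_pools)
  pheno <- forcing$t_avg[1]
  leaf_on_prev <- pheno > config$pheno_thresh

  annual <- vector("list", length(years))
  daily_dates <- if (record_daily) forcing$date else NULL
  daily_nep <- if (record_daily) numeric(nrow(forcing)) else NULL
  day_counter <- 0L

  for (yi in seq_along(years)) {
    yr <- years[yi]
    fy <- forcing[forcing$year == yr, , drop = FALSE]
    nd <- nrow(fy)
    abort_if(nd != days_in_year(yr) && nd != 365L,
             "forcing for year %d is incomplete (%d days)", yr, nd)
    t_avg <- fy$t_avg; t_day <- fy$t_day; t_night <- fy$t_night
    d_sun <- fy$d_sun; precip <- fy$precip; rh <- fy$rh
    par_noon <- fy$par_noon; co2 <- fy$co2; doy <- fy$doy
    month <- as.integer(format(fy$date, "%m"))
    heat_i <- thornthwaite_heat_index(
      tapply(t_avg, month, mean)[as.character(1:12)])
    pet <- pet_thornthwaite(t_avg, d_sun, heat_i)

    gpp_sum <- rm_sum <- rg_sum <- rs_sum <- litter_sum <- 0

    for (i in seq_len(nd)) {
      soil$t_s <- soil_temperature_step(soil$t_s, t_avg[i], config$tau_soil)
      soil$w_s <- water_balance_step(soil$w_s, soil$w_f, precip[i], pet[i])
      pheno <- pheno + (t_avg[i] - pheno) / config$tau_pheno
      leaf_on <- pheno > config$pheno_thresh
      shed <- leaf_on_prev && !leaf_on
      leaf_on_prev <- leaf_on

      lai_tree <- trees$c_leaf * sp$sla / area
      lai_raw <- sum(lai_tree)
      lai_eff <- lai_raw * (1 - sp$decid_frac * !leaf_on)

      gppm <- gpp_max(sp$a_m, d_sun[i], sp$k_ext, sp$s_slope,
                      par_noon[i], lai_eff)
      gppd <- gpp_daily(gppm,
                        f_co2(co2[i], c0_ref),
                        f_water(soil$w_s, soil$w_f, rh[i], sp$w_tol),
                        f_temp(t_avg[i], sp$t_min_p, sp$t_opt_p, sp$t_max_p),
                        sp$alpha, soil$n_s)
      soil$n_s <- soil$n_s - gppd / sp$alpha

      shares <- if (lai_raw > 0) lai_tree / lai_raw else rep(0, length(lai_tree))
      gpp_i <- shares * (gppd * area)
      tf <- (d_sun[i] * resp_temp_factor(t_day[i]) +
               (24 - d_sun[i]) * resp_temp_factor(t_night[i])) / 24
      rm_i <- tf * (sp$rk_leaf * trees$c_leaf + sp$rk_froot * trees$c_froot +
                      sp$rk_wood * tree_sapwood(trees, sp))
      rg_i <- sp$r_g * pmax(gpp_i - rm_i, 0)
      trees$c_buffer <- trees$c_buffer + gpp_i - rm_i - rg_i

      lf <- daily_litterfall(trees, sp, shed = shed)
      trees <- lf$trees
      soil$c_pools <- soil$c_pools +
        litter_partition(lf$leaf / area, lf$froot / area, lf$branch / area,
                         lf$stem / area, lf$croot / area, 0,
                         sp$metab_leaf, sp$metab_froot)

      dec <- decomposition_step(soil$c_pools, soilp,
                                temp_effect(soil$t_s),
                                water_effect(soil$w_s, soil$w_f, soilp$e_w),
                                soil$l_s)
      soil$c_pools <- dec$pools
      soil$n_s <- soil$n_s + dec$n_min

      gpp_sum <- gpp_sum + gppd
      rm_sum <- rm_sum + sum(rm_i) / area
      rg_sum <- rg_sum + sum(rg_i) / area
      rs_sum <- rs_sum + dec$rs
      litter_sum <- litter_sum +
        (lf$leaf + lf$froot + lf$branch + lf$stem + lf$croot) / area
      day_counter <- day_counter + 1L
      if (record_daily) {
        daily_nep[day_counter] <-
          gppd - sum(rm_i) / area - sum(rg_i) / area - dec$rs
      }
    }

    ag <- annual_growth(trees, sp, config$reserve_frac)
    trees <- ag$trees
    soil$c_pools <- soil$c_pools +
      litter_partition(0, 0, 0, 0, 0, ag$fruit_litter / area,
                       sp$metab_leaf, sp$metab_froot)
    litter_sum <- litter_sum + ag$fruit_litter / area

    npp <- gpp_sum - rm_sum - rg_sum
    annual[[yi]] <- data.frame(
      year = yr, gpp = gpp_sum, ra = rm_sum + rg_sum, npp = npp,
      rs = rs_sum, nep = npp - rs_sum,
      veg_c = tree_carbon(trees) / area, soil_c = sum(soil$c_pools),
      eco_c = tree_carbon(trees) / area + sum(soil$c_pools),
      litter = litter_sum)
  }

  cell$trees <- trees
  cell$soil <- soil
  out <- list(annual = do.call(rbind, annual), cell = cell,
              initial = list(veg_c = init_veg, soil_c = init_soil))
  if (record_daily) out$daily <- data.frame(date = daily_dates, nep = daily_nep)
  structure(out, class = "gapflux_run")
}

#' Spin the soil state of a cell to equilibrium
#'
#' Recycles a single forcing year until the relative change of total soil
#' carbon between consecutive cycles drops below `tol`, or `max_cycles`
#' is reached (then flagged non-converged with a warning, not an error).
#' The tree state is reset to its initial value each cycle, so spin-up
#' equilibrates the soil store under a periodic litter input without
#' letting the stand grow unboundedly.
#'
#' @param cell A grid cell.
#' @param forcing_year One full calendar year of daily forcing.
#' @param tol Relative soil-carbon change tolerance, default 1e-4.
#' @param max_cycles Maximum number of recycled years, default 100.
#' @param config Run configuration.
#' @return The equilibrated cell, with attributes `cycles` (count used),
#'   `converged` (logical) and `soilc_trajectory` (total soil C after
#'   each cycle).
#' @export
spinup <- function(cell, forcing_year, tol = 1e-4, max_cycles = 100,
                   config = default_config()) {
  abort_if(tol <= 0, "tol must be positive")
  abort_if(length(unique(forcing_year$year)) != 1,
           "forcing_year must cover exactly one year")
  trees0 <- cell$trees
  prev <- sum(cell$soil$c_pools)
  traj <- numeric(0)
  converged <- FALSE
  cycles <- 0L
  for (cyc in seq_len(max_cycles)) {
    run <- simulate_cell(cell, forcing_year, config)
    cell <- run$cell
    cell$trees <- trees0
    tot <- sum(cell$soil$c_pools)
    traj <- c(traj, tot)
    cycles <- cyc
    if (abs(tot - prev) / max(tot, 1e-12) < tol) {
      converged <- TRUE
      break
    }
    prev <- tot
  }
  if (!converged) {
    warning(sprintf("spin-up not converged after %d cycles", cycles),
            call. = FALSE)
  }
  attr(cell, "cycles") <- cycles
  attr(cell, "converged") <- converged
  attr(cell, "soilc_trajectory") <- traj
  cell
}

#' Run the simulator over a collection of cells
#'
#' Applies [simulate_cell()] to each cell with its forcing and binds the
#' annual flux tables. Deterministic given states and forcing.
#'
#' @param cells List of grid cells.
#' @param forcing Either one forcing data frame shared by all cells or a
#'   list of per-cell data frames (same length as `cells`).
#' @param config Run configuration.
#' @return List with `fluxes` (row-bound annual table with a `cell`,
#'   `forest_type`, `area` and `coverage` column prepended) and `runs`
#'   (the per-cell `gapflux_run` objects).
#' @export
run_simulation <- function(cells, forcing, config = default_config()) {
  per_cell <- if (is.data.frame(forcing)) {
    rep(list(forcing), length(cells))
  } else {
    abort_if(length(forcing) != length(cells),
             "need one forcing table per cell")
    forcing
  }
  runs <- lapply(seq_along(cells), function(i) {
    simulate_cell(cells[[i]], per_cell[[i]], config)
  })
  fluxes <- do.call(rbind, lapply(seq_along(runs), function(i) {
    a <- runs[[i]]$annual
    cbind(data.frame(cell = cells[[i]]$id,
                     forest_type = cells[[i]]$forest_type,
                     area = cells[[i]]$area,
                     coverage = cells[[i]]$coverage), a)
  }))
  list(fluxes = fluxes, runs = runs)
}
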