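#' One-day update of soil temperature
#'
#' First-order (exponential) relaxation of soil temperature toward the air
#' temperature: `T_s' = T_air + (T_s - T_air) * exp(-1 / tau)` with time
#' constant `tau` in days. With `tau = 0` the soil temperature tracks the
#' air temperature exactly; a step change in air temperature is followed as
#' `1 - exp(-t / tau)`.
#'
#' @param t_s Current soil temperature \[degC\].
#' @param t_air Today's mean air temperature \[degC\].
#' @param tau Damping time constant \[d\], default 15.
#' @return Updated soil temperature \[degC\].
#' @export
soil_temperature_step <- function(t_s, t_air, tau = 15) {
  abort_if(tau < 0, "tau must be >= 0")
  if (tau == 0) return(t_air)
  t_air + (t_s - t_air) * exp(-1 / tau)
}

#' Thornthwaite heat index of a year
#'
#' `I = sum_m (T_m / 5)^1.514` over the twelve monthly mean temperatures,
#' counting only months above freezing.
#'
#' @param t_monthly Twelve monthly mean air temperatures \[degC\].
#' @return Annual heat index (dimensionless).
#' @export
thornthwaite_heat_index <- function(t_monthly) {
  abort_if(length(t_monthly) != 12, "need twelve monthly mean temperatures")
  tm <- pmax(t_monthly, 0)
  sum((tm / 5)^1.514)
}

#' Daily potential evapotranspiration (Thornthwaite-type)
#'
#' Temperature-and-day-length driven PET: the Thornthwaite monthly formula
#' `16 * (10 T / I)^a` \[mm month^-1\] scaled to a day and adjusted for day
#' length, returned in cm so it can be passed directly to
#' [water_balance_step()]. Zero at and below 0 degC.
#'
#' @param t_avg Daily mean air temperature \[degC\], vectorized.
#' @param d_sun Day length or sunshine hours \[h\] used for the daylight
#'   adjustment (`d_sun / 12`).
#' @param heat_index Annual heat index from [thornthwaite_heat_index()].
#' @return Daily PET \[cm d^-1\].
#' @export
pet_thornthwaite <- function(t_avg, d_sun, heat_index) {
  abort_if(heat_index < 0, "heat_index must be >= 0")
  if (heat_index == 0) return(rep(0, length(t_avg)))
  a <- 6.75e-7 * heat_index^3 - 7.71e-5 * heat_index^2 +
    1.792e-2 * heat_index + 0.49239
  pet_mm <- ifelse(t_avg <= 0, 0,
                   16 * (10 * t_avg / heat_index)^a * (d_sun / 12) / 30)
  pet_mm / 10
}

#' One-day bucket water balance
#'
#' `W_s' = clamp(W_s + precip/10 - AET, 0, W_f)` with actual
#' evapotranspiration `AET = PET * (W_s / W_f)`; any excess above field
#' capacity drains and is discarded. Note the unit convention: `precip`
#' enters in mm (converted to cm), `pet` enters in cm.
#'
#' @param w_s Soil water content \[cm\], must not exceed `w_f`.
#' @param w_f Field capacity \[cm\], positive.
#' @param precip Daily precipitation \[mm\], non-negative.
#' @param pet Daily potential evapotranspiration \[cm\].
#' @return Updated soil water content \[cm\].
#' @export
water_balance_step <- function(w_s, w_f, precip, pet) {
  abort_if(any(w_f <= 0), "w_f must be positive")
  abort_if(any(precip < 0), "precip must be >= 0")
  abort_if(any(pet < 0), "pet must be >= 0")
  abort_if(any(w_s > w_f + 1e-9), "w_s must not exceed w_f")
  aet <- pet * (w_s / w_f)
  pmin(pmax(w_s + precip / 10 - aet, 0), w_f)
}

#' Temperature modifier of decomposition
#'
#' `G_t = exp(3.36 * (T_s - 40) / (T_s + 31.79))`: strictly increasing in
#' soil temperature, equal to 1 at 40 degC, with a pole at -31.79 degC
#' below which the expression is undefined.
#'
#' @param t_s Soil temperature \[degC\], must exceed -31.79.
#' @return Dimensionless rate modifier, vectorized.
#' @export
temp_effect <- function(t_s) {
  abort_if(any(t_s <= -31.79), "t_s must exceed -31.79 degC")
  exp(3.36 * (t_s - 40) / (t_s + 31.79))
}

#' Moisture modifier of decomposition
#'
#' `G_w = 1 - (W_s / (e_w * W_f) - 1)^2`, clamped to \[0, 1\]: a parabola
#' in relative soil water with its optimum (1) at `W_s = e_w * W_f` and
#' zero in completely dry soil.
#'
#' @param w_s Soil water content \[cm\].
#' @param w_f Field capacity \[cm\], positive.
#' @param e_w Moisture optimum constant, default 0.6.
#' @return Dimensionless rate modifier in \[0, 1\], vectorized.
#' @export
water_effect <- function(w_s, w_f, e_w = 0.6) {
  abort_if(any(w_f <= 0), "w_f must be positive")
  abort_if(any(w_s < 0) || any(w_s > w_f + 1e-9), "w_s must lie in [0, w_f]")
  pmin(pmax(1 - (w_s / (e_w * w_f) - 1)^2, 0), 1)
}

#' One-day decomposition of the ten-pool soil carbon store
#'
#' Each pool loses `flux_u = min(S_u * G_t * G_w * shield_u, 1) * C_u`
#' where `shield_u = exp(-b_lignin * L_s)` for the structural litter pools
#' and 1 otherwise. A fraction `P_u` of the flux is respired as
#' heterotrophic CO2; the remainder is routed to downstream pools by the
#' transfer matrix. Net nitrogen mineralization is the respired flux
#' divided by the source pool's C:N ratio. Carbon is conserved exactly:
#' the total pool decrease equals the respired flux plus any routed share
#' not retained (none, with the default loss-free topology).
#'
#' @param pools Numeric length-10 vector of pool carbon \[kgC m^-2\].
#' @param params A [soil_params()] object.
#' @param g_t,g_w Temperature and moisture rate modifiers (>= 0).
#' @param l_s Lignin fraction of the structural litter pools, in \[0, 1).
#' @return List with `pools` (updated vector), `rs` (heterotrophic
#'   respiration \[kgC m^-2 d^-1\]), `n_min` (net mineralized nitrogen
#'   \[kgN m^-2 d^-1\]) and `flux` (per-pool decomposition flux).
#' @export
decomposition_step <- function(pools, params, g_t, g_w, l_s = 0.2) {
  abort_if(!inherits(params, "gapflux_soil_params"),
           "params must come from soil_params()")
  abort_if(length(pools) != 10 || any(pools < 0),
           "pools must be 10 non-negative stocks")
  abort_if(g_t < 0 || g_w < 0, "g_t and g_w must be >= 0")
  abort_if(l_s < 0 || l_s >= 1, "l_s must lie in [0, 1)")
  shield <- rep(1, 10)
  shield[params$shield_pools] <- exp(-params$b_lignin * l_s)
  k <- pmin(params$s_u * g_t * g_w * shield, 1)
  flux <- k * pools
  respired <- params$p_u * flux
  gains <- drop(flux %*% params$transfer)
  list(pools = pools - flux + gains,
       rs = sum(respired),
       n_min = sum(respired / params$cn),
       flux = flux)
}

#' Annual heterotrophic respiration from daily records
#'
#' Sum of daily heterotrophic respiration over one full calendar year
#' (365 or 366 values).
#'
#' @param rs_daily Daily heterotrophic respiration \[kgC m^-2 d^-1\].
#' @return Annual total \[kgC m^-2 a^-1\].
#' @export
annual_rs <- function(rs_daily) {
  abort_if(!(length(rs_daily) %in% c(365L, 366L)),
           "need exactly one calendar year of daily records (got %d days)",
           length(rs_daily))
  sum(rs_daily)
}

#' Partition litter inputs into the ten soil pools
#'
#' Leaf (and flower/fruit) litter splits between the above-ground
#' metabolic and structural pools by the metabolic fraction; fine-root
#' litter splits the same way below ground; branch litter enters the fine
#' woody pool, stem litter the coarse woody pool and coarse-root litter
#' the below-ground coarse pool. The additions sum exactly to the inputs.
#'
#' @param leaf,froot,branch,stem,croot,fruit Litter masses \[kgC m^-2\],
#'   non-negative.
#' @param metab_leaf Metabolic fraction of leaf/fruit litter, default 0.55.
#' @param metab_froot Metabolic fraction of fine-root litter, default 0.5.
#' @return Numeric length-10 vector of pool additions \[kgC m^-2\].
#' @export
litter_partition <- function(leaf = 0, froot = 0, branch = 0, stem = 0,
                             croot = 0, fruit = 0,
                             metab_leaf = 0.55, metab_froot = 0.5) {
  masses <- c(leaf, froot, branch, stem, croot, fruit)
  abort_if(any(masses < 0), "litter masses must be >= 0")
  abort_if(metab_leaf < 0 || metab_leaf > 1 || metab_froot < 0 || metab_froot > 1,
           "metabolic fractions must lie in [0, 1]")
  ag <- leaf + fruit
  add <- numeric(10)
  add[1] <- ag * metab_leaf
  add[2] <- ag * (1 - metab_leaf)
  add[3] <- froot * metab_froot
  add[4] <- froot * (1 - metab_froot)
  add[5] <- branch
  add[6] <- stem
  add[7] <- croot
  names(add) <- soil_pool_names()
  add
}
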