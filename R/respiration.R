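#' Temperature factor of maintenance respiration
#'
#' `exp(0.069315 * (t - 15) - 0.009 * (t - 15)^2)`: a modified Q10 response
#' normalized to 1 at 15 degC (the linear coefficient 0.069315 = ln(2)/10
#' corresponds to Q10 = 2 near the reference), with a quadratic term that
#' caps the response at high temperature (vertex at
#' 15 + 0.069315 / (2 * 0.009) ~= 18.85 degC above reference scaling).
#'
#' @param t Temperature \[degC\], vectorized.
#' @return Dimensionless factor, 1 at 15 degC.
#' @export
resp_temp_factor <- function(t) {
  exp(0.069315 * (t - 15) - 0.009 * (t - 15)^2)
}

#' Daily maintenance respiration of one tree
#'
#' Day/night weighted sum over tissue components:
#' \deqn{R_m = \sum_k \frac{1}{24}\left[D\, g(T_d) + (24 - D)\, g(T_n)\right]
#'       R_k C_k}
#' with `g` the [resp_temp_factor()], `D` the sunshine hours, `T_d`/`T_n`
#' the day/night mean temperatures, `R_k` the relative respiration rate at
#' 15 degC and `C_k` the respiring carbon pool: the live pool itself for
#' leaves and fine roots, the sapwood carbon for branches, stems and coarse
#' roots.
#'
#' @param d_sun Sunshine hours \[h\], in \[0, 24\].
#' @param t_day,t_night Daytime and nighttime mean temperatures \[degC\].
#' @param r_k Numeric vector of relative respiration rates \[d^-1\].
#' @param c_k Numeric vector (same length) of respiring carbon pools
#'   \[kgC\].
#' @return Maintenance respiration \[kgC d^-1\] per tree.
#' @export
maintenance_respiration <- function(d_sun, t_day, t_night, r_k, c_k) {
  abort_if(any(d_sun < 0) || any(d_sun > 24), "d_sun must lie in [0, 24]")
  abort_if(length(r_k) != length(c_k), "r_k and c_k must have equal length")
  abort_if(any(r_k < 0), "respiration rates must be >= 0")
  abort_if(any(c_k < 0), "carbon pools must be >= 0")
  f <- (d_sun * resp_temp_factor(t_day) +
        (24 - d_sun) * resp_temp_factor(t_night)) / 24
  sum(f * r_k * c_k)
}

#' Daily growth respiration
#'
#' `R_g = r_g * max(GPP_d - R_m, 0)`: a fixed fraction of the positive
#' daily assimilate remaining after maintenance. Clamped at zero on days
#' when maintenance exceeds assimilation (negative growth respiration is
#' unphysical; such days draw on the photosynthate buffer instead).
#'
#' @param gpp_d Daily gross primary production (same unit as `r_m`).
#' @param r_m Daily maintenance respiration.
#' @param r_g_coef Growth respiration coefficient in (0, 1), default 0.25.
#' @return Growth respiration, vectorized.
#' @export
growth_respiration <- function(gpp_d, r_m, r_g_coef = 0.25) {
  abort_if(r_g_coef <= 0 || r_g_coef >= 1, "r_g_coef must lie in (0, 1)")
  r_g_coef * pmax(gpp_d - r_m, 0)
}

#' Annual net primary production from daily fluxes
#'
#' `NPP = sum_d (GPP_d - R_m - R_g)` over one full calendar year of daily
#' records (365 or 366 days). May be negative in a year when respiration
#' exceeds assimilation.
#'
#' @param gpp_d,r_m,r_g Equal-length daily flux vectors
#'   \[kgC m^-2 d^-1\] covering exactly one calendar year.
#' @return Annual NPP \[kgC m^-2 a^-1\].
#' @export
accumulate_npp <- function(gpp_d, r_m, r_g) {
  n <- length(gpp_d)
  abort_if(length(r_m) != n || length(r_g) != n,
           "gpp_d, r_m and r_g must have equal length")
  abort_if(!(n %in% c(365L, 366L)),
           "need exactly one calendar year of daily records (got %d days)", n)
  sum(gpp_d - r_m - r_g)
}
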