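#' CO2 modifier of gross primary production
#'
#' `F_c = 1 + (C_t - C_0) / (C_t + 2 * C_0)`, the fractional enhancement of
#' canopy assimilation at annual-mean CO2 `C_t` relative to the reference
#' concentration `C_0`. Bounded in (1/2, 2) for positive concentrations and
#' equal to 1 at `C_t = C_0`.
#'
#' @param c_t Annual mean CO2 concentration \[ppm\].
#' @param c_0 Reference CO2 concentration \[ppm\].
#' @return Dimensionless modifier, vectorized over inputs.
#' @export
f_co2 <- function(c_t, c_0) {
  abort_if(any(c_t <= 0) || any(c_0 <= 0), "CO2 concentrations must be positive")
  1 + (c_t - c_0) / (c_t + 2 * c_0)
}

#' Soil-water modifier of gross primary production
#'
#' `F_w = min(1, W_s/W_f + max(Rh - 0.5, 0.1)) ^ (w_tol / 2)`: relative soil
#' water plus an air-humidity relief term, capped at 1, raised to half the
#' species drought-tolerance exponent. Lies in (0, 1], equals 1 for
#' saturated soil, and is non-decreasing in both `w_s` and `rh`.
#'
#' @param w_s Soil water content \[cm\].
#' @param w_f Field capacity \[cm\], must be positive.
#' @param rh Relative air humidity, fraction in \[0, 1\].
#' @param w_tol Drought tolerance exponent (> 0); larger values mean a
#'   steeper penalty in dry conditions.
#' @return Dimensionless modifier, vectorized.
#' @export
f_water <- function(w_s, w_f, rh, w_tol) {
  abort_if(any(w_f <= 0), "field capacity w_f must be positive")
  abort_if(any(w_s < 0) || any(w_s > w_f + 1e-9), "w_s must lie in [0, w_f]")
  abort_if(any(rh < 0) || any(rh > 1), "rh must lie in [0, 1]")
  abort_if(any(w_tol <= 0), "w_tol must be positive")
  inner <- pmin(1, w_s / w_f + pmax(rh - 0.5, 0.1))
  inner^(w_tol / 2)
}

#' Temperature modifier of gross primary production
#'
#' Beta-type response over the cardinal temperatures of photosynthesis:
#' `F_t = ((t_max_p - t)/(t_max_p - t_opt_p)) *
#'        ((t - t_min_p)/(t_opt_p - t_min_p)) ^
#'        ((t_opt_p - t_min_p)/(t_max_p - t_opt_p))`,
#' clamped to 0 outside `[t_min_p, t_max_p]`. Equals 1 at the optimum,
#' vanishes at both cardinal extremes, and is bounded in \[0, 1\] with its
#' unique maximum at `t_opt_p`.
#'
#' @param t Air temperature \[degC\], vectorized.
#' @param t_min_p,t_opt_p,t_max_p Cardinal temperatures \[degC\], strictly
#'   ordered.
#' @return Dimensionless modifier in \[0, 1\].
#' @export
f_temp <- function(t, t_min_p, t_opt_p, t_max_p) {
  abort_if(!(t_min_p < t_opt_p && t_opt_p < t_max_p),
           "cardinal temperatures must satisfy t_min_p < t_opt_p < t_max_p")
  ft <- rep(0, length(t))
  inside <- t > t_min_p & t < t_max_p
  ti <- t[inside]
  ex <- (t_opt_p - t_min_p) / (t_max_p - t_opt_p)
  ft[inside] <- ((t_max_p - ti) / (t_max_p - t_opt_p)) *
    ((ti - t_min_p) / (t_opt_p - t_min_p))^ex
  pmin(pmax(ft, 0), 1)
}

#' Daily maximum gross primary production (big-leaf light response)
#'
#' Integrates a rectangular-hyperbola leaf light response over an
#' exponentially extinguished canopy profile:
#' \deqn{GPP_m = \frac{2 A_m D}{K}\,
#'   \ln\!\left[\frac{1 + \sqrt{1 + K S\,PAR / A_m}}
#'                   {1 + \sqrt{1 + K S\,PAR\, e^{-K\,LAI} / A_m}}\right]}
#' with `A_m` the maximum leaf photosynthesis, `D` the sunshine hours,
#' `K` the extinction coefficient, `S` the initial slope and `PAR` the
#' canopy photosynthetically active radiation at noon. Non-negative and
#' non-decreasing in `PAR`, `LAI` and `D`; exactly 0 when `PAR = 0` or
#' `LAI = 0`.
#'
#' @param a_m Maximum leaf photosynthesis \[kgC m^-2 h^-1\].
#' @param d_sun Sunshine hours \[h\], in \[0, 24\].
#' @param k_ext Canopy extinction coefficient (> 0).
#' @param s_slope Initial slope of the light response (> 0).
#' @param par_noon Canopy PAR at noon \[W m^-2\], >= 0.
#' @param lai Leaf area index \[m^2 m^-2\], >= 0.
#' @return Daily maximum GPP \[kgC m^-2 d^-1\], vectorized.
#' @export
gpp_max <- function(a_m, d_sun, k_ext, s_slope, par_noon, lai) {
  abort_if(any(a_m <= 0), "a_m must be positive")
  abort_if(any(d_sun < 0) || any(d_sun > 24), "d_sun must lie in [0, 24]")
  abort_if(any(k_ext <= 0) || any(s_slope <= 0), "k_ext and s_slope must be positive")
  abort_if(any(par_noon < 0) || any(lai < 0), "par_noon and lai must be >= 0")
  q <- k_ext * s_slope * par_noon / a_m
  (2 * a_m * d_sun / k_ext) *
    log((1 + sqrt(1 + q)) / (1 + sqrt(1 + q * exp(-k_ext * lai))))
}

#' Daily gross primary production with nitrogen limitation
#'
#' `GPP_d = min(GPP_m * F_c * F_w * F_t, alpha * N_s)`: the
#' environmentally modified light-driven rate, capped by the carbon gain
#' supportable from available soil nitrogen at the assimilation C:N
#' parameter `alpha`.
#'
#' @param gpp_m Daily maximum GPP \[kgC m^-2 d^-1\].
#' @param f_c,f_w,f_t CO2, soil-water and temperature modifiers (>= 0).
#' @param alpha Assimilation C:N ratio parameter, default 150.
#' @param n_s Available soil nitrogen \[kgN m^-2\].
#' @return Daily GPP \[kgC m^-2 d^-1\], vectorized.
#' @export
gpp_daily <- function(gpp_m, f_c, f_w, f_t, alpha = 150, n_s) {
  abort_if(any(c(gpp_m, f_c, f_w, f_t, alpha, n_s) < 0),
           "all gpp_daily inputs must be >= 0")
  pmin(gpp_m * f_c * f_w * f_t, alpha * n_s)
}
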