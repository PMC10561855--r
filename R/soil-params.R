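#' Names of the ten litter and soil organic matter pools
#'
#' Pool order used everywhere a length-10 carbon vector appears:
#' above-ground metabolic litter (1), above-ground structural litter (2),
#' below-ground metabolic litter (3), below-ground structural litter (4),
#' fine woody litter (5), coarse woody litter (6), below-ground coarse
#' litter (7), active SOM (8), slow SOM (9), resistant SOM (10).
#'
#' @return Character vector of length 10.
#' @export
soil_pool_names <- function() {
  c("ag_metabolic", "ag_structural", "bg_metabolic", "bg_structural",
    "fine_woody", "coarse_woody", "bg_coarse", "active_som", "slow_som",
    "resistant_som")
}

# internal: routing of the non-respired decomposition flux.  Rows are source
# pools, columns destinations; each row sums to 1 and is later scaled by
# (1 - P_u).  CENTURY-style topology: litter feeds active SOM (structural
# pools route a lignin share to slow SOM), woody pools feed slow SOM, active
# and slow SOM exchange with a small leak into the resistant pool.
default_routes <- function() {
  r <- matrix(0, 10, 10, dimnames = list(soil_pool_names(), soil_pool_names()))
  r["ag_metabolic", "active_som"] <- 1
  r["ag_structural", c("active_som", "slow_som")] <- c(0.7, 0.3)
  r["bg_metabolic", "active_som"] <- 1
  r["bg_structural", c("active_som", "slow_som")] <- c(0.7, 0.3)
  r["fine_woody", c("active_som", "slow_som")] <- c(0.5, 0.5)
  r["coarse_woody", "slow_som"] <- 1
  r["bg_coarse", "slow_som"] <- 1
  r["active_som", c("slow_som", "resistant_som")] <- c(0.95, 0.05)
  r["slow_som", c("active_som", "resistant_som")] <- c(0.9, 0.1)
  r["resistant_som", "active_som"] <- 1
  r
}

#' Decomposition parameter set for the ten-pool soil model
#'
#' Bundles the reference relative decomposition rates `s_u` (per day, at
#' the temperature/moisture optimum), the respired fraction `p_u` of each
#' pool's decomposition flux, the transfer matrix routing the non-respired
#' flux between pools, the lignin shielding constant `b_lignin`, the
#' moisture optimum constant `e_w`, and per-pool C:N ratios used for net
#' nitrogen mineralization.
#'
#' The default `s_u` vector is the published reference rate set
#' (0.021, 0.1, 0.027, 0.13, 0.01, 0.002, 0.002, 0.042, 0.001, 3.5e-5).
#' `p_u`, the transfer topology and the C:N ratios are not published for
#' this model; the defaults are CENTURY-style values (metabolic litter
#' respires a larger share than structural; SOM pools exchange with a small
#' leak into the resistant pool) and are fully overridable.
#'
#' @param s_u Numeric length-10, reference decomposition rates \[d^-1\].
#' @param p_u Numeric length-10, respired fraction of the decomposition
#'   flux, each in \[0, 1\].
#' @param routes 10 x 10 matrix; row `u` gives the destination split of the
#'   non-respired flux of pool `u` and must sum to 1 (rows may sum to less
#'   than 1 to represent leaching losses).
#' @param b_lignin Lignin shielding constant (flux scaled by
#'   `exp(-b_lignin * L_s)` on structural pools), default 5.0.
#' @param e_w Moisture optimum constant of the decomposition water
#'   modifier, default 0.6.
#' @param cn Numeric length-10, C:N ratio of each pool.
#' @param shield_pools Integer indices of pools subject to lignin
#'   shielding (default the two structural litter pools, 2 and 4).
#' @return A list of class `gapflux_soil_params`.
#' @export
soil_params <- function(s_u = c(0.021, 0.1, 0.027, 0.13, 0.01, 0.002,
                                0.002, 0.042, 0.001, 3.5e-5),
                        p_u = c(0.55, 0.45, 0.55, 0.45, 0.45, 0.45, 0.45,
                                0.60, 0.55, 0.55),
                        routes = default_routes(),
                        b_lignin = 5.0,
                        e_w = 0.6,
                        cn = c(15, 150, 15, 150, 250, 500, 250, 8, 12, 7),
                        shield_pools = c(2L, 4L)) {
  abort_if(length(s_u) != 10 || any(s_u < 0), "s_u must be 10 non-negative rates")
  abort_if(length(p_u) != 10 || any(p_u < 0) || any(p_u > 1),
           "p_u must be 10 fractions in [0, 1]")
  abort_if(!is.matrix(routes) || any(dim(routes) != 10) || any(routes < 0),
           "routes must be a non-negative 10 x 10 matrix")
  abort_if(any(rowSums(routes) > 1 + 1e-12), "route rows must sum to <= 1")
  abort_if(length(cn) != 10 || any(cn <= 0), "cn must be 10 positive ratios")
  abort_if(b_lignin < 0, "b_lignin must be >= 0")
  abort_if(e_w <= 0 || e_w > 1, "e_w must lie in (0, 1]")
  # transfer[u, v]: fraction of pool u's decomposition flux gained by pool v
  transfer <- routes * (1 - p_u)
  abort_if(any(rowSums(transfer) > 1 - p_u + 1e-12),
           "transfer rows must not exceed 1 - p_u")
  structure(list(s_u = s_u, p_u = p_u, routes = routes, transfer = transfer,
                 b_lignin = b_lignin, e_w = e_w, cn = cn,
                 shield_pools = as.integer(shield_pools)),
            class = "gapflux_soil_params")
}
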