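# Regional aggregation of annual NEP, contribution accounting, and
# evaluation against eddy-covariance observations.

#' Aggregate per-cell annual NEP to per-type regional totals
#'
#' Converts each cell's mean annual NEP per unit area to an absolute
#' annual carbon budget over its forested area
#' (`NEP [gC m^-2 a^-1] * area [m^2] * coverage`), sums by forest type
#' and reports teragrams of carbon per year
#' (1 TgC = 10^12 g). The national total is the sum over types in
#' petagrams (1 PgC = 10^3 TgC).
#'
#' @param fluxes Annual flux table from [run_simulation()] (`cell`,
#'   `forest_type`, `area`, `coverage`, `nep` \[kgC m^-2 a^-1\]), or any
#'   data frame with those columns; multiple years per cell are averaged
#'   (annual-mean reporting).
#' @return List with `per_type_tg` (named vector over the types present,
#'   TgC a^-1), `national_pg` (PgC a^-1) and `table` (a tidy data
#'   frame).
#' @export
aggregate_regional <- function(fluxes) {
  need <- c("cell", "forest_type", "area", "coverage", "nep")
  abort_if(!all(need %in% names(fluxes)), "fluxes needs columns: %s",
           paste(need, collapse = ", "))
  # mean annual NEP per cell, then absolute budget per cell
  percell <- do.call(rbind, lapply(split(fluxes, fluxes$cell), function(d) {
    data.frame(cell = d$cell[1], forest_type = d$forest_type[1],
               area = d$area[1], coverage = d$coverage[1],
               nep = mean(d$nep))
  }))
  # kgC m-2 a-1 * m2 -> kgC a-1; * 1e3 g/kg / 1e12 g/Tg = 1e-9
  percell$nep_tg <- percell$nep * percell$area * percell$coverage * 1e-9
  per_type <- tapply(percell$nep_tg, percell$forest_type, sum)
  per_type <- per_type[order(match(names(per_type), forest_types()))]
  list(per_type_tg = per_type,
       national_pg = sum(per_type) / 1e3,
       table = data.frame(forest_type = names(per_type),
                          nep_tg = as.numeric(per_type),
                          row.names = NULL))
}

#' Relative contribution of each forest type to the total carbon budget
#'
#' `contribution[t] = 100 * nep[t] / sum(nep)`. The denominator is the
#' net total over all types, including negative (carbon source) entries,
#' so the contributions always sum to 100% and a source type carries a
#' negative share.
#'
#' @param per_type_tg Named numeric vector of per-type annual NEP totals
#'   (any common unit); the net total must be nonzero.
#' @return Named numeric vector of percentages summing to 100.
#' @export
contributions <- function(per_type_tg) {
  abort_if(length(per_type_tg) == 0, "per_type_tg must not be empty")
  total <- sum(per_type_tg)
  abort_if(total == 0, "net total is zero; contributions are undefined")
  100 * per_type_tg / total
}

#' Compare simulated NEP with observed monthly NEE
#'
#' Sums the simulated daily NEP to calendar months, pairs them with the
#' observed monthly series and computes bias, RMSE and the Pearson
#' correlation. Sign convention: NEP is positive for a carbon sink;
#' eddy-covariance NEE is equal in magnitude with the opposite sign, so
#' observations are flipped (`nep_obs = -nee`) unless
#' `obs_is_nep = TRUE`.
#'
#' @param sim_daily Data frame with `date` and daily `nep` (any carbon
#'   per area unit; metrics are in the same unit per month).
#' @param obs Data frame with `year`, `month` and `nee` (or `nep` when
#'   `obs_is_nep = TRUE`).
#' @param obs_is_nep Is the observed series already in NEP sign
#'   convention?
#' @return List with `bias` (mean simulated minus observed), `rmse`,
#'   `r` (Pearson), `n_months`, and `monthly` (the paired table).
#' @export
evaluate_monthly <- function(sim_daily, obs, obs_is_nep = FALSE) {
  abort_if(!all(c("date", "nep") %in% names(sim_daily)),
           "sim_daily needs columns date, nep")
  obs_col <- if (obs_is_nep) "nep" else "nee"
  abort_if(!all(c("year", "month", obs_col) %in% names(obs)),
           "obs needs columns year, month, %s", obs_col)
  year <- as.integer(format(sim_daily$date, "%Y"))
  month <- as.integer(format(sim_daily$date, "%m"))
  sim_monthly <- stats::aggregate(list(nep_sim = sim_daily$nep),
                                  list(year = year, month = month), sum)
  obs$nep_obs <- if (obs_is_nep) obs[[obs_col]] else -obs[[obs_col]]
  paired <- merge(sim_monthly, obs[, c("year", "month", "nep_obs")],
                  by = c("year", "month"))
  abort_if(nrow(paired) < 3, "need at least 3 overlapping months (got %d)",
           nrow(paired))
  paired <- paired[order(paired$year, paired$month), ]
  err <- paired$nep_sim - paired$nep_obs
  list(bias = mean(err),
       rmse = sqrt(mean(err^2)),
       r = stats::cor(paired$nep_sim, paired$nep_obs),
       n_months = nrow(paired),
       monthly = paired)
}
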