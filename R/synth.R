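# Synthetic soil, stand and grid generators.  All draws are pure functions
# of (parameters, seed); per-cell seeds are split deterministically from the
# run seed so whole-grid fixtures are bit-reproducible.

# internal: per-type soil priors (total C mean [kgC m-2], field capacity
# range [cm]); dispersion is lognormal with the stated CV
soil_priors <- function() {
  list(
    mean_c = c(ECF = 12, DCF = 16, CBF = 13, DBF = 11, EBF = 10,
               EDBF = 10.5, SRF = 9, RF = 9),
    cv_c = 0.20,
    wf_range = c(ECF = 12, DCF = 10, CBF = 12, DBF = 14, EBF = 16,
                 EDBF = 15, SRF = 18, RF = 20),
    # split of total C across the ten pools (sums to 1)
    pool_frac = c(0.02, 0.03, 0.02, 0.03, 0.02, 0.05, 0.03, 0.05, 0.45, 0.30)
  )
}

#' Synthetic soil state for one forest type
#'
#' Draws a plausible initial soil: total carbon lognormal around a
#' per-type mean (coefficient of variation 0.2) split across the ten
#' pools in fixed fractions, total nitrogen at a soil C:N of 12, available
#' nitrogen seeded at 0.003 kgN m^-2, field capacity near the per-type
#' prior, and soil water initialized at field capacity. Deterministic for
#' a given seed.
#'
#' @param forest_type One of [forest_types()].
#' @param seed Integer seed.
#' @param lignin Lignin fraction of the structural litter pools,
#'   default 0.2.
#' @return A list with elements `w_s`, `w_f` \[cm\], `t_s` \[degC\],
#'   `n_s`, `n_pool` \[kgN m^-2\], `c_pools` (length-10, kgC m^-2) and
#'   `l_s`.
#' @export
synth_soil <- function(forest_type, seed, lignin = 0.2) {
  abort_if(!(forest_type %in% forest_types()),
           "forest_type must be one of: %s", paste(forest_types(), collapse = ", "))
  pr <- soil_priors()
  set.seed(as.integer(seed))
  mu <- pr$mean_c[[forest_type]]
  sdlog <- sqrt(log(1 + pr$cv_c^2))
  total_c <- stats::rlnorm(1, log(mu) - sdlog^2 / 2, sdlog)
  w_f <- pr$wf_range[[forest_type]] * stats::runif(1, 0.8, 1.2)
  pools <- total_c * pr$pool_frac
  names(pools) <- soil_pool_names()
  list(w_s = w_f, w_f = w_f, t_s = 5, n_s = 0.003,
       n_pool = total_c / 12, c_pools = pools, l_s = lignin)
}

# internal: allometric helpers (DBH in cm, masses in kgC, height in m)
wood_from_dbh <- function(dbh, sp) sp$a_w * dbh^sp$b_w
dbh_from_wood <- function(wood, sp) (wood / sp$a_w)^(1 / sp$b_w)
height_from_dbh <- function(dbh, sp) 1.3 + sp$a_h * dbh^sp$b_h
leaf_cap <- function(dbh, sp) sp$a_l * dbh^sp$b_l

# internal: build an initial stand.  DBH lognormal; woody pools from
# allometry; leaf carbon scaled so the patch leaf area matches lai_init
# (capped at the allometric leaf maximum of each tree).
init_trees <- function(sp, lai_init, n_trees, patch_area, seed) {
  set.seed(as.integer(seed))
  dbh <- pmin(pmax(stats::rlnorm(n_trees, log(18), 0.25), 6), 45)
  wood <- wood_from_dbh(dbh, sp)
  cap <- leaf_cap(dbh, sp)
  target_leaf <- lai_init * patch_area / sp$sla
  scale <- if (sum(cap) > 0) min(target_leaf / sum(cap), 1) else 0
  c_leaf <- cap * scale
  c_froot <- sp$froot_ratio * c_leaf
  list(dbh = dbh,
       height = height_from_dbh(dbh, sp),
       ub_height = 0.4 * height_from_dbh(dbh, sp),
       c_leaf = c_leaf,
       c_froot = c_froot,
       c_branch = 0.15 * wood,
       c_stem = 0.65 * wood,
       c_croot = 0.20 * wood,
       c_buffer = 0.5 * c_leaf,
       starved = rep(FALSE, n_trees))
}

# internal: sapwood carbon of each tree
tree_sapwood <- function(trees, sp) {
  sp$sap_frac * (trees$c_branch + trees$c_stem + trees$c_croot)
}

# internal: total vegetation carbon of the stand [kgC]
tree_carbon <- function(trees) {
  sum(trees$c_leaf + trees$c_froot + trees$c_branch + trees$c_stem +
        trees$c_croot + trees$c_buffer)
}

#' Synthetic grid of forest cells
#'
#' Builds `n_cells` grid cells (default 10 km x 10 km) with forest types
#' allocated in proportion to `type_mix`, per-cell NDVI drawn uniformly
#' inside the type's scene bounds, coverage drawn in (0.4, 0.95), a
#' synthetic stand whose initial leaf area matches the NDVI-derived LAI,
#' and a synthetic soil. Per-cell randomness is split deterministically
#' from `seed`, so the whole grid is reproducible.
#'
#' @param n_cells Number of cells, >= 1.
#' @param type_mix Named numeric vector of forest-type fractions summing
#'   to 1 (names from [forest_types()]).
#' @param seed Integer seed.
#' @param config Run configuration from [default_config()].
#' @return List of cell lists, each with `id`, `lat`, `lon`, `area`
#'   \[m^2\], `forest_type`, `coverage`, `ndvi`, `lai_init`, `patch_area`
#'   \[m^2\], `species` (parameter list), `trees` and `soil`.
#' @export
synth_grid <- function(n_cells, type_mix, seed, config = default_config()) {
  abort_if(length(type_mix) == 0, "type_mix must not be empty")
  abort_if(is.null(names(type_mix)) ||
             !all(names(type_mix) %in% forest_types()),
           "type_mix must be named by forest types")
  abort_if(any(type_mix < 0) || abs(sum(type_mix) - 1) > 1e-9,
           "type_mix fractions must be non-negative and sum to 1")
  abort_if(n_cells < 1, "n_cells must be >= 1")
  # largest-remainder allocation of cells to types, then seed-driven shuffle
  counts <- floor(type_mix * n_cells)
  rem <- type_mix * n_cells - counts
  short <- n_cells - sum(counts)
  if (short > 0) {
    counts[order(rem, decreasing = TRUE)[seq_len(short)]] <-
      counts[order(rem, decreasing = TRUE)[seq_len(short)]] + 1
  }
  types <- rep(names(type_mix), counts)
  set.seed(as.integer(seed))
  types <- sample(types)
  lapply(seq_len(n_cells), function(i) {
    cell_seed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    set.seed(cell_seed)
    ty <- types[i]
    sp <- species_params(ty, config$species[[ty]])
    arch <- archetype_for_type(ty)
    ndvi <- stats::runif(1, sp$ndvi_min, sp$ndvi_max)
    coverage <- stats::runif(1, 0.4, 0.95)
    lat <- arch$lat + stats::runif(1, -1.5, 1.5)
    lon <- stats::runif(1, 95, 125)
    lai_init <- lai_from_ndvi(ndvi, sp)
    trees <- init_trees(sp, lai_init, config$n_trees, config$patch_area,
                        seed = (cell_seed + 1L) %% .Machine$integer.max)
    soil <- synth_soil(ty, seed = (cell_seed + 2L) %% .Machine$integer.max,
                       lignin = sp$lignin_frac)
    list(id = i, lat = lat, lon = lon, area = config$cell_area,
         forest_type = ty, coverage = coverage, ndvi = ndvi,
         lai_init = lai_init, patch_area = config$patch_area,
         species = sp, trees = trees, soil = soil)
  })
}
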