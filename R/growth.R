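#' Initial leaf area index from NDVI
#'
#' Linear inversion between the per-type scene NDVI bounds:
#' `LAI = lai_v * (NDVI - ndvi_min) / (ndvi_max - ndvi_min)`, so the
#' scene minimum maps to bare canopy and the scene maximum to the type's
#' maximum LAI. NDVI outside the bounds is clamped with a warning.
#'
#' @param ndvi NDVI value(s).
#' @param sp Species parameter list from [species_params()].
#' @return Initial LAI in `[0, lai_v]`.
#' @export
lai_from_ndvi <- function(ndvi, sp) {
  if (any(ndvi < sp$ndvi_min | ndvi > sp$ndvi_max)) {
    warning("NDVI outside [ndvi_min, ndvi_max]; clamping", call. = FALSE)
    ndvi <- pmin(pmax(ndvi, sp$ndvi_min), sp$ndvi_max)
  }
  sp$lai_v * (ndvi - sp$ndvi_min) / (sp$ndvi_max - sp$ndvi_min)
}

#' Daily litter production of a stand
#'
#' Constant daily turnover of each live pool (leaf, fine root, branch,
#' stem, coarse root). On a deciduous leaf-off day (`shed = TRUE`) the
#' deciduous fraction of the remaining leaf pool is shed in full on top of
#' the ordinary turnover. Litter never exceeds the pool.
#'
#' @param trees Stand state list (vectors per tree).
#' @param sp Species parameter list.
#' @param shed Logical: is today the deciduous leaf-off day?
#' @return List with the updated `trees` and per-component stand litter
#'   totals \[kgC\]: `leaf`, `froot`, `branch`, `stem`, `croot`.
#' @export
daily_litterfall <- function(trees, sp, shed = FALSE) {
  l_leaf <- sp$leaf_turn * trees$c_leaf
  if (shed && sp$decid_frac > 0) {
    l_leaf <- l_leaf + sp$decid_frac * (trees$c_leaf - l_leaf)
  }
  l_froot <- sp$froot_turn * trees$c_froot
  l_branch <- sp$branch_turn * trees$c_branch
  l_stem <- sp$stem_turn * trees$c_stem
  l_croot <- sp$croot_turn * trees$c_croot
  trees$c_leaf <- trees$c_leaf - l_leaf
  trees$c_froot <- trees$c_froot - l_froot
  trees$c_branch <- trees$c_branch - l_branch
  trees$c_stem <- trees$c_stem - l_stem
  trees$c_croot <- trees$c_croot - l_croot
  list(trees = trees, leaf = sum(l_leaf), froot = sum(l_froot),
       branch = sum(l_branch), stem = sum(l_stem), croot = sum(l_croot))
}

#' Annual allocation of the photosynthate buffer to tree structure
#'
#' Year-end scheme, per tree: a negative buffer (a year of respiration
#' exceeding assimilation) is repaid from stem carbon, flagging the tree
#' carbon-starved if the stem cannot cover it. From a positive buffer a
#' fixed fraction is shed as flower/fruit litter; the remainder refills
#' the leaf pool up to its allometric cap, then the fine-root pool up to
#' its target ratio to leaf, and the rest (minus a retained reserve
#' fraction) becomes woody growth split across stem, branch and coarse
#' root. The new total woody carbon is inverted through the allometry to
#' update DBH, height and under-branch height. Carbon is conserved
#' exactly: fruit litter + structural increments + retained buffer equal
#' the starting buffer.
#'
#' @param trees Stand state list.
#' @param sp Species parameter list.
#' @param reserve_frac Fraction of the allocatable surplus retained in the
#'   buffer as a reserve, default 0.1.
#' @return List with the updated `trees` and `fruit_litter` (stand total,
#'   kgC).
#' @export
annual_growth <- function(trees, sp, reserve_frac = 0.1) {
  abort_if(any(!is.finite(trees$c_buffer)), "buffer must be finite")
  abort_if(reserve_frac < 0 || reserve_frac >= 1,
           "reserve_frac must lie in [0, 1)")
  buffer <- trees$c_buffer

  # repay any buffer deficit (a year of respiration exceeding assimilation)
  # from structure, stem first; trees that cannot cover it are flagged
  for (pool in c("c_stem", "c_branch", "c_croot", "c_leaf", "c_froot")) {
    repay <- pmin(pmax(-buffer, 0), trees[[pool]])
    trees[[pool]] <- trees[[pool]] - repay
    buffer <- buffer + repay
  }
  trees$starved <- trees$starved | (buffer < -1e-9)
  buffer <- pmax(buffer, 0)

  fruit <- sp$fruit_frac * buffer
  avail <- buffer - fruit

  leaf_gap <- pmax(leaf_cap(trees$dbh, sp) - trees$c_leaf, 0)
  leaf_alloc <- pmin(avail, leaf_gap)
  avail <- avail - leaf_alloc
  trees$c_leaf <- trees$c_leaf + leaf_alloc

  froot_gap <- pmax(sp$froot_ratio * trees$c_leaf - trees$c_froot, 0)
  froot_alloc <- pmin(avail, froot_gap)
  avail <- avail - froot_alloc
  trees$c_froot <- trees$c_froot + froot_alloc

  wood_alloc <- (1 - reserve_frac) * avail
  trees$c_buffer <- avail - wood_alloc
  trees$c_stem <- trees$c_stem + 0.65 * wood_alloc
  trees$c_branch <- trees$c_branch + 0.15 * wood_alloc
  trees$c_croot <- trees$c_croot + 0.20 * wood_alloc

  wood <- trees$c_branch + trees$c_stem + trees$c_croot
  trees$dbh <- pmax(dbh_from_wood(wood, sp), trees$dbh)
  trees$height <- height_from_dbh(trees$dbh, sp)
  trees$ub_height <- 0.4 * trees$height

  list(trees = trees, fruit_litter = sum(fruit))
}
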