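#' Default run configuration
#'
#' All tunable simulator settings with their defaults:
#' \describe{
#'   \item{patch_area}{representative stand patch area \[m^2\], 1000}
#'   \item{cell_area}{grid cell area \[m^2\], 1e8 (10 km x 10 km)}
#'   \item{n_trees}{trees on the patch, 60}
#'   \item{k_d}{daytime-mean position of the day/night temperature
#'     split, 0.5}
#'   \item{tau_soil}{soil temperature damping constant \[d\], 15}
#'   \item{tau_pheno}{smoothing constant of the phenology temperature
#'     \[d\], 10}
#'   \item{pheno_thresh}{leaf-on threshold of the smoothed air
#'     temperature \[degC\], 5}
#'   \item{reserve_frac}{buffer reserve retained at annual allocation,
#'     0.1}
#'   \item{co2_reference}{reference CO2 for the CO2 modifier \[ppm\];
#'     `NULL` means the first forcing year's concentration}
#'   \item{spinup_tol, spinup_max_cycles}{spin-up convergence tolerance
#'     (1e-4) and cycle cap (100)}
#'   \item{soil_params}{a [soil_params()] object}
#'   \item{species}{named list of per-type parameter overrides, e.g.
#'     `list(ECF = list(a_m = 0.002))`}
#' }
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    patch_area = 1000,
    cell_area = 1e8,
    n_trees = 60,
    k_d = 0.5,
    tau_soil = 15,
    tau_pheno = 10,
    pheno_thresh = 5,
    reserve_frac = 0.1,
    co2_reference = NULL,
    spinup_tol = 1e-4,
    spinup_max_cycles = 100,
    soil_params = soil_params(),
    species = list()
  )
}

# internal: recursively check user keys against the defaults
check_config_keys <- function(user, ref, path = "") {
  bad <- setdiff(names(user), names(ref))
  abort_if(length(bad) > 0, "unknown configuration key(s): %s",
           paste0(path, bad, collapse = ", "))
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(ref[[k]]) && k != "species" &&
        !inherits(ref[[k]], "gapflux_soil_params")) {
      check_config_keys(user[[k]], ref[[k]], paste0(path, k, "."))
    }
  }
  invisible(NULL)
}

#' Load and validate a run configuration from YAML
#'
#' Reads a YAML file, rejects unknown keys, merges the values over
#' [default_config()] and rebuilds the soil parameter object (so e.g.
#' `soil_params: {s_u: [...]}` overrides a single component). An empty or
#' missing-override file resolves to pure defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Resolved configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  abort_if(!file.exists(path), "config file not found: %s", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  check_config_keys(user, cfg)
  soil_over <- user$soil_params
  user$soil_params <- NULL
  cfg <- utils::modifyList(cfg, user)
  if (!is.null(soil_over)) {
    allowed <- setdiff(names(formals(soil_params)), "routes")
    bad <- setdiff(names(soil_over), allowed)
    abort_if(length(bad) > 0, "unknown soil parameter key(s): %s",
             paste(bad, collapse = ", "))
    if (!is.null(soil_over$s_u)) soil_over$s_u <- as.numeric(soil_over$s_u)
    if (!is.null(soil_over$p_u)) soil_over$p_u <- as.numeric(soil_over$p_u)
    if (!is.null(soil_over$cn)) soil_over$cn <- as.numeric(soil_over$cn)
    cfg$soil_params <- do.call(soil_params, soil_over)
  }
  cfg
}

#' Save a resolved configuration as YAML
#'
#' Writes every scalar/vector setting (the soil parameter object is
#' expanded into its overridable components) so a saved configuration
#' reloads to an identical resolved configuration.
#'
#' @param config Resolved configuration list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  out <- config
  sp <- out$soil_params
  out$soil_params <- list(s_u = sp$s_u, p_u = sp$p_u,
                          b_lignin = sp$b_lignin, e_w = sp$e_w,
                          cn = sp$cn,
                          shield_pools = sp$shield_pools)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}
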