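#' Simulate a PEGylation titration series
#'
#' Emulates sequential addition of PEGylated polymer to a gold nanoparticle
#' solution. Uptake is mass-balanced against the added amount at every step:
#' with `softness = 0` the particles take up everything until the surface
#' capacity is reached (hard saturation; the sharp plateau seen when uptake
#' and shell thickness level off together), after which all further polymer
#' stays in the supernatant. With `softness > 0` a Langmuir-like soft
#' saturation `uptake = capacity * (1 - exp(-added / (softness * capacity)))`
#' is used for robustness studies. Shell thickness at every step comes from
#' the brush model at the current grafting density.
#'
#' @param step_added cumulative polymer added per step (molecules), strictly
#'   increasing.
#' @param capacity_molecules total surface capacity (molecules), > 0.
#' @param gold_spec list with `core_diameter_nm`,
#'   `particle_concentration_per_uL`, `volume_uL`.
#' @param brush_params list with `n_monomers` and `monomer_nm` for the
#'   grafted PEG (defaults: 5-kDa PEG, N = 114, a = 0.35 nm).
#' @param softness saturation softness, >= 0; 0 = hard saturation.
#' @return A `titration_series`: data.frame with columns `step_added`,
#'   `uptake`, `supernatant`, `shell_thickness_nm`, plus the gold spec as an
#'   attribute.
#' @export
gen_titration <- function(step_added, capacity_molecules, gold_spec,
                          brush_params = list(n_monomers = 114, monomer_nm = 0.35),
                          softness = 0) {
  if (any(diff(step_added) <= 0)) {
    stop("step_added must be strictly increasing", call. = FALSE)
  }
  if (capacity_molecules <= 0) stop("capacity must be positive", call. = FALSE)
  stopifnot(softness >= 0)
  uptake <- if (softness > 0) {
    capacity_molecules * (1 - exp(-step_added / (softness * capacity_molecules)))
  } else {
    pmin(step_added, capacity_molecules)
  }
  supernatant <- step_added - uptake
  n_particles <- gold_spec$particle_concentration_per_uL * gold_spec$volume_uL
  dens <- grafting_density(uptake, gold_spec$core_diameter_nm, n_particles)
  L <- ifelse(dens > 0,
              brush_thickness(brush_params$n_monomers, brush_params$monomer_nm, dens),
              0)
  out <- data.frame(step_added = step_added, uptake = uptake,
                    supernatant = supernatant, shell_thickness_nm = L)
  structure(out, class = c("titration_series", "data.frame"),
            gold = gold_spec, brush = brush_params,
            capacity_molecules = capacity_molecules, softness = softness)
}

#' Locate the saturation plateau of a titration
#'
#' Scans a titration series for the first step at which the marginal uptake
#' falls below 1\% of the marginal addition — the operational saturation
#' point at which shell thickness and uptake plateau concurrently. The
#' plateau grafting density is computed from the uptake at that step and the
#' gold surface area (complete-uptake bookkeeping), and the plateau thickness
#' from the brush model.
#'
#' @param series a `titration_series` (or data.frame with the same columns
#'   plus `gold`/`brush` attributes or explicitly supplied specs).
#' @param gold_spec,brush_params overrides for the series attributes.
#' @return list with `saturation_step` (index, NA if censored),
#'   `plateau_density` (PEG/nm2), `plateau_thickness` (nm), `censored`.
#' @export
analyze_titration <- function(series, gold_spec = attr(series, "gold"),
                              brush_params = attr(series, "brush")) {
  stopifnot(is.data.frame(series),
            all(c("step_added", "uptake", "supernatant") %in% names(series)))
  if (is.null(gold_spec)) stop("gold_spec required", call. = FALSE)
  if (is.null(brush_params)) brush_params <- list(n_monomers = 114, monomer_nm = 0.35)
  bal <- series$uptake + series$supernatant - series$step_added
  if (max(abs(bal)) > 1e-8 * max(series$step_added)) {
    stop("titration mass balance violated (uptake + supernatant != added)",
         call. = FALSE)
  }
  d_add <- diff(series$step_added)
  d_upt <- diff(series$uptake)
  sat <- which(d_upt < 0.01 * d_add)
  if (length(sat) == 0L) {
    return(list(saturation_step = NA_integer_, plateau_density = NA_real_,
                plateau_thickness = NA_real_, censored = TRUE))
  }
  step <- sat[1L] + 1L  # first step past the saturating increment
  n_particles <- gold_spec$particle_concentration_per_uL * gold_spec$volume_uL
  dens <- grafting_density(series$uptake[step], gold_spec$core_diameter_nm, n_particles)
  list(saturation_step = step,
       plateau_density = dens,
       plateau_thickness = brush_thickness(brush_params$n_monomers,
                                           brush_params$monomer_nm, dens),
       censored = FALSE)
}
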