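#' Particle populations
#'
#' A `particle_population` is the number-weighted sample of core diameters
#' (nm) that every downstream stage consumes. It is a thin S3 wrapper around
#' a numeric vector so that generative parameters (median, log-sd, seed)
#' travel with the sample.
#'
#' @name particle_population
NULL

new_particle_population <- function(diameters, label = "", generative = NULL) {
  stopifnot(is.numeric(diameters), length(diameters) >= 1L)
  if (any(!is.finite(diameters)) || any(diameters <= 0)) {
    stop("all diameters must be finite and positive", call. = FALSE)
  }
  structure(
    list(diameters = as.numeric(diameters), label = as.character(label),
         generative = generative),
    class = "particle_population"
  )
}

#' @export
print.particle_population <- function(x, ...) {
  cat(sprintf("<particle_population> '%s': n = %d, median = %.3g nm, rel SD = %.3g\n",
              x$label, length(x$diameters), stats::median(x$diameters),
              stats::sd(x$diameters) / mean(x$diameters)))
  invisible(x)
}

#' @export
length.particle_population <- function(x) length(x$diameters)

#' Generate a log-normal core population
#'
#' Draws `n` core diameters from a log-normal distribution parameterized by
#' its median and a target relative standard deviation. The log-scale SD is
#' `sigma_log = sqrt(log(1 + rel_sd^2))`, the moment identity under which the
#' sample relative SD converges to `rel_sd` as `n` grows. A constant
#' `rel_sd` across a dilution series emulates commercial citrate-stabilized
#' gold nanoparticle size series, whose relative width is constant across
#' nominal sizes.
#'
#' @param median_nm population median diameter (nm), > 0.
#' @param rel_sd target relative standard deviation, in `[0, 1)`. Zero gives
#'   an exactly monodisperse sample.
#' @param n number of particles (>= 1).
#' @param seed integer seed; mandatory, draws are bit-reproducible.
#' @param label optional sample label carried through the pipeline.
#' @return A `particle_population`.
#' @export
gen_core_population <- function(median_nm, rel_sd, n, seed, label = NULL) {
  if (!is.numeric(median_nm) || length(median_nm) != 1L || median_nm <= 0) {
    stop("median_nm must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(rel_sd) || rel_sd < 0 || rel_sd >= 1) {
    stop("rel_sd must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (missing(seed) || is.null(seed)) {
    stop("seed is mandatory for stochastic generation", call. = FALSE)
  }
  n <- as.integer(n)
  sigma_log <- sqrt(log(1 + rel_sd^2))
  d <- if (sigma_log == 0) {
    rep(median_nm, n)
  } else {
    withr::with_seed(seed, stats::rlnorm(n, meanlog = log(median_nm), sdlog = sigma_log))
  }
  if (is.null(label)) label <- sprintf("%g nm", median_nm)
  new_particle_population(
    d, label = label,
    generative = list(median_nm = median_nm, sigma_log = sigma_log,
                      rel_sd = rel_sd, n = n, seed = seed)
  )
}

#' Generate the nominal gold reference series
#'
#' Convenience wrapper producing one population per nominal size of the
#' 11-member gold series (5, 10, 30, 40, 50, 60, 80, 100, 150, 200, 250 nm),
#' each with the same relative SD. Per-population seeds are derived from
#' `seed` deterministically.
#'
#' @param nominal_nm nominal median diameters (nm).
#' @param rel_sd shared relative standard deviation.
#' @param n particles per population.
#' @param seed base seed.
#' @return named list of `particle_population`.
#' @export
gen_gold_series <- function(nominal_nm = c(5, 10, 30, 40, 50, 60, 80, 100, 150, 200, 250),
                            rel_sd = 0.05, n = 500, seed = 1) {
  pops <- lapply(seq_along(nominal_nm), function(i) {
    gen_core_population(nominal_nm[i], rel_sd, n, seed = (seed * 1009L + i) %% 2147483647L,
                        label = sprintf("%g nm", nominal_nm[i]))
  })
  names(pops) <- vapply(pops, function(p) p$label, character(1))
  pops
}

#' Functionalize a core population with a uniform shell
#'
#' Adds a shell of thickness `L` (nm) to every particle: hydrodynamic
#' diameter d2 = d1 + 2L, deterministically. The distribution width is
#' preserved (the shell shifts, never broadens, the size distribution) and
#' the operation is exactly invertible by subtracting 2L.
#'
#' @param pop a `particle_population` of cores.
#' @param shell_thickness_nm shell thickness L >= 0 (nm).
#' @return A `functionalized_population` with fields `core`,
#'   `shell_thickness_nm` and `hydrodynamic_diameters`.
#' @export
functionalize <- function(pop, shell_thickness_nm) {
  stopifnot(inherits(pop, "particle_population"))
  if (!is.numeric(shell_thickness_nm) || length(shell_thickness_nm) != 1L ||
      shell_thickness_nm < 0) {
    stop("shell_thickness_nm must be a single non-negative number", call. = FALSE)
  }
  structure(
    list(core = pop,
         shell_thickness_nm = shell_thickness_nm,
         hydrodynamic_diameters = pop$diameters + 2 * shell_thickness_nm),
    class = "functionalized_population"
  )
}

#' @export
print.functionalized_population <- function(x, ...) {
  cat(sprintf("<functionalized_population> core '%s' + shell L = %g nm\n",
              x$core$label, x$shell_thickness_nm))
  invisible(x)
}

#' Formulation descriptor for a polyplex
#'
#' Records the formulation parameters that drive self-assembly: the molar
#' N/P ratio (PEI nitrogen per nucleic-acid phosphate), the PEI/(R)PP amine
#' blend ratio of unconjugated to PEGylated PEI, the degree of PEG
#' conjugation (% of PEI amines carrying a PEG chain), and the nucleic acid.
#'
#' @param np_ratio molar N/P ratio, > 0.
#' @param pei_pp_ratio molar PEI/(R)PP amine ratio, > 0.
#' @param conjugation_pct percentage of PEI amines bearing PEG, in (0, 100].
#' @param nucleic_acid list with `name`, `mw_g_per_mol`, `shape_factor`
#'   (AFM height-to-equivalent-sphere correction; 1.2 for oligo DNA, 1.7 for
#'   siRNA polyplexes).
#' @return A `formulation`.
#' @export
formulation <- function(np_ratio = 4, pei_pp_ratio = 10, conjugation_pct = 10,
                        nucleic_acid = list(name = "oligo", mw_g_per_mol = 12850,
                                            shape_factor = 1.2)) {
  if (np_ratio <= 0) stop("np_ratio must be positive", call. = FALSE)
  if (pei_pp_ratio <= 0) stop("pei_pp_ratio must be positive", call. = FALSE)
  if (conjugation_pct <= 0 || conjugation_pct > 100) {
    stop("conjugation_pct must lie in (0, 100]", call. = FALSE)
  }
  structure(list(np_ratio = np_ratio, pei_pp_ratio = pei_pp_ratio,
                 conjugation_pct = conjugation_pct, nucleic_acid = nucleic_acid),
            class = "formulation")
}

#' Default polydispersity schedule for polyplex cores
#'
#' The observed trend is qualitative: core polydispersity grows with the
#' PEI/(R)PP ratio through the middle of the parameter space and narrows
#' again once cores exceed ~100 nm. As a stand-in functional form we use a
#' Gaussian bump in log(ratio) centered at 10:1 on a narrow baseline:
#' `sigma_log(r) = base + amp * exp(-(log(r) - log(center))^2 / (2 * width^2))`.
#'
#' @param base baseline log-sd away from the bump (default 0.05, gold-like).
#' @param amp bump amplitude (default 0.20, so sigma_log peaks at 0.25).
#' @param center PEI/(R)PP ratio of maximal polydispersity (default 10).
#' @param width bump width in log units (default 0.6).
#' @return A function `ratio -> sigma_log`.
#' @export
default_polydispersity_schedule <- function(base = 0.05, amp = 0.20,
                                            center = 10, width = 0.6) {
  force(base); force(amp); force(center); force(width)
  function(pei_pp_ratio) {
    base + amp * exp(-(log(pei_pp_ratio) - log(center))^2 / (2 * width^2))
  }
}

#' Generate polyplex cores under the equilibrium-grafting-density growth model
#'
#' Cores grow by PEI-driven condensation of nucleic acid until the PEG
#' grafting density on their total surface falls to the equilibrium density
#' D* — the shell then arrests further growth. At fixed total core volume
#' V_tot this pins the median diameter at `d = 6 * V_tot * D* / P_total`
#' (monodisperse-sphere surface/volume identity), with P_total the total
#' number of PEG chains in the formulation. The sample polydispersity
#' follows `polydispersity_schedule(pei_pp_ratio)`.
#'
#' @param formulation a [formulation()].
#' @param model list with `equilibrium_density_per_nm2` (D*, PEG/nm2),
#'   `total_core_volume_nm3` (V_tot) and either `total_peg_count` (P_total,
#'   used as given) or `total_amine_count` (all PEI amines in the blend; then
#'   only the PEGylated fraction `1 / (1 + pei_pp_ratio)` of them can carry
#'   PEG, and P_total = amines / (1 + pei_pp_ratio) * conjugation_pct / 100).
#' @param polydispersity_schedule function mapping pei_pp_ratio to sigma_log;
#'   default [default_polydispersity_schedule()].
#' @param n number of cores to draw.
#' @param seed integer seed (mandatory).
#' @return A `particle_population`; its `generative` field records the model.
#' @export
gen_polyplex_cores <- function(formulation, model,
                               polydispersity_schedule = default_polydispersity_schedule(),
                               n = 500, seed) {
  stopifnot(inherits(formulation, "formulation"), is.list(model))
  if (missing(seed) || is.null(seed)) {
    stop("seed is mandatory for stochastic generation", call. = FALSE)
  }
  dstar <- model$equilibrium_density_per_nm2
  vtot <- model$total_core_volume_nm3
  if (is.null(dstar) || dstar <= 0 || is.null(vtot) || vtot <= 0) {
    stop("model must supply positive equilibrium_density_per_nm2 and total_core_volume_nm3",
         call. = FALSE)
  }
  ptotal <- model$total_peg_count
  if (is.null(ptotal)) {
    if (is.null(model$total_amine_count) || model$total_amine_count <= 0) {
      stop("model needs total_peg_count or total_amine_count", call. = FALSE)
    }
    ptotal <- model$total_amine_count / (1 + formulation$pei_pp_ratio) *
      formulation$conjugation_pct / 100
  }
  if (ptotal <= 0) {
    stop("total PEG count must be positive: shell-limited growth requires PEG",
         call. = FALSE)
  }
  median_nm <- equilibrium_core_diameter(vtot, ptotal, dstar)
  sigma_log <- polydispersity_schedule(formulation$pei_pp_ratio)
  rel_sd <- sqrt(exp(sigma_log^2) - 1)
  pop <- gen_core_population(median_nm, rel_sd, n, seed,
                             label = sprintf("polyplex %g:1", formulation$pei_pp_ratio))
  pop$generative$model <- list(equilibrium_density_per_nm2 = dstar,
                               total_core_volume_nm3 = vtot,
                               total_peg_count = ptotal)
  pop$generative$formulation <- formulation
  pop
}
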