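#' Polymer-brush shell thickness
#'
#' Brush-regime scaling for a grafted polymer layer: `L = N * a^(5/3) * D^(1/3)`
#' with N the monomer count per chain, a the monomer size (nm) and D the
#' grafting density (chains/nm2). For 5-kDa PEG, N = 114 and a = 0.35 nm.
#'
#' @param n_monomers monomers per chain N, > 0.
#' @param monomer_nm monomer size a (nm), > 0.
#' @param density_per_nm2 grafting density D (chains/nm2), >= 0.
#' @return shell thickness L (nm). Vectorized over `density_per_nm2`.
#' @export
brush_thickness <- function(n_monomers, monomer_nm, density_per_nm2) {
  if (n_monomers <= 0 || monomer_nm <= 0) {
    stop("n_monomers and monomer_nm must be positive", call. = FALSE)
  }
  if (any(density_per_nm2 < 0)) stop("density must be non-negative", call. = FALSE)
  n_monomers * monomer_nm^(5/3) * density_per_nm2^(1/3)
}

#' Invert the brush model for grafting density
#'
#' `D = (L / (N * a^(5/3)))^3`; exact inverse of [brush_thickness()].
#'
#' @param thickness_nm shell thickness L (nm), >= 0.
#' @inheritParams brush_thickness
#' @return grafting density (chains/nm2).
#' @export
brush_density <- function(thickness_nm, n_monomers, monomer_nm) {
  if (n_monomers <= 0 || monomer_nm <= 0) {
    stop("n_monomers and monomer_nm must be positive", call. = FALSE)
  }
  if (any(thickness_nm < 0)) stop("thickness must be non-negative", call. = FALSE)
  (thickness_nm / (n_monomers * monomer_nm^(5/3)))^3
}

#' Monomer count of a PEG chain from its molar mass
#'
#' Rounds `mw_polymer / mw_repeat` to the nearest integer; the ethylene
#' oxide repeat unit is 44.05 g/mol, so 5-kDa PEG has N = 114.
#'
#' @param mw_polymer polymer molar mass (g/mol).
#' @param mw_repeat repeat-unit molar mass (g/mol), default 44.05.
#' @return integer monomer count.
#' @export
monomer_count <- function(mw_polymer, mw_repeat = 44.05) {
  if (any(mw_polymer <= 0) || mw_repeat <= 0) {
    stop("molar masses must be positive", call. = FALSE)
  }
  as.integer(round(mw_polymer / mw_repeat))
}

#' Grafting density from uptake, core size and particle count
#'
#' Chains per unit area on spherical cores: `D = uptake / (count * pi * d^2)`.
#' This is the complete-uptake estimate combining (i) the amount of PEG mixed
#' in, (ii) the AFM core size and (iii) the particle concentration.
#'
#' @param peg_molecules_taken_up number of chains adsorbed (vectorized).
#' @param core_diameter_nm sphere diameter d (nm).
#' @param particle_count number of particles.
#' @return grafting density (PEG/nm2).
#' @export
grafting_density <- function(peg_molecules_taken_up, core_diameter_nm, particle_count) {
  if (core_diameter_nm <= 0 || particle_count <= 0) {
    stop("core diameter and particle count must be positive", call. = FALSE)
  }
  if (any(peg_molecules_taken_up < 0)) stop("uptake must be non-negative", call. = FALSE)
  peg_molecules_taken_up / (particle_count * pi * core_diameter_nm^2)
}

#' DNA mass fraction of a polyplex core from the N/P ratio
#'
#' Stoichiometric bookkeeping for the core composition: one nucleotide
#' carries one phosphate (330 g/mol of DNA per phosphate) and PEI carries one
#' nitrogen per 43.1 g/mol. At molar ratio N/P = r the DNA mass fraction is
#' `f = 330 / (330 + r * 43.1)`; r -> 0 recovers a pure-DNA core.
#'
#' @param np_ratio molar N/P ratio, > 0.
#' @param mw_per_phosphate g DNA per mol phosphate (default 330).
#' @param mw_per_nitrogen g PEI per mol nitrogen (default 43.1).
#' @return DNA mass fraction in (0, 1).
#' @export
dna_mass_fraction <- function(np_ratio, mw_per_phosphate = 330, mw_per_nitrogen = 43.1) {
  if (any(np_ratio <= 0)) stop("np_ratio must be positive", call. = FALSE)
  mw_per_phosphate / (mw_per_phosphate + np_ratio * mw_per_nitrogen)
}

#' Payload parameters
#'
#' Defaults follow the oligo-DNA system: core density 1370 ug/uL
#' (protein-compressibility-based approximation) and oligo MW 12850 g/mol.
#'
#' @param core_density_ug_per_uL core mass density rho (ug/uL).
#' @param na_mw_g_per_mol nucleic-acid molar mass (g/mol).
#' @param dna_mass_fraction DNA mass fraction f of the core, in (0, 1].
#' @return a `payload_params` list.
#' @export
payload_params <- function(core_density_ug_per_uL = 1370,
                           na_mw_g_per_mol = 12850,
                           dna_mass_fraction = nanoshell::dna_mass_fraction(4)) {
  stopifnot(core_density_ug_per_uL > 0, na_mw_g_per_mol > 0,
            dna_mass_fraction > 0, dna_mass_fraction <= 1)
  structure(list(core_density_ug_per_uL = core_density_ug_per_uL,
                 na_mw_g_per_mol = na_mw_g_per_mol,
                 dna_mass_fraction = dna_mass_fraction),
            class = "payload_params")
}

# 1 ug/uL = 1e-6 g / 1e18 nm3 = 1e-24 g/nm3 (1 uL = 1 mm3 = 1e18 nm3)
ug_per_ul_to_g_per_nm3 <- function(x) x * 1e-24

AVOGADRO <- 6.02214076e23

#' Nucleic-acid payload per particle
#'
#' Number of nucleic-acid molecules condensed in one spherical core:
#' `count = (pi/6) d^3 * rho * f / MW * N_A`, with d the AFM core diameter
#' (nm), rho the core density converted to g/nm3, f the DNA mass fraction and
#' MW the nucleic-acid molar mass. A 30-nm oligo core at N/P = 4 holds about
#' 6e2 oligos.
#'
#' @param core_diameter_nm core diameter(s), nm.
#' @param params a [payload_params()].
#' @return molecules per particle (vectorized over diameter).
#' @export
payload_count <- function(core_diameter_nm, params = payload_params()) {
  if (any(core_diameter_nm <= 0)) stop("diameter must be positive", call. = FALSE)
  rho <- ug_per_ul_to_g_per_nm3(params$core_density_ug_per_uL)
  vol <- pi / 6 * core_diameter_nm^3
  vol * rho * params$dna_mass_fraction / params$na_mw_g_per_mol * AVOGADRO
}

#' Equilibrium core diameter under shell-limited growth
#'
#' If condensation continues until the PEG grafting density on the total
#' core surface relaxes to the equilibrium value D*, then for a fixed total
#' core volume V_tot (set by the amount of nucleic acid and PEI) and total
#' PEG count P the monodisperse-sphere identity A_tot = 6 V_tot / d pins
#' the diameter at `d = 6 * V_tot * D* / P`.
#'
#' @param total_core_volume_nm3 V_tot (nm3), > 0.
#' @param total_peg_count P, > 0.
#' @param equilibrium_density_per_nm2 D* (PEG/nm2), > 0.
#' @return equilibrium core diameter (nm).
#' @export
equilibrium_core_diameter <- function(total_core_volume_nm3, total_peg_count,
                                      equilibrium_density_per_nm2) {
  if (any(c(total_core_volume_nm3, total_peg_count, equilibrium_density_per_nm2) <= 0)) {
    stop("all growth-model inputs must be positive", call. = FALSE)
  }
  6 * total_core_volume_nm3 * equilibrium_density_per_nm2 / total_peg_count
}

#' Total-surface-area ratio of two conjugation degrees
#'
#' Under the equilibrium growth model at fixed total core volume and fixed
#' PEI/nucleic-acid amounts, the total PEG count is proportional to the
#' degree of conjugation, so the total core surface areas satisfy
#' `A1 / A2 = c1 / c2` (equivalently the inverse ratio of core diameters).
#' For 7% vs 10% conjugation the ratio is 0.7.
#'
#' @param conjugation_pct_1,conjugation_pct_2 degrees of conjugation in
#'   (0, 100].
#' @return surface-area ratio A1/A2.
#' @export
surface_area_ratio <- function(conjugation_pct_1, conjugation_pct_2) {
  if (any(c(conjugation_pct_1, conjugation_pct_2) <= 0) ||
      any(c(conjugation_pct_1, conjugation_pct_2) > 100)) {
    stop("conjugation degrees must lie in (0, 100]", call. = FALSE)
  }
  conjugation_pct_1 / conjugation_pct_2
}

#' PEG chains per PEI macromolecule
#'
#' From the degree of conjugation (% of PEI amines carrying a PEG chain) and
#' the amine count of the PEI. The default amine count for branched 25-kDa
#' PEI takes all amines at one nitrogen per 43 g/mol: 25000/43 = 581.
#'
#' @param conjugation_pct degree of conjugation, (0, 100].
#' @param amines_per_pei amines per PEI macromolecule (default 581).
#' @return PEG chains per PEI.
#' @export
peg_per_pei <- function(conjugation_pct, amines_per_pei = 581) {
  if (any(conjugation_pct <= 0) || any(conjugation_pct > 100)) {
    stop("conjugation_pct must lie in (0, 100]", call. = FALSE)
  }
  amines_per_pei * conjugation_pct / 100
}
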