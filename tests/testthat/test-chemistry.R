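test_that("brush thickness follows the N a^(5/3) D^(1/3) scaling", {
  expect_equal(brush_thickness(114, 0.35, 0), 0)
  # plateau densities of the two polymer systems: cube-root scaling
  expect_equal(brush_thickness(114, 0.35, 0.5) / brush_thickness(114, 0.35, 0.15),
               (0.5 / 0.15)^(1/3))
  # 5-kDa PEG at the equilibrium density: close to the measured 17-nm shell
  L <- brush_thickness(114, 0.35, 0.5)
  expect_lt(abs(L - 17) / 17, 0.10)
  expect_error(brush_thickness(-1, 0.35, 0.5), "positive")
})

test_that("brush density inverts brush thickness to machine precision", {
  for (D in c(1e-3, 0.01, 0.15, 0.5, 2, 10)) {
    L <- brush_thickness(114, 0.35, D)
    expect_equal(brush_density(L, 114, 0.35), D, tolerance = 1e-12)
  }
})

test_that("monomer count rounds the polymer/repeat mass ratio", {
  expect_identical(monomer_count(5000), 114L)
  expect_identical(monomer_count(44.05), 1L)
  expect_identical(monomer_count(2000), 45L)
})

test_that("grafting density is uptake per total sphere surface", {
  expect_equal(grafting_density(pi * 1e4, 100, 1), 1.0)
  expect_equal(grafting_density(1e6, 100, 2), grafting_density(1e6, 100, 1) / 2)
})

test_that("DNA mass fraction is stoichiometric and monotone in N/P", {
  expect_equal(dna_mass_fraction(4), 330 / (330 + 4 * 43.1))
  expect_lt(abs(dna_mass_fraction(4) - 0.657), 0.001)
  expect_gt(dna_mass_fraction(1e-9), 0.9999999)
  np <- c(0.5, 1, 2, 4, 8)
  expect_true(all(diff(dna_mass_fraction(np)) < 0))
})

test_that("payload count matches the hand-computed 30-nm oligo core", {
  # (pi/6) 30^3 nm3 * 1.37e-21 g/nm3 * 0.657 / 12850 g/mol * N_A ~ 6e2
  params <- payload_params(1370, 12850, dna_mass_fraction(4))
  expect_equal(payload_count(30, params), 596.2, tolerance = 1e-3)
  # d^3 scaling
  expect_equal(payload_count(60, params) / payload_count(30, params), 8)
  # self-consistency: f = 1, MW = mass of one core -> exactly one molecule
  core_mass_g <- pi / 6 * 30^3 * 1.37e-21
  one <- payload_params(1370, core_mass_g * 6.02214076e23, 1)
  expect_equal(payload_count(30, one), 1, tolerance = 1e-12)
})

test_that("payload conserves total DNA mass over a population", {
  pop <- gen_core_population(40, 0.2, 2000, seed = 31)
  params <- payload_params()
  counts <- payload_count(pop$diameters, params)
  total_dna_g <- sum(counts) * params$na_mw_g_per_mol / 6.02214076e23
  vtot <- sum(pi / 6 * pop$diameters^3)
  expect_equal(total_dna_g,
               params$dna_mass_fraction * 1370e-24 * vtot,
               tolerance = 1e-12)
})

test_that("equilibrium diameter and surface-area ratio are mutually consistent", {
  expect_equal(equilibrium_core_diameter(1e9, 3e7, 1.0),
               2 * equilibrium_core_diameter(1e9, 3e7, 0.5))
  expect_equal(surface_area_ratio(7, 10), 0.7)
  expect_equal(surface_area_ratio(5, 5), 1)
  # growth-model consistency: conjugation route == diameter route, exactly
  amines <- 3e8; vtot <- 1e9; dstar <- 0.5
  d7 <- equilibrium_core_diameter(vtot, amines * 0.07, dstar)
  d10 <- equilibrium_core_diameter(vtot, amines * 0.10, dstar)
  expect_equal(surface_area_ratio(7, 10), (6 * vtot / d7) / (6 * vtot / d10),
               tolerance = 1e-14)
  expect_error(surface_area_ratio(0, 10), "conjugation")
})

test_that("titration series conserves mass and saturates hard by default", {
  gold <- list(core_diameter_nm = 100, particle_concentration_per_uL = 5.6e6,
               volume_uL = 20)
  np <- gold$particle_concentration_per_uL * gold$volume_uL
  cap <- 0.5 * np * pi * 100^2
  added <- seq(cap / 10, 2 * cap, length.out = 20)
  ser <- gen_titration(added, cap, gold)
  expect_equal(ser$uptake + ser$supernatant, ser$step_added, tolerance = 1e-15)
  expect_true(all(diff(ser$uptake) >= 0))
  # below capacity: complete uptake; at 2x capacity: half in supernatant
  expect_equal(ser$supernatant[added < cap], rep(0, sum(added < cap)))
  expect_equal(ser$uptake[20], cap)
  expect_equal(ser$supernatant[20], cap)
  expect_error(gen_titration(c(1, 1), cap, gold), "strictly increasing")
})

test_that("titration analysis recovers the generative plateau density", {
  gold <- list(core_diameter_nm = 100, particle_concentration_per_uL = 5.6e6,
               volume_uL = 20)
  np <- gold$particle_concentration_per_uL * gold$volume_uL
  for (dstar in c(0.15, 0.5)) {
    cap <- dstar * np * pi * 100^2
    added <- seq(cap / 10, 2 * cap, length.out = 25)
    res <- analyze_titration(gen_titration(added, cap, gold))
    expect_false(res$censored)
    # saturation flagged at the first step past capacity
    expect_equal(res$saturation_step, min(which(added >= cap)) + 1L)
    expect_lt(abs(res$plateau_density - dstar) / dstar, 0.02)
    expect_equal(res$plateau_thickness, brush_thickness(114, 0.35, res$plateau_density))
  }
  # soft saturation: recovery within 5%
  cap <- 0.5 * np * pi * 100^2
  added <- seq(cap / 10, 6 * cap, length.out = 60)
  soft <- analyze_titration(gen_titration(added, cap, gold, softness = 0.2))
  expect_lt(abs(soft$plateau_density - 0.5) / 0.5, 0.05)
  # no plateau -> censored, not an error
  short <- gen_titration(seq(cap / 10, cap / 2, length.out = 5), cap, gold)
  expect_true(analyze_titration(short)$censored)
})

test_that("peg_per_pei counts chains from the conjugation degree", {
  expect_equal(peg_per_pei(10), 58.1)
  expect_equal(peg_per_pei(7) / peg_per_pei(10), 0.7)
})
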