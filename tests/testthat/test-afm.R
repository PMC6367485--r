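test_that("rendered topographs are deterministic with correct peak height", {
  p <- gen_core_population(50, 0, 1, seed = 4)
  t1 <- gen_afm_topograph(p, pixel_nm = 1, field_nm = 200, seed = 5)
  t2 <- gen_afm_topograph(p, pixel_nm = 1, field_nm = 200, seed = 5)
  expect_identical(t1$heights, t2$heights)
  # noise 0, tilt 0, one 50-nm sphere: max pixel = 50 nm (within sub-pixel
  # sampling of the apex)
  expect_equal(max(t1$heights), 50, tolerance = 1e-3)
  # oblate rendering keeps ground-truth width/height at the requested aspect
  t3 <- gen_afm_topograph(gen_core_population(144, 0, 5, seed = 1),
                          pixel_nm = 1, field_nm = 1500,
                          shape_aspect = 1.728, seed = 6)
  expect_equal(t3$ground_truth$width_x_nm / t3$ground_truth$height_nm,
               rep(1.728, 5))
  # infeasible packing is rejected
  expect_error(gen_afm_topograph(gen_core_population(50, 0, 100, seed = 2),
                                 pixel_nm = 1, field_nm = 220, seed = 3),
               "field too small")
})

test_that("first-order flattening is exact on planes, idempotent, and zero-mean", {
  z <- outer(1:80, 1:80, function(i, j) 3 + 0.05 * i - 0.02 * j)
  topo <- afm_topograph(z, 2)
  flat <- flatten_first_order(topo)
  expect_lt(max(abs(flat$heights)), 1e-10)
  p <- gen_core_population(50, 0.05, 10, seed = 8)
  noisy <- gen_afm_topograph(p, pixel_nm = 2, field_nm = 800,
                             tilt_nm_per_px = 0.05, noise_sd_nm = 0.2, seed = 9)
  f1 <- flatten_first_order(noisy)
  f2 <- flatten_first_order(f1)
  expect_equal(f2$heights, f1$heights, tolerance = 1e-10)
  expect_lt(abs(mean(f1$heights)), 1e-10)
  expect_error(flatten_first_order(topo, matrix(TRUE, 80, 80)), "masked")
})

test_that("flattening with a particle mask preserves peak heights within noise", {
  p <- gen_core_population(50, 0.05, 12, seed = 14)
  topo <- gen_afm_topograph(p, pixel_nm = 2, field_nm = 900,
                            tilt_nm_per_px = 0.05, noise_sd_nm = 0.2, seed = 15)
  m <- measure_topograph(topo, min_height_nm = 5)
  ok <- m[!m$excluded, ]
  truth <- sort(topo$ground_truth$height_nm)
  expect_equal(nrow(ok) + sum(m$excluded), 12L)
  matched <- sort(ok$height_nm)
  if (nrow(ok) == 12L) {
    expect_lt(max(abs(matched - truth)), 5 * 0.2 + 0.5)
  }
})

test_that("detection counts isolated particles and ignores blank noise", {
  blank <- afm_topograph(matrix(rnorm(100 * 100, 0, 0.3), 100, 100), 2)
  expect_length(detect_particles(flatten_first_order(blank), 5 * 0.3), 0L)
  p <- gen_core_population(60, 0.05, 15, seed = 16)
  topo <- gen_afm_topograph(p, pixel_nm = 2, field_nm = 1100,
                            noise_sd_nm = 0.3, seed = 17)
  regs <- detect_particles(flatten_first_order(topo), 1.5)
  expect_length(regs, 15L)
})

test_that("fused particle pairs are excluded by the eccentricity filter", {
  topo <- fused_pair_topograph()
  flat <- flatten_first_order(topo)
  regs <- detect_particles(flat, 5)
  expect_length(regs, 1L)   # merged into a single region
  m <- measure_particle(flat, regs[[1]])
  expect_true(m$excluded)
  expect_identical(m$reason, "fused")
})

test_that("border-touching regions are excluded with a reason", {
  z <- matrix(0, 120, 120)
  z <- nanoshell:::render_spheroid(z, 1, 2, 60, 50, 50)   # clipped at border
  flat <- flatten_first_order(afm_topograph(z, 1))
  regs <- detect_particles(flat, 5)
  m <- measure_particle(flat, regs[[1]])
  expect_true(m$excluded)
  expect_identical(m$reason, "border")
})

test_that("sphere measurement gives h = w1 = w2 = d within a pixel", {
  p <- gen_core_population(50, 0, 1, seed = 4)
  topo <- gen_afm_topograph(p, pixel_nm = 1, field_nm = 200, seed = 5)
  m <- measure_topograph(topo, min_height_nm = 5)
  expect_equal(m$height_nm, 50, tolerance = 1e-3)
  expect_lt(abs(m$width1_nm - 50), 1 + 1e-9)    # half-max width within 1 px
  expect_lt(abs(m$width2_nm - 50), 1 + 1e-9)
  expect_lt(abs(m$aspect - 1), 0.05)
})

test_that("oblate spheroids are measured at the rendered aspect ratio", {
  p <- gen_core_population(144, 0, 12, seed = 2)
  topo <- gen_afm_topograph(p, pixel_nm = 1, field_nm = 2000,
                            shape_aspect = 1.728, seed = 3)
  m <- measure_topograph(topo, min_height_nm = 5)
  ok <- m[!m$excluded, ]
  expect_gte(nrow(ok), 10L)
  expect_lt(max(abs(ok$aspect - 1.728) / 1.728), 0.05)
})

test_that("equivalent-sphere diameter uses the volume-preserving convention", {
  expect_equal(equivalent_sphere_diameter(50, 50, 50), 50)
  expect_equal(equivalent_sphere_diameter(100, 172.8, 172.8), 144,
               tolerance = 1e-3)
  expect_error(equivalent_sphere_diameter(0, 10, 10), "positive")
})

test_that("shape correction factor is 1 for spheres and 1.44 at aspect 1.728", {
  spheres <- data.frame(height_nm = seq(30, 80, length.out = 12),
                        d_eq_nm = seq(30, 80, length.out = 12),
                        excluded = FALSE)
  expect_equal(shape_correction_factor(spheres)$f, 1)
  # scale invariance
  scaled <- transform(spheres, height_nm = height_nm * 3, d_eq_nm = d_eq_nm * 3)
  expect_equal(shape_correction_factor(scaled)$f, 1)
  p <- gen_core_population(144, 0, 12, seed = 2)
  topo <- gen_afm_topograph(p, pixel_nm = 1, field_nm = 2000,
                            shape_aspect = 1.728, seed = 3)
  m <- measure_topograph(topo, min_height_nm = 5)
  f <- shape_correction_factor(m)
  expect_lt(abs(f$f - 1.44) / 1.44, 0.05)
  # factor applied to a height-only population is elementwise multiplication
  h <- c(20, 30, 40)
  expect_equal(f$f * h, h * f$f)
  expect_error(shape_correction_factor(spheres[1:5, ]), "at least")
})

test_that("log-normal MLE recovers parameters and satisfies the mode identity", {
  p <- gen_core_population(100, sqrt(exp(0.1^2) - 1), 5000, seed = 51)
  fit <- fit_lognormal(p$diameters)
  expect_lt(abs(fit$median_nm - 100) / 100, 0.01)
  expect_lt(abs(fit$sigma_log - 0.1) / 0.1, 0.05)
  expect_equal(fit$mode_nm, fit$median_nm * exp(-fit$sigma_log^2))
  mono <- fit_lognormal(rep(60, 25))
  expect_equal(mono$sigma_log, 0)
  expect_equal(mono$mode_nm, mono$median_nm)
  expect_error(fit_lognormal(c(rep(10, 25), -1)), "positive")
  expect_error(fit_lognormal(rep(10, 5)), "at least 20")
})
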