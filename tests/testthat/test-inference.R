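make_pair <- function(n = 11, delta = 34, labels = sprintf("s%02d", seq_len(n)),
                      d = seq(50, 250, length.out = n)) {
  build_series_pair(
    data.frame(label = labels, d_afm_nm = d, sigma_log_afm = 0.05),
    data.frame(label = labels, d_dls_nm = d + delta)
  )
}

test_that("series pairs join on labels and report unmatched rows", {
  pair <- make_pair(11)
  expect_s3_class(pair, "series_pair")
  expect_equal(nrow(pair), 11L)
  expect_length(attr(pair, "unmatched"), 0L)
  afm <- data.frame(label = c("a", "b"), d_afm_nm = c(50, 100))
  dls <- data.frame(label = c("a", "c"), d_dls_nm = c(84, 130))
  joined <- build_series_pair(afm, dls)
  expect_equal(nrow(joined), 1L)
  expect_setequal(attr(joined, "unmatched"), c("b", "c"))
  dup <- data.frame(label = c("a", "a"), d_afm_nm = c(50, 60))
  expect_error(build_series_pair(dup, dls), "duplicate")
  expect_error(build_series_pair(afm, data.frame(label = "z", d_dls_nm = 10)),
               "no common labels")
})

test_that("screening flags small cores and broad distributions without deleting", {
  pair <- build_series_pair(
    data.frame(label = sprintf("%g nm", gold_nominal), d_afm_nm = gold_nominal,
               sigma_log_afm = 0.05),
    data.frame(label = sprintf("%g nm", gold_nominal), d_dls_nm = gold_nominal + 34)
  )
  sc <- screen_rows(pair)
  expect_equal(nrow(sc), 11L)   # nothing deleted
  expect_setequal(sc$label[sc$excluded], c("5 nm", "10 nm", "30 nm", "40 nm"))
  expect_true(all(sc$reason[sc$excluded] == "curvature"))
  # a broad row is flagged for polydispersity
  pair2 <- make_pair(5, d = c(60, 80, 100, 120, 140))
  pair2$sigma_log_afm[3] <- 0.30
  sc2 <- screen_rows(pair2)
  expect_identical(sc2$reason[3], "polydispersity")
  # all-narrow large series: none flagged
  expect_false(any(screen_rows(make_pair(5, d = c(60, 80, 100, 120, 140)))$excluded))
  # too few survivors is an error
  small <- make_pair(3, d = c(10, 20, 30))
  expect_error(screen_rows(small), "fewer than 2")
})

test_that("an exact offset series is recovered deterministically", {
  est <- estimate_shell_thickness(make_pair(7, delta = 34,
                                            d = c(50, 60, 80, 100, 150, 200, 250)))
  expect_equal(est$thickness_nm, 17)
  expect_equal(est$se_nm, 0)
  expect_equal(est$n_used, 7L)
  expect_equal(est$slope_diagnostic, 1, tolerance = 1e-9)
})

test_that("negative fitted shells are flagged, never clamped", {
  pair <- make_pair(4, delta = -6, d = c(60, 80, 100, 120))
  expect_warning(est <- estimate_shell_thickness(pair), "negative")
  expect_equal(est$thickness_nm, -3)
  expect_true(est$negative_warning)
})

test_that("offset estimator is unbiased with calibrated interval coverage", {
  nominal <- c(50, 60, 80, 100, 150, 200, 250)
  for (L_true in c(8, 17)) {
    Lh <- se <- numeric(200)
    for (s in seq_len(200)) {
      est <- estimate_shell_thickness(
        simulate_series_pair(nominal, L_true, 0.028, 0.016, seed = s))
      Lh[s] <- est$thickness_nm; se[s] <- est$se_nm
    }
    mc_se <- sd(Lh) / sqrt(200)
    expect_lt(abs(mean(Lh) - L_true), 3 * mc_se + 0.25)
    expect_lt(abs(mean(Lh) - L_true), 1)
    coverage <- mean(abs(Lh - L_true) <= 2 * se)
    expect_lt(abs(coverage - 0.95), 0.07)
  }
})

test_that("adding a biased broad-distribution row degrades the estimate", {
  # a wide-distribution member whose DLS side carries the polydispersity
  # bias; including it should not improve accuracy in expectation
  nominal <- c(50, 60, 80, 100, 150, 200, 250)
  sigma_wide <- 0.30
  bias <- 100 * (exp(5.5 * sigma_wide^2) - exp(-sigma_wide^2))
  err_with <- err_without <- numeric(100)
  for (s in seq_len(100)) {
    pair <- simulate_series_pair(nominal, 17, 0.028, 0.016, seed = 1000 + s)
    wide <- build_series_pair(
      data.frame(label = "wide", d_afm_nm = 100, sigma_log_afm = sigma_wide),
      data.frame(label = "wide", d_dls_nm = 100 + 34 + bias))
    both <- rbind(pair, wide)
    class(both) <- class(pair)
    err_without[s] <- abs(estimate_shell_thickness(pair)$thickness_nm - 17)
    err_with[s] <- abs(estimate_shell_thickness(both)$thickness_nm - 17)
  }
  expect_gt(mean(err_with), mean(err_without))
  # screening removes exactly that row
  both <- rbind(simulate_series_pair(nominal, 17, 0.028, 0.016, seed = 7),
                build_series_pair(
                  data.frame(label = "wide", d_afm_nm = 100,
                             sigma_log_afm = sigma_wide),
                  data.frame(label = "wide", d_dls_nm = 134 + bias)))
  class(both) <- c("series_pair", "data.frame")
  sc <- screen_rows(both)
  expect_identical(sc$label[sc$excluded], "wide")
})

test_that("polydispersity gap is zero for monodisperse and grows with sigma", {
  expect_equal(polydispersity_gap(rep(100, 50)), 0, tolerance = 1e-12)
  # closed-form check at sigma = 0.2, median 100 (quantile sample, n large)
  qs <- seq(0.00025, 0.99975, length.out = 4000)
  gap <- polydispersity_gap(stats::qlnorm(qs, log(100), 0.2))
  expect_equal(gap, 100 * (exp(5.5 * 0.04) - exp(-0.04)), tolerance = 0.03 * 28.5)
  gaps <- vapply(c(0.05, 0.1, 0.15, 0.2, 0.25), function(s)
    polydispersity_gap(stats::qlnorm(qs, log(100), s)), numeric(1))
  expect_true(all(diff(gaps) > 0))
  expect_true(all(gaps > 0))
})

test_that("uncertainty budgets combine in quadrature with coverage factor", {
  b <- combine_uncertainty(c(afm = 3, dls = 4))
  expect_equal(b$combined_pct, 5)
  expect_equal(b$expanded_pct, 10)
  expect_identical(b$confidence_label, "95% confidence interval")
  expect_equal(combine_uncertainty(7)$combined_pct, 7)
  # permutation invariance and degree-1 homogeneity
  expect_equal(combine_uncertainty(c(1, 2, 3))$combined_pct,
               combine_uncertainty(c(3, 1, 2))$combined_pct)
  expect_equal(combine_uncertainty(2 * c(1, 2, 3))$combined_pct,
               2 * combine_uncertainty(c(1, 2, 3))$combined_pct)
  expect_error(combine_uncertainty(numeric(0)), "at least one")
  expect_error(combine_uncertainty(c(1, -2)), "non-negative")
})
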