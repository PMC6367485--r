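#' Join AFM and DLS results into a series pair
#'
#' One row per sample label, combining the modal corrected AFM core
#' diameter with the DLS z-average. Labels present on only one side are
#' reported in the `unmatched` attribute, never dropped silently; duplicate
#' labels are an error.
#'
#' @param afm_fits data.frame with columns `label`, `d_afm_nm` and
#'   optionally `sigma_log_afm`.
#' @param dls_results data.frame with columns `label`, `d_dls_nm`.
#' @return a `series_pair` data.frame with columns `label`, `d_afm_nm`,
#'   `d_dls_nm`, `sigma_log_afm`, `excluded`, `reason`; attribute
#'   `unmatched` lists one-sided labels.
#' @export
build_series_pair <- function(afm_fits, dls_results) {
  stopifnot(all(c("label", "d_afm_nm") %in% names(afm_fits)),
            all(c("label", "d_dls_nm") %in% names(dls_results)))
  if (anyDuplicated(afm_fits$label)) stop("duplicate labels in AFM table", call. = FALSE)
  if (anyDuplicated(dls_results$label)) stop("duplicate labels in DLS table", call. = FALSE)
  common <- intersect(afm_fits$label, dls_results$label)
  if (length(common) == 0L) stop("no common labels between AFM and DLS tables",
                                 call. = FALSE)
  a <- afm_fits[match(common, afm_fits$label), , drop = FALSE]
  d <- dls_results[match(common, dls_results$label), , drop = FALSE]
  out <- data.frame(label = common,
                    d_afm_nm = a$d_afm_nm,
                    d_dls_nm = d$d_dls_nm,
                    sigma_log_afm = if ("sigma_log_afm" %in% names(a))
                      a$sigma_log_afm else NA_real_,
                    excluded = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  if (any(out$d_afm_nm <= 0) || any(out$d_dls_nm <= 0)) {
    stop("diameters must be positive", call. = FALSE)
  }
  attr(out, "unmatched") <- setdiff(union(afm_fits$label, dls_results$label), common)
  class(out) <- c("series_pair", "data.frame")
  out
}

#' Screen series-pair rows for curvature and polydispersity
#'
#' Flags (never deletes) rows that would bias the trendline shift: cores
#' below `min_core_nm` (default 50 nm, below which brush curvature thins the
#' shell noticeably) are flagged `"curvature"`; rows with
#' `sigma_log_afm > max_sigma_log` (broad distributions, whose DLS and AFM
#' responses diverge) are flagged `"polydispersity"`.
#'
#' @param pair a `series_pair`.
#' @param min_core_nm curvature cutoff (nm), default 50.
#' @param max_sigma_log narrow-distribution cutoff on the AFM log-sd,
#'   default 0.15.
#' @return the pair with `excluded`/`reason` updated; errors if fewer than
#'   2 rows survive.
#' @export
screen_rows <- function(pair, min_core_nm = 50, max_sigma_log = 0.15) {
  stopifnot(inherits(pair, "series_pair"), min_core_nm > 0, max_sigma_log > 0)
  curv <- pair$d_afm_nm < min_core_nm
  poly <- !is.na(pair$sigma_log_afm) & pair$sigma_log_afm > max_sigma_log
  pair$excluded <- pair$excluded | curv | poly
  pair$reason <- ifelse(curv, "curvature", ifelse(poly, "polydispersity", pair$reason))
  if (sum(!pair$excluded) < 2L) {
    stop("fewer than 2 rows survive screening", call. = FALSE)
  }
  pair
}

#' Shell thickness from the trendline shift
#'
#' The bare reference series shows a ~1:1 relation between AFM and DLS
#' sizes, so the functionalized series is fitted as
#' `d_dls = d_afm + Delta` with the slope fixed at 1: Delta is the
#' (inverse-variance weighted, if uncertainties are present) mean offset
#' over the screened rows, and the shell thickness is `L = Delta / 2` with
#' the standard error of that mean, halved. A free-slope fit is reported as
#' a diagnostic but never used for L. A negative fitted shell is returned
#' with a warning flag, never clamped.
#'
#' @param pair a screened `series_pair`.
#' @param weights optional per-row weights (e.g. inverse variances);
#'   default equal weights over included rows.
#' @return a `shell_estimate`: list with `thickness_nm`, `se_nm`, `n_used`,
#'   `excluded` (labels + reasons), `slope_diagnostic`, `negative_warning`.
#' @export
estimate_shell_thickness <- function(pair, weights = NULL) {
  stopifnot(inherits(pair, "series_pair"))
  use <- !pair$excluded
  if (sum(use) < 2L) stop("need at least 2 included rows", call. = FALSE)
  x <- pair$d_afm_nm[use]; y <- pair$d_dls_nm[use]
  w <- if (is.null(weights)) rep(1, sum(use)) else {
    stopifnot(length(weights) == nrow(pair))
    weights[use]
  }
  w <- w / sum(w)
  offs <- y - x
  delta <- sum(w * offs)
  # weighted SE of the weighted mean offset
  n_eff <- 1 / sum(w^2)
  var_w <- sum(w * (offs - delta)^2) * n_eff / (n_eff - 1)
  se_delta <- sqrt(var_w / n_eff)
  slope_fit <- stats::lm(y ~ x, weights = w)
  est <- list(thickness_nm = delta / 2,
              se_nm = se_delta / 2,
              n_used = sum(use),
              excluded = pair[pair$excluded, c("label", "reason"), drop = FALSE],
              slope_diagnostic = unname(stats::coef(slope_fit)[2]),
              negative_warning = delta < 0)
  if (est$negative_warning) {
    warning("fitted shell thickness is negative; check screening")
  }
  structure(est, class = "shell_estimate")
}

#' @export
print.shell_estimate <- function(x, ...) {
  cat(sprintf("<shell_estimate> L = %.2f nm (se %.2f nm, n = %d, %d excluded)\n",
              x$thickness_nm, x$se_nm, x$n_used, nrow(x$excluded)))
  invisible(x)
}

#' Simulate a measured series pair
#'
#' Generates the per-sample summary table that the trendline-shift method
#' consumes: nominal core diameters plus a uniform shell, with independent
#' multiplicative Gaussian measurement noise on the AFM and DLS sides
#' (relative SDs `afm_noise` and `dls_noise`).
#'
#' @param nominal_nm vector of core diameters (nm).
#' @param shell_thickness_nm true shell thickness L (nm).
#' @param afm_noise,dls_noise relative measurement noise SDs (e.g. 0.028 and
#'   0.016).
#' @param seed integer seed (mandatory).
#' @param sigma_log_afm per-row distribution widths carried into screening
#'   (default 0.05, gold-like narrow).
#' @return a `series_pair`.
#' @export
simulate_series_pair <- function(nominal_nm, shell_thickness_nm,
                                 afm_noise = 0.028, dls_noise = 0.016,
                                 seed, sigma_log_afm = 0.05) {
  if (missing(seed) || is.null(seed)) {
    stop("seed is mandatory for stochastic generation", call. = FALSE)
  }
  n <- length(nominal_nm)
  withr::with_seed(seed, {
    d_afm <- nominal_nm * (1 + stats::rnorm(n, 0, afm_noise))
    d_dls <- (nominal_nm + 2 * shell_thickness_nm) * (1 + stats::rnorm(n, 0, dls_noise))
  })
  build_series_pair(
    data.frame(label = sprintf("%g nm", nominal_nm), d_afm_nm = d_afm,
               sigma_log_afm = rep(sigma_log_afm, length.out = n)),
    data.frame(label = sprintf("%g nm", nominal_nm), d_dls_nm = d_dls)
  )
}

#' Polydispersity gap between DLS and AFM size reporters
#'
#' The z-average (harmonic intensity-weighted mean) and the AFM modal
#' diameter respond differently to distribution width: for a log-normal
#' population with median m and log-sd sigma the gap
#' `z_average - mode = m * (exp(5.5 sigma^2) - exp(-sigma^2))` is zero only
#' at sigma = 0 and grows strictly with sigma. This is the mechanism that
#' bends the DLS/AFM correlation away from the 1:1 line for broad polyplex
#' distributions.
#'
#' @param pop a `particle_population` (or numeric diameters, nm).
#' @param shape_factor multiplicative AFM shape correction applied to the
#'   modal diameter (default 1, appropriate for spheres).
#' @return gap (nm): `z_average_closed_form(pop) - shape_factor * mode`.
#' @export
polydispersity_gap <- function(pop, shape_factor = 1) {
  d <- if (inherits(pop, "particle_population")) pop$diameters else as.numeric(pop)
  if (length(d) == 0L) stop("population is empty", call. = FALSE)
  mu <- mean(log(d))
  sigma <- sqrt(mean((log(d) - mu)^2))
  mode_nm <- exp(mu - sigma^2)
  z_average_closed_form(d) - shape_factor * mode_nm
}

#' Root-sum-of-squares uncertainty budget
#'
#' Combines independent relative uncertainty components as
#' `u_c = sqrt(sum(u_i^2))` and expands with the coverage factor:
#' `U = k * u_c`; k = 2 corresponds to the 95% confidence interval.
#'
#' @param components named numeric vector (or list of `name = u_pct`) of
#'   standard-uncertainty components, each >= 0 (percent).
#' @param k coverage factor (default 2).
#' @return an `uncertainty_budget`: list with `components`, `combined_pct`,
#'   `coverage_k`, `expanded_pct`, `confidence_label`.
#' @export
combine_uncertainty <- function(components, k = 2) {
  u <- unlist(components)
  if (length(u) == 0L) stop("at least one uncertainty component required",
                            call. = FALSE)
  if (any(u < 0)) stop("uncertainty components must be non-negative", call. = FALSE)
  uc <- sqrt(sum(u^2))
  structure(list(components = u, combined_pct = uc, coverage_k = k,
                 expanded_pct = k * uc,
                 confidence_label = if (k == 2) "95% confidence interval"
                 else sprintf("k = %g", k)),
            class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat(sprintf("<uncertainty_budget> u_c = %.3g%%, U = %.3g%% (k = %g, %s)\n",
              x$combined_pct, x$expanded_pct, x$coverage_k, x$confidence_label))
  invisible(x)
}
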