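#' DLS instrument configuration
#'
#' Optical and sample parameters entering the scattering vector and the
#' Stokes-Einstein relation. Defaults match a backscatter instrument at
#' 25 degrees C in water: 173 degrees, 633 nm, n = 1.33, viscosity
#' 0.00089 Pa s, coherence factor beta = 0.9.
#'
#' @param temperature_K absolute temperature (K).
#' @param viscosity_Pa_s solvent viscosity (Pa s).
#' @param wavelength_nm laser vacuum wavelength (nm).
#' @param scattering_angle_deg scattering angle, in (0, 180).
#' @param refractive_index solvent refractive index.
#' @param beta intercept (coherence) factor, in (0, 1].
#' @return a `dls_config`.
#' @export
dls_config <- function(temperature_K = 298.15, viscosity_Pa_s = 0.00089,
                       wavelength_nm = 633, scattering_angle_deg = 173,
                       refractive_index = 1.33, beta = 0.9) {
  stopifnot(temperature_K > 0, viscosity_Pa_s > 0, wavelength_nm > 0,
            scattering_angle_deg > 0, scattering_angle_deg < 180,
            refractive_index > 0, beta > 0, beta <= 1)
  structure(list(temperature_K = temperature_K, viscosity_Pa_s = viscosity_Pa_s,
                 wavelength_nm = wavelength_nm,
                 scattering_angle_deg = scattering_angle_deg,
                 refractive_index = refractive_index, beta = beta),
            class = "dls_config")
}

BOLTZMANN_J_PER_K <- 1.380649e-23

#' Scattering vector magnitude
#'
#' `q = 4 pi n sin(theta/2) / lambda`, in 1/nm.
#'
#' @param config a [dls_config()].
#' @return q (1/nm).
#' @export
scattering_vector <- function(config) {
  stopifnot(inherits(config, "dls_config"))
  theta <- config$scattering_angle_deg * pi / 180
  4 * pi * config$refractive_index * sin(theta / 2) / config$wavelength_nm
}

#' Stokes-Einstein conversions between diameter and diffusion coefficient
#'
#' `D_t = k_B T / (3 pi eta d)`; `stokes_einstein_diameter` inverts it.
#' Diameters are in nm, diffusion coefficients in m2/s.
#'
#' @param d_nm hydrodynamic diameter(s), nm.
#' @param D_t translational diffusion coefficient(s), m2/s.
#' @param config a [dls_config()].
#' @return the converted quantity; the two functions are exact inverses.
#' @export
diffusion_coefficient <- function(d_nm, config) {
  stopifnot(inherits(config, "dls_config"))
  if (any(d_nm <= 0)) stop("diameter must be positive", call. = FALSE)
  BOLTZMANN_J_PER_K * config$temperature_K /
    (3 * pi * config$viscosity_Pa_s * d_nm * 1e-9)
}

#' @rdname diffusion_coefficient
#' @export
stokes_einstein_diameter <- function(D_t, config) {
  stopifnot(inherits(config, "dls_config"))
  if (any(D_t <= 0)) stop("diffusion coefficient must be positive", call. = FALSE)
  BOLTZMANN_J_PER_K * config$temperature_K /
    (3 * pi * config$viscosity_Pa_s * D_t) * 1e9
}

#' Rayleigh intensity weights
#'
#' Scattered-intensity weight of each particle in the Rayleigh approximation,
#' `w_i` proportional to `d_i^6`, normalized to sum 1. The approximation
#' degrades above roughly lambda/10 (the 200-250 nm members of the gold
#' series); a user-supplied weight vector may be substituted wherever weights
#' are accepted.
#'
#' @param diameters particle diameters (nm), > 0.
#' @return normalized weights summing to 1.
#' @export
intensity_weights <- function(diameters) {
  if (any(diameters <= 0)) stop("diameters must be positive", call. = FALSE)
  w <- (diameters / max(diameters))^6  # scale first: d^6 overflows for large d
  w / sum(w)
}

#' Simulate an intensity autocorrelation function
#'
#' Forward model for a DLS measurement of a number-weighted population:
#' `g1(tau) = sum_i w_i exp(-q^2 D_i tau)` with Rayleigh weights, and
#' `g2 = 1 + beta g1^2` plus additive Gaussian noise.
#'
#' @param pop a `particle_population` (or bare numeric diameters, nm).
#' @param config a [dls_config()].
#' @param taus lag times (s), strictly increasing. Default: 200 log-spaced
#'   lags from 1e-7 to 1 s.
#' @param noise_sd additive noise SD on g2 (0 = noise-free).
#' @param seed integer seed; mandatory when `noise_sd > 0`.
#' @return a `correlogram`: list with `taus_s`, `g2`, `config`.
#' @export
simulate_g2 <- function(pop, config = dls_config(),
                        taus = exp(seq(log(1e-7), log(1), length.out = 200)),
                        noise_sd = 0, seed = NULL) {
  d <- if (inherits(pop, "particle_population")) pop$diameters else as.numeric(pop)
  if (any(diff(taus) <= 0)) stop("taus must be strictly increasing", call. = FALSE)
  if (noise_sd > 0 && is.null(seed)) {
    stop("seed is mandatory when noise_sd > 0", call. = FALSE)
  }
  q_m <- scattering_vector(config) * 1e9           # 1/nm -> 1/m
  Dt <- diffusion_coefficient(d, config)           # m2/s
  w <- intensity_weights(d)
  g1 <- as.numeric(crossprod(w, exp(-q_m^2 * outer(Dt, taus))))
  g2 <- 1 + config$beta * g1^2
  if (noise_sd > 0) {
    g2 <- g2 + withr::with_seed(seed, stats::rnorm(length(g2), 0, noise_sd))
  }
  structure(list(taus_s = taus, g2 = g2, config = config), class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("<correlogram> %d lags, tau in [%.3g, %.3g] s, intercept %.3f\n",
              length(x$taus_s), min(x$taus_s), max(x$taus_s), x$g2[1] - 1))
  invisible(x)
}

#' Cumulant analysis of a correlogram
#'
#' Quadratic cumulant fit of the field correlation decay:
#' `ln(g1) = 0.5 ln((g2-1)/beta) = -Gamma_bar tau + (mu2/2) tau^2`, fitted by
#' least squares over lags where `g2 - 1` stays above `fit_fraction` of its
#' initial value. The z-average diameter is the Stokes-Einstein diameter at
#' `D_t = Gamma_bar / q^2` and the polydispersity index is
#' `PDI = mu2 / Gamma_bar^2`.
#'
#' @param corr a `correlogram`.
#' @param fit_fraction fit down to this fraction of the initial `g2 - 1`
#'   (default 0.1, a common instrument default).
#' @return a `cumulant_result`: list with `z_average_nm`, `pdi`,
#'   `gamma_bar_per_s`, `mu2_per_s2`, `n_fitted`.
#' @export
cumulant_analysis <- function(corr, fit_fraction = 0.1) {
  stopifnot(inherits(corr, "correlogram"), fit_fraction > 0, fit_fraction < 1)
  y0 <- corr$g2[1] - 1
  if (!is.finite(y0) || y0 <= 0) stop("no decay signal: g2(0) - 1 <= 0", call. = FALSE)
  keep <- (corr$g2 - 1) >= fit_fraction * y0
  # negative g2-1 inside the window (noise): truncate at first offender
  neg <- which(corr$g2 - 1 <= 0)
  if (length(neg) > 0L && any(keep[neg])) {
    keep[neg[1L]:length(keep)] <- FALSE
    warning("negative g2 - 1 inside fit range; range truncated")
  }
  if (sum(keep) < 3L) stop("fewer than 3 usable lags in fit range", call. = FALSE)
  tau <- corr$taus_s[keep]
  y <- 0.5 * log((corr$g2[keep] - 1) / corr$config$beta)
  fit <- stats::lm(y ~ tau + I(tau^2))
  gamma_bar <- -stats::coef(fit)[["tau"]]
  mu2 <- 2 * stats::coef(fit)[["I(tau^2)"]]
  if (gamma_bar <= 0) stop("fitted mean decay rate is non-positive", call. = FALSE)
  q_m <- scattering_vector(corr$config) * 1e9
  dz <- stokes_einstein_diameter(gamma_bar / q_m^2, corr$config)
  structure(list(z_average_nm = dz, pdi = max(mu2 / gamma_bar^2, 0),
                 gamma_bar_per_s = gamma_bar, mu2_per_s2 = mu2,
                 n_fitted = sum(keep)),
            class = "cumulant_result")
}

#' @export
print.cumulant_result <- function(x, ...) {
  cat(sprintf("<cumulant_result> z-average %.2f nm, PDI %.4f (%d lags)\n",
              x$z_average_nm, x$pdi, x$n_fitted))
  invisible(x)
}

#' Regularized non-negative least-squares size distribution
#'
#' Inverts a correlogram into an intensity-weighted distribution on a fixed
#' diameter grid: finds non-negative amplitudes x minimizing
#' `||A x - g1_obs||^2 + lambda ||L2 x||^2` where `A[i,j] = exp(-q^2 D(d_j)
#' tau_i)`, `g1_obs = sqrt(max(g2-1, 0)/beta)` and L2 is the second-difference
#' operator. Solved via non-negative least squares on the Tikhonov-augmented
#' design. The default is plain non-negative least squares (lambda = 0),
#' which resolves sharp modes exactly on noise-free data; if the solver
#' fails, lambda is raised along the documented ladder (1e-4, 1e-3, 1e-2,
#' 1e-1) with a warning, trading resolution for stability.
#'
#' @param corr a `correlogram`.
#' @param diameter_grid positive, strictly increasing diameters (nm);
#'   default 64 log-spaced points from 1 to 1000 nm.
#' @param regularization smoothing weight lambda (default 0).
#' @return data.frame with `diameter_nm` and `intensity_fraction`
#'   (amplitudes normalized to sum 1).
#' @export
nnls_size_distribution <- function(corr,
                                   diameter_grid = exp(seq(log(1), log(1000),
                                                           length.out = 64)),
                                   regularization = 0) {
  stopifnot(inherits(corr, "correlogram"))
  if (any(diameter_grid <= 0) || any(diff(diameter_grid) <= 0)) {
    stop("diameter grid must be positive and strictly increasing", call. = FALSE)
  }
  g1_obs <- sqrt(pmax(corr$g2 - 1, 0) / corr$config$beta)
  if (max(g1_obs) <= 0) stop("all-zero signal: no decay to fit", call. = FALSE)
  q_m <- scattering_vector(corr$config) * 1e9
  Dt <- diffusion_coefficient(diameter_grid, corr$config)
  A <- exp(-outer(corr$taus_s, q_m^2 * Dt))
  m <- length(diameter_grid)
  L2 <- matrix(0, m - 2, m)
  for (j in seq_len(m - 2)) L2[j, j:(j + 2)] <- c(1, -2, 1)
  ladder <- sort(unique(c(regularization, 1e-4, 1e-3, 1e-2, 1e-1)))
  ladder <- ladder[ladder >= regularization]
  x <- NULL
  for (lam in ladder) {
    Aaug <- rbind(A, sqrt(lam) * L2)
    baug <- c(g1_obs, rep(0, m - 2))
    sol <- tryCatch(pracma::lsqnonneg(Aaug, baug), error = function(e) NULL)
    if (!is.null(sol)) { x <- sol$x; break }
    warning(sprintf("NNLS failed at lambda = %g; raising regularization", lam))
  }
  if (is.null(x)) stop("NNLS failed at every regularization level", call. = FALSE)
  s <- sum(x)
  if (s <= 0) stop("NNLS returned an all-zero distribution", call. = FALSE)
  data.frame(diameter_nm = diameter_grid, intensity_fraction = x / s)
}

#' Closed-form z-average of a population
#'
#' Exact harmonic intensity-weighted mean diameter,
#' `d_z = sum(w_i) / sum(w_i / d_i)` with Rayleigh weights `w_i ~ d_i^6`.
#' Serves as the independent oracle for [cumulant_analysis()].
#'
#' @param pop a `particle_population` or numeric diameters (nm).
#' @return z-average diameter (nm).
#' @export
z_average_closed_form <- function(pop) {
  d <- if (inherits(pop, "particle_population")) pop$diameters else as.numeric(pop)
  if (length(d) == 0L) stop("population is empty", call. = FALSE)
  w <- intensity_weights(d)
  sum(w) / sum(w / d)
}
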