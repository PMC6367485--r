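#' AFM topograph container
#'
#' A height map in nm on a square-pixel grid. Pixel coordinates are 0-based
#' and row-major; physical coordinates are `index * pixel_nm` at pixel
#' centers.
#'
#' @param heights numeric matrix of heights (nm).
#' @param pixel_nm grid spacing (nm), > 0.
#' @param ground_truth optional data.frame of rendered-particle truth.
#' @return an `afm_topograph`.
#' @export
afm_topograph <- function(heights, pixel_nm, ground_truth = NULL) {
  stopifnot(is.matrix(heights), is.numeric(heights), pixel_nm > 0)
  structure(list(heights = heights, pixel_nm = pixel_nm,
                 ground_truth = ground_truth),
            class = "afm_topograph")
}

#' @export
print.afm_topograph <- function(x, ...) {
  cat(sprintf("<afm_topograph> %d x %d px at %g nm/px (%g x %g nm)\n",
              nrow(x$heights), ncol(x$heights), x$pixel_nm,
              nrow(x$heights) * x$pixel_nm, ncol(x$heights) * x$pixel_nm))
  invisible(x)
}

# Upper surface of an oblate spheroid resting on the z = 0 plane.
# height h, lateral full width w = aspect * h; maximum height equals h and
# the half-maximum contour sits exactly at lateral extent w.
render_spheroid <- function(heights, pixel_nm, cx_nm, cy_nm, h_nm, w_nm) {
  nr <- nrow(heights); nc <- ncol(heights)
  a <- w_nm / 2                       # lateral semi-axis
  i0 <- max(0L, floor((cx_nm - a) / pixel_nm)); i1 <- min(nr - 1L, ceiling((cx_nm + a) / pixel_nm))
  j0 <- max(0L, floor((cy_nm - a) / pixel_nm)); j1 <- min(nc - 1L, ceiling((cy_nm + a) / pixel_nm))
  if (i0 > i1 || j0 > j1) return(heights)
  xi <- (i0:i1) * pixel_nm - cx_nm
  yj <- (j0:j1) * pixel_nm - cy_nm
  r2 <- outer(xi^2, yj^2, `+`) / a^2
  z <- matrix(0, length(xi), length(yj))
  inside <- r2 <= 1
  z[inside] <- h_nm / 2 * (1 + sqrt(1 - r2[inside]))
  blk <- heights[(i0:i1) + 1L, (j0:j1) + 1L, drop = FALSE]
  heights[(i0:i1) + 1L, (j0:j1) + 1L] <- pmax(blk, z)
  heights
}

#' Generate a synthetic AFM topograph of a particle population
#'
#' Renders every particle of `pop` as an (optionally oblate) spheroid
#' resting on the substrate plane — maximum pixel height equals the particle
#' height — placed by rejection sampling so that footprints never overlap,
#' on a tilted background plane with additive Gaussian pixel noise. Particles
#' are rigid (attachment-induced deformation is represented only through
#' `shape_aspect`, the lateral-width-to-height ratio); no tip convolution is
#' modeled.
#'
#' @param pop a `particle_population` of equivalent-sphere diameters (nm);
#'   each rendered particle has height `d / shape_aspect^(2/3)` and width
#'   `aspect * height` so its volume-equivalent sphere diameter is `d`.
#' @param pixel_nm pixel size (nm), > 0.
#' @param field_nm image side length (nm).
#' @param tilt_nm_per_px background plane slope; applied as `tilt * row +
#'   tilt/2 * col` (nm per pixel index).
#' @param noise_sd_nm additive Gaussian noise SD per pixel (nm).
#' @param shape_aspect width/height ratio of rendered spheroids (1 = sphere).
#' @param seed integer seed (mandatory).
#' @param max_tries rejection-sampling attempts per particle before the
#'   field is declared too small.
#' @return an `afm_topograph`; `$ground_truth` holds one row per particle
#'   (`center_x_nm`, `center_y_nm`, `height_nm`, `width_x_nm`, `width_y_nm`).
#' @export
gen_afm_topograph <- function(pop, pixel_nm, field_nm, tilt_nm_per_px = 0,
                              noise_sd_nm = 0, shape_aspect = 1, seed,
                              max_tries = 2000L) {
  d <- if (inherits(pop, "particle_population")) pop$diameters else as.numeric(pop)
  stopifnot(pixel_nm > 0, field_nm > 0, shape_aspect >= 1, all(d > 0))
  if (missing(seed) || is.null(seed)) {
    stop("seed is mandatory for stochastic generation", call. = FALSE)
  }
  npix <- as.integer(round(field_nm / pixel_nm))
  h <- d / shape_aspect^(2/3)           # so (h * w^2)^(1/3) == d
  w <- shape_aspect * h
  margin <- 2 * pixel_nm
  if (any(w + 2 * margin > field_nm)) {
    stop("field too small for the largest particle", call. = FALSE)
  }
  withr::with_seed(seed, {
    cx <- cy <- numeric(length(d))
    for (k in seq_along(d)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        x <- stats::runif(1, w[k] / 2 + margin, field_nm - w[k] / 2 - margin)
        y <- stats::runif(1, w[k] / 2 + margin, field_nm - w[k] / 2 - margin)
        if (k == 1L) { ok <- TRUE } else {
          prev <- seq_len(k - 1L)
          ok <- all(sqrt((cx[prev] - x)^2 + (cy[prev] - y)^2) >
                      (w[prev] + w[k]) / 2 + margin)
        }
        if (ok) { cx[k] <- x; cy[k] <- y; placed <- TRUE; break }
      }
      if (!placed) {
        stop("field too small: could not place all particles without overlap",
             call. = FALSE)
      }
    }
    heights <- matrix(0, npix, npix)
    for (k in seq_along(d)) {
      heights <- render_spheroid(heights, pixel_nm, cx[k], cy[k], h[k], w[k])
    }
    heights <- heights +
      tilt_nm_per_px * (row(heights) - 1) + tilt_nm_per_px / 2 * (col(heights) - 1)
    if (noise_sd_nm > 0) {
      heights <- heights + matrix(stats::rnorm(npix * npix, 0, noise_sd_nm), npix, npix)
    }
    afm_topograph(heights, pixel_nm,
                  ground_truth = data.frame(center_x_nm = cx, center_y_nm = cy,
                                            height_nm = h, width_x_nm = w,
                                            width_y_nm = w))
  })
}
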