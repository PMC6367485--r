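#' First-order image flattening
#'
#' Fits a plane `z = b0 + b1 * row + b2 * col` by least squares over all
#' pixels outside `exclusion_mask` (the particles, which must not bias the
#' background) and subtracts it from the whole image — a global first-order
#' background. The operation is a projection: flattening a flattened image
#' changes nothing, and background pixels have zero mean afterwards.
#'
#' @param topo an `afm_topograph`.
#' @param exclusion_mask logical matrix, `TRUE` on pixels excluded from the
#'   background fit (particles). `NULL` = use every pixel.
#' @return the flattened `afm_topograph`.
#' @export
flatten_first_order <- function(topo, exclusion_mask = NULL) {
  stopifnot(inherits(topo, "afm_topograph"))
  z <- topo$heights
  if (is.null(exclusion_mask)) exclusion_mask <- matrix(FALSE, nrow(z), ncol(z))
  stopifnot(is.logical(exclusion_mask), all(dim(exclusion_mask) == dim(z)))
  bg <- !exclusion_mask
  if (sum(bg) < 3L) stop("all (or nearly all) pixels masked: no background left",
                         call. = FALSE)
  ri <- row(z)[bg]; ci <- col(z)[bg]
  if (length(unique(ri)) == 1L && length(unique(ci)) == 1L) {
    stop("background pixels are collinear; cannot fit a plane", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, ri, ci), z[bg])
  b <- fit$coefficients
  b[is.na(b)] <- 0
  plane <- b[1] + b[2] * row(z) + b[3] * col(z)
  afm_topograph(z - plane, topo$pixel_nm, ground_truth = topo$ground_truth)
}

#' Detect particles in a flattened topograph
#'
#' Thresholds the height map at `min_height_nm`, labels connected components
#' (8-connectivity, via EBImage), and keeps regions of at least
#' `min_area_px` pixels. Detection is an automated surrogate for manual
#' particle identification; exclusion decisions (border contact, fused
#' particles) are made later, per region, in [measure_particle()].
#'
#' @param topo a flattened `afm_topograph`.
#' @param min_height_nm detection threshold (nm); choose well above the
#'   noise floor, e.g. 5 x noise SD.
#' @param min_area_px minimum region area in pixels.
#' @return list of regions; each has `pixels` (2-column index matrix),
#'   `area_px`, `centroid_px`, `peak_px`, `label`.
#' @export
detect_particles <- function(topo, min_height_nm, min_area_px = 4L) {
  stopifnot(inherits(topo, "afm_topograph"), min_height_nm > 0)
  bw <- topo$heights > min_height_nm
  if (!any(bw)) return(list())
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  labm <- EBImage::imageData(lab)
  idx <- which(labm > 0, arr.ind = TRUE)
  labs <- labm[labm > 0]
  split_idx <- split(seq_len(nrow(idx)), labs)
  regions <- lapply(split_idx, function(ii) {
    px <- idx[ii, , drop = FALSE]
    hts <- topo$heights[px]
    pk <- px[which.max(hts), ]
    list(pixels = px, area_px = nrow(px),
         centroid_px = colMeans(px), peak_px = pk)
  })
  keep <- vapply(regions, function(r) r$area_px >= min_area_px, logical(1))
  regions <- regions[keep]
  for (i in seq_along(regions)) regions[[i]]$label <- i
  unname(regions)
}

# moment eccentricity of a pixel region: sqrt(1 - lambda2/lambda1)
region_eccentricity <- function(pixels) {
  if (nrow(pixels) < 3L) return(0)
  cv <- stats::cov(pixels)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(0)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

# full width at fraction `frac` of peak height along one axis through the
# peak pixel: contiguous run of pixels >= frac * h containing the peak
run_width_px <- function(profile, peak_at, level) {
  above <- profile >= level
  if (!above[peak_at]) return(1L)
  lo <- peak_at
  while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- peak_at
  while (hi < length(profile) && above[hi + 1L]) hi <- hi + 1L
  hi - lo + 1L
}

#' Measure one detected particle
#'
#' Height is the maximum flattened height in the region (local background is
#' zero after flattening); the two perpendicular widths are the full extents
#' at half-maximum height along the image row and column through the peak.
#' Regions touching the image border, or with moment eccentricity above
#' `max_eccentricity` (fused particles), are excluded with a reason instead
#' of being measured.
#'
#' @param topo the flattened `afm_topograph`.
#' @param region one element of [detect_particles()] output.
#' @param max_eccentricity fused-particle cutoff on the region's moment
#'   eccentricity (default 0.85; rendered single spheres stay below ~0.5,
#'   while a fused pair of equal spheres reaches ~0.89).
#' @return one-row data.frame: `height_nm`, `width1_nm`, `width2_nm`,
#'   `d_eq_nm`, `aspect`, `excluded`, `reason`.
#' @export
measure_particle <- function(topo, region, max_eccentricity = 0.85) {
  stopifnot(inherits(topo, "afm_topograph"))
  z <- topo$heights
  px <- region$pixels
  excluded_row <- function(reason) {
    data.frame(height_nm = NA_real_, width1_nm = NA_real_, width2_nm = NA_real_,
               d_eq_nm = NA_real_, aspect = NA_real_, excluded = TRUE,
               reason = reason)
  }
  if (any(px[, 1] == 1L) || any(px[, 1] == nrow(z)) ||
      any(px[, 2] == 1L) || any(px[, 2] == ncol(z))) {
    return(excluded_row("border"))
  }
  if (region_eccentricity(px) > max_eccentricity) {
    return(excluded_row("fused"))
  }
  pk <- region$peak_px
  h <- z[pk[1], pk[2]]
  if (h <= 0) return(excluded_row("nonpositive height"))
  w1 <- run_width_px(z[, pk[2]], pk[1], h / 2) * topo$pixel_nm
  w2 <- run_width_px(z[pk[1], ], pk[2], h / 2) * topo$pixel_nm
  d_eq <- equivalent_sphere_diameter(h, w1, w2)
  data.frame(height_nm = h, width1_nm = w1, width2_nm = w2, d_eq_nm = d_eq,
             aspect = max(w1, w2) / h, excluded = FALSE, reason = "")
}

#' Measure every particle in a topograph
#'
#' Convenience chain: threshold-free two-pass flattening (first pass with no
#' mask, detected regions become the exclusion mask for the second pass),
#' detection, and per-particle measurement.
#'
#' @inheritParams detect_particles
#' @inheritParams measure_particle
#' @return data.frame of per-particle measurements (one row per region,
#'   excluded rows flagged).
#' @export
measure_topograph <- function(topo, min_height_nm, min_area_px = 4L,
                              max_eccentricity = 0.85) {
  flat1 <- flatten_first_order(topo)
  regions1 <- detect_particles(flat1, min_height_nm, min_area_px)
  mask <- matrix(FALSE, nrow(topo$heights), ncol(topo$heights))
  for (r in regions1) mask[r$pixels] <- TRUE
  mask <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(mask * 1), EBImage::makeBrush(5, "disc"))) > 0
  flat <- flatten_first_order(topo, exclusion_mask = mask)
  regions <- detect_particles(flat, min_height_nm, min_area_px)
  if (length(regions) == 0L) {
    return(data.frame(height_nm = numeric(), width1_nm = numeric(),
                      width2_nm = numeric(), d_eq_nm = numeric(),
                      aspect = numeric(), excluded = logical(),
                      reason = character()))
  }
  do.call(rbind, lapply(regions, function(r)
    measure_particle(flat, r, max_eccentricity)))
}

#' Equivalent-sphere diameter of a measured particle
#'
#' Volume-preserving oblate-spheroid convention:
#' `d_eq = (h * w1 * w2)^(1/3)`. For a particle measured by height only, the
#' empirical shape correction factor f (1.2 for oligo-DNA-based and 1.7 for
#' siRNA-based polyplexes) gives `d_eq = f * h`.
#'
#' @param h peak height (nm), > 0.
#' @param w1,w2 perpendicular widths at half maximum (nm), > 0.
#' @return equivalent-sphere diameter (nm).
#' @export
equivalent_sphere_diameter <- function(h, w1, w2) {
  if (any(c(h, w1, w2) <= 0)) stop("h, w1, w2 must be positive", call. = FALSE)
  (h * w1 * w2)^(1/3)
}

#' Shape correction factor from a measured subset
#'
#' `f = median(d_eq / h)` over particles with width measurements, reported
#' with the median absolute deviation. Applied multiplicatively to
#' height-only populations: corrected diameter = f * h. Spherical particles
#' give exactly f = 1; f is invariant under uniform scaling of all
#' dimensions.
#'
#' @param measurements data.frame with `height_nm` and `d_eq_nm` columns
#'   (excluded rows are dropped).
#' @param min_n minimum usable measurements (default 10).
#' @return list with `f`, `mad`, `n`.
#' @export
shape_correction_factor <- function(measurements, min_n = 10L) {
  m <- measurements[!measurements$excluded & is.finite(measurements$d_eq_nm), ,
                    drop = FALSE]
  if (nrow(m) < min_n) {
    stop(sprintf("need at least %d measurements with widths, got %d",
                 min_n, nrow(m)), call. = FALSE)
  }
  ratio <- m$d_eq_nm / m$height_nm
  list(f = stats::median(ratio), mad = stats::mad(ratio), n = nrow(m))
}

#' Maximum-likelihood log-normal fit to a diameter sample
#'
#' MLE on log-diameters: `median = exp(mean(log d))`,
#' `sigma_log = sd(log d)` (ML variant, denominator n), and the derived mode
#' `mode = median * exp(-sigma_log^2)`. Goodness is the sum of squared
#' residuals between observed and fitted bin counts on a Sturges histogram.
#'
#' @param diameters positive diameters (nm), n >= 20.
#' @return a `lognormal_fit`: list with `median_nm`, `sigma_log`, `mode_nm`,
#'   `n`, `goodness`.
#' @export
fit_lognormal <- function(diameters) {
  d <- as.numeric(diameters)
  d <- d[is.finite(d)]
  if (length(d) < 20L) stop("need at least 20 diameters", call. = FALSE)
  if (any(d <= 0)) stop("diameters must be positive", call. = FALSE)
  lg <- log(d)
  mu <- mean(lg)
  sigma <- sqrt(mean((lg - mu)^2))
  median_nm <- exp(mu)
  hist <- graphics::hist(d, breaks = "Sturges", plot = FALSE)
  expected <- length(d) * diff(stats::plnorm(hist$breaks, mu, max(sigma, 1e-12)))
  structure(list(median_nm = median_nm, sigma_log = sigma,
                 mode_nm = median_nm * exp(-sigma^2), n = length(d),
                 goodness = sum((hist$counts - expected)^2)),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("<lognormal_fit> median %.2f nm, sigma_log %.4f, mode %.2f nm (n = %d)\n",
              x$median_nm, x$sigma_log, x$mode_nm, x$n))
  invisible(x)
}
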