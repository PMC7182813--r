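#' Specification for a synthetic adherent-cell micrograph
#'
#' Collects the parameters of the micrograph generator. Cells are rendered
#' as filled disks with normally distributed radii on a uniform background;
#' realism extras are an optional linear illumination gradient and additive
#' Gaussian read noise. The per-image target coverage is jittered around
#' `true_coverage` (`coverage_sd`, truncated normal) to emulate the
#' replicate-to-replicate spread real assay images show; set
#' `coverage_sd = 0` for exactly reproducible targets.
#'
#' @param width,height Image size in pixels (>= 64).
#' @param true_coverage Nominal covered-area fraction in (0, 1).
#' @param coverage_sd Between-image sd of the target coverage (>= 0).
#' @param cell_radius_mean,cell_radius_sd Cell radius distribution, px
#'   (radii are clipped to >= 2 px).
#' @param cell_intensity,background_intensity Grayscale levels (8-bit
#'   scale, 0-255); cells darker than background by default.
#' @param noise_sd Additive Gaussian noise sd, grayscale units.
#' @param illumination_gradient Fractional intensity change across the
#'   field (0 = flat).
#' @param overlap_policy `"allow"` (cells may overlap, the default --
#'   settled yeast clusters) or `"forbid"`.
#' @param seed Integer seed.
#' @return A `micrograph_spec`.
#' @export
micrograph_spec <- function(width = 256L, height = 256L,
                            true_coverage = 0.5, coverage_sd = 0.04,
                            cell_radius_mean = 6, cell_radius_sd = 1.5,
                            cell_intensity = 60,
                            background_intensity = 200, noise_sd = 10,
                            illumination_gradient = 0,
                            overlap_policy = c("allow", "forbid"),
                            seed = 1L) {
  overlap_policy <- match.arg(overlap_policy)
  if (width < 64 || height < 64) stop("image must be at least 64 x 64")
  if (true_coverage <= 0 || true_coverage >= 1)
    stop("true_coverage must lie in (0, 1)")
  if (coverage_sd < 0) stop("coverage_sd must be >= 0")
  if (cell_intensity < 0 || cell_intensity > 255 ||
      background_intensity < 0 || background_intensity > 255)
    stop("intensities must lie within the 8-bit range [0, 255]")
  structure(list(width = as.integer(width), height = as.integer(height),
                 true_coverage = true_coverage, coverage_sd = coverage_sd,
                 cell_radius_mean = cell_radius_mean,
                 cell_radius_sd = cell_radius_sd,
                 cell_intensity = cell_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd,
                 illumination_gradient = illumination_gradient,
                 overlap_policy = overlap_policy,
                 seed = as.integer(seed)),
            class = "micrograph_spec")
}

## Rasterize one disk into a logical matrix (TRUE inside).
disk_pixels <- function(nr, nc, cx, cy, r) {
  x0 <- max(1L, floor(cx - r)); x1 <- min(nr, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(nc, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(NULL)
  xs <- x0:x1; ys <- y0:y1
  inside <- outer((xs - cx)^2, (ys - cy)^2, `+`) <= r^2
  cbind(rep(xs, times = length(ys))[inside],
        rep(ys, each = length(xs))[inside])
}

#' Generate a synthetic micrograph with known coverage
#'
#' Places disk-shaped "cells" at uniform random positions until the mask
#' first reaches the (jittered) target coverage, then renders the scene
#' with the spec's intensities, optional illumination gradient, and
#' additive Gaussian noise, clipped to \[0, 255\]. The exact foreground
#' mask is returned as ground truth; `realized_coverage` is its foreground
#' fraction, measured from the mask itself.
#'
#' @param spec A [micrograph_spec()].
#' @param image_id,condition_id Labels for the emitted [micrograph()].
#' @return List with `image` (a `micrograph`), `mask` (logical matrix),
#'   `realized_coverage`, `target_coverage`, `n_cells`, and `spec`.
#' @examples
#' g <- gen_micrograph(micrograph_spec(true_coverage = 0.3, seed = 7))
#' g$realized_coverage
#' @export
gen_micrograph <- function(spec, image_id = paste0("sim_", spec$seed),
                           condition_id = "sim") {
  if (!inherits(spec, "micrograph_spec"))
    stop("'spec' must be a micrograph_spec")
  nr <- spec$height; nc <- spec$width
  with_seed(spec$seed, {
    target <- rtruncnorm1(spec$true_coverage, spec$coverage_sd,
                          0.01, 0.95)
    mask <- matrix(FALSE, nr, nc)
    n_cells <- 0L
    max_attempts <- 200L * ceiling(target * nr * nc /
                                   (pi * max(2, spec$cell_radius_mean)^2))
    attempts <- 0L
    while (mean(mask) < target) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("could not reach coverage ", signif(target, 3), " under '",
             spec$overlap_policy, "' placement after ", max_attempts,
             " attempts")
      r <- max(2, stats::rnorm(1, spec$cell_radius_mean,
                               spec$cell_radius_sd))
      cx <- stats::runif(1, 1, nr)
      cy <- stats::runif(1, 1, nc)
      px <- disk_pixels(nr, nc, cx, cy, r)
      if (is.null(px)) next
      if (spec$overlap_policy == "forbid" && any(mask[px])) next
      mask[px] <- TRUE
      n_cells <- n_cells + 1L
    }
    img <- matrix(spec$background_intensity, nr, nc)
    img[mask] <- spec$cell_intensity
    if (spec$illumination_gradient != 0) {
      ramp <- 1 + spec$illumination_gradient *
        (seq_len(nc) - (nc + 1) / 2) / (nc - 1)
      img <- sweep(img, 2, ramp, `*`)
    }
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    img <- pmin(pmax(img, 0), 255)
    list(image = micrograph(img, image_id, condition_id),
         mask = mask,
         realized_coverage = mean(mask),
         target_coverage = target,
         n_cells = n_cells,
         spec = spec)
  })
}

#' Generate a replicate set of micrographs for one condition
#'
#' Calls [gen_micrograph()] `n_images` times with seeds derived from
#' `spec$seed` (seed + image index), one condition label throughout.
#'
#' @param spec A [micrograph_spec()]; its `seed` anchors the set.
#' @param n_images Number of replicate images.
#' @param condition_id Condition label.
#' @return List of [gen_micrograph()] results.
#' @export
gen_micrograph_set <- function(spec, n_images = 10L, condition_id = "sim") {
  lapply(seq_len(n_images), function(i) {
    s <- spec
    s$seed <- spec$seed + i
    gen_micrograph(s, image_id = sprintf("%s_img%02d", condition_id, i),
                   condition_id = condition_id)
  })
}

#' Forward-model a noisy contact-angle set from known components
#'
#' Computes the exact contact angle of each liquid on a surface with the
#' given components ([forward_contact_angle()]), then simulates
#' `n_readings` sessile-drop readings per liquid as the true angle plus
#' Gaussian noise truncated to \[0, 180\], and summarises them to
#' mean/sd [contact_angle()] objects. With `noise_sd_deg = 0` the exact
#' forward angles are returned.
#'
#' @param components A `surface_energy` (signed roots honoured).
#' @param liquids List of `test_liquid` objects (default
#'   [probe_liquids()]).
#' @param noise_sd_deg Reading noise sd, degrees.
#' @param n_readings Readings per liquid.
#' @param seed Integer seed.
#' @return List of `contact_angle` objects, one per liquid, with attribute
#'   `true_angles` (the noise-free forward angles).
#' @export
gen_contact_angles <- function(components, liquids = probe_liquids(),
                               noise_sd_deg = 0, n_readings = 10L,
                               seed = 1L) {
  true <- vapply(liquids, function(L)
    tryCatch(forward_contact_angle(components, L),
             error = function(e) stop("liquid '", L$name, "': ",
                                      conditionMessage(e))), numeric(1))
  out <- with_seed(seed, {
    lapply(seq_along(liquids), function(i) {
      if (noise_sd_deg == 0)
        return(contact_angle(liquids[[i]], true[i], 0, n_readings))
      reads <- rtruncnorm_n(n_readings, true[i], noise_sd_deg, 0, 180)
      contact_angle(liquids[[i]], mean(reads),
                    if (n_readings > 1) stats::sd(reads) else 0,
                    n_readings)
    })
  })
  attr(out, "true_angles") <- true
  out
}

#' Generate a linear kinetic trace with known slope
#'
#' Absorbance = intercept + slope * t + Gaussian noise on evenly spaced
#' times over \[0, duration\].
#'
#' @param true_slope Absorbance/s.
#' @param intercept Absorbance at t = 0.
#' @param duration Seconds (> 0).
#' @param n_points Number of samples (>= 3).
#' @param noise_sd Absorbance noise sd.
#' @param seed Integer seed.
#' @param ... Passed to [kinetic_trace()] (volume, path length, mass,
#'   sample).
#' @return A [kinetic_trace()] with attributes `true_slope` and
#'   `true_intercept`.
#' @export
gen_kinetic_trace <- function(true_slope, intercept = 0.05, duration = 100,
                              n_points = 50L, noise_sd = 0, seed = 1L,
                              ...) {
  if (n_points < 3) stop("n_points must be >= 3")
  if (duration <= 0) stop("duration must be positive")
  times <- seq(0, duration, length.out = n_points)
  abs_ <- with_seed(seed,
    intercept + true_slope * times +
      if (noise_sd > 0) stats::rnorm(n_points, 0, noise_sd) else 0)
  tr <- kinetic_trace(times, abs_, ...)
  attr(tr, "true_slope") <- true_slope
  attr(tr, "true_intercept") <- intercept
  tr
}
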