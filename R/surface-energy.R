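deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Round half away from zero
#'
#' Display rounding used for table output: 0.05 rounds to 0.1 (R's
#' [round()] rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Lewis acid-base surface-energy component
#'
#' \eqn{\gamma^{AB} = 2\sqrt{\gamma^{+}\gamma^{-}}}: the polar (acid-base)
#' part of a surface energy from its electron-acceptor and electron-donor
#' components.
#'
#' @param gamma_plus Electron-acceptor component, mJ/m^2 (>= 0).
#' @param gamma_minus Electron-donor component, mJ/m^2 (>= 0).
#' @return Acid-base component, mJ/m^2.
#' @examples
#' acid_base_component(25.5, 25.5) # water: 51.0
#' @export
acid_base_component <- function(gamma_plus, gamma_minus) {
  if (any(!is.finite(gamma_plus)) || any(!is.finite(gamma_minus)) ||
      any(gamma_plus < 0) || any(gamma_minus < 0))
    stop("gamma_plus and gamma_minus must be finite and >= 0")
  2 * sqrt(gamma_plus * gamma_minus)
}

#' Total surface energy
#'
#' \eqn{\gamma^{tot} = \gamma^{LW} + \gamma^{AB}}: apolar plus polar parts.
#'
#' @param gamma_lw Lifshitz-van der Waals component, mJ/m^2.
#' @param gamma_ab Acid-base component, mJ/m^2.
#' @return Total surface energy, mJ/m^2.
#' @examples
#' total_energy(45.2, 44.6) # polystyrene: 89.8
#' @export
total_energy <- function(gamma_lw, gamma_ab) {
  if (any(!is.finite(gamma_lw)) || any(!is.finite(gamma_ab)))
    stop("inputs must be finite")
  gamma_lw + gamma_ab
}

#' Hydrophobicity class from the water contact angle
#'
#' Rijnaarts-style banding of surfaces by their water contact angle
#' \eqn{\theta_w}: hydrophilic below 20 degrees, intermediately hydrophobic
#' in \[20, 50), hydrophobic at 50 degrees and above. Boundaries are closed
#' on the left (20 is intermediate, 50 is hydrophobic).
#'
#' @param theta_water Water contact angle, degrees, in \[0, 180\].
#' @return One of `"hydrophilic"`, `"intermediately_hydrophobic"`,
#'   `"hydrophobic"` (vectorised).
#' @examples
#' classify_hydrophobicity(c(16.6, 35, 77.8))
#' @export
classify_hydrophobicity <- function(theta_water) {
  if (any(!is.finite(theta_water)) || any(theta_water < 0) ||
      any(theta_water > 180))
    stop("water contact angle outside [0, 180] degrees")
  ifelse(theta_water < 20, "hydrophilic",
         ifelse(theta_water < 50, "intermediately_hydrophobic",
                "hydrophobic"))
}

## Coefficient matrix and rhs of the three-liquid Young equation system,
## unknowns (x, y, z) = (sqrt(gLW_j), sqrt(g+_j), sqrt(g-_j)):
##   (1 + cos theta_i) * gamma_i = 2 (x sqrt(gLW_i) + y sqrt(g-_i) + z sqrt(g+_i))
young_system <- function(angles) {
  A <- t(vapply(angles, function(a)
    c(sqrt(a$liquid$gamma_lw), sqrt(a$liquid$gamma_minus),
      sqrt(a$liquid$gamma_plus)), numeric(3)))
  b <- vapply(angles, function(a)
    (1 + cos(deg2rad(a$theta_mean))) * a$liquid$gamma_total / 2, numeric(1))
  list(A = A, b = b)
}

#' Apolar-liquid diagnostic for a contact-angle set
#'
#' For each measured angle, reports the solid's \eqn{\gamma^{LW}} that would
#' follow if that angle had been measured with the apolar probe liquid:
#' \eqn{\gamma^{LW}_j = \gamma_M (1+\cos\theta)^2 / 4}, where
#' \eqn{\gamma_M} is the apolar liquid's surface tension. Because an apolar
#' liquid decouples the system, this identifies which angle column actually
#' determined a published \eqn{\gamma^{LW}} -- useful when a table's liquid
#' columns are suspected of being transposed.
#'
#' @param angles List of `contact_angle` objects.
#' @param apolar_liquid The apolar `test_liquid`; defaults to the apolar
#'   member of `angles` (error if none).
#' @return Data frame with columns `liquid`, `theta_deg`,
#'   `implied_gamma_lw`.
#' @export
apolar_lw_diagnostic <- function(angles, apolar_liquid = NULL) {
  if (is.null(apolar_liquid)) {
    ap <- Filter(function(a) is_apolar(a$liquid), angles)
    if (!length(ap))
      stop("no apolar liquid among the angles; supply 'apolar_liquid'")
    apolar_liquid <- ap[[1]]$liquid
  }
  th <- vapply(angles, function(a) a$theta_mean, numeric(1))
  data.frame(
    liquid = vapply(angles, function(a) a$liquid$name, character(1)),
    theta_deg = th,
    implied_gamma_lw =
      apolar_liquid$gamma_total * (1 + cos(deg2rad(th)))^2 / 4,
    stringsAsFactors = FALSE)
}

#' Solve solid surface-energy components from three-liquid contact angles
#'
#' Solves the van Oss-Chaudhury-Good three-liquid system (Young's equation
#' in acid-base form) for a solid `j` probed with liquids `i`:
#' \deqn{(1+\cos\theta_i)\,\gamma_i = 2\left(
#'   \sqrt{\gamma_j^{LW}\gamma_i^{LW}} + \sqrt{\gamma_j^{+}\gamma_i^{-}} +
#'   \sqrt{\gamma_j^{-}\gamma_i^{+}}\right)}
#' The system is linear in the square roots
#' \eqn{(x,y,z)=(\sqrt{\gamma_j^{LW}},\sqrt{\gamma_j^{+}},\sqrt{\gamma_j^{-}})}
#' and is solved directly for three liquids, or by ordinary least squares
#' when more than three are supplied. A solved root can come out negative;
#' the stored component is its square (magnitude) and the root's sign is
#' retained in `root_signs` (and flagged) so that forward modeling
#' ([forward_contact_angle()]) reproduces the measured angles exactly.
#'
#' @param angles List of >= 3 `contact_angle` objects on distinct liquids,
#'   at least two of them polar.
#' @param surface_name Label for the solid.
#' @param max_condition Condition-number cap for the coefficient matrix;
#'   beyond it the triplet is rejected as degenerate.
#' @param warn_condition Condition number above which a warning is issued.
#' @return An object of class `surface_energy`: list with `surface_name`,
#'   `gamma_lw`, `gamma_plus`, `gamma_minus`, `gamma_ab`, `gamma_total`
#'   (all magnitudes, mJ/m^2), `roots` (signed square roots),
#'   `root_signs`, `negative_root_flag` (per-component logical),
#'   `residual_rel` (per-liquid relative residuals), `condition_number`,
#'   `liquids`, `angles`, and `apolar_diagnostic` (see
#'   [apolar_lw_diagnostic()]).
#' @examples
#' liq <- probe_liquids()
#' pet <- solve_components(list(
#'   contact_angle(liq$water, 77.8),
#'   contact_angle(liq$formamide, 58.2),
#'   contact_angle(liq$methylene_iodide, 20.5)), surface_name = "PET")
#' pet
#' @export
solve_components <- function(angles, surface_name = "surface",
                             max_condition = 1e6, warn_condition = 1e3) {
  if (!is.list(angles) || length(angles) < 3)
    stop("need at least three contact-angle measurements")
  if (!all(vapply(angles, inherits, logical(1), "contact_angle")))
    stop("'angles' must be a list of contact_angle objects")
  liq_names <- vapply(angles, function(a) a$liquid$name, character(1))
  if (anyDuplicated(liq_names))
    stop("liquids must be distinct; duplicated: ",
         paste(unique(liq_names[duplicated(liq_names)]), collapse = ", "))
  n_polar <- sum(vapply(angles, function(a) is_polar(a$liquid), logical(1)))
  if (n_polar < 2)
    stop("at least two of the probe liquids must be polar; got ", n_polar)

  sys <- young_system(angles)
  kap <- kappa(sys$A, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition)
    stop("degenerate liquid set {", paste(liq_names, collapse = ", "),
         "}: condition number ", signif(kap, 4), " exceeds cap ",
         max_condition)
  if (kap > warn_condition)
    warning("ill-conditioned liquid set {",
            paste(liq_names, collapse = ", "), "}: condition number ",
            signif(kap, 4))

  roots <- if (length(angles) == 3L) as.numeric(solve(sys$A, sys$b))
           else as.numeric(qr.coef(qr(sys$A), sys$b))
  names(roots) <- c("sqrt_gamma_lw", "sqrt_gamma_plus", "sqrt_gamma_minus")
  resid <- as.numeric(sys$A %*% roots - sys$b) / sys$b

  gamma_lw <- roots[[1]]^2
  gamma_plus <- roots[[2]]^2
  gamma_minus <- roots[[3]]^2
  gamma_ab <- acid_base_component(gamma_plus, gamma_minus)
  structure(
    list(surface_name = surface_name,
         gamma_lw = gamma_lw, gamma_plus = gamma_plus,
         gamma_minus = gamma_minus, gamma_ab = gamma_ab,
         gamma_total = total_energy(gamma_lw, gamma_ab),
         roots = roots, root_signs = sign(roots),
         negative_root_flag = stats::setNames(roots < 0,
           c("gamma_lw", "gamma_plus", "gamma_minus")),
         residual_rel = stats::setNames(resid, liq_names),
         condition_number = kap,
         liquids = lapply(angles, `[[`, "liquid"),
         angles = angles,
         apolar_diagnostic = tryCatch(apolar_lw_diagnostic(angles),
                                      error = function(e) NULL)),
    class = "surface_energy")
}

#' Build surface-energy components from known magnitudes
#'
#' Constructs a `surface_energy` object directly from component magnitudes
#' (all roots taken positive), e.g. to forward-model contact angles for a
#' hypothetical surface.
#'
#' @param gamma_lw,gamma_plus,gamma_minus Component magnitudes, mJ/m^2
#'   (>= 0).
#' @param surface_name Label.
#' @return A `surface_energy` object.
#' @examples
#' surface_energy(40, 1, 30, "model surface")
#' @export
surface_energy <- function(gamma_lw, gamma_plus, gamma_minus,
                           surface_name = "surface") {
  if (any(c(gamma_lw, gamma_plus, gamma_minus) < 0))
    stop("component magnitudes must be >= 0")
  roots <- c(sqrt_gamma_lw = sqrt(gamma_lw),
             sqrt_gamma_plus = sqrt(gamma_plus),
             sqrt_gamma_minus = sqrt(gamma_minus))
  gamma_ab <- acid_base_component(gamma_plus, gamma_minus)
  structure(
    list(surface_name = surface_name, gamma_lw = gamma_lw,
         gamma_plus = gamma_plus, gamma_minus = gamma_minus,
         gamma_ab = gamma_ab,
         gamma_total = total_energy(gamma_lw, gamma_ab),
         roots = roots, root_signs = sign(roots),
         negative_root_flag = stats::setNames(roots < 0,
           c("gamma_lw", "gamma_plus", "gamma_minus")),
         residual_rel = NULL, condition_number = NA_real_,
         liquids = NULL, angles = NULL, apolar_diagnostic = NULL),
    class = "surface_energy")
}

#' @export
print.surface_energy <- function(x, ...) {
  flag <- function(i) if (x$negative_root_flag[[i]]) "*" else ""
  cat(sprintf("<surface_energy> %s (mJ/m^2)\n", x$surface_name))
  cat(sprintf("  gamma_LW  = %6.1f%s\n", round_half_up(x$gamma_lw),
              flag("gamma_lw")))
  cat(sprintf("  gamma_+   = %6.1f%s\n", round_half_up(x$gamma_plus),
              flag("gamma_plus")))
  cat(sprintf("  gamma_-   = %6.1f%s\n", round_half_up(x$gamma_minus),
              flag("gamma_minus")))
  cat(sprintf("  gamma_AB  = %6.1f\n", round_half_up(x$gamma_ab)))
  # display total = sum of displayed parts, so the printout is additive
  cat(sprintf("  gamma_tot = %6.1f\n",
              round_half_up(x$gamma_lw) + round_half_up(x$gamma_ab)))
  if (any(x$negative_root_flag))
    cat("  (* component stored as squared magnitude of a negative root)\n")
  invisible(x)
}

#' Forward-model a contact angle from surface components
#'
#' Inverts the three-liquid Young system for one liquid: given a solid's
#' components (with signed square roots retained), returns the contact
#' angle the liquid would exhibit. Composing with [solve_components()] is
#' the identity on angles when root signs are retained.
#'
#' @param components A `surface_energy` object.
#' @param liquid A `test_liquid`.
#' @return Contact angle in degrees.
#' @examples
#' liq <- probe_liquids()
#' forward_contact_angle(surface_energy(50.8, 0, 0), liq$methylene_iodide)
#' @export
forward_contact_angle <- function(components, liquid) {
  if (!inherits(components, "surface_energy"))
    stop("'components' must be a surface_energy object")
  if (!inherits(liquid, "test_liquid"))
    stop("'liquid' must be a test_liquid object")
  r <- components$roots
  cos_theta <- -1 + 2 * (r[[1]] * sqrt(liquid$gamma_lw) +
                         r[[2]] * sqrt(liquid$gamma_minus) +
                         r[[3]] * sqrt(liquid$gamma_plus)) /
                       liquid$gamma_total
  if (cos_theta < -1 - 1e-12 || cos_theta > 1 + 1e-12)
    stop("implied cos(theta) = ", signif(cos_theta, 6), " for liquid '",
         liquid$name, "' lies outside [-1, 1]; surface/liquid pair has no ",
         "physical sessile-drop angle")
  rad2deg(acos(min(1, max(-1, cos_theta))))
}

#' Monte-Carlo uncertainty propagation for the three-liquid solve
#'
#' Resamples each contact angle from an independent normal distribution
#' (mean `theta_mean`, sd `theta_sd`, truncated to \[0, 180\] degrees by
#' inverse-CDF sampling so the draw count is deterministic), re-solves the
#' system per draw, and summarises the component magnitudes.
#'
#' @param angles List of 3+ `contact_angle` objects with `theta_sd` set.
#' @param n_draws Number of Monte-Carlo draws (>= 100).
#' @param seed Integer seed; results are reproducible under a fixed seed.
#' @param ... Passed to [solve_components()].
#' @return List with `mean` and `sd` (named vectors over `gamma_lw`,
#'   `gamma_plus`, `gamma_minus`, `gamma_ab`, `gamma_total`),
#'   `root_mean` and `root_sd` (signed square roots, which respond
#'   linearly to angle noise, so their means are unbiased for the point
#'   solve's roots; squaring adds a positive bias of about the root
#'   variance to the component magnitudes), `negative_root_fraction`
#'   (per component), `failure_fraction`, and `n_draws`.
#' @export
propagate_uncertainty <- function(angles, n_draws = 1000L, seed = 1L, ...) {
  if (n_draws < 100) stop("n_draws must be >= 100")
  if (any(vapply(angles, function(a) a$theta_sd < 0, logical(1))))
    stop("theta_sd must be >= 0 for all liquids")
  comp_names <- c("gamma_lw", "gamma_plus", "gamma_minus", "gamma_ab",
                  "gamma_total")
  draws <- matrix(NA_real_, n_draws, length(comp_names),
                  dimnames = list(NULL, comp_names))
  root_draws <- matrix(NA_real_, n_draws, 3,
                       dimnames = list(NULL, c("sqrt_gamma_lw",
                                               "sqrt_gamma_plus",
                                               "sqrt_gamma_minus")))
  neg <- matrix(FALSE, n_draws, 3,
                dimnames = list(NULL, c("gamma_lw", "gamma_plus",
                                        "gamma_minus")))
  failed <- logical(n_draws)
  with_seed(seed, {
    for (k in seq_len(n_draws)) {
      pert <- lapply(angles, function(a)
        contact_angle(a$liquid,
                      rtruncnorm1(a$theta_mean, a$theta_sd, 0, 180),
                      a$theta_sd, a$n_readings))
      fit <- tryCatch(suppressWarnings(solve_components(pert, ...)),
                      error = function(e) NULL)
      if (is.null(fit)) { failed[k] <- TRUE; next }
      draws[k, ] <- c(fit$gamma_lw, fit$gamma_plus, fit$gamma_minus,
                      fit$gamma_ab, fit$gamma_total)
      root_draws[k, ] <- fit$roots
      neg[k, ] <- fit$negative_root_flag
    }
  })
  fail_frac <- mean(failed)
  if (fail_frac > 0.5)
    stop("more than half of the Monte-Carlo draws failed to solve (",
         signif(100 * fail_frac, 3), "%)")
  ok <- !failed
  list(mean = colMeans(draws[ok, , drop = FALSE]),
       sd = apply(draws[ok, , drop = FALSE], 2, stats::sd),
       root_mean = colMeans(root_draws[ok, , drop = FALSE]),
       root_sd = apply(root_draws[ok, , drop = FALSE], 2, stats::sd),
       negative_root_fraction = colMeans(neg[ok, , drop = FALSE]),
       failure_fraction = fail_frac,
       n_draws = n_draws)
}

#' Surface-energy results as a table
#'
#' Flattens one or more `surface_energy` objects into a data frame with
#' both full-precision and one-decimal display columns, plus the water
#' contact angle's hydrophobicity class when a water angle is present.
#'
#' @param fits List of `surface_energy` objects (or a single one).
#' @return Data frame, one row per surface.
#' @export
surface_energy_table <- function(fits) {
  if (inherits(fits, "surface_energy")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    theta_w <- NA_real_
    if (!is.null(f$angles)) {
      iw <- which(vapply(f$angles, function(a)
        grepl("water", a$liquid$name, ignore.case = TRUE), logical(1)))
      if (length(iw)) theta_w <- f$angles[[iw[1]]]$theta_mean
    }
    data.frame(
      surface = f$surface_name,
      gamma_lw = round_half_up(f$gamma_lw),
      gamma_plus = round_half_up(f$gamma_plus),
      gamma_minus = round_half_up(f$gamma_minus),
      gamma_ab = round_half_up(f$gamma_ab),
      # display total adds the displayed parts (keeps the table additive
      # at one-decimal precision); the exact total is in gamma_total_full
      gamma_total = round_half_up(f$gamma_lw) + round_half_up(f$gamma_ab),
      negative_root_flags = paste(
        names(f$negative_root_flag)[f$negative_root_flag], collapse = ";"),
      hydrophobicity_class = if (is.na(theta_w)) NA_character_
                             else classify_hydrophobicity(theta_w),
      gamma_lw_full = f$gamma_lw,
      gamma_plus_full = f$gamma_plus,
      gamma_minus_full = f$gamma_minus,
      gamma_ab_full = f$gamma_ab,
      gamma_total_full = f$gamma_total,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
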