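#' Probe-liquid surface-tension components
#'
#' Constructs a `test_liquid` object holding the surface-tension components
#' of a probe liquid used in sessile-drop contact-angle work: the total
#' surface tension \eqn{\gamma}, its Lifshitz-van der Waals (apolar) part
#' \eqn{\gamma^{LW}}, and the Lewis electron-acceptor / electron-donor parts
#' \eqn{\gamma^{+}} and \eqn{\gamma^{-}}. All values are in mJ/m^2.
#'
#' The components must be internally consistent:
#' \eqn{\gamma \approx \gamma^{LW} + 2\sqrt{\gamma^{+}\gamma^{-}}} within
#' 0.5 mJ/m^2. An apolar liquid (e.g. methylene iodide) has
#' \eqn{\gamma^{+} = \gamma^{-} = 0}.
#'
#' @param name Liquid label, e.g. `"water"`.
#' @param gamma_total Total surface tension, mJ/m^2 (> 0).
#' @param gamma_lw Lifshitz-van der Waals component, mJ/m^2 (>= 0).
#' @param gamma_plus Electron-acceptor component, mJ/m^2 (>= 0).
#' @param gamma_minus Electron-donor component, mJ/m^2 (>= 0).
#' @return An object of class `test_liquid`.
#' @examples
#' water <- test_liquid("water", 72.8, 21.8, 25.5, 25.5)
#' water
#' @export
test_liquid <- function(name, gamma_total, gamma_lw, gamma_plus, gamma_minus) {
  stopifnot(is.character(name), length(name) == 1L)
  vals <- c(gamma_total = gamma_total, gamma_lw = gamma_lw,
            gamma_plus = gamma_plus, gamma_minus = gamma_minus)
  if (any(!is.finite(vals)))
    stop("liquid '", name, "': all surface-tension components must be finite")
  if (gamma_total <= 0)
    stop("liquid '", name, "': gamma_total must be positive")
  if (gamma_lw < 0 || gamma_plus < 0 || gamma_minus < 0)
    stop("liquid '", name, "': components must be non-negative")
  recon <- gamma_lw + 2 * sqrt(gamma_plus * gamma_minus)
  if (abs(recon - gamma_total) > 0.5)
    stop("liquid '", name, "': gamma_lw + 2*sqrt(gamma_plus*gamma_minus) = ",
         signif(recon, 6), " differs from gamma_total = ", gamma_total,
         " by more than 0.5 mJ/m^2")
  structure(
    list(name = name, gamma_total = gamma_total, gamma_lw = gamma_lw,
         gamma_ab = 2 * sqrt(gamma_plus * gamma_minus),
         gamma_plus = gamma_plus, gamma_minus = gamma_minus),
    class = "test_liquid")
}

#' @export
print.test_liquid <- function(x, ...) {
  cat(sprintf(
    "<test_liquid> %s: gamma=%.2f LW=%.2f AB=%.2f (+)=%.3f (-)=%.2f mJ/m^2\n",
    x$name, x$gamma_total, x$gamma_lw, x$gamma_ab, x$gamma_plus,
    x$gamma_minus))
  invisible(x)
}

is_apolar <- function(liquid) {
  liquid$gamma_plus == 0 && liquid$gamma_minus == 0
}

is_polar <- function(liquid) !is_apolar(liquid)

#' Standard probe-liquid set
#'
#' Returns the conventional three-liquid probe set (water, formamide,
#' methylene iodide) with the van Oss-Chaudhury-Good surface-tension
#' components, read from the CSV shipped with the package
#' (`system.file("extdata", "probe_liquids.csv", package = "adhesim")`).
#'
#' @return Named list of `test_liquid` objects.
#' @examples
#' probe_liquids()$water
#' @export
probe_liquids <- function() {
  path <- system.file("extdata", "probe_liquids.csv", package = "adhesim",
                      mustWork = TRUE)
  read_liquids(path)
}

#' Read probe liquids from CSV
#'
#' Reads a liquid-constants table with columns
#' `name,gamma_total,gamma_lw,gamma_ab,gamma_plus,gamma_minus` (mJ/m^2).
#' The `gamma_ab` column is informational; the stored value is recomputed
#' from `gamma_plus` and `gamma_minus`.
#'
#' @param path CSV file path.
#' @return Named list of `test_liquid` objects.
#' @export
read_liquids <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "gamma_total", "gamma_lw", "gamma_plus", "gamma_minus")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("liquid table ", path, " lacks columns: ", paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    test_liquid(df$name[i], df$gamma_total[i], df$gamma_lw[i],
                df$gamma_plus[i], df$gamma_minus[i]))
  names(out) <- df$name
  out
}

#' Single contact-angle measurement
#'
#' Pairs a probe liquid with the mean and standard deviation of replicate
#' sessile-drop contact-angle readings on one surface.
#'
#' @param liquid A `test_liquid`.
#' @param theta_mean Mean contact angle, degrees, in \[0, 180\].
#' @param theta_sd Standard deviation of the readings, degrees (>= 0).
#' @param n_readings Number of readings averaged (>= 1).
#' @return An object of class `contact_angle`.
#' @examples
#' contact_angle(probe_liquids()$water, 77.8, theta_sd = 1.3, n_readings = 10)
#' @export
contact_angle <- function(liquid, theta_mean, theta_sd = 0, n_readings = 1L) {
  if (!inherits(liquid, "test_liquid"))
    stop("'liquid' must be a test_liquid object")
  if (!is.finite(theta_mean) || theta_mean < 0 || theta_mean > 180)
    stop("theta_mean = ", theta_mean, " outside [0, 180] degrees")
  if (!is.finite(theta_sd) || theta_sd < 0)
    stop("theta_sd must be >= 0")
  if (n_readings < 1)
    stop("n_readings must be >= 1")
  structure(
    list(liquid = liquid, theta_mean = theta_mean, theta_sd = theta_sd,
         n_readings = as.integer(n_readings)),
    class = "contact_angle")
}

#' @export
print.contact_angle <- function(x, ...) {
  cat(sprintf("<contact_angle> %s: %.1f +/- %.1f deg (n=%d)\n",
              x$liquid$name, x$theta_mean, x$theta_sd, x$n_readings))
  invisible(x)
}

#' Read contact angles from CSV
#'
#' Reads a table with columns `surface,liquid,theta_mean,theta_sd,n_readings`
#' and resolves each `liquid` against a named list of `test_liquid` objects.
#'
#' @param path CSV file path.
#' @param liquids Named list of `test_liquid` objects
#'   (default [probe_liquids()]).
#' @return Named list (by surface) of lists of `contact_angle` objects.
#' @export
read_contact_angles <- function(path, liquids = probe_liquids()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("surface", "liquid", "theta_mean")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("angle table ", path, " lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(df$theta_sd)) df$theta_sd <- 0
  if (is.null(df$n_readings)) df$n_readings <- 1L
  unknown <- setdiff(unique(df$liquid), names(liquids))
  if (length(unknown))
    stop("unknown liquids in ", path, ": ", paste(unknown, collapse = ", "))
  split_df <- split(df, df$surface)
  lapply(split_df, function(s)
    lapply(seq_len(nrow(s)), function(i)
      contact_angle(liquids[[s$liquid[i]]], s$theta_mean[i],
                    s$theta_sd[i], s$n_readings[i])))
}
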