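#' Grayscale micrograph container
#'
#' Wraps a numeric intensity matrix as a `micrograph` with identifying
#' labels. Intensities are on whatever scale the source used (8-bit images
#' are read as 0-255); the analysis is scale-free because thresholds are
#' computed from the observed range.
#'
#' @param pixels Numeric matrix, at least 64 x 64, all values finite.
#' @param image_id Image label.
#' @param condition_id Assay-condition label the image belongs to.
#' @return A `micrograph` (matrix with attributes).
#' @export
micrograph <- function(pixels, image_id = "img", condition_id = "cond") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix (single channel)")
  if (nrow(pixels) < 64 || ncol(pixels) < 64)
    stop("micrograph must be at least 64 x 64 pixels; got ",
         nrow(pixels), " x ", ncol(pixels))
  if (any(!is.finite(pixels)))
    stop("micrograph intensities must all be finite")
  structure(pixels, image_id = image_id, condition_id = condition_id,
            class = c("micrograph", "matrix"))
}

#' Read a grayscale micrograph from TIFF or PNG
#'
#' Reads an 8- or 16-bit image and returns it as a [micrograph()] on a
#' 0-255 scale. Multi-channel images are averaged to one channel.
#'
#' @param path Image file path.
#' @param image_id Label; defaults to the file name.
#' @param condition_id Condition label.
#' @return A `micrograph`.
#' @export
read_micrograph <- function(path, image_id = basename(path),
                            condition_id = "cond") {
  img <- EBImage::readImage(path)
  d <- dim(img)
  m <- if (length(d) == 2) EBImage::imageData(img)
       else apply(EBImage::imageData(img), c(1, 2), mean)
  micrograph(m * 255, image_id = image_id, condition_id = condition_id)
}

new_mask <- function(pixels, threshold_used, polarity, src = NULL) {
  structure(pixels, threshold_used = threshold_used, polarity = polarity,
            image_id = attr(src, "image_id"),
            condition_id = attr(src, "condition_id"),
            class = c("binary_mask", "matrix"))
}

#' Flatten uneven illumination
#'
#' Subtracts a rolling-mean background (separable moving average with the
#' given window) from a micrograph and re-centres on the original mean
#' intensity. Off by default in [binarize()]; useful when images carry a
#' lamp gradient.
#'
#' @param image A `micrograph`.
#' @param window Odd window size in pixels for the moving average.
#' @return A `micrograph` with the low-frequency background removed.
#' @export
flatten_illumination <- function(image, window = 63L) {
  window <- as.integer(window)
  if (window < 3L) return(image)
  if (window %% 2L == 0L) window <- window + 1L
  k <- rep(1 / window, window)
  pad <- (window - 1L) %/% 2L
  smooth1 <- function(m) {
    # reflect-pad rows, then run the moving average down each column
    mp <- rbind(m[pad:1, , drop = FALSE], m,
                m[nrow(m):(nrow(m) - pad + 1L), , drop = FALSE])
    f <- stats::filter(mp, k, sides = 2)
    matrix(f[(pad + 1L):(pad + nrow(m)), ], nrow(m), ncol(m))
  }
  bg <- t(smooth1(t(smooth1(unclass(image)))))
  out <- unclass(image) - bg + mean(image)
  micrograph(out, attr(image, "image_id"), attr(image, "condition_id"))
}

#' Binarize a micrograph into a cell mask
#'
#' Converts a grayscale micrograph to a foreground/background mask, the
#' first step of coverage quantification. The threshold is either computed
#' by Otsu's method over the image's intensity range or supplied as a fixed
#' value; `polarity` states whether cells are darker or lighter than the
#' background.
#'
#' @param image A `micrograph`.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold Threshold intensity, required for `method = "fixed"`.
#' @param polarity `"dark_cells"` (foreground below threshold) or
#'   `"light_cells"` (above).
#' @param correct_illumination Apply [flatten_illumination()] first.
#' @return A `binary_mask` (logical matrix) with attributes
#'   `threshold_used` and `polarity`.
#' @examples
#' img <- gen_micrograph(micrograph_spec(true_coverage = 0.3, seed = 1))
#' mask <- binarize(img$image)
#' mean(mask)
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL,
                     polarity = c("dark_cells", "light_cells"),
                     correct_illumination = FALSE) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  if (!inherits(image, "micrograph")) image <- micrograph(image)
  if (correct_illumination) image <- flatten_illumination(image)
  m <- unclass(image)
  rng <- range(m)
  if (method == "otsu") {
    if (diff(rng) == 0)
      stop("constant-intensity image: Otsu threshold is degenerate")
    scaled <- (m - rng[1]) / diff(rng)
    thr01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1),
                           levels = 256)
    threshold <- rng[1] + thr01 * diff(rng)
  } else {
    if (is.null(threshold) || !is.finite(threshold))
      stop("method = 'fixed' requires a finite 'threshold'")
  }
  fg <- if (polarity == "dark_cells") m < threshold else m > threshold
  new_mask(fg, threshold_used = threshold, polarity = polarity, src = image)
}

## 8-connected labeling of a logical matrix. EBImage::bwlabel is
## 4-connected, and object counts must follow the 8-connectivity
## convention, so components are taken on the 8-neighbour pixel graph.
label_components <- function(mask) {
  m <- unclass(mask)
  nr <- nrow(m); nc <- ncol(m)
  idx <- which(m)
  lab <- matrix(0L, nr, nc)
  if (!length(idx)) return(lab)
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  row <- ((idx - 1L) %% nr) + 1L
  edges <- list()
  # column-major offsets: down, right, down-right, up-right
  offs <- list(c(1L, 1L), c(nr, 0L), c(nr + 1L, 1L), c(nr - 1L, -1L))
  for (o in offs) {
    nb <- idx + o[1]
    ok <- nb >= 1L & nb <= nr * nc & (row + o[2]) >= 1L & (row + o[2]) <= nr
    ok[ok] <- m[nb[ok]]
    if (any(ok))
      edges[[length(edges) + 1L]] <- rbind(vid[idx[ok]], vid[nb[ok]])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  lab[idx] <- igraph::components(g)$membership
  lab
}

#' Morphological cleanup of a binary mask
#'
#' Opens the mask with a disk structuring element, then drops connected
#' components (8-connectivity) smaller than `min_object_px`. Both steps can
#' only remove foreground, never add it; radius 0 and `min_object_px = 0`
#' are the identity.
#'
#' @param mask A `binary_mask`.
#' @param min_object_px Minimum object size kept, pixels (>= 0).
#' @param opening_radius Disk radius for the morphological opening (>= 0).
#' @return Cleaned `binary_mask`.
#' @export
denoise <- function(mask, min_object_px = 25L, opening_radius = 1L) {
  if (min_object_px < 0 || opening_radius < 0)
    stop("min_object_px and opening_radius must be >= 0")
  m <- unclass(mask)
  if (opening_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(opening_radius) + 1L, "disc")
    m <- EBImage::imageData(
      EBImage::opening(EBImage::Image(m * 1), brush)) > 0.5
  }
  if (min_object_px > 0 && any(m)) {
    lab <- label_components(m)
    areas <- tabulate(lab[lab > 0L])
    keep <- which(areas >= min_object_px)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  new_mask(m, threshold_used = attr(mask, "threshold_used"),
           polarity = attr(mask, "polarity"), src = mask)
}

#' Quantify cell coverage from a cleaned mask
#'
#' Labels foreground objects (8-connectivity) and returns the adhesion
#' readout: the coverage fraction, occupied pixels over total pixels, plus
#' the object count and per-object areas. Object counts depend on the
#' labeling convention and on whether touching cells merge; the coverage
#' fraction does not.
#'
#' @param mask A `binary_mask` (typically after [denoise()]).
#' @param image_id Optional label override.
#' @return A `coverage_result`: list with `coverage_fraction`,
#'   `object_count`, `object_areas_px`, `image_id`, `condition_id`,
#'   `threshold_used`.
#' @export
quantify <- function(mask, image_id = NULL) {
  m <- unclass(mask)
  lab <- label_components(m)
  areas <- if (any(m)) tabulate(lab[lab > 0L]) else integer(0)
  structure(
    list(coverage_fraction = sum(m) / length(m),
         object_count = length(areas),
         object_areas_px = areas,
         image_id = image_id %||% attr(mask, "image_id") %||% "img",
         condition_id = attr(mask, "condition_id") %||% "cond",
         threshold_used = attr(mask, "threshold_used")),
    class = "coverage_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("<coverage_result> %s: coverage %.4f, %d objects\n",
              x$image_id, x$coverage_fraction, x$object_count))
  invisible(x)
}

#' Replicate summary of coverage fractions
#'
#' Builds a `replicate_summary` either from raw numbers (e.g. when
#' ingesting a published table) or via [summarize_replicates()] from
#' per-image results.
#'
#' @param mean_coverage Mean coverage fraction in \[0, 1\].
#' @param sd_coverage Standard deviation (>= 0); `NA` when unknown.
#' @param n_images Number of replicate images (>= 1).
#' @param single_replicate Flag set when the sd is a convention (n = 1).
#' @return A `replicate_summary`.
#' @export
replicate_summary <- function(mean_coverage, sd_coverage = NA_real_,
                              n_images = 1L, single_replicate = FALSE) {
  if (!is.finite(mean_coverage) || mean_coverage < 0 || mean_coverage > 1)
    stop("mean_coverage must lie in [0, 1]")
  if (!is.na(sd_coverage) && sd_coverage < 0)
    stop("sd_coverage must be >= 0")
  if (n_images < 1) stop("n_images must be >= 1")
  structure(list(mean_coverage = mean_coverage, sd_coverage = sd_coverage,
                 n_images = as.integer(n_images),
                 single_replicate = single_replicate),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("<replicate_summary> %.3f +/- %s (n=%d)\n", x$mean_coverage,
              ifelse(is.na(x$sd_coverage), "NA",
                     sprintf("%.3f", x$sd_coverage)), x$n_images))
  invisible(x)
}

#' Summarise replicate coverage results for one condition
#'
#' Mean and sample standard deviation (n - 1 denominator) of the coverage
#' fractions of replicate images from a single assay condition. A single
#' image yields sd 0 with the `single_replicate` flag set.
#'
#' @param results List of `coverage_result` objects sharing one
#'   `condition_id`.
#' @return A [replicate_summary()].
#' @export
summarize_replicates <- function(results) {
  if (!is.list(results) || !length(results))
    stop("need at least one coverage_result")
  if (!all(vapply(results, inherits, logical(1), "coverage_result")))
    stop("'results' must be a list of coverage_result objects")
  conds <- unique(vapply(results, `[[`, character(1), "condition_id"))
  if (length(conds) > 1)
    stop("results mix condition_ids: ", paste(conds, collapse = ", "))
  cov <- vapply(results, `[[`, numeric(1), "coverage_fraction")
  n <- length(cov)
  replicate_summary(mean_coverage = mean(cov),
                    sd_coverage = if (n > 1) stats::sd(cov) else 0,
                    n_images = n, single_replicate = n == 1)
}

#' Run the coverage pipeline over a batch of micrographs
#'
#' Applies [binarize()], [denoise()], [quantify()] to each image and
#' [summarize_replicates()] per condition.
#'
#' @param images List of `micrograph` objects.
#' @param method,threshold,polarity,correct_illumination Passed to
#'   [binarize()].
#' @param min_object_px,opening_radius Passed to [denoise()].
#' @return List with `per_image` (data frame: image_id, condition_id,
#'   coverage_fraction, object_count, threshold_used) and `per_condition`
#'   (data frame: condition_id, mean_coverage, sd_coverage, n_images).
#' @export
analyze_micrographs <- function(images, method = "otsu", threshold = NULL,
                                polarity = "dark_cells",
                                correct_illumination = FALSE,
                                min_object_px = 25L, opening_radius = 1L) {
  results <- lapply(images, function(img)
    quantify(denoise(binarize(img, method = method, threshold = threshold,
                              polarity = polarity,
                              correct_illumination = correct_illumination),
                     min_object_px = min_object_px,
                     opening_radius = opening_radius)))
  per_image <- data.frame(
    image_id = vapply(results, `[[`, character(1), "image_id"),
    condition_id = vapply(results, `[[`, character(1), "condition_id"),
    coverage_fraction = vapply(results, `[[`, numeric(1),
                               "coverage_fraction"),
    object_count = vapply(results, `[[`, integer(1), "object_count"),
    threshold_used = vapply(results, `[[`, numeric(1), "threshold_used"),
    stringsAsFactors = FALSE)
  split_res <- split(results, per_image$condition_id)
  per_condition <- do.call(rbind, lapply(names(split_res), function(cid) {
    s <- summarize_replicates(split_res[[cid]])
    data.frame(condition_id = cid, mean_coverage = s$mean_coverage,
               sd_coverage = s$sd_coverage, n_images = s$n_images,
               stringsAsFactors = FALSE)
  }))
  list(per_image = per_image, per_condition = per_condition)
}
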