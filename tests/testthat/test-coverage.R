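# pixel values of a mask, attribute-free, for comparison with ground truth
px <- function(m) {
  m <- unclass(m)
  attributes(m) <- list(dim = dim(m))
  m
}

noiseless_spec <- function(cov, seed = 1)
  micrograph_spec(true_coverage = cov, coverage_sd = 0, noise_sd = 0,
                  seed = seed)

test_that("otsu binarization recovers the generator mask exactly when noise-free", {
  g <- gen_micrograph(noiseless_spec(0.3, seed = 2))
  mask <- binarize(g$image)
  expect_identical(px(mask), g$mask)
  thr <- attr(mask, "threshold_used")
  expect_true(thr > 60 && thr < 200)
})

test_that("binarization handles polarity, fixed thresholds, and degenerate images", {
  g <- gen_micrograph(noiseless_spec(0.4, seed = 5))
  dark <- binarize(g$image, polarity = "dark_cells")
  inverted <- micrograph(255 - unclass(g$image))
  light <- binarize(inverted, polarity = "light_cells")
  expect_identical(px(light), px(dark))
  # fixed threshold below every intensity finds nothing
  bg <- micrograph(matrix(200, 64, 64))
  expect_identical(sum(binarize(bg, "fixed", threshold = 100)), 0L)
  expect_error(binarize(bg, "otsu"), "degenerate")
  expect_error(binarize(bg, "fixed"), "requires a finite 'threshold'")
})

test_that("denoise removes specks but keeps cell-scale objects", {
  m <- matrix(FALSE, 128, 128)
  m[outer((1:128 - 40)^2, (1:128 - 40)^2, `+`) <= 12.6^2] <- TRUE  # ~500 px
  disk_px <- sum(m)
  set.seed(3)
  specks <- sample(which(!m), 30)
  m[specks] <- TRUE
  mask <- structure(m, threshold_used = 100, polarity = "dark_cells",
                    class = c("binary_mask", "matrix"))
  clean <- denoise(mask, min_object_px = 10, opening_radius = 1)
  q <- quantify(clean)
  expect_identical(q$object_count, 1L)
  expect_lte(sum(clean), disk_px + 30)
  # degenerate parameters are the identity
  expect_identical(px(denoise(mask, 0, 0)), px(mask))
  # empty in, empty out
  empty <- structure(matrix(FALSE, 64, 64), class = c("binary_mask",
                                                      "matrix"))
  expect_identical(sum(denoise(empty, 25, 1)), 0L)
})

test_that("quantify counts 8-connected objects and pixel-exact coverage", {
  mk <- function(m) structure(m, class = c("binary_mask", "matrix"))
  expect_equal(quantify(mk(matrix(FALSE, 64, 64)))$coverage_fraction, 0)
  expect_identical(quantify(mk(matrix(FALSE, 64, 64)))$object_count, 0L)
  full <- quantify(mk(matrix(TRUE, 64, 64)))
  expect_equal(full$coverage_fraction, 1)
  expect_identical(full$object_count, 1L)
  # two disjoint 32x32 squares in a 256x256 field
  m <- matrix(FALSE, 256, 256)
  m[1:32, 1:32] <- TRUE
  m[100:131, 200:231] <- TRUE
  q <- quantify(mk(m))
  expect_identical(q$object_count, 2L)
  expect_equal(q$coverage_fraction, 2048 / 65536)
  expect_identical(sort(q$object_areas_px), c(1024L, 1024L))
  # diagonal contact merges under 8-connectivity
  d <- matrix(FALSE, 64, 64)
  d[10, 10] <- TRUE; d[11, 11] <- TRUE; d[12, 10] <- TRUE
  expect_identical(quantify(mk(d))$object_count, 1L)
})

test_that("replicate summaries use the sample standard deviation", {
  mk <- function(cov, id) structure(
    list(coverage_fraction = cov, object_count = 1L,
         object_areas_px = 1L, image_id = id, condition_id = "A",
         threshold_used = 100), class = "coverage_result")
  s <- summarize_replicates(list(mk(0.5, "a"), mk(0.5, "b"), mk(0.5, "c")))
  expect_equal(s$mean_coverage, 0.5)
  expect_equal(s$sd_coverage, 0)
  s2 <- summarize_replicates(list(mk(0.4, "a"), mk(0.6, "b")))
  expect_equal(s2$mean_coverage, 0.5)
  expect_equal(s2$sd_coverage, sqrt((0.01 + 0.01) / 1))
  one <- summarize_replicates(list(mk(0.3, "a")))
  expect_true(one$single_replicate)
  expect_equal(one$sd_coverage, 0)
  bad <- mk(0.2, "z"); bad$condition_id <- "B"
  expect_error(summarize_replicates(list(mk(0.1, "a"), bad)), "mix")
  expect_error(summarize_replicates(list()), "at least one")
})

test_that("the pipeline recovers generator ground truth at default noise", {
  for (seed in c(1, 17)) {
    for (cov in c(0.1, 0.5)) {
      set <- gen_micrograph_set(micrograph_spec(true_coverage = cov,
                                                seed = seed * 1000),
                                n_images = 3, condition_id = "x")
      est <- vapply(set, function(g)
        quantify(denoise(binarize(g$image)))$coverage_fraction, numeric(1))
      truth <- vapply(set, `[[`, numeric(1), "realized_coverage")
      expect_lt(mean(abs(est - truth)), 0.02)
    }
  }
})

test_that("raising min_object_px never increases coverage", {
  g <- gen_micrograph(micrograph_spec(true_coverage = 0.3, seed = 9))
  mask <- binarize(g$image)
  covs <- vapply(c(0, 10, 50, 200, 1000), function(mp)
    quantify(denoise(mask, min_object_px = mp))$coverage_fraction,
    numeric(1))
  expect_true(all(diff(covs) <= 0))
})

test_that("the pipeline is deterministic and duplication leaves the mean fixed", {
  g <- gen_micrograph(micrograph_spec(true_coverage = 0.4, seed = 21))
  q1 <- quantify(denoise(binarize(g$image)))
  q2 <- quantify(denoise(binarize(g$image)))
  expect_identical(q1, q2)
  s1 <- summarize_replicates(list(q1))
  s2 <- summarize_replicates(list(q1, q2))
  expect_equal(s1$mean_coverage, s2$mean_coverage)
})

test_that("illumination flattening rescues a strong lamp gradient", {
  spec <- micrograph_spec(true_coverage = 0.4, coverage_sd = 0,
                          noise_sd = 5, illumination_gradient = 0.4,
                          seed = 33)
  g <- gen_micrograph(spec)
  plain <- quantify(denoise(binarize(g$image)))
  flat <- quantify(denoise(binarize(g$image, correct_illumination = TRUE)))
  err_plain <- abs(plain$coverage_fraction - g$realized_coverage)
  err_flat <- abs(flat$coverage_fraction - g$realized_coverage)
  expect_lte(err_flat, err_plain + 0.005)
  expect_lt(err_flat, 0.05)
})

test_that("micrograph containers validate shape and finiteness", {
  expect_error(micrograph(matrix(1, 10, 10)), "at least 64 x 64")
  expect_error(micrograph(matrix(NA_real_, 64, 64)), "finite")
  m <- micrograph(matrix(5, 64, 64), "id1", "condA")
  expect_identical(attr(m, "image_id"), "id1")
})
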