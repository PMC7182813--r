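test_that("the PET three-liquid solve reproduces the published components", {
  fit <- pet_fit()
  expect_equal(round_half_up(fit$gamma_lw), 47.6)
  expect_equal(round_half_up(fit$gamma_plus), 0.2)
  expect_equal(round_half_up(fit$gamma_minus), 8.1)
  expect_equal(round_half_up(fit$gamma_ab), 2.8)
  # the electron-acceptor root comes out negative and must be flagged,
  # never zeroed
  expect_true(fit$negative_root_flag[["gamma_plus"]])
  expect_false(fit$negative_root_flag[["gamma_lw"]])
  expect_false(fit$negative_root_flag[["gamma_minus"]])
  expect_lt(fit$roots[["sqrt_gamma_plus"]], 0)
  # back-substitution residuals of all three Young equations
  expect_lt(max(abs(fit$residual_rel)), 1e-9)
})

test_that("component identities hold exactly on unrounded fields", {
  fit <- pet_fit()
  expect_identical(fit$gamma_ab,
                   2 * sqrt(fit$gamma_plus * fit$gamma_minus))
  expect_identical(fit$gamma_total, fit$gamma_lw + fit$gamma_ab)
  expect_identical(fit$gamma_lw, fit$roots[["sqrt_gamma_lw"]]^2)
  expect_identical(fit$gamma_plus, fit$roots[["sqrt_gamma_plus"]]^2)
  expect_identical(fit$gamma_minus, fit$roots[["sqrt_gamma_minus"]]^2)
})

test_that("acid_base_component and total_energy match scalar arithmetic", {
  expect_equal(acid_base_component(25.5, 25.5), 51.0)
  expect_equal(acid_base_component(0.2446, 8.095),
               2 * sqrt(0.2446 * 8.095))
  expect_equal(acid_base_component(0, 123.4), 0)
  expect_error(acid_base_component(-1, 2), "finite and >= 0")
  expect_equal(total_energy(45.2, 44.6), 89.8)
  expect_equal(total_energy(47.6, 2.8), 50.4)
  expect_equal(total_energy(0, 0), 0)
  expect_error(total_energy(Inf, 1), "finite")
})

test_that("forward modeling inverts the solve", {
  fit <- pet_fit()
  expect_equal(forward_contact_angle(fit, liq$water), 77.8,
               tolerance = 1e-9)
  expect_equal(forward_contact_angle(fit, liq$formamide), 58.2,
               tolerance = 1e-9)
  expect_equal(forward_contact_angle(fit, liq$methylene_iodide), 20.5,
               tolerance = 1e-9)
  # a purely apolar surface is completely wetted by its energetic twin
  expect_equal(forward_contact_angle(surface_energy(50.8, 0, 0),
                                     liq$methylene_iodide), 0)
  # independent scalar evaluation of the closed form for formamide
  comp <- surface_energy(40, 1, 30)
  cos_hand <- -1 + 2 * (sqrt(40 * 39.0) + sqrt(1 * 39.6) +
                        sqrt(30 * 2.28)) / 58.0
  expect_equal(forward_contact_angle(comp, liq$formamide),
               acos(cos_hand) * 180 / pi, tolerance = 1e-12)
  # an unphysical pairing is a domain error, not NaN
  expect_error(forward_contact_angle(surface_energy(200, 50, 80),
                                     liq$methylene_iodide),
               "outside \\[-1, 1\\]")
})

test_that("solve o forward is the identity on random components", {
  set.seed(11)
  n_checked <- 0
  for (i in 1:60) {
    truth <- surface_energy(runif(1, 20, 60), runif(1, 0, 5),
                            runif(1, 0, 40))
    # high-energy draws can imply complete wetting (no finite angle);
    # the identity is asserted on every physically realisable draw
    angs <- tryCatch(lapply(liq, function(L)
      contact_angle(L, forward_contact_angle(truth, L))),
      error = function(e) NULL)
    if (is.null(angs)) next
    fit <- solve_components(unname(angs))
    expect_equal(fit$gamma_lw, truth$gamma_lw, tolerance = 1e-6)
    expect_equal(fit$gamma_plus, truth$gamma_plus, tolerance = 1e-6)
    expect_equal(fit$gamma_minus, truth$gamma_minus, tolerance = 1e-6)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 20)
})

test_that("the apolar liquid alone fixes gamma_LW", {
  base <- pet_fit()
  # complete wetting by the apolar liquid pins gamma_LW at the liquid's own
  # surface tension
  wet <- solve_components(list(contact_angle(liq$water, 77.8),
                               contact_angle(liq$formamide, 58.2),
                               contact_angle(liq$methylene_iodide, 0)))
  expect_equal(wet$gamma_lw, 50.8, tolerance = 1e-9)
  # perturbing the polar-liquid angles leaves gamma_LW untouched
  pert <- solve_components(list(contact_angle(liq$water, 60),
                                contact_angle(liq$formamide, 70),
                                contact_angle(liq$methylene_iodide, 20.5)))
  expect_equal(pert$gamma_lw, base$gamma_lw, tolerance = 1e-12)
})

test_that("solver preconditions are enforced", {
  apolar2 <- test_liquid("alkane", 27.5, 27.5, 0, 0)
  expect_error(solve_components(list(
    contact_angle(apolar2, 30), contact_angle(liq$methylene_iodide, 20),
    contact_angle(liq$water, 70))), "two of the probe liquids must be polar")
  expect_error(solve_components(list(
    contact_angle(liq$water, 70), contact_angle(liq$water, 71),
    contact_angle(liq$formamide, 50))), "distinct")
  expect_error(contact_angle(liq$water, 190), "outside \\[0, 180\\]")
  # near-collinear liquid set trips the conditioning cap and names it
  w2 <- test_liquid("water2", 72.8, 21.8, 25.5, 25.5)
  w3 <- test_liquid("water3", 72.81, 21.81, 25.5, 25.5)
  expect_error(
    solve_components(list(contact_angle(liq$water, 70),
                          contact_angle(w2, 71), contact_angle(w3, 72)),
                     max_condition = 1e4),
    "water2")
})

test_that("more than three liquids fall back to least squares", {
  truth <- surface_energy(42, 2, 25)
  four <- c(liq, list(glycerol = test_liquid("glycerol", 64, 34, 3.92,
                                             57.4)))
  angs <- lapply(four, function(L)
    contact_angle(L, forward_contact_angle(truth, L)))
  fit <- solve_components(unname(angs))
  expect_equal(fit$gamma_lw, 42, tolerance = 1e-6)
  expect_equal(fit$gamma_plus, 2, tolerance = 1e-6)
  expect_equal(fit$gamma_minus, 25, tolerance = 1e-6)
})

test_that("hydrophobicity classification has exactly two breakpoints", {
  expect_identical(classify_hydrophobicity(16.6), "hydrophilic")
  expect_identical(classify_hydrophobicity(35.0),
                   "intermediately_hydrophobic")
  expect_identical(classify_hydrophobicity(77.8), "hydrophobic")
  # left-closed boundaries
  expect_identical(classify_hydrophobicity(c(19.999, 20, 49.999, 50)),
                   c("hydrophilic", "intermediately_hydrophobic",
                     "intermediately_hydrophobic", "hydrophobic"))
  # total on [0, 180]
  grid <- seq(0, 180, by = 0.5)
  cls <- classify_hydrophobicity(grid)
  expect_false(anyNA(cls))
  expect_identical(sum(diff(as.integer(factor(cls,
    levels = c("hydrophilic", "intermediately_hydrophobic",
               "hydrophobic")))) != 0), 2L)
  expect_error(classify_hydrophobicity(-1), "outside")
  expect_error(classify_hydrophobicity(181), "outside")
})

test_that("uncertainty propagation degenerates to the point solve", {
  point <- pet_fit()
  pu <- propagate_uncertainty(pet_angles(c(0, 0, 0)), n_draws = 100,
                              seed = 1)
  expect_equal(unname(pu$sd), rep(0, 5))
  expect_equal(unname(pu$mean[1:3]),
               c(point$gamma_lw, point$gamma_plus, point$gamma_minus))
  expect_equal(pu$failure_fraction, 0)
})

test_that("uncertainty propagation is unbiased in root space", {
  point <- pet_fit()
  n <- 2000
  pu <- propagate_uncertainty(pet_angles(c(1.3, 1.8, 2.2)), n_draws = n,
                              seed = 7)
  # signed roots respond linearly to angle noise: means within 3 MC
  # standard errors of the point solve
  se <- pu$root_sd / sqrt(n)
  expect_true(all(abs(pu$root_mean - point$roots) < 3 * se))
  # squared magnitudes acquire a positive bias of order the root variance
  expect_true(all(abs(pu$mean[c("gamma_lw", "gamma_minus")] -
                      c(point$gamma_lw, point$gamma_minus)) <
                  3 * se[c(1, 3)] * 2 * abs(point$roots[c(1, 3)]) +
                  pu$root_sd[c(1, 3)]^2))
  # the negative acceptor root shows up in most draws
  expect_gt(pu$negative_root_fraction[["gamma_plus"]], 0.5)
  expect_identical(pu$n_draws, n)
})

test_that("component sds grow when every angle sd doubles", {
  for (s in 1:3) {
    lo <- propagate_uncertainty(pet_angles(c(1.3, 1.8, 2.2)),
                                n_draws = 400, seed = s)
    hi <- propagate_uncertainty(pet_angles(2 * c(1.3, 1.8, 2.2)),
                                n_draws = 400, seed = s)
    expect_true(all(hi$sd > lo$sd))
  }
})

test_that("reproducibility: identical seeds give identical propagation", {
  a <- propagate_uncertainty(pet_angles(c(1, 1, 1)), n_draws = 150,
                             seed = 42)
  b <- propagate_uncertainty(pet_angles(c(1, 1, 1)), n_draws = 150,
                             seed = 42)
  expect_identical(a, b)
})

test_that("liquid constructors validate their invariants", {
  expect_error(test_liquid("bad", 72.8, 21.8, 25.5, 10),
               "differs from gamma_total")
  expect_error(test_liquid("neg", 50, -1, 0, 0), "non-negative")
  expect_error(test_liquid("zero", 0, 0, 0, 0), "positive")
  # shipped liquid set satisfies the composition identity within 0.5
  for (L in liq)
    expect_lt(abs(L$gamma_lw + 2 * sqrt(L$gamma_plus * L$gamma_minus) -
                  L$gamma_total), 0.5)
  expect_equal(liq$methylene_iodide$gamma_plus, 0)
  expect_equal(liq$methylene_iodide$gamma_minus, 0)
})

test_that("surface_energy_table reports display and full precision", {
  tab <- surface_energy_table(pet_fit())
  expect_equal(tab$gamma_lw, 47.6)
  expect_equal(tab$gamma_total, 50.4)  # additive at display precision
  expect_equal(tab$gamma_lw_full + tab$gamma_ab_full, tab$gamma_total_full)
  expect_identical(tab$negative_root_flags, "gamma_plus")
  expect_identical(tab$hydrophobicity_class, "hydrophobic")
})

test_that("round_half_up rounds halves away from zero", {
  expect_equal(round_half_up(c(0.05, 0.15, -0.05), 1), c(0.1, 0.2, -0.1))
  expect_equal(round_half_up(2.25, 1), 2.3)
})
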