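test_that("regular-polygon coefficient and hexagon slope take their closed-form values", {
  expect_equal(polygon_shape_coefficient(6), 24 * tan(pi / 6), tolerance = 1e-15)
  expect_equal(polygon_shape_coefficient(6), 13.8564, tolerance = 1e-4)
  expect_equal(polygon_shape_coefficient(4), 16, tolerance = 1e-12) # squares: p^2/a = 16
  expect_equal(hexagon_slope(), sqrt(13.85641) / 2, tolerance = 1e-6)
  # slope is d p / d a along p = sqrt(c6 a) at a = 1, checked numerically
  h <- 1e-7
  num <- (sqrt(13.856406 * (1 + h)) - sqrt(13.856406 * (1 - h))) / (2 * h)
  expect_equal(hexagon_slope(), num, tolerance = 1e-6)
})

test_that("mean-field closed forms evaluate and obey their limits", {
  c_hex <- 1.861
  mfa <- meanfield_fitness_area(-0.1, gamma = 1, lam = 1, c = c_hex)
  expect_equal(mfa$s, 0.1 * (c_hex^2 / (1 + c_hex^2)), tolerance = 1e-12)
  expect_equal(mfa$s, 0.0776, tolerance = 1e-3)
  mfp <- meanfield_fitness_perimeter(0.1, gamma = 1, lam = 1, c = c_hex)
  expect_equal(mfp$s, 0.1 * c_hex / (1 + c_hex^2), tolerance = 1e-12)
  expect_equal(mfp$s, 0.0417, tolerance = 1e-3)
  # no preference difference, no fitness difference
  expect_equal(meanfield_fitness_area(0)$s, 0)
  expect_equal(meanfield_fitness_perimeter(0)$s, 0)
  # gamma -> 0 kills the effect; gamma -> Inf saturates at -lam * delta_a0
  expect_equal(meanfield_fitness_area(-0.1, gamma = 0)$s, 0)
  expect_equal(meanfield_fitness_area(-0.1, gamma = 1e12)$s, 0.1, tolerance = 1e-9)
  # monotone in gamma for delta_a0 < 0
  ss <- vapply(c(0.1, 0.5, 1, 2, 5, 20), function(g)
    meanfield_fitness_area(-0.1, gamma = g)$s, 1.0)
  expect_true(all(diff(ss) > 0))
  # perimeter direction: sign(s) = sign(delta_p0)
  expect_gt(meanfield_fitness_perimeter(0.3)$s, 0)
  expect_lt(meanfield_fitness_perimeter(-0.3)$s, 0)
})

test_that("invasion initialization places the requested contiguous droplet", {
  des <- invasion_design(resident = solid_resident(), mutant = list(a0 = 0.9),
                         n0 = 400, initial_fraction = 0.1, relax_steps = 20L)
  st <- init_invasion(des, seed = 12)
  expect_equal(sum(st$types == "mutant"), 40)
  # contiguity: every mutant has at least one mutant Voronoi neighbor
  te <- build_tessellation(st, tissue_box(400))
  mut <- which(st$types == "mutant")
  has_mut_nbr <- vapply(mut, function(i) any(te$neighbors[[i]] %in% mut), TRUE)
  expect_true(all(has_mut_nbr))
  # determinism
  st2 <- init_invasion(des, seed = 12)
  expect_identical(st$positions, st2$positions)
  expect_identical(st$types, st2$types)
  # degenerate fractions are rejected
  expect_error(invasion_design(initial_fraction = 0), "between 0 and 1")
  expect_error(invasion_design(initial_fraction = 1), "between 0 and 1")
  expect_error(label_droplet(st, tissue_box(400), 0.999999), "not a mixture")
})

test_that("a neutral invasion has selection coefficient consistent with zero", {
  des <- invasion_design(resident = solid_resident(), n0 = 100,
                         initial_fraction = 0.3, n_replicates = 5,
                         horizon = 10, record_every = 50L, relax_steps = 150L)
  res <- run_invasion(des, seed = 7)
  expect_lt(abs(res$fit$s), 4 * res$fit$stderr + 0.02)
  expect_equal(res$fit$method, "invasion_fit")
  expect_true(all(res$trajectory$f > 0 & res$trajectory$f < 1))
})

test_that("a pure basal-birth advantage reproduces its rate difference as the logit slope", {
  delta <- 0.08
  des <- invasion_design(resident = solid_resident(),
                         mutant = list(rb0 = delta),
                         n0 = 100, initial_fraction = 0.3, n_replicates = 6,
                         horizon = 15, record_every = 50L, relax_steps = 150L)
  res <- run_invasion(des, seed = 31)
  expect_gt(res$fit$s, 0)
  expect_equal(res$fit$s, delta, tolerance = 0.5)
})

test_that("the mixture predictor is neutral for identical types and deterministic", {
  fit <- mixture_predictor(solid_resident(), solid_resident(), n0 = 64,
                           horizon = 10, record_every = 50L,
                           relax_steps = 150L, seed = 3)
  expect_lt(abs(fit$s), 0.05)
  fit2 <- mixture_predictor(solid_resident(), solid_resident(), n0 = 64,
                            horizon = 10, record_every = 50L,
                            relax_steps = 150L, seed = 3)
  expect_identical(fit$s, fit2$s)
  expect_equal(fit$method, "mixture")
  expect_error(mixture_predictor(type_params(beta = 0.5)), "beta = 0")
})

test_that("fitted area-perimeter slope is positive in the solid phase and weaker in the liquid", {
  fs <- acc_memo("mix_solid_363", mixture_predictor(
    reference_resident(3.63), list(a0 = 0.9), n0 = 100, horizon = 30,
    record_every = 25L, relax_steps = 300L, seed = 11))
  fl <- mixture_predictor(liquid_resident(), list(a0 = 0.9), n0 = 100,
                          horizon = 30, record_every = 25L,
                          relax_steps = 300L, seed = 11)
  c_solid <- estimate_c(fs)
  c_liquid <- estimate_c(fl)
  expect_gt(c_solid, 0)
  expect_gt(c_solid, c_liquid)
  # degenerate records fall back to the analytic hexagon value
  degen <- data.frame(time = 1, type = 0L, area = rep(1, 10),
                      perimeter = rep(3.7, 10))
  expect_message(cc <- estimate_c(degen), "analytic hexagon")
  expect_equal(cc, hexagon_slope())
})

test_that("fitness JSON writer emits the estimate fields", {
  fit <- meanfield_fitness_area(-0.1)
  path <- tempfile(fileext = ".json")
  write_fitness_json(fit, path)
  x <- jsonlite::read_json(path)
  expect_equal(x$method, "meanfield_area")
  expect_equal(x$s, fit$s, tolerance = 1e-12)
})
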