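test_that("energy vanishes at the lattice ground state and splits into its two parts", {
  box <- tissue_box(56)
  st <- make_fixture("hexagonal", 56, box)
  te <- build_tessellation(st, box)
  p_star <- te$perimeters[1]
  e <- tissue_energy(te, type_params(a0 = 1, p0 = p_star), st$types)
  expect_equal(e$total, 0, tolerance = 1e-20)
  # perturbing any center must not lower the energy (local minimum)
  params <- type_params(a0 = 1, p0 = p_star)
  for (k in 1:5) {
    st2 <- st
    st2$positions[k, ] <- st2$positions[k, ] + 0.05 * c(cos(k), sin(k))
    st2$positions <- wrap_positions(st2$positions, box)
    e2 <- tissue_energy(build_tessellation(st2, box), params, st2$types)
    expect_gt(e2$total, 0)
  }
})

test_that("energy decomposes per cell and matches an independent summation", {
  n <- 64
  box <- tissue_box(n)
  st <- rand_state(n, seed = 11)
  st$types[sample.int(n, 30)] <- "mutant"
  pp <- hetero_pair()
  te <- build_tessellation(st, box)
  e <- tissue_energy(te, pp, st$types)
  # independent per-cell loop with scalar arithmetic
  acc <- 0
  for (i in seq_len(n)) {
    p <- if (st$types[i] == "mutant") pp$mutant else pp$resident
    acc <- acc + p$k / 2 * (te$areas[i] - p$a0)^2 +
      p$gamma / 2 * (te$perimeters[i] - p$p0)^2
  }
  expect_equal(e$total, acc, tolerance = 1e-12)
  expect_equal(e$total, e$area_part + e$perimeter_part, tolerance = 1e-12)
  expect_equal(sum(e$per_cell), e$total, tolerance = 1e-12)
  expect_true(all(e$per_cell >= 0))
})

test_that("a single-cell area perturbation costs the quadratic penalty", {
  # gamma = 0 resident: e = (a - a0)^2 / 2 summed over cells
  box <- tissue_box(4)
  st <- make_fixture("square", 4, box)
  te <- build_tessellation(st, box)
  params <- type_params(a0 = 1, p0 = 4, gamma = 0)
  delta <- 0.07
  e <- tissue_energy(list(areas = te$areas + c(delta, 0, 0, 0),
                          perimeters = te$perimeters, n = 4),
                     params, st$types)
  expect_equal(e$total, delta^2 / 2, tolerance = 1e-12)
})

test_that("analytic forces match central finite differences on heterogeneous states", {
  n <- 32
  box <- tissue_box(n)
  for (seed in 1:4) {
    st <- rand_state(n, seed = seed)
    set.seed(seed + 100)
    st$types[sample.int(n, 16)] <- "mutant"
    pp <- hetero_pair()
    fa <- tissue_forces(st, box, pp)
    fd <- tissue_forces_fd(st, box, pp)
    expect_lt(max(abs(fa - fd) / (abs(fd) + 1e-8)), 1e-5)
    # momentum conservation
    expect_lt(max(abs(colSums(fa))), 1e-9)
  }
})

test_that("forces vanish at the lattice ground state and are translation invariant", {
  box <- tissue_box(56)
  st <- make_fixture("hexagonal", 56, box)
  te <- build_tessellation(st, box)
  params <- type_params(a0 = 1, p0 = te$perimeters[1])
  f <- tissue_forces(st, box, params)
  expect_lt(max(abs(f)), 1e-9)

  st2 <- rand_state(48, seed = 21)
  f1 <- tissue_forces(st2, tissue_box(48), solid_resident())
  st2$positions <- wrap_positions(st2$positions + 1.7, tissue_box(48))
  f2 <- tissue_forces(st2, tissue_box(48), solid_resident())
  expect_equal(f1, f2, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("pressure follows the signed area/perimeter deviations", {
  params <- type_params(a0 = 1, p0 = 3.5, gamma = 0)
  fake <- function(a, p) list(areas = a, perimeters = p, n = length(a))
  # both deviations zero -> zero pressure
  expect_equal(cell_pressure(fake(1, 3.5), params, "resident"), 0)
  # gamma = 0, a below preferred -> positive pressure K*(a0 - a)
  expect_equal(cell_pressure(fake(0.9, 3.5), params, "resident"), 0.1,
               tolerance = 1e-15)
  # full expression with gamma > 0
  pg <- type_params(a0 = 1, p0 = 3.5, gamma = 0.8, k = 1.2)
  expect_equal(cell_pressure(fake(1.1, 3.9), pg, "resident"),
               -1.2 * 0.1 - 0.8 * 3.9 / (2 * 1.1) * 0.4, tolerance = 1e-12)
})

test_that("with gamma = 0 the pressure is exactly minus the area-energy gradient", {
  n <- 36
  box <- tissue_box(n)
  st <- rand_state(n, seed = 8)
  params <- type_params(a0 = 1, p0 = 3.3, gamma = 0)
  te <- build_tessellation(st, box)
  P <- cell_pressure(te, params, st$types)
  expect_equal(P, -(te$areas - 1), tolerance = 1e-14)
})

test_that("gradient descent monotonically decreases the energy", {
  n <- 48
  box <- tissue_box(n)
  st <- rand_state(n, seed = 13)
  pair <- spv_params(utils::modifyList(unclass(solid_resident()),
                                       list(v0 = 0, d_r = 0)))
  run <- simulate_tissue(st, box, pair, n_steps = 1000, dt = 0.01,
                         record_every = 1L, coupling = "none", seed = 1)
  e <- run$observables$energy
  frac_down <- mean(diff(e) <= 1e-12)
  expect_gte(frac_down, 0.99)
  expect_lt(e[length(e)], e[1])
})
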