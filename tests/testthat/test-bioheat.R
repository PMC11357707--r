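lib <- load_default_library()

test_that("no source, no exchange: temperature stays at equilibrium", {
  g <- homogeneous_grid(c(10, 10, 10), "muscle")
  sar <- as_sar_field(g, array(0, dim = g$dim))
  bc <- boundary_conditions(convective_h = 0, external_temperature = 20)
  prot <- ablation_protocol(80, 40, 100, 20)
  f <- solve_bioheat(g, lib, sar, bc, prot)
  for (v in f$values) expect_equal(max(abs(v - 20)), 0, tolerance = 1e-9)
})

test_that("insulated uniform source heats adiabatically: T = T0 + SAR*t/c", {
  g <- homogeneous_grid(c(8, 8, 8), "cancellous bone")
  p <- lookup(lib, "cancellous bone")
  sar_wkg <- 50  # W/kg
  sar <- as_sar_field(g, array(sar_wkg, dim = g$dim))
  bc <- boundary_conditions(convective_h = 0)
  prot <- ablation_protocol(80, 40, 200, 25)
  f <- solve_bioheat(g, lib, sar, bc, prot, max_dt = 10)
  want <- 25 + sar_wkg * 200 / p$specific_heat
  got <- f$values[[length(f$values)]]
  expect_lt(max(abs(got - want)) / (want - 25), 1e-3)
})

test_that("stepped-face slab follows the erfc conduction solution", {
  # semi-infinite muscle slab, face held at 50 C through a high-k
  # Dirichlet layer so the fixed plane sits at the first face
  sp <- 0.5e-3
  g <- homogeneous_grid(c(60, 7, 7), "muscle", sp)
  mask <- array(FALSE, dim = g$dim); mask[1, , ] <- TRUE
  g <- set_dirichlet(g, mask)
  lib2 <- load_default_library()
  lib2$entries[["applicator"]]$thermal_conductivity <- 1e6
  p <- lookup(lib2, "muscle")
  kappa <- p$thermal_conductivity / (p$density * p$specific_heat)
  T0 <- 20; Ts <- 50; dur <- 60
  bc <- boundary_conditions(convective_h = 0, applicator_temperature = Ts)
  prot <- ablation_protocol(80, 40, dur, T0)
  sar <- as_sar_field(g, array(0, dim = g$dim))
  f <- solve_bioheat(g, lib2, sar, bc, prot, max_dt = 0.25, store = "final")
  got <- f$values[[2]][, 4, 4]
  for (i in c(5, 8, 12, 16, 20)) {   # depths >= 3 voxels from the face
    x <- (i - 1.5) * sp              # distance from the Dirichlet face
    want <- T0 + (Ts - T0) * pracma::erfc(x / (2 * sqrt(kappa * dur)))
    expect_lt(abs(got[i] - want) / (Ts - T0), 0.02,
              label = sprintf("depth %g mm", x * 1e3))
  }
})

test_that("insulated domain conserves energy exactly", {
  g <- homogeneous_grid(c(10, 10, 10), "cortical bone")
  co <- voxel_coords(g)
  sar_arr <- array(0, dim = g$dim)
  for (i in 1:10) sar_arr[i, , ] <- 10 * i   # nonuniform source
  sar <- as_sar_field(g, sar_arr)
  bc <- boundary_conditions(convective_h = 0)
  prot <- ablation_protocol(80, 40, 120, 20)
  f <- solve_bioheat(g, lib, sar, bc, prot, max_dt = 10)
  p <- lookup(lib, "cortical bone")
  V <- g$spacing^3
  dT <- f$values[[length(f$values)]] - f$values[[1]]
  enthalpy <- sum(p$density * p$specific_heat * dT * V)
  injected <- sum(p$density * sar_arr * V) * 120
  expect_lt(abs(enthalpy - injected) / injected, 0.01)
})

test_that("zero-source temperatures respect the discrete maximum principle", {
  g <- homogeneous_grid(c(12, 12, 12), "cancellous bone")
  mask <- array(FALSE, dim = g$dim); mask[6:7, 6:7, ] <- TRUE
  g <- set_dirichlet(g, mask)
  sar <- as_sar_field(g, array(0, dim = g$dim))
  bc <- boundary_conditions(convective_h = 10, external_temperature = 20,
                            applicator_temperature = 30)
  prot <- ablation_protocol(80, 40, 300, 20)
  f <- solve_bioheat(g, lib, sar, bc, prot)
  for (v in f$values) {
    expect_gte(min(v), 20 - 1e-9)
    expect_lte(max(v), 30 + 1e-9)
  }
})

test_that("implicit solver agrees with an explicit fine-step reference", {
  g <- homogeneous_grid(c(8, 8, 8), "cancellous bone")
  mask <- array(FALSE, dim = g$dim); mask[4:5, 4:5, 1:8] <- FALSE
  mask[4, 4, ] <- TRUE
  g <- set_dirichlet(g, mask)
  co <- voxel_coords(g)
  sar_arr <- array(0, dim = g$dim)
  ii <- arrayInd(seq_len(prod(g$dim)), g$dim)
  r2 <- (co$x[ii[, 1]])^2 + (co$y[ii[, 2]])^2 + (co$z[ii[, 3]])^2
  sar_arr[] <- 2000 * exp(-r2 / (2 * (2e-3)^2))   # hot blob, W/kg
  sar <- as_sar_field(g, sar_arr)
  bc <- boundary_conditions(convective_h = 10, external_temperature = 20,
                            applicator_temperature = 30)
  prot <- ablation_protocol(80, 40, 30, 20)
  f <- solve_bioheat(g, lib, sar, bc, prot, max_dt = 0.25, store = "final")
  ref <- explicit_reference(g, lib, sar_arr, bc, 20, 30, 1e-3)
  tissue <- g$labels != match("applicator", g$classes)
  scale <- max(ref[tissue]) - 20
  expect_lt(max(abs(f$values[[2]][tissue] - ref[tissue])) / scale, 0.005)
})

test_that("scaling the source scales temperatures monotonically", {
  spec <- phantom_spec()
  pose <- default_applicator_pose(spec)
  g <- place_applicator(build_phantom(spec, 1e-3), pose)
  params <- directional_source_params(absorbed_fraction = 0.1)
  sar1 <- synthesize_sar(g, pose, params, lib, 40)
  sar2 <- as_sar_field(g, 2 * sar1$values, 80)
  bc <- boundary_conditions()
  prot <- ablation_protocol(80, 40, 60, 20)
  f1 <- solve_bioheat(g, lib, sar1, bc, prot, store = "final")
  f2 <- solve_bioheat(g, lib, sar2, bc, prot, store = "final")
  expect_true(all(f2$values[[2]] >= f1$values[[2]] - 1e-9))
})

test_that("identical configurations give bit-identical fields", {
  spec <- phantom_spec()
  prot <- ablation_protocol(80, 40, 60, 20)
  r1 <- simulate_protocol(spec, protocol = prot, store = "final")
  r2 <- simulate_protocol(spec, protocol = prot, store = "final")
  expect_identical(r1$field$values, r2$field$values)
  expect_identical(r1$logs$T1$temperatures, r2$logs$T1$temperatures)
})

test_that("short protocols barely move the probes off the initial state", {
  spec <- phantom_spec()
  prot <- ablation_protocol(80, 40, 1, 20)   # one second
  r <- simulate_protocol(spec, protocol = prot, store = "final",
                         params = directional_source_params(
                           absorbed_fraction = 0.08))
  expect_lt(abs(delta_T(r$logs$T1)$delta), 0.5)
  expect_lt(abs(delta_T(r$logs$T2)$delta), 0.5)
})

test_that("field invariants hold on a full protocol run", {
  spec <- phantom_spec()
  prot <- ablation_protocol(80, 40, 210, 20)
  r <- simulate_protocol(spec, protocol = prot,
                         params = directional_source_params(
                           absorbed_fraction = 0.08))
  f <- r$field
  expect_identical(f$times[1], 0)
  expect_identical(f$times[length(f$times)], 210)
  v0 <- f$values[[1]]
  expect_true(all(v0[!f$grid$applicator_mask] == 20))
  expect_true(all(v0[f$grid$applicator_mask] == 30))
  floor_T <- min(20, f$bc$external_temperature, f$bc$applicator_temperature)
  for (v in f$values) {
    expect_false(anyNA(v))
    expect_gte(min(v), floor_T - 1e-6)
  }
})
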