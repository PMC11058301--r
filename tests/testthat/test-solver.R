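test_that("solver input constructors validate their contracts", {
  expect_error(boundary_conditions(-0.1, 0.2), "inlet_velocity")
  expect_error(boundary_conditions(0.2, 0), "inlet_hematocrit")
  expect_error(solver_config(relax_v = 0), "relax_v")
  expect_error(solver_config(phi_bounds = c(0.5, 0.1)), "phi_bounds")
})

test_that("single-phase tube flow recovers axisymmetric Poiseuille", {
  ax <- poiseuille_fixture("axisymmetric")
  expect_true(ax$state$converged)
  ## centerline / mean velocity ratio = 2 within 2%
  expect_equal(ax$ratio, 2.0, tolerance = 0.02)
  ## parabolic profile: max pointwise error < 2% of the centerline value
  prof <- ax$profile
  R <- 50e-6
  exact <- 2 * 0.2 * (1 - (prof$y / R)^2)
  expect_lt(max(abs(prof$u_plasma - exact)) / max(exact), 0.02)
})

test_that("single-phase channel flow recovers plane Poiseuille", {
  pl <- poiseuille_fixture("planar")
  expect_true(pl$state$converged)
  expect_equal(pl$ratio, 1.5, tolerance = 0.02)
})

test_that("converged solves satisfy global and field-level sanity bounds", {
  fx <- stenosis_fixture()
  st <- fx$state
  expect_true(st$converged)
  expect_true(all(is.finite(st$vp)), all(is.finite(st$vr)),
              all(is.finite(st$p)))
  ## phi bounds maintained
  expect_true(all(st$phi >= st$config$phi_bounds[1] - 1e-15))
  expect_true(all(st$phi <= st$config$phi_bounds[2] + 1e-15))
  ## slip bounded by the plasma velocity scale
  expect_lte(max(abs(st$vr - st$vp)), max(abs(st$vp)))
  ## clipped volume-fraction mass is a negligible share of the cumulative
  ## RBC throughput of the pseudo-transient iteration
  mb <- phase_mass_balance(st, fx$grid)
  expect_lt(st$clipped_mass, 1e-3 * mb[["rbc_in"]] * st$iterations)
})

test_that("per-phase mass is conserved to 1e-6 on a converged case", {
  fx <- stenosis_fixture()
  mb <- phase_mass_balance(fx$state, fx$grid)
  expect_lt(mb[["plasma_imbalance"]], 1e-6)
  expect_lt(mb[["rbc_imbalance"]], 1e-6)
  ## inlet fluxes match the imposed boundary values
  R <- fx$geom$H
  expect_equal(mb[["plasma_in"]], 0.8 * 0.2 * R^2 / 2, tolerance = 1e-9)
  expect_equal(mb[["rbc_in"]], 0.2 * 0.2 * R^2 / 2, tolerance = 1e-9)
})

test_that("solver is deterministic: identical configs, identical histories", {
  geom <- stenosis_geometry()
  grid <- build_stenosis_grid(geom, nx = 40, ny = 8, cluster_wall = -1.2,
                              cluster_throat = 2.5)
  bc <- boundary_conditions(0.2, 0.2)
  cfg <- solver_config(max_outer = 40, tol = 1e-12)
  s1 <- suppressWarnings(steady_solve(grid, bc, config = cfg))
  s2 <- suppressWarnings(steady_solve(grid, bc, config = cfg))
  expect_identical(s1$residual_history, s2$residual_history)
  expect_identical(s1$phi, s2$phi)
  expect_identical(s1$vp, s2$vp)
})

test_that("centerline velocity error shrinks with grid refinement", {
  errs <- vapply(list(c(60, 8), c(120, 16)), function(lv) {
    px <- poiseuille_fixture("axisymmetric", lv[1], lv[2])
    abs(px$ratio - 2)
  }, numeric(1))
  err_fine <- abs(poiseuille_fixture("axisymmetric")$ratio - 2)
  expect_true(all(diff(c(errs, err_fine)) < 0))
})

test_that("uniform phi with divergence-free fluxes is a transport fixed point", {
  ## apply the implicit transport step directly with an exactly
  ## divergence-free (uniform axial) face-flux field and uniform phi
  geom <- stenosis_geometry(hs = 50e-6, mode = "planar")
  grid <- build_stenosis_grid(geom, nx = 20, ny = 6)
  bc <- boundary_conditions(0.3, 0.25)
  ws <- hemoflow:::new_workspace(grid, bc, fluid_properties(),
                                 rheology_coefficients(),
                                 interaction_params(), solver_config())
  ws$phi <- rep(0.25, grid$n)
  ws$Ur <- hemoflow:::init_face_flux(grid, c(0.3, 0))
  hemoflow:::phi_transport(ws)
  expect_equal(ws$phi, rep(0.25, grid$n), tolerance = 1e-12)
})
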