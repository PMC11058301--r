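test_that("wall traction reduces to mu |du/dn| for analytic simple shear", {
  ## flat-wall channel grid with an imposed linear shear field
  geom <- stenosis_geometry(hs = 50e-6, mode = "planar")
  grid <- build_stenosis_grid(geom, nx = 20, ny = 8)
  gam <- 2000
  n <- grid$n
  st <- list(phi = rep(0, n),
             vp = cbind(gam * grid$yc, rep(0, n)),
             vr = cbind(rep(0, n), rep(0, n)),
             props = fluid_properties(), coeffs = rheology_coefficients())
  ## one-sided difference at the wall for u = gam*(y - H) + gam*H is exact:
  ## u_cell/dn = gam * yc / (H - yc)... the traction formula must equal
  ## mu * u_cell / dn for each wall face
  wp <- wall_shear_stress(st, grid)
  f <- grid$face; iw <- grid$wall$faces
  dn <- abs(f$ym[iw] - grid$yc[f$owner[iw]])
  exact <- st$props$plasma_viscosity * gam * grid$yc[f$owner[iw]] / dn
  expect_lt(max(abs(wp$tau_wss - exact) / exact), 1e-8)
  ## quiescent state: zero everywhere
  st0 <- st; st0$vp[] <- 0
  expect_equal(max(wall_shear_stress(st0, grid)$tau_wss), 0)
  ## x strictly increasing along the straight wall
  expect_true(all(diff(wp$x) > 0))
})

test_that("tube WSS matches the Poiseuille closed form within 3%", {
  ax <- poiseuille_fixture("axisymmetric")
  expect_equal(ax$wss / ax$wss_exact, 1, tolerance = 0.03)
})

test_that("section profiles honour boundaries; phi stays uniform in the
          tight-coupling limit", {
  ## drag-only straight tube: as the RBC size a shrinks, the drag coupling
  ## tightens (~1/a^2), the interphase slip vanishes and the uniform inlet
  ## hematocrit persists through the vessel
  geom <- stenosis_geometry(hs = 50e-6, L_up = 0.25e-3, L_down = 0.25e-3)
  grid <- build_stenosis_grid(geom, nx = 40, ny = 8)
  bc <- boundary_conditions(0.2, 0.2)
  res <- lapply(c(8e-6, 2e-6, 1e-6), function(a) {
    st <- suppressWarnings(steady_solve(
      grid, bc, props = fluid_properties(rbc_size_a = a),
      params = interaction_params(saffman = FALSE, spin = FALSE),
      config = solver_config(max_outer = 300, tol = 1e-7)))
    sp <- section_profile(st, grid, 0.1e-3)
    c(slip = max(abs(st$vr - st$vp)),
      dev = max(abs(sp$phi - 0.2)) / 0.2,
      mean_phi = mean(sp$phi))
  })
  slip <- vapply(res, `[`, numeric(1), "slip")
  dev <- vapply(res, `[`, numeric(1), "dev")
  expect_true(all(diff(slip) < 0))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 0.02)
  expect_equal(res[[3]][["mean_phi"]], 0.2, tolerance = 0.005)
  ## no-slip at the wall end of the sampling, on the full-physics case
  fx <- stenosis_fixture()
  sp0 <- section_profile(fx$state, fx$grid, 0)
  expect_equal(sp0$u_plasma[nrow(sp0)], 0)
  expect_equal(max(sp0$y), 25e-6, tolerance = 0.05)
  expect_error(section_profile(fx$state, fx$grid, 1), "domain")
})

test_that("throat velocity profile has a flat core plateau", {
  fx <- stenosis_fixture()
  spB <- section_profile(fx$state, fx$grid, 0)
  core <- spB$u_plasma[spB$y <= 0.5 * max(spB$y)]
  expect_lt((max(core) - min(core)) / max(core), 0.10)
})

test_that("conservative section fluxes are equal through every section", {
  fx <- stenosis_fixture()
  qA <- section_flux(fx$state, fx$grid, -30e-6)
  qB <- section_flux(fx$state, fx$grid, 0)
  qC <- section_flux(fx$state, fx$grid, 30e-6)
  mix <- c(qA[["mixture"]], qB[["mixture"]], qC[["mixture"]])
  expect_lt((max(mix) - min(mix)) / mix[1], 1e-6)
  ## and they match the imposed inlet flux Vt R^2 / 2 per radian
  expect_equal(mix[2], 0.2 * (50e-6)^2 / 2, tolerance = 1e-6)
})

test_that("recirculation detection is empty on unobstructed tube flow", {
  ax <- poiseuille_fixture("axisymmetric", 60, 8)
  rc <- recirculation_extent(ax$state, ax$grid)
  expect_true(is.na(rc[["x_sep"]]))
})

test_that("layer metrics are zero for uniform phi and pure functions", {
  fx <- stenosis_fixture()
  n <- fx$grid$n
  st_unif <- fx$state
  st_unif$phi <- rep(0.2, n)
  lm0 <- layer_metrics(st_unif, fx$grid)
  expect_equal(nrow(lm0$cell_free_components), 0)
  expect_equal(nrow(lm0$cell_rich_components), 0)
  expect_equal(max(lm0$cfl_thickness$thickness), 0)
  ## pure function of (state, grid): repeated calls identical
  l1 <- layer_metrics(fx$state, fx$grid)
  l2 <- layer_metrics(fx$state, fx$grid)
  expect_identical(l1, l2)
  w1 <- wall_shear_stress(fx$state, fx$grid)
  w2 <- wall_shear_stress(fx$state, fx$grid)
  expect_identical(w1, w2)
})

test_that("outputs round-trip: VTK bit-exact, CSV schema, summary keys", {
  fx <- stenosis_fixture()
  td <- withr::local_tempdir()
  files <- write_outputs(fx$state, fx$grid, td,
                         sections = c(-30e-6, 0, 30e-6), case = "test")
  vtk <- read_vtk_structured(file.path(td, "fields_block1.vtk"))
  blk <- fx$grid$blocks[[1]]
  expect_identical(vtk$dims[1:2], c(blk$nx + 1L, blk$ny + 1L))
  expect_identical(vtk$points[, 1], as.vector(blk$X))
  expect_identical(vtk$data$phi,
                   as.vector(hemoflow:::cells_to_nodes(fx$grid, 1,
                                                       fx$state$phi)))
  expect_identical(vtk$data$vp[, 1],
                   as.vector(hemoflow:::cells_to_nodes(fx$grid, 1,
                                                       fx$state$vp[, 1])))
  wp_csv <- utils::read.csv(file.path(td, "wall_profile.csv"))
  expect_identical(names(wp_csv), c("x", "y_wall", "tau_wss"))
  sec_csv <- utils::read.csv(file.path(td, "section_x_+0.0um.csv"))
  expect_identical(names(sec_csv), c("y", "phi", "u_plasma", "u_rbc"))
  summ <- yaml::read_yaml(file.path(td, "summary.yaml"))
  expect_setequal(names(summ), hemoflow:::SUMMARY_KEYS)
})

test_that("tidy, glance and autoplot methods work on solver results", {
  fx <- stenosis_fixture()
  td <- tidy(fx$state, fx$grid)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), fx$grid$n)
  expect_named(td, c("x", "y", "phi", "p", "u_plasma", "v_plasma",
                     "u_rbc", "v_rbc"))
  gl <- glance(fx$state)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  wp <- wall_shear_stress(fx$state, fx$grid)
  expect_s3_class(autoplot(wp), "ggplot")
  sp <- section_profile(fx$state, fx$grid, 0)
  expect_s3_class(autoplot(sp), "ggplot")
  expect_s3_class(autoplot(sp, "velocity"), "ggplot")
})

test_that("profile-integrated section fluxes agree within the desk-scale
          reconstruction bound", {
  ## integrating the interpolated cell-centered profiles carries a few
  ## percent of cell-to-face reconstruction error at the throat; the
  ## conservative face fluxes (section_flux) are exact. Documented bound: 5%.
  fx <- stenosis_fixture()
  mixflux <- function(x) {
    sp <- section_profile(fx$state, fx$grid, x, n_sample = 400)
    u <- sp$u_plasma * (1 - sp$phi) + sp$u_rbc * sp$phi
    trapz(sp$y, u * sp$y)
  }
  q <- vapply(c(-30e-6, 0, 30e-6), mixflux, numeric(1))
  expect_lt((max(q) - min(q)) / abs(q[1]), 0.05)
  ## and each is within 5% of the exact imposed inlet flux
  expect_equal(q / (0.2 * (50e-6)^2 / 2), rep(1, 3), tolerance = 0.05)
})
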