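test_that("stenosis wall profile hits throat, shoulders and quarter point", {
  geom <- stenosis_geometry(H = 50e-6, hs = 25e-6, Ls = 70e-6)
  expect_equal(stenosis_wall_radius(0, geom), 25e-6)
  expect_equal(stenosis_wall_radius(geom$Ls / 2, geom), 50e-6)
  expect_equal(stenosis_wall_radius(-geom$Ls / 2, geom), 50e-6)
  expect_equal(stenosis_wall_radius(geom$Ls / 4, geom), 37.5e-6)
  ## continuous at the shoulder and flat outside
  eps <- 1e-12
  expect_equal(stenosis_wall_radius(geom$Ls / 2 + 1e-6, geom), geom$H)
  expect_lt(abs(stenosis_wall_radius(geom$Ls / 2 - eps, geom) - geom$H),
            1e-9 * geom$H)
  expect_error(stenosis_wall_radius(1, geom), "domain")
})

test_that("dimensionless ratios match the study geometry", {
  geom <- stenosis_geometry(H = 50e-6, hs = 25e-6, Ls = 70e-6)
  r <- dimensionless_ratios(geom)
  expect_equal(r[["eta_h"]], 0.5)
  expect_equal(r[["eta_L"]], 1.4)
  ## no stenosis limit
  r0 <- dimensionless_ratios(stenosis_geometry(hs = 50e-6))
  expect_equal(r0[["eta_h"]], 1)
})

test_that("geometry constructors validate their inputs", {
  expect_error(stenosis_geometry(hs = 60e-6), "hs")
  expect_error(stenosis_geometry(hs = 0), "hs")
  expect_error(expansion_geometry(h_down = 40e-6), "h_down")
  ## defaults encode the benchmark dimensions
  ge <- expansion_geometry()
  expect_equal(ge$L_up + ge$L_down, 3e-3)
  expect_equal(ge$h_down / ge$h_up, 2)
})

test_that("stenosis grid has expected counts, positive volumes, closure", {
  geom <- stenosis_geometry()
  g <- build_stenosis_grid(geom, nx = 8, ny = 4)
  expect_equal(g$n, 32)
  expect_equal(dim(g$blocks[[1]]$X), c(9, 5))
  expect_true(all(g$vol > 0))
  expect_lt(grid_closure_residual(g), 1e-12)
  ## boundary tags partition the boundary
  tags <- g$face$tag[!g$face$interior]
  expect_setequal(unique(tags), c("inlet", "outlet", "wall", "symmetry"))
  expect_equal(length(tags), 2 * 8 + 2 * 4)
})

test_that("uniform-channel limits: areas and axisymmetric volume are exact", {
  ## planar, no stenosis: rectangular grid, analytic total area
  geom <- stenosis_geometry(hs = 50e-6, mode = "planar")
  g <- build_stenosis_grid(geom, nx = 10, ny = 5)
  expect_equal(sum(g$vol), (geom$L_up + geom$L_down) * geom$H,
               tolerance = 1e-12)
  expect_equal(max(g$vol) / min(g$vol), 1, tolerance = 1e-9)
  ## axisymmetric: per-radian volume R^2 L / 2
  geom2 <- stenosis_geometry(hs = 50e-6, mode = "axisymmetric")
  g2 <- build_stenosis_grid(geom2, nx = 10, ny = 5)
  expect_equal(sum(g2$vol),
               geom2$H^2 * (geom2$L_up + geom2$L_down) / 2,
               tolerance = 1e-10)
  expect_lt(grid_closure_residual(g2), 1e-12)
})

test_that("wall faces track the cosine profile at increasing order", {
  ## short entry/exit lengths so the refinement acts on the cosine segment
  geom <- stenosis_geometry(L_up = 100e-6, L_down = 100e-6)
  err <- vapply(c(40, 80, 160), function(nx) {
    g <- build_stenosis_grid(geom, nx = nx, ny = 4)
    iw <- g$wall$faces
    xm <- g$face$xm[iw]
    keep <- abs(xm) < geom$Ls / 2
    max(abs(g$face$ym[iw][keep] - stenosis_wall_radius(xm[keep], geom)))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  ## observed order >= 2 on the cosine segment
  order_obs <- log2(err[1] / err[3]) / 2
  expect_gte(order_obs, 1.9)
})

test_that("expansion grid blocks conform and tags are consistent", {
  geom <- expansion_geometry()
  g <- build_expansion_grid(geom, nx_up = 8, ny_up = 4, nx_down = 10)
  ## cell count nx_up*ny_up + nx_down*ny_down
  expect_equal(g$n, 8 * 4 + 10 * 8)
  expect_true(all(g$vol > 0))
  expect_lt(grid_closure_residual(g), 1e-12)
  ## the step face at x = 0 is a wall
  stepf <- which(g$face$tag == "wall" & abs(g$face$xm) < 1e-12)
  expect_equal(length(stepf), 4)
  expect_true(all(g$face$ym[stepf] > geom$h_up - 1e-12))
  ## non-conforming resolutions are rejected
  expect_error(build_expansion_grid(geom, nx_up = 8, ny_up = 4,
                                    ny_down = 9), "conforming")
})

test_that("grid stretching keeps volumes positive and clusters wallward", {
  geom <- stenosis_geometry()
  g <- build_stenosis_grid(geom, nx = 30, ny = 10, cluster_wall = 1.5,
                           cluster_throat = 3)
  expect_true(all(g$vol > 0))
  expect_lt(grid_closure_residual(g), 1e-12)
  ## wall-adjacent spacing finer than axis-adjacent spacing
  Y <- g$blocks[[1]]$Y
  expect_lt(Y[1, ncol(Y)] - Y[1, ncol(Y) - 1], Y[1, 2] - Y[1, 1])
  ## throat columns tighter than far-field columns
  X <- g$blocks[[1]]$X[, 1]
  dx <- diff(X)
  expect_lt(dx[which.min(abs(X[-1]))], max(dx) / 2)
})
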