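pr <- fluid_properties()
ip <- interaction_params()

test_that("hindrance function matches hand values", {
  expect_equal(hindrance(0), 0)
  expect_equal(hindrance(0.2), 0.462)
  expect_equal(hindrance(0.4), 1.448)
  expect_error(hindrance(1.5), "phi")
})

test_that("drag force matches the hand-evaluated magnitude and is linear", {
  z <- matrix(c(0, 0), 1)
  slip <- matrix(c(0.01, 0), 1)
  expect_equal(drag_force(0.2, slip, slip, pr), cbind(0, 0))
  f <- drag_force(0.2, z, slip, pr)
  expect_equal(f[1], 3.1185e5, tolerance = 1e-10)
  expect_equal(f[2], 0)
  ## linear in slip
  expect_equal(drag_force(0.2, z, 2 * slip, pr), 2 * f)
  ## Galilean invariance
  shift <- matrix(c(5, -3), 1)
  expect_equal(drag_force(0.2, z + shift, slip + shift, pr), f)
})

test_that("Saffman lift matches the frozen scalar oracle and regularizes", {
  slip <- matrix(c(0.01, 0), 1)
  z <- matrix(c(0, 0), 1)
  D <- tensor_field(0, 50, 0)          # simple shear 100/s
  ## frozen from an independent scalar evaluation of the printed formula:
  ## (3*6.46*sqrt(rho mu)/(4 pi a)) * phi * gd^(-1/2) * D.slip
  f <- saffman_lift(0.2, D, z, slip, pr, ip)
  expect_equal(f[1], 0)
  expect_equal(f[2], 1914.1446, tolerance = 1e-7)
  ## zero slip and zero strain both kill the force
  expect_equal(saffman_lift(0.2, D, slip, slip, pr, ip), cbind(0, 0))
  expect_equal(saffman_lift(0.2, tensor_field(0, 0, 0), z, slip, pr, ip),
               cbind(0, 0))
  ## continuity across the shear floor
  eps <- 1e-13
  Dlo <- tensor_field(0, (ip$shear_floor - eps) / 2, 0)
  Dhi <- tensor_field(0, (ip$shear_floor + eps) / 2, 0)
  flo <- saffman_lift(0.2, Dlo, z, slip, pr, ip)
  fhi <- saffman_lift(0.2, Dhi, z, slip, pr, ip)
  expect_lt(abs(fhi[2] - flo[2]) / abs(fhi[2]), 1e-9)
})

test_that("spin lift is transverse to the slip and matches hand value", {
  slip <- matrix(c(0.01, 0), 1)
  z <- matrix(c(0, 0), 1)
  W0 <- tensor_field(0, 0, 0)
  Wd <- tensor_field(0, 50, yx = -50, 0)   # spin difference 50/s
  expect_equal(spin_lift(0.2, Wd, Wd, z, slip, pr, ip), cbind(0, 0))
  expect_equal(spin_lift(0.2, W0, Wd, slip, slip, pr, ip), cbind(0, 0))
  f <- spin_lift(0.2, W0, Wd, z, slip, pr, ip)
  ## (3/4) * 1027 * 0.2 * 50 * 0.01 transverse to slip
  expect_equal(f[1], 0)
  expect_equal(abs(f[2]), 77.025, tolerance = 1e-12)
  ## orthogonality for arbitrary slip
  slip2 <- matrix(c(0.3, -0.2), 1)
  f2 <- spin_lift(0.3, W0, Wd, z, slip2, pr, ip)
  expect_equal(sum(f2 * slip2), 0)
  ## non-antisymmetric input is a contract violation
  expect_error(spin_lift(0.2, tensor_field(1, 2, 3), W0, z, slip, pr, ip),
               "antisymmetric")
})

test_that("total interaction sums enabled terms and closes pairwise", {
  n <- 20
  set.seed(42)
  st <- list(phi = runif(n, 0.05, 0.5),
             vp = cbind(runif(n), runif(n)),
             vr = cbind(runif(n), runif(n)))
  om <- runif(n, -20, 20)
  tens <- list(Dp = tensor_field(runif(n), runif(n), runif(n)),
               Dr = tensor_field(0, 0, 0),
               Wp = tensor_field(0, om, yx = -om, 0),
               Wr = tensor_field(0, 0, 0))
  off <- interaction_params(drag = FALSE, saffman = FALSE, spin = FALSE)
  expect_equal(total_interaction(st, tens, pr, off), matrix(0, n, 2))
  only_drag <- interaction_params(saffman = FALSE, spin = FALSE)
  expect_equal(total_interaction(st, tens, pr, only_drag),
               drag_force(st$phi, st$vp, st$vr, pr))
  fI <- total_interaction(st, tens, pr, ip)
  ## plasma gain + RBC loss = 0 cell-wise by the sign contract
  expect_equal(fI + (-fI), matrix(0, n, 2))
  ## Galilean invariance of the full sum
  st2 <- st; st2$vp <- st$vp + 1.7; st2$vr <- st$vr + 1.7
  expect_equal(total_interaction(st2, tens, pr, ip), fI, tolerance = 1e-12)
})

test_that("drag per unit volume approaches the dilute Stokes limit", {
  slip <- matrix(c(0.01, 0), 1)
  z <- matrix(c(0, 0), 1)
  K0 <- 9 * pr$plasma_viscosity / (2 * pr$rbc_size_a^2)
  for (ph in c(1e-4, 1e-3, 1e-2)) {
    f <- drag_force(ph, z, slip, pr)
    ratio <- f[1] / (ph * K0 * 0.01)
    expect_equal(ratio, 1, tolerance = 7 * ph)
  }
})
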