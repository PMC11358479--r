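test_that("parameter construction validates values and stability", {
  p <- dispersal_params()
  expect_equal(p$rho_c_max, 5)
  expect_equal(p$dt_yr, 10 / 365.25)
  expect_equal(dispersal_params(V = 10, G = 0.05, tau = 10)$alpha,
               10 / (0.05 * 10))
  expect_error(dispersal_params(gamma = -1), "positive")
  expect_error(dispersal_params(eta = 0.8), "eta")
  # diffusive bound violated on a fine grid with a long step
  g_fine <- build_grid(c(0, 1), c(0, 1), 0.05)
  expect_error(dispersal_params(dt_days = 100, grid = g_fine), "stability")
  expect_s3_class(dispersal_params(grid = flat_grid()), "pd_params")
})

test_that("Gaussian seeding hits the requested total and stays on land", {
  g <- build_grid(c(30, 40), c(28, 36), 0.5)
  land <- all_land(g)
  land[, 1:2] <- FALSE
  st <- init_population(g, land, center = c(35, 32.5), spread_km = 150,
                        total_population = 5000)
  expect_lt(abs(total_population(st$rho, g) - 5000), 1)
  expect_true(all(st$rho[!land] == 0))
  expect_true(all(st$vx == 0))

  st0 <- init_population(g, land, center = c(35, 32.5),
                         total_population = 0)
  expect_true(all(st0$rho == 0))

  st2 <- init_population(g, land, center = c(35, 32.5),
                         total_population = 10000)
  expect_equal(st2$rho, 2 * st$rho)   # linear in the total

  expect_error(init_population(g, land, center = c(35, 28.25)), "water")
  expect_error(init_population(g, land, center = c(0, 0)), "outside")
})

test_that("drift velocity follows the damped forced solution", {
  g <- flat_grid(4, 2, 0.5)
  p <- dispersal_params()
  zero <- list(u = matrix(0, g$nlon, g$nlat), v = matrix(0, g$nlon, g$nlat))

  # free decay: v(t) = v0 exp(-gamma t)
  st <- make_state(matrix(1, g$nlon, g$nlat))
  st$vx[] <- 3
  for (k in 1:50) st <- update_velocity(st, zero, p, dt_yr = 0.1)
  expect_equal(st$vx[1, 1], 3 * exp(-p$gamma * 5), tolerance = 1e-12)

  # constant forcing: fixed point alpha grad / gamma
  gr <- list(u = matrix(0.02, g$nlon, g$nlat), v = zero$v)
  st2 <- make_state(matrix(1, g$nlon, g$nlat))
  for (k in 1:4000) st2 <- update_velocity(st2, gr, p, dt_yr = 0.5)
  expect_equal(st2$vx[1, 1], p$alpha * 0.02 / p$gamma, tolerance = 1e-8)

  # alpha = 0 and v0 = 0 stays zero
  p0 <- dispersal_params(alpha = 1e-300)
  st3 <- update_velocity(make_state(matrix(1, g$nlon, g$nlat)), gr, p0)
  expect_lt(max(abs(st3$vx)), 1e-290)
})

test_that("diffusivity scales with speed and grid size and is clipped", {
  # equator grid with sqrt(dx dy) close to 50 km
  g <- build_grid(c(0, 0.9), c(-0.45, 0.45), 0.45)
  p <- dispersal_params(d_min = 1e-6, d_max = 1e6)
  st <- make_state(matrix(0, g$nlon, g$nlat))
  st$vx[] <- 20
  expect_equal(diffusivity(st, g, p)[1, 1], 100, tolerance = 0.01)

  pd <- dispersal_params()        # default bounds 10-100
  st0 <- make_state(matrix(0, g$nlon, g$nlat))
  expect_true(all(diffusivity(st0, g, pd) == 10))     # v = 0 floors at d_min
  st$vx[] <- 1e5
  expect_true(all(diffusivity(st, g, pd) == 100))     # capped at d_max
})

test_that("the transport step is conservative, positive and inert at zero", {
  g <- flat_grid(8, 4, 0.5)
  land <- all_land(g)
  p <- dispersal_params()
  set.seed(3)
  rho0 <- matrix(runif(g$nlon * g$nlat), g$nlon, g$nlat)

  # v = 0, D = 0: bitwise unchanged
  st <- make_state(rho0)
  expect_identical(advect_diffuse(st, 0, g, land, p)$rho, rho0)

  # closed basin, rotating drift + diffusion, 1000 steps: mass conserved
  xy <- grid_xy_km(g)
  st2 <- make_state(rho0)
  st2$vx <- -xy$y / 100
  st2$vy <- xy$x / 100
  lam0 <- total_population(st2$rho, g)
  for (k in 1:1000) st2 <- advect_diffuse(st2, 30, g, land, p)
  expect_lt(abs(total_population(st2$rho, g) - lam0) / lam0, 1e-6)
  expect_gte(min(st2$rho), 0)

  # water cells hold zero density throughout
  land2 <- land; land2[4, ] <- FALSE
  st3 <- make_state(rho0 * matrix(land2, g$nlon, g$nlat))
  for (k in 1:50) st3 <- advect_diffuse(st3, 30, g, land2, p)
  expect_true(all(st3$rho[!land2] == 0))
})

test_that("stability violations abort with the offending cell", {
  g <- flat_grid(4, 2, 0.5)
  land <- all_land(g)
  p <- dispersal_params()
  st <- make_state(matrix(1, g$nlon, g$nlat))
  st$vx[2, 1] <- 1e6
  expect_error(advect_diffuse(st, 10, g, land, p), "cell \\(2, 1\\)")
  st$vx[2, 1] <- 0
  expect_error(advect_diffuse(st, 1e9, g, land, p), "diffusive stability")
})

test_that("free diffusion spreads a Gaussian with variance growth 2Dt", {
  g <- build_grid(c(0, 15), c(-3, 3), 0.25)
  land <- all_land(g)
  xy <- grid_xy_km(g)
  rho <- exp(-(xy$x^2 + xy$y^2) / (2 * 60^2))
  st <- make_state(rho)
  p <- dispersal_params()
  D <- 50
  n <- round(40 / p$dt_yr)
  m2 <- function(r) {
    w <- r * g$area
    c(sum(w * xy$x^2), sum(w * xy$y^2)) / sum(w)
  }
  v0 <- m2(st$rho)
  for (k in seq_len(n)) st <- advect_diffuse(st, D, g, land, p)
  growth <- m2(st$rho) - v0
  expect_equal(growth[1], 2 * D * n * p$dt_yr, tolerance = 0.02)
  expect_equal(growth[2], 2 * D * n * p$dt_yr, tolerance = 0.02)
})

test_that("the growth step solves the logistic exactly", {
  g <- flat_grid(2, 2, 1)
  p <- dispersal_params()
  rho_c <- matrix(2.5, g$nlon, g$nlat)
  phi_av <- matrix(1.2, g$nlon, g$nlat)
  r <- p$r_max * 1.2 / p$rho_c_max

  # at carrying capacity: unchanged
  st <- make_state(rho_c)
  expect_equal(grow_population(st, rho_c, phi_av, p)$rho, rho_c)

  # trajectory matches the closed form to 1e-12 relative
  st <- make_state(matrix(0.25, g$nlon, g$nlat))
  for (k in 1:500) st <- grow_population(st, rho_c, phi_av, p)
  tt <- 500 * p$dt_yr
  exact <- 2.5 * 0.25 * exp(r * tt) / (2.5 + 0.25 * (exp(r * tt) - 1))
  expect_lt(abs(st$rho[1, 1] - exact) / exact, 1e-12)

  # above capacity the density relaxes downward
  st <- make_state(matrix(4, g$nlon, g$nlat))
  new <- grow_population(st, rho_c, phi_av, p)$rho[1, 1]
  expect_lt(new, 4)
  expect_gt(new, 2.5)

  # uninhabitable cells decay toward zero
  st <- make_state(matrix(1, g$nlon, g$nlat))
  zero <- matrix(0, g$nlon, g$nlat)
  out <- grow_population(st, zero, zero, p)$rho[1, 1]
  expect_equal(out, exp(-p$r_max * p$dt_yr), tolerance = 1e-12)
})

test_that("runs decay under zero HEP and grow toward the habitable ceiling", {
  w0 <- uniform_world(phi = 0)
  run0 <- run_dispersal(w0$grid, w0$land, w0$stack, w0$iso,
                        dispersal_params(),
                        start_ka = 45, end_ka = 44.8,
                        init = list(center = c(4, 33), spread_km = 100,
                                    total_population = 1000))
  expect_true(all(diff(run0$lambda) <= 0))
  expect_lt(run0$lambda[length(run0$lambda)], 250)

  w1 <- uniform_world(phi = 0.8)
  run1 <- run_dispersal(w1$grid, w1$land, w1$stack, w1$iso,
                        dispersal_params(),
                        start_ka = 45, end_ka = 44.2,
                        init = list(center = c(4, 33), spread_km = 100,
                                    total_population = 1000))
  ceiling_persons <- total_population(matrix(0.8 * 5, w1$grid$nlon,
                                             w1$grid$nlat), w1$grid)
  expect_true(all(diff(run1$lambda) >= -1e-6))
  expect_lt(max(run1$lambda), ceiling_persons)
  expect_gt(max(run1$lambda) / run1$lambda[1], 2)
})

test_that("scaling accessible HEP up never lowers the attained population", {
  base <- uniform_world(phi = 0.6)
  up <- uniform_world(phi = 0.6 * 1.1)
  args <- list(params = dispersal_params(), start_ka = 45, end_ka = 44.5,
               init = list(center = c(4, 33), spread_km = 100,
                           total_population = 1000))
  r1 <- do.call(run_dispersal, c(list(base$grid, base$land, base$stack,
                                      base$iso), args))
  r2 <- do.call(run_dispersal, c(list(up$grid, up$land, up$stack, up$iso),
                                 args))
  expect_gte(r2$lambda[length(r2$lambda)], r1$lambda[length(r1$lambda)])
})

test_that("identical configurations give bit-identical runs", {
  w <- uniform_world(phi = 0.7)
  go <- function() run_dispersal(w$grid, w$land, w$stack, w$iso,
                                 dispersal_params(),
                                 start_ka = 45, end_ka = 44.9,
                                 init = list(center = c(4, 33),
                                             spread_km = 100,
                                             total_population = 800))
  r1 <- go(); r2 <- go()
  expect_identical(r1$lambda, r2$lambda)
  expect_identical(r1$snapshots, r2$snapshots)
  expect_identical(r1$arrival, r2$arrival)
})
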