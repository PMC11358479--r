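test_that("total population integrates density over spherical cell areas", {
  g <- build_grid(c(0, 10), c(10, 20), 0.5)
  expect_equal(total_population(matrix(0, g$nlon, g$nlat), g), 0)
  # uniform 1 P 100 km^-2: Lambda = box area / 100 (in km^2)
  box_km2 <- spherical_box_area(0, 10, 10, 20) / 1e6
  expect_equal(total_population(matrix(1, g$nlon, g$nlat), g), box_km2 / 100,
               tolerance = 1e-12)
})

test_that("population flux combines drift and down-gradient diffusion", {
  g <- flat_grid(8, 4, 0.5)
  land <- all_land(g)
  u0 <- matrix(0, g$nlon, g$nlat)

  # uniform density, no drift: zero flux
  f0 <- population_flux(matrix(2, g$nlon, g$nlat), u0, u0, 30, g, land)
  expect_true(all(f0$u == 0) && all(f0$v == 0))

  # uniform density with drift: f = v rho (per decade: x10, per 100 km2: /100)
  f1 <- population_flux(matrix(2, g$nlon, g$nlat), u0 + 3, u0, 30, g, land)
  expect_equal(f1$u[2, 2], 3 * 2 / 100 * 10)
  f1y <- population_flux(matrix(2, g$nlon, g$nlat), u0 + 3, u0, 30, g, land,
                         per_decade = FALSE)
  expect_equal(f1$u, 10 * f1y$u)           # decade conversion is exactly 10

  # density decreasing eastward, no drift: zonal flux positive (down-gradient)
  xy <- grid_xy_km(g)
  rho <- 5 - 0.002 * xy$x
  f2 <- population_flux(rho, u0, u0, 30, g, land)
  expect_true(all(f2$u > 0))
})

test_that("the mobility index sums flux magnitudes and ignores direction", {
  g <- flat_grid(4, 2, 0.5)
  u <- matrix(0, g$nlon, g$nlat)
  v <- matrix(0, g$nlon, g$nlat)
  expect_equal(mobility_index(vfield(g, u, v)), 0)
  u[3, 1] <- 2
  expect_equal(mobility_index(vfield(g, u, v)), 2)
  expect_equal(mobility_index(vfield(g, -u, -v)), 2)
})

test_that("snapshot series reproduce the in-run population and mobility", {
  w <- uniform_world(phi = 0.7)
  run <- run_dispersal(w$grid, w$land, w$stack, w$iso, dispersal_params(),
                       start_ka = 45, end_ka = 44.9,
                       init = list(center = c(4, 33), spread_km = 100,
                                   total_population = 1000))
  for (k in c(1, 5, length(run$times_ka))) {
    expect_identical(total_population(run$snapshots[[k]], run$grid),
                     run$lambda[k])
    vs <- run$v_snapshots[[k]]
    fl <- population_flux(run$snapshots[[k]], vs$vx, vs$vy, vs$d, run$grid,
                          run$land, per_decade = FALSE)
    expect_identical(mobility_index(fl), run$mobility[k])
  }
})

test_that("arrival maps record first threshold crossings at snapshot times", {
  w <- uniform_world(phi = 0.8)
  run <- run_dispersal(w$grid, w$land, w$stack, w$iso, dispersal_params(),
                       start_ka = 45, end_ka = 44.5,
                       init = list(center = c(4, 33), spread_km = 60,
                                   total_population = 1500))
  arr <- arrival_time_map(run)
  expect_true(any(!is.na(arr$values)))

  # monotone in threshold: a higher threshold is reached later or never
  arr_hi <- arrival_time_map(run, threshold = 1.2)
  both <- !is.na(arr$values) & !is.na(arr_hi$values)
  expect_true(all(arr_hi$values[both] <= arr$values[both]))
  expect_true(all(is.na(arr_hi$values[is.na(arr$values)])))

  # never-reached cells are NA; a cell crossing between snapshots gets the
  # time of the snapshot that first sees it
  k <- which(vapply(run$snapshots, function(s) s[5, 5] >= 0.4, logical(1)))
  if (length(k) > 0) expect_equal(arr$values[5, 5], run$times_ka[min(k)])

  # matches the run's online arrival bookkeeping
  expect_identical(arr$values[!is.na(arr$values)],
                   run$arrival[!is.na(run$arrival)])
})

test_that("occupation regions nest and the boundary follows the level set", {
  g <- flat_grid(6, 4, 0.5)
  land <- all_land(g)
  expect_equal(nrow(occupation_contour(matrix(0, g$nlon, g$nlat), g)$cells), 0)

  oc_all <- occupation_contour(matrix(2, g$nlon, g$nlat), g, level = 1,
                               land = land)
  expect_equal(nrow(oc_all$cells), g$nlon * g$nlat)

  xy <- grid_xy_km(g)
  rho <- 3 * exp(-(xy$x^2 + xy$y^2) / (2 * 80^2))
  oc1 <- occupation_contour(rho, g, level = 1)
  oc2 <- occupation_contour(rho, g, level = 2)
  key <- function(oc) paste(oc$cells$i, oc$cells$j)
  expect_true(all(key(oc2) %in% key(oc1)))        # nested level sets
  expect_gt(nrow(oc1$boundary), 0)
  # scaling the field down never grows the occupied region
  oc_half <- occupation_contour(rho * 0.5, g, level = 1)
  expect_true(all(key(oc_half) %in% key(oc1)))
})

test_that("chronology comparison aggregates ensemble arrivals per site", {
  g <- build_grid(c(0, 4), c(40, 42), 0.5)
  land <- all_land(g)
  mk <- function(t1) {
    m <- matrix(NA_real_, g$nlon, g$nlat)
    m[2, 2] <- t1
    m[3, 2] <- 42
    f <- field(g, ifelse(is.na(m), 0, m), "ka", mask = !is.na(m))
    f$values[is.na(m)] <- NA_real_
    f
  }
  sites <- tibble::tibble(site = c("a", "b", "c"),
                          lon = c(0.75, 1.25, 3.75),
                          lat = c(40.75, 40.75, 41.75),
                          dated_ka = c(43.5, 42.2, 41.0))

  one <- compare_chronology(mk(43), sites)
  expect_equal(one$model_sd_ka[1], 0)               # single member
  expect_false(one$reached[3])                      # never-reached site

  two <- compare_chronology(list(mk(43), mk(44)), sites)
  expect_equal(two$model_mean_ka[1], 43.5)
  expect_equal(two$model_sd_ka[1], 0.5)             # population convention
  expect_equal(two$n_members[1], 2)

  expect_error(compare_chronology(mk(43),
                                  tibble::tibble(site = "x", lon = 99,
                                                 lat = 0)),
               "outside")
})
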