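# Shared fixtures: all built in code, nothing read from disk.

# near-equator grid where the spherical metric is effectively flat
flat_grid <- function(lon_span = 10, lat_span = 5, res = 0.5) {
  build_grid(c(0, lon_span), c(-lat_span / 2, lat_span / 2), res)
}

all_land <- function(grid) matrix(TRUE, grid$nlon, grid$nlat)

# bare population state around a given density matrix
make_state <- function(rho) {
  z <- matrix(0, nrow(rho), ncol(rho))
  structure(list(rho = rho, vx = z, vy = z, time_ka = NA_real_),
            class = "pd_state")
}

# km offsets of cell centers from the domain center (flat-metric reading)
grid_xy_km <- function(grid) {
  deg2km <- grid$earth_radius * pi / 180
  list(x = outer((grid$lon - mean(grid$lon)) * deg2km, rep(1, grid$nlat)),
       y = outer(rep(1, grid$nlon), (grid$lat - mean(grid$lat)) * deg2km))
}

# predictor set over abstract cells with N(0,1) standardized predictors
gaussian_predictors <- function(n, seed) {
  set.seed(seed)
  d <- tibble::tibble(i = 1L, j = 1L, cell = seq_len(n), lon = 0, lat = 0)
  for (v in pd_bioclim_vars) {
    d[[v]] <- rnorm(n)
    d[[paste0("z_", v)]] <- d[[v]]
  }
  structure(list(data = d,
                 stats = tibble::tibble(var = pd_bioclim_vars,
                                        center = 0, scale = 1),
                 vars = pd_bioclim_vars),
            class = "pd_predictors")
}

# default synthetic study inputs, built once and reused read-only
scenario_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- synthetic_scenario()
      cache <<- list(sc = sc,
                     inp = build_synthetic_inputs(sc, iso_start_ka = 45,
                                                  iso_end_ka = 42.9))
    }
    cache
  }
})

# small favourable world for fast solver runs: uniform accessible HEP
uniform_world <- function(phi = 0.8, nlon = 16, nlat = 12, res = 0.5) {
  g <- build_grid(c(0, nlon * res), c(30, 30 + nlat * res), res)
  land <- all_land(g)
  f <- field(g, phi, "1", mask = land)
  stack <- hep_stack(f, f)
  iso <- normalize_isotope(synth_isotope(50, 20, period_yr = 1000,
                                         shape = "square"))
  list(grid = g, land = land, stack = stack, iso = iso)
}
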