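#' Construct a niche model from known coefficients
#'
#' Builds a `pd_niche` object directly from a symmetric quadratic matrix
#' `A`, linear coefficients `B` and intercept `C` over standardized
#' predictors -- used for truth models in simulation studies and for models
#' restored from disk.
#'
#' @param A symmetric numeric matrix (p x p).
#' @param B numeric vector (length p).
#' @param C scalar intercept.
#' @param stats standardization statistics tibble (var/center/scale), or
#'   `NULL` for identity.
#' @param vars predictor names (default [pd_bioclim_vars]).
#' @return A `pd_niche`.
#' @export
niche_model <- function(A, B, C, stats = NULL, vars = pd_bioclim_vars) {
  p <- length(vars)
  stopifnot(all(dim(A) == c(p, p)), length(B) == p, length(C) == 1)
  if (max(abs(A - t(A))) > 1e-12) stop("A must be symmetric", call. = FALSE)
  if (any(!is.finite(A)) || any(!is.finite(B)) || !is.finite(C))
    stop("coefficients must be finite", call. = FALSE)
  theta <- c(C, B)
  nm <- c("C", vars)
  for (i in seq_len(p)) for (j in i:p) {
    theta <- c(theta, A[i, j])
    nm <- c(nm, paste0("A_", i, "_", j))
  }
  stats <- stats %||% tibble::tibble(var = vars, center = 0, scale = 1)
  structure(list(A = A, B = stats::setNames(B, vars), C = C,
                 vcov = matrix(NA_real_, length(theta), length(theta)),
                 theta = theta, feature_names = nm, vars = vars,
                 stats = stats, n = 0L, iterations = 0L, ridge = 0,
                 z_range = matrix(c(-Inf, Inf), 2, p,
                                  dimnames = list(NULL, vars))),
            class = "pd_niche")
}

#' Synthetic-study scenario
#'
#' Defines the study conditions for a fully synthetic pipeline: a regular
#' grid, a known truth niche model over standardized bioclim predictors,
#' smooth climate fields with a stadial/interstadial contrast, Bernoulli
#' site sampling from the truth suitability, a periodic isotope series, and
#' simple ridge topography with an ocean margin. Identical seeds give
#' identical outputs throughout.
#'
#' Defaults describe a 40 x 30 cell mid-latitude domain at 0.5 degrees with
#' an interstadial-to-stadial annual-temperature contrast of 6 degC
#' (typical of millennial-scale stadial cooling in mid-latitude Europe),
#' increased seasonality and reduced wettest-month precipitation in
#' stadials, and about 150 sampled sites.
#'
#' @param lon_range,lat_range,resolution grid specification (defaults
#'   0--20 degE, 30--45 degN, 0.5 deg: 40 x 30 cells).
#' @param truth a `pd_niche` truth model on standardized predictors, or
#'   `NULL` for the built-in default (strong linear effects, concave
#'   quadratic).
#' @param gs_offset named list of stadial offsets added to the interstadial
#'   fields (defaults bio1 -6 degC, bio4 +2 degC, bio13 -20 mm, bio15 +5).
#' @param noise_amp named list of Gaussian-random-field noise amplitudes per
#'   predictor (defaults bio1 0.8, bio4 0.4, bio13 6, bio15 1.5; set to 0
#'   for noise-free fields).
#' @param n_sites target number of sampled sites (default 150).
#' @param iso_period_yr,iso_shape isotope forcing period and shape
#'   (defaults 1000 years, "square").
#' @param ridges list of ridge definitions for [synth_topography()]
#'   (default none).
#' @param ocean_margin width of the masked ocean rim, cells (default 1).
#' @param seed integer master seed (default 1).
#' @return An object of class `pd_scenario` (a named list).
#' @export
synthetic_scenario <- function(lon_range = c(0, 20), lat_range = c(30, 45),
                               resolution = 0.5, truth = NULL,
                               gs_offset = list(bio1 = -6, bio4 = 2,
                                                bio13 = -20, bio15 = 5),
                               noise_amp = list(bio1 = 0.8, bio4 = 0.4,
                                                bio13 = 6, bio15 = 1.5),
                               n_sites = 150,
                               iso_period_yr = 1000, iso_shape = "square",
                               ridges = list(), ocean_margin = 1,
                               seed = 1L) {
  truth <- truth %||% niche_model(
    A = diag(c(-0.8, -0.3, -0.5, -0.2)),
    B = c(2.2, -1.2, 1.4, -1.0),
    C = -0.5)
  structure(list(lon_range = lon_range, lat_range = lat_range,
                 resolution = resolution, truth = truth,
                 gs_offset = gs_offset, noise_amp = noise_amp,
                 n_sites = n_sites, iso_period_yr = iso_period_yr,
                 iso_shape = iso_shape, ridges = ridges,
                 ocean_margin = ocean_margin, seed = as.integer(seed)),
            class = "pd_scenario")
}

# smooth Gaussian random field: seeded white noise blurred with a separable
# Gaussian kernel and rescaled to unit standard deviation
smooth_noise <- function(nlon, nlat, smooth_cells = 4) {
  z <- matrix(stats::rnorm(nlon * nlat), nlon, nlat)
  half <- max(1L, ceiling(2 * smooth_cells))
  k <- stats::dnorm(seq(-half, half), sd = smooth_cells)
  k <- k / sum(k)
  pad_conv <- function(m, along) {
    if (along == 2) m <- t(m)
    n <- nrow(m)
    idx <- pmin(pmax(outer(seq_len(n), seq(-half, half), `+`), 1L), n)
    out <- matrix(0, n, ncol(m))
    for (u in seq_along(k)) out <- out + k[u] * m[idx[, u], , drop = FALSE]
    if (along == 2) t(out) else out
  }
  z <- pad_conv(pad_conv(z, 1), 2)
  s <- stats::sd(z)
  if (s > 0) z / s else z
}

#' Synthetic paired stadial/interstadial bioclim fields
#'
#' Smooth latitudinal/longitudinal base climate plus seeded
#' Gaussian-random-field noise gives the interstadial (GI) fields; the
#' stadial (GS) fields are the GI fields shifted by the configured offsets,
#' so GI is warmer than GS everywhere by exactly the bio1 offset. With the
#' noise amplitudes at zero, annual mean temperature decreases monotonically
#' with latitude along every meridian.
#'
#' @param scenario a `pd_scenario`.
#' @param grid optional pre-built `pd_grid` (defaults to the scenario grid).
#' @return A tibble with one row per (cell, regime): `lon`, `lat`, `regime`
#'   ("GS"/"GI") and the four bioclim columns.
#' @export
synth_bioclim <- function(scenario, grid = NULL) {
  g <- grid %||% build_grid(scenario$lon_range, scenario$lat_range,
                            scenario$resolution)
  lon <- rep(g$lon, times = g$nlat)
  lat <- rep(g$lat, each = g$nlon)
  noise <- with_seed(scenario$seed, purrr::map(1:4, function(k)
    as.vector(smooth_noise(g$nlon, g$nlat))))
  amp <- scenario$noise_amp
  gi <- tibble::tibble(
    lon = lon, lat = lat, regime = "GI",
    bio1 = 40 - lat + amp$bio1 * noise[[1]],
    bio4 = 4 + 0.2 * (lat - min(g$lat)) + amp$bio4 * noise[[2]],
    bio13 = 120 - 3 * (lat - min(g$lat)) + 1.0 * (lon - mean(g$lon)) +
      amp$bio13 * noise[[3]],
    bio15 = 20 + 0.5 * (lat - min(g$lat)) + amp$bio15 * noise[[4]])
  gs <- gi
  gs$regime <- "GS"
  for (v in names(scenario$gs_offset)) gs[[v]] <- gs[[v]] + scenario$gs_offset[[v]]
  dplyr::bind_rows(gi, gs)
}

#' Sample a synthetic site catalogue from a truth niche model
#'
#' Marks each candidate cell present with probability equal to the truth
#' suitability `Phi_E` (Bernoulli, seeded), places one site at each sampled
#' cell center, then thins at random to approximately `n_target` sites.
#'
#' @param truth a `pd_niche` truth model.
#' @param predictors a `pd_predictors` over the candidate (land) cells.
#' @param n_target target number of sites; 0 gives an empty catalogue.
#' @param seed integer seed.
#' @param phase phase tag for the catalogue (default "P1").
#' @return A tibble with `id`, `lon`, `lat`, `phase`.
#' @export
synth_sites <- function(truth, predictors, n_target = 150, seed = 1L,
                        phase = "P1") {
  d <- predictors$data
  phi <- predict_hep(truth, d, warn_extrapolation = FALSE)
  empty <- tibble::tibble(id = character(), lon = numeric(),
                          lat = numeric(), phase = character())
  if (n_target <= 0) return(empty)
  with_seed(seed, {
    hit <- which(stats::runif(nrow(d)) < phi)
    if (length(hit) == 0) {
      warning("truth suitability too low: empty site catalogue", call. = FALSE)
      return(empty)
    }
    if (length(hit) > n_target) hit <- sort(sample(hit, n_target))
    tibble::tibble(id = sprintf("site_%03d", seq_along(hit)),
                   lon = d$lon[hit], lat = d$lat[hit], phase = phase)
  })
}

#' Simulate presence/absence records directly from a truth model
#'
#' Labels every candidate cell by a Bernoulli draw with success probability
#' equal to the truth suitability. Unlike the archaeological construction in
#' [build_presence_absence()], every label carries signal, which is what
#' parameter- and field-recovery simulations require.
#'
#' @param truth a `pd_niche` truth model.
#' @param predictors a `pd_predictors` over the candidate cells.
#' @param seed integer seed.
#' @return A `pd_pa` whose records are all provenance "simulated".
#' @export
simulate_presence_absence <- function(truth, predictors, seed = 1L) {
  d <- predictors$data
  phi <- predict_hep(truth, d, warn_extrapolation = FALSE)
  lab <- with_seed(seed, as.integer(stats::runif(nrow(d)) < phi))
  rec <- dplyr::bind_cols(
    tibble::tibble(block = as.character(d$cell), cell = d$cell,
                   lon = d$lon, lat = d$lat, label = lab,
                   provenance = "simulated"),
    d[paste0("z_", predictors$vars)])
  structure(list(records = rec, n_p = sum(lab), n_pa = 0L,
                 stats = predictors$stats, vars = predictors$vars,
                 block_size = NA_real_, option = NA_integer_),
            class = "pd_pa")
}

#' Synthetic isotope forcing series
#'
#' A periodic temperature-proxy series at 20-year steps between two ages.
#' The square shape alternates between two values (pure stadial / pure
#' interstadial epochs after normalization); the sine shape attains its
#' extremes at the crests.
#'
#' @param start_ka,end_ka series interval, `start_ka > end_ka`.
#' @param period_yr oscillation period in years (default 1000).
#' @param shape "square" or "sine".
#' @param levels `c(cold, warm)` proxy values (default -44, -38 permil).
#' @return A tibble with `age_ka` (descending) and `d18O`, step 0.02 ka.
#' @export
synth_isotope <- function(start_ka, end_ka, period_yr = 1000,
                          shape = c("square", "sine"),
                          levels = c(-44, -38)) {
  shape <- match.arg(shape)
  stopifnot(start_ka > end_ka, period_yr > 0)
  age <- seq(start_ka, end_ka, by = -0.02)
  elapsed <- (start_ka - age) * 1000
  d18O <- if (shape == "square") {
    ifelse(floor(elapsed / (period_yr / 2)) %% 2 == 0, levels[1], levels[2])
  } else {
    mean(levels) + diff(levels) / 2 * sin(2 * pi * elapsed / period_yr)
  }
  tibble::tibble(age_ka = age, d18O = d18O)
}

#' Synthetic topography: ridges, roughness and a land mask
#'
#' Elevation is a sum of meridionally oriented Gaussian ridges; the sub-grid
#' elevation standard deviation scales with the local ridge height; the land
#' mask is everything except an ocean rim of `ocean_margin` cells around the
#' domain. With no ridges, both rasters are zero so the terrain modifiers
#' are 1 everywhere on land.
#'
#' @param grid a `pd_grid`.
#' @param ridges list of ridges, each `list(lon =, height =, width_deg =)`
#'   (height in m).
#' @param ocean_margin width of the masked rim in cells (default 1).
#' @param sd_fraction sub-grid roughness as a fraction of local elevation
#'   (default 0.2).
#' @return A list with `elevation` and `elevation_sd` (`pd_field`s, m) and
#'   `land` (logical matrix).
#' @export
synth_topography <- function(grid, ridges = list(), ocean_margin = 1,
                             sd_fraction = 0.2) {
  ele <- matrix(0, grid$nlon, grid$nlat)
  for (r in ridges) {
    prof <- r$height * exp(-((grid$lon - r$lon) / r$width_deg)^2)
    ele <- ele + matrix(rep(prof, times = grid$nlat), grid$nlon, grid$nlat)
  }
  land <- matrix(TRUE, grid$nlon, grid$nlat)
  m <- ocean_margin
  if (m > 0) {
    land[c(seq_len(m), grid$nlon - seq_len(m) + 1), ] <- FALSE
    land[, c(seq_len(m), grid$nlat - seq_len(m) + 1)] <- FALSE
  }
  if (!any(land)) stop("ocean margin leaves no land", call. = FALSE)
  list(elevation = field(grid, ele, units = "m"),
       elevation_sd = field(grid, sd_fraction * ele, units = "m"),
       land = land)
}

#' Build the full set of synthetic inputs for a scenario
#'
#' Convenience wrapper generating everything the pipeline needs: the grid,
#' topography and land mask, paired GS/GI climate, the standardized
#' predictor set (statistics from the interstadial fields, which are also
#' used to transform the stadial fields), the truth model's suitability, a
#' site catalogue and the isotope forcing.
#'
#' @param scenario a `pd_scenario`.
#' @param iso_start_ka,iso_end_ka coverage of the isotope series (defaults
#'   45 and 42 ka).
#' @return A list with `grid`, `topo`, `climate` (long tibble), `predictors`
#'   (GI, land cells only), `predictors_gs`, `truth`, `phi_true`, `sites`,
#'   `iso_series`.
#' @export
build_synthetic_inputs <- function(scenario, iso_start_ka = 45,
                                   iso_end_ka = 42) {
  grid <- build_grid(scenario$lon_range, scenario$lat_range,
                     scenario$resolution)
  topo <- synth_topography(grid, scenario$ridges, scenario$ocean_margin)
  climate <- synth_bioclim(scenario, grid)
  land_cells <- which(as.vector(topo$land))
  keep <- function(d) {
    loc <- locate_cells(grid, d$lon, d$lat)
    d[loc$cell %in% land_cells, ]
  }
  gi <- keep(dplyr::filter(climate, .data$regime == "GI"))
  gs <- keep(dplyr::filter(climate, .data$regime == "GS"))
  predictors <- make_predictor_set(gi, grid)
  predictors_gs <- predictors
  predictors_gs$data <- apply_predictor_stats(
    dplyr::bind_cols(predictors$data[c("i", "j", "cell")],
                     gs[c("lon", "lat", pd_bioclim_vars)]),
    predictors$stats)
  phi_true <- predict_hep(scenario$truth, predictors,
                          warn_extrapolation = FALSE)
  sites <- synth_sites(scenario$truth, predictors, scenario$n_sites,
                       seed = scenario$seed)
  iso_series <- synth_isotope(iso_start_ka, iso_end_ka,
                              period_yr = scenario$iso_period_yr,
                              shape = scenario$iso_shape)
  list(grid = grid, topo = topo, climate = climate,
       predictors = predictors, predictors_gs = predictors_gs,
       truth = scenario$truth, phi_true = phi_true, sites = sites,
       iso_series = iso_series)
}
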