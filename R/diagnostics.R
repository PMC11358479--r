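#' Total population
#'
#' `Lambda = sum(rho_ij * s_ij)` over all (unmasked) grid cells, with the
#' density convention of persons per 100 km^2 handled, so the result is in
#' persons.
#'
#' @param rho density matrix or `pd_field`, P 100 km^-2.
#' @param grid a `pd_grid` (ignored if `rho` is a field).
#' @return Total population in persons.
#' @export
total_population <- function(rho, grid = NULL) {
  if (inherits(rho, "pd_field")) {
    grid <- rho$grid
    m <- rho$values
    if (!is.null(rho$mask)) m[!rho$mask] <- 0
  } else m <- rho
  stopifnot(inherits(grid, "pd_grid"))
  sum(m * grid$area) / 100
}

#' Population flux field
#'
#' `f = v rho - D grad(rho)`: a drift plus a (down-gradient) diffusive
#' contribution, evaluated at cell centers. It measures the number of people
#' moving across a section of unit length per time; reported per decade
#' (P km^-1 (10 yr)^-1), stored internally per year, conversion factor
#' exactly 10.
#'
#' @param rho density matrix, P 100 km^-2.
#' @param vx,vy drift-velocity component matrices, km yr^-1.
#' @param d_field diffusivity matrix or scalar, km^2 yr^-1.
#' @param grid a `pd_grid`.
#' @param land optional logical land mask.
#' @param per_decade report in P km^-1 per 10 years (default TRUE).
#' @return A `pd_vfield` of flux components. Note the 100 km^-2 density
#'   convention: a density of 1 P 100 km^-2 drifting at 1 km yr^-1 moves
#'   0.01 P km^-1 yr^-1.
#' @export
population_flux <- function(rho, vx, vy, d_field, grid, land = NULL,
                            per_decade = TRUE) {
  gr <- gradient_m(grid, rho, land)
  scale <- if (per_decade) 10 else 1
  fx <- (vx * rho - d_field * gr$u) / 100 * scale
  fy <- (vy * rho - d_field * gr$v) / 100 * scale
  if (!is.null(land)) { fx[!land] <- 0; fy[!land] <- 0 }
  vfield(grid, fx, fy,
         units = if (per_decade) "P km-1 (10 yr)-1" else "P km-1 yr-1",
         mask = land)
}

#' Mobility index
#'
#' `M = sum |f_ij|` over unmasked cells: the domain-integrated strength of
#' population movement.
#'
#' @param flux a `pd_vfield` (e.g. from [population_flux()]).
#' @return Sum of flux magnitudes.
#' @export
mobility_index <- function(flux) {
  stopifnot(inherits(flux, "pd_vfield"))
  mag <- sqrt(flux$u^2 + flux$v^2)
  if (!is.null(flux$mask)) mag <- mag[flux$mask]
  sum(mag)
}

#' First-arrival-time map
#'
#' The earliest snapshot time (ka) at which the density reaches the arrival
#' threshold in each cell; cells never reaching it (including all water
#' cells) are `NA`.
#'
#' @param run a `pd_run`.
#' @param threshold density threshold, P 100 km^-2 (default the run's
#'   configured arrival threshold, 0.4).
#' @return A `pd_field` of arrival times (ka BP), masked to land; `NA` =
#'   never reached.
#' @export
arrival_time_map <- function(run, threshold = run$params$arrival_threshold) {
  stopifnot(inherits(run, "pd_run"), length(run$snapshots) >= 1)
  arr <- matrix(NA_real_, run$grid$nlon, run$grid$nlat)
  for (k in seq_along(run$snapshots)) {
    hit <- is.na(arr) & run$snapshots[[k]] >= threshold & run$land
    arr[hit] <- run$times_ka[k]
  }
  f <- field(run$grid, ifelse(is.na(arr), 0, arr), units = "ka",
             mask = !is.na(arr))
  f$values[is.na(arr)] <- NA_real_
  f
}

#' Occupation region and contour at a density level
#'
#' Cells at or above the level, plus the marching-squares boundary polyline
#' of the level set.
#'
#' @param rho density matrix or `pd_field`, P 100 km^-2.
#' @param grid a `pd_grid` (ignored if `rho` is a field).
#' @param level density level, P 100 km^-2 (default 1).
#' @param land optional logical land mask.
#' @return A list with `cells` (tibble lon/lat/i/j of occupied cells) and
#'   `boundary` (tibble lon/lat/piece of contour vertices).
#' @export
occupation_contour <- function(rho, grid = NULL, level = 1, land = NULL) {
  if (inherits(rho, "pd_field")) {
    grid <- rho$grid
    if (is.null(land)) land <- rho$mask
    rho <- rho$values
  }
  stopifnot(inherits(grid, "pd_grid"))
  m <- rho
  if (!is.null(land)) m[!land] <- 0
  occ <- which(m >= level, arr.ind = TRUE)
  cells <- tibble::tibble(
    i = as.integer(occ[, 1]), j = as.integer(occ[, 2]),
    lon = grid$lon[occ[, 1]], lat = grid$lat[occ[, 2]])
  cl <- if (min(m) < level && max(m) >= level)
    grDevices::contourLines(grid$lon, grid$lat, m, levels = level)
  else list()   # level set has no boundary inside the domain
  boundary <- purrr::imap_dfr(cl, function(piece, k)
    tibble::tibble(lon = piece$x, lat = piece$y, piece = k))
  list(cells = cells, boundary = boundary, level = level)
}

#' Compare simulated chronology with dated sites
#'
#' Looks up the first-arrival time at each site's containing grid cell in
#' every ensemble member's arrival map, and reports the ensemble mean and
#' standard deviation (population convention, divide by n) next to the dated
#' value. Sites in never-reached cells are reported with `NA` model values
#' and `reached = FALSE`.
#'
#' @param arrival_maps list of arrival `pd_field`s (or a single one), e.g.
#'   from [arrival_time_map()] over ensemble members.
#' @param sites data frame with `site`, `lon`, `lat` and optionally
#'   `dated_ka`, `dated_error_ka` columns.
#' @return A tibble with one row per site: the dated columns plus
#'   `model_mean_ka`, `model_sd_ka`, `n_members`, `reached`.
#' @export
compare_chronology <- function(arrival_maps, sites) {
  if (inherits(arrival_maps, "pd_field")) arrival_maps <- list(arrival_maps)
  stopifnot(length(arrival_maps) >= 1)
  grid <- arrival_maps[[1]]$grid
  loc <- locate_cells(grid, sites$lon, sites$lat)
  if (anyNA(loc$cell)) stop("site outside the model domain", call. = FALSE)
  vals <- vapply(arrival_maps, function(f) f$values[loc$cell],
                 numeric(nrow(sites)))
  vals <- matrix(vals, nrow = nrow(sites))
  mean_ka <- rowMeans(vals)
  sd_ka <- sqrt(rowMeans(vals^2) - mean_ka^2)     # population s.d.
  out <- tibble::as_tibble(sites)
  out$model_mean_ka <- mean_ka
  out$model_sd_ka <- ifelse(is.na(mean_ka), NA_real_, pmax(sd_ka, 0))
  out$n_members <- length(arrival_maps)
  out$reached <- !is.na(mean_ka)
  out
}

#' Plots of gridded and time-series results
#'
#' `autoplot()` methods: a raster map for `pd_field` (density, HEP, arrival
#' time), and Lambda/M time series for `pd_run`.
#'
#' @param object the object to plot.
#' @param ... unused.
#' @return A ggplot object.
#' @name autoplot-paleodisp
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an occupation contour over a density field
#'
#' @param rho a density `pd_field`.
#' @param level contour level, P 100 km^-2.
#' @return A ggplot object.
#' @export
plot_occupation <- function(rho, level = 1) {
  oc <- occupation_contour(rho, level = level)
  p <- autoplot(rho)
  if (nrow(oc$boundary) > 0)
    p <- p + ggplot2::geom_path(
      data = oc$boundary,
      ggplot2::aes(.data$lon, .data$lat, group = .data$piece),
      inherit.aes = FALSE, colour = "red")
  p
}
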