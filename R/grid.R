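#' Build a regular latitude-longitude grid
#'
#' Constructs the regular lon/lat mesh on which all fields live. Coordinates
#' are cell centers; cell edges are half-open intervals so any point inside
#' the domain belongs to exactly one cell. Spherical cell geometry (areas,
#' face lengths, center spacings) is precomputed once and reused by the
#' differential operators and the transport solver.
#'
#' @param lon_range numeric(2), degrees east (ascending).
#' @param lat_range numeric(2), degrees north (ascending), within [-90, 90].
#' @param resolution grid spacing in degrees; must divide both ranges.
#' @param earth_radius radius in km (default 6371).
#' @return An object of class `pd_grid`.
#' @examples
#' g <- build_grid(c(-15, 49), c(20, 60), 0.5)
#' g$nlon; g$nlat
#' @export
build_grid <- function(lon_range, lat_range, resolution, earth_radius = 6371) {
  stopifnot(length(lon_range) == 2, length(lat_range) == 2)
  if (resolution <= 0) stop("resolution must be positive", call. = FALSE)
  if (lon_range[2] <= lon_range[1] || lat_range[2] <= lat_range[1])
    stop("degenerate lon/lat range", call. = FALSE)
  if (lat_range[1] < -90 || lat_range[2] > 90)
    stop("latitude range must lie within [-90, 90]", call. = FALSE)

  n_of <- function(range, axis) {
    span <- range[2] - range[1]
    n <- span / resolution
    if (abs(n - round(n)) > 1e-6)
      stop(sprintf("resolution %g does not divide the %s range [%g, %g]",
                   resolution, axis, range[1], range[2]), call. = FALSE)
    as.integer(round(n))
  }
  nlon <- n_of(lon_range, "longitude")
  nlat <- n_of(lat_range, "latitude")

  lon <- lon_range[1] + (seq_len(nlon) - 0.5) * resolution
  lat <- lat_range[1] + (seq_len(nlat) - 0.5) * resolution

  deg <- pi / 180
  dlam <- resolution * deg
  dphi <- resolution * deg
  lat_faces <- lat_range[1] + (0:nlat) * resolution

  # spherical cell areas, km^2: R^2 * dlam * (sin(top) - sin(bottom))
  area_lat <- earth_radius^2 * dlam *
    (sin(lat_faces[-1] * deg) - sin(lat_faces[-(nlat + 1)] * deg))
  area <- matrix(rep(area_lat, each = nlon), nlon, nlat)

  structure(list(
    lon = lon, lat = lat,
    lon_range = lon_range, lat_range = lat_range,
    resolution = resolution, earth_radius = earth_radius,
    nlon = nlon, nlat = nlat,
    area = area,
    dx = earth_radius * dlam * cos(lat * deg),   # center spacing along lon, km (per lat row)
    dy = earth_radius * dphi,                    # center spacing along lat, km
    len_we = earth_radius * dphi,                # length of west/east cell faces, km
    len_sn = earth_radius * dlam * cos(lat_faces * deg)  # south/north face lengths, km (nlat+1)
  ), class = "pd_grid")
}

#' @export
print.pd_grid <- function(x, ...) {
  cat(sprintf("<pd_grid> %d x %d cells, %.4g deg, lon [%g, %g], lat [%g, %g]\n",
              x$nlon, x$nlat, x$resolution,
              x$lon_range[1], x$lon_range[2], x$lat_range[1], x$lat_range[2]))
  invisible(x)
}

#' Scalar field on a grid
#'
#' A light container pairing a value matrix (`nlon x nlat`) with its grid,
#' a units tag and an optional validity mask (`TRUE` = valid cell).
#'
#' @param grid a `pd_grid`.
#' @param values matrix `nlon x nlat`, or a scalar to be recycled.
#' @param units non-empty units string (e.g. "P 100 km-2", "degC", "1").
#' @param mask optional logical matrix, `TRUE` where the field is valid.
#' @return An object of class `pd_field`.
#' @export
field <- function(grid, values, units, mask = NULL) {
  stopifnot(inherits(grid, "pd_grid"))
  if (length(values) == 1) values <- matrix(values, grid$nlon, grid$nlat)
  if (!is.matrix(values) || !all(dim(values) == c(grid$nlon, grid$nlat)))
    stop("values must be an nlon x nlat matrix", call. = FALSE)
  if (!is.character(units) || !nzchar(units))
    stop("units tag must be a non-empty string", call. = FALSE)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(values)))
    if (any(!is.finite(values[mask])))
      stop("non-finite values on unmasked cells", call. = FALSE)
  } else if (any(!is.finite(values))) {
    stop("non-finite values in field", call. = FALSE)
  }
  structure(list(grid = grid, values = values, units = units, mask = mask),
            class = "pd_field")
}

#' Vector field on a grid
#'
#' @param grid a `pd_grid`.
#' @param u zonal component matrix (km per yr by convention).
#' @param v meridional component matrix.
#' @param units units string.
#' @param mask optional logical validity matrix.
#' @return An object of class `pd_vfield`.
#' @export
vfield <- function(grid, u, v, units = "km yr-1", mask = NULL) {
  stopifnot(inherits(grid, "pd_grid"))
  if (length(u) == 1) u <- matrix(u, grid$nlon, grid$nlat)
  if (length(v) == 1) v <- matrix(v, grid$nlon, grid$nlat)
  stopifnot(all(dim(u) == c(grid$nlon, grid$nlat)), all(dim(v) == dim(u)))
  ok <- if (is.null(mask)) TRUE else mask
  if (any(!is.finite(u[ok])) || any(!is.finite(v[ok])))
    stop("non-finite vector components on unmasked cells", call. = FALSE)
  structure(list(grid = grid, u = u, v = v, units = units, mask = mask),
            class = "pd_vfield")
}

#' Cell areas of a grid
#'
#' Spherical areas `R^2 * dlam * (sin(phi_top) - sin(phi_bottom))` per cell.
#' Summed over the grid they telescope exactly to the spherical area of the
#' bounding box.
#'
#' @param grid a `pd_grid`.
#' @return A `pd_field` with units km^2.
#' @export
cell_areas <- function(grid) {
  field(grid, grid$area, units = "km^2")
}

#' Spherical area of a lon/lat box
#'
#' `R^2 * dlam * (sin(lat_max) - sin(lat_min))` with R in meters.
#'
#' @param lon_min,lon_max longitude bounds, degrees (span <= 360).
#' @param lat_min,lat_max latitude bounds, degrees, `lat_min < lat_max`.
#' @param earth_radius_m radius in meters (default 6371e3).
#' @return Area in m^2.
#' @examples
#' spherical_box_area(-180, 180, -90, 90) # 4 pi R^2
#' @export
spherical_box_area <- function(lon_min, lon_max, lat_min, lat_max,
                               earth_radius_m = 6371e3) {
  if (lat_min >= lat_max) stop("lat_min must be below lat_max", call. = FALSE)
  if (lat_min < -90 || lat_max > 90)
    stop("latitudes must lie within [-90, 90]", call. = FALSE)
  span <- lon_max - lon_min
  if (span < 0 || span > 360) stop("longitude span must be in [0, 360]", call. = FALSE)
  deg <- pi / 180
  earth_radius_m^2 * span * deg * (sin(lat_max * deg) - sin(lat_min * deg))
}

#' Convert a volume flux over an area into an equivalent depth rate
#'
#' Used e.g. to express a freshwater volume flux spread over an ocean box as
#' a net gain in mm per day.
#'
#' @param volume_flux m^3 s^-1.
#' @param area m^2, positive.
#' @return Rate in mm day^-1.
#' @export
flux_to_depth_rate <- function(volume_flux, area) {
  if (!is.numeric(area) || any(area <= 0)) stop("area must be positive", call. = FALSE)
  volume_flux / area * 86400 * 1000
}

# neighbour shifts on an nlon x nlat matrix; outside cells become NA
shift_lon <- function(m, by) {
  n <- nrow(m)
  out <- matrix(NA_real_, n, ncol(m))
  if (by == 1L) out[1:(n - 1), ] <- m[2:n, ]       # east neighbour
  else out[2:n, ] <- m[1:(n - 1), ]                # west neighbour
  out
}
shift_lat <- function(m, by) {
  n <- ncol(m)
  out <- matrix(NA_real_, nrow(m), n)
  if (by == 1L) out[, 1:(n - 1)] <- m[, 2:n]       # north neighbour
  else out[, 2:n] <- m[, 1:(n - 1)]                # south neighbour
  out
}

mask_na <- function(values, mask) {
  if (!is.null(mask)) values[!mask] <- NA_real_
  values
}

#' Gradient of a scalar field
#'
#' Centered second-order differences with the spherical metric
#' (`dx = R dlam cos(lat)`, `dy = R dphi`); one-sided differences at domain
#' and mask edges, zero where no valid neighbour exists in a direction.
#'
#' @param f a `pd_field`.
#' @return A `pd_vfield` in field-units per km.
#' @export
field_gradient <- function(f) {
  stopifnot(inherits(f, "pd_field"))
  g <- f$grid
  m <- mask_na(f$values, f$mask)
  dxm <- matrix(rep(g$dx, each = g$nlon), g$nlon, g$nlat)

  comp <- function(fp, fm, h) {
    out <- (fp - fm) / (2 * h)
    use_fwd <- is.na(out) & !is.na(fp)
    if (any(use_fwd)) out[use_fwd] <- ((fp - m) / h)[use_fwd]
    use_bwd <- is.na(out) & !is.na(fm)
    if (any(use_bwd)) out[use_bwd] <- ((m - fm) / h)[use_bwd]
    out[is.na(out)] <- 0
    out[is.na(m)] <- 0
    out
  }
  u <- comp(shift_lon(m, 1L), shift_lon(m, -1L), dxm)
  v <- comp(shift_lat(m, 1L), shift_lat(m, -1L), g$dy)
  vfield(g, u, v, units = paste0(f$units, " km-1"), mask = f$mask)
}

#' Laplacian of a scalar field
#'
#' Finite-volume divergence of the metric-aware gradient: face-normal
#' gradients times spherical face lengths, summed and divided by the cell
#' area. Domain and mask edges are treated as no-flux boundaries, so the
#' area-weighted sum of the Laplacian over a closed region vanishes
#' (discrete divergence theorem). Reduces to the 5-point stencil in the
#' flat-metric limit.
#'
#' @param f a `pd_field`.
#' @return A `pd_field` in field-units per km^2.
#' @export
field_laplacian <- function(f) {
  stopifnot(inherits(f, "pd_field"))
  g <- f$grid
  m <- mask_na(f$values, f$mask)
  nlon <- g$nlon; nlat <- g$nlat
  dxm <- matrix(rep(g$dx, each = nlon), nlon, nlat)
  len_s <- matrix(rep(g$len_sn[1:nlat], each = nlon), nlon, nlat)
  len_n <- matrix(rep(g$len_sn[2:(nlat + 1)], each = nlon), nlon, nlat)

  fx <- function(nb, h, len) {
    fl <- (nb - m) / h * len
    fl[is.na(fl)] <- 0            # no-flux at mask/domain edges
    fl
  }
  total <- fx(shift_lon(m, 1L), dxm, g$len_we) +
    fx(shift_lon(m, -1L), dxm, g$len_we) +
    fx(shift_lat(m, 1L), g$dy, len_n) +
    fx(shift_lat(m, -1L), g$dy, len_s)
  vals <- total / g$area
  vals[is.na(m)] <- 0
  field(g, vals, units = paste0(f$units, " km-2"), mask = f$mask)
}

#' Locate points on a grid
#'
#' Half-open cell binning: a point belongs to the cell whose interval
#' `[edge, edge + resolution)` contains it. Points outside the domain get
#' `NA` indices.
#'
#' @param grid a `pd_grid`.
#' @param lon,lat point coordinates, degrees.
#' @return A tibble with columns `lon`, `lat`, `i`, `j`, `cell` (linear
#'   index, lon-major).
#' @export
locate_cells <- function(grid, lon, lat) {
  i <- floor((lon - grid$lon_range[1]) / grid$resolution) + 1
  j <- floor((lat - grid$lat_range[1]) / grid$resolution) + 1
  bad <- i < 1 | i > grid$nlon | j < 1 | j > grid$nlat
  i[bad] <- NA_integer_; j[bad] <- NA_integer_
  tibble::tibble(lon = lon, lat = lat, i = as.integer(i), j = as.integer(j),
                 cell = as.integer(i + (j - 1L) * grid$nlon))
}

#' Field to tibble
#'
#' Long-format view of a field: one row per cell with `lon`, `lat`, `value`
#' and (if the field has a mask) a logical `valid` column.
#'
#' @param f a `pd_field`.
#' @return A tibble.
#' @export
field_tbl <- function(f) {
  stopifnot(inherits(f, "pd_field"))
  g <- f$grid
  out <- tibble::tibble(
    lon = rep(g$lon, times = g$nlat),
    lat = rep(g$lat, each = g$nlon),
    value = as.vector(f$values)
  )
  if (!is.null(f$mask)) out$valid <- as.vector(f$mask)
  out
}

#' Tibble to field
#'
#' Inverse of [field_tbl()]: builds a field from a long tibble with `lon`,
#' `lat` and a value column. Every grid cell must appear exactly once.
#'
#' @param grid a `pd_grid`.
#' @param data data frame with columns `lon`, `lat` and `value_col`.
#' @param value_col name of the value column (default "value").
#' @param units units tag.
#' @param mask optional logical matrix.
#' @return A `pd_field`.
#' @export
tbl_field <- function(data, grid, value_col = "value", units = "1", mask = NULL) {
  loc <- locate_cells(grid, data$lon, data$lat)
  if (anyNA(loc$cell)) stop("points outside the grid domain", call. = FALSE)
  if (anyDuplicated(loc$cell) || nrow(data) != grid$nlon * grid$nlat)
    stop("data must cover every grid cell exactly once", call. = FALSE)
  vals <- matrix(NA_real_, grid$nlon, grid$nlat)
  vals[loc$cell] <- data[[value_col]]
  field(grid, vals, units = units, mask = mask)
}

#' @rdname autoplot-paleodisp
#' @export
autoplot.pd_field <- function(object, ...) {
  d <- field_tbl(object)
  if (!is.null(object$mask)) d$value[!d$valid] <- NA_real_
  ggplot2::ggplot(d, ggplot2::aes(.data$lon, .data$lat, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85", name = object$units) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitude (deg E)", y = "latitude (deg N)")
}
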