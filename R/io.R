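# Readers and writers for the plain-text interchange formats: rasters and
# tables as CSV (full double precision, round-trip exact), fitted models as
# JSON, configuration as YAML. Every file written here carries a provenance
# comment line with the configuration hash and seed.

provenance_line <- function(meta = list()) {
  sprintf("# paleodisp v%s config_hash=%s seed=%s",
          as.character(utils::packageVersion("paleodisp")),
          meta$config_hash %||% "none", meta$seed %||% "none")
}

write_csv_prov <- function(data, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(meta), con)
  fmt <- as.data.frame(lapply(data, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col   # round-trip exact
  }), optional = TRUE, stringsAsFactors = FALSE)
  names(fmt) <- names(data)
  utils::write.csv(fmt, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_prov <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE))
}

#' Write and read gridded fields as CSV rasters
#'
#' Long format, one row per cell: `lon`, `lat`, then one column per field.
#' Values are written in full double precision so a write/read round trip is
#' value-exact. A provenance comment line (`# paleodisp ...`) records the
#' configuration hash and seed.
#'
#' @param fields a `pd_field`, or a named list of `pd_field`s on one grid.
#' @param path output CSV path.
#' @param meta optional list with `config_hash` and `seed`.
#' @return `path`, invisibly.
#' @export
write_raster_csv <- function(fields, path, meta = list()) {
  if (inherits(fields, "pd_field")) fields <- list(value = fields)
  g <- fields[[1]]$grid
  d <- tibble::tibble(lon = rep(g$lon, times = g$nlat),
                      lat = rep(g$lat, each = g$nlon))
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (!identical(dim(f$values), c(g$nlon, g$nlat)))
      stop(sprintf("grid mismatch for field '%s'", nm), call. = FALSE)
    d[[nm]] <- as.vector(f$values)
  }
  write_csv_prov(d, path, meta)
}

#' @rdname write_raster_csv
#' @param grid a `pd_grid` the raster must live on; inferred from the
#'   coordinates when `NULL`.
#' @param units units tag for the returned fields.
#' @return For the reader: a named list of `pd_field`s (one per value
#'   column).
#' @export
read_raster_csv <- function(path, grid = NULL, units = "1") {
  d <- read_csv_prov(path)
  if (!all(c("lon", "lat") %in% names(d)))
    stop(sprintf("%s: raster CSV needs lon and lat columns", path),
         call. = FALSE)
  grid <- grid %||% infer_grid(d$lon, d$lat)
  loc <- locate_cells(grid, d$lon, d$lat)
  if (anyNA(loc$cell) || nrow(d) != grid$nlon * grid$nlat)
    stop(sprintf("%s: raster does not match the grid", path), call. = FALSE)
  vars <- setdiff(names(d), c("lon", "lat"))
  setNames(purrr::map(vars, function(v) {
    m <- matrix(NA_real_, grid$nlon, grid$nlat)
    m[loc$cell] <- d[[v]]
    field(grid, m, units = units)
  }), vars)
}

#' Infer a regular grid from cell-center coordinates
#'
#' @param lon,lat coordinate vectors covering every cell once.
#' @return A `pd_grid`.
#' @export
infer_grid <- function(lon, lat) {
  ulon <- sort(unique(lon)); ulat <- sort(unique(lat))
  res <- stats::median(diff(ulon))
  if (max(abs(diff(ulon) - res)) > 1e-9 || max(abs(diff(ulat) - res)) > 1e-9)
    stop("coordinates are not on a uniform grid", call. = FALSE)
  build_grid(c(min(ulon) - res / 2, max(ulon) + res / 2),
             c(min(ulat) - res / 2, max(ulat) + res / 2), res)
}

#' Read and write site catalogues, isotope series and scalar tables
#'
#' Site CSVs have header `id, lon, lat, phase`; isotope CSVs `age_ka, d18O`.
#'
#' @param path CSV path.
#' @param sites,series data frames to write.
#' @param meta provenance list (`config_hash`, `seed`).
#' @return Tibbles (readers) or the path (writers).
#' @export
read_sites_csv <- function(path) {
  d <- read_csv_prov(path)
  if (!all(c("lon", "lat") %in% names(d)))
    stop(sprintf("%s: site CSV needs lon and lat columns", path), call. = FALSE)
  d
}

#' @rdname read_sites_csv
#' @export
write_sites_csv <- function(sites, path, meta = list())
  write_csv_prov(sites, path, meta)

#' @rdname read_sites_csv
#' @export
read_isotope_csv <- function(path) {
  d <- read_csv_prov(path)
  if (!all(c("age_ka", "d18O") %in% names(d)))
    stop(sprintf("%s: isotope CSV needs age_ka and d18O columns", path),
         call. = FALSE)
  d
}

#' @rdname read_sites_csv
#' @export
write_isotope_csv <- function(series, path, meta = list())
  write_csv_prov(series, path, meta)

#' Serialize a fitted niche model (or ensemble) to JSON
#'
#' Stores coefficients, standardization statistics, training options and
#' held-out scores, enough to restore prediction-capable models.
#'
#' @param x a `pd_niche` or `pd_niche_ens`.
#' @param path output JSON path.
#' @param meta provenance list.
#' @return `path`, invisibly.
#' @export
write_niche_json <- function(x, path, meta = list()) {
  pack_model <- function(m)
    list(A = m$A, B = unname(m$B), C = m$C, vars = m$vars,
         stats = m$stats)
  payload <- if (inherits(x, "pd_niche_ens")) {
    list(type = "ensemble", n_members = x$n_members, seed = x$seed,
         train_fraction = x$train_fraction, bss = x$bss,
         scores = x$scores, stats = x$stats, vars = x$vars,
         members = purrr::map(x$members, pack_model))
  } else if (inherits(x, "pd_niche")) {
    c(list(type = "model"), pack_model(x))
  } else stop("not a niche model or ensemble", call. = FALSE)
  payload$provenance <- list(
    package = as.character(utils::packageVersion("paleodisp")),
    config_hash = meta$config_hash %||% "none", seed = meta$seed %||% "none")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_niche_json
#' @return For the reader: a `pd_niche` or list of them (for an ensemble
#'   file, a list with `members` and the stored scores).
#' @export
read_niche_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpack <- function(m) niche_model(
    A = matrix(unlist(m$A), length(m$vars), length(m$vars)),
    B = unlist(m$B), C = m$C,
    stats = tibble::as_tibble(m$stats), vars = m$vars)
  if (identical(p$type, "model")) return(unpack(p))
  members <- purrr::map(seq_len(p$n_members), function(k)
    unpack(list(A = p$members$A[[k]], B = p$members$B[[k]],
                C = p$members$C[k], vars = p$vars,
                stats = p$stats)))
  list(members = members, scores = tibble::as_tibble(p$scores),
       bss = p$bss, stats = tibble::as_tibble(p$stats), vars = p$vars)
}
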