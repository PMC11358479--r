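#' Accessibility modifier configuration
#'
#' Unit-interval modifiers that reduce the environment HEP to accessible
#' HEP: a water-body indicator, a terrain-elevation ramp and a sub-grid
#' terrain-roughness ramp. Each ramp is 1 below its start breakpoint and
#' falls linearly to 0 at its end breakpoint.
#'
#' @param ele_start,ele_end elevation ramp breakpoints, m (defaults 1500,
#'   2500: full access below 1500 m, none above 2500 m).
#' @param std_start,std_end sub-grid elevation standard-deviation ramp
#'   breakpoints, m (defaults 300, 600).
#' @return An object of class `pd_modifiers`.
#' @export
modifier_config <- function(ele_start = 1500, ele_end = 2500,
                            std_start = 300, std_end = 600) {
  stopifnot(ele_start < ele_end, std_start < std_end)
  structure(list(ele_start = ele_start, ele_end = ele_end,
                 std_start = std_start, std_end = std_end),
            class = "pd_modifiers")
}

# linear ramp: 1 below a, 0 above b
ramp_down <- function(x, a, b) pmin(1, pmax(0, (b - x) / (b - a)))

#' Accessible HEP from environment HEP and terrain
#'
#' `Phi_Ac = Phi_E * g_ele * g_std * g_wat * ...`: the pointwise product of
#' the environment HEP with every configured unit-interval modifier. Water
#' cells (mask FALSE) get `g_wat = 0`, so `Phi_Ac = 0` there regardless of
#' climate.
#'
#' @param phi_e `pd_field`, environment HEP in [0, 1].
#' @param modifiers a `pd_modifiers` configuration.
#' @param elevation `pd_field`, terrain elevation (m).
#' @param elevation_sd `pd_field`, sub-grid elevation standard deviation (m).
#' @param land logical matrix, TRUE on land.
#' @param extra optional named list of additional modifier matrices in
#'   [0, 1].
#' @return A `pd_field` in [0, 1] with the land mask attached.
#' @export
accessible_hep <- function(phi_e, modifiers, elevation, elevation_sd, land,
                           extra = list()) {
  stopifnot(inherits(phi_e, "pd_field"), inherits(modifiers, "pd_modifiers"))
  g <- phi_e$grid
  stopifnot(all(dim(land) == dim(phi_e$values)))
  vals <- phi_e$values *
    ramp_down(elevation$values, modifiers$ele_start, modifiers$ele_end) *
    ramp_down(elevation_sd$values, modifiers$std_start, modifiers$std_end) *
    ifelse(land, 1, 0)
  for (nm in names(extra)) {
    gx <- extra[[nm]]
    if (any(gx < 0 | gx > 1))
      stop(sprintf("modifier '%s' outside [0, 1]", nm), call. = FALSE)
    vals <- vals * gx
  }
  field(g, vals, units = "1", mask = land)
}

#' A-priori habitability modifier from raw climate
#'
#' Expert-knowledge override: human existence potential is set to exactly
#' zero where the raw climate falls outside the habitable ranges (by
#' default annual mean temperature outside [-2, 16] degC or wettest-month
#' precipitation outside [30, 250] mm -- the same rules that define a-priori
#' absence cells in training). Used as an extra `g_x` modifier in
#' [accessible_hep()]; without it a fitted logistic model never returns an
#' exact zero, and uninhabitable cells would not lose population.
#'
#' @param climate data frame with `lon`, `lat` and the raw columns named in
#'   `apriori`.
#' @param grid a `pd_grid`.
#' @param apriori named list of inclusive habitable ranges (default
#'   `list(bio1 = c(-2, 16), bio13 = c(30, 250))`).
#' @return A 0/1 matrix (`nlon x nlat`); cells without climate records are 1.
#' @export
apriori_modifier <- function(climate, grid,
                             apriori = list(bio1 = c(-2, 16),
                                            bio13 = c(30, 250))) {
  loc <- locate_cells(grid, climate$lon, climate$lat)
  ok <- rep(TRUE, nrow(climate))
  for (v in names(apriori))
    ok <- ok & climate[[v]] >= apriori[[v]][1] & climate[[v]] <= apriori[[v]][2]
  m <- matrix(1, grid$nlon, grid$nlat)
  m[loc$cell] <- as.numeric(ok)
  m
}

#' Accessible-HEP stack from fitted models and paired climates
#'
#' Pipeline convenience: evaluates the (ensemble-mean) environment HEP on
#' the interstadial and stadial predictor sets, applies the terrain/water
#' modifiers and the a-priori habitability override, and bundles the result
#' as a phase x regime stack (the two phases share fields unless separate
#' models are given).
#'
#' @param models a `pd_niche`, a list of them (averaged pointwise), or a
#'   `pd_niche_ens`.
#' @param predictors_gi,predictors_gs `pd_predictors` for the two regimes
#'   (standardized with the same training statistics).
#' @param topo list with `elevation`, `elevation_sd` (fields) and `land`
#'   (matrix), e.g. from [synth_topography()].
#' @param modifiers a `pd_modifiers` (default [modifier_config()]).
#' @param apriori habitable-range list for [apriori_modifier()], or `NULL`
#'   to skip the override.
#' @return A `pd_hep_stack`.
#' @export
accessible_stack <- function(models, predictors_gi, predictors_gs, topo,
                             modifiers = modifier_config(),
                             apriori = list(bio1 = c(-2, 16),
                                            bio13 = c(30, 250))) {
  if (inherits(models, "pd_niche_ens")) models <- models$members
  if (inherits(models, "pd_niche")) models <- list(models)
  grid <- topo$elevation$grid
  one <- function(pred) {
    d <- pred$data
    phi <- rowMeans(vapply(models, function(m)
      predict_hep(m, d, warn_extrapolation = FALSE), numeric(nrow(d))))
    vals <- matrix(0, grid$nlon, grid$nlat)
    vals[d$cell] <- phi
    extra <- if (!is.null(apriori))
      list(apriori = apriori_modifier(d, grid, apriori)) else list()
    accessible_hep(field(grid, vals, "1"), modifiers, topo$elevation,
                   topo$elevation_sd, topo$land, extra = extra)
  }
  hep_stack(one(predictors_gs), one(predictors_gi))
}

#' Local carrying capacity from accessible HEP
#'
#' `rho_c = rho_c_max * Phi_Ac`: the population density at which net
#' production vanishes, scaled linearly by the accessible HEP.
#'
#' @param phi_ac `pd_field`, accessible HEP in [0, 1].
#' @param rho_c_max cultural carrying capacity, P 100 km^-2 (default 5).
#' @return A `pd_field` in P 100 km^-2.
#' @export
carrying_capacity <- function(phi_ac, rho_c_max = 5) {
  stopifnot(inherits(phi_ac, "pd_field"), rho_c_max > 0)
  field(phi_ac$grid, rho_c_max * phi_ac$values, units = "P 100 km-2",
        mask = phi_ac$mask)
}

# Weibull-density population-pressure response in x = rho/rho_c, and its mode
weibull_w <- function(x, epsilon, eta) {
  (eta / epsilon) * (x / epsilon)^(eta - 1) * exp(-(x / epsilon)^eta)
}

#' Mode of the Weibull population-pressure response
#'
#' Closed form `epsilon * ((eta - 1) / eta)^(1/eta)` for shape `eta > 1`:
#' the ratio `rho / rho_c` at which the available HEP peaks.
#'
#' @param epsilon scale parameter (> 0).
#' @param eta shape parameter (> 1).
#' @return The maximizing ratio.
#' @export
weibull_mode <- function(epsilon, eta) {
  stopifnot(epsilon > 0, eta > 1)
  epsilon * ((eta - 1) / eta)^(1 / eta)
}

#' Available HEP from density and carrying capacity
#'
#' Two competing effects shape the resources available per person: mutual
#' support at low density, and population pressure once density approaches
#' the local carrying capacity. Both are captured by a Weibull-density
#' response in `x = rho / rho_c`:
#' `w = (eta/epsilon) (x/epsilon)^(eta-1) exp(-(x/epsilon)^eta)`, and
#' `Phi_Av = (w / w_max) * rho_c` with `w_max` the supremum of `w` over
#' `x >= 0` (attained at the Weibull mode), so `Phi_Av` ranges over
#' `[0, rho_c]`. Cells with `rho_c = 0` get `Phi_Av = 0`.
#'
#' @param rho density matrix or `pd_field`, P 100 km^-2, non-negative.
#' @param rho_c carrying-capacity matrix or `pd_field`, P 100 km^-2.
#' @param epsilon Weibull scale (default 0.4).
#' @param eta Weibull shape (default 2.5; must exceed 1).
#' @return Available HEP with the same shape as `rho` (matrix in, matrix
#'   out; field in, field out), units P 100 km^-2.
#' @export
available_hep <- function(rho, rho_c, epsilon = 0.4, eta = 2.5) {
  as_f <- inherits(rho, "pd_field")
  grid <- if (as_f) rho$grid
  mask <- if (as_f) rho$mask
  r <- if (as_f) rho$values else rho
  rc <- if (inherits(rho_c, "pd_field")) rho_c$values else rho_c
  if (length(rc) == 1) rc <- array(rc, dim = dim(r) %||% length(r))
  stopifnot(epsilon > 0, eta > 1)
  if (any(r < 0)) stop("negative population density", call. = FALSE)
  w_max <- weibull_w(weibull_mode(epsilon, eta), epsilon, eta)
  x <- ifelse(rc > 0, r / rc, 0)
  out <- ifelse(rc > 0 & x > 0, weibull_w(x, epsilon, eta) / w_max * rc, 0)
  if (!is.null(dim(r))) dim(out) <- dim(r)
  if (as_f) field(grid, out, units = "P 100 km-2", mask = mask) else out
}

#' Normalize an isotope series over the study window
#'
#' Affine map of the delta-18-O temperature proxy onto [0, 1]:
#' `d18O_n = (d18O - min) / (max - min)`, with the minimum and maximum taken
#' within the configured study period only. 0 corresponds to the coldest
#' (most stadial) and 1 to the warmest (most interstadial) state.
#'
#' @param series data frame with columns `age_ka` and `d18O` (20-year steps,
#'   ages descending in simulation order).
#' @param window optional `c(start_ka, end_ka)` study period (start > end);
#'   defaults to the full series.
#' @return An object of class `pd_isotope`: tibble `series` with an added
#'   `d18O_n` column restricted to the window, plus `d18O_min`, `d18O_max`.
#' @export
normalize_isotope <- function(series, window = NULL) {
  stopifnot(all(c("age_ka", "d18O") %in% names(series)))
  s <- tibble::as_tibble(series)
  if (!is.null(window)) {
    stopifnot(window[1] > window[2])
    s <- dplyr::filter(s, .data$age_ka <= window[1], .data$age_ka >= window[2])
  }
  s <- dplyr::arrange(s, dplyr::desc(.data$age_ka))
  lo <- min(s$d18O); hi <- max(s$d18O)
  if (hi <= lo) stop("cannot normalize a constant isotope series", call. = FALSE)
  s$d18O_n <- (s$d18O - lo) / (hi - lo)
  structure(list(series = s, d18O_min = lo, d18O_max = hi),
            class = "pd_isotope")
}

#' @export
print.pd_isotope <- function(x, ...) {
  cat(sprintf("<pd_isotope> %d steps, %.2f-%.2f ka, d18O in [%.2f, %.2f]\n",
              nrow(x$series), max(x$series$age_ka), min(x$series$age_ka),
              x$d18O_min, x$d18O_max))
  invisible(x)
}

# normalized isotope value at time t (ka), nearest 20-yr step
isotope_at <- function(iso, t_ka) {
  s <- iso$series
  if (t_ka > max(s$age_ka) + 1e-9 || t_ka < min(s$age_ka) - 1e-9)
    stop(sprintf("time %.3f ka outside the isotope series coverage", t_ka),
         call. = FALSE)
  s$d18O_n[which.min(abs(s$age_ka - t_ka))]
}

#' Accessible-HEP stack for two phases and two climate regimes
#'
#' Bundles the four accessible-HEP fields indexed by cultural phase (P1, P2)
#' and climate regime (GS stadial, GI interstadial), plus the phase-boundary
#' time. All fields must share one grid and lie in [0, 1].
#'
#' @param p1_gs,p1_gi,p2_gs,p2_gi `pd_field`s of accessible HEP.
#' @param phase_boundary_ka hard switch time between the phase stacks
#'   (default 38 ka; times above it use P1).
#' @return An object of class `pd_hep_stack`.
#' @export
hep_stack <- function(p1_gs, p1_gi, p2_gs = p1_gs, p2_gi = p1_gi,
                      phase_boundary_ka = 38) {
  fields <- list(P1_GS = p1_gs, P1_GI = p1_gi, P2_GS = p2_gs, P2_GI = p2_gi)
  g <- fields[[1]]$grid
  for (nm in names(fields)) {
    f <- fields[[nm]]
    stopifnot(inherits(f, "pd_field"))
    if (!identical(dim(f$values), dim(fields[[1]]$values)))
      stop("all HEP fields must share one grid", call. = FALSE)
    ok <- if (is.null(f$mask)) TRUE else f$mask
    if (any(f$values[ok] < 0 | f$values[ok] > 1))
      stop(sprintf("HEP field %s outside [0, 1]", nm), call. = FALSE)
  }
  structure(list(fields = fields, grid = g,
                 phase_boundary_ka = phase_boundary_ka),
            class = "pd_hep_stack")
}

#' Accessible HEP at a given time
#'
#' Linear blend of the phase-appropriate stadial and interstadial fields
#' driven by the normalized isotope proxy:
#' `HEP(t) = (1 - d18O_n(t)) * HEP_GS + d18O_n(t) * HEP_GI`, with the
#' isotope value taken at the nearest 20-year step and the phase selected by
#' `t` relative to the stack's phase boundary (hard switch).
#'
#' @param stack a `pd_hep_stack`.
#' @param iso a `pd_isotope`.
#' @param t_ka time in ka BP (within the series coverage).
#' @return A `pd_field` of accessible HEP.
#' @export
hep_at_time <- function(stack, iso, t_ka) {
  stopifnot(inherits(stack, "pd_hep_stack"), inherits(iso, "pd_isotope"))
  wn <- isotope_at(iso, t_ka)
  ph <- if (t_ka > stack$phase_boundary_ka) "P1" else "P2"
  gs <- stack$fields[[paste0(ph, "_GS")]]
  gi <- stack$fields[[paste0(ph, "_GI")]]
  field(stack$grid, (1 - wn) * gs$values + wn * gi$values, units = "1",
        mask = gs$mask)
}
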