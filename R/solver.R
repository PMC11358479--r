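#' Dispersal model parameters
#'
#' Parameters of the population-dynamics core, with defaults for an Upper
#' Palaeolithic hunter-gatherer culture. Internal units are km, years and
#' persons per 100 km^2.
#'
#' @param rho_c_max cultural carrying capacity, P 100 km^-2 (default 5).
#' @param epsilon,eta Weibull scale and shape of the available-HEP response
#'   (defaults 0.4 and 2.5).
#' @param alpha drift scaling coefficient (default 20, P km^2 yr^-2 as
#'   printed; treated as an opaque calibration constant in internal units).
#'   Alternatively supply `V`, `G`, `tau` (scaling velocity, scaling
#'   available-HEP gradient and response time) and `alpha = V / (G * tau)`.
#' @param gamma drift damping coefficient, yr^-1 (default 0.1).
#' @param d_min,d_max diffusivity bounds, km^2 yr^-1 (defaults 10 and 100).
#' @param kappa,kappa_l,kappa_sigma diffusivity prefactor, length-scale and
#'   velocity-variability coefficients (defaults 1, 1, 0.1).
#' @param r_max maximum net production rate, yr^-1 (default 0.01).
#' @param dt_days numerical time step, days (default 10).
#' @param arrival_threshold density defining first arrival, P 100 km^-2
#'   (default 0.4).
#' @param snapshot_yr output interval, model years (default 10).
#' @param V,G,tau optional scaling triple defining `alpha`.
#' @param grid optional `pd_grid`; if given, the diffusive stability bound
#'   `d_max * dt / min(dx, dy)^2 < 0.25` is checked at construction.
#' @return An object of class `pd_params` (a named list).
#' @export
dispersal_params <- function(rho_c_max = 5, epsilon = 0.4, eta = 2.5,
                             alpha = 20, gamma = 0.1,
                             d_min = 10, d_max = 100,
                             kappa = 1, kappa_l = 1, kappa_sigma = 0.1,
                             r_max = 0.01, dt_days = 10,
                             arrival_threshold = 0.4, snapshot_yr = 10,
                             V = NULL, G = NULL, tau = NULL, grid = NULL) {
  if (!is.null(V) || !is.null(G) || !is.null(tau)) {
    stopifnot(!is.null(V), !is.null(G), !is.null(tau))
    alpha <- V / (G * tau)
  }
  p <- list(rho_c_max = rho_c_max, epsilon = epsilon, eta = eta,
            alpha = alpha, gamma = gamma, d_min = d_min, d_max = d_max,
            kappa = kappa, kappa_l = kappa_l, kappa_sigma = kappa_sigma,
            r_max = r_max, dt_days = dt_days,
            arrival_threshold = arrival_threshold, snapshot_yr = snapshot_yr)
  num <- unlist(p)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all dispersal parameters must be positive and finite", call. = FALSE)
  if (d_min > d_max) stop("d_min must not exceed d_max", call. = FALSE)
  if (eta <= 1) stop("Weibull shape eta must exceed 1", call. = FALSE)
  p$dt_yr <- dt_days / 365.25
  if (!is.null(grid)) {
    h <- min(min(grid$dx), grid$dy)
    if (d_max * p$dt_yr / h^2 >= 0.25)
      stop(sprintf(
        "diffusive stability bound violated: d_max*dt/h^2 = %.3g >= 0.25 (h = %.3g km)",
        d_max * p$dt_yr / h^2, h), call. = FALSE)
  }
  structure(p, class = "pd_params")
}

#' Gaussian initial population
#'
#' Seeds the run with a population whose density is a Gaussian of
#' great-circle distance to a center point, restricted to land and scaled so
#' that the domain total equals `total_population` persons. The drift
#' velocity starts at zero.
#'
#' @param grid a `pd_grid`.
#' @param land logical land mask matrix.
#' @param center `c(lon, lat)` of the seeding center, degrees; must be on
#'   land (default `c(35, 32.5)`, the Levant).
#' @param spread_km Gaussian standard deviation, km (default 150).
#' @param total_population persons (default 5000).
#' @return An object of class `pd_state`: list with matrices `rho`
#'   (P 100 km^-2), `vx`, `vy` (km yr^-1) and `time_ka = NA` until attached
#'   to a run.
#' @export
init_population <- function(grid, land, center = c(35, 32.5),
                            spread_km = 150, total_population = 5000) {
  stopifnot(inherits(grid, "pd_grid"), spread_km > 0, total_population >= 0)
  loc <- locate_cells(grid, center[1], center[2])
  if (is.na(loc$cell)) stop("seeding center outside the domain", call. = FALSE)
  if (!land[loc$i, loc$j])
    stop("seeding center falls on a water cell", call. = FALSE)
  pts <- cbind(rep(grid$lon, grid$nlat), rep(grid$lat, each = grid$nlon))
  d_km <- geosphere::distHaversine(pts, center,
                                   r = grid$earth_radius * 1000) / 1000
  rho <- matrix(exp(-d_km^2 / (2 * spread_km^2)), grid$nlon, grid$nlat)
  rho[!land] <- 0
  persons <- sum(rho * grid$area) / 100
  rho <- if (persons > 0) rho * (total_population / persons) else rho * 0
  structure(list(rho = rho, vx = matrix(0, grid$nlon, grid$nlat),
                 vy = matrix(0, grid$nlon, grid$nlat), time_ka = NA_real_),
            class = "pd_state")
}

# metric-aware centered gradient on a raw matrix (one-sided at edges/mask)
gradient_m <- function(grid, m, land = NULL) {
  if (!is.null(land)) m[!land] <- NA_real_
  dxm <- lat_mat(grid, grid$dx)
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
  list(u = comp(shift_lon(m, 1L), shift_lon(m, -1L), dxm),
       v = comp(shift_lat(m, 1L), shift_lat(m, -1L), grid$dy))
}

#' Damped drift-velocity update
#'
#' Integrates `dv/dt = alpha * grad(Phi_Av) - gamma * v` over one step with
#' the exact exponential-Euler formula for piecewise-constant forcing:
#' `v <- v * exp(-gamma dt) + (alpha/gamma) * (1 - exp(-gamma dt)) * grad`,
#' which is unconditionally stable and bounded by `|alpha grad| / gamma`.
#'
#' @param state a `pd_state`.
#' @param grad list with matrices `u`, `v`: gradient of available HEP
#'   (P 100 km^-2 per km), e.g. from [field_gradient()].
#' @param params a `pd_params`.
#' @param dt_yr step length in years (default the configured step).
#' @return The state with updated `vx`, `vy`.
#' @export
update_velocity <- function(state, grad, params, dt_yr = params$dt_yr) {
  decay <- exp(-params$gamma * dt_yr)
  gain <- params$alpha / params$gamma * (1 - decay)
  state$vx <- state$vx * decay + gain * grad$u
  state$vy <- state$vy * decay + gain * grad$v
  state
}

#' Velocity-dependent diffusivity
#'
#' `D = kappa * l * sigma_v` with sub-grid length scale
#' `l = kappa_l * sqrt(dx dy)` and velocity variability
#' `sigma_v = kappa_sigma * |v|`, clipped to the configured
#' `[d_min, d_max]` range.
#'
#' @param state a `pd_state` (uses `vx`, `vy`).
#' @param grid a `pd_grid`.
#' @param params a `pd_params`.
#' @return Matrix of diffusivities, km^2 yr^-1.
#' @export
diffusivity <- function(state, grid, params) {
  l <- params$kappa_l * sqrt(lat_mat(grid, grid$dx) * grid$dy)
  sigma_v <- params$kappa_sigma * sqrt(state$vx^2 + state$vy^2)
  d <- params$kappa * l * sigma_v
  d[d < params$d_min] <- params$d_min
  d[d > params$d_max] <- params$d_max
  d
}

#' Conservative transport step (advection + diffusion)
#'
#' One explicit finite-volume update of the density under drift and
#' diffusion: first-order upwind advective fluxes and centered diffusive
#' fluxes across cell faces, with spherical face lengths and cell areas.
#' Water cells and domain boundaries are no-flux, so the domain total
#' `sum(rho * area)` is conserved to rounding and positivity is preserved
#' under the stability bounds, which are checked every call
#' (`max|v| dt / min(dx, dy) < 1` and `D dt / min(dx, dy)^2 < 0.25`).
#'
#' @param state a `pd_state`.
#' @param d_field diffusivity matrix (km^2 yr^-1) or scalar.
#' @param grid a `pd_grid`.
#' @param land logical land mask.
#' @param params a `pd_params`.
#' @param dt_yr step length in years.
#' @return The state with updated `rho`.
#' @export
advect_diffuse <- function(state, d_field, grid, land, params,
                           dt_yr = params$dt_yr) {
  nlon <- grid$nlon; nlat <- grid$nlat
  rho <- state$rho
  if (length(d_field) == 1) d_field <- matrix(d_field, nlon, nlat)

  h <- min(min(grid$dx), grid$dy)
  vmax <- max(abs(state$vx), abs(state$vy))
  if (vmax * dt_yr / h >= 1) {
    bad <- which(pmax(abs(state$vx), abs(state$vy)) == vmax, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "advective stability violated at cell (%d, %d): |v| = %.3g km/yr, CFL = %.3g",
      bad[1], bad[2], vmax, vmax * dt_yr / h), call. = FALSE)
  }
  dmax <- max(d_field)
  if (dmax * dt_yr / h^2 >= 0.25) {
    bad <- which(d_field == dmax, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "diffusive stability violated at cell (%d, %d): D = %.3g km^2/yr, D dt/h^2 = %.3g",
      bad[1], bad[2], dmax, dmax * dt_yr / h^2), call. = FALSE)
  }

  tend <- matrix(0, nlon, nlat)

  if (nlon > 1) {
    # east faces between i and i+1; open only between two land cells
    iw <- 1:(nlon - 1)
    open <- land[iw, , drop = FALSE] & land[iw + 1, , drop = FALSE]
    ue <- 0.5 * (state$vx[iw, , drop = FALSE] + state$vx[iw + 1, , drop = FALSE])
    up <- ifelse(ue > 0, rho[iw, , drop = FALSE], rho[iw + 1, , drop = FALSE])
    dxf <- lat_mat(grid, grid$dx)[iw, , drop = FALSE]
    df <- 0.5 * (d_field[iw, , drop = FALSE] + d_field[iw + 1, , drop = FALSE])
    fe <- (ue * up - df * (rho[iw + 1, , drop = FALSE] -
                             rho[iw, , drop = FALSE]) / dxf) * grid$len_we
    fe[!open] <- 0
    tend[iw, ] <- tend[iw, , drop = FALSE] - fe
    tend[iw + 1, ] <- tend[iw + 1, , drop = FALSE] + fe
  }
  if (nlat > 1) {
    # north faces between j and j+1 at latitude face j+1
    js <- 1:(nlat - 1)
    open <- land[, js, drop = FALSE] & land[, js + 1, drop = FALSE]
    vn <- 0.5 * (state$vy[, js, drop = FALSE] + state$vy[, js + 1, drop = FALSE])
    up <- ifelse(vn > 0, rho[, js, drop = FALSE], rho[, js + 1, drop = FALSE])
    df <- 0.5 * (d_field[, js, drop = FALSE] + d_field[, js + 1, drop = FALSE])
    lenf <- matrix(rep(grid$len_sn[js + 1], each = nlon), nlon, nlat - 1)
    fn <- (vn * up - df * (rho[, js + 1, drop = FALSE] -
                             rho[, js, drop = FALSE]) / grid$dy) * lenf
    fn[!open] <- 0
    tend[, js] <- tend[, js, drop = FALSE] - fn
    tend[, js + 1] <- tend[, js + 1, drop = FALSE] + fn
  }

  rho <- rho + dt_yr * tend / grid$area
  rho[!land] <- 0
  state$rho <- rho
  state
}

#' Logistic growth step (exact per-cell solution)
#'
#' Net production follows the logistic law `p = r rho (1 - rho / rho_c)`
#' with growth rate `r = r_max * Phi_Av / rho_c_max`. The step applies the
#' closed-form logistic solution over `dt` per cell (not an Euler step), so
#' it is exact for constant rate and unconditionally stable; densities above
#' `rho_c` relax down towards it. Uninhabitable cells (`rho_c = 0`) decay
#' exponentially at rate `r_max`.
#'
#' @param state a `pd_state`.
#' @param rho_c carrying-capacity matrix, P 100 km^-2.
#' @param phi_av available-HEP matrix, P 100 km^-2.
#' @param params a `pd_params`.
#' @param dt_yr step length in years.
#' @return The state with updated `rho`.
#' @export
grow_population <- function(state, rho_c, phi_av, params,
                            dt_yr = params$dt_yr) {
  rho <- state$rho
  r <- params$r_max * phi_av / params$rho_c_max
  hab <- rho_c > 0
  if (any(hab)) {
    e <- exp(r[hab] * dt_yr)
    rc <- rho_c[hab]
    ro <- rho[hab]
    rho[hab] <- rc * ro * e / (rc + ro * (e - 1))
  }
  if (any(!hab)) rho[!hab] <- rho[!hab] * exp(-params$r_max * dt_yr)
  state$rho <- rho
  state
}

#' Run the dispersal simulation
#'
#' Integrates the population equation forward in time from `start_ka` to
#' `end_ka` under time-varying accessible HEP. Each 10-day step refreshes
#' the HEP blend whenever the 20-year isotope step changes, then computes
#' the carrying capacity and available HEP, updates the drift velocity and
#' diffusivity, applies the conservative transport step and the exact
#' logistic growth step. Snapshots (density, velocity, diffusivity), the
#' total-population series Lambda(t), the mobility index M(t) and the
#' first-arrival map are recorded every `snapshot_yr` model years. The run
#' is fully deterministic given its configuration.
#'
#' @param grid a `pd_grid`.
#' @param land logical land mask.
#' @param stack a `pd_hep_stack` of accessible HEP.
#' @param iso a `pd_isotope` forcing series covering the run.
#' @param params a `pd_params`.
#' @param start_ka,end_ka run interval in ka BP, `start_ka > end_ka`
#'   (defaults 45 and 43).
#' @param init initial state from [init_population()], or a list of
#'   arguments for it (e.g. `list(center = c(35, 32.5), spread_km = 150,
#'   total_population = 5000)`).
#' @param store_velocity also keep velocity and diffusivity snapshots so
#'   that flux fields can be reconstructed at snapshot times (default TRUE).
#' @return An object of class `pd_run`: snapshot times (ka), `lambda` and
#'   `mobility` series, `snapshots` (list of density matrices), optional
#'   `v_snapshots`, the arrival-time matrix (ka, `NA` = never reached), the
#'   final state, and the full configuration.
#' @export
run_dispersal <- function(grid, land, stack, iso, params = dispersal_params(),
                          start_ka = 45, end_ka = 43, init = list(),
                          store_velocity = TRUE) {
  stopifnot(inherits(grid, "pd_grid"), inherits(stack, "pd_hep_stack"),
            inherits(iso, "pd_isotope"), inherits(params, "pd_params"))
  if (start_ka <= end_ka) stop("start_ka must exceed end_ka", call. = FALSE)
  state <- if (inherits(init, "pd_state")) init
  else do.call(init_population, c(list(grid = grid, land = land), init))

  dt <- params$dt_yr
  duration <- (start_ka - end_ka) * 1000
  n_steps <- ceiling(duration / dt - 1e-9)
  w_max <- weibull_w(weibull_mode(params$epsilon, params$eta),
                     params$epsilon, params$eta)

  avail_m <- function(rho, rc) {
    out <- matrix(0, grid$nlon, grid$nlat)
    pos <- rc > 0 & rho > 0
    if (any(pos)) {
      x <- rho[pos] / rc[pos]
      out[pos] <- weibull_w(x, params$epsilon, params$eta) / w_max * rc[pos]
    }
    out
  }

  refresh_hep <- function(t_ka) {
    phi_ac <- hep_at_time(stack, iso, t_ka)$values
    phi_ac[!land] <- 0
    phi_ac
  }

  snap_times <- c()
  lambda <- c()
  mobility <- c()
  snapshots <- list()
  v_snapshots <- if (store_velocity) list()
  arrival <- matrix(NA_real_, grid$nlon, grid$nlat)

  record <- function(elapsed, state, d_field) {
    t_ka <- start_ka - elapsed / 1000
    snap_times[[length(snap_times) + 1]] <<- t_ka
    lambda[[length(lambda) + 1]] <<- sum(state$rho * grid$area) / 100
    gr <- gradient_m(grid, state$rho, land)
    fx <- (state$vx * state$rho - d_field * gr$u) / 100   # P km^-1 yr^-1
    fy <- (state$vy * state$rho - d_field * gr$v) / 100
    mobility[[length(mobility) + 1]] <<- sum(sqrt(fx^2 + fy^2)[land])
    snapshots[[length(snapshots) + 1]] <<- state$rho
    if (store_velocity)
      v_snapshots[[length(v_snapshots) + 1]] <<-
        list(vx = state$vx, vy = state$vy, d = d_field)
    hit <- is.na(arrival) & state$rho >= params$arrival_threshold & land
    arrival[hit] <<- t_ka
  }

  elapsed <- 0
  iso_step <- -1L
  phi_ac <- NULL
  rho_c <- NULL
  d_field <- diffusivity(state, grid, params)
  record(0, state, d_field)
  next_snap <- params$snapshot_yr

  for (s in seq_len(n_steps)) {
    t_ka <- start_ka - elapsed / 1000
    step_now <- as.integer(floor(elapsed / 20))
    if (step_now != iso_step) {
      phi_ac <- refresh_hep(t_ka)
      rho_c <- params$rho_c_max * phi_ac
      iso_step <- step_now
    }
    phi_av <- avail_m(state$rho, rho_c)
    grad <- gradient_m(grid, phi_av, land)
    state <- update_velocity(state, grad, params, dt)
    state$vx[!land] <- 0
    state$vy[!land] <- 0
    d_field <- diffusivity(state, grid, params)
    state <- advect_diffuse(state, d_field, grid, land, params, dt)
    state <- grow_population(state, rho_c, phi_av, params, dt)
    elapsed <- elapsed + dt
    if (elapsed >= next_snap - 1e-9 || s == n_steps) {
      record(elapsed, state, d_field)
      next_snap <- next_snap + params$snapshot_yr
    }
  }
  state$time_ka <- start_ka - elapsed / 1000

  structure(list(
    grid = grid, land = land,
    times_ka = unlist(snap_times),
    lambda = unlist(lambda), mobility = unlist(mobility),
    snapshots = snapshots, v_snapshots = v_snapshots,
    arrival = arrival, final_state = state, params = params,
    start_ka = start_ka, end_ka = end_ka,
    init = if (inherits(init, "pd_state")) list() else init
  ), class = "pd_run")
}

#' @export
print.pd_run <- function(x, ...) {
  cat(sprintf(
    "<pd_run> %g-%g ka, %d snapshots, final Lambda = %.0f persons\n",
    x$start_ka, x$end_ka, length(x$times_ka),
    x$lambda[length(x$lambda)]))
  invisible(x)
}

#' Tidy a dispersal run
#'
#' @param x a `pd_run`.
#' @param ... unused.
#' @return Tibble with `time_ka`, `lambda` (persons) and `mobility`
#'   (`tidy`), or a one-row run summary (`glance`).
#' @export
tidy.pd_run <- function(x, ...) {
  tibble::tibble(time_ka = x$times_ka, lambda = x$lambda,
                 mobility = x$mobility)
}

#' @rdname tidy.pd_run
#' @export
glance.pd_run <- function(x, ...) {
  tibble::tibble(start_ka = x$start_ka, end_ka = x$end_ka,
                 n_snapshots = length(x$times_ka),
                 lambda_final = x$lambda[length(x$lambda)],
                 lambda_max = max(x$lambda),
                 cells_reached = sum(!is.na(x$arrival)))
}

#' @rdname autoplot-paleodisp
#' @export
autoplot.pd_run <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("lambda", "mobility"),
                        names_to = "series", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$time_ka, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "time (ka BP)", y = NULL)
}
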