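#' Build a perturbed-parameter ensemble specification
#'
#' Full-factorial design over the key dispersal parameters: the cultural
#' carrying capacity `rho_c_max`, the drift scaling `alpha` and the
#' diffusivity range (perturbed by a common scale factor on both bounds).
#' Defaults are 5 evenly spaced levels per parameter spanning +/-50% of the
#' base value, giving 5 x 5 x 5 = 125 members.
#'
#' @param base a `pd_params` base configuration.
#' @param ranges named list of `c(lo, hi)` multiplier-free ranges for
#'   `rho_c_max` and `alpha`, and of the dimensionless `d_scale` factor
#'   applied to both diffusivity bounds. Defaults to +/-50% around the base.
#' @param levels integer number of levels per parameter (length 1 or 3,
#'   order `rho_c_max`, `alpha`, `d_scale`; default 5).
#' @param base_seed integer recorded in the spec for provenance.
#' @return An object of class `pd_ensemble_spec` with a `members` manifest
#'   tibble (member id + parameter values) and the base configuration.
#' @export
build_ensemble <- function(base = dispersal_params(), ranges = NULL,
                           levels = 5, base_seed = 1L) {
  stopifnot(inherits(base, "pd_params"))
  ranges <- ranges %||% list(
    rho_c_max = c(0.5, 1.5) * base$rho_c_max,
    alpha = c(0.5, 1.5) * base$alpha,
    d_scale = c(0.5, 1.5))
  if (length(levels) == 1) levels <- rep(levels, 3)
  stopifnot(length(levels) == 3, all(levels >= 1))
  vals <- purrr::map2(ranges[c("rho_c_max", "alpha", "d_scale")], levels,
                      function(r, k) {
    if (any(r <= 0) || r[1] > r[2]) stop("ranges must be positive and ordered",
                                         call. = FALSE)
    if (r[1] == r[2] && k > 1)
      stop("zero-width range with more than one level", call. = FALSE)
    if (k == 1) mean(r) else seq(r[1], r[2], length.out = k)
  })
  members <- tidyr::expand_grid(rho_c_max = vals$rho_c_max,
                                alpha = vals$alpha,
                                d_scale = vals$d_scale)
  members$member <- seq_len(nrow(members))
  structure(list(members = members[c("member", "rho_c_max", "alpha", "d_scale")],
                 base = base, base_seed = base_seed),
            class = "pd_ensemble_spec")
}

#' @export
print.pd_ensemble_spec <- function(x, ...) {
  cat(sprintf("<pd_ensemble_spec> %d members over rho_c_max, alpha, D\n",
              nrow(x$members)))
  invisible(x)
}

# parameters of one ensemble member
member_params <- function(spec, k) {
  row <- spec$members[spec$members$member == k, ]
  b <- spec$base
  dispersal_params(
    rho_c_max = row$rho_c_max, epsilon = b$epsilon, eta = b$eta,
    alpha = row$alpha, gamma = b$gamma,
    d_min = b$d_min * row$d_scale, d_max = b$d_max * row$d_scale,
    kappa = b$kappa, kappa_l = b$kappa_l, kappa_sigma = b$kappa_sigma,
    r_max = b$r_max, dt_days = b$dt_days,
    arrival_threshold = b$arrival_threshold, snapshot_yr = b$snapshot_yr)
}

#' Run a perturbed-parameter ensemble
#'
#' Runs every member independently (results are order-invariant and each
#' member is reproducible from its manifest row) and summarises the member
#' population series and arrival maps: ensemble mean and population standard
#' deviation of Lambda(t), and cellwise mean/sd of the first-arrival times.
#' A failing member is recorded with a warning and the summary is computed
#' over the completed members.
#'
#' @param spec a `pd_ensemble_spec`.
#' @param grid,land,stack,iso,start_ka,end_ka,init as in [run_dispersal()].
#' @return An object of class `pd_ensemble_run`: `runs` (list, `NULL` for
#'   failed members), `manifest`, `lambda_summary` tibble
#'   (time_ka/mean/sd), `arrival_maps` (list of `pd_field`s), `failed`.
#' @export
run_ensemble <- function(spec, grid, land, stack, iso,
                         start_ka = 45, end_ka = 43, init = list()) {
  stopifnot(inherits(spec, "pd_ensemble_spec"))
  runs <- purrr::map(spec$members$member, function(k) {
    tryCatch(
      run_dispersal(grid, land, stack, iso, member_params(spec, k),
                    start_ka = start_ka, end_ka = end_ka, init = init,
                    store_velocity = FALSE),
      error = function(e) {
        warning(sprintf("ensemble member %d failed: %s", k, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) stop("all ensemble members failed", call. = FALSE)
  done <- runs[ok]

  lam <- vapply(done, function(r) r$lambda, numeric(length(done[[1]]$lambda)))
  lam <- matrix(lam, ncol = length(done))
  lam_mean <- rowMeans(lam)
  lam_sd <- sqrt(pmax(rowMeans(lam^2) - lam_mean^2, 0))
  arrival_maps <- purrr::map(done, arrival_time_map)

  structure(list(
    runs = runs, manifest = spec$members, spec = spec,
    lambda_summary = tibble::tibble(time_ka = done[[1]]$times_ka,
                                    mean = lam_mean, sd = lam_sd),
    arrival_maps = arrival_maps,
    failed = spec$members$member[!ok]
  ), class = "pd_ensemble_run")
}

#' @export
print.pd_ensemble_run <- function(x, ...) {
  cat(sprintf("<pd_ensemble_run> %d/%d members completed\n",
              sum(!vapply(x$runs, is.null, logical(1))), length(x$runs)))
  invisible(x)
}

#' Tidy an ensemble run
#'
#' @param x a `pd_ensemble_run`.
#' @param ... unused.
#' @return The manifest joined with each member's final population
#'   (`tidy`), or the Lambda(t) summary (`glance` returns a one-row
#'   overview).
#' @export
tidy.pd_ensemble_run <- function(x, ...) {
  lam <- vapply(x$runs, function(r)
    if (is.null(r)) NA_real_ else r$lambda[length(r$lambda)], numeric(1))
  dplyr::mutate(x$manifest, lambda_final = lam,
                completed = !is.na(lam))
}

#' @rdname tidy.pd_ensemble_run
#' @export
glance.pd_ensemble_run <- function(x, ...) {
  tibble::tibble(n_members = nrow(x$manifest),
                 n_failed = length(x$failed),
                 lambda_mean_final = x$lambda_summary$mean[nrow(x$lambda_summary)],
                 lambda_sd_final = x$lambda_summary$sd[nrow(x$lambda_summary)])
}
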