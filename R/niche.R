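#' Default bioclimatic predictor set
#'
#' The four bioclimatic predictors used by the niche model: annual mean
#' temperature (bio1), temperature seasonality (bio4), precipitation of the
#' wettest month (bio13) and precipitation seasonality (bio15).
#' @export
pd_bioclim_vars <- c("bio1", "bio4", "bio13", "bio15")

#' Standardize a predictor
#'
#' Centers and scales a raw predictor to zero mean and unit standard
#' deviation, keeping the statistics so that prediction-time inputs can be
#' transformed with the training statistics.
#'
#' @param x numeric vector with at least two distinct values.
#' @return A list with `values` (standardized), `center` and `scale`.
#' @seealso [standardize_apply()]
#' @export
standardize <- function(x) {
  if (length(unique(x[is.finite(x)])) < 2)
    stop("degenerate predictor: fewer than two distinct values", call. = FALSE)
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("degenerate predictor: zero variance", call. = FALSE)
  list(values = (x - m) / s, center = m, scale = s)
}

#' Apply stored standardization statistics to new values
#'
#' @param x numeric vector of raw values.
#' @param center,scale statistics from [standardize()].
#' @return Standardized values `(x - center) / scale`.
#' @export
standardize_apply <- function(x, center, scale) (x - center) / scale

#' Build a standardized predictor set from per-cell climate values
#'
#' Bins the climate records to grid cells, keeps one record per cell, and
#' standardizes each predictor over the supplied cells. The standardized
#' columns are prefixed `z_`; the raw columns are kept for the a-priori
#' absence rules.
#'
#' @param climate data frame with `lon`, `lat` and the raw predictor columns.
#' @param grid a `pd_grid`.
#' @param vars predictor column names (default [pd_bioclim_vars]).
#' @return An object of class `pd_predictors`: list with `data` (tibble with
#'   cell indices, raw and `z_` columns) and `stats` (tibble var/center/scale).
#' @export
make_predictor_set <- function(climate, grid, vars = pd_bioclim_vars) {
  stopifnot(inherits(grid, "pd_grid"), all(vars %in% names(climate)))
  loc <- locate_cells(grid, climate$lon, climate$lat)
  if (anyNA(loc$cell)) stop("climate records outside the grid domain", call. = FALSE)
  if (anyDuplicated(loc$cell)) stop("more than one climate record per cell", call. = FALSE)
  d <- dplyr::bind_cols(loc[c("i", "j", "cell")],
                        tibble::as_tibble(climate)[c("lon", "lat", vars)])
  stats <- purrr::map(vars, function(v) {
    s <- standardize(d[[v]])
    d[[paste0("z_", v)]] <<- s$values
    tibble::tibble(var = v, center = s$center, scale = s$scale)
  })
  structure(list(data = d, stats = dplyr::bind_rows(stats), vars = vars),
            class = "pd_predictors")
}

# standardize raw predictor columns of `data` with a stored stats tibble
apply_predictor_stats <- function(data, stats) {
  for (k in seq_len(nrow(stats))) {
    v <- stats$var[k]
    data[[paste0("z_", v)]] <-
      standardize_apply(data[[v]], stats$center[k], stats$scale[k])
  }
  data
}

#' Build presence/absence records for niche-model training
#'
#' Aggregates predictor cells into spatial blocks of `block_size` degrees
#' (the default equals the grid resolution, so blocks are grid cells), then
#' labels each block:
#' \itemize{
#' \item presence: blocks containing at least one site (several sites in one
#'   block are downsampled to a single presence record);
#' \item a-priori absence: site-free blocks whose annual mean temperature is
#'   outside `apriori$bio1` or whose wettest-month precipitation is outside
#'   `apriori$bio13`;
#' \item pseudo-absence: everything else, handled by `option` --
#'   1: excluded; 2: one third labelled 0 and one third labelled 1 (random,
#'   seeded), one third excluded; 3: labelled 1 with probability
#'   `N_p / (N_p + N_pa)`, else 0 (random, seeded).
#' }
#'
#' @param sites data frame with `lon`, `lat` (and optionally `id`, `phase`).
#' @param predictors a `pd_predictors` from [make_predictor_set()].
#' @param block_size block edge in degrees, at least the grid resolution.
#' @param option pseudo-absence option, 1, 2 or 3 (default 3).
#' @param seed integer seed for the random pseudo-absence labelling.
#' @param apriori list of inclusive habitable ranges for the raw rules,
#'   default `list(bio1 = c(-2, 16), bio13 = c(30, 250))` (degC, mm).
#' @param grid the `pd_grid` the predictors live on.
#' @return An object of class `pd_pa`: list with `records` (tibble: block,
#'   cell, lon, lat, label, provenance, `z_` predictor columns), counts
#'   `n_p`, `n_pa`, the standardization `stats`, `vars` and `block_size`.
#' @export
build_presence_absence <- function(sites, predictors, grid,
                                   block_size = grid$resolution,
                                   option = 3, seed = NULL,
                                   apriori = list(bio1 = c(-2, 16),
                                                  bio13 = c(30, 250))) {
  stopifnot(inherits(predictors, "pd_predictors"), option %in% 1:3)
  if (block_size < grid$resolution - 1e-9)
    stop("block_size must be at least the grid resolution", call. = FALSE)
  d <- predictors$data
  zvars <- paste0("z_", predictors$vars)

  block_of <- function(lon, lat) {
    bi <- floor((lon - grid$lon_range[1]) / block_size)
    bj <- floor((lat - grid$lat_range[1]) / block_size)
    paste(bi, bj, sep = "_")
  }
  d$block <- block_of(d$lon, d$lat)

  sloc <- locate_cells(grid, sites$lon, sites$lat)
  if (anyNA(sloc$cell)) stop("sites outside the model domain", call. = FALSE)
  site_blocks <- unique(block_of(sites$lon, sites$lat))

  blocks <- d |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(
      cell = .data$cell[1], lon = mean(.data$lon), lat = mean(.data$lat),
      dplyr::across(dplyr::all_of(c(predictors$vars, zvars)), mean),
      .groups = "drop")

  is_presence <- blocks$block %in% site_blocks
  outside <- function(x, rng) x < rng[1] | x > rng[2]
  is_apriori <- !is_presence &
    (outside(blocks$bio1, apriori$bio1) | outside(blocks$bio13, apriori$bio13))
  is_pseudo <- !is_presence & !is_apriori

  n_p <- sum(is_presence)
  n_pa <- sum(is_pseudo)
  if (n_p == 0) stop("no presence blocks: cannot fit a niche model", call. = FALSE)

  blocks$label <- NA_integer_
  blocks$label[is_presence] <- 1L
  blocks$label[is_apriori] <- 0L
  blocks$provenance <- dplyr::case_when(
    is_presence ~ "presence",
    is_apriori ~ "a-priori-absence",
    TRUE ~ "pseudo-absence")

  if (option == 1) {
    keep <- !is_pseudo
  } else if (option == 2) {
    keep <- rep(TRUE, nrow(blocks))
    idx <- which(is_pseudo)
    lab <- with_seed(seed, {
      third <- floor(length(idx) / 3)
      pool <- c(rep(0L, third), rep(1L, third),
                rep(NA_integer_, length(idx) - 2L * third))
      sample(pool)
    })
    blocks$label[idx] <- lab
    keep[idx] <- !is.na(lab)
  } else {
    keep <- rep(TRUE, nrow(blocks))
    p1 <- n_p / (n_p + n_pa)
    blocks$label[is_pseudo] <-
      with_seed(seed, as.integer(stats::runif(n_pa) < p1))
  }

  records <- blocks[keep, c("block", "cell", "lon", "lat", "label",
                            "provenance", zvars)]
  structure(list(records = records, n_p = n_p, n_pa = n_pa,
                 stats = predictors$stats, vars = predictors$vars,
                 block_size = block_size, option = option),
            class = "pd_pa")
}

#' @export
print.pd_pa <- function(x, ...) {
  cat(sprintf(
    "<pd_pa> %d records (%d presence, %d a-priori absence, %d pseudo-absence kept), option %d, block %g deg\n",
    nrow(x$records), sum(x$records$provenance == "presence"),
    sum(x$records$provenance == "a-priori-absence"),
    sum(x$records$provenance == "pseudo-absence"), x$option, x$block_size))
  invisible(x)
}

# quadratic feature expansion of a matrix of standardized predictors:
# columns 1 (intercept), P, then for i <= j: 0.5*Pi^2 (i == j) or Pi*Pj.
quad_features <- function(P) {
  p <- ncol(P)
  cols <- list(matrix(1, nrow(P), 1), P)
  nm <- c("C", colnames(P))
  for (i in seq_len(p)) for (j in i:p) {
    cols <- c(cols, list(if (i == j) 0.5 * P[, i]^2 else P[, i] * P[, j]))
    nm <- c(nm, paste0("A_", i, "_", j))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- nm
  X
}

pa_matrix <- function(records, vars) {
  P <- as.matrix(records[paste0("z_", vars)])
  colnames(P) <- vars
  P
}

#' Fit the quadratic logistic niche model
#'
#' Maximum-likelihood fit of the environment-suitability model
#' `Phi_E = 1 / (1 + exp(-q))` with `q(P) = 0.5 P' A P + B.P + C` over the
#' standardized predictors, by Newton iteration (iteratively reweighted
#' least squares) with a small ridge penalty on `A` and `B` (not `C`) to
#' stabilise quasi-separable data.
#'
#' @param pa a `pd_pa` from [build_presence_absence()].
#' @param ridge ridge penalty on the quadratic and linear coefficients
#'   (default 1e-6).
#' @param tol convergence tolerance on the penalized gradient norm
#'   (default 1e-8).
#' @param max_iter maximum Newton iterations (default 200).
#' @return An object of class `pd_niche`: coefficients `A` (symmetric
#'   matrix), `B`, `C`, their joint covariance, the standardization `stats`,
#'   and fit diagnostics.
#' @export
fit_niche <- function(pa, ridge = 1e-6, tol = 1e-8, max_iter = 200) {
  stopifnot(inherits(pa, "pd_pa"))
  fit_niche_records(pa$records, pa$vars, pa$stats, ridge, tol, max_iter)
}

# core Newton fit on a records tibble (label + z_ columns)
fit_niche_records <- function(records, vars, stats,
                              ridge = 1e-6, tol = 1e-8, max_iter = 200) {
  y <- records$label
  if (length(unique(y)) < 2)
    stop("unfittable data: a single class in the labels", call. = FALSE)
  P <- pa_matrix(records, vars)
  X <- quad_features(P)
  k <- ncol(X)
  pen <- ridge * c(0, rep(1, k - 1))        # C unpenalized
  theta <- numeric(k)
  theta[1] <- stats::qlogis(mean(y))        # start at the intercept-only fit
  grad_norm <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% theta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - mu)) - pen * theta
    grad_norm <- sqrt(sum(grad^2))
    if (grad_norm < tol) break
    w <- mu * (1 - mu)
    H <- crossprod(X, X * w) + diag(pen, k)
    step <- tryCatch(solve(H, grad), error = function(e)
      solve(H + diag(1e-8, k), grad))
    theta <- theta + step
  }
  if (grad_norm >= tol) {
    cond <- structure(class = c("pd_fit_error", "error", "condition"),
                      list(message = sprintf(
                        "niche fit did not converge after %d iterations (gradient norm %.3g)",
                        max_iter, grad_norm), call = NULL,
                        grad_norm = grad_norm, theta = theta))
    stop(cond)
  }
  mu <- stats::plogis(drop(X %*% theta))
  H <- crossprod(X, X * (mu * (1 - mu))) + diag(pen, k)
  vcov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, k, k))
  dimnames(vcov) <- list(colnames(X), colnames(X))

  p <- length(vars)
  A <- matrix(0, p, p, dimnames = list(vars, vars))
  idx <- p + 1L
  for (i in seq_len(p)) for (j in i:p) {
    idx <- idx + 1L
    A[i, j] <- theta[idx]
    A[j, i] <- theta[idx]
  }
  structure(list(A = A, B = stats::setNames(theta[2:(p + 1)], vars),
                 C = theta[1], vcov = vcov, theta = theta,
                 feature_names = colnames(X), vars = vars, stats = stats,
                 n = length(y), iterations = it, ridge = ridge,
                 z_range = apply(P, 2, range)),
            class = "pd_niche")
}

#' @export
print.pd_niche <- function(x, ...) {
  cat(sprintf("<pd_niche> quadratic logistic model in %d predictors (%s), n = %d\n",
              length(x$vars), paste(x$vars, collapse = ", "), x$n))
  invisible(x)
}

#' Evaluate the quadratic score q(P) of a niche model
#'
#' @param model a `pd_niche`.
#' @param data data frame with the model's standardized `z_` columns (or a
#'   `pd_predictors`).
#' @param warn_extrapolation flag predictors outside the training range
#'   (default TRUE); the quadratic is still evaluated, never clamped.
#' @return Numeric vector of q values.
#' @export
niche_q <- function(model, data, warn_extrapolation = TRUE) {
  stopifnot(inherits(model, "pd_niche"))
  if (inherits(data, "pd_predictors")) data <- data$data
  P <- as.matrix(data[paste0("z_", model$vars)])
  colnames(P) <- model$vars
  if (warn_extrapolation) {
    lo <- model$z_range[1, ]; hi <- model$z_range[2, ]
    n_out <- sum(sweep(P, 2, lo, `<`) | sweep(P, 2, hi, `>`))
    if (n_out > 0)
      rlang::inform(sprintf(
        "predict_hep: %d predictor values outside the training range; quadratic extrapolation used",
        n_out), .frequency = "once", .frequency_id = "pd_extrapolation")
  }
  drop(quad_features(P) %*% model$theta)
}

#' Predict environment HEP from a fitted niche model
#'
#' `Phi_E = 1 / (1 + exp(-q(P)))` per cell, strictly inside (0, 1) for
#' finite coefficients. Inputs must be standardized with the training
#' statistics (see [make_predictor_set()] and [apply_predictor_stats]).
#'
#' @inheritParams niche_q
#' @return Numeric vector of Phi_E values in (0, 1).
#' @export
predict_hep <- function(model, data, warn_extrapolation = TRUE) {
  stats::plogis(niche_q(model, data, warn_extrapolation))
}

#' @export
predict.pd_niche <- function(object, newdata, ...) predict_hep(object, newdata)

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes.
#'
#' @param predictions probabilities in [0, 1].
#' @param labels binary outcomes of the same length.
#' @return The Brier score.
#' @export
brier_score <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels),
            all(predictions >= 0 & predictions <= 1),
            all(labels %in% c(0, 1)))
  mean((predictions - labels)^2)
}

#' Brier skill score over ensemble members
#'
#' `BSS = (1/N) sum_n (1 - BS_n / BS_0n)` where `BS_n` is the member's
#' held-out Brier score and `BS_0n` the Brier score of the same member with
#' the quadratic and linear coefficients zeroed (intercept-only reference).
#' 1 is a perfect model, 0 matches the reference, negative is worse.
#'
#' @param predictions list (one element per member) of predicted
#'   probabilities, or a single numeric vector.
#' @param labels list of held-out binary labels (or a single vector).
#' @param reference list of reference-model probabilities on the same
#'   held-out records (or a single vector; a constant reference may be given
#'   as length-1).
#' @return The Brier skill score.
#' @export
brier_skill_score <- function(predictions, labels, reference) {
  as_list <- function(x) if (is.list(x)) x else list(x)
  predictions <- as_list(predictions); labels <- as_list(labels)
  reference <- as_list(reference)
  stopifnot(length(predictions) == length(labels),
            length(reference) == length(labels))
  skill <- purrr::pmap_dbl(list(predictions, labels, reference),
                           function(p, y, r) {
    if (length(r) == 1) r <- rep(r, length(y))
    bs0 <- brier_score(r, y)
    if (bs0 == 0) stop("undefined skill: reference Brier score is zero",
                       call. = FALSE)
    1 - brier_score(p, y) / bs0
  })
  mean(skill)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random presence scores
#' above a random absence, with ties counted one half.
#'
#' @param predictions numeric scores.
#' @param labels binary labels (both classes must be present).
#' @return AUC in [0, 1].
#' @export
auc <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("undefined AUC: a single class in the labels", call. = FALSE)
  r <- rank(predictions)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train an ensemble of niche models
#'
#' Repeatedly fits the quadratic logistic model on a random `train_fraction`
#' of the presence/absence records and scores each member on its own
#' held-out remainder (Brier score against the member's intercept-only
#' reference, and AUC). The ensemble-mean and ensemble-standard-deviation
#' `Phi_E` fields are the pointwise mean and (population) standard deviation
#' of the member predictions over the full predictor set, which keeps the
#' mean field inside [0, 1].
#'
#' @param pa a `pd_pa`.
#' @param predictors the full `pd_predictors` set on which to evaluate the
#'   ensemble-mean field.
#' @param n_members number of members (default 1000).
#' @param train_fraction fraction of records used for training (default 0.8).
#' @param seed integer seed controlling the splits.
#' @param ridge,tol,max_iter passed to [fit_niche()].
#' @return An object of class `pd_niche_ens`: `members` (list of `pd_niche`),
#'   `scores` (tibble member/bs/bs0/auc/skill), `hep` (tibble cell/lon/lat/
#'   phi_mean/phi_sd), `bss`, and the training options.
#' @export
train_hep_ensemble <- function(pa, predictors, n_members = 1000,
                               train_fraction = 0.8, seed = NULL,
                               ridge = 1e-6, tol = 1e-8, max_iter = 200) {
  stopifnot(inherits(pa, "pd_pa"), n_members >= 1,
            train_fraction > 0, train_fraction < 1)
  records <- pa$records
  n <- nrow(records)
  n_train <- round(train_fraction * n)
  if (n_train < 2 || n_train > n - 1)
    stop("too few records for the requested split", call. = FALSE)

  with_seed(seed, {
    members <- vector("list", n_members)
    scores <- vector("list", n_members)
    for (m in seq_len(n_members)) {
      split_ok <- FALSE
      for (attempt in 1:100) {
        tr <- sample.int(n, n_train)
        if (length(unique(records$label[tr])) == 2 &&
            length(unique(records$label[-tr])) == 2) { split_ok <- TRUE; break }
      }
      if (!split_ok)
        stop("data imbalance: no valid 80/20 split found in 100 attempts",
             call. = FALSE)
      fit <- fit_niche_records(records[tr, ], pa$vars, pa$stats,
                               ridge = ridge, tol = tol, max_iter = max_iter)
      held <- records[-tr, ]
      pred <- predict_hep(fit, held, warn_extrapolation = FALSE)
      ref <- stats::plogis(fit$C)   # same member with A and B zeroed
      bs <- brier_score(pred, held$label)
      bs0 <- brier_score(rep(ref, nrow(held)), held$label)
      members[[m]] <- fit
      scores[[m]] <- tibble::tibble(
        member = m, bs = bs, bs0 = bs0,
        skill = if (bs0 > 0) 1 - bs / bs0 else NA_real_,
        auc = tryCatch(auc(pred, held$label), error = function(e) NA_real_))
    }
    scores <- dplyr::bind_rows(scores)

    phi <- vapply(members, function(f)
      predict_hep(f, predictors, warn_extrapolation = FALSE),
      numeric(nrow(predictors$data)))
    phi <- matrix(phi, ncol = n_members)
    phi_mean <- rowMeans(phi)
    phi_sd <- sqrt(rowMeans(phi^2) - phi_mean^2)
    phi_sd[phi_sd < 0 | is.na(phi_sd)] <- 0

    hep <- dplyr::bind_cols(predictors$data[c("cell", "i", "j", "lon", "lat")],
                            tibble::tibble(phi_mean = phi_mean, phi_sd = phi_sd))
    structure(list(members = members, scores = scores, hep = hep,
                   bss = mean(scores$skill, na.rm = TRUE),
                   n_members = n_members, train_fraction = train_fraction,
                   seed = seed, vars = pa$vars, stats = pa$stats),
              class = "pd_niche_ens")
  })
}

#' @export
print.pd_niche_ens <- function(x, ...) {
  cat(sprintf("<pd_niche_ens> %d members, BSS %.3f, mean held-out AUC %.3f\n",
              x$n_members, x$bss, mean(x$scores$auc, na.rm = TRUE)))
  invisible(x)
}

#' Ensemble-mean HEP as a gridded field
#'
#' @param ens a `pd_niche_ens`.
#' @param grid the `pd_grid` of the predictor set.
#' @param what `"mean"` or `"sd"`.
#' @return A `pd_field` (dimensionless), masked outside the predictor cells.
#' @export
hep_field <- function(ens, grid, what = c("mean", "sd")) {
  what <- match.arg(what)
  vals <- matrix(0, grid$nlon, grid$nlat)
  mask <- matrix(FALSE, grid$nlon, grid$nlat)
  col <- if (what == "mean") ens$hep$phi_mean else ens$hep$phi_sd
  vals[ens$hep$cell] <- col
  mask[ens$hep$cell] <- TRUE
  field(grid, vals, units = "1", mask = mask)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted niche model
#'
#' One row per coefficient with estimate and standard error. Terms are `C`,
#' the predictor names (linear part `B`) and `A_i_j` (quadratic part).
#'
#' @param x a `pd_niche`.
#' @param ... unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.pd_niche <- function(x, ...) {
  nm <- x$feature_names
  nm[2:(length(x$vars) + 1)] <- x$vars
  tibble::tibble(term = nm, estimate = x$theta,
                 std.error = sqrt(diag(x$vcov)))
}

#' @rdname tidy.pd_niche
#' @export
glance.pd_niche <- function(x, ...) {
  tibble::tibble(n = x$n, iterations = x$iterations, ridge = x$ridge,
                 converged = TRUE)
}

#' Tidy an ensemble of niche models
#'
#' @param x a `pd_niche_ens`.
#' @param ... unused.
#' @return Per-member held-out scores (`tidy`) or a one-row summary
#'   (`glance`).
#' @export
tidy.pd_niche_ens <- function(x, ...) x$scores

#' @rdname tidy.pd_niche_ens
#' @export
glance.pd_niche_ens <- function(x, ...) {
  tibble::tibble(n_members = x$n_members, bss = x$bss,
                 mean_auc = mean(x$scores$auc, na.rm = TRUE),
                 train_fraction = x$train_fraction)
}
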