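test_that("standardization centers, scales, and is reusable at prediction time", {
  s <- standardize(c(1, 2, 3))
  expect_equal(mean(s$values), 0)
  expect_equal(sd(s$values), 1)
  expect_error(standardize(rep(2, 10)), "degenerate")
  expect_equal(standardize_apply(s$center, s$center, s$scale), 0)

  fx <- scenario_fixture()
  d <- fx$inp$predictors$data
  for (v in pd_bioclim_vars) {
    expect_lt(abs(mean(d[[paste0("z_", v)]])), 1e-8)
    expect_lt(abs(sd(d[[paste0("z_", v)]]) - 1), 1e-8)
  }
})

test_that("presence/absence construction follows the labelling rules", {
  g <- build_grid(c(0, 5), c(0, 5), 0.5)
  n <- g$nlon * g$nlat
  set.seed(1)
  climate <- tibble::tibble(
    lon = rep(g$lon, g$nlat), lat = rep(g$lat, each = g$nlon),
    bio1 = rep(8, n), bio4 = rnorm(n, 5), bio13 = rnorm(n, 100, 5),
    bio15 = rnorm(n, 20))
  climate$bio1[1:20] <- -5                       # a-priori cold strip
  pred <- make_predictor_set(climate, g)

  # two sites in one cell downsample to a single presence record
  sites <- tibble::tibble(lon = c(2.1, 2.2, 3.3), lat = c(2.1, 2.2, 3.3))
  pa <- build_presence_absence(sites, pred, g, option = 1)
  expect_equal(sum(pa$records$provenance == "presence"), 2)
  expect_equal(pa$n_p, 2)

  # site-free cold cells are a-priori absences with label 0
  apr <- dplyr::filter(pa$records, .data$provenance == "a-priori-absence")
  expect_equal(nrow(apr), 20)
  expect_true(all(apr$label == 0))

  # option 1 excludes all pseudo-absence cells
  expect_equal(nrow(pa$records), 22)

  # option 2 keeps two thirds of pseudo cells, split between the labels
  pa2 <- build_presence_absence(sites, pred, g, option = 2, seed = 3)
  ps2 <- dplyr::filter(pa2$records, .data$provenance == "pseudo-absence")
  n_pseudo <- n - 22
  expect_equal(nrow(ps2), 2 * floor(n_pseudo / 3))
  expect_equal(sum(ps2$label == 0), floor(n_pseudo / 3))

  # option 3 keeps all pseudo cells, labelled 1 with probability Np/(Np+Npa)
  pa3 <- build_presence_absence(sites, pred, g, option = 3, seed = 3)
  expect_equal(nrow(pa3$records), n)

  expect_error(build_presence_absence(tibble::tibble(lon = 99, lat = 99),
                                      pred, g), "outside")
})

test_that("duplicating every site leaves the records unchanged", {
  fx <- scenario_fixture()
  sites <- fx$inp$sites
  pa1 <- build_presence_absence(sites, fx$inp$predictors, fx$inp$grid,
                                option = 3, seed = 11)
  pa2 <- build_presence_absence(dplyr::bind_rows(sites, sites),
                                fx$inp$predictors, fx$inp$grid,
                                option = 3, seed = 11)
  expect_identical(pa1$records, pa2$records)
  expect_identical(pa1$n_p, pa2$n_p)
})

test_that("option-3 labelling matches its expected presence fraction", {
  fx <- scenario_fixture()
  pa <- build_presence_absence(fx$inp$sites, fx$inp$predictors, fx$inp$grid,
                               option = 3, seed = 5)
  ps <- dplyr::filter(pa$records, .data$provenance == "pseudo-absence")
  expect_gte(nrow(ps), 500)
  p <- pa$n_p / (pa$n_p + pa$n_pa)
  se <- sqrt(p * (1 - p) / nrow(ps))
  expect_lt(abs(mean(ps$label) - p), 3 * se)
})

test_that("larger spatial blocks aggregate cells before labelling", {
  fx <- scenario_fixture()
  pa05 <- build_presence_absence(fx$inp$sites, fx$inp$predictors,
                                 fx$inp$grid, option = 1)
  pa20 <- build_presence_absence(fx$inp$sites, fx$inp$predictors,
                                 fx$inp$grid, block_size = 2, option = 1)
  expect_lt(pa20$n_p, pa05$n_p)
  expect_lt(nrow(pa20$records), nrow(pa05$records))
  expect_error(build_presence_absence(fx$inp$sites, fx$inp$predictors,
                                      fx$inp$grid, block_size = 0.1),
               "block_size")
})

test_that("the quadratic logistic fit recovers known coefficients", {
  truth <- niche_model(A = diag(c(-0.8, -0.3, -0.5, -0.2)),
                       B = c(2.2, -1.2, 1.4, -1.0), C = -0.5)
  pred <- gaussian_predictors(5000, seed = 1)
  pa <- simulate_presence_absence(truth, pred, seed = 1)
  fit <- fit_niche(pa)
  z <- (fit$theta - truth$theta) / sqrt(diag(fit$vcov))
  expect_lt(max(abs(z)), 3)

  # independent oracle: an unpenalized glm on the same feature expansion
  gfit <- stats::glm(
    pa$records$label ~ paleodisp:::quad_features(
      paleodisp:::pa_matrix(pa$records, pa$vars))[, -1],
    family = stats::binomial())
  expect_equal(unname(fit$theta), unname(coef(gfit)), tolerance = 1e-6)
})

test_that("degenerate label sets are rejected", {
  pred <- gaussian_predictors(100, seed = 2)
  zero <- niche_model(A = matrix(0, 4, 4), B = rep(0, 4), C = -50)
  expect_error(fit_niche(simulate_presence_absence(zero, pred, seed = 1)),
               "single class")
})

test_that("labels independent of predictors give near-null fits", {
  truth <- niche_model(A = matrix(0, 4, 4), B = rep(0, 4), C = 0)
  pred <- gaussian_predictors(4000, seed = 3)
  pa <- simulate_presence_absence(truth, pred, seed = 3)   # p = 0.5 everywhere
  fit <- fit_niche(pa)
  expect_lt(max(abs(fit$B)), 0.2)
  expect_lt(max(abs(fit$A)), 0.3)
  ens <- train_hep_ensemble(pa, pred, n_members = 20, seed = 4)
  expect_lt(abs(ens$bss), 0.05)
})

test_that("HEP prediction applies the logistic map to the quadratic score", {
  m0 <- niche_model(A = matrix(0, 4, 4), B = rep(0, 4), C = 0)
  pred <- gaussian_predictors(50, seed = 5)
  expect_equal(predict_hep(m0, pred$data), rep(0.5, 50))

  m1 <- niche_model(A = matrix(0, 4, 4), B = rep(0, 4), C = log(3))
  expect_equal(predict_hep(m1, pred$data), rep(0.75, 50))

  # strictly inside (0,1) and monotone in q
  m2 <- niche_model(A = diag(rep(-0.5, 4)), B = c(2, 0, 0, 0), C = 0)
  q <- niche_q(m2, pred$data, warn_extrapolation = FALSE)
  phi <- predict_hep(m2, pred$data)
  expect_true(all(phi > 0 & phi < 1))
  expect_true(all(diff(phi[order(q)]) >= 0))
})

test_that("ensemble training is deterministic and its spread behaves", {
  truth <- scenario_fixture()$sc$truth
  pred <- gaussian_predictors(600, seed = 6)
  pa <- simulate_presence_absence(truth, pred, seed = 6)

  e1 <- train_hep_ensemble(pa, pred, n_members = 1, seed = 9)
  expect_true(all(e1$hep$phi_sd == 0))

  e2 <- train_hep_ensemble(pa, pred, n_members = 5, seed = 9)
  e3 <- train_hep_ensemble(pa, pred, n_members = 5, seed = 9)
  expect_identical(purrr::map(e2$members, "theta"),
                   purrr::map(e3$members, "theta"))
  expect_true(all(e2$hep$phi_mean >= 0 & e2$hep$phi_mean <= 1))
  expect_true(all(e2$hep$phi_sd >= 0))
})

test_that("Brier score and skill score match their definitions", {
  expect_equal(brier_score(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier_score(c(0.5, 0.5), c(1, 0)), 0.25)
  expect_equal(brier_skill_score(c(1, 0, 1, 0), c(1, 0, 1, 0),
                                 reference = 0.5), 1)
  # a member identical to its reference contributes zero skill
  ref <- rep(0.4, 6)
  y <- c(1, 0, 0, 1, 0, 0)
  expect_equal(brier_skill_score(list(ref, y), list(y, y),
                                 reference = list(ref, ref)),
               mean(c(0, 1 - brier_score(y, y) / brier_score(ref, y))))
  expect_equal(brier_skill_score(ref, y, reference = ref), 0)
  expect_error(brier_skill_score(c(0.3, 0.6), c(1, 0), reference = c(1, 0)),
               "undefined skill")
})

test_that("AUC follows the Mann-Whitney formulation with half ties", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc(c(0.1, 0.9), c(1, 1)), "single class")

  set.seed(10)
  scores <- runif(10000)
  labels <- rbinom(10000, 1, 0.5)
  expect_lt(abs(auc(scores, labels) - 0.5), 0.02)

  # independent oracle: pROC on a tied, unbalanced example
  set.seed(11)
  s2 <- round(runif(300), 1)
  y2 <- rbinom(300, 1, plogis(3 * s2 - 1.5))
  expect_equal(auc(s2, y2),
               as.numeric(pROC::auc(pROC::roc(y2, s2, quiet = TRUE))))
})

test_that("tidy and glance expose coefficients and scores", {
  truth <- scenario_fixture()$sc$truth
  pred <- gaussian_predictors(500, seed = 12)
  pa <- simulate_presence_absence(truth, pred, seed = 12)
  fit <- fit_niche(pa)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(nrow(td), 15)
  expect_equal(glance(fit)$n, 500)

  ens <- train_hep_ensemble(pa, pred, n_members = 3, seed = 13)
  expect_equal(nrow(tidy(ens)), 3)
  expect_named(glance(ens), c("n_members", "bss", "mean_auc", "train_fraction"))
})
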