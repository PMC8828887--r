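test_that("bayes ridge recovers coefficients of a well-conditioned fit", {
  set.seed(31)
  X <- matrix(rnorm(600), 200, 3)
  y <- 2 + X %*% c(1.5, -0.7, 0.3) + rnorm(200, sd = 0.05)
  fit <- bayes_ridge(X, drop(y))
  ols <- coef(lm(y ~ X))
  expect_equal(fit$coef, unname(ols[-1]), tolerance = 0.01)
  expect_equal(fit$intercept, unname(ols[1]), tolerance = 0.01)
  expect_equal(predict(fit, X), drop(y), tolerance = 0.2)
  # strong prior shrinkage on pure noise: coefficients stay near zero
  noise <- bayes_ridge(matrix(rnorm(500), 100, 5), rnorm(100))
  expect_lt(max(abs(noise$coef)), 0.5)
})

test_that("imputation is a no-op without gaps and never alters observed values", {
  net <- bench_network(missing_fraction = 0)
  wide <- ringmap:::wide_series(net$data, "temperature",
                                sort(unique(ringmap:::format_timestamps(net$data$timestamp))),
                                net$sites$site_id)
  res <- iterative_impute(wide[, 1], wide[, -1])
  expect_identical(res$values, unname(wide[, 1]))
  expect_false(any(res$imputed))

  holed <- bench_network(missing_fraction = 0.25)
  wide_h <- ringmap:::wide_series(holed$data, "temperature",
                                  sort(unique(ringmap:::format_timestamps(holed$data$timestamp))),
                                  holed$sites$site_id)
  res_h <- suppressWarnings(iterative_impute(wide_h[, 1], wide_h[, -1]))
  obs <- !is.na(wide_h[, 1])
  expect_identical(res_h$values[obs], unname(wide_h[obs, 1]))  # bit-identical
  expect_identical(res_h$imputed, unname(is.na(wide_h[, 1])))
})

test_that("a perfectly informative covariate reproduces the target at its holes", {
  set.seed(32)
  x <- rnorm(500, 10, 3)
  target <- x
  holes <- sample(500, 125)
  target[holes] <- NA
  res <- iterative_impute(target, cbind(copy = x, other = rnorm(500)))
  expect_equal(res$values[holes], x[holes], tolerance = 0.05)
})

test_that("imputation accuracy grows with inter-site correlation", {
  rhos <- c(0.7, 0.9)
  spearman <- vapply(rhos, function(r) {
    net <- bench_network(rho = r, n_days = 30)
    g <- suppressWarnings(
      scenario_grid(net$data, net$sites, test_sites = "S01",
                    measurements = "temperature", fractions = 0.25,
                    modes = "random"))
    g$spearman_rho[g$resolution == "hourly"]
  }, numeric(1))
  expect_true(all(diff(spearman) > 0))
  expect_gt(spearman[2], 0.8)
})

test_that("a pure-noise covariate barely degrades the fit", {
  net <- bench_network(rho = 0.9, n_days = 30)
  times <- sort(unique(ringmap:::format_timestamps(net$data$timestamp)))
  wide <- ringmap:::wide_series(net$data, "temperature", times, net$sites$site_id)
  truth <- ringmap:::wide_series(net$truth, "temperature", times, net$sites$site_id)
  holes <- is.na(wide[, "S01"])
  base <- suppressWarnings(iterative_impute(wide[, "S01"], wide[, -1]))
  set.seed(33)
  noisy <- suppressWarnings(
    iterative_impute(wide[, "S01"], cbind(wide[, -1], junk = rnorm(nrow(wide)))))
  rho_base <- cor(truth[holes, "S01"], base$values[holes], method = "spearman")
  rho_noisy <- cor(truth[holes, "S01"], noisy$values[holes], method = "spearman")
  expect_gt(rho_noisy, rho_base - 0.05)
})

test_that("network imputation fills retained sites and honours the SO2 opt-out", {
  cfg <- synth_config(n_sites = 5, n_days = 20, rho = 0.9,
                      missing_fraction = 0.2, seed = 7)
  map <- make_region_map(cfg)
  net <- make_sensor_network(map, cfg, measurements = c("NO2", "SO2"),
                             kinds = "pollutant")
  crit <- coverage_criteria(retain_days = 1, reference_days = 15)
  res <- suppressWarnings(impute_network(net$data, net$sites,
                                         c("NO2", "SO2"), criteria = crit))
  expect_false(anyNA(res$data$NO2))                       # every gap filled
  expect_identical(is.na(res$data$SO2), is.na(net$data$SO2))  # SO2 untouched
  expect_false(any(res$mask$SO2))
  obs <- !is.na(net$data$NO2)
  expect_identical(res$data$NO2[obs], net$data$NO2[obs])
  expect_identical(res$mask$NO2, is.na(net$data$NO2))

  # with the opt-in, SO2 gaps fill too
  res2 <- suppressWarnings(impute_network(net$data, net$sites, c("NO2", "SO2"),
                                          config = imputation_config(impute_so2 = TRUE),
                                          criteria = crit))
  expect_false(anyNA(res2$data$SO2))

  # a network without gaps passes through identically
  full <- make_sensor_network(map, synth_config(n_sites = 5, n_days = 20,
                                                missing_fraction = 0, seed = 7))
  res3 <- impute_network(full$data, full$sites, "temperature", criteria = crit)
  expect_identical(res3$data, full$data)
  expect_false(any(res3$mask$temperature))
})

test_that("sites below retention coverage are skipped and logged", {
  cfg <- synth_config(n_sites = 4, n_days = 20, missing_fraction = 0.2, seed = 9)
  map <- make_region_map(cfg)
  net <- make_sensor_network(map, cfg)
  # push one site below any sane retention threshold
  poor <- net$data$site_id == "S04"
  net$data$temperature[poor][-(1:24)] <- NA
  res <- suppressWarnings(impute_network(net$data, net$sites, "temperature",
                                         criteria = coverage_criteria(retain_days = 10,
                                                                      reference_days = 15)))
  lg <- res$log
  expect_true(any(lg$site_id == "S04" & lg$action == "skipped-below-retention"))
  expect_true(anyNA(res$data$temperature[poor]))
})
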