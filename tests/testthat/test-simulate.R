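test_that("bathymetry generator is deterministic and respects its envelope", {
  cfg <- sim_config(grid_nrow = 60, grid_ncol = 80, cell_size = 4,
                    noise_sd = 0, ridges = list(count = 0, amplitude = 0,
                                                wavelength = 1,
                                                along_wavelength = 1),
                    seed = 4)
  g <- generate_bathymetry(cfg)
  # no ridges, no noise: an exact plane falling northward
  sa <- slope_aspect(g)
  sl <- sa$slope$values[2:59, 2:79]
  expect_equal(sl, sl * 0 + sl[1, 1], tolerance = 1e-10)
  expect_equal(sa$aspect$values[30, 40], 0, tolerance = 1e-8)
  expect_true(all(g$values >= min(cfg$depth_range) &
                    g$values <= max(cfg$depth_range)))

  cfg2 <- sim_config(grid_nrow = 50, grid_ncol = 60, seed = 12)
  expect_identical(generate_bathymetry(cfg2)$values,
                   generate_bathymetry(cfg2)$values)
  # ridged, noise-free surface stays within gradient range +/- amplitude
  cfg3 <- sim_config(grid_nrow = 80, grid_ncol = 90, noise_sd = 0,
                     seed = 3)
  g3 <- generate_bathymetry(cfg3)
  expect_true(all(g3$values >= min(cfg3$depth_range) &
                    g3$values <= max(cfg3$depth_range) +
                      cfg3$ridges$amplitude))
  expect_error(sim_config(grid_nrow = 0), "positive")
})

test_that("site sampling honours minimum spacing, strata and determinism", {
  cfg <- sim_config(grid_nrow = 100, grid_ncol = 150, cell_size = 4,
                    seed = 6)
  g <- generate_bathymetry(cfg)
  s <- sample_sites(g, n_sites = 50, min_spacing = 40, seed = 20)
  expect_equal(nrow(s), 50)
  D <- as.matrix(dist(cbind(s$x, s$y)))
  expect_true(all(D[upper.tri(D)] >= 40))  # exhaustive O(n^2) check
  expect_equal(sort(unique(s$stratum)), 1:4)

  s2 <- sample_sites(g, n_sites = 50, min_spacing = 40, seed = 20)
  expect_identical(s, s2)

  expect_equal(nrow(sample_sites(g, 1, 0, seed = 1)), 1)
  expect_equal(nrow(sample_sites(g, 30, 0, seed = 2)), 30)
  # a 400 m x 600 m domain cannot hold 50 sites 400 m apart
  expect_error(sample_sites(g, 50, 400, seed = 3, max_tries = 50),
               "infeasible")
})

test_that("simulated MaxN matches its negative binomial law", {
  # intercept-only truth on a large site set: mean, dispersion and the
  # zero fraction all match the analytic NB values
  cfg <- sim_config(grid_nrow = 80, grid_ncol = 80, cell_size = 4,
                    seed = 8)
  g <- generate_bathymetry(cfg)
  st <- derive_terrain(g)
  sites <- sample_sites(st$layers$bathymetry, 600, 0, seed = 9)
  covs <- sample_covariates(st, sites)
  beta0 <- 0.9; theta <- 2
  truth <- list(species_truth(
    "flat",
    abundance = list(intercept = beta0, effects = list(), theta = theta),
    biomass = list(intercept = 6, effects = list(), shape = 2),
    lw = lw_params("flat", 1e-5, 3, cutoff_g = 500)
  ))
  surv <- simulate_fish(covs, truth, seed = 10)
  y <- surv$maxn$maxn
  n <- length(y)
  mu <- exp(beta0)
  se_mean <- sqrt(mu + mu^2 / theta) / sqrt(n)
  expect_lt(abs(mean(y) - mu), 3 * se_mean)
  p0 <- (theta / (theta + mu))^theta
  expect_lt(abs(mean(y == 0) - p0), 3 * sqrt(p0 * (1 - p0) / n))

  # biomass is strictly positive and lengths invert the power law
  expect_true(all(surv$individuals$biomass_g > 0))
  expect_equal(
    length_to_biomass(surv$individuals$fork_length_mm, truth[[1]]$lw),
    surv$individuals$biomass_g, tolerance = 1e-6)
  # per-site individual counts equal MaxN
  per_site <- table(factor(surv$individuals$site_id,
                           levels = surv$sites$site_id))
  expect_equal(as.integer(per_site), y)
})

test_that("large theta approaches the Poisson variance-mean identity", {
  covs <- tibble::tibble(site_id = sprintf("s%04d", 1:5000),
                         x = runif(5000), y = runif(5000))
  truth <- list(species_truth(
    "poissonish",
    abundance = list(intercept = 1, effects = list(), theta = 1e6),
    biomass = list(intercept = 6, effects = list(), shape = 2),
    lw = lw_params("p", 1e-5, 3)
  ))
  surv <- simulate_fish(covs, truth, seed = 13)
  y <- surv$maxn$maxn
  expect_gt(var(y) / mean(y), 0.8)
  expect_lt(var(y) / mean(y), 1.2)
})

test_that("truth specifications are validated", {
  expect_error(species_truth("x",
                             abundance = list(intercept = 0, effects = list(),
                                              theta = -1),
                             biomass = list(intercept = 1, effects = list(),
                                            shape = 2),
                             lw = lw_params("x", 1e-5, 3)),
               "theta")
  expect_error(species_truth("x",
                             abundance = list(intercept = 0, effects = list(),
                                              theta = 2),
                             biomass = list(intercept = 1, effects = list(),
                                            shape = 0),
                             lw = lw_params("x", 1e-5, 3)),
               "shape")
  sim <- small_sim()
  bad <- list(species_truth("x",
                            abundance = list(intercept = 0, effects = list(
                              list(predictor = "nope", curve = "linear",
                                   coef = 1)), theta = 2),
                            biomass = list(intercept = 1, effects = list(),
                                           shape = 2),
                            lw = lw_params("x", 1e-5, 3)))
  expect_error(simulate_fish(sim$covs, bad, seed = 1), "nope")
})
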