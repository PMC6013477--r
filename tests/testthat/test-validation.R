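test_that("cross-validation is reproducible and partitions folds evenly", {
  sim <- small_sim()
  d <- response_data(sim$survey, "sp1", "abundance")
  cv1 <- repeated_kfold_cv(d, "maxn", "bathymetry", family = "nb",
                           folds = 5, repetitions = 3, seed = 42)
  cv2 <- repeated_kfold_cv(d, "maxn", "bathymetry", family = "nb",
                           folds = 5, repetitions = 3, seed = 42)
  expect_identical(cv1$rmse, cv2$rmse)
  expect_equal(nrow(cv1), 3)
  expect_true(all(cv1$nrmse_pct >= 0))
  g <- glance(cv1)
  expect_equal(g$nrmse_pct_mean, mean(cv1$nrmse_pct))

  # fold sizes differ by at most one (observed through the fold labels the
  # partition rule produces)
  withr::with_seed(42, {
    sizes <- table(sample(rep(1:5, length.out = 23)))
    expect_lte(diff(range(sizes)), 1)
  })
})

test_that("a perfect oracle predictor yields zero normalized RMSE", {
  d <- data.frame(y = rpois(25, 5) + 1, x = rnorm(25))
  oracle <- function(train) function(newdata) newdata$y
  cv <- repeated_kfold_cv(d, "y", character(0), family = "nb", folds = 5,
                          repetitions = 2, seed = 1, fit_fun = oracle)
  expect_equal(cv$nrmse_pct, c(0, 0))
})

test_that("constant responses make normalized RMSE undefined", {
  d <- data.frame(y = rep(3L, 30), x = rnorm(30))
  expect_error(repeated_kfold_cv(d, "y", "x", family = "nb"),
               "constant")
  expect_error(repeated_kfold_cv(data.frame(y = rpois(6, 2)), "y",
                                 character(0), folds = 5),
               "2 observations per fold")
})

test_that("the true model cross-validates no worse than the intercept-only model", {
  sim <- small_sim()
  d <- response_data(sim$survey, "sp1", "abundance")
  truth <- c("bathymetry", "eastness", "northness")
  wins <- vapply(1:3, function(s) {
    cv_true <- repeated_kfold_cv(d, "maxn", truth, family = "nb",
                                 repetitions = 5, seed = s)
    cv_null <- repeated_kfold_cv(d, "maxn", character(0), family = "nb",
                                 repetitions = 5, seed = s)
    mean(cv_true$nrmse_pct) <= mean(cv_null$nrmse_pct)
  }, logical(1))
  expect_true(all(wins))
})

test_that("GWR with an effectively infinite bandwidth reproduces global OLS", {
  withr::with_seed(5, {
    n <- 60
    coords <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
    pred <- runif(n, 1, 10)
    obs <- 2 + 1.5 * pred + rnorm(n)
    g <- fit_gwr(obs, pred, coords, fixed_bandwidth = 1e9)
    ols <- coef(lm(obs ~ pred))
    expect_equal(g$intercept, rep(ols[[1]], n), tolerance = 1e-6)
    expect_equal(g$slope, rep(ols[[2]], n), tolerance = 1e-6)
  })
})

test_that("GWR residuals vanish when observed equals predicted", {
  withr::with_seed(6, {
    n <- 30
    coords <- cbind(runif(n), runif(n))
    pred <- seq(1, 5, length.out = n)
    g <- fit_gwr(pred, pred, coords, adaptive_k = 15)
    expect_equal(g$residual, rep(0, n), tolerance = 1e-9)
    expect_equal(g$std_residual, rep(0, n))
  })
})

test_that("GWR enforces minimum size, distinct coordinates and sane residuals", {
  expect_error(fit_gwr(1:3, 1:3, cbind(1:3, 1:3)), "at least 10")
  coords <- cbind(c(1, 1, 2:10), c(1, 1, 2:10))
  expect_error(fit_gwr(rnorm(11), rnorm(11), coords), "distinct")

  # on well-specified data the standardized residuals centre near zero
  sim <- small_sim()
  d <- response_data(sim$survey, "sp1", "abundance")
  f <- fit_sdm_gam(d, "maxn", c("bathymetry", "eastness"), family = "nb")
  g <- fit_gwr(d$maxn, predict(f, d), cbind(d$x, d$y))
  expect_lt(abs(mean(g$std_residual)), 0.1)
  expect_equal(sd(g$std_residual), 1, tolerance = 1e-9)
})

test_that("Moran's I equals -1 for alternating values on a rook-adjacency line", {
  n <- 12
  vals <- rep(c(1, -1), n / 2)
  coords <- cbind(seq_len(n), rep(0, n))
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    W[i, i + 1] <- 1; W[i + 1, i] <- 1
  }
  m <- morans_i(vals, weights = W)
  # brute-force double sum oracle
  Wrs <- W / rowSums(W)
  z <- vals - mean(vals)
  I_oracle <- (n / sum(Wrs)) *
    sum(outer(seq_len(n), seq_len(n),
              Vectorize(function(i, j) Wrs[i, j] * z[i] * z[j]))) / sum(z^2)
  expect_equal(m$I, -1, tolerance = 1e-12)
  expect_equal(m$I, I_oracle, tolerance = 1e-12)
  expect_equal(m$expected, -1 / (n - 1))
})

test_that("Moran's I matches the brute-force formula with knn weights", {
  withr::with_seed(9, {
    n <- 40
    coords <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    vals <- rnorm(n)
    m <- morans_i(vals, coords, k = 6)
    # independent recomputation from first principles
    D <- as.matrix(dist(coords))
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      W[i, order(D[i, ])[2:7]] <- 1
    }
    W <- W / rowSums(W)
    z <- vals - mean(vals)
    I2 <- (n / sum(W)) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
    expect_equal(m$I, I2, tolerance = 1e-12)
    expect_true(m$p_value >= 0 && m$p_value <= 1)
  })
})

test_that("Moran's I is invariant to location and positive scale changes", {
  withr::with_seed(10, {
    n <- 50
    coords <- cbind(runif(n), runif(n))
    vals <- rnorm(n)
    m0 <- morans_i(vals, coords, k = 8)
    expect_equal(morans_i(vals + 100, coords, k = 8)$I, m0$I,
                 tolerance = 1e-12)
    expect_equal(morans_i(vals * 7.3, coords, k = 8)$I, m0$I,
                 tolerance = 1e-12)
  })
  expect_error(morans_i(rep(1, 20), cbind(1:20, 1)), "constant")
  expect_error(morans_i(1:3, cbind(1:3, 1)), "at least 4")
})
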