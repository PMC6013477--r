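# Full-subsets machinery: enumeration, AICc, weights, fitting, selection.

test_that("collinearity screening flags duplicated, constant and boundary cases", {
  withr::with_seed(2, {
    d <- tibble::tibble(a = rnorm(50), c = rnorm(50))
    d$b <- d$a  # perfect copy
    out <- screen_collinearity(d, cutoff = 0.28)
    expect_true(any(out$var1 == "a" & out$var2 == "b"))
    expect_equal(out$r[out$var1 == "a" & out$var2 == "b"], 1)

    # constant column: undefined correlations, all its pairs excluded
    d2 <- tibble::tibble(a = rnorm(30), k = rep(2, 30), b = rnorm(30))
    out2 <- screen_collinearity(d2, cutoff = 0.28)
    expect_true(all(c("a", "b") %in%
                      c(out2$var1[out2$var2 == "k" | out2$var1 == "k"],
                        out2$var2[out2$var1 == "k" | out2$var2 == "k"])))

    # cutoff 0 excludes every pair
    d3 <- tibble::tibble(a = rnorm(20), b = rnorm(20), c = rnorm(20))
    expect_equal(nrow(screen_collinearity(d3, cutoff = 0)), 3)

    # independent standard normals at n = 10000 stay below 0.28
    d4 <- as.data.frame(matrix(rnorm(10000 * 4), ncol = 4))
    expect_equal(nrow(screen_collinearity(d4, cutoff = 0.28)), 0)
  })
  expect_error(screen_collinearity(data.frame(a = 1:2, b = 2:1)), "3 rows")
})

test_that("candidate enumeration matches brute-force powerset filtering", {
  # 7 predictors, <= 4 terms: C(7,1)+C(7,2)+C(7,3)+C(7,4) = 98 non-null
  subs <- enumerate_candidate_models(letters[1:7], max_terms = 4)
  expect_equal(length(subs) - 1, 98)
  expect_identical(subs[[1]], character(0))

  expect_equal(length(enumerate_candidate_models(letters[1:3], 4)) - 1, 7)

  # independent brute-force oracle: filter the full powerset directly
  powerset <- function(v) {
    idx <- expand.grid(rep(list(c(FALSE, TRUE)), length(v)))
    lapply(seq_len(nrow(idx)), function(i) v[unlist(idx[i, ])])
  }
  excl <- tibble::tibble(var1 = c("a", "c"), var2 = c("b", "e"))
  for (np in c(5, 8)) {
    v <- letters[1:np]
    got <- enumerate_candidate_models(v, 4, excl)
    want <- Filter(function(s) {
      length(s) <= 4 &&
        !any(excl$var1 %in% s & excl$var2 %in% s)
    }, powerset(v))
    canon <- function(l) sort(vapply(l, paste, "", collapse = "+"))
    expect_setequal(canon(got), canon(want))
  }
  # exclusion removes exactly the subsets containing both members
  got <- enumerate_candidate_models(c("a", "b", "c"), 3,
                                    tibble::tibble(var1 = "a", var2 = "b"))
  expect_false(any(vapply(got, function(s) all(c("a", "b") %in% s),
                          logical(1))))
  expect_true(any(vapply(got, function(s) setequal(s, c("a", "c")),
                         logical(1))))
})

test_that("AICc matches hand arithmetic and approaches AIC as n grows", {
  expect_equal(aicc(-10, 3, 20), 27.5)  # 26 + 24/16
  aic <- -2 * (-10) + 2 * 3
  expect_lt(abs(aicc(-10, 3, 1e8) - aic), 1e-6)
  expect_error(aicc(-10, 3, 4), "exceed")
})

test_that("Akaike weights normalize, respect Delta = 2, and shift-invariance", {
  expect_equal(akaike_weights(c(100, 100)), c(0.5, 0.5))
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(0.7311, 0.2689), tolerance = 1e-4)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  v <- c(311.2, 308.8, 315.0, 309.1)
  expect_equal(akaike_weights(v), akaike_weights(v + 57.3),
               tolerance = 1e-12)
})

test_that("intercept-only gamma GAM fits the sample mean", {
  withr::with_seed(31, {
    d <- data.frame(w = rgamma(80, shape = 2, rate = 0.01))
    f <- fit_sdm_gam(d, "w", character(0), family = "gamma")
    expect_equal(unique(round(f$fitted_values, 8)), round(mean(d$w), 8))
  })
})

test_that("negative binomial GAM recovers a known mean structure", {
  withr::with_seed(77, {
    n <- 500
    d <- data.frame(x = rnorm(n))
    mu <- exp(1 + 0.8 * d$x)
    d$y <- rnbinom(n, size = 2, mu = mu)
    f <- fit_sdm_gam(d, "y", "x", family = "nb")
    expect_gt(cor(f$fitted_values, mu, method = "spearman"), 0.9)
    # each smooth is capped at k - 1 = 3 effective df
    expect_lte(sum(f$fit$edf) - 1, 3 + 1e-6)
  })
})

test_that("fit_sdm_gam rejects invalid responses and too-small samples", {
  d <- data.frame(y = c(1.5, 2, 3, 1, 0, 2, 4, 1, 0, 2), x = rnorm(10))
  expect_error(fit_sdm_gam(d, "y", "x", family = "nb"), "integer")
  d2 <- data.frame(w = c(-1, rgamma(9, 2)), x = rnorm(10))
  expect_error(fit_sdm_gam(d2, "w", "x", family = "gamma"), "positive")
  d3 <- data.frame(y = rpois(4, 2), x = rnorm(4), z = rnorm(4))
  expect_error(fit_sdm_gam(d3, "y", c("x", "z"), family = "nb"),
               "too few")
})

test_that("best-model selection respects the Delta < 2 band and tie-breaks", {
  tab <- tibble::tibble(
    predictors = c("a", "a+b", "c"),
    terms = list("a", c("a", "b"), "c"),
    n_terms = c(1, 2, 1),
    aicc = c(10, 11.5, 13)
  )
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tab$akaike_weight <- akaike_weights(tab$aicc)
  best <- rank_and_select(tab)
  expect_equal(best$predictors, "a")

  # exact AICc tie: the smaller subset wins
  tab2 <- tibble::tibble(
    predictors = c("a+b", "c"), terms = list(c("a", "b"), "c"),
    n_terms = c(2, 1), aicc = c(10, 10)
  )
  tab2$delta_aicc <- 0
  tab2$akaike_weight <- akaike_weights(tab2$aicc)
  expect_equal(rank_and_select(tab2)$predictors, "c")
  expect_equal(rank_and_select(tab2[1, ])$predictors, "a+b")
})

test_that("variable importance sums weights over models containing each term", {
  tab <- tibble::tibble(
    predictors = c("A", "A+B"), terms = list("A", c("A", "B")),
    n_terms = 1:2, aicc = c(1, 2), akaike_weight = c(0.6, 0.4)
  )
  vi <- variable_importance(tab, predictors = c("A", "B", "C"))
  expect_equal(vi$importance[vi$predictor == "A"], 1.0)
  expect_equal(vi$importance[vi$predictor == "B"], 0.4)
  expect_equal(vi$importance[vi$predictor == "C"], 0)
  expect_true(all(vi$importance >= 0 & vi$importance <= 1))
})

test_that("full-subsets run emits a coherent, deterministic candidate table", {
  sim <- small_sim()
  d <- response_data(sim$survey, "sp1", "abundance")
  preds <- c("bathymetry", "eastness", "slope")
  fs <- suppressWarnings(
    run_full_subsets(d, "maxn", preds, family = "nb", max_terms = 4,
                     corr_cutoff = 1))  # cutoff 1: nothing screened
  expect_equal(nrow(fs$candidates), 8)  # 2^3 - 1 + null
  expect_equal(sum(fs$candidates$akaike_weight), 1, tolerance = 1e-12)
  expect_equal(min(fs$candidates$delta_aicc), 0)
  expect_true(all(diff(fs$candidates$aicc) >= 0))  # sorted
  expect_s3_class(best_model(fs), "sdm_gam")

  # refitting the same data reproduces AICc exactly (determinism contract)
  fs2 <- suppressWarnings(
    run_full_subsets(d, "maxn", preds, family = "nb", max_terms = 4,
                     corr_cutoff = 1))
  expect_equal(fs$candidates$aicc, fs2$candidates$aicc, tolerance = 1e-8)

  td <- tidy(fs)
  expect_false("terms" %in% names(td))
  g <- glance(fs)
  expect_equal(g$n_candidates, 8)
  expect_equal(g$predictors, fs$best_id)
})

test_that("adding a predictor never increases -2 logLik for fixed-df fits", {
  sim <- small_sim()
  d <- response_data(sim$survey, "sp1", "abundance")
  f0 <- fit_sdm_gam(d, "maxn", character(0), family = "nb",
                    fixed_df = TRUE)
  for (p in c("bathymetry", "curvature")) {
    f1 <- fit_sdm_gam(d, "maxn", p, family = "nb", fixed_df = TRUE)
    expect_lte(-2 * f1$log_lik, -2 * f0$log_lik + 1e-6)
  }
  # adding a useless term to a real one still cannot lose likelihood
  f1 <- fit_sdm_gam(d, "maxn", "bathymetry", family = "nb",
                    fixed_df = TRUE)
  f2 <- fit_sdm_gam(d, "maxn", c("bathymetry", "curvature"), family = "nb",
                    fixed_df = TRUE)
  expect_lte(-2 * f2$log_lik, -2 * f1$log_lik + 1e-6)
})
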