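# Model validation: repeated k-fold cross-validation with range-normalized
# RMSE, geographically weighted regression of observed on predicted values
# (local bisquare-kernel least squares), and Moran's I on the standardized
# GWR residuals.

#' Repeated k-fold cross-validation
#'
#' Randomly partitions the data into `folds` near-equal parts, fits the
#' model on all but one part and predicts the held-out part on the response
#' scale; the RMSE of each repetition pools the held-out predictions of
#' all folds. Normalized RMSE expresses that error as a percentage of the
#' full dataset's observed response range, `100 * RMSE / (max(y) - min(y))`.
#'
#' @inheritParams fit_sdm_gam
#' @param predictors Covariates of the (already selected) model; no
#'   re-selection happens inside folds.
#' @param folds Number of folds (default 5).
#' @param repetitions Number of random re-partitions (default 50).
#' @param seed Integer seed; the partition sequence is fully reproducible.
#' @param fit_fun Optional custom learner: a function taking the training
#'   data and returning a prediction function of new data. Defaults to
#'   refitting the GAM defined by `predictors`/`family`/`k`.
#' @return A `cv_result` tibble with one row per repetition (`repetition`,
#'   `rmse`, `nrmse_pct`) and attributes `folds`, `repetitions`, `seed`,
#'   `response_range`.
#' @export
repeated_kfold_cv <- function(data, response, predictors,
                              family = c("nb", "gamma"), k = 4, folds = 5,
                              repetitions = 50, seed = 1, fit_fun = NULL) {
  family <- match.arg(family)
  data <- as.data.frame(data)
  n <- nrow(data)
  if (n < 2 * folds) stop("need at least 2 observations per fold",
                          call. = FALSE)
  y <- data[[response]]
  y_range <- diff(range(y))
  if (y_range == 0) {
    stop("constant response: normalized RMSE undefined", call. = FALSE)
  }
  if (is.null(fit_fun)) {
    fit_fun <- function(train) {
      fit <- fit_sdm_gam(train, response, predictors, family = family,
                         k = k)
      function(newdata) predict(fit, newdata)
    }
  }
  res <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(repetitions), function(rep_i) {
      fold_id <- sample(rep(seq_len(folds), length.out = n))
      pred <- numeric(n)
      for (f in seq_len(folds)) {
        test <- fold_id == f
        predictor <- fit_fun(data[!test, , drop = FALSE])
        pred[test] <- predictor(data[test, , drop = FALSE])
      }
      rmse <- sqrt(mean((y - pred)^2))
      tibble::tibble(repetition = rep_i, rmse = rmse,
                     nrmse_pct = 100 * rmse / y_range)
    })
  })
  structure(res, class = c("cv_result", class(res)),
            folds = folds, repetitions = repetitions, seed = seed,
            response_range = y_range)
}

#' Summarize a cross-validation result
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return One-row tibble: mean and sd of RMSE and normalized RMSE.
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    folds = attr(x, "folds"), repetitions = attr(x, "repetitions"),
    rmse_mean = mean(x$rmse), rmse_sd = stats::sd(x$rmse),
    nrmse_pct_mean = mean(x$nrmse_pct), nrmse_pct_sd = stats::sd(x$nrmse_pct)
  )
}

#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$nrmse_pct)) +
    ggplot2::geom_histogram(bins = 15, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "Normalized RMSE (%)", y = "Repetitions") +
    ggplot2::theme_minimal()
}

bisquare_weights <- function(d, h) {
  w <- (1 - (d / h)^2)^2
  w[d >= h] <- 0
  w
}

gwr_local_fit <- function(observed, predicted, W) {
  n <- length(observed)
  X <- cbind(1, predicted)
  t(vapply(seq_len(n), function(i) {
    w <- W[i, ]
    XtW <- t(X * w)
    M <- XtW %*% X
    if (!is.finite(determinant(M)$modulus) ||
        abs(det(M)) < 1e-12 * max(abs(M))^2) {
      stop(sprintf("singular local fit at site %d (bandwidth too small)", i),
           call. = FALSE)
    }
    as.numeric(solve(M, XtW %*% observed))
  }, numeric(2)))
}

#' Geographically weighted regression of observed on predicted
#'
#' Fits, at every site, a weighted least-squares regression of observed on
#' model-predicted values with bisquare spatial kernel weights, exposing
#' spatial nonstationarity in model fit. The bandwidth is either a fixed
#' distance or adaptive (the distance to the `adaptive_k`-th nearest
#' neighbour of each site); when neither is given, the adaptive neighbour
#' count is chosen by minimizing the leave-one-out cross-validation score.
#' Local standardized residuals divide the raw local residual by the
#' global residual standard deviation.
#'
#' @param observed,predicted Numeric vectors (n >= 10).
#' @param coords n x 2 matrix or data frame of site coordinates (distinct).
#' @param adaptive_k Neighbour count for the adaptive bandwidth, or `NULL`.
#' @param fixed_bandwidth Fixed kernel bandwidth in coordinate units, or
#'   `NULL`.
#' @return A `gwr_result` tibble: `x`, `y`, `observed`, `predicted`,
#'   `intercept`, `slope`, `fitted`, `residual`, `std_residual`; attributes
#'   record the bandwidth used and the kernel.
#' @export
fit_gwr <- function(observed, predicted, coords, adaptive_k = NULL,
                    fixed_bandwidth = NULL) {
  coords <- as.matrix(coords)
  n <- length(observed)
  if (n < 10) stop("GWR needs at least 10 sites", call. = FALSE)
  if (length(predicted) != n || nrow(coords) != n) {
    stop("observed, predicted and coords must have equal length",
         call. = FALSE)
  }
  if (anyDuplicated(coords)) {
    stop("site coordinates must be distinct", call. = FALSE)
  }
  D <- as.matrix(stats::dist(coords))
  bw_of_k <- function(kk) {
    # adaptive bandwidth: distance to the kk-th nearest other site
    apply(D, 1, function(dd) sort(dd[-which.min(dd)])[kk] * 1.0000001)
  }
  if (!is.null(fixed_bandwidth)) {
    h <- rep(fixed_bandwidth, n)
    bw_info <- list(type = "fixed", bandwidth = fixed_bandwidth)
  } else {
    if (is.null(adaptive_k)) {
      cand <- unique(pmin(n - 1, pmax(8, round(n * c(0.15, 0.25, 0.4, 0.6,
                                                     0.8, 0.99)))))
      scores <- vapply(cand, function(kk) {
        h <- bw_of_k(kk)
        W <- bisquare_weights(D, matrix(h, n, n))
        diag(W) <- 0  # leave-one-out
        err <- vapply(seq_len(n), function(i) {
          w <- W[i, ]
          X <- cbind(1, predicted)
          M <- t(X * w) %*% X
          if (abs(det(M)) < 1e-12) return(NA_real_)
          b <- solve(M, t(X * w) %*% observed)
          observed[i] - (b[1] + b[2] * predicted[i])
        }, numeric(1))
        if (any(is.na(err))) Inf else sum(err^2)
      }, numeric(1))
      adaptive_k <- cand[which.min(scores)]
    }
    h <- bw_of_k(adaptive_k)
    bw_info <- list(type = "adaptive", neighbours = adaptive_k)
  }
  W <- bisquare_weights(D, matrix(h, n, n, byrow = FALSE))
  diag(W) <- 1
  beta <- gwr_local_fit(observed, predicted, W)
  fitted <- beta[, 1] + beta[, 2] * predicted
  residual <- observed - fitted
  sd_res <- stats::sd(residual)
  # numerically exact fits leave only rounding noise; report zeros rather
  # than standardizing it
  scale_ref <- max(abs(observed), 1)
  std_residual <- if (sd_res > 1e-10 * scale_ref) residual / sd_res
                  else residual * 0
  res <- tibble::tibble(
    x = coords[, 1], y = coords[, 2],
    observed = observed, predicted = predicted,
    intercept = beta[, 1], slope = beta[, 2],
    fitted = fitted, residual = residual, std_residual = std_residual
  )
  structure(res, class = c("gwr_result", class(res)),
            bandwidth = bw_info, kernel = "bisquare")
}

#' @export
autoplot.gwr_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$std_residual,
                                       size = abs(.data$std_residual))) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "grey85",
                                    high = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "Std residual", size = NULL,
                  title = "GWR local standardized residuals") +
    ggplot2::theme_minimal()
}

knn_weights <- function(coords, k) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k >= n) stop("k must be smaller than the number of sites",
                   call. = FALSE)
  D <- as.matrix(stats::dist(coords))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))
    nb <- setdiff(ord, i)[seq_len(k)]
    W[i, nb] <- 1
  }
  W
}

#' Moran's I spatial autocorrelation test
#'
#' Global Moran's I, `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2`
#' with centred values `z`, over a row-standardized spatial weights matrix
#' (by default the `k` nearest neighbours of each site). The expectation
#' under no autocorrelation is `-1/(n-1)`; the z-score and two-sided
#' p-value use the variance under the normality assumption.
#'
#' @param values Numeric vector (non-constant, n >= 4).
#' @param coords n x 2 coordinates (used when `weights` is `NULL`).
#' @param k Neighbour count for the default k-nearest-neighbour weights
#'   (default 8).
#' @param weights Optional n x n spatial weights matrix (zero diagonal);
#'   row-standardized internally unless `row_standardize = FALSE`.
#' @param row_standardize Scale each row of the weights to sum to 1.
#' @return A `moran_result` list: `I`, `expected`, `variance`, `z_score`,
#'   `p_value`, `n`, `k`.
#' @export
morans_i <- function(values, coords = NULL, k = 8, weights = NULL,
                     row_standardize = TRUE) {
  n <- length(values)
  if (n < 4) stop("Moran's I needs at least 4 values", call. = FALSE)
  if (stats::sd(values) == 0) stop("values are constant", call. = FALSE)
  W <- if (is.null(weights)) knn_weights(coords, k) else as.matrix(weights)
  diag(W) <- 0
  if (row_standardize) {
    rs <- rowSums(W)
    rs[rs == 0] <- 1
    W <- W / rs
  }
  z <- values - mean(values)
  S0 <- sum(W)
  I <- (n / S0) * sum(W * outer(z, z)) / sum(z^2)
  EI <- -1 / (n - 1)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  VI <- (n^2 * S1 - n * S2 + 3 * S0^2) / ((n^2 - 1) * S0^2) - EI^2
  zsc <- (I - EI) / sqrt(VI)
  structure(
    list(I = I, expected = EI, variance = VI, z_score = zsc,
         p_value = 2 * stats::pnorm(-abs(zsc)), n = n,
         k = if (is.null(weights)) k else NA_integer_),
    class = "moran_result"
  )
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expected %.4f), z = %.3f, p = %.4f, n = %d\n",
              x$I, x$expected, x$z_score, x$p_value, x$n))
  invisible(x)
}

#' @export
tidy.moran_result <- function(x, ...) {
  tibble::tibble(I = x$I, expected = x$expected, variance = x$variance,
                 z_score = x$z_score, p_value = x$p_value, n = x$n)
}
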