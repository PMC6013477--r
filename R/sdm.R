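# Full-subsets information-theoretic GAM selection.
#
# Counts (MaxN) are modelled with a negative binomial GAM, individual
# biomass with a gamma GAM, both with log links and penalized smooths of
# basis dimension k = 4. Every admissible predictor subset (size <=
# max_terms, collinearity-screened) is fitted and ranked by AICc; Akaike
# weights over the candidate set give per-model support and summed-weight
# variable importance.

#' Screen covariate pairs for collinearity
#'
#' Flags unordered covariate pairs whose absolute Pearson correlation
#' exceeds `cutoff`; such pairs never co-occur in one candidate model.
#' Constant columns have undefined correlations: all their pairs are
#' flagged (with `r = NA`) and excluded.
#'
#' @param covariates Data frame of numeric covariate columns (>= 3 rows).
#' @param cutoff Absolute Pearson correlation threshold (default 0.28, the
#'   conservative convention of full-subsets model selection in ecology).
#' @return Tibble with columns `var1`, `var2`, `r` (one row per excluded
#'   pair; zero rows if nothing is flagged).
#' @export
screen_collinearity <- function(covariates, cutoff = 0.28) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) < 3) stop("need at least 3 rows", call. = FALSE)
  num <- vapply(covariates, is.numeric, logical(1))
  covariates <- covariates[num]
  vars <- names(covariates)
  if (length(vars) < 2) {
    return(tibble::tibble(var1 = character(), var2 = character(),
                          r = numeric()))
  }
  constant <- vapply(covariates, function(x) stats::sd(x) == 0 || !is.finite(stats::sd(x)),
                     logical(1))
  pairs <- utils::combn(vars, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    v1 <- pairs[1, j]; v2 <- pairs[2, j]
    if (constant[[v1]] || constant[[v2]]) {
      return(tibble::tibble(var1 = v1, var2 = v2, r = NA_real_))
    }
    r <- stats::cor(covariates[[v1]], covariates[[v2]])
    if (abs(r) > cutoff || (cutoff == 0 && abs(r) >= 0)) {
      tibble::tibble(var1 = v1, var2 = v2, r = r)
    } else {
      tibble::tibble(var1 = character(), var2 = character(), r = numeric())
    }
  })
  res
}

#' Enumerate candidate predictor subsets
#'
#' All non-empty subsets of the predictors with at most `max_terms`
#' members and containing no excluded (collinear) pair, plus the
#' intercept-only model (the empty subset, returned first).
#'
#' @param predictors Character vector of candidate covariate names.
#' @param max_terms Maximum subset size (default 4).
#' @param excluded_pairs Output of [screen_collinearity()] (or any data
#'   frame with `var1`, `var2` columns), or `NULL`.
#' @return List of character vectors; the first element is `character(0)`
#'   (intercept-only).
#' @export
enumerate_candidate_models <- function(predictors, max_terms = 4,
                                       excluded_pairs = NULL) {
  if (max_terms < 1) stop("`max_terms` must be >= 1", call. = FALSE)
  predictors <- unique(as.character(predictors))
  subsets <- list(character(0))
  if (length(predictors) > 0) {
    for (s in seq_len(min(max_terms, length(predictors)))) {
      subsets <- c(subsets,
                   utils::combn(predictors, s, simplify = FALSE))
    }
  }
  if (!is.null(excluded_pairs) && nrow(excluded_pairs) > 0) {
    subsets <- purrr::keep(subsets, function(sub) {
      !any(excluded_pairs$var1 %in% sub & excluded_pairs$var2 %in% sub)
    })
  }
  subsets
}

#' Small-sample-corrected AIC
#'
#' `AICc = -2 * logLik + 2k + 2k(k+1) / (n - k - 1)`, the finite-sample
#' correction of AIC. Undefined when `n <= k + 1`.
#'
#' @param log_likelihood Model log-likelihood.
#' @param k Number of estimated parameters (here: total effective degrees
#'   of freedom including intercept and dispersion).
#' @param n Number of observations.
#' @return The AICc value.
#' @export
aicc <- function(log_likelihood, k, n) {
  if (n <= k + 1) {
    stop("AICc undefined: n must exceed k + 1", call. = FALSE)
  }
  -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AICc_i - min(AICc)`: the relative likelihood of each model
#' being the best in the candidate set. Invariant to adding a constant to
#' all AICc values.
#'
#' @param aicc_values Numeric vector of finite AICc values.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  if (length(aicc_values) == 0 || any(!is.finite(aicc_values))) {
    stop("`aicc_values` must be non-empty and finite", call. = FALSE)
  }
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

family_for <- function(family) {
  switch(family,
         nb = mgcv::nb(),
         gamma = stats::Gamma(link = "log"),
         stop("`family` must be 'nb' or 'gamma'", call. = FALSE))
}

#' Fit one abundance or biomass GAM
#'
#' Fits `response ~ s(x1, k) + ...` by penalized likelihood (REML) with a
#' negative binomial family (log link, dispersion estimated by maximum
#' likelihood) for counts, or a gamma family (log link) for strictly
#' positive biomass. Every predictor enters as a thin-plate smooth of
#' basis dimension `k` (default 4, so each smooth has at most k - 1 = 3
#' effective degrees of freedom).
#'
#' @param data Data frame holding the response and covariates.
#' @param response Name of the response column.
#' @param predictors Character vector of covariate names (may be empty for
#'   the intercept-only model).
#' @param family `"nb"` (negative binomial counts) or `"gamma"` (positive
#'   continuous biomass).
#' @param k Smooth basis dimension (default 4).
#' @param fixed_df Use unpenalized regression splines of fixed degrees of
#'   freedom (`fx = TRUE`) instead of penalized smooths. Mainly useful for
#'   likelihood comparisons across nested models.
#' @return An `sdm_gam` object: the mgcv fit plus log-likelihood, total
#'   effective df, AICc, deviance-based adjusted R-squared and the
#'   training range of each covariate (used for constrained prediction).
#' @export
fit_sdm_gam <- function(data, response, predictors = character(),
                        family = c("nb", "gamma"), k = 4,
                        fixed_df = FALSE) {
  family <- match.arg(family)
  data <- as.data.frame(data)
  y <- data[[response]]
  if (is.null(y)) stop("response column `", response, "` not found",
                       call. = FALSE)
  if (any(!is.finite(y))) stop("response contains non-finite values",
                               call. = FALSE)
  if (family == "nb" && (any(y < 0) || any(y != round(y)))) {
    stop("abundance responses must be non-negative integers", call. = FALSE)
  }
  if (family == "gamma" && any(y <= 0)) {
    stop("biomass responses must be strictly positive", call. = FALSE)
  }
  n <- nrow(data)
  basis_dim <- 1 + length(predictors) * (k - 1)
  if (n <= basis_dim) {
    stop("too few observations for the requested basis dimension",
         call. = FALSE)
  }
  rhs <- if (length(predictors) == 0) "1" else {
    paste(sprintf("s(%s, k = %d%s)", predictors, k,
                  if (fixed_df) ", fx = TRUE" else ""),
          collapse = " + ")
  }
  form <- stats::as.formula(paste(response, "~", rhs))
  fit <- mgcv::gam(form, family = family_for(family), data = data,
                   method = "REML")
  edf_total <- sum(fit$edf)
  df <- edf_total + 1  # + dispersion/scale parameter
  ll <- as.numeric(stats::logLik(fit))
  r2_dev <- 1 - fit$deviance / fit$null.deviance
  adj_r2 <- 1 - (1 - r2_dev) * (n - 1) / (n - edf_total)
  ranges <- purrr::map(predictors, function(p) range(data[[p]]))
  names(ranges) <- predictors
  structure(
    list(fit = fit, response = response, predictors = predictors,
         family = family, k = k, n = n, log_lik = ll,
         edf_total = edf_total, df = df,
         aicc = aicc(ll, df, n), adjusted_r2 = adj_r2,
         training_ranges = ranges,
         fitted_values = as.numeric(stats::fitted(fit))),
    class = "sdm_gam"
  )
}

#' @export
print.sdm_gam <- function(x, ...) {
  cat(sprintf("<sdm_gam> %s ~ %s (%s, log link), n = %d\n", x$response,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ")
              else "1", x$family, x$n))
  cat(sprintf("  AICc %.2f, df %.2f, adj R2 %.3f\n", x$aicc, x$df,
              x$adjusted_r2))
  invisible(x)
}

#' Predict from an `sdm_gam` on the response scale
#'
#' @param object An `sdm_gam`.
#' @param newdata Data frame containing the model's covariates.
#' @param clamp Clamp covariates to the training envelope before
#'   predicting ("constrained" prediction, the default for mapping).
#' @param ... Unused.
#' @return Numeric vector of response-scale predictions (> 0).
#' @export
predict.sdm_gam <- function(object, newdata, clamp = FALSE, ...) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$predictors, names(newdata))
  if (length(missing) > 0) {
    stop("newdata lacks covariates: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (clamp) {
    for (p in object$predictors) {
      rg <- object$training_ranges[[p]]
      newdata[[p]] <- pmin(pmax(newdata[[p]], rg[1]), rg[2])
    }
  }
  as.numeric(mgcv::predict.gam(object$fit, newdata = newdata,
                               type = "response"))
}

#' Select the best model from a candidate table
#'
#' Restricts the table to models with `delta_aicc < delta_threshold` (the
#' conventional "tied for best" set) and returns the row with the highest
#' Akaike weight. Exact ties break deterministically: fewest predictors
#' first, then lexicographic order of the predictor string.
#'
#' @param table Candidate tibble with columns `aicc`, `delta_aicc`,
#'   `akaike_weight`, `n_terms`, `predictors`.
#' @param delta_threshold AICc difference defining the candidate set
#'   (default 2).
#' @return The selected row (one-row tibble).
#' @export
rank_and_select <- function(table, delta_threshold = 2) {
  if (nrow(table) == 0) stop("empty candidate table", call. = FALSE)
  cand <- dplyr::filter(table, .data$delta_aicc < delta_threshold)
  dplyr::slice(
    dplyr::arrange(cand, dplyr::desc(.data$akaike_weight), .data$n_terms,
                   .data$predictors),
    1
  )
}

#' Summed-weight variable importance
#'
#' For each covariate, the sum of the Akaike weights of every candidate
#' model containing it. Since weights sum to 1 over the set, importance
#' lies in [0, 1]; covariates appearing in no model score 0.
#'
#' @param table Candidate tibble with a `terms` list-column and an
#'   `akaike_weight` column (as produced by [run_full_subsets()]).
#' @param predictors Full predictor set to report (defaults to the
#'   `all_predictors` attribute of `table`, falling back to the union of
#'   terms).
#' @return Tibble with columns `predictor`, `importance`, sorted by
#'   decreasing importance.
#' @export
variable_importance <- function(table, predictors = NULL) {
  if (is.null(predictors)) {
    predictors <- attr(table, "all_predictors") %||%
      sort(unique(unlist(table$terms)))
  }
  imp <- vapply(predictors, function(v) {
    sum(table$akaike_weight[vapply(table$terms, function(tt) v %in% tt,
                                   logical(1))])
  }, numeric(1))
  dplyr::arrange(
    tibble::tibble(predictor = predictors, importance = unname(imp)),
    dplyr::desc(.data$importance)
  )
}

subset_label <- function(terms) {
  if (length(terms) == 0) "(intercept)" else paste(terms, collapse = "+")
}

#' Full-subsets AICc model selection
#'
#' Fits a GAM for every admissible predictor subset (size <= `max_terms`,
#' no collinear pair, plus the intercept-only null), ranks the set by
#' AICc, computes Akaike weights and summed-weight variable importance,
#' and selects the best model (highest weight among models with
#' `delta_aicc < delta_threshold`). Individual fit failures are dropped
#' with a single aggregated warning; only if every fit fails is this an
#' error.
#'
#' @inheritParams fit_sdm_gam
#' @param predictors Candidate covariate names.
#' @param max_terms Maximum number of predictors per model (default 4).
#' @param corr_cutoff Collinearity screening threshold passed to
#'   [screen_collinearity()].
#' @param delta_threshold AICc band for the best-model set (default 2).
#' @return An `fs_model_set`: list with `candidates` (tibble: `predictors`,
#'   `terms`, `n_terms`, `adjusted_r2`, `df`, `log_lik`, `aicc`,
#'   `delta_aicc`, `akaike_weight`), `models` (named list of `sdm_gam`),
#'   `importance`, `best_id`, `excluded_pairs`, `failures`.
#' @export
run_full_subsets <- function(data, response, predictors,
                             family = c("nb", "gamma"), max_terms = 4,
                             k = 4, corr_cutoff = 0.28,
                             delta_threshold = 2) {
  family <- match.arg(family)
  data <- as.data.frame(data)
  excluded <- screen_collinearity(data[predictors], cutoff = corr_cutoff)
  subsets <- enumerate_candidate_models(predictors, max_terms, excluded)
  fits <- list()
  failures <- character()
  for (sub in subsets) {
    id <- subset_label(sub)
    res <- tryCatch(
      fit_sdm_gam(data, response, sub, family = family, k = k),
      error = function(e) conditionMessage(e)
    )
    if (inherits(res, "sdm_gam")) fits[[id]] <- res
    else failures <- c(failures, sprintf("%s: %s", id, res))
  }
  if (length(fits) == 0) {
    stop("all candidate model fits failed", call. = FALSE)
  }
  if (length(failures) > 0) {
    warning(sprintf("%d candidate model(s) failed to fit and were dropped",
                    length(failures)), call. = FALSE)
  }
  candidates <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      predictors = subset_label(f$predictors),
      terms = list(f$predictors),
      n_terms = length(f$predictors),
      adjusted_r2 = f$adjusted_r2,
      df = f$df,
      log_lik = f$log_lik,
      aicc = f$aicc
    )
  })
  candidates$delta_aicc <- candidates$aicc - min(candidates$aicc)
  candidates$akaike_weight <- akaike_weights(candidates$aicc)
  candidates <- dplyr::arrange(candidates, .data$aicc)
  attr(candidates, "all_predictors") <- predictors
  best <- rank_and_select(candidates, delta_threshold)
  structure(
    list(candidates = candidates,
         models = fits,
         importance = variable_importance(candidates, predictors),
         best_id = best$predictors[[1]],
         response = response, family = family, k = k,
         n = nrow(data), max_terms = max_terms,
         excluded_pairs = excluded, failures = failures),
    class = "fs_model_set"
  )
}

#' Extract the selected best model
#' @param x An `fs_model_set`.
#' @return The best `sdm_gam`.
#' @export
best_model <- function(x) {
  stopifnot(inherits(x, "fs_model_set"))
  x$models[[x$best_id]]
}

#' @export
print.fs_model_set <- function(x, ...) {
  cat(sprintf("<fs_model_set> %s (%s), %d candidate models, n = %d\n",
              x$response, x$family, nrow(x$candidates), x$n))
  cat(sprintf("  best: %s (AICc %.2f, weight %.3f)\n", x$best_id,
              min(x$candidates$aicc),
              max(x$candidates$akaike_weight)))
  invisible(x)
}

#' Tidy a full-subsets model set
#'
#' @param x An `fs_model_set`.
#' @param ... Unused.
#' @return The candidate tibble (one row per fitted subset, sorted by
#'   AICc) without the list-column.
#' @export
tidy.fs_model_set <- function(x, ...) {
  dplyr::select(x$candidates, -"terms")
}

#' One-row summary of the selected best model
#'
#' @param x An `fs_model_set`.
#' @param ... Unused.
#' @return One-row tibble mirroring a best-model summary table row.
#' @export
glance.fs_model_set <- function(x, ...) {
  b <- x$models[[x$best_id]]
  row <- dplyr::filter(x$candidates, .data$predictors == x$best_id)
  tibble::tibble(
    response = x$response, family = x$family,
    predictors = x$best_id,
    intercept = unname(stats::coef(b$fit)[1]),
    adjusted_r2 = b$adjusted_r2, df = b$df, aicc = b$aicc,
    delta_aicc = row$delta_aicc[[1]],
    akaike_weight = row$akaike_weight[[1]],
    n = x$n, n_candidates = nrow(x$candidates)
  )
}

#' @export
autoplot.fs_model_set <- function(object, ...) {
  imp <- object$importance
  ggplot2::ggplot(imp, ggplot2::aes(
    x = stats::reorder(.data$predictor, .data$importance),
    y = .data$importance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Summed Akaike weight",
                  title = sprintf("Variable importance (%s, %s)",
                                  object$response, object$family)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
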