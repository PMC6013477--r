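# Raster prediction and hotspot scoring.

#' Predict a fitted model over the terrain stack
#'
#' Evaluates the model at every valid cell of the stack on the response
#' scale. Prediction is "constrained": by default, covariate values beyond
#' the training envelope are clamped to the training minimum/maximum, so
#' the map never extrapolates the smooths; alternatively extrapolated
#' cells can be masked out entirely.
#'
#' @param model An `sdm_gam`.
#' @param stack A `terrain_stack` containing every model covariate.
#' @param constrain `"clamp"` (default) or `"mask"`.
#' @return A [sea_raster] of response-scale predictions (> 0 where valid).
#' @export
predict_raster <- function(model, stack, constrain = c("clamp", "mask")) {
  constrain <- match.arg(constrain)
  missing <- setdiff(model$predictors, names(stack$layers))
  if (length(missing) > 0) {
    stop("terrain stack lacks layer(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ref <- stack$layers[[1]]
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  newdata <- purrr::map(stack$layers[union(model$predictors,
                                           names(stack$layers)[1])],
                        function(l) as.vector(l$values))
  newdata <- tibble::as_tibble(newdata)
  valid <- stats::complete.cases(newdata)
  if (constrain == "mask") {
    for (p in model$predictors) {
      rg <- model$training_ranges[[p]]
      valid <- valid & newdata[[p]] >= rg[1] & newdata[[p]] <= rg[2]
    }
  }
  out <- rep(NA_real_, nr * nc)
  if (any(valid)) {
    out[valid] <- predict(model, newdata[valid, , drop = FALSE],
                          clamp = (constrain == "clamp"))
  }
  sea_raster(matrix(out, nr, nc), ref$cell_size, ref$origin,
             name = sprintf("pred_%s", model$response))
}

#' Reclassify a biomass prediction into a life-stage class
#'
#' Splits a continuous predicted-biomass raster at the species'
#' juvenile/adult cutoff: the juvenile map is 1 where predicted individual
#' biomass is below the cutoff, the mature map is 1 at or above it (cells
#' exactly at the cutoff count as mature).
#'
#' @param raster A prediction [sea_raster].
#' @param cutoff_g Positive biomass cutoff in grams.
#' @param side `"juvenile"` or `"mature"`.
#' @return A binary (0/1) [sea_raster].
#' @export
reclassify_biomass <- function(raster, cutoff_g,
                               side = c("juvenile", "mature")) {
  side <- match.arg(side)
  if (!is.finite(cutoff_g) || cutoff_g <= 0) {
    stop("`cutoff_g` must be positive", call. = FALSE)
  }
  v <- raster$values
  out <- if (side == "juvenile") (v < cutoff_g) else (v >= cutoff_g)
  sea_raster(out * 1, raster$cell_size, raster$origin,
             name = sprintf("%s_%s", raster$name, side))
}

sum_rasters <- function(rasters, name) {
  stopifnot(is.list(rasters), length(rasters) >= 1)
  stop_if_incompatible(rasters)
  vals <- Reduce(`+`, lapply(rasters, function(r) r$values))
  ref <- rasters[[1]]
  sea_raster(vals, ref$cell_size, ref$origin, name = name)
}

#' Hotspot score across species
#'
#' Cellwise sum of per-species binary life-stage rasters: an integer raster
#' from 0 to S (number of species) counting how many species' predicted
#' class coincides at the cell. With three species a juvenile (or mature)
#' hotspot has the maximum score of 3.
#'
#' @param binary_rasters List of co-registered binary [sea_raster]s, one
#'   per species.
#' @return An integer-valued [sea_raster] in `[0, S]`.
#' @export
hotspot_sum <- function(binary_rasters) {
  sum_rasters(binary_rasters, name = "hotspot")
}

#' Cumulative predicted abundance
#'
#' Cellwise sum of the response-scale abundance prediction rasters of all
#' study species, highlighting areas of high multi-species abundance.
#'
#' @param prediction_rasters List of co-registered prediction
#'   [sea_raster]s.
#' @return A [sea_raster].
#' @export
cumulative_abundance <- function(prediction_rasters) {
  sum_rasters(prediction_rasters, name = "cumulative_abundance")
}

#' Plot a raster layer
#' @param r A [sea_raster].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_raster <- function(r, ...) {
  df <- as_tibble(r)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = r$name, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sea_raster <- function(object, ...) plot_raster(object, ...)
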