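# Response-variable construction: MaxN relative abundance, length-weight
# biomass, and joining site covariates sampled from the terrain stack.

#' Length-weight parameters for a species
#'
#' Power-law coefficients of `W = a * L^b` (weight in grams, fork length in
#' millimetres), separately for males and females. Monomorphic species can
#' pass a single pair. `cutoff_g` is the biomass threshold separating
#' juveniles from sexually mature adults, used for hotspot reclassification.
#'
#' @param species Species label.
#' @param a_male,b_male,a_female,b_female Positive power-law coefficients;
#'   female values default to the male values.
#' @param cutoff_g Juvenile/adult biomass cutoff in grams (optional).
#' @return A `lw_params` list.
#' @export
lw_params <- function(species, a_male, b_male, a_female = a_male,
                      b_female = b_male, cutoff_g = NA_real_) {
  vals <- c(a_male, b_male, a_female, b_female)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("length-weight coefficients must be positive", call. = FALSE)
  }
  structure(list(species = species, a_male = a_male, b_male = b_male,
                 a_female = a_female, b_female = b_female,
                 cutoff_g = cutoff_g),
            class = "lw_params")
}

#' MaxN from per-frame counts
#'
#' MaxN is the maximum number of individuals of one species visible in any
#' single video frame of a deployment -- a conservative relative-abundance
#' index that cannot double-count individuals.
#'
#' @param frame_counts Non-negative integer counts, one per frame.
#' @return A single non-negative integer.
#' @export
maxn_from_counts <- function(frame_counts) {
  if (length(frame_counts) == 0) {
    stop("`frame_counts` must be a non-empty sequence", call. = FALSE)
  }
  if (any(!is.finite(frame_counts)) || any(frame_counts < 0) ||
      any(frame_counts != round(frame_counts))) {
    stop("`frame_counts` must be non-negative integers", call. = FALSE)
  }
  as.integer(max(frame_counts))
}

#' Biomass from fork length
#'
#' Applies the species' power law `W = a * L^b`. When the sex cannot be
#' determined (the usual case on video), the male and female predictions
#' are averaged.
#'
#' @param length_mm Fork length(s) in mm, > 0.
#' @param params A [lw_params] object.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @return Biomass in grams, same length as `length_mm`.
#' @export
length_to_biomass <- function(length_mm, params,
                              sex = c("unknown", "male", "female")) {
  sex <- match.arg(sex)
  if (any(!is.finite(length_mm)) || any(length_mm <= 0)) {
    stop("`length_mm` must be positive", call. = FALSE)
  }
  male <- params$a_male * length_mm^params$b_male
  female <- params$a_female * length_mm^params$b_female
  switch(sex, male = male, female = female, unknown = (male + female) / 2)
}

#' Fork length from biomass
#'
#' Inverts [length_to_biomass()]. For known sex this is the closed form
#' `(W/a)^(1/b)`; for unknown sex (averaged prediction) the length solves
#' the averaged power law numerically.
#'
#' @param biomass_g Biomass in grams, > 0.
#' @param params A [lw_params] object.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @return Fork length(s) in mm.
#' @export
biomass_to_length <- function(biomass_g, params,
                              sex = c("unknown", "male", "female")) {
  sex <- match.arg(sex)
  if (any(!is.finite(biomass_g)) || any(biomass_g <= 0)) {
    stop("`biomass_g` must be positive", call. = FALSE)
  }
  if (sex == "male" ||
      (sex == "unknown" && params$a_male == params$a_female &&
       params$b_male == params$b_female)) {
    return((biomass_g / params$a_male)^(1 / params$b_male))
  }
  if (sex == "female") {
    return((biomass_g / params$a_female)^(1 / params$b_female))
  }
  vapply(biomass_g, function(w) {
    stats::uniroot(function(L) length_to_biomass(L, params, "unknown") - w,
                   lower = 1e-6, upper = 1e5, tol = 1e-10)$root
  }, numeric(1))
}

#' Sample terrain covariates at survey sites
#'
#' Looks up the value of the cell containing each site in every layer of a
#' terrain stack (point sampling; the neighbourhood structure is already
#' encoded in layers like `range10`). Sites falling on nodata cells are
#' dropped with a warning reporting how many; sites outside the raster
#' extent are an error naming the offending `site_id`s.
#'
#' @param stack A `terrain_stack` from [derive_terrain()].
#' @param sites Data frame with columns `site_id`, `x`, `y` (projected
#'   metres).
#' @return A tibble: `sites` columns plus one column per terrain layer.
#' @export
sample_covariates <- function(stack, sites) {
  stopifnot(all(c("site_id", "x", "y") %in% names(sites)))
  ref <- stack$layers[[1]]
  rc <- xy_to_rowcol(ref, sites$x, sites$y)
  outside <- is.na(rc$row) | is.na(rc$col)
  if (any(outside)) {
    stop("sites outside raster extent: ",
         paste(sites$site_id[outside], collapse = ", "), call. = FALSE)
  }
  idx <- cbind(rc$row, rc$col)
  covs <- purrr::map_dfc(stack$layers, function(l) l$values[idx])
  out <- dplyr::bind_cols(tibble::as_tibble(sites), covs)
  on_nodata <- !stats::complete.cases(covs)
  if (any(on_nodata)) {
    warning(sprintf("%d site(s) on nodata cells excluded", sum(on_nodata)),
            call. = FALSE)
    out <- out[!on_nodata, , drop = FALSE]
  }
  out
}
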