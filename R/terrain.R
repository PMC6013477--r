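# Terrain derivatives from a bathymetry grid.
#
# All stencil operations work on the internal matrix orientation (row 1 =
# northernmost row, columns increase eastward), vectorized through shifted
# copies of the elevation matrix. Derivative layers (slope, aspect,
# curvature) are conservative: any NA in the 3x3 neighbourhood makes the
# cell NA. Focal relief is permissive: it uses whatever valid cells the
# window contains.

# neighbour at row offset dr (positive = southward) and col offset dc
# (positive = eastward); cells falling outside the grid become NA
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  sr <- seq_len(nr) + dr
  sc <- seq_len(nc) + dc
  keep_r <- sr >= 1L & sr <= nr
  keep_c <- sc >= 1L & sc <= nc
  out[keep_r, keep_c] <- m[sr[keep_r], sc[keep_c]]
  out
}

check_stencil_grid <- function(grid) {
  stopifnot(inherits(grid, "sea_raster"))
  if (nrow(grid$values) < 3 || ncol(grid$values) < 3) {
    stop("grid must be at least 3x3 cells", call. = FALSE)
  }
  if (all(is.na(grid$values))) {
    stop("grid has no valid cells", call. = FALSE)
  }
}

horn_gradients <- function(grid) {
  z <- grid$values
  L <- grid$cell_size
  nb <- list(
    nw = shift_mat(z, -1L, -1L), n = shift_mat(z, -1L, 0L), ne = shift_mat(z, -1L, 1L),
    w  = shift_mat(z, 0L, -1L),                              e = shift_mat(z, 0L, 1L),
    sw = shift_mat(z, 1L, -1L),  s = shift_mat(z, 1L, 0L),  se = shift_mat(z, 1L, 1L)
  )
  valid <- is.finite(z)
  for (m in nb) valid <- valid & is.finite(m)
  p <- ((nb$ne + 2 * nb$e + nb$se) - (nb$nw + 2 * nb$w + nb$sw)) / (8 * L)
  q <- ((nb$nw + 2 * nb$n + nb$ne) - (nb$sw + 2 * nb$s + nb$se)) / (8 * L)
  p[!valid] <- NA_real_; q[!valid] <- NA_real_
  list(p = p, q = q, valid = valid, neighbours = nb)
}

#' Slope and aspect by the Horn 3x3 method
#'
#' Slope is the first derivative of elevation expressed as percent rise,
#' `100 * sqrt(p^2 + q^2)`, with the eight-neighbour weighted finite
#' differences of Horn (the algorithm used by ArcGIS Spatial Analyst).
#' Aspect is the compass direction the slope faces (downhill): 0 = north,
#' 90 = east. Flat cells (zero gradient) get aspect `-1`; cells whose 3x3
#' neighbourhood contains missing data are `NA` in both layers.
#'
#' @param grid A [sea_raster] of elevation (metres, negative below datum).
#' @return A list with [sea_raster] elements `slope` (% rise) and `aspect`
#'   (compass degrees, flat coded `-1`).
#' @export
slope_aspect <- function(grid) {
  check_stencil_grid(grid)
  g <- horn_gradients(grid)
  slope <- 100 * sqrt(g$p^2 + g$q^2)
  # downhill unit direction is -(p, q) in (east, north); compass angle
  # measures clockwise from north
  aspect <- (atan2(-g$p, -g$q) * 180 / pi) %% 360
  aspect[slope == 0] <- -1
  aspect[!g$valid] <- NA_real_
  list(
    slope = sea_raster(slope, grid$cell_size, grid$origin, name = "slope"),
    aspect = sea_raster(aspect, grid$cell_size, grid$origin, name = "aspect")
  )
}

#' Eastness and northness of the aspect
#'
#' Linearize the circular aspect as `sin(aspect)` (eastness: +1 east-facing,
#' -1 west-facing) and `cos(aspect)` (northness: +1 north-facing, -1
#' south-facing). Flat cells (aspect coded `-1`) get the neutral value 0.
#'
#' @param aspect_raster Aspect [sea_raster] from [slope_aspect()].
#' @return A [sea_raster] in `[-1, 1]`.
#' @export
eastness <- function(aspect_raster) {
  a <- aspect_raster$values
  v <- ifelse(a < 0, 0, sin(a * pi / 180))
  sea_raster(v, aspect_raster$cell_size, aspect_raster$origin, name = "eastness")
}

#' @rdname eastness
#' @export
northness <- function(aspect_raster) {
  a <- aspect_raster$values
  v <- ifelse(a < 0, 0, cos(a * pi / 180))
  sea_raster(v, aspect_raster$cell_size, aspect_raster$origin, name = "northness")
}

#' Focal relief (range) in a square moving window
#'
#' Maximum minus minimum elevation over a `window_cells` x `window_cells`
#' neighbourhood centred on each cell -- a coarse-scale rugosity proxy. The
#' window truncates at grid edges; for even window sizes it extends
#' `floor((w-1)/2)` cells north/west and `floor(w/2)` cells south/east. A
#' cell needs at least one valid neighbour, otherwise it is `NA`.
#'
#' @param grid A [sea_raster].
#' @param window_cells Window side in cells (default 10; on a 4 m grid the
#'   footprint is 40 m x 40 m = 1600 m2).
#' @return A [sea_raster] of local relief (metres, >= 0).
#' @export
focal_range <- function(grid, window_cells = 10) {
  stopifnot(inherits(grid, "sea_raster"))
  if (!is.numeric(window_cells) || length(window_cells) != 1 ||
      window_cells < 1) {
    stop("`window_cells` must be a positive integer", call. = FALSE)
  }
  w <- as.integer(window_cells)
  lo <- -((w - 1L) %/% 2L); hi <- w %/% 2L
  z <- grid$values
  mx <- matrix(-Inf, nrow(z), ncol(z))
  mn <- matrix(Inf, nrow(z), ncol(z))
  any_valid <- matrix(FALSE, nrow(z), ncol(z))
  for (dr in lo:hi) {
    for (dc in lo:hi) {
      s <- shift_mat(z, dr, dc)
      ok <- is.finite(s)
      any_valid <- any_valid | ok
      s_hi <- s; s_hi[!ok] <- -Inf
      s_lo <- s; s_lo[!ok] <- Inf
      mx <- pmax(mx, s_hi)
      mn <- pmin(mn, s_lo)
    }
  }
  out <- mx - mn
  out[!any_valid] <- NA_real_
  sea_raster(out, grid$cell_size, grid$origin,
             name = sprintf("range%d", w))
}

#' Combined (profile + plan) curvature
#'
#' Second derivative of the terrain from the Zevenbergen-Thorne 3x3
#' quadratic fit: with `D = ((z_W + z_E)/2 - z_C) / L^2` and
#' `E = ((z_N + z_S)/2 - z_C) / L^2`, combined curvature is
#' `-2 (D + E) * 100` (the conventional x100 scaling; positive values are
#' upwardly convex terrain). Cells whose 3x3 neighbourhood contains missing
#' data are `NA`.
#'
#' @param grid A [sea_raster].
#' @return A [sea_raster] of curvature.
#' @export
curvature <- function(grid) {
  check_stencil_grid(grid)
  g <- horn_gradients(grid)
  z <- grid$values
  L <- grid$cell_size
  nb <- g$neighbours
  D <- ((nb$w + nb$e) / 2 - z) / L^2
  E <- ((nb$n + nb$s) / 2 - z) / L^2
  out <- -2 * (D + E) * 100
  out[!g$valid] <- NA_real_
  sea_raster(out, grid$cell_size, grid$origin, name = "curvature")
}

#' Derive the full terrain covariate stack
#'
#' Builds the six co-registered covariate layers used by the distribution
#' models: bathymetry itself plus eastness, northness, slope, focal relief
#' (`range10` by default) and curvature. All layers share a union nodata
#' mask, so every covariate is defined wherever any one of them is.
#'
#' @param grid Bathymetry [sea_raster].
#' @param window_cells Relief window side in cells (default 10).
#' @return A `terrain_stack`: list with `layers` (named [sea_raster] list:
#'   `bathymetry`, `eastness`, `northness`, `slope`, `range10`,
#'   `curvature`), `cell_size`, `origin`, `window_cells`.
#' @export
derive_terrain <- function(grid, window_cells = 10) {
  check_stencil_grid(grid)
  sa <- slope_aspect(grid)
  layers <- list(
    bathymetry = sea_raster(grid$values, grid$cell_size, grid$origin,
                            name = "bathymetry"),
    eastness = eastness(sa$aspect),
    northness = northness(sa$aspect),
    slope = sa$slope,
    range10 = focal_range(grid, window_cells),
    curvature = curvature(grid)
  )
  na_union <- Reduce(`|`, lapply(layers, function(l) is.na(l$values)))
  layers <- lapply(layers, function(l) {
    l$values[na_union] <- NA_real_
    l
  })
  structure(
    list(layers = layers, cell_size = grid$cell_size, origin = grid$origin,
         window_cells = as.integer(window_cells)),
    class = "terrain_stack"
  )
}

#' @export
print.terrain_stack <- function(x, ...) {
  cat(sprintf("<terrain_stack> %d layers (%s), %d x %d cells, cell %g m\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              nrow(x$layers[[1]]$values), ncol(x$layers[[1]]$values),
              x$cell_size))
  invisible(x)
}

#' Names of the terrain covariates
#' @param stack A `terrain_stack`.
#' @return Character vector of layer names.
#' @export
terrain_layer_names <- function(stack) names(stack$layers)

#' Write every layer of a terrain stack as ESRI ASCII grids
#' @param stack A `terrain_stack`.
#' @param dir Output directory (created if needed).
#' @return Tibble of layer names and file paths.
#' @export
write_terrain_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::imap_chr(stack$layers, function(l, nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(l, p)
    p
  })
  tibble::tibble(layer = names(paths), path = unname(paths))
}
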