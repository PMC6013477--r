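# Shared fixture builders. Everything is generated in code; the cache
# avoids re-deriving the same terrain stack across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# inclined plane z = ax + by + c sampled at cell centres
plane_grid <- function(a = 0, b = 0, c = 0, nr = 12, nc = 15,
                       cell_size = 2, origin = c(0, 0)) {
  xs <- origin[1] + (seq_len(nc) - 1) * cell_size
  ys <- origin[2] + (nr - seq_len(nr)) * cell_size
  z <- outer(ys, xs, function(y, x) a * x + b * y + c)
  sea_raster(z, cell_size, origin)
}

# quadratic bowl/dome z = s * c * ((x-x0)^2 + (y-y0)^2)
quad_grid <- function(cc = 0.01, sign = 1, nr = 11, nc = 13,
                      cell_size = 2) {
  xs <- (seq_len(nc) - 1) * cell_size
  ys <- (nr - seq_len(nr)) * cell_size
  x0 <- mean(xs); y0 <- mean(ys)
  z <- outer(ys, xs, function(y, x) sign * cc * ((x - x0)^2 + (y - y0)^2))
  sea_raster(z, cell_size)
}

random_grid <- function(seed = 42, nr = 20, nc = 20, cell_size = 3) {
  withr::with_seed(seed, {
    sea_raster(matrix(stats::rnorm(nr * nc, -20, 4), nr, nc), cell_size)
  })
}

# compact simulated seascape + survey shared by model-level tests
small_sim <- function() {
  cached("small_sim", function() {
    cfg <- sim_config(grid_nrow = 150, grid_ncol = 200, cell_size = 4,
                      n_sites = 120, min_spacing = 30, seed = 99)
    bathy <- generate_bathymetry(cfg)
    stack <- derive_terrain(bathy)
    sites <- sample_sites(stack$layers$bathymetry, n_sites = 120,
                          min_spacing = 30, seed = 100)
    covs <- sample_covariates(stack, sites)
    survey <- simulate_fish(covs, default_species_truth(), seed = 101)
    list(cfg = cfg, bathy = bathy, stack = stack, covs = covs,
         survey = survey)
  })
}

terrain_predictors <- c("bathymetry", "eastness", "northness", "slope",
                        "range10", "curvature")

# independent per-cell stencil oracle used by the terrain tests: slow,
# direct evaluation of the Horn and Zevenbergen-Thorne formulas cell by
# cell, kept free of the vectorized implementation
oracle_terrain_cell <- function(z, i, j, L) {
  if (i < 2 || j < 2 || i > nrow(z) - 1 || j > ncol(z) - 1) {
    return(list(slope = NA, aspect = NA, curv = NA))
  }
  nbr <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
  if (any(!is.finite(nbr))) return(list(slope = NA, aspect = NA, curv = NA))
  # rows of nbr: north, centre, south; cols: west, centre, east
  p <- ((nbr[1, 3] + 2 * nbr[2, 3] + nbr[3, 3]) -
        (nbr[1, 1] + 2 * nbr[2, 1] + nbr[3, 1])) / (8 * L)
  q <- ((nbr[1, 1] + 2 * nbr[1, 2] + nbr[1, 3]) -
        (nbr[3, 1] + 2 * nbr[3, 2] + nbr[3, 3])) / (8 * L)
  slope <- 100 * sqrt(p^2 + q^2)
  aspect <- if (slope == 0) -1 else (atan2(-p, -q) * 180 / pi) %% 360
  D <- ((nbr[2, 1] + nbr[2, 3]) / 2 - nbr[2, 2]) / L^2
  E <- ((nbr[1, 2] + nbr[3, 2]) / 2 - nbr[2, 2]) / L^2
  list(slope = slope, aspect = aspect, curv = -2 * (D + E) * 100)
}

oracle_focal_range <- function(z, i, j, w) {
  lo <- -((w - 1L) %/% 2L); hi <- w %/% 2L
  rows <- max(1, i + lo):min(nrow(z), i + hi)
  cols <- max(1, j + lo):min(ncol(z), j + hi)
  vals <- z[rows, cols]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) NA_real_ else max(vals) - min(vals)
}
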