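# Pipeline orchestration: terrain -> survey -> selection -> validation ->
# mapping as one configured, seeded, logged run.

#' Default pipeline configuration
#'
#' A self-contained simulated run sized for interactive use: two synthetic
#' species over a 7 km x 10 km embayment gridded at 20 m (the generator's
#' native 4 m resolution is available by setting `cell_size = 4`; terrain
#' metrics are scale-aware), 200 sites at least 400 m apart, full-subsets
#' selection over the six terrain covariates with at most four terms, and
#' 50 x 5-fold cross-validation of each selected model.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @return Nested configuration list understood by [run_all()].
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = TRUE,
    # used when simulate = FALSE:
    bathymetry_path = NULL,
    survey_maxn_path = NULL,
    survey_individuals_path = NULL,
    sim = list(grid_nrow = 350, grid_ncol = 500, cell_size = 20,
               depth_range = c(-5, -40),
               ridges = list(count = 3, amplitude = 3, wavelength = 900,
                             along_wavelength = 2500),
               noise_sd = 0.5, n_sites = 200, min_spacing = 400,
               n_strata = 4),
    terrain = list(window_cells = 10),
    model = list(predictors = c("bathymetry", "eastness", "northness",
                                "slope", "range10", "curvature"),
                 max_terms = 4, k = 4, corr_cutoff = 0.28,
                 delta_threshold = 2),
    validation = list(folds = 5, repetitions = 50, moran_k = 8),
    mapping = list(constrain = "clamp")
  )
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys fall back to [default_config()] values.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

#' Run the full analysis pipeline
#'
#' Executes every stage for each species and response: synthetic data
#' generation (or loading a bathymetry ASCII grid plus survey CSVs),
#' terrain covariate derivation, full-subsets GAM selection, repeated
#' k-fold cross-validation, GWR + Moran's I residual diagnostics, raster
#' prediction, juvenile/mature biomass reclassification, hotspot scoring
#' and cumulative abundance. Writes a best-model summary CSV, per-model
#' candidate CSVs, validation reports, ESRI ASCII rasters and a JSON run
#' manifest into `out_dir`. Deterministic under `config$seed`.
#'
#' @param config Configuration list (see [default_config()]) or a YAML
#'   path.
#' @param out_dir Output directory (created).
#' @param species Optional list of [species_truth] objects (defaults to
#'   [default_species_truth()] when simulating).
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_all <- function(config = default_config(), out_dir, species = NULL) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config, seed = config$seed,
                   r_version = as.character(getRversion()),
                   status = list(), warnings = list(), outputs = list())
  finish_stage <- function(stage, outputs = character()) {
    manifest$status[[stage]] <<- "ok"
    if (length(outputs)) manifest$outputs[[stage]] <<- outputs
  }
  fail <- function(stage, e) {
    manifest$status[[stage]] <<- "failed"
    write_manifest(manifest, out_dir)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }
  note_warning <- function(stage) {
    function(w) {
      manifest$warnings[[stage]] <<-
        c(manifest$warnings[[stage]], conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  }
  run_stage <- function(stage, expr) {
    tryCatch(
      withCallingHandlers(expr, warning = note_warning(stage)),
      error = function(e) fail(stage, e)
    )
  }

  # -- input: simulate or load --------------------------------------------
  input <- run_stage("input", {
    if (isTRUE(config$simulate)) {
      sp <- species %||% default_species_truth()
      cfg <- sim_config(
        grid_nrow = config$sim$grid_nrow, grid_ncol = config$sim$grid_ncol,
        cell_size = config$sim$cell_size,
        depth_range = config$sim$depth_range, ridges = config$sim$ridges,
        noise_sd = config$sim$noise_sd, n_sites = config$sim$n_sites,
        min_spacing = config$sim$min_spacing,
        n_strata = config$sim$n_strata, seed = config$seed, species = sp)
      bathy <- generate_bathymetry(cfg)
      list(bathy = bathy, cfg = cfg, species = sp)
    } else {
      if (is.null(config$bathymetry_path) ||
          !file.exists(config$bathymetry_path)) {
        stop("bathymetry path missing or not found", call. = FALSE)
      }
      list(bathy = read_ascii_grid(config$bathymetry_path), cfg = NULL,
           species = species)
    }
  })
  finish_stage("input")

  # -- terrain ------------------------------------------------------------
  stack <- run_stage("terrain", {
    derive_terrain(input$bathy, window_cells = config$terrain$window_cells)
  })
  terr_paths <- write_terrain_stack(stack, file.path(out_dir, "terrain"))
  finish_stage("terrain", terr_paths$path)

  # -- survey -------------------------------------------------------------
  survey <- run_stage("survey", {
    if (isTRUE(config$simulate)) {
      # sample from the union-masked bathymetry so every site has all
      # six covariates defined
      sites <- sample_sites(stack$layers$bathymetry,
                            n_sites = input$cfg$n_sites,
                            min_spacing = input$cfg$min_spacing,
                            seed = config$seed + 101L,
                            n_strata = input$cfg$n_strata)
      site_covs <- sample_covariates(stack, sites)
      simulate_fish(site_covs, input$species, seed = config$seed + 202L)
    } else {
      load_survey(config, stack)
    }
  })
  survey_paths <- write_survey_csv(survey, file.path(out_dir, "survey"))
  finish_stage("survey", survey_paths$path)

  # -- model selection ----------------------------------------------------
  mc <- config$model
  species_names <- unique(survey$maxn$species)
  combos <- tidyr::expand_grid(species = species_names,
                               response = c("abundance", "biomass"))
  fits <- run_stage("models", {
    purrr::pmap(combos, function(species, response) {
      d <- response_data(survey, species, response)
      resp_col <- if (response == "abundance") "maxn" else "biomass_g"
      family <- if (response == "abundance") "nb" else "gamma"
      run_full_subsets(d, resp_col, mc$predictors, family = family,
                       max_terms = mc$max_terms, k = mc$k,
                       corr_cutoff = mc$corr_cutoff,
                       delta_threshold = mc$delta_threshold)
    })
  })
  names(fits) <- paste(combos$species, combos$response, sep = "_")
  cand_paths <- purrr::imap_chr(fits, function(f, nm) {
    p <- file.path(out_dir, sprintf("candidates_%s.csv", nm))
    utils::write.csv(tidy(f), p, row.names = FALSE)
    p
  })
  finish_stage("models", unname(cand_paths))

  # -- validation ---------------------------------------------------------
  vc <- config$validation
  validation <- run_stage("validation", {
    purrr::imap(fits, function(f, nm) {
      sp_name <- sub("_(abundance|biomass)$", "", nm)
      response <- sub("^.*_", "", nm)
      d <- response_data(survey, sp_name, response)
      resp_col <- if (response == "abundance") "maxn" else "biomass_g"
      b <- best_model(f)
      cv <- repeated_kfold_cv(d, resp_col, b$predictors, family = b$family,
                              k = b$k, folds = vc$folds,
                              repetitions = vc$repetitions,
                              seed = config$seed + 303L)
      # spatial diagnostics at site level (biomass aggregated to site
      # means so coordinates are distinct)
      site_d <- dplyr::summarise(
        dplyr::group_by(d, .data$site_id),
        observed = mean(.data[[resp_col]]), .groups = "drop")
      site_d <- dplyr::inner_join(site_d, survey$sites, by = "site_id")
      site_pred <- predict(b, site_d)
      gwr <- NULL; moran <- NULL
      if (nrow(site_d) >= 10 && stats::sd(site_d$observed) > 0) {
        gwr <- fit_gwr(site_d$observed, site_pred,
                       cbind(site_d$x, site_d$y))
        moran <- morans_i(gwr$std_residual, cbind(site_d$x, site_d$y),
                          k = min(vc$moran_k, nrow(site_d) - 1))
      }
      list(cv = cv, gwr = gwr, moran = moran)
    })
  })
  val_paths <- purrr::imap_chr(validation, function(v, nm) {
    p <- file.path(out_dir, sprintf("validation_%s.json", nm))
    out <- list(cv = as.list(glance(v$cv)),
                moran = if (!is.null(v$moran)) as.list(tidy(v$moran)))
    jsonlite::write_json(out, p, auto_unbox = TRUE, digits = 10)
    if (!is.null(v$gwr)) {
      utils::write.csv(
        dplyr::select(v$gwr, "x", "y", "std_residual"),
        file.path(out_dir, sprintf("gwr_residuals_%s.csv", nm)),
        row.names = FALSE)
    }
    p
  })
  finish_stage("validation", unname(val_paths))

  # -- mapping ------------------------------------------------------------
  maps <- run_stage("mapping", {
    preds <- purrr::map(fits, function(f) {
      predict_raster(best_model(f), stack,
                     constrain = config$mapping$constrain)
    })
    cutoffs <- purrr::map_dbl(input$species %||% list(),
                              function(s) s$lw$cutoff_g)
    names(cutoffs) <- purrr::map_chr(input$species %||% list(),
                                     function(s) s$species)
    juv <- list(); mat <- list()
    for (sp_name in species_names) {
      pb <- preds[[paste0(sp_name, "_biomass")]]
      co <- cutoffs[[sp_name]]
      if (!is.null(co) && is.finite(co)) {
        juv[[sp_name]] <- reclassify_biomass(pb, co, "juvenile")
        mat[[sp_name]] <- reclassify_biomass(pb, co, "mature")
      }
    }
    ab <- preds[paste0(species_names, "_abundance")]
    list(predictions = preds,
         hotspot_juvenile = if (length(juv)) hotspot_sum(juv),
         hotspot_mature = if (length(mat)) hotspot_sum(mat),
         cumulative_abundance = cumulative_abundance(ab))
  })
  map_dir <- file.path(out_dir, "maps")
  dir.create(map_dir, showWarnings = FALSE)
  map_paths <- character()
  for (nm in names(maps$predictions)) {
    p <- file.path(map_dir, sprintf("pred_%s.asc", nm))
    write_ascii_grid(maps$predictions[[nm]], p)
    map_paths <- c(map_paths, p)
  }
  for (nm in c("hotspot_juvenile", "hotspot_mature",
               "cumulative_abundance")) {
    if (!is.null(maps[[nm]])) {
      p <- file.path(map_dir, paste0(nm, ".asc"))
      write_ascii_grid(maps[[nm]], p)
      map_paths <- c(map_paths, p)
    }
  }
  finish_stage("mapping", map_paths)

  # -- summary ------------------------------------------------------------
  summary_tbl <- run_stage("summary", {
    purrr::imap_dfr(fits, function(f, nm) {
      g <- glance(f)
      g$species <- sub("_(abundance|biomass)$", "", nm)
      g$response <- sub("^.*_", "", nm)
      g$nrmse_pct <- mean(validation[[nm]]$cv$nrmse_pct)
      g$moran_p <- if (!is.null(validation[[nm]]$moran)) {
        validation[[nm]]$moran$p_value
      } else NA_real_
      dplyr::select(g, "species", "response", "predictors", "intercept",
                    "adjusted_r2", "df", "aicc", "delta_aicc",
                    "akaike_weight", "nrmse_pct", "moran_p", "n")
    })
  })
  sum_path <- file.path(out_dir, "best_models_summary.csv")
  utils::write.csv(summary_tbl, sum_path, row.names = FALSE)
  finish_stage("summary", sum_path)

  manifest$summary <- summary_tbl
  write_manifest(manifest, out_dir)
  invisible(manifest)
}

write_manifest <- function(manifest, out_dir) {
  m <- manifest
  m$summary <- if (!is.null(m$summary)) as.data.frame(m$summary)
  # configs can hold nested lists and function-free scalars only
  jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, force = TRUE,
                       null = "null")
  invisible(NULL)
}

load_survey <- function(config, stack) {
  if (is.null(config$survey_maxn_path) ||
      !file.exists(config$survey_maxn_path)) {
    stop("survey MaxN path missing or not found", call. = FALSE)
  }
  wide <- utils::read.csv(config$survey_maxn_path)
  maxn_cols <- grep("^maxn_", names(wide), value = TRUE)
  maxn <- tidyr::pivot_longer(
    wide[c("site_id", maxn_cols)], dplyr::all_of(maxn_cols),
    names_to = "species", values_to = "maxn", names_prefix = "maxn_")
  sites <- wide[setdiff(names(wide), maxn_cols)]
  site_covs <- sample_covariates(stack, sites)
  individuals <- if (!is.null(config$survey_individuals_path) &&
                     file.exists(config$survey_individuals_path)) {
    tibble::as_tibble(utils::read.csv(config$survey_individuals_path))
  } else {
    tibble::tibble(site_id = character(), species = character(),
                   individual = integer(), biomass_g = numeric(),
                   fork_length_mm = numeric())
  }
  structure(list(sites = site_covs,
                 maxn = dplyr::semi_join(tibble::as_tibble(maxn), site_covs,
                                         by = "site_id"),
                 individuals = individuals, seed = config$seed),
            class = "survey_table")
}
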