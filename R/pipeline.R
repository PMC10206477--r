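# Configuration, table validation and end-to-end orchestration.
#
# The pipeline runs: standardize camera + scat surveys -> merge into the
# visit matrix -> modularity (multi-restart LPAwb+) -> null-model
# significance -> node roles -> stand x module contingency test -> trait
# discrimination (VIF + Wilks + LDA) -> seed-rain estimation, contribution
# regression, group comparisons and inequality rankings. All stage seeds
# derive from one master seed, so runs are fully reproducible.

#' Pipeline configuration
#'
#' Either point `paths` at the four input CSVs (plants, species,
#' camera_records, scat_records, in the schemas written by
#' [synthesize_study()]) or supply a `synthesis` [study_config()] block to
#' generate them in memory.
#'
#' @param paths named list with elements plants, species, camera_records,
#'   scat_records.
#' @param synthesis optional [study_config()] used when `paths` is NULL.
#' @param study_days study duration (days).
#' @param n_null null-model replicates (0 disables the significance stage).
#' @param n_restarts modularity restarts.
#' @param max_steps,tolerance LPAwb+ iteration controls.
#' @param vif_threshold,entry_alpha trait-screen controls.
#' @param bootstrap_reps bootstrap resamples for per-species totals.
#' @param rng_seed master seed.
#' @param out_dir optional output directory for the artifact files.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(paths = NULL, synthesis = NULL, study_days = 434,
                            n_null = 100, n_restarts = 10, max_steps = 1000,
                            tolerance = 1e-10, vif_threshold = 3,
                            entry_alpha = 0.2, bootstrap_reps = 1000,
                            rng_seed = 1L, out_dir = NULL) {
  if (is.null(paths) && is.null(synthesis)) {
    stop_input("supply input paths or a synthesis block")
  }
  if (!is.null(synthesis)) stopifnot(inherits(synthesis, "study_config"))
  structure(list(
    paths = paths, synthesis = synthesis, study_days = study_days,
    n_null = n_null, n_restarts = n_restarts, max_steps = max_steps,
    tolerance = tolerance, vif_threshold = vif_threshold,
    entry_alpha = entry_alpha, bootstrap_reps = bootstrap_reps,
    rng_seed = as.integer(rng_seed), out_dir = out_dir
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML or JSON file
#'
#' The file holds the arguments of [pipeline_config()]; a `synthesis` block,
#' if present, holds arguments of [study_config()] (or of
#' [strong_signal_config()] when it contains `strong_signal: true`).
#'
#' @param path a .yaml/.yml or .json file.
#' @return a [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  spec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(spec$synthesis)) {
    syn_args <- spec$synthesis
    strong <- isTRUE(syn_args$strong_signal)
    syn_args$strong_signal <- NULL
    spec$synthesis <- do.call(if (strong) strong_signal_config else study_config,
                              syn_args)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(spec), known)
  if (length(unknown) > 0) {
    stop_input("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, spec)
}

validate_columns <- function(df, needed, what) {
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop_input(sprintf("%s: missing column(s) %s", what,
                       paste(missing, collapse = ", ")))
  }
}

collect_problems <- function(df, checks, what) {
  problems <- character(0)
  for (nm in names(checks)) {
    bad <- which(!checks[[nm]])
    if (length(bad) > 0) {
      problems <- c(problems, sprintf("%s: %s (rows %s)", what, nm,
                                      paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  problems
}

#' Read and validate the four input tables
#'
#' Loads plants, species, camera and scat CSVs (UTF-8, '.' decimal) and
#' validates their schemas: required columns present, identifiers unique,
#' fractions inside \[0, 1\], positive areas and counts. All problems are
#' reported at once with offending row numbers. Extra columns are preserved
#' but ignored.
#'
#' @param paths named list of file paths (plants, species, camera_records,
#'   scat_records).
#' @return list of validated data.frames.
#' @export
read_tables <- function(paths) {
  needed <- c("plants", "species", "camera_records", "scat_records")
  missing <- setdiff(needed, names(paths))
  if (length(missing) > 0) {
    stop_input("paths lack entries: ", paste(missing, collapse = ", "))
  }
  for (p in unlist(paths[needed])) {
    if (!file.exists(p)) stop_input("input file not found: ", p)
  }
  plants <- utils::read.csv(paths$plants, stringsAsFactors = FALSE)
  species <- utils::read.csv(paths$species, stringsAsFactors = FALSE)
  camera <- utils::read.csv(paths$camera_records, stringsAsFactors = FALSE)
  scats <- utils::read.csv(paths$scat_records, stringsAsFactors = FALSE)

  validate_columns(plants, c("plant_id", "stand", "cover", "crop_size",
                             "seeds_per_cone", "seed_viability"), "plants")
  validate_columns(species, c("species_id", "functional_group", "feeding_rate",
                              "undamaged_fraction"), "species")
  validate_columns(camera, c("plant_id", "species_id", "n_records",
                             "recorded_days", "coverage_fraction"), "camera_records")
  validate_columns(scats, c("plant_id", "species_id", "n_samples",
                            "sampled_area", "canopy_area", "active_days"),
                   "scat_records")

  problems <- c(
    collect_problems(plants, list(
      "duplicate plant_id" = !duplicated(plants$plant_id),
      "nonpositive cover" = plants$cover > 0,
      "seed_viability outside [0,1]" =
        plants$seed_viability >= 0 & plants$seed_viability <= 1,
      "seeds_per_cone outside [1,10]" =
        plants$seeds_per_cone >= 1 & plants$seeds_per_cone <= 10
    ), "plants"),
    collect_problems(species, list(
      "duplicate species_id" = !duplicated(species$species_id),
      "nonpositive feeding_rate" = species$feeding_rate > 0,
      "undamaged_fraction outside [0,1]" =
        species$undamaged_fraction >= 0 & species$undamaged_fraction <= 1
    ), "species"),
    collect_problems(camera, list(
      "negative record count" = camera$n_records >= 0,
      "coverage_fraction outside (0,1]" =
        camera$coverage_fraction > 0 & camera$coverage_fraction <= 1,
      "nonpositive recorded_days" = camera$recorded_days > 0,
      "unknown plant_id" = camera$plant_id %in% plants$plant_id
    ), "camera_records"),
    collect_problems(scats, list(
      "negative sample count" = scats$n_samples >= 0,
      "nonpositive sampled_area" = scats$sampled_area > 0,
      "nonpositive canopy_area" = scats$canopy_area > 0,
      "nonpositive active_days" = scats$active_days > 0,
      "unknown plant_id" = scats$plant_id %in% plants$plant_id
    ), "scat_records")
  )
  if (length(problems) > 0) {
    stop_input("validation failed:\n  ", paste(problems, collapse = "\n  "))
  }
  list(plants = plants, species = species, camera_records = camera,
       scat_records = scats)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured inputs and returns (and optionally
#' writes) the full report bundle. Stages that cannot run on degenerate input
#' (e.g. the trait discrimination when only one module is found) are reported
#' as NULL with a message rather than aborting the whole run.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with elements visit_matrix,
#'   partition, null_ensemble, roles, contingency, chisq, discrimination,
#'   seed_rain, shares, regression, anova_module, anova_stand, ranking,
#'   cover_regression, strength_regression, inputs, seeds.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$paths)) {
    inputs <- read_tables(config$paths)
    truth <- NULL
  } else {
    syn <- synthesize_study(config$synthesis)
    inputs <- list(plants = syn$plants, species = syn$species,
                   camera_records = syn$camera_records,
                   scat_records = syn$scat_records)
    truth <- syn$ground_truth
  }
  plants <- inputs$plants
  plant_ids <- plants$plant_id
  species_ids <- inputs$species$species_id
  sd_days <- config$study_days

  cam_mat <- standardize_camera(inputs$camera_records, sd_days,
                                plant_ids = plant_ids, species_ids = species_ids)
  scat_mat <- standardize_scats(inputs$scat_records, sd_days,
                                plant_ids = plant_ids,
                                species_ids = setdiff(
                                  unique(c(species_ids,
                                           inputs$scat_records$species_id)),
                                  "UNIDENTIFIED"))
  scat_mat <- scat_mat[, species_ids, drop = FALSE]
  visit_matrix <- merge_visit_matrices(cam_mat, scat_mat)
  # keep species that were ever observed; a zero column cannot be assigned
  observed_species <- colSums(visit_matrix) > 0
  visit_matrix <- visit_matrix[, observed_species, drop = FALSE]
  if (sum(visit_matrix) == 0) stop_input("no interactions after standardization")
  observed_plants <- rowSums(visit_matrix) > 0
  analysis_matrix <- visit_matrix[observed_plants, , drop = FALSE]

  partition <- dirt_lpawb_plus(analysis_matrix, n_restarts = config$n_restarts,
                               rng_seed = derive_seed(config$rng_seed, 11),
                               max_steps = config$max_steps,
                               tolerance = config$tolerance)
  nulls <- NULL
  if (config$n_null >= 2) {
    nulls <- vaznull_ensemble(analysis_matrix, n_null = config$n_null,
                              rng_seed = derive_seed(config$rng_seed, 12),
                              n_restarts = min(config$n_restarts, 5),
                              observed = partition)
  }
  roles <- node_roles(analysis_matrix, partition)

  contingency <- stand_module_table(partition,
                                    plants[plants$plant_id %in%
                                             rownames(analysis_matrix), ])
  chisq <- tryCatch(pearson_chi_squared(contingency), error = function(e) {
    message("contingency test skipped: ", conditionMessage(e))
    NULL
  })

  module_labels <- partition$row_labels
  discrimination <- tryCatch(
    discriminate_modules(plants[plants$plant_id %in% names(module_labels), ],
                         module_labels, vif_threshold = config$vif_threshold,
                         entry_alpha = config$entry_alpha),
    error = function(e) {
      message("trait discrimination skipped: ", conditionMessage(e))
      NULL
    })

  rain <- estimate_dispersed_seeds(visit_matrix, inputs$species, plants)
  shares <- species_shares(rain)
  regression <- tryCatch(
    contribution_regression(rain, visit_matrix, inputs$species, plants,
                            focal_species = names(shares)[which.max(shares)]),
    error = function(e) {
      message("contribution regression skipped: ", conditionMessage(e))
      NULL
    })
  module_of_plant <- module_labels[names(rain$plant_totals)]
  anova_module <- tryCatch(
    group_anova_tukey(rain$plant_totals[!is.na(module_of_plant)],
                      module_of_plant[!is.na(module_of_plant)]),
    error = function(e) NULL)
  stand_of_plant <- stats::setNames(plants$stand, plants$plant_id)
  anova_stand <- tryCatch(
    group_anova_tukey(rain$plant_totals, stand_of_plant),
    error = function(e) NULL)
  ranking <- stand_zscores(rain, plants)
  strength <- node_strength(visit_matrix)
  cover_reg <- loglog_regression(rain$plant_totals,
                                 stats::setNames(plants$cover, plants$plant_id))
  strength_reg <- tryCatch(
    loglog_regression(rain$plant_totals, strength$plants),
    error = function(e) NULL)

  result <- structure(list(
    visit_matrix = visit_matrix,
    analysis_matrix = analysis_matrix,
    partition = partition,
    null_ensemble = nulls,
    roles = roles,
    contingency = contingency,
    chisq = chisq,
    discrimination = discrimination,
    seed_rain = rain,
    shares = shares,
    regression = regression,
    anova_module = anova_module,
    anova_stand = anova_stand,
    ranking = ranking,
    cover_regression = cover_reg,
    strength_regression = strength_reg,
    inputs = inputs,
    ground_truth = truth,
    seeds = list(master = config$rng_seed)
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

write_pipeline_outputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_visit_matrix(result$visit_matrix, file.path(dir, "visit_matrix.csv"))
  part <- result$partition
  modules_df <- rbind(
    data.frame(node = names(part$row_labels), side = "plant",
               module = unname(part$row_labels)),
    data.frame(node = names(part$col_labels), side = "species",
               module = unname(part$col_labels))
  )
  utils::write.csv(modules_df, file.path(dir, "modules.csv"), row.names = FALSE)
  utils::write.csv(result$roles, file.path(dir, "roles.csv"), row.names = FALSE)
  if (!is.null(result$null_ensemble)) {
    ne <- result$null_ensemble
    jsonlite::write_json(list(Q_obs = ne$Q_obs, z = ne$z, p_normal = ne$p_normal,
                              p_empirical = ne$p_empirical, null_Q = ne$null_Q),
                         file.path(dir, "qvalues.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(result$contingency)) {
    utils::write.csv(as.data.frame.matrix(result$contingency),
                     file.path(dir, "contingency.csv"))
  }
  if (!is.null(result$chisq)) {
    jsonlite::write_json(list(statistic = result$chisq$statistic,
                              df = result$chisq$df, p = result$chisq$p_value),
                         file.path(dir, "chisq.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  write_visit_matrix(result$seed_rain$seeds, file.path(dir, "seed_rain.csv"))
  utils::write.csv(result$ranking$table, file.path(dir, "ranking.csv"),
                   row.names = FALSE)
  if (!is.null(result$regression)) {
    jsonlite::write_json(list(
      coefficients = result$regression$coefficients,
      r_squared = result$regression$r_squared,
      aicc = result$regression$aicc,
      lmg = as.list(result$regression$lmg)
    ), file.path(dir, "regression_report.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Individual-based frugivory network analysis\n")
  cat(sprintf("  visit matrix: %d plants x %d species, total %.0f visits\n",
              nrow(x$visit_matrix), ncol(x$visit_matrix), sum(x$visit_matrix)))
  cat(sprintf("  modules: %d (Q = %.3f)\n", x$partition$n_modules, x$partition$Q))
  if (!is.null(x$null_ensemble)) {
    cat(sprintf("  modularity z = %.2f (normal p = %.2g)\n",
                x$null_ensemble$z, x$null_ensemble$p_normal))
  }
  if (!is.null(x$chisq)) {
    cat(sprintf("  stand x module: X2 = %.2f, df = %d, p = %.2g\n",
                x$chisq$statistic, x$chisq$df, x$chisq$p_value))
  }
  cat(sprintf("  pooled viable seed rain: %.0f seeds\n",
              sum(x$seed_rain$plant_totals)))
  invisible(x)
}
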