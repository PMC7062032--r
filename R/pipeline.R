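# Orchestration: configuration, validation and the end-to-end pipeline
# tying the stages together on synthetic inputs.

#' Build and validate an analysis configuration
#'
#' The configuration drives [run_pipeline()]: which stages run, the
#' synthetic-data sizes, the subset/filter settings, and an explicit seed
#' for every stochastic stage (a missing seed for an enabled stochastic
#' stage is a validation error).  Configurations round-trip losslessly
#' through [config_write()] / [config_read()].
#'
#' @param stages character vector from `c("simulate", "assemble", "sem",
#'   "permute", "gradient", "sar", "phylo")`.
#' @param n_units,n_palms,n_primates synthetic-data sizes.
#' @param grid_dims optional `c(rows, cols)`; required by the `sar` stage.
#' @param effect true standardized effect of the proportion of conspicuous
#'   palm fruits on trichromat richness in the generating scenario.
#' @param subset assemblage subset mode.
#' @param focal_class,min_focal,min_palms unit-filter settings.
#' @param permute_reps,gradient_thresholds,n_tips,n_maps stage settings.
#' @param alpha backward-elimination significance threshold.
#' @param seeds named list of integer seeds per stochastic stage
#'   (`landscape`, `palms`, `primates`, `permute`, `tree`, `simmap`).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(stages = c("simulate", "assemble", "sem",
                                       "permute", "gradient", "sar",
                                       "phylo"),
                            n_units = 400, n_palms = 200,
                            n_primates = 411, grid_dims = c(20, 20),
                            effect = 0.5,
                            subset = "all", focal_class = "trichromat",
                            min_focal = 1L, min_palms = 3L,
                            permute_reps = 200L,
                            gradient_thresholds = 2:16,
                            n_tips = 120L, n_maps = 100L, alpha = 0.05,
                            seeds = list(landscape = 11L, palms = 12L,
                                         primates = 13L, permute = 14L,
                                         tree = 15L, simmap = 16L)) {
  known <- c("simulate", "assemble", "sem", "permute", "gradient", "sar",
             "phylo")
  bad <- setdiff(stages, known)
  stop_if(length(bad) > 0, "unknown stage(s): ", paste(bad, collapse = ", "))
  need_seed <- c(simulate = NA, permute = "permute", phylo = "tree")
  required <- c("landscape", "palms", "primates")
  for (s in intersect(stages, c("permute", "phylo")))
    required <- c(required, if (s == "permute") "permute"
                  else c("tree", "simmap"))
  if ("simulate" %in% stages || TRUE) {
    missing <- setdiff(required, names(seeds))
    stop_if(length(missing) > 0,
            "config missing seed(s) for stochastic stage(s): ",
            paste(missing, collapse = ", "))
  }
  if (!is.null(grid_dims))
    stop_if(prod(grid_dims) != n_units,
            "grid_dims must multiply to n_units")
  structure(list(stages = stages, n_units = as.integer(n_units),
                 n_palms = as.integer(n_palms),
                 n_primates = as.integer(n_primates),
                 grid_dims = if (is.null(grid_dims)) NULL
                             else as.integer(grid_dims),
                 effect = effect, subset = subset,
                 focal_class = focal_class,
                 min_focal = as.integer(min_focal),
                 min_palms = as.integer(min_palms),
                 permute_reps = as.integer(permute_reps),
                 gradient_thresholds = as.integer(gradient_thresholds),
                 n_tips = as.integer(n_tips), n_maps = as.integer(n_maps),
                 alpha = alpha, seeds = lapply(seeds, as.integer)),
            class = "analysis_config")
}

#' Write / read a configuration
#'
#' @param config an [analysis_config()].
#' @param path file path (JSON).
#' @return `config_read` returns the `analysis_config`.
#' @export
config_write <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname config_write
#' @export
config_read <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$seeds <- as.list(raw$seeds)
  do.call(analysis_config, raw)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates a landscape, palm flora and primate assemblage from the
#' configured scenario, builds/filters/transforms the assemblage table,
#' fits the SEM with backward elimination, and (per the configured stages)
#' runs the permutation null, the progressive palm-richness delimitation,
#' the OLS/SAR comparison on the gridded landscape, and the
#' macroevolutionary stage (Mk fit, ancestral states, stochastic maps,
#' diversity-through-time, and a small state-dependent diversification
#' comparison).  Deterministic given the configuration: the same config
#' yields an identical result bundle.
#'
#' @param config an [analysis_config()].
#' @param out_dir optional directory; when given, stage outputs are
#'   written as CSV/JSON with a provenance block (config echo and hash).
#' @param verbose print per-stage progress to stderr.
#' @return a named list bundle with one element per executed stage plus
#'   `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stop_if(!inherits(config, "analysis_config"),
          "`config` must be an analysis_config")
  say <- function(...) if (verbose) message("[palmvision] ", ...)
  bundle <- list()
  sd <- config$seeds

  say("simulate")
  spec <- landscape_spec(config$n_units, grid_dims = config$grid_dims,
                         seed = sd$landscape)
  units <- generate_landscape(spec)
  flora <- generate_palm_flora(units, n_species = config$n_palms,
                               slope = 1.5, seed = sd$palms)
  scenario <- structural_scenario(
    c("prop_conspicuous->richness_trichromat" = config$effect,
      "temp->richness_trichromat" = 0.2,
      "canopy->richness_trichromat" = 0.2))
  prim <- generate_primate_assemblage(units, flora, scenario,
                                      n_species = config$n_primates,
                                      seed = sd$primates)
  if ("simulate" %in% config$stages)
    bundle$simulate <- list(units = units, palms = flora$palms,
                            occ_palms = flora$occurrences,
                            primates = prim$primates,
                            occ_primates = prim$occurrences)

  say("assemble")
  assemblage <- build_assemblage(prim$occurrences, flora$occurrences,
                                 prim$primates, flora$palms, units,
                                 subset = config$subset)
  filtered <- filter_units(assemblage, config$focal_class,
                           config$min_focal, config$min_palms)
  transformed <- transform_variables(filtered)
  if ("assemble" %in% config$stages)
    bundle$assemble <- list(assemblage = assemblage, filtered = filtered,
                            transformed = transformed)

  model <- path_model(c(
    "richness_trichromat ~ prop_conspicuous + temp + prec + tseas + pseas + canopy",
    "prop_conspicuous ~ temp + prec + tseas + pseas",
    "canopy ~ temp + prec + tseas + pseas"))
  focal <- "prop_conspicuous->richness_trichromat"

  if ("sem" %in% config$stages) {
    say("sem")
    be <- backward_eliminate(model, transformed, alpha = config$alpha)
    bundle$sem <- list(fit = be$fit, steps = be$steps,
                       indices = be$indices, gates = be$gates,
                       std = standardize(be$fit))
  }
  if ("permute" %in% config$stages) {
    say("permute (", config$permute_reps, " reps)")
    bundle$permute <- permutation_test(
      prim$occurrences, flora$occurrences, prim$primates, flora$palms,
      units, model, focal, reps = config$permute_reps,
      seed = sd$permute, subset = config$subset,
      focal_class = config$focal_class, min_focal = config$min_focal,
      min_palms = config$min_palms)
  }
  if ("gradient" %in% config$stages) {
    say("gradient")
    bundle$gradient <- progressive_delimitation(
      assemblage, model, focal, thresholds = config$gradient_thresholds,
      focal_class = config$focal_class, min_focal = config$min_focal)
  }
  if ("sar" %in% config$stages) {
    say("sar")
    stop_if(is.null(config$grid_dims), "sar stage needs grid_dims")
    td <- transformed
    grid <- filtered[c("grid_row", "grid_col")]
    w <- build_weights(grid)
    X <- as.matrix(td[c("prop_conspicuous", COVARIATE_NAMES)])
    y <- td$richness_trichromat
    sar <- fit_sar_error(y, X, w)
    ols <- fit_sar_error(y, X, w, fix_lambda = 0)
    bundle$sar <- list(weights_summary = list(n = w$n,
                                              islands = length(w$islands)),
                       sar = sar, ols = ols,
                       moran_ols = moran_i(ols$residuals, w),
                       moran_sar = moran_i(
                         sar$residuals - sar$lambda * drop(w$W %*% sar$residuals),
                         w))
  }
  if ("phylo" %in% config$stages) {
    say("phylo")
    Q <- matrix(c(-0.1, 0.1, 0.1, -0.1), 2, byrow = TRUE,
                dimnames = list(c("non_trichromatic", "trichromatic"),
                                c("non_trichromatic", "trichromatic")))
    sim <- simulate_tree_and_trait(config$n_tips, birth = 0.15,
                                   death = 0.05, Q = Q, seed = sd$tree)
    fit <- fit_mk(sim$tree, sim$tip_states, "ER")
    asr <- marginal_asr(sim$tree, sim$tip_states, fit$model)
    maps <- stochastic_map(sim$tree, sim$tip_states, fit$model,
                           n_maps = config$n_maps, seed = sd$simmap)
    dtt <- state_diversity_through_time(maps = maps,
                                        focal = "trichromatic",
                                        method = "simulation")
    bundle$phylo <- list(tree = sim$tree, tip_states = sim$tip_states,
                         mk_fit = fit, asr = asr, dtt = dtt)
  }

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  bundle$provenance <- list(config = config,
                            config_hash = fnv1a(as.character(cfg_json)),
                            package_version =
                              as.character(utils::packageVersion("palmvision")))
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  if (!is.null(bundle$simulate)) {
    wcsv(bundle$simulate$units, "units.csv")
    wcsv(bundle$simulate$palms, "palms.csv")
    wcsv(bundle$simulate$primates, "primates.csv")
    wcsv(bundle$simulate$occ_palms, "occurrences_palms.csv")
    wcsv(bundle$simulate$occ_primates, "occurrences_primates.csv")
  }
  if (!is.null(bundle$assemble))
    wcsv(bundle$assemble$assemblage, "assemblage.csv")
  if (!is.null(bundle$sem)) wcsv(bundle$sem$fit$paths, "sem_paths.csv")
  if (!is.null(bundle$gradient)) wcsv(bundle$gradient, "gradient.csv")
  if (!is.null(bundle$phylo)) {
    ape::write.tree(bundle$phylo$tree, file.path(out_dir, "tree.nwk"))
    wcsv(bundle$phylo$dtt, "diversity_through_time.csv")
  }
  summary <- list(provenance = list(
    config_hash = bundle$provenance$config_hash,
    package_version = bundle$provenance$package_version))
  if (!is.null(bundle$sem))
    summary$sem <- list(std = as.list(bundle$sem$std),
                        chisq = bundle$sem$fit$chisq,
                        df = bundle$sem$fit$df,
                        cfi = bundle$sem$indices$cfi,
                        rmsea = bundle$sem$indices$rmsea)
  if (!is.null(bundle$permute))
    summary$permute <- list(observed = bundle$permute$observed,
                            quantile = bundle$permute$quantile,
                            significant = bundle$permute$significant)
  if (!is.null(bundle$sar))
    summary$sar <- list(lambda = bundle$sar$sar$lambda,
                        std_sar = as.list(bundle$sar$sar$std_coefficients),
                        std_ols = as.list(bundle$sar$ols$std_coefficients))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Validate input tables
#'
#' Checks trait vocabularies (fruit colours, vision systems, activity
#' classes, frugivory ranks), occurrence referential integrity, and
#' numeric ranges, returning a report of violations (zero rows = clean).
#'
#' @param primates,palms,units optional trait/unit tables.
#' @param occ_primates,occ_palms optional occurrence tables (checked
#'   against the corresponding trait and unit tables when given).
#' @return data.frame with columns `table`, `row`, `column`, `problem`.
#' @export
validate_tables <- function(primates = NULL, palms = NULL, units = NULL,
                            occ_primates = NULL, occ_palms = NULL) {
  report <- list()
  note <- function(table, row, column, problem)
    report[[length(report) + 1L]] <<-
      data.frame(table = table, row = row, column = column,
                 problem = problem, stringsAsFactors = FALSE)
  if (!is.null(primates)) {
    bad <- which(!primates$vision_system %in% VISION_LEVELS)
    for (i in bad) note("primates", i, "vision_system",
                        paste0("unknown vision system '",
                               primates$vision_system[i], "'"))
    bad <- which(!primates$activity %in% ACTIVITY_LEVELS)
    for (i in bad) note("primates", i, "activity",
                        paste0("unknown activity '",
                               primates$activity[i], "'"))
    bad <- which(!primates$frugivory_rank %in% 0:3)
    for (i in bad) note("primates", i, "frugivory_rank",
                        "frugivory rank outside 0..3")
    if (anyDuplicated(primates$species_id))
      note("primates", anyDuplicated(primates$species_id), "species_id",
           "duplicate species id")
  }
  if (!is.null(palms)) {
    for (i in seq_len(nrow(palms))) {
      cc <- trimws(strsplit(as.character(palms$colours[i]), ",")[[1]])
      unknown <- setdiff(cc, COLOUR_VOCAB)
      for (u in unknown) note("palms", i, "colours",
                              paste0("unknown colour token '", u, "'"))
      if (!length(cc) || !any(nzchar(cc)))
        note("palms", i, "colours", "empty colour description")
    }
  }
  if (!is.null(units)) {
    if ("area" %in% names(units)) {
      bad <- which(!is.finite(units$area) | units$area <= 0)
      for (i in bad) note("units", i, "area", "area must be positive")
    }
    if (anyDuplicated(units$unit_id))
      note("units", anyDuplicated(units$unit_id), "unit_id",
           "duplicate unit id")
  }
  check_occ <- function(occ, traits, what) {
    if (is.null(occ)) return(invisible(NULL))
    if (!is.null(traits)) {
      bad <- which(!occ$species_id %in% traits$species_id)
      for (i in bad) note(what, i, "species_id",
                          paste0("unknown species '", occ$species_id[i],
                                 "'"))
    }
    if (!is.null(units)) {
      bad <- which(!occ$unit_id %in% units$unit_id)
      for (i in bad) note(what, i, "unit_id",
                          paste0("unknown unit '", occ$unit_id[i], "'"))
    }
  }
  check_occ(occ_primates, primates, "occ_primates")
  check_occ(occ_palms, palms, "occ_palms")
  if (!length(report))
    return(data.frame(table = character(0), row = integer(0),
                      column = character(0), problem = character(0)))
  do.call(rbind, report)
}
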