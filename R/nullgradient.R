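# The two bespoke inference procedures around the SEM: a richness-
# preserving permutation null for the focal path, and the progressive
# palm-richness delimitation analysis.

#' Reshuffle primate occurrences, preserving per-unit richness
#'
#' For each unit with observed primate richness k, draws k distinct species
#' uniformly from the global species pool, independently across units (a
#' species may occupy several units, as in range data).  Palm data are
#' untouched; per-unit total richness is exactly preserved.
#'
#' @param occ_primates occurrence table (`unit_id`, `species_id`).
#' @param species_pool character vector: the global pool (all primate
#'   species ids).
#' @param seed integer seed.
#' @return a reshuffled occurrence table.
#' @export
permute_primates <- function(occ_primates, species_pool, seed = NULL) {
  occ <- unique(occ_primates[c("unit_id", "species_id")])
  k <- table(occ$unit_id)
  stop_if(any(k > length(species_pool)),
          "unit richness exceeds the species pool size")
  with_seed(seed, {
    units <- names(k)
    sp <- lapply(as.integer(k), function(ki)
      sample_distinct(species_pool, ki))
    data.frame(unit_id = rep(units, times = as.integer(k)),
               species_id = unlist(sp), stringsAsFactors = FALSE)
  })
}

# Cached pipeline context: everything that does not change under primate
# permutation (palm counts, covariates), plus the trait lookups needed to
# recount vision-class richness quickly.
make_pipeline_context <- function(occ_palms, primate_traits, palm_traits,
                                  units, subset, cathemeral_is_diurnal,
                                  focal_class, min_focal, min_palms) {
  base <- build_assemblage(
    occ_primates = data.frame(unit_id = character(0),
                              species_id = character(0)),
    occ_palms = occ_palms, primate_traits = primate_traits,
    palm_traits = palm_traits, units = units, subset = subset,
    cathemeral_is_diurnal = cathemeral_is_diurnal)
  keep <- rep(TRUE, nrow(primate_traits))
  if (subset == "diurnal_frugivores") {
    diurnal <- primate_traits$activity == "diurnal"
    if (cathemeral_is_diurnal)
      diurnal <- diurnal | primate_traits$activity == "cathemeral_crepuscular"
    keep <- diurnal & primate_traits$frugivory_rank >= 1
  }
  list(base = base,
       unit_levels = units$unit_id,
       vis = setNames(primate_traits$vision_system,
                      primate_traits$species_id),
       incl = setNames(keep, primate_traits$species_id),
       pool = primate_traits$species_id,
       focal_class = focal_class, min_focal = min_focal,
       min_palms = min_palms)
}

# Rebuild the assemblage for a new primate occurrence table using the
# cached palm/covariate columns, then filter and transform.
context_tables <- function(ctx, occ_primates) {
  occ <- unique(occ_primates[c("unit_id", "species_id")])
  occ <- occ[ctx$incl[occ$species_id], , drop = FALSE]
  uf <- factor(occ$unit_id, levels = ctx$unit_levels)
  v <- ctx$vis[occ$species_id]
  tab <- ctx$base
  tab$richness_trichromat <-
    as.integer(table(uf[v == "routine_trichromatic"]))
  tab$richness_polymorph <- as.integer(table(uf[v == "polymorphic"]))
  tab$richness_other <-
    as.integer(table(uf[v == "dichromatic_or_monochromatic"]))
  filtered <- filter_units(tab, ctx$focal_class, ctx$min_focal,
                           ctx$min_palms)
  if (!nrow(filtered)) return(NULL)
  suppressMessages(transform_variables(filtered))
}

# Integer-coded machinery for the permutation loop.  pool_class codes each
# species in the global pool as 1..3 (vision class, counted) or 0
# (excluded by the subset rule); base_cols holds the permutation-invariant
# model columns.
make_fast_context <- function(ctx, model, units) {
  cls_code <- c(routine_trichromatic = 1L, polymorphic = 2L,
                dichromatic_or_monochromatic = 3L)
  pc <- unname(cls_code[ctx$vis[ctx$pool]])
  pc[!ctx$incl[ctx$pool]] <- 0L
  base <- ctx$base
  cols <- list(prop_conspicuous = base$prop_conspicuous,
               temp = base$temp, prec = base$prec, tseas = base$tseas,
               pseas = base$pseas, canopy = base$canopy)
  if (!is.null(base$area)) cols$log_area <- log(base$area)
  rich_names <- c("richness_trichromat", "richness_polymorph",
                  "richness_other")
  bad <- setdiff(model$variables, c(names(cols), rich_names))
  stop_if(length(bad) > 0,
          "model variable(s) not available in the pipeline: ",
          paste(bad, collapse = ", "))
  list(pool_class = pc,
       base_cols = cols,
       palatable = base$n_conspicuous + base$n_nonconspicuous,
       vars = model$variables,
       rich_vars = intersect(model$variables, rich_names),
       focal_class = ctx$focal_class, min_focal = ctx$min_focal,
       min_palms = ctx$min_palms)
}

class_counts <- function(unit_idx, sp_class, n_units) {
  cbind(richness_trichromat = tabulate(unit_idx[sp_class == 1L], n_units),
        richness_polymorph = tabulate(unit_idx[sp_class == 2L], n_units),
        richness_other = tabulate(unit_idx[sp_class == 3L], n_units))
}

# Filter units, apply the sqrt/min-max transforms to the model variables
# and return the sample covariance; NULL when the subset degenerates.
fast_tables <- function(fc, counts) {
  focal <- switch(fc$focal_class,
                  trichromat = counts[, 1L],
                  polymorph = counts[, 2L],
                  trichromat_polymorph = counts[, 1L] + counts[, 2L])
  keep <- focal >= fc$min_focal & fc$palatable >= fc$min_palms
  n <- sum(keep)
  if (n <= length(fc$vars) + 2L) return(NULL)
  X <- matrix(NA_real_, n, length(fc$vars),
              dimnames = list(NULL, fc$vars))
  for (v in fc$vars) {
    x <- if (v %in% colnames(counts)) sqrt(counts[keep, v])
         else fc$base_cols[[v]][keep]
    r <- range(x)
    if (r[2] - r[1] <= 0) return(NULL)
    X[, v] <- (x - r[1]) / (r[2] - r[1])
  }
  list(S = cov(X), n = n)
}

#' Permutation test for a focal SEM path
#'
#' Repeats the full pipeline -- reshuffle primate occurrences with
#' [permute_primates()], rebuild the assemblage, apply the unit filter and
#' modelling transforms, refit the SEM, extract the standardized
#' coefficient of the focal path -- `reps` times, and compares the observed
#' standardized coefficient against the null distribution.  The one-sided
#' test is significant when the observed effect exceeds 95% of the
#' simulated effects.
#'
#' @param occ_primates,occ_palms occurrence tables.
#' @param primate_traits,palm_traits trait tables.
#' @param units unit table.
#' @param model a [path_model()] on the transformed variable names.
#' @param focal `"cause->effect"` string naming the focal path.
#' @param reps number of permutations (>= 1).
#' @param seed integer seed.
#' @param subset,cathemeral_is_diurnal passed to [build_assemblage()].
#' @param focal_class,min_focal,min_palms passed to [filter_units()].
#' @param alternative `"greater"` (default, the reported criterion) or
#'   `"two_sided"`.
#' @param level significance level of the one-sided criterion
#'   (default 0.95).
#' @param max_fail abort when more than this fraction of permutation
#'   replicates fails to converge.
#' @return object of class `permutation_result`: `observed`, `null`
#'   (length-`reps` vector), `quantile`, `significant`, `reps`, `seed`.
#' @export
permutation_test <- function(occ_primates, occ_palms, primate_traits,
                             palm_traits, units, model, focal,
                             reps = 1000, seed = 1L,
                             subset = c("all", "diurnal_frugivores"),
                             cathemeral_is_diurnal = FALSE,
                             focal_class = "trichromat", min_focal = 1L,
                             min_palms = 3L,
                             alternative = c("greater", "two_sided"),
                             level = 0.95, max_fail = 0.05) {
  subset <- match.arg(subset)
  alternative <- match.arg(alternative)
  stop_if(!is_count(reps), "`reps` must be a positive integer")
  ctx <- make_pipeline_context(occ_palms, primate_traits, palm_traits,
                               units, subset, cathemeral_is_diurnal,
                               focal_class, min_focal, min_palms)
  fc <- make_fast_context(ctx, model, units)

  # per-unit richness (distinct species), fixed across permutations
  occ <- unique(occ_primates[c("unit_id", "species_id")])
  ui <- match(occ$unit_id, ctx$unit_levels)
  stop_if(anyNA(ui), "occurrences reference unknown units")
  k_per_unit <- tabulate(ui, nbins = length(ctx$unit_levels))
  npool <- length(ctx$pool)
  stop_if(any(k_per_unit > npool),
          "unit richness exceeds the species pool size")

  coef_for <- function(counts) {
    td <- fast_tables(fc, counts)
    if (is.null(td)) return(NA_real_)
    fit <- fit_path_model(model, td$S, n = td$n, se = FALSE)
    if (!fit$converged) return(NA_real_)
    unname(standardize(fit)[focal])
  }
  sp_class <- fc$pool_class[match(occ$species_id, ctx$pool)]
  observed <- coef_for(class_counts(ui, sp_class,
                                    length(ctx$unit_levels)))
  stop_if(is.na(observed),
          "observed SEM did not converge (or focal path '", focal,
          "' missing)")
  # reshuffle: k distinct species per unit, uniform from the global pool
  # (the scheme of permute_primates, integer-coded for speed); per-unit
  # richness is preserved by construction
  draw_units <- which(k_per_unit > 0L)
  unit_rep <- rep(draw_units, times = k_per_unit[draw_units])
  null <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      idx <- unlist(lapply(draw_units, function(u)
        sample.int(npool, k_per_unit[u])), use.names = FALSE)
      counts <- class_counts(unit_rep, fc$pool_class[idx],
                             length(ctx$unit_levels))
      tryCatch(coef_for(counts), error = function(e) NA_real_)
    }, numeric(1))
  })
  n_fail <- sum(is.na(null))
  stop_if(n_fail > max_fail * reps,
          n_fail, " of ", reps, " permutation replicates failed to ",
          "converge (limit ", round(max_fail * reps), ")")
  ok <- null[!is.na(null)]
  qtl <- mean(ok < observed)
  significant <- switch(alternative,
                        greater = qtl > level,
                        two_sided = qtl > 1 - (1 - level) / 2 ||
                          qtl < (1 - level) / 2)
  structure(list(observed = observed, null = null, quantile = qtl,
                 significant = significant, reps = reps, seed = seed,
                 alternative = alternative, level = level,
                 n_failed = n_fail, focal = focal),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test for", x$focal, "\n")
  cat(sprintf("  observed std. coef. = %.4f, null quantile = %.3f (%d reps)\n",
              x$observed, x$quantile, x$reps))
  cat("  significant (", x$alternative, ", level ", x$level, "): ",
      x$significant, "\n", sep = "")
  invisible(x)
}

#' Progressive palm-richness delimitation of the focal effect
#'
#' Refits the SEM on nested subsets of units obtained by progressively
#' raising the minimum palatable palm (food-plant) richness from
#' `thresholds[1]` to the last threshold, and records the standardized
#' coefficient of the focal path with its standard error at each step.
#' With the default thresholds 2..16 this yields 15 fits, tracing how the
#' effect strength changes from arid, palm-poor regions towards humid
#' species-rich ones.  Thresholds whose subset retains fewer than
#' `min_units` units are recorded as skipped.
#'
#' @param table an `assemblage` table (gridded or not).
#' @param model a [path_model()] on the transformed variable names.
#' @param focal `"cause->effect"` string.
#' @param thresholds strictly increasing integer vector of minimum palm
#'   richness values (default `2:16`).
#' @param focal_class,min_focal passed to [filter_units()].
#' @param min_units floor on retained units below which a threshold is
#'   skipped (default 30).
#' @return data.frame of class `gradient_result`: `threshold`, `n_units`,
#'   `estimate` (standardized), `se`, `gates_ok`, `skipped`.
#' @export
progressive_delimitation <- function(table, model, focal,
                                     thresholds = 2:16,
                                     focal_class = "trichromat",
                                     min_focal = 1L, min_units = 30L) {
  stop_if(length(thresholds) < 1 || any(diff(thresholds) <= 0),
          "`thresholds` must be strictly increasing")
  sp <- strsplit(focal, "->", fixed = TRUE)[[1]]
  out <- data.frame(threshold = thresholds, n_units = NA_integer_,
                    estimate = NA_real_, se = NA_real_,
                    gates_ok = NA, skipped = FALSE)
  for (i in seq_along(thresholds)) {
    t_i <- thresholds[i]
    sub <- suppressMessages(
      filter_units(table, focal_class, min_focal, min_palms = t_i))
    out$n_units[i] <- nrow(sub)
    if (nrow(sub) < min_units) {
      out$skipped[i] <- TRUE
      next
    }
    td <- transform_variables(sub)
    fit <- fit_path_model(model, td)
    std <- standardize(fit)
    row <- which(fit$paths$cause == sp[1] & fit$paths$effect == sp[2])
    stop_if(!length(row), "focal path '", focal, "' not in the model")
    sds <- sqrt(diag(fit$Sigma))
    out$estimate[i] <- std[[focal]]
    out$se[i] <- fit$paths$se[row] * sds[[sp[1]]] / sds[[sp[2]]]
    out$gates_ok[i] <- fit_gates(fit)$all_ok
  }
  class(out) <- c("gradient_result", "data.frame")
  attr(out, "focal") <- focal
  out
}
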