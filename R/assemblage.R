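# Assemblage construction: per-unit richness by colour-vision class, palm
# fruit-colour counts and the proportion conspicuous, unit filtering and
# the modelling transforms.

#' Classify a fruit-colour description
#'
#' A species is `excluded` when none of its listed colours belongs to the
#' set primates feed on (brown, green, orange, yellow, red, purple);
#' otherwise it is `conspicuous` when any colour is orange, red, yellow or
#' pink, else `non_conspicuous`.  Palatability is tested against the union
#' of listed colours first; conspicuousness then triggers on any
#' conspicuous colour (a fruit displaying any reddish colour is detectable
#' to a trichromat).  Excluded species never enter the proportion
#' conspicuous.
#'
#' @param colours character vector: the set of colours in one species'
#'   fruit description (non-empty, all from the 14-colour vocabulary).
#' @return one of `"conspicuous"`, `"non_conspicuous"`, `"excluded"`.
#' @examples
#' classify_fruit_colour("red")            # conspicuous
#' classify_fruit_colour("blue")           # excluded (not a primate colour)
#' classify_fruit_colour(c("green","red")) # conspicuous
#' @export
classify_fruit_colour <- function(colours) {
  stop_if(length(colours) == 0L || any(is.na(colours)) ||
            any(!nzchar(colours)),
          "colour set must be non-empty")
  unknown <- setdiff(colours, COLOUR_VOCAB)
  stop_if(length(unknown) > 0,
          "unknown colour token(s): ", paste(unknown, collapse = ", "))
  if (!any(colours %in% PALATABLE_COLOURS)) return("excluded")
  if (any(colours %in% CONSPICUOUS_COLOURS)) return("conspicuous")
  "non_conspicuous"
}

#' Classify many comma-separated fruit-colour descriptions
#'
#' @param colour_strings character vector, each element a comma-separated
#'   colour list (e.g. `"green,red"`).
#' @return character vector of classifications.
#' @export
classify_fruit_colours <- function(colour_strings) {
  vapply(strsplit(as.character(colour_strings), ","),
         function(cc) classify_fruit_colour(trimws(cc)), character(1))
}

#' Build a per-unit assemblage table
#'
#' One row per unit in `units`: richness of each colour-vision class
#' (optionally restricted to day-active frugivores), counts of conspicuous
#' and non-conspicuous palatable palm species, the proportion conspicuous
#' (total conspicuous divided by conspicuous plus non-conspicuous; `NA`
#' with `prop_defined = FALSE` when no palatable palms occur), and the unit
#' covariates.  Occurrence rows are de-duplicated, so the table is
#' invariant to repeated rows.
#'
#' @param occ_primates,occ_palms occurrence tables (`unit_id`,
#'   `species_id`).
#' @param primate_traits trait table with `species_id`, `vision_system`,
#'   `activity`, `frugivory_rank`.
#' @param palm_traits trait table with `species_id`, `colours`
#'   (comma-separated string).
#' @param units unit table with `unit_id`, covariates, `area`, `realm` and
#'   optional grid coordinates.
#' @param subset `"all"`, or `"diurnal_frugivores"` to count only
#'   day-active primates with frugivory rank 1-3.  Cathemeral/crepuscular
#'   species are not treated as day-active unless
#'   `cathemeral_is_diurnal = TRUE`.
#' @param cathemeral_is_diurnal logical toggle for the conservative
#'   activity reading.
#' @return data.frame of class `assemblage`.
#' @export
build_assemblage <- function(occ_primates, occ_palms, primate_traits,
                             palm_traits, units,
                             subset = c("all", "diurnal_frugivores"),
                             cathemeral_is_diurnal = FALSE) {
  subset <- match.arg(subset)
  check_occurrences(occ_primates, primate_traits$species_id, units$unit_id,
                    "primate")
  check_occurrences(occ_palms, palm_traits$species_id, units$unit_id,
                    "palm")
  occ_primates <- unique(occ_primates[c("unit_id", "species_id")])
  occ_palms <- unique(occ_palms[c("unit_id", "species_id")])

  stop_if(any(!primate_traits$vision_system %in% VISION_LEVELS),
          "vision_system must be one of: ",
          paste(VISION_LEVELS, collapse = ", "))
  stop_if(any(!primate_traits$frugivory_rank %in% 0:3),
          "frugivory_rank must be in 0..3")

  keep <- rep(TRUE, nrow(primate_traits))
  if (subset == "diurnal_frugivores") {
    diurnal <- primate_traits$activity == "diurnal"
    if (cathemeral_is_diurnal)
      diurnal <- diurnal | primate_traits$activity == "cathemeral_crepuscular"
    keep <- diurnal & primate_traits$frugivory_rank >= 1
  }
  vis <- setNames(primate_traits$vision_system, primate_traits$species_id)
  incl <- setNames(keep, primate_traits$species_id)

  op <- occ_primates[incl[occ_primates$species_id], , drop = FALSE]
  uf <- factor(op$unit_id, levels = units$unit_id)
  count_class <- function(level)
    as.integer(table(uf[vis[op$species_id] == level]))
  richness_trichromat <- count_class("routine_trichromatic")
  richness_polymorph <- count_class("polymorphic")
  richness_other <- count_class("dichromatic_or_monochromatic")

  cls <- setNames(classify_fruit_colours(palm_traits$colours),
                  palm_traits$species_id)
  pf <- factor(occ_palms$unit_id, levels = units$unit_id)
  pc <- cls[occ_palms$species_id]
  n_conspicuous <- as.integer(table(pf[pc == "conspicuous"]))
  n_nonconspicuous <- as.integer(table(pf[pc == "non_conspicuous"]))
  palatable <- n_conspicuous + n_nonconspicuous
  prop <- ifelse(palatable > 0, n_conspicuous / pmax(palatable, 1L),
                 NA_real_)

  out <- data.frame(unit_id = units$unit_id,
                    richness_trichromat = richness_trichromat,
                    richness_polymorph = richness_polymorph,
                    richness_other = richness_other,
                    n_conspicuous = n_conspicuous,
                    n_nonconspicuous = n_nonconspicuous,
                    prop_conspicuous = prop,
                    prop_defined = palatable > 0,
                    stringsAsFactors = FALSE)
  covs <- intersect(c(COVARIATE_NAMES, "area", "realm", "grid_row",
                      "grid_col"), names(units))
  out <- cbind(out, units[covs])
  attr(out, "subset") <- subset
  class(out) <- c("assemblage", "data.frame")
  out
}

check_occurrences <- function(occ, species_ids, unit_ids, what) {
  stop_if(!all(c("unit_id", "species_id") %in% names(occ)),
          what, " occurrence table needs unit_id and species_id columns")
  bad_sp <- setdiff(unique(occ$species_id), species_ids)
  stop_if(length(bad_sp) > 0,
          what, " occurrences reference species missing from traits: ",
          paste(head(bad_sp, 10), collapse = ", "))
  bad_u <- setdiff(unique(occ$unit_id), unit_ids)
  stop_if(length(bad_u) > 0,
          what, " occurrences reference unknown units: ",
          paste(head(bad_u, 10), collapse = ", "))
  invisible(NULL)
}

#' Filter assemblage units for analysis
#'
#' Keeps units with at least `min_focal` species of the focal colour-vision
#' class and at least `min_palms` palatable (non-excluded) palm species.
#' The defaults implement "more than zero trichromats and/or polymorphs and
#' more than two palm species"; "palm species" counts only palatable
#' species, since excluded species never enter the proportion.
#'
#' @param table an `assemblage` table.
#' @param focal_class `"trichromat"`, `"polymorph"`, or
#'   `"trichromat_polymorph"` (the sum).
#' @param min_focal minimum focal richness (default 1).
#' @param min_palms minimum palatable palm richness (default 3).
#' @return the filtered table (possibly with zero rows).
#' @export
filter_units <- function(table,
                         focal_class = c("trichromat", "polymorph",
                                         "trichromat_polymorph"),
                         min_focal = 1L, min_palms = 3L) {
  focal_class <- match.arg(focal_class)
  focal <- focal_richness(table, focal_class)
  palatable <- table$n_conspicuous + table$n_nonconspicuous
  keep <- focal >= min_focal & palatable >= min_palms
  out <- table[keep, , drop = FALSE]
  attr(out, "subset") <- attr(table, "subset")
  attr(out, "focal_class") <- focal_class
  if (!nrow(out))
    message("filter_units: no units satisfy the filter")
  out
}

focal_richness <- function(table, focal_class) {
  switch(focal_class,
         trichromat = table$richness_trichromat,
         polymorph = table$richness_polymorph,
         trichromat_polymorph =
           table$richness_trichromat + table$richness_polymorph)
}

#' Transform assemblage variables for modelling
#'
#' Applies the modelling transforms in this order: square root of each
#' richness column (to normalise counts), natural log of area, then min-max
#' scaling of every model variable to \[0, 1\].  Transforming before
#' scaling preserves the purpose of each transform on the modelled scale.
#' Scaling constants are recorded in `attr(, "scaling")` so values can be
#' inverted.
#'
#' @param table a (filtered) `assemblage` table.
#' @param vars variables to scale; defaults to the richness columns,
#'   `prop_conspicuous`, the climate/canopy covariates and `area` (when
#'   present).
#' @return data.frame of the transformed variables, `unit_id` first, with a
#'   `scaling` attribute (var, transform, min, max).
#' @export
transform_variables <- function(table, vars = NULL) {
  rich_cols <- intersect(c("richness_trichromat", "richness_polymorph",
                           "richness_other"), names(table))
  if (is.null(vars))
    vars <- intersect(c(rich_cols, "prop_conspicuous", COVARIATE_NAMES,
                        "area"), names(table))
  stop_if(!all(vars %in% names(table)),
          "missing variables: ", paste(setdiff(vars, names(table)),
                                       collapse = ", "))
  out <- data.frame(unit_id = table$unit_id, stringsAsFactors = FALSE)
  scaling <- data.frame(var = vars, transform = "none", min = NA_real_,
                        max = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(vars)) {
    v <- vars[i]
    x <- table[[v]]
    stop_if(any(is.na(x)),
            "variable '", v, "' has missing values (filter units first)")
    if (v %in% rich_cols) {
      x <- sqrt(x)
      scaling$transform[i] <- "sqrt"
    } else if (v == "area") {
      stop_if(any(x <= 0), "area must be positive")
      x <- log(x)
      scaling$transform[i] <- "log"
    }
    lo <- min(x)
    hi <- max(x)
    stop_if(hi - lo <= 0, "variable '", v,
            "' is constant after transformation; cannot min-max scale")
    out[[v]] <- (x - lo) / (hi - lo)
    scaling$min[i] <- lo
    scaling$max[i] <- hi
  }
  if ("area" %in% vars) names(out)[names(out) == "area"] <- "log_area"
  attr(out, "scaling") <- scaling
  attr(out, "subset") <- attr(table, "subset")
  out
}
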