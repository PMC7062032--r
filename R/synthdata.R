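# Synthetic-data generators.  These emulate the statistical structure of the
# real inputs -- spatial units with correlated climate covariates, palm
# floras with a conspicuousness gradient, primate assemblages generated from
# a known structural equation, and phylogenies with discrete-trait
# evolution -- so every downstream stage can be exercised and calibrated
# without any external download.

#' Specify a synthetic landscape of spatial units
#'
#' A landscape is a set of sampling units (botanical countries or equal-area
#' grid cells) with climate/structure covariates drawn from a multivariate
#' normal distribution and log-normal areas.
#'
#' @param n_units number of units (>= 1).
#' @param covariate_means named numeric vector of means for the five
#'   covariates `temp` (annual mean temperature, degC x 10), `prec` (annual
#'   precipitation, mm), `tseas` (temperature seasonality, sd degC x 10),
#'   `pseas` (precipitation seasonality, CV), `canopy` (canopy height, m).
#' @param covariate_sds named numeric vector of standard deviations, same
#'   names.
#' @param covariate_correlation 5x5 correlation matrix (positive
#'   semi-definite, unit diagonal) in the order of `covariate_means`.
#' @param area_log_mean,area_log_sd mean and sd of log area (km^2).
#' @param grid_dims optional `c(rows, cols)`; if given, `rows * cols` must
#'   equal `n_units` and units receive integer grid coordinates.
#' @param seed integer seed; the same spec (including seed) always yields an
#'   identical landscape.
#' @return an object of class `landscape_spec`.
#' @seealso [generate_landscape()]
#' @export
landscape_spec <- function(n_units,
                           covariate_means = c(temp = 240, prec = 1400,
                                               tseas = 250, pseas = 60,
                                               canopy = 25),
                           covariate_sds = c(temp = 40, prec = 700,
                                             tseas = 120, pseas = 25,
                                             canopy = 10),
                           covariate_correlation = default_covariate_correlation(),
                           area_log_mean = log(2e5), area_log_sd = 1,
                           grid_dims = NULL, seed = 1L) {
  stop_if(!is_count(n_units), "`n_units` must be a positive integer")
  stop_if(!all(COVARIATE_NAMES %in% names(covariate_means)) ||
            !all(COVARIATE_NAMES %in% names(covariate_sds)),
          "covariate means/sds must be named ",
          paste(COVARIATE_NAMES, collapse = ", "))
  R <- as.matrix(covariate_correlation)
  stop_if(!isTRUE(all.equal(dim(R), c(5L, 5L))) ||
            !isTRUE(all.equal(R, t(R), tolerance = 1e-8)) ||
            !isTRUE(all.equal(unname(diag(R)), rep(1, 5))),
          "`covariate_correlation` must be a symmetric 5x5 correlation matrix")
  stop_if(any(abs(R) > 1 + 1e-12), "correlations must lie in [-1, 1]")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  stop_if(min(ev) < -1e-8,
          "`covariate_correlation` is not positive semi-definite")
  if (!is.null(grid_dims)) {
    stop_if(length(grid_dims) != 2L || !is_count(grid_dims[1]) ||
              !is_count(grid_dims[2]),
            "`grid_dims` must be two positive integers")
    stop_if(prod(grid_dims) != n_units,
            "grid_dims (", grid_dims[1], " x ", grid_dims[2],
            ") do not multiply to n_units = ", n_units)
  }
  structure(list(n_units = as.integer(n_units),
                 covariate_means = covariate_means[COVARIATE_NAMES],
                 covariate_sds = covariate_sds[COVARIATE_NAMES],
                 covariate_correlation = R,
                 area_log_mean = area_log_mean, area_log_sd = area_log_sd,
                 grid_dims = if (is.null(grid_dims)) NULL
                             else as.integer(grid_dims),
                 seed = as.integer(seed)),
            class = "landscape_spec")
}

#' Default covariate correlation for synthetic landscapes
#'
#' Moderate, climate-realistic dependence: wetter places are warmer and have
#' taller canopies and lower seasonality.
#' @return a 5x5 correlation matrix.
#' @export
default_covariate_correlation <- function() {
  R <- diag(5)
  dimnames(R) <- list(COVARIATE_NAMES, COVARIATE_NAMES)
  set2 <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set2("temp", "prec", 0.30)
  set2("temp", "tseas", -0.45)
  set2("prec", "pseas", -0.35)
  set2("prec", "canopy", 0.55)
  set2("temp", "canopy", 0.25)
  set2("tseas", "canopy", -0.30)
  R
}

#' Generate a landscape unit table
#'
#' Draws per-unit covariates from the multivariate normal distribution in
#' the spec (non-negative variables are floored at a small positive value),
#' log-normal areas, and optional grid coordinates.
#'
#' @param spec a [landscape_spec()].
#' @param realm realm label attached to every unit.
#' @return data.frame with columns `unit_id`, the five covariates, `area`,
#'   `realm`, and `grid_row`/`grid_col` when the spec is gridded.
#' @export
generate_landscape <- function(spec, realm = "Africa") {
  stop_if(!inherits(spec, "landscape_spec"), "`spec` must be a landscape_spec")
  n <- spec$n_units
  sds <- spec$covariate_sds
  Sigma <- diag(sds) %*% spec$covariate_correlation %*% diag(sds)
  with_seed(spec$seed, {
    X <- MASS::mvrnorm(n, mu = spec$covariate_means, Sigma = Sigma)
    X <- matrix(X, nrow = n, dimnames = list(NULL, COVARIATE_NAMES))
    for (v in c("prec", "tseas", "pseas", "canopy"))
      X[, v] <- pmax(X[, v], 0.01 * spec$covariate_means[[v]])
    area <- exp(rnorm(n, spec$area_log_mean, spec$area_log_sd))
    out <- data.frame(unit_id = id_seq("u", n), X, area = area,
                      realm = realm, stringsAsFactors = FALSE)
    if (!is.null(spec$grid_dims)) {
      out$grid_row <- rep(seq_len(spec$grid_dims[1]),
                          each = spec$grid_dims[2])
      out$grid_col <- rep(seq_len(spec$grid_dims[2]),
                          times = spec$grid_dims[1])
    }
    out
  })
}

#' Generate a synthetic palm flora with a conspicuousness gradient
#'
#' Each synthetic palm species carries a single fruit colour.  Palatable
#' species (colours primates feed on) split into conspicuous and
#' non-conspicuous pools; per unit, palm richness is Poisson and the number
#' of conspicuous species is binomial with success probability
#' `plogis(intercept + slope * z)` where `z` is the standardised gradient
#' covariate, so the per-unit expected proportion conspicuous follows a
#' logistic function of that covariate with exactly the requested slope.  A
#' small fraction of species get non-palatable colours; these exercise the
#' exclusion rule downstream and never enter the proportion.
#'
#' @param units a unit table from [generate_landscape()].
#' @param n_species total number of palm species in the pool.
#' @param gradient_covariate name of the unit covariate driving the
#'   conspicuousness gradient.
#' @param slope logistic slope on the standardised covariate (0 = no
#'   gradient).
#' @param intercept logistic intercept (0 means proportion 0.5 at the
#'   covariate mean).
#' @param mean_richness expected palatable palm richness per unit.
#' @param excluded_fraction fraction of the species pool given non-palatable
#'   colours.
#' @param seed integer seed.
#' @return list with `palms` (species_id, colours) and `occurrences`
#'   (unit_id, species_id).
#' @export
generate_palm_flora <- function(units, n_species = 200,
                                gradient_covariate = "prec", slope = 1,
                                intercept = 0, mean_richness = 8,
                                excluded_fraction = 0.1, seed = 1L) {
  stop_if(!is_count(n_species), "`n_species` must be >= 1")
  stop_if(!gradient_covariate %in% names(units),
          "gradient covariate '", gradient_covariate,
          "' not found in unit table")
  x <- units[[gradient_covariate]]
  z <- if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  p_consp <- plogis(intercept + slope * z)

  n_excl <- round(n_species * excluded_fraction)
  n_pal <- n_species - n_excl
  n_c <- ceiling(n_pal / 2)
  n_n <- n_pal - n_c
  with_seed(seed, {
    ids <- id_seq("palm", n_species)
    consp_ids <- ids[seq_len(n_c)]
    non_ids <- ids[n_c + seq_len(n_n)]
    excl_ids <- if (n_excl > 0) ids[n_pal + seq_len(n_excl)] else character(0)
    colours <- c(sample(c("red", "orange", "yellow"), n_c, replace = TRUE),
                 sample(c("brown", "green", "purple"), n_n, replace = TRUE),
                 sample(c("blue", "white", "cream", "grey", "ivory",
                          "straw", "pink"), n_excl, replace = TRUE))
    palms <- data.frame(species_id = ids, colours = colours,
                        stringsAsFactors = FALSE)

    occ <- vector("list", nrow(units))
    for (i in seq_len(nrow(units))) {
      R <- rpois(1L, mean_richness)
      # one binomial split of the palatable richness into conspicuous vs not
      k_c <- min(rbinom(1L, R, p_consp[i]), n_c)
      k_n <- min(R - k_c, n_n)
      k_x <- min(rpois(1L, mean_richness * excluded_fraction * 0.5), n_excl)
      sp <- c(sample_distinct(consp_ids, k_c),
              sample_distinct(non_ids, k_n),
              sample_distinct(excl_ids, k_x))
      occ[[i]] <- if (length(sp))
        data.frame(unit_id = units$unit_id[i], species_id = sp,
                   stringsAsFactors = FALSE)
      else NULL
    }
    occurrences <- do.call(rbind, occ)
    rownames(occurrences) <- NULL
    list(palms = palms, occurrences = occurrences)
  })
}

#' Define a ground-truth structural scenario
#'
#' The scenario fixes the standardized path coefficients used to generate
#' primate richness from (standardised) unit-level predictors.  Richness is
#' generated on the square-root scale with Gaussian noise and
#' back-transformed, matching the analysis transform, so the downstream
#' standardized-coefficient estimates recover the scenario values in
#' expectation.
#'
#' @param paths named numeric vector; names are edges `"cause->effect"`
#'   (e.g. `"prop_conspicuous->richness_trichromat"`), values are
#'   standardized coefficients in \[-1, 1\].
#' @param residual_sd optional named vector of residual sds per endogenous
#'   variable on the standardised scale; defaults to the value that makes
#'   each endogenous variable have unit variance (so the coefficients are
#'   standardized coefficients exactly).
#' @param noise_model `"sqrt_gaussian"` (Gaussian noise on the sqrt-richness
#'   scale, then squared and rounded) or `"poisson"` (Poisson counts with
#'   mean equal to the squared sqrt-scale linear predictor).
#' @param sqrt_mean,sqrt_scale location and scale mapping the standardised
#'   response to the sqrt-richness scale.
#' @return object of class `structural_scenario`.
#' @export
structural_scenario <- function(paths,
                                residual_sd = NULL,
                                noise_model = c("sqrt_gaussian", "poisson"),
                                sqrt_mean = 3, sqrt_scale = 0.6) {
  noise_model <- match.arg(noise_model)
  stop_if(is.null(names(paths)) || any(!grepl("->", names(paths))),
          "`paths` must be named 'cause->effect'")
  stop_if(any(abs(paths) > 1), "standardized coefficients must lie in [-1, 1]")
  edges <- do.call(rbind, strsplit(names(paths), "->", fixed = TRUE))
  edges <- data.frame(cause = trimws(edges[, 1]), effect = trimws(edges[, 2]),
                      beta = unname(paths), stringsAsFactors = FALSE)
  stop_if(any(edges$cause == edges$effect), "self-loop in scenario paths")
  # acyclicity check by repeated leaf stripping
  vars <- unique(c(edges$cause, edges$effect))
  e <- edges
  repeat {
    leaves <- setdiff(vars, e$cause)
    if (!length(leaves)) break
    vars <- setdiff(vars, leaves)
    e <- e[!(e$effect %in% leaves), , drop = FALSE]
    if (!nrow(e)) break
  }
  stop_if(nrow(e) > 0, "scenario edge set is cyclic")
  structure(list(edges = edges, residual_sd = residual_sd,
                 noise_model = noise_model, sqrt_mean = sqrt_mean,
                 sqrt_scale = sqrt_scale),
            class = "structural_scenario")
}

#' Generate a synthetic primate assemblage from a structural scenario
#'
#' Computes the per-unit predictors (proportion of conspicuous palm fruits
#' from the palm flora, plus the landscape covariates and log area),
#' standardises them, generates the endogenous richness variables named in
#' the scenario from the structural equations, and assigns species
#' identities by drawing, for each unit and vision class, the realised
#' number of species uniformly without replacement from a global class pool
#' (so vision labels are exchangeable across units in the null scenario).
#'
#' Endogenous variable names must be among `richness_trichromat`,
#' `richness_polymorph`, `richness_other`; classes without a structural
#' equation get independent Poisson richness.
#'
#' @param units unit table from [generate_landscape()].
#' @param palm_flora list from [generate_palm_flora()].
#' @param scenario a [structural_scenario()].
#' @param n_species global primate pool size; split across vision classes by
#'   `class_fractions` (defaults follow the observed global shares of
#'   routine trichromats and polymorphs among primates).
#' @param class_fractions named fractions for trichromat/polymorph/other.
#' @param baseline_richness Poisson mean for classes with no structural
#'   equation.
#' @param seed integer seed.
#' @return list with `primates` (trait table), `occurrences`
#'   (unit_id, species_id) and `truth` (per-unit generated richness and the
#'   standardised predictors used).
#' @export
generate_primate_assemblage <- function(units, palm_flora, scenario,
                                        n_species = 411,
                                        class_fractions = c(trichromat = 0.38,
                                                            polymorph = 0.31,
                                                            other = 0.31),
                                        baseline_richness = 3,
                                        seed = 1L) {
  stop_if(!inherits(scenario, "structural_scenario"),
          "`scenario` must be a structural_scenario")
  preds <- unit_predictors(units, palm_flora)
  known <- c(colnames(preds),
             "richness_trichromat", "richness_polymorph", "richness_other")
  bad <- setdiff(unique(scenario$edges$cause), known)
  stop_if(length(bad) > 0,
          "scenario references missing predictor(s): ",
          paste(bad, collapse = ", "))
  endo <- unique(scenario$edges$effect)
  bad_endo <- setdiff(endo, c("richness_trichromat", "richness_polymorph",
                              "richness_other"))
  stop_if(length(bad_endo) > 0,
          "scenario endogenous variables must be richness classes, not: ",
          paste(bad_endo, collapse = ", "))

  zscale <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  Z <- as.data.frame(lapply(as.data.frame(preds), zscale))
  n <- nrow(units)

  with_seed(seed, {
    classes <- c("richness_trichromat", "richness_polymorph",
                 "richness_other")
    rich <- matrix(0L, n, 3, dimnames = list(NULL, classes))
    # topological order over endogenous variables (effects may feed effects)
    order_endo <- character(0)
    remaining <- endo
    while (length(remaining)) {
      e <- scenario$edges[scenario$edges$effect %in% remaining, , drop = FALSE]
      ready <- remaining[!vapply(remaining, function(v)
        any(e$cause[e$effect == v] %in% remaining), logical(1))]
      stop_if(!length(ready), "cyclic scenario (should be unreachable)")
      order_endo <- c(order_endo, ready)
      remaining <- setdiff(remaining, ready)
    }
    for (v in classes) {
      if (!v %in% endo) {
        rich[, v] <- rpois(n, baseline_richness)
        next
      }
      ed <- scenario$edges[scenario$edges$effect == v, , drop = FALSE]
      lin <- rep(0, n)
      for (j in seq_len(nrow(ed))) lin <- lin + ed$beta[j] * Z[[ed$cause[j]]]
      res_sd <- scenario$residual_sd[[v]] %||% {
        v_lin <- var(lin)
        stop_if(v_lin >= 1,
                "scenario implies standardized variance > 1 for ", v)
        sqrt(1 - v_lin)
      }
      ystar <- lin + rnorm(n, 0, res_sd)
      ysqrt <- pmax(scenario$sqrt_mean + scenario$sqrt_scale * ystar, 0)
      rich[, v] <- switch(scenario$noise_model,
                          sqrt_gaussian = as.integer(round(ysqrt^2)),
                          poisson = rpois(n, ysqrt^2))
      Z[[v]] <- zscale(sqrt(rich[, v]))  # allow downstream endogenous use
    }

    # global species pools and traits
    n_t <- round(n_species * class_fractions[["trichromat"]])
    n_p <- round(n_species * class_fractions[["polymorph"]])
    n_o <- n_species - n_t - n_p
    vision <- rep(VISION_LEVELS, times = c(n_t, n_p, n_o))
    ids <- id_seq("prim", n_species)
    act_prob <- rbind(routine_trichromatic = c(0.90, 0.05, 0.05),
                      polymorphic = c(0.85, 0.05, 0.10),
                      dichromatic_or_monochromatic = c(0.25, 0.65, 0.10))
    activity <- vapply(vision, function(v)
      sample(ACTIVITY_LEVELS, 1L, prob = act_prob[v, ]), character(1))
    frug <- sample(0:3, n_species, replace = TRUE,
                   prob = c(0.2, 0.3, 0.3, 0.2))
    primates <- data.frame(species_id = ids, vision_system = vision,
                           activity = unname(activity), frugivory_rank = frug,
                           realm = units$realm[1] %||% "Africa",
                           stringsAsFactors = FALSE)
    pools <- split(ids, vision)

    occ <- vector("list", n * 3)
    key <- c(richness_trichromat = "routine_trichromatic",
             richness_polymorph = "polymorphic",
             richness_other = "dichromatic_or_monochromatic")
    idx <- 1L
    for (i in seq_len(n)) {
      for (v in classes) {
        k <- rich[i, v]
        pool <- pools[[key[[v]]]]
        k <- min(k, length(pool))
        if (k > 0) {
          occ[[idx]] <- data.frame(unit_id = units$unit_id[i],
                                   species_id = sample_distinct(pool, k),
                                   stringsAsFactors = FALSE)
          idx <- idx + 1L
        }
      }
    }
    occurrences <- do.call(rbind, occ[seq_len(idx - 1L)])
    if (is.null(occurrences))
      occurrences <- data.frame(unit_id = character(0),
                                species_id = character(0))
    rownames(occurrences) <- NULL
    truth <- cbind(data.frame(unit_id = units$unit_id), as.data.frame(rich),
                   Z[colnames(preds)])
    list(primates = primates, occurrences = occurrences, truth = truth)
  })
}

# Per-unit predictor table: proportion conspicuous from the palm flora plus
# covariates and log area.  Internal; the assemblage module owns the public
# equivalent.
unit_predictors <- function(units, palm_flora) {
  cls <- classify_fruit_colours(palm_flora$palms$colours)
  tab <- merge(palm_flora$occurrences,
               data.frame(species_id = palm_flora$palms$species_id,
                          cls = cls, stringsAsFactors = FALSE),
               by = "species_id")
  nc <- tapply(tab$cls == "conspicuous", tab$unit_id, sum)
  nn <- tapply(tab$cls == "non_conspicuous", tab$unit_id, sum)
  ncv <- setNames(rep(0, nrow(units)), units$unit_id)
  nnv <- ncv
  ncv[names(nc)] <- nc
  nnv[names(nn)] <- nn
  prop <- rep(0.5, nrow(units))  # neutral fill where no palatable palms
  ok <- (ncv + nnv) > 0
  prop[ok] <- ncv[ok] / (ncv[ok] + nnv[ok])
  out <- data.frame(prop_conspicuous = unname(prop),
                    temp = units$temp, prec = units$prec,
                    tseas = units$tseas, pseas = units$pseas,
                    canopy = units$canopy, log_area = log(units$area))
  out
}

#' Simulate a birth-death tree with a discrete trait
#'
#' The tree is an ultrametric birth-death phylogeny conditioned on the
#' number of tips (via [ape::rphylo()]); the trait then evolves along the
#' branches under a continuous-time Markov chain with rate matrix `Q`.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth,death speciation and extinction rates (events/lineage/Myr);
#'   `death < birth` is required for conditioning on survival.
#' @param Q k x k rate matrix, rows summing to zero, off-diagonals >= 0;
#'   dimnames give the state labels (defaults `s1..sk`).
#' @param root_state optional state label for the root; default drawn from
#'   the uniform distribution over states.
#' @param seed integer seed.
#' @return list with `tree` (an [ape::phylo]), `tip_states` (named character
#'   vector) and `node_states`.
#' @export
simulate_tree_and_trait <- function(n_tips, birth = 1, death = 0, Q,
                                    root_state = NULL, seed = 1L) {
  stop_if(!is_count(n_tips, 2L), "`n_tips` must be >= 2")
  stop_if(death >= birth,
          "death >= birth: conditioning on n_tips survivors is impossible")
  Q <- validate_rate_matrix(Q)
  states <- rownames(Q)
  with_seed(seed, {
    tree <- ape::rphylo(n_tips, birth, death)
    sts <- sim_ctmc_on_tree(tree, Q, root_state)
    list(tree = tree, tip_states = sts$tip_states,
         node_states = sts$node_states)
  })
}

# Evolve a CTMC along a phylo; returns tip and node states.  Uses the
# current RNG stream (callers seed it).
sim_ctmc_on_tree <- function(tree, Q, root_state = NULL) {
  states <- rownames(Q)
  k <- length(states)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  st <- integer(ntip + nnode)
  st[root] <- if (is.null(root_state)) sample.int(k, 1L)
              else match(root_state, states)
  stop_if(is.na(st[root]), "unknown root_state")
  ord <- reorder(tree, "cladewise")  # parent before child
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]
    chd <- ord$edge[e, 2]
    st[chd] <- sim_ctmc_branch(st[par], ord$edge.length[e], Q)$end
  }
  tip_states <- setNames(states[st[seq_len(ntip)]], tree$tip.label)
  node_states <- setNames(states[st[root:(ntip + nnode)]],
                          as.character(root:(ntip + nnode)))
  list(tip_states = tip_states, node_states = node_states)
}

# One CTMC realisation along a branch; returns end state and the segment
# history (states and durations, in order from the start of the branch).
sim_ctmc_branch <- function(start, len, Q) {
  s <- start
  t <- 0
  seg_state <- integer(0)
  seg_len <- numeric(0)
  repeat {
    rate <- -Q[s, s]
    dt <- if (rate <= 0) Inf else rexp(1L, rate)
    if (t + dt >= len) {
      seg_state <- c(seg_state, s)
      seg_len <- c(seg_len, len - t)
      break
    }
    seg_state <- c(seg_state, s)
    seg_len <- c(seg_len, dt)
    t <- t + dt
    p <- Q[s, ]
    p[s] <- 0
    s <- sample.int(length(p), 1L, prob = p)
  }
  list(end = s, states = seg_state, durations = seg_len)
}

validate_rate_matrix <- function(Q, what = "Q") {
  Q <- as.matrix(Q)
  stop_if(nrow(Q) != ncol(Q) || nrow(Q) < 2,
          what, " must be a k x k matrix with k >= 2")
  if (is.null(rownames(Q))) {
    rownames(Q) <- colnames(Q) <- paste0("s", seq_len(nrow(Q)))
  }
  off <- Q
  diag(off) <- 0
  stop_if(any(off < 0), what, " off-diagonal rates must be >= 0")
  stop_if(any(abs(rowSums(Q)) > 1e-8 * max(1, max(abs(Q)))),
          what, " rows must sum to zero")
  Q
}

#' Specify a state-dependent speciation-extinction (SSE) model
#'
#' @param lambda per-state speciation rates (events/lineage/Myr).
#' @param mu per-state extinction rates.
#' @param Q transition rate matrix among states (rows sum to zero).
#' @param root_treatment how state probabilities are combined at the root of
#'   a likelihood computation: `"likelihood_weighted"` (FitzJohn weights),
#'   `"flat"`, or `"equilibrium"` (stationary distribution of `Q`).
#' @param pi optional explicit root prior overriding `root_treatment`.
#' @return object of class `sse_model`.
#' @export
sse_model <- function(lambda, mu, Q,
                      root_treatment = c("likelihood_weighted", "flat",
                                         "equilibrium"),
                      pi = NULL) {
  root_treatment <- match.arg(root_treatment)
  Q <- validate_rate_matrix(Q)
  k <- nrow(Q)
  stop_if(length(lambda) != k || length(mu) != k,
          "lambda and mu must have one rate per state")
  stop_if(any(!is.finite(lambda)) || any(lambda < 0) ||
            any(!is.finite(mu)) || any(mu < 0),
          "rates must be finite and >= 0")
  if (!is.null(pi)) {
    stop_if(length(pi) != k || any(pi < 0) || abs(sum(pi) - 1) > 1e-8,
            "pi must be a probability simplex over the states")
  }
  structure(list(lambda = setNames(as.numeric(lambda), rownames(Q)),
                 mu = setNames(as.numeric(mu), rownames(Q)),
                 Q = Q, states = rownames(Q),
                 root_treatment = root_treatment, pi = pi),
            class = "sse_model")
}

#' Simulate a tree under a state-dependent diversification model
#'
#' Forward (Gillespie) birth-death simulation in which each lineage
#' speciates, goes extinct, or changes state at the rates of its current
#' state.  Extinct lineages are pruned; the simulation stops when the
#' extant count reaches `n_tips` (the tree is cut at that moment, so it is
#' ultrametric) or at `max_time`.  All-extinct realisations are retried up
#' to `max_retries` times.
#'
#' @param model an [sse_model()].
#' @param n_tips stop when this many lineages are extant (>= 2), or `NULL`.
#' @param max_time stop at this time, or `NULL`.  Exactly one of `n_tips`
#'   and `max_time` must be given.
#' @param root_state optional starting state label (default: uniform draw).
#' @param seed integer seed.
#' @param max_retries bounded retry count for all-extinct realisations.
#' @return list with `tree` (ultrametric [ape::phylo]) and `tip_states`.
#' @export
simulate_sse_tree <- function(model, n_tips = NULL, max_time = NULL,
                              root_state = NULL, seed = 1L,
                              max_retries = 100L) {
  stop_if(!inherits(model, "sse_model"), "`model` must be an sse_model")
  stop_if(is.null(n_tips) == is.null(max_time),
          "give exactly one of `n_tips` or `max_time`")
  if (!is.null(n_tips)) stop_if(!is_count(n_tips, 2L), "`n_tips` must be >= 2")
  with_seed(seed, {
    for (try in seq_len(max_retries)) {
      sim <- sse_forward_once(model, n_tips, max_time, root_state)
      if (!is.null(sim)) return(sim)
    }
    stop("all lineages went extinct in every one of ", max_retries,
         " attempts", call. = FALSE)
  })
}

# One forward realisation; NULL when fewer than 2 lineages survive.
sse_forward_once <- function(model, n_tips, max_time, root_state) {
  k <- length(model$states)
  lam <- model$lambda
  mu <- model$mu
  Q <- model$Q
  s0 <- if (is.null(root_state)) sample.int(k, 1L)
        else match(root_state, model$states)
  stop_if(is.na(s0), "unknown root_state")
  # lineage records: parent, birth time, end time, state, fate
  parent <- c(0L)
  btime <- c(0)
  etime <- c(NA_real_)
  state <- c(s0)
  fate <- c(NA_character_)  # "split", "extinct", "alive"
  alive <- c(1L)
  t <- 0
  cap <- 100000L
  repeat {
    n_alive <- length(alive)
    if (n_alive == 0L) break
    if (!is.null(n_tips) && n_alive >= n_tips) {
      fate[alive] <- "alive"
      etime[alive] <- t
      break
    }
    rates <- (lam + mu - diag(Q))[state[alive]]
    total <- sum(rates)
    dt <- if (total > 0) rexp(1L, total) else Inf
    if (!is.null(max_time) && t + dt >= max_time) {
      fate[alive] <- "alive"
      etime[alive] <- max_time
      break
    }
    stop_if(!is.finite(dt), "zero total rate with no stopping time")
    t <- t + dt
    i <- alive[sample.int(n_alive, 1L, prob = rates)]
    si <- state[i]
    ev_p <- c(lam[si], mu[si], -Q[si, si])
    ev <- sample.int(3L, 1L, prob = ev_p)
    if (ev == 1L) {                      # speciation
      etime[i] <- t
      fate[i] <- "split"
      parent <- c(parent, i, i)
      btime <- c(btime, t, t)
      etime <- c(etime, NA_real_, NA_real_)
      state <- c(state, si, si)
      fate <- c(fate, NA_character_, NA_character_)
      alive <- c(setdiff(alive, i), length(parent) - 1L, length(parent))
      if (!is.null(n_tips) && length(alive) >= n_tips) {
        fate[alive] <- "alive"
        etime[alive] <- t
        break
      }
    } else if (ev == 2L) {               # extinction
      etime[i] <- t
      fate[i] <- "extinct"
      alive <- setdiff(alive, i)
    } else {                             # state change
      p <- Q[si, ]
      p[si] <- 0
      state[i] <- sample.int(k, 1L, prob = p)
    }
    stop_if(length(parent) > cap, "simulation exceeded lineage cap")
  }
  keep_alive <- which(fate == "alive")
  if (length(keep_alive) < 2L) return(NULL)
  ph <- lineages_to_phylo(parent, btime, etime, fate)
  if (is.null(ph)) return(NULL)
  tip_states <- setNames(model$states[state[ph$record_id]], ph$tree$tip.label)
  extinct <- names(tip_states)[fate[ph$record_id] == "extinct"]
  tree <- ph$tree
  if (length(extinct)) {
    if (length(tree$tip.label) - length(extinct) < 2L) return(NULL)
    tree <- ape::drop.tip(tree, extinct)
    tip_states <- tip_states[tree$tip.label]
  }
  list(tree = tree, tip_states = tip_states)
}

# Build an ape::phylo from lineage records (including extinct tips, dropped
# by the caller).  Lineage 1 is the root lineage; its pre-split segment
# becomes the root edge.
lineages_to_phylo <- function(parent, btime, etime, fate) {
  n_rec <- length(parent)
  is_tip <- fate %in% c("alive", "extinct")
  tip_ids <- which(is_tip)
  int_ids <- which(fate == "split")
  ntip <- length(tip_ids)
  if (ntip < 2L || !length(int_ids)) return(NULL)
  node_of <- integer(n_rec)
  node_of[tip_ids] <- seq_len(ntip)
  node_of[int_ids] <- ntip + seq_along(int_ids)
  edge <- cbind(node_of[parent[-1L]], node_of[-1L])
  elen <- (etime - btime)[-1L]
  # record ids ordered as phylo numbering (tips first, then internals)
  record_id <- c(tip_ids, int_ids)
  tree <- list(edge = edge, edge.length = elen, Nnode = length(int_ids),
               tip.label = paste0("t", seq_len(ntip)),
               root.edge = etime[1L] - btime[1L])
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  list(tree = tree, record_id = record_id)
}
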