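test_that("landscape generation is seeded-deterministic and validates", {
  spec <- landscape_spec(100, seed = 1)
  expect_identical(generate_landscape(spec), generate_landscape(spec))

  expect_error(landscape_spec(100, grid_dims = c(10, 10), seed = 1),
               NA)
  expect_error(landscape_spec(99, grid_dims = c(10, 10)),
               "do not multiply")
  badR <- default_covariate_correlation()
  badR["temp", "prec"] <- badR["prec", "temp"] <- 0.999
  badR["temp", "tseas"] <- badR["tseas", "temp"] <- 0.999
  badR["prec", "tseas"] <- badR["tseas", "prec"] <- -0.999
  expect_error(landscape_spec(10, covariate_correlation = badR),
               "positive semi-definite")
})

test_that("landscape covariates reproduce the requested correlation", {
  R <- diag(5)
  dimnames(R) <- list(palmvision:::COVARIATE_NAMES,
                      palmvision:::COVARIATE_NAMES)
  R["temp", "prec"] <- R["prec", "temp"] <- 0.5
  u <- generate_landscape(landscape_spec(2000, covariate_correlation = R,
                                         seed = 7))
  # Fisher-z 95% CI half-width at n = 2000 is about 0.035; allow 0.06
  expect_lt(abs(cor(u$temp, u$prec) - 0.5), 0.06)
})

test_that("palm flora follows the conspicuousness gradient", {
  units <- generate_landscape(landscape_spec(2000, seed = 3))
  fl <- generate_palm_flora(units, n_species = 400, slope = 2, seed = 5)
  expect_identical(fl,
                   generate_palm_flora(units, n_species = 400, slope = 2,
                                       seed = 5))
  cls <- classify_fruit_colours(fl$palms$colours)
  occ <- merge(fl$occurrences,
               data.frame(species_id = fl$palms$species_id, cls = cls))
  nc <- tapply(occ$cls == "conspicuous", occ$unit_id, sum)
  nn <- tapply(occ$cls == "non_conspicuous", occ$unit_id, sum)
  z <- scale(units$prec)[match(names(nc), units$unit_id)]
  g <- stats::glm(cbind(nc, nn) ~ z, family = stats::binomial)
  expect_lt(abs(coef(g)[2] - 2), 0.2)

  # null gradient: slope CI covers zero
  fl0 <- generate_palm_flora(units, n_species = 400, slope = 0, seed = 6)
  occ0 <- merge(fl0$occurrences,
                data.frame(species_id = fl0$palms$species_id,
                           cls = classify_fruit_colours(fl0$palms$colours)))
  nc0 <- tapply(occ0$cls == "conspicuous", occ0$unit_id, sum)
  nn0 <- tapply(occ0$cls == "non_conspicuous", occ0$unit_id, sum)
  z0 <- scale(units$prec)[match(names(nc0), units$unit_id)]
  g0 <- stats::glm(cbind(nc0, nn0) ~ z0, family = stats::binomial)
  ci <- suppressMessages(stats::confint.default(g0))["z0", ]
  expect_true(ci[1] < 0 && ci[2] > 0)

  expect_error(generate_palm_flora(units, n_species = 0), "n_species")
  expect_error(generate_palm_flora(units, gradient_covariate = "nope"),
               "not found")
})

test_that("primate assemblages respect referential integrity and pools", {
  syn <- make_synth_inputs(80, effect = 0.4, seed = 11)
  expect_true(all(syn$prim$occurrences$species_id %in%
                    syn$prim$primates$species_id))
  expect_true(all(syn$prim$occurrences$unit_id %in% syn$units$unit_id))
  expect_true(all(syn$flora$occurrences$species_id %in%
                    syn$flora$palms$species_id))
  # per-unit distinct species
  expect_false(any(duplicated(syn$prim$occurrences)))
  # realised richness equals the truth table's counts
  cnt <- table(factor(
    syn$prim$occurrences$unit_id[
      syn$prim$primates$vision_system[
        match(syn$prim$occurrences$species_id,
              syn$prim$primates$species_id)] == "routine_trichromatic"],
    levels = syn$units$unit_id))
  expect_equal(as.integer(cnt),
               pmin(syn$prim$truth$richness_trichromat, 156))
})

test_that("a unit with requested richness zero has no species", {
  units <- generate_landscape(landscape_spec(30, seed = 2))
  flora <- generate_palm_flora(units, n_species = 60, seed = 3)
  scen <- structural_scenario(
    c("prop_conspicuous->richness_trichromat" = 0),
    sqrt_mean = 0, sqrt_scale = 0.01)  # forces richness ~ 0 everywhere
  prim <- generate_primate_assemblage(units, flora, scen,
                                      baseline_richness = 0, seed = 4)
  zero_units <- prim$truth$unit_id[prim$truth$richness_trichromat == 0 &
                                     prim$truth$richness_polymorph == 0 &
                                     prim$truth$richness_other == 0]
  expect_false(any(prim$occurrences$unit_id %in% zero_units))
})

test_that("scenario validation rejects bad inputs", {
  expect_error(structural_scenario(c("a->b" = 1.2)), "\\[-1, 1\\]")
  expect_error(structural_scenario(c("a->b" = .5, "b->a" = .5)), "cyclic")
  units <- generate_landscape(landscape_spec(20, seed = 1))
  flora <- generate_palm_flora(units, n_species = 40, seed = 2)
  expect_error(
    generate_primate_assemblage(units, flora,
                                structural_scenario(c("ghost->richness_trichromat" = 0.3))),
    "missing predictor")
})

test_that("birth-death trees with Mk traits behave at the limits", {
  Q0 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  sim <- simulate_tree_and_trait(20, birth = 1, Q = Q0, root_state = "a",
                                 seed = 5)
  expect_length(sim$tree$tip.label, 20)
  expect_true(all(sim$tip_states == "a"))  # Q = 0: no change from root

  expect_error(simulate_tree_and_trait(20, birth = 1, death = 1.5,
                                       Q = Q0),
               "impossible")

  # fast ER chain on a deep tree reaches its stationary distribution
  Qf <- matrix(c(-10, 10, 10, -10), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  freqs <- vapply(1:40, function(i) {
    s <- simulate_tree_and_trait(40, birth = 1, Q = Qf, seed = 100 + i)
    mean(s$tip_states == "a")
  }, numeric(1))
  expect_lt(abs(mean(freqs) - 0.5), 0.05)
})

test_that("SSE forward simulation matches pure-birth expectations", {
  q0 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  m <- sse_model(c(1, 1), c(0, 0), q0)
  s1 <- simulate_sse_tree(m, n_tips = 30, seed = 5)
  s2 <- simulate_sse_tree(m, n_tips = 30, seed = 5)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_length(s1$tree$tip.label, 30)
  expect_true(ape::is.ultrametric(s1$tree))

  # E[N(t)] for Yule from one lineage is e^{lambda t}; conditioned on the
  # >= 2 survivors we can return, E[N | N >= 2] = (e^{lt} - p1)/(1 - p1)
  tips <- vapply(1:150, function(i) {
    s <- simulate_sse_tree(m, max_time = 1.5, seed = 1000 + i)
    length(s$tree$tip.label)
  }, numeric(1))
  p1 <- exp(-1.5)
  expected <- (exp(1.5) - p1) / (1 - p1)
  se <- sd(tips) / sqrt(length(tips))
  expect_lt(abs(mean(tips) - expected), 3 * se + 0.1)
})

test_that("state-dependent speciation inflates the fast state's tips", {
  q <- matrix(c(-.1, .1, .1, -.1), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  msd <- sse_model(c(0.5, 1), c(0.1, 0.1), q)
  fr <- vapply(1:40, function(i) {
    s <- simulate_sse_tree(msd, n_tips = 60, seed = 2000 + i)
    mean(s$tip_states == "b")
  }, numeric(1))
  expect_gt(mean(fr), 0.5)  # sign check: fast state over-represented
})
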