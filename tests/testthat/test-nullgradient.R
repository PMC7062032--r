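test_that("permutation preserves per-unit richness and is seeded", {
  syn <- make_synth_inputs(60, effect = 0.3, seed = 31)
  occ <- syn$prim$occurrences
  pool <- syn$prim$primates$species_id
  p1 <- permute_primates(occ, pool, seed = 5)
  p2 <- permute_primates(occ, pool, seed = 5)
  p3 <- permute_primates(occ, pool, seed = 6)
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
  k_before <- table(occ$unit_id)
  k_after <- table(p1$unit_id)
  expect_equal(as.integer(k_after[names(k_before)]),
               as.integer(k_before))
  # distinct species within every unit
  expect_false(any(duplicated(p1)))
  expect_error(permute_primates(occ, pool[1:3]), "pool")
})

test_that("permuted trichromat richness matches its hypergeometric mean", {
  syn <- make_synth_inputs(40, effect = 0, seed = 33)
  occ <- syn$prim$occurrences
  traits <- syn$prim$primates
  pool <- traits$species_id
  frac_t <- mean(traits$vision_system == "routine_trichromatic")
  k <- table(occ$unit_id)
  u0 <- names(k)[which.max(k)]  # deepest unit: largest expected count
  is_t <- setNames(traits$vision_system == "routine_trichromatic",
                   traits$species_id)
  sims <- vapply(1:500, function(i) {
    p <- permute_primates(occ, pool, seed = 100 + i)
    sum(is_t[p$species_id[p$unit_id == u0]])
  }, numeric(1))
  expected <- as.integer(k[u0]) * frac_t
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - expected), 3 * se + 0.05)
})

test_that("the permutation null is centred near zero when labels are
          exchangeable", {
  # fully null generation: richness independent of every predictor, so
  # vision labels are exchangeable.  Conditionally on one design the null
  # mean inherits a small offset from the finite-sample correlation of
  # total richness with the predictors, so centring is assessed over
  # several independent designs.
  means <- vapply(1:6, function(i) {
    syn <- make_synth_inputs(150, effect = 0, temp_effect = 0,
                             seed = 35 + 100 * i)
    pt <- permutation_test(syn$prim$occurrences, syn$flora$occurrences,
                           syn$prim$primates, syn$flora$palms, syn$units,
                           syn$model, syn$focal, reps = 300,
                           seed = 36 + i)
    expect_true(pt$quantile >= 0 && pt$quantile <= 1)
    mean(pt$null, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(abs(means) < 0.12))  # far below real effect sizes
  expect_lt(abs(mean(means)), 2 * sd(means) / sqrt(length(means)) + 0.02)
  syn <- make_synth_inputs(60, effect = 0, seed = 37)
  expect_error(
    permutation_test(syn$prim$occurrences, syn$flora$occurrences,
                     syn$prim$primates, syn$flora$palms, syn$units,
                     syn$model, syn$focal, reps = 0),
    "reps")
})

test_that("a real effect is detected by the permutation test", {
  hits <- vapply(1:10, function(i) {
    syn <- make_synth_inputs(300, effect = 0.5, seed = 400 + 7 * i)
    pt <- permutation_test(syn$prim$occurrences, syn$flora$occurrences,
                           syn$prim$primates, syn$flora$palms, syn$units,
                           syn$model, syn$focal, reps = 100,
                           seed = 500 + i)
    pt$significant
  }, logical(1))
  expect_gte(sum(hits), 9)  # >= 90% power at this effect size
})

test_that("progressive delimitation traces nested refits", {
  syn <- make_synth_inputs(400, effect = 0.5, seed = 41,
                           mean_richness = 10, grid_dims = c(20, 20))
  asm <- build_assemblage(syn$prim$occurrences, syn$flora$occurrences,
                          syn$prim$primates, syn$flora$palms, syn$units)
  gr <- progressive_delimitation(asm, syn$model, syn$focal)
  expect_s3_class(gr, "gradient_result")
  expect_equal(nrow(gr), 15)          # thresholds 2..16
  expect_equal(gr$threshold, 2:16)
  expect_true(all(diff(gr$n_units) <= 0))
  expect_true(all(gr$skipped[gr$n_units < 30]))
  expect_false(any(gr$skipped[gr$n_units >= 30]))
  expect_error(progressive_delimitation(asm, syn$model, syn$focal,
                                        thresholds = c(4, 4, 5)),
               "strictly increasing")

  # threshold at the minimum observed palm richness reproduces the
  # full-data SEM exactly
  filt <- filter_units(asm, "trichromat", min_palms = 1)
  min_pal <- min(filt$n_conspicuous + filt$n_nonconspicuous)
  gr0 <- progressive_delimitation(filt, syn$model, syn$focal,
                                  thresholds = min_pal)
  full <- fit_path_model(syn$model, transform_variables(filt))
  expect_equal(gr0$n_units, nrow(filt))
  expect_equal(gr0$estimate, unname(standardize(full)[syn$focal]),
               tolerance = 1e-8)
})

test_that("a constructed mid-gradient effect yields an interior maximum", {
  # effect present only at intermediate palm richness: build richness by
  # hand from the palm tables so the coefficient must rise then fall
  units <- generate_landscape(landscape_spec(900, seed = 43))
  flora <- generate_palm_flora(units, n_species = 300, slope = 1.5,
                               mean_richness = 9, seed = 44)
  scen <- structural_scenario(
    c("prop_conspicuous->richness_trichromat" = 0))
  prim <- generate_primate_assemblage(units, flora, scen, seed = 45)
  asm <- build_assemblage(prim$occurrences, flora$occurrences,
                          prim$primates, flora$palms, units)
  pal <- asm$n_conspicuous + asm$n_nonconspicuous
  mid <- pal >= 7 & pal <= 11
  prop <- ifelse(is.na(asm$prop_conspicuous), 0.5, asm$prop_conspicuous)
  z <- (prop - mean(prop)) / sd(prop)
  set.seed(46)
  ysqrt <- 3 + 0.6 * (ifelse(mid, 0.8 * z, 0) +
                        rnorm(nrow(asm), 0, sqrt(1 - 0.64)))
  asm$richness_trichromat <- as.integer(round(pmax(ysqrt, 0)^2))
  model <- path_model("richness_trichromat ~ prop_conspicuous + temp")
  gr <- progressive_delimitation(asm, model,
                                 "prop_conspicuous->richness_trichromat",
                                 thresholds = 2:13, min_units = 25)
  est <- gr$estimate[!gr$skipped]
  peak <- which.max(est)
  expect_gt(peak, 1)
  expect_lt(peak, length(est))
})
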