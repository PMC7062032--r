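test_that("model parsing builds the declared DAG and rejects cycles", {
  m <- path_model(c("y ~ x1 + x2", "x2 ~ x1"))
  expect_setequal(m$variables, c("x1", "x2", "y"))
  expect_equal(m$exogenous, "x1")
  expect_equal(nrow(m$edges), 3)
  expect_error(path_model(c("a ~ b", "b ~ a")), "cycle")
  expect_error(path_model("a ~ a"), "self-loop")
})

test_that("ML estimates equal per-equation OLS on random recursive models", {
  set.seed(21)
  for (i in 1:25) {
    inst <- random_recursive_instance(sample(3:6, 1), 200)
    fit <- fit_path_model(inst$model, inst$data, se = FALSE)
    expect_true(fit$converged)
    for (v in inst$model$endogenous) {
      pa <- inst$model$edges$cause[inst$model$edges$effect == v]
      ols <- coef(lm(reformulate(pa, v), inst$data))[pa]
      ml <- fit$paths$estimate[fit$paths$effect == v]
      names(ml) <- fit$paths$cause[fit$paths$effect == v]
      expect_lt(max(abs(ml[pa] - ols)), 1e-6)
    }
  }
})

test_that("saturated models have zero discrepancy and zero df", {
  set.seed(2)
  d <- data.frame(a = rnorm(50))
  d$b <- 0.5 * d$a + rnorm(50)
  d$c <- 0.3 * d$a - 0.4 * d$b + rnorm(50)
  fit <- fit_path_model(path_model(c("b ~ a", "c ~ a + b")), d)
  expect_equal(fit$chisq, 0, tolerance = 1e-8)
  expect_equal(fit$df, 0)
  ix <- fit_indices(fit)
  expect_equal(ix$cfi, 1)
  expect_equal(ix$rmsea, 0)
  expect_false(ix$rmsea_defined)
})

test_that("collinear predictors raise a singularity error", {
  set.seed(3)
  d <- data.frame(x1 = rnorm(60))
  d$x2 <- 2 * d$x1
  d$y <- d$x1 + rnorm(60)
  expect_error(fit_path_model(path_model("y ~ x1 + x2"), d), "singular")
})

test_that("chi-square p-values are uniform under a correct null model", {
  # independence-structured data fitted with the (true) no-path model
  set.seed(4)
  pv <- vapply(1:200, function(i) {
    d <- data.frame(x = rnorm(120), y = rnorm(120), z = rnorm(120))
    # a model with y ~ (nothing): omit x->y, x->z, y->z, all truly zero
    f <- fit_path_model(path_model(c("y ~ x", "z ~ x")), d, se = FALSE)
    f$p_chisq
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("standardized coefficients scale and stay invariant", {
  set.seed(5)
  d <- data.frame(x = rnorm(300))
  d$y <- 2 * d$x + rnorm(300, 0, 1)
  fit <- fit_path_model(path_model("y ~ x"), d)
  # b * sd(x) / sd(y) by definition, with model-implied sds
  expect_equal(unname(standardize(fit)),
               fit$paths$estimate * sd(d$x) / sqrt(fit$Sigma["y", "y"]),
               tolerance = 1e-6)
  # invariance under positive rescaling of any variable
  d2 <- transform(d, x = 13 * x, y = y / 7)
  fit2 <- fit_path_model(path_model("y ~ x"), d2)
  expect_equal(standardize(fit), standardize(fit2), tolerance = 1e-6)
  expect_equal(fit$chisq, fit2$chisq, tolerance = 1e-6)
})

test_that("standardized effects are recovered from generated data", {
  set.seed(6)
  est <- vapply(1:50, function(i) {
    x <- rnorm(400)
    y <- 0.5 * x + rnorm(400, 0, sqrt(1 - 0.25))
    f <- fit_path_model(path_model("y ~ x"), data.frame(x, y), se = FALSE)
    unname(standardize(f))
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.05)
})

test_that("chi-square never decreases when a path is removed", {
  set.seed(7)
  for (i in 1:10) {
    inst <- random_recursive_instance(5, 150)
    if (nrow(inst$model$edges) < 2) next
    f_full <- fit_path_model(inst$model, inst$data, se = FALSE)
    drop1 <- palmvision:::new_path_model(
      inst$model$variables, inst$model$edges[-1, , drop = FALSE],
      inst$model$exogenous)
    f_red <- fit_path_model(drop1, inst$data, se = FALSE)
    expect_gte(f_red$chisq, f_full$chisq - 1e-6)
  }
})

test_that("RMSEA confidence limits match a bisection inversion", {
  set.seed(8)
  n <- 400
  x1 <- rnorm(n)
  x2 <- 0.5 * x1 + rnorm(n)
  y <- 0.4 * x1 + 0.3 * x2 + rnorm(n)
  fit <- fit_path_model(path_model(c("y ~ x1", "x2 ~ x1")),
                        data.frame(x1, x2, y))
  ix <- fit_indices(fit)
  brute_ncp <- function(obs, df, target) {
    lo <- 0
    hi <- 1e6
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (pchisq(obs, df, ncp = mid) > target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  want <- sqrt(c(brute_ncp(fit$chisq, fit$df, 0.95),
                 brute_ncp(fit$chisq, fit$df, 0.05)) /
                 (fit$df * (fit$n - 1)))
  expect_equal(ix$rmsea_ci, want, tolerance = 1e-6)
  expect_true(ix$rmsea_ci[1] <= ix$rmsea && ix$rmsea <= ix$rmsea_ci[2])
  expect_gte(ix$cfi, 0)
  expect_lte(ix$cfi, 1)
  # chi-square equal to its df pins RMSEA at zero
  expect_equal(palmvision:::rmsea_ci(fit$df, fit$df, n, 0.9)[1], 0)
})

test_that("backward elimination removes the true-zero path first", {
  set.seed(9)
  hits <- 0
  for (i in 1:20) {
    n <- 1000
    x1 <- rnorm(n)
    x2 <- 0.5 * x1 + rnorm(n)
    y <- 0.4 * x1 + 0 * x2 + rnorm(n)
    be <- backward_eliminate(path_model(c("y ~ x1 + x2", "x2 ~ x1")),
                             data.frame(x1, x2, y))
    if (nrow(be$steps) >= 1 &&
          be$steps$cause[1] == "x2" && be$steps$effect[1] == "y")
      hits <- hits + 1
  }
  expect_gte(hits, 18)  # >= 90% of replicates
})

test_that("elimination respects its stopping conditions", {
  set.seed(10)
  n <- 800
  x <- rnorm(n)
  y <- 0.8 * x + rnorm(n)
  # every path strongly significant: nothing removed
  be <- backward_eliminate(path_model("y ~ x"), data.frame(x, y))
  expect_equal(nrow(be$steps), 0)
  # alpha = 1: no removals even with junk paths
  z <- rnorm(n)
  be1 <- backward_eliminate(path_model("y ~ x + z"),
                            data.frame(x, y, z), alpha = 1)
  expect_equal(nrow(be1$steps), 0)
  expect_equal(nrow(be1$fit$paths), 2)
  # pure-noise model collapses to the covariates-only fit with a warning
  d0 <- data.frame(x = rnorm(300), y = rnorm(300))
  expect_warning(be0 <- backward_eliminate(path_model("y ~ x"), d0),
                 "covariates-only")
  expect_equal(nrow(be0$fit$paths), 0)
})

test_that("modification indices are exact chi-square drops", {
  set.seed(11)
  n <- 400
  x1 <- rnorm(n)
  x2 <- 0.5 * x1 + rnorm(n)
  y <- 0.4 * x1 + 0.3 * x2 + rnorm(n)
  fit <- fit_path_model(path_model(c("y ~ x1", "x2 ~ x1")),
                        data.frame(x1, x2, y))
  mi <- modification_indices(fit, "x2->y")
  # freeing the only missing edge saturates the model
  expect_equal(mi$delta_chisq, fit$chisq, tolerance = 1e-6)
  expect_equal(mi$new_df, 0)
  expect_error(modification_indices(fit, "y->x1"), "cycle")
  # a truly-zero candidate edge has Delta-chisq ~ chi2(1): mean near 1
  deltas <- vapply(1:60, function(i) {
    d <- data.frame(a = rnorm(200), b = rnorm(200))
    d$y <- 0.5 * d$a + rnorm(200)
    f <- fit_path_model(path_model("y ~ a + b"), d, se = FALSE)
    f0 <- fit_path_model(palmvision:::new_path_model(
      f$model$variables, f$model$edges[f$model$edges$cause != "b", ],
      f$model$exogenous), d, se = FALSE)
    modification_indices(f0, "b->y")$delta_chisq
  }, numeric(1))
  expect_lt(abs(mean(deltas) - 1), 3 * sd(deltas) / sqrt(length(deltas)))
})
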