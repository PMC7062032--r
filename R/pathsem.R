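# Maximum-likelihood path analysis for recursive observed-variable models.
# The Wishart discrepancy F = ln|Sigma(theta)| - ln|S| + tr(S Sigma^-1) - p
# is minimised by quasi-Newton iteration from per-equation OLS starting
# values; chi-square uses the (n-1) Wishart convention.  Exogenous
# covariances are always free; endogenous residuals are uncorrelated.

#' Specify a recursive path model
#'
#' The model is given as regression-style equations, one per endogenous
#' variable: `"effect ~ cause1 + cause2"`.  Lines can be supplied as a
#' character vector or one string separated by newlines or `;`.  Variables
#' never appearing on the left-hand side are exogenous; their covariances
#' are always free.  The directed graph must be acyclic.
#'
#' @param spec character; the equations.
#' @return object of class `path_model` with `variables`, `edges`
#'   (cause/effect), `exogenous`, `endogenous`.
#' @examples
#' path_model(c("y ~ x1 + x2", "x2 ~ x1"))
#' @export
path_model <- function(spec) {
  lines <- unlist(strsplit(spec, "[;\n]"))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  stop_if(!length(lines), "empty model specification")
  edges <- NULL
  endo <- character(0)
  for (ln in lines) {
    parts <- strsplit(ln, "~", fixed = TRUE)[[1]]
    stop_if(length(parts) != 2L, "cannot parse equation: ", ln)
    eff <- trimws(parts[1])
    causes <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
    causes <- causes[nzchar(causes) & causes != "1"]
    stop_if(!nzchar(eff), "missing effect in: ", ln)
    stop_if(eff %in% endo, "duplicate equation for ", eff)
    endo <- c(endo, eff)
    if (length(causes))
      edges <- rbind(edges, data.frame(cause = causes, effect = eff,
                                       stringsAsFactors = FALSE))
  }
  if (is.null(edges))
    edges <- data.frame(cause = character(0), effect = character(0))
  stop_if(any(edges$cause == edges$effect), "self-loop in model")
  variables <- unique(c(edges$cause, edges$effect, endo))
  exogenous <- setdiff(variables, endo)
  new_path_model(variables, edges, exogenous)
}

new_path_model <- function(variables, edges, exogenous) {
  stop_if(!edges_acyclic(edges, variables), "path diagram contains a cycle")
  structure(list(variables = variables, edges = edges,
                 exogenous = exogenous,
                 endogenous = setdiff(variables, exogenous)),
            class = "path_model")
}

edges_acyclic <- function(edges, variables) {
  vars <- variables
  e <- edges
  repeat {
    if (!nrow(e)) return(TRUE)
    sinks <- setdiff(vars, e$cause)
    keep <- !(e$effect %in% sinks)
    if (all(keep)) return(FALSE)
    e <- e[keep, , drop = FALSE]
    vars <- setdiff(vars, sinks)
  }
}

#' @export
print.path_model <- function(x, ...) {
  cat("Recursive path model:", length(x$variables), "variables,",
      nrow(x$edges), "paths\n")
  cat("  exogenous:", paste(x$exogenous, collapse = ", "), "\n")
  for (v in x$endogenous) {
    pa <- x$edges$cause[x$edges$effect == v]
    cat("  ", v, "~", if (length(pa)) paste(pa, collapse = " + ") else "1",
        "\n")
  }
  invisible(x)
}

# Parameter bookkeeping: theta = [b_edges, vech(L) for exogenous Cholesky
# (diagonal on log scale), log psi for endogenous residual variances].
sem_param_map <- function(model) {
  p <- length(model$variables)
  q <- length(model$exogenous)
  m <- p - q
  ne <- nrow(model$edges)
  nchol <- q * (q + 1) / 2
  list(p = p, q = q, m = m, ne = ne, nchol = nchol,
       npar = ne + nchol + m,
       i_b = seq_len(ne),
       i_chol = ne + seq_len(nchol),
       i_psi = ne + nchol + seq_len(m),
       exog_idx = match(model$exogenous, model$variables),
       endo_idx = match(model$endogenous, model$variables),
       ci = match(model$edges$cause, model$variables),
       ei = match(model$edges$effect, model$variables))
}

sem_implied_sigma <- function(theta, model, map) {
  p <- map$p
  B <- matrix(0, p, p)
  if (map$ne) B[cbind(map$ei, map$ci)] <- theta[map$i_b]
  Psi0 <- matrix(0, p, p)
  if (map$q) {
    L <- matrix(0, map$q, map$q)
    L[lower.tri(L, diag = TRUE)] <- theta[map$i_chol]
    diag(L) <- exp(diag(L))
    Psi0[map$exog_idx, map$exog_idx] <- tcrossprod(L)
  }
  if (map$m)
    Psi0[cbind(map$endo_idx, map$endo_idx)] <- exp(theta[map$i_psi])
  A <- diag(p) - B
  Ainv <- solve(A)
  Ainv %*% Psi0 %*% t(Ainv)
}

sem_discrepancy <- function(theta, model, map, S, logdetS) {
  Sig <- sem_implied_sigma(theta, model, map)
  cS <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(cS)) return(1e10)
  logdet <- 2 * sum(log(diag(cS)))
  tr <- sum(S * chol2inv(cS))
  f <- logdet - logdetS + tr - map$p
  if (!is.finite(f)) 1e10 else f
}

# OLS-based starting values; for recursive models with uncorrelated
# residuals this is the exact ML solution, so iteration mostly polishes.
sem_start <- function(model, map, S) {
  theta <- numeric(map$npar)
  vars <- model$variables
  if (map$ne) {
    for (v in model$endogenous) {
      rows <- which(model$edges$effect == v)
      if (!length(rows)) next
      pa <- model$edges$cause[rows]
      b <- solve(S[pa, pa, drop = FALSE], S[pa, v])
      theta[map$i_b][rows] <- b
    }
  }
  if (map$q) {
    Phi <- S[model$exogenous, model$exogenous, drop = FALSE]
    L <- t(chol(Phi))
    diag(L) <- log(diag(L))
    theta[map$i_chol] <- L[lower.tri(L, diag = TRUE)]
  }
  for (j in seq_along(model$endogenous)) {
    v <- model$endogenous[j]
    rows <- which(model$edges$effect == v)
    psi <- S[v, v]
    if (length(rows)) {
      pa <- model$edges$cause[rows]
      b <- theta[map$i_b][rows]
      psi <- S[v, v] - sum(b * S[pa, v])
    }
    theta[map$i_psi][j] <- log(max(psi, 1e-10))
  }
  theta
}

#' Fit a path model by maximum likelihood
#'
#' Minimises the Wishart ML discrepancy over the free parameters (path
#' coefficients, exogenous covariance Cholesky, log residual variances)
#' with BFGS from OLS starting values.  `chisq = (n - 1) * F` at the
#' optimum; standard errors come from the inverse observed information of
#' the fit function.
#'
#' @param model a [path_model()].
#' @param data data.frame containing every model variable, or a covariance
#'   matrix (then `n` is required).
#' @param n sample size (defaults to `nrow(data)`).
#' @param se compute standard errors (skip for speed inside permutation
#'   loops).
#' @param reltol convergence tolerance on the discrepancy.
#' @return object of class `sem_fit`: `paths` (estimate, se, z, p, std),
#'   `Sigma`, `S`, `F_ml`, `chisq`, `df`, `p_chisq`, `loglik`, `converged`.
#' @export
fit_path_model <- function(model, data, n = NULL, se = TRUE,
                           reltol = 1e-12) {
  stop_if(!inherits(model, "path_model"), "`model` must be a path_model")
  vars <- model$variables
  if (is.matrix(data) && isTRUE(all.equal(data, t(data)))) {
    stop_if(is.null(n), "`n` required when data is a covariance matrix")
    S <- data[vars, vars]
  } else {
    data <- as.data.frame(data)
    missing <- setdiff(vars, names(data))
    stop_if(length(missing) > 0,
            "data lacks model variable(s): ", paste(missing, collapse = ", "))
    X <- as.matrix(data[vars])
    stop_if(anyNA(X), "missing values in model variables")
    n <- n %||% nrow(X)
    S <- cov(X)
  }
  p <- length(vars)
  stop_if(n <= p, "need n greater than the number of variables")
  cSfull <- tryCatch(chol(S), error = function(e) NULL)
  stop_if(is.null(cSfull) || rcond(S) < 1e-12,
          "sample covariance matrix is singular ",
          "(collinear variables?)")
  logdetS <- 2 * sum(log(diag(cSfull)))

  map <- sem_param_map(model)
  start <- sem_start(model, map, S)
  opt <- optim(start, sem_discrepancy, model = model, map = map, S = S,
               logdetS = logdetS, method = "BFGS",
               control = list(reltol = reltol, maxit = 500))
  theta <- opt$par
  F_ml <- max(opt$value, 0)
  Sigma <- sem_implied_sigma(theta, model, map)
  dimnames(Sigma) <- list(vars, vars)
  chisq <- (n - 1) * F_ml
  df <- p * (p + 1) / 2 - map$npar
  stop_if(df < 0, "model has more free parameters than moments")
  p_chisq <- if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else NA_real_

  est <- theta[map$i_b]
  se_b <- rep(NA_real_, map$ne)
  if (se && map$npar > 0) {
    H <- tryCatch(
      optimHess(theta, function(th)
        0.5 * (n - 1) * sem_discrepancy(th, model, map, S, logdetS)),
      error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
      dv <- diag(V)[map$i_b]
      se_b <- ifelse(dv > 0, sqrt(dv), NA_real_)
    }
  }
  sds <- sqrt(pmax(diag(Sigma), 0))
  std <- est * sds[map$ci] / sds[map$ei]
  z <- est / se_b
  paths <- data.frame(cause = model$edges$cause,
                      effect = model$edges$effect,
                      estimate = est, se = se_b, z = z,
                      p = 2 * pnorm(-abs(z)), std = std,
                      stringsAsFactors = FALSE)
  Sn <- S * (n - 1) / n
  loglik <- -(n / 2) * (p * log(2 * pi) +
                          2 * sum(log(diag(chol(Sigma)))) +
                          sum(Sn * chol2inv(chol(Sigma))))
  structure(list(model = model, paths = paths, Sigma = Sigma, S = S, n = n,
                 theta = theta, F_ml = F_ml, chisq = chisq, df = df,
                 p_chisq = p_chisq, loglik = loglik,
                 converged = opt$convergence == 0, opt = opt),
            class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, digits = 3, ...) {
  cat("ML path analysis: n =", x$n, "\n")
  cat(sprintf("  chi-square = %.4g on %d df (p = %s), F_ml = %.4g%s\n",
              x$chisq, x$df,
              if (is.na(x$p_chisq)) "saturated" else format(x$p_chisq,
                                                            digits = 3),
              x$F_ml, if (x$converged) "" else "  [NOT CONVERGED]"))
  if (nrow(x$paths)) {
    pr <- x$paths
    pr[3:7] <- lapply(pr[3:7], round, digits)
    print(pr, row.names = FALSE)
  } else cat("  (no paths)\n")
  invisible(x)
}

#' Standardized path coefficients
#'
#' Each raw coefficient is scaled by `sd(cause) / sd(effect)` using the
#' model-implied variances.
#'
#' @param fit an `sem_fit`.
#' @return named numeric vector (`"cause->effect"`).
#' @export
standardize <- function(fit) {
  stop_if(!inherits(fit, "sem_fit"), "`fit` must be an sem_fit")
  sds <- sqrt(diag(fit$Sigma))
  stop_if(any(sds <= 0), "zero model-implied variance")
  setNames(fit$paths$std,
           paste0(fit$paths$cause, "->", fit$paths$effect))
}

#' Model fit indices (CFI, RMSEA with confidence interval)
#'
#' The baseline is the independence model (all covariances zero, variances
#' free), whose chi-square has the closed form
#' `(n-1) * (sum(log diag S) - log det S)`.  RMSEA confidence limits are
#' found by numerically inverting the noncentral chi-square distribution.
#' When `df = 0` the RMSEA is undefined and reported as 0 with
#' `rmsea_defined = FALSE`.
#'
#' @param fit an `sem_fit`.
#' @param conf confidence level for the RMSEA interval (default 0.90, the
#'   conventional choice).
#' @return list with `cfi`, `rmsea`, `rmsea_ci`, `chisq`, `df`, `p_chisq`,
#'   `baseline_chisq`, `baseline_df`, `rmsea_defined`.
#' @export
fit_indices <- function(fit, conf = 0.90) {
  stop_if(!inherits(fit, "sem_fit"), "`fit` must be an sem_fit")
  S <- fit$S
  n <- fit$n
  p <- nrow(S)
  chisq_b <- (n - 1) * (sum(log(diag(S))) - 2 * sum(log(diag(chol(S)))))
  chisq_b <- max(chisq_b, 0)
  df_b <- p * (p - 1) / 2
  num <- max(fit$chisq - fit$df, 0)
  den <- max(chisq_b - df_b, fit$chisq - fit$df, 0)
  cfi <- if (den > 0) 1 - num / den else 1
  if (fit$df > 0) {
    rmsea <- sqrt(max(fit$chisq - fit$df, 0) / (fit$df * (n - 1)))
    ci <- rmsea_ci(fit$chisq, fit$df, n, conf)
    defined <- TRUE
  } else {
    rmsea <- 0
    ci <- c(0, 0)
    defined <- FALSE
  }
  list(cfi = cfi, rmsea = rmsea, rmsea_ci = ci, conf = conf,
       chisq = fit$chisq, df = fit$df, p_chisq = fit$p_chisq,
       baseline_chisq = chisq_b, baseline_df = df_b,
       rmsea_defined = defined)
}

# Invert pchisq(obs, df, ncp = lambda) = target over lambda.
invert_ncp <- function(obs, df, target) {
  if (pchisq(obs, df) < target) return(0)
  hi <- max(obs * 2, df * 2, 10)
  while (pchisq(obs, df, ncp = hi) > target && hi < 1e8) hi <- hi * 2
  uniroot(function(l) pchisq(obs, df, ncp = l) - target,
          lower = 0, upper = hi, tol = 1e-8)$root
}

rmsea_ci <- function(chisq, df, n, conf) {
  lo_ncp <- invert_ncp(chisq, df, (1 + conf) / 2)
  hi_ncp <- invert_ncp(chisq, df, (1 - conf) / 2)
  sqrt(c(lo_ncp, hi_ncp) / (df * (n - 1)))
}

#' Adequacy gates for a fitted SEM
#'
#' Checks the fit against the adequacy criteria: chi-square p > 0.05,
#' CFI > 0.90, and the RMSEA confidence-interval criterion.  The RMSEA
#' criterion is interpreted as the CI lower bound below `rmsea_cut`, with
#' the upper bound also reported so either reading can be audited.
#'
#' @param fit an `sem_fit`.
#' @param indices optional precomputed [fit_indices()].
#' @param p_cut,cfi_cut,rmsea_cut gate thresholds.
#' @return list of logical gates plus `all_ok`.
#' @export
fit_gates <- function(fit, indices = NULL, p_cut = 0.05, cfi_cut = 0.90,
                      rmsea_cut = 0.05) {
  ix <- indices %||% fit_indices(fit)
  chisq_ok <- if (is.na(fit$p_chisq)) TRUE else fit$p_chisq > p_cut
  cfi_ok <- ix$cfi > cfi_cut
  rmsea_lower_ok <- ix$rmsea_ci[1] < rmsea_cut
  rmsea_upper_ok <- ix$rmsea_ci[2] < rmsea_cut
  list(chisq_ok = chisq_ok, cfi_ok = cfi_ok,
       rmsea_lower_ok = rmsea_lower_ok, rmsea_upper_ok = rmsea_upper_ok,
       all_ok = chisq_ok && cfi_ok && rmsea_lower_ok)
}

#' Backward elimination of non-significant paths
#'
#' Iteratively removes the path with the largest p-value (ties broken by
#' smallest absolute z, then lexical `cause->effect` order), refitting
#' after each removal, until every remaining path is significant at
#' `alpha`.  The exogenous set of the initial model is kept fixed
#' throughout, so successive models are nested and chi-square never
#' decreases.
#'
#' @param model initial [path_model()].
#' @param data data.frame with the model variables.
#' @param alpha significance threshold (default 0.05).
#' @param n optional sample size override.
#' @return list: `fit` (final `sem_fit`), `steps` (elimination log),
#'   `indices` ([fit_indices()] of the final fit), `gates`
#'   ([fit_gates()]).
#' @export
backward_eliminate <- function(model, data, alpha = 0.05, n = NULL) {
  stop_if(alpha <= 0 || alpha > 1, "`alpha` must be in (0, 1]")
  cur <- model
  steps <- NULL
  repeat {
    fit <- fit_path_model(cur, data, n = n)
    if (!nrow(cur$edges)) {
      warning("backward elimination removed every path; ",
              "returning the covariates-only fit")
      break
    }
    pv <- fit$paths$p
    pv[!is.finite(pv)] <- 1  # undefined p counts as least significant
    if (all(pv < alpha) || alpha >= 1) break
    ord <- order(-pv, abs(fit$paths$z),
                 paste0(fit$paths$cause, "->", fit$paths$effect))
    drop_i <- ord[1]
    steps <- rbind(steps,
                   data.frame(step = (nrow(steps) %||% 0) + 1,
                              cause = fit$paths$cause[drop_i],
                              effect = fit$paths$effect[drop_i],
                              estimate = fit$paths$estimate[drop_i],
                              p = pv[drop_i], stringsAsFactors = FALSE))
    cur <- new_path_model(cur$variables,
                          cur$edges[-drop_i, , drop = FALSE],
                          cur$exogenous)
  }
  ix <- fit_indices(fit)
  list(fit = fit, steps = steps %||% data.frame(), indices = ix,
       gates = fit_gates(fit, ix))
}

#' Modification indices by exact refit
#'
#' For each candidate edge absent from the model, refits with the edge
#' freed and reports the exact chi-square drop (not the Lagrange-multiplier
#' approximation).  Candidates that would create a cycle raise an error.
#'
#' @param fit a fitted `sem_fit`.
#' @param candidates character vector of `"cause->effect"` edges, or a
#'   data.frame with `cause` and `effect` columns.
#' @return data.frame: cause, effect, `delta_chisq`, `new_df`.
#' @export
modification_indices <- function(fit, candidates) {
  stop_if(!inherits(fit, "sem_fit"), "`fit` must be an sem_fit")
  if (is.character(candidates)) {
    sp <- strsplit(candidates, "->", fixed = TRUE)
    candidates <- data.frame(cause = trimws(vapply(sp, `[`, "", 1)),
                             effect = trimws(vapply(sp, `[`, "", 2)),
                             stringsAsFactors = FALSE)
  }
  model <- fit$model
  out <- candidates
  out$delta_chisq <- NA_real_
  out$new_df <- NA_integer_
  for (i in seq_len(nrow(candidates))) {
    ca <- candidates$cause[i]
    ef <- candidates$effect[i]
    stop_if(!all(c(ca, ef) %in% model$variables),
            "candidate edge uses unknown variable: ", ca, "->", ef)
    dup <- any(model$edges$cause == ca & model$edges$effect == ef)
    stop_if(dup, "candidate edge already in the model: ", ca, "->", ef)
    edges2 <- rbind(model$edges,
                    data.frame(cause = ca, effect = ef,
                               stringsAsFactors = FALSE))
    stop_if(!edges_acyclic(edges2, model$variables),
            "candidate edge would create a cycle: ", ca, "->", ef)
    # freeing an edge into a formerly exogenous variable makes it
    # endogenous; recompute status from the augmented edge set
    exo2 <- setdiff(model$variables, unique(edges2$effect))
    m2 <- new_path_model(model$variables, edges2, exo2)
    f2 <- fit_path_model(m2, fit$S, n = fit$n, se = FALSE)
    out$delta_chisq[i] <- fit$chisq - f2$chisq
    out$new_df[i] <- f2$df
  }
  out
}
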