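# State-dependent speciation-extinction (BiSSE/MuSSE) likelihoods and
# model comparison, plus the constant-rate birth-death likelihood used as
# the factorisation anchor: with state-independent lambda and mu, the
# MuSSE log-likelihood equals the birth-death log-likelihood plus the Mk
# log-likelihood.

#' MuSSE log-likelihood
#'
#' Integrates the per-branch extinction/data ordinary differential
#' equations from the tips towards the root with an adaptive Runge-Kutta
#' scheme (compiled), combines branches at each node with the speciation
#' rate of the node state, and applies the model's root treatment.  No
#' conditioning on survival is applied (every internal node, including the
#' root, contributes its speciation factor).
#'
#' @param tree rooted, ultrametric [ape::phylo].
#' @param tip_states named vector of state labels; `NA` = ambiguous.
#' @param model an [sse_model()].
#' @param sampling_fraction probability that an extant species is sampled
#'   (scalar or per-state vector).
#' @param rtol,atol integration tolerances.
#' @return the log-likelihood.
#' @export
sse_loglik <- function(tree, tip_states, model, sampling_fraction = 1,
                       rtol = 1e-8, atol = 1e-12) {
  stop_if(!inherits(model, "sse_model"), "`model` must be an sse_model")
  k <- length(model$states)
  f <- rep(sampling_fraction, length.out = k)
  stop_if(any(f <= 0 | f > 1), "sampling_fraction must be in (0, 1]")
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  Dm <- matrix(0, nn, k)
  Em <- matrix(NA_real_, nn, k)
  tipL <- tip_partials(tr, tip_states, model$states)
  Dm[seq_len(ntip), ] <- sweep(tipL, 2, f, `*`)
  Em[seq_len(ntip), ] <- matrix(1 - f, ntip, k, byrow = TRUE)
  seen <- logical(nn)
  seen[seq_len(ntip)] <- TRUE
  logscale <- 0
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]
    chd <- tr$edge[e, 2]
    y0 <- c(Em[chd, ], Dm[chd, ])
    y <- sse_branch_cpp(y0, tr$edge.length[e], model$lambda, model$mu,
                        model$Q, rtol, atol)
    E <- y[seq_len(k)]
    D <- y[k + seq_len(k)]
    if (any(D < -1e-6))
      warning("negative data probabilities from branch integration; ",
              "clipped (consider tightening tolerances)")
    D <- pmax(D, 0)
    E <- pmin(pmax(E, 0), 1)
    if (!seen[par]) {
      Dm[par, ] <- D * model$lambda
      Em[par, ] <- E
      seen[par] <- TRUE
    } else {
      Dm[par, ] <- Dm[par, ] * D
    }
    sc <- max(Dm[par, ])
    if (sc > 0) {
      Dm[par, ] <- Dm[par, ] / sc
      logscale <- logscale + log(sc)
    }
  }
  root <- ntip + 1L
  D <- Dm[root, ]
  w <- sse_root_weights(model, D)
  lik <- sum(w * D)
  if (lik <= 0) return(-Inf)
  log(lik) + logscale
}

sse_root_weights <- function(model, D) {
  k <- length(model$states)
  if (!is.null(model$pi)) return(model$pi)
  switch(model$root_treatment,
         flat = rep(1 / k, k),
         equilibrium = stationary_distribution(model$Q),
         likelihood_weighted = if (sum(D) > 0) D / sum(D) else rep(1 / k, k))
}

#' Constant-rate birth-death log-likelihood
#'
#' Closed-form likelihood of an ultrametric tree under a constant-rate
#' birth-death process, in the same convention as [sse_loglik()] (one
#' speciation factor per internal node including the root; no survival
#' conditioning; complete sampling), so that with state-independent rates
#' `sse_loglik = bd_loglik + mk_loglik`.
#'
#' @param tree ultrametric [ape::phylo].
#' @param lambda,mu speciation and extinction rates (`mu < lambda` not
#'   required; `mu >= 0`).
#' @return the log-likelihood.
#' @export
bd_loglik <- function(tree, lambda, mu = 0) {
  stop_if(lambda <= 0, "lambda must be positive")
  stop_if(mu < 0, "mu must be >= 0")
  age <- node_ages(tree)
  r <- lambda - mu
  log_dhat <- function(t) {
    if (abs(r) < 1e-12) return(-2 * log1p(lambda * t))
    -r * t + 2 * (log(r) - log(lambda - mu * exp(-r * t)))
  }
  ll <- tree$Nnode * log(lambda)
  for (e in seq_len(nrow(tree$edge))) {
    ll <- ll + log_dhat(age[tree$edge[e, 1]]) -
      log_dhat(age[tree$edge[e, 2]])
  }
  ll
}

#' Fit state-dependent diversification models
#'
#' Maximum-likelihood fits of a set of nested MuSSE parameterisations and
#' an AIC / likelihood-ratio comparison table.  Available constraints:
#' `"free"` (per-state lambda and mu), `"equal_lambda"` (shared lambda,
#' per-state mu), `"equal_lambda_mu"` (shared lambda and mu — the
#' state-independent null).  Transition rates are all distinct
#' (`q_constraint = "ARD"`) or shared (`"ER"`).
#'
#' @param tree rooted ultrametric phylogeny.
#' @param tip_states named state vector.
#' @param constraints non-empty character vector of model constraints.
#' @param q_constraint transition-rate constraint.
#' @param sampling_fraction passed to [sse_loglik()].
#' @param root_treatment passed to [sse_model()].
#' @param rtol,atol integration tolerances used during optimisation.
#' @return list of class `sse_fit_set`: `fits` (per constraint: `model`,
#'   `loglik`, `npar`, `AIC`, `converged`), `table` (comparison
#'   data.frame), `best` (constraint name with lowest AIC).
#' @export
fit_sse <- function(tree, tip_states,
                    constraints = c("free", "equal_lambda_mu"),
                    q_constraint = c("ARD", "ER"), sampling_fraction = 1,
                    root_treatment = "likelihood_weighted",
                    rtol = 1e-6, atol = 1e-9) {
  q_constraint <- match.arg(q_constraint)
  stop_if(length(constraints) == 0, "`constraints` must be non-empty")
  bad <- setdiff(constraints, c("free", "equal_lambda", "equal_lambda_mu"))
  stop_if(length(bad) > 0, "unknown constraint(s): ",
          paste(bad, collapse = ", "))
  stop_if(!ape::is.ultrametric(tree, option = 2),
          "tree must be ultrametric")
  states <- sort(unique(stats::na.omit(unname(tip_states))))
  stop_if(length(states) < 2, "need at least 2 observed states")
  k <- length(states)
  nq <- if (q_constraint == "ER") 1L else k * (k - 1L)

  build_model <- function(constraint, par) {
    # par on log scale: [lambda block][mu block][q block]
    nl <- if (constraint == "free") k else 1L
    nm <- if (constraint == "equal_lambda_mu") 1L else k
    lam <- rep(exp(par[seq_len(nl)]), length.out = k)
    mu <- rep(exp(par[nl + seq_len(nm)]), length.out = k)
    qv <- exp(par[nl + nm + seq_len(nq)])
    Q <- matrix(0, k, k, dimnames = list(states, states))
    Q[row(Q) != col(Q)] <- rep(qv, length.out = k * (k - 1L))
    diag(Q) <- -rowSums(Q)
    sse_model(lam, mu, Q, root_treatment = root_treatment)
  }
  npar_of <- function(constraint)
    (if (constraint == "free") k else 1L) +
    (if (constraint == "equal_lambda_mu") 1L else k) + nq

  bl <- sum(tree$edge.length)
  ntip <- length(tree$tip.label)
  lam0 <- max(ntip - 2L, 1L) / bl
  start_of <- function(constraint)
    log(c(rep(lam0, if (constraint == "free") k else 1L),
          rep(lam0 * 0.1, if (constraint == "equal_lambda_mu") 1L else k),
          rep(lam0 * 0.2, nq)))

  fits <- lapply(constraints, function(con) {
    nll <- function(par) {
      m <- tryCatch(build_model(con, par), error = function(e) NULL)
      if (is.null(m)) return(1e10)
      ll <- tryCatch(suppressWarnings(
        sse_loglik(tree, tip_states, m, sampling_fraction, rtol, atol)),
        error = function(e) -1e10)
      if (!is.finite(ll)) 1e10 else -ll
    }
    opt <- optim(start_of(con), nll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-8))
    list(constraint = con, model = build_model(con, opt$par),
         loglik = -opt$value, npar = npar_of(con),
         AIC = 2 * opt$value + 2 * npar_of(con),
         converged = opt$convergence == 0)
  })
  names(fits) <- constraints
  tab <- data.frame(model = constraints,
                    npar = vapply(fits, `[[`, 0, "npar"),
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    AIC = vapply(fits, `[[`, 0, "AIC"),
                    stringsAsFactors = FALSE)
  tab$dAIC <- tab$AIC - min(tab$AIC)
  structure(list(fits = fits, table = tab,
                 best = tab$model[which.min(tab$AIC)]),
            class = "sse_fit_set")
}

#' @export
print.sse_fit_set <- function(x, ...) {
  cat("State-dependent diversification fits (best by AIC:", x$best, ")\n")
  print(transform(x$table, loglik = round(loglik, 3),
                  AIC = round(AIC, 2), dAIC = round(dAIC, 2)),
        row.names = FALSE)
  invisible(x)
}
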