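# Mk-model machinery: pruning likelihood, ML rate estimation, and marginal
# ancestral state reconstruction (with marginals at arbitrary points along
# edges, used by the diversity-through-time estimator).

#' Specify an Mk model
#'
#' @param Q k x k rate matrix (rows sum to zero, off-diagonals >= 0);
#'   dimnames give state labels (defaults `s1..sk`).
#' @param root_prior `"stationary"` (stationary distribution of `Q`, the
#'   default), `"flat"`, or an explicit probability vector over states.
#' @return object of class `mk_model`.
#' @export
mk_model <- function(Q, root_prior = "stationary") {
  Q <- validate_rate_matrix(Q)
  k <- nrow(Q)
  if (is.character(root_prior)) {
    pi <- switch(root_prior,
                 stationary = stationary_distribution(Q),
                 flat = rep(1 / k, k),
                 stop("unknown root_prior: ", root_prior, call. = FALSE))
  } else {
    stop_if(length(root_prior) != k || any(root_prior < 0) ||
              abs(sum(root_prior) - 1) > 1e-8,
            "numeric root_prior must be a probability simplex of length k")
    pi <- as.numeric(root_prior)
  }
  structure(list(Q = Q, states = rownames(Q),
                 pi = setNames(pi, rownames(Q))),
            class = "mk_model")
}

stationary_distribution <- function(Q) {
  k <- nrow(Q)
  if (all(Q == 0)) return(rep(1 / k, k))
  # left null vector of Q: solve t(Q) v = 0 with sum(v) = 1
  A <- rbind(t(Q), rep(1, k))
  v <- qr.solve(A, c(rep(0, k), 1))
  v <- pmax(v, 0)
  v / sum(v)
}

# Eigen-based transition probabilities P(t) = expm(Q t); clips tiny
# negative entries.  Falls back to scaling-and-squaring when the
# eigenvector matrix is ill-conditioned.
make_pfun <- function(Q) {
  eg <- eigen(Q)
  V <- eg$vectors
  use_eigen <- rcond(V) > 1e-10
  if (use_eigen) Vinv <- solve(V)
  function(t) {
    P <- if (use_eigen) {
      Re(V %*% (exp(eg$values * t) * Vinv))
    } else {
      expm_ss(Q * t)
    }
    P[P < 0] <- 0
    P / rowSums(P)
  }
}

# Matrix exponential by scaling and squaring with a Taylor core; only used
# as a fallback for defective rate matrices.
expm_ss <- function(A) {
  nrm <- max(abs(A))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  As <- A / 2^s
  P <- diag(nrow(A))
  term <- P
  for (i in 1:20) {
    term <- term %*% As / i
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

# Tip partial-likelihood matrix: rows = tips in tree order, indicator of
# the observed state; NA = fully ambiguous.
tip_partials <- function(tree, tip_states, states) {
  ntip <- length(tree$tip.label)
  miss <- setdiff(names(tip_states), tree$tip.label)
  stop_if(length(miss) > 0,
          "tip state(s) for taxa missing from the tree: ",
          paste(head(miss, 5), collapse = ", "))
  L <- matrix(0, ntip, length(states))
  for (i in seq_len(ntip)) {
    s <- tip_states[[tree$tip.label[i]]]
    stop_if(is.null(s), "no state for tip ", tree$tip.label[i])
    if (is.na(s)) L[i, ] <- 1
    else {
      j <- match(s, states)
      stop_if(is.na(j), "tip state '", s, "' not among model states")
      L[i, j] <- 1
    }
  }
  L
}

# Core pruning pass plus the quantities shared by the likelihood, the
# marginal reconstruction and stochastic mapping:
#   L   down partials (scaled rows; logscale holds the log of the factors)
#   M   per-edge child messages M_e(s_parent) = sum_s P_e[s_parent, s] L[child, s]
#   P   per-edge transition matrices
mk_machinery <- function(tree, tip_states, model) {
  stop_if(!inherits(model, "mk_model"), "`model` must be an mk_model")
  tr <- ape::reorder.phylo(tree, "postorder")
  k <- length(model$states)
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  pfun <- make_pfun(model$Q)
  L <- matrix(1, nn, k)
  L[seq_len(ntip), ] <- tip_partials(tr, tip_states, model$states)
  nedge <- nrow(tr$edge)
  P <- vector("list", nedge)
  M <- matrix(0, nedge, k)
  logscale <- 0
  for (e in seq_len(nedge)) {
    par <- tr$edge[e, 1]
    chd <- tr$edge[e, 2]
    P[[e]] <- pfun(tr$edge.length[e])
    M[e, ] <- P[[e]] %*% L[chd, ]
    L[par, ] <- L[par, ] * M[e, ]
    sc <- max(L[par, ])
    if (sc > 0 && sc < 1e-100) {  # guard against underflow on deep trees
      L[par, ] <- L[par, ] / sc
      logscale <- logscale + log(sc)
    }
  }
  root <- ntip + 1L
  lik <- sum(model$pi * L[root, ])
  # renormalise all internal rows for reuse, tracking each row's log factor
  rowlog <- numeric(nn)
  for (v in (ntip + 1L):nn) {
    sc <- max(L[v, ])
    if (sc > 0) {
      L[v, ] <- L[v, ] / sc
      rowlog[v] <- log(sc)
    }
  }
  list(tree = tr, L = L, M = M, P = P, k = k, ntip = ntip, nn = nn,
       root = root, loglik = log(lik) + logscale,
       pfun = pfun, model = model)
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' @param tree a rooted [ape::phylo] with branch lengths.
#' @param tip_states named vector of state labels (names = tip labels);
#'   `NA` marks an ambiguous tip.
#' @param model an [mk_model()].
#' @return the log-likelihood.
#' @export
mk_loglik <- function(tree, tip_states, model) {
  mk_machinery(tree, tip_states, model)$loglik
}

#' Fit an Mk model by maximum likelihood
#'
#' Rates are optimised on the log scale under one of the standard
#' constraints: `ER` (one rate), `SYM` (symmetric rates), `ARD` (all rates
#' distinct).
#'
#' @param tree rooted phylogeny.
#' @param tip_states named state vector.
#' @param constraint rate constraint.
#' @param states optional state labels (defaults to the sorted observed
#'   states).
#' @param root_prior passed to [mk_model()]; the default uses the fitted
#'   stationary distribution.
#' @return list of class `mk_fit`: `model` (with the ML `Q`), `loglik`,
#'   `rates`, `npar`, `AIC`, `constraint`, `boundary` flag.
#' @export
fit_mk <- function(tree, tip_states, constraint = c("ER", "SYM", "ARD"),
                   states = NULL, root_prior = "stationary") {
  constraint <- match.arg(constraint)
  obs <- sort(unique(stats::na.omit(unname(tip_states))))
  states <- states %||% obs
  stop_if(length(states) < 2, "need at least 2 states")
  k <- length(states)
  single <- length(obs) < 2
  if (single)
    warning("a single state observed at the tips; ",
            "rate estimate lies at the zero boundary")
  absent <- setdiff(states, obs)
  if (length(absent) && !single)
    warning("state(s) never observed at tips: ",
            paste(absent, collapse = ", "), "; rates weakly identified")
  npar <- switch(constraint, ER = 1L, SYM = k * (k - 1L) %/% 2L,
                 ARD = k * (k - 1L))
  build_Q <- function(logr) {
    r <- exp(logr)
    Q <- matrix(0, k, k, dimnames = list(states, states))
    if (constraint == "ER") Q[row(Q) != col(Q)] <- r
    else if (constraint == "SYM") {
      Q[upper.tri(Q)] <- r
      Q[lower.tri(Q)] <- t(Q)[lower.tri(Q)]
    } else Q[row(Q) != col(Q)] <- r  # ARD fills column-major off-diagonals
    diag(Q) <- -rowSums(Q)
    Q
  }
  nll <- function(logr) {
    m <- tryCatch(mk_model(build_Q(logr), root_prior),
                  error = function(e) NULL)
    if (is.null(m)) return(1e10)
    ll <- tryCatch(mk_loglik(tree, tip_states, m),
                   error = function(e) -1e10)
    if (!is.finite(ll)) 1e10 else -ll
  }
  height <- max(ape::node.depth.edgelength(tree))
  start <- rep(log(1 / height), npar)
  lb <- log(1e-9)
  ub <- log(1e4)
  if (npar == 1L) {
    opt <- optim(start, nll, method = "Brent", lower = lb, upper = ub)
  } else {
    opt <- optim(start, nll, method = "L-BFGS-B", lower = lb, upper = ub,
                 control = list(factr = 1e4))
  }
  rates <- exp(opt$par)
  boundary <- any(opt$par <= lb + 1e-6) || any(opt$par >= ub - 1e-6)
  model <- mk_model(build_Q(opt$par), root_prior)
  structure(list(model = model, loglik = -opt$value, rates = rates,
                 npar = npar, AIC = 2 * opt$value + 2 * npar,
                 constraint = constraint, boundary = boundary || single,
                 converged = opt$convergence == 0),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk fit (", x$constraint, "): logLik = ", round(x$loglik, 4),
      ", AIC = ", round(x$AIC, 2),
      if (x$boundary) " [rate at boundary]" else "", "\n", sep = "")
  print(round(x$model$Q, 5))
  invisible(x)
}

# Uppass quantities for marginal reconstruction:
#   U[v, ]  partial likelihood of everything outside the clade of v, as a
#           function of the state at v (rows normalised)
#   Tmat[e, ]  the "edge-top" vector T_e(s_parent): U[parent] times the
#           messages of all sibling edges of e
mk_uppass <- function(mach) {
  tr <- mach$tree
  nedge <- nrow(tr$edge)
  U <- matrix(0, mach$nn, mach$k)
  U[mach$root, ] <- mach$model$pi
  Tmat <- matrix(0, nedge, mach$k)
  children <- split(seq_len(nedge), tr$edge[, 1])
  # preorder: visit edges parent-before-child
  ord <- rev(seq_len(nedge))
  for (e in ord) {
    par <- tr$edge[e, 1]
    sibs <- setdiff(children[[as.character(par)]], e)
    tvec <- U[par, ]
    for (b in sibs) tvec <- tvec * mach$M[b, ]
    Tmat[e, ] <- tvec
    chd <- tr$edge[e, 2]
    u <- drop(tvec %*% mach$P[[e]])
    s <- sum(u)
    U[chd, ] <- if (s > 0) u / s else u
  }
  list(U = U, Tmat = Tmat)
}

#' Marginal ancestral state probabilities
#'
#' Computes, for every internal node, the marginal posterior probability of
#' each state given the tip data and the model (the re-rooting/two-pass
#' algorithm); rows sum to one.
#'
#' @inheritParams mk_loglik
#' @return matrix (internal nodes x states); row names are ape node
#'   numbers `(ntip+1)..(ntip+Nnode)`.
#' @export
marginal_asr <- function(tree, tip_states, model) {
  mach <- mk_machinery(tree, tip_states, model)
  up <- mk_uppass(mach)
  nodes <- (mach$ntip + 1L):mach$nn
  post <- mach$L[nodes, , drop = FALSE] * up$U[nodes, , drop = FALSE]
  post <- post / rowSums(post)
  dimnames(post) <- list(nodes, mach$model$states)
  post
}

# Marginal state probabilities at interior points of edges.  `points` is a
# data.frame with `edge` (row index into mach$tree$edge) and `dist`
# (distance from the parent end).  Requires the uppass to have been run.
marginal_at_points <- function(mach, up, points) {
  out <- matrix(0, nrow(points), mach$k)
  for (i in seq_len(nrow(points))) {
    e <- points$edge[i]
    d <- points$dist[i]
    len <- mach$tree$edge.length[e]
    chd <- mach$tree$edge[e, 2]
    top <- drop(up$Tmat[e, ] %*% mach$pfun(d))
    bottom <- drop(mach$pfun(len - d) %*% mach$L[chd, ])
    m <- top * bottom
    out[i, ] <- m / sum(m)
  }
  colnames(out) <- mach$model$states
  out
}
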