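# Independent oracles used across the suite.  These deliberately avoid the
# package's own algorithms: likelihoods by exhaustive enumeration, OLS by
# closed-form normal equations, ODEs by a fixed-step integrator.

# Matrix exponential for the oracles (eigen route, independent of the
# package's internal scaled-squaring fallback path usage).
oracle_expm <- function(Q, t) {
  eg <- eigen(Q)
  Re(eg$vectors %*% (exp(eg$values * t) * solve(eg$vectors)))
}

# Mk likelihood by summing over every internal-node state assignment.
oracle_mk_loglik <- function(tree, tip_states, Q, pi) {
  pi <- unname(pi)
  states <- rownames(Q)
  k <- length(states)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  P <- lapply(tree$edge.length, function(t) oracle_expm(Q, t))
  tipidx <- match(tip_states[tree$tip.label], states)
  internal <- (ntip + 1):nn
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    st <- integer(nn)
    st[seq_len(ntip)] <- tipidx
    st[internal] <- grid[g, ]
    pr <- pi[st[ntip + 1]]
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * P[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    tot <- tot + pr
  }
  log(tot)
}

# Marginal node probabilities by the same enumeration.
oracle_mk_marginals <- function(tree, tip_states, Q, pi) {
  pi <- unname(pi)
  states <- rownames(Q)
  k <- length(states)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  P <- lapply(tree$edge.length, function(t) oracle_expm(Q, t))
  tipidx <- match(tip_states[tree$tip.label], states)
  internal <- (ntip + 1):nn
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  joint <- matrix(0, length(internal), k)
  for (g in seq_len(nrow(grid))) {
    st <- integer(nn)
    st[seq_len(ntip)] <- tipidx
    st[internal] <- grid[g, ]
    pr <- pi[st[ntip + 1]]
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * P[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    for (j in seq_along(internal))
      joint[j, grid[g, j]] <- joint[j, grid[g, j]] + pr
  }
  out <- joint / rowSums(joint)
  dimnames(out) <- list(internal, states)
  out
}

# Marginal state probability at a point on an edge, by enumeration: the
# edge is split into two transition factors around the point.
oracle_point_marginal <- function(tree, tip_states, Q, pi, edge, dist) {
  pi <- unname(pi)
  states <- rownames(Q)
  k <- length(states)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  P <- lapply(tree$edge.length, function(t) oracle_expm(Q, t))
  Pa <- oracle_expm(Q, dist)
  Pb <- oracle_expm(Q, tree$edge.length[edge] - dist)
  tipidx <- match(tip_states[tree$tip.label], states)
  internal <- (ntip + 1):nn
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  out <- numeric(k)
  for (s in seq_len(k)) {
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      st <- integer(nn)
      st[seq_len(ntip)] <- tipidx
      st[internal] <- grid[g, ]
      pr <- pi[st[ntip + 1]]
      for (e in seq_len(nrow(tree$edge))) {
        pr <- pr * if (e == edge)
          Pa[st[tree$edge[e, 1]], s] * Pb[s, st[tree$edge[e, 2]]]
        else P[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
      }
      tot <- tot + pr
    }
    out[s] <- tot
  }
  names(out) <- states
  out / sum(out)
}

# MuSSE log-likelihood with a brute-force fixed-step RK4 integrator,
# written independently of the package's postorder/Rcpp implementation.
oracle_sse_loglik <- function(tree, tip_states, model, nsteps = 2000) {
  k <- length(model$states)
  lam <- unname(model$lambda)
  mu <- unname(model$mu)
  Q <- unname(model$Q)
  deriv <- function(y) {
    E <- y[1:k]
    D <- y[k + 1:k]
    qout <- -diag(Q)
    dE <- mu - (lam + mu + qout) * E + lam * E^2 +
      drop(Q %*% E) - diag(Q) * E
    dD <- -(lam + mu + qout) * D + 2 * lam * E * D +
      drop(Q %*% D) - diag(Q) * D
    c(dE, dD)
  }
  integrate_branch <- function(y, len) {
    h <- len / nsteps
    for (i in seq_len(nsteps)) {
      k1 <- deriv(y)
      k2 <- deriv(y + h / 2 * k1)
      k3 <- deriv(y + h / 2 * k2)
      k4 <- deriv(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    y
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  Dm <- matrix(0, nn, k)
  Em <- matrix(0, nn, k)
  for (i in seq_len(ntip)) {
    s <- match(tip_states[[tr$tip.label[i]]], model$states)
    Dm[i, s] <- 1
  }
  seen <- logical(nn)
  seen[seq_len(ntip)] <- TRUE
  logscale <- 0
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]
    chd <- tr$edge[e, 2]
    y <- integrate_branch(c(Em[chd, ], Dm[chd, ]), tr$edge.length[e])
    E <- y[1:k]
    D <- pmax(y[k + 1:k], 0)
    if (!seen[par]) {
      Dm[par, ] <- D * lam
      Em[par, ] <- E
      seen[par] <- TRUE
    } else Dm[par, ] <- Dm[par, ] * D
    sc <- max(Dm[par, ])
    Dm[par, ] <- Dm[par, ] / sc
    logscale <- logscale + log(sc)
  }
  root <- ntip + 1L
  D <- Dm[root, ]
  w <- if (!is.null(model$pi)) model$pi
       else switch(model$root_treatment,
                   flat = rep(1 / k, k),
                   likelihood_weighted = D / sum(D),
                   equilibrium = rep(1 / k, k))
  log(sum(w * D)) + logscale
}

# Random rate matrix with named states.
random_Q <- function(k, lo = 0.1, hi = 1) {
  Q <- matrix(runif(k * k, lo, hi), k)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rownames(Q) <- colnames(Q) <- paste0("s", seq_len(k))
  Q
}

# Random recursive path-model instance: a DAG over p ordered variables
# (each forward pair an edge with probability `dens`), data generated from
# the corresponding linear system.
random_recursive_instance <- function(p, n, dens = 0.5) {
  vars <- paste0("v", seq_len(p))
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, vars))
  edges <- NULL
  for (j in 2:p) {
    pa <- which(runif(j - 1) < dens)
    if (length(pa)) {
      b <- runif(length(pa), -0.8, 0.8)
      X[, j] <- X[, j] + X[, pa, drop = FALSE] %*% b
      edges <- rbind(edges, data.frame(cause = vars[pa], effect = vars[j]))
    }
  }
  if (is.null(edges))  # degenerate draw: keep one (truly zero) edge
    edges <- data.frame(cause = "v1", effect = "v2")
  endo <- unique(edges$effect)
  eqs <- vapply(endo, function(v)
    paste(v, "~", paste(edges$cause[edges$effect == v], collapse = " + ")),
    character(1))
  list(model = path_model(eqs), data = as.data.frame(X), edges = edges)
}

# Full synthetic input set under a simple scenario; shared by the
# permutation/gradient tests.
make_synth_inputs <- function(n_units, effect, seed, n_palms = 150,
                              mean_richness = 8, slope = 1.5,
                              grid_dims = NULL, temp_effect = 0.2) {
  units <- generate_landscape(landscape_spec(n_units, grid_dims = grid_dims,
                                             seed = seed))
  flora <- generate_palm_flora(units, n_species = n_palms, slope = slope,
                               mean_richness = mean_richness,
                               seed = seed + 1L)
  scen <- structural_scenario(
    c("prop_conspicuous->richness_trichromat" = effect,
      "temp->richness_trichromat" = temp_effect))
  prim <- generate_primate_assemblage(units, flora, scen, seed = seed + 2L)
  list(units = units, flora = flora, prim = prim,
       model = path_model("richness_trichromat ~ prop_conspicuous + temp"),
       focal = "prop_conspicuous->richness_trichromat")
}
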