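# Stochastic character mapping (endpoint-conditioned via uniformization)
# and trait-state lineage-diversity-through-time curves.

#' Stochastic character maps
#'
#' Samples complete character histories conditional on the tip data and an
#' Mk model: node states are drawn root-to-tips from their joint
#' conditional distributions, then each branch history is sampled
#' conditioned on its endpoint states by uniformization (exact; no
#' rejection blow-up on long branches).
#'
#' @inheritParams mk_loglik
#' @param n_maps number of maps.
#' @param seed integer seed; the same seed yields an identical map set.
#' @return list of class `simmap_set`; each element is a `simmap_sample`
#'   with `node_states` (state label per node, tips included, in ape
#'   numbering of the postorder-reordered tree returned in the `tree`
#'   attribute) and `histories` (per edge, a data.frame of `state` and
#'   `duration` segments ordered from the parent end; durations sum to the
#'   branch length and adjacent segments differ in state).
#' @export
stochastic_map <- function(tree, tip_states, model, n_maps = 100,
                           seed = 1L) {
  stop_if(!is_count(n_maps), "`n_maps` must be >= 1")
  mach <- mk_machinery(tree, tip_states, model)
  tr <- mach$tree
  k <- mach$k
  Q <- mach$model$Q
  nedge <- nrow(tr$edge)
  preorder <- rev(seq_len(nedge))
  # uniformization setup (shared by all maps)
  Om <- max(-diag(Q))
  R <- if (Om > 0) diag(k) + Q / Om else diag(k)
  Rpow <- list(diag(k))  # Rpow[[n+1]] = R^n
  get_Rpow <- function(n) {
    while (length(Rpow) < n + 1L)
      Rpow[[length(Rpow) + 1L]] <<- Rpow[[length(Rpow)]] %*% R
    Rpow[[n + 1L]]
  }
  root_p <- mach$model$pi * mach$L[mach$root, ]
  root_p <- root_p / sum(root_p)

  maps <- with_seed(seed, lapply(seq_len(n_maps), function(m) {
    st <- integer(mach$nn)
    st[mach$root] <- sample.int(k, 1L, prob = root_p)
    hist <- vector("list", nedge)
    for (e in preorder) {
      par <- tr$edge[e, 1]
      chd <- tr$edge[e, 2]
      p <- mach$P[[e]][st[par], ] * mach$L[chd, ]
      st[chd] <- sample.int(k, 1L, prob = p)
      hist[[e]] <- sample_branch_history(
        st[par], st[chd], tr$edge.length[e], Q, Om, R, get_Rpow,
        mach$P[[e]], mach$model$states)
    }
    structure(list(node_states = setNames(mach$model$states[st],
                                          seq_len(mach$nn)),
                   histories = hist),
              class = "simmap_sample")
  }))
  structure(maps, class = "simmap_set", tree = tr,
            states = mach$model$states, seed = seed)
}

# Endpoint-conditioned CTMC history on one branch by uniformization.
# Returns data.frame(state, duration), segments from the parent end.
sample_branch_history <- function(a, b, len, Q, Om, R, get_Rpow, P,
                                  states, max_jumps = 10000L) {
  if (Om <= 0 || len <= 0) {
    stop_if(a != b, "no transitions possible but endpoint states differ")
    return(data.frame(state = states[a], duration = len,
                      stringsAsFactors = FALSE))
  }
  Pab <- P[a, b]
  stop_if(Pab <= 0, "endpoint-conditioned sampling failed: impossible ",
          "endpoint pair on a branch")
  # number of virtual jumps: P(N = n) = dpois(n, Om*len) R^n[a,b] / Pab
  u <- runif(1L)
  cum <- 0
  n <- -1L
  repeat {
    n <- n + 1L
    stop_if(n > max_jumps, "uniformization exceeded the jump cap")
    cum <- cum + dpois(n, Om * len) * get_Rpow(n)[a, b] / Pab
    if (u <= cum || cum >= 1 - 1e-12) break
  }
  if (n == 0L)
    return(data.frame(state = states[a], duration = len,
                      stringsAsFactors = FALSE))
  # jump-chain bridge: states at the virtual jumps
  s <- integer(n + 1L)
  s[1L] <- a
  s[n + 1L] <- b
  if (n > 1L) {
    for (j in 2:n) {
      w <- R[s[j - 1L], ] * get_Rpow(n + 1L - j)[, b]
      s[j] <- sample.int(length(w), 1L, prob = w)
    }
  }
  times <- sort(runif(n, 0, len))
  # collapse virtual (self) jumps into segments
  seg_state <- s[1L]
  seg_start <- 0
  out_state <- integer(0)
  out_dur <- numeric(0)
  cur <- s[1L]
  for (j in seq_len(n)) {
    if (s[j + 1L] != cur) {
      out_state <- c(out_state, cur)
      out_dur <- c(out_dur, times[j] - seg_start)
      seg_start <- times[j]
      cur <- s[j + 1L]
    }
  }
  out_state <- c(out_state, cur)
  out_dur <- c(out_dur, len - seg_start)
  data.frame(state = states[out_state], duration = out_dur,
             stringsAsFactors = FALSE)
}

#' @export
print.simmap_set <- function(x, ...) {
  tr <- attr(x, "tree")
  cat("Stochastic character maps:", length(x), "maps on a tree with",
      length(tr$tip.label), "tips; states:",
      paste(attr(x, "states"), collapse = ", "), "\n")
  invisible(x)
}

# Node ages (time before present) and edge endpoints in ages.
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth)
  height - depth
}

#' Trait-state lineage diversity through time
#'
#' For each internal-node time (ordered from the root towards the
#' present), estimates the expected number of contemporaneous lineages in
#' the focal state among all lineages alive at that time.
#' `method = "simulation"` averages indicator counts over stochastic maps;
#' `method = "asr"` sums exact per-lineage marginal state probabilities
#' evaluated at the corresponding point of each branch.  Summing the focal
#' diversity over all states returns the number of lineages alive.
#'
#' @param tree rooted, (near-)ultrametric phylogeny.  Ignored (taken from
#'   the maps) when `maps` is given.
#' @param tip_states,model required for `method = "asr"`.
#' @param maps a `simmap_set` from [stochastic_map()], required for
#'   `method = "simulation"`.
#' @param focal focal state label.
#' @param method estimation method.
#' @return data.frame of class `diversity_curve`: `node` (ape number),
#'   `time` (age, Ma), `n_focal`, `n_total`.
#' @export
state_diversity_through_time <- function(tree = NULL, tip_states = NULL,
                                         model = NULL, maps = NULL, focal,
                                         method = c("simulation", "asr")) {
  method <- match.arg(method)
  if (method == "simulation") {
    stop_if(is.null(maps), "method = 'simulation' needs `maps`")
    tr <- attr(maps, "tree")
    states <- attr(maps, "states")
  } else {
    stop_if(is.null(tree) || is.null(tip_states) || is.null(model),
            "method = 'asr' needs `tree`, `tip_states` and `model`")
    mach <- mk_machinery(tree, tip_states, model)
    up <- mk_uppass(mach)
    tr <- mach$tree
    states <- mach$model$states
  }
  stop_if(!focal %in% states,
          "focal state '", focal, "' unknown; states: ",
          paste(states, collapse = ", "))
  ntip <- length(tr$tip.label)
  age <- node_ages(tr)
  internal <- (ntip + 1L):(ntip + tr$Nnode)
  ord <- internal[order(age[internal], decreasing = TRUE)]
  eps <- max(min(tr$edge.length[tr$edge.length > 0]) * 1e-6, 1e-12)
  age_par <- age[tr$edge[, 1]]
  age_chd <- age[tr$edge[, 2]]

  out <- data.frame(node = ord, time = age[ord], n_focal = NA_real_,
                    n_total = NA_integer_)
  for (i in seq_along(ord)) {
    s_eval <- age[ord[i]] - eps
    alive <- which(age_par > s_eval & age_chd <= s_eval)
    out$n_total[i] <- length(alive)
    d <- age_par[alive] - s_eval
    if (method == "asr") {
      pts <- data.frame(edge = alive, dist = d)
      probs <- marginal_at_points(mach, up, pts)
      out$n_focal[i] <- sum(probs[, focal])
    } else {
      counts <- vapply(maps, function(m) {
        sum(vapply(seq_along(alive), function(j) {
          h <- m$histories[[alive[j]]]
          sgm <- cumsum(h$duration)
          idx <- which(sgm >= d[j] - 1e-12)[1]
          h$state[idx] == focal
        }, logical(1)))
      }, numeric(1))
      out$n_focal[i] <- mean(counts)
    }
  }
  class(out) <- c("diversity_curve", "data.frame")
  attr(out, "focal") <- focal
  attr(out, "method") <- method
  out
}
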