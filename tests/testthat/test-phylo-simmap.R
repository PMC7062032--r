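test_that("stochastic maps satisfy their structural invariants", {
  set.seed(71)
  tr <- ape::rcoal(8)
  Q <- random_Q(2, 0.3, 0.8)
  ts <- setNames(sample(rownames(Q), 8, TRUE), tr$tip.label)
  m <- mk_model(Q, root_prior = "flat")
  maps <- stochastic_map(tr, ts, m, n_maps = 100, seed = 3)
  trp <- attr(maps, "tree")
  for (mp in maps) {
    for (e in seq_len(nrow(trp$edge))) {
      h <- mp$histories[[e]]
      expect_lt(abs(sum(h$duration) - trp$edge.length[e]), 1e-9)
      if (nrow(h) > 1)
        expect_true(all(h$state[-1] != h$state[-nrow(h)]))
      # endpoint states agree with the sampled node states
      expect_equal(h$state[1],
                   mp$node_states[[trp$edge[e, 1]]])
      expect_equal(h$state[nrow(h)],
                   mp$node_states[[trp$edge[e, 2]]])
    }
    # tips carry their observed states
    for (i in seq_along(trp$tip.label))
      expect_equal(mp$node_states[[i]], ts[[trp$tip.label[i]]])
  }
  expect_identical(maps, stochastic_map(tr, ts, m, n_maps = 100, seed = 3))
})

test_that("maps contain no transitions when the rate is zero", {
  tr <- ape::rcoal(6)
  Q0 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  ts <- setNames(rep("a", 6), tr$tip.label)
  maps <- stochastic_map(tr, ts, mk_model(Q0, root_prior = "flat"),
                         n_maps = 10, seed = 1)
  for (mp in maps)
    expect_true(all(vapply(mp$histories, nrow, 0L) == 1L))
})

test_that("node-state frequencies converge to the marginal probabilities", {
  set.seed(72)
  tr <- ape::rcoal(10)
  Q <- random_Q(2, 0.3, 0.7)
  ts <- setNames(sample(rownames(Q), 10, TRUE), tr$tip.label)
  m <- mk_model(Q, root_prior = "flat")
  maps <- stochastic_map(tr, ts, m, n_maps = 800, seed = 5)
  asr <- marginal_asr(tr, ts, m)
  for (v in rownames(asr)) {
    freq <- mean(vapply(maps, function(mp)
      mp$node_states[[as.integer(v)]] == "s1", logical(1)))
    mc_se <- sqrt(max(asr[v, "s1"] * (1 - asr[v, "s1"]), 1e-4) / 800)
    expect_lt(abs(freq - asr[v, "s1"]), 3.5 * mc_se + 0.005)
  }
})

test_that("diversity-through-time conserves lineage counts and matches a
          monomorphic lineage-through-time curve", {
  set.seed(73)
  tr <- ape::rcoal(9)
  Q <- random_Q(2, 0.2, 0.5)
  ts <- setNames(sample(rownames(Q), 9, TRUE), tr$tip.label)
  m <- mk_model(Q, root_prior = "flat")
  d1 <- state_diversity_through_time(tr, ts, m, focal = "s1",
                                     method = "asr")
  d2 <- state_diversity_through_time(tr, ts, m, focal = "s2",
                                     method = "asr")
  expect_equal(d1$n_focal + d2$n_focal, as.numeric(d1$n_total),
               tolerance = 1e-9)
  # counts go 2, 3, ... from the root for a binary coalescent tree
  expect_equal(d1$n_total, 2:9)
  expect_true(all(diff(d1$time) < 0))

  maps <- stochastic_map(tr, ts, m, n_maps = 300, seed = 6)
  s1 <- state_diversity_through_time(maps = maps, focal = "s1",
                                     method = "simulation")
  s2 <- state_diversity_through_time(maps = maps, focal = "s2",
                                     method = "simulation")
  expect_equal(s1$n_focal + s2$n_focal, as.numeric(s1$n_total),
               tolerance = 1e-9)

  # degenerate single-state tree: focal curve equals lineages alive
  ts_mono <- setNames(rep("s1", 9), tr$tip.label)
  dm <- state_diversity_through_time(
    tr, ts_mono, mk_model(Q * 1e-8, root_prior = "flat"),
    focal = "s1", method = "asr")
  expect_equal(dm$n_focal, as.numeric(dm$n_total), tolerance = 1e-5)

  expect_error(state_diversity_through_time(tr, ts, m, focal = "nope",
                                            method = "asr"),
               "unknown")
})

test_that("the asr curve equals enumeration on a worked 5-tip fixture", {
  tr <- ape::read.tree(text =
    "((a:1.0,b:1.0):1.5,(c:0.8,(d:0.5,e:0.5):0.3):1.7);")
  Q <- matrix(c(-0.4, 0.4, 0.25, -0.25), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("s1", "s2")))
  ts <- c(a = "s1", b = "s2", c = "s1", d = "s1", e = "s2")
  m <- mk_model(Q, root_prior = "flat")
  curve <- state_diversity_through_time(tr, ts, m, focal = "s1",
                                        method = "asr")
  # independent expectation: enumerate the point marginal of every
  # lineage alive just below each node time and sum the focal column
  trp <- ape::reorder.phylo(tr, "postorder")
  age <- palmvision:::node_ages(trp)
  for (r in seq_len(nrow(curve))) {
    s_eval <- curve$time[r] - 1e-9
    alive <- which(age[trp$edge[, 1]] > s_eval &
                     age[trp$edge[, 2]] <= s_eval)
    want <- sum(vapply(alive, function(e)
      oracle_point_marginal(trp, ts, Q, m$pi, e,
                            age[trp$edge[e, 1]] - s_eval)["s1"],
      numeric(1)))
    expect_equal(curve$n_focal[r], want, tolerance = 1e-6)
    expect_equal(curve$n_total[r], length(alive))
  }
})
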