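test_that("triplet selection enumerates, thresholds and caps correctly", {
  K4 <- connectivity_matrix(matrix(1, 4, 4) - diag(4))
  tr <- select_triplets(K4, "dense")
  expect_equal(nrow(tr), 12)  # 4 targets x choose(3, 2)
  expect_true(all(tr$s1 < tr$s2))
  expect_true(all(tr$target != tr$s1 & tr$target != tr$s2))

  # dense count N (N-1) (N-2) / 2 for N <= 8, against brute force
  for (n in 5:8) {
    Kn <- connectivity_matrix(matrix(1, n, n) - diag(n))
    got <- nrow(select_triplets(Kn, "dense"))
    brute <- 0
    for (i in 1:n) for (j in 1:(n - 1)) for (k in (j + 1):n) {
      if (j != i && k != i && j < k) brute <- brute + 1
    }
    expect_equal(got, brute)
    expect_equal(got, n * (n - 1) * (n - 2) / 2)
  }

  # sparse mode: only edges (1-2), (1-3) survive -> single triplet
  C <- cm_from_edges(5, list(c(1, 2, 10), c(1, 3, 9), c(2, 4, 1), c(3, 5, 0.5)))
  trs <- select_triplets(C, "sparse", target_density = 0.2)
  expect_equal(nrow(trs), 1)
  expect_equal(trs$target, 1)
  expect_setequal(c(trs$s1, trs$s2), c(2, 3))

  # no qualifying triplet errors
  C2 <- cm_from_edges(5, list(c(1, 2, 10), c(3, 4, 9)))
  expect_error(select_triplets(C2, "sparse", target_density = 0.2), "qualifying")

  # cap determinism
  K8 <- connectivity_matrix(matrix(1, 8, 8) - diag(8))
  a <- select_triplets(K8, "dense", max_triplets = 10, seed = 5)
  b <- select_triplets(K8, "dense", max_triplets = 10, seed = 5)
  expect_identical(a, b)
  expect_equal(nrow(a), 10)

  # top_k mode: every node gets choose(k, 2) triplets
  set.seed(2)
  w <- matrix(stats::runif(64), 8, 8); w <- w + t(w); diag(w) <- 0
  Cw <- connectivity_matrix(w)
  trk <- select_triplets(Cw, "top_k", k_sources = 4)
  expect_equal(nrow(trk), 8 * choose(4, 2))
  expect_equal(as.integer(table(trk$target)), rep(choose(4, 2), 8))
})

test_that("sparse selection is monotone in the link density", {
  set.seed(3)
  w <- matrix(0, 10, 10)
  w[upper.tri(w)] <- stats::runif(45)
  C <- connectivity_matrix(w + t(w))
  key <- function(tr) paste(tr$target, tr$s1, tr$s2)
  lo <- select_triplets(C, "sparse", target_density = 0.15)
  mid <- select_triplets(C, "sparse", target_density = 0.20)
  hi <- select_triplets(C, "sparse", target_density = 0.25)
  expect_true(all(key(lo) %in% key(mid)))
  expect_true(all(key(mid) %in% key(hi)))
})

test_that("per-node synergy averages over targeting triplets", {
  set.seed(4)
  m <- matrix(sample(c(-1L, 1L), 3000, TRUE), 300, 10)
  tr2 <- data.frame(target = c(3L, 3L), s1 = c(1L, 2L), s2 = c(5L, 7L))
  # expected: mean of the two per-triplet synergies, computed independently
  s_each <- vapply(1:2, function(r) {
    pid_decompose(estimate_lagged_joint(m, 3, c(tr2$s1[r], tr2$s2[r])))$S
  }, numeric(1))
  prof <- node_incoming_synergy(m, tr2, 10)
  expect_equal(prof$incoming_synergy[3], mean(s_each), tolerance = 1e-12)
  expect_equal(prof$n_triplets[3], 2L)
  # untargeted nodes report NaN, not 0
  expect_true(all(is.nan(prof$incoming_synergy[-3])))
  expect_true(all(prof$n_triplets[-3] == 0))

  # single triplet
  pr1 <- node_incoming_synergy(m, tr2[1, ], 10)
  expect_equal(pr1$incoming_synergy[3], s_each[1], tolerance = 1e-12)

  # permutation invariance over triplet order
  tr_many <- data.frame(target = c(3L, 4L, 3L, 4L), s1 = c(1L, 1L, 2L, 2L),
                        s2 = c(5L, 5L, 7L, 7L))
  p_fwd <- node_incoming_synergy(m, tr_many, 10)
  p_rev <- node_incoming_synergy(m, tr_many[4:1, ], 10)
  expect_equal(p_fwd$incoming_synergy, p_rev$incoming_synergy, tolerance = 1e-12)

  # frozen series: zero synergy for every triplet
  frozen <- matrix(1L, 200, 10)
  pf <- node_incoming_synergy(frozen, tr2, 10)
  expect_equal(pf$incoming_synergy[3], 0)
  expect_error(node_incoming_synergy(m, tr2[0, ], 10), "nonempty")
})

test_that("TE profiles vanish for independent spins", {
  set.seed(5)
  m <- matrix(sample(c(-1L, 1L), 8 * 20000, TRUE), 20000, 8)
  prof <- node_te_profile(m, 8)
  bias_bound <- 3 * 7 / (2 * 20000 * log(2)) + 0.002
  expect_true(all(prof$incoming_TE < bias_bound))
  expect_true(all(prof$outgoing_TE < bias_bound))
})

test_that("hub synergy curves locate per-hub peaks on a sweep", {
  C <- generate_heterogeneous_connectome(20, seed = 31)
  proto <- simulation_protocol(suggest_beta_grid(C, 8), relaxation = 400,
                               discard = 200, collect = 2500, runs = 1, seed = 2)
  sw <- temperature_sweep(C, proto)
  hc <- hub_synergy_curves(sw, C, n_hubs = 3, pairs_per_hub = 15, seed = 1)
  expect_equal(dim(hc$curves), c(3, 8))
  expect_setequal(hc$hubs, order(node_strength(C), decreasing = TRUE)[1:3])
  expect_true(all(hc$peak_beta %in% sw$betas))
  # determinism
  hc2 <- hub_synergy_curves(sw, C, n_hubs = 3, pairs_per_hub = 15, seed = 1)
  expect_identical(hc$curves, hc2$curves)
  # keep_series = FALSE is rejected
  proto$keep_series <- FALSE
  sw0 <- temperature_sweep(C, proto)
  expect_error(hub_synergy_curves(sw0, C), "keep_series")
})

test_that("synergy-topology association computes rank correlations", {
  C <- generate_heterogeneous_connectome(15, seed = 41)
  topo <- centrality_metrics(C)
  # synergy identical to strength: rho = 1 against strength
  prof <- data.frame(node = 1:15, incoming_synergy = topo$strength)
  a <- synergy_topology_association(prof, topo)
  expect_equal(a$rho[a$metric == "strength"], 1)
  # random permutation: small rho (no systematic association)
  set.seed(6)
  rhos <- replicate(30, {
    pr <- data.frame(node = 1:15, incoming_synergy = sample(topo$strength))
    synergy_topology_association(pr, topo)$rho[1]
  })
  expect_lt(abs(mean(rhos)), 0.2)
  prof$incoming_synergy[1:12] <- NaN
  expect_error(synergy_topology_association(prof, topo), "at least 5")
})

test_that("node synergy profiles are rank-stable across thresholds", {
  C <- generate_heterogeneous_connectome(20, seed = 51)
  proto <- simulation_protocol(suggest_beta_grid(C, 6), relaxation = 400,
                               discard = 200, collect = 3000, runs = 1, seed = 3)
  sw <- temperature_sweep(C, proto)
  ser <- sw$series[[which.max(sw$chi)]]
  st <- synergy_threshold_stability(ser, C, densities = c(0.20, 0.15, 0.25))
  expect_equal(st$rank_correlation[1], 1)
  expect_true(all(st$rank_correlation > 0.5))
})
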