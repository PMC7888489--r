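test_that("matrix files load, validate and round-trip", {
  # zero matrix
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,0,0", "0,0,0", "0,0,0"), f)
  C <- load_connectome(f)
  expect_s3_class(C, "connectivity_matrix")
  expect_equal(unname(node_strength(C)), c(0, 0, 0))

  # single edge
  writeLines(c("0,2,0", "2,0,0", "0,0,0"), f)
  expect_equal(unname(node_strength(load_connectome(f))), c(2, 2, 0))

  # asymmetric beyond tolerance errors
  writeLines(c("0,1", "3,0"), f)
  expect_error(load_connectome(f), "asymmetric")

  # negative / NaN / non-square all rejected
  writeLines(c("0,-1", "-1,0"), f)
  expect_error(load_connectome(f), "negative")
  writeLines(c("0,NaN", "NaN,0"), f)
  expect_error(load_connectome(f), "NaN")
  writeLines(c("0,1,2", "1,0,1"), f)
  expect_error(load_connectome(f))

  # round trip to 1e-12 relative, with labels sidecar
  set.seed(1)
  w <- matrix(stats::runif(49), 7, 7); w <- w + t(w); diag(w) <- 0
  C0 <- connectivity_matrix(w, labels = sprintf("roi_%d", 1:7))
  lf <- withr::local_tempfile()
  write_connectome(C0, f, labels_path = lf)
  C1 <- load_connectome(f, labels_path = lf)
  expect_equal(C1$weights, C0$weights, tolerance = 1e-12)
  expect_identical(C1$labels, C0$labels)
})

test_that("averaging connectomes is the elementwise mean", {
  set.seed(2)
  w <- matrix(stats::runif(16), 4, 4); w <- w + t(w); diag(w) <- 0
  M <- connectivity_matrix(w)
  zero <- connectivity_matrix(matrix(0, 4, 4))
  expect_equal(average_connectomes(list(M))$weights, M$weights)
  expect_equal(average_connectomes(list(M, zero))$weights, M$weights / 2)
  # disjoint single edges of weight 2 -> both present with weight 1
  A <- cm_from_edges(4, list(c(1, 2, 2)))
  B <- cm_from_edges(4, list(c(3, 4, 2)))
  avg <- average_connectomes(list(A, B))
  expect_equal(avg$weights[1, 2], 1)
  expect_equal(avg$weights[3, 4], 1)
  expect_equal(sum(avg$weights), 4)  # two undirected edges, both directions
  expect_error(average_connectomes(list()), "at least one")
  expect_error(average_connectomes(list(M, connectivity_matrix(matrix(0, 3, 3)))),
               "mismatch")
})

test_that("density thresholding hits the target and excludes ties", {
  set.seed(3)
  w <- matrix(0, 5, 5)
  w[upper.tri(w)] <- sample(1:10)  # distinct positive weights on all 10 pairs
  C <- connectivity_matrix(w + t(w))
  th <- density_threshold(C, 0.2)
  expect_equal(sum(th$mask[upper.tri(th$mask)]), 2L)
  kept <- C$weights[upper.tri(C$weights)][th$mask[upper.tri(th$mask)]]
  expect_setequal(kept, c(9, 10))

  # target 1 keeps every positive edge, threshold below minimum weight
  th1 <- density_threshold(C, 1.0)
  expect_equal(sum(th1$mask[upper.tri(th1$mask)]), 10L)
  expect_lt(th1$J_th, min(C$weights[C$weights > 0]))

  # density already matching the positive support
  C4 <- cm_from_edges(5, list(c(1, 2, 5), c(2, 3, 4), c(3, 4, 3), c(4, 5, 2)))
  th4 <- density_threshold(C4, 0.4)
  expect_equal(sum(th4$mask[upper.tri(th4$mask)]), 4L)

  # all-equal weights cannot hit an intermediate target
  Ceq <- connectivity_matrix(matrix(1, 4, 4) - diag(4))
  expect_warning(theq <- density_threshold(Ceq, 0.5), "equal")
  expect_equal(sum(theq$mask), 0L)
  expect_error(density_threshold(C, 0), "target_density")
})

test_that("retained density is within one edge of target for distinct weights", {
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- stats::runif(n * (n - 1) / 2)
    C <- connectivity_matrix(w + t(w))
    d <- stats::runif(1, 0.05, 0.95)
    th <- density_threshold(C, d)
    n_pairs <- n * (n - 1) / 2
    kept <- sum(th$mask[upper.tri(th$mask)])
    expect_lte(abs(kept - d * n_pairs), 1)
    expect_lte(kept, floor(d * n_pairs))
  }
})

test_that("strength and centralities match brute-force enumeration", {
  # path graph a-b-c: betweenness maximal at middle, zero at the ends
  P <- cm_from_edges(3, list(c(1, 2, 1), c(2, 3, 1)))
  cp <- centrality_metrics(P)
  expect_equal(cp$betweenness, c(0, 1, 0))

  # complete unit-weight graph: zero betweenness, equal closeness
  K <- connectivity_matrix(matrix(1, 4, 4) - diag(4))
  ck <- centrality_metrics(K)
  expect_equal(ck$betweenness, rep(0, 4))
  expect_true(all(abs(ck$closeness - ck$closeness[1]) < 1e-12))
  expect_equal(unname(node_strength(K)), rep(3, 4))

  # star on 5 nodes: hub strictly dominates both centralities
  S <- cm_from_edges(5, lapply(2:5, function(j) c(1, j, 1)))
  cs <- centrality_metrics(S)
  expect_true(all(cs$betweenness[1] > cs$betweenness[-1]))
  expect_true(all(cs$closeness[1] > cs$closeness[-1]))

  # random weighted graphs up to 6 nodes against exhaustive enumeration
  set.seed(5)
  for (rep in 1:8) {
    n <- sample(4:6, 1)
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- stats::runif(n * (n - 1) / 2, 0.5, 2)
    C <- connectivity_matrix(w + t(w))
    got <- centrality_metrics(C)
    want <- oracle_centrality(C$weights)
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-10)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-10)
    expect_equal(got$strength, unname(rowSums(C$weights)))
  }
})

test_that("rich-club ratio separates planted cores from nulls", {
  # structureless weighted graphs: mean ratio over independent draws ~ 1
  # (a single small club's weight mass is too variable to test one draw)
  set.seed(6)
  ratios <- replicate(10, {
    w <- matrix(0, 20, 20)
    w[upper.tri(w)] <- sample(stats::rexp(190))
    C0 <- connectivity_matrix(w + t(w))
    rich_club_check(C0, n_null = 20, seed = 1, ranks = c(6, 8, 10))$ratio
  })
  expect_true(all(abs(rowMeans(ratios) - 1) < 0.3))

  # planted core: top-strength nodes knit by the largest weights
  C1 <- generate_heterogeneous_connectome(30, rich_club_fraction = 0.2,
                                          rich_club_boost = 5, seed = 2)
  rc1 <- rich_club_check(C1, n_null = 30, seed = 1, ranks = c(4, 6))
  expect_true(all(rc1$ratio > 1.05))

  # deterministic given seed
  rca <- rich_club_check(C1, n_null = 1, seed = 9, ranks = c(5))
  rcb <- rich_club_check(C1, n_null = 1, seed = 9, ranks = c(5))
  expect_identical(rca, rcb)
  expect_error(rich_club_check(C1, n_null = 0), "n_null")
})

test_that("cohort manifests read back with validation", {
  d <- withr::local_tempdir()
  C <- cm_from_edges(3, list(c(1, 2, 1)))
  write_connectome(C, file.path(d, "s1.csv"))
  write_connectome(C, file.path(d, "s2.csv"))
  writeLines(c("subject_id,age,path", "a,10,s1.csv", "b,50,s2.csv"),
             file.path(d, "manifest.csv"))
  mf <- read_cohort_manifest(file.path(d, "manifest.csv"))
  expect_equal(mf$subject_id, c("a", "b"))
  expect_true(all(file.exists(mf$path)))
  writeLines(c("subject_id,age,path", "a,10,s1.csv", "a,50,s2.csv"),
             file.path(d, "manifest.csv"))
  expect_error(read_cohort_manifest(file.path(d, "manifest.csv")), "duplicate")
  writeLines(c("subject_id,age,path", "a,-3,s1.csv"),
             file.path(d, "manifest.csv"))
  expect_error(read_cohort_manifest(file.path(d, "manifest.csv")), "range")
})
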