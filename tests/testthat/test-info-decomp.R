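test_that("lagged joint estimation counts configurations correctly", {
  # constant all-up series: all mass on the all-(+1) cell
  const <- matrix(1L, 50, 3)
  p <- estimate_lagged_joint(const, 1, 2)
  expect_equal(p$p["+1", "+1", "+1"], 1)
  expect_equal(sum(p$p), 1)

  # alternating all-up / all-down: two antisymmetric cells with mass 1/2
  # (odd row count -> an even number of transitions, split exactly in half)
  alt <- matrix(rep(rep(c(1L, -1L), length.out = 101), each = 3),
                ncol = 3, byrow = TRUE)
  pa <- estimate_lagged_joint(alt, 1, 2)
  expect_equal(pa$p["-1", "+1", "+1"], 0.5)
  expect_equal(pa$p["+1", "-1", "-1"], 0.5)
  expect_equal(sum(pa$p > 0), 2)

  # pooling runs = count-weighted average of per-run distributions
  set.seed(20)
  r1 <- matrix(sample(c(-1L, 1L), 300, TRUE), 100, 3)
  r2 <- matrix(sample(c(-1L, 1L), 300, TRUE), 100, 3)
  pool <- estimate_lagged_joint(list(r1, r2), 1, c(2, 3))
  p1 <- estimate_lagged_joint(r1, 1, c(2, 3))
  p2 <- estimate_lagged_joint(r2, 1, c(2, 3))
  expect_equal(pool$p, (p1$p * p1$n + p2$p * p2$n) / (p1$n + p2$n))

  # marginal consistency: sum over the future equals 1 per construction
  expect_equal(sum(pool$p), 1, tolerance = 1e-12)
  expect_error(estimate_lagged_joint(r1, 1, 1), "target")
  expect_error(estimate_lagged_joint(r1[1, , drop = FALSE], 1, 2), "short")
})

test_that("conditional mutual information matches closed forms", {
  # product distribution -> 0
  p <- array(1 / 8, c(2, 2, 2),
             dimnames = list(future = c("-1", "+1"), present = c("-1", "+1"),
                             src1 = c("-1", "+1")))
  expect_equal(conditional_mutual_information(p, 1, 3, 2), 0)

  # future copies the source exactly, present independent -> 1 bit
  pc <- array(0, c(2, 2, 2), dimnames = dimnames(p))
  pc[1, , 1] <- 0.25; pc[2, , 2] <- 0.25
  expect_equal(conditional_mutual_information(pc, 1, 3, 2), 1)
  # by name
  expect_equal(conditional_mutual_information(pc, "future", "src1", "present"), 1)

  # binary symmetric channel with flip probability 0.1
  eps <- 0.1
  pb <- array(0, c(2, 2, 2), dimnames = dimnames(p))
  for (f in 1:2) for (s in 1:2) {
    pb[f, , s] <- 0.25 * if (f == s) 1 - eps else eps
  }
  hb <- -(eps * log2(eps) + (1 - eps) * log2(1 - eps))
  expect_equal(conditional_mutual_information(pb, 1, 3, 2), 1 - hb)
  expect_error(conditional_mutual_information(p, 1, 1, 2), "malformed")
  expect_error(conditional_mutual_information(p, "future", "nope"), "unknown")
})

test_that("plugin transfer entropy behaves on canonical mechanisms", {
  set.seed(21)
  T_len <- 20000
  # independent coins: bounded by plugin bias ~ (cells-1)/(2 T ln 2)
  m_ind <- matrix(sample(c(-1L, 1L), 2 * T_len, TRUE), T_len, 2)
  expect_lt(transfer_entropy(m_ind, 1, 2), 3 * 7 / (2 * T_len * log(2)) + 0.002)

  # deterministic copy: s_i(t+1) = s_j(t) -> 1 bit
  sj <- sample(c(-1L, 1L), T_len, TRUE)
  si <- c(1L, sj[-T_len])
  m_cp <- cbind(si, sj)
  expect_equal(transfer_entropy(m_cp, 1, 2), 1, tolerance = 0.01)

  # adding a constant second source changes nothing
  m3 <- cbind(m_cp, rep(1L, T_len))
  expect_equal(transfer_entropy(m3, 1, c(2, 3)),
               transfer_entropy(m_cp, 1, 2), tolerance = 1e-12)

  # joint TE dominates single-source TE on the same pooled distribution
  set.seed(22)
  mm <- matrix(sample(c(-1L, 1L), 3 * 5000, TRUE), 5000, 3)
  p16 <- estimate_lagged_joint(mm, 1, c(2, 3))
  T_joint <- te_from_joint(p16)
  T_j <- te_from_joint(apply(p16$p, c(1, 2, 3), sum))
  T_k <- te_from_joint(apply(p16$p, c(1, 2, 4), sum))
  expect_gte(T_joint, max(T_j, T_k) - 1e-12)
})

test_that("transfer entropy recovers the analytic value of a known chain", {
  J <- matrix(c(0, 1, 0, 1, 0, 0.5, 0, 0.5, 0), 3, 3)
  chain <- oracle_chain(J, beta = 0.6)
  te_true <- chain$te(1, 2)
  te_hat <- vapply(1:6, function(sd) {
    transfer_entropy(chain$simulate(30000, sd), 1, 2)
  }, numeric(1))
  expect_lt(abs(mean(te_hat) - te_true),
            3 * stats::sd(te_hat) / sqrt(length(te_hat)))
})

test_that("MMI decomposition solves the closure equations", {
  # hand-solved example
  r <- pid_mmi(0.9, 0.3, 0.5)
  expect_equal(r$R, 0.3)
  expect_equal(r$U_j, 0)
  expect_equal(r$U_k, 0.2)
  expect_equal(r$S, 0.4)

  # XOR mechanism: pure synergy
  set.seed(23)
  T_len <- 30000
  sj <- sample(c(-1L, 1L), T_len, TRUE); sk <- sample(c(-1L, 1L), T_len, TRUE)
  f <- -sj * sk
  m <- cbind(c(1L, f[-T_len]), sj, sk)
  pid <- pid_decompose(estimate_lagged_joint(m, 1, c(2, 3)))
  expect_equal(pid$S, 1, tolerance = 0.01)
  expect_lt(pid$R, 0.01)
  expect_lt(max(pid$U_j, pid$U_k), 0.01)

  # duplicated sources: pure redundancy
  m_dup <- cbind(c(1L, sj[-T_len]), sj, sj + 0L)
  # estimator forbids identical indices; duplicate the column physically
  m_dup2 <- m_dup; m_dup2[, 3] <- m_dup[, 2]
  pid_d <- pid_decompose(estimate_lagged_joint(m_dup2, 1, c(2, 3)))
  expect_equal(pid_d$R, pid_d$T_j, tolerance = 1e-10)
  expect_equal(pid_d$S, 0, tolerance = 1e-10)
  expect_equal(pid_d$U_j, 0, tolerance = 1e-10)

  expect_error(pid_mmi(0.1, 0.5, 0.4), "inconsistent")
})

test_that("decomposition closure and symmetry hold on random distributions", {
  set.seed(24)
  for (rep in 1:200) {
    p <- random_joint16()
    pid <- pid_decompose(p)
    expect_lt(abs(pid$T_joint - (pid$U_j + pid$U_k + pid$R + pid$S)), 1e-10)
    expect_lt(abs(pid$T_j - (pid$U_j + pid$R)), 1e-10)
    expect_lt(abs(pid$T_k - (pid$U_k + pid$R)), 1e-10)
    expect_true(all(c(pid$R, pid$U_j, pid$U_k, pid$S) >= -1e-10))
    # source exchange swaps the unique terms, preserves R and S
    psw <- aperm(p, c(1, 2, 4, 3))
    pid_sw <- pid_decompose(psw)
    expect_equal(pid_sw$U_j, pid$U_k, tolerance = 1e-12)
    expect_equal(pid_sw$U_k, pid$U_j, tolerance = 1e-12)
    expect_equal(pid_sw$R, pid$R, tolerance = 1e-12)
    expect_equal(pid_sw$S, pid$S, tolerance = 1e-12)
  }
})

test_that("constrained-minimization synergy solves canonical cases", {
  # product distribution: transfer entropy already 0, synergy 0
  p0 <- array(1 / 16, c(2, 2, 2, 2),
              dimnames = dimnames(random_joint16()))
  b0 <- pid_bertschinger(p0)
  expect_equal(b0$S, 0, tolerance = 1e-9)

  # XOR: the fixed pairwise marginals admit an independent q with zero TE
  px <- array(0, c(2, 2, 2, 2), dimnames = dimnames(p0))
  for (j in 1:2) for (k in 1:2) {
    f <- if (j == k) 1 else 2      # -1*-1 = +1 -> product coding: xor cell
    px[f, , j, k] <- 0.25 / 2
  }
  bx <- pid_bertschinger(px)
  expect_equal(bx$T_joint, 1, tolerance = 1e-9)
  expect_equal(bx$S, 1, tolerance = 1e-6)

  # the minimization never exceeds T(p), so S >= 0 always
  set.seed(25)
  for (rep in 1:20) {
    p <- random_joint16()
    b <- pid_bertschinger(p)
    expect_gte(b$S, -1e-9)
    expect_lte(b$S, b$T_joint + 1e-9)
    # closure equations still hold
    expect_lt(abs(b$T_joint - (b$U_j + b$U_k + b$R + b$S)), 1e-9)
  }
})

test_that("batch estimators are exactly the per-triplet estimators", {
  set.seed(26)
  m <- matrix(sample(c(-1L, 1L), 4000, TRUE), 400, 10)
  C <- connectivity_matrix(matrix(1, 10, 10) - diag(10))
  tr <- select_triplets(C, "dense", max_triplets = 60, seed = 1)
  batch <- triplet_pid_batch(m, tr)
  for (r in sample(nrow(tr), 10)) {
    p <- estimate_lagged_joint(m, tr$target[r], c(tr$s1[r], tr$s2[r]))
    pid <- pid_decompose(p)
    expect_equal(batch$T_joint[r], pid$T_joint, tolerance = 1e-12)
    expect_equal(batch$S[r], pid$S, tolerance = 1e-12)
  }
  pairs <- data.frame(target = tr$target[1:20], source = tr$s1[1:20])
  te_b <- pair_te_batch(m, pairs)
  for (r in sample(20, 6)) {
    expect_equal(te_b[r], transfer_entropy(m, pairs$target[r], pairs$source[r]),
                 tolerance = 1e-12)
  }
})
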