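# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: entropies are summed directly, shortest paths are
# enumerated exhaustively, and the 3-spin chain is solved by eigen-analysis.

# direct entropy of a probability vector/array (bits)
oracle_H <- function(q) {
  q <- as.vector(q)
  q <- q[q > 0]
  -sum(q * log2(q))
}

# brute-force all-pairs shortest paths and geodesic counts on a small
# weighted graph (edge length = 1/weight), by enumerating simple paths
oracle_centrality <- function(w) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  paths_between <- function(s, t) {
    # all simple paths s -> t as lists of node sequences
    out <- list()
    grow <- function(path) {
      last <- path[length(path)]
      if (last == t) {
        out[[length(out) + 1]] <<- path
        return(invisible())
      }
      for (nb in seq_len(n)) {
        if (is.finite(len[last, nb]) && !(nb %in% path)) grow(c(path, nb))
      }
    }
    grow(s)
    out
  }
  btw <- numeric(n)
  dist <- matrix(Inf, n, n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    ps <- paths_between(s, t)
    if (length(ps) == 0) next
    lens <- vapply(ps, function(p) {
      sum(len[cbind(p[-length(p)], p[-1])])
    }, numeric(1))
    dmin <- min(lens)
    dist[s, t] <- dist[t, s] <- dmin
    geo <- ps[abs(lens - dmin) < 1e-12]
    for (g in geo) {
      inner <- setdiff(g, c(s, t))
      for (v in inner) btw[v] <- btw[v] + 1 / length(geo)
    }
  }
  diag(dist) <- 0
  cls <- vapply(1:n, function(v) {
    d <- dist[v, -v]
    if (any(!is.finite(d))) return(NA_real_)
    (n - 1) / sum(d)
  }, numeric(1))
  list(betweenness = btw / ((n - 1) * (n - 2) / 2), closeness = cls)
}

# Synchronous logistic 3-spin chain: exact transition matrix, stationary
# distribution, analytic transfer entropies, and a simulator.
oracle_chain <- function(J, beta) {
  states <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  pup <- 1 / (1 + exp(-2 * beta * states %*% J))
  P <- matrix(0, 8, 8)
  for (a in 1:8) for (b in 1:8) {
    pr <- 1
    for (i in 1:3) pr <- pr * if (states[b, i] == 1) pup[a, i] else 1 - pup[a, i]
    P[a, b] <- pr
  }
  ev <- eigen(t(P))
  pi_s <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi_s <- pi_s / sum(pi_s)
  joint <- pi_s * P  # joint[a, b] = pi(a) P(a, b)
  te <- function(target, source) {
    tab <- array(0, c(2, 2, 2))
    for (a in 1:8) for (b in 1:8) {
      f <- (states[b, target] + 3) / 2
      si <- (states[a, target] + 3) / 2
      sj <- (states[a, source] + 3) / 2
      tab[f, si, sj] <- tab[f, si, sj] + joint[a, b]
    }
    oracle_H(apply(tab, c(1, 2), sum)) + oracle_H(apply(tab, c(2, 3), sum)) -
      oracle_H(tab) - oracle_H(apply(tab, 2, sum))
  }
  simulate <- function(T_len, seed) {
    set.seed(seed)
    m <- matrix(0L, T_len, 3)
    s <- c(1L, 1L, 1L)
    for (t in seq_len(T_len)) {
      idx <- 1L + (s[1] + 1L) %/% 2L + (s[2] + 1L) + 2L * (s[3] + 1L)
      s <- ifelse(stats::runif(3) < pup[idx, ], 1L, -1L)
      m[t, ] <- s
    }
    m
  }
  list(te = te, simulate = simulate, stationary = pi_s, P = P)
}

# random valid 16-cell lagged joint distribution
random_joint16 <- function() {
  p <- stats::rexp(16)
  p <- p / sum(p)
  array(p, dim = c(2, 2, 2, 2),
        dimnames = list(future = c("-1", "+1"), present = c("-1", "+1"),
                        src1 = c("-1", "+1"), src2 = c("-1", "+1")))
}

# small connectivity matrix from an explicit upper-triangular spec
cm_from_edges <- function(n, edges) {
  w <- matrix(0, n, n)
  for (e in edges) w[e[1], e[2]] <- w[e[2], e[1]] <- e[3]
  connectivity_matrix(w)
}
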