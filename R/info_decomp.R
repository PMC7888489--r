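#' Estimate the lagged joint distribution of target and sources
#'
#' Plugin (empirical frequency) estimate of the joint distribution of the
#' target's future state, the target's present state, and one or two source
#' spins' present states.  Counts every valid transition in the series;
#' a list of series (e.g. independent runs at the same temperature) is pooled
#' by summing counts, never by concatenating across run boundaries.
#'
#' @param series a `spin_series`, a T x N matrix of -1/+1, or a list of
#'   either (pooled).
#' @param target target node index.
#' @param sources one or two source node indices (excluding the target).
#' @param lag time lag in sweeps (default 1).
#' @return a `lagged_joint` object: `p` (probability array with dims
#'   `(future, present, src1[, src2])`, each of size 2 ordered as -1, +1),
#'   `counts`, `n` (sample count), `vars`.
#' @export
estimate_lagged_joint <- function(series, target, sources, lag = 1L) {
  sources <- as.integer(sources)
  target <- as.integer(target)
  if (length(sources) < 1 || length(sources) > 2) stop("need 1 or 2 sources")
  if (target %in% sources) stop("target must not be among the sources")
  if (anyDuplicated(sources)) stop("sources must be distinct")
  mats <- series_matrices(series)
  k <- length(sources)
  n_cells <- 2L^(2L + k)
  counts <- integer(n_cells)
  for (m in mats) {
    T_len <- nrow(m)
    if (T_len <= lag) stop("series too short for the requested lag")
    bt <- (m[, target] + 1L) %/% 2L  # 0/1 coding
    b1 <- (m[, sources[1]] + 1L) %/% 2L
    idx <- 1L + bt[(1 + lag):T_len] + 2L * bt[1:(T_len - lag)] +
      4L * b1[1:(T_len - lag)]
    if (k == 2L) {
      b2 <- (m[, sources[2]] + 1L) %/% 2L
      idx <- idx + 8L * b2[1:(T_len - lag)]
    }
    counts <- counts + tabulate(idx, nbins = n_cells)
  }
  n <- sum(counts)
  dims <- rep(2L, 2L + k)
  lev <- c("-1", "+1")
  dn <- c(list(future = lev, present = lev),
          stats::setNames(rep(list(lev), k), paste0("src", seq_len(k))))
  p <- array(counts / n, dim = dims, dimnames = dn)
  structure(list(p = p, counts = array(counts, dim = dims, dimnames = dn),
                 n = n, target = target, sources = sources, lag = lag),
            class = "lagged_joint")
}

series_matrices <- function(series) {
  if (inherits(series, "spin_series")) return(list(series$samples))
  if (is.matrix(series)) return(list(series))
  if (is.list(series)) {
    return(unlist(lapply(series, series_matrices), recursive = FALSE))
  }
  stop("series must be a spin_series, a matrix, or a list of them")
}

#' @export
print.lagged_joint <- function(x, ...) {
  cat("<lagged_joint> target ", x$target, " <- sources {",
      paste(x$sources, collapse = ", "), "}, ", length(x$p),
      " cells, n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Conditional mutual information of a probability array
#'
#' `I(X; Y | Z)` in bits over a joint probability array, with `X`, `Y`, `Z`
#' declared as dimension indices (or dimension names) of the array.  Cells
#' with zero probability contribute zero (`0 log 0 = 0`), as do conditional
#' terms whose conditioning event has zero mass.
#'
#' @param p probability array (sums to 1) or a `lagged_joint`.
#' @param x,y dimension indices/names of the two variable groups.
#' @param z dimension indices/names of the conditioning group; may be empty
#'   (plain mutual information).
#' @return nonnegative scalar, bits.
#' @export
conditional_mutual_information <- function(p, x, y, z = integer(0)) {
  if (inherits(p, "lagged_joint")) p <- p$p
  dn <- names(dimnames(p))
  resolve <- function(d) {
    if (is.character(d)) {
      i <- match(d, dn)
      if (anyNA(i)) stop("unknown variable name: ", paste(d[is.na(i)], collapse = ", "))
      i
    } else as.integer(d)
  }
  x <- resolve(x); y <- resolve(y); z <- resolve(z)
  all_d <- c(x, y, z)
  if (anyDuplicated(all_d) || any(all_d < 1) || any(all_d > length(dim(p)))) {
    stop("malformed variable declaration")
  }
  # marginalize out dimensions not involved
  keep <- sort(all_d)
  if (length(keep) < length(dim(p))) {
    p <- apply(p, keep, sum)
    remap <- function(d) match(d, keep)
    x <- remap(x); y <- remap(y); z <- remap(z)
  }
  p_xz <- apply(p, c(x, z), sum)
  p_yz <- apply(p, c(y, z), sum)
  p_z <- if (length(z)) apply(p, z, sum) else 1
  # entropy helper: -sum q log2 q with 0 log 0 = 0
  H <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  H(p_xz) + H(p_yz) - H(p) - H(p_z)
}

#' Transfer entropy from source spin(s) to a target spin
#'
#' `TE = I(future_target ; sources | present_target)` in bits, computed from
#' the plugin lagged joint distribution.  With two sources this is the joint
#' (trivariate) transfer entropy, which on a common estimated distribution is
#' never below either single-source transfer entropy.
#'
#' @param series as in [estimate_lagged_joint()].
#' @param target target node index.
#' @param sources one or two source node indices.
#' @param lag time lag (default 1).
#' @return scalar transfer entropy in bits.
#' @export
transfer_entropy <- function(series, target, sources, lag = 1L) {
  p <- estimate_lagged_joint(series, target, sources, lag)
  te_from_joint(p)
}

#' Transfer entropy implied by a lagged joint distribution
#'
#' @param p a `lagged_joint` or probability array with dims
#'   `(future, present, sources...)`.
#' @return scalar bits.
#' @export
te_from_joint <- function(p) {
  arr <- if (inherits(p, "lagged_joint")) p$p else p
  nd <- length(dim(arr))
  conditional_mutual_information(arr, x = 1L, y = seq(3L, nd), z = 2L)
}

#' Minimum-mutual-information partial information decomposition
#'
#' Closes the decomposition `T_joint = U_j + U_k + R + S`,
#' `T_j = U_j + R`, `T_k = U_k + R` by identifying the redundancy with the
#' minimum single-source transfer entropy: `R = min(T_j, T_k)`.  The synergy
#' follows as `S = T_joint - max(T_j, T_k)`, nonnegative whenever all three
#' transfer entropies come from one pooled distribution.
#'
#' @param T_joint joint (two-source) transfer entropy, bits.
#' @param T_j,T_k single-source transfer entropies, bits.
#' @param tol consistency tolerance for `T_joint >= max(T_j, T_k)`.
#' @return a `pid_result` list with `T_joint`, `T_j`, `T_k`, `U_j`, `U_k`,
#'   `R`, `S`, `method = "MMI"`.
#' @export
pid_mmi <- function(T_joint, T_j, T_k, tol = 1e-8) {
  if (any(!is.finite(c(T_joint, T_j, T_k)))) stop("inputs must be finite")
  if (T_joint < max(T_j, T_k) - tol) {
    stop("inconsistent inputs: T_joint < max(T_j, T_k) beyond tolerance; ",
         "all three must come from one pooled distribution")
  }
  R <- min(T_j, T_k)
  structure(list(T_joint = T_joint, T_j = T_j, T_k = T_k,
                 U_j = T_j - R, U_k = T_k - R, R = R,
                 S = T_joint - T_j - T_k + R, method = "MMI"),
            class = "pid_result")
}

#' @export
print.pid_result <- function(x, ...) {
  cat("<pid_result> method = ", x$method, "\n", sep = "")
  v <- unlist(x[c("T_joint", "T_j", "T_k", "U_j", "U_k", "R", "S")])
  print(round(v, 6))
  invisible(x)
}

#' Full PID of a two-source lagged joint distribution
#'
#' Computes the joint and the two single-source transfer entropies from one
#' 16-cell distribution (single-source terms by marginalizing out the other
#' source), then applies the chosen decomposition.
#'
#' @param p a `lagged_joint` over two sources (16 cells).
#' @param method `"mmi"` (default) or `"bertschinger"`.
#' @return a `pid_result`.
#' @export
pid_decompose <- function(p, method = c("mmi", "bertschinger")) {
  method <- match.arg(method)
  arr <- if (inherits(p, "lagged_joint")) p$p else p
  if (length(dim(arr)) != 4L) stop("need a two-source (16-cell) distribution")
  T_joint <- te_from_joint(arr)
  T_j <- te_from_joint(apply(arr, c(1, 2, 3), sum))
  T_k <- te_from_joint(apply(arr, c(1, 2, 4), sum))
  if (method == "mmi") {
    pid_mmi(T_joint, T_j, T_k)
  } else {
    pid_bertschinger(arr, T_joint = T_joint, T_j = T_j, T_k = T_k)
  }
}

#' Constrained-optimization (Bertschinger-style) synergy
#'
#' Defines the synergy as `S = T(p) - min_q T(q)` where `q` ranges over all
#' distributions with the same target-source marginals as `p`: in the lagged
#' setting, the trivariate marginals `(future, present, src1)` and
#' `(future, present, src2)` are held fixed.  Under these constraints each of
#' the four `(future, present)` blocks of the 16-cell table is a 2x2 table
#' with fixed row and column sums, leaving at most 4 free coordinates; the
#' transfer entropy is minimized over this box by bounded quasi-Newton from
#' deterministic multi-starts (block corners, midpoint, and the blockwise
#' independence point).  The remaining decomposition terms follow from the
#' closure equations: `R = T_j + T_k - T_joint + S`, `U = T - R`.
#'
#' @param p a `lagged_joint` over two sources, or its 16-cell array.
#' @param T_joint,T_j,T_k optionally precomputed transfer entropies.
#' @param tol optimizer convergence tolerance on the objective.
#' @return a `pid_result` with `method = "Bertschinger"` and attribute
#'   `"converged"`.
#' @export
pid_bertschinger <- function(p, T_joint = NULL, T_j = NULL, T_k = NULL,
                             tol = 1e-9) {
  arr <- if (inherits(p, "lagged_joint")) p$p else p
  if (length(dim(arr)) != 4L) stop("need a two-source (16-cell) distribution")
  if (is.null(T_joint)) T_joint <- te_from_joint(arr)
  if (is.null(T_j)) T_j <- te_from_joint(apply(arr, c(1, 2, 3), sum))
  if (is.null(T_k)) T_k <- te_from_joint(apply(arr, c(1, 2, 4), sum))

  # Per (future, present) block: rows = src1, cols = src2.
  blocks <- vector("list", 4L)
  ib <- 0L
  for (f in 1:2) for (s in 1:2) {
    ib <- ib + 1L
    blocks[[ib]] <- list(f = f, s = s,
                         r1 = sum(arr[f, s, 1, ]),   # q(src1 = -1) within block
                         c1 = sum(arr[f, s, , 1]),   # q(src2 = -1) within block
                         tot = sum(arr[f, s, , ]))
  }
  lo <- vapply(blocks, function(b) max(0, b$r1 + b$c1 - b$tot), numeric(1))
  hi <- vapply(blocks, function(b) min(b$r1, b$c1), numeric(1))
  free <- which(hi - lo > 1e-12)

  build_q <- function(theta_free) {
    theta <- (lo + hi) / 2
    theta[free] <- theta_free
    q <- arr
    for (ib in seq_len(4L)) {
      b <- blocks[[ib]]
      t11 <- min(max(theta[ib], lo[ib]), hi[ib])
      q[b$f, b$s, 1, 1] <- t11
      q[b$f, b$s, 1, 2] <- b$r1 - t11
      q[b$f, b$s, 2, 1] <- b$c1 - t11
      q[b$f, b$s, 2, 2] <- b$tot - b$r1 - b$c1 + t11
    }
    q
  }
  objective <- function(theta_free) te_from_joint(build_q(theta_free))

  if (length(free) == 0L) {
    S <- T_joint - T_joint  # marginals pin q = p entirely
    q_min <- T_joint
    converged <- TRUE
  } else {
    starts <- list(arr_start = vapply(free, function(i) {
      blocks[[i]]$r1 * blocks[[i]]$c1 /
        max(blocks[[i]]$tot, .Machine$double.eps)  # blockwise independence
    }, numeric(1)),
    mid = (lo[free] + hi[free]) / 2,
    p_itself = vapply(free, function(i) arr[blocks[[i]]$f, blocks[[i]]$s, 1, 1],
                      numeric(1)))
    # deterministic corner starts (capped at 8)
    n_corner <- min(2^length(free), 8L)
    for (ci in seq_len(n_corner)) {
      bits <- as.integer(intToBits(ci - 1L))[seq_along(free)]
      starts[[length(starts) + 1L]] <- ifelse(bits == 1L, hi[free], lo[free])
    }
    vals <- rep(NA_real_, length(starts))
    any_flag0 <- FALSE
    for (si in seq_along(starts)) {
      st <- pmin(pmax(starts[[si]], lo[free]), hi[free])
      fit <- tryCatch(
        stats::optim(st, objective, method = "L-BFGS-B",
                     lower = lo[free], upper = hi[free],
                     control = list(factr = tol / .Machine$double.eps,
                                    maxit = 500)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        vals[si] <- fit$value
        if (fit$convergence == 0L) any_flag0 <- TRUE
      }
    }
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0L) stop("Bertschinger optimizer failed on all starts")
    best <- min(vals)
    # converged if the optimizer says so from any start, or if independent
    # starts agree on the minimum (the practical criterion for a convex box
    # problem where the line search can terminate with a nonzero flag)
    converged <- any_flag0 ||
      (length(vals) >= 2 && sort(vals)[2] - best < 100 * tol)
    if (!converged) {
      warning("Bertschinger optimizer did not report convergence; ",
              "returning best bound found")
    }
    q_min <- best
    S <- T_joint - q_min
  }
  S <- max(S, 0)
  R <- T_j + T_k - T_joint + S
  out <- structure(list(T_joint = T_joint, T_j = T_j, T_k = T_k,
                        U_j = T_j - R, U_k = T_k - R, R = R, S = S,
                        method = "Bertschinger"),
                   class = "pid_result")
  attr(out, "converged") <- converged
  attr(out, "min_te") <- q_min
  out
}

# Shared-cell entropy helper for the vectorized batch paths: given a 16 x K
# (or 8 x K) probability matrix and a cell-grouping vector, the entropy of the
# grouped marginal for every column.
group_entropy <- function(p, groups) {
  q <- rowsum(p, groups)
  ql <- q
  ql[q > 0] <- q[q > 0] * log2(q[q > 0])
  ql[q <= 0] <- 0
  -colSums(ql)
}

#' Batch MMI decomposition of many triplets
#'
#' Vectorized plugin estimation and MMI decomposition for a table of
#' triplets on one series (or list of pooled series).  Exactly equivalent to
#' calling [estimate_lagged_joint()] and [pid_decompose()] per triplet with
#' `method = "mmi"`, but orders of magnitude faster for the thousands of
#' triplets of a full profile.
#'
#' @param series series as in [estimate_lagged_joint()].
#' @param triplets data.frame with columns `target`, `s1`, `s2`.
#' @param lag time lag.
#' @return data.frame with one row per triplet: `target`, `s1`, `s2`,
#'   `T_joint`, `T_j`, `T_k`, `U_j`, `U_k`, `R`, `S`.
#' @export
triplet_pid_batch <- function(series, triplets, lag = 1L) {
  mats <- series_matrices(series)
  tm <- as.matrix(triplets[, c("target", "s1", "s2")])
  storage.mode(tm) <- "integer"
  counts <- matrix(0L, 16L, nrow(tm))
  for (m in mats) counts <- counts + count_triplets_cpp(m, tm, as.integer(lag))
  p <- counts / rep(colSums(counts), each = 16L)
  cells <- 0:15
  bf <- cells %% 2L
  bsi <- (cells %/% 2L) %% 2L
  bs1 <- (cells %/% 4L) %% 2L
  bs2 <- cells %/% 8L
  H_all <- group_entropy(p, cells)
  H_fsi <- group_entropy(p, bf + 2L * bsi)
  H_si <- group_entropy(p, bsi)
  H_si12 <- group_entropy(p, bsi + 2L * bs1 + 4L * bs2)
  H_fsi1 <- group_entropy(p, bf + 2L * bsi + 4L * bs1)
  H_fsi2 <- group_entropy(p, bf + 2L * bsi + 4L * bs2)
  H_si1 <- group_entropy(p, bsi + 2L * bs1)
  H_si2 <- group_entropy(p, bsi + 2L * bs2)
  T_joint <- H_fsi + H_si12 - H_all - H_si
  T_j <- H_fsi + H_si1 - H_fsi1 - H_si
  T_k <- H_fsi + H_si2 - H_fsi2 - H_si
  R <- pmin(T_j, T_k)
  data.frame(target = tm[, 1], s1 = tm[, 2], s2 = tm[, 3],
             T_joint = T_joint, T_j = T_j, T_k = T_k,
             U_j = T_j - R, U_k = T_k - R, R = R,
             S = T_joint - T_j - T_k + R)
}

#' Batch pairwise transfer entropy
#'
#' Vectorized plugin transfer entropy for a table of (target, source) pairs,
#' equivalent to [transfer_entropy()] per pair.
#'
#' @param series series as in [estimate_lagged_joint()].
#' @param pairs data.frame or 2-column matrix: target, source.
#' @param lag time lag.
#' @return numeric vector of transfer entropies (bits), one per pair.
#' @export
pair_te_batch <- function(series, pairs, lag = 1L) {
  mats <- series_matrices(series)
  pm <- as.matrix(pairs)[, 1:2, drop = FALSE]
  storage.mode(pm) <- "integer"
  counts <- matrix(0L, 8L, nrow(pm))
  for (m in mats) counts <- counts + count_pairs_cpp(m, pm, as.integer(lag))
  p <- counts / rep(colSums(counts), each = 8L)
  cells <- 0:7
  bf <- cells %% 2L
  bsi <- (cells %/% 2L) %% 2L
  bs <- cells %/% 4L
  group_entropy(p, bf + 2L * bsi) + group_entropy(p, bsi + 2L * bs) -
    group_entropy(p, cells) - group_entropy(p, bsi)
}

#' PID results as a data.frame row
#'
#' @param pid a `pid_result`.
#' @param ... extra columns (e.g. target, sources, beta).
#' @return one-row data.frame.
#' @export
pid_as_row <- function(pid, ...) {
  data.frame(..., T_joint = pid$T_joint, T_j = pid$T_j, T_k = pid$T_k,
             U_j = pid$U_j, U_k = pid$U_k, R = pid$R, S = pid$S,
             method = pid$method, stringsAsFactors = FALSE)
}
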