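#' Select triplets (target, source pair) for information decomposition
#'
#' Dense mode enumerates all `N * choose(N-1, 2)` triplets, appropriate for
#' dense group-average connectomes (optionally subsampled uniformly to
#' `max_triplets`, which leaves per-node mean synergy unbiased).  Sparse mode
#' keeps only triplets whose two source-to-target links both survive
#' [density_threshold()] at `target_density`, the selection rule for sparse
#' individual connectomes where most pairs carry no streamlines.
#'
#' @param C a `connectivity_matrix`.
#' @param mode `"dense"`, `"sparse"`, or `"top_k"` (per-target strongest
#'   in-edges: every target gets the pairs of its `k_sources` heaviest
#'   sources, so no node is left without triplets on sparse matrices).
#' @param target_density link density retained in sparse mode (default 0.2).
#' @param max_triplets optional cap; triplets are subsampled uniformly.
#' @param seed RNG seed used only when subsampling.
#' @param k_sources number of sources per target in `top_k` mode.
#' @return data.frame with integer columns `target`, `s1`, `s2` (`s1 < s2`).
#' @export
select_triplets <- function(C, mode = c("dense", "sparse", "top_k"),
                            target_density = 0.2, max_triplets = NULL,
                            seed = 1L, k_sources = 6L) {
  mode <- match.arg(mode)
  n <- n_nodes(C)
  if (n < 3) stop("need at least 3 nodes")
  if (mode == "top_k") {
    k <- min(k_sources, n - 1L)
    if (k < 2) stop("k_sources must be >= 2")
    out <- do.call(rbind, lapply(seq_len(n), function(i) {
      src <- order(C$weights[, i], decreasing = TRUE)
      src <- setdiff(src, i)[seq_len(k)]
      pr <- t(utils::combn(sort(src), 2L))
      data.frame(target = i, s1 = pr[, 1], s2 = pr[, 2])
    }))
  } else if (mode == "dense") {
    pairs <- t(utils::combn(n, 2L))
    out <- do.call(rbind, lapply(seq_len(n), function(i) {
      keep <- pairs[, 1] != i & pairs[, 2] != i
      data.frame(target = i, s1 = pairs[keep, 1], s2 = pairs[keep, 2])
    }))
  } else {
    mask <- density_threshold(C, target_density)$mask
    rows <- lapply(seq_len(n), function(i) {
      src <- which(mask[, i])
      src <- setdiff(src, i)
      if (length(src) < 2) return(NULL)
      pr <- t(utils::combn(src, 2L))
      data.frame(target = i, s1 = pr[, 1], s2 = pr[, 2])
    })
    out <- do.call(rbind, rows)
    if (is.null(out) || nrow(out) == 0L) {
      stop("no qualifying triplet at this density (degenerate matrix)")
    }
  }
  rownames(out) <- NULL
  if (!is.null(max_triplets) && nrow(out) > max_triplets) {
    set.seed(seed)
    out <- out[sort(sample.int(nrow(out), max_triplets)), ]
    rownames(out) <- NULL
  }
  out
}

#' Per-node incoming synergy profile
#'
#' For every selected triplet the two-source transfer entropy into the target
#' is decomposed, and per node the synergy `S` is averaged over all triplets
#' having that node as the target.  Nodes targeted by no triplet get `NaN`
#' (not zero), so cohort averages are never silently diluted.
#'
#' @param series series at one temperature (see [estimate_lagged_joint()]).
#' @param triplets data.frame from [select_triplets()].
#' @param n_nodes total number of nodes.
#' @param method PID method, `"mmi"` (default) or `"bertschinger"`.
#' @param lag time lag.
#' @return data.frame with columns `node`, `incoming_synergy`, `n_triplets`.
#' @export
node_incoming_synergy <- function(series, triplets, n_nodes,
                                  method = "mmi", lag = 1L) {
  if (nrow(triplets) == 0L) stop("triplets must be nonempty")
  if (method == "mmi") {
    syn <- triplet_pid_batch(series, triplets, lag)$S
  } else {
    syn <- vapply(seq_len(nrow(triplets)), function(r) {
      p <- estimate_lagged_joint(series, triplets$target[r],
                                 c(triplets$s1[r], triplets$s2[r]), lag)
      pid_decompose(p, method = method)$S
    }, numeric(1))
  }
  agg_mean <- tapply(syn, triplets$target, mean)
  agg_n <- tapply(syn, triplets$target, length)
  out <- data.frame(node = seq_len(n_nodes),
                    incoming_synergy = NaN, n_triplets = 0L)
  idx <- as.integer(names(agg_mean))
  out$incoming_synergy[idx] <- as.numeric(agg_mean)
  out$n_triplets[idx] <- as.integer(agg_n)
  out
}

#' Per-node incoming and outgoing transfer entropy
#'
#' Pairwise plugin transfer entropy over all ordered node pairs:
#' `outgoing_TE[i]` is the mean TE from node `i` into every other node
#' (typical outgoing TE), `incoming_TE[i]` the mean TE from every other node
#' into `i`.
#'
#' @param series series at one temperature.
#' @param n_nodes number of nodes.
#' @param lag time lag.
#' @return data.frame with columns `node`, `incoming_TE`, `outgoing_TE`.
#' @export
node_te_profile <- function(series, n_nodes, lag = 1L) {
  grid <- expand.grid(target = seq_len(n_nodes), source = seq_len(n_nodes))
  grid <- grid[grid$target != grid$source, ]
  te_vals <- pair_te_batch(series, grid[, c("target", "source")], lag)
  te <- matrix(0, n_nodes, n_nodes)  # te[d, t]: driver d -> target t
  te[cbind(grid$source, grid$target)] <- te_vals
  data.frame(node = seq_len(n_nodes),
             incoming_TE = colSums(te) / (n_nodes - 1L),
             outgoing_TE = rowSums(te) / (n_nodes - 1L))
}

#' Hub incoming-synergy curves across the temperature sweep
#'
#' For each of the `n_hubs` highest-strength nodes, the mean incoming synergy
#' (over a seeded sample of source pairs) is traced along the beta grid of an
#' [temperature_sweep()] result.  On heterogeneous connectomes the hub curves
#' peak below the susceptibility-peak beta: hub synergy is a precursor of the
#' critical transition.
#'
#' @param sweep an `ising_sweep` with kept series.
#' @param C the `connectivity_matrix` the sweep was run on.
#' @param n_hubs number of top-strength nodes to trace (default 5).
#' @param pairs_per_hub cap on source pairs per hub (seeded uniform sample
#'   over all pairs of other nodes).
#' @param seed RNG seed for the pair sample.
#' @param method PID method.
#' @return a `hub_synergy` object: `betas`, `hubs` (node indices),
#'   `curves` (n_hubs x n_beta matrix of mean synergy), `peak_beta` (per
#'   hub), `critical_beta`.
#' @export
hub_synergy_curves <- function(sweep, C, n_hubs = 5, pairs_per_hub = 30,
                               seed = 1L, method = "mmi") {
  if (is.null(sweep$series)) stop("sweep was run with keep_series = FALSE")
  if (length(sweep$betas) < 3) stop("need at least 3 beta points")
  n <- n_nodes(C)
  hubs <- order(node_strength(C), decreasing = TRUE)[seq_len(min(n_hubs, n))]
  set.seed(seed)
  hub_triplets <- lapply(hubs, function(h) {
    others <- setdiff(seq_len(n), h)
    pr <- t(utils::combn(others, 2L))
    if (nrow(pr) > pairs_per_hub) pr <- pr[sample.int(nrow(pr), pairs_per_hub), , drop = FALSE]
    data.frame(target = h, s1 = pr[, 1], s2 = pr[, 2])
  })
  curves <- matrix(NA_real_, length(hubs), length(sweep$betas))
  for (ib in seq_along(sweep$betas)) {
    ser <- sweep$series[[ib]]
    for (hi in seq_along(hubs)) {
      tr <- hub_triplets[[hi]]
      if (method == "mmi") {
        s_vals <- triplet_pid_batch(ser, tr)$S
      } else {
        s_vals <- vapply(seq_len(nrow(tr)), function(r) {
          p <- estimate_lagged_joint(ser, tr$target[r], c(tr$s1[r], tr$s2[r]))
          pid_decompose(p, method = method)$S
        }, numeric(1))
      }
      curves[hi, ib] <- mean(s_vals)
    }
  }
  peak_idx <- apply(curves, 1, which.max)
  if (any(peak_idx == 1L | peak_idx == length(sweep$betas))) {
    warning("some hub synergy curves peak at a grid endpoint")
  }
  structure(list(betas = sweep$betas, hubs = hubs, curves = curves,
                 peak_beta = sweep$betas[peak_idx],
                 critical_beta = sweep$critical_beta),
            class = "hub_synergy")
}

#' @export
print.hub_synergy <- function(x, ...) {
  cat("<hub_synergy> ", length(x$hubs), " hubs, critical beta ",
      format(x$critical_beta, digits = 4), "\n", sep = "")
  print(data.frame(hub = x$hubs, peak_beta = x$peak_beta))
  invisible(x)
}

#' @export
plot.hub_synergy <- function(x, ...) {
  graphics::matplot(x$betas, t(x$curves), type = "b", pch = 1,
                    xlab = expression(beta), ylab = "incoming synergy (bits)",
                    main = "Hub synergy across temperature", ...)
  graphics::abline(v = x$critical_beta, lty = 2)
  invisible(x)
}

#' Rank association of node synergy with topology
#'
#' Spearman correlations of the per-node incoming synergy with strength,
#' betweenness and closeness, over nodes with a defined synergy.
#'
#' @param profile data.frame with `node` and `incoming_synergy`.
#' @param topo data.frame from [centrality_metrics()].
#' @return data.frame with columns `metric`, `rho`, `n`.
#' @export
synergy_topology_association <- function(profile, topo) {
  m <- merge(profile, topo, by = "node")
  ok <- is.finite(m$incoming_synergy)
  if (sum(ok) < 5) stop("need at least 5 nodes with defined synergy")
  m <- m[ok, ]
  mets <- c("strength", "betweenness", "closeness")
  data.frame(metric = mets,
             rho = vapply(mets, function(v) {
               stats::cor(m$incoming_synergy, m[[v]], method = "spearman")
             }, numeric(1)),
             n = sum(ok), row.names = NULL, stringsAsFactors = FALSE)
}

#' Stability of the synergy profile across threshold choices
#'
#' Recomputes the per-node incoming synergy at several sparse-mode link
#' densities and reports the Spearman rank correlation of each profile with
#' the reference density's profile, a robustness check on the arbitrary
#' threshold.
#'
#' @param series series at one temperature.
#' @param C the `connectivity_matrix`.
#' @param densities densities to compare (first is the reference).
#' @param max_triplets cap per density.
#' @param seed seed.
#' @param method PID method.
#' @return data.frame with `density` and `rank_correlation` (reference row
#'   has correlation 1).
#' @export
synergy_threshold_stability <- function(series, C,
                                        densities = c(0.20, 0.15, 0.25),
                                        max_triplets = 5000, seed = 1L,
                                        method = "mmi") {
  n <- n_nodes(C)
  profs <- lapply(densities, function(d) {
    tr <- select_triplets(C, "sparse", target_density = d,
                          max_triplets = max_triplets, seed = seed)
    node_incoming_synergy(series, tr, n, method = method)$incoming_synergy
  })
  ref <- profs[[1]]
  rho <- vapply(profs, function(p) {
    ok <- is.finite(ref) & is.finite(p)
    stats::cor(ref[ok], p[ok], method = "spearman")
  }, numeric(1))
  data.frame(density = densities, rank_correlation = rho)
}
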