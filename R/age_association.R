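#' Projection-based bivariate outlier detection
#'
#' Flags points of a bivariate cloud that are outlying along any projection
#' through the spatial median: for each data point, all points are projected
#' onto the direction from the spatial median to that point, and a point is
#' flagged if its projected value violates the MAD-median rule
#' (`|x - median| / (MAD/0.6745) > sqrt(chi^2_{0.975, 2})`) on any of these
#' directions.  This is the "skipped" step of the skipped correlation and is
#' fully deterministic.
#'
#' @param x,y numeric vectors of equal length (n >= 10).
#' @return logical mask, TRUE for outliers.  Warns if more than 25% of
#'   points are flagged.
#' @export
detect_bivariate_outliers <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 10) stop("need at least 10 points")
  if (anyNA(x) || anyNA(y)) stop("x and y must be complete")
  cutoff <- sqrt(stats::qchisq(0.975, df = 2))
  flag <- as.logical(project_outliers_cpp(x, y, cutoff))
  if (mean(flag) > 0.25) {
    warning("more than 25% of points flagged as bivariate outliers")
  }
  flag
}

# Weiszfeld iteration for the spatial (geometric) median of a point cloud.
spatial_median <- function(z, tol = 1e-10, max_iter = 200) {
  ctr <- colMeans(z)
  for (it in seq_len(max_iter)) {
    d <- sqrt(rowSums(sweep(z, 2, ctr)^2))
    if (any(d < tol)) d[d < tol] <- tol
    w <- 1 / d
    new_ctr <- colSums(z * w) / sum(w)
    if (sqrt(sum((new_ctr - ctr)^2)) < tol) return(new_ctr)
    ctr <- new_ctr
  }
  ctr
}

#' Skipped Spearman correlation
#'
#' Spearman's rank correlation computed on the points surviving
#' [detect_bivariate_outliers()], with a two-sided p value from a seeded
#' full-procedure percentile bootstrap: each bootstrap resample re-runs the
#' outlier detection before correlating, so the selection step's variability
#' is reflected in the null calibration; the p value is twice the smaller
#' tail probability of the bootstrap distribution around zero.  On
#' contamination-free data the outlier mask is empty and the coefficient
#' equals the ordinary Spearman correlation.
#'
#' @param x,y numeric vectors (n >= 10).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return list with `rho`, `p_raw`, `n_used` (points retained), `outliers`
#'   (logical mask) and `degenerate` (TRUE when a variable has zero variance,
#'   in which case `rho = 0`, `p_raw = 1`).
#' @export
skipped_spearman <- function(x, y, n_boot = 1000, seed = 1L) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 10) stop("need at least 10 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = 0, p_raw = 1, n_used = n,
                outliers = rep(FALSE, n), degenerate = TRUE))
  }
  cutoff <- sqrt(stats::qchisq(0.975, df = 2))
  set.seed(seed)
  res <- skipped_spearman_cpp(x, y, as.integer(n_boot), cutoff)
  mask <- as.logical(res$mask)
  if (res$n_used < 5) stop("fewer than 5 points survive outlier removal")
  if (!is.finite(res$rho)) {
    return(list(rho = 0, p_raw = 1, n_used = res$n_used,
                outliers = mask, degenerate = TRUE))
  }
  if (res$n_boot_ok == 0) stop("all bootstrap replicates degenerate")
  p_lo <- (res$n_lo + 0.5 * res$n_zero) / res$n_boot_ok
  p_raw <- 2 * min(p_lo, 1 - p_lo)
  p_raw <- min(max(p_raw, 1 / res$n_boot_ok), 1)
  list(rho = res$rho, p_raw = p_raw, n_used = res$n_used, outliers = mask,
       degenerate = FALSE)
}

#' Hochberg step-up family-wise error adjustment
#'
#' Step-up adjusted p values (`stats::p.adjust(method = "hochberg")`): the
#' i-th largest raw p is multiplied by its step factor and running minima are
#' taken from the top, capped at 1.  Rejections at level `alpha` are a
#' superset of Bonferroni rejections.
#'
#' @param p_values raw p values in \[0, 1\].
#' @param alpha family-wise error level (default 0.05).
#' @return list with `p_adjusted` and logical `reject`.
#' @export
hochberg_adjust <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p values must be in [0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "hochberg")
  list(p_adjusted = adj, reject = !is.na(adj) & adj <= alpha)
}

#' Per-node association of incoming synergy with age
#'
#' Applies [skipped_spearman()] to every node's synergy column against age
#' and controls the family-wise error rate across nodes with
#' [hochberg_adjust()].  Degenerate (zero-variance) columns report `rho = 0`,
#' `p = 1` with a flag instead of erroring, so one bad node cannot abort a
#' cohort analysis.
#'
#' @param synergy subjects x nodes matrix of incoming synergy (bits), each
#'   row computed at that subject's own critical beta.
#' @param ages numeric vector of subject ages (years).
#' @param alpha family-wise error level.
#' @param n_boot bootstrap replicates per node.
#' @param seed master seed; node `j` uses `seed + j`.
#' @param labels optional node labels.
#' @return an `age_correlation` object: data.frame with columns `node`,
#'   `label`, `rho`, `p_raw`, `p_hochberg`, `significant`, `sign`, `n_used`,
#'   `degenerate`, sorted by adjusted p.
#' @export
run_age_analysis <- function(synergy, ages, alpha = 0.05, n_boot = 1000,
                             seed = 1L, labels = NULL) {
  synergy <- as.matrix(synergy)
  if (nrow(synergy) != length(ages)) stop("one synergy row per subject required")
  if (nrow(synergy) < 10) stop("need at least 10 subjects")
  n_node <- ncol(synergy)
  if (is.null(labels)) labels <- sprintf("node_%03d", seq_len(n_node) - 1L)
  res <- lapply(seq_len(n_node), function(j) {
    col <- synergy[, j]
    ok <- is.finite(col) & is.finite(ages)
    if (sum(ok) < 10 || stats::sd(col[ok]) == 0) {
      return(list(rho = 0, p_raw = 1, n_used = sum(ok), degenerate = TRUE))
    }
    skipped_spearman(col[ok], ages[ok], n_boot = n_boot, seed = seed + j)
  })
  df <- data.frame(node = seq_len(n_node), label = labels,
                   rho = vapply(res, `[[`, numeric(1), "rho"),
                   p_raw = vapply(res, `[[`, numeric(1), "p_raw"),
                   n_used = vapply(res, `[[`, numeric(1), "n_used"),
                   degenerate = vapply(res, `[[`, logical(1), "degenerate"),
                   stringsAsFactors = FALSE)
  hb <- hochberg_adjust(df$p_raw, alpha)
  df$p_hochberg <- hb$p_adjusted
  df$significant <- hb$reject
  df$sign <- ifelse(df$degenerate | df$rho == 0, "0",
                    ifelse(df$rho > 0, "+", "-"))
  df <- df[order(df$p_hochberg, df$p_raw), c("node", "label", "rho", "p_raw",
                                             "p_hochberg", "significant",
                                             "sign", "n_used", "degenerate")]
  rownames(df) <- NULL
  structure(df, class = c("age_correlation", "data.frame"),
            alpha = alpha, n_subjects = nrow(synergy))
}

#' @export
print.age_correlation <- function(x, ...) {
  alpha <- attr(x, "alpha")
  cat("Per-node synergy-age association (skipped Spearman, Hochberg FWER, alpha = ",
      alpha, ")\n", sep = "")
  cat(attr(x, "n_subjects"), "subjects,", nrow(x), "nodes,",
      sum(x$significant), "significant\n\n")
  print.data.frame(utils::head(as.data.frame(x), 15), digits = 3, row.names = FALSE)
  if (nrow(x) > 15) cat("... (", nrow(x) - 15, " more rows)\n", sep = "")
  invisible(x)
}

#' Strength-vs-age follow-up for selected nodes
#'
#' Applies the same robust machinery (skipped Spearman + Hochberg) to the
#' structural strength of the given nodes across subjects, to check whether a
#' synergy-age association is explained by a simple strength-age trend.
#'
#' @param matrices list of `connectivity_matrix`, one per subject.
#' @param ages subject ages.
#' @param nodes node indices to test; default all.
#' @param alpha,n_boot,seed as in [run_age_analysis()].
#' @return an `age_correlation` object over the selected nodes.
#' @export
strength_age_followup <- function(matrices, ages, nodes = NULL, alpha = 0.05,
                                  n_boot = 1000, seed = 1L) {
  strengths <- t(vapply(matrices, function(M) unname(node_strength(M)),
                        numeric(n_nodes(matrices[[1]]))))
  labels <- matrices[[1]]$labels
  if (is.null(nodes)) nodes <- seq_len(ncol(strengths))
  out <- run_age_analysis(strengths[, nodes, drop = FALSE], ages,
                          alpha = alpha, n_boot = n_boot, seed = seed,
                          labels = labels[nodes])
  out$node <- nodes[out$node]
  out
}
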