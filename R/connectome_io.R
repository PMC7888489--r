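#' Construct a connectivity matrix object
#'
#' A `connectivity_matrix` is a symmetric, nonnegative, zero-diagonal weighted
#' adjacency matrix over labelled nodes, the standard container for structural
#' connectomes whose weights are streamline-count-like quantities.
#'
#' @param weights square numeric matrix of nonnegative weights.
#' @param labels optional character vector of node names; defaults to
#'   `node_000`, `node_001`, ...
#' @param symmetrize_tol relative tolerance below which small asymmetries
#'   (text round-off) are silently symmetrized; larger asymmetry is an error.
#' @return An object of class `connectivity_matrix` with elements `weights`
#'   (numeric matrix) and `labels` (character).
#' @export
connectivity_matrix <- function(weights, labels = NULL, symmetrize_tol = 1e-8) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("`weights` must be a numeric matrix")
  }
  if (nrow(weights) != ncol(weights)) {
    stop("connectivity matrix must be square, got ",
         nrow(weights), " x ", ncol(weights))
  }
  if (anyNA(weights) || any(!is.finite(weights))) {
    stop("connectivity matrix contains NA/NaN/Inf entries")
  }
  if (any(weights < 0)) stop("connectivity matrix has negative entries")
  scale <- max(abs(weights))
  asym <- max(abs(weights - t(weights)))
  if (scale > 0 && asym > symmetrize_tol * scale) {
    stop("matrix is asymmetric beyond tolerance (max |w_ij - w_ji| = ",
         format(asym), ")")
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  n <- nrow(weights)
  if (is.null(labels)) {
    labels <- sprintf("node_%03d", seq_len(n) - 1L)
  }
  if (length(labels) != n) stop("labels length does not match matrix size")
  dimnames(weights) <- NULL
  structure(list(weights = weights, labels = as.character(labels)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  n <- n_nodes(x)
  w <- x$weights[upper.tri(x$weights)]
  cat("<connectivity_matrix> ", n, " nodes, ",
      sum(w > 0), "/", length(w), " positive pairs, total weight ",
      format(sum(w), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Number of nodes of a connectivity matrix
#' @param C a `connectivity_matrix`.
#' @return integer node count.
#' @export
n_nodes <- function(C) nrow(C$weights)

#' Read a connectome from a dense text adjacency matrix
#'
#' Reads whitespace- or comma-delimited dense square matrices, the dialect in
#' which connectome databases typically distribute region-by-region streamline
#' counts.  An optional header row of labels is detected; a labels sidecar
#' file (one name per line) overrides any header.
#'
#' @param path path to the matrix file.
#' @param labels_path optional path to a labels file, one node name per line.
#' @return a [connectivity_matrix()].
#' @export
load_connectome <- function(path, labels_path = NULL) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tokens <- scan(text = first, what = "character", sep = if (sep == ",") "," else "",
                 quiet = TRUE, strip.white = TRUE)
  # a row is a header only if some token is neither a number nor a numeric
  # literal like NaN/Inf (those must reach validation as values, not labels)
  numeric_like <- !is.na(suppressWarnings(as.numeric(tokens))) |
    tolower(tokens) %in% c("nan", "na", "inf", "-inf", "+inf")
  has_header <- any(!numeric_like)
  df <- utils::read.table(path, header = has_header, sep = sep,
                          check.names = FALSE)
  labels <- if (has_header) colnames(df) else NULL
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("matrix file contains non-numeric entries: ", path)
  if (!is.null(labels_path)) {
    labels <- readLines(labels_path)
    labels <- labels[nzchar(trimws(labels))]
  }
  connectivity_matrix(m, labels = labels)
}

#' Write a connectome as a dense text adjacency matrix
#'
#' Round-trips through [load_connectome()] to 1e-12 relative precision.
#'
#' @param C a `connectivity_matrix`.
#' @param path output file path.
#' @param labels_path optional path for a labels sidecar.
#' @param sep field separator, `","` (default) or whitespace.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(C, path, labels_path = NULL, sep = ",") {
  m <- C$weights
  lines <- apply(m, 1L, function(r) paste(format(r, digits = 17), collapse = sep))
  writeLines(lines, path)
  if (!is.null(labels_path)) writeLines(C$labels, labels_path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with header `subject_id,age,path` mapping each
#' subject to an age in years and a connectome matrix file.  Paths are
#' resolved relative to the manifest's directory unless absolute.
#'
#' @param path manifest CSV path.
#' @param age_range allowed age range in years; ages outside it are an error.
#' @return data.frame with columns `subject_id`, `age`, `path`.
#' @export
read_cohort_manifest <- function(path, age_range = c(0, 120)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "path")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$subject_id)) stop("duplicate subject_id in manifest")
  if (any(!is.finite(df$age)) || any(df$age < age_range[1] | df$age > age_range[2])) {
    stop("ages outside declared range [", age_range[1], ", ", age_range[2], "]")
  }
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  df[need]
}

#' Average a set of connectomes elementwise
#'
#' Produces the group-average connectivity matrix: the elementwise arithmetic
#' mean of the subject matrices.  Individual tractography matrices are sparse;
#' their average is dense, which is why dense- and sparse-mode triplet
#' selection both exist downstream.
#'
#' @param matrices list of `connectivity_matrix` objects with identical size
#'   and label order.
#' @return a `connectivity_matrix`.
#' @export
average_connectomes <- function(matrices) {
  if (length(matrices) == 0L) stop("need at least one matrix to average")
  ref <- matrices[[1L]]
  for (M in matrices) {
    if (!inherits(M, "connectivity_matrix")) stop("all inputs must be connectivity_matrix")
    if (n_nodes(M) != n_nodes(ref)) stop("dimension mismatch across matrices")
    if (!identical(M$labels, ref$labels)) stop("label mismatch across matrices")
  }
  avg <- Reduce(`+`, lapply(matrices, `[[`, "weights")) / length(matrices)
  connectivity_matrix(avg, labels = ref$labels)
}

#' Threshold a connectome to a target link density
#'
#' Finds the smallest threshold `J_th` such that the number of unordered node
#' pairs with weight strictly above `J_th` does not exceed
#' `floor(target_density * n*(n-1)/2)`.  Ties at the threshold are excluded,
#' so the retained density never overshoots the target.
#'
#' @param C a `connectivity_matrix`.
#' @param target_density fraction of all possible pairs to retain, in (0, 1].
#' @return list with `J_th` (numeric threshold) and `mask` (logical n x n
#'   matrix, symmetric, TRUE on retained edges).
#' @export
density_threshold <- function(C, target_density = 0.2) {
  stopifnot(inherits(C, "connectivity_matrix"))
  if (!is.numeric(target_density) || target_density <= 0 || target_density > 1) {
    stop("target_density must be in (0, 1]")
  }
  w <- C$weights[upper.tri(C$weights)]
  n_pairs <- length(w)
  m_target <- floor(target_density * n_pairs)
  pos <- w[w > 0]
  if (length(unique(w)) == 1L) {
    if (m_target >= n_pairs) {
      J_th <- if (w[1] > 0) w[1] / 2 else 0
    } else {
      warning("all off-diagonal weights are equal; cannot hit target density, ",
              "returning empty mask")
      J_th <- w[1]
    }
  } else if (m_target >= length(pos)) {
    # every positive edge can be kept
    J_th <- if (length(pos)) min(pos) / 2 else 0
  } else {
    ws <- sort(w, decreasing = TRUE)
    J_th <- ws[m_target + 1L]
  }
  mask <- C$weights > J_th
  structure(list(J_th = J_th, mask = mask), class = "density_threshold")
}

#' Node strength
#'
#' The strength of a node is the sum of the weights of its connections
#' (row sum of the adjacency matrix).
#'
#' @param C a `connectivity_matrix`.
#' @return named numeric vector of strengths.
#' @export
node_strength <- function(C) {
  stopifnot(inherits(C, "connectivity_matrix"))
  s <- rowSums(C$weights)
  names(s) <- C$labels
  s
}

#' Weighted topology profile: strength, betweenness, closeness
#'
#' Betweenness and closeness are computed on edge lengths `1/weight`, the
#' usual convention for streamline-count connectomes where heavier links are
#' shorter paths; `binarize = TRUE` uses unit lengths on the positive support
#' instead.  Betweenness is normalized to \[0, 1\] by `(n-1)(n-2)/2`;
#' closeness is the normalized harmonic of shortest-path lengths
#' (per connected component, with a warning if the graph is disconnected).
#'
#' @param C a `connectivity_matrix`.
#' @param binarize if TRUE, use unit edge lengths instead of `1/weight`.
#' @return data.frame with columns `node`, `label`, `strength`,
#'   `betweenness`, `closeness`.
#' @export
centrality_metrics <- function(C, binarize = FALSE) {
  stopifnot(inherits(C, "connectivity_matrix"))
  n <- n_nodes(C)
  w <- C$weights
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- if (binarize) rep(1, igraph::ecount(g)) else 1 / igraph::E(g)$weight
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    warning("graph is disconnected (", comp$no,
            " components); closeness computed per component")
  }
  btw <- igraph::betweenness(g, weights = len, normalized = TRUE)
  cls <- suppressWarnings(
    igraph::closeness(g, weights = len, normalized = TRUE, mode = "all")
  )
  cls[!is.finite(cls)] <- 0  # isolated nodes
  data.frame(node = seq_len(n), label = C$labels,
             strength = unname(rowSums(w)),
             betweenness = unname(btw),
             closeness = unname(cls),
             stringsAsFactors = FALSE)
}

#' Weighted rich-club coefficient against degree-preserving nulls
#'
#' For each strength rank `k` the weighted rich-club coefficient is the total
#' weight among the top-`k`-strength nodes divided by the sum of the `E_k`
#' largest edge weights anywhere in the network (`E_k` = number of edges among
#' the top-`k` nodes).  The returned ratio divides this by its mean over
#' `n_null` nulls in which edge weights are shuffled over the fixed topology;
#' ratios above 1 indicate rich-club organization.
#'
#' @param C a `connectivity_matrix`.
#' @param n_null number of weight-shuffled null networks (>= 1).
#' @param seed RNG seed.
#' @param ranks integer vector of club sizes to evaluate; default
#'   `2:(n-1)`.
#' @return data.frame with columns `k`, `phi`, `phi_null`, `ratio`.
#' @export
rich_club_check <- function(C, n_null = 50, seed = 1L, ranks = NULL) {
  stopifnot(inherits(C, "connectivity_matrix"))
  if (n_null < 1) stop("n_null must be >= 1")
  n <- n_nodes(C)
  if (is.null(ranks)) ranks <- 2:(n - 1L)
  w <- C$weights
  ut <- upper.tri(w)
  edge_w <- w[ut][w[ut] > 0]
  phi_of <- function(weights_mat) {
    ew <- sort(weights_mat[ut][weights_mat[ut] > 0], decreasing = TRUE)
    ord <- order(rowSums(weights_mat), decreasing = TRUE)
    vapply(ranks, function(k) {
      club <- ord[seq_len(k)]
      sub <- weights_mat[club, club]
      sw <- sub[upper.tri(sub)]
      e_k <- sum(sw > 0)
      if (e_k == 0L) return(NA_real_)
      sum(sw) / sum(ew[seq_len(e_k)])
    }, numeric(1))
  }
  phi <- phi_of(w)
  set.seed(seed)
  nulls <- replicate(n_null, {
    wn <- w
    wn[ut][w[ut] > 0] <- sample(edge_w)
    wn[lower.tri(wn)] <- t(wn)[lower.tri(wn)]
    phi_of(wn)
  })
  phi_null <- rowMeans(matrix(nulls, nrow = length(ranks)), na.rm = TRUE)
  data.frame(k = ranks, phi = phi, phi_null = phi_null,
             ratio = phi / phi_null)
}

#' Write a node-profile table as CSV
#'
#' @param profile data.frame with at least columns `node`, `label`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_node_profile <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}
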