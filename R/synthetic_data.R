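#' Periodic 2D lattice connectome
#'
#' Builds the 4-neighbour periodic square lattice with uniform coupling `J`,
#' the standard validation surface for critical Ising dynamics: its
#' susceptibility peak must sit near the known 2D critical coupling
#' (approximately 0.4407 in the infinite-size limit, shifted slightly on
#' finite lattices).  For `L = 2` the periodic wrap creates parallel edges
#' which merge, so each neighbouring pair carries weight `2J`.
#'
#' @param L lattice side length (>= 2); the graph has `L^2` nodes.
#' @param J coupling weight per lattice bond.
#' @return a [connectivity_matrix()]; every node strength equals `4*J`.
#' @export
generate_lattice2d <- function(L, J = 1) {
  if (L < 2) stop("L must be >= 2")
  n <- L * L
  w <- matrix(0, n, n)
  idx <- function(r, c) ((r - 1L) %% L) * L + ((c - 1L) %% L) + 1L
  for (r in seq_len(L)) {
    for (c in seq_len(L)) {
      i <- idx(r, c)
      for (j in c(idx(r + 1L, c), idx(r, c + 1L))) {
        w[i, j] <- w[i, j] + J
        w[j, i] <- w[j, i] + J
      }
    }
  }
  diag(w) <- 0
  connectivity_matrix(w, labels = sprintf("site_%03d", seq_len(n) - 1L))
}

#' Heterogeneous rich-club connectome
#'
#' Emulates the statistical structure of a group-average structural
#' connectome: dense, symmetric, nonnegative weights with a heavy-tailed node
#' strength distribution and a rich-club core.  Node "fitness" values are
#' drawn from a Pareto distribution with the requested tail exponent; the
#' weight of pair (i, j) is the product of fitnesses times lognormal noise,
#' so strengths inherit the heavy tail.  The top `rich_club_fraction` of
#' nodes by fitness have their mutual links boosted so the core is knit by
#' the largest weights.
#'
#' @param n_nodes number of nodes (>= 10).
#' @param strength_tail_exponent Pareto tail exponent of the fitness
#'   distribution (> 1); smaller means heavier tail.  Default 3.
#' @param rich_club_fraction fraction of top-fitness nodes forming the
#'   planted core, in \[0, 1\]; 0 plants no core.
#' @param rich_club_boost multiplicative boost applied to intra-core links.
#' @param noise_sd standard deviation of lognormal edge noise.
#' @param seed RNG seed; output is deterministic given the seed.
#' @return a [connectivity_matrix()].
#' @export
generate_heterogeneous_connectome <- function(n_nodes,
                                              strength_tail_exponent = 2.5,
                                              rich_club_fraction = 0.1,
                                              rich_club_boost = 3,
                                              noise_sd = 0.25,
                                              seed = 1L) {
  if (n_nodes < 10) stop("n_nodes must be >= 10")
  if (rich_club_fraction < 0 || rich_club_fraction > 1) stop("invalid rich_club_fraction")
  if (strength_tail_exponent <= 1) stop("strength_tail_exponent must be > 1")
  set.seed(seed)
  # Pareto(1, alpha-1) fitnesses -> strength tail exponent ~ alpha
  u <- stats::runif(n_nodes)
  fit <- u^(-1 / (strength_tail_exponent - 1))
  w <- outer(fit, fit)
  noise <- matrix(stats::rnorm(n_nodes^2, sd = noise_sd), n_nodes)
  noise <- (noise + t(noise)) / sqrt(2)
  w <- w * exp(noise)
  core_n <- floor(rich_club_fraction * n_nodes)
  if (core_n >= 2) {
    core <- order(fit, decreasing = TRUE)[seq_len(core_n)]
    w[core, core] <- w[core, core] * rich_club_boost
  }
  diag(w) <- 0
  w <- (w + t(w)) / 2
  connectivity_matrix(w)
}

#' Specify a planted age effect on one node
#'
#' Describes how the connectivity of one node changes with subject age:
#' monotone in `direction`, either linearly across the whole age range or
#' saturating (piecewise-linear ramp up to `saturation_age`, flat after),
#' emulating lifespan patterns where some regions' connectivity declines
#' steadily while others strengthen during maturation and then plateau.
#'
#' @param node node index (1-based).
#' @param direction `"increasing"` or `"decreasing"`.
#' @param shape `"linear"` or `"saturating"`.
#' @param effect_size relative weight change per decade (e.g. 0.08 = 8%).
#' @param saturation_age age (years) at which a saturating effect plateaus.
#' @return an `aging_effect` list.
#' @export
aging_effect <- function(node, direction = c("increasing", "decreasing"),
                         shape = c("linear", "saturating"),
                         effect_size = 0.08, saturation_age = 30) {
  direction <- match.arg(direction)
  shape <- match.arg(shape)
  if (!is.finite(effect_size) || effect_size < 0) stop("effect_size must be finite and >= 0")
  structure(list(node = as.integer(node), direction = direction, shape = shape,
                 effect_size = effect_size, saturation_age = saturation_age),
            class = "aging_effect")
}

#' Evaluate an aging-effect multiplier at given ages
#'
#' The multiplier is 1 at the lower end of the age range and changes by
#' `effect_size` per decade (sign per `direction`), clipped below at 0.05 so
#' weights stay positive; saturating effects stop changing at
#' `saturation_age`.
#'
#' @param effect an [aging_effect()].
#' @param age ages in years.
#' @param age_range cohort age range; the multiplier is anchored to 1 at
#'   `age_range[1]`.
#' @return numeric vector of multipliers.
#' @export
effect_multiplier <- function(effect, age, age_range) {
  a <- pmin(age, if (effect$shape == "saturating") effect$saturation_age else Inf)
  decades <- (a - age_range[1]) / 10
  sgn <- if (effect$direction == "increasing") 1 else -1
  pmax(1 + sgn * effect$effect_size * decades, 0.05)
}

#' Specify a synthetic aging cohort
#'
#' @param n_subjects number of subjects (>= 3).
#' @param n_nodes number of nodes in the base connectome (>= 10).
#' @param age_range cohort age range in years; default 4-85, the lifespan
#'   range of the cohorts this generator emulates.
#' @param effects list of [aging_effect()] specifications.
#' @param noise_sd dispersion of multiplicative lognormal edge noise.
#' @param sparsity fraction of weakest pairs zeroed per subject, in \[0, 1).
#' @param seed RNG seed.
#' @param base optional `connectivity_matrix` to use as the base connectome;
#'   default is a heterogeneous rich-club connectome on `n_nodes` nodes.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects, n_nodes, age_range = c(4, 85),
                        effects = list(), noise_sd = 0.1, sparsity = 0.3,
                        seed = 1L, base = NULL) {
  if (n_subjects < 3) stop("n_subjects must be >= 3")
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must be in [0, 1)")
  for (e in effects) {
    if (!inherits(e, "aging_effect")) stop("effects must be aging_effect objects")
    if (e$node < 1 || e$node > n_nodes) stop("effect node index out of range")
    if (e$shape == "saturating" &&
        (e$saturation_age < age_range[1] || e$saturation_age > age_range[2])) {
      stop("saturation_age outside cohort age range")
    }
  }
  structure(list(n_subjects = as.integer(n_subjects), n_nodes = as.integer(n_nodes),
                 age_range = age_range, effects = effects, noise_sd = noise_sd,
                 sparsity = sparsity, seed = as.integer(seed), base = base),
            class = "cohort_spec")
}

#' Generate a synthetic aging cohort
#'
#' Ages are drawn uniformly over the cohort range.  Each subject's matrix is
#' the base connectome with every edge incident to an effect node scaled by
#' that node's effect multiplier at the subject's age, then multiplied by
#' symmetric lognormal edge noise, then sparsified by zeroing the subject's
#' weakest pairs (mimicking tractography's weak-connection dropout).  The
#' strength of an "increasing, linear" effect node is therefore positively
#' rank-correlated with age across subjects: a recoverable planted signal.
#'
#' @param spec a [cohort_spec()].
#' @return list with `manifest` (data.frame `subject_id`, `age`; `path` is NA
#'   until written with [write_cohort()]) and `matrices` (list of
#'   `connectivity_matrix`).
#' @export
generate_aging_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  base <- spec$base
  if (is.null(base)) {
    base <- generate_heterogeneous_connectome(spec$n_nodes, seed = spec$seed + 1L)
  }
  if (n_nodes(base) != spec$n_nodes) stop("base connectome size mismatch")
  set.seed(spec$seed)
  ages <- stats::runif(spec$n_subjects, spec$age_range[1], spec$age_range[2])
  n <- spec$n_nodes
  ut <- upper.tri(base$weights)
  matrices <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    w <- base$weights
    for (e in spec$effects) {
      m <- effect_multiplier(e, ages[s], spec$age_range)
      w[e$node, ] <- w[e$node, ] * m
      w[, e$node] <- w[, e$node] * m
      # the diagonal scaling applied twice is irrelevant: diagonal is zero
    }
    if (spec$noise_sd > 0) {
      noise <- matrix(0, n, n)
      noise[ut] <- stats::rnorm(sum(ut), sd = spec$noise_sd)
      noise <- noise + t(noise)
      w <- w * exp(noise)
    }
    if (spec$sparsity > 0) {
      wv <- w[ut]
      k_drop <- floor(spec$sparsity * length(wv))
      if (k_drop > 0) {
        thr <- sort(wv)[k_drop]
        w[w <= thr] <- 0
      }
    }
    diag(w) <- 0
    matrices[[s]] <- connectivity_matrix(w, labels = base$labels)
  }
  manifest <- data.frame(subject_id = sprintf("sub_%03d", seq_len(spec$n_subjects)),
                         age = ages, path = NA_character_,
                         stringsAsFactors = FALSE)
  list(manifest = manifest, matrices = matrices, spec = spec, base = base)
}

#' Reference planted-effect cohort for recovery experiments
#'
#' Builds the package's standard parameter-recovery experiment: a synthetic
#' aging cohort on a heterogeneous rich-club base connectome with three
#' linearly increasing and two linearly decreasing effect nodes, low
#' multiplicative noise and moderate per-subject sparsification.  Effect
#' nodes are placed on low-to-mid-strength nodes that do not appear among
#' any other node's strongest in-edges: low-strength targets sit on the
#' rising branch of the synergy-versus-coupling curve (so the planted signal
#' is monotone in age), and zero source-set participation localizes the
#' effect, keeping information-flow spillover to unplanted nodes small.
#'
#' @param n_subjects cohort size (default 60).
#' @param n_nodes base connectome size (default 30).
#' @param replicate_seed seed for ages/noise/sparsity draws (one value per
#'   replicate of the experiment).
#' @param base_seed seed of the fixed base connectome.
#' @param effect_size relative weight change per decade (default 0.08).
#' @param noise_sd lognormal edge-noise dispersion (default 0.05).
#' @param sparsity per-subject fraction of dropped weakest pairs (default 0.2).
#' @return list with `cohort` (from [generate_aging_cohort()]) and `planted`
#'   (data.frame `node`, `direction`).
#' @export
demo_aging_cohort <- function(n_subjects = 60, n_nodes = 30,
                              replicate_seed = 1L, base_seed = 101L,
                              effect_size = 0.08, noise_sd = 0.05,
                              sparsity = 0.2) {
  base <- generate_heterogeneous_connectome(n_nodes, seed = base_seed)
  ord <- order(node_strength(base))
  # effect placement by strength quantile: increasing effects on weak nodes
  # (rising branch of the synergy-coupling curve), decreasing on mid nodes;
  # ranks are deduplicated upward for small networks
  ranks <- pmax(1, round(c(0.067, 0.133, 0.2, 0.333, 0.433) * n_nodes))
  for (i in seq_along(ranks)[-1]) {
    if (ranks[i] <= ranks[i - 1]) ranks[i] <- ranks[i - 1] + 1
  }
  if (max(ranks) > n_nodes) stop("n_nodes too small for the planted design")
  inc <- ord[ranks[1:3]]
  dec <- ord[ranks[4:5]]
  effects <- c(lapply(inc, aging_effect, direction = "increasing",
                      shape = "linear", effect_size = effect_size),
               lapply(dec, aging_effect, direction = "decreasing",
                      shape = "linear", effect_size = effect_size))
  spec <- cohort_spec(n_subjects, n_nodes, effects = effects,
                      noise_sd = noise_sd, sparsity = sparsity,
                      seed = replicate_seed, base = base)
  list(cohort = generate_aging_cohort(spec),
       planted = data.frame(node = c(inc, dec),
                            direction = rep(c("increasing", "decreasing"),
                                            c(length(inc), length(dec)))))
}

#' Write a generated cohort to disk
#'
#' Writes each subject matrix in the dense-text dialect plus a manifest CSV
#' (`subject_id,age,path`) readable by [read_cohort_manifest()], and a
#' human-readable key-value file recording the generating parameters.
#'
#' @param cohort result of [generate_aging_cohort()].
#' @param dir output directory (created if needed).
#' @return path to the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- sprintf("%s.csv", cohort$manifest$subject_id)
  for (s in seq_along(cohort$matrices)) {
    write_connectome(cohort$matrices[[s]], file.path(dir, paths[s]))
  }
  manifest <- cohort$manifest
  manifest$path <- paths
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  sp <- cohort$spec
  cfg <- c(sprintf("n_subjects: %d", sp$n_subjects),
           sprintf("n_nodes: %d", sp$n_nodes),
           sprintf("age_range: %g %g", sp$age_range[1], sp$age_range[2]),
           sprintf("noise_sd: %g", sp$noise_sd),
           sprintf("sparsity: %g", sp$sparsity),
           sprintf("seed: %d", sp$seed),
           vapply(sp$effects, function(e) {
             sprintf("effect: node=%d direction=%s shape=%s size=%g sat_age=%g",
                     e$node, e$direction, e$shape, e$effect_size, e$saturation_age)
           }, character(1)))
  writeLines(cfg, file.path(dir, "cohort_spec.txt"))
  invisible(mpath)
}
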