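#' Derive a stage seed from the master seed
#'
#' Pure function of (master seed, stage name, optional id): partial reruns
#' and parallel subject execution reproduce exactly regardless of order.
#'
#' @param master master integer seed.
#' @param stage stage name string.
#' @param id optional subject/replicate identifier.
#' @return integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(master, stage, id = "") {
  s <- paste0(stage, "::", id)
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147480009
  as.integer((as.numeric(master) * 7919 + h) %% 2147480009 + 1)
}

#' Pipeline configuration
#'
#' @param preset `"desk"` (scaled-down; default) or `"paper"` (the
#'   full-scale protocol: 80 beta points, 20 runs, 1e6 collected sweeps,
#'   density 0.20).
#' @param betas optional explicit beta grid (otherwise suggested per
#'   network via [suggest_beta_grid()]).
#' @param triplet_mode `"dense"` or `"sparse"`.
#' @param target_density sparse-mode link density.
#' @param max_triplets triplet cap.
#' @param pid_method `"mmi"` or `"bertschinger"`.
#' @param alpha family-wise error level.
#' @param n_boot bootstrap replicates.
#' @param seed master seed.
#' @param normalization weight normalization mode.
#' @param sweep optional named list overriding the preset's sweep schedule;
#'   recognized entries: `n_beta`, `runs`, `collect`, `discard`,
#'   `relaxation`, and `collect_star` (length of the dedicated recording run
#'   at the located critical beta in cohort analyses; defaults to `collect`).
#' @param k_sources sources per target in `top_k` triplet mode.
#' @param triplet_frame for cohort analyses: `"subject"` selects triplets on
#'   each subject's own matrix (each network its own threshold), `"average"`
#'   selects them once on the cohort-average connectome so every subject is
#'   measured in the same frame.
#' @param beta_mode for cohort analyses: `"subject"` evaluates each subject
#'   at its own susceptibility-peak beta; `"cohort"` evaluates every subject
#'   at the critical beta of the cohort-average connectome (a fixed-beta
#'   sensitivity mode that removes per-subject peak-location jitter).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(preset = c("desk", "paper"), betas = NULL,
                            triplet_mode = c("sparse", "dense", "top_k"),
                            target_density = 0.2,
                            max_triplets = if (preset == "paper") 2e5 else 5e3,
                            pid_method = "mmi", alpha = 0.05, n_boot = 1000,
                            seed = 1L,
                            normalization = "mean_positive",
                            sweep = list(), k_sources = 6L,
                            triplet_frame = c("subject", "average"),
                            beta_mode = c("subject", "cohort")) {
  preset <- match.arg(preset)
  triplet_mode <- match.arg(triplet_mode)
  triplet_frame <- match.arg(triplet_frame)
  beta_mode <- match.arg(beta_mode)
  bad <- setdiff(names(sweep),
                 c("n_beta", "runs", "collect", "discard", "relaxation",
                   "collect_star"))
  if (length(bad)) stop("unknown sweep overrides: ", paste(bad, collapse = ", "))
  structure(list(preset = preset, betas = betas, triplet_mode = triplet_mode,
                 target_density = target_density, max_triplets = max_triplets,
                 pid_method = pid_method, alpha = alpha, n_boot = n_boot,
                 seed = as.integer(seed), normalization = normalization,
                 sweep = sweep, k_sources = as.integer(k_sources),
                 triplet_frame = triplet_frame, beta_mode = beta_mode),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a key-value file
#'
#' Accepts a simple `key: value` text file (a YAML subset).  Unknown keys
#' are an error.
#'
#' @param path config file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), character(1))
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = ":")), character(1))
  known <- c("preset", "triplet_mode", "target_density", "max_triplets",
             "pid_method", "alpha", "n_boot", "seed", "normalization",
             "k_sources", "triplet_frame")
  if (any(!keys %in% known)) {
    stop("unknown config keys: ", paste(setdiff(keys, known), collapse = ", "))
  }
  args <- stats::setNames(as.list(vals), keys)
  for (k in c("target_density", "max_triplets", "alpha", "n_boot", "seed",
              "k_sources")) {
    if (!is.null(args[[k]])) args[[k]] <- as.numeric(args[[k]])
  }
  do.call(pipeline_config, args)
}

#' Configuration of the reference cohort recovery experiment
#'
#' The settings under which the package's planted-effect cohorts (see
#' [demo_aging_cohort()]) are analysed: per-target strongest-source triplets
#' selected once on the cohort-average connectome, spectral weight
#' normalization (so the beta axis is pinned by the hub spectrum and does
#' not drift with the planted effects), a fixed 14-point beta grid, and the
#' two-stage sweep (short runs to locate each subject's susceptibility peak,
#' one long recording run at that beta).
#'
#' @param seed master seed.
#' @param n_boot bootstrap replicates per node.
#' @return a [pipeline_config()].
#' @export
demo_cohort_config <- function(seed = 7L, n_boot = 2000) {
  pipeline_config(triplet_mode = "top_k", k_sources = 6,
                  triplet_frame = "average",
                  betas = seq(0.5, 5, length.out = 28),
                  normalization = "spectral", n_boot = n_boot, seed = seed,
                  sweep = list(runs = 2, collect = 2500, discard = 300,
                               relaxation = 800, collect_star = 60000))
}

config_protocol <- function(config, C) {
  sw <- config$sweep
  n_beta <- if (!is.null(sw$n_beta)) sw$n_beta else
    if (config$preset == "paper") 80 else 20
  betas <- config$betas
  if (is.null(betas)) {
    betas <- suggest_beta_grid(C, n_points = n_beta,
                               normalization = config$normalization)
  }
  proto <- protocol_preset(config$preset, betas = betas, seed = config$seed,
                           normalization = config$normalization)
  for (k in c("runs", "collect", "discard", "relaxation")) {
    if (!is.null(sw[[k]])) proto[[k]] <- sw[[k]]
  }
  proto
}

#' Average-connectome analysis
#'
#' The first end-to-end workflow: adiabatic Glauber sweep on one (typically
#' group-average) connectome, per-node synergy and transfer-entropy profiles
#' at the critical temperature, hub synergy curves across the sweep, and the
#' rank association of synergy with strength, betweenness and closeness.
#'
#' @param C a `connectivity_matrix`.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; result tables are written as CSV with a
#'   JSON sidecar of parameters.
#' @return an `average_analysis` bundle: `sweep`, `critical_beta`,
#'   `node_profile` (strength/betweenness/closeness + synergy + TE),
#'   `hub_curves`, `topology_association`, `config`.
#' @export
run_average_analysis <- function(C, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(C, "connectivity_matrix"))
  protocol <- config_protocol(config, C)
  protocol$seed <- derive_seed(config$seed, "simulate")
  sweep <- temperature_sweep(C, protocol)
  ib <- which.max(sweep$chi)
  ser <- sweep$series[[ib]]
  n <- n_nodes(C)
  triplets <- select_triplets(C, config$triplet_mode,
                              target_density = config$target_density,
                              max_triplets = config$max_triplets,
                              seed = derive_seed(config$seed, "triplets"),
                              k_sources = config$k_sources)
  syn <- node_incoming_synergy(ser, triplets, n, method = config$pid_method)
  te <- node_te_profile(ser, n)
  topo <- centrality_metrics(C)
  profile <- Reduce(function(a, b) merge(a, b, by = "node"),
                    list(topo, syn, te))
  profile$beta <- sweep$critical_beta
  hub_curves <- hub_synergy_curves(sweep, C,
                                   seed = derive_seed(config$seed, "hubs"),
                                   method = config$pid_method)
  assoc <- synergy_topology_association(syn, topo)
  out <- structure(list(sweep = sweep, critical_beta = sweep$critical_beta,
                        node_profile = profile, hub_curves = hub_curves,
                        topology_association = assoc, config = config),
                   class = "average_analysis")
  if (!is.null(out_dir)) write_average_bundle(out, out_dir)
  out
}

#' @export
print.average_analysis <- function(x, ...) {
  cat("<average_analysis>\n")
  cat("  critical beta: ", format(x$critical_beta, digits = 4), "\n", sep = "")
  cat("  node profile: ", nrow(x$node_profile), " nodes\n", sep = "")
  cat("  synergy-topology rank correlations:\n")
  print(x$topology_association, row.names = FALSE, digits = 3)
  invisible(x)
}

write_average_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$node_profile,
                   file.path(out_dir, "node_profile.csv"), row.names = FALSE)
  utils::write.csv(bundle$topology_association,
                   file.path(out_dir, "topology_association.csv"), row.names = FALSE)
  hc <- bundle$hub_curves
  utils::write.csv(data.frame(beta = hc$betas, t(hc$curves)),
                   file.path(out_dir, "hub_synergy_curves.csv"), row.names = FALSE)
  sidecar <- list(critical_beta = bundle$critical_beta,
                  config = unclass(bundle$config),
                  betas = bundle$sweep$betas)
  jsonlite::write_json(sidecar, file.path(out_dir, "analysis_params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Per-subject critical-state synergy profile
#'
#' Runs the subject's own temperature sweep, locates the subject's critical
#' beta at the susceptibility peak, and computes the per-node incoming
#' synergy at that beta.  When the config's sweep list sets `collect_star`
#' larger than `collect`, a dedicated recording run of that length is
#' performed at the critical beta (two-stage scheme: a cheap sweep locates
#' the peak, a long run nails down the plugin tables).
#'
#' @param C subject `connectivity_matrix`.
#' @param config a [pipeline_config()].
#' @param seed subject-specific seed.
#' @param triplets optional precomputed triplet table (e.g. selected on the
#'   cohort-average connectome); default selects per the config on `C`.
#' @return list with `critical_beta`, `synergy` (per-node vector, NaN where
#'   no triplet targets the node), `n_triplets`.
#' @export
subject_synergy_profile <- function(C, config = pipeline_config(), seed = 1L,
                                    triplets = NULL, beta_fixed = NULL) {
  protocol <- config_protocol(config, C)
  protocol$seed <- seed
  collect_star <- config$sweep$collect_star
  if (!is.null(beta_fixed)) {
    wn <- normalize_weights(C$weights, config$normalization)
    Cn <- connectivity_matrix(wn, labels = C$labels)
    set.seed(seed + 1L)
    ser <- simulate_at_beta(Cn, beta_fixed,
                            discard = max(protocol$discard, 2000),
                            collect = if (!is.null(collect_star)) collect_star
                                      else protocol$collect)
    sweep <- list(critical_beta = beta_fixed)
  } else if (!is.null(collect_star) && collect_star > protocol$collect) {
    protocol$keep_series <- FALSE
    sweep <- temperature_sweep(C, protocol)
    wn <- normalize_weights(C$weights, config$normalization)
    Cn <- connectivity_matrix(wn, labels = C$labels)
    set.seed(seed + 1L)
    ser <- simulate_at_beta(Cn, sweep$critical_beta,
                            discard = max(protocol$discard, 2000),
                            collect = collect_star)
  } else {
    sweep <- temperature_sweep(C, protocol)
    ser <- sweep$series[[which.max(sweep$chi)]]
  }
  if (is.null(triplets)) {
    triplets <- select_triplets(C, config$triplet_mode,
                                target_density = config$target_density,
                                max_triplets = config$max_triplets,
                                seed = seed, k_sources = config$k_sources)
  }
  syn <- node_incoming_synergy(ser, triplets, n_nodes(C),
                               method = config$pid_method)
  list(critical_beta = sweep$critical_beta, synergy = syn$incoming_synergy,
       n_triplets = syn$n_triplets)
}

#' Cohort aging analysis
#'
#' The second end-to-end workflow: for every subject, an individual
#' temperature sweep and a synergy profile at that subject's own critical
#' beta; the cohort synergy table is then tested node-by-node for robust
#' association with age (skipped Spearman + Hochberg), with a strength-age
#' follow-up on the significant nodes.  A subject whose matrix fails to load
#' or simulate is skipped with a warning; fewer than 10 usable subjects
#' aborts.
#'
#' @param cohort either the result of [generate_aging_cohort()] or a
#'   manifest data.frame (`subject_id`, `age`, `path`) whose paths are read
#'   with [load_connectome()].
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for CSV results.
#' @return a `cohort_analysis` bundle: `ages`, `critical_betas`,
#'   `synergy_table` (subjects x nodes), `age_result` (an
#'   `age_correlation`), `strength_result`, `subjects_used`, `config`.
#' @export
run_cohort_analysis <- function(cohort, config = pipeline_config(),
                                out_dir = NULL) {
  if (is.data.frame(cohort)) {
    manifest <- cohort
    matrices <- vector("list", nrow(manifest))
    for (s in seq_len(nrow(manifest))) {
      matrices[[s]] <- tryCatch(load_connectome(manifest$path[s]),
                                error = function(e) {
                                  warning("skipping subject ", manifest$subject_id[s],
                                          ": ", conditionMessage(e))
                                  NULL
                                })
    }
  } else {
    manifest <- cohort$manifest
    matrices <- cohort$matrices
  }
  usable <- !vapply(matrices, is.null, logical(1))
  if (sum(usable) < 10) stop("fewer than 10 usable subjects")
  manifest <- manifest[usable, ]
  matrices <- matrices[usable]
  n_sub <- length(matrices)
  n <- n_nodes(matrices[[1]])
  avg <- if (config$triplet_frame == "average" ||
             config$beta_mode == "cohort") average_connectomes(matrices)
  frame_triplets <- if (config$triplet_frame == "average") {
    select_triplets(avg, config$triplet_mode,
                    target_density = config$target_density,
                    max_triplets = config$max_triplets,
                    seed = derive_seed(config$seed, "triplets"),
                    k_sources = config$k_sources)
  } else NULL
  beta_fixed <- if (config$beta_mode == "cohort") {
    proto_avg <- config_protocol(config, avg)
    proto_avg$seed <- derive_seed(config$seed, "cohort-beta")
    proto_avg$keep_series <- FALSE
    temperature_sweep(avg, proto_avg)$critical_beta
  } else NULL
  syn_tab <- matrix(NA_real_, n_sub, n)
  beta_star <- numeric(n_sub)
  for (s in seq_len(n_sub)) {
    prof <- tryCatch(
      subject_synergy_profile(matrices[[s]], config,
                              seed = derive_seed(config$seed, "subject",
                                                 manifest$subject_id[s]),
                              triplets = frame_triplets,
                              beta_fixed = beta_fixed),
      error = function(e) {
        warning("subject ", manifest$subject_id[s], " failed: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(prof)) next
    syn_tab[s, ] <- prof$synergy
    beta_star[s] <- prof$critical_beta
  }
  done <- rowSums(is.finite(syn_tab) | is.nan(syn_tab)) > 0
  if (sum(done) < 10) stop("fewer than 10 subjects simulated successfully")
  syn_tab <- syn_tab[done, , drop = FALSE]
  manifest <- manifest[done, ]
  beta_star <- beta_star[done]
  age_result <- run_age_analysis(syn_tab, manifest$age, alpha = config$alpha,
                                 n_boot = config$n_boot,
                                 seed = derive_seed(config$seed, "age"),
                                 labels = matrices[[1]]$labels)
  sig_nodes <- age_result$node[age_result$significant]
  strength_result <- if (length(sig_nodes) > 0) {
    strength_age_followup(matrices[done], manifest$age, nodes = sig_nodes,
                          alpha = config$alpha, n_boot = config$n_boot,
                          seed = derive_seed(config$seed, "strength"))
  } else NULL
  out <- structure(list(ages = manifest$age, critical_betas = beta_star,
                        synergy_table = syn_tab, age_result = age_result,
                        strength_result = strength_result,
                        subjects_used = manifest$subject_id, config = config),
                   class = "cohort_analysis")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(age_result),
                     file.path(out_dir, "age_association.csv"), row.names = FALSE)
    if (!is.null(strength_result)) {
      utils::write.csv(as.data.frame(strength_result),
                       file.path(out_dir, "strength_followup.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(data.frame(subject_id = manifest$subject_id,
                                age = manifest$age,
                                critical_beta = beta_star),
                     file.path(out_dir, "subject_critical_betas.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(config = unclass(config),
                              n_subjects = length(beta_star)),
                         file.path(out_dir, "analysis_params.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("<cohort_analysis> ", length(x$ages), " subjects, ",
      ncol(x$synergy_table), " nodes\n", sep = "")
  cat("  critical beta range: [",
      format(min(x$critical_betas), digits = 3), ", ",
      format(max(x$critical_betas), digits = 3), "]\n", sep = "")
  print(x$age_result)
  invisible(x)
}
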