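#' Glauber single-flip probability
#'
#' The probability that a spin flips given the energy change `delta_E` the
#' flip would cause, at inverse temperature `beta`:
#' `1 / (1 + exp(beta * delta_E))`.  At `beta = 0` every spin has exactly a
#' 50% chance to flip regardless of its neighbourhood.
#'
#' @param delta_E energy change(s) of the proposed flip.
#' @param beta inverse temperature (>= 0).
#' @return flip probability in \[0, 1\]; vectorized over `delta_E`.
#' @export
flip_probability <- function(delta_E, beta) {
  if (any(beta < 0)) stop("beta must be >= 0")
  if (any(!is.finite(delta_E))) stop("delta_E must be finite")
  1 / (1 + exp(beta * delta_E))
}

#' Total energy of a spin configuration
#'
#' `H = -(1/2) * sum_{i,j} J_ij s_i s_j`; the double sum counts each pair
#' twice, hence the half.
#'
#' @param state vector of spins, each -1 or +1.
#' @param C a `connectivity_matrix`.
#' @return scalar energy.
#' @export
total_energy <- function(state, C) {
  check_spins(state, n_nodes(C))
  -0.5 * as.numeric(state %*% C$weights %*% state)
}

#' Energy change of flipping one spin
#'
#' `delta_E_i = 2 * s_i * sum_j J_ij s_j`, the exact difference
#' `H(flipped) - H(current)`.
#'
#' @param state spin vector (-1/+1).
#' @param C a `connectivity_matrix`.
#' @param i node index (1-based).
#' @return scalar energy change.
#' @export
delta_energy <- function(state, C, i) {
  check_spins(state, n_nodes(C))
  if (i < 1 || i > n_nodes(C)) stop("node index out of range")
  2 * state[i] * sum(C$weights[i, ] * state)
}

check_spins <- function(state, n) {
  if (length(state) != n) stop("state length does not match network size")
  if (!all(state %in% c(-1L, 1L))) stop("spins must be -1 or +1")
  invisible(TRUE)
}

#' One Glauber sweep
#'
#' Updates every spin exactly once, in a fresh random permutation, each
#' update flipping with probability [flip_probability()] of the energy change
#' computed against the current (sequentially updated) configuration.
#' Randomness comes from R's RNG, so `set.seed()` makes sweeps reproducible.
#'
#' @param state spin vector (-1/+1).
#' @param C a `connectivity_matrix`.
#' @param beta inverse temperature.
#' @return the updated spin vector.
#' @export
glauber_sweep <- function(state, C, beta) {
  check_spins(state, n_nodes(C))
  if (beta < 0) stop("beta must be >= 0")
  as.integer(glauber_sweep_cpp(C$weights, beta, as.integer(state)))
}

#' Simulate Glauber dynamics at fixed inverse temperature
#'
#' Runs `discard` unrecorded equilibration sweeps followed by `collect`
#' recorded sweeps; one configuration is recorded per completed sweep, so the
#' sample at row `t` is the full-system state after `t` sweeps.
#'
#' @param C a `connectivity_matrix`.
#' @param beta inverse temperature.
#' @param initial initial spin vector; default random +/-1.
#' @param discard equilibration sweeps (unrecorded).
#' @param collect recorded sweeps (>= 1).
#' @param seed optional RNG seed (`set.seed` applied if non-NULL).
#' @return a `spin_series` object: list with `samples` (collect x n matrix of
#'   -1/+1), `beta`, `final` state (for adiabatic continuation), and
#'   `flip_rate` (per-spin fraction of recorded sweeps in which the spin
#'   changed state).
#' @export
simulate_at_beta <- function(C, beta, initial = NULL, discard = 0L,
                             collect = 1000L, seed = NULL) {
  stopifnot(inherits(C, "connectivity_matrix"))
  if (collect < 1) stop("collect must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- n_nodes(C)
  if (is.null(initial)) initial <- sample(c(-1L, 1L), n, replace = TRUE)
  check_spins(initial, n)
  res <- glauber_run_cpp(C$weights, beta, as.integer(initial),
                         as.integer(discard), as.integer(collect), TRUE)
  structure(list(samples = res$samples, beta = beta,
                 final = as.integer(res$final),
                 flip_rate = res$flip_count / collect),
            class = "spin_series")
}

#' @export
print.spin_series <- function(x, ...) {
  cat("<spin_series> beta = ", format(x$beta), ", ",
      nrow(x$samples), " sweeps x ", ncol(x$samples), " spins\n", sep = "")
  invisible(x)
}

#' Susceptibility of a recorded spin series
#'
#' `chi = N * beta * (<m^2> - <|m|>^2)` with `m(t)` the mean spin at sweep
#' `t`.  Using `|m|` makes the estimator well defined on finite systems where
#' the magnetization flips sign.
#'
#' @param series a `spin_series`, or a T x N sample matrix.
#' @param beta inverse temperature; taken from the series if missing.
#' @return nonnegative scalar.
#' @export
susceptibility <- function(series, beta = NULL) {
  if (inherits(series, "spin_series")) {
    if (is.null(beta)) beta <- series$beta
    samples <- series$samples
  } else {
    samples <- series
    if (is.null(beta)) stop("beta required when passing a bare matrix")
  }
  if (nrow(samples) < 2) stop("need at least 2 recorded sweeps")
  m <- rowMeans(samples)
  ncol(samples) * beta * max(mean(m^2) - mean(abs(m))^2, 0)
}

#' Simulation protocol
#'
#' Bundles the Glauber sweep schedule.  The `"paper"` preset carries the
#' full-scale protocol (relaxation 1e5, discard 1e4 and collect 1e6 sweeps
#' per temperature, 20 runs at each of 80 temperature points); the `"desk"`
#' preset is an explicitly scaled-down schedule for interactive use and
#' testing (20 points, 3 runs, 2e4 collected sweeps).
#'
#' @param betas strictly increasing grid of inverse temperatures.
#' @param relaxation sweeps run once at the first beta before recording.
#' @param discard sweeps discarded at each subsequent beta.
#' @param collect recorded sweeps per beta per run.
#' @param runs independent adiabatic chains per beta grid.
#' @param seed master seed; run `r` uses `seed + r - 1`.
#' @param normalization weight normalization: `"mean_positive"` divides
#'   couplings by the mean positive weight (so the critical beta is O(1) on
#'   lattice-like graphs), `"spectral"` divides by the leading eigenvalue
#'   (critical beta near 1 on dense mean-field-like graphs), `"none"` leaves
#'   raw weights.  Normalization only rescales the beta axis.
#' @param keep_series if TRUE, recorded series are kept per beta for
#'   downstream information decomposition.
#' @return a `simulation_protocol` list.
#' @export
simulation_protocol <- function(betas, relaxation = 1e5, discard = 1e4,
                                collect = 1e6, runs = 20, seed = 1L,
                                normalization = c("mean_positive", "spectral", "none"),
                                keep_series = TRUE) {
  normalization <- match.arg(normalization)
  betas <- as.numeric(betas)
  if (length(betas) < 1 || any(diff(betas) <= 0)) {
    stop("betas must be a non-empty strictly increasing grid")
  }
  if (any(c(relaxation, discard, collect, runs) < 1)) stop("all counts must be >= 1")
  structure(list(betas = betas, relaxation = relaxation, discard = discard,
                 collect = collect, runs = runs, seed = as.integer(seed),
                 normalization = normalization, keep_series = keep_series),
            class = "simulation_protocol")
}

#' Preset protocols
#'
#' @param preset `"paper"` (full-scale) or `"desk"` (scaled-down).
#' @param betas beta grid; defaults to 80 (paper) or 20 (desk) points on
#'   \[0.1, 2\].
#' @param seed master seed.
#' @param ... further arguments to [simulation_protocol()].
#' @return a `simulation_protocol`.
#' @export
protocol_preset <- function(preset = c("desk", "paper"), betas = NULL,
                            seed = 1L, ...) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    if (is.null(betas)) betas <- seq(0.1, 2, length.out = 80)
    simulation_protocol(betas, relaxation = 1e5, discard = 1e4, collect = 1e6,
                        runs = 20, seed = seed, ...)
  } else {
    if (is.null(betas)) betas <- seq(0.1, 2, length.out = 20)
    simulation_protocol(betas, relaxation = 2e3, discard = 1e3, collect = 2e4,
                        runs = 3, seed = seed, ...)
  }
}

#' Suggest a beta grid enclosing the transition
#'
#' Centres a linear grid on the mean-field estimate of the critical coupling,
#' `1 / lambda_max(J_normalized)`, spanning a factor range wide enough to
#' enclose the susceptibility peak of both lattice-like and dense
#' heterogeneous graphs.
#'
#' @param C a `connectivity_matrix`.
#' @param n_points grid size.
#' @param normalization as in [simulation_protocol()].
#' @param span multiplicative range around `1/lambda_max`.
#' @return numeric beta grid.
#' @export
suggest_beta_grid <- function(C, n_points = 20,
                              normalization = "mean_positive",
                              span = c(0.4, 8)) {
  w <- normalize_weights(C$weights, normalization)
  lam <- max(eigen(w, symmetric = TRUE, only.values = TRUE)$values)
  seq(span[1] / lam, span[2] / lam, length.out = n_points)
}

normalize_weights <- function(w, normalization) {
  switch(normalization,
         mean_positive = {
           mp <- mean(w[w > 0])
           if (!is.finite(mp) || mp == 0) w else w / mp
         },
         spectral = {
           lam <- max(eigen(w, symmetric = TRUE, only.values = TRUE)$values)
           if (lam > 0) w / lam else w
         },
         none = w,
         stop("unknown normalization: ", normalization))
}

#' Adiabatic temperature sweep
#'
#' Runs the full Glauber protocol on a network: for each independent run, an
#' initial relaxation at the first (smallest) beta from a random
#' configuration, then an adiabatic chain over the increasing beta grid where
#' each temperature starts from the previous one's final configuration.  At
#' each beta, `discard` sweeps are dropped and `collect` sweeps recorded; the
#' mean absolute magnetization, susceptibility and per-spin flip rate are
#' computed per run and averaged across runs.
#'
#' @param C a `connectivity_matrix`.
#' @param protocol a [simulation_protocol()].
#' @return an `ising_sweep` object: `betas`, `chi` (across-run mean
#'   susceptibility per beta), `chi_runs` (runs x betas), `mean_abs_m`,
#'   `flip_rate` (betas x nodes, across-run mean), `critical_beta`,
#'   `series` (if kept: per-beta list of per-run sample matrices),
#'   `normalization`, `protocol`.
#' @export
temperature_sweep <- function(C, protocol) {
  stopifnot(inherits(C, "connectivity_matrix"),
            inherits(protocol, "simulation_protocol"))
  w <- normalize_weights(C$weights, protocol$normalization)
  nb <- length(protocol$betas)
  n <- n_nodes(C)
  chi_runs <- matrix(NA_real_, protocol$runs, nb)
  m_runs <- matrix(NA_real_, protocol$runs, nb)
  flip <- array(0, c(protocol$runs, nb, n))
  series <- if (protocol$keep_series) {
    lapply(seq_len(nb), function(i) vector("list", protocol$runs))
  } else NULL
  for (r in seq_len(protocol$runs)) {
    set.seed(protocol$seed + r - 1L)
    state <- sample(c(-1L, 1L), n, replace = TRUE)
    res <- glauber_run_cpp(w, protocol$betas[1], state,
                           as.integer(protocol$relaxation), 0L, FALSE)
    state <- as.integer(res$final)
    for (ib in seq_len(nb)) {
      beta <- protocol$betas[ib]
      res <- glauber_run_cpp(w, beta, state, as.integer(protocol$discard),
                             as.integer(protocol$collect), TRUE)
      state <- as.integer(res$final)
      m <- rowMeans(res$samples)
      m_runs[r, ib] <- mean(abs(m))
      chi_runs[r, ib] <- n * beta * max(mean(m^2) - mean(abs(m))^2, 0)
      flip[r, ib, ] <- res$flip_count / protocol$collect
      if (protocol$keep_series) series[[ib]][[r]] <- res$samples
    }
  }
  chi <- colMeans(chi_runs)
  out <- structure(list(betas = protocol$betas, chi = chi, chi_runs = chi_runs,
                        mean_abs_m = colMeans(m_runs),
                        flip_rate = apply(flip, c(2, 3), mean),
                        series = series, normalization = protocol$normalization,
                        protocol = protocol, labels = C$labels),
                   class = "ising_sweep")
  out$critical_beta <- if (nb >= 3) critical_beta(out) else out$betas[which.max(chi)]
  out
}

#' Critical inverse temperature from a sweep
#'
#' The beta at the argmax of the across-run mean susceptibility; a warning is
#' issued when the argmax sits at a grid endpoint, meaning the transition is
#' not enclosed by the grid.
#'
#' @param sweep an `ising_sweep`, or a list with `betas` and `chi`.
#' @return scalar beta.
#' @export
critical_beta <- function(sweep) {
  if (length(sweep$betas) < 3) stop("need at least 3 beta grid points")
  i <- which.max(sweep$chi)
  if (i == 1L || i == length(sweep$betas)) {
    warning("susceptibility peak at grid endpoint: transition not enclosed")
  }
  sweep$betas[i]
}

#' @export
print.ising_sweep <- function(x, ...) {
  cat("<ising_sweep> ", length(x$betas), " beta points in [",
      format(min(x$betas), digits = 4), ", ", format(max(x$betas), digits = 4),
      "], ", nrow(x$chi_runs), " run(s)\n", sep = "")
  cat("  critical beta (chi peak): ", format(x$critical_beta, digits = 4),
      "  (normalization: ", x$normalization, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.ising_sweep <- function(object, ...) {
  df <- data.frame(beta = object$betas, chi = object$chi,
                   mean_abs_m = object$mean_abs_m,
                   mean_flip_rate = rowMeans(object$flip_rate))
  cat("Adiabatic Glauber sweep over", length(object$betas), "temperatures,",
      nrow(object$chi_runs), "run(s) each\n")
  cat("Critical beta:", format(object$critical_beta, digits = 4), "\n\n")
  print(df, row.names = FALSE, digits = 4)
  invisible(df)
}

#' @export
plot.ising_sweep <- function(x, ...) {
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  plot(x$betas, x$chi, type = "b", xlab = expression(beta),
       ylab = expression(chi), main = "Susceptibility", ...)
  graphics::abline(v = x$critical_beta, lty = 2)
  plot(x$betas, x$mean_abs_m, type = "b", xlab = expression(beta),
       ylab = "<|m|>", main = "Magnetization", ...)
  invisible(x)
}

#' Freezing inverse temperature per spin
#'
#' The first beta on the grid at which a spin's flip rate drops below the
#' given threshold; NA if it never does.  On heterogeneous networks the
#' freezing beta is smaller for stronger nodes (they freeze while the system
#' is still hot).
#'
#' @param sweep an `ising_sweep`.
#' @param threshold flip-rate threshold (default 0.25).
#' @return numeric vector, one freezing beta per node.
#' @export
freezing_beta <- function(sweep, threshold = 0.25) {
  apply(sweep$flip_rate, 2, function(fr) {
    i <- which(fr < threshold)[1]
    if (is.na(i)) NA_real_ else sweep$betas[i]
  })
}
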