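---
title: "Ising dynamics, synergy, and aging on weighted connectomes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ising dynamics, synergy, and aging on weighted connectomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models, estimators and design
choices.  It states no empirical numbers beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The model

A structural connectome is a symmetric, nonnegative, zero-diagonal weight
matrix $J_{ij}$ over $N$ labelled regions, with streamline-count-like weights.
On it we run kinetic Ising (Glauber) dynamics: spins $s_i = \pm 1$, energy

$$\mathcal{H} = -\tfrac{1}{2}\sum_{i,j} J_{ij} s_i s_j,$$

and single-spin updates that flip $s_i$ with probability
$1/(1 + e^{\beta \Delta E_i})$, where
$\Delta E_i = 2 s_i \sum_j J_{ij} s_j$ is the exact energy change of the flip
and $\beta$ the inverse temperature.  Within one sweep every spin is updated
exactly once, in a fresh random permutation: the update *count* per iteration
is fixed by the sampling convention (one recorded configuration per sweep);
the *order* is randomized to avoid artifacts of a fixed scan order.  At
$\beta = 0$ every spin flips with probability exactly one half regardless of
the network.

An adiabatic sweep (`temperature_sweep()`) starts from a random configuration
at the smallest $\beta$ (the disordered side), relaxes, and then carries the
final configuration of each temperature over to the next.  The susceptibility
is estimated as

$$\chi = N\beta\,(\langle m^2\rangle - \langle |m|\rangle^2),
\qquad m(t) = \tfrac{1}{N}\sum_i s_i(t),$$

using $|m|$ because on finite systems the magnetization changes sign; the
$\beta$ at the argmax of the across-run mean $\chi$ defines the critical
state.  A warning is raised when the argmax sits on a grid endpoint (the grid
does not enclose the transition).

**Weight normalization.**  Raw streamline-like weights put the transition at
tiny $\beta$.  Normalization only rescales the $\beta$ axis; three modes are
provided.  `mean_positive` (default) divides by the mean positive weight,
which makes lattice-like couplings order one.  `spectral` divides by the
leading eigenvalue $\lambda_{\max}(J)$, pinning the mean-field critical
coupling near 1; because $\lambda_{\max}$ is dominated by the hub block, this
mode keeps the $\beta$ axis of a cohort comparable across subjects whose
peripheral connectivity differs — which is why the cohort workflow uses it.
`none` leaves raw weights.  `suggest_beta_grid()` centres a linear grid on
$1/\lambda_{\max}$ with a wide multiplicative span, because on heavy-tailed
networks hub freezing and the bulk transition can be more than a decade of
$\beta$ apart.

**Update-count interpretation.**  The full-scale protocol constants
(relaxation $10^5$, discard $10^4$, collect $10^6$, 20 runs, 80 temperatures)
are carried by the `paper` preset, interpreting the counts as full sweeps,
since one time series value per spin is recorded per full-system iteration.
This interpretation is configurable through `simulation_protocol()`.

## Information decomposition

For target spin $s_i$ and source set $\{s_j,\dots\}$ the transfer entropy is
the conditional mutual information
$\mathcal{T}_{\{j\dots\}\to i} = I(\tilde s_i; s_j,\dots \mid s_i)$ with
$\tilde s_i$ the target one step ahead.  All probabilities are plugin
(empirical frequency) estimates over 8- or 16-cell tables; $0\log 0 = 0$;
counts from independent runs at the same temperature are pooled by summation
(never by concatenating series across run boundaries).  Information is
measured in bits.  No bias correction is applied, matching the plugin
convention; at the collection lengths used here the plugin bias
$(\text{cells}-1)/(2T\ln 2)$ is far below the effects of interest, and the
tests that compare estimates against analytic values budget for it
explicitly.

With two sources, the decomposition

$$\mathcal{T}_{jk\to i} = \mathcal{U}_{j\to i} + \mathcal{U}_{k\to i}
  + \mathcal{R}_{jk\to i} + \mathcal{S}_{jk\to i},\qquad
  \mathcal{T}_{j\to i} = \mathcal{U}_{j\to i} + \mathcal{R}_{jk\to i},\qquad
  \mathcal{T}_{k\to i} = \mathcal{U}_{k\to i} + \mathcal{R}_{jk\to i}$$

is closed by one additional definition:

* **MMI** (default): $\mathcal{R} = \min(\mathcal{T}_{j\to i},
  \mathcal{T}_{k\to i})$.  Algebraically closed, nonnegative terms whenever
  all three transfer entropies come from one pooled table (the package always
  computes the single-source terms by marginalizing the 16-cell table, which
  guarantees this).
* **Constrained minimization** (`pid_bertschinger()`):
  $\mathcal{S} = \mathcal{T}(p) - \min_{q \in \Delta_p} \mathcal{T}(q)$,
  where $\Delta_p$ fixes the marginals linking target and each single source.
  The defining construction is written for a static triple; in the lagged
  setting the package fixes the *trivariate* marginals
  $(\tilde s_i, s_i, s_j)$ and $(\tilde s_i, s_i, s_k)$ — this is an
  interpretation, flagged here, chosen because the target's own past is part
  of the conditioning in every transfer-entropy term.  Under these
  constraints each of the four $(\tilde s_i, s_i)$ blocks of the table is a
  $2\times 2$ table with fixed margins, leaving at most four free bounded
  coordinates; the objective is minimized by L-BFGS-B from deterministic
  multi-starts (block corners, midpoint, blockwise independence, and $p$
  itself).  Since $q = p$ is feasible, $\mathcal{S} \ge 0$ by construction.

The suite verifies that the two definitions agree to well under 0.01 bits on
distributions estimated from the simulated dynamics, so MMI (orders of
magnitude cheaper) is the default throughout the pipeline.

## Triplets and per-node profiles

Targets receive information from source *pairs*.  Three selection rules:

* `dense`: all $N\binom{N-1}{2}$ triplets, for dense average connectomes,
  with seeded uniform subsampling above a cap (the per-node mean synergy is
  unbiased under uniform subsampling);
* `sparse`: both source-to-target links must survive a global weight
  threshold chosen so that a fixed fraction (default 20%) of all pairs is
  retained; ties at the threshold are excluded so the target density is never
  overshot.  This is the rule for sparse individual matrices;
* `top_k`: each target takes its `k_sources` heaviest in-edges and all their
  pairs.  This guarantees every node a profile on sparse matrices (the global
  threshold can orphan weakly connected nodes) and keeps the number of
  triplets per node constant.

A node's **incoming synergy** is the mean $\mathcal{S}$ over the selected
triplets targeting it; nodes with no qualifying triplet report `NaN`, never
zero, so averages are not diluted.  `synergy_threshold_stability()` recomputes
profiles at 15/20/25% density and reports rank stability, the built-in
robustness check on the arbitrary threshold.  Incoming/outgoing transfer
entropy profiles are plain means of pairwise TE over drivers/targets.

## The synthetic generators

The 2D periodic lattice (`generate_lattice2d`) is the validation surface: its
susceptibility peak must fall near the known infinite-size critical coupling
$\approx 0.4407$, with a finite-size shift, which the acceptance suite checks
on $L = 16$.

`generate_heterogeneous_connectome()` emulates the statistical structure of a
group-average connectome, not its anatomy: node fitnesses are Pareto with
tail exponent 2.5 (heavy-tailed strengths, in line with the strongly
right-skewed strength distributions of streamline-count connectomes), weights
are fitness products with lognormal noise, and the top fitness decile is
boosted threefold among itself, planting a rich club knit by the largest
weights.  Note that multiplicative fitness weights carry an *emergent*
weight rich club even with no planted core (high-fitness pairs share the
largest products), so the boost strengthens an organization the weight model
already has; the true null for the rich-club ratio is a weight-shuffled
graph, not the zero-boost generator.  The generator makes no attempt at
spatial embedding or distance-dependent wiring; consequences are discussed
under Limitations.

`generate_aging_cohort()` draws subject ages uniformly over 4–85 years (the
lifespan range of the cohorts this emulates), scales every edge incident to
an effect node by a per-decade factor — linear, or piecewise-linear ramping
to a plateau at a saturation age, the simplest shape matching
maturation-then-plateau trajectories — applies symmetric lognormal edge
noise, and drops each subject's weakest pairs (deterministic given the noise),
mimicking tractography's weak-connection dropout.  Multipliers are clipped at
0.05 so weights stay positive.

**The reference recovery experiment** (`demo_aging_cohort()` +
`demo_cohort_config()`) plants three linearly increasing and two linearly
decreasing nodes (8%/decade, noise 0.05, sparsity 0.2, 60 subjects, 30
nodes).  Two placement rules, both decided from the physics of the model and
fixed once:

* effect nodes sit in the low-to-mid strength range, where incoming synergy
  is monotone in the node's coupling scale at criticality (strong nodes are
  near or past their synergy peak, so scaling them further produces flat or
  non-monotone age responses);
* effect nodes are chosen among nodes that appear in *no other node's*
  strongest-source set, which localizes the planted signal: scaling a node's
  edges also perturbs the triplets of targets that use those edges as
  sources, and when a planted node serves as a top source elsewhere this
  information-flow spillover can rival the target effect itself.

The analysis side uses `top_k` triplets selected once on the cohort-average
connectome (a fixed measurement frame across subjects; the per-subject
`sparse` rule remains the default elsewhere and is the faithful choice for
purely observational use), spectral normalization (see above), and a
two-stage schedule per subject: short runs (two chains of 2 500 sweeps per
temperature) over a fixed 28-point $\beta$ grid locate the subject's
susceptibility peak, then one long run (60 000 sweeps) at that $\beta$
provides the plugin tables.  The long dedicated run pushes the per-triplet
plugin bias and variance well below the planted effect; spending the same
budget across the whole grid would not.

Two aspects of this schedule matter more than they look.  First, evaluating
every subject at its *own* critical $\beta$ is not just fidelity to the
procedure — it is the control that absorbs cohort-wide coupling drift: the
planted effects change each subject's total coupling slightly with age, and
at any *fixed* $\beta$ that drift shows up as a coherent, spurious age trend
across all nodes (the package's `beta_mode = "cohort"` sensitivity mode
demonstrates this).  Second, the $\beta$ grid must be fine enough for the
located peak to track that drift: with a coarse grid the peak is quantized,
the residual sub-grid drift leaks into the synergy of exactly the most
$\beta$-sensitive nodes (the weakest nodes on their steep rising branch, and
the hubs near freezing), and those nodes acquire systematic false trends.
The 28-point grid makes the quantization step small relative to the
between-subject spread of critical $\beta$.

## Robust age association

Per node, synergy-versus-age association uses the skipped Spearman
correlation: bivariate outliers are removed by the projection rule (project
all points on every direction through the spatial median; flag any point
violating the MAD-median rule at cutoff $\sqrt{\chi^2_{0.975,2}}$ on any
direction — deterministic, no tuning), and Spearman's $\rho$ is computed on
the survivors.  The robust-statistics literature this estimator comes from
names the procedure but not its p-value mechanics; the package uses a seeded
percentile bootstrap of
the *skipped* estimator: cleaned pairs are resampled and the outlier
detection is re-run inside every bootstrap replicate, so the selection step's
variability enters the null calibration.  (Bootstrapping with a frozen
outlier mask is markedly anticonservative — the suite's type-I-error
simulation is the regression test for this choice.)  The two-sided p value is
twice the smaller tail mass of the bootstrap distribution around zero,
floored at $1/B$.  Zero-variance columns report $\rho = 0$, $p = 1$ with a
degeneracy flag rather than erroring, so one bad node cannot abort a cohort
run.  Family-wise error across nodes is controlled by Hochberg's step-up
procedure at $\alpha = 0.05$ (via `stats::p.adjust`), with the hand-worked
step-up examples asserted in the tests.

Each subject's synergy is evaluated at that subject's own critical $\beta$;
this is also what makes the cohort analysis insensitive to overall weight
scale, since a global rescaling of a subject's matrix only shifts its
$\beta$ axis.

## Numerical choices

* RNG: all C++ code draws from R's generator, so `set.seed()` governs every
  result; pipeline stages derive their seeds as a pure hash of (master seed,
  stage name, subject id), making partial reruns and any execution order
  reproducible.
* Susceptibility uses the $|m|$ estimator (above); $\chi$ is clamped at 0
  against floating-point cancellation.
* Plugin tables: counts are tabulated in C++ for the batch paths
  (`triplet_pid_batch`, `pair_te_batch`); the batch estimators are tested to
  be exactly equal to the scalar ones.
* The constrained-minimization optimizer tolerance is $10^{-9}$ on the
  objective with up to 500 iterations per start; with all-corner multi-starts
  this is belt-and-braces for a convex objective on a box.
* Thresholding ties: excluded (conservative, deterministic).
* Asymmetry tolerance on input matrices: $10^{-8}$ relative, enough for text
  round-off, small enough to catch genuinely directed input.
* Degenerate inputs: all-equal off-diagonal weights make a density target
  unreachable (warning + empty mask); disconnected graphs get per-component
  closeness with a warning; frozen (constant) series give zero synergy.

## Problem sizes

Everything in the tests and the acceptance script runs at desk scale, chosen
as the package's standard study conditions: $L = 16$ lattices; 50-node
connectomes with 24-point grids, 3 runs and 8 000 collected sweeps for the
average-network claims; the 60-subject recovery experiment above; 200
simulated null datasets for the calibration check.  The `paper` preset
reproduces the full-scale protocol constants for users with the budget to run
them.

## Limitations

* The generator is not spatially embedded, so topology metrics that hinge on
  geometry are collinear in a way real connectomes' are not: in particular
  closeness and strength rank nearly together on synthetic networks, and the
  empirical observation that synergy associates more with centrality than
  with strength is *not* reproduced (and not asserted) on them.  The
  association function itself is exercised against oracle values instead.
* Plugin TE with one step of target history; longer histories and continuous
  estimators are out of scope.
* Two-source decompositions only; no higher-order PID lattices, and no global
  (all-driver) transfer entropy, whose estimation is infeasible at these
  dimensions.
* The recovery experiment demonstrates sensitivity under its stated
  conditions — localized planted effects, low noise — not a general detection
  guarantee; diffuse or interacting effects entangle targets through
  information-flow spillover, which the placement rules above deliberately
  avoid.
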