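# isingsyn

Kinetic Ising dynamics and synergistic information flow on weighted
structural connectomes, with robust cohort-level aging analysis.

## What it does, and for whom

For researchers who study how brain structure constrains simulated dynamics:
the package implements an end-to-end pipeline that

1. reads symmetric, nonnegative connectivity matrices (dense text adjacency
   files with a `subject_id,age,path` cohort manifest),
2. simulates Glauber dynamics of the Ising model
   `H = -(1/2) Σ J_ij s_i s_j`, with flip probability
   `1/(1 + exp(β ΔE_i))`, `ΔE_i = 2 s_i Σ_j J_ij s_j`, over an adiabatic
   inverse-temperature sweep, locating the critical state at the peak of the
   susceptibility `χ = Nβ(⟨m²⟩ − ⟨|m|⟩²)`,
3. estimates directed information flow between spins with plugin transfer
   entropy `T_{j→i} = I(s̃_i ; s_j | s_i)` and decomposes the two-source
   transfer entropy into unique, redundant and synergistic parts
   (`T_{jk→i} = U_j + U_k + R + S`), closing the system with the
   minimum-mutual-information redundancy `R = min(T_j, T_k)` and
   cross-checking against the constrained-minimization synergy
   `S = T(p) − min_{q∈Δ_p} T(q)`,
4. profiles each node's incoming synergy (mean `S` over triplets targeting
   it) against strength, betweenness and closeness, and traces hub synergy
   across temperature — on heterogeneous rich-club networks the hubs' synergy
   peaks *before* the critical temperature, a precursor of the transition,
5. across a cohort, correlates per-node incoming synergy (each subject
   evaluated at its own critical β) with age using the skipped Spearman
   correlation (projection-based bivariate outlier removal, bootstrap p
   values) under Hochberg family-wise error control at α = 0.05.

Synthetic generators (2D lattices, heterogeneous rich-club connectomes,
aging cohorts with planted node effects) make the whole pipeline testable
without any data download.

## Worked example

```r
library(isingsyn)

C <- generate_heterogeneous_connectome(30, seed = 42)
cfg <- pipeline_config(triplet_mode = "dense", max_triplets = 2000, seed = 1,
                       sweep = list(n_beta = 16, runs = 2, collect = 4000,
                                    discard = 400, relaxation = 800))
res <- run_average_analysis(C, cfg)
res
```

```
<average_analysis>
  critical beta: 0.04016
  node profile: 30 nodes
  synergy-topology rank correlations:
      metric    rho  n
    strength  0.366 30
 betweenness -0.448 30
   closeness  0.275 30
```

The critical beta is the susceptibility-peak β on the suggested grid
(mean-weight-normalized couplings, hence the small scale: normalization only
rescales the β axis).  The rank correlations relate each node's incoming
synergy at criticality to its topology.  `res$hub_curves$peak_beta` holds
each top-strength hub's synergy-peak β; the strongest hubs peak below
`res$critical_beta` — hub synergy as a precursor of the transition:

```r
res$hub_curves$peak_beta < res$critical_beta
#> [1]  TRUE  TRUE  TRUE FALSE FALSE
```

(On the 50-node networks with finer sweeps used by the test suite, all five
top hubs peak strictly before criticality.)

For a cohort with planted aging effects:

```r
x <- demo_aging_cohort(n_subjects = 60, n_nodes = 30, replicate_seed = 1001)
res <- run_cohort_analysis(x$cohort, demo_cohort_config(seed = 8))
res$age_result
```

```
Per-node synergy-age association (skipped Spearman, Hochberg FWER, alpha = 0.05)
60 subjects, 30 nodes, 5 significant

 node    label    rho  p_raw p_hochberg significant sign n_used degenerate
    9 node_008 -0.901 0.0005      0.013        TRUE    -     60      FALSE
   11 node_010  0.807 0.0005      0.013        TRUE    +     60      FALSE
   14 node_013  0.696 0.0005      0.013        TRUE    +     60      FALSE
   16 node_015 -0.915 0.0005      0.013        TRUE    -     60      FALSE
   25 node_024  0.744 0.0005      0.013        TRUE    +     60      FALSE
   23 node_022 -0.238 0.0370      0.925       FALSE    -     60      FALSE
 ...
```

The five significant nodes are exactly the five planted effect nodes
(`x$planted`), with the planted signs.

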