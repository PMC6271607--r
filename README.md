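# stickyslds

Bayesian nonparametric state segmentation for noisily measured
single-particle-tracking (SPT) trajectories.

A tracked molecule in a live cell wanders through hidden kinetic states —
free diffusion, slowed diffusion, confinement, an abruptly relocated
harmonic well — and the microscope reports its position only up to
localization noise that is often as large as the per-frame displacement.
`stickyslds` segments such trajectories without fixing the number of
states in advance: each state is a discretized overdamped-Langevin
(multivariate Ornstein–Uhlenbeck) diffusion

    r[i+1] = mu_k + F_k r[i] + eta,   eta ~ N(0, Sigma_k)
    psi[i] = H r[i] + eps,            eps ~ N(0, R)

and switching among states carries a *sticky* hierarchical Dirichlet
process prior (weak-limit truncation), so the number of occupied states,
the state sequence, the per-state kinetics (diffusion matrix, corral
rate, fixed point) and the localization-noise covariance are inferred
jointly by a blocked Gibbs sampler: simulation smoother for the latent
path, forward-filter backward-sampling for the labels, conjugate
matrix-normal inverse-Wishart updates for the dynamics, and
auxiliary-variable draws for the HDP concentrations and the stickiness
rho = kappa/(alpha+kappa).

The package also ships the benchmark machinery around the sampler: a
region-switching 3D trajectory simulator (diffusivity drops, confinement
changes, fixed-point shifts driven by where the particle is),
label-aligned Hamming-distance scoring with exact (Hungarian-equivalent)
label assignment, and an experiment layer that re-analyzes a fixed
simulated ensemble under matched and deliberately misspecified priors.

## Worked example

Simulate one benchmark trajectory, fit it, and score the segmentation:

```r
library(stickyslds)

cfg   <- dgp_config(n_obs = 1000, n_traj = 1, seed = 5001) # 22 Hz, 3D DGP
tr    <- simulate_trajectory(cfg)
table(tr$s)                          # this draw mixes states 1, 2 and 4
#>   1   2   4
#> 882  52  66
prior <- build_prior_from_dgp(cfg, mode = "exact")        # matched base measure
fit   <- hdpslds(tr$psi, dt = cfg$dt, prior = prior,
                 hyper = hdp_config(n_sweeps = 2000), seed = 11)

print(fit)
#> Sticky HDP-SLDS fit: 1000 observations, d = 3 , d_obs = 3
#>   inferred states (point estimate): 2
#>   occupancy: 4 = 934, 10 = 66

average_hamming(tr$s, fitted(fit))
#> Segmentation match: Hamming = 0.066  Match Score = 0.934
```

A Match Score of 0.934 means 93.4% of the 1000 time points received the
correct state label after optimally matching the sampler's arbitrary
label identities (here 4 and 10) to the simulator's. In this draw the
brief slow-diffusion excursion (state 2, 52 frames) was merged into the
base state — exactly the kind of error the ensemble benchmarks quantify —
while the shifted-well segment (state 4) was recovered frame-accurately.

`summary(fit)` reports per-state
posterior-mean kinetics (with physical diffusion coefficients recovered
through the exact continuous-time embedding), `plot(fit, truth = tr$s)`
overlays the inferred and true label sequences, and `coef`, `residuals`,
`predict` and `simulate` behave as for any fitted R model.

The scenario layer reproduces the benchmark tables at any scale:

```r
dgp <- dgp_config(n_obs = 1000, n_traj = 8, seed = 1)
ens <- simulate_ensemble(dgp, min_states = 2)
reports <- lapply(c("baseline", "D_div4", "R_div4"), function(nm)
  run_scenario(scenario_config(nm, dgp = dgp, n_sweeps = 800), ensemble = ens))
summarize_tables(reports)
```

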