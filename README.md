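# blanketrg

Multiscale characterization of coupled stochastic dynamics through Markov
blankets and the renormalization group, for systems-neuroscience time series
(resting-state or task fMRI, calcium imaging, or any spatially embedded
multivariate recording) and for the synthetic linear systems needed to
validate such analyses end to end.

The package answers three questions in sequence:

1. **Who couples to whom?** From a multivariate time series it estimates a
   sparse, directed Jacobian `J` (effective connectivity, in Hz) for the
   linearized state-space model

   ```
   dx/dt = J x + C u + omega,     y = k * x + noise
   ```

   by turning the model into a row-wise general linear model in the
   temporal derivative of the observations, `D y = y J' + omega` with
   structured noise covariance `sum_ij gamma_ij K_i K_j' + gamma_D D D' +
   gamma_I I`, solved by variational Laplace (Gaussian posteriors over each
   row, lognormal priors over the covariance scales) and sparsified by
   Bayesian model reduction: couplings beyond 32 mm are precluded, a pair
   of reciprocal connections is removed when dropping both raises the model
   evidence by 3 nats (a 20:1 odds ratio), and a family of distance-bounded
   models is scored to find the most likely coupling radius.

2. **What are the particles?** States are grouped into *particles* —
   internal states wrapped in a Markov blanket of sensory and active
   states — using the blanket-forming matrix `B = A + A' + A'A` on the
   directed adjacency of `J`, with graph-Laplacian degree picking the
   internal seeds. Internal states of a particle touch nothing outside it,
   so the blanket carries all inter-particle coupling.

3. **What happens across scales?** Each particle's blanket Jacobian is
   reduced to its slow eigenmodes (eigenvalues with `Re > -1` Hz, the
   adiabatic approximation), which become the states of the next scale;
   grouping and reduction are applied recursively. The package then
   characterizes every scale in closed form — transfer functions,
   stationary and cross-covariances, a solenoidal/dissipative (Helmholtz)
   decomposition with per-mode kinetic energies, distance power laws of
   excitatory and inhibitory coupling — and fits the spatiotemporal scaling
   law `sigma_tau = gamma * sigma_len^alpha` across scales, extrapolating
   the geometric cascade to uncharacterized scales.

A synthetic-data module generates spatially embedded ground-truth systems
(Mexican-hat coupling: short-range excitation, inhibitory penumbra;
hemodynamic-like observation kernels; bilateral mirror-symmetric
geometries), so every stage is testable without external data.

## A worked example

```r
library(blanketrg)

## ground truth: 20 states on a bilateral 8 mm grid, Mexican-hat coupling
g   <- make_geometry(10, 8, "grid", seed = 3)
sys <- sample_jacobian(g, seed = 43, eps_stab = 0.1)

## simulate 500 s of latent dynamics; observe through a hemodynamic-like
## kernel at TR = 0.5 s with measurement noise
lat <- simulate_latent(sys, duration = 580, dt = 0.05, seed = 44)
obs <- observe(lat, observation_model(gamma_kernel_basis(0.05),
                                      observation_noise = 0.02, TR = 0.5),
               seed = 45)
obs$values <- obs$values[1:1000, ]

## estimate the sparse Jacobian and coarse-grain it
post  <- estimate_jacobian(obs, g, config = list(TR = 0.5))
summary(post)
#> 20 states; 78 couplings retained (19.5%): 41 excitatory, 37 inhibitory
#> total free energy -7052.23 nats; all rows converged: TRUE

model <- run_rg(coef(post), geometry = g, n_scales = 3, n_internal = 2)
model
#> multiscale_model: 3 scale(s)
#>   scale 1: 20 states, mean Re(lambda) = -0.7954 Hz, 4 particles
#>   scale 2: 11 states, mean Re(lambda) = -0.6172 Hz, 2 particles
#>   scale 3: 9 states, mean Re(lambda) = -0.5771 Hz

fit <- fit_scaling(model)
fit
#> scaling_fit: alpha = 0.793 (sigma_tau = 0.25 * sigma_len^alpha)
#>   per-step factors: time x1.23, space x1.29

extrapolate_scales(fit, c(0, 2, 4))
#>   scale sigma_len sigma_tau
#> 1     0   8.00000  1.303636
#> 2     2  13.31203  1.970499
#> 3     4  22.15128  2.978489
```

The estimate is quantitative, not just structural: on this example the
correlation between estimated and true couplings on the true support is
0.885 (the packaged validation study, `jacobian_recovery_study()`, averages
about 0.95 with support-recovery F1 about 0.85 over seeds). Read the
numbers as: couplings decay on a ~1 s timescale at the finest scale; each
coarse-graining step slows the dynamics by ~1.2x while enlarging spatial
support by ~1.3x, and the cascade extrapolates geometrically in both
directions.

The methods vignette (`vignettes/multiscale-blankets.Rmd`) documents the
model, the priors and thresholds, the difference-scheme and
identifiability caveats, the synthetic study conditions, and known
limitations.

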